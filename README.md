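# csfqtl

Quantitative-trait GWAS and genetic adjustment of CSF protein biomarkers.

Cerebrospinal-fluid (CSF) proteins such as YKL-40 are promising biomarkers
for Alzheimer's disease, but their levels vary widely between individuals.
When a large fraction of that variability is driven by a single genetic
locus that is itself unrelated to disease, the genetic component is pure
noise from the biomarker's point of view — and removing it should sharpen
the biomarker's correlation with disease-linked analytes such as
phosphorylated tau (ptau181). `csfqtl` implements that analysis end to end
for statistical geneticists and biomarker researchers:

1. **Genotype QC** — per-variant call rate, minor allele frequency (MAF)
   and Hardy–Weinberg-equilibrium (HWE) exact-test filters, per-sample call
   rate, duplicate detection by genotype concordance, and EIGENSTRAT-style
   principal components for population structure.
2. **Single-variant association** — for each variant, the additive model

   `y = β₀ + β·G + γᵀC + ε,  G ∈ {0,1,2}`

   where `y` is the log-transformed, standardized biomarker and `C` the
   covariates (age, gender, batch, top PCs); two-sided t tests, the
   genome-wide (`p < 5×10⁻⁸`) and suggestive (`p < 1×10⁻⁵`) classes, the
   genomic inflation factor `λ = median(χ²)/0.4549`, and conditional
   analysis on an index variant.
3. **Variance decomposition** — nested-model ΔR²: the variance explained by
   the top variant over and above the covariates.
4. **Genetic adjustment** — externally studentized residuals of `y` on the
   top variant's allele counts: the genetically residualized biomarker.
5. **Correlation comparison** — Pearson correlations of the unadjusted and
   adjusted biomarker with a target analyte, compared with the Meng Z-test
   for dependent overlapping correlations:

   `Z = (z_jk − z_jh) · sqrt( (n−3) / (2(1−r_kh)h) )`

   with `z` the Fisher transforms, `h = (1 − f·r̄²)/(1 − r̄²)`,
   `f = min(1, (1−r_kh)/(2(1−r̄²)))`, `r̄² = (r_jk² + r_jh²)/2`.
6. **Case/control association** — logistic regression of status on the
   (adjusted or unadjusted) biomarker with covariates.
7. **Cohort simulator** — genotype + phenotype cohorts with exactly the
   structure the analysis assumes (one causal locus, covariate effects, a
   latent factor shared with ptau181/tau, a case-status shift), used by the
   test suite and the calibration script.

## Worked example

Simulate a 379-person cohort (one causal variant at MAF 0.244 explaining
12.74 % of log-biomarker variance, covariates explaining 14.89 %, a latent
biomarker–ptau correlation of 0.52, 21 % cases) and run the whole pipeline:

```r
library(csfqtl)
cfg <- sim_config(seed = 2025)
man <- run_pipeline(cfg, out_dir = "readme_run")
print(man)
#> <run_manifest> seed=2025
#>   top variant: snp_causal (beta=0.614, p=2.58e-18, genome-wide)
#>   R2: covariates=0.1431 variant=0.1589, lambda=1.041
#>   comparison: r 0.560 -> 0.594 (Meng p=0.0383, reject)
#>   status test: beta=1.449 p=6.18e-13
```

Reading the output: the causal variant is recovered as the top hit at
genome-wide significance (`p = 2.6×10⁻¹⁸`, `β = 0.61` per counted-allele
copy on the standardized log scale). In this single cohort draw the
covariates explain 14.3 % of the biomarker variance and the variant another
15.9 % (ΔR²). The genomic inflation factor is ≈ 1, i.e. the association
tests are calibrated. After residualizing the biomarker on the variant, its
correlation with the ptau analogue rises from 0.560 to 0.594, and the Meng
Z-test calls that increase significant (`p = 0.038`, the 95 % CI on the
Fisher-z difference excludes 0). Cases remain significantly elevated after
adjustment (`β = 1.45`, `p = 6×10⁻¹³`).

Every stage also has a direct function interface (`filter_variants()`,
`run_gwas()`, `conditional_analysis()`, `variance_explained()`,
`genetic_adjust()`, `compare_adjusted()`, `test_status_association()`), and
a thin command-line wrapper with subcommands
(`simulate`, `qc`, `pca`, `gwas`, `adjust`, `compare`, `status-test`,
`run-all`) lives at `inst/cli/csfqtl.R`:

```sh
Rscript inst/cli/csfqtl.R gwas --vcf genotypes.vcf --pheno phenotypes.tsv \
  --pheno-col ykl40 --covar-cols age,gender,batch --out assoc.tsv
```

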