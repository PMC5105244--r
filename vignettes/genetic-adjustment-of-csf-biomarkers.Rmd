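---
title: "Genetic adjustment of CSF biomarkers: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic adjustment of CSF biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfqtl)
```

## The problem

A CSF protein biomarker (the motivating case is YKL-40, the chitinase-3-like
1 glycoprotein) can be strongly regulated by a single genetic locus that has
nothing to do with the disease the biomarker is meant to track. For such a
biomarker, the genetically driven part of its variance is inter-individual
noise: two equally sick people can differ substantially in measured level
purely because of genotype. If the locus is known, that noise is removable.
`csfqtl` implements the full chain: find the locus by quantitative-trait
GWAS, quantify how much variance it explains, residualize the biomarker on
it, and test formally whether the residualized biomarker correlates more
strongly with disease-linked analytes (ptau181, tau, the Tau/Aβ42 ratio)
than the raw one did.

## Models and procedures

### Phenotype transformation

Analyte levels are strictly positive and right-skewed, so the pipeline works
on `z = (log(x) − mean) / sd` (natural log; sample SD with the n−1
denominator). Standardization makes the choice of log base immaterial — any
affine change on the log scale is absorbed, which the test suite asserts
exactly. A Shapiro–Wilk check (`normality_check()`) reports how normal the
transformed values look; it is advisory and never gates the pipeline.

### Genotype QC

Variants are hard allele counts `G ∈ {0, 1, 2}` of a recorded counted allele
(the VCF ALT). QC applies, in order: sample call rate (< 0.98 excluded),
then per-variant call rate (< 0.98), MAF (< 0.02) and the Hardy–Weinberg
exact test (p < 10⁻⁶). The order is a convention — the thresholds are
standard array-QC values and all are arguments. The HWE test is the exact
conditional test (sum of probabilities of all heterozygote counts no more
probable than the observed one, given the allele counts), computed by the
stable ratio recurrence anchored at the largest feasible heterozygote count;
the non-mid-p formulation is used, matching the default of the standard
GWAS tooling. Call-rate exclusion happens when the rate is strictly below
the threshold; the threshold itself passes.

Duplicate screening uses pairwise genotype concordance (fraction of
identical calls over mutually non-missing sites, flagged at ≥ 0.95). This
deliberately replaces method-of-moments identity-by-descent estimation: for
the QC purpose here — catching duplicates and near-identical relatives —
concordance is sufficient and far simpler; it is not a kinship estimator
and the package does not claim one.

Population structure uses EIGENSTRAT-style PCA: each variant column is
centered at `2p̂` and scaled by `sqrt(2 p̂ (1 − p̂))`; missing calls are
mean-imputed *for the PCA only*; monomorphic columns are dropped. The top
components (default 2) enter the GWAS as covariates.

### Association

Each variant is tested by OLS of the transformed biomarker on its allele
count plus covariates, with two-sided p-values from the t distribution
(not the normal approximation — at a few hundred samples the difference is
visible). Missing genotypes are handled by per-variant complete cases; no
dosage imputation. Internally, variants with complete calls go through an
exact Frisch–Waugh–Lovell shortcut — phenotype and genotypes are
residualized against the covariates once, after which each per-variant slope,
standard error and t statistic are recovered with the correct full-model
degrees of freedom. This is algebraically identical to the one-OLS-per-variant
definition (the acceptance tests compare both against explicit normal
equations at 10⁻¹⁰ relative tolerance) and is what makes a 50,000-variant
scan take seconds. Significance classes use the conventional thresholds
(genome-wide 5×10⁻⁸, suggestive 10⁻⁵); calibration is summarized by the
genomic inflation factor λ (median association χ² over 0.4549364). Variants
monomorphic in their complete cases are reported as NA rows with a reason
code, never dropped silently. Conditional analysis appends an index
variant's counts to the covariates and reports the index row as
`conditioned_on`.

The per-allele effect sign depends on which allele is counted; the table
records the counted allele (`A1`) and its frequency explicitly so the sign
is never ambiguous.

### Variance decomposition and adjustment

`variance_explained()` reports the covariate-only R² and the increment ΔR²
from adding the variant — by model nesting the increment is nonnegative up
to numerical tolerance, and it is clamped at 0 and defined as exactly 0 for
a constant variant column. `genetic_adjust()` regresses the transformed
biomarker on intercept + allele counts *only* (no covariates — the
adjustment removes the genetic effect, nothing else; a covariate-augmented
decomposition remains available through `variance_explained()`), and returns
externally studentized residuals `e_i / (s_{(i)} sqrt(1 − h_ii))`, with the
leave-one-out variance `s_{(i)}²`. Internal studentization is available via
`method = "internal"`; at cohort sizes in the hundreds the two are
indistinguishable (property-tested correlation > 0.9999), so the choice of
the external form simply follows the common statistical-software default
(`rstudent`, with which the implementation agrees to 10⁻¹⁰).

Why adjustment helps: if the genetic component `g` is independent of the
target analyte `t`, removing it rescales the correlation,

\[ \mathrm{cor}(y - \hat y(g),\, t) \;\to\; \frac{\mathrm{cor}(y, t)}{\sqrt{1 - R^2_g}} , \]

so a locus explaining R²_g of the biomarker raises an underlying correlation
r to r/√(1−R²_g). The acceptance suite verifies this closed form at
n = 10,000 and the direction (adjusted > unadjusted) across paper-scale
replicate cohorts.

### Comparing dependent correlations

The unadjusted and adjusted biomarker are correlated with the same target on
the same subjects, so the two correlations are dependent and share one
variable. `meng_test()` implements the Meng–Rosenthal–Rubin Z statistic on
Fisher-transformed correlations, with `f` capped at 1 (the original
formulation; the cap prevents a negative variance multiplier for unusual
triples). The 95 % CI is reported on the Fisher-z difference scale, where
the method is defined; the null is retained exactly when the interval
contains 0. The correlation triple is computed on a single common
complete-case `n` — the formula assumes one n — rather than pairwise ns.
A validity check rejects correlation triples that are not positive
semidefinite. The degenerate case `r_kh = 1` (adjusted column identical to
the unadjusted one) collapses the null variance; a zero difference is then
reported as Z = 0 / retain, and a nonzero difference is impossible there
(it would fail the PSD check). Alternative tests for the same hypothesis
(Steiger, Hittner) are deliberately not implemented; they are known to give
comparable answers and one well-tested statistic keeps the surface small.

### Case/control stage

Status is tested by logistic regression of case/control on the
log-standardized analyte plus covariates, fit by IRLS (`stats::glm.fit`)
with Wald inference recomputed from the converged weights. Complete or
quasi-complete separation is raised as an error rather than returned as
divergent coefficients — at these cohort sizes separation is a data problem
the analyst must see. No Firth correction is applied for the same reason.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the exact structure the analysis assumes. On
the standardized log-biomarker scale, with variance budget summing to 1:

* a causal Hardy–Weinberg variant (default MAF 0.244) whose effect size is
  solved from the target variance fraction (`solve_effect_size()`; default
  ΔR² 0.1274);
* covariate effects of age (N(70.9, 8.8²) years), gender (Bernoulli, coded
  0/1) and batch (default 2 batches — the minimal realistic batch structure,
  matching a study genotyped on two arrays), jointly explaining 14.89 % by
  default, split evenly across the three;
* a latent factor L shared with ptau181 and tau: the biomarker and the
  targets each load √0.52 on L, so the generative biomarker–ptau
  correlation is 0.52 exactly, while the genetic component stays independent
  of ptau by construction;
* a case-status mean shift (default 21.11 % cases, +0.7 SD on the log
  scale — consistent with reported case/control level ratios for CSF
  YKL-40 and a logistic coefficient near 0.7 on the standardized scale);
* Gaussian noise absorbing the remainder (the constructor rejects budgets
  that leave none).

Analytes are exponentiated to realistic positive scales (e.g. biomarker
centered at ~307 ng/mL), so the pipeline's log-standardization step
linearizes them exactly — closed-form checks in the tests stay exact.
Aβ42 is generated independent of everything, giving a true-null target for
type-I-error checks; `tau_abeta_ratio` is the literal ratio.

Deliberately **not** emulated: linkage disequilibrium between variants
(every variant is independent, so the conditional-analysis behavior on
correlated proxies is untested), imputation dosages (hard calls only),
X-chromosome data, longitudinal trajectories, and population admixture
(the null cohorts are homogeneous; the PCA tests build structured cohorts
separately). Passing tests therefore demonstrate the statistical machinery
on the assumed structure, not robustness to LD pruning or imputation noise
in real array data.

Default null-variant MAFs are drawn uniform on [0.05, 0.5], so a freshly
simulated cohort clears the MAF ≥ 0.02 filter with sampling margin; the
calibration script widens this to [0.02, 0.5] since it bypasses QC.

## Numerical choices

* OLS via QR; explicit normal equations appear only as test oracles.
* The HWE recurrence runs in normalized probability space; p-values are
  accumulated with a `1 + 10⁻¹²` relative guard against ties lost to
  floating-point rounding, and agree with direct log-gamma enumeration to
  10⁻¹² relative over every table with ≤ 200 alleles.
* ΔR² is clamped at 0 (nesting guarantees nonnegativity up to rounding).
* Ties in p for top-variant selection break by (chromosome, position), so
  the "top SNP" is deterministic.
* IRLS convergence: deviance tolerance 10⁻¹², max 50 iterations; the
  reported fit carries the largest score-equation residual so convergence
  is checkable, and separation is detected from pinned fitted probabilities
  together with diverging coefficients.
* All simulation is reproducible: every generator takes a seed, restores
  the caller's RNG state, and `run_pipeline()` writes md5 digests of every
  stage file into its manifest; the same config + seed reproduces identical
  digests.

## Problem sizes used by the test suite

The suite exercises: a 379 × 50,000 null scan for λ; 500 replicate cohorts
(n = 379) for variance-fraction recovery; 2,000 replicates for Meng-test
size; 300 replicates for the adjustment direction; 200 cohorts for power
and conditional analysis; and full HWE enumeration to 200 alleles. These
sizes were chosen to keep Monte-Carlo standard errors comfortably inside
the asserted tolerances.

## Known limitations

* Duplicate detection is concordance-based; related-but-not-duplicate
  individuals (e.g. siblings) are not flagged unless sharing exceeds the
  threshold.
* The association model is fixed-effects OLS; no kinship/mixed-model
  correction, so cryptic relatedness would inflate λ.
* Adjustment uses a single variant; no polygenic-score adjustment.
* The Meng CI is on the Fisher-z difference scale; users wanting an
  interval on the correlation-difference scale must back-transform
  themselves, and the back-transform is not a simple tanh of the endpoints.
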