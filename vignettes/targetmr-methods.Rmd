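---
title: "Methods: drug-target and clustered MR in targetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target and clustered MR in targetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

# Scope and model

`targetmr` implements two-sample summary-data Mendelian randomization for
a quantitative exposure (effects in SD units) on a binary outcome (effects
on the log-odds scale), in two tracks:

* **drug-target (cis) MR**: instruments restricted to a gene region
  (gene ± 100 kb flank by default) in low LD (r² < 0.1), analysed with
  correlated-instrument estimators and substantiated by colocalization;
* **genome-wide clustered MR**: independent instruments (r² < 0.001)
  analysed jointly and then clustered on their variant-level causal
  estimates to expose heterogeneous mechanisms.

The usual instrumental-variable assumptions apply: instruments are
strongly associated with the exposure (checked via the per-variant
F-statistic (β/se)²), share no confounder with the outcome (supported by
a user-supplied exclusion list for variants linked to candidate
confounders — the package deliberately does not query any annotation
service), and affect the outcome only through the exposure (probed by the
MR-Egger intercept and the weighted median).

# Harmonization rules

Exposure and outcome records are aligned on the exposure's effect allele.
Matching alleles are kept; swapped alleles negate the outcome beta and
complement its frequency; strand complements (A/G vs T/C etc.) are
resolved first. Palindromic variants (A/T, G/C) cannot be resolved by
allele labels, so they are retained only when both allele frequencies lie
on the same side of 0.5 **and** outside the window (0.42, 0.58); a
missing frequency on either side drops the variant. The window is the
conventional ambiguity band for palindromic alignment and is exposed as
`palindromic_window` because the underlying data sources differ in how
informative their frequencies are.

Variants absent from the outcome (or with incompatible allele sets) are
replaced by the best proxy with r² ≥ 0.8 when an LD matrix is supplied:
maximal r², ties broken by physical distance then lexicographic id, so
output is deterministic. The proxy's outcome beta is multiplied by the
sign of the LD correlation r, which presumes the signed LD matrix is
oriented to the counted (effect) alleles of the datasets as supplied —
the tests verify this convention by reorienting a proxy's allele together
with its LD column and checking invariance.

# Estimators

All estimators use first-order weights `1/se(Γ)²`, ignoring exposure-side
sampling error; this is the standard convention for summary-data MR and
is accurate when instruments are genome-wide significant (F ≫ 10).

* **IVW**: weighted origin regression. The `auto` effects model is fixed
  for ≤3 instruments and multiplicative random effects for ≥4, with the
  variance-inflation factor `max(1, sqrt(Q/(J-1)))` floored at one so the
  reported standard error can never fall below the fixed-effects one.
* **Correlated IVW / Egger**: generalized weighted least squares with
  `Ω = D ρ D` (D diagonal of outcome standard errors, ρ signed LD). The
  Cholesky factorization is attempted on Ω as given; only if it fails is
  a 1e-8 diagonal ridge applied, and a matrix still not positive definite
  is an error naming the offending eigenvalue. Conditioning only on
  demand keeps the identity-LD case *exactly* equal to the uncorrelated
  formulas, a property the tests assert at 1e-10.
* **MR-Egger** is not invariant to allele orientation, so variants are
  flipped to positive exposure effects before fitting (the LD matrix rows
  and columns are sign-flipped consistently). Both coefficient standard
  errors share the `max(1, sqrt(Q/(J-2)))` inflation under random
  effects.
* **Weighted median**: ratios sorted ascending, weights normalized, and
  the estimate interpolated at cumulative midpoint weight 0.5. Its
  standard error is a parametric bootstrap (default 1000 resamples of
  (γ̂, Γ̂) from their stated normal errors); pass a seed for exact
  reproducibility.
* Confidence intervals and p-values are normal throughout, matching
  summary-data MR practice; estimates are re-expressed per 1-SD exposure
  *reduction* (`lowering_orientation()`) at the reporting layer, where
  binary-outcome slopes become odds ratios by exponentiation.

# Instrument selection

Selection is greedy p-value-ranked clumping: repeatedly keep the most
significant candidate and discard candidates with r² ≥ the threshold
against anything kept. Removal is strict at the boundary (r² < threshold
is retained), ties in p are broken by position then id, and pruning for a
cis region uses the region's candidates only. Variants on different
chromosomes, or missing from the LD matrix, count as uncorrelated. An
empty candidate set is a labelled, empty instrument set — some targets
are genuinely not instrumentable and that is a result, not an error.

# Colocalization

Per-variant Wakefield log approximate Bayes factors
`½(log(1−r) + r z²)`, `r = W/(V+W)`, feed the standard five-hypothesis
posterior with per-variant priors p1 = p2 = 1e-4 and p12 = 1e-5. Effect
priors default to W = 0.15² for quantitative and 0.2² for binary traits;
only the p-priors are fixed by convention, so both SDs are configuration
options. Everything is computed in log space; the H3 mass
`log(exp(S1+S2) − exp(S12))` uses `log1p(-exp(gap))` with a guard that
sets PP3 to zero when the gap is non-negative (which is exact for a
single shared variant). Variants with minor allele frequency ≤ 0.1% are
excluded before testing. The conditional probability PP4/(PP3+PP4) is
reported because power for H4 is limited when the outcome association is
weak.

# Clustered MR mixture

Wald ratios θ̂ⱼ with known standard errors σⱼ are modelled as a mixture of
K substantive components N(μₖ, σⱼ²), a null component N(0, σⱼ²) and a junk
component N(θ̄, σⱼ² + ψ²), where θ̄ and ψ² are the unweighted mean and
variance of all ratios and stay **fixed** during EM. Anchoring the junk
component avoids the classic EM pathology of a component collapsing onto
a single observation, and together with the null component it demands
substantial evidence of similarity before a substantive cluster forms.
There is no within-cluster variance beyond σⱼ² (a hard
"similar causal estimates" model); a τ² extension is out of scope.

The E/M steps are standard (inclusion-weighted precision-weighted means;
mean responsibilities); the iteration stops when the log-likelihood gain
falls below 1e-8 or at 500 iterations, and components whose proportion
falls below 1e-8 are removed. K runs from 0 to `k_max` with `n_restarts`
seeded restarts per K (initial means at random quantiles of θ̂); K is
chosen by BIC = −2·loglik + (2K+1)·log J (K means plus K+1 free
proportions), ascending in K with strict improvement so ties favour the
smaller model. The EM inner loop is compiled (Rcpp) because the
calibration studies fit tens of thousands of mixtures.

Reporting follows the conservative rule: a variant belongs to a cluster
only when that cluster is its maximum-probability component **and** its
inclusion probability strictly exceeds 0.80; clusters with fewer than 4
such members are suppressed. Per-cluster IVW/median/Egger estimates are
recomputed on the members with the uncorrelated formulas, which is valid
because genome-wide instruments are pre-pruned to r² < 0.001.

# Synthetic data and what it does (not) show

The generator produces the statistical geometry the estimators consume,
not raw genotypes:

* `simulate_genome()` draws true exposure effects from
  N(0, `exposure_effect_sd`²) conditioned (rejection sampling, capped) to
  genome-wide significance, assigns each variant to a cluster by weight,
  sets the true outcome effect to slope × exposure effect (or 0 for null,
  or a direct pleiotropic draw for junk), and adds sampling noise at
  se = 1/√n (quantitative) and se = 1/√(n·φ(1−φ)) (binary, case fraction
  φ). Defaults mirror the motivating study design: exposure n 1,231,289
  (the European-ancestry lipids meta-analysis scale), outcome n 367,289
  with φ = 30,547/367,289, and two opposing substantive clusters (−0.3,
  +0.4) with 15% null and 5% junk weight. `exposure_effect_sd = 0.02`
  gives F-statistics in the hundreds, typical of selected lipid loci.
* `simulate_region()` draws two traits' z-scores from MVN(√n·R·b, R)
  over an AR(1) LD block (ρ = 0.9 by default, a dense cis region), with
  the causal configuration shared / distinct / trait1-only / none.
* `simulate_multistudy()` reuses one set of true effects across studies
  with independent noise — the fixed-effects regime — or draws
  independent truths.

Deliberate simplifications: standardized-genotype standard errors (no
allele-frequency dependence), no logistic fine structure for the binary
trait, no LD in the genome-wide generator, and uniform allele
frequencies. Passing calibration on these data shows the *procedures*
are implemented correctly and calibrated under their own assumptions; it
does not certify behaviour under real-data pathologies such as
participation bias, ancestry mismatch between LD reference and GWAS, or
winner's curse in instrument selection.

# Numerical and design choices

* Cholesky-based inversion with on-demand ridge (above); degenerate
  instruments (γ̂ = 0) are an explicit error for the Wald ratio.
* The spurious-cluster and recovery studies in the tests and acceptance
  script use `k_max = 5`, `n_restarts = 10` on J = 100 ratios, and the
  coverage studies use 500 replicates of a 100-variant genome — sizes at
  which all Monte-Carlo margins are comfortable on a single CPU.
* Heterogeneity "suggesting" a random-effects meta-model is
  operationalized as Cochran's Q p < 0.05 (`het_alpha`), with
  DerSimonian–Laird τ²; τ² = 0 reproduces fixed-effects pooling exactly.
* Percentages in cohort tables are rounded to one decimal, matching how
  baseline tables are printed; JSON reports keep full precision.
* The analysis entry points are plain R functions (`run_drug_target()`,
  `run_clustered()`, `cohort_summary()`, plus `scripts/acceptance.R`);
  no shell wrapper is shipped because the package is used from R.

# Known limitations

Single-causal-variant colocalization only (no masking of secondary
signals); no MR-PRESSO, mode-based, multivariable or Steiger extensions;
no LD computation from genotype panels (LD is always an input); no
genome-build liftover and no indel alleles; meta-analysis is univariate
inverse-variance pooling.
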