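# targetmr

Drug-target and clustered Mendelian randomization (MR) from GWAS summary
statistics, with approximate-Bayes-factor colocalization, cross-study
meta-analysis, and a known-truth synthetic-data generator for calibration.

## The problem

When a lipid-lowering drug's molecular target is encoded by a known gene,
variants in or near that gene that alter the exposure (for example plasma
LDL-cholesterol) act as genetic mimics of pharmacological modulation.
Comparing their effects on a disease outcome (for example gallstone
disease) estimates what the drug would do — *drug-target MR*. Because a
single exposure is regulated by several biological pathways that need not
act on the outcome in the same direction, the package also clusters
genome-wide variant-level causal estimates to expose distinct, possibly
opposing, mechanisms — *clustered MR*.

The core quantities: for variant *j* with exposure association γ̂ⱼ and
outcome association Γ̂ⱼ,

- Wald ratio: θ̂ⱼ = Γ̂ⱼ / γ̂ⱼ, se(θ̂ⱼ) = se(Γ̂ⱼ)/|γ̂ⱼ|;
- IVW estimate: weighted regression of Γ̂ on γ̂ through the origin with
  weights 1/se(Γ̂ⱼ)², fixed effects for ≤3 variants and multiplicative
  random effects (floored at 1) for ≥4; for correlated instruments the
  weighting matrix becomes Ωᵢⱼ = se(Γ̂ᵢ)se(Γ̂ⱼ)ρᵢⱼ with LD correlations ρ;
- MR-Egger: the same regression with an intercept (directional-pleiotropy
  test), after orienting all γ̂ⱼ > 0;
- weighted median: the ratio at half the cumulative γ̂²/se(Γ̂)² weight;
- colocalization: Wakefield log approximate Bayes factors
  ½(log(1−r) + r z²), r = W/(V+W), combined into posteriors for the five
  hypotheses H0–H4, plus the conditional probability PP4/(PP3+PP4);
- clustered MR: an EM-fitted Gaussian mixture over θ̂ⱼ with K substantive
  components N(μₖ, σⱼ²), a null component at 0 and a fixed broad junk
  component, K selected by BIC; clusters are reported only when ≥4 variants
  exceed inclusion probability 0.80.

## Worked example

Simulate a cis region whose shared causal variant raises the exposure by
0.1 SD and the (log-odds) outcome by 0.035 — a causal slope of +0.35 per
SD, i.e. a protective effect of exposure *lowering* — then run the full
drug-target analysis:

```r
library(targetmr)
sim <- simulate_region(region_sim_config(n_variants = 120, ld_rho = 0.9,
                                         causal_mode = "shared",
                                         causal_betas = c(0.1, 0.035),
                                         seed = 42))
target <- gene_region("TARGET1", "1", 40000, 80000, flank = 20000)
run_drug_target(sim$trait1, sim$trait2, sim$ld, target, seed = 1)
#> Drug-target MR report: TARGET1 - ok
#>   instruments: 3
#>            method      slope         se     ci_low    ci_high      p_value ...
#> 1       ivw_fixed -0.3719866 0.04564795 -0.4614549 -0.2825183 3.668496e-16
#> 2           egger -0.4095004 0.06454331 -0.5360030 -0.2829978 2.230287e-10
#> 3 weighted_median -0.3677496 0.04646479 -0.4588189 -0.2766803 2.480762e-15
#>   coloc PP4 = 1.000 (conditional 1.000)
```

Three low-LD instruments survive the cis selection (r² < 0.1, p < 5×10⁻⁸).
The slopes are reported in the lowering orientation, so −0.37 means a
1-SD *reduction* in the exposure lowers the outcome log-odds by 0.37
(odds ratio `exp(-0.37) ≈ 0.69`), and PP4 ≈ 1 confirms both traits share
one causal variant rather than being confounded by LD.

The clustered track on a genome-wide simulation with two opposing
mechanism clusters (true raising slopes −0.3 and +0.4):

```r
gsim <- simulate_genome(genome_sim_config(n_variants = 100,
                                          exposure_effect_sd = 0.06, seed = 14))
crep <- run_clustered(gsim$exposure, gsim$outcome, k_max = 4, n_restarts = 8,
                      n_boot = 200, seed = 2)
crep$solution
#> Clustered MR solution: 2 substantive cluster(s), J = 99
#>   means: -0.2925, 0.4095
#>   proportions: cluster_1 0.46, cluster_2 0.39, null 0.08, junk 0.07
```

The all-variant IVW is near zero with enormous heterogeneity (Q ≈ 1482 on
98 df) — exactly the signature of opposing pathways cancelling — while the
mixture recovers both generating slopes and the per-cluster IVW estimates
take opposite signs.

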