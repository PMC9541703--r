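# crossmix

Cross-trait polygenic overlap and conjunctional FDR analysis of GWAS
summary statistics.

Two complex traits can share most of their causal variants yet show
little genetic correlation, because shared variants with concordant and
discordant effect directions cancel. `crossmix` quantifies this from
summary statistics alone, for psychiatric-genetics-style analyses where
only z-scores, p-values and sample sizes are available:

* **Bivariate causal Gaussian mixture model.** Each variant belongs to
  one of four components — null, trait-1-only, trait-2-only, shared —
  with probabilities (π₀, π₁′, π₂′, π₁₂). Nonzero effects are Gaussian
  with variance σᵦ² ("discoverability"); shared effects have
  correlation ρ₁₂; the observed z-score is the LD-weighted effect sum
  plus inflated noise (scale σ₀, cross-trait correlation ρ₀ from sample
  overlap). The likelihood is the characteristic-function convolution
  `φ(t) = exp(−σ₀²t²/2) · Π_i [1 − π₁ + π₁ exp(−N σᵦ² r²ᵢ t²/2)]`
  inverted by FFT (compiled in `src/mixture.cpp`). Derived quantities:
  shared/unique causal-variant counts, genetic correlation
  `r_g = ρ₁₂ π₁₂ / √((π₁′+π₁₂)(π₂′+π₁₂))`, the concordant-effect
  fraction `½ + arcsin(ρ₁₂)/π`, n90, and AIC against minimal- and
  maximal-overlap reference models.
* **condFDR / conjFDR.** The conditional FDR
  `condFDR(p₁ | p₂ ≤ s) = p₁ / F̂(p₁ | p₂ ≤ s)` built on a stratified
  empirical-CDF lookup averaged over random LD-pruning iterations
  (r² > 0.1), with conditional QQ plots; the conjunctional FDR is the
  maximum of the two mutual condFDR values, thresholded at 0.05.
* **Loci.** FUMA-protocol clumping (independent significant SNPs at
  r² < 0.6, leads at r² < 0.1, 250 kb merge, candidates at
  conjFDR < 0.10 and r² ≥ 0.6), effect-direction concordance, novelty
  against known-locus lists, and transdiagnostic merging of physically
  overlapping loci that share a jointly significant candidate SNP.
* **Replication and annotation.** En-masse sign-concordance testing
  (one-sided exact binomial), positional gene mapping, hypergeometric
  gene-set enrichment with BH adjustment.
* **Synthetic studies with ground truth.** A generator producing
  two-trait GWAS z-scores under exactly the four-component model with
  block AR(1) LD, retained component labels, true effects and
  LD-weighted signals, plus replication draws — so every stage is
  validated against known truth.

## Worked example

Simulate the standard two-trait study (50,000 variants, 4% shared
causal variants with effect correlation 0.6), fit the mixture, and
discover jointly associated loci:

```r
library(crossmix)
library(dplyr)

study  <- simulate_study(sim_config(M = 50000, n_blocks = 500, seed = 1))
merged <- harmonize_pair(study$trait1, study$trait2)

f1 <- fit_univariate(select(merged, variant_id, z = z1, n = n1), study$ld,
                     M = 50000, n_iter = 20, n_subsample = 5000, seed = 1)
f2 <- fit_univariate(select(merged, variant_id, z = z2, n = n2), study$ld,
                     M = 50000, n_iter = 20, n_subsample = 5000, seed = 2)
fb <- fit_bivariate(merged, study$ld, f1, f2, n_iter = 20,
                    n_subsample = 5000, seed = 3)
fb
#> <crossmix bivariate fit: 20 iterations, M = 50000>
#> # A tibble: 3 × 3
#>   term  estimate       sd
#>   <chr>    <dbl>    <dbl>
#> 1 pi12    0.0405 0.000806
#> 2 rho12   0.620  0.0354
#> 3 rho0   -0.0438 0.0610
#> derived:
#> # A tibble: 1 × 10
#>   n_shared n_unique_1 n_unique_2 n_total_1 n_total_2    rg concordant_fraction
#>      <dbl>      <dbl>      <dbl>     <dbl>     <dbl> <dbl>               <dbl>
#> 1    2023.      1515.      1877.     3538.     3900. 0.338               0.713
```

The simulation used π₁₂ = 0.04 (2,000 of 50,000 variants shared) and
ρ₁₂ = 0.6: the fit recovers π̂₁₂ = 0.0405 (≈2,023 shared variants) and
ρ̂₁₂ = 0.62, a concordant-effect fraction of 71% (closed form at the
true ρ₁₂: 70.5%), and finds no spurious sample-overlap correlation
(ρ̂₀ ≈ −0.04). SDs are over the 20 resampling iterations.

```r
cj   <- conj_fdr_table(merged, study$ld, seed = 4)
sum(cj$table$significant)       # variants at conjFDR < 0.05
#> [1] 5415
loci <- define_loci(cj$table, study$ld)
nrow(loci)
#> [1] 23
directional_concordance(loci)$summary
#> # A tibble: 1 × 4
#>   n_tested n_concordant n_excluded percent
#>      <int>        <int>      <int>   <dbl>
#> 1       23           21          0    91.3

rep <- simulate_replication(study$truth, study$ld, n_rep = 5e4, seed = 99)
sign_concordance_test(tibble::tibble(variant_id = loci$lead_snp,
                                     z = loci$lead_z1), rep)
#>   n_leads n_tested n_concordant n_missing n_zero      p_value
#> 1      23       23           23         0      0 1.192093e-07
```

23 jointly associated loci, 91.3% with concordant lead-SNP effect
directions across the two traits, and all 23 lead SNPs replicating
their sign in an independent draw (exact binomial p = 1.2e-7).
`plot_conjfdr_manhattan(cj$table, loci)`, `autoplot()` on QQ objects
and fits, and `tidy()`/`glance()` on fit objects give the standard
views. `run_pipeline(pipeline_config(...), out_dir)` executes the same
flow from a (YAML-able) configuration and writes every stage as TSV
with a JSON manifest.

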