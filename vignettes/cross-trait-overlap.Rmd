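---
title: "Quantifying cross-trait polygenic overlap with crossmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-trait polygenic overlap with crossmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmix)
library(dplyr)
```

## The problem

Two complex traits can share most of their causal genetic variants while
showing almost no genetic correlation, because shared variants with
concordant and discordant effect directions cancel.  crossmix implements
the two complementary statistics used to dissect this situation from GWAS
summary statistics alone:

* a **bivariate causal Gaussian mixture model** that estimates how many
  variants influence each trait, how many influence both, and how
  correlated the shared effects are — irrespective of effect direction;
* the **conditional / conjunctional false discovery rate**
  (condFDR/conjFDR), which borrows power across traits to discover the
  individual loci jointly associated with both.

Downstream stages clump jointly associated variants into independent
genomic loci (FUMA protocol), merge loci across several trait-pair
analyses into transdiagnostic loci, test discovery–replication sign
concordance, and run positional gene mapping with hypergeometric
gene-set enrichment.

## The mixture model

For variant $j$ of trait $t$ the observed z-score is modelled as

$$z_{tj} \;=\; \delta_{tj} + \varepsilon_{tj}, \qquad
  \delta_{tj} = \sqrt{N_t}\sum_{i \in \mathrm{nbr}(j)} r_{ij}\,\beta_{ti},$$

where $r_{ij}$ is the LD correlation, $\beta_{ti}$ the standardized
per-allele effect, and $\varepsilon$ Gaussian noise with scale
$\sigma_0$ ($> 1$ under residual inflation) and cross-trait correlation
$\rho_0$ (sample overlap).  Each variant belongs to one of four latent
components — null, trait-1-only, trait-2-only, shared — with
probabilities $(\pi_0, \pi_1', \pi_2', \pi_{12})$; nonzero effects are
Gaussian with variance $\sigma_{\beta t}^2$ ("discoverability"), and
shared effects are correlated with $\rho_{12}$.

The marginal density of $z_j$ follows from the characteristic function

$$\varphi_j(t) = e^{-\sigma_0^2 t^2/2}
  \prod_{i \in \mathrm{nbr}(j)}
  \bigl[\,1-\pi_1 + \pi_1\, e^{-N\sigma_\beta^2 r_{ij}^2 t^2/2}\,\bigr],$$

with a four-component analogue in two dimensions.  Densities are
recovered by FFT on a symmetric grid; variants with identical multisets
of neighbor $r^2$ values share one density ("LD profiles"), which makes
genome-scale evaluation cheap.  The compiled kernel lives in
`src/mixture.cpp`.

Derived quantities follow closed forms: the genetic correlation
$r_g = \rho_{12}\pi_{12}/\sqrt{(\pi_1'+\pi_{12})(\pi_2'+\pi_{12})}$,
the concordant-effect fraction $\tfrac12 + \arcsin(\rho_{12})/\pi$, and
n90 — the number of largest-effect causal variants explaining 90% of
SNP heritability — via the $\chi^2_1$ truncated-mean identity
$E[X\,1\{X>t\}] = P(\chi^2_3 > t)$, giving
$n_{90} \approx 0.445\,\pi M$ independent of $\sigma_\beta^2$.

### Estimation

Estimation is staged.  The univariate stage fits
$(\pi_1, \sigma_\beta^2, \sigma_0)$ per trait; the bivariate stage holds
the per-trait totals fixed and fits only $(\pi_{12}, \rho_{12}, \rho_0)$,
with $\pi_t' = \pi_{t,\mathrm{total}} - \pi_{12}$ constrained
nonnegative.  Both stages resample: each of 20 iterations draws a random
variant subsample (20,000 by default; the test suite uses 5,000 at
$M = 50{,}000$), randomly prunes it at $r^2 > 0.8$, and maximizes the
likelihood by Nelder–Mead simplex on transformed scales (logit for
proportions, log for variances, atanh for correlations).  Point
estimates are iteration means and the reported SDs are iteration SDs.
The first iteration uses random multi-starts (5 univariate, 3
bivariate); later iterations warm-start from the first solution — the
subsamples overlap heavily, so re-running the full multi-start in every
iteration would only re-find the same basin at several times the cost.

Model support is summarized by AIC against two reference models:
minimal overlap ($\pi_{12} = 0$, refitting $\rho_0$) and maximal overlap
($\pi_{12} = \min$ of the totals, refitting $\rho_{12}, \rho_0$).

### Numerical choices

* Univariate FFT grid: 2048 points over $|z| \le \max(20, \max|z|+5)$;
  bivariate: 128 points per axis.  Doubling either grid moves the
  log-likelihood by well under $10^{-4}$ per variant (asserted in the
  tests); interpolation to observed z-scores is Catmull–Rom cubic
  (bicubic in 2-D), so the coarser bivariate grid loses no practical
  accuracy.
* The shared-component characteristic factor is evaluated as a single
  positive-semi-definite quadratic form in the exponent; splitting it
  into marginal factors times a cross term overflows for large $|t|$.
* LD sums (both in the generator's $\delta$ construction and in the
  likelihood) truncate at $|r| < 0.05$, so generator and likelihood
  remain exactly conjugate.
* p-values are clamped to $[10^{-300}, 1]$ before any log transform.
* Degenerate inputs: $\pi_1 = 0$ collapses to the pure null normal
  (used as an exactness test); $\sigma_0$ is bounded below at 0.5;
  infeasible $\pi_{12}$ is impossible by construction of the
  logit-bounded parameterization.

## condFDR / conjFDR

The conditional FDR of trait 1 given trait 2 is estimated conservatively
(null proportion set to 1) as
$\mathrm{condFDR}(p_1 \mid p_2 \le s) = p_1 / \hat F(p_1 \mid p_2 \le s)$
on a grid over $(-\log_{10} p_1, -\log_{10} p_2)$ with nested
conditioning strata ($s = 1, 0.1, 0.01, 0.001$), linear interpolation
between strata, and monotone regularization (non-increasing in
$-\log_{10} p_1$ and along the conditioning axis by cumulative minimum).
To undo LD-induced distortion of the empirical CDFs, the grid is
averaged over 20 random pruning iterations, each keeping one random
variant per LD cluster at $r^2 > 0.1$; regions of long-range LD (the
extended MHC, chr6:25–34 Mb, and the chr8 inversion, chr8:7–12 Mb) are
excluded from CDF construction but still receive interpolated values.
The conjunctional FDR is the maximum of the two mutual condFDR values,
and `conjFDR < 0.05` is the single significance threshold used by every
downstream stage.

The calibration experiment in the test suite runs on a singleton-block
(LD-free) template, where the latent component labels coincide with the
per-variant hypothesis "no signal for at least one trait", so the
empirical false-discovery proportion is unambiguous; across 20 seeds at
$M = 10^5$ it stays below the conservative bound.  On templates with
LD, a perfect tag of a shared causal variant is a true discovery at the
variant level, so there the pipeline scores calls against the retained
LD-weighted signals $\delta$ ($\delta_{1j} \ne 0$ and
$\delta_{2j} \ne 0$) rather than against labels.

## Locus definition and transdiagnostic merging

Within a conjFDR analysis, significant variants (conjFDR < 0.05) are
clumped greedily by ascending conjFDR (ties: position, then id):
variants not in $r^2 \ge 0.6$ with an already-selected one become
independent significant SNPs; among these, lead SNPs are selected at
mutual $r^2 < 0.1$; independent significant SNPs within 250 kb (the
FUMA default merge distance) or in $r^2 \ge 0.1$ collapse into one
locus.  Candidate SNPs are all variants at conjFDR < 0.10 in
$r^2 \ge 0.6$ with an independent significant SNP — the locus interval
is the min–max position of its candidates, and the looser 0.10
threshold (rather than 0.05) is used for bounds and gene mapping so
that putative causal variants are not clipped away.

Across analyses, loci merge into a transdiagnostic locus when their
intervals physically overlap (1-based inclusive:
$\max(\text{starts}) \le \min(\text{ends})$) and at least one shared
candidate SNP has conjFDR ≤ 0.05 in both members of the pair; groups
close transitively, so a chain A–B–C merges even if A and C share no
candidate directly.  The transdiagnostic lead SNP minimizes, over the
group's candidate SNPs, the maximum conjFDR across contributing
analyses (ties: smaller position).  All of these rules are verified
against brute-force oracles that enumerate the definitions directly.

## Replication and enrichment

Discovery lead SNPs are compared with an independent replication sample
by an en-masse sign concordance test: $k$ of $n$ matching z-score signs
against the one-sided exact binomial tail $P(X \ge k \mid n, 1/2)$.
Missing leads and zero z-scores are dropped and counted.  The exact
test is used deliberately — on printed counts such as 74/96 it
reproduces published p-values to three significant figures, which a
normal approximation does not.  Note the test's discreteness: at
$n = 50$ the largest attainable level below 0.05 is about 0.032, so the
null rejection share sits at 3.2%, not 5%.

Gene mapping is positional: a gene maps to a locus when its span,
extended by a 10 kb window (FUMA's default), covers any candidate SNP.
Gene-set enrichment is the hypergeometric upper tail on a user-supplied
gene list (for real studies, a "credible gene" list that external
eQTL/chromatin evidence would produce) against a GMT collection, with
Benjamini–Hochberg adjustment across sets within one analysis.

## The synthetic study

`sim_config()` defaults define the package's standard study: $M = 10^5$
variants in 1,000 contiguous AR(1) LD blocks of 100 variants
($r = 0.8^{d}$ at in-block distance $d$, zero across blocks,
500–1500 bp spacing over 22 chromosomes), component probabilities
$(0.90, 0.03, 0.03, 0.04)$, effect variance $2\times10^{-4}$ at
$N = 10^5$ (so $N\sigma_\beta^2 = 20$ and the median causal
$\chi^2 \approx 10$ — strong but realistic single-variant signal),
$\rho_{12} = 0.6$, unit noise, no sample overlap, and a replication
sample of 50,000.  Parameter-recovery experiments use $M = 50{,}000$
with 20 × 5,000-variant fit iterations; the univariate sparse
architecture uses $\pi_1 = 0.01$.

What the generator deliberately does not emulate: allele-frequency
dependent effect sizes (the downstream statistics consume only z, p,
N), realistic LD beyond block-AR(1) (so the $r^2 > 0.8$ prune is
exercised on explicit sparse fixtures rather than in simulation, where
adjacent variants reach only $r^2 = 0.64$), population stratification
beyond a scalar $\sigma_0$, and the physical density of real variant
maps — synthetic variants sit ~1 kb apart, so significant loci chain
along whole synthetic chromosomes and locus counts are small by
construction.  Passing tests therefore demonstrate correctness of the
estimators and procedures under the model's own assumptions, not
robustness to real-data artifacts.

All randomness flows from a single master seed through named
substreams (`substream_seed()`), so stages can be rerun independently
and identical configurations give byte-identical outputs.

## A short tour

```{r tour, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
merged <- harmonize_pair(study$trait1, study$trait2)

f1 <- fit_univariate(select(merged, variant_id, z = z1, n = n1),
                     study$ld, M = nrow(merged))
f2 <- fit_univariate(select(merged, variant_id, z = z2, n = n2),
                     study$ld, M = nrow(merged))
fb <- fit_bivariate(merged, study$ld, f1, f2)
tidy(fb)
autoplot(fb)

cj <- conj_fdr_table(merged, study$ld)
loci <- define_loci(cj$table, study$ld)
directional_concordance(loci)$summary
plot_conjfdr_manhattan(cj$table, loci)

rep <- simulate_replication(study$truth, study$ld, n_rep = 5e4, seed = 99)
sign_concordance_test(tibble::tibble(variant_id = loci$lead_snp,
                                     z = loci$lead_z1), rep)
```

The same flow is available as a configured pipeline
(`pipeline_config()` / `read_pipeline_config()` + `run_pipeline()`)
that writes every stage as TSV with a JSON manifest; swapping simulated
inputs for summary-statistics files is a config edit, not a code
change.

## Known limitations

* The likelihood treats LD profiles as exact and shares densities
  within a profile; with arbitrary empirical LD matrices the profile
  count grows and evaluation slows, though results are unchanged.
* The bivariate stage fixes univariate parameters rather than jointly
  refitting all nine; this mirrors the staged procedure it implements
  but propagates univariate bias into the overlap estimates.
* condFDR's conservativeness (null proportion 1) costs power when true
  polygenicity is high.
* The sign-concordance test assumes independent replication; overlap
  between discovery and replication cohorts would inflate it.
* Hypergeometric enrichment ignores gene size and LD clustering of
  genes; it is the appropriate simple test only because conjFDR
  statistics violate the null-uniformity assumption of competitive
  gene-set methods.
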