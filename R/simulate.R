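# Synthetic GWAS summary statistics for two traits under the
# four-component causal mixture the analysis assumes: per variant a latent
# component label (null / trait1-only / trait2-only / shared), Gaussian
# effects with within-shared-component correlation, block AR(1) LD,
# null inflation via the noise scale sigma0, and optional correlated noise
# (rho0) emulating sample overlap.  Ground truth (labels, effects, LD-
# weighted signals delta) is retained for validation.

#' Simulation configuration
#'
#' Defaults describe the package's standard synthetic study: 100,000
#' variants in 1,000 AR(1) LD blocks (decay 0.8), 90% null variants, 3%
#' unique to each trait and 4% shared with effect correlation 0.6,
#' per-variant effect variance 2e-4 at sample size 100,000 (so N * sigma_b2
#' = 20, putting the median causal chi-square near 10), unit null noise and
#' no sample-overlap correlation.
#'
#' @param M Number of variants.
#' @param n_blocks Number of contiguous LD blocks.
#' @param rho_block Within-block AR(1) correlation decay, |rho| < 1.
#' @param pis Component probabilities (null, trait1-only, trait2-only,
#'   shared); must be nonnegative and sum to 1.
#' @param sigma_b2_1,sigma_b2_2 Per-trait effect-size variances
#'   (standardized per-allele units).
#' @param rho12 Effect correlation within the shared component.
#' @param N1,N2 Per-trait GWAS sample sizes.
#' @param sigma0_1,sigma0_2 Null noise scales (1 = no inflation).
#' @param rho0 Noise correlation between traits (sample overlap).
#' @param n_rep Replication-sample size used by [simulate_replication()].
#' @param seed Master seed; every operation draws from a named substream.
#' @return A validated list of class `crossmix_sim_config`.
#' @export
sim_config <- function(M = 1e5, n_blocks = 1000, rho_block = 0.8,
                       pis = c(0.90, 0.03, 0.03, 0.04),
                       sigma_b2_1 = 2e-4, sigma_b2_2 = 2e-4, rho12 = 0.6,
                       N1 = 1e5, N2 = 1e5, sigma0_1 = 1, sigma0_2 = 1,
                       rho0 = 0, n_rep = 5e4, seed = 1) {
  stopifnot(M >= n_blocks, n_blocks >= 1, abs(rho_block) < 1)
  if (length(pis) != 4 || any(pis < 0) || abs(sum(pis) - 1) > 1e-12) {
    abort("pis must be 4 nonnegative probabilities summing to 1")
  }
  stopifnot(sigma_b2_1 >= 0, sigma_b2_2 >= 0, abs(rho12) <= 1,
            abs(rho0) <= 1, sigma0_1 >= 0, sigma0_2 >= 0, N1 > 0, N2 > 0)
  structure(list(M = as.integer(M), n_blocks = as.integer(n_blocks),
                 rho_block = rho_block, pis = pis,
                 sigma_b2_1 = sigma_b2_1, sigma_b2_2 = sigma_b2_2,
                 rho12 = rho12, N1 = N1, N2 = N2, sigma0_1 = sigma0_1,
                 sigma0_2 = sigma0_2, rho0 = rho0, n_rep = n_rep,
                 seed = as.integer(seed)),
            class = "crossmix_sim_config")
}

COMPONENTS <- c("null", "trait1_only", "trait2_only", "shared")

#' Build a genome template with block AR(1) LD
#'
#' Variants are split into contiguous blocks of near-equal size, assigned
#' round-robin to chromosomes 1-22; within a block r(i, j) =
#' rho_block^|i-j|, across blocks r = 0.  Positions are strictly
#' increasing within a chromosome.
#'
#' @param M Number of variants.
#' @param n_blocks Number of blocks (`M >= n_blocks >= 1`).
#' @param rho_block AR(1) decay, |rho| < 1.
#' @param seed Integer seed (position jitter).
#' @return A list with `template` (tibble: `variant_id`, `chromosome`,
#'   `position`, `block`) and `ld` (a `crossmix_ld`).
#' @export
make_genome_template <- function(M, n_blocks, rho_block, seed = 1) {
  if (M < n_blocks) abort("M must be at least n_blocks")
  stopifnot(n_blocks >= 1, abs(rho_block) < 1)
  M <- as.integer(M)
  n_blocks <- as.integer(n_blocks)
  bounds <- floor(seq(0, M, length.out = n_blocks + 1))
  block <- rep(seq_len(n_blocks), times = diff(bounds))
  chromosome <- ((block - 1L) %% 22L) + 1L
  withr_seed(substream_seed(seed, "positions"))
  gap <- sample(500:1500, M, replace = TRUE)
  position <- stats::ave(gap, chromosome, FUN = cumsum)
  ids <- sprintf("rs%07d", seq_len(M))
  template <- tibble(variant_id = ids, chromosome = chromosome,
                     position = position, block = block)
  list(template = template, ld = ld_ar1(ids, block, rho_block))
}

#' Assign causal-mixture component labels
#'
#' Independent categorical draw per variant with probabilities `pis` over
#' (null, trait1-only, trait2-only, shared).
#'
#' @param template Genome template tibble.
#' @param pis Probability 4-vector summing to 1.
#' @param seed Integer seed.
#' @return Tibble with `variant_id`, `component` (factor).
#' @export
assign_components <- function(template, pis, seed = 1) {
  if (length(pis) != 4 || any(pis < 0) || abs(sum(pis) - 1) > 1e-12) {
    abort("pis must be 4 nonnegative probabilities summing to 1")
  }
  withr_seed(substream_seed(seed, "labels"))
  lab <- sample.int(4, nrow(template), replace = TRUE, prob = pis)
  tibble(variant_id = template$variant_id,
         component = factor(COMPONENTS[lab], levels = COMPONENTS))
}

#' Draw true effect sizes given component labels
#'
#' Trait-specific components draw one Gaussian effect and set the other
#' trait's effect to zero; the shared component draws a bivariate Gaussian
#' with correlation `rho12`; null variants are exactly (0, 0).
#'
#' @param labels Tibble from [assign_components()].
#' @param sigma1,sigma2 Effect standard deviations per trait.
#' @param rho12 Correlation of shared-component effects.
#' @param seed Integer seed.
#' @return Truth table tibble: `variant_id`, `component`, `beta1`, `beta2`.
#' @export
draw_effects <- function(labels, sigma1, sigma2, rho12, seed = 1) {
  if (sigma1 < 0 || sigma2 < 0) abort("effect standard deviations must be nonnegative")
  stopifnot(abs(rho12) <= 1)
  M <- nrow(labels)
  withr_seed(substream_seed(seed, "effects"))
  a <- rnorm(M)
  b <- rnorm(M)
  comp <- as.character(labels$component)
  beta1 <- numeric(M)
  beta2 <- numeric(M)
  i1 <- comp == "trait1_only"
  i2 <- comp == "trait2_only"
  i12 <- comp == "shared"
  beta1[i1] <- sigma1 * a[i1]
  beta2[i2] <- sigma2 * a[i2]
  beta1[i12] <- sigma1 * a[i12]
  beta2[i12] <- sigma2 * (rho12 * a[i12] + sqrt(1 - rho12^2) * b[i12])
  tibble(variant_id = labels$variant_id, component = labels$component,
         beta1 = beta1, beta2 = beta2)
}

# LD-weighted signal: delta_j = sqrt(N) * sum_i r(i, j) beta_i over
# neighbors with |r| >= the structure's truncation.
ld_convolve <- function(ld, beta, N) {
  if (ld$type == "ar1") {
    L <- ar1_max_lag(ld$rho, ld$min_r)
    M <- length(beta)
    acc <- beta
    if (L > 0 && M > 1) {
      for (d in seq_len(min(L, M - 1))) {
        w <- ld$rho^d
        fwd <- c(rep(0, d), beta[seq_len(M - d)])
        fwd_blk <- c(rep(NA_integer_, d), ld$block[seq_len(M - d)])
        fwd[is.na(fwd_blk) | fwd_blk != ld$block] <- 0
        bwd <- c(beta[(d + 1):M], rep(0, d))
        bwd_blk <- c(ld$block[(d + 1):M], rep(NA_integer_, d))
        bwd[is.na(bwd_blk) | bwd_blk != ld$block] <- 0
        acc <- acc + w * (fwd + bwd)
      }
    }
    sqrt(N) * acc
  } else {
    nz <- which(beta != 0)
    delta <- numeric(length(beta))
    names(delta) <- ld$ids
    delta[nz] <- beta[nz]
    if (length(nz) > 0) {
      nb <- ld_neighbors(ld, ld$ids[nz])
      nb <- nb[nb$variant_id != nb$neighbor, ]
      if (nrow(nb) > 0) {
        contrib <- nb$r * beta[match(nb$variant_id, ld$ids)]
        add <- tapply(contrib, nb$neighbor, sum)
        delta[names(add)] <- delta[names(add)] + add
      }
    }
    unname(sqrt(N) * delta)
  }
}

#' Simulate z-scores for both traits
#'
#' For trait t and variant j the signal is
#' `delta_tj = sqrt(N_t) * sum_i r(i, j) beta_ti` over the LD block
#' (|r| >= 0.05), and `z_tj = delta_tj + eps_tj` with (eps_1j, eps_2j)
#' bivariate Gaussian (marginal scales sigma0_t, correlation rho0).
#' Two-sided p-values use the unit-variance reference.
#'
#' @param truth Truth table from [draw_effects()].
#' @param ld LD structure on the same template.
#' @param config A [sim_config()]; its `seed` drives the noise substreams.
#' @return List with `trait1`, `trait2` (variant tables), `deltas`
#'   (tibble: `variant_id`, `delta1`, `delta2`), and `template` columns
#'   carried on the trait tables.
#' @export
simulate_zscores <- function(truth, ld, config) {
  M <- nrow(truth)
  delta1 <- ld_convolve(ld, truth$beta1, config$N1)
  delta2 <- ld_convolve(ld, truth$beta2, config$N2)
  withr_seed(substream_seed(config$seed, "noise1"))
  a <- rnorm(M)
  withr_seed(substream_seed(config$seed, "noise2"))
  b <- rnorm(M)
  e1 <- config$sigma0_1 * a
  e2 <- config$sigma0_2 * (config$rho0 * a + sqrt(1 - config$rho0^2) * b)
  z1 <- delta1 + e1
  z2 <- delta2 + e2
  mk <- function(z, N) {
    tibble(variant_id = truth$variant_id, z = z, p = two_sided_p(z),
           n = N)
  }
  list(trait1 = mk(z1, config$N1), trait2 = mk(z2, config$N2),
       deltas = tibble(variant_id = truth$variant_id, delta1 = delta1,
                       delta2 = delta2))
}

#' Simulate a replication draw
#'
#' Identical LD-weighted signal construction with sample size `n_rep` and
#' fresh independent noise; variant ids are preserved.  Calling with the
#' same seed and sample size as a discovery trait reproduces that trait's
#' z-vector exactly (when the discovery noise was uncorrelated).
#'
#' @param truth Truth table from [draw_effects()].
#' @param ld LD structure on the same template.
#' @param n_rep Replication sample size.
#' @param seed Integer seed.
#' @param trait Which trait's effects to replicate (1 or 2).
#' @param sigma0 Null noise scale of the replication sample.
#' @return A variant table tibble (`variant_id`, `z`, `p`, `n`).
#' @export
simulate_replication <- function(truth, ld, n_rep, seed, trait = 1,
                                 sigma0 = 1) {
  beta <- if (trait == 1) truth$beta1 else truth$beta2
  delta <- ld_convolve(ld, beta, n_rep)
  withr_seed(substream_seed(seed, if (trait == 1) "noise1" else "noise2"))
  z <- delta + sigma0 * rnorm(nrow(truth))
  tibble(variant_id = truth$variant_id, z = z, p = two_sided_p(z),
         n = n_rep)
}

#' Simulate a complete two-trait study
#'
#' Convenience wrapper running template construction, component
#' assignment, effect draws and z-score simulation from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `template`, `ld`, `truth`, `trait1`, `trait2`,
#'   `deltas`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "crossmix_sim_config"))
  gen <- make_genome_template(config$M, config$n_blocks, config$rho_block,
                              seed = config$seed)
  labels <- assign_components(gen$template, config$pis, seed = config$seed)
  truth <- draw_effects(labels, sqrt(config$sigma_b2_1),
                        sqrt(config$sigma_b2_2), config$rho12,
                        seed = config$seed)
  zz <- simulate_zscores(truth, gen$ld, config)
  t1 <- left_join(gen$template, zz$trait1, by = "variant_id")
  t2 <- left_join(gen$template, zz$trait2, by = "variant_id")
  t1$allele_effect <- "A"
  t1$allele_other <- "G"
  t2$allele_effect <- "A"
  t2$allele_other <- "G"
  list(template = gen$template, ld = gen$ld, truth = truth,
       trait1 = select(t1, "variant_id", "chromosome", "position",
                       "allele_effect", "allele_other", "z", "p", "n"),
       trait2 = select(t2, "variant_id", "chromosome", "position",
                       "allele_effect", "allele_other", "z", "p", "n"),
       deltas = zz$deltas)
}
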