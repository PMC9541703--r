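# Causal Gaussian mixture model of GWAS z-scores.
#
# Univariate stage: each variant is causal with probability pi1; causal
# effects are Gaussian with variance sigma_b2; the observed z-score is the
# LD-weighted sum of neighboring effects plus inflated null noise sigma0.
# Bivariate stage: four components (null / trait1-only / trait2-only /
# shared) with correlation rho12 within the shared component and noise
# correlation rho0 across traits.  Densities come from the characteristic-
# function convolution evaluated by FFT (see src/mixture.cpp); estimation
# resamples variant subsets with random LD pruning and reports the
# iteration mean and SD, MiXeR-style.

ids_or_index <- function(tbl) {
  if ("variant_id" %in% names(tbl)) tbl$variant_id
  else as.character(seq_len(nrow(tbl)))
}

no_ld_profiles <- function(n) {
  list(r2 = 1, counts = matrix(1, 1, 1), prof = rep(0L, n))
}

profiles_for <- function(ld, ids) {
  if (is.null(ld)) no_ld_profiles(length(ids)) else ld_profiles(ld, ids)
}

check_grid <- function(z, grid_n, zmax) {
  if (!is.null(zmax) && zmax < max(abs(z))) {
    abort(sprintf(
      "grid too coarse to cover max |z| = %.2f (zmax = %.2f)",
      max(abs(z)), zmax), class = "crossmix_config_error")
  }
  zmax %||% max(20, max(abs(z)) + 5)
}

#' Univariate mixture log-likelihood
#'
#' Sum over variants of the log density of the observed z-score under the
#' causal mixture: the density of z_j has characteristic function
#' `exp(-sigma0^2 t^2 / 2) * prod_i [1 - pi1 + pi1 exp(-N sigma_b2 r_ij^2
#' t^2 / 2)]` over LD neighbors i of j, inverted on a symmetric FFT grid.
#'
#' @param params List with `pi1` (causal proportion), `sigma_b2`
#'   (effect-size variance, per-allele standardized units) and `sigma0`
#'   (null noise scale).
#' @param sumstats Variant table with columns `z` and `n` (and
#'   `variant_id` when `ld` is supplied).
#' @param ld Optional `crossmix_ld`; `NULL` treats variants as LD-free.
#' @param grid List with `n` (FFT points, default 2048) and `zmax`
#'   (half-width; default `max(20, max |z| + 5)`).  A user-supplied `zmax`
#'   smaller than the largest |z| is a configuration error.
#' @return Scalar log-likelihood.
#' @export
univariate_loglik <- function(params, sumstats, ld = NULL, grid = NULL) {
  stopifnot(all(c("z", "n") %in% names(sumstats)))
  z <- sumstats$z
  stopifnot(all(is.finite(z)))
  grid_n <- grid$n %||% 2048
  zmax <- check_grid(z, grid_n, grid$zmax)
  pr <- profiles_for(ld, ids_or_index(sumstats))
  n_ref <- median(sumstats$n)
  cpp_uni_loglik(z, pr$prof, pr$counts, pr$r2, params$pi1,
                 params$sigma_b2 * n_ref, params$sigma0, grid_n, zmax)
}

#' Bivariate mixture log-likelihood
#'
#' Joint density of (z1, z2) under the four-component model: each LD
#' neighbor belongs to null / trait1-only / trait2-only / shared with
#' probabilities (pi0, pi1, pi2, pi12); shared effects have correlation
#' `rho12`; the noise is bivariate Gaussian with scales `sigma0_1`,
#' `sigma0_2` and correlation `rho0`.
#'
#' @param params List with `pi1`, `pi2`, `pi12`, `sigma_b2_1`,
#'   `sigma_b2_2`, `rho12`, `sigma0_1`, `sigma0_2`, `rho0`.  `pi1`/`pi2`
#'   are the trait-unique proportions.
#' @param merged Merged pair table with `z1`, `z2`, `n1`, `n2` (and
#'   `variant_id` when `ld` is supplied).
#' @param ld Optional `crossmix_ld`.
#' @param grid List with `n` (per-axis FFT points, default 128) and
#'   `zmax`.
#' @return Scalar log-likelihood.
#' @export
bivariate_loglik <- function(params, merged, ld = NULL, grid = NULL) {
  stopifnot(all(c("z1", "z2", "n1", "n2") %in% names(merged)))
  p <- params
  if (p$pi1 + p$pi2 + p$pi12 > 1 + 1e-12) {
    abort("component proportions exceed 1")
  }
  z1 <- merged$z1
  z2 <- merged$z2
  grid_n <- grid$n %||% 128
  zmax <- check_grid(c(z1, z2), grid_n, grid$zmax)
  pr <- profiles_for(ld, ids_or_index(merged))
  s1 <- p$sigma_b2_1 * median(merged$n1)
  s2 <- p$sigma_b2_2 * median(merged$n2)
  cpp_biv_loglik(z1, z2, pr$prof, pr$counts, pr$r2,
                 p$pi1, p$pi2, p$pi12, s1, s2, p$rho12,
                 p$sigma0_1, p$sigma0_2, p$rho0, grid_n, zmax)
}

random_uni_starts <- function(n_starts) {
  lapply(seq_len(n_starts), function(i) {
    c(qlogis(10^runif(1, -3.5, -0.8)),
      log(10^runif(1, 0, 2)),
      log(runif(1, 0.9, 1.2) - 0.5))
  })
}

run_starts <- function(starts, fn, reltol, maxit = 400) {
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      optim(st, fn, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) abort("optimizer failed to converge in all starts")
  best
}

#' Fit the univariate causal mixture
#'
#' Resampling estimator: per iteration a random variant subsample is
#' drawn, randomly pruned at the r-squared threshold, and (pi1, sigma_b2,
#' sigma0) maximized by Nelder-Mead simplex on transformed scales (logit /
#' log).  The first iteration uses `n_starts` random multi-starts;
#' subsequent iterations warm-start from the first solution.  Point
#' estimates are iteration means with iteration SDs.
#'
#' @param sumstats Variant table (`variant_id`, `z`, `n`).
#' @param ld `crossmix_ld` over the template (or `NULL` for LD-free data).
#' @param M Template size used to scale proportions into variant counts
#'   (defaults to `nrow(sumstats)`).
#' @param n_iter Number of resampling iterations (default 20).
#' @param n_subsample Variants drawn per iteration (default 20000).
#' @param prune_r2 Random-pruning threshold (default 0.8).
#' @param n_starts Random multi-starts in the first iteration (default 5).
#' @param seed Master seed; iterations use named substreams.
#' @param grid_n,zmax FFT grid (see [univariate_loglik()]).
#' @param reltol Simplex convergence tolerance.
#' @return A `crossmix_univariate_fit` with iteration table, estimates,
#'   SDs, log-likelihood, AIC against the pi1 = 0 null model, and derived
#'   quantities (causal-variant count, n90, heritability scale).
#' @export
fit_univariate <- function(sumstats, ld = NULL, M = nrow(sumstats),
                           n_iter = 20, n_subsample = 20000,
                           prune_r2 = 0.8, n_starts = 5, seed = 1,
                           grid_n = 2048, zmax = NULL, reltol = 1e-5) {
  ids_all <- ids_or_index(sumstats)
  z_all <- sumstats$z
  n_ref <- median(sumstats$n)
  zmax <- check_grid(z_all, grid_n, zmax)
  pr <- profiles_for(ld, ids_all)

  iter_rows <- vector("list", n_iter)
  eval_data <- NULL
  warm <- NULL
  warned_small <- FALSE
  for (k in seq_len(n_iter)) {
    withr_seed(substream_seed(seed, paste0("uni_iter_", k)))
    idx <- if (n_subsample < length(ids_all)) {
      sort(sample.int(length(ids_all), n_subsample))
    } else seq_along(ids_all)
    kept <- if (is.null(ld)) ids_all[idx] else {
      ld_prune(ld, ids_all[idx], prune_r2,
               seed = substream_seed(seed, paste0("uni_prune_", k)))
    }
    sel <- match(kept, ids_all)
    if (length(sel) < 1000 && !warned_small) {
      warn(sprintf("only %d variants after pruning (iteration %d)",
                   length(sel), k))
      warned_small <- TRUE
    }
    zz <- z_all[sel]
    pp <- pr$prof[sel]
    negll <- function(par) {
      -cpp_uni_loglik(zz, pp, pr$counts, pr$r2, plogis(par[1]),
                      exp(par[2]), 0.5 + exp(par[3]), grid_n, zmax)
    }
    if (k == 1) {
      withr_seed(substream_seed(seed, "uni_starts"))
      starts <- random_uni_starts(n_starts)
      eval_data <- list(z = zz, prof = pp)
    } else {
      starts <- list(warm)
    }
    best <- run_starts(starts, negll, reltol)
    if (k == 1) warm <- best$par
    iter_rows[[k]] <- tibble(
      iteration = k, pi1 = plogis(best$par[1]),
      sigma_b2 = exp(best$par[2]) / n_ref,
      sigma0 = 0.5 + exp(best$par[3]),
      loglik = -best$value, n_variants = length(sel))
  }
  iters <- bind_rows(iter_rows)
  est <- c(pi1 = mean(iters$pi1), sigma_b2 = mean(iters$sigma_b2),
           sigma0 = mean(iters$sigma0))
  sds <- if (n_iter >= 2) {
    c(sd(iters$pi1), sd(iters$sigma_b2), sd(iters$sigma0))
  } else rep(NA_real_, 3)

  ll_fit <- cpp_uni_loglik(eval_data$z, eval_data$prof, pr$counts, pr$r2,
                           est[["pi1"]], est[["sigma_b2"]] * n_ref,
                           est[["sigma0"]], grid_n, zmax)
  ll_null <- optimize(function(s0) {
    cpp_uni_loglik(eval_data$z, eval_data$prof, pr$counts, pr$r2,
                   0, 1, s0, grid_n, zmax)
  }, c(0.5, 5), maximum = TRUE)
  aic <- tibble(
    model = c("mixture", "null_pi1_0"),
    k = c(3, 1),
    loglik = c(ll_fit, ll_null$objective),
    aic = 2 * c(3, 1) - 2 * c(ll_fit, ll_null$objective))

  derived <- tibble(
    n_causal = est[["pi1"]] * M,
    n_causal_thousands = est[["pi1"]] * M / 1000,
    n90 = n90(est[["pi1"]], M, est[["sigma_b2"]]),
    h2_scale = M * est[["pi1"]] * est[["sigma_b2"]] * n_ref)

  structure(list(
    kind = "univariate",
    estimate = tibble(term = names(est), estimate = unname(est), sd = sds),
    iterations = iters, loglik = ll_fit, aic = aic, derived = derived,
    M = M, n_ref = n_ref, sb2N = est[["sigma_b2"]] * n_ref,
    grid = list(n = grid_n, zmax = zmax),
    config = list(n_iter = n_iter, n_subsample = n_subsample,
                  prune_r2 = prune_r2, n_starts = n_starts, seed = seed)),
    class = c("crossmix_univariate_fit", "crossmix_fit"))
}

fit_param <- function(fit, term) {
  fit$estimate$estimate[fit$estimate$term == term]
}

#' Fit the bivariate causal mixture
#'
#' The second, staged estimation step: per-trait totals (pi_total,
#' sigma_b2, sigma0) are held fixed at their univariate estimates and
#' (pi12, rho12, rho0) are maximized, with the unique proportions
#' constrained nonnegative via pi_t' = pi_total_t - pi12 and pi12 bounded
#' by the smaller total.  Resampling mirrors [fit_univariate()].
#'
#' @param merged Harmonized pair table (`variant_id`, `z1`, `z2`, `n1`,
#'   `n2`).
#' @param ld `crossmix_ld` (or `NULL`).
#' @param fit1,fit2 Univariate fits for the two traits.
#' @param M Template size.
#' @param n_iter,n_subsample,prune_r2,seed,reltol As in
#'   [fit_univariate()].
#' @param n_starts Random multi-starts in the first iteration (default 3).
#' @param grid_n Per-axis FFT points (default 128).
#' @param zmax Grid half-width (default `max(20, max |z| + 5)`).
#' @return A `crossmix_bivariate_fit` with iteration table, estimates and
#'   SDs, AIC against the minimal-overlap (pi12 = 0) and maximal-overlap
#'   (pi12 = min of totals) reference models, and derived quantities
#'   (shared/unique variant counts, genetic correlation, concordant
#'   fraction, n90 per component).
#' @export
fit_bivariate <- function(merged, ld = NULL, fit1, fit2, M = fit1$M,
                          n_iter = 20, n_subsample = 20000,
                          prune_r2 = 0.8, n_starts = 3, seed = 1,
                          grid_n = 128, zmax = NULL, reltol = 1e-4) {
  ids_all <- ids_or_index(merged)
  zmax <- check_grid(c(merged$z1, merged$z2), grid_n, zmax)
  pr <- profiles_for(ld, ids_all)

  ptot1 <- fit_param(fit1, "pi1")
  ptot2 <- fit_param(fit2, "pi1")
  s1 <- fit1$sb2N
  s2 <- fit2$sb2N
  sig01 <- fit_param(fit1, "sigma0")
  sig02 <- fit_param(fit2, "sigma0")
  pimax <- min(ptot1, ptot2)

  ll_at <- function(pi12, rho12, rho0, zz1, zz2, pp) {
    cpp_biv_loglik(zz1, zz2, pp, pr$counts, pr$r2,
                   ptot1 - pi12, ptot2 - pi12, pi12, s1, s2, rho12,
                   sig01, sig02, rho0, grid_n, zmax)
  }

  iter_rows <- vector("list", n_iter)
  eval_data <- NULL
  warm <- NULL
  for (k in seq_len(n_iter)) {
    withr_seed(substream_seed(seed, paste0("biv_iter_", k)))
    idx <- if (n_subsample < length(ids_all)) {
      sort(sample.int(length(ids_all), n_subsample))
    } else seq_along(ids_all)
    kept <- if (is.null(ld)) ids_all[idx] else {
      ld_prune(ld, ids_all[idx], prune_r2,
               seed = substream_seed(seed, paste0("biv_prune_", k)))
    }
    sel <- match(kept, ids_all)
    zz1 <- merged$z1[sel]
    zz2 <- merged$z2[sel]
    pp <- pr$prof[sel]
    negll <- function(par) {
      -ll_at(pimax * plogis(par[1]), tanh(par[2]), tanh(par[3]),
             zz1, zz2, pp)
    }
    if (k == 1) {
      withr_seed(substream_seed(seed, "biv_starts"))
      starts <- lapply(seq_len(n_starts), function(i) {
        c(qlogis(runif(1, 0.1, 0.9)), atanh(runif(1, -0.9, 0.9)),
          atanh(runif(1, -0.3, 0.3)))
      })
      eval_data <- list(z1 = zz1, z2 = zz2, prof = pp)
    } else {
      starts <- list(warm)
    }
    best <- run_starts(starts, negll, reltol, maxit = 300)
    if (k == 1) warm <- best$par
    iter_rows[[k]] <- tibble(
      iteration = k, pi12 = pimax * plogis(best$par[1]),
      rho12 = tanh(best$par[2]), rho0 = tanh(best$par[3]),
      loglik = -best$value, n_variants = length(sel))
  }
  iters <- bind_rows(iter_rows)
  est <- c(pi12 = mean(iters$pi12), rho12 = mean(iters$rho12),
           rho0 = mean(iters$rho0))
  sds <- if (n_iter >= 2) {
    c(sd(iters$pi12), sd(iters$rho12), sd(iters$rho0))
  } else rep(NA_real_, 3)

  ll_fit <- ll_at(est[["pi12"]], est[["rho12"]], est[["rho0"]],
                  eval_data$z1, eval_data$z2, eval_data$prof)
  ll_min <- optimize(function(r0) {
    ll_at(0, 0, r0, eval_data$z1, eval_data$z2, eval_data$prof)
  }, c(-0.99, 0.99), maximum = TRUE)
  opt_max <- optim(c(atanh(est[["rho12"]]), atanh(est[["rho0"]])),
                   function(par) {
                     -ll_at(pimax, tanh(par[1]), tanh(par[2]),
                            eval_data$z1, eval_data$z2, eval_data$prof)
                   }, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 300))
  aic <- tibble(
    model = c("fitted", "min_overlap_pi12_0", "max_overlap_pi12_min_total"),
    k = c(3, 1, 2),
    loglik = c(ll_fit, ll_min$objective, -opt_max$value),
    aic = 2 * c(3, 1, 2) - 2 * c(ll_fit, ll_min$objective, -opt_max$value))

  params <- list(pi1 = ptot1 - est[["pi12"]], pi2 = ptot2 - est[["pi12"]],
                 pi12 = est[["pi12"]], rho12 = est[["rho12"]],
                 rho0 = est[["rho0"]])
  derived <- tibble(
    n_shared = est[["pi12"]] * M,
    n_unique_1 = (ptot1 - est[["pi12"]]) * M,
    n_unique_2 = (ptot2 - est[["pi12"]]) * M,
    n_total_1 = ptot1 * M,
    n_total_2 = ptot2 * M,
    rg = genetic_correlation(params),
    concordant_fraction = concordant_fraction(est[["rho12"]]),
    n90_shared = n90(est[["pi12"]], M, s1),
    n90_total_1 = n90(ptot1, M, s1),
    n90_total_2 = n90(ptot2, M, s2))

  structure(list(
    kind = "bivariate",
    estimate = tibble(term = names(est), estimate = unname(est), sd = sds),
    fixed = tibble(term = c("pi_total_1", "pi_total_2", "sigma0_1",
                            "sigma0_2"),
                   estimate = c(ptot1, ptot2, sig01, sig02)),
    iterations = iters, loglik = ll_fit, aic = aic, derived = derived,
    M = M, grid = list(n = grid_n, zmax = zmax),
    config = list(n_iter = n_iter, n_subsample = n_subsample,
                  prune_r2 = prune_r2, n_starts = n_starts, seed = seed)),
    class = c("crossmix_bivariate_fit", "crossmix_fit"))
}

#' Number of causal variants explaining 90% of heritability
#'
#' Under chi-square(1)-distributed squared effects, the count of largest-
#' effect causal variants whose effects account for 90% of total
#' heritability: solve `E[X 1(X > t)] = 0.9 E[X]` for X ~ chi-square(1)
#' (equivalently `P(chisq_3 > t) = 0.9`) and return
#' `round(pi * M * P(X > t))`.  The ratio n90 / (pi M) is a constant,
#' independent of the effect variance.
#'
#' @param pi Causal proportion in \[0, 1\].
#' @param M Template variant count.
#' @param sigma_b2 Effect-size variance (unused by the ratio; accepted for
#'   interface symmetry).
#' @return Integer count.
#' @export
n90 <- function(pi, M, sigma_b2 = NULL) {
  stopifnot(pi >= 0, pi <= 1)
  if (pi == 0) return(0)
  t <- qchisq(0.9, 3, lower.tail = FALSE)
  round(pi * M * pchisq(t, 1, lower.tail = FALSE))
}

#' Genetic correlation from bivariate mixture parameters
#'
#' With effect variance shared within trait across components,
#' `rg = rho12 * pi12 / sqrt((pi1 + pi12) * (pi2 + pi12))`; 0 when either
#' trait has no causal variants.
#'
#' @param params List (or bivariate fit) with `pi1`, `pi2` (unique
#'   proportions), `pi12` and `rho12`.
#' @return Scalar correlation.
#' @export
genetic_correlation <- function(params) {
  if (inherits(params, "crossmix_bivariate_fit")) {
    fx <- setNames(params$fixed$estimate, params$fixed$term)
    es <- setNames(params$estimate$estimate, params$estimate$term)
    params <- list(pi1 = fx[["pi_total_1"]] - es[["pi12"]],
                   pi2 = fx[["pi_total_2"]] - es[["pi12"]],
                   pi12 = es[["pi12"]], rho12 = es[["rho12"]])
  }
  tot1 <- params$pi1 + params$pi12
  tot2 <- params$pi2 + params$pi12
  if (tot1 <= 0 || tot2 <= 0) return(0)
  params$rho12 * params$pi12 / sqrt(tot1 * tot2)
}

#' Fraction of shared variants with concordant effect directions
#'
#' Orthant probability of a centered bivariate normal:
#' `1/2 + arcsin(rho12) / pi`.
#'
#' @param rho12 Shared-component effect correlation in \[-1, 1\].
#' @return Probability in \[0, 1\].
#' @export
concordant_fraction <- function(rho12) {
  stopifnot(all(abs(rho12) <= 1))
  0.5 + asin(rho12) / pi
}

#' @export
print.crossmix_fit <- function(x, ...) {
  cat(sprintf("<crossmix %s fit: %d iterations, M = %g>\n", x$kind,
              nrow(x$iterations), x$M))
  print(x$estimate)
  cat("derived:\n")
  print(x$derived)
  invisible(x)
}

#' @export
tidy.crossmix_fit <- function(x, ...) {
  rename(x$estimate, std.error = "sd")
}

#' @export
glance.crossmix_fit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic$aic[1],
         n_iterations = nrow(x$iterations), M = x$M)
}

#' Venn-style overlap summary plot for a bivariate fit
#'
#' Shows the estimated trait-unique and shared causal-variant counts (in
#' thousands) as a horizontal stacked bar, annotated with the genetic
#' correlation.
#'
#' @param object A `crossmix_bivariate_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmix_bivariate_fit <- function(object, ...) {
  d <- object$derived
  df <- tibble(
    component = factor(c("trait 1 only", "shared", "trait 2 only"),
                       levels = c("trait 1 only", "shared", "trait 2 only")),
    thousands = c(d$n_unique_1, d$n_shared, d$n_unique_2) / 1000)
  ggplot(df, aes(x = "overlap", y = .data$thousands,
                 fill = .data$component)) +
    geom_col(width = 0.5) +
    coord_flip() +
    labs(x = NULL, y = "causal variants (thousands)",
         title = sprintf("shared %.1fk, rg = %.2f, concordant %.0f%%",
                         d$n_shared / 1000, d$rg,
                         100 * d$concordant_fraction)) +
    theme_minimal()
}
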