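# Mixture likelihood correctness (closed forms, Monte-Carlo oracles,
# symmetry, grid refinement), derived quantities, and model selection.

test_that("pi1 = 0 collapses the univariate likelihood to the null normal", {
  z <- seq(-6, 6, by = 0.37)
  ss <- tibble::tibble(z = z, n = 1e5)
  ll <- univariate_loglik(list(pi1 = 0, sigma_b2 = 1e-4, sigma0 = 1.3),
                          ss, NULL, grid = list(n = 2048, zmax = 20))
  expect_lt(abs(ll - sum(dnorm(z, 0, 1.3, log = TRUE))),
            1e-6 * length(z))
})

test_that("single-variant density matches a large Monte-Carlo draw", {
  set.seed(101)
  n_mc <- 1e6
  caus <- rbinom(n_mc, 1, 0.5)
  zmc <- rnorm(n_mc, 0, sqrt(1 + caus * 20))
  h <- 0.2
  for (z0 in c(0, 1, 2, 4, 6)) {
    ll <- univariate_loglik(list(pi1 = 0.5, sigma_b2 = 2e-4, sigma0 = 1),
                            tibble::tibble(z = z0, n = 1e5), NULL,
                            grid = list(n = 2048, zmax = 20))
    p_pred <- exp(ll) * h
    p_hat <- mean(abs(zmc - z0) < h / 2)
    se <- sqrt(p_pred * (1 - p_pred) / n_mc)
    expect_lt(abs(p_hat - p_pred), 3 * se + 1e-5)
  }
})

test_that("the univariate density is symmetric in z", {
  ss_pos <- tibble::tibble(z = c(0.7, 2.3, 5.1), n = 5e4)
  ss_neg <- tibble::tibble(z = -ss_pos$z, n = 5e4)
  p <- list(pi1 = 0.1, sigma_b2 = 3e-4, sigma0 = 1.05)
  g <- list(n = 2048, zmax = 20)
  expect_equal(univariate_loglik(p, ss_pos, NULL, g),
               univariate_loglik(p, ss_neg, NULL, g))
})

test_that("a too-narrow grid is a configuration error", {
  ss <- tibble::tibble(z = c(0, 25), n = 1e4)
  expect_error(
    univariate_loglik(list(pi1 = 0, sigma_b2 = 1e-4, sigma0 = 1), ss,
                      NULL, grid = list(n = 2048, zmax = 10)),
    class = "crossmix_config_error")
})

test_that("AR(1) profile grouping equals an explicit sparse-LD evaluation", {
  cfg <- sim_config(M = 90, n_blocks = 3, rho_block = 0.8, seed = 6)
  st <- simulate_study(cfg)
  ids <- st$template$variant_id
  rows <- list()
  for (i in seq_along(ids)) {
    nb <- ld_neighbors(st$ld, ids[i])
    nb <- nb[nb$variant_id != nb$neighbor & match(nb$neighbor, ids) > i, ]
    if (nrow(nb) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant_i = nb$variant_id, variant_j = nb$neighbor, r = nb$r)
    }
  }
  sp <- ld_from_pairs(dplyr::bind_rows(rows), ids = ids)
  ss <- dplyr::select(st$trait1, variant_id, z, n)
  p <- list(pi1 = 0.08, sigma_b2 = 2e-4, sigma0 = 1)
  g <- list(n = 2048, zmax = 25)
  expect_equal(univariate_loglik(p, ss, st$ld, g),
               univariate_loglik(p, ss, sp, g), tolerance = 1e-8)
})

test_that("doubling the grid leaves the log-likelihood unchanged at 1e-4 per variant", {
  cfg <- sim_config(M = 2000, n_blocks = 20, seed = 7)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  ss <- dplyr::select(m, variant_id, z = z1, n = n1)
  p <- list(pi1 = 0.07, sigma_b2 = 2e-4, sigma0 = 1)
  zm <- max(20, max(abs(ss$z)) + 5)
  l1 <- univariate_loglik(p, ss, st$ld, grid = list(n = 2048, zmax = zm))
  l2 <- univariate_loglik(p, ss, st$ld, grid = list(n = 4096, zmax = zm))
  expect_lt(abs(l1 - l2) / nrow(ss), 1e-4)

  pb <- list(pi1 = 0.03, pi2 = 0.03, pi12 = 0.04, sigma_b2_1 = 2e-4,
             sigma_b2_2 = 2e-4, rho12 = 0.6, sigma0_1 = 1, sigma0_2 = 1,
             rho0 = 0)
  zb <- max(20, max(abs(c(m$z1, m$z2))) + 5)
  b1 <- bivariate_loglik(pb, m, st$ld, grid = list(n = 128, zmax = zb))
  b2 <- bivariate_loglik(pb, m, st$ld, grid = list(n = 256, zmax = zb))
  expect_lt(abs(b1 - b2) / nrow(m), 1e-4)
})

test_that("the null bivariate model collapses to a bivariate normal exactly", {
  m <- tibble::tibble(z1 = c(-2, 0, 1, 3), z2 = c(1, -1, 0, 2),
                      n1 = 1e5, n2 = 1e5)
  p <- list(pi1 = 0, pi2 = 0, pi12 = 0, sigma_b2_1 = 1e-4,
            sigma_b2_2 = 1e-4, rho12 = 0, sigma0_1 = 1.1,
            sigma0_2 = 0.9, rho0 = 0.4)
  lb <- bivariate_loglik(p, m, NULL, grid = list(n = 1024, zmax = 12))
  S <- matrix(c(1.1^2, 0.4 * 1.1 * 0.9, 0.4 * 1.1 * 0.9, 0.9^2), 2)
  Si <- solve(S)
  ref <- sum(apply(cbind(m$z1, m$z2), 1, function(v) {
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * t(v) %*% Si %*% v
  }))
  expect_lt(abs(lb - ref), 1e-6 * nrow(m))
})

test_that("single-variant bivariate density matches a Monte-Carlo oracle on a probe grid", {
  set.seed(202)
  n_mc <- 1e6
  comp <- sample.int(4, n_mc, replace = TRUE,
                     prob = c(0.55, 0.1, 0.15, 0.2))
  s1 <- 20
  s2 <- 10
  rho12 <- 0.6
  b1 <- b2 <- numeric(n_mc)
  i1 <- comp == 2
  i2 <- comp == 3
  i12 <- comp == 4
  b1[i1] <- sqrt(s1) * rnorm(sum(i1))
  b2[i2] <- sqrt(s2) * rnorm(sum(i2))
  a <- rnorm(sum(i12))
  b1[i12] <- sqrt(s1) * a
  b2[i12] <- sqrt(s2) * (rho12 * a + sqrt(1 - rho12^2) * rnorm(sum(i12)))
  e <- matrix(rnorm(2 * n_mc), ncol = 2) %*% chol(matrix(c(1, 0.2, 0.2, 1), 2))
  z1 <- b1 + e[, 1]
  z2 <- b2 + e[, 2]
  params <- list(pi1 = 0.1, pi2 = 0.15, pi12 = 0.2, sigma_b2_1 = 2e-4,
                 sigma_b2_2 = 1e-4, rho12 = 0.6, sigma0_1 = 1,
                 sigma0_2 = 1, rho0 = 0.2)
  h <- 0.2  # small bin so the midpoint rule is exact to within MC noise
  for (x0 in c(-4, -2, 0, 2, 4)) {
    for (y0 in c(-4, -2, 0, 2, 4)) {
      ll <- bivariate_loglik(params,
                             tibble::tibble(z1 = x0, z2 = y0, n1 = 1e5,
                                            n2 = 1e5), NULL,
                             grid = list(n = 512, zmax = 16))
      p_pred <- exp(ll) * h^2
      p_hat <- mean(abs(z1 - x0) < h / 2 & abs(z2 - y0) < h / 2)
      se <- sqrt(p_pred * (1 - p_pred) / n_mc)
      expect_lt(abs(p_hat - p_pred), 3 * se + 2e-5)
    }
  }
})

test_that("swapping trait labels and transposing parameters leaves the likelihood unchanged", {
  cfg <- sim_config(M = 500, n_blocks = 10, seed = 8, sigma_b2_2 = 1e-4,
                    sigma0_2 = 1.05, rho0 = 0.1)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  p <- list(pi1 = 0.02, pi2 = 0.05, pi12 = 0.03, sigma_b2_1 = 2e-4,
            sigma_b2_2 = 1e-4, rho12 = -0.4, sigma0_1 = 1,
            sigma0_2 = 1.05, rho0 = 0.1)
  ps <- list(pi1 = p$pi2, pi2 = p$pi1, pi12 = p$pi12,
             sigma_b2_1 = p$sigma_b2_2, sigma_b2_2 = p$sigma_b2_1,
             rho12 = p$rho12, sigma0_1 = p$sigma0_2,
             sigma0_2 = p$sigma0_1, rho0 = p$rho0)
  ms <- dplyr::mutate(m, zz = z1, z1 = z2, z2 = zz, nn = n1, n1 = n2,
                      n2 = nn)
  g <- list(n = 128, zmax = 25)
  expect_equal(bivariate_loglik(p, m, st$ld, g),
               bivariate_loglik(ps, ms, st$ld, g), tolerance = 1e-10)
})

test_that("fits are deterministic under a fixed seed", {
  cfg <- sim_config(M = 4000, n_blocks = 40, seed = 31)
  st <- simulate_study(cfg)
  ss <- dplyr::select(st$trait1, variant_id, z, n)
  f1 <- fit_univariate(ss, st$ld, M = 4000, n_iter = 2,
                       n_subsample = 2000, seed = 5)
  f2 <- fit_univariate(ss, st$ld, M = 4000, n_iter = 2,
                       n_subsample = 2000, seed = 5)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$iterations, f2$iterations)
})

test_that("a pure-null fit does not beat the null model by more than 2 AIC", {
  cfg <- sim_config(M = 20000, n_blocks = 20000, pis = c(1, 0, 0, 0),
                    seed = 17)
  st <- simulate_study(cfg)
  ss <- dplyr::select(st$trait1, variant_id, z, n)
  f <- suppressWarnings(
    fit_univariate(ss, NULL, M = 20000, n_iter = 2, n_subsample = 10000,
                   seed = 3))
  aic <- setNames(f$aic$aic, f$aic$model)
  expect_lte(aic[["null_pi1_0"]] - aic[["mixture"]], 2)
})

test_that("independent traits prefer the minimal-overlap reference within 2 AIC", {
  cfg <- sim_config(M = 20000, n_blocks = 20000,
                    pis = c(0.9, 0.05, 0.05, 0), seed = 23)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  f1 <- fit_univariate(dplyr::select(m, variant_id, z = z1, n = n1),
                       NULL, M = 20000, n_iter = 2, n_subsample = 10000,
                       seed = 3)
  f2 <- fit_univariate(dplyr::select(m, variant_id, z = z2, n = n2),
                       NULL, M = 20000, n_iter = 2, n_subsample = 10000,
                       seed = 4)
  fb <- fit_bivariate(m, NULL, f1, f2, M = 20000, n_iter = 2,
                      n_subsample = 10000, seed = 5)
  aic <- setNames(fb$aic$aic, fb$aic$model)
  expect_lte(aic[["min_overlap_pi12_0"]], aic[["fitted"]] + 2)
})

test_that("n90 follows the chi-square truncated-mean identity", {
  expect_equal(n90(0, 1e5), 0)
  # quadrature oracle: solve E[X 1(X > t)] = 0.9 for X ~ chisq(1)
  g <- function(t) {
    stats::integrate(function(x) x * dchisq(x, 1), t, Inf,
                     rel.tol = 1e-10)$value
  }
  t_star <- stats::uniroot(function(t) g(t) - 0.9, c(0.01, 5),
                           tol = 1e-10)$root
  ratio_oracle <- pchisq(t_star, 1, lower.tail = FALSE)
  expect_lt(abs(n90(0.1, 1e6) / (0.1 * 1e6) - ratio_oracle), 1e-3)
  # monotone in pi at fixed M
  pis <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(pis, n90, numeric(1), M = 5e4)) >= 0))
})

test_that("genetic correlation matches its definition and a Monte-Carlo identity", {
  expect_equal(genetic_correlation(list(pi1 = 0.1, pi2 = 0.1, pi12 = 0,
                                        rho12 = 0.9)), 0)
  expect_equal(genetic_correlation(list(pi1 = 0, pi2 = 0, pi12 = 0.05,
                                        rho12 = 1)), 1)
  # sample correlation of true effects across all variants
  gen <- make_genome_template(2e5, 2000, 0.8, seed = 1)
  pis <- c(0.85, 0.05, 0.04, 0.06)
  lab <- assign_components(gen$template, pis, seed = 11)
  tr <- draw_effects(lab, 0.01, 0.01, rho12 = 0.7, seed = 12)
  rg_formula <- genetic_correlation(list(pi1 = pis[2], pi2 = pis[3],
                                         pi12 = pis[4], rho12 = 0.7))
  expect_lt(abs(cor(tr$beta1, tr$beta2) - rg_formula), 0.03)
})

test_that("concordant fraction is the bivariate normal orthant probability", {
  expect_equal(concordant_fraction(0), 0.5)
  expect_equal(concordant_fraction(0.5), 2 / 3, tolerance = 1e-12)
  set.seed(33)
  n <- 1e5
  a <- rnorm(n)
  b <- 0.3 * a + sqrt(1 - 0.09) * rnorm(n)
  expect_lt(abs(mean(sign(a) == sign(b)) - concordant_fraction(0.3)),
            0.005)
})
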