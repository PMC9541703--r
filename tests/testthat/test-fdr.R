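# Conditional QQ construction and condFDR/conjFDR estimation.

test_that("a threshold-1 stratum reproduces the unconditional QQ curve", {
  cfg <- sim_config(M = 5000, n_blocks = 50, seed = 14)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  qq <- conditional_qq(m, strata = c(1, 0.1), primary = 1)
  s1 <- qq[qq$stratum == 1, ]
  uncond <- sort(-log10(pmax(m$p1, 1e-300)), decreasing = TRUE)
  expect_equal(s1$observed, uncond)
  expect_equal(s1$n[1], nrow(m))
})

test_that("small strata are flagged unstable but still returned", {
  m <- tibble::tibble(z1 = rnorm(50), z2 = rnorm(50))
  m$p1 <- 2 * pnorm(-abs(m$z1))
  m$p2 <- 2 * pnorm(-abs(m$z2))
  qq <- conditional_qq(m, strata = c(1, 0.5))
  expect_true(all(qq$unstable))
  expect_gt(nrow(qq), 0)
})

test_that("independent traits show no stratified enrichment beyond sampling noise", {
  cfg <- sim_config(M = 1e5, pis = c(0.9, 0.05, 0.05, 0), seed = 15)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  qq <- conditional_qq(m, primary = 1)
  # each stratum draws from the same marginal distribution of p1, so its
  # 99th-percentile point must sit inside the sampling band of the full
  # (threshold-1) stratum's quantile at that stratum's sample size
  full <- qq$observed[qq$stratum == 1]
  for (s in unique(qq$stratum)) {
    sub <- qq[qq$stratum == s, ]
    n_s <- sub$n[1]
    sig <- 3 * sqrt(0.01 * 0.99 / n_s)
    band <- quantile(full, c(max(0.99 - sig, 0), min(0.99 + sig, 1)),
                     names = FALSE)
    obs <- quantile(sub$observed, 0.99, names = FALSE)
    expect_gte(obs, band[1] - 0.1)
    expect_lte(obs, band[2] + 0.1)
  }
})

test_that("shared signal deflects strata in order of conditioning strictness", {
  cfg <- sim_config(M = 1e5, seed = 16)  # pi12 = 0.04, rho12 = 0.6
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  qq <- conditional_qq(m, primary = 1)
  q99 <- vapply(sort(unique(qq$stratum), decreasing = TRUE),
                function(s) {
                  quantile(qq$observed[qq$stratum == s], 0.99,
                           names = FALSE)
                }, numeric(1))
  expect_true(all(diff(q99) > 0))  # stricter conditioning, stronger curve
})

test_that("condFDR reproduces direct stratified arithmetic on a toy table", {
  # 10 variants all inside the conditioning stratum, 2 with p1 <= 0.01
  m <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:10), chromosome = 1L,
    position = 1:10 * 1000,
    p1 = c(0.002, 0.009, seq(0.3, 0.9, length.out = 8)),
    p2 = rep(0.005, 10))
  lk <- build_fdr_lookup(m, ld = NULL, primary = 1,
                         strata = c(1, 0.01), n_prune_iter = 1,
                         exclusions = NULL, seed = 1)
  expect_equal(cond_fdr(lk, 0.01, 0.005), 0.01 / 0.2)
  # querying exactly at a grid node returns the stored value
  ix <- which(lk$grid_x == 2)
  iy <- length(lk$grid_y)
  expect_equal(cond_fdr(lk, 1e-2, 1e-2), lk$values[ix, iy])
})

test_that("condFDR is monotone and reduces to the unconditional estimate at p2 = 1", {
  cfg <- sim_config(M = 2e4, n_blocks = 200, seed = 18)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  lk <- build_fdr_lookup(m, st$ld, primary = 1, n_prune_iter = 5,
                         exclusions = NULL, seed = 2)
  # non-increasing when the conditioning p gets smaller at fixed p1
  p2s <- c(1, 0.5, 0.1, 0.05, 0.01, 0.001)
  v <- cond_fdr(lk, rep(1e-4, length(p2s)), p2s)
  expect_true(all(diff(v) <= 1e-12))
  # non-decreasing in p1 along a conditioning slice
  p1s <- 10^seq(-8, 0, by = 0.5)
  w <- cond_fdr(lk, p1s, rep(0.01, length(p1s)))
  expect_true(all(diff(w) >= -1e-12))
  # vacuous conditioning equals p / Fhat on the pruned sets
  kept_union <- lapply(1:5, function(it) {
    ld_prune(st$ld, m$variant_id, 0.1,
             seed = substream_seed(2, paste0("fdr_prune_", it)))
  })
  p_query <- 1e-3
  cf_direct <- mean(vapply(kept_union, function(k) {
    f <- mean(m$p1[m$variant_id %in% k] <= p_query)
    min(p_query / f, 1)
  }, numeric(1)))
  expect_equal(cond_fdr(lk, p_query, 1), cf_direct, tolerance = 1e-9)
})

test_that("complete-null data give condFDR near 1 on the moderate grid", {
  cfg <- sim_config(M = 1e5, n_blocks = 1e5, pis = c(1, 0, 0, 0),
                    seed = 19)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  lk <- build_fdr_lookup(m, NULL, primary = 1, n_prune_iter = 20,
                         exclusions = NULL, seed = 3)
  # probe only where the stratified CDF rests on enough variants for
  # p / Fhat to concentrate (expected count at least ~50)
  probes <- list(c(0.5, 1), c(1, 1), c(1.5, 1), c(2, 1), c(2.5, 1),
                 c(0.5, 0.1), c(1, 0.1), c(1.5, 0.1),
                 c(0.5, 0.01), c(1, 0.01))
  for (pr in probes) {
    v <- cond_fdr(lk, 10^-pr[1], pr[2])
    expect_gte(v, 0.8)
    expect_lte(v, 1)
  }
})

test_that("the lookup is deterministic and round-trips through TSV", {
  cfg <- sim_config(M = 5000, n_blocks = 50, seed = 20)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  a <- build_fdr_lookup(m, st$ld, primary = 1, n_prune_iter = 3, seed = 9)
  b <- build_fdr_lookup(m, st$ld, primary = 1, n_prune_iter = 3, seed = 9)
  expect_identical(a$values, b$values)
  path <- tempfile(fileext = ".tsv")
  write_fdr_lookup(a, path)
  c <- read_fdr_lookup(path)
  expect_equal(unname(c$values), unname(a$values), tolerance = 1e-6)
  expect_equal(c$strata, a$strata)
})

test_that("doubling pruning iterations barely moves the averaged grid", {
  cfg <- sim_config(M = 2e4, n_blocks = 200, seed = 22)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  l20 <- build_fdr_lookup(m, st$ld, primary = 1, n_prune_iter = 20,
                          seed = 4)
  l40 <- build_fdr_lookup(m, st$ld, primary = 1, n_prune_iter = 40,
                          seed = 4)
  rms <- sqrt(mean((l20$values - l40$values)^2))
  expect_lt(rms, 0.01)
})

test_that("conjFDR is the maximum of the two mutual halves", {
  cfg <- sim_config(M = 5000, n_blocks = 50, seed = 24)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  res <- conj_fdr_table(m, st$ld, n_prune_iter = 3, seed = 5)
  tab <- res$table
  expect_equal(tab$conjfdr, pmax(tab$condfdr_1, tab$condfdr_2))
  expect_equal(tab$significant, tab$conjfdr < 0.05)
  # symmetric traits: conjFDR equals either half (LD-free so that the
  # two lookups see identical pruning)
  m_sym <- dplyr::mutate(m, z2 = z1, p2 = p1, n2 = n1)
  sym <- conj_fdr_table(m_sym, NULL, n_prune_iter = 3, seed = 5)
  expect_equal(sym$table$conjfdr, sym$table$condfdr_1, tolerance = 1e-9)
})

test_that("exclusion-region variants are left out of the CDF but still scored", {
  m <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:40), chromosome = 6L,
    position = c(seq(26e6, 33e6, length.out = 20),
                 seq(40e6, 60e6, length.out = 20)),
    p1 = rep(c(0.001, 0.3, 0.5, 0.9), 10), p2 = 0.5)
  with_excl <- build_fdr_lookup(m, NULL, primary = 1, strata = c(1),
                                n_prune_iter = 1, seed = 1)
  no_excl <- build_fdr_lookup(m, NULL, primary = 1, strata = c(1),
                              n_prune_iter = 1, exclusions = NULL,
                              seed = 1)
  # same p-value mix inside and outside the MHC here, so the grids agree;
  # scoring an excluded variant still returns an interpolated value
  v <- cond_fdr(with_excl, m$p1[1], m$p2[1])
  expect_true(v > 0 && v <= 1)
  expect_false(is.null(with_excl$exclusions))
  expect_null(no_excl$exclusions)
})
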