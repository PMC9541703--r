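# Locus definition against brute-force oracles, novelty flagging,
# concordance summaries and transdiagnostic merging.

test_that("a single significant variant forms a singleton locus", {
  tbl <- tibble::tibble(variant_id = "v1", chromosome = 1L,
                        position = 500, conjfdr = 0.01, z1 = 2, z2 = 1)
  ld <- ld_from_pairs(tibble::tibble(variant_i = character(0),
                                     variant_j = character(0),
                                     r = numeric(0)), ids = "v1")
  loci <- define_loci(tbl, ld)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$lead_snp, "v1")
  expect_equal(loci$start, 500)
  expect_equal(loci$end, 500)
  expect_true(loci$concordant)
})

test_that("variants failing both merge rules form separate loci", {
  tbl <- tibble::tibble(variant_id = c("v1", "v2"), chromosome = 1L,
                        position = c(1e6, 2e6), conjfdr = c(0.01, 0.02),
                        z1 = c(2, -2), z2 = c(1, 1))
  ld <- ld_from_pairs(tibble::tibble(variant_i = "v1", variant_j = "v2",
                                     r = sqrt(0.05)),
                      ids = c("v1", "v2"))
  loci <- define_loci(tbl, ld)
  expect_equal(nrow(loci), 2)
  expect_equal(sort(loci$lead_snp), c("v1", "v2"))
})

test_that("no significant variant yields an empty loci table, not an error", {
  tbl <- tibble::tibble(variant_id = "v1", chromosome = 1L,
                        position = 100, conjfdr = 0.2, z1 = 1, z2 = 1)
  ld <- ld_from_pairs(tibble::tibble(variant_i = character(0),
                                     variant_j = character(0),
                                     r = numeric(0)), ids = "v1")
  expect_equal(nrow(define_loci(tbl, ld)), 0)
})

test_that("candidate selection matches exhaustive rule evaluation", {
  # 6-variant fixture: v1 significant; v2 in strong LD and sub-0.10;
  # v3 strong LD but conjFDR 0.2; v4 weak LD; v5 sub-0.10 but no LD;
  # v6 significant on its own
  tbl <- tibble::tibble(
    variant_id = paste0("v", 1:6), chromosome = 1L,
    position = 1:6 * 1e5,
    conjfdr = c(0.01, 0.07, 0.20, 0.08, 0.09, 0.04),
    z1 = rnorm(6), z2 = rnorm(6))
  pairs <- tibble::tibble(
    variant_i = c("v1", "v1", "v1", "v6"),
    variant_j = c("v2", "v3", "v4", "v5"),
    r = c(0.9, 0.85, 0.5, 0.3))
  ld <- ld_from_pairs(pairs, ids = tbl$variant_id)
  r2 <- oracle_r2_matrix(tbl$variant_id, pairs)
  indep <- c("v1", "v6")
  got <- find_candidate_snps(tbl, ld, indep)
  expect_setequal(got$variant_id, oracle_candidates(tbl, r2, indep))
  # a variant above the candidate threshold is excluded whatever its LD
  expect_false("v3" %in% got$variant_id)
  # an independent significant SNP is always its own candidate
  expect_true(all(indep %in% got$variant_id))
})

test_that("clumping matches the brute-force oracle on randomized fixtures", {
  for (seed in 1:8) {
    fx <- random_locus_fixture(seed, n = 10)
    got <- define_loci(fx$tbl, fx$ld)
    want <- oracle_clump(fx$tbl, fx$r2)
    expect_equal(nrow(got), length(want$loci), info = paste("seed", seed))
    if (nrow(got) == 0) next
    got_members <- lapply(got$independent_snps, sort)
    want_members <- lapply(want$loci, function(l) l$members)
    om <- order(vapply(got_members, paste, character(1), collapse = ","))
    ow <- order(vapply(want_members, paste, character(1), collapse = ","))
    for (k in seq_along(om)) {
      g <- got[om[k], ]
      w <- want$loci[[ow[k]]]
      expect_equal(sort(g$independent_snps[[1]]), w$members)
      expect_equal(g$lead_snp, w$lead)
      expect_equal(sort(g$candidate_snps[[1]]), w$candidates)
      expect_equal(g$start, w$start)
      expect_equal(g$end, w$end)
    }
  }
})

test_that("every significant variant lands in exactly one locus and leads are unlinked", {
  cfg <- sim_config(M = 2e4, n_blocks = 200, seed = 26)
  st <- simulate_study(cfg)
  m <- harmonize_pair(st$trait1, st$trait2)
  cj <- conj_fdr_table(m, st$ld, n_prune_iter = 5, seed = 6)
  loci <- define_loci(cj$table, st$ld)
  sig_ids <- cj$table$variant_id[cj$table$significant]
  cand_all <- unlist(loci$candidate_snps)
  expect_equal(anyDuplicated(cand_all), 0)
  expect_true(all(sig_ids %in% cand_all))
  leads <- loci$lead_snp
  if (length(leads) > 1) {
    for (i in seq_along(leads)) {
      r <- ld_r(st$ld, rep(leads[i], length(leads)), leads)^2
      r[i] <- 0
      expect_true(all(r < 0.1))
    }
  }
})

test_that("concordance summaries match the printed-percentage convention", {
  mk <- function(k, n) {
    tibble::tibble(lead_z1 = rep(1, n),
                   lead_z2 = c(rep(1, k), rep(-1, n - k)))
  }
  expect_equal(directional_concordance(mk(157, 163))$summary$percent, 96.3)
  expect_equal(directional_concordance(mk(39, 60))$summary$percent, 65.0)
  # a zero z has no sign: excluded and the denominator shrinks
  z0 <- tibble::tibble(lead_z1 = c(1, 0, -1), lead_z2 = c(1, 1, -2))
  s <- directional_concordance(z0)$summary
  expect_equal(s$n_tested, 2)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$n_concordant, 2)
})

test_that("novelty respects inclusive interval overlap", {
  loci <- tibble::tibble(locus_id = 1L, chromosome = 1L, start = 100,
                         end = 200)
  overlapping <- list(t1 = tibble::tibble(chromosome = 1L, start = 200,
                                          end = 300))
  adjacent <- list(t1 = tibble::tibble(chromosome = 1L, start = 201,
                                       end = 300))
  none <- list(t1 = tibble::tibble(chromosome = integer(0),
                                   start = numeric(0), end = numeric(0)))
  expect_false(annotate_novelty(loci, overlapping)$novel_t1)
  expect_true(annotate_novelty(loci, adjacent)$novel_t1)
  expect_true(annotate_novelty(loci, none)$novel_t1)
})

mk_analysis <- function(loci_rows, conjfdr_tbl) {
  list(loci = loci_rows, conjfdr = conjfdr_tbl)
}

test_that("transdiagnostic merging follows overlap and shared-candidate rules", {
  univ <- tibble::tibble(
    variant_id = paste0("v", 1:6), position = 1:6 * 1e4,
    chromosome = c(1L, 1L, 1L, 2L, 2L, 2L))
  mk_conj <- function(fdrs) {
    tibble::tibble(variant_id = univ$variant_id,
                   position = univ$position,
                   chromosome = univ$chromosome, conjfdr = fdrs,
                   z1 = rep(1, 6), z2 = rep(1, 6))
  }
  locus <- function(chr, s, e, cands, lead = cands[1]) {
    tibble::tibble(locus_id = 1L, chromosome = chr, start = s, end = e,
                   lead_snp = lead, candidate_snps = list(cands))
  }
  # different chromosomes never merge
  a <- mk_analysis(locus(1L, 1e4, 3e4, c("v1", "v2")),
                   mk_conj(c(0.01, 0.02, 1, 1, 1, 1)))
  b <- mk_analysis(locus(2L, 4e4, 6e4, c("v4", "v5")),
                   mk_conj(c(1, 1, 1, 0.01, 0.02, 1)))
  expect_equal(nrow(merge_transdiagnostic(list(A = a, B = b))), 0)

  # physical overlap without a jointly significant shared candidate
  c1 <- mk_analysis(locus(1L, 1e4, 3e4, c("v1", "v2")),
                    mk_conj(c(0.01, 0.03, 1, 1, 1, 1)))
  c2 <- mk_analysis(locus(1L, 2e4, 3e4, c("v2", "v3")),
                    mk_conj(c(1, 0.08, 0.04, 1, 1, 1)))
  expect_equal(nrow(merge_transdiagnostic(list(A = c1, B = c2))), 0)
  # the same pair with the shared candidate significant in both merges
  c2b <- mk_analysis(locus(1L, 2e4, 3e4, c("v2", "v3")),
                     mk_conj(c(1, 0.02, 0.04, 1, 1, 1)))
  tr <- merge_transdiagnostic(list(A = c1, B = c2b))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 1e4)
  expect_equal(tr$end, 3e4)
})

test_that("three-analysis merging matches the brute-force oracle and input order", {
  univ <- tibble::tibble(
    variant_id = paste0("v", 1:8), position = 1:8 * 1e4,
    chromosome = rep(1L, 8))
  set.seed(77)
  mk_conj <- function(fdrs) {
    tibble::tibble(variant_id = univ$variant_id,
                   position = univ$position,
                   chromosome = univ$chromosome, conjfdr = fdrs,
                   z1 = rnorm(8), z2 = rnorm(8))
  }
  lt <- function(s, e, cands) {
    tibble::tibble(locus_id = 1L, chromosome = 1L, start = s, end = e,
                   lead_snp = cands[1], candidate_snps = list(cands))
  }
  A <- mk_analysis(lt(1e4, 4e4, c("v1", "v2", "v3")),
                   mk_conj(c(0.01, 0.02, 0.04, 1, 1, 1, 1, 1)))
  B <- mk_analysis(lt(3e4, 6e4, c("v3", "v4", "v5")),
                   mk_conj(c(1, 1, 0.03, 0.01, 0.2, 1, 1, 1)))
  C <- mk_analysis(lt(6e4, 8e4, c("v6", "v7")),
                   mk_conj(c(1, 1, 1, 1, 0.04, 0.01, 0.03, 1)))
  got <- merge_transdiagnostic(list(A = A, B = B, C = C))
  want <- oracle_transdiag(list(A = A, B = B, C = C))
  expect_equal(nrow(got), length(want))
  o <- order(got$start)
  for (k in seq_along(want)) {
    expect_equal(sort(got$analyses[[o[k]]]), want[[k]]$analyses)
    expect_equal(got$lead_snp[o[k]], want[[k]]$lead)
    expect_equal(got$start[o[k]], want[[k]]$start)
    expect_equal(got$end[o[k]], want[[k]]$end)
  }
  # permuting the input order changes nothing
  got_perm <- merge_transdiagnostic(list(C = C, A = A, B = B))
  expect_equal(as.data.frame(got), as.data.frame(got_perm))
})
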