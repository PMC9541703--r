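# Independent brute-force oracles and fixture builders.  These re-derive
# expected results directly from the stated rules (loops and explicit
# enumeration) and never share code with the implementation under test.

# exact binomial upper tail by direct pmf summation
oracle_binom_tail <- function(k, n) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i), numeric(1))) / 2^n
}

# exact hypergeometric upper tail by combinatorial sum
oracle_hyper_tail <- function(q, K, N, n) {
  if (q <= 0) return(1)
  hi <- min(K, n)
  if (q > hi) return(0)
  sum(vapply(q:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# symmetric r^2 matrix from a sparse pair tibble
oracle_r2_matrix <- function(ids, pairs) {
  m <- diag(1, length(ids))
  rownames(m) <- colnames(m) <- ids
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$variant_i[i]
    b <- pairs$variant_j[i]
    m[a, b] <- m[b, a] <- pairs$r[i]^2
  }
  m
}

# candidate rule evaluated exhaustively over every variant
oracle_candidates <- function(tbl, r2, indep_ids, cand = 0.10,
                              r2c = 0.6) {
  out <- character(0)
  for (v in tbl$variant_id) {
    fdr <- tbl$conjfdr[tbl$variant_id == v]
    if (fdr >= cand) next
    if (any(r2[v, indep_ids] >= r2c)) out <- c(out, v)
  }
  sort(out)
}

# full clumping oracle: greedy by the stated rules on an explicit r^2
# matrix, with transitive closure for locus grouping done by repeated
# sweeps
oracle_clump <- function(tbl, r2, sig = 0.05, cand = 0.10, r2i = 0.6,
                         r2l = 0.1, merge_bp = 250000) {
  ord <- tbl[order(tbl$conjfdr, tbl$position, tbl$variant_id), ]
  sigs <- ord[ord$conjfdr < sig, ]
  indep <- character(0)
  for (v in sigs$variant_id) {
    if (length(indep) == 0 || all(r2[v, indep] < r2i)) {
      indep <- c(indep, v)
    }
  }
  leads <- character(0)
  for (v in indep) {
    if (length(leads) == 0 || all(r2[v, leads] < r2l)) {
      leads <- c(leads, v)
    }
  }
  # locus membership: repeated sweeps until stable
  grp <- seq_along(indep)
  repeat {
    changed <- FALSE
    for (i in seq_along(indep)) {
      for (j in seq_along(indep)) {
        if (i == j) next
        ci <- tbl[tbl$variant_id == indep[i], ]
        cj <- tbl[tbl$variant_id == indep[j], ]
        link <- ci$chromosome == cj$chromosome &&
          (abs(ci$position - cj$position) <= merge_bp ||
             r2[indep[i], indep[j]] >= r2l)
        if (link && grp[i] != grp[j]) {
          g <- min(grp[i], grp[j])
          grp[grp == grp[i] | grp == grp[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # candidates and their locus assignment (strongest r^2, ties by
  # independent-SNP id)
  cand_ids <- oracle_candidates(tbl, r2, indep, cand, r2i)
  cand_locus <- vapply(cand_ids, function(v) {
    rs <- r2[v, indep]
    best <- indep[order(-rs, indep)][1]
    grp[match(best, indep)]
  }, numeric(1))
  loci <- lapply(sort(unique(grp)), function(g) {
    members <- indep[grp == g]
    cands <- cand_ids[cand_locus == g]
    pos <- tbl$position[match(cands, tbl$variant_id)]
    lead_cands <- members[members %in% leads]
    mtab <- tbl[match(members, tbl$variant_id), ]
    mord <- members[order(mtab$conjfdr, mtab$position, members)]
    list(members = sort(members),
         lead = if (length(lead_cands) > 0) {
           lc <- tbl[match(lead_cands, tbl$variant_id), ]
           lead_cands[order(lc$conjfdr, lc$position, lead_cands)][1]
         } else mord[1],
         candidates = sort(cands),
         start = min(pos), end = max(pos),
         chromosome = tbl$chromosome[match(members[1], tbl$variant_id)])
  })
  list(indep = indep, leads = leads, loci = loci)
}

# transdiagnostic merging oracle: all overlap pairs enumerated, closure
# by sweeps, lead by exhaustive scan of the candidate union
oracle_transdiag <- function(analyses, sig = 0.05) {
  analyses <- analyses[sort(names(analyses))]
  rows <- list()
  for (nm in names(analyses)) {
    lt <- analyses[[nm]]$loci
    for (i in seq_len(nrow(lt))) {
      rows[[length(rows) + 1]] <- list(
        analysis = nm, chromosome = lt$chromosome[i],
        start = lt$start[i], end = lt$end[i],
        candidates = lt$candidate_snps[[i]])
    }
  }
  n <- length(rows)
  grp <- seq_len(n)
  conj <- function(nm, ids) {
    tab <- analyses[[nm]]$conjfdr
    tab$conjfdr[match(ids, tab$variant_id)]
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || rows[[i]]$analysis == rows[[j]]$analysis) next
        if (rows[[i]]$chromosome != rows[[j]]$chromosome) next
        if (max(rows[[i]]$start, rows[[j]]$start) >
              min(rows[[i]]$end, rows[[j]]$end)) next
        shared <- intersect(rows[[i]]$candidates, rows[[j]]$candidates)
        if (length(shared) == 0) next
        ok <- conj(rows[[i]]$analysis, shared) <= sig &
          conj(rows[[j]]$analysis, shared) <= sig
        if (any(ok) && grp[i] != grp[j]) {
          g <- min(grp[i], grp[j])
          grp[grp == grp[i] | grp == grp[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- list()
  for (g in sort(unique(grp))) {
    members <- rows[grp == g]
    contributing <- sort(unique(vapply(members, function(m) m$analysis,
                                       character(1))))
    if (length(contributing) < 2) next
    cand_union <- sort(unique(unlist(lapply(members,
                                            function(m) m$candidates))))
    maxc <- rep(-Inf, length(cand_union))
    for (nm in contributing) maxc <- pmax(maxc, conj(nm, cand_union))
    pos <- analyses[[contributing[1]]]$conjfdr$position[
      match(cand_union, analyses[[contributing[1]]]$conjfdr$variant_id)]
    o <- order(maxc, pos, cand_union)
    out[[length(out) + 1]] <- list(
      analyses = contributing, lead = cand_union[o[1]],
      start = min(vapply(members, function(m) m$start, numeric(1))),
      end = max(vapply(members, function(m) m$end, numeric(1))))
  }
  out
}

# small sparse-LD fixture generator for clumping property tests
random_locus_fixture <- function(seed, n = 10) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  chr <- sample(1:2, n, replace = TRUE)
  pos <- integer(n)
  for (c in unique(chr)) {
    k <- sum(chr == c)
    pos[chr == c] <- sort(sample(1:2e6, k))
  }
  tbl <- tibble::tibble(variant_id = ids, chromosome = chr,
                        position = pos,
                        conjfdr = round(runif(n, 0.001, 0.2), 4),
                        z1 = rnorm(n), z2 = rnorm(n))
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i < pairs$j & chr[pairs$i] == chr[pairs$j], ]
  keep <- runif(nrow(pairs)) < 0.4
  pairs <- pairs[keep, , drop = FALSE]
  pr <- tibble::tibble(variant_i = ids[pairs$i], variant_j = ids[pairs$j],
                       r = round(runif(nrow(pairs), -0.95, 0.95), 3))
  list(tbl = tbl, pairs = pr, ld = ld_from_pairs(pr, ids = ids),
       r2 = oracle_r2_matrix(ids, pr))
}

write_tmp_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}
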