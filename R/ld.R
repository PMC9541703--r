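# Linkage-disequilibrium structure.
#
# Two representations share one query interface:
#   * "sparse"  -- an explicit pair list (variant_i, variant_j, r); unlisted
#                  pairs are exactly 0, the diagonal is exactly 1.
#   * "ar1"     -- block-diagonal AR(1) correlation used by the synthetic
#                  genome: within a block r(i, j) = rho^|i-j|, across blocks 0.
#
# Likelihood code additionally consumes "LD profiles": variants grouped by
# the multiset of squared correlations to their neighbors (|r| >= min_r,
# self included), so that variants with identical local LD share one density.

new_ld <- function(type, ...) {
  structure(list(type = type, ...), class = "crossmix_ld")
}

#' Build an LD structure from an explicit pair table
#'
#' @param pairs Data frame with columns `variant_i`, `variant_j`, `r`
#'   (signed correlation in \[-1, 1\]).  Symmetry is implied: each pair needs
#'   to be listed once.  Pairs absent from the table have r = 0; every
#'   variant has r = 1 with itself.
#' @param ids Optional character vector giving the full variant universe
#'   (defaults to the ids present in `pairs`).
#' @return An object of class `crossmix_ld`.
#' @export
ld_from_pairs <- function(pairs, ids = NULL) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("variant_i", "variant_j", "r") %in% names(pairs)))
  bad <- which(abs(pairs$r) > 1)
  if (length(bad) > 0) {
    abort(sprintf("|r| > 1 at pair row %d", bad[1]), class = "crossmix_format_error")
  }
  pairs <- dplyr::filter(pairs, .data$variant_i != .data$variant_j)
  ids <- ids %||% sort(unique(c(pairs$variant_i, pairs$variant_j)))
  new_ld("sparse", pairs = pairs, ids = ids)
}

#' Block AR(1) LD over an ordered variant template
#'
#' @param ids Character vector of variant ids in template order.
#' @param block Integer block id per variant (blocks are contiguous runs).
#' @param rho Within-block correlation decay parameter, |rho| < 1; r between
#'   variants at in-block distance d is `rho^d`.
#' @param min_r Truncation for neighbor enumeration and signal construction;
#'   pairs with |r| below this are treated as 0 (default 0.05).
#' @return An object of class `crossmix_ld`.
#' @export
ld_ar1 <- function(ids, block, rho, min_r = 0.05) {
  stopifnot(length(ids) == length(block), abs(rho) < 1, min_r > 0)
  new_ld("ar1", ids = ids, block = as.integer(block), rho = rho,
         min_r = min_r, index = setNames(seq_along(ids), ids))
}

#' @export
print.crossmix_ld <- function(x, ...) {
  cat(sprintf("<crossmix_ld: %s, %d variants>\n", x$type, length(x$ids)))
  invisible(x)
}

# maximum in-block distance with |r| >= min_r (ar1)
ar1_max_lag <- function(rho, min_r) {
  if (rho == 0) return(0L)
  as.integer(floor(log(min_r) / log(abs(rho)) + 1e-9))
}

# maximum in-block distance with r^2 above r2_threshold (ar1); strict
# controls whether equality counts as in-LD
ar1_max_lag_r2 <- function(rho, r2_threshold, strict = TRUE) {
  if (rho == 0) return(0L)
  if (r2_threshold <= 0) abort("r2 threshold must be positive")
  if (strict && r2_threshold >= 1) return(0L)
  d <- log(r2_threshold) / (2 * log(abs(rho)))
  lag <- if (strict) as.integer(ceiling(d - 1e-9) - 1)
    else as.integer(floor(d + 1e-9))
  max(lag, 0L)
}

#' Pairwise LD correlation lookup
#'
#' Vectorized over pairs of variant ids.  Unknown pairs return 0; the
#' diagonal returns 1 without being listed.
#'
#' @param ld A `crossmix_ld` object.
#' @param id_a,id_b Character vectors of variant ids (recycled to a common
#'   length).
#' @return Numeric vector of signed correlations.
#' @export
ld_r <- function(ld, id_a, id_b) {
  n <- max(length(id_a), length(id_b))
  id_a <- rep_len(id_a, n)
  id_b <- rep_len(id_b, n)
  out <- numeric(n)
  out[id_a == id_b] <- 1
  off <- which(id_a != id_b)
  if (length(off) == 0) return(out)
  if (ld$type == "sparse") {
    key <- c(paste(ld$pairs$variant_i, ld$pairs$variant_j, sep = "\r"),
             paste(ld$pairs$variant_j, ld$pairs$variant_i, sep = "\r"))
    val <- setNames(rep(ld$pairs$r, 2), key)
    hit <- val[paste(id_a[off], id_b[off], sep = "\r")]
    hit[is.na(hit)] <- 0
    out[off] <- unname(hit)
  } else {
    ia <- ld$index[id_a[off]]
    ib <- ld$index[id_b[off]]
    same <- !is.na(ia) & !is.na(ib) & ld$block[ia] == ld$block[ib]
    r <- numeric(length(off))
    r[same] <- ld$rho^abs(ia[same] - ib[same])
    out[off] <- r
  }
  out
}

#' Neighbor list for a set of variants
#'
#' Returns every pair (id, neighbor) with |r| at or above `min_r`,
#' including the variant itself (r = 1).
#'
#' @param ld A `crossmix_ld` object.
#' @param ids Character vector of focal variant ids.
#' @param min_r Minimum |r| to report (default the structure's truncation,
#'   or 0.05 for sparse tables).
#' @return Tibble with columns `variant_id`, `neighbor`, `r`.
#' @export
ld_neighbors <- function(ld, ids, min_r = NULL) {
  min_r <- min_r %||% (ld$min_r %||% 0.05)
  self <- tibble(variant_id = ids, neighbor = ids, r = 1)
  if (ld$type == "sparse") {
    both <- bind_rows(
      tibble(variant_id = ld$pairs$variant_i, neighbor = ld$pairs$variant_j,
             r = ld$pairs$r),
      tibble(variant_id = ld$pairs$variant_j, neighbor = ld$pairs$variant_i,
             r = ld$pairs$r))
    nb <- dplyr::filter(both, .data$variant_id %in% ids, abs(.data$r) >= min_r)
    return(arrange(bind_rows(self, nb), .data$variant_id, desc(abs(.data$r))))
  }
  L <- ar1_max_lag(ld$rho, min_r)
  if (L == 0) return(self)
  idx <- ld$index[ids]
  M <- length(ld$ids)
  rows <- vector("list", 2 * L + 1)
  k <- 1
  for (d in c(-(L:1), 1:L)) {
    j <- idx + d
    ok <- j >= 1 & j <= M
    ok[ok] <- ld$block[j[ok]] == ld$block[idx[ok]]
    rows[[k]] <- tibble(variant_id = ids[ok], neighbor = ld$ids[j[ok]],
                        r = ld$rho^abs(d))
    k <- k + 1
  }
  arrange(bind_rows(self, rows), .data$variant_id, desc(abs(.data$r)))
}

# Edge list (0-based CSR) among `ids` at r^2 above `r2_threshold`
# (strictly above when strict = TRUE, at-or-above otherwise).
ld_adjacency <- function(ld, ids, r2_threshold, strict = TRUE) {
  n <- length(ids)
  if (ld$type == "sparse") {
    above <- if (strict) ld$pairs$r^2 > r2_threshold
      else ld$pairs$r^2 >= r2_threshold
    pr <- ld$pairs[above & ld$pairs$variant_i %in% ids &
                     ld$pairs$variant_j %in% ids, ]
    pos <- setNames(seq_len(n), ids)
    ii <- unname(pos[pr$variant_i]) - 1L
    jj <- unname(pos[pr$variant_j]) - 1L
  } else {
    L <- ar1_max_lag_r2(ld$rho, r2_threshold, strict)
    idx <- sort(unname(ld$index[ids]))
    ord_ids <- ld$ids[idx]
    ii <- jj <- integer(0)
    if (L > 0 && n > 1) {
      rank_of <- seq_len(n)
      for (d in seq_len(min(L, n - 1))) {
        a <- idx[seq_len(n - d)]
        b <- idx[seq_len(n - d) + d]
        ok <- (b - a) <= L & ld$block[a] == ld$block[b]
        ii <- c(ii, rank_of[seq_len(n - d)][ok] - 1L)
        jj <- c(jj, rank_of[seq_len(n - d) + d][ok] - 1L)
      }
    }
    ids <- ord_ids
  }
  # symmetric CSR
  from <- c(ii, jj)
  to <- c(jj, ii)
  o <- order(from, to)
  from <- from[o]
  to <- to[o]
  ptr <- c(0L, cumsum(tabulate(from + 1L, nbins = n)))
  list(ids = ids, ptr = as.integer(ptr), idx = as.integer(to))
}

#' Random LD pruning
#'
#' Greedy sequential pruning in a random order: a variant is kept iff no
#' variant already kept is in LD with it above the r-squared threshold
#' (strict).  With no LD above the threshold every variant is kept.
#'
#' @param ld A `crossmix_ld` object.
#' @param ids Variant ids to prune.
#' @param r2_threshold Strict r-squared threshold defining LD clusters.
#' @param seed Integer seed for the random visiting order.
#' @return Character vector of kept variant ids.
#' @export
ld_prune <- function(ld, ids, r2_threshold, seed) {
  adj <- ld_adjacency(ld, ids, r2_threshold)
  n <- length(adj$ids)
  if (n == 0) return(character(0))
  withr_seed(seed)
  ord <- sample.int(n) - 1L
  keep <- cpp_greedy_keep(ord, adj$ptr, adj$idx)
  adj$ids[keep]
}

# set.seed without polluting the caller's RNG state
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% 2147483647))
  invisible(NULL)
}

# LD profiles for likelihood evaluation: group variants by the multiset of
# squared correlations (|r| >= min_r, self included) to template neighbors.
ld_profiles <- function(ld, ids, min_r = 0.05) {
  if (ld$type == "ar1") {
    min_r <- max(min_r, ld$min_r)
    L <- ar1_max_lag(ld$rho, min_r)
    idx <- ld$index[ids]
    blk <- ld$block[idx]
    # distance to block edges, capped at L
    first_of_block <- tapply(seq_along(ld$block), ld$block, min)
    last_of_block <- tapply(seq_along(ld$block), ld$block, max)
    dl <- pmin(idx - first_of_block[as.character(blk)], L)
    dr <- pmin(last_of_block[as.character(blk)] - idx, L)
    a <- pmin(dl, dr)
    b <- pmax(dl, dr)
    key <- paste(a, b)
    r2 <- ld$rho^(2 * (0:L))
    ukey <- sort(unique(key))
    counts <- matrix(0, nrow = length(ukey), ncol = L + 1)
    parts <- strsplit(ukey, " ", fixed = TRUE)
    for (p in seq_along(ukey)) {
      aa <- as.integer(parts[[p]][1])
      bb <- as.integer(parts[[p]][2])
      counts[p, ] <- if (L > 0) c(1, (seq_len(L) <= aa) + (seq_len(L) <= bb)) else 1
    }
    prof <- match(key, ukey)
  } else {
    nb <- ld_neighbors(ld, ids, min_r = min_r)
    nb$r2 <- round(nb$r^2, 9)
    per <- split(nb$r2, factor(nb$variant_id, levels = ids))
    key <- vapply(per, function(v) paste(sort(v), collapse = ","),
                  character(1))
    r2 <- sort(unique(nb$r2))
    ukey <- sort(unique(key))
    counts <- matrix(0, nrow = length(ukey), ncol = length(r2))
    for (p in seq_along(ukey)) {
      vals <- as.numeric(strsplit(ukey[p], ",", fixed = TRUE)[[1]])
      tb <- table(factor(vals, levels = r2))
      counts[p, ] <- as.numeric(tb)
    }
    prof <- match(key, ukey)
  }
  list(r2 = r2, counts = counts, prof = as.integer(prof) - 1L)
}
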