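# Conditional QQ curves and condFDR/conjFDR estimation.
#
# condFDR(p1 | p2 <= s) is the conservative empirical-Bayes estimate
# p1 / Fhat(p1 | p2 <= s) (null proportion set to 1), built on a grid over
# (-log10 p1, -log10 p2) from stratified empirical CDFs, averaged over
# random LD-pruning iterations and monotone-regularized.  conjFDR is the
# maximum of the two mutual condFDR values; conjFDR < 0.05 is the single
# significance threshold used everywhere downstream.

#' Default exclusion regions
#'
#' Regions with long-range or inverted LD that would distort the empirical
#' CDFs: the extended MHC (chr6:25-34 Mb) and the chr8 inversion
#' (chr8:7-12 Mb).  Variants inside are excluded from CDF construction but
#' still receive interpolated condFDR values.
#'
#' @return Tibble with `chromosome`, `start`, `end` (1-based inclusive).
#' @export
default_exclusion_regions <- function() {
  tibble(chromosome = c(6L, 8L), start = c(25e6, 7e6), end = c(34e6, 12e6))
}

in_regions <- function(chromosome, position, regions) {
  hit <- rep(FALSE, length(chromosome))
  if (is.null(regions) || nrow(regions) == 0) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chromosome == regions$chromosome[i] &
                    position >= regions$start[i] &
                    position <= regions$end[i])
  }
  hit
}

#' Conditional QQ curves
#'
#' For each conditioning stratum (p of the conditioning trait at or below
#' the threshold), the empirical quantiles of -log10 p of the primary
#' trait against the uniform expectation.  Successive leftward deflection
#' with stricter conditioning visualizes cross-trait enrichment.
#'
#' @param merged Harmonized pair table (`z1`, `p1`, `z2`, `p2`).
#' @param strata Descending conditioning thresholds (default 1, 0.1, 0.01,
#'   0.001).
#' @param primary Which trait's p-values are plotted (1 or 2); the other
#'   conditions.
#' @return A tibble of class `crossmix_qq` with columns `stratum`, `n`,
#'   `unstable` (fewer than 100 variants), `expected`, `observed`
#'   (-log10 scale).
#' @export
conditional_qq <- function(merged, strata = c(1, 0.1, 0.01, 0.001),
                           primary = 1) {
  stopifnot(nrow(merged) > 0, all(diff(strata) < 0), all(strata <= 1),
            all(strata > 0))
  pp <- if (primary == 1) merged$p1 else merged$p2
  pc <- if (primary == 1) merged$p2 else merged$p1
  rows <- lapply(strata, function(s) {
    sel <- pc <= s
    n <- sum(sel)
    if (n == 0) {
      return(tibble(stratum = s, n = 0L, unstable = TRUE,
                    expected = numeric(0), observed = numeric(0)))
    }
    obs <- sort(-log10(clamp_p(pp[sel])), decreasing = TRUE)
    exp_q <- -log10((seq_len(n) - 0.5) / n)
    tibble(stratum = s, n = n, unstable = n < 100,
           expected = exp_q, observed = obs)
  })
  out <- bind_rows(rows)
  class(out) <- c("crossmix_qq", class(out))
  attr(out, "primary") <- primary
  out
}

#' @export
autoplot.crossmix_qq <- function(object, ...) {
  df <- mutate(object, stratum = factor(.data$stratum,
                                        levels = sort(unique(.data$stratum),
                                                      decreasing = TRUE)))
  ggplot(df, aes(x = .data$expected, y = .data$observed,
                 color = .data$stratum)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = expression(-log[10] * " expected p"),
         y = expression(-log[10] * " observed p"),
         color = "conditioning\nthreshold") +
    theme_minimal()
}

ecdf_at <- function(sorted_p, grid_p, n_floor) {
  # empirical CDF evaluated at grid_p, floored at 1/n (conservative)
  n <- length(sorted_p)
  if (n == 0) return(rep(NA_real_, length(grid_p)))
  f <- findInterval(grid_p, sorted_p) / n
  pmax(f, n_floor / n)
}

#' Build a conditional FDR lookup
#'
#' For each random-pruning iteration one variant per LD cluster (r-squared
#' above `prune_r2`) is kept; for each conditioning stratum the empirical
#' CDF of the primary p-value is formed among kept variants passing the
#' conditioning threshold and condFDR = p / Fhat on the -log10 grid.
#' Grids are averaged over iterations, interpolated between strata along
#' the conditioning axis, and monotone-regularized (non-increasing in
#' -log10 p1; non-increasing in -log10 p2 via cumulative minimum).
#' Exclusion-region variants are removed before CDF construction.
#'
#' @param merged Harmonized pair table (`variant_id`, `chromosome`,
#'   `position`, `p1`, `p2`).
#' @param ld `crossmix_ld` (or `NULL` for LD-free data).
#' @param primary Trait whose p-value the lookup is for (1 or 2); the
#'   other trait conditions.
#' @param strata Descending conditioning thresholds.
#' @param grid_x -log10 p grid for the primary axis (default 0..10 by
#'   0.1).
#' @param n_y Nodes on the conditioning axis (default 41).
#' @param n_prune_iter Random-pruning iterations (default 20).
#' @param prune_r2 LD-cluster threshold (default 0.1).
#' @param exclusions Interval tibble (default
#'   [default_exclusion_regions()]); `NULL` disables.
#' @param seed Integer seed.
#' @return An object of class `crossmix_fdr_lookup`.
#' @export
build_fdr_lookup <- function(merged, ld = NULL, primary = 1,
                             strata = c(1, 0.1, 0.01, 0.001),
                             grid_x = seq(0, 10, by = 0.1), n_y = 41,
                             n_prune_iter = 20, prune_r2 = 0.1,
                             exclusions = default_exclusion_regions(),
                             seed = 1) {
  stopifnot(all(diff(strata) < 0), all(strata > 0), all(strata <= 1))
  p1 <- clamp_p(if (primary == 1) merged$p1 else merged$p2)
  p2 <- clamp_p(if (primary == 1) merged$p2 else merged$p1)
  ids <- merged$variant_id
  excl <- if (!is.null(exclusions) &&
              all(c("chromosome", "position") %in% names(merged))) {
    in_regions(merged$chromosome, merged$position, exclusions)
  } else rep(FALSE, nrow(merged))

  grid_p <- 10^(-grid_x)
  n_strata <- length(strata)
  acc <- matrix(0, nrow = length(grid_x), ncol = n_strata)
  for (it in seq_len(n_prune_iter)) {
    kept_ids <- if (is.null(ld)) ids else {
      ld_prune(ld, ids, prune_r2,
               seed = substream_seed(seed, paste0("fdr_prune_", it)))
    }
    kept <- ids %in% kept_ids & !excl
    cf_prev <- NULL
    for (s in seq_len(n_strata)) {
      sel <- kept & p2 <= strata[s]
      if (sum(sel) == 0) {
        if (is.null(cf_prev)) {
          abort("no variants available for the least strict stratum")
        }
        warn(sprintf("empty stratum %g merged with parent", strata[s]))
        cf <- cf_prev
      } else {
        f <- ecdf_at(sort(p1[sel]), grid_p, n_floor = 1)
        cf <- pmin(grid_p / f, 1)
      }
      acc[, s] <- acc[, s] + cf
      cf_prev <- cf
    }
  }
  vals_strata <- acc / n_prune_iter

  # interpolate strata onto a regular conditioning grid (-log10 p2)
  y_strata <- -log10(strata)
  if (length(strata) == 1) {
    grid_y <- y_strata
    vals <- vals_strata
  } else {
    grid_y <- seq(min(y_strata), max(y_strata), length.out = n_y)
    vals <- matrix(NA_real_, nrow = length(grid_x), ncol = n_y)
    for (i in seq_along(grid_x)) {
      vals[i, ] <- stats::approx(y_strata, vals_strata[i, ],
                                 xout = grid_y, rule = 2)$y
    }
  }
  # regularize: non-increasing along -log10 p1 and along -log10 p2
  for (j in seq_len(ncol(vals))) vals[, j] <- cummin(vals[, j])
  for (i in seq_along(grid_x)) vals[i, ] <- cummin(vals[i, ])
  vals <- pmin(pmax(vals, P_FLOOR), 1)

  structure(list(grid_x = grid_x, grid_y = grid_y, values = vals,
                 strata = strata, primary = primary,
                 n_prune_iter = n_prune_iter, prune_r2 = prune_r2,
                 exclusions = exclusions, seed = seed),
            class = "crossmix_fdr_lookup")
}

#' @export
print.crossmix_fdr_lookup <- function(x, ...) {
  cat(sprintf(
    "<crossmix_fdr_lookup: primary trait %d, %d x %d grid, %d pruning iterations>\n",
    x$primary, length(x$grid_x), length(x$grid_y), x$n_prune_iter))
  invisible(x)
}

#' Conditional FDR for (p1, p2) pairs
#'
#' Bilinear interpolation of the lookup in (-log10 p1, -log10 p2);
#' queries outside the grid are clamped to the nearest edge.  Results are
#' clamped to (0, 1].
#'
#' @param lookup A `crossmix_fdr_lookup`.
#' @param p1 Primary-trait p-values.
#' @param p2 Conditioning-trait p-values.
#' @return Numeric vector of condFDR values.
#' @export
cond_fdr <- function(lookup, p1, p2) {
  x <- -log10(clamp_p(p1))
  y <- -log10(clamp_p(p2))
  gx <- lookup$grid_x
  gy <- lookup$grid_y
  x <- pmin(pmax(x, gx[1]), gx[length(gx)])
  y <- pmin(pmax(y, gy[1]), gy[length(gy)])
  ix <- pmin(findInterval(x, gx), max(length(gx) - 1, 1))
  iy <- pmin(findInterval(y, gy), max(length(gy) - 1, 1))
  wx <- if (length(gx) > 1) (x - gx[ix]) / (gx[ix + 1] - gx[ix]) else 0
  wy <- if (length(gy) > 1) (y - gy[iy]) / (gy[iy + 1] - gy[iy]) else 0
  if (length(gx) == 1) ix <- pmin(ix, 1)
  if (length(gy) == 1) iy <- pmin(iy, 1)
  v <- lookup$values
  ix2 <- pmin(ix + 1, length(gx))
  iy2 <- pmin(iy + 1, length(gy))
  val <- (1 - wx) * (1 - wy) * v[cbind(ix, iy)] +
    wx * (1 - wy) * v[cbind(ix2, iy)] +
    (1 - wx) * wy * v[cbind(ix, iy2)] +
    wx * wy * v[cbind(ix2, iy2)]
  pmin(pmax(val, P_FLOOR), 1)
}

#' Conjunctional FDR
#'
#' The maximum of the two mutual conditional FDR values for each variant:
#' an upper bound on the posterior probability that the variant is
#' associated with neither or only one trait.
#'
#' @param lookup12 Lookup with trait 1 primary.
#' @param lookup21 Lookup with trait 2 primary.
#' @param merged Harmonized pair table (`p1`, `p2`).
#' @return Tibble: `merged` plus `condfdr_1`, `condfdr_2`, `conjfdr`.
#' @export
conj_fdr <- function(lookup12, lookup21, merged) {
  c12 <- cond_fdr(lookup12, merged$p1, merged$p2)
  c21 <- cond_fdr(lookup21, merged$p2, merged$p1)
  mutate(as_tibble(merged), condfdr_1 = c12, condfdr_2 = c21,
         conjfdr = pmax(c12, c21))
}

#' One-call conjFDR table
#'
#' Builds both mutual lookups and returns the per-variant conjFDR table
#' with the significance mask at the single threshold used everywhere.
#'
#' @inheritParams build_fdr_lookup
#' @param significance_threshold conjFDR significance threshold (default
#'   0.05).
#' @return List with `table` (per-variant tibble including `conjfdr` and
#'   `significant`), `lookup12`, `lookup21`.
#' @export
conj_fdr_table <- function(merged, ld = NULL,
                           strata = c(1, 0.1, 0.01, 0.001),
                           n_prune_iter = 20, prune_r2 = 0.1,
                           exclusions = default_exclusion_regions(),
                           seed = 1, significance_threshold = 0.05) {
  l12 <- build_fdr_lookup(merged, ld, primary = 1, strata = strata,
                          n_prune_iter = n_prune_iter,
                          prune_r2 = prune_r2, exclusions = exclusions,
                          seed = substream_seed(seed, "lookup12"))
  l21 <- build_fdr_lookup(merged, ld, primary = 2, strata = strata,
                          n_prune_iter = n_prune_iter,
                          prune_r2 = prune_r2, exclusions = exclusions,
                          seed = substream_seed(seed, "lookup21"))
  tab <- conj_fdr(l12, l21, merged)
  tab$significant <- tab$conjfdr < significance_threshold
  list(table = tab, lookup12 = l12, lookup21 = l21)
}

#' Write / read an FDR lookup as TSV
#'
#' The grid is stored as a plain TSV matrix with `#`-prefixed header
#' metadata so lookups can be exchanged between runs.
#'
#' @param lookup A `crossmix_fdr_lookup`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `crossmix_fdr_lookup` (reader).
#' @export
write_fdr_lookup <- function(lookup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# primary=%d", lookup$primary), con)
  writeLines(sprintf("# n_prune_iter=%d", lookup$n_prune_iter), con)
  writeLines(sprintf("# prune_r2=%g", lookup$prune_r2), con)
  writeLines(sprintf("# strata=%s",
                     paste(lookup$strata, collapse = ",")), con)
  writeLines(sprintf("# grid_y=%s",
                     paste(signif(lookup$grid_y, 10), collapse = ",")), con)
  df <- as.data.frame(lookup$values)
  names(df) <- sprintf("y%d", seq_along(lookup$grid_y))
  df <- cbind(neglog10_p1 = lookup$grid_x, df)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fdr_lookup
#' @export
read_fdr_lookup <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- utils::read.table(textConnection(lines[!grepl("^#", lines)]),
                            header = TRUE, sep = "\t")
  structure(list(
    grid_x = body$neglog10_p1,
    grid_y = as.numeric(strsplit(meta$grid_y, ",")[[1]]),
    values = as.matrix(body[, -1, drop = FALSE]),
    strata = as.numeric(strsplit(meta$strata, ",")[[1]]),
    primary = as.integer(meta$primary),
    n_prune_iter = as.integer(meta$n_prune_iter),
    prune_r2 = as.numeric(meta$prune_r2),
    exclusions = NULL, seed = NA_integer_),
    class = "crossmix_fdr_lookup")
}

#' Manhattan-style conjFDR plot
#'
#' -log10 conjFDR against genomic position, with the significance
#' threshold drawn as a dashed line and lead SNPs (if a loci table is
#' supplied) circled.
#'
#' @param conj_tbl Per-variant conjFDR table (needs `chromosome`,
#'   `position`, `conjfdr`).
#' @param loci Optional loci table from [define_loci()].
#' @param threshold Significance threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_conjfdr_manhattan <- function(conj_tbl, loci = NULL,
                                   threshold = 0.05) {
  df <- mutate(conj_tbl,
               neglog = -log10(clamp_p(.data$conjfdr)),
               odd = factor(.data$chromosome %% 2))
  p <- ggplot(df, aes(x = .data$position, y = .data$neglog,
                      color = .data$odd)) +
    geom_point(size = 0.4, show.legend = FALSE) +
    facet_grid(. ~ chromosome, scales = "free_x", space = "free_x",
               switch = "x") +
    geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    labs(x = "chromosome", y = expression(-log[10] * " conjFDR")) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.spacing.x = unit(0, "pt"))
  if (!is.null(loci)) {
    leads <- semi_join(df, tibble(variant_id = loci$lead_snp),
                       by = "variant_id")
    p <- p + geom_point(data = leads, shape = 1, size = 2,
                        color = "black")
  }
  p
}
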