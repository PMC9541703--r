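# Shared small helpers.

# p-values are clamped to [1e-300, 1] before any log transform so that
# underflowed p cannot produce infinities downstream.
P_FLOOR <- 1e-300

clamp_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from a single master seed; each
#' operation draws from its own named substream so that stages can be rerun
#' independently without disturbing one another.  The substream seed is a
#' deterministic hash of the master seed and the stream name, kept within
#' the 32-bit integer range R requires.
#'
#' @param seed Master integer seed.
#' @param name Character stream name, e.g. `"labels"` or `"noise1"`.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1, "labels")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483629
  s <- (abs(seed) %% m)
  as.integer(((s * 69069) %% m + h) %% m)
}

two_sided_p <- function(z) clamp_p(2 * pnorm(-abs(z)))

# 1-based inclusive interval overlap: the single rule used everywhere.
intervals_overlap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) <= pmin(end1, end2)
}

# Minimal union-find used for locus grouping and transdiagnostic merging.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}
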