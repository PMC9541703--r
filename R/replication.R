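# Discovery-replication sign concordance, positional gene mapping, and
# hypergeometric gene-set enrichment.

#' En-masse sign concordance test
#'
#' Compares the effect direction of discovery lead SNPs in an independent
#' replication sample: k = number of leads with matching z sign, tested
#' against chance with the one-sided exact binomial tail
#' `P(X >= k | n, 1/2)`.  Leads missing from the replication table (or
#' with zero z in either sample) are dropped and counted.
#'
#' @param leads Tibble with `variant_id` and discovery `z`.
#' @param replication Variant table with `variant_id`, `z`.
#' @return Tibble of class `crossmix_concordance`: `n_leads`, `n_tested`,
#'   `n_concordant`, `n_missing`, `n_zero`, `p_value` (NA when nothing is
#'   testable).
#' @export
sign_concordance_test <- function(leads, replication) {
  m <- left_join(select(leads, "variant_id", z_disc = "z"),
                 select(replication, "variant_id", z_rep = "z"),
                 by = "variant_id")
  missing <- is.na(m$z_rep)
  zero <- !missing & (m$z_disc == 0 | m$z_rep == 0)
  tested <- !missing & !zero
  k <- sum(sign(m$z_disc[tested]) == sign(m$z_rep[tested]))
  n <- sum(tested)
  p <- if (n == 0) NA_real_ else pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  out <- tibble(n_leads = nrow(m), n_tested = n, n_concordant = k,
                n_missing = sum(missing), n_zero = sum(zero),
                p_value = p)
  class(out) <- c("crossmix_concordance", class(out))
  out
}

#' One-sided exact binomial tail probability
#'
#' `P(X >= k)` for X ~ Binomial(n, 1/2); the reference test behind
#' [sign_concordance_test()], exposed for direct use on printed counts.
#'
#' @param k Successes.
#' @param n Trials.
#' @return Tail probability.
#' @export
binomial_sign_p <- function(k, n) {
  stopifnot(k >= 0, k <= n)
  pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Positional gene mapping
#'
#' A gene maps to a locus when its span, extended by the window on both
#' sides, covers the position of any candidate SNP of the locus.
#'
#' @param loci Loci table from [define_loci()].
#' @param genes Gene table (`symbol`, `chromosome`, `start`, `end`).
#' @param snp_positions Tibble `variant_id`, `chromosome`, `position` for
#'   candidate SNP lookup.
#' @param window Extension in base pairs (default 10 kb, the FUMA
#'   positional-mapping default).
#' @return Tibble `locus_id`, `symbol`, one row per mapped gene-locus
#'   pair.
#' @export
map_genes_positional <- function(loci, genes, snp_positions,
                                 window = 10000) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    cands <- loci$candidate_snps[[i]]
    sp <- snp_positions[match(cands, snp_positions$variant_id), ]
    sp <- sp[!is.na(sp$position), ]
    if (nrow(sp) == 0) return(NULL)
    hit <- vapply(seq_len(nrow(genes)), function(g) {
      genes$chromosome[g] == loci$chromosome[i] &&
        any(sp$position >= genes$start[g] - window &
              sp$position <= genes$end[g] + window &
              sp$chromosome == genes$chromosome[g])
    }, logical(1))
    if (!any(hit)) return(NULL)
    tibble(locus_id = loci$locus_id[i], symbol = genes$symbol[hit])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(locus_id = integer(0), symbol = character(0))
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, the upper tail `P(overlap >= observed)` under
#' Hypergeometric(N = |background|, K = |set|, n = |list|), with sets
#' intersected with the background first and Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param gene_list Character vector of genes (must be a subset of
#'   `background`).
#' @param gene_sets Long tibble from [read_gmt()] (`set_name`, `gene`).
#' @param background Character vector: the gene universe.
#' @return Tibble `set_name`, `n_overlap`, `set_size`, `list_size`,
#'   `background_size`, `p_value`, `p_adjusted`, ordered by p.
#' @export
hypergeometric_enrichment <- function(gene_list, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) abort("background gene universe is empty")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background)) {
    abort("gene_list must be a subset of background")
  }
  N <- length(background)
  n <- length(gene_list)
  sets <- split(gene_sets$gene, gene_sets$set_name)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    K <- length(set)
    q <- length(intersect(set, gene_list))
    p <- phyper(q - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, n_overlap = q, set_size = K, list_size = n,
           background_size = N, p_value = p)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value, .data$set_name)
}
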