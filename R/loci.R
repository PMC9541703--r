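# FUMA-protocol locus definition on conjFDR results.
#
# Significant variants (conjFDR < 0.05) are clumped greedily by ascending
# conjFDR: a significant variant not in r^2 >= 0.6 with an already-chosen
# one becomes an independent significant SNP; among those, lead SNPs are
# chosen greedily at mutual r^2 < 0.1; independent significant SNPs within
# the merge distance (default 250 kb) or in r^2 >= 0.1 collapse into one
# locus.  Candidate SNPs are any variants at conjFDR < 0.10 in r^2 >= 0.6
# with an independent significant SNP; locus bounds are the min-max
# positions of its candidates.  Ties in the greedy order break by position
# then variant id, making the procedure deterministic.

clump_order <- function(tbl) {
  arrange(tbl, .data$conjfdr, .data$position, .data$variant_id)
}

# an LD structure with no pairs: every variant independent
ld_empty <- function(ids) {
  ld_from_pairs(tibble(variant_i = character(0),
                       variant_j = character(0), r = numeric(0)),
                ids = ids)
}

#' Candidate SNP selection
#'
#' All variants with conjFDR below the candidate threshold and r^2 at or
#' above 0.6 with at least one independent significant SNP; each
#' independent significant SNP is its own candidate (self r^2 = 1).
#'
#' @param conj_tbl Per-variant conjFDR table (`variant_id`, `conjfdr`).
#' @param ld `crossmix_ld`.
#' @param significant_ids Independent significant SNP ids.
#' @param cand_threshold Candidate conjFDR threshold (default 0.10).
#' @param r2_candidate LD threshold linking candidates (default 0.6).
#' @return Tibble `variant_id`, `linked_to` (independent significant SNP
#'   with the strongest r^2), `r2`.
#' @export
find_candidate_snps <- function(conj_tbl, ld, significant_ids,
                                cand_threshold = 0.10,
                                r2_candidate = 0.6) {
  if (length(significant_ids) == 0) {
    return(tibble(variant_id = character(0), linked_to = character(0),
                  r2 = numeric(0)))
  }
  if (is.null(ld)) ld <- ld_empty(conj_tbl$variant_id)
  nb <- ld_neighbors(ld, significant_ids, min_r = sqrt(r2_candidate))
  nb <- dplyr::filter(nb, .data$r^2 >= r2_candidate)
  nb <- left_join(nb, select(conj_tbl, "variant_id", "conjfdr"),
                  by = c(neighbor = "variant_id"))
  nb <- dplyr::filter(nb, !is.na(.data$conjfdr),
                      .data$conjfdr < cand_threshold)
  out <- nb |>
    mutate(r2 = .data$r^2) |>
    group_by(.data$neighbor) |>
    arrange(desc(.data$r2), .data$variant_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  tibble(variant_id = out$neighbor, linked_to = out$variant_id,
         r2 = out$r2)
}

#' Define independent genomic loci from conjFDR results
#'
#' @param conj_tbl Per-variant table with `variant_id`, `chromosome`,
#'   `position`, `conjfdr`, and optionally `z1`, `z2`.
#' @param ld `crossmix_ld`.
#' @param sig_threshold conjFDR significance threshold (default 0.05).
#' @param cand_threshold Candidate threshold (default 0.10).
#' @param r2_independent r^2 below which significant SNPs are independent
#'   (default 0.6).
#' @param r2_lead r^2 below which independent SNPs are in approximate
#'   linkage equilibrium, defining leads (default 0.1).
#' @param merge_kb Distance (kb) within which independent significant
#'   SNPs are merged into one locus (default 250).
#' @return Tibble of class `crossmix_loci`, one row per locus: `locus_id`,
#'   `chromosome`, `start`, `end`, `lead_snp`, `lead_conjfdr`, `lead_z1`,
#'   `lead_z2`, `concordant`, `n_independent`, `n_candidates`, plus
#'   list-columns `independent_snps`, `candidate_snps`.  Empty when no
#'   variant is significant.
#' @export
define_loci <- function(conj_tbl, ld, sig_threshold = 0.05,
                        cand_threshold = 0.10, r2_independent = 0.6,
                        r2_lead = 0.1, merge_kb = 250) {
  empty <- tibble(locus_id = integer(0), chromosome = integer(0),
                  start = numeric(0), end = numeric(0),
                  lead_snp = character(0), lead_conjfdr = numeric(0),
                  lead_z1 = numeric(0), lead_z2 = numeric(0),
                  concordant = logical(0), n_independent = integer(0),
                  n_candidates = integer(0),
                  independent_snps = list(), candidate_snps = list())
  class(empty) <- c("crossmix_loci", class(empty))
  if (is.null(ld)) ld <- ld_empty(conj_tbl$variant_id)
  sig <- clump_order(dplyr::filter(conj_tbl,
                                   .data$conjfdr < sig_threshold))
  if (nrow(sig) == 0) return(empty)

  # greedy selection in clump order against a fixed adjacency: a variant
  # is selected iff no already-selected variant is in LD with it
  greedy_select <- function(ids_ordered, r2_threshold) {
    adj <- ld_adjacency(ld, ids_ordered, r2_threshold, strict = FALSE)
    ord <- match(ids_ordered, adj$ids) - 1L
    keep <- cpp_greedy_keep(ord, adj$ptr, adj$idx)
    # keep is in adj$ids order; report in visiting order
    ids_ordered[ids_ordered %in% adj$ids[keep]]
  }
  indep <- greedy_select(sig$variant_id, r2_independent)
  leads <- greedy_select(indep, r2_lead)

  info <- select(conj_tbl, "variant_id", "chromosome", "position",
                 "conjfdr", dplyr::any_of(c("z1", "z2")))
  ind_tbl <- clump_order(semi_join(info, tibble(variant_id = indep),
                                   by = "variant_id"))

  # group independent SNPs into loci: same chromosome and within
  # merge_kb, or r^2 >= r2_lead
  n_ind <- nrow(ind_tbl)
  parent <- uf_new(n_ind)
  adj_lead <- ld_adjacency(ld, ind_tbl$variant_id, r2_lead,
                           strict = FALSE)
  lpos <- match(adj_lead$ids, ind_tbl$variant_id)
  for (v in seq_along(adj_lead$ids)) {
    for (e in seq(adj_lead$ptr[v] + 1, length.out =
                    adj_lead$ptr[v + 1] - adj_lead$ptr[v])) {
      parent <- uf_union(parent, lpos[v], lpos[adj_lead$idx[e] + 1L])
    }
  }
  po <- order(ind_tbl$chromosome, ind_tbl$position)
  for (k in seq_len(max(n_ind - 1, 0))) {
    i <- po[k]
    j <- po[k + 1]
    if (ind_tbl$chromosome[i] == ind_tbl$chromosome[j] &&
        abs(ind_tbl$position[i] - ind_tbl$position[j]) <=
          merge_kb * 1000) {
      parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)

  cand <- find_candidate_snps(conj_tbl, ld, ind_tbl$variant_id,
                              cand_threshold, r2_independent)
  cand$locus_comp <- comp[match(cand$linked_to, ind_tbl$variant_id)]
  cand <- left_join(cand, select(info, "variant_id", "position",
                                 cand_conjfdr = "conjfdr"),
                    by = "variant_id")

  rows <- lapply(sort(unique(comp)), function(cc) {
    members <- ind_tbl[comp == cc, ]
    cands <- cand[cand$locus_comp == cc, ]
    lead_candidates <- members$variant_id[members$variant_id %in% leads]
    lead <- if (length(lead_candidates) > 0) lead_candidates[1] else
      members$variant_id[1]
    lrow <- members[members$variant_id == lead, ]
    tibble(chromosome = members$chromosome[1],
           start = min(cands$position), end = max(cands$position),
           lead_snp = lead, lead_conjfdr = lrow$conjfdr,
           lead_z1 = if ("z1" %in% names(lrow)) lrow$z1 else NA_real_,
           lead_z2 = if ("z2" %in% names(lrow)) lrow$z2 else NA_real_,
           n_independent = nrow(members), n_candidates = nrow(cands),
           independent_snps = list(members$variant_id),
           candidate_snps = list(sort(cands$variant_id)))
  })
  out <- bind_rows(rows) |>
    arrange(.data$chromosome, .data$start) |>
    mutate(locus_id = row_number(),
           concordant = sign(.data$lead_z1) * sign(.data$lead_z2) > 0) |>
    select("locus_id", "chromosome", "start", "end", "lead_snp",
           "lead_conjfdr", "lead_z1", "lead_z2", "concordant",
           "n_independent", "n_candidates", "independent_snps",
           "candidate_snps")
  class(out) <- c("crossmix_loci", class(out))
  out
}

#' Effect-direction concordance of lead SNPs
#'
#' A locus is concordant when its lead SNP has same-signed z in both
#' traits; leads with z = 0 in either trait have undefined sign and are
#' excluded from the denominator.
#'
#' @param loci Loci table from [define_loci()] (needs `lead_z1`,
#'   `lead_z2`).
#' @return List with `per_locus` (loci plus `concordant` flag) and
#'   `summary` (tibble: `n_tested`, `n_concordant`, `n_excluded`,
#'   `percent` at one decimal).
#' @export
directional_concordance <- function(loci) {
  s <- sign(loci$lead_z1) * sign(loci$lead_z2)
  excluded <- s == 0 | is.na(s)
  conc <- s > 0 & !excluded
  n <- sum(!excluded)
  k <- sum(conc)
  list(per_locus = mutate(loci, concordant = ifelse(excluded, NA, s > 0)),
       summary = tibble(n_tested = n, n_concordant = k,
                        n_excluded = sum(excluded),
                        percent = round(100 * k / n, 1)))
}

#' Flag loci as novel against known-locus interval lists
#'
#' A locus is novel for a trait when its interval overlaps no known
#' interval for that trait (1-based inclusive overlap: intervals overlap
#' iff max(start) <= min(end)).
#'
#' @param loci Loci table.
#' @param known Named list of interval tibbles (`chromosome`, `start`,
#'   `end`), one per trait; a column `novel_<name>` is added per entry.
#' @return The loci table with novelty flags.
#' @export
annotate_novelty <- function(loci, known) {
  for (nm in names(known)) {
    kn <- known[[nm]]
    flag <- vapply(seq_len(nrow(loci)), function(i) {
      if (is.null(kn) || nrow(kn) == 0) return(TRUE)
      hit <- kn$chromosome == loci$chromosome[i] &
        intervals_overlap(loci$start[i], loci$end[i], kn$start, kn$end)
      !any(hit)
    }, logical(1))
    loci[[paste0("novel_", nm)]] <- flag
  }
  loci
}

#' Merge loci across analyses into transdiagnostic loci
#'
#' Loci from different trait-pair analyses are linked when they
#' physically overlap (candidate-SNP min-max bounds, 1-based inclusive)
#' and share at least one candidate SNP with conjFDR at or below the
#' significance threshold in both paired analyses; link groups are closed
#' transitively.  The transdiagnostic lead SNP minimizes, over the
#' group's candidate SNPs, the maximum conjFDR across contributing
#' analyses (ties: smaller position, then id).
#'
#' @param analyses Named list; each element is a list with `loci` (a
#'   `crossmix_loci`) and `conjfdr` (the analysis's per-variant table with
#'   `variant_id`, `position`, `conjfdr`, and optionally `z1`, `z2`).
#' @param sig_threshold Shared-candidate significance threshold (default
#'   0.05).
#' @return Tibble of class `crossmix_transdiag`: one row per merged
#'   locus with `chromosome`, `start`, `end`, `n_analyses`, `analyses`
#'   (list), `lead_snp`, `lead_position`, per-analysis conjFDR at the
#'   lead (list-column `lead_conjfdr`), and per-analysis concordance
#'   flags (list-column `concordant`).
#' @export
merge_transdiagnostic <- function(analyses, sig_threshold = 0.05) {
  stopifnot(length(analyses) >= 2, !is.null(names(analyses)))
  analyses <- analyses[sort(names(analyses))]
  all_loci <- bind_rows(lapply(names(analyses), function(nm) {
    mutate(analyses[[nm]]$loci, analysis = nm)
  }))
  empty <- tibble(chromosome = integer(0), start = numeric(0),
                  end = numeric(0), n_analyses = integer(0),
                  analyses = list(), lead_snp = character(0),
                  lead_position = numeric(0), lead_conjfdr = list(),
                  concordant = list())
  class(empty) <- c("crossmix_transdiag", class(empty))
  if (nrow(all_loci) == 0) return(empty)

  conj_of <- function(nm, ids) {
    tab <- analyses[[nm]]$conjfdr
    tab$conjfdr[match(ids, tab$variant_id)]
  }

  n <- nrow(all_loci)
  parent <- uf_new(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (all_loci$analysis[i] == all_loci$analysis[j]) next
      if (all_loci$chromosome[i] != all_loci$chromosome[j]) next
      if (!intervals_overlap(all_loci$start[i], all_loci$end[i],
                             all_loci$start[j], all_loci$end[j])) next
      shared <- intersect(all_loci$candidate_snps[[i]],
                          all_loci$candidate_snps[[j]])
      if (length(shared) == 0) next
      ci <- conj_of(all_loci$analysis[i], shared)
      cj <- conj_of(all_loci$analysis[j], shared)
      if (any(!is.na(ci) & !is.na(cj) & ci <= sig_threshold &
                cj <= sig_threshold)) {
        parent <- uf_union(parent, i, j)
      }
    }
  }
  comp <- uf_components(parent)

  rows <- lapply(sort(unique(comp)), function(cc) {
    members <- all_loci[comp == cc, ]
    contributing <- sort(unique(members$analysis))
    if (length(contributing) < 2) return(NULL)
    cand_union <- sort(unique(unlist(members$candidate_snps)))
    maxc <- rep(-Inf, length(cand_union))
    for (nm in contributing) {
      maxc <- pmax(maxc, conj_of(nm, cand_union))
    }
    pos <- analyses[[contributing[1]]]$conjfdr$position[
      match(cand_union, analyses[[contributing[1]]]$conjfdr$variant_id)]
    ok <- is.finite(maxc)
    cand_union <- cand_union[ok]
    maxc <- maxc[ok]
    pos <- pos[ok]
    o <- order(maxc, pos, cand_union)
    lead <- cand_union[o[1]]
    lead_pos <- pos[o[1]]
    per_fdr <- vapply(contributing, function(nm) conj_of(nm, lead),
                      numeric(1))
    per_conc <- vapply(contributing, function(nm) {
      tab <- analyses[[nm]]$conjfdr
      row <- tab[match(lead, tab$variant_id), ]
      if (all(c("z1", "z2") %in% names(row))) {
        sign(row$z1) * sign(row$z2) > 0
      } else NA
    }, logical(1))
    tibble(chromosome = members$chromosome[1],
           start = min(members$start), end = max(members$end),
           n_analyses = length(contributing),
           analyses = list(contributing), lead_snp = lead,
           lead_position = lead_pos,
           lead_conjfdr = list(setNames(per_fdr, contributing)),
           concordant = list(setNames(per_conc, contributing)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- arrange(bind_rows(rows), .data$chromosome, .data$start)
  class(out) <- c("crossmix_transdiag", class(out))
  out
}

#' Write loci as TSV and BED
#'
#' @param loci Loci table from [define_loci()].
#' @param path Output TSV path; a BED file (0-based half-open) with the
#'   same stem is written alongside when `bed = TRUE`.
#' @param analysis Label recorded in the `analysis` column.
#' @param bed Also write BED intervals (default TRUE).
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path, analysis = "analysis", bed = TRUE) {
  flat <- loci |>
    mutate(analysis = analysis,
           independent_snps = vapply(.data$independent_snps, paste,
                                     character(1), collapse = ","),
           candidate_snps = vapply(.data$candidate_snps, paste,
                                   character(1), collapse = ","))
  readr::write_tsv(as_tibble(flat), path, progress = FALSE)
  if (bed && nrow(loci) > 0) {
    bed_path <- sub("\\.tsv$", ".bed", path)
    bed_df <- tibble(chrom = paste0("chr", loci$chromosome),
                     start = as.integer(loci$start - 1),
                     end = as.integer(loci$end),
                     name = loci$lead_snp)
    readr::write_tsv(bed_df, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
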