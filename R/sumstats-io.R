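# Reading, validating, harmonizing and writing GWAS summary statistics and
# the auxiliary tabular formats the pipeline touches (LD tables, interval
# lists, GMT gene sets).
#
# Canonical per-variant columns: variant_id, chromosome, position,
# allele_effect, allele_other, z, p, n.  Coordinates are 1-based inclusive
# throughout; BED input (0-based half-open) is converted on read.

default_dialect <- function() {
  list(
    variant_id = c("variant_id", "snp", "rsid", "markername", "id"),
    chromosome = c("chromosome", "chr", "chrom"),
    position = c("position", "bp", "pos", "base_pair_location"),
    allele_effect = c("allele_effect", "a1", "effect_allele", "alt"),
    allele_other = c("allele_other", "a2", "other_allele", "ref"),
    z = c("z", "zscore", "z_score", "stat"),
    p = c("p", "pval", "p_value", "pvalue"),
    n = c("n", "neff", "n_total", "samplesize"),
    beta = c("beta", "b", "effect"),
    se = c("se", "stderr", "standard_error")
  )
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

resolve_columns <- function(header, dialect) {
  base <- default_dialect()
  if (!is.null(dialect)) {
    for (nm in names(dialect)) base[[nm]] <- c(dialect[[nm]], base[[nm]])
  }
  lower <- tolower(header)
  out <- list()
  for (nm in names(base)) {
    hit <- which(lower %in% tolower(base[[nm]]))
    if (length(hit) > 0) out[[nm]] <- header[hit[1]]
  }
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header, resolving column names
#' case-insensitively through a dialect mapping.  If only beta/SE are
#' present, z = beta/SE is computed; if p is absent it is derived from z
#' (two-sided).  Rows whose numeric fields fail to parse are dropped and
#' counted in the load report (`attr(x, "load_report")`).
#'
#' @param path Path to a tab-delimited file with header.
#' @param dialect Optional named list mapping canonical column names
#'   (`variant_id`, `chromosome`, `position`, `allele_effect`,
#'   `allele_other`, `z`, `p`, `n`, `beta`, `se`) to file column names.
#' @return A validated tibble (`variant_id`, `chromosome`, `position`,
#'   `allele_effect`, `allele_other`, `z`, `p`, `n`) with a `load_report`
#'   attribute.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cols <- resolve_columns(names(raw), dialect)
  required <- c("variant_id", "chromosome", "position", "allele_effect",
                "allele_other")
  missing <- setdiff(required, names(cols))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "crossmix_format_error")
  }
  has_signed <- "z" %in% names(cols) ||
    all(c("beta", "se") %in% names(cols))
  if (!has_signed) {
    abort("missing required column(s): z (or beta and se)",
          class = "crossmix_format_error")
  }

  tbl <- tibble(
    variant_id = raw[[cols$variant_id]],
    chromosome = suppressWarnings(as.integer(gsub("^chr", "",
                                                  raw[[cols$chromosome]]))),
    position = suppressWarnings(as.numeric(raw[[cols$position]])),
    allele_effect = toupper(raw[[cols$allele_effect]]),
    allele_other = toupper(raw[[cols$allele_other]])
  )
  num <- function(nm) {
    if (is.null(cols[[nm]])) rep(NA_real_, nrow(raw))
    else suppressWarnings(as.numeric(raw[[cols[[nm]]]]))
  }
  z <- num("z")
  p <- num("p")
  nn <- num("n")
  beta <- num("beta")
  se <- num("se")
  if (is.null(cols[["z"]])) z <- beta / se
  if (is.null(cols[["p"]])) p <- two_sided_p(z)
  tbl$z <- unname(z)
  tbl$p <- unname(clamp_p(p))
  tbl$n <- nn

  ok <- !is.na(tbl$variant_id) & !is.na(tbl$chromosome) &
    !is.na(tbl$position) & tbl$position > 0 &
    !is.na(tbl$z) & !is.na(tbl$p) &
    tbl$allele_effect %in% names(COMPLEMENT) &
    tbl$allele_other %in% names(COMPLEMENT)
  n_dropped <- sum(!ok)
  tbl <- tbl[ok, ]

  dup <- duplicated(tbl$variant_id)
  if (any(dup)) {
    abort(sprintf("duplicate variant_id: %s",
                  paste(head(unique(tbl$variant_id[dup]), 5), collapse = ", ")),
          class = "crossmix_format_error")
  }
  attr(tbl, "load_report") <- list(n_read = nrow(raw), n_kept = nrow(tbl),
                                   n_dropped = n_dropped)
  tbl
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Columns are written as SNP, CHR, BP, A1, A2, Z, P, N (tab-delimited);
#' [read_sumstats()] on the result reproduces the table field for field.
#'
#' @param tbl A variant table as returned by [read_sumstats()] or the
#'   simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tbl, path) {
  out <- tibble(SNP = tbl$variant_id, CHR = tbl$chromosome,
                BP = tbl$position, A1 = tbl$allele_effect,
                A2 = tbl$allele_other, Z = tbl$z, P = tbl$p, N = tbl$n)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Harmonize two summary-statistics tables onto shared effect alleles
#'
#' Intersects on `variant_id` and reconciles alleles: where the second
#' table's alleles are swapped relative to the first, z2 changes sign and
#' `allele_flipped` is set; where they are the strand complement the
#' alleles are complemented first; strand-ambiguous variants (A/T, C/G)
#' are dropped (default) or kept per policy.  Irreconcilable records are
#' dropped and counted, not fatal.
#'
#' @param t1,t2 Validated variant tables.
#' @param ambiguous_policy `"drop"` (default) or `"keep"`.
#' @return A merged tibble with columns `variant_id`, `chromosome`,
#'   `position`, `allele_effect`, `allele_other`, `z1`, `p1`, `n1`, `z2`,
#'   `p2`, `n2`, `allele_flipped`, and a `harmonize_report` attribute.
#' @export
harmonize_pair <- function(t1, t2, ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  m <- inner_join(
    select(t1, "variant_id", "chromosome", "position",
           "allele_effect", "allele_other", z1 = "z", p1 = "p", n1 = "n"),
    select(t2, "variant_id", b1 = "allele_effect", b2 = "allele_other",
           z2 = "z", p2 = "p", n2 = "n"),
    by = "variant_id")

  ambiguous <- unname(m$allele_effect == COMPLEMENT[m$allele_other])
  n_ambiguous <- sum(ambiguous)
  if (ambiguous_policy == "drop") m <- m[!ambiguous, ]

  same <- m$b1 == m$allele_effect & m$b2 == m$allele_other
  swap <- m$b1 == m$allele_other & m$b2 == m$allele_effect
  comp <- unname(COMPLEMENT[m$b1] == m$allele_effect &
    COMPLEMENT[m$b2] == m$allele_other)
  comp_swap <- unname(COMPLEMENT[m$b1] == m$allele_other &
    COMPLEMENT[m$b2] == m$allele_effect)
  flip <- (swap | comp_swap) & !same
  ok <- same | swap | comp | comp_swap
  n_irreconcilable <- sum(!ok)

  m <- m[ok, ]
  flip <- flip[ok]
  m$z2 <- ifelse(flip, -m$z2, m$z2)
  m$allele_flipped <- flip
  m <- select(m, -"b1", -"b2")
  attr(m, "harmonize_report") <- list(
    n_shared = nrow(m) + n_irreconcilable +
      if (ambiguous_policy == "drop") n_ambiguous else 0L,
    n_ambiguous_dropped = if (ambiguous_policy == "drop") n_ambiguous else 0L,
    n_irreconcilable = n_irreconcilable,
    n_flipped = sum(flip))
  m
}

#' Read a pairwise LD table
#'
#' Accepts either a generic three-column table (`variant_i`, `variant_j`,
#' `r` -- the first three columns are used whatever their names) or the
#' PLINK `.ld` dialect (`SNP_A`, `SNP_B`, and `R` or `R2`).  When only R2
#' is available, |r| is stored and the structure is flagged
#' `sign_unknown`.
#'
#' @param path Path to a whitespace- or tab-delimited file with header.
#' @return A `crossmix_ld` object (sparse representation).
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  lower <- tolower(names(raw))
  sign_unknown <- FALSE
  if (all(c("snp_a", "snp_b") %in% lower)) {
    i <- raw[[which(lower == "snp_a")[1]]]
    j <- raw[[which(lower == "snp_b")[1]]]
    if ("r" %in% lower) {
      r <- suppressWarnings(as.numeric(raw[[which(lower == "r")[1]]]))
    } else if ("r2" %in% lower) {
      r2 <- suppressWarnings(as.numeric(raw[[which(lower == "r2")[1]]]))
      r <- sqrt(r2)
      sign_unknown <- TRUE
    } else {
      abort("PLINK .ld file lacks both R and R2 columns",
            class = "crossmix_format_error")
    }
  } else {
    if (ncol(raw) < 3) {
      abort("LD table needs at least three columns (id_i, id_j, r)",
            class = "crossmix_format_error")
    }
    i <- raw[[1]]
    j <- raw[[2]]
    r <- suppressWarnings(as.numeric(raw[[3]]))
  }
  bad <- which(!is.na(r) & abs(r) > 1)
  if (length(bad) > 0) {
    abort(sprintf("|r| > 1 at line %d of %s", bad[1] + 1L, path),
          class = "crossmix_format_error")
  }
  ld <- ld_from_pairs(tibble(variant_i = i, variant_j = j, r = r))
  ld$sign_unknown <- sign_unknown
  ld
}

#' Read an interval list
#'
#' BED files (0-based, half-open) are converted to the package's 1-based
#' inclusive convention on read; files with header columns
#' chromosome/start/end are taken as already 1-based inclusive.
#'
#' @param path Path to a BED or TSV interval file.
#' @param format `"bed"` (default for `.bed` paths) or `"tsv"`.
#' @return Tibble with `chromosome`, `start`, `end` (1-based inclusive).
#' @export
read_intervals <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||% (if (grepl("\\.bed$", path, ignore.case = TRUE))
    "bed" else "tsv")
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    tibble(chromosome = as.integer(gsub("^chr", "", raw[[1]])),
           start = as.numeric(raw[[2]]) + 1,
           end = as.numeric(raw[[3]]))
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    lower <- tolower(names(raw))
    tibble(chromosome = as.integer(gsub("^chr", "",
                                        raw[[match("chromosome", lower)]])),
           start = as.numeric(raw[[match("start", lower)]]),
           end = as.numeric(raw[[match("end", lower)]]))
  }
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set name, description, tab-separated
#'   gene symbols).
#' @return Long tibble with columns `set_name`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort("GMT line with fewer than 3 fields", class = "crossmix_format_error")
    }
    tibble(set_name = f[1], description = f[2], gene = f[-(1:2)])
  })
  bind_rows(rows)
}
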