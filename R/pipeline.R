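# End-to-end orchestration: simulate (or read) -> harmonize -> causal
# mixture -> conjFDR -> loci -> transdiagnostic merge -> replication ->
# enrichment, with every stage output written as TSV and a JSON manifest
# recording the seed, parameters and per-stage record counts.  Identical
# configurations produce byte-identical TSV outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param analyses Named list of analyses (trait pairs).  Each element is
#'   either `list(simulate = sim_config(...))` or
#'   `list(trait1 = path, trait2 = path, ld = path)` with optional
#'   `dialect1`/`dialect2` column mappings.
#' @param mixture `NULL` to skip the causal-mixture stage, otherwise a
#'   list of [fit_univariate()]/[fit_bivariate()] settings
#'   (`n_iter`, `n_subsample`, `prune_r2`, `n_starts`).
#' @param fdr List of conjFDR settings (`strata`, `n_prune_iter`,
#'   `prune_r2`, `use_exclusions`).
#' @param loci List of locus settings (`sig_threshold`, `cand_threshold`,
#'   `r2_independent`, `r2_lead`, `merge_kb`).
#' @param replication `NULL`, or a list with `trait` (1 or 2) and either
#'   `path` (summary statistics file) or `n_rep` (simulate a replication
#'   draw; requires a simulated analysis).
#' @param known Named list of interval tables or file paths for novelty
#'   annotation.
#' @param genes,gene_sets,gene_list Optional gene table (tibble or TSV
#'   path), GMT path/long tibble, and credible gene list for enrichment.
#' @param seed Master seed recorded in the manifest.
#' @return Validated list of class `crossmix_pipeline_config`.
#' @export
pipeline_config <- function(analyses, mixture = NULL,
                            fdr = list(), loci = list(),
                            replication = NULL, known = NULL,
                            genes = NULL, gene_sets = NULL,
                            gene_list = NULL, seed = 1) {
  stopifnot(is.list(analyses), length(analyses) >= 1,
            !is.null(names(analyses)), all(nzchar(names(analyses))))
  for (nm in names(analyses)) {
    a <- analyses[[nm]]
    has_sim <- !is.null(a$simulate)
    has_files <- !is.null(a$trait1) && !is.null(a$trait2)
    if (!has_sim && !has_files) {
      abort(sprintf(
        "analysis '%s' needs either a simulate block or trait1/trait2 paths",
        nm))
    }
    if (has_files) {
      for (f in c(a$trait1, a$trait2, a$ld)) {
        if (!is.null(f) && !file.exists(f)) {
          abort(sprintf("input file not found: %s", f))
        }
      }
    }
  }
  fdr <- utils::modifyList(
    list(strata = c(1, 0.1, 0.01, 0.001), n_prune_iter = 20,
         prune_r2 = 0.1, use_exclusions = TRUE,
         significance_threshold = 0.05), fdr)
  loci <- utils::modifyList(
    list(sig_threshold = 0.05, cand_threshold = 0.10,
         r2_independent = 0.6, r2_lead = 0.1, merge_kb = 250), loci)
  if (!is.null(mixture)) {
    mixture <- utils::modifyList(
      list(n_iter = 20, n_subsample = 20000, prune_r2 = 0.8,
           n_starts = 5, grid_n_uni = 2048, grid_n_biv = 128), mixture)
  }
  structure(list(analyses = analyses, mixture = mixture, fdr = fdr,
                 loci = loci, replication = replication, known = known,
                 genes = genes, gene_sets = gene_sets,
                 gene_list = gene_list, seed = as.integer(seed)),
            class = "crossmix_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' A structured key-value file mirroring [pipeline_config()]'s arguments;
#' a `simulate:` block inside an analysis is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `crossmix_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  analyses <- lapply(raw$analyses, function(a) {
    if (!is.null(a$simulate)) a$simulate <- do.call(sim_config, a$simulate)
    a
  })
  pipeline_config(analyses = analyses, mixture = raw$mixture,
                  fdr = raw$fdr %||% list(), loci = raw$loci %||% list(),
                  replication = raw$replication, known = raw$known,
                  genes = raw$genes, gene_sets = raw$gene_sets,
                  gene_list = unlist(raw$gene_list),
                  seed = raw$seed %||% 1)
}

load_analysis_inputs <- function(a, seed) {
  if (!is.null(a$simulate)) {
    study <- simulate_study(a$simulate)
    list(trait1 = study$trait1, trait2 = study$trait2, ld = study$ld,
         truth = study$truth, deltas = study$deltas,
         sim = a$simulate)
  } else {
    t1 <- read_sumstats(a$trait1, dialect = a$dialect1)
    t2 <- read_sumstats(a$trait2, dialect = a$dialect2)
    ld <- if (!is.null(a$ld)) read_ld_table(a$ld) else NULL
    list(trait1 = t1, trait2 = t2, ld = ld, truth = NULL, deltas = NULL,
         sim = NULL)
  }
}

#' Run the full cross-trait pipeline
#'
#' Executes every configured stage for each analysis, writes stage
#' outputs under `out_dir` and a `manifest.json` recording the seed, a
#' configuration hash, per-stage record counts and completed stages.
#'
#' @param config A `crossmix_pipeline_config`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `manifest` and per-analysis result
#'   objects (`merged`, `fits`, `conjfdr`, `loci`, `concordance`,
#'   `replication`, `enrichment`, `transdiagnostic`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "crossmix_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   stages = character(0), counts = list())
  results <- list()
  trans_inputs <- list()

  for (nm in names(config$analyses)) {
    inp <- load_analysis_inputs(config$analyses[[nm]], config$seed)
    merged <- harmonize_pair(inp$trait1, inp$trait2)
    rep_h <- attr(merged, "harmonize_report")
    manifest$counts[[nm]] <- list(
      n_trait1 = nrow(inp$trait1), n_trait2 = nrow(inp$trait2),
      n_harmonized = nrow(merged),
      n_ambiguous_dropped = rep_h$n_ambiguous_dropped,
      n_irreconcilable = rep_h$n_irreconcilable)
    readr::write_tsv(merged, file.path(out_dir,
                                       sprintf("%s_merged.tsv", nm)),
                     progress = FALSE)

    fits <- NULL
    if (!is.null(config$mixture)) {
      mx <- config$mixture
      M <- nrow(merged)
      f1 <- fit_univariate(
        select(merged, "variant_id", z = "z1", n = "n1"),
        inp$ld, M = M, n_iter = mx$n_iter, n_subsample = mx$n_subsample,
        prune_r2 = mx$prune_r2, n_starts = mx$n_starts,
        seed = substream_seed(config$seed, paste0(nm, "_uni1")),
        grid_n = mx$grid_n_uni)
      f2 <- fit_univariate(
        select(merged, "variant_id", z = "z2", n = "n2"),
        inp$ld, M = M, n_iter = mx$n_iter, n_subsample = mx$n_subsample,
        prune_r2 = mx$prune_r2, n_starts = mx$n_starts,
        seed = substream_seed(config$seed, paste0(nm, "_uni2")),
        grid_n = mx$grid_n_uni)
      fb <- fit_bivariate(
        merged, inp$ld, f1, f2, M = M, n_iter = mx$n_iter,
        n_subsample = mx$n_subsample, prune_r2 = mx$prune_r2,
        seed = substream_seed(config$seed, paste0(nm, "_biv")),
        grid_n = mx$grid_n_biv)
      fits <- list(trait1 = f1, trait2 = f2, bivariate = fb)
      readr::write_tsv(bind_rows(
        mutate(tidy(f1), model = "univariate_trait1"),
        mutate(tidy(f2), model = "univariate_trait2"),
        mutate(tidy(fb), model = "bivariate")),
        file.path(out_dir, sprintf("%s_mixture_estimates.tsv", nm)),
        progress = FALSE)
      readr::write_tsv(fb$iterations,
                       file.path(out_dir,
                                 sprintf("%s_mixture_iterations.tsv", nm)),
                       progress = FALSE)
      readr::write_tsv(fb$derived,
                       file.path(out_dir,
                                 sprintf("%s_mixture_derived.tsv", nm)),
                       progress = FALSE)
      manifest$stages <- c(manifest$stages, paste0(nm, ":mixture"))
    }

    fd <- config$fdr
    excl <- if (isTRUE(fd$use_exclusions)) default_exclusion_regions()
      else NULL
    cj <- conj_fdr_table(merged, inp$ld, strata = fd$strata,
                         n_prune_iter = fd$n_prune_iter,
                         prune_r2 = fd$prune_r2, exclusions = excl,
                         seed = substream_seed(config$seed,
                                               paste0(nm, "_fdr")),
                         significance_threshold =
                           fd$significance_threshold)
    out_tab <- tibble(
      SNP = cj$table$variant_id, CHR = cj$table$chromosome,
      BP = cj$table$position, A1 = cj$table$allele_effect,
      A2 = cj$table$allele_other, Z1 = cj$table$z1, Z2 = cj$table$z2,
      P1 = cj$table$p1, P2 = cj$table$p2,
      condFDR1 = cj$table$condfdr_1, condFDR2 = cj$table$condfdr_2,
      conjFDR = cj$table$conjfdr, significant = cj$table$significant)
    readr::write_tsv(out_tab, file.path(out_dir,
                                        sprintf("%s_conjfdr.tsv", nm)),
                     progress = FALSE)
    qq <- conditional_qq(cj$table, strata = fd$strata, primary = 1)
    readr::write_tsv(as_tibble(qq),
                     file.path(out_dir, sprintf("%s_qq.tsv", nm)),
                     progress = FALSE)
    manifest$stages <- c(manifest$stages, paste0(nm, ":conjfdr"))
    manifest$counts[[nm]]$n_significant <- sum(cj$table$significant)

    lc <- config$loci
    loci <- define_loci(cj$table, inp$ld,
                        sig_threshold = lc$sig_threshold,
                        cand_threshold = lc$cand_threshold,
                        r2_independent = lc$r2_independent,
                        r2_lead = lc$r2_lead, merge_kb = lc$merge_kb)
    if (!is.null(config$known)) {
      known <- lapply(config$known, function(k) {
        if (is.character(k)) read_intervals(k) else k
      })
      loci <- annotate_novelty(loci, known)
    }
    conc <- directional_concordance(loci)
    write_loci(loci, file.path(out_dir, sprintf("%s_loci.tsv", nm)),
               analysis = nm)
    readr::write_tsv(conc$summary,
                     file.path(out_dir,
                               sprintf("%s_concordance.tsv", nm)),
                     progress = FALSE)
    manifest$stages <- c(manifest$stages, paste0(nm, ":loci"))
    manifest$counts[[nm]]$n_loci <- nrow(loci)

    rep_res <- NULL
    rp <- config$replication
    if (!is.null(rp)) {
      rep_tbl <- if (!is.null(rp$path)) {
        read_sumstats(rp$path)
      } else if (!is.null(inp$truth)) {
        simulate_replication(inp$truth, inp$ld,
                             n_rep = rp$n_rep %||% inp$sim$n_rep,
                             seed = substream_seed(config$seed,
                                                   paste0(nm, "_rep")),
                             trait = rp$trait %||% 1)
      } else NULL
      if (!is.null(rep_tbl) && nrow(loci) > 0) {
        zcol <- if ((rp$trait %||% 1) == 1) "lead_z1" else "lead_z2"
        leads <- tibble(variant_id = loci$lead_snp, z = loci[[zcol]])
        rep_res <- sign_concordance_test(leads, rep_tbl)
        readr::write_tsv(as_tibble(rep_res),
                         file.path(out_dir,
                                   sprintf("%s_replication.tsv", nm)),
                         progress = FALSE)
        manifest$stages <- c(manifest$stages, paste0(nm, ":replication"))
      }
    }

    enr <- NULL
    if (!is.null(config$genes) && !is.null(config$gene_sets) &&
        nrow(loci) > 0) {
      genes <- if (is.character(config$genes)) {
        readr::read_tsv(config$genes, show_col_types = FALSE)
      } else config$genes
      gs <- if (is.character(config$gene_sets)) {
        read_gmt(config$gene_sets)
      } else config$gene_sets
      mapped <- map_genes_positional(
        loci, genes, select(cj$table, "variant_id", "chromosome",
                            "position"))
      gl <- config$gene_list %||% unique(mapped$symbol)
      enr <- hypergeometric_enrichment(gl, gs, unique(genes$symbol))
      readr::write_tsv(enr, file.path(out_dir,
                                      sprintf("%s_enrichment.tsv", nm)),
                       progress = FALSE)
      manifest$stages <- c(manifest$stages, paste0(nm, ":enrichment"))
    }

    results[[nm]] <- list(merged = merged, fits = fits, conjfdr = cj,
                          loci = loci, concordance = conc,
                          replication = rep_res, enrichment = enr,
                          truth = inp$truth, deltas = inp$deltas)
    trans_inputs[[nm]] <- list(loci = loci, conjfdr = cj$table)
  }

  trans <- NULL
  if (length(trans_inputs) >= 2) {
    trans <- merge_transdiagnostic(trans_inputs,
                                   sig_threshold =
                                     config$fdr$significance_threshold)
    flat <- trans |>
      mutate(analyses = vapply(.data$analyses, paste, character(1),
                               collapse = ","),
             lead_conjfdr = vapply(.data$lead_conjfdr, function(x)
               paste(signif(x, 4), collapse = ","), character(1)),
             concordant = vapply(.data$concordant, paste, character(1),
                                 collapse = ","))
    readr::write_tsv(as_tibble(flat),
                     file.path(out_dir, "transdiagnostic.tsv"),
                     progress = FALSE)
    manifest$stages <- c(manifest$stages, "transdiagnostic")
    manifest$counts$n_transdiagnostic <- nrow(trans)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results,
                 transdiagnostic = trans))
}
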