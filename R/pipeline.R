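#' Discovery pipeline: datasets to conserved signature
#'
#' Runs the full discovery chain on two or more probe-level datasets:
#' optional lymph-node contamination filtering (ranges fitted per dataset on
#' its own PO group), probe-to-gene collapse by strongest differential
#' score, universe restriction (joint intersection by default), signed
#' ranking, pairwise RRHO and signature intersection, and optional cell-type
#' profiling of the result.
#'
#' @param datasets List of probe-level [expr_dataset()]s (>= 2).
#' @param lymph_genes Lymph-node classifier gene symbols; `NULL` skips the
#'   contamination filter.
#' @param min_votes Classifier exceedances that exclude an FO sample.
#' @param step RRHO grid spacing (`NULL` = per-pair default).
#' @param quadrant Quadrant mined for the signature (default `"FO-FO"`).
#' @param joint_universe Intersect all platforms before ranking (default);
#'   `FALSE` ranks each platform on its own universe and lets
#'   [build_signature()] intersect per pair.
#' @param es_table Optional [enrichment_table()] for cell-type profiling.
#' @param es_threshold Enrichment score cutoff (strictly greater).
#' @param top_k Cell types reported.
#' @param var_equal Classical Student t (default) or Welch.
#' @param out_dir Optional directory; when given, every artifact (filtered
#'   sample reports, ranked lists, RRHO maps, signature, cell-type table,
#'   run manifest) is written there.
#' @param seed Seed recorded in the manifest (the discovery chain itself is
#'   deterministic).
#' @return List with `signature`, `ranked_lists`, `report`
#'   ([signature_report()]), `excluded_samples`, `cell_type_counts`,
#'   `top_cell_types`.
#' @export
run_discovery <- function(datasets, lymph_genes = NULL, min_votes = 3,
                          step = NULL, quadrant = "FO-FO",
                          joint_universe = TRUE, es_table = NULL,
                          es_threshold = 700, top_k = 10, var_equal = TRUE,
                          out_dir = NULL, seed = NULL) {
  if (length(datasets) < 2) stop("need at least 2 discovery datasets")
  excluded <- list()
  if (!is.null(lymph_genes)) {
    datasets <- lapply(datasets, function(ds) {
      rng <- fit_lymph_ranges(ds, lymph_genes, min_votes = min_votes)
      flt <- filter_fo_samples(ds, rng)
      excluded[[ds$platform_id]] <<- flt$excluded
      flt$kept
    })
  }
  collapsed <- lapply(datasets, collapse_probes)
  if (joint_universe) collapsed <- intersect_universe(collapsed)
  ranked <- lapply(collapsed, rank_genes, var_equal = var_equal)
  names(ranked) <- vapply(collapsed, `[[`, "", "platform_id")
  sig <- build_signature(ranked, step = step, quadrant = quadrant)
  report <- signature_report(sig)

  counts <- top <- NULL
  if (!is.null(es_table) && length(sig$genes)) {
    counts <- count_high_es(sig, es_table, threshold = es_threshold)
    top <- top_cell_types(counts, k = top_k)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(ranked))
      write_ranked_list(ranked[[nm]], file.path(out_dir,
                                                paste0("ranked_", nm, ".tsv")))
    for (pr in sig$pairwise_results)
      write_rrho_map(pr$map, file.path(out_dir,
                                       paste0("rrho_", gsub("~", "_vs_", pr$pair), ".tsv")))
    write_signature(sig, file.path(out_dir, "signature.txt"))
    utils::write.table(report$pairs, file.path(out_dir, "pairwise_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(excluded)) {
      excl <- do.call(rbind, excluded)
      utils::write.table(excl, file.path(out_dir, "excluded_samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(top))
      utils::write.table(top, file.path(out_dir, "top_cell_types.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(package_version = as.character(utils::packageVersion("rrhosig")),
                     r_version = R.version.string,
                     seed = seed, quadrant = quadrant, step = step,
                     joint_universe = joint_universe,
                     min_votes = min_votes,
                     n_datasets = length(datasets),
                     signature_size = length(sig$genes),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(signature = sig, ranked_lists = ranked, report = report,
       excluded_samples = excluded, cell_type_counts = counts,
       top_cell_types = top)
}

#' Validation pipeline: classify independent cohorts with a signature
#'
#' @param sig Signature object or gene vector (non-empty).
#' @param cohorts List of gene-collapsed (or probe-level, auto-collapsed)
#'   [expr_dataset()]s with class labels.
#' @param out_dir Optional output directory for per-cohort votes and
#'   summaries.
#' @param ... Passed to [evaluate_cohort()] / [wgv_statistics()].
#' @return Named list of [evaluate_cohort()] summaries (cohorts that fail,
#'   e.g. for missing class structure, are reported as `NULL` with a
#'   warning and the rest continue).
#' @export
run_validation <- function(sig, cohorts, out_dir = NULL, ...) {
  genes <- if (inherits(sig, "signature")) sig$genes else as.character(sig)
  if (!length(genes)) stop("signature is empty")
  out <- lapply(cohorts, function(ds) {
    if (anyDuplicated(dataset_genes(ds))) ds <- collapse_probes(ds)
    tryCatch(evaluate_cohort(ds, sig, ...), error = function(e) {
      warning("cohort '", ds$platform_id, "' skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  names(out) <- vapply(cohorts, `[[`, "", "platform_id")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      if (!is.null(out[[nm]]))
        write_evaluation(out[[nm]], file.path(out_dir, nm))
  }
  out
}
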