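#' Write / read an expression dataset as TSV
#'
#' The on-disk dialect is two files: the expression table (columns `probe`,
#' `gene`, then one column per sample) and a sample annotation table
#' (`sample`, `class`, and `time`/`event` when survival is annotated).
#'
#' @param ds An [expr_dataset()].
#' @param values_path Path of the expression TSV.
#' @param annot_path Path of the sample annotation TSV; default replaces the
#'   values file's extension with `.samples.tsv`.
#' @return `values_path`, invisibly.
#' @export
write_expr_dataset <- function(ds, values_path,
                               annot_path = sub("\\.tsv$", ".samples.tsv",
                                                values_path)) {
  stopifnot(inherits(ds, "expr_dataset"))
  tab <- data.frame(probe = rownames(ds$values),
                    gene = unname(ds$probe_to_gene[rownames(ds$values)]),
                    ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  annot <- data.frame(sample = colnames(ds$values),
                      class = unname(ds$sample_classes),
                      stringsAsFactors = FALSE)
  if (!is.null(ds$survival)) {
    annot$time <- ds$survival$time[match(annot$sample, ds$survival$sample)]
    annot$event <- ds$survival$event[match(annot$sample, ds$survival$sample)]
  }
  utils::write.table(annot, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' @rdname write_expr_dataset
#' @param platform_id Platform id for the reconstructed dataset.
#' @export
read_expr_dataset <- function(values_path,
                              annot_path = sub("\\.tsv$", ".samples.tsv",
                                               values_path),
                              platform_id = NULL) {
  tab <- utils::read.table(values_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(tab)[1:2]))
    stop("expression TSV must start with columns 'probe' and 'gene'")
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(values) <- tab$probe
  annot <- utils::read.table(annot_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  surv <- if (all(c("time", "event") %in% names(annot)))
    data.frame(sample = annot$sample, time = annot$time, event = annot$event)
  else NULL
  if (is.null(platform_id))
    platform_id <- sub("\\.tsv$", "", basename(values_path))
  expr_dataset(values, stats::setNames(tab$gene, tab$probe),
               stats::setNames(annot$class, annot$sample)[colnames(values)],
               surv, platform_id)
}

#' Write / read a ranked list as two-column TSV
#'
#' File row order is rank order; columns are `gene` and `score`.
#'
#' @param rl A [ranked_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(rl, path) {
  stopifnot(inherits(rl, "ranked_list"))
  utils::write.table(data.frame(gene = rl$genes, score = rl$scores),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ranked_list(tab$gene, tab$score,
              metadata = list(dataset_id = sub("\\.tsv$", "", basename(path))))
}

#' Export an RRHO map as a TSV matrix
#'
#' Row/column headers are the rank thresholds; cells are `-log10 p`.
#'
#' @param map An [rrho_map()].
#' @param path Output path.
#' @param what `"neglog_p"` (default) or `"overlap_counts"`.
#' @return `path`, invisibly.
#' @export
write_rrho_map <- function(map, path, what = c("neglog_p", "overlap_counts")) {
  stopifnot(inherits(map, "rrho_map"))
  what <- match.arg(what)
  utils::write.table(map[[what]], path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Write a signature as plain text and JSON
#'
#' @param sig A signature object.
#' @param path Path of the gene-list text file (one symbol per line); a
#'   `.json` sibling carries genes, provenance and the pairwise report.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature"))
  writeLines(sig$genes, path)
  rep <- signature_report(sig)
  jsonlite::write_json(
    list(genes = sig$genes, quadrant = sig$quadrant,
         provenance = sig$provenance, report = rep$pairs,
         intersection_size = rep$intersection_size),
    sub("\\.[a-z]+$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an evaluation summary (votes TSV + metrics JSON)
#'
#' @param ev An [evaluate_cohort()] summary.
#' @param prefix Output path prefix; writes `<prefix>_votes.tsv` and
#'   `<prefix>_summary.json`.
#' @return The JSON path, invisibly.
#' @export
write_evaluation <- function(ev, prefix) {
  stopifnot(inherits(ev, "evaluation_summary"))
  utils::write.table(ev$votes, paste0(prefix, "_votes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- list(cohort = ev$cohort, confusion = ev$confusion, auc = ev$auc,
              n_correct = ev$n_correct, n_total = ev$n_total,
              logrank = ev$logrank)
  path <- paste0(prefix, "_summary.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an enrichment score table from TSV
#'
#' First column = probe/gene id (optionally a second `gene` column), the
#' rest one column per cell type.
#'
#' @param path TSV path.
#' @return An [enrichment_table()].
#' @export
read_enrichment_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  has_gene <- names(tab)[2] == "gene"
  scores <- as.matrix(tab[, -(1:(1 + has_gene)), drop = FALSE])
  rownames(scores) <- tab[[1]]
  p2g <- if (has_gene) stats::setNames(tab$gene, tab[[1]]) else NULL
  enrichment_table(scores, probe_to_gene = p2g)
}

#' Write an enrichment score table as TSV
#'
#' @param table An [enrichment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  tab <- data.frame(probe = rownames(table$scores),
                    gene = unname(table$probe_to_gene),
                    table$scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
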