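#' Cell-type enrichment score table
#'
#' Dense matrix of enrichment scores, one row per probe (or gene) and one
#' column per cell/tissue type, as exported from a curated profiling
#' database.
#'
#' @param scores Numeric matrix with probe row names and cell-type column
#'   names; all entries finite.
#' @param probe_to_gene Optional named map probe -> gene symbol; defaults to
#'   the identity (rows already carry gene symbols).
#' @return An `enrichment_table` object.
#' @export
enrichment_table <- function(scores, probe_to_gene = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` needs probe row names and cell-type column names")
  if (!all(is.finite(scores))) stop("enrichment scores must be finite")
  if (is.null(probe_to_gene))
    probe_to_gene <- stats::setNames(rownames(scores), rownames(scores))
  missing <- setdiff(rownames(scores), names(probe_to_gene))
  if (length(missing))
    stop("probes absent from `probe_to_gene`: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(list(scores = scores,
                 probe_to_gene = probe_to_gene[rownames(scores)],
                 cell_types = colnames(scores)),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> %d probes x %d cell types\n",
              nrow(x$scores), length(x$cell_types)))
  invisible(x)
}

#' Count high-enrichment signature probes per cell type
#'
#' For each cell/tissue type, counts how many signature probes carry an
#' enrichment score strictly above `threshold` — many high-scoring probes
#' for the same type indicate that cell type infiltrating the tumors the
#' signature came from. Signature entries are matched to table rows by gene
#' symbol; a gene with several probes contributes each matching probe.
#' Signature genes absent from the table are skipped with a message.
#'
#' @param sig A [build_signature()]/[as_signature()] object, or a character
#'   vector of gene symbols.
#' @param table An [enrichment_table()].
#' @param threshold Score above which a probe represents a cell type
#'   (default 700, strictly greater).
#' @return Named integer vector of counts, one per cell type (table column
#'   order).
#' @export
count_high_es <- function(sig, table, threshold = 700) {
  stopifnot(inherits(table, "enrichment_table"))
  genes <- if (inherits(sig, "signature")) sig$genes else as.character(sig)
  row_genes <- unname(table$probe_to_gene)
  keep <- row_genes %in% genes
  n_absent <- sum(!genes %in% row_genes)
  if (!any(keep))
    stop("no signature gene present in the enrichment table")
  if (n_absent > 0)
    message(n_absent, " signature gene(s) absent from the enrichment table")
  sub <- table$scores[keep, , drop = FALSE]
  counts <- colSums(sub > threshold)
  storage.mode(counts) <- "integer"
  counts
}

#' Top cell types by high-enrichment probe count
#'
#' @param counts Named counts from [count_high_es()].
#' @param k How many cell types to return (default 10).
#' @return Data frame (`cell_type`, `count`, `rank`) sorted by count
#'   descending, ties broken alphabetically.
#' @export
top_cell_types <- function(counts, k = 10) {
  if (!length(counts)) stop("`counts` must be non-empty")
  if (k <= 0) stop("`k` must be positive")
  ord <- order(-counts, names(counts))
  top <- utils::head(ord, k)
  data.frame(cell_type = names(counts)[top],
             count = as.integer(counts[top]),
             rank = seq_along(top),
             stringsAsFactors = FALSE)
}
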