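#' Expression dataset container
#'
#' Bundles a probe-by-sample expression matrix (log-intensity scale) with a
#' probe-to-gene map, a two-class outcome label per sample (`"FO"` favorable,
#' `"PO"` poor) and optional right-censored survival annotations.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param probe_to_gene Named character vector mapping every probe id (names)
#'   to one gene symbol. Genes may own several probes. Probes mapping to `NA`
#'   or `""` are allowed here and are dropped (with a message) by
#'   [collapse_probes()].
#' @param sample_classes Character vector of `"FO"`/`"PO"` labels; either
#'   named by sample id or in column order of `values`.
#' @param survival Optional `data.frame` with columns `sample`, `time`
#'   (months, > 0) and `event` (1 = death observed, 0 = censored), covering
#'   every sample.
#' @param platform_id Character scalar identifying the platform/cohort.
#'
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `probe_to_gene`, `sample_classes`, `survival`, `platform_id`.
#' @export
expr_dataset <- function(values, probe_to_gene, sample_classes,
                         survival = NULL, platform_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated probe ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in `values`")
  if (is.null(names(probe_to_gene))) stop("`probe_to_gene` must be named by probe id")
  missing_map <- setdiff(rownames(values), names(probe_to_gene))
  if (length(missing_map))
    stop("probes absent from `probe_to_gene`: ", paste(utils::head(missing_map, 5), collapse = ", "))
  probe_to_gene <- probe_to_gene[rownames(values)]

  samples <- colnames(values)
  if (!is.null(names(sample_classes))) {
    if (!setequal(names(sample_classes), samples))
      stop("`sample_classes` names do not match sample ids")
    sample_classes <- sample_classes[samples]
  } else {
    if (length(sample_classes) != length(samples))
      stop("`sample_classes` must cover every sample")
    names(sample_classes) <- samples
  }
  sample_classes <- as.character(sample_classes)
  names(sample_classes) <- samples
  if (!all(sample_classes %in% c("FO", "PO")))
    stop("sample classes must be 'FO' or 'PO'")

  if (!is.null(survival)) {
    req <- c("sample", "time", "event")
    if (!all(req %in% names(survival)))
      stop("`survival` needs columns sample, time, event")
    if (!setequal(survival$sample, samples))
      stop("`survival` must cover exactly the dataset samples")
    survival <- survival[match(samples, survival$sample), req, drop = FALSE]
    rownames(survival) <- NULL
    if (any(survival$time <= 0)) stop("survival times must be positive")
    if (!all(survival$event %in% c(0, 1))) stop("survival events must be 0/1")
  }

  structure(
    list(values = values, probe_to_gene = probe_to_gene,
         sample_classes = sample_classes, survival = survival,
         platform_id = as.character(platform_id)),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset '%s'> %d probes x %d samples (%d FO / %d PO)%s\n",
              x$platform_id, nrow(x$values), ncol(x$values),
              sum(x$sample_classes == "FO"), sum(x$sample_classes == "PO"),
              if (is.null(x$survival)) "" else ", survival annotated"))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Gene symbols of a dataset
#'
#' @param ds An [expr_dataset()].
#' @return Character vector of gene symbols, one per probe row (may repeat).
#' @export
dataset_genes <- function(ds) unname(ds$probe_to_gene[rownames(ds$values)])

#' Subset a dataset by sample ids
#'
#' @param ds An [expr_dataset()].
#' @param samples Character vector of sample ids to keep.
#' @return A new `expr_dataset` restricted to `samples` (original order kept).
#' @export
subset_samples <- function(ds, samples) {
  keep <- colnames(ds$values)[colnames(ds$values) %in% samples]
  if (!length(keep)) stop("no samples left after subsetting")
  surv <- ds$survival
  if (!is.null(surv)) surv <- surv[surv$sample %in% keep, , drop = FALSE]
  expr_dataset(ds$values[, keep, drop = FALSE], ds$probe_to_gene,
               ds$sample_classes[keep], surv, ds$platform_id)
}

# internal: column indices per outcome class
.class_idx <- function(ds) {
  list(fo = which(ds$sample_classes == "FO"),
       po = which(ds$sample_classes == "PO"))
}
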