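#' Signed differential score for one gene
#'
#' The score that orders every ranked profile: the two-sided Student t-test
#' p-value on the log scale, signed by the direction of the mean difference,
#' `sign(mean_FO - mean_PO) * (-log10 p)`. Large positive scores mean
#' strongly FO-overexpressed; large negative, strongly PO-overexpressed.
#'
#' With zero pooled variance the score is `0` when the group means agree and
#' `+/-Inf` otherwise (a sentinel ranked outermost by [rank_genes()]).
#'
#' @param fo_values,po_values Numeric vectors of expression in the favorable
#'   and poor outcome groups (each of length >= 2, finite).
#' @param var_equal Use the classical equal-variance Student t (default);
#'   `FALSE` switches to Welch.
#' @return A single signed score. Attributes `t`, `df` and `p` carry the
#'   underlying statistic.
#' @export
differential_score <- function(fo_values, po_values, var_equal = TRUE) {
  if (length(fo_values) < 2 || length(po_values) < 2)
    stop("need at least 2 samples per group")
  if (!all(is.finite(fo_values)) || !all(is.finite(po_values)))
    stop("expression values must be finite")
  st <- .row_tstats(rbind(c(fo_values, po_values)),
                    seq_along(fo_values),
                    length(fo_values) + seq_along(po_values),
                    var_equal = var_equal)
  structure(st$score, t = st$t, df = st$df, p = st$p)
}

# Vectorized row-wise two-sample t statistics.
# Returns t, df, two-sided p and the signed -log10(p) score; degenerate rows
# (zero variance) get score 0 when means agree, +/-Inf otherwise.
.row_tstats <- function(values, fo_idx, po_idx, var_equal = TRUE) {
  x <- values[, fo_idx, drop = FALSE]
  y <- values[, po_idx, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2); ss2 <- rowSums((y - m2)^2)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(diff))
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    df[se == 0] <- n1 + n2 - 2
  }
  t <- diff / se
  # log-space p so huge |t| does not underflow before the -log10 transform
  logp <- log(2) + stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  score <- sign(diff) * (-logp / log(10))
  p <- exp(logp)

  degen <- se == 0
  if (any(degen)) {
    zero_diff <- degen & diff == 0
    t[zero_diff] <- 0; p[zero_diff] <- 1; score[zero_diff] <- 0
    inf <- degen & diff != 0
    t[inf] <- sign(diff[inf]) * Inf
    p[inf] <- 0
    score[inf] <- sign(diff[inf]) * Inf
  }
  list(t = t, df = df, p = p, score = score)
}

#' Ranked differential expression profile
#'
#' Orders the genes of a (gene-collapsed) dataset by their signed
#' [differential_score()], rank 1 being the most FO-overexpressed gene. Ties
#' on the score are broken by |t| descending, then gene symbol ascending;
#' `+Inf` sentinels rank first and `-Inf` last, among themselves by symbol.
#'
#' @param ds An [expr_dataset()] with one probe per gene and both classes
#'   represented (>= 2 samples each).
#' @param var_equal Passed to the t statistic (see [differential_score()]).
#' @return A `ranked_list`: list with `genes` (ordered symbols), `scores`
#'   (non-increasing), `t` (tie-break statistic) and `metadata`.
#' @export
rank_genes <- function(ds, var_equal = TRUE) {
  stopifnot(inherits(ds, "expr_dataset"))
  genes <- dataset_genes(ds)
  if (anyDuplicated(genes))
    stop("dataset must be collapsed to gene level first (see collapse_probes)")
  idx <- .class_idx(ds)
  if (length(idx$fo) < 2 || length(idx$po) < 2)
    stop("need >= 2 samples in each class")
  st <- .row_tstats(ds$values, idx$fo, idx$po, var_equal = var_equal)
  ord <- order(-st$score, -abs(st$t), genes)
  ranked_list(genes = genes[ord], scores = st$score[ord], t = st$t[ord],
              metadata = list(dataset_id = ds$platform_id,
                              n_fo = length(idx$fo), n_po = length(idx$po)))
}

#' Construct a ranked list
#'
#' @param genes Ordered gene symbols (unique).
#' @param scores Signed scores, non-increasing with rank.
#' @param t Optional per-gene t statistics (tie-breaking metadata).
#' @param metadata List of provenance fields (`dataset_id`, `n_fo`, `n_po`).
#' @return A `ranked_list` object.
#' @export
ranked_list <- function(genes, scores, t = NULL, metadata = list()) {
  if (length(genes) != length(scores)) stop("genes and scores differ in length")
  if (anyDuplicated(genes)) stop("duplicated genes in ranked list")
  fin <- is.finite(scores)
  if (any(fin) && is.unsorted(-scores[fin]))
    stop("scores must be non-increasing with rank")
  structure(list(genes = as.character(genes), scores = as.numeric(scores),
                 t = t, metadata = metadata),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> %d genes (%s), top: %s (%.3f)\n",
              length(x$genes),
              if (is.null(x$metadata$dataset_id)) "?" else x$metadata$dataset_id,
              x$genes[1], x$scores[1]))
  invisible(x)
}

#' @export
length.ranked_list <- function(x) length(x$genes)

#' Restrict a ranked list to a gene subset
#'
#' Keeps the relative order (and scores) of the surviving genes — the
#' re-ranking used when two platforms are compared on their common universe.
#'
#' @param rl A `ranked_list`.
#' @param genes Genes to keep.
#' @return A `ranked_list` over `intersect(rl$genes, genes)`.
#' @export
restrict_ranked <- function(rl, genes) {
  keep <- rl$genes %in% genes
  ranked_list(rl$genes[keep], rl$scores[keep],
              t = if (is.null(rl$t)) NULL else rl$t[keep],
              metadata = rl$metadata)
}

# reverse a ranked list: most PO-enriched first, scores negated
.reverse_ranked <- function(rl) {
  n <- length(rl$genes)
  ranked_list(rev(rl$genes), rev(-rl$scores),
              t = if (is.null(rl$t)) NULL else rev(-rl$t),
              metadata = rl$metadata)
}

#' Cutoff-based overlap baseline
#'
#' The conventional alternative RRHO improves on: call genes significant in
#' each dataset by fold change and p-value thresholds, then intersect the
#' calls per direction. Expression matrices are log2-intensity, so the fold
#' change criterion |FC| > `fc_threshold` becomes |mean difference| >
#' log2(`fc_threshold`).
#'
#' @param ds1,ds2 Gene-collapsed [expr_dataset()]s on a common gene universe.
#' @param fc_threshold Fold-change bound (> 1 on the ratio scale).
#' @param p_threshold Two-sided p-value bound.
#' @param var_equal Passed to the t statistic.
#' @return List with `up` and `down`: genes passing both filters in both
#'   datasets with consistent direction (FO-up or FO-down).
#' @export
cutoff_overlap <- function(ds1, ds2, fc_threshold = 1.5, p_threshold = 0.05,
                           var_equal = TRUE) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  calls <- lapply(list(ds1, ds2), function(ds) {
    genes <- dataset_genes(ds)
    if (anyDuplicated(genes)) stop("datasets must be gene-collapsed")
    idx <- .class_idx(ds)
    st <- .row_tstats(ds$values, idx$fo, idx$po, var_equal = var_equal)
    diff <- rowMeans(ds$values[, idx$fo, drop = FALSE]) -
      rowMeans(ds$values[, idx$po, drop = FALSE])
    lfc <- log2(fc_threshold)
    list(up = genes[diff > lfc & st$p < p_threshold],
         down = genes[diff < -lfc & st$p < p_threshold])
  })
  list(up = sort(intersect(calls[[1]]$up, calls[[2]]$up)),
       down = sort(intersect(calls[[1]]$down, calls[[2]]$down)))
}
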