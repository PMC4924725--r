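#' Weighted-gene-voting class statistics
#'
#' Per signature gene: mean and standard deviation (n-1 denominator) of its
#' expression in the "alive" (FO) and "dead" (PO) groups, the
#' signal-to-noise weight `W = (mean_alive - mean_dead) /
#' (stdev_alive + stdev_dead)`, and the decision boundary the vote is taken
#' against. The boundary defaults to the midpoint of the two class means,
#' `(mean_alive + mean_dead) / 2`; `strict_formula = TRUE` instead uses the
#' half-difference `(mean_alive - mean_dead) / 2` (see the methods vignette
#' for why the midpoint is the default).
#'
#' @param ds Gene-collapsed [expr_dataset()].
#' @param sig Signature object or character vector of genes. Genes absent
#'   from the dataset are skipped with a message.
#' @param exclude_sample Optional sample id excluded from the statistics
#'   (leave-one-out mode).
#' @param strict_formula Use the half-difference boundary instead of the
#'   midpoint.
#' @param loo_means_only In leave-one-out mode, recompute only the class
#'   means from the reduced group and keep full-cohort standard deviations
#'   (default `FALSE`: both recomputed).
#' @return Data frame with one row per usable gene: `gene`, `mean_alive`,
#'   `mean_dead`, `sd_alive`, `sd_dead`, `weight`, `boundary`. Genes with a
#'   zero stdev sum are dropped with a message.
#' @export
wgv_statistics <- function(ds, sig, exclude_sample = NULL,
                           strict_formula = FALSE, loo_means_only = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"))
  genes <- if (inherits(sig, "signature")) sig$genes else as.character(sig)
  ds_genes <- dataset_genes(ds)
  if (anyDuplicated(ds_genes)) stop("dataset must be gene-collapsed")
  present <- genes[genes %in% ds_genes]
  n_absent <- length(genes) - length(present)
  if (n_absent > 0)
    message(n_absent, " signature gene(s) absent from '", ds$platform_id,
            "' skipped")
  if (!length(present)) stop("no signature gene present in the dataset")

  keep <- colnames(ds$values)
  if (!is.null(exclude_sample)) keep <- setdiff(keep, exclude_sample)
  cls <- ds$sample_classes[keep]
  fo <- keep[cls == "FO"]; po <- keep[cls == "PO"]
  if (length(fo) < 2 || length(po) < 2)
    stop("need >= 2 samples per class after any holdout")

  rows <- match(present, ds_genes)
  m_a <- rowMeans(ds$values[rows, fo, drop = FALSE])
  m_d <- rowMeans(ds$values[rows, po, drop = FALSE])
  sd_cols <- if (loo_means_only) {
    all_cls <- ds$sample_classes
    list(fo = names(all_cls)[all_cls == "FO"],
         po = names(all_cls)[all_cls == "PO"])
  } else list(fo = fo, po = po)
  s_a <- apply(ds$values[rows, sd_cols$fo, drop = FALSE], 1, stats::sd)
  s_d <- apply(ds$values[rows, sd_cols$po, drop = FALSE], 1, stats::sd)

  usable <- (s_a + s_d) > 0
  if (any(!usable))
    message(sum(!usable), " gene(s) with zero class-stdev sum skipped")
  if (!any(usable)) stop("no usable signature genes (all zero variance)")

  w <- (m_a - m_d) / (s_a + s_d)
  boundary <- if (strict_formula) (m_a - m_d) / 2 else (m_a + m_d) / 2
  data.frame(gene = present, mean_alive = m_a, mean_dead = m_d,
             sd_alive = s_a, sd_dead = s_d, weight = w,
             boundary = boundary, row.names = NULL,
             stringsAsFactors = FALSE)[usable, , drop = FALSE]
}

#' Single-gene vote
#'
#' `vote = W * (S - boundary)`: the signal-to-noise weight times the sample's
#' offset from the class-mean boundary. Positive votes argue for the
#' favorable ("alive") class.
#'
#' @param stats_g One row of [wgv_statistics()] (or any list with `weight`
#'   and `boundary`).
#' @param s_value The expression value of the sample being classified.
#' @return The vote (numeric scalar; vectorizes over rows when `stats_g` is
#'   a full data frame).
#' @export
gene_vote <- function(stats_g, s_value) {
  stats_g$weight * (s_value - stats_g$boundary)
}

#' Leave-one-out classification of one sample
#'
#' Recomputes the class statistics without the held-out sample, sums the
#' votes of all usable signature genes on that sample's expression, and
#' predicts FO when the sum is positive (a zero sum predicts PO).
#'
#' @param ds Gene-collapsed [expr_dataset()].
#' @param sig Signature or gene vector.
#' @param sample_id Sample to hold out and classify.
#' @param ... Passed to [wgv_statistics()] (`strict_formula`,
#'   `loo_means_only`).
#' @return List with `sample`, `vote_sum`, `predicted_class`, `true_class`
#'   and `votes` (named per-gene votes, for audit).
#' @export
classify_sample_loo <- function(ds, sig, sample_id, ...) {
  if (!sample_id %in% colnames(ds$values)) stop("unknown sample: ", sample_id)
  st <- wgv_statistics(ds, sig, exclude_sample = sample_id, ...)
  s <- ds$values[match(st$gene, dataset_genes(ds)), sample_id]
  votes <- stats::setNames(gene_vote(st, s), st$gene)
  vote_sum <- sum(votes)
  list(sample = sample_id, vote_sum = vote_sum,
       predicted_class = if (vote_sum > 0) "FO" else "PO",
       true_class = unname(ds$sample_classes[sample_id]),
       votes = votes)
}

#' Confusion metrics with FO as the positive class
#'
#' @param tp,fp,tn,fn Confusion counts (FO = positive).
#' @return List with the counts and `ppv`, `npv`, `sensitivity`,
#'   `specificity`, `accuracy` (NaN where the denominator is 0).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' @param scores Numeric classification scores (larger = more FO-like).
#' @param labels True classes, `"FO"`/`"PO"` (or logical, TRUE = positive).
#' @return AUC in `[0, 1]`; ties share 1/2. `NA` if either class is empty.
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "FO"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-group log-rank test
#'
#' Standard observed-versus-expected log-rank comparison of two
#' right-censored survival samples; the statistic is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param time Survival times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return List with `chi_square` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly 2 groups")
  if (sum(event) < 1) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Leave-one-out evaluation of a cohort
#'
#' Classifies every sample with [classify_sample_loo()], then summarizes:
#' confusion counts and derived metrics (FO positive), ROC AUC of the vote
#' sum, and — when survival annotations are present — Kaplan-Meier curves
#' per predicted class with the log-rank split test.
#'
#' @param ds Gene-collapsed [expr_dataset()] with class labels.
#' @param sig Signature or gene vector.
#' @param ... Passed to [wgv_statistics()].
#' @return An `evaluation_summary`: list with `cohort`, `votes` (data frame
#'   sample/vote_sum/predicted/true), `confusion` ([confusion_metrics()]
#'   list), `auc`, `n_correct`, `n_total`, and `logrank`/`km` (NULL without
#'   survival data or with a one-sided prediction).
#' @export
evaluate_cohort <- function(ds, sig, ...) {
  samples <- colnames(ds$values)
  res <- lapply(samples, function(s) classify_sample_loo(ds, sig, s, ...))
  votes <- data.frame(
    sample = samples,
    vote_sum = vapply(res, `[[`, 0, "vote_sum"),
    predicted = vapply(res, `[[`, "", "predicted_class"),
    true = vapply(res, `[[`, "", "true_class"),
    stringsAsFactors = FALSE)

  conf <- confusion_metrics(
    tp = sum(votes$predicted == "FO" & votes$true == "FO"),
    fp = sum(votes$predicted == "FO" & votes$true == "PO"),
    tn = sum(votes$predicted == "PO" & votes$true == "PO"),
    fn = sum(votes$predicted == "PO" & votes$true == "FO"))
  auc <- auc_score(votes$vote_sum, votes$true)

  logrank <- km <- NULL
  if (!is.null(ds$survival) && length(unique(votes$predicted)) == 2 &&
      sum(ds$survival$event) >= 1) {
    surv <- ds$survival[match(votes$sample, ds$survival$sample), ]
    logrank <- logrank_test(surv$time, surv$event, votes$predicted)
    km <- survival::survfit(
      survival::Surv(surv$time, surv$event) ~ votes$predicted)
  }
  structure(list(cohort = ds$platform_id, votes = votes, confusion = conf,
                 auc = auc, n_correct = conf$tp + conf$tn,
                 n_total = nrow(votes), logrank = logrank, km = km),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  c0 <- x$confusion
  cat(sprintf("<evaluation_summary '%s'> %d/%d correct (accuracy %.3f)\n",
              x$cohort, x$n_correct, x$n_total, c0$accuracy))
  cat(sprintf("  PPV %.3f | NPV %.3f | sensitivity %.3f | specificity %.3f | AUC %s\n",
              c0$ppv, c0$npv, c0$sensitivity, c0$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank split: chi-square %.3f, p %.4g\n",
                x$logrank$chi_square, x$logrank$p))
  invisible(x)
}
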