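#' Collapse probes to genes
#'
#' Keeps, for each gene symbol, the probe carrying the strongest differential
#' signal: the probe whose `stat_per_probe` value has the largest absolute
#' value wins; ties go to the lexicographically smallest probe id. Probes
#' without a gene mapping (`NA` or empty symbol) are dropped with a message.
#'
#' @param ds An [expr_dataset()] at probe level.
#' @param stat_per_probe Named numeric vector (probe id -> score, typically a
#'   signed [differential_score()]) covering every probe; `NULL` computes the
#'   default differential score from the dataset's own classes.
#' @return A gene-level [expr_dataset()] whose row names are gene symbols and
#'   whose `probe_to_gene` is the identity map; attribute `chosen_probe`
#'   records the retained probe per gene.
#' @export
collapse_probes <- function(ds, stat_per_probe = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (is.null(stat_per_probe)) {
    idx <- .class_idx(ds)
    st <- .row_tstats(ds$values, idx$fo, idx$po)
    stat_per_probe <- stats::setNames(st$score, rownames(ds$values))
  }
  probes <- rownames(ds$values)
  missing <- setdiff(probes, names(stat_per_probe))
  if (length(missing))
    stop("`stat_per_probe` does not cover probes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  genes <- unname(ds$probe_to_gene[probes])
  unmapped <- is.na(genes) | genes == ""
  if (any(unmapped)) {
    message(sum(unmapped), " probe(s) without gene mapping dropped")
    probes <- probes[!unmapped]; genes <- genes[!unmapped]
  }
  if (!length(probes)) stop("no mapped probes left to collapse")

  stat <- abs(stat_per_probe[probes])
  # order so the first row per gene is the winner: |stat| desc, probe id asc
  ord <- order(genes, -stat, probes, method = "radix")
  first <- !duplicated(genes[ord])
  chosen <- probes[ord][first]
  chosen_genes <- genes[ord][first]

  values <- ds$values[chosen, , drop = FALSE]
  rownames(values) <- chosen_genes
  out <- expr_dataset(values, stats::setNames(chosen_genes, chosen_genes),
                      ds$sample_classes, ds$survival, ds$platform_id)
  attr(out, "chosen_probe") <- stats::setNames(chosen, chosen_genes)
  out
}

#' Restrict datasets to their common gene universe
#'
#' Cross-platform comparison only makes sense on genes measured everywhere;
#' each gene-collapsed dataset is cut down to the intersection of all gene
#' sets, rows sorted identically (alphabetically) across outputs.
#'
#' @param ds_list List of gene-collapsed [expr_dataset()]s.
#' @return List of datasets over the identical, identically ordered universe.
#' @export
intersect_universe <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  gene_sets <- lapply(ds_list, function(ds) {
    g <- dataset_genes(ds)
    if (anyDuplicated(g)) stop("datasets must be gene-collapsed first")
    g
  })
  common <- sort(Reduce(intersect, gene_sets))
  if (!length(common))
    stop("empty gene universe intersection across ",
         length(ds_list), " datasets")
  lapply(ds_list, function(ds) {
    expr_dataset(ds$values[common, , drop = FALSE],
                 ds$probe_to_gene[common], ds$sample_classes,
                 ds$survival, ds$platform_id)
  })
}

#' Fit lymph-node classifier expression ranges
#'
#' Establishes, per classifier gene, the upper end of the expression range
#' observed in the poor-outcome (PO) group — the reference against which
#' favorable-outcome samples are screened for lymphoid-tissue contamination.
#'
#' @param ds An [expr_dataset()] (probe or gene level).
#' @param classifier_genes Gene symbols of the lymph-node classifiers
#'   (typically 6). A gene with several probes is summarized per sample by
#'   the maximum over its probes.
#' @param min_votes Number of classifiers a sample must exceed to be
#'   excluded (default 3).
#' @return A `lymph_ranges` object: list with `classifier_genes`,
#'   `upper_bound` (named per gene) and `min_votes`.
#' @export
fit_lymph_ranges <- function(ds, classifier_genes, min_votes = 3) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (min_votes > length(classifier_genes))
    stop("`min_votes` cannot exceed the number of classifier genes")
  po <- .class_idx(ds)$po
  if (!length(po)) stop("no PO samples to fit ranges on")
  gvals <- .classifier_values(ds, classifier_genes)
  upper <- apply(gvals[, po, drop = FALSE], 1, max)
  structure(list(classifier_genes = classifier_genes,
                 upper_bound = upper, min_votes = as.integer(min_votes)),
            class = "lymph_ranges")
}

# per-sample classifier gene values; multi-probe genes collapsed by max
.classifier_values <- function(ds, classifier_genes) {
  genes <- dataset_genes(ds)
  out <- matrix(NA_real_, length(classifier_genes), ncol(ds$values),
                dimnames = list(classifier_genes, colnames(ds$values)))
  for (g in classifier_genes) {
    rows <- which(genes == g)
    if (!length(rows)) stop("classifier gene absent from dataset: ", g)
    out[g, ] <- if (length(rows) == 1) ds$values[rows, ]
    else apply(ds$values[rows, , drop = FALSE], 2, max)
  }
  out
}

#' Exclude lymph-node-contaminated FO samples
#'
#' A favorable-outcome sample is excluded when its expression exceeds
#' (strictly) the PO-group upper bound on `min_votes` or more classifier
#' genes. PO samples are never excluded.
#'
#' @param ds The [expr_dataset()] the ranges were fitted on.
#' @param ranges A [fit_lymph_ranges()] result.
#' @return List with `kept` (filtered dataset) and `excluded`: a data frame
#'   (`sample`, `votes`, `genes` — comma-separated offending classifiers),
#'   empty when nothing is excluded.
#' @export
filter_fo_samples <- function(ds, ranges) {
  stopifnot(inherits(ds, "expr_dataset"), inherits(ranges, "lymph_ranges"))
  gvals <- .classifier_values(ds, ranges$classifier_genes)
  over <- gvals > ranges$upper_bound  # recycled per column
  votes <- colSums(over)
  is_fo <- ds$sample_classes == "FO"
  drop <- is_fo & votes >= ranges$min_votes
  excluded <- data.frame(
    sample = colnames(ds$values)[drop],
    votes = as.integer(votes[drop]),
    genes = vapply(which(drop), function(j)
      paste(ranges$classifier_genes[over[, j]], collapse = ","), ""),
    stringsAsFactors = FALSE)
  kept <- if (any(drop)) subset_samples(ds, colnames(ds$values)[!drop]) else ds
  list(kept = kept, excluded = excluded)
}
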