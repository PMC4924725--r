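#' Build the conserved outcome signature from pairwise RRHO overlaps
#'
#' For every unordered pair of ranked profiles: restrict both lists to the
#' pair's common gene universe (keeping each list's own order), compute the
#' RRHO map, locate the most significant threshold pair in the requested
#' quadrant, and extract its overlapping genes. The signature is the
#' intersection of all pairwise overlap sets — the genes every pair of
#' studies agrees are enriched in the favorable class.
#'
#' @param ranked_lists List of two or more [ranked_list()]s.
#' @param step RRHO grid spacing; `NULL` uses each pair's default
#'   (`max(1, floor(N_common / 100))`).
#' @param quadrant Direction quadrant to mine, default `"FO-FO"`.
#' @return A `signature` object: list with `genes` (ordered by total rank
#'   across the input lists), `provenance` (per gene, the pair labels whose
#'   overlap contained it), and `pairwise_results` (per pair: the
#'   [find_quadrant_max()] record, the overlap gene set, and the common
#'   universe size).
#' @export
build_signature <- function(ranked_lists, step = NULL, quadrant = "FO-FO") {
  if (length(ranked_lists) < 2) stop("need at least 2 ranked lists")
  if (is.null(names(ranked_lists)) || any(names(ranked_lists) == ""))
    names(ranked_lists) <- vapply(seq_along(ranked_lists), function(k) {
      id <- ranked_lists[[k]]$metadata$dataset_id
      if (is.null(id)) paste0("list", k) else id
    }, "")
  ids <- names(ranked_lists)
  if (anyDuplicated(ids)) ids <- names(ranked_lists) <- make.unique(ids)

  pairs <- utils::combn(length(ranked_lists), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(pq) {
    p <- pq[1]; q <- pq[2]
    pair_id <- paste(ids[p], ids[q], sep = "~")
    common <- intersect(ranked_lists[[p]]$genes, ranked_lists[[q]]$genes)
    if (!length(common))
      stop("pair ", pair_id, ": empty common gene universe")
    a <- restrict_ranked(ranked_lists[[p]], common)
    b <- restrict_ranked(ranked_lists[[q]], common)
    map <- rrho_map(a, b, step = step)
    qmax <- tryCatch(find_quadrant_max(map, quadrant),
                     error = function(e)
                       stop("pair ", pair_id, ": ", conditionMessage(e),
                            call. = FALSE))
    genes <- overlap_genes(a, b, qmax$i_star, qmax$j_star, quadrant)
    list(pair = pair_id, universe_size = length(common),
         max = qmax, genes = genes, map = map)
  })
  names(pairwise) <- vapply(pairwise, `[[`, "", "pair")

  sig_genes <- Reduce(intersect, lapply(pairwise, `[[`, "genes"))
  # deterministic order: total rank across the input lists, ties by symbol
  if (length(sig_genes)) {
    total_rank <- Reduce(`+`, lapply(ranked_lists, function(rl)
      match(sig_genes, rl$genes)))
    sig_genes <- sig_genes[order(total_rank, sig_genes)]
  }
  provenance <- lapply(stats::setNames(sig_genes, sig_genes), function(g)
    names(pairwise)[vapply(pairwise, function(pr) g %in% pr$genes, TRUE)])

  structure(list(genes = sig_genes, provenance = provenance,
                 pairwise_results = pairwise, quadrant = quadrant),
            class = "signature")
}

#' Wrap a plain gene vector as a signature
#'
#' Convenience for classifying with an externally supplied gene list.
#'
#' @param genes Character vector of gene symbols (de-duplicated, trimmed).
#' @return A minimal `signature` object.
#' @export
as_signature <- function(genes) {
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[genes != ""]
  structure(list(genes = genes, provenance = NULL,
                 pairwise_results = NULL, quadrant = NA_character_),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %d genes", length(x$genes)))
  if (!is.null(x$pairwise_results))
    cat(sprintf(" from %d pairwise overlaps (%s quadrant)",
                length(x$pairwise_results), x$quadrant))
  cat("\n")
  invisible(x)
}

#' Summarize a signature build
#'
#' @param sig A [build_signature()] result.
#' @return List with `pairs`: data frame (pair, universe size, thresholds,
#'   max `-log10 p`, overlap size) and `intersection_size`.
#' @export
signature_report <- function(sig) {
  stopifnot(inherits(sig, "signature"))
  if (is.null(sig$pairwise_results))
    return(list(pairs = data.frame(), intersection_size = length(sig$genes)))
  pairs <- do.call(rbind, lapply(sig$pairwise_results, function(pr)
    data.frame(pair = pr$pair, universe_size = pr$universe_size,
               i_star = pr$max$i_star, j_star = pr$max$j_star,
               neglog_p_max = pr$max$neglog_p_max,
               overlap_size = length(pr$genes),
               stringsAsFactors = FALSE)))
  rownames(pairs) <- NULL
  list(pairs = pairs, intersection_size = length(sig$genes))
}
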