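#' Hypergeometric upper-tail probability of an overlap
#'
#' Probability that two unrelated subsets of sizes `i` and `j`, drawn from a
#' universe of `N` genes, share at least `k` members: `P(X >= k)` for `X`
#' hypergeometric with population `N`, `i` successes and `j` draws. Symmetric
#' in `(i, j)`.
#'
#' @param k Observed overlap count (feasible: `max(0, i+j-N) <= k <= min(i,j)`).
#' @param i,j Subset sizes, each in `0..N`.
#' @param N Universe size.
#' @param log10p If `TRUE`, return `-log10 p` computed in log space, which
#'   survives universes of tens of thousands of genes without underflow.
#' @return The tail probability (or its `-log10` when `log10p = TRUE`).
#'   Vectorized over `k`, `i`, `j`, `N`.
#' @export
hypergeom_tail <- function(k, i, j, N, log10p = FALSE) {
  if (any(i < 0 | j < 0 | i > N | j > N))
    stop("`i` and `j` must lie in 0..N")
  if (any(k < pmax(0, i + j - N) | k > pmin(i, j)))
    stop("`k` outside the feasible overlap range")
  if (log10p) {
    lp <- stats::phyper(k - 1, i, N - i, j, lower.tail = FALSE, log.p = TRUE)
    -lp / log(10)
  } else {
    stats::phyper(k - 1, i, N - i, j, lower.tail = FALSE)
  }
}

#' Rank-rank hypergeometric overlap map
#'
#' The threshold-free comparison of two ranked gene lists over the same
#' universe: for every pair of rank thresholds `(i, j)` on a step-spaced
#' grid, the overlap `k` between the top-`i` prefix of `rl1` and the top-`j`
#' prefix of `rl2` is scored by `-log10` of its hypergeometric upper-tail
#' p-value. The grid always contains `(N, N)` and never a zero threshold.
#' Overlap counts are accumulated by a two-dimensional cumulative sum over
#' gene rank positions — `O(N + cells)`, not an intersection per cell.
#'
#' @param rl1,rl2 [ranked_list()]s over the identical gene set.
#' @param step Grid spacing in ranks; default `max(1, floor(N / 100))`
#'   (about a 100 x 100 map).
#' @return An `rrho_map` object: list with `thresholds_1`, `thresholds_2`,
#'   `neglog_p` (matrix, rows = thresholds_1), `overlap_counts`,
#'   `universe_size`, `step`, `quadrant_boundaries` (rank of the last
#'   positive-score gene in each list) and the two ranked lists.
#' @export
rrho_map <- function(rl1, rl2, step = NULL) {
  stopifnot(inherits(rl1, "ranked_list"), inherits(rl2, "ranked_list"))
  bad <- c(setdiff(rl1$genes, rl2$genes), setdiff(rl2$genes, rl1$genes))
  if (length(bad))
    stop("ranked lists differ in gene universe; offending genes: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  N <- length(rl1$genes)
  if (is.null(step)) step <- max(1L, N %/% 100L)
  step <- as.integer(step)
  if (step < 1) stop("`step` must be >= 1")

  thresholds <- unique(c(seq.int(step, N, by = step), N))
  L <- length(thresholds)

  # rank of each gene in both lists, then bin into first covering threshold
  pos2 <- match(rl1$genes, rl2$genes)      # list-2 rank of list-1's r-th gene
  idx1 <- findInterval(seq_len(N) - 1L, thresholds) + 1L
  idx2 <- findInterval(pos2 - 1L, thresholds) + 1L
  counts <- matrix(0L, L, L)
  tab <- table(factor(idx1, levels = seq_len(L)),
               factor(idx2, levels = seq_len(L)))
  counts[] <- as.integer(tab)
  counts <- apply(counts, 2, cumsum)
  counts <- t(apply(counts, 1, cumsum))

  ii <- matrix(thresholds, L, L)
  jj <- matrix(thresholds, L, L, byrow = TRUE)
  neglog <- matrix(hypergeom_tail(as.vector(counts), as.vector(ii),
                                  as.vector(jj), N, log10p = TRUE), L, L)
  dimnames(neglog) <- dimnames(counts) <-
    list(as.character(thresholds), as.character(thresholds))

  structure(list(thresholds_1 = thresholds, thresholds_2 = thresholds,
                 neglog_p = neglog, overlap_counts = counts,
                 universe_size = N, step = step,
                 quadrant_boundaries = c(sum(rl1$scores > 0),
                                         sum(rl2$scores > 0)),
                 rl1 = rl1, rl2 = rl2),
            class = "rrho_map")
}

#' @export
print.rrho_map <- function(x, ...) {
  cat(sprintf("<rrho_map> N=%d, step=%d, %dx%d grid, max -log10 p = %.2f\n",
              x$universe_size, x$step, length(x$thresholds_1),
              length(x$thresholds_2), max(x$neglog_p)))
  invisible(x)
}

# region of the (possibly re-oriented) grid belonging to a quadrant, given
# positive-score boundaries b1, b2 of the oriented lists
.quadrant_region <- function(thresholds, b) thresholds <= b

# orient the two ranked lists for a quadrant: concordant-FO keeps both,
# PO-PO reverses both, discordant quadrants reverse one list
.orient_lists <- function(rl1, rl2, quadrant) {
  N <- length(rl1$genes)
  switch(quadrant,
    "FO-FO" = list(rl1 = rl1, rl2 = rl2,
                   b1 = sum(rl1$scores > 0), b2 = sum(rl2$scores > 0)),
    "PO-PO" = list(rl1 = .reverse_ranked(rl1), rl2 = .reverse_ranked(rl2),
                   b1 = sum(rl1$scores < 0), b2 = sum(rl2$scores < 0)),
    "FO-PO" = list(rl1 = rl1, rl2 = .reverse_ranked(rl2),
                   b1 = sum(rl1$scores > 0), b2 = sum(rl2$scores < 0)),
    "PO-FO" = list(rl1 = .reverse_ranked(rl1), rl2 = rl2,
                   b1 = sum(rl1$scores < 0), b2 = sum(rl2$scores > 0)),
    stop("unknown quadrant: ", quadrant))
}

#' Most significant threshold pair within a quadrant
#'
#' Scans the map cells belonging to a direction quadrant and returns the
#' threshold pair maximizing `-log10 p`. The FO-FO quadrant covers cells with
#' `i` and `j` at or below each list's last positive-score rank; the PO-PO
#' quadrant is the suffix analog, scanned on the map of the reversed lists
#' (thresholds then count from the PO end). Ties are broken by the smallest
#' `i`, then the smallest `j`.
#'
#' @param map An [rrho_map()].
#' @param quadrant One of `"FO-FO"`, `"PO-PO"`, `"FO-PO"`, `"PO-FO"`.
#' @return List with `i_star`, `j_star`, `neglog_p_max`, `k` (overlap count
#'   at the maximum) and `quadrant`. For non-FO-FO quadrants, thresholds
#'   refer to prefixes of the re-oriented (reversed) lists.
#' @export
find_quadrant_max <- function(map, quadrant = "FO-FO") {
  stopifnot(inherits(map, "rrho_map"))
  or <- .orient_lists(map$rl1, map$rl2, quadrant)
  m <- if (quadrant == "FO-FO") map else rrho_map(or$rl1, or$rl2, map$step)
  if (or$b1 < min(m$thresholds_1) || or$b2 < min(m$thresholds_2))
    stop("quadrant ", quadrant, " is empty: positive-direction boundaries (",
         or$b1, ", ", or$b2, ") lie below the first grid threshold")
  r1 <- which(.quadrant_region(m$thresholds_1, or$b1))
  r2 <- which(.quadrant_region(m$thresholds_2, or$b2))
  sub <- m$neglog_p[r1, r2, drop = FALSE]
  best <- max(sub)
  # tie rule: smallest i first, then smallest j
  hit <- which(sub == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i_star <- m$thresholds_1[r1[hit[1, 1]]]
  j_star <- m$thresholds_2[r2[hit[1, 2]]]
  list(i_star = i_star, j_star = j_star, neglog_p_max = best,
       k = m$overlap_counts[as.character(i_star), as.character(j_star)],
       quadrant = quadrant)
}

#' Genes overlapping at a threshold pair
#'
#' The gene set behind a map cell: for the FO-FO quadrant the intersection of
#' the top-`i_star` and top-`j_star` prefixes; for PO-PO the analogous
#' prefixes of the reversed lists (i.e. the most PO-enriched tails). Returned
#' in rank-sum order (sum of the gene's ranks in the two oriented lists,
#' ties by symbol) for determinism.
#'
#' @param rl1,rl2 The [ranked_list()]s the map was built from.
#' @param i_star,j_star Rank thresholds (in oriented-list coordinates, as
#'   returned by [find_quadrant_max()]).
#' @param quadrant Direction quadrant label.
#' @return Character vector of overlapping gene symbols.
#' @export
overlap_genes <- function(rl1, rl2, i_star, j_star, quadrant = "FO-FO") {
  or <- .orient_lists(rl1, rl2, quadrant)
  N <- length(or$rl1$genes)
  if (i_star < 0 || i_star > N || j_star < 0 || j_star > N)
    stop("thresholds out of bounds")
  top1 <- or$rl1$genes[seq_len(i_star)]
  top2 <- or$rl2$genes[seq_len(j_star)]
  genes <- intersect(top1, top2)
  rank_sum <- match(genes, or$rl1$genes) + match(genes, or$rl2$genes)
  genes[order(rank_sum, genes)]
}

#' Draw an RRHO map as a heatmap
#'
#' @param x An [rrho_map()].
#' @param main Plot title.
#' @param ... Further arguments to [graphics::image()].
#' @export
plot.rrho_map <- function(x, main = "RRHO -log10 hypergeometric p", ...) {
  graphics::image(x = x$thresholds_1, y = x$thresholds_2, z = x$neglog_p,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "rank threshold (list 1)",
                  ylab = "rank threshold (list 2)", main = main, ...)
  invisible(x)
}
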