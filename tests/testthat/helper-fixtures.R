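# Shared fixture builders; everything is generated in code, no files.

# Minimal dataset from a plain matrix: probes p1..pn, genes g1..gn (1:1
# unless `genes` given), classes in column order.
make_ds <- function(values, classes, genes = NULL, survival = NULL,
                    platform_id = "test") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(genes)) genes <- sub("^p", "g", rownames(values))
  expr_dataset(values, stats::setNames(genes, rownames(values)),
               classes, survival, platform_id)
}

# Two-class dataset with a planted FO shift on the first `n_shift` genes.
make_two_class <- function(n_genes = 50, n_fo = 5, n_po = 5, effect = 0,
                           n_shift = 0, sd = 1, seed = 1,
                           platform_id = "test") {
  set.seed(seed)
  values <- matrix(rnorm(n_genes * (n_fo + n_po), sd = sd), n_genes)
  if (n_shift > 0)
    values[seq_len(n_shift), seq_len(n_fo)] <-
      values[seq_len(n_shift), seq_len(n_fo)] + effect * sd
  make_ds(values, c(rep("FO", n_fo), rep("PO", n_po)),
          platform_id = platform_id)
}

# Ranked list over genes g001..gN with given (or default descending) scores.
make_ranked <- function(n = 100, scores = NULL, genes = NULL, id = "rl") {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(n))
  if (is.null(scores)) scores <- seq(n / 2, by = -1, length.out = n)
  ranked_list(genes, scores, metadata = list(dataset_id = id))
}

# Random ranked list: a permutation of `genes` with mixed-sign scores.
random_ranked <- function(genes, seed, id = "rl") {
  set.seed(seed)
  n <- length(genes)
  ranked_list(sample(genes), seq(n / 2, by = -1, length.out = n),
              metadata = list(dataset_id = id))
}
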