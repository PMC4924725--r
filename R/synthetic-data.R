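#' Simulation configuration for multi-platform two-class studies
#'
#' Describes the synthetic world the generator emulates: several microarray
#' platforms with overlapping but unequal gene universes, a planted gene set
#' overexpressed in the favorable-outcome (FO) class on every platform,
#' additive per-platform offsets, a subset of FO samples contaminated with
#' elevated lymph-node classifier genes, and exponential class-dependent
#' survival with uniform right-censoring.
#'
#' @param n_platforms Number of platforms (cohorts).
#' @param genes_per_platform Genes on each platform.
#' @param shared_gene_fraction Fraction of each platform's universe shared by
#'   all platforms (a common core; the remainder is platform-private).
#' @param n_signature_genes Planted FO-overexpressed genes, all in the core.
#' @param effect_size Standardized mean shift of signature genes in FO
#'   samples, in units of `noise_sd`.
#' @param noise_sd Gaussian noise standard deviation (log-intensity units).
#' @param n_fo,n_po Samples per class per platform.
#' @param n_contaminated_fo FO samples per platform receiving the lymph-node
#'   contamination boost (the first `n_contaminated_fo` FO samples).
#' @param contamination_boost Additive shift (expression units) applied to
#'   every lymph classifier gene in contaminated samples. The default (6 SD)
#'   makes contaminated samples exceed the PO range on essentially all six
#'   classifiers, as the filter design assumes.
#' @param n_lymph_classifiers Number of lymph-node classifier genes (6, as in
#'   the filtering rule).
#' @param survival_scale_fo,survival_scale_po Mean survival (months) of the
#'   exponential survival time per class.
#' @param censor_fraction Fraction of samples right-censored at a uniform
#'   fraction of their event time.
#' @param seed Integer seed; every generator output is reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_platforms = 3,
                       genes_per_platform = 5000,
                       shared_gene_fraction = 0.5,
                       n_signature_genes = 200,
                       effect_size = 2,
                       noise_sd = 1,
                       n_fo = 10, n_po = 10,
                       n_contaminated_fo = 0,
                       contamination_boost = 6,
                       n_lymph_classifiers = 6,
                       survival_scale_fo = 60,
                       survival_scale_po = 12,
                       censor_fraction = 0.2,
                       seed = 1L) {
  cfg <- list(n_platforms = as.integer(n_platforms),
              genes_per_platform = as.integer(genes_per_platform),
              shared_gene_fraction = shared_gene_fraction,
              n_signature_genes = as.integer(n_signature_genes),
              effect_size = effect_size, noise_sd = noise_sd,
              n_fo = as.integer(n_fo), n_po = as.integer(n_po),
              n_contaminated_fo = as.integer(n_contaminated_fo),
              contamination_boost = contamination_boost,
              n_lymph_classifiers = as.integer(n_lymph_classifiers),
              survival_scale_fo = survival_scale_fo,
              survival_scale_po = survival_scale_po,
              censor_fraction = censor_fraction,
              seed = as.integer(seed))
  counts <- c("n_platforms", "genes_per_platform", "n_signature_genes",
              "n_fo", "n_po", "n_contaminated_fo", "n_lymph_classifiers")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0) stop("`", nm, "` must be a count >= 0")
  for (nm in c("shared_gene_fraction", "censor_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("`", nm, "` must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be positive")
  if (cfg$n_contaminated_fo > cfg$n_fo)
    stop("`n_contaminated_fo` cannot exceed `n_fo`")
  n_core <- round(cfg$shared_gene_fraction * cfg$genes_per_platform)
  if (cfg$n_signature_genes + cfg$n_lymph_classifiers > n_core)
    stop("signature plus lymph classifiers exceed the shared gene core (",
         n_core, " genes)")
  structure(cfg, class = "sim_config")
}

# run expr with a fixed RNG state, restoring the caller's stream afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

# platform universes: a core shared by all platforms plus private remainders
.study_universes <- function(config) {
  n_core <- round(config$shared_gene_fraction * config$genes_per_platform)
  n_priv <- config$genes_per_platform - n_core
  core <- sprintf("GC%05d", seq_len(n_core))
  lapply(seq_len(config$n_platforms), function(p) {
    priv <- if (n_priv > 0) sprintf("GP%d_%05d", p, seq_len(n_priv)) else character(0)
    c(core, priv)
  })
}

#' Generate one synthetic platform dataset
#'
#' Baseline expression is i.i.d. Gaussian(0, `noise_sd`) plus an additive
#' per-platform offset (2 units per platform index, a nuisance the rank-based
#' downstream analysis must ignore). Signature genes gain
#' `effect_size * noise_sd` in FO samples only; the first `n_contaminated_fo`
#' FO samples gain `contamination_boost` on every lymph classifier gene.
#' Survival times are exponential with the class-specific mean and a random
#' `censor_fraction` of samples is right-censored uniformly on (0, T).
#'
#' @param config A [sim_config()].
#' @param platform_index Platform number in `1..n_platforms`.
#' @param signature_genes Genes to plant as FO-overexpressed (must be in the
#'   platform universe).
#' @param lymph_genes Lymph-node classifier genes (must be in the universe).
#' @param universe Optional explicit gene universe; defaults to the platform's
#'   universe from the study layout.
#' @return An [expr_dataset()] with one probe per gene (probe id
#'   `p_<gene>`), FO samples first, and survival annotations.
#' @export
generate_dataset <- function(config, platform_index, signature_genes,
                             lymph_genes = character(0), universe = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (platform_index < 1 || platform_index > config$n_platforms)
    stop("`platform_index` out of range")
  if (is.null(universe)) universe <- .study_universes(config)[[platform_index]]
  missing <- setdiff(c(signature_genes, lymph_genes), universe)
  if (length(missing))
    stop("planted genes absent from the platform universe: ",
         paste(utils::head(missing, 5), collapse = ", "))

  n_genes <- length(universe)
  n_fo <- config$n_fo; n_po <- config$n_po
  n <- n_fo + n_po
  pid <- sprintf("platform%d", platform_index)
  samples <- c(sprintf("%s_FO%02d", pid, seq_len(n_fo)),
               sprintf("%s_PO%02d", pid, seq_len(n_po)))
  classes <- c(rep("FO", n_fo), rep("PO", n_po))

  .with_seed(config$seed + 7919L * platform_index, {
    values <- matrix(stats::rnorm(n_genes * n, sd = config$noise_sd),
                     nrow = n_genes, ncol = n,
                     dimnames = list(paste0("p_", universe), samples))
    values <- values + 2 * (platform_index - 1)  # platform offset
    fo_cols <- seq_len(n_fo)
    if (length(signature_genes) && n_fo > 0)
      values[paste0("p_", signature_genes), fo_cols] <-
        values[paste0("p_", signature_genes), fo_cols, drop = FALSE] +
        config$effect_size * config$noise_sd
    if (config$n_contaminated_fo > 0 && length(lymph_genes))
      values[paste0("p_", lymph_genes), seq_len(config$n_contaminated_fo)] <-
        values[paste0("p_", lymph_genes), seq_len(config$n_contaminated_fo),
               drop = FALSE] + config$contamination_boost

    scale <- ifelse(classes == "FO", config$survival_scale_fo,
                    config$survival_scale_po)
    time <- stats::rexp(n, rate = 1 / scale)
    event <- rep(1L, n)
    n_cens <- round(config$censor_fraction * n)
    if (n_cens > 0) {
      cens <- sample(n, n_cens)
      event[cens] <- 0L
      time[cens] <- time[cens] * stats::runif(n_cens)
    }
    time <- pmax(time, 1e-6)

    p2g <- stats::setNames(universe, paste0("p_", universe))
    expr_dataset(values, p2g, classes,
                 survival = data.frame(sample = samples, time = time,
                                       event = event),
                 platform_id = pid)
  })
}

#' Generate a full multi-platform study with planted truth
#'
#' Builds the platform universes (shared core + private genes), draws the
#' planted signature and lymph classifier genes from the core (disjoint
#' sets), simulates every platform with [generate_dataset()], and returns the
#' ground truth needed for recovery testing.
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (list of [expr_dataset()]), and `truth`: a
#'   list with `signature_genes`, `lymph_genes`, and `contaminated_samples`
#'   (character vector of contaminated FO sample ids across platforms).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universes <- .study_universes(config)
  core <- Reduce(intersect, universes)
  if (config$n_signature_genes + config$n_lymph_classifiers > length(core))
    stop("requested signature larger than the joint universe intersection")
  picks <- .with_seed(config$seed, {
    idx <- sample(length(core),
                  config$n_signature_genes + config$n_lymph_classifiers)
    core[idx]
  })
  signature_genes <- picks[seq_len(config$n_signature_genes)]
  lymph_genes <- if (config$n_lymph_classifiers > 0)
    picks[config$n_signature_genes + seq_len(config$n_lymph_classifiers)]
  else character(0)

  datasets <- lapply(seq_len(config$n_platforms), function(p)
    generate_dataset(config, p, signature_genes, lymph_genes,
                     universe = universes[[p]]))
  contaminated <- unlist(lapply(datasets, function(ds) {
    fo <- names(ds$sample_classes)[ds$sample_classes == "FO"]
    utils::head(fo, config$n_contaminated_fo)
  }), use.names = FALSE)

  list(datasets = datasets,
       truth = list(signature_genes = signature_genes,
                    lymph_genes = lymph_genes,
                    contaminated_samples = contaminated))
}

#' Synthetic cell-type enrichment score table
#'
#' Dense probe-by-cell-type score fixture standing in for a curated
#' enrichment-score database. Planted (probe, cell type) cells score above
#' `high_score`; everything else scores strictly below it.
#'
#' @param cell_types Character vector of cell/tissue type labels (non-empty).
#' @param probes Character vector of probe (or gene symbol) row ids.
#' @param planted_assignments Named character vector: names are probes, values
#'   the cell type each probe is planted for. May be empty.
#' @param high_score Score threshold separating planted from background cells.
#' @param seed Integer seed.
#' @param probe_to_gene Optional named map probe -> gene symbol; defaults to
#'   the identity (rows already carry gene symbols).
#' @return An [enrichment_table()].
#' @export
generate_enrichment_table <- function(cell_types, probes, planted_assignments =
                                        stats::setNames(character(0), character(0)),
                                      high_score = 700, seed = 1L,
                                      probe_to_gene = NULL) {
  if (!length(cell_types)) stop("`cell_types` must be non-empty")
  if (length(planted_assignments)) {
    if (!all(names(planted_assignments) %in% probes))
      stop("planted probes absent from `probes`")
    if (!all(planted_assignments %in% cell_types))
      stop("planted cell types absent from `cell_types`")
  }
  .with_seed(seed, {
    scores <- matrix(stats::runif(length(probes) * length(cell_types),
                                  min = 0, max = 0.95 * high_score),
                     nrow = length(probes),
                     dimnames = list(probes, cell_types))
    if (length(planted_assignments))
      scores[cbind(names(planted_assignments),
                   unname(planted_assignments))] <-
        high_score + stats::runif(length(planted_assignments), 50, 300)
    enrichment_table(scores, probe_to_gene = probe_to_gene)
  })
}
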