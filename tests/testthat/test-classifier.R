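# tiny separable cohort: first `n_sig` genes shifted up in FO
.cohort <- function(n_genes = 20, n_fo = 6, n_po = 6, effect = 5, n_sig = 10,
                    seed = 1, survival = FALSE) {
  ds <- make_two_class(n_genes, n_fo, n_po, effect = effect, n_shift = n_sig,
                       seed = seed, platform_id = "cohort")
  if (survival) {
    set.seed(seed + 500)
    n <- n_fo + n_po
    surv <- data.frame(sample = colnames(ds$values),
                       time = rexp(n, rate = ifelse(ds$sample_classes == "FO",
                                                    1 / 60, 1 / 12)),
                       event = rbinom(n, 1, 0.8))
    if (sum(surv$event) == 0) surv$event[1] <- 1
    ds <- make_ds(ds$values, ds$sample_classes, genes = dataset_genes(ds),
                  survival = surv, platform_id = "cohort")
  }
  ds
}

test_that("gene_vote does the stated arithmetic", {
  st <- list(weight = 2, boundary = 1)   # means 2/0, sds 0.5 each
  expect_equal(gene_vote(st, 1.5), 1.0)
  expect_equal(gene_vote(st, 1), 0)      # sample at the midpoint votes 0
})

test_that("wgv_statistics computes weights, boundaries and flags", {
  values <- rbind(g1 = c(2, 2, 2, 0, 0, 0),     # sd 0 both classes
                  g2 = c(1, 2, 3, 0, 1, 2))
  colnames(values) <- paste0("s", 1:6)
  ds <- make_ds(values, c(rep("FO", 3), rep("PO", 3)), genes = rownames(values))
  expect_message(st <- wgv_statistics(ds, c("g1", "g2")), "zero class-stdev")
  expect_identical(st$gene, "g2")
  expect_equal(st$weight, 1 / 2)                 # (2-1)/(1+1)
  expect_equal(st$boundary, 1.5)                 # midpoint (2+1)/2
  st_strict <- suppressMessages(
    wgv_statistics(ds, c("g1", "g2"), strict_formula = TRUE))
  expect_equal(st_strict$boundary, 0.5)          # half-difference (2-1)/2
  expect_message(wgv_statistics(ds, c("g2", "nope")), "absent")
  # all genes unusable -> reject
  expect_error(suppressMessages(wgv_statistics(ds, "g1")), "no usable")
})

test_that("label swap negates every vote sum and flips the evaluation", {
  ds <- .cohort(seed = 3)
  sig <- paste0("g", 1:10)
  swapped <- make_ds(ds$values,
                     ifelse(ds$sample_classes == "FO", "PO", "FO"),
                     genes = dataset_genes(ds), platform_id = "swap")
  for (s in colnames(ds$values)[c(1, 7)]) {
    a <- classify_sample_loo(ds, sig, s)
    b <- classify_sample_loo(swapped, sig, s)
    expect_equal(a$vote_sum, -b$vote_sum, tolerance = 1e-12)
  }
  ev <- evaluate_cohort(ds, sig)
  ev_sw <- evaluate_cohort(swapped, sig)
  expect_identical(c(ev$confusion$tp, ev$confusion$fn),
                   c(ev_sw$confusion$tn, ev_sw$confusion$fp))
  # swapping the positive class at fixed scores maps AUC to 1 - AUC; the
  # combined swap (scores negated too) leaves it invariant
  expect_equal(auc_score(ev$votes$vote_sum,
                         ifelse(ev$votes$true == "FO", "PO", "FO")),
               1 - ev$auc, tolerance = 1e-12)
  expect_equal(ev_sw$auc, ev$auc, tolerance = 1e-12)
})

test_that("LOO excludes the held-out sample from its own statistics", {
  ds <- .cohort(seed = 4)
  sig <- paste0("g", 1:10)
  target <- "s1"
  st_before <- wgv_statistics(ds, sig, exclude_sample = target)
  # corrupt the held-out column: the statistics used to score it cannot move
  ds2 <- ds
  ds2$values[, target] <- ds2$values[, target] + 1000
  st_after <- wgv_statistics(ds2, sig, exclude_sample = target)
  expect_equal(st_before, st_after, tolerance = 1e-12)
  # ...and the prediction equals scoring the twin with the sample removed
  dup <- ds$values
  dup[, "s2"] <- dup[, "s1"]            # s2 is now a twin of s1
  ds_twin <- make_ds(dup, ds$sample_classes, genes = dataset_genes(ds))
  loo <- classify_sample_loo(ds_twin, sig, "s1")
  without <- subset_samples(ds_twin, setdiff(colnames(dup), "s1"))
  st <- wgv_statistics(without, sig)
  s_twin <- without$values[match(st$gene, dataset_genes(without)), "s2"]
  expect_equal(loo$vote_sum, sum(gene_vote(st, s_twin)), tolerance = 1e-12)
})

test_that("holdout that empties a class is rejected", {
  values <- matrix(rnorm(20), 4, 5,
                   dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  ds <- make_ds(values, c("FO", "FO", "PO", "PO", "PO"))
  expect_error(classify_sample_loo(ds, paste0("g", 1:4), "s1"),
               ">= 2 samples per class")
  expect_error(classify_sample_loo(ds, paste0("g", 1:4), "nope"), "unknown")
})

test_that("a strongly separable cohort is classified perfectly", {
  ds <- .cohort(effect = 5, seed = 5)
  ev <- evaluate_cohort(ds, paste0("g", 1:10))
  expect_identical(ev$n_correct, ev$n_total)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$confusion$accuracy, 1.0)
})

test_that("confusion identities hold over random matrices", {
  set.seed(10)
  for (rep in 1:25) {
    cts <- as.list(rpois(4, 8) + 1)
    names(cts) <- c("tp", "fp", "tn", "fn")
    m <- do.call(confusion_metrics, cts)
    expect_equal(m$ppv, cts$tp / (cts$tp + cts$fp))
    expect_equal(m$npv, cts$tn / (cts$tn + cts$fn))
    expect_equal(m$sensitivity, cts$tp / (cts$tp + cts$fn))
    expect_equal(m$specificity, cts$tn / (cts$tn + cts$fp))
    expect_true(all(unlist(m[c("ppv", "npv", "sensitivity", "specificity",
                               "accuracy")]) >= 0))
  }
})

test_that("AUC equals the brute-force pairwise fraction, ties at half", {
  brute <- function(scores, pos) {
    pairs <- expand.grid(p = which(pos), n = which(!pos))
    mean((scores[pairs$p] > scores[pairs$n]) +
           0.5 * (scores[pairs$p] == scores[pairs$n]))
  }
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), 1)          # rounding forces some ties
    labels <- sample(c("FO", "PO"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), brute(scores, labels == "FO"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(auc_score(1:3, c("FO", "FO", "FO"))))
})

test_that("log-rank matches a direct observed-minus-expected oracle", {
  # oracle: textbook O-E / V accumulation over distinct event times
  logrank_oracle <- function(time, event, grp1) {
    times <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in times) {
      at1 <- sum(time >= t & grp1); at2 <- sum(time >= t & !grp1)
      n <- at1 + at2
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & grp1)
      O <- O + d1
      E <- E + d * at1 / n
      if (n > 1) V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  }
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  grp <- rep(c("a", "b"), each = 3)
  res <- logrank_test(time, event, grp)
  expect_equal(res$chi_square, logrank_oracle(time, event, grp == "a"),
               tolerance = 1e-10)
  # randomized cases with censoring
  set.seed(12)
  for (rep in 1:10) {
    n <- 16
    time <- round(rexp(n, 1 / 20), 1) + 0.1
    event <- rbinom(n, 1, 0.8)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(event) == 0) next
    expect_equal(logrank_test(time, event, grp)$chi_square,
                 logrank_oracle(time, event, grp == "a"), tolerance = 1e-8)
  }
  # identical groups: chi-square 0, p 1
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "no events")
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 groups")
})

test_that("evaluate_cohort wires survival through to the log-rank split", {
  ds <- .cohort(effect = 5, seed = 6, survival = TRUE)
  ev <- evaluate_cohort(ds, paste0("g", 1:10))
  expect_false(is.null(ev$logrank))
  expect_true(ev$logrank$p >= 0 && ev$logrank$p <= 1)
  expect_s3_class(ev$km, "survfit")
  # without survival annotations the split is absent
  ev0 <- evaluate_cohort(.cohort(effect = 5, seed = 6), paste0("g", 1:10))
  expect_null(ev0$logrank)
})
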