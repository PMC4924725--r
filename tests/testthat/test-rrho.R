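test_that("hypergeom_tail handles the closed-form corner cases", {
  expect_identical(hypergeom_tail(0, 3, 4, 10), 1)            # certain event
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)                              # exact enumeration
  expect_equal(hypergeom_tail(4, 10, 4, 10), 1)               # i = N forces k = j
  expect_error(hypergeom_tail(3, 2, 2, 10), "feasible")
  expect_error(hypergeom_tail(0, 11, 2, 10), "0..N")
  # symmetry in (i, j)
  expect_equal(hypergeom_tail(3, 7, 5, 20), hypergeom_tail(3, 5, 7, 20),
               tolerance = 1e-14)
})

test_that("-log10 tail survives large-N underflow", {
  # N = 20000, perfect overlap of the top half: p ~ 1/C(20000,10000), far
  # below double precision, must come back as a finite large -log10
  v <- hypergeom_tail(10000, 10000, 10000, 20000, log10p = TRUE)
  expect_true(is.finite(v))
  expect_equal(v, lchoose(20000, 10000) / log(10), tolerance = 1e-9)
})

test_that("monotonicity: -log10 p strictly increases with k", {
  ks <- 2:10
  v <- hypergeom_tail(ks, 10, 10, 40, log10p = TRUE)
  expect_true(all(diff(v) > 0))
})

test_that("identical lists give the diagonal identity and closed-form max", {
  rl <- make_ranked(100)                      # all scores positive
  m <- rrho_map(rl, rl, step = 1)
  expect_identical(unname(diag(m$overlap_counts)), 1:100)
  q <- find_quadrant_max(m, "FO-FO")
  expect_identical(c(q$i_star, q$j_star), c(50L, 50L))
  expect_equal(q$neglog_p_max, lchoose(100, 50) / log(10), tolerance = 1e-6)
  expect_identical(q$k, 50L)
})

test_that("map respects grid construction and count bounds", {
  genes <- sprintf("g%03d", 1:103)
  r1 <- random_ranked(genes, 1); r2 <- random_ranked(genes, 2)
  m <- rrho_map(r1, r2, step = 10)
  expect_identical(m$thresholds_1, c(seq.int(10L, 100L, 10L), 103L))  # includes N
  expect_false(0 %in% m$thresholds_1)
  expect_true(all(m$neglog_p >= 0))
  ii <- matrix(m$thresholds_1, 11, 11)
  jj <- t(ii)
  expect_true(all(m$overlap_counts >= pmax(0, ii + jj - 103)))
  expect_true(all(m$overlap_counts <= pmin(ii, jj)))
  expect_identical(m$overlap_counts[11, 11], 103L)
})

test_that("counts match brute-force intersection on random lists", {
  genes <- sprintf("g%02d", 1:60)
  r1 <- random_ranked(genes, 10); r2 <- random_ranked(genes, 11)
  m <- rrho_map(r1, r2, step = 7)
  for (a in seq_along(m$thresholds_1))
    for (b in seq_along(m$thresholds_2)) {
      i <- m$thresholds_1[a]; j <- m$thresholds_2[b]
      expect_identical(m$overlap_counts[a, b],
                       length(intersect(head(r1$genes, i), head(r2$genes, j))))
    }
})

test_that("transpose symmetry holds for counts and values", {
  genes <- sprintf("g%02d", 1:40)
  r1 <- random_ranked(genes, 3); r2 <- random_ranked(genes, 4)
  m12 <- rrho_map(r1, r2, step = 3)
  m21 <- rrho_map(r2, r1, step = 3)
  expect_identical(m12$overlap_counts, t(m21$overlap_counts))
  expect_equal(m12$neglog_p, t(m21$neglog_p), tolerance = 1e-12)
})

test_that("universe mismatch is rejected with the offending genes", {
  r1 <- make_ranked(5, genes = c("a", "b", "c", "d", "e"))
  r2 <- make_ranked(5, genes = c("a", "b", "c", "d", "z"))
  expect_error(rrho_map(r1, r2), "z")
})

test_that("map is invariant to a platform offset in one dataset", {
  ds1 <- make_two_class(n_genes = 60, effect = 2, n_shift = 10, seed = 6,
                        platform_id = "p1")
  ds2 <- make_two_class(n_genes = 60, effect = 2, n_shift = 10, seed = 7,
                        platform_id = "p2")
  ds2_off <- make_ds(ds2$values + 11, ds2$sample_classes,
                     genes = dataset_genes(ds2))
  m <- rrho_map(rank_genes(ds1), rank_genes(ds2), step = 5)
  m_off <- rrho_map(rank_genes(ds1), rank_genes(ds2_off), step = 5)
  expect_identical(m$overlap_counts, m_off$overlap_counts)
  expect_equal(m$neglog_p, m_off$neglog_p, tolerance = 1e-9)
})

test_that("find_quadrant_max scans only its quadrant and breaks ties low", {
  genes <- sprintf("g%03d", 1:100)
  r1 <- random_ranked(genes, 20); r2 <- random_ranked(genes, 21)
  m <- rrho_map(r1, r2, step = 10)
  # plant a unique max inside the FO-FO region (boundaries are 50/50)
  m$neglog_p["30", "40"] <- 999
  q <- find_quadrant_max(m, "FO-FO")
  expect_identical(c(q$i_star, q$j_star), c(30L, 40L))
  expect_identical(q$neglog_p_max, 999)
  # a larger cell outside the quadrant must be ignored
  m$neglog_p["90", "90"] <- 1e6
  expect_identical(find_quadrant_max(m, "FO-FO")$i_star, 30L)
  # tied maxima at (10,20) and (20,10): smallest i wins, then smallest j
  m$neglog_p["30", "40"] <- 0
  m$neglog_p["10", "20"] <- 999
  m$neglog_p["20", "10"] <- 999
  q2 <- find_quadrant_max(m, "FO-FO")
  expect_identical(c(q2$i_star, q2$j_star), c(10L, 20L))
})

test_that("empty quadrants are rejected with a diagnostic", {
  rl <- make_ranked(50, scores = seq(50, 1))  # every score positive
  m <- rrho_map(rl, rl, step = 5)
  expect_error(find_quadrant_max(m, "PO-PO"), "empty")
  expect_error(find_quadrant_max(m, "bogus"), "unknown quadrant")
})

test_that("label-swap duality maps FO-FO onto PO-PO exactly", {
  ds1 <- make_two_class(n_genes = 80, effect = 2, n_shift = 15, seed = 8)
  ds2 <- make_two_class(n_genes = 80, effect = 2, n_shift = 15, seed = 9)
  swap <- function(ds) make_ds(ds$values,
                               ifelse(ds$sample_classes == "FO", "PO", "FO"),
                               genes = dataset_genes(ds))
  m <- rrho_map(rank_genes(ds1), rank_genes(ds2), step = 5)
  m_sw <- rrho_map(rank_genes(swap(ds1)), rank_genes(swap(ds2)), step = 5)
  q_fo <- find_quadrant_max(m, "FO-FO")
  q_po <- find_quadrant_max(m_sw, "PO-PO")
  expect_identical(c(q_fo$i_star, q_fo$j_star), c(q_po$i_star, q_po$j_star))
  expect_equal(q_fo$neglog_p_max, q_po$neglog_p_max, tolerance = 1e-9)
  g_fo <- overlap_genes(rank_genes(ds1), rank_genes(ds2),
                        q_fo$i_star, q_fo$j_star, "FO-FO")
  g_po <- overlap_genes(rank_genes(swap(ds1)), rank_genes(swap(ds2)),
                        q_po$i_star, q_po$j_star, "PO-PO")
  expect_identical(g_fo, g_po)
})

test_that("overlap_genes extracts prefix intersections deterministically", {
  r1 <- make_ranked(4, scores = c(2, 1, -1, -2), genes = c("a", "b", "c", "d"))
  r2 <- make_ranked(4, scores = c(2, 1, -1, -2), genes = c("b", "a", "d", "c"))
  expect_identical(overlap_genes(r1, r2, 2, 2), c("a", "b"))
  expect_setequal(overlap_genes(r1, r2, 4, 4), c("a", "b", "c", "d"))
  # PO-PO works on the reversed (most PO-enriched first) prefixes
  expect_identical(overlap_genes(r1, r2, 2, 2, "PO-PO"), c("c", "d"))
  expect_error(overlap_genes(r1, r2, 9, 2), "out of bounds")
  # invariant: |genes| equals the map's overlap count at the max
  genes <- sprintf("g%03d", 1:90)
  ra <- random_ranked(genes, 30); rb <- random_ranked(genes, 31)
  m <- rrho_map(ra, rb, step = 9)
  q <- find_quadrant_max(m, "FO-FO")
  expect_identical(length(overlap_genes(ra, rb, q$i_star, q$j_star)),
                   as.integer(q$k))
})
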