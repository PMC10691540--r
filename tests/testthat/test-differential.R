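# Chi-square and Dirichlet-multinomial tests, p-value combination, WARM,
# MPRO, final-signal rules, per-cell WARM and the hierarchical walk.

test_that("pooled chi-square matches the hand-computed Pearson statistic", {
  # groups with pooled table [[30,70],[70,30]]: statistic 32, df 1
  X <- rbind(matrix(rep(c(30, 70) / 10, 10), ncol = 2, byrow = TRUE),
             matrix(rep(c(70, 30) / 10, 10), ncol = 2, byrow = TRUE))
  grp <- rep(c("A", "B"), each = 10)
  ct <- pa_chisq_test(X, grp)
  expect_equal(ct$stat, 32, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  expect_equal(ct$p, pchisq(32, 1, lower.tail = FALSE))
})

test_that("homogeneous proportions give p ~ 1 and degenerate tables are flagged", {
  X <- matrix(rep(c(500, 500), 40), ncol = 2, byrow = TRUE)
  ct <- pa_chisq_test(X, rep(c("A", "B"), 20))
  expect_lt(ct$stat, 1e-9)
  expect_equal(ct$p, 1, tolerance = 1e-9)
  # one group all zeros -> degenerate after dropping
  X2 <- rbind(matrix(5, 10, 2), matrix(0, 10, 2))
  ct2 <- pa_chisq_test(X2, rep(c("A", "B"), each = 10))
  expect_equal(ct2$p, 1)
  expect_true(ct2$flagged)
})

test_that("DM maximum likelihood recovers planted alpha", {
  set.seed(11)
  X <- rdm_counts(2000, c(2, 5), umi_mean = 20)
  f <- dm_fit(X)
  expect_true(f$converged)
  expect_true(all(abs(f$alpha - c(2, 5)) / c(2, 5) < 0.15))
})

test_that("DM degenerate fits behave as declared", {
  # J = 1: trivial fit, log-likelihood 0
  f1 <- dm_fit(matrix(5, 20, 1))
  expect_equal(f1$loglik, 0)
  # identical proportions, large n: alpha grows to the cap, boundary flag
  X <- matrix(rep(c(50, 50), 50), ncol = 2, byrow = TRUE)
  f2 <- dm_fit(X, max_iter = 2000)
  expect_true(f2$boundary)
  expect_true(max(f2$alpha) > 1e3)
  # all counts on one peak: capped boundary fit, no error
  X3 <- cbind(rep(10, 30), rep(0, 30))
  f3 <- dm_fit(X3)
  expect_true(f3$boundary)
})

test_that("identical data in both groups gives a null LRT", {
  set.seed(12)
  X <- rdm_counts(100, c(3, 3))
  XX <- rbind(X, X)
  lrt <- dm_lrt(XX, rep(c("A", "B"), each = 100))
  expect_lt(lrt$stat, 0.02)
  expect_gt(lrt$p, 0.99)
  expect_equal(lrt$df, 2)
})

test_that("DM LRT has power against opposite usage shifts", {
  set.seed(13)
  X <- rbind(rdm_counts(300, c(2, 5)), rdm_counts(300, c(5, 2)))
  lrt <- dm_lrt(X, rep(c("A", "B"), each = 300))
  expect_lt(lrt$p, 1e-3)
})

test_that("max-p combination and BH match hand-computed oracles", {
  co <- combine_and_adjust(c(0.01, 0.001, 0.02, 0.8), c(0.20, 0.0005, 0.01, 0.5))
  expect_equal(co$p_combined, c(0.20, 0.001, 0.02, 0.8))
  bh <- combine_and_adjust(c(0.001, 0.01, 0.02, 0.8), c(0, 0, 0, 0))
  expect_equal(bh$p_adj, c(0.004, 0.02, 0.02 * 4 / 3, 0.8))
  # step-up oracle on random vectors
  set.seed(14)
  for (rep in 1:5) {
    p <- runif(200)^2
    o <- order(p)
    stepup <- numeric(200)
    stepup[o] <- rev(cummin(rev(p[o] * 200 / seq_len(200))))
    stepup <- pmin(stepup, 1)
    expect_equal(combine_and_adjust(p, rep(0, 200))$p_adj, stepup)
  }
})

test_that("WARM matches hand-computed examples and stays in [0, 1]", {
  expect_equal(compute_warm(c(0, 100), c(30, 70)), 0.7)
  expect_equal(compute_warm(c(0, 50, 200), c(10, 10, 20)), 0.5625)
  expect_equal(compute_warm(c(0, 50, 200), c(10, 0, 0)), 0)
  expect_true(is.na(compute_warm(c(0, 100), c(0, 0))))
  # rank spacing for peaks from different UTRs
  expect_equal(compute_warm(c(0, 50, 200), c(10, 10, 20), same_utr = FALSE),
               (0 * 10 + 0.5 * 10 + 1 * 20) / 40)
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    pos <- sort(sample(0:2000, n))
    cnt <- rpois(n, 20) + 1
    w <- compute_warm(pos, cnt, sample(c(TRUE, FALSE), 1))
    expect_true(w >= 0 && w <= 1)
  }
})

test_that("MPRO matches the pair-enumeration oracle and sign convention", {
  m2 <- compute_mpro(c(20, 80), c(70, 30))
  expect_equal(as.numeric(m2), 1.0)          # base more distal -> positive
  expect_equal(as.numeric(compute_mpro(c(50, 50), c(50, 50))), 0)
  m3 <- compute_mpro(c(50, 30, 20), c(20, 30, 50))
  expect_equal(as.numeric(m3), -0.6)
  expect_equal(attr(m3, "pair"), c(1L, 3L))
  # J = 2: MPRO equals twice the change in distal proportion
  set.seed(16)
  for (rep in 1:20) {
    b <- rpois(2, 50) + 1; a <- rpois(2, 50) + 1
    d2 <- b[2] / sum(b) - a[2] / sum(a)
    expect_equal(as.numeric(compute_mpro(b, a)), 2 * d2, tolerance = 1e-12)
  }
})

test_that("swapping base and alt flips MPRO and negates the WARM difference", {
  set.seed(17)
  for (rep in 1:20) {
    J <- sample(2:5, 1)
    b <- rpois(J, 30) + 1; a <- rpois(J, 30) + 1
    pos <- sort(sample(0:2000, J))
    expect_equal(as.numeric(compute_mpro(b, a)), -as.numeric(compute_mpro(a, b)),
                 tolerance = 1e-12)
    dw <- compute_warm(pos, b) - compute_warm(pos, a)
    expect_equal(dw, -(compute_warm(pos, a) - compute_warm(pos, b)),
                 tolerance = 1e-12)
  }
})

test_that("final-signal rules apply the declared thresholds strictly", {
  expect_true(call_signals(0.01, TRUE, 0.5))
  expect_false(call_signals(0.01, TRUE, 0.2))    # |MPRO| must exceed 0.2
  expect_true(call_signals(0.05, TRUE, 0.3))     # adjusted p is inclusive
  expect_false(call_signals(0.051, TRUE, 0.3))
  expect_false(call_signals(0.01, FALSE, 0.5))   # expression rule
})

test_that("expression rule: a group whose best peak is under 5% of cells blocks the call", {
  set.seed(18)
  # strong shift but group B expresses the gene in only 3% of cells
  Xa <- rdm_counts(100, c(8, 2))
  Xb <- rdm_counts(100, c(2, 8))
  zero <- sample(100, 97)
  Xb[zero, ] <- 0
  cnt <- counts_from_matrix(rbind(Xa, Xb))
  grp <- setNames(rep(c("A", "B"), each = 100), cnt$barcodes)
  res <- test_pa(cnt, grp, base_group = "A")
  expect_false(res$significant)
  expect_lt(res[["expr_frac_B"]], 0.05)
})

test_that("per-cell WARM averages per the chosen weighting", {
  peaks <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                      peak_id = c("g1:P1", "g1:P2", "g2:P1", "g2:P2"),
                      chrom = "chr1", strand = "+",
                      mu = c(1000, 1400, 5000, 5400), sigma = 30, weight = .5,
                      stringsAsFactors = FALSE)
  m <- Matrix::Matrix(matrix(c(8, 2, 6, 24,
                               0, 0, 5, 5), ncol = 2), sparse = TRUE)
  dimnames(m) <- list(peaks$peak_id, c("c1", "c2"))
  cnt <- structure(list(matrix = methods::as(m, "CsparseMatrix"), peaks = peaks,
                        barcodes = c("c1", "c2"), qc = list()),
                   class = "apa_counts")
  # cell 1: g1 warm 0.2 (10 counts), g2 warm 0.8 (30 counts)
  expect_equal(unname(compute_cell_warm(cnt, "equal")["c1"]), 0.5)
  expect_equal(unname(compute_cell_warm(cnt, "expression")["c1"]), 0.65)
  # cell 2 expresses only g2 (warm 0.5)
  expect_equal(unname(compute_cell_warm(cnt, "equal")["c2"]), 0.5)
})

test_that("hierarchical walk enumerates nodes with non-empty complements", {
  fx <- ref_pipeline()
  cells <- fx$sim$barcodes
  grp <- fx$sim$groups$group
  # two-level tree: root -> {A, B}; A -> {A1, A2}, B -> {B1} (B1's
  # complement in B is empty -> skipped)
  tax <- data.frame(cell = cells,
                    level1 = ifelse(grp == "g1", "A", "B"),
                    level2 = ifelse(grp == "g1",
                                    rep(c("A1", "A2"), length.out = length(cells)),
                                    "B1"),
                    stringsAsFactors = FALSE)
  h <- hierarchical_test_pa(fx$counts, tax)
  expect_setequal(h$comparisons$node, c("root/A", "root/B", "A/A1", "A/A2"))
  expect_true("B/B1" %in% h$skipped)
  # tree-walk oracle for the comparison count
  n_expected <- 0
  for (node in c("A", "B")) if (sum(tax$level1 != node) > 0) n_expected <- n_expected + 1
  for (node in c("A1", "A2")) n_expected <- n_expected + 1
  expect_equal(nrow(h$comparisons), n_expected)
  # a flat two-group tree reduces to exactly the A-vs-B comparison set
  tax2 <- data.frame(cell = cells, level1 = ifelse(grp == "g1", "A", "B"))
  h2 <- hierarchical_test_pa(fx$counts, tax2)
  expect_setequal(h2$comparisons$node, c("root/A", "root/B"))
})

test_that("a signal confined to deep siblings is tagged at that node", {
  set.seed(19)
  # 4 leaf types; only C1 vs C2 (siblings under C) differ
  ncell <- 80
  Xc1 <- rdm_counts(ncell, c(8, 2))
  Xc2 <- rdm_counts(ncell, c(2, 8))
  Xd <- rdm_counts(2 * ncell, c(5, 5))
  cnt <- counts_from_matrix(rbind(Xc1, Xc2, Xd))
  cells <- cnt$barcodes
  tax <- data.frame(cell = cells,
                    level1 = rep(c("C", "D"), each = 2 * ncell),
                    level2 = rep(c("C1", "C2", "D1", "D2"), each = ncell))
  h <- hierarchical_test_pa(cnt, tax)
  sig <- h$results[h$results$significant, ]
  expect_true(all(sig$node %in% c("C/C1", "C/C2")))
  expect_gt(nrow(sig), 0)
})
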