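test_that("fixed differences give F_ST = 1 and identical populations <= 0", {
  pop <- rep(c("A", "B"), each = 5)
  fixed <- make_gd(matrix(rep(c(0L, 2L), c(5, 5)), 10, 10, byrow = TRUE), pop)
  expect_equal(fstWeirCockerham(fixed)$fst, 1)
  same <- make_gd(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 2), 6, 10, byrow = TRUE), pop)
  expect_lte(fstWeirCockerham(same)$fst, 0)
})

test_that("monomorphic-only data is an error", {
  gd <- make_gd(matrix(0L, 5, 8), rep(c("A", "B"), each = 4))
  expect_error(fstWeirCockerham(gd), "undefined")
})

test_that("W&C components match the independent step-by-step oracle", {
  set.seed(51)
  pop <- rep(c("A", "B"), each = 6)
  for (rep in 1:5) {
    gt <- matrix(sample(0:2, 20 * 12, replace = TRUE), 20, 12)
    gt[sample(length(gt), 15)] <- NA
    gd <- make_gd(gt, pop)
    expect_equal(fstWeirCockerham(gd)$fst,
                 oracle_wc_fst(gt, pop, c("A", "B")), tolerance = 1e-12)
  }
})

test_that("Nei basic statistics match the independent oracle", {
  set.seed(52)
  pop <- rep(c("A", "B"), each = 6)
  for (rep in 1:5) {
    gt <- matrix(sample(0:2, 20 * 12, replace = TRUE), 20, 12)
    gt[sample(length(gt), 10)] <- NA
    gd <- make_gd(gt, pop)
    res <- neiBasicStats(gd)
    ora <- oracle_nei_stats(gt, pop)
    expect_equal(res@HO, ora$HO, tolerance = 1e-12)
    expect_equal(res@HS, ora$HS, tolerance = 1e-12)
    expect_equal(res@HT, ora$HT, tolerance = 1e-12)
    expect_equal(res@FIS, ora$FIS, tolerance = 1e-12)
    expect_equal(res@FSTNei, ora$FST, tolerance = 1e-12)
  }
})

test_that("Nei F_ST approaches its limits for undifferentiated and fixed data", {
  pop <- rep(c("A", "B"), each = 500)
  # identical allele frequencies, large n: F_ST ~ 0
  g <- rep(c(0L, 1L, 2L, 1L), length.out = 500)
  same <- make_gd(rbind(c(g, g), c(rev(g), rev(g))), pop)
  expect_lt(abs(neiBasicStats(same)@FSTNei), 0.005)
  fixed <- make_gd(matrix(rep(c(0L, 2L), each = 500), 3, 1000, byrow = TRUE), pop)
  expect_gt(neiBasicStats(fixed)@FSTNei, 0.99)
  expect_error(neiBasicStats(make_gd(matrix(1L, 2, 4), rep("A", 4))),
               "two populations")
})

test_that("both estimators are invariant to relabeling and allele swaps", {
  set.seed(53)
  pop <- rep(c("A", "B"), each = 8)
  gt <- matrix(sample(0:2, 30 * 16, replace = TRUE), 30, 16)
  gd <- make_gd(gt, pop)
  wc0 <- fstWeirCockerham(gd)$fst
  nei0 <- neiBasicStats(gd)@FSTNei
  # permute samples within populations
  perm <- c(sample(1:8), sample(9:16))
  gdP <- make_gd(gt[, perm], pop)
  expect_equal(fstWeirCockerham(gdP)$fst, wc0, tolerance = 1e-12)
  expect_equal(neiBasicStats(gdP)@FSTNei, nei0, tolerance = 1e-12)
  # swap allele labels at a subset of loci
  gtS <- gt
  gtS[1:10, ] <- 2L - gtS[1:10, ]
  gdS <- make_gd(gtS, pop)
  expect_equal(fstWeirCockerham(gdS)$fst, wc0, tolerance = 1e-12)
  expect_equal(neiBasicStats(gdS)@FSTNei, nei0, tolerance = 1e-12)
})

test_that("the two estimators are strongly rank-correlated across datasets", {
  set.seed(54)
  wc <- nei <- numeric(30)
  for (i in 1:30) {
    p <- IMParams(2000, 2000, 2000, tDiv = Inf,
                  mPA = 10^runif(1, -4.5, -2.5), mAP = 10^runif(1, -4.5, -2.5),
                  mu = 2e-7)
    gd <- simulateGenotypes(p, c(6, 6), L = 4e4, locusLen = 400)
    wc[i] <- fstWeirCockerham(gd)$fst
    nei[i] <- neiBasicStats(gd)@FSTNei
  }
  expect_gt(cor(wc, nei, method = "spearman"), 0.9)
})

test_that("locus bootstrap yields valid intervals, a floored p and determinism", {
  pop <- rep(c("A", "B"), each = 5)
  fixed <- make_gd(matrix(rep(c(0L, 2L), c(5, 5)), 10, 10, byrow = TRUE), pop)
  set.seed(55)
  r <- bootstrapFst(fixed, B = 200)
  expect_equal(c(r@ciLow, r@ciHigh), c(1, 1))
  expect_equal(r@p, 1 / 201)
  set.seed(56)
  gt <- matrix(sample(0:2, 40 * 10, replace = TRUE), 40, 10)
  gd <- make_gd(gt, pop)
  set.seed(1); a <- bootstrapFst(gd, B = 500)
  set.seed(1); b <- bootstrapFst(gd, B = 500)
  expect_identical(a@fstWC, b@fstWC)
  expect_identical(c(a@ciLow, a@ciHigh, a@p), c(b@ciLow, b@ciHigh, b@p))
  expect_lte(a@ciLow, a@ciHigh)
  expect_error(bootstrapFst(gd, B = 50), "B >= 100")
})

test_that("identical populations rarely reach bootstrap significance", {
  set.seed(57)
  pop <- rep(c("A", "B"), each = 8)
  sig <- 0
  for (i in 1:40) {
    gt <- t(replicate(30, rbinom(16, 2, runif(1, 0.2, 0.8))))
    r <- bootstrapFst(make_gd(gt, pop), B = 200)
    if (r@p <= 0.05) sig <- sig + 1
  }
  expect_lte(sig / 40, 0.1)
})

test_that("Holm adjustment matches the hand-rolled step-down", {
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(c(1, 1)), c(1, 1))
  expect_equal(holmAdjust(0.2), 0.2)
  set.seed(58)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holmAdjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(holmAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("pairwiseFst covers every population pair with adjusted p-values", {
  set.seed(59)
  pop <- rep(c("A", "B", "C"), each = 6)
  gt <- matrix(sample(0:2, 25 * 18, replace = TRUE), 25, 18)
  out <- pairwiseFst(make_gd(gt, pop), B = 100)
  expect_equal(nrow(out), 3L)
  expect_equal(out$pHolm, holmAdjust(out$p))
})
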