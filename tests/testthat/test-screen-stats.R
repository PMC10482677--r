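test_that("mutational index reproduces its defining ratio", {
  expect_equal(mutationalIndex(10, 1000, 5, 2000),
               (10 / 990) / (5 / 1995), tolerance = 1e-12)
  expect_equal(mutationalIndex(10, 1000, 5, 2000), 4.030303,
               tolerance = 1e-6)
  expect_identical(mutationalIndex(7, 500, 7, 500), 1)
  expect_identical(mutationalIndex(0, 100, 9, 100), 0)
  expect_identical(mutationalIndex(5, 100, 0, 100), Inf)
  expect_true(is.nan(mutationalIndex(0, 100, 0, 100)))
  expect_error(mutationalIndex(11, 10, 1, 10), "input error")
})

test_that("MI antisymmetry and monotonicity hold on random count tuples", {
  set.seed(101)
  H <- sample(50:2000, 300, replace = TRUE)
  L <- sample(50:2000, 300, replace = TRUE)
  a <- vapply(H, function(h) sample.int(h, 1L) - 1L, 0L)
  b <- vapply(L, function(l) sample.int(l, 1L) - 1L, 0L)
  mi <- mutationalIndex(a, H, b, L)
  swap <- mutationalIndex(b, L, a, H)
  ok <- a > 0 & b > 0
  expect_equal(swap[ok], 1 / mi[ok], tolerance = 1e-12)
  expect_identical(swap[a > 0 & b == 0], rep(0, sum(a > 0 & b == 0)))
  # strictly increasing in a for fixed b, H, L
  aa <- 0:99
  mis <- mutationalIndex(aa, 100, 10, 200)
  expect_true(all(diff(mis) > 0))
})

test_that("two-sided Fisher P matches enumeration and closed forms", {
  expect_equal(fisherExactP(3, 3, 0, 3), 0.1, tolerance = 1e-12)
  expect_identical(fisherExactP(5, 10, 5, 10), 1)
  set.seed(103)
  for (i in 1:200) {
    H <- sample.int(150, 1L); L <- sample.int(200 - H, 1L)
    a <- sample.int(H + 1L, 1L) - 1L
    b <- sample.int(L + 1L, 1L) - 1L
    p <- fisherExactP(a, H, b, L)
    expect_lte(abs(p - fisherOracle(a, H, b, L)), 1e-9)
    expect_true(p >= 0 && p <= 1)
    # swapping populations leaves the two-sided P unchanged
    expect_equal(fisherExactP(b, L, a, H), p, tolerance = 1e-12)
  }
  # agreement with the standard R implementation as a second oracle
  set.seed(104)
  for (i in 1:50) {
    H <- sample(100:4000, 1L); L <- sample(100:4000, 1L)
    a <- rbinom(1L, H, 0.02); b <- rbinom(1L, L, 0.02)
    ref <- stats::fisher.test(matrix(c(a, H - a, b, L - b), 2,
                                     byrow = TRUE))$p.value
    expect_equal(fisherExactP(a, H, b, L), ref, tolerance = 1e-7)
  }
})

test_that("regulator calls are strict at alpha and directional by MI", {
  res <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3", "g4"),
    a = c(40L, 2L, 10L, 0L), b = c(5L, 35L, 10L, 0L),
    H = 500L, L = 500L,
    mi = c(4.03, 0.2, 1, NaN),
    p_value = c(0.04999, 0.05, 0.9, 1))
  out <- callRegulators(res, alpha = 0.05)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$direction[1], "enriched_high")
  expect_identical(out$regulator[1], "negative regulator")
  expect_identical(out$direction[2], "none")  # P == alpha: not significant
  # MI < 1 significant would be a positive regulator
  res$p_value[2] <- 0.001
  out2 <- callRegulators(res, alpha = 0.05)
  expect_identical(out2$regulator[2], "positive regulator")
  expect_identical(S4Vectors::metadata(out2)$alpha, 0.05)
})

test_that("testScreen assembles counts, MI and P per gene", {
  ct <- S4Vectors::DataFrame(gene_id = c("gA", "gB"),
                             a = c(10L, 3L), b = c(5L, 3L),
                             H = c(1000L, 1000L), L = c(2000L, 2000L))
  res <- testScreen(ct)
  expect_equal(res$mi[1], 4.030303, tolerance = 1e-6)
  expect_equal(res$p_value, fisherExactP(ct$a, ct$H, ct$b, ct$L),
               tolerance = 1e-12)
  expect_identical(res$total_insertions, c(15L, 6L))
  # BH option adjusts the call, not the raw P
  resF <- testScreen(ct, fdr = TRUE)
  expect_identical(resF$p_value, res$p_value)
  expect_true(all(resF$p_adjusted >= resF$p_value))
})

test_that("fishtail table applies the documented pseudocount policy", {
  ct <- S4Vectors::DataFrame(
    gene_id = c("gInf", "gOne", "gZero", "gNaN"),
    a = c(12L, 7L, 0L, 0L), b = c(0L, 7L, 9L, 0L),
    H = c(500L, 500L, 500L, 500L), L = c(400L, 500L, 400L, 400L))
  res <- testScreen(ct)
  ft <- fishtailTable(res, pseudocount = TRUE)
  # undefined-MI gene excluded
  expect_false("gNaN" %in% ft$gene_id)
  # MI = 1 plots at y = 0 (haldane keeps symmetric counts symmetric)
  expect_equal(ft$log2_mi[ft$gene_id == "gOne"], 0, tolerance = 1e-12)
  # documented Haldane formula for the infinite-MI gene
  expect_equal(ft$log2_mi[ft$gene_id == "gInf"],
               log2((12.5 / (500 - 12)) * ((400 - 0) / 0.5)),
               tolerance = 1e-12)
  expect_identical(S4Vectors::metadata(ft)$pseudocount, "haldane+0.5")
  # exact mode keeps infinities out of the smoothing
  fte <- fishtailTable(res, pseudocount = FALSE)
  expect_identical(fte$log2_mi[fte$gene_id == "gInf"], Inf)
  # empty input: empty table, no error
  empty <- fishtailTable(testScreen(ct[0, ]))
  expect_identical(nrow(empty), 0L)
  # plot construction works on both
  expect_s3_class(plotFishtail(res), "ggplot")
})

test_that("screen comparison takes exact log2 differences under the insertion filter", {
  mk <- function(a, b, H = 10000L, L = 10000L)
    S4Vectors::DataFrame(gene_id = c("g8", "g2", "gRare"),
                         a = a, b = b, H = H, L = L)
  # engineered MI of exactly 8 and 2 via symmetric totals
  r1 <- testScreen(mk(a = c(80L, 80L, 14L), b = c(10L, 10L, 15L)))
  r2 <- testScreen(mk(a = c(20L, 40L, 200L), b = c(10L, 20L, 200L)))
  cmp <- compareScreens(r1, r2, minInsertions = 30L)
  # MI ratios: near 8/2 up to the leave-one-out denominators
  d <- cmp$delta_log2_mi[cmp$gene_id == "g8"]
  expect_equal(d, log2(r1$mi[1]) - log2(r2$mi[1]), tolerance = 1e-12)
  # 29 insertions in screen 1 vs 400 in screen 2 fails the filter
  expect_false(cmp$passes_filter[cmp$gene_id == "gRare"])
  expect_true(is.na(cmp$delta_log2_mi[cmp$gene_id == "gRare"]))
  # identical screens give delta 0
  cmp0 <- compareScreens(r1, r1)
  expect_true(all(cmp0$delta_log2_mi[cmp0$passes_filter] == 0))
  # disjoint universes are an input error
  r3 <- testScreen(S4Vectors::DataFrame(gene_id = "other", a = 5L,
                                        b = 5L, H = 100L, L = 100L))
  expect_error(compareScreens(r1, r3), "disjoint")
})

test_that("exact powers of two survive the log2 difference exactly", {
  # tables whose MI are exactly 8 and 2: all ratios are dyadic, so the
  # floating-point arithmetic is exact end to end
  r1 <- testScreen(S4Vectors::DataFrame(gene_id = "g", a = 128L,
                                        b = 16L, H = 2176L, L = 2064L))
  r2 <- testScreen(S4Vectors::DataFrame(gene_id = "g", a = 32L,
                                        b = 16L, H = 2080L, L = 2064L))
  expect_identical(r1$mi, 8)
  expect_identical(r2$mi, 2)
  cmp <- compareScreens(r1, r2, minInsertions = 30L)
  expect_identical(cmp$delta_log2_mi, 2)
})
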