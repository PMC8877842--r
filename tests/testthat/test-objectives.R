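test_that("Tversky index is exact on the worked single-class case", {
  # 4x4 one-class layout: 8 foreground GT pixels, prediction covers 4 of
  # them (TP=4, FN=4) plus 2 background pixels (FP=2); with alpha=0.7,
  # beta=0.3 the index is (4+w)/(4+w + 0.7*4 + 0.3*2 + w) = 4/7.4
  gt1 <- matrix(0, 4, 4); gt1[1:2, 1:4] <- 1
  p1 <- matrix(0, 4, 4); p1[1, 1:4] <- 1; p1[3, 1:2] <- 1
  probs <- array(c(1 - p1, p1), c(4, 4, 2))
  gt <- array(c(1 - gt1, gt1), c(4, 4, 2))
  ti <- tverskyIndex(probs, gt, tverskyParams(omega = 1e-6))
  expect_equal(attr(ti, "perClass")[2], 4 / 7.4, tolerance = 1e-5)
})

test_that("Tversky index is 1 at perfect prediction, ~0 at disjoint masks", {
  set.seed(4)
  lab <- random_labelmap(8, 8)
  oh <- encodeOneHot(lab)
  for (a in c(0.3, 0.5, 0.7)) {
    ti <- tverskyIndex(oh, oh, tverskyParams(alpha = a, beta = 1 - a))
    expect_equal(as.numeric(ti), 1, tolerance = 1e-6)
    expect_equal(tverskyLoss(oh, oh, tverskyParams(alpha = a, beta = 1 - a)),
                 0, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # fully disjoint binary masks: index collapses to the smoothing floor
  g <- matrix(0, 16, 16); g[1:8, ] <- 1
  p <- 1 - g
  probs <- array(c(1 - p, p), c(16, 16, 2))
  gt <- array(c(1 - g, g), c(16, 16, 2))
  expect_lt(attr(tverskyIndex(probs, gt), "perClass")[2], 1e-5)
})

test_that("Tversky equals Dice at alpha = beta = 0.5 on binary masks", {
  set.seed(11)
  for (i in 1:20) {
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    probs <- array(c(1 - p, p), c(8, 8, 2))
    gt <- array(c(1 - g, g), c(8, 8, 2))
    ti <- attr(tverskyIndex(probs, gt, tverskyParams(0.5, 0.5)), "perClass")[2]
    inter <- sum(p & g)
    dice <- if (sum(p) + sum(g) == 0) 1 else 2 * inter / (sum(p) + sum(g))
    # Tversky(0.5, 0.5) = TP / (TP + (FN+FP)/2) = Dice
    expect_equal(ti, dice, tolerance = 1e-4)
  }
})

test_that("loss strictly decreases when a false-positive probability shrinks", {
  g <- matrix(0, 4, 4); g[1:2, ] <- 1
  gt <- array(c(1 - g, g), c(4, 4, 2))
  base <- array(0.5, c(4, 4, 2))
  hi <- base; hi[4, 4, 2] <- 0.9; hi[4, 4, 1] <- 0.1   # confident FP
  lo <- base; lo[4, 4, 2] <- 0.2; lo[4, 4, 1] <- 0.8
  expect_lt(tverskyLoss(lo, gt), tverskyLoss(hi, gt))
})

test_that("Tversky gradient is finite and matches finite differences", {
  set.seed(7)
  probs <- array(runif(4 * 4 * 5, 0.05, 0.95), c(4, 4, 5))
  gt <- encodeOneHot(random_labelmap(4, 4))
  tp <- tverskyParams()
  gr <- sssnet:::tversky_grad(probs, gt, tp)
  expect_true(all(is.finite(gr)))
  eps <- 1e-6
  for (k in sample(length(probs), 5)) {
    p2 <- probs; p2[k] <- p2[k] + eps
    p3 <- probs; p3[k] <- p3[k] - eps
    num <- as.numeric(tverskyLoss(p2, gt, tp) - tverskyLoss(p3, gt, tp)) / (2 * eps)
    expect_equal(gr[k], num, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("Tversky index is invariant to pixel permutations", {
  set.seed(13)
  lab <- random_labelmap(8, 8)
  probs <- array(runif(8 * 8 * 5), c(8, 8, 5))
  gt <- encodeOneHot(lab)
  perm <- sample(64)
  pp <- array(apply(probs, 3, function(ch) ch[perm]), c(8, 8, 5))
  gp <- array(apply(gt, 3, function(ch) ch[perm]), c(8, 8, 5))
  expect_equal(as.numeric(tverskyIndex(probs, gt)),
               as.numeric(tverskyIndex(pp, gp)), tolerance = 1e-12)
})

test_that("mask shape and binarity are enforced", {
  probs <- array(0.2, c(4, 4, 5))
  expect_error(tverskyIndex(probs, array(0, c(4, 5, 5))), "shape")
  expect_error(tverskyIndex(probs, array(0.5, c(4, 4, 5))), "binary")
})

test_that("confusion counts match hand counts and swap symmetry", {
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE)
  gt <- matrix(c(0L, 1L, 0L, 1L), 2, 2, byrow = TRUE)
  cc <- confusionCounts(pred, gt, 2L)
  expect_equal(unname(cc@counts["ZP", c("TP", "FP", "FN")]), c(2, 1, 0))
  expect_equal(unname(cc@counts["background", c("TP", "FP", "FN")]), c(1, 0, 1))
  # identity
  ccI <- confusionCounts(gt, gt, 2L)
  expect_true(all(ccI@counts[, c("FP", "FN")] == 0))
  # swapping pred and gt swaps FP and FN
  ccS <- confusionCounts(gt, pred, 2L)
  expect_equal(unname(ccS@counts[, "FP"]), unname(cc@counts[, "FN"]))
  expect_equal(unname(ccS@counts[, "FN"]), unname(cc@counts[, "FP"]))
  expect_error(confusionCounts(matrix(5L, 2, 2), matrix(0L, 2, 2)), "range")
})

test_that("per-class Jaccard equals brute-force set arithmetic exactly", {
  set.seed(21)
  for (i in 1:200) {
    pred <- random_labelmap(16, 16)
    gt <- random_labelmap(16, 16)
    ji <- jaccardPerClass(confusionCounts(pred, gt))
    expect_identical(as.numeric(ji), jaccard_bruteforce(pred, gt))
  }
})

test_that("Jaccard direct formula and absent-class convention", {
  counts <- cbind(TP = c(8, 0), FP = c(2, 0), FN = c(2, 0), TN = c(4, 16))
  rownames(counts) <- c("background", "ZP")
  cc <- new("ConfusionCounts", counts = counts, nPixels = 16)
  ji <- jaccardPerClass(cc)
  expect_equal(ji[["background"]], 8 / 12)
  expect_equal(ji[["ZP"]], 1)              # absent from both: 1 by convention
  expect_equal(unname(attr(ji, "absent")), c(FALSE, TRUE))
})

test_that("meanJI reproduces the reported per-variant row means", {
  resid <- c(0.9603, 0.8288, 0.7740, 0.8839, 0.8494)  # bg, ZP, TE, BL, ICM
  dense <- c(0.9582, 0.8451, 0.7815, 0.8868, 0.8450)
  expect_equal(meanJI(resid), 0.8593, tolerance = 0.005 / 0.8593)
  expect_equal(meanJI(dense), 0.8634, tolerance = 0.005 / 0.8634)
  expect_equal(meanJI(rep(1, 5)), 1)
  expect_error(meanJI(c(0.5, 0.5)), "five")
  expect_error(meanJI(c(0.5, 0.5, NA, 0.5, 0.5)), "missing")
})
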