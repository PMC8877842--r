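test_that("the reference training configuration echoes the study protocol", {
  cfg <- trainConfig()
  expect_equal(cfg@learningRate, 1e-4)
  expect_equal(cfg@epsilon, 1e-6)
  expect_equal(cfg@batchSize, 20L)
  expect_equal(cfg@iterations, 11200L)
  expect_equal(cfg@loss@alpha, 0.7)
  expect_equal(cfg@loss@beta, 0.3)
  # with 3200 training pairs this protocol is 160 iterations per epoch,
  # i.e. 70 epochs
  expect_equal(3200 / cfg@batchSize, 160)
  expect_equal(cfg@iterations / 160, 70)
})

test_that("prediction is the per-pixel argmax with lowest-index tie-breaking", {
  net <- buildNetwork(tiny_spec(), seed = 2)
  # force channel 3 (class index 3, BL) to win everywhere via the head bias
  net@params[["head.w"]][] <- 0
  net@params[["head.b"]] <- c(0, 0, 0, 5, 0)
  ph <- small_phantom(seed = 30, size = 32L)
  lab <- predictLabels(net, ph@image)
  expect_true(all(lab == 3L))
  ms <- attr(lab, "maskStack")
  expect_equal(dim(ms), c(32L, 32L, 5L))
  expect_true(all(ms[, , 4] == 1))
  # exact tie between classes 0 and 2 resolves to 0
  net@params[["head.b"]] <- c(2, 0, 2, 0, 0)
  lab2 <- predictLabels(net, ph@image)
  expect_true(all(lab2 %in% c(0L, 2L)))
  expect_true(any(lab2 == 0L))
})

test_that("binarized mask stacks decode to the predicted label map", {
  set.seed(41)
  for (i in 1:20) {
    scores <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
    probs <- softmaxHead(scores)
    m <- matrix(probs, 64, 5)
    lab <- matrix(max.col(m, ties.method = "first") - 1L, 8, 8)
    expect_identical(decodeOneHot(encodeOneHot(lab)), structure(lab, oneHot = TRUE))
  }
})

test_that("a short run on noiseless phantoms reduces the training loss", {
  phs <- lapply(1:8, function(i) generatePhantom(phantomParams(
    imageSize = 64L, noiseSigma = 0, illuminationGradient = 5,
    icmAngle = i * pi / 4, seed = 100 + i)))
  net <- buildNetwork(compactNetworkSpec("dense"), seed = 4)
  cfg <- trainConfig(iterations = 50L, batchSize = 8L, seed = 3)
  r <- trainNetwork(net, lapply(phs, function(p) p@image),
                    lapply(phs, function(p) p@gt), cfg)
  expect_true(all(is.finite(r$log@losses)))
  expect_lt(mean(utils::tail(r$log@losses, 5)),
            mean(utils::head(r$log@losses, 5)))
})

test_that("identical seeds give identical training logs", {
  phs <- lapply(1:4, function(i) small_phantom(seed = 200 + i, size = 32L))
  imgs <- lapply(phs, function(p) p@image)
  gts <- lapply(phs, function(p) p@gt)
  run <- function() {
    net <- buildNetwork(tiny_spec(), seed = 6)
    trainNetwork(net, imgs, gts,
                 trainConfig(iterations = 5L, batchSize = 4L, seed = 11))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$log@losses, r2$log@losses)
  expect_identical(r1$model@params, r2$model@params)
})

test_that("evaluation pools confusion counts and is order-invariant", {
  phs <- lapply(1:4, function(i) small_phantom(seed = 300 + i, size = 32L))
  imgs <- lapply(phs, function(p) p@image)
  gts <- lapply(phs, function(p) p@gt)
  net <- buildNetwork(tiny_spec(), seed = 8)
  r1 <- evaluateNetwork(net, imgs, gts)
  r2 <- evaluateNetwork(net, rev(imgs), rev(gts))
  expect_equal(r1@perClassJI, r2@perClassJI)
  expect_equal(r1@meanJI, mean(r1@perClassJI))
  # pooled counts equal the sum of per-image counts
  pooled <- NULL
  for (i in 1:4) {
    cc <- confusionCounts(predictLabels(net, imgs[[i]]), gts[[i]])
    pooled <- if (is.null(pooled)) cc@counts else pooled + cc@counts
  }
  expect_equal(unname(r1@perClassJI),
               unname(as.numeric(jaccardPerClass(
                 new("ConfusionCounts", counts = pooled,
                     nPixels = sum(pooled[1, ]))))))
  expect_error(evaluateNetwork(net, list(), list()), "empty")
})

test_that("uniform random predictions approach the analytic JI expectation", {
  # for two independent uniform 5-class maps, E[TP] = n/25 per class and
  # E[JI] -> (n/25) / (n/25 + 2 * 4n/25) = 1/9 as n grows
  set.seed(55)
  pred <- random_labelmap(200, 200)
  gt <- random_labelmap(200, 200)
  ji <- jaccardPerClass(confusionCounts(pred, gt))
  expect_equal(unname(as.numeric(ji)), rep(1 / 9, 5), tolerance = 0.05)
})

test_that("a model reproducing the ground truth scores JI 1 for every class", {
  ph <- small_phantom(seed = 44, size = 32L)
  cc <- confusionCounts(ph@gt, ph@gt)
  ji <- jaccardPerClass(cc)
  expect_equal(unname(as.numeric(ji)), rep(1, 5))
  expect_equal(meanJI(as.numeric(ji)), 1)
})

test_that("checkpoints are self-describing and restore the exact model", {
  d <- withr::local_tempdir()
  net <- buildNetwork(tiny_spec("residual"), seed = 13)
  f <- file.path(d, "ckpt.rds")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  expect_identical(net2@params, net@params)
  expect_identical(net2@spec@variant, "residual")
  ph <- small_phantom(seed = 50, size = 32L)
  expect_identical(predictLabels(net2, ph@image), predictLabels(net, ph@image))
  saveRDS(list(a = 1), f)
  expect_error(loadCheckpoint(f), "checkpoint")
})

test_that("training rejects empty or mismatched data", {
  net <- buildNetwork(tiny_spec(), seed = 1)
  expect_error(trainNetwork(net, list(), list()), "empty")
  ph <- small_phantom(seed = 60, size = 32L)
  expect_error(trainNetwork(net, list(ph@image), list()), "length")
  bad <- array(0, c(30, 30, 3))
  expect_error(trainNetwork(net, list(bad), list(matrix(0L, 30, 30))),
               "divisible")
})

test_that("the fused training-loss kernel equals the composed operations", {
  set.seed(71)
  sc <- array(rnorm(8 * 8 * 5 * 2), c(8, 8, 5, 2))
  gt <- array(0, c(8, 8, 5, 2))
  for (n in 1:2) gt[, , , n] <- encodeOneHot(random_labelmap(8, 8))
  tp <- tverskyParams()
  f <- sssnet:::cpp_softmax_tversky(sc, gt, tp@alpha, tp@beta, tp@omega)
  p <- softmaxHead(sc)
  expect_equal(f$loss, as.numeric(tverskyLoss(p, gt, tp)), tolerance = 1e-12)
  dsR <- sssnet:::softmax_backward(p, sssnet:::tversky_grad(p, gt, tp))
  expect_equal(f$dscores, dsR, tolerance = 1e-10)
})
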