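test_that("output spatial dims equal input dims for divisible sizes, both variants", {
  for (variant in c("residual", "dense")) {
    net <- buildNetwork(tiny_spec(variant), seed = 1)
    for (hw in list(c(8L, 8L), c(16L, 16L), c(16L, 64L), c(64L, 64L),
                    c(128L, 128L))) {
      x <- array(rnorm(prod(hw) * 3), c(hw, 3L))
      fw <- sssnet:::network_forward(net, x)
      expect_equal(dim(fw$scores), c(hw, 5L, 1L))
    }
  }
})

test_that("non-divisible input sizes raise an error naming the divisor", {
  net <- buildNetwork(tiny_spec(), seed = 1)
  x <- array(0, c(12, 16, 3))
  expect_error(sssnet:::network_forward(net, x), "divisible by 8")
})

test_that("residual and dense variants have identical total parameter counts", {
  for (mk in list(tiny_spec, compactNetworkSpec, referenceNetworkSpec)) {
    nr <- countTrainableParameters(buildNetwork(mk("residual"), seed = 1))@total
    nd <- countTrainableParameters(buildNetwork(mk("dense"), seed = 1))@total
    expect_equal(nr, nd)
  }
})

test_that("parameter count is independent of input spatial size", {
  net <- buildNetwork(tiny_spec(), seed = 3)
  n0 <- countTrainableParameters(net)@total
  invisible(sssnet:::network_forward(net, array(0, c(8, 8, 3))))
  invisible(sssnet:::network_forward(net, array(0, c(32, 32, 3))))
  expect_equal(countTrainableParameters(net)@total, n0)
  # FLOP estimate, by contrast, scales with the pixel count
  r8 <- countTrainableParameters(net, c(8L, 8L))@flopsPerForward
  r16 <- countTrainableParameters(net, c(16L, 16L))@flopsPerForward
  expect_gt(r16, 3.9 * r8)
})

test_that("trivial parameter-count cases match hand counts", {
  # a single 1x1 convolution with bias: 3*4 + 4 = 16
  p <- list(w = array(0, c(1, 1, 3, 4)), b = rep(0, 4))
  toy <- new("SCBBlock", spec = scbSpec(3L, 4L), params = p, state = list())
  expect_equal(countTrainableParameters(toy)@total, 16)
  # a 2-layer toy net: 3x3 conv 2->3 without bias (54) + 1x1 conv 3->1 with
  # bias (3 + 1) = 58
  p2 <- list(w1 = array(0, c(3, 3, 2, 3)), w2 = array(0, c(1, 1, 3, 1)),
             b2 = 0)
  toy2 <- new("SCBBlock", spec = scbSpec(2L, 3L), params = p2, state = list())
  expect_equal(countTrainableParameters(toy2)@total, 58)
})

test_that("bottleneck sits at 1/8 resolution", {
  net <- buildNetwork(tiny_spec(), seed = 1)
  fw <- sssnet:::network_forward(net, array(rnorm(64 * 64 * 3), c(64, 64, 3)))
  b4 <- sssnet:::vget(fw$ctx, "br4r")
  expect_equal(dim(b4)[1:2], c(8L, 8L))
})

test_that("softmax head produces per-pixel distributions", {
  # all-zero scores: uniform 1/5
  p <- softmaxHead(array(0, c(4, 4, 5)))
  expect_equal(as.vector(p), rep(0.2, 80))
  # saturated channel wins
  s <- array(0, c(2, 2, 5)); s[, , 3] <- 1000
  expect_true(all(softmaxHead(s)[, , 3] > 1 - 1e-12))
  # random scores: sums are exactly 1 within tolerance
  set.seed(9)
  p <- softmaxHead(array(rnorm(4 * 4 * 5), c(4, 4, 5)))
  expect_true(max(abs(apply(p, c(1, 2), sum) - 1)) < 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(softmaxHead(array(NaN, c(2, 2, 5))), "finite")
})

test_that("one optimisation step moves every trainable parameter", {
  for (variant in c("residual", "dense")) {
    net <- buildNetwork(tiny_spec(variant), seed = 5)
    ph <- small_phantom(seed = 20, size = 32L)
    cfg <- trainConfig(iterations = 1L, batchSize = 1L, seed = 2,
                       learningRate = 1e-3)
    r <- trainNetwork(net, list(ph@image), list(ph@gt), cfg)
    moved <- vapply(names(net@params), function(nm)
      any(r$model@params[[nm]] != net@params[[nm]]), TRUE)
    expect_true(all(moved), info = paste("dead:", paste(
      names(moved)[!moved], collapse = ", ")))
  }
})

test_that("network spec validity enforces the fixed topology counts", {
  spec <- tiny_spec()
  bad <- spec; bad@stridedWidths <- c(4L, 6L)
  expect_error(validObject(bad), "3 strided")
  bad <- spec; bad@bridgeWidths <- rep(6L, 3L)
  expect_error(validObject(bad), "4 bridge")
  bad <- spec; bad@scbSpecs <- spec@scbSpecs[1:3]
  expect_error(validObject(bad), "4 SCBSpec")
})

test_that("spec YAML round-trips", {
  f <- tempfile(fileext = ".yaml")
  spec <- compactNetworkSpec("residual")
  specToYAML(spec, f)
  spec2 <- specFromYAML(f)
  expect_equal(sssnet:::spec_to_list(spec2), sssnet:::spec_to_list(spec))
})
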