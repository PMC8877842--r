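test_that("SCB preserves spatial size and hits the specified output width", {
  spec <- scbSpec(8L, 8L, 8L, 8L, 8L, 16L)
  block <- buildSCB(spec, seed = 1)
  x <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  y <- scbForward(block, x)
  expect_equal(dim(y), c(32L, 32L, 16L, 1L))
  # non-square input, batched
  xb <- array(rnorm(16 * 24 * 8 * 2), c(16, 24, 8, 2))
  expect_equal(dim(scbForward(block, xb)), c(16L, 24L, 16L, 2L))
})

test_that("branch concatenation widths follow the block arithmetic", {
  spec <- scbSpec(8L, 8L, asymWidth = 16L, conv3Width = 12L, sepWidth = 4L,
                  outWidth = 24L)
  expect_equal(scbConcatAWidth(spec), 32L)
  expect_equal(scbConcatBWidth(spec), 32L + 12L + 4L)
})

test_that("SCB parameter count matches a layer-by-layer hand enumeration", {
  # Enumerated independently of the builder: point-wise conv carries a bias
  # (it is not followed by batch norm), all other convolutions are
  # bias-free, each batch norm contributes 2 learnable scalars per channel.
  cin <- 8L; g <- 8L; a <- 8L; c3 <- 8L; f <- 8L; o <- 16L
  hand <- (cin * g + g) +            # point-wise 1x1 + bias
    3 * g * a + 3 * g * a +          # 1x3 and 3x1 asymmetric convs
    2 * (2 * a) +                    # BN over the asymmetric concat
    9 * g * c3 + 2 * c3 +            # 3x3 branch + BN
    9 * cin + cin * f + 2 * f +      # depth-wise 3x3, point-wise, BN
    (2 * a + c3 + f) * o + 2 * o     # end bottleneck + BN
  expect_equal(hand, 1776)
  block <- buildSCB(scbSpec(cin, g, a, c3, f, o))
  rep <- countTrainableParameters(block)
  expect_equal(rep@total, hand)
  expect_equal(sum(rep@perLayer$count), rep@total)
})

test_that("invalid SCB widths and channel mismatches are rejected", {
  expect_error(scbSpec(0L, 8L), "positive")
  expect_error(scbSpec(8L, -1L), "positive")
  block <- buildSCB(scbSpec(4L, 4L))
  x <- array(0, c(16, 16, 3))
  expect_error(scbForward(block, x), "channels")
})

test_that("all SCB branches share spatial dims so concatenation is defined", {
  # checked indirectly: the block runs on odd sizes where a padding slip
  # would break concatenation
  block <- buildSCB(scbSpec(3L, 4L))
  for (hw in list(c(7L, 7L), c(5L, 9L), c(11L, 6L))) {
    y <- scbForward(block, array(rnorm(prod(hw) * 3), c(hw, 3L)))
    expect_equal(dim(y)[1:2], hw)
  }
})
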