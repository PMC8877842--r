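test_that("noiseless flat-light phantom is piecewise constant at the class intensities", {
  p <- phantomParams(imageSize = 64L, noiseSigma = 0, illuminationGradient = 0,
                     seed = 2)
  ph <- generatePhantom(p)
  ints <- p@classIntensities
  # per-channel jitter is a constant offset; compare channel means per region
  gray <- ph@image[, , 1] - (ph@image[1, 1, 1] - ints[["background"]])
  for (k in 0:3) {
    base <- c(ints[["background"]], ints[["ZP"]], ints[["TE"]], ints[["BL"]])[k + 1]
    vals <- gray[ph@gt == k]
    expect_true(all(abs(vals - base) < 1e-9),
                info = paste("class", k, "not constant"))
  }
  icm <- gray[ph@gt == 4L]
  expect_true(all(abs(icm - (ints[["TE"]] + p@teIcmContrast)) < 1e-9))
})

test_that("TE and ICM stay within the configured gray-level contrast", {
  p <- phantomParams(imageSize = 64L, noiseSigma = 0, illuminationGradient = 0,
                     teIcmContrast = 6, seed = 3)
  ph <- generatePhantom(p)
  te <- mean(ph@image[, , 1][ph@gt == 2L])
  icm <- mean(ph@image[, , 1][ph@gt == 4L])
  expect_lte(abs(te - icm), p@teIcmContrast + 1e-9)
})

test_that("ZP annulus area matches the analytic value within 3%", {
  p <- phantomParams(imageSize = 256L, outerRadius = 50, zpThickness = 6,
                     teThickness = 10, icmRadius = 12, ellipticity = 1,
                     noiseSigma = 0, seed = 4)
  ph <- generatePhantom(p)
  analytic <- pi * (50^2 - 44^2)     # ~1772 px
  measured <- sum(ph@gt == 1L)
  expect_lt(abs(measured - analytic) / analytic, 0.03)
})

test_that("identical parameters give a bit-identical phantom", {
  p <- phantomParams(seed = 9)
  a <- generatePhantom(p)
  b <- generatePhantom(p)
  expect_identical(a@image, b@image)
  expect_identical(a@gt, b@gt)
  expect_false(identical(generatePhantom(phantomParams(seed = 10))@image,
                         a@image))
})

test_that("phantom GT has the nested blastocyst topology", {
  ph <- small_phantom(seed = 12, size = 64L)
  p <- ph@params
  idx <- which(ph@gt >= 0, arr.ind = TRUE)
  reff <- sqrt(((idx[, 1] - p@center[1]) * p@ellipticity)^2 +
                 (idx[, 2] - p@center[2])^2)
  r_by_class <- split(reff, as.vector(ph@gt))
  # background strictly outside ZP, ZP outside TE, TE outside the cavity
  expect_gt(min(r_by_class[["0"]]), max(pmin(r_by_class[["1"]], Inf)) - 1e-9)
  expect_gt(mean(r_by_class[["1"]]), mean(r_by_class[["2"]]))
  expect_gt(mean(r_by_class[["2"]]), mean(r_by_class[["3"]]))
  # ICM touches the TE band: its outermost pixel reaches the cavity edge
  expect_gt(max(r_by_class[["4"]]),
            p@outerRadius - p@zpThickness - p@teThickness - 2)
})

test_that("generated datasets contain all five classes and round-trip the pipeline", {
  ds <- generateDataset(6, imageSize = 64L, seed = 17)
  expect_length(ds$phantoms, 6)
  expect_equal(nrow(ds$manifest), 6)
  for (ph in ds$phantoms) {
    expect_setequal(unique(as.vector(ph@gt)), 0:4)
    expect_identical(decodeGT(renderLabelMap(ph@gt), tolerance = 0), ph@gt)
  }
})

test_that("degenerate ranges pin the drawn parameters to the bound", {
  ds <- generateDataset(2, imageSize = 64L,
                        ranges = list(outerRadius = c(0.4, 0.4),
                                      noiseSigma = c(5, 5)), seed = 2)
  expect_true(all(ds$manifest$outerRadius == 0.4))
  expect_true(all(ds$manifest$noiseSigma == 5))
  expect_error(generateDataset(2, ranges = list(bogus = c(0, 1))), "unknown")
  expect_error(generateDataset(0), "positive")
})

test_that("class areas respond monotonically to their generating parameters", {
  mk <- function(zp, icm) generatePhantom(phantomParams(
    imageSize = 96L, zpThickness = zp, icmRadius = icm, noiseSigma = 0,
    seed = 5))
  a1 <- mk(5, 10); a2 <- mk(8, 10); a3 <- mk(8, 14)
  expect_gt(sum(a2@gt == 1L), sum(a1@gt == 1L))   # thicker ZP, larger annulus
  expect_gt(sum(a3@gt == 4L), sum(a2@gt == 4L))   # larger ICM radius
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantomParams(imageSize = 100L), "divisible")
  expect_error(phantomParams(imageSize = 64L, outerRadius = 20,
                             zpThickness = 8, teThickness = 8, icmRadius = 6),
               "nested")
  expect_error(phantomParams(imageSize = 64L, outerRadius = 40), "fit")
})

test_that("written datasets are ingestible from disk", {
  d <- withr::local_tempdir()
  ds <- generateDataset(3, imageSize = 64L, seed = 23)
  man <- writeDataset(ds, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  for (i in 1:3) {
    img <- readImageRGB(man$image[i])
    expect_equal(img, ds$phantoms[[i]]@image, tolerance = 0.51)
    expect_identical(readLabelMap(man$label[i]), ds$phantoms[[i]]@gt)
    expect_identical(decodeGT(readImageRGB(man$gt[i]), tolerance = 0),
                     ds$phantoms[[i]]@gt)
  }
})
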