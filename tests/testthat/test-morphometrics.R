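test_that("agreeing predictions render pure class colors", {
  set.seed(61)
  lab <- random_labelmap(12, 12)
  ov <- overlayErrors(lab, lab)
  expect_identical(ov, renderLabelMap(lab))
})

test_that("a missed ZP ring is painted pink; spurious foreground is black", {
  ph <- small_phantom(seed = 62, size = 48L)
  gt <- ph@gt
  pred <- matrix(0L, nrow(gt), ncol(gt))     # all background
  ov <- overlayErrors(pred, gt)
  style <- defaultOverlayStyle()
  fg <- gt > 0L
  pink <- ov[, , 1] == style@fnColor[1] & ov[, , 2] == style@fnColor[2] &
    ov[, , 3] == style@fnColor[3]
  expect_identical(unname(which(pink)), unname(which(fg)))
  # spurious prediction on background renders black (FP convention)
  pred2 <- gt
  pred2[1:3, 1:3] <- 2L                       # corner is background in gt
  ov2 <- overlayErrors(pred2, gt)
  expect_true(all(ov2[1:3, 1:3, ] == 0))
  expect_error(overlayErrors(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
})

test_that("pink and black pixel tallies reconcile with the confusion counts", {
  set.seed(63)
  for (i in 1:10) {
    pred <- random_labelmap(16, 16)
    gt <- random_labelmap(16, 16)
    ov <- overlayErrors(pred, gt)
    style <- defaultOverlayStyle()
    pink <- sum(ov[, , 1] == style@fnColor[1] & ov[, , 2] == style@fnColor[2] &
                  ov[, , 3] == style@fnColor[3])
    cc <- confusionCounts(pred, gt)@counts
    # pink = false negatives of the four foreground classes;
    # black-over-gt-background = missed background = FN of class 0;
    # together they are every disagreeing pixel
    expect_equal(pink, sum(cc[2:5, "FN"]))
    black_fp <- sum(pred != gt & gt == 0L)
    expect_equal(black_fp, cc["background", "FN"])
    expect_equal(pink + black_fp, sum(pred != gt))
  }
})

test_that("component areas are exact and partition the image", {
  set.seed(64)
  lab <- random_labelmap(20, 20)
  tot <- 0
  for (k in 0:4) {
    a <- componentArea(lab, k)
    expect_equal(a$pixels, sum(lab == k))
    expect_equal(a$fraction, a$pixels / 400)
    tot <- tot + a$pixels
  }
  expect_equal(tot, 400)
  expect_equal(componentArea(matrix(0L, 4, 4), 3L)$pixels, 0)
  expect_error(componentArea(lab, 9), "0..4")
})

test_that("annulus morphometrics recover the generating geometry", {
  p <- phantomParams(imageSize = 256L, outerRadius = 50, zpThickness = 6,
                     teThickness = 10, icmRadius = 12, ellipticity = 1,
                     noiseSigma = 0, seed = 65)
  ph <- generatePhantom(p)
  # area within 3% of pi (Ro^2 - Ri^2)
  a <- componentArea(ph@gt, 1L)
  expect_equal(a$pixels, pi * (50^2 - 44^2), tolerance = 0.03)
  # medial-axis thickness within 1 px of the generating parameter
  th <- zpThickness(ph@gt)
  expect_true(th$present)
  expect_lt(abs(th$mean - 6), 1)
  expect_true(is.data.frame(th$profile))
})

test_that("estimated ZP thickness scales with the generating thickness", {
  mk <- function(t) zpThickness(generatePhantom(phantomParams(
    imageSize = 192L, outerRadius = 70, zpThickness = t, teThickness = 10,
    icmRadius = 12, ellipticity = 1, noiseSigma = 0, seed = 66))@gt)$mean
  t4 <- mk(4); t8 <- mk(8); t16 <- mk(16)
  expect_lt(abs(t8 / t4 - 2), 0.3)
  expect_lt(abs(t16 / t8 - 2), 0.3)
})

test_that("absent components are flagged, not errors", {
  empty <- matrix(0L, 16, 16)
  th <- zpThickness(empty)
  expect_false(th$present)
  expect_true(is.na(th$mean))
  bl <- blastocoelPresence(empty)
  expect_false(bl$present)
  expect_equal(bl$fraction, 0)
})

test_that("blastocoel presence follows the area-fraction threshold", {
  ph <- small_phantom(seed = 67, size = 64L)
  bl <- blastocoelPresence(ph@gt, 0.01)
  expect_true(bl$present)
  expect_gt(bl$fraction, 0.01)
  expect_false(blastocoelPresence(ph@gt, min(bl$fraction + 0.05, 0.99))$present)
  expect_error(blastocoelPresence(ph@gt, 1.2), "minFraction")
})

test_that("the full morphometrics report is internally consistent", {
  ph <- small_phantom(seed = 68, size = 64L)
  rep <- morphometricsReport(ph@gt)
  expect_equal(sum(rep@areas), length(ph@gt))
  expect_equal(sum(rep@fractions), 1)
  expect_true(rep@blPresent)
  expect_true(all(!is.na(rep@centroids)))
  # the ICM centroid sits on the ICM side of the embryo centre
  icm_dir <- rep@centroids["ICM", ] - rep@centroids["BL", ]
  expect_gt(sqrt(sum(icm_dir^2)), 1)
  lst <- morphometricsAsList(rep)
  expect_equal(lst$areas$ZP, unname(rep@areas["ZP"]))
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE)
  expect_true(jsonlite::validate(txt))
})
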