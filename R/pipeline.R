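# Ground-truth palette handling, one-hot encoding, dataset splitting,
# paired augmentation, and image/label I/O.

#' Class palette for blastocyst ground truth
#'
#' Fixed class order and display colors: background = black (class 0),
#' ZP = green (1), TE = red (2), BL = yellow (3), ICM = blue (4).
#'
#' @return data.frame with columns class, name, r, g, b (0-255).
#' @export
blastocystPalette <- function() {
  data.frame(
    class = 0:4,
    name = c("background", "ZP", "TE", "BL", "ICM"),
    r = c(0L, 0L, 255L, 255L, 0L),
    g = c(0L, 255L, 0L, 255L, 0L),
    b = c(0L, 0L, 0L, 0L, 255L),
    stringsAsFactors = FALSE)
}

#' Class names for label indices
#' @param cls integer vector of class indices (0-4).
#' @return character vector of class names.
#' @export
className <- function(cls) blastocystPalette()$name[cls + 1L]

# Accepts images scaled 0..1 (as read by png) or 0..255; returns 0..255.
to255 <- function(img) {
  if (max(img) <= 1 + 1e-9) img * 255 else img
}

#' Decode a color-coded ground-truth image to a label map
#'
#' Assigns every pixel the palette class with the nearest color (Euclidean
#' distance in RGB), provided that distance is within `tolerance`; any pixel
#' farther than `tolerance` from every palette color is an error, reported
#' with its coordinates and color.
#'
#' @param img RGB array (H, W, 3), values in 0..1 or 0..255.
#' @param palette palette data.frame, see [blastocystPalette()].
#' @param tolerance maximum allowed RGB distance (0-255 scale); default 10
#'   absorbs anti-aliased label edges in real exports.
#' @return integer label matrix (H, W) with values 0-4.
#' @export
decodeGT <- function(img, palette = blastocystPalette(), tolerance = 10) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("ground-truth image must be a 3-channel RGB array")
  if (tolerance < 0) stop("tolerance must be non-negative")
  img <- to255(img[, , 1:3, drop = FALSE])
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- matrix(img, h * w, 3)
  K <- nrow(palette)
  d2 <- matrix(0, h * w, K)
  for (k in seq_len(K))
    d2[, k] <- (px[, 1] - palette$r[k])^2 + (px[, 2] - palette$g[k])^2 +
      (px[, 3] - palette$b[k])^2
  best <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(h * w), best)])
  bad <- which(mind > tolerance)
  if (length(bad)) {
    i <- bad[seq_len(min(5L, length(bad)))]
    stop(sprintf(
      "%d pixel(s) match no palette color within tolerance %g; e.g. %s",
      length(bad), tolerance,
      paste(sprintf("(%d,%d)=[%d,%d,%d]",
                    (i - 1L) %% h + 1L, (i - 1L) %/% h + 1L,
                    round(px[i, 1]), round(px[i, 2]), round(px[i, 3])),
            collapse = ", ")))
  }
  matrix(palette$class[best], h, w)
}

#' Render a label map with the class palette
#'
#' Inverse of [decodeGT()] at tolerance 0: produces the color-coded RGB
#' image of a label map.
#'
#' @param labelMap integer matrix (H, W), classes 0-4.
#' @param palette palette data.frame.
#' @return RGB array (H, W, 3), values 0-255.
#' @export
renderLabelMap <- function(labelMap, palette = blastocystPalette()) {
  idx <- as.vector(labelMap) + 1L
  h <- nrow(labelMap); w <- ncol(labelMap)
  array(as.numeric(c(palette$r[idx], palette$g[idx], palette$b[idx])),
        c(h, w, 3))
}

#' One-hot encode a label map
#'
#' @param labelMap integer matrix with values in `[0, numClasses)`.
#' @param numClasses number of channels (default 5).
#' @return binary array (H, W, numClasses); channel c+1 is 1 exactly where
#'   the label is c.
#' @export
encodeOneHot <- function(labelMap, numClasses = 5L) {
  lv <- as.vector(labelMap)
  if (any(lv < 0 | lv >= numClasses))
    stop(sprintf("labels out of range [0, %d)", numClasses))
  h <- nrow(labelMap); w <- ncol(labelMap)
  m <- matrix(0, h * w, numClasses)
  m[cbind(seq_len(h * w), lv + 1L)] <- 1
  array(m, c(h, w, numClasses))
}

#' Decode a (one-hot) mask stack to a label map
#'
#' The argmax over channels, with ties broken toward the lowest class
#' index.  A stack that is not strictly one-hot (per-pixel channel sum not
#' equal to 1) is still decoded but flagged with a warning and the
#' `"oneHot"` attribute set to FALSE.
#'
#' @param maskStack array (H, W, K).
#' @return integer label matrix (H, W) with values `0..K-1`.
#' @export
decodeOneHot <- function(maskStack) {
  d <- dim(maskStack)
  m <- matrix(maskStack, d[1] * d[2], d[3])
  onehot <- all(m %in% c(0, 1)) && all(abs(rowSums(m) - 1) < 1e-9)
  if (!onehot)
    warning("mask stack is not strictly one-hot; ties broken toward the lowest class")
  lab <- matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
  structure(lab, oneHot = onehot)
}

#' Deterministic train/test split
#'
#' @param nTotal number of items.
#' @param trainFraction fraction assigned to training; the train size is
#'   `round(nTotal * trainFraction)` (235 at 0.85 gives 200/35).
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return list with sorted integer vectors `train` and `test`, a disjoint
#'   exhaustive partition of `1:nTotal`.
#' @export
splitDataset <- function(nTotal, trainFraction = 0.85, seed = 1L) {
  if (nTotal <= 0L) stop("nTotal must be positive")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nTrain <- round(nTotal * trainFraction)
  train <- sort(sample.int(nTotal, nTrain))
  list(train = train, test = setdiff(seq_len(nTotal), train))
}

# ---- paired augmentation -------------------------------------------------

tf_flip <- function(horizontal = TRUE, vertical = FALSE)
  list(kind = "flip", horizontal = horizontal, vertical = vertical,
       name = paste0("flip", if (horizontal) "H" else "", if (vertical) "V" else ""))

tf_rotate <- function(degrees, flipH = FALSE)
  list(kind = "rotate", degrees = degrees, flipH = flipH,
       name = sprintf("rot%+g%s", degrees, if (flipH) "+flipH" else ""))

tf_translate <- function(dr, dc)
  list(kind = "translate", dr = dr, dc = dc,
       name = sprintf("shift(%+d,%+d)", dr, dc))

#' The 16-transform augmentation plan
#'
#' The fixed plan that expands every source image--GT pair sixteen-fold
#' (200 pairs become 3200): horizontal, vertical and double flip; rotations
#' by +-5, +-10 and +-15 degrees; translations by (+-10, 0), (0, +-10) and
#' the two (+-10, +-10) diagonals; plus a horizontally flipped +-5 degree
#' rotation pair.  Images are resampled bilinearly, label maps with nearest
#' neighbour; the originals are not included in the output.
#'
#' @return an \linkS4class{AugmentationPlan} of exactly 16 transforms.
#' @export
defaultAugmentationPlan <- function() {
  new("AugmentationPlan", transforms = list(
    tf_flip(TRUE, FALSE), tf_flip(FALSE, TRUE), tf_flip(TRUE, TRUE),
    tf_rotate(5), tf_rotate(-5), tf_rotate(10), tf_rotate(-10),
    tf_rotate(15), tf_rotate(-15),
    tf_translate(10, 0), tf_translate(-10, 0),
    tf_translate(0, 10), tf_translate(0, -10),
    tf_translate(10, 10), tf_translate(-10, -10),
    tf_rotate(5, flipH = TRUE)))
}

# Inverse-mapped affine resampling.  Source coordinates for every target
# pixel; image channels sample bilinearly with clamp-to-edge, labels sample
# nearest-neighbour with out-of-range pixels set to the background class.
affine_coords <- function(h, w, tf) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  if (tf$kind == "flip") {
    sr <- if (tf$vertical) h + 1 - r else r
    sc <- if (tf$horizontal) w + 1 - c else c
  } else if (tf$kind == "translate") {
    sr <- r - tf$dr
    sc <- c - tf$dc
  } else if (tf$kind == "rotate") {
    cth <- cos(tf$degrees * pi / 180); sth <- sin(tf$degrees * pi / 180)
    dc <- c - cc
    if (isTRUE(tf$flipH)) dc <- -dc
    dr <- r - cr
    sr <- cr + cth * dr - sth * dc
    sc <- cc + sth * dr + cth * dc
  } else stop("unknown transform kind: ", tf$kind)
  list(sr = sr, sc = sc)
}

warp_image <- function(img, co) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  r0 <- floor(co$sr); c0 <- floor(co$sc)
  fr <- co$sr - r0; fc <- co$sc - c0
  cl <- function(x, n) pmin(pmax(x, 1), n)
  i00 <- cbind(as.vector(cl(r0, h)), as.vector(cl(c0, w)))
  i01 <- cbind(as.vector(cl(r0, h)), as.vector(cl(c0 + 1, w)))
  i10 <- cbind(as.vector(cl(r0 + 1, h)), as.vector(cl(c0, w)))
  i11 <- cbind(as.vector(cl(r0 + 1, h)), as.vector(cl(c0 + 1, w)))
  out <- array(0, dim(img))
  frv <- as.vector(fr); fcv <- as.vector(fc)
  for (k in seq_len(nc)) {
    ch <- img[, , k]
    v <- (1 - frv) * ((1 - fcv) * ch[i00] + fcv * ch[i01]) +
      frv * ((1 - fcv) * ch[i10] + fcv * ch[i11])
    out[, , k] <- v
  }
  out
}

warp_labels <- function(labelMap, co, fill = 0L) {
  h <- nrow(labelMap); w <- ncol(labelMap)
  rn <- round(co$sr); cn <- round(co$sc)
  inside <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
  out <- matrix(fill, h, w)
  idx <- cbind(as.vector(pmin(pmax(rn, 1), h)), as.vector(pmin(pmax(cn, 1), w)))
  vals <- labelMap[idx]
  out[as.vector(inside)] <- vals[as.vector(inside)]
  out
}

#' Apply one transform to an image--label pair
#'
#' @param image RGB array (H, W, 3).
#' @param labelMap integer matrix (H, W).
#' @param tf a transform descriptor from an \linkS4class{AugmentationPlan}.
#' @return list(image, labelMap, name).
#' @export
applyTransform <- function(image, labelMap, tf) {
  if (!all(dim(image)[1:2] == dim(labelMap)))
    stop("image and label map dims disagree")
  if (tf$kind == "identity")
    return(list(image = image, labelMap = labelMap, name = "identity"))
  co <- affine_coords(nrow(labelMap), ncol(labelMap), tf)
  list(image = warp_image(image, co),
       labelMap = warp_labels(labelMap, co),
       name = tf$name)
}

#' Augment a set of image--GT pairs
#'
#' Applies every transform of the plan to every pair, yielding
#' `length(plan) * n` transformed pairs (16-fold with the default plan; the
#' originals are not included).  Ground truth is warped with
#' nearest-neighbour sampling so no new class labels can appear except the
#' background fill at exposed borders.
#'
#' @param images list of RGB arrays.
#' @param labelMaps list of label matrices, same length and dims.
#' @param plan an \linkS4class{AugmentationPlan}.
#' @return list with `images`, `labelMaps` and a character `provenance`
#'   vector of "source_index:transform" strings.
#' @export
augmentPairs <- function(images, labelMaps, plan = defaultAugmentationPlan()) {
  if (length(images) != length(labelMaps))
    stop("images and labelMaps must have the same length")
  nt <- length(plan@transforms)
  outI <- vector("list", nt * length(images))
  outL <- vector("list", nt * length(images))
  prov <- character(nt * length(images))
  k <- 0L
  for (i in seq_along(images)) {
    for (t in plan@transforms) {
      k <- k + 1L
      r <- applyTransform(images[[i]], labelMaps[[i]], t)
      outI[[k]] <- r$image
      outL[[k]] <- r$labelMap
      prov[k] <- paste0(i, ":", r$name)
    }
  }
  list(images = outI, labelMaps = outL, provenance = prov)
}

# ---- image / label map I/O ----------------------------------------------

#' Read an RGB image
#'
#' PNG files are read with the png package; other formats (BMP, JPEG, TIFF)
#' via EBImage.  16-bit input is scaled to the 0-255 range.
#'
#' @param path file path.
#' @return RGB array (H, W, 3), values 0-255.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    img <- aperm(EBImage::imageData(e), if (length(dim(e)) == 3L) c(2, 1, 3) else c(2, 1))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an RGB image as PNG
#'
#' @param img RGB array (H, W, 3), values 0-255 (or 0-1).
#' @param path output path (.png).
#' @export
writeImageRGB <- function(img, path) {
  img <- to255(img)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Read / write label maps as index PNGs
#'
#' Label maps are stored as single-channel 8-bit PNGs whose pixel value is
#' the class index, a lossless round trip.  [writeLabelMapRGB()] writes the
#' palette-rendered color version instead (decodable with [decodeGT()]).
#'
#' @param path file path.
#' @return integer label matrix.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L)
    stop("not an index label map (multi-channel PNG); use decodeGT() on color-coded ground truth")
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname readLabelMap
#' @param labelMap integer matrix, classes 0-4.
#' @export
writeLabelMap <- function(labelMap, path) {
  png::writePNG(labelMap / 255, path)
  invisible(path)
}

#' @rdname readLabelMap
#' @param palette palette data.frame.
#' @export
writeLabelMapRGB <- function(labelMap, path, palette = blastocystPalette()) {
  writeImageRGB(renderLabelMap(labelMap, palette), path)
}
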