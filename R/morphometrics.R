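# Error-overlay rendering and mask-based morphometrics.

#' @describeIn OverlayStyle default style: class colors from
#'   [blastocystPalette()], pink false negatives, black false positives.
#' @export
defaultOverlayStyle <- function() {
  pal <- blastocystPalette()
  new("OverlayStyle",
      classColors = as.matrix(pal[, c("r", "g", "b")]),
      fnColor = c(255, 105, 180), fpColor = c(0, 0, 0))
}

setValidity("OverlayStyle", function(object) {
  cc <- object@classColors
  if (nrow(cc) != 5L || ncol(cc) != 3L) return("classColors must be 5 x 3")
  for (col in list(object@fnColor)) {
    if (any(apply(cc, 1, function(x) all(x == col))))
      return("FN color must differ from every class color")
  }
  TRUE
})

#' Render the prediction/ground-truth disagreement overlay
#'
#' Pixels where prediction and ground truth agree are painted with the
#' class color.  Disagreeing pixels whose ground truth is a foreground
#' component are painted pink (a false negative for that component);
#' disagreeing pixels lying on ground-truth background (a foreground class
#' predicted where there is none) are painted black, the false-positive
#' convention.  Black is also the background class color, so false
#' positives are only distinguishable over ground-truth background, which
#' is where they are defined.
#'
#' @param pred,gt integer label matrices of identical shape.
#' @param style an \linkS4class{OverlayStyle}.
#' @return RGB array (H, W, 3), values 0-255.
#' @export
overlayErrors <- function(pred, gt, style = defaultOverlayStyle()) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  h <- nrow(gt); w <- ncol(gt)
  cc <- style@classColors
  out <- matrix(0, h * w, 3)
  gv <- as.vector(gt); pv <- as.vector(pred)
  agree <- pv == gv
  out[agree, ] <- cc[gv[agree] + 1L, , drop = FALSE]
  fn <- !agree & gv > 0L
  if (any(fn)) out[fn, ] <- matrix(style@fnColor, sum(fn), 3, byrow = TRUE)
  fp <- !agree & gv == 0L
  if (any(fp)) out[fp, ] <- matrix(style@fpColor, sum(fp), 3, byrow = TRUE)
  array(out, c(h, w, 3))
}

#' Pixel area and image fraction of one class
#'
#' @param labelMap integer label matrix.
#' @param classId class index (0-4).
#' @return list with `pixels` (exact count) and `fraction` (of the image).
#' @export
componentArea <- function(labelMap, classId) {
  if (classId < 0 || classId > 4) stop("classId must be in 0..4")
  n <- sum(labelMap == classId)
  list(pixels = n, fraction = n / length(labelMap))
}

# Medial-axis pixels: foreground pixels whose Euclidean distance-to-
# background is a local maximum (ties allowed) over the 8-neighbourhood.
medial_axis_distances <- function(mask) {
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- EBImage::imageData(dm)
  h <- nrow(d); w <- ncol(d)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- d
  mx <- matrix(-Inf, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    mx <- pmax(mx, pad[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)])
  }
  ridge <- d > 0 & d >= mx
  d[ridge]
}

#' Zona pellucida thickness from a label map
#'
#' Thickness is estimated from the medial axis of the ZP region: the mean
#' distance-to-boundary along the ridge of the Euclidean distance
#' transform, doubled (with a half-pixel correction for the pixel-centre
#' to boundary offset).  A per-angle thickness profile around the region
#' centroid (radial extent per 5-degree bin) is returned alongside.
#'
#' @param labelMap integer label matrix.
#' @return list with `present` (logical), `mean`, `min`, `max` thickness in
#'   pixels (NA when absent), and `profile` (data.frame angle/thickness).
#' @export
zpThickness <- function(labelMap) {
  mask <- labelMap == 1L
  if (!any(mask))
    return(list(present = FALSE, mean = NA_real_, min = NA_real_,
                max = NA_real_, profile = NULL))
  md <- medial_axis_distances(mask)
  th <- 2 * (md - 0.5)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  bin <- floor((ang + pi) / (5 * pi / 180))
  prof <- do.call(rbind, lapply(split(rad, bin), function(r)
    c(thickness = max(r) - min(r) + 1)))
  profile <- data.frame(angle = (as.numeric(rownames(prof)) + 0.5) * 5 - 180,
                        thickness = prof[, "thickness"])
  list(present = TRUE, mean = mean(th), min = min(th), max = max(th),
       profile = profile)
}

#' Blastocoel formation indicator
#'
#' TRUE when the blastocoel (class 3) occupies at least `minFraction` of
#' the image.  The default threshold (1%) is a tool parameter for flagging
#' cavity formation in masks, not a clinical criterion.
#'
#' @param labelMap integer label matrix.
#' @param minFraction area-fraction threshold in [0, 1).
#' @return list with `present` (logical) and `fraction`.
#' @export
blastocoelPresence <- function(labelMap, minFraction = 0.01) {
  if (minFraction < 0 || minFraction >= 1)
    stop("minFraction must lie in [0, 1)")
  a <- componentArea(labelMap, 3L)
  list(present = a$fraction >= minFraction, fraction = a$fraction)
}

#' Full morphometrics report for a label map
#'
#' Per-class areas and image fractions, ZP thickness, blastocoel presence
#' and per-class centroids (a neutral reading of component "position").
#'
#' @param labelMap integer label matrix.
#' @param blMinFraction threshold for [blastocoelPresence()].
#' @return a \linkS4class{MorphometricsReport}.
#' @export
morphometricsReport <- function(labelMap, blMinFraction = 0.01) {
  pal <- blastocystPalette()
  areas <- vapply(pal$class, function(k) componentArea(labelMap, k)$pixels, 0)
  names(areas) <- pal$name
  cent <- t(vapply(pal$class, function(k) {
    idx <- which(labelMap == k, arr.ind = TRUE)
    if (nrow(idx) == 0L) c(NA_real_, NA_real_) else colMeans(idx)
  }, numeric(2)))
  dimnames(cent) <- list(pal$name, c("row", "col"))
  zp <- zpThickness(labelMap)
  bl <- blastocoelPresence(labelMap, blMinFraction)
  new("MorphometricsReport", areas = areas,
      fractions = areas / length(labelMap),
      zpThicknessPx = zp[c("present", "mean", "min", "max")],
      blPresent = bl$present, blFraction = bl$fraction, centroids = cent)
}

#' Convert a morphometrics report to a plain list (for JSON export)
#' @param report a \linkS4class{MorphometricsReport}.
#' @return nested list mirroring the report slots.
#' @export
morphometricsAsList <- function(report) {
  list(schema = "sssnet-morphometrics-1",
       areas = as.list(report@areas),
       fractions = as.list(report@fractions),
       zpThicknessPx = report@zpThicknessPx,
       blastocoel = list(present = report@blPresent,
                         fraction = report@blFraction),
       centroids = apply(report@centroids, 1, as.list))
}
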