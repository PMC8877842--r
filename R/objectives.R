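# Training objective (Tversky) and evaluation protocol (Jaccard).

as_class_matrix <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  db <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(db[1] * db[2] * db[4], db[3])
  m
}

check_mask_pair <- function(probs, gt) {
  dp <- dim(probs); dg <- dim(gt)
  if (length(dp) != length(dg) || any(dp != dg))
    stop("probability and ground-truth masks must have identical shape")
  gv <- as.vector(gt)
  if (any(gv != 0 & gv != 1))
    stop("ground truth must be a binary one-hot mask")
}

#' Tversky overlap index
#'
#' Computes, per class, the smoothed Tversky ratio
#' \deqn{T_c = \frac{\sum_i p_{ic} g_{ic} + \omega}
#'   {\sum_i p_{ic} g_{ic} + \omega + \alpha \sum_i (1-p_{ic}) g_{ic}
#'    + \beta \sum_i p_{ic} (1-g_{ic}) + \omega}}
#' where \eqn{p} are predicted foreground probabilities and \eqn{g} binary
#' ground-truth indicators, summed over all pixels (and batch images), and
#' returns the unweighted mean over classes.  \eqn{\alpha} penalises false
#' negatives and \eqn{\beta} false positives.  At \eqn{\alpha=\beta=0.5} and
#' binary predictions this reduces to the Dice coefficient.
#'
#' @param probs array (H, W, K) or (H, W, K, N) of class probabilities.
#' @param gt one-hot binary array of the same shape.
#' @param params a \linkS4class{TverskyParams}.
#' @return the mean index in (0, 1], with attribute `"perClass"`.
#' @export
tverskyIndex <- function(probs, gt, params = tverskyParams()) {
  validObject(params)
  check_mask_pair(probs, gt)
  P <- as_class_matrix(probs)
  G <- as_class_matrix(gt)
  S <- colSums(P * G)
  FNw <- colSums((1 - P) * G)
  FPw <- colSums(P * (1 - G))
  om <- params@omega
  ti <- (S + om) / (S + om + params@alpha * FNw + params@beta * FPw + om)
  structure(mean(ti), perClass = ti)
}

#' Tversky loss
#'
#' One minus the mean [tverskyIndex()]; zero at a perfect prediction and
#' differentiable in the probabilities, which makes it the training
#' objective for class-imbalanced segmentation.
#'
#' @inheritParams tverskyIndex
#' @return non-negative scalar.
#' @export
tverskyLoss <- function(probs, gt, params = tverskyParams()) {
  ti <- tverskyIndex(probs, gt, params)
  structure(1 - as.numeric(ti), perClass = 1 - attr(ti, "perClass"))
}

# Gradient of the Tversky loss with respect to the probabilities, same
# shape as probs.
tversky_grad <- function(probs, gt, params) {
  d <- dim(probs)
  P <- as_class_matrix(probs)
  G <- as_class_matrix(gt)
  K <- ncol(P)
  S <- colSums(P * G)
  FNw <- colSums((1 - P) * G)
  FPw <- colSums(P * (1 - G))
  om <- params@omega
  num <- S + om
  den <- S + om + params@alpha * FNw + params@beta * FPw + om
  # dT_c/dp_ic = [ g D - num (g - alpha g + beta (1-g)) ] / D^2
  dP <- matrix(0, nrow(P), K)
  for (k in seq_len(K)) {
    g <- G[, k]
    dT <- (g * den[k] - num[k] * (g - params@alpha * g + params@beta * (1 - g))) /
      den[k]^2
    dP[, k] <- -dT / K        # loss = 1 - mean_c T_c
  }
  db <- if (length(d) == 3L) c(d, 1L) else d
  dim(dP) <- c(db[1], db[2], db[4], db[3])
  dP <- aperm(dP, c(1, 2, 4, 3))
  if (length(d) == 3L) dim(dP) <- d
  dP
}

# Chain rule through the per-pixel softmax: given dL/dp, return dL/dscores.
softmax_backward <- function(probs, dprobs) {
  d <- dim(probs)
  P <- as_class_matrix(probs)
  dP <- as_class_matrix(dprobs)
  inner <- rowSums(dP * P)
  dS <- P * (dP - inner)
  db <- if (length(d) == 3L) c(d, 1L) else d
  dim(dS) <- c(db[1], db[2], db[4], db[3])
  dS <- aperm(dS, c(1, 2, 4, 3))
  if (length(d) == 3L) dim(dS) <- d
  dS
}

#' Per-class pixel confusion counts
#'
#' Tallies, for every class, the true-positive, false-positive,
#' false-negative and true-negative pixels of a predicted label map against
#' the ground truth.
#'
#' @param pred,gt integer label matrices of identical shape with values in
#'   `[0, numClasses)`.
#' @param numClasses number of classes (default 5).
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(pred, gt, numClasses = 5L) {
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt must have identical shape")
  pv <- as.vector(pred); gv <- as.vector(gt)
  if (any(pv < 0 | pv >= numClasses | gv < 0 | gv >= numClasses))
    stop(sprintf("labels out of range [0, %d)", numClasses))
  n <- length(pv)
  tab <- table(factor(pv, levels = 0:(numClasses - 1L)),
               factor(gv, levels = 0:(numClasses - 1L)))
  tp <- diag(tab)
  fp <- rowSums(tab) - tp
  fn <- colSums(tab) - tp
  tn <- n - tp - fp - fn
  counts <- cbind(TP = as.numeric(tp), FP = as.numeric(fp),
                  FN = as.numeric(fn), TN = as.numeric(tn))
  rownames(counts) <- className(0:(numClasses - 1L))
  new("ConfusionCounts", counts = counts, nPixels = n)
}

#' Combine confusion counts from several images
#'
#' @param ... \linkS4class{ConfusionCounts} objects over the same classes.
#' @return pooled \linkS4class{ConfusionCounts}.
#' @export
poolConfusionCounts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "ConfusionCounts"))
    xs <- xs[[1L]]
  counts <- Reduce(`+`, lapply(xs, function(x) x@counts))
  new("ConfusionCounts", counts = counts,
      nPixels = sum(vapply(xs, function(x) x@nPixels, 0)))
}

#' Jaccard index per class
#'
#' `JI_c = TP_c / (TP_c + FP_c + FN_c)`, the intersection-over-union of the
#' predicted and ground-truth masks of class c.  A class absent from both
#' (zero denominator) scores 1 by convention and is flagged in the
#' `"absent"` attribute.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return named numeric in [0,1] per class, with attribute `"absent"`.
#' @export
jaccardPerClass <- function(counts) {
  validObject(counts)
  cc <- counts@counts
  den <- cc[, "TP"] + cc[, "FP"] + cc[, "FN"]
  ji <- ifelse(den == 0, 1, cc[, "TP"] / pmax(den, 1))
  structure(as.numeric(ji), names = rownames(cc), absent = den == 0)
}

#' Mean Jaccard index
#'
#' Unweighted arithmetic mean of the five per-class Jaccard indices
#' (background, ZP, TE, BL, ICM).
#'
#' @param perClass numeric of length 5 as returned by [jaccardPerClass()].
#' @return scalar in [0, 1].
#' @export
meanJI <- function(perClass) {
  if (length(perClass) != 5L)
    stop("meanJI expects the five per-class values (background, ZP, TE, BL, ICM)")
  if (any(is.na(perClass))) stop("missing per-class Jaccard value")
  mean(perClass)
}
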