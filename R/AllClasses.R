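#' Sprint convolutional block specification
#'
#' Widths of the five internal branches of a sprint convolutional block
#' (SCB).  An SCB feeds its input through a point-wise 1x1 convolution whose
#' output goes in parallel to a 1x3 and a 3x1 asymmetric convolution and a
#' plain 3x3 convolution, while a depth-wise separable branch sees the block
#' input directly; the asymmetric pair is concatenated first, then all
#' branches are concatenated and compressed by an end 1x1 bottleneck.
#'
#' @slot inChannels input channel count.
#' @slot pointwiseWidth channels of the point-wise 1x1 convolution.
#' @slot asymWidth channels of each asymmetric (1x3 and 3x1) convolution.
#' @slot conv3Width channels of the 3x3 convolution branch.
#' @slot sepWidth channels of the depth-wise separable branch.
#' @slot outWidth channels of the end 1x1 bottleneck (the block output).
#' @export
setClass("SCBSpec", representation(
  inChannels = "integer", pointwiseWidth = "integer", asymWidth = "integer",
  conv3Width = "integer", sepWidth = "integer", outWidth = "integer"
))

setValidity("SCBSpec", function(object) {
  w <- c(object@inChannels, object@pointwiseWidth, object@asymWidth,
         object@conv3Width, object@sepWidth, object@outWidth)
  if (any(is.na(w)) || any(w <= 0L)) return("all SCB widths must be positive integers")
  TRUE
})

#' @describeIn SCBSpec constructor.
#' @param inChannels,pointwiseWidth,asymWidth,conv3Width,sepWidth,outWidth
#'   positive integers, see slots.
#' @export
scbSpec <- function(inChannels, pointwiseWidth, asymWidth = pointwiseWidth,
                    conv3Width = pointwiseWidth, sepWidth = pointwiseWidth,
                    outWidth = 2L * pointwiseWidth) {
  new("SCBSpec", inChannels = as.integer(inChannels),
      pointwiseWidth = as.integer(pointwiseWidth),
      asymWidth = as.integer(asymWidth), conv3Width = as.integer(conv3Width),
      sepWidth = as.integer(sepWidth), outWidth = as.integer(outWidth))
}

#' Channel count of the two-branch asymmetric concatenation
#' @param spec an \linkS4class{SCBSpec}.
#' @return integer, `2 * asymWidth`.
#' @export
scbConcatAWidth <- function(spec) 2L * spec@asymWidth

#' Channel count of the full branch concatenation before the end bottleneck
#' @param spec an \linkS4class{SCBSpec}.
#' @return integer, `2 * asymWidth + conv3Width + sepWidth`.
#' @export
scbConcatBWidth <- function(spec)
  2L * spec@asymWidth + spec@conv3Width + spec@sepWidth

#' Network architecture specification
#'
#' Describes the whole encoder--decoder: four SCBs interleaved with three
#' strided 3x3 convolutions (so the bottleneck sits at 1/8 of the input
#' resolution), a four-convolution bridge, three transposed convolutions on
#' the way up, a skip connection per resolution level merged either by
#' element-wise addition (`"residual"`) or depth-wise concatenation plus 1x1
#' projection (`"dense"`), and a pixel classification head with one filter
#' per class.  Both merge styles carry the same number of trainable
#' parameters.
#'
#' @slot variant `"residual"` or `"dense"` skip connectivity.
#' @slot inChannels image channels (3 for RGB).
#' @slot numClasses number of output classes (5 for blastocyst components).
#' @slot scbSpecs list of exactly 4 \linkS4class{SCBSpec}.
#' @slot stridedWidths integer(3), output channels of the strided convolutions.
#' @slot bridgeWidths integer(4), channels of the bridge convolutions.
#' @slot upsampleWidths integer(3), channels of the transposed convolutions
#'   (deepest first).
#' @slot inputDivisor input height/width must be divisible by this (8).
#' @export
setClass("NetworkSpec", representation(
  variant = "character", inChannels = "integer", numClasses = "integer",
  scbSpecs = "list", stridedWidths = "integer", bridgeWidths = "integer",
  upsampleWidths = "integer", inputDivisor = "integer"
))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (!object@variant %in% c("residual", "dense"))
    msg <- c(msg, "variant must be 'residual' or 'dense'")
  if (length(object@scbSpecs) != 4L ||
      !all(vapply(object@scbSpecs, is, TRUE, "SCBSpec")))
    msg <- c(msg, "scbSpecs must hold exactly 4 SCBSpec objects")
  if (length(object@stridedWidths) != 3L)
    msg <- c(msg, "exactly 3 strided convolutions are required")
  if (length(object@bridgeWidths) != 4L)
    msg <- c(msg, "exactly 4 bridge convolutions are required")
  if (length(object@upsampleWidths) != 3L)
    msg <- c(msg, "exactly 3 transposed convolutions are required")
  if (object@inputDivisor != 8L)
    msg <- c(msg, "three 2x downsamplings imply an input divisor of 8")
  if (object@numClasses <= 0L || object@inChannels <= 0L)
    msg <- c(msg, "inChannels and numClasses must be positive")
  if (length(msg) == 0L) {
    # channel plumbing must be consistent
    for (k in 1:3) {
      if (object@scbSpecs[[k + 1]]@inChannels != object@stridedWidths[k])
        msg <- c(msg, sprintf("SCB %d input must match strided conv %d width", k + 1, k))
    }
    if (object@scbSpecs[[1]]@inChannels != object@inChannels)
      msg <- c(msg, "SCB 1 input must match image channels")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn NetworkSpec constructor.
#' @param variant,inChannels,numClasses,scbSpecs,stridedWidths,bridgeWidths,upsampleWidths
#'   see slots.
#' @export
networkSpec <- function(variant = c("dense", "residual"), scbSpecs,
                        stridedWidths, bridgeWidths, upsampleWidths,
                        inChannels = 3L, numClasses = 5L) {
  variant <- match.arg(variant)
  new("NetworkSpec", variant = variant, inChannels = as.integer(inChannels),
      numClasses = as.integer(numClasses), scbSpecs = scbSpecs,
      stridedWidths = as.integer(stridedWidths),
      bridgeWidths = as.integer(bridgeWidths),
      upsampleWidths = as.integer(upsampleWidths), inputDivisor = 8L)
}

#' A built segmentation network
#'
#' Holds the architecture specification together with all trainable
#' parameters (convolution kernels, biases, batch-norm scale/shift) and the
#' non-trainable batch-norm running statistics.  Networks are value objects:
#' [trainNetwork()] returns an updated copy.
#'
#' @slot spec the \linkS4class{NetworkSpec}.
#' @slot params named list of parameter arrays.
#' @slot state named list of batch-norm running means/variances.
#' @slot seed integer seed the weights were initialised from.
#' @export
setClass("SSSNet", representation(
  spec = "NetworkSpec", params = "list", state = "list", seed = "integer"
))

#' A standalone sprint convolutional block
#'
#' @slot spec the \linkS4class{SCBSpec}.
#' @slot params named list of parameter arrays.
#' @slot state batch-norm running statistics.
#' @export
setClass("SCBBlock", representation(
  spec = "SCBSpec", params = "list", state = "list"
))

#' Trainable parameter report
#'
#' @slot total total number of trainable scalars.
#' @slot perLayer data.frame with one row per parameter array (layer, count).
#' @slot flopsPerForward floating-point operations of one forward pass
#'   (multiply-add counted as 2 operations) at the queried input size, or NA.
#' @export
setClass("ParameterReport", representation(
  total = "numeric", perLayer = "data.frame", flopsPerForward = "numeric"
))

setValidity("ParameterReport", function(object) {
  if (abs(object@total - sum(object@perLayer$count)) > 0.5)
    return("total must equal the sum of per-layer counts")
  TRUE
})

#' Tversky loss parameters
#'
#' The Tversky overlap index generalises Dice with asymmetric penalties:
#' `alpha` weights false negatives and `beta` false positives, with
#' `alpha + beta = 1`; `omega` is a small smoothing constant guarding the
#' ratio against empty masks.
#'
#' @slot alpha false-negative weight, in (0,1).
#' @slot beta false-positive weight, in (0,1).
#' @slot omega smoothing constant, > 0.
#' @export
setClass("TverskyParams", representation(
  alpha = "numeric", beta = "numeric", omega = "numeric"
))

setValidity("TverskyParams", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1 || object@beta <= 0 || object@beta >= 1)
    return("alpha and beta must lie in (0,1)")
  if (abs(object@alpha + object@beta - 1) > 1e-9)
    return("alpha + beta must equal 1")
  if (object@omega <= 0) return("omega must be positive")
  TRUE
})

#' @describeIn TverskyParams constructor with the study defaults
#'   (alpha 0.7, beta 0.3, omega 1e-6).
#' @param alpha,beta,omega see slots.
#' @export
tverskyParams <- function(alpha = 0.7, beta = 0.3, omega = 1e-6)
  new("TverskyParams", alpha = alpha, beta = beta, omega = omega)

#' Per-class pixel confusion tallies
#'
#' @slot counts integer matrix, one row per class, columns TP, FP, FN, TN.
#' @slot nPixels total number of pixels tallied.
#' @export
setClass("ConfusionCounts", representation(
  counts = "matrix", nPixels = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  if (!all(colnames(object@counts) == c("TP", "FP", "FN", "TN")))
    return("counts columns must be TP, FP, FN, TN")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(abs(rowSums(object@counts) - object@nPixels) > 0.5))
    return("TP+FP+FN+TN must equal the total pixel count for every class")
  TRUE
})

#' Segmentation evaluation report
#'
#' @slot perClassJI named numeric, Jaccard index per class.
#' @slot meanJI unweighted mean of the per-class values.
#' @slot absentClasses names of classes absent from both prediction and
#'   ground truth (their JI is reported as 1 by convention).
#' @export
setClass("EvalReport", representation(
  perClassJI = "numeric", meanJI = "numeric", absentClasses = "character"
))

#' Training configuration
#'
#' Defaults mirror the study protocol: Adam with initial learning rate 1e-4
#' and epsilon 1e-6, mini-batches of 20 images, 11200 iterations, gradients
#' clipped by their global L2 norm, Tversky loss with alpha 0.7 / beta 0.3.
#'
#' @slot learningRate constant Adam step size.
#' @slot epsilon Adam denominator offset.
#' @slot gradientClip global L2-norm clipping threshold.
#' @slot iterations number of optimisation steps.
#' @slot batchSize images per mini-batch.
#' @slot seed RNG seed controlling batch order.
#' @slot loss \linkS4class{TverskyParams}.
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric", epsilon = "numeric", gradientClip = "numeric",
  iterations = "integer", batchSize = "integer", seed = "integer",
  loss = "TverskyParams"
))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@iterations <= 0L || object@batchSize <= 0L)
    return("iterations and batchSize must be positive")
  TRUE
})

#' @describeIn TrainConfig constructor with the reference protocol defaults.
#' @param learningRate,epsilon,gradientClip,iterations,batchSize,seed,loss
#'   see slots.
#' @export
trainConfig <- function(learningRate = 1e-4, epsilon = 1e-6,
                        gradientClip = 1.0, iterations = 11200L,
                        batchSize = 20L, seed = 1L, loss = tverskyParams()) {
  new("TrainConfig", learningRate = learningRate, epsilon = epsilon,
      gradientClip = gradientClip, iterations = as.integer(iterations),
      batchSize = as.integer(batchSize), seed = as.integer(seed), loss = loss)
}

#' Synthetic blastocyst phantom parameters
#'
#' Geometry and appearance of one synthetic Hoffman-Modulation-Contrast-like
#' blastocyst image: a bright zona pellucida (ZP) annulus enclosing a
#' trophectoderm (TE) cell band, a blastocoel (BL) fluid cavity, and an
#' inner cell mass (ICM) blob attached to the TE on one side.  Gray levels of
#' TE and ICM are kept close (`teIcmContrast`) and the field carries a
#' non-uniform illumination ramp plus Gaussian noise.
#'
#' @slot imageSize square image side in pixels, divisible by 8.
#' @slot center (row, col) of the embryo centre.
#' @slot outerRadius outer ZP radius in pixels.
#' @slot zpThickness ZP annulus thickness in pixels.
#' @slot teThickness TE band thickness in pixels.
#' @slot icmAngle direction of the ICM from the centre, radians.
#' @slot icmRadius ICM blob radius in pixels.
#' @slot ellipticity vertical compression factor, >= 1.
#' @slot classIntensities named numeric, mean gray level per class (0-255)
#'   for background, ZP, TE, BL; the ICM level is derived from TE.
#' @slot teIcmContrast gray-level offset between TE and ICM.
#' @slot illuminationGradient amplitude of the illumination ramp (gray levels).
#' @slot noiseSigma Gaussian pixel noise standard deviation.
#' @slot seed RNG seed for texture, noise and illumination direction.
#' @export
setClass("PhantomParams", representation(
  imageSize = "integer", center = "numeric", outerRadius = "numeric",
  zpThickness = "numeric", teThickness = "numeric", icmAngle = "numeric",
  icmRadius = "numeric", ellipticity = "numeric",
  classIntensities = "numeric", teIcmContrast = "numeric",
  illuminationGradient = "numeric", noiseSigma = "numeric", seed = "integer"
))

setValidity("PhantomParams", function(object) {
  p <- object
  if (p@imageSize %% 8L != 0L) return("imageSize must be divisible by 8")
  if (p@zpThickness <= 0 || p@teThickness <= 0) return("thicknesses must be positive")
  if (p@icmRadius <= 0) return("icmRadius must be positive")
  if (p@outerRadius - p@zpThickness - p@teThickness <= p@icmRadius)
    return("nested geometry violated: outerRadius - zpThickness - teThickness must exceed icmRadius")
  if (p@ellipticity < 1) return("ellipticity must be >= 1")
  if (p@noiseSigma < 0) return("noiseSigma must be non-negative")
  need <- c("background", "ZP", "TE", "BL")
  if (!all(need %in% names(p@classIntensities)))
    return("classIntensities must name background, ZP, TE, BL")
  half <- p@imageSize / 2
  if (p@outerRadius + 2 > half)
    return("geometry does not fit the image")
  TRUE
})

#' A synthetic blastocyst phantom
#'
#' @slot image 8-bit RGB image array (H, W, 3), values 0-255.
#' @slot gt integer label matrix (H, W), classes 0-4.
#' @slot params the generating \linkS4class{PhantomParams}.
#' @export
setClass("Phantom", representation(
  image = "array", gt = "matrix", params = "PhantomParams"
))

#' Paired augmentation plan
#'
#' An ordered list of deterministic transforms (flips, translations, small
#' rotations and flip-rotation combinations), each applied identically to an
#' image and its label map.
#'
#' @slot transforms list of transform descriptors (kind plus parameters).
#' @export
setClass("AugmentationPlan", representation(transforms = "list"))

setValidity("AugmentationPlan", function(object) {
  ok <- vapply(object@transforms, function(t)
    is.list(t) && t$kind %in% c("identity", "flip", "rotate", "translate"), TRUE)
  if (!all(ok)) return("unknown transform kind")
  TRUE
})

#' Error-overlay rendering style
#'
#' @slot classColors 5x3 matrix of 0-255 RGB rows for the agreeing classes.
#' @slot fnColor RGB for false negatives (pink).
#' @slot fpColor RGB for false positives painted over ground-truth
#'   background (black).
#' @export
setClass("OverlayStyle", representation(
  classColors = "matrix", fnColor = "numeric", fpColor = "numeric"
))

#' Training log
#'
#' @slot losses per-iteration training loss.
#' @slot valIters iterations at which validation was run.
#' @slot valMeanJI validation mean Jaccard index at those iterations.
#' @slot elapsed wall-clock seconds.
#' @export
setClass("TrainLog", representation(
  losses = "numeric", valIters = "integer", valMeanJI = "numeric",
  elapsed = "numeric"
))

#' Mask morphometrics report
#'
#' @slot areas named numeric, pixel area per class.
#' @slot fractions named numeric, area / image area per class.
#' @slot zpThicknessPx list with mean/min/max ZP thickness (px) and presence flag.
#' @slot blPresent logical, blastocoel formed (area fraction over threshold).
#' @slot blFraction blastocoel area fraction.
#' @slot centroids 5x2 matrix of per-class centroid (row, col), NA if absent.
#' @export
setClass("MorphometricsReport", representation(
  areas = "numeric", fractions = "numeric", zpThicknessPx = "list",
  blPresent = "logical", blFraction = "numeric", centroids = "matrix"
))
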