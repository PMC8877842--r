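# show() methods for the user-facing classes.

setMethod("show", "SCBSpec", function(object) {
  cat(sprintf(
    "SCBSpec: in %d | pointwise %d, asym 2x%d, 3x3 %d, sep %d -> out %d\n",
    object@inChannels, object@pointwiseWidth, object@asymWidth,
    object@conv3Width, object@sepWidth, object@outWidth))
})

setMethod("show", "NetworkSpec", function(object) {
  outs <- vapply(object@scbSpecs, function(s) s@outWidth, 0L)
  cat(sprintf("NetworkSpec (%s skip connectivity)\n", object@variant))
  cat(sprintf("  encoder: 4 SCBs (out %s), 3 strided convs (%s)\n",
              paste(outs, collapse = "/"),
              paste(object@stridedWidths, collapse = "/")))
  cat(sprintf("  bridge: %s; decoder: 3 transposed convs (%s); %d classes\n",
              paste(object@bridgeWidths, collapse = "/"),
              paste(object@upsampleWidths, collapse = "/"),
              object@numClasses))
  cat(sprintf("  input: %d channels, H and W divisible by %d\n",
              object@inChannels, object@inputDivisor))
})

setMethod("show", "SSSNet", function(object) {
  show(object@spec)
  cat(sprintf("  %s trainable parameters (seed %d)\n",
              format(sum(vapply(object@params, length, 0)), big.mark = ","),
              object@seed))
})

setMethod("show", "ParameterReport", function(object) {
  cat(sprintf("ParameterReport: %s trainable parameters (%.2f M) in %d arrays\n",
              format(object@total, big.mark = ","), object@total / 1e6,
              nrow(object@perLayer)))
  if (!is.na(object@flopsPerForward))
    cat(sprintf("  forward cost: %.2f GFLOPs (multiply-add = 2 ops)\n",
                object@flopsPerForward / 1e9))
})

setMethod("show", "TverskyParams", function(object) {
  cat(sprintf("TverskyParams: alpha %.2f (FN), beta %.2f (FP), omega %g\n",
              object@alpha, object@beta, object@omega))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts over %s pixels\n",
              format(object@nPixels, big.mark = ",")))
  print(object@counts)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (Jaccard index, pooled confusion counts)\n")
  for (nm in names(object@perClassJI))
    cat(sprintf("  %-11s %.4f%s\n", nm, object@perClassJI[[nm]],
                if (nm %in% object@absentClasses) "  [absent: JI = 1 by convention]" else ""))
  cat(sprintf("  mean JI     %.4f\n", object@meanJI))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: Adam lr %g (eps %g), batch %d, %d iterations, clip %g, seed %d\n",
    object@learningRate, object@epsilon, object@batchSize, object@iterations,
    object@gradientClip, object@seed))
  show(object@loss)
})

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf(
    "PhantomParams: %dpx, ZP outer r %.1f (thick %.1f), TE thick %.1f, ICM r %.1f @ %.2f rad\n",
    object@imageSize, object@outerRadius, object@zpThickness,
    object@teThickness, object@icmRadius, object@icmAngle))
  cat(sprintf("  noise sd %.1f, illumination %.1f, TE/ICM contrast %.1f, seed %d\n",
              object@noiseSigma, object@illuminationGradient,
              object@teIcmContrast, object@seed))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom %dx%d px; class pixels: %s\n",
              nrow(object@gt), ncol(object@gt),
              paste(sprintf("%s=%d", blastocystPalette()$name,
                            vapply(0:4, function(k) sum(object@gt == k), 0L)),
                    collapse = ", ")))
})

setMethod("show", "AugmentationPlan", function(object) {
  cat(sprintf("AugmentationPlan with %d paired transforms:\n",
              length(object@transforms)))
  cat(" ", paste(vapply(object@transforms, function(t) t$name, ""),
                 collapse = ", "), "\n")
})

setMethod("show", "MorphometricsReport", function(object) {
  cat("MorphometricsReport\n")
  for (nm in names(object@areas))
    cat(sprintf("  %-11s area %7d px (%5.2f%%)\n", nm, as.integer(object@areas[[nm]]),
                100 * object@fractions[[nm]]))
  z <- object@zpThicknessPx
  if (isTRUE(z$present))
    cat(sprintf("  ZP thickness: mean %.1f px (min %.1f, max %.1f)\n",
                z$mean, z$min, z$max))
  cat(sprintf("  blastocoel %s (%.2f%% of image)\n",
              if (object@blPresent) "present" else "absent",
              100 * object@blFraction))
})

setMethod("show", "TrainLog", function(object) {
  n <- length(object@losses)
  cat(sprintf("TrainLog: %d iterations in %.1f s; loss %.4f -> %.4f\n",
              n, object@elapsed, object@losses[1], object@losses[n]))
  if (length(object@valIters))
    cat(sprintf("  last validation meanJI %.4f (iter %d)\n",
                utils::tail(object@valMeanJI, 1), utils::tail(object@valIters, 1)))
})
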