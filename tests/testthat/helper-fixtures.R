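# Shared fixtures: a tiny architecture for fast structural tests and small
# phantom helpers.  Everything is generated in code; no files are shipped.

tiny_spec <- function(variant = "dense", w = c(2L, 2L, 3L, 3L),
                      numClasses = 5L) {
  outs <- 2L * w
  scbs <- list(scbSpec(3L, w[1]), scbSpec(outs[1], w[2]),
               scbSpec(outs[2], w[3]), scbSpec(outs[3], w[4]))
  networkSpec(variant, scbs, stridedWidths = outs[1:3],
              bridgeWidths = rep(2L * w[4], 4L),
              upsampleWidths = outs[3:1], numClasses = numClasses)
}

random_labelmap <- function(h, w, numClasses = 5L) {
  matrix(sample(0:(numClasses - 1L), h * w, replace = TRUE), h, w)
}

small_phantom <- function(seed = 1L, size = 64L, noise = 6, illum = 12) {
  generatePhantom(phantomParams(imageSize = size, noiseSigma = noise,
                                illuminationGradient = illum, seed = seed))
}

# Brute-force Jaccard via explicit set arithmetic on pixel index sets;
# independent of the confusion-count implementation.
jaccard_bruteforce <- function(pred, gt, numClasses = 5L) {
  vapply(0:(numClasses - 1L), function(k) {
    p <- which(pred == k); g <- which(gt == k)
    u <- length(union(p, g))
    if (u == 0L) 1 else length(intersect(p, g)) / u
  }, 0)
}
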