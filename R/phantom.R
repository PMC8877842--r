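# Synthetic blastocyst phantom generator: nested geometry (ZP annulus,
# TE cell band, BL cavity, lateral ICM blob) with exact ground truth,
# low-contrast gray levels, an illumination ramp and Gaussian noise.

#' @describeIn PhantomParams constructor with defaults emulating a
#'   Hoffman-Modulation-Contrast blastocyst at 128 x 128: a bright ZP
#'   annulus on a mid-gray background, a darker fluid cavity, and TE/ICM
#'   gray levels kept within `teIcmContrast` of each other so the two
#'   tissues are distinguishable mainly by position and texture.
#' @param imageSize,center,outerRadius,zpThickness,teThickness,icmAngle,icmRadius,ellipticity,classIntensities,teIcmContrast,illuminationGradient,noiseSigma,seed
#'   see slots.
#' @export
phantomParams <- function(imageSize = 128L,
                          center = c(imageSize / 2 + 0.5, imageSize / 2 + 0.5),
                          outerRadius = 0.42 * imageSize,
                          zpThickness = 0.07 * imageSize,
                          teThickness = 0.06 * imageSize,
                          icmAngle = pi / 4,
                          icmRadius = 0.13 * imageSize,
                          ellipticity = 1.05,
                          classIntensities = c(background = 95, ZP = 185,
                                               TE = 130, BL = 70),
                          teIcmContrast = 6,
                          illuminationGradient = 20,
                          noiseSigma = 8,
                          seed = 1L) {
  new("PhantomParams", imageSize = as.integer(imageSize), center = center,
      outerRadius = outerRadius, zpThickness = zpThickness,
      teThickness = teThickness, icmAngle = icmAngle, icmRadius = icmRadius,
      ellipticity = ellipticity, classIntensities = classIntensities,
      teIcmContrast = teIcmContrast,
      illuminationGradient = illuminationGradient, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Generate one synthetic blastocyst phantom
#'
#' The ground truth is derived from exact geometry before any noise is
#' applied: pixels outside the outer radius are background, the ZP annulus
#' sits between the outer radius and `outerRadius - zpThickness`, the TE
#' band (textured as a ring of overlapping cell-like discs) lines its
#' inside, the remaining interior is the BL cavity, and an ICM disc is
#' carved out of the cavity touching the TE band at `icmAngle`.  The image
#' is the per-class base intensity plus a planar illumination ramp and
#' Gaussian noise, clipped to [0, 255], replicated to RGB with slight
#' per-channel offsets.  Identical parameters (including seed) give a
#' bit-identical phantom.
#'
#' @param params a \linkS4class{PhantomParams}.
#' @return a \linkS4class{Phantom}.
#' @examples
#' ph <- generatePhantom(phantomParams(seed = 7))
#' table(className(ph@gt))
#' @export
generatePhantom <- function(params = phantomParams()) {
  validObject(params)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(params@seed)
  S <- params@imageSize
  cr <- params@center[1]; cc <- params@center[2]
  r <- matrix(seq_len(S), S, S)
  c <- matrix(seq_len(S), S, S, byrow = TRUE)
  # effective (elliptic) radius: rows compressed by the ellipticity factor
  reff <- sqrt(((r - cr) * params@ellipticity)^2 + (c - cc)^2)
  Ro <- params@outerRadius
  Ri <- Ro - params@zpThickness          # ZP inner = TE outer
  Rt <- Ri - params@teThickness          # TE inner = cavity radius
  gt <- matrix(0L, S, S)
  gt[reff < Ro] <- 1L                    # ZP
  gt[reff < Ri] <- 2L                    # TE band
  gt[reff < Rt] <- 3L                    # BL cavity
  # TE texture: overlapping cell discs along the band mid-line, bulging
  # slightly into the cavity
  Rmid <- (Ri + Rt) / 2
  nCells <- max(6L, round(2 * pi * Rmid / (1.3 * params@teThickness)))
  angs <- seq(0, 2 * pi, length.out = nCells + 1L)[-1L] +
    runif(nCells, -0.05, 0.05)
  dr <- params@teThickness * 0.72
  for (a in angs) {
    dcr <- cr + (Rmid / params@ellipticity) * sin(a)
    dcc <- cc + Rmid * cos(a)
    disc <- (r - dcr)^2 + (c - dcc)^2 < dr^2
    gt[disc & reff < Ri & gt != 0L & gt != 1L] <- 2L
  }
  # ICM: disc attached to the TE band on one side, carved from the cavity
  dIcm <- Rt - 0.85 * params@icmRadius
  icr <- cr + (dIcm / params@ellipticity) * sin(params@icmAngle)
  icc <- cc + dIcm * cos(params@icmAngle)
  icm <- (r - icr)^2 + (c - icc)^2 < params@icmRadius^2
  gt[icm & gt == 3L] <- 4L
  # image: class intensity + illumination ramp + noise
  ci <- params@classIntensities
  base <- c(ci[["background"]], ci[["ZP"]], ci[["TE"]], ci[["BL"]],
            ci[["TE"]] + params@teIcmContrast)
  img <- matrix(base[gt + 1L], S, S)
  theta <- runif(1, 0, 2 * pi)
  ramp <- cos(theta) * (c - cc) / S + sin(theta) * (r - cr) / S
  img <- img + params@illuminationGradient * ramp
  if (params@noiseSigma > 0)
    img <- img + matrix(rnorm(S * S, 0, params@noiseSigma), S, S)
  jit <- runif(3, -2, 2)
  rgb <- array(0, c(S, S, 3))
  for (k in 1:3) rgb[, , k] <- pmin(pmax(img + jit[k], 0), 255)
  new("Phantom", image = rgb, gt = gt, params = params)
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms whose parameters are sampled uniformly from the given
#' ranges under per-item seeds derived from `seed`, and records every
#' parameter in a manifest.
#'
#' @param n number of phantoms.
#' @param imageSize square image side, divisible by 8.
#' @param ranges named list of `c(min, max)` ranges overriding the default
#'   sampling ranges for `outerRadius`, `zpThickness`, `teThickness`,
#'   `icmRadius`, `icmAngle`, `ellipticity`, `noiseSigma`,
#'   `illuminationGradient` (values relative to `imageSize` for the first
#'   four).
#' @param seed master seed.
#' @return list with `phantoms` (list of \linkS4class{Phantom}) and
#'   `manifest` (data.frame of drawn parameters).
#' @export
generateDataset <- function(n, imageSize = 128L, ranges = list(), seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  def <- list(outerRadius = c(0.36, 0.44), zpThickness = c(0.055, 0.085),
              teThickness = c(0.05, 0.07), icmRadius = c(0.11, 0.15),
              icmAngle = c(0, 2 * pi), ellipticity = c(1, 1.12),
              noiseSigma = c(6, 10), illuminationGradient = c(10, 25))
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (!nm %in% names(def)) stop("unknown parameter range: ", nm)
    if (length(rg) != 2L || rg[2] < rg[1]) stop("invalid range for ", nm)
    def[[nm]] <- rg
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  draw <- function(rg) runif(1, rg[1], rg[2])
  rel <- c("outerRadius", "zpThickness", "teThickness", "icmRadius")
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- lapply(def, draw)
    drawn <- v
    for (nm in rel) v[[nm]] <- v[[nm]] * imageSize
    itemSeed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    p <- phantomParams(imageSize = imageSize, outerRadius = v$outerRadius,
                       zpThickness = v$zpThickness, teThickness = v$teThickness,
                       icmRadius = v$icmRadius, icmAngle = v$icmAngle,
                       ellipticity = v$ellipticity, noiseSigma = v$noiseSigma,
                       illuminationGradient = v$illuminationGradient,
                       seed = itemSeed)
    phantoms[[i]] <- generatePhantom(p)
    rows[[i]] <- data.frame(item = i, seed = itemSeed,
                            as.data.frame(drawn[names(def)]))
  }
  list(phantoms = phantoms, manifest = do.call(rbind, rows))
}

#' Write a phantom dataset to disk
#'
#' Writes `phantom_###.png` (image), `gt_###.png` (palette-rendered ground
#' truth), `label_###.png` (index ground truth) and `manifest.csv`.
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return the manifest with file path columns added, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$phantoms)
  man <- dataset$manifest
  man$image <- file.path(dir, sprintf("phantom_%03d.png", seq_len(n)))
  man$gt <- file.path(dir, sprintf("gt_%03d.png", seq_len(n)))
  man$label <- file.path(dir, sprintf("label_%03d.png", seq_len(n)))
  for (i in seq_len(n)) {
    ph <- dataset$phantoms[[i]]
    writeImageRGB(ph@image, man$image[i])
    writeLabelMapRGB(ph@gt, man$gt[i])
    writeLabelMap(ph@gt, man$label[i])
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
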