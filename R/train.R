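# Training loop (Adam + Tversky), inference, evaluation, checkpoints.

# Images enter the network scaled to [0, 1].
input_scale <- function(img) to255(img) / 255

stack_batch <- function(images, idx) {
  d <- dim(images[[idx[1]]])
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (j in seq_along(idx)) x[, , , j] <- input_scale(images[[idx[j]]])
  x
}

stack_gt <- function(labelMaps, idx, numClasses) {
  d <- dim(labelMaps[[idx[1]]])
  g <- array(0, c(d[1], d[2], numClasses, length(idx)))
  for (j in seq_along(idx)) g[, , , j] <- encodeOneHot(labelMaps[[idx[j]]], numClasses)
  g
}

#' Train a segmentation network
#'
#' Minimises the Tversky loss with Adam at a constant learning rate,
#' clipping gradients by their global L2 norm before every step.  The batch
#' order is deterministic under the configuration seed: each epoch is a
#' fresh permutation of the training set, consumed in mini-batches.
#' Optionally evaluates mean JI on a held-aside validation fraction of the
#' training set at regular intervals, and writes periodic checkpoints.
#'
#' @param model an \linkS4class{SSSNet} from [buildNetwork()].
#' @param images list of RGB arrays (H, W, 3), all dims divisible by 8.
#' @param labelMaps list of integer label matrices matching `images`.
#' @param config a \linkS4class{TrainConfig}.
#' @param valEvery run validation every this many iterations (0 = never).
#' @param valFraction fraction of the training data held aside for
#'   validation monitoring (never taken from any test set); ignored when an
#'   explicit validation set is supplied.
#' @param valImages,valLabelMaps optional explicit validation set used for
#'   monitoring instead of carving a fraction out of the training data.
#' @param checkpointEvery write a checkpoint every this many iterations
#'   (0 = only at the end, and only if `checkpointPath` is set).
#' @param checkpointPath optional path for checkpoints (.rds).
#' @param verbose print progress to stderr.
#' @return list with `model` (trained \linkS4class{SSSNet}) and `log`
#'   (\linkS4class{TrainLog}).
#' @export
trainNetwork <- function(model, images, labelMaps, config = trainConfig(),
                         valEvery = 0L, valFraction = 0.1,
                         valImages = NULL, valLabelMaps = NULL,
                         checkpointEvery = 0L, checkpointPath = NULL,
                         verbose = FALSE) {
  validObject(config)
  if (length(images) == 0L) stop("training set is empty")
  if (length(images) != length(labelMaps))
    stop("images and labelMaps must have the same length")
  for (im in images) check_input_dims(model@spec, dim(im)[1], dim(im)[2])
  K <- model@spec@numClasses
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config@seed)

  trainIdx <- seq_along(images)
  valIdx <- integer(0)
  external_val <- !is.null(valImages)
  if (valEvery > 0L && !external_val && length(images) >= 10L) {
    nVal <- max(1L, round(valFraction * length(images)))
    valIdx <- sort(sample(trainIdx, nVal))
    trainIdx <- setdiff(trainIdx, valIdx)
  }
  bs <- min(config@batchSize, length(trainIdx))

  params <- model@params
  state <- model@state
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  losses <- numeric(config@iterations)
  valIters <- integer(0); valJI <- numeric(0)
  order <- sample(trainIdx)
  pos <- 1L
  t0 <- Sys.time()

  for (it in seq_len(config@iterations)) {
    if (pos + bs - 1L > length(order)) { order <- sample(trainIdx); pos <- 1L }
    idx <- order[pos:(pos + bs - 1L)]
    pos <- pos + bs

    x <- stack_batch(images, idx)
    g <- stack_gt(labelMaps, idx, K)

    net <- new("SSSNet", spec = model@spec, params = params, state = state,
               seed = model@seed)
    fw <- network_forward(net, x, training = TRUE)
    lt <- cpp_softmax_tversky(fw$scores, g, config@loss@alpha,
                              config@loss@beta, config@loss@omega)
    loss <- lt$loss
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at iteration %d (batch: %s)",
                   it, paste(idx, collapse = ",")))
    losses[it] <- loss
    state <- as.list(fw$ctx$state)

    gp <- backward_tape(fw$ctx, fw$out, lt$dscores)

    # global L2-norm gradient clipping
    gnames <- names(params)
    sq <- 0
    for (nm in gnames) {
      gv <- if (exists(nm, envir = gp, inherits = FALSE))
        get(nm, envir = gp, inherits = FALSE) else NULL
      if (!is.null(gv)) sq <- sq + sum(gv * gv)
    }
    gnorm <- sqrt(sq)
    scale <- if (gnorm > config@gradientClip) config@gradientClip / gnorm else 1

    bc1 <- 1 - 0.9^it
    bc2 <- 1 - 0.999^it
    for (nm in gnames) {
      if (!exists(nm, envir = gp, inherits = FALSE)) next
      gv <- get(nm, envir = gp, inherits = FALSE) * scale
      mAdam[[nm]] <- 0.9 * mAdam[[nm]] + 0.1 * gv
      vAdam[[nm]] <- 0.999 * vAdam[[nm]] + 0.001 * gv * gv
      step <- config@learningRate * (mAdam[[nm]] / bc1) /
        (sqrt(vAdam[[nm]] / bc2) + config@epsilon)
      params[[nm]] <- params[[nm]] - step
    }
    rm(fw, gp, x, g, lt)

    doVal <- valEvery > 0L && (external_val || length(valIdx)) &&
      (it %% valEvery == 0L || it == config@iterations)
    doCkpt <- !is.null(checkpointPath) &&
      ((checkpointEvery > 0L && it %% checkpointEvery == 0L) ||
         it == config@iterations)
    if (doVal || doCkpt) {
      cur <- new("SSSNet", spec = model@spec, params = params, state = state,
                 seed = model@seed)
      if (doVal) {
        rep <- if (external_val) evaluateNetwork(cur, valImages, valLabelMaps)
               else evaluateNetwork(cur, images[valIdx], labelMaps[valIdx])
        valIters <- c(valIters, it)
        valJI <- c(valJI, rep@meanJI)
        if (verbose)
          message(sprintf("iter %d  loss %.4f  val meanJI %.4f",
                          it, loss, rep@meanJI))
      }
      if (doCkpt) saveCheckpoint(cur, checkpointPath)
    } else if (verbose && it %% 25L == 0L) {
      message(sprintf("iter %d  loss %.4f", it, loss))
    }
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(model = new("SSSNet", spec = model@spec, params = params,
                   state = state, seed = model@seed),
       log = new("TrainLog", losses = losses, valIters = valIters,
                 valMeanJI = valJI, elapsed = elapsed))
}

#' Predict class probabilities for one image
#'
#' @param model a trained \linkS4class{SSSNet}.
#' @param image RGB array (H, W, 3) with H, W divisible by 8.
#' @return probability array (H, W, numClasses).
#' @export
predictProbs <- function(model, image) {
  fw <- network_forward(model, input_scale(image), training = FALSE)
  p <- softmaxHead(fw$scores)
  d <- dim(p)
  array(p, d[1:3])
}

#' Predict a label map for one image
#'
#' Per-pixel argmax over the five-channel probability mask; exact ties are
#' broken toward the lowest class index.  The binarized one-hot mask stack
#' is attached as the `"maskStack"` attribute.
#'
#' @inheritParams predictProbs
#' @return integer label matrix (H, W) with attribute `"maskStack"`.
#' @export
predictLabels <- function(model, image) {
  p <- predictProbs(model, image)
  d <- dim(p)
  m <- matrix(p, d[1] * d[2], d[3])
  lab <- matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
  structure(lab, maskStack = encodeOneHot(lab, d[3]))
}

#' Evaluate a network on a test set
#'
#' Confusion counts are pooled over all test pixels first and the per-class
#' Jaccard indices are computed from the pooled tallies (not averaged per
#' image), then averaged without weighting into the mean JI.
#'
#' @param model a trained \linkS4class{SSSNet}.
#' @param images list of RGB arrays.
#' @param labelMaps list of ground-truth label matrices.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateNetwork <- function(model, images, labelMaps) {
  if (length(images) == 0L) stop("test set is empty")
  K <- model@spec@numClasses
  pooled <- NULL
  for (i in seq_along(images)) {
    pred <- predictLabels(model, images[[i]])
    cc <- confusionCounts(pred, labelMaps[[i]], K)
    pooled <- if (is.null(pooled)) cc else poolConfusionCounts(pooled, cc)
  }
  ji <- jaccardPerClass(pooled)
  new("EvalReport", perClassJI = as.numeric(ji) |> stats::setNames(names(ji)),
      meanJI = meanJI(as.numeric(ji)),
      absentClasses = names(ji)[attr(ji, "absent")])
}

# ---- checkpoints and spec serialization ---------------------------------

spec_to_list <- function(spec) {
  list(variant = spec@variant, inChannels = spec@inChannels,
       numClasses = spec@numClasses,
       scbSpecs = lapply(spec@scbSpecs, function(s) list(
         inChannels = s@inChannels, pointwiseWidth = s@pointwiseWidth,
         asymWidth = s@asymWidth, conv3Width = s@conv3Width,
         sepWidth = s@sepWidth, outWidth = s@outWidth)),
       stridedWidths = spec@stridedWidths, bridgeWidths = spec@bridgeWidths,
       upsampleWidths = spec@upsampleWidths, inputDivisor = spec@inputDivisor)
}

spec_from_list <- function(x) {
  scbs <- lapply(x$scbSpecs, function(s)
    scbSpec(s$inChannels, s$pointwiseWidth, s$asymWidth, s$conv3Width,
            s$sepWidth, s$outWidth))
  networkSpec(x$variant, scbs, x$stridedWidths, x$bridgeWidths,
              x$upsampleWidths, x$inChannels, x$numClasses)
}

#' Serialize a network specification to / from YAML
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param path file path; for `specToYAML` the YAML text is returned
#'   invisibly if `path` is NULL.
#' @return `specFromYAML` returns a \linkS4class{NetworkSpec}.
#' @export
specToYAML <- function(spec, path = NULL) {
  txt <- yaml::as.yaml(spec_to_list(spec))
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname specToYAML
#' @export
specFromYAML <- function(path) {
  spec_from_list(yaml::read_yaml(path))
}

#' Save / load a network checkpoint
#'
#' Checkpoints embed the full \linkS4class{NetworkSpec} (as a plain list)
#' alongside all parameters and batch-norm statistics, so a checkpoint file
#' is self-describing.
#'
#' @param model an \linkS4class{SSSNet}.
#' @param path checkpoint path (.rds).
#' @return `loadCheckpoint` returns the restored \linkS4class{SSSNet}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "sssnet-checkpoint-1", spec = spec_to_list(model@spec),
               params = model@params, state = model@state, seed = model@seed),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "sssnet-checkpoint-1"))
    stop("not a recognised checkpoint file: ", path)
  new("SSSNet", spec = spec_from_list(x$spec), params = x$params,
      state = x$state, seed = as.integer(x$seed))
}
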