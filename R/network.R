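# Architecture assembly: parameter initialisation, the forward graph, and
# the reference width schedule.

he_uniform <- function(d, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(d), -lim, lim), d)
}

conv_param <- function(kh, kw, cin, cout) he_uniform(c(kh, kw, cin, cout),
                                                     kh * kw * cin)

bn_param <- function(params, state, prefix, ch) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, ch)
  params[[paste0(prefix, ".beta")]] <- rep(0, ch)
  state[[paste0(prefix, ".rmean")]] <- rep(0, ch)
  state[[paste0(prefix, ".rvar")]] <- rep(1, ch)
  list(params = params, state = state)
}

init_scb_params <- function(s, p, params = list(), state = list()) {
  params[[paste0(p, ".G.w")]] <- conv_param(1, 1, s@inChannels, s@pointwiseWidth)
  params[[paste0(p, ".G.b")]] <- rep(0, s@pointwiseWidth)
  params[[paste0(p, ".KA.w")]] <- conv_param(1, 3, s@pointwiseWidth, s@asymWidth)
  params[[paste0(p, ".KB.w")]] <- conv_param(3, 1, s@pointwiseWidth, s@asymWidth)
  r <- bn_param(params, state, paste0(p, ".DAbn"), 2L * s@asymWidth)
  params <- r$params; state <- r$state
  params[[paste0(p, ".L.w")]] <- conv_param(3, 3, s@pointwiseWidth, s@conv3Width)
  r <- bn_param(params, state, paste0(p, ".Lbn"), s@conv3Width)
  params <- r$params; state <- r$state
  params[[paste0(p, ".Fdw.w")]] <- array(
    runif(9 * s@inChannels, -sqrt(6 / 9), sqrt(6 / 9)), c(3, 3, s@inChannels))
  params[[paste0(p, ".Fpw.w")]] <- conv_param(1, 1, s@inChannels, s@sepWidth)
  r <- bn_param(params, state, paste0(p, ".Fbn"), s@sepWidth)
  params <- r$params; state <- r$state
  params[[paste0(p, ".O.w")]] <- conv_param(1, 1, scbConcatBWidth(s), s@outWidth)
  r <- bn_param(params, state, paste0(p, ".Obn"), s@outWidth)
  r
}

# Emits the SCB subgraph; returns the name of the block output value.
emit_scb <- function(ctx, p, xin) {
  emit_conv(ctx, paste0(p, ".G"), xin, paste0(p, ".G.w"), paste0(p, ".G.b"))
  emit_conv(ctx, paste0(p, ".KA"), paste0(p, ".G"), paste0(p, ".KA.w"))
  emit_conv(ctx, paste0(p, ".KB"), paste0(p, ".G"), paste0(p, ".KB.w"))
  emit_concat(ctx, paste0(p, ".DA"), c(paste0(p, ".KA"), paste0(p, ".KB")))
  emit_bnrelu(ctx, paste0(p, ".DAr"), paste0(p, ".DA"), paste0(p, ".DAbn"))
  emit_conv(ctx, paste0(p, ".L"), paste0(p, ".G"), paste0(p, ".L.w"))
  emit_bnrelu(ctx, paste0(p, ".Lr"), paste0(p, ".L"), paste0(p, ".Lbn"))
  emit_dwconv(ctx, paste0(p, ".Fd"), xin, paste0(p, ".Fdw.w"))
  emit_conv(ctx, paste0(p, ".Fp"), paste0(p, ".Fd"), paste0(p, ".Fpw.w"))
  emit_bnrelu(ctx, paste0(p, ".Fr"), paste0(p, ".Fp"), paste0(p, ".Fbn"))
  emit_concat(ctx, paste0(p, ".DB"),
              c(paste0(p, ".DAr"), paste0(p, ".Lr"), paste0(p, ".Fr")))
  emit_conv(ctx, paste0(p, ".O"), paste0(p, ".DB"), paste0(p, ".O.w"))
  emit_bnrelu(ctx, paste0(p, ".out"), paste0(p, ".O"), paste0(p, ".Obn"))
  paste0(p, ".out")
}

init_network_params <- function(spec, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  params <- list(); state <- list()
  sw <- spec@stridedWidths
  outs <- vapply(spec@scbSpecs, function(s) s@outWidth, 0L)
  for (k in 1:4) {
    r <- init_scb_params(spec@scbSpecs[[k]], paste0("scb", k), params, state)
    params <- r$params; state <- r$state
    if (k < 4) {
      params[[paste0("str", k, ".w")]] <- conv_param(3, 3, outs[k], sw[k])
      r <- bn_param(params, state, paste0("str", k, "bn"), sw[k])
      params <- r$params; state <- r$state
    }
  }
  bw <- spec@bridgeWidths
  bin <- outs[4]
  for (j in 1:4) {
    params[[paste0("br", j, ".w")]] <- conv_param(3, 3, bin, bw[j])
    r <- bn_param(params, state, paste0("br", j, "bn"), bw[j])
    params <- r$params; state <- r$state
    bin <- bw[j]
  }
  uw <- spec@upsampleWidths
  uin <- bw[4]
  skips <- outs[3:1]
  for (j in 1:3) {
    # transposed kernel dim (4, 4, Cout, Cin)
    params[[paste0("up", j, ".w")]] <- he_uniform(c(4, 4, uw[j], uin), 16 * uin)
    r <- bn_param(params, state, paste0("up", j, "bn"), uw[j])
    params <- r$params; state <- r$state
    u <- uw[j]; s <- skips[j]
    if (spec@variant == "residual") {
      params[[paste0("mg", j, ".up.w")]] <- conv_param(1, 1, u, u)
      params[[paste0("mg", j, ".skip.w")]] <- conv_param(1, 1, s, u)
    } else {
      params[[paste0("mg", j, ".w")]] <- conv_param(1, 1, u + s, u)
    }
    r <- bn_param(params, state, paste0("mg", j, "bn"), u)
    params <- r$params; state <- r$state
    uin <- u
  }
  params[["head.w"]] <- conv_param(1, 1, uw[3], spec@numClasses)
  params[["head.b"]] <- rep(0, spec@numClasses)
  list(params = params, state = state)
}

# Full forward graph; returns the name of the raw score value.
emit_network <- function(ctx, spec, xin) {
  e <- character(4)
  cur <- xin
  for (k in 1:4) {
    e[k] <- emit_scb(ctx, paste0("scb", k), cur)
    cur <- e[k]
    if (k < 4) {
      emit_conv(ctx, paste0("str", k), cur, paste0("str", k, ".w"), stride = 2L)
      emit_bnrelu(ctx, paste0("str", k, "r"), paste0("str", k),
                  paste0("str", k, "bn"))
      cur <- paste0("str", k, "r")
    }
  }
  for (j in 1:4) {
    emit_conv(ctx, paste0("br", j), cur, paste0("br", j, ".w"))
    emit_bnrelu(ctx, paste0("br", j, "r"), paste0("br", j), paste0("br", j, "bn"))
    cur <- paste0("br", j, "r")
  }
  skips <- e[3:1]
  for (j in 1:3) {
    emit_tconv(ctx, paste0("up", j), cur, paste0("up", j, ".w"))
    emit_bnrelu(ctx, paste0("up", j, "r"), paste0("up", j), paste0("up", j, "bn"))
    if (spec@variant == "residual") {
      emit_conv(ctx, paste0("mg", j, ".pu"), paste0("up", j, "r"),
                paste0("mg", j, ".up.w"))
      emit_conv(ctx, paste0("mg", j, ".ps0"), skips[j], paste0("mg", j, ".skip.w"))
      emit_bn(ctx, paste0("mg", j, ".ps"), paste0("mg", j, ".ps0"),
              paste0("mg", j, "bn"))
      emit_add(ctx, paste0("mg", j, ".sum"), paste0("mg", j, ".pu"),
               paste0("mg", j, ".ps"))
      emit_relu(ctx, paste0("mg", j, ".out"), paste0("mg", j, ".sum"))
    } else {
      emit_concat(ctx, paste0("mg", j, ".cc"), c(paste0("up", j, "r"), skips[j]))
      emit_conv(ctx, paste0("mg", j, ".pc"), paste0("mg", j, ".cc"),
                paste0("mg", j, ".w"))
      emit_bnrelu(ctx, paste0("mg", j, ".out"), paste0("mg", j, ".pc"),
                  paste0("mg", j, "bn"))
    }
    cur <- paste0("mg", j, ".out")
  }
  emit_conv(ctx, "scores", cur, "head.w", "head.b")
  "scores"
}

check_input_dims <- function(spec, h, w) {
  d <- spec@inputDivisor
  if (h %% d != 0L || w %% d != 0L)
    stop(sprintf("input spatial dims (%d x %d) must be divisible by %d", h, w, d))
}

#' Build a segmentation network
#'
#' Instantiates all trainable parameters of the encoder--decoder described
#' by a \linkS4class{NetworkSpec}.  Convolution kernels use He-uniform
#' initialisation; batch-norm scale/shift start at 1/0.  Convolutions that
#' feed a batch-norm layer carry no bias; the point-wise convolution inside
#' each SCB and the classification head do.
#'
#' @param spec a \linkS4class{NetworkSpec}, e.g. [referenceNetworkSpec()].
#' @param seed integer seed for weight initialisation.
#' @return an \linkS4class{SSSNet}.
#' @examples
#' net <- buildNetwork(compactNetworkSpec("dense"), seed = 1)
#' countTrainableParameters(net)@total
#' @export
buildNetwork <- function(spec, seed = 1L) {
  validObject(spec)
  r <- init_network_params(spec, seed)
  new("SSSNet", spec = spec, params = r$params, state = r$state,
      seed = as.integer(seed))
}

#' Build a standalone sprint convolutional block
#'
#' @param spec an \linkS4class{SCBSpec}.
#' @param seed integer seed for weight initialisation.
#' @return an \linkS4class{SCBBlock}.
#' @export
buildSCB <- function(spec, seed = 1L) {
  validObject(spec)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  r <- init_scb_params(spec, "scb")
  new("SCBBlock", spec = spec, params = r$params, state = r$state)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Run a sprint convolutional block forward
#'
#' @param block an \linkS4class{SCBBlock}.
#' @param x array (H, W, C) or (H, W, C, N) with C equal to the block's
#'   input channel count.
#' @param training logical; use batch statistics (TRUE) or running
#'   statistics (FALSE) in batch norm.
#' @return array of shape (H, W, outWidth, N): all branches use same
#'   padding, so the spatial size is preserved.
#' @export
scbForward <- function(block, x, training = FALSE) {
  x <- as_batch(x)
  if (dim(x)[3] != block@spec@inChannels)
    stop(sprintf("input has %d channels; block expects %d",
                 dim(x)[3], block@spec@inChannels))
  ctx <- ctx_new(block@params, block@state, training)
  vset(ctx, "x", x)
  out <- emit_scb(ctx, "scb", "x")
  vget(ctx, out)
}

# Forward pass of the full network; returns raw scores (H, W, K, N) plus,
# in training mode, the tape context for the backward pass.
network_forward <- function(net, x, training = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  check_input_dims(net@spec, d[1], d[2])
  if (d[3] != net@spec@inChannels)
    stop(sprintf("input has %d channels; network expects %d", d[3],
                 net@spec@inChannels))
  ctx <- ctx_new(net@params, net@state, training)
  vset(ctx, "x", x)
  out <- emit_network(ctx, net@spec, "x")
  list(scores = vget(ctx, out), ctx = ctx, out = out)
}

#' Per-pixel softmax over class scores
#'
#' Converts a raw score map to a five-channel probability mask whose
#' per-pixel channel values sum to 1.
#'
#' @param scores array (H, W, K) or (H, W, K, N) of raw class scores.
#' @return array of the same shape with probabilities in [0, 1].
#' @export
softmaxHead <- function(scores) {
  if (!all(is.finite(scores))) stop("non-finite scores passed to softmaxHead")
  d <- dim(scores)
  batched <- length(d) == 4L
  if (!batched) dim(scores) <- c(d, 1L)
  db <- dim(scores)
  K <- db[3]
  m <- aperm(scores, c(1, 2, 4, 3))
  dim(m) <- c(db[1] * db[2] * db[4], K)
  mx <- m[, 1]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, m[, k])
  m <- exp(m - mx)
  m <- m / rowSums(m)
  dim(m) <- c(db[1], db[2], db[4], K)
  p <- aperm(m, c(1, 2, 4, 3))
  if (!batched) dim(p) <- d
  p
}

#' Reference architecture width schedule
#'
#' The width schedule used throughout: SCB inner widths (40, 68, 84, 108)
#' with output widths twice the inner width, channel-preserving strided
#' convolutions, a four-convolution bridge at 216 channels, and a decoder
#' mirroring the encoder widths (168, 136, 80).  Under this schedule the
#' total trainable parameter count is 4,039,980 for both skip variants,
#' i.e. 4.04 million.
#'
#' @param variant `"residual"` or `"dense"`.
#' @return a \linkS4class{NetworkSpec}.
#' @export
referenceNetworkSpec <- function(variant = c("dense", "residual")) {
  variant <- match.arg(variant)
  w <- c(40L, 68L, 84L, 108L)
  outs <- 2L * w
  scbs <- list(
    scbSpec(3L, w[1]),
    scbSpec(outs[1], w[2]),
    scbSpec(outs[2], w[3]),
    scbSpec(outs[3], w[4]))
  networkSpec(variant, scbs, stridedWidths = outs[1:3],
              bridgeWidths = rep(2L * w[4], 4L),
              upsampleWidths = outs[3:1])
}

#' Compact width schedule for CPU-scale experiments
#'
#' A narrow version of the reference schedule (same topology, SCB inner
#' widths 8/12/16/24, 175,380 parameters) used for desk-scale training runs
#' and examples where a 4-million-parameter network would be needlessly
#' slow.  Among narrow schedules this width was chosen because it trades a
#' higher per-iteration cost for far fewer iterations to a given accuracy
#' on the phantom task, which is the better bargain on a CPU.
#'
#' @param variant `"residual"` or `"dense"`.
#' @return a \linkS4class{NetworkSpec}.
#' @export
compactNetworkSpec <- function(variant = c("dense", "residual")) {
  variant <- match.arg(variant)
  w <- c(8L, 12L, 16L, 24L)
  outs <- 2L * w
  scbs <- list(
    scbSpec(3L, w[1]),
    scbSpec(outs[1], w[2]),
    scbSpec(outs[2], w[3]),
    scbSpec(outs[3], w[4]))
  networkSpec(variant, scbs, stridedWidths = outs[1:3],
              bridgeWidths = rep(2L * w[4], 4L),
              upsampleWidths = outs[3:1])
}

#' Count trainable parameters
#'
#' Sums every learnable scalar: convolution kernels, biases, and batch-norm
#' scale/shift pairs (running statistics are not trainable and are not
#' counted).  Optionally estimates the floating-point cost of one forward
#' pass at a given input size (one multiply-add counted as 2 operations;
#' convolutions and transposed convolutions only, normalisation and
#' activations excluded).
#'
#' @param model an \linkS4class{SSSNet} or \linkS4class{SCBBlock}.
#' @param inputSize optional c(H, W) at which to estimate FLOPs.
#' @return a \linkS4class{ParameterReport}.
#' @export
countTrainableParameters <- function(model, inputSize = NULL) {
  pl <- data.frame(layer = names(model@params),
                   count = vapply(model@params, length, 0),
                   row.names = NULL, stringsAsFactors = FALSE)
  fl <- NA_real_
  if (!is.null(inputSize) && is(model, "SSSNet"))
    fl <- estimate_flops(model@spec, inputSize[1], inputSize[2])
  new("ParameterReport", total = sum(pl$count), perLayer = pl,
      flopsPerForward = fl)
}

# 2 * multiply-adds of all (transposed) convolutions at input H x W.
estimate_flops <- function(spec, H, W) {
  check_input_dims(spec, H, W)
  macs <- 0
  hw <- H * W
  outs <- vapply(spec@scbSpecs, function(s) s@outWidth, 0L)
  for (k in 1:4) {
    s <- spec@scbSpecs[[k]]
    macs <- macs + hw * (s@inChannels * s@pointwiseWidth +      # G (1x1)
      3 * s@pointwiseWidth * s@asymWidth * 2 +                  # KA, KB
      9 * s@pointwiseWidth * s@conv3Width +                     # L
      9 * s@inChannels + s@inChannels * s@sepWidth +            # sep
      scbConcatBWidth(s) * s@outWidth)                          # bottleneck
    if (k < 4) {
      hw <- hw / 4
      macs <- macs + hw * 9 * outs[k] * spec@stridedWidths[k]
    }
  }
  bin <- outs[4]
  for (j in 1:4) {
    macs <- macs + hw * 9 * bin * spec@bridgeWidths[j]
    bin <- spec@bridgeWidths[j]
  }
  uin <- spec@bridgeWidths[4]
  skips <- outs[3:1]
  for (j in 1:3) {
    u <- spec@upsampleWidths[j]
    macs <- macs + hw * 16 * uin * u      # transposed conv, counted at input res
    hw <- hw * 4
    macs <- macs + hw * (u * u + skips[j] * u)   # merge projections
    uin <- u
  }
  macs <- macs + hw * spec@upsampleWidths[3] * spec@numClasses
  2 * macs
}
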