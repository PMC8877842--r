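# Minimal reverse-mode tape over the C++ convolutional primitives.
#
# Feature values live in ctx$vals keyed by value name; trainable parameters
# in ctx$params keyed by parameter name.  Every emit_* computes the value
# and, in training mode, appends a tape entry; backward_tape() walks the
# tape in reverse accumulating gradients for values and parameters.

ctx_new <- function(params, state, training) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$state <- state
  ctx$training <- isTRUE(training)
  ctx$vals <- new.env(parent = emptyenv())
  ctx$tape <- vector("list", 0L)
  ctx$bn_eps <- 1e-5
  ctx$bn_momentum <- 0.1
  ctx
}

vget <- function(ctx, name) get(name, envir = ctx$vals, inherits = FALSE)
vset <- function(ctx, name, v) assign(name, v, envir = ctx$vals)
tape_rec <- function(ctx, entry) {
  if (ctx$training) ctx$tape[[length(ctx$tape) + 1L]] <- entry
  invisible(NULL)
}

same_pad <- function(k) as.integer((k - 1L) %/% 2L)

emit_conv <- function(ctx, out, xn, wn, bn = NULL, stride = 1L) {
  x <- vget(ctx, xn)
  w <- ctx$params[[wn]]
  kd <- dim(w)
  ph <- same_pad(kd[1]); pw <- same_pad(kd[2])
  b <- if (is.null(bn)) NULL else ctx$params[[bn]]
  vset(ctx, out, cpp_conv2d_fwd(x, w, as.integer(stride), ph, pw, b))
  tape_rec(ctx, list(op = "conv", out = out, x = xn, w = wn, b = bn,
                     stride = as.integer(stride), ph = ph, pw = pw))
  out
}

# Transposed convolution, kernel 4x4 stride 2 pad 1: doubles H and W.
# The kernel has dim (4, 4, Cout, Cin); forward is the adjoint of the
# corresponding strided convolution.
emit_tconv <- function(ctx, out, xn, wn) {
  x <- vget(ctx, xn)
  w <- ctx$params[[wn]]
  d <- dim(x)
  vset(ctx, out, cpp_conv2d_bwd_data(x, w, 2L, 1L, 1L, 2L * d[1], 2L * d[2]))
  tape_rec(ctx, list(op = "tconv", out = out, x = xn, w = wn))
  out
}

emit_dwconv <- function(ctx, out, xn, wn) {
  x <- vget(ctx, xn)
  vset(ctx, out, cpp_dwconv_fwd(x, ctx$params[[wn]]))
  tape_rec(ctx, list(op = "dwconv", out = out, x = xn, w = wn))
  out
}

emit_bn <- function(ctx, out, xn, prefix) {
  x <- vget(ctx, xn)
  g <- ctx$params[[paste0(prefix, ".gamma")]]
  b <- ctx$params[[paste0(prefix, ".beta")]]
  if (ctx$training) {
    r <- cpp_bn_fwd(x, g, b, ctx$bn_eps)
    vset(ctx, out, r$y)
    mom <- ctx$bn_momentum
    rm <- paste0(prefix, ".rmean"); rv <- paste0(prefix, ".rvar")
    ctx$state[[rm]] <- (1 - mom) * ctx$state[[rm]] + mom * r$mean
    ctx$state[[rv]] <- (1 - mom) * ctx$state[[rv]] + mom * r$var
    tape_rec(ctx, list(op = "bn", out = out, x = xn, prefix = prefix,
                       mean = r$mean, var = r$var))
  } else {
    vset(ctx, out, cpp_bn_infer(x, g, b,
                                ctx$state[[paste0(prefix, ".rmean")]],
                                ctx$state[[paste0(prefix, ".rvar")]],
                                ctx$bn_eps))
  }
  out
}

# Fused batch-norm + ReLU (training); falls back to the composed ops at
# inference where running statistics are used.
emit_bnrelu <- function(ctx, out, xn, prefix) {
  if (!ctx$training) {
    emit_bn(ctx, paste0(out, ".bn"), xn, prefix)
    x <- vget(ctx, paste0(out, ".bn"))
    vset(ctx, out, cpp_relu(x))
    return(out)
  }
  x <- vget(ctx, xn)
  g <- ctx$params[[paste0(prefix, ".gamma")]]
  b <- ctx$params[[paste0(prefix, ".beta")]]
  r <- cpp_bn_relu_fwd(x, g, b, ctx$bn_eps)
  vset(ctx, out, r$y)
  mom <- ctx$bn_momentum
  rm <- paste0(prefix, ".rmean"); rv <- paste0(prefix, ".rvar")
  ctx$state[[rm]] <- (1 - mom) * ctx$state[[rm]] + mom * r$mean
  ctx$state[[rv]] <- (1 - mom) * ctx$state[[rv]] + mom * r$var
  tape_rec(ctx, list(op = "bnrelu", out = out, x = xn, prefix = prefix,
                     mean = r$mean, var = r$var))
  out
}

emit_relu <- function(ctx, out, xn) {
  y <- cpp_relu(vget(ctx, xn))
  vset(ctx, out, y)
  tape_rec(ctx, list(op = "relu", out = out, x = xn))
  out
}

emit_concat <- function(ctx, out, xns) {
  vs <- lapply(xns, function(n) vget(ctx, n))
  chans <- vapply(vs, function(v) dim(v)[3], 0L)
  vset(ctx, out, cpp_concat_channels(vs))
  tape_rec(ctx, list(op = "concat", out = out, x = xns, chans = chans))
  out
}

emit_add <- function(ctx, out, an, bn) {
  vset(ctx, out, vget(ctx, an) + vget(ctx, bn))
  tape_rec(ctx, list(op = "add", out = out, x = c(an, bn)))
  out
}

# Accumulates gradients.  The stored array is accumulated into in place,
# which is safe because every stored gradient is a freshly allocated array
# private to this accumulator (backward entries that would otherwise store
# an aliased array pass a copy).
grad_acc <- function(genv, name, v) {
  if (exists(name, envir = genv, inherits = FALSE))
    cpp_axpy_inplace(get(name, envir = genv, inherits = FALSE), v)
  else assign(name, v, envir = genv)
}

# Walks the tape backwards from the gradient of the final value.
# Returns an environment of parameter gradients.
backward_tape <- function(ctx, final, dfinal) {
  gv <- new.env(parent = emptyenv())   # value gradients
  gp <- new.env(parent = emptyenv())   # parameter gradients
  assign(final, dfinal, envir = gv)
  for (i in rev(seq_along(ctx$tape))) {
    e <- ctx$tape[[i]]
    if (!exists(e$out, envir = gv, inherits = FALSE)) next
    g <- get(e$out, envir = gv, inherits = FALSE)
    rm(list = e$out, envir = gv)
    switch(e$op,
      conv = {
        x <- vget(ctx, e$x)
        w <- ctx$params[[e$w]]
        kd <- dim(w)
        wb <- cpp_conv2d_bwd_wb(x, g, kd[1], kd[2], e$stride, e$ph, e$pw,
                                !is.null(e$b))
        grad_acc(gp, e$w, wb$dw)
        if (!is.null(e$b)) grad_acc(gp, e$b, wb$db)
        dx <- cpp_conv2d_bwd_data(g, w, e$stride, e$ph, e$pw,
                                  dim(x)[1], dim(x)[2])
        grad_acc(gv, e$x, dx)
      },
      tconv = {
        x <- vget(ctx, e$x)
        w <- ctx$params[[e$w]]
        grad_acc(gv, e$x, cpp_conv2d_fwd(g, w, 2L, 1L, 1L, NULL))
        grad_acc(gp, e$w, cpp_conv2d_bwd_wb(g, x, 4L, 4L, 2L, 1L, 1L, FALSE)$dw)
      },
      dwconv = {
        x <- vget(ctx, e$x)
        w <- ctx$params[[e$w]]
        kd <- dim(w)
        grad_acc(gv, e$x, cpp_dwconv_bwd_data(g, w))
        grad_acc(gp, e$w, cpp_dwconv_bwd_weights(x, g, kd[1], kd[2]))
      },
      bn = {
        x <- vget(ctx, e$x)
        gam <- ctx$params[[paste0(e$prefix, ".gamma")]]
        r <- cpp_bn_bwd(x, g, gam, e$mean, e$var, ctx$bn_eps)
        grad_acc(gp, paste0(e$prefix, ".gamma"), r$dgamma)
        grad_acc(gp, paste0(e$prefix, ".beta"), r$dbeta)
        grad_acc(gv, e$x, r$dx)
      },
      bnrelu = {
        x <- vget(ctx, e$x)
        y <- vget(ctx, e$out)
        gam <- ctx$params[[paste0(e$prefix, ".gamma")]]
        r <- cpp_bn_relu_bwd(x, y, g, gam, e$mean, e$var, ctx$bn_eps)
        grad_acc(gp, paste0(e$prefix, ".gamma"), r$dgamma)
        grad_acc(gp, paste0(e$prefix, ".beta"), r$dbeta)
        grad_acc(gv, e$x, r$dx)
      },
      relu = {
        grad_acc(gv, e$x, cpp_relu_bwd(vget(ctx, e$out), g))
      },
      concat = {
        off <- 0L
        for (j in seq_along(e$x)) {
          grad_acc(gv, e$x[j], cpp_slice_channels(g, off, e$chans[j]))
          off <- off + e$chans[j]
        }
      },
      add = {
        grad_acc(gv, e$x[1], g + 0)
        grad_acc(gv, e$x[2], g)
      },
      stop("unknown tape op: ", e$op)
    )
  }
  gp
}
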