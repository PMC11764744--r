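# Minimal reverse-mode tape used by the training engine.
#
# Feature maps are numeric arrays with dim = c(H, W, C, N).  A "tensor" is an
# environment holding a value and (after backward) a gradient; non-leaf
# tensors carry a closure that maps the output gradient to parent gradients.
# Graphs are rebuilt on every forward pass (define-by-run), so the tape is
# simply the list of nodes in creation order.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$tape <- list()
  g$n <- 0L
  g
}

ag_leaf <- function(value) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$node <- NULL
  class(t) <- "ag_tensor"
  t
}

ag_node <- function(g, value, parents, backward) {
  t <- ag_leaf(value)
  t$parents <- parents
  t$backward <- backward
  g$n <- g$n + 1L
  g$tape[[g$n]] <- t
  t
}

# Reverse sweep over the tape.  Once a node has propagated its gradient,
# none of its fields are needed again (its consumers, which reference its
# value, have already run), so they are released eagerly to keep the peak
# memory of a training step close to the forward-pass footprint.  Callers
# must copy any node value they still need before invoking this.
ag_backward <- function(g, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(g$n))) {
    nd <- g$tape[[i]]
    if (!is.null(nd$grad)) {
      grads <- nd$backward(nd$grad)
      for (j in seq_along(nd$parents)) {
        gj <- grads[[j]]
        if (is.null(gj)) next
        p <- nd$parents[[j]]
        p$grad <- if (is.null(p$grad)) gj else p$grad + gj
      }
    }
    nd$grad <- NULL
    nd$value <- NULL
    nd$backward <- NULL
    nd$parents <- NULL
  }
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ag_conv2d <- function(g, x, w, pad, dil = 1L, groups = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, pad, dil, groups)
  xdim <- dim(x$value); wdim <- dim(w$value)
  ag_node(g, y, list(x, w), function(gy) {
    list(cpp_conv2d_bwd_input(gy, w$value, xdim, pad, dil, groups),
         cpp_conv2d_bwd_weight(x$value, gy, wdim, pad, dil, groups))
  })
}

ag_bias <- function(g, x, b) {
  C <- dim(x$value)[3]
  y <- cpp_chan_affine(x$value, rep(1, C), b$value)
  ag_node(g, y, list(x, b), function(gy) list(gy, cpp_chan_sum(gy)))
}

ag_relu <- function(g, x) {
  y <- cpp_relu_fwd(x$value)
  ag_node(g, y, list(x), function(gy) list(cpp_relu_bwd(gy, y)))
}

ag_add <- function(g, a, b) {
  ag_node(g, a$value + b$value, list(a, b), function(gy) list(gy, gy))
}

ag_mul <- function(g, a, b) {
  ag_node(g, a$value * b$value, list(a, b),
          function(gy) list(gy * b$value, gy * a$value))
}

ag_maxpool2 <- function(g, x) {
  f <- cpp_maxpool2_fwd(x$value)
  xdim <- dim(x$value)
  ag_node(g, f$y, list(x),
          function(gy) list(cpp_maxpool2_bwd(gy, f$idx, xdim)))
}

ag_upsample2 <- function(g, x) {
  xdim <- dim(x$value)
  ag_node(g, cpp_upsample2_fwd(x$value), list(x),
          function(gy) list(cpp_upsample2_bwd(gy, xdim)))
}

ag_concat <- function(g, xs) {
  dims <- lapply(xs, function(t) dim(t$value))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(cs[i]), ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_node(g, out, xs, function(gy) {
    at <- 0L
    lapply(seq_along(xs), function(i) {
      gi <- gy[, , at + seq_len(cs[i]), , drop = FALSE]
      at <<- at + cs[i]
      gi
    })
  })
}

ag_narrow <- function(g, x, from, len) {
  xdim <- dim(x$value)
  idx <- from - 1L + seq_len(len)
  ag_node(g, x$value[, , idx, , drop = FALSE], list(x), function(gy) {
    gx <- array(0, xdim)
    gx[, , idx, ] <- gy
    list(gx)
  })
}

ag_shift <- function(g, x, disp) {
  ag_node(g, shift_apply(x$value, disp), list(x),
          function(gy) list(shift_apply(gy, -disp)))
}

# Batch normalization.  `gamma`/`beta` are length-C tensors, `state` an
# environment with running_mean / running_var (updated in training mode, as
# exponential moving averages with the given momentum; the running variance
# uses the unbiased estimator).
# `relu = TRUE` fuses a ReLU into the same pass (the mask for backward is the
# non-negativity of the stored output).
ag_bn <- function(g, x, gamma, beta, state, training, relu = FALSE,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  C <- d[3]
  if (training) {
    mu <- cpp_chan_sum(x$value) / m
    va <- cpp_chan_dot(x$value, x$value) / m - mu^2
    va[va < 0] <- 0
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (m > 1) va * m / (m - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  aff <- if (relu) cpp_chan_affine_relu else cpp_chan_affine
  y <- aff(x$value, gamma$value * istd,
           beta$value - mu * gamma$value * istd)
  ag_node(g, y, list(x, gamma, beta), function(gy) {
    if (relu) gy <- cpp_relu_bwd(gy, y)
    xhat <- cpp_chan_affine(x$value, istd, -mu * istd)
    dgamma <- cpp_chan_dot(gy, xhat)
    dbeta <- cpp_chan_sum(gy)
    if (training) {
      gx <- cpp_chan_affine(gy - cpp_chan_affine(xhat, dgamma / m, dbeta / m),
                            gamma$value * istd, numeric(C))
    } else {
      gx <- cpp_chan_affine(gy, gamma$value * istd, numeric(C))
    }
    list(gx, dgamma, dbeta)
  })
}

ag_sigmoid <- function(g, x) {
  p <- 1 / (1 + exp(-x$value))
  ag_node(g, p, list(x), function(gy) list(gy * p * (1 - p)))
}

# Composite segmentation loss on logits: mean over class channels of
# 0.5 * BCE + Dice, with BCE computed in the numerically stable
# log-sum-exp form and Dice pooled over the whole batch per class.
ag_composite_loss <- function(g, z, target, eps = 1e-5) {
  d <- dim(z$value)
  C <- d[3]
  hw <- d[1] * d[2]
  npix <- hw * d[4]
  p <- 1 / (1 + exp(-z$value))
  cidx <- function(c) slice.index(array(0, d), 3) == c
  bce_c <- dice_c <- num <- den <- numeric(C)
  inter <- psum <- gsum <- numeric(C)
  for (c in seq_len(C)) {
    zc <- z$value[, , c, ]; gc <- target[, , c, ]; pc <- p[, , c, ]
    bce_c[c] <- mean(pmax(zc, 0) - zc * gc + log1p(exp(-abs(zc))))
    inter[c] <- sum(pc * gc)
    psum[c] <- sum(pc^2)
    gsum[c] <- sum(gc^2)
    dice_c[c] <- 1 - (2 * inter[c] + eps) / (psum[c] + gsum[c] + eps)
  }
  val <- mean(0.5 * bce_c + dice_c)
  ag_node(g, val, list(z), function(gy) {
    gz <- array(0, d)
    for (c in seq_len(C)) {
      gc <- target[, , c, ]; pc <- p[, , c, ]
      dbce <- (pc - gc) / npix
      D <- psum[c] + gsum[c] + eps
      ddice_dp <- -(2 * gc * D - (2 * inter[c] + eps) * 2 * pc) / D^2
      gz[, , c, ] <- (0.5 * dbce + ddice_dp * pc * (1 - pc)) / C
    }
    list(gy * gz)
  })
}
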