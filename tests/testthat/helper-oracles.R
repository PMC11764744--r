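# Shared fixtures and independent oracles for the test suite.

rand_fmap <- function(h, w, c, n = 1, sd = 1) {
  array(stats::rnorm(h * w * c * n, sd = sd), c(h, w, c, n))
}

# Independent dense 2-D convolution ("same" zero padding, odd kernel,
# CNN/cross-correlation orientation), one channel plane at a time; written
# with plain shifted-matrix arithmetic, no package kernels.
naive_conv_plane <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2 * ph, W + 2 * pw)
  xp[ph + seq_len(H), pw + seq_len(W)] <- x
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * xp[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
    }
  }
  out
}

# Independent multi-channel 3x3 convolution: y[., ., o] = sum_c x_c * K[,,c,o]
naive_conv3x3 <- function(x, K) {
  d <- dim(x)
  O <- dim(K)[4]
  out <- array(0, c(d[1], d[2], O, d[4]))
  for (n in seq_len(d[4])) {
    for (o in seq_len(O)) {
      acc <- matrix(0, d[1], d[2])
      for (c in seq_len(d[3]))
        acc <- acc + naive_conv_plane(x[, , c, n], K[, , c, o])
      out[, , o, n] <- acc
    }
  }
  out
}

# True convolution of two 1-channel kernels, the second zero-upsampled by
# rate r (the composition law for cascaded cross-correlations).
compose_kernels <- function(k1, k2, r) {
  k2u <- matrix(0, (nrow(k2) - 1) * r + 1, (ncol(k2) - 1) * r + 1)
  k2u[seq(1, nrow(k2u), by = r), seq(1, ncol(k2u), by = r)] <- k2
  n1 <- nrow(k1); n2 <- nrow(k2u)
  out <- matrix(0, n1 + n2 - 1, n1 + n2 - 1)
  for (i in seq_len(n1))
    for (j in seq_len(n1))
      out[i + seq_len(n2) - 1, j + seq_len(n2) - 1] <-
        out[i + seq_len(n2) - 1, j + seq_len(n2) - 1] + k1[i, j] * k2u
  out
}

# Exhaustive HD95 oracle: boundary by explicit neighbor checks, all pairwise
# distances by double loop over boundary pixels.
oracle_hd95 <- function(a, b, q = 0.95) {
  bound <- function(m) {
    pts <- NULL
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (!m[i, j]) next
        nb <- c(if (i > 1) m[i - 1, j] else FALSE,
                if (i < nrow(m)) m[i + 1, j] else FALSE,
                if (j > 1) m[i, j - 1] else FALSE,
                if (j < ncol(m)) m[i, j + 1] else FALSE)
        if (!all(nb)) pts <- rbind(pts, c(i, j))
      }
    }
    pts
  }
  ae <- !any(a); be <- !any(b)
  if (ae && be) return(0)
  if (ae || be) return(Inf)
  pa <- bound(a); pb <- bound(b)
  dmin_ab <- apply(pa, 1, function(p)
    min(sqrt((pb[, 1] - p[1])^2 + (pb[, 2] - p[2])^2)))
  dmin_ba <- apply(pb, 1, function(p)
    min(sqrt((pa[, 1] - p[1])^2 + (pa[, 2] - p[2])^2)))
  max(stats::quantile(dmin_ab, q, names = FALSE),
      stats::quantile(dmin_ba, q, names = FALSE))
}

tiny_arch <- function(...) {
  arch_config(stage_channels = c(16, 16, 16, 16, 16), ...)
}

# set all entries of the named parameters to zero
zero_params <- function(obj, pattern) {
  for (nm in grep(pattern, names(obj$params), value = TRUE))
    obj$params[[nm]][] <- 0
  obj
}
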