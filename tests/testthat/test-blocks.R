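# The bespoke operators: receptive field formula, DLKA, MSGP, spatial shift,
# SPPW and the aggregating-shift decoder block.

test_that("receptive field formula matches the cascade settings", {
  expect_equal(receptive_field(3, 7, 5), 33)
  expect_equal(receptive_field(3, 3, 5), 13)
  expect_equal(receptive_field(3, 5, 5), 23)
  expect_equal(receptive_field(3, 9, 5), 43)
  expect_equal(receptive_field(1, 1, 5), 1)
  expect_error(receptive_field(2, 7, 5), "odd")
  expect_error(receptive_field(3, -1, 5), "odd|positive")
  expect_error(receptive_field(3, 7, 0), "dilation")
})

test_that("receptive field is strictly increasing in k2 and in r", {
  for (k2 in c(3, 5, 7)) {
    expect_gt(receptive_field(3, k2 + 2, 5), receptive_field(3, k2, 5))
    expect_gt(receptive_field(3, k2, 6), receptive_field(3, k2, 5))
  }
})

test_that("DLKA changes channels, preserves space, and is gated by the attention BN", {
  set.seed(1)
  p <- dlka_params(8, 16)
  x <- rand_fmap(24, 20, 8, 2)
  y <- dlka_forward(x, p)
  expect_equal(dim(y), c(24, 20, 16, 2))
  expect_true(all(is.finite(y)))
  expect_error(dlka_forward(rand_fmap(8, 8, 5), p), "channels")

  # with the attention BN scale and shift zeroed, Att == 0 and the (bias-free)
  # output point-wise conv contributes nothing: the block is the identity on
  # the expanded feature X'
  p0 <- zero_params(p, "^dlka\\.att\\.bn\\.")
  y0 <- dlka_forward(x, p0)
  # recompute X' = relu(bn(pw(x))) from the same weights via a 1-layer path:
  ns <- asNamespace("lkmulite")
  g <- ns$ag_graph()
  st <- ns$make_store(p0$params)
  xpt <- ns$fw_bn(g, ns$ag_conv2d(g, ns$ag_leaf(x),
                                  st[["dlka.expand.conv.w"]], 0L),
                  st, p0$buffers, "dlka.expand.bn", FALSE, relu = TRUE)
  expect_equal(y0, xpt$value, tolerance = 1e-12)
})

test_that("DLKA spatial preservation holds across input sizes", {
  set.seed(2)
  p <- dlka_params(4, 8)
  for (s in c(8, 16, 33, 64)) {
    y <- dlka_forward(rand_fmap(s, s, 4), p)
    expect_equal(dim(y), c(s, s, 8, 1))
  }
})

test_that("the DW o DWD cascade equals the composed dense depthwise kernel", {
  # the identity is exact away from the image border (each stage pads with
  # zeros, so the two paths see different virtual values within the margin)
  set.seed(3)
  ns <- asNamespace("lkmulite")
  S <- 56L
  for (k2 in c(3, 5, 7, 9)) {
    r <- 5L
    C <- 3L
    x <- rand_fmap(S, S, C, 1)
    k1w <- array(rnorm(3 * 3 * C, sd = 0.4), c(3, 3, 1, C))
    k2w <- array(rnorm(k2 * k2 * C, sd = 0.3), c(k2, k2, 1, C))
    casc <- ns$cpp_conv2d_fwd(ns$cpp_conv2d_fwd(x, k1w, 1L, 1L, C),
                              k2w, as.integer(r * (k2 - 1) / 2), r, C)
    R <- receptive_field(3, k2, r)
    core <- (1 + (R - 1) %/% 2):(S - (R - 1) %/% 2)
    for (c in seq_len(C)) {
      comp <- compose_kernels(k1w[, , 1, c], k2w[, , 1, c], r)
      expect_equal(dim(comp), c(R, R))
      dense <- naive_conv_plane(x[, , c, 1], comp)
      expect_lt(max(abs(casc[core, core, c, 1] - dense[core, core])), 1e-4)
    }
  }
})

test_that("MSGP preserves channels and space, and splits into four parts", {
  set.seed(4)
  p <- msgp_params(16)
  x <- rand_fmap(20, 24, 16, 2)
  y <- msgp_forward(x, p)
  expect_equal(dim(y), dim(x))
  expect_error(msgp_params(18), "divisible by 4")
  expect_error(msgp_forward(rand_fmap(8, 8, 12), p), "channels")
  expect_error(msgp_params(16, c(3, 3, 7)), "increasing")

  # with every dilated conv weight and BN zeroed, k2 = k3 = k4 = 0 and the
  # output is Concat(f1, 0, 0, 0) + F
  p0 <- zero_params(zero_params(p, "\\.conv\\.w$"), "\\.bn\\.")
  y0 <- msgp_forward(x, p0)
  expected <- x
  expected[, , 1:4, ] <- expected[, , 1:4, ] + x[, , 1:4, ]
  expect_equal(y0, expected, tolerance = 1e-12)
})

test_that("MSGP spatial preservation holds across sizes and both adder modes", {
  set.seed(5)
  for (adder in c("input", "processed")) {
    p <- msgp_params(8, adder = adder)
    for (s in c(8, 16, 40, 64)) {
      y <- msgp_forward(rand_fmap(s, s, 8), p)
      expect_equal(dim(y), c(s, s, 8, 1))
    }
  }
})

test_that("spatial shift moves each channel group by its unit displacement", {
  disp <- shift_spec()$displacements
  expect_equal(nrow(disp), 8)
  expect_equal(nrow(unique(disp)), 8)
  expect_true(all(abs(disp) <= 1) && !any(disp[, 1] == 0 & disp[, 2] == 0))

  # constant-one input: each channel keeps 1 everywhere except the border
  # row/column vacated by its group's displacement
  x <- array(1, c(5, 5, 8, 1))
  y <- spatial_shift(x)
  for (gi in 1:8) {
    plane <- y[, , gi, 1]
    expected <- matrix(1, 5, 5)
    dy <- disp[gi, 1]; dx <- disp[gi, 2]
    if (dy == 1) expected[1, ] <- 0
    if (dy == -1) expected[5, ] <- 0
    if (dx == 1) expected[, 1] <- 0
    if (dx == -1) expected[, 5] <- 0
    expect_equal(plane, expected)
  }

  # a single nonzero pixel lands at (i, j) + d, or vanishes off-grid
  for (gi in 1:8) {
    x1 <- array(0, c(7, 7, 8, 1))
    x1[4, 4, gi, 1] <- 3
    y1 <- spatial_shift(x1)
    expect_equal(y1[4 + disp[gi, 1], 4 + disp[gi, 2], gi, 1], 3)
    expect_equal(sum(y1 != 0), 1)
    xe <- array(0, c(7, 7, 8, 1))
    xe[if (disp[gi, 1] == 1) 7 else 1, if (disp[gi, 2] == 1) 7 else 1,
       gi, 1] <- 1
    ye <- spatial_shift(xe)
    if (disp[gi, 1] != 0 || disp[gi, 2] != 0)
      expect_true(sum(ye[, , gi, 1] != 0) <= 1)
  }
})

test_that("spatial shift is linear and never increases absolute mass", {
  set.seed(6)
  for (t in 1:5) {
    x <- rand_fmap(9, 11, 16, 2)
    y <- rand_fmap(9, 11, 16, 2)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(spatial_shift(a * x + b * y),
                 a * spatial_shift(x) + b * spatial_shift(y),
                 tolerance = 1e-12)
    expect_lte(sum(abs(spatial_shift(x))), sum(abs(x)))
  }
})

test_that("spatial shift leaves remainder channels unshifted", {
  x <- array(0, c(5, 5, 19, 1))  # base group size 2, remainder 3
  x[3, 3, , 1] <- 1
  y <- spatial_shift(x)
  for (c in 17:19) expect_equal(y[, , c, 1], x[, , c, 1])
  expect_equal(y[3 + 1, 3 + 1, 16, 1], 1)  # group 8 shifted by (1, 1)
})

test_that("SPPW equals the constrained sparse 3x3 convolution", {
  set.seed(7)
  ns <- asNamespace("lkmulite")
  disp <- shift_spec()$displacements
  for (cin in c(16, 32, 96, 416)) {
    cout <- max(4L, cin %/% 5L)
    x <- rand_fmap(12, 12, cin, 1)
    p <- sppw_params(cin, cout)
    y <- sppw_forward(x, p)
    expect_equal(dim(y), c(12, 12, cout, 1))
    # constrained kernel: input channel c contributes only at tap -d_{g(c)}
    W <- p$params[["sppw.conv.w"]]  # (1,1,cin,cout)
    K <- array(0, c(3, 3, cin, cout))
    base <- cin %/% 8
    for (c in seq_len(cin)) {
      gi <- min((c - 1) %/% base + 1, 9)
      d <- if (gi <= 8 && c <= 8 * base) disp[gi, ] else c(0L, 0L)
      K[2 - d[1], 2 - d[2], c, ] <- W[1, 1, c, ]
    }
    ref <- naive_conv3x3(x, K)
    # push the oracle through the same BN + ReLU (inference statistics)
    st <- get("sppw.bn", envir = p$buffers)
    gam <- p$params[["sppw.bn.gamma"]]; bet <- p$params[["sppw.bn.beta"]]
    istd <- 1 / sqrt(st$running_var + 1e-5)
    for (o in seq_len(cout))
      ref[, , o, 1] <- pmax((ref[, , o, 1] - st$running_mean[o]) * istd[o] *
                              gam[o] + bet[o], 0)
    expect_lt(max(abs(y - ref)), 1e-5)
  }
})

test_that("SPPW on zero input yields the broadcast BN shift through ReLU", {
  set.seed(8)
  p <- sppw_params(16, 8)
  p$params[["sppw.bn.beta"]] <- rnorm(8)
  st <- get("sppw.bn", envir = p$buffers)
  y <- sppw_forward(array(0, c(6, 6, 16, 1)), p)
  expected <- pmax(p$params[["sppw.bn.beta"]] -
                     st$running_mean / sqrt(st$running_var + 1e-5) *
                     p$params[["sppw.bn.gamma"]], 0)
  for (o in 1:8) expect_equal(y[, , o, 1], matrix(expected[o], 6, 6))
})

test_that("aggregating-shift decoder has the 1/2 + 1/4 + 1/4 channel budget", {
  set.seed(9)
  p <- aggshift_params(416, 160)
  x <- rand_fmap(16, 16, 416, 1)
  y <- aggshift_decoder_forward(x, p)
  expect_equal(dim(y), c(16, 16, 160, 1))
  for (c0 in c(32, 64, 128, 160))
    expect_equal(c0 %/% 2 + c0 %/% 4 + c0 %/% 4, c0)
  expect_error(aggshift_params(64, 30), "divisible by 4")
})

test_that("zeroing the trailing SPPWs reduces the decoder block to its aggregation", {
  set.seed(10)
  p <- aggshift_params(24, 16)
  x <- rand_fmap(10, 10, 24, 1)
  # zero both trailing convs and their BN parameters: the residual refinement
  # contributes nothing and Y = ReLU(Yd) = Yd (Yd is post-ReLU already)
  p0 <- zero_params(zero_params(p, "^dec\\.tail[12]\\.conv\\.w$"),
                    "^dec\\.tail[12]\\.bn\\.")
  y0 <- aggshift_decoder_forward(x, p0)
  ns <- asNamespace("lkmulite")
  g <- ns$ag_graph(); st <- ns$make_store(p0$params)
  a <- ns$fw_sppw(g, ns$ag_leaf(x), st, p0$buffers, "dec.agg.sppw",
                  "aggshift", FALSE)
  gc <- ns$ag_conv2d(g, ns$ag_leaf(x), st[["dec.agg.gc.conv.w"]], 1L, 1L, 4L)
  gc <- ns$fw_bn(g, gc, st, p0$buffers, "dec.agg.gc.bn", FALSE, relu = TRUE)
  dc <- ns$ag_conv2d(g, ns$ag_leaf(x), st[["dec.agg.dc.conv.w"]], 3L, 3L)
  dc <- ns$fw_bn(g, dc, st, p0$buffers, "dec.agg.dc.bn", FALSE, relu = TRUE)
  yd <- ns$ag_concat(g, list(a, gc, dc))
  expect_equal(y0, yd$value, tolerance = 1e-12)
})
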