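# The bespoke operators of LKMU-Lite: decoupled large-kernel attention
# (DLKA), multi-scale group perception (MSGP), the parameter-free spatial
# shift with point-wise convolution (SPPW), and the aggregating-shift
# decoder block built from them.
#
# Each block exists in two coupled forms that share one "plan":
#   * a plan: the flat list of parameterized layers (name, kind, shapes),
#     consumed by the initializer and by the analytic complexity counter;
#   * a forward: the autograd computation referring to the planned names.

# ---- plan rows -------------------------------------------------------------

plan_row <- function(name, kind, cin = 0L, cout = 0L, k = 1L, dil = 1L,
                     groups = 1L, bias = FALSE, scale = 1L) {
  list(name = name, kind = kind, cin = cin, cout = cout, k = k, dil = dil,
       groups = groups, bias = bias, scale = scale)
}

dlka_plan <- function(pfx, cin, cout, k1, k2, r, scale = 1L) {
  list(
    plan_row(paste0(pfx, ".expand.conv"), "conv", cin, cout, 1L, scale = scale),
    plan_row(paste0(pfx, ".expand.bn"), "bn", cout = cout, scale = scale),
    plan_row(paste0(pfx, ".expand.relu"), "relu", cout = cout, scale = scale),
    plan_row(paste0(pfx, ".dw.conv"), "conv", cout, cout, k1,
             groups = cout, scale = scale),
    plan_row(paste0(pfx, ".dwd.conv"), "conv", cout, cout, k2, dil = r,
             groups = cout, scale = scale),
    plan_row(paste0(pfx, ".att.conv"), "conv", cout, cout, 1L, scale = scale),
    plan_row(paste0(pfx, ".att.bn"), "bn", cout = cout, scale = scale),
    plan_row(paste0(pfx, ".out.conv"), "conv", cout, cout, 1L, scale = scale)
  )
}

msgp_plan <- function(pfx, channels, rates, scale = 1L) {
  q <- channels %/% 4L
  rows <- list()
  for (i in 2:4) {
    p <- paste0(pfx, ".p", i)
    rows <- c(rows, list(
      plan_row(paste0(p, ".conv"), "conv", q, q, 3L, dil = rates[i - 1],
               scale = scale),
      plan_row(paste0(p, ".bn"), "bn", cout = q, scale = scale),
      plan_row(paste0(p, ".relu"), "relu", cout = q, scale = scale)
    ))
  }
  rows
}

sppw_plan <- function(pfx, cin, cout, variant, scale = 1L, relu = TRUE) {
  k <- if (variant == "conv3x3_mod") 3L else 1L
  rows <- list(
    plan_row(paste0(pfx, ".conv"), "conv", cin, cout, k, scale = scale),
    plan_row(paste0(pfx, ".bn"), "bn", cout = cout, scale = scale)
  )
  if (relu)
    rows <- c(rows, list(plan_row(paste0(pfx, ".relu"), "relu",
                                  cout = cout, scale = scale)))
  rows
}

aggshift_plan <- function(pfx, cin, c0, variant, scale = 1L) {
  if (variant == "conv3x3") {
    return(list(
      plan_row(paste0(pfx, ".c1.conv"), "conv", cin, c0, 3L, scale = scale),
      plan_row(paste0(pfx, ".c1.bn"), "bn", cout = c0, scale = scale),
      plan_row(paste0(pfx, ".c1.relu"), "relu", cout = c0, scale = scale),
      plan_row(paste0(pfx, ".c2.conv"), "conv", c0, c0, 3L, scale = scale),
      plan_row(paste0(pfx, ".c2.bn"), "bn", cout = c0, scale = scale),
      plan_row(paste0(pfx, ".proj.conv"), "conv", cin, c0, 1L, scale = scale),
      plan_row(paste0(pfx, ".proj.bn"), "bn", cout = c0, scale = scale),
      plan_row(paste0(pfx, ".out.relu"), "relu", cout = c0, scale = scale)
    ))
  }
  c(
    sppw_plan(paste0(pfx, ".agg.sppw"), cin, c0 %/% 2L, variant, scale),
    list(
      plan_row(paste0(pfx, ".agg.gc.conv"), "conv", cin, c0 %/% 4L, 3L,
               groups = 4L, scale = scale),
      plan_row(paste0(pfx, ".agg.gc.bn"), "bn", cout = c0 %/% 4L, scale = scale),
      plan_row(paste0(pfx, ".agg.gc.relu"), "relu", cout = c0 %/% 4L,
               scale = scale),
      plan_row(paste0(pfx, ".agg.dc.conv"), "conv", cin, c0 %/% 4L, 3L,
               dil = 3L, scale = scale),
      plan_row(paste0(pfx, ".agg.dc.bn"), "bn", cout = c0 %/% 4L, scale = scale),
      plan_row(paste0(pfx, ".agg.dc.relu"), "relu", cout = c0 %/% 4L,
               scale = scale)
    ),
    sppw_plan(paste0(pfx, ".tail1"), c0, c0, variant, scale),
    sppw_plan(paste0(pfx, ".tail2"), c0, c0, variant, scale, relu = FALSE),
    list(plan_row(paste0(pfx, ".out.relu"), "relu", cout = c0, scale = scale))
  )
}

# ---- initialization --------------------------------------------------------

# Kaiming (fan-out) normal initialization for conv weights, BN scale 1 /
# shift 0.  Convolutions followed by batch normalization carry no bias; the
# prediction head (bias = TRUE in its plan row) keeps one, initialized to 0.
init_from_plan <- function(plan) {
  params <- list()
  buffers <- new.env(parent = emptyenv())
  for (row in plan) {
    if (row$kind == "conv") {
      cin_pg <- row$cin %/% row$groups
      fan_out <- row$k * row$k * row$cout / row$groups
      w <- array(stats::rnorm(row$k * row$k * cin_pg * row$cout,
                              sd = sqrt(2 / fan_out)),
                 c(row$k, row$k, cin_pg, row$cout))
      params[[paste0(row$name, ".w")]] <- w
      if (row$bias) params[[paste0(row$name, ".b")]] <- numeric(row$cout)
    } else if (row$kind == "bn") {
      params[[paste0(row$name, ".gamma")]] <- rep(1, row$cout)
      params[[paste0(row$name, ".beta")]] <- rep(0, row$cout)
      st <- new.env(parent = emptyenv())
      st$running_mean <- rep(0, row$cout)
      st$running_var <- rep(1, row$cout)
      assign(row$name, st, envir = buffers)
    }
  }
  list(params = params, buffers = buffers)
}

make_store <- function(params) {
  st <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, ag_leaf(params[[nm]]), envir = st)
  st
}

fw_get <- function(st, nm) {
  if (!exists(nm, envir = st, inherits = FALSE))
    stop("internal: missing parameter tensor '", nm, "'")
  get(nm, envir = st, inherits = FALSE)
}

fw_bn <- function(g, x, st, bufs, nm, training, relu = FALSE) {
  ag_bn(g, x, fw_get(st, paste0(nm, ".gamma")), fw_get(st, paste0(nm, ".beta")),
        get(nm, envir = bufs, inherits = FALSE), training, relu = relu)
}

# ---- block forwards --------------------------------------------------------

fw_dlka <- function(g, x, st, bufs, pfx, k1, k2, r, training) {
  xp <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".expand.conv.w")), 0L)
  xp <- fw_bn(g, xp, st, bufs, paste0(pfx, ".expand.bn"), training,
              relu = TRUE)
  cout <- dim(xp$value)[3]
  t <- ag_conv2d(g, xp, fw_get(st, paste0(pfx, ".dw.conv.w")),
                 (k1 - 1L) %/% 2L, 1L, cout)
  t <- ag_conv2d(g, t, fw_get(st, paste0(pfx, ".dwd.conv.w")),
                 as.integer(r * (k2 - 1L) / 2L), r, cout)
  t <- ag_conv2d(g, t, fw_get(st, paste0(pfx, ".att.conv.w")), 0L)
  att <- fw_bn(g, t, st, bufs, paste0(pfx, ".att.bn"), training)
  gated <- ag_mul(g, att, xp)
  ag_add(g, ag_conv2d(g, gated, fw_get(st, paste0(pfx, ".out.conv.w")), 0L), xp)
}

fw_msgp <- function(g, x, st, bufs, pfx, rates, adder, training) {
  C <- dim(x$value)[3]
  q <- C %/% 4L
  f <- lapply(0:3, function(i) ag_narrow(g, x, i * q + 1L, q))
  ks <- vector("list", 4)
  ks[[1]] <- f[[1]]
  for (i in 2:4) {
    operand <- if (adder == "processed") ks[[i - 1]] else f[[i - 1]]
    s <- ag_add(g, f[[i]], operand)
    rate <- as.integer(rates[i - 1])
    s <- ag_conv2d(g, s, fw_get(st, paste0(pfx, ".p", i, ".conv.w")),
                   rate, rate)
    ks[[i]] <- fw_bn(g, s, st, bufs, paste0(pfx, ".p", i, ".bn"), training,
                     relu = TRUE)
  }
  ag_add(g, ag_concat(g, ks), x)
}

fw_sppw <- function(g, x, st, bufs, pfx, variant, training, relu = TRUE) {
  if (variant == "conv3x3_mod") {
    y <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".conv.w")), 1L)
  } else {
    y <- ag_shift(g, x, shift_displacements())
    y <- ag_conv2d(g, y, fw_get(st, paste0(pfx, ".conv.w")), 0L)
  }
  fw_bn(g, y, st, bufs, paste0(pfx, ".bn"), training, relu = relu)
}

fw_aggshift <- function(g, x, st, bufs, pfx, variant, training) {
  if (variant == "conv3x3") {
    y <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".c1.conv.w")), 1L)
    y <- fw_bn(g, y, st, bufs, paste0(pfx, ".c1.bn"), training, relu = TRUE)
    y <- ag_conv2d(g, y, fw_get(st, paste0(pfx, ".c2.conv.w")), 1L)
    y <- fw_bn(g, y, st, bufs, paste0(pfx, ".c2.bn"), training)
    p <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".proj.conv.w")), 0L)
    p <- fw_bn(g, p, st, bufs, paste0(pfx, ".proj.bn"), training)
    return(ag_relu(g, ag_add(g, y, p)))
  }
  a <- fw_sppw(g, x, st, bufs, paste0(pfx, ".agg.sppw"), variant, training)
  gc <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".agg.gc.conv.w")), 1L, 1L, 4L)
  gc <- fw_bn(g, gc, st, bufs, paste0(pfx, ".agg.gc.bn"), training,
              relu = TRUE)
  dc <- ag_conv2d(g, x, fw_get(st, paste0(pfx, ".agg.dc.conv.w")), 3L, 3L)
  dc <- fw_bn(g, dc, st, bufs, paste0(pfx, ".agg.dc.bn"), training,
              relu = TRUE)
  yd <- ag_concat(g, list(a, gc, dc))
  t <- fw_sppw(g, yd, st, bufs, paste0(pfx, ".tail1"), variant, training)
  t <- fw_sppw(g, t, st, bufs, paste0(pfx, ".tail2"), variant, training,
               relu = FALSE)
  ag_relu(g, ag_add(g, t, yd))
}

# ---- spatial shift ---------------------------------------------------------

shift_displacements <- function() {
  matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L,
           -1L, -1L, -1L, 1L, 1L, -1L, 1L, 1L),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("dy", "dx")))
}

shift_apply <- function(x, disp) {
  storage.mode(disp) <- "integer"
  cpp_shift(x, disp)
}

# ---- public operator API ---------------------------------------------------

#' Equivalent receptive field of a depthwise + depthwise-dilated cascade
#'
#' Side length of the receptive field obtained by cascading a depthwise
#' `k1 x k1` convolution with a depthwise-dilated `k2 x k2` convolution of
#' dilation rate `r`: `R = k1 + k2 + (k2 - 1) * (r - 1) - 1`.
#'
#' @param k1 Kernel size of the depthwise convolution (odd, >= 1).
#' @param k2 Kernel size of the depthwise-dilated convolution (odd, >= 1).
#' @param r Dilation rate (>= 1).
#' @return The receptive-field side length in pixels.
#' @examples
#' receptive_field(3, 7, 5) # 33
#' @export
receptive_field <- function(k1, k2, r) {
  if (k1 < 1 || k2 < 1 || k1 %% 2 == 0 || k2 %% 2 == 0)
    stop("kernel sizes must be positive odd integers")
  if (r < 1) stop("dilation rate must be >= 1")
  k1 + k2 + (k2 - 1) * (r - 1) - 1
}

#' Spatial-shift specification
#'
#' The eight unit displacements and the channel-grouping rule of the
#' parameter-free spatial-shift operation: channels are partitioned into
#' eight contiguous equal groups (channel order), each shifted by one of the
#' eight unit displacements with zero fill; when the channel count is not
#' divisible by eight, the remainder channels are left unshifted.
#'
#' @return A list with the `displacements` matrix (columns `dy`, `dx`).
#' @export
shift_spec <- function() {
  list(displacements = shift_displacements())
}

#' Parameter-free spatial shift
#'
#' Translates each of eight contiguous channel groups of a feature map by one
#' of the eight unit displacements, filling vacated pixels with zeros.
#'
#' @param x Feature map, a 4-D array with dim `c(H, W, C, N)`.
#' @param spec A [shift_spec()].
#' @return A feature map of the same shape.
#' @export
spatial_shift <- function(x, spec = shift_spec()) {
  check_feature_map(x)
  shift_apply(x, spec$displacements)
}

check_feature_map <- function(x) {
  if (!is.numeric(x) || length(dim(x)) != 4)
    stop("feature maps must be 4-D numeric arrays with dim c(H, W, C, N)")
  if (any(dim(x) <= 0) || any(!is.finite(x)))
    stop("feature maps must have positive dimensions and finite values")
  invisible(x)
}

block_object <- function(plan, cfg, class) {
  ini <- init_from_plan(plan)
  structure(list(plan = plan, cfg = cfg, params = ini$params,
                 buffers = ini$buffers), class = c(class, "lkmu_block"))
}

run_block <- function(x, obj, fwd, training = FALSE) {
  check_feature_map(x)
  g <- ag_graph()
  st <- make_store(obj$params)
  out <- fwd(g, ag_leaf(x), st, obj$buffers)
  out$value
}

#' Decoupled large-kernel attention (DLKA) parameters
#'
#' Creates the learnable state of a DLKA block: a channel-expanding
#' point-wise convolution (the only place the stage channel count changes),
#' a depthwise `dw_kernel` convolution cascaded with a depthwise-dilated
#' `dwd_kernel` (rate `dilation`) convolution, an attention point-wise
#' convolution, and an output point-wise convolution.  Weights are drawn
#' from the current RNG state (Kaiming fan-out); convolutions followed by
#' batch normalization are bias-free.
#'
#' @param in_channels,out_channels Channel counts of input and output.
#' @param dw_kernel Depthwise kernel size (odd), default 3.
#' @param dwd_kernel Depthwise-dilated kernel size (odd), default 7.
#' @param dilation Dilation rate of the depthwise-dilated convolution,
#'   default 5.
#' @return An object usable with [dlka_forward()].
#' @export
dlka_params <- function(in_channels, out_channels, dw_kernel = 3L,
                        dwd_kernel = 7L, dilation = 5L) {
  if (out_channels < 1) stop("out_channels must be >= 1")
  if (dw_kernel %% 2 == 0 || dwd_kernel %% 2 == 0)
    stop("kernel sizes must be odd")
  if (dilation < 1) stop("dilation must be >= 1")
  cfg <- list(cin = as.integer(in_channels), cout = as.integer(out_channels),
              k1 = as.integer(dw_kernel), k2 = as.integer(dwd_kernel),
              r = as.integer(dilation))
  block_object(dlka_plan("dlka", cfg$cin, cfg$cout, cfg$k1, cfg$k2, cfg$r),
               cfg, "dlka_params")
}

#' DLKA forward pass
#'
#' Expands channels with a point-wise convolution (BN + ReLU), forms an
#' attention map from the depthwise / depthwise-dilated cascade followed by a
#' point-wise convolution and BN, gates the expanded feature by the attention
#' map (Hadamard product), and applies an output point-wise convolution with
#' a residual connection back to the expanded feature.  Spatial size is
#' preserved.
#'
#' @param x Feature map `c(H, W, in_channels, N)`.
#' @param p A [dlka_params()] object.
#' @param training Use batch statistics (`TRUE`) or running statistics in the
#'   batch-norm layers.
#' @return Feature map `c(H, W, out_channels, N)`.
#' @export
dlka_forward <- function(x, p, training = FALSE) {
  if (dim(x)[3] != p$cfg$cin)
    stop("input has ", dim(x)[3], " channels; DLKA block expects ", p$cfg$cin)
  run_block(x, p, function(g, xt, st, bufs)
    fw_dlka(g, xt, st, bufs, "dlka", p$cfg$k1, p$cfg$k2, p$cfg$r, training))
}

#' Multi-scale group perception (MSGP) parameters
#'
#' @param channels Channel count (divisible by 4).
#' @param dilation_rates Strictly increasing dilation rates of the three
#'   dilated 3x3 convolutions, default `c(3, 7, 11)`.
#' @param adder Operand of the adjacent-path adder: the raw channel split
#'   (`"input"`, default) or the processed previous path (`"processed"`).
#' @return An object usable with [msgp_forward()].
#' @export
msgp_params <- function(channels, dilation_rates = c(3L, 7L, 11L),
                        adder = c("input", "processed")) {
  if (channels %% 4 != 0) stop("channels must be divisible by 4")
  if (any(diff(dilation_rates) <= 0) || length(dilation_rates) != 3)
    stop("dilation_rates must be three strictly increasing values")
  adder <- match.arg(adder)
  cfg <- list(channels = as.integer(channels),
              rates = as.integer(dilation_rates), adder = adder)
  block_object(msgp_plan("msgp", cfg$channels, cfg$rates), cfg, "msgp_params")
}

#' MSGP forward pass
#'
#' Splits the input into four equal channel groups; group 1 passes through
#' unchanged, groups 2-4 add the adjacent group and pass through a dilated
#' 3x3 convolution (rates 3/7/11) with BN + ReLU; the groups are concatenated
#' and a residual connection adds the block input.  Channel count and spatial
#' size are preserved.
#'
#' @inheritParams dlka_forward
#' @param p A [msgp_params()] object.
#' @export
msgp_forward <- function(x, p, training = FALSE) {
  if (dim(x)[3] != p$cfg$channels)
    stop("input has ", dim(x)[3], " channels; MSGP block expects ",
         p$cfg$channels)
  run_block(x, p, function(g, xt, st, bufs)
    fw_msgp(g, xt, st, bufs, "msgp", p$cfg$rates, p$cfg$adder, training))
}

#' Spatial-shift point-wise convolution (SPPW) parameters
#'
#' @param in_channels,out_channels Channel counts.
#' @param variant `"aggshift"` (spatial shift + 1x1 convolution, default) or
#'   `"conv3x3_mod"` (plain 3x3 convolution, the decoder-ablation setting).
#' @return An object usable with [sppw_forward()].
#' @export
sppw_params <- function(in_channels, out_channels,
                        variant = c("aggshift", "conv3x3_mod")) {
  variant <- match.arg(variant)
  cfg <- list(cin = as.integer(in_channels), cout = as.integer(out_channels),
              variant = variant)
  block_object(sppw_plan("sppw", cfg$cin, cfg$cout, variant), cfg,
               "sppw_params")
}

#' SPPW forward pass
#'
#' Applies the parameter-free eight-direction spatial shift followed by a
#' point-wise convolution, batch normalization and ReLU.  Together the shift
#' and the 1x1 convolution span the receptive field of a 3x3 convolution at a
#' fraction of its parameters.
#'
#' @inheritParams dlka_forward
#' @param p A [sppw_params()] object.
#' @export
sppw_forward <- function(x, p, training = FALSE) {
  if (dim(x)[3] != p$cfg$cin)
    stop("input has ", dim(x)[3], " channels; SPPW expects ", p$cfg$cin)
  run_block(x, p, function(g, xt, st, bufs)
    fw_sppw(g, xt, st, bufs, "sppw", p$cfg$variant, training))
}

#' Aggregating-shift decoder block parameters
#'
#' @param in_channels Channels of the concatenated decoder input.
#' @param out_channels Output channels `C0` (divisible by 4); the multi-path
#'   aggregation allocates `C0/2` to the SPPW path and `C0/4` each to the
#'   4-group 3x3 convolution and the rate-3 dilated 3x3 convolution.
#' @param variant Decoder variant: `"aggshift"` (default), `"conv3x3_mod"`
#'   (every SPPW replaced by a 3x3 convolution, aggregation retained) or
#'   `"conv3x3"` (a plain two-layer 3x3 residual block).
#' @return An object usable with [aggshift_decoder_forward()].
#' @export
aggshift_params <- function(in_channels, out_channels,
                            variant = c("aggshift", "conv3x3_mod", "conv3x3")) {
  variant <- match.arg(variant)
  if (out_channels %% 4 != 0) stop("out_channels must be divisible by 4")
  cfg <- list(cin = as.integer(in_channels), c0 = as.integer(out_channels),
              variant = variant)
  block_object(aggshift_plan("dec", cfg$cin, cfg$c0, variant), cfg,
               "aggshift_params")
}

#' Aggregating-shift decoder forward pass
#'
#' Aggregates the input through three parallel paths (SPPW to `C0/2`
#' channels, 4-group 3x3 convolution to `C0/4`, rate-3 dilated 3x3
#' convolution to `C0/4`, each BN + ReLU), concatenates them, and refines the
#' result with two trailing SPPW operators and a residual connection (the
#' second trailing BN output is added pre-activation, then passed through
#' ReLU).
#'
#' @inheritParams dlka_forward
#' @param p An [aggshift_params()] object.
#' @export
aggshift_decoder_forward <- function(x, p, training = FALSE) {
  if (dim(x)[3] != p$cfg$cin)
    stop("input has ", dim(x)[3], " channels; decoder block expects ",
         p$cfg$cin)
  run_block(x, p, function(g, xt, st, bufs)
    fw_aggshift(g, xt, st, bufs, "dec", p$cfg$variant, training))
}
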