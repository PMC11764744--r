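# Assembly of the five-stage U-shaped LKMU-Lite segmentation network.

#' Architecture configuration
#'
#' Structural description of the network: channel widths of the five stages,
#' the depthwise-dilated kernel size of the DLKA blocks (3/5/7/9 give
#' equivalent receptive fields 13/23/33/43 at dilation 5), the MSGP dilation
#' rates, and the decoder variant.
#'
#' @param in_channels Input channels (default 3; grayscale inputs are
#'   replicated so that ImageNet channel statistics apply).
#' @param num_classes Number of foreground classes; each gets an independent
#'   sigmoid logit channel, background is implicit.
#' @param stage_channels Channels of the five encoder stages (each divisible
#'   by 4); the decoder mirrors them in reverse.
#' @param dwd_kernel Depthwise-dilated kernel size in DLKA (odd).
#' @param msgp_rates Dilation rates of the three MSGP paths.
#' @param msgp_adder Adjacent-path adder operand in MSGP, see [msgp_params()].
#' @param decoder_variant `"aggshift"`, `"conv3x3_mod"`, or `"conv3x3"`, see
#'   [aggshift_params()].
#' @return An `arch_config` object.
#' @export
arch_config <- function(in_channels = 3L, num_classes = 1L,
                        stage_channels = c(32L, 64L, 128L, 160L, 256L),
                        dwd_kernel = 7L, msgp_rates = c(3L, 7L, 11L),
                        msgp_adder = c("input", "processed"),
                        decoder_variant = c("aggshift", "conv3x3_mod",
                                            "conv3x3")) {
  if (length(stage_channels) != 5)
    stop("stage_channels must have exactly 5 entries")
  if (any(stage_channels %% 4 != 0) || any(stage_channels <= 0))
    stop("all stage channels must be positive and divisible by 4")
  if (dwd_kernel %% 2 == 0 || dwd_kernel < 1)
    stop("dwd_kernel must be a positive odd integer")
  if (num_classes < 1) stop("num_classes must be >= 1")
  structure(list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    stage_channels = as.integer(stage_channels),
    dwd_kernel = as.integer(dwd_kernel),
    msgp_rates = as.integer(msgp_rates),
    msgp_adder = match.arg(msgp_adder),
    decoder_variant = match.arg(decoder_variant)
  ), class = "arch_config")
}

# Flat layer inventory of the whole network; the single source of truth for
# parameter initialization and for the analytic complexity counter.  `scale`
# is the spatial downsampling factor at which a layer's OUTPUT lives.
net_plan <- function(cfg) {
  ch <- cfg$stage_channels
  rows <- list()
  cin <- cfg$in_channels
  for (s in 1:5) {
    sc <- 2L^(s - 1L)
    rows <- c(rows,
              dlka_plan(paste0("enc", s, ".dlka"), cin, ch[s], 3L,
                        cfg$dwd_kernel, 5L, sc),
              msgp_plan(paste0("enc", s, ".msgp"), ch[s], cfg$msgp_rates, sc))
    if (s < 5)
      rows <- c(rows, list(plan_row(paste0("enc", s, ".pool"), "pool",
                                    cout = ch[s], scale = 2L^s)))
    cin <- ch[s]
  }
  prev <- ch[5]
  for (d in 1:4) {
    sc <- 2L^(4L - d)
    rows <- c(rows, list(plan_row(paste0("dec", d, ".up"), "upsample",
                                  cout = prev, scale = sc)))
    rows <- c(rows, aggshift_plan(paste0("dec", d), prev + ch[5 - d],
                                  ch[5 - d], cfg$decoder_variant, sc))
    prev <- ch[5 - d]
  }
  c(rows, list(plan_row("head.conv", "conv", prev, cfg$num_classes, 1L,
                        bias = TRUE, scale = 1L)))
}

#' Build an LKMU-Lite model
#'
#' Instantiates every learnable tensor of the configured network (Kaiming
#' fan-out initialization for convolution weights, BN scale 1 / shift 0) in a
#' flat registry with stable names.
#'
#' @param cfg An [arch_config()].
#' @param seed Optional integer seed for the weight initialization; when
#'   `NULL` the current RNG state is used.
#' @return An `lkmu_model` object.
#' @export
build_model <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "arch_config")) stop("cfg must be an arch_config object")
  if (!is.null(seed)) set.seed(seed)
  plan <- net_plan(cfg)
  ini <- init_from_plan(plan)
  structure(list(cfg = cfg, plan = plan, params = ini$params,
                 buffers = ini$buffers), class = "lkmu_model")
}

#' @export
print.lkmu_model <- function(x, ...) {
  rep <- count_parameters(x)
  cat("LKMU-Lite segmentation model\n")
  cat("  stage channels:", paste(x$cfg$stage_channels, collapse = "/"),
      " decoder:", x$cfg$decoder_variant, "\n")
  cat("  classes:", x$cfg$num_classes,
      " parameters:", rep$total_params,
      sprintf("(%.2f M)\n", rep$params_M))
  invisible(x)
}

fw_model <- function(g, xt, st, bufs, cfg, training) {
  skips <- vector("list", 5)
  cur <- xt
  for (s in 1:5) {
    cur <- fw_dlka(g, cur, st, bufs, paste0("enc", s, ".dlka"), 3L,
                   cfg$dwd_kernel, 5L, training)
    cur <- fw_msgp(g, cur, st, bufs, paste0("enc", s, ".msgp"),
                   cfg$msgp_rates, cfg$msgp_adder, training)
    skips[[s]] <- cur
    if (s < 5) cur <- ag_maxpool2(g, cur)
  }
  y <- skips[[5]]
  for (d in 1:4) {
    y <- ag_upsample2(g, y)
    y <- ag_concat(g, list(y, skips[[5 - d]]))
    y <- fw_aggshift(g, y, st, bufs, paste0("dec", d), cfg$decoder_variant,
                     training)
  }
  y <- ag_conv2d(g, y, fw_get(st, "head.conv.w"), 0L)
  ag_bias(g, y, fw_get(st, "head.conv.b"))
}

#' Forward pass of a built model
#'
#' @param model An [build_model()] result.
#' @param batch Feature map `c(H, W, in_channels, N)` with `H`, `W` divisible
#'   by 16 (four pooling stages).
#' @param training Use batch statistics in batch norm and update running
#'   statistics (`TRUE`), or run in inference mode (default).
#' @return Logits, `c(H, W, num_classes, N)` (not probabilities).
#' @export
forward <- function(model, batch, training = FALSE) {
  check_feature_map(batch)
  d <- dim(batch)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input spatial dims (", d[1], "x", d[2], ") must be divisible by ",
         "16; pad or resize the image")
  if (d[3] != model$cfg$in_channels)
    stop("input has ", d[3], " channels; model expects ",
         model$cfg$in_channels)
  g <- ag_graph()
  st <- make_store(model$params)
  out <- fw_model(g, ag_leaf(batch), st, model$buffers, model$cfg, training)
  out$value
}

# Forward pass that keeps the graph and parameter leaves, for training.
forward_train <- function(model, batch, training = TRUE) {
  g <- ag_graph()
  st <- make_store(model$params)
  out <- fw_model(g, ag_leaf(batch), st, model$buffers, model$cfg, training)
  list(logits = out, graph = g, store = st)
}

#' Convert logits to a label mask
#'
#' Applies a per-class sigmoid; a pixel is foreground for a class when its
#' probability exceeds `threshold`; when several classes exceed it, the class
#' with the highest probability wins.
#'
#' @param logits Array `c(H, W, C, N)` of per-class logits.
#' @param threshold Foreground probability threshold in (0, 1).
#' @return Integer label array `c(H, W, N)` with values in `0..C`.
#' @export
mask_from_logits <- function(logits, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  d <- dim(logits)
  p <- 1 / (1 + exp(-logits))
  best <- array(p[, , 1, ], c(d[1], d[2], d[4]))
  label <- array(1L, c(d[1], d[2], d[4]))
  for (c in seq_len(d[3])[-1]) {
    pc <- array(p[, , c, ], c(d[1], d[2], d[4]))
    better <- pc > best
    best[better] <- pc[better]
    label[better] <- c
  }
  label[best <= threshold] <- 0L
  label
}

#' Segment one grayscale image
#'
#' Replicates the grayscale image to three channels, normalizes it with the
#' ImageNet channel statistics, runs the model in inference mode and
#' thresholds the per-class probabilities.
#'
#' @param model A built model.
#' @param image Matrix in `[0, 1]` (H x W), spatial dims divisible by 16.
#' @param threshold Foreground probability threshold.
#' @return Integer label matrix (H x W), values `0..num_classes`.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  x <- normalize_image(image)
  dim(x) <- c(dim(x), 1L)
  logits <- forward(model, x)
  mask_from_logits(logits, threshold)[, , 1]
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load model checkpoints
#'
#' The checkpoint is an RDS file holding the configuration, the parameter
#' registry and the batch-norm running statistics, plus a human-readable JSON
#' sidecar (`<path>.json`) with the architecture configuration so checkpoints
#' remain interpretable without loading them.
#'
#' @param model A built model.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  bufs <- lapply(ls(model$buffers), function(nm) {
    st <- get(nm, envir = model$buffers)
    list(running_mean = st$running_mean, running_var = st$running_var)
  })
  names(bufs) <- ls(model$buffers)
  saveRDS(list(cfg = unclass(model$cfg), params = model$params,
               buffers = bufs), path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(arch_config, ck$cfg[c("in_channels", "num_classes",
                                       "stage_channels", "dwd_kernel",
                                       "msgp_rates", "msgp_adder",
                                       "decoder_variant")])
  model <- build_model(cfg)
  if (!identical(sort(names(model$params)), sort(names(ck$params))))
    stop("checkpoint parameter registry does not match the architecture")
  model$params <- ck$params
  for (nm in names(ck$buffers)) {
    st <- get(nm, envir = model$buffers)
    st$running_mean <- ck$buffers[[nm]]$running_mean
    st$running_var <- ck$buffers[[nm]]$running_var
  }
  model
}
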