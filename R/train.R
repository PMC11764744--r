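# Training (Adam + polynomial LR decay + composite loss), checkpoint
# selection by validation loss, evaluation and file-level prediction.

#' Training configuration
#'
#' @param arch An [arch_config()].
#' @param train_manifest,val_manifest Paths to manifest CSVs (image/mask
#'   paths are resolved relative to the manifest's directory).
#' @param out_dir Directory for the log, checkpoints and sidecar files.
#' @param epochs Training epochs (default 150).
#' @param batch_size Mini-batch size (default 8).
#' @param lr Initial Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty added to the gradients (default 1e-4).
#' @param power Polynomial decay exponent (default 0.9).
#' @param seed Seed covering initialization, data order and augmentation.
#' @param augment Apply random flip/rotation augmentation to training data
#'   (validation data is never augmented).
#' @param target_train_dsc Optional early-exit threshold: stop once the
#'   epoch's training Dice reaches this value (used for capacity checks).
#' @return A `train_config` object.
#' @export
train_config <- function(arch, train_manifest, val_manifest, out_dir,
                         epochs = 150L, batch_size = 8L, lr = 1e-3,
                         weight_decay = 1e-4, power = 0.9, seed = 1L,
                         augment = TRUE, target_train_dsc = NULL) {
  stopifnot(inherits(arch, "arch_config"), epochs >= 1, batch_size >= 1,
            lr > 0, weight_decay >= 0, power > 0)
  if (!file.exists(train_manifest)) stop("missing manifest: ", train_manifest)
  if (!file.exists(val_manifest)) stop("missing manifest: ", val_manifest)
  structure(list(arch = arch, train_manifest = train_manifest,
                 val_manifest = val_manifest, out_dir = out_dir,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, power = power,
                 seed = as.integer(seed), augment = augment,
                 target_train_dsc = target_train_dsc),
            class = "train_config")
}

load_samples <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  if (nrow(man) == 0) stop("manifest is empty: ", manifest_path)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(file.path(base, man$image[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(file.path(base, man$mask[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    d <- dim(img)
    if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
      stop("image ", man$image[i], " has size ", d[1], "x", d[2],
           ", not divisible by 16")
    list(image = img, mask = matrix(as.integer(round(msk * 255)), d[1], d[2]),
         id = man$image[i])
  })
}

make_batch <- function(samples, idx, n_classes, do_augment) {
  d <- dim(samples[[idx[1]]]$image)
  n <- length(idx)
  x <- array(0, c(d[1], d[2], 3L, n))
  y <- array(0, c(d[1], d[2], n_classes, n))
  for (j in seq_along(idx)) {
    s <- samples[[idx[j]]]
    if (do_augment) s <- augment(s)
    x[, , , j] <- normalize_image(s$image)
    for (c in seq_len(n_classes)) y[, , c, j] <- as.numeric(s$mask == c)
  }
  list(x = x, y = y)
}

adam_init <- function(params) {
  z <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = z, v = z, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- 0
    g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

batch_dsc_counts <- function(logits, y, threshold = 0.5) {
  C <- dim(y)[3]
  lab <- mask_from_logits(logits, threshold)
  t(vapply(seq_len(C), function(c) {
    p <- lab == c
    g <- array(y[, , c, ] > 0.5, dim(lab))
    c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g))
  }, c(tp = 0, fp = 0, fn = 0)))
}

#' Train a model
#'
#' Runs the full training protocol: Adam with weight decay, polynomial
#' per-epoch learning-rate decay, the composite 0.5*BCE + Dice loss on the
#' logits, optional flip/rotation augmentation, and per-epoch validation.
#' The checkpoint with the lowest validation loss is kept
#' (`out_dir/best.ckpt` with a JSON architecture sidecar); the per-epoch log
#' is written to `out_dir/train_log.csv` with columns
#' `epoch, lr, train_loss, train_dsc, val_loss`.
#'
#' @param cfg A [train_config()].
#' @return Invisibly, a list with the log data frame, `best_epoch`,
#'   `best_val_loss`, the checkpoint path, and the number of epochs run.
#' @export
train <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  model <- build_model(cfg$arch)
  tr <- load_samples(cfg$train_manifest)
  va <- load_samples(cfg$val_manifest)
  nc <- cfg$arch$num_classes
  opt <- adam_init(model$params)
  ckpt <- file.path(cfg$out_dir, "best.ckpt")
  best_val <- Inf
  best_epoch <- NA_integer_
  log_rows <- vector("list", cfg$epochs)
  epochs_run <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- poly_lr(epoch - 1L, cfg$lr, cfg$epochs, cfg$power)
    perm <- sample(length(tr))
    tl_sum <- 0; tl_n <- 0
    counts <- matrix(0, nc, 3)
    for (b in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      batch <- make_batch(tr, b, nc, cfg$augment)
      fw <- forward_train(model, batch$x, training = TRUE)
      loss <- ag_composite_loss(fw$graph, fw$logits, batch$y)
      loss_value <- loss$value
      counts <- counts + batch_dsc_counts(fw$logits$value, batch$y)
      ag_backward(fw$graph, loss)  # releases the activation tape
      grads <- lapply(stats::setNames(nm = names(model$params)),
                      function(nm) fw$store[[nm]]$grad)
      upd <- adam_step(model$params, grads, opt, lr_e, cfg$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      tl_sum <- tl_sum + loss_value * length(b)
      tl_n <- tl_n + length(b)
    }
    train_dsc <- mean(ifelse(2 * counts[, 1] + counts[, 2] + counts[, 3] == 0,
                             1, 2 * counts[, 1] /
                               (2 * counts[, 1] + counts[, 2] + counts[, 3])))
    vl_sum <- 0; vl_n <- 0
    for (b in split(seq_along(va), ceiling(seq_along(va) / cfg$batch_size))) {
      batch <- make_batch(va, b, nc, do_augment = FALSE)
      logits <- forward(model, batch$x, training = FALSE)
      p <- 1 / (1 + exp(-logits))
      vl_sum <- vl_sum + composite_loss(p, batch$y) * length(b)
      vl_n <- vl_n + length(b)
    }
    val_loss <- vl_sum / vl_n
    epochs_run <- epoch
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                                    train_loss = tl_sum / tl_n,
                                    train_dsc = train_dsc,
                                    val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_epoch <- epoch
      save_checkpoint(model, ckpt)
    }
    if (!is.null(cfg$target_train_dsc) &&
        train_dsc >= cfg$target_train_dsc) break
  }
  log <- do.call(rbind, log_rows[seq_len(epochs_run)])
  utils::write.csv(log, file.path(cfg$out_dir, "train_log.csv"),
                   row.names = FALSE)
  invisible(list(log = log, best_epoch = best_epoch, best_val_loss = best_val,
                 checkpoint = ckpt, epochs_run = epochs_run))
}

#' Evaluate a checkpoint on a manifest
#'
#' Computes IoU, DSC, HD95, precision and sensitivity per sample and class,
#' a per-sample mean row, and overall mean rows (sample `"mean"`), all from
#' deterministic inference-mode predictions.
#'
#' @param checkpoint Path to a checkpoint (or a model object).
#' @param manifest Path to a manifest CSV.
#' @param out_csv Optional path for the metrics CSV.
#' @param threshold Foreground probability threshold.
#' @return The metrics data frame.
#' @export
evaluate <- function(checkpoint, manifest, out_csv = NULL, threshold = 0.5) {
  model <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else
    checkpoint
  samples <- load_samples(manifest)
  nc <- model$cfg$num_classes
  max_lab <- max(vapply(samples, function(s) max(s$mask), 0L))
  if (max_lab > nc)
    stop("manifest masks contain label ", max_lab,
         " but the checkpoint predicts ", nc, " classes")
  rows <- lapply(samples, function(s) {
    pred <- predict_mask(model, s$image, threshold)
    m <- seg_metrics(pred, s$mask, nc)
    hd <- vapply(seq_len(nc), function(c) hd95(pred == c, s$mask == c), 0)
    m$hd95 <- c(hd, mean(hd))
    m$sample <- s$id
    m
  })
  out <- do.call(rbind, rows)
  num_cols <- c("iou", "dsc", "hd95", "precision", "sensitivity")
  mean_rows <- do.call(rbind, lapply(unique(out$class), function(cl) {
    sub <- out[out$class == cl, ]
    data.frame(class = cl, iou = mean(sub$iou), dsc = mean(sub$dsc),
               precision = mean(sub$precision),
               sensitivity = mean(sub$sensitivity), hd95 = mean(sub$hd95),
               sample = "mean")
  }))
  out <- rbind(out, mean_rows)
  out <- out[, c("sample", "class", num_cols)]
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

overlay_palette <- function() {
  list("1" = c(1, 0, 0), "2" = c(1, 1, 0), "3" = c(0, 0, 1))
}

#' Predict masks for image files
#'
#' Writes, per readable input image, a label-mask PNG
#' (`<stem>_mask.png`, literal label values) and an RGB overlay PNG
#' (`<stem>_overlay.png`) with class 1 red, class 2 yellow, class 3 blue
#' painted opaquely over the grayscale image.  Unreadable images produce a
#' warning; an error is raised only if every input fails.
#'
#' @param checkpoint Path to a checkpoint (or a model object).
#' @param image_paths Character vector of grayscale PNG paths.
#' @param out_dir Output directory.
#' @param threshold Foreground probability threshold.
#' @return Invisibly, the per-file output paths (NA where reading failed).
#' @export
predict_images <- function(checkpoint, image_paths, out_dir,
                           threshold = 0.5) {
  model <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else
    checkpoint
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pal <- overlay_palette()
  ok <- character(0)
  outs <- rep(NA_character_, length(image_paths))
  for (i in seq_along(image_paths)) {
    path <- image_paths[i]
    img <- tryCatch({
      x <- png::readPNG(path)
      if (length(dim(x)) == 3) x <- x[, , 1]
      x
    }, error = function(e) {
      warning("cannot read ", path, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    mask <- predict_mask(model, img, threshold)
    stem <- sub("\\.[^.]*$", "", basename(path))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    over_path <- file.path(out_dir, paste0(stem, "_overlay.png"))
    png::writePNG(mask / 255, mask_path)
    rgb <- array(rep(img, 3), c(dim(img), 3))
    for (c in seq_len(model$cfg$num_classes)) {
      col <- pal[[as.character(c)]]
      sel <- mask == c
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[sel] <- col[ch]
        rgb[, , ch] <- plane
      }
    }
    png::writePNG(rgb, over_path)
    outs[i] <- mask_path
    ok <- c(ok, path)
  }
  if (length(ok) == 0 && length(image_paths) > 0)
    stop("no input image could be read")
  invisible(outs)
}
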