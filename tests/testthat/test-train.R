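# Training loop, checkpoint selection, evaluation and file-level prediction.
# Uses a narrow 16-channel architecture on 32x32 phantoms so each run takes
# seconds.

make_tiny_dataset <- function(dir, n = 4, n_classes = 1, seed = 3) {
  spec <- phantom_spec(height = 32, width = 32, n_classes = n_classes,
                       curvature_amplitude = 3, axis_range = c(3, 10),
                       blobs_per_class = c(1, 2))
  generate_dataset(spec, n, seed = seed, dir)
}

tiny_train_cfg <- function(dir, out, epochs = 3, seed = 1, ...) {
  train_config(
    arch = tiny_arch(num_classes = 1),
    train_manifest = file.path(dir, "manifest.csv"),
    val_manifest = file.path(dir, "manifest.csv"),
    out_dir = out, epochs = epochs, batch_size = 2, seed = seed,
    augment = FALSE, ...)
}

test_that("training logs follow the schedule and select the best checkpoint", {
  dir <- withr::local_tempdir(); out <- withr::local_tempdir()
  make_tiny_dataset(dir)
  cfg <- tiny_train_cfg(dir, out, epochs = 4)
  res <- train(cfg)
  log <- res$log
  expect_equal(nrow(log), 4)
  expect_equal(names(log), c("epoch", "lr", "train_loss", "train_dsc",
                             "val_loss"))
  # logged LR column equals the polynomial schedule, recomputed
  expect_equal(log$lr, vapply(log$epoch - 1, poly_lr, 0, eta_init = cfg$lr,
                              num_epochs = cfg$epochs, power = cfg$power),
               tolerance = 1e-12)
  expect_equal(res$best_epoch, log$epoch[which.min(log$val_loss)])
  expect_equal(res$best_val_loss, min(log$val_loss))
  expect_lte(min(log$val_loss), log$val_loss[1])
  expect_true(file.exists(res$checkpoint))
  expect_true(file.exists(file.path(out, "train_log.csv")))
})

test_that("training is deterministic given the seed", {
  dir <- withr::local_tempdir()
  make_tiny_dataset(dir)
  r1 <- train(tiny_train_cfg(dir, withr::local_tempdir(), epochs = 2))
  r2 <- train(tiny_train_cfg(dir, withr::local_tempdir(), epochs = 2))
  expect_identical(r1$log, r2$log)
})

test_that("one optimization step moves every parameter", {
  dir <- withr::local_tempdir()
  make_tiny_dataset(dir)
  cfg <- tiny_train_cfg(dir, withr::local_tempdir(), epochs = 1,
                        seed = 7)
  set.seed(cfg$seed)
  init <- build_model(cfg$arch)$params
  train(cfg)
  trained <- load_checkpoint(file.path(cfg$out_dir, "best.ckpt"))$params
  unchanged <- names(init)[vapply(names(init), function(nm)
    identical(init[[nm]], trained[[nm]]), TRUE)]
  expect_length(unchanged, 0)
})

test_that("evaluation is deterministic, mean rows are consistent, mismatches error", {
  dir <- withr::local_tempdir(); out <- withr::local_tempdir()
  make_tiny_dataset(dir)
  res <- train(tiny_train_cfg(dir, out, epochs = 1))
  m1 <- evaluate(res$checkpoint, file.path(dir, "manifest.csv"),
                 out_csv = file.path(out, "m1.csv"))
  m2 <- evaluate(res$checkpoint, file.path(dir, "manifest.csv"),
                 out_csv = file.path(out, "m2.csv"))
  expect_identical(readLines(file.path(out, "m1.csv")),
                   readLines(file.path(out, "m2.csv")))
  per_sample <- m1[m1$sample != "mean" & m1$class == "1", ]
  overall <- m1[m1$sample == "mean" & m1$class == "1", ]
  expect_equal(overall$iou, mean(per_sample$iou), tolerance = 1e-12)
  expect_equal(overall$dsc, mean(per_sample$dsc), tolerance = 1e-12)
  # 3-class masks against a 1-class checkpoint must fail loudly
  dir3 <- withr::local_tempdir()
  make_tiny_dataset(dir3, n_classes = 3)
  expect_error(evaluate(res$checkpoint, file.path(dir3, "manifest.csv")),
               "classes")
})

test_that("file prediction writes masks and overlays with the class palette", {
  dir <- withr::local_tempdir(); out <- withr::local_tempdir()
  preds <- withr::local_tempdir()
  make_tiny_dataset(dir, n = 2)
  res <- train(tiny_train_cfg(dir, out, epochs = 1))
  imgs <- file.path(dir, lkmulite:::read_manifest(
    file.path(dir, "manifest.csv"))$image)
  predict_images(res$checkpoint, imgs, preds)
  mask_files <- list.files(preds, pattern = "_mask\\.png$", full.names = TRUE)
  over_files <- list.files(preds, pattern = "_overlay\\.png$",
                           full.names = TRUE)
  expect_length(mask_files, 2)
  expect_length(over_files, 2)
  msk <- round(png::readPNG(mask_files[1]) * 255)
  expect_equal(dim(msk), c(32, 32))
  expect_true(all(msk %in% 0:1))
  over <- png::readPNG(over_files[1])
  img <- png::readPNG(imgs[1])
  bg <- msk == 0
  for (ch in 1:3) {
    plane <- over[, , ch]
    expect_equal(plane[bg], img[bg])
  }
  fg <- msk == 1
  if (any(fg)) {
    expect_true(all(over[, , 1][fg] == 1))  # class 1 painted red
    expect_true(all(over[, , 3][fg] == 0))
  }
  # unreadable inputs warn; all-unreadable errors
  expect_warning(predict_images(res$checkpoint,
                                c(imgs[1], file.path(dir, "nope.png")),
                                preds),
                 "cannot read")
  expect_error(suppressWarnings(
    predict_images(res$checkpoint, file.path(dir, "nope.png"), preds)),
    "no input image")
})
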