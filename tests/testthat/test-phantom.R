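# Synthetic OCT phantoms: determinism, fluid contrast, dataset round trips,
# splits, augmentation and normalization.

small_spec <- function(...) phantom_spec(height = 96, width = 96, ...)

test_that("phantom generation is deterministic and respects the label alphabet", {
  spec <- small_spec(n_classes = 3)
  s1 <- generate_phantom(spec, 42)
  s2 <- generate_phantom(spec, 42)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_true(all(s1$mask %in% 0:3))
  expect_setequal(setdiff(unique(as.vector(s1$mask)), 0L), 1:3)
  s3 <- generate_phantom(spec, 43)
  expect_false(identical(s1$image, s3$image))
  expect_error(generate_phantom(list(), 1), "phantom_spec")
  expect_error(phantom_spec(n_classes = 2), "1 or 3")
  expect_error(phantom_spec(intensity_drop = c(0, 0.5)), "intensity_drop")
})

test_that("fluid regions are darker than their surrounding annulus", {
  spec <- small_spec(n_classes = 1)
  hits <- 0; total <- 0
  for (seed in 1:5) {
    s <- generate_phantom(spec, seed)
    for (cls in setdiff(unique(as.vector(s$mask)), 0L)) {
      inside <- s$mask == cls
      # 5-px annulus via repeated 4-neighbor dilation
      grow <- inside
      for (k in 1:5) {
        g2 <- grow
        g2[-1, ] <- g2[-1, ] | grow[-nrow(grow), ]
        g2[-nrow(g2), ] <- g2[-nrow(g2), ] | grow[-1, ]
        g2[, -1] <- g2[, -1] | grow[, -ncol(grow)]
        g2[, -ncol(g2)] <- g2[, -ncol(g2)] | grow[, -1]
        grow <- g2
      }
      annulus <- grow & !inside & s$mask == 0
      total <- total + 1
      if (mean(s$image[inside]) < mean(s$image[annulus])) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("dataset files round-trip and the manifest counts match the masks", {
  dir <- withr::local_tempdir()
  spec <- small_spec(n_classes = 3, device_profile = "mix")
  man <- generate_dataset(spec, 6, seed = 5, dir)
  expect_equal(nrow(man), 6)
  expect_setequal(unique(man$device_profile), c("A", "B", "C"))
  expect_length(list.files(dir, pattern = "^img_.*png$"), 6)
  expect_length(list.files(dir, pattern = "^mask_.*png$"), 6)
  for (i in seq_len(3)) {
    msk <- round(png::readPNG(file.path(dir, man$mask[i])) * 255)
    for (c in 1:3)
      expect_equal(sum(msk == c), man[[paste0("pixels_class", c)]][i])
  }
  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  generate_dataset(spec, 6, seed = 5, dir2)
  for (f in c(man$image[1], man$mask[1], "manifest.csv"))
    expect_identical(readBin(file.path(dir, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  # manifest reader skips the dialect header
  man2 <- lkmulite:::read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$image, man$image)
})

test_that("splits are disjoint, exhaustive, and follow the floor allocation", {
  man <- data.frame(image = sprintf("img_%03d.png", 1:100))
  sp <- split_dataset(man, c(8, 1, 1), seed = 2)
  expect_equal(vapply(sp, nrow, 0), c(train = 80, val = 10, test = 10))
  all_rows <- sort(unname(unlist(lapply(sp, function(d) d$image))))
  expect_equal(all_rows, sort(man$image))
  sp10 <- split_dataset(man[1:10, , drop = FALSE], c(8, 1, 1), seed = 2)
  expect_equal(vapply(sp10, nrow, 0), c(train = 8, val = 1, test = 1))
  # remainder goes to training
  sp9 <- split_dataset(man[1:9, , drop = FALSE], c(8, 1, 1), seed = 2)
  expect_equal(vapply(sp9, nrow, 0), c(train = 9, val = 0, test = 0))
  expect_error(split_dataset(man, c(1, -1, 1)), "positive")
})

test_that("augmentation components are involutive / identity when forced", {
  s <- generate_phantom(small_spec(n_classes = 3), 9)
  a <- augment(s, hflip = TRUE, vflip = FALSE, angle = 0)
  b <- augment(a, hflip = TRUE, vflip = FALSE, angle = 0)
  expect_equal(b$image, s$image)
  expect_equal(b$mask, s$mask)
  idt <- augment(s, hflip = FALSE, vflip = FALSE, angle = 0)
  expect_identical(idt$image, s$image)
  # rotation never invents labels; mask and image move together
  for (seed in 1:5) {
    r <- augment(s, seed = seed)
    expect_true(all(unique(as.vector(r$mask)) %in% unique(as.vector(s$mask))))
    expect_equal(dim(r$image), dim(s$image))
  }
  r2 <- augment(s, seed = 1)
  r3 <- augment(s, seed = 1)
  expect_identical(r2$image, r3$image)
})

test_that("normalization replicates to 3 channels and inverts exactly", {
  img <- matrix(runif(64 * 48), 64, 48)
  x <- normalize_image(img)
  expect_equal(dim(x), c(64, 48, 3))
  back <- denormalize_image(x)
  for (c in 1:3) expect_equal(back[, , c], img, tolerance = 1e-6)
  stats <- lkmulite:::imagenet_stats()
  const <- matrix(stats$mean[2], 8, 8)
  expect_equal(normalize_image(const)[, , 2], matrix(0, 8, 8),
               tolerance = 1e-12)
})

test_that("device profile C has stronger speckle than profile A", {
  va <- vc <- numeric(20)
  for (seed in 1:20) {
    sa <- generate_phantom(small_spec(device_profile = "A"), seed)
    sc <- generate_phantom(small_spec(device_profile = "C"), seed)
    highfreq <- function(img) {
      sm <- EBImage::gblur(img, 2)
      mean((img - sm)^2)
    }
    va[seed] <- highfreq(sa$image)
    vc[seed] <- highfreq(sc$image)
  }
  expect_gt(mean(vc), mean(va))
})
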