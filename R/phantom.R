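# Synthetic OCT B-scan phantoms: curved retinal bands, multiplicative gamma
# speckle, and low-contrast hypo-reflective fluid pockets with per-pixel
# labels.  The three fluid classes mimic the morphology of the clinical
# categories: class 1, irregular intraretinal pockets; class 2, lens-shaped
# pockets under a layer boundary; class 3, dome-shaped detachments of the
# bottom band.  Device profiles A/B/C emulate scanners with progressively
# lower contrast and stronger speckle.

#' Phantom specification
#'
#' @param height,width Image size in pixels (default 256 x 256).
#' @param n_layers Range of retinal band counts, drawn per sample.
#' @param layer_intensity Range of band mean intensities; bands alternate
#'   between the lower and upper half of the range for visible contrast.
#' @param curvature_amplitude Vertical sinusoidal displacement of the band
#'   stack, in pixels.
#' @param speckle_shape Gamma shape parameter of the multiplicative speckle
#'   (unit mean; larger = cleaner).
#' @param n_classes 1 (single intraretinal class) or 3 (three fluid types).
#' @param blobs_per_class Range of fluid regions per class.
#' @param axis_range Range of fluid-region axis lengths, pixels.
#' @param intensity_drop Range of the relative darkening of fluid regions
#'   below their local background, in (0, 1).
#' @param device_profile `"A"`, `"B"`, `"C"` (decreasing contrast, increasing
#'   speckle) or `"mix"` to cycle through all three across a dataset.
#' @param blur_sigma Gaussian blur applied before speckle, emulating blurred
#'   edge structure.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_layers = c(6L, 10L),
                         layer_intensity = c(0.2, 0.8),
                         curvature_amplitude = 12,
                         speckle_shape = 6, n_classes = 1L,
                         blobs_per_class = c(1L, 4L),
                         axis_range = c(4, 60), intensity_drop = c(0.2, 0.5),
                         device_profile = c("A", "B", "C", "mix"),
                         blur_sigma = 1.2) {
  device_profile <- match.arg(device_profile)
  if (!n_classes %in% c(1L, 3L)) stop("n_classes must be 1 or 3")
  stopifnot(height >= 32, width >= 32, diff(range(n_layers)) >= 0,
            n_layers[1] >= 2, speckle_shape > 0, blur_sigma >= 0,
            axis_range[1] > 0, axis_range[2] >= axis_range[1])
  if (any(intensity_drop <= 0) || any(intensity_drop >= 1))
    stop("intensity_drop must lie in (0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_layers = as.integer(n_layers),
                 layer_intensity = layer_intensity,
                 curvature_amplitude = curvature_amplitude,
                 speckle_shape = speckle_shape,
                 n_classes = as.integer(n_classes),
                 blobs_per_class = as.integer(blobs_per_class),
                 axis_range = axis_range, intensity_drop = intensity_drop,
                 device_profile = device_profile, blur_sigma = blur_sigma),
            class = "phantom_spec")
}

device_profiles <- list(
  A = list(contrast = 1.00, speckle_factor = 1.0),
  B = list(contrast = 0.85, speckle_factor = 0.65),
  C = list(contrast = 0.70, speckle_factor = 0.40)
)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

spec_digest <- function(spec) {
  # small polynomial rolling hash of the serialized spec, for provenance
  s <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Generate one OCT-like phantom
#'
#' Deterministic given `(spec, seed)`: layered bands with smooth sinusoidal
#' curvature, per-class fluid regions darkened by a random fraction of their
#' local background, Gaussian edge blur, then multiplicative gamma speckle.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A list with `image` (matrix in `[0, 1]`), `mask` (integer label
#'   matrix, 0 = background) and `meta` (seed, spec digest, blob inventory).
#' @export
generate_phantom <- function(spec, seed) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    prof <- device_profiles[[if (spec$device_profile == "mix") "A" else
      spec$device_profile]]
    xs <- seq_len(W)
    amp <- spec$curvature_amplitude
    phase <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 0.6, 1.4)
    curve <- amp * sin(2 * pi * freq * xs / W + phase) +
      0.35 * amp * sin(4 * pi * freq * xs / W + stats::runif(1, 0, 2 * pi))
    top <- H * 0.22 + curve
    bottom <- H * 0.78 + 0.85 * curve + amp * 0.2 *
      sin(2 * pi * xs / W + stats::runif(1, 0, 2 * pi))
    nl <- if (spec$n_layers[1] == spec$n_layers[2]) spec$n_layers[1] else
      sample(spec$n_layers[1]:spec$n_layers[2], 1)
    props <- sort(stats::runif(nl - 1, 0.05, 0.95))
    lo <- spec$layer_intensity[1]; hi <- spec$layer_intensity[2]
    mid <- (lo + hi) / 2
    band_mean <- ifelse(seq_len(nl) %% 2 == 1,
                        stats::runif(nl, mid + 0.05, hi),
                        stats::runif(nl, lo, mid - 0.05))
    # band index per pixel, column by column
    img <- matrix(0.05, H, W)
    ys <- seq_len(H)
    for (x in xs) {
      bounds <- c(top[x], top[x] + props * (bottom[x] - top[x]), bottom[x])
      band <- findInterval(ys, bounds)
      inside <- band >= 1 & band <= nl
      img[inside, x] <- band_mean[band[inside]]
    }
    mask <- matrix(0L, H, W)
    blobs <- list()
    add_blob <- function(pix, class, info) {
      pix <- pix[mask[pix] == 0L]
      if (length(pix) < 20) return(FALSE)
      mask[pix] <<- as.integer(class)
      drop <- stats::runif(1, spec$intensity_drop[1], spec$intensity_drop[2])
      img[pix] <<- img[pix] * (1 - drop)
      blobs[[length(blobs) + 1]] <<- c(list(class = class, drop = drop), info)
      TRUE
    }
    n_blobs <- function() sample(spec$blobs_per_class[1]:spec$blobs_per_class[2], 1)
    band_of <- function(y, x) y >= top[x] & y < bottom[x]

    if (spec$n_classes == 3L) {
      # class 3: dome-shaped bumps on the bottom band
      for (b in seq_len(n_blobs())) {
        for (try in 1:25) {
          x0 <- stats::runif(1, 0.15 * W, 0.85 * W)
          hw <- stats::runif(1, max(6, spec$axis_range[1]),
                             min(spec$axis_range[2], 45))
          hgt <- stats::runif(1, 4, min(22, 0.5 * hw + 6))
          xr <- pmax(1, ceiling(x0 - hw)):pmin(W, floor(x0 + hw))
          pix <- integer(0)
          for (x in xr) {
            dome <- hgt * (1 - ((x - x0) / hw)^2)
            yy <- ys[ys >= bottom[x] - dome & ys < bottom[x] & ys >= top[x]]
            pix <- c(pix, yy + (x - 1L) * H)
          }
          if (add_blob(pix, 3L, list(x0 = x0, hw = hw, hgt = hgt))) break
        }
      }
      # class 2: lens-shaped pockets under an internal layer boundary
      for (b in seq_len(n_blobs())) {
        for (try in 1:25) {
          j <- sample(seq_len(nl - 1), 1)
          x0 <- stats::runif(1, 0.15 * W, 0.85 * W)
          hw <- stats::runif(1, max(6, spec$axis_range[1]),
                             min(spec$axis_range[2], 45))
          dep <- stats::runif(1, 3, min(18, 0.5 * hw + 4))
          xr <- pmax(1, ceiling(x0 - hw)):pmin(W, floor(x0 + hw))
          pix <- integer(0)
          for (x in xr) {
            yb <- top[x] + props[j] * (bottom[x] - top[x])
            lens <- dep * (1 - ((x - x0) / hw)^2)
            yy <- ys[ys >= yb & ys < yb + lens & ys < bottom[x]]
            pix <- c(pix, yy + (x - 1L) * H)
          }
          if (add_blob(pix, 2L, list(boundary = j, x0 = x0, hw = hw,
                                     depth = dep))) break
        }
      }
    }
    # class 1: irregular hypo-reflective pockets inside the band stack
    for (b in seq_len(n_blobs())) {
      for (try in 1:25) {
        cx <- stats::runif(1, 0.1 * W, 0.9 * W)
        thick <- bottom[round(cx)] - top[round(cx)]
        cy <- stats::runif(1, top[round(cx)] + 0.15 * thick,
                           bottom[round(cx)] - 0.15 * thick)
        ax <- stats::runif(1, spec$axis_range[1], spec$axis_range[2]) / 2
        ay <- stats::runif(1, spec$axis_range[1],
                           min(spec$axis_range[2], 0.7 * thick)) / 2
        wob <- stats::runif(1, 0.05, 0.25)
        kk <- sample(2:5, 1)
        ph <- stats::runif(1, 0, 2 * pi)
        xr <- pmax(1, floor(cx - 1.3 * ax)):pmin(W, ceiling(cx + 1.3 * ax))
        pix <- integer(0)
        for (x in xr) {
          u <- (x - cx) / ax
          yr <- ys[abs(ys - cy) <= 1.3 * ay]
          v <- (yr - cy) / ay
          th <- atan2(v, u)
          rad <- 1 + wob * sin(kk * th + ph)
          sel <- (u^2 + v^2) <= rad^2 & band_of(yr, x)
          pix <- c(pix, yr[sel] + (x - 1L) * H)
        }
        if (add_blob(pix, 1L, list(cx = cx, cy = cy, ax = ax, ay = ay))) break
      }
    }

    img <- img * prof$contrast + (1 - prof$contrast) * 0.35
    if (spec$blur_sigma > 0) img <- EBImage::gblur(img, spec$blur_sigma)
    shape <- spec$speckle_shape * prof$speckle_factor
    img <- img * matrix(stats::rgamma(H * W, shape = shape, rate = shape), H, W)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask,
         meta = list(seed = seed, spec_digest = spec_digest(spec),
                     device_profile = if (spec$device_profile == "mix") "A"
                     else spec$device_profile,
                     n_layers = nl, blobs = blobs))
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs and a manifest CSV.  Images are 8-bit
#' grayscale; masks are single-channel 8-bit PNGs holding literal label
#' values (0 = background, 1..n_classes), as noted in the manifest header
#' comment.  With `device_profile = "mix"` samples cycle through profiles
#' A, B, C.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of samples.
#' @param seed Integer seed; sample `i` uses a seed derived from `seed` and
#'   `i`, so regeneration is byte-identical.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(spec, n, seed, out_dir) {
  if (n < 1) stop("n must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  profiles <- c("A", "B", "C")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    if (spec$device_profile == "mix")
      spec_i$device_profile <- profiles[(i - 1L) %% 3L + 1L]
    si <- (seed + 104729 * i) %% .Machine$integer.max
    s <- generate_phantom(spec_i, si)
    img_name <- sprintf("img_%04d.png", i)
    mask_name <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(out_dir, img_name))
    png::writePNG(s$mask / 255, file.path(out_dir, mask_name))
    counts <- vapply(1:3, function(c) sum(s$mask == c), 0L)
    rows[[i]] <- data.frame(image = img_name, mask = mask_name, seed = si,
                            device_profile = spec_i$device_profile,
                            n_classes = spec$n_classes,
                            pixels_class1 = counts[1],
                            pixels_class2 = counts[2],
                            pixels_class3 = counts[3])
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  con <- file(path, "w")
  writeLines(paste("# masks: single-channel 8-bit PNG, literal label values",
                   "0..n_classes (0 = background)"), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  close(con)
  invisible(manifest)
}

read_manifest <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Split a manifest into train/validation/test sets
#'
#' Disjoint, exhaustive random split.  Set sizes are the floor allocation of
#' the ratios, with remainder samples assigned to the training set.
#'
#' @param manifest Data frame (or path to a manifest CSV).
#' @param ratios Positive weights, default `c(8, 1, 1)`.
#' @param seed Integer seed for the permutation.
#' @return Named list of data frames `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, ratios = c(8, 1, 1), seed = 1L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- nrow(manifest)
  n_val <- floor(n * ratios[2] / sum(ratios))
  n_test <- floor(n * ratios[3] / sum(ratios))
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample(n))
  list(train = manifest[sort(perm[seq_len(n_train)]), , drop = FALSE],
       val = manifest[sort(perm[n_train + seq_len(n_val)]), , drop = FALSE],
       test = manifest[sort(perm[n_train + n_val + seq_len(n_test)]), ,
                       drop = FALSE])
}

#' Random augmentation of a phantom sample
#'
#' Independent 0.5-probability horizontal and vertical flips and a rotation
#' uniform in [-15, 15] degrees; the image is interpolated bilinearly, the
#' mask with nearest neighbor so no new label values can appear.  Pass
#' `hflip` / `vflip` / `angle` to force a deterministic transform.
#'
#' @param sample A list with `image` and `mask` (as from
#'   [generate_phantom()]).
#' @param seed Optional seed for the random draws.
#' @param hflip,vflip,angle Optional forced transform components.
#' @return The transformed sample.
#' @export
augment <- function(sample, seed = NULL, hflip = NULL, vflip = NULL,
                    angle = NULL) {
  draw <- function() list(hflip = stats::runif(1) < 0.5,
                          vflip = stats::runif(1) < 0.5,
                          angle = stats::runif(1, -15, 15))
  r <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (!is.null(hflip)) r$hflip <- hflip
  if (!is.null(vflip)) r$vflip <- vflip
  if (!is.null(angle)) r$angle <- angle
  img <- sample$image
  msk <- sample$mask
  if (r$hflip) {
    img <- img[, ncol(img):1, drop = FALSE]
    msk <- msk[, ncol(msk):1, drop = FALSE]
  }
  if (r$vflip) {
    img <- img[nrow(img):1, , drop = FALSE]
    msk <- msk[nrow(msk):1, , drop = FALSE]
  }
  if (r$angle != 0) {
    d <- dim(img)
    img <- EBImage::rotate(img, r$angle, filter = "bilinear",
                           output.dim = d, bg.col = 0)
    msk <- EBImage::rotate(msk, r$angle, filter = "none",
                           output.dim = d, bg.col = 0)
    img <- matrix(pmin(pmax(as.numeric(img), 0), 1), d[1], d[2])
    msk <- matrix(as.integer(round(as.numeric(msk))), d[1], d[2])
  }
  out <- sample
  out$image <- img
  out$mask <- msk
  out$meta$augment <- r
  out
}

imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Normalize a grayscale image for the network
#'
#' Replicates the single channel to three and standardizes each channel with
#' the ImageNet pixel statistics (overridable).
#'
#' @param image Matrix in `[0, 1]`.
#' @param mean,sd Per-channel constants.
#' @return Array `c(H, W, 3)`.
#' @export
normalize_image <- function(image, mean = imagenet_stats()$mean,
                            sd = imagenet_stats()$sd) {
  d <- dim(image)
  out <- array(0, c(d[1], d[2], 3L))
  for (c in 1:3) out[, , c] <- (image - mean[c]) / sd[c]
  out
}

#' @rdname normalize_image
#' @param x Array `c(H, W, 3)` as produced by `normalize_image`.
#' @export
denormalize_image <- function(x, mean = imagenet_stats()$mean,
                              sd = imagenet_stats()$sd) {
  out <- x
  for (c in 1:3) out[, , c] <- x[, , c] * sd[c] + mean[c]
  out
}
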