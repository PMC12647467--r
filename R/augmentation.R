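#' Configuration of the 10-fold geometric/colour augmentation strategy
#'
#' Geometric operators (applied identically to image and mask, the mask via
#' nearest-neighbour lookup) and colour operators (image only). Each draw
#' composes a random subset with parameters sampled from the stated ranges.
#' Out-of-frame regions after rotation/translation are filled with black in
#' the image and background (0) in the mask, matching the black-cloth scene.
#'
#' @param hflip,vflip Enable horizontal/vertical flips (each drawn with
#'   probability 1/2 when enabled).
#' @param scale Multiplicative scale range.
#' @param translate Maximum translation as a fraction of each dimension.
#' @param rotate Maximum absolute rotation in degrees.
#' @param brightness Maximum relative brightness change.
#' @param hue Maximum absolute hue shift (fraction of the hue circle).
#' @param saturation Maximum relative saturation change.
#' @param contrast Contrast factor range.
#' @param gaussian_noise Maximum noise standard deviation (intensity units).
#' @param gaussian_blur Maximum blur standard deviation (pixels).
#' @param per_image_count Augmented draws per source image (default 10).
#' @param seed Base seed of the counter-based per-draw randomness.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(hflip = TRUE, vflip = TRUE,
                                scale = c(0.8, 1.2), translate = 0.1,
                                rotate = 25,
                                brightness = 0.2, hue = 0.1, saturation = 0.1,
                                contrast = c(0.8, 1.25),
                                gaussian_noise = 0.02, gaussian_blur = 1.5,
                                per_image_count = 10L, seed = 1L) {
  if (per_image_count < 1L) stop("per_image_count must be >= 1")
  vals <- c(scale, translate, rotate, brightness, hue, saturation, contrast,
            gaussian_noise, gaussian_blur)
  if (any(!is.finite(vals))) stop("augmentation ranges must be finite")
  structure(list(hflip = hflip, vflip = vflip, scale = scale,
                 translate = translate, rotate = rotate,
                 brightness = brightness, hue = hue, saturation = saturation,
                 contrast = contrast, gaussian_noise = gaussian_noise,
                 gaussian_blur = gaussian_blur,
                 per_image_count = as.integer(per_image_count),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Configuration of the background-reducing crop strategy
#'
#' @param crops_per_image Crops per source image (default 5, which maps 250
#'   sources to 1,250 outputs).
#' @param crop_size Crop size `c(h, w)`; must fit inside the source images.
#' @param selection_rule `"min_background_fraction"` picks, per crop, the
#'   candidate window with the smallest background fraction;
#'   `"stem_fraction_weighted"` centers candidate windows on randomly chosen
#'   stem pixels. Both degrade to uniform random crops on all-background
#'   images.
#' @param candidates Candidate windows examined per crop.
#' @param seed Base seed of the counter-based per-draw randomness.
#' @return An object of class `crop_config`.
#' @export
crop_config <- function(crops_per_image = 5L, crop_size = c(64L, 64L),
                        selection_rule = c("min_background_fraction",
                                           "stem_fraction_weighted"),
                        candidates = 10L, seed = 1L) {
  if (crops_per_image < 1L) stop("crops_per_image must be >= 1")
  structure(list(crops_per_image = as.integer(crops_per_image),
                 crop_size = as.integer(crop_size),
                 selection_rule = match.arg(selection_rule),
                 candidates = as.integer(candidates),
                 seed = as.integer(seed)),
            class = "crop_config")
}

# Counter-based stream: one derived seed per (seed, image id, draw index),
# so draws are reproducible independently of execution order.
.draw_seed <- function(seed, image_index, draw_index) {
  as.integer((as.double(seed) * 7919 + as.double(image_index) * 104729 +
                as.double(draw_index) * 131) %% 2147483647)
}

# Sample one composite transform record.
.draw_transform <- function(config, image_index, draw_index) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.draw_seed(config$seed, image_index, draw_index))
  tr <- list(
    hflip = isTRUE(config$hflip) && stats::runif(1) < 0.5,
    vflip = isTRUE(config$vflip) && stats::runif(1) < 0.5,
    scale = stats::runif(1, config$scale[1], config$scale[2]),
    translate = stats::runif(2, -config$translate, config$translate),
    rotate = stats::runif(1, -config$rotate, config$rotate),
    brightness = 1 + stats::runif(1, -config$brightness, config$brightness),
    hue = stats::runif(1, -config$hue, config$hue),
    saturation = 1 + stats::runif(1, -config$saturation, config$saturation),
    contrast = stats::runif(1, config$contrast[1], config$contrast[2]),
    noise_sd = stats::runif(1, 0, config$gaussian_noise),
    blur_sd = stats::runif(1, 0, config$gaussian_blur),
    noise_seed = sample.int(.Machine$integer.max, 1))
  structure(tr, class = "aug_transform")
}

# Inverse affine map from output to input pixel-center coordinates.
# Forward transform: center -> flip -> scale -> rotate -> translate -> uncenter.
.affine_inverse <- function(tr, H, W) {
  th <- tr$rotate * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(c(tr$scale, tr$scale))
  Fm <- diag(c(if (tr$hflip) -1 else 1, if (tr$vflip) -1 else 1))
  A <- R %*% S %*% Fm
  t <- c(tr$translate[1] * W, tr$translate[2] * H)
  Ainv <- solve(A)
  list(Ainv = Ainv, t = t, cx = W / 2, cy = H / 2)
}

# Warp with the inverse map; interp "bilinear" (image plane) or "nearest"
# (mask), out-of-frame filled with `fill`.
.warp <- function(x, tr, interp, fill = 0) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  m <- .affine_inverse(tr, H, W)
  xc <- rep(seq_len(W) - 0.5, each = H) - m$cx - m$t[1]
  yc <- rep(seq_len(H) - 0.5, times = W) - m$cy - m$t[2]
  xs <- m$Ainv[1, 1] * xc + m$Ainv[1, 2] * yc + m$cx
  ys <- m$Ainv[2, 1] * xc + m$Ainv[2, 2] * yc + m$cy
  if (interp == "nearest") {
    ci <- floor(xs) + 1L; ri <- floor(ys) + 1L
    ok <- ci >= 1L & ci <= W & ri >= 1L & ri <= H
    idx <- ifelse(ok, (ci - 1L) * H + ri, NA_integer_)
    out <- matrix(fill, H, W)
    out[!is.na(idx)] <- x[idx[!is.na(idx)]]
    storage.mode(out) <- storage.mode(x)
    out
  } else {
    c0 <- floor(xs - 0.5); r0 <- floor(ys - 0.5)
    wx <- xs - 0.5 - c0; wy <- ys - 0.5 - r0
    gather <- function(ri, ci, ch) {
      ok <- ci >= 0L & ci < W & ri >= 0L & ri < H
      v <- numeric(length(ri))
      pl <- x[, , ch]
      v[ok] <- pl[ci[ok] * H + ri[ok] + 1L]
      v[!ok] <- fill
      v
    }
    out <- array(0, dim = d)
    for (ch in seq_len(d[3])) {
      v <- gather(r0, c0, ch) * (1 - wx) * (1 - wy) +
        gather(r0, c0 + 1L, ch) * wx * (1 - wy) +
        gather(r0 + 1L, c0, ch) * (1 - wx) * wy +
        gather(r0 + 1L, c0 + 1L, ch) * wx * wy
      out[, , ch] <- v
    }
    out
  }
}

.rgb_to_hsv <- function(img) {
  d <- dim(img)
  m <- t(matrix(img, ncol = 3L))        # 3 x n in [0,1]
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(hsv = hsv, dims = d)
}

.hsv_to_rgb <- function(hsvm, dims) {
  h <- hsvm[1, ] * 6; s <- hsvm[2, ]; v <- hsvm[3, ]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = dims)
}

.gaussian_blur <- function(img, sd) {
  if (sd <= 0.05) return(img)
  r <- max(1L, as.integer(ceiling(2 * sd)))
  g <- stats::dnorm(seq(-r, r), sd = sd)
  g <- g / sum(g)
  k <- outer(g, g)
  d <- dim(img)
  x <- array(img, dim = c(d[1], d[2], 1L, d[3]))     # channels as batch
  w <- array(k, dim = c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  y <- .conv2d_fwd(x, w, NULL, 1L, r, 1L)
  array(y, dim = d)
}

.apply_colour <- function(img, tr) {
  if (abs(tr$hue) > 1e-9 || abs(tr$saturation - 1) > 1e-9) {
    hv <- .rgb_to_hsv(img)
    hv$hsv[1, ] <- (hv$hsv[1, ] + tr$hue) %% 1
    hv$hsv[2, ] <- pmin(pmax(hv$hsv[2, ] * tr$saturation, 0), 1)
    img <- .hsv_to_rgb(hv$hsv, hv$dims)
  }
  img <- img * tr$brightness
  img <- (img - 0.5) * tr$contrast + 0.5
  img <- .gaussian_blur(img, tr$blur_sd)
  if (tr$noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(tr$noise_seed)
    img <- img + stats::rnorm(length(img), sd = tr$noise_sd)
  }
  pmin(pmax(img, 0), 1)
}

#' Apply the transform record of an augmentation draw to a mask
#'
#' Replays only the geometric part of a stored transform, via
#' nearest-neighbour lookup with background fill — by construction this
#' reproduces exactly the mask produced by [augment_pair()] for the same
#' record.
#'
#' @param mask Integer label-mask matrix.
#' @param transform A transform record from [augment_pair()].
#' @return Transformed mask.
#' @export
apply_transform_mask <- function(mask, transform) {
  .warp(mask, transform, "nearest", fill = 0L)
}

#' One augmentation draw for an image/mask pair
#'
#' Composes a random geometric transform (flips, scale, rotation,
#' translation), applied identically to image (bilinear) and mask
#' (nearest-neighbour, labels preserved), followed by colour operators
#' (brightness, hue/saturation, contrast, Gaussian blur and noise) on the
#' image only. Fully determined by `(config$seed, image_index, draw_index)`.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param mask Integer label-mask matrix of the same spatial size.
#' @param config An [augmentation_config()].
#' @param draw_index Draw counter (1-based).
#' @param image_index Source-image counter used in the random stream.
#' @return List with `image`, `mask` and the `transform` record.
#' @export
augment_pair <- function(image, mask, config, draw_index = 1L,
                         image_index = 1L) {
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask sizes differ")
  tr <- .draw_transform(config, image_index, draw_index)
  img <- .warp(image, tr, "bilinear", fill = 0)
  msk <- .warp(mask, tr, "nearest", fill = 0L)
  img <- .apply_colour(img, tr)
  list(image = img, mask = msk, transform = tr)
}

#' Strategy 1: k-fold geometric/colour augmentation of a dataset
#'
#' Produces exactly `config$per_image_count` draws per input sample
#' (10 by default, so 250 sources yield 2,500 outputs), with provenance
#' (source id, draw index, transform record) attached to every output.
#'
#' @param samples List of `list(id, image, mask)` samples.
#' @param config An [augmentation_config()].
#' @return List of `list(id, source_id, draw_index, image, mask, transform)`.
#' @export
augment_dataset <- function(samples, config = augmentation_config()) {
  if (!length(samples)) stop("empty sample list")
  out <- vector("list", length(samples) * config$per_image_count)
  k <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (d in seq_len(config$per_image_count)) {
      a <- augment_pair(s$image, s$mask, config, d, i)
      k <- k + 1L
      out[[k]] <- list(id = paste0(s$id, "_aug", d), source_id = s$id,
                       draw_index = d, image = a$image, mask = a$mask,
                       transform = a$transform)
    }
  }
  out
}

#' Strategy 2: background-reducing crop augmentation
#'
#' Produces `config$crops_per_image` crops per input (5 by default, so 250
#' sources yield 1,250 outputs), selecting crop windows by the configured
#' rule so that the mean background fraction over the outputs is lower than
#' over the inputs. On an all-background image the rule degrades to a
#' uniform random crop.
#'
#' @param samples List of `list(id, image, mask)` samples.
#' @param config A [crop_config()].
#' @return List of `list(id, source_id, draw_index, image, mask, offset)`.
#' @export
crop_augment_dataset <- function(samples, config = crop_config()) {
  if (!length(samples)) stop("empty sample list")
  ch <- config$crop_size[1]; cw <- config$crop_size[2]
  out <- vector("list", length(samples) * config$crops_per_image)
  k <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    H <- nrow(s$mask); W <- ncol(s$mask)
    if (ch > H || cw > W) stop("crop_size exceeds image size")
    for (d in seq_len(config$crops_per_image)) {
      old <- .save_rng()
      set.seed(.draw_seed(config$seed, i, d))
      if (config$selection_rule == "min_background_fraction") {
        r0 <- sample.int(H - ch + 1L, config$candidates, replace = TRUE)
        c0 <- sample.int(W - cw + 1L, config$candidates, replace = TRUE)
        bg <- vapply(seq_len(config$candidates), function(j) {
          mean(s$mask[r0[j]:(r0[j] + ch - 1L), c0[j]:(c0[j] + cw - 1L)] == 0L)
        }, numeric(1))
        j <- which.min(bg)
        off <- c(r0[j], c0[j])
      } else {
        stem <- which(s$mask == 1L, arr.ind = TRUE)
        if (nrow(stem) == 0L) {
          off <- c(sample.int(H - ch + 1L, 1L), sample.int(W - cw + 1L, 1L))
        } else {
          ctr <- stem[sample.int(nrow(stem), 1L), ]
          off <- c(min(max(ctr[1] - ch %/% 2L, 1L), H - ch + 1L),
                   min(max(ctr[2] - cw %/% 2L, 1L), W - cw + 1L))
        }
      }
      .restore_rng(old)
      rows <- off[1]:(off[1] + ch - 1L); cols <- off[2]:(off[2] + cw - 1L)
      k <- k + 1L
      out[[k]] <- list(id = paste0(s$id, "_crop", d), source_id = s$id,
                       draw_index = d, image = s$image[rows, cols, , drop = FALSE],
                       mask = s$mask[rows, cols, drop = FALSE],
                       offset = off)
    }
  }
  out
}

#' Write an augmented dataset to disk with a provenance manifest
#'
#' @param aug Output of [augment_dataset()] or [crop_augment_dataset()].
#' @param out_dir Destination directory; images as `<id>_img.png`, masks as
#'   `<id>_mask.png`, plus `manifest.json` recording provenance.
#' @return Invisibly, the manifest path.
#' @export
write_augmented_dataset <- function(aug, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- lapply(aug, function(a) {
    write_image(a$image, file.path(out_dir, paste0(a$id, "_img.png")))
    write_mask(a$mask, file.path(out_dir, paste0(a$id, "_mask.png")))
    prov <- list(id = a$id, source_id = a$source_id, draw_index = a$draw_index)
    if (!is.null(a$transform)) prov$transform <- unclass(a$transform)
    if (!is.null(a$offset)) prov$offset <- as.integer(a$offset)
    prov
  })
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
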