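#' Specification of a synthetic branch scene
#'
#' Parameters of one rendered scene: a thin curved stem polyline, petioles
#' branching off it, trifoliate leaflet clusters (three rotated ellipses per
#' petiole tip), a dark cloth-textured background, and an optional
#' "high-light" illumination regime with bright speckles concentrated between
#' leaflets. The generator is deliberately schematic: it reproduces the
#' statistical structure segmentation models confront on branch imagery —
#' thin elongated stem structures, blob-like leaves, extreme class imbalance
#' (background >> leaf >> stem) and illumination confounds — not
#' photorealism. Geometry defaults are expressed at a 96 x 160 canvas and
#' scale linearly with canvas height.
#'
#' @param canvas Scene size `c(H, W)`.
#' @param stem_width Stem thickness in pixels.
#' @param stem_length Relative stem extent in `[0, 1]`; 0 renders no stem
#'   (and therefore no petioles), giving an all-background scene.
#' @param n_petioles Number of petioles (each carrying one trifoliate
#'   cluster).
#' @param petiole_length,petiole_width Petiole length range and thickness.
#' @param leaflet_major,leaflet_minor Leaflet ellipse semi-axis ranges.
#' @param orientation_jitter Leaflet orientation jitter (degrees, sd).
#' @param bg_base,bg_texture_sd Background base intensity and cloth-texture
#'   standard deviation.
#' @param pixel_noise_sd Per-pixel sensor noise standard deviation.
#' @param illumination `"normal"` or `"high_light"`.
#' @param speckle_density Speckles per pixel under high light.
#' @param speckle_intensity Speckle brightness range.
#' @param highlight_lift Background intensity lift under high light.
#' @param seed Scene RNG seed; the same spec renders byte-identically.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(canvas = c(96L, 160L), stem_width = NULL,
                       stem_length = 1, n_petioles = 4L, petiole_length = NULL,
                       petiole_width = NULL, leaflet_major = NULL,
                       leaflet_minor = NULL, orientation_jitter = 8,
                       bg_base = 0.06, bg_texture_sd = 0.02,
                       pixel_noise_sd = 0.015,
                       illumination = c("normal", "high_light"),
                       speckle_density = 0.004,
                       speckle_intensity = c(0.35, 0.7),
                       highlight_lift = 0.10, seed = 1L) {
  canvas <- as.integer(canvas)
  sc <- canvas[1] / 96
  spec <- list(
    canvas = canvas,
    stem_width = stem_width %||% max(1, round(3 * sc)),
    stem_length = stem_length,
    n_petioles = as.integer(n_petioles),
    petiole_length = petiole_length %||% (c(12, 22) * sc),
    petiole_width = petiole_width %||% max(1, round(2 * sc)),
    leaflets_per_petiole = 3L,
    leaflet_major = leaflet_major %||% (c(7, 11) * sc),
    leaflet_minor = leaflet_minor %||% (c(4, 7) * sc),
    orientation_jitter = orientation_jitter,
    bg_base = bg_base, bg_texture_sd = bg_texture_sd,
    pixel_noise_sd = pixel_noise_sd,
    illumination = match.arg(illumination),
    speckle_density = speckle_density,
    speckle_intensity = speckle_intensity,
    highlight_lift = highlight_lift,
    seed = as.integer(seed))
  if (spec$stem_width < 1) stop("stem width must be >= 1 px")
  if (any(spec$leaflet_major <= 0) || any(spec$leaflet_minor <= 0))
    stop("leaflet axes must be positive")
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> ", x$canvas[1], "x", x$canvas[2], ", ", x$n_petioles,
      " petioles, ", x$illumination, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Mark pixels within width/2 of any segment of a polyline (x, y 0-based).
.draw_thick_polyline <- function(mask, pts, width, value) {
  H <- nrow(mask); W <- ncol(mask)
  r <- width / 2
  for (i in seq_len(nrow(pts) - 1L)) {
    p <- pts[i, ]; q <- pts[i + 1L, ]
    lo_c <- max(1L, floor(min(p[1], q[1]) - r)); hi_c <- min(W, ceiling(max(p[1], q[1]) + r) + 1L)
    lo_r <- max(1L, floor(min(p[2], q[2]) - r)); hi_r <- min(H, ceiling(max(p[2], q[2]) + r) + 1L)
    if (lo_c > hi_c || lo_r > hi_r) next
    cc <- lo_c:hi_c; rr <- lo_r:hi_r
    cx <- rep(cc - 0.5, each = length(rr))
    cy <- rep(rr - 0.5, times = length(cc))
    vx <- q[1] - p[1]; vy <- q[2] - p[2]
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((cx - p[1]) * vx + (cy - p[2]) * vy) / L2, 0), 1) else 0
    d2 <- (cx - (p[1] + t * vx))^2 + (cy - (p[2] + t * vy))^2
    hit <- d2 <= r^2
    if (any(hit)) {
      sub <- mask[rr, cc]
      sub[hit] <- value
      mask[rr, cc] <- sub
    }
  }
  mask
}

.fill_ellipse <- function(mask, cx0, cy0, a, b, phi, value) {
  H <- nrow(mask); W <- ncol(mask)
  r <- max(a, b)
  lo_c <- max(1L, floor(cx0 - r)); hi_c <- min(W, ceiling(cx0 + r) + 1L)
  lo_r <- max(1L, floor(cy0 - r)); hi_r <- min(H, ceiling(cy0 + r) + 1L)
  if (lo_c > hi_c || lo_r > hi_r) return(mask)
  cc <- lo_c:hi_c; rr <- lo_r:hi_r
  dx <- rep(cc - 0.5 - cx0, each = length(rr))
  dy <- rep(rr - 0.5 - cy0, times = length(cc))
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  hit <- u^2 + v^2 <= 1
  if (any(hit)) {
    sub <- mask[rr, cc]
    sub[hit] <- value
    mask[rr, cc] <- sub
  }
  mask
}

# Smooth low-frequency noise field (cloth texture).
.texture_field <- function(H, W, sd_out) {
  z <- matrix(stats::rnorm(H * W), H, W)
  z <- .gaussian_blur(array(z, dim = c(H, W, 1L)), 2.5)[, , 1]
  z <- z / max(stats::sd(z), 1e-9) * sd_out
  z
}

# Draw the scene geometry; returns mask plus per-structure bookkeeping.
.scene_geometry <- function(spec) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  mask <- matrix(0L, H, W)
  leaf_id <- matrix(0L, H, W)
  # stem polyline bottom -> top with lateral wander
  k <- 6L
  top_y <- (H - 1) * (1 - 0.95 * min(max(spec$stem_length, 0), 1))
  xs <- numeric(k); ys <- seq(H - 1, top_y, length.out = k)
  xs[1] <- stats::runif(1, 0.35, 0.65) * W
  for (i in 2:k)
    xs[i] <- min(max(xs[i - 1] + stats::rnorm(1, 0, 0.04 * W), 0.12 * W), 0.88 * W)
  stem_pts <- cbind(xs, ys)
  if (spec$stem_length > 0)
    mask <- .draw_thick_polyline(mask, stem_pts, spec$stem_width, 1L)
  # cumulative arc length for petiole attachment
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seg))
  total <- if (spec$stem_length > 0) cum[k] else 0
  interp_stem <- function(t) {
    s <- t * total
    i <- max(1L, min(k - 1L, findInterval(s, cum)))
    f <- (s - cum[i]) / seg[i]
    c(xs[i] + f * (xs[i + 1] - xs[i]), ys[i] + f * (ys[i + 1] - ys[i]),
      atan2(ys[i + 1] - ys[i], xs[i + 1] - xs[i]))
  }
  n_leaf <- 0L
  for (p in if (total > 0) seq_len(spec$n_petioles) else integer(0)) {
    at <- interp_stem(stats::runif(1, 0.15, 0.9))
    side <- if (p %% 2L == 0L) 1 else -1
    ang <- at[3] + side * stats::runif(1, 50, 80) * pi / 180
    len <- stats::runif(1, spec$petiole_length[1], spec$petiole_length[2])
    mid <- at[1:2] + 0.5 * len * c(cos(ang), sin(ang)) +
      stats::rnorm(2, 0, 0.06 * len)
    tip <- at[1:2] + len * c(cos(ang), sin(ang))
    tip <- c(min(max(tip[1], 2), W - 2), min(max(tip[2], 2), H - 2))
    mask <- .draw_thick_polyline(mask, rbind(at[1:2], mid, tip),
                                 spec$petiole_width, 1L)
    # trifoliate cluster at the petiole tip
    tip_ang <- atan2(tip[2] - mid[2], tip[1] - mid[1])
    for (off in c(-50, 0, 50)) {
      n_leaf <- n_leaf + 1L
      la <- stats::runif(1, spec$leaflet_major[1], spec$leaflet_major[2])
      lb <- stats::runif(1, spec$leaflet_minor[1], spec$leaflet_minor[2])
      if (off == 0) { la <- la * 1.1; lb <- lb * 1.1 }
      th <- tip_ang + off * pi / 180 +
        stats::rnorm(1, 0, spec$orientation_jitter * pi / 180)
      ctr <- tip + 0.55 * la * c(cos(th), sin(th))
      mask <- .fill_ellipse(mask, ctr[1], ctr[2], la, lb, th, 2L)
      leaf_id <- .fill_ellipse(leaf_id, ctr[1], ctr[2], la, lb, th, n_leaf)
    }
  }
  list(mask = mask, leaf_id = leaf_id, n_leaf = n_leaf)
}

#' Render a synthetic branch scene with its ground-truth mask
#'
#' Renders the stem and petioles as thick polylines (class 1), trifoliate
#' leaflets as filled rotated ellipses drawn over them (class 2), and a dark
#' cloth-textured background (class 0). The image colours each class
#' (green leaves with per-leaflet brightness variation, pale brown-green
#' stems) and adds texture, an illumination gradient and sensor noise; the
#' mask is the exact render geometry. Under the `"high_light"` regime the
#' background is additionally lifted and bright speckles are scattered
#' between the leaflets; the mask is unaffected by illumination.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (`(H, W, 3)` in `[0, 1]`) and `mask`
#'   (integer `H x W`, labels 0/1/2).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  geo <- .scene_geometry(spec)
  mask <- geo$mask
  # background: warm-tinted dark cloth with smooth texture
  tex <- .texture_field(H, W, spec$bg_texture_sd)
  base <- pmax(spec$bg_base + tex, 0)
  tint <- c(1.0, 0.97, 0.92)
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- base * tint[ch]
  # stems: pale brown-green with per-pixel jitter
  stem_col <- c(0.47, 0.40, 0.24)
  sj <- 1 + stats::rnorm(sum(mask == 1L), 0, 0.08)
  for (ch in 1:3) img[, , ch][mask == 1L] <- stem_col[ch] * sj
  # leaves: green, per-leaflet brightness factor
  leaf_col <- c(0.16, 0.48, 0.14)
  lf <- stats::runif(max(geo$n_leaf, 1L), 0.85, 1.15)
  lj <- 1 + stats::rnorm(sum(mask == 2L), 0, 0.05)
  for (ch in 1:3) {
    pl <- img[, , ch]
    sel <- mask == 2L
    pl[sel] <- leaf_col[ch] * lf[geo$leaf_id[sel]] * lj
    img[, , ch] <- pl
  }
  # vertical illumination gradient and sensor noise
  grad <- 1 + 0.05 * (row(mask) / H - 0.5)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
  img <- img + stats::rnorm(length(img), 0, spec$pixel_noise_sd)
  # high-light regime: lifted background plus bright speckles between leaves
  if (spec$illumination == "high_light" && spec$speckle_density > 0) {
    set.seed(spec$seed + 777L)
    bg <- mask == 0L
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[bg] <- pl[bg] + spec$highlight_lift * tint[ch]
      img[, , ch] <- pl
    }
    # candidate sites: background near (but not on) leaves
    leaf <- array(as.double(mask == 2L), dim = c(H, W, 1L, 1L))
    near <- .maxpool_fwd(leaf, 9L, 1L, 4L)$y[, , 1, 1] > 0
    cand <- which(near & bg)
    if (!length(cand)) cand <- which(bg)
    n_spk <- max(1L, round(spec$speckle_density * H * W))
    ctr <- cand[sample.int(length(cand), min(n_spk, length(cand)))]
    rs <- ((ctr - 1L) %% H) + 1L
    cs <- ((ctr - 1L) %/% H) + 1L
    for (s in seq_along(ctr)) {
      rad <- stats::runif(1, 0.8, 2.2)
      amp <- stats::runif(1, spec$speckle_intensity[1], spec$speckle_intensity[2])
      rr <- max(1L, rs[s] - 3L):min(H, rs[s] + 3L)
      cc <- max(1L, cs[s] - 3L):min(W, cs[s] + 3L)
      d2 <- outer((rr - rs[s])^2, (cc - cs[s])^2, `+`)
      blob <- amp * exp(-d2 / (2 * rad^2))
      for (ch in 1:3) img[rr, cc, ch] <- img[rr, cc, ch] + blob
    }
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Render the high-light variant of a scene
#'
#' Same geometry and mask as [generate_scene()] with
#' `illumination = "high_light"`: raised background intensity and bright
#' speckles concentrated between leaflets — the stimulus for
#' background-between-leaves misclassification. With `speckle_density = 0`
#' the renderer reduces exactly to the normal regime.
#'
#' @param spec A [scene_spec()]; its illumination is forced to high_light.
#' @return As [generate_scene()].
#' @export
generate_highlight_scene <- function(spec) {
  spec$illumination <- "high_light"
  generate_scene(spec)
}

#' Generate a batch of scenes in memory
#'
#' @param n Number of scenes.
#' @param canvas Scene size `c(H, W)`.
#' @param seed Base seed; scene i is seeded by a fixed hash of `(seed, i)`.
#' @param highlight_fraction Fraction of scenes rendered under high light.
#' @return List of `list(id, image, mask, spec)`.
#' @export
generate_scene_batch <- function(n, canvas = c(96L, 160L), seed = 0L,
                                 highlight_fraction = 0.15) {
  stopifnot(n >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  hl <- stats::runif(n) < highlight_fraction
  lapply(seq_len(n), function(i) {
    sp <- scene_spec(canvas = canvas,
                     illumination = if (hl[i]) "high_light" else "normal",
                     seed = .draw_seed(seed, i, 0L))
    sc <- generate_scene(sp)
    list(id = sprintf("scene%04d", i), image = sc$image, mask = sc$mask,
         spec = sp)
  })
}

#' Write a fixture dataset of synthetic scenes with a manifest
#'
#' Renders `n_scenes` scenes and writes image PNGs, mask PNGs and a JSON
#' manifest of the underlying [scene_spec()]s; the dataset is byte-identical
#' when regenerated from the manifest via [regenerate_from_manifest()].
#'
#' @param out_dir Destination directory.
#' @param n_scenes Number of scenes (300 emulates a typical annotated corpus).
#' @param canvas Scene size.
#' @param seed Base seed.
#' @param highlight_fraction Fraction of high-light scenes.
#' @return Invisibly, the manifest path.
#' @export
build_fixture_dataset <- function(out_dir, n_scenes, canvas = c(96L, 160L),
                                  seed = 0L, highlight_fraction = 0.15) {
  batch <- generate_scene_batch(n_scenes, canvas, seed, highlight_fraction)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- lapply(batch, function(s) {
    write_image(s$image, file.path(out_dir, paste0(s$id, "_img.png")))
    write_mask(s$mask, file.path(out_dir, paste0(s$id, "_mask.png")))
    c(list(id = s$id), unclass(s$spec))
  })
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Regenerate scenes from a fixture manifest
#'
#' @param manifest_path Path to a `manifest.json` from
#'   [build_fixture_dataset()].
#' @return List of `list(id, image, mask, spec)` identical to the original
#'   batch.
#' @export
regenerate_from_manifest <- function(manifest_path) {
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  lapply(man, function(m) {
    sp <- scene_spec(canvas = unlist(m$canvas), stem_width = m$stem_width,
                     stem_length = m$stem_length, n_petioles = m$n_petioles,
                     petiole_length = unlist(m$petiole_length),
                     petiole_width = m$petiole_width,
                     leaflet_major = unlist(m$leaflet_major),
                     leaflet_minor = unlist(m$leaflet_minor),
                     orientation_jitter = m$orientation_jitter,
                     bg_base = m$bg_base, bg_texture_sd = m$bg_texture_sd,
                     pixel_noise_sd = m$pixel_noise_sd,
                     illumination = m$illumination,
                     speckle_density = m$speckle_density,
                     speckle_intensity = unlist(m$speckle_intensity),
                     highlight_lift = m$highlight_lift, seed = m$seed)
    sc <- generate_scene(sp)
    list(id = m$id, image = sc$image, mask = sc$mask, spec = sp)
  })
}
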