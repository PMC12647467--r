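#' Polygon annotation
#'
#' One labelled polygon in pixel coordinates. The coordinate system is
#' continuous, 0-based, origin at the top-left image corner, x rightwards and
#' y downwards; the pixel in matrix row r, column c (1-based) has its center
#' at `(x, y) = (c - 0.5, r - 0.5)`.
#'
#' @param label Class label, `"branch"` or `"leaf"`.
#' @param vertices Numeric n x 2 matrix of (x, y) vertices, n >= 3.
#' @param image_size Integer `c(H, W)`.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(label, vertices, image_size) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  structure(list(label = label, vertices = vertices,
                 image_size = as.integer(image_size)),
            class = "polygon_annotation")
}

#' Read labelme-style polygon annotations from JSON
#'
#' Expects the labelme dialect: a top-level object with `shapes` (each having
#' `label` and `points`), `imageHeight` and `imageWidth`. Non-polygon shapes
#' and unknown fields are ignored.
#'
#' @param path Path to a `.json` annotation file.
#' @return List with `annotations` (list of [polygon_annotation()]) and
#'   `image_size` `c(H, W)`.
#' @export
read_labelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  size <- c(as.integer(j$imageHeight), as.integer(j$imageWidth))
  shapes <- j$shapes %||% list()
  annos <- lapply(shapes, function(s) {
    pts <- s$points
    if (!is.matrix(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    polygon_annotation(s$label, pts, size)
  })
  list(annotations = annos, image_size = size)
}

# Scanline even-odd fill of one polygon onto an existing integer canvas.
# Half-open vertical rule (ymin <= y < ymax per edge) so shared vertices are
# counted once; pixel centers at (c - 0.5, r - 0.5).
.fill_polygon <- function(canvas, vertices, value) {
  H <- nrow(canvas); W <- ncol(canvas)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  keep <- vy != y2
  x1 <- vx[keep]; y1 <- vy[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(canvas)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  r0 <- max(1L, as.integer(ceiling(min(ylo) + 0.5)))
  r1 <- min(H, as.integer(ceiling(max(yhi) + 0.5)) - 1L)
  if (r0 > r1) return(canvas)
  for (r in r0:r1) {
    yc <- r - 0.5
    act <- ylo <= yc & yc < yhi
    if (!any(act)) next
    xs <- x1[act] + (yc - y1[act]) * (x2[act] - x1[act]) / (y2[act] - y1[act])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- max(1L, as.integer(ceiling(xs[k] + 0.5)))
      c1 <- min(W, as.integer(ceiling(xs[k + 1L] + 0.5)) - 1L)
      if (c0 <= c1) canvas[r, c0:c1] <- value
    }
  }
  canvas
}

#' Rasterize polygon annotations into a label mask
#'
#' Scanline even-odd fill of each polygon onto a zero (background) canvas,
#' in file order, later polygons overwriting earlier ones; `"branch"` maps to
#' 1 and `"leaf"` to 2. A pixel is inside a polygon when its center lies
#' inside under the even-odd rule.
#'
#' @param annos List of [polygon_annotation()] objects.
#' @param H,W Output mask size.
#' @param label_map Named integer vector mapping label strings to classes.
#' @return Integer `H x W` label mask.
#' @export
rasterize_annotations <- function(annos, H, W,
                                  label_map = c(branch = 1L, leaf = 2L)) {
  mask <- matrix(0L, H, W)
  for (a in annos) {
    if (!a$label %in% names(label_map))
      stop("unknown annotation label: ", a$label)
    if (nrow(a$vertices) < 3L) {
      warning("skipping degenerate polygon with fewer than 3 vertices")
      next
    }
    mask <- .fill_polygon(mask, a$vertices, label_map[[a$label]])
  }
  mask
}

#' Write / read a label mask as single-channel 8-bit PNG
#'
#' Class integers are stored directly in the 8-bit channel, so the
#' write-then-read round trip is the identity for any mask with values
#' 0..255. Use [write_mask_preview()] for a colourized view.
#'
#' @param mask Integer label-mask matrix.
#' @param path Output `.png` path.
#' @export
write_mask <- function(mask, path) {
  storage.mode(mask) <- "integer"
  if (any(mask < 0L | mask > 255L)) stop("mask values must be in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask` returns the integer label-mask matrix.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  m
}

#' Colourized preview of a label mask (background black, branch red, leaf green)
#' @param mask Integer label mask with values in 0..2.
#' @param path Output `.png` path.
#' @export
write_mask_preview <- function(mask, path) {
  pal <- rbind(c(0, 0, 0), c(0.8, 0.1, 0.1), c(0.1, 0.7, 0.1))
  img <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (k in 0:2) for (ch in 1:3) img[, , ch][mask == k] <- pal[k + 1L, ch]
  png::writePNG(img, path)
  invisible(path)
}

#' Read / write an RGB image as PNG
#' @param path A `.png` path.
#' @return `read_image` returns an `(H, W, 3)` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  x[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Nearest-neighbour index map with half-pixel alignment.
.nn_index <- function(n_in, n_out) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
}

#' Resize an image/mask pair to the model input size
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour lookup (which cannot invent labels), both using
#' half-pixel sample alignment.
#'
#' @param image `(H, W, 3)` array, or NULL.
#' @param mask Integer label-mask matrix, or NULL.
#' @param target Output size `c(H, W)` (default 480 x 1024, the reference input size).
#' @return List with resized `image` and `mask`.
#' @export
resize_sample <- function(image, mask, target = c(480L, 1024L)) {
  target <- as.integer(target)
  if (any(target <= 0L)) stop("target size must be positive")
  out <- list(image = NULL, mask = NULL)
  if (!is.null(image)) {
    d <- dim(image)
    x <- array(image, dim = c(d[1], d[2], d[3], 1L))
    y <- .bilinear_fwd(x, target[1], target[2])
    out$image <- array(y, dim = c(target, d[3]))
  }
  if (!is.null(mask)) {
    ri <- .nn_index(nrow(mask), target[1])
    ci <- .nn_index(ncol(mask), target[2])
    out$mask <- mask[ri, ci, drop = FALSE]
  }
  out
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids with the given seed, draws the test set first, and splits
#' the remainder by the train/validation ratios (7:3 by default; 300 ids
#' with 50 test yield 175/75/50).
#'
#' @param ids Character or integer vector of sample ids.
#' @param ratios Train/validation proportions, summing to 1.
#' @param test_count Number of ids drawn into the test set.
#' @param seed Integer RNG seed.
#' @return An object of class `dataset_split` with `train_ids`, `val_ids`,
#'   `test_ids`, `ratios`, `seed`.
#' @export
split_dataset <- function(ids, ratios = c(0.7, 0.3), test_count, seed = 0L) {
  stopifnot(length(ratios) == 2L, abs(sum(ratios) - 1) < 1e-8)
  if (length(ids) <= test_count) stop("need more ids than test_count")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sh <- sample(ids)
  test <- sh[seq_len(test_count)]
  rest <- sh[-seq_len(test_count)]
  n_train <- round(ratios[1] * length(rest))
  structure(list(train_ids = rest[seq_len(n_train)],
                 val_ids = rest[-seq_len(n_train)],
                 test_ids = test, ratios = ratios, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train=", length(x$train_ids), " val=", length(x$val_ids),
      " test=", length(x$test_ids), " (ratios ", x$ratios[1], ":", x$ratios[2],
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Convert a directory of labelme JSON files to label-mask PNGs
#' @param json_dir Directory of `.json` annotation files.
#' @param out_dir Output directory for `<stem>.png` masks.
#' @return Invisibly, the written file paths.
#' @export
convert_annotations <- function(json_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(json_dir, pattern = "\\.json$", full.names = TRUE)
  out <- character(length(files))
  for (i in seq_along(files)) {
    lj <- read_labelme(files[i])
    mask <- rasterize_annotations(lj$annotations, lj$image_size[1],
                                  lj$image_size[2])
    out[i] <- file.path(out_dir, sub("\\.json$", ".png", basename(files[i])))
    write_mask(mask, out[i])
  }
  invisible(out)
}

# RNG bracket helpers: run seeded code without disturbing the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
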