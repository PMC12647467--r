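# Independent oracles used across the suite. These deliberately use naive
# scalar algorithms so they share no code path with the implementation.

# Direct-summation convolution, scalar loops.
conv2d_oracle <- function(x, w, b, stride, pad, dil) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - (dil * (kh - 1) + 1)) %/% stride + 1
  Wo <- (d[2] + 2 * pad - (dil * (kw - 1) + 1)) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(d[3])) {
        hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
        wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
          acc <- acc + x[hi, wi, ci, n] * w[i, j, ci, co]
      }
      y[ho, wo, co, n] <- acc
    }
  y
}

# Naive double-loop pixel metrics (accuracy and mean IoU).
metrics_oracle <- function(pred, truth, K = 3L) {
  correct <- 0L
  tp <- fp <- fn <- integer(K)
  for (r in seq_len(nrow(pred))) for (c in seq_len(ncol(pred))) {
    p <- pred[r, c]; t <- truth[r, c]
    if (p == t) {
      correct <- correct + 1L
      tp[t + 1L] <- tp[t + 1L] + 1L
    } else {
      fp[p + 1L] <- fp[p + 1L] + 1L
      fn[t + 1L] <- fn[t + 1L] + 1L
    }
  }
  iou <- numeric(K)
  for (i in seq_len(K)) {
    den <- tp[i] + fp[i] + fn[i]
    iou[i] <- if (den == 0L) 1 else tp[i] / den
  }
  list(accuracy = correct / length(pred), miou = mean(iou), iou = iou)
}

# Even-odd crossing-number point-in-polygon test at every pixel center.
rasterize_oracle <- function(vertices, H, W, value = 1L) {
  mask <- matrix(0L, H, W)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  nv <- length(vx)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    px <- c - 0.5; py <- r - 0.5
    inside <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      if ((vy[i] > py) != (vy[j] > py)) {
        xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    if (inside) mask[r, c] <- value
  }
  mask
}

# Random star-shaped (hence simple) polygon around a center.
random_simple_polygon <- function(H, W, n_vertices = 8L) {
  cx <- runif(1, W * 0.25, W * 0.75)
  cy <- runif(1, H * 0.25, H * 0.75)
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.1, 0.45) * min(H, W)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# Connected-component check by breadth-first flood fill on a binary matrix
# (4-connectivity). Returns TRUE when all TRUE cells form one component.
is_connected <- function(bin) {
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  H <- nrow(bin); W <- ncol(bin)
  seen <- matrix(FALSE, H, W)
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r >= 1 && r <= H && c >= 1 && c <= W && bin[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  sum(seen) == sum(bin)
}

# Relative L2 distance between analytic and numeric gradients.
rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-12)

# Central-difference numeric gradient of a scalar function of one array.
numeric_grad <- function(f, x, eps = 1e-3, idx = seq_along(x)) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    q <- idx[k]
    x2 <- x; x2[q] <- x2[q] + eps
    x3 <- x; x3[q] <- x3[q] - eps
    g[k] <- (f(x2) - f(x3)) / (2 * eps)
  }
  g
}

# A degenerate augmentation configuration whose every draw is the identity.
identity_aug_config <- function(seed = 1L) {
  augmentation_config(hflip = FALSE, vflip = FALSE, scale = c(1, 1),
                      translate = 0, rotate = 0, brightness = 0, hue = 0,
                      saturation = 0, contrast = c(1, 1), gaussian_noise = 0,
                      gaussian_blur = 0, per_image_count = 1L, seed = seed)
}

# Small in-memory scene set shared by several files.
tiny_scenes <- function(n, canvas = c(96L, 160L), seed = 42L)
  generate_scene_batch(n, canvas = canvas, seed = seed)
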