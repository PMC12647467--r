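#' Pixel-wise confusion tally between predicted and true label masks
#'
#' Compares two label masks cell by cell and accumulates, for each class
#' `i` in `0..K-1`, the true positives (pixels of class i predicted as i),
#' false positives (pixels of another class predicted as i) and false
#' negatives (pixels of class i predicted otherwise), plus the total number
#' of correct pixels and the total pixel count.
#'
#' @param pred,truth Integer matrices of identical shape with values in
#'   `0..K-1`.
#' @param K Number of classes (default 3: background, branch/stem, leaf).
#' @return An object of class `confusion_tally` with integer vectors `tp`,
#'   `fp`, `fn` (length K, named by class index) and scalars `total_correct`,
#'   `total_pixels`.
#' @export
tally_confusion <- function(pred, truth, K = 3L) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical shapes")
  K <- as.integer(K)
  p <- as.integer(pred); t <- as.integer(truth)
  if (anyNA(p) || anyNA(t) || any(p < 0L | p >= K) || any(t < 0L | t >= K))
    stop("labels must lie in 0..K-1")
  lv <- 0:(K - 1L)
  cm <- table(truth = factor(t, levels = lv), pred = factor(p, levels = lv))
  cm <- matrix(as.integer(cm), K, K)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  structure(list(tp = stats::setNames(as.integer(tp), lv),
                 fp = stats::setNames(as.integer(fp), lv),
                 fn = stats::setNames(as.integer(fn), lv),
                 total_correct = as.integer(sum(tp)),
                 total_pixels = length(p),
                 K = K),
            class = "confusion_tally")
}

#' Add two confusion tallies (pooled evaluation over many images)
#' @param e1,e2 `confusion_tally` objects with equal K.
#' @return A pooled `confusion_tally`.
#' @export
"+.confusion_tally" <- function(e1, e2) {
  stopifnot(e1$K == e2$K)
  structure(list(tp = e1$tp + e2$tp, fp = e1$fp + e2$fp, fn = e1$fn + e2$fn,
                 total_correct = e1$total_correct + e2$total_correct,
                 total_pixels = e1$total_pixels + e2$total_pixels, K = e1$K),
            class = "confusion_tally")
}

#' @export
print.confusion_tally <- function(x, ...) {
  cat("<confusion_tally> K=", x$K, ", ", x$total_correct, "/", x$total_pixels,
      " correct\n", sep = "")
  print(data.frame(class = names(x$tp), tp = x$tp, fp = x$fp, fn = x$fn,
                   iou = round(class_iou(x), 4), row.names = NULL))
  invisible(x)
}

#' Pixel accuracy: correct predictions over total predictions
#' @param tally A [tally_confusion()] result.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(tally) {
  stopifnot(inherits(tally, "confusion_tally"))
  if (tally$total_pixels == 0L) stop("empty tally: no pixels")
  tally$total_correct / tally$total_pixels
}

#' Per-class intersection over union
#'
#' `TP_i / (TP_i + FP_i + FN_i)` for each class. A class absent from both
#' masks (zero denominator) is scored 1: an absent class predicted absent is
#' a perfect prediction for that class.
#'
#' @param tally A [tally_confusion()] result.
#' @return Named numeric vector of length K.
#' @export
class_iou <- function(tally) {
  stopifnot(inherits(tally, "confusion_tally"))
  den <- tally$tp + tally$fp + tally$fn
  ifelse(den == 0L, 1, tally$tp / den)
}

#' Mean intersection over union across classes
#'
#' The unweighted mean of the per-class IoU values
#' `(1/K) * sum_i TP_i / (TP_i + FP_i + FN_i)`.
#'
#' @param tally A [tally_confusion()] result.
#' @return mIoU in `[0, 1]`.
#' @export
mean_iou <- function(tally) mean(class_iou(tally))

# logits: (H, W, K) or (H, W, K, N); truth: H x W matrix or (H, W, N) array.
# Returns list(p = softmax probs matrix (pixels x K), ti = 1-based true class
# per pixel, dims).
.flatten_logits <- function(logits, truth, K = NULL) {
  d <- dim(logits)
  if (length(d) == 3L) { dim(logits) <- c(d, 1L); d <- dim(logits) }
  if (length(d) != 4L) stop("logits must be (H, W, K) or (H, W, K, N)")
  td <- dim(truth)
  if (length(td) == 2L) dim(truth) <- c(td, 1L)
  if (!identical(as.integer(dim(truth)), as.integer(d[c(1, 2, 4)])))
    stop("logits and truth shapes do not match")
  Kc <- d[3]
  if (!is.null(K) && K != Kc) stop("logit channels do not match K")
  t <- as.integer(truth)
  if (any(t < 0L | t >= Kc)) stop("labels must lie in 0..K-1")
  zm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = Kc)   # pixels x K
  zmax <- do.call(pmax, as.data.frame(zm))
  ez <- exp(zm - zmax)
  p <- ez / rowSums(ez)
  list(p = p, zm = zm, ti = t + 1L, K = Kc, dims = d)
}

#' Pixel-averaged cross-entropy loss
#'
#' Mean over all pixels of the negative log softmax probability of the true
#' class, computed with a stabilized log-sum-exp.
#'
#' @param logits Numeric array `(H, W, K)` or `(H, W, K, N)` of unnormalized
#'   class scores.
#' @param truth Integer label mask `H x W` (or `(H, W, N)`), values `0..K-1`.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(logits, truth) {
  f <- .flatten_logits(logits, truth)
  zmax <- do.call(pmax, as.data.frame(f$zm))
  lse <- log(rowSums(exp(f$zm - zmax))) + zmax
  zt <- f$zm[cbind(seq_len(nrow(f$zm)), f$ti)]
  mean(lse - zt)
}

#' Soft Dice loss
#'
#' `1 - (1/K) * sum_i (2 * sum(p_i t_i) + s) / (sum(p_i) + sum(t_i) + s)`
#' with softmax probabilities `p`, one-hot truth `t` and smoothing `s`,
#' averaged over all K classes. Sensitive to small foreground regions, which
#' makes it a common companion to cross-entropy under class imbalance.
#'
#' @inheritParams cross_entropy_loss
#' @param smooth Smoothing constant `s` (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(logits, truth, smooth = 1) {
  f <- .flatten_logits(logits, truth)
  d <- numeric(f$K)
  for (i in seq_len(f$K)) {
    ti <- as.numeric(f$ti == i)
    d[i] <- (2 * sum(f$p[, i] * ti) + smooth) / (sum(f$p[, i]) + sum(ti) + smooth)
  }
  1 - mean(d)
}

#' Combined cross-entropy + Dice loss
#'
#' `w_ce * cross_entropy + w_dice * dice`. With weights `c(1, 0)` this is
#' exactly the cross-entropy loss.
#'
#' @inheritParams dice_loss
#' @param weights Nonnegative pair `c(w_ce, w_dice)` (default `c(1, 1)`).
#' @return An object of class `loss_value` with fields `cross_entropy`,
#'   `dice`, `combined`, `weights`.
#' @export
combined_loss <- function(logits, truth, weights = c(1, 1), smooth = 1) {
  stopifnot(length(weights) == 2L, all(weights >= 0))
  ce <- cross_entropy_loss(logits, truth)
  dc <- dice_loss(logits, truth, smooth)
  structure(list(cross_entropy = ce, dice = dc,
                 combined = weights[1] * ce + weights[2] * dc,
                 weights = weights),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> ce=%.5f dice=%.5f combined=%.5f (w=%g,%g)\n",
              x$cross_entropy, x$dice, x$combined, x$weights[1], x$weights[2]))
  invisible(x)
}

# Loss value + gradient w.r.t. logits, used by the training engine.
# Returns list(loss, grad) with grad shaped like logits.
.loss_and_grad <- function(logits, truth, loss = c("ce", "ce_plus_dice"),
                           weights = c(1, 1), smooth = 1) {
  loss <- match.arg(loss)
  f <- .flatten_logits(logits, truth)
  M <- nrow(f$p); K <- f$K
  onehot_idx <- cbind(seq_len(M), f$ti)
  ce <- -mean(log(pmax(f$p[onehot_idx], 1e-12)))
  gce <- f$p
  gce[onehot_idx] <- gce[onehot_idx] - 1
  gce <- gce / M
  if (loss == "ce") {
    gm <- gce; val <- ce
  } else {
    A <- B <- Dn <- numeric(K)
    tmat <- matrix(0, M, K)
    tmat[onehot_idx] <- 1
    for (i in seq_len(K)) {
      A[i] <- sum(f$p[, i] * tmat[, i])
      B[i] <- sum(f$p[, i]) + sum(tmat[, i])
      Dn[i] <- (2 * A[i] + smooth) / (B[i] + smooth)
    }
    dice <- 1 - mean(Dn)
    # d(dice)/dp_i(x) = -(1/K) * (2 t_i(x) (B_i+s) - (2 A_i+s)) / (B_i+s)^2
    gp <- matrix(0, M, K)
    for (i in seq_len(K))
      gp[, i] <- -(2 * tmat[, i] * (B[i] + smooth) - (2 * A[i] + smooth)) /
        (K * (B[i] + smooth)^2)
    # chain through softmax: gz = p * (gp - rowSums(gp * p))
    gdice <- f$p * (gp - rowSums(gp * f$p))
    gm <- weights[1] * gce + weights[2] * gdice
    val <- weights[1] * ce + weights[2] * dice
  }
  d <- f$dims
  grad <- aperm(array(gm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(loss = val, grad = grad)
}

#' Evaluate predicted masks against ground truth, per image and pooled
#'
#' @param pairs A list of `list(id, pred, truth)` entries with label-mask
#'   matrices.
#' @param K Number of classes.
#' @return A data.frame with one row per image plus a final `pooled` row:
#'   columns `image`, `accuracy`, `iou_background`, `iou_branch`, `iou_leaf`
#'   (for K = 3; generally `iou_<class>`), `miou`.
#' @export
evaluate_masks <- function(pairs, K = 3L) {
  cls <- if (K == 3L) c("background", "branch", "leaf") else paste0("class", 0:(K - 1L))
  pooled <- NULL
  rows <- lapply(pairs, function(p) {
    tl <- tally_confusion(p$pred, p$truth, K)
    pooled <<- if (is.null(pooled)) tl else pooled + tl
    ious <- class_iou(tl)
    out <- data.frame(image = as.character(p$id), accuracy = accuracy(tl))
    for (i in seq_len(K)) out[[paste0("iou_", cls[i])]] <- ious[i]
    out$miou <- mean_iou(tl)
    out
  })
  res <- do.call(rbind, rows)
  pr <- data.frame(image = "pooled", accuracy = accuracy(pooled))
  ious <- class_iou(pooled)
  for (i in seq_len(K)) pr[[paste0("iou_", cls[i])]] <- ious[i]
  pr$miou <- mean_iou(pooled)
  rbind(res, pr)
}
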