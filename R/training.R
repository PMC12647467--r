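#' Training protocol configuration
#'
#' The reference training protocol: minibatch size 5, Adam with initial learning rate
#' 0.001, cross-entropy loss (optionally combined with soft Dice), and an
#' optional per-epoch multiplicative learning-rate decay (0.95^epoch in the
#' 100-epoch fine-tuning stage).
#'
#' @param batch_size Minibatch size (>= 1; the final short batch is kept).
#' @param initial_lr Initial Adam learning rate.
#' @param epochs Number of epochs.
#' @param lr_decay_factor Per-epoch multiplicative decay in (0, 1]; 1
#'   disables decay.
#' @param loss `"ce"` (cross-entropy) or `"ce_plus_dice"`.
#' @param loss_weights Weights `c(w_ce, w_dice)` for the combined loss.
#' @param seed Seed governing initialization, data order and all draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 5L, initial_lr = 0.001,
                            epochs = 50L, lr_decay_factor = 1.0,
                            loss = c("ce", "ce_plus_dice"),
                            loss_weights = c(1, 1), seed = 0L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("lr_decay_factor must be in (0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 optimizer = "adam", initial_lr = initial_lr,
                 epochs = as.integer(epochs),
                 lr_decay_factor = lr_decay_factor,
                 loss = match.arg(loss), loss_weights = loss_weights,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Learning rate in effect at a given epoch
#'
#' `initial_lr * lr_decay_factor^epoch` with 0-based epoch numbering, so
#' epoch 0 trains at the initial rate and epoch 10 at
#' `0.001 * 0.95^10 ~ 5.987e-4` under the decayed schedule.
#'
#' @param config A [training_config()].
#' @param epoch Epoch index, 0-based, >= 0.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$initial_lr * config$lr_decay_factor^epoch
}

# Stack list-of-samples into batch arrays.
.stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, dim = c(d[1], d[2], d[3], length(idx)))
  t <- array(0L, dim = c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]$image
    t[, , j] <- samples[[idx[j]]]$mask
  }
  list(x = x, t = t)
}

.batch_loss <- function(model, batch, config) {
  fw <- nn_forward(model, batch$x, training = FALSE, keep = FALSE)
  .loss_and_grad(fw$out, batch$t, config$loss, config$loss_weights)$loss
}

#' Train a segmentation model
#'
#' Standard seeded minibatch loop: per epoch the training samples are
#' shuffled, forward/backward passes accumulate Adam updates at the
#' learning rate of [lr_at_epoch()], and the epoch is logged with training
#' loss, validation loss, and (when a test set is supplied) pooled test
#' accuracy, per-class IoU and mIoU — the protocol evaluates the test set every
#' epoch to support best-epoch selection. A non-finite loss aborts with a
#' diagnostic. Parameters of the best-accuracy epoch are retained.
#'
#' @param model An initialized or uninitialized `dunet_model` (uninitialized
#'   models are initialized from `config$seed`).
#' @param train_set,val_set,test_set Lists of `list(image, mask)` samples
#'   (`val_set`/`test_set` may be NULL).
#' @param config A [training_config()].
#' @param checkpoint_dir Optional directory for per-epoch checkpoints.
#' @param verbose Print one line per epoch.
#' @return An object of class `training_run`: `records` (one data.frame row
#'   per epoch), `model` (final), `best` (epoch index and parameters),
#'   `config`.
#' @export
train <- function(model, train_set, val_set = NULL, config = training_config(),
                  test_set = NULL, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dunet_model"), length(train_set) >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  if (is.null(model$params)) model <- nn_init_model(model, config$seed)
  state <- adam_init(model$params)
  n <- length(train_set)
  records <- NULL
  best <- list(epoch = NA_integer_, accuracy = -Inf, params = NULL,
               buffers = NULL)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep - 1L)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tr_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      batch <- .stack_batch(train_set, idx)
      fw <- nn_forward(model, batch$x, training = TRUE)
      model$buffers <- fw$buffers
      lg <- .loss_and_grad(fw$out, batch$t, config$loss, config$loss_weights)
      if (!is.finite(lg$loss))
        stop(sprintf("divergent loss (%.4g) at epoch %d batch %d", lg$loss,
                     ep, bi))
      grads <- nn_backward(model, fw$cache, lg$grad)
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      tr_losses[bi] <- lg$loss
    }
    rec <- data.frame(epoch = ep, lr = lr, train_loss = mean(tr_losses),
                      val_loss = NA_real_, accuracy = NA_real_,
                      iou_background = NA_real_, iou_branch = NA_real_,
                      iou_leaf = NA_real_, miou = NA_real_)
    if (!is.null(val_set) && length(val_set)) {
      starts <- seq(1L, length(val_set), by = config$batch_size)
      vl <- vapply(starts, function(s0) {
        idx <- s0:min(s0 + config$batch_size - 1L, length(val_set))
        .batch_loss(model, .stack_batch(val_set, idx), config)
      }, numeric(1))
      rec$val_loss <- mean(vl)
    }
    if (!is.null(test_set) && length(test_set)) {
      m <- evaluate_model(model, test_set, batch_size = config$batch_size)
      rec$accuracy <- m$accuracy
      rec$iou_background <- m$class_iou[1]
      rec$iou_branch <- m$class_iou[2]
      rec$iou_leaf <- m$class_iou[3]
      rec$miou <- m$miou
      if (m$accuracy > best$accuracy) {
        best <- list(epoch = ep, accuracy = m$accuracy, params = model$params,
                     buffers = model$buffers)
      }
    }
    records <- rbind(records, rec)
    if (!is.null(checkpoint_dir))
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("epoch%03d.rds", ep)))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %s  acc %s  miou %s",
                      ep, lr, rec$train_loss,
                      ifelse(is.na(rec$val_loss), "-", sprintf("%.4f", rec$val_loss)),
                      ifelse(is.na(rec$accuracy), "-", sprintf("%.4f", rec$accuracy)),
                      ifelse(is.na(rec$miou), "-", sprintf("%.4f", rec$miou))))
  }
  structure(list(records = records, model = model, best = best,
                 config = config),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat("<training_run> ", nrow(x$records), " epochs",
      if (!is.na(x$best$epoch)) sprintf(", best epoch %d (accuracy %.4f)",
                                        x$best$epoch, x$best$accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Select the best epochs of a run by test accuracy
#'
#' Returns the `k` epoch records with the highest test accuracy; ties are
#' broken in favour of the earlier epoch. This is the statistical unit of
#' the repetition protocol (5 repetitions x top-5 epochs = 25 parameter sets).
#'
#' @param records A `training_run` or its `records` data.frame.
#' @param k Number of epochs to select (default 5).
#' @return Data.frame of `k` epoch records, ordered best-first.
#' @export
select_best_epochs <- function(records, k = 5L) {
  if (inherits(records, "training_run")) records <- records$records
  if (nrow(records) < k) stop("need at least k epoch records")
  if (anyNA(records$accuracy)) stop("records lack test accuracy")
  ord <- order(-records$accuracy, records$epoch)
  records[ord[seq_len(k)], , drop = FALSE]
}

#' Pool best-epoch selections across repetitions
#'
#' Applies [select_best_epochs()] to each repetition and binds the
#' selections (n_rep x k rows; 25 under the default protocol), with mean and
#' standard-deviation summaries of accuracy and mIoU.
#'
#' @param runs List of `training_run`s or records data.frames.
#' @param k Epochs selected per repetition.
#' @return List with `selected` (data.frame with `repetition` column) and
#'   `summary` (mean/sd of accuracy and mIoU).
#' @export
summarize_repetitions <- function(runs, k = 5L) {
  sel <- do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- select_best_epochs(runs[[i]], k)
    s$repetition <- i
    s
  }))
  list(selected = sel,
       summary = data.frame(
         n = nrow(sel),
         accuracy_mean = mean(sel$accuracy), accuracy_sd = stats::sd(sel$accuracy),
         miou_mean = mean(sel$miou), miou_sd = stats::sd(sel$miou)))
}

#' Predict a label mask for an image
#'
#' Runs the network in evaluation mode and takes the per-pixel argmax over
#' class logits; ties break to the lowest class index.
#'
#' @param object An initialized `dunet_model`.
#' @param image `(H, W, 3)` array with H, W matching the model input size
#'   (divisible by 32).
#' @param ... Unused.
#' @return Integer `H x W` label mask.
#' @export
predict.dunet_model <- function(object, image, ...) {
  d <- dim(image)
  if (any(d[1:2] %% 32L != 0L))
    stop("input size must be divisible by 32")
  if (!identical(as.integer(d[1:2]), object$config$input_size))
    stop("image size does not match the model input size; resize first")
  fw <- nn_forward(object, array(image, dim = c(d, 1L)), training = FALSE,
                   keep = FALSE)
  .argmax_mask(fw$out)[, , 1]
}

# Per-pixel argmax over (H, W, K, N) logits; ties to the lowest class.
.argmax_mask <- function(logits) {
  d <- dim(logits)
  zm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  lab <- max.col(zm, ties.method = "first") - 1L
  aperm(array(lab, dim = d[c(1, 2, 4)]), c(1, 2, 3))
}

#' Evaluate a model on a sample set (pooled pixel-level metrics)
#'
#' @param model An initialized `dunet_model`.
#' @param samples List of `list(image, mask)` samples.
#' @param batch_size Forward-pass batch size.
#' @return List with `accuracy`, `class_iou` (background, branch, leaf),
#'   `miou` and the pooled `tally`.
#' @export
evaluate_model <- function(model, samples, batch_size = 5L) {
  K <- model$config$num_classes
  pooled <- NULL
  starts <- seq(1L, length(samples), by = batch_size)
  for (s0 in starts) {
    idx <- s0:min(s0 + batch_size - 1L, length(samples))
    batch <- .stack_batch(samples, idx)
    fw <- nn_forward(model, batch$x, training = FALSE, keep = FALSE)
    pred <- .argmax_mask(fw$out)
    for (j in seq_along(idx)) {
      tl <- tally_confusion(pred[, , j], batch$t[, , j], K)
      pooled <- if (is.null(pooled)) tl else pooled + tl
    }
  }
  list(accuracy = accuracy(pooled), class_iou = class_iou(pooled),
       miou = mean_iou(pooled), tally = pooled)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files holding the configuration, parameters and
#' normalization buffers; save-load-predict is bit-identical to predicting
#' before the save.
#'
#' @param model An initialized `dunet_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(builder = model$builder, config = model$config,
               params = model$params, buffers = model$buffers), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `dunet_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- switch(ck$builder,
    unet_baseline = build_unet_baseline(ck$config$num_classes,
                                        ck$config$input_size),
    dunet = build_dunet(do.call(model_config,
      ck$config[c("encoder_family", "width_numerator", "use_cbam",
                  "num_classes", "aspp_rates", "input_size")])),
    stop("unsupported checkpoint builder: ", ck$builder))
  model$params <- ck$params
  model$buffers <- ck$buffers
  model
}

#' Scaled-down fixture benchmark of DU-Net-L
#'
#' The desk-scale stand-in for full-scale training runs: a DU-Net
#' with resnet34 encoder at width 2/8 trained with the reference protocol
#' (batch 5, Adam 0.001, cross-entropy) on synthetic branch scenes, then
#' evaluated on held-out scenes. Problem sizes default to 200 training and
#' 20 test scenes at 96 x 160 for 20 epochs.
#'
#' @param n_train,n_test Scene counts.
#' @param canvas Scene size (divisible by 32).
#' @param epochs Training epochs.
#' @param width_numerator Channel-scaling numerator (default 2).
#' @param seed Master seed for scenes, initialization and data order.
#' @param verbose Print per-epoch progress.
#' @return List with `run` (the `training_run`), `metrics` (final held-out
#'   accuracy, per-class IoU, mIoU) and the sets' sizes.
#' @export
run_fixture_benchmark <- function(n_train = 200L, n_test = 20L,
                                  canvas = c(96L, 160L), epochs = 20L,
                                  width_numerator = 2L, seed = 0L,
                                  verbose = FALSE) {
  scenes <- generate_scene_batch(n_train + n_test, canvas = canvas,
                                 seed = seed)
  train_set <- scenes[seq_len(n_train)]
  test_set <- scenes[n_train + seq_len(n_test)]
  cfg <- model_config("resnet34", width_numerator, num_classes = 3L,
                      input_size = canvas)
  model <- nn_init_model(build_dunet(cfg), seed)
  tc <- training_config(batch_size = 5L, initial_lr = 0.001, epochs = epochs,
                        lr_decay_factor = 1.0, loss = "ce", seed = seed)
  run <- train(model, train_set, val_set = NULL, config = tc,
               test_set = test_set, verbose = verbose)
  metrics <- evaluate_model(run$model, test_set)
  list(run = run, metrics = metrics, n_train = n_train, n_test = n_test)
}
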