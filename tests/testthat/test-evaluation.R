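# Pixel metrics and losses, checked from first principles.

test_that("tally_confusion reproduces the enumerated 2x2 example and its symmetry", {
  truth <- matrix(c(0L, 2L, 1L, 1L), 2)   # [[0,1],[2,1]] row-wise
  pred <- matrix(c(0L, 1L, 1L, 1L), 2)    # [[0,1],[1,1]]
  tl <- tally_confusion(pred, truth, 3L)
  expect_identical(unname(tl$tp), c(1L, 2L, 0L))
  expect_identical(unname(tl$fp), c(0L, 1L, 0L))
  expect_identical(unname(tl$fn), c(0L, 0L, 1L))
  expect_identical(tl$total_correct, 3L)
  expect_equal(accuracy(tl), 0.75)
  expect_equal(mean_iou(tl), (1 + 2 / 3 + 0) / 3)
  # swapping pred and truth swaps FP and FN
  tl2 <- tally_confusion(truth, pred, 3L)
  expect_identical(tl$fp, tl2$fn)
  expect_identical(tl$fn, tl2$fp)
  # identity and disjoint extremes
  tli <- tally_confusion(truth, truth, 3L)
  expect_true(all(tli$fp == 0L) && all(tli$fn == 0L))
  expect_equal(accuracy(tli), 1)
  expect_equal(mean_iou(tli), 1)
  expect_equal(accuracy(tally_confusion(matrix(1L, 2, 2), matrix(2L, 2, 2), 3L)), 0)
  # errors
  expect_error(tally_confusion(matrix(0L, 2, 2), matrix(0L, 3, 2)), "shape")
  expect_error(tally_confusion(matrix(5L, 2, 2), matrix(0L, 2, 2), 3L), "labels")
  expect_error(accuracy(structure(list(total_pixels = 0L),
                                  class = "confusion_tally")), "empty")
})

test_that("metrics agree with a naive double-loop oracle on random masks", {
  set.seed(101)
  for (i in 1:100) {
    h <- sample(1:8, 1); w <- sample(1:8, 1)
    truth <- matrix(sample(0:2, h * w, TRUE), h)
    pred <- matrix(sample(0:2, h * w, TRUE), h)
    tl <- tally_confusion(pred, truth, 3L)
    o <- metrics_oracle(pred, truth, 3L)
    expect_equal(accuracy(tl), o$accuracy)
    expect_equal(mean_iou(tl), o$miou)
    expect_equal(unname(class_iou(tl)), o$iou)
  }
})

test_that("metrics are invariant under simultaneous pixel permutation", {
  set.seed(102)
  truth <- matrix(sample(0:2, 48, TRUE), 6)
  pred <- matrix(sample(0:2, 48, TRUE), 6)
  pm <- sample(48)
  t2 <- matrix(truth[pm], 6); p2 <- matrix(pred[pm], 6)
  expect_equal(accuracy(tally_confusion(pred, truth)),
               accuracy(tally_confusion(p2, t2)))
  expect_equal(mean_iou(tally_confusion(pred, truth)),
               mean_iou(tally_confusion(p2, t2)))
})

test_that("cross-entropy has its closed-form values and scalar-loop oracle agreement", {
  truth <- matrix(sample(0:2, 16, TRUE), 4)
  expect_equal(cross_entropy_loss(array(0, dim = c(4, 4, 3)), truth), log(3))
  # huge margin on the true class drives the loss to zero
  big <- array(0, dim = c(4, 4, 3))
  for (r in 1:4) for (c in 1:4) big[r, c, truth[r, c] + 1L] <- 50
  expect_lt(cross_entropy_loss(big, truth), 1e-12)
  # random case vs an independent scalar loop
  set.seed(103)
  z <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  acc <- 0
  for (r in 1:4) for (c in 1:4) {
    p <- exp(z[r, c, ]) / sum(exp(z[r, c, ]))
    acc <- acc - log(p[truth[r, c] + 1L])
  }
  expect_equal(cross_entropy_loss(z, truth), acc / 16, tolerance = 1e-6)
  expect_error(cross_entropy_loss(array(0, dim = c(3, 4, 3)), truth), "match")
})

test_that("cross-entropy decreases strictly when a true-class logit increases", {
  set.seed(104)
  truth <- matrix(sample(0:2, 16, TRUE), 4)
  z <- array(rnorm(48), dim = c(4, 4, 3))
  l0 <- cross_entropy_loss(z, truth)
  z[2, 3, truth[2, 3] + 1L] <- z[2, 3, truth[2, 3] + 1L] + 0.5
  expect_lt(cross_entropy_loss(z, truth), l0)
})

test_that("dice loss: identity, disjoint and per-class-loop oracle", {
  truth <- matrix(sample(0:2, 16, TRUE), 4)
  big <- array(0, dim = c(4, 4, 3))
  for (r in 1:4) for (c in 1:4) big[r, c, truth[r, c] + 1L] <- 60
  expect_lt(dice_loss(big, truth), 1e-3)   # perfect up to smoothing
  # hard disjoint prediction over all classes, vanishing smoothing -> loss 1
  truth2 <- matrix(rep(0:2, length.out = 16), 4)
  wrong <- array(0, dim = c(4, 4, 3))
  for (r in 1:4) for (c in 1:4)
    wrong[r, c, (truth2[r, c] + 1L) %% 3L + 1L] <- 60
  expect_gt(dice_loss(wrong, truth2, smooth = 1e-9), 1 - 1e-6)
  # random case vs an independent per-class loop
  set.seed(105)
  z <- array(rnorm(48), dim = c(4, 4, 3))
  p <- apply(z, c(1, 2), function(v) exp(v) / sum(exp(v)))  # 3 x 4 x 4
  ds <- numeric(3)
  for (i in 1:3) {
    ti <- (truth == i - 1L) * 1
    pi <- matrix(p[i, , ], 4)
    ds[i] <- (2 * sum(pi * ti) + 1) / (sum(pi) + sum(ti) + 1)
  }
  expect_equal(dice_loss(z, truth), 1 - mean(ds), tolerance = 1e-6)
})

test_that("combined loss with weights (1,0) is exactly cross-entropy", {
  set.seed(106)
  truth <- matrix(sample(0:2, 16, TRUE), 4)
  z <- array(rnorm(48), dim = c(4, 4, 3))
  cl <- combined_loss(z, truth, weights = c(1, 0))
  expect_identical(cl$combined, cl$cross_entropy)
  expect_equal(cl$cross_entropy, cross_entropy_loss(z, truth))
  cl2 <- combined_loss(z, truth, weights = c(1, 1))
  expect_equal(cl2$combined, cl2$cross_entropy + cl2$dice)
})

test_that("loss gradients match finite differences for both loss modes", {
  set.seed(107)
  truth <- array(sample(0:2, 32, TRUE), dim = c(4, 4, 2))
  z <- array(rnorm(4 * 4 * 3 * 2), dim = c(4, 4, 3, 2))
  for (mode in c("ce", "ce_plus_dice")) {
    lg <- dunet:::.loss_and_grad(z, truth, mode)
    idx <- sample(length(z), 10)
    gnum <- numeric_grad(function(zz)
      dunet:::.loss_and_grad(zz, truth, mode)$loss, z, eps = 1e-4, idx = idx)
    expect_lt(rel_err(lg$grad[idx], gnum), 1e-3)
  }
})

test_that("evaluate_masks reports per-image rows plus a pooled row", {
  set.seed(108)
  pairs <- lapply(1:3, function(i) {
    t <- matrix(sample(0:2, 25, TRUE), 5)
    p <- t; p[1, 1] <- (p[1, 1] + 1L) %% 3L
    list(id = paste0("im", i), pred = p, truth = t)
  })
  res <- evaluate_masks(pairs)
  expect_identical(nrow(res), 4L)
  expect_identical(res$image[4], "pooled")
  expect_equal(res$accuracy[1:3], rep(24 / 25, 3))
  expect_equal(res$accuracy[4], 72 / 75)
  expect_true(all(c("iou_background", "iou_branch", "iou_leaf", "miou")
                  %in% names(res)))
})
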