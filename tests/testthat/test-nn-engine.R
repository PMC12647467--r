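# The computation-graph engine: kernel correctness against scalar oracles,
# end-to-end gradients against finite differences, and determinism.

test_that("conv2d forward matches the direct-summation oracle across geometries", {
  set.seed(11)
  cases <- list(c(3, 1, 1, 1),   # k, stride, pad, dilation
                c(3, 1, 2, 2),
                c(1, 1, 0, 1),
                c(3, 2, 1, 1),
                c(7, 2, 3, 1))
  for (cs in cases) {
    x <- array(rnorm(8 * 10 * 4 * 2), dim = c(8, 10, 4, 2))
    w <- array(rnorm(cs[1]^2 * 4 * 3), dim = c(cs[1], cs[1], 4, 3))
    b <- rnorm(3)
    got <- dunet:::.conv2d_fwd(x, w, b, cs[2], cs[3], cs[4])
    want <- conv2d_oracle(x, w, b, cs[2], cs[3], cs[4])
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("conv2d backward matches finite differences", {
  set.seed(12)
  for (cs in list(c(3, 1, 1, 1), c(3, 1, 2, 2), c(1, 1, 0, 1), c(3, 2, 1, 1))) {
    x <- array(rnorm(6 * 7 * 3 * 2), dim = c(6, 7, 3, 2))
    w <- array(rnorm(cs[1]^2 * 3 * 2), dim = c(cs[1], cs[1], 3, 2))
    b <- rnorm(2)
    y <- dunet:::.conv2d_fwd(x, w, b, cs[2], cs[3], cs[4])
    r <- array(rnorm(length(y)), dim = dim(y))
    bw <- dunet:::.conv2d_bwd(x, w, r, cs[2], cs[3], cs[4], TRUE, TRUE)
    iw <- sample(length(w), min(8, length(w)))
    gnum <- numeric_grad(function(wx)
      sum(dunet:::.conv2d_fwd(x, wx, b, cs[2], cs[3], cs[4]) * r), w, idx = iw)
    expect_lt(rel_err(bw$gw[iw], gnum), 1e-2)
    ix <- sample(length(x), 8)
    gnum <- numeric_grad(function(xx)
      sum(dunet:::.conv2d_fwd(xx, w, b, cs[2], cs[3], cs[4]) * r), x, idx = ix)
    expect_lt(rel_err(bw$gx[ix], gnum), 1e-2)
  }
})

test_that("maxpool, bilinear resize and batchnorm backward match finite differences", {
  set.seed(13)
  x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))

  mp <- dunet:::.maxpool_fwd(x, 2L, 2L, 0L)
  r <- array(rnorm(length(mp$y)), dim = dim(mp$y))
  gx <- dunet:::.maxpool_bwd(r, mp$idx, dim(x))
  ix <- sample(length(x), 10)
  gnum <- numeric_grad(function(xx)
    sum(dunet:::.maxpool_fwd(xx, 2L, 2L, 0L)$y * r), x, eps = 1e-4, idx = ix)
  expect_lt(rel_err(gx[ix], gnum), 1e-2)

  up <- dunet:::.bilinear_fwd(x, 16L, 12L)
  r <- array(rnorm(length(up)), dim = dim(up))
  gx <- dunet:::.bilinear_bwd(r, 8L, 8L)
  gnum <- numeric_grad(function(xx)
    sum(dunet:::.bilinear_fwd(xx, 16L, 12L) * r), x, idx = ix)
  expect_lt(rel_err(gx[ix], gnum), 1e-3)

  p <- list(gamma = runif(2, 0.5, 1.5), beta = rnorm(2))
  buf <- list(mean = numeric(2), var = rep(1, 2))
  fw <- dunet:::.bn_fwd(x, p, buf, training = TRUE)
  r <- array(rnorm(length(fw$y)), dim = dim(fw$y))
  bw <- dunet:::.bn_bwd(r, p, fw$aux)
  gnum <- numeric_grad(function(xx)
    sum(dunet:::.bn_fwd(xx, p, buf, training = TRUE)$y * r), x,
    eps = 1e-4, idx = ix)
  expect_lt(rel_err(bw$gx[ix], gnum), 1e-3)
  gnum <- numeric_grad(function(gg)
    sum(dunet:::.bn_fwd(x, list(gamma = gg, beta = p$beta), buf, TRUE)$y * r),
    p$gamma, eps = 1e-4)
  expect_lt(rel_err(bw$grads$gamma, gnum), 1e-3)
})

test_that("CBAM gates preserve shape, lie in (0,1), and backward matches finite differences", {
  set.seed(14)
  x <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  g <- dunet:::nn_graph(4L, c(6L, 6L))
  g <- dunet:::g_add(g, "att", "cbam", "input", list(reduction = 2L))
  model <- structure(list(graph = g), class = "dunet_model")
  ini <- dunet:::nn_init(g, 5L)
  model$params <- ini$params; model$buffers <- ini$buffers
  fw <- dunet:::nn_forward(model, x, training = TRUE)
  expect_identical(dim(fw$out), dim(x))
  aux <- fw$cache[["att"]]$aux
  expect_true(all(aux$s > 0 & aux$s < 1))
  expect_true(all(aux$t > 0 & aux$t < 1))

  r <- array(rnorm(length(x)), dim = dim(x))
  grads <- dunet:::nn_backward(model, fw$cache, r)
  loss_of <- function(pname, val) {
    m2 <- model; m2$params$att[[pname]] <- val
    sum(dunet:::nn_forward(m2, x, training = TRUE)$out * r)
  }
  for (pn in c("w1", "b1", "w2", "b2", "ws", "bs")) {
    p0 <- model$params$att[[pn]]
    idx <- sample(length(p0), min(6, length(p0)))
    gnum <- numeric_grad(function(v) loss_of(pn, v), p0, eps = 1e-4, idx = idx)
    expect_lt(rel_err(as.numeric(grads$att[[pn]])[idx], gnum), 2e-2)
  }
})

test_that("a small full network has correct end-to-end gradients", {
  set.seed(15)
  cfg <- model_config("resnet18", 2L, input_size = c(32L, 32L))
  model <- nn_init_model(build_dunet(cfg), 7L)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  truth <- array(sample(0:2, 32 * 32 * 2, TRUE), dim = c(32, 32, 2))
  fw <- dunet:::nn_forward(model, x, training = TRUE)
  lg <- dunet:::.loss_and_grad(fw$out, truth, "ce")
  grads <- dunet:::nn_backward(model, fw$cache, lg$grad)
  loss_at <- function(node, pname, val) {
    m2 <- model; m2$params[[node]][[pname]] <- val
    f <- dunet:::nn_forward(m2, x, training = TRUE)
    dunet:::.loss_and_grad(f$out, truth, "ce")$loss
  }
  # probe a spread of layers: first conv, a residual conv, an ASPP conv,
  # a decoder conv, the final classifier, and a batchnorm gamma
  probes <- list(c("stem_conv", "w"), c("s2b1_conv1", "w"),
                 c("aspp_b2", "w"), c("un_d0_conv2", "w"),
                 c("logits", "w"), c("s1b1_bn1", "gamma"))
  for (pr in probes) {
    p0 <- model$params[[pr[1]]][[pr[2]]]
    idx <- sample(length(p0), min(4, length(p0)))
    gnum <- numeric_grad(function(v) loss_at(pr[1], pr[2], v), p0,
                         eps = 1e-3, idx = idx)
    expect_lt(rel_err(as.numeric(grads[[pr[1]]][[pr[2]]])[idx], gnum), 5e-2)
  }
})

test_that("builds and forward passes are deterministic given config and seed", {
  cfg <- model_config("resnet18", 3L, input_size = c(32L, 64L))
  m1 <- nn_init_model(build_dunet(cfg), 3L)
  m2 <- nn_init_model(build_dunet(cfg), 3L)
  expect_identical(m1$params, m2$params)
  s1 <- architecture_summary(m1); s2 <- architecture_summary(m2)
  expect_identical(s1$layers, s2$layers)
  x <- array(runif(32 * 64 * 3), dim = c(32, 64, 3, 1))
  o1 <- dunet:::nn_forward(m1, x, keep = FALSE)$out
  o2 <- dunet:::nn_forward(m2, x, keep = FALSE)$out
  expect_identical(o1, o2)
})

test_that("adam steps reduce a simple quadratic objective", {
  params <- list(node = list(w = matrix(c(5, -3, 2, 1), 2)))
  st <- dunet:::adam_init(params)
  for (i in 1:400) {
    g <- list(node = list(w = 2 * params$node$w))
    upd <- dunet:::adam_step(params, g, st, lr = 0.05)
    params <- upd$params; st <- upd$state
  }
  expect_lt(max(abs(params$node$w)), 1e-2)
})
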