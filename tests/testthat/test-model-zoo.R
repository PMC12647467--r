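# Architecture construction, width scaling and exact size accounting.

test_that("model_config validates its fields", {
  expect_error(model_config(width_numerator = 1L), "width_numerator")
  expect_error(model_config(width_numerator = 9L), "width_numerator")
  expect_error(model_config(num_classes = 1L), "num_classes")
  expect_error(model_config(aspp_rates = c(6L, -2L, 18L)), "aspp_rates")
  expect_error(model_config(input_size = c(100L, 1024L)), "divisible by 32")
  expect_error(model_config("vgg16", use_cbam = TRUE), "residual")
})

test_that("encoder taps have the canonical scaled widths and strides", {
  for (n in c(8L, 4L)) {
    enc <- build_encoder(model_config("resnet34", n, input_size = c(64L, 96L)))
    sh <- dunet:::g_shape(enc$graph, enc$taps[["c5"]])
    expect_identical(sh[1], dunet:::scale_width(512L, n))
    expect_identical(sh[2:3], c(64L, 96L) %/% 16L)  # output stride 16
    expect_identical(dunet:::g_shape(enc$graph, enc$taps[["stem"]])[2:3],
                     c(32L, 48L))
    expect_identical(dunet:::g_shape(enc$graph, enc$taps[["c2"]])[1],
                     dunet:::scale_width(64L, n))
  }
  # resnet34 at n=4 has all widths halved
  enc <- build_encoder(model_config("resnet34", 4L, input_size = c(64L, 96L)))
  expect_identical(dunet:::g_shape(enc$graph, enc$taps[["c5"]])[1], 256L)
})

test_that("halving the width quarters the encoder's conv-weight parameters (quadratic law)", {
  weight_count <- function(n) {
    s <- architecture_summary(build_encoder(model_config("resnet34", n)))
    l <- s$layers
    conv <- l$kind %in% c("conv", "pointwise_conv")
    sum(l$params[conv]) - sum(l$out_channels[conv & l$has_bias])
  }
  w8 <- weight_count(8L); w4 <- weight_count(4L)
  expect_lt(abs(w4 / (w8 / 4) - 1), 0.05)
})

test_that("total parameters are monotone non-increasing as n decreases 8 to 2", {
  totals <- vapply(8:2, function(n)
    count_parameters(architecture_summary(
      build_dunet(model_config("resnet34", n)))), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("ASPP branch concatenates five parallel branches before projection", {
  cfg <- model_config("resnet34", 8L, input_size = c(64L, 96L))
  full <- build_dunet(cfg)
  cat_node <- full$graph$nodes[["aspp_cat"]]
  expect_length(cat_node$inputs, 5L)
  wa <- dunet:::g_shape(full$graph, "aspp_b0")[1]
  expect_identical(dunet:::g_shape(full$graph, "aspp_cat")[1], 5L * wa)
  # atrous branches: parameter count independent of dilation
  l <- architecture_summary(full)$layers
  atrous <- l[l$name %in% c("aspp_b1", "aspp_b2", "aspp_b3"), ]
  expect_identical(unique(atrous$params),
                   9L * atrous$in_channels[1] * atrous$out_channels[1] +
                     atrous$out_channels[1])
  expect_identical(atrous$dilation, cfg$aspp_rates)
  expect_error(model_config(aspp_rates = c(0L, 12L, 18L)))
})

test_that("U-Net branch top block preserves input resolution and concats align", {
  cfg <- model_config("resnet34", 4L, input_size = c(64L, 96L))
  full <- build_dunet(cfg)
  expect_identical(dunet:::g_shape(full$graph, "top_conv2_relu")[2:3],
                   c(64L, 96L))
  for (nd in full$graph$nodes) {
    if (nd$op != "concat") next
    hw <- vapply(nd$inputs, function(i)
      dunet:::g_shape(full$graph, i)[2:3], integer(2))
    expect_true(all(hw[1, ] == hw[1, 1]) && all(hw[2, ] == hw[2, 1]))
  }
  expect_error(build_unet_branch(structure(
    list(graph = full$graph, taps = full$taps[c("input", "stem")],
         config = cfg), class = "dunet_model")), "missing tap")
})

test_that("DU-Net logits have shape (H, W, K) at the reference input size and are finite", {
  cfg <- model_config("resnet34", 2L, input_size = c(480L, 1024L))
  model <- nn_init_model(build_dunet(cfg), 0L)
  x <- array(0, dim = c(480L, 1024L, 3L, 1L))
  out <- dunet:::nn_forward(model, x, training = FALSE, keep = FALSE)$out
  expect_identical(dim(out), c(480L, 1024L, 3L, 1L))
  expect_true(all(is.finite(out)))
})

test_that("the pinned baseline U-Net reproduces the reference model size", {
  s <- architecture_summary(build_unet_baseline(3L))
  expect_identical(count_parameters(s), 34513475L)
  expect_identical(s$model_size_mb, 138.05)
  # padded convolutions keep the spatial size
  m <- build_unet_baseline(3L, input_size = c(64L, 96L))
  expect_identical(dunet:::g_shape(m$graph, "logits")[2:3], c(64L, 96L))
})

test_that("DU-Net-L (resnet34 encoder, width 4/8) reproduces the reference model size", {
  s <- architecture_summary(build_dunet(model_config("resnet34", 4L)))
  expect_identical(s$model_size_mb, 25.42)
})

test_that("analytic parameter counts equal a traversal of realized weight arrays", {
  for (builder in list(
    function() build_dunet(model_config("resnet18", 4L, input_size = c(32L, 32L))),
    function() build_dunet(model_config("resnet34", 2L, use_cbam = TRUE,
                                        input_size = c(32L, 32L))),
    function() build_unet_baseline(3L, input_size = c(32L, 32L)))) {
    model <- nn_init_model(builder(), 1L)
    analytic <- count_parameters(architecture_summary(model))
    realized <- sum(vapply(model$params, function(p)
      sum(vapply(p, length, numeric(1))), numeric(1)))
    expect_identical(analytic, as.integer(realized))
  }
})

test_that("vgg encoders build with scaled widths and reject CBAM", {
  for (fam in c("vgg16", "vgg19")) {
    enc <- build_encoder(model_config(fam, 4L, input_size = c(64L, 96L)))
    expect_identical(dunet:::g_shape(enc$graph, enc$taps[["c5"]])[1], 256L)
    expect_identical(dunet:::g_shape(enc$graph, enc$taps[["c5"]])[2:3],
                     c(4L, 6L))
    expect_error(attach_cbam(enc), "residual")
  }
  # full fusion model builds on a VGG encoder too
  s <- architecture_summary(build_dunet(model_config("vgg16", 4L)))
  expect_gt(s$total_params, 0)
})

test_that("CBAM insertion adds attention layers and identity gates reproduce the plain network", {
  cfg <- model_config("resnet18", 2L, input_size = c(32L, 32L))
  plain <- nn_init_model(build_encoder(cfg), 2L)
  gated <- nn_init_model(attach_cbam(build_encoder(cfg)), 2L)
  kinds <- architecture_summary(gated)$layers$kind
  expect_identical(sum(kinds == "attention"), 4L)
  # share the conv/bn parameters, force every gate to saturate at 1
  for (nm in names(plain$params)) gated$params[[nm]] <- plain$params[[nm]]
  for (nm in names(gated$params)) {
    if (!grepl("_cbam$", nm)) next
    p <- gated$params[[nm]]
    p$w1[] <- 0; p$b1[] <- 0; p$w2[] <- 0; p$b2[] <- 60
    p$ws[] <- 0; p$bs <- 60
    gated$params[[nm]] <- p
  }
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  o1 <- dunet:::nn_forward(plain, x, keep = FALSE)$out
  o2 <- dunet:::nn_forward(gated, x, keep = FALSE)$out
  expect_lt(max(abs(o1 - o2)), 1e-4)
})

test_that("single-layer parameter arithmetic and the audit table behave", {
  g <- dunet:::nn_graph(3L, c(32L, 32L))
  g <- dunet:::g_conv(g, "c", "input", 8L, k = 3L)
  m <- structure(list(graph = g), class = "dunet_model")
  s <- architecture_summary(m)
  expect_identical(s$layers$params, 3L * 8L * 9L + 8L)   # 224
  expect_identical(count_parameters(s), 224L)
  a <- audit_model("unet", input_size = c(64L, 96L))
  expect_identical(sum(a$layers$params), a$total_params)
  expect_identical(a$model_size_mb, round(a$total_params * 4 / 1e6, 2))
  expect_true(all(a$layers$params[a$layers$kind %in%
    c("pooling", "upsample", "concat", "global_pool")] == 0L))
})
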