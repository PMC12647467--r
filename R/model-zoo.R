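#' Architecture configuration for the DU-Net family
#'
#' Describes one member of the DU-Net family: the shared encoder backbone, the
#' channel-width scaling numerator of the n/8 lightweighting scheme, the
#' optional convolutional block attention (CBAM) variant, the atrous rates of
#' the spatial pyramid, and the input geometry. `DU-Net-L` is the member with
#' `encoder_family = "resnet34"` and `width_numerator = 4` (all channel widths
#' halved).
#'
#' @param encoder_family Backbone of the shared feature extractor.
#' @param width_numerator Integer n in 2..8; every canonical channel width C
#'   is scaled to `floor(C * n / 8)` (minimum 1).
#' @param use_cbam Insert a channel+spatial attention block after each
#'   residual encoder stage (residual families only).
#' @param num_classes Number of output classes (default 3: background,
#'   branch/stem, leaf).
#' @param aspp_rates Dilation rates of the three 3x3 atrous pyramid branches.
#' @param input_size Input image size `c(H, W)`; both must be divisible by 32.
#' @return An object of class `model_config`.
#' @export
model_config <- function(encoder_family = c("resnet34", "resnet18", "vgg16", "vgg19"),
                         width_numerator = 8L,
                         use_cbam = FALSE,
                         num_classes = 3L,
                         aspp_rates = c(6L, 12L, 18L),
                         input_size = c(480L, 1024L)) {
  encoder_family <- match.arg(encoder_family)
  width_numerator <- as.integer(width_numerator)
  if (is.na(width_numerator) || width_numerator < 2L || width_numerator > 8L)
    stop("width_numerator must be an integer in 2..8")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  aspp_rates <- as.integer(aspp_rates)
  if (length(aspp_rates) != 3L || any(aspp_rates <= 0L))
    stop("aspp_rates must be three positive integers")
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 32L != 0L))
    stop("input_size must be c(H, W) with both divisible by 32")
  if (isTRUE(use_cbam) && !grepl("^resnet", encoder_family))
    stop("CBAM attention requires a residual encoder family")
  structure(list(encoder_family = encoder_family,
                 width_numerator = width_numerator,
                 use_cbam = isTRUE(use_cbam),
                 num_classes = num_classes,
                 aspp_rates = aspp_rates,
                 input_size = input_size),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$encoder_family, ", width ", x$width_numerator, "/8",
      if (x$use_cbam) " + CBAM", ", ", x$num_classes, " classes, input ",
      x$input_size[1], "x", x$input_size[2], ", ASPP rates ",
      paste(x$aspp_rates, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# floor(C * n/8), clamped to at least one channel
scale_width <- function(C, n) pmax(1L, as.integer((C * n) %/% 8L))

.resnet_depths <- list(resnet18 = c(2L, 2L, 2L, 2L),
                       resnet34 = c(3L, 4L, 6L, 3L))
.vgg_stages <- list(vgg16 = list(c(64, 64), c(128, 128), c(256, 256, 256),
                                 c(512, 512, 512), c(512, 512, 512)),
                    vgg19 = list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                                 c(512, 512, 512, 512), c(512, 512, 512, 512)))

# Basic residual block: conv-bn-relu-conv-bn + shortcut, relu.
.add_basic_block <- function(g, prefix, input, out_ch, stride = 1L, dilation = 1L) {
  in_ch <- g_shape(g, input)[1]
  g <- g_conv(g, paste0(prefix, "_conv1"), input, out_ch, stride = stride,
              dilation = dilation, bias = FALSE)
  g <- g_add(g, paste0(prefix, "_bn1"), "bn", paste0(prefix, "_conv1"))
  g <- g_add(g, paste0(prefix, "_relu1"), "relu", paste0(prefix, "_bn1"))
  g <- g_conv(g, paste0(prefix, "_conv2"), paste0(prefix, "_relu1"), out_ch,
              dilation = dilation, bias = FALSE)
  g <- g_add(g, paste0(prefix, "_bn2"), "bn", paste0(prefix, "_conv2"))
  short <- input
  if (stride != 1L || in_ch != out_ch) {
    g <- g_conv(g, paste0(prefix, "_down"), input, out_ch, k = 1L,
                stride = stride, bias = FALSE)
    g <- g_add(g, paste0(prefix, "_downbn"), "bn", paste0(prefix, "_down"))
    short <- paste0(prefix, "_downbn")
  }
  g <- g_add(g, paste0(prefix, "_add"), "add", c(paste0(prefix, "_bn2"), short))
  g_add(g, paste0(prefix, "_relu2"), "relu", paste0(prefix, "_add"))
}

# Shared encoder with output stride 16 (last stage trades stride for
# dilation 2, the DeepLabV3+ convention). Returns the graph plus named tap
# points: input, stem (1/2), c2 (1/4), c3 (1/8), c4 (1/16), c5 (1/16).
.add_encoder <- function(g, config) {
  n <- config$width_numerator
  fam <- config$encoder_family
  taps <- c(input = "input")
  if (grepl("^resnet", fam)) {
    depths <- .resnet_depths[[fam]]
    widths <- scale_width(c(64L, 128L, 256L, 512L), n)
    g <- g_conv(g, "stem_conv", "input", scale_width(64L, n), k = 7L,
                stride = 2L, pad = 3L)
    g <- g_add(g, "stem_relu", "relu", "stem_conv")
    taps["stem"] <- "stem_relu"
    g <- g_add(g, "pool1", "maxpool", "stem_relu",
               list(k = 3L, stride = 2L, pad = 1L))
    prev <- "pool1"
    strides <- c(1L, 2L, 2L, 1L)
    dils <- c(1L, 1L, 1L, 2L)
    for (s in 1:4) {
      for (b in seq_len(depths[s])) {
        pre <- sprintf("s%db%d", s, b)
        g <- .add_basic_block(g, pre, prev, widths[s],
                              stride = if (b == 1L) strides[s] else 1L,
                              dilation = dils[s])
        prev <- paste0(pre, "_relu2")
      }
      if (config$use_cbam) {
        g <- g_add(g, sprintf("s%d_cbam", s), "cbam", prev, list(reduction = 8L))
        prev <- sprintf("s%d_cbam", s)
      }
      taps[paste0("c", s + 1L)] <- prev
    }
  } else {
    stages <- .vgg_stages[[fam]]
    prev <- "input"
    for (s in seq_along(stages)) {
      ws <- scale_width(stages[[s]], n)
      dil <- if (s == 5L) 2L else 1L
      for (b in seq_along(ws)) {
        nm <- sprintf("v%dc%d", s, b)
        g <- g_conv_relu(g, nm, prev, ws[b], dilation = dil)
        prev <- paste0(nm, "_relu")
      }
      if (s < 5L) {
        g <- g_add(g, sprintf("vpool%d", s), "maxpool", prev,
                   list(k = 2L, stride = 2L, pad = 0L))
        prev <- sprintf("vpool%d", s)
      }
      taps[c("stem", "c2", "c3", "c4", "c5")[s]] <- prev
    }
  }
  list(g = g, taps = taps)
}

# Atrous-pyramid branch: 1x1 + three 3x3 atrous convs + pooled branch,
# concatenated and projected, then the DeepLabV3+ decoder against the
# stride-4 low-level tap. Head sits at 1/4 resolution.
.add_aspp <- function(g, config, taps) {
  n <- config$width_numerator
  wa <- scale_width(192L, n)
  wll <- scale_width(48L, n)
  wd1 <- scale_width(96L, n)
  wd2 <- scale_width(64L, n)
  c5 <- taps[["c5"]]
  s5 <- g_shape(g, c5)
  g <- g_conv_relu(g, "aspp_b0", c5, wa, k = 1L)
  for (i in 1:3) {
    r <- config$aspp_rates[i]
    g <- g_conv_relu(g, paste0("aspp_b", i), c5, wa, dilation = r)
  }
  g <- g_add(g, "aspp_gap", "gap", c5)
  g <- g_conv_relu(g, "aspp_pool_conv", "aspp_gap", wa, k = 1L)
  g <- g_add(g, "aspp_pool_up", "upsample", "aspp_pool_conv",
             list(out_hw = s5[2:3]))
  g <- g_add(g, "aspp_cat", "concat",
             c("aspp_b0_relu", "aspp_b1_relu", "aspp_b2_relu", "aspp_b3_relu",
               "aspp_pool_up"))
  g <- g_conv_relu(g, "aspp_proj", "aspp_cat", wa, k = 1L)
  low <- taps[["c2"]]
  slow <- g_shape(g, low)
  g <- g_add(g, "aspp_up1", "upsample", "aspp_proj_relu",
             list(out_hw = slow[2:3]))
  g <- g_conv_relu(g, "aspp_ll", low, wll, k = 1L)
  g <- g_add(g, "aspp_dcat", "concat", c("aspp_up1", "aspp_ll_relu"))
  g <- g_conv_relu(g, "aspp_dconv1", "aspp_dcat", wd1)
  g <- g_conv_relu(g, "aspp_dconv2", "aspp_dconv1_relu", wd2)
  list(g = g, head = "aspp_dconv2_relu")
}

# U-Net-style branch: a full-resolution double-conv top block over the raw
# input, then concatenate-and-upsample decoder blocks against every encoder
# tap except the deepest (Conv5_x). Head sits at full resolution.
.add_unet_branch <- function(g, config, taps) {
  n <- config$width_numerator
  wt <- scale_width(32L, n)
  g <- g_conv_relu(g, "top_conv1", "input", wt)
  g <- g_conv_relu(g, "top_conv2", "top_conv1_relu", wt)
  prev <- taps[["c4"]]
  steps <- list(list(skip = taps[["c3"]], nm = "d3", w = scale_width(128L, n)),
                list(skip = taps[["c2"]], nm = "d2", w = scale_width(48L, n)),
                list(skip = taps[["stem"]], nm = "d1", w = scale_width(32L, n)),
                list(skip = "top_conv2_relu", nm = "d0", w = scale_width(32L, n)))
  for (st in steps) {
    sk <- g_shape(g, st$skip)
    w <- st$w
    up <- paste0("un_", st$nm, "_up")
    g <- g_add(g, up, "upsample", prev, list(out_hw = sk[2:3]))
    cat <- paste0("un_", st$nm, "_cat")
    g <- g_add(g, cat, "concat", c(up, st$skip))
    g <- g_conv_relu(g, paste0("un_", st$nm, "_conv1"), cat, w)
    g <- g_conv_relu(g, paste0("un_", st$nm, "_conv2"),
                     paste0("un_", st$nm, "_conv1_relu"), w)
    prev <- paste0("un_", st$nm, "_conv2_relu")
  }
  list(g = g, head = prev)
}

.new_model <- function(graph, taps, config, builder, head = NULL) {
  structure(list(graph = graph, taps = taps, config = config,
                 builder = builder, head = head, params = NULL,
                 buffers = NULL),
            class = "dunet_model")
}

#' Build the shared width-scalable encoder
#'
#' Constructs the residual (or VGG) feature extractor shared by the two
#' branches of DU-Net, with stage outputs exposed as named tap points
#' (`stem` at stride 2, `c2`..`c4` at strides 4/8/16, and `c5` at stride 16
#' via dilation). Stage channel widths are the family's canonical widths
#' scaled by `width_numerator/8`.
#'
#' @param config A [model_config()].
#' @return A `dunet_model` holding the encoder subgraph and its tap points
#'   (uninitialized; see [nn_init_model()]).
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "model_config"))
  g <- nn_graph(3L, config$input_size)
  enc <- .add_encoder(g, config)
  .new_model(enc$g, enc$taps, config, "encoder", head = enc$taps[["c5"]])
}

#' Build the atrous-pyramid (DeepLabV3+) branch on an encoder
#'
#' Appends the full DeepLabV3+ head to an encoder: an atrous spatial pyramid
#' (1x1 conv, three 3x3 atrous convs at the configured rates, and a pooled
#' 1x1 branch) over the deepest tap, concatenation and 1x1 projection, then
#' the decoder that upsamples to the stride-4 tap, merges it through a 1x1
#' reduction, and refines with two 3x3 convs. All widths scale by n/8.
#'
#' @param encoder A `dunet_model` from [build_encoder()].
#' @param config The same [model_config()] used for the encoder.
#' @return A `dunet_model` whose `head` is the branch output (1/4 resolution).
#' @export
build_aspp_branch <- function(encoder, config = encoder$config) {
  stopifnot(inherits(encoder, "dunet_model"))
  if (!identical(g_shape(encoder$graph, encoder$taps[["c5"]])[1],
                 scale_width(512L, config$width_numerator)))
    stop("deepest encoder tap width does not match the configured family/width")
  a <- .add_aspp(encoder$graph, config, encoder$taps)
  .new_model(a$g, encoder$taps, config, "aspp_branch", head = a$head)
}

#' Build the U-Net-style branch on an encoder
#'
#' Appends the U-Net elements of the fusion model: a top-level double 3x3
#' convolution block at full input resolution over the raw image, and a
#' skip decoder that, for every encoder tap except the deepest, upsamples the
#' running feature map, concatenates the tap, and applies a double 3x3
#' convolution.
#'
#' @inheritParams build_aspp_branch
#' @return A `dunet_model` whose `head` is the branch output (full resolution).
#' @export
build_unet_branch <- function(encoder, config = encoder$config) {
  stopifnot(inherits(encoder, "dunet_model"))
  need <- c("input", "stem", "c2", "c3", "c4")
  if (!all(need %in% names(encoder$taps)))
    stop("encoder is missing tap(s): ",
         paste(setdiff(need, names(encoder$taps)), collapse = ", "))
  u <- .add_unet_branch(encoder$graph, config, encoder$taps)
  .new_model(u$g, encoder$taps, config, "unet_branch", head = u$head)
}

#' Build the full DU-Net fusion network
#'
#' Shared encoder, atrous-pyramid branch and U-Net branch; both branch
#' outputs are brought to input resolution by bilinear upsampling,
#' concatenated, and reduced by a 3x3 convolution followed by a 1x1
#' convolution to per-class logits of shape `(H, W, num_classes)`.
#' With `encoder_family = "resnet34"` and `width_numerator = 4` the result is
#' DU-Net-L.
#'
#' @param config A [model_config()].
#' @return A `dunet_model` (uninitialized; see [nn_init_model()]).
#' @export
build_dunet <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  g <- nn_graph(3L, config$input_size)
  enc <- .add_encoder(g, config)
  a <- .add_aspp(enc$g, config, enc$taps)
  u <- .add_unet_branch(a$g, config, enc$taps)
  g <- u$g
  n <- config$width_numerator
  g <- g_add(g, "fuse_up_aspp", "upsample", a$head,
             list(out_hw = config$input_size))
  g <- g_add(g, "fuse_cat", "concat", c("fuse_up_aspp", u$head))
  g <- g_conv_relu(g, "fuse_conv", "fuse_cat", scale_width(32L, n))
  g <- g_conv(g, "logits", "fuse_conv_relu", config$num_classes, k = 1L)
  .new_model(g, enc$taps, config, "dunet", head = "logits")
}

#' Build the classical U-Net baseline
#'
#' The comparison network: double 3x3 padded biased convolutions (no
#' normalization) at widths 64-128-256-512 with a 1024-wide bottleneck,
#' 2x2 max-pool downsampling, and a decoder of parameter-free 2x bilinear
#' upsampling followed by a channel-halving 3x3 convolution, skip
#' concatenation and a double convolution; a final 1x1 convolution maps to
#' class logits. Under these conventions the 3-class model has 34,513,475
#' parameters = 138.05 MB at 4 bytes per parameter.
#'
#' @param num_classes Number of output classes (>= 2).
#' @param input_size Input size `c(H, W)`, divisible by 16.
#' @return A `dunet_model`.
#' @export
build_unet_baseline <- function(num_classes = 3L, input_size = c(480L, 1024L)) {
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  input_size <- as.integer(input_size)
  if (any(input_size %% 16L != 0L)) stop("input_size must be divisible by 16")
  g <- nn_graph(3L, input_size)
  widths <- c(64L, 128L, 256L, 512L)
  prev <- "input"
  skips <- character(0)
  for (i in seq_along(widths)) {
    nm <- paste0("enc", i)
    g <- g_conv_relu(g, paste0(nm, "_conv1"), prev, widths[i])
    g <- g_conv_relu(g, paste0(nm, "_conv2"), paste0(nm, "_conv1_relu"), widths[i])
    skips[i] <- paste0(nm, "_conv2_relu")
    g <- g_add(g, paste0("pool", i), "maxpool", skips[i],
               list(k = 2L, stride = 2L, pad = 0L))
    prev <- paste0("pool", i)
  }
  g <- g_conv_relu(g, "bott_conv1", prev, 1024L)
  g <- g_conv_relu(g, "bott_conv2", "bott_conv1_relu", 1024L)
  prev <- "bott_conv2_relu"
  for (i in rev(seq_along(widths))) {
    nm <- paste0("dec", i)
    sk <- g_shape(g, skips[i])
    g <- g_add(g, paste0(nm, "_up"), "upsample", prev, list(out_hw = sk[2:3]))
    g <- g_conv_relu(g, paste0(nm, "_upconv"), paste0(nm, "_up"), widths[i],
                     role = "upconv")
    g <- g_add(g, paste0(nm, "_cat"), "concat",
               c(paste0(nm, "_upconv_relu"), skips[i]))
    g <- g_conv_relu(g, paste0(nm, "_conv1"), paste0(nm, "_cat"), widths[i])
    g <- g_conv_relu(g, paste0(nm, "_conv2"), paste0(nm, "_conv1_relu"), widths[i])
    prev <- paste0(nm, "_conv2_relu")
  }
  g <- g_conv(g, "logits", prev, num_classes, k = 1L)
  cfg <- list(encoder_family = "unet", width_numerator = 8L, use_cbam = FALSE,
              num_classes = num_classes, input_size = input_size)
  .new_model(g, c(input = "input"), cfg, "unet_baseline", head = "logits")
}

#' Insert CBAM attention blocks after each encoder stage
#'
#' Rebuilds the architecture with a convolutional block attention module
#' (channel attention: shared MLP over global max/avg pooled vectors with a
#' sigmoid gate, then spatial attention: 7x7 convolution over channel-pooled
#' max/avg maps with a sigmoid gate) appended to every residual encoder
#' stage output. Gates are multiplicative and shape-preserving. Any existing
#' parameters are discarded (the layer set changes).
#'
#' @param model A `dunet_model` with a residual encoder family.
#' @return A rebuilt `dunet_model` with `use_cbam = TRUE`.
#' @export
attach_cbam <- function(model) {
  stopifnot(inherits(model, "dunet_model"))
  cfg <- model$config
  if (!grepl("^resnet", cfg$encoder_family %||% ""))
    stop("CBAM attention requires a residual encoder family")
  cfg$use_cbam <- TRUE
  cfg <- do.call(model_config, cfg[c("encoder_family", "width_numerator",
                                     "use_cbam", "num_classes", "aspp_rates",
                                     "input_size")])
  switch(model$builder,
         encoder = build_encoder(cfg),
         dunet = build_dunet(cfg),
         stop("attach_cbam supports encoder and dunet builders"))
}

#' Initialize model parameters
#'
#' Realizes the layer graph as weight arrays: He (fan-in) normal
#' initialization for convolution kernels, zero biases, unit-gamma/zero-beta
#' batch normalization. Fully determined by `seed`.
#'
#' @param model A `dunet_model`.
#' @param seed Integer RNG seed.
#' @return The model with `$params` and `$buffers` filled.
#' @export
nn_init_model <- function(model, seed = 0L) {
  stopifnot(inherits(model, "dunet_model"))
  ini <- nn_init(model$graph, seed)
  model$params <- ini$params
  model$buffers <- ini$buffers
  model
}

#' @export
print.dunet_model <- function(x, ...) {
  s <- architecture_summary(x)
  cat("<dunet_model> builder=", x$builder,
      if (!is.null(x$config$encoder_family)) paste0(" (", x$config$encoder_family,
        ", width ", x$config$width_numerator, "/8)"),
      "\n  layers: ", nrow(s$layers),
      "  params: ", format(s$total_params, big.mark = ","),
      "  size: ", sprintf("%.2f MB", s$model_size_mb),
      "  ", if (is.null(x$params)) "(uninitialized)" else "(initialized)", "\n",
      sep = "")
  invisible(x)
}

.layer_params <- function(nd) {
  cfg <- nd$cfg
  as.integer(switch(nd$op,
    conv = prod(cfg$k) * cfg$in_ch * cfg$out_ch +
      if (isTRUE(cfg$bias)) cfg$out_ch else 0L,
    bn = 2L * nd$out_shape[1],
    cbam = {
      C <- nd$out_shape[1]
      Cr <- max(1L, C %/% (cfg$reduction %||% 8L))
      2L * Cr * C + Cr + C + 7L * 7L * 2L + 1L
    },
    0L))
}

.layer_kind <- function(nd) {
  switch(nd$op,
    conv = if (all(nd$cfg$k == 1L)) "pointwise_conv"
           else if (identical(nd$cfg$role, "upconv")) "transposed_or_upsample_conv"
           else "conv",
    maxpool = "pooling",
    upsample = "upsample",
    concat = "concat",
    add = "add",
    gap = "global_pool",
    cbam = "attention",
    bn = "norm",
    NA_character_)
}

#' Enumerate an architecture's layers and account for its size
#'
#' Walks the layer graph in order and produces one row per layer (activation
#' functions omitted) with kind, shapes, kernel geometry and exact parameter
#' count. `total_params` is the integer sum; `model_size_mb` is
#' `total_params * 4 / 1e6` (32-bit parameters, decimal megabytes) reported
#' to two decimals — the conventional model-size accounting used in architecture comparisons.
#'
#' @param model A `dunet_model`.
#' @return An object of class `architecture_summary` with elements `layers`
#'   (data.frame), `total_params` and `model_size_mb`.
#' @export
architecture_summary <- function(model) {
  stopifnot(inherits(model, "dunet_model"))
  nds <- Filter(function(nd) !nd$op %in% c("input", "relu"), model$graph$nodes)
  rows <- lapply(nds, function(nd) {
    cfg <- nd$cfg
    ish <- if (length(nd$inputs))
      g_shape(model$graph, nd$inputs[[1]])[1] else NA_integer_
    data.frame(
      name = nd$name,
      kind = .layer_kind(nd),
      in_channels = as.integer(if (nd$op == "conv") cfg$in_ch
                    else if (nd$op == "concat") sum(vapply(nd$inputs,
                      function(i) g_shape(model$graph, i)[1], numeric(1)))
                    else ish),
      out_channels = nd$out_shape[1],
      kernel = if (nd$op == "conv") paste(cfg$k, collapse = "x")
               else if (nd$op == "maxpool") paste(cfg$k, cfg$k, sep = "x")
               else "",
      stride = if (nd$op %in% c("conv", "maxpool")) cfg$stride else 1L,
      dilation = if (nd$op == "conv") cfg$dilation[1] else 1L,
      has_bias = if (nd$op == "conv") isTRUE(cfg$bias) else FALSE,
      out_c = nd$out_shape[1], out_h = nd$out_shape[2], out_w = nd$out_shape[3],
      params = .layer_params(nd),
      stringsAsFactors = FALSE)
  })
  layers <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  total <- as.integer(sum(layers$params))
  structure(list(layers = layers, total_params = total,
                 model_size_mb = round(total * 4 / 1e6, 2)),
            class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("<architecture_summary> ", nrow(x$layers), " layers, ",
      format(x$total_params, big.mark = ","), " params, ",
      sprintf("%.2f MB", x$model_size_mb), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.architecture_summary <- function(x, ...) x$layers

#' Count trainable parameters
#'
#' For an [architecture_summary()] this is the exact integer sum of the
#' per-layer counts; for an initialized model it is obtained by traversing
#' every realized weight container, which must agree with the analytic count.
#'
#' @param x An `architecture_summary` or `dunet_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.architecture_summary <- function(x) sum(x$layers$params)

#' @export
count_parameters.dunet_model <- function(x) {
  if (is.null(x$params)) return(count_parameters(architecture_summary(x)))
  as.integer(sum(vapply(x$params, function(p)
    sum(vapply(p, length, numeric(1))), numeric(1))))
}

#' Model size in decimal megabytes
#'
#' `params * 4 / 1e6` (32-bit parameters), rounded to two decimals.
#'
#' @param x An `architecture_summary` or `dunet_model`.
#' @return Numeric size in MB.
#' @export
model_size_mb <- function(x) round(count_parameters(x) * 4 / 1e6, 2)

#' Per-layer audit table for a named architecture variant
#'
#' Builds the requested variant and returns its layer table with totals —
#' the machine-readable form of the conventional model-size accounting.
#'
#' @param variant One of `"dunet"`, `"dunet_l"`, `"unet"`, `"encoder"`.
#' @param input_size Input size `c(H, W)`.
#' @param width_numerator Channel-scaling numerator n (2..8); ignored for
#'   `"unet"`; `"dunet_l"` forces 4.
#' @param encoder_family Backbone family for DU-Net variants.
#' @param num_classes Number of classes.
#' @return A list with `layers` (data.frame), `total_params`, `model_size_mb`.
#' @export
audit_model <- function(variant = c("dunet_l", "dunet", "unet", "encoder"),
                        input_size = c(480L, 1024L), width_numerator = 8L,
                        encoder_family = "resnet34", num_classes = 3L) {
  variant <- match.arg(variant)
  model <- switch(variant,
    unet = build_unet_baseline(num_classes, input_size),
    dunet_l = build_dunet(model_config("resnet34", 4L, num_classes = num_classes,
                                       input_size = input_size)),
    dunet = build_dunet(model_config(encoder_family, width_numerator,
                                     num_classes = num_classes,
                                     input_size = input_size)),
    encoder = build_encoder(model_config(encoder_family, width_numerator,
                                         num_classes = num_classes,
                                         input_size = input_size)))
  s <- architecture_summary(model)
  list(layers = s$layers, total_params = s$total_params,
       model_size_mb = s$model_size_mb)
}
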