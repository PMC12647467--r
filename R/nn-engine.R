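# Minimal computation-graph engine for the segmentation networks.
#
# A graph is an ordered list of nodes (insertion order is topological).
# Activations are (H, W, C, N) double arrays; label masks are H x W integer
# matrices. Heavy kernels (convolution, pooling, bilinear resize) live in
# src/convops.cpp; everything else is vectorized R.

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_graph <- function(input_channels, input_hw) {
  g <- list(nodes = list())
  g <- g_add(g, "input", "input", character(),
             list(channels = input_channels, hw = input_hw))
  g
}

#' @noRd
g_shape <- function(g, name) g$nodes[[name]]$out_shape  # c(C, H, W)

# Append a node, inferring its static output shape and validating wiring.
g_add <- function(g, name, op, inputs, cfg = list()) {
  if (!is.null(g$nodes[[name]])) stop("duplicate node name: ", name)
  missing <- setdiff(inputs, names(g$nodes))
  if (length(missing)) stop("unknown input node(s): ", paste(missing, collapse = ", "))
  ins <- lapply(inputs, function(i) g$nodes[[i]]$out_shape)
  shape <- switch(op,
    input = c(cfg$channels, cfg$hw),
    conv = {
      s <- ins[[1]]
      if (s[1] != cfg$in_ch) stop("conv ", name, ": expected ", cfg$in_ch,
                                  " input channels, got ", s[1])
      eff <- cfg$dilation * (cfg$k - 1) + 1
      c(cfg$out_ch,
        (s[2] + 2 * cfg$pad[1] - eff[1]) %/% cfg$stride + 1,
        (s[3] + 2 * cfg$pad[2] - eff[2]) %/% cfg$stride + 1)
    },
    bn = , relu = , cbam = ins[[1]],
    maxpool = {
      s <- ins[[1]]
      c(s[1],
        (s[2] + 2 * cfg$pad - cfg$k) %/% cfg$stride + 1,
        (s[3] + 2 * cfg$pad - cfg$k) %/% cfg$stride + 1)
    },
    upsample = c(ins[[1]][1], cfg$out_hw),
    gap = c(ins[[1]][1], 1, 1),
    concat = {
      hw <- vapply(ins, function(s) s[2:3], numeric(2))
      if (any(hw[1, ] != hw[1, 1]) || any(hw[2, ] != hw[2, 1]))
        stop("concat ", name, ": spatial mismatch among inputs (",
             paste(apply(hw, 2, paste, collapse = "x"), collapse = " vs "), ")")
      c(sum(vapply(ins, `[`, numeric(1), 1)), ins[[1]][2:3])
    },
    add = {
      if (!identical(ins[[1]], ins[[2]])) stop("add ", name, ": shape mismatch")
      ins[[1]]
    },
    stop("unknown op: ", op)
  )
  g$nodes[[name]] <- list(name = name, op = op, inputs = inputs,
                          cfg = cfg, out_shape = as.integer(shape))
  g
}

# Convenience builders used by the model zoo ---------------------------------

g_conv <- function(g, name, input, out_ch, k = c(3L, 3L), stride = 1L,
                   pad = NULL, dilation = c(1L, 1L), bias = TRUE, role = "conv") {
  if (length(k) == 1) k <- c(k, k)
  if (length(dilation) == 1) dilation <- c(dilation, dilation)
  if (is.null(pad)) pad <- dilation * (k - 1) %/% 2
  if (length(pad) == 1) pad <- c(pad, pad)
  in_ch <- g_shape(g, input)[1]
  g_add(g, name, "conv", input,
        list(in_ch = in_ch, out_ch = as.integer(out_ch), k = as.integer(k),
             stride = as.integer(stride), pad = as.integer(pad),
             dilation = as.integer(dilation), bias = bias, role = role))
}

g_conv_relu <- function(g, name, input, out_ch, ...) {
  g <- g_conv(g, name, input, out_ch, ...)
  g_add(g, paste0(name, "_relu"), "relu", name)
}

# Parameter initialization (He fan-in) ---------------------------------------

nn_init <- function(graph, seed = 0L) {
  set.seed(as.integer(seed))
  params <- list(); buffers <- list()
  for (nd in graph$nodes) {
    if (nd$op == "conv") {
      cfg <- nd$cfg
      fan_in <- prod(cfg$k) * cfg$in_ch
      w <- array(stats::rnorm(prod(cfg$k) * cfg$in_ch * cfg$out_ch,
                              sd = sqrt(2 / fan_in)),
                 dim = c(cfg$k, cfg$in_ch, cfg$out_ch))
      p <- list(w = w)
      if (cfg$bias) p$b <- numeric(cfg$out_ch)
      params[[nd$name]] <- p
    } else if (nd$op == "bn") {
      C <- nd$out_shape[1]
      params[[nd$name]] <- list(gamma = rep(1, C), beta = numeric(C))
      buffers[[nd$name]] <- list(mean = numeric(C), var = rep(1, C))
    } else if (nd$op == "cbam") {
      C <- nd$out_shape[1]
      r <- nd$cfg$reduction %||% 8L
      Cr <- max(1L, C %/% r)
      params[[nd$name]] <- list(
        w1 = matrix(stats::rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
        b1 = numeric(Cr),
        w2 = matrix(stats::rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr),
        b2 = numeric(C),
        ws = array(stats::rnorm(7 * 7 * 2, sd = sqrt(2 / (7 * 7 * 2))),
                   dim = c(7L, 7L, 2L, 1L)),
        bs = 0)
    }
  }
  list(params = params, buffers = buffers)
}

# Batch normalization --------------------------------------------------------

# The (H, W, C, N) array viewed as an (H*W) x (C*N) matrix has channel
# index (j - 1) %% C + 1 for column j, so per-channel statistics reduce over
# a C x N fold of the column sums; this avoids any aperm copy.
.bn_fwd <- function(x, p, buf, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(HW, C * N)
  if (training) {
    mu <- rowMeans(matrix(colMeans(xm), C, N))
    ex2 <- rowMeans(matrix(colMeans(xm^2), C, N))
    va <- ex2 - mu^2
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * va
  } else {
    mu <- buf$mean; va <- buf$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xm, 2, rep(mu, N))
  xhat <- sweep(xhat, 2, rep(istd, N), `*`)
  ym <- sweep(xhat, 2, rep(p$gamma, N), `*`)
  ym <- sweep(ym, 2, rep(p$beta, N), `+`)
  dim(ym) <- d
  list(y = ym, aux = list(xhat = xhat, istd = istd, dims = d,
                          training = training),
       buf = buf)
}

.bn_bwd <- function(gy, p, aux) {
  d <- aux$dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gym <- gy; dim(gym) <- c(HW, C * N)
  M <- HW * N
  chsum <- function(m) rowSums(matrix(colSums(m), C, N))
  ggamma <- chsum(gym * aux$xhat)
  gbeta <- chsum(gym)
  gxhat <- sweep(gym, 2, rep(p$gamma, N), `*`)
  if (aux$training) {
    t1 <- sweep(gxhat, 2, rep(chsum(gxhat) / M, N))
    t2 <- aux$xhat * rep(rep(chsum(gxhat * aux$xhat) / M, N), each = HW)
    gxm <- (t1 - t2) * rep(rep(aux$istd, N), each = HW)
  } else {
    gxm <- gxhat * rep(rep(aux$istd, N), each = HW)
  }
  dim(gxm) <- d
  list(gx = gxm, grads = list(gamma = ggamma, beta = gbeta))
}

# CBAM: channel attention (shared MLP over global avg/max vectors), then
# spatial attention (7x7 conv over channel-pooled mean/max maps).

.sigmoid <- function(z) 1 / (1 + exp(-z))

.cbam_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(H * W, C * N)
  av <- matrix(colMeans(xm), C, N)
  mxi <- apply(xm, 2, which.max)
  mx <- matrix(xm[cbind(mxi, seq_len(C * N))], C, N)
  pre_a <- p$w1 %*% av + p$b1
  pre_m <- p$w1 %*% mx + p$b1
  ha <- pmax(pre_a, 0); hm <- pmax(pre_m, 0)
  z <- p$w2 %*% (ha + hm) + p$b2
  s <- .sigmoid(z)                      # C x N channel gate
  x1 <- x * rep(s, each = H * W)
  # spatial attention over x1
  x1m <- x1; dim(x1m) <- c(H * W, C, N)
  mm <- apply(x1m, c(1, 3), mean)       # (H*W) x N
  sxi <- apply(aperm(x1m, c(2, 1, 3)), c(2, 3), which.max)  # (H*W) x N channel idx
  ms <- array(0, dim = c(H * W, N))
  for (n in seq_len(N)) ms[, n] <- x1m[cbind(seq_len(H * W), sxi[, n], n)]
  sp_in <- aperm(array(c(mm, ms), dim = c(H * W, N, 2L)), c(1, 3, 2))
  dim(sp_in) <- c(H, W, 2L, N)
  conv <- .conv2d_fwd(sp_in, p$ws, p$bs, 1L, 3L, 1L)
  t <- .sigmoid(conv)                   # (H, W, 1, N)
  tb <- array(0, dim = d)               # gate broadcast over channels
  for (n in seq_len(N)) tb[, , , n] <- array(rep(t[, , 1, n], C), dim = c(H, W, C))
  y <- x1 * tb
  list(y = y, aux = list(x = x, s = s, z = z, pre_a = pre_a, pre_m = pre_m,
                         av = av, mx = mx, mxi = mxi, x1 = x1, sxi = sxi,
                         sp_in = sp_in, t = t, tb = tb, dims = d))
}

.cbam_bwd <- function(gy, p, aux) {
  d <- aux$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  # spatial gate
  gx1 <- gy * aux$tb
  gt <- array(0, dim = c(H, W, 1L, N))
  for (n in seq_len(N)) gt[, , 1, n] <- rowSums(matrix((gy * aux$x1)[, , , n], H * W, C))
  gconv <- gt * aux$t * (1 - aux$t)
  cb <- .conv2d_bwd(aux$sp_in, p$ws, gconv, 1L, 3L, 1L, TRUE, TRUE)
  gsp <- cb$gx                          # (H, W, 2, N)
  gmm <- matrix(gsp[, , 1, ], H * W, N)
  gms <- matrix(gsp[, , 2, ], H * W, N)
  # mean map: spread over channels; max map: route to argmax channel
  gx1m <- array(gx1, dim = c(H * W, C, N))
  for (n in seq_len(N)) {
    gx1m[, , n] <- gx1m[, , n] + gmm[, n] / C
    idx <- cbind(seq_len(H * W), aux$sxi[, n])
    gx1m[, , n][idx] <- gx1m[, , n][idx] + gms[, n]
  }
  gx1 <- array(gx1m, dim = d)
  # channel gate
  gs <- matrix(0, C, N)
  xm <- aux$x; dim(xm) <- c(H * W, C * N)
  g1m <- gx1; dim(g1m) <- c(H * W, C * N)
  gs[] <- colSums(g1m * xm)
  gx <- gx1 * rep(aux$s, each = H * W)
  gz <- gs * aux$s * (1 - aux$s)
  ha <- pmax(aux$pre_a, 0); hm <- pmax(aux$pre_m, 0)
  gw2 <- gz %*% t(ha + hm)
  gb2 <- rowSums(gz)
  gha <- (t(p$w2) %*% gz) * (aux$pre_a > 0)
  ghm <- (t(p$w2) %*% gz) * (aux$pre_m > 0)
  gw1 <- gha %*% t(aux$av) + ghm %*% t(aux$mx)
  gb1 <- rowSums(gha + ghm)
  gav <- t(p$w1) %*% gha
  gmx <- t(p$w1) %*% ghm
  # avg pool: spread; max pool: route
  gxm <- matrix(0, H * W, C * N)
  gxm <- gxm + rep(as.vector(gav), each = H * W) / (H * W)
  gxm[cbind(aux$mxi, seq_len(C * N))] <- gxm[cbind(aux$mxi, seq_len(C * N))] +
    as.vector(gmx)
  gx <- gx + array(gxm, dim = d)
  list(gx = gx, grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2,
                             ws = cb$gw, bs = cb$gb))
}

# Forward / backward over the graph ------------------------------------------

nn_forward <- function(model, x, training = FALSE, keep = TRUE) {
  g <- model$graph; P <- model$params; B <- model$buffers
  if (is.null(P)) stop("model parameters not initialized; call nn_init_model()")
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  cache <- vector("list", length(g$nodes))
  names(cache) <- names(g$nodes)
  for (nd in g$nodes) {
    nm <- nd$name
    inp <- lapply(nd$inputs, function(i) cache[[i]]$out)
    res <- switch(nd$op,
      input = list(out = x),
      conv = {
        cfg <- nd$cfg
        list(out = .conv2d_fwd(inp[[1]], P[[nm]]$w, P[[nm]]$b,
                               cfg$stride, cfg$pad[1], cfg$dilation[1]))
      },
      bn = {
        r <- .bn_fwd(inp[[1]], P[[nm]], B[[nm]], training)
        B[[nm]] <- r$buf
        list(out = r$y, aux = r$aux)
      },
      relu = list(out = .relu_fwd(inp[[1]])),
      maxpool = {
        r <- .maxpool_fwd(inp[[1]], nd$cfg$k, nd$cfg$stride, nd$cfg$pad)
        list(out = r$y, aux = list(idx = r$idx, xdim = dim(inp[[1]])))
      },
      upsample = list(out = .bilinear_fwd(inp[[1]], nd$cfg$out_hw[1], nd$cfg$out_hw[2]),
                      aux = list(in_hw = dim(inp[[1]])[1:2])),
      gap = {
        xi <- inp[[1]]; d <- dim(xi)
        m <- colMeans(matrix(xi, d[1] * d[2], d[3] * d[4]))
        list(out = array(m, dim = c(1L, 1L, d[3], d[4])), aux = list(in_dim = d))
      },
      concat = {
        d1 <- dim(inp[[1]])
        cs <- vapply(inp, function(a) dim(a)[3], numeric(1))
        out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
        off <- 0L
        for (a in inp) {
          out[, , off + seq_len(dim(a)[3]), ] <- a
          off <- off + dim(a)[3]
        }
        list(out = out, aux = list(splits = cs))
      },
      add = list(out = inp[[1]] + inp[[2]]),
      cbam = {
        r <- .cbam_fwd(inp[[1]], P[[nm]])
        list(out = r$y, aux = r$aux)
      }
    )
    cache[[nm]] <- res
  }
  last <- names(g$nodes)[length(g$nodes)]
  out <- cache[[last]]$out
  if (!keep) cache <- NULL
  list(out = out, cache = cache, buffers = B, output_node = last)
}

nn_backward <- function(model, cache, gout) {
  g <- model$graph; P <- model$params
  nms <- names(g$nodes)
  gmap <- vector("list", length(nms)); names(gmap) <- nms
  gmap[[nms[length(nms)]]] <- gout
  grads <- list()
  for (nd in rev(g$nodes)) {
    nm <- nd$name
    gy <- gmap[[nm]]
    gmap[[nm]] <- NULL
    if (is.null(gy) || nd$op == "input") next
    push <- function(target, g) {
      if (is.null(gmap[[target]])) gmap[[target]] <<- g
      else gmap[[target]] <<- gmap[[target]] + g
    }
    aux <- cache[[nm]]$aux
    switch(nd$op,
      conv = {
        cfg <- nd$cfg
        xin <- cache[[nd$inputs]]$out
        need_gx <- g$nodes[[nd$inputs]]$op != "input"
        r <- .conv2d_bwd(xin, P[[nm]]$w, gy, cfg$stride, cfg$pad[1],
                         cfg$dilation[1], need_gx, isTRUE(cfg$bias))
        grads[[nm]] <- if (isTRUE(cfg$bias)) list(w = r$gw, b = r$gb) else list(w = r$gw)
        if (need_gx) push(nd$inputs, r$gx)
      },
      bn = {
        r <- .bn_bwd(gy, P[[nm]], aux)
        grads[[nm]] <- r$grads
        push(nd$inputs, r$gx)
      },
      relu = push(nd$inputs, .relu_bwd(gy, cache[[nm]]$out)),
      maxpool = push(nd$inputs, .maxpool_bwd(gy, aux$idx, aux$xdim)),
      upsample = push(nd$inputs, .bilinear_bwd(gy, aux$in_hw[1], aux$in_hw[2])),
      gap = {
        d <- aux$in_dim
        gv <- as.vector(gy) / (d[1] * d[2])
        push(nd$inputs, array(rep(gv, each = d[1] * d[2]), dim = d))
      },
      concat = {
        off <- 0L
        for (i in seq_along(nd$inputs)) {
          ci <- aux$splits[i]
          push(nd$inputs[i], gy[, , off + seq_len(ci), , drop = FALSE])
          off <- off + ci
        }
      },
      add = { push(nd$inputs[1], gy); push(nd$inputs[2], gy) },
      cbam = {
        r <- .cbam_bwd(gy, P[[nm]], aux)
        grads[[nm]] <- r$grads
        push(nd$inputs, r$gx)
      }
    )
  }
  grads
}

# Adam optimizer --------------------------------------------------------------

adam_init <- function(params) {
  st <- rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
  list(t = 0L, mv = st)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      gnow <- grads[[nm]][[pn]]
      if (is.null(gnow)) next
      s <- state$mv[[nm]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * gnow
      s$v <- beta2 * s$v + (1 - beta2) * gnow^2
      state$mv[[nm]][[pn]] <- s
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
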