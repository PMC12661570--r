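# Minimal dense/convolutional network engine.
#
# Batches are column-major arrays with dim (H, W, C, N); fully connected
# activations are matrices with dim (features, N). Each layer is a plain list
# carrying its parameters; forward passes return caches that the backward
# passes consume. The engine supports the three architectures used in the
# package (frame CNN, conditional generator, conditional critic) plus the
# linearized tangent propagation required for the exact WGAN-GP penalty
# gradient (activation masks and normalization statistics held fixed).

nn_rnorm <- function(n, sd) stats::rnorm(n, mean = 0, sd = sd)

nn_conv <- function(cin, cout, k, stride = 1L) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       cin = cin, cout = cout,
       params = list(W = array(nn_rnorm(k * k * cin * cout, sd),
                               dim = c(k, k, cin, cout)),
                     b = numeric(cout)))
}

nn_convt <- function(cin, cout, k, stride) {
  sd <- sqrt(2 / (k * k * cin))
  # weight stored as (k, k, cout, cin): transpose convolution is the adjoint
  # of a conv whose weight matrix is matrix(W, k*k*cout, cin)
  list(type = "convt", k = as.integer(k), stride = as.integer(stride),
       cin = cin, cout = cout,
       params = list(W = array(nn_rnorm(k * k * cout * cin, sd),
                               dim = c(k, k, cout, cin)),
                     b = numeric(cout)))
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", c = c, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       buffers = list(run_mean = numeric(c), run_var = rep(1, c)))
}

nn_relu   <- function() list(type = "relu", params = list())
nn_lrelu  <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha, params = list())
nn_tanh   <- function() list(type = "tanh", params = list())
nn_tanh01 <- function() list(type = "tanh01", params = list())  # (tanh(x)+1)/2
nn_maxpool <- function(p) list(type = "maxpool", p = as.integer(p), params = list())
nn_adaptavg <- function(oh, ow = oh) list(type = "adaptavg", oh = oh, ow = ow, params = list())
nn_flatten <- function() list(type = "flatten", params = list())
nn_linear <- function(nin, nout) {
  sd <- sqrt(2 / nin)
  list(type = "linear", nin = nin, nout = nout,
       params = list(W = matrix(nn_rnorm(nin * nout, sd), nout, nin),
                     b = numeric(nout)))
}
nn_dropout <- function(p = 0.5) list(type = "dropout", p = p, params = list())
# concatenates a one-hot label matrix (n_labels, N) below the feature matrix
nn_concat_label <- function(n_labels) list(type = "concat_label", n_labels = n_labels, params = list())
nn_resize <- function(out_h, out_w = out_h) list(type = "resize", oh = out_h, ow = out_w, params = list())

# adaptive average-pooling bin edges (PyTorch convention)
adapt_bins <- function(n_in, n_out) {
  lo <- floor((0:(n_out - 1)) * n_in / n_out) + 1L
  hi <- ceiling((1:n_out) * n_in / n_out)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# bilinear interpolation weight matrix (align_corners = TRUE), dense (out x in)
bilinear_mat <- function(n_in, n_out) {
  if (n_in == 1L) return(matrix(1, n_out, 1))
  pos <- (0:(n_out - 1)) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 2)
  w1 <- pos - i0
  M <- matrix(0, n_out, n_in)
  M[cbind(1:n_out, i0 + 1)] <- 1 - w1
  M[cbind(1:n_out, i0 + 2)] <- M[cbind(1:n_out, i0 + 2)] + w1
  M
}

conv_out_size <- function(H, k, stride) (H - k) %/% stride + 1L

layer_forward <- function(layer, x, labels, training) {
  t <- layer$type
  if (t == "conv") {
    d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    k <- layer$k; s <- layer$stride
    if (H < k || W < k) stop("conv: input ", H, "x", W, " smaller than kernel ", k)
    Ho <- conv_out_size(H, k, s); Wo <- conv_out_size(W, k, s)
    cols <- im2col_cpp(x, H, W, C, N, k, s)
    Wm <- matrix(layer$params$W, nrow = k * k * C)
    ym <- crossprod(Wm, cols) + layer$params$b          # (cout, P*N)
    y <- aperm(array(ym, dim = c(layer$cout, Ho, Wo, N)), c(2, 3, 1, 4))
    list(out = y, cache = list(cols = cols, dims = d, odims = dim(y)))
  } else if (t == "convt") {
    d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    k <- layer$k; s <- layer$stride
    Ho <- (H - 1L) * s + k; Wo <- (W - 1L) * s + k
    xm <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = C)     # (cin, P*N)
    Wm <- matrix(layer$params$W, nrow = k * k * layer$cout)
    cols <- Wm %*% xm
    y <- col2im_cpp(cols, Ho, Wo, layer$cout, N, k, s)
    y <- y + rep(rep(layer$params$b, each = Ho * Wo), times = N)
    dim(y) <- c(Ho, Wo, layer$cout, N)
    list(out = y, cache = list(xm = xm, dims = d, odims = dim(y)))
  } else if (t == "bn") {
    d <- dim(x)
    if (is.null(d)) stop("bn expects a 4-d activation")
    H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)     # (H*W*N, C)
    if (training) {
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
    } else {
      mu <- layer$buffers$run_mean
      v <- layer$buffers$run_var
    }
    sd_ <- sqrt(v + layer$eps)
    xh <- sweep(sweep(xm, 2, mu), 2, sd_, "/")
    ym <- sweep(sweep(xh, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
    y <- aperm(array(ym, dim = c(H, W, N, C)), c(1, 2, 4, 3))
    list(out = y,
         cache = list(xh = xh, sd = sd_, dims = d, training = training,
                      new_run = if (training) {
                        m <- layer$momentum
                        list(mean = (1 - m) * layer$buffers$run_mean + m * mu,
                             var  = (1 - m) * layer$buffers$run_var  + m * v)
                      } else NULL))
  } else if (t == "relu") {
    mask <- x > 0
    list(out = x * mask, cache = list(mask = mask))
  } else if (t == "lrelu") {
    mask <- x > 0
    slope <- ifelse(mask, 1, layer$alpha)
    list(out = x * slope, cache = list(slope = slope))
  } else if (t == "tanh") {
    th <- tanh(x)
    list(out = th, cache = list(th = th))
  } else if (t == "tanh01") {
    th <- tanh(x)
    list(out = (th + 1) / 2, cache = list(th = th))
  } else if (t == "maxpool") {
    d <- dim(x)
    r <- maxpool_fwd_cpp(x, d[1], d[2], d[3], d[4], layer$p)
    list(out = r$y, cache = list(idx = r$idx, dims = d))
  } else if (t == "adaptavg") {
    d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    bh <- adapt_bins(H, layer$oh); bw <- adapt_bins(W, layer$ow)
    y <- array(0, dim = c(layer$oh, layer$ow, C, N))
    for (a in seq_len(layer$oh)) for (b in seq_len(layer$ow)) {
      y[a, b, , ] <- apply(x[bh$lo[a]:bh$hi[a], bw$lo[b]:bw$hi[b], , , drop = FALSE],
                           c(3, 4), mean)
    }
    list(out = y, cache = list(dims = d, bh = bh, bw = bw))
  } else if (t == "flatten") {
    d <- dim(x); N <- d[length(d)]
    list(out = matrix(x, ncol = N), cache = list(dims = d))
  } else if (t == "linear") {
    list(out = layer$params$W %*% x + layer$params$b, cache = list(x = x))
  } else if (t == "dropout") {
    if (training) {
      mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
      dim(mask) <- dim(x)
      list(out = x * mask, cache = list(mask = mask))
    } else {
      list(out = x, cache = list(mask = NULL))
    }
  } else if (t == "concat_label") {
    if (is.null(labels)) stop("concat_label: no labels supplied")
    list(out = rbind(x, labels), cache = list(nf = nrow(x)))
  } else if (t == "resize") {
    d <- dim(x)
    Mh <- bilinear_mat(d[1], layer$oh); Mw <- bilinear_mat(d[2], layer$ow)
    y <- array(0, dim = c(layer$oh, layer$ow, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      y[, , c, n] <- Mh %*% x[, , c, n] %*% t(Mw)
    list(out = y, cache = list(dims = d, Mh = Mh, Mw = Mw))
  } else stop("unknown layer type: ", t)
}

layer_backward <- function(layer, cache, gy) {
  t <- layer$type
  if (t == "conv") {
    d <- cache$dims; od <- cache$odims
    k <- layer$k; s <- layer$stride
    gym <- matrix(aperm(gy, c(3, 1, 2, 4)), nrow = layer$cout)  # (cout, P*N)
    Wm <- matrix(layer$params$W, nrow = k * k * d[3])
    gW <- t(tcrossprod(gym, cache$cols))              # (k*k*cin, cout)
    gx <- col2im_cpp(Wm %*% gym, d[1], d[2], d[3], d[4], k, s)
    list(gx = gx,
         grads = list(W = array(gW, dim = dim(layer$params$W)),
                      b = rowSums(gym)))
  } else if (t == "convt") {
    d <- cache$dims; od <- cache$odims
    k <- layer$k; s <- layer$stride
    cols_gy <- im2col_cpp(gy, od[1], od[2], od[3], od[4], k, s)
    Wm <- matrix(layer$params$W, nrow = k * k * layer$cout)
    gxm <- crossprod(Wm, cols_gy)                                # (cin, P*N)
    gx <- aperm(array(gxm, dim = c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
    gW <- tcrossprod(cols_gy, cache$xm)                          # (k*k*cout, cin)
    gb <- rowSums(matrix(aperm(gy, c(3, 1, 2, 4)), nrow = layer$cout))
    list(gx = gx,
         grads = list(W = array(gW, dim = dim(layer$params$W)), b = gb))
  } else if (t == "bn") {
    d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)            # (H*W*N, C)
    xh <- cache$xh
    ggamma <- colSums(gym * xh)
    gbeta <- colSums(gym)
    gxh <- sweep(gym, 2, layer$params$gamma, "*")
    if (isTRUE(cache$training)) {
      m <- nrow(gym)
      gxm <- sweep(gxh - matrix(colMeans(gxh), m, C, byrow = TRUE) -
                     sweep(xh, 2, colMeans(gxh * xh), "*"),
                   2, cache$sd, "/")
    } else {
      gxm <- sweep(gxh, 2, cache$sd, "/")
    }
    gx <- aperm(array(gxm, dim = c(H, W, N, C)), c(1, 2, 4, 3))
    list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
  } else if (t == "relu") {
    list(gx = gy * cache$mask, grads = list())
  } else if (t == "lrelu") {
    list(gx = gy * cache$slope, grads = list())
  } else if (t == "tanh") {
    list(gx = gy * (1 - cache$th^2), grads = list())
  } else if (t == "tanh01") {
    list(gx = gy * (1 - cache$th^2) / 2, grads = list())
  } else if (t == "maxpool") {
    d <- cache$dims
    list(gx = maxpool_bwd_cpp(gy, cache$idx, d[1], d[2], d[3], d[4]), grads = list())
  } else if (t == "adaptavg") {
    d <- cache$dims
    gx <- array(0, dim = d)
    bh <- cache$bh; bw <- cache$bw
    for (a in seq_along(bh$lo)) for (b in seq_along(bw$lo)) {
      nh <- bh$hi[a] - bh$lo[a] + 1L; nw <- bw$hi[b] - bw$lo[b] + 1L
      g <- array(gy[a, b, , ], dim = c(d[3], d[4])) / (nh * nw)
      spread <- aperm(array(g, dim = c(d[3], d[4], nh, nw)), c(3, 4, 1, 2))
      gx[bh$lo[a]:bh$hi[a], bw$lo[b]:bw$hi[b], , ] <-
        gx[bh$lo[a]:bh$hi[a], bw$lo[b]:bw$hi[b], , , drop = FALSE] + spread
    }
    list(gx = gx, grads = list())
  } else if (t == "flatten") {
    gx <- gy
    dim(gx) <- cache$dims
    list(gx = gx, grads = list())
  } else if (t == "linear") {
    list(gx = crossprod(layer$params$W, gy),
         grads = list(W = tcrossprod(gy, cache$x), b = rowSums(gy)))
  } else if (t == "dropout") {
    if (is.null(cache$mask)) list(gx = gy, grads = list())
    else list(gx = gy * cache$mask, grads = list())
  } else if (t == "concat_label") {
    list(gx = gy[seq_len(cache$nf), , drop = FALSE], grads = list())
  } else if (t == "resize") {
    d <- cache$dims
    gx <- array(0, dim = d)
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      gx[, , c, n] <- t(cache$Mh) %*% gy[, , c, n] %*% cache$Mw
    list(gx = gx, grads = list())
  } else stop("unknown layer type: ", t)
}

#' @keywords internal
net_forward <- function(net, x, labels = NULL, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[l]], x, labels, training)
    caches[[l]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

# Backward pass from upstream gradient `gout` at the network output.
# Returns gradient w.r.t. the input, per-layer parameter gradients, and
# (optionally) the per-layer output deltas needed by the penalty gradient.
net_backward <- function(net, caches, gout, record_deltas = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  deltas_out <- if (record_deltas) vector("list", L) else NULL
  g <- gout
  for (l in rev(seq_len(L))) {
    if (record_deltas) deltas_out[[l]] <- g
    r <- layer_backward(net$layers[[l]], caches[[l]], g)
    grads[[l]] <- r$grads
    g <- r$gx
  }
  list(gin = g, grads = grads, deltas_out = deltas_out)
}

# Tangent (Jacobian-vector) propagation through the network linearized at the
# cached forward pass: activation masks, pooling argmaxes, dropout masks and
# normalization statistics are held fixed; biases drop out. Returns the
# tangent entering every layer plus the output tangent.
net_forward_tangent <- function(net, caches, v) {
  L <- length(net$layers)
  tin <- vector("list", L)
  for (l in seq_len(L)) {
    layer <- net$layers[[l]]; cache <- caches[[l]]
    tin[[l]] <- v
    t <- layer$type
    if (t == "conv") {
      d <- cache$dims
      k <- layer$k; s <- layer$stride
      Ho <- conv_out_size(d[1], k, s); Wo <- conv_out_size(d[2], k, s)
      cols <- im2col_cpp(v, d[1], d[2], d[3], d[4], k, s)
      Wm <- matrix(layer$params$W, nrow = k * k * d[3])
      ym <- crossprod(Wm, cols)
      v <- aperm(array(ym, dim = c(layer$cout, Ho, Wo, d[4])), c(2, 3, 1, 4))
    } else if (t == "convt") {
      d <- cache$dims; od <- cache$odims
      k <- layer$k; s <- layer$stride
      vm <- matrix(aperm(v, c(3, 1, 2, 4)), nrow = d[3])
      Wm <- matrix(layer$params$W, nrow = k * k * layer$cout)
      v <- col2im_cpp(Wm %*% vm, od[1], od[2], od[3], od[4], k, s)
    } else if (t == "bn") {
      d <- cache$dims
      vm <- matrix(aperm(v, c(1, 2, 4, 3)), ncol = d[3])
      vh <- sweep(vm, 2, cache$sd, "/")
      ym <- sweep(vh, 2, layer$params$gamma, "*")
      v <- aperm(array(ym, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else if (t == "relu") {
      v <- v * cache$mask
    } else if (t == "lrelu") {
      v <- v * cache$slope
    } else if (t == "tanh") {
      v <- v * (1 - cache$th^2)
    } else if (t == "tanh01") {
      v <- v * (1 - cache$th^2) / 2
    } else if (t == "maxpool") {
      d <- cache$dims
      picked <- as.numeric(v)[cache$idx + 1L]
      v <- array(picked, dim = c(d[1] %/% layer$p, d[2] %/% layer$p, d[3], d[4]))
    } else if (t == "adaptavg") {
      r <- layer_forward(layer, v, NULL, FALSE)
      v <- r$out
    } else if (t == "flatten") {
      d <- cache$dims
      v <- matrix(v, ncol = d[length(d)])
    } else if (t == "linear") {
      v <- layer$params$W %*% v
    } else if (t == "dropout") {
      if (!is.null(cache$mask)) v <- v * cache$mask
    } else if (t == "concat_label") {
      v <- rbind(v, matrix(0, layer$n_labels, ncol(v)))
    } else if (t == "resize") {
      r <- layer_forward(layer, v, NULL, FALSE)
      v <- r$out
    } else stop("unknown layer type in tangent pass: ", t)
  }
  list(tout = v, tin = tin)
}

# Parameter gradients of S = sum(delta_out . d(out)/d(theta) applied to
# tangents): exactly the usual weight-gradient formulas with the layer input
# replaced by the propagated tangent. Biases and BN beta do not enter.
net_tangent_param_grads <- function(net, caches, deltas_out, tin) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    layer <- net$layers[[l]]
    t <- layer$type
    if (t == "conv") {
      d <- caches[[l]]$dims
      k <- layer$k
      gym <- matrix(aperm(deltas_out[[l]], c(3, 1, 2, 4)), nrow = layer$cout)
      cols <- im2col_cpp(tin[[l]], d[1], d[2], d[3], d[4], k, layer$stride)
      grads[[l]] <- list(W = array(t(tcrossprod(gym, cols)),
                                   dim = dim(layer$params$W)),
                         b = numeric(layer$cout))
    } else if (t == "convt") {
      od <- caches[[l]]$odims
      k <- layer$k
      cols_gy <- im2col_cpp(deltas_out[[l]], od[1], od[2], od[3], od[4], k, layer$stride)
      vm <- matrix(aperm(tin[[l]], c(3, 1, 2, 4)), nrow = layer$cin)
      grads[[l]] <- list(W = array(tcrossprod(cols_gy, vm), dim = dim(layer$params$W)),
                         b = numeric(layer$cout))
    } else if (t == "bn") {
      d <- caches[[l]]$dims
      gym <- matrix(aperm(deltas_out[[l]], c(1, 2, 4, 3)), ncol = d[3])
      vm <- matrix(aperm(tin[[l]], c(1, 2, 4, 3)), ncol = d[3])
      vh <- sweep(vm, 2, caches[[l]]$sd, "/")
      grads[[l]] <- list(gamma = colSums(gym * vh), beta = numeric(layer$c))
    } else if (t == "linear") {
      grads[[l]] <- list(W = tcrossprod(deltas_out[[l]], tin[[l]]),
                         b = numeric(layer$nout))
    } else grads[[l]] <- list()
  }
  grads
}

# ---- optimizers ------------------------------------------------------------

opt_new <- function(kind = c("adam", "rmsprop"), lr,
                    beta1 = 0.9, beta2 = 0.999, alpha = 0.99, eps = 1e-8) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, alpha = alpha,
       eps = eps, t = 0L, state = list())
}

# applies one update; params/grads are nested lists layer -> name -> array
opt_step <- function(opt, net, grads) {
  opt$t <- opt$t + 1L
  for (l in seq_along(net$layers)) {
    pnames <- names(net$layers[[l]]$params)
    for (p in pnames) {
      g <- grads[[l]][[p]]
      if (is.null(g)) next
      key <- paste0(l, ".", p)
      if (opt$kind == "adam") {
        st <- opt$state[[key]]
        if (is.null(st)) st <- list(m = g * 0, v = g * 0)
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
        mhat <- st$m / (1 - opt$beta1^opt$t)
        vhat <- st$v / (1 - opt$beta2^opt$t)
        net$layers[[l]]$params[[p]] <- net$layers[[l]]$params[[p]] -
          opt$lr * mhat / (sqrt(vhat) + opt$eps)
        opt$state[[key]] <- st
      } else {
        st <- opt$state[[key]]
        if (is.null(st)) st <- list(v = g * 0)
        st$v <- opt$alpha * st$v + (1 - opt$alpha) * g^2
        net$layers[[l]]$params[[p]] <- net$layers[[l]]$params[[p]] -
          opt$lr * g / (sqrt(st$v) + opt$eps)
        opt$state[[key]] <- st
      }
    }
  }
  list(opt = opt, net = net)
}

# merge freshly computed BN running statistics back into the network
net_commit_bn <- function(net, caches) {
  for (l in seq_along(net$layers)) {
    if (net$layers[[l]]$type == "bn" && !is.null(caches[[l]]$new_run)) {
      net$layers[[l]]$buffers$run_mean <- caches[[l]]$new_run$mean
      net$layers[[l]]$buffers$run_var <- caches[[l]]$new_run$var
    }
  }
  net
}

scale_grads <- function(grads, s) {
  lapply(grads, function(g) lapply(g, function(x) x * s))
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (l in seq_along(a)) {
    for (p in names(a[[l]])) {
      if (!is.null(b[[l]][[p]])) a[[l]][[p]] <- a[[l]][[p]] + b[[l]][[p]]
    }
  }
  a
}
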