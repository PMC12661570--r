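#' Training configuration for the conditional WGAN-GP
#'
#' Defaults follow the augmentation model's published schedule: 151 epochs,
#' batch size 32, Adam generator at 8e-5, RMSprop critic at 6.7e-6, five
#' critic updates per generator update, 100-dimensional latent space, two
#' condition labels, gradient-penalty coefficient 10, and 200x200 images.
#' `image_size` can be reduced for desk-scale smoke runs.
#'
#' @param epochs,batch_size training schedule.
#' @param lr_generator,lr_critic learning rates.
#' @param critic_steps_per_gen critic updates per generator update.
#' @param latent_dim latent vector length.
#' @param n_labels number of condition classes.
#' @param gp_lambda gradient-penalty coefficient.
#' @param image_size output image side in pixels.
#' @param seed integer seed.
#' @return list of class `gan_config`.
#' @export
gan_config <- function(epochs = 151L, batch_size = 32L,
                       lr_generator = 8e-5, lr_critic = 6.7e-6,
                       critic_steps_per_gen = 5L, latent_dim = 100L,
                       n_labels = 2L, gp_lambda = 10,
                       image_size = 200L, seed = 1L) {
  assert_that(epochs >= 1 && batch_size >= 1 && latent_dim >= 1 &&
                n_labels >= 2 && critic_steps_per_gen >= 1,
              "all counts must be positive")
  assert_that(gp_lambda >= 0, "gp_lambda must be >= 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_generator = lr_generator, lr_critic = lr_critic,
                 critic_steps_per_gen = as.integer(critic_steps_per_gen),
                 latent_dim = as.integer(latent_dim),
                 n_labels = as.integer(n_labels), gp_lambda = gp_lambda,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "gan_config")
}

#' Build the conditional generator
#'
#' Five transposed-convolution stages with channel sequence
#' latent+labels -> 256 -> 128 -> 64 -> 32 -> 16 and kernel/stride pairs
#' (3,2), (3,2), (5,3), (3,3), (3,2), batch normalization and ReLU on stages
#' 1-4 and a saturating tanh on stage 5. Traced from a 1x1 latent input the
#' backbone ends at a 139x139 16-channel map, so an output head follows: a
#' 1x1 projection to a single channel, an affine map of the saturating
#' output onto [0, 1], and bilinear resizing to `image_size`.
#'
#' @param config a [gan_config()].
#' @return list of class `gan_generator` with the layer stack and geometry.
#' @export
build_generator <- function(config) {
  cin <- config$latent_dim + config$n_labels
  layers <- list(
    nn_convt(cin, 256, 3, 2), nn_bn(256), nn_relu(),
    nn_convt(256, 128, 3, 2), nn_bn(128), nn_relu(),
    nn_convt(128, 64, 5, 3), nn_bn(64), nn_relu(),
    nn_convt(64, 32, 3, 3), nn_bn(32), nn_relu(),
    nn_convt(32, 16, 3, 2), nn_tanh(),
    nn_conv(16, 1, 1, 1), nn_tanh01(),
    nn_resize(config$image_size)
  )
  structure(list(layers = layers, latent_dim = config$latent_dim,
                 n_labels = config$n_labels, image_size = config$image_size,
                 backbone_size = 139L),
            class = c("gan_generator", "nn_net"))
}

#' Build the conditional critic
#'
#' Two strided convolution stages 1 -> 128 -> 256 (kernel 4, stride 2) with
#' batch normalization and LeakyReLU, adaptive average pooling to a 2x2 grid
#' (so the flattened feature width is exactly 256*2*2 = 1024 for any image
#' size), one-hot label concatenation, a 1026 -> 64 linear layer with
#' LeakyReLU and dropout, and a final linear map to one unbounded score.
#'
#' @param config a [gan_config()].
#' @return list of class `gan_critic`.
#' @export
build_critic <- function(config) {
  layers <- list(
    nn_conv(1, 128, 4, 2), nn_bn(128), nn_lrelu(0.2),
    nn_conv(128, 256, 4, 2), nn_bn(256), nn_lrelu(0.2),
    nn_adaptavg(2, 2), nn_flatten(),
    nn_concat_label(config$n_labels),
    nn_linear(1024 + config$n_labels, 64), nn_lrelu(0.2),
    nn_dropout(0.3),
    nn_linear(64, 1)
  )
  structure(list(layers = layers, n_labels = config$n_labels,
                 flatten_width = 1024L),
            class = c("gan_critic", "nn_net"))
}

one_hot <- function(labels, n_labels) {
  m <- matrix(0, n_labels, length(labels))
  m[cbind(labels + 1L, seq_along(labels))] <- 1
  m
}

# latent (latent_dim, N) + one-hot labels -> (1,1,latent+labels,N) input
generator_input <- function(z, labels, n_labels) {
  zc <- rbind(z, one_hot(labels, n_labels))
  array(zc, dim = c(1, 1, nrow(zc), ncol(zc)))
}

generator_forward <- function(gen, z, labels, training = FALSE) {
  x <- generator_input(z, labels, gen$n_labels)
  net_forward(gen, x, labels = NULL, training = training)
}

critic_forward <- function(critic, images, labels, training = FALSE) {
  net_forward(critic, images, labels = one_hot(labels, critic$n_labels),
              training = training)
}

#' Critic score for a batch of images
#'
#' @param critic a `gan_critic`.
#' @param images array (H, W, 1, N) or list of matrices.
#' @param labels integer vector of class labels (0-based).
#' @param training logical; use batch statistics and dropout.
#' @return numeric vector of N unbounded scores.
#' @export
critic_score <- function(critic, images, labels, training = FALSE) {
  if (is.list(images)) images <- pixels_to_batch(images, channels = 1)
  as.numeric(critic_forward(critic, images, labels, training)$out)
}

# stack a list of (H x W) matrices into an (H, W, C, N) batch,
# replicating the single channel when `channels > 1`
pixels_to_batch <- function(pixels, channels = 1) {
  H <- nrow(pixels[[1]]); W <- ncol(pixels[[1]]); N <- length(pixels)
  x <- array(0, dim = c(H, W, channels, N))
  for (n in seq_len(N)) for (c in seq_len(channels)) x[, , c, n] <- pixels[[n]]
  x
}

#' WGAN gradient penalty
#'
#' For interpolates `x^ = eps * real + (1 - eps) * fake` (one uniform eps per
#' sample), the penalty is
#' `lambda * mean((||grad_x D(x^, label)||_2 - 1)^2)`. The critic is
#' evaluated with its running normalization statistics and dropout disabled,
#' making the value deterministic given the interpolates and matching a
#' finite-difference derivative of the same evaluation.
#'
#' @param critic a `gan_critic`.
#' @param real,fake arrays (H, W, 1, N) or lists of matrices.
#' @param labels integer vector (0-based), aligned with both batches.
#' @param gp_lambda penalty coefficient.
#' @param eps optional fixed interpolation weights (length N), for testing.
#' @param seed seed for the interpolation weights when `eps` is NULL.
#' @return scalar penalty value, with attribute `"grad_norms"` carrying the
#'   per-sample gradient norms.
#' @export
gradient_penalty <- function(critic, real, fake, labels, gp_lambda = 10,
                             eps = NULL, seed = NULL) {
  if (is.list(real)) real <- pixels_to_batch(real, 1)
  if (is.list(fake)) fake <- pixels_to_batch(fake, 1)
  assert_that(all(dim(real) == dim(fake)), "real/fake batch shapes differ")
  N <- dim(real)[4]
  assert_that(length(labels) == N, "labels misaligned with batch")
  if (is.null(eps)) eps <- with_seed(seed, stats::runif(N))
  xhat <- real
  for (n in seq_len(N)) xhat[, , , n] <- eps[n] * real[, , , n] +
      (1 - eps[n]) * fake[, , , n]
  r <- penalty_backward(critic, xhat, labels)
  norms <- r$norms
  val <- gp_lambda * mean((norms - 1)^2)
  attr(val, "grad_norms") <- norms
  val
}

# eval-mode forward + backward at xhat; returns per-sample input gradients,
# their norms, the caches and per-layer output deltas (for the exact
# penalty parameter gradient)
penalty_backward <- function(critic, xhat, labels) {
  fwd <- critic_forward(critic, xhat, labels, training = FALSE)
  N <- dim(xhat)[4]
  gout <- matrix(1, 1, N)
  bwd <- net_backward(critic, fwd$caches, gout, record_deltas = TRUE)
  g <- bwd$gin
  norms <- sqrt(apply(g^2, 4, sum))
  list(g = g, norms = norms, caches = fwd$caches, deltas = bwd$deltas_out,
       scores = as.numeric(fwd$out))
}

# exact parameter gradient of the penalty at fixed activation masks and
# normalization statistics: dP/dtheta = d/dtheta (v . dD/dx) with
# v = (2 lambda / N) (||g|| - 1) g / ||g|| held constant
penalty_param_grads <- function(critic, xhat, labels, gp_lambda) {
  r <- penalty_backward(critic, xhat, labels)
  N <- dim(xhat)[4]
  v <- r$g
  for (n in seq_len(N)) {
    nv <- max(r$norms[n], 1e-12)
    v[, , , n] <- v[, , , n] * (2 * gp_lambda / N) * (r$norms[n] - 1) / nv
  }
  tg <- net_forward_tangent(critic, r$caches, v)
  grads <- net_tangent_param_grads(critic, r$caches, r$deltas, tg$tin)
  penalty <- gp_lambda * mean((r$norms - 1)^2)
  list(grads = grads, penalty = penalty)
}

#' Train the conditional WGAN-GP on real training-subject scalograms
#'
#' Alternates `critic_steps_per_gen` critic updates (Wasserstein loss plus
#' gradient penalty, RMSprop) with one generator update (Adam). Only
#' scalograms with provenance `"real"` whose subjects are outside
#' `test_subjects` are accepted — the leakage guard of the subject-wise
#' evaluation protocol.
#'
#' @param scalograms tibble with `pixels`, `label`, `provenance`,
#'   `subject_id` columns.
#' @param config a [gan_config()].
#' @param test_subjects character vector of held-out subject ids; any
#'   overlap with the training scalograms is an error.
#' @return list of class `gan_checkpoint`: `generator`, `critic`, `config`,
#'   `epoch`, `losses` (per-step tibble).
#' @export
train_cwgan <- function(scalograms, config = gan_config(),
                        test_subjects = character(0)) {
  assert_that(all(scalograms$provenance == "real"),
              "GAN training inputs must all have provenance 'real'")
  leaked <- intersect(unique(scalograms$subject_id), test_subjects)
  if (length(leaked) > 0)
    stop("leakage: scalograms from held-out subject(s) ",
         paste(leaked, collapse = ", "), " in GAN training set", call. = FALSE)
  labs <- scalograms$label
  assert_that(length(unique(labs)) == config$n_labels,
              "every label class needs at least one training scalogram")
  px <- scalograms$pixels
  if (nrow(px[[1]]) != config$image_size)
    stop("scalogram size ", nrow(px[[1]]), " != config image_size ",
         config$image_size, call. = FALSE)

  with_seed(config$seed, {
    gen <- build_generator(config)
    critic <- build_critic(config)
  })
  opt_g <- opt_new("adam", config$lr_generator, beta1 = 0.5, beta2 = 0.9)
  opt_c <- opt_new("rmsprop", config$lr_critic)
  nimg <- length(px)
  bs <- min(config$batch_size, nimg)
  losses <- list()
  step <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nimg)
      nb <- nimg %/% bs
      for (b in seq_len(nb)) {
        take <- ord[((b - 1) * bs + 1):(b * bs)]
        xr <- pixels_to_batch(px[take], 1)
        yb <- labs[take]

        # ----- critic update -----
        z <- matrix(stats::rnorm(config$latent_dim * bs), config$latent_dim)
        gf <- generator_forward(gen, z, yb, training = TRUE)
        xf <- gf$out

        fr <- critic_forward(critic, xr, yb, training = TRUE)
        br <- net_backward(critic, fr$caches, matrix(-1 / bs, 1, bs))
        critic <- net_commit_bn(critic, fr$caches)
        ff <- critic_forward(critic, xf, yb, training = TRUE)
        bf <- net_backward(critic, ff$caches, matrix(1 / bs, 1, bs))
        critic <- net_commit_bn(critic, ff$caches)

        eps <- stats::runif(bs)
        xhat <- xr
        for (n in seq_len(bs)) xhat[, , , n] <- eps[n] * xr[, , , n] +
            (1 - eps[n]) * xf[, , , n]
        pg <- penalty_param_grads(critic, xhat, yb, config$gp_lambda)

        grads_c <- add_grads(add_grads(br$grads, bf$grads), pg$grads)
        sc <- opt_step(opt_c, critic, grads_c)
        opt_c <- sc$opt; critic <- sc$net
        loss_c <- mean(ff$out) - mean(fr$out) + pg$penalty
        step <- step + 1L

        loss_g <- NA_real_
        # ----- generator update every critic_steps_per_gen batches -----
        if (step %% config$critic_steps_per_gen == 0L) {
          z <- matrix(stats::rnorm(config$latent_dim * bs), config$latent_dim)
          yg <- sample(0:(config$n_labels - 1), bs, replace = TRUE)
          gf <- generator_forward(gen, z, yg, training = TRUE)
          fg <- critic_forward(critic, gf$out, yg, training = TRUE)
          bw_c <- net_backward(critic, fg$caches, matrix(-1 / bs, 1, bs))
          bw_g <- net_backward(gen, gf$caches, bw_c$gin)
          gen <- net_commit_bn(gen, gf$caches)
          sg <- opt_step(opt_g, gen, bw_g$grads)
          opt_g <- sg$opt; gen <- sg$net
          loss_g <- -mean(fg$out)
        }
        losses[[length(losses) + 1L]] <-
          tibble::tibble(epoch = epoch, step = step,
                         critic_loss = loss_c, penalty = pg$penalty,
                         generator_loss = loss_g)
      }
    }
  })
  structure(list(generator = gen, critic = critic, config = config,
                 epoch = config$epochs, losses = dplyr::bind_rows(losses)),
            class = "gan_checkpoint")
}

#' @export
print.gan_checkpoint <- function(x, ...) {
  cat(sprintf("<gan_checkpoint> %d epoch(s), image %dx%d, %d critic step(s)\n",
              x$epoch, x$config$image_size, x$config$image_size,
              nrow(x$losses)))
  invisible(x)
}

#' Sample class-conditional scalograms from a trained generator
#'
#' @param checkpoint a `gan_checkpoint`.
#' @param label class label (0-based) to condition on.
#' @param n number of images.
#' @param seed integer seed.
#' @return tibble with `pixels` (list of matrices in [0,1]), `label`,
#'   `provenance = "synthetic"` and empty subject linkage.
#' @export
synthesize <- function(checkpoint, label, n, seed = 1L) {
  cfg <- checkpoint$config
  assert_that(label >= 0 && label < cfg$n_labels, "invalid label")
  gen <- checkpoint$generator
  with_seed(seed, {
    z <- matrix(stats::rnorm(cfg$latent_dim * n), cfg$latent_dim)
    out <- generator_forward(gen, z, rep(as.integer(label), n),
                             training = FALSE)$out
    tibble::tibble(
      subject_id = NA_character_,
      window_index = NA_integer_,
      frame_index = NA_integer_,
      provenance = "synthetic",
      label = as.integer(label),
      pixels = purrr::map(seq_len(n), ~ out[, , 1, .x])
    )
  })
}

#' Combine real scalograms with synthetic ones for augmentation
#'
#' Two augmentation policies: `percent_increase` adds
#' `round(amount/100 * n_real)` synthetic scalograms split evenly across the
#' labels; `balance_to_equal` adds per-class synthetic counts that equalize
#' the class totals.
#'
#' @param real tibble of real scalograms (`pixels`, `label`, `provenance`).
#' @param checkpoint a trained `gan_checkpoint`.
#' @param mode `"percent_increase"` or `"balance_to_equal"`.
#' @param amount percentage increase (first mode only).
#' @param seed seed for the synthesis.
#' @return combined tibble; provenance tags preserved.
#' @export
augment_training_set <- function(real, checkpoint,
                                 mode = c("percent_increase", "balance_to_equal"),
                                 amount = 75, seed = 1L) {
  mode <- match.arg(mode)
  assert_that(amount >= 0, "amount must be non-negative")
  n_labels <- checkpoint$config$n_labels
  counts <- integer(n_labels)
  if (mode == "percent_increase") {
    n_add <- round(amount / 100 * nrow(real))
    base <- n_add %/% n_labels
    counts <- rep(base, n_labels)
    extra <- n_add - base * n_labels
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  } else {
    per_class <- vapply(0:(n_labels - 1),
                        function(l) sum(real$label == l), integer(1))
    counts <- max(per_class) - per_class
  }
  seeds <- derive_seeds(seed, n_labels)
  synth <- purrr::map(which(counts > 0), function(i) {
    synthesize(checkpoint, i - 1L, counts[i], seed = seeds[i])
  })
  dplyr::bind_rows(c(list(real), synth))
}
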