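#' Frame-classifier architecture specification
#'
#' Five convolution stages (stride 1, no padding), each followed by batch
#' normalization, ReLU and max pooling, then a fully connected stack ending
#' in a single logit. The default mirrors the published classifier: kernel
#' sizes 5, 3, 13, 5, 2, pooling 2, 2, 2, 2, 3, a final channel count of 512
#' so that a 3-channel 200x200 input flattens to exactly 2048 features
#' (spatial trace 200 -> 98 -> 48 -> 18 -> 7 -> 2), and fully connected
#' widths 1024, 256, 64, 1 with dropout 0.5 after every non-final layer.
#'
#' @param image_size input image side, pixels.
#' @param in_channels input channels (grayscale scalograms are replicated to
#'   3 channels at batch assembly).
#' @param kernels,channels,pools per-stage kernel sizes, output channels and
#'   max-pooling sizes (equal lengths).
#' @param fc fully connected widths; last entry must be 1.
#' @param dropout dropout probability after each non-final linear layer.
#' @return list of class `cnn_spec`; `$flatten_width` gives the flattened
#'   feature width implied by the geometry.
#' @export
cnn_spec <- function(image_size = 200L, in_channels = 3L,
                     kernels = c(5L, 3L, 13L, 5L, 2L),
                     channels = c(16L, 32L, 64L, 128L, 512L),
                     pools = c(2L, 2L, 2L, 2L, 3L),
                     fc = c(1024L, 256L, 64L, 1L),
                     dropout = 0.5) {
  assert_that(length(kernels) == length(channels) &&
                length(kernels) == length(pools),
              "kernels, channels and pools must have equal length")
  assert_that(fc[length(fc)] == 1, "final fully connected width must be 1")
  s <- image_size
  for (j in seq_along(kernels)) {
    s <- s - kernels[j] + 1L
    if (s < 1) stop("configuration error: stage ", j,
                    " kernel exceeds its input size", call. = FALSE)
    s <- s %/% pools[j]
    if (s < 1) stop("configuration error: stage ", j,
                    " pooling collapses the feature map", call. = FALSE)
  }
  flat <- s * s * channels[length(channels)]
  spec <- structure(list(image_size = as.integer(image_size),
                         in_channels = as.integer(in_channels),
                         kernels = as.integer(kernels),
                         channels = as.integer(channels),
                         pools = as.integer(pools),
                         fc = as.integer(fc), dropout = dropout,
                         flatten_width = as.integer(flat * 1L),
                         final_spatial = as.integer(s)),
                    class = "cnn_spec")
  default_geom <- identical(spec$kernels, c(5L, 3L, 13L, 5L, 2L)) &&
    identical(spec$pools, c(2L, 2L, 2L, 2L, 3L)) && spec$image_size == 200L
  if (default_geom && spec$flatten_width != 2048L)
    stop("configuration error: default geometry must flatten to 2048 features",
         call. = FALSE)
  spec
}

#' A reduced classifier spec for small test images
#'
#' Three small convolution stages; used by the desk-scale experiments and
#' tests, never by the default pipeline.
#'
#' @param image_size input side, pixels (>= 16).
#' @return a `cnn_spec`.
#' @export
cnn_spec_small <- function(image_size = 48L) {
  cnn_spec(image_size = image_size, in_channels = 3L,
           kernels = c(3L, 3L, 3L), channels = c(8L, 16L, 32L),
           pools = c(2L, 2L, 2L), fc = c(64L, 32L, 1L), dropout = 0.25)
}

#' Build the frame classifier network
#'
#' @param spec a [cnn_spec()].
#' @return list of class `cnn_model` wrapping the layer stack; forward
#'   passes map a (size, size, channels, N) batch to one logit per image.
#' @export
build_cnn <- function(spec = cnn_spec()) {
  layers <- list()
  cin <- spec$in_channels
  for (j in seq_along(spec$kernels)) {
    layers <- c(layers, list(nn_conv(cin, spec$channels[j], spec$kernels[j], 1L),
                             nn_bn(spec$channels[j]), nn_relu(),
                             nn_maxpool(spec$pools[j])))
    cin <- spec$channels[j]
  }
  layers <- c(layers, list(nn_flatten()))
  nin <- spec$flatten_width
  for (j in seq_along(spec$fc)) {
    layers <- c(layers, list(nn_linear(nin, spec$fc[j])))
    if (j < length(spec$fc))
      layers <- c(layers, list(nn_relu(), nn_dropout(spec$dropout)))
    nin <- spec$fc[j]
  }
  structure(list(layers = layers, spec = spec), class = c("cnn_model", "nn_net"))
}

# index (into the layer list) of the ReLU output of convolution stage `k`
cnn_stage_relu_index <- function(model, k) 4L * (k - 1L) + 3L

#' Flattened feature width of a built classifier
#'
#' Runs a forward pass up to the flatten point and reports the feature count
#' entering the fully connected stack.
#'
#' @param model a `cnn_model`.
#' @return integer feature count.
#' @export
cnn_flatten_width <- function(model) {
  spec <- model$spec
  x <- array(0, dim = c(spec$image_size, spec$image_size, spec$in_channels, 1L))
  for (l in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[l]], x, NULL, FALSE)
    x <- r$out
    if (model$layers[[l]]$type == "flatten") return(nrow(x))
  }
  stop("no flatten layer found")
}

#' Classifier training configuration
#'
#' @param epochs,batch_size training schedule.
#' @param lr Adam learning rate (default 0.001).
#' @param seed integer seed.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(epochs = 10L, batch_size = 32L, lr = 0.001,
                              seed = 1L) {
  assert_that(lr > 0, "learning rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the frame classifier
#'
#' Binary cross-entropy on the sigmoid of the single logit, Adam optimizer.
#' Real scalograms from subjects in `test_subjects` abort with a leakage
#' error; synthetic scalograms (no subject linkage) are always admissible.
#'
#' @param scalograms tibble with `pixels`, `label`, `provenance`,
#'   `subject_id`.
#' @param config a [classifier_config()].
#' @param spec a [cnn_spec()].
#' @param test_subjects held-out subject ids (leakage guard).
#' @return list of class `cnn_fit`: `model`, `spec`, `config`,
#'   `loss_history` (per-epoch mean BCE).
#' @export
train_classifier <- function(scalograms, config = classifier_config(),
                             spec = cnn_spec(), test_subjects = character(0)) {
  real_ids <- unique(scalograms$subject_id[scalograms$provenance == "real"])
  leaked <- intersect(real_ids, test_subjects)
  if (length(leaked) > 0)
    stop("leakage: held-out subject(s) ", paste(leaked, collapse = ", "),
         " present in classifier training set", call. = FALSE)
  labs <- scalograms$label
  assert_that(length(unique(labs)) == 2, "both classes must be present")
  px <- scalograms$pixels
  assert_that(nrow(px[[1]]) == spec$image_size,
              "scalogram size does not match the classifier spec")

  model <- with_seed(config$seed, build_cnn(spec))
  opt <- opt_new("adam", config$lr)
  nimg <- length(px)
  bs <- min(config$batch_size, nimg)
  loss_history <- numeric(config$epochs)

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nimg)
      nb <- nimg %/% bs
      ep_loss <- 0
      for (b in seq_len(nb)) {
        take <- ord[((b - 1) * bs + 1):(b * bs)]
        x <- pixels_to_batch(px[take], spec$in_channels)
        y <- labs[take]
        fwd <- net_forward(model, x, training = TRUE)
        z <- as.numeric(fwd$out)
        p <- 1 / (1 + exp(-z))
        eps <- 1e-12
        loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
        gout <- matrix((p - y) / bs, 1, bs)
        bwd <- net_backward(model, fwd$caches, gout)
        model <- net_commit_bn(model, fwd$caches)
        st <- opt_step(opt, model, bwd$grads)
        opt <- st$opt; model <- st$net
        ep_loss <- ep_loss + loss
      }
      loss_history[epoch] <- ep_loss / nb
    }
  })
  structure(list(model = model, spec = spec, config = config,
                 loss_history = loss_history),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> %dx%d input, %d epochs, final BCE %.4f\n",
              x$spec$image_size, x$spec$image_size, x$config$epochs,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Frame-level predictions
#'
#' Deterministic evaluation pass (running batch statistics, dropout off).
#' The hard label is 1 when the predicted probability is at least 0.5
#' (inclusive threshold).
#'
#' @param fit a `cnn_fit`.
#' @param scalograms tibble with `pixels` plus identification columns.
#' @param batch_size evaluation batch size.
#' @return tibble: `subject_id`, `window_index`, `frame_index`,
#'   `probability`, `hard_label`, `true_label`.
#' @export
predict_frames <- function(fit, scalograms, batch_size = 64L) {
  spec <- fit$spec
  px <- scalograms$pixels
  assert_that(nrow(px[[1]]) == spec$image_size, "image size mismatch")
  n <- length(px)
  probs <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    x <- pixels_to_batch(px[take], spec$in_channels)
    z <- as.numeric(net_forward(fit$model, x, training = FALSE)$out)
    probs[take] <- 1 / (1 + exp(-z))
  }
  tibble::tibble(
    subject_id = scalograms$subject_id,
    window_index = scalograms$window_index,
    frame_index = scalograms$frame_index,
    probability = probs,
    hard_label = as.integer(probs >= 0.5),
    true_label = scalograms$label
  )
}
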