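# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# scalograms of noisy tones at two distinct ridge frequencies -> a perfectly
# separable two-class image set with subject bookkeeping
tone_scalograms <- function(n_per_class = 32, size = 32, f0 = 1.0, f1 = 2.0,
                            n_subjects_per_class = 4, seed = 42) {
  withr::with_seed(seed, {
    mk <- function(f, n) lapply(seq_len(n), function(i) {
      tone <- sin(2 * pi * f * (0:799) / 200 + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(800, 0, 0.2)
      cwt_scalogram(tone, 200, scalogram_config(size = size))$pixels
    })
    per_subj <- n_per_class / n_subjects_per_class
    tibble::tibble(
      subject_id = rep(sprintf("T%02d", seq_len(2 * n_subjects_per_class)),
                       each = per_subj),
      window_index = 0L,
      frame_index = rep(seq_len(per_subj) - 1L, 2 * n_subjects_per_class),
      provenance = "real",
      label = rep(c(0L, 1L), each = n_per_class),
      pixels = c(mk(f0, n_per_class), mk(f1, n_per_class))
    )
  })
}

fixture_tone_set <- function() cached("tone_set", function() {
  tone_scalograms(n_per_class = 32, size = 32)
})

# one smoke-trained conditional WGAN checkpoint on the tone set
fixture_gan_checkpoint <- function() cached("gan_ck", function() {
  train_cwgan(fixture_tone_set(),
              gan_config(epochs = 1L, batch_size = 16L, image_size = 32L,
                         critic_steps_per_gen = 2L, seed = 11L))
})

# an untrained checkpoint (architecture only) for cheap synthesis tests
fixture_untrained_checkpoint <- function(image_size = 32L) {
  cfg <- gan_config(image_size = image_size, seed = 5L)
  ck <- withr::with_seed(5, list(generator = build_generator(cfg),
                                 critic = build_critic(cfg),
                                 config = cfg, epoch = 0L,
                                 losses = tibble::tibble()))
  class(ck) <- "gan_checkpoint"
  ck
}

# a small trained classifier on the tone set
fixture_tone_fit <- function() cached("tone_fit", function() {
  sc <- fixture_tone_set()
  train_classifier(sc, classifier_config(epochs = 3L, seed = 9L),
                   cnn_spec_small(32L))
})

# standard synthetic mixture: slow large respiration + fast small pulse
# train, at the raw 2 kHz rate
standard_mixture <- function(fs = 2000, duration = 10, resp_f = 0.25,
                             resp_a = 4, beat_f = 1.2, beat_a = 0.3,
                             sigma = 0.06, phase = 0.7) {
  t <- (seq_len(fs * duration) - 1) / fs
  resp <- resp_a * sin(2 * pi * resp_f * t + phase)
  beats <- seq(0.3, duration, by = 1 / beat_f)
  cardiac <- rowSums(vapply(beats, function(b) {
    beat_a * exp(-((t - b)^2) / (2 * sigma^2))
  }, numeric(length(t))))
  list(t = t, resp = resp, cardiac = cardiac, total = resp + cardiac, fs = fs)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
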