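test_that("default classifier geometry flattens to exactly 2048 features", {
  spec <- cnn_spec()
  expect_equal(spec$flatten_width, 2048L)
  model <- withr::with_seed(1, build_cnn(spec))
  expect_equal(cnn_flatten_width(model), 2048L)

  x <- array(stats::runif(200 * 200 * 3), c(200, 200, 3, 1))
  out1 <- radarleak:::net_forward(model, x)$out
  expect_equal(dim(out1), c(1, 1))  # one logit per image
  expect_identical(out1, radarleak:::net_forward(model, x)$out)

  # geometry that breaks the printed flatten constraint is rejected
  expect_error(cnn_spec(channels = c(16L, 32L, 64L, 128L, 256L)),
               "configuration error")
  expect_error(cnn_spec(image_size = 16), "configuration error")
})

test_that("training learns a separable fixture and is seed reproducible", {
  sc <- fixture_tone_set()
  fit <- fixture_tone_fit()
  expect_lt(fit$loss_history[length(fit$loss_history)], fit$loss_history[1])

  pr <- predict_frames(fit, sc)
  expect_gte(mean(pr$hard_label == pr$true_label), 0.95)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr, predict_frames(fit, sc))

  fit2 <- train_classifier(sc, classifier_config(epochs = 3L, seed = 9L),
                           cnn_spec_small(32L))
  expect_identical(fit$loss_history, fit2$loss_history)
})

test_that("the decision threshold at probability 0.5 is inclusive", {
  spec <- cnn_spec_small(24L)
  model <- withr::with_seed(2, build_cnn(spec))
  # zero the output layer: every logit is 0, probability exactly 0.5
  L <- length(model$layers)
  model$layers[[L]]$params$W[] <- 0
  model$layers[[L]]$params$b[] <- 0
  fit <- structure(list(model = model, spec = spec,
                        config = classifier_config(), loss_history = NA_real_),
                   class = "cnn_fit")
  sc <- tibble::tibble(subject_id = "A", window_index = 0L, frame_index = 0L,
                       provenance = "real", label = 0L,
                       pixels = list(matrix(0.5, 24, 24)))
  pr <- predict_frames(fit, sc)
  expect_equal(pr$probability, 0.5)
  expect_equal(pr$hard_label, 1L)
})

test_that("classifier training enforces the subject leakage guard", {
  sc <- fixture_tone_set()
  expect_error(train_classifier(sc, classifier_config(epochs = 1L),
                                cnn_spec_small(32L),
                                test_subjects = "T02"),
               "leakage.*T02")
  # synthetic scalograms carry no subject and are always admissible
  synth <- synthesize(fixture_untrained_checkpoint(32L), 1L, 4, seed = 1)
  mixed <- dplyr::bind_rows(sc[sc$subject_id != "T02", ], synth)
  expect_no_error(train_classifier(mixed, classifier_config(epochs = 1L),
                                   cnn_spec_small(32L),
                                   test_subjects = "T02"))
  expect_error(train_classifier(sc[sc$label == 1, ],
                                classifier_config(epochs = 1L),
                                cnn_spec_small(32L)),
               "both classes")
})
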