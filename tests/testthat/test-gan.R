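test_that("generator geometry matches the conditioning contract", {
  cfg <- gan_config(image_size = 64)
  gen <- build_generator(cfg)
  expect_equal(gen$layers[[1]]$cin, 102)  # latent 100 + 2 one-hot labels

  withr::with_seed(1, z <- matrix(stats::rnorm(200), 100))
  out1 <- radarleak:::generator_forward(gen, z, c(0L, 1L))$out
  out2 <- radarleak:::generator_forward(gen, z, c(0L, 1L))$out
  expect_identical(out1, out2)
  expect_equal(dim(out1), c(64, 64, 1, 2))
  expect_true(all(out1 >= 0 & out1 <= 1))
})

test_that("critic flattens to 1024 features and scores depend on the label", {
  cfg <- gan_config(image_size = 64)
  critic <- withr::with_seed(2, build_critic(cfg))
  x <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  a <- x
  flat_width <- NULL
  for (l in seq_along(critic$layers)) {
    if (critic$layers[[l]]$type == "concat_label" && is.null(flat_width))
      flat_width <- nrow(a)
    a <- radarleak:::layer_forward(critic$layers[[l]], a,
                                   radarleak:::one_hot(0L, 2), FALSE)$out
  }
  expect_equal(flat_width, 1024)
  expect_equal(dim(a), c(1, 1))

  s0 <- critic_score(critic, x, 0L)
  s1 <- critic_score(critic, x, 1L)
  expect_length(s0, 1)
  expect_gt(abs(s0 - s1), 0)
})

test_that("gradient penalty matches closed forms and finite differences", {
  # D(x) = w.x with ||w|| = 1: penalty identically zero
  lin <- structure(list(layers = list(radarleak:::nn_flatten(),
                                      radarleak:::nn_linear(4, 1)),
                        n_labels = 2),
                   class = c("gan_critic", "nn_net"))
  lin$layers[[2]]$params$W <- matrix(0.5, 1, 4)
  lin$layers[[2]]$params$b <- 0
  withr::with_seed(3, {
    real <- array(stats::runif(12), c(2, 2, 1, 3))
    fake <- array(stats::runif(12), c(2, 2, 1, 3))
  })
  p0 <- gradient_penalty(lin, real, fake, labels = c(0L, 1L, 0L),
                         gp_lambda = 10, seed = 1)
  expect_equal(as.numeric(p0), 0, tolerance = 1e-12)

  # D(x) = 2 * sum(x) over 4 inputs: gradient norm 4, penalty 10*(4-1)^2
  lin$layers[[2]]$params$W <- matrix(2, 1, 4)
  p90 <- gradient_penalty(lin, real, fake, labels = c(0L, 1L, 0L),
                          gp_lambda = 10, seed = 1)
  expect_equal(as.numeric(p90), 90, tolerance = 1e-12)
  expect_error(gradient_penalty(lin, real, fake[, , , 1:2, drop = FALSE],
                                labels = c(0L, 1L, 0L)), "shapes differ")

  # small random critic: analytic input gradient vs central differences
  cfg <- gan_config(image_size = 16)
  critic <- withr::with_seed(4, build_critic(cfg))
  withr::with_seed(5, {
    real <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
    fake <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
    eps_w <- stats::runif(2)
  })
  labs <- c(0L, 1L)
  xhat <- real
  for (n in 1:2) xhat[, , , n] <- eps_w[n] * real[, , , n] +
      (1 - eps_w[n]) * fake[, , , n]
  g <- radarleak:::penalty_backward(critic, xhat, labs)$g
  h <- 1e-5
  withr::with_seed(6, idx <- cbind(sample(16, 4, TRUE), sample(16, 4, TRUE),
                                   1L, sample(2, 4, TRUE)))
  for (r in 1:4) {
    xp <- xhat; xp[idx[r, 1], idx[r, 2], 1, idx[r, 4]] <-
      xp[idx[r, 1], idx[r, 2], 1, idx[r, 4]] + h
    xm <- xhat; xm[idx[r, 1], idx[r, 2], 1, idx[r, 4]] <-
      xm[idx[r, 1], idx[r, 2], 1, idx[r, 4]] - h
    fd <- (critic_score(critic, xp, labs)[idx[r, 4]] -
             critic_score(critic, xm, labs)[idx[r, 4]]) / (2 * h)
    expect_equal(fd, g[idx[r, 1], idx[r, 2], 1, idx[r, 4]], tolerance = 1e-4)
  }

  # penalty parameter gradients (double backward) vs finite differences
  pg <- radarleak:::penalty_param_grads(critic, xhat, labs, 10)
  pfun <- function(net) as.numeric(gradient_penalty(net, real, fake, labs,
                                                    10, eps = eps_w))
  for (probe in list(list(1L, "W"), list(2L, "gamma"), list(10L, "W"))) {
    l <- probe[[1]]; pn <- probe[[2]]
    arr <- critic$layers[[l]]$params[[pn]]
    ii <- withr::with_seed(l, sample(length(arr), 1))
    cp <- critic; cp$layers[[l]]$params[[pn]][ii] <- arr[ii] + h
    cm <- critic; cm$layers[[l]]$params[[pn]][ii] <- arr[ii] - h
    fd <- (pfun(cp) - pfun(cm)) / (2 * h)
    expect_equal(fd, pg$grads[[l]][[pn]][ii], tolerance = 1e-4)
  }
})

test_that("smoke training runs, is seeded and separates real from fake", {
  ck <- fixture_gan_checkpoint()
  expect_true(all(is.finite(ck$losses$critic_loss)))
  expect_true(all(is.finite(ck$losses$penalty)))
  expect_true(any(is.finite(ck$losses$generator_loss)))

  sc <- fixture_tone_set()
  # critic prefers real over generated samples after the smoke run
  fake <- synthesize(ck, 0L, 8, seed = 2)
  rs <- critic_score(ck$critic, sc$pixels[1:8], sc$label[1:8])
  fs <- critic_score(ck$critic, fake$pixels, rep(0L, 8))
  expect_gt(mean(rs), mean(fs))

  # conditioning: label-0 and label-1 batches differ
  m0 <- Reduce(`+`, synthesize(ck, 0L, 6, seed = 3)$pixels) / 6
  m1 <- Reduce(`+`, synthesize(ck, 1L, 6, seed = 3)$pixels) / 6
  expect_gt(sqrt(mean((m0 - m1)^2)), 0)
})

test_that("training is reproducible from the seed", {
  sc <- fixture_tone_set()[seq(1, 64, by = 2), ]
  cfg <- gan_config(epochs = 1L, batch_size = 16L, image_size = 32L,
                    critic_steps_per_gen = 2L, seed = 13L)
  a <- train_cwgan(sc, cfg)
  b <- train_cwgan(sc, cfg)
  expect_identical(a$losses, b$losses)
  expect_identical(synthesize(a, 1L, 2, seed = 1)$pixels,
                   synthesize(b, 1L, 2, seed = 1)$pixels)
})

test_that("synthesis honors label, provenance and determinism contracts", {
  ck <- fixture_untrained_checkpoint(32L)
  s <- synthesize(ck, 0L, 10, seed = 4)
  expect_equal(nrow(s), 10)
  expect_true(all(s$provenance == "synthetic"))
  expect_true(all(s$label == 0L))
  expect_true(all(is.na(s$subject_id)))
  expect_true(all(vapply(s$pixels, function(p) all(dim(p) == c(32, 32)),
                         logical(1))))
  expect_true(all(unlist(s$pixels) >= 0 & unlist(s$pixels) <= 1))
  expect_identical(s$pixels, synthesize(ck, 0L, 10, seed = 4)$pixels)
  expect_error(synthesize(ck, 5L, 1), "invalid label")
})

test_that("augmentation arithmetic is exact and preserves provenance", {
  ck <- fixture_untrained_checkpoint(32L)
  real <- fixture_tone_set()

  aug <- augment_training_set(real, ck, "percent_increase", 75, seed = 5)
  expect_equal(nrow(aug), nrow(real) + round(0.75 * nrow(real)))
  expect_equal(sum(aug$provenance == "real"), nrow(real))

  aug0 <- augment_training_set(real, ck, "percent_increase", 0)
  expect_equal(nrow(aug0), nrow(real))

  unbal <- real[c(which(real$label == 0), which(real$label == 1)[1:16]), ]
  bal <- augment_training_set(unbal, ck, "balance_to_equal")
  expect_equal(sum(bal$label == 0), sum(bal$label == 1))
  expect_equal(nrow(bal), nrow(unbal) + 16)

  expect_error(augment_training_set(real, ck, "percent_increase", -5),
               "non-negative")
})

test_that("GAN training rejects held-out subjects and bad provenance", {
  sc <- fixture_tone_set()
  cfg <- gan_config(epochs = 1L, image_size = 32L)
  expect_error(train_cwgan(sc, cfg, test_subjects = c("T03", "T99")),
               "leakage.*T03")
  sc2 <- sc
  sc2$provenance[5] <- "synthetic"
  expect_error(train_cwgan(sc2, cfg), "provenance")
  expect_error(train_cwgan(sc[sc$label == 0, ], cfg), "label")
})
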