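frame_tbl <- function(hard, prob = NULL, truth = 1L, subject = "A",
                      window = 0L) {
  tibble::tibble(subject_id = subject, window_index = window,
                 frame_index = seq_along(hard) - 1L,
                 probability = prob %||% ifelse(hard == 1L, 0.9, 0.1),
                 hard_label = as.integer(hard), true_label = truth)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window voting agrees with brute-force majority counting", {
  expect_equal(vote_windows(frame_tbl(c(1, 1, 1, 0, 0)))$voted_label, 1L)
  expect_equal(vote_windows(frame_tbl(c(rep(0, 7), rep(1, 6))))$voted_label, 0L)
  # 6-6 tie broken by mean probability
  tie <- frame_tbl(rep(c(0L, 1L), 6), prob = rep(0.62, 12))
  expect_equal(vote_windows(tie)$voted_label, 1L)
  tie_low <- frame_tbl(rep(c(0L, 1L), 6), prob = rep(0.38, 12))
  expect_equal(vote_windows(tie_low)$voted_label, 0L)

  # exhaustive oracle over random vote patterns up to 13 frames
  withr::with_seed(11, {
    for (r in 1:200) {
      k <- sample(1:13, 1)
      hard <- sample(0:1, k, replace = TRUE)
      prob <- stats::runif(k)
      v <- vote_windows(frame_tbl(hard, prob))$voted_label
      n1 <- sum(hard); n0 <- k - n1
      oracle <- if (n1 > n0) 1L else if (n1 < n0) 0L
                else as.integer(mean(prob) >= 0.5)
      expect_identical(v, oracle)
    }
  })
  expect_error(vote_windows(frame_tbl(integer(0))), "no frame")
})

test_that("metrics match a brute-force formula oracle and the FAR/FRR identity", {
  # symmetric confusion: 8/2 per class -> all macro metrics 80
  wp <- tibble::tibble(
    subject_id = "A", window_index = 1:20,
    true_label = rep(c(0L, 1L), each = 10),
    voted_label = c(rep(0L, 8), rep(1L, 2), rep(1L, 8), rep(0L, 2)),
    votes_0 = 0L, votes_1 = 0L, mean_probability = 0.5)
  m <- compute_metrics(wp)
  expect_equal(m$precision, 80)
  expect_equal(m$recall, 80)
  expect_equal(m$far, 20)
  expect_equal(m$frr, 20)
  expect_equal(m$f1, 80)
  expect_equal(m$accuracy_windows, 80)

  # perfect predictions
  mp <- compute_metrics(dplyr::mutate(wp, voted_label = .data$true_label))
  expect_equal(mp$accuracy_windows, 100)
  expect_equal(mp$far, 0)
  expect_equal(mp$frr, 0)
  expect_equal(mp$f1, 100)

  # random confusion tables: identity holds exactly, values match oracle
  withr::with_seed(12, {
    for (r in 1:50) {
      n <- sample(10:60, 1)
      truth <- sample(0:1, n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      pred <- sample(0:1, n, replace = TRUE)
      wpr <- tibble::tibble(subject_id = "A", window_index = seq_len(n),
                            true_label = truth, voted_label = pred,
                            votes_0 = 0L, votes_1 = 0L,
                            mean_probability = 0.5)
      mr <- compute_metrics(wpr)
      expect_equal(mr$far + mr$precision, 100, tolerance = 1e-12)
      expect_equal(mr$frr + mr$recall, 100, tolerance = 1e-12)
      # brute-force per-class oracle
      pr <- rr <- ff <- numeric(2)
      for (cl in 0:1) {
        tp <- sum(pred == cl & truth == cl)
        fp <- sum(pred == cl & truth != cl)
        fn <- sum(pred != cl & truth == cl)
        pr[cl + 1] <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
        rr[cl + 1] <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
        ff[cl + 1] <- if (pr[cl + 1] + rr[cl + 1] == 0) 0
                      else 2 * pr[cl + 1] * rr[cl + 1] / (pr[cl + 1] + rr[cl + 1])
      }
      expect_equal(mr$precision, mean(pr))
      expect_equal(mr$recall, mean(rr))
      expect_equal(mr$f1, mean(ff))
      expect_equal(mr$accuracy_windows, 100 * mean(pred == truth))
    }
  })

  expect_error(compute_metrics(dplyr::mutate(wp, true_label = 0L)),
               "undefined rates")
})

test_that("Welch test matches the textbook formulas to 1e-10", {
  a <- c(0.70, 0.72, 0.74); b <- c(0.80, 0.82, 0.84)
  w <- welch_test(a, b)
  va <- stats::var(a) / 3; vb <- stats::var(b) / 3
  t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_ref <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
  expect_equal(w$t_statistic, t_ref, tolerance = 1e-10)
  expect_equal(w$degrees_of_freedom, df_ref, tolerance = 1e-10)
  expect_equal(w$p_value, p_ref, tolerance = 1e-10)
  expect_true(w$ci95_low < w$mean_difference &&
                w$mean_difference < w$ci95_high)

  withr::with_seed(13, {
    for (r in 1:25) {
      na <- sample(3:12, 1); nb <- sample(3:12, 1)
      x <- stats::rnorm(na); y <- stats::rnorm(nb, 0.3, 1.4)
      w2 <- welch_test(x, y)
      vx <- stats::var(x) / na; vy <- stats::var(y) / nb
      t2 <- (mean(x) - mean(y)) / sqrt(vx + vy)
      df2 <- (vx + vy)^2 / (vx^2 / (na - 1) + vy^2 / (nb - 1))
      expect_equal(w2$t_statistic, t2, tolerance = 1e-10)
      expect_equal(w2$degrees_of_freedom, df2, tolerance = 1e-10)
      expect_equal(w2$p_value, 2 * stats::pt(-abs(t2), df2), tolerance = 1e-10)
    }
  })

  ident <- c(0.1, 0.2, 0.3)
  wi <- welch_test(ident, ident)
  expect_equal(wi$t_statistic, 0)
  expect_equal(wi$p_value, 1)
  expect_error(welch_test(1, c(1, 2)), "at least two")
})

test_that("subject splits are stratified, seeded and disjoint", {
  subjects <- tibble::tibble(subject_id = sprintf("S%02d", 1:30),
                             label = rep(c(0L, 1L), c(14, 16)))
  sp <- subject_split(subjects, n_test = 6, stratify = "label", seed = 3)
  expect_length(sp$test_subjects, 6)
  labs <- subjects$label[match(sp$test_subjects, subjects$subject_id)]
  expect_equal(sum(labs == 0), 3)
  expect_equal(sum(labs == 1), 3)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$test_subjects),
                  subjects$subject_id)
  sp2 <- subject_split(subjects, n_test = 6, stratify = "label", seed = 3)
  expect_identical(sp$test_subjects, sp2$test_subjects)

  small <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                          label = rep(c(0L, 1L), c(4, 2)))
  expect_error(subject_split(small, n_test = 8, stratify = "label"),
               "fewer subjects")
})

test_that("temporal aggregation enumerates qualifying runs and bins them", {
  # always-correct predictor over two subjects, two windows each
  fp <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 26),
    window_index = rep(rep(0:1, each = 13), 2),
    frame_index = rep(0:12, 4),
    probability = 0.9, hard_label = 1L, true_label = 1L)
  ag <- temporal_aggregation(fp)
  expect_true(all(ag$per_subject$accuracy == 1))
  expect_equal(ag$cohort$fraction_confident[1], 1)
  expect_true(all(diff(ag$cohort$fraction_confident) >= 0))
  # shortest qualifying in-window run: 7 frames span 4 + 0.5*6 = 7 s
  expect_equal(min(ag$per_subject$duration_bin), 7)

  expect_error(temporal_aggregation(fp, min_span_s = 1000), "minimum span")
})

test_that("13-frame voting follows the binomial law for iid frame accuracy", {
  p <- 0.7
  closed <- sum(vapply(7:13, function(i) {
    choose(13, i) * p^i * (1 - p)^(13 - i)
  }, numeric(1)))
  withr::with_seed(14, {
    n_win <- 10000
    correct <- vapply(seq_len(n_win), function(w) {
      frames_ok <- stats::rbinom(13, 1, p)
      sum(frames_ok) >= 7
    }, logical(1))
  })
  mc_se <- sqrt(closed * (1 - closed) / 10000)
  expect_lt(abs(mean(correct) - closed), 4 * mc_se)
  expect_gte(closed, p)  # voting amplifies above-chance frame accuracy

  # the same law through the voting implementation itself
  withr::with_seed(15, {
    acc <- vapply(1:2000, function(w) {
      ok <- stats::rbinom(13, 1, p)
      truth <- 1L
      hard <- ifelse(ok == 1L, truth, 1L - truth)
      v <- vote_windows(frame_tbl(hard, prob = ifelse(hard == 1, .8, .2)))
      v$voted_label == truth
    }, logical(1))
  })
  expect_lt(abs(mean(acc) - closed), 4 * sqrt(closed * (1 - closed) / 2000))
})

test_that("Grad-CAM maps are normalized, sized and match an analytic oracle", {
  sc <- fixture_tone_set()
  fit <- fixture_tone_fit()
  gc <- grad_cam(fit, sc[c(1:4, 61:64), ], stage = 3)
  for (m in gc$maps) {
    if (is.null(m)) next
    expect_equal(dim(m), c(32, 32))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_equal(sum(gc$n_instances), 8L)  # separable fixture: all correct

  # hand-built network: 1-channel target stage, score = sum of activation
  spec <- cnn_spec(image_size = 12, in_channels = 1, kernels = 3,
                   channels = 1, pools = 1, fc = 1, dropout = 0)
  model <- withr::with_seed(16, build_cnn(spec))
  model$layers[[2]]$params$gamma <- 1
  model$layers[[2]]$params$beta <- 0
  model$layers[[2]]$buffers$run_mean <- 0
  model$layers[[2]]$buffers$run_var <- 1 - model$layers[[2]]$eps
  L <- length(model$layers)
  model$layers[[L]]$params$W <- matrix(1, 1, 100)
  model$layers[[L]]$params$b <- 0
  ofit <- structure(list(model = model, spec = spec), class = "cnn_fit")
  withr::with_seed(17, x <- matrix(stats::runif(144), 12, 12))
  scx <- tibble::tibble(subject_id = "A", window_index = 0L, frame_index = 0L,
                        provenance = "real", label = 1L, pixels = list(x))
  gc2 <- NULL
  expect_warning(gc2 <- grad_cam(ofit, scx, stage = 1), "class 0")
  a <- array(x, c(12, 12, 1, 1))
  for (l in 1:3) a <- radarleak:::layer_forward(model$layers[[l]], a,
                                                NULL, FALSE)$out
  up <- radarleak:::bilinear_mat(10, 12) %*% a[, , 1, 1] %*%
    t(radarleak:::bilinear_mat(10, 12))
  expect_equal(gc2$maps[["1"]], up / max(up), tolerance = 1e-10)
})
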