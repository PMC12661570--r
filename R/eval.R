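#' Subject-wise train/test split
#'
#' Splits at the subject level so no individual contributes to both sides,
#' optionally stratified on a label column with an equal number of test
#' subjects per stratum (the protocol behind a 3 + 3 test set drawn from a
#' 14/16 cohort).
#'
#' @param subjects tibble with a `subject_id` column plus label columns.
#' @param n_test total number of test subjects.
#' @param stratify optional column name to stratify on (test subjects split
#'   evenly across its classes).
#' @param seed integer seed.
#' @return list of class `split_plan`: `train_subjects`, `test_subjects`,
#'   `stratify`, `seed`.
#' @export
subject_split <- function(subjects, n_test, stratify = NULL, seed = 1L) {
  subjects <- dplyr::distinct(subjects, dplyr::across(dplyr::all_of(
    c("subject_id", stratify))))
  test <- with_seed(seed, {
    if (is.null(stratify)) {
      sample(subjects$subject_id, n_test)
    } else {
      strata <- split(subjects$subject_id, subjects[[stratify]])
      per <- n_test / length(strata)
      assert_that(per == round(per),
                  "n_test must divide evenly across the strata")
      bad <- names(strata)[vapply(strata, length, integer(1)) < per]
      if (length(bad) > 0)
        stop("stratum ", paste(bad, collapse = ", "),
             " has fewer subjects than requested", call. = FALSE)
      unlist(lapply(strata, sample, size = per), use.names = FALSE)
    }
  })
  structure(list(train_subjects = setdiff(subjects$subject_id, test),
                 test_subjects = test, stratify = stratify, seed = seed),
            class = "split_plan")
}

#' Aggregate frame predictions into window decisions by hard voting
#'
#' Majority vote over the thresholded frame labels of each window; a tie is
#' broken by the mean predicted probability (>= 0.5 votes class 1).
#'
#' @param frame_preds tibble from [predict_frames()].
#' @return tibble with one row per (subject, window): `voted_label`,
#'   `votes_0`, `votes_1`, `mean_probability`, `true_label`.
#' @export
vote_windows <- function(frame_preds) {
  assert_that(nrow(frame_preds) > 0, "no frame predictions to vote on")
  frame_preds |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", "window_index")))) |>
    dplyr::summarise(
      votes_0 = sum(.data$hard_label == 0L),
      votes_1 = sum(.data$hard_label == 1L),
      mean_probability = mean(.data$probability),
      true_label = .data$true_label[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(voted_label = dplyr::case_when(
      .data$votes_1 > .data$votes_0 ~ 1L,
      .data$votes_1 < .data$votes_0 ~ 0L,
      .default = as.integer(.data$mean_probability >= 0.5)
    ))
}

#' Window- and frame-level classification metrics
#'
#' Per-class precision, recall and F1 are macro-averaged over the two
#' classes; F1 is the macro average of the per-class F1 values (not the
#' harmonic mean of the macro precision/recall). The error rates follow the
#' convention that the printed result tables of this analysis satisfy
#' exactly: FAR = 100 - macro precision (a macro false-discovery rate) and
#' FRR = 100 - macro recall (a macro miss rate). All values are percentages.
#'
#' @param window_preds tibble from [vote_windows()].
#' @param frame_preds tibble from [predict_frames()] (for frame accuracy).
#' @return list of class `leak_metrics` with `accuracy_windows`,
#'   `accuracy_frames`, `far`, `frr`, `precision`, `recall`, `f1` and the
#'   per-class `confusion` tibble.
#' @export
compute_metrics <- function(window_preds, frame_preds = NULL) {
  truth <- window_preds$true_label
  pred <- window_preds$voted_label
  if (length(unique(truth)) < 2)
    stop("undefined rates: a true class is absent from the evaluation set",
         call. = FALSE)
  per_class <- purrr::map(c(0L, 1L), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1)
  }) |> dplyr::bind_rows()
  precision <- mean(per_class$precision)
  recall <- mean(per_class$recall)
  structure(list(
    accuracy_windows = 100 * mean(pred == truth),
    accuracy_frames = if (is.null(frame_preds)) NA_real_
                      else 100 * mean(frame_preds$hard_label == frame_preds$true_label),
    far = 100 - precision,
    frr = 100 - recall,
    precision = precision,
    recall = recall,
    f1 = mean(per_class$f1),
    confusion = per_class
  ), class = "leak_metrics")
}

#' @export
print.leak_metrics <- function(x, ...) {
  cat(sprintf(paste0("<leak_metrics> windows %.2f%% | frames %s | FAR %.2f | ",
                     "FRR %.2f | P %.2f | R %.2f | F1 %.2f\n"),
              x$accuracy_windows,
              ifelse(is.na(x$accuracy_frames), "-",
                     sprintf("%.2f%%", x$accuracy_frames)),
              x$far, x$frr, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Welch's two-sample t-test on repeated-run accuracies
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' two-sided p-value, and the 95% confidence interval of the difference in
#' means.
#'
#' @param acc_a,acc_b numeric vectors of per-run accuracies (length >= 2,
#'   non-zero variance).
#' @return list of class `welch_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `ci95_low`, `ci95_high`,
#'   `mean_difference`.
#' @export
welch_test <- function(acc_a, acc_b) {
  assert_that(length(acc_a) >= 2 && length(acc_b) >= 2,
              "each condition needs at least two runs")
  assert_that(stats::sd(acc_a) > 0 || stats::sd(acc_b) > 0,
              "zero variance in both conditions")
  ht <- stats::t.test(acc_a, acc_b, var.equal = FALSE, conf.level = 0.95)
  structure(list(t_statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = ht$p.value,
                 ci95_low = ht$conf.int[1], ci95_high = ht$conf.int[2],
                 mean_difference = mean(acc_a) - mean(acc_b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.2f, p = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Temporal-aggregation threat curves
#'
#' Enumerates every contiguous run of frame predictions per subject (frames
#' ordered by window and in-window offset; runs may cross window
#' boundaries), keeps runs spanning at least `min_span_s` seconds (a run of
#' k in-window frames spans `frame_s + stride_s * (k - 1)` seconds),
#' majority-votes each run, bins runs by duration, and reports per-subject
#' mean accuracy per bin plus the cohort curve: the cumulative fraction of
#' subjects whose accuracy has reached at least 95% at or before each
#' duration.
#'
#' @param frame_preds tibble from [predict_frames()] (one subject may span
#'   several windows).
#' @param min_span_s minimum run duration in seconds.
#' @param bin_s bin width in seconds.
#' @param frame_s,stride_s framing geometry used to produce the frames.
#' @param window_s analysis window length (start-time bookkeeping across
#'   window boundaries).
#' @return list of class `aggregation_curve`: `per_subject` tibble
#'   (`subject_id`, `duration_bin`, `accuracy`, `n_runs`) and `cohort`
#'   tibble (`duration_bin`, `fraction_confident`).
#' @export
temporal_aggregation <- function(frame_preds, min_span_s = 7, bin_s = 1,
                                 frame_s = 4, stride_s = 0.5, window_s = 10) {
  per_subject <- frame_preds |>
    dplyr::group_by(dplyr::across(dplyr::all_of("subject_id"))) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$window_index, .data$frame_index)
      start <- df$window_index * window_s + df$frame_index * stride_s
      hard <- df$hard_label
      prob <- df$probability
      truth <- df$true_label[1]
      Fn <- nrow(df)
      cs_hard <- cumsum(hard); cs_prob <- cumsum(prob)
      rows <- list()
      for (s in seq_len(Fn)) {
        for (e in s:Fn) {
          dur <- (start[e] + frame_s) - start[s]
          if (dur < min_span_s) next
          k <- e - s + 1
          ones <- cs_hard[e] - if (s > 1) cs_hard[s - 1] else 0
          mp <- (cs_prob[e] - if (s > 1) cs_prob[s - 1] else 0) / k
          vote <- if (2 * ones > k) 1L else if (2 * ones < k) 0L
                  else as.integer(mp >= 0.5)
          rows[[length(rows) + 1L]] <- c(dur, as.integer(vote == truth))
        }
      }
      if (length(rows) == 0) return(NULL)
      m <- do.call(rbind, rows)
      tibble::tibble(subject_id = key$subject_id,
                     duration = m[, 1], correct = m[, 2])
    }) |> dplyr::bind_rows()
  if (nrow(per_subject) == 0)
    stop("no contiguous run reaches the minimum span of ", min_span_s, " s",
         call. = FALSE)
  per_subject <- per_subject |>
    dplyr::mutate(duration_bin = floor(.data$duration / bin_s) * bin_s) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", "duration_bin")))) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     n_runs = dplyr::n(), .groups = "drop")
  bins <- sort(unique(per_subject$duration_bin))
  first_conf <- per_subject |>
    dplyr::filter(.data$accuracy >= 0.95) |>
    dplyr::group_by(dplyr::across(dplyr::all_of("subject_id"))) |>
    dplyr::summarise(first_bin = min(.data$duration_bin), .groups = "drop")
  n_sub <- dplyr::n_distinct(per_subject$subject_id)
  cohort <- tibble::tibble(
    duration_bin = bins,
    fraction_confident = vapply(bins, function(b) {
      sum(first_conf$first_bin <= b) / n_sub
    }, numeric(1))
  )
  structure(list(per_subject = per_subject, cohort = cohort,
                 min_span_s = min_span_s, bin_s = bin_s),
            class = "aggregation_curve")
}

#' Grad-CAM class-evidence maps
#'
#' Gradient-weighted class activation mapping at a chosen convolution stage
#' (default the fourth): per instance, channel weights are the spatial means
#' of the gradient of the class score with respect to the stage's ReLU
#' activations; the map is the rectified weighted activation sum, bilinearly
#' upsampled to the input size and normalized to [0, 1]. Maps are averaged
#' per class over correctly classified instances only. The class score is
#' the logit for class 1 and its negative for class 0.
#'
#' @param fit a `cnn_fit`.
#' @param scalograms tibble with `pixels` and `label`.
#' @param stage convolution stage to inspect (1-based).
#' @return list of class `grad_cam_map`: per-class `maps` (list of matrices
#'   in [0, 1], or NULL when no correctly classified instance exists) and
#'   `n_instances`.
#' @export
grad_cam <- function(fit, scalograms, stage = 4L) {
  model <- fit$model
  n_stages <- sum(vapply(model$layers, function(l) l$type == "conv", logical(1)))
  assert_that(stage >= 1 && stage <= n_stages, "no such convolution stage")
  target <- cnn_stage_relu_index(model, stage)
  size <- fit$spec$image_size
  acc <- list(`0` = NULL, `1` = NULL)
  counts <- c(`0` = 0L, `1` = 0L)
  for (k in seq_len(nrow(scalograms))) {
    x <- pixels_to_batch(scalograms$pixels[k], fit$spec$in_channels)
    # forward, capturing the target activation
    caches <- vector("list", length(model$layers))
    a <- x; target_act <- NULL
    for (l in seq_along(model$layers)) {
      r <- layer_forward(model$layers[[l]], a, NULL, FALSE)
      caches[[l]] <- r$cache
      a <- r$out
      if (l == target) target_act <- a
    }
    z <- as.numeric(a)
    pred <- as.integer(1 / (1 + exp(-z)) >= 0.5)
    truth <- scalograms$label[k]
    if (pred != truth) next
    sign <- if (truth == 1L) 1 else -1
    bwd <- net_backward(model, caches, matrix(sign, 1, 1),
                        record_deltas = TRUE)
    grad_act <- bwd$deltas_out[[target]]
    w <- apply(grad_act[, , , 1, drop = FALSE], 3, mean)
    A <- target_act[, , , 1]
    if (length(dim(A)) == 2) A <- array(A, dim = c(dim(A), 1))
    cam <- matrix(0, dim(A)[1], dim(A)[2])
    for (c in seq_along(w)) cam <- cam + w[c] * A[, , c]
    cam[cam < 0] <- 0
    Mh <- bilinear_mat(nrow(cam), size); Mw <- bilinear_mat(ncol(cam), size)
    cam <- Mh %*% cam %*% t(Mw)
    if (max(cam) > 0) cam <- cam / max(cam)
    key <- as.character(truth)
    acc[[key]] <- if (is.null(acc[[key]])) cam else acc[[key]] + cam
    counts[key] <- counts[key] + 1L
  }
  maps <- purrr::imap(acc, function(m, key) {
    if (is.null(m)) {
      warning("no correctly classified instance for class ", key,
              "; empty map", call. = FALSE)
      return(NULL)
    }
    m <- m / counts[[key]]
    if (max(m) > 0) m / max(m) else m
  })
  structure(list(maps = maps, n_instances = counts, stage = stage),
            class = "grad_cam_map")
}

#' Run a full augmentation experiment on a scalogram set
#'
#' For each augmentation amount and repetition: subject-wise split, optional
#' conditional-GAN training on the training subjects, augmentation,
#' classifier training, prediction, voting and metrics. Optionally compares
#' two amounts with a Welch test over the repetition accuracies.
#'
#' @param scalograms real-scalogram tibble from [compute_scalograms()].
#' @param task `"sex"` or `"age_group"`; selects the label column.
#' @param amounts numeric vector of percent increases (0 = no augmentation).
#' @param repetitions runs per amount (each with its own split/seed).
#' @param n_test test subjects per split.
#' @param spec classifier [cnn_spec()].
#' @param config [classifier_config()].
#' @param gan [gan_config()] used when any amount > 0.
#' @param welch_pair optional length-2 amounts to compare with [welch_test()].
#' @param seed master seed.
#' @return list of class `leak_experiment`: `report` tibble (one row per
#'   amount x repetition with all metric columns), `welch` (or NULL), and
#'   the per-run `details`.
#' @export
run_experiment <- function(scalograms, task = c("sex", "age_group"),
                           amounts = c(0, 75), repetitions = 2L,
                           n_test = 2L, spec = cnn_spec_small(),
                           config = classifier_config(epochs = 6L),
                           gan = gan_config(epochs = 2L, image_size = spec$image_size,
                                            critic_steps_per_gen = 2L),
                           welch_pair = NULL, seed = 1L) {
  task <- match.arg(task)
  label_col <- paste0(task, "_label")
  scalograms <- dplyr::mutate(scalograms,
                              label = as.integer(scalograms[[label_col]]))
  seeds <- derive_seeds(seed, repetitions * (length(amounts) + 2L))
  si <- 0L
  rows <- list(); details <- list()
  for (rep in seq_len(repetitions)) {
    si <- si + 1L
    split <- subject_split(
      dplyr::distinct(scalograms[scalograms$provenance == "real", ],
                      dplyr::across(dplyr::all_of(c("subject_id", "label")))),
      n_test = n_test, stratify = "label", seed = seeds[si])
    train_set <- scalograms[scalograms$subject_id %in% split$train_subjects, ]
    test_set <- scalograms[scalograms$subject_id %in% split$test_subjects, ]
    checkpoint <- NULL
    if (any(amounts > 0)) {
      gan$seed <- seeds[si]
      checkpoint <- train_cwgan(train_set, gan,
                                test_subjects = split$test_subjects)
    }
    for (amount in amounts) {
      si <- si + 1L
      aug <- if (amount > 0)
        augment_training_set(train_set, checkpoint, "percent_increase",
                             amount, seed = seeds[si])
      else train_set
      cfg <- config; cfg$seed <- seeds[si]
      fit <- train_classifier(aug, cfg, spec,
                              test_subjects = split$test_subjects)
      fp <- predict_frames(fit, test_set)
      wp <- vote_windows(fp)
      met <- compute_metrics(wp, fp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        task = task, amount = amount, repetition = rep,
        n_train_scalograms = nrow(aug),
        accuracy_windows = met$accuracy_windows,
        accuracy_frames = met$accuracy_frames,
        far = met$far, frr = met$frr, precision = met$precision,
        recall = met$recall, f1 = met$f1)
      details[[length(details) + 1L]] <-
        list(amount = amount, repetition = rep, split = split,
             metrics = met, fit_loss = fit$loss_history)
    }
  }
  report <- dplyr::bind_rows(rows)
  welch <- NULL
  if (!is.null(welch_pair)) {
    a <- report$accuracy_windows[report$amount == welch_pair[1]]
    b <- report$accuracy_windows[report$amount == welch_pair[2]]
    welch <- welch_test(a / 100, b / 100)
  }
  structure(list(report = report, welch = welch, details = details,
                 task = task),
            class = "leak_experiment")
}
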