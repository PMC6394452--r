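#' Equalise exemplar counts across conditions
#'
#' Subsamples every condition uniformly (without replacement) down to the
#' smallest condition's exemplar count — the conservative balancing applied
#' before classification so that theoretical chance is exact.
#'
#' @param patterns list of exemplar matrices (exemplars x features), one per
#'   condition.
#' @param seed integer seed driving the subsampling.
#' @return list of matrices, all with `min(n)` rows.
#' @export
balance_trials <- function(patterns, seed = 1) {
  n <- vapply(patterns, nrow, 0L)
  if (any(n == 0)) stop("a condition has no exemplars", call. = FALSE)
  nmin <- min(n)
  set.seed(seed)
  lapply(patterns, function(x) {
    if (nrow(x) == nmin) x else x[sort(sample.int(nrow(x), nmin)), , drop = FALSE]
  })
}

#' Average exemplars within each run (block averaging)
#'
#' Replaces the single trials of every run-by-condition cell with their
#' arithmetic mean, yielding one higher signal-to-noise exemplar per run
#' per condition.
#'
#' @param patterns_by_run list (runs) of exemplar matrices for one condition.
#' @return matrix with one row per run.
#' @export
block_average <- function(patterns_by_run) {
  rows <- lapply(patterns_by_run, function(x) {
    if (is.null(x) || nrow(x) == 0) stop("a run has no trials to average", call. = FALSE)
    colMeans(x)
  })
  do.call(rbind, rows)
}

#' Pool exemplars across runs
#'
#' Concatenates the trials of all runs for one condition, recording run
#' provenance.
#'
#' @param patterns_by_run list (runs) of exemplar matrices for one condition.
#' @return list with `x` (pooled matrix, run order) and `run` (provenance).
#' @export
pool_blocks <- function(patterns_by_run) {
  x <- do.call(rbind, patterns_by_run)
  run <- rep(seq_along(patterns_by_run), vapply(patterns_by_run, nrow, 0L))
  list(x = x, run = run)
}

#' Assign exemplars to cross-validation sets
#'
#' Randomly partitions `n` exemplars into `k` sets of exactly
#' `floor(n / k)` exemplars; the `n %% k` left-over exemplars are excluded
#' for this cross-validation cycle so that no set is larger than another.
#'
#' @param n number of exemplars (per condition).
#' @param k number of cross-validation sets.
#' @param seed integer seed.
#' @return list with `sets` (list of k index vectors) and `excluded`.
#' @export
assign_cv_sets <- function(n, k, seed = 1) {
  if (n < k)
    stop(sprintf("%d exemplars cannot fill %d cross-validation sets; choose a smaller k", n, k),
         call. = FALSE)
  per <- n %/% k
  set.seed(seed)
  ord <- sample.int(n)
  sets <- lapply(seq_len(k), function(j) sort(ord[((j - 1L) * per + 1L):(j * per)]))
  list(sets = sets, excluded = sort(ord[seq_len(n %% k) + k * per]))
}

#' Train a linear decoder on one fold and score the held-out data
#'
#' Classification: fits a linear C-SVM on the training exemplars and returns
#' the percentage of test exemplars assigned their true label. Regression:
#' fits linear epsilon-SVR and returns the Fisher-Z transformed Pearson
#' correlation between predicted and true labels. Also returns the fitted
#' primal weight vector of the linear model.
#'
#' @param train_x,train_y training exemplars and labels.
#' @param test_x,test_y test exemplars and labels.
#' @param analysis `"classification"` or `"regression"`.
#' @param cost C parameter (defaults: 1 for classification, 0.1 for
#'   regression).
#' @param epsilon SVR tube width.
#' @param zscore_features if `TRUE`, each feature is z-scored with training
#'   statistics (applied unchanged to the test set) before fitting.
#' @return list with `score` (percent correct, or Fisher-Z), `w` (weights,
#'   a matrix with one column per class pair for multi-class), `b`, and
#'   `degenerate` (`TRUE` when a regression correlation was undefined and
#'   the score was recorded as 0).
#' @export
train_and_test <- function(train_x, train_y, test_x, test_y,
                           analysis = c("classification", "regression"),
                           cost = NULL, epsilon = 0.1, zscore_features = FALSE) {
  analysis <- match.arg(analysis)
  stopifnot(ncol(train_x) == ncol(test_x))
  if (zscore_features) {
    mu <- colMeans(train_x)
    sg <- apply(train_x, 2, stats::sd)
    sg[sg == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sg, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sg, "/")
  }
  if (analysis == "classification") {
    cost <- cost %||% 1
    fit <- linear_svm(train_x, train_y, cost = cost)
    pred <- predict(fit, test_x)
    list(score = 100 * mean(pred == test_y),
         w = fit$w, b = fit$b, degenerate = FALSE)
  } else {
    cost <- cost %||% 0.1
    fit <- linear_svr(train_x, train_y, cost = cost, epsilon = epsilon)
    pred <- predict(fit, test_x)
    degen <- stats::sd(pred) == 0 || stats::sd(test_y) == 0
    score <- if (degen) 0 else fisher_z(stats::cor(pred, test_y))
    if (degen) warning("constant predictions or labels; Fisher-Z recorded as 0", call. = FALSE)
    list(score = score, w = matrix(fit$w, ncol = 1), b = fit$b, degenerate = degen)
  }
}

# Assemble, per analysis window, the exemplar matrices per condition:
# pooled single trials or block averages, plus regression labels.
step_patterns <- function(dataset, start, width, mode, channel, average_by_block) {
  nc <- n_conditions(dataset); nr <- n_runs(dataset)
  out <- vector("list", nc)
  for (ck in seq_len(nc)) {
    per_run <- lapply(seq_len(nr), function(r)
      extract_patterns(dataset$data[[r, ck]], start, width, mode, channel))
    if (average_by_block) {
      out[[ck]] <- list(x = block_average(per_run), run = seq_len(nr), labels = NULL)
    } else {
      p <- pool_blocks(per_run)
      labels <- NULL
      if (!is.null(dataset$svr_labels))
        labels <- unlist(lapply(seq_len(nr), function(r) dataset$svr_labels[[r, ck]]))
      out[[ck]] <- list(x = p$x, run = p$run, labels = labels)
    }
  }
  out
}

#' Sliding-window multivariate decoding of an epoched EEG dataset
#'
#' The central fitting function. For every analysis time window it runs
#' `m` independent repetitions of `k`-fold cross-validated linear decoding
#' (classification between the dataset's conditions, or support vector
#' regression of per-trial labels within one condition), averaging the
#' `m * k` per-analysis scores into one performance value per window.
#' Optionally the identical procedure is repeated with condition labels
#' independently re-shuffled in every repetition, yielding the empirical
#' chance distribution. Feature weights of the linear models are stored,
#' Haufe-corrected, and reduced to one absolute z-standardised value per
#' channel per window.
#'
#' @param dataset an [epoched_dataset()].
#' @param conditions condition indices forming the discrimination group
#'   (default: all; exactly one for regression).
#' @param analysis `"classification"` or `"regression"`.
#' @param mode `"spatial"`, `"temporal"` or `"spatiotemporal"` feature
#'   extraction (see [extract_patterns()]).
#' @param window_width_ms,step_ms analysis window width and step in ms;
#'   must be whole numbers of samples at the dataset's sampling rate.
#' @param channel channel index, required for temporal mode.
#' @param k number of cross-validation sets (default 10).
#' @param m number of independent repetitions of the cross-validation
#'   cycle (default 10; `k = m = 10` gives the standard 100 analyses).
#' @param cost SVM cost C (defaults 1 / 0.1 for classification/regression).
#' @param epsilon SVR tube width.
#' @param average_by_block use run averages instead of single trials as
#'   exemplars.
#' @param permute_labels also run the permuted-label (empirical chance)
#'   analyses.
#' @param zscore_features z-score features with training statistics.
#' @param seed master seed; all child seeds are derived deterministically
#'   per (window, repetition, purpose).
#' @param store_weights keep feature-weight maps (default `TRUE`).
#' @return an object of class `erp_decoding`; see [summary.erp_decoding()].
#' @examples
#' noise <- simulate_noise_dataset(synthetic_spec(n_timepoints = 30, n_channels = 8,
#'                                                n_epochs = 40, rng_seed = 1))
#' signal <- simulate_signal_dataset(synthetic_spec(n_timepoints = 30, n_channels = 8,
#'                                                  n_epochs = 40, signal_value = 1,
#'                                                  signal_channels = 1:4,
#'                                                  signal_timepoints = 16:30, rng_seed = 2))
#' d <- combine_conditions(noise, signal)
#' fit <- decode_erp(d, window_width_ms = 10, step_ms = 10, k = 4, m = 2, seed = 7)
#' fit$accuracy
#' @export
decode_erp <- function(dataset,
                       conditions = seq_len(n_conditions(dataset)),
                       analysis = c("classification", "regression"),
                       mode = c("spatial", "temporal", "spatiotemporal"),
                       window_width_ms = 10, step_ms = 10, channel = NULL,
                       k = 10, m = 10, cost = NULL, epsilon = 0.1,
                       average_by_block = FALSE, permute_labels = FALSE,
                       zscore_features = FALSE, seed = 1, store_weights = TRUE) {
  analysis <- match.arg(analysis)
  mode <- match.arg(mode)
  validate_epoched_dataset(dataset)
  stopifnot(k >= 2, m >= 1)
  dataset <- reduce_conditions(dataset, conditions)
  nc <- n_conditions(dataset)
  if (analysis == "classification" && nc < 2)
    stop("classification needs at least two conditions", call. = FALSE)
  if (analysis == "regression") {
    if (nc != 1) stop("regression uses exactly one condition", call. = FALSE)
    if (is.null(dataset$svr_labels))
      stop("regression requires per-trial labels (svr_labels)", call. = FALSE)
  }
  width <- ms_to_samples(window_width_ms, dataset$sampling_rate_hz, "window width")
  step <- ms_to_samples(step_ms, dataset$sampling_rate_hz, "step size")
  plan <- window_plan(n_timepoints(dataset), width, step)
  nch <- n_channels(dataset)
  layout <- feature_layout(mode, nch, width, channel)
  d <- length(layout$channel)

  per_analysis <- array(NA_real_, c(plan$n_steps, m, k))
  perm_analysis <- if (permute_labels) array(NA_real_, c(plan$n_steps, m, k))
  w_raw <- if (store_weights) matrix(0, plan$n_steps, d)
  w_cor <- if (store_weights) matrix(0, plan$n_steps, d)
  degenerate <- FALSE

  for (s in seq_len(plan$n_steps)) {
    pats <- step_patterns(dataset, plan$starts[s], width, mode, channel, average_by_block)
    nw <- 0L
    for (rep_i in seq_len(m)) {
      # per-repetition re-draw of the balancing subsample, then of the k sets
      bal <- balance_trials(lapply(pats, `[[`, "x"),
                            seed = derive_seed(seed, s, rep_i, 1L))
      nb <- nrow(bal[[1]])
      asg <- lapply(seq_len(nc), function(ck)
        assign_cv_sets(nb, k, seed = derive_seed(seed, s, rep_i, 2L, ck)))
      if (analysis == "regression") {
        bal_lab <- pats[[1]]$labels
        if (nb < length(bal_lab)) {
          # balancing never drops for a single condition, but keep it safe
          bal_lab <- bal_lab[seq_len(nb)]
        }
      }
      perm_y <- NULL
      for (fold in seq_len(k)) {
        train_list <- list(); test_list <- list()
        train_y <- c(); test_y <- c()
        for (ck in seq_len(nc)) {
          te <- asg[[ck]]$sets[[fold]]
          tr <- unlist(asg[[ck]]$sets[-fold])
          train_list[[ck]] <- bal[[ck]][tr, , drop = FALSE]
          test_list[[ck]] <- bal[[ck]][te, , drop = FALSE]
          if (analysis == "classification") {
            train_y <- c(train_y, rep(ck, length(tr)))
            test_y <- c(test_y, rep(ck, length(te)))
          } else {
            train_y <- c(train_y, bal_lab[tr])
            test_y <- c(test_y, bal_lab[te])
          }
        }
        train_x <- do.call(rbind, train_list)
        test_x <- do.call(rbind, test_list)
        res <- train_and_test(train_x, train_y, test_x, test_y, analysis,
                              cost = cost, epsilon = epsilon,
                              zscore_features = zscore_features)
        per_analysis[s, rep_i, fold] <- res$score
        degenerate <- degenerate || isTRUE(res$degenerate)
        if (store_weights) {
          wf <- rowMeans(res$w)    # binary / svr: one column; multi-class: pair mean
          w_raw[s, ] <- w_raw[s, ] + wf
          w_cor[s, ] <- w_cor[s, ] + haufe_correct(wf, train_x)
          nw <- nw + 1L
        }
        if (!is.null(perm_analysis)) {
          if (is.null(perm_y)) {
            # labels independently re-shuffled per repetition on the same
            # data with the identical set assignment. The shuffle preserves
            # class balance within every cross-validation set (equivalent in
            # distribution to re-sorting exemplars by shuffled label): an
            # unstratified shuffle would leave the permuted folds
            # imbalanced, biasing permuted accuracy below chance while the
            # real analyses use balanced folds.
            set.seed(derive_seed(seed, s, rep_i, 3L))
            if (analysis == "classification") {
              per <- length(asg[[1]]$sets[[1]])
              perm_y <- lapply(seq_len(k), function(j)
                matrix(sample(rep(seq_len(nc), per)), per, nc))
            } else {
              perm_y <- sample(bal_lab)
            }
          }
          ptrain_y <- c(); ptest_y <- c()
          for (ck in seq_len(nc)) {
            if (analysis == "classification") {
              ptest_y <- c(ptest_y, perm_y[[fold]][, ck])
              ptrain_y <- c(ptrain_y,
                            unlist(lapply(setdiff(seq_len(k), fold),
                                          function(j) perm_y[[j]][, ck])))
            } else {
              ptest_y <- c(ptest_y, perm_y[asg[[ck]]$sets[[fold]]])
              ptrain_y <- c(ptrain_y, perm_y[unlist(asg[[ck]]$sets[-fold])])
            }
          }
          perm_analysis[s, rep_i, fold] <-
            train_and_test(train_x, ptrain_y, test_x, ptest_y, analysis,
                           cost = cost, epsilon = epsilon,
                           zscore_features = zscore_features)$score
        }
      }
    }
    if (store_weights && nw > 0) {
      w_raw[s, ] <- w_raw[s, ] / nw
      w_cor[s, ] <- w_cor[s, ] / nw
    }
  }

  weights <- NULL
  if (store_weights) {
    per_channel <- if (mode %in% c("spatial", "spatiotemporal"))
      suppressWarnings(reduce_to_channels(w_cor, layout, mode, nch))
    weights <- list(raw = w_raw, corrected = w_cor, per_channel = per_channel,
                    layout = layout)
  }
  chance <- if (analysis == "classification") 100 / nc else 0

  structure(list(
    accuracy = apply(per_analysis, 1, mean),
    per_analysis = per_analysis,
    permuted_accuracy = if (!is.null(perm_analysis)) apply(perm_analysis, 1, mean, na.rm = TRUE),
    permuted_per_analysis = perm_analysis,
    feature_weights = weights,
    plan = plan,
    times_ms = dataset$epoch_start_ms +
      (plan$starts - 1) * 1000 / dataset$sampling_rate_hz,
    chance = chance,
    analysis = analysis, mode = mode,
    n_channels = nch, channel_names = dataset$channel_names,
    degenerate = degenerate,
    config = list(conditions = conditions, analysis = analysis, mode = mode,
                  window_width_ms = window_width_ms, step_ms = step_ms,
                  channel = channel, k = k, m = m,
                  cost = cost %||% (if (analysis == "classification") 1 else 0.1),
                  epsilon = epsilon, average_by_block = average_by_block,
                  permute_labels = permute_labels,
                  zscore_features = zscore_features, seed = seed,
                  sampling_rate_hz = dataset$sampling_rate_hz,
                  epoch_start_ms = dataset$epoch_start_ms)),
    class = "erp_decoding")
}

#' Cross-condition generalisation decoding
#'
#' Trains the classifier on the conditions of one experimental context and
#' evaluates it on the conditions of a disjoint context (classes matched by
#' position in the two tuples). Because training and test data are already
#' independent there is no k-fold split; the analysis is repeated `m` times
#' with re-drawn balancing subsamples.
#'
#' @param dataset an [epoched_dataset()].
#' @param train_conditions,test_conditions disjoint, equally long condition
#'   index tuples: `train_conditions[i]` and `test_conditions[i]` carry the
#'   same class.
#' @inheritParams decode_erp
#' @return an `erp_decoding` object with `per_analysis` of shape
#'   `n_steps x m x 1`.
#' @export
cross_decode <- function(dataset, train_conditions, test_conditions,
                         mode = c("spatial", "temporal", "spatiotemporal"),
                         window_width_ms = 10, step_ms = 10, channel = NULL,
                         m = 10, cost = NULL, average_by_block = FALSE,
                         zscore_features = FALSE, seed = 1, store_weights = TRUE) {
  mode <- match.arg(mode)
  validate_epoched_dataset(dataset)
  if (length(train_conditions) != length(test_conditions))
    stop("train and test contexts must have the same class count", call. = FALSE)
  if (length(intersect(train_conditions, test_conditions)))
    stop("train and test contexts overlap", call. = FALSE)
  g <- length(train_conditions)
  if (g < 2) stop("need at least two classes per context", call. = FALSE)
  dtr <- reduce_conditions(dataset, train_conditions)
  dte <- reduce_conditions(dataset, test_conditions)
  width <- ms_to_samples(window_width_ms, dataset$sampling_rate_hz, "window width")
  step <- ms_to_samples(step_ms, dataset$sampling_rate_hz, "step size")
  plan <- window_plan(n_timepoints(dataset), width, step)
  nch <- n_channels(dataset)
  layout <- feature_layout(mode, nch, width, channel)
  d <- length(layout$channel)

  per_analysis <- array(NA_real_, c(plan$n_steps, m, 1))
  w_raw <- if (store_weights) matrix(0, plan$n_steps, d)
  w_cor <- if (store_weights) matrix(0, plan$n_steps, d)

  for (s in seq_len(plan$n_steps)) {
    ptr <- step_patterns(dtr, plan$starts[s], width, mode, channel, average_by_block)
    pte <- step_patterns(dte, plan$starts[s], width, mode, channel, average_by_block)
    for (rep_i in seq_len(m)) {
      btr <- balance_trials(lapply(ptr, `[[`, "x"), seed = derive_seed(seed, s, rep_i, 4L))
      bte <- balance_trials(lapply(pte, `[[`, "x"), seed = derive_seed(seed, s, rep_i, 5L))
      train_x <- do.call(rbind, btr)
      test_x <- do.call(rbind, bte)
      train_y <- rep(seq_len(g), vapply(btr, nrow, 0L))
      test_y <- rep(seq_len(g), vapply(bte, nrow, 0L))
      res <- train_and_test(train_x, train_y, test_x, test_y, "classification",
                            cost = cost, zscore_features = zscore_features)
      per_analysis[s, rep_i, 1] <- res$score
      if (store_weights) {
        wf <- rowMeans(res$w)
        w_raw[s, ] <- w_raw[s, ] + wf / m
        w_cor[s, ] <- w_cor[s, ] + haufe_correct(wf, train_x) / m
      }
    }
  }
  weights <- NULL
  if (store_weights) {
    per_channel <- if (mode %in% c("spatial", "spatiotemporal"))
      suppressWarnings(reduce_to_channels(w_cor, layout, mode, nch))
    weights <- list(raw = w_raw, corrected = w_cor, per_channel = per_channel,
                    layout = layout)
  }
  structure(list(
    accuracy = apply(per_analysis, 1, mean),
    per_analysis = per_analysis,
    permuted_accuracy = NULL, permuted_per_analysis = NULL,
    feature_weights = weights, plan = plan,
    times_ms = dataset$epoch_start_ms + (plan$starts - 1) * 1000 / dataset$sampling_rate_hz,
    chance = 100 / g, analysis = "classification", mode = mode,
    n_channels = nch, channel_names = dataset$channel_names,
    degenerate = FALSE,
    config = list(train_conditions = train_conditions,
                  test_conditions = test_conditions, mode = mode,
                  window_width_ms = window_width_ms, step_ms = step_ms,
                  m = m, cost = cost %||% 1, seed = seed,
                  cross_condition = TRUE,
                  sampling_rate_hz = dataset$sampling_rate_hz,
                  epoch_start_ms = dataset$epoch_start_ms)),
    class = "erp_decoding")
}

#' @export
print.erp_decoding <- function(x, ...) {
  cat(sprintf("Sliding-window %s decoding (%s mode)\n", x$analysis, x$mode))
  cat(sprintf("  %d window(s); %s per window; chance %.1f%s\n",
              x$plan$n_steps,
              paste(dim(x$per_analysis)[2] * dim(x$per_analysis)[3], "analyses"),
              x$chance, if (x$analysis == "classification") "%" else " (Fisher-Z)"))
  cat(sprintf("  performance range %.2f .. %.2f\n", min(x$accuracy), max(x$accuracy)))
  if (!is.null(x$permuted_accuracy))
    cat(sprintf("  permuted-label mean %.2f\n", mean(x$permuted_accuracy)))
  invisible(x)
}

#' Summarise a decoding result
#'
#' @param object an `erp_decoding` fit.
#' @param ... unused.
#' @return a data frame with one row per analysis window: window start time
#'   (ms), mean performance, the SD over the individual analyses, and the
#'   permuted-label mean where available.
#' @export
summary.erp_decoding <- function(object, ...) {
  df <- data.frame(
    window = seq_len(object$plan$n_steps),
    time_ms = object$times_ms,
    performance = object$accuracy,
    sd_analyses = apply(object$per_analysis, 1, stats::sd))
  if (!is.null(object$permuted_accuracy)) df$permuted <- object$permuted_accuracy
  df
}

#' @export
coef.erp_decoding <- function(object, type = c("per_channel", "corrected", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(object$feature_weights)) stop("weights were not stored", call. = FALSE)
  object$feature_weights[[type]]
}
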