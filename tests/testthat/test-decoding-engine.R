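test_that("trial balancing equalises counts by the minimum rule", {
  mats <- lapply(c(30, 24), function(n) matrix(rnorm(n * 3), n, 3))
  bal <- balance_trials(mats, seed = 1)
  expect_equal(vapply(bal, nrow, 0L), c(24L, 24L))
  # already balanced input is untouched
  mats2 <- lapply(c(50, 50), function(n) matrix(rnorm(n * 2), n, 2))
  expect_identical(balance_trials(mats2, seed = 1), mats2)
  # three conditions
  mats3 <- lapply(c(40, 30, 20), function(n) matrix(rnorm(n * 2), n, 2))
  expect_equal(vapply(balance_trials(mats3, seed = 2), nrow, 0L), rep(20L, 3))
  # subsampled rows are a subset of the originals
  expect_true(all(bal[[1]] %in% mats[[1]]))
  expect_error(balance_trials(list(matrix(0, 0, 2), mats[[1]])), "no exemplars")
})

test_that("block averaging and pooling behave as exemplar constructors", {
  runs <- lapply(1:10, function(r) matrix(rnorm(30 * 4, mean = r), 30, 4))
  avg <- block_average(runs)
  expect_equal(dim(avg), c(10, 4))                    # one exemplar per run
  expect_equal(avg[3, ], colMeans(runs[[3]]))
  # single-trial runs: averaging is the identity
  single <- lapply(1:4, function(r) matrix(r + 0:3, 1, 4))
  expect_equal(block_average(single), do.call(rbind, single))
  # constant trials average to the constant
  const <- list(matrix(5, 8, 2))
  expect_true(all(block_average(const) == 5))

  p <- pool_blocks(list(matrix(1, 3, 2), matrix(2, 5, 2)))
  expect_equal(nrow(p$x), 8)
  expect_equal(p$run, rep(1:2, c(3, 5)))
  expect_equal(pool_blocks(list(matrix(9, 4, 2)))$x, matrix(9, 4, 2))
})

test_that("cross-validation sets respect the floor/mod partition rule", {
  a <- assign_cv_sets(95, 10, seed = 3)
  expect_equal(vapply(a$sets, length, 0L), rep(9L, 10))
  expect_equal(length(a$excluded), 5L)
  all_idx <- c(unlist(a$sets), a$excluded)
  expect_equal(sort(all_idx), 1:95)                  # partition, no overlap

  b <- assign_cv_sets(100, 10, seed = 4)
  expect_equal(vapply(b$sets, length, 0L), rep(10L, 10))
  expect_equal(length(b$excluded), 0L)

  c10 <- assign_cv_sets(10, 10, seed = 5)
  expect_equal(vapply(c10$sets, length, 0L), rep(1L, 10))
  expect_error(assign_cv_sets(9, 10), "smaller k")
})

test_that("fold scoring implements percent-correct and Fisher-Z contracts", {
  set.seed(6)
  tr <- rbind(matrix(rnorm(40, -10), 20, 2), matrix(rnorm(40, 10), 20, 2))
  te <- rbind(matrix(rnorm(20, -10), 10, 2), matrix(rnorm(20, 10), 10, 2))
  y_tr <- rep(1:2, each = 20); y_te <- rep(1:2, each = 10)
  res <- train_and_test(tr, y_tr, te, y_te, "classification")
  expect_equal(res$score, 100)

  # scoring path oracle: a degenerate always-class-1 model scores the
  # class-1 share of the test set
  fit0 <- linear_svm(tr, y_tr); fit0$w[] <- 0; fit0$b[] <- 0
  pred <- predict(fit0, te)
  expect_equal(100 * mean(pred == y_te), 50)

  # regression: perfect predictions -> capped Fisher-Z, finite and large
  xr <- matrix(seq(-1, 1, length.out = 30), 30, 1)
  yr <- drop(3 * xr)
  rr <- train_and_test(xr, yr, xr, yr, "regression", cost = 10, epsilon = 0)
  expect_true(is.finite(rr$score))
  expect_gt(rr$score, 5)                              # atanh near 1 is huge
  expect_lte(rr$score, atanh(1 - 1e-12))

  # constant labels -> degenerate branch: score 0 plus warning
  expect_warning(
    r0 <- train_and_test(xr, rep(1, 30), xr, rep(1, 30), "regression"),
    "Fisher-Z")
  expect_equal(r0$score, 0)
  expect_true(r0$degenerate)
})

test_that("repetition bookkeeping yields m x k analyses and exact averaging", {
  d <- tiny_dataset(n_timepoints = 10, n_channels = 4, n_epochs = 25, seed = 20)
  fit <- decode_erp(d, window_width_ms = 10, step_ms = 10, k = 5, m = 3, seed = 2)
  expect_equal(dim(fit$per_analysis), c(1, 3, 5))
  expect_equal(fit$accuracy, apply(fit$per_analysis, 1, mean))  # exact identity

  # k = 2, m = 1 on 4 exemplars -> exactly 2 analyses
  d4 <- tiny_dataset(n_timepoints = 10, n_channels = 3, n_epochs = 4, seed = 21)
  f4 <- decode_erp(d4, window_width_ms = 10, step_ms = 10, k = 2, m = 1, seed = 3)
  expect_equal(sum(!is.na(f4$per_analysis)), 2)
})

test_that("pure-noise decoding stays at theoretical chance (2 and 3 classes)", {
  d <- tiny_dataset(n_timepoints = 20, n_channels = 6, n_epochs = 40, signal = 0, seed = 30)
  fit <- decode_erp(d, window_width_ms = 10, step_ms = 10, k = 5, m = 4, seed = 4)
  se <- sd(fit$per_analysis) / sqrt(length(fit$per_analysis))
  expect_lt(abs(mean(fit$accuracy) - 50), max(3 * se, 3))

  n3 <- lapply(1:3, function(i) simulate_noise_dataset(synthetic_spec(
    n_timepoints = 20, n_channels = 6, n_epochs = 30, rng_seed = 40 + i)))
  d3 <- do.call(combine_conditions, n3)
  f3 <- decode_erp(d3, window_width_ms = 10, step_ms = 10, k = 5, m = 4, seed = 5)
  se3 <- sd(f3$per_analysis) / sqrt(length(f3$per_analysis))
  expect_lt(abs(mean(f3$accuracy) - 100 / 3), max(3 * se3, 3))
})

test_that("permuted-label analyses share data and assignment but stay at chance", {
  d <- tiny_dataset(n_timepoints = 10, n_channels = 5, n_epochs = 30, signal = 1.5,
                    signal_channels = 1:2, seed = 50)
  fit <- decode_erp(d, window_width_ms = 10, step_ms = 10, k = 5, m = 6,
                    permute_labels = TRUE, seed = 6)
  # real decoding far above chance, permuted near chance on the same data
  expect_gt(mean(fit$accuracy), 75)
  perm <- fit$permuted_per_analysis
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - 50), max(3 * se, 3.5))
  expect_equal(dim(perm), dim(fit$per_analysis))
})

test_that("duplicating every exemplar does not reduce decodability", {
  d <- tiny_dataset(n_timepoints = 10, n_channels = 5, n_epochs = 20, signal = 0.8,
                    signal_channels = 1:3, seed = 60)
  dup <- d
  for (ck in 1:2) {
    a <- d$data[[1, ck]]
    dup$data[[1, ck]] <- array(c(a, a), c(dim(a)[1:2], 2 * dim(a)[3]))
  }
  f1 <- decode_erp(d, window_width_ms = 10, step_ms = 10, k = 4, m = 3, seed = 7)
  f2 <- decode_erp(dup, window_width_ms = 10, step_ms = 10, k = 4, m = 3, seed = 7)
  expect_gte(mean(f2$accuracy) + 3, mean(f1$accuracy))   # Monte-Carlo slack
})

test_that("decoding is reproducible under a fixed master seed", {
  d <- tiny_dataset(n_timepoints = 10, n_channels = 4, n_epochs = 20, signal = 0.4, seed = 70)
  f1 <- decode_erp(d, window_width_ms = 5, step_ms = 5, k = 4, m = 2,
                   permute_labels = TRUE, seed = 9)
  f2 <- decode_erp(d, window_width_ms = 5, step_ms = 5, k = 4, m = 2,
                   permute_labels = TRUE, seed = 9)
  expect_identical(f1$per_analysis, f2$per_analysis)
  expect_identical(f1$permuted_per_analysis, f2$permuted_per_analysis)
  expect_identical(f1$feature_weights$corrected, f2$feature_weights$corrected)
})

test_that("support vector regression recovers a linear stimulus code", {
  d <- simulate_svr_dataset(synthetic_spec(n_timepoints = 20, n_channels = 6,
                                           n_epochs = 60, signal_channels = 1:3,
                                           signal_timepoints = 11:20, rng_seed = 80),
                            slope = 3)
  fit <- decode_erp(d, conditions = 1, analysis = "regression",
                    window_width_ms = 10, step_ms = 10, k = 5, m = 2, seed = 10)
  expect_lt(abs(fit$accuracy[1]), 0.35)   # no signal in the first window
  expect_gt(fit$accuracy[2], 0.5)         # strong Fisher-Z in the coded window

  # slope 0: no information anywhere
  d0 <- simulate_svr_dataset(synthetic_spec(n_timepoints = 20, n_channels = 6,
                                            n_epochs = 60, rng_seed = 81), slope = 0)
  f0 <- decode_erp(d0, conditions = 1, analysis = "regression",
                   window_width_ms = 10, step_ms = 10, k = 5, m = 2, seed = 11)
  expect_lt(max(abs(f0$accuracy)), 0.4)
})

test_that("cross-condition generalisation transfers, flips, and nulls correctly", {
  mk <- function(signal, seed) simulate_signal_dataset(synthetic_spec(
    n_timepoints = 10, n_channels = 5, n_epochs = 40, signal_value = signal,
    signal_channels = 1:2, signal_timepoints = 6:10, rng_seed = seed))
  # context A: classes (noise, +1); context B: same generator
  d <- combine_conditions(mk(0, 1), mk(1, 2), mk(0, 3), mk(1, 4))
  f <- cross_decode(d, train_conditions = c(1, 2), test_conditions = c(3, 4),
                    window_width_ms = 5, step_ms = 5, m = 3, seed = 12)
  expect_equal(dim(f$per_analysis), c(2, 3, 1))
  expect_gt(f$accuracy[2], 75)

  # class-swapped test context: symmetrically below chance
  fs <- cross_decode(d, train_conditions = c(1, 2), test_conditions = c(4, 3),
                     window_width_ms = 5, step_ms = 5, m = 3, seed = 12)
  expect_lt(fs$accuracy[2], 25)
  expect_equal(f$accuracy[2] - 50, 50 - fs$accuracy[2], tolerance = 1e-8)

  # zero-signal training context: chance on any test context
  dn <- combine_conditions(mk(0, 5), mk(0, 6), mk(0, 7), mk(1, 8))
  fn <- cross_decode(dn, train_conditions = c(1, 2), test_conditions = c(3, 4),
                     window_width_ms = 5, step_ms = 5, m = 4, seed = 13)
  expect_lt(abs(mean(fn$accuracy) - 50), 12)

  expect_error(cross_decode(d, c(1, 2), c(2, 3)), "overlap")
  expect_error(cross_decode(d, c(1, 2), c(3, 4, 2)), "same class count")
})

test_that("temporal and spatiotemporal modes run the full pipeline", {
  d <- combine_conditions(
    simulate_noise_dataset(synthetic_spec(n_timepoints = 20, n_channels = 4,
                                          n_epochs = 30, rng_seed = 1)),
    simulate_signal_dataset(synthetic_spec(n_timepoints = 20, n_channels = 4,
                                           n_epochs = 30, signal_value = 1.2,
                                           signal_channels = 2,
                                           signal_timepoints = 11:20, rng_seed = 2)))
  ft <- decode_erp(d, mode = "temporal", channel = 2, window_width_ms = 10,
                   step_ms = 10, k = 5, m = 2, seed = 3)
  expect_gt(ft$accuracy[2], 75)            # the informative channel decodes
  expect_null(ft$feature_weights$per_channel)  # no channel map for temporal
  expect_error(decode_erp(d, mode = "temporal", window_width_ms = 10,
                          step_ms = 10, k = 5, m = 2), "requires a channel")

  fst <- decode_erp(d, mode = "spatiotemporal", window_width_ms = 10,
                    step_ms = 10, k = 5, m = 2, seed = 3)
  expect_equal(ncol(fst$feature_weights$raw), 4 * 10)   # channels x samples
  expect_equal(dim(fst$feature_weights$per_channel), c(2, 4))
  expect_gt(fst$accuracy[2], 75)
  # the signal channel dominates the spatiotemporal channel map
  expect_equal(which.max(fst$feature_weights$per_channel[2, ]), 2L)
})
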