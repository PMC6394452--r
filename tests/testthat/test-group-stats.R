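test_that("Student and Yuen paired tests match the textbook formula oracles", {
  set.seed(1)
  X <- matrix(rnorm(12 * 10, mean = 52, sd = 4), 12, 10)
  res_s <- test_vs_chance(X, chance = 50, test = "student")
  res_y <- test_vs_chance(X, chance = 50, test = "yuen")
  for (s in 1:10) {
    os <- oracle_paired_t(X[, s], rep(50, 12))
    oy <- oracle_yuen_paired(X[, s], rep(50, 12))
    expect_equal(res_s$t[s], os$t, tolerance = 1e-10)
    expect_equal(res_s$p[s], os$p, tolerance = 1e-10)
    expect_equal(res_y$t[s], oy$t, tolerance = 1e-10)
    expect_equal(res_y$p[s], oy$p, tolerance = 1e-10)
  }
  # matrix-valued empirical chance reference
  P <- matrix(rnorm(12 * 10, 50, 2), 12, 10)
  res_e <- test_vs_chance(X, chance = P, test = "student")
  o <- oracle_paired_t(X[, 3], P[, 3])
  expect_equal(res_e$t[3], o$t, tolerance = 1e-10)
})

test_that("degenerate variance branches return t = 0, p = 1 with a warning", {
  X <- matrix(50, 5, 4)
  expect_warning(r <- test_vs_chance(X, chance = 50), "zero-variance")
  expect_equal(r$t, rep(0, 4))
  expect_equal(r$p, rep(1, 4))
  # constant offset against a per-subject reference: also degenerate
  P <- matrix(rnorm(20, 50, 3), 5, 4)
  expect_warning(r2 <- test_vs_chance(P + 5, chance = P), "zero-variance")
  expect_equal(r2$p, rep(1, 4))
  expect_error(test_vs_chance(X[1:2, ], 50), "at least 3")
})

test_that("Holm correction follows the step-down definition", {
  r <- correct_multiple(p = c(0.010, 0.030, 0.040), method = "holm", alpha = 0.05)
  expect_equal(r$mask, c(TRUE, FALSE, FALSE))   # 0.01<=0.05/3; 0.03>0.05/2 stops
  expect_equal(correct_multiple(p = rep(1, 6), method = "holm", alpha = 0.05)$mask,
               rep(FALSE, 6))
  # brute-force agreement on random vectors, and Holm >= Bonferroni
  set.seed(2)
  for (i in 1:30) {
    p <- runif(sample(3:12, 1))^2
    mask <- correct_multiple(p = p, method = "holm", alpha = 0.05)$mask
    expect_equal(mask, oracle_holm(p, 0.05))
    expect_true(all(mask[p <= 0.05 / length(p)]))  # superset of Bonferroni
  }
})

test_that("FDR step-up rules match the brute-force criterion", {
  r <- correct_multiple(p = c(0.001, 0.002, 0.5, 0.9), method = "fdr_bh", alpha = 0.05)
  expect_equal(r$mask, c(TRUE, TRUE, FALSE, FALSE))
  set.seed(3)
  for (i in 1:30) {
    p <- runif(sample(3:12, 1))^3
    expect_equal(correct_multiple(p = p, method = "fdr_bh", alpha = 0.05)$mask,
                 oracle_bh(p, 0.05))
  }
  # two-stage adaptive variant: all-null and all-signal edge cases
  expect_equal(correct_multiple(p = rep(0.9, 5), method = "fdr_bky")$mask, rep(FALSE, 5))
  expect_equal(correct_multiple(p = rep(1e-6, 5), method = "fdr_bky")$mask, rep(TRUE, 5))
  # adaptive stage never loses rejections relative to plain BH here
  set.seed(4)
  for (i in 1:10) {
    p <- runif(8)^3
    bh <- correct_multiple(p = p, method = "fdr_bh", alpha = 0.05)$mask
    bky <- correct_multiple(p = p, method = "fdr_bky", alpha = 0.05)$mask
    expect_true(all(bky[bh]))
  }
})

test_that("permutation corrections detect strong effects and spare pure noise", {
  set.seed(5)
  null_d <- matrix(rnorm(12 * 8), 12, 8)
  sig_d <- null_d; sig_d[, 3:5] <- sig_d[, 3:5] + 2.5
  for (meth in c("max_perm", "cluster_perm", "gfwer_korn")) {
    rs <- correct_multiple(method = meth, diffs = sig_d, alpha = 0.05,
                           n_permutations = 500, seed = 6)
    expect_true(all(rs$mask[3:5]), info = meth)
    rn <- correct_multiple(method = meth, diffs = null_d, alpha = 0.05,
                           n_permutations = 500, seed = 7)
    expect_lt(sum(rn$mask), 3)
  }
  expect_warning(correct_multiple(method = "max_perm", diffs = null_d,
                                  n_permutations = 50), "unreliable")
  expect_error(correct_multiple(method = "max_perm"), "difference scores")
})

test_that("permutation p-values are invariant to subject relabelling", {
  set.seed(8)
  D <- matrix(rnorm(10 * 6, 0.5), 10, 6)
  r1 <- correct_multiple(method = "max_perm", diffs = D, n_permutations = 2000, seed = 9)
  r2 <- correct_multiple(method = "max_perm", diffs = D[sample(10), ],
                         n_permutations = 2000, seed = 10)
  expect_equal(r1$p_adjusted, r2$p_adjusted, tolerance = 0.05)
})

test_that("prevalence inference: exact form, bounds, and degenerate cases", {
  # all subjects below their own permutation median -> no rejection, bound 0
  set.seed(11)
  perms <- matrix(runif(6 * 20, 50, 60), 6, 20)
  obs <- apply(perms, 1, min) - 1
  r <- prevalence_minstat(obs, perms, n_second_level = 2000, seed = 12)
  expect_false(r$reject)
  expect_equal(r$prevalence_lower_bound, 0)

  # two subjects at the maximum of their own permutations: the exact
  # global-null p is the product of the per-subject tail fractions (the
  # minimal achievable p given the counts), here (1/(P1+1))^2
  perms2 <- matrix(runif(2 * 9), 2, 9)
  obs2 <- apply(perms2, 1, max) + 1
  rex <- prevalence_minstat(obs2, perms2, method = "exact")
  expect_equal(rex$global_null_p, (1 / 10)^2, tolerance = 1e-12)

  # Monte-Carlo agrees with the exact product form
  set.seed(13)
  perms3 <- matrix(rnorm(8 * 15, 50, 5), 8, 15)
  obs3 <- rnorm(8, 58, 2)
  rmc <- prevalence_minstat(obs3, perms3, n_second_level = 20000, seed = 14)
  rex3 <- prevalence_minstat(obs3, perms3, method = "exact")
  expect_equal(rmc$global_null_p, rex3$global_null_p, tolerance = 0.01)
  if (rex3$reject) {
    expect_gt(rex3$prevalence_lower_bound, 0)
    expect_lte(rex3$prevalence_lower_bound, 1)
  }
  expect_error(prevalence_minstat(obs3, perms3[, 1, drop = FALSE]), "at least 2")
  expect_error(prevalence_minstat(obs3, perms3, alpha = 0.05, n_second_level = 10),
               "at least 20")
})

test_that("group feature-weight testing: zero maps, idempotence, locality", {
  zero <- replicate(5, matrix(0, 3, 6), simplify = FALSE)
  expect_warning(r0 <- group_feature_weights(zero), "zero-variance")
  expect_false(any(r0$significant))

  set.seed(15)
  maps <- replicate(8, {
    m <- matrix(rnorm(3 * 6, 0, 0.1), 3, 6)
    m[, 1:2] <- m[, 1:2] + 2           # channels 1-2 loaded in every window
    m
  }, simplify = FALSE)
  r <- group_feature_weights(maps, alpha = 0.05, correction = "holm")
  expect_true(all(r$significant[1:2]))
  expect_false(any(r$significant[3:6]))

  # averaging a single step equals selecting it
  r1 <- group_feature_weights(maps, steps = 2)
  r2 <- group_feature_weights(maps, steps = c(2))
  expect_identical(r1, r2)
  expect_error(group_feature_weights(maps, steps = integer(0)), "non-empty")
  expect_error(group_feature_weights(maps, correction = "cluster_perm"), "channels")
  bad <- maps; bad[[2]] <- bad[[2]][, 1:5]
  expect_error(group_feature_weights(bad), "channel count")
})

test_that("group_decode aggregates, tests and corrects end to end", {
  specs <- synthetic_spec(n_timepoints = 20, n_channels = 5, n_epochs = 24,
                          signal_value = 1.2, signal_channels = 1:2,
                          signal_timepoints = 11:20, rng_seed = 99)
  study <- simulate_group_study(specs, n_subjects = 6)
  fits <- lapply(study, function(d)
    decode_erp(d, window_width_ms = 10, step_ms = 10, k = 4, m = 3,
               permute_labels = TRUE, seed = 17))
  grp <- group_decode(fits, test = "student", chance = "empirical",
                      correction = "holm", prevalence = TRUE,
                      n_second_level = 2000, feature_weights = TRUE, seed = 18)
  expect_equal(dim(grp$subject_matrix), c(6, 2))
  expect_false(grp$significant_mask[1])          # no signal in window 1
  expect_true(grp$significant_mask[2])           # strong signal in window 2
  expect_gt(grp$prevalence_lower_bound[2], 0)
  # averaged over all windows the strongest signal channel survives; the
  # signal window alone shows both carrying channels
  expect_true(grp$feature_weight_stats$significant[1])
  expect_false(any(grp$feature_weight_stats$significant[3:5]))
  maps <- lapply(fits, function(f) f$feature_weights$per_channel)
  fw2 <- group_feature_weights(maps, steps = 2, correction = "holm")
  expect_true(all(fw2$significant[1:2]))
  sm <- summary(grp)
  expect_equal(nrow(sm), 2)
  expect_true(all(c("mean", "se", "t", "p", "significant") %in% names(sm)))
  expect_error(group_decode(fits[1:2]), "at least 3")
  # theoretical-chance route without permuted fits
  fits0 <- lapply(study[1:3], function(d)
    decode_erp(d, window_width_ms = 10, step_ms = 10, k = 4, m = 2, seed = 19))
  g0 <- group_decode(fits0, chance = "theoretical", correction = "fdr_bh")
  expect_length(g0$p_values, 2)
  expect_error(group_decode(fits0, chance = "empirical"), "permute_labels")
})
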