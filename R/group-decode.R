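#' Group-level analysis of per-subject decoding results
#'
#' Aggregates a list of per-subject [decode_erp()] fits into a
#' subjects-by-windows performance matrix, tests every window against
#' chance (theoretical, or the empirical permuted-label reference), applies
#' the chosen multiple-comparison correction, and optionally computes
#' minimum-statistic prevalence bounds and group feature-weight statistics.
#'
#' @param results list of `erp_decoding` fits (>= 3), one per subject,
#'   obtained with identical configurations.
#' @param test `"student"` or `"yuen"` paired test.
#' @param chance `"empirical"` (per-subject permuted-label means; requires
#'   fits run with `permute_labels = TRUE`) or `"theoretical"`.
#' @param correction multiple-comparison method, see [correct_multiple()].
#' @param alpha significance level.
#' @param tail test direction (default `"greater"`).
#' @param prevalence if `TRUE`, run [prevalence_minstat()] per window using
#'   each subject's per-repetition permuted-label means as first-level
#'   permutations.
#' @param n_permutations sign-flip resamples for permutation corrections.
#' @param n_second_level second-level draws for prevalence inference.
#' @param feature_weights if `TRUE` and weights were stored, also test the
#'   per-channel weight maps at the group level (over all windows).
#' @param seed integer seed for all resampling.
#' @return an object of class `erp_group`.
#' @export
group_decode <- function(results, test = c("student", "yuen"),
                         chance = c("empirical", "theoretical"),
                         correction = "holm", alpha = 0.05,
                         tail = "greater", prevalence = FALSE,
                         n_permutations = 1000, n_second_level = 10000,
                         feature_weights = FALSE, seed = 1) {
  test <- match.arg(test)
  chance <- match.arg(chance)
  if (length(results) < 3) stop("group analysis needs at least 3 subjects", call. = FALSE)
  ns <- results[[1]]$plan$n_steps
  if (!all(vapply(results, function(r) r$plan$n_steps, 0L) == ns))
    stop("subjects differ in the analysis window grid", call. = FALSE)
  subject_matrix <- t(vapply(results, `[[`, numeric(ns), "accuracy"))

  permuted_matrix <- NULL
  if (chance == "empirical" || prevalence) {
    if (any(vapply(results, function(r) is.null(r$permuted_per_analysis), TRUE)))
      stop("empirical chance / prevalence need fits run with permute_labels = TRUE",
           call. = FALSE)
    permuted_matrix <- t(vapply(results, function(r)
      apply(r$permuted_per_analysis, 1, mean, na.rm = TRUE), numeric(ns)))
  }
  ref <- if (chance == "empirical") permuted_matrix else results[[1]]$chance

  ht <- test_vs_chance(subject_matrix, chance = ref, test = test, tail = tail)
  diffs <- subject_matrix - (if (is.matrix(ref)) ref
                             else matrix(ref, nrow(subject_matrix), ns))
  corr <- correct_multiple(p = ht$p, method = correction, alpha = alpha,
                           diffs = diffs, n_permutations = n_permutations,
                           seed = derive_seed(seed, 11L))

  prev <- NULL
  if (prevalence) {
    # first-level permutations: per-repetition fold means of the
    # permuted-label analyses (one independent label shuffle each)
    prev <- lapply(seq_len(ns), function(s) {
      perms <- t(vapply(results, function(r)
        apply(r$permuted_per_analysis[s, , , drop = FALSE], 2, mean, na.rm = TRUE),
        numeric(dim(results[[1]]$permuted_per_analysis)[2])))
      prevalence_minstat(subject_matrix[, s], perms, alpha = alpha,
                         n_second_level = n_second_level,
                         seed = derive_seed(seed, 12L, s))
    })
  }

  fw <- NULL
  if (feature_weights) {
    maps <- lapply(results, function(r) r$feature_weights$per_channel)
    if (any(vapply(maps, is.null, TRUE)))
      warning("per-channel weights missing in some fits; skipping weight stats", call. = FALSE)
    else fw <- group_feature_weights(maps, alpha = alpha,
                                     correction = if (correction == "cluster_perm") "holm"
                                                  else correction,
                                     n_permutations = n_permutations,
                                     seed = derive_seed(seed, 13L))
  }

  structure(list(
    subject_matrix = subject_matrix,
    permuted_matrix = permuted_matrix,
    t_stats = ht$t, p_values = ht$p, df = ht$df,
    significant_mask = corr$mask,
    p_adjusted = corr$p_adjusted,
    prevalence = prev,
    prevalence_lower_bound = if (!is.null(prev))
      vapply(prev, `[[`, 0, "prevalence_lower_bound"),
    feature_weight_stats = fw,
    times_ms = results[[1]]$times_ms,
    chance_level = results[[1]]$chance,
    analysis = results[[1]]$analysis,
    method_echo = list(test = test, chance = chance, correction = correction,
                       alpha = alpha, tail = tail,
                       n_permutations = n_permutations,
                       n_second_level = n_second_level, seed = seed,
                       n_subjects = length(results))),
    class = "erp_group")
}

#' @export
print.erp_group <- function(x, ...) {
  cat(sprintf("Group decoding analysis: %d subjects, %d windows\n",
              nrow(x$subject_matrix), ncol(x$subject_matrix)))
  cat(sprintf("  %s test vs %s chance, %s correction (alpha %g)\n",
              x$method_echo$test, x$method_echo$chance,
              x$method_echo$correction, x$method_echo$alpha))
  cat(sprintf("  %d / %d windows significant\n",
              sum(x$significant_mask), length(x$significant_mask)))
  if (!is.null(x$prevalence_lower_bound))
    cat(sprintf("  prevalence lower bounds: %s\n",
                paste(sprintf("%.2f", x$prevalence_lower_bound), collapse = " ")))
  invisible(x)
}

#' Summarise a group analysis as a flat table
#'
#' @param object an `erp_group`.
#' @param ... unused.
#' @return data frame with one row per window: time, group mean, SE, t, p,
#'   corrected significance, and prevalence bound where computed.
#' @export
summary.erp_group <- function(object, ...) {
  sm <- object$subject_matrix
  df <- data.frame(
    window = seq_len(ncol(sm)),
    time_ms = object$times_ms,
    mean = colMeans(sm),
    se = apply(sm, 2, stats::sd) / sqrt(nrow(sm)),
    t = object$t_stats,
    p = object$p_values,
    significant = object$significant_mask)
  if (!is.null(object$permuted_matrix)) df$permuted_mean <- colMeans(object$permuted_matrix)
  if (!is.null(object$prevalence_lower_bound))
    df$prevalence_lower_bound <- object$prevalence_lower_bound
  df
}

#' Write the group summary to CSV
#'
#' @param group an `erp_group`.
#' @param path output CSV path.
#' @export
write_group_csv <- function(group, path) {
  utils::write.csv(summary(group), path, row.names = FALSE)
  invisible(path)
}
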