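# Group-level inference on subject-by-window performance matrices.

# winsorized helpers for Yuen's trimmed paired test
winsorize <- function(x, g) {
  xs <- sort(x)
  lo <- xs[g + 1L]; hi <- xs[length(x) - g]
  pmin(pmax(x, lo), hi)
}
trimmed_mean <- function(x, trim) mean(x, trim = trim)

#' Paired tests of decoding performance against chance
#'
#' Compares, per analysis window, the subjects' real decoding performance
#' against a chance reference: either the theoretical chance level (a
#' constant) or each subject's mean permuted-label performance (the
#' empirical chance distribution). `"student"` is the ordinary paired
#' t-test; `"yuen"` uses 20%-trimmed means and winsorised (co)variances and
#' is robust to the non-normality typical of accuracy scores.
#'
#' @param subject_matrix numeric matrix, subjects x windows, real
#'   performance.
#' @param chance a single number (theoretical chance) or a matrix like
#'   `subject_matrix` of per-subject chance references.
#' @param test `"student"` or `"yuen"`.
#' @param tail `"greater"` (default: above-chance is the hypothesis),
#'   `"two.sided"` or `"less"`.
#' @param trim trimming proportion for Yuen's test (default 0.2).
#' @return list with per-window `t`, `p`, and `df`. Windows with zero
#'   (winsorised) variance of the differences give `t = 0`, `p = 1` and a
#'   warning.
#' @export
test_vs_chance <- function(subject_matrix, chance = 50,
                           test = c("student", "yuen"),
                           tail = c("greater", "two.sided", "less"),
                           trim = 0.2) {
  test <- match.arg(test)
  tail <- match.arg(tail)
  subject_matrix <- as.matrix(subject_matrix)
  n <- nrow(subject_matrix)
  if (n < 3) stop("group analysis needs at least 3 subjects", call. = FALSE)
  ref <- if (is.matrix(chance)) {
    stopifnot(all(dim(chance) == dim(subject_matrix)))
    chance
  } else matrix(chance, n, ncol(subject_matrix))
  ns <- ncol(subject_matrix)
  tval <- pval <- dfv <- numeric(ns)
  degen <- FALSE
  for (s in seq_len(ns)) {
    x <- subject_matrix[, s]; y <- ref[, s]
    if (test == "student") {
      d <- x - y
      se <- stats::sd(d) / sqrt(n)
      df <- n - 1
      if (se == 0) { tval[s] <- 0; pval[s] <- 1; dfv[s] <- df; degen <- TRUE; next }
      tv <- mean(d) / se
    } else {
      g <- floor(trim * n); h <- n - 2 * g
      wx <- winsorize(x, g); wy <- winsorize(y, g)
      q1 <- (n - 1) * stats::var(wx)
      q2 <- (n - 1) * stats::var(wy)
      q3 <- (n - 1) * stats::cov(wx, wy)
      df <- h - 1
      se <- sqrt((q1 + q2 - 2 * q3) / (h * (h - 1)))
      if (se == 0) { tval[s] <- 0; pval[s] <- 1; dfv[s] <- df; degen <- TRUE; next }
      tv <- (trimmed_mean(x, trim) - trimmed_mean(y, trim)) / se
    }
    tval[s] <- tv; dfv[s] <- df
    pval[s] <- switch(tail,
      greater = stats::pt(tv, df, lower.tail = FALSE),
      less = stats::pt(tv, df),
      two.sided = 2 * stats::pt(abs(tv), df, lower.tail = FALSE))
  }
  if (degen) warning("zero-variance differences in some windows; p set to 1", call. = FALSE)
  list(t = tval, p = pval, df = dfv, test = test, tail = tail)
}

col_t <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  v <- (colSums(D * D) - n * mu^2) / (n - 1)
  s <- sqrt(pmax(v, 0))
  ifelse(s == 0, 0, mu / (s / sqrt(n)))
}

#' Multiple-comparison correction across analysis windows
#'
#' Controls the family-wise error (or false discovery) rate over the many
#' window-wise tests. `holm`, `fdr_bh` and `fdr_bky` operate on p-values;
#' `max_perm`, `cluster_perm` and `gfwer_korn` are permutation procedures
#' on the subjects' difference scores (real minus chance reference) using
#' random within-subject sign flips, exploiting the temporal structure of
#' the window grid.
#'
#' @param p numeric vector of uncorrected p-values (needed for `holm`,
#'   `fdr_bh`, `fdr_bky`).
#' @param method one of `"holm"`, `"max_perm"`, `"cluster_perm"`,
#'   `"gfwer_korn"`, `"fdr_bh"`, `"fdr_bky"`.
#' @param alpha significance level.
#' @param diffs subjects x windows matrix of difference scores (needed for
#'   the permutation methods); windows must be temporally adjacent for the
#'   cluster method.
#' @param n_permutations number of sign-flip resamples (default 1000; a
#'   warning is issued below 100).
#' @param cluster_alpha cluster-forming threshold, expressed as the
#'   two-sided uncorrected p-value per window (default `alpha`).
#' @param u number of tolerated false positives for generalised FWER
#'   control (default 1; implemented as the single-step (u+1)-th maximum
#'   statistic procedure).
#' @param seed integer seed for the resampling.
#' @return list with `mask` (logical, per window), `p_adjusted` (where the
#'   method defines adjusted values, else `NULL`), and method details.
#' @export
correct_multiple <- function(p = NULL,
                             method = c("holm", "max_perm", "cluster_perm",
                                        "gfwer_korn", "fdr_bh", "fdr_bky"),
                             alpha = 0.05, diffs = NULL, n_permutations = 1000,
                             cluster_alpha = alpha, u = 1, seed = 1) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  if (method %in% c("holm", "fdr_bh", "fdr_bky")) {
    if (is.null(p)) stop(method, " needs p-values", call. = FALSE)
    m <- length(p)
    if (method == "holm") {
      adj <- stats::p.adjust(p, "holm")
      return(list(mask = adj <= alpha, p_adjusted = adj, method = method))
    }
    if (method == "fdr_bh") {
      adj <- stats::p.adjust(p, "BH")
      return(list(mask = adj <= alpha, p_adjusted = adj, method = method))
    }
    # two-stage adaptive linear step-up (sharpened FDR)
    a1 <- alpha / (1 + alpha)
    r1 <- sum(stats::p.adjust(p, "BH") <= a1)
    mask <- if (r1 == 0) rep(FALSE, m)
            else if (r1 == m) rep(TRUE, m)
            else stats::p.adjust(p, "BH") <= a1 * m / (m - r1)
    return(list(mask = mask, p_adjusted = NULL, method = method, stage1 = r1))
  }

  if (is.null(diffs)) stop(method, " needs the subject difference scores", call. = FALSE)
  if (n_permutations < 100) warning("fewer than 100 permutations is unreliable", call. = FALSE)
  D <- as.matrix(diffs)
  n <- nrow(D); m <- ncol(D)
  t_obs <- col_t(D)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE), n_permutations, n)

  if (method == "max_perm") {
    null_max <- vapply(seq_len(n_permutations),
                       function(b) max(col_t(D * signs[b, ])), 0)
    padj <- vapply(t_obs, function(tv) (1 + sum(null_max >= tv)) / (n_permutations + 1), 0)
    return(list(mask = padj <= alpha, p_adjusted = padj, method = method, t = t_obs))
  }

  if (method == "gfwer_korn") {
    kth <- function(tv) sort(tv, decreasing = TRUE)[min(u + 1L, m)]
    null_k <- vapply(seq_len(n_permutations),
                     function(b) kth(col_t(D * signs[b, ])), 0)
    padj <- vapply(t_obs, function(tv) (1 + sum(null_k >= tv)) / (n_permutations + 1), 0)
    return(list(mask = padj <= alpha, p_adjusted = padj, method = method, u = u, t = t_obs))
  }

  # cluster-based permutation: suprathreshold runs of same-signed t,
  # cluster mass = sum of t, compared to the null maximum absolute mass
  df <- n - 1
  t_crit <- stats::qt(1 - cluster_alpha / 2, df)
  find_clusters <- function(tv) {
    above <- abs(tv) > t_crit
    cl <- list()
    i <- 1L
    while (i <= m) {
      if (above[i]) {
        j <- i
        while (j < m && above[j + 1L] && sign(tv[j + 1L]) == sign(tv[i])) j <- j + 1L
        cl[[length(cl) + 1L]] <- list(idx = i:j, mass = sum(tv[i:j]))
        i <- j + 1L
      } else i <- i + 1L
    }
    cl
  }
  obs_cl <- find_clusters(t_obs)
  null_mass <- vapply(seq_len(n_permutations), function(b) {
    cl <- find_clusters(col_t(D * signs[b, ]))
    if (length(cl) == 0) 0 else max(vapply(cl, function(x) abs(x$mass), 0))
  }, 0)
  mask <- rep(FALSE, m)
  cl_p <- numeric(length(obs_cl))
  for (ci in seq_along(obs_cl)) {
    cl_p[ci] <- (1 + sum(null_mass >= abs(obs_cl[[ci]]$mass))) / (n_permutations + 1)
    if (cl_p[ci] <= alpha) mask[obs_cl[[ci]]$idx] <- TRUE
  }
  list(mask = mask, p_adjusted = NULL, method = method,
       clusters = obs_cl, cluster_p = cl_p, t = t_obs)
}

#' Minimum-statistic prevalence inference
#'
#' Permutation-based group inference on the across-subject minimum of the
#' decoding statistic. Rejecting the global null establishes that at
#' least some subjects carry decodable information; in addition a lower
#' bound on the population prevalence of decodable information is returned.
#' The observed value of each subject is included as one first-level
#' permutation (the neutral permutation). Second-level Monte-Carlo
#' resampling draws one first-level permutation per subject and takes the
#' minimum across subjects; the global-null p-value is the rank of the
#' observed minimum in that distribution. The prevalence lower bound is the
#' largest majority fraction `gamma0` whose null is still rejected at
#' `alpha`:
#' `gamma0* = (alpha^(1/N) - p^(1/N)) / (1 - p^(1/N))`.
#'
#' @param observed numeric vector, one observed performance per subject.
#' @param perms matrix subjects x first-level permutations of permuted-label
#'   performance (at least 2 per subject; the observed value is appended
#'   internally as the neutral permutation).
#' @param alpha significance level.
#' @param n_second_level number of second-level Monte-Carlo draws (default
#'   10000; the observed combination always counts as one).
#' @param seed integer seed.
#' @param method `"montecarlo"` (default) or `"exact"`: because the
#'   second-level draws are independent across subjects,
#'   `P(min >= min_obs)` is exactly the product of the per-subject tail
#'   fractions; the exact form is useful for small problems and as a
#'   cross-check.
#' @return list with `global_null_p`, `reject` and
#'   `prevalence_lower_bound` (0 when the global null is not rejected).
#' @export
prevalence_minstat <- function(observed, perms, alpha = 0.05,
                               n_second_level = 10000, seed = 1,
                               method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  perms <- as.matrix(perms)
  N <- length(observed)
  stopifnot(nrow(perms) == N)
  if (ncol(perms) < 2)
    stop("every subject needs at least 2 first-level permutation values", call. = FALSE)
  if (method == "montecarlo" && n_second_level < ceiling(1 / alpha))
    stop(sprintf("n_second_level must be at least %d for alpha = %g",
                 ceiling(1 / alpha), alpha), call. = FALSE)
  P <- cbind(observed, perms)            # neutral permutation included
  P1 <- ncol(P)
  min_obs <- min(observed)
  if (method == "exact") {
    pval <- prod(rowSums(P >= min_obs) / P1)
  } else {
    set.seed(seed)
    B <- n_second_level - 1L
    mins <- rep(Inf, B)
    for (i in seq_len(N))
      mins <- pmin(mins, P[i, sample.int(P1, B, replace = TRUE)])
    pval <- (1L + sum(mins >= min_obs)) / n_second_level  # observed counts
  }
  reject <- pval <= alpha
  bound <- 0
  if (reject && pval < 1) {
    bound <- (alpha^(1 / N) - pval^(1 / N)) / (1 - pval^(1 / N))
    bound <- min(max(bound, 0), 1)
  }
  list(global_null_p = pval, reject = reject, prevalence_lower_bound = bound)
}

#' Group-level inference on per-channel feature weights
#'
#' Averages each subject's absolute z-standardised per-channel weights over
#' the requested analysis windows and tests, per channel, whether the group
#' mean exceeds zero (one-sample t, one-sided by default), correcting
#' across channels.
#'
#' @param maps list of subject matrices `n_steps x n_channels` (as stored in
#'   `coef(fit, "per_channel")`).
#' @param steps window indices to average before testing (default: all).
#' @param alpha significance level.
#' @param correction `"holm"`, `"fdr_bh"`, `"fdr_bky"`, `"max_perm"`,
#'   `"gfwer_korn"` (cluster correction is not meaningful over unordered
#'   channels).
#' @param tail test direction (default `"greater"`).
#' @param n_permutations,seed passed to [correct_multiple()] for the
#'   permutation methods.
#' @return data frame with one row per channel: group mean weight, t, p,
#'   and the corrected significance flag.
#' @export
group_feature_weights <- function(maps, steps = NULL, alpha = 0.05,
                                  correction = "holm", tail = "greater",
                                  n_permutations = 1000, seed = 1) {
  stopifnot(length(maps) >= 3)
  nch <- ncol(maps[[1]])
  if (!all(vapply(maps, ncol, 0L) == nch))
    stop("subjects differ in channel count", call. = FALSE)
  steps <- steps %||% seq_len(nrow(maps[[1]]))
  if (length(steps) == 0) stop("steps must be non-empty", call. = FALSE)
  subj <- t(vapply(maps, function(mp) colMeans(mp[steps, , drop = FALSE]), numeric(nch)))
  res <- test_vs_chance(subj, chance = 0, test = "student", tail = tail)
  if (correction == "cluster_perm")
    stop("cluster correction is defined over adjacent windows, not channels", call. = FALSE)
  corr <- correct_multiple(p = res$p, method = correction, alpha = alpha,
                           diffs = subj, n_permutations = n_permutations, seed = seed)
  data.frame(channel = seq_len(nch),
             mean_weight = colMeans(subj),
             t = res$t, p = res$p,
             significant = corr$mask)
}
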