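#' Haufe activation-pattern correction of linear decoder weights
#'
#' Linear decoder weights are extraction filters and cannot be read as the
#' expression of the signal per feature: a feature carrying pure noise that
#' is correlated with other features can receive a large weight. The
#' corresponding forward-model activation pattern is obtained as
#' `a = Sigma_X w / var(w'X)`, where `Sigma_X` is the empirical feature
#' covariance of the training data (the single-component form of the
#' Haufe transformation).
#'
#' @param w numeric weight vector (length = number of features).
#' @param x training pattern matrix (exemplars x features) the weights were
#'   fitted on; at least 2 rows.
#' @return the activation pattern, a numeric vector like `w`.
#' @export
haufe_correct <- function(w, x) {
  x <- as.matrix(x)
  stopifnot(length(w) == ncol(x))
  if (nrow(x) < 2) stop("need at least 2 training exemplars", call. = FALSE)
  s <- drop(x %*% w)
  v <- stats::var(s)
  if (!is.finite(v) || v <= 0)
    stop("projected scores have zero variance; activation pattern undefined", call. = FALSE)
  drop(stats::cov(x) %*% w) / v
}

#' Reduce per-feature weights to per-channel scores
#'
#' For each analysis window: averages the (signed) weights of each channel's
#' timepoint features, takes absolute values, and z-standardises across
#' channels — yielding one absolute, z-standardised weight per channel per
#' window. Only spatial and spatiotemporal analyses admit this reduction;
#' temporal analyses use a single channel.
#'
#' @param weights numeric matrix `n_steps x n_features` (or a vector for a
#'   single step).
#' @param layout feature layout as built internally (list with `$channel`
#'   giving the channel of every feature position).
#' @param mode `"spatial"` or `"spatiotemporal"`.
#' @param n_channels total channel count.
#' @return matrix `n_steps x n_channels` of z-standardised absolute weights.
#'   A window whose channel means are all equal yields all-zero z-scores
#'   (degenerate rule) with a warning.
#' @export
reduce_to_channels <- function(weights, layout, mode, n_channels) {
  if (!mode %in% c("spatial", "spatiotemporal"))
    stop("per-channel weight reduction is only defined for spatial and spatiotemporal analyses",
         call. = FALSE)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  stopifnot(ncol(weights) == length(layout$channel))
  out <- matrix(0, nrow(weights), n_channels)
  for (s in seq_len(nrow(weights))) {
    chmean <- vapply(seq_len(n_channels),
                     function(ch) mean(weights[s, layout$channel == ch]), 0)
    out[s, ] <- zscore_safe(abs(chmean), warn = FALSE)
    if (stats::sd(abs(chmean)) == 0)
      warning(sprintf("window %d: constant channel weights; z-scores set to 0", s), call. = FALSE)
  }
  out
}
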