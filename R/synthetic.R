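#' Specification of a synthetic epoched-EEG generator
#'
#' Describes the ground-truth world used for validation: every timepoint,
#' channel and epoch is an independent Gaussian draw (mean 0, SD 1 by
#' default), and an optional constant signal is added to a subset of
#' channels over a subset of timepoints. Defaults follow the validation
#' design: 100 timepoints, 64 channels, signal on channels 1-10 over
#' timepoints 51-100. Temporally independent noise is not typical of real
#' EEG; an optional AR(1) coefficient adds within-epoch temporal
#' correlation for stress tests (off by default).
#'
#' @param n_timepoints,n_channels,n_epochs dimensions of each generated
#'   condition dataset.
#' @param noise_mean,noise_sd Gaussian noise parameters.
#' @param signal_value constant added on the signal block (0 = pure noise).
#' @param signal_channels,signal_timepoints 1-based index sets of the block.
#' @param n_runs number of runs/blocks the epochs are split into.
#' @param ar1 optional AR(1) coefficient in [0, 1) for temporally correlated
#'   noise (stationary marginal SD preserved).
#' @param rng_seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_timepoints = 100, n_channels = 64, n_epochs = 1000,
                           noise_mean = 0, noise_sd = 1, signal_value = 0,
                           signal_channels = NULL, signal_timepoints = NULL,
                           n_runs = 1, ar1 = 0, rng_seed = 1) {
  if (n_timepoints < 1 || n_channels < 1 || n_epochs < 1 || n_runs < 1)
    stop("dimensions must be positive", call. = FALSE)
  # defaults reproduce the validation design: signal on the first 10
  # channels over the second half of the epoch (1:10 x 51:100 at full size)
  signal_channels <- signal_channels %||% seq_len(min(10L, n_channels))
  signal_timepoints <- signal_timepoints %||% seq(n_timepoints %/% 2 + 1L, n_timepoints)
  if (length(signal_channels) && (min(signal_channels) < 1 || max(signal_channels) > n_channels))
    stop("signal_channels out of range", call. = FALSE)
  if (length(signal_timepoints) && (min(signal_timepoints) < 1 || max(signal_timepoints) > n_timepoints))
    stop("signal_timepoints out of range", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  structure(list(n_timepoints = n_timepoints, n_channels = n_channels,
                 n_epochs = n_epochs, noise_mean = noise_mean, noise_sd = noise_sd,
                 signal_value = signal_value, signal_channels = signal_channels,
                 signal_timepoints = signal_timepoints, n_runs = n_runs,
                 ar1 = ar1, rng_seed = rng_seed),
            class = "synthetic_spec")
}

noise_array <- function(spec, n_epochs) {
  a <- array(stats::rnorm(spec$n_timepoints * spec$n_channels * n_epochs,
                          spec$noise_mean, spec$noise_sd),
             c(spec$n_timepoints, spec$n_channels, n_epochs))
  if (spec$ar1 > 0) {
    # AR(1) along time with the stationary marginal SD preserved
    innov_sd <- sqrt(1 - spec$ar1^2)
    for (t in 2:spec$n_timepoints)
      a[t, , ] <- spec$noise_mean + spec$ar1 * (a[t - 1, , ] - spec$noise_mean) +
        innov_sd * (a[t, , ] - spec$noise_mean)
  }
  a
}

#' Generate a pure-noise single-condition dataset
#'
#' @param spec a [synthetic_spec()] with `signal_value = 0`.
#' @return a one-condition [epoched_dataset()].
#' @export
simulate_noise_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$signal_value != 0)
    stop("noise generator requires signal_value = 0; use simulate_signal_dataset", call. = FALSE)
  simulate_signal_dataset(spec)
}

#' Generate a single-condition dataset with an additive constant signal
#'
#' Gaussian noise plus `signal_value` added exactly on
#' `signal_channels x signal_timepoints` in every epoch.
#'
#' @param spec a [synthetic_spec()].
#' @return a one-condition [epoched_dataset()].
#' @export
simulate_signal_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$rng_seed)
  per_run <- rep(spec$n_epochs %/% spec$n_runs, spec$n_runs)
  extra <- spec$n_epochs %% spec$n_runs
  if (extra > 0) per_run[seq_len(extra)] <- per_run[seq_len(extra)] + 1L
  cells <- matrix(vector("list", spec$n_runs), spec$n_runs, 1)
  for (r in seq_len(spec$n_runs)) {
    a <- noise_array(spec, per_run[r])
    if (spec$signal_value != 0 && length(spec$signal_channels) && length(spec$signal_timepoints))
      a[spec$signal_timepoints, spec$signal_channels, ] <-
        a[spec$signal_timepoints, spec$signal_channels, ] + spec$signal_value
    cells[[r, 1]] <- a
  }
  epoched_dataset(cells, sampling_rate_hz = 1000, epoch_start_ms = 0)
}

#' Combine single-condition datasets into one multi-condition dataset
#'
#' @param ... one-condition `epoched_dataset`s sharing dimensions and runs.
#' @return an `epoched_dataset` whose conditions are the inputs, in order.
#' @export
combine_conditions <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  nr <- n_runs(parts[[1]])
  cells <- matrix(vector("list", nr * length(parts)), nr, length(parts))
  labels <- NULL
  has_labels <- any(!vapply(parts, function(p) is.null(p$svr_labels), TRUE))
  if (has_labels) labels <- matrix(vector("list", nr * length(parts)), nr, length(parts))
  for (ck in seq_along(parts)) {
    p <- parts[[ck]]
    if (n_runs(p) != nr) stop("datasets differ in run count", call. = FALSE)
    for (r in seq_len(nr)) {
      cells[[r, ck]] <- p$data[[r, 1]]
      if (has_labels)
        labels[[r, ck]] <- p$svr_labels[[r, 1]] %||% rep(NA_real_, dim(p$data[[r, 1]])[3])
    }
  }
  epoched_dataset(cells, sampling_rate_hz = parts[[1]]$sampling_rate_hz,
                  epoch_start_ms = parts[[1]]$epoch_start_ms,
                  channel_names = parts[[1]]$channel_names,
                  svr_labels = labels)
}

#' Generate a synthetic group study
#'
#' One two-condition dataset per subject: condition 1 is pure noise,
#' condition 2 carries the additive signal. Subject-specific seeds are
#' derived from the spec seed. A stated fraction of subjects can receive no
#' signal (`heterogeneity`), which makes the design suitable for testing
#' prevalence inference.
#'
#' @param spec a [synthetic_spec()]; `signal_value` is the signal given to
#'   the carrying subjects.
#' @param n_subjects number of subjects (>= 2).
#' @param heterogeneity fraction of subjects whose signal is set to 0
#'   (the first `round(heterogeneity * n_subjects)` subjects).
#' @return list of `epoched_dataset`s, one per subject, with attribute
#'   `"carries_signal"` (logical vector).
#' @export
simulate_group_study <- function(spec, n_subjects, heterogeneity = 0) {
  stopifnot(inherits(spec, "synthetic_spec"), n_subjects >= 2)
  n_null <- round(heterogeneity * n_subjects)
  carries <- c(rep(FALSE, n_null), rep(TRUE, n_subjects - n_null))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sp_noise <- spec; sp_noise$signal_value <- 0
    sp_noise$rng_seed <- derive_seed(spec$rng_seed, i, 1L)
    sp_sig <- spec
    sp_sig$signal_value <- if (carries[i]) spec$signal_value else 0
    sp_sig$rng_seed <- derive_seed(spec$rng_seed, i, 2L)
    out[[i]] <- combine_conditions(simulate_signal_dataset(sp_noise),
                                   simulate_signal_dataset(sp_sig))
  }
  attr(out, "carries_signal") <- carries
  out
}

#' Generate a single-condition dataset with labels for regression
#'
#' Per-trial labels are drawn uniformly on [0, 1]; the signal-block
#' amplitude of each trial is `slope * label` plus noise, so a linear
#' read-out of the block recovers the label.
#'
#' @param spec a [synthetic_spec()] (its `signal_value` is ignored).
#' @param slope scaling of the label into the signal block.
#' @return a one-condition `epoched_dataset` with `svr_labels`.
#' @export
simulate_svr_dataset <- function(spec, slope) {
  stopifnot(inherits(spec, "synthetic_spec"), is.finite(slope))
  sp <- spec; sp$signal_value <- 0
  d <- simulate_signal_dataset(sp)
  set.seed(derive_seed(spec$rng_seed, 99L))
  labels <- matrix(vector("list", n_runs(d)), n_runs(d), 1)
  for (r in seq_len(n_runs(d))) {
    nt <- dim(d$data[[r, 1]])[3]
    lab <- stats::runif(nt)
    if (length(spec$signal_channels) && length(spec$signal_timepoints) && slope != 0) {
      for (tr in seq_len(nt))
        d$data[[r, 1]][spec$signal_timepoints, spec$signal_channels, tr] <-
          d$data[[r, 1]][spec$signal_timepoints, spec$signal_channels, tr] + slope * lab[tr]
    }
    labels[[r, 1]] <- lab
  }
  d$svr_labels <- labels
  validate_epoched_dataset(d)
}
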