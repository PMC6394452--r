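#' Sliding analysis-window grid
#'
#' Computes the grid of analysis time windows stepped through the epoch.
#' Windows that would run past the end of the epoch are dropped, never
#' truncated, so the feature dimensionality is constant across steps:
#' `n_steps = floor((T - width)/step) + 1`.
#'
#' @param n_timepoints epoch length T in samples.
#' @param width_samples window width in samples (1..T).
#' @param step_samples step size in samples (>= 1).
#' @return an object of class `window_plan` with 1-based window start
#'   indices, width, step and step count.
#' @export
window_plan <- function(n_timepoints, width_samples, step_samples) {
  stopifnot(step_samples >= 1)
  if (width_samples < 1 || width_samples > n_timepoints)
    stop(sprintf("window width %d samples does not fit an epoch of %d samples",
                 width_samples, n_timepoints), call. = FALSE)
  n_steps <- (n_timepoints - width_samples) %/% step_samples + 1L
  starts <- 1L + step_samples * (seq_len(n_steps) - 1L)
  structure(list(starts = as.integer(starts),
                 width_samples = as.integer(width_samples),
                 step_samples = as.integer(step_samples),
                 n_steps = as.integer(n_steps)),
            class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("Window plan: %d step(s), width %d, step %d; starts %s\n",
              x$n_steps, x$width_samples, x$step_samples,
              paste(utils::head(x$starts, 8), collapse = ",")))
  invisible(x)
}

# Feature layout: channel index for every feature position, fixed
# channel-major order for spatiotemporal mode (all window timepoints of
# channel 1, then channel 2, ...). Needed later to average weights per channel.
feature_layout <- function(mode, n_channels, width_samples, channel = NULL) {
  switch(mode,
    spatial = list(channel = seq_len(n_channels), offset = rep(0L, n_channels)),
    temporal = list(channel = rep(channel, width_samples), offset = seq_len(width_samples) - 1L),
    spatiotemporal = list(channel = rep(seq_len(n_channels), each = width_samples),
                          offset = rep(seq_len(width_samples) - 1L, n_channels)),
    stop("unknown mode: ", mode, call. = FALSE))
}

#' Extract per-trial feature vectors for one analysis window
#'
#' Builds the classifier input for one window of one dataset cell, in one of
#' three modes: `spatial` (within-window time average per channel; one
#' feature per channel), `temporal` (the raw window samples of a single
#' channel), or `spatiotemporal` (all samples of all channels, channel-major
#' order).
#'
#' @param arr 3-D array `timepoints x channels x trials`.
#' @param start 1-based first sample of the window.
#' @param width window width in samples.
#' @param mode one of `"spatial"`, `"temporal"`, `"spatiotemporal"`.
#' @param channel channel index, required for (and only for) temporal mode.
#' @return numeric matrix `trials x features`.
#' @export
extract_patterns <- function(arr, start, width, mode = c("spatial", "temporal", "spatiotemporal"),
                             channel = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(dim(arr)) == 3)
  Tn <- dim(arr)[1]; Ch <- dim(arr)[2]; Tr <- dim(arr)[3]
  if (start < 1 || start + width - 1 > Tn)
    stop("window does not fit within the epoch", call. = FALSE)
  if (mode == "temporal") {
    if (is.null(channel)) stop("temporal mode requires a channel index", call. = FALSE)
    if (channel < 1 || channel > Ch)
      stop(sprintf("channel %d out of range 1..%d", channel, Ch), call. = FALSE)
  } else if (!is.null(channel)) {
    stop("channel argument is only used in temporal mode", call. = FALSE)
  }
  win <- arr[start:(start + width - 1L), , , drop = FALSE]
  if (mode == "spatial") {
    # time-average per channel -> trials x channels
    m <- apply(win, c(2, 3), mean)
    t(m)
  } else if (mode == "temporal") {
    m <- win[, channel, , drop = FALSE]      # width x 1 x trials
    t(matrix(m, width, Tr))
  } else {
    # channel-major: all timepoints of channel 1, then channel 2, ...
    out <- matrix(0, Tr, Ch * width)
    for (ch in seq_len(Ch)) {
      out[, ((ch - 1L) * width + 1L):(ch * width)] <- t(matrix(win[, ch, ], width, Tr))
    }
    out
  }
}
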