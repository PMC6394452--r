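#' Epoched EEG dataset container
#'
#' Holds per-subject epoched amplitude data organised by experimental
#' run (block) and condition. Each cell is a 3-D numeric array of
#' `timepoints x channels x trials` (microvolts), the layout in which
#' epoched ERP data is conventionally exported for decoding. Optional
#' per-trial continuous labels (for support vector regression) mirror the
#' cell structure, one value per trial.
#'
#' @param data a list-matrix (`matrix` of mode list, runs in rows, conditions
#'   in columns) of 3-D arrays, or a plain list of such lists
#'   (`data[[run]][[cond]]`). All arrays must share the first two dimensions.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param epoch_start_ms time of the first sample relative to the event of
#'   interest, in ms (negative for a pre-event baseline).
#' @param channel_names optional character vector of channel labels.
#' @param svr_labels optional list-matrix matching `data`, each cell a numeric
#'   vector with one label per trial.
#' @return an object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(data, sampling_rate_hz, epoch_start_ms = 0,
                            channel_names = NULL, svr_labels = NULL) {
  if (is.list(data) && !is.matrix(data)) {
    nr <- length(data)
    nc <- length(data[[1]])
    cells <- matrix(vector("list", nr * nc), nr, nc)
    for (r in seq_len(nr)) for (ck in seq_len(nc)) cells[[r, ck]] <- data[[r]][[ck]]
    data <- cells
  }
  if (!is.null(svr_labels) && is.list(svr_labels) && !is.matrix(svr_labels)) {
    nr <- length(svr_labels); nc <- length(svr_labels[[1]])
    lab <- matrix(vector("list", nr * nc), nr, nc)
    for (r in seq_len(nr)) for (ck in seq_len(nc)) lab[[r, ck]] <- svr_labels[[r]][[ck]]
    svr_labels <- lab
  }
  obj <- structure(list(data = data,
                        sampling_rate_hz = sampling_rate_hz,
                        epoch_start_ms = epoch_start_ms,
                        channel_names = channel_names,
                        svr_labels = svr_labels),
                   class = "epoched_dataset")
  validate_epoched_dataset(obj)
}

#' Validate an epoched dataset
#'
#' Checks the container invariants: consistent timepoint/channel dimensions
#' across all run-by-condition cells, at least one trial per cell, and, when
#' regression labels are present, one label per trial.
#'
#' @param x an `epoched_dataset`.
#' @return `x`, invisibly unchanged, or an error describing every offending cell.
#' @export
validate_epoched_dataset <- function(x) {
  stopifnot(inherits(x, "epoched_dataset"))
  if (!is.matrix(x$data) || !is.list(x$data) || length(x$data) == 0)
    stop("data must be a non-empty run x condition list-matrix", call. = FALSE)
  if (!is.numeric(x$sampling_rate_hz) || x$sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  ref <- NULL
  bad <- character(0)
  for (r in seq_len(nrow(x$data))) for (ck in seq_len(ncol(x$data))) {
    a <- x$data[[r, ck]]
    if (is.null(a)) { bad <- c(bad, sprintf("(run %d, cond %d): empty cell", r, ck)); next }
    if (!is.numeric(a) || length(dim(a)) != 3) {
      bad <- c(bad, sprintf("(run %d, cond %d): not a 3-D numeric array", r, ck)); next
    }
    if (dim(a)[3] < 1) bad <- c(bad, sprintf("(run %d, cond %d): no trials", r, ck))
    if (is.null(ref)) ref <- dim(a)[1:2]
    else if (!all(dim(a)[1:2] == ref))
      bad <- c(bad, sprintf("(run %d, cond %d): dims %dx%d, expected %dx%d",
                            r, ck, dim(a)[1], dim(a)[2], ref[1], ref[2]))
  }
  if (length(bad)) stop("invalid epoched dataset:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  if (!is.null(x$channel_names) && length(x$channel_names) != ref[2])
    stop(sprintf("channel_names has %d entries but data has %d channels",
                 length(x$channel_names), ref[2]), call. = FALSE)
  if (!is.null(x$svr_labels)) {
    if (!all(dim(x$svr_labels) == dim(x$data)))
      stop("svr_labels must mirror the run x condition layout of data", call. = FALSE)
    for (r in seq_len(nrow(x$data))) for (ck in seq_len(ncol(x$data))) {
      nt <- dim(x$data[[r, ck]])[3]
      nl <- length(x$svr_labels[[r, ck]])
      if (nl != nt)
        stop(sprintf("(run %d, cond %d): %d labels for %d trials", r, ck, nl, nt), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf("Epoched EEG dataset: %d run(s) x %d condition(s)\n",
              n_runs(x), n_conditions(x)))
  cat(sprintf("  %d timepoints x %d channels @ %g Hz (epoch start %g ms)\n",
              n_timepoints(x), n_channels(x), x$sampling_rate_hz, x$epoch_start_ms))
  tr <- vapply(seq_len(n_conditions(x)), function(ck)
    sum(vapply(seq_len(n_runs(x)), function(r) dim(x$data[[r, ck]])[3], 0L)), 0L)
  cat("  trials per condition:", paste(tr, collapse = ", "), "\n")
  if (!is.null(x$svr_labels)) cat("  per-trial regression labels present\n")
  invisible(x)
}

#' @rdname epoched_dataset
#' @export
n_runs <- function(x) nrow(x$data)
#' @rdname epoched_dataset
#' @export
n_conditions <- function(x) ncol(x$data)
#' @rdname epoched_dataset
#' @export
n_timepoints <- function(x) dim(x$data[[1, 1]])[1]
#' @rdname epoched_dataset
#' @export
n_channels <- function(x) dim(x$data[[1, 1]])[2]

#' Reduce a dataset to selected conditions
#'
#' Restricts the dataset to the conditions of the discrimination group of
#' interest, re-indexed 1..n in the order given. The source object is not
#' modified. For regression a single condition is selected.
#'
#' @param dataset an `epoched_dataset`.
#' @param conditions integer vector of 1-based condition indices.
#' @return a new `epoched_dataset` with `length(conditions)` conditions.
#' @export
reduce_conditions <- function(dataset, conditions) {
  validate_epoched_dataset(dataset)
  conditions <- as.integer(conditions)
  nc <- n_conditions(dataset)
  if (any(conditions < 1 | conditions > nc))
    stop(sprintf("unknown condition index %s (dataset has %d conditions)",
                 paste(conditions[conditions < 1 | conditions > nc], collapse = ", "), nc),
         call. = FALSE)
  out <- dataset
  out$data <- dataset$data[, conditions, drop = FALSE]
  if (!is.null(dataset$svr_labels))
    out$svr_labels <- dataset$svr_labels[, conditions, drop = FALSE]
  validate_epoched_dataset(out)
}
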