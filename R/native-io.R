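#' Native on-disk container for epoched datasets
#'
#' The native format is a directory holding a JSON manifest (dimensions,
#' sampling rate, epoch start, channel names, regression labels) plus one
#' raw little-endian float64 file per run-by-condition cell — transparent to
#' diff and cheap to load partially. Round trips are exact.
#'
#' @param dataset an `epoched_dataset`.
#' @param path directory to create (or overwrite).
#' @return `path` (write) or an `epoched_dataset` (read).
#' @export
write_native <- function(dataset, path) {
  validate_epoched_dataset(dataset)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nr <- n_runs(dataset); nc <- n_conditions(dataset)
  cells <- list()
  for (r in seq_len(nr)) for (ck in seq_len(nc)) {
    a <- dataset$data[[r, ck]]
    fn <- sprintf("run%02d_cond%02d.f64", r, ck)
    writeBin(as.numeric(a), file.path(path, fn), size = 8, endian = "little")
    lf <- NULL
    if (!is.null(dataset$svr_labels)) {
      lf <- sprintf("run%02d_cond%02d_labels.f64", r, ck)
      writeBin(as.numeric(dataset$svr_labels[[r, ck]]), file.path(path, lf),
               size = 8, endian = "little")
    }
    cells[[length(cells) + 1L]] <- list(run = r, condition = ck, file = fn,
                                        dim = dim(a), labels_file = lf)
  }
  manifest <- list(format = "erpdecode-native", version = 1L,
                   n_runs = nr, n_conditions = nc,
                   n_timepoints = n_timepoints(dataset),
                   n_channels = n_channels(dataset),
                   sampling_rate_hz = dataset$sampling_rate_hz,
                   epoch_start_ms = dataset$epoch_start_ms,
                   channel_names = dataset$channel_names,
                   has_labels = !is.null(dataset$svr_labels),
                   cells = cells)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_native
#' @export
read_native <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("not a native dataset directory (missing manifest.json): ", path, call. = FALSE)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(m$format, "erpdecode-native"))
    stop("manifest does not describe an erpdecode native dataset", call. = FALSE)
  nr <- m$n_runs; nc <- m$n_conditions
  cells <- matrix(vector("list", nr * nc), nr, nc)
  labels <- if (isTRUE(m$has_labels)) matrix(vector("list", nr * nc), nr, nc)
  for (i in seq_len(nrow(m$cells))) {
    ce <- m$cells[i, ]
    dm <- unlist(ce$dim)
    v <- readBin(file.path(path, ce$file), "numeric", prod(dm), size = 8, endian = "little")
    dim(v) <- dm
    cells[[ce$run, ce$condition]] <- v
    if (!is.null(labels))
      labels[[ce$run, ce$condition]] <-
        readBin(file.path(path, ce$labels_file), "numeric", dm[3], size = 8, endian = "little")
  }
  epoched_dataset(cells, sampling_rate_hz = m$sampling_rate_hz,
                  epoch_start_ms = m$epoch_start_ms,
                  channel_names = if (length(m$channel_names)) m$channel_names,
                  svr_labels = labels)
}
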