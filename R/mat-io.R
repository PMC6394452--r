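# Minimal MATLAB MAT (level 5 / v7) reader and writer.
#
# Supports what the epoched-data interchange format needs: numeric arrays
# (double/single/int classes) and cell arrays, little-endian files,
# including zlib-compressed (v7) data elements. v7.3 files are HDF5
# containers and are rejected with a pointer to resave as v7/-v6.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_CELL <- 1L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L

mat_read_numeric <- function(bytes, mitype) {
  switch(as.character(mitype),
    "1" = as.double(readBin(bytes, "integer", length(bytes), size = 1, signed = TRUE)),
    "2" = as.double(readBin(bytes, "integer", length(bytes), size = 1, signed = FALSE)),
    "3" = as.double(readBin(bytes, "integer", length(bytes) / 2, size = 2, signed = TRUE, endian = "little")),
    "4" = as.double(readBin(bytes, "integer", length(bytes) / 2, size = 2, signed = FALSE, endian = "little")),
    "5" = as.double(readBin(bytes, "integer", length(bytes) / 4, size = 4, endian = "little")),
    "6" = {
      v <- readBin(bytes, "integer", length(bytes) / 4, size = 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    "7" = readBin(bytes, "numeric", length(bytes) / 4, size = 4, endian = "little"),
    "9" = readBin(bytes, "numeric", length(bytes) / 8, size = 8, endian = "little"),
    "12" = readBin(bytes, "numeric", length(bytes) / 8, size = 8, endian = "little"),
    "13" = readBin(bytes, "numeric", length(bytes) / 8, size = 8, endian = "little"),
    stop(sprintf("unsupported MAT data type %d", mitype), call. = FALSE))
}

# Parse the sequence of data elements in `raw`, starting at offset `pos`
# (1-based); returns list of parsed elements. Each element is parsed by
# mat_parse_element which returns list(name=, value=) for miMATRIX.
mat_parse_stream <- function(raw, pos = 1L) {
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    type <- readBin(raw[pos:(pos + 3L)], "integer", 1, size = 4, endian = "little")
    small <- bitwAnd(type, -65536L) != 0L   # upper 16 bits set -> small element
    if (small) {
      nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16)
      type <- bitwAnd(type, 65535L)
      body <- raw[(pos + 4L):(pos + 3L + nbytes)]
      pos <- pos + 8L
    } else {
      nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, size = 4, endian = "little")
      body <- if (nbytes > 0) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
      pad <- if (type == MI_COMPRESSED) 0L else (8L - nbytes %% 8L) %% 8L
      pos <- pos + 8L + nbytes + pad
    }
    if (type == MI_COMPRESSED) {
      inner <- memDecompress(body, type = "gzip")
      out <- c(out, mat_parse_stream(inner, 1L))
    } else if (type == MI_MATRIX) {
      out[[length(out) + 1L]] <- mat_parse_matrix(body)
    }
    # other top-level types (e.g. padding) ignored
  }
  out
}

# Parse the body of one miMATRIX element.
mat_parse_matrix <- function(body) {
  sub <- mat_subelements(body)
  flags <- readBin(sub[[1]]$bytes[1:4], "integer", 1, size = 4, endian = "little")
  mxclass <- bitwAnd(flags, 255L)
  dims <- readBin(sub[[2]]$bytes, "integer", length(sub[[2]]$bytes) / 4, size = 4, endian = "little")
  nm <- rawToChar(sub[[3]]$bytes)
  if (mxclass == MX_CELL) {
    cells <- vector("list", prod(dims))
    ci <- 1L
    for (k in seq(4L, length(sub))) {
      if (sub[[k]]$type != MI_MATRIX) next
      cells[[ci]] <- mat_parse_matrix(sub[[k]]$bytes)$value
      ci <- ci + 1L
    }
    dim(cells) <- dims
    list(name = nm, value = cells)
  } else if (mxclass == MX_CHAR) {
    v <- mat_read_numeric(sub[[4]]$bytes, if (sub[[4]]$type == 16L) MI_UINT8 else sub[[4]]$type)
    list(name = nm, value = intToUtf8(v[v > 0]))
  } else if (mxclass >= 6L && mxclass <= 13L) {
    v <- mat_read_numeric(sub[[4]]$bytes, sub[[4]]$type)
    if (length(dims) > 1) dim(v) <- dims
    list(name = nm, value = v)
  } else {
    list(name = nm, value = NULL)
  }
}

# Split a miMATRIX body into its sub-elements (tag walk).
mat_subelements <- function(body) {
  out <- list(); pos <- 1L; n <- length(body)
  while (pos + 7L <= n) {
    type <- readBin(body[pos:(pos + 3L)], "integer", 1, size = 4, endian = "little")
    small <- bitwAnd(type, -65536L) != 0L
    if (small) {
      nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16)
      type <- bitwAnd(type, 65535L)
      bytes <- if (nbytes > 0) body[(pos + 4L):(pos + 3L + nbytes)] else raw(0)
      pos <- pos + 8L
    } else {
      nbytes <- readBin(body[(pos + 4L):(pos + 7L)], "integer", 1, size = 4, endian = "little")
      bytes <- if (nbytes > 0) body[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
      pos <- pos + 8L + nbytes + (8L - nbytes %% 8L) %% 8L
    }
    out[[length(out) + 1L]] <- list(type = type, bytes = bytes)
  }
  out
}

# Read all supported variables of a MAT file into a named list.
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT file: ", path, call. = FALSE)
  header <- rawToChar(raw[1:19])
  if (!startsWith(header, "MATLAB")) stop("not a MATLAB MAT file: ", path, call. = FALSE)
  if (grepl("MATLAB 7.3", header))
    stop("MAT v7.3 (HDF5) files are not supported; resave with MATLAB's ",
         "save(..., '-v7') or scipy.io.savemat", call. = FALSE)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("big-endian MAT files are not supported", call. = FALSE)
  els <- mat_parse_stream(raw, 129L)
  vals <- lapply(els, `[[`, "value")
  names(vals) <- vapply(els, `[[`, "", "name")
  vals
}

mat_tag <- function(type, bytes) {
  n <- length(bytes)
  c(writeBin(as.integer(c(type, n)), raw(), size = 4, endian = "little"),
    bytes, raw((8L - n %% 8L) %% 8L))
}

mat_numeric_element <- function(a, mxclass = MX_DOUBLE) {
  dims <- dim(a) %||% c(1L, length(a))
  flags <- mat_tag(MI_UINT32, writeBin(c(mxclass, 0L), raw(), size = 4, endian = "little"))
  dimel <- mat_tag(MI_INT32, writeBin(as.integer(dims), raw(), size = 4, endian = "little"))
  nameel <- mat_tag(MI_INT8, raw(0))
  data <- mat_tag(MI_DOUBLE, writeBin(as.numeric(a), raw(), size = 8, endian = "little"))
  c(flags, dimel, nameel, data)
}

mat_matrix_element <- function(name, value) {
  if (is.list(value)) {
    dims <- dim(value) %||% c(1L, length(value))
    flags <- mat_tag(MI_UINT32, writeBin(c(MX_CELL, 0L), raw(), size = 4, endian = "little"))
    dimel <- mat_tag(MI_INT32, writeBin(as.integer(dims), raw(), size = 4, endian = "little"))
    nameel <- mat_tag(MI_INT8, charToRaw(name))
    cells <- lapply(value, function(v) mat_tag(MI_MATRIX, mat_numeric_element(v)))
    body <- c(flags, dimel, nameel, do.call(c, cells))
  } else {
    dims <- dim(value) %||% c(1L, length(value))
    flags <- mat_tag(MI_UINT32, writeBin(c(MX_DOUBLE, 0L), raw(), size = 4, endian = "little"))
    dimel <- mat_tag(MI_INT32, writeBin(as.integer(dims), raw(), size = 4, endian = "little"))
    nameel <- mat_tag(MI_INT8, charToRaw(name))
    data <- mat_tag(MI_DOUBLE, writeBin(as.numeric(value), raw(), size = 8, endian = "little"))
    body <- c(flags, dimel, nameel, data)
  }
  mat_tag(MI_MATRIX, body)
}

# Write a named list of numeric arrays / cell list-matrices as MAT level 5.
write_mat <- function(vars, path) {
  txt <- sprintf("MATLAB 5.0 MAT-file, written by erpdecode on %s", format(Sys.time(), "%Y-%m-%d"))
  # 116-byte text, 8-byte subsystem offset, version 0x0100, endian tag "IM"
  header <- c(charToRaw(txt), rep(as.raw(0x20), 116 - nchar(txt)), raw(8),
              as.raw(c(0x00, 0x01)), charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) body <- c(body, mat_matrix_element(nm, vars[[nm]]))
  writeBin(c(header, body), path)
  invisible(path)
}

#' Read an epoched EEG dataset from a MAT file
#'
#' Reads the conventional run-by-condition cell-array layout
#' (`eeg_sorted_cond{run, cond}`, each cell `timepoints x channels x trials`)
#' from a MATLAB MAT (v5/v6/v7) file. Because the MAT layout carries no
#' acquisition metadata, the sampling rate and epoch start are supplied by
#' the caller. An optional companion cell array of per-trial continuous
#' labels (for regression) can be read from the same or another variable.
#'
#' @param path path to the MAT file.
#' @param data_var name of the cell-array variable (default
#'   `"eeg_sorted_cond"`).
#' @param labels_var optional name of the cell-array variable holding one
#'   numeric label per trial (same run x condition layout).
#' @param sampling_rate_hz,epoch_start_ms,channel_names dataset metadata,
#'   see [epoched_dataset()].
#' @return an `epoched_dataset`.
#' @export
read_mat_dataset <- function(path, data_var = "eeg_sorted_cond", labels_var = NULL,
                             sampling_rate_hz = 1000, epoch_start_ms = 0,
                             channel_names = NULL) {
  vars <- read_mat(path)
  if (!data_var %in% names(vars))
    stop(sprintf("MAT file does not contain the expected variable '%s' (found: %s)",
                 data_var, paste(names(vars), collapse = ", ")), call. = FALSE)
  cells <- vars[[data_var]]
  if (!is.list(cells) || length(cells) == 0)
    stop(sprintf("'%s' is not a non-empty cell array", data_var), call. = FALSE)
  if (is.null(dim(cells))) dim(cells) <- c(1L, length(cells))
  cells <- apply_cells(cells, function(a) {
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)  # single-trial cells
    a
  })
  labels <- NULL
  if (!is.null(labels_var)) {
    if (!labels_var %in% names(vars))
      stop(sprintf("MAT file does not contain the label variable '%s'", labels_var), call. = FALSE)
    lv <- vars[[labels_var]]
    if (!is.list(lv)) lv <- list(as.numeric(lv))
    if (is.null(dim(lv))) dim(lv) <- dim(cells)
    labels <- apply_cells(lv, as.numeric)
  }
  epoched_dataset(cells, sampling_rate_hz = sampling_rate_hz,
                  epoch_start_ms = epoch_start_ms, channel_names = channel_names,
                  svr_labels = labels)
}

apply_cells <- function(cells, f) {
  out <- cells
  for (i in seq_along(cells)) out[[i]] <- f(cells[[i]])
  out
}

#' Write an epoched EEG dataset to a MAT (v5) file
#'
#' Writes the run-by-condition cell-array layout readable by
#' [read_mat_dataset()] and by MATLAB/scipy.
#'
#' @param dataset an `epoched_dataset`.
#' @param path output path.
#' @param data_var,labels_var variable names to use.
#' @return the path, invisibly.
#' @export
write_mat_dataset <- function(dataset, path, data_var = "eeg_sorted_cond",
                              labels_var = "svr_labels") {
  validate_epoched_dataset(dataset)
  vars <- list()
  vars[[data_var]] <- dataset$data
  if (!is.null(dataset$svr_labels)) vars[[labels_var]] <- dataset$svr_labels
  write_mat(vars, path)
}
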