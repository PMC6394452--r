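# Result plots: information time courses and channel maps (base graphics).

open_figure_device <- function(path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdf = grDevices::pdf(path, width = width, height = height),
    png = grDevices::png(path, width = width * 100, height = height * 100, res = 100),
    tiff = , tif = grDevices::tiff(path, width = width * 100, height = height * 100, res = 100),
    eps = grDevices::postscript(path, width = width, height = height,
                                onefile = FALSE, horizontal = FALSE, paper = "special"),
    stop("unknown figure format '", ext, "'; supported: pdf, png, tiff, eps", call. = FALSE))
}

#' Plot a single-subject decoding time course
#'
#' Mean performance per analysis window against window start time (ms,
#' derived from the epoch start and sampling rate), with the theoretical
#' chance level as reference and the permuted-label trace overlaid when
#' available.
#'
#' @param x an `erp_decoding` fit.
#' @param file optional output file (pdf/png/tiff/eps); plots to the active
#'   device when `NULL`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.erp_decoding <- function(x, file = NULL, ...) {
  if (!is.null(file)) { open_figure_device(file); on.exit(grDevices::dev.off()) }
  ylab <- if (x$analysis == "classification") "Classification accuracy (%)" else "Fisher-Z correlation"
  rng <- range(c(x$accuracy, x$permuted_accuracy, x$chance))
  graphics::plot(x$times_ms, x$accuracy, type = "o", pch = 16,
                 xlab = "Window start (ms)", ylab = ylab, ylim = rng, ...)
  graphics::abline(h = x$chance, lty = 3, col = "grey40")
  if (!is.null(x$permuted_accuracy))
    graphics::lines(x$times_ms, x$permuted_accuracy, type = "o", pch = 1, col = "blue")
  invisible(x)
}

#' Plot a group decoding time course
#'
#' Group mean performance with standard-error bars, the permuted-label
#' group trace when available, the chance reference, and shading of the
#' windows significant after the chosen correction.
#'
#' @param x an `erp_group` object.
#' @param file optional output file (pdf/png/tiff/eps).
#' @param ... passed to [graphics::plot()].
#' @export
plot.erp_group <- function(x, file = NULL, ...) {
  if (!is.null(file)) { open_figure_device(file); on.exit(grDevices::dev.off()) }
  sm <- x$subject_matrix
  mu <- colMeans(sm)
  se <- apply(sm, 2, stats::sd) / sqrt(nrow(sm))
  ylab <- if (x$analysis == "classification") "Classification accuracy (%)" else "Fisher-Z correlation"
  rng <- range(c(mu + se, mu - se, x$chance_level,
                 if (!is.null(x$permuted_matrix)) colMeans(x$permuted_matrix)))
  graphics::plot(x$times_ms, mu, type = "n", xlab = "Window start (ms)",
                 ylab = ylab, ylim = rng, ...)
  if (any(x$significant_mask)) {
    step <- if (length(x$times_ms) > 1) diff(x$times_ms)[1] else 1
    for (s in which(x$significant_mask))
      graphics::rect(x$times_ms[s], rng[1], x$times_ms[s] + step, rng[2],
                     col = grDevices::adjustcolor("orange", 0.25), border = NA)
  }
  pos <- se > 0
  if (any(pos))
    graphics::arrows(x$times_ms[pos], (mu - se)[pos], x$times_ms[pos], (mu + se)[pos],
                     angle = 90, code = 3, length = 0.03, col = "grey30")
  graphics::lines(x$times_ms, mu, type = "o", pch = 16)
  if (!is.null(x$permuted_matrix))
    graphics::lines(x$times_ms, colMeans(x$permuted_matrix), type = "o", pch = 1, col = "blue")
  graphics::abline(h = x$chance_level, lty = 3, col = "grey40")
  invisible(x)
}

#' Plot per-channel values as a channel map
#'
#' With electrode coordinates (a data frame with `x`, `y` and optionally
#' `name` per channel) values are drawn as a colour-coded top-view scalp
#' layout; without coordinates the display degrades to an ordered bar
#' strip over channel index.
#'
#' @param values numeric vector, one value per channel.
#' @param coords optional data frame of 2-D electrode coordinates.
#' @param file optional output file (pdf/png/tiff/eps).
#' @param main plot title.
#' @export
plot_channel_map <- function(values, coords = NULL, file = NULL, main = "Channel map") {
  if (!is.null(file)) { open_figure_device(file); on.exit(grDevices::dev.off()) }
  if (is.null(coords)) {
    graphics::barplot(values, names.arg = seq_along(values), main = main,
                      xlab = "Channel", ylab = "Value", border = NA, col = "steelblue")
  } else {
    stopifnot(nrow(coords) == length(values))
    pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
    idx <- cut(values, breaks = 64, labels = FALSE)
    graphics::plot(coords$x, coords$y, pch = 21, cex = 3, bg = pal[idx],
                   axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
    if (!is.null(coords$name))
      graphics::text(coords$x, coords$y, coords$name, cex = 0.5)
  }
  invisible(values)
}
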