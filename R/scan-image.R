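#' Calibrated scanning-probe image
#'
#' A `scan_image` wraps a rectangular grid of measured values together with
#' its physical calibration: the (isotropic) pixel size in nanometres and the
#' measurement channel. Topography images carry heights in nm; potential
#' images carry contact potential difference (CPD) in mV. Row 1 is the top
#' scan line and the column index increases along the fast scan axis; pixel
#' `[i, j]` is centred at `((i - 0.5) * pixel_size, (j - 0.5) * pixel_size)`.
#'
#' @param values Numeric matrix of measurements, at least 8 x 8, all finite.
#' @param pixel_size Pixel edge length in nm (> 0).
#' @param channel `"topography"` (values in nm) or `"potential"` (values in mV).
#' @param metadata Named list of free-form strings (instrument, composition,
#'   surface pressure, ...).
#'
#' @return An object of class `scan_image`.
#' @examples
#' img <- scan_image(matrix(rnorm(64), 8), pixel_size = 10)
#' img
#' @export
scan_image <- function(values, pixel_size, channel = c("topography", "potential"),
                       metadata = list()) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("validation_error", "`values` must be a numeric matrix")
  if (nrow(values) < 8L || ncol(values) < 8L)
    stopf("validation_error", "scan images must be at least 8 x 8 pixels (got %d x %d)",
          nrow(values), ncol(values))
  if (!all(is.finite(values)))
    stopf("validation_error", "scan image contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stopf("validation_error", "`pixel_size` must be a single positive number (nm)")
  structure(
    list(values = unname(values), pixel_size = as.numeric(pixel_size),
         channel = channel, metadata = metadata),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d x %d px, %.4g nm/px, channel = %s (%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$channel,
              scan_units(x)))
  cat(sprintf("  range: [%.4g, %.4g] %s\n", min(x$values), max(x$values),
              scan_units(x)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.scan_image <- function(x) dim(x$values)

scan_units <- function(image) {
  switch(image$channel, topography = "nm", potential = "mV")
}

# Reject operations that mix channels (e.g. subtracting mV from nm).
check_channel <- function(image, channel) {
  if (!image$channel %in% channel)
    stopf("validation_error", "expected a %s image, got channel '%s'",
          paste(channel, collapse = "/"), image$channel)
  invisible(image)
}

#' Convert a scan image to a long tibble
#'
#' One row per pixel with physical coordinates (nm, y measured down from the
#' top scan line) and the measured value — convenient for ggplot2 and dplyr.
#'
#' @param x A [scan_image()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x_nm`, `y_nm`, `value`.
#' @export
tidy.scan_image <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values)
  ) |>
    dplyr::mutate(
      x_nm = (.data$col - 0.5) * x$pixel_size,
      y_nm = (.data$row - 0.5) * x$pixel_size
    ) |>
    dplyr::select("row", "col", "x_nm", "y_nm", "value")
}

#' @export
glance.scan_image <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$values), n_cols = ncol(x$values),
    pixel_size_nm = x$pixel_size, channel = x$channel,
    units = scan_units(x),
    min = min(x$values), max = max(x$values),
    mean = mean(x$values), sd = stats::sd(as.vector(x$values))
  )
}

#' Plot a scan image as a calibrated raster
#'
#' @param object A [scan_image()].
#' @param ... Unused.
#' @return A ggplot object; the fill scale is labelled with the channel units.
#' @export
autoplot.scan_image <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = scan_units(object)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("%s image", object$channel))
}
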