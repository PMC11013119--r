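#' Read a scan image from disk
#'
#' Two plain dialects are supported. `ascii_matrix` is a Gwyddion-style text
#' export: optional `#`-prefixed header lines of the form `# key: value`
#' (recognised keys `pixel_size_nm`, `channel`, `units`) followed by one
#' whitespace-separated row of numbers per scan line. `float_tiff` is an
#' uncompressed single-strip grayscale TIFF with IEEE floating-point samples
#' (32- or 64-bit), as written by [write_scan()]; calibration is carried in
#' the ImageDescription tag.
#'
#' Header/tag metadata, when present, overrides the `pixel_size` and
#' `channel` arguments.
#'
#' @param path Path to the file.
#' @param dialect `"ascii_matrix"` or `"float_tiff"`.
#' @param pixel_size Fallback pixel size in nm when the file has no header.
#' @param channel Fallback channel when the file has no header.
#' @return A [scan_image()].
#' @seealso [write_scan()]
#' @export
read_scan <- function(path, dialect = c("ascii_matrix", "float_tiff"),
                      pixel_size = 1, channel = "topography") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stopf("io_error", "file not found: %s", path)
  parsed <- switch(dialect,
    ascii_matrix = read_ascii_matrix(path),
    float_tiff = read_float_tiff(path)
  )
  hdr <- parsed$header
  if (!is.null(hdr$pixel_size_nm)) pixel_size <- as.numeric(hdr$pixel_size_nm)
  if (!is.null(hdr$channel)) channel <- hdr$channel
  meta <- hdr[setdiff(names(hdr), c("pixel_size_nm", "channel", "units"))]
  scan_image(parsed$values, pixel_size = pixel_size, channel = channel,
             metadata = meta)
}

#' Write a scan image to disk
#'
#' `ascii_matrix` stores values with 9 significant digits (round trips to
#' better than 1e-8 relative); `float_tiff` stores raw IEEE floats and round
#' trips exactly at 64-bit (the default). Calibration metadata
#' (`pixel_size_nm`, `channel`, `units`) is written to the ASCII header or
#' the TIFF ImageDescription tag and is recovered by [read_scan()].
#'
#' @param image A [scan_image()].
#' @param path Output path.
#' @param dialect `"ascii_matrix"` or `"float_tiff"`.
#' @param bits Sample width for `float_tiff`: 64 (exact) or 32.
#' @return `path`, invisibly.
#' @export
write_scan <- function(image, path, dialect = c("ascii_matrix", "float_tiff"),
                       bits = 64L) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(image, "scan_image"))
  switch(dialect,
    ascii_matrix = write_ascii_matrix(image, path),
    float_tiff = write_float_tiff(image, path, bits = bits)
  )
  invisible(path)
}

# ---- ASCII matrix dialect -------------------------------------------------

read_ascii_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(trimws(lines), "#")
  header <- list()
  for (h in lines[is_hdr]) {
    h <- sub("^\\s*#\\s*", "", h)
    m <- regmatches(h, regexec("^([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) header[[trimws(m[2])]] <- trimws(m[3])
  }
  data_lines <- lines[!is_hdr & nzchar(trimws(lines))]
  if (!length(data_lines))
    stopf("parse_error", "no data rows in %s", path)
  rows <- lapply(strsplit(trimws(data_lines), "\\s+"), as.numeric)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stopf("parse_error",
          "ragged matrix in %s: row %d has %d values, expected %d",
          path, bad, widths[bad], widths[1])
  }
  values <- do.call(rbind, rows)
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!apply(is.finite(values), 1, all))[1]
    stopf("validation_error", "non-finite entry in %s at row %d", path, bad)
  }
  list(values = values, header = header)
}

write_ascii_matrix <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pixel_size_nm: %s", format(image$pixel_size, digits = 12)),
    sprintf("# channel: %s", image$channel),
    sprintf("# units: %s", scan_units(image))
  ), con)
  if (length(image$metadata))
    writeLines(sprintf("# %s: %s", names(image$metadata),
                       vapply(image$metadata, as.character, "")), con)
  apply(image$values, 1, function(r)
    paste(formatC(r, digits = 9, format = "g"), collapse = " ")) |>
    writeLines(con)
}

# ---- minimal float TIFF ---------------------------------------------------
# Single-strip, uncompressed, little-endian grayscale TIFF with IEEE
# floating-point samples. Written by hand because general-purpose TIFF
# writers in R quantize to [0, 1]; scan data are nm/mV-scale floats and the
# round trip must be exact.

write_float_tiff <- function(image, path, bits = 64L) {
  bits <- as.integer(bits)
  if (!bits %in% c(32L, 64L))
    stopf("validation_error", "float_tiff bits must be 32 or 64")
  v <- image$values
  h <- nrow(v); w <- ncol(v)
  desc <- sprintf("pixel_size_nm=%s;channel=%s;units=%s",
                  format(image$pixel_size, digits = 12), image$channel,
                  scan_units(image))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0))
  data_len <- h * w * (bits %/% 8L)
  desc_off <- 8L + data_len
  ifd_off <- desc_off + length(desc_raw)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  # pixel data, row-major (row 1 = top scan line)
  writeBin(as.numeric(t(v)), con, size = bits %/% 8L, endian = "little")
  writeBin(desc_raw, con)
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entries <- list(
    c(256L, 4L, 1L, w),                       # ImageWidth
    c(257L, 4L, 1L, h),                       # ImageLength
    c(258L, 3L, 1L, bits),                    # BitsPerSample
    c(259L, 3L, 1L, 1L),                      # Compression = none
    c(262L, 3L, 1L, 1L),                      # Photometric = BlackIsZero
    c(270L, 2L, length(desc_raw), desc_off),  # ImageDescription
    c(273L, 4L, 1L, 8L),                      # StripOffsets
    c(277L, 3L, 1L, 1L),                      # SamplesPerPixel
    c(278L, 4L, 1L, h),                       # RowsPerStrip
    c(279L, 4L, 1L, data_len),                # StripByteCounts
    c(339L, 3L, 1L, 3L)                       # SampleFormat = IEEE float
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) entry(e[1], e[2], e[3], e[4])
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

read_float_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4,
                               endian = "little")
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stopf("parse_error", "%s is not a little-endian TIFF", path)
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tags[[as.character(u16(off))]] <-
      list(type = u16(off + 2L), count = u32(off + 4L), value = u32(off + 8L))
  }
  need <- function(tag, default = NULL) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) {
      if (is.null(default)) stopf("parse_error", "TIFF tag %d missing", tag)
      return(default)
    }
    t$value
  }
  if (need(259, 1L) != 1L)
    stopf("parse_error", "compressed TIFF not supported")
  if (need(339, 1L) != 3L)
    stopf("parse_error", "only IEEE-float TIFF samples supported")
  w <- need(256); h <- need(257); bits <- need(258)
  if (!bits %in% c(32L, 64L))
    stopf("parse_error", "unsupported float TIFF bit depth %d", bits)
  strip <- need(273)
  n <- h * w
  vals <- readBin(raw[strip + seq_len(n * (bits %/% 8L))], "double",
                  n = n, size = bits %/% 8L, endian = "little")
  if (!all(is.finite(vals)))
    stopf("validation_error", "non-finite entry in %s", path)
  header <- list()
  dtag <- tags[["270"]]
  if (!is.null(dtag)) {
    dr <- raw[dtag$value + seq_len(dtag$count)]
    dr <- dr[dr != as.raw(0)]
    for (kv in strsplit(rawToChar(dr), ";")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L) header[[trimws(p[1])]] <- trimws(p[2])
    }
  }
  list(values = matrix(vals, nrow = h, byrow = TRUE), header = header)
}
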