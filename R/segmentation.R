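#' Plane and scan-line levelling
#'
#' Removes the slow background that Langmuir-Blodgett deposition and scanner
#' drift superimpose on raw topography before any histogram analysis:
#' subtracts the global least-squares plane (`order = 1`) or the mean
#' (`order = 0`), and optionally each scan line's median (`per_line = TRUE`,
#' scan lines being matrix rows), which suppresses the streak/striation
#' artifacts aligned with the fast axis.
#'
#' For two-phase films a plain fit is biased by the phase pattern itself:
#' the high domains pull the fitted plane, and a plain per-line median
#' shears any scan line that is majority high-phase. `per_line = TRUE`
#' therefore performs a masked flatten, the standard practice for
#' phase-separated scanning-probe images: pixels are roughly classified by
#' Otsu's threshold, the plane is refitted on matrix-phase (low) pixels
#' only, per-line offsets are medians over each line's matrix-phase pixels
#' (lines with too few inherit interpolated offsets from their
#' neighbours), and the classification is refined once.
#'
#' @param image A [scan_image()] (either channel).
#' @param order 0 (constant) or 1 (plane).
#' @param per_line Also subtract per-scan-line (row) median offsets.
#' @return A levelled [scan_image()]; mean approximately 0.
#' @export
level_image <- function(image, order = 1, per_line = FALSE) {
  stopifnot(inherits(image, "scan_image"))
  v <- image$values
  if (diff(range(v)) == 0) {
    warn("constant image: levelling returns an all-zero image")
    out <- image
    out$values <- v * 0
    return(out)
  }
  if (!order %in% c(0, 1))
    stopf("validation_error", "order must be 0 or 1")
  if (order == 0) {
    v <- v - mean(v)
  } else {
    # least-squares plane on a regular grid: row/col slopes decouple
    r <- row(v) - (nrow(v) + 1) / 2
    cc <- col(v) - (ncol(v) + 1) / 2
    b_r <- sum(r * v) / sum(r * r)
    b_c <- sum(cc * v) / sum(cc * cc)
    v <- v - mean(v) - b_r * r - b_c * cc
  }
  if (per_line) {
    v0 <- v
    low <- v0 < otsu_threshold(v0)
    for (it in 1:2) {
      v <- v0
      if (order == 1 && sum(low) > 16L && sum(!low) > 0L) {
        # refit the plane on matrix-phase pixels only: high domains pull a
        # full-image fit whenever they cluster toward one corner
        r <- row(v0) - (nrow(v0) + 1) / 2
        cc <- col(v0) - (ncol(v0) + 1) / 2
        X <- cbind(1, r[low], cc[low])
        beta <- qr.coef(qr(X), v0[low])
        v <- v0 - (beta[1] + beta[2] * r + beta[3] * cc)
      }
      off <- vapply(seq_len(nrow(v)), function(i) {
        li <- low[i, ]
        if (sum(li) >= 8L) median(v[i, li]) else NA_real_
      }, 0)
      if (anyNA(off)) {
        idx <- which(!is.na(off))
        if (!length(idx)) off <- apply(v, 1, median)
        else off <- stats::approx(idx, off[idx], xout = seq_along(off),
                                  rule = 2)$y
      }
      v <- v - off
      if (it == 1L) low <- v < otsu_threshold(v)
    }
    v <- v - mean(v)
  }
  out <- image
  out$values <- v
  out
}

# Otsu's threshold (maximum between-class variance) on a 256-bin
# histogram; deterministic rough classifier used by the masked flatten.
otsu_threshold <- function(v) {
  v <- as.vector(v)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  n_bins <- 256L
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE),
                               1L), n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Bimodal histogram threshold
#'
#' Implements the minimum-between-two-peaks rule used to separate
#' coexisting monolayer phases: build an `n_bins` histogram of pixel
#' values, smooth the counts with a moving average starting at
#' `smooth_bandwidth` bins and widening until at most two local maxima
#' survive (the classical successive-smoothing minimum method), and return
#' the centre of the lowest bin strictly between the two surviving peaks.
#' Peaks closer than 10 bins, or a valley shallower than 80% of the lower
#' peak, indicate the image is not genuinely two-phase.
#'
#' @param image A levelled [scan_image()].
#' @param n_bins Number of histogram bins.
#' @param smooth_bandwidth Initial moving-average width in bins (odd values
#'   used).
#' @return Threshold in image units, strictly between the image min and max.
#' @section Errors: signals a `not_bimodal` condition when fewer than two
#'   separated peaks exist (e.g. a single-phase image).
#' @export
histogram_threshold <- function(image, n_bins = 256L, smooth_bandwidth = 5L) {
  stopifnot(inherits(image, "scan_image"))
  v <- as.vector(image$values)
  rng <- range(v)
  if (diff(rng) == 0)
    stopf("not_bimodal", "image is constant; no bimodal histogram exists")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L),
                          n_bins), nbins = n_bins)
  moving_avg <- function(x, bw) {
    if (bw %% 2L == 0L) bw <- bw + 1L
    half <- bw %/% 2L
    padded <- c(rep(0, half), x, rep(0, half))
    vapply(seq_along(x), function(i) mean(padded[i:(i + bw - 1L)]), 0)
  }
  local_maxima <- function(s) {
    # collapse runs of equal value; a run is one maximum when both
    # neighbouring runs are lower (image borders count as lower)
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    vals <- r$values
    nleft <- c(-Inf, vals[-length(vals)])
    nright <- c(vals[-1], -Inf)
    is_max <- vals > nleft & vals > nright
    as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  }
  # successive smoothing: widen the kernel until at most two maxima remain,
  # so noise ripples within one broad mode cannot masquerade as a second
  # phase peak
  bw <- max(1L, as.integer(smooth_bandwidth))
  repeat {
    smoothed <- moving_avg(counts, bw)
    peaks <- local_maxima(smoothed)
    # bumps from a handful of outlier pixels are not phase modes; pruning
    # them keeps the smoothing from running away trying to merge them
    peaks <- peaks[smoothed[peaks] >= 0.01 * max(smoothed)]
    if (length(peaks) <= 2L || bw > n_bins %/% 2L) break
    bw <- bw + 2L
  }
  if (length(peaks) < 2L)
    stopf("not_bimodal", "fewer than two histogram peaks after smoothing")
  p1 <- peaks[which.max(smoothed[peaks])]
  p2 <- setdiff(peaks, p1)[1]
  if (abs(p2 - p1) < 10L)
    stopf("not_bimodal", "histogram peaks are fewer than 10 bins apart")
  lo <- min(p1, p2); hi <- max(p1, p2)
  between <- (lo + 1L):(hi - 1L)
  vals <- smoothed[between]
  argmin <- between[vals == min(vals)]
  m <- argmin[ceiling(length(argmin) / 2)]
  # a genuine two-phase histogram dips well below its lower peak; without
  # this the two highest bumps of a unimodal noise histogram would pass
  if (smoothed[m] > 0.8 * min(smoothed[p1], smoothed[p2]))
    stopf("not_bimodal",
          "histogram valley is too shallow for a two-phase image")
  (breaks[m] + breaks[m + 1L]) / 2
}

new_segmentation_result <- function(method, threshold, mask, image,
                                    particles = NULL) {
  structure(
    list(method = method, threshold = threshold, mask = mask,
         coverage = mean(mask), particles = particles,
         pixel_size = image$pixel_size, channel = image$channel),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method = %s, threshold = %.4g, coverage = %.3f\n",
              x$method, x$threshold, x$coverage))
  if (!is.null(x$particles))
    cat(sprintf("  %d particles retained\n", nrow(x$particles)))
  invisible(x)
}

#' Surface coverage by the histogram method
#'
#' Thresholds the image at the minimum between the two histogram peaks
#' ([histogram_threshold()]) and reports the fraction of pixels above it —
#' the area fraction occupied by the higher (gel-phase) domains.
#'
#' @inheritParams histogram_threshold
#' @return A `segmentation_result`: method, threshold, binary mask (1 =
#'   higher domain), and `coverage = mean(mask)` exactly.
#' @export
coverage_histogram <- function(image, n_bins = 256L, smooth_bandwidth = 5L) {
  thr <- histogram_threshold(image, n_bins, smooth_bandwidth)
  mask <- matrix(as.integer(image$values > thr),
                 nrow(image$values), ncol(image$values))
  new_segmentation_result("histogram", thr, mask, image)
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels that touch diagonally are merged via the
# components of the label-adjacency graph.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    d1a <- lab[-nr, -nc]; d1b <- lab[-1, -1]    # \ diagonal
    d2a <- lab[-nr, -1];  d2b <- lab[-1, -nc]   # / diagonal
    pairs <- rbind(cbind(as.vector(d1a), as.vector(d1b)),
                   cbind(as.vector(d2a), as.vector(d2b)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                       directed = FALSE)
      comp <- igraph::components(g)
      remap <- seq_len(max(lab))
      remap[as.integer(igraph::V(g)$name)] <-
        max(lab) + comp$membership  # temporary ids, re-densified below
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      lab[lab > 0L] <- match(lab[lab > 0L], sort(unique(lab[lab > 0L])))
    }
  }
  lab
}

#' Surface coverage by the particle-detection method
#'
#' Thresholds the image (by default at the histogram threshold), labels the
#' connected components of the high-phase mask, discards particles smaller
#' than `min_area`, and reports the retained area fraction together with a
#' per-particle table.
#'
#' @param image A levelled [scan_image()].
#' @param threshold Threshold in image units; `NULL` uses
#'   [histogram_threshold()].
#' @param min_area Minimum particle area in nm^2; `NULL` means 4 pixels.
#'   Use 0 to disable filtering.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @return A `segmentation_result` whose `particles` element is a tibble
#'   with `label`, `area_nm2`, `n_pixels`, `centroid_row`, `centroid_col`.
#' @export
coverage_particle <- function(image, threshold = NULL, min_area = NULL,
                              connectivity = 8L) {
  stopifnot(inherits(image, "scan_image"))
  if (!connectivity %in% c(4L, 8L))
    stopf("validation_error", "connectivity must be 4 or 8")
  if (is.null(threshold)) threshold <- histogram_threshold(image)
  px_area <- image$pixel_size^2
  if (is.null(min_area)) min_area <- 4 * px_area
  mask <- matrix(as.integer(image$values > threshold),
                 nrow(image$values), ncol(image$values))
  lab <- label_components(mask, connectivity)
  keep_mask <- mask * 0L
  particles <- tibble::tibble(label = integer(), area_nm2 = numeric(),
                              n_pixels = integer(), centroid_row = numeric(),
                              centroid_col = numeric())
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * px_area >= min_area)
    if (length(keep)) {
      keep_mask <- matrix(as.integer(lab %in% keep), nrow(lab), ncol(lab))
      rows <- row(lab)[lab %in% keep]
      cols <- col(lab)[lab %in% keep]
      labs <- lab[lab %in% keep]
      particles <- tibble::tibble(
        label = seq_along(keep),
        area_nm2 = sizes[keep] * px_area,
        n_pixels = sizes[keep],
        centroid_row = as.numeric(tapply(rows, labs, mean)),
        centroid_col = as.numeric(tapply(cols, labs, mean))
      )
    }
  }
  new_segmentation_result("particle", threshold, keep_mask, image,
                          particles = particles)
}

#' Combine the two coverage estimators into a model average
#'
#' Mean of the histogram- and particle-method point estimates with the
#' margins combined in quadrature, \eqn{\sqrt{m_a^2 + m_b^2}}; optionally
#' rounded to a fixed number of digits (integer percent by default, matching
#' how such coverages are conventionally reported).
#'
#' @param a,b Length-2 numeric vectors `c(estimate, margin)`, in percent.
#' @param digits Digits to round to, or `NULL` for full precision.
#' @return A tibble with columns `estimate` and `margin`.
#' @examples
#' model_average(c(29, 3), c(25, 3))      # 27 +/- 4
#' model_average(c(55.6, 0.6), c(53, 4))  # 54 +/- 4
#' @export
model_average <- function(a, b, digits = 0) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (a[2] < 0 || b[2] < 0)
    stopf("validation_error", "margins must be >= 0")
  est <- (a[1] + b[1]) / 2
  mar <- sqrt(a[2]^2 + b[2]^2)
  if (!is.null(digits)) {
    est <- round(est, digits)
    mar <- round(mar, digits)
  }
  tibble::tibble(estimate = est, margin = mar)
}

#' @export
tidy.segmentation_result <- function(x, ...) {
  if (is.null(x$particles))
    return(tibble::tibble(label = 1L,
                          area_nm2 = sum(x$mask) * x$pixel_size^2,
                          n_pixels = sum(x$mask),
                          centroid_row = NA_real_, centroid_col = NA_real_))
  x$particles
}

#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, threshold = x$threshold, coverage = x$coverage,
    coverage_pct = 100 * x$coverage,
    n_particles = if (is.null(x$particles)) NA_integer_ else nrow(x$particles)
  )
}

#' @export
autoplot.segmentation_result <- function(object, ...) {
  d <- dim(object$mask)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    phase = factor(ifelse(as.vector(object$mask) == 1L, "high", "low"),
                   levels = c("low", "high"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(low = "grey20", high = "goldenrod")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s segmentation, coverage %.1f%%",
                                  object$method, 100 * object$coverage),
                  x = "column", y = "row")
}
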