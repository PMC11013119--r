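#' Extract a cross-section profile by bilinear interpolation
#'
#' Samples the image along the straight line from `p0` to `p1` at
#' `n_samples` equally spaced points. Endpoints are given in pixel
#' coordinates `c(row, col)` where integer coordinates are pixel centres
#' (row 1 = top scan line); positions along the profile are reported in nm.
#'
#' @param image A [scan_image()].
#' @param p0,p1 Endpoints, `c(row, col)` in pixel coordinates, inside the
#'   grid.
#' @param n_samples Number of samples (>= 16).
#' @return A `scan_profile`: list with `positions` (nm, strictly
#'   increasing), `values` (nm or mV), `endpoints`, `channel`.
#' @export
extract_profile <- function(image, p0, p1, n_samples = 64L) {
  stopifnot(inherits(image, "scan_image"))
  d <- dim(image$values)
  for (p in list(p0, p1))
    if (length(p) != 2L || p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2])
      stopf("validation_error",
            "profile endpoint (%.1f, %.1f) outside the %d x %d grid",
            p[1], p[2], d[1], d[2])
  if (all(p0 == p1))
    stopf("validation_error", "zero-length profile")
  n_samples <- max(16L, as.integer(n_samples))
  t <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  vals <- bilinear_at(image$values, r, cc)
  len_nm <- sqrt(sum((p1 - p0)^2)) * image$pixel_size
  structure(
    list(positions = t * len_nm, values = vals,
         endpoints = rbind(p0, p1), channel = image$channel,
         units = scan_units(image)),
    class = "scan_profile"
  )
}

bilinear_at <- function(v, r, cc) {
  d <- dim(v)
  r0 <- pmin(pmax(floor(r), 1L), d[1] - 1L)
  c0 <- pmin(pmax(floor(cc), 1L), d[2] - 1L)
  fr <- r - r0
  fc <- cc - c0
  idx <- function(i, j) v[cbind(i, j)]
  (1 - fr) * (1 - fc) * idx(r0, c0) +
    fr * (1 - fc) * idx(r0 + 1L, c0) +
    (1 - fr) * fc * idx(r0, c0 + 1L) +
    fr * fc * idx(r0 + 1L, c0 + 1L)
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("<scan_profile> %d samples over %.1f nm, channel = %s\n",
              length(x$values), max(x$positions), x$channel))
  invisible(x)
}

#' @export
tidy.scan_profile <- function(x, ...) {
  tibble::tibble(position_nm = x$positions, value = x$values,
                 channel = x$channel, units = x$units)
}

#' @export
autoplot.scan_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (nm)",
                  y = sprintf("%s (%s)", object$channel, object$units))
}

#' Step height (or potential) of a profile crossing one domain boundary
#'
#' Locates the dominant step as the split point maximising the mean
#' difference between the two profile segments, discards the central
#' `exclusion` fraction of samples around it (where tip blur mixes the
#' phases), classifies the remaining samples as high/low against the
#' profile's midrange, and returns `median(high) - median(low)`. Medians
#' make the estimate robust to streaks and outliers; the result is exactly
#' equivariant under affine rescaling of the values.
#'
#' @param profile A `scan_profile` from [extract_profile()]; should cross a
#'   single phase boundary (multi-step profiles yield the dominant step).
#' @param exclusion Fraction of samples to drop around the crossing (the
#'   default clears 3 standard deviations of the default tip blur on the
#'   default profile geometry).
#' @return The step amplitude, in the profile's units (nm or mV).
#' @section Errors: signals a `no_step` condition when one class is empty
#'   (e.g. a constant profile).
#' @export
step_delta <- function(profile, exclusion = 0.3) {
  stopifnot(inherits(profile, "scan_profile"))
  v <- profile$values
  n <- length(v)
  if (diff(range(v)) == 0)
    stopf("no_step", "constant profile: no step to measure")
  mid <- (min(v) + max(v)) / 2
  cls <- v >= mid
  if (all(cls) || !any(cls))
    stopf("no_step", "profile does not cross a domain boundary")
  # exclude a window around every class transition, so blur tails at the
  # far boundary of small domains do not contaminate the plateau medians
  half_excl <- ceiling(exclusion * n / 2)
  trans <- which(diff(cls) != 0)  # crossing between trans and trans + 1
  keep <- rep(TRUE, n)
  for (t_star in trans)
    keep <- keep & abs(seq_len(n) - (t_star + 0.5)) > half_excl
  # a profile ending just short of a phase boundary carries the boundary's
  # blur tail without a detectable class flip; trim the same window at the
  # profile ends unless the whole end segment sits in one phase anyway
  ends <- c(seq_len(min(half_excl, n)), n + 1L - seq_len(min(half_excl, n)))
  keep_trim <- keep
  keep_trim[ends] <- FALSE
  if (any(keep_trim & cls) && any(keep_trim & !cls)) keep <- keep_trim
  high <- v[keep & cls]
  low <- v[keep & !cls]
  if (!length(high) || !length(low))
    stopf("no_step", "profile does not cross a domain boundary")
  median(high) - median(low)
}

#' Draw random boundary-crossing profiles from a segmentation mask
#'
#' Picks `n_profiles` random boundary pixels of the high-phase mask
#' (seeded), estimates the local boundary orientation from the gradient of
#' the smoothed mask, and lays a profile of the given physical length
#' through each pixel perpendicular to the boundary. Candidates whose
#' endpoints leave the image are skipped; if the boundary is too short to
#' honour `n_profiles`, the available profiles are returned with a warning.
#'
#' @param image A [scan_image()] to sample values from.
#' @param mask 0/1 integer matrix (1 = high phase), same shape as `image`.
#' @param n_profiles Number of profiles requested.
#' @param length Profile length in nm.
#' @param seed Integer seed for the (restored-afterwards) RNG.
#' @param samples_per_px Sampling density along the line.
#' @param clearance_px Minimum distance (pixels) the line must keep from
#'   boundaries other than the one it crosses; matched to roughly three
#'   tip-blur widths so neighbouring domains cannot contaminate the
#'   plateau statistics.
#' @return A list of `scan_profile` objects.
#' @export
sample_boundary_profiles <- function(image, mask, n_profiles = 100L,
                                     length = 400, seed = 1L,
                                     samples_per_px = 2, clearance_px = 8) {
  stopifnot(inherits(image, "scan_image"))
  d <- dim(image$values)
  if (!identical(dim(mask), d))
    stopf("validation_error", "mask shape does not match the image")
  inner <- matrix(FALSE, d[1], d[2])
  m <- mask == 1L
  inner[-1, ] <- inner[-1, ] | (m[-1, ] & !m[-d[1], ])
  inner[-d[1], ] <- inner[-d[1], ] | (m[-d[1], ] & !m[-1, ])
  inner[, -1] <- inner[, -1] | (m[, -1] & !m[, -d[2]])
  inner[, -d[2]] <- inner[, -d[2]] | (m[, -d[2]] & !m[, -1])
  boundary <- which(inner)
  if (!length(boundary))
    stopf("validation_error", "mask has no phase boundary")
  smooth <- gaussian_blur(matrix(as.numeric(mask), d[1], d[2]), sigma = 2)
  # clearance field: a blurred mask value in (0.0013, 0.9987) flags pixels
  # within ~3 blur widths of a phase boundary
  clear <- gaussian_blur(matrix(as.numeric(mask), d[1], d[2]),
                         sigma = clearance_px / 3)
  half_px <- (length / 2) / image$pixel_size
  n_samples <- max(16L, ceiling(samples_per_px * length / image$pixel_size))
  local_seed(seed, {
    cand <- sample(boundary)
    out <- vector("list", n_profiles)
    got <- 0L
    for (k in cand) {
      if (got >= n_profiles) break
      i <- ((k - 1L) %% d[1]) + 1L
      j <- ((k - 1L) %/% d[1]) + 1L
      if (i < 2L || i > d[1] - 1L || j < 2L || j > d[2] - 1L) next
      g <- c(smooth[i + 1L, j] - smooth[i - 1L, j],
             smooth[i, j + 1L] - smooth[i, j - 1L])
      gn <- sqrt(sum(g^2))
      if (gn < 1e-8) next
      nrm <- g / gn  # points from low toward high phase
      p0 <- c(i, j) - half_px * nrm
      p1 <- c(i, j) + half_px * nrm
      if (any(p0 < 1) || any(p1 < 1) ||
          p0[1] > d[1] || p1[1] > d[1] || p0[2] > d[2] || p1[2] > d[2]) next
      # step_delta assumes a single, clean boundary crossing: keep only
      # candidate lines whose mask sequence flips exactly once and which,
      # outside a window around that crossing, stay clear of all other
      # domain boundaries (the automated analogue of drawing cross
      # sections through isolated domains)
      tt <- seq(0, 1, length.out = n_samples)
      mr <- pmin(pmax(round(p0[1] + tt * (p1[1] - p0[1])), 1L), d[1])
      mc <- pmin(pmax(round(p0[2] + tt * (p1[2] - p0[2])), 1L), d[2])
      lin <- cbind(mr, mc)
      trans <- which(diff(m[lin]) != 0)
      if (length(trans) != 1L) next
      away <- abs(seq_len(n_samples) - (trans + 0.5)) >
        clearance_px * samples_per_px
      prox <- clear[lin][away]
      if (any(prox > 0.0013 & prox < 0.9987)) next
      got <- got + 1L
      out[[got]] <- extract_profile(image, p0, p1, n_samples)
    }
    if (got < n_profiles)
      warn(sprintf("only %d of %d requested boundary profiles fit the image",
                   got, n_profiles))
    out[seq_len(got)]
  })
}

#' Aggregate per-profile step measurements into a domain contrast
#'
#' Mean step with a Student-t confidence margin,
#' \eqn{\bar{x} \pm t_{1-\alpha/2, n-1} \, s/\sqrt{n}}.
#'
#' @param deltas Numeric vector of per-profile steps (n >= 2).
#' @param confidence Confidence level (default 0.95).
#' @param channel Optional channel tag carried into the result.
#' @return A `domain_contrast`: `mean_delta`, `margin`, `n`,
#'   `per_profile_deltas`.
#' @export
aggregate_contrast <- function(deltas, confidence = 0.95, channel = NULL) {
  deltas <- as.numeric(deltas)
  n <- length(deltas)
  if (n < 2L)
    stopf("validation_error",
          "need at least 2 profile measurements for a confidence margin")
  s <- sd(deltas)
  margin <- if (confidence <= 0) 0
            else qt(1 - (1 - confidence) / 2, df = n - 1L) * s / sqrt(n)
  structure(
    list(mean_delta = mean(deltas), margin = margin, n = n,
         per_profile_deltas = deltas, confidence = confidence,
         channel = channel),
    class = "domain_contrast"
  )
}

#' @export
print.domain_contrast <- function(x, ...) {
  cat(sprintf("<domain_contrast> %.4g +/- %.2g (n = %d, %.0f%% CI)%s\n",
              x$mean_delta, x$margin, x$n, 100 * x$confidence,
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]")))
  invisible(x)
}

#' @export
tidy.domain_contrast <- function(x, ...) {
  tibble::tibble(profile = seq_len(x$n), delta = x$per_profile_deltas,
                 channel = x$channel %||% NA_character_)
}

#' @export
glance.domain_contrast <- function(x, ...) {
  tibble::tibble(mean_delta = x$mean_delta, margin = x$margin, n = x$n,
                 confidence = x$confidence,
                 channel = x$channel %||% NA_character_)
}
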