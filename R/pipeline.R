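#' Configuration for a full monolayer analysis
#'
#' Bundles everything [run_analysis()] needs: the input (either a
#' [monolayer_spec()] to synthesise, or paths to a paired topography +
#' potential image), segmentation and profile parameters, the confidence
#' level, an optional output directory, and the seed. The configuration is
#' fully serialisable; its hash is embedded in the report provenance.
#'
#' @param spec A [monolayer_spec()], or `NULL` when reading images.
#' @param topography,potential Input image paths (ignored when `spec` is
#'   given); dialect inferred from the extension (`.tif`/`.tiff` = float
#'   TIFF, otherwise ASCII matrix).
#' @param pixel_size Fallback pixel size (nm) for headerless inputs.
#' @param n_bins,smooth_bandwidth Histogram-threshold parameters.
#' @param min_area Particle filter, nm^2 (`NULL` = 4 pixels).
#' @param connectivity Particle connectivity, 4 or 8.
#' @param n_profiles,profile_length_nm,exclusion Cross-section parameters.
#' @param confidence Confidence level for all margins.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed for profile placement (and the spec's own seed
#'   for synthesis).
#' @param log_level `"info"` or `"quiet"`.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(spec = NULL, topography = NULL, potential = NULL,
                            pixel_size = 1, n_bins = 256L,
                            smooth_bandwidth = 5L, min_area = NULL,
                            connectivity = 8L, n_profiles = 100L,
                            profile_length_nm = 400, exclusion = 0.3,
                            confidence = 0.95, out_dir = NULL, seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(spec) && (is.null(topography) || is.null(potential)))
    stopf("validation_error",
          "provide either a monolayer spec or both image paths")
  structure(
    list(spec = spec, topography = topography, potential = potential,
         pixel_size = pixel_size, n_bins = as.integer(n_bins),
         smooth_bandwidth = as.integer(smooth_bandwidth),
         min_area = min_area, connectivity = as.integer(connectivity),
         n_profiles = as.integer(n_profiles),
         profile_length_nm = profile_length_nm, exclusion = exclusion,
         confidence = confidence, out_dir = out_dir,
         seed = as.integer(seed), log_level = log_level),
    class = "analysis_config"
  )
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), c("out_dir", "log_level"))]
  keep$spec <- if (is.null(keep$spec)) NULL else unclass(keep$spec)
  rlang::hash(keep)
}

stage_log <- function(config, stage, fmt, ...) {
  if (config$log_level == "quiet") return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

dialect_of <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "float_tiff"
  else "ascii_matrix"
}

# Coverage margin at the chosen confidence from the spread of the four
# image-quadrant estimates (the desk-scale analogue of averaging repeated
# experiments); returns c(estimate_pct, margin_pct).
quadrant_coverage <- function(mask, confidence) {
  nr <- nrow(mask); nc <- ncol(mask)
  hr <- nr %/% 2L; hc <- nc %/% 2L
  q <- c(mean(mask[1:hr, 1:hc]), mean(mask[1:hr, (hc + 1):nc]),
         mean(mask[(hr + 1):nr, 1:hc]), mean(mask[(hr + 1):nr, (hc + 1):nc]))
  margin <- if (confidence <= 0) 0
            else qt(1 - (1 - confidence) / 2, df = 3) * sd(q) / 2
  c(100 * mean(mask), 100 * margin)
}

#' Run the full domain-analysis pipeline
#'
#' Level the topography (plane + per-line median), estimate surface
#' coverage with both the histogram and particle methods (sharing one
#' threshold) and combine them into the model average, then draw random
#' boundary-crossing cross sections from the topography-derived mask and
#' measure the domain height contrast on the levelled topography and the
#' potential contrast on the raw potential image — the same profile
#' geometry on both channels, as when AFM and KPFM image the same sample
#' area. Deterministic under the config seed.
#'
#' @param config An [analysis_config()].
#' @return A [monolayer_report()]; when the config has an `out_dir`, the
#'   report (CSV + JSON), the segmentation mask and any synthesised images
#'   are written there too.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  truth <- NULL
  if (!is.null(config$spec)) {
    stage_log(config, "generate", "synthesising %s spec, seed %d",
              config$spec$morphology, config$spec$seed)
    truth <- generate_mask(config$spec)
    pair <- render_pair(truth)
    topo_raw <- pair$topography
    pot_raw <- pair$potential
    inputs <- list(spec_morphology = config$spec$morphology,
                   spec_seed = config$spec$seed)
  } else {
    stage_log(config, "load", "reading %s and %s",
              config$topography, config$potential)
    topo_raw <- read_scan(config$topography, dialect_of(config$topography),
                          pixel_size = config$pixel_size,
                          channel = "topography")
    pot_raw <- read_scan(config$potential, dialect_of(config$potential),
                         pixel_size = config$pixel_size,
                         channel = "potential")
    inputs <- list(topography = basename(config$topography),
                   potential = basename(config$potential))
  }
  check_channel(topo_raw, "topography")
  check_channel(pot_raw, "potential")
  if (!identical(dim(topo_raw$values), dim(pot_raw$values)))
    stopf("validation_error",
          "topography (%d x %d) and potential (%d x %d) shapes differ",
          nrow(topo_raw$values), ncol(topo_raw$values),
          nrow(pot_raw$values), ncol(pot_raw$values))

  stage_log(config, "level", "plane + per-line median levelling")
  topo <- level_image(topo_raw, order = 1, per_line = TRUE)

  stage_log(config, "segment", "histogram + particle coverage (%d bins)",
            config$n_bins)
  cov_h <- tryCatch(
    coverage_histogram(topo, config$n_bins, config$smooth_bandwidth),
    not_bimodal = function(e) {
      stopf("not_bimodal",
            paste("topography histogram is not bimodal — the film may be",
                  "single-phase, or levelling failed: %s"),
            conditionMessage(e))
    })
  cov_p <- coverage_particle(topo, threshold = cov_h$threshold,
                             min_area = config$min_area,
                             connectivity = config$connectivity)
  ch <- quadrant_coverage(cov_h$mask, config$confidence)
  cp <- quadrant_coverage(cov_p$mask, config$confidence)
  ma <- model_average(ch, cp, digits = NULL)
  stage_log(config, "segment",
            "coverage: histogram %.1f%%, particle %.1f%%, model avg %.1f%%",
            ch[1], cp[1], ma$estimate)

  stage_log(config, "profile", "%d boundary cross sections, %.0f nm each",
            config$n_profiles, config$profile_length_nm)
  profiles_topo <- sample_boundary_profiles(
    topo, cov_h$mask, n_profiles = config$n_profiles,
    length = config$profile_length_nm, seed = config$seed)
  profiles_pot <- lapply(profiles_topo, function(p)
    extract_profile(pot_raw, p$endpoints[1, ], p$endpoints[2, ],
                    length(p$values)))
  safe_delta <- function(p) tryCatch(step_delta(p, config$exclusion),
                                     error = function(e) NA_real_)
  dh <- vapply(profiles_topo, safe_delta, 0)
  dv <- vapply(profiles_pot, safe_delta, 0)
  ok <- !is.na(dh) & !is.na(dv)
  if (sum(ok) < 2L)
    stopf("runtime_error", "fewer than 2 usable cross-section profiles")
  contrast_h <- aggregate_contrast(dh[ok], config$confidence, "topography")
  contrast_v <- aggregate_contrast(dv[ok], config$confidence, "potential")
  stage_log(config, "aggregate",
            "delta_h = %.3f +/- %.3f nm, delta_v = %.1f +/- %.1f mV (n = %d)",
            contrast_h$mean_delta, contrast_h$margin,
            contrast_v$mean_delta, contrast_v$margin, contrast_h$n)

  report <- monolayer_report(
    coverage_histogram = ch, coverage_particle = cp,
    coverage_model_average = c(ma$estimate, ma$margin),
    delta_h = c(contrast_h$mean_delta, contrast_h$margin),
    delta_v = c(contrast_v$mean_delta, contrast_v$margin),
    n_profiles = contrast_h$n,
    provenance = c(inputs, list(config_hash = config_hash(config)))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report"))
    write_mask(cov_h$mask, file.path(config$out_dir, "mask.txt"))
    if (!is.null(truth)) {
      write_scan(topo_raw, file.path(config$out_dir, "topography.txt"),
                 "ascii_matrix")
      write_scan(pot_raw, file.path(config$out_dir, "potential.txt"),
                 "ascii_matrix")
      write_mask(truth$mask, file.path(config$out_dir, "truth_mask.txt"))
    }
    stage_log(config, "write", "report and masks written to %s",
              config$out_dir)
  }
  report
}

#' Write / read a 0/1 mask as plain text
#'
#' @param mask 0/1 integer matrix.
#' @param path File path.
#' @return `path` (write) or an integer matrix (read), invisibly for write.
#' @export
write_mask <- function(mask, path) {
  writeLines(apply(mask, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  rows <- lapply(strsplit(trimws(readLines(path)), "\\s+"), as.integer)
  do.call(rbind, rows)
}
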