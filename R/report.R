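#' Assemble an analysis report
#'
#' The report mirrors how monolayer image analyses are conventionally
#' tabulated: coverage by each estimator and their model average (percent
#' with a 95% margin), and the domain height and potential contrasts
#' (`delta_h` in nm, `delta_v` in mV) with their margins and the number of
#' profiles behind them. Values are stored at full precision; `print()`
#' rounds to the conventional reporting precision (integer %, 0.01 nm,
#' 1 mV).
#'
#' @param coverage_histogram,coverage_particle,coverage_model_average
#'   Length-2 `c(estimate_pct, margin_pct)` or `NULL` when unavailable.
#' @param delta_h,delta_v Length-2 `c(estimate, margin)` or `NULL`.
#' @param n_profiles Number of cross-section profiles behind the contrasts.
#' @param provenance Named list: input identifiers and `config_hash`.
#' @return A `monolayer_report`.
#' @export
monolayer_report <- function(coverage_histogram = NULL,
                             coverage_particle = NULL,
                             coverage_model_average = NULL,
                             delta_h = NULL, delta_v = NULL,
                             n_profiles = NA_integer_,
                             provenance = list()) {
  chk <- function(x, what, pct = FALSE) {
    if (is.null(x)) return(NULL)
    stopifnot(length(x) == 2L)
    if (!is.na(x[2]) && x[2] < 0)
      stopf("validation_error", "%s margin must be >= 0", what)
    if (pct && (x[1] < 0 || x[1] > 100))
      stopf("validation_error", "%s must be a percentage in [0, 100]", what)
    as.numeric(x)
  }
  if ((!is.null(delta_h) || !is.null(delta_v)) &&
      (is.na(n_profiles) || n_profiles < 2L))
    stopf("validation_error",
          "contrasts with confidence margins require n_profiles >= 2")
  structure(
    list(coverage_histogram = chk(coverage_histogram, "coverage_histogram", TRUE),
         coverage_particle = chk(coverage_particle, "coverage_particle", TRUE),
         coverage_model_average = chk(coverage_model_average,
                                      "coverage_model_average", TRUE),
         delta_h = chk(delta_h, "delta_h"),
         delta_v = chk(delta_v, "delta_v"),
         n_profiles = as.integer(n_profiles),
         provenance = provenance),
    class = "monolayer_report"
  )
}

report_fields <- c("coverage_histogram", "coverage_particle",
                   "coverage_model_average", "delta_h", "delta_v")
report_units <- c(coverage_histogram = "%", coverage_particle = "%",
                  coverage_model_average = "%", delta_h = "nm",
                  delta_v = "mV")

#' @export
print.monolayer_report <- function(x, ...) {
  cat("<monolayer_report>\n")
  fmt <- function(v, digits) {
    if (is.null(v)) return("-")
    sprintf(paste0("%.", digits, "f +/- %.", digits, "f"), v[1], v[2])
  }
  cat(sprintf("  coverage (histogram):  %s %%\n", fmt(x$coverage_histogram, 0)))
  cat(sprintf("  coverage (particle):   %s %%\n", fmt(x$coverage_particle, 0)))
  cat(sprintf("  coverage (model avg):  %s %%\n",
              fmt(x$coverage_model_average, 0)))
  cat(sprintf("  delta_h:               %s nm\n", fmt(x$delta_h, 2)))
  cat(sprintf("  delta_v:               %s mV\n", fmt(x$delta_v, 0)))
  cat(sprintf("  n_profiles: %s\n", x$n_profiles))
  invisible(x)
}

#' @export
tidy.monolayer_report <- function(x, ...) {
  purrr::map_dfr(report_fields, function(f) {
    v <- x[[f]]
    tibble::tibble(quantity = f,
                   estimate = if (is.null(v)) NA_real_ else v[1],
                   margin = if (is.null(v)) NA_real_ else v[2],
                   units = unname(report_units[f]))
  })
}

#' @export
glance.monolayer_report <- function(x, ...) {
  out <- tidy(x)
  wide <- setNames(as.list(out$estimate), out$quantity)
  tibble::as_tibble(c(wide, list(n_profiles = x$n_profiles)))
}

#' Write a report as CSV and JSON
#'
#' Serialises all fields with units in a deterministic order. `path` is the
#' stem: `<path>.csv` and `<path>.json` are written. Missing optional
#' fields serialise as empty (CSV) / null (JSON), never as zero.
#'
#' @param report A [monolayer_report()].
#' @param path Output path stem (no extension).
#' @return Character vector of the two written paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "monolayer_report"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  readr::write_csv(tidy(report), csv)
  payload <- lapply(setNames(report_fields, report_fields), function(f) {
    v <- report[[f]]
    if (is.null(v)) NULL
    else list(estimate = v[1], margin = v[2], units = unname(report_units[f]))
  })
  payload$n_profiles <- report$n_profiles
  payload$provenance <- report$provenance
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv, json))
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path stem or the `.json` path itself.
#' @return A [monolayer_report()].
#' @export
read_report <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  p <- jsonlite::read_json(path)
  get2 <- function(f)
    if (is.null(p[[f]])) NULL else c(p[[f]]$estimate, p[[f]]$margin)
  monolayer_report(
    coverage_histogram = get2("coverage_histogram"),
    coverage_particle = get2("coverage_particle"),
    coverage_model_average = get2("coverage_model_average"),
    delta_h = get2("delta_h"), delta_v = get2("delta_v"),
    n_profiles = p$n_profiles %||% NA_integer_,
    provenance = p$provenance %||% list()
  )
}
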