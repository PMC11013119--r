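#' Physical constants used by the electrostatics models
#'
#' Vacuum permittivity (F/m), elementary charge (C), and the milli-Debye to
#' C m conversion.
#' @keywords internal
.const <- list(
  eps0 = 8.854e-12,       # F/m
  e = 1.602e-19,          # C
  mD_to_Cm = 3.33564e-33, # C m per mDebye
  A2_to_m2 = 1e-20        # m^2 per square Angstrom
)

#' Helmholtz dipole-sheet surface potential
#'
#' The electrical surface potential of a uniform, effectively infinite sheet
#' of aligned molecular dipoles, in the practical unit convention used
#' throughout the monolayer literature:
#' \deqn{V[\mathrm{mV}] = 12\pi \, \mu_\perp[\mathrm{mD}] / A[\mathrm{\AA^2}]}
#' where \eqn{\mu_\perp} is the normal component of the molecular dipole
#' moment and \eqn{A} the area per molecule. The prefactor \eqn{12\pi}
#' absorbs \eqn{1/\epsilon_0} and all unit conversions.
#'
#' @param mu Normal dipole moment per molecule, in milliDebye (>= 0).
#' @param area Area per molecule, in square Angstroms (> 0).
#' @return Surface potential in mV. Vectorised over both arguments.
#' @examples
#' dipole_sheet_potential(488, 46)  # ~400 mV (gel-phase DPPC at 20 mN/m)
#' @export
dipole_sheet_potential <- function(mu, area) {
  if (any(area <= 0)) stopf("domain_error", "area per molecule must be > 0")
  if (any(mu < 0)) stopf("domain_error", "dipole moment must be >= 0")
  12 * pi * mu / area
}

#' Invert the dipole-sheet model for the molecular dipole moment
#'
#' @param v Surface potential in mV.
#' @param area Area per molecule in square Angstroms (> 0).
#' @return Normal dipole moment in milliDebye; exact inverse of
#'   [dipole_sheet_potential()].
#' @examples
#' dipole_from_potential(400, 46)  # ~488 mD
#' @export
dipole_from_potential <- function(v, area) {
  if (any(area <= 0)) stopf("domain_error", "area per molecule must be > 0")
  v * area / (12 * pi)
}

#' Potential difference between two monolayer phases
#'
#' Signed contrast \eqn{\Delta V = V_{high} - V_{low}}, conventionally the
#' gel-phase (DPPC-rich) potential minus the fluid-phase (DOPC-rich) one.
#'
#' @param v_high,v_low Phase potentials in mV.
#' @return Signed difference in mV.
#' @export
phase_potential_difference <- function(v_high, v_low) v_high - v_low

#' Potential above an infinite charged sheet
#'
#' \deqn{V = z \sigma / (2 \epsilon_0)}
#' for a probe at height `z` above a uniform surface charge density `sigma`.
#' SI units throughout.
#'
#' @param z Probe height in metres (> 0).
#' @param sigma Surface charge density in C/m^2.
#' @return Potential in volts; linear in both arguments.
#' @export
charged_sheet_potential <- function(z, sigma) {
  if (any(z <= 0)) stopf("domain_error", "tip height z must be > 0")
  z * sigma / (2 * .const$eps0)
}

#' Number density of divalent surfactant from a charged-sheet potential
#'
#' Inverts the charged-sheet model for the surface charge density,
#' \eqn{\sigma = 2\epsilon_0 V / z}, and divides by the 2+ molecular charge
#' (2e) of a cationic gemini surfactant to obtain molecules per square metre.
#'
#' @param v Excess sheet potential in volts (>= 0).
#' @param z Probe height in metres (> 0).
#' @return Number density in molecules / m^2.
#' @seealso [charged_sheet_sigma_literal()] for the uninverted textbook
#'   shorthand \eqn{\epsilon_0 V / z}.
#' @export
gemini_number_density <- function(v, z) {
  if (any(z <= 0)) stopf("domain_error", "tip height z must be > 0")
  if (any(v < 0)) stopf("domain_error", "sheet potential must be >= 0")
  sigma <- 2 * .const$eps0 * v / z
  sigma / (2 * .const$e)
}

#' Literal charge-density shorthand \eqn{\epsilon_0 V / z}
#'
#' The compact form sometimes quoted for the charge density under a
#' charged-sheet potential. Note it omits the factor 2 that a strict
#' inversion of [charged_sheet_potential()] requires and has units of C/m^2,
#' not molecules/m^2; it is provided for auditability against the published
#' shorthand, not for quantitative use.
#'
#' @inheritParams gemini_number_density
#' @return \eqn{\epsilon_0 v / z} in C/m^2.
#' @export
charged_sheet_sigma_literal <- function(v, z) {
  if (any(z <= 0)) stopf("domain_error", "tip height z must be > 0")
  .const$eps0 * v / z
}

#' Surfactant-to-lipid molecular ratio
#'
#' Converts an areal number density of surfactant into molecules per lipid,
#' given the area one lipid occupies.
#'
#' @param n Surfactant number density, molecules / m^2 (> 0).
#' @param area_per_lipid Area per lipid molecule, square Angstroms (> 0).
#' @return Surfactant molecules per lipid molecule.
#' @examples
#' # one surfactant in the area of four 45-A^2 lipids:
#' gs_per_lipid(1 / (4 * 45e-20), 45)
#' @export
gs_per_lipid <- function(n, area_per_lipid) {
  if (any(n <= 0) || any(area_per_lipid <= 0))
    stopf("domain_error", "inputs must be positive")
  n * area_per_lipid * .const$A2_to_m2
}

#' Literature values for DOPC and DPPC monolayers
#'
#' A curated set of published surface pressures, areas per molecule,
#' surface potentials and normal dipole moments for pure DOPC and DPPC
#' monolayers on various subphases. Cells flagged `*_derived` were not
#' measured but computed from the dipole-sheet model
#' ([dipole_sheet_potential()] / [dipole_from_potential()]) by the original
#' compilation; [table3_check()] re-derives every one of them.
#'
#' @return A tibble with columns `lipid`, `pressure_mN_m`, `area_A2`,
#'   `potential_mV`, `dipole_mD`, `potential_derived`, `dipole_derived`,
#'   `subphase`, `source`.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "dopc_dppc_literature.csv",
                      package = "monodomain", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    lipid = "c", pressure_mN_m = "d", area_A2 = "d",
                    potential_mV = "d", dipole_mD = "d",
                    potential_derived = "l", dipole_derived = "l",
                    subphase = "c", source = "c"))
}

#' Published per-method surface coverages for the control mixtures
#'
#' The reported higher-domain surface coverages of the pure-lipid control
#' films at two DOPC-DPPC mixing ratios, as estimated by the histogram and
#' particle-detection methods (percent, with 95% margins). Used to audit
#' the [model_average()] combination rule.
#'
#' @return A tibble with columns `dopc_dppc_ratio`, `method`,
#'   `coverage_pct`, `margin_pct`.
#' @export
coverage_literature_fixture <- function() {
  path <- system.file("extdata", "coverage_literature.csv",
                      package = "monodomain", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    dopc_dppc_ratio = "c", method = "c",
                    coverage_pct = "d", margin_pct = "d"))
}

#' Audit the derived cells of the literature table
#'
#' Recomputes every dipole-sheet-derived cell of [table3_fixture()] (dipole
#' moments back-calculated from measured potentials, potentials forward-
#' calculated from measured dipoles) and the DPPC-minus-DOPC potential
#' differences on a pure-water subphase at matched pressures. A cell passes
#' when the recomputed value agrees with the printed one within one unit in
#' the last printed digit.
#'
#' @return A tibble with columns `quantity`, `lipid`, `pressure_mN_m`,
#'   `printed`, `recomputed`, `units`, `ok`.
#' @export
table3_check <- function() {
  tab <- table3_fixture()
  rows <- list()
  der <- dplyr::filter(tab, .data$dipole_derived)
  if (nrow(der))
    rows$mu <- tibble::tibble(
      quantity = "dipole_mD", lipid = der$lipid,
      pressure_mN_m = der$pressure_mN_m, printed = der$dipole_mD,
      recomputed = dipole_from_potential(der$potential_mV, der$area_A2),
      units = "mD")
  dep <- dplyr::filter(tab, .data$potential_derived)
  if (nrow(dep))
    rows$v <- tibble::tibble(
      quantity = "potential_mV", lipid = dep$lipid,
      pressure_mN_m = dep$pressure_mN_m, printed = dep$potential_mV,
      recomputed = dipole_sheet_potential(dep$dipole_mD, dep$area_A2),
      units = "mV")
  # DPPC - DOPC potential contrast at matched pressures on water
  dv_printed <- c(`20` = 94, `30` = 271)
  h2o <- dplyr::filter(tab, .data$subphase == "H2O",
                       !is.na(.data$potential_mV))
  dv <- purrr::map_dfr(names(dv_printed), function(p) {
    pr <- as.numeric(p)
    vh <- h2o$potential_mV[h2o$lipid == "DPPC" & h2o$pressure_mN_m == pr]
    vl <- h2o$potential_mV[h2o$lipid == "DOPC" & h2o$pressure_mN_m == pr]
    tibble::tibble(
      quantity = "delta_v_mV", lipid = "DPPC-DOPC", pressure_mN_m = pr,
      printed = dv_printed[[p]],
      recomputed = phase_potential_difference(vh, vl), units = "mV")
  })
  out <- dplyr::bind_rows(rows$mu, rows$v, dv)
  dplyr::mutate(out, ok = abs(round(.data$recomputed) - .data$printed) <= 1)
}

#' Predicted phase potential contrast from literature entries
#'
#' Computes the dipole-sheet potential of each phase from a literature row
#' (using the printed potential when present, otherwise deriving it from the
#' dipole moment and molecular area) and returns the high-minus-low
#' difference. Feeding the gel-phase (DPPC) row as `entry_high` and the
#' fluid-phase (DOPC) row as `entry_low` yields the theoretical KPFM domain
#' contrast.
#'
#' @param entry_high,entry_low One-row data frames with columns
#'   `potential_mV`, `dipole_mD` and `area_A2` (e.g. rows of
#'   [table3_fixture()]).
#' @return Predicted contrast in mV.
#' @examples
#' tab <- table3_fixture()
#' dppc <- tab[tab$lipid == "DPPC" & tab$pressure_mN_m %in% 30 &
#'             tab$subphase == "H2O", ]
#' dopc <- tab[tab$lipid == "DOPC" & tab$pressure_mN_m %in% 30 &
#'             tab$subphase == "H2O", ]
#' predict_dv(dppc, dopc)  # ~271 mV
#' @export
predict_dv <- function(entry_high, entry_low) {
  v_of <- function(e) {
    stopifnot(nrow(e) == 1L)
    if (!is.na(e$potential_mV)) return(e$potential_mV)
    if (is.na(e$dipole_mD) || is.na(e$area_A2))
      stopf("validation_error",
            "entry has neither a potential nor (dipole, area)")
    dipole_sheet_potential(e$dipole_mD, e$area_A2)
  }
  phase_potential_difference(v_of(entry_high), v_of(entry_low))
}
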