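test_that("dipole-sheet model reproduces the literature worked values", {
  # gel-phase DPPC: measured V and A imply the quoted dipole moments
  expect_equal(round(dipole_from_potential(400, 46)), 488)
  expect_equal(round(dipole_from_potential(600, 44)), 700)
  expect_equal(round(dipole_from_potential(700, 42)), 780)
  # fluid DOPC at high pressure: dipole and area imply the quoted potential
  expect_equal(round(dipole_sheet_potential(486, 59)), 311)
  expect_equal(round(dipole_sheet_potential(488, 46)), 400)
  expect_equal(round(dipole_sheet_potential(700, 44)), 600)
  expect_equal(dipole_sheet_potential(0, 37), 0)
  expect_error(dipole_sheet_potential(100, 0), class = "domain_error")
  expect_error(dipole_from_potential(100, -1), class = "domain_error")
})

test_that("dipole-sheet forward and inverse are exact inverses and scale correctly", {
  mus <- c(1, 486, 700, 2500)
  areas <- c(40, 59, 78, 120)
  for (mu in mus) for (a in areas) {
    v <- dipole_sheet_potential(mu, a)
    expect_equal(dipole_from_potential(v, a), mu, tolerance = 1e-12)
  }
  # linear in mu, homogeneous of degree -1 in area
  expect_equal(dipole_sheet_potential(2 * 486, 59),
               2 * dipole_sheet_potential(486, 59))
  expect_equal(dipole_sheet_potential(486, 2 * 59),
               dipole_sheet_potential(486, 59) / 2)
})

test_that("phase potential differences match the tabulated contrasts", {
  expect_equal(phase_potential_difference(600, 329), 271)
  expect_equal(phase_potential_difference(400, 306), 94)
  expect_equal(phase_potential_difference(123.4, 123.4), 0)
})

test_that("charged-sheet model is linear and round-trips with number density", {
  expect_equal(charged_sheet_potential(1, 2 * 8.854e-12), 1)
  expect_equal(charged_sheet_potential(5, 0), 0)
  # direct evaluation: z = 10 nm, sigma = 0.01 C/m^2
  expect_equal(charged_sheet_potential(1e-8, 0.01),
               1e-8 * 0.01 / (2 * 8.854e-12), tolerance = 1e-12)
  expect_equal(charged_sheet_potential(1e-8, 0.01), 5.647, tolerance = 1e-3)
  # linearity in both arguments
  expect_equal(charged_sheet_potential(2e-9, 0.03),
               2 * charged_sheet_potential(1e-9, 0.03))
  expect_equal(charged_sheet_potential(2e-9, 0.06),
               2 * charged_sheet_potential(2e-9, 0.03))
  # number density inverts the sheet potential through the 2+ charge
  n <- gemini_number_density(0.322, 1e-9)
  expect_equal(n, 8.854e-12 * 0.322 / (1e-9 * 1.602e-19), tolerance = 1e-12)
  expect_equal(charged_sheet_potential(1e-9, 2 * 1.602e-19 * n), 0.322,
               tolerance = 1e-12)
  expect_equal(gemini_number_density(0, 1e-9), 0)
  expect_error(gemini_number_density(1, 0), class = "domain_error")
  # the literal printed shorthand lacks the inversion factor 2
  expect_equal(charged_sheet_sigma_literal(0.322, 1e-9),
               8.854e-12 * 0.322 / 1e-9)
})

test_that("surfactant-per-lipid ratio converts areal densities correctly", {
  expect_equal(gs_per_lipid(1 / (4 * 45e-20), 45), 0.25)
  expect_equal(gs_per_lipid(2e17, 45), 2 * gs_per_lipid(1e17, 45))
  # consistency with a hand unit chain: V -> n -> ratio
  n <- gemini_number_density(0.322, 1e-9)
  by_hand <- (2 * 8.854e-12 * 0.322 / 1e-9) / (2 * 1.602e-19) * 45 * 1e-20
  expect_equal(gs_per_lipid(n, 45), by_hand, tolerance = 1e-12)
})

test_that("every derived literature cell reproduces within printed precision", {
  chk <- table3_check()
  expect_gte(nrow(chk), 6)
  expect_true(all(chk$ok))
  # the potential contrasts recompute exactly from the printed potentials
  dv <- chk[chk$quantity == "delta_v_mV", ]
  expect_equal(dv$recomputed[dv$pressure_mN_m == 20], 94)
  expect_equal(dv$recomputed[dv$pressure_mN_m == 30], 271)
})

test_that("predict_dv derives potentials from dipoles when needed", {
  tab <- table3_fixture()
  pick <- function(lipid, p) tab[tab$lipid == lipid &
                                 !is.na(tab$pressure_mN_m) &
                                 tab$pressure_mN_m == p &
                                 tab$subphase == "H2O", ]
  expect_equal(predict_dv(pick("DPPC", 30), pick("DOPC", 30)), 271)
  expect_equal(predict_dv(pick("DPPC", 20), pick("DOPC", 20)), 94)
  one <- pick("DPPC", 30)
  expect_equal(predict_dv(one, one), 0)
  # with the potential blanked, the dipole-sheet route is used
  no_v <- pick("DOPC", 45)
  no_v$potential_mV <- NA
  expect_equal(round(dipole_sheet_potential(no_v$dipole_mD, no_v$area_A2)),
               311)
  expect_equal(predict_dv(pick("DPPC", 30), no_v),
               600 - dipole_sheet_potential(486, 59))
})
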