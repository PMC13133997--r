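test_that("absorption coefficient from absorption length", {
  expect_equal(mu_from_length(8.77), 0.114e-3, tolerance = 0.005)
  expect_equal(mu_from_length(0.67), 1.49e-3, tolerance = 0.005)
  expect_equal(mu_from_length(Inf), 0)
  expect_error(mu_from_length(-1), "positive")
  expect_error(mu_from_length(0), "positive")
})

test_that("relativistic factor matches the printed values and limits", {
  expect_equal(round(relativistic_factor(100), 2), 1.09)
  expect_equal(round(relativistic_factor(300), 2), 1.23)
  expect_equal(relativistic_factor(0), 1)
  expect_true(all(diff(relativistic_factor(seq(10, 1000, by = 10))) > 0))
})

test_that("electron wavelength is the relativistic de Broglie value", {
  expect_equal(electron_wavelength(100), 3.70, tolerance = 0.002)
  expect_equal(electron_wavelength(300), 1.97, tolerance = 0.002)
  E <- seq(20, 1000, by = 20)
  expect_true(all(diff(electron_wavelength(E)) < 0))
})

test_that("registry materials are self-consistent (mu * L = 1 within 1%)", {
  for (nm in dlr_materials()$name) {
    m <- dlr_materials(nm)
    xp <- m$xray_props
    both <- !is.na(xp$L_um) & !is.na(xp$mu_nm)
    if (any(both))
      expect_true(all(abs(xp$mu_nm[both] * xp$L_um[both] * 1e3 - 1) < 0.01),
                  label = paste("mu*L consistency for", nm))
  }
})

test_that("X-ray optical-constant lookups reproduce the tabulated data", {
  p <- xray_optical_constants(dlr_materials("protein"), 500)
  expect_equal(p$mu_nm, 1.49e-3)
  expect_equal(p$one_plus_eps1, 1.065e-3)
  expect_equal(xray_optical_constants(dlr_materials("ice"), 8000)$mu_nm,
               0.95e-6)
  d_eps <- xray_optical_constants(dlr_materials("protein"), 500)$one_plus_eps1 -
    xray_optical_constants(dlr_materials("ice"), 500)$one_plus_eps1
  expect_equal(d_eps, 0.49e-3, tolerance = 0.01)
  d_eps8 <- xray_optical_constants(dlr_materials("protein"), 8000)$one_plus_eps1 -
    xray_optical_constants(dlr_materials("ice"), 8000)$one_plus_eps1
  expect_equal(d_eps8, 1.3e-6, tolerance = 0.01)
  expect_error(xray_optical_constants(dlr_materials("ice"), 1234),
               "ice.*1234")
})

test_that("beam objects derive wavelength and relativistic factor", {
  bx <- beam("xray", 500)
  expect_equal(bx$wavelength_nm * 500, 1239.84, tolerance = 1e-3)
  expect_equal(bx$wavelength_nm, 2.48, tolerance = 0.002)
  be <- beam("electron", 300e3)
  expect_equal(be$rf, 1.23, tolerance = 0.005)
  expect_equal(be$wavelength_nm, 1.97e-3, tolerance = 0.002)
  expect_error(beam("xray", -5), "positive")
})

test_that("material constructor validates its invariants", {
  expect_error(dlr_material("x", c(C = 0.5), 1), "positive integers")
  expect_error(dlr_material("x", c(C = 1), -1), "positive")
  expect_error(dlr_material("x", setNames(2, NULL), 1), "named")
  expect_error(
    dlr_material("x", c(C = 1), 1,
                 xray_props = data.frame(energy_eV = 500, L_um = 1,
                                         mu_nm = 2e-3)),
    "disagree")
})

test_that("Lenz closed form agrees with numeric integration of the cross section", {
  for (Z in c(6, 7, 8)) {
    for (E0 in c(100, 300)) {
      for (beta in c(0, 5e-3, 20e-3)) {
        closed <- dlrcalc:::.lenz_sigma_el(Z, E0, beta)
        brute <- oracle_lenz_sigma(Z, E0, beta)
        expect_equal(closed, brute, tolerance = 0.005,
                     label = sprintf("sigma_el(Z=%d, E0=%d, beta=%g)",
                                     Z, E0, beta))
      }
    }
  }
})

test_that("Beer's-law scattering length grows with aperture angle", {
  carbon <- dlr_materials("carbon")
  L <- vapply(c(2, 5, 10, 20), function(b)
    lenz_mean_free_paths(carbon, 300, beta_mrad = b)$L_beta_nm, numeric(1))
  expect_true(all(diff(L) > 0))
  # amorphous carbon at 300 keV, 5 mrad: a few hundred nm
  L5 <- lenz_mean_free_paths(carbon, 300, beta_mrad = 5)$L_beta_nm
  expect_gt(L5, 100)
  expect_lt(L5, 1000)
})

test_that("doubling density halves every mean free path", {
  m1 <- toy_material(density = 1)
  m2 <- toy_material(density = 2)
  a <- lenz_mean_free_paths(m1, 100, beta_mrad = 8, use_registry = FALSE)
  b <- lenz_mean_free_paths(m2, 100, beta_mrad = 8, use_registry = FALSE)
  expect_equal(a$lambda_e_nm / b$lambda_e_nm, 2, tolerance = 1e-12)
  expect_equal(a$lambda_i_nm / b$lambda_i_nm, 2, tolerance = 1e-12)
  expect_equal(a$L_beta_nm / b$L_beta_nm, 2, tolerance = 1e-12)
})

test_that("perturbed materials scale interaction properties coherently", {
  p <- dlr_materials("protein")
  p9 <- perturb_material(p, 0.9)
  expect_equal(p9$density, 0.9 * p$density)
  expect_equal(xray_optical_constants(p9, 500)$mu_nm,
               0.9 * xray_optical_constants(p, 500)$mu_nm)
  expect_equal(p9$mip, 0.9 * p$mip)
  # L scales inversely so mu*L stays 1
  expect_equal(p9$xray_props$L_um[1] * p9$xray_props$mu_nm[1] * 1e3, 1,
               tolerance = 0.01)
})
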