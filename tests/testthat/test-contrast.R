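pro <- dlr_materials("protein")
ice <- dlr_materials("ice")
bx <- beam("xray", 500)
be <- beam("electron", 300e3)

test_that("X-ray absorption contrast and efficiency behave at the limits", {
  # equal coefficients -> no contrast at any thickness
  expect_equal(cf_xray_absorption(100, 10, 1e-3, 1e-3, "voxel")$C, 0)
  expect_equal(cf_xray_absorption(500, 10, 1e-3, 1e-3, "column")$C, 0)
  # t -> 0 -> F -> 1
  expect_equal(cf_xray_absorption(1e-9, 1e-10, 1e-3, 1e-4, "column")$F, 1,
               tolerance = 1e-9)
  # protein in ice at 500 eV: contrast per unit depth 1.376e-3 /nm
  mu_f <- xray_optical_constants(pro, 500)$mu_nm
  mu_m <- xray_optical_constants(ice, 500)$mu_nm
  expect_equal(mu_f - mu_m, 1.376e-3, tolerance = 1e-3)
  cf <- cf_xray_absorption(100, 10, mu_f, mu_m, "voxel")
  expect_equal(cf$C, (mu_f - mu_m) * 10)
  # organelle model: 10% perturbed protein gives contrast 0.1 mu_f delta
  p9 <- perturb_material(pro, 0.9)
  mu_m9 <- xray_optical_constants(p9, 500)$mu_nm
  cf9 <- cf_xray_absorption(100, 10, mu_f, mu_m9, "voxel")
  expect_equal(cf9$C, 0.1 * mu_f * 10, tolerance = 1e-12)
  # voxel taller than the specimen is a geometry error
  expect_error(cf_xray_absorption(5, 10, 1e-3, 1e-4, "voxel"), "exceeds")
})

test_that("X-ray phase contrast is linear in delta, d_eps1 and 1/lambda", {
  base <- cf_xray_phase(100, 10, 2.48, 0.49e-3, 1.49e-3, "voxel")
  expect_equal(cf_xray_phase(100, 10, 2.48, 0, 1.49e-3, "voxel")$C, 0)
  expect_equal(cf_xray_phase(100, 20, 2.48, 0.49e-3, 1.49e-3, "voxel")$C,
               2 * base$C)
  expect_equal(cf_xray_phase(100, 10, 2.48, 0.98e-3, 1.49e-3, "voxel")$C,
               2 * base$C)
  expect_equal(cf_xray_phase(100, 10, 1.24, 0.49e-3, 1.49e-3, "voxel")$C,
               2 * base$C)
  # efficiency is the feature-column absorption expression
  expect_equal(base$F, exp(-1.49e-3 * 100))
})

test_that("TEM phase contrast vanishes for equal potentials and F decays from 1", {
  expect_equal(cf_tem_phase(pro, pro, be, 100, 10, "voxel")$C, 0)
  ts <- c(1, 30, 100, 300, 1000)
  Fs <- vapply(ts, function(t)
    cf_tem_phase(pro, ice, be, t, 1, "voxel")$F, numeric(1))
  expect_true(all(diff(Fs) < 0))
  expect_equal(cf_tem_phase(pro, ice, be, 1e-9, 1e-10, "voxel")$F, 1,
               tolerance = 1e-9)
  noMip <- toy_material(); noMip$mip <- NULL
  expect_error(cf_tem_phase(noMip, ice, be, 100, 10, "voxel"),
               "mean inner potential")
  # weak-phase warning for thick strongly phase-shifting objects
  expect_warning(cf_tem_phase(pro, ice, beam("electron", 100e3), 500, 500,
                              "column"), "weak-phase")
})

test_that("bright-field scattering contrast follows the Beer's-law model", {
  expect_equal(cf_tem_brightfield(pro, pro, be, 100, 10, "voxel")$delta_k, 0)
  expect_equal(cf_tem_brightfield(pro, ice, be, 1e-9, 1e-10, "voxel")$F, 1,
               tolerance = 1e-9)
  # contrast sign flips when feature and matrix are swapped
  a <- cf_tem_brightfield(pro, ice, be, 100, 10, "voxel")
  b <- cf_tem_brightfield(ice, pro, be, 100, 10, "voxel")
  expect_equal(a$C, -b$C, tolerance = 1e-12)
  # validity flag beyond t_max, not an exception
  thick <- cf_tem_brightfield(pro, ice, be, 900, 10, "voxel")
  expect_true(thick$beyond_validity)
})

test_that("dark field is complementary to bright field", {
  for (t in c(10, 100, 500, 2000)) {
    fb <- cf_tem_brightfield(pro, ice, be, t, 5, "voxel")$F
    fd <- cf_stem_darkfield(pro, ice, be, t, 5, "voxel")$F
    expect_equal(fb + fd, 1, tolerance = 1e-12)
  }
  expect_equal(cf_stem_darkfield(pro, ice, be, 1e-9, 1e-10, "voxel")$F, 0,
               tolerance = 1e-9)
  # saturating growth in thickness
  ts <- c(10, 50, 250, 1250)
  Fd <- vapply(ts, function(t)
    cf_stem_darkfield(pro, ice, be, t, 5, "voxel")$F, numeric(1))
  expect_true(all(diff(Fd) > 0))
  expect_true(all(Fd <= 1))
})

test_that("every mode keeps F in (0, 1] and matches column/voxel at delta = t", {
  modes <- c("xray_absorption", "xray_phase", "tem_phase",
             "tem_brightfield", "stem_darkfield")
  for (mname in modes) {
    md <- mode_config(mname)
    bm <- if (grepl("xray", mname)) bx else be
    for (t in c(20, 200)) {
      col <- contrast_efficiency(md, pro, ice, bm, t, t, "column")
      vox <- contrast_efficiency(md, pro, ice, bm, t, t, "voxel")
      lab <- paste(mname, "t =", t)
      expect_gt(col$F, 0)
      expect_lte(col$F, 1)
      if (mname != "stem_darkfield") expect_gt(vox$F, 0)
      expect_lte(vox$F, 1)
      # geometric consistency: voxel contrast at delta = t is column contrast
      expect_equal(vox$C, col$C, tolerance = 1e-12, label = lab)
    }
  }
})

test_that("the mode registry is exhaustive over modes and printed energies", {
  grid <- 10^seq(1, 2.5, length.out = 4)
  for (mname in c("xray_absorption", "xray_phase")) {
    for (E in c(500, 8000)) {
      cur <- dlr_curve(mode_config(mname), pro, ice, beam("xray", E), grid)
      expect_equal(nrow(cur), 4, label = paste(mname, E))
    }
  }
  for (mname in c("tem_phase", "tem_brightfield", "stem_darkfield")) {
    for (E in c(100e3, 300e3)) {
      cur <- dlr_curve(mode_config(mname), pro, ice, beam("electron", E),
                       grid)
      expect_equal(nrow(cur), 4, label = paste(mname, E))
      expect_true(all(is.finite(cur$delta_v_nm)))
    }
  }
})

test_that("information coefficient decays with thickness from the undamped limit", {
  expect_equal(information_coefficient(0, 0, 100, 30)$T, 1)
  z <- vapply(c(1, 10, 100, 1000), function(t)
    information_coefficient(2e-5, 6e-5, t, 30)$zeta, numeric(1))
  expect_true(all(diff(z) < 0))
  expect_lt(information_coefficient(2e-5, 6e-5, 1e6, 30)$zeta, 1e-12)
})

test_that("the damage-limited figure of merit orders resolutions correctly", {
  expect_equal(figure_of_merit(0, 0.5, pro, bx), 0)
  # strictly increasing in F at fixed contrast
  z <- vapply(c(0.1, 0.3, 0.6, 1), function(F)
    figure_of_merit(0.1, F, pro, bx), numeric(1))
  expect_true(all(diff(z) > 0))
  # higher zeta0 <=> smaller DLR at a fixed damage model
  set.seed(3)
  k <- dose_per_fluence(pro, bx, quiet = TRUE)
  N1e <- 100 / k  # fixed damage model: D_1/e = 100 MGy
  pars <- tibble::tibble(C0 = runif(12, 0.01, 0.4), F = runif(12, 0.05, 1))
  zeta0 <- mapply(function(C0, F) figure_of_merit(C0, F, pro, bx),
                  pars$C0, pars$F)
  delta <- mapply(function(C0, F)
    dlr_fixed_contrast(C0, N1e, F, DQE = 0.5), pars$C0, pars$F)
  ord <- order(zeta0)
  expect_true(all(diff(delta[ord]) < 0))
})
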