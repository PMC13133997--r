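# Worked SNR example: C0 = 10%, delta = 3.13 nm, DQE = 0.5, F = 0.1,
# N_1/e = 1e4 /nm^2 -> SNR peaks at N_1/e/2 with value 3.0.
fig2 <- list(C0 = 0.1, N_1e = 1e4, delta = 3.13, F = 0.1, DQE = 0.5)

test_that("SNR under contrast fading peaks at N_1/e/2 with the worked value", {
  s_opt <- with(fig2, snr_vs_fluence(N_1e / 2, C0, N_1e, delta, F, DQE))
  expect_equal(s_opt, 3.0, tolerance = 0.01 / 3)
  expect_equal(with(fig2, snr_vs_fluence(0, C0, N_1e, delta, F, DQE)), 0)
  # numeric maximization lands on the optimum exposure
  o <- with(fig2, oracle_snr_max(C0, N_1e, delta, F, DQE))
  expect_equal(o$N, fig2$N_1e / 2, tolerance = 1e-6)
  expect_equal(optimum_exposure(fig2$N_1e), fig2$N_1e / 2)
  expect_equal(optimum_exposure(2), 1)
  expect_error(snr_vs_fluence(-1, 0.1, 1, 1), "non-negative")
})

test_that("negative contrast enters through its magnitude", {
  expect_equal(snr_vs_fluence(500, -0.1, 1e4, 3, 0.1, 0.5),
               snr_vs_fluence(500, 0.1, 1e4, 3, 0.1, 0.5))
})

test_that("fixed-contrast DLR inverts the worked example and the oracle", {
  d <- with(fig2, dlr_fixed_contrast(C0, N_1e, F, DQE, snr = 3))
  expect_equal(d, 3.13, tolerance = 0.01 / 3.13)
  # doubling the threshold doubles delta
  expect_equal(with(fig2, dlr_fixed_contrast(C0, N_1e, F, DQE, snr = 6)),
               2 * d, tolerance = 1e-12)
  # maximize-and-invert oracle
  set.seed(7)
  for (i in 1:8) {
    C0 <- runif(1, 0.01, 0.5); N1e <- 10^runif(1, 2, 6)
    F <- runif(1, 0.05, 1); DQE <- runif(1, 0.1, 1)
    snr <- sample(c(3, 5), 1)
    expect_equal(
      dlr_fixed_contrast(C0, N1e, F, DQE, snr),
      oracle_dlr(function(d) C0, function(d) F, function(d) N1e, DQE, snr),
      tolerance = 1e-6)
  }
})

toy <- toy_material()
bx <- beam("xray", 500)

test_that("column DLR: degenerate exponent reduces to the fixed-contrast form", {
  dm0 <- damage_model(alpha = 0, D_ref_MGy = 100)
  k <- dose_per_fluence(toy, bx, quiet = TRUE)
  s <- solve_dlr_column(2e-3, t_nm = 50, damage = dm0, material = toy,
                        beam = bx, F = 0.3, DQE = 0.5, snr = 3)
  expect_equal(s$delta_nm,
               dlr_fixed_contrast(2e-3 * 50, 100 / k, F = 0.3, DQE = 0.5),
               tolerance = 1e-5)
})

test_that("column DLR scales as t^(-2/3) under the linear damage law", {
  sol <- function(t) suppressWarnings(
    solve_dlr_column(1e-3, t, material = toy, beam = bx, F = 0.5)$delta_nm)
  expect_equal(sol(200) / sol(25), 8^(-2 / 3), tolerance = 1e-5)
  t <- c(5, 20, 80, 320)
  d <- vapply(t, sol, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("voxel DLR follows the quarter-power law at fixed fluence", {
  # alpha = 0: N_1/e independent of delta; delta_v ~ N^(-1/4) over 3 decades
  sol <- function(Dref)
    solve_dlr_voxel(1e-3, 100, damage_model(alpha = 0, D_ref_MGy = Dref),
                    material = toy, beam = bx)$delta_nm
  slope <- log(sol(1000) / sol(1)) / log(1000)
  expect_equal(slope, -1 / 4, tolerance = 1e-5)
})

test_that("voxel DLR follows the fifth-power law under the linear damage law", {
  sol <- function(Dref)
    solve_dlr_voxel(1e-3, 100, damage_model(alpha = 1, D_ref_MGy = Dref),
                    material = toy, beam = bx)$delta_nm
  slope <- log(sol(1000) / sol(1)) / log(1000)
  expect_equal(slope, -1 / 5, tolerance = 1e-5)
})

test_that("DLR scales as 1/delta_k (column) and delta_k^(-2/5) (voxel)", {
  csol <- function(dk) solve_dlr_column(dk, 100, material = toy,
                                        beam = bx)$delta_nm
  # column with alpha = 1: delta ~ dk^(-2/3) self-consistently;
  # at alpha = 0 it is exactly 1/dk
  dm0 <- damage_model(alpha = 0)
  c0 <- function(dk) solve_dlr_column(dk, 100, dm0, material = toy,
                                      beam = bx)$delta_nm
  expect_equal(c0(2e-3) / c0(1e-3), 1 / 2, tolerance = 1e-5)
  vsol <- function(dk) solve_dlr_voxel(dk, 100, material = toy,
                                       beam = bx)$delta_nm
  expect_equal(vsol(1e-2) / vsol(1e-3), 10^(-2 / 5), tolerance = 1e-5)
})

test_that("solvers agree with the brute-force maximize-and-invert oracle", {
  set.seed(11)
  k <- dose_per_fluence(toy, bx, quiet = TRUE)
  for (i in 1:20) {
    dk <- 10^runif(1, -4, -2)
    t <- 10^runif(1, 1, 3)
    alpha <- runif(1, 0, 2)
    Dref <- 10^runif(1, 1, 3)
    DQE <- runif(1, 0.2, 1)
    snr <- sample(c(3, 5), 1)
    Fc <- runif(1, 0.1, 1)
    dm <- damage_model(alpha = alpha, D_ref_MGy = Dref)
    n1e <- function(d) characteristic_dose(dm, d) / k

    s_col <- suppressWarnings(
      solve_dlr_column(dk, t, dm, toy, bx, F = Fc, DQE = DQE, snr = snr))
    o_col <- oracle_dlr(function(d) dk * t, function(d) Fc, n1e, DQE, snr)
    expect_equal(s_col$delta_nm, o_col, tolerance = 1e-5)

    # voxel with a delta-dependent efficiency (absorption-style)
    mu <- 10^runif(1, -4, -3)
    F_fun <- function(d) exp(-mu * (t - min(d, t)) - 2 * mu * min(d, t))
    s_vox <- suppressWarnings(
      solve_dlr_voxel(dk, t, dm, toy, bx, F = F_fun, DQE = DQE, snr = snr))
    o_vox <- oracle_dlr(function(d) dk * d, F_fun, n1e, DQE, snr)
    expect_equal(s_vox$delta_nm, o_vox, tolerance = 1e-5)

    # the returned optimum satisfies the threshold exactly
    expect_equal(s_col$snr_at_solution, snr, tolerance = 1e-6)
    expect_equal(s_vox$snr_at_solution, snr, tolerance = 1e-6)
    # and the optimum fluence is half the characteristic fluence there
    expect_equal(s_vox$optimum_fluence, n1e(s_vox$delta_nm) / 2,
                 tolerance = 1e-9)
  }
})

test_that("a voxel solution taller than the specimen is flagged, not clamped", {
  expect_warning(
    s <- solve_dlr_voxel(1e-4, t_nm = 2, material = toy, beam = bx),
    "exceeds the specimen thickness")
  expect_true(s$voxel_exceeds_thickness)
  expect_gt(s$delta_nm, 2)
})

test_that("solutions tidy into one-row tibbles", {
  s <- solve_dlr_column(1e-3, 100, material = toy, beam = bx)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$delta_nm, s$delta_nm)
  gl <- glance(s)
  expect_true(gl$converged)
  expect_equal(gl$snr_threshold, 3)
})

test_that("DLR curves cross at delta = t and have the expected shape", {
  md <- mode_config("xray_absorption")
  pro <- dlr_materials("protein"); ice <- dlr_materials("ice")
  cur <- dlr_curve(md, pro, ice, bx, 10^seq(0, 3.5, length.out = 25))
  # column branch falls monotonically in the thin regime
  thin <- cur$t_nm <= 100
  expect_true(all(diff(cur$delta_c_nm[thin]) < 0))
  # voxel branch is flat then rises
  flat <- cur$delta_v_nm[cur$t_nm >= 10 & cur$t_nm <= 300]
  expect_lt(max(flat) / min(flat), 1.1)
  expect_gt(cur$delta_v_nm[nrow(cur)], max(flat))
  # crossing where delta = t: at the thickness t* with delta_v(t*) = t*,
  # the column and voxel solutions coincide
  s <- optimum_voxel_dlr(md, pro, ice, bx)
  expect_equal(s$delta_nm, s$thickness_nm, tolerance = 1e-4)
  cross <- dlr_curve(md, pro, ice, bx, s$thickness_nm)
  expect_equal(cross$delta_c_nm, cross$delta_v_nm, tolerance = 1e-4)
  # empty grid -> empty table
  expect_equal(nrow(dlr_curve(md, pro, ice, bx, numeric(0))), 0)
})
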