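# Independent oracles used across the suite. These re-derive results by brute
# force (numeric maximization, bisection, quadrature) without reusing the
# package's closed forms.

# SNR under exponential contrast fading, written out independently
oracle_snr <- function(N, C0, N_1e, delta, F, DQE) {
  abs(C0) * exp(-N / N_1e) * delta * sqrt(DQE * F * N)
}

# numerically maximize SNR over fluence for a fixed feature size
oracle_snr_max <- function(C0, N_1e, delta, F, DQE) {
  opt <- stats::optimize(function(N) oracle_snr(N, C0, N_1e, delta, F, DQE),
                         interval = c(1e-9 * N_1e, 20 * N_1e),
                         maximum = TRUE, tol = 1e-12)
  list(N = opt$maximum, snr = opt$objective)
}

# brute-force DLR: outer bisection on delta of (max_N SNR) - snr_threshold,
# with delta-dependent contrast, efficiency and characteristic fluence
oracle_dlr <- function(C_fun, F_fun, N1e_fun, DQE, snr,
                       lower = 1e-4, upper = 1e6) {
  g <- function(delta) {
    oracle_snr_max(C_fun(delta), N1e_fun(delta), delta,
                   F_fun(delta), DQE)$snr - snr
  }
  stats::uniroot(g, lower = lower, upper = upper, tol = 1e-12)$root
}

# numeric integration of the Lenz differential elastic cross section over
# [beta, pi] with the full spherical Jacobian 2 pi sin(theta)
oracle_lenz_sigma <- function(Z, E0_keV, beta_rad = 0) {
  me_c2 <- 510.99895e3                       # eV
  E0 <- E0_keV * 1e3
  lambda_nm <- 1239.84198 / sqrt(E0 * (E0 + 2 * me_c2))
  k0 <- 2 * pi / lambda_nm
  a0 <- 0.052917721
  gamma <- 1 + E0 / me_c2
  theta0 <- Z^(1 / 3) / (k0 * a0)
  integrand <- function(th)
    4 * gamma^2 * Z^2 / (k0^4 * a0^2) * (th^2 + theta0^2)^-2 *
      2 * pi * sin(th)
  stats::integrate(integrand, lower = beta_rad, upper = pi,
                   rel.tol = 1e-10)$value
}

# toy material with round-number properties for solver tests
toy_material <- function(mu = 1e-3, density = 1, eps = 1e-3,
                         S100 = 4, mip = 5) {
  dlr_material("toy", c(C = 1), density = density,
               xray_props = data.frame(energy_eV = 500, mu_nm = mu,
                                       one_plus_eps1 = eps),
               electron_props = data.frame(energy_keV = 100,
                                           S_MeVcm2g = S100,
                                           lambda_i_nm = 200),
               mip = mip)
}
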