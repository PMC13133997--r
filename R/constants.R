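# Canonical internal units: nm, eV, g/cm^3, MGy, particles/nm^2.
# Every unit conversion in the package goes through this table.

.const <- list(
  # hc in eV nm: lambda_photon [nm] = hc_eV_nm / E_ph [eV]
  hc_eV_nm        = 1239.84198,
  # electron rest energy, keV
  me_c2_keV       = 510.99895,
  # Bohr radius, nm
  a0_nm           = 0.052917721,
  # Avogadro constant, mol^-1
  N_A             = 6.02214076e23,
  # elementary charge, J per eV
  J_per_eV        = 1.602176634e-19,
  # speed of light, nm per fs
  c_nm_fs         = 299.792458,
  # X-ray dose: D [MGy] = N [nm^-2] * mu [nm^-1] * E_ph [eV] * k / rho [g/cm^3]
  #   (1 eV/nm^3 = 1.602176634e8 J/m^3; 1 g/cm^3 = 1000 kg/m^3; 1 MGy = 1e6 Gy)
  MGy_x_factor    = 0.1602176634,
  # electron dose: 1 e/nm^2 x 1 MeV cm^2/g = 1.602176634e-2 MGy
  MGy_e_factor    = 1.602176634e-2
)

# standard atomic weights for registry compositions
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)
.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15)
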