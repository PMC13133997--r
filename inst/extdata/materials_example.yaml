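# Example user-material config for dlr_read_materials().
# Units: energy_eV (photon energy), L_um (absorption length, micrometres),
# mu_nm (absorption coefficient, nm^-1), one_plus_eps1 (refractive-index
# decrement), energy_keV (electron energy), S_MeVcm2g (mass stopping power),
# lambda_i_nm (inelastic mean free path), density (g/cm^3), mip (volts).
epoxy_resin:
  composition: {C: 21, H: 25, O: 5}
  density: 1.15
  mip: 7.6
  xray_props:
    - {energy_eV: 500, mu_nm: 1.1e-3}
    - {energy_eV: 8000, mu_nm: 0.8e-6}
  electron_props:
    - {energy_keV: 100, S_MeVcm2g: 3.9}
    - {energy_keV: 300, S_MeVcm2g: 2.25}
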