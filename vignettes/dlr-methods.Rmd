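---
title: "Damage-limited resolution: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damage-limited resolution: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlrcalc)
```

## The problem

For organic and other beam-sensitive specimens, the resolution of X-ray and
transmission electron microscopy is often set not by the optics but by
radiolysis: ionization-driven chemistry destroys the structure being imaged,
so the particle fluence that can be spent on a feature is capped. `dlrcalc`
computes the *damage-limited resolution* (DLR): the size of the smallest
feature that can be detected before its contrast fades away, as a function
of specimen thickness, imaging mode, beam energy and the materials involved.

## The SNR model

A feature of size $\delta$ inside a thin specimen contributes
$n = F N \delta^2$ detected particles, where $N$ is the fluence
(particles/nm$^2$) and $F$ the collection efficiency of the imaging mode.
With Weber contrast $C$ the feature signal is $\Delta n = C n$, and Poisson
statistics give

$$\mathrm{SNR} = |C|\,\delta\,\sqrt{\mathrm{DQE}\; F\, N}.$$

Radiolysis makes the contrast fade approximately exponentially with fluence,
$C = C_0 e^{-N/N_{1/e}}$, where $N_{1/e}$ is the characteristic (critical)
fluence. The product $e^{-N/N_{1/e}}\sqrt{N}$ is maximal at the *optimum
exposure* $N = N_{1/e}/2$, giving

$$\mathrm{SNR}_{\max}
  = |C_0|\, e^{-1/2}\, \delta\, \sqrt{\mathrm{DQE}\; F\, N_{1/e}/2}.$$

Setting $\mathrm{SNR}_{\max}$ equal to a detection threshold (the Rose
criterion, default 3; 5 for conservative work) and inverting for $\delta$
defines the DLR. For contrast independent of $\delta$ the inversion is the
closed form implemented in `dlr_fixed_contrast()`. The canonical worked
example — $C_0 = 0.10$, $\mathrm{DQE} = 0.5$, $F = 0.1$,
$N_{1/e} = 10^4$ nm$^{-2}$ — pins this algebra: the SNR peaks at
$N = 5\,000$ nm$^{-2}$ with value 3.0 for $\delta = 3.13$ nm, which the test
suite verifies both through the closed form and by numerical maximization.

```{r}
dlr_fixed_contrast(C0 = 0.1, N_1e = 1e4, F = 0.1, DQE = 0.5, snr = 3)
```

## Column and voxel geometry

Two geometries bracket real features:

* **Column** — the feature spans the full thickness $t$, so
  $|C_0| = t\,\Delta k$ with $\Delta k$ the contrast per unit depth.
  Increasing $t$ improves the column DLR (more signal volume); with the
  linear damage law below it falls as $t^{-2/3}$.
* **Voxel** — an equiaxed feature of size $\delta \le t$, so
  $|C_0| = \delta\,\Delta k$. The extra factor of $\delta$ makes the voxel
  DLR depend only weakly on everything else: at fixed fluence it scales as
  $N^{-1/4}$, and with the linear damage law as the inverse *fifth* root of
  the reference dose.

The two branches cross where $\delta = t$; that crossing is the optimum
operating point (`optimum_voxel_dlr()` solves the $\delta_v(t) = t$ fixed
point directly). In `dlr_curve()` the voxel contrast is capped at the column
value for $\delta > t$ (an equiaxed feature cannot be taller than the
specimen), so below the crossing the two branches coincide. The raw
`solve_dlr_voxel()` deliberately applies no cap: an unphysical
$\delta_v > t$ solution is reported as-is with a warning flag, so the user
can see where the voxel description breaks down.

## Resolution-dependent damage

Fading measurements show high-resolution information is destroyed first, so
the characteristic fluence depends on the length scale recorded. The damage
model is a power law anchored at a reference resolution:

$$D_{1/e}(d) = D_{\mathrm{ref}}\,(d/d_0)^{\alpha}.$$

The default — $d_0 = 1$ nm, $D_\mathrm{ref} = 100$ MGy, $\alpha = 1$, i.e.
$D_{1/e} = 100\,d$ MGy — is the linear cryogenic calibration used for all
default curves; it gives 20–50 MGy in the near-atomic 0.2–0.5 nm range,
consistent with accepted cryo dose limits. Steeper exponents
($\alpha \approx 1.7$–2) reported below 0.5 nm are available as a piecewise
model (`damage_model(alpha = c(1.86, 1), breaks = 0.5)`), continuous across
the break by construction; they are not the default because the headline
curves all use the linear law. $\alpha = 0$ (resolution-independent damage)
is accepted as a degenerate case even though measured exponents lie in
[0.5, 2]; it reduces the solver to the fixed-contrast closed form and is
used as such in the tests. Values $\alpha < 0.5$ other than 0 (e.g. the
speculative 0.7 diffusion regime) are accepted as parameters but never used
as defaults.

Since contrast and damage both depend on $\delta$, the DLR equation is
self-consistent. The solver brackets $\log\delta$ in $[10^{-3}, 10^{5}]$ nm
and bisects to a relative tolerance of $10^{-6}$ (at most 200 iterations),
re-evaluating any $\delta$-dependent efficiency inside the bracket function
rather than in a separate fixed-point loop. The test suite checks every
solver against a brute-force oracle (outer bisection on $\delta$, inner
numerical maximization of the SNR over $N$) on randomized parameter sets.

## Dosimetry

Gray units allow electron and X-ray damage to be compared. For thin
specimens,

* X-rays: $D = N\,\mu\,E_\mathrm{ph}/\rho$, valid while the absorbed
  fraction is small ($t \ll L = 1/\mu$). In the package's canonical units
  (nm, eV, g/cm$^3$) the conversion constant is
  $0.1602$ MGy per (photon nm$^{-2}$ · nm$^{-1}$ · eV / (g cm$^{-3}$)).
* Electrons: $D = N\,S'$ with $S'$ the mass stopping power;
  1 e/nm$^2$ × 1 MeV cm$^2$/g = $1.602\times10^{-2}$ MGy.

Two conversion bases are exposed. The default (`"computed"`) applies these
formulas to the registry's material constants. A `"table"` basis returns the
published conversion-factor table verbatim. For ice (both energies), PMMA
(both) and carbon at 8 keV the two agree to the printed precision; for
protein (both X-ray energies) and carbon at 500 eV they differ by 20–30%,
which the package surfaces as a warning rather than hiding — the published
protein factor cannot be reproduced from the published optical constants.
The dose basis for DLR solves (does the *feature* or the *matrix* absorb the
characteristic dose?) is an explicit parameter, defaulting to the feature
material.

## Contrast modes

Each mode supplies $(C, F)$ as functions of $(t, \delta)$:

* **X-ray absorption** (`xray_absorption`): $C = (\mu_f - \mu_m)\,z$ in the
  thin limit; $F = e^{-\mu_f t}$ for a column. For a voxel the beam crosses
  matrix for $t - \delta$ and feature for $\delta$, so
  $F = e^{-\mu_m (t-\delta) - \mu_f \delta}$; this reduces to the common
  $e^{-\mu_m t}$ approximation when the coefficients are close or
  $\delta \ll t$, and the exact two-material path is used throughout.
* **X-ray (Zernike) phase** (`xray_phase`): the phase advance per unit path
  through a refractive-index difference $\Delta\varepsilon_1$ is
  $(2\pi/\lambda)\Delta\varepsilon_1$, and an ideal phase plate converts a
  weak phase shift into contrast $C = 2\,\Delta\phi$, so
  $C = 2(2\pi/\lambda)\Delta\varepsilon_1 z$. The efficiency is the
  absorption expression of the column geometry. The factor 2 mirrors the
  weak-phase TEM convention; with it the 500 eV protein-in-ice voxel DLR
  lands within ~15% of the corresponding absorption-contrast value, as
  expected for the water window.
* **TEM phase** (`tem_phase`): $d\phi/dz = \pi\,\mathrm{RF}\,\Phi /
  (\lambda E_0)$, with $\mathrm{RF} = (1 + E_0/511\,\mathrm{keV})/(1 +
  E_0/1022\,\mathrm{keV})$ (1.09 at 100 keV, 1.23 at 300 keV) and $\Phi$
  the mean inner potential; contrast from the MIP *difference*, again
  $C = 2\Delta\phi$ for a weak phase object (warned above
  $\Delta\phi = 0.5$). The efficiency removes electrons lost to plural
  elastic and to any inelastic scattering,
  $F = \exp(-t/\lambda_e - t/\lambda_i)$ — the package's transcription of
  the "elastic and inelastic mean free path" efficiency for an ideal-phase-
  plate image with no contribution from mixed scattering. A Volta-style
  phase plate is represented by halving the DQE in `mode_config()`.
* **Bright-field scattering contrast** (`tem_brightfield`): Beer's law with
  a $\beta$-dependent scattering length,
  $F = \exp(-t/L_m(\beta))$, $\Delta k = 1/L_f - 1/L_m$, where $L(\beta)$
  is the Lenz-model elastic mean free path for scattering *beyond* the
  aperture semi-angle $\beta$ (default 5 mrad). Beyond a validity thickness
  (default 500 nm, configurable; measured values range 150–750 nm at
  300 keV depending on material) plural scattering invalidates Beer's law
  and results carry a `beyond_validity` flag.
* **Dark-field STEM** (`stem_darkfield`): the annular detector collects what
  the bright-field aperture rejects, $F = 1 - \exp(-t/L_m(\beta))$ —
  exactly complementary under the shared single-scattering model
  ($F_\mathrm{BF} + F_\mathrm{DF} = 1$). Whether inelastic removal should
  additionally attenuate the dark-field signal is ambiguous; it is available
  as the optional `zero_loss` multiplier $e^{-t/\lambda_i}$, off by
  default, for both scattering modes.

Geometric consistency — voxel contrast at $\delta = t$ equals column
contrast — holds for every mode and is enforced by tests.

### Figures of merit

`information_coefficient()` reports the unscattered fraction
$T = \exp[-n t(\sigma_e + \sigma_i)]$ together with
$\zeta = \sigma_e/(\sigma_e + \sigma_i)\, T$, a thickness-dependent
information coefficient for phase contrast when chromatic aberration
disperses every scattered electron. The exact published form of this
coefficient is not fixed by the prose it comes from; the transcription here
satisfies the constraints that matter (undamped limit $T = 1$, monotone
decay with thickness, vanishing as $t \to \infty$).
`figure_of_merit()` implements the damage-limited alternative: from the DLR
closed form, resolution at a fixed damage model improves with
$|C_0|\sqrt{F/k}$, where $k$ is the fluence-to-dose factor; larger values
mean finer DLR, monotonically.

## Material registry and its provenance

Built-ins: `protein` (H$_{50}$C$_{30}$N$_9$O$_{10}$S, 1.35 g/cm$^3$), `ice`
(vitreous, 0.94), `pmma` (1.19), `carbon` (amorphous, 1.8). Three tiers of
constants:

1. **Tabulated** (Henke-style): X-ray absorption lengths/coefficients at
   500 eV and 8 keV, and $1+\varepsilon_1$ decrements for protein and ice.
   Where both $L$ and $\mu$ are stored they must agree ($\mu L = 1$ within
   1%) and the stored $\mu$ takes precedence. One tabulated pair (carbon at
   500 eV) is internally inconsistent by 21%; only its $\mu$ is kept.
2. **ESTAR-style stopping powers**: not part of the optical tabulations;
   stored values are consistent with the standard electron conversion
   factors for these materials (e.g. ice 4.06 MeV cm$^2$/g at 100 keV vs
   the ESTAR water value 4.115).
3. **Defaults flagged as assumptions**: mean inner potentials (protein
   8.0 V, ice 3.5 V, PMMA 7.8 V, carbon 9.1 V) and inelastic mean free
   paths. These drive the TEM-phase rows only; the summary table marks
   every electron-mode row `assumed_constants = TRUE`, and all DLR
   operations accept explicit overrides so nothing downstream is silently
   tied to them.

The Lenz elastic model uses the screened-Rutherford small-angle form with
screening angle $\theta_0 = Z^{1/3}/(k_0 a_0)$, integrated in closed form
over $[\beta, \pi]$; composite materials sum per-atom cross sections by
stoichiometry. The closed form is tested against numerical quadrature of
the same differential cross section with the full spherical Jacobian
(agreement well under 0.5%; the scattering is concentrated at mrad angles).
Where no tabulated inelastic mean free path exists the
$\sigma_i/\sigma_e \approx 20/Z$ rule provides an estimate — adequate for
the qualitative thickness dependence it feeds, not for quantitative
inelastic work. Plural-scattering angular redistribution beyond Beer's law
is deliberately out of scope.

User materials load from YAML (`dlr_read_materials()`; see
`inst/extdata/materials_example.yaml`), and `perturb_material()` builds
density-perturbed variants such as the "10% organelle" pairing, scaling
$\mu$, $1+\varepsilon_1$, $\Phi$ and density together.

## Localization of radiolysis

X-ray absorption ejects a photoelectron or Auger electron of range
$R(\mathrm{nm}) = 0.01\,E^{1.3}$ ($E$ in eV, organic matter). Its energy is
deposited along the track following the Everhart–Hoff universal depth–dose
polynomial $\lambda(y) = 0.60 + 6.21y - 12.40y^2 + 5.69y^3$ on $y = z/R$,
renormalized so the cumulative fraction reaches exactly 1 at $y = 1$
(the raw polynomial integrates to 0.994). A time scale follows by
integrating the inverse relativistic speed along the depth, with the
residual kinetic energy at each depth equal to the initial energy minus the
cumulative deposition (floored at $10^{-4}$ of the initial energy so the
end-of-range speed stays finite). The half-energy times computed this way
are of order 1–2 fs at 500 eV and 10–20 fs at 8 keV.

Caveat: this is a *depth* profile along the track, the quantity the
Everhart–Hoff parameterization actually provides. Radial spreading is not
modelled; mapping depth to an isotropic radial point-spread function would
be an additional approximation, and a user-supplied PSF table is the
supported route for quantitative delocalization work. Consistent with that,
the computed 8 keV half-energy depth (~0.4 of the range) is smaller than
delocalization distances sometimes quoted from radial constructions; the
package does not force agreement.

## Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| SNR threshold | 3 | Rose detection criterion (5 = conservative) |
| DQE | 0.5 | detector chain noise degradation |
| $\beta$ | 5 mrad | BF aperture / DF inner angle |
| $d_0$, $D_\mathrm{ref}$, $\alpha$ | 1 nm, 100 MGy, 1 | linear damage law $D_{1/e} = 100\,d$ MGy |
| dose basis | feature | material assumed to absorb $D_{1/e}$ |
| conversion basis | computed | thin-specimen formulas on registry constants |

## Problem sizes and determinism

All core quantities are closed-form or one-dimensional root-finds, so every
result is exact-arithmetic deterministic: repeated runs (and the
config-driven `dlr_run()`) emit byte-identical files. The test suite
evaluates 60-point log-spaced thickness curves and 20-case randomized
oracle comparisons per mode under fixed seeds; these sizes fully resolve
the power-law scalings being checked, and a full two-pairing 60-point curve
evaluates in well under a second.

## Known limitations

* Weak-contrast linearization ($|C_0| = t\Delta k$) is used as stated; the
  solvers warn when $|C_0| > 0.3$.
* Instrumental resolution limits (aberrations, beam broadening, depth of
  field) are intentionally excluded: DLR is a property of dose and
  contrast, separate from optics, and cannot be folded into a PSF.
* Temperature dependence of the critical dose, dose-rate effects and dark
  progression are not modelled.
* Single-particle averaging and crystalline ("Bragg boost") signal
  amplification are out of scope: all results are for single features.
* Absolute TEM-phase/BF/DF values inherit the uncertainty of the assumed
  mean inner potentials and mean free paths; their thickness and parameter
  *scalings* are the tested, reliable content.
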