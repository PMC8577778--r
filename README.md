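# rfdosim

Radio-frequency (RF) dosimetry of insect-scale bodies by
finite-difference time-domain (FDTD) simulation, 2–240 GHz.

As telecommunication carriers move into the millimetre-wave band, their
wavelengths approach the body size of insects, and absorbed RF power —
the proxy for dielectric heating — can rise sharply near whole-body
resonance. rfdosim is for researchers who want to quantify that
absorption for small dielectric bodies such as the yellow fever
mosquito (*Aedes aegypti*): it bundles the dielectric model, the
geometry tooling, the field solver and the exposure protocol such a
study needs, each independently testable against analytic oracles.

The pipeline:

* **Dielectric**: a multi-relaxation Debye model with static
  conduction,
  ε′(ω) = ε∞ + Σᵢ Δεᵢ/(1+(ωτᵢ)²),
  ε″(ω) = σs/(ωε₀) + Σᵢ Δεᵢωτᵢ/(1+(ωτᵢ)²),
  σ = ε″ωε₀ — evaluation, bounded least-squares fitting to
  coaxial-probe spectra (5–67 GHz grid), and extrapolation to
  2–300 GHz. Fitted two-relaxation parameter rows for homogenized
  *A. aegypti* tissue are built in (`aedes_debye()`).
* **Geometry**: STL read/write (ASCII and binary), parity ray-casting
  voxelization on uniform grids, morphometrics (volume, body length,
  bounding-box diagonal), body-part partitioning and editing (e.g. leg
  removal).
* **Synthetic data**: noisy spectra on the measurement grid and a
  parametric mosquito-like phantom (labeled head/thorax/abdomen/legs)
  matched to specimen morphometrics, plus homogeneous-sphere phantoms.
* **Solver**: a 3-D Yee-grid FDTD for conductive dielectrics with
  convolutional-PML absorbing boundaries, exact plane-wave excitation
  at arbitrary incidence via the scattered-field formulation,
  steady-state phasor extraction, and absorbed power
  P_abs = ∫σ|E_rms|²dV (volume and Poynting-flux estimators). An
  independent Mie-series oracle validates it on lossy spheres.
* **Exposure protocol**: the 12 standard plane waves (6 directions ×
  2 polarizations, 1 V/m RMS), frequency sweeps, seeded random
  orientations, per-part absorption, quadratic field rescaling
  (P_abs,real = P_abs(1 V/m)·E²), group comparison
  (Kolmogorov–Smirnov) and sensitivity experiments.

## Worked example

```r
library(rfdosim)

## the built-in A. aegypti dielectric rows
evaluate_debye(aedes_debye("eps"), 240e9)
#> eps_real eps_imag    sigma
#>   4.7441   1.5091  20.1488

wavelength_in_medium(240e9, 4.7441) * 1e6   # smallest in-medium wavelength, um
#> [1] 573.4988

loss_peak_frequency(aedes_debye("sigma")) / 1e9   # GHz
#> [1] 9.499264

## fit recovery from a noisy synthetic probe spectrum (265 points)
tr <- aedes_debye("pair")
sp <- synth_spectrum(tr$eps, params_sigma = tr$sigma,
                     noise = noise_model(0.01, 0.01, seed = 7))
fit_debye(sp, n_relaxations = 2)
#> Debye fit (2 relaxations, separate mode)
#>   R^2 eps' = 0.999287, R^2 sigma = 0.999253
#> eps' row: Debye parameters (2 relaxations)
#>   eps_inf = 4.48447
#>   relaxation 1: delta_eps = 13.3329, tau = 14.918 ps
#>   relaxation 2: delta_eps = 5.11334, tau = 3.47708 ps
#>   sigma_s = 0 S/m
#> sigma row: Debye parameters (2 relaxations)
#>   eps_inf = 1
#>   relaxation 1: delta_eps = 12.763, tau = 12.1542 ps
#>   relaxation 2: delta_eps = 4.2009, tau = 2.51221 ps
#>   sigma_s = 1.324131 S/m

## a labeled male phantom at 25 um voxels
ph <- make_phantom(phantom_spec(), h = 25e-6)
model_metrics(ph$model)
#> $volume_mm3
#> [1] 0.8100938
#>
#> $body_length_mm
#> [1] 3.525
#>
#> $diagonal_mm
#> [1] 5.527262

## Mie oracle: power absorbed by a 0.5 mm sphere of mosquito tissue
## at 60 GHz, 1 V/m incident RMS field
d <- debye_curve(aedes_debye("eps"), aedes_debye("sigma"), 60e9)
mie_absorbed_power(0.5e-3, d$eps_real, d$sigma_s_per_m, 60e9) * 1e9   # nW
#> [1] 1.635521
```

The numbers read as follows: at 240 GHz the tissue permittivity has
relaxed to ε′ ≈ 4.74, putting the in-medium wavelength at 573.5 µm —
the quantity that sets the grid rule h ≤ λ_med/10 for every
simulation. The loss factor peaks near 9.5 GHz, the signature of the
slower Debye relaxation over the static-conduction tail. A
two-relaxation fit to a 1%-noise synthetic spectrum returns the
generating parameters within a few percent with R² ≈ 0.999, and a
half-millimetre sphere of this tissue in a 1 V/m far field at 60 GHz
absorbs 1.64 nW — the closed-form anchor the FDTD solver is validated
against (12-wave mean within 5% on a conformal sphere domain).

An exposure study then runs through one call, e.g.

```r
res <- run_protocol(phantom_spec(n_legs = 0, proboscis_length = 0),
                    config = exposure_config(
                      frequencies_ghz = c(2, 6, 12, 24, 60, 90),
                      voxel_um = 140))
aggregate_exposure(res)$per_model
```

which exposes the phantom to all 12 waves per frequency and tabulates
absorbed power per wave and body part (see the methods vignette,
`vignettes/rf-dosimetry.Rmd`, for the physics, the defaults and their
rationale). A thin command-line wrapper over the same functions is
installed at `inst/cli/rfdosim` (subcommands `fit`, `synth`,
`voxelize`, `metrics`, `simulate`, `protocol`, `sensitivity`).

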