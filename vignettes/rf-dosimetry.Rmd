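---
title: "Radio-frequency dosimetry of insect-scale bodies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radio-frequency dosimetry of insect-scale bodies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rfdosim estimates the radio-frequency (RF) power absorbed by
insect-scale dielectric bodies exposed to far-field plane waves between
roughly 2 and 240 GHz — the band where 4G/5G carrier wavelengths cross
the body size of a mosquito and whole-body resonance effects appear.
This vignette is the package's own account of the science it
implements: the dielectric model, the solver, the synthetic inputs, the
exposure protocol, and the numerical decisions behind them.

## The dielectric model

Biological soft tissue in this band is well described by a sum of Debye
relaxations plus static ionic conduction. With angular frequency
$\omega = 2\pi f$, relaxation strengths $\Delta\epsilon_i$, relaxation
times $\tau_i$, high-frequency permittivity $\epsilon_\infty$ and static
conductivity $\sigma_s$:

$$\epsilon'(\omega) = \epsilon_\infty +
  \sum_i \frac{\Delta\epsilon_i}{1 + (\omega\tau_i)^2}, \qquad
\epsilon''(\omega) = \frac{\sigma_s}{\omega\epsilon_0} +
  \sum_i \frac{\Delta\epsilon_i\,\omega\tau_i}{1 + (\omega\tau_i)^2},$$

with $\sigma(\omega) = \epsilon''\,\omega\epsilon_0$. The package ships
two fitted two-relaxation parameter rows for homogenized *Aedes
aegypti* tissue measured by open-coaxial-probe spectroscopy at 22 °C
(`aedes_debye()`): one row fitted to $\epsilon'$
($\tau_1 = 3.493$ ps, $\Delta\epsilon_1 = 4.978$,
$\tau_2 = 14.68$ ps, $\Delta\epsilon_2 = 13.24$,
$\epsilon_\infty = 4.544$) and one to $\sigma$
($\tau_1 = 2.477$ ps, $\Delta\epsilon_1 = 4.213$, $\tau_2 = 12.23$ ps,
$\Delta\epsilon_2 = 12.89$, $\sigma_s = 1.297$ S/m). The pipeline
deliberately evaluates $\epsilon'$ from the first row and $\sigma$
(hence $\epsilon''$) from the second, mirroring how the two quantities
were tabulated from the measurement; the two rows are close but not
Kramers–Kronig consistent, so no such consistency is asserted anywhere.
Single-relaxation fits are supported, but no built-in single-relaxation
parameter row is shipped: only the two-relaxation rows are available as
vetted values. With these rows, $\epsilon'$ decreases monotonically and
$\sigma$ increases monotonically over 2–300 GHz, and $\epsilon''(f)$
has a single interior maximum near 9.5 GHz — the relaxation signature
of the slower ($\tau_2$) process, with the $\sigma_s/\omega\epsilon_0$
term dominating below it.

`fit_debye()` recovers such parameters from a measured spectrum by
bounded Levenberg–Marquardt least squares with relative (scale-free)
residuals, so $\epsilon'$ (dimensionless, ~5–20) and $\sigma$ (S/m,
~1–20) contribute comparably. Because relaxation-time labels can swap
and the loss surface has local minima, the fit restarts from a
deterministic grid of log-spaced $\tau$ values in $[0.1, 100]$ ps and
keeps the best deviance; bounds are $\Delta\epsilon_i \ge 0$,
$\sigma_s \ge 0$, $\tau_i \in [0.1, 100]$ ps. The default `"separate"`
mode fits the two rows independently; a `"joint"` mode (one parameter
set against both quantities, pooled relative residuals) exists because
either convention is defensible when only tabulated rows survive of a
measurement. On noiseless self-generated spectra both modes recover
all parameters to well under 1%.

The measurement grid emulated by the synthetic module
(`dak_tl_grid()`) is the native grid of a 5–67 GHz thin-layer
coaxial-probe kit: 50 MHz steps from 5 to 6 GHz, then 250 MHz steps to
67 GHz — 265 points. Outside the measured band the Debye rows serve as
the extrapolation model, down to 2 GHz and up to 300 GHz.

## Synthetic inputs and what they stand in for

Real inputs to a study like this are specimen micro-CT meshes and probe
spectra; the synthetic module generates stand-ins with known ground
truth.

**Spectra.** `synth_spectrum()` evaluates the Debye rows on the
measurement grid and applies independent multiplicative noise per
frequency, $1 + s\,z$ with $z$ truncated-normal ($|z| \le 3.5$).
Defaults $s_{\epsilon'} = 4.04\%$ and $s_\sigma = 5.81\%$ match the
observed inter-sample spread of the homogenate measurements. Truncation
rather than a lognormal keeps the factor symmetric around 1 at these
small sds while guaranteeing positivity; the two choices are
indistinguishable at the percent level. What this does *not* emulate:
frequency-correlated probe calibration error (real probe uncertainty is
strongly correlated across neighboring frequencies), so parameter
recovery under this noise model is somewhat easier than on real
spectra.

**Phantoms.** `make_phantom()` builds a mosquito-like body from
analytic solids along a chosen grid axis: a spherical head, a prolate
ellipsoidal thorax (axially inflated 12% so the segments fuse into one
connected body), a prolate ellipsoidal abdomen, an optional cylindrical
proboscis, and up to six cylindrical legs rooted on the thorax surface
pointing down and outward. Head/thorax/abdomen axial fractions default
to 0.15/0.30/0.55 of the body length, and the thorax is 1.25× wider
than the abdomen — proportions chosen once to look like a resting
mosquito. The transverse scale is solved on the voxel grid (three
fixed-point iterations) so the occupied volume hits the target within
1–5%, and the axial span equals the body-length target within one
voxel. Defaults target the mean morphometrics reported for micro-CT-scanned
male specimens (length 3.544 mm, volume 0.812 mm³);
`sex = "female"` targets the female means (4.015 mm, 1.196 mm³).
Deliberately absent: wings, antennae, scales and internal tissue
contrast — the specimen models the phantom stands in for also lack
fine structures, and the body is simulated as a homogeneous dielectric
throughout. The emitted mesh is the exact boundary surface of the
voxel mask (two triangles per exposed face): watertight by
construction and consistent with the mask under re-voxelization, at
the cost of a blocky, non-smooth surface. Smooth test geometry comes
from `sphere_mesh()` / `make_sphere_phantom()`, which also provide the
homogeneous sphere used by the analytic oracle.

## Geometry

`voxelize()` marks a voxel occupied iff its center lies inside the
closed mesh, decided by parity ray casting along $+x$. Degenerate hits
(a ray grazing a triangle edge or vertex, which happens systematically
for blocky meshes) are re-cast with a small deterministic jitter that
grows over up to six attempts, so the result is reproducible
bit-for-bit. The grid is padded by 1.25 cells beyond the mesh bounding
box — the quarter-cell offset keeps voxel centers off axis-aligned
surfaces that would otherwise coincide exactly with grid planes.
Morphometrics follow the conventions used for specimen models: volume is occupied count
times $h^3$; body length is the occupied extent along the declared
body axis, restricted to the head/thorax/abdomen labels when labels
exist (an automated stand-in for the anatomical pronotum-to-abdomen
measurement, which cannot be recovered from an unlabeled scan); the
diagonal is the space diagonal of the occupied bounding box, which is
dominated by legs when they are present. Body-part views
(`partition_parts()`) accept label selectors or axis-aligned boxes;
boxes are half-open ($[lo, hi)$) so face-adjacent boxes partition the
voxels deterministically, and each view reports both its occupied
volume and (for boxes) the region volume, since per-part averaging can
be defined against either.

## The field solver

`run_fdtd()` advances Maxwell's curl equations on a staggered Yee grid
with a conductivity term (leapfrog; E on integer steps, H on
half-steps), time step $0.98\,h/(c\sqrt{3})$ snapped so an incident
period is an integer number of steps. Materials are sampled at each
staggered field position as the mean of the voxel cells sharing that
edge (plain one-cell staircase sampling is available as
`averaging = "cell"`).

**Plane-wave injection.** The solver advances the *scattered* field:
the incident plane wave — arbitrary direction and polarization, peak
amplitude $\sqrt{2} E_{rms}$, raised-cosine turn-on over two periods —
enters analytically as a source current in every cell whose material
differs from vacuum. This makes oblique and randomly oriented
incidence exact (no total-field/scattered-field interface bookkeeping)
at the cost of evaluating the incident field in material cells each
step, a good trade for compact scatterers. Total fields are recovered
by adding the analytic incident phasor.

**Boundaries.** The grid is terminated by a stretched-coordinate
convolutional PML (10 cells, cubic conductivity grading, $10^{-6}$
target reflection) behind a PEC wall, applied to the scattered field
on all six faces. In the continuous limit this is the same
stretched-coordinate absorber as the uniaxial PML; the convolutional
form was chosen because it admits lossy interior media in one unified
update. Absorbed power is insensitive to the air gap between scatterer
and PML (tested 6 → 24 cells, change $< 10^{-3}$ relative).

**Termination.** A run must complete at least the period floor of
`required_periods()` — 7 periods at 2 GHz rising log-linearly to 35 at
240 GHz, never less than twice the body size over the wavelength plus
a margin — and then continue until the cycle-averaged absorbed power
changes by less than `conv_tol` ($10^{-3}$ by default) between
consecutive periods. Phasors are then extracted by projecting onto
$\cos\omega t$ / $\sin\omega t$ over whole final periods; because the
time step divides the period exactly, the projection has no spectral
leakage.

**Absorbed power.** Two estimators are reported.
`compute_pabs()` integrates $\sigma |E_{rms}|^2 h^3$ over (a region
of) the body — the textbook definition, and the only one that
resolves body parts. `compute_pabs_flux()` integrates the net
time-averaged Poynting vector $\mathrm{Re}(E \times H^*)$ over a
closed box in the air gap, with H obtained from the discrete Faraday
law. In steady state the two agree to the solver's numerical floor;
the flux form is reported as the whole-body `pabs` because it is the
natural power-balance diagnostic. Neither estimator escapes the real
limitation: a staircased surface of a strongly lossy body *physically
absorbs more in the discrete model* than the smooth body it
approximates, because the normal-field jump (factor $|\hat\epsilon|$,
here ≈ 8.5 at 60 GHz) cannot be represented inside one cell. This
error is first order in $h$ and can reach tens of percent at a few
cells per radius — which is why the solver is validated against the
Mie oracle with `conformal_sphere_domain()`: each staggered sample
near the sphere surface is treated as a small capacitor network,
harmonically averaging the complex permittivity along the field
direction (series path, exact chord fractions) and arithmetically
across the transverse face (parallel paths). On the validation sphere
(radius 0.5 mm, mosquito dielectric at 60 GHz) at a 38 µm grid — the
smallest in-medium wavelength in the band (573.5 µm at 240 GHz) over
15 — this
brings the solver within ~2% of the Mie series, versus ~12% for the
plain staircase. Insect models keep the plain staircase, matching how
voxelized specimen models are normally simulated; comparisons between
staircased models (frequency trends, ratios, leg removal, sex
differences) share the bias and are therefore far more accurate than
any single absolute value.

**Oracle.** `mie_absorbed_power()` is an independent closed form, not
a wrapper: absorption efficiency from the Mie series (logarithmic-
derivative downward recursion, Riccati–Bessel upward recursion,
truncated at $x + 4x^{1/3} + 2$ and verified converged) times the
geometric cross-section times the incident power density
$E_{rms}^2/\eta_0$. It agrees with the quasi-static closed form
$P = \sigma\,|3/(\hat\epsilon + 2)|^2 E_{rms}^2\,(4\pi r^3/3)$ within
1% at $r = \lambda/100$ and with an arbitrary-precision Bessel
evaluation to all printed digits.

## The exposure protocol

A resting or flying insect sees far-field RF from unknown directions —
formally, any field in the Fraunhofer region
($r \gg 2l^2/\lambda$, `far_field_min_distance()`) is a superposition
of plane waves. The protocol therefore exposes each model to twelve
standard waves (`standard_12_waves()`): propagation along
$\pm x, \pm y, \pm z$, two orthogonal polarizations each, 1 V/m RMS.
The ordering convention is ours and documented (directions
$+x, -x, +y, -y, +z, -z$; polarizations along the remaining axes in
axis order). `random_waves()` supplements them with seeded
uniformly-random incidence and polarization (30 draws being the
conventional check size). Since the solver is linear, results at any
field strength follow from `scale_pabs()`:
$P_{abs}(E) = P_{abs}(1\,\mathrm{V/m})\cdot E^2$.

`run_protocol()` sweeps the frequency list (default 2, 6, 12, 24, 60,
90, 120, 240 GHz), evaluating $\epsilon'$ and $\sigma$ from the two
Debye rows at each frequency, enforcing the $h \le \lambda_{med}/10$
grid rule, running every wave and recording whole-body and per-part
absorbed power in a tidy table. When given a `phantom_spec` rather
than a fixed voxel model, it rebuilds the phantom at each frequency at
the pitch the grid rule allows — per-frequency regridding, which is
why part volumes can vary slightly across frequencies. Per-part
absorbed power is integrated over the part's own occupied voxels, and
the part's occupied volume is reported alongside so users can form
volume-averaged absorption; averaging against a bounding-region volume
instead is possible via box selectors, since either denominator is a
defensible reading of "averaged over the part volume".

`aggregate_exposure()` summarizes per model and group (mean/min/max by
frequency), forms frequency-pair ratios of the grand mean over all
models and waves, and compares two groups (e.g. male vs female) with a
two-sample Kolmogorov–Smirnov test computed from the empirical-CDF
definition, pooling the per-wave whole-body values — the pooling
choice is ours, made because nothing in a tabulated KS p-value reveals
what samples entered it. `sensitivity_suite()` reruns the protocol
under $\pm 4.04\%$ on $\epsilon'$ and $\pm 5.81\%$ on $\sigma$ (the
measured inter-sample spread), under a refined grid, and with legs
removed, reporting maximal relative deviations.

## Problem sizes, tolerances and degenerate inputs

The shipped test suite exercises the full pipeline at reduced sizes
chosen as the package's desk-scale defaults: the validation sphere at
a 38 µm grid (~52³ cells including absorber), and the protocol on a
legless male phantom at 140 µm pitch for 2–90 GHz (rebuilt at ~109 µm
for 120 GHz), with an 8-cell PML and 4-cell gap and one projection
period. At these sizes the qualitative protocol findings are stable:
mean absorbed power rises monotonically from 2 to 90 GHz; below
90 GHz the twelve waves collapse into three bundles of four by
polarization axis (within-bundle spread < 10%); the spectrum is
unimodal with its peak at or above 90 GHz; and the 60/6 GHz and
120/6 GHz ratios of mean absorbed power land near the ~16× and ~21.8×
reported for the specimen models. Per-specimen absolute powers are
*not* reproduced: they require the actual micro-CT models, most of
which are not publicly deposited, and absolute staircase values at
coarse pitch carry the boundary bias discussed above.

Degenerate inputs fail loudly rather than silently: non-positive
frequencies, non-orthogonal polarizations, empty meshes and models,
open surfaces in strict voxelization, constant or under-determined
spectra (fewer than three points per free parameter), infeasible
phantom targets, grid-rule violations, and solver divergence or
non-convergence all raise errors that name the offending quantity.
Ties are broken deterministically throughout: ray-casting jitter is
fixed, boxes are half-open, labels at staggered positions take the
lower adjacent cell, and multi-start fitting uses a fixed start grid,
so every result in the package is reproducible without any RNG state
except where a seed is an explicit argument.

## Known limitations

* Homogeneous tissue only; real insects have internal dielectric
  contrast that redistributes absorption.
* Staircase materials for voxel models: absolute absorbed power at
  coarse pitch is biased high; trends and ratios are robust.
* The phantom is a caricature: correct length, volume and gross
  segmentation, but no wings, antennae or surface texture, so
  surface-dominated effects at the lowest frequencies are only
  qualitatively right.
* Single-frequency runs only: exposure at multiple simultaneous
  carriers, pulsed sources and near-field antennas are out of scope,
  as is converting absorbed power into temperature rise.
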