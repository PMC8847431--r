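---
title: "Multi-modal imaging with a hybrid Compton camera ring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal imaging with a hybrid Compton camera ring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The instrument and its three modalities

`hccimager` models a ring of hybrid Compton cameras (HCCs).  Each camera is
a pair of pixelated GAGG scintillator planes: a 45 x 45 front plane of
1 x 1 x 3 mm pixels with a 3 x 3 mm aperture machined through its center,
and a 45 x 45 rear plane of 1 x 1 x 5 mm pixels 40 mm behind it.  Four
cameras face the world origin with opposite front faces 300 mm apart; the
source is rotated in 30 degree steps (three rotations by default, i.e.
twelve effective view angles).

One hardware configuration supports three imaging modes simultaneously,
selected purely in software after the measurement:

* **Compton mode** (photons above roughly 200 keV): the photon scatters in
  the thin front plane and the scattered photon is absorbed in the rear
  plane of the same camera.  The energy pair (front deposit `E_f`, rear
  deposit `E_r`) fixes the scattering angle through the Compton relation
  `cos(theta) = 1 - m_e c^2 (1/E_r - 1/(E_f + E_r))`, so each event
  constrains the source to a cone.
* **Pinhole mode** (photons below roughly 200 keV): the front plane is
  nearly opaque at these energies and acts as an *active* pinhole shield —
  photons that touch it are detected and vetoed, and only photons through
  the central aperture reach the rear plane, which then works as a pinhole
  camera.
* **PET mode**: a back-to-back 511 keV annihilation pair absorbed by two
  different cameras defines a line of response (LOR).

## Event model and selection

Hits are list-mode records (time, camera, plane, pixel, blurred deposit).
Coincidence grouping is greedy with a 100 ns window anchored at the first
hit of each event; the window length is configurable (the instrument
timestamps all cameras on a common clock, and no value is published — 100
ns is typical for scintillator coincidence electronics).  Hit patterns
classify candidates per camera: front-and-rear for Compton, rear-only for
pinhole, two cameras with deposits for PET.  Energy windows per target
nuclide then select the events; Compton targets carry both a front-deposit
window (which removes back-scatter topologies) and a total-energy window.
The windows are tabulated in `energy_cut()` for Cs-137 (662 keV), Am-241
(60), Na-22 (511), Ga-67 (93 and 300), In-111 (245) and At-211 (79).

Multi-hit events sum deposits per plane and use the highest-energy pixel
per plane as the interaction position.  A PET endpoint is the front-pixel
center when the front plane fired, else the rear-pixel center.  Events may
be candidates for several modes at once; each reconstruction run makes its
own selection.

## The Monte Carlo event generator

The simulator emulates the acquisitions end to end: decays form a Poisson
process at the summed activity; emission lines are sampled from embedded
nuclide tables; annihilation pairs are emitted back to back; photons
optionally traverse a water slab with narrow-beam survival
`exp(-mu_w(E) d / cos(alpha))`; photons entering a front face either pass
the aperture, interact in the front slab (photoelectric stop or a
Klein-Nishina-sampled Compton scatter), or transmit; whatever reaches the
rear plane is absorbed there with its slant-path interaction probability,
depositing its full energy.  Deposits are blurred with the resolution
model below and a 1 keV readout threshold is applied.

Choices worth making explicit:

* **Attenuation data.** Water and GAGG mass-attenuation tables are
  embedded (log-log interpolated).  Water values follow the standard
  compilations to within a percent; the GAGG photoelectric column is an
  element-weighted digitization dominated by gadolinium (K edge at
  50.2 keV, represented by two adjacent grid points) and is accurate to
  tens of percent, which is ample for the loose efficiency-scale checks it
  feeds.  Coherent scattering is ignored in GAGG (it deposits no energy)
  but included in the narrow-beam water coefficient.
* **Interaction positions** are pixel centers; depth of interaction is not
  modeled, matching how the reconstructions use the data.
* **Directional importance sampling.** Photons are aimed into cones that
  cover the camera front faces from the emission point, and the effective
  isotropically-emitted count is corrected by the sampled cone fraction.
  This is unbiased — photons outside those cones cannot reach a detector
  (the tungsten case is treated as a perfect absorber) — and buys a
  20-40x speed-up.  For annihilation pairs the cone set must be
  antipodally symmetric, which the default ring is; disable `bias` for
  asymmetric PET studies.
* **Decay identity.** Photons carry a decay index so that cascade photons
  (e.g. the In-111 171 + 245 keV cascade, or a Na-22 pair with its
  1275 keV gamma) share a timestamp and produce true coincidence summing;
  random coincidences arise from the Poisson process itself.
* **Septal penetration is real.** At 60 keV the 3 mm front slab transmits
  ~2e-5 and the pinhole data are clean; at 93 keV it transmits ~3%, which
  (being ~7x the aperture solid angle) puts a diffuse full-energy
  background under the Ga-67 pinhole histogram, as in the physical camera.
* **What is not modeled:** Doppler broadening, coherent scatter,
  scattered-photon tracking across cameras, pulse pile-up and dead time,
  and scattered photons re-entering the beam after a water interaction
  (the optional single-scatter mode is off by default because no
  quantitative background model is published).  Passing the synthetic
  tests therefore demonstrates the reconstruction chain, not detector-level
  fidelity: absolute efficiencies agree with the reference instrument only
  at order-of-magnitude level, and the simulated spectra lack the
  scatter continua of real data.

**Energy resolution.** The pixel FWHM is modeled as
`FWHM%(E) = sqrt(alpha + beta/E)` fitted to the measured calibration
points 7.3% at 662 keV, 7.8% at 511 keV and 22.8% at 60 keV; the fitted
curve passes within the quoted uncertainties of all three.

## Reconstruction

**Compton (list-mode MLEM).**  The update is

    lambda_j <- lambda_j * sum_k t_kj v_k /
                (s_j^{l_k} * sum_j' t_kj' lambda_j')

with the cone system matrix

    t_kj = 2 pi (1 - d/sqrt(d^2 + a^2))
           * exp(-((Theta_j - theta_k)/sigma)^2 / 2) / sin(theta_k),

where `d` is the scatter-pixel-to-voxel distance, `a` the voxel half
width (1.15 mm at the default 2.3 mm pitch), `Theta_j` the angle between
the absorption-to-scatter axis and the voxel direction, and `theta_k` the
energy-derived scattering angle.  Both angles are magnitudes in [0, pi].
The Gaussian width is `sigma = 2.5 deg` by default — deliberately small so
that angular uncertainty is not double counted.  `v_k`, the probability
that an event originates in the image space, is fixed at 1 (no formula is
published) and kept as a hook.  Numerical choices: uniform positive
initialization (`lambda = 1`); elements beyond 3 sigma from the cone are
dropped (below `exp(-4.5)`, a ~10x cost saving); `d = 0` caps the solid
angle at `2 pi`; events with an all-zero row are dropped with a warning;
20 iterations for point-source demonstrations and 10 for distributed
sources (convergence-checked values).  The compiled kernel is verified
against a literal dense-loop transcription of the update at 1e-12
relative tolerance, and the per-iteration Poisson log-likelihood is
checked to be non-decreasing.

**Sensitivity.**  `s_j^l` is the probability that a photon emitted from
voxel `j` is accepted as a Compton event at acquisition angle `l`,
estimated by irradiating the cameras with a uniform source drawn from the
grid volume through the full transport + selection chain.  At desk-scale
photon budgets the per-voxel tallies are sparse (far fewer than one
accepted event per voxel), while the true map varies smoothly and only by
a factor of about two across the field of view.  The estimator therefore
tallies on a 4x-coarsened grid and fits a log-quadratic Poisson response
surface (ten coefficients pooled over all accepted events); a 3x3x3
box-smoothing alternative is retained as an option.  The map is floored
at 1% of its positive median so that edge voxels cannot blow up under the
`1/s` weighting.  The surface fit was adopted after the box-smoothed map's
residual noise was found to dominate the variance of ROI intensity
ratios.

**Pinhole (hist-mode MLEM).**  Counts are binned per (angle, camera, rear
pixel) — all angles share one image — and updated with

    lambda_j <- lambda_j / (sum_i c_ij) *
                sum_i c_ij y_i / (sum_j' c_ij' lambda_j')

with `c_ij = Omega_ij * p_int(E)`: the small-angle solid angle
`area * cos(alpha) / r^2` of the rear pixel at the voxel (exact-polygon
correction < 1e-4 at these distances), times the rear-slab interaction
probability with a `1/cos(alpha)` slant path, gated by the binary
aperture test at the front entrance plane (no edge-penetration
modeling).  Voxels whose rays miss every aperture are masked out of the
support rather than floored.  An optional cylindrical field-of-view
restriction about the vertical axis is available for single-angle
acquisitions, where weakly sampled corners can accumulate the diffuse
septal-penetration background.  Count conservation
(`sum_i (C lambda)_i = sum_i y_i`) holds after every iteration over the
modeled bins and is asserted at 1e-9.

**PET (back projection).**  LORs are back-projected with exact Siddon ray
traversal — each traversed voxel receives the chord length — with
half-open voxel boundaries (a grazing segment belongs to the lower-index
voxel).  Per-LOR deposited length equals the in-grid chord at 1e-9.
Filtered or iterative PET reconstruction is deliberately out of scope.

## Spectral thickness estimation

Tissue between source and camera attenuates low-energy photopeaks faster
than high-energy ones, so the net-area ratio `R = A(81)/A(356)` of the two
main Ba-133 photopeaks encodes the water thickness:
`ln R = ln R0 - (mu_w(81) - mu_w(356)) d`, a log-linear law with slope
~0.072/cm.  Photopeak areas come from Gaussian + local-linear-background
least squares (Levenberg-Marquardt), which is robust to the scatter
continuum growing with thickness; net (background-subtracted) areas are
used.  The calibration is a weighted least-squares fit of `ln R` on the
node thicknesses 0-12 cm, and the inversion
`d = ln(R0/R) / dmu` propagates both the measured-ratio error and the fit
covariance.  The geometry is fixed during calibration: source 18 cm from
the camera, slab face nearest the camera fixed.  The calibration source
activity is set to 370 kBq (a typical laboratory check source; no value
is published) with 30-minute acquisitions, which yields ~0.2 cm estimation
precision at 5 cm.

## Problem sizes and reproducibility

Simulations in the test-suite and in `scripts/acceptance.R` run at desk
scale, chosen so the whole chain reruns in minutes on one core: a few
thousand selected Compton events and LORs, tens of thousands of pinhole
events, 21^3-33^3 voxel grids at 2.3 mm pitch, and 1e6-4e6 aimed photons
per angle for sensitivity maps.  These are 3-10x below the real
acquisitions; peak-localization results are insensitive to this, while
ratio estimates carry correspondingly wider error bars.  With a fixed
seed every simulation is bit-reproducible.

ROI intensity ratios integrate 3-voxel-radius (~7 mm) spheres, matching
point-like sources of diameter < 1 cm; with eight view angles the
limited-angle cone artifact can leave faint structure at the grid
corners, so ratio ROIs are placed at the known source regions (as in the
bottle experiments) rather than at the global image maximum.

## Known limitations

* The transport is single-interaction-per-plane: a rear-plane interaction
  absorbs the photon completely, so partial rear deposits (escape events)
  are missing and Compton-mode efficiencies are optimistic.
* The GAGG attenuation digitization limits absolute-efficiency statements
  to order-of-magnitude accuracy.
* Compton reconstruction has no attenuation correction inside the imaged
  object and no Doppler-broadening resolution model.
* The aperture test is binary at the entrance plane; penumbra and
  high-energy septal penetration through the front slab are not part of
  the pinhole system matrix (penetration *is* simulated, and shows up as
  background counts in unmodeled bins).
* The PET energy window is applied per camera (each photon), one of two
  readings of the published cut; list-mode files record enough to re-cut
  differently.
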