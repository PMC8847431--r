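# hccimager

Simulation and reconstruction toolkit for **multi-modal 3D radionuclide
imaging with a ring of hybrid Compton cameras (HCCs)**.

Nuclear-medicine tracers emit photons from a few tens of keV to several
MeV, but SPECT and PET scanners each cover only a slice of that range.  A
hybrid Compton camera covers it with one instrument: each camera is a pair
of pixelated GAGG scintillator planes in which the thin front plane plays
two roles.  For high-energy photons (≳ 200 keV) it is a Compton scatterer
— a scatter in the front plane followed by absorption in the rear plane
constrains the source to a cone.  For low-energy photons (≲ 200 keV) it is
an *active pinhole shield* — photons that touch it are vetoed, and only
photons through a central 3 × 3 mm aperture reach the rear plane, which
acts as a pinhole camera.  Coincident 511 keV deposits in two different
cameras of the ring add a PET mode.  One acquisition therefore yields
Compton, pinhole and PET images of different nuclides simultaneously,
selected purely in software.

The package is aimed at instrument and algorithm developers who want a
faithful, fully scriptable model of this imaging chain: a list-mode Monte
Carlo event generator for the 4-camera, 12-angle ring (nuclide emission
tables, Klein–Nishina scattering, energy-resolution blur, water phantoms),
the event-selection rules (hit patterns and per-nuclide energy windows),
the three reconstruction algorithms, and the photopeak-ratio analysis that
estimates how much water lies between source and camera.

## The algorithms

**Compton mode — list-mode MLEM.**  With per-angle sensitivity `s_j^l`
and event weight `v_k = 1`,

    lambda_j <- lambda_j * sum_k  t_kj v_k / (s_j^{l_k} sum_j' t_kj' lambda_j')

using the Gaussian-broadened cone system matrix

    t_kj = 2π (1 − d/√(d² + a²)) · exp(−((Θ_j − θ_k)/σ)²/2) / sin θ_k

where `θ_k` is the scattering angle from the energy pair,
`cos θ = 1 − m_e c² (1/E_r − 1/(E_f+E_r))`, `Θ_j` the voxel's angle from
the scatter axis, `d` the scatter-pixel-to-voxel distance, `a` the voxel
half width and `σ = 2.5°`.  `s_j^l` is estimated by Monte Carlo
irradiation of the cameras from the imaged volume.

**Pinhole mode — hist-mode MLEM.**  Counts `y_i` per (angle, camera, rear
pixel) bin with system matrix `c_ij = Ω_ij · p_int(E)`: the solid angle of
rear pixel `i` at voxel `j` through the aperture times the slant-path
interaction probability in the 5 mm rear slab.

**PET mode — back projection.**  Each line of response adds its exact
per-voxel chord length (Siddon ray traversal).

**Thickness estimation.**  Beer–Lambert attenuation makes the Ba-133
photopeak-area ratio log-linear in water thickness,
`ln R(d) = ln R₀ − (μ_w(81 keV) − μ_w(356 keV)) d`; a weighted fit over
calibration slabs (0–12 cm) is inverted in closed form for an unknown
thickness.

## Worked example

Simulate a 0.9 MBq Cs-137 point source at (20, 0, 20) mm in the default
ring, select Compton events with the 662 keV windows, and reconstruct:

```r
library(hccimager)
set.seed(7)

setup <- acquisition_setup()   # 4 cameras, 3 rotations of 30 deg, 300 mm ring
hits <- simulate_acquisition(source_spec("cs137", 9.04e5, c(20, 0, 20)),
                             setup, duration_s = 90)
events  <- group_coincidences(hits)
compton <- extract_compton_events(events, setup, target = "cs137")
nrow(compton)
#> [1] 11277

grid <- voxel_grid(n = 21, pitch = 2.3)
sens <- sensitivity_mc(setup, grid, "cs137", n_photons = 1e6)
img  <- mlem_listmode(compton, grid, sens, sigma_deg = 2.5, n_iter = 20)
find_peak(img)$position
#> [1] 20.7  0.0 18.4

absolute_efficiency(nrow(compton), hits, target_kev = 662)
#> [1] 5.42915e-05
```

The reconstruction peaks at (20.7, 0, 18.4) mm — within one 2.3 mm voxel
of the true source position — and the absolute Compton efficiency (events
per 662 keV photon emitted) lands at the few-10⁻⁵ level characteristic of
the instrument.  `extract_pinhole_events()` + `mlem_hist()` and
`pair_pet_events()` + `backproject_lors()` run the other two modes on the
same list-mode data; `write_volume()` exports float32 volumes with a JSON
sidecar (optionally NIfTI).

A thin command-line wrapper over the same functions is installed at
`inst/cli/hcc` (`hcc simulate | recon | analyze`), with YAML configs read
by `read_config()`.

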