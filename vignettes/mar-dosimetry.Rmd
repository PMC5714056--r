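---
title: "Metal artifact reduction and its dosimetric consequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal artifact reduction and its dosimetric consequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctmar` re-creates, entirely in software, a phantom experiment that asks a
dosimetric question: when a CT volume corrupted by metal artifacts is
repaired by a projection-domain metal artifact reduction (MAR) algorithm,
does the repaired volume support accurate radiotherapy dose computation?
This vignette documents the models behind every stage, the tunable
parameters and their defaults, the design decisions taken where the design
was genuinely open, and the limitations a reader should keep in mind. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## The phantom and its ground truth

The digital phantom is a 33 cm diameter solid-water cylinder with two
experimental slots on the horizontal axis at (±7, 0) cm and a ring of six
tissue-surrogate inserts (lung, adipose, breast, liver, inner bone,
cortical bone; 2.8 cm diameter at 11 cm radius). Three configurations are
studied: 1 cm titanium in both slots (low-Z metal, ρ = 4.540 g/cm³), 3 cm
Cerrobend (high-Z Bi/Pb/Sn/Cd alloy, ρ = 9.760 g/cm³), and 3 cm solid
water (ρ = 1.004 g/cm³, the metal-free reference). Voxel membership is by
center-in-shape; partial volume arises naturally from reconstruction, not
from the voxelization.

The artifact-free *ground truth* (GT) is built the way such experiments
define it: the metal-free configuration is acquired and reconstructed, and
the slot voxels are overwritten in software with the metal's HU at the
reconstruction reference energy (which saturates at the scanner clamp,
3071 HU, for both metals). The GT therefore contains the same acquisition
noise and residual beam hardening as any other scan, but no metal
artifacts — and its metal boundary is an exact center-in-disk
voxelization, a property that matters later.

Three cylindrical planning target volumes (4 cm diameter) probe different
regions: PTV1 at the center of the streak band between the slots, PTV2
off-axis near the band, PTV3 on slot A, overlapping the metal. The PTV
centers are not prescribed anywhere precisely; the presets satisfy the
stated topology and are lattice-commensurate so all three rasterize to
identical voxel counts. Default grid: 256×256 at 1.5 mm with three 2.5 mm
slices; the desk-scale experiments and the acceptance surface run at
128×128 at 3 mm with 180 views, a size chosen so the complete study (two
metal configurations, three plans each) runs in well under a minute.

## Acquisition model

The simulator is parallel-beam (360 views over 180° by default, detector
bins at the voxel pitch spanning twice the image width). Parallel geometry
makes the 0th moment of every view equal — the mass-conservation property
the completion stage exploits — and is the reason it was preferred over
fan-beam for this study.

Physics data are shipped as a per-material table of mass attenuation and
mass energy-absorption coefficients on a 17-point log energy grid
(20–2000 keV), interpolated log-log, with elemental compositions for
electron-density computation. The Cerrobend curve is a smooth, K-edge-free
approximation; K-edge structure is deliberately out of scope. The 140 kVp
tungsten spectrum is a 12-bin fixture (25–135 keV bin centers) with a
lightly filtered diagnostic shape; its effective energy through 16 cm of
water (≈ 65 keV) is the reconstruction reference energy, so water
reconstructs near 0 HU with a residual cupping of a few tens of HU across
the 33 cm body — larger than a clinical scanner, which applies a water
precorrection this simulator does not model.

For each ray the exact per-material intersection lengths are computed by
Amanatides–Woo traversal (compiled code); expected counts are
`λ = N0 Σ_E w(E) exp(−p(E))` and observed counts are Poisson draws,
deterministic given the seed (per-slice seeds derive from the master
seed). Log normalization uses a floor of 0.5 counts, and bins below 5
counts are flagged *starved*. `N0 = 1e7` photons per bin: this reproduces
the noise floor implied by the corrected-image statistics of the source
experiment (single-image noise ≈ 5–7 HU) while keeping the study's
designed contrast — rays through 3 cm of Cerrobend are fully starved
(expected counts ≪ 1) while rays through 1 cm of titanium retain several
thousand counts. A much lower `N0` would bury the low-Z beam-hardening
artifact under photon noise and make every image comparison
noise-dominated, which contradicts the artifact-dominated regime the
study design assumes.

Reconstruction is classic filtered back projection: frequency-domain ramp
filter (optional Hann apodization), pixel-driven linear-interpolation
backprojection, conversion to HU clamped to `[-1024, 3071]`. The
*uncorrected* reconstruction deliberately uses starved bins as-is; that is
what produces the streaks.

## The MAR algorithm

The algorithm distinguishes the two corruption mechanisms.

**Metal segmentation.** Voxels ≥ 1800 HU seed connected components
(4-connectivity, per slice; components under 3 voxels are dropped). The
default threshold sits above the densest tissue surrogate (cortical bone
reconstructs near 1600 HU here) and below the apparent HU of a 1 cm
titanium insert at the default grids, where partial volume and beam
hardening suppress titanium to roughly 1500–2500 HU. Unsaturated
components (low-Z inserts) are extended to their half-peak level within a
3-voxel neighborhood — the FWHM contour is a scale-stable estimate of a
blurred object's extent — unless they lie within 4 cm of saturated metal,
in which case they are bright starvation streaks, not implants, and are
rejected. Saturated components (clamped at 3071 HU) are first opened
morphologically (~4 mm radius) to cut streak bridges that can join
separate implants, then FWHM-extended, eroded one layer (the threshold
contour of a saturated object is dilated by about a voxel), and
re-voxelized as the equal-area disk at their centroid — the package's
scope is cylindrical inserts, and the study's GT is defined by exact disk
voxelization.

Because the GT metal boundary is exact, sub-voxel mask errors dominate the
corrected-vs-GT *dose* comparison: a single misclassified rim voxel, seen
tangentially by a beam, changes the radiological path by several
water-equivalent centimetres. The pipeline therefore refines each
saturated disk from the photon-starvation footprint itself: in every view
the starved run delineates the metal in projection space, free of the
reconstruction's point spread. For a disk with center **c** and radius
*r*, the run at angle θ is centered on the projection of **c** with
half-width `sqrt(r² − t*²/4)`, where `t*` — the metal thickness at which
expected counts cross the starvation threshold — is computed from the
spectrum, the attenuation table, and the water background estimated from
the flanking valid bins. Least squares over run midpoints gives the
center; a trimmed mean over view phases (the per-view width is
bin-quantized and bimodal, so a median would lock onto the mode) gives the
radius. With ~150 usable views both are accurate to a small fraction of a
voxel.

**Physics correction (beam hardening).** A 2-D lookup
`p_poly(t_water, t_metal)` is precomputed from the spectrum (121×41 grid).
For every valid bin crossing metal, the measured polychromatic value is
inverted at the known metal path for the water-equivalent thickness; the
bin is then rebuilt with the metal's contribution replaced by its
monochromatic equivalent at the reference energy while the water part
keeps its polychromatic response. Keeping water polychromatic — rather
than outputting the fully monochromatic
`μ_w(E_ref) t_w + μ_m(E_ref) t_m` — keeps corrected bins consistent with
their uncorrected neighbors and with the metal-free GT acquisition, which
also carries water beam hardening; converting the water part too would
introduce a trace-shaped inconsistency of several percent. Bins whose
measurement falls outside the lookup column for their metal path
(typically grazing rays at metal edges) are flagged *correction failed*
and handed to the completion stage rather than clamped: a clamped
inversion would inject arbitrarily wrong values into valid data. In the
reconstruction path the pipeline substitutes the metal as water
(`metal_substitute = "water"`) and restores it afterwards by image-space
reinsertion; reconstructing a sharp monochromatic high-Z disk at 3 mm
voxels would ring (Gibbs) at hundreds of HU against the GT's clean
substitution.

**Completion (photon starvation).** The missing set is the starved bins,
the failed corrections, and — when more than 2% of a metal trace is
starved, i.e. the high-Z case — the entire (dilated) metal trace: a trace
that is mostly starved cannot be represented consistently by its few
surviving edge bins. The trace is dilated by 2 detector bins because rays
grazing the sub-voxel partial-volume shell attenuate strongly yet project
outside the binary mask. Missing bins are re-estimated by minimizing

`λ_s · Σ_missing (Laplacian p)² + λ_c · Σ_views (Σ_bins p Δs − M̂)²`

with valid bins held fixed (hard data fidelity), `λ_s = 1`, `λ_c = 10`.
`M̂` is the median per-view mass over views with < 10% missing bins (or
the cleanest decile when no view qualifies, as happens for the high-Z
phantom where every view crosses metal). The quadratic is solved by
conjugate gradient from a per-view linear-interpolation initialization
(the operator — zero-padded Laplacian plus per-view rank-one moment terms
— is symmetric positive semidefinite; plain gradient descent with a
Lipschitz step was tried first and stalls at the initialization for large
traces). Iterations stop at a relative change of 1e-4 or 200 iterations;
the objective trace is recorded and is non-increasing. After convergence
an exact per-view moment projection enforces the consistency constraint,
and two *image-prior passes* reconcile the sinogram with image space: the
completed data are reconstructed, reprojected through the missing bins,
and re-projected onto the moment constraint. This is the concrete form of
the "image smoothness" idea: structures hidden behind the trace in one
view are seen by other views and re-enter through the prior. A
sinogram-domain-only variant (no prior passes) is available via
`mar_config(image_prior = FALSE)`; a separate image-domain smoothness
penalty inside the quadratic was not implemented.

**Reinsertion.** Each metal component re-enters the reconstructed image
as a single HU value. With a known implant assignment (the study always
knows its insert) the value is the material's HU at the reference energy —
exactly the GT substitution rule, and the desk-scale analogue of a
clinical density override for a known implant. For a generic metal the
larger of the uncorrected and corrected component means is used:
beam hardening biases the uncorrected estimate low, starved-trace
inpainting erases the corrected one, so each is a lower bound of the
saturated true value.

## Dosimetry

HU convert to relative electron density through a monotone
piecewise-linear calibration whose control points are the shipped
materials evaluated at the reference energy (air and water anchor the
curve near (−1000, 0) and (0, 1)), plus a point mapping the clamped metal
HU to the known implant's electron density. The beam model is
monoenergetic 2 MeV photons — a 6 MV-like, Compton-dominated surrogate
with a single parameter. The primary engine is a collision-kerma
pencil-beam: per beamlet (5 mm wide), dose = weight ×
`exp(−μ_eff × radiological path)`, with the radiological path computed by
exact voxel traversal of the density volume; dose is exactly linear in
fluence. A Monte Carlo mode transports photons with Klein–Nishina Compton
sampling and a photoelectric channel (an `E^-3.1` power-law fraction for
water), deposits energy under the kerma approximation (no secondary
electron transport), scatters in-plane, and reports batch-based
uncertainties; it serves as an independent cross-check of the primary
engine on narrow-beam cases, not as the study engine.

Beam angles are selected from 1° candidates by casting each direction
through the metal mask: a direction is blocked when any target voxel sees
metal upstream. The 5 most-spread feasible angles are chosen (greedy
nearest-to-ideal-72°-spacing, lexicographically smallest among ties); if
the PTV itself contains metal no metal-free direction exists and the
selection returns the most-spread candidates flagged `"unavoidable"`.
Fluence weights solve a nonnegative least-squares problem — mean-squared
prescription error inside the PTV plus `γ = 0.1` times the mean-squared
dose outside — by projected gradient with a fixed 500-iteration budget
and a step from the exact Lipschitz constant. Both terms are normalized
per voxel; with raw sums the out-of-target term (an order of magnitude
more voxels) would force a systematic target underdose at any fixed `γ`.
Plans are optimized on the *uncorrected* density volume, then recomputed
with fixed fluence on the corrected and GT volumes — the fluence is never
re-optimized per volume, mirroring the study design.

## Evaluation conventions

Difference statistics use the population standard deviation (divide by
n) over the body region with metal voxels excluded. DVHs use 0.05 Gy
bins; `D_x` interpolates linearly between bin edges and `D100` is the
structure minimum. `Acc_x = |D_x − D_x^GT| / D_x^GT × 100`. The
Wilcoxon–Mann–Whitney comparison of corrected-vs-GT PTV dose uses the
exact two-sided p-value when `min(n, m) ≤ 8` without ties and the
tie-and-continuity-corrected normal approximation otherwise; because
neighboring voxels are strongly correlated, voxel-level p-values are
reported as descriptive only. Reports serialize deterministically (no
timestamps, fixed formatting), so identical configuration and seed give
byte-identical JSON.

## What the generator does and does not emulate

It emulates: polychromatic beam hardening with realistic cupping, genuine
photon starvation behind high-Z metal with the resulting streak
morphology, Poisson noise at a clinically plausible level, the clamped
scanner HU range, and software-substituted ground truth.

It does not emulate: automatic exposure control (fixed `N0`), vendor
water/bone precorrections, fan-beam or helical geometry, detector
aperture, scatter-to-primary contamination, K-edges, or a clinical Monte
Carlo engine with electron transport. Passing tests therefore demonstrate
the algorithm's behavior under the modeled physics at desk scale; they do
not certify performance on clinical scanner data.

Two desk-scale effects deserve emphasis. First, because the GT metal
boundary is an exact voxelized disk, corrected-vs-GT dose accuracy is
limited by the sub-voxel precision of the estimated metal mask; the
starvation-footprint refinement brings this down to roughly one boundary
voxel, worth up to ~0.5 Gy in a tangential beam at 3 mm voxels — the same
"small region around the metal" effect the original experiment reported
at ~6× finer resolution. Second, the *uncorrected* low-Z volume
reconstructs titanium at roughly half its true electron density (beam
hardening without vendor precorrection plus partial volume of a 1 cm
insert), so uncorrected low-Z dose errors in the metal-containing PTV are
1–3% here, versus below 0.3% reported on clinical hardware that
reproduces titanium HU correctly. The MAR-corrected volumes do not suffer
this: the correction restores the metal at its true density.

## Numerical choices and degenerate inputs

Ray tracing is exact (Siddon/Amanatides–Woo) with slab clipping; rays that
miss the grid contribute zero. The ramp filter zero-pads to the next power
of two. The completion errors out only when a view is fully starved and
both neighbors are too (an unrecoverable acquisition). The physics-lookup
inversion is monotone by construction; ties in beam-angle spread break to
the lexicographically smallest set; the fluence optimizer initializes at
zero and projects onto the nonnegative orthant each step. All stochastic
stages take explicit integer seeds, derived from the master seed below
2³¹. Test-suite problem sizes (96–128 voxels in-plane, 60–180 views, one
to three slices) are the package's chosen desk scale; the defaults
(256×256, 360 views) remain practical on a laptop.
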