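---
title: "Tracing filament bundles: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing filament bundles: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bundletrac)
```

This vignette is the package's own account of the science it implements:
the assumptions behind each stage, what every tunable parameter means and
why its default is what it is, what the synthetic phantom does and does not
emulate, and the numerical decisions that were genuinely open.

## The problem and its core assumption

An actin bundle — as in the shaft of a hair-cell stereocilium — consists of
hundreds of roughly parallel filaments in hexagonal packing, about 11–13
voxels apart at ~1 nm/voxel, cross-linked into a nearly crystalline
arrangement. Cryo-electron tomograms of such bundles combine three
difficulties: very low signal (low-dose imaging), molecular crowding
(filaments closer together than their apparent thickness after blurring),
and anisotropic resolution (the missing tilt wedge elongates every density
roughly twofold along z).

Everything in this package leans on one structural assumption: *the bundle
changes direction gradually and collectively*. Filaments do not kink, and
neighbors stay neighbors. This licenses three moves:

* a single direction field v(y) for the whole bundle, estimated from
  cross-correlation of cross-sections;
* averaging each voxel along v(y) without smearing filament structure;
* placing the next marker of a filament by a *local* search around the
  position predicted by v(y).

The volume convention is fixed throughout: arrays are indexed (x, y, z)
with the bundle along +y, cross-sections are x–z planes, and coordinates
are 0-based and continuous with voxel centers at integers (sub-voxel
marker accuracy requires continuous coordinates). Maps are assumed
pre-rotated so the bundle runs along an axis; higher density means more
filament mass (`read_volume(..., invert = TRUE)` flips maps with dark
filaments).

## Axis detection

`estimate_axis()` samples slabs of `thickness` planes (default 30 — the
slab width at which the hexagonal pattern becomes visible in a noisy map)
every `step` planes (default 55, wide enough to measure a small angle
accurately, narrow enough to follow gradual direction change). The shift
between consecutive slabs comes from the peak of their 2D
cross-correlation, computed on mean-subtracted images with FFT
zero-padding (no wrap-around bias); the sub-pixel peak is a 2D quadratic
fit to the 3×3 neighborhood of the integer peak. A shift (dx, dz) over a
step of Δy gives direction ∝ (dx, Δy, dz), assigned to the midpoint of the
pair; `axis_at()` interpolates directions piecewise-linearly (renormalized)
and extrapolates as constants.

Shifts larger than step·tan(30°) are treated as correlation failures and
dropped with a warning: the premise of a roughly parallel bundle makes
such shifts non-physical. The slab thickness for correlation and the
sub-pixel estimator are not dictated by the method itself; both defaults
are package decisions validated on phantoms (tilted noise-free bundles are
recovered to well under 0.1°, see the test suite).

## Longitudinal averaging

`longitudinal_average()` replaces each voxel by the mean of 2h+1 trilinear
samples along the local direction (default h = 15 voxels, ≈14 nm at
0.947 nm/voxel). The averaging direction follows the interpolated axis
field rather than a single global axis. Samples outside the volume are
dropped and the mean taken over the in-bounds ones, which keeps the
estimator unbiased near borders. For an axis exactly along +y the noise
variance falls by 1/(2h+1); the test suite verifies both the exact rate
and the brute-force equality with a direct column mean.

The optional isotropic Gaussian pre-filter (`gaussian_filter()`, default
σ = 1 voxel, truncated at 4σ) is deliberately mild: it is not tuned to the
anisotropy of the data, and its measured effect on tracing accuracy is
small — slightly positive on real-data-like conditions, slightly negative
on the already-smooth averaged phantom. It is kept because the five-way
ablation explicitly includes it.

## The matched-filter tracer

### Kernel

`render_kernel()` builds the score template: unit-amplitude 2D Gaussians
(width `sigma_voxels`, default 2.5 — roughly the apparent filament radius
after blurring) at the origin and, for the seven-peak variant, at six
hexagon vertices at distance `spacing_voxels`. The image is
mean-subtracted and normalized to unit Euclidean norm, so scores are
invariant to constant density offsets and commensurable across slabs and
step distances — without this normalization, comparing candidate steps
would be intensity-biased.

### Search

`optimize_placement()` maximizes the score over position (0.5-voxel grid
in a disc), hexagon spacing (11–15 voxels in 0.5 steps — the physical
inter-filament spacing constraint) and orientation (5° steps). For the
default 3-voxel radius the scan is exhaustive; for larger radii a coarse
integer-grid scan with a mid-range reference kernel localizes the optimum
first and the exhaustive scan runs in a 1.5-voxel disc around it — the
same argmax on the smooth, locally unimodal score surfaces the gradual-
change assumption guarantees, at a fraction of the cost. Ties break
deterministically: smallest displacement from the starting point, then
smallest spacing, then smallest orientation.

Sub-voxel refinement fits a quadratic to the 3×3 *integer-grid* score
neighborhood of the best grid point. Integer centers are scored without
interpolation; fractional centers require bilinear resampling of the
patch, which slightly attenuates their scores and would otherwise lock
positions to the grid (a bias of up to ~0.25 voxel).

### Two stabilizing constraints

Two constraints beyond the plain argmax proved necessary, both direct
consequences of bundle physics, and both were added after the plain
version demonstrably failed on noise-free phantoms:

* **Radius cap.** The per-step search radius scales with the step distance
  (`search_radius_voxels` per 10 voxels advanced) but is capped at
  `max_search_radius_voxels` (default 3, safely below half the minimum
  inter-filament spacing). Without the cap, a 70-voxel step allows a
  21-voxel search disc — wide enough to land on a *neighboring* filament,
  which scores higher for edge filaments because the bundle interior has
  more density mass under the kernel.
* **Orientation anchoring.** The hexagon orientation is a property of the
  bundle lattice, not of a single filament; the packing is coherent across
  the cross-section. `trace_bundle()` therefore estimates the orientation
  once, by an unconstrained scan at the most interior seed on the seed
  slab, and restricts the per-step orientation search to
  `theta_halfwidth_steps` grid steps around it (default 0: fixed). With a
  free per-step orientation re-fit, filaments on the bundle surface —
  which have only three or four real neighbors — lock onto spuriously
  rotated kernel configurations a voxel or two inward and then walk to a
  neighbor over a few steps. On the default noisy 37-filament fixture,
  anchoring is the difference between 37/37 and 35/37 filaments within
  3 voxels. Spacing remains re-optimized at every step (it genuinely
  varies along the bundle); set `theta_halfwidth_steps` > 0 if a slow
  lattice twist along y is expected.

### Stepping and termination

`next_marker()` evaluates the four candidate step distances (10, 25, 45,
70 voxels); each candidate's slab is the 30-plane average centered at the
candidate height, padded with its mean so that the kernel support of
edge filaments remains scoreable, and the in-plane start is the current
marker advanced along `axis_at()`. The candidate with the highest score
wins; exact ties go to the smallest step. The longer steps exist to
carry a trace across locally corrupted stretches of density. Tracing
terminates when no candidate slab fits inside the volume; from a seed
section away from the volume edge, tracing runs in both +y and −y.

## The phantom generator

`bundle_spec()` defaults define the package's study fixture: 37 filaments
(3 hexagonal shells) at spacing 12, Gaussian cross-section σ = 2 voxels
(apparent 8–10-voxel thickness after blur), length 400, point-spread
σ_xy = 1.5 with z-elongation 2 (σ_z = 3), additive i.i.d. Gaussian noise
with σ = 1.0 at unit filament peak amplitude, seed 42. The collective bend
is a single sinusoidal displacement field shared by all filaments, so
spacing is conserved exactly and the tracing problem the method targets is
isolated from packing irregularities. The in-plane margin between the
outermost filament and the volume edge defaults to 16 voxels, comfortably
above the 3σ minimum the generator enforces: a real tomogram holds the
bundle inside a wider field of view.

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: the enclosing membrane (real edge filaments have
membrane density outside them; synthetic ones have vacuum, making them
*harder* to anchor), cross-linker densities, packing defects and
"irregular" filaments that swap neighbors, correlated noise, CTF effects,
and a true Fourier missing wedge (the anisotropy is modeled as the
z-elongated Gaussian point spread, matching the resolution model used by
the denoiser). The noise level of real tomograms is not known numerically;
σ = 1.0 is chosen as a visually featureless-per-slice regime that the
30-slab averaging just resolves.

One practical regime limit found while validating: with the full study
point spread (σ_z = 3) a *seven*-filament bundle — where six of seven
filaments are surface filaments with only three neighbors — is at the edge
of what the seven-peak kernel can anchor. The bundles the method is meant
for have dozens to hundreds of filaments, and the 37-filament fixture
traces cleanly at full blur and noise; the small-bundle tests therefore
use a slightly milder point spread (σ_xy = 1).

## The polynomial kernel-regression denoiser

At each voxel p the map is approximated by a trivariate quadratic
f(x, y, z) = Σ a_ij x_i x_j + Σ b_i x_i + c (10 coefficients), fit by
weighted least squares with weight W(q − p), and the denoised value is
f(p) = c. W is the convolution of the filament-shaped kernel S — Gaussian,
σ_long (default 8 voxels) along the local bundle direction, σ_thick
(default 2, the filament radius) across — with the resolution kernel R —
Gaussian, σ_r (default 1) in x–y and 2σ_r along z. Being Gaussian, W has
covariance H = H_S + H_R exactly; the defaults are package choices (the
method defines the shapes, not numbers).

Numerics: W is truncated at 3 standard deviations of H per axis, and
values below exp(−9/2) of the peak are zeroed — unbounded support would
make the per-voxel cost prohibitive. Because the weights do not depend on
the data, the WLS solution is linear in the map: `denoise_polyreg()`
precomputes the c-row of (XᵀWX)⁻¹XᵀW once per distinct direction (one per
y, deduplicated) and applies it as a linear filter, algebraically
identical to the per-voxel solve (the test suite checks agreement with an
independent dense solve to 1e-8, exact reproduction of quadratic fields,
and linearity). Voxels whose full support extends outside the volume are
copied from the input and counted; `local_fit()` by contrast solves
clipped supports directly and reports rank deficiency when fewer than 10
usable voxels remain. The per-voxel direction comes from the axis field
(one direction per y), the information actually available before tracing.

## The cross-distance metric

D_f between a reference and a test filament is the mean, over reference
markers in the common y-range, of the 3D distance to the nearest point of
the test trace. Decisions made here: the normalization by n (the formula
is used as an *average* cross-distance; magnitudes of ~1 voxel over
thousands of sections are only consistent with a mean); nearest points by
exact projection onto the linearly interpolated trace segments — the limit
of the finely-sampled-interpolation formulation, stable under any sampling
step; and restriction of reference markers to the overlapping y-range so
that longitudinal offset is not penalized. A per-section variant
(`planar = TRUE`), which measures the in-plane distance at each reference
marker's own height, is available for sensitivity analysis; filament
correspondence is by id (seeds fix it), never by proximity.

## Problem sizes used in validation

The bundled tests and the acceptance script use: the default 37-filament,
length-400 fixture for recovery and the five-way ablation (about a minute
for all five traced variants); 7-filament, length 120–160 bundles for
per-operation oracles; small random volumes (≈10⁴–10⁵ voxels) for the
brute-force oracles of averaging, regression and scoring. These sizes were
chosen so the full suite exercises every code path in a couple of minutes
while keeping every statistical check well away from its threshold.

## Known limitations

* The taper region of a stereocilium, where filaments terminate
  individually, is out of scope; so is automatic repair of "irregular"
  filaments that jump between neighbors (they can be flagged afterwards by
  inter-filament spacing statistics, but re-tracing is manual).
* Seeds are required — one per filament on a starting slab; there is no
  automatic seed detection.
* The missing wedge is modeled as an anisotropic Gaussian point spread,
  not a Fourier-domain wedge mask.
* Maps must be pre-rotated so the bundle runs roughly along one axis.
* IMOD binary model files are not read; use CSV or Chimera CMM.
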