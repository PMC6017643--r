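# bundletrac

Semi-automatic tracing of actin filament bundles in cryo-electron
tomograms.

The shaft of an inner-ear hair-cell stereocilium contains hundreds of
roughly parallel actin filaments, hexagonally packed about 12 nm (11–13
voxels) apart. Cryo-ET maps of such bundles are extremely noisy and
anisotropic — the missing wedge elongates every density about twofold along
z — so per-filament tracing methods fail. `bundletrac` implements a
bundle-aware pipeline for structural biologists working on such data:

1. **Bundle-axis detection.** Cross-section slabs (x–z planes averaged over
   ~30 slices) are sampled every 55 planes along the bundle axis y; the
   sub-pixel peak shift of the 2D cross-correlation between consecutive
   slabs gives the local bundle direction, yielding a piecewise axis field
   v(y).
2. **Longitudinal averaging.** Each voxel is replaced by the mean of
   trilinear samples taken at p + k·v(p_y), k = −15…15. Filament signal
   adds coherently along the axis while noise averages out, which makes the
   hexagonal cross-section pattern visible.
3. **Seed-based tracing.** From one expert seed per filament, the next
   marker is placed by maximizing the inner product between a zero-mean,
   unit-norm matched filter — either a single 2D Gaussian ("one-peak") or a
   seven-peak kernel, one Gaussian at the center and six at hexagon
   vertices, mimicking a seven-filament neighborhood — and downstream
   slabs at distances 10, 25, 45 and 70 voxels. The hexagon spacing is
   re-optimized within the physical 11–15-voxel range; its orientation is
   anchored to the bundle lattice, estimated once from the seed slab.
4. **Evaluation.** Two models are compared by the cross-distance: for each
   reference marker P_i in the common y-range, Q_i is the nearest point of
   the finely interpolated comparison filament, and
   D_f = (1/n) Σ‖P_i − Q_i‖. A bundle-level report gives the unweighted
   mean of D_f over filaments and the fraction within a 3-voxel threshold.
5. **Polynomial kernel-regression denoising.** At each voxel a trivariate
   quadratic f is fit by weighted least squares, min Σ_q (f(q) − Φ(q))² W(q−p),
   and the denoised value is f(p). The weight kernel is the convolution
   W = S ∗ R of a shape kernel S (a Gaussian elongated along the local
   filament direction, cross-section matched to the filament thickness) and
   a resolution kernel R (a Gaussian approximation of the missing-wedge
   point spread, twice as wide along z). Both being Gaussian, W is Gaussian
   with covariance H = H_S + H_R.

A synthetic phantom generator (`synthesize_bundle()`) produces bundles with
known ground truth — hexagonal packing, collective bend/tilt, z-elongated
point spread, controllable noise — so the whole pipeline is testable
without tomogram downloads.

## Worked example

Trace a noisy 37-filament phantom end to end:

```r
library(bundletrac)

ph <- synthesize_bundle(bundle_spec(n_shells = 3, length_voxels = 200,
                                    noise_sigma = 1.0, rng_seed = 7))
field <- estimate_axis(ph$volume)
avg   <- longitudinal_average(gaussian_filter(ph$volume, 1.0), field, 15L)

pts   <- t(sapply(ph$truth$traces, function(t) t$markers[16, c(1, 3)]))
seeds <- seed_set(pts, y0 = 15L, ids = names(ph$truth$traces))
model <- trace_bundle(avg, seeds, field, n_peaks = 7)

evaluate_model(ph$truth, model, threshold = 3)
#> <cross_distance_report> 37 filaments
#>   mean D_f: 0.4221 voxels (per-filament range 0.1301-1.257)
#>   within 3 voxels: 37 / 37 (100.0%)
```

At unit filament amplitude the phantom's noise standard deviation is 1.0 —
individual cross-sections are visually featureless — yet the traced model
deviates from the ground truth by 0.42 voxels on average, and every
filament stays within the 3-voxel acceptance threshold. Tracing with
`n_peaks = 1` (each filament followed by its own density alone) or without
the longitudinal average gives a measurably larger mean cross-distance —
on the default length-400 fixture about 0.55 voxels versus 0.39;
`run_ablation()` reproduces the full five-way comparison in one call.

A command-line front end covering the same pipeline
(`phantom`, `axis`, `average`, `denoise`, `trace`, `evaluate`, `ablation`)
is installed at `inst/bin/bundletrac`:

```sh
Rscript inst/bin/bundletrac phantom --n-shells 3 --length 200 \
    --out-volume vol.mrc --out-truth truth.csv --out-seeds seeds.csv
Rscript inst/bin/bundletrac axis vol.mrc --out axis.csv
Rscript inst/bin/bundletrac trace vol.mrc --seeds seeds.csv --axis axis.csv --out model.csv
Rscript inst/bin/bundletrac evaluate --ref truth.csv --test model.csv --out report.json
```

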