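## Shared fixtures, built in code. The small bundle keeps tests fast; the
## point-spread is milder than the study fixture so that even a 7-filament
## bundle (whose outer filaments have only 3 real neighbors) anchors well.

small_bundle <- function(noise = 0, seed = 1, n_shells = 1, length = 120,
                         tilt = 0, bend = 0, psf = 1.0) {
  synthesize_bundle(bundle_spec(
    n_shells = n_shells, length_voxels = length, noise_sigma = noise,
    rng_seed = seed, psf_sigma_xy_voxels = psf, tilt_deg = tilt,
    bend_amplitude_deg = bend))
}

seeds_from_truth <- function(truth, y0 = 15L, slab = 30L) {
  pts <- t(vapply(truth$traces, function(t) {
    i <- which.min(abs(t$markers[, 2] - y0))
    t$markers[i, c(1, 3)]
  }, numeric(2)))
  seed_set(pts, y0, slab_thickness = slab, ids = names(truth$traces))
}

## mean in-plane (x, z) error of traced markers against the true centerline
mean_inplane_error <- function(model, truth) {
  errs <- unlist(lapply(names(model$traces), function(id) {
    tr <- model$traces[[id]]$markers
    tt <- truth$traces[[id]]$markers
    vapply(seq_len(nrow(tr)), function(i) {
      j <- which.min(abs(tt[, 2] - tr[i, 2]))
      sqrt(sum((tr[i, c(1, 3)] - tt[j, c(1, 3)])^2))
    }, 0)
  }))
  mean(errs)
}
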