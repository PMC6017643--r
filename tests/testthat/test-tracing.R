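test_that("rendered kernels are zero-mean, unit-norm, with peaks where designed", {
  k1 <- render_kernel(kernel_spec(1, sigma_voxels = 2))
  expect_equal(mean(k1), 0, tolerance = 1e-12)
  expect_equal(sum(k1^2), 1, tolerance = 1e-9)
  ctr <- (dim(k1)[1] + 1) / 2
  expect_equal(unname(which(k1 == max(k1), arr.ind = TRUE)[1, ]),
               c(ctr, ctr))

  k7 <- render_kernel(kernel_spec(7, 2, spacing_voxels = 12, theta_rad = 0))
  expect_equal(mean(k7), 0, tolerance = 1e-12)
  expect_equal(sum(k7^2), 1, tolerance = 1e-9)
  R <- (dim(k7)[1] - 1) / 2
  ## local maxima at the six hexagon vertices, within half a voxel
  for (a in (0:5) * pi / 3) {
    px <- 12 * cos(a); pz <- 12 * sin(a)
    i <- round(px) + R + 1; j <- round(pz) + R + 1
    nb <- k7[(i - 2):(i + 2), (j - 2):(j + 2)]
    pk <- which(nb == max(nb), arr.ind = TRUE)[1, ] - 3
    expect_lte(sqrt(sum((c(round(px) + pk[1] - px,
                           round(pz) + pk[2] - pz))^2)), 0.75)
  }
  expect_error(render_kernel(kernel_spec(7, 2, 12), support_radius = 10),
               "insufficient support")
})

test_that("score_placement is the matched-filter inner product", {
  spec <- kernel_spec(7, 2, spacing_voxels = 12, theta_rad = 0.2)
  k <- render_kernel(spec)
  R <- (dim(k)[1] - 1) / 2
  ## section = the kernel itself embedded at a known center
  sec <- matrix(0, 61, 61)
  c0 <- 30  # 0-based center
  sec[(c0 - R):(c0 + R) + 1, (c0 - R):(c0 + R) + 1] <- k
  s_at <- score_placement(sec, c(c0, c0), spec)
  expect_equal(s_at, 1, tolerance = 1e-12)   # unit-norm patch: its own norm
  for (off in list(c(2, 0), c(0, -3), c(4, 4)))
    expect_lt(score_placement(sec, c(c0, c0) + off, spec), s_at)
  ## invariance to constant offsets
  expect_equal(score_placement(sec + 5, c(c0, c0), spec), s_at,
               tolerance = 1e-9)
  expect_error(score_placement(sec, c(2, 2), spec), "outside")
})

test_that("scores at integer offsets match a double-loop inner-product oracle", {
  set.seed(31)
  sec <- matrix(rnorm(31 * 31), 31, 31)
  spec <- kernel_spec(1, sigma_voxels = 1.5)
  k <- render_kernel(spec)
  R <- (dim(k)[1] - 1) / 2
  for (off in list(c(0, 0), c(1, -2), c(-3, 3), c(2, 2), c(-1, 0))) {
    ctr <- c(15, 15) + off
    oracle <- 0
    for (u in -R:R) for (v in -R:R)
      oracle <- oracle + k[u + R + 1, v + R + 1] *
        sec[ctr[1] + u + 1, ctr[2] + v + 1]
    expect_equal(score_placement(sec, ctr, spec), oracle, tolerance = 1e-10)
  }
})

## noise-free synthetic section: seven Gaussian blobs at a known geometry
hex_section <- function(n, center, spacing, theta, sigma, amp = 1) {
  sec <- matrix(0, n, n)
  xs <- 0:(n - 1)
  px <- center[1] + c(0, spacing * cos(theta + (0:5) * pi / 3))
  pz <- center[2] + c(0, spacing * sin(theta + (0:5) * pi / 3))
  for (p in seq_along(px))
    sec <- sec + amp * outer(exp(-(xs - px[p])^2 / (2 * sigma^2)),
                             exp(-(xs - pz[p])^2 / (2 * sigma^2)))
  sec
}

test_that("optimize_placement recovers position, spacing and orientation", {
  sec <- hex_section(81, c(40.3, 39.6), spacing = 12, theta = 0, sigma = 2.5)
  params <- trace_params()
  opt <- optimize_placement(sec, init = c(38.3, 38.2), params, n_peaks = 7)
  expect_lt(sqrt(sum((opt$position - c(40.3, 39.6))^2)), 0.25)
  expect_lt(abs(opt$spec$spacing_voxels - 12), 0.5 + 1e-9)
  th_err <- min(opt$spec$theta_rad %% (pi / 3),
                pi / 3 - opt$spec$theta_rad %% (pi / 3))
  expect_lt(th_err, 5 * pi / 180 + 1e-9)

  ## one-peak on a single off-center Gaussian
  sec1 <- hex_section(41, c(20.6, 19.8), spacing = 12, theta = 0, sigma = 2.5)
  opt1 <- optimize_placement(sec1, init = c(19, 21), params, n_peaks = 1)
  expect_lt(sqrt(sum((opt1$position - c(20.6, 19.8))^2)), 0.25)
})

test_that("ties break deterministically toward the smaller displacement", {
  ## two identical single-peak optima equidistant from init
  n <- 61; xs <- 0:(n - 1)
  sec <- outer(exp(-(xs - 24)^2 / 8), exp(-(xs - 30)^2 / 8)) +
         outer(exp(-(xs - 36)^2 / 8), exp(-(xs - 30)^2 / 8))
  params <- trace_params(search_radius_voxels = 3)
  ## init nearer the first optimum
  o1 <- optimize_placement(sec, c(26, 30), params, n_peaks = 1)
  expect_lt(o1$position[1], 30)
  ## exactly equidistant: deterministic, reproducible
  oa <- optimize_placement(sec, c(30, 30), params, n_peaks = 1)
  ob <- optimize_placement(sec, c(30, 30), params, n_peaks = 1)
  expect_identical(oa, ob)
})

test_that("next_marker advances a straight filament and terminates at the end", {
  ph <- small_bundle(n_shells = 0, length = 120)
  f <- true_axis_field(bundle_spec(n_shells = 0, length_voxels = 120,
                                   noise_sigma = 0, psf_sigma_xy_voxels = 1))
  tr <- ph$truth$traces[[1]]$markers
  cur <- tr[16, ]
  nm <- next_marker(ph$volume, cur, f)
  expect_equal(unname(nm$marker[2]), 25)   # smallest step wins the tie
  expect_lt(sqrt(sum((nm$marker[c(1, 3)] - tr[26, c(1, 3)])^2)), 0.25)
  expect_null(next_marker(ph$volume, tr[116, ], f))
})

test_that("a gently bent bundle is followed within half a voxel", {
  sp <- bundle_spec(n_shells = 1, length_voxels = 160, noise_sigma = 0,
                    psf_sigma_xy_voxels = 1, bend_amplitude_deg = 3,
                    bend_wavelength_voxels = 160)
  ph <- synthesize_bundle(sp)
  f <- true_axis_field(sp)
  tr <- ph$truth$traces[[1]]$markers
  cur <- tr[16, ]
  for (s in 1:10) {
    nm <- next_marker(ph$volume, cur, f)
    if (is.null(nm) || nm$marker[2] > 115) break
    j <- round(nm$marker[2]) + 1
    expect_lt(sqrt(sum((nm$marker[c(1, 3)] - tr[j, c(1, 3)])^2)), 0.5)
    cur <- nm$marker
  }
  expect_gt(cur[2], 100)  # actually advanced over 100 voxels
})

test_that("trace_bundle on a noise-free 7-filament phantom is sub-quarter-voxel", {
  ph <- small_bundle(n_shells = 1, length = 120)
  f <- estimate_axis(ph$volume)
  seeds <- seeds_from_truth(ph$truth)
  m <- trace_bundle(ph$volume, seeds, f)
  expect_length(m$traces, 7)
  expect_lt(mean_inplane_error(m, ph$truth), 0.25)
  ## determinism
  m2 <- trace_bundle(ph$volume, seeds, f)
  expect_identical(as.data.frame(m), as.data.frame(m2))
})

test_that("empty seed sets and out-of-volume seeds are handled", {
  ph <- small_bundle(n_shells = 0, length = 100)
  f <- straight_field <- axis_field(0, rbind(c(0, 1, 0)))
  empty <- seed_set(matrix(numeric(0), 0, 2), 15L)
  expect_length(trace_bundle(ph$volume, empty, f)$traces, 0)
  bad <- seed_set(rbind(c(1000, 1000)), 15L)
  expect_error(trace_bundle(ph$volume, bad, f), "seed 1")
})

test_that("integer in-plane translation of volume and seeds shifts all markers", {
  sp <- bundle_spec(n_shells = 0, length_voxels = 100, noise_sigma = 0.3,
                    rng_seed = 3, psf_sigma_xy_voxels = 1, margin_voxels = 22)
  ph <- synthesize_bundle(sp)
  f <- true_axis_field(sp)
  v <- ph$volume$data
  shift <- c(3, -2)
  vs <- array(0, dim(v))
  vs[(1 + shift[1]):dim(v)[1], , 1:(dim(v)[3] + shift[2])] <-
    v[1:(dim(v)[1] - shift[1]), , (1 - shift[2]):dim(v)[3]]
  s0 <- seeds_from_truth(ph$truth)
  s1 <- seed_set(sweep(s0$points, 2, shift, "+"), s0$y0, ids = s0$ids)
  m0 <- trace_bundle(ph$volume, s0, f)
  m1 <- trace_bundle(density_volume(vs), s1, f)
  a <- as.data.frame(m0); b <- as.data.frame(m1)
  keep <- a$y > 30 & a$y < 70   # away from the shifted-in borders
  expect_equal(b$x[keep] - a$x[keep], rep(shift[1], sum(keep)),
               tolerance = 0.15)
  expect_equal(b$z[keep] - a$z[keep], rep(shift[2], sum(keep)),
               tolerance = 0.15)
})

test_that("consecutive markers respect the gradual-change displacement bound", {
  ph <- small_bundle(noise = 0.8, seed = 33, n_shells = 1, length = 160)
  f <- estimate_axis(ph$volume)
  params <- trace_params()
  m <- trace_bundle(ph$volume, seeds_from_truth(ph$truth), f, params)
  for (tr in m$traces) {
    mk <- tr$markers
    for (i in seq_len(nrow(mk) - 1)) {
      dy <- mk[i + 1, 2] - mk[i, 2]
      cap <- min(params$search_radius_voxels * dy / 10,
                 params$max_search_radius_voxels)
      disp <- sqrt(sum((mk[i + 1, c(1, 3)] - mk[i, c(1, 3)])^2))
      ## allow the axis-following prediction a small extra margin
      expect_lte(disp, cap + 0.75)
    }
  }
})

test_that("seed files round-trip with their slab metadata", {
  s <- seed_set(rbind(c(10.5, 12), c(22, 13.25)), 15L, 30L, c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_seeds(s, path)
  b <- read_seeds(path)
  expect_equal(b$points, s$points)
  expect_identical(b$y0, 15L)
  expect_identical(b$slab_thickness, 30L)
  expect_identical(b$ids, c("a", "b"))
})
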