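test_that("extract_section averages exactly over the slab", {
  arr <- array(0, c(5, 6, 4))
  arr[, 3, ] <- 0; arr[, 4, ] <- 2
  v <- density_volume(arr)
  expect_equal(extract_section(v, 2, 1), matrix(0, 5, 4))
  expect_equal(extract_section(v, 2, 2), matrix(1, 5, 4))
  expect_error(extract_section(v, 5, 2), "outside")
  expect_error(extract_section(v, 0, 0), ">= 1")
})

test_that("a 30-slice slab of the noisy phantom resolves the hexagonal pattern", {
  ph <- small_bundle(noise = 1.0, seed = 4, n_shells = 1, length = 60)
  sec <- extract_section(ph$volume, 15, 30)
  pts <- t(vapply(ph$truth$traces, function(t) t$markers[31, c(1, 3)],
                  numeric(2)))
  peak_vals <- sec[round(pts) + 1]
  ## midpoints between the center filament and each ring filament
  mids <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ], function(a, b) (a + b) / 2)
  mid_vals <- sec[round(mids) + 1]
  expect_gt(min(peak_vals), max(mid_vals))
})

test_that("correlation_shift recovers integer and sub-pixel translations", {
  set.seed(5)
  base <- matrix(rnorm(48 * 44), 48, 44)
  ## smooth it so sub-pixel structure is meaningful
  sm <- function(m) {
    k <- dnorm(-4:4, sd = 1.5); k <- k / sum(k)
    m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
    t(apply(t(m), 2, function(col) stats::filter(col, k, circular = TRUE)))
  }
  img <- sm(base)
  expect_equal(unname(correlation_shift(img, img)), c(0, 0), tolerance = 1e-9)

  shifted <- img[((0:47 - 3) %% 48) + 1, ((0:43 + 2) %% 44) + 1]  # shift (3, -2)
  sh <- correlation_shift(img, shifted)
  expect_equal(unname(sh), c(3, -2), tolerance = 0.25 / 3)
  ## brute-force overlap correlation over all integer shifts confirms argmax
  a0 <- img - mean(img); b0 <- shifted - mean(shifted)
  brute <- function(dx, dz) {
    ia <- max(1, 1 - dx):min(48, 48 - dx)
    ka <- max(1, 1 - dz):min(44, 44 - dz)
    sum(a0[ia, ka] * b0[ia + dx, ka + dz])
  }
  g <- expand.grid(dx = -6:6, dz = -6:6)
  g$v <- mapply(brute, g$dx, g$dz)
  expect_equal(unlist(g[which.max(g$v), c("dx", "dz")]),
               c(dx = 3, dz = -2))

  ## half-pixel shift via Fourier phase ramp
  fshift <- function(m, dx) {
    n <- nrow(m)
    ph <- exp(-2i * pi * (c(0:(n %/% 2), -(ceiling(n / 2) - 1):-1)) * dx / n)
    Re(stats::mvfft(stats::mvfft(m) * ph, inverse = TRUE)) / n
  }
  sub <- fshift(img, 0.5)
  sh2 <- correlation_shift(img, sub)
  expect_lt(abs(sh2[1] - 0.5), 0.25)
  expect_lt(abs(sh2[2]), 0.25)
})

test_that("correlation is invariant to constant offsets and rejects constants", {
  set.seed(6)
  a <- matrix(rnorm(30 * 30), 30, 30)
  b <- a[c(2:30, 1), ]
  expect_equal(correlation_shift(a, b), correlation_shift(a + 5, b - 3),
               tolerance = 1e-9)
  expect_error(correlation_shift(matrix(1, 5, 5), a[1:5, 1:5]), "degenerate")
  expect_error(correlation_shift(a, a[1:10, 1:10]), "same shape")
})

test_that("estimate_axis recovers straight, tilted and bent bundle directions", {
  ph0 <- small_bundle(n_shells = 1, length = 150)
  f0 <- estimate_axis(ph0$volume, step = 55, thickness = 30)
  ang0 <- acos(pmin(1, f0$dirs[, 2])) * 180 / pi
  expect_lt(max(ang0), 0.1)

  pht <- small_bundle(n_shells = 1, length = 150, tilt = 5)
  ft <- estimate_axis(pht$volume, step = 55, thickness = 30)
  truth <- c(sin(5 * pi / 180), cos(5 * pi / 180), 0)
  err <- acos(pmin(1, ft$dirs %*% truth)) * 180 / pi
  expect_lt(max(err), 0.5)
})

test_that("axis sample count follows the sampling arithmetic", {
  ## three straight filaments along a 1194-plane volume
  arr <- array(0, c(31, 1194, 31))
  for (cc in list(c(10, 15), c(20, 10), c(16, 22)))
    arr <- arr + outer(exp(-((0:30) - cc[1])^2 / 8),
                       outer(rep(1, 1194), exp(-((0:30) - cc[2])^2 / 8)))
  v <- density_volume(aperm(arr, c(1, 2, 3)))
  f <- estimate_axis(v, step = 55, thickness = 30)
  expect_equal(length(f$y), 21)   # floor((1194 - 30) / 55) pairs
  expect_true(all(diff(f$y) == 55))
  expect_error(estimate_axis(density_volume(array(1, c(5, 50, 5)))),
               "too short")
})

test_that("axis_at interpolates piecewise-linearly with renormalization", {
  single <- axis_field(10, rbind(c(0.1, 0.99, 0)))
  expect_equal(axis_at(single, -5), axis_at(single, 100), tolerance = 1e-12)
  d1 <- c(0, 1, 0)
  d2 <- c(sin(10 * pi / 180), cos(10 * pi / 180), 0)
  f <- axis_field(c(0, 20), rbind(d1, d2))
  expect_equal(unname(axis_at(f, 20)), d2, tolerance = 1e-12)
  mid <- axis_at(f, 10)
  expected <- (d1 + d2) / sqrt(sum((d1 + d2)^2))  # normalized chord midpoint
  expect_equal(unname(mid), expected, tolerance = 1e-6)
  ## 5-degree tilt at the midpoint
  expect_equal(unname(acos(mid[2]) * 180 / pi), 5, tolerance = 1e-6)
})

test_that("axis_field validates unit directions and ordering", {
  expect_error(axis_field(c(0, 0), rbind(c(0, 1, 0), c(0, 1, 0))), "increasing")
  expect_error(axis_field(0, rbind(c(0, -1, 0))), "positive y")
  expect_error(axis_field(0, rbind(c(0, 0, 0))), "nonzero")
})

test_that("rotating the volume 90 degrees about y permutes the detected shift", {
  pht <- small_bundle(n_shells = 1, length = 100, tilt = 4)
  v <- pht$volume$data
  ## rotate: (x, y, z) -> (z, y, nx - 1 - x)
  vr <- aperm(v, c(3, 2, 1))[, , dim(v)[1]:1]
  fr <- estimate_axis(density_volume(vr), step = 55, thickness = 30)
  f <- estimate_axis(pht$volume, step = 55, thickness = 30)
  expect_equal(unname(fr$dirs[, 3]), unname(-f$dirs[, 1]), tolerance = 5e-3)
  expect_equal(unname(abs(fr$dirs[, 1])), unname(abs(f$dirs[, 3])), tolerance = 5e-3)
})
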