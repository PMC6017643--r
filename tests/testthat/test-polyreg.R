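test_that("weight kernel covariances: closed form, symmetry, positive definiteness", {
  wk <- build_weight_kernel(c(0, 1, 0), sigma_long = 1, sigma_thick = 1,
                            sigma_r = 1)
  expect_equal(wk$H, diag(c(2, 2, 5)), tolerance = 1e-12)
  expect_equal(wk$H, wk$H_S + wk$H_R)

  set.seed(41)
  for (i in 1:10) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    sl <- runif(1, 2, 9); st <- runif(1, 0.5, 3)
    w <- build_weight_kernel(d, sigma_long = sl, sigma_thick = st,
                             sigma_r = runif(1, 0.5, 2))
    expect_equal(w$H_S, t(w$H_S), tolerance = 1e-12)
    expect_no_error(chol(w$H_S))
    expect_no_error(chol(w$H))
    ## H_S has eigenvalues (sigma_long^2, sigma_thick^2 x2), long axis = dir
    ev <- eigen(w$H_S, symmetric = TRUE)
    expect_equal(sort(ev$values), sort(c(sl^2, st^2, st^2)), tolerance = 1e-9)
    vmax <- ev$vectors[, which.max(ev$values)]
    expect_equal(abs(sum(vmax * d)), 1, tolerance = 1e-9)
  }
  expect_error(build_weight_kernel(c(0, 2, 0), 1, 1, 1), "unit")
  expect_error(build_weight_kernel(c(1, 0, 0), -1, 1, 1), "positive")
})

test_that("closed-form W equals the numerical convolution of S and R", {
  ## S along x (dir (1,0,0)) so both S and R are axis-aligned; convolve the
  ## two sampled Gaussians numerically and compare on a grid.
  sl <- 2.2; st <- 1.1; sr <- 0.9
  wk <- build_weight_kernel(c(1, 0, 0), sl, st, sr)
  r <- 7L
  xs <- -r:r
  g3 <- function(sx, sy, sz) {
    a <- exp(-xs^2 / (2 * sx^2)); b <- exp(-xs^2 / (2 * sy^2))
    c_ <- exp(-xs^2 / (2 * sz^2))
    outer(outer(a, b), c_)
  }
  S <- g3(sl, st, st); R <- g3(sr, sr, 2 * sr)
  ## direct (zero-padded) 3D convolution evaluated at the central region
  conv_at <- function(dx, dy, dz) {
    acc <- 0
    for (i in xs) for (j in xs) for (k in xs) {
      ii <- dx - i; jj <- dy - j; kk <- dz - k
      if (abs(ii) <= r && abs(jj) <= r && abs(kk) <= r)
        acc <- acc + S[i + r + 1, j + r + 1, k + r + 1] *
          R[ii + r + 1, jj + r + 1, kk + r + 1]
    }
    acc
  }
  Hinv <- solve(wk$H)
  w_at <- function(p) exp(-0.5 * sum(p * (Hinv %*% p)))
  c0 <- conv_at(0, 0, 0)
  for (p in list(c(1, 0, 0), c(0, 2, 0), c(0, 0, 2), c(2, 1, 1), c(-1, 2, -2)))
    expect_equal(conv_at(p[1], p[2], p[3]) / c0, w_at(p), tolerance = 0.01)
})

test_that("local_fit recovers an exact quadratic and a constant field", {
  A <- matrix(c(0.5, 0.2, -0.1, 0.2, -0.3, 0.15, -0.1, 0.15, 0.4), 3, 3)
  b <- c(1, -2, 0.5); cc <- 3.7
  g <- function(x, y, z) {
    p <- c(x, y, z); sum(p * (A %*% p)) + sum(b * p) + cc
  }
  n <- 13
  arr <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    arr[i, j, k] <- g(i - 7, j - 7, k - 7)   # centered at voxel (6,6,6) 0-based
  v <- density_volume(arr)
  wk <- build_weight_kernel(c(0, 1, 0), 1.5, 1.2, 0.8)
  fit <- local_fit(v, c(6, 6, 6), wk)
  expect_equal(fit$value, cc, tolerance = 1e-8)
  expect_equal(fit$poly$A, A, tolerance = 1e-7)
  expect_equal(fit$poly$b, b, tolerance = 1e-7)

  cv <- density_volume(array(7.0, c(9, 9, 9)))
  fitc <- local_fit(cv, c(4, 4, 4), wk)
  expect_equal(fitc$value, 7.0, tolerance = 1e-10)
  expect_equal(fitc$poly$A, matrix(0, 3, 3), tolerance = 1e-9)
  expect_equal(fitc$poly$b, c(0, 0, 0), tolerance = 1e-9)
})

test_that("local_fit agrees with an independent dense weighted LS oracle", {
  set.seed(42)
  arr <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  v <- density_volume(arr)
  wk <- build_weight_kernel(c(sin(0.3), cos(0.3), 0), 2, 1.2, 0.7)
  Hinv <- solve(wk$H)
  pts <- cbind(sample(3:5, 10, TRUE), sample(3:5, 10, TRUE),
               sample(3:5, 10, TRUE))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    ## oracle: build the full design over the whole volume, weights from W
    g <- as.matrix(expand.grid(x = 0:8, y = 0:8, z = 0:8))
    rel <- sweep(g, 2, p)
    w <- exp(-0.5 * rowSums((rel %*% Hinv) * rel))
    w[w < exp(-4.5)] <- 0
    ## respect the implementation's support-box truncation
    inbox <- abs(rel[, 1]) <= wk$support_radius[1] &
             abs(rel[, 2]) <= wk$support_radius[2] &
             abs(rel[, 3]) <= wk$support_radius[3]
    keep <- w > 0 & inbox
    X <- cbind(rel[keep, 1]^2, rel[keep, 1] * rel[keep, 2],
               rel[keep, 1] * rel[keep, 3], rel[keep, 2]^2,
               rel[keep, 2] * rel[keep, 3], rel[keep, 3]^2,
               rel[keep, 1], rel[keep, 2], rel[keep, 3], 1)
    phi <- arr[g[keep, , drop = FALSE] + 1]
    beta <- qr.coef(qr(X * sqrt(w[keep])), phi * sqrt(w[keep]))
    fit <- local_fit(v, p, wk)
    expect_equal(fit$value, unname(beta[10]), tolerance = 1e-8)
  }
})

test_that("denoising is exact on quadratics and leaves constants alone", {
  n <- 21
  arr <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    arr[i, j, k] <- 0.3 * (i - 11)^2 - 0.2 * (i - 11) * (k - 11) +
      0.1 * (j - 11)^2 + 2 * (k - 11) + 5
  v <- density_volume(arr)
  f <- axis_field(0, rbind(c(0, 1, 0)))
  out <- suppressMessages(denoise_polyreg(v, f, sigma_long = 2,
                                          sigma_thick = 1.2, sigma_r = 0.8))
  wk <- build_weight_kernel(c(0, 1, 0), 2, 1.2, 0.8)
  r <- wk$support_radius
  interior <- out$data[(r[1] + 1):(n - r[1]), (r[2] + 1):(n - r[2]),
                       (r[3] + 1):(n - r[3])]
  expected <- arr[(r[1] + 1):(n - r[1]), (r[2] + 1):(n - r[2]),
                  (r[3] + 1):(n - r[3])]
  expect_equal(interior, expected, tolerance = 1e-6)

  cv <- density_volume(array(2.5, c(15, 15, 15)))
  outc <- suppressMessages(denoise_polyreg(cv, f, 2, 1.2, 0.8))
  expect_equal(outc$data, cv$data, tolerance = 1e-9)
})

test_that("denoising is linear in the data", {
  set.seed(44)
  a1 <- array(rnorm(12 * 14 * 12), c(12, 14, 12))
  a2 <- array(rnorm(12 * 14 * 12), c(12, 14, 12))
  f <- axis_field(0, rbind(c(0, 1, 0)))
  dn <- function(a) suppressMessages(
    denoise_polyreg(density_volume(a), f, 2, 1, 0.7))$data
  lhs <- dn(2 * a1 - 0.5 * a2)
  rhs <- 2 * dn(a1) - 0.5 * dn(a2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("denoising reduces MSE against the noise-free phantom", {
  sp <- bundle_spec(n_shells = 1, length_voxels = 70, noise_sigma = 0.8,
                    rng_seed = 45, psf_sigma_xy_voxels = 1, margin_voxels = 10)
  ph <- synthesize_bundle(sp)
  f <- true_axis_field(sp)
  out <- suppressMessages(denoise_polyreg(ph$volume, f, sigma_long = 4,
                                          sigma_thick = 1.5, sigma_r = 0.8))
  mse <- function(a) mean((a - ph$clean$data)^2)
  expect_lt(mse(out$data), mse(ph$volume$data))
})

test_that("rank deficiency at impossible supports is reported", {
  v <- density_volume(array(1.0, c(3, 3, 3)))
  wk <- build_weight_kernel(c(0, 1, 0), 0.3, 0.3, 0.2)
  expect_error(local_fit(v, c(0, 0, 0), wk), "rank")
})
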