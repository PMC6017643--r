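## Local quadratic polynomial kernel regression: at each voxel p, a
## quadratic f is fit to the map by weighted least squares with an
## anisotropic Gaussian weight W(q - p); the denoised value is f(p). The
## weight is the convolution of a filament-shaped kernel S (elongated along
## the local bundle direction) with a resolution kernel R (the Gaussian
## approximation of the missing-wedge point spread, 2x wider along z).
## Both being Gaussian, W is Gaussian with covariance H = H_S + H_R.

## rotation taking (1,0,0) to the unit vector `dir` (Rodrigues)
rotation_to <- function(dir) {
  a <- c(1, 0, 0)
  v <- c(a[2] * dir[3] - a[3] * dir[2],
         a[3] * dir[1] - a[1] * dir[3],
         a[1] * dir[2] - a[2] * dir[1])
  c_ <- sum(a * dir)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(-1, -1, 1)))  # antiparallel: any 180-degree rotation
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Build the anisotropic regression weight kernel
#'
#' The shape kernel S is a Gaussian elongated along the filament direction
#' (sd \code{sigma_long}) with cross-sectional width \code{sigma_thick}
#' (the expected filament radius); the resolution kernel R is a Gaussian
#' with sd \code{sigma_r} in x and y and twice that along z (the
#' missing-wedge anisotropy). Their convolution W is Gaussian with
#' covariance H = H_S + H_R.
#'
#' @param filament_dir unit 3-vector, local filament/bundle direction.
#' @param sigma_long S's sd along the filament (voxels).
#' @param sigma_thick S's sd across the filament (voxels).
#' @param sigma_r R's sd in the x--y plane (voxels); along z it is doubled.
#' @return an object of class \code{weight_kernel}: list with the 3x3
#'   covariances \code{H_S}, \code{H_R}, \code{H} (= H_S + H_R) and the
#'   per-axis truncation \code{support_radius} (3 sd of H, rounded up).
#' @export
build_weight_kernel <- function(filament_dir, sigma_long = 8,
                                sigma_thick = 2, sigma_r = 1) {
  filament_dir <- as.numeric(filament_dir)
  if (length(filament_dir) != 3L || !all(is.finite(filament_dir)) ||
      abs(sqrt(sum(filament_dir^2)) - 1) > 1e-6)
    stop("`filament_dir` must be a unit 3-vector")
  if (any(c(sigma_long, sigma_thick, sigma_r) <= 0))
    stop("all sigmas must be positive")
  R <- rotation_to(filament_dir)
  H_S <- R %*% diag(c(sigma_long^2, sigma_thick^2, sigma_thick^2)) %*% t(R)
  H_S <- (H_S + t(H_S)) / 2
  H_R <- diag(c(sigma_r^2, sigma_r^2, (2 * sigma_r)^2))
  H <- H_S + H_R
  structure(list(H_S = H_S, H_R = H_R, H = H,
                 support_radius = as.integer(ceiling(3 * sqrt(diag(H))))),
            class = "weight_kernel")
}

## W evaluated on the truncated support grid; values below exp(-9/2) * max
## are zeroed. Returns list(offsets = n x 3, w = n, dims, full arrays).
weight_grid <- function(kernel) {
  r <- kernel$support_radius
  Hinv <- solve(kernel$H)
  xs <- -r[1]:r[1]; ys <- -r[2]:r[2]; zs <- -r[3]:r[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  q <- rowSums((g %*% Hinv) * g)
  w <- exp(-0.5 * q)
  w[w < exp(-4.5)] <- 0
  list(offsets = g, w = w, dims = c(length(xs), length(ys), length(zs)))
}

## the 10 quadratic monomials at offsets (order: x2 xy xz y2 yz z2 x y z 1)
design_matrix <- function(g) {
  cbind(g[, 1]^2, g[, 1] * g[, 2], g[, 1] * g[, 3], g[, 2]^2,
        g[, 2] * g[, 3], g[, 3]^2, g[, 1], g[, 2], g[, 3], 1)
}

coeffs_to_poly <- function(beta) {
  A <- matrix(c(beta[1], beta[2] / 2, beta[3] / 2,
                beta[2] / 2, beta[4], beta[5] / 2,
                beta[3] / 2, beta[5] / 2, beta[6]), 3, 3)
  structure(list(A = A, b = beta[7:9], c = beta[10]),
            class = "quadratic_poly")
}

#' Weighted local quadratic fit at one voxel
#'
#' Solves the weighted least squares problem min sum_q (f(q) - map(q))^2
#' W(q - p) over the 10 coefficients of a trivariate quadratic, in
#' coordinates centered at \code{p}, over the voxels inside the kernel's
#' truncated support. The denoised value at p is the constant term f(p) = c.
#'
#' @param vol a \code{\link{density_volume}}.
#' @param p integer 3-vector, 0-based voxel position.
#' @param kernel a \code{\link{build_weight_kernel}} result.
#' @return list(poly, value): \code{poly} has the symmetric quadratic matrix
#'   \code{A}, linear part \code{b} and constant \code{c}; \code{value = c}.
#' @export
local_fit <- function(vol, p, kernel) {
  stopifnot(inherits(vol, "density_volume"), inherits(kernel, "weight_kernel"))
  d <- dim(vol$data)
  p <- as.numeric(p)
  if (any(p < 0) || any(p > d - 1)) stop("`p` must lie inside the volume")
  wg <- weight_grid(kernel)
  q <- sweep(wg$offsets, 2, p, "+")
  inside <- q[, 1] >= 0 & q[, 1] <= d[1] - 1 &
            q[, 2] >= 0 & q[, 2] <= d[2] - 1 &
            q[, 3] >= 0 & q[, 3] <= d[3] - 1
  keep <- inside & wg$w > 0
  if (sum(keep) < 10)
    stop("rank deficiency: fewer than 10 voxels in the kernel support")
  g <- wg$offsets[keep, , drop = FALSE]
  w <- wg$w[keep]
  X <- design_matrix(g)
  phi <- vol$data[cbind(q[keep, 1], q[keep, 2], q[keep, 3]) + 1]
  XtW <- t(X * w)
  M <- XtW %*% X
  beta <- tryCatch(solve(M, XtW %*% phi),
                   error = function(e) stop("rank deficiency: singular normal equations"))
  poly <- coeffs_to_poly(as.numeric(beta))
  list(poly = poly, value = poly$c)
}

## the c-coefficient row of the WLS solution as a linear filter over the
## full support box: value(p) = sum_q filter(q) * map(p + q)
polyreg_filter <- function(kernel) {
  wg <- weight_grid(kernel)
  X <- design_matrix(wg$offsets)
  XtW <- t(X * wg$w)
  M <- XtW %*% X
  crow <- solve(M, XtW)[10, ]
  array(crow, dim = wg$dims)
}

#' Denoise a volume by local quadratic kernel regression
#'
#' Applies the weighted quadratic fit at every voxel, taking the weight
#' kernel's filament direction from the axis field at the voxel's height.
#' Because the weights do not depend on the data, the fit is a linear
#' filter per direction: the c-row of the weighted normal equations is
#' precomputed per distinct direction and applied by convolution, which is
#' algebraically identical to the per-voxel solve. Voxels whose full
#' support extends outside the volume (near borders) are copied from the
#' input; their count is reported in the provenance.
#'
#' @param vol a \code{\link{density_volume}}.
#' @param field an \code{\link{axis_field}}.
#' @param sigma_long,sigma_thick,sigma_r see \code{\link{build_weight_kernel}}.
#' @return a \code{\link{density_volume}}; the denoised map is exact on any
#'   globally quadratic input (interior voxels).
#' @export
denoise_polyreg <- function(vol, field, sigma_long = 8, sigma_thick = 2,
                            sigma_r = 1) {
  stopifnot(inherits(vol, "density_volume"))
  if (!inherits(field, "axis_field")) stop("`field` must be an axis_field")
  ny <- dim(vol$data)[2]
  dirs <- matrix(axis_at(field, 0:(ny - 1)), ncol = 3)
  key <- apply(round(dirs, 6), 1, paste, collapse = ",")
  uk <- unique(key)
  fidx <- match(key, uk)
  filters <- lapply(uk, function(k) {
    i <- match(k, key)
    polyreg_filter(build_weight_kernel(dirs[i, ] / sqrt(sum(dirs[i, ]^2)),
                                       sigma_long, sigma_thick, sigma_r))
  })
  res <- cpp_polyreg_apply(vol$data, filters, as.integer(fidx))
  message(sprintf("denoise_polyreg: %d border voxel(s) copied from the input",
                  as.integer(res$n_copied)))
  density_volume(res$volume, voxel_size_nm = vol$voxel_size_nm,
                 origin_nm = vol$origin_nm,
                 provenance = c(sprintf(
                   "denoise_polyreg(sigma_long = %g, sigma_thick = %g, sigma_r = %g); %d border voxels copied",
                   sigma_long, sigma_thick, sigma_r, as.integer(res$n_copied)),
                   vol$provenance))
}
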