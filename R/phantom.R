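#' Hexagonal lattice of filament centers
#'
#' Centers of a hexagonally packed bundle cross-section: one center filament
#' plus \code{n_shells} full hexagonal rings around it, every point's nearest
#' neighbor at exactly \code{spacing}. Actin filaments in the stereocilium
#' core pack this way at roughly 11--13 voxels (~12 nm) spacing.
#'
#' @param n_shells non-negative integer; number of rings.
#' @param spacing nearest-neighbor distance (voxels).
#' @return a matrix with \code{1 + 3 n (n+1)} rows and columns (x, z).
#' @examples
#' nrow(hex_lattice(3, 12))  # 37
#' @export
hex_lattice <- function(n_shells, spacing = 12) {
  if (length(n_shells) != 1L || is.na(n_shells) || n_shells < 0 ||
      n_shells != round(n_shells))
    stop("`n_shells` must be a non-negative integer")
  if (!is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a positive scalar")
  n_shells <- as.integer(n_shells)
  ## axial coordinates (a, b) with basis vectors 60 degrees apart
  u <- c(1, 0)
  v <- c(cos(pi / 3), sin(pi / 3))
  pts <- matrix(0, nrow = 1, ncol = 2)
  if (n_shells > 0) {
    ab <- expand.grid(a = -n_shells:n_shells, b = -n_shells:n_shells)
    ab <- ab[abs(ab$a + ab$b) <= n_shells & !(ab$a == 0 & ab$b == 0), ]
    ring <- pmax(abs(ab$a), abs(ab$b), abs(ab$a + ab$b))
    ab <- ab[ring <= n_shells, ]
    pts <- rbind(pts, cbind(ab$a * u[1] + ab$b * v[1],
                            ab$a * u[2] + ab$b * v[2]))
  }
  pts <- pts * spacing
  colnames(pts) <- c("x", "z")
  pts
}

#' Bundle phantom specification
#'
#' Parameters of the synthetic actin-bundle phantom. Defaults reproduce the
#' geometry of the stereocilium shaft at reduced length: 37 hexagonally
#' packed filaments 12 voxels apart, Gaussian filament cross-sections of
#' width 2 voxels (an apparent 8--10-voxel thickness after the point-spread
#' blur), a point spread elongated 2x along z to mimic the missing wedge,
#' and additive Gaussian noise with standard deviation 1.0 relative to the
#' unit filament peak amplitude.
#'
#' @param n_shells hexagonal shells around the center filament.
#' @param spacing_voxels nearest-neighbor centerline spacing (voxels).
#' @param filament_sigma_voxels Gaussian cross-section width (voxels).
#' @param length_voxels bundle length along y (voxels).
#' @param bend_amplitude_deg maximum direction deviation of the shared
#'   sinusoidal collective bend (degrees); 0 disables bending.
#' @param bend_wavelength_voxels wavelength of the collective bend (voxels).
#' @param tilt_deg global tilt of the bundle from +y, in the x--y plane.
#' @param psf_sigma_xy_voxels point-spread Gaussian width in x and y.
#' @param z_elongation_factor ratio of the z point-spread width to the x--y
#'   width (>= 1); 2 emulates the missing-wedge anisotropy.
#' @param noise_sigma additive Gaussian noise sd (filament peak = 1).
#' @param rng_seed integer seed; identical specs give bit-identical volumes.
#' @param margin_voxels in-plane margin between the outermost filament and
#'   the volume edge.
#' @param nx,nz optional in-plane volume dimensions; computed from the
#'   lattice extent plus margin when NULL.
#' @return an object of class \code{bundle_spec} (a validated list).
#' @export
bundle_spec <- function(n_shells = 3, spacing_voxels = 12,
                        filament_sigma_voxels = 2.0, length_voxels = 400,
                        bend_amplitude_deg = 0, bend_wavelength_voxels = 400,
                        tilt_deg = 0, psf_sigma_xy_voxels = 1.5,
                        z_elongation_factor = 2, noise_sigma = 1.0,
                        rng_seed = 42, margin_voxels = 16,
                        nx = NULL, nz = NULL) {
  spec <- list(n_shells = as.integer(n_shells),
               spacing_voxels = as.numeric(spacing_voxels),
               filament_sigma_voxels = as.numeric(filament_sigma_voxels),
               length_voxels = as.integer(length_voxels),
               bend_amplitude_deg = as.numeric(bend_amplitude_deg),
               bend_wavelength_voxels = as.numeric(bend_wavelength_voxels),
               tilt_deg = as.numeric(tilt_deg),
               psf_sigma_xy_voxels = as.numeric(psf_sigma_xy_voxels),
               z_elongation_factor = as.numeric(z_elongation_factor),
               noise_sigma = as.numeric(noise_sigma),
               rng_seed = as.integer(rng_seed),
               margin_voxels = as.numeric(margin_voxels),
               nx = if (is.null(nx)) NULL else as.integer(nx),
               nz = if (is.null(nz)) NULL else as.integer(nz))
  sc <- unlist(spec[c("spacing_voxels", "filament_sigma_voxels",
                      "bend_amplitude_deg", "bend_wavelength_voxels",
                      "tilt_deg", "psf_sigma_xy_voxels",
                      "z_elongation_factor", "noise_sigma")])
  if (!all(is.finite(sc))) stop("all bundle_spec scalars must be finite")
  if (spec$n_shells < 0) stop("`n_shells` must be >= 0")
  if (spec$spacing_voxels <= 0) stop("`spacing_voxels` must be positive")
  if (spec$z_elongation_factor < 1) stop("`z_elongation_factor` must be >= 1")
  if (spec$filament_sigma_voxels <= 0) stop("`filament_sigma_voxels` must be positive")
  if (spec$length_voxels < 2) stop("`length_voxels` must be >= 2")
  if (spec$noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (spec$bend_wavelength_voxels <= 0) stop("`bend_wavelength_voxels` must be positive")
  class(spec) <- "bundle_spec"
  spec
}

## shared in-plane x displacement of all centerlines at height y (0-based)
phantom_displacement_x <- function(spec, y) {
  y_mid <- (spec$length_voxels - 1) / 2
  amp <- tan(spec$bend_amplitude_deg * pi / 180) *
    spec$bend_wavelength_voxels / (2 * pi)
  tan(spec$tilt_deg * pi / 180) * (y - y_mid) +
    amp * sin(2 * pi * y / spec$bend_wavelength_voxels)
}

#' True bundle direction field of a phantom
#'
#' The exact local bundle direction of the phantom defined by \code{spec},
#' sampled at every integer y: the analytical derivative of the shared
#' displacement field. With zero bend and tilt this is (0, 1, 0) everywhere,
#' which serves as the oracle for \code{\link{estimate_axis}}.
#'
#' @param spec a \code{\link{bundle_spec}}.
#' @return an \code{\link{axis_field}}.
#' @export
true_axis_field <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  y <- 0:(spec$length_voxels - 1)
  amp <- tan(spec$bend_amplitude_deg * pi / 180) *
    spec$bend_wavelength_voxels / (2 * pi)
  slope <- tan(spec$tilt_deg * pi / 180) +
    amp * (2 * pi / spec$bend_wavelength_voxels) *
      cos(2 * pi * y / spec$bend_wavelength_voxels)
  dirs <- cbind(slope, 1, 0)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  axis_field(y, dirs)
}

#' Synthesize a bundle phantom
#'
#' Builds a synthetic tomogram of an actin bundle with known ground truth.
#' Each centerline is a hexagonal lattice point displaced by the shared
#' smooth bend/tilt field (filaments stay parallel, so the nearest-neighbor
#' spacing is conserved exactly). The clean density is a sum of radially
#' Gaussian filament profiles (peak 1) around each centerline; it is then
#' blurred with an anisotropic Gaussian point spread (sigma_z =
#' \code{z_elongation_factor} times sigma_xy, mimicking the missing wedge)
#' and i.i.d. Gaussian noise is added under \code{rng_seed}. The global RNG
#' state is left untouched.
#'
#' @param spec a \code{\link{bundle_spec}}.
#' @return a list with elements \code{volume} (a
#'   \code{\link{density_volume}}), \code{truth} (a
#'   \code{\link{bundle_model}} with markers at every integer y), and
#'   \code{clean} (the noise-free volume, for validation).
#' @export
synthesize_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  lat <- hex_lattice(spec$n_shells, spec$spacing_voxels)
  ny <- spec$length_voxels
  y <- 0:(ny - 1)
  dx <- phantom_displacement_x(spec, y)
  sigma_tot <- spec$filament_sigma_voxels +
    spec$psf_sigma_xy_voxels * spec$z_elongation_factor
  xr <- range(outer(lat[, 1], dx, "+"))   # extent of centerline x, pre-centering
  zr <- range(lat[, 2])
  margin <- max(spec$margin_voxels, 3 * sigma_tot)
  nx <- if (is.null(spec$nx))
    as.integer(ceiling(diff(xr) + 2 * margin) + 1L) else spec$nx
  nz <- if (is.null(spec$nz))
    as.integer(ceiling(diff(zr) + 2 * margin) + 1L) else spec$nz
  need_x <- ceiling(diff(xr) + 2 * 3 * sigma_tot)
  need_z <- ceiling(diff(zr) + 2 * 3 * sigma_tot)
  if (nx < need_x || nz < need_z)
    stop(sprintf(paste0("volume too small for the lattice plus a 3-sigma ",
                        "margin: need at least %d x %d in-plane, got %d x %d"),
                 need_x, need_z, nx, nz))
  cx0 <- (nx - 1) / 2 - mean(xr)          # shift lattice midpoint to center
  cz0 <- (nz - 1) / 2 - mean(zr)
  ## centerlines: cx[filament, y], cz constant per filament
  cx <- outer(lat[, 1] + cx0, dx, "+")   # nfil x ny
  cz <- lat[, 2] + cz0
  nfil <- nrow(lat)

  vol <- array(0, dim = c(nx, ny, nz))
  sf <- spec$filament_sigma_voxels
  half <- ceiling(4 * sf)
  xs <- 0:(nx - 1)
  zs <- 0:(nz - 1)
  for (j in seq_len(ny)) {
    plane <- matrix(0, nx, nz)
    for (f in seq_len(nfil)) {
      cxf <- cx[f, j]; czf <- cz[f]
      xi <- max(0, floor(cxf - half)):min(nx - 1, ceiling(cxf + half))
      zi <- max(0, floor(czf - half)):min(nz - 1, ceiling(czf + half))
      if (!length(xi) || !length(zi)) next
      gx <- exp(-(xi - cxf)^2 / (2 * sf^2))
      gz <- exp(-(zi - czf)^2 / (2 * sf^2))
      plane[xi + 1, zi + 1] <- plane[xi + 1, zi + 1] + outer(gx, gz)
    }
    vol[, j, ] <- plane
  }

  sx <- spec$psf_sigma_xy_voxels
  sz <- sx * spec$z_elongation_factor
  if (sx > 0) {
    vol <- gaussian_blur_axis(vol, sx, 0L)
    vol <- gaussian_blur_axis(vol, sx, 1L)
    vol <- gaussian_blur_axis(vol, sz, 2L)
  }
  clean <- vol
  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$rng_seed)
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sigma), dim = dim(vol))
  }

  prov <- sprintf(
    "phantom: %d filaments, spacing %g, sigma_f %g, psf (%g, %g), noise %g, seed %d",
    nfil, spec$spacing_voxels, sf, sx, sz, spec$noise_sigma, spec$rng_seed)
  truth <- bundle_model(lapply(seq_len(nfil), function(f)
    filament_trace(cbind(cx[f, ], y, cz[f]), id = as.character(f))),
    provenance = prov)
  list(volume = density_volume(vol, provenance = prov),
       truth = truth,
       clean = density_volume(clean, provenance = paste(prov, "(noise-free)")))
}

## 1D Gaussian blur along one axis (0 = x, 1 = y, 2 = z), truncated at 4 sigma
gaussian_blur_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  cpp_convolve_axis(arr, k, as.integer(axis))
}
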