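#' Bundle axis field
#'
#' A piecewise description of the local bundle direction: unit 3-vectors
#' sampled at increasing y positions. Directions always have a positive
#' y-component (the bundle runs along +y).
#'
#' @param y numeric vector of sample positions (voxels), strictly increasing.
#' @param dirs numeric matrix, one row per sample, columns (dx, dy, dz);
#'   rows are renormalized to unit length.
#' @return an object of class \code{axis_field}.
#' @export
axis_field <- function(y, dirs) {
  dirs <- as.matrix(dirs)
  if (nrow(dirs) != length(y)) stop("one direction per y sample required")
  if (length(y) < 1L) stop("axis field must have at least one sample")
  if (any(diff(y) <= 0)) stop("y samples must be strictly increasing")
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm == 0) || any(!is.finite(nrm))) stop("directions must be nonzero and finite")
  dirs <- dirs / nrm
  if (any(dirs[, 2] <= 0))
    stop("all directions must have a positive y-component")
  dimnames(dirs) <- list(NULL, c("dx", "dy", "dz"))
  structure(list(y = as.numeric(y), dirs = dirs), class = "axis_field")
}

#' @export
print.axis_field <- function(x, ...) {
  n <- length(x$y)
  ang <- acos(pmin(1, x$dirs[, 2])) * 180 / pi
  cat(sprintf("<axis_field> %d sample%s, y in [%g, %g], tilt from +y: %.2f-%.2f deg\n",
              n, if (n == 1) "" else "s", min(x$y), max(x$y), min(ang), max(ang)))
  invisible(x)
}

#' Interpolate the bundle direction at a height
#'
#' Piecewise-linear interpolation of the sampled directions, renormalized to
#' unit length; constant extrapolation beyond the first/last sample.
#'
#' @param field an \code{\link{axis_field}}.
#' @param y height(s) in voxels.
#' @return a unit 3-vector, or an n x 3 matrix when \code{y} has length > 1.
#' @export
axis_at <- function(field, y) {
  stopifnot(inherits(field, "axis_field"))
  ys <- pmin(pmax(y, field$y[1]), field$y[length(field$y)])
  if (length(field$y) == 1L) {
    out <- matrix(field$dirs[1, ], nrow = length(y), ncol = 3, byrow = TRUE)
  } else {
    out <- vapply(1:3, function(c)
      approx(field$y, field$dirs[, c], xout = ys)$y, numeric(length(ys)))
    out <- matrix(out, ncol = 3)
    out <- out / sqrt(rowSums(out^2))
  }
  colnames(out) <- c("dx", "dy", "dz")
  if (length(y) == 1L) out[1, ] else out
}

#' Extract a cross-section slab
#'
#' Mean of \code{thickness} consecutive x--z planes starting at integer
#' height \code{y}: the ~30-slice slabs that make the hexagonal filament
#' pattern visible in a noisy map.
#'
#' @param vol a \code{\link{density_volume}}.
#' @param y 0-based starting plane index.
#' @param thickness number of planes to average (>= 1).
#' @return an nx x nz matrix (x in rows, z in columns).
#' @export
extract_section <- function(vol, y, thickness = 1L) {
  stopifnot(inherits(vol, "density_volume"))
  thickness <- as.integer(thickness)
  y <- as.integer(y)
  ny <- dim(vol$data)[2]
  if (thickness < 1L) stop("`thickness` must be >= 1")
  if (y < 0L || y + thickness > ny)
    stop(sprintf("section window [%d, %d) outside the volume (ny = %d)",
                 y, y + thickness, ny))
  a <- vol$data[, (y + 1):(y + thickness), , drop = FALSE]
  d <- dim(a)
  b <- aperm(a, c(2, 1, 3))
  dim(b) <- c(d[2], d[1] * d[3])
  matrix(colMeans(b), d[1], d[3])
}

## 2D quadratic fit to a 3x3 score neighborhood (grid step `h`); returns the
## stationary-point offset clamped to the cell, or c(0,0) when the surface
## is not locally concave.
quad_peak_2d <- function(s, h = 1) {
  u <- rep(c(-1, 0, 1), 3)
  v <- rep(c(-1, 0, 1), each = 3)
  X <- cbind(1, u, v, u^2, u * v, v^2)
  cf <- qr.coef(qr(X), as.vector(s))
  A <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
  det_ok <- is.finite(det(A)) && det(A) > 0 && A[1, 1] < 0
  if (!det_ok) return(c(0, 0))
  off <- -solve(A, cf[2:3])
  if (any(abs(off) > 1)) return(c(0, 0))
  off * h
}

#' Sub-pixel shift between two cross-sections by 2D cross-correlation
#'
#' Computes the zero-padded cross-correlation of the mean-subtracted images
#' via FFT and returns the sub-pixel peak location: the in-plane shift that
#' best maps \code{img_a} onto \code{img_b}. A perfectly parallel bundle
#' gives (0, 0); a tilted bundle shifts the lattice between sections and the
#' peak moves accordingly. Sub-pixel refinement is a 2D quadratic fit to the
#' 3x3 neighborhood of the integer peak.
#'
#' @param img_a,img_b numeric matrices of identical dimensions, non-constant.
#' @param max_shift optional cap on |dx| and |dz|; the peak is searched only
#'   within the cap (used to reject implausible correlation failures).
#' @return c(dx, dz).
#' @export
correlation_shift <- function(img_a, img_b, max_shift = Inf) {
  if (!all(dim(img_a) == dim(img_b))) stop("images must have the same shape")
  a <- img_a - mean(img_a)
  b <- img_b - mean(img_b)
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate input: constant image, correlation undefined up to offset")
  nr <- nrow(a); nc <- ncol(a)
  pr <- 2L * nr - 1L; pc <- 2L * nc - 1L
  A <- matrix(0, pr, pc); A[1:nr, 1:nc] <- a
  B <- matrix(0, pr, pc); B[1:nr, 1:nc] <- b
  cc <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / (pr * pc)
  ## cc[(s mod pr) + 1, (t mod pc) + 1] = sum a[p] * b[p + (s,t)]
  sx <- c(0:(nr - 1), -(nr - 1):-1)
  sz <- c(0:(nc - 1), -(nc - 1):-1)
  ok <- outer(abs(sx) <= max_shift, abs(sz) <= max_shift)
  cc_ok <- ifelse(ok, cc, -Inf)
  pk <- arrayInd(which.max(cc_ok), dim(cc))
  i0 <- pk[1]; j0 <- pk[2]
  nb <- cc[(i0 + c(-1, 0, 1) - 1) %% pr + 1, (j0 + c(-1, 0, 1) - 1) %% pc + 1]
  off <- quad_peak_2d(nb)
  c(dx = sx[i0] + off[1], dz = sz[j0] + off[2])
}

#' Estimate the bundle axis field
#'
#' Samples cross-section slabs in increments of \code{step} planes along y
#' and computes the peak shift between each consecutive pair by 2D
#' cross-correlation; each shift (dx, dz) over the y increment gives one
#' local direction vector normalize(dx, step, dz), assigned to the midpoint
#' between the pair. Shifts larger than \code{step * tan(30 deg)} (the
#' bundle is only roughly parallel; larger shifts indicate correlation
#' failure) and degenerate sections are dropped with a warning.
#'
#' @param vol a \code{\link{density_volume}}.
#' @param step sampling increment along y (planes).
#' @param thickness slab thickness averaged for each section (planes).
#' @return an \code{\link{axis_field}}.
#' @export
estimate_axis <- function(vol, step = 55L, thickness = 30L) {
  stopifnot(inherits(vol, "density_volume"))
  step <- as.integer(step); thickness <- as.integer(thickness)
  ny <- dim(vol$data)[2]
  if (ny < step + thickness)
    stop("volume too short along y: need at least step + thickness = ",
         step + thickness, " planes, have ", ny)
  ys <- seq(0L, ny - thickness, by = step)
  sections <- lapply(ys, function(y) extract_section(vol, y, thickness))
  cap <- step * tan(pi / 6)
  keep_y <- numeric(0)
  keep_d <- NULL
  for (i in seq_len(length(ys) - 1L)) {
    sh <- tryCatch(correlation_shift(sections[[i]], sections[[i + 1]],
                                     max_shift = cap),
                   error = function(e) NULL)
    if (is.null(sh) || any(abs(sh) > cap)) {
      warning(sprintf("axis sample at y = %g dropped (degenerate or capped correlation)",
                      ys[i] + (thickness - 1) / 2 + step / 2))
      next
    }
    keep_y <- c(keep_y, ys[i] + (thickness - 1) / 2 + step / 2)
    keep_d <- rbind(keep_d, c(sh[1], step, sh[2]))
  }
  if (is.null(keep_d)) stop("no usable axis samples: all correlations degenerate")
  axis_field(keep_y, keep_d)
}

#' Read / write an axis field as CSV
#'
#' Columns \code{y,dx,dy,dz}.
#'
#' @param field an \code{\link{axis_field}}.
#' @param path file path.
#' @return \code{read_axis_field}: an \code{\link{axis_field}};
#'   \code{write_axis_field}: \code{path}, invisibly.
#' @export
write_axis_field <- function(field, path) {
  stopifnot(inherits(field, "axis_field"))
  write.csv(data.frame(y = field$y, dx = field$dirs[, 1],
                       dy = field$dirs[, 2], dz = field$dirs[, 3]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_axis_field
#' @export
read_axis_field <- function(path) {
  df <- read.csv(path)
  axis_field(df$y, cbind(df$dx, df$dy, df$dz))
}
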