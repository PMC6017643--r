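## Matched-filter tracing: each next marker is placed by maximizing the
## inner product between a zero-mean, unit-norm kernel of one or seven 2D
## Gaussians (a filament and its hexagonal neighborhood) and a thickness-
## averaged cross-section slab, over position and - for seven peaks - over
## the hexagon spacing and orientation.

.bt_cache <- new.env(parent = emptyenv())

#' Tracing kernel specification
#'
#' A matched-filter kernel of one central 2D Gaussian or seven (one central
#' plus six at hexagon vertices, mimicking a seven-filament neighborhood).
#'
#' @param n_peaks 1 or 7.
#' @param sigma_voxels per-peak Gaussian width (> 0).
#' @param spacing_voxels center-to-vertex hexagon distance (7 peaks only).
#' @param theta_rad hexagon orientation in [0, pi/3) (7 peaks only; the
#'   hexagon has 60-degree symmetry).
#' @return an object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(n_peaks = 7, sigma_voxels = 2.5,
                        spacing_voxels = NULL, theta_rad = 0) {
  if (!n_peaks %in% c(1, 7)) stop("`n_peaks` must be 1 or 7")
  if (!is.finite(sigma_voxels) || sigma_voxels <= 0)
    stop("`sigma_voxels` must be positive")
  if (n_peaks == 7) {
    if (is.null(spacing_voxels) || !is.finite(spacing_voxels) ||
        spacing_voxels <= 0)
      stop("a seven-peak kernel needs a positive `spacing_voxels`")
    if (!is.finite(theta_rad) || theta_rad < 0 || theta_rad >= pi / 3)
      stop("`theta_rad` must lie in [0, pi/3)")
  } else {
    spacing_voxels <- NULL
    theta_rad <- 0
  }
  structure(list(n_peaks = as.integer(n_peaks),
                 sigma_voxels = as.numeric(sigma_voxels),
                 spacing_voxels = if (is.null(spacing_voxels)) NULL else
                   as.numeric(spacing_voxels),
                 theta_rad = as.numeric(theta_rad)),
            class = "kernel_spec")
}

#' Tracing parameters
#'
#' @param step_candidates downstream step distances along y tried for each
#'   next marker (voxels); strictly increasing positive integers.
#' @param spacing_range allowed hexagon spacing (voxels), the inter-filament
#'   spacing constraint (11--15).
#' @param spacing_step grid step for the spacing search (voxels).
#' @param theta_step_rad grid step for the hexagon orientation search.
#' @param theta_halfwidth_steps when tracing anchors the hexagon orientation
#'   to the bundle lattice (see \code{\link{trace_bundle}}), the per-step
#'   search spans this many grid steps on each side of the anchor. The
#'   hexagonal packing of a bundle has one coherent orientation, so an
#'   unconstrained re-fit at every step lets weakly anchored edge filaments
#'   lock onto spuriously rotated configurations and drift inward.
#' @param search_radius_voxels maximum in-plane marker displacement per 10
#'   voxels advanced; the actual search radius scales linearly with the step
#'   distance.
#' @param max_search_radius_voxels hard cap on the scaled search radius.
#'   Keeping it below half the minimum inter-filament spacing prevents a
#'   trace from hopping onto a neighboring filament over long steps - the
#'   spacing constraint that makes bundle tracing well-posed.
#' @param section_thickness number of planes averaged for each scoring slab.
#' @param sigma_voxels per-peak Gaussian width of the tracing kernel.
#' @return an object of class \code{trace_params}.
#' @export
trace_params <- function(step_candidates = c(10L, 25L, 45L, 70L),
                         spacing_range = c(11, 15), spacing_step = 0.5,
                         theta_step_rad = pi / 36,
                         theta_halfwidth_steps = 0L,
                         search_radius_voxels = 3,
                         max_search_radius_voxels = 3,
                         section_thickness = 30L, sigma_voxels = 2.5) {
  step_candidates <- as.integer(step_candidates)
  if (any(step_candidates <= 0) || any(diff(step_candidates) <= 0))
    stop("`step_candidates` must be positive and strictly increasing")
  if (length(spacing_range) != 2L || spacing_range[1] > spacing_range[2])
    stop("`spacing_range` must be c(low, high) with low <= high")
  if (search_radius_voxels <= 0) stop("`search_radius_voxels` must be positive")
  if (section_thickness < 1) stop("`section_thickness` must be >= 1")
  structure(list(step_candidates = step_candidates,
                 spacing_range = as.numeric(spacing_range),
                 spacing_step = as.numeric(spacing_step),
                 theta_step_rad = as.numeric(theta_step_rad),
                 theta_halfwidth_steps = as.integer(theta_halfwidth_steps),
                 search_radius_voxels = as.numeric(search_radius_voxels),
                 max_search_radius_voxels = as.numeric(max_search_radius_voxels),
                 section_thickness = as.integer(section_thickness),
                 sigma_voxels = as.numeric(sigma_voxels)),
            class = "trace_params")
}

#' Seed set
#'
#' One expert-provided in-plane seed point per filament, all on a common
#' starting cross-section slab.
#'
#' @param points n x 2 matrix of (x, z) positions, 0-based voxel units.
#' @param y0 integer y of the seed cross-section.
#' @param slab_thickness thickness of the seed slab (planes).
#' @param ids optional filament ids (default "1".."n").
#' @return an object of class \code{seed_set}.
#' @export
seed_set <- function(points, y0, slab_thickness = 30L, ids = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have 2 columns (x, z)")
  if (!all(is.finite(points))) stop("seed coordinates must be finite")
  if (nrow(points) > 1) {
    d <- as.matrix(stats::dist(points))
    diag(d) <- Inf
    if (min(d) == 0) stop("duplicate seed points")
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))
  if (length(ids) != nrow(points)) stop("one id per seed point required")
  if (anyDuplicated(ids)) stop("seed ids must be unique")
  structure(list(points = unname(points), y0 = as.integer(y0),
                 slab_thickness = as.integer(slab_thickness),
                 ids = as.character(ids)),
            class = "seed_set")
}

#' Read / write seed points
#'
#' CSV with columns \code{x,z} (optionally \code{filament_id}); the seed
#' cross-section height and slab thickness are carried in comment header
#' lines \code{# y0=...} and \code{# slab_thickness=...}.
#'
#' @param seeds a \code{\link{seed_set}}.
#' @param path file path.
#' @return \code{read_seeds}: a \code{\link{seed_set}}.
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# y0=%d", seeds$y0),
               sprintf("# slab_thickness=%d", seeds$slab_thickness)), con)
  write.csv(data.frame(filament_id = seeds$ids, x = seeds$points[, 1],
                       z = seeds$points[, 2]),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  hdr <- readLines(path, n = 10L)
  getv <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (!length(ln)) stop("seeds file lacks a '# ", key, "=' header line")
    as.integer(sub(".*=", "", ln[1]))
  }
  df <- read.csv(path, comment.char = "#")
  ids <- if ("filament_id" %in% names(df)) as.character(df$filament_id) else NULL
  seed_set(cbind(df$x, df$z), y0 = getv("y0"),
           slab_thickness = getv("slab_thickness"), ids = ids)
}

#' Render a tracing kernel
#'
#' Renders the kernel on a (2R+1) x (2R+1) grid: unit-amplitude Gaussians at
#' the origin and, for seven peaks, at radius \code{spacing_voxels} and
#' angles \code{theta_rad + k * 60} degrees; the image is then
#' mean-subtracted and scaled to unit Euclidean norm, which makes the
#' matched-filter score invariant to constant offsets of the density and
#' commensurable across slabs.
#'
#' @param spec a \code{\link{kernel_spec}}.
#' @param support_radius integer half-width R of the grid; must cover the
#'   outer peaks plus 3 sigma.
#' @return a (2R+1) x (2R+1) matrix with zero mean and unit norm; rows are
#'   x offsets, columns z offsets, center at offset (0, 0).
#' @export
render_kernel <- function(spec, support_radius = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  need <- 3 * spec$sigma_voxels +
    if (spec$n_peaks == 7) spec$spacing_voxels else 0
  if (is.null(support_radius)) support_radius <- ceiling(need)
  support_radius <- as.integer(support_radius)
  if (support_radius < need - 1e-9)
    stop(sprintf("insufficient support: radius %d < required %.3g",
                 support_radius, need))
  off <- -support_radius:support_radius
  if (spec$n_peaks == 7) {
    ang <- spec$theta_rad + (0:5) * pi / 3
    px <- c(0, spec$spacing_voxels * cos(ang))
    pz <- c(0, spec$spacing_voxels * sin(ang))
  } else {
    px <- 0; pz <- 0
  }
  k <- matrix(0, length(off), length(off))
  s2 <- 2 * spec$sigma_voxels^2
  for (p in seq_along(px)) {
    gx <- exp(-(off - px[p])^2 / s2)
    gz <- exp(-(off - pz[p])^2 / s2)
    k <- k + outer(gx, gz)
  }
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Matched-filter score at a continuous position
#'
#' Inner product of the rendered kernel with the section patch centered at
#' the continuous position \code{center}: the kernel grid is shifted to the
#' center and the section is bilinearly resampled at the shifted grid
#' points. Because the kernel has zero mean, the score is invariant to
#' adding a constant to the section.
#'
#' @param section numeric matrix (x in rows, z in columns).
#' @param center c(x, z), continuous 0-based position.
#' @param spec a \code{\link{kernel_spec}}.
#' @param support_radius optional kernel grid half-width.
#' @return scalar score.
#' @export
score_placement <- function(section, center, spec, support_radius = NULL) {
  k <- render_kernel(spec, support_radius)
  s <- cpp_score_single(section, k, center[1], center[2])
  if (is.na(s))
    stop(sprintf("kernel support at (%.3g, %.3g) extends outside the section",
                 center[1], center[2]))
  s
}

## ---- internal search machinery --------------------------------------------

## offsets on a `step`-spaced grid inside a disc, ordered by distance from
## the center (then angle): scan order implements the smallest-displacement
## tie-break.
disc_offsets <- function(radius, step) {
  n <- floor(radius / step)
  g <- expand.grid(du = (-n:n) * step, dv = (-n:n) * step)
  r2 <- g$du^2 + g$dv^2
  keep <- r2 <= radius^2 + 1e-9
  g <- g[keep, ]; r2 <- r2[keep]
  ang <- atan2(g$dv, g$du)
  o <- order(r2, ang)
  as.matrix(g[o, , drop = FALSE])
}

## configuration grid (spacing ascending, then theta ascending) and the
## matching kernel stack at common support, cached by parameters.
kernel_stack <- function(params, n_peaks) {
  key <- paste(n_peaks, params$sigma_voxels,
               paste(params$spacing_range, collapse = ":"),
               params$spacing_step, params$theta_step_rad, sep = "|")
  hit <- .bt_cache[[key]]
  if (!is.null(hit)) return(hit)
  sig <- params$sigma_voxels
  if (n_peaks == 7) {
    spacings <- seq(params$spacing_range[1], params$spacing_range[2],
                    by = params$spacing_step)
    thetas <- seq(0, pi / 3 - 1e-12, by = params$theta_step_rad)
    cfg <- expand.grid(theta = thetas, spacing = spacings)[, c("spacing", "theta")]
    cfg <- cfg[order(cfg$spacing, cfg$theta), ]
    support <- as.integer(ceiling(max(spacings) + 3 * sig))
    stack <- array(0, dim = c(2L * support + 1L, 2L * support + 1L, nrow(cfg)))
    for (i in seq_len(nrow(cfg)))
      stack[, , i] <- render_kernel(kernel_spec(7, sig, cfg$spacing[i],
                                                cfg$theta[i]), support)
  } else {
    cfg <- data.frame(spacing = NA_real_, theta = 0)
    support <- as.integer(ceiling(3 * sig))
    stack <- array(render_kernel(kernel_spec(1, sig), support),
                   dim = c(2L * support + 1L, 2L * support + 1L, 1L))
  }
  out <- list(stack = stack, cfg = cfg, support = support, sigma = sig,
              n_peaks = as.integer(n_peaks))
  .bt_cache[[key]] <- out
  out
}

## pick the best (position, config) from a score matrix respecting the scan
## order (positions pre-sorted by displacement; configs by spacing, theta)
best_cell <- function(scores) {
  if (all(is.na(scores))) return(NULL)
  m <- max(scores, na.rm = TRUE)
  hits <- which(scores == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(pos = hits[1, 1], cfg = hits[1, 2], score = m)
}

## full position x configuration grid scan around `init`
scan_grid <- function(section, stk, init, offsets) {
  pos <- cbind(offsets[, 1] + init[1], offsets[, 2] + init[2])
  scores <- cpp_score_stack(section, stk$stack, pos)
  b <- best_cell(scores)
  if (is.null(b)) return(NULL)
  list(position = pos[b$pos, ], cfg = b$cfg, score = b$score)
}

#' Locally optimize a kernel placement
#'
#' Finds the position (and, for seven peaks, the hexagon spacing and
#' orientation) that maximize the matched-filter score near \code{init}.
#' For search radii up to 3 voxels this is an exhaustive scan: positions on
#' a 0.5-voxel grid inside the disc, spacing over \code{spacing_range} in
#' \code{spacing_step} increments, orientation over [0, 60) degrees in
#' \code{theta_step_rad} increments, followed by one 2D quadratic sub-voxel
#' refinement of the score surface. For larger radii a coarse integer-grid
#' scan with a mid-range reference kernel first localizes the optimum, and
#' the exhaustive scan then runs in a 1.5-voxel disc around it. Ties are
#' broken by smallest displacement from \code{init}, then smallest spacing,
#' then smallest orientation (the deterministic scan order).
#'
#' @param section numeric matrix (x--z slab).
#' @param init c(x, z) starting position.
#' @param params a \code{\link{trace_params}}.
#' @param n_peaks 1 or 7.
#' @param search_radius maximum displacement from \code{init} (voxels).
#' @param theta_center optional orientation anchor (radians): restrict the
#'   seven-peak orientation search to \code{theta_halfwidth_steps} grid
#'   steps around this angle (modulo the hexagon's 60-degree symmetry).
#'   NULL searches the full [0, 60) degree range.
#' @return a list with \code{position} (c(x, z)), \code{spec} (the winning
#'   \code{\link{kernel_spec}}), and \code{score}; or NULL when no placement
#'   keeps the kernel support inside the section.
#' @export
optimize_placement <- function(section, init, params = trace_params(),
                               n_peaks = 7,
                               search_radius = params$search_radius_voxels,
                               theta_center = NULL) {
  stk <- kernel_stack(params, n_peaks)
  if (!is.null(theta_center) && stk$n_peaks == 7) {
    dth <- abs(stk$cfg$theta - theta_center %% (pi / 3))
    dth <- pmin(dth, pi / 3 - dth)
    keep <- which(dth <= params$theta_halfwidth_steps *
                    params$theta_step_rad + 1e-9)
    stk <- list(stack = stk$stack[, , keep, drop = FALSE],
                cfg = stk$cfg[keep, , drop = FALSE], support = stk$support,
                sigma = stk$sigma, n_peaks = stk$n_peaks)
  }
  if (search_radius <= 3 + 1e-9) {
    best <- scan_grid(section, stk, init, disc_offsets(search_radius, 0.5))
  } else {
    ioffs <- disc_offsets(search_radius, 1)
    ipos <- cbind(round(init[1]) + ioffs[, 1], round(init[2]) + ioffs[, 2])
    keep <- (ipos[, 1] - init[1])^2 + (ipos[, 2] - init[2])^2 <=
      search_radius^2 + 1e-9
    ipos <- ipos[keep, , drop = FALSE]
    if (!nrow(ipos)) return(NULL)
    ref_idx <- if (stk$n_peaks == 7)
      which.min(abs(stk$cfg$spacing - mean(params$spacing_range)) +
                  0.01 * pmin(stk$cfg$theta, pi / 3 - stk$cfg$theta)) else 1L
    cs <- cpp_score_integer(section, stk$stack[, , ref_idx],
                            matrix(as.integer(round(ipos)), ncol = 2))
    if (all(is.na(cs))) return(NULL)
    coarse <- ipos[which.max(cs), ]
    offs <- disc_offsets(1.5, 0.5)
    fine_pos <- cbind(coarse[1] + offs[, 1], coarse[2] + offs[, 2])
    keep <- (fine_pos[, 1] - init[1])^2 + (fine_pos[, 2] - init[2])^2 <=
      search_radius^2 + 1e-9
    offs <- offs[keep, , drop = FALSE]
    if (!nrow(offs)) return(NULL)
    best <- scan_grid(section, stk, coarse, offs)
  }
  if (is.null(best)) return(NULL)
  spec <- if (stk$n_peaks == 7)
    kernel_spec(7, stk$sigma, stk$cfg$spacing[best$cfg], stk$cfg$theta[best$cfg])
  else kernel_spec(1, stk$sigma)
  ## Sub-voxel refinement: quadratic fit to the 3x3 integer-grid score
  ## neighborhood around the best position. Integer centers need no
  ## interpolation when scoring, so this surface is free of the mild
  ## grid-locking bias that bilinear resampling imprints on scores at
  ## fractional centers.
  kone <- stk$stack[, , best$cfg, drop = FALSE]
  q <- round(best$position)
  nb <- expand.grid(du = -1:1, dv = -1:1)
  nbpos <- cbind(q[1] + nb$du, q[2] + nb$dv)
  ns <- cpp_score_stack(section, kone, nbpos)[, 1]
  if (!any(is.na(ns))) {
    off <- quad_peak_2d(matrix(ns, 3, 3), h = 1)
    refined <- q + off
    if (any(off != 0) &&
        sum((refined - init)^2) <= search_radius^2 + 1e-9 &&
        any(refined != best$position)) {
      rs <- cpp_score_stack(section, kone, rbind(refined))[1, 1]
      if (!is.na(rs)) {
        best$position <- refined
        best$score <- max(rs, best$score)
      }
    }
  }
  list(position = unname(best$position), spec = spec, score = best$score)
}

## thickness-averaged slab centered at integer y, padded with the section
## mean so that edge-filament supports stay scoreable; cached per y.
padded_section <- function(vol, y_center, thickness, pad, cache = NULL) {
  key <- sprintf("s%d_%d", y_center, thickness)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  ny <- dim(vol$data)[2]
  ystart <- y_center - floor(thickness / 2)
  sec <- extract_section(vol, ystart, thickness)
  big <- matrix(mean(sec), nrow(sec) + 2 * pad, ncol(sec) + 2 * pad)
  big[pad + seq_len(nrow(sec)), pad + seq_len(ncol(sec))] <- sec
  out <- list(mat = big, pad = pad)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

## is the centered slab window for y_center fully inside the volume?
section_fits <- function(ny, y_center, thickness) {
  ystart <- y_center - floor(thickness / 2)
  ystart >= 0 && (ystart + thickness) <= ny && y_center >= 0 && y_center <= ny - 1
}

#' Place the next marker along a filament
#'
#' Tries the four downstream step distances (default 10, 25, 45 and 70
#' voxels): for each candidate, forms the thickness-averaged slab centered
#' at the candidate height, predicts the in-plane position by advancing the
#' current marker along the local bundle direction, and locally optimizes
#' the kernel placement with a search radius that scales linearly with the
#' step distance. The candidate with the highest matched-filter score
#' becomes the next marker (ties go to the smallest step). Returns NULL
#' when no candidate slab fits inside the volume (normal termination).
#'
#' @param vol a \code{\link{density_volume}}.
#' @param current c(x, y, z) current marker.
#' @param field an \code{\link{axis_field}}.
#' @param params a \code{\link{trace_params}}.
#' @param n_peaks 1 or 7.
#' @param direction +1 to advance in +y, -1 in -y.
#' @param cache optional environment for slab caching across calls.
#' @param theta_center optional orientation anchor passed to
#'   \code{\link{optimize_placement}}.
#' @return list(marker = c(x, y, z), score, spec) or NULL.
#' @export
next_marker <- function(vol, current, field, params = trace_params(),
                        n_peaks = 7, direction = 1L, cache = NULL,
                        theta_center = NULL) {
  ny <- dim(vol$data)[2]
  stk <- kernel_stack(params, n_peaks)
  max_radius <- params$search_radius_voxels * max(params$step_candidates) / 10
  pad <- as.integer(ceiling(stk$support + max_radius + 2))
  best <- NULL
  for (d in params$step_candidates) {
    y_next <- current[2] + direction * d
    if (!section_fits(ny, y_next, params$section_thickness)) next
    sec <- padded_section(vol, y_next, params$section_thickness, pad, cache)
    v <- axis_at(field, (current[2] + y_next) / 2)
    adv <- (y_next - current[2]) / v[2]
    pred <- c(current[1] + adv * v[1], current[3] + adv * v[3])
    radius <- min(params$search_radius_voxels * d / 10,
                  params$max_search_radius_voxels)
    opt <- optimize_placement(sec$mat, pred + sec$pad, params, n_peaks,
                              search_radius = radius,
                              theta_center = theta_center)
    if (is.null(opt)) next
    if (is.null(best) || opt$score > best$score)
      best <- list(marker = c(opt$position[1] - sec$pad, y_next,
                              opt$position[2] - sec$pad),
                   score = opt$score, spec = opt$spec)
  }
  best
}

#' Trace a filament bundle from seed points
#'
#' The central fitting routine: starting from one seed point per filament
#' on a common cross-section, repeatedly places the next marker by locally
#' optimized one-peak or seven-peak Gaussian matched filtering on downstream
#' slabs, following the bundle axis field. Each seed is first refined
#' in-plane on the seed slab; tracing then proceeds in +y and, when the
#' seed section is not at the volume edge, also in -y. Tracing is fully
#' deterministic.
#'
#' @param vol a \code{\link{density_volume}} (possibly pre-filtered with
#'   \code{\link{gaussian_filter}} and/or \code{\link{longitudinal_average}}).
#' @param seeds a \code{\link{seed_set}}.
#' @param field an \code{\link{axis_field}}; defaults to estimating it from
#'   \code{vol}.
#' @param params a \code{\link{trace_params}}.
#' @param n_peaks 1 or 7 (7 exploits the hexagonal neighborhood and is more
#'   robust to noise).
#' @return a \code{\link{bundle_model}} with one trace per seed, markers
#'   sorted by y, and provenance recording the parameters.
#' @export
trace_bundle <- function(vol, seeds, field = NULL, params = trace_params(),
                         n_peaks = 7) {
  stopifnot(inherits(vol, "density_volume"), inherits(seeds, "seed_set"))
  d <- dim(vol$data)
  if (is.null(field)) field <- estimate_axis(vol)
  if (!length(seeds$ids))
    return(bundle_model(list(), provenance = "trace_bundle: empty seed set"))
  for (i in seq_along(seeds$ids)) {
    p <- seeds$points[i, ]
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[3] - 1 ||
        seeds$y0 < 0 || seeds$y0 > d[2] - 1)
      stop(sprintf("seed %d (id %s) lies outside the volume", i, seeds$ids[i]))
  }
  if (nrow(seeds$points) > 1) {
    dd <- as.matrix(stats::dist(seeds$points)); diag(dd) <- Inf
    if (min(dd) < 2 * params$sigma_voxels)
      warning("some seed points are closer than 2 * sigma; traces may merge")
  }
  stk <- kernel_stack(params, n_peaks)
  max_radius <- params$search_radius_voxels * max(params$step_candidates) / 10
  pad <- as.integer(ceiling(stk$support + max_radius + 2))
  cache <- new.env(parent = emptyenv())
  ## seed slab: centered at y0, clamped to the volume
  th0 <- min(seeds$slab_thickness, d[2])
  y0c <- min(max(seeds$y0, floor(th0 / 2)), d[2] - 1 - (th0 - floor(th0 / 2) - 1))
  sec0 <- padded_section(vol, y0c, th0, pad, cache)
  ## Anchor the hexagon orientation: the bundle lattice has one coherent
  ## orientation, so estimate it once on the seed slab at the most interior
  ## seed (fullest neighborhood) with the unconstrained scan; per-step
  ## searches then stay within theta_halfwidth_steps of it.
  theta_hat <- NULL
  if (n_peaks == 7 && nrow(seeds$points) > 0) {
    ctr <- colMeans(seeds$points)
    i0 <- which.min((seeds$points[, 1] - ctr[1])^2 +
                      (seeds$points[, 2] - ctr[2])^2)
    opt0 <- optimize_placement(sec0$mat, seeds$points[i0, ] + sec0$pad,
                               params, 7,
                               search_radius = params$search_radius_voxels)
    if (!is.null(opt0)) theta_hat <- opt0$spec$theta_rad
  }
  traces <- list()
  for (i in seq_along(seeds$ids)) {
    opt <- optimize_placement(sec0$mat, seeds$points[i, ] + sec0$pad, params,
                              n_peaks,
                              search_radius = params$search_radius_voxels,
                              theta_center = theta_hat)
    m0 <- if (is.null(opt)) c(seeds$points[i, 1], seeds$y0, seeds$points[i, 2])
          else c(opt$position[1] - sec0$pad, seeds$y0, opt$position[2] - sec0$pad)
    markers <- rbind(m0)
    for (dir in c(1L, -1L)) {
      cur <- m0
      repeat {
        nm <- next_marker(vol, cur, field, params, n_peaks, direction = dir,
                          cache = cache, theta_center = theta_hat)
        if (is.null(nm)) break
        markers <- rbind(markers, nm$marker)
        cur <- nm$marker
      }
    }
    markers <- markers[order(markers[, 2]), , drop = FALSE]
    if (nrow(markers) < 2L) {
      warning("filament ", seeds$ids[i],
              ": volume too short to place a second marker; trace dropped")
      next
    }
    traces[[length(traces) + 1L]] <- filament_trace(markers, id = seeds$ids[i])
  }
  bundle_model(traces, provenance = c(
    sprintf("trace_bundle: n_peaks = %d, steps = %s, spacing = [%g, %g], sigma = %g, thickness = %d",
            n_peaks, paste(params$step_candidates, collapse = ","),
            params$spacing_range[1], params$spacing_range[2],
            params$sigma_voxels, params$section_thickness),
    sprintf("bundletrac %s", as.character(packageVersion("bundletrac"))),
    vol$provenance))
}
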