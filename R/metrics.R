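## Cross-distance: for each marker of a reference filament, the distance to
## the nearest point of the finely interpolated comparison filament; the
## per-filament value D_f is the mean over the reference markers in the
## common y-range, so purely longitudinal offset does not contribute.

## resample a polyline at uniform arc-length steps
interp_polyline <- function(markers, step = 0.1) {
  seg <- sqrt(rowSums(diff(markers)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t <- unique(c(seq(0, total, by = step), total))
  cbind(approx(s, markers[, 1], xout = t)$y,
        approx(s, markers[, 2], xout = t)$y,
        approx(s, markers[, 3], xout = t)$y)
}

#' Cross-distance between two filament traces
#'
#' The test trace is treated as finely interpolated: for each reference
#' marker P_i inside the y-range common to both traces, Q_i is the nearest
#' point of the linearly interpolated test trace in 3D Euclidean distance
#' (computed by exact projection onto the trace segments, i.e. the limit of
#' interpolation at arbitrarily fine arc steps), and D_f is the mean of
#' |P_i - Q_i| over those n markers. Reference markers outside the overlap
#' are excluded, so the metric does not penalize a purely longitudinal
#' length mismatch.
#'
#' @param ref reference \code{\link{filament_trace}} (e.g. ground truth).
#' @param test comparison trace.
#' @param step retained for compatibility with sampled-interpolation
#'   workflows; the exact projection is below any sampling step, so the
#'   result does not depend on it.
#' @param planar if TRUE, measure instead the in-plane (x--z) distance to
#'   the test trace interpolated at each reference marker's own y (a
#'   per-section variant for sensitivity analysis).
#' @return list(D_f, n): the mean distance and the number of reference
#'   markers used.
#' @export
cross_distance <- function(ref, test, step = 0.1, planar = FALSE) {
  stopifnot(inherits(ref, "filament_trace"), inherits(test, "filament_trace"))
  ylo <- max(min(ref$markers[, 2]), min(test$markers[, 2]))
  yhi <- min(max(ref$markers[, 2]), max(test$markers[, 2]))
  keep <- ref$markers[, 2] >= ylo - 1e-9 & ref$markers[, 2] <= yhi + 1e-9
  if (yhi < ylo || sum(keep) < 2)
    stop("traces must overlap in y over at least 2 reference markers (ids ",
         ref$id, " / ", test$id, ")")
  P <- ref$markers[keep, , drop = FALSE]
  if (planar) {
    tx <- approx(test$markers[, 2], test$markers[, 1], xout = P[, 2])$y
    tz <- approx(test$markers[, 2], test$markers[, 3], xout = P[, 2])$y
    d <- sqrt((P[, 1] - tx)^2 + (P[, 3] - tz)^2)
  } else {
    ## exact projection onto the polyline segments: the limit of sampling
    ## the interpolated trace at arbitrarily fine arc steps
    d <- cpp_polyline_dist(P, test$markers)
  }
  list(D_f = mean(d), n = sum(keep))
}

#' Evaluate a traced bundle against a reference model
#'
#' Computes the per-filament cross-distance for every id present in the
#' reference (matching by filament id), the unweighted mean over filaments,
#' and how many filaments fall within the acceptance threshold.
#'
#' @param ref reference \code{\link{bundle_model}}.
#' @param test comparison \code{\link{bundle_model}} with matching ids.
#' @param threshold per-filament D_f acceptance threshold (voxels).
#' @param step interpolation arc step passed to \code{\link{cross_distance}}.
#' @return an object of class \code{cross_distance_report}: list with
#'   \code{per_filament} (data.frame id, D_f, n), \code{mean_Df},
#'   \code{threshold}, \code{n_within}, \code{fraction_within}.
#' @export
evaluate_model <- function(ref, test, threshold = 3, step = 0.1) {
  stopifnot(inherits(ref, "bundle_model"), inherits(test, "bundle_model"))
  rid <- names(ref$traces); tid <- names(test$traces)
  miss <- setdiff(rid, tid)
  if (length(miss))
    stop("filament ids missing from the test model: ",
         paste(miss, collapse = ", "))
  per <- lapply(rid, function(id)
    cross_distance(ref$traces[[id]], test$traces[[id]], step = step))
  df <- data.frame(id = rid,
                   D_f = vapply(per, `[[`, 0, "D_f"),
                   n = vapply(per, `[[`, 0L, "n"))
  structure(list(per_filament = df,
                 mean_Df = mean(df$D_f),
                 threshold = threshold,
                 n_within = sum(df$D_f <= threshold),
                 fraction_within = mean(df$D_f <= threshold)),
            class = "cross_distance_report")
}

#' @export
print.cross_distance_report <- function(x, ...) {
  cat(sprintf("<cross_distance_report> %d filaments\n", nrow(x$per_filament)))
  cat(sprintf("  mean D_f: %.4g voxels (per-filament range %.4g-%.4g)\n",
              x$mean_Df, min(x$per_filament$D_f), max(x$per_filament$D_f)))
  cat(sprintf("  within %g voxels: %d / %d (%.1f%%)\n", x$threshold,
              x$n_within, nrow(x$per_filament), 100 * x$fraction_within))
  invisible(x)
}

#' Relative error improvement
#'
#' Percentage reduction of an error relative to a baseline:
#' (err_base - err_new) / err_base * 100.
#'
#' @param err_base baseline error (> 0).
#' @param err_new comparison error.
#' @return percentage.
#' @examples
#' improvement(2.420, 1.300)  # ~46.28
#' @export
improvement <- function(err_base, err_new) {
  if (!is.finite(err_base) || err_base <= 0)
    stop("`err_base` must be a positive finite scalar")
  (err_base - err_new) / err_base * 100
}
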