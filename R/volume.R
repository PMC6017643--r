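#' Density volume
#'
#' A 3D scalar density grid with isotropic voxel size. Internally the array
#' is indexed (x, y, z) with the bundle axis approximately along +y, so
#' cross-sections of the bundle are x--z planes. Voxel coordinates used
#' throughout the package are 0-based and continuous, with voxel centers at
#' integer coordinates (a marker at x = 3.5 lies midway between the voxel
#' centers 3 and 4).
#'
#' @param data numeric 3D array, dimensions (nx, ny, nz), all values finite.
#' @param voxel_size_nm positive scalar, nm per voxel (isotropic).
#' @param origin_nm numeric 3-vector, position of voxel (0,0,0) in nm.
#' @param provenance optional character notes on how the volume was made.
#' @return an object of class \code{density_volume}: a list with elements
#'   \code{data}, \code{voxel_size_nm}, \code{origin_nm}, \code{provenance}.
#' @examples
#' vol <- density_volume(array(0, c(4, 6, 4)), voxel_size_nm = 0.947)
#' dim(vol$data)
#' @export
density_volume <- function(data, voxel_size_nm = 1, origin_nm = c(0, 0, 0),
                           provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume values must all be finite")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a positive finite scalar")
  if (length(origin_nm) != 3L || !all(is.finite(origin_nm)))
    stop("`origin_nm` must be a finite 3-vector")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 origin_nm = as.numeric(origin_nm),
                 provenance = as.character(provenance)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  if (length(x$provenance)) cat("  provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

## ---- MRC2014 I/O -----------------------------------------------------------
## The MRC2014 header is 1024 bytes of 4-byte words. We read/write mode 2
## (float32), little-endian, with MAPC/MAPR/MAPS recording the axis order on
## disk; data are permuted so the in-memory array is always (x, y, z).

#' Read an MRC2014 density volume
#'
#' Reads a mode-2 (float32) MRC2014 file. On-disk axis order (MAPC, MAPR,
#' MAPS) is mapped so that the returned array is indexed (x, y, z)
#' crystallographic axes; the mapping applied is recorded in the volume's
#' provenance. Pixel spacing is converted from Angstrom to nm.
#'
#' @param path path to an MRC2014 file.
#' @param invert if \code{TRUE}, negate the map (for maps where filaments are
#'   dark); the tracing algorithm assumes higher value = more filament mass.
#' @return a \code{\link{density_volume}}.
#' @export
read_volume <- function(path, invert = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 1024)
    stop("malformed MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  int_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "integer",
                                size = 4, endian = "little")
  flt_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "numeric",
                                size = 4, endian = "little")
  nc <- int_at(1); nr <- int_at(2); ns <- int_at(3)
  mode <- int_at(4)
  if (any(c(nc, nr, ns) < 1) || any(c(nc, nr, ns) > 1e5))
    stop("malformed MRC header: implausible dimensions NX/NY/NZ = ",
         nc, "/", nr, "/", ns)
  if (mode != 2)
    stop("unsupported MRC MODE ", mode, " (only mode 2, float32, is supported)")
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  mapc <- int_at(17); mapr <- int_at(18); maps <- int_at(19)
  if (!setequal(c(mapc, mapr, maps), 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS must be a permutation of 1:3, got ",
         mapc, "/", mapr, "/", maps)
  nsymbt <- int_at(24)
  if (nsymbt < 0) stop("malformed MRC header: negative NSYMBT")
  origin <- c(flt_at(50), flt_at(51), flt_at(52))
  n_expected <- as.double(nc) * nr * ns
  if (fsize < 1024 + nsymbt + 4 * n_expected)
    stop("truncated MRC file: header promises ", n_expected,
         " float32 voxels after NSYMBT = ", nsymbt,
         " extended-header bytes, but the file is too short")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  vals <- readBin(con, "numeric", n = n_expected, size = 4, endian = "little")
  if (length(vals) != n_expected) stop("truncated MRC file data section")
  arr <- array(vals, dim = c(nc, nr, ns))
  ## permute so axis 1 = crystallographic X, 2 = Y, 3 = Z
  disk_axes <- c(mapc, mapr, maps)        # crystallographic axis of each disk dim
  perm <- match(1:3, disk_axes)
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  m_per <- c(mx, my, mz)
  m_per[m_per == 0] <- dim(arr)[m_per == 0]
  vox_A <- cella / m_per
  if (any(vox_A <= 0)) vox_A <- c(10, 10, 10)  # unset cell: fall back to 1 nm
  if (diff(range(vox_A)) > 1e-3 * mean(vox_A))
    warning("anisotropic pixel spacing in header; using the X spacing")
  vol <- density_volume(arr, voxel_size_nm = vox_A[1] / 10,
                        origin_nm = origin / 10,
                        provenance = sprintf("read_volume('%s'), disk axes (%d,%d,%d)",
                                             path, mapc, mapr, maps))
  if (invert) vol$data <- -vol$data
  vol
}

#' Write an MRC2014 density volume
#'
#' Writes mode 2 (float32), little-endian, MAPC/MAPR/MAPS = 1/2/3. Data are
#' rounded to float32; a volume previously read with \code{\link{read_volume}}
#' round-trips bit-exactly. Header min/max/mean/rms statistics are recomputed
#' from the grid.
#'
#' @param vol a \code{\link{density_volume}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$data)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                              # words 1-3   NX NY NZ
  wi(2)                              # word  4     MODE float32
  wi(c(0, 0, 0))                     # words 5-7   NXSTART..
  wi(d)                              # words 8-10  MX MY MZ
  wf(d * vol$voxel_size_nm * 10)     # words 11-13 CELLA (Angstrom)
  wf(c(90, 90, 90))                  # words 14-16 CELLB
  wi(c(1, 2, 3))                     # words 17-19 MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # words 20-22
  wi(1)                              # word  23    ISPG (volume)
  wi(0)                              # word  24    NSYMBT
  wi(c(0L, 0L))                      # words 25-26 EXTRA
  writeBin(raw(4), con)              # word  27    EXTTYP (none)
  wi(20140)                          # word  28    NVERSION
  wi(rep(0L, 21))                    # words 29-49 EXTRA
  wf(vol$origin_nm * 10)             # words 50-52 ORIGIN (Angstrom)
  writeBin(charToRaw("MAP "), con)   # word  53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # word 54 MACHST (LE)
  wf(sd(vol$data))                   # word  55    RMS
  wi(0)                              # word  56    NLABL
  writeBin(raw(800), con)            # words 57-256 labels
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

## ---- Filament traces and bundle models ------------------------------------

#' Filament trace
#'
#' An ordered run of continuous 3D markers (in 0-based voxel coordinates)
#' along one filament: the "balls" of a ball-and-stick model. Marker
#' y-coordinates must be strictly monotonic, since traces advance along the
#' bundle axis.
#'
#' @param markers numeric matrix, n >= 2 rows, columns (x, y, z).
#' @param id filament label (coerced to character).
#' @return an object of class \code{filament_trace}.
#' @export
filament_trace <- function(markers, id = "1") {
  markers <- as.matrix(markers)
  if (ncol(markers) != 3L) stop("markers must have 3 columns (x, y, z)")
  if (nrow(markers) < 2L) stop("a filament trace needs at least 2 markers")
  if (!all(is.finite(markers))) stop("marker coordinates must be finite")
  dy <- diff(markers[, 2])
  if (!(all(dy > 0) || all(dy < 0)))
    stop("marker y-coordinates must be strictly monotonic (filament id ",
         id, ")")
  if (all(dy < 0)) markers <- markers[nrow(markers):1, , drop = FALSE]
  dimnames(markers) <- list(NULL, c("x", "y", "z"))
  structure(list(markers = markers, id = as.character(id)[1]),
            class = "filament_trace")
}

#' Bundle model
#'
#' A set of filament traces (a ball-and-stick model of the whole bundle)
#' plus free-text provenance recording how it was made.
#'
#' @param traces list of \code{\link{filament_trace}} objects with unique ids.
#' @param provenance character vector of free-text metadata.
#' @return an object of class \code{bundle_model}.
#' @seealso \code{\link{trace_bundle}}, \code{\link{evaluate_model}}
#' @export
bundle_model <- function(traces = list(), provenance = character()) {
  if (!all(vapply(traces, inherits, TRUE, "filament_trace")))
    stop("all elements of `traces` must be filament_trace objects")
  ids <- vapply(traces, function(t) t$id, "")
  if (anyDuplicated(ids))
    stop("trace ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(traces) <- ids
  structure(list(traces = traces, provenance = as.character(provenance)),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  n <- length(x$traces)
  cat(sprintf("<bundle_model> %d filament%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    nm <- vapply(x$traces, function(t) nrow(t$markers), 0L)
    yr <- range(unlist(lapply(x$traces, function(t) range(t$markers[, 2]))))
    cat(sprintf("  markers per filament: %d-%d (median %g); y range [%g, %g]\n",
                min(nm), max(nm), stats::median(nm), yr[1], yr[2]))
  }
  for (p in utils::head(x$provenance, 3)) cat("  ", p, "\n", sep = "")
  invisible(x)
}

#' @export
summary.bundle_model <- function(object, ...) {
  df <- as.data.frame(object)
  nm <- table(df$filament_id)
  out <- list(n_filaments = length(object$traces),
              n_markers = nrow(df),
              markers_per_filament = as.vector(nm),
              y_range = if (nrow(df)) range(df$y) else c(NA, NA),
              provenance = object$provenance)
  class(out) <- "summary.bundle_model"
  out
}

#' @export
print.summary.bundle_model <- function(x, ...) {
  cat(sprintf("Bundle model: %d filaments, %d markers, y in [%g, %g]\n",
              x$n_filaments, x$n_markers, x$y_range[1], x$y_range[2]))
  if (length(x$markers_per_filament))
    cat(sprintf("Markers per filament: min %d / median %g / max %d\n",
                min(x$markers_per_filament),
                stats::median(x$markers_per_filament),
                max(x$markers_per_filament)))
  invisible(x)
}

#' @export
as.data.frame.bundle_model <- function(x, ...) {
  if (!length(x$traces))
    return(data.frame(filament_id = character(), x = numeric(),
                      y = numeric(), z = numeric()))
  do.call(rbind, lapply(x$traces, function(t)
    data.frame(filament_id = t$id, x = t$markers[, 1], y = t$markers[, 2],
               z = t$markers[, 3], row.names = NULL)))
}

#' Plot a bundle model
#'
#' Draws the filament centerlines projected on the x--y plane (left) and the
#' marker positions on the first cross-section (right).
#'
#' @param x a \code{\link{bundle_model}}.
#' @param ... passed to \code{matplot}.
#' @export
plot.bundle_model <- function(x, ...) {
  if (!length(x$traces)) { plot.new(); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  xr <- range(unlist(lapply(x$traces, function(t) range(t$markers[, 1]))))
  yr <- range(unlist(lapply(x$traces, function(t) range(t$markers[, 2]))))
  plot(NA, xlim = yr, ylim = xr, xlab = "y (voxels)", ylab = "x (voxels)",
       main = "side view", ...)
  for (t in x$traces) graphics::lines(t$markers[, 2], t$markers[, 1],
                                      col = "#00000060")
  first <- t(vapply(x$traces, function(t) t$markers[1, c(1, 3)], numeric(2)))
  plot(first[, 2], first[, 1], asp = 1, xlab = "z (voxels)",
       ylab = "x (voxels)", main = "first cross-section", pch = 16)
  invisible(x)
}

## ---- model file formats ----------------------------------------------------

validate_model_df <- function(df) {
  need <- c("filament_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("model table must have columns ", paste(need, collapse = ", "))
  traces <- lapply(split(df, factor(df$filament_id,
                                    levels = unique(df$filament_id))),
                   function(g) filament_trace(as.matrix(g[, c("x", "y", "z")]),
                                              id = g$filament_id[1]))
  bundle_model(unname(traces))
}

#' Read / write filament models
#'
#' Two dialects are supported, chosen by file extension: CSV with columns
#' \code{filament_id,x,y,z} (0-based voxel units, one row per marker, markers
#' in order along each filament), and Chimera CMM marker-set XML (one
#' \code{marker_set} per filament, markers linked in order). Round-tripping
#' preserves coordinates to at least 6 significant digits and per-filament
#' marker order. Markers whose y-coordinates are not strictly monotonic
#' within a filament raise a validation error naming the filament.
#'
#' @param path file path; \code{.cmm} selects the Chimera dialect, anything
#'   else the CSV dialect.
#' @param model a \code{\link{bundle_model}} (for writing).
#' @return \code{read_model}: a \code{\link{bundle_model}};
#'   \code{write_model}: \code{path}, invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (grepl("\\.cmm$", path, ignore.case = TRUE)) {
    doc <- xml2::read_xml(path)
    sets <- xml2::xml_find_all(doc, "//marker_set")
    if (!length(sets)) stop("no <marker_set> elements in ", path)
    traces <- lapply(sets, function(ms) {
      mk <- xml2::xml_find_all(ms, "./marker")
      m <- cbind(x = as.numeric(xml2::xml_attr(mk, "x")),
                 y = as.numeric(xml2::xml_attr(mk, "y")),
                 z = as.numeric(xml2::xml_attr(mk, "z")))
      filament_trace(m, id = xml2::xml_attr(ms, "name"))
    })
    bundle_model(traces, provenance = sprintf("read_model('%s') [cmm]", path))
  } else {
    df <- read.csv(path, comment.char = "#")
    m <- validate_model_df(df)
    m$provenance <- sprintf("read_model('%s') [csv]", path)
    m
  }
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bundle_model"))
  if (grepl("\\.cmm$", path, ignore.case = TRUE)) {
    doc <- xml2::xml_new_root("marker_sets")
    for (t in model$traces) {
      ms <- xml2::xml_add_child(doc, "marker_set", name = t$id)
      n <- nrow(t$markers)
      for (i in seq_len(n))
        xml2::xml_add_child(ms, "marker", id = as.character(i),
                            x = sprintf("%.8g", t$markers[i, 1]),
                            y = sprintf("%.8g", t$markers[i, 2]),
                            z = sprintf("%.8g", t$markers[i, 3]),
                            radius = "1")
      for (i in seq_len(n - 1))
        xml2::xml_add_child(ms, "link", id1 = as.character(i),
                            id2 = as.character(i + 1))
    }
    xml2::write_xml(doc, path)
  } else {
    df <- as.data.frame(model)
    df$x <- signif(df$x, 9); df$y <- signif(df$y, 9); df$z <- signif(df$z, 9)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
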