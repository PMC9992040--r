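#' Cine phase-contrast series
#'
#' Container for a velocity-encoded 2D cine acquisition: a magnitude and a
#' phase image stack over the cardiac cycle, plus the acquisition metadata
#' needed to interpret them (pixel spacing, velocity-encoding limit,
#' optionally heart rate). Phase is stored in radians in `[-pi, pi)` and maps
#' to through-plane velocity via [phase_to_velocity()].
#'
#' @param magnitude Numeric array `[row, col, cardiac_phase]`, non-negative
#'   signal magnitude.
#' @param phase Numeric array of the same shape, radians. Values outside
#'   `[-pi, pi)` are wrapped into range with a warning.
#' @param pixel_spacing_mm Length-2 numeric, (row, col) spacing in mm.
#' @param venc_cm_s Velocity-encoding limit in cm/s: the velocity mapped to a
#'   phase of pi.
#' @param heart_rate_bpm Optional heart rate in beats per minute.
#' @param grid_kind `"acquired"` or `"reconstructed"` (after k-space
#'   zero-filling).
#'
#' @return An object of class `cine_pc_series`: a list with elements
#'   `magnitude`, `phase`, `pixel_spacing_mm`, `venc_cm_s`, `heart_rate_bpm`,
#'   `n_cardiac_phases`, `grid_kind`.
#' @export
cine_pc_series <- function(magnitude, phase, pixel_spacing_mm, venc_cm_s,
                           heart_rate_bpm = NA_real_,
                           grid_kind = c("acquired", "reconstructed")) {
  grid_kind <- match.arg(grid_kind)
  magnitude <- as_cine_stack(magnitude, "magnitude")
  phase <- as_cine_stack(phase, "phase")
  if (!identical(dim(magnitude), dim(phase))) {
    stop("format error: `magnitude` and `phase` must have identical shapes (",
         paste(dim(magnitude), collapse = "x"), " vs ",
         paste(dim(phase), collapse = "x"), ")", call. = FALSE)
  }
  if (any(magnitude < 0)) {
    stop("format error: `magnitude` must be non-negative everywhere", call. = FALSE)
  }
  n_phases <- dim(magnitude)[3L]
  if (n_phases < 2 || n_phases > 64) {
    stop("format error: `n_cardiac_phases` must lie in [2, 64], got ", n_phases,
         call. = FALSE)
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0)) {
    stop("format error: `pixel_spacing_mm` must be two positive numbers", call. = FALSE)
  }
  if (is.null(venc_cm_s) || length(venc_cm_s) != 1L || is.na(venc_cm_s) ||
      venc_cm_s <= 0) {
    stop("configuration error: `venc_cm_s` must be a single positive number",
         call. = FALSE)
  }
  if (any(phase < -pi | phase >= pi)) {
    warning("phase values outside [-pi, pi) wrapped into range")
    phase <- wrap_phase(phase)
  }
  structure(
    list(
      magnitude = magnitude,
      phase = phase,
      pixel_spacing_mm = pixel_spacing_mm,
      venc_cm_s = as.numeric(venc_cm_s),
      heart_rate_bpm = as.numeric(heart_rate_bpm),
      n_cardiac_phases = as.integer(n_phases),
      grid_kind = grid_kind
    ),
    class = "cine_pc_series"
  )
}

as_cine_stack <- function(x, what) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop("format error: `", what, "` must be a numeric [row, col, phase] array",
         call. = FALSE)
  }
  d <- dim(x)
  x <- as.double(x)        # canonical plain array, no foreign attributes
  dim(x) <- d
  x
}

#' Wrap phase values into `[-pi, pi)`
#' @param phi Numeric array of phase values (radians).
#' @return Array of the same shape with all values in `[-pi, pi)`.
#' @export
wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' @export
print.cine_pc_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat("<cine_pc_series> ", d[1], "x", d[2], " pixels, ", d[3],
      " cardiac phases (", x$grid_kind, " grid)\n", sep = "")
  cat("  pixel spacing: ", paste(signif(x$pixel_spacing_mm, 4), collapse = " x "),
      " mm, venc: ", x$venc_cm_s, " cm/s", sep = "")
  if (is.finite(x$heart_rate_bpm)) cat(", heart rate: ", x$heart_rate_bpm, " bpm", sep = "")
  cat("\n")
  invisible(x)
}

#' Region-of-interest mask on the image grid
#'
#' @param mask Logical matrix with the same row/col shape as the series it
#'   accompanies. Must contain at least one `TRUE` pixel for analysis.
#' @param label Short text label for the region.
#' @return An object of class `roi_mask` (a logical matrix with a `label`
#'   attribute).
#' @export
roi_mask <- function(mask, label = "ROI") {
  if (is.array(mask) && length(dim(mask)) == 2L) mask <- as.matrix(mask)
  if (!is.matrix(mask)) stop("format error: `mask` must be a matrix", call. = FALSE)
  mode(mask) <- "logical"
  if (anyNA(mask)) stop("format error: `mask` must not contain NA", call. = FALSE)
  structure(mask, label = as.character(label), class = c("roi_mask", "matrix", "array"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", attr(x, "label"), "': ", nrow(x), "x", ncol(x),
      ", ", sum(x), " pixels set\n", sep = "")
  invisible(x)
}

check_roi <- function(series, roi) {
  if (!inherits(roi, "roi_mask")) roi <- roi_mask(roi)
  d <- dim(series$magnitude)
  if (!identical(dim(roi)[1:2], d[1:2])) {
    stop("format error: ROI shape (", paste(dim(roi), collapse = "x"),
         ") does not match series grid (", d[1], "x", d[2], ")", call. = FALSE)
  }
  if (!any(roi)) stop("ROI is empty: at least one pixel required", call. = FALSE)
  roi
}

#' Convert phase images to velocity maps
#'
#' Standard phase-contrast scaling: a phase of pi corresponds to the
#' velocity-encoding limit, so `v = venc * phase / pi` elementwise. Positive
#' velocity is through-plane flow along the slice normal.
#'
#' @param series A [cine_pc_series()].
#' @return Numeric array `[row, col, phase]` of velocities in cm/s, bounded by
#'   `venc` in absolute value.
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_pc_series"))
  series$venc_cm_s * series$phase / pi
}

#' Physical pixel-center positions (mm)
#'
#' Pixel `(r, c)` (1-based) is centered at
#' `((r - 0.5) * spacing_row, (c - 0.5) * spacing_col)` mm.
#'
#' @param series A [cine_pc_series()].
#' @return List with numeric vectors `y_mm` (row centers) and `x_mm`
#'   (col centers).
#' @export
pixel_centers_mm <- function(series) {
  d <- dim(series$magnitude)
  list(
    y_mm = (seq_len(d[1]) - 0.5) * series$pixel_spacing_mm[1],
    x_mm = (seq_len(d[2]) - 0.5) * series$pixel_spacing_mm[2]
  )
}

# Symmetric k-space zero-padding of one complex frame.
# Frequencies of an N-point DFT are reassigned onto an M-point grid (M >= N)
# keeping the DC bin at [1,1]; inverse transform is scaled so image
# intensities (and the spatial mean / DC level) are preserved.
zero_fill_frame <- function(frame, nr2, nc2) {
  nr <- nrow(frame); nc <- ncol(frame)
  kf <- stats::fft(frame)
  pad <- matrix(0 + 0i, nr2, nc2)
  ri <- dft_index_map(nr, nr2)
  ci <- dft_index_map(nc, nc2)
  pad[ri, ci] <- kf
  stats::fft(pad, inverse = TRUE) / (nr * nc)
}

# Map DFT bin indices of size n onto a size m >= n grid: the first
# ceil(n/2) bins stay at the front, the remaining negative frequencies move
# to the back. (For even n the single Nyquist bin is kept on the positive
# side; the frames are complex so Hermitian splitting is not required.)
dft_index_map <- function(n, m) {
  n_pos <- ceiling(n / 2)
  c(seq_len(n_pos), m - (n - n_pos) + seq_len(n - n_pos))
}

#' Reconstruct a finer grid by k-space zero-filling
#'
#' Each complex frame (`magnitude * exp(i * phase)`) is Fourier-transformed,
#' symmetrically zero-padded in k-space to the target matrix size, and
#' inverse-transformed. This interpolates the image onto a finer grid without
#' adding information; the spatial mean (DC component) of every frame is
#' preserved to numerical precision. When the target spacing does not divide
#' the field of view into an integer matrix, the matrix size is rounded up
#' and the achieved spacing recorded in the output metadata.
#'
#' @param series A [cine_pc_series()] on the acquired grid.
#' @param target_spacing_mm Desired (row, col) spacing, `<=` the acquired
#'   spacing; a single number is recycled.
#' @return A [cine_pc_series()] with `grid_kind = "reconstructed"` and
#'   attribute `requested_spacing_mm` documenting any rounding.
#' @export
zero_fill_reconstruct <- function(series, target_spacing_mm) {
  stopifnot(inherits(series, "cine_pc_series"))
  if (series$grid_kind != "acquired") {
    stop("`series` must be on the acquired grid (grid_kind = 'acquired')",
         call. = FALSE)
  }
  target <- as.numeric(target_spacing_mm)
  if (length(target) == 1L) target <- rep(target, 2L)
  if (any(target <= 0) || any(target > series$pixel_spacing_mm + 1e-12)) {
    stop("`target_spacing_mm` must be positive and <= the acquired spacing",
         call. = FALSE)
  }
  d <- dim(series$magnitude)
  fov <- d[1:2] * series$pixel_spacing_mm
  n2 <- as.integer(ceiling(fov / target - 1e-9))
  achieved <- fov / n2
  cplx <- series$magnitude * exp(1i * series$phase)
  mag2 <- array(0, c(n2, d[3]))
  phi2 <- array(0, c(n2, d[3]))
  for (k in seq_len(d[3])) {
    fr <- zero_fill_frame(cplx[, , k], n2[1], n2[2])
    mag2[, , k] <- Mod(fr)
    phi2[, , k] <- Arg(fr)
  }
  out <- cine_pc_series(mag2, wrap_phase(phi2), achieved, series$venc_cm_s,
                        series$heart_rate_bpm, grid_kind = "reconstructed")
  attr(out, "requested_spacing_mm") <- target
  out
}

#' Read / write a cine phase-contrast series
#'
#' A series is stored as two NIfTI volumes, `<prefix>_mag.nii.gz` and
#' `<prefix>_phase.nii.gz` (row x col x cardiac phase, double precision), plus
#' a YAML sidecar `<prefix>.yaml` holding the acquisition metadata (keys
#' `venc_cm_s`, `pixel_spacing_mm`, `heart_rate_bpm`, `n_cardiac_phases`,
#' `grid_kind`). The round trip is bit-exact for the arrays and exact for the
#' metadata. Phase values stored outside `[-pi, pi)` are wrapped on read with
#' a warning.
#'
#' @param prefix Path prefix (no extension).
#' @param series A [cine_pc_series()] (for writing).
#' @return `read_cine_series()` returns a [cine_pc_series()];
#'   `write_cine_series()` returns `prefix` invisibly.
#' @export
read_cine_series <- function(prefix) {
  sidecar <- paste0(prefix, ".yaml")
  if (!file.exists(sidecar)) {
    stop("format error: missing sidecar metadata file '", sidecar, "'",
         call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar)
  for (key in c("venc_cm_s", "pixel_spacing_mm", "n_cardiac_phases", "grid_kind")) {
    if (is.null(meta[[key]])) {
      stop("format error: sidecar is missing required field '", key, "'",
           call. = FALSE)
    }
  }
  mag <- as.array(RNifti::readNifti(paste0(prefix, "_mag.nii.gz")))
  phi <- as.array(RNifti::readNifti(paste0(prefix, "_phase.nii.gz")))
  if (length(dim(mag)) == 2L) mag <- array(mag, c(dim(mag), 1L))
  if (length(dim(phi)) == 2L) phi <- array(phi, c(dim(phi), 1L))
  if (dim(mag)[3] != meta$n_cardiac_phases) {
    stop("format error: field 'n_cardiac_phases' (", meta$n_cardiac_phases,
         ") does not match image stack depth (", dim(mag)[3], ")", call. = FALSE)
  }
  cine_pc_series(
    magnitude = mag, phase = phi,
    pixel_spacing_mm = as.numeric(meta$pixel_spacing_mm),
    venc_cm_s = meta$venc_cm_s,
    heart_rate_bpm = meta$heart_rate_bpm %||% NA_real_,
    grid_kind = meta$grid_kind
  )
}

#' @rdname read_cine_series
#' @export
write_cine_series <- function(series, prefix) {
  stopifnot(inherits(series, "cine_pc_series"))
  RNifti::writeNifti(RNifti::asNifti(series$magnitude, datatype = "double"),
                     paste0(prefix, "_mag.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(series$phase, datatype = "double"),
                     paste0(prefix, "_phase.nii.gz"))
  meta <- list(
    venc_cm_s = series$venc_cm_s,
    pixel_spacing_mm = series$pixel_spacing_mm,
    heart_rate_bpm = if (is.finite(series$heart_rate_bpm)) series$heart_rate_bpm,
    n_cardiac_phases = series$n_cardiac_phases,
    grid_kind = series$grid_kind
  )
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Read / write a binary ROI mask as NIfTI
#'
#' @param path File path (`.nii` / `.nii.gz`).
#' @param roi A [roi_mask()] (for writing).
#' @param label Label for the mask on read.
#' @return `read_roi_mask()` returns a [roi_mask()]; `write_roi_mask()`
#'   returns `path` invisibly.
#' @export
read_roi_mask <- function(path, label = "ROI") {
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) == 3L && dim(m)[3] == 1L) m <- m[, , 1]
  roi_mask(m != 0, label = label)
}

#' @rdname read_roi_mask
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  m <- matrix(as.integer(roi), nrow(roi), ncol(roi))
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
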