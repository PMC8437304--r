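#' Construct a Jones-matrix volume
#'
#' A PS-OCT raster volume of per-voxel 2x2 complex Jones matrices, stored as
#' the row-major target vector c = (J11, J12, J21, J22) along the fourth array
#' dimension. Axes are (z axial, x lateral within B-scan, y slow across
#' B-scans). Axial index increases with depth, so "above the RPE" means a
#' smaller z.
#'
#' @param data complex array, either `(nz, nx, ny, 4)` (target-vector layout)
#'   or `(nz, nx, ny, 2, 2)` (explicit Jones matrices, `[ , , , i, j]` = Jij).
#' @param axial_pitch_um axial sampling pitch in micrometres per pixel.
#'   The default 13/3 reproduces the instrument convention that 3 pixels span
#'   13 um.
#' @param scan_width_mm lateral extent of the raster in millimetres (default
#'   6 mm); the lateral pitch is `scan_width_mm * 1000 / n_ascans`.
#' @return an object of class `jones_volume` with fields `data`,
#'   `axial_pitch_um`, `lateral_pitch_um`, `n_ascans`, `n_bscans`, `nz`.
#' @examples
#' jv <- jones_volume(array(complex(real = rnorm(2 * 4 * 4 * 4)),
#'                          c(2, 4, 4, 4)))
#' jv$n_ascans
#' @export
jones_volume <- function(data, axial_pitch_um = 13 / 3, scan_width_mm = 6) {
  if (!is.complex(data)) storage.mode(data) <- "complex"
  d <- dim(data)
  if (length(d) == 5L && all(d[4:5] == 2L)) {
    # (z,x,y,i,j) row-major -> target vector order (J11,J12,J21,J22)
    data <- array(c(data[, , , 1, 1], data[, , , 1, 2],
                    data[, , , 2, 1], data[, , , 2, 2]), c(d[1:3], 4L))
    d <- dim(data)
  }
  if (length(d) != 4L || d[4] != 4L)
    stop("data must be a (nz, nx, ny, 4) or (nz, nx, ny, 2, 2) complex array")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("Jones volume contains non-finite entries")
  if (any(d[1:3] < 1L)) stop("all volume dimensions must be positive")
  structure(list(
    data = data,
    axial_pitch_um = axial_pitch_um,
    lateral_pitch_um = scan_width_mm * 1000 / d[2],
    scan_width_mm = scan_width_mm,
    nz = d[1], n_ascans = d[2], n_bscans = d[3]
  ), class = "jones_volume")
}

#' @export
print.jones_volume <- function(x, ...) {
  cat(sprintf(
    "<jones_volume> %d axial px x %d A-scans x %d B-scans\n  axial pitch %.3f um, lateral pitch %.2f um (%.1f mm scan)\n",
    x$nz, x$n_ascans, x$n_bscans, x$axial_pitch_um, x$lateral_pitch_um,
    x$scan_width_mm))
  invisible(x)
}

# total backscattered power per voxel: squared Frobenius norm of J
jones_power <- function(jv) {
  p <- Re(jv$data[, , , 1])^2 + Im(jv$data[, , , 1])^2
  for (e in 2:4) p <- p + Re(jv$data[, , , e])^2 + Im(jv$data[, , , e])^2
  p
}

#' OCT intensity in decibels relative to the noise floor
#'
#' Intensity is the squared Frobenius norm of the Jones matrix, expressed in
#' dB relative to the total noise-floor power (the expected `sum |n_ij|^2` of
#' pure detector noise, i.e. four times the per-element noise variance).
#' Absolute instrument calibration is not attempted: 0 dB is the noise floor.
#'
#' @param jv a [jones_volume()].
#' @param floor_db detection threshold in dB above the noise floor; voxels
#'   below it are flagged undetected.
#' @param noise_power total noise-floor power (4 x per-element variance from
#'   [estimate_noise_power()]); the reference mapped to 0 dB.
#' @return an `intensity_volume`: `I_db` array and logical `detection_mask`.
#' @export
intensity_db <- function(jv, floor_db = 3, noise_power = 1) {
  stopifnot(inherits(jv, "jones_volume"), noise_power > 0)
  p <- jones_power(jv)
  if (all(p == 0)) stop("empty signal")
  idb <- 10 * log10(p / noise_power)  # zero-power voxels -> -Inf, masked below
  structure(list(
    I_db = idb,
    detection_mask = idb >= floor_db,
    floor_db = floor_db,
    noise_power = noise_power
  ), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s px, floor %.1f dB, %.1f%% detected\n",
              paste(dim(x$I_db), collapse = " x "), x$floor_db,
              100 * mean(x$detection_mask)))
  invisible(x)
}

#' Estimate the per-element detector noise power
#'
#' Averages `|J_ij|^2` over the four matrix elements in an axial index range
#' known to contain only noise (in the phantom, the region above the ILM).
#'
#' @param jv a [jones_volume()].
#' @param background_rows integer vector of axial (z) indices of the
#'   signal-free region.
#' @return `sigma2`, the per-element noise variance (a scalar).
#' @export
estimate_noise_power <- function(jv, background_rows) {
  stopifnot(inherits(jv, "jones_volume"))
  background_rows <- as.integer(background_rows)
  if (length(background_rows) == 0) stop("background region is empty")
  if (any(background_rows < 1L | background_rows > jv$nz))
    stop("background region outside volume")
  sub <- jv$data[background_rows, , , , drop = FALSE]
  pw <- Re(sub)^2 + Im(sub)^2
  # guard against the region dipping into tissue: per-row mean power should be
  # flat for pure noise
  if (length(background_rows) >= 3) {
    rowmean <- apply(pw, 1, mean)
    if (max(rowmean) > 3 * min(rowmean) + .Machine$double.eps)
      warning("background region may overlap signal; noise power overestimated")
  }
  mean(pw)
}
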