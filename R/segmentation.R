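# container for per-A-scan surface indices (1-based axial px)
surfaces_object <- function(z_ilm, z_rpe, z_csi, quality = NULL) {
  stopifnot(all(dim(z_ilm) == dim(z_rpe)), all(dim(z_ilm) == dim(z_csi)))
  if (is.null(quality)) quality <- !is.na(z_ilm) & !is.na(z_rpe) & !is.na(z_csi)
  structure(list(z_ilm = z_ilm, z_rpe = z_rpe, z_csi = z_csi,
                 quality = quality),
            class = "oct_surfaces")
}

#' @export
print.oct_surfaces <- function(x, ...) {
  cat(sprintf(
    "<oct_surfaces> %d x %d A-scans, %.1f%% good quality\n  median z: ILM %.0f, RPE %.0f, CSI %.0f\n",
    nrow(x$z_ilm), ncol(x$z_ilm), 100 * mean(x$quality),
    median(x$z_ilm, na.rm = TRUE), median(x$z_rpe, na.rm = TRUE),
    median(x$z_csi, na.rm = TRUE)))
  invisible(x)
}

# first / last row index where a logical matrix column is TRUE (NA if none)
first_true <- function(B) {
  hit <- colSums(B) > 0
  idx <- max.col(t(B) * 1L, ties.method = "first")
  idx[!hit] <- NA_integer_
  idx
}
last_true <- function(B) {
  hit <- colSums(B) > 0
  idx <- max.col(t(B) * 1L, ties.method = "last")
  idx[!hit] <- NA_integer_
  idx
}

# separable lateral median smoothing of a surface map (NA-tolerant:
# missing A-scans are interpolated along columns before filtering)
smooth_surface <- function(m, window = 11L) {
  if (anyNA(m)) {
    m <- apply(m, 2, function(v) {
      nas <- is.na(v)
      if (all(nas) || !any(nas)) return(v)
      v[nas] <- stats::approx(which(!nas), v[!nas], xout = which(nas),
                              rule = 2)$y
      v
    })
    if (anyNA(m)) {  # whole columns missing: interpolate along rows
      m <- t(apply(m, 1, function(v) {
        nas <- is.na(v)
        if (all(nas) || !any(nas)) return(v)
        v[nas] <- stats::approx(which(!nas), v[!nas], xout = which(nas),
                                rule = 2)$y
        v
      }))
    }
  }
  median_smooth_cpp(m, as.integer(window))
}

#' Segment the ILM, RPE and chorioscleral interface
#'
#' Surface recovery from co-registered intensity and entropy volumes, suited
#' to phantom-like geometry. Per A-scan, on the axially smoothed intensity:
#' the ILM is the first depth where the signal stays above the detection
#' threshold for `m_consecutive` pixels; the RPE is the depth below the ILM
#' maximizing smoothed linear intensity x entropy (the RPE is the bright,
#' depolarizing band); the CSI is the last supra-threshold depth below the
#' RPE. Surfaces are then median-filtered laterally and the ordering
#' ILM < RPE < CSI is enforced; A-scans violating it are interpolated from
#' neighbours and flagged in `quality`.
#'
#' @param iv an [intensity_db()] volume.
#' @param ev an [entropy_volume()] co-registered with `iv`.
#' @param floor_db detection threshold (dB above noise floor); defaults to
#'   the one carried by `iv`.
#' @param m_consecutive supra-threshold run length declaring the ILM
#'   (rejects isolated noise spikes).
#' @param median_window lateral median-filter window (px).
#' @return an `oct_surfaces` object: matrices `z_ilm`, `z_rpe`, `z_csi`
#'   (axial px, 1-based) and a logical `quality` flag per A-scan.
#' @export
segment_surfaces <- function(iv, ev, floor_db = NULL, m_consecutive = 3L,
                             median_window = 11L) {
  stopifnot(inherits(iv, "intensity_volume"), inherits(ev, "entropy_volume"))
  dims <- dim(iv$I_db)
  stopifnot(all(dims == dim(ev$H)))
  nz <- dims[1]; nx <- dims[2]; ny <- dims[3]
  thr <- floor_db %||% iv$floor_db

  # axial 3-pt smoothing, in linear power
  lin <- 10^(iv$I_db / 10)
  dim(lin) <- c(nz, nx * ny)
  sm <- lin
  sm[2:(nz - 1), ] <- (lin[1:(nz - 2), ] + lin[2:(nz - 1), ] + lin[3:nz, ]) / 3
  above <- sm >= 10^(thr / 10)

  # ILM: first index opening a run of m consecutive supra-threshold px.
  # The run is evaluated on the raw intensity: centered smoothing would leak
  # signal one pixel above the true boundary and bias the ILM upward.
  above_raw <- lin >= 10^(thr / 10)
  run <- above_raw
  if (m_consecutive > 1) {
    for (k in seq_len(m_consecutive - 1)) {
      shifted <- rbind(above_raw[-seq_len(k), , drop = FALSE],
                       matrix(FALSE, k, ncol(above_raw)))
      run <- run & shifted
    }
  }
  z_ilm <- first_true(run)

  # RPE: argmax of smoothed intensity x entropy strictly below the ILM
  H0 <- ev$H
  H0[!ev$valid] <- 0
  dim(H0) <- c(nz, nx * ny)
  score <- sm * H0
  zrow <- matrix(seq_len(nz), nz, ncol(score))
  ilm_m <- matrix(z_ilm, nz, ncol(score), byrow = TRUE)
  score[is.na(ilm_m) | zrow <= ilm_m] <- -Inf
  z_rpe <- max.col(t(score), ties.method = "first")
  z_rpe[!is.finite(apply(score, 2, max))] <- NA_integer_

  # CSI: last supra-threshold index below the RPE band
  below <- above
  rpe_m <- matrix(z_rpe, nz, ncol(below), byrow = TRUE)
  below[is.na(rpe_m) | zrow <= rpe_m + 3] <- FALSE
  z_csi <- last_true(below)

  ok <- !is.na(z_ilm) & !is.na(z_rpe) & !is.na(z_csi) &
    z_ilm < z_rpe & z_rpe < z_csi
  if (mean(ok) < 0.5) stop("segmentation failed")

  shape <- function(v) matrix(as.numeric(v), nx, ny, byrow = FALSE)
  z_ilm <- shape(z_ilm); z_rpe <- shape(z_rpe); z_csi <- shape(z_csi)
  qual <- shape(ok) > 0
  z_ilm[!qual] <- NA; z_rpe[!qual] <- NA; z_csi[!qual] <- NA

  z_ilm <- round(smooth_surface(z_ilm, median_window))
  z_rpe <- round(smooth_surface(z_rpe, median_window))
  z_csi <- round(smooth_surface(z_csi, median_window))

  # enforce ordering after smoothing
  z_rpe <- pmax(z_rpe, z_ilm + 1)
  z_csi <- pmax(z_csi, z_rpe + 1)
  z_ilm <- pmax(pmin(z_ilm, nz), 1)
  z_rpe <- pmax(pmin(z_rpe, nz), 1)
  z_csi <- pmax(pmin(z_csi, nz), 1)

  surfaces_object(z_ilm, z_rpe, z_csi, quality = qual)
}

#' Retinal thickness map
#'
#' ILM-to-RPE distance per A-scan, in micrometres.
#'
#' @param s an `oct_surfaces` object.
#' @param axial_pitch_um axial pitch in um per pixel.
#' @return numeric matrix (n_ascans x n_bscans) of thickness in um.
#' @examples
#' s <- polent:::surfaces_object(matrix(40, 2, 2), matrix(100, 2, 2),
#'                               matrix(150, 2, 2))
#' retinal_thickness(s, 13 / 3)[1, 1]  # 60 px -> 260 um
#' @export
retinal_thickness <- function(s, axial_pitch_um = 13 / 3) {
  stopifnot(inherits(s, "oct_surfaces"))
  (s$z_rpe - s$z_ilm) * axial_pitch_um
}

#' Locate the fovea as the retinal thickness minimum
#'
#' @param s an `oct_surfaces` object.
#' @param smooth lateral median window applied to the thickness map before
#'   taking the minimum.
#' @return integer `(x, y)` pixel position.
#' @export
find_fovea <- function(s, smooth = 5L) {
  th <- smooth_surface(s$z_rpe - s$z_ilm, smooth)
  # centroid of the near-minimal region is robust to flat/tied minima
  w <- which(th <= min(th, na.rm = TRUE) + 0.5, arr.ind = TRUE)
  as.integer(round(colMeans(w)))
}
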