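# columns of a B-scan within a lateral radius of the fovea column
radius_columns <- function(nx, fovea_col, lateral_pitch_um, radius_um) {
  half <- floor(radius_um / lateral_pitch_um)
  max(1L, fovea_col - half):min(nx, fovea_col + half)
}

#' RPE entropy-signal area percentage on a B-scan
#'
#' On the fovea-spanning B-scan, the unit RPE area is a 7-row band (the
#' segmented RPE line plus 3 px above and 3 px below, inclusive) restricted
#' to columns within 1500 um of the fovea. The metric is the percentage of
#' band pixels whose entropy strictly exceeds the depolarization threshold.
#'
#' @param ev an [entropy_volume()].
#' @param s co-registered `oct_surfaces`.
#' @param bscan B-scan (slow-axis) index to analyze.
#' @param fovea_col A-scan (column) index of the fovea on that B-scan.
#' @param lateral_pitch_um lateral pitch in um per px.
#' @param threshold entropy threshold (strict `>`), default 0.1.
#' @param radius_um lateral analysis half-width, default 1500 um.
#' @param band_halfwidth_px rows above/below the RPE line, default 3.
#' @return a one-row tibble: `percent`, `n_band_px`, `n_signal_px`,
#'   `n_masked` (band pixels with no valid entropy; counted in the
#'   denominator), `bscan`, `fovea_col`.
#' @export
rpe_entropy_area_percent <- function(ev, s, bscan, fovea_col,
                                     lateral_pitch_um,
                                     threshold = 0.1, radius_um = 1500,
                                     band_halfwidth_px = 3L) {
  stopifnot(inherits(ev, "entropy_volume"), inherits(s, "oct_surfaces"))
  nz <- dim(ev$H)[1]; nx <- dim(ev$H)[2]
  stopifnot(bscan >= 1, bscan <= dim(ev$H)[3])
  cols <- radius_columns(nx, fovea_col, lateral_pitch_um, radius_um)
  zr <- s$z_rpe[cols, bscan]
  if (mean(is.na(zr)) > 0.2) stop("RPE line undefined on >20% of columns")

  H <- ev$H[, , bscan]
  V <- ev$valid[, , bscan]
  n_band <- 0L; n_sig <- 0L; n_masked <- 0L
  for (i in seq_along(cols)) {
    if (is.na(zr[i])) next
    rows <- max(1L, zr[i] - band_halfwidth_px):min(nz, zr[i] + band_halfwidth_px)
    n_band <- n_band + length(rows)
    v <- V[rows, cols[i]]
    h <- H[rows, cols[i]]
    n_sig <- n_sig + sum(v & !is.na(h) & h > threshold)
    n_masked <- n_masked + sum(!v)
  }
  if (n_band == 0) stop("empty RPE band")
  tibble::tibble(percent = 100 * n_sig / n_band,
                 n_band_px = n_band, n_signal_px = n_sig,
                 n_masked = n_masked, bscan = bscan, fovea_col = fovea_col)
}

# connected components of a logical matrix, filtered by area
label_components <- function(mask, min_area = 1L, max_area = Inf) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) {
    return(list(labels = lab,
                comps = tibble::tibble(id = integer(0), z = numeric(0),
                                       x = numeric(0), area_px = integer(0))))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  area <- tabulate(ids)
  keep <- which(area >= min_area & area <= max_area)
  zc <- vapply(keep, function(k) mean(idx[ids == k, 1]), numeric(1))
  xc <- vapply(keep, function(k) mean(idx[ids == k, 2]), numeric(1))
  lab[!(lab %in% keep)] <- 0L
  list(labels = lab,
       comps = tibble::tibble(id = keep, z = zc, x = xc,
                              area_px = area[keep]))
}

#' Detect hyperreflective foci and entropy dots on a B-scan
#'
#' Automated surrogate for expert counting: hyperreflective foci (HRF) are
#' connected components of 3x3 boxcar-smoothed linear intensity at least
#' `rel_threshold_db` above the median smoothed retinal intensity (smoothing
#' suppresses fully developed speckle, whose per-pixel fluctuations would
#' otherwise dominate any threshold), inside the sensory-retina slab (ILM to
#' 3 px above the RPE) and within 1500 um of the fovea; entropy dots are
#' components of the depolarization mask (`H > threshold`) in the same
#' region. Components are detected over the whole slab and kept when their
#' centroid column lies within the radius, so the analysis window never cuts
#' a focus in half. `n_overlap` counts the HRF components that carry at
#' least one entropy-dot pixel (the reading "foci overlaid with entropy
#' signal"), capped at `n_dots` so that
#' `n_overlap <= min(n_hrf, n_dots)` always holds even when one dot
#' component spans several foci.
#'
#' @param iv an [intensity_db()] volume.
#' @param ev co-registered [entropy_volume()].
#' @param s co-registered `oct_surfaces`.
#' @param bscan B-scan index.
#' @param fovea_col fovea column on that B-scan.
#' @param lateral_pitch_um lateral pitch, um per px.
#' @param min_area,max_area component area bounds in px (defaults 2, 200).
#' @param rel_threshold_db HRF brightness margin over the median smoothed
#'   retinal intensity (default 8 dB).
#' @param threshold entropy-dot threshold (strict `>`), default 0.1.
#' @param radius_um lateral analysis half-width, default 1500 um.
#' @return a `foci_set`: tibble `foci` (kind, z, x, area_px) and counts
#'   `n_hrf`, `n_dots`, `n_overlap`.
#' @export
detect_hrf <- function(iv, ev, s, bscan, fovea_col, lateral_pitch_um,
                       min_area = 2L, max_area = 200L, rel_threshold_db = 8,
                       threshold = 0.1, radius_um = 1500) {
  stopifnot(inherits(iv, "intensity_volume"), inherits(ev, "entropy_volume"),
            inherits(s, "oct_surfaces"))
  nz <- dim(iv$I_db)[1]; nx <- dim(iv$I_db)[2]
  cols <- radius_columns(nx, fovea_col, lateral_pitch_um, radius_um)

  slab <- layer_slab(s, "retina")
  region <- matrix(FALSE, nz, nx)
  # the entropy-dot region shrinks by the kernel half-height: windows of the
  # outermost slab rows straddle the vitreous / RPE and would smear a
  # spurious high-entropy fringe into the retina
  kh <- ev$kernel[1] %/% 2
  region_dot <- region
  for (x in seq_len(nx)) {
    a <- slab$start[x, bscan]; b <- slab$end[x, bscan] - 1
    if (is.na(a) || is.na(b) || b < a) next
    region[max(1, a):min(nz, b), x] <- TRUE
    if (b - kh >= a + kh)
      region_dot[max(1, a + kh):min(nz, b - kh), x] <- TRUE
  }
  if (!any(region[, cols])) stop("retina slab undefined within the analysis radius")

  # speckle suppression: 3x3 boxcar on linear intensity before thresholding
  I_lin <- 10^(iv$I_db[, , bscan] / 10)
  I_sm <- EBImage::filter2(I_lin, matrix(1 / 9, 3, 3), boundary = "replicate")
  I <- 10 * log10(pmax(I_sm, .Machine$double.xmin))
  reg_in <- region
  reg_in[, -cols] <- FALSE
  med <- median(I[reg_in])
  hrf_mask <- region & (I >= med + rel_threshold_db)
  H <- ev$H[, , bscan]
  V <- ev$valid[, , bscan]
  dot_mask <- region_dot & V & !is.na(H) & (H > threshold)

  half <- floor(radius_um / lateral_pitch_um)
  lh <- label_components(hrf_mask, min_area, max_area)
  ld <- label_components(dot_mask, min_area, max_area)
  # keep components whose centroid column lies within the radius
  prune <- function(l) {
    keep <- abs(l$comps$x - fovea_col) <= half
    l$labels[!(l$labels %in% l$comps$id[keep])] <- 0L
    l$comps <- l$comps[keep, , drop = FALSE]
    l
  }
  lh <- prune(lh)
  ld <- prune(ld)

  both <- lh$labels > 0 & ld$labels > 0
  n_overlap <- min(length(unique(lh$labels[both])), nrow(ld$comps))
  foci <- rbind(
    tibble::tibble(kind = rep("HRF", nrow(lh$comps)), lh$comps[-1]),
    tibble::tibble(kind = rep("entropy_dot", nrow(ld$comps)), ld$comps[-1]))
  structure(list(foci = foci, n_hrf = nrow(lh$comps), n_dots = nrow(ld$comps),
                 n_overlap = n_overlap, bscan = bscan,
                 fovea_col = fovea_col),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> B-scan %d: %d HRF, %d entropy dots, %d overlapping\n",
              x$bscan, x$n_hrf, x$n_dots, x$n_overlap))
  invisible(x)
}
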