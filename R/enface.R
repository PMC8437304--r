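#' Axial slab boundaries for a retinal layer
#'
#' Pixel-defined slabs relative to the segmented surfaces, applied per
#' A-scan as half-open ranges `[start, end)`:
#' retina `[z_ilm, z_rpe - 3)` (ILM down to 3 px / 13 um above the RPE),
#' RPE `[z_rpe - 3, z_rpe + 3)` (6 px / 26 um centered at the RPE line;
#' an even count cannot be symmetric about one row, so the extra row lies on
#' the choroid side), and choroid `[z_rpe + 3, z_csi)` (3 px / 13 um below
#' the RPE down to the CSI). The three slabs are contiguous and disjoint and
#' partition `[z_ilm, z_csi)`.
#'
#' @param s an `oct_surfaces` object.
#' @param layer `"retina"`, `"rpe"` or `"choroid"`.
#' @return list of matrices `start` and `end` (half-open, 1-based axial px);
#'   a pixel whose slab is empty (`end <= start`) carries no layer there.
#' @export
layer_slab <- function(s, layer = c("retina", "rpe", "choroid")) {
  stopifnot(inherits(s, "oct_surfaces"))
  layer <- match.arg(layer)
  switch(layer,
    retina  = list(start = s$z_ilm,     end = s$z_rpe - 3),
    rpe     = list(start = s$z_rpe - 3, end = s$z_rpe + 3),
    choroid = list(start = s$z_rpe + 3, end = s$z_csi))
}

#' Layer-projected en-face entropy map
#'
#' For every A-scan, averages entropy over the valid voxels of the layer
#' slab ([layer_slab()]), producing a 2-D map with the lateral dimensions of
#' the volume (512 x 512 for the instrument raster). A pixel is masked when
#' its slab is empty, when fewer than `min_valid_frac` of the slab voxels
#' are valid, or when the A-scan segmentation quality flag is unset.
#'
#' @param ev an [entropy_volume()].
#' @param s co-registered `oct_surfaces`.
#' @param layer `"retina"`, `"rpe"` or `"choroid"`.
#' @param min_valid_frac minimal fraction of valid slab voxels (default 0.5).
#' @return an `enface_map`: `values` (mean entropy), `mask`, `layer`.
#' @export
enface_entropy_map <- function(ev, s, layer = c("retina", "rpe", "choroid"),
                               min_valid_frac = 0.5) {
  stopifnot(inherits(ev, "entropy_volume"), inherits(s, "oct_surfaces"))
  layer <- match.arg(layer)
  dims <- dim(ev$H)
  nz <- dims[1]; nx <- dims[2]; ny <- dims[3]
  stopifnot(all(dim(s$z_ilm) == c(nx, ny)))
  slab <- layer_slab(s, layer)

  # cumulative sums along z turn every slab mean into two lookups
  Hv <- ev$H
  Hv[!ev$valid] <- 0
  dim(Hv) <- c(nz, nx * ny)
  Vv <- ev$valid
  dim(Vv) <- c(nz, nx * ny)
  csH <- rbind(0, Hv)  # csH[k + 1, ] = sum over rows 1..k
  csV <- rbind(0, Vv * 1)
  for (i in seq_len(nz)) {
    csH[i + 1, ] <- csH[i, ] + csH[i + 1, ]
    csV[i + 1, ] <- csV[i, ] + csV[i + 1, ]
  }

  a <- pmax(pmin(as.vector(slab$start), nz + 1), 1)       # first row in slab
  b <- pmax(pmin(as.vector(slab$end) - 1, nz), 0)         # last row in slab
  col <- seq_len(nx * ny)
  empty <- is.na(a) | is.na(b) | (b < a)
  a[empty] <- 1; b[empty] <- 1
  n_slab <- b - a + 1
  sumH <- csH[cbind(b + 1, col)] - csH[cbind(a, col)]
  nval <- csV[cbind(b + 1, col)] - csV[cbind(a, col)]

  vals <- ifelse(nval > 0, sumH / nval, NA_real_)
  mask <- !empty & (nval >= min_valid_frac * n_slab) & (nval > 0) &
    as.vector(s$quality)
  vals[!mask] <- NA_real_
  structure(list(values = matrix(vals, nx, ny),
                 mask = matrix(mask, nx, ny),
                 layer = layer),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<enface_map> layer %s, %d x %d px, %.1f%% valid, mean %.3f\n",
    x$layer, nrow(x$values), ncol(x$values), 100 * mean(x$mask),
    if (length(v)) mean(v) else NA))
  invisible(x)
}
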