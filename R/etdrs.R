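#' ETDRS sector labels
#'
#' The nine macular zones: central disk `C`, inner ring `SI, II, NI, TI`
#' (superior / inferior / nasal / temporal inner) and outer ring
#' `SO, IO, NO, TO`.
#' @return character vector of the nine labels.
#' @export
etdrs_sector_labels <- function() {
  c("C", "SI", "II", "NI", "TI", "SO", "IO", "NO", "TO")
}

#' Build the ETDRS nine-sector grid in pixel space
#'
#' Concentric circles of 1, 3 and 6 mm diameter centered on the fovea define
#' a central disk, an inner and an outer ring; the rings are split at the
#' +-45 degree diagonals into superior, inferior, nasal and temporal wedges
#' — nine zones in total. Radius boundaries are half-open (a pixel at
#' r = 0.5 mm belongs to the inner ring) and pixels exactly on a diagonal
#' belong to the superior/inferior wedge, so the sector masks are mutually
#' disjoint, their union is exactly the 6 mm disk, and the partition mirrors
#' cleanly between eyes. Nasal is +x for a right eye (OD) and -x for a left
#' eye (OS); decreasing y is superior.
#'
#' @param center `(x, y)` fovea position in px.
#' @param lateral_pitch_um lateral pixel pitch in um.
#' @param laterality `"OD"` or `"OS"`.
#' @param dim `(nx, ny)` map dimensions in px.
#' @return an `etdrs_grid`: list of nine logical `sector_masks`, the center,
#'   pitch, laterality and radii (0.5, 1.5, 3 mm).
#' @examples
#' g <- etdrs_grid(c(33, 33), 93.75, "OD", c(64, 64))
#' names(g$sector_masks)
#' @export
etdrs_grid <- function(center, lateral_pitch_um, laterality = "OD",
                       dim) {
  stopifnot(length(center) == 2, length(dim) == 2,
            laterality %in% c("OD", "OS"))
  nx <- dim[1]; ny <- dim[2]
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny)
    stop("grid center outside map")
  dx_px <- outer(seq_len(nx) - center[1], rep(1, ny))
  dy_px <- outer(rep(1, nx), seq_len(ny) - center[2])
  r_mm <- sqrt(dx_px^2 + dy_px^2) * lateral_pitch_um / 1000
  # horizontal: nasal toward +x for OD, -x for OS; vertical: -y is superior
  h <- if (laterality == "OD") dx_px else -dx_px
  v <- -dy_px  # positive = superior
  # wedge split at the 45-degree diagonals; pixels exactly on a diagonal are
  # owned by the vertical (superior/inferior) wedge, a tie-break that is
  # symmetric under the OD/OS mirror so nasal<->temporal swap exactly
  wedge <- matrix("N", nx, ny)
  wedge[v > 0 & v >= abs(h)] <- "S"
  wedge[v < 0 & -v >= abs(h)] <- "I"
  wedge[h < 0 & -h > abs(v)] <- "T"

  radii <- c(0.5, 1.5, 3.0)
  masks <- list(C = r_mm < radii[1])
  inner <- r_mm >= radii[1] & r_mm < radii[2]
  outer_ring <- r_mm >= radii[2] & r_mm < radii[3]
  for (w in c("S", "I", "N", "T")) {
    masks[[paste0(w, "I")]] <- inner & wedge == w
    masks[[paste0(w, "O")]] <- outer_ring & wedge == w
  }
  masks <- masks[etdrs_sector_labels()]
  clipped <- (center[1] - radii[3] * 1000 / lateral_pitch_um < 1) ||
    (center[1] + radii[3] * 1000 / lateral_pitch_um > nx) ||
    (center[2] - radii[3] * 1000 / lateral_pitch_um < 1) ||
    (center[2] + radii[3] * 1000 / lateral_pitch_um > ny)
  structure(list(center = center, lateral_pitch_um = lateral_pitch_um,
                 radii_mm = radii, laterality = laterality,
                 sector_masks = masks, clipped = clipped),
            class = "etdrs_grid")
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf(
    "<etdrs_grid> center (%g, %g), pitch %.2f um, %s%s\n  sector px: %s\n",
    x$center[1], x$center[2], x$lateral_pitch_um, x$laterality,
    if (x$clipped) " (clipped)" else "",
    paste(sprintf("%s=%d", names(x$sector_masks),
                  vapply(x$sector_masks, sum, integer(1))), collapse = " ")))
  invisible(x)
}

#' Per-sector means of an en-face map
#'
#' Averages map values over the valid pixels of each requested ETDRS sector.
#' Two pooled scopes are available: `"whole_grid"` (pixel-weighted mean over
#' the union of all nine sectors) and `"irradiated"` (union of the sectors in
#' `irradiated`).
#'
#' @param map an [enface_entropy_map()] (or any list with `values` and
#'   `mask` matrices).
#' @param grid an [etdrs_grid()] in the same pixel frame.
#' @param sectors sector labels to report; default all nine.
#' @param irradiated optional sector labels whose union is reported as scope
#'   `"irradiated"`.
#' @param whole_grid also report the pooled `"whole_grid"` row (default
#'   TRUE).
#' @return a tibble with columns `sector`, `mean`, `n_valid`; sectors with no
#'   valid pixel get `NA` mean.
#' @export
sector_means <- function(map, grid, sectors = etdrs_sector_labels(),
                         irradiated = NULL, whole_grid = TRUE) {
  stopifnot(inherits(grid, "etdrs_grid"))
  vals <- map$values
  ok <- map$mask
  stopifnot(all(dim(vals) == dim(grid$sector_masks[[1]])))
  bad <- setdiff(c(sectors, irradiated), etdrs_sector_labels())
  if (length(bad)) stop("unknown sector label: ", paste(bad, collapse = ", "))

  one <- function(m, label) {
    sel <- m & ok
    n <- sum(sel)
    tibble::tibble(sector = label,
                   mean = if (n > 0) mean(vals[sel]) else NA_real_,
                   n_valid = n)
  }
  rows <- lapply(sectors, function(s) one(grid$sector_masks[[s]], s))
  if (whole_grid) {
    all_m <- Reduce(`|`, grid$sector_masks)
    rows <- c(rows, list(one(all_m, "whole_grid")))
  }
  if (!is.null(irradiated) && length(irradiated)) {
    irr <- Reduce(`|`, grid$sector_masks[irradiated])
    rows <- c(rows, list(one(irr, "irradiated")))
  }
  do.call(rbind, rows)
}
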