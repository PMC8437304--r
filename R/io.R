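# Volume storage: 8 multi-page 32-bit TIFF stacks (real and imaginary part
# per Jones element, one page per B-scan) plus a JSON sidecar with pitches
# and the affine scaling that maps the stored [0,1] range back to values.

elem_names <- c("J11", "J12", "J21", "J22")

#' Write a Jones volume as paired TIFF stacks with a JSON sidecar
#'
#' @param jv a [jones_volume()].
#' @param prefix path prefix; files `<prefix>_<elem>_<re|im>.tif` and
#'   `<prefix>_meta.json` are produced.
#' @return the prefix, invisibly.
#' @export
write_jones_tiff <- function(jv, prefix) {
  stopifnot(inherits(jv, "jones_volume"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  scales <- list()
  for (e in 1:4) {
    for (part in c("re", "im")) {
      v <- if (part == "re") Re(jv$data[, , , e]) else Im(jv$data[, , , e])
      lo <- min(v); hi <- max(v)
      rng <- if (hi > lo) hi - lo else 1
      pages <- lapply(seq_len(jv$n_bscans),
                      function(y) (v[, , y] - lo) / rng)
      fn <- sprintf("%s_%s_%s.tif", prefix, elem_names[e], part)
      tiff::writeTIFF(pages, fn, bits.per.sample = 32L)
      scales[[paste(elem_names[e], part, sep = "_")]] <- list(lo = lo,
                                                             rng = rng)
    }
  }
  meta <- list(nz = jv$nz, n_ascans = jv$n_ascans, n_bscans = jv$n_bscans,
               axial_pitch_um = jv$axial_pitch_um,
               scan_width_mm = jv$scan_width_mm, scales = scales)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a Jones volume stored by [write_jones_tiff()]
#'
#' @param prefix path prefix used at write time.
#' @return a [jones_volume()].
#' @export
read_jones_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  dims <- c(meta$nz, meta$n_ascans, meta$n_bscans)
  data <- array(complex(real = 0), c(dims, 4))
  for (e in 1:4) {
    parts <- lapply(c("re", "im"), function(part) {
      fn <- sprintf("%s_%s_%s.tif", prefix, elem_names[e], part)
      pages <- tiff::readTIFF(fn, all = TRUE)
      sc <- meta$scales[[paste(elem_names[e], part, sep = "_")]]
      arr <- array(0, dims)
      for (y in seq_along(pages)) arr[, , y] <- pages[[y]] * sc$rng + sc$lo
      arr
    })
    data[, , , e] <- complex(real = parts[[1]], imaginary = parts[[2]])
  }
  jones_volume(data, axial_pitch_um = meta$axial_pitch_um,
               scan_width_mm = meta$scan_width_mm)
}

#' Write an en-face map as a 32-bit TIFF
#'
#' Entropy values are already in `[0, 1]`; masked pixels are written as 0
#' and the mask is stored as a second page.
#'
#' @param map an [enface_entropy_map()].
#' @param path output file.
#' @export
write_enface_tiff <- function(map, path) {
  v <- map$values
  v[!map$mask] <- 0
  v <- pmin(pmax(v, 0), 1)
  tiff::writeTIFF(list(v, map$mask * 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Export surfaces as CSV (x, y, z_ilm, z_rpe, z_csi, quality)
#'
#' @param s an `oct_surfaces` object.
#' @param path output file.
#' @export
write_surfaces_csv <- function(s, path) {
  nx <- nrow(s$z_ilm); ny <- ncol(s$z_ilm)
  df <- data.frame(x = rep(seq_len(nx), ny),
                   y = rep(seq_len(ny), each = nx),
                   z_ilm = as.vector(s$z_ilm),
                   z_rpe = as.vector(s$z_rpe),
                   z_csi = as.vector(s$z_csi),
                   quality = as.vector(s$quality))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read surfaces from a CSV written by [write_surfaces_csv()]
#'
#' @param path CSV file.
#' @return an `oct_surfaces` object.
#' @export
read_surfaces_csv <- function(path) {
  df <- read.csv(path)
  nx <- max(df$x); ny <- max(df$y)
  m <- function(col) matrix(df[[col]], nx, ny)
  surfaces_object(m("z_ilm"), m("z_rpe"), m("z_csi"), m("quality") > 0)
}
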