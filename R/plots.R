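#' Plot an en-face entropy map with the ETDRS grid overlay
#'
#' @param map an [enface_entropy_map()].
#' @param grid optional [etdrs_grid()] whose circles and diagonals are drawn.
#' @return a ggplot object.
#' @export
plot_enface <- function(map, grid = NULL) {
  nx <- nrow(map$values); ny <- ncol(map$values)
  df <- data.frame(x = rep(seq_len(nx), ny),
                   y = rep(seq_len(ny), each = nx),
                   H = as.vector(map$values))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$H)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("en-face entropy: %s", map$layer),
                  fill = "H") +
    ggplot2::theme_minimal()
  if (!is.null(grid)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- do.call(rbind, lapply(grid$radii_mm, function(r) {
      rp <- r * 1000 / grid$lateral_pitch_um
      data.frame(x = grid$center[1] + rp * cos(th),
                 y = grid$center[2] + rp * sin(th), r = r)
    }))
    p <- p + ggplot2::geom_path(
      data = circ, ggplot2::aes(x = .data$x, y = .data$y,
                                group = .data$r),
      inherit.aes = FALSE, colour = "white", linewidth = 0.3)
  }
  p
}

#' Plot a B-scan: intensity, entropy, or the depolarization overlay
#'
#' Replicates the standard display: grayscale intensity, 0-1 color entropy
#' with sub-threshold pixels black, or the entropy mask overlaid in red on
#' intensity.
#'
#' @param an an `oct_analysis` from [analyze_jones_volume()].
#' @param bscan B-scan index.
#' @param what `"intensity"`, `"entropy"` or `"overlay"`.
#' @param threshold overlay threshold (strict `>`), default 0.1.
#' @return a ggplot object.
#' @export
plot_bscan <- function(an, bscan, what = c("intensity", "entropy", "overlay"),
                       threshold = 0.1) {
  what <- match.arg(what)
  I <- an$intensity$I_db[, , bscan]
  nz <- nrow(I); nx <- ncol(I)
  df <- data.frame(z = rep(seq_len(nz), nx),
                   x = rep(seq_len(nx), each = nz))
  base_theme <- list(ggplot2::scale_y_reverse(), ggplot2::coord_fixed(),
                     ggplot2::theme_minimal())
  if (what == "intensity") {
    df$v <- as.vector(pmax(I, 0))
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                            fill = .data$v)) +
             ggplot2::geom_raster() +
             ggplot2::scale_fill_gradient(low = "black", high = "white") +
             base_theme + ggplot2::labs(fill = "dB"))
  }
  H <- an$entropy$H[, , bscan]
  if (what == "entropy") {
    df$v <- as.vector(H)
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                            fill = .data$v)) +
             ggplot2::geom_raster() +
             ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                           na.value = "black") +
             base_theme + ggplot2::labs(fill = "H"))
  }
  df$v <- as.vector(pmax(I, 0))
  mk <- an$entropy$valid[, , bscan] & !is.na(H) & H > threshold
  ov <- df[as.vector(mk), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_raster(data = ov, fill = "red", inherit.aes = FALSE,
                         ggplot2::aes(x = .data$x, y = .data$z)) +
    base_theme + ggplot2::labs(fill = "dB")
}
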