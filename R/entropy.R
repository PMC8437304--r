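#' Noise-bias-corrected polarimetric entropy of local Jones matrices
#'
#' For every voxel the 4-vector c = vec(J) is averaged into a local coherency
#' matrix T = <c c'> over a `kernel[1]` (axial) x `kernel[2]` (lateral,
#' within the B-scan) window, truncated at volume edges. Additive detector
#' noise contributes an isotropic term to T, so the noise bias is removed by
#' subtracting `sigma2 * I4` before eigen-decomposition (Cloude-Pottier);
#' negative eigenvalues are clamped to zero. With normalized eigenvalues
#' `p_i`, entropy is `H = -sum p_i log4 p_i`, dimensionless, 0 for a uniform
#' (fully polarized) field and 1 for completely random polarization.
#'
#' Voxels whose clamped spectrum sums to zero cannot carry an entropy value
#' and are marked invalid (never assigned H = 0, which would bias layer
#' means). If `mask` is supplied (typically the `detection_mask` of
#' [intensity_db()]), voxels outside it are invalid too.
#'
#' @param jv a [jones_volume()].
#' @param kernel odd `(kz, kx)` window; default `c(3, 3)`. Small kernels keep
#'   resolution but the eigenvalue spectrum estimated from few samples is
#'   dispersed, biasing H upward for ordered fields and downward for random
#'   ones (see the package vignette); use wider kernels for quantitative
#'   layer means.
#' @param sigma2 per-element noise variance, e.g. from
#'   [estimate_noise_power()].
#' @param mask optional logical array of detected voxels, or an
#'   `intensity_volume` whose `detection_mask` is used.
#' @param keep_coherency return the averaged (uncorrected) coherency
#'   matrices as a `(4, 4, nz, nx, ny)` complex array (memory-heavy).
#' @return an `entropy_volume` (fields `H`, `valid`, `kernel`, `sigma2`);
#'   if `keep_coherency`, a `coherency` field with the T array.
#' @examples
#' jv <- jones_volume(array(rep(c(1, 0, 0, 1) / sqrt(2), each = 5 * 6 * 4),
#'                          c(5, 6, 4, 4)))
#' ev <- entropy_volume(jv)
#' range(ev$H[ev$valid])  # uniform field: entropy 0
#' @export
entropy_volume <- function(jv, kernel = c(3, 3), sigma2 = 0, mask = NULL,
                           keep_coherency = FALSE) {
  stopifnot(inherits(jv, "jones_volume"))
  kernel <- as.integer(kernel)
  if (length(kernel) != 2 || any(kernel < 1) || any(kernel %% 2 == 0))
    stop("kernel must be two odd positive integers (kz, kx)")
  if (kernel[1] > jv$nz || kernel[2] > jv$n_ascans)
    stop("kernel larger than volume")
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 < 0)
    stop("sigma2 must be a single non-negative number")
  if (inherits(mask, "intensity_volume")) mask <- mask$detection_mask

  dims <- c(jv$nz, jv$n_ascans, jv$n_bscans)
  res <- entropy_jones_cpp(as.vector(jv$data), dims, kernel[1], kernel[2],
                           sigma2, keep_coherency)
  H <- array(res$H, dims)
  lsum <- array(res$lambda_sum, dims)
  valid <- is.finite(H) & (lsum > 0)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dims))
    valid <- valid & mask
  }
  H[!valid] <- NA_real_
  ev <- structure(list(H = H, valid = valid, kernel = kernel, sigma2 = sigma2),
                  class = "entropy_volume")
  if (keep_coherency) {
    ev$coherency <- structure(
      list(T = array(res$T, c(4, 4, dims)), kernel = kernel),
      class = "coherency_volume")
  }
  ev
}

#' @export
print.entropy_volume <- function(x, ...) {
  h <- x$H[x$valid]
  cat(sprintf(
    "<entropy_volume> %s px, kernel %dx%d, sigma2 %.3g\n  valid %.1f%%, H in [%.3f, %.3f], mean %.3f\n",
    paste(dim(x$H), collapse = " x "), x$kernel[1], x$kernel[2], x$sigma2,
    100 * mean(x$valid),
    if (length(h)) min(h) else NA, if (length(h)) max(h) else NA,
    if (length(h)) mean(h) else NA))
  invisible(x)
}

#' Depolarizing-pixel mask
#'
#' Flags voxels whose entropy strictly exceeds a threshold (default 0.1, the
#' display/analysis threshold for depolarizing tissue such as the
#' melanin-bearing RPE). Invalid voxels are never flagged.
#'
#' @param ev an [entropy_volume()].
#' @param threshold entropy threshold in `[0, 1]`; the comparison is the
#'   strict `H > threshold`.
#' @return logical array of the volume's dimensions.
#' @export
depolarization_mask <- function(ev, threshold = 0.1) {
  stopifnot(inherits(ev, "entropy_volume"),
            is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  m <- ev$valid & !is.na(ev$H) & (ev$H > threshold)
  m[is.na(m)] <- FALSE
  m
}

#' Entropy of a single coherency matrix
#'
#' Applies the noise-bias correction and the Cloude-Pottier entropy formula
#' to one 4x4 coherency matrix, e.g. one obtained by averaging target
#' vectors over an arbitrarily large sample (where a voxel-wise kernel is
#' not meaningful).
#'
#' @param T 4x4 complex Hermitian coherency matrix (`mean of c c'`).
#' @param sigma2 per-element noise variance subtracted from the diagonal.
#' @return entropy in `[0, 1]`, or `NA` if the clamped spectrum sums to 0.
#' @examples
#' coherency_entropy(diag(c(0.5, 0.5, 0, 0)))  # two equal states: H = 0.5
#' @export
coherency_entropy <- function(T, sigma2 = 0) {
  stopifnot(is.matrix(T), all(dim(T) == c(4, 4)))
  if (max(abs(T - Conj(t(T)))) > 1e-8 * max(1, max(abs(T))))
    stop("T must be Hermitian")
  Tc <- (T + Conj(t(T))) / 2 - diag(sigma2, 4)
  lam <- Re(eigen(Tc, symmetric = TRUE, only.values = TRUE)$values)
  lam[lam < 0] <- 0
  s <- sum(lam)
  if (s <= 0) return(NA_real_)
  p <- lam[lam > 0] / s
  -sum(p * log(p)) / log(4)
}
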