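# Shared fixtures: all inputs are generated in code at test time.

# a uniform (fully polarized) Jones volume: identical matrix everywhere
uniform_jones <- function(nz = 10, nx = 12, ny = 4, J = c(1, 0, 0, 1) / sqrt(2)) {
  jones_volume(array(rep(complex(real = Re(J), imaginary = Im(J)),
                         each = nz * nx * ny), c(nz, nx, ny, 4)))
}

# homogeneous partial-depolarization field with unit power: covariance
# (1 - d) c0 c0' + (d/4) I (+ sigma2 I detector noise). Independent of the
# phantom module's sampling code path in structure, but the same model.
mixture_jones <- function(d, nz = 20, nx = 20, ny = 4, power = 1,
                          sigma2 = 0, seed = 1) {
  set.seed(seed)
  c0 <- c(1, 0, 0, 1) / sqrt(2)
  n <- nz * nx * ny
  cn <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
  a <- sqrt(power * (1 - d)) * cn(n)
  data <- array(complex(real = 0), c(nz, nx, ny, 4))
  for (e in 1:4)
    data[, , , e] <- a * c0[e] + sqrt(power * d / 4) * cn(n) +
      if (sigma2 > 0) sqrt(sigma2) * cn(n) else 0
  jones_volume(data)
}

# small but fully featured layered-eye spec (feasible at nz = 56)
small_eye_spec <- function(...) {
  args <- list(...)
  defaults <- list(nz = 56, n_ascans = 24, n_bscans = 24,
                   ilm_depth_um = 60, retina_thickness_um = 90,
                   pit_depth_um = 30, pit_radius_mm = 0.6,
                   choroid_thickness_um = 40, snr_db = 30, seed = 1)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# minimal cohort-scale spec used by the longitudinal simulations
cohort_eye_spec <- function(...) {
  args <- list(...)
  defaults <- list(nz = 44, n_ascans = 20, n_bscans = 20,
                   ilm_depth_um = 52, retina_thickness_um = 90,
                   pit_depth_um = 30, pit_radius_mm = 0.6,
                   choroid_thickness_um = 30, snr_db = 30,
                   keep_labels = FALSE, seed = 1)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# ---- independent oracles ---------------------------------------------------

# entropy of an eigenvalue spectrum, scalar reference implementation
oracle_spectrum_entropy <- function(lam) {
  lam[lam < 0] <- 0
  if (sum(lam) <= 0) return(NA_real_)
  p <- lam[lam > 0] / sum(lam)
  -sum(p * log(p)) / log(4)
}

# brute-force per-voxel entropy: explicit window gathering, outer products
# averaged in R, base eigen() on the 4x4 Hermitian matrix
oracle_voxel_entropy <- function(jv, z, x, y, kernel, sigma2 = 0) {
  hz <- kernel[1] %/% 2; hx <- kernel[2] %/% 2
  zs <- max(1, z - hz):min(jv$nz, z + hz)
  xs <- max(1, x - hx):min(jv$n_ascans, x + hx)
  Tm <- matrix(0 + 0i, 4, 4)
  n <- 0
  for (xx in xs) for (zz in zs) {
    cvec <- jv$data[zz, xx, y, ]
    Tm <- Tm + outer(cvec, Conj(cvec))
    n <- n + 1
  }
  Tm <- Tm / n - diag(sigma2 + 0i, 4)
  lam <- Re(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
  oracle_spectrum_entropy(lam)
}

# entropy volume object with prescribed H values (all valid)
manual_entropy_volume <- function(H, valid = NULL) {
  if (is.null(valid)) valid <- array(TRUE, dim(H))
  structure(list(H = H, valid = valid, kernel = c(1L, 1L), sigma2 = 0),
            class = "entropy_volume")
}

manual_surfaces <- function(nx, ny, z_ilm, z_rpe, z_csi) {
  polent:::surfaces_object(matrix(z_ilm, nx, ny), matrix(z_rpe, nx, ny),
                           matrix(z_csi, nx, ny))
}
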