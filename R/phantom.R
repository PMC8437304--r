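#' Expected entropy of the depolarization mixing model
#'
#' The phantom models partially depolarizing tissue as a zero-mean complex
#' Gaussian target vector with coherency `(1 - d) c0 c0' + (d/4) I4` (unit
#' power): a fully polarized component mixed with an isotropic one. Its
#' eigenvalue spectrum is `(1 - 3d/4, d/4, d/4, d/4)`, so the entropy has the
#' closed form `-sum p log4 p` — the analytic ground truth the estimator is
#' validated against. `expected_entropy(0) = 0`, `expected_entropy(1) = 1`,
#' and the function is strictly increasing in between.
#'
#' @param d mixing (depolarization) parameter in `[0, 1]`; vectorized.
#' @return entropy in `[0, 1]`.
#' @examples
#' expected_entropy(c(0, 0.5, 1))
#' @export
expected_entropy <- function(d) {
  if (any(!is.finite(d)) || any(d < 0 | d > 1))
    stop("d must lie in [0, 1]")
  vapply(d, function(di) {
    lam <- c(1 - 3 * di / 4, rep(di / 4, 3))
    p <- lam[lam > 0] / sum(lam)
    -sum(p * log(p)) / log(4)
  }, numeric(1))
}

#' Inverse of [expected_entropy()]
#'
#' Numerically inverts the closed-form entropy of the mixing model; used to
#' prescribe a target layer entropy (e.g. a longitudinal decline schedule)
#' in terms of the generating parameter d.
#'
#' @param h entropy in `[0, 1]`; vectorized.
#' @return mixing parameter d in `[0, 1]`.
#' @export
inverse_expected_entropy <- function(h) {
  if (any(!is.finite(h)) || any(h < 0 | h > 1))
    stop("h must lie in [0, 1]")
  vapply(h, function(hi) {
    if (hi <= 0) return(0)
    if (hi >= 1) return(1)
    uniroot(function(d) expected_entropy(d) - hi, c(0, 1),
            tol = 1e-10)$root
  }, numeric(1))
}

#' Specify a synthetic layered-eye phantom
#'
#' Defines a three-layer macular phantom (retina / RPE band / choroid) under
#' a noise-only vitreous, with a parametric foveal pit, per-layer backscatter
#' power and depolarization, additive complex detector noise, optional
#' sector-wise macular edema, and sparse hyperreflective depolarizing foci
#' (HRF) seeded in the foveal B-scan plane. Defaults follow the instrument
#' geometry: a 6 x 6 mm raster of 512 A-scans x 512 B-scans and an axial
#' pitch of 13/3 um (3 px = 13 um). Tests and examples use smaller rasters;
#' the model is scale-free.
#'
#' Layer anatomy along each A-scan (z grows with depth): noise above the ILM;
#' retina from the ILM to 3 px above the RPE line; a 6 px RPE band centered
#' on the RPE line; choroid from 3 px below the line to the CSI; noise below.
#'
#' @param nz,n_ascans,n_bscans volume dimensions (axial, lateral, slow).
#' @param axial_pitch_um,scan_width_mm sampling geometry.
#' @param ilm_depth_um depth of the ILM base below the top of the volume.
#' @param retina_thickness_um ILM-to-RPE thickness away from the fovea.
#' @param pit_depth_um,pit_radius_mm foveal pit: thickness is reduced by
#'   `pit_depth_um * exp(-(r/pit_radius_mm)^2)` around the fovea center.
#' @param choroid_thickness_um RPE band bottom to CSI.
#' @param fovea_center `(x, y)` pixel of the fovea; default raster center.
#' @param power named backscatter power (trace of the coherency) per layer:
#'   `retina`, `rpe`, `choroid`.
#' @param d named depolarization per layer, each in `[0, 1]`.
#' @param snr_db retina signal-to-noise ratio in dB; per-element noise
#'   variance is `power["retina"] * 10^(-snr_db/10) / 4`. `Inf` disables
#'   noise.
#' @param d_rpe_map optional `(n_ascans, n_bscans)` matrix overriding the RPE
#'   depolarization per A-scan (used for sector-confined treatment effects).
#' @param edema_um optional named vector of added retinal thickness (um) per
#'   ETDRS sector label, or NULL.
#' @param edema_field optional `(n_ascans, n_bscans)` matrix of added
#'   thickness in um (overrides `edema_um`).
#' @param laterality `"OD"` or `"OS"`; orients sector labels for edema.
#' @param hrf NULL or `list(n, size_px, power, d, max_radius_mm)`: number of
#'   foci, cube edge in px, backscatter power, depolarization, and maximal
#'   lateral distance from the fovea.
#' @param seed integer RNG seed; a fixed seed makes the volume reproducible.
#' @param keep_labels store the per-voxel layer label array in the truth
#'   (memory ~ volume size; disable for large rasters).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(nz = 384, n_ascans = 512, n_bscans = 512,
                         axial_pitch_um = 13 / 3, scan_width_mm = 6,
                         ilm_depth_um = 400, retina_thickness_um = 350,
                         pit_depth_um = 130, pit_radius_mm = 0.75,
                         choroid_thickness_um = 250,
                         fovea_center = NULL,
                         power = c(retina = 1, rpe = 4, choroid = 0.5),
                         d = c(retina = 0.02, rpe = 0.6, choroid = 0.3),
                         snr_db = 30,
                         d_rpe_map = NULL,
                         edema_um = NULL, edema_field = NULL,
                         laterality = "OD",
                         hrf = NULL,
                         seed = 1L,
                         keep_labels = TRUE) {
  stopifnot(nz >= 8, n_ascans >= 4, n_bscans >= 1)
  need <- c("retina", "rpe", "choroid")
  if (!all(need %in% names(power)) || !all(need %in% names(d)))
    stop("power and d must name retina, rpe, choroid")
  if (any(d[need] < 0 | d[need] > 1)) stop("layer d must lie in [0, 1]")
  if (!laterality %in% c("OD", "OS")) stop("laterality must be OD or OS")
  if (is.null(fovea_center))
    fovea_center <- c(round((n_ascans + 1) / 2), round((n_bscans + 1) / 2))
  if (!is.null(d_rpe_map)) {
    stopifnot(all(dim(d_rpe_map) == c(n_ascans, n_bscans)),
              all(d_rpe_map >= 0 & d_rpe_map <= 1))
  }
  if (!is.null(hrf)) {
    hrf <- utils::modifyList(
      list(n = 10L, size_px = 3L, power = 30, d = 0.7, max_radius_mm = 1.4),
      hrf)
  }
  structure(list(
    nz = as.integer(nz), n_ascans = as.integer(n_ascans),
    n_bscans = as.integer(n_bscans),
    axial_pitch_um = axial_pitch_um, scan_width_mm = scan_width_mm,
    ilm_depth_um = ilm_depth_um, retina_thickness_um = retina_thickness_um,
    pit_depth_um = pit_depth_um, pit_radius_mm = pit_radius_mm,
    choroid_thickness_um = choroid_thickness_um,
    fovea_center = fovea_center, power = power, d = d, snr_db = snr_db,
    d_rpe_map = d_rpe_map, edema_um = edema_um, edema_field = edema_field,
    laterality = laterality, hrf = hrf, seed = as.integer(seed),
    keep_labels = isTRUE(keep_labels)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d x %d, pitch %.3f um axial, SNR %s dB\n  d: retina %.2f rpe %.2f choroid %.2f; seed %d\n",
    x$nz, x$n_ascans, x$n_bscans, x$axial_pitch_um, format(x$snr_db),
    x$d[["retina"]], x$d[["rpe"]], x$d[["choroid"]], x$seed))
  invisible(x)
}

# resolve the phantom's exact layer surfaces (px, 1-based) from the spec
phantom_surfaces <- function(spec) {
  ap <- spec$axial_pitch_um
  nx <- spec$n_ascans; ny <- spec$n_bscans
  lp <- spec$scan_width_mm * 1000 / nx
  cx <- spec$fovea_center[1]; cy <- spec$fovea_center[2]
  r_mm <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+")) *
    lp / 1000
  thick <- spec$retina_thickness_um -
    spec$pit_depth_um * exp(-(r_mm / spec$pit_radius_mm)^2)
  ed <- spec$edema_field
  if (is.null(ed) && !is.null(spec$edema_um)) {
    grid <- etdrs_grid(spec$fovea_center, lp, spec$laterality, c(nx, ny))
    ed <- matrix(0, nx, ny)
    for (s in names(spec$edema_um))
      ed[grid$sector_masks[[s]]] <- spec$edema_um[[s]]
    if (requireNamespace("EBImage", quietly = TRUE))
      ed <- EBImage::gblur(ed, sigma = 2)
  }
  if (!is.null(ed)) thick <- thick + ed
  if (any(thick < 6 * ap))
    stop("inconsistent surfaces: retinal thickness below 6 axial px")
  z_rpe <- round((spec$ilm_depth_um + spec$retina_thickness_um) / ap)
  z_ilm <- z_rpe - round(thick / ap)
  z_csi <- z_rpe + 3 + round(spec$choroid_thickness_um / ap)
  if (min(z_ilm) < 5)
    stop("inconsistent surfaces: no noise-only region above the ILM")
  if (z_csi > spec$nz)
    stop("inconsistent surfaces: CSI below the volume")
  list(z_ilm = z_ilm,
       z_rpe = matrix(z_rpe, nx, ny),
       z_csi = matrix(z_csi, nx, ny))
}

# deterministic placement of HRF cubes in the foveal B-scan plane
phantom_hrf_positions <- function(spec, surf) {
  h <- spec$hrf
  if (is.null(h) || h$n < 1) return(NULL)
  nx <- spec$n_ascans
  lp <- spec$scan_width_mm * 1000 / nx
  cx <- spec$fovea_center[1]; cy <- spec$fovea_center[2]
  max_dx <- floor(h$max_radius_mm * 1000 / lp)
  xs <- max(2L, cx - max_dx):min(nx - h$size_px, cx + max_dx)
  # separation keeps foci (and their kernel-smeared entropy footprints)
  # from merging into one connected component downstream
  sep <- h$size_px + 5L
  # greedy packing over a shuffled candidate lattice (deterministic under
  # the seed; succeeds whenever a packing exists for the shuffle order)
  cand <- do.call(rbind, lapply(xs, function(x) {
    zlo <- surf$z_ilm[x, cy] + 2L
    zhi <- surf$z_rpe[x, cy] - 3L - h$size_px - 2L
    if (zhi <= zlo) return(NULL)
    cbind(x = x, z = zlo:zhi)
  }))
  if (is.null(cand)) stop("no room for HRF inside the retina")
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  acc_x <- integer(0); acc_z <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc_x) >= h$n) break
    x <- cand[i, "x"]; z <- cand[i, "z"]
    if (length(acc_x) &&
        any(pmax(abs(acc_x - x), abs(acc_z - z)) < sep)) next
    acc_x <- c(acc_x, x); acc_z <- c(acc_z, z)
  }
  if (length(acc_x) < h$n)
    stop("could not place the requested number of HRF without overlap")
  tibble::tibble(x = acc_x, z = acc_z, y = cy, size_px = h$size_px)
}

#' Generate a phantom Jones-matrix volume with known truth
#'
#' Draws, for every voxel of layer L, a Jones target vector from a zero-mean
#' complex Gaussian with coherency `P_L [(1 - d_L) c0 c0' + (d_L/4) I4]`
#' (c0 = vectorized identity Jones matrix), then adds independent complex
#' detector noise of per-element variance sigma2. The generating parameters
#' — exact surfaces, per-layer d and its closed-form entropy, fovea center,
#' HRF coordinates — are returned as ground truth for recovery tests.
#' Output is deterministic for a fixed spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `jones` (a [jones_volume()]) and `truth`
#'   (surfaces, layer parameters, `sigma2`, `background_rows`, `fovea`,
#'   `hrf`, and — unless disabled — a per-voxel `labels` array coded
#'   0 background, 1 retina, 2 RPE, 3 choroid, 4 HRF).
#' @examples
#' ph <- generate_phantom(phantom_spec(nz = 64, n_ascans = 24, n_bscans = 8,
#'                                     ilm_depth_um = 80,
#'                                     retina_thickness_um = 120,
#'                                     pit_depth_um = 40,
#'                                     choroid_thickness_um = 60))
#' ph$jones
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$nz; nx <- spec$n_ascans; ny <- spec$n_bscans
  surf <- phantom_surfaces(spec)
  sigma2 <- if (is.finite(spec$snr_db))
    spec$power[["retina"]] * 10^(-spec$snr_db / 10) / 4 else 0

  set.seed(spec$seed)
  hrf_pos <- phantom_hrf_positions(spec, surf)

  c0 <- jones_c0()
  data <- array(complex(real = 0), c(nz, nx, ny, 4))
  labels <- if (spec$keep_labels) array(0L, c(nz, nx, ny)) else NULL
  pw <- spec$power; dl <- spec$d

  cplx_norm <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) /
    sqrt(2)
  expand <- function(m, ys) {
    # (nx, |ys|) surface/parameter map -> (nz, nx, |ys|) block
    aperm(array(m[, ys, drop = FALSE], c(nx, length(ys), nz)), c(3, 1, 2))
  }

  # vectorize over blocks of B-scans to cap the working-set size
  block <- max(1L, min(ny, floor(2e6 / (nz * nx))))
  for (y0 in seq(1L, ny, by = block)) {
    ys <- y0:min(ny, y0 + block - 1L)
    nb <- nz * nx * length(ys)
    zg <- array(seq_len(nz), c(nz, nx, length(ys)))
    ilm <- expand(surf$z_ilm, ys)
    rpe <- expand(surf$z_rpe, ys)
    csi <- expand(surf$z_csi, ys)
    L <- array(0L, dim(zg))
    L[zg >= ilm & zg < rpe - 3] <- 1L
    L[zg >= rpe - 3 & zg < rpe + 3] <- 2L
    L[zg >= rpe + 3 & zg < csi] <- 3L

    P <- array(0, dim(zg))
    D <- array(0, dim(zg))
    P[L == 1L] <- pw[["retina"]]; D[L == 1L] <- dl[["retina"]]
    P[L == 3L] <- pw[["choroid"]]; D[L == 3L] <- dl[["choroid"]]
    P[L == 2L] <- pw[["rpe"]]
    if (is.null(spec$d_rpe_map)) {
      D[L == 2L] <- dl[["rpe"]]
    } else {
      drpe <- expand(spec$d_rpe_map, ys)
      D[L == 2L] <- drpe[L == 2L]
    }

    # detector noise folds into the isotropic Gaussian term: the voxel
    # covariance P[(1-d) c0 c0' + (d/4) I] + sigma2 I is sampled directly
    a <- cplx_norm(nb)
    amp_pol <- sqrt(P * (1 - D)) * a
    amp_iso <- sqrt(P * D / 4 + sigma2)
    for (e in 1:4) {
      data[, , ys, e] <- amp_pol * c0[e] + amp_iso * cplx_norm(nb)
    }
    if (!is.null(labels)) labels[, , ys] <- L
  }

  # hyperreflective foci: redraw the affected voxels with the focus power
  # and depolarization (noise included), after the bulk volume
  if (!is.null(hrf_pos)) {
    for (k in seq_len(nrow(hrf_pos))) {
      zi <- hrf_pos$z[k]:(hrf_pos$z[k] + hrf_pos$size_px[k] - 1L)
      xi <- hrf_pos$x[k]:(hrf_pos$x[k] + hrf_pos$size_px[k] - 1L)
      yk <- hrf_pos$y[k]
      nf <- length(zi) * length(xi)
      Pf <- spec$hrf$power * pw[["retina"]]
      a <- cplx_norm(nf)
      for (e in 1:4) {
        data[zi, xi, yk, e] <- sqrt(Pf * (1 - spec$hrf$d)) * a * c0[e] +
          sqrt(Pf * spec$hrf$d / 4 + sigma2) * cplx_norm(nf)
      }
      if (!is.null(labels)) labels[zi, xi, yk] <- 4L
    }
  }

  jv <- jones_volume(data, axial_pitch_um = spec$axial_pitch_um,
                     scan_width_mm = spec$scan_width_mm)
  truth <- structure(list(
    surfaces = surfaces_object(surf$z_ilm, surf$z_rpe, surf$z_csi),
    d = spec$d,
    d_rpe_map = spec$d_rpe_map,
    expected_entropy = vapply(spec$d, expected_entropy, numeric(1)),
    sigma2 = sigma2,
    background_rows = seq_len(min(surf$z_ilm) - 2L),
    fovea = spec$fovea_center,
    laterality = spec$laterality,
    hrf = hrf_pos,
    labels = labels,
    spec = spec
  ), class = "phantom_truth")
  list(jones = jv, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> fovea (%d, %d), layer H: retina %.3f rpe %.3f choroid %.3f, %d HRF\n",
    x$fovea[1], x$fovea[2], x$expected_entropy[["retina"]],
    x$expected_entropy[["rpe"]], x$expected_entropy[["choroid"]],
    if (is.null(x$hrf)) 0L else nrow(x$hrf)))
  invisible(x)
}

#' Generate a co-registered longitudinal phantom series
#'
#' Emulates a treated eye imaged at baseline and follow-up visits: the RPE
#' depolarization declines only inside the laser-irradiated ETDRS sectors
#' according to `d_rpe_schedule`, and sector edema shrinks according to
#' `edema_um_schedule`. Geometry is otherwise identical across timepoints
#' (volumes are co-registered by construction); speckle and noise are
#' redrawn independently per visit.
#'
#' @param spec baseline [phantom_spec()].
#' @param timepoints character labels, default
#'   `c("baseline", "1m", "2m", "3m", "6m")`.
#' @param irradiated_sectors ETDRS sector labels (subset of C, SI, II, NI,
#'   TI, SO, IO, NO, TO) receiving the treatment effect.
#' @param d_rpe_schedule numeric vector, one RPE depolarization value per
#'   timepoint, applied inside the irradiated sectors (elsewhere the phantom
#'   specification's `d["rpe"]` holds). NULL keeps d constant (null model).
#' @param edema_um_schedule numeric vector of added retinal thickness (um)
#'   per timepoint inside the irradiated sectors; NULL for none.
#' @param retina_thickness_schedule optional numeric vector overriding
#'   `retina_thickness_um` per timepoint (global thickness change).
#' @param d_jitter_sd session-to-session variability: at each visit a single
#'   zero-mean Gaussian perturbation (sd on the depolarization scale) is
#'   added to every layer's d (clamped to `[0, 1]`), emulating alignment and
#'   instrument repeatability differences between sessions. Default 0.04.
#' @param seed base seed; visit i uses `seed + i - 1`.
#' @return a `phantom_series`: list of per-timepoint phantoms plus the grid
#'   and schedules.
#' @export
longitudinal_series <- function(spec,
                                timepoints = c("baseline", "1m", "2m", "3m", "6m"),
                                irradiated_sectors = character(),
                                d_rpe_schedule = NULL,
                                edema_um_schedule = NULL,
                                retina_thickness_schedule = NULL,
                                d_jitter_sd = 0.04,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  bad <- setdiff(irradiated_sectors, etdrs_sector_labels())
  if (length(bad)) stop("unknown sector label: ", paste(bad, collapse = ", "))
  nt <- length(timepoints)
  chk <- function(v) {
    if (!is.null(v) && length(v) != nt)
      stop("schedule length must match the number of timepoints")
    v
  }
  d_rpe_schedule <- chk(d_rpe_schedule)
  edema_um_schedule <- chk(edema_um_schedule)
  retina_thickness_schedule <- chk(retina_thickness_schedule)

  nx <- spec$n_ascans; ny <- spec$n_bscans
  lp <- spec$scan_width_mm * 1000 / nx
  grid <- etdrs_grid(spec$fovea_center, lp, spec$laterality, c(nx, ny))
  irr <- matrix(FALSE, nx, ny)
  for (s in irradiated_sectors) irr <- irr | grid$sector_masks[[s]]

  set.seed(as.integer(seed %% 2147480000L))
  jitter <- if (d_jitter_sd > 0) rnorm(nt, 0, d_jitter_sd) else numeric(nt)

  phantoms <- vector("list", nt)
  names(phantoms) <- timepoints
  for (i in seq_len(nt)) {
    sp <- spec
    sp$seed <- as.integer(seed + i - 1L)
    sp$d <- pmin(pmax(spec$d + jitter[i], 0), 1)  # names preserved
    if (!is.null(d_rpe_schedule) || jitter[i] != 0) {
      m <- matrix(sp$d[["rpe"]], nx, ny)
      if (!is.null(d_rpe_schedule))
        m[irr] <- min(1, max(0, d_rpe_schedule[i] + jitter[i]))
      sp$d_rpe_map <- m
    }
    if (!is.null(edema_um_schedule)) {
      ed <- matrix(0, nx, ny)
      ed[irr] <- edema_um_schedule[i]
      if (requireNamespace("EBImage", quietly = TRUE))
        ed <- EBImage::gblur(ed, sigma = 2)
      sp$edema_field <- ed
      sp$edema_um <- NULL
    }
    if (!is.null(retina_thickness_schedule))
      sp$retina_thickness_um <- retina_thickness_schedule[i]
    phantoms[[i]] <- generate_phantom(sp)
  }
  structure(list(
    timepoints = timepoints, phantoms = phantoms, grid = grid,
    irradiated_sectors = irradiated_sectors,
    d_rpe_schedule = d_rpe_schedule,
    edema_um_schedule = edema_um_schedule,
    d_jitter = jitter
  ), class = "phantom_series")
}
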