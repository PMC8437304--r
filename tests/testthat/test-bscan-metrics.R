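test_that("RPE band percentage counts strict exceedances over all band pixels", {
  nz <- 30; nx <- 41; ny <- 3
  H <- array(0, c(nz, nx, ny))
  ev <- manual_entropy_volume(H)
  s <- manual_surfaces(nx, ny, z_ilm = 5, z_rpe = 15, z_csi = 27)
  # pitch 100 um, radius 1500 um -> 15 px either side of the fovea column 21
  r0 <- rpe_entropy_area_percent(ev, s, bscan = 2, fovea_col = 21,
                                 lateral_pitch_um = 100)
  expect_equal(r0$percent, 0)
  expect_equal(r0$n_band_px, 31 * 7)   # 7 rows x 31 columns

  # exactly 25 of the first 100 band pixels above threshold
  H2 <- H
  band_rows <- 12:18
  cols <- 6:36
  k <- 0
  for (x in cols) for (z in band_rows) {
    k <- k + 1
    if (k <= 100 && k %% 4 == 0) H2[z, x, 2] <- 0.6  # every 4th of 100
  }
  ev2 <- manual_entropy_volume(H2)
  r2 <- rpe_entropy_area_percent(ev2, s, 2, 21, 100)
  expect_equal(r2$n_signal_px, 25)
  expect_equal(r2$percent, 100 * 25 / 217)

  # H exactly at the threshold does not count
  H3 <- H; H3[band_rows, cols, 2] <- 0.1
  expect_equal(rpe_entropy_area_percent(manual_entropy_volume(H3),
                                        s, 2, 21, 100)$percent, 0)

  # undefined RPE on too many columns errors
  s_bad <- s
  s_bad$z_rpe[6:15, ] <- NA  # 10 of the 31 in-radius columns
  expect_error(rpe_entropy_area_percent(ev, s_bad, 2, 21, 100), "undefined")
})

test_that("band percentage rises with RPE depolarization on phantoms", {
  pct <- vapply(c(0.05, 0.3, 0.8), function(d) {
    sp <- small_eye_spec(d = c(retina = 0.02, rpe = d, choroid = 0.3),
                         seed = 61)
    ph <- generate_phantom(sp)
    s2 <- estimate_noise_power(ph$jones, ph$truth$background_rows)
    ev <- entropy_volume(ph$jones, kernel = c(3, 3), sigma2 = s2)
    rpe_entropy_area_percent(ev, ph$truth$surfaces, ph$truth$fovea[2],
                             ph$truth$fovea[1],
                             ph$jones$lateral_pitch_um)$percent
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_gt(pct[3], 90)
})

hrf_phantom <- function(n = 7, seed = 71, d_hrf = 0.9, snr_db = Inf, ...) {
  sp <- small_eye_spec(n_ascans = 64, n_bscans = 5,
                       fovea_center = c(33, 3),
                       retina_thickness_um = 120,
                       hrf = list(n = n, size_px = 3, power = 30, d = d_hrf,
                                  max_radius_mm = 1.3),
                       snr_db = snr_db, seed = seed, ...)
  ph <- generate_phantom(sp)
  s2 <- if (is.finite(snr_db))
    estimate_noise_power(ph$jones, ph$truth$background_rows) else 0
  iv <- intensity_db(ph$jones, noise_power = max(4 * s2, 1e-12))
  ev <- entropy_volume(ph$jones, kernel = c(3, 3), sigma2 = s2, mask = iv)
  list(ph = ph, iv = iv, ev = ev)
}

test_that("seeded HRF are recovered exactly on noiseless phantoms", {
  r <- hrf_phantom(n = 7)
  tr <- r$ph$truth
  fs <- detect_hrf(r$iv, r$ev, tr$surfaces, bscan = tr$fovea[2],
                   fovea_col = tr$fovea[1],
                   lateral_pitch_um = r$ph$jones$lateral_pitch_um)
  expect_equal(fs$n_hrf, 7)
  # centroids match the seeded positions within the focus size
  hrf <- fs$foci[fs$foci$kind == "HRF", ]
  d <- vapply(seq_len(nrow(tr$hrf)), function(k)
    min(abs(hrf$x - (tr$hrf$x[k] + 0.5)) + abs(hrf$z - (tr$hrf$z[k] + 0.5))),
    numeric(1))
  expect_lt(max(d), 2)
  # strongly depolarizing foci all carry an entropy dot
  expect_equal(fs$n_overlap, fs$n_hrf)
  expect_lte(fs$n_overlap, min(fs$n_hrf, fs$n_dots))
})

test_that("foci outside the 1500 um radius are excluded", {
  r <- hrf_phantom(n = 5, seed = 73)
  tr <- r$ph$truth
  lp <- r$ph$jones$lateral_pitch_um  # 93.75 um at 64 px / 6 mm
  # paint a bright depolarized blob 1600 um temporal to the fovea
  far_x <- tr$fovea[1] + round(1600 / lp)
  zr <- tr$surfaces$z_ilm[far_x, tr$fovea[2]] + 4
  jv2 <- r$ph$jones
  set.seed(1)
  jv2$data[zr:(zr + 2), far_x:(far_x + 2), tr$fovea[2], ] <-
    complex(real = rnorm(36, sd = 6), imaginary = rnorm(36, sd = 6))
  iv2 <- intensity_db(jv2, noise_power = 1e-12)
  ev2 <- entropy_volume(jv2, kernel = c(3, 3), sigma2 = 0, mask = iv2)
  fs <- detect_hrf(iv2, ev2, tr$surfaces, tr$fovea[2], tr$fovea[1], lp)
  expect_equal(fs$n_hrf, 5)  # the far blob does not count
  # at 1500 um the blob's column is 17.07 px away; radius floor(1500/lp) = 16
  expect_true(all(abs(fs$foci$x - tr$fovea[1]) <= 16 + 1))
})

test_that("counting is invariant under a left-right mirror of the volume", {
  r <- hrf_phantom(n = 6, seed = 74)
  tr <- r$ph$truth
  lp <- r$ph$jones$lateral_pitch_um
  fs <- detect_hrf(r$iv, r$ev, tr$surfaces, tr$fovea[2], tr$fovea[1], lp)

  nx <- r$ph$jones$n_ascans
  jm <- jones_volume(r$ph$jones$data[, nx:1, , , drop = FALSE])
  ivm <- intensity_db(jm, noise_power = 1e-12)
  evm <- entropy_volume(jm, kernel = c(3, 3), sigma2 = 0, mask = ivm)
  sm <- polent:::surfaces_object(tr$surfaces$z_ilm[nx:1, , drop = FALSE],
                                 tr$surfaces$z_rpe[nx:1, , drop = FALSE],
                                 tr$surfaces$z_csi[nx:1, , drop = FALSE])
  fsm <- detect_hrf(ivm, evm, sm, tr$fovea[2], nx + 1 - tr$fovea[1], lp)
  expect_equal(fsm$n_hrf, fs$n_hrf)
  expect_equal(fsm$n_dots, fs$n_dots)
  expect_equal(fsm$n_overlap, fs$n_overlap)
})

test_that("seeded counts recover exactly across many seeds", {
  for (seed in 101:115) {
    r <- hrf_phantom(n = 5, seed = seed)
    tr <- r$ph$truth
    fs <- detect_hrf(r$iv, r$ev, tr$surfaces, tr$fovea[2], tr$fovea[1],
                     r$ph$jones$lateral_pitch_um)
    expect_equal(fs$n_hrf, 5)
    expect_lte(fs$n_overlap, min(fs$n_hrf, fs$n_dots))
  }
})
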