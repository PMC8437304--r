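test_that("closed-form mixture entropy has the right endpoints and shape", {
  expect_equal(expected_entropy(0), 0)
  expect_equal(expected_entropy(1), 1)
  expect_equal(expected_entropy(0.5), 0.7743975, tolerance = 1e-6)
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(expected_entropy(d)) > 0))
  expect_error(expected_entropy(1.2), "0, 1")
  # inverse round-trips
  h <- c(0, 0.2, 0.5, 0.77, 0.95, 1)
  expect_equal(expected_entropy(inverse_expected_entropy(h)), h,
               tolerance = 1e-8)
})

test_that("the generator is deterministic under a fixed seed", {
  sp <- small_eye_spec(n_ascans = 48, seed = 99, hrf = list(n = 4))
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$jones$data, b$jones$data)
  expect_identical(a$truth$hrf, b$truth$hrf)
})

test_that("mean layer entropy recovers the closed form across the d sweep", {
  # wide kernel (9x9 = 81 samples) keeps the eigenvalue-spectrum sampling
  # bias below the tolerance; homogeneous volume, interior voxels only
  for (d in c(0, 0.25, 0.5, 0.75, 1)) {
    jv <- mixture_jones(d, nz = 30, nx = 30, ny = 3, seed = 300 + d * 4)
    ev <- entropy_volume(jv, kernel = c(9, 9), sigma2 = 0)
    h <- ev$H[5:26, 5:26, , drop = FALSE]
    expect_lt(abs(mean(h) - expected_entropy(d)), 0.03)
  }
})

test_that("a noiseless uniform retina yields near-zero estimated entropy", {
  sp <- small_eye_spec(d = c(retina = 0, rpe = 0.6, choroid = 0.3),
                       snr_db = Inf, seed = 2)
  ph <- generate_phantom(sp)
  ev <- entropy_volume(ph$jones, kernel = c(3, 3), sigma2 = 0)
  # interior voxels: windows of boundary rows straddle neighbouring layers
  in_ret <- ph$truth$labels == 1L
  nz <- dim(in_ret)[1]
  core <- in_ret
  core[] <- FALSE
  core[2:(nz - 1), , ] <- in_ret[2:(nz - 1), , ] & in_ret[1:(nz - 2), , ] &
    in_ret[3:nz, , ]
  expect_lt(mean(ev$H[core], na.rm = TRUE), 0.02)
})

test_that("RPE entropy at full depolarization approaches one", {
  sp <- small_eye_spec(n_ascans = 48,
                       d = c(retina = 0.02, rpe = 1, choroid = 0.3),
                       snr_db = Inf, seed = 3)
  ph <- generate_phantom(sp)
  # a 3 x 27 kernel stays inside the 6 px RPE band axially while drawing
  # 81 samples laterally
  ev <- entropy_volume(ph$jones, kernel = c(3, 27), sigma2 = 0)
  zr <- ph$truth$surfaces$z_rpe[1, 1]
  h <- ev$H[(zr - 2):(zr + 1), 14:35, , drop = FALSE]
  expect_lt(abs(mean(h) - 1), 0.02)
})

test_that("phantom geometry is consistent and the fovea is recoverable", {
  sp <- small_eye_spec(seed = 12)
  ph <- generate_phantom(sp)
  tr <- ph$truth$surfaces
  expect_true(all(tr$z_ilm < tr$z_rpe - 3))
  expect_true(all(tr$z_rpe + 3 < tr$z_csi))
  an <- analyze_jones_volume(ph$jones,
                             background_rows = ph$truth$background_rows)
  expect_lte(max(abs(an$fovea - ph$truth$fovea)), 2)

  # impossible geometry errors out
  expect_error(generate_phantom(small_eye_spec(retina_thickness_um = 20,
                                               pit_depth_um = 0)),
               "inconsistent surfaces")
})

test_that("sector edema raises that sector's true thickness by the set amount", {
  sp <- phantom_spec(nz = 200, n_ascans = 128, n_bscans = 128,
                     ilm_depth_um = 200, retina_thickness_um = 300,
                     pit_depth_um = 100, choroid_thickness_um = 80,
                     edema_um = c(TI = 150), seed = 5)
  surf <- polent:::phantom_surfaces(sp)
  th <- (surf$z_rpe - surf$z_ilm) * sp$axial_pitch_um
  lp <- sp$scan_width_mm * 1000 / sp$n_ascans
  g <- etdrs_grid(sp$fovea_center, lp, "OD", c(128, 128))
  # evaluate on the sector plateau (away from the smoothed roll-off at the
  # sector boundary) using a distance map
  plateau <- function(m) EBImage::distmap(m * 1) > 7
  expect_lt(abs(mean(th[plateau(g$sector_masks$TI)]) -
                mean(th[plateau(g$sector_masks$NI)]) - 150), 10)
})

test_that("longitudinal schedules apply only inside irradiated sectors", {
  sp <- cohort_eye_spec(seed = 8)
  expect_error(longitudinal_series(sp, irradiated_sectors = "XX"),
               "unknown sector label")
  expect_error(longitudinal_series(sp, timepoints = c("baseline", "1m"),
                                   d_rpe_schedule = c(0.6, 0.4, 0.2)),
               "schedule length")

  ser <- longitudinal_series(sp, timepoints = c("baseline", "1m", "2m"),
                             irradiated_sectors = "TI",
                             d_rpe_schedule = c(0.6, 0.45, 0.3),
                             d_jitter_sd = 0, seed = 8)
  irr <- ser$grid$sector_masks$TI
  for (i in seq_along(ser$timepoints)) {
    dmap <- ser$phantoms[[i]]$truth$spec$d_rpe_map
    expect_true(all(dmap[irr] == ser$d_rpe_schedule[i]))
    expect_true(all(dmap[!irr] == sp$d[["rpe"]]))
  }
  # series regeneration is reproducible, including the visit jitter path
  ser2 <- longitudinal_series(sp, timepoints = c("baseline", "1m", "2m"),
                              irradiated_sectors = "TI",
                              d_rpe_schedule = c(0.6, 0.45, 0.3), seed = 8)
  ser3 <- longitudinal_series(sp, timepoints = c("baseline", "1m", "2m"),
                              irradiated_sectors = "TI",
                              d_rpe_schedule = c(0.6, 0.45, 0.3), seed = 8)
  expect_identical(ser2$phantoms$`2m`$jones$data,
                   ser3$phantoms$`2m`$jones$data)
  expect_identical(ser2$d_jitter, ser3$d_jitter)
})

test_that("a null longitudinal series leaves sector entropy stable", {
  sp <- cohort_eye_spec(seed = 40)
  ser <- longitudinal_series(sp, timepoints = c("baseline", "3m"),
                             d_jitter_sd = 0, seed = 40)
  vals <- vapply(ser$phantoms, function(ph) {
    an <- analyze_jones_volume(ph$jones,
                               background_rows = ph$truth$background_rows)
    sm <- sector_means(an$maps$rpe, ser$grid)
    sm$mean[sm$sector == "whole_grid"]
  }, numeric(1))
  expect_lt(abs(diff(vals)), 0.02)
})
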