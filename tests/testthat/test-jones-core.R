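test_that("intensity is dB over the noise floor with a detection mask", {
  jv <- uniform_jones(J = c(1, 0, 0, 1))  # |J|_F^2 = 2 per voxel
  iv <- intensity_db(jv, floor_db = 3, noise_power = 1)
  expect_equal(unname(iv$I_db[1, 1, 1]), 10 * log10(2), tolerance = 1e-12)
  expect_true(all(iv$detection_mask))

  # a dark voxel falls below any finite floor
  jv$data[2, 3, 1, ] <- 0
  iv <- intensity_db(jv, floor_db = -100, noise_power = 1)
  expect_false(iv$detection_mask[2, 3, 1])
  expect_true(iv$detection_mask[1, 1, 1])

  zero <- jones_volume(array(complex(real = 0), c(4, 4, 2, 4)))
  expect_error(intensity_db(zero), "empty signal")
})

test_that("a 100:1 layer power ratio maps to a 20 dB difference", {
  data <- array(complex(real = 0), c(10, 6, 2, 4))
  data[1:5, , , 1] <- 10   # power 100
  data[6:10, , , 1] <- 1   # power 1
  iv <- intensity_db(jones_volume(data), noise_power = 1)
  expect_equal(mean(iv$I_db[1:5, , ]) - mean(iv$I_db[6:10, , ]), 20,
               tolerance = 1e-12)
})

test_that("noise power estimation recovers the per-element variance", {
  # noiseless region
  data <- array(complex(real = 0), c(10, 8, 4, 4))
  data[6:10, , , ] <- 1
  jv <- jones_volume(data)
  expect_equal(estimate_noise_power(jv, 1:5), 0)
  expect_error(estimate_noise_power(jv, integer(0)), "empty")

  # complex Gaussian noise with per-element variance 0.25
  set.seed(42)
  n <- 50 * 50 * 50
  noisy <- jones_volume(array(
    complex(real = rnorm(4 * n, sd = sqrt(0.125)),
            imaginary = rnorm(4 * n, sd = sqrt(0.125))), c(50, 50, 50, 4)))
  expect_equal(estimate_noise_power(noisy, 1:50), 0.25, tolerance = 0.01)

  # region dipping into signal is flagged and overestimates
  mixed <- jones_volume(data + noisy$data[1:10, 1:8, 1:4, ] * 0.5)
  expect_warning(s2 <- estimate_noise_power(mixed, 1:10), "overlap")
  expect_gt(s2, 0.25 * 0.25)  # scaled noise variance alone is 0.0625
})

test_that("uniform fields have zero entropy; known spectra match closed forms", {
  ev <- entropy_volume(uniform_jones(), kernel = c(3, 3), sigma2 = 0)
  expect_true(all(ev$valid))
  expect_equal(max(abs(ev$H)), 0, tolerance = 1e-10)

  # two equally weighted orthogonal states: H = log4(2) = 0.5
  expect_equal(coherency_entropy(diag(c(0.5, 0.5, 0, 0)) + 0i), 0.5,
               tolerance = 1e-12)
  # completely random polarization
  expect_equal(coherency_entropy(diag(4) / 4 + 0i), 1, tolerance = 1e-12)
  # mixing model at d = 0.5: spectrum (0.625, 0.125, 0.125, 0.125)
  expect_equal(expected_entropy(0.5),
               oracle_spectrum_entropy(c(0.625, 0.125, 0.125, 0.125)),
               tolerance = 1e-12)
  expect_equal(expected_entropy(0.5), 0.7743975, tolerance = 1e-6)
})

test_that("entropy volume input contracts are enforced", {
  jv <- uniform_jones()
  expect_error(entropy_volume(jv, kernel = c(2, 3)), "odd")
  expect_error(entropy_volume(jv, kernel = c(99, 3)), "larger than volume")
  expect_error(entropy_volume(jv, sigma2 = -1), "sigma2")
  expect_error(jones_volume(array(NaN + 0i, c(2, 2, 2, 4))), "finite")
})

test_that("depolarization mask uses a strict threshold and respects validity", {
  H <- array(0.1, c(4, 5, 2))
  ev <- manual_entropy_volume(H)
  expect_false(any(depolarization_mask(ev, 0.1)))  # H = 0.1 exactly
  ev$H[1, 1, 1] <- 0.1 + 1e-9
  expect_true(depolarization_mask(ev, 0.1)[1, 1, 1])
  ev$valid[1, 1, 1] <- FALSE
  expect_false(depolarization_mask(ev, 0.1)[1, 1, 1])

  # zero-entropy volume
  ev0 <- entropy_volume(uniform_jones())
  expect_false(any(depolarization_mask(ev0)))
})

test_that("depolarizing RPE separates from quiet retina at SNR 30 dB", {
  sp <- small_eye_spec(d = c(retina = 0.01, rpe = 0.9, choroid = 0.3),
                       seed = 11)
  ph <- generate_phantom(sp)
  s2 <- estimate_noise_power(ph$jones, ph$truth$background_rows)
  ev <- entropy_volume(ph$jones, kernel = c(3, 3), sigma2 = s2)
  mask <- depolarization_mask(ev, 0.1)
  lab <- ph$truth$labels
  # interior voxels only: kernel windows must not straddle layer boundaries
  zr <- ph$truth$surfaces$z_rpe[1, 1]
  rpe_core <- lab == 2L & slice.index(lab, 1) >= zr - 2 &
    slice.index(lab, 1) <= zr + 1
  in_retina <- lab == 1L
  ret_core <- in_retina
  ret_core[] <- FALSE
  nz <- dim(lab)[1]
  ret_core[3:(nz - 2), , ] <- in_retina[3:(nz - 2), , ] &
    in_retina[1:(nz - 4), , ] & in_retina[5:nz, , ]
  expect_gt(mean(mask[rpe_core]), 0.99)
  expect_lt(mean(mask[ret_core]), 0.01)
})
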