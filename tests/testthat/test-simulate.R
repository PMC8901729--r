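test_that("square-wave motion alternates between plateaus the stated distance apart", {
  m <- list(kind = "square_wave", amplitude_mm = c(26, 0), freq_hz = 0.33,
            rise_time_s = 0.1)
  d0 <- displacementAt(0, m)
  expect_equal(d0$dx_mm, 0)
  expect_equal(d0$dy_mm, 0)
  dmid <- displacementAt(1 / (2 * 0.33), m)   # mid-plateau of the other state
  expect_equal(dmid$dx_mm, 26)
  # zero amplitude: identically zero at all times
  mz <- m; mz$amplitude_mm <- c(0, 0)
  tt <- seq(0, 10, by = 0.05)
  expect_true(all(displacementAt(tt, mz)$dx_mm == 0))
  # bounded and continuous
  dx <- displacementAt(tt, m)$dx_mm
  expect_true(all(dx >= 0 & dx <= 26))
  expect_lt(max(abs(diff(dx))), 26 * 0.05 / 0.1 * 1.2)
})

test_that("sinusoidal motion reaches its amplitude a quarter period in", {
  m <- list(kind = "resp_cardiac", resp_amp_mm = c(4.5, 2.12),
            resp_freq_hz = 0.25, card_amp_mm = c(0, 0), card_freq_hz = 0.825,
            card_phase = 0)
  expect_equal(displacementAt(0, m)$dx_mm, 0)
  expect_equal(displacementAt(1, m)$dx_mm, 4.5)      # quarter period of 0.25 Hz
  expect_equal(displacementAt(1, m)$dy_mm, 2.12)
})

test_that("the in-vivo-like trace filters to the configured respiratory amplitude", {
  # amplitudes (4.5, 2.12) resp + (1.92, 1.52) cardiac; the low-pass (0.377 Hz)
  # component of the analytic trace must carry the respiratory amplitude,
  # attenuated only by the filter's own gain at 0.25 Hz
  m <- list(kind = "resp_cardiac", resp_amp_mm = c(4.5, 2.12),
            resp_freq_hz = 0.25, card_amp_mm = c(0, 0),
            card_freq_hz = 0.825, card_phase = pi / 3)
  fs <- 1 / (2 * 0.02414)
  tt <- seq(0, 60, by = 1 / fs)
  x <- displacementAt(tt, m)$dx_mm
  lp <- gaussianLowpass(x - mean(x), 0.377, fs)
  gain <- 2^(-(0.25 / 0.377)^2 / 2)  # analytic Gaussian response at 0.25 Hz
  core <- lp[tt > 5 & tt < 55]
  expect_equal(max(abs(core)), 4.5 * gain, tolerance = 0.02)
})

test_that("scene construction validates hotspot geometry and is deterministic", {
  expect_error(makeScene(sceneConfig("phantom", n_pix = 48L,
                                     hotspot = list(center_mm = c(500, 0)))),
               "outside the FoV")
  expect_error(makeScene(sceneConfig("phantom", n_pix = 48L,
                                     hotspot = list(sigma_mm = -2))),
               "sigma")
  s1 <- makeScene(sceneConfig("phantom", n_pix = 48L, seed = 9))
  s2 <- makeScene(sceneConfig("phantom", n_pix = 48L, seed = 9))
  expect_identical(s1@magnitude, s2@magnitude)
  expect_identical(s1@sensitivities, s2@sensitivities)
  expect_true(all(s1@magnitude >= 0))
})

test_that("opposed spokes of a real object sample mirrored conjugate values", {
  s <- staticScene()
  sc <- s$scene
  sc@sensitivities <- array(1 + 0i, dim(sc@sensitivities))
  sc@background_phase_model$static[] <- 0
  sc@background_phase_model$motion_coupled[] <- 0
  sc@drift_rad_per_s <- 0
  k <- simulateAcquisition(sc, s$params, 2L, seed = 1, angles_deg = c(0, 180),
                           noise_sigma = 0)
  n <- s$params@n_readout
  s0 <- k@data[1, , 1]; s180 <- k@data[2, , 1]
  # k-locations mirror, so values mirror; Hermitian symmetry for a real object
  expect_lt(max(abs(s180[2:n] - rev(s0[2:n]))) / max(abs(s0)), 1e-12)
  expect_lt(max(abs(s180[2:n] - Conj(rev(Conj(s0[2:n])))))/ max(abs(s0)), 1e-12)
})

test_that("a rigidly shifted scene equals the static scene times the shift-theorem ramp", {
  s <- staticScene()
  p <- s$params
  ks <- simulateAcquisition(s$scene, p, 40L, seed = 1, noise_sigma = 0)
  kst <- simulateAcquisition(s$scene, p, 40L, seed = 1,
                             extra_shift_mm = c(7.3, -4.1), noise_sigma = 0)
  kr <- buildTrajectory(ks@angles_deg, p)@kr
  rho <- (ks@angles_deg %% 360) * pi / 180
  u <- (7.3 * cos(rho) - 4.1 * sin(rho)) / p@fov_mm
  ramp <- exp(-2i * pi * outer(u, kr))
  for (ch in c(1, dim(ks@data)[3])) {
    expect_lt(relErr(kst@data[, , ch], ks@data[, , ch] * ramp), 1e-6)
  }
})

test_that("simulated noise is calibrated and seeded deterministically", {
  s <- staticScene()
  scz <- s$scene
  scz@magnitude[] <- 0
  scz@coil_model$amplitude <- 0
  kz <- simulateAcquisition(scz, s$params, 50L, seed = 2, noise_sigma = 0.37)
  expect_equal(sd(Re(kz@data)), 0.37, tolerance = 0.05)
  expect_equal(sd(Im(kz@data)), 0.37, tolerance = 0.05)
  ka <- simulateAcquisition(s$scene, s$params, 10L, seed = 5)
  kb <- simulateAcquisition(s$scene, s$params, 10L, seed = 5)
  expect_identical(ka@data, kb@data)
})

test_that("ground-truth series follows the parametric ramp exactly", {
  px <- 220 / 48
  sc <- makeScene(sceneConfig("phantom", n_pix = 48L, seed = 2,
                              hotspot = list(t_start_s = 10, t_ramp_s = 20,
                                             peak_degC = 30,
                                             center_mm = c(6 * px, -3 * px))))
  gt <- groundTruthSeries(sc, c(5, 20, 30))
  expect_equal(max(abs(gt@deltaT[, , 1])), 0)          # before ramp start
  expect_equal(max(gt@deltaT[, , 2]), 15, tolerance = 1e-6)   # mid-ramp
  expect_equal(max(gt@deltaT[, , 3]), 30, tolerance = 1e-6)   # ramp end
})

test_that("mismatched scene grid and params are rejected", {
  s <- staticScene()
  p_bad <- acquisitionParams(n_readout = 96L, matrix_size = 48L)
  expect_error(simulateAcquisition(s$scene, p_bad, 5L), "inconsistent")
})
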