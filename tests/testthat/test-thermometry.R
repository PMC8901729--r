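test_that("phase-to-temperature conversion matches the closed-form constant", {
  p <- acquisitionParams()   # TE 20 ms, 1.5 T, alpha -0.01 ppm/degC
  # |2 pi gamma B0 alpha 1e-6 TE| = 0.08026 rad per degC
  expect_equal(abs(prfRadPerDegC(p)), 0.08026, tolerance = 1e-4)
  expect_equal(phaseToTemperature(0, p), 0)
  expect_equal(phaseToTemperature(-0.08026, p), 1.000, tolerance = 1e-3)
  # linearity
  th <- matrix(c(-0.1, 0.05, 0, -0.2), 2)
  expect_equal(phaseToTemperature(2 * th, p), 2 * phaseToTemperature(th, p))
  p0 <- p; p0@prf_alpha_ppm_per_degC <- 0
  expect_error(phaseToTemperature(1, p0), "alpha")
})

test_that("image-domain fit recovers injected phase components", {
  sl <- staticLibrary()
  lib <- sl$lib; pb <- sl$basis
  nch <- dim(lib@images)[4]
  x1 <- array(lib@images[, , 1, ], c(64, 64, nch))
  prf <- prfRadPerDegC(sl$params)
  # identity: y = x_1 exactly
  fit0 <- imageDomainFit(x1, lib, pb)
  expect_equal(as.vector(fit0$w), 1, tolerance = 1e-6)
  expect_lt(max(abs(fit0$theta)), 1e-8)
  expect_lt(max(abs(fit0$c)), 1e-8)
  # known smooth hotspot phase: recovered to 1e-3 rad (noiseless)
  th_true <- prf * hotspotDeltaT(sl$scene, 45)   # includes ramp fraction
  y <- x1 * array(exp(1i * rep(th_true, nch)), dim(x1))
  fit <- imageDomainFit(y, lib, pb, sign_constraint = -1)
  strong <- fit$mask & abs(x1[, , 1]) > 0.1 * max(abs(x1[, , 1]))
  expect_lt(max(abs(fit$theta - th_true)[strong]), 1e-3)
  # background-only polynomial phase: absorbed by c, theta stays zero
  cstar <- rep(0, 28); cstar[2] <- 0.4; cstar[5] <- -0.25
  phi <- matrix(pb@basis %*% cstar, 64, 64)
  y2 <- x1 * array(exp(1i * rep(phi, nch)), dim(x1))
  fit2 <- imageDomainFit(y2, lib, pb)
  expect_lt(max(abs(fit2$theta[strong])), 1e-8)
  expect_equal(as.vector(fit2$c), cstar, tolerance = 1e-6)
  # all-zero library errors
  lib0 <- lib; lib0@images[] <- 0i
  expect_error(imageDomainFit(y, lib0, pb), "zero")
})

test_that("the k-space fit agrees with the image-domain oracle when fully sampled", {
  sl <- staticLibrary()
  s <- sl$scene; p <- sl$params
  nch <- dim(sl$lib@images)[4]
  sc <- s
  sc@hotspot_model$t_start_s <- 5
  sc@hotspot_model$t_ramp_s <- 10
  sc@hotspot_model$peak_degC <- 15
  kh <- simulateAcquisition(sc, p, 160L, seed = 9, start_index = 700L,
                            noise_sigma = 0)
  khc <- applyChannelModel(kh, sl$model)
  sp <- array(0i, c(p@n_readout, 160, nch))
  for (ci in seq_len(nch)) sp[, , ci] <- t(khc@data[, , ci])
  traj <- buildTrajectory(khc@angles_deg, p)
  cfg0 <- fitConfig(lambda = 0, beta = 0, window_spokes = 160L,
                    max_outer = 60L, tol = 1e-4, inner_theta = 8L)
  fitk <- kspaceFit(sp, traj, sl$lib, pb <- sl$basis, cfg0, p)
  plan <- nufftPlan(traj, 64L)
  img <- array(0i, c(64, 64, nch))
  for (ci in seq_len(nch)) img[, , ci] <- nufftInverse(sp[, , ci], plan)
  fiti <- imageDomainFit(img, sl$lib, sl$basis, sign_constraint = -1)
  magB <- abs(sl$lib@images[, , 1, 1])
  strong <- fitk$mask & magB > 0.2 * max(magB)
  expect_lt(max(abs(fitk$theta - fiti$theta)[strong]), 1e-2)
})

test_that("an unheated undersampled window yields near-zero temperature", {
  sl <- staticLibrary()
  p <- sl$params
  nch <- dim(sl$lib@images)[4]
  kh <- simulateAcquisition(sl$scene, p, 40L, seed = 10, start_index = 500L)
  khc <- applyChannelModel(kh, sl$model)
  sp <- array(0i, c(p@n_readout, 40, nch))
  for (ci in seq_len(nch)) sp[, , ci] <- t(khc@data[, , ci])
  traj <- buildTrajectory(khc@angles_deg, p)
  cfg <- fitConfig(resolution_mm = 3, window_spokes = 40L)
  fit <- kspaceFit(sp, traj, sl$lib, sl$basis, cfg, p)
  dT <- phaseToTemperature(fit$theta, p)
  magB <- abs(sl$lib@images[, , 1, 1])
  strong <- fit$mask & magB > 0.2 * max(magB)
  # consistent with noise (no systematic heating): the sign constraint
  # rectifies the noise, so the median stays small and only isolated voxels
  # reach the heavy phase-noise tail
  expect_lt(median(abs(dT[strong])), 1.5)
  expect_lt(mean(abs(dT[strong]) > 10), 0.02)
  # the baseline weights concentrate on a valid combination
  expect_equal(sum(fit$w), 1, tolerance = 0.2)
})

test_that("frame windows advance at the printed temporal resolutions", {
  sl <- staticLibrary()
  p <- sl$params
  k <- simulateAcquisition(sl$scene, p, 260L, seed = 11, start_index = 400L)
  kc <- applyChannelModel(k, sl$model)
  for (spec in list(c(40, 0.9656), c(20, 0.4828), c(30, 0.7242))) {
    cfg <- fitConfig(resolution_mm = 3, window_spokes = as.integer(spec[1]),
                     max_outer = 2L)
    ser <- runSeries(kc, sl$lib, sl$basis, cfg, start_spoke = 1L)
    expect_equal(diff(ser@times_s)[1], spec[2], tolerance = 1e-6)
    expect_equal(ser@window_spokes, as.integer(spec[1]))
  }
  # sliding-window extension: stride 1 updates every TR
  cfg1 <- fitConfig(resolution_mm = 3, window_spokes = 40L, stride_spokes = 1L,
                    max_outer = 1L)
  ser1 <- runSeries(subsetSpokes(kc, 1:45), sl$lib, sl$basis, cfg1,
                    start_spoke = 1L)
  expect_equal(diff(ser1@times_s)[1], p@tr_s, tolerance = 1e-9)
  # window larger than the data stops cleanly
  expect_error(runSeries(subsetSpokes(kc, 1:10), sl$lib, sl$basis,
                         fitConfig(window_spokes = 40L), start_spoke = 1L),
               "does not fit")
})

test_that("the temporal Butterworth filter smooths without distorting steps", {
  p <- acquisitionParams()
  mk <- function(vals) {
    nf <- length(vals)
    th <- array(rep(vals, each = 4), c(2, 2, nf)) * prfRadPerDegC(p)
    new("TemperatureSeries", theta = th,
        deltaT = th / prfRadPerDegC(p),
        times_s = (seq_len(nf) - 1) * 0.9656,
        spoke_idx = vector("list", nf),
        w = matrix(0, 1, nf), c = matrix(0, 1, nf),
        converged = rep(TRUE, nf), window_spokes = 40L,
        stride_spokes = 40L, params = p)
  }
  # constant series unchanged
  cs <- temporalFilter(mk(rep(2.5, 40)))
  expect_equal(as.vector(cs@deltaT[1, 1, ]), rep(2.5, 40), tolerance = 1e-2)
  # contamination at 0.35 Hz is attenuated per the order-4 response
  tt <- (0:79) * 0.9656
  contam <- sin(2 * pi * 0.35 * tt)
  fser <- temporalFilter(mk(contam))
  gain_th <- 1 / sqrt(1 + (0.35 / 0.14)^(2 * 4))
  core <- 10:70
  expect_lt(max(abs(fser@deltaT[1, 1, core])), 3 * gain_th + 0.02)
  # a heating step stays monotone-ish: overshoot bounded by the step response
  step <- c(rep(0, 30), rep(10, 50))
  fstep <- temporalFilter(mk(step))
  expect_lt(max(fstep@deltaT[1, 1, ]), 10 * 1.2)
  expect_gt(min(fstep@deltaT[1, 1, 45:80]), 9)
  # cutoff above frame Nyquist rejected
  expect_error(temporalFilter(mk(rep(0, 40)), cutoff_hz = 0.6), "Nyquist")
})

test_that("ROI uncertainty summarises the temporal SD over the stated span", {
  p <- acquisitionParams()
  nf <- 60L
  set.seed(3)
  th <- array(0, c(4, 4, nf))
  sds <- matrix(runif(16, 0.5, 1.5), 4)
  for (f in seq_len(nf)) th[, , f] <- rnorm(16, sd = sds)
  ser <- new("TemperatureSeries", theta = th * prfRadPerDegC(p), deltaT = th,
             times_s = 50 + seq_len(nf) * 0.9656,
             spoke_idx = vector("list", nf), w = matrix(0, 1, nf),
             c = matrix(0, 1, nf), converged = rep(TRUE, nf),
             window_spokes = 40L, stride_spokes = 40L, params = p)
  roi <- matrix(TRUE, 4, 4)
  rs <- roiUncertainty(ser, roi, 50, Inf)
  # per-voxel sample SDs concentrate around the true SDs (chi distribution)
  expect_equal(rs@mean_sd, mean(sds), tolerance = 0.1)
  expect_equal(rs@n_frames, nf)
  # constant series: exactly zero
  ser0 <- ser; ser0@deltaT[] <- 1.23
  rs0 <- roiUncertainty(ser0, roi, 50, Inf)
  expect_equal(rs0@mean_sd, 0)
  expect_equal(rs0@sd_sd, 0)
  # empty span errors
  expect_error(roiUncertainty(ser, roi, 500, 600), "no frames")
})
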