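test_that("coil profiles peak at the projected coil position", {
  s <- staticScene()
  p <- s$params
  k <- simulateAcquisition(s$scene, p, 6L, seed = 1, noise_sigma = 0)
  prox <- which(channelRoles(k) == "microcoil_proximal")
  pos0 <- s$scene@microcoil_positions[1, ]
  for (i in 1:3) {
    pr <- smoothAndLocate(coilProfile(k@data[i, , prox], k@angles_deg[i], p, i))
    rho <- (k@angles_deg[i] %% 360) * pi / 180
    expect_true(pr@valid)
    expect_equal(pr@peak_mm, pos0[1] * cos(rho) + pos0[2] * sin(rho),
                 tolerance = 0.5 * p@fov_mm / p@matrix_size)
  }
  # a pure complex exponential spoke is a single-pixel peak at its frequency
  n <- p@n_readout
  kr <- buildTrajectory(0, p)@kr
  u0 <- 10 / p@fov_mm                      # 10 mm
  pr <- coilProfile(exp(-2i * pi * kr * u0), 0, p)
  expect_equal(pr@positions_mm[which.max(pr@profile)], 10,
               tolerance = p@fov_mm / p@matrix_size)
  # all-zero spoke flags an invalid peak
  przero <- smoothAndLocate(coilProfile(rep(0i, n), 0, p))
  expect_false(przero@valid)
})

test_that("peak location handles symmetric, split and delta peaks", {
  p <- acquisitionParams(n_readout = 128L, matrix_size = 64L)
  pos <- radialtherm:::profilePositions(p)
  px <- pos[2] - pos[1]
  g <- function(c0, s) exp(-(pos - c0)^2 / (2 * s^2))
  # symmetric single peak: barycentre at its centre
  pr <- new("CoilProfile", profile = g(12.1, 3 * px), positions_mm = pos,
            angle_deg = 0, spoke_index = 1L, peak_mm = NA_real_,
            peak_intensity = NA_real_, valid = TRUE)
  expect_equal(smoothAndLocate(pr)@peak_mm, 12.1, tolerance = 0.05 * px)
  # two equal peaks 2 px apart: midpoint, matching the brute-force
  # weighted mean over the above-threshold support
  c1 <- pos[60]; c2 <- pos[62]
  split <- g(c1, 1.2 * px) + g(c2, 1.2 * px)
  pr@profile <- split
  est <- smoothAndLocate(pr)@peak_mm
  sm <- radialtherm:::gaussSmooth(split, 2)
  above <- sm >= max(sm) / 2
  brute <- sum(pos[above] * sm[above]) / sum(sm[above])
  expect_equal(est, brute, tolerance = 0.2 * px)
  expect_equal(est, (c1 + c2) / 2, tolerance = 0.1 * px)
  # delta at a sample position
  d <- numeric(length(pos)); d[40] <- 1
  pr@profile <- d
  expect_equal(smoothAndLocate(pr)@peak_mm, pos[40], tolerance = 1e-6)
  # flat profile is invalid
  pr@profile <- rep(1, length(pos))
  expect_false(smoothAndLocate(pr)@valid)
})

test_that("two-projection localization inverts the projection geometry", {
  # axis-aligned pair
  loc <- localizePair(3.2, -1.7, 0, 90)
  expect_equal(c(loc$x_mm, loc$y_mm), c(3.2, -1.7))
  # coil at centre: zero for any angle pair
  loc0 <- localizePair(0, 0, 37.3, 148.55)
  expect_equal(c(loc0$x_mm, loc0$y_mm), c(0, 0))
  # golden-angle pair: forward-project then solve recovers exactly
  xy <- c(10, -5)
  r1 <- 0; r2 <- 111.25
  p1 <- xy[1] * cos(r1 * pi / 180) + xy[2] * sin(r1 * pi / 180)
  p2 <- xy[1] * cos(r2 * pi / 180) + xy[2] * sin(r2 * pi / 180)
  loc2 <- localizePair(p1, p2, r1, r2)
  expect_lt(max(abs(c(loc2$x_mm, loc2$y_mm) - xy)), 1e-9)
  # property: round trip over random positions and angle pairs
  set.seed(4)
  for (i in 1:25) {
    xy <- runif(2, -60, 60)
    r1 <- runif(1, 0, 360); r2 <- r1 + 111.246
    p1 <- xy[1] * cos(r1 * pi / 180) + xy[2] * sin(r1 * pi / 180)
    p2 <- xy[1] * cos(r2 * pi / 180) + xy[2] * sin(r2 * pi / 180)
    loc <- localizePair(p1, p2, r1, r2)
    expect_lt(max(abs(c(loc$x_mm, loc$y_mm) - xy)), 1e-9)
  }
  # near-parallel projections are flagged invalid
  expect_false(localizePair(1, 1, 10, 10 + 180)$valid)
  # the back-projection diagnostic agrees with the algebraic solution
  pos <- radialtherm:::profilePositions(acquisitionParams(n_readout = 256L,
                                                          matrix_size = 128L))
  mk <- function(c0, ang) new("CoilProfile",
    profile = exp(-(pos - c0)^2 / (2 * 9)), positions_mm = pos,
    angle_deg = ang, spoke_index = 1L, peak_mm = NA_real_,
    peak_intensity = NA_real_, valid = TRUE)
  r1 <- 20; r2 <- r1 + 111.25; xy <- c(14, -22)
  pp <- c(xy[1] * cos(r1 * pi/180) + xy[2] * sin(r1 * pi/180),
          xy[1] * cos(r2 * pi/180) + xy[2] * sin(r2 * pi/180))
  sm <- radonSpotMap(mk(pp[1], r1), mk(pp[2], r2), n_grid = 220L, fov_mm = 220)
  expect_lt(max(abs(sm$argmax_mm - xy)), 2 * 220 / 220)
})

test_that("angle-dependent bias is fitted and removed", {
  n <- 600
  ang <- goldenAngles(n)
  th <- (ang %% 360) * pi / 180
  base <- new("MotionTrace", times_s = (seq_len(n) - 1) * 0.04828,
              x_mm = rep(5, n), y_mm = rep(-2, n),
              z_intensity = rep(1, n), valid = rep(TRUE, n),
              variant = "raw", tr_s = 0.02414)
  # bias-free: unchanged within fit tolerance
  out0 <- debiasPositions(base, ang)
  expect_lt(max(abs(out0@x_mm - base@x_mm)), 1e-9)
  # injected sinusoidal angle bias of 0.5 mm: residual < 0.05 mm
  biased <- base
  biased@x_mm <- base@x_mm + 0.5 * sin(2 * th + 0.3)
  out <- debiasPositions(biased, ang)
  expect_lt(max(abs(out@x_mm - 5)), 0.05)
  expect_equal(mean(out@x_mm), 5, tolerance = 1e-3)
  # noisy static trace: debiasing cannot increase the spread
  set.seed(2)
  noisy <- base
  noisy@x_mm <- base@x_mm + 0.3 * sin(3 * th) + rnorm(n, sd = 0.1)
  expect_lte(sd(debiasPositions(noisy, ang)@x_mm), sd(noisy@x_mm))
  # insufficient coverage: warning and identity
  short <- new("MotionTrace", times_s = 1:6, x_mm = rnorm(6), y_mm = rnorm(6),
               z_intensity = rep(1, 6), valid = rep(TRUE, 6),
               variant = "raw", tr_s = 0.02414)
  expect_warning(debiasPositions(short, goldenAngles(6)), "coverage")
})

test_that("the Gaussian low-pass has the stated -3 dB response", {
  fs <- 1 / 0.04828
  tt <- seq(0, 80, by = 1 / fs)
  # DC gain one
  expect_equal(gaussianLowpass(rep(3.3, length(tt)), 0.883, fs),
               rep(3.3, length(tt)), tolerance = 1e-9)
  # amplitude 1/sqrt(2) at the cutoff, within 2 %
  for (fc in c(0.883, 0.377)) {
    y <- gaussianLowpass(sin(2 * pi * fc * tt), fc, fs)
    core <- y[tt > 10 & tt < 70]
    expect_equal(max(abs(core)), 1 / sqrt(2), tolerance = 0.02)
  }
  # strong attenuation two octaves up
  y4 <- gaussianLowpass(sin(2 * pi * 4 * 0.377 * tt), 0.377, fs)
  expect_lt(max(abs(y4[tt > 10 & tt < 70])), 0.05)
  # cutoff at/above Nyquist is rejected
  expect_error(gaussianLowpass(sin(tt), fs / 2, fs), "Nyquist")
})

test_that("motion decomposition routes frequencies to the right components", {
  fs <- 1 / 0.04828
  tt <- seq(0, 60, by = 1 / fs)
  n <- length(tt)
  mk <- function(x) new("MotionTrace", times_s = tt, x_mm = x,
                        y_mm = rep(0, n), z_intensity = rep(1, n),
                        valid = rep(TRUE, n), variant = "raw", tr_s = 0.02414)
  # pure respiratory-band sinusoid: stays in respiratory, cardiac residual small
  d1 <- decomposeMotion(mk(sin(2 * pi * 0.25 * tt)))
  core <- tt > 5 & tt < 55
  expect_gt(max(abs(d1$respiratory@x_mm[core])), 0.75)
  # the small cardiac residual equals the difference of the two filter gains
  resid <- 2^(-(0.25 / 0.883)^2 / 2) - 2^(-(0.25 / 0.377)^2 / 2)
  expect_equal(max(abs(d1$cardiac@x_mm[core])), resid, tolerance = 0.02)
  # pure cardiac-band sinusoid: appears in cardiac at the filtered gain
  d2 <- decomposeMotion(mk(sin(2 * pi * 0.825 * tt)))
  g_med <- 2^(-(0.825 / 0.883)^2 / 2)
  g_low <- 2^(-(0.825 / 0.377)^2 / 2)
  expect_equal(max(abs(d2$cardiac@x_mm[core])), g_med - g_low,
               tolerance = 0.08)
  # zero trace: all zero
  d0 <- decomposeMotion(mk(rep(0, n)))
  expect_true(all(abs(d0$filtered@x_mm) < 1e-12))
  # linearity of the decomposition
  x1 <- sin(2 * pi * 0.2 * tt); x2 <- cos(2 * pi * 0.9 * tt)
  dsum <- decomposeMotion(mk(x1 + x2))
  dsep <- decomposeMotion(mk(x1))$filtered@x_mm +
    decomposeMotion(mk(x2))$filtered@x_mm
  expect_equal(dsum$filtered@x_mm, dsep - mean(dsep) + mean(dsum$filtered@x_mm),
               tolerance = 1e-9)
  # filtered variants are mean-centred
  expect_lt(abs(mean(d2$filtered@x_mm)), 1e-6)
  expect_lt(abs(mean(d2$respiratory@x_mm)), 1e-6)
})

test_that("catheter tracking recovers square-wave and static motion", {
  # noiseless static coil: localisation SD below 1e-6 mm
  s <- staticScene()
  k0 <- simulateAcquisition(s$scene, s$params, 200L, seed = 1, noise_sigma = 0)
  m0 <- trackCatheter(k0)
  expect_lt(sd(m0$raw@x_mm), 1e-6)
  expect_lt(sd(m0$raw@y_mm), 1e-6)
  # time spacing is two TR
  expect_equal(diff(m0$raw@times_s)[1], 2 * 0.02414, tolerance = 1e-9)
  # static coil at the configured noise: SD within the 0.3-pixel bound
  k1 <- simulateAcquisition(s$scene, s$params, 400L, seed = 2)
  m1 <- trackCatheter(k1)
  px <- s$params@fov_mm / s$params@matrix_size
  expect_lte(sd(m1$raw@x_mm), 0.3 * px)
  expect_lte(sd(m1$raw@y_mm), 0.3 * px)
  # square-wave phantom: two levels 26 +/- 0.5 mm apart
  scm <- makeScene(sceneConfig("phantom", n_pix = 64L, seed = 3))
  km <- simulateAcquisition(scm, sceneParams(scm), 1200L, seed = 3)
  mm <- trackCatheter(km)
  r <- mm$raw@x_mm
  mid <- mean(range(r))
  sep <- median(r[r > mid]) - median(r[r < mid])
  expect_equal(sep, 26, tolerance = 0.5)
})

test_that("tracking is equivariant under rigid scene translation", {
  s <- staticScene()
  k0 <- simulateAcquisition(s$scene, s$params, 120L, seed = 6, noise_sigma = 0)
  ka <- simulateAcquisition(s$scene, s$params, 120L, seed = 6,
                            extra_shift_mm = c(8, -6), noise_sigma = 0)
  m0 <- trackCatheter(k0); ma <- trackCatheter(ka)
  px <- s$params@fov_mm / s$params@matrix_size
  expect_lt(abs(mean(ma$raw@x_mm) - mean(m0$raw@x_mm) - 8), px / 2)
  expect_lt(abs(mean(ma$raw@y_mm) - mean(m0$raw@y_mm) + 6), px / 2)
})

test_that("projection selection keeps the quiet fraction of the z cycle", {
  fs <- 1 / 0.04828
  tt <- seq(0, 30, by = 1 / fs)
  n <- length(tt)
  # keep_fraction 1: everything kept
  expect_true(all(selectProjections(rep(1, n), 1, fs)))
  # constant z: earliest ties kept
  msk <- selectProjections(rep(2, n), 0.7, fs)
  keep_n <- ceiling(0.7 * n)
  expect_equal(which(msk[seq(1, 2 * n, by = 2)]), seq_len(keep_n))
  # cardiac-modulated z: discarded samples sit on the steep flanks
  z <- cos(2 * pi * 0.825 * tt)
  msk2 <- selectProjections(z, 0.7, fs)
  pair_mask <- msk2[seq(1, 2 * n, by = 2)]
  flank <- abs(sin(2 * pi * 0.825 * tt))     # |dz/dt| up to scale
  expect_gt(mean(flank[!pair_mask]), mean(flank[pair_mask]))
  # invalid keep fraction
  expect_error(selectProjections(z, 0, fs), "keep_fraction")
  expect_error(selectProjections(z, 1.2, fs), "keep_fraction")
})
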