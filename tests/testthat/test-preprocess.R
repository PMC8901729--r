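mkNoiseK <- function(n_spokes, n_read, L, sigma = 1, seed = 1) {
  # multichannel pure-noise acquisition with channel covariance L %*% Conj(t(L))
  set.seed(seed)
  nc <- nrow(L)
  X <- matrix(complex(real = rnorm(n_spokes * n_read * nc, sd = sigma / sqrt(2)),
                      imaginary = rnorm(n_spokes * n_read * nc, sd = sigma / sqrt(2))),
              ncol = nc) %*% t(L)
  dat <- array(0i, c(n_spokes, n_read, nc))
  for (j in seq_len(nc)) dat[, , j] <- matrix(X[, j], n_spokes, n_read)
  p <- acquisitionParams(n_readout = as.integer(n_read),
                         matrix_size = as.integer(n_read / 2))
  radialKspace(dat, goldenAngles(n_spokes), (seq_len(n_spokes) - 1) * p@tr_s,
               rep("imaging", nc), p)
}

test_that("noise covariance is recovered from the readout edges", {
  # known diagonal covariance
  k <- mkNoiseK(400, 256, diag(c(1, 0.5, 2)), seed = 3)
  C <- estimateNoise(k)@covariance
  expect_equal(Re(diag(C)), c(1, 0.25, 4), tolerance = 0.1)
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
  # correlated two-channel noise with known correlation
  rho <- 0.6
  L <- t(chol(matrix(c(1, rho, rho, 1), 2)))
  k2 <- mkNoiseK(400, 256, L, seed = 4)
  C2 <- estimateNoise(k2)@covariance
  expect_equal(Re(C2[1, 2]) / sqrt(Re(C2[1, 1]) * Re(C2[2, 2])), rho,
               tolerance = 0.15)
  # too few samples: warning and identity
  k3 <- mkNoiseK(3, 64, diag(2))
  expect_warning(m3 <- estimateNoise(k3), "1000")
  expect_equal(m3@covariance, diag(2) + 0i)
})

test_that("pre-whitening and PCA compression behave per contract", {
  s <- staticScene()
  k <- simulateAcquisition(s$scene, s$params, 150L, seed = 7)
  # threshold 1: rotation only, channel count preserved
  pw1 <- prewhitenAndCompress(k, estimateNoise(k), 1.0)
  expect_equal(pw1$model@n_out, length(imagingChannels(k)))
  # whitened noise covariance is the identity
  C <- estimateNoise(pw1$k)@covariance
  expect_equal(Re(diag(C)), rep(1, nrow(C)), tolerance = 0.15)
  expect_lt(max(abs(C[upper.tri(C)])), 0.15)
  # whitening idempotence: a second pass changes the data negligibly
  pw2 <- prewhitenAndCompress(pw1$k, estimateNoise(pw1$k), 1.0)
  expect_lt(relErr(pw2$k@data, pw1$k@data), 1e-2)
  # default threshold keeps at least 90 % of the variance in <= all channels
  pw <- prewhitenAndCompress(k, estimateNoise(k), 0.90)
  expect_gte(pw$model@retained_variance, 0.90)
  expect_lte(pw$model@n_out, length(imagingChannels(k)))
  # micro-coil channels pass through unchanged
  expect_identical(pw$k@data[, , pw$model@n_out + 1L],
                   k@data[, , microcoilChannels(k)[1]])
  # invalid thresholds
  expect_error(prewhitenAndCompress(k, estimateNoise(k), 0), "variance_threshold")
  expect_error(prewhitenAndCompress(k, estimateNoise(k), 1.5), "variance_threshold")
})

test_that("two independent sources compress to few channels at 90 %", {
  set.seed(5)
  n <- 4000; nc <- 8
  src <- matrix(rnorm(2 * n) + 1i * rnorm(2 * n), n, 2)
  mix <- matrix(rnorm(2 * nc), 2, nc)
  X <- src %*% mix + 0.01 * (matrix(rnorm(n * nc), n, nc) +
                               1i * matrix(rnorm(n * nc), n, nc))
  dat <- array(0i, c(40, 100, nc))
  for (j in seq_len(nc)) dat[, , j] <- matrix(X[, j], 40, 100)
  p <- acquisitionParams(n_readout = 100L, matrix_size = 50L)
  k <- radialKspace(dat, goldenAngles(40), (0:39) * p@tr_s,
                    rep("imaging", nc), p)
  model <- suppressWarnings(estimateNoise(k))   # tiny fixture: too few edge samples
  model@covariance <- diag(nc) * 1e-4 + 0i      # known near-noiseless floor
  pw <- prewhitenAndCompress(k, model, 0.90)
  expect_lte(pw$model@n_out, 3L)
})

test_that("single-channel input passes through compression unchanged", {
  s <- staticScene()
  k <- simulateAcquisition(s$scene, s$params, 60L, seed = 8)
  d <- k@data[, , c(imagingChannels(k)[1], microcoilChannels(k))]
  k1 <- radialKspace(d, k@angles_deg, k@times_s,
                     c("imaging", "microcoil_proximal", "microcoil_distal"),
                     k@params)
  pw <- suppressWarnings(prewhitenAndCompress(k1, estimateNoise(k1), 0.9))
  expect_equal(pw$model@n_out, 1L)
  expect_lt(relErr(abs(pw$k@data[, , 1]), abs(k1@data[, , 1])), 1e-9)
})

test_that("spoke correction implements the shift theorem exactly", {
  s <- staticScene()
  p <- s$params
  kr <- buildTrajectory(0, p)@kr
  set.seed(1)
  spoke <- rnorm(p@n_readout) + 1i * rnorm(p@n_readout)
  # zero displacement: identity
  expect_identical(correctSpoke(spoke, kr, 37, 0, 0, p@fov_mm), spoke)
  # correction by (d) then (-d): identity to machine precision
  c1 <- correctSpoke(spoke, kr, 37, 3.1, -2.2, p@fov_mm)
  c2 <- correctSpoke(c1, kr, 37, -3.1, 2.2, p@fov_mm)
  expect_lt(relErr(c2, spoke), 1e-12)
  # energy preservation
  expect_equal(sum(abs(c1)^2), sum(abs(spoke)^2), tolerance = 1e-12)
  # correcting a simulator-shifted scene recovers the static-scene spokes
  ks <- simulateAcquisition(s$scene, p, 30L, seed = 1, noise_sigma = 0)
  kst <- simulateAcquisition(s$scene, p, 30L, seed = 1,
                             extra_shift_mm = c(7.3, -4.1), noise_sigma = 0)
  for (i in c(1, 17)) {
    corr <- correctSpoke(kst@data[i, , 1], kr, ks@angles_deg[i], 7.3, -4.1,
                         p@fov_mm)
    expect_lt(relErr(corr, ks@data[i, , 1]), 1e-6)
  }
  # NaN displacement: passthrough with a flag
  flagged <- correctSpoke(spoke, kr, 0, NaN, 0, p@fov_mm)
  expect_true(attr(flagged, "flagged"))
  expect_equal(as.vector(flagged), spoke)
})

test_that("correcting all spokes undoes a constant simulated shift", {
  s <- staticScene()
  p <- s$params
  ks <- simulateAcquisition(s$scene, p, 60L, seed = 2, noise_sigma = 0)
  kst <- simulateAcquisition(s$scene, p, 60L, seed = 2,
                             extra_shift_mm = c(5, 3), noise_sigma = 0)
  n_pairs <- 30L
  tr <- new("MotionTrace",
            times_s = (seq_len(n_pairs) - 0.5) * 2 * p@tr_s,
            x_mm = rep(5, n_pairs), y_mm = rep(3, n_pairs),
            z_intensity = rep(1, n_pairs), valid = rep(TRUE, n_pairs),
            variant = "filtered", tr_s = p@tr_s)
  kc <- correctAll(kst, tr, reference = "zero")
  for (ch in imagingChannels(ks))
    expect_lt(relErr(kc@data[, , ch], ks@data[, , ch]), 1e-6)
  # zero trace: unchanged
  tr0 <- tr; tr0@x_mm[] <- 0; tr0@y_mm[] <- 0
  k0 <- correctAll(kst, tr0, reference = "zero")
  expect_identical(k0@data, kst@data)
  # micro-coil channels are never touched
  expect_identical(kc@data[, , microcoilChannels(ks)],
                   kst@data[, , microcoilChannels(ks)])
  # span mismatch
  trshort <- new("MotionTrace", times_s = 1:5, x_mm = rep(0, 5),
                 y_mm = rep(0, 5), z_intensity = rep(1, 5),
                 valid = rep(TRUE, 5), variant = "filtered", tr_s = p@tr_s)
  expect_error(correctAll(kst, trshort), "cover")
})

test_that("motion correction sharpens the image of a moving scene", {
  scm <- makeScene(sceneConfig("phantom", n_pix = 64L, seed = 6))
  p <- sceneParams(scm)
  k <- simulateAcquisition(scm, p, 600L, seed = 6)
  m <- trackCatheter(k)
  kc <- correctAll(k, m$filtered)
  img_un <- abs(reconstructImage(k)@image)
  img_co <- abs(reconstructImage(kc)@image)
  ge <- function(img) {
    gx <- img[-1, ] - img[-nrow(img), ]
    gy <- img[, -1] - img[, -ncol(img)]
    sum(gx^2) + sum(gy^2)
  }
  expect_gt(ge(img_co), ge(img_un))
})
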