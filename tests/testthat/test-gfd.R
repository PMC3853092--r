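blobMask <- function(seed = 3, n = 64) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  m[cbind(sample(12:(n - 12), 180, TRUE),
          sample(12:(n - 12), 180, TRUE))] <- TRUE
  m
}

rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m)))]

test_that("moment families produce the contracted feature counts", {
  m <- blobMask()
  expect_equal(vapply(c(2, 4, 8, 16),
                      function(o) length(zernikeFeatures(m, o)), 0),
               c(4, 9, 25, 81))
  expect_equal(vapply(c(2, 4, 8, 16),
                      function(o) length(legendreFeatures(m, o)), 0),
               c(9, 25, 81, 289))
  expect_equal(vapply(c(2, 4, 8, 16),
                      function(o) length(tchebichefFeatures(m, o)), 0),
               c(9, 25, 81, 289))
  expect_length(genericFourierFeatures(m), 60)
  expect_error(zernikeFeatures(matrix(FALSE, 8, 8), 2), "empty")
  expect_error(legendreFeatures(matrix(FALSE, 8, 8), 2), "empty")
  expect_error(tchebichefFeatures(matrix(FALSE, 8, 8), 2), "empty")
})

test_that("Zernike magnitudes are rotation and translation invariant", {
  m <- blobMask()
  z1 <- zernikeFeatures(m, 8)
  z2 <- zernikeFeatures(rot90cw(m), 8)
  expect_lt(max(abs(z1 - z2)), 1e-6 * max(z1))
  shifted <- matrix(FALSE, 64, 64)
  shifted[which(m, arr.ind = TRUE) + 5] <- TRUE
  expect_lt(max(abs(z1 - zernikeFeatures(shifted, 8))), 1e-6 * max(z1))
})

test_that("|Z_00| of a centered disk equals the direct double sum", {
  m <- matrix(FALSE, 65, 65)
  m[diskPixels(c(33, 33), 14)] <- TRUE
  z <- zernikeFeatures(m, 2)
  # independent oracle: direct summation of the n=0 radial polynomial
  # (identically 1) over the unit-disk-mapped pixels
  w <- which(m, arr.ind = TRUE)
  ctr <- colMeans(w)
  R <- max(sqrt((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2))
  inside <- sqrt((w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2) / R <= 1
  expected <- sum(inside) / (pi * R^2)
  expect_equal(unname(z["zern_n0_m0"]), expected, tolerance = 1e-12)
})

test_that("Legendre normalization gives lambda_00 = 1 on all-ones", {
  lam <- legendreFeatures(matrix(TRUE, 48, 40), 4)
  expect_equal(unname(lam["leg_p0_q0"]), 1, tolerance = 1e-12)
})

test_that("Tchebichef moments match an orthonormalized-basis oracle", {
  m <- blobMask(5, 32)
  got <- tchebichefFeatures(m, 4)
  # independent oracle: the orthonormal degree-n polynomial basis on the
  # grid {0..N-1} is unique up to sign, and QR factorization of the
  # Vandermonde matrix constructs it without any recurrence
  N <- 32
  V <- outer(0:(N - 1), 0:4, `^`)
  Q <- qr.Q(qr(V))
  for (p in 0:4) for (q in 0:4) {
    oracle <- abs(sum(outer(Q[, p + 1], Q[, q + 1]) * m))
    expect_equal(abs(unname(got[sprintf("tcheb_p%d_q%d", p, q)])),
                 oracle, tolerance = 1e-9)
  }
})

test_that("generic Fourier features self-normalize and tolerate rotation", {
  m <- blobMask(7)
  g <- genericFourierFeatures(m)
  expect_equal(unname(g[1]), 1)
  g90 <- genericFourierFeatures(rot90cw(m))
  expect_lt(sqrt(mean((g - g90)^2)) / sqrt(mean(g^2)), 0.05)
})

test_that("Haralick features have the contracted layout and GLCM algebra", {
  set.seed(2)
  img <- matrix(runif(64 * 64, 0, 900), 64, 64)
  h <- haralickFeatures(img)
  expect_length(h, 180)
  expect_true(all(is.finite(h)))
  q <- quantizeGray(img, 8)
  for (a in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
    P <- glcm(q, a[1] * 2L, a[2] * 2L, 8)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
  }
})

test_that("constant images hit the degenerate GLCM conventions", {
  h <- haralickFeatures(matrix(42, 32, 32))
  for (d in 1:5) {
    expect_equal(unname(h[sprintf("har_d%d_contrast_mean", d)]), 0)
    expect_equal(unname(h[sprintf("har_d%d_asm_mean", d)]), 1)
    expect_equal(unname(h[sprintf("har_d%d_correlation_mean", d)]), 0)
  }
})

test_that("checkerboard GLCM contrast matches hand enumeration", {
  # 1-px checkerboard: every horizontal neighbor pair differs maximally
  img <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  q <- quantizeGray(img, 8)
  expect_setequal(unique(as.vector(q)), c(1L, 8L))
  P <- glcm(q, 0L, 1L, 8)
  # hand enumeration: all pairs are (1,8) or (8,1): contrast = 7^2
  st <- neuroHCS:::haralickStats(P)
  expect_equal(unname(st["contrast"]), 49)
  expect_equal(unname(st["asm"]), 0.5)
})

test_that("Gabor bank length, flat response and orientation tuning", {
  set.seed(4)
  img <- matrix(runif(48 * 48), 48, 48)
  g <- gaborFeatures(img)
  expect_length(g, 60)
  flat <- gaborFeatures(matrix(3, 32, 32))
  expect_true(all(flat[grep("_sd$", names(flat))] < 1e-8))
  # horizontal grating at the scale-1 frequency: the filter oriented
  # along x (orientation 1) must respond most strongly
  grat <- matrix(sin(2 * pi * 0.25 * (1:64)), 64, 64, byrow = TRUE)
  gg <- gaborFeatures(grat)
  means <- gg[sprintf("gabor_o%d_s1_mean", 1:6)]
  expect_equal(unname(which.max(means)), 1L)
})

test_that("wavelet energies: length, zero image and Parseval identity", {
  expect_length(daubechies4Features(matrix(0, 40, 40)), 30)
  expect_true(all(daubechies4Features(matrix(0, 40, 40)) == 0))
  set.seed(6)
  x <- matrix(rnorm(64 * 64), 64, 64)
  dec <- neuroHCS:::dwt2Periodic(x, 4)
  energy <- sum(dec$approx^2) +
    sum(vapply(dec$details, function(b)
      sum(b$lh^2) + sum(b$hl^2) + sum(b$hh^2), 0))
  expect_equal(energy, sum(x^2), tolerance = 1e-6)
})

test_that("extractGFD dispatches modalities with invariant lengths", {
  spec <- simpleSceneSpecs(nNeurites = 2)
  sc <- generateScene(spec$somata, spec$neurites, shape = c(128, 128),
                      noiseSd = 0)
  seg <- segmentNeuronImage(sc$image)
  mask <- somaMask(seg) | neuriteMask(seg)
  out <- extractGFD(sc$image, mask)
  expect_named(out, c("zernike", "legendre", "tchebichef",
                      "genericFourier", "haralick", "gabor",
                      "daubechies4"))
  expect_equal(vapply(out, length, 0L),
               c(zernike = 119L, legendre = 404L, tchebichef = 404L,
                 genericFourier = 60L, haralick = 180L, gabor = 60L,
                 daubechies4 = 30L))
  # determinism
  out2 <- extractGFD(sc$image, mask)
  expect_identical(out, out2)
  # empty mask: shape families error, texture families still compute
  expect_error(extractGFD(sc$image, matrix(FALSE, 128, 128),
                          gfdConfig(families = "zernike")), "empty")
  tex <- extractGFD(sc$image, matrix(FALSE, 128, 128),
                    gfdConfig(families = c("haralick", "gabor")))
  expect_length(tex$haralick, 180)
})
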