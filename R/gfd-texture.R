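# Texture descriptors on grayscale images: Haralick co-occurrence
# statistics, a Gabor filter bank, and Daubechies-4 wavelet energies.

#' Quantize a grayscale image into equal-width bins
#'
#' Uniform bins over the per-image min-max range; a constant image maps
#' entirely to bin 1.
#'
#' @param image numeric matrix.
#' @param bins number of gray levels.
#' @return integer matrix with values in `1..bins`.
#' @export
quantizeGray <- function(image, bins = 8) {
  rng <- range(image)
  if (rng[2] <= rng[1]) return(matrix(1L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  q[q > bins] <- bins
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' Gray-level co-occurrence matrix
#'
#' Symmetric, normalized GLCM of a quantized image for the pixel offset
#' `(dr, dc)`; entries sum to 1.
#'
#' @param q integer matrix from [quantizeGray()].
#' @param dr,dc row/column offset of the pixel pair.
#' @param bins number of gray levels.
#' @return `bins x bins` numeric matrix.
#' @export
glcm <- function(q, dr, dc, bins = 8) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  P <- matrix(0, bins, bins)
  tab <- table(factor(a, levels = 1:bins), factor(b, levels = 1:bins))
  P <- P + tab + t(tab)
  P / sum(P)
}

# x*log(x) with the 0 log 0 = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# The 18 co-occurrence statistics used throughout: Haralick's 13 classic
# measures plus autocorrelation, dissimilarity, cluster shade, cluster
# prominence and maximum probability. Degenerate (point-mass) matrices
# follow limit conventions: contrast 0, ASM 1, correlation 0, IMC1 0.
haralickStatNames <- c(
  "asm", "contrast", "correlation", "variance", "idm", "sumAverage",
  "sumVariance", "sumEntropy", "entropy", "diffVariance", "diffEntropy",
  "imc1", "imc2", "autocorrelation", "dissimilarity", "clusterShade",
  "clusterProminence", "maxProb")

haralickStats <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px))
  sy <- sqrt(sum(((1:G) - muy)^2 * py))
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), 0)
  pdiff <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), 0)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sx * sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sa <- sum((2:(2 * G)) * psum)
  sv <- sum(((2:(2 * G)) - sa)^2 * psum)
  se <- -sum(xlogx(psum))
  ent <- -sum(xlogx(P))
  da <- sum((0:(G - 1)) * pdiff)
  dv <- sum(((0:(G - 1)) - da)^2 * pdiff)
  de <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * ifelse(pxy > 0, log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))
  autoc <- sum(i * j * P)
  dissim <- sum(abs(i - j) * P)
  shade <- sum((i + j - mux - muy)^3 * P)
  prom <- sum((i + j - mux - muy)^4 * P)
  mp <- max(P)
  stats <- c(asm, contrast, corr, variance, idm, sa, sv, se, ent, dv, de,
             imc1, imc2, autoc, dissim, shade, prom, mp)
  names(stats) <- haralickStatNames
  stats
}

#' Haralick texture features
#'
#' For each pixel distance in `distances`, builds the four directional
#' symmetric normalized GLCMs (0, 45, 90, 135 degrees) of the 8-bin
#' quantized image, computes 18 co-occurrence statistics per direction,
#' and records their mean and range over the four directions:
#' `18 x 2 x 5 = 180` features by default.
#'
#' @param image numeric grayscale matrix.
#' @param distances pixel-pair distances.
#' @param bins quantization levels.
#' @return named numeric vector (`har_d<d>_<stat>_<mean|range>`).
#' @export
haralickFeatures <- function(image, distances = 1:5, bins = 8) {
  q <- quantizeGray(image, bins)
  angles <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  out <- c()
  for (d in distances) {
    per <- vapply(angles, function(a)
      haralickStats(glcm(q, a[1] * d, a[2] * d, bins)),
      numeric(length(haralickStatNames)))
    mu <- rowMeans(per)
    rg <- apply(per, 1, max) - apply(per, 1, min)
    v <- as.vector(rbind(mu, rg))
    names(v) <- as.vector(rbind(
      sprintf("har_d%d_%s_mean", d, haralickStatNames),
      sprintf("har_d%d_%s_range", d, haralickStatNames)))
    out <- c(out, v)
  }
  out
}

# FFT convolution of an image with a (possibly complex) kernel, periodic
# boundaries, kernel centered.
convolveFFT <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nr || kc > nc) {        # center-crop oversized kernels
    r0 <- max(1, (kr - nr) %/% 2 + 1); c0 <- max(1, (kc - nc) %/% 2 + 1)
    kernel <- kernel[r0:(r0 + min(kr, nr) - 1),
                     c0:(c0 + min(kc, nc) - 1), drop = FALSE]
    kr <- nrow(kernel); kc <- ncol(kernel)
  }
  K <- matrix(0 + 0i, nr, nc)
  K[1:kr, 1:kc] <- kernel
  # rotate so the kernel center sits at (1, 1)
  cr <- (kr + 1) %/% 2; cc <- (kc + 1) %/% 2
  K <- K[c(cr:nr, seq_len(cr - 1)), c(cc:nc, seq_len(cc - 1))]
  stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE) / (nr * nc)
}

gaborKernel <- function(freq, theta, sigma) {
  half <- min(ceiling(3 * sigma), 127L)
  xs <- -half:half
  X <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- matrix(xs, 2 * half + 1, 2 * half + 1)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  env * exp(2i * pi * freq * xr) / (2 * pi * sigma^2)
}

#' Gabor filter-bank features
#'
#' Convolves the image with a bank of complex Gabor filters (default 6
#' orientations x 5 octave-spaced scales, one-octave bandwidth) and
#' records the mean and standard deviation of the response magnitude:
#' 60 features by default.
#'
#' @param image numeric grayscale matrix.
#' @param nOrientations number of equally spaced orientations.
#' @param nScales number of octave-spaced frequencies, highest 0.25
#'   cycles/px.
#' @return named numeric vector (`gabor_o<k>_s<s>_<mean|sd>`).
#' @export
gaborFeatures <- function(image, nOrientations = 6, nScales = 5) {
  out <- c()
  for (s in seq_len(nScales)) {
    freq <- 0.25 / 2^(s - 1)
    sigma <- sqrt(log(2) / 2) * 3 / pi / freq   # one-octave bandwidth
    for (o in seq_len(nOrientations)) {
      theta <- (o - 1) * pi / nOrientations
      resp <- Mod(convolveFFT(image, gaborKernel(freq, theta, sigma)))
      v <- c(mean(resp), sd(resp))
      names(v) <- sprintf("gabor_o%d_s%d_%s", o, s, c("mean", "sd"))
      out <- c(out, v)
    }
  }
  out
}

# Daubechies-4 (4-tap) analysis filters, orthonormal.
db4Filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(h = h, g = c(h[4], -h[3], h[2], -h[1]))
}

# One periodic analysis step along columns of x (length divisible by 2).
dwtStepCols <- function(x, filt) {
  N <- nrow(x)
  idx <- function(k) ((2 * (0:(N / 2 - 1)) + k) %% N) + 1
  lo <- matrix(0, N / 2, ncol(x)); hi <- lo
  for (k in 0:3) {
    rows <- idx(k)
    lo <- lo + filt$h[k + 1] * x[rows, , drop = FALSE]
    hi <- hi + filt$g[k + 1] * x[rows, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# Separable 2-D periodic Daubechies-4 DWT; dims must divide 2^levels.
dwt2Periodic <- function(x, levels) {
  filt <- db4Filters()
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    cstep <- dwtStepCols(x, filt)
    loT <- dwtStepCols(t(cstep$lo), filt)
    hiT <- dwtStepCols(t(cstep$hi), filt)
    ll <- t(loT$lo); lh <- t(loT$hi)
    hl <- t(hiT$lo); hh <- t(hiT$hi)
    out[[l]] <- list(lh = lh, hl = hl, hh = hh)
    x <- ll
  }
  list(details = out, approx = x)
}

# Reflect-pad a matrix to the target dimensions.
padReflect <- function(x, nr, nc) {
  refl <- function(n, N) {
    if (n == 1L) return(rep(1L, N))
    period <- 2L * n - 2L
    k <- (0:(N - 1)) %% period
    ifelse(k < n, k + 1L, 2L * n - k - 1L)
  }
  x[refl(nrow(x), nr), refl(ncol(x), nc), drop = FALSE]
}

#' Daubechies-4 wavelet energy features
#'
#' Ten-level separable 2-D discrete wavelet transform with the 4-tap
#' Daubechies filter and periodic boundary handling (the image is
#' reflect-padded to the smallest dyadic-compatible size); for each level
#' the mean energy (mean squared coefficient) of the horizontal, vertical
#' and diagonal detail sub-bands is recorded: 30 features.
#'
#' @param image numeric grayscale matrix.
#' @param levels decomposition depth.
#' @return named numeric vector (`db4_l<level>_<lh|hl|hh>`).
#' @export
daubechies4Features <- function(image, levels = 10) {
  target <- 2^levels
  nr <- target * ceiling(nrow(image) / target)
  nc <- target * ceiling(ncol(image) / target)
  x <- padReflect(image, nr, nc)
  dec <- dwt2Periodic(x, levels)
  out <- numeric(3 * levels); nm <- character(3 * levels)
  for (l in seq_len(levels)) {
    b <- dec$details[[l]]
    out[3 * l - 2] <- mean(b$lh^2)
    out[3 * l - 1] <- mean(b$hl^2)
    out[3 * l] <- mean(b$hh^2)
    nm[(3 * l - 2):(3 * l)] <- sprintf("db4_l%d_%s", l, c("lh", "hl", "hh"))
  }
  names(out) <- nm
  out
}
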