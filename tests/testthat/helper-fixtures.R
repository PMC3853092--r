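# Shared fixtures: small oracle scenes and synthetic feature tables.

# A single soma at the frame center with optional straight neurites.
simpleSceneSpecs <- function(nNeurites = 1, somaRadius = 10,
                             len = 50, center = c(64, 64)) {
  soma <- somaSpec(center, somaRadius, peakIntensity = 600)
  neurites <- lapply(seq_len(nNeurites), function(k) {
    ang <- (k - 1) * 2 * pi / max(nNeurites, 1)
    dir <- c(-cos(ang), sin(ang))
    start <- center + somaRadius * dir
    end <- center + (somaRadius + len) * dir
    neuriteSpec(1, rbind(start, end), width = 3, intensity = 300)
  })
  list(somata = list(soma), neurites = neurites)
}

# Feature table with monotone class signal in `nInformative` columns and
# pure noise elsewhere; 6 ordinal dose classes.
plantedSignalTable <- function(nInformative = 3, nNoise = 10,
                               perClass = 12, noiseSd = 0.4, seed = 42) {
  set.seed(seed)
  cls <- rep(c(0, 10, 50, 100, 200, 1000), each = perClass)
  x <- logDose(cls)
  inf <- sapply(seq_len(nInformative), function(i)
    -i * x + rnorm(length(x), 0, noiseSd))
  noise <- matrix(rnorm(length(x) * nNoise), ncol = nNoise)
  mat <- cbind(inf, noise)
  colnames(mat) <- c(sprintf("inf%d", seq_len(nInformative)),
                     sprintf("noise%d", seq_len(nNoise)))
  featureTable(mat, cls)
}

# Planted table whose three informative features carry complementary
# monotone step signals: each one is necessary to separate all six dose
# classes, so a faithful wrapper selection must keep all three.
plantedComplementaryTable <- function(perClass = 12, noiseSd = 0.3,
                                      nNoise = 10, seed = 42) {
  set.seed(seed)
  cls <- rep(c(0, 10, 50, 100, 200, 1000), each = perClass)
  x <- logDose(cls)
  f1 <- (x >= 1) + (x >= 2.3) + rnorm(length(x), 0, noiseSd)
  f2 <- (x >= 1.69) + rnorm(length(x), 0, noiseSd)
  f3 <- (x >= 2) + (x >= 2.65) + rnorm(length(x), 0, noiseSd)
  noise <- matrix(rnorm(length(x) * nNoise), ncol = nNoise)
  mat <- cbind(f1, f2, f3, noise)
  colnames(mat) <- c(sprintf("inf%d", 1:3),
                     sprintf("noise%d", seq_len(nNoise)))
  featureTable(mat, cls)
}

# Brute-force 3x3 neighborhood classifier over the circular run count,
# written independently of the package's vectorized version: explicit
# loop over the 8 neighbors in clockwise order.
bruteForceNeighborhood <- function(nbr) {
  # nbr: logical(8) clockwise from north
  runs <- 0L
  for (k in 1:8) {
    nxt <- if (k == 8L) 1L else k + 1L
    if (!nbr[k] && nbr[nxt]) runs <- runs + 1L
  }
  list(count = sum(nbr), runs = runs)
}

# Classify every skeleton pixel of a mask with the brute-force rule.
bruteForceClassify <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  offs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)
  t(apply(idx, 1, function(p) {
    nbr <- logical(8)
    for (k in 1:8) {
      r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
      nbr[k] <- r >= 1 && r <= nrow(skel) && c >= 1 && c <= ncol(skel) &&
        skel[r, c]
    }
    cl <- bruteForceNeighborhood(nbr)
    c(end = cl$count == 1L, branch = cl$count >= 3L && cl$runs >= 3L)
  }))
}
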