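# Synthetic multi-neuron scenes with exact geometric ground truth.
#
# The generator emulates the structure of a multi-neuron high-content
# screen: bright disk-like somata on a dark background, thin curvilinear
# neurites with sub-branches attached at the soma perimeter, rendered at
# 16-bit depth so that the default soma-intensity threshold (288) of the
# preprocessing pipeline is meaningful.

#' Render a synthetic neuron scene
#'
#' Renders somata as filled disks and neurites as Bresenham polylines
#' dilated to their stroke width, adds clipped Gaussian noise, and returns
#' the image together with ground truth computed from the geometric
#' specifications (never from the rendered pixels).
#'
#' @param somata list of [SomaSpec-class] objects.
#' @param neurites list of [NeuriteSpec-class] objects.
#' @param shape integer(2), image size `(H, W)` in pixels.
#' @param backgroundLevel constant background gray level.
#' @param noiseSd standard deviation of additive Gaussian noise (gray
#'   levels); clipped to `[0, 65535]`.
#' @param seed integer seed for the noise draw.
#' @return `list(image = <H x W numeric matrix>, truth =
#'   <`[SceneGroundTruth-class]`>)`.
#' @examples
#' sc <- generateScene(list(somaSpec(c(32, 32), 8)), list(),
#'                     shape = c(64, 64), noiseSd = 0)
#' sc$truth
#' @export
generateScene <- function(somata = list(), neurites = list(),
                          shape = c(256, 256), backgroundLevel = 100,
                          noiseSd = 8, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  H <- shape[1]; W <- shape[2]
  img <- matrix(backgroundLevel, H, W)

  somaPx <- lapply(somata, function(s) {
    methods::validObject(s)
    px <- diskPixels(s@center, s@radius)
    if (any(px < 1L) || any(px[, 1] > H) || any(px[, 2] > W))
      stop("soma disk outside the image frame")
    px
  })

  neuritePx <- list(); totalLen <- 0; nEnding <- 0L; nBranch <- 0L
  for (nv in neurites) {
    methods::validObject(nv)
    s <- somata[[nv@attachmentSoma]]
    d0 <- sqrt(sum((nv@path[1, ] - s@center)^2))
    if (abs(d0 - s@radius) > 1.6)
      stop("neurite path must start at its soma perimeter")
    px <- rasterPolyline(nv@path)
    totalLen <- totalLen + polylineLength(nv@path)
    nEnding <- nEnding + 1L                 # free end of the main path
    for (b in nv@branches) {
      px <- rbind(px, rasterPolyline(b$path))
      totalLen <- totalLen + polylineLength(b$path)
      nEnding <- nEnding + 1L
      nBranch <- nBranch + 1L
    }
    px <- dilatePixels(px, nv@width)
    if (any(px < 1L) || any(px[, 1] > H) || any(px[, 2] > W))
      stop("neurite stroke outside the image frame")
    neuritePx[[length(neuritePx) + 1L]] <-
      list(px = px, intensity = nv@intensity)
  }

  for (np in neuritePx)
    img[np$px] <- pmax(img[np$px], backgroundLevel + np$intensity)
  for (i in seq_along(somaPx))
    img[somaPx[[i]]] <- pmax(img[somaPx[[i]]],
                             backgroundLevel + somata[[i]]@peakIntensity)

  if (noiseSd > 0)
    img <- img + withSeed(seed, matrix(rnorm(H * W, 0, noiseSd), H, W))
  img <- pmin(pmax(img, 0), 65535)

  somaMask <- matrix(FALSE, H, W)
  for (px in somaPx) somaMask[px] <- TRUE
  neuMask <- matrix(FALSE, H, W)
  for (np in neuritePx) neuMask[np$px] <- TRUE
  neuMask <- neuMask & !somaMask

  truth <- new("SceneGroundTruth",
               somaCount = length(somata),
               somaAreaPx = sum(somaMask),
               neuriteLengthPx = totalLen,
               neuriteAreaPx = sum(neuMask),
               nAttachment = length(neurites),
               nEnding = nEnding, nBranch = nBranch)
  list(image = img, truth = truth)
}

# A jittered near-straight polyline from `start` along `heading` (radians),
# total length ~len, confined to the box (rmin..rmax, cmin..cmax).
wigglyPath <- function(start, heading, len, box, step = 7, jitterDeg = 8,
                       maxDevDeg = 22) {
  pts <- matrix(start, 1, 2)
  h <- heading; pos <- start; travelled <- 0
  while (travelled < len) {
    stp <- min(step, len - travelled)
    h <- h + runif(1, -jitterDeg, jitterDeg) * pi / 180
    dev <- ((h - heading + pi) %% (2 * pi)) - pi
    lim <- maxDevDeg * pi / 180
    if (dev > lim) h <- heading + lim
    if (dev < -lim) h <- heading - lim
    nxt <- pos + stp * c(-cos(h), sin(h))   # row decreases upward
    if (nxt[1] < box[1] || nxt[1] > box[2] ||
        nxt[2] < box[3] || nxt[2] > box[4]) break
    pts <- rbind(pts, nxt); pos <- nxt; travelled <- travelled + stp
  }
  pts
}

# TRUE when every pixel of `px` farther than 6 px from `junction` keeps a
# distance of at least `minDist` from every pixel of `ref`.
strokeSeparated <- function(px, ref, junction, minDist) {
  dj <- sqrt((px[, 1] - junction[1])^2 + (px[, 2] - junction[2])^2)
  px <- px[dj > 6, , drop = FALSE]
  if (nrow(px) == 0L) return(TRUE)
  d2 <- outer(px[, 1], ref[, 1], `-`)^2 + outer(px[, 2], ref[, 2], `-`)^2
  all(apply(d2, 1L, min) >= minDist^2)
}

#' Build a well-separated random scene specification
#'
#' Places up to four neurons on a 2 x 2 tile grid so that somata are far
#' apart and the neurites of different neurons cannot touch; each neurite
#' radiates in its own angular sector with near-straight jittered paths,
#' optionally carrying one sub-branch. Such scenes give landmark counts
#' that feature extraction should recover exactly.
#'
#' @param nSomata 1 to 4 neurons.
#' @param neuritesPerSoma 0 to 3 neurites per neuron.
#' @param branchProb probability that a neurite carries one sub-branch.
#' @param shape image size `(H, W)`; at least 220 px each.
#' @param somaRadius soma disk radius, pixels.
#' @param neuriteLen nominal main-path length, pixels.
#' @param width neurite stroke width.
#' @param seed RNG seed.
#' @return `list(somata=, neurites=)` ready for [generateScene()].
#' @export
sampleScene <- function(nSomata = 4, neuritesPerSoma = 3, branchProb = 0.6,
                        shape = c(256, 256), somaRadius = 8,
                        neuriteLen = 38, width = 3, seed = 1L) {
  stopifnot(nSomata >= 1, nSomata <= 4, neuritesPerSoma <= 3)
  withSeed(seed, {
    H <- shape[1]; W <- shape[2]
    tileH <- H / 2; tileW <- W / 2
    centers <- list(c(tileH / 2, tileW / 2), c(tileH / 2, tileW * 1.5),
                    c(tileH * 1.5, tileW / 2), c(tileH * 1.5, tileW * 1.5))
    somata <- list(); neurites <- list()
    for (i in seq_len(nSomata)) {
      ctr <- round(centers[[i]] + runif(2, -4, 4))
      somata[[i]] <- somaSpec(ctr, somaRadius,
                              peakIntensity = 500 + runif(1, 0, 150))
      box <- c(max(2, ctr[1] - tileH / 2 + 4),
               min(H - 1, ctr[1] + tileH / 2 - 4),
               max(2, ctr[2] - tileW / 2 + 4),
               min(W - 1, ctr[2] + tileW / 2 - 4))
      if (neuritesPerSoma < 1) next
      sector <- 2 * pi / max(neuritesPerSoma, 1)
      base <- runif(1, 0, 2 * pi)
      for (k in seq_len(neuritesPerSoma)) {
        heading <- base + (k - 1) * sector + runif(1, -0.1, 0.1)
        start <- ctr + somaRadius * c(-cos(heading), sin(heading))
        path <- wigglyPath(start, heading,
                           neuriteLen * runif(1, 0.8, 1.2), box)
        if (nrow(path) < 3) next
        mainPx <- rasterPolyline(path)
        branches <- list()
        if (runif(1) < branchProb) {
          at <- max(2L, min(nrow(path) - 1L,
                            round(nrow(path) * runif(1, 0.45, 0.7))))
          side <- sample(c(-1, 1), 1)
          bh <- heading + side * runif(1, 32, 45) * pi / 180
          blen <- neuriteLen * runif(1, 0.35, 0.5)
          bpath <- wigglyPath(path[at, ], bh, blen, box, jitterDeg = 5,
                              maxDevDeg = 10)
          # the branch must diverge cleanly: beyond the junction
          # neighborhood it may not come back within a stroke width of
          # the parent, and its tip must stay clear of the parent's tip
          if (nrow(bpath) >= 3 && polylineLength(bpath) > 3 * width &&
              strokeSeparated(rasterPolyline(bpath), mainPx,
                              junction = path[at, ],
                              minDist = width + 3))
            branches <- list(list(at = at, path = bpath))
        }
        neurites[[length(neurites) + 1L]] <-
          neuriteSpec(i, path, branches, width = width,
                      intensity = 250 + runif(1, 0, 80))
      }
    }
    list(somata = somata, neurites = neurites)
  })
}

#' Configuration of a synthetic dose series
#'
#' Defines the study conditions emulated by [generateDoseSeries()]: the
#' six-dose nocodazole design (36 images per dose by default) with
#' per-class trends in soma abundance, neurite abundance, neurite length
#' and soma clustering that mirror the published dose-group means
#' (soma count peaking at intermediate dose, neurite abundance and length
#' falling monotonically, clustering rising with dose).
#'
#' @param doses strictly increasing concentrations, ng/mL.
#' @param imagesPerDose images per concentration class.
#' @param shape image size `(H, W)`.
#' @param trend named list of functions of dose: `somaCount` (mean somata
#'   per image), `neuritesPerSoma` (mean neurites per soma),
#'   `neuriteLength` (mean main-path length, px), `clusteringProb`
#'   (probability a soma is placed touching a neighbor).
#' @param noiseCv coefficient of variation applied to the per-image draws
#'   of the trend parameters; 0 gives noiseless means.
#' @param pixelNoiseSd Gaussian pixel noise SD, gray levels; the default
#'   keeps the noise floor below the preprocessing contrast step, as
#'   with the camera data the standard parameter set presumes.
#' @param seed integer seed.
#' @return A validated list of class `"DoseSeriesConfig"`.
#' @export
doseSeriesConfig <- function(doses = c(0, 10, 50, 100, 200, 1000),
                             imagesPerDose = 36,
                             shape = c(256, 256),
                             trend = defaultDoseTrends(),
                             noiseCv = 0.15,
                             pixelNoiseSd = 3,
                             seed = 1L) {
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (imagesPerDose < 1) stop("imagesPerDose must be >= 1")
  stopifnot(all(c("somaCount", "neuritesPerSoma", "neuriteLength",
                  "clusteringProb") %in% names(trend)))
  structure(list(doses = doses, imagesPerDose = imagesPerDose,
                 shape = shape, trend = trend, noiseCv = noiseCv,
                 pixelNoiseSd = pixelNoiseSd, seed = as.integer(seed)),
            class = "DoseSeriesConfig")
}

#' Default dose-trend functions
#'
#' Piecewise-linear interpolations (on log10 dose, control at 0) of the
#' published per-class pattern, scaled to a renderable number of neurons
#' per frame: soma count rises slightly then collapses at the top dose;
#' neurite abundance and length decline monotonically (the drug's neurite
#' retraction); clustering probability grows with dose.
#'
#' @return named list of functions of dose (ng/mL).
#' @export
defaultDoseTrends <- function() {
  xs <- c(0, 1, log10(50), 2, log10(200), 3)
  mk <- function(vals) {
    f <- stats::approxfun(xs, vals, rule = 2)
    function(dose) f(ifelse(dose > 0, log10(dose), 0))
  }
  list(
    # published soma counts 224..137 scaled by 1/16 to 14.0..8.6 per frame
    somaCount      = mk(c(224, 249, 255, 251, 221, 137) / 16),
    # per-soma neurite abundance follows the Avg_attachmentPoint decline,
    # rescaled to 0.6..2.4 neurites per soma
    neuritesPerSoma = mk(c(2.4, 1.8, 1.4, 1.1, 0.9, 0.6)),
    # per-neurite length follows the Avg_neuriteLength decline 372..65,
    # scaled by 0.12 into the renderable 45..8 px range (floor 8)
    neuriteLength  = mk(pmax(c(372, 244, 151, 100, 71, 65) * 0.12, 8)),
    clusteringProb = mk(c(0, 0.02, 0.05, 0.1, 0.2, 0.5))
  )
}

# One random scene drawn from the dose-trend parameters (somata may
# cluster; neurites may cross - unlike sampleScene these scenes emulate
# crowded cultures, not landmark-exact fixtures).
randomDoseScene <- function(cfg, dose) {
  H <- cfg$shape[1]; W <- cfg$shape[2]
  cv <- cfg$noiseCv
  jitter <- function(mu) if (cv > 0) max(0, rnorm(1, mu, cv * mu)) else mu
  nSoma <- max(1L, round(jitter(cfg$trend$somaCount(dose))))
  clusterP <- cfg$trend$clusteringProb(dose)
  rad <- 8
  centers <- list()
  for (i in seq_len(nSoma)) {
    placed <- FALSE
    for (try in 1:50) {
      if (length(centers) > 0 && runif(1) < clusterP) {
        anchor <- centers[[sample(length(centers), 1)]]
        ctr <- anchor + runif(2, -1.2 * rad, 1.2 * rad)
      } else {
        mH <- min(45, max(2, floor((H - 2 * rad) / 2) - 4))
        mW <- min(45, max(2, floor((W - 2 * rad) / 2) - 4))
        ctr <- c(runif(1, rad + mH, H - rad - mH),
                 runif(1, rad + mW, W - rad - mW))
        if (length(centers) > 0) {
          dmin <- min(vapply(centers, function(p)
            sqrt(sum((p - ctr)^2)), 0))
          if (dmin < 2 * rad + 6) next
        }
      }
      if (ctr[1] > rad + 1 && ctr[1] < H - rad &&
          ctr[2] > rad + 1 && ctr[2] < W - rad) { placed <- TRUE; break }
    }
    if (placed) centers[[length(centers) + 1L]] <- ctr
  }
  somata <- lapply(centers, function(ctr)
    somaSpec(round(ctr), rad, peakIntensity = 500 + runif(1, 0, 150)))
  neurites <- list()
  box <- c(2, H - 1, 2, W - 1)
  for (i in seq_along(somata)) {
    nNeu <- rpois(1, jitter(cfg$trend$neuritesPerSoma(dose)))
    if (nNeu < 1) next
    base <- runif(1, 0, 2 * pi)
    for (k in seq_len(nNeu)) {
      heading <- base + (k - 1) * 2 * pi / nNeu + runif(1, -0.25, 0.25)
      len <- max(6, jitter(cfg$trend$neuriteLength(dose)))
      start <- somata[[i]]@center + rad * c(-cos(heading), sin(heading))
      path <- wigglyPath(start, heading, len, box)
      if (nrow(path) < 2) next
      branches <- list()
      if (len > 20 && runif(1) < 0.4) {
        at <- max(2L, min(nrow(path) - 1L, round(nrow(path) * 0.55)))
        bpath <- wigglyPath(path[at, ],
                            heading + sample(c(-1, 1), 1) * 0.7,
                            len * 0.4, box, jitterDeg = 5, maxDevDeg = 10)
        if (nrow(bpath) >= 3)
          branches <- list(list(at = at, path = bpath))
      }
      neurites[[length(neurites) + 1L]] <-
        neuriteSpec(i, path, branches, width = 3,
                    intensity = 250 + runif(1, 0, 80))
    }
  }
  list(somata = somata, neurites = neurites)
}

#' Generate a labeled synthetic dose series
#'
#' Deterministic for a fixed config seed: draws `imagesPerDose` scenes per
#' concentration whose parameters follow the configured trend functions,
#' renders each scene, and returns images with exact ground truth and dose
#' labels.
#'
#' @param config a [doseSeriesConfig()].
#' @return list of `list(image=, truth=, dose=)`, ordered by dose then
#'   replicate.
#' @export
generateDoseSeries <- function(config) {
  stopifnot(inherits(config, "DoseSeriesConfig"))
  out <- vector("list", length(config$doses) * config$imagesPerDose)
  idx <- 0L
  withSeed(config$seed, {
    for (dose in config$doses) {
      for (rep in seq_len(config$imagesPerDose)) {
        spec <- randomDoseScene(config, dose)
        sceneSeed <- sample.int(.Machine$integer.max, 1L)
        sc <- generateScene(spec$somata, spec$neurites,
                            shape = config$shape,
                            noiseSd = config$pixelNoiseSd,
                            seed = sceneSeed)
        idx <- idx + 1L
        out[[idx]] <- list(image = sc$image, truth = sc$truth, dose = dose)
      }
    }
  })
  out[seq_len(idx)]
}

#' Write a dose series to disk
#'
#' Writes each scene as a 16-bit grayscale TIFF plus a CSV manifest with
#' the ground truth and dose label of every image.
#'
#' @param series output of [generateDoseSeries()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
writeDoseSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(series), function(i) {
    it <- series[[i]]
    fn <- sprintf("scene_%03d_dose%g.tif", i, it$dose)
    tiff::writeTIFF(it$image / 65535, file.path(dir, fn),
                    bits.per.sample = 16L)
    t <- it$truth
    data.frame(filename = fn, dose_ng_per_ml = it$dose,
               soma_count = t@somaCount, soma_area_px = t@somaAreaPx,
               neurite_length_px = t@neuriteLengthPx,
               neurite_area_px = t@neuriteAreaPx,
               n_attachment = t@nAttachment, n_ending = t@nEnding,
               n_branch = t@nBranch)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
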