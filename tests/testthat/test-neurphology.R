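test_that("background subtraction flattens structure-free images", {
  expect_true(all(subtractBackground(matrix(300, 64, 64)) == 0))
  expect_error(subtractBackground(array(0, c(4, 4, 3))), "single-channel")
})

test_that("background subtraction keeps a bright disk near its contrast", {
  img <- matrix(100, 128, 128)
  img[diskPixels(c(64, 64), 10)] <- 500
  out <- subtractBackground(img, contrast = 13)
  inner <- diskPixels(c(64, 64), 6)
  expect_true(all(out[inner] > 350))
  expect_true(all(out >= 0))
  border <- out[1:20, 1:20]
  expect_true(all(border == 0))
})

test_that("soma segmentation erases neurites and merges touching somata", {
  spec <- simpleSceneSpecs(nNeurites = 3)
  sc <- generateScene(spec$somata, spec$neurites, shape = c(128, 128),
                      noiseSd = 0)
  bg <- subtractBackground(sc$image)
  mask <- segmentSomata(bg)
  expect_identical(max(labelComponents(mask)), 1L)
  # overlapping pair counts once
  two <- generateScene(list(somaSpec(c(60, 60), 10),
                            somaSpec(c(60, 72), 10)), list(),
                       shape = c(128, 128), noiseSd = 0)
  m2 <- segmentSomata(subtractBackground(two$image))
  expect_identical(max(labelComponents(m2)), 1L)
  expect_true(!any(segmentSomata(matrix(0, 64, 64))))
})

test_that("neurite segmentation keeps thin strokes and drops specks", {
  spec <- simpleSceneSpecs(nNeurites = 1, len = 50)
  sc <- generateScene(spec$somata, spec$neurites, shape = c(128, 128),
                      noiseSd = 0)
  bg <- subtractBackground(sc$image)
  soma <- segmentSomata(bg)
  neu <- segmentNeurites(bg, soma)
  expect_false(any(neu & soma))
  # a width-3, ~50 px stroke has close to 150 px of mask
  expect_gt(sum(neu), 100)
  expect_lt(sum(neu), 200)
  # somata-only scene leaves no neurite pixels
  solo <- generateScene(spec$somata, list(), shape = c(128, 128),
                        noiseSd = 0)
  bg2 <- subtractBackground(solo$image)
  expect_equal(sum(segmentNeurites(bg2, segmentSomata(bg2))), 0)
  # isolated 10 px speck below particle cleanup 15 vanishes
  img <- matrix(0, 64, 64); img[30, 21:30] <- 400
  expect_equal(sum(segmentNeurites(img, matrix(FALSE, 64, 64))), 0)
})

test_that("thinning yields 1-px-wide connected skeletons", {
  bar <- matrix(FALSE, 60, 60); bar[30:32, 6:55] <- TRUE
  sk <- skeletonizeNeurites(bar)
  expect_identical(max(labelComponents(sk)), 1L)
  expect_gt(sum(sk), 40); expect_lt(sum(sk), 55)
  expect_equal(nrow(detectEndingPoints(sk)), 2)
  # no 2x2 block anywhere, also for a solid disk
  no2x2 <- function(m)
    !any(m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
           m[-nrow(m), -1] & m[-1, -1])
  expect_true(no2x2(sk))
  disk <- matrix(FALSE, 64, 64); disk[diskPixels(c(32, 32), 15)] <- TRUE
  expect_true(no2x2(skeletonizeNeurites(disk)))
  expect_false(any(skeletonizeNeurites(matrix(FALSE, 8, 8))))
})

test_that("ending and branch detectors match elementary skeletons", {
  line <- matrix(FALSE, 20, 20); line[10, 3:17] <- TRUE
  expect_equal(nrow(detectEndingPoints(line)), 2)
  expect_equal(nrow(detectBranchPoints(line)), 0)
  # Y: three arms meeting at (10, 10)
  y <- matrix(FALSE, 20, 20)
  y[10, 3:10] <- TRUE
  for (k in 1:6) { y[10 - k, 10 + k] <- TRUE; y[10 + k, 10 + k] <- TRUE }
  expect_equal(nrow(detectEndingPoints(y)), 3)
  expect_equal(nrow(detectBranchPoints(y)), 1)
  # X: four arms through one junction
  xm <- matrix(FALSE, 21, 21)
  for (k in -6:6) { xm[11 + k, 11 + k] <- TRUE; xm[11 - k, 11 + k] <- TRUE }
  expect_equal(nrow(detectBranchPoints(xm)), 1)
  # closed ring has no endpoints
  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  expect_equal(nrow(detectEndingPoints(ring)), 0)
})

test_that("detectors agree with the brute-force 3x3 classifier", {
  set.seed(9)
  for (rep in 1:5) {
    spec <- sampleScene(nSomata = 4, neuritesPerSoma = 3, seed = rep)
    sc <- generateScene(spec$somata, spec$neurites, noiseSd = 0, seed = 1)
    seg <- segmentNeuronImage(sc$image)
    skel <- skeletonMask(seg)
    if (!any(skel)) next
    bf <- bruteForceClassify(skel)
    idx <- which(skel, arr.ind = TRUE)
    endsDet <- detectEndingPoints(skel)
    endKey <- paste(endsDet[, 1], endsDet[, 2])
    expect_setequal(endKey, paste(idx[bf[, "end"] == 1, 1],
                                  idx[bf[, "end"] == 1, 2]))
    # branch hits: every reported junction is a brute-force hit, and
    # every brute-force hit lies within 2 px of a reported junction
    brDet <- detectBranchPoints(skel)
    hits <- idx[bf[, "branch"] == 1, , drop = FALSE]
    if (nrow(hits) > 0) {
      expect_gt(nrow(brDet), 0)
      for (i in seq_len(nrow(brDet)))
        expect_true(any(hits[, 1] == brDet[i, 1] &
                          hits[, 2] == brDet[i, 2]))
      for (i in seq_len(nrow(hits)))
        expect_lte(min(abs(hits[i, 1] - brDet[, 1]) +
                         abs(hits[i, 2] - brDet[, 2])), 4)
    }
  }
})

test_that("attachment detection needs adjacency to the soma", {
  spec <- simpleSceneSpecs(nNeurites = 2)
  sc <- generateScene(spec$somata, spec$neurites, shape = c(128, 128),
                      noiseSd = 0)
  seg <- segmentNeuronImage(sc$image)
  expect_equal(nrow(seg@attachmentPoints), 2)
  # no soma -> no attachments
  expect_equal(nrow(detectAttachmentPoints(skeletonMask(seg),
                                           matrix(FALSE, 128, 128))), 0)
  # a line far from the soma contributes nothing
  soma <- matrix(FALSE, 64, 64); soma[diskPixels(c(20, 20), 6)] <- TRUE
  sk <- matrix(FALSE, 64, 64); sk[50, 10:40] <- TRUE
  expect_equal(nrow(detectAttachmentPoints(sk, soma)), 0)
})

test_that("extractNFD returns 13 named features honoring the averages", {
  spec <- sampleScene(nSomata = 3, neuritesPerSoma = 2, seed = 4)
  sc <- generateScene(spec$somata, spec$neurites, noiseSd = 0, seed = 1)
  v <- extractNFD(sc$image)
  expect_identical(names(v), nfdFeatureNames())
  expect_length(v, 13)
  sc2 <- v[["somaCount"]]
  for (nm in c("somaArea", "neuriteLength", "neuriteArea"))
    expect_equal(v[[paste0("Avg_", nm)]] * sc2, v[[nm]])
  expect_equal(v[["Avg_endingPoint#"]] * sc2, v[["endingPoint#"]])
  # empty image: zero raw features, NA averages, a warning but no error
  expect_warning(v0 <- extractNFD(matrix(0, 96, 96)), "no soma")
  expect_true(all(v0[1:7] == 0))
  expect_true(all(is.na(v0[8:13])))
})

test_that("NFD recovers ground truth on separated noiseless scenes", {
  lenErr <- c()
  for (s in 1:8) {
    spec <- sampleScene(nSomata = 4, neuritesPerSoma = 3, seed = s)
    sc <- generateScene(spec$somata, spec$neurites, noiseSd = 0, seed = 1)
    v <- extractNFD(sc$image); tr <- sc$truth
    expect_identical(as.integer(v[["somaCount"]]), tr@somaCount)
    expect_identical(as.integer(v[["attachmentPoint#"]]), tr@nAttachment)
    expect_identical(as.integer(v[["endingPoint#"]]), tr@nEnding)
    expect_identical(as.integer(v[["branchPoint#"]]), tr@nBranch)
    lenErr <- c(lenErr,
                abs(v[["neuriteLength"]] - tr@neuriteLengthPx) /
                  tr@neuriteLengthPx)
  }
  expect_true(all(lenErr <= 0.15))
})

test_that("the descriptor is invariant to in-frame translation", {
  spec <- simpleSceneSpecs(nNeurites = 2, center = c(70, 70))
  sc1 <- generateScene(spec$somata, spec$neurites, shape = c(160, 160),
                       noiseSd = 0)
  shift <- c(15, 20)
  somataS <- lapply(spec$somata, function(s)
    somaSpec(s@center + shift, s@radius, s@peakIntensity))
  neuS <- lapply(spec$neurites, function(nv)
    neuriteSpec(nv@attachmentSoma,
                sweep(nv@path, 2, shift, `+`),
                lapply(nv@branches, function(b)
                  list(at = b$at, path = sweep(b$path, 2, shift, `+`))),
                nv@width, nv@intensity))
  sc2 <- generateScene(somataS, neuS, shape = c(160, 160), noiseSd = 0)
  expect_equal(extractNFD(sc1$image), extractNFD(sc2$image))
})

test_that("clustered somata merge into fewer detected components", {
  sep <- generateScene(list(somaSpec(c(40, 40), 8),
                            somaSpec(c(90, 90), 8)), list(),
                       shape = c(128, 128), noiseSd = 0)
  merged <- generateScene(list(somaSpec(c(60, 60), 8),
                               somaSpec(c(60, 70), 8)), list(),
                          shape = c(128, 128), noiseSd = 0)
  vSep <- suppressWarnings(extractNFD(sep$image))
  vMer <- suppressWarnings(extractNFD(merged$image))
  expect_equal(unname(vSep[["somaCount"]]), 2)
  expect_equal(unname(vMer[["somaCount"]]), 1)
})
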