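# Soma/neurite segmentation and the 13-feature neuromorphology descriptor.
#
# The pipeline is parameterized by four values in the tradition of
# ImageJ-lineage neurite tools: `contrast` (minimum foreground-background
# difference after background subtraction), `somaIntensity` (absolute
# gray-level cut for soma cores, applied after a neurite-erasing opening),
# `neuriteWidth` (disk radius of the opening/top-hat separating thin
# processes from compact cell bodies) and `particleCleanup` (minimum
# connected-component area kept, in pixels).

#' Preprocessing parameters
#'
#' @param contrast minimum local contrast against the background estimate
#'   (gray levels); pixels below it are zeroed.
#' @param somaIntensity absolute threshold for soma segmentation, applied
#'   to the neurite-erased (opened) image. The default 288 presumes 16-bit
#'   input.
#' @param neuriteWidth expected neurite width, px; sets the disk radius of
#'   the soma-isolating opening and the neurite top-hat.
#' @param particleCleanup minimum object area kept, px.
#' @param backgroundRadius disk radius of the background-estimating
#'   opening; must exceed the largest soma radius.
#' @return list of class `"PreprocessParams"`.
#' @export
preprocessParams <- function(contrast = 13, somaIntensity = 288,
                             neuriteWidth = 5, particleCleanup = 15,
                             backgroundRadius = 25) {
  vals <- c(contrast, somaIntensity, neuriteWidth, particleCleanup)
  if (any(vals <= 0)) stop("all preprocessing parameters must be positive")
  structure(list(contrast = contrast, somaIntensity = somaIntensity,
                 neuriteWidth = neuriteWidth,
                 particleCleanup = particleCleanup,
                 backgroundRadius = backgroundRadius),
            class = "PreprocessParams")
}

discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
}

grayOpening <- function(img, radius) {
  # EBImage clamps grayscale images to [0, 1]; run on the 16-bit-normalized
  # scale and map back
  b <- discBrush(radius)
  as.matrix(EBImage::opening(img / 65535, b)) * 65535
}

#' Subtract the low-frequency background
#'
#' Estimates the background by a grayscale morphological opening with a
#' large disk (rolling-ball style), subtracts it, and zeroes pixels whose
#' contrast against the estimate falls below `contrast`. Output is never
#' negative.
#'
#' @param image single-channel numeric matrix.
#' @param contrast minimum retained foreground-background difference.
#' @param backgroundRadius disk radius of the background opening.
#' @return background-subtracted image, same size.
#' @export
subtractBackground <- function(image, contrast = 13, backgroundRadius = 25) {
  if (length(dim(image)) != 2L)
    stop("subtractBackground expects a single-channel image")
  bg <- grayOpening(image, backgroundRadius)
  out <- image - bg
  out[out < contrast] <- 0
  out
}

#' Segment somata
#'
#' Opens the background-subtracted image with a disk of radius
#' `neuriteWidth` (erasing thin neurites), thresholds at the absolute
#' `somaIntensity` level, and drops components smaller than
#' `particleCleanup`. Overlapping cell bodies merge into a single
#' component, mirroring soma clustering in crowded cultures.
#'
#' @param image background-subtracted image.
#' @param somaIntensity absolute gray-level threshold.
#' @param particleCleanup minimum component area, px.
#' @param neuriteWidth disk radius of the neurite-erasing opening.
#' @return logical soma mask.
#' @export
segmentSomata <- function(image, somaIntensity = 288, particleCleanup = 15,
                          neuriteWidth = 5) {
  opened <- grayOpening(image, neuriteWidth)
  removeSmall(opened >= somaIntensity, particleCleanup)
}

#' Segment neurites
#'
#' A white top-hat with a disk of radius `neuriteWidth` keeps structures
#' thinner than about twice that radius; the result is thresholded at
#' `contrast`, the (slightly dilated) soma mask is removed, and small
#' particles are cleaned up.
#'
#' @param image background-subtracted image.
#' @param somaMask logical soma mask from [segmentSomata()].
#' @param neuriteWidth top-hat disk radius, px.
#' @param particleCleanup minimum component area, px.
#' @param contrast threshold on the top-hat response.
#' @return logical neurite mask, disjoint from the soma mask.
#' @export
segmentNeurites <- function(image, somaMask, neuriteWidth = 5,
                            particleCleanup = 15, contrast = 13) {
  tophat <- image - grayOpening(image, neuriteWidth)
  fg <- tophat >= contrast
  somaZone <- as.matrix(EBImage::dilate(somaMask * 1, discBrush(2))) > 0
  removeSmall(fg & !somaZone, particleCleanup)
}

#' Skeletonize a binary mask to one-pixel width
#'
#' Topology-preserving parallel thinning (Zhang-Suen) followed by a
#' sequential pass that removes redundant pixels from any remaining 2 x 2
#' foreground block while preserving local connectivity. Every foreground
#' component yields one 8-connected skeleton component.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonizeNeurites <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  # thin inside the padded bounding box only
  w <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(w[, 1]) - 2L); r1 <- min(nrow(mask), max(w[, 1]) + 2L)
  c0 <- max(1L, min(w[, 2]) - 2L); c1 <- min(ncol(mask), max(w[, 2]) + 2L)
  m <- mask[r0:r1, c0:c1, drop = FALSE]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      st <- neighborStack(m)
      B <- Reduce(`+`, lapply(st, function(x) x + 0L))
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in seq_len(8L)) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + ((!st[[k]]) & st[[nxt]])
      }
      # st indices: 1=N(P2) 2=NE 3=E(P4) 4=SE 5=S(P6) 6=SW 7=W(P8) 8=NW
      if (phase == 1L) {
        c1c <- !(st[[1]] & st[[3]] & st[[5]])
        c2c <- !(st[[3]] & st[[5]] & st[[7]])
      } else {
        c1c <- !(st[[1]] & st[[3]] & st[[7]])
        c2c <- !(st[[1]] & st[[5]] & st[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1L & c1c & c2c
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- pruneSquareBlocks(m)
  out <- mask & FALSE
  out[r0:r1, c0:c1] <- m
  out
}

# Remove pixels sitting in 2x2 foreground blocks when deletion preserves
# the connectivity of their neighborhood (circular-run count 1).
pruneSquareBlocks <- function(m) {
  repeat {
    blk <- m & shiftMat(m, 0, -1) & shiftMat(m, -1, 0) & shiftMat(m, -1, -1)
    if (!any(blk)) return(m)
    idx <- which(blk, arr.ind = TRUE)
    removedAny <- FALSE
    for (i in seq_len(nrow(idx))) {
      for (off in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- idx[i, 1] + off[1]; cc <- idx[i, 2] + off[2]
        if (!m[r, cc]) next
        nbr <- vapply(seq_len(8L), function(k) {
          rr <- r + NBR_OFFSETS[k, 1]; c2 <- cc + NBR_OFFSETS[k, 2]
          rr >= 1 && rr <= nrow(m) && c2 >= 1 && c2 <= ncol(m) && m[rr, c2]
        }, TRUE)
        runs <- sum(!nbr & nbr[c(2:8, 1)])
        if (runs == 1L && sum(nbr) >= 2L) {
          m[r, cc] <- FALSE
          removedAny <- TRUE
          break
        }
      }
    }
    if (!removedAny) return(m)
  }
}

#' Prune short skeleton spurs
#'
#' Removes terminal twigs of at most `maxLen` pixels that emanate from a
#' junction pixel; these are thinning artifacts at junctions and stroke
#' ends, not genuine neurite arms. Walks from each endpoint along the
#' skeleton; if a pixel of degree >= 3 is reached within `maxLen` steps
#' the walked pixels (junction excluded) are deleted.
#'
#' @param skeleton logical skeleton matrix.
#' @param maxLen maximum spur length to remove, px.
#' @return pruned logical skeleton.
#' @export
pruneSpurs <- function(skeleton, maxLen = 4L) {
  m <- skeleton
  nr <- nrow(m); nc <- ncol(m)
  skeletonNbrs <- function(cur, visited) {
    nb <- sweep(NBR_OFFSETS, 2L, as.integer(cur), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[m[nb], , drop = FALSE]
    if (nrow(nb) && nrow(visited))
      nb <- nb[!(paste(nb[, 1], nb[, 2]) %in%
                   paste(visited[, 1], visited[, 2])), , drop = FALSE]
    nb
  }
  for (pass in 1:2) {
    deg <- neighborCount(m)
    isJunction <- m & deg >= 3L & neighborRuns(m) >= 3L
    ends <- which(m & deg == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    changed <- FALSE
    for (i in seq_len(nrow(ends))) {
      path <- matrix(as.integer(ends[i, ]), 1, 2)
      cur <- path[1, ]
      for (step in seq_len(maxLen + 1L)) {
        if (isJunction[cur[1], cur[2]]) {
          # delete the walked twig, keep the junction pixel
          m[path[-nrow(path), , drop = FALSE]] <- FALSE
          changed <- TRUE
          break
        }
        if (step > maxLen) break
        nb <- skeletonNbrs(cur, path)
        if (nrow(nb) == 0L) break
        cur <- nb[1, ]
        path <- rbind(path, cur)
      }
    }
    if (!changed) break
  }
  m
}

#' Detect neurite ending points
#'
#' Skeleton pixels with exactly one 8-connected skeleton neighbor.
#'
#' @param skeleton logical 1-px-wide skeleton.
#' @return n x 2 matrix of `(row, col)` coordinates.
#' @export
detectEndingPoints <- function(skeleton) {
  maskWhich(skeleton & neighborCount(skeleton) == 1L)
}

#' Detect neurite branch points
#'
#' A skeleton pixel is a branch-pattern hit when its 3 x 3 neighborhood
#' carries at least three distinct arms: at least three skeleton neighbors
#' falling in at least three circular runs (runs of set neighbors
#' separated by background when traversing the 8-neighborhood). Adjacent
#' hits within one junction are merged and reported once.
#'
#' @param skeleton logical 1-px-wide skeleton.
#' @return n x 2 matrix of representative junction coordinates.
#' @export
detectBranchPoints <- function(skeleton) {
  hits <- skeleton & neighborCount(skeleton) >= 3L &
    neighborRuns(skeleton) >= 3L
  if (!any(hits)) return(zeroPoints())
  # hits of one junction can sit a pixel apart after thinning; cluster
  # within a 1-px bridge before assigning one representative per junction
  grown <- as.matrix(EBImage::dilate(hits * 1, discBrush(1))) > 0
  lab <- labelComponents(grown)
  labs <- lab[hits]
  idx <- which(hits, arr.ind = TRUE)
  reps <- do.call(rbind, lapply(split(seq_len(nrow(idx)), labs),
                                function(rows) {
    sub <- idx[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    sub[which.min((sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2), ]
  }))
  colnames(reps) <- c("row", "col")
  reps
}

# One representative (row, col) per 8-connected component of a mask.
componentRepresentatives <- function(mask) {
  if (!any(mask)) return(zeroPoints())
  lab <- labelComponents(mask)
  idx <- which(mask, arr.ind = TRUE)
  labs <- lab[mask]
  reps <- do.call(rbind, lapply(split(seq_len(nrow(idx)), labs),
                                function(rows) {
    sub <- idx[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    sub[which.min((sub[, 1] - ctr[1])^2 + (sub[, 2] - ctr[2])^2), ]
  }))
  colnames(reps) <- c("row", "col")
  reps
}

#' Detect neurite-soma attachment points
#'
#' Skeleton pixels falling within a small dilation ring of the soma mask;
#' contiguous runs of such pixels along one contact are counted once.
#'
#' @param skeleton logical skeleton.
#' @param somaMask logical soma mask.
#' @param gap adjacency radius in px; it must bridge the soma-exclusion
#'   border of the neurite mask (2 px) plus the terminal retraction of
#'   thinning (about half the stroke width).
#' @return n x 2 matrix of attachment coordinates.
#' @export
detectAttachmentPoints <- function(skeleton, somaMask, gap = 7) {
  if (!any(somaMask)) return(zeroPoints())
  zone <- as.matrix(EBImage::dilate(somaMask * 1, discBrush(gap))) > 0
  componentRepresentatives(skeleton & zone)
}

#' Canonical names of the 13 neuromorphology features
#' @return character(13) in canonical order.
#' @export
nfdFeatureNames <- function() {
  c("somaCount", "somaArea", "neuriteLength", "neuriteArea",
    "attachmentPoint#", "endingPoint#", "branchPoint#",
    "Avg_somaArea", "Avg_neuriteLength", "Avg_neuriteArea",
    "Avg_attachmentPoint#", "Avg_endingPoint#", "Avg_branchPoint#")
}

#' Segment a multi-neuron image
#'
#' Runs the full chain: background subtraction, soma segmentation, neurite
#' segmentation, skeletonization, and landmark detection.
#'
#' @param image single-channel numeric matrix.
#' @param params a [preprocessParams()] list.
#' @return A [SegmentationResult-class] object.
#' @export
segmentNeuronImage <- function(image, params = preprocessParams()) {
  bg <- subtractBackground(image, params$contrast, params$backgroundRadius)
  soma <- segmentSomata(bg, params$somaIntensity, params$particleCleanup,
                        params$neuriteWidth)
  neu <- segmentNeurites(bg, soma, params$neuriteWidth,
                         params$particleCleanup, params$contrast)
  skel <- pruneSpurs(skeletonizeNeurites(neu))
  attachGap <- 7
  attach <- detectAttachmentPoints(skel, soma, gap = attachGap)
  ends <- detectEndingPoints(skel)
  # termini inside the attachment zone are contact points, not free ends;
  # the exclusion radius must match the attachment gap
  if (nrow(ends) > 0 && any(soma)) {
    zone <- as.matrix(EBImage::dilate(soma * 1, discBrush(attachGap))) > 0
    ends <- ends[!zone[ends], , drop = FALSE]
  }
  branch <- detectBranchPoints(skel)
  new("SegmentationResult", somaMask = soma, neuriteMask = neu,
      skeleton = skel, attachmentPoints = attach, endingPoints = ends,
      branchPoints = branch)
}

#' Extract the 13-feature neuromorphology descriptor
#'
#' Counts and measures from the segmentation chain: soma count and area,
#' neurite skeleton length and mask area, attachment/ending/branch point
#' counts, and each cumulative feature divided by the soma count as its
#' per-neuron average. With no detected soma the six averages are
#' reported as `NA` with a warning (never a division failure).
#'
#' @param image single-channel numeric matrix (or a
#'   [SegmentationResult-class] to reuse an existing segmentation).
#' @param params a [preprocessParams()] list.
#' @return named numeric(13) in the canonical order of
#'   [nfdFeatureNames()].
#' @export
extractNFD <- function(image, params = preprocessParams()) {
  seg <- if (methods::is(image, "SegmentationResult")) image
         else segmentNeuronImage(image, params)
  somaCnt <- max(labelComponents(seg@somaMask))
  raw <- c(somaCnt, sum(seg@somaMask), sum(seg@skeleton),
           sum(seg@neuriteMask), nrow(seg@attachmentPoints),
           nrow(seg@endingPoints), nrow(seg@branchPoints))
  if (somaCnt > 0) {
    avg <- raw[2:7] / somaCnt
  } else {
    warning("no soma detected; per-soma averages reported as NA")
    avg <- rep(NA_real_, 6L)
  }
  out <- c(raw, avg)
  names(out) <- nfdFeatureNames()
  out
}
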