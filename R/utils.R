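# Internal helpers: seeded RNG scope, integer rasterization, neighbor counts.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Pixels of a filled disk: integer (row, col) matrix.
diskPixels <- function(center, radius) {
  r0 <- round(center[1]); c0 <- round(center[2]); rad <- radius
  rr <- seq(floor(r0 - rad), ceiling(r0 + rad))
  cc <- seq(floor(c0 - rad), ceiling(c0 + rad))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= rad^2
  as.matrix(g[keep, , drop = FALSE])
}

# Bresenham line between two integer points, inclusive.
bresenham <- function(p0, p1) {
  x0 <- round(p0[1]); y0 <- round(p0[2])
  x1 <- round(p1[1]); y1 <- round(p1[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  out <- matrix(0L, n, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx)  { err <- err + dx; y0 <- y0 + sy }
  }
  out[seq_len(i), , drop = FALSE]
}

# Rasterize a polyline (n x 2 vertices) as Bresenham segments.
rasterPolyline <- function(path) {
  segs <- lapply(seq_len(nrow(path) - 1L), function(i)
    bresenham(path[i, ], path[i + 1L, ]))
  unique(do.call(rbind, segs))
}

# Dilate a pixel set with a disk structuring element of the given odd width.
dilatePixels <- function(px, width) {
  if (width <= 1) return(unique(px))
  rad <- (width - 1) / 2
  offs <- diskPixels(c(0, 0), rad + 1e-9)
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    cbind(px[, 1] + offs[i, 1], px[, 2] + offs[i, 2])))
  unique(out)
}

# Euclidean arc length of a polyline.
polylineLength <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

# Logical matrix shifted by (dr, dc), zero-filled at the border.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + dr; cdst <- cs + dc
  rok <- rdst >= 1L & rdst <= nr
  cok <- cdst >= 1L & cdst <= nc
  out[rdst[rok], cdst[cok]] <- m[rs[rok], cs[cok]]
  out
}

# The eight neighbor offsets in clockwise order starting north
# (P2..P9 in the thinning literature).
NBR_OFFSETS <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                        1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                      ncol = 2L, byrow = TRUE)

# List of the 8 shifted copies of a logical matrix, clockwise from north.
# neighborStack(m)[[k]][i, j] is TRUE when neighbor k of (i, j) is set.
neighborStack <- function(m) {
  lapply(seq_len(8L), function(k)
    shiftMat(m, -NBR_OFFSETS[k, 1L], -NBR_OFFSETS[k, 2L]))
}

# Count of set 8-neighbors for every pixel.
neighborCount <- function(m) {
  Reduce(`+`, lapply(neighborStack(m), function(x) x + 0L))
}

# Number of circular foreground runs among the 8 neighbors of each pixel:
# transitions FALSE -> TRUE walking the neighborhood circularly.
neighborRuns <- function(m) {
  st <- neighborStack(m)
  runs <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    runs <- runs + ((!st[[k]]) & st[[nxt]])
  }
  runs
}

# 8-connected labeling. EBImage::bwlabel is 4-connected (it would
# fragment diagonal one-pixel skeletons), so its labels are merged
# across diagonal adjacencies with a small union-find over label ids.
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nr, nc)
  n <- max(lab)
  if (n > 1L) {
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    parent <- seq_len(n)
    findRoot <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    if (nrow(pairs) > 0L) {
      pairs <- unique(pairs)
      for (i in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[i, 1]); rb <- findRoot(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(n), findRoot, 0L)
    relabel <- as.integer(factor(roots))
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  lab
}

# Remove connected components smaller than minPx.
removeSmall <- function(mask, minPx) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minPx)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Coordinates (row, col) of TRUE pixels.
maskWhich <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("row", "col")
  w
}

zeroPoints <- function() matrix(integer(0), 0L, 2L,
                                dimnames = list(NULL, c("row", "col")))
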