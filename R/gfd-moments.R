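# Shape descriptors on binary masks: orthogonal moment families and the
# polar (generic) Fourier descriptor. All operate about the mask centroid
# where the family calls for it, so the magnitudes are translation
# invariant within the frame.

maskCentroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask: centroid undefined")
  colMeans(w)
}

# Radial Zernike polynomial R_nm(rho) for scalars n, m and a rho vector.
zernikeRadial <- function(n, m, rho) {
  s <- 0:((n - m) / 2)
  coef <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) / 2 - s) *
       factorial((n - m) / 2 - s))
  pw <- outer(rho, n - 2 * s, `^`)
  drop(pw %*% coef)
}

#' Zernike moment magnitudes of a binary mask
#'
#' Computes `|Z_nm|` for all `n <= order`, `m >= 0`, `n - m` even, on the
#' unit disk centered at the mask centroid with radius enclosing the mask.
#' The feature count is `(order/2 + 1)^2`: 4, 9, 25, 81 for orders 2, 4,
#' 8, 16.
#'
#' @param mask logical matrix; must contain at least one pixel.
#' @param order maximum moment order (even).
#' @return named numeric vector of moment magnitudes.
#' @export
zernikeFeatures <- function(mask, order = 8) {
  ctr <- maskCentroid(mask)
  w <- which(mask, arr.ind = TRUE)
  dy <- w[, 1] - ctr[1]; dx <- w[, 2] - ctr[2]
  R <- max(sqrt(dy^2 + dx^2), 1e-9)
  rho <- sqrt(dy^2 + dx^2) / R
  theta <- atan2(dy, dx)
  keep <- rho <= 1
  rho <- rho[keep]; theta <- theta[keep]
  out <- c(); nm <- c()
  for (n in 0:order) {
    for (m in seq(n %% 2, n, by = 2)) {
      rad <- zernikeRadial(n, m, rho)
      z <- sum(rad * exp(-1i * m * theta)) * (n + 1) / (pi * R^2)
      out <- c(out, Mod(z))
      nm <- c(nm, sprintf("zern_n%d_m%d", n, m))
    }
  }
  names(out) <- nm
  out
}

legendrePoly <- function(p, x) {
  # rows: orders 0..p, columns: x
  out <- matrix(0, p + 1L, length(x))
  out[1, ] <- 1
  if (p >= 1) out[2, ] <- x
  if (p >= 2) for (k in 2:p)
    out[k + 1, ] <- ((2 * k - 1) * x * out[k, ] - (k - 1) * out[k - 1, ]) / k
  out
}

#' Legendre moments of a binary mask
#'
#' Moments `lambda_pq` for `p, q <= order` of the mask mapped onto
#' `[-1, 1]^2`, with the standard normalization
#' `(2p+1)(2q+1)/(N M)`; the all-ones mask gives `lambda_00 = 1`.
#' Feature count `(order + 1)^2`: 9, 25, 81, 289 for orders 2, 4, 8, 16.
#'
#' @param mask logical matrix, non-empty.
#' @param order maximum order in each direction.
#' @return named numeric vector.
#' @export
legendreFeatures <- function(mask, order = 8) {
  if (!any(mask)) stop("empty mask")
  N <- nrow(mask); M <- ncol(mask)
  x <- (2 * seq_len(N) - N - 1) / (N - 1)
  y <- (2 * seq_len(M) - M - 1) / (M - 1)
  Px <- legendrePoly(order, x)              # (order+1) x N
  Py <- legendrePoly(order, y)              # (order+1) x M
  core <- Px %*% mask %*% t(Py)             # (order+1) x (order+1)
  norm <- outer(2 * (0:order) + 1, 2 * (0:order) + 1) / (N * M)
  lam <- norm * core
  out <- as.vector(t(lam))
  names(out) <- as.vector(t(outer(0:order, 0:order, function(p, q)
    sprintf("leg_p%d_q%d", p, q))))
  out
}

# Orthonormal discrete Chebyshev polynomials t_0..t_p on {0..N-1}
# (unit norm), by the stabilized three-term recurrence.
tchebichefPoly <- function(p, N) {
  x <- 0:(N - 1)
  out <- matrix(0, p + 1L, N)
  out[1, ] <- 1 / sqrt(N)
  if (p >= 1)
    out[2, ] <- (2 * x + 1 - N) * sqrt(3 / (N * (N^2 - 1)))
  if (p >= 2) for (n in 2:p) {
    a1 <- (2 / n) * sqrt((4 * n^2 - 1) / (N^2 - n^2))
    a2 <- ((1 - N) / n) * sqrt((4 * n^2 - 1) / (N^2 - n^2))
    a3 <- -((n - 1) / n) * sqrt((2 * n + 1) / (2 * n - 3)) *
      sqrt((N^2 - (n - 1)^2) / (N^2 - n^2))
    out[n + 1, ] <- (a1 * x + a2) * out[n, ] + a3 * out[n - 1, ]
  }
  out
}

#' Tchebichef (discrete Chebyshev) moments of a binary mask
#'
#' Moments `T_pq` for `p, q <= order` using orthonormal discrete
#' Chebyshev polynomials on the pixel grid. Feature count
#' `(order + 1)^2`: 9, 25, 81, 289 for orders 2, 4, 8, 16.
#'
#' @param mask logical matrix, non-empty.
#' @param order maximum order in each direction.
#' @return named numeric vector.
#' @export
tchebichefFeatures <- function(mask, order = 8) {
  if (!any(mask)) stop("empty mask")
  N <- nrow(mask); M <- ncol(mask)
  Tx <- tchebichefPoly(order, N)
  Ty <- tchebichefPoly(order, M)
  core <- Tx %*% mask %*% t(Ty)
  out <- as.vector(t(core))
  names(out) <- as.vector(t(outer(0:order, 0:order, function(p, q)
    sprintf("tcheb_p%d_q%d", p, q))))
  out
}

#' Generic (polar) Fourier descriptor of a binary mask
#'
#' Magnitudes of the polar two-dimensional Fourier transform about the
#' mask centroid, sampled at `nAngular` angular x `nRadial` radial
#' frequencies and normalized by the DC term (which therefore equals 1
#' exactly). Default grid 5 x 12 gives 60 features.
#'
#' @param mask logical matrix, non-empty.
#' @param nAngular angular frequencies.
#' @param nRadial radial frequencies.
#' @return named numeric vector of length `nAngular * nRadial`.
#' @export
genericFourierFeatures <- function(mask, nAngular = 5, nRadial = 12) {
  ctr <- maskCentroid(mask)
  w <- which(mask, arr.ind = TRUE)
  dy <- w[, 1] - ctr[1]; dx <- w[, 2] - ctr[2]
  R <- max(sqrt(dy^2 + dx^2), 1e-9)
  r <- sqrt(dy^2 + dx^2) / R
  th <- atan2(dy, dx)
  out <- numeric(nAngular * nRadial)
  nm <- character(length(out))
  k <- 0L
  dc <- length(r)                    # |G(0,0)| = pixel count
  for (phi in 0:(nAngular - 1L)) {
    for (rho in 0:(nRadial - 1L)) {
      k <- k + 1L
      g <- sum(exp(-2i * pi * r * rho - 1i * phi * th))
      out[k] <- Mod(g) / dc
      nm[k] <- sprintf("gfour_a%d_r%d", phi, rho)
    }
  }
  names(out) <- nm
  out
}
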