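# Fibre orientation distributions are held as real even-order spherical-
# harmonic (SH) coefficient grids, the standard output representation of
# constrained spherical deconvolution. Basis convention: for each even l and
# m = -l..l, Y_{l,m} built from associated Legendre functions (MATLAB/
# Condon-Shortley convention) with sqrt(2)*cos/sin
# azimuthal factors for |m| > 0, coefficients ordered (l,m) = (0,0), (2,-2)
# ... (2,2), (4,-4) ... — the MRtrix-style ordering.

sh_ncoef <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

sh_order_from_ncoef <- function(ncoef) {
  for (l in seq(0L, 20L, 2L)) if (sh_ncoef(l) == ncoef) return(l)
  stop("coefficient count ", ncoef,
       " does not match any even SH order", call. = FALSE)
}

# Associated Legendre functions P_l^m(x) for l = 0..lmax, m = 0..l, with the
# Condon-Shortley phase (MATLAB convention), by the standard stable upward
# recurrences, vectorised over x. Returns list indexed [[l+1]] of
# (l+1) x n matrices (rows m = 0..l).
assoc_legendre <- function(lmax, x) {
  n <- length(x)
  somx2 <- sqrt(pmax(1 - x^2, 0))
  P <- matrix(0, (lmax + 1L) * (lmax + 1L), n)   # row index: l * (lmax+1) + m + 1
  ix <- function(l, m) l * (lmax + 1L) + m + 1L
  P[ix(0L, 0L), ] <- 1
  for (m in 0:lmax) {
    if (m > 0L)
      P[ix(m, m), ] <- -(2 * m - 1) * somx2 * P[ix(m - 1L, m - 1L), ]
    if (m < lmax)
      P[ix(m + 1L, m), ] <- (2 * m + 1) * x * P[ix(m, m), ]
    if (m + 2L <= lmax)
      for (l in (m + 2L):lmax)
        P[ix(l, m), ] <- ((2 * l - 1) * x * P[ix(l - 1L, m), ] -
                            (l + m - 1) * P[ix(l - 2L, m), ]) / (l - m)
  }
  lapply(0:lmax, function(l)
    P[ix(l, 0L:l), , drop = FALSE])
}

#' Evaluate the real even-order SH basis at unit directions
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param lmax Maximum (even) harmonic order.
#' @return n x ncoef basis matrix, ncoef = (lmax+1)(lmax+2)/2.
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- rbind3(dirs)
  n <- nrow(dirs)
  theta_cos <- pmin(pmax(dirs[, 3], -1), 1)          # cos(polar angle)
  phi <- atan2(dirs[, 2], dirs[, 1])
  Ptab <- assoc_legendre(lmax, theta_cos)
  B <- matrix(0, n, sh_ncoef(lmax))
  col <- 1L
  for (l in seq(0L, lmax, 2L)) {
    P <- Ptab[[l + 1L]]                               # (l+1) x n, rows m=0..l
    for (m in (-l):l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrm * P[am + 1L, ]
      B[, col] <- if (m < 0) sqrt(2) * base * sin(am * phi)
                  else if (m == 0) base
                  else sqrt(2) * base * cos(am * phi)
      col <- col + 1L
    }
  }
  B
}

#' Spherical-harmonic fODF coefficient field
#'
#' @param coef 4D array (x, y, z, ncoef) of real even-order SH coefficients.
#' @param lmax Maximum harmonic order; must match `dim(coef)[4]`.
#' @param affine 4x4 voxel-to-world matrix (RAS+).
#' @return An object of class `fodf_field`. A flattened voxel x coefficient
#'   matrix is cached for fast interpolation during tracking.
#' @export
fodf_field <- function(coef, lmax, affine) {
  if (length(dim(coef)) != 4L) stop("coef must be 4D", call. = FALSE)
  if (dim(coef)[4] != sh_ncoef(lmax))
    stop(sprintf("coef has %d coefficients but lmax=%d needs %d",
                 dim(coef)[4], lmax, sh_ncoef(lmax)), call. = FALSE)
  check_affine(affine)
  if (!all(is.finite(coef))) stop("fODF coefficients must be finite", call. = FALSE)
  dm <- dim(coef)[1:3]
  coef_mat <- matrix(coef, nrow = prod(dm), ncol = dim(coef)[4])
  structure(list(coef = coef, coef_mat = coef_mat, lmax = lmax,
                 affine = affine, dim = dm),
            class = "fodf_field")
}

#' @export
print.fodf_field <- function(x, ...) {
  cat(sprintf("<fodf_field dim=%s lmax=%d>\n",
              paste(x$dim, collapse = "x"), x$lmax))
  invisible(x)
}

# trilinearly interpolated SH coefficient vectors at world points (n x ncoef)
interp_coef <- function(field, points) {
  points <- rbind3(points)
  dm <- field$dim
  idx <- world_to_voxel(points, field$affine)
  idx[, 1] <- pmin(pmax(idx[, 1], 0), dm[1] - 1)
  idx[, 2] <- pmin(pmax(idx[, 2], 0), dm[2] - 1)
  idx[, 3] <- pmin(pmax(idx[, 3], 0), dm[3] - 1)
  i0 <- floor(idx)
  i0[, 1] <- pmin(pmax(i0[, 1], 0), dm[1] - 2)
  i0[, 2] <- pmin(pmax(i0[, 2], 0), dm[2] - 2)
  i0[, 3] <- pmin(pmax(i0[, 3], 0), dm[3] - 2)
  f <- idx - i0
  acc <- matrix(0, nrow(points), ncol(field$coef_mat))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- 1 + (i0[, 1] + dx) + dm[1] * ((i0[, 2] + dy) + dm[2] * (i0[, 3] + dz))
    acc <- acc + w * field$coef_mat[lin, , drop = FALSE]
  }
  acc
}

#' Evaluate fODF amplitude at a point along directions
#'
#' The SH expansion is evaluated at the given unit directions with
#' coefficients trilinearly interpolated between voxels; negative values are
#' clamped to zero.
#'
#' @param field A [fodf_field].
#' @param point Length-3 world-mm position (must lie inside the field domain).
#' @param dirs n x 3 matrix (or length-3 vector) of unit directions.
#' @return Numeric vector of non-negative amplitudes, one per direction.
#' @export
fodf_amplitude <- function(field, point, dirs) {
  point <- rbind3(point)
  if (!points_in_domain(point, field$affine, field$dim))
    stop("point lies outside the fODF field domain", call. = FALSE)
  dirs <- rbind3(dirs)
  coef <- interp_coef(field, point)
  amp <- as.vector(sh_basis(dirs, field$lmax) %*% t(coef))
  pmax(amp, 0)
}

# fast path used by the tracker: coefficients already interpolated
amplitude_from_coef <- function(coef_vec, dirs, lmax) {
  pmax(as.vector(sh_basis(dirs, lmax) %*% coef_vec), 0)
}

#' Global maximum fODF amplitude of a field
#'
#' Approximated by evaluating the expansion at every voxel over a fixed set
#' of well-distributed unit directions; cached on first use. The tracker's
#' amplitude cutoffs ("x% of the maximum amplitude") are referenced to this
#' value.
#'
#' @param field A [fodf_field].
#' @param n_dirs Number of probe directions.
#' @return Scalar maximum amplitude.
#' @export
fodf_max_amplitude <- function(field, n_dirs = 100L) {
  cached <- attr(field, "max_amp")
  if (!is.null(cached)) return(cached)
  dirs <- fibonacci_sphere(n_dirs)
  B <- sh_basis(dirs, field$lmax)
  # voxels in chunks to bound memory
  nvox <- nrow(field$coef_mat)
  mx <- 0
  chunk <- 20000L
  for (start in seq(1L, nvox, chunk)) {
    end <- min(start + chunk - 1L, nvox)
    amp <- field$coef_mat[start:end, , drop = FALSE] %*% t(B)
    mx <- max(mx, max(amp))
  }
  max(mx, 0)
}

# deterministic well-distributed unit directions (golden-spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# least-squares SH projection operator for a direction set:
# coef = P %*% f(dirs)
sh_projector <- function(dirs, lmax) {
  B <- sh_basis(dirs, lmax)
  solve(crossprod(B), t(B))
}
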