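#' @keywords internal
"_PACKAGE"

# Degree-based trigonometry helpers used throughout: all user-facing angles
# (rotation angles, fiber directions, inclinations, radiality) are degrees.
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise rows of a matrix to unit length
#' @noRd
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("zero-length vector cannot be normalised")
  m / n
}

#' Deterministic completion of a unit vector to an orthonormal frame
#'
#' Returns a 3x3 matrix whose first column is `d`; the remaining columns are
#' chosen deterministically (seeded from the coordinate axis least aligned
#' with `d`), so repeated calls agree bit-for-bit.
#' @noRd
orthonormal_frame <- function(d) {
  d <- d / sqrt(sum(d^2))
  e <- diag(3)[, which.min(abs(d))]
  u <- e - sum(e * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  cbind(d, u, v, deparse.level = 0)
}

#' Build a symmetric tensor from a principal direction and eigenvalues
#'
#' Eigenvalue order: along `d`, then the two transverse axes. For axially
#' symmetric tensors (l2 == l3) the result does not depend on the frame
#' completion.
#' @noRd
tensor_from_direction <- function(d, evals) {
  R <- orthonormal_frame(d)
  R %*% diag(evals) %*% t(R)
}

#' Fractional anisotropy from three eigenvalues
#' @noRd
fa_from_evals <- function(l) {
  l <- pmax(l, 0)
  ss <- sum(l^2)
  if (ss == 0) return(0)
  lb <- mean(l)
  min(1, max(0, sqrt(3 / 2 * sum((l - lb)^2) / ss)))
}

#' World coordinates of voxel centers
#'
#' Voxel (i, j, k), 0-based, occupies the half-open cube
#' [i - 0.5, i + 0.5) x ... in voxel space; its center maps through the
#' affine. `idx` is an n x 3 matrix of 0-based indices.
#' @noRd
voxel_to_world <- function(idx, affine) {
  h <- cbind(idx, 1)
  t(affine[1:3, , drop = FALSE] %*% t(h))
}

#' Map world points to 0-based voxel indices (voxel-center containment)
#' @noRd
world_to_voxel <- function(pts, affine) {
  h <- cbind(pts, 1)
  v <- t(solve(affine) %*% t(h))[, 1:3, drop = FALSE]
  floor(v + 0.5)
}

#' 0-based voxel indices of all nonzero voxels of a 3D array
#' @noRd
mask_indices <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (length(w) == 0) return(matrix(numeric(0), 0, 3))
  w - 1
}

#' Simple RAS affine from a voxel size and world origin
#' @noRd
affine_from_voxsize <- function(voxel_size, origin = c(0, 0, 0)) {
  a <- diag(4)
  a[1, 1] <- voxel_size[1]
  a[2, 2] <- voxel_size[2]
  a[3, 3] <- voxel_size[3]
  a[1:3, 4] <- origin
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unit tangents of a dense polyline by central differences
#' @noRd
polyline_tangents <- function(pos) {
  n <- nrow(pos)
  tg <- matrix(0, n, 3)
  tg[2:(n - 1), ] <- pos[3:n, ] - pos[1:(n - 2), ]
  tg[1, ] <- -3 * pos[1, ] + 4 * pos[2, ] - pos[3, ]
  tg[n, ] <- 3 * pos[n, ] - 4 * pos[n - 1, ] + pos[n - 2, ]
  unit_rows(tg)
}
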