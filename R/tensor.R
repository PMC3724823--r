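# Diffusion-tensor fitting, FA and direction-coded colour maps.

#' Fit a diffusion tensor per voxel
#'
#' Plain (unweighted) log-linear least squares of
#' \deqn{\ln S = \ln S_0 - b\, g^T D g}
#' per voxel. All b = 0 measurements are averaged into a single baseline
#' before fitting. Negative eigenvalues are clamped to 1e-12 mm^2/s; FA uses
#' the standard normalised eigenvalue-dispersion formula; the principal
#' direction is the eigenvector of the largest eigenvalue (sign-ambiguous).
#'
#' @param dwi A `dwi_volume` (or list with `signal`, `scheme`, `affine`,
#'   `voxel_size`).
#' @param mask Binary 3D array on the same grid; `NULL` fits everywhere.
#' @param weighted If `TRUE`, one reweighted pass with weights S^2 (the
#'   usual WLS approximation); default plain LS.
#' @param signal_floor Signals at or below zero are floored here before the
#'   log (with a warning).
#' @return An object of class `tensor_field`: `tensors` (n x 6 lower
#'   triangle: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, mm^2/s), `evals` (n x 3,
#'   descending), `fa`, `md`, `principal_dir` (n x 3 unit rows), `s0`,
#'   `voxel_index` (0-based, n x 3), `mask`, `affine`, `voxel_size`.
#' @export
fit_tensors <- function(dwi, mask = NULL, weighted = FALSE,
                        signal_floor = 1e-6) {
  scheme <- dwi$scheme
  b <- scheme$bvalues
  g <- scheme$directions
  if (sum(b > 0) < 6) stop("insufficient data: need >= 6 diffusion-weighted measurements")
  if (sum(b == 0) < 1) stop("insufficient data: need >= 1 b = 0 measurement")
  dims <- dim(dwi$signal)[1:3]
  if (is.null(mask)) mask <- array(1, dim = dims)
  if (!identical(dim(mask), dims)) stop("mask grid does not match DWI grid")
  vi <- mask_indices(mask)
  if (nrow(vi) == 0) stop("empty mask")

  nvox_total <- prod(dims)
  flat <- which(mask != 0)
  m <- length(b)
  S <- matrix(0, m, length(flat))
  for (q in seq_len(m)) S[q, ] <- dwi$signal[flat + (q - 1) * nvox_total]

  # Average the b = 0 measurements into one baseline row.
  i0 <- which(b == 0)
  iw <- which(b > 0)
  S <- rbind(colMeans(S[i0, , drop = FALSE]), S[iw, , drop = FALSE])
  b <- c(0, b[iw])
  g <- rbind(c(0, 0, 0), g[iw, , drop = FALSE])

  # Design: ln S = X beta, beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  if (qr(X[-1, -1])$rank < 6) {
    stop("insufficient data: gradient directions are collinear/degenerate")
  }
  nonpos <- S <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " non-positive signal value(s) floored at ",
            signal_floor, " before log")
    S[nonpos] <- signal_floor
  }
  Y <- log(S)
  beta <- qr.solve(X, Y)
  if (weighted) {
    # One IRLS pass with the fitted signals squared as weights.
    W <- exp(X %*% beta)^2
    beta <- vapply(seq_len(ncol(Y)), function(j) {
      w <- W[, j]
      qr.solve(X * sqrt(w), Y[, j] * sqrt(w))
    }, numeric(7))
  }

  n <- ncol(Y)
  evals <- matrix(0, n, 3)
  pdir <- matrix(0, n, 3)
  fa <- numeric(n)
  for (j in seq_len(n)) {
    d6 <- beta[2:7, j]
    D <- matrix(c(d6[1], d6[4], d6[5],
                  d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    l <- pmax(e$values, 1e-12)
    evals[j, ] <- l
    pdir[j, ] <- e$vectors[, 1]
    fa[j] <- fa_from_evals(l)
  }
  structure(list(
    tensors = t(beta[2:7, , drop = FALSE]),
    evals = evals, fa = fa, md = rowMeans(evals),
    principal_dir = unit_rows(pdir),
    s0 = exp(beta[1, ]),
    voxel_index = vi, mask = mask,
    affine = dwi$affine, voxel_size = dwi$voxel_size
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("Tensor field:", nrow(x$tensors), "voxels; mean FA",
      round(mean(x$fa), 3), "\n")
  invisible(x)
}

#' Direction-coded colour map
#'
#' Standard DTI colour convention: red = left-right (|v_x|), green =
#' posterior-anterior (|v_y|), blue = inferior-superior (|v_z|), scaled by
#' FA (or unscaled). Sign-invariant by construction.
#'
#' @param field A `tensor_field`.
#' @param scale_by_fa Multiply colours by FA (default `TRUE`).
#' @return 4D array (grid dims x 3) with values in [0, 1].
#' @export
direction_color_map <- function(field, scale_by_fa = TRUE) {
  stopifnot(inherits(field, "tensor_field"))
  if (is.null(field$affine)) stop("tensor field has no affine")
  dims <- dim(field$mask)
  rgb <- array(0, dim = c(dims, 3))
  s <- if (scale_by_fa) field$fa else 1
  col <- abs(field$principal_dir) * s
  flat <- which(field$mask != 0)
  nt <- prod(dims)
  for (ch in 1:3) rgb[flat + (ch - 1) * nt] <- pmin(1, col[, ch])
  rgb
}

#' Write FA, principal-direction and RGB maps as NIfTI
#'
#' @param field A `tensor_field`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_tensor_maps <- function(field, dir, prefix = "dti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  dims <- dim(field$mask)
  nt <- prod(dims)
  flat <- which(field$mask != 0)
  fa_vol <- array(0, dims); fa_vol[flat] <- field$fa
  dir_vol <- array(0, c(dims, 3))
  for (ch in 1:3) dir_vol[flat + (ch - 1) * nt] <- field$principal_dir[, ch]
  write_nifti(fa_vol, p("_fa.nii.gz"), field$affine)
  write_nifti(dir_vol, p("_v1.nii.gz"), field$affine)
  write_nifti(direction_color_map(field), p("_rgb.nii.gz"), field$affine)
  invisible(c(fa = p("_fa.nii.gz"), v1 = p("_v1.nii.gz"),
              rgb = p("_rgb.nii.gz")))
}
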