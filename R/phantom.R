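# Curved-nucleus diffusion phantom with planted ground truth.
#
# The phantom mimics the caudate head+body in a sagittal plane: a planar
# circular-arc centerline swept by a tube on an isotropic grid. Every masked
# voxel carries a tangential fiber compartment (along the local arc tangent)
# and a radial one (in-plane, perpendicular to the arc), with a volume-
# fraction schedule along arc length that plants the two microstructural
# boundaries: the radial fraction crosses 0.5 exactly at the first boundary
# (so the fitted principal direction flips there and the radiality profile
# crosses 45 degrees), stays radial-dominant through the middle segment, and
# dips into a narrow tangential zone at the second boundary (the near-head
# local minimum) before turning radial again toward the tip.

#' Default compartment configuration for the phantom
#'
#' Eigenvalues are typical for coherent white/gray-matter fiber populations
#' (1.7, 0.3, 0.3) x 1e-3 mm^2/s. The radial-fraction schedule is piecewise
#' linear in arc-length fraction with knots placed so the 0.5 crossing falls
#' exactly on `boundaries[1]` and the V-shaped minimum exactly on
#' `boundaries[2]`.
#'
#' @param boundaries Two arc-length fractions in (0,1), strictly increasing.
#' @return List with `evals_tangential`, `evals_radial` (mm^2/s triples) and
#'   `radial_knots` (two-column matrix: arc fraction, radial fraction).
#' @export
default_compartment_config <- function(boundaries = c(0.45, 0.75)) {
  b1 <- boundaries[1]
  b2 <- boundaries[2]
  knots <- rbind(
    c(0,            0.15),
    c(b1 - 0.10,    0.20),
    c(b1 + 0.10,    0.80),   # midpoint of the ramp = 0.5 at b1
    c(b2 - 0.10,    0.80),
    c(b2,           0.30),   # tangential dip: the near-head local minimum
    c(b2 + 0.10,    0.80),
    c(1,            0.85)
  )
  list(
    evals_tangential = c(1.7e-3, 3e-4, 3e-4),
    evals_radial     = c(1.7e-3, 3e-4, 3e-4),
    radial_knots     = knots
  )
}

#' Generate the curved-nucleus phantom
#'
#' Builds a connected voxel mask around a planar circular-arc centerline in
#' the sagittal (y-z) plane, with per-voxel tangential/radial fiber
#' compartments and planted segment boundaries. The arc center doubles as
#' the anterior-commissure surrogate, so the angle about `ac_point` is an
#' exact arc parameter. Arc length s = 0 at the posterior end.
#'
#' @param arc_radius Radius of the centerline circle, mm (default 25).
#' @param arc_span Angular extent of the arc, degrees (default 120).
#' @param tube_radius Radius of the swept tube, mm (default 4).
#' @param voxel_size Isotropic voxel edge, mm (default 1).
#' @param boundaries Two arc-length fractions (0 < f1 < f2 < 1) where the
#'   segment labels switch (default c(0.45, 0.75)).
#' @param compartment_config See [default_compartment_config()]. A
#'   `radial_knots` schedule with all fractions 0 yields a single tangential
#'   compartment per voxel.
#' @return An object of class `cn_phantom`: `mask`, `affine`, `voxel_size`,
#'   `arc` (centerline points, posterior end first), `arc_length_total` (mm),
#'   `planted_boundaries` (mm arc length), `segment_labels` (1 posterior /
#'   2 middle / 3 anterior), `ac_point`, `compartments` (per-slot unit
#'   directions, fractions and tensor eigenvalues for the masked voxels),
#'   `voxel_arc_length` (per masked voxel, mm) and `voxel_index` (0-based).
#' @export
make_cn_phantom <- function(arc_radius = 25, arc_span = 120,
                            tube_radius = 4, voxel_size = 1,
                            boundaries = c(0.45, 0.75),
                            compartment_config =
                              default_compartment_config(boundaries)) {
  if (length(boundaries) != 2 ||
      any(boundaries <= 0) || any(boundaries >= 1) ||
      boundaries[1] >= boundaries[2]) {
    stop("boundaries must be two strictly increasing fractions in (0, 1)")
  }
  if (arc_radius <= 0 || tube_radius <= 0 || voxel_size <= 0) {
    stop("arc radius, tube radius and voxel size must be positive")
  }
  if (tube_radius < voxel_size) {
    stop("degenerate geometry: tube radius (", tube_radius,
         " mm) below one voxel (", voxel_size, " mm)")
  }
  kn <- compartment_config$radial_knots
  if (any(kn[, 2] < 0) || any(kn[, 2] > 1)) {
    stop("radial fractions must lie in [0, 1]")
  }
  if (is.unsorted(kn[, 1], strictly = TRUE)) {
    stop("radial-fraction knot positions must be strictly increasing")
  }

  # Arc in the y-z plane, center at the origin (= ac surrogate), spanning
  # [-90 - span/2, -90 + span/2] degrees so posterior (-y) comes first.
  th0 <- deg2rad(-90 - arc_span / 2)
  th1 <- deg2rad(-90 + arc_span / 2)
  arc_len_total <- arc_radius * (th1 - th0)

  margin <- tube_radius + 2 * voxel_size
  yr <- range(arc_radius * cos(c(th0, th1, (th0 + th1) / 2)))
  zr <- range(arc_radius * sin(c(th0, th1, (th0 + th1) / 2)))
  lo <- c(-margin, yr[1] - margin, zr[1] - margin)
  hi <- c(margin, yr[2] + margin, zr[2] + margin)
  dims <- ceiling((hi - lo) / voxel_size) + 1L
  affine <- affine_from_voxsize(rep(voxel_size, 3), lo)

  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  w <- voxel_to_world(idx, affine)
  # Distance to the arc: off-plane (x) plus in-plane distance to the circle,
  # with the angle clamped to the arc's angular range.
  th_v <- atan2(w[, 3], w[, 2])
  th_c <- pmin(pmax(th_v, th0), th1)
  nearest <- cbind(0, arc_radius * cos(th_c), arc_radius * sin(th_c))
  d2 <- rowSums((w - nearest)^2)
  # clip to the angular range (no spherical end caps) so the angular
  # parameter coverage matches the arc length exactly
  inside <- d2 <= tube_radius^2 & th_v >= th0 & th_v <= th1

  mask <- array(0, dim = dims)
  mask[idx[inside, , drop = FALSE] + 1] <- 1

  vi <- idx[inside, , drop = FALSE]
  wv <- w[inside, , drop = FALSE]
  th <- th_c[inside]
  s <- arc_radius * (th - th0)           # projected arc length, mm

  # Unit tangent (increasing s) and outward in-plane radial direction.
  tan_dir <- cbind(0, -sin(th), cos(th))
  rad_dir <- cbind(0, cos(th), sin(th))

  f_rad <- stats::approx(kn[, 1], kn[, 2], xout = s / arc_len_total,
                         rule = 2)$y
  comps <- list(
    tangential = list(directions = tan_dir, fraction = 1 - f_rad,
                      evals = compartment_config$evals_tangential),
    radial = list(directions = rad_dir, fraction = f_rad,
                  evals = compartment_config$evals_radial)
  )
  comps <- Filter(function(cc) max(cc$fraction) > 0, comps)

  sb <- boundaries * arc_len_total
  labels <- array(0, dim = dims)
  labels[vi + 1] <- 1 + (s >= sb[1]) + (s >= sb[2])

  arc_pts <- {
    tt <- seq(th0, th1, length.out = 200)
    cbind(0, arc_radius * cos(tt), arc_radius * sin(tt))
  }

  structure(list(
    mask = mask, affine = affine, voxel_size = rep(voxel_size, 3),
    arc = arc_pts, arc_length_total = arc_len_total,
    planted_boundaries = sb, segment_labels = labels,
    ac_point = c(0, 0, 0), compartments = comps,
    voxel_arc_length = s, voxel_index = vi
  ), class = "cn_phantom")
}

#' @export
print.cn_phantom <- function(x, ...) {
  cat("Curved-nucleus phantom:", sum(x$mask), "voxels, arc length",
      round(x$arc_length_total, 1), "mm, planted boundaries at",
      paste(round(x$planted_boundaries, 2), collapse = " / "), "mm\n")
  invisible(x)
}

#' Ground-truth longitudinal axis of a phantom
#'
#' Builds a `longitudinal_spline` object directly from the phantom's
#' analytic arc (exact positions, tangents and arc lengths) instead of
#' fitting one to the mask. Useful for isolating the radiality computation
#' from axis-estimation error.
#'
#' @param truth A `cn_phantom`.
#' @param n_samples Number of equidistant parameter samples (default 45).
#' @return A `longitudinal_spline`.
#' @export
truth_spline <- function(truth, n_samples = 45) {
  stopifnot(inherits(truth, "cn_phantom"))
  # recover the angular range and radius from the stored arc points
  th <- atan2(truth$arc[, 3] - truth$ac_point[3],
              truth$arc[, 2] - truth$ac_point[2])
  th0 <- th[1]; th1 <- th[length(th)]
  R <- truth$arc_length_total / (th1 - th0)
  mk <- function(tt) {
    list(pos = cbind(truth$ac_point[1], truth$ac_point[2] + R * cos(tt),
                     truth$ac_point[3] + R * sin(tt)),
         tan = cbind(0, -sin(tt), cos(tt)))
  }
  param <- seq(rad2deg(th0), rad2deg(th1), length.out = n_samples)
  dense_param <- seq(rad2deg(th0), rad2deg(th1),
                     length.out = max(20 * n_samples, 400))
  s45 <- mk(deg2rad(param))
  sd <- mk(deg2rad(dense_param))
  structure(list(
    param = param, positions = s45$pos, tangents = s45$tan,
    arc_length = R * (deg2rad(param) - th0),
    dense_param = dense_param, dense_pos = sd$pos,
    dense_arc = R * (deg2rad(dense_param) - th0),
    dense_tangents = sd$tan,
    ac_point = truth$ac_point, n_samples = n_samples,
    plane = NULL
  ), class = "longitudinal_spline")
}

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Noiseless signal at each masked voxel is the multi-tensor mixture
#' \deqn{S(b, g) = S_0 \sum_i f_i \exp(-b\, g^T D_i g)}
#' with each compartment tensor built from its unit direction and
#' eigenvalues. Voxels outside the mask get an isotropic background
#' (diffusivity 0.7e-3 mm^2/s). Rician (magnitude) noise of scale
#' `noise_sigma` is applied when positive.
#'
#' @param truth A `cn_phantom`.
#' @param scheme A `gradient_scheme` (default: 60 directions at
#'   b = 1000 s/mm^2 plus one b = 0).
#' @param s0 Baseline (b = 0) signal, same units as `noise_sigma`.
#' @param noise_sigma Rician noise scale; SNR on b = 0 is `s0/noise_sigma`.
#' @param rng_seed Integer seed; identical seeds give bit-identical output.
#' @param background_adc Isotropic background diffusivity, mm^2/s.
#' @return An object of class `dwi_volume`: `signal` (4D array), `scheme`,
#'   `voxel_size`, `affine`.
#' @export
simulate_dwi <- function(truth, scheme = default_scheme(), s0 = 1,
                         noise_sigma = 0, rng_seed = 1L,
                         background_adc = 0.7e-3) {
  stopifnot(inherits(truth, "cn_phantom"))
  if (!inherits(scheme, "gradient_scheme")) stop("scheme must be a gradient_scheme")
  if (s0 < 0) stop("s0 must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")

  fr <- vapply(truth$compartments, function(cc) cc$fraction,
               numeric(length(truth$voxel_arc_length)))
  fr <- matrix(fr, ncol = length(truth$compartments))
  if (max(abs(rowSums(fr) - 1)) > 1e-9) {
    stop("compartment fractions must sum to 1 at every masked voxel")
  }

  sig <- multi_tensor_signal(truth$compartments, scheme, s0)
  dims <- dim(truth$mask)
  m <- length(scheme)
  signal <- array(0, dim = c(dims, m))
  bg <- s0 * exp(-scheme$bvalues * background_adc)
  for (q in seq_len(m)) signal[, , , q] <- bg[q]
  flat_mask <- which(truth$mask != 0)
  nvox_total <- prod(dims)
  for (q in seq_len(m)) {
    signal[flat_mask + (q - 1) * nvox_total] <- sig[, q]
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(rng_seed))
    n <- length(signal)
    signal <- sqrt((signal + stats::rnorm(n, 0, noise_sigma))^2 +
                     stats::rnorm(n, 0, noise_sigma)^2)
    signal <- array(signal, dim = c(dims, m))
  }
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = truth$voxel_size, affine = truth$affine),
            class = "dwi_volume")
}

# Noiseless mixture signal for the masked voxels: n_vox x n_meas matrix.
multi_tensor_signal <- function(compartments, scheme, s0) {
  g <- scheme$directions
  b <- scheme$bvalues
  nv <- nrow(compartments[[1]]$directions)
  sig <- matrix(0, nv, length(b))
  for (cc in compartments) {
    l <- cc$evals
    d <- cc$directions
    if (abs(l[2] - l[3]) < 1e-300) {
      # axially symmetric: g'Dg = l3 + (l1 - l3) (g . d)^2
      dg <- d %*% t(g)                    # nv x m
      q <- l[3] + (l[1] - l[3]) * dg^2
    } else {
      q <- matrix(0, nv, length(b))
      for (v in seq_len(nv)) {
        D <- tensor_from_direction(d[v, ], l)
        q[v, ] <- colSums(g %*% D * t(g))  # diag(G D G')
      }
    }
    e <- exp(-sweep(q, 2, b, `*`))
    sig <- sig + cc$fraction * e
  }
  s0 * sig
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "measurements\n")
  invisible(x)
}

#' Write a phantom's DWI and ground truth to disk
#'
#' DWI as NIfTI-1 + FSL bvec/bval; segment labels as a NIfTI label volume;
#' boundary positions, arc points and ac point as a JSON sidecar.
#'
#' @param truth A `cn_phantom`.
#' @param dwi A `dwi_volume` simulated from it.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(truth, dwi, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  write_nifti(dwi$signal, p("_dwi.nii.gz"), dwi$affine)
  write_gradient_table(dwi$scheme, p(".bvec"), p(".bval"))
  write_nifti(truth$mask, p("_mask.nii.gz"), truth$affine, "int16")
  write_nifti(truth$segment_labels, p("_truth_labels.nii.gz"),
              truth$affine, "int16")
  sidecar <- list(
    planted_boundaries_mm = truth$planted_boundaries,
    arc_length_total_mm = truth$arc_length_total,
    ac_point = truth$ac_point,
    arc_points = truth$arc
  )
  jsonlite::write_json(sidecar, p("_truth.json"), digits = NA,
                       auto_unbox = FALSE)
  out <- c(dwi = p("_dwi.nii.gz"), bvec = p(".bvec"), bval = p(".bval"),
           mask = p("_mask.nii.gz"), labels = p("_truth_labels.nii.gz"),
           truth = p("_truth.json"))
  invisible(out)
}
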