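# Longitudinal spline axis, radiality-index profile, boundary detection,
# tri-partition segmentation and typical-subject selection — the package's
# core computation.

#' Fit the longitudinal spline axis of an arc-shaped mask
#'
#' Each mask voxel's angle about `ac_point` (the anterior-commissure
#' surrogate), measured in the best-fit plane of the mask, serves as the
#' spline parameter. A cubic smoothing spline of each world coordinate
#' against this angle gives the axis, sampled equidistantly on the
#' parameter axis at `n_samples` points with unit tangents and cumulative
#' arc length. Arc length 0 is at the posterior end (smaller y in RAS).
#'
#' @param mask Binary 3D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param ac_point World coordinate of the anterior-commissure surrogate;
#'   must lie outside the mask arc so the angular parameter is monotone.
#' @param n_samples Number of equidistant parameter samples (default 45).
#' @param df Effective degrees of freedom of each coordinate's smoothing
#'   spline (default 8; the axis coordinates are slowly varying in the
#'   angular parameter, and cross-validation against the full-thickness
#'   voxel scatter badly undersmooths).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; overrides `df` when given.
#' @return An object of class `longitudinal_spline` with `param` (degrees),
#'   `positions` (n x 3 mm), `tangents` (n x 3 unit rows), `arc_length`
#'   (cumulative mm, 0 at the posterior end), and a dense polyline
#'   (`dense_param`, `dense_pos`, `dense_arc`) used for projection.
#' @export
fit_longitudinal_spline <- function(mask, affine, ac_point, n_samples = 45,
                                    df = 8, spar = NULL) {
  vi <- mask_indices(mask)
  if (nrow(vi) < 8) stop("mask is empty or too small to fit an axis")
  w <- voxel_to_world(vi, affine)

  ctr <- colMeans(w)
  pc <- eigen(stats::cov(w), symmetric = TRUE)$vectors
  e1 <- pc[, 1]; e2 <- pc[, 2]
  rel <- sweep(w, 2, ac_point)
  u <- rel %*% e1
  v <- rel %*% e2
  phi <- rad2deg(atan2(v, u))

  # Unwrap: place the branch cut in the largest angular gap so the
  # parameter is continuous over the mask.
  so <- sort(phi)
  gaps <- c(diff(so), so[1] + 360 - so[length(so)])
  cut <- so[which.max(gaps)] + max(gaps) / 2
  phi <- (phi - cut) %% 360

  rng <- range(phi)
  if (diff(rng) < 10) {
    stop("degenerate axis: angular range about ac_point is ",
         round(diff(rng), 2), " degrees (< 10)")
  }
  so <- sort(phi)
  d <- diff(so)
  # a one-voxel step at the innermost radius subtends this many degrees;
  # gaps below a few of those are discretisation, not disconnection
  rr <- sqrt(u^2 + v^2)
  vox_deg <- rad2deg(max(sqrt(colSums(affine[1:3, 1:3]^2))) /
                       max(stats::median(rr) / 2, 1e-6))
  big <- which(d > pmax(8 * vox_deg, 10 * stats::median(d)))
  if (length(big) > 0) {
    stop("mask splits into ", length(big) + 1,
         " disconnected angular components (gaps at ",
         paste(round(so[big], 1), collapse = ", "), " degrees)")
  }

  nuniq <- length(unique(round(phi, 6)))
  df <- min(df, nuniq - 1)
  fits <- lapply(1:3, function(a) {
    if (is.null(spar)) {
      stats::smooth.spline(phi, w[, a], df = df, keep.data = FALSE)
    } else {
      stats::smooth.spline(phi, w[, a], spar = spar, keep.data = FALSE)
    }
  })
  eval_curve <- function(p) {
    vapply(fits, function(f) stats::predict(f, p)$y, numeric(length(p)))
  }
  # Tangents by local quadratic regression (Savitzky-Golay derivative)
  # over a 9-sample window of the evaluated curve: the smoothing spline's
  # natural boundary conditions (f'' = 0) bias its own derivative near the
  # profile ends, while the curve positions stay accurate.
  fd_tangents <- function(p, k = 9) {
    n <- length(p)
    pos <- eval_curve(p)
    k <- min(k, n)
    hw <- k %/% 2
    tg <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      j <- max(1, min(i - hw, n - k + 1)):min(n, max(i + hw, k))
      d <- p[j] - p[i]
      co <- qr.solve(cbind(1, d, d^2), pos[j, , drop = FALSE])
      tg[i, ] <- co[2, ]
    }
    list(pos = pos, tangents = unit_rows(tg))
  }

  param <- seq(rng[1], rng[2], length.out = n_samples)
  dense_param <- seq(rng[1], rng[2], length.out = max(20 * n_samples, 400))
  dense_pos <- eval_curve(dense_param)
  dense_arc <- c(0, cumsum(sqrt(rowSums(diff(dense_pos)^2))))
  dense_tan <- polyline_tangents(dense_pos)

  ft <- fd_tangents(param)
  pos <- ft$pos
  tang <- ft$tangents
  arc <- stats::approx(dense_param, dense_arc, xout = param)$y

  # Orient posterior-first: s = 0 must sit at the posterior (-y) end.
  if (pos[1, 2] > pos[n_samples, 2]) {
    param <- rev(param); pos <- pos[n_samples:1, ]
    tang <- -tang[n_samples:1, ]
    arc <- max(arc) - rev(arc)
    dense_param <- rev(dense_param)
    dense_pos <- dense_pos[nrow(dense_pos):1, ]
    dense_tan <- -dense_tan[nrow(dense_tan):1, ]
    dense_arc <- max(dense_arc) - rev(dense_arc)
  }
  structure(list(
    param = param, positions = pos, tangents = tang, arc_length = arc,
    dense_param = dense_param, dense_pos = dense_pos, dense_arc = dense_arc,
    dense_tangents = dense_tan,
    ac_point = ac_point, n_samples = n_samples,
    plane = list(center = ctr, e1 = e1, e2 = e2)
  ), class = "longitudinal_spline")
}

#' @export
print.longitudinal_spline <- function(x, ...) {
  cat("Longitudinal spline:", x$n_samples, "samples over",
      round(max(x$arc_length), 1), "mm of arc\n")
  invisible(x)
}

#' Project world points onto a longitudinal spline
#'
#' Orthogonal projection via the spline's dense polyline: each point is
#' assigned the parameter/arc length of its nearest curve point and the
#' index of the nearest of the equidistant parameter samples.
#'
#' @param spline A `longitudinal_spline`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return List with `param`, `arc_length` (mm), `sample` (1-based index),
#'   `dense_index` (index into the dense polyline), and `dist` (mm,
#'   distance to the curve).
#' @export
project_to_spline <- function(spline, pts) {
  pts <- matrix(pts, ncol = 3)
  n <- nrow(pts)
  dp <- spline$dense_pos
  nearest <- integer(n)
  dist <- numeric(n)
  chunk <- max(1, floor(2e6 / nrow(dp)))
  for (a in seq(1, n, by = chunk)) {
    b <- min(n, a + chunk - 1)
    d2 <- outer(rowSums(pts[a:b, , drop = FALSE]^2), rowSums(dp^2), `+`) -
      2 * pts[a:b, , drop = FALSE] %*% t(dp)
    nearest[a:b] <- max.col(-d2, ties.method = "first")
    dist[a:b] <- sqrt(pmax(0, d2[cbind(seq_len(b - a + 1), nearest[a:b])]))
  }
  par <- spline$dense_param[nearest]
  p0 <- spline$param[1]
  dstep <- diff(spline$param[1:2])
  smp <- pmin(spline$n_samples,
              pmax(1, round((par - p0) / dstep) + 1))
  list(param = par, arc_length = spline$dense_arc[nearest],
       sample = smp, dense_index = nearest, dist = dist)
}

#' Radiality-index profile along the spline
#'
#' Every masked voxel is projected onto the spline and assigned to the
#' nearest parameter sample; the acute angle between the voxel's principal
#' diffusion direction and the spline tangent at the voxel's projected
#' point, arccos(|v . t|) in degrees, is averaged per sample.
#' 0 = tangential, 90 = radial.
#'
#' @param field A `tensor_field`.
#' @param spline A `longitudinal_spline`.
#' @param fa_min Voxels with FA below this are excluded (default 0: none).
#' @param subject,hemisphere Optional tags carried in the result.
#' @return An object of class `radiality_profile`: a data.frame with
#'   columns `sample`, `param`, `arc_length_mm`, `mean_angle_deg`,
#'   `n_voxels`, plus attributes `subject`, `hemisphere`,
#'   `voxel_sample` / `voxel_angle` (per-voxel assignment).
#' @export
radiality_profile <- function(field, spline, fa_min = 0,
                              subject = NA, hemisphere = NA) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(spline, "longitudinal_spline"))
  keep <- field$fa >= fa_min
  vi <- field$voxel_index[keep, , drop = FALSE]
  pd <- field$principal_dir[keep, , drop = FALSE]
  w <- voxel_to_world(vi, field$affine)
  pr <- project_to_spline(spline, w)
  tloc <- spline$dense_tangents[pr$dense_index, , drop = FALSE]
  dots <- abs(rowSums(pd * tloc))
  ang <- rad2deg(acos(pmin(1, dots)))

  ns <- spline$n_samples
  cnt <- tabulate(pr$sample, nbins = ns)
  mean_ang <- rep(NA_real_, ns)
  sums <- vapply(seq_len(ns), function(i) sum(ang[pr$sample == i]),
                 numeric(1))
  mean_ang[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  if (mean(cnt == 0) > 0.2) {
    warning(sum(cnt == 0), " of ", ns, " spline samples have no voxels")
  }
  out <- data.frame(sample = seq_len(ns), param = spline$param,
                    arc_length_mm = spline$arc_length,
                    mean_angle_deg = mean_ang, n_voxels = cnt)
  attr(out, "subject") <- subject
  attr(out, "hemisphere") <- hemisphere
  attr(out, "voxel_sample") <- pr$sample
  attr(out, "voxel_angle") <- ang
  class(out) <- c("radiality_profile", "data.frame")
  out
}

#' Detect the group-level microstructural boundaries
#'
#' Profiles are averaged across subjects on their common sample grid. The
#' first boundary is the linearly interpolated 45-degree crossing of the
#' mean radiality inside the central search window; the second is the
#' discrete local minimum inside the head window (after an optional
#' 3-sample moving-average smoothing) — the near-head tangential zone.
#'
#' @param profiles A `radiality_profile` or list of them (common grid).
#' @param central_window,head_window Arc-length fractions (of total arc)
#'   delimiting the two searches.
#' @param smooth_minimum Apply 3-sample moving average before the minimum
#'   search (default `TRUE`).
#' @return An object of class `boundary_set`: `b_45` and `b_min` (mm arc
#'   length), `level = "group"`, the mean profile, and the windows used.
#' @export
detect_group_boundaries <- function(profiles,
                                    central_window = c(0.25, 0.65),
                                    head_window = c(0.60, 0.90),
                                    smooth_minimum = TRUE) {
  if (inherits(profiles, "radiality_profile")) profiles <- list(profiles)
  if (length(profiles) < 1) stop("need at least one profile")
  arc <- profiles[[1]]$arc_length_mm
  angs <- vapply(profiles, function(p) {
    if (nrow(p) != length(arc)) {
      stop("profiles are not sampled on a common parameter grid")
    }
    p$mean_angle_deg
  }, numeric(length(arc)))
  mean_ang <- rowMeans(matrix(angs, ncol = length(profiles)), na.rm = TRUE)
  total <- max(arc)

  b_45 <- find_45_crossing(arc, mean_ang, central_window * total)
  b_min <- find_local_minimum(arc, mean_ang, head_window * total,
                              smooth_minimum)
  if (b_45 >= b_min) {
    warning("45-degree crossing (", round(b_45, 2),
            " mm) is not posterior to the local minimum (",
            round(b_min, 2), " mm)")
  }
  structure(list(b_45 = b_45, b_min = b_min, level = "group",
                 search_radius = NA_real_,
                 central_window = central_window, head_window = head_window,
                 mean_profile = data.frame(arc_length_mm = arc,
                                           mean_angle_deg = mean_ang)),
            class = "boundary_set")
}

find_45_crossing <- function(arc, ang, window) {
  inw <- which(arc >= window[1] & arc <= window[2] & !is.na(ang))
  if (length(inw) < 2) stop("central window contains fewer than 2 samples")
  i <- inw[-length(inw)]
  i <- i[!is.na(ang[i + 1])]
  cross <- i[(ang[i] - 45) * (ang[i + 1] - 45) <= 0]
  cross <- cross[ang[cross] != ang[cross + 1] | ang[cross] == 45]
  if (length(cross) == 0) {
    stop("no 45-degree crossing inside the central window; profile range ",
         round(min(ang[inw]), 1), "-", round(max(ang[inw]), 1), " degrees")
  }
  pos <- vapply(cross, function(j) {
    if (ang[j] == 45) return(arc[j])
    arc[j] + (45 - ang[j]) / (ang[j + 1] - ang[j]) * (arc[j + 1] - arc[j])
  }, numeric(1))
  ctr <- mean(window)
  if (length(pos) > 1) {
    message("multiple 45-degree crossings (", length(pos),
            "); choosing the one closest to the window center")
  }
  pos[which.min(abs(pos - ctr))]
}

find_local_minimum <- function(arc, ang, window, smooth = TRUE) {
  a <- ang
  if (smooth) {
    n <- length(a)
    sm <- a
    for (i in seq_len(n)) {
      j <- max(1, i - 1):min(n, i + 1)
      sm[i] <- mean(a[j], na.rm = TRUE)
    }
    a <- sm
  }
  inw <- which(arc >= window[1] & arc <= window[2] & !is.na(a))
  if (length(inw) < 1) stop("head window contains no usable samples")
  n <- length(arc)
  is_min <- vapply(inw, function(i) {
    left <- if (i > 1) a[i - 1] else Inf
    right <- if (i < n) a[i + 1] else Inf
    !is.na(a[i]) && a[i] <= left && a[i] <= right
  }, logical(1))
  cand <- inw[is_min]
  if (length(cand) == 0) cand <- inw      # monotone window: take its argmin
  if (length(cand) > 1) {
    message("multiple local minima in head window; choosing the deepest ",
            "(posterior-most on ties)")
  }
  best <- cand[order(a[cand], arc[cand])][1]
  arc[best]
}

#' Refine boundaries on an individual profile
#'
#' Within an arc-length radius of each group boundary, picks the subject's
#' sample whose mean angle is closest to 45 degrees (first boundary) or
#' lowest (second boundary). Ties go to the posterior-most sample.
#'
#' @param profile A `radiality_profile`.
#' @param group A group-level `boundary_set`.
#' @param radius Search radius along the spline, mm (default 10).
#' @return A subject-level `boundary_set`.
#' @export
refine_subject_boundaries <- function(profile, group, radius = 10) {
  stopifnot(inherits(group, "boundary_set"))
  if (group$level != "group") stop("`group` must be a group-level boundary_set")
  if (radius <= 0) stop("radius must be positive")
  arc <- profile$arc_length_mm
  ang <- profile$mean_angle_deg
  pick <- function(center, score) {
    if (center - radius < min(arc) || center + radius > max(arc)) {
      warning("search window around ", round(center, 2),
              " mm extends past the profile ends; clipped")
    }
    inw <- which(abs(arc - center) <= radius & !is.na(ang))
    if (length(inw) == 0) stop("no usable samples within the search radius")
    inw[order(score(ang[inw]), arc[inw])][1]
  }
  i45 <- pick(group$b_45, function(a) abs(a - 45))
  imin <- pick(group$b_min, function(a) a)
  structure(list(b_45 = arc[i45], b_min = arc[imin], level = "subject",
                 search_radius = radius,
                 subject = attr(profile, "subject"),
                 hemisphere = attr(profile, "hemisphere")),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(x$level, "boundaries: 45-degree crossing at", round(x$b_45, 2),
      "mm; local minimum at", round(x$b_min, 2), "mm\n")
  invisible(x)
}

#' Tri-partition of the mask by the detected boundaries
#'
#' Labels every masked voxel by its projected arc length: 1 = posterior
#' (s < b_45), 2 = middle, 3 = anterior (s >= b_min).
#'
#' @param mask Binary 3D array.
#' @param spline A `longitudinal_spline` fitted to the mask.
#' @param boundaries A `boundary_set` with `b_45 < b_min`.
#' @param affine Voxel-to-world matrix of the mask grid.
#' @return Integer label array (0 outside the mask).
#' @export
segment_cn <- function(mask, spline, boundaries, affine) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (boundaries$b_45 >= boundaries$b_min) {
    stop("boundaries must satisfy b_45 < b_min")
  }
  rngs <- range(spline$dense_arc)
  if (boundaries$b_45 < rngs[1] || boundaries$b_min > rngs[2]) {
    stop("boundary outside the spline arc-length range")
  }
  vi <- mask_indices(mask)
  w <- voxel_to_world(vi, affine)
  s <- project_to_spline(spline, w)$arc_length
  lab <- 1L + (s >= boundaries$b_45) + (s >= boundaries$b_min)
  out <- array(0L, dim = dim(mask))
  out[vi + 1] <- lab
  out
}

#' Most typical subject from a pairwise deformation-cost matrix
#'
#' The most typical subject is the one requiring the least cumulative
#' deformation to all other subjects: the argmin of the off-diagonal row
#' sums. Ties break to the lowest index.
#'
#' @param cost_matrix Square non-negative matrix; diagonal ignored.
#' @return Subject index (1-based).
#' @export
choose_typical_subject <- function(cost_matrix) {
  cm <- as.matrix(cost_matrix)
  if (nrow(cm) != ncol(cm)) stop("cost matrix must be square")
  if (any(cm < 0)) stop("cost matrix entries must be non-negative")
  rs <- rowSums(cm) - diag(cm)
  idx <- which.min(rs)            # which.min takes the first on ties
  if (sum(rs == rs[idx]) > 1) {
    message("tie in cumulative deformation; choosing lowest index ", idx)
  }
  as.integer(idx)
}

#' Write a radiality profile as CSV
#'
#' Columns: sample, arc_length_mm, mean_angle_deg, n_voxels.
#' @param profile A `radiality_profile`.
#' @param path Output path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile[, c("sample", "arc_length_mm",
                               "mean_angle_deg", "n_voxels")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a boundary set as JSON
#' @param boundaries A `boundary_set`.
#' @param path Output path.
#' @export
write_boundaries_json <- function(boundaries, path) {
  jsonlite::write_json(
    list(b_45_mm = boundaries$b_45, b_min_mm = boundaries$b_min,
         level = boundaries$level,
         search_radius_mm = boundaries$search_radius),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
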