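# Deterministic streamline tractography on discrete direction fields with
# the published constraints (curvature radius, minimum length, amplitude
# cutoff), declarative inclusion/exclusion bundle classification, and
# per-subregion endpoint target maps.

#' Construct a direction field
#'
#' @param dirs Numeric array `dims x 3 x K`: K unit peak directions per
#'   voxel (zero rows allowed where no peak exists).
#' @param amp Array `dims x K` of non-negative peak amplitudes.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `direction_field`.
#' @export
direction_field <- function(dirs, amp, affine) {
  dd <- dim(dirs)
  if (length(dd) == 4) {
    dirs <- array(dirs, c(dd, 1))
    dd <- dim(dirs)
  }
  if (length(dd) != 5 || dd[4] != 3) stop("dirs must be dims x 3 x K")
  if (length(dim(amp)) == 3) amp <- array(amp, c(dim(amp), 1))
  if (!identical(dim(amp), dd[c(1:3, 5)])) {
    stop("amp must be dims x K, matching dirs")
  }
  if (any(amp < 0)) stop("amplitudes must be non-negative")
  structure(list(dirs = dirs, amp = amp, affine = affine,
                 dims = dd[1:3], n_peaks = dd[5]),
            class = "direction_field")
}

#' Direction field from a fitted tensor field
#'
#' Single peak per voxel: the principal eigenvector, with FA as amplitude.
#'
#' @param field A `tensor_field`.
#' @return A `direction_field`.
#' @export
tensor_direction_field <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$mask)
  dirs <- array(0, c(dims, 3, 1))
  amp <- array(0, c(dims, 1))
  flat <- which(field$mask != 0)
  nt <- prod(dims)
  for (a in 1:3) dirs[flat + (a - 1) * nt] <- field$principal_dir[, a]
  amp[flat] <- field$fa
  direction_field(dirs, amp, field$affine)
}

#' Streamline tractography with curvature, length and amplitude constraints
#'
#' Seeds are drawn uniformly within the seed-mask voxels; tracking is
#' bidirectional fixed-step Euler with trilinear, sign-aligned
#' interpolation of the peak most consistent with the incoming direction.
#' A step terminates on leaving the grid, on interpolated amplitude below
#' the cutoff, or on a step angle exceeding the discrete curvature bound
#' theta_max = 2 asin(step / (2 R)). Streamlines shorter than `min_length`
#' are discarded.
#'
#' @param field A `direction_field`.
#' @param seed_mask Binary 3D array on the field grid.
#' @param n_seeds Number of seeds (default 500).
#' @param step Step size, mm (default 0.5).
#' @param curvature_radius Minimum radius of curvature R, mm (default 2).
#' @param min_length Minimum retained streamline length, mm (default 30).
#' @param cutoff Amplitude cutoff (default 0.05).
#' @param cutoff_mode `"relative"`: cutoff is a fraction of the field's
#'   global maximum amplitude (default, the fODF reading); `"absolute"`:
#'   cutoff applies to the amplitude directly (the FA reading).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param max_steps Safety bound on steps per direction (default 5000).
#' @return An object of class `streamline_set`: `streamlines` (list of
#'   n_i x 3 world-coordinate matrices), `seeds` (n_seeds x 3, all drawn
#'   seeds), `seed_kept` (logical), `rng_seed`, `params`.
#' @export
track_streamlines <- function(field, seed_mask, n_seeds = 500,
                              step = 0.5, curvature_radius = 2,
                              min_length = 30, cutoff = 0.05,
                              cutoff_mode = c("relative", "absolute"),
                              rng_seed = 1L, max_steps = 5000) {
  stopifnot(inherits(field, "direction_field"))
  cutoff_mode <- match.arg(cutoff_mode)
  if (step <= 0 || curvature_radius <= 0 || min_length < 0 || cutoff < 0) {
    stop("tracking parameters must be positive")
  }
  if (step >= 2 * curvature_radius) {
    stop("step (", step, " mm) must be below twice the curvature radius (",
         curvature_radius, " mm): the per-step angle bound is undefined")
  }
  if (!identical(dim(seed_mask), field$dims)) {
    stop("seed mask is not on the field grid")
  }
  svox <- mask_indices(seed_mask)
  if (nrow(svox) == 0) stop("seed mask is empty")

  theta_max <- 2 * asin(step / (2 * curvature_radius))
  cos_min <- cos(theta_max)
  amp_cut <- if (cutoff_mode == "relative") cutoff * max(field$amp) else cutoff

  set.seed(as.integer(rng_seed))
  pick <- sample.int(nrow(svox), n_seeds, replace = TRUE)
  jitter <- matrix(stats::runif(3 * n_seeds, -0.5, 0.5), n_seeds, 3)
  seeds_vox <- svox[pick, , drop = FALSE] + jitter
  seeds <- voxel_to_world(seeds_vox, field$affine)

  # Flattened field arrays and affine inverse for the inner loop.
  dims <- field$dims
  nt <- prod(dims)
  K <- field$n_peaks
  dirs_flat <- matrix(field$dirs, nt * K, 3)   # rows: voxel-major, then peak
  amp_flat <- matrix(field$amp, nt, K)
  Ainv <- solve(field$affine)
  R3 <- Ainv[1:3, 1:3]; t3 <- Ainv[1:3, 4]
  off8 <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  stride <- c(1, dims[1], dims[1] * dims[2])

  interp <- function(p, u) {
    vc <- R3 %*% p + t3
    i0 <- floor(vc)
    f <- as.numeric(vc - i0)
    nb <- sweep(off8, 2, as.numeric(i0), `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
      nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    if (!any(ok)) return(NULL)
    w <- (off8[, 1] * f[1] + (1 - off8[, 1]) * (1 - f[1])) *
      (off8[, 2] * f[2] + (1 - off8[, 2]) * (1 - f[2])) *
      (off8[, 3] * f[3] + (1 - off8[, 3]) * (1 - f[3]))
    w[!ok] <- 0
    if (sum(w) <= 0) return(NULL)
    flat <- as.integer(nb[ok, , drop = FALSE] %*% stride) + 1L
    wk <- w[ok]
    if (K == 1) {
      d8 <- dirs_flat[flat, , drop = FALSE]
      a8 <- amp_flat[flat, 1]
    } else {
      # per-neighbour best peak by alignment with the incoming direction
      d8 <- matrix(0, length(flat), 3)
      a8 <- numeric(length(flat))
      best_score <- rep(-Inf, length(flat))
      for (k in seq_len(K)) {
        dk <- dirs_flat[flat + (k - 1) * nt, , drop = FALSE]
        sc <- abs(dk %*% u)
        upd <- sc > best_score & amp_flat[flat, k] > 0
        if (any(upd)) {
          best_score[upd] <- sc[upd]
          d8[upd, ] <- dk[upd, , drop = FALSE]
          a8[upd] <- amp_flat[flat, k][upd]
        }
      }
    }
    sgn <- sign(d8 %*% u)
    sgn[sgn == 0] <- 1
    d <- colSums((wk * as.numeric(sgn)) * d8)
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) return(NULL)
    list(d = d / nrm, a = sum(wk * a8) / sum(wk))
  }

  in_grid <- function(p) {
    vc <- R3 %*% p + t3
    all(vc > -0.5 & vc < dims - 0.5)
  }

  track_one_dir <- function(p0, u0) {
    pts <- list()
    p <- p0; u <- u0
    for (i in seq_len(max_steps)) {
      it <- interp(p, u)
      if (is.null(it) || it$a < amp_cut) break
      if (sum(it$d * u) < cos_min) break
      p2 <- p + step * it$d
      if (!in_grid(p2)) break
      pts[[length(pts) + 1]] <- p2
      p <- p2
      u <- it$d
    }
    if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)
  }

  streamlines <- vector("list", n_seeds)
  kept <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    p0 <- seeds[s, ]
    # initial direction: the strongest peak at the seed voxel
    v0 <- world_to_voxel(matrix(p0, 1), field$affine)
    v0 <- pmin(pmax(v0, 0), matrix(dims - 1, 1))
    fl <- as.integer(v0 %*% stride) + 1L
    k0 <- which.max(amp_flat[fl, ])
    u0 <- dirs_flat[fl + (k0 - 1) * nt, ]
    if (sum(u0^2) == 0) next
    u0 <- u0 / sqrt(sum(u0^2))
    fwd <- track_one_dir(p0, u0)
    bwd <- track_one_dir(p0, -u0)
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 matrix(p0, 1), fwd)
    len <- (nrow(pts) - 1) * step
    if (len >= min_length) {
      streamlines[[s]] <- pts
      kept[s] <- TRUE
    }
  }
  structure(list(
    streamlines = streamlines[kept], seeds = seeds, seed_kept = kept,
    rng_seed = rng_seed,
    params = list(step = step, curvature_radius = curvature_radius,
                  min_length = min_length, cutoff = cutoff,
                  cutoff_mode = cutoff_mode, n_seeds = n_seeds)
  ), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  lens <- vapply(x$streamlines, nrow, integer(1))
  cat("Streamline set:", length(x$streamlines), "of", x$params$n_seeds,
      "seeds retained; mean length",
      if (length(lens)) round(mean((lens - 1) * x$params$step), 1) else 0,
      "mm\n")
  invisible(x)
}

#' Classify streamlines into bundles by inclusion/exclusion rules
#'
#' Rules are checked in order; the first rule whose exclusion masks are all
#' avoided and whose every inclusion group is visited assigns its label.
#' Visiting means any streamline point falls inside a mask voxel
#' (voxel-center containment). Unmatched streamlines get `"unassigned"`.
#'
#' @param sset A `streamline_set`.
#' @param rules List of rules: each a list with `label` (character),
#'   `include` (list of AND-combined groups; a group is one mask array or a
#'   list of OR-combined mask arrays), and optional `exclude` (list of mask
#'   arrays).
#' @param affine Voxel-to-world matrix of the mask grid.
#' @return Character vector of labels, one per streamline, with the rule
#'   set stored as attribute `rules`.
#' @export
classify_bundles <- function(sset, rules, affine) {
  stopifnot(inherits(sset, "streamline_set"))
  labs <- vapply(rules, function(r) r$label, character(1))
  if (anyDuplicated(labs)) stop("bundle labels must be unique")
  grid_dim <- NULL
  for (r in rules) {
    for (g in r$include) {
      gm <- if (is.list(g)) g else list(g)
      for (m in gm) grid_dim <- grid_dim %||% dim(m)
    }
  }
  visits <- function(pts, mask) {
    v <- world_to_voxel(pts, affine)
    ok <- v[, 1] >= 0 & v[, 1] < dim(mask)[1] &
      v[, 2] >= 0 & v[, 2] < dim(mask)[2] &
      v[, 3] >= 0 & v[, 3] < dim(mask)[3]
    if (!any(ok)) return(FALSE)
    any(mask[v[ok, , drop = FALSE] + 1] != 0)
  }
  out <- rep("unassigned", length(sset$streamlines))
  for (i in seq_along(sset$streamlines)) {
    pts <- sset$streamlines[[i]]
    for (r in rules) {
      excl <- r$exclude %||% list()
      if (any(vapply(excl, function(m) visits(pts, m), logical(1)))) next
      groups_ok <- vapply(r$include, function(g) {
        gm <- if (is.list(g)) g else list(g)
        any(vapply(gm, function(m) visits(pts, m), logical(1)))
      }, logical(1))
      if (all(groups_ok)) {
        out[i] <- r$label
        break
      }
    }
  }
  attr(out, "rules") <- labs
  out
}

#' Read bundle rules from a JSON file
#'
#' Format: an array of objects `{"label": ..., "include": [["maskA.nii.gz",
#' "maskB.nii.gz"], ...], "exclude": ["maskC.nii.gz"]}`; inner arrays are
#' OR-combined within a group, groups AND-combined. Paths are resolved
#' against `mask_dir` and loaded as strict binary masks.
#'
#' @param path JSON rule file.
#' @param mask_dir Directory holding the mask volumes.
#' @return Rule list suitable for [classify_bundles()].
#' @export
read_bundle_rules <- function(path, mask_dir = dirname(path)) {
  spec <- jsonlite::read_json(path)
  lapply(spec, function(r) {
    list(
      label = r$label,
      include = lapply(r$include, function(g) {
        g <- if (is.list(g)) g else list(g)
        lapply(g, function(f) read_mask(file.path(mask_dir, f))$data)
      }),
      exclude = lapply(r$exclude %||% list(), function(f) {
        read_mask(file.path(mask_dir, f))$data
      })
    )
  })
}

#' Endpoint target maps per subregion
#'
#' Each streamline is attributed to the subregion label of its seed voxel;
#' both of its endpoints are accumulated into that subregion's count
#' volume. Seeds falling outside the labeled mask are attributed to the
#' nearest labeled voxel (with a warning).
#'
#' @param sset A `streamline_set`.
#' @param labels Integer label volume (e.g. from [segment_cn()]).
#' @param affine Voxel-to-world matrix of the label grid.
#' @return Named list of count volumes, one per label value, each summing
#'   to 2x the number of streamlines attributed to that subregion.
#' @export
endpoint_density <- function(sset, labels, affine) {
  stopifnot(inherits(sset, "streamline_set"))
  dims <- dim(labels)
  seeds <- sset$seeds[sset$seed_kept, , drop = FALSE]
  n <- length(sset$streamlines)
  if (n == 0) {
    vals <- sort(unique(labels[labels != 0]))
    return(stats::setNames(lapply(vals, function(v) array(0, dims)),
                           paste0("label_", vals)))
  }
  sv <- world_to_voxel(seeds, affine)
  sv <- pmin(pmax(sv, 0), matrix(rep(dims - 1, each = n), n, 3))
  seed_lab <- labels[sv + 1]
  if (any(seed_lab == 0)) {
    n_outside <- sum(seed_lab == 0)
    li <- mask_indices(labels != 0)
    lw <- voxel_to_world(li, affine)
    for (i in which(seed_lab == 0)) {
      d2 <- rowSums(sweep(lw, 2, seeds[i, ])^2)
      j <- which.min(d2)
      seed_lab[i] <- labels[matrix(li[j, ] + 1, 1)]
    }
    warning(n_outside,
            " seed(s) outside the labeled mask attributed to nearest label")
  }
  vals <- sort(unique(labels[labels != 0]))
  out <- stats::setNames(lapply(vals, function(v) array(0, dims)),
                         paste0("label_", vals))
  for (i in seq_len(n)) {
    pts <- sset$streamlines[[i]]
    ends <- pts[c(1, nrow(pts)), , drop = FALSE]
    ev <- world_to_voxel(ends, affine)
    key <- paste0("label_", seed_lab[i])
    if (!key %in% names(out)) next
    for (e in 1:2) {
      v <- ev[e, ]
      if (all(v >= 0) && all(v < dims)) {
        out[[key]][matrix(v + 1, 1)] <- out[[key]][matrix(v + 1, 1)] + 1
      }
    }
  }
  out
}

# --- TCK (MRtrix track format) -------------------------------------------

#' Write streamlines as a TCK file
#'
#' MRtrix track format: text header, Float32LE point triplets with
#' NaN-triplet separators and an Inf-triplet terminator. Coordinates are in
#' world space (mm).
#'
#' @param sset A `streamline_set` (or plain list of n x 3 matrices).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(sset, path) {
  sl <- if (inherits(sset, "streamline_set")) sset$streamlines else sset
  hdr_fixed <- c("mrtrix tracks", "datatype: Float32LE",
                 paste0("count: ", length(sl)))
  # the 'file' line contains the data offset, which depends on its own width
  offset <- 0
  for (guess in 1:5) {
    file_line <- paste0("file: . ", offset)
    total <- sum(nchar(c(hdr_fixed, file_line, "END"))) +
      length(hdr_fixed) + 2          # newlines
    if (total == offset) break
    offset <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr_fixed, paste0("file: . ", offset), "END"), con, sep = "\n")
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, 4, endian = "little")
  invisible(path)
}

#' Read a TCK file
#'
#' @param path TCK path.
#' @return List of n x 3 streamline point matrices.
#' @export
read_tck <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # locate the END marker without decoding the binary payload
  endpat <- charToRaw("\nEND\n")
  hdr_len <- NA
  for (i in seq_len(min(4096, length(raw_all)) - 4)) {
    if (identical(raw_all[i:(i + 4)], endpat)) {
      hdr_len <- i + 4
      break
    }
  }
  if (is.na(hdr_len)) stop("TCK header END marker not found in ", path)
  lines <- strsplit(rawToChar(raw_all[seq_len(hdr_len)]), "\n")[[1]]
  if (lines[1] != "mrtrix tracks") stop("not a TCK file: ", path)
  fl <- grep("^file: \\. ", lines, value = TRUE)[1]
  if (is.na(fl)) stop("TCK header lacks a file offset")
  offset <- as.integer(sub("^file: \\. ", "", fl))
  n <- (length(raw_all) - offset) / 4
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "numeric", n, 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      if (!is.null(cur)) out[[length(out) + 1]] <- do.call(rbind, cur)
      cur <- NULL
    } else {
      cur <- c(cur, list(p))
    }
  }
  out
}
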