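# Shared fixtures, built in code at test time.

# Small phantom for fast unit tests (the default-size phantom is reserved
# for the acceptance suite).
small_phantom <- function(...) {
  make_cn_phantom(arc_radius = 15, tube_radius = 3, ...)
}

# Single-voxel ground-truth object for closed-form signal checks.
single_voxel_truth <- function(directions, fractions,
                               evals = c(1.7e-3, 3e-4, 3e-4)) {
  directions <- matrix(directions, ncol = 3)
  comps <- lapply(seq_along(fractions), function(i) {
    list(directions = directions[i, , drop = FALSE],
         fraction = fractions[i],
         evals = if (is.list(evals)) evals[[i]] else evals)
  })
  names(comps) <- paste0("c", seq_along(comps))
  structure(list(
    mask = array(1, c(1, 1, 1)), affine = diag(4), voxel_size = c(1, 1, 1),
    arc = cbind(0, seq(0, 1, length.out = 5), 0), arc_length_total = 1,
    planted_boundaries = c(0.4, 0.7),
    segment_labels = array(1, c(1, 1, 1)),
    ac_point = c(0, 5, 0), compartments = comps,
    voxel_arc_length = 0.5, voxel_index = matrix(0, 1, 3)
  ), class = "cn_phantom")
}

# A tensor_field stub with prescribed principal directions on a mask.
stub_tensor_field <- function(mask, affine, principal_dir, fa = 0.5) {
  vi <- which(mask != 0, arr.ind = TRUE) - 1
  n <- nrow(vi)
  pd <- if (is.matrix(principal_dir)) principal_dir
  else matrix(principal_dir, n, 3, byrow = TRUE)
  pd <- pd / sqrt(rowSums(pd^2))
  structure(list(
    tensors = matrix(0, n, 6), evals = matrix(1e-3, n, 3),
    fa = rep(fa, length.out = n), md = rep(1e-3, n),
    principal_dir = pd, s0 = rep(1, n),
    voxel_index = vi, mask = mask, affine = affine,
    voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))
  ), class = "tensor_field")
}

# Uniform direction field along `dir` on a grid of `dims` (1 mm voxels).
uniform_field <- function(dims, dir, amp = 1) {
  dirs <- array(0, c(dims, 3, 1))
  for (a in 1:3) dirs[, , , a, 1] <- dir[a]
  direction_field(dirs, array(amp, c(dims, 1)), diag(4))
}

# World coordinates of a phantom's masked voxels.
phantom_world <- function(ph) {
  h <- cbind(ph$voxel_index, 1)
  t(ph$affine[1:3, ] %*% t(h))
}

# Random positive-definite tensor via random rotation of positive evals.
random_tensor <- function() {
  evals <- sort(runif(3, 2e-4, 2e-3), decreasing = TRUE)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(D = q %*% diag(evals) %*% t(q), evals = evals, pdir = q[, 1])
}

# Noiseless single-tensor signals for a scheme (independent of simulate_dwi).
signal_from_tensor <- function(D, scheme, s0 = 1) {
  g <- scheme$directions
  q <- rowSums((g %*% D) * g)
  s0 * exp(-scheme$bvalues * q)
}

# Wrap single-voxel signals into a dwi_volume.
dwi_from_signals <- function(sig, scheme) {
  structure(list(signal = array(sig, c(1, 1, 1, length(sig))),
                 scheme = scheme, voxel_size = c(1, 1, 1), affine = diag(4)),
            class = "dwi_volume")
}
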