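# Polarized light imaging: forward birefringence model and the inverse
# per-pixel sinusoid analysis recovering in-plane fiber direction and
# out-of-plane inclination.
#
# Physics (Jones calculus for a birefringent retarder between polarizers):
#   crossed polarizers:  I(rho) = I0 sin^2(2(rho - phi)) sin^2(delta/2)
#   + quarter-wave:      I(rho) = I0/2 (1 + sin(2(rho - phi)) sin(delta))
# with retardance delta = delta_max cos^2(alpha); phi = in-plane direction,
# alpha = inclination. With delta_max <= pi/2 the amplitude-to-inclination
# map is invertible (thin-section regime).

#' PLI acquisition protocol
#'
#' Defaults match the two standard rotation series: crossed polarizers over
#' 90 degrees in 10-degree steps (9 images), or crossed polarizers plus a
#' quarter-wave plate over 180 degrees in 20-degree steps (9 images).
#'
#' @param mode `"crossed"` or `"quarter_wave"`.
#' @param rotation_angles Filter rotation angles in degrees; `NULL` gives
#'   the mode's default nine-angle series.
#' @param pixel_size Pixel edge lengths in micrometres (default 64 x 64).
#' @param section_thickness Section thickness in micrometres (default 100).
#' @param delta_max Maximum retardance (radians) reached by an in-plane
#'   fiber; default pi/2.
#' @return An object of class `pli_protocol`.
#' @export
pli_protocol <- function(mode = c("crossed", "quarter_wave"),
                         rotation_angles = NULL,
                         pixel_size = c(64, 64),
                         section_thickness = 100,
                         delta_max = pi / 2) {
  mode <- match.arg(mode)
  if (is.null(rotation_angles)) {
    rotation_angles <- if (mode == "crossed") seq(0, 80, by = 10)
    else seq(0, 160, by = 20)
  }
  if (length(rotation_angles) < 1) stop("rotation angle list is empty")
  if (delta_max <= 0 || delta_max > pi) stop("delta_max must lie in (0, pi]")
  structure(list(mode = mode, rotation_angles = rotation_angles,
                 pixel_size = pixel_size,
                 section_thickness = section_thickness,
                 delta_max = delta_max),
            class = "pli_protocol")
}

#' Simulate a PLI rotation series from known orientation maps
#'
#' @param direction_map Matrix of in-plane fiber directions phi, degrees.
#' @param inclination_map Matrix of inclinations alpha, degrees in
#'   [-90, 90] (sign is irrelevant to the signal).
#' @param protocol A `pli_protocol`.
#' @param i0 Transmitted intensity scale (matrix or scalar, default 1).
#' @param noise_sigma Additive Gaussian (camera) noise sd; 0 for none.
#' @param rng_seed Integer seed used when `noise_sigma > 0`.
#' @return An object of class `pli_stack`: `images` (list of matrices, one
#'   per rotation angle) and `protocol`.
#' @export
simulate_pli_section <- function(direction_map, inclination_map, protocol,
                                 i0 = 1, noise_sigma = 0, rng_seed = 1L) {
  stopifnot(inherits(protocol, "pli_protocol"))
  direction_map <- as.matrix(direction_map)
  inclination_map <- as.matrix(inclination_map)
  if (!identical(dim(direction_map), dim(inclination_map))) {
    stop("direction and inclination maps must have the same shape")
  }
  if (any(inclination_map < -90 | inclination_map > 90)) {
    stop("inclination must lie in [-90, 90] degrees")
  }
  delta <- protocol$delta_max * cos(deg2rad(inclination_map))^2
  phi <- deg2rad(direction_map)
  if (noise_sigma > 0) set.seed(as.integer(rng_seed))
  images <- lapply(protocol$rotation_angles, function(rho_deg) {
    rho <- deg2rad(rho_deg)
    img <- if (protocol$mode == "crossed") {
      i0 * sin(2 * (rho - phi))^2 * sin(delta / 2)^2
    } else {
      i0 / 2 * (1 + sin(2 * (rho - phi)) * sin(delta))
    }
    img <- matrix(img, nrow(direction_map))
    if (noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                          nrow(img))
    }
    img
  })
  structure(list(images = images, protocol = protocol), class = "pli_stack")
}

#' @export
print.pli_stack <- function(x, ...) {
  cat("PLI stack (", x$protocol$mode, "): ", length(x$images),
      " images of ", paste(dim(x$images[[1]]), collapse = " x "),
      " pixels\n", sep = "")
  invisible(x)
}

#' Least-squares sinusoid fit to a rotation series
#'
#' Fits I(rho) = a + b sin(h rho + c) by linear regression on
#' {1, sin(h rho), cos(h rho)}, with b >= 0 and c wrapped to [0, 360).
#' The physiological harmonic is h = 2 for the quarter-wave series and
#' h = 4 for the crossed series.
#'
#' @param rotation_angles Angles rho in degrees (>= 3, distinct).
#' @param intensities Either a vector (one pixel) or a matrix with one row
#'   per angle and one column per pixel.
#' @param harmonic Angular frequency multiplier h (default 2).
#' @return List with `offset` (a), `amplitude` (b >= 0), `phase` (c,
#'   degrees in [0, 360)), and `phase_defined` (FALSE where b is below
#'   machine tolerance); each a vector with one entry per pixel.
#' @export
fit_sinusoid <- function(rotation_angles, intensities, harmonic = 2) {
  if (length(rotation_angles) < 3) {
    stop("insufficient data: need at least 3 rotation angles")
  }
  if (anyDuplicated(rotation_angles)) stop("rotation angles must be distinct")
  Y <- if (is.matrix(intensities)) intensities else cbind(intensities)
  if (nrow(Y) != length(rotation_angles)) {
    stop("intensities must have one row per rotation angle")
  }
  th <- deg2rad(harmonic * rotation_angles)
  X <- cbind(1, sin(th), cos(th))
  if (qr(X)$rank < 3) {
    stop("rotation angles are degenerate for harmonic ", harmonic)
  }
  beta <- qr.solve(X, Y)
  a <- unname(beta[1, ])
  p <- unname(beta[2, ]); q <- unname(beta[3, ])
  b <- sqrt(p^2 + q^2)
  tol <- max(.Machine$double.eps * 100 * max(abs(Y)), 1e-300)
  defined <- b > tol
  phase <- rad2deg(atan2(q, p)) %% 360
  phase[phase >= 360] <- 0            # guard the %% 360 rounding edge
  phase[!defined] <- NA_real_
  list(offset = a, amplitude = b, phase = phase, phase_defined = defined)
}

#' Recover fiber direction and inclination maps from two PLI series
#'
#' The in-plane direction phi comes from the quarter-wave series' phase
#' (the signal is a + b sin(2 rho - 2 phi), so phi = -phase/2 mod 180); the
#' normalised amplitude b/a = sin(delta) gives the retardance, and the
#' inclination follows from delta = delta_max cos^2(alpha). Pixels whose
#' amplitude falls below the noise floor (steep fibers, unmyelinated
#' tissue) are flagged invalid.
#'
#' @param crossed A crossed-polarizer `pli_stack` (used for the
#'   maximum-intensity map and the validity floor), or `NULL`.
#' @param quarter A quarter-wave `pli_stack`.
#' @param noise_floor Amplitude below which a pixel is invalid; `NULL`
#'   estimates 3x a robust background amplitude (pixels darker than 10% of
#'   the global maximum), falling back to a machine-precision floor when no
#'   background exists (noiseless phantoms).
#' @return An object of class `pli_orientation`: matrices `direction`
#'   (degrees in [0, 180)), `inclination` (degrees in [0, 90]),
#'   `amplitude`, `offset`, `valid` (logical), `max_intensity`.
#' @export
estimate_orientation <- function(crossed = NULL, quarter,
                                 noise_floor = NULL) {
  stopifnot(inherits(quarter, "pli_stack"))
  if (quarter$protocol$mode != "quarter_wave") {
    stop("`quarter` must be a quarter-wave stack")
  }
  shp <- dim(quarter$images[[1]])
  if (!is.null(crossed)) {
    stopifnot(inherits(crossed, "pli_stack"))
    if (!identical(dim(crossed$images[[1]]), shp)) {
      stop("crossed and quarter-wave stacks have different shapes")
    }
  }
  delta_max <- quarter$protocol$delta_max
  if (is.null(delta_max)) stop("delta_max not configured in the protocol")

  Y <- vapply(quarter$images, as.vector, numeric(prod(shp)))
  fit <- fit_sinusoid(quarter$protocol$rotation_angles, t(Y), harmonic = 2)

  if (is.null(noise_floor)) {
    mx <- apply(Y, 1, max)
    dark <- mx < 0.1 * max(mx)
    noise_floor <- if (any(dark)) 3 * stats::median(fit$amplitude[dark])
    else .Machine$double.eps^0.5 * max(abs(Y))
    if (noise_floor == 0) noise_floor <- .Machine$double.eps
  }
  valid <- fit$phase_defined & fit$amplitude >= noise_floor

  direction <- (-fit$phase / 2) %% 180
  direction[!valid] <- NA_real_
  sin_delta <- pmin(1, pmax(0, fit$amplitude / pmax(fit$offset, 1e-300)))
  # snap to 1 within fit precision: the amplitude->inclination map is
  # singular at sin(delta) = 1 (alpha = 0), where rounding noise would
  # otherwise blow up through asin/acos
  sin_delta[abs(sin_delta - 1) < 1e-12] <- 1
  delta <- asin(sin_delta)
  inclination <- rad2deg(acos(sqrt(pmin(1, pmax(0, delta / delta_max)))))
  inclination[!valid] <- NA_real_

  mi_stack <- if (!is.null(crossed)) crossed else quarter
  structure(list(
    direction = matrix(direction, shp[1]),
    inclination = matrix(inclination, shp[1]),
    amplitude = matrix(fit$amplitude, shp[1]),
    offset = matrix(fit$offset, shp[1]),
    valid = matrix(valid, shp[1]),
    max_intensity = maximum_intensity_map(mi_stack),
    noise_floor = noise_floor
  ), class = "pli_orientation")
}

#' @export
print.pli_orientation <- function(x, ...) {
  cat("PLI orientation map:", paste(dim(x$direction), collapse = " x "),
      "pixels;", sum(x$valid), "valid\n")
  invisible(x)
}

#' Maximum-intensity map of a rotation series
#'
#' Per-pixel maximum over the rotation sequence; encodes fiber inclination
#' (in-plane myelinated fibers bright, steep or unmyelinated dark).
#'
#' @param stack A `pli_stack`.
#' @return Matrix of per-pixel maxima.
#' @export
maximum_intensity_map <- function(stack) {
  stopifnot(inherits(stack, "pli_stack"))
  Reduce(pmax, stack$images)
}
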