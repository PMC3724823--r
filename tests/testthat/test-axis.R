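# Longitudinal spline, radiality profile, boundary detection, segmentation
# and typical-subject selection.

test_that("spline recovers a circular arc laid out voxel-exactly", {
  # voxels on (not around) an arc of radius 20 about the origin
  th <- seq(-140, -40, by = 1.2) * pi / 180
  pts <- cbind(5, 20 * cos(th), 20 * sin(th))
  dims <- c(11, 60, 40)
  affine <- diag(4); affine[1:3, 4] <- c(0, -30, -25)
  mask <- array(0, dims)
  vox <- floor(sweep(pts, 2, c(0, -30, -25)) + 0.5)
  mask[unique(vox) + 1] <- 1
  sp <- fit_longitudinal_spline(mask, affine, ac_point = c(5, 0, 0))
  expect_equal(sp$n_samples, 45)
  expect_true(all(diff(sp$arc_length) > 0))
  # sampled positions on the arc within half a voxel
  r <- sqrt(sp$positions[, 2]^2 + sp$positions[, 3]^2)
  expect_lt(max(abs(r - 20)), 0.5)
  # tangents perpendicular to the radius vector within 2 degrees
  rad <- cbind(0, sp$positions[, 2], sp$positions[, 3])
  rad <- rad / sqrt(rowSums(rad^2))
  dev <- abs(90 - acos(pmin(1, abs(rowSums(sp$tangents * rad)))) * 180 / pi)
  expect_lt(max(dev), 2)
  # s = 0 at the posterior (-y) end
  expect_lt(sp$positions[1, 2], sp$positions[45, 2])
})

test_that("degenerate axes are rejected", {
  mask <- array(0, c(3, 40, 3)); mask[2, , 2] <- 1   # straight segment
  aff <- diag(4)
  # ac very far away: angular range collapses
  expect_error(fit_longitudinal_spline(mask, aff, c(0, 0, 1e5)),
               "degenerate axis")
  # two disconnected angular blobs
  mask2 <- array(0, c(3, 60, 60))
  mask2[2, 1:6, 30] <- 1
  mask2[2, 30, 1:6] <- 1
  expect_error(fit_longitudinal_spline(mask2, aff, c(0, 60, 60)),
               "disconnected")
})

test_that("phantom voxels project onto the fitted spline nearby", {
  ph <- small_phantom()
  sp <- fit_longitudinal_spline(ph$mask, ph$affine, ph$ac_point)
  pr <- project_to_spline(sp, phantom_world(ph))
  expect_lte(mean(pr$dist), 3)        # tube radius of the small phantom
  expect_equal(max(sp$arc_length), ph$arc_length_total, tolerance = 0.05)
})

test_that("radiality hits the exact extremes for planted fields", {
  ph <- small_phantom()
  sp <- truth_spline(ph)
  w <- phantom_world(ph)
  th <- atan2(w[, 3], w[, 2])
  tang <- cbind(0, -sin(th), cos(th))
  radial <- cbind(0, cos(th), sin(th))
  pr_t <- radiality_profile(stub_tensor_field(ph$mask, ph$affine, tang), sp)
  pr_r <- radiality_profile(stub_tensor_field(ph$mask, ph$affine, radial), sp)
  ok <- !is.na(pr_t$mean_angle_deg)
  expect_lt(max(pr_t$mean_angle_deg[ok]), 0.2)
  expect_gt(min(pr_r$mean_angle_deg[ok]), 89.8)
  # voxel counts partition the mask
  expect_equal(sum(pr_t$n_voxels), sum(ph$mask))
  # bounded in [0, 90] and sign-flip invariant
  pr_f <- radiality_profile(stub_tensor_field(ph$mask, ph$affine, -tang), sp)
  expect_equal(pr_f$mean_angle_deg, pr_t$mean_angle_deg, tolerance = 1e-12)
})

test_that("noiseless profile equals an independent per-voxel loop oracle", {
  ph <- small_phantom()
  dwi <- simulate_dwi(ph, default_scheme(n_dirs = 30), noise_sigma = 0)
  tf <- fit_tensors(dwi, ph$mask)
  sp <- fit_longitudinal_spline(ph$mask, ph$affine, ph$ac_point)
  pr <- radiality_profile(tf, sp)
  # brute-force oracle: explicit loops, nearest dense point by full search
  w <- phantom_world(ph)
  sums <- numeric(45); cnts <- integer(45)
  for (v in seq_len(nrow(w))) {
    d2 <- colSums((t(sp$dense_pos) - w[v, ])^2)
    j <- which.min(d2)
    smp <- which.min(abs(sp$param - sp$dense_param[j]))
    a <- acos(min(1, abs(sum(tf$principal_dir[v, ] *
                               sp$dense_tangents[j, ])))) * 180 / pi
    sums[smp] <- sums[smp] + a
    cnts[smp] <- cnts[smp] + 1L
  }
  oracle <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  expect_equal(pr$n_voxels, cnts)
  expect_equal(pr$mean_angle_deg, oracle, tolerance = 1e-6)
})

test_that("group boundary detection interpolates and finds minima", {
  # linear profile from 70 to 20 degrees inside the central window
  arc <- seq(0, 44)
  ang <- rep(60, 45)
  w0 <- 11; w1 <- 29                       # window [0.25, 0.65] of 44
  ang[(w0:w1) + 1] <- seq(70, 20, length.out = w1 - w0 + 1)
  prof <- data.frame(sample = 1:45, param = arc, arc_length_mm = arc,
                     mean_angle_deg = ang, n_voxels = 10)
  class(prof) <- c("radiality_profile", "data.frame")
  bs <- detect_group_boundaries(prof, central_window = c(0.25, 0.65),
                                head_window = c(0.60, 0.90),
                                smooth_minimum = FALSE)
  expect_equal(bs$b_45, mean(c(w0, w1)))   # exactly halfway
  # V-shaped minimum at sample 34 (arc 33)
  ang2 <- 60 - pmax(0, 10 - abs(arc - 33)) * 3
  prof2 <- prof; prof2$mean_angle_deg <- ang2
  bs2 <- detect_group_boundaries(prof2, smooth_minimum = FALSE)
  expect_equal(bs2$b_min, 33)
  # no crossing: clear error
  prof3 <- prof; prof3$mean_angle_deg <- rep(80, 45)
  expect_error(detect_group_boundaries(prof3), "no 45-degree crossing")
})

test_that("subject refinement respects the 10 mm window and tie-breaks", {
  arc <- seq(0, 44)                        # 1 mm spacing
  ang <- rep(60, 45)
  prof <- data.frame(sample = 1:45, param = arc, arc_length_mm = arc,
                     mean_angle_deg = ang, n_voxels = 10)
  class(prof) <- c("radiality_profile", "data.frame")
  group <- structure(list(b_45 = 20, b_min = 33, level = "group",
                          search_radius = NA), class = "boundary_set")
  # a sample outside the radius is closer to 45 but must be ignored
  prof$mean_angle_deg[45] <- 45       # arc 44, outside 20 +- 10
  prof$mean_angle_deg[25] <- 50       # arc 24, inside
  sb <- refine_subject_boundaries(prof, group, radius = 10)
  expect_equal(sb$b_45, 24)
  expect_true(abs(sb$b_45 - group$b_45) <= 10)
  expect_true(abs(sb$b_min - group$b_min) <= 10)
  # tie: two samples equally close to 45 -> posterior-most wins
  prof2 <- prof
  prof2$mean_angle_deg[] <- 60
  prof2$mean_angle_deg[c(13, 27)] <- c(50, 40)   # arc 12 and 26, both 5 off
  sb2 <- suppressWarnings(        # radius-15 window clips the profile end
    refine_subject_boundaries(prof2, group, radius = 15))
  expect_equal(sb2$b_45, 12)
  # profile identical to the group mean reproduces the group boundaries
  arc3 <- seq(0, 44)
  ang3 <- approx(c(0, 10, 30, 32, 35, 38, 44),
                 c(70, 70, 20, 40, 25, 50, 55), xout = arc3)$y
  prof3 <- data.frame(sample = 1:45, param = arc3, arc_length_mm = arc3,
                      mean_angle_deg = ang3, n_voxels = 10)
  class(prof3) <- c("radiality_profile", "data.frame")
  bsg <- suppressMessages(
    detect_group_boundaries(prof3, smooth_minimum = FALSE))
  sbg <- refine_subject_boundaries(prof3, bsg, radius = 10)
  expect_equal(sbg$b_45, bsg$b_45)    # 45 hit exactly at a sample (arc 20)
  expect_equal(sbg$b_min, bsg$b_min)  # unique minimum at arc 30
})

test_that("segmentation partitions the mask monotonically in arc length", {
  ph <- small_phantom()
  sp <- truth_spline(ph)
  total <- ph$arc_length_total
  bs <- structure(list(b_45 = total / 3, b_min = 2 * total / 3,
                       level = "group"), class = "boundary_set")
  lab <- segment_cn(ph$mask, sp, bs, ph$affine)
  expect_equal(sum(lab > 0), sum(ph$mask))          # exactly one label each
  counts <- table(lab[lab > 0])
  expect_equal(length(counts), 3L)
  # thirds of a uniform-density tube within 10%
  expect_true(all(abs(counts / sum(counts) - 1 / 3) < 1 / 30))
  # monotone along arc
  s <- project_to_spline(sp, phantom_world(ph))$arc_length
  l <- lab[ph$voxel_index + 1]
  expect_true(all(tapply(s, l, max)[1:2] <= tapply(s, l, min)[2:3] +
                    max(diff(sp$dense_arc))))
  # detected-vs-planted agreement when boundaries are close to truth
  bs2 <- structure(list(b_45 = ph$planted_boundaries[1] + 0.5,
                        b_min = ph$planted_boundaries[2] - 0.5,
                        level = "group"), class = "boundary_set")
  lab2 <- segment_cn(ph$mask, sp, bs2, ph$affine)
  agree <- mean(lab2[ph$voxel_index + 1] ==
                  ph$segment_labels[ph$voxel_index + 1])
  expect_gte(agree, 0.95)
  expect_error(segment_cn(ph$mask, sp,
                          structure(list(b_45 = -5, b_min = 10,
                                         level = "group"),
                                    class = "boundary_set"), ph$affine),
               "outside")
})

test_that("boundary recovery is equivariant under uniform scaling", {
  run_one <- function(R, tube, vox) {
    ph <- make_cn_phantom(arc_radius = R, tube_radius = tube,
                          voxel_size = vox)
    tf <- fit_tensors(simulate_dwi(ph, default_scheme(n_dirs = 30)),
                      ph$mask)
    sp <- fit_longitudinal_spline(ph$mask, ph$affine, ph$ac_point)
    bs <- detect_group_boundaries(radiality_profile(tf, sp))
    c(bs$b_45, bs$b_min, max(sp$arc_length))
  }
  big <- run_one(15, 3, 1)
  small <- run_one(7.5, 1.5, 0.5)
  # arc fractions agree within one sample spacing (1/44 of the arc)
  expect_lt(max(abs(big[1:2] / big[3] - small[1:2] / small[3])), 1.5 / 44)
})

test_that("typical-subject choice equals the brute-force row-sum argmin", {
  cm <- matrix(c(0, 2, 3, 1, 0, 1, 4, 5, 0), 3, 3, byrow = TRUE)
  expect_equal(choose_typical_subject(cm), 2L)      # row sums 5, 2, 9
  expect_message(expect_equal(choose_typical_subject(matrix(1, 4, 4)), 1L),
                 "tie")
  expect_error(choose_typical_subject(matrix(-1, 2, 2)), "non-negative")
  set.seed(20)
  for (i in 1:10) {
    cm <- matrix(runif(13 * 13), 13, 13)
    oracle <- which.min(sapply(1:13, function(r) sum(cm[r, -r])))
    expect_equal(choose_typical_subject(cm), oracle)
  }
})
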