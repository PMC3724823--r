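# Streamline tractography, bundle rules, endpoint maps.

test_that("uniform-field tracks span the mask within one step", {
  dims <- c(5, 60, 5)
  fld <- uniform_field(dims, c(0, 1, 0))
  seed_mask <- array(0, dims); seed_mask[3, 30, 3] <- 1
  ss <- track_streamlines(fld, seed_mask, n_seeds = 20, rng_seed = 1)
  expect_length(ss$streamlines, 20)
  expect_equal(nrow(ss$seeds), 20)
  for (sl in ss$streamlines) {
    len <- (nrow(sl) - 1) * ss$params$step
    expect_gte(len, 30)                      # min-length invariant
    # spans the 60 mm box within one step at each end
    expect_gte(len, 59 - 1e-9)
    expect_lte(len, 60 + 1e-9)
    # fixed step spacing
    spac <- sqrt(rowSums(diff(sl)^2))
    expect_lt(max(abs(spac - ss$params$step)), 1e-6)
    # straight: x and z constant
    expect_lt(max(abs(sweep(sl[, c(1, 3)], 2, sl[1, c(1, 3)]))), 1e-9)
  }
})

test_that("translation invariance: length independent of seed position", {
  dims <- c(5, 60, 5)
  fld <- uniform_field(dims, c(0, 1, 0))
  lens <- sapply(c(10, 25, 45), function(j) {
    sm <- array(0, dims); sm[3, j, 3] <- 1
    ss <- track_streamlines(fld, sm, n_seeds = 5, rng_seed = 2)
    mean(sapply(ss$streamlines, nrow))
  })
  expect_lte(diff(range(lens)), 2 + 1e-9)   # within one step (two points)
})

test_that("curvature bound terminates tight circular fields", {
  dims <- c(9, 9, 3)
  dirs <- array(0, c(dims, 3, 1)); amp <- array(0, c(dims, 1))
  ctr <- c(4, 4)
  for (i in 0:8) for (j in 0:8) {
    v <- c(-(j - ctr[2]), i - ctr[1])
    n <- sqrt(sum(v^2))
    if (n > 0) {
      dirs[i + 1, j + 1, , 1, 1] <- v[1] / n
      dirs[i + 1, j + 1, , 2, 1] <- v[2] / n
      amp[i + 1, j + 1, , 1] <- 1
    }
  }
  fld <- direction_field(dirs, amp, diag(4))
  sm <- array(0, dims); sm[6, 5, 2] <- 1    # one voxel off center: r ~ 1 mm
  # the flow circles at ~1 mm radius, far below the 2 mm curvature bound:
  # every track dies at its first step-angle violation
  ss <- track_streamlines(fld, sm, n_seeds = 30, rng_seed = 3,
                          curvature_radius = 2, min_length = 30)
  expect_length(ss$streamlines, 0)
  expect_error(track_streamlines(fld, sm, step = 5, curvature_radius = 2),
               "curvature")
  expect_error(track_streamlines(fld, array(0, dims)), "empty")
})

test_that("retained streamlines satisfy the curvature invariant", {
  ph <- small_phantom()
  tf <- fit_tensors(simulate_dwi(ph, default_scheme(n_dirs = 30),
                                 noise_sigma = 0.05, rng_seed = 6), ph$mask)
  fld <- tensor_direction_field(tf)
  ss <- track_streamlines(fld, ph$mask, n_seeds = 50, min_length = 10,
                          rng_seed = 4)
  expect_gt(length(ss$streamlines), 0)
  theta_max <- 2 * asin(ss$params$step / (2 * ss$params$curvature_radius))
  for (sl in ss$streamlines) {
    if (nrow(sl) < 3) next
    seg <- diff(sl)
    seg <- seg / sqrt(rowSums(seg^2))
    cosang <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
    expect_gte(min(cosang), cos(theta_max) - 1e-9)
  }
})

test_that("tracking is deterministic under a fixed seed", {
  dims <- c(5, 45, 5)
  fld <- uniform_field(dims, c(0, 1, 0))
  sm <- array(0, dims); sm[2:4, 20:25, 2:4] <- 1
  s1 <- track_streamlines(fld, sm, n_seeds = 10, rng_seed = 9)
  s2 <- track_streamlines(fld, sm, n_seeds = 10, rng_seed = 9)
  expect_identical(s1$streamlines, s2$streamlines)
  expect_identical(s1$seeds, s2$seeds)
})

test_that("bundle classification equals a brute-force point-in-mask oracle", {
  set.seed(40)
  dims <- c(20, 20, 20)
  rand_mask <- function() {
    m <- array(0, dims)
    c0 <- sample(3:16, 3)
    m[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)] <- 1
    m
  }
  polylines <- lapply(1:200, function(i) {
    start <- runif(3, 0, 19)
    steps <- matrix(rnorm(3 * 30, 0, 1), ncol = 3)
    pts <- sweep(apply(steps, 2, cumsum), 2, start, `+`)
    pts
  })
  sset <- structure(list(streamlines = polylines,
                         seeds = matrix(0, 200, 3),
                         seed_kept = rep(TRUE, 200),
                         params = list()), class = "streamline_set")
  for (rep in 1:4) {
    rules <- lapply(1:4, function(k) {
      list(label = paste0("b", k),
           include = list(rand_mask(), rand_mask()),
           exclude = list(rand_mask()))
    })
    got <- classify_bundles(sset, rules, diag(4))
    # independent oracle: literal loops, floor(x + 0.5) voxel membership
    oracle <- vapply(polylines, function(pts) {
      vox <- floor(pts + 0.5)
      inside <- function(m) {
        for (r in seq_len(nrow(vox))) {
          v <- vox[r, ]
          if (all(v >= 0) && all(v <= 19) &&
              m[v[1] + 1, v[2] + 1, v[3] + 1] != 0) return(TRUE)
        }
        FALSE
      }
      for (rule in rules) {
        if (inside(rule$exclude[[1]])) next
        if (inside(rule$include[[1]]) && inside(rule$include[[2]])) {
          return(rule$label)
        }
      }
      "unassigned"
    }, character(1))
    expect_identical(as.vector(got), oracle)
  }
})

test_that("rule semantics: AND-inclusion, exclusion veto, first match", {
  dims <- c(10, 30, 10)
  mkmask <- function(jr) { m <- array(0, dims); m[, jr, ] <- 1; m }
  sl <- list(cbind(5, seq(0, 29, by = 0.5), 5))    # runs the length of y
  sset <- structure(list(streamlines = sl, seeds = matrix(5, 1, 3),
                         seed_kept = TRUE, params = list()),
                    class = "streamline_set")
  rule_ab <- list(label = "ab", include = list(mkmask(3:5), mkmask(20:22)))
  expect_equal(as.vector(classify_bundles(sset, list(rule_ab), diag(4))),
               "ab")
  rule_excl <- c(rule_ab[1:2], list(exclude = list(mkmask(10))))
  rule_excl$label <- "vetoed"
  got <- classify_bundles(sset, list(rule_excl, rule_ab), diag(4))
  expect_equal(as.vector(got), "ab")               # first rule vetoed
  expect_equal(as.vector(classify_bundles(sset, list(), diag(4))),
               "unassigned")
})

test_that("endpoint maps attribute both endpoints to the seed's subregion", {
  dims <- c(7, 40, 30)
  labels <- array(0L, dims)
  labels[3:5, 5:12, 3:5] <- 1L     # posterior block: field along +y
  labels[3:5, 25:32, 3:5] <- 2L    # middle block: field along +z
  dirs <- array(0, c(dims, 3, 1)); amp <- array(1, c(dims, 1))
  dirs[, 1:20, , 2, 1] <- 1        # +y in the posterior half
  dirs[, 21:40, , 3, 1] <- 1       # +z in the anterior half
  fld <- direction_field(dirs, amp, diag(4))
  slab <- array(0, dims); slab[, , 29:30] <- 1   # target slab: top layers
  ss <- track_streamlines(fld, (labels > 0) * 1, n_seeds = 40,
                          min_length = 15, rng_seed = 12)
  expect_gt(length(ss$streamlines), 0)
  dens <- endpoint_density(ss, labels, diag(4))
  expect_named(dens, c("label_1", "label_2"))
  # total endpoint mass = 2 x streamline count (none leave the grid mid-slab)
  expect_equal(sum(dens$label_1) + sum(dens$label_2),
               2 * length(ss$streamlines))
  # planted connectivity: only label-2 (z-field) seeds reach the slab
  expect_gt(sum(dens$label_2 * slab), 0)
  expect_equal(sum(dens$label_1 * slab), 0)
  # single-streamline and empty-bundle edge cases
  one <- structure(list(streamlines = ss$streamlines[1],
                        seeds = ss$seeds[which(ss$seed_kept)[1], , drop = FALSE],
                        seed_kept = TRUE, params = ss$params),
                   class = "streamline_set")
  d1 <- endpoint_density(one, labels, diag(4))
  expect_equal(sum(d1$label_1) + sum(d1$label_2), 2)
  empty <- structure(list(streamlines = list(), seeds = matrix(0, 0, 3),
                          seed_kept = logical(0), params = list()),
                     class = "streamline_set")
  de <- endpoint_density(empty, labels, diag(4))
  expect_true(all(sapply(de, sum) == 0))
})
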