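# PLI forward model, sinusoid fitting and orientation inversion.

test_that("forward model has the textbook zeros, maxima and limits", {
  proto_c <- pli_protocol("crossed")
  expect_equal(proto_c$rotation_angles, seq(0, 80, by = 10))
  st <- simulate_pli_section(matrix(0), matrix(0), proto_c)
  expect_length(st$images, 9)                     # nine images per set
  ints <- sapply(st$images, function(m) m[1, 1])
  expect_equal(ints[1], 0)                        # rho = phi: extinction
  # the true maximum sits at rho = 45; the sampled 40 and 50 flank it evenly
  expect_equal(which.max(ints), which(proto_c$rotation_angles == 40))
  expect_equal(ints[proto_c$rotation_angles == 40],
               ints[proto_c$rotation_angles == 50], tolerance = 1e-12)
  # fiber perpendicular to the section: delta = 0, both sets flat
  st90c <- simulate_pli_section(matrix(30), matrix(90), proto_c)
  expect_true(all(abs(sapply(st90c$images, c)) < 1e-12))
  proto_q <- pli_protocol("quarter_wave")
  expect_equal(proto_q$rotation_angles, seq(0, 160, by = 20))
  st90q <- simulate_pli_section(matrix(30), matrix(90), proto_q)
  expect_equal(sapply(st90q$images, c), rep(0.5, 9), tolerance = 1e-12)
  expect_error(simulate_pli_section(matrix(0), matrix(95), proto_q),
               "\\[-90, 90\\]")
})

test_that("forward intensities are periodic in the filter rotation", {
  phi <- matrix(c(10, 75, 130), 1)
  alpha <- matrix(c(0, 30, 60), 1)
  at <- function(proto, rho) {
    simulate_pli_section(phi, alpha,
                         pli_protocol(proto, rotation_angles = rho))$images[[1]]
  }
  for (rho in c(0, 37, 61)) {
    expect_equal(at("crossed", rho), at("crossed", rho + 90),
                 tolerance = 1e-12)
    expect_equal(at("quarter_wave", rho), at("quarter_wave", rho + 180),
                 tolerance = 1e-12)
  }
})

test_that("sinusoid fitting is exact on noiseless data", {
  rho <- seq(0, 160, by = 20)
  ints <- 10 + 5 * sin(2 * rho * pi / 180)        # a = 10, b = 5, c = 0
  fit <- fit_sinusoid(rho, ints)
  expect_equal(fit$offset, 10, tolerance = 1e-9)
  expect_equal(fit$amplitude, 5, tolerance = 1e-9)
  expect_lt(min(fit$phase, 360 - fit$phase), 1e-9)
  # constant series: amplitude 0, phase undefined
  fit0 <- fit_sinusoid(rho, rep(7, 9))
  expect_equal(fit0$offset, 7)
  expect_equal(fit0$amplitude, 0, tolerance = 1e-12)
  expect_false(fit0$phase_defined)
  expect_true(is.na(fit0$phase))
  expect_error(fit_sinusoid(c(0, 10), c(1, 2)), "insufficient")
  expect_error(fit_sinusoid(c(0, 10, 10), c(1, 2, 3)), "distinct")
})

test_that("fitted phase is unbiased under Gaussian noise", {
  rho <- seq(0, 160, by = 20)
  a <- 10; b <- 5; c_true <- 40
  clean <- a + b * sin((2 * rho + c_true) * pi / 180)
  set.seed(30)
  nrep <- 2000
  Y <- matrix(clean, 9, nrep) + matrix(rnorm(9 * nrep, 0, 0.1 * b), 9)
  fit <- fit_sinusoid(rho, Y)
  # circular mean of recovered phase vs truth
  err <- (fit$phase - c_true + 180) %% 360 - 180
  se <- sd(err) / sqrt(nrep)
  expect_lt(abs(mean(err)), 3 * se + 1e-3)
})

test_that("orientation round-trips through the forward model", {
  proto_q <- pli_protocol("quarter_wave")
  proto_c <- pli_protocol("crossed")
  # direction sweep at alpha = 0
  phi <- matrix(0:179, 1)
  alpha <- matrix(0, 1, 180)
  qs <- simulate_pli_section(phi, alpha, proto_q)
  cs <- simulate_pli_section(phi, alpha, proto_c)
  om <- estimate_orientation(cs, qs, noise_floor = 1e-9)
  err <- pmin(abs(om$direction - phi),
              180 - abs(om$direction - phi))
  expect_lt(max(err), 1e-6)
  expect_lt(max(abs(om$inclination)), 1e-3)
  # inclination sweep
  alpha2 <- matrix(seq(0, 70, by = 2), 1)
  phi2 <- matrix(50, 1, ncol(alpha2))
  om2 <- estimate_orientation(
    quarter = simulate_pli_section(phi2, alpha2, proto_q),
    noise_floor = 1e-9)
  expect_lt(max(abs(om2$inclination - alpha2)), 1e-3)
  expect_lt(max(abs(om2$direction - 50)), 1e-6)
})

test_that("steep fibers are flagged invalid via the noise floor", {
  proto_q <- pli_protocol("quarter_wave")
  phi <- matrix(30, 2, 2)
  alpha <- matrix(c(0, 0, 0, 90), 2, 2)
  om <- estimate_orientation(
    quarter = simulate_pli_section(phi, alpha, proto_q))
  expect_true(all(om$valid[alpha == 0]))
  expect_false(om$valid[2, 2])
  expect_true(is.na(om$direction[2, 2]))
})

test_that("direction estimation is equivariant under map rotation", {
  proto_q <- pli_protocol("quarter_wave")
  phi <- matrix(c(5, 40, 95, 170), 2)
  alpha <- matrix(20, 2, 2)
  om0 <- estimate_orientation(
    quarter = simulate_pli_section(phi, alpha, proto_q), noise_floor = 1e-9)
  for (shift in c(15, 90)) {
    om1 <- estimate_orientation(
      quarter = simulate_pli_section((phi + shift) %% 180, alpha, proto_q),
      noise_floor = 1e-9)
    d <- (om1$direction - om0$direction - shift) %% 180
    expect_lt(max(pmin(d, 180 - d)), 1e-6)
  }
})

test_that("maximum-intensity map equals the loop oracle and orders by inclination", {
  proto_c <- pli_protocol("crossed")
  set.seed(31)
  phi <- matrix(runif(30, 0, 180), 5)
  alpha <- matrix(runif(30, 0, 80), 5)
  st <- simulate_pli_section(phi, alpha, proto_c, noise_sigma = 0.01,
                             rng_seed = 8)
  mi <- maximum_intensity_map(st)
  oracle <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) {
    v <- -Inf
    for (k in seq_along(st$images)) v <- max(v, st$images[[k]][i, j])
    oracle[i, j] <- v
  }
  expect_equal(mi, oracle)
  # flat fiber brighter than steep fiber at equal I0
  st2 <- simulate_pli_section(matrix(c(20, 20), 1), matrix(c(0, 80), 1),
                              proto_c)
  mi2 <- maximum_intensity_map(st2)
  expect_gt(mi2[1, 1], mi2[1, 2])
  # constant sequence maps to the constant
  stc <- structure(list(images = lapply(1:9, function(i) matrix(7, 2, 2)),
                        protocol = proto_c), class = "pli_stack")
  expect_equal(maximum_intensity_map(stc), matrix(7, 2, 2))
})
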