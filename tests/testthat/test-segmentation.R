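test_that("polar unwrap reproduces analytic image structure", {
  # constant slice -> constant polar grid
  pol <- polar_unwrap(matrix(0.7, 41, 41), c(21, 21), 15, 36, 30)
  expect_lt(max(abs(pol$values - 0.7)), 1e-12)
  expect_false(any(pol$oob))

  # smooth radially symmetric ring -> constant along the angle axis
  yy <- matrix(1:61, 61, 61); xx <- t(yy)
  r <- sqrt((yy - 31)^2 + (xx - 31)^2)
  ring <- exp(-(r - 15)^2 / (2 * 8^2))
  pol <- polar_unwrap(ring, c(31, 31), 25, 72, 50)
  spread <- apply(pol$values, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 0.01)     # bilinear interpolation tolerance

  # out-of-bounds samples are flagged
  pol <- polar_unwrap(matrix(1, 21, 21), c(11, 11), 15, 36, 30)
  expect_true(any(pol$oob))
  expect_error(polar_unwrap(matrix(1, 21, 21), c(30, 11), 5, 36, 30),
               "outside")
})

test_that("rotating the slice circularly shifts the polar rows", {
  f <- function(y, x) {                       # smooth, angularly asymmetric
    exp(-((y - 31) - 8)^2 / 40 - (x - 31)^2 / 60) +
      0.5 * exp(-((x - 31) - 12)^2 / 80 - (y - 31)^2 / 50)
  }
  n_angles <- 36
  th <- 2 * pi / n_angles
  yy <- matrix(1:61, 61, 61); xx <- t(yy)
  s1 <- f(yy, xx)
  # rotate the analytic field by exactly one angular step about the center
  ry <- 31 + (yy - 31) * cos(th) - (xx - 31) * sin(th)
  rx <- 31 + (yy - 31) * sin(th) + (xx - 31) * cos(th)
  s2 <- f(ry, rx)
  p1 <- polar_unwrap(s1, c(31, 31), 20, n_angles, 40)
  p2 <- polar_unwrap(s2, c(31, 31), 20, n_angles, 40)
  shifted <- p1$values[c(n_angles, 1:(n_angles - 1)), ]
  expect_equal(p2$values, shifted, tolerance = 0.01)
})

test_that("boundary costs carry the documented sign convention", {
  # radially decreasing intensity: inner cost favourable, outer unfavourable
  yy <- matrix(1:41, 41, 41); xx <- t(yy)
  r <- sqrt((yy - 21)^2 + (xx - 21)^2)
  pol <- polar_unwrap(41 - r, c(21, 21), 14, 36, 28)
  ci <- boundary_cost(pol, "inner")
  co <- boundary_cost(pol, "outer")
  expect_true(all(ci < 0))
  expect_true(all(co > 0))

  # constant grid -> zero cost
  pol <- polar_unwrap(matrix(1, 41, 41), c(21, 21), 14, 36, 28)
  expect_lt(max(abs(boundary_cost(pol, "inner"))), 1e-12)

  # sharp annulus: per-angle argmin of the inner cost sits at the inner edge
  sl <- make_annulus_slice(61, c(31, 31), 8, 14)
  pol <- polar_unwrap(sl, c(31, 31), 20, 36, 40)
  ci <- boundary_cost(pol, "inner")
  r_step <- 20 / 40
  argmin_r <- pol$r[apply(ci, 1, which.min)]
  expect_true(all(abs(argmin_r - 8) <= 1 + r_step))
})

test_that("circular DP matches exhaustive enumeration and keeps its contract", {
  set.seed(11)
  for (k in 1:20) {
    cost <- matrix(rnorm(6 * 5), 6, 5)
    delta <- sample(1:2, 1)
    lambda <- sample(c(0, 0.25), 1)
    res <- dp_circular_path(cost, delta, lambda)
    expect_equal(res$objective, brute_force_dp(cost, delta, lambda),
                 tolerance = 1e-12)
    p <- res$path
    expect_true(all(abs(diff(c(p, p[1]))) <= delta))
    expect_equal(res$objective,
                 sum(cost[cbind(1:6, p)]) + lambda * sum(diff(c(p, p[1]))^2),
                 tolerance = 1e-12)
  }

  # a single zero-cost ring is the unique optimum
  cost <- matrix(1, 12, 8); cost[, 5] <- 0
  expect_identical(dp_circular_path(cost, 1, 0)$path, rep(5L, 12))

  # unconstrained separable limit: path = per-angle argmin
  set.seed(12)
  cost <- matrix(rnorm(8 * 5), 8, 5)
  am <- apply(cost, 1, which.min)
  if (all(abs(diff(c(am, am[1]))) <= 5))
    expect_identical(dp_circular_path(cost, 5, 0)$path, am)

  # fully forbidden column -> lost
  cost <- matrix(1, 6, 5); cost[3, ] <- Inf
  expect_true(dp_circular_path(cost, 1, 0)$lost)
})

test_that("contour fitting recovers a noiseless annulus", {
  sl <- make_annulus_slice(101, c(51, 51), 8, 14)
  fit <- fit_contour(sl, c(49, 53), 20, segmentation_params())
  expect_false(fit$lost)
  expect_false(fit$gap)
  expect_lt(abs(mean(fit$outer$radii) - 14), 0.5)
  expect_lt(abs(mean(fit$inner$radii) - 8), 0.5)
  expect_lt(sqrt(sum((fit$outer$center - c(51, 51))^2)), 0.3)

  # exact-center symmetric start: recovered center barely moves
  fit2 <- fit_contour(sl, c(51, 51), 20, segmentation_params())
  expect_lt(sqrt(sum((fit2$outer$center - c(51, 51))^2)), 0.1)
})

test_that("pure-noise slices score above the lost threshold", {
  params <- segmentation_params()
  set.seed(21)
  costs <- vapply(1:20, function(k) {
    sl <- matrix(rnorm(76 * 76, 1, 0.05), 76, 76)
    fit_contour(sl, c(38, 38), 15, params)$mean_cost
  }, numeric(1))
  expect_gt(mean(costs > params$cost_threshold), 0.85)

  # and the calibration routine reproduces a threshold of that order
  tau <- calibrate_cost_threshold(params, n = 50, seed = 5)
  expect_lt(tau, 0)
  expect_gt(tau, 10 * params$cost_threshold)
})

test_that("propagation tracks straight and helical phantom fibres", {
  cfg <- small_phantom_config(seed = 31)
  sim <- simulate_study_volume(cfg)
  vs <- cfg$voxel_size_nm
  nz <- cfg$shape[1]

  # large fibre: full z coverage, both ends at the volume edge
  f <- sim$truth$fibres[[1]]
  seg <- propagate(sim$volume, 16L, f$centerline[16, c("y", "x")] / vs + 1,
                   1.3 * f$r_outer_nm[16] / vs)
  expect_identical(seg$slices, seq_len(nz))
  expect_identical(unname(seg$status), c("volume_edge", "volume_edge"))
  rec <- vapply(seg$contours, function(cp) mean(cp$outer$radii), numeric(1))
  expect_lt(mean(abs(rec - f$r_outer_nm[seg$slices] / vs)), 0.5)

  # helical thin fibre: centerline recovered within 1 voxel everywhere
  hid <- sim$truth$clusters[[1]][1]
  fh <- sim$truth$fibres[[hid]]
  segh <- propagate(sim$volume, 16L, fh$centerline[16, c("y", "x")] / vs + 1,
                    1.4 * fh$r_outer_nm[16] / vs)
  expect_identical(segh$slices, seq_len(nz))
  cl <- centerline_of(segh)
  err <- sqrt(rowSums((cl[, c("y", "x")] -
                       fh$centerline[segh$slices, c("y", "x")])^2)) / vs
  expect_lt(max(err), 1)

  # seeding in empty background raises the documented error
  expect_error(propagate(sim$volume, 16L, c(5, 5), 4), "no fibre")
})

test_that("recovered radii are equivariant under slice rotation", {
  # smooth annulus with an angular bulge, rotated by two angular steps
  n_angles <- 36
  th <- 2 * 2 * pi / n_angles
  shape_fn <- function(y, x) {
    r <- sqrt((y - 41)^2 + (x - 41)^2)
    a <- atan2(y - 41, x - 41)
    r_in <- 8 + 1.5 * cos(a); r_out <- 14 + 1.5 * cos(a)
    0.55 * stats::plogis(-(r - r_in), scale = 0.5) +
      0.15 * (stats::plogis(r - r_in, scale = 0.5) *
              stats::plogis(-(r - r_out), scale = 0.5)) +
      1.0 * stats::plogis(r - r_out, scale = 0.5)
  }
  yy <- matrix(1:81, 81, 81); xx <- t(yy)
  s1 <- shape_fn(yy, xx)
  ry <- 41 + (yy - 41) * cos(th) - (xx - 41) * sin(th)
  rx <- 41 + (yy - 41) * sin(th) + (xx - 41) * cos(th)
  s2 <- shape_fn(ry, rx)
  par <- segmentation_params(n_angles = n_angles)
  f1 <- fit_contour(s1, c(41, 41), 18, par)
  f2 <- fit_contour(s2, c(41, 41), 18, par)
  shifted <- f1$outer$radii[c(n_angles - 1, n_angles, 1:(n_angles - 2))]
  expect_equal(f2$outer$radii, shifted, tolerance = 0.25)
})

test_that("radius error grows with the noise level", {
  noise <- c(0, 0.05, 0.1, 0.2)
  errs <- vapply(noise, function(s) {
    mean(vapply(1:6, function(k) {
      cfg <- phantom_config(shape = c(4, 96, 96), n_large_fibres = 1,
                            cluster = list(n_clusters = 0,
                                           fibres_per_cluster = 0,
                                           helix_radius_nm = 0, turns = 0,
                                           r_outer_nm = c(900, 1200),
                                           g_ratio = c(0.6, 0.7),
                                           gap_nm = 2000),
                            vessel = list(enabled = FALSE, radius_nm = 0),
                            noise_sigma = s, seed = 100 + k)
      sim <- simulate_study_volume(cfg)
      f <- sim$truth$fibres[[1]]
      vs <- cfg$voxel_size_nm
      fit <- fit_contour(sim$volume$data[2, , ],
                         f$centerline[2, c("y", "x")] / vs + 1,
                         1.3 * f$r_outer_nm[2] / vs)
      abs(mean(fit$outer$radii) - f$r_outer_nm[2] / vs)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) > -0.02))   # non-decreasing up to seed noise
  expect_gt(errs[4], errs[1])
})
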