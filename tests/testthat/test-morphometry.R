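test_that("circular contours reproduce closed-form morphometry", {
  # circles r = 8 and 14 voxels at 130 nm: diameters 2080/3640 nm,
  # thickness 780 nm, g-ratio 4/7 (polygon area converges to the circle)
  seg <- make_circle_seg(1:3, rbind(c(30, 30), c(30, 30), c(30, 30)),
                         r_in = rep(8, 3), r_out = rep(14, 3),
                         n_angles = 72, voxel_size_nm = 130)
  m <- fibre_metrics(seg)
  s <- attr(m, "summary")
  expect_equal(s$axon_diameter_nm, 2080, tolerance = 1e-3)
  expect_equal(s$fibre_diameter_nm, 3640, tolerance = 1e-3)
  expect_equal(s$myelin_thickness_nm, 780, tolerance = 1e-9)
  expect_equal(s$g_ratio, 4 / 7, tolerance = 1e-9)
  expect_true(all(m$g_ratio > 0 & m$g_ratio < 1))

  # regular n-gon area closed form, exercised through the equivalent diameter
  for (n in c(4, 7, 12)) {
    segn <- make_circle_seg(1, rbind(c(30, 30)), r_in = 5, r_out = 10,
                            n_angles = n, voxel_size_nm = 1)
    a_ngon <- 0.5 * n * 10^2 * sin(2 * pi / n)
    got <- attr(fibre_metrics(segn), "summary")$fibre_diameter_nm
    expect_equal(got, 2 * sqrt(a_ngon / pi), tolerance = 1e-9)
  }

  # gap slices are excluded from the summary
  segg <- make_circle_seg(1:4, matrix(30, 4, 2), r_in = rep(8, 4),
                          r_out = rep(14, 4), n_angles = 36,
                          gap = c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(attr(fibre_metrics(segg), "summary")$n_gap_slices, 2L)
})

test_that("centerlines are centroids and translate linearly", {
  seg <- make_circle_seg(1:5, matrix(rep(c(20, 25), each = 5), 5, 2),
                         r_in = rep(4, 5), r_out = rep(9, 5), n_angles = 36)
  cl <- centerline_of(seg)
  expect_equal(unname(cl[, "y"]), rep((20 - 1) * 130, 5), tolerance = 1e-9)
  expect_equal(unname(cl[, "x"]), rep((25 - 1) * 130, 5), tolerance = 1e-9)

  seg2 <- make_circle_seg(1:5, matrix(rep(c(23, 21), each = 5), 5, 2),
                          r_in = rep(4, 5), r_out = rep(9, 5), n_angles = 36)
  cl2 <- centerline_of(seg2)
  expect_equal(cl2[, "y"] - cl[, "y"], rep(3 * 130, 5), tolerance = 1e-9)
  expect_equal(cl2[, "x"] - cl[, "x"], rep(-4 * 130, 5), tolerance = 1e-9)
})

test_that("winding measures intertwining and honours its symmetries", {
  sl <- 1:200
  # parallel straight lines: zero turns
  a <- helix_centerline(sl, c(0, 0), 0.001, 0)
  b <- helix_centerline(sl, c(5000, 0), 0.001, 0)
  expect_equal(pairwise_winding(a, b)$winding_turns, 0, tolerance = 1e-9)

  # double helix, 3 full turns
  h1 <- helix_centerline(sl, c(0, 0), 1500, 3, phase = 0)
  h2 <- helix_centerline(sl, c(0, 0), 1500, 3, phase = pi)
  w <- pairwise_winding(h1, h2)
  expect_equal(w$winding_turns, 3, tolerance = 0.02)
  expect_identical(w$shared_slices, 200L)

  # swapping the pair leaves winding unchanged
  expect_equal(pairwise_winding(h2, h1)$winding_turns, w$winding_turns,
               tolerance = 1e-12)

  # z-reversal (traversing both curves from high to low z) flips the sign
  rev_cl <- function(cl) structure(cl[rev(seq_len(nrow(cl))), ],
                                   slices = rev(attr(cl, "slices")),
                                   class = class(cl))
  phi_fwd <- pairwise_winding(h1, h2)$winding_turns
  expect_equal(pairwise_winding(rev_cl(h1), rev_cl(h2))$winding_turns,
               -phi_fwd, tolerance = 1e-9)

  # global in-plane rotation leaves winding unchanged
  th <- 0.7
  rot <- function(cl) {
    out <- cl
    out[, "y"] <- cl[, "y"] * cos(th) - cl[, "x"] * sin(th)
    out[, "x"] <- cl[, "y"] * sin(th) + cl[, "x"] * cos(th)
    out
  }
  expect_equal(pairwise_winding(rot(h1), rot(h2))$winding_turns, phi_fwd,
               tolerance = 1e-9)

  # coincident points are an error naming the slice
  bad <- h2; bad[5, c("y", "x")] <- h1[5, c("y", "x")]
  expect_error(pairwise_winding(h1, bad), "slice")
})

test_that("cluster classification flags intertwined pairs", {
  sl <- 1:100
  h1 <- helix_centerline(sl, c(0, 0), 1500, 2, phase = 0)
  h2 <- helix_centerline(sl, c(0, 0), 1500, 2, phase = 2 * pi / 3)
  s1 <- helix_centerline(sl, c(20000, 0), 0.001, 0)
  cw <- classify_cluster(list(a = h1, b = h2, far = s1))
  expect_identical(nrow(cw), 3L)
  expect_true(cw$intertwined[cw$fibre_a == "a" & cw$fibre_b == "b"])
  expect_false(any(cw$intertwined[cw$fibre_b == "far"]))

  # threshold 0 flags every pair
  expect_true(all(classify_cluster(list(h1, h2, s1),
                                   threshold_turns = 0)$intertwined))
  expect_error(classify_cluster(list(h1)), "at least 2")
})

test_that("gap detection returns half-open runs of thin myelin", {
  # constant thickness: nothing to report
  seg <- make_circle_seg(1:20, matrix(30, 20, 2), r_in = rep(6, 20),
                         r_out = rep(12, 20), n_angles = 36)
  expect_identical(nrow(detect_myelin_gaps(seg)), 0L)

  # slices 8..15 thin (8-slice run): one interval [8, 16)
  r_out <- rep(12, 20); r_out[8:15] <- 6.5
  seg <- make_circle_seg(1:20, matrix(30, 20, 2), r_in = rep(6, 20),
                         r_out = r_out, n_angles = 36)
  g <- detect_myelin_gaps(seg, min_gap_slices = 3)
  expect_identical(nrow(g), 1L)
  expect_identical(g$z_start, 8L)
  expect_identical(g$z_end, 16L)
  expect_identical(g$n_slices, 8L)

  # a min_gap longer than every run filters everything out
  expect_identical(nrow(detect_myelin_gaps(seg, min_gap_slices = 9)), 0L)
})

test_that("fibre density counts centerline points per area", {
  mk <- function(cy, cx, diam) {
    seg <- make_circle_seg(1, rbind(c(cy, cx)), r_in = diam / 2 / 130 * 0.6,
                           r_out = diam / 2 / 130, n_angles = 36)
    fibre_metrics(seg)
  }
  # 5 fibres inside a 100 x 100 um ROI (0.01 mm^2) -> 500 per mm^2
  recs <- lapply(1:5, function(i) mk(10 + i, 10 + i, 6000))
  roi <- c(0, 1e5, 0, 1e5)
  d <- fibre_density(recs, roi, slice_z = 1)
  expect_identical(d$count, 5L)
  expect_equal(d$density_per_mm2, 500)
  expect_equal(d$density_per_mm2 * 0.01, d$count)  # integer consistency

  # ROI covering no centerlines
  expect_identical(fibre_density(recs, c(2e5, 3e5, 2e5, 3e5), 1)$count, 0L)
  # diameter filter removes small fibres
  recs2 <- c(recs, list(mk(12, 13, 2000)))
  expect_identical(fibre_density(recs2, roi, 1)$count, 6L)
  expect_identical(fibre_density(recs2, roi, 1,
                                 min_diameter_nm = 5000)$count, 5L)
  expect_error(fibre_density(recs, c(0, 0, 0, 1e5), 1), "area")
})

test_that("a sparser phantom yields a lower large-fibre density", {
  mk_density <- function(n_large, seed) {
    cfg <- phantom_config(shape = c(6, 192, 192), n_large_fibres = n_large,
                          cluster = list(n_clusters = 0,
                                         fibres_per_cluster = 0,
                                         helix_radius_nm = 0, turns = 0,
                                         r_outer_nm = c(900, 1200),
                                         g_ratio = c(0.6, 0.7),
                                         gap_nm = 2000),
                          vessel = list(enabled = FALSE, radius_nm = 0),
                          seed = seed)
    sim <- simulate_study_volume(cfg)
    vs <- cfg$voxel_size_nm
    recs <- lapply(sim$truth$fibres, function(f) {
      seg <- propagate(sim$volume, 3L, f$centerline[3, c("y", "x")] / vs + 1,
                       1.3 * f$r_outer_nm[3] / vs, fibre_id = f$id)
      fibre_metrics(seg)
    })
    roi <- c(0, 191 * vs, 0, 191 * vs)
    fibre_density(recs, roi, slice_z = 3)$density_per_mm2
  }
  expect_lt(mk_density(2, seed = 41), mk_density(7, seed = 42))
})
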