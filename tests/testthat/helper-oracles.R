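# Brute-force oracle for the circular dynamic programme: exhaustive
# enumeration over all wrap-consistent radial index paths.
brute_force_dp <- function(cost, delta, lambda) {
  na <- nrow(cost); nr <- ncol(cost)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(nr)), na)))
  best <- Inf
  for (k in seq_len(nrow(grid))) {
    p <- grid[k, ]
    dr <- diff(c(p, p[1]))
    if (any(abs(dr) > delta)) next
    obj <- sum(cost[cbind(seq_len(na), p)]) + lambda * sum(dr^2)
    if (obj < best) best <- obj
  }
  best
}

# Analytic annulus test slice: axon disc inside a dark myelin ring on a
# bright background (sharp edges, no blur or noise).
make_annulus_slice <- function(side, center, r_in, r_out,
                               bg = 1, ax = 0.55, my = 0.15) {
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  d <- sqrt((yy - center[1])^2 + (xx - center[2])^2)
  ifelse(d < r_in, ax, ifelse(d < r_out, my, bg))
}

# Build an nn_fibre_segmentation from per-slice circular contours without
# running the tracker (for export/morphometry unit tests).
make_circle_seg <- function(slices, centers, r_in, r_out, n_angles = 4,
                            voxel_size_nm = 130, gap = rep(FALSE,
                                                           length(slices))) {
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  contours <- lapply(seq_along(slices), function(k) {
    ct_o <- nervenano:::nn_contour(centers[k, ], rep(r_out[k], n_angles),
                                   angles, slices[k])
    ct_i <- nervenano:::nn_contour(centers[k, ], rep(r_in[k], n_angles),
                                   angles, slices[k])
    list(inner = ct_i, outer = ct_o, mean_cost = -1, gap = gap[k])
  })
  structure(list(fibre_id = 1L, slices = as.integer(slices),
                 contours = contours,
                 status = c(lower = "volume_edge", upper = "volume_edge"),
                 voxel_size_nm = voxel_size_nm, origin_nm = c(0, 0, 0)),
            class = "nn_fibre_segmentation")
}

# Analytic helix centerline (pitch expressed through turns over the slices).
helix_centerline <- function(slices, center_nm, radius_nm, turns, phase = 0,
                             voxel_size_nm = 130) {
  z <- (slices - 1) * voxel_size_nm
  t <- (z - min(z)) / (max(z) - min(z))
  ang <- phase + 2 * pi * turns * t
  structure(cbind(z = z, y = center_nm[1] + radius_nm * sin(ang),
                  x = center_nm[2] + radius_nm * cos(ang)),
            slices = as.integer(slices),
            class = c("nn_centerline", "matrix", "array"))
}

# Small phantom configuration for fast tests.
small_phantom_config <- function(...) {
  phantom_config(shape = c(32, 128, 128), n_large_fibres = 2,
                 large_r_outer_nm = c(1600, 2200),
                 cluster = list(n_clusters = 1, fibres_per_cluster = 2,
                                helix_radius_nm = 1500, turns = 0.6,
                                r_outer_nm = c(900, 1200),
                                g_ratio = c(0.60, 0.70), gap_nm = 2000),
                 vessel = list(enabled = FALSE, radius_nm = 2500), ...)
}
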