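#' Segmentation parameters
#'
#' Tuning knobs of the per-slice closed-curve fit and its z propagation.
#' The curve is a closed polar path: `n_angles` radial spokes about a
#' center, each spoke carrying `n_radii` uniformly spaced radial samples up
#' to an adaptive maximum radius (capped at `r_max_vox`). The dynamic
#' programme constrains the radial index to change by at most `delta`
#' samples between neighbouring spokes (wrap included) and adds a quadratic
#' smoothness penalty `lambda * (dr)^2`.
#'
#' @param n_angles number of angular samples (>= 8).
#' @param n_radii number of radial samples per spoke (>= 4).
#' @param r_max_vox hard cap on the unwrap radius, voxels.
#' @param delta maximum radial-index jump between neighbouring angles.
#' @param lambda quadratic smoothness weight on the per-angular-step radial
#'   change, in voxel^2 units (0 disables); converted internally to the
#'   radial-sample units of the dynamic programme.
#' @param max_drift maximum allowed center displacement between consecutive
#'   slices, voxels; larger displacements terminate tracking as `lost`.
#' @param cost_threshold `tau`: a fitted slice whose mean outer-path cost
#'   exceeds this value is considered to have lost the fibre. The default
#'   was computed with [calibrate_cost_threshold()] at the generator's
#'   default noise level (sigma 0.05): 95% of pure-noise fits fall above it.
#' @param max_slices per-direction cap on propagation length.
#' @param window_lo,window_hi search window for the outer boundary as
#'   multiples of the initial radius (plus 2 voxels of slack on top).
#' @param gap_contrast myelin-presence margin (intensity units): the ring
#'   between the inner and outer paths must be darker than the axoplasm core
#'   by at least this much, otherwise the slice is flagged as a myelin gap.
#' @param gap_flag_vox slices whose mean myelin thickness falls below this
#'   many voxels are also flagged as gaps.
#' @param subvoxel logical; parabolic sub-sample refinement of the optimal
#'   radial indices.
#' @return a `nn_segmentation_params` list.
#' @export
segmentation_params <- function(n_angles = 72, n_radii = 60, r_max_vox = 45,
                                delta = 1, lambda = 0.1, max_drift = 3,
                                cost_threshold = -0.021, max_slices = 4096,
                                window_lo = 0.45, window_hi = 1.6,
                                gap_contrast = 0.1, gap_flag_vox = 2,
                                subvoxel = FALSE) {
  stopifnot(n_angles >= 8, n_radii >= 4, delta >= 1, r_max_vox > 0,
            is.finite(cost_threshold), max_drift > 0, max_slices >= 1)
  structure(list(n_angles = as.integer(n_angles),
                 n_radii = as.integer(n_radii), r_max_vox = r_max_vox,
                 delta = as.integer(delta), lambda = lambda,
                 max_drift = max_drift, cost_threshold = cost_threshold,
                 max_slices = as.integer(max_slices),
                 window_lo = window_lo, window_hi = window_hi,
                 gap_contrast = gap_contrast, gap_flag_vox = gap_flag_vox,
                 subvoxel = isTRUE(subvoxel)),
            class = "nn_segmentation_params")
}

#' Resample an image slice onto a polar grid
#'
#' Entry `(i, j)` is the bilinear interpolation of the slice at
#' `center + r_j * (sin(theta_i), cos(theta_i))` (y, x), with
#' `theta_i = 2*pi*(i-1)/n_angles` and `r_j = j * r_max_vox / n_radii`
#' spanning `(0, r_max_vox]`. Samples falling outside the slice take the
#' nearest-edge value and are flagged out-of-bounds.
#'
#' @param slice 2D numeric matrix (y, x).
#' @param center `(y, x)` in 1-based voxel coordinates; must lie inside the
#'   slice.
#' @param r_max_vox maximum radius, voxels.
#' @param n_angles,n_radii polar grid size.
#' @return a `nn_polar`: list with `values` and `oob` (`n_angles x n_radii`
#'   matrices), `r` (radii, voxels), `angles` (radians), `r_step`, `center`.
#' @export
polar_unwrap <- function(slice, center, r_max_vox, n_angles = 72,
                         n_radii = 60) {
  stopifnot(is.matrix(slice), r_max_vox > 0)
  ny <- nrow(slice); nx <- ncol(slice)
  if (center[1] < 1 || center[1] > ny || center[2] < 1 || center[2] > nx)
    stop("center lies outside the slice")
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  r <- seq_len(n_radii) * r_max_vox / n_radii
  ys <- center[1] + outer(sin(angles), r)     # n_angles x n_radii
  xs <- center[2] + outer(cos(angles), r)
  oob <- ys < 1 | ys > ny | xs < 1 | xs > nx
  vals <- bilinear_sample(slice, pmin(pmax(ys, 1), ny), pmin(pmax(xs, 1), nx))
  structure(list(values = vals, oob = oob, r = r, angles = angles,
                 r_step = r_max_vox / n_radii, center = center),
            class = "nn_polar")
}

# vectorized bilinear interpolation; y, x same shape, already clamped
bilinear_sample <- function(mat, y, x) {
  ny <- nrow(mat); nx <- ncol(mat)
  y0 <- pmin(floor(y), ny - 1); x0 <- pmin(floor(x), nx - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v <- (1 - fy) * (1 - fx) * mat[i00] +
       (1 - fy) * fx       * mat[i00 + rep(c(0L, 1L), each = length(y))] +
       fy       * (1 - fx) * mat[i00 + rep(c(1L, 0L), each = length(y))] +
       fy       * fx       * mat[i00 + 1L]
  array(v, dim(y))
}

#' Radial boundary cost from a polar grid
#'
#' The radial derivative (central differences along each spoke, one-sided at
#' the ends). The inner boundary is the bright-axoplasm-to-dark-myelin
#' transition going outward, so its cost is `+dI/dr`; the outer boundary is
#' dark myelin to bright background, cost `-dI/dr`. Lower cost = stronger
#' edge of the right polarity. Out-of-bounds samples cost `+Inf`.
#'
#' @param polar a [polar_unwrap()] result.
#' @param boundary `"inner"` or `"outer"`.
#' @return cost matrix, `n_angles x n_radii`.
#' @export
boundary_cost <- function(polar, boundary = c("outer", "inner")) {
  boundary <- match.arg(boundary)
  v <- polar$values
  nr <- ncol(v)
  if (nr < 2L) stop("need at least 2 radial samples")
  d <- matrix(0, nrow(v), nr)
  d[, 2:(nr - 1)] <- (v[, 3:nr] - v[, 1:(nr - 2)]) / 2
  d[, 1] <- v[, 2] - v[, 1]
  d[, nr] <- v[, nr] - v[, nr - 1]
  cost <- if (boundary == "inner") d else -d
  cost[polar$oob] <- Inf
  cost
}

#' Globally optimal circular path through a cost grid
#'
#' Minimizes `sum_i cost[i, p_i] + lambda * sum_i (p_{i+1} - p_i)^2` over
#' radial index paths `p` subject to `|p_{i+1} - p_i| <= delta` for every
#' angular step including the wrap pair. Exact wrap closure is obtained by
#' running the dynamic programme once per candidate start radius and keeping
#' the best wrap-consistent solution; ties break toward the smaller total
#' radius, then the smaller start radius. Columns that are entirely `+Inf`
#' (fully out of bounds) make the path infeasible and yield `lost = TRUE`.
#'
#' @param cost `n_angles x n_radii` matrix; `+Inf` marks forbidden samples.
#' @param delta maximum index jump per angular step (>= 1).
#' @param lambda quadratic smoothness weight.
#' @return list with `path` (1-based radial indices, length `n_angles`),
#'   `objective`, and `lost`.
#' @export
dp_circular_path <- function(cost, delta = 1, lambda = 0) {
  stopifnot(is.matrix(cost), delta >= 1)
  res <- .dp_circular_cpp(cost, as.integer(delta), as.double(lambda))
  if (!res$lost) {
    p <- res$path
    jumps <- abs(diff(c(p, p[1])))
    stopifnot(all(jumps <= delta))     # contract: wrap-consistent path
  }
  res
}

# parabolic sub-sample refinement of a radial index path on its cost grid
refine_path_subvoxel <- function(cost, path) {
  nr <- ncol(cost)
  out <- as.numeric(path)
  for (i in seq_along(path)) {
    j <- path[i]
    if (j > 1 && j < nr) {
      c0 <- cost[i, j - 1]; c1 <- cost[i, j]; c2 <- cost[i, j + 1]
      den <- c0 - 2 * c1 + c2
      if (is.finite(den) && den > 0) {
        off <- 0.5 * (c0 - c2) / den
        out[i] <- j + max(-0.5, min(0.5, off))
      }
    }
  }
  out
}

#' Fit inner and outer myelin contours in one slice
#'
#' Unwraps the slice about `init_center` into polar coordinates (adaptive
#' radial extent `min(r_max_vox, window_hi * init_radius + 2)`), finds the
#' outer boundary by [dp_circular_path()] on the outer cost restricted to a
#' radial window around `init_radius`, then the inner boundary on the inner
#' cost restricted strictly below the outer path. The center is then moved
#' to the area centroid of the outer polygon and the fit repeated once
#' (two fixed passes). If the ring between the two paths is not darker than
#' the axoplasm core by `gap_contrast`, the slice is flagged as a myelin gap
#' and the inner path is placed touching the outer one.
#'
#' @param slice 2D numeric matrix (y, x).
#' @param init_center `(y, x)` starting center, voxels.
#' @param init_radius starting radius estimate (voxels); sets the search
#'   window.
#' @param params a [segmentation_params()].
#' @return list with `inner`, `outer` (each a `nn_contour`: `slice_z`,
#'   `center`, `radii` in voxels, `angles`), `mean_cost` (mean per-angle
#'   optimal outer cost), `gap`, `lost`.
#' @export
fit_contour <- function(slice, init_center, init_radius,
                        params = segmentation_params()) {
  center <- as.numeric(init_center)
  fit <- NULL
  for (pass in 1:2) {
    fit <- fit_contour_once(slice, center, init_radius, params)
    if (fit$lost) return(fit)
    center <- fit$outer$center
  }
  fit
}

fit_contour_once <- function(slice, center, init_radius, params) {
  r_max <- min(params$r_max_vox, params$window_hi * init_radius + 2)
  pol <- polar_unwrap(slice, center, r_max, params$n_angles, params$n_radii)
  lost_val <- list(inner = NULL, outer = NULL, mean_cost = Inf,
                   gap = FALSE, lost = TRUE)

  co <- boundary_cost(pol, "outer")
  win_lo <- params$window_lo * init_radius
  co[, pol$r < win_lo] <- Inf
  # lambda is specified per voxel^2; the DP works in radial-sample indices
  lam <- params$lambda * pol$r_step^2
  dpo <- dp_circular_path(co, params$delta, lam)
  if (dpo$lost) return(lost_val)
  p_out <- dpo$path
  mean_cost <- mean(co[cbind(seq_along(p_out), p_out)])

  ci <- boundary_cost(pol, "inner")
  for (i in seq_along(p_out)) ci[i, p_out[i]:ncol(ci)] <- Inf  # strictly below
  dpi <- dp_circular_path(ci, params$delta, lam)
  if (dpi$lost) return(lost_val)
  p_in <- dpi$path

  # myelin-presence check: the ring between the paths must be darker than
  # the axoplasm core; otherwise this is a node-gap slice
  band <- ring_mean(pol$values, p_in, p_out)
  core <- core_mean(pol$values, p_out)
  gap <- !is.na(band) && !is.na(core) && band >= core - params$gap_contrast
  if (gap) p_in <- pmax(p_out - 1L, 1L)

  r_out <- if (params$subvoxel) refine_path_subvoxel(co, p_out) else p_out
  r_in <- if (params$subvoxel && !gap) refine_path_subvoxel(ci, p_in) else p_in
  outer <- nn_contour(center, r_out * pol$r_step, pol$angles)
  inner <- nn_contour(center, r_in * pol$r_step, pol$angles)
  gap <- isTRUE(gap) ||
    mean(outer$radii - inner$radii) < params$gap_flag_vox
  outer$center <- polygon_centroid_yx(outer)
  list(inner = inner, outer = outer, mean_cost = mean_cost,
       gap = isTRUE(gap), lost = FALSE)
}

# mean polar intensity strictly between the inner and outer paths
ring_mean <- function(values, p_in, p_out) {
  tot <- 0; n <- 0L
  for (i in seq_along(p_out)) {
    if (p_out[i] - p_in[i] >= 2L) {
      j <- (p_in[i] + 1L):(p_out[i] - 1L)
      tot <- tot + sum(values[i, j]); n <- n + length(j)
    }
  }
  if (n == 0L) NA_real_ else tot / n
}

# mean polar intensity in the axoplasm core: the innermost 30% of the
# outer radius lies inside the axon for any anatomically plausible g-ratio,
# and stays defined even when the inner path collapses in a node gap
core_mean <- function(values, p_out) {
  tot <- 0; n <- 0L
  for (i in seq_along(p_out)) {
    jmax <- max(1L, floor(0.3 * p_out[i]))
    tot <- tot + sum(values[i, seq_len(jmax)]); n <- n + jmax
  }
  if (n == 0L) NA_real_ else tot / n
}

nn_contour <- function(center, radii_vox, angles, slice_z = NA_integer_) {
  structure(list(slice_z = slice_z, center = as.numeric(center),
                 radii = as.numeric(radii_vox), angles = angles),
            class = "nn_contour")
}

# area centroid (shoelace) of a contour polygon, voxel coordinates (y, x)
polygon_centroid_yx <- function(ct) {
  y <- ct$center[1] + ct$radii * sin(ct$angles)
  x <- ct$center[2] + ct$radii * cos(ct$angles)
  i <- seq_along(x); j <- c(i[-1], i[1])
  cr <- x[i] * y[j] - x[j] * y[i]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(y), mean(x)))
  cx <- sum((x[i] + x[j]) * cr) / (6 * a)
  cy <- sum((y[i] + y[j]) * cr) / (6 * a)
  c(cy, cx)
}

# shoelace area of a contour polygon in voxel^2 (absolute value)
polygon_area <- function(ct) {
  y <- ct$center[1] + ct$radii * sin(ct$angles)
  x <- ct$center[2] + ct$radii * cos(ct$angles)
  i <- seq_along(x); j <- c(i[-1], i[1])
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

#' Propagate a contour fit through the volume
#'
#' Fits the seed slice with [fit_contour()], then marches in +z and -z,
#' each next slice initialized from the previous slice's outer-polygon
#' centroid and mean outer radius (the fibre surface moves only slightly
#' between slices). A direction terminates when the mean outer cost exceeds
#' `cost_threshold` or the center jumps by more than `max_drift` voxels
#' (`"lost"`), when the contour would leave the slice laterally or the z
#' range ends (`"volume_edge"`), or after `max_slices` slices
#' (`"max_slices"`).
#'
#' @param vol an `nn_volume`.
#' @param seed_slice z index of the seed slice.
#' @param seed_center `(y, x)` seed center, voxels; the seed circle must
#'   enclose the target fibre.
#' @param seed_radius seed radius, voxels.
#' @param params a [segmentation_params()].
#' @param fibre_id id stored in the result.
#' @return an `nn_fibre_segmentation`: `fibre_id`, `slices` (z indices),
#'   `contours` (list of per-slice lists `inner`, `outer`, `mean_cost`,
#'   `gap`), `status` (`lower`, `upper`), `voxel_size_nm`, `origin_nm`.
#' @export
propagate <- function(vol, seed_slice, seed_center, seed_radius,
                      params = segmentation_params(), fibre_id = 1L) {
  stopifnot(inherits(vol, "nn_volume"))
  d <- dim(vol$data)
  seed_fit <- fit_contour(vol$data[seed_slice, , ], seed_center, seed_radius,
                          params)
  if (seed_fit$lost || seed_fit$mean_cost > params$cost_threshold)
    stop("no fibre at seed: the seed-slice fit lost the boundary")
  seed_fit$inner$slice_z <- seed_fit$outer$slice_z <- as.integer(seed_slice)

  march <- function(dir) {
    out <- list()
    status <- "volume_edge"
    prev <- seed_fit
    # remembered outer calibre from the last slice with a myelin ring: in a
    # node gap the outer path collapses onto the axon, and the search window
    # must still admit the (possibly swollen, paranodal) sheath after the gap
    ref_rad <- mean(seed_fit$outer$radii)
    z <- seed_slice + dir
    n <- 0L
    while (z >= 1L && z <= d[1]) {
      if (n >= params$max_slices) { status <- "max_slices"; break }
      ctr <- prev$outer$center
      rad <- if (isTRUE(prev$gap)) max(mean(prev$outer$radii), ref_rad)
             else mean(prev$outer$radii)
      if (ctr[1] - rad - 2 < 1 || ctr[1] + rad + 2 > d[2] ||
          ctr[2] - rad - 2 < 1 || ctr[2] + rad + 2 > d[3]) {
        status <- "volume_edge"; break
      }
      fit <- fit_contour(vol$data[z, , ], ctr, max(rad, 3), params)
      if (fit$lost || fit$mean_cost > params$cost_threshold) {
        status <- "lost"; break
      }
      drift <- sqrt(sum((fit$outer$center - ctr)^2))
      if (drift > params$max_drift) { status <- "lost"; break }
      fit$inner$slice_z <- fit$outer$slice_z <- as.integer(z)
      if (!isTRUE(fit$gap)) ref_rad <- mean(fit$outer$radii)
      n <- n + 1L
      out[[n]] <- fit
      prev <- fit
      z <- z + dir
    }
    list(fits = out, status = status)
  }

  dn <- march(-1L)
  up <- march(+1L)
  fits <- c(rev(dn$fits), list(seed_fit), up$fits)
  slices <- vapply(fits, function(f) f$outer$slice_z, integer(1))
  contours <- lapply(fits, function(f)
    list(inner = f$inner, outer = f$outer, mean_cost = f$mean_cost,
         gap = f$gap))
  structure(list(fibre_id = as.integer(fibre_id), slices = slices,
                 contours = contours,
                 status = c(lower = dn$status, upper = up$status),
                 voxel_size_nm = vol$voxel_size_nm,
                 origin_nm = vol$origin_nm),
            class = "nn_fibre_segmentation")
}

#' @export
print.nn_fibre_segmentation <- function(x, ...) {
  cat(sprintf(
    "<nn_fibre_segmentation> fibre %d: slices %d..%d (%d), ends: -z %s, +z %s\n",
    x$fibre_id, min(x$slices), max(x$slices), length(x$slices),
    x$status[["lower"]], x$status[["upper"]]))
  ng <- sum(vapply(x$contours, function(cp) isTRUE(cp$gap), logical(1)))
  if (ng) cat(sprintf("  %d slice(s) flagged as myelin gaps\n", ng))
  invisible(x)
}

#' Calibrate the lost-fibre cost threshold from pure noise
#'
#' Fits contours in slices containing only background plus additive Gaussian
#' noise and returns the requested lower quantile of the resulting mean
#' outer-path costs. With the default `prob = 0.05`, 95% of pure-noise fits
#' have a cost above the returned threshold and are therefore flagged as
#' lost, while true myelin edges score far below it.
#'
#' @param params a [segmentation_params()].
#' @param noise_sigma noise level (intensity units).
#' @param background background intensity.
#' @param n number of noise slices.
#' @param init_radius seed radius used for the noise fits, voxels.
#' @param prob quantile of the noise-cost distribution to return.
#' @param seed RNG seed.
#' @return the calibrated threshold (scalar).
#' @export
calibrate_cost_threshold <- function(params = segmentation_params(),
                                     noise_sigma = 0.05, background = 1,
                                     n = 100, init_radius = 15, prob = 0.05,
                                     seed = 42) {
  side <- as.integer(4 * init_radius + 16)
  costs <- with_seed(seed, {
    vapply(seq_len(n), function(k) {
      sl <- matrix(stats::rnorm(side * side, background, noise_sigma),
                   side, side)
      fit <- fit_contour(sl, c(side / 2, side / 2), init_radius, params)
      if (fit$lost) NA_real_ else fit$mean_cost
    }, numeric(1))
  })
  stats::quantile(costs, prob, na.rm = TRUE, names = FALSE)
}
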