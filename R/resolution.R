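#' Extract a 1D intensity profile along a straight probe line
#'
#' Trilinear interpolation of the volume at `n_samples` uniformly spaced
#' positions along a straight segment, used to sample the grey-value
#' transition across a material edge (typically myelin to background).
#'
#' @param vol an `nn_volume`.
#' @param start physical start point `(z, y, x)` in nm.
#' @param direction direction vector `(z, y, x)` (normalized internally).
#' @param length_nm probe length in nm.
#' @param n_samples number of samples (>= 8).
#' @return an `nn_edge_profile`: data frame `position_nm, value` with
#'   attributes `start`, `direction`.
#' @export
extract_edge_profile <- function(vol, start, direction, length_nm,
                                 n_samples = 20) {
  stopifnot(inherits(vol, "nn_volume"), n_samples >= 8, length_nm > 0)
  u <- direction / sqrt(sum(direction^2))
  t <- seq(0, length_nm, length.out = n_samples)
  pts <- cbind(start[1] + t * u[1], start[2] + t * u[2], start[3] + t * u[3])
  idx <- nm_to_voxel(vol, pts)
  d <- dim(vol$data)
  if (any(idx < 1) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3]))
    stop("probe segment exits the volume")
  vals <- trilinear_sample(vol$data, idx)
  structure(data.frame(position_nm = t, value = vals),
            start = start, direction = u, class = c("nn_edge_profile",
                                                    "data.frame"))
}

# trilinear interpolation at fractional (z, y, x) indices (n x 3), in-bounds
trilinear_sample <- function(arr, idx) {
  d <- dim(arr)
  z0 <- pmin(floor(idx[, 1]), d[1] - 1); fz <- idx[, 1] - z0
  y0 <- pmin(floor(idx[, 2]), d[2] - 1); fy <- idx[, 2] - y0
  x0 <- pmin(floor(idx[, 3]), d[3] - 1); fx <- idx[, 3] - x0
  z0 <- pmax(z0, 1); y0 <- pmax(y0, 1); x0 <- pmax(x0, 1)
  v <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
         (if (dx) fx else 1 - fx)
    v <- v + w * arr[cbind(z0 + dz, y0 + dy, x0 + dx)]
  }
  v
}

#' Fit a hyperbolic-tangent edge model to a profile
#'
#' Least-squares fit of `I(x) = a + b * tanh((x - x0) / w)` by
#' Levenberg-Marquardt. Initialization: `a` is the mean of the two
#' end-quartile means and `b` half their difference, `x0` the position of
#' the largest absolute finite difference, `w` twice the sample spacing.
#' Iterates to a relative parameter tolerance of 1e-8 or 200 iterations;
#' when the optimizer fails the best-so-far (or initial) values are
#' returned with `converged = FALSE`.
#'
#' @param profile an `nn_edge_profile` (or data frame with `position_nm`,
#'   `value`).
#' @return an `nn_edge_fit`: list `a, b, x0_nm, w_nm, fwhm_nm,
#'   rms_residual, converged, n`.
#' @export
fit_tanh_edge <- function(profile) {
  x <- profile$position_nm; v <- profile$value
  ok <- is.finite(x) & is.finite(v)
  if (sum(ok) < 4L) stop("fewer than 4 usable samples")
  x <- x[ok]; v <- v[ok]
  n <- length(x)
  q <- max(2L, floor(n / 4))
  m1 <- mean(v[seq_len(q)]); m2 <- mean(v[(n - q + 1L):n])
  sp <- mean(diff(x))
  start <- list(a = (m1 + m2) / 2, b = (m2 - m1) / 2,
                x0 = x[which.max(abs(diff(v)))], w = 2 * sp)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a + b * tanh((x - x0) / w), start = start,
                      lower = c(-Inf, -Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ptol = 1e-8, ftol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- start$a + start$b * tanh((x - start$x0) / start$w)
    return(structure(list(a = start$a, b = start$b, x0_nm = start$x0,
                          w_nm = start$w, fwhm_nm = fwhm_of_fit(start$w),
                          rms_residual = sqrt(mean((v - pred)^2)),
                          converged = FALSE, n = n),
                     class = "nn_edge_fit"))
  }
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 x0_nm = unname(cf["x0"]), w_nm = unname(cf["w"]),
                 fwhm_nm = fwhm_of_fit(unname(cf["w"])),
                 rms_residual = sqrt(mean(stats::resid(fit)^2)),
                 converged = conv, n = n),
            class = "nn_edge_fit")
}

#' @export
print.nn_edge_fit <- function(x, ...) {
  cat(sprintf(
    "<nn_edge_fit> a=%.4g b=%.4g x0=%.4g nm w=%.4g nm -> FWHM %.1f nm (%s, rms %.3g)\n",
    x$a, x$b, x$x0_nm, x$w_nm, x$fwhm_nm,
    if (x$converged) "converged" else "NOT converged", x$rms_residual))
  invisible(x)
}

#' FWHM of the derivative of the tanh edge model
#'
#' The derivative of `tanh((x - x0)/w)` is proportional to
#' `sech^2((x - x0)/w)`, which reaches half its maximum where
#' `cosh((x - x0)/w) = sqrt(2)`; the full width at half maximum is
#' therefore `2 * log(1 + sqrt(2)) * w ~= 1.762747 * w`. This is the
#' spatial-resolution estimate associated with a fitted edge width `w`.
#'
#' @param w edge width parameter (> 0), any length unit.
#' @return FWHM in the same unit.
#' @examples
#' fwhm_of_fit(130)   # 229.157... nm
#' @export
fwhm_of_fit <- function(w) {
  if (any(w <= 0)) stop("w must be positive")
  2 * log(1 + sqrt(2)) * w
}

#' Estimate spatial resolution from edge-spread fits
#'
#' Extracts a profile and fits the tanh edge model for every probe, rejects
#' fits that did not converge or whose RMS residual exceeds
#' `max_residual_frac * |b|`, and summarizes the per-probe FWHM values
#' (mean, sd, n). Probes are either given explicitly (`probes`: data frame
#' with columns `z, y, x, dz, dy, dx` in nm plus optional `length_nm`), or
#' drawn automatically: `n_probes` sites at seeded random slices and
#' angles of the supplied segmentations, probing radially across the outer
#' myelin/background boundary.
#'
#' @param vol an `nn_volume`.
#' @param probes explicit probe table (see above) or `NULL` for auto mode.
#' @param segmentations list of `nn_fibre_segmentation` (auto mode).
#' @param n_probes number of auto probes.
#' @param seed RNG seed for auto probe placement.
#' @param probe_len_vox probe length in voxels (centered on the edge).
#' @param n_samples samples per probe.
#' @param max_residual_frac quality gate on `rms_residual / |b|`.
#' @return an `nn_resolution`: list `fits`, `fwhm_nm` (per accepted probe),
#'   `mean_fwhm_nm`, `sd_fwhm_nm`, `n_used`, `n_total`.
#' @export
estimate_resolution <- function(vol, probes = NULL, segmentations = NULL,
                                n_probes = 12, seed = 1,
                                probe_len_vox = 20, n_samples = 20,
                                max_residual_frac = 0.15) {
  stopifnot(inherits(vol, "nn_volume"))
  vs <- vol$voxel_size_nm
  if (is.null(probes)) {
    if (is.null(segmentations)) stop("need `probes` or `segmentations`")
    probes <- with_seed(seed, auto_probes(vol, segmentations, n_probes,
                                          probe_len_vox))
  }
  if (is.null(probes$length_nm)) probes$length_nm <- probe_len_vox * vs
  fits <- lapply(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    prof <- extract_edge_profile(vol, c(p$z, p$y, p$x), c(p$dz, p$dy, p$dx),
                                 p$length_nm, n_samples)
    fit_tanh_edge(prof)
  })
  keep <- vapply(fits, function(f)
    f$converged && abs(f$b) > 0 &&
      f$rms_residual <= max_residual_frac * abs(f$b), logical(1))
  if (!any(keep)) stop("no probe yielded an accepted edge fit")
  fw <- vapply(fits[keep], function(f) f$fwhm_nm, numeric(1))
  structure(list(fits = fits, fwhm_nm = fw, mean_fwhm_nm = mean(fw),
                 sd_fwhm_nm = stats::sd(fw), n_used = sum(keep),
                 n_total = length(fits)),
            class = "nn_resolution")
}

# draw probes perpendicular to segmented outer contours
auto_probes <- function(vol, segmentations, n_probes, probe_len_vox) {
  vs <- vol$voxel_size_nm
  d <- dim(vol$data)
  rows <- list()
  tries <- 0L
  while (length(rows) < n_probes && tries < 50L * n_probes) {
    tries <- tries + 1L
    seg <- segmentations[[sample.int(length(segmentations), 1L)]]
    k <- sample.int(length(seg$contours), 1L)
    ct <- seg$contours[[k]]$outer
    if (isTRUE(seg$contours[[k]]$gap)) next
    i <- sample.int(length(ct$angles), 1L)
    u <- c(0, sin(ct$angles[i]), cos(ct$angles[i]))     # radial, in-plane
    edge_vox <- c(ct$slice_z, ct$center[1] + ct$radii[i] * sin(ct$angles[i]),
                  ct$center[2] + ct$radii[i] * cos(ct$angles[i]))
    start_vox <- edge_vox - c(0, u[2], u[3]) * probe_len_vox / 2
    end_vox <- edge_vox + c(0, u[2], u[3]) * probe_len_vox / 2
    if (any(start_vox < 1) || any(end_vox < 1) ||
        any(start_vox > d) || any(end_vox > d)) next
    start_nm <- voxel_to_nm(vol, start_vox)
    rows[[length(rows) + 1L]] <- data.frame(
      z = start_nm[1], y = start_nm[2], x = start_nm[3],
      dz = 0, dy = u[2], dx = u[3], length_nm = probe_len_vox * vs)
  }
  if (length(rows) < n_probes)
    nn_log("warn", "placed only ", length(rows), " of ", n_probes, " probes")
  do.call(rbind, rows)
}

#' @export
print.nn_resolution <- function(x, ...) {
  cat(sprintf(
    "<nn_resolution> FWHM %.1f +/- %.1f nm (%d of %d probes accepted)\n",
    x$mean_fwhm_nm, x$sd_fwhm_nm, x$n_used, x$n_total))
  invisible(x)
}
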