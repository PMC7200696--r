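#' Per-slice and summary morphometry of a segmented fibre
#'
#' For every segmented slice, contour polygon areas are computed with the
#' shoelace formula and converted to equivalent diameters (the diameter of
#' the circle with the same area); myelin thickness is the mean over angles
#' of (outer radius - inner radius); the g-ratio is the equivalent axon
#' diameter over the equivalent fibre diameter. Slices flagged as myelin
#' gaps (nodes of Ranvier) are reported but excluded from the summary means.
#'
#' @param seg an `nn_fibre_segmentation`.
#' @param voxel_size_nm voxel size; defaults to the one stored in `seg`.
#' @return an `nn_morphometry`: data frame with one row per slice
#'   (`fibre_id, slice_z, cy_nm, cx_nm, axon_diameter_nm,
#'   fibre_diameter_nm, myelin_thickness_nm, g_ratio, gap`) carrying a
#'   `summary` attribute (named list of means over non-gap slices).
#' @export
fibre_metrics <- function(seg, voxel_size_nm = seg$voxel_size_nm) {
  stopifnot(inherits(seg, "nn_fibre_segmentation"))
  if (length(seg$contours) == 0L) stop("empty segmentation")
  vs <- voxel_size_nm
  rows <- lapply(seg$contours, function(cp) {
    a_in <- polygon_area(cp$inner) * vs^2
    a_out <- polygon_area(cp$outer) * vs^2
    ctr <- polygon_centroid_yx(cp$outer)
    d_ax <- 2 * sqrt(a_in / pi)
    d_fb <- 2 * sqrt(a_out / pi)
    data.frame(fibre_id = seg$fibre_id, slice_z = cp$outer$slice_z,
               cy_nm = seg$origin_nm[2] + (ctr[1] - 1) * vs,
               cx_nm = seg$origin_nm[3] + (ctr[2] - 1) * vs,
               axon_diameter_nm = d_ax, fibre_diameter_nm = d_fb,
               myelin_thickness_nm = mean(cp$outer$radii - cp$inner$radii) * vs,
               g_ratio = d_ax / d_fb,
               gap = isTRUE(cp$gap))
  })
  tb <- do.call(rbind, rows)
  ok <- !tb$gap
  summ <- list(axon_diameter_nm = mean(tb$axon_diameter_nm[ok]),
               fibre_diameter_nm = mean(tb$fibre_diameter_nm[ok]),
               myelin_thickness_nm = mean(tb$myelin_thickness_nm[ok]),
               g_ratio = mean(tb$g_ratio[ok]),
               n_slices = nrow(tb), n_gap_slices = sum(tb$gap))
  structure(tb, summary = summ, class = c("nn_morphometry", class(tb)))
}

#' @export
print.nn_morphometry <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<nn_morphometry> fibre %d, %d slices (%d gap): axon %.0f nm, fibre %.0f nm, myelin %.0f nm, g-ratio %.3f\n",
    x$fibre_id[1], s$n_slices, s$n_gap_slices, s$axon_diameter_nm,
    s$fibre_diameter_nm, s$myelin_thickness_nm, s$g_ratio))
  invisible(x)
}

#' Centerline of a segmented fibre
#'
#' Per-slice outer-polygon area centroid in physical nm coordinates.
#'
#' @param seg an `nn_fibre_segmentation`.
#' @return an `nn_centerline` (matrix `z, y, x` in nm, attribute `slices`).
#' @export
centerline_of <- function(seg) {
  stopifnot(inherits(seg, "nn_fibre_segmentation"))
  if (length(seg$contours) == 0L) stop("empty segmentation")
  vs <- seg$voxel_size_nm
  pts <- t(vapply(seg$contours, function(cp) {
    ctr <- polygon_centroid_yx(cp$outer)
    c(seg$origin_nm[1] + (cp$outer$slice_z - 1) * vs,
      seg$origin_nm[2] + (ctr[1] - 1) * vs,
      seg$origin_nm[3] + (ctr[2] - 1) * vs)
  }, numeric(3)))
  colnames(pts) <- c("z", "y", "x")
  structure(pts, slices = seg$slices,
            class = c("nn_centerline", class(pts)))
}

#' Winding of one centerline about another
#'
#' On the shared z grid, form the in-plane vector from curve `a` to curve
#' `b`, track its polar angle along z (increments unwrapped to (-pi, pi\])
#' and report the accumulated rotation in full turns. Two fibres of a
#' regenerative cluster that twist about each other accumulate turns;
#' parallel fibres stay near zero. Antisymmetric under z reversal,
#' symmetric under swapping `a` and `b`, invariant under global in-plane
#' rotation.
#'
#' @param a,b `nn_centerline` matrices (columns `z, y, x`, nm).
#' @return list with `winding_turns` and `shared_slices`.
#' @export
pairwise_winding <- function(a, b) {
  za <- round(a[, "z"], 6); zb <- round(b[, "z"], 6)
  zz <- intersect(za, zb)
  if (length(zz) < 2L) stop("shared z-range must cover at least 2 slices")
  ia <- match(zz, za); ib <- match(zz, zb)
  vy <- b[ib, "y"] - a[ia, "y"]
  vx <- b[ib, "x"] - a[ia, "x"]
  nrm <- sqrt(vy^2 + vx^2)
  if (any(nrm == 0))
    stop("coincident centerline points at slice index ", which(nrm == 0)[1],
         ": winding angle undefined")
  phi <- atan2(vy, vx)
  d <- diff(phi)
  d <- ((d + pi) %% (2 * pi)) - pi       # wrap to [-pi, pi)
  d[d == -pi] <- pi                      # half-open (-pi, pi]
  list(winding_turns = sum(d) / (2 * pi), shared_slices = length(zz))
}

#' Pairwise intertwining classification of a set of centerlines
#'
#' Evaluates [pairwise_winding()] for every pair and flags a pair as
#' intertwined when `|winding_turns| >= threshold_turns`. The summary mean
#' of `|winding|` characterizes the cluster as a whole: regenerative
#' clusters score high, separate clusters or parallel fibres near zero.
#'
#' @param centerlines named or unnamed list of `nn_centerline` objects.
#' @param threshold_turns intertwining flag threshold, in full turns.
#' @return an `nn_cluster_winding`: data frame (`fibre_a, fibre_b,
#'   winding_turns, shared_slices, intertwined`) with attribute
#'   `mean_abs_winding`.
#' @export
classify_cluster <- function(centerlines, threshold_turns = 0.5) {
  n <- length(centerlines)
  if (n < 2L) stop("need at least 2 centerlines")
  ids <- names(centerlines) %||% as.character(seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- pairwise_winding(centerlines[[i]], centerlines[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      fibre_a = ids[i], fibre_b = ids[j],
      winding_turns = w$winding_turns, shared_slices = w$shared_slices,
      intertwined = abs(w$winding_turns) >= threshold_turns)
  }
  tb <- do.call(rbind, rows)
  structure(tb, mean_abs_winding = mean(abs(tb$winding_turns)),
            threshold_turns = threshold_turns,
            class = c("nn_cluster_winding", class(tb)))
}

#' @export
print.nn_cluster_winding <- function(x, ...) {
  cat(sprintf(
    "<nn_cluster_winding> %d pairs, mean |winding| %.3f turns, %d intertwined (threshold %.2f)\n",
    nrow(x), attr(x, "mean_abs_winding"), sum(x$intertwined),
    attr(x, "threshold_turns")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Detect myelin gaps (candidate nodes of Ranvier) along a fibre
#'
#' Maximal runs of at least `min_gap_slices` consecutive slices whose mean
#' myelin thickness falls below `thin_threshold_nm` (slices flagged as gaps
#' by the segmentation count as zero thickness). Intervals are half-open:
#' `[z_start, z_end)`.
#'
#' @param seg an `nn_fibre_segmentation`.
#' @param min_gap_slices minimum run length, slices.
#' @param thin_threshold_nm thickness threshold, nm; defaults to 2 voxels.
#' @return data frame `z_start, z_end, n_slices` (zero rows if no gaps).
#' @export
detect_myelin_gaps <- function(seg, min_gap_slices = 3,
                               thin_threshold_nm = 2 * seg$voxel_size_nm) {
  stopifnot(inherits(seg, "nn_fibre_segmentation"))
  vs <- seg$voxel_size_nm
  thin <- vapply(seg$contours, function(cp) {
    if (isTRUE(cp$gap)) return(TRUE)
    mean(cp$outer$radii - cp$inner$radii) * vs < thin_threshold_nm
  }, logical(1))
  r <- rle(thin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_gap_slices
  data.frame(z_start = seg$slices[starts[keep]],
             z_end = seg$slices[ends[keep]] + 1L,
             n_slices = r$lengths[keep])
}

#' Fibre density in a rectangular region of interest
#'
#' Counts the fibres whose centerline point at `slice_z` lies inside the
#' ROI and divides by the ROI area in mm^2. An optional minimum equivalent
#' fibre diameter restricts the count to large fibres.
#'
#' @param records list of `nn_morphometry` tables (one per fibre), each
#'   carrying per-slice centroids.
#' @param roi `c(y_min, y_max, x_min, x_max)` in nm.
#' @param slice_z slice at which positions are evaluated.
#' @param min_diameter_nm optional diameter filter (e.g. 6000 to count
#'   large fibres only; uses each fibre's summary fibre diameter).
#' @return list with `count` and `density_per_mm2`.
#' @export
fibre_density <- function(records, roi, slice_z, min_diameter_nm = NULL) {
  stopifnot(length(roi) == 4L)
  area_mm2 <- (roi[2] - roi[1]) * (roi[4] - roi[3]) / 1e12
  if (area_mm2 <= 0) stop("ROI has zero or negative area")
  inside <- vapply(records, function(r) {
    if (!is.null(min_diameter_nm) &&
        attr(r, "summary")$fibre_diameter_nm < min_diameter_nm) return(FALSE)
    k <- which(r$slice_z == slice_z)
    if (length(k) != 1L) return(FALSE)
    r$cy_nm[k] >= roi[1] && r$cy_nm[k] <= roi[2] &&
      r$cx_nm[k] >= roi[3] && r$cx_nm[k] <= roi[4]
  }, logical(1))
  list(count = sum(inside), density_per_mm2 = sum(inside) / area_mm2)
}
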