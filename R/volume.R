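#' 3D greyscale volume
#'
#' The universal container for reconstructed tomography data in nervenano.
#' Voxels are isotropic; the array is indexed `data[z, y, x]` with `z` the
#' fibre axis (nerve fibres run roughly along `z` in the reconstructed
#' volumes this package targets). Indices are 1-based; the physical position
#' of the center of voxel `(1, 1, 1)` is `origin_nm`, and voxel `(i, j, k)`
#' sits at `origin_nm + (c(i, j, k) - 1) * voxel_size_nm`.
#'
#' @param data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_nm positive scalar, isotropic voxel edge length in nm.
#' @param origin_nm length-3 numeric `(z, y, x)` physical coordinate (nm) of
#'   the center of voxel `(1, 1, 1)`. Default `c(0, 0, 0)`.
#' @return An object of class `nn_volume`: a list with elements `data`,
#'   `voxel_size_nm`, `origin_nm`.
#' @examples
#' v <- volume(array(0, c(4, 5, 6)), voxel_size_nm = 130)
#' dim(v$data)
#' @export
volume <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a positive scalar")
  if (length(origin_nm) != 3L || !is.numeric(origin_nm))
    stop("`origin_nm` must be a length-3 numeric (z, y, x)")
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
         origin_nm = as.numeric(origin_nm)),
    class = "nn_volume")
}

#' @export
print.nn_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nn_volume> %d x %d x %d voxels (z, y, x), %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  cat(sprintf("  extent: %.2f x %.2f x %.2f um, intensity range [%.4g, %.4g]\n",
              d[1] * x$voxel_size_nm / 1e3, d[2] * x$voxel_size_nm / 1e3,
              d[3] * x$voxel_size_nm / 1e3,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxel_to_nm()` maps (possibly fractional) 1-based voxel indices to
#' physical nm positions; `nm_to_voxel()` is its exact inverse. Both accept a
#' matrix with columns `(z, y, x)` or a single length-3 vector.
#'
#' @param vol an `nn_volume`.
#' @param idx,pos matrix (n x 3) or length-3 vector, `(z, y, x)` order.
#' @return matrix (or vector) of the same shape in the other coordinate
#'   system.
#' @export
voxel_to_nm <- function(vol, idx) {
  v <- as_zyx_matrix(idx)
  out <- sweep((v - 1) * vol$voxel_size_nm, 2, vol$origin_nm, "+")
  if (is.null(dim(idx))) drop(out) else out
}

#' @rdname voxel_to_nm
#' @export
nm_to_voxel <- function(vol, pos) {
  v <- as_zyx_matrix(pos)
  out <- sweep(v, 2, vol$origin_nm, "-") / vol$voxel_size_nm + 1
  if (is.null(dim(pos))) drop(out) else out
}

as_zyx_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("expected a length-3 (z, y, x) vector")
    matrix(as.numeric(x), 1L, 3L)
  } else {
    if (ncol(x) != 3L) stop("expected an n x 3 (z, y, x) matrix")
    matrix(as.numeric(x), nrow(x), 3L)
  }
}

#' Acquisition metadata
#'
#' Describes a tomographic acquisition: number of projections, angular range,
#' exposure, effective pixel size and reconstructed grid side. Defaults match
#' a typical holographic nanotomography scan of a nerve biopsy: 1500
#' projections over 180 degrees, 0.5 s exposure, 130 nm effective pixel size,
#' 2048 voxels per dimension.
#'
#' @param n_projections number of projections recorded (>= 1).
#' @param angular_range_deg total angular range in degrees (> 0).
#' @param exposure_s exposure time per projection, seconds.
#' @param pixel_size_nm effective (reconstructed) pixel size, nm.
#' @param grid_side reconstructed voxels per dimension.
#' @return An object of class `nn_acquisition`.
#' @examples
#' m <- acquisition_meta()
#' derived_angle_step_deg(m)  # 0.12
#' @export
acquisition_meta <- function(n_projections = 1500, angular_range_deg = 180,
                             exposure_s = 0.5, pixel_size_nm = 130,
                             grid_side = 2048) {
  stopifnot(n_projections >= 1, angular_range_deg > 0,
            pixel_size_nm > 0, grid_side >= 1)
  structure(list(n_projections = n_projections,
                 angular_range_deg = angular_range_deg,
                 exposure_s = exposure_s,
                 pixel_size_nm = pixel_size_nm,
                 grid_side = grid_side),
            class = "nn_acquisition")
}

#' @export
print.nn_acquisition <- function(x, ...) {
  fov <- derived_fov_um(x)
  cat(sprintf(
    "<nn_acquisition> %d projections / %g deg (%.4g deg/frame), %g s exposure\n",
    x$n_projections, x$angular_range_deg, derived_angle_step_deg(x),
    x$exposure_s))
  cat(sprintf("  grid %d^3 at %g nm -> field of view %.2f um (~%d um)\n",
              x$grid_side, x$pixel_size_nm, fov$fov_um, fov$fov_um_display))
  invisible(x)
}

#' Field of view implied by acquisition metadata
#'
#' Side length of the reconstructed cube: `grid_side * pixel_size_nm / 1000`
#' micrometres, computed in exact arithmetic on the two inputs. Also returns
#' the nearest-integer value used for display (a 2048-voxel grid at 130 nm
#' covers 266.24 um, quoted as a 266 um field of view).
#'
#' @param meta an `nn_acquisition`.
#' @return list with `fov_um` (exact) and `fov_um_display` (rounded to the
#'   nearest integer).
#' @examples
#' derived_fov_um(acquisition_meta(grid_side = 2048, pixel_size_nm = 130))
#' @export
derived_fov_um <- function(meta) {
  stopifnot(inherits(meta, "nn_acquisition"))
  fov <- meta$grid_side * meta$pixel_size_nm / 1000
  list(fov_um = fov, fov_um_display = as.integer(round(fov)))
}

#' Angular step between projections
#'
#' `angular_range_deg / n_projections`, in degrees per frame (180 degrees
#' over 1500 projections gives 0.12 degrees/frame).
#'
#' @param meta an `nn_acquisition`.
#' @return scalar, degrees per projection.
#' @export
derived_angle_step_deg <- function(meta) {
  stopifnot(inherits(meta, "nn_acquisition"))
  meta$angular_range_deg / meta$n_projections
}
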