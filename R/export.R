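#' Export fibre contours as CSV
#'
#' One row per sampled boundary point: `fibre_id, slice_z, boundary, angle_index,
#' x_nm, y_nm`. Points are the polygon vertices of each per-slice closed
#' curve, in physical nm coordinates. `read_contours()` reads the table back.
#'
#' @param seg an `nn_fibre_segmentation` (see [propagate()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_contours <- function(seg, path) {
  stopifnot(inherits(seg, "nn_fibre_segmentation"))
  if (length(seg$contours) == 0L) stop("empty segmentation")
  rows <- lapply(seg$contours, function(cp) {
    do.call(rbind, lapply(c("inner", "outer"), function(b) {
      ct <- cp[[b]]
      p <- contour_points_nm(ct, seg$voxel_size_nm, seg$origin_nm)
      data.frame(fibre_id = seg$fibre_id, slice_z = ct$slice_z, boundary = b,
                 angle_index = seq_along(ct$radii),
                 x_nm = p[, "x"], y_nm = p[, "y"])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_contours
#' @export
read_contours <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# polygon vertices of a contour in nm; columns x, y
contour_points_nm <- function(ct, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  y <- ct$center[1] + ct$radii * sin(ct$angles)
  x <- ct$center[2] + ct$radii * cos(ct$angles)
  cbind(x = origin_nm[3] + (x - 1) * voxel_size_nm,
        y = origin_nm[2] + (y - 1) * voxel_size_nm)
}

#' Export a fibre segmentation as a PLY surface mesh
#'
#' Triangulates consecutive contour rings into a tube: each boundary
#' contributes `n_slices * n_angles` vertices and
#' `(n_slices - 1) * n_angles * 2` triangles (no end caps). Written as ASCII
#' PLY with vertex coordinates in nm, the standard route to 3D renderings of
#' segmented fibres.
#'
#' @param seg an `nn_fibre_segmentation`.
#' @param path output `.ply` path.
#' @param boundary which surface(s) to export: `"outer"`, `"inner"` or
#'   `"both"` (two disjoint shells in one file).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(seg, path, boundary = c("both", "outer", "inner")) {
  stopifnot(inherits(seg, "nn_fibre_segmentation"))
  boundary <- match.arg(boundary)
  if (length(seg$contours) == 0L) stop("empty segmentation")
  bnds <- if (boundary == "both") c("inner", "outer") else boundary
  verts <- NULL
  faces <- NULL
  for (b in bnds) {
    offset <- if (is.null(verts)) 0L else nrow(verts)
    rings <- lapply(seg$contours, function(cp) {
      ct <- cp[[b]]
      p <- contour_points_nm(ct, seg$voxel_size_nm, seg$origin_nm)
      z <- seg$origin_nm[1] + (ct$slice_z - 1) * seg$voxel_size_nm
      cbind(p[, "x"], p[, "y"], z)
    })
    na <- nrow(rings[[1]])
    ns <- length(rings)
    verts <- rbind(verts, do.call(rbind, rings))
    if (ns >= 2L) {
      for (s in seq_len(ns - 1L)) {
        j <- seq_len(na)
        jn <- c(j[-1L], j[1L])                      # wrapped next angle
        a <- offset + (s - 1L) * na + j - 1L         # PLY is 0-based
        bq <- offset + (s - 1L) * na + jn - 1L
        cq <- offset + s * na + j - 1L
        dq <- offset + s * na + jn - 1L
        faces <- rbind(faces, cbind(a, cq, bq), cbind(bq, cq, dq))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", if (is.null(faces)) 0L else nrow(faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", verts[, 1], verts[, 2], verts[, 3]), con)
  if (!is.null(faces))
    writeLines(sprintf("3 %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}
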