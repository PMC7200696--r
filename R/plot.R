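#' Display one x-y slice of a volume
#'
#' @param x an `nn_volume`.
#' @param z slice index.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.nn_volume <- function(x, z = ceiling(dim(x$data)[1] / 2), ...) {
  sl <- x$data[z, , ]
  graphics::image(t(sl)[, rev(seq_len(nrow(sl)))],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, main = sprintf("slice z = %d", z), ...)
  invisible(x)
}

#' Overlay segmented contours on a volume slice
#'
#' @param x an `nn_fibre_segmentation`.
#' @param vol the `nn_volume` it was traced in.
#' @param z slice index (defaults to the middle segmented slice).
#' @param ... passed to [plot.nn_volume()].
#' @return invisibly, `x`.
#' @export
plot.nn_fibre_segmentation <- function(x, vol, z = NULL, ...) {
  if (is.null(z)) z <- x$slices[ceiling(length(x$slices) / 2)]
  k <- which(x$slices == z)
  if (length(k) != 1L) stop("slice ", z, " is not part of this segmentation")
  plot.nn_volume(vol, z, ...)
  d <- dim(vol$data)
  for (b in c("inner", "outer")) {
    ct <- x$contours[[k]][[b]]
    py <- ct$center[1] + ct$radii * sin(ct$angles)
    px <- ct$center[2] + ct$radii * cos(ct$angles)
    # image() maps the slice onto [0,1] x [0,1] with y flipped
    graphics::lines(c(px - 1, px[1] - 1) / (d[3] - 1),
                    1 - c(py - 1, py[1] - 1) / (d[2] - 1),
                    col = if (b == "outer") "red" else "cyan", lwd = 2)
  }
  invisible(x)
}

#' Plot an edge profile with its fitted tanh model
#'
#' @param x an `nn_edge_profile`.
#' @param fit optional `nn_edge_fit` to overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.nn_edge_profile <- function(x, fit = NULL, ...) {
  graphics::plot(x$position_nm, x$value, xlab = "position (nm)",
                 ylab = "intensity (a.u.)", pch = 19, ...)
  if (!is.null(fit)) {
    xx <- seq(min(x$position_nm), max(x$position_nm), length.out = 200)
    graphics::lines(xx, fit$a + fit$b * tanh((xx - fit$x0_nm) / fit$w_nm),
                    col = "red")
    graphics::mtext(sprintf("FWHM = %.0f nm", fit$fwhm_nm), side = 3,
                    line = -1.5, adj = 0.98, col = "red")
  }
  invisible(x)
}
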