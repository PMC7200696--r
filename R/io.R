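#' Read a volume from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`tiff_stack`}{a single multi-page TIFF, one x-y page per z slice.
#'     Voxel size is read from the sidecar if present (see
#'     [write_volume()]), otherwise it defaults to 130 nm with a warning.}
#'   \item{`raw`}{headerless binary in z-major order plus a YAML sidecar
#'     (`<path>.yml`) recording shape, dtype, endianness, voxel size and
#'     origin; this is the bitwise-lossless interchange format.}
#' }
#' HDF5 input is not provided in this build; use `raw` for lossless exchange.
#'
#' @param path file path.
#' @param format one of `"tiff_stack"`, `"raw"`. Guessed from the extension
#'   when missing (`.tif`/`.tiff` vs anything else).
#' @param voxel_size_nm override/fallback voxel size in nm. For `raw` the
#'   sidecar value wins; for TIFF stacks lacking a sidecar this value is used
#'   (default 130, with a warning if it was not given explicitly).
#' @return an [volume()] (`nn_volume`).
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "raw"),
                        voxel_size_nm = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "raw"
  if (format == "raw") {
    side <- sidecar_path(path)
    if (!file.exists(path)) stop("file not found: ", path)
    if (!file.exists(side)) stop("raw volume requires a sidecar: ", side)
    meta <- yaml::read_yaml(side)
    shape <- as.integer(meta$shape)
    if (length(shape) != 3L) stop("sidecar `shape` must have 3 entries")
    dtype <- meta$dtype %||% "float64"
    size <- switch(dtype, float32 = 4L, float64 = 8L,
                   stop("unsupported dtype in sidecar: ", dtype))
    n <- prod(shape)
    endian <- meta$endianness %||% "little"
    x <- readBin(path, what = "double", n = n, size = size, endian = endian)
    if (length(x) != n)
      stop(sprintf("raw payload has %d values but sidecar declares %d",
                   length(x), n))
    # payload is x-fastest (x, then y, then z); R arrays are first-index
    # fastest, so build as (nx, ny, nz) and permute to (nz, ny, nx)
    arr <- aperm(array(x, dim = rev(shape)), c(3, 2, 1))
    vs <- meta$voxel_size_nm %||% voxel_size_nm
    if (is.null(vs)) stop("sidecar lacks voxel_size_nm and none was supplied")
    org <- as.numeric(meta$origin_nm %||% c(0, 0, 0))
    volume(arr, voxel_size_nm = vs, origin_nm = org)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    side <- sidecar_path(path)
    vs <- NULL; org <- c(0, 0, 0)
    if (file.exists(side)) {
      meta <- yaml::read_yaml(side)
      vs <- meta$voxel_size_nm
      org <- as.numeric(meta$origin_nm %||% c(0, 0, 0))
    }
    if (is.null(vs)) vs <- voxel_size_nm
    if (is.null(vs)) {
      vs <- 130
      warning("no voxel size in metadata; defaulting to 130 nm")
    }
    volume(arr, voxel_size_nm = vs, origin_nm = org)
  }
}

#' Write a volume to disk
#'
#' `raw` writes a little-endian float64 payload (x fastest, z slowest) plus a
#' YAML sidecar `<path>.yml` with shape, dtype, endianness, voxel size and
#' origin; the round trip is bitwise exact. `tiff_stack` writes one 32-bit
#' page per z slice together with the same sidecar; the TIFF backend stores
#' 32-bit samples as scaled integers on \[0, 1\], so intensities must lie in
#' that range (values are preserved to ~2^-32) — use `raw` for arbitrary or
#' exact payloads.
#'
#' @param vol an `nn_volume`.
#' @param path output path; the sidecar is written next to it.
#' @param format `"raw"` or `"tiff_stack"` (`"auto"` guesses from extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff_stack", "raw")) {
  stopifnot(inherits(vol, "nn_volume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "raw"
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  d <- dim(vol$data)
  meta <- list(shape = as.integer(d), dtype = "float64",
               endianness = "little",
               voxel_size_nm = vol$voxel_size_nm,
               origin_nm = vol$origin_nm)
  if (format == "raw") {
    # (nz, ny, nx) array -> x-fastest stream
    writeBin(as.vector(aperm(vol$data, c(3, 2, 1))), path,
             size = 8L, endian = "little")
    yaml::write_yaml(meta, sidecar_path(path))
  } else {
    rng <- range(vol$data)
    if (rng[1] < 0 || rng[2] > 1)
      stop("tiff_stack requires intensities in [0, 1]; ",
           "use format = \"raw\" for lossless storage of this volume")
    pages <- lapply(seq_len(d[1]), function(z) vol$data[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    meta$dtype <- "uint32_scaled"
    yaml::write_yaml(meta, sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yml")

`%||%` <- function(a, b) if (is.null(a)) b else a
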