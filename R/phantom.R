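#' Phantom configuration
#'
#' Parameters of the synthetic nerve-volume generator. The defaults emulate a
#' desk-scale crop of an osmium-stained peripheral-nerve nanotomography
#' reconstruction: dark myelin annuli around brighter axoplasm on a bright
#' background, ten large wavy parallel fibres, two regenerative clusters of
#' thin helically intertwined fibres, one low-contrast vessel, detector/optics
#' blur and additive Gaussian noise.
#'
#' Intensity ordering is constrained to myelin < axon < background, the
#' contrast situation the segmentation exploits (myelin appears dark).
#'
#' @param shape integer `(nz, ny, nx)` grid size in voxels.
#' @param voxel_size_nm isotropic voxel size, nm.
#' @param intensities named list `background`, `axon`, `myelin`, `vessel`
#'   (arbitrary units; must satisfy myelin < axon < background).
#' @param n_large_fibres number of large wavy fibres.
#' @param large_r_outer_nm length-2 range for large-fibre outer radius, nm.
#' @param large_g_ratio length-2 range for the axon/fibre diameter ratio used
#'   to draw inner radii.
#' @param waveform list `amplitude_nm`, `period_nm` of the sinusoidal
#'   in-plane waveform of large fibres.
#' @param cluster list `n_clusters`, `fibres_per_cluster`, `helix_radius_nm`,
#'   `turns`, `r_outer_nm` (range), `g_ratio` (range), `gap_nm` (minimum
#'   clearance between cluster envelopes).
#' @param vessel list `enabled`, `radius_nm`.
#' @param features character vector of optional anatomy on/next to large
#'   fibre 1: any of `"node_of_ranvier"`, `"bulb_dead_end"`, `"sprout"`,
#'   `"incisure"`. A bulb or sprout implies the node.
#' @param node_gap_slices length of the node myelin gap, in slices.
#' @param psf_sigma_vox Gaussian blur sigma (voxels) applied by [degrade()].
#' @param noise_sigma additive Gaussian noise sigma (intensity units).
#' @param supersampling anti-aliasing factor (1, 2 or 3 subsamples per axis).
#' @param max_tries placement attempts per object before giving up.
#' @param seed RNG seed for fibre placement and noise.
#' @return a `nn_phantom_config` list.
#' @export
phantom_config <- function(shape = c(128, 256, 256),
                           voxel_size_nm = 130,
                           intensities = list(background = 1.0, axon = 0.55,
                                              myelin = 0.15, vessel = 0.8),
                           n_large_fibres = 10,
                           large_r_outer_nm = c(1600, 2600),
                           large_g_ratio = c(0.55, 0.70),
                           waveform = list(amplitude_nm = 600,
                                           period_nm = 33000),
                           cluster = list(n_clusters = 2,
                                          fibres_per_cluster = 3,
                                          helix_radius_nm = 1800,
                                          turns = 2,
                                          r_outer_nm = c(900, 1200),
                                          g_ratio = c(0.60, 0.70),
                                          gap_nm = 2000),
                           vessel = list(enabled = TRUE, radius_nm = 2500),
                           features = character(0),
                           node_gap_slices = 8,
                           psf_sigma_vox = 0.8,
                           noise_sigma = 0.05,
                           supersampling = 2,
                           max_tries = 5000,
                           seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1), voxel_size_nm > 0,
            supersampling %in% 1:3, psf_sigma_vox >= 0, noise_sigma >= 0)
  with(intensities, stopifnot(myelin < axon, axon < background))
  if (length(features) &&
      any(features %in% c("bulb_dead_end", "sprout")) &&
      !("node_of_ranvier" %in% features))
    features <- c("node_of_ranvier", features)
  structure(list(shape = as.integer(shape), voxel_size_nm = voxel_size_nm,
                 intensities = intensities, n_large_fibres = n_large_fibres,
                 large_r_outer_nm = large_r_outer_nm,
                 large_g_ratio = large_g_ratio, waveform = waveform,
                 cluster = cluster, vessel = vessel, features = features,
                 node_gap_slices = node_gap_slices,
                 psf_sigma_vox = psf_sigma_vox, noise_sigma = noise_sigma,
                 supersampling = as.integer(supersampling),
                 max_tries = max_tries, seed = seed),
            class = "nn_phantom_config")
}

# label codes shared by phantom truth and downstream code
#' Label codes used in phantom truth label volumes
#' @format integer vector: background 0, axon 1, myelin 2, vessel 3.
#' @export
phantom_labels <- c(background = 0L, axon = 1L, myelin = 2L, vessel = 3L)

#' Generate a fibre centerline
#'
#' One sample per z slice, in physical nm coordinates (z along the fibre
#' axis). Kinds:
#' \describe{
#'   \item{straight}{constant in-plane position `center_nm`.}
#'   \item{sinusoid}{in-plane offset `amplitude_nm * sin(2*pi*z/period_nm +
#'     phase)` along the unit in-plane `direction`, about `center_nm` — the
#'     waveform of normal large myelinated fibres.}
#'   \item{helix}{the point rotates about the in-plane axis point `center_nm`
#'     by `2*pi*turns` across the whole z range at constant `radius_nm` — the
#'     twisted geometry of regenerative-cluster fibres.}
#' }
#'
#' @param kind `"straight"`, `"sinusoid"` or `"helix"`.
#' @param z_range integer slice indices (first and last, inclusive) or a
#'   vector of slices.
#' @param voxel_size_nm voxel size (sets the z spacing).
#' @param center_nm in-plane `(y, x)` anchor in nm.
#' @param amplitude_nm,period_nm,phase sinusoid parameters.
#' @param direction in-plane `(y, x)` direction of the sinusoidal offset
#'   (normalized internally).
#' @param radius_nm,turns helix parameters.
#' @return an `nn_centerline`: matrix with columns `z, y, x` (nm), one row
#'   per slice, strictly increasing z; attribute `slices` gives the slice
#'   indices.
#' @export
make_centerline <- function(kind = c("straight", "sinusoid", "helix"),
                            z_range, voxel_size_nm, center_nm,
                            amplitude_nm = NULL, period_nm = NULL, phase = 0,
                            direction = c(1, 0),
                            radius_nm = NULL, turns = NULL) {
  kind <- match.arg(kind)
  slices <- if (length(z_range) == 2L) seq(z_range[1], z_range[2]) else
    as.integer(z_range)
  if (length(slices) < 1L) stop("z_range is empty")
  if (length(center_nm) != 2L) stop("center_nm must be (y, x)")
  z <- (slices - 1) * voxel_size_nm
  yx <- switch(kind,
    straight = cbind(rep(center_nm[1], length(z)), rep(center_nm[2], length(z))),
    sinusoid = {
      if (is.null(amplitude_nm) || is.null(period_nm))
        stop("sinusoid requires amplitude_nm and period_nm")
      u <- direction / sqrt(sum(direction^2))
      off <- amplitude_nm * sin(2 * pi * z / period_nm + phase)
      cbind(center_nm[1] + off * u[1], center_nm[2] + off * u[2])
    },
    helix = {
      if (is.null(radius_nm) || is.null(turns))
        stop("helix requires radius_nm and turns")
      span <- max(z) - min(z)
      t <- if (span > 0) (z - min(z)) / span else rep(0, length(z))
      ang <- phase + 2 * pi * turns * t
      cbind(center_nm[1] + radius_nm * sin(ang),
            center_nm[2] + radius_nm * cos(ang))
    })
  out <- cbind(z = z, y = yx[, 1], x = yx[, 2])
  structure(out, slices = slices, class = c("nn_centerline", class(out)))
}

#' Fibre specification (phantom ground truth for one fibre)
#'
#' @param centerline an `nn_centerline`.
#' @param r_axon_nm,r_outer_nm inner (axon) and outer (myelin) radii in nm;
#'   scalars or per-slice vectors. Must satisfy `0 < r_axon < r_outer`.
#' @param features list of feature annotations, each a list with `kind` (one
#'   of `"node_of_ranvier"`, `"incisure_thinning"`, `"bulb_dead_end"`),
#'   `z_start`, `z_end` (half-open slice interval `[z_start, z_end)`) and
#'   optional parameters. A `bulb_dead_end` terminates the fibre at `z_end`.
#' @param id integer fibre id.
#' @param type `"fibre"` or `"vessel"` (a vessel renders as a solid
#'   low-contrast tube and takes part in no morphometry).
#' @return an `nn_fibre_spec`.
#' @export
fibre_spec <- function(centerline, r_axon_nm, r_outer_nm,
                       features = list(), id = 1L, type = c("fibre", "vessel")) {
  type <- match.arg(type)
  n <- nrow(centerline)
  r_ax <- rep_len(r_axon_nm, n)
  r_out <- rep_len(r_outer_nm, n)
  if (type == "fibre" && any(r_ax <= 0 | r_out <= r_ax))
    stop("radii must satisfy 0 < r_axon < r_outer")
  # a bulb_dead_end terminates the fibre: drop samples at/after z_end
  for (f in features) {
    if (identical(f$kind, "bulb_dead_end")) {
      keep <- attr(centerline, "slices") < f$z_end
      centerline <- structure(centerline[keep, , drop = FALSE],
                              slices = attr(centerline, "slices")[keep],
                              class = class(centerline))
      r_ax <- r_ax[keep]; r_out <- r_out[keep]
    }
  }
  structure(list(centerline = centerline, r_axon_nm = r_ax,
                 r_outer_nm = r_out, features = features,
                 id = as.integer(id), type = type),
            class = "nn_fibre_spec")
}

# per-slice effective render geometry after applying features
# returns data.frame: slice, cy_nm, cx_nm, r_ax, r_out (nm), solid, gap
fibre_render_table <- function(fs) {
  sl <- attr(fs$centerline, "slices")
  tb <- data.frame(slice = sl,
                   cy_nm = fs$centerline[, "y"], cx_nm = fs$centerline[, "x"],
                   r_ax = fs$r_axon_nm, r_out = fs$r_outer_nm,
                   solid = fs$type == "vessel", gap = FALSE)
  if (fs$type == "vessel") {
    tb$r_ax <- 0
    return(tb)
  }
  for (f in fs$features) {
    idx <- which(sl >= f$z_start & sl < f$z_end)
    if (identical(f$kind, "node_of_ranvier")) {
      # myelin absent in the gap; paranodal swelling on the 5 flanking slices
      tb$r_out[idx] <- tb$r_ax[idx]
      tb$gap[idx] <- TRUE
      swell <- f$paranode_swell %||% 1.5
      for (side in list(which(sl >= f$z_start - 5 & sl < f$z_start),
                        which(sl >= f$z_end & sl < f$z_end + 5)))
        tb$r_out[side] <- tb$r_ax[side] +
          swell * (tb$r_out[side] - tb$r_ax[side])
    } else if (identical(f$kind, "incisure_thinning")) {
      # local myelin thinning: sheath thickness reduced 40%
      tb$r_out[idx] <- tb$r_ax[idx] + 0.6 * (tb$r_out[idx] - tb$r_ax[idx])
    } else if (identical(f$kind, "bulb_dead_end")) {
      # terminal ellipsoid of myelin: solid cap tapering to the dead end
      idx <- which(sl >= f$z_start)        # fibre already truncated at z_end
      if (length(idx)) {
        len <- f$z_end - f$z_start
        t <- (sl[idx] - f$z_start + 1) / len
        rmax <- f$bulb_radius_nm %||% (1.5 * tb$r_out[idx[1]])
        tb$r_out[idx] <- rmax * sqrt(pmax(0, 1 - t^2))
        tb$r_ax[idx] <- 0
        tb$solid[idx] <- TRUE
      }
    }
  }
  tb
}

#' Render fibre specifications into a volume
#'
#' Rasterizes each fibre slice by slice: voxels with in-plane distance `d`
#' from the centerline get axon intensity for `d < r_axon` and myelin
#' intensity for `r_axon <= d < r_outer`; everything else keeps the
#' background. Later fibres overwrite earlier ones where they overlap.
#' Anti-aliasing supersamples the in/out indicator `supersampling^2` times
#' per voxel and blends partially covered voxels with the background. Node
#' gaps leave the former myelin annulus at background level, bulbs render as
#' solid tapering myelin caps, vessels as solid low-contrast tubes.
#'
#' The returned truth carries a per-voxel label map (label = majority
#' subsample label; codes in [phantom_labels]).
#'
#' @param config a [phantom_config()].
#' @param fibres list of [fibre_spec()] objects.
#' @param clusters optional list of integer fibre-id vectors recording
#'   cluster membership (stored in the truth).
#' @return list with `volume` (an `nn_volume`, noiseless and unblurred — see
#'   [degrade()]) and `truth` (an `nn_phantom_truth`).
#' @export
render_fibres <- function(config, fibres, clusters = list()) {
  stopifnot(inherits(config, "nn_phantom_config"))
  d <- config$shape; nz <- d[1]; ny <- d[2]; nx <- d[3]
  vs <- config$voxel_size_nm
  ints <- config$intensities
  s <- config$supersampling
  off <- ((seq_len(s)) - (s + 1) / 2) / s
  vol <- array(ints$background, d)
  lab <- array(0L, d)
  clipped <- character(0)
  for (fs in fibres) {
    tb <- fibre_render_table(fs)
    lab_fib <- if (fs$type == "vessel") phantom_labels[["vessel"]] else NA
    for (k in seq_len(nrow(tb))) {
      z <- tb$slice[k]
      if (z < 1L || z > nz) next
      cy <- tb$cy_nm[k] / vs + 1; cx <- tb$cx_nm[k] / vs + 1
      r_out <- tb$r_out[k] / vs; r_ax <- tb$r_ax[k] / vs
      if (r_out <= 0) next
      y0 <- floor(cy - r_out - 1); y1 <- ceiling(cy + r_out + 1)
      x0 <- floor(cx - r_out - 1); x1 <- ceiling(cx + r_out + 1)
      if (y0 < 1 || x0 < 1 || y1 > ny || x1 > nx) {
        clipped <- union(clipped, as.character(fs$id))
        y0 <- max(1, y0); x0 <- max(1, x0)
        y1 <- min(ny, y1); x1 <- min(nx, x1)
        if (y0 > y1 || x0 > x1) next
      }
      ys <- y0:y1; xs <- x0:x1
      fa <- matrix(0, length(ys), length(xs))
      fm <- fa
      for (oy in off) for (ox in off) {
        d2 <- outer((ys + oy - cy)^2, (xs + ox - cx)^2, "+")
        if (!tb$solid[k]) {
          fa <- fa + (d2 < r_ax^2)
          fm <- fm + (d2 >= r_ax^2 & d2 < r_out^2)
        } else {
          fm <- fm + (d2 < r_out^2)
        }
      }
      fa <- fa / s^2; fm <- fm / s^2
      cov <- fa + fm
      int_in <- if (fs$type == "vessel") ints$vessel else ints$axon
      int_my <- if (fs$type == "vessel") ints$vessel else ints$myelin
      patch <- ints$background * (1 - cov) + int_in * fa + int_my * fm
      sl <- vol[z, ys, xs]
      sel <- cov > 0
      sl[sel] <- patch[sel]
      vol[z, ys, xs] <- sl
      lb <- lab[z, ys, xs]
      maj <- cov >= 0.5
      if (fs$type == "vessel") {
        lb[maj] <- phantom_labels[["vessel"]]
      } else {
        lb[maj & fa >= fm] <- phantom_labels[["axon"]]
        lb[maj & fa < fm] <- phantom_labels[["myelin"]]
      }
      lab[z, ys, xs] <- lb
    }
  }
  if (length(clipped))
    nn_log("warn", "fibre(s) clipped at the grid boundary: ",
           paste(clipped, collapse = ", "))
  truth <- structure(list(fibres = fibres, label_volume = lab,
                          clusters = clusters, config = config),
                     class = "nn_phantom_truth")
  list(volume = volume(vol, voxel_size_nm = vs), truth = truth)
}

#' Apply imaging degradation: Gaussian blur then additive noise
#'
#' Isotropic 3D Gaussian blur of sigma `psf_sigma_vox` voxels (separable,
#' replicated edges) models the optics/detector point-spread function;
#' additive zero-mean Gaussian noise of sigma `noise_sigma` follows. The
#' result is deterministic given `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param vol an `nn_volume`.
#' @param psf_sigma_vox blur sigma in voxels (0 = no blur).
#' @param noise_sigma noise sigma in intensity units (0 = no noise).
#' @param seed RNG seed for the noise draw.
#' @return a degraded `nn_volume`.
#' @export
degrade <- function(vol, psf_sigma_vox = 0.8, noise_sigma = 0.05, seed = 1) {
  stopifnot(inherits(vol, "nn_volume"), psf_sigma_vox >= 0, noise_sigma >= 0)
  a <- vol$data
  if (psf_sigma_vox > 0) a <- gaussian_blur_3d(a, psf_sigma_vox)
  if (noise_sigma > 0) {
    a <- a + with_seed(seed, array(stats::rnorm(length(a), 0, noise_sigma),
                                   dim(a)))
  }
  volume(a, voxel_size_nm = vol$voxel_size_nm, origin_nm = vol$origin_nm)
}

# separable Gaussian blur with replicated edges, shift-and-add
gaussian_blur_3d <- function(a, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  for (axis in 1:3) {
    out <- array(0, d)
    n <- d[axis]
    for (k in -r:r) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)  # replicate edges
      shifted <- switch(axis,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      out <- out + w[k + r + 1] * shifted
    }
    a <- out
  }
  a
}

# evaluate expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a full study volume with ground truth
#'
#' Composes [make_centerline()], [render_fibres()] and [degrade()] into the
#' generator's standard scene: `n_large_fibres` non-overlapping sinusoidally
#' wavy large fibres, the configured regenerative clusters (thin fibres
#' sharing one helix axis per cluster, clusters mutually separated by the
#' configured gap), optionally a node of Ranvier / terminal myelin bulb /
#' sprouting axon arranged around large fibre 1, and a low-contrast vessel.
#' Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with `volume` (degraded `nn_volume`) and `truth`
#'   (`nn_phantom_truth`, whose `fibres`, `label_volume`, `clusters` and
#'   `features` describe the clean geometry).
#' @export
simulate_study_volume <- function(config = phantom_config()) {
  stopifnot(inherits(config, "nn_phantom_config"))
  res <- with_seed(config$seed, simulate_scene(config))
  vol <- degrade(res$volume, config$psf_sigma_vox, config$noise_sigma,
                 seed = config$seed + 1L)
  list(volume = vol, truth = res$truth)
}

simulate_scene <- function(config) {
  d <- config$shape; nz <- d[1]; ny <- d[2]; nx <- d[3]
  vs <- config$voxel_size_nm
  placed <- list()   # each: list(cy, cx, margin, kind) in nm
  place <- function(margin_nm, kind = "fibre", cluster_gap = 0) {
    lim_y <- c(margin_nm, (ny - 1) * vs - margin_nm)
    lim_x <- c(margin_nm, (nx - 1) * vs - margin_nm)
    if (lim_y[1] >= lim_y[2] || lim_x[1] >= lim_x[2])
      stop("grid too small to place an object of margin ", margin_nm, " nm")
    for (t in seq_len(config$max_tries)) {
      cy <- stats::runif(1, lim_y[1], lim_y[2])
      cx <- stats::runif(1, lim_x[1], lim_x[2])
      ok <- TRUE
      for (p in placed) {
        extra <- if (kind == "cluster" && p$kind == "cluster") cluster_gap
                 else 0
        if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) <
            margin_nm + p$margin + extra) { ok <- FALSE; break }
      }
      if (ok) {
        placed[[length(placed) + 1L]] <<- list(cy = cy, cx = cx,
                                               margin = margin_nm,
                                               kind = kind)
        return(c(cy, cx))
      }
    }
    stop("could not place all phantom objects without overlap in ",
         config$max_tries, " attempts; use a larger grid or fewer fibres")
  }

  fibres <- list()
  fid <- 0L
  feature_rows <- list()
  amp <- config$waveform$amplitude_nm

  # --- large wavy fibres ---
  for (i in seq_len(config$n_large_fibres)) {
    r_out <- stats::runif(1, config$large_r_outer_nm[1],
                          config$large_r_outer_nm[2])
    g <- stats::runif(1, config$large_g_ratio[1], config$large_g_ratio[2])
    ctr <- place(r_out + amp + 2 * vs)
    cl <- make_centerline("sinusoid", c(1L, nz), vs, center_nm = ctr,
                          amplitude_nm = amp,
                          period_nm = config$waveform$period_nm,
                          phase = stats::runif(1, 0, 2 * pi),
                          direction = { a <- stats::runif(1, 0, 2 * pi)
                                        c(sin(a), cos(a)) })
    fid <- fid + 1L
    feats <- list()
    if (i == 1L && length(config$features)) {
      gap_len <- config$node_gap_slices
      z0 <- as.integer(nz / 2 - gap_len / 2)
      z1 <- z0 + gap_len
      if ("node_of_ranvier" %in% config$features) {
        feats <- c(feats, list(list(kind = "node_of_ranvier",
                                    z_start = z0, z_end = z1)))
        feature_rows <- c(feature_rows, list(data.frame(
          fibre_id = fid, kind = "node_of_ranvier", z_start = z0, z_end = z1)))
      }
      if ("incisure" %in% config$features) {
        iz <- max(2L, as.integer(nz / 4))
        feats <- c(feats, list(list(kind = "incisure_thinning",
                                    z_start = iz, z_end = iz + 5L)))
        feature_rows <- c(feature_rows, list(data.frame(
          fibre_id = fid, kind = "incisure_thinning",
          z_start = iz, z_end = iz + 5L)))
      }
    }
    fibres[[fid]] <- fibre_spec(cl, r_axon_nm = g * r_out, r_outer_nm = r_out,
                                features = feats, id = fid)
  }
  node <- Filter(function(f) identical(f$kind, "node_of_ranvier"),
                 fibres[[1]]$features)
  node <- if (length(node)) node[[1]] else NULL

  # --- bulb-terminated degenerated fibre attached next to the paranode ---
  if ("bulb_dead_end" %in% config$features) {
    f1 <- fibres[[1]]
    r_b <- 0.55 * mean(f1$r_outer_nm)
    z_end <- node$z_start                       # dead end at the node
    anchor <- f1$centerline[node$z_start, c("y", "x")]
    ctr <- anchor + c(0, mean(f1$r_outer_nm) + 1.6 * r_b)
    cl <- make_centerline("straight", c(1L, z_end), vs, center_nm = ctr)
    fid <- fid + 1L
    bz0 <- z_end - config$node_gap_slices
    fibres[[fid]] <- fibre_spec(cl, r_axon_nm = 0.6 * r_b, r_outer_nm = r_b,
                                features = list(list(kind = "bulb_dead_end",
                                                     z_start = bz0,
                                                     z_end = z_end,
                                                     bulb_radius_nm = 1.5 * r_b)),
                                id = fid)
    feature_rows <- c(feature_rows, list(data.frame(
      fibre_id = fid, kind = "bulb_dead_end", z_start = bz0, z_end = z_end)))
  }

  # --- sprout: thin fibre leaving the far paranode, diverging laterally ---
  if ("sprout" %in% config$features) {
    f1 <- fibres[[1]]
    z0 <- node$z_end
    anchor <- f1$centerline[z0, c("y", "x")]
    r_s <- 800
    start <- anchor - c(0, mean(f1$r_outer_nm) + 1.8 * r_s)
    sl <- z0:nz
    drift <- 0.4 * vs * (seq_along(sl) - 1)      # 0.4 vox/slice, < max_drift
    pts <- cbind(z = (sl - 1) * vs, y = start[1] - drift,
                 x = rep(start[2], length(sl)))
    cl <- structure(pts, slices = sl, class = c("nn_centerline", "matrix",
                                                "array"))
    fid <- fid + 1L
    fibres[[fid]] <- fibre_spec(cl, r_axon_nm = 0.62 * r_s, r_outer_nm = r_s,
                                id = fid)
    feature_rows <- c(feature_rows, list(data.frame(
      fibre_id = fid, kind = "sprout", z_start = z0, z_end = nz + 1L)))
  }

  # --- regenerative clusters: helices about a shared axis ---
  clusters <- list()
  cc <- config$cluster
  for (k in seq_len(cc$n_clusters)) {
    r_thin <- stats::runif(cc$fibres_per_cluster, cc$r_outer_nm[1],
                           cc$r_outer_nm[2])
    env <- cc$helix_radius_nm + max(r_thin) + 2 * vs
    ctr <- place(env, kind = "cluster", cluster_gap = cc$gap_nm)
    phase0 <- stats::runif(1, 0, 2 * pi)
    ids <- integer(0)
    for (j in seq_len(cc$fibres_per_cluster)) {
      g <- stats::runif(1, cc$g_ratio[1], cc$g_ratio[2])
      cl <- make_centerline("helix", c(1L, nz), vs, center_nm = ctr,
                            radius_nm = cc$helix_radius_nm,
                            turns = cc$turns,
                            phase = phase0 + 2 * pi * (j - 1) /
                              cc$fibres_per_cluster)
      fid <- fid + 1L
      fibres[[fid]] <- fibre_spec(cl, r_axon_nm = g * r_thin[j],
                                  r_outer_nm = r_thin[j], id = fid)
      ids <- c(ids, fid)
    }
    clusters[[k]] <- ids
  }

  # --- low-contrast vessel ---
  if (isTRUE(config$vessel$enabled)) {
    r_v <- config$vessel$radius_nm
    ctr <- place(r_v + 2 * vs)
    cl <- make_centerline("straight", c(1L, nz), vs, center_nm = ctr)
    fid <- fid + 1L
    fibres[[fid]] <- fibre_spec(cl, r_axon_nm = 0, r_outer_nm = r_v,
                                id = fid, type = "vessel")
  }

  out <- render_fibres(config, fibres, clusters = clusters)
  out$truth$features <- if (length(feature_rows))
    do.call(rbind, feature_rows) else
    data.frame(fibre_id = integer(0), kind = character(0),
               z_start = integer(0), z_end = integer(0))
  out
}

#' @export
print.nn_phantom_truth <- function(x, ...) {
  nf <- sum(vapply(x$fibres, function(f) f$type == "fibre", logical(1)))
  cat(sprintf("<nn_phantom_truth> %d fibres (%d in %d clusters), %s vessel\n",
              nf, length(unlist(x$clusters)), length(x$clusters),
              if (any(vapply(x$fibres, function(f) f$type == "vessel",
                             logical(1)))) "1" else "no"))
  if (!is.null(x$features) && nrow(x$features))
    cat("  features:", paste(unique(x$features$kind), collapse = ", "), "\n")
  invisible(x)
}

#' Export phantom ground-truth geometry as CSV
#'
#' Writes one row per fibre per slice (`fibre_id, slice_z, cy_nm, cx_nm,
#' r_axon_nm, r_outer_nm`) and, optionally, the feature annotation table.
#'
#' @param truth an `nn_phantom_truth`.
#' @param geometry_csv path for the geometry table.
#' @param features_csv optional path for the feature table.
#' @return `geometry_csv`, invisibly.
#' @export
export_truth <- function(truth, geometry_csv, features_csv = NULL) {
  stopifnot(inherits(truth, "nn_phantom_truth"))
  rows <- lapply(truth$fibres, function(f) {
    data.frame(fibre_id = f$id, slice_z = attr(f$centerline, "slices"),
               cy_nm = f$centerline[, "y"], cx_nm = f$centerline[, "x"],
               r_axon_nm = f$r_axon_nm, r_outer_nm = f$r_outer_nm)
  })
  utils::write.csv(do.call(rbind, rows), geometry_csv, row.names = FALSE)
  if (!is.null(features_csv) && !is.null(truth$features))
    utils::write.csv(truth$features, features_csv, row.names = FALSE)
  invisible(geometry_csv)
}
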