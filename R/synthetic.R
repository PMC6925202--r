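#' Parameters for a synthetic MPS localization scene
#'
#' Defines a straight axon segment lined by periodic actin rings, the
#' structural model of the membrane-associated periodic scaffold (MPS):
#' circumferential rings spaced every ~185 nm by spectrin tetramers. Rings
#' are placed at `k * period` plus independent Gaussian jitter; each ring
#' contributes a Poisson number of fluorophore labels spread uniformly
#' across the axon width and blurred isotropically by the localization
#' precision; uniform background localizations are added over the axon
#' footprint.
#'
#' @param period ring center-to-center spacing, nm.
#' @param period_jitter_sd per-ring Gaussian jitter of the ring position, nm
#'   (independent per ring; no cumulative drift).
#' @param axon_length length of the simulated segment, nm (>= 2 periods).
#' @param axon_width transverse extent the rings span, nm.
#' @param axis_angle orientation of the axon axis, degrees (in the y-down
#'   image coordinate frame).
#' @param localization_precision_sd isotropic localization error, nm.
#' @param labels_per_ring expected label count per ring (Poisson).
#' @param background_density background localizations per square micron.
#' @param photon_mean,photon_sd mean and sd of the per-localization photon
#'   count, drawn log-normal (photon counts are positive).
#' @param n_frames number of acquisition frames localizations are spread over.
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(period = 185, period_jitter_sd = 5,
                         axon_length = 4000, axon_width = 300,
                         axis_angle = 0, localization_precision_sd = 10,
                         labels_per_ring = 50, background_density = 1,
                         photon_mean = 3000, photon_sd = 1500,
                         n_frames = 30000, seed = 1) {
  p <- list(period = period, period_jitter_sd = period_jitter_sd,
            axon_length = axon_length, axon_width = axon_width,
            axis_angle = axis_angle,
            localization_precision_sd = localization_precision_sd,
            labels_per_ring = labels_per_ring,
            background_density = background_density,
            photon_mean = photon_mean, photon_sd = photon_sd,
            n_frames = n_frames, seed = seed)
  if (!is.numeric(period) || period <= 0) {
    stop("scene_params: period must be > 0")
  }
  if (axon_length < 2 * period) {
    stop("scene_params: axon_length must be >= 2 * period")
  }
  if (localization_precision_sd < 0 || period_jitter_sd < 0 ||
      background_density < 0 || labels_per_ring < 0 || axon_width <= 0) {
    stop("scene_params: widths/densities must be non-negative")
  }
  class(p) <- "scene_params"
  p
}

#' Parameters for a synthetic braid-like PREM image
#'
#' Actin braids appear in platinum-replica EM as regularly spaced ridges
#' perpendicular to the axon axis. Each braid is a pair of filaments; a
#' single filament's apparent width is `filament_diameter +
#' 2 * coating_thickness` (a 7 nm actin filament rotary-shadowed with ~2 nm
#' of platinum appears 9-11 nm wide). Filaments are rendered as ridges with
#' Gaussian cross-section whose FWHM equals that apparent width; when
#' `braid_gap > 0` the two filaments of a braid are laterally separated (the
#' "split" configuration), otherwise they coincide.
#'
#' @param spacing braid center-to-center spacing, nm (default 184, the
#'   measured mean braid spacing in axons).
#' @param spacing_jitter_sd Gaussian jitter of each braid position, nm.
#' @param filament_diameter actin filament core diameter, nm.
#' @param coating_thickness platinum coat thickness, nm.
#' @param braid_gap lateral separation of the two filaments of a braid, nm;
#'   0 when tightly braided.
#' @param pixel_size image pixel size, nm.
#' @param image_size `c(rows, cols)` in pixels.
#' @param peak_intensity ridge peak intensity per filament (arbitrary units).
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param seed RNG seed.
#' @return A validated list of class `braid_scene_params`.
#' @export
braid_scene_params <- function(spacing = 184, spacing_jitter_sd = 0,
                               filament_diameter = 7, coating_thickness = 2,
                               braid_gap = 0, pixel_size = 2,
                               image_size = c(256, 512),
                               peak_intensity = 1000, noise_sd = 0,
                               seed = 1) {
  p <- list(spacing = spacing, spacing_jitter_sd = spacing_jitter_sd,
            filament_diameter = filament_diameter,
            coating_thickness = coating_thickness, braid_gap = braid_gap,
            pixel_size = pixel_size, image_size = as.integer(image_size),
            peak_intensity = peak_intensity, noise_sd = noise_sd,
            seed = seed)
  if (spacing <= 0) stop("braid_scene_params: spacing must be > 0")
  if (pixel_size <= 0) stop("braid_scene_params: pixel_size must be > 0")
  if (filament_diameter <= 0 || coating_thickness < 0 || braid_gap < 0 ||
      spacing_jitter_sd < 0 || noise_sd < 0) {
    stop("braid_scene_params: geometric parameters must be non-negative")
  }
  class(p) <- "braid_scene_params"
  p
}

# apparent single-filament width model (FWHM of the rendered ridge), nm
apparent_filament_width <- function(p) {
  p$filament_diameter + 2 * p$coating_thickness
}

# Run expr with a private RNG stream; the caller's RNG state is untouched,
# so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate an MPS localization scene
#'
#' Generates a localization table for a straight axon segment with periodic
#' rings, plus the ground truth needed to validate downstream estimators.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements `locs` (a [localization_table()]) and
#'   `truth` (ring positions along the axis in nm, per-ring and background
#'   localization counts, and the axis geometry).
#' @examples
#' sc <- make_mps_localizations(scene_params(seed = 7))
#' nrow(sc$locs)
#' @export
make_mps_localizations <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  with_seed(p$seed, {
    n_rings <- floor(p$axon_length / p$period) + 1L
    ring_pos <- (seq_len(n_rings) - 1L) * p$period +
      if (p$period_jitter_sd > 0) stats::rnorm(n_rings, 0, p$period_jitter_sd) else 0
    n_per_ring <- stats::rpois(n_rings, p$labels_per_ring)
    axial <- rep(ring_pos, n_per_ring)
    n_ring_locs <- length(axial)
    trans <- stats::runif(n_ring_locs, -p$axon_width / 2, p$axon_width / 2)
    area_um2 <- p$axon_length * p$axon_width / 1e6
    n_bg <- stats::rpois(1L, p$background_density * area_um2)
    axial <- c(axial, stats::runif(n_bg, 0, p$axon_length))
    trans <- c(trans, stats::runif(n_bg, -p$axon_width / 2, p$axon_width / 2))
    n <- n_ring_locs + n_bg
    if (p$localization_precision_sd > 0 && n > 0) {
      axial <- axial + stats::rnorm(n, 0, p$localization_precision_sd)
      trans <- trans + stats::rnorm(n, 0, p$localization_precision_sd)
    }
    a <- p$axis_angle * pi / 180
    x <- cos(a) * axial - sin(a) * trans
    y <- sin(a) * axial + cos(a) * trans
    if (n > 0) {
      frame <- sample.int(p$n_frames, n, replace = TRUE)
      sdlog <- sqrt(log(1 + (p$photon_sd / p$photon_mean)^2))
      meanlog <- log(p$photon_mean) - sdlog^2 / 2
      photons <- stats::rlnorm(n, meanlog, sdlog)
    } else {
      frame <- integer(); photons <- numeric()
    }
    locs <- localization_table(frame = frame, x = x, y = y, photons = photons,
                               uncertainty = rep(p$localization_precision_sd, n),
                               channel = rep("ch1", n))
    truth <- list(ring_positions = ring_pos,
                  n_ring_localizations = n_per_ring,
                  n_background = n_bg,
                  axis_angle = p$axis_angle,
                  axon_width = p$axon_width,
                  axon_length = p$axon_length,
                  period = p$period)
    list(locs = locs, truth = truth)
  })
}

#' Simulate a braid-like PREM image
#'
#' Renders vertical ridges (braids perpendicular to the axon axis) with
#' Gaussian cross-sections at regularly spaced positions, on a zero
#' background with optional additive Gaussian noise.
#'
#' @param params a [braid_scene_params()] object. The image must be wide
#'   enough to contain at least 3 braids.
#' @return A list with `image` (a [rendered_image()]) and `truth`
#'   (braid center x-positions in nm, per-braid filament x-offsets, and the
#'   centerline [polyline()]s).
#' @export
make_braid_image <- function(params) {
  stopifnot(inherits(params, "braid_scene_params"))
  p <- params
  ny <- p$image_size[1]; nx <- p$image_size[2]
  width_nm <- nx * p$pixel_size
  margin <- p$spacing / 2
  n_braids <- floor((width_nm - 2 * margin) / p$spacing) + 1L
  if (n_braids < 3L) {
    stop("make_braid_image: image too small to contain 3 braids at this spacing")
  }
  with_seed(p$seed, {
    centers <- margin + (seq_len(n_braids) - 1L) * p$spacing +
      if (p$spacing_jitter_sd > 0) stats::rnorm(n_braids, 0, p$spacing_jitter_sd) else 0
    sd_nm <- apparent_filament_width(p) / (2 * sqrt(2 * log(2)))
    fil_x <- c(centers - p$braid_gap / 2, centers + p$braid_gap / 2)
    xc <- (seq_len(nx) - 1L) * p$pixel_size  # origin at (0, 0)
    profile <- rep(0, nx)
    for (fx in fil_x) {
      profile <- profile + p$peak_intensity * exp(-(xc - fx)^2 / (2 * sd_nm^2))
    }
    img <- matrix(profile, nrow = ny, ncol = nx, byrow = TRUE)
    if (p$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(ny * nx, 0, p$noise_sd), ny, nx)
    }
    y_extent <- (ny - 1L) * p$pixel_size
    centerlines <- lapply(centers, function(cx) {
      polyline(rbind(c(cx, 0), c(cx, y_extent)), band_width = 0)
    })
    truth <- list(braid_centers = centers,
                  filament_offsets = c(-p$braid_gap / 2, p$braid_gap / 2),
                  centerlines = centerlines,
                  apparent_filament_width = apparent_filament_width(p),
                  spacing = p$spacing)
    list(image = rendered_image(img, p$pixel_size, c(0, 0)), truth = truth)
  })
}

#' Simulate a matched SMLM / PREM correlative pair
#'
#' Builds one ring geometry, expresses it as a localization table in the
#' SMLM frame and, through `transform`, as a braid-ridge image in the EM
#' frame, together with matched control points (fiducials) for registration.
#'
#' @param loc_params a [scene_params()] for the SMLM side.
#' @param braid_params a [braid_scene_params()]; its spacing/jitter are
#'   ignored (ring geometry comes from `loc_params`) but its filament
#'   geometry, pixel size and noise model are used for the EM rendering.
#' @param transform an [affine2d()] mapping SMLM coordinates to EM
#'   coordinates.
#' @param n_fiducials number of control-point pairs (>= 3, non-collinear).
#' @param fiducial_jitter_sd Gaussian jitter added to the EM-side control
#'   points, nm.
#' @param fiducial_positions optional n x 2 matrix of SMLM-frame fiducial
#'   positions; by default fiducials are spread on a circle around the
#'   scene. Collinear positions are rejected.
#' @return A list with `locs`, `em_image`, `control_points` (data frame
#'   `x_src, y_src, x_dst, y_dst`) and `truth` (including `transform`).
#' @export
make_correlative_pair <- function(loc_params, braid_params, transform,
                                  n_fiducials = 6, fiducial_jitter_sd = 0,
                                  fiducial_positions = NULL) {
  stopifnot(inherits(loc_params, "scene_params"),
            inherits(braid_params, "braid_scene_params"),
            inherits(transform, "affine2d"))
  if (n_fiducials < 3L) stop("make_correlative_pair: need >= 3 fiducials")
  scene <- make_mps_localizations(loc_params)
  a <- loc_params$axis_angle * pi / 180
  w <- loc_params$axon_width
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  # ring segments across the axon width, SMLM frame
  seg_ends <- lapply(scene$truth$ring_positions, function(pos) {
    p1 <- rot %*% c(pos, -w / 2)
    p2 <- rot %*% c(pos, +w / 2)
    rbind(as.vector(p1), as.vector(p2))
  })
  seg_em <- lapply(seg_ends, function(s) affine_apply(transform, s))
  all_pts <- do.call(rbind, seg_em)
  ps <- braid_params$pixel_size
  pad <- 100
  xlim <- range(all_pts[, 1]) + c(-pad, pad)
  ylim <- range(all_pts[, 2]) + c(-pad, pad)
  nx <- ceiling(diff(xlim) / ps); ny <- ceiling(diff(ylim) / ps)
  sd_nm <- apparent_filament_width(braid_params) / (2 * sqrt(2 * log(2)))
  xc <- xlim[1] + ps / 2 + (seq_len(nx) - 1L) * ps
  yc <- ylim[1] + ps / 2 + (seq_len(ny) - 1L) * ps
  gx <- matrix(xc, ny, nx, byrow = TRUE)
  gy <- matrix(yc, ny, nx)
  img <- matrix(0, ny, nx)
  for (s in seg_em) {
    d <- dist_to_segment(gx, gy, s[1, ], s[2, ])
    img <- img + braid_params$peak_intensity * exp(-d^2 / (2 * sd_nm^2))
  }
  with_seed(braid_params$seed, {
    if (braid_params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(ny * nx, 0, braid_params$noise_sd), ny, nx)
    }
    if (is.null(fiducial_positions)) {
      bb_x <- range(scene$locs$x); bb_y <- range(scene$locs$y)
      ctr <- c(mean(bb_x), mean(bb_y))
      r <- max(diff(bb_x), diff(bb_y), 200) / 2
      ang <- 2 * pi * (seq_len(n_fiducials) - 1L) / n_fiducials + pi / 7
      fiducial_positions <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    } else {
      fiducial_positions <- rbind2cols(fiducial_positions)
      if (nrow(fiducial_positions) != n_fiducials) {
        stop("make_correlative_pair: fiducial_positions must have n_fiducials rows")
      }
    }
    if (points_collinear(fiducial_positions)) {
      stop("make_correlative_pair: fiducial positions are collinear")
    }
    dst <- affine_apply(transform, fiducial_positions)
    if (fiducial_jitter_sd > 0) {
      dst <- dst + matrix(stats::rnorm(length(dst), 0, fiducial_jitter_sd),
                          ncol = 2)
    }
    cp <- data.frame(x_src = fiducial_positions[, 1],
                     y_src = fiducial_positions[, 2],
                     x_dst = dst[, 1], y_dst = dst[, 2])
    truth <- scene$truth
    truth$transform <- transform
    truth$ring_segments_em <- seg_em
    list(locs = scene$locs,
         em_image = rendered_image(img, ps, c(xc[1], yc[1])),
         control_points = cp,
         truth = truth)
  })
}

# distance from grid points to the segment p1-p2 (all in nm)
dist_to_segment <- function(gx, gy, p1, p2) {
  d <- p2 - p1
  len2 <- sum(d^2)
  t <- ((gx - p1[1]) * d[1] + (gy - p1[2]) * d[2]) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt((gx - (p1[1] + t * d[1]))^2 + (gy - (p1[2] + t * d[2]))^2)
}

points_collinear <- function(pts, tol = 1e-6) {
  if (nrow(pts) < 3L) return(TRUE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  sv[2] <= tol * max(sv[1], 1)
}
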