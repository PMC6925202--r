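#' Five-line measurement set
#'
#' The PREM morphometry protocol measures each distance data point as the
#' mean of five traced line segments: between consecutive braids for braid
#' spacing, or across a single braid (before / after splitting) for braid
#' width.
#'
#' @param segments 5 x 4 numeric matrix, rows `(x1, y1, x2, y2)` in nm, or a
#'   list of five 2 x 2 endpoint matrices.
#' @param kind `"between_braids"` or `"across_braid"`.
#' @return An object of class `line_set`.
#' @export
line_set <- function(segments, kind = c("between_braids", "across_braid")) {
  kind <- match.arg(kind)
  if (is.list(segments)) {
    segments <- do.call(rbind, lapply(segments, function(s) c(t(s))))
  }
  segments <- matrix(as.numeric(segments), ncol = 4)
  if (nrow(segments) != 5L) {
    stop("line_set: the protocol requires exactly five lines (got ",
         nrow(segments), ")")
  }
  len <- segment_lengths(segments)
  if (any(len <= 0)) stop("line_set: all segments must have positive length")
  structure(list(segments = segments, kind = kind), class = "line_set")
}

segment_lengths <- function(segments) {
  sqrt((segments[, 3] - segments[, 1])^2 + (segments[, 4] - segments[, 2])^2)
}

#' Distance data point from a five-line set
#'
#' Averages the Euclidean lengths of the five lines into one distance data
#' point, retaining the individual component values for audit.
#'
#' @param lines a [line_set()].
#' @return An object of class `morpho_datapoint` with `value` (nm, the
#'   mean), `kind` (`"spacing"` for between-braid sets, `"width"` for
#'   across-braid sets), and `component_values` (the five lengths).
#' @examples
#' segs <- cbind(0, 1:5 * 10, 184, 1:5 * 10)
#' distance_datapoint(line_set(segs, "between_braids"))$value  # 184
#' @export
distance_datapoint <- function(lines) {
  stopifnot(inherits(lines, "line_set"))
  len <- segment_lengths(lines$segments)
  structure(list(value = mean(len),
                 kind = if (lines$kind == "between_braids") "spacing" else "width",
                 component_values = len),
            class = "morpho_datapoint")
}

#' Filament width from an intensity cross-section (FWHM)
#'
#' Samples the image along a cut crossing a single ridge (bilinear
#' interpolation at quarter-pixel steps), subtracts the local background
#' (median of the profile's end samples), and measures the full width at
#' half maximum by linear interpolation of the half-maximum crossings
#' around the peak. Optionally corrects for an oblique cut by multiplying
#' the measured width by the cosine of the angle between the cut and the
#' ridge normal, estimated from the local image structure tensor (off by
#' default, mirroring the manual protocol).
#'
#' @param image a [rendered_image()].
#' @param cut length-4 numeric `(x1, y1, x2, y2)` in nm, crossing one ridge.
#' @param obliquity_correction logical; apply the structure-tensor cosine
#'   correction.
#' @return Width in nm (FWHM above local background).
#' @export
width_profile <- function(image, cut, obliquity_correction = FALSE) {
  stopifnot(inherits(image, "rendered_image"), length(cut) == 4L)
  p1 <- cut[1:2]; p2 <- cut[3:4]
  len <- sqrt(sum((p2 - p1)^2))
  step <- image$pixel_size / 4
  s <- seq(0, len, by = step)
  xs <- p1[1] + (p2[1] - p1[1]) * s / len
  ys <- p1[2] + (p2[2] - p1[2]) * s / len
  v <- interp_bilinear(image, xs, ys)
  if (anyNA(v)) stop("width_profile: cut leaves the image")
  n <- length(v)
  n_end <- max(2L, floor(0.15 * n))
  bg <- stats::median(c(v[seq_len(n_end)], v[seq(n - n_end + 1L, n)]))
  ipk <- which.max(v)
  peak <- v[ipk]
  if (ipk <= n_end || ipk > n - n_end || peak <= bg) {
    stop("width_profile: no ridge peak above local background on this cut")
  }
  half <- bg + (peak - bg) / 2
  il <- ipk
  while (il > 1L && v[il] > half) il <- il - 1L
  ir <- ipk
  while (ir < n && v[ir] > half) ir <- ir + 1L
  if (v[il] > half || v[ir] > half) {
    stop("width_profile: half-maximum crossings not found; cut does not cross a single ridge")
  }
  sl <- s[il] + (half - v[il]) / (v[il + 1L] - v[il]) * step
  sr <- s[ir - 1L] + (half - v[ir - 1L]) / (v[ir] - v[ir - 1L]) * step
  width <- sr - sl
  if (obliquity_correction) {
    normal <- ridge_normal(image, xs[ipk], ys[ipk])
    cut_dir <- (p2 - p1) / len
    width <- width * abs(sum(cut_dir * normal))
  }
  width
}

# Ridge normal direction at a physical point, from the dominant eigenvector
# of the local intensity structure tensor (gradients point across a ridge).
ridge_normal <- function(image, x, y, halfwin = 7L) {
  ps <- image$pixel_size
  cx <- round((x - image$origin[1]) / ps) + 1L
  cy <- round((y - image$origin[2]) / ps) + 1L
  m <- image$pixels
  rows <- max(2L, cy - halfwin):min(nrow(m) - 1L, cy + halfwin)
  cols <- max(2L, cx - halfwin):min(ncol(m) - 1L, cx + halfwin)
  gx <- (m[rows, cols + 1L] - m[rows, cols - 1L]) / (2 * ps)
  gy <- (m[rows + 1L, cols] - m[rows - 1L, cols]) / (2 * ps)
  st <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy), sum(gy * gy)), 2, 2)
  ev <- eigen(st, symmetric = TRUE)
  ev$vectors[, 1]
}

#' Summarize morphometry data points
#'
#' @param points list of `morpho_datapoint` objects (or a numeric vector of
#'   values in nm), optionally filtered by `kind`.
#' @param kind optional kind filter (`"spacing"`, `"width"`, `"length"`).
#' @return A list `mean`, `sem` (sd / sqrt(n); 0 with a warning for n = 1),
#'   and `n`.
#' @export
summarize_morpho <- function(points, kind = NULL) {
  if (is.numeric(points)) {
    vals <- points
  } else {
    if (!is.null(kind)) {
      points <- Filter(function(p) p$kind == kind, points)
    }
    vals <- vapply(points, function(p) p$value, numeric(1))
  }
  if (length(vals) == 0L) stop("summarize_morpho: no data points")
  n <- length(vals)
  if (n == 1L) {
    warning("summarize_morpho: single data point, SEM reported as 0")
    sem <- 0
  } else {
    sem <- stats::sd(vals) / sqrt(n)
  }
  list(mean = mean(vals), sem = sem, n = n)
}

#' Auto-placed five-line braid spacing data points
#'
#' Detects braid ridge positions from the column-mean intensity profile of a
#' braids-perpendicular image (local maxima above half the global maximum)
#' and builds one five-line [line_set()] between each pair of consecutive
#' ridges, spreading the five lines evenly along the ridges. A convenience
#' for synthetic validation scenes; on real PREM views lines are traced
#' manually.
#'
#' @param image a [rendered_image()] with near-vertical ridges.
#' @return List of `morpho_datapoint`s, one per consecutive ridge pair.
#' @export
braid_spacing_datapoints <- function(image) {
  stopifnot(inherits(image, "rendered_image"))
  prof <- colMeans(image$pixels)
  xs <- image$origin[1] + (seq_along(prof) - 1L) * image$pixel_size
  pk <- which(diff(sign(diff(prof))) == -2) + 1L
  pk <- pk[prof[pk] > max(prof) / 2]
  if (length(pk) < 2L) {
    stop("braid_spacing_datapoints: fewer than two ridges detected")
  }
  y0 <- image$origin[2]
  y1 <- y0 + (nrow(image$pixels) - 1L) * image$pixel_size
  ys <- seq(y0 + 0.1 * (y1 - y0), y1 - 0.1 * (y1 - y0), length.out = 5)
  lapply(seq_len(length(pk) - 1L), function(i) {
    segs <- cbind(xs[pk[i]], ys, xs[pk[i + 1L]], ys)
    distance_datapoint(line_set(segs, "between_braids"))
  })
}
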