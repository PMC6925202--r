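#' Polyline trace in physical coordinates
#'
#' Ordered vertex list in nm, used for axon tracings and measurement lines.
#' `band_width` is the averaging width perpendicular to the path used when
#' extracting intensity profiles.
#'
#' @param vertices n x 2 numeric matrix of (x, y) in nm, n >= 2; consecutive
#'   vertices must be distinct.
#' @param band_width averaging band width perpendicular to the path, nm.
#' @return An object of class `polyline`.
#' @export
polyline <- function(vertices, band_width = 160) {
  vertices <- rbind2cols(vertices)
  if (nrow(vertices) < 2L) stop("polyline: need at least 2 vertices")
  if (any(!is.finite(vertices))) stop("polyline: vertices must be finite")
  seglen <- sqrt(rowSums(diff(vertices)^2))
  if (any(seglen == 0)) stop("polyline: consecutive vertices must be distinct")
  if (!is.numeric(band_width) || band_width < 0) {
    stop("polyline: band_width must be >= 0")
  }
  structure(list(vertices = vertices, band_width = band_width),
            class = "polyline")
}

#' Arc length of a polyline trace
#'
#' Sum of the Euclidean lengths of the segments, in nm. This is the braid /
#' filament length measurement used on PREM views.
#'
#' @param trace a [polyline()].
#' @return Length in nm.
#' @examples
#' trace_length(polyline(rbind(c(0, 0), c(500, 0))))  # 500
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "polyline"))
  sum(sqrt(rowSums(diff(trace$vertices)^2)))
}

# Resample a polyline at uniform arc-length step. Returns positions (nm along
# arc), points (n x 2) and unit tangents (n x 2) at each sample.
resample_polyline <- function(trace, step) {
  stopifnot(inherits(trace, "polyline"), step > 0)
  v <- trace$vertices
  d <- diff(v)
  seglen <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg > nrow(d)] <- nrow(d)
  frac <- (s - cum[seg]) / seglen[seg]
  pts <- v[seg, , drop = FALSE] + d[seg, , drop = FALSE] * frac
  tans <- d[seg, , drop = FALSE] / seglen[seg]
  list(positions = s, points = pts, tangents = tans, segment = seg)
}

#' Read / write polyline annotations as JSON
#'
#' On-disk form: `{"vertices_nm": [[x, y], ...], "band_width_nm": w}`, or a
#' JSON array of such objects for several traces.
#'
#' @param path file path.
#' @param traces a [polyline()] or list of them.
#' @return `read_polylines_json` returns a list of `polyline`s.
#' @export
read_polylines_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(obj$vertices_nm)) obj <- list(obj)
  lapply(obj, function(o) {
    verts <- if (is.matrix(o$vertices_nm)) o$vertices_nm else
      do.call(rbind, lapply(o$vertices_nm, as.numeric))
    polyline(verts, band_width = if (is.null(o$band_width_nm)) 160 else o$band_width_nm)
  })
}

#' @rdname read_polylines_json
#' @export
write_polylines_json <- function(traces, path) {
  if (inherits(traces, "polyline")) traces <- list(traces)
  obj <- lapply(traces, function(tr) {
    list(vertices_nm = apply(tr$vertices, 1, as.numeric, simplify = FALSE),
         band_width_nm = tr$band_width)
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
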