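#' Fit an affine transform from control points
#'
#' Least-squares estimate of the planar affine map (6 parameters, or 4 in
#' the similarity-constrained mode for low point counts) minimizing the
#' mean squared residual in the target (EM) frame, where biological
#' distances are read. With 3 exact non-collinear pairs the affine
#' interpolates and the residual is 0.
#'
#' @param points data frame with columns `x_src, y_src, x_dst, y_dst` (nm),
#'   n >= 3, source points not all collinear.
#' @param type `"affine"` (default, full 6-parameter) or `"similarity"`
#'   (rotation + isotropic scale + translation).
#' @return A list with `transform` (an [affine2d()]) and `rms_nm` (root
#'   mean square residual in the target frame).
#' @export
fit_affine <- function(points, type = c("affine", "similarity")) {
  type <- match.arg(type)
  req <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(req %in% names(points))) {
    stop("fit_affine: points must have columns ", paste(req, collapse = ", "))
  }
  n <- nrow(points)
  if (n < 3L) stop("fit_affine: need at least 3 control-point pairs")
  src <- cbind(points$x_src, points$y_src)
  if (anyDuplicated(src)) stop("fit_affine: duplicated source points")
  dst <- cbind(points$x_dst, points$y_dst)
  if (type == "affine") {
    X <- cbind(src, 1)
    qrX <- qr(X)
    if (qrX$rank < 3L) {
      stop("fit_affine: control points are collinear (rank-deficient design)")
    }
    beta <- qr.coef(qrX, dst)              # 3 x 2
    t <- affine2d(t(beta[1:2, ]), beta[3, ])
  } else {
    # dst_x = a*x - b*y + tx ; dst_y = b*x + a*y + ty
    X <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
               cbind(src[, 2],  src[, 1], 0, 1))
    yv <- c(dst[, 1], dst[, 2])
    qrX <- qr(X)
    if (qrX$rank < 4L) stop("fit_affine: degenerate control points")
    b <- qr.coef(qrX, yv)
    t <- affine2d(matrix(c(b[1], b[2], -b[2], b[1]), 2, 2), b[3:4])
  }
  res <- affine_apply(t, src) - dst
  list(transform = t, rms_nm = sqrt(mean(rowSums(res^2))))
}

#' Apply an affine transform to a localization table
#'
#' Maps the `x`, `y` coordinates into the target frame; all other fields
#' are unchanged.
#'
#' @param t an [affine2d()].
#' @param table a [localization_table()].
#' @return The transformed table.
#' @export
apply_affine <- function(t, table) {
  stopifnot(inherits(t, "affine2d"), inherits(table, "localization_table"))
  if (nrow(table) > 0L) {
    xy <- affine_apply(t, cbind(table$x, table$y))
    table$x <- xy[, 1]
    table$y <- xy[, 2]
  }
  table
}

#' Overlay SMLM content onto an EM view
#'
#' Resamples the SMLM content into the EM pixel grid through the affine
#' transform, producing a two-channel aligned image: channel `em` is the
#' EM view, channel `smlm` carries the transformed SMLM signal (0 outside
#' the SMLM footprint). A localization table is transformed exactly and
#' re-rendered in histogram mode (no double interpolation); a rendered SMLM
#' image is inverse-mapped and bilinearly resampled.
#'
#' @param em a [rendered_image()] PREM view (target frame).
#' @param smlm a [localization_table()] or [rendered_image()] in the SMLM
#'   frame.
#' @param t an [affine2d()] mapping SMLM coordinates to EM coordinates.
#' @return An object of class `correlative_overlay`: list with `em` and
#'   `smlm` intensity matrices on the EM grid, plus `pixel_size` and
#'   `origin`.
#' @export
overlay_correlative <- function(em, smlm, t) {
  stopifnot(inherits(em, "rendered_image"), inherits(t, "affine2d"))
  ext <- image_extent(em)
  if (inherits(smlm, "localization_table")) {
    mapped <- apply_affine(t, smlm)
    inside <- mapped$x >= ext$xlim[1] & mapped$x <= ext$xlim[2] &
      mapped$y >= ext$ylim[1] & mapped$y <= ext$ylim[2]
    if (!any(inside)) {
      stop("overlay_correlative: transformed localizations do not intersect the EM view")
    }
    ch2 <- reconstruct(mapped, pixel_size = em$pixel_size, mode = "histogram",
                       bounds = ext)$pixels
    # reconstruct() sizes the grid from the bounds; match the EM grid exactly
    ch2 <- ch2[seq_len(nrow(em$pixels)), seq_len(ncol(em$pixels)), drop = FALSE]
  } else if (inherits(smlm, "rendered_image")) {
    tinv <- affine_invert(t)
    nx <- ncol(em$pixels); ny <- nrow(em$pixels)
    xc <- em$origin[1] + (seq_len(nx) - 1L) * em$pixel_size
    yc <- em$origin[2] + (seq_len(ny) - 1L) * em$pixel_size
    grid <- cbind(rep(xc, each = ny), rep(yc, times = nx))
    src <- affine_apply(tinv, grid)
    vals <- interp_bilinear(smlm, src[, 1], src[, 2])
    if (all(is.na(vals))) {
      stop("overlay_correlative: transformed SMLM footprint does not intersect the EM view")
    }
    vals[is.na(vals)] <- 0
    ch2 <- matrix(vals, nrow = ny, ncol = nx)
  } else {
    stop("overlay_correlative: smlm must be a localization_table or rendered_image")
  }
  structure(list(em = em$pixels, smlm = ch2,
                 pixel_size = em$pixel_size, origin = em$origin),
            class = "correlative_overlay")
}

#' Read / write control points as CSV
#'
#' Columns `x_smlm, y_smlm, x_em, y_em` in nm.
#'
#' @param path file path.
#' @param points data frame with columns `x_src, y_src, x_dst, y_dst`.
#' @return `read_control_points` returns that data frame.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  req <- c("x_smlm", "y_smlm", "x_em", "y_em")
  if (!all(req %in% names(df))) {
    stop("read_control_points: expected columns ", paste(req, collapse = ", "))
  }
  data.frame(x_src = df$x_smlm, y_src = df$y_smlm,
             x_dst = df$x_em, y_dst = df$y_em)
}

#' @rdname read_control_points
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(data.frame(x_smlm = points$x_src, y_smlm = points$y_src,
                              x_em = points$x_dst, y_em = points$y_dst),
                   path, row.names = FALSE)
  invisible(path)
}
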