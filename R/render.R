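#' Rendered image with physical pixel size
#'
#' A 2-D intensity grid with a physical pixel size (nm) and the physical
#' coordinates of the top-left pixel center. Used both for SMLM
#' reconstructions and for PREM views. Matrix rows run along y (downward),
#' columns along x.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size pixel size in nm (> 0).
#' @param origin (x, y) in nm of the top-left pixel center.
#' @return An object of class `rendered_image`.
#' @export
rendered_image <- function(pixels, pixel_size, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("rendered_image: pixel_size must be > 0")
  }
  if (any(!is.finite(pixels))) stop("rendered_image: intensities must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d px, %.3g nm/px, origin (%.4g, %.4g) nm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# physical extent covered by the pixel grid (outer pixel edges), nm
image_extent <- function(img) {
  ps <- img$pixel_size
  list(xlim = c(img$origin[1] - ps / 2, img$origin[1] + (ncol(img$pixels) - 0.5) * ps),
       ylim = c(img$origin[2] - ps / 2, img$origin[2] + (nrow(img$pixels) - 0.5) * ps))
}

#' Reconstruct a super-resolution image from localizations
#'
#' Histogram mode: each pixel counts the localizations whose position falls
#' inside it (half-open bins, so boundary localizations are assigned
#' deterministically); total counts are conserved exactly. Gaussian mode:
#' each localization deposits a unit-integral Gaussian of standard deviation
#' `blur_sd` (or its per-record `uncertainty` when `blur_sd` is `NULL`).
#'
#' @param table a [localization_table()].
#' @param pixel_size pixel size in nm; the default 16 nm is the analysis grid
#'   used for autocorrelation quantification.
#' @param mode `"histogram"` (default; counts are what the autocorrelation
#'   operates on) or `"gaussian"`.
#' @param blur_sd Gaussian mode blur in nm; `NULL` uses each record's
#'   `uncertainty` field.
#' @param bounds optional `list(xlim =, ylim =)` physical extent in nm
#'   (outer pixel edges). When `NULL`, the tight bounding box of the
#'   localizations is used, padded by `3 * blur_sd` in gaussian mode.
#' @return A [rendered_image()] covering all localizations.
#' @export
reconstruct <- function(table, pixel_size = 16,
                        mode = c("histogram", "gaussian"),
                        blur_sd = NULL, bounds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "localization_table"), pixel_size > 0)
  if (nrow(table) == 0L && is.null(bounds)) {
    stop("reconstruct: empty table and no explicit bounds")
  }
  if (mode == "gaussian") {
    sds <- if (is.null(blur_sd)) table$uncertainty else rep(blur_sd, nrow(table))
    if (any(!is.finite(sds)) || any(sds <= 0)) {
      stop("reconstruct: gaussian mode needs positive blur_sd or per-record uncertainty")
    }
  }
  if (is.null(bounds)) {
    pad <- if (mode == "gaussian") 3 * max(sds) else 0
    bounds <- list(xlim = range(table$x) + c(-pad, pad),
                   ylim = range(table$y) + c(-pad, pad))
  }
  nx <- max(1L, ceiling(diff(bounds$xlim) / pixel_size))
  ny <- max(1L, ceiling(diff(bounds$ylim) / pixel_size))
  origin <- c(bounds$xlim[1] + pixel_size / 2, bounds$ylim[1] + pixel_size / 2)
  img <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(table) > 0L) {
    # 0-based pixel indices, half-open bins [edge, edge + pixel_size)
    ix <- floor((table$x - bounds$xlim[1]) / pixel_size)
    iy <- floor((table$y - bounds$ylim[1]) / pixel_size)
    inside <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    if (mode == "histogram") {
      idx <- iy[inside] + 1L + ix[inside] * ny
      tab <- tabulate(idx, nbins = nx * ny)
      img <- matrix(tab, nrow = ny, ncol = nx)
    } else {
      xc <- origin[1] + (seq_len(nx) - 1L) * pixel_size
      yc <- origin[2] + (seq_len(ny) - 1L) * pixel_size
      for (i in seq_len(nrow(table))) {
        s <- sds[i]
        r <- 4 * s
        jx <- which(abs(xc - table$x[i]) <= r)
        jy <- which(abs(yc - table$y[i]) <= r)
        if (length(jx) == 0L || length(jy) == 0L) next
        gx <- exp(-(xc[jx] - table$x[i])^2 / (2 * s^2))
        gy <- exp(-(yc[jy] - table$y[i])^2 / (2 * s^2))
        img[jy, jx] <- img[jy, jx] +
          (pixel_size^2 / (2 * pi * s^2)) * outer(gy, gx)
      }
    }
  }
  rendered_image(img, pixel_size, origin)
}

#' Write / read a rendered image as TIFF with a JSON sidecar
#'
#' Intensities are scaled to the unit interval for storage (16-bit for
#' integer-valued histogram images, 32-bit float otherwise); the physical
#' pixel size, origin and intensity scale are stored in `<path>.json` and
#' restored on read.
#'
#' @param img a [rendered_image()].
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return `read_rendered_tiff` returns a [rendered_image()];
#'   `write_rendered_tiff` returns `path` invisibly.
#' @export
write_rendered_tiff <- function(img, path) {
  stopifnot(inherits(img, "rendered_image"))
  px <- img$pixels
  scale <- max(px, 1e-300)
  integerish <- all(px == round(px)) && scale <= 65535
  bits <- if (integerish) 16L else 32L
  store_scale <- if (integerish) 65535 else scale
  tiff::writeTIFF(px / store_scale, path, bits.per.sample = bits)
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size,
                            origin_nm = img$origin,
                            intensity_scale = store_scale,
                            bits_per_sample = bits),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rendered_tiff
#' @export
read_rendered_tiff <- function(path) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rendered_image(px * meta$intensity_scale, meta$pixel_size_nm,
                   meta$origin_nm)
  } else {
    rendered_image(px, 1)
  }
}

# Bilinear interpolation of image intensity at physical coordinates (nm).
# Returns NA for points outside the grid of pixel centers.
interp_bilinear <- function(img, x, y) {
  ps <- img$pixel_size
  px <- (x - img$origin[1]) / ps
  py <- (y - img$origin[2]) / ps
  nx <- ncol(img$pixels); ny <- nrow(img$pixels)
  out <- rep(NA_real_, length(px))
  ok <- px >= 0 & px <= nx - 1 & py >= 0 & py <= ny - 1
  if (!any(ok)) return(out)
  x0 <- pmin(floor(px[ok]), nx - 2); x0[x0 < 0] <- 0
  y0 <- pmin(floor(py[ok]), ny - 2); y0[y0 < 0] <- 0
  if (nx == 1L) x0 <- rep(0, sum(ok))
  if (ny == 1L) y0 <- rep(0, sum(ok))
  fx <- px[ok] - x0; fy <- py[ok] - y0
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  m <- img$pixels
  v00 <- m[cbind(y0 + 1, x0 + 1)]; v01 <- m[cbind(y0 + 1, x1 + 1)]
  v10 <- m[cbind(y1 + 1, x0 + 1)]; v11 <- m[cbind(y1 + 1, x1 + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}
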