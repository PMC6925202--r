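#' Planar affine transform
#'
#' A 6-parameter affine map between two planar coordinate frames (nm to nm),
#' stored as a 2x2 linear part and a length-2 translation:
#' `y = linear %*% x + translation`.
#'
#' @param linear 2x2 numeric matrix (must be invertible).
#' @param translation numeric length-2 vector, nm.
#' @return An object of class `affine2d`.
#' @examples
#' t <- affine2d(matrix(c(0, -1, 1, 0), 2, 2), c(100, 50))  # 90 deg + shift
#' affine_apply(t, cbind(1, 0))
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  translation <- as.numeric(translation)
  if (length(translation) != 2L || any(!is.finite(translation)) ||
      any(!is.finite(linear))) {
    stop("affine2d: linear part and translation must be finite (2x2 and length 2)")
  }
  if (abs(det(linear)) <= 1e-12) {
    stop("affine2d: linear part is singular (|det| <= 1e-12)")
  }
  structure(list(linear = linear, translation = translation),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d (nm -> nm)\n")
  m <- cbind(x$linear, x$translation)
  dimnames(m) <- list(c("x'", "y'"), c("x", "y", "1"))
  print(m)
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param t an [affine2d()] transform.
#' @param xy n x 2 matrix (or length-2 vector) of coordinates, nm.
#' @return n x 2 matrix of mapped coordinates.
#' @export
affine_apply <- function(t, xy) {
  stopifnot(inherits(t, "affine2d"))
  xy <- rbind2cols(xy)
  out <- xy %*% t(t$linear)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#' @param t an [affine2d()] transform.
#' @return The inverse `affine2d`.
#' @export
affine_invert <- function(t) {
  stopifnot(inherits(t, "affine2d"))
  ainv <- solve(t$linear)
  affine2d(ainv, -as.vector(ainv %*% t$translation))
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `t2` first, then `t1`.
#' @param t1,t2 [affine2d()] transforms.
#' @export
affine_compose <- function(t1, t2) {
  stopifnot(inherits(t1, "affine2d"), inherits(t2, "affine2d"))
  affine2d(t1$linear %*% t2$linear,
           as.vector(t1$linear %*% t2$translation) + t1$translation)
}

#' Read / write an affine transform as JSON
#'
#' The on-disk form is a row-major 2x3 matrix under key `"matrix"`, i.e.
#' `[[a11, a12, tx], [a21, a22, ty]]`.
#'
#' @param t an [affine2d()] transform.
#' @param path file path.
#' @return `read_affine_json` returns an `affine2d`; `write_affine_json`
#'   returns `path` invisibly.
#' @export
write_affine_json <- function(t, path) {
  stopifnot(inherits(t, "affine2d"))
  m <- cbind(t$linear, t$translation)
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix), 2, 3)
  affine2d(m[, 1:2], m[, 3])
}

# coerce vectors/data.frames to an n x 2 numeric matrix
rbind2cols <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, 1:2])
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  storage.mode(xy) <- "double"
  xy
}
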