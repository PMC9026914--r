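# Per-image illumination correction: fit a full quadratic surface to the
# intensity field and subtract it, clipping at zero.

.quad_design <- function(nr, nc) {
  # normalized coordinates on [0,1]^2; x runs along columns, y along rows
  x <- if (nc > 1) (col(matrix(0, nr, nc)) - 1) / (nc - 1) else matrix(0, nr, nc)
  y <- if (nr > 1) (row(matrix(0, nr, nc)) - 1) / (nr - 1) else matrix(0, nr, nc)
  cbind(1, as.vector(x), as.vector(y),
        as.vector(x)^2, as.vector(y)^2, as.vector(x) * as.vector(y))
}

#' Fit a quadratic illumination surface to an image
#'
#' Least-squares fit of intensity on the full quadratic
#' `a + b*x + c*y + d*x^2 + e*y^2 + f*x*y` over normalized pixel
#' coordinates `(x, y) in [0,1]^2` (x along columns, y along rows). This
#' models the smooth lamp/optics bias of a wide-field acquisition; the
#' order-2 polynomial is fit per image, not pooled across the plate.
#'
#' @param image A [channel_image()] or numeric matrix with >= 6 pixels.
#' @return An `illumination_surface` with `coefficients`
#'   (named a..f) and `shape`.
#' @export
fit_polynomial_surface <- function(image) {
  px <- .pixels(image)
  if (length(px) < 6) stop("need at least 6 pixels to fit a quadratic surface")
  X <- .quad_design(nrow(px), ncol(px))
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    warning("degenerate pixel grid; using pseudo-inverse for the surface fit")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% as.vector(px)) / sv$d[keep])
    beta <- as.vector(beta)
  } else {
    beta <- qr.coef(qrX, as.vector(px))
  }
  names(beta) <- c("a", "b", "c", "d", "e", "f")
  structure(list(coefficients = beta, shape = dim(px)),
            class = "illumination_surface")
}

#' Evaluate an illumination surface on its grid
#'
#' @param surface An `illumination_surface`.
#' @param shape Optional `(rows, cols)` to evaluate on; defaults to the
#'   grid the surface was fitted on.
#' @return Numeric matrix of surface values.
#' @export
evaluate_surface <- function(surface, shape = NULL) {
  stopifnot(inherits(surface, "illumination_surface"))
  if (is.null(shape)) shape <- surface$shape
  X <- .quad_design(shape[1], shape[2])
  matrix(X %*% surface$coefficients, shape[1], shape[2])
}

#' Subtract an illumination surface from an image
#'
#' Applies `corrected = max(image - surface, 0)`. Negative fluorescence
#' is meaningless, and downstream thresholds assume non-negative input,
#' hence the clip at zero.
#'
#' @param image A [channel_image()] or matrix.
#' @param surface An `illumination_surface` fitted on the same shape, or
#'   `NULL` to fit one on the image itself.
#' @return Same type as `image`, corrected.
#' @export
subtract_illumination <- function(image, surface = NULL) {
  px <- .pixels(image)
  if (is.null(surface)) surface <- fit_polynomial_surface(px)
  if (!all(dim(px) == surface$shape))
    stop("image shape does not match the illumination surface")
  corrected <- pmax(px - evaluate_surface(surface), 0)
  if (inherits(image, "channel_image")) {
    image$pixels <- corrected
    image
  } else corrected
}

#' Illumination-correct one image in a single call
#'
#' Convenience wrapper: fit the quadratic surface on the image and
#' subtract it.
#'
#' @param image A [channel_image()] or matrix.
#' @return Corrected image of the same type.
#' @export
correct_illumination <- function(image) {
  subtract_illumination(image, fit_polynomial_surface(image))
}
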