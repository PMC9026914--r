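# Threshold computation: Otsu 2-class, Otsu 3-class, minimum cross-entropy
# (Li), manual; global or adaptive (block-wise with bilinear interpolation).
# All methods operate on intensities in [0,1]; histogram methods use a fixed
# 256-bin grid so results are reproducible across source bit depths.

#' Threshold specification
#'
#' Describes how a threshold is computed: the method, whether it is a
#' single global value or an adaptive per-pixel grid, how the middle
#' class of a three-class Otsu split is assigned, and clamp bounds.
#'
#' @param method One of `"otsu2"` (two-class Otsu), `"otsu3"`
#'   (three-class Otsu), `"min_cross_entropy"` (Li), `"manual"`.
#' @param scope `"global"` or `"adaptive"`.
#' @param middle_class For `otsu3`: assign the middle intensity class to
#'   the `"background"` (stricter; suppresses dim debris) or the
#'   `"foreground"` (permissive; keeps dim puncta).
#' @param window Adaptive block size in px (odd, >= 3).
#' @param manual_value Threshold on `[0,1]`, required iff
#'   `method = "manual"`.
#' @param bounds Length-2 clamp `(lower, upper)` applied to computed
#'   thresholds.
#' @param nbins Number of histogram bins on `[0,1]`.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(method = c("otsu2", "otsu3", "min_cross_entropy", "manual"),
                           scope = c("global", "adaptive"),
                           middle_class = c("background", "foreground"),
                           window = 51L, manual_value = NULL,
                           bounds = c(0, 1), nbins = 256L) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  middle_class <- match.arg(middle_class)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (length(bounds) != 2L || bounds[1] > bounds[2])
    stop("bounds must be (lower, upper) with lower <= upper")
  if (method == "manual") {
    if (is.null(manual_value) || manual_value < 0 || manual_value > 1)
      stop("manual method requires manual_value in [0, 1]")
  } else if (!is.null(manual_value)) {
    stop("manual_value is only meaningful for method = 'manual'")
  }
  structure(list(method = method, scope = scope, middle_class = middle_class,
                 window = window, manual_value = manual_value, bounds = bounds,
                 nbins = as.integer(nbins)),
            class = "threshold_spec")
}

.hist_counts <- function(x, nbins) {
  idx <- pmin(floor(x * nbins) + 1L, nbins)
  tabulate(idx, nbins)
}

# per-bin pixel counts and intensity sums: class means over any bin range
# are then exact (no bin-center discretization)
.hist_sums <- function(x, nbins) {
  idx <- pmin(floor(x * nbins) + 1L, nbins)
  cnt <- tabulate(idx, nbins)
  sm <- numeric(nbins)
  agg <- rowsum(x, idx)
  sm[as.integer(rownames(agg))] <- agg[, 1]
  list(cnt = cnt, sum = sm)
}

#' Two-class Otsu threshold
#'
#' Maximizes the between-class variance over all cut points of a fixed
#' 256-bin histogram on `[0,1]`. The returned threshold is the upper
#' edge of the last background bin; foreground pixels are those strictly
#' above it.
#'
#' @param x Numeric vector or matrix of intensities in `[0,1]`.
#' @param nbins Histogram bins.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.vector(.pixels(x))
  h <- .hist_sums(x, nbins)
  if (sum(h$cnt > 0) < 2L) {
    warning("degenerate histogram: constant image")
    return(x[1])
  }
  n <- length(x)
  w0 <- cumsum(h$cnt)[-nbins] / n
  mu0 <- cumsum(h$sum)[-nbins] / n
  mu_t <- sum(h$sum) / n
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, nbins - 1L)
  sb[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb)
  k / nbins
}

#' Three-class Otsu thresholds
#'
#' Exhaustive search for the two cut points maximizing the three-class
#' between-class variance on a fixed histogram. Returns both cuts; which
#' becomes the effective foreground threshold depends on where the
#' middle class is assigned (see [threshold_spec()]).
#'
#' @inheritParams otsu_threshold
#' @return Numeric length-2 vector `(lower_cut, upper_cut)`.
#' @export
otsu3_thresholds <- function(x, nbins = 256L) {
  x <- as.vector(.pixels(x))
  h <- .hist_sums(x, nbins)
  if (sum(h$cnt > 0) < 2L) {
    warning("degenerate histogram: constant image")
    return(c(x[1], x[1]))
  }
  n <- length(x)
  W <- cumsum(h$cnt) / n
  M <- cumsum(h$sum) / n
  best <- -Inf; bk <- c(1L, 2L)
  for (k1 in 1:(nbins - 2L)) {
    w0 <- W[k1]
    if (w0 == 0) next
    m0 <- M[k1] / w0
    k2 <- (k1 + 1L):(nbins - 1L)
    w1 <- W[k2] - W[k1]
    w2 <- 1 - W[k2]
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    m1 <- (M[k2] - M[k1]) / w1
    m2 <- (M[nbins] - M[k2]) / w2
    mu <- M[nbins]
    sb <- w0 * (m0 - mu)^2 + w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2
    sb[!ok] <- -Inf
    i <- which.max(sb)
    if (sb[i] > best) { best <- sb[i]; bk <- c(k1, k2[i]) }
  }
  bk / nbins
}

#' Minimum cross-entropy (Li) threshold
#'
#' Li & Lee's iterative minimum cross-entropy threshold: the fixed point
#' of `t = (mu_bg - mu_fg) / (log(mu_bg) - log(mu_fg))` where the means
#' are taken below/above the current threshold.
#'
#' @inheritParams otsu_threshold
#' @param tol Convergence tolerance on the threshold.
#' @return Scalar threshold.
#' @export
li_threshold <- function(x, tol = 0.5 / 65535) {
  x <- as.vector(.pixels(x))
  if (diff(range(x)) == 0) {
    warning("degenerate histogram: constant image")
    return(x[1])
  }
  eps <- 1e-12
  t_cur <- mean(x)
  for (iter in 1:200) {
    back <- x[x <= t_cur]
    fore <- x[x > t_cur]
    if (length(back) == 0 || length(fore) == 0) break
    mb <- max(mean(back), eps)
    mf <- max(mean(fore), eps)
    t_new <- if (abs(mb - mf) < eps) t_cur else (mb - mf) / (log(mb) - log(mf))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur
}

.global_threshold <- function(x, spec) {
  switch(spec$method,
         otsu2 = otsu_threshold(x, spec$nbins),
         otsu3 = {
           ts <- otsu3_thresholds(x, spec$nbins)
           if (spec$middle_class == "background") ts[2] else ts[1]
         },
         min_cross_entropy = li_threshold(x),
         manual = spec$manual_value)
}

#' Compute a threshold from a specification
#'
#' Global scope returns a single value; adaptive scope computes the
#' method per `window`-sized block, bilinearly interpolates block-center
#' values to a per-pixel grid, and clamps to `spec$bounds`.
#'
#' @param image A [channel_image()] or matrix.
#' @param spec A [threshold_spec()].
#' @return Scalar (global) or matrix (adaptive) of thresholds.
#' @export
compute_threshold <- function(image, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  px <- .pixels(image)
  if (length(px) == 0) stop("empty image")
  if (spec$scope == "global") {
    th <- .global_threshold(px, spec)
    return(min(max(th, spec$bounds[1]), spec$bounds[2]))
  }
  nr <- nrow(px); nc <- ncol(px); w <- spec$window
  nbr <- max(1L, ceiling(nr / w)); nbc <- max(1L, ceiling(nc / w))
  redge <- round(seq(0, nr, length.out = nbr + 1))
  cedge <- round(seq(0, nc, length.out = nbc + 1))
  block_th <- matrix(NA_real_, nbr, nbc)
  for (bi in seq_len(nbr)) {
    for (bj in seq_len(nbc)) {
      blk <- px[(redge[bi] + 1):redge[bi + 1], (cedge[bj] + 1):cedge[bj + 1]]
      if (diff(range(blk)) == 0) next  # degenerate block; filled globally below
      block_th[bi, bj] <- suppressWarnings(.global_threshold(blk, spec))
    }
  }
  if (anyNA(block_th))
    block_th[is.na(block_th)] <- suppressWarnings(.global_threshold(px, spec))
  rc <- (redge[-1] + redge[-length(redge)] + 1) / 2
  cc <- (cedge[-1] + cedge[-length(cedge)] + 1) / 2
  interp_r <- if (nbr > 1) {
    apply(block_th, 2, function(v) stats::approx(rc, v, xout = seq_len(nr), rule = 2)$y)
  } else matrix(block_th[1, ], nr, nbc, byrow = TRUE)
  grid <- if (nbc > 1) {
    t(apply(interp_r, 1, function(v) stats::approx(cc, v, xout = seq_len(nc), rule = 2)$y))
  } else matrix(interp_r[, 1], nr, nc)
  pmin(pmax(grid, spec$bounds[1]), spec$bounds[2])
}

#' Apply a threshold specification to an image
#'
#' @inheritParams compute_threshold
#' @return Logical matrix: `TRUE` where the pixel is strictly above the
#'   (local) threshold.
#' @export
apply_threshold <- function(image, spec) {
  px <- .pixels(image)
  px > compute_threshold(px, spec)
}
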