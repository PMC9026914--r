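# Mitochondrial morphology assay: tubeness enhancement of the network
# channel, global minimum-cross-entropy segmentation, a grayscale granular
# spectrum as the fragmentation readout, and skeleton endpoint geodesic
# distances as the length readout.

#' Enhance tubular structures (Hessian tubeness)
#'
#' Smooths the image at scale `scale_sigma`, computes the Hessian by
#' central finite differences, and responds with `|lambda2|` where
#' `lambda2` is the more-negative Hessian eigenvalue (ridges are dark in
#' the second derivative across the tube); non-ridge pixels
#' (`lambda2 >= 0`) are clamped to zero and the response is rescaled to
#' `[0, 1]`. Elongated ridges score above isotropic blobs of the same
#' height because smoothing attenuates blobs in two directions.
#'
#' @param image A [channel_image()] or matrix.
#' @param scale_sigma Gaussian smoothing scale in px (> 0); choose about
#'   half the expected tube width.
#' @return Enhanced image of the same type.
#' @export
enhance_tubeness <- function(image, scale_sigma = 1.5) {
  if (scale_sigma <= 0) stop("scale_sigma must be > 0")
  px <- .pixels(image)
  g <- .as_matrix(EBImage::gblur(px, sigma = scale_sigma))
  nr <- nrow(g); nc <- ncol(g)
  # replicate-padded central second differences
  up    <- g[c(1, 1:(nr - 1)), ]; down  <- g[c(2:nr, nr), ]
  left  <- g[, c(1, 1:(nc - 1))]; right <- g[, c(2:nc, nc)]
  lrr <- up + down - 2 * g       # d2/drow2
  lcc <- left + right - 2 * g    # d2/dcol2
  ul <- g[c(1, 1:(nr - 1)), c(1, 1:(nc - 1))]
  dr <- g[c(2:nr, nr), c(2:nc, nc)]
  ur <- g[c(1, 1:(nr - 1)), c(2:nc, nc)]
  dl <- g[c(2:nr, nr), c(1, 1:(nc - 1))]
  lrc <- (ul + dr - ur - dl) / 4
  tr <- lrr + lcc
  disc <- sqrt(pmax((lrr - lcc)^2 + 4 * lrc^2, 0))
  lambda2 <- (tr - disc) / 2     # the more-negative eigenvalue
  resp <- pmax(-lambda2, 0)
  resp[lambda2 >= 0] <- 0
  m <- max(resp)
  if (m > 0) resp <- resp / m
  if (inherits(image, "channel_image")) { image$pixels <- resp; image }
  else resp
}

#' Segment mitochondria from a tubeness-enhanced image
#'
#' Binary mask = enhanced intensity at or above the larger of the Li
#' minimum-cross-entropy threshold and `manual_floor`; objects are then
#' labeled and filtered to the mitochondrial diameter window.
#'
#' @param enhanced Output of [enhance_tubeness()].
#' @param spec A [threshold_spec()] (default global minimum
#'   cross-entropy).
#' @param manual_floor Lower manual bound on the threshold, `[0, 1]`.
#' @param diameter_range `(min, max)` equivalent object diameter, px.
#' @return Integer label matrix of mitochondrial objects.
#' @export
segment_mitochondria <- function(enhanced,
                                 spec = threshold_spec("min_cross_entropy"),
                                 manual_floor = 0.1,
                                 diameter_range = c(3, 100)) {
  px <- .pixels(enhanced)
  th <- max(compute_threshold(px, spec), manual_floor)
  mask <- px >= th
  labels <- label_objects(mask)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) {
    area <- as.vector(table(factor(labels[labels > 0], levels = ids)))
    dia <- 2 * sqrt(area / pi)
    drop <- ids[dia < diameter_range[1] | dia > diameter_range[2]]
    if (length(drop) > 0) labels[labels %in% drop] <- 0L
  }
  relabel_objects(labels)
}

#' Grayscale granular spectrum of a region
#'
#' Granulometry by iterated erosion and morphological reconstruction:
#' after optional downsampling and background removal (subtracting the
#' grayscale opening with a disk of radius `element_size`), the region
#' intensity `I_0` is eroded one step at a time (3x3 structuring
#' element); after each erosion the image is reconstructed under the
#' background-removed original and the remaining intensity `I_i`
#' recorded. Spectrum element `g_i = 100 (I_{i-1} - I_i) / I_0` is the
#' percentage of intensity living at granule scale `i`: fragmented
#' (punctate) mitochondria concentrate the spectrum in the first bins,
#' tubular networks spread it to larger scales.
#'
#' @param image Intensity image (typically the raw mitochondrial
#'   channel).
#' @param region Logical or label matrix restricting the measurement
#'   (e.g. one cell's cytoplasm); `NULL` uses the whole frame.
#' @param subsample Downsampling fraction in `(0, 1]`.
#' @param element_size Background-removal disk radius in px (on the
#'   downsampled grid).
#' @param length Number of spectrum elements `L`.
#' @return A `granularity_spectrum`: list with `values` (length `L`,
#'   percentages), `element_size`, `subsample`.
#' @export
granularity_spectrum <- function(image, region = NULL, subsample = 0.25,
                                 element_size = 10, length = 16L) {
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  px <- .pixels(image)
  if (is.null(region)) region <- matrix(TRUE, nrow(px), ncol(px))
  region <- .as_matrix(region) > 0
  if (!all(dim(region) == dim(px))) stop("region and image shapes differ")
  if (!any(region)) stop("region is empty")
  # crop to the region bounding box
  ri <- range(which(rowSums(region) > 0)); ci <- range(which(colSums(region) > 0))
  px <- px[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  region <- region[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
  px[!region] <- 0
  if (subsample < 1) {
    w <- max(3L, round(nrow(px) * subsample))
    h <- max(3L, round(ncol(px) * subsample))
    px <- .as_matrix(EBImage::resize(px, w = w, h = h))
    region <- .as_matrix(EBImage::resize(region * 1, w = w, h = h)) > 0.5
    if (!any(region)) region <- matrix(TRUE, nrow(px), ncol(px))
  }
  brush <- .disc_kernel(element_size)
  bg <- pmax(px - .as_matrix(EBImage::opening(px, brush)), 0)
  values <- numeric(length)
  i0 <- sum(bg[region])
  if (i0 <= 0) {
    warning("zero total intensity in region; granular spectrum is all zero")
  } else {
    kern <- EBImage::makeBrush(3, shape = "box")
    ero <- bg
    prev <- i0
    for (i in seq_len(length)) {
      ero <- .as_matrix(EBImage::erode(ero, kern))
      rec <- cpp_reconstruct_gray(ero, bg)
      cur <- sum(rec[region])
      values[i] <- 100 * (prev - cur) / i0
      prev <- cur
    }
  }
  structure(list(values = values, element_size = element_size,
                 subsample = subsample),
            class = "granularity_spectrum")
}

#' @export
print.granularity_spectrum <- function(x, ...) {
  cat("<granularity_spectrum> L =", length(x$values),
      " total removed:", sprintf("%.1f%%", sum(x$values)), "\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Fragmentation percentage from a granular spectrum
#'
#' Sum of the first `k` spectrum elements: the percentage of intensity
#' residing at granule scales up to `k`. The default `k = 1` reads out
#' the smallest scale, which rises as the network fragments into
#' puncta.
#'
#' @param spectrum A [granularity_spectrum()].
#' @param k Number of leading spectrum elements to sum.
#' @return Percentage in `[0, 100]`.
#' @export
fragmentation_percent <- function(spectrum, k = 1L) {
  stopifnot(inherits(spectrum, "granularity_spectrum"))
  if (k < 1 || k > length(spectrum$values)) stop("k must be in 1..L")
  sum(spectrum$values[seq_len(k)])
}

#' Skeleton endpoints
#'
#' @param skeleton Logical matrix (1-px skeleton).
#' @return Two-column matrix of 1-based (row, col) endpoint positions:
#'   skeleton pixels with exactly one 8-connected skeleton neighbour.
#' @export
skeleton_endpoints <- function(skeleton) {
  sk <- .as_matrix(skeleton) > 0
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk
  nbr <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr <- nbr + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  which(sk & nbr == 1L, arr.ind = TRUE)
}

.skeleton_edges <- function(skeleton) {
  # Adjacency of skeleton pixels: axial steps weigh 1, diagonal steps
  # sqrt(2). A diagonal edge is included only when neither of its two
  # orthogonal "stepping-stone" pixels is itself on the skeleton, so
  # the path never cuts the corner of an axial bend (an L of two 10-px
  # arms measures 18, not 16 + sqrt(2)).
  sk <- which(skeleton, arr.ind = TRUE)
  n <- nrow(sk)
  id <- matrix(0L, nrow(skeleton), ncol(skeleton))
  id[sk] <- seq_len(n)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nrow(skeleton) & c >= 1 & c <= ncol(skeleton)
    v <- logical(length(r)); v[ok] <- skeleton[cbind(r[ok], c[ok])]
    v
  }
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- sk[, 1] + off[1]; cc <- sk[, 2] + off[2]
    ok <- at(rr, cc)
    if (all(off != 0)) {
      stone1 <- at(sk[, 1] + off[1], sk[, 2])
      stone2 <- at(sk[, 1], sk[, 2] + off[2])
      ok <- ok & !stone1 & !stone2
    }
    if (!any(ok)) next
    w <- if (all(off != 0)) sqrt(2) else 1
    edges <- rbind(edges, cbind(id[sk[ok, , drop = FALSE]],
                                id[cbind(rr[ok], cc[ok])], w))
  }
  list(n = n, id = id, edges = edges)
}

.skeleton_geodesic <- function(skeleton, endpoints) {
  # all-pairs endpoint geodesic distances along the skeleton
  if (nrow(endpoints) < 2) return(numeric(0))
  eg <- .skeleton_edges(skeleton)
  if (eg$n == 0) return(numeric(0))
  ep_id <- eg$id[endpoints]
  if (is.null(eg$edges)) return(rep(Inf, choose(nrow(endpoints), 2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = eg$edges[, 1], to = eg$edges[, 2],
               weight = eg$edges[, 3]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(eg$n)))
  d <- igraph::distances(g, v = as.character(ep_id), to = as.character(ep_id))
  d[upper.tri(d)]
}

.skeleton_total_length <- function(skeleton) {
  # total branch length: minimum spanning tree weight of the skeleton graph
  eg <- .skeleton_edges(skeleton)
  if (eg$n < 2 || is.null(eg$edges)) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = eg$edges[, 1], to = eg$edges[, 2],
               weight = eg$edges[, 3]),
    directed = FALSE, vertices = data.frame(name = seq_len(eg$n)))
  sum(igraph::E(igraph::mst(g))$weight)
}

#' Skeletonize mitochondria and measure endpoint geodesic lengths
#'
#' Each mitochondrial object is thinned to a 1-px skeleton (Zhang-Suen
#' thinning); endpoints are skeleton pixels with exactly one 8-connected
#' skeleton neighbour. With `summary = "longest_path"` (default) the
#' object's length is the maximum pairwise geodesic distance between
#' endpoints along the skeleton (steps weigh 1 axially and sqrt(2)
#' diagonally); with `summary = "total"` it is the total branch length
#' (sum of edge weights of the skeleton's spanning tree). Objects with
#' fewer than two endpoints contribute length 0 and are flagged.
#' Per-cell means are taken over objects whose centroid lies in the
#' cell.
#'
#' @param mito Integer label matrix of mitochondrial objects.
#' @param cells Integer label matrix of cells on the same grid (or
#'   `NULL` to report per-object results only).
#' @param pixel_size_um Micrometres per pixel for the µm conversion.
#' @param summary `"longest_path"` or `"total"`.
#' @return A `skeleton_result`: list with `objects` (per-object
#'   `data.frame`: `object`, `cell`, `n_endpoints`, `length_px`,
#'   `length_um`, `degenerate`) and `per_cell` (`cell`,
#'   `n_mitochondria`, `mean_length_px`, `mean_length_um`).
#' @export
skeletonize_and_measure <- function(mito, cells = NULL, pixel_size_um = 0.299,
                                    summary = c("longest_path", "total")) {
  summary <- match.arg(summary)
  mito <- .as_matrix(mito)
  if (!is.null(cells)) {
    cells <- .as_matrix(cells)
    if (!all(dim(mito) == dim(cells))) stop("mito and cells shapes differ")
  }
  ids <- sort(unique(mito[mito > 0]))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    i <- ids[k]
    pos <- which(mito == i, arr.ind = TRUE)
    rpad <- 1L
    r0 <- max(1L, min(pos[, 1]) - rpad); r1 <- min(nrow(mito), max(pos[, 1]) + rpad)
    c0 <- max(1L, min(pos[, 2]) - rpad); c1 <- min(ncol(mito), max(pos[, 2]) + rpad)
    sub <- mito[r0:r1, c0:c1, drop = FALSE] == i
    skel <- cpp_thin(sub)
    ep <- skeleton_endpoints(skel)
    len <- 0
    degenerate <- nrow(ep) < 2
    if (!degenerate) {
      if (summary == "longest_path") {
        d <- .skeleton_geodesic(skel, ep)
        d <- d[is.finite(d)]
        if (length(d) > 0) len <- max(d) else degenerate <- TRUE
      } else {
        len <- .skeleton_total_length(skel)
      }
    }
    cen <- round(colMeans(pos))  # 1-based (row, col)
    cell <- if (is.null(cells)) NA_integer_ else cells[cen[1], cen[2]]
    rows[[k]] <- data.frame(object = i,
                            cell = ifelse(!is.na(cell) && cell > 0, cell,
                                          NA_integer_),
                            n_endpoints = nrow(ep), length_px = len,
                            length_um = len * pixel_size_um,
                            degenerate = degenerate)
  }
  objects <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(object = integer(0), cell = integer(0), n_endpoints = integer(0),
               length_px = numeric(0), length_um = numeric(0),
               degenerate = logical(0))
  rownames(objects) <- NULL
  with_cell <- objects[!is.na(objects$cell), , drop = FALSE]
  per_cell <- if (nrow(with_cell) > 0) {
    agg <- stats::aggregate(cbind(length_px, length_um) ~ cell,
                            data = with_cell, FUN = mean)
    cnt <- stats::aggregate(object ~ cell, data = with_cell, FUN = length)
    data.frame(cell = agg$cell, n_mitochondria = cnt$object,
               mean_length_px = agg$length_px, mean_length_um = agg$length_um)
  } else {
    data.frame(cell = integer(0), n_mitochondria = integer(0),
               mean_length_px = numeric(0), mean_length_um = numeric(0))
  }
  structure(list(objects = objects, per_cell = per_cell),
            class = "skeleton_result")
}
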