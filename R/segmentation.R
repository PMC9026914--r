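# Object segmentation front end shared by all assays: nuclei (primary),
# whole cells (secondary, seeded propagation), cytoplasm (tertiary), object
# measurements and rule-based filtering. Conventions used throughout the
# package: 8-connectivity, integer labels with 0 = background, labels
# compacted to 1..n after any filtering step.

#' Label connected foreground components (8-connectivity)
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels `0..n`, with attribute `n_objects`.
#' @export
label_objects <- function(mask) {
  mask <- .as_matrix(mask)
  storage.mode(mask) <- "logical"
  cpp_label8(mask)
}

#' Compact object labels to 1..n
#'
#' Removes gaps in the label sequence while preserving the relative
#' order of surviving labels.
#'
#' @param labels Integer label matrix.
#' @return Relabeled integer matrix with attribute `n_objects`.
#' @export
relabel_objects <- function(labels) {
  labels <- .as_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(ids) > 0) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- labels > 0
    out[pos] <- lut[labels[pos]]
  }
  attr(out, "n_objects") <- length(ids)
  out
}

.n_objects <- function(labels) {
  n <- attr(labels, "n_objects")
  if (is.null(n)) n <- max(0L, max(labels))
  n
}

.border_labels <- function(labels) {
  unique(c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)]))
}

#' Measure per-object features
#'
#' Computes area, centroid (0-based row/col pixel indices), equivalent
#' diameter, eccentricity (from central second moments; 0 for a disk,
#' approaching 1 for a line), border contact, and mean/integrated
#' intensity for each named intensity channel.
#'
#' @param labels Integer label matrix.
#' @param intensity_images Named list of matrices / [channel_image()]s
#'   on the same grid.
#' @return `data.frame`, one row per object: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `eq_diameter`, `eccentricity`,
#'   `touches_border`, and `mean_<name>` / `integrated_<name>` columns.
#' @export
measure_objects <- function(labels, intensity_images = list()) {
  labels <- .as_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    df <- data.frame(label = integer(0), area = numeric(0),
                     centroid_row = numeric(0), centroid_col = numeric(0),
                     eq_diameter = numeric(0), eccentricity = numeric(0),
                     touches_border = logical(0))
    for (nm in names(intensity_images)) {
      df[[paste0("mean_", nm)]] <- numeric(0)
      df[[paste0("integrated_", nm)]] <- numeric(0)
    }
    return(df)
  }
  pos <- which(labels > 0)
  lab <- labels[pos]
  f <- factor(lab, levels = ids)
  rr <- (pos - 1L) %% nrow(labels)        # 0-based row index
  cc <- (pos - 1L) %/% nrow(labels)       # 0-based col index
  area <- as.vector(table(f))
  s_r <- rowsum(as.numeric(rr), f)[, 1]
  s_c <- rowsum(as.numeric(cc), f)[, 1]
  cen_r <- s_r / area
  cen_c <- s_c / area
  # central second moments
  mu_rr <- rowsum(as.numeric(rr)^2, f)[, 1] / area - cen_r^2
  mu_cc <- rowsum(as.numeric(cc)^2, f)[, 1] / area - cen_c^2
  mu_rc <- rowsum(as.numeric(rr) * cc, f)[, 1] / area - cen_r * cen_c
  tr <- mu_rr + mu_cc
  det_part <- sqrt(pmax((mu_rr - mu_cc)^2 + 4 * mu_rc^2, 0))
  l1 <- (tr + det_part) / 2
  l2 <- (tr - det_part) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  border <- ids %in% .border_labels(labels)
  df <- data.frame(label = ids, area = area,
                   centroid_row = cen_r, centroid_col = cen_c,
                   eq_diameter = 2 * sqrt(area / pi),
                   eccentricity = ecc, touches_border = border)
  for (nm in names(intensity_images)) {
    px <- .pixels(intensity_images[[nm]])
    tot <- rowsum(px[pos], f)[, 1]
    df[[paste0("mean_", nm)]] <- tot / area
    df[[paste0("integrated_", nm)]] <- tot
  }
  rownames(df) <- NULL
  df
}

#' Identify primary objects (nuclei)
#'
#' Threshold, label 8-connected components, optionally fill holes,
#' discard components whose equivalent diameter falls outside
#' `diameter_range`, optionally discard border-touching components, and
#' compact labels.
#'
#' @param image A [channel_image()] or matrix.
#' @param spec A [threshold_spec()].
#' @param diameter_range `(min, max)` equivalent diameter in px.
#' @param fill_holes Fill holes inside each object.
#' @param exclude_border Drop objects touching the image edge.
#' @return Integer label matrix with attribute `n_objects`.
#' @export
identify_primary <- function(image, spec = threshold_spec("otsu3"),
                             diameter_range = c(8, 100),
                             fill_holes = TRUE, exclude_border = FALSE) {
  if (diameter_range[1] > diameter_range[2])
    stop("diameter_range must be (min, max) with min <= max")
  px <- .pixels(image)
  mask <- px > compute_threshold(px, spec)
  labels <- label_objects(mask)
  if (fill_holes && .n_objects(labels) > 0)
    labels <- .as_matrix(EBImage::fillHull(labels))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) > 0) {
    area <- as.vector(table(factor(labels[labels > 0], levels = ids)))
    dia <- 2 * sqrt(area / pi)
    drop <- ids[dia < diameter_range[1] | dia > diameter_range[2]]
    if (exclude_border) drop <- union(drop, .border_labels(labels))
    if (length(drop) > 0) labels[labels %in% drop] <- 0L
  }
  relabel_objects(labels)
}

#' Identify secondary objects by seeded propagation
#'
#' Grows each seed (primary object) outwards over the above-threshold
#' region of `image`, CellProfiler-style: a pixel joins the seed
#' reachable at minimal accumulated cost, where the step cost blends the
#' local intensity difference with a spatial regularization term
#' (`regularization`; larger values push the dividing lines between
#' touching cells towards the geometric midline). Every seed is
#' contained in its secondary object.
#'
#' @param image Intensity image guiding propagation.
#' @param seeds Integer label matrix of primary objects.
#' @param spec A [threshold_spec()] for the cell-body region.
#' @param regularization Non-negative propagation regularization.
#' @return Integer label matrix; labels correspond one-to-one with seed
#'   labels.
#' @export
identify_secondary_propagation <- function(image, seeds,
                                           spec = threshold_spec("otsu3",
                                             middle_class = "foreground"),
                                           regularization = 0.05) {
  if (regularization < 0) stop("regularization must be >= 0")
  px <- .pixels(image)
  seeds <- .as_matrix(seeds)
  if (!all(dim(px) == dim(seeds))) stop("image and seeds shapes differ")
  if (all(seeds == 0)) stop("seeds are empty")
  mask <- px > compute_threshold(px, spec)
  below <- setdiff(unique(seeds[seeds > 0 & !mask]), unique(seeds[seeds > 0 & mask]))
  if (length(below) > 0)
    warning("seed(s) entirely below threshold; secondary equals the seed for: ",
            paste(below, collapse = ", "))
  mask <- mask | seeds > 0   # each secondary object contains its seed
  out <- EBImage::propagate(x = px, seeds = seeds, mask = mask,
                            lambda = regularization)
  out <- .as_matrix(out)
  storage.mode(out) <- "integer"
  attr(out, "n_objects") <- length(unique(out[out > 0]))
  out
}

#' Identify tertiary objects (cytoplasm)
#'
#' Subtracts each primary object from the secondary object sharing its
#' label: `tertiary_i = secondary_i \ primary_i`.
#'
#' @param secondary,primary Integer label matrices with corresponding
#'   label ids.
#' @return Integer label matrix of tertiary objects (labels preserved
#'   from the secondary map).
#' @export
identify_tertiary <- function(secondary, primary) {
  secondary <- .as_matrix(secondary); primary <- .as_matrix(primary)
  if (!all(dim(secondary) == dim(primary)))
    stop("secondary and primary shapes differ")
  orphan <- setdiff(unique(primary[primary > 0]), unique(secondary[secondary > 0]))
  if (length(orphan) > 0)
    warning("primary label(s) with no matching secondary object skipped: ",
            paste(orphan, collapse = ", "))
  out <- secondary
  out[primary > 0 & primary == secondary] <- 0L
  storage.mode(out) <- "integer"
  attr(out, "n_objects") <- length(unique(out[out > 0]))
  out
}

#' Filter objects by feature criteria
#'
#' Removes objects failing any `(feature, min, max)` criterion, and
#' optionally objects touching the image border; survivors are
#' relabeled 1..n preserving order. Applying the same filter twice is
#' the identity.
#'
#' @param labels Integer label matrix.
#' @param measurements Output of [measure_objects()] on the same labels
#'   (computed internally when `NULL`).
#' @param criteria List of `list(feature, min, max)` entries; `feature`
#'   names a `measurements` column (e.g. `"area"`, `"eccentricity"`,
#'   `"mean_<channel>"`). Use `-Inf`/`Inf` for open bounds.
#' @param drop_border Drop objects touching the image edge.
#' @return Filtered, compacted label matrix.
#' @export
filter_objects <- function(labels, measurements = NULL, criteria = list(),
                           drop_border = FALSE) {
  labels <- .as_matrix(labels)
  if (is.null(measurements)) measurements <- measure_objects(labels)
  keep <- measurements$label
  for (cr in criteria) {
    feat <- cr[[1]]
    if (!feat %in% names(measurements))
      stop("unknown feature '", feat, "'; available: ",
           paste(setdiff(names(measurements), "label"), collapse = ", "))
    v <- measurements[[feat]][match(keep, measurements$label)]
    lo <- if (length(cr) >= 2 && !is.null(cr[[2]])) cr[[2]] else -Inf
    hi <- if (length(cr) >= 3 && !is.null(cr[[3]])) cr[[3]] else Inf
    keep <- keep[v >= lo & v <= hi]
  }
  if (drop_border) {
    tb <- measurements$label[measurements$touches_border]
    keep <- setdiff(keep, tb)
  }
  out <- labels
  out[!(out %in% keep)] <- 0L
  relabel_objects(out)
}
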