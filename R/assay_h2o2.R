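# Mitochondrial H2O2 assay: enhance MitoPY1-like speckles with a white
# top-hat, detect puncta, relate them to cells, and score each cell by the
# fraction of its mitochondrial-mask area covered by puncta.

#' Enhance speckle-like features (white top-hat)
#'
#' Subtracts the grayscale opening with a disk of radius
#' `ceiling(feature_size / 2)` from the image, keeping bright regions
#' smaller than the structuring element and flattening everything
#' broader. With the default `feature_size` equal to the largest
#' expected punctum diameter, no valid punctum is suppressed.
#'
#' @param image A [channel_image()] or matrix.
#' @param feature_size Expected maximal feature diameter in px (>= 1).
#' @return Enhanced image of the same type; intensities are >= 0.
#' @export
enhance_speckles <- function(image, feature_size = 35) {
  if (feature_size < 1) stop("feature_size must be >= 1")
  px <- .pixels(image)
  brush <- .disc_kernel(ceiling(feature_size / 2))
  enhanced <- pmax(.as_matrix(EBImage::whiteTopHat(px, brush)), 0)
  if (inherits(image, "channel_image")) { image$pixels <- enhanced; image }
  else enhanced
}

#' Detect fluorescent puncta
#'
#' Identifies speckles on a speckle-enhanced image with an adaptive
#' three-class Otsu threshold (middle class kept as foreground so dim
#' puncta survive) and a puncta-scale diameter window. When the spec's
#' bounds are left at the default `(0, 1)`, the adaptive grid is
#' clamped from below at `max(0.05, 0.7 x global Otsu)`: blocks without
#' structure would otherwise threshold inside the noise of the enhanced
#' channel.
#'
#' @param enhanced Output of [enhance_speckles()].
#' @param spec A [threshold_spec()].
#' @param diameter_range `(min, max)` equivalent punctum diameter, px.
#' @return A `puncta_set`: list with `labels` (label matrix), `table`
#'   (per-punctum measurements with a `parent_cell` column, `NA` until
#'   related to cells).
#' @export
detect_puncta <- function(enhanced,
                          spec = threshold_spec("otsu3", scope = "adaptive",
                                                middle_class = "foreground"),
                          diameter_range = c(3, 35)) {
  spec <- .floor_adaptive_at_global(spec, enhanced)
  labels <- identify_primary(enhanced, spec, diameter_range,
                             fill_holes = FALSE, exclude_border = FALSE)
  tab <- measure_objects(labels, list(intensity = .pixels(enhanced)))
  tab$parent_cell <- rep(NA_integer_, nrow(tab))
  structure(list(labels = labels, table = tab), class = "puncta_set")
}

# Adaptive thresholds in structure-free blocks collapse into the noise;
# unless the caller set explicit bounds, clamp the adaptive grid from
# below at 70% of the global two-class Otsu threshold, and never below
# 5% of the dynamic range (an absolute noise floor for enhanced
# channels, whose true background is near zero).
.floor_adaptive_at_global <- function(spec, image) {
  if (spec$scope == "adaptive" && identical(spec$bounds, c(0, 1))) {
    g <- suppressWarnings(otsu_threshold(.pixels(image), spec$nbins))
    spec$bounds <- c(max(0.05, 0.7 * g), 1)
  }
  spec
}

#' Relate puncta to parent cells
#'
#' Assigns each punctum to the cell whose region contains the punctum
#' centroid (rounded to the nearest pixel); centroids on background get
#' no parent and are excluded from per-cell sums.
#'
#' @param puncta A `puncta_set` from [detect_puncta()].
#' @param cells Integer label matrix of cells on the same grid.
#' @return The `puncta_set` with `parent_cell` filled in.
#' @export
relate_puncta_to_cells <- function(puncta, cells) {
  cells <- .as_matrix(cells)
  if (!all(dim(puncta$labels) == dim(cells)))
    stop("puncta and cells are on different grids")
  if (nrow(puncta$table) > 0) {
    # centroids are 0-based; convert to 1-based matrix indices
    ri <- pmin(pmax(round(puncta$table$centroid_row) + 1L, 1L), nrow(cells))
    ci <- pmin(pmax(round(puncta$table$centroid_col) + 1L, 1L), ncol(cells))
    parent <- cells[cbind(ri, ci)]
    puncta$table$parent_cell <- ifelse(parent > 0, parent, NA_integer_)
  }
  puncta
}

#' Per-cell mitochondrial H2O2 level
#'
#' For each cell, the colocalized area is the footprint of the puncta
#' related to that cell intersected with the mitochondrial mask inside
#' the cell; the H2O2 level is that area divided by the cell's
#' mitochondrial-mask area (or by the puncta footprint area with
#' `denominator = "puncta"`). Cells without any mitochondrial-mask area
#' are excluded, not reported as zero; the exclusion count is attached
#' as attribute `n_excluded`.
#'
#' @param puncta A `puncta_set` related to cells
#'   (see [relate_puncta_to_cells()]).
#' @param mito_mask Logical matrix (thresholded mitochondrial channel)
#'   or label matrix treated as a mask.
#' @param cells Integer label matrix of cells.
#' @param denominator `"mito"` (default) or `"puncta"`.
#' @return `data.frame` with columns `cell`, `mito_area`, `coloc_area`,
#'   `n_puncta`, `h2o2_level`.
#' @export
mito_h2o2_level <- function(puncta, mito_mask, cells,
                            denominator = c("mito", "puncta")) {
  denominator <- match.arg(denominator)
  cells <- .as_matrix(cells)
  mito_mask <- .as_matrix(mito_mask) > 0
  if (!all(dim(mito_mask) == dim(cells)))
    stop("mito_mask and cells are on different grids")
  ids <- sort(unique(cells[cells > 0]))
  if (length(ids) == 0) {
    out <- data.frame(cell = integer(0), mito_area = numeric(0),
                      coloc_area = numeric(0), n_puncta = integer(0),
                      h2o2_level = numeric(0))
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  f <- factor(cells[cells > 0], levels = ids)
  mito_area <- rowsum(as.numeric(mito_mask[cells > 0]), f)[, 1]
  # footprint of puncta whose parent is this cell
  related <- puncta$table$label[!is.na(puncta$table$parent_cell)]
  parent_of <- puncta$table$parent_cell[match(puncta$labels, puncta$table$label)]
  parent_of[is.na(parent_of)] <- 0L
  dim(parent_of) <- dim(puncta$labels)
  coloc_px <- puncta$labels > 0 & parent_of == cells & mito_mask & cells > 0
  coloc_area <- rowsum(as.numeric(coloc_px[cells > 0]), f)[, 1]
  pf <- puncta$table$parent_cell[!is.na(puncta$table$parent_cell)]
  n_puncta <- as.vector(table(factor(pf, levels = ids)))
  # puncta footprint inside the cell (alternative denominator)
  pa_px <- puncta$labels > 0 & parent_of == cells & cells > 0
  puncta_area <- rowsum(as.numeric(pa_px[cells > 0]), f)[, 1]
  denom <- if (denominator == "mito") mito_area else puncta_area
  keep <- denom > 0
  out <- data.frame(cell = ids, mito_area = mito_area,
                    coloc_area = coloc_area, n_puncta = n_puncta,
                    h2o2_level = ifelse(keep, coloc_area / denom, NA_real_))
  excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
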