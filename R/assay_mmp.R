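# Mitochondrial membrane potential assay: JC-10 ratio imaging. Orange
# J-aggregates (polarized mitochondria) and green J-monomers (cytosol) are
# mutually masked; the per-cell orange/green mean-intensity ratio reports
# membrane potential, falling as mitochondria depolarize.

#' Detect J-aggregates in the orange channel
#'
#' Small bright dots (3-15 px diameter by default) found with an
#' adaptive three-class Otsu threshold on the illumination-corrected
#' Rhodamine channel. Default-bounds specs get the same noise-floor
#' clamp as [detect_puncta()].
#'
#' @param orange A [channel_image()] or matrix (orange/Rhodamine
#'   channel).
#' @param spec A [threshold_spec()].
#' @param diameter_range `(min, max)` aggregate diameter, px.
#' @return Integer label matrix of aggregates.
#' @export
detect_aggregates <- function(orange,
                              spec = threshold_spec("otsu3", scope = "adaptive",
                                                    middle_class = "foreground"),
                              diameter_range = c(3, 15)) {
  spec <- .floor_adaptive_at_global(spec, orange)
  identify_primary(orange, spec, diameter_range,
                   fill_holes = FALSE, exclude_border = FALSE)
}

#' Mask objects by a region (keep overlapping, retain labels)
#'
#' Clips every target object to its intersection with `mask_region`;
#' objects left empty are removed; survivors keep their original label
#' ids. Idempotent, and never increases any object's area.
#'
#' @param target Integer label matrix.
#' @param mask_region Logical matrix, or label matrix treated as a mask
#'   (any positive label).
#' @return Masked label matrix (labels retained, not compacted).
#' @export
mask_objects <- function(target, mask_region) {
  target <- .as_matrix(target)
  mask_region <- .as_matrix(mask_region) > 0
  if (!all(dim(target) == dim(mask_region)))
    stop("target and mask_region are on different grids")
  out <- target
  out[!mask_region] <- 0L
  storage.mode(out) <- "integer"
  attr(out, "n_objects") <- length(unique(out[out > 0]))
  out
}

#' Per-cell JC-10 orange/green intensity ratio
#'
#' For each cell `i` (a monomer secondary object): `A*` is the aggregate
#' footprint clipped to the cell's monomer region; `M*` is, under the
#' default literal reading, the monomer region clipped to the union of
#' aggregate footprints ("monomers masked by aggregates"), or its
#' complement within the monomer region with
#' `monomer_mask = "complement"`. The ratio is the mean orange intensity
#' over `A*` divided by the mean green intensity over `M*`. Cells with
#' either region empty are excluded and counted in attribute
#' `n_excluded`.
#'
#' @param aggregates Integer label matrix from [detect_aggregates()].
#' @param monomers Integer label matrix of monomer secondary objects
#'   (one per cell, seeded by nuclei).
#' @param orange,green Intensity images (matrices or
#'   [channel_image()]s).
#' @param cells Optional cell label matrix; defaults to `monomers`.
#' @param monomer_mask `"aggregates"` (literal; green under aggregate
#'   footprints) or `"complement"` (green outside aggregates).
#' @return `data.frame` with `cell`, `aggregate_masked_area`,
#'   `monomer_masked_area`, `mean_orange`, `mean_green`, `mmp_ratio`.
#' @export
mmp_ratio_per_cell <- function(aggregates, monomers, orange, green,
                               cells = NULL,
                               monomer_mask = c("aggregates", "complement")) {
  monomer_mask <- match.arg(monomer_mask)
  aggregates <- .as_matrix(aggregates)
  monomers <- .as_matrix(monomers)
  if (is.null(cells)) cells <- monomers else cells <- .as_matrix(cells)
  opx <- .pixels(orange); gpx <- .pixels(green)
  stopifnot(all(dim(aggregates) == dim(monomers)),
            all(dim(opx) == dim(monomers)), all(dim(gpx) == dim(monomers)))
  agg_union <- aggregates > 0
  ids <- sort(unique(cells[cells > 0]))
  rows <- vector("list", length(ids))
  excluded <- 0L
  for (k in seq_along(ids)) {
    i <- ids[k]
    region_m <- monomers == i & cells == i
    a_star <- agg_union & region_m
    m_star <- if (monomer_mask == "aggregates") region_m & agg_union
              else region_m & !agg_union
    na <- sum(a_star); nm <- sum(m_star)
    if (na == 0 || nm == 0) { excluded <- excluded + 1L; next }
    mo <- mean(opx[a_star]); mg <- mean(gpx[m_star])
    if (mg <= 0) {
      warning("cell ", i, " has zero mean green intensity; excluded")
      excluded <- excluded + 1L
      next
    }
    rows[[k]] <- data.frame(cell = i, aggregate_masked_area = na,
                            monomer_masked_area = nm,
                            mean_orange = mo, mean_green = mg,
                            mmp_ratio = mo / mg)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cell = integer(0), aggregate_masked_area = numeric(0),
                      monomer_masked_area = numeric(0), mean_orange = numeric(0),
                      mean_green = numeric(0), mmp_ratio = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
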