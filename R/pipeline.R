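# End-to-end pipelines: shared segmentation front end, one analysis
# function per assay, plate-level drivers, and the run_pipeline() entry
# point the command-line wrapper calls.

#' Default analysis parameters
#'
#' All tunable parameters of the three assays with the package defaults,
#' suitable for full-resolution (1080 px, 0.299 um/px) acquisitions.
#' Every leaf can be overridden via the config (see [run_pipeline()]).
#'
#' @return Nested list of parameters.
#' @export
default_params <- function() {
  list(
    pixel_size_um = 0.299,
    illumination_correction = TRUE,
    nucleus = list(
      spec = threshold_spec("otsu3", middle_class = "background"),
      diameter_range = c(8, 100),
      area = c(100, 10000),
      eccentricity_max = 0.95),
    cell = list(
      spec = threshold_spec("otsu3", middle_class = "foreground"),
      regularization = 0.05,
      drop_border = TRUE),
    h2o2 = list(
      feature_size = 35,
      puncta_spec = threshold_spec("otsu3", scope = "adaptive",
                                   middle_class = "foreground"),
      puncta_diameter = c(3, 35),
      mito_spec = threshold_spec("otsu3", middle_class = "background"),
      denominator = "mito"),
    mmp = list(
      aggregate_spec = threshold_spec("otsu3", scope = "adaptive",
                                      middle_class = "foreground"),
      aggregate_diameter = c(3, 15),
      monomer_mask = "aggregates"),
    morphology = list(
      scale_sigma = 1.5,
      mito_spec = threshold_spec("min_cross_entropy"),
      manual_floor = 0.1,
      mito_diameter = c(3, 100),
      granularity_subsample = 0.25,
      granularity_element_size = 10,
      granularity_length = 16L,
      granularity_k = 1L,
      length_summary = "longest_path"))
}

#' Analysis parameters for reduced-scale (256 px) fields
#'
#' The same parameter set as [default_params()] with the size-dependent
#' windows scaled to the [validation_design()] geometry: smaller nuclei,
#' a lower nucleus-area floor, and granularity measured without
#' downsampling (cell regions are already small).
#'
#' @return Nested list of parameters.
#' @export
validation_params <- function() {
  p <- default_params()
  p$nucleus$diameter_range <- c(6, 40)
  p$nucleus$area <- c(25, 2500)
  p$morphology$scale_sigma <- 0.9
  p$morphology$granularity_subsample <- 1
  p$morphology$granularity_element_size <- 5
  p
}

.corrected_channel <- function(fieldset, dye, params) {
  if (!dye %in% names(fieldset$channels))
    stop("incomplete field: missing channel '", dye, "' in well (",
         fieldset$well[1], ",", fieldset$well[2], ") field ", fieldset$field)
  px <- .pixels(fieldset$channels[[dye]])
  if (isTRUE(params$illumination_correction)) subtract_illumination(px) else px
}

#' Shared segmentation front end of a field
#'
#' Illumination-corrects the channels in use, identifies nuclei
#' (primary), grows whole cells by seeded propagation on `cell_channel`
#' (secondary), filters nuclei by area/eccentricity, optionally drops
#' border-touching cells (with their nuclei), and derives the cytoplasm
#' (tertiary).
#'
#' @param fieldset A `field_image_set`.
#' @param params Parameter list (see [default_params()]).
#' @param cell_channel Dye used for the cell body (`"mitoid_red"` for
#'   the H2O2/morphology assays, `"jc10_green"` for membrane
#'   potential).
#' @return List with `nuclei`, `cells`, `cytoplasm` label matrices and
#'   `corrected` (named list of corrected channel matrices).
#' @export
segment_field <- function(fieldset, params = default_params(),
                          cell_channel = "mitoid_red") {
  hoechst <- .corrected_channel(fieldset, "hoechst", params)
  cellpx <- .corrected_channel(fieldset, cell_channel, params)
  nuclei <- identify_primary(hoechst, params$nucleus$spec,
                             params$nucleus$diameter_range,
                             fill_holes = TRUE, exclude_border = FALSE)
  meas <- measure_objects(nuclei)
  nuclei <- filter_objects(nuclei, meas, criteria = list(
    list("area", params$nucleus$area[1], params$nucleus$area[2]),
    list("eccentricity", 0, params$nucleus$eccentricity_max)))
  if (.n_objects(nuclei) == 0) {
    empty <- matrix(0L, nrow(hoechst), ncol(hoechst))
    return(list(nuclei = empty, cells = empty, cytoplasm = empty,
                corrected = stats::setNames(list(hoechst, cellpx),
                                            c("hoechst", cell_channel))))
  }
  cells <- identify_secondary_propagation(cellpx, nuclei, params$cell$spec,
                                          params$cell$regularization)
  if (isTRUE(params$cell$drop_border)) {
    drop <- setdiff(.border_labels(cells), 0L)
    if (length(drop) > 0) {
      cells[cells %in% drop] <- 0L
      nuclei[nuclei %in% drop] <- 0L
      # compact both maps with one shared lookup so labels stay matched
      ids <- sort(unique(cells[cells > 0]))
      lut <- integer(max(c(ids, 1L)))
      if (length(ids) > 0) lut[ids] <- seq_along(ids)
      cells[cells > 0] <- lut[cells[cells > 0]]
      nuclei[nuclei > 0] <- lut[nuclei[nuclei > 0]]
      attr(cells, "n_objects") <- length(ids)
      attr(nuclei, "n_objects") <- length(ids)
    }
  }
  cytoplasm <- identify_tertiary(cells, nuclei)
  list(nuclei = nuclei, cells = cells, cytoplasm = cytoplasm,
       corrected = stats::setNames(list(hoechst, cellpx),
                                   c("hoechst", cell_channel)))
}

.field_id_cols <- function(fieldset, n) {
  data.frame(well_row = rep(fieldset$well[[1]], n),
             well_column = rep(fieldset$well[[2]], n),
             field = rep(fieldset$field, n))
}

#' Per-cell mitochondrial H2O2 levels for one field
#'
#' @param fieldset A `field_image_set` with hoechst, mitoid_red and
#'   mitopy1 channels.
#' @param params Parameter list.
#' @param seg Optional precomputed [segment_field()] result (on the
#'   mitochondrial channel), reused to avoid re-segmenting when several
#'   assays run on one field.
#' @return Per-cell `data.frame` (well, field, cell, mito_area,
#'   coloc_area, n_puncta, h2o2_level), with attribute `n_excluded`.
#' @export
analyze_field_h2o2 <- function(fieldset, params = default_params(),
                               seg = NULL) {
  if (is.null(seg))
    seg <- segment_field(fieldset, params, cell_channel = "mitoid_red")
  mitopy <- .corrected_channel(fieldset, "mitopy1", params)
  enhanced <- enhance_speckles(mitopy, params$h2o2$feature_size)
  puncta <- detect_puncta(enhanced, params$h2o2$puncta_spec,
                          params$h2o2$puncta_diameter)
  puncta <- relate_puncta_to_cells(puncta, seg$cells)
  mito <- seg$corrected$mitoid_red
  mito_mask <- mito > compute_threshold(mito, params$h2o2$mito_spec)
  res <- mito_h2o2_level(puncta, mito_mask, seg$cells,
                         denominator = params$h2o2$denominator)
  out <- cbind(.field_id_cols(fieldset, nrow(res)), res)
  attr(out, "n_excluded") <- attr(res, "n_excluded")
  out
}

#' Per-cell JC-10 membrane-potential ratios for one field
#'
#' @param fieldset A `field_image_set` with hoechst, jc10_orange and
#'   jc10_green channels.
#' @param params Parameter list.
#' @return Per-cell `data.frame` with `mmp_ratio` and masked areas.
#' @export
analyze_field_mmp <- function(fieldset, params = default_params()) {
  seg <- segment_field(fieldset, params, cell_channel = "jc10_green")
  orange <- .corrected_channel(fieldset, "jc10_orange", params)
  green <- seg$corrected$jc10_green
  aggregates <- detect_aggregates(orange, params$mmp$aggregate_spec,
                                  params$mmp$aggregate_diameter)
  res <- mmp_ratio_per_cell(aggregates, seg$cells, orange, green,
                            cells = seg$cells,
                            monomer_mask = params$mmp$monomer_mask)
  out <- cbind(.field_id_cols(fieldset, nrow(res)), res)
  attr(out, "n_excluded") <- attr(res, "n_excluded")
  out
}

#' Per-cell mitochondrial morphology metrics for one field
#'
#' Granular-spectrum fragmentation percentage (measured on the raw
#' corrected mitochondrial channel restricted to each cell's cytoplasm)
#' and mean skeleton length of the cell's mitochondria.
#'
#' @param fieldset A `field_image_set` with hoechst and mitoid_red
#'   channels.
#' @param params Parameter list.
#' @param seg Optional precomputed [segment_field()] result (on the
#'   mitochondrial channel).
#' @return Per-cell `data.frame` with `n_mitochondria`,
#'   `fragmentation_percent`, `mean_length_px`, `mean_length_um`.
#' @export
analyze_field_morphology <- function(fieldset, params = default_params(),
                                     seg = NULL) {
  if (is.null(seg))
    seg <- segment_field(fieldset, params, cell_channel = "mitoid_red")
  mito_px <- seg$corrected$mitoid_red
  enhanced <- enhance_tubeness(mito_px, params$morphology$scale_sigma)
  mito <- segment_mitochondria(enhanced, params$morphology$mito_spec,
                               params$morphology$manual_floor,
                               params$morphology$mito_diameter)
  skel <- skeletonize_and_measure(mito, seg$cells,
                                  pixel_size_um = params$pixel_size_um,
                                  summary = params$morphology$length_summary)
  ids <- sort(unique(seg$cells[seg$cells > 0]))
  frag <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    region <- seg$cytoplasm == ids[k]
    if (!any(region) || sum(mito_px[region]) <= 0) next
    sp <- suppressWarnings(granularity_spectrum(
      mito_px, region,
      subsample = params$morphology$granularity_subsample,
      element_size = params$morphology$granularity_element_size,
      length = params$morphology$granularity_length))
    frag[k] <- fragmentation_percent(sp, params$morphology$granularity_k)
  }
  pc <- skel$per_cell
  m <- match(ids, pc$cell)
  out <- data.frame(cell = ids,
                    n_mitochondria = ifelse(is.na(m), 0L, pc$n_mitochondria[m]),
                    fragmentation_percent = frag,
                    mean_length_px = pc$mean_length_px[m],
                    mean_length_um = pc$mean_length_um[m])
  cbind(.field_id_cols(fieldset, nrow(out)), out)
}

#' Analyze one field with the named assay
#'
#' @param fieldset A `field_image_set`.
#' @param assay `"h2o2"`, `"mmp"` or `"morphology"`.
#' @param params Parameter list.
#' @return Per-cell `data.frame`.
#' @export
analyze_field <- function(fieldset, assay = c("h2o2", "mmp", "morphology"),
                          params = default_params()) {
  assay <- match.arg(assay)
  switch(assay,
         h2o2 = analyze_field_h2o2(fieldset, params),
         mmp = analyze_field_mmp(fieldset, params),
         morphology = analyze_field_morphology(fieldset, params))
}

#' Load a plate directory into field image sets
#'
#' Lists the `.tif` files of an Operetta-style export, parses their
#' names, loads them and groups them per field. If a `manifest.csv`
#' written by [generate_plate()] is present, well conditions are read
#' from it.
#'
#' @param dir Plate directory.
#' @param channel_map Channel-index to dye mapping.
#' @param pixel_size_um Micrometres per pixel.
#' @return List with `fieldsets` and `conditions` (data.frame mapping
#'   well to condition, or `NULL`).
#' @export
load_plate <- function(dir, channel_map = default_channel_map(),
                       pixel_size_um = 0.299) {
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(files) == 0) stop("no .tif images found in ", dir)
  images <- lapply(files, load_channel_image, pixel_size_um = pixel_size_um)
  fieldsets <- group_image_set(images, channel_map)
  conditions <- NULL
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    man <- utils::read.csv(mf)
    conditions <- unique(man[, c("row", "column", "condition")])
  }
  list(fieldsets = fieldsets, conditions = conditions)
}

#' Analyze a plate with the named assay
#'
#' @param input Plate directory, or a list of `field_image_set`s.
#' @param assay `"h2o2"`, `"mmp"` or `"morphology"`.
#' @param params Parameter list.
#' @param channel_map Channel-index to dye mapping (directory input).
#' @param conditions Optional `data.frame(row, column, condition)`;
#'   read from the plate manifest when the input is a directory.
#' @return Per-cell `data.frame` across all fields, with a `condition`
#'   column when known.
#' @export
analyze_plate <- function(input, assay = c("h2o2", "mmp", "morphology"),
                          params = default_params(),
                          channel_map = default_channel_map(),
                          conditions = NULL) {
  assay <- match.arg(assay)
  if (is.character(input)) {
    plate <- load_plate(input, channel_map, params$pixel_size_um)
    fieldsets <- plate$fieldsets
    if (is.null(conditions)) conditions <- plate$conditions
  } else fieldsets <- input
  res <- lapply(fieldsets, analyze_field, assay = assay, params = params)
  out <- do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
  if (is.null(out)) return(NULL)
  if (!is.null(conditions)) {
    m <- match(paste(out$well_row, out$well_column),
               paste(conditions$row, conditions$column))
    out$condition <- conditions$condition[m]
  }
  rownames(out) <- NULL
  out
}

.metric_for_assay <- c(h2o2 = "h2o2_level", mmp = "mmp_ratio",
                       morphology = "fragmentation_percent")

#' Read a pipeline configuration file
#'
#' YAML with optional blocks `params` (leaf overrides of
#' [default_params()]), `design` (arguments of [plate_design()]),
#' `channel_map`, and `stats` (`metric`).
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.merge_params <- function(config) {
  p <- default_params()
  if (!is.null(config$params)) p <- utils::modifyList(p, config$params)
  p
}

#' Run a pipeline command end to end
#'
#' `simulate` renders a synthetic plate into `out`; the assay commands
#' (`h2o2`, `mmp`, `morphology`) analyze the plate in `input` and write
#' `per_cell.csv`, `per_well.csv` and `run_log.txt` into `out`; `stats`
#' reads a per-cell CSV from `input` and writes `comparisons.csv`.
#'
#' @param command One of `"simulate"`, `"h2o2"`, `"mmp"`,
#'   `"morphology"`, `"stats"`.
#' @param config Configuration list or YAML path (see [read_config()]).
#' @param input Input directory (assays) or per-cell CSV (`stats`).
#' @param out Output directory.
#' @param seed Integer seed overriding the design seed (`simulate`).
#' @param overwrite Passed to [generate_plate()].
#' @return Invisibly, the primary result (manifest, per-cell table, or
#'   comparison result).
#' @export
run_pipeline <- function(command = c("simulate", "h2o2", "mmp", "morphology",
                                     "stats"),
                         config = list(), input = NULL, out = NULL,
                         seed = NULL, overwrite = FALSE) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  if (is.null(out)) stop("an output directory (out) is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (command == "simulate") {
    args <- config$design
    if (!is.null(args$conditions)) args$conditions <- as.data.frame(args$conditions)
    if (!is.null(seed)) args$seed <- seed
    scale <- if (!is.null(config$design_scale)) config$design_scale else "full"
    design <- if (identical(scale, "validation"))
      do.call(validation_design, args[setdiff(names(args), "image_size")])
    else do.call(plate_design, if (is.null(args)) list() else args)
    man <- generate_plate(design, out, overwrite = overwrite)
    .write_run_log(out, command, config, design$seed,
                   sprintf("%d images written", nrow(man)))
    return(invisible(man))
  }
  if (command == "stats") {
    if (is.null(input) || !file.exists(input)) stop("no data: ", input)
    per_cell <- utils::read.csv(input)
    metric <- config$stats$metric
    if (is.null(metric))
      metric <- intersect(unname(.metric_for_assay), names(per_cell))[1]
    if (nrow(per_cell) == 0 || is.na(metric) || is.null(per_cell$condition))
      stop("no data to compare (need rows, a metric and a condition column)")
    groups <- split(per_cell[[metric]][!is.na(per_cell[[metric]])],
                    per_cell$condition[!is.na(per_cell[[metric]])])
    cmp <- compare_groups(groups,
                          design = if (length(groups) > 2) "multi" else "two")
    cmp_df <- if (!is.null(cmp$pairwise)) cmp$pairwise else
      data.frame(comparison = paste(cmp$groups, collapse = "-"),
                 diff = NA_real_, p_adj = cmp$p_value, stars = cmp$stars)
    write.csv(cbind(test = cmp$test, statistic = cmp$statistic,
                    p_value = cmp$p_value, cmp_df),
              file.path(out, "comparisons.csv"), row.names = FALSE)
    .write_run_log(out, command, config, NA,
                   sprintf("%s on %d groups, p = %.4g", cmp$test,
                           length(groups), cmp$p_value))
    return(invisible(cmp))
  }
  # assay commands
  if (is.null(input)) stop("an input plate directory is required")
  params <- .merge_params(config)
  chmap <- if (!is.null(config$channel_map)) config$channel_map
           else default_channel_map()
  per_cell <- analyze_plate(input, assay = command, params = params,
                            channel_map = chmap)
  if (is.null(per_cell)) stop("no cells found in ", input)
  write.csv(per_cell, file.path(out, "per_cell.csv"), row.names = FALSE)
  metric <- .metric_for_assay[[command]]
  keep <- !is.na(per_cell[[metric]])
  wm <- stats::aggregate(per_cell[[metric]][keep],
                         by = list(well_row = per_cell$well_row[keep],
                                   well_column = per_cell$well_column[keep]),
                         FUN = mean)
  names(wm)[3] <- paste0("mean_", metric)
  write.csv(wm, file.path(out, "per_well.csv"), row.names = FALSE)
  .write_run_log(out, command, config, NA,
                 sprintf("%d cells in %d fields", sum(keep),
                         nrow(unique(per_cell[c("well_row", "well_column",
                                                "field")]))))
  invisible(per_cell)
}

.write_run_log <- function(out, command, config, seed, summary_line) {
  lines <- c(sprintf("command: %s", command),
             sprintf("package: mitoscreen %s",
                     as.character(utils::packageVersion("mitoscreen"))),
             sprintf("R: %s", R.version.string),
             sprintf("seed: %s", seed),
             "note: per-cell values are pooled within condition for inference;",
             "  replicate wells on one plate are technical replicates (n = 1",
             "  plate per condition) -- well means are emitted for well-level",
             "  inference.",
             sprintf("result: %s", summary_line))
  writeLines(lines, file.path(out, "run_log.txt"))
}
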