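# Synthetic plate generator: renders Operetta-style multi-channel fields
# with known ground truth. Each cell carries a Hoechst-like nucleus, a
# mitochondrial tube network (MITO-ID-like) whose tubes fragment with a
# per-condition probability, H2O2 puncta (MitoPY1-like) whose Poisson count
# scales with a dose knob, and JC-10 orange aggregates / green cytosolic
# haze whose amplitudes shift with a polarization knob. A smooth quadratic
# illumination bias and Poisson-Gaussian noise complete the camera model.

#' Default channel-index to dye mapping for synthetic plates
#'
#' @return Named list: channel `1` = hoechst, `2` = mitoid_red,
#'   `3` = mitopy1, `4` = jc10_orange, `5` = jc10_green.
#' @export
default_channel_map <- function() {
  list(`1` = "hoechst", `2` = "mitoid_red", `3` = "mitopy1",
       `4` = "jc10_orange", `5` = "jc10_green")
}

#' Default stress-condition table
#'
#' Three conditions forming a dose sweep: the H2O2-dose proxy
#' (`puncta_density`, expected puncta per cell) rises, the
#' membrane-potential proxy (`polarization`, 1 = fully polarized) falls,
#' and the fission proxy (`fragmentation`, per-tube splitting
#' probability) rises.
#'
#' @return `data.frame` with columns `condition`, `puncta_density`,
#'   `polarization`, `fragmentation`.
#' @export
stress_conditions <- function() {
  data.frame(condition = c("control", "low", "high"),
             puncta_density = c(1, 4, 8),
             polarization = c(0.9, 0.6, 0.3),
             fragmentation = c(0.1, 0.4, 0.7))
}

#' Synthetic plate design
#'
#' Collects the generative parameters of a synthetic plate: the
#' condition table, plate layout (each condition occupies one plate row;
#' replicate wells fill columns), acquisition geometry, per-cell
#' geometry, and the noise/illumination model. The same design and seed
#' always render bit-identical images.
#'
#' @param conditions Condition table as in [stress_conditions()].
#' @param wells_per_condition Replicate wells per condition.
#' @param fields_per_well Fields imaged per well.
#' @param image_size Field edge length in px.
#' @param pixel_size_um Micrometres per pixel.
#' @param bit_depth Bits per pixel of the rendered TIFFs.
#' @param cells_per_field `(min, max)`; per-field counts are uniform on
#'   this range.
#' @param nucleus_radius_px,cell_radius_px `(min, max)` radii in px.
#' @param tube_width_px Gaussian half-width of rendered tubes.
#' @param tubes_per_cell,aggregates_per_cell `(min, max)` counts.
#' @param illumination_bias Quadratic surface coefficients (a..f over
#'   normalized coordinates) added to every channel.
#' @param noise `c(gaussian_sd, poisson_scale)`: additive read noise and
#'   the photon scale of the Poisson shot noise.
#' @param cell_spacing_factor Minimal center-to-center distance between
#'   placed cells, in units of the mean cell radius.
#' @param seed Integer master seed.
#' @return A `plate_design` with a `wells` table (row, column,
#'   condition and its dose knobs).
#' @export
plate_design <- function(conditions = stress_conditions(),
                         wells_per_condition = 2L,
                         fields_per_well = 10L,
                         image_size = 1080L,
                         pixel_size_um = 0.299,
                         bit_depth = 16L,
                         cells_per_field = c(15L, 40L),
                         nucleus_radius_px = c(18, 26),
                         cell_radius_px = c(45, 65),
                         tube_width_px = 2.2,
                         tubes_per_cell = c(6L, 12L),
                         aggregates_per_cell = c(8L, 16L),
                         illumination_bias = c(a = 0, b = 0.03, c = -0.02,
                                               d = -0.025, e = 0.015, f = 0.01),
                         noise = c(gaussian_sd = 0.005, poisson_scale = 2000),
                         cell_spacing_factor = 2.0,
                         seed = 1L) {
  stopifnot(all(c("condition", "puncta_density", "polarization",
                  "fragmentation") %in% names(conditions)),
            all(conditions$polarization >= 0 & conditions$polarization <= 1),
            all(conditions$fragmentation >= 0 & conditions$fragmentation <= 1),
            all(conditions$puncta_density >= 0),
            cells_per_field[1] <= cells_per_field[2])
  wells <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    data.frame(row = i, column = seq_len(wells_per_condition),
               conditions[i, , drop = FALSE], row.names = NULL)
  }))
  structure(list(conditions = conditions, wells = wells,
                 wells_per_condition = as.integer(wells_per_condition),
                 fields_per_well = as.integer(fields_per_well),
                 image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth),
                 cells_per_field = as.integer(cells_per_field),
                 nucleus_radius_px = nucleus_radius_px,
                 cell_radius_px = cell_radius_px,
                 tube_width_px = tube_width_px,
                 tubes_per_cell = as.integer(tubes_per_cell),
                 aggregates_per_cell = as.integer(aggregates_per_cell),
                 illumination_bias = illumination_bias,
                 noise = noise,
                 cell_spacing_factor = cell_spacing_factor,
                 seed = as.integer(seed)),
            class = "plate_design")
}

#' Reduced-scale design for validation studies and examples
#'
#' The full acquisition geometry (1080 px fields, 15-40 large fibroblasts
#' per field) is expensive to simulate in bulk; this design shrinks the
#' field to 256 px and the cells proportionally (6-10 cells per field)
#' while keeping the dose-response structure, and is what the package's
#' own validation studies run on.
#'
#' @inheritParams plate_design
#' @param ... Further arguments passed to [plate_design()].
#' @return A `plate_design`.
#' @export
validation_design <- function(conditions = stress_conditions(), seed = 1L, ...) {
  plate_design(conditions = conditions, seed = seed,
               image_size = 256L,
               cells_per_field = c(4L, 6L),
               nucleus_radius_px = c(4, 6),
               cell_radius_px = c(24, 30),
               tube_width_px = 2.2,
               tubes_per_cell = c(3L, 5L),
               aggregates_per_cell = c(6L, 10L),
               cell_spacing_factor = 2.1,
               ...)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.quantize <- function(x, bits) {
  # same truncation rule the TIFF writer applies, so in-memory fields and
  # re-loaded files agree exactly
  floor(.clamp01(x) * (2^bits - 1)) / (2^bits - 1)
}

.soft_ellipse <- function(nr, nc, center, ra, rb, angle, soft = 0.1) {
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  u <- rr * cos(angle) + cc * sin(angle)
  v <- -rr * sin(angle) + cc * cos(angle)
  rho <- sqrt((u / ra)^2 + (v / rb)^2)
  .clamp01((1 - rho) / soft + 1)
}

.add_dots <- function(img, pos, sigma, amp) {
  # pos: matrix of (row, col); amp recycled
  if (is.null(pos) || nrow(pos) == 0) return(img)
  amp <- rep_len(amp, nrow(pos))
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(3 * sigma)
  for (k in seq_len(nrow(pos))) {
    r0 <- max(1, round(pos[k, 1]) - w); r1 <- min(nr, round(pos[k, 1]) + w)
    c0 <- max(1, round(pos[k, 2]) - w); c1 <- min(nc, round(pos[k, 2]) + w)
    if (r0 > r1 || c0 > c1) next
    dr <- (r0:r1) - pos[k, 1]; dc <- (c0:c1) - pos[k, 2]
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      amp[k] * exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  }
  img
}

.dist_to_segment <- function(pr, pc, a, b) {
  # distance from grid points (pr, pc matrices) to segment a->b
  abr <- b[1] - a[1]; abc <- b[2] - a[2]
  len2 <- abr^2 + abc^2
  if (len2 == 0) return(sqrt((pr - a[1])^2 + (pc - a[2])^2))
  t <- .clamp01(((pr - a[1]) * abr + (pc - a[2]) * abc) / len2)
  sqrt((pr - (a[1] + t * abr))^2 + (pc - (a[2] + t * abc))^2)
}

.add_tubes <- function(img, segments, width, amp) {
  # segments: list of 2x2 matrices rbind(p_start, p_end) in (row, col)
  if (length(segments) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  allp <- do.call(rbind, segments)
  margin <- ceiling(3 * width)
  r0 <- max(1, floor(min(allp[, 1])) - margin); r1 <- min(nr, ceiling(max(allp[, 1])) + margin)
  c0 <- max(1, floor(min(allp[, 2])) - margin); c1 <- min(nc, ceiling(max(allp[, 2])) + margin)
  if (r0 > r1 || c0 > c1) return(img)
  pr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
  pc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  d <- Inf
  for (s in segments) d <- pmin(d, .dist_to_segment(pr, pc, s[1, ], s[2, ]))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * exp(-d^2 / (2 * (width / 1.6)^2))
  img
}

.subpolyline <- function(pts, t0, t1) {
  # sub-segment of a polyline between arc-length fractions t0 < t1
  d <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  interp <- function(t) {
    a <- t * total
    k <- max(1, findInterval(a, cum, rightmost.closed = TRUE))
    k <- min(k, nrow(pts) - 1)
    u <- (a - cum[k]) / max(cum[k + 1] - cum[k], 1e-9)
    pts[k, ] + u * (pts[k + 1, ] - pts[k, ])
  }
  rbind(interp(t0), interp(t1))
}

.sample_on_segments <- function(segments, n) {
  if (n == 0 || length(segments) == 0) return(NULL)
  lens <- vapply(segments, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  lens[lens == 0] <- 1e-6
  pick <- sample.int(length(segments), n, replace = TRUE, prob = lens)
  t(vapply(pick, function(i) {
    s <- segments[[i]]; u <- runif(1)
    s[1, ] + u * (s[2, ] - s[1, ])
  }, numeric(2)))
}

.field_seed <- function(design, well_index, field) {
  as.integer((design$seed %% 100000L) * 20011L + well_index * 1009L + field * 17L)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Render one synthetic field with ground truth
#'
#' Draws the field's cells and renders the five channels (Hoechst
#' nuclei, mitochondrial tubes, H2O2 puncta, JC-10 orange aggregates and
#' green cytosolic haze), applies the quadratic illumination bias, adds
#' Poisson shot noise plus Gaussian read noise, and quantizes to the
#' design bit depth. The returned ground truth records every generative
#' quantity needed for parameter-recovery tests.
#'
#' @param design A [plate_design()].
#' @param well_index Row index into `design$wells`.
#' @param field Field number (1-based).
#' @return List with `images` (a `field_image_set`) and `truth` (field-
#'   and cell-level generative parameters).
#' @export
generate_field <- function(design, well_index, field) {
  stopifnot(inherits(design, "plate_design"),
            well_index >= 1, well_index <= nrow(design$wells),
            field >= 1)
  wellrow <- design$wells[well_index, ]
  .with_seed(.field_seed(design, well_index, field), {
    s <- design$image_size
    blank <- matrix(0, s, s)
    ch <- list(hoechst = blank, mitoid_red = blank, mitopy1 = blank,
               jc10_orange = blank, jc10_green = blank)
    n_target <- if (design$cells_per_field[1] == design$cells_per_field[2])
      design$cells_per_field[1] else
      sample(design$cells_per_field[1]:design$cells_per_field[2], 1)
    mean_R <- mean(design$cell_radius_px)
    margin <- 0.8 * mean_R
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_target && tries < 150 * n_target) {
      tries <- tries + 1
      cand <- c(runif(1, margin, s - margin), runif(1, margin, s - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
            design$cell_spacing_factor * mean_R)
        centers <- rbind(centers, cand)
    }
    n_cells <- nrow(centers)
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cen <- centers[i, ]
      nra <- runif(1, design$nucleus_radius_px[1], design$nucleus_radius_px[2])
      nrb <- nra * runif(1, 0.75, 1)
      nang <- runif(1, 0, pi)
      R <- runif(1, design$cell_radius_px[1], design$cell_radius_px[2])
      Rb <- R * runif(1, 0.85, 1)
      cang <- runif(1, 0, pi)
      ch$hoechst <- ch$hoechst +
        0.7 * .soft_ellipse(s, s, cen, nra, nrb, nang, soft = 0.15)
      # gradual haze falloff: a sharp rim would itself look like a ridge
      # or speckle to the enhancement filters
      cellmask <- .soft_ellipse(s, s, cen, R, Rb, cang, soft = 0.45)
      ch$mitoid_red <- ch$mitoid_red + 0.12 * cellmask
      ch$mitopy1 <- ch$mitopy1 + 0.015 * cellmask
      ch$jc10_orange <- ch$jc10_orange + 0.012 * cellmask
      green_amp <- 0.5 * (1 - wellrow$polarization)
      ch$jc10_green <- ch$jc10_green + (0.04 + green_amp) * cellmask
      # mitochondrial tubes radiating from the nucleus rim
      n_tubes <- sample(design$tubes_per_cell[1]:design$tubes_per_cell[2], 1)
      segs <- list()         # dye-placement support (tubes and fragments)
      render_segs <- list()  # intact tubes to draw with the tube kernel
      n_frag <- 0L
      sector <- 2 * pi / n_tubes   # one tube per angular sector: tubes of a
      phase <- runif(1, 0, 2 * pi) # cell stay laterally separated
      for (tj in seq_len(n_tubes)) {
        theta <- phase + (tj - 0.5) * sector + runif(1, -0.12, 0.12) * sector
        r0 <- 1.6 * max(nra, nrb)
        reach <- r0 + runif(1, 0.45, 0.75) * max(R - r0, 2)
        npts <- 5L
        angs <- theta + cumsum(c(0, rnorm(npts - 1, 0, 0.08)))
        rads <- seq(r0, reach, length.out = npts)
        pts <- cbind(cen[1] + rads * sin(angs), cen[2] + rads * cos(angs))
        fragmented <- runif(1) < wellrow$fragmentation
        if (fragmented) {
          n_frag <- n_frag + 1L
          # fission: the tube collapses into three punctate fragments
          # along its former path, each smaller than the tube width
          fpos <- t(vapply(c(0.12, 0.5, 0.88), function(tt)
            .subpolyline(pts, tt, tt + 1e-3)[1, ], numeric(2)))
          ch$mitoid_red <- .add_dots(ch$mitoid_red, fpos,
                                     sigma = 0.45 * design$tube_width_px,
                                     amp = 0.6)
          # degenerate support segments so dye puncta can still land on
          # the fragments
          tube_segs <- lapply(seq_len(3), function(k)
            rbind(fpos[k, ], fpos[k, ] + 0.1))
        } else {
          tube_segs <- lapply(seq_len(npts - 1),
                              function(k) pts[k:(k + 1), , drop = FALSE])
          render_segs <- c(render_segs, tube_segs)
        }
        segs <- c(segs, tube_segs)
      }
      ch$mitoid_red <- .add_tubes(ch$mitoid_red, render_segs,
                                  design$tube_width_px, 0.55)
      # H2O2 puncta on the tubes
      n_punc <- rpois(1, wellrow$puncta_density)
      ppos <- .sample_on_segments(segs, n_punc)
      n_punc <- if (is.null(ppos)) 0L else nrow(ppos)
      ch$mitopy1 <- .add_dots(ch$mitopy1, ppos, sigma = 2,
                              amp = runif(max(n_punc, 1), 0.45, 0.7))
      # JC-10 aggregates on the tubes, amplitude tracking polarization
      n_agg <- sample(design$aggregates_per_cell[1]:design$aggregates_per_cell[2], 1)
      apos <- .sample_on_segments(segs, n_agg)
      ch$jc10_orange <- .add_dots(ch$jc10_orange, apos, sigma = 1.3,
                                  amp = wellrow$polarization *
                                    runif(max(n_agg, 1), 0.55, 0.8))
      cells[[i]] <- data.frame(
        cell = i, center_row = cen[1], center_col = cen[2],
        nucleus_ra = nra, nucleus_rb = nrb, nucleus_angle = nang,
        cell_ra = R, cell_rb = Rb, cell_angle = cang,
        n_tubes = n_tubes, n_fragmented = n_frag,
        true_puncta = n_punc,
        polarization = wellrow$polarization,
        fragmentation = wellrow$fragmentation)
    }
    # optics blur, illumination bias, then noise
    surf <- structure(list(coefficients = design$illumination_bias,
                           shape = c(s, s)), class = "illumination_surface")
    bias <- evaluate_surface(surf)
    gsd <- design$noise[["gaussian_sd"]]
    pscale <- design$noise[["poisson_scale"]]
    key0 <- list(row = wellrow$row, column = wellrow$column, field = field)
    chan_idx <- seq_along(ch)
    images <- lapply(chan_idx, function(k) {
      px <- .as_matrix(EBImage::gblur(.clamp01(ch[[k]] + 0.004), sigma = 0.7))
      px <- .clamp01(px + bias)
      if (pscale > 0) px <- rpois(length(px), px * pscale) / pscale
      px <- px + rnorm(length(px), 0, gsd)
      dim(px) <- c(s, s)
      channel_image(.quantize(px, design$bit_depth),
                    key = image_key(key0$row, key0$column, key0$field,
                                    time = 1L, stack = 1L, channel = k),
                    bit_depth = design$bit_depth,
                    pixel_size_um = design$pixel_size_um)
    })
    names(images) <- names(ch)
    fieldset <- structure(list(well = c(row = wellrow$row,
                                        column = wellrow$column),
                               field = field, time = 1L, stack = 1L,
                               channels = images),
                          class = "field_image_set")
    truth <- list(condition = wellrow$condition,
                  n_cells = n_cells,
                  cells = if (n_cells > 0) do.call(rbind, cells) else NULL,
                  illumination = design$illumination_bias,
                  puncta_density = wellrow$puncta_density,
                  polarization = wellrow$polarization,
                  fragmentation = wellrow$fragmentation)
    list(images = fieldset, truth = truth)
  })
}

#' Write a full synthetic plate to disk
#'
#' Renders every (well, field) of the design, writes one grayscale TIFF
#' per channel named by the plate filename dialect, and writes
#' `manifest.csv` (file, plate coordinates, dye, condition),
#' `truth_cells.csv` and `truth_fields.csv`.
#'
#' @param design A [plate_design()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the manifest `data.frame`.
#' @export
generate_plate <- function(design, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dyes <- names(default_channel_map())
  manifest <- list(); truth_cells <- list(); truth_fields <- list()
  for (i in seq_len(nrow(design$wells))) {
    for (f in seq_len(design$fields_per_well)) {
      gf <- generate_field(design, i, f)
      for (k in seq_along(gf$images$channels)) {
        im <- gf$images$channels[[k]]
        fn <- format_image_filename(im$key)
        tiff::writeTIFF(im$pixels, file.path(out_dir, fn),
                        bits.per.sample = design$bit_depth)
        manifest[[length(manifest) + 1L]] <- data.frame(
          file = fn, row = im$key$row, column = im$key$column,
          field = im$key$field, time = im$key$time, stack = im$key$stack,
          channel = im$key$channel,
          dye = default_channel_map()[[as.character(im$key$channel)]],
          condition = gf$truth$condition)
      }
      truth_fields[[length(truth_fields) + 1L]] <- data.frame(
        row = design$wells$row[i], column = design$wells$column[i],
        field = f, n_cells = gf$truth$n_cells,
        condition = gf$truth$condition,
        t(design$illumination_bias))
      if (!is.null(gf$truth$cells))
        truth_cells[[length(truth_cells) + 1L]] <- data.frame(
          row = design$wells$row[i], column = design$wells$column[i],
          field = f, condition = gf$truth$condition, gf$truth$cells)
    }
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(do.call(rbind, truth_fields),
            file.path(out_dir, "truth_fields.csv"), row.names = FALSE)
  if (length(truth_cells) > 0)
    write.csv(do.call(rbind, truth_cells),
              file.path(out_dir, "truth_cells.csv"), row.names = FALSE)
  invisible(manifest)
}
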