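# Operetta/Columbus-style plate file handling: filename metadata, TIFF
# loading with bit-depth normalization, grouping into per-field channel sets.

#' Image key: plate coordinates of one channel image
#'
#' Identifies a single acquired image by plate row, column, field, time
#' point, z-stack index and channel index, all 1-based positive integers.
#'
#' @param row,column Plate well coordinates (integers >= 1, <= 999).
#' @param field Field-of-view index within the well (1-99).
#' @param time,stack Time point and z-stack index (default 1).
#' @param channel Fluorescence channel index.
#' @return An object of class `image_key`.
#' @seealso [parse_image_filename()], [format_image_filename()]
#' @export
image_key <- function(row, column, field, time = 1L, stack = 1L, channel = 1L) {
  vals <- c(row = row, column = column, field = field,
            time = time, stack = stack, channel = channel)
  if (any(is.na(vals)) || any(vals < 1) || any(vals != round(vals)))
    stop("image_key fields must be positive integers")
  if (vals[["field"]] > 99L || any(vals[c(1, 2, 4, 5, 6)] > 999L))
    stop("image_key field out of representable range")
  structure(stats::setNames(as.list(as.integer(vals)), names(vals)),
            class = "image_key")
}

#' @export
print.image_key <- function(x, ...) {
  cat(sprintf("<image_key> well (%d,%d) field %d time %d stack %d channel %d\n",
              x$row, x$column, x$field, x$time, x$stack, x$channel))
  invisible(x)
}

.filename_regex <- paste0(
  "^([0-9]{3})([0-9]{3})-([0-9]{1,2})-([0-9]{3})([0-9]{3})([0-9]{3})\\.tif$")

#' Parse an Operetta-style image file name
#'
#' File names follow the dialect
#' `RRRCCC-F-TTTSSSCCC.tif`: zero-padded 3-digit row, column, time, stack
#' and channel, with a 1- or 2-digit field index. Any other name is
#' rejected rather than guessed at.
#'
#' @param name Bare file name (no directory part).
#' @return An [image_key()].
#' @examples
#' parse_image_filename("002003-12-001001002.tif")
#' @export
parse_image_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name != basename(name))
    stop("expected a bare file name, got a path: ", name)
  m <- regmatches(name, regexec(.filename_regex, name))[[1]]
  if (length(m) == 0L)
    stop("unrecognized filename: ", name)
  v <- as.integer(m[-1])
  image_key(row = v[1], column = v[2], field = v[3],
            time = v[4], stack = v[5], channel = v[6])
}

#' Format an image key back into its file name
#'
#' Inverse of [parse_image_filename()]: `parse(format(key))` is the
#' identity for every valid key.
#'
#' @param key An [image_key()].
#' @return File name string.
#' @export
format_image_filename <- function(key) {
  stopifnot(inherits(key, "image_key"))
  sprintf("%03d%03d-%d-%03d%03d%03d.tif",
          key$row, key$column, key$field, key$time, key$stack, key$channel)
}

#' Construct a channel image
#'
#' A single-channel 2-D intensity grid with plate metadata. Intensities
#' are stored on `[0, 1]`: raw integer pixel values are divided by
#' `2^bit_depth - 1`, so thresholds downstream are independent of the
#' camera bit depth.
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param key An [image_key()] or `NULL`.
#' @param bit_depth Source bits per pixel.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, key = NULL, bit_depth = 16L,
                          pixel_size_um = 0.299) {
  pixels <- .as_matrix(pixels)
  if (!is.numeric(pixels) || length(dim(pixels)) != 2L)
    stop("pixels must be a 2-D numeric matrix")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("pixel intensities must lie in [0, 1]")
  if (!is.null(key) && !inherits(key, "image_key"))
    stop("key must be an image_key or NULL")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(list(pixels = pixels, key = key,
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um,
                 shape = dim(pixels)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d px, %d-bit, %.3f um/px, range [%.4f, %.4f]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  if (!is.null(x$key)) print(x$key)
  invisible(x)
}

.pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels else .as_matrix(x)
}

#' Load a grayscale TIFF as a channel image
#'
#' Reads a single-plane unsigned 8- or 16-bit grayscale TIFF, normalizes
#' intensities to `[0, 1]` by the full representable range, and parses
#' the plate metadata from the file name.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_um Micrometres per pixel recorded in the metadata.
#' @return A [channel_image()].
#' @export
load_channel_image <- function(path, pixel_size_um = 0.299) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(raw)) > 2L)
    stop("not grayscale (multi-channel TIFF): ", path)
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  key <- parse_image_filename(basename(path))
  px <- matrix(as.numeric(raw) / (2^bits - 1), nrow(raw), ncol(raw))
  channel_image(px, key = key, bit_depth = as.integer(bits),
                pixel_size_um = pixel_size_um)
}

#' Group channel images into per-field multi-channel sets
#'
#' Partitions images into one set per (well, field, time, stack)
#' combination and names each member by its dye via `channel_map`. Every
#' image lands in exactly one set; sets are ordered by (row, column,
#' field).
#'
#' @param images List of [channel_image()] objects with non-`NULL` keys.
#' @param channel_map Named list/vector mapping channel index (as
#'   character, e.g. `"1"`) to a dye name such as `"hoechst"`.
#' @return A list of `field_image_set` objects, each with elements
#'   `well = c(row, column)`, `field`, `time`, `stack`, and `channels`
#'   (a named list of channel images).
#' @export
group_image_set <- function(images, channel_map) {
  if (length(images) == 0L) return(list())
  keys <- lapply(images, function(im) {
    if (!inherits(im, "channel_image") || is.null(im$key))
      stop("all images must be channel_image objects with keys")
    im$key
  })
  idstr <- vapply(keys, format_image_filename, character(1))
  if (anyDuplicated(idstr))
    stop("duplicate image: ", idstr[duplicated(idstr)][1])
  chmap <- as.list(channel_map)
  chidx <- vapply(keys, function(k) k$channel, integer(1))
  missing_ch <- setdiff(as.character(unique(chidx)), names(chmap))
  if (length(missing_ch) > 0)
    stop("channel_map does not cover channel index: ",
         paste(missing_ch, collapse = ", "))
  grp <- vapply(keys, function(k)
    sprintf("%03d:%03d:%02d:%03d:%03d", k$row, k$column, k$field, k$time, k$stack),
    character(1))
  out <- lapply(split(seq_along(images), grp), function(ii) {
    k1 <- keys[[ii[1]]]
    chans <- stats::setNames(
      images[ii],
      vapply(ii, function(i) as.character(chmap[[as.character(keys[[i]]$channel)]]),
             character(1)))
    shp <- vapply(ii, function(i) images[[i]]$shape, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
      stop("channel images within one field differ in shape")
    structure(list(well = c(row = k1$row, column = k1$column),
                   field = k1$field, time = k1$time, stack = k1$stack,
                   channels = chans),
              class = "field_image_set")
  })
  ord <- order(vapply(out, function(s) s$well[1] * 1e6 + s$well[2] * 1e3 + s$field,
                      numeric(1)))
  unname(out[ord])
}

#' Check a field set for the dyes an assay needs
#'
#' @param fieldset A `field_image_set`.
#' @param dyes Character vector of required dye names.
#' @return `TRUE` if complete, otherwise `FALSE` with attribute
#'   `"missing"` naming absent dyes.
#' @export
field_is_complete <- function(fieldset, dyes) {
  missing <- setdiff(dyes, names(fieldset$channels))
  if (length(missing) == 0) return(TRUE)
  structure(FALSE, missing = missing)
}
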