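test_that("filename parsing decodes the plate coordinate groups", {
  k <- parse_image_filename("002003-12-001001002.tif")
  expect_equal(unlist(k[c("row", "column", "field", "time", "stack", "channel")]),
               c(row = 2L, column = 3L, field = 12L, time = 1L, stack = 1L,
                 channel = 2L))
  k1 <- parse_image_filename("001001-1-001001001.tif")
  expect_equal(unlist(k1), c(row = 1L, column = 1L, field = 1L, time = 1L,
                             stack = 1L, channel = 1L))
  expect_error(parse_image_filename("A01-1-001.tif"), "unrecognized filename")
  expect_error(parse_image_filename("002003-123-001001002.tif"),
               "unrecognized filename")  # 3-digit field not in the dialect
  expect_error(parse_image_filename("some/dir/001001-1-001001001.tif"),
               "bare file name")
})

test_that("format -> parse is the identity on random valid keys", {
  set.seed(42)
  for (i in 1:50) {
    k <- image_key(row = sample(999, 1), column = sample(999, 1),
                   field = sample(99, 1), time = sample(999, 1),
                   stack = sample(999, 1), channel = sample(999, 1))
    expect_equal(parse_image_filename(format_image_filename(k)), k)
  }
})

test_that("TIFF loading normalizes by the full representable range", {
  dir <- withr::local_tempdir()
  f16 <- file.path(dir, "001001-1-001001001.tif")
  tiff::writeTIFF(matrix(1, 8, 8), f16, bits.per.sample = 16L)
  im <- load_channel_image(f16)
  expect_true(all(im$pixels == 1))
  expect_equal(im$bit_depth, 16L)
  expect_equal(im$key$channel, 1L)

  tiff::writeTIFF(matrix(0, 8, 8), f16, bits.per.sample = 16L)
  expect_true(all(load_channel_image(f16)$pixels == 0))

  f8 <- file.path(dir, "001001-1-001001002.tif")
  tiff::writeTIFF(matrix(128 / 255, 8, 8), f8, bits.per.sample = 8L)
  im8 <- load_channel_image(f8)
  expect_equal(im8$pixels[1, 1], 128 / 255, tolerance = 1e-12)
  expect_equal(im8$bit_depth, 8L)

  frgb <- file.path(dir, "001001-1-001001003.tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), frgb)
  expect_error(load_channel_image(frgb), "not grayscale")
  expect_error(load_channel_image(file.path(dir, "missing.tif")),
               "cannot read")
})

test_that("normalization endpoints and monotonicity", {
  # 0 maps to 0 and 2^bits-1 maps to 1 exactly at load; monotone between
  dir <- withr::local_tempdir()
  f <- file.path(dir, "001001-1-001001001.tif")
  vals <- c(0, 0.25, 0.5, 0.75, 1)
  tiff::writeTIFF(matrix(vals, 1, 5), f, bits.per.sample = 16L)
  px <- load_channel_image(f)$pixels
  expect_equal(px[1, 1], 0)
  expect_equal(px[1, 5], 1)
  expect_true(all(diff(px[1, ]) > 0))
})

test_that("grouping partitions images into per-field channel sets", {
  mk <- function(row, col, field, channel)
    channel_image(matrix(0.5, 4, 4),
                  key = image_key(row, col, field, channel = channel))
  imgs <- list()
  for (r in 1:2) for (f in 1:2) for (ch in 1:3)
    imgs[[length(imgs) + 1]] <- mk(r, 1, f, ch)
  sets <- group_image_set(imgs, list(`1` = "hoechst", `2` = "mitoid_red",
                                     `3` = "mitopy1"))
  expect_length(sets, 4)
  expect_true(all(vapply(sets, function(s) length(s$channels), integer(1)) == 3))
  # every image in exactly one set
  expect_equal(sum(vapply(sets, function(s) length(s$channels), integer(1))),
               length(imgs))
  # deterministic ordering by (row, column, field)
  ord <- t(vapply(sets, function(s) c(s$well, s$field), numeric(3)))
  expect_true(all(diff(ord[, 1] * 1e6 + ord[, 2] * 1e3 + ord[, 3]) > 0))

  expect_equal(group_image_set(list(), list()), list())
  expect_error(group_image_set(c(imgs, imgs[1]),
                               list(`1` = "hoechst", `2` = "mitoid_red",
                                    `3` = "mitopy1")),
               "duplicate image")
  expect_error(group_image_set(imgs, list(`1` = "hoechst")),
               "channel_map does not cover")
})

test_that("incomplete fields are flagged for the dyes an assay needs", {
  mk <- function(field, channel)
    channel_image(matrix(0.5, 4, 4), key = image_key(1, 1, field,
                                                     channel = channel))
  imgs <- list(mk(1, 1), mk(1, 2), mk(1, 3), mk(2, 1), mk(2, 2))
  sets <- group_image_set(imgs, list(`1` = "hoechst", `2` = "mitoid_red",
                                     `3` = "mitopy1"))
  expect_true(isTRUE(field_is_complete(sets[[1]],
                                       c("hoechst", "mitoid_red", "mitopy1"))))
  flag <- field_is_complete(sets[[2]], c("hoechst", "mitoid_red", "mitopy1"))
  expect_false(isTRUE(flag))
  expect_equal(attr(flag, "missing"), "mitopy1")
})

test_that("channel images validate their invariants", {
  expect_error(channel_image(matrix(1.5, 2, 2)), "\\[0, 1\\]")
  expect_error(channel_image(matrix(0.5, 2, 2), pixel_size_um = 0), "> 0")
  expect_error(image_key(0, 1, 1), "positive")
})
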