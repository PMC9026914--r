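test_that("speckle enhancement is a white top-hat", {
  flat <- matrix(0.4, 40, 40)
  expect_true(all(enhance_speckles(flat, 35) == 0))

  # single compact dot on flat background: preserved, background zero
  img <- matrix(0.1, 48, 48)
  img[23:25, 23:25] <- 0.9
  enh <- enhance_speckles(img, 35)
  expect_equal(enh[24, 24], 0.8, tolerance = 1e-12)
  expect_equal(enh[5, 5], 0)
  # matches the brute-force min/max filter composition
  want <- oracle_tophat(img, ceiling(35 / 2))
  expect_equal(enh, want, tolerance = 1e-12)
})

test_that("broad plateaus are suppressed while puncta survive", {
  img <- matrix(0.05, 90, 90)
  img[20:70, 20:70] <- 0.45           # plateau much larger than feature_size
  img[45, 45] <- 0.95                 # punctum riding on it
  enh <- enhance_speckles(img, 15)
  r <- ceiling(15 / 2)
  want <- oracle_tophat(img, r)
  expect_equal(enh, want, tolerance = 1e-12)
  # plateau interior (away from its rim) is flattened below 10% of height
  interior <- enh[35:40, 30:40]
  expect_lt(max(interior), 0.1 * 0.4)
  expect_gt(enh[45, 45], 0.4)
})

test_that("puncta detection recovers a known count and respects the size window", {
  set.seed(31)
  centers <- cbind(sample(seq(20, 236, by = 24), 20, replace = TRUE),
                   sample(seq(20, 236, by = 24)))
  centers <- unique(centers)
  img <- draw_dots(256, 256, centers, sigma = 2, amp = 0.5) +
    matrix(rnorm(256^2, 0.02, 0.005), 256, 256)
  img <- pmin(pmax(img, 0), 1)
  enh <- enhance_speckles(img, 35)
  p <- detect_puncta(enh)
  expect_gte(nrow(p$table), nrow(centers) - 1)
  expect_lte(nrow(p$table), nrow(centers) + 1)
  expect_true(all(p$table$eq_diameter >= 3 & p$table$eq_diameter <= 35))

  # generator fixture: detected count tracks the rendered puncta count
  d <- validation_design(
    conditions = data.frame(condition = "mid", puncta_density = 5,
                            polarization = 0.9, fragmentation = 0.1),
    seed = 77, wells_per_condition = 1L, fields_per_well = 1L)
  gf <- generate_field(d, 1, 1)
  truth_n <- sum(gf$truth$cells$true_puncta)
  enh2 <- enhance_speckles(correct_illumination(
    gf$images$channels$mitopy1$pixels), 35)
  p2 <- detect_puncta(enh2)
  # puncta sharing a tube can merge into one detected speckle, so the
  # count may undercount but never overcounts
  expect_lte(nrow(p2$table), truth_n + 1)
  expect_gte(nrow(p2$table), ceiling(0.5 * truth_n))

  # a 50-px blob exceeds the window
  blob <- matrix(0.05, 128, 128)
  d2 <- (row(blob) - 64)^2 + (col(blob) - 64)^2
  blob[d2 <= 25^2] <- 0.8
  pb <- detect_puncta(blob, threshold_spec("otsu3", middle_class = "foreground"))
  expect_equal(nrow(pb$table), 0L)
})

test_that("blank noise-only fields yield at most one false punctum", {
  for (sd in 1:3) {
    set.seed(sd)
    img <- pmin(pmax(matrix(rnorm(512^2, 0.02, 0.005), 512, 512), 0), 1)
    enh <- enhance_speckles(img, 35)
    p <- detect_puncta(enh)
    expect_lte(nrow(p$table), 1L)
  }
})

test_that("puncta are related to cells by centroid containment", {
  cells <- matrix(0L, 40, 40)
  cells[, 1:20] <- 1L; cells[, 21:34] <- 3L   # background strip on the right
  plab <- matrix(0L, 40, 40)
  plab[10:12, 10:12] <- 1L                    # inside cell 1
  plab[20:22, 19:23] <- 2L                    # straddles; centroid col 21 -> cell 3
  plab[30:32, 36:38] <- 3L                    # centroid on background
  tab <- measure_objects(plab)
  tab$parent_cell <- NA_integer_
  pset <- structure(list(labels = plab, table = tab), class = "puncta_set")
  rel <- relate_puncta_to_cells(pset, cells)
  expect_equal(rel$table$parent_cell, c(1L, 3L, NA_integer_))
})

test_that("the H2O2 level is the colocalized fraction of the mito mask", {
  cells <- matrix(0L, 30, 30); cells[1:30, 1:30] <- 1L
  mito <- matrix(FALSE, 30, 30); mito[10:14, 10:19] <- TRUE  # 50 px
  plab <- matrix(0L, 30, 30); plab[11:12, 11:15] <- 1L       # 10 px inside
  tab <- measure_objects(plab); tab$parent_cell <- 1L
  pset <- structure(list(labels = plab, table = tab), class = "puncta_set")
  res <- mito_h2o2_level(pset, mito, cells)
  expect_equal(res$h2o2_level, 0.2)
  expect_equal(res$coloc_area, 10)
  expect_equal(res$n_puncta, 1L)

  # no puncta: level 0 for every cell with mitochondria
  pset0 <- structure(list(labels = matrix(0L, 30, 30),
                          table = tab[0, ]), class = "puncta_set")
  res0 <- mito_h2o2_level(pset0, mito, cells)
  expect_equal(res0$h2o2_level, 0)

  # a cell with no mitochondrial area is excluded, not reported as zero
  cells2 <- cells; cells2[, 25:30] <- 2L
  res2 <- mito_h2o2_level(pset, mito, cells2)
  expect_equal(res2$cell, 1L)
  expect_equal(attr(res2, "n_excluded"), 1L)
})

test_that("the level is invariant to common intensity rescaling", {
  # area-based metric: thresholds are data-driven, so scaling both
  # channels by a constant in (0,1] keeps masks and level identical
  set.seed(13)
  d <- validation_design(seed = 5)
  gf <- generate_field(d, 2, 1)
  p <- validation_params()
  r1 <- suppressWarnings(analyze_field_h2o2(gf$images, p))
  gf2 <- gf
  for (nm in names(gf2$images$channels))
    gf2$images$channels[[nm]]$pixels <- gf2$images$channels[[nm]]$pixels * 0.5
  r2 <- suppressWarnings(analyze_field_h2o2(gf2$images, p))
  expect_equal(r1$h2o2_level, r2$h2o2_level, tolerance = 0.05)

  # coloc area never exceeds the total puncta footprint
  expect_lte(sum(r1$coloc_area), sum(r1$mito_area))
})
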