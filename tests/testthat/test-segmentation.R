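disk_image <- function(nr, nc, center, radius, value = 0.9, bg = 0.05) {
  img <- matrix(bg, nr, nc)
  d2 <- (row(img) - center[1])^2 + (col(img) - center[2])^2
  img[d2 <= radius^2] <- value
  img
}

test_that("labeling uses 8-connectivity and relabeling compacts", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal pair: one object
  m[5, 5] <- TRUE                    # separate object
  lab <- label_objects(m)
  expect_equal(attr(lab, "n_objects"), 2L)
  lab[lab == 1L] <- 0L
  out <- relabel_objects(lab)
  expect_equal(attr(out, "n_objects"), 1L)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
})

test_that("primary identification finds a disk with the right area", {
  img <- disk_image(64, 64, c(32, 32), 10)
  lab <- identify_primary(img, threshold_spec("otsu2"), c(5, 50))
  expect_equal(attr(lab, "n_objects"), 1L)
  area <- sum(lab > 0)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)
})

test_that("diameter window and border exclusion filter primary objects", {
  img <- disk_image(80, 80, c(20, 20), 2)           # diameter 4
  d2 <- (row(img) - 55)^2 + (col(img) - 55)^2
  img[d2 <= 100] <- 0.9                              # diameter 20
  lab <- identify_primary(img, threshold_spec("otsu2"), c(8, 40))
  expect_equal(attr(lab, "n_objects"), 1L)

  edge <- disk_image(64, 64, c(2, 32), 8)
  lab2 <- identify_primary(edge, threshold_spec("otsu2"), c(5, 50),
                           exclude_border = TRUE)
  expect_equal(attr(lab2, "n_objects"), 0L)
})

test_that("propagation fills one basin and splits uniform regions at the bisector", {
  img <- disk_image(48, 48, c(24, 24), 15)
  seeds <- matrix(0L, 48, 48); seeds[24, 24] <- 1L
  out <- identify_secondary_propagation(img, seeds, threshold_spec("otsu2"))
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_true(all(out[img > 0.5] == 1L))

  # uniform bright rectangle, two symmetric seeds: dividing line at the
  # perpendicular bisector within 1 px
  rect <- matrix(0.02, 40, 60); rect[10:30, 10:50] <- 0.8
  seeds2 <- matrix(0L, 40, 60); seeds2[20, 20] <- 1L; seeds2[20, 40] <- 2L
  out2 <- identify_secondary_propagation(rect, seeds2,
                                         threshold_spec("otsu2"),
                                         regularization = 0.05)
  fg <- rect > 0.5
  expect_setequal(unique(out2[fg]), c(1L, 2L))
  cols1 <- col(out2)[out2 == 1L]
  cols2 <- col(out2)[out2 == 2L]
  expect_lte(max(cols1), 31)   # bisector at column 30 +/- 1
  expect_gte(min(cols2), 30)
  # each seed contained in its object
  expect_equal(out2[20, 20], 1L)
  expect_equal(out2[20, 40], 2L)
  # partition of the above-threshold region
  expect_true(all(out2[fg] > 0))
})

test_that("infinite regularization converges to the nearest-seed partition", {
  rect <- matrix(0.8, 40, 60)
  rect[1, 1] <- 0  # keep the threshold below the plateau
  seeds <- matrix(0L, 40, 60); seeds[12, 15] <- 1L; seeds[30, 45] <- 2L
  out <- identify_secondary_propagation(rect, seeds,
                                        threshold_spec("manual",
                                                       manual_value = 0.5),
                                        regularization = 1e4)
  d1 <- (row(rect) - 12)^2 + (col(rect) - 15)^2
  d2 <- (row(rect) - 30)^2 + (col(rect) - 45)^2
  voronoi <- ifelse(d1 <= d2, 1L, 2L)
  fg <- rect > 0.5
  agree <- mean(out[fg] == voronoi[fg])
  expect_gt(agree, 0.98)   # disagreement only within 1 px of the bisector
})

test_that("tertiary subtraction satisfies the exact area identities", {
  secondary <- matrix(0L, 20, 20); secondary[3:12, 3:12] <- 1L  # area 100
  primary <- matrix(0L, 20, 20); primary[5:9, 5:10] <- 1L       # area 30
  tert <- identify_tertiary(secondary, primary)
  expect_equal(sum(tert == 1L), 100 - 30)

  # primary partially outside the secondary: only the overlap subtracts
  primary2 <- matrix(0L, 20, 20); primary2[9:13, 9:14] <- 1L    # area 30
  overlap <- sum(primary2 > 0 & secondary > 0)
  tert2 <- identify_tertiary(secondary, primary2)
  expect_equal(sum(tert2 == 1L), 100 - overlap)

  # empty primary: identity
  tert3 <- identify_tertiary(secondary, matrix(0L, 20, 20))
  expect_equal(tert3[3:12, 3:12], secondary[3:12, 3:12])

  expect_warning(identify_tertiary(matrix(0L, 20, 20), primary),
                 "no matching secondary")
})

test_that("object measurements satisfy their internal identities", {
  img <- disk_image(40, 40, c(20, 20), 8)
  lab <- identify_primary(img, threshold_spec("otsu2"), c(4, 30))
  m <- measure_objects(lab, list(sig = img))
  expect_equal(m$integrated_sig, m$mean_sig * m$area, tolerance = 1e-9)
  expect_lt(m$eccentricity, 0.2)   # a disk is round
  expect_equal(m$eq_diameter, 2 * sqrt(m$area / pi))
  expect_false(m$touches_border)

  line <- matrix(0L, 20, 20); line[10, 2:18] <- 1L
  ml <- measure_objects(line)
  expect_gt(ml$eccentricity, 0.99)  # 1-px line is maximally eccentric
})

test_that("filtering drops failing objects, is idempotent, names unknown features", {
  lab <- matrix(0L, 40, 60)
  lab[2:4, 2:11] <- 1L        # area 30
  lab[10:19, 10:19] <- 2L     # area 100
  lab[21:40, 25:54] <- 3L     # area 600
  m <- measure_objects(lab)
  out <- filter_objects(lab, m, criteria = list(list("area", 50, 500)))
  expect_equal(attr(out, "n_objects"), 1L)
  expect_equal(sum(out > 0), 100)

  # no criteria, no border drop: identity
  expect_equal(filter_objects(lab, m), relabel_objects(lab))
  # idempotent
  m2 <- measure_objects(out)
  again <- filter_objects(out, m2, criteria = list(list("area", 50, 500)))
  expect_equal(again, out)

  expect_error(filter_objects(lab, m, criteria = list(list("blob", 0, 1))),
               "unknown feature 'blob'.*area")

  # eccentricity criterion removes a line object
  line <- matrix(0L, 30, 30); line[5, 2:25] <- 1L; line[15:22, 10:17] <- 2L
  mline <- measure_objects(line)
  kept <- filter_objects(line, mline,
                         criteria = list(list("eccentricity", 0, 0.95)))
  expect_equal(attr(kept, "n_objects"), 1L)
})

test_that("filter never increases the object count", {
  set.seed(8)
  img <- matrix(rbinom(64 * 64, 1, 0.1) * 0.9, 64, 64)
  lab <- identify_primary(img, threshold_spec("otsu2"), c(0, Inf),
                          fill_holes = FALSE)
  m <- measure_objects(lab)
  out <- filter_objects(lab, m, criteria = list(list("area", 2, Inf)))
  expect_lte(attr(out, "n_objects"), attr(lab, "n_objects"))
})
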