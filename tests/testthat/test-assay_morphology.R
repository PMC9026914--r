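gauss_ridge <- function(nr, nc, row0, width_sigma, height = 1,
                        c0 = 1, c1 = nc) {
  img <- matrix(0, nr, nc)
  for (r in 1:nr) img[r, c0:c1] <- height * exp(-(r - row0)^2 /
                                                  (2 * width_sigma^2))
  img
}

test_that("tubeness responds to ridges, not flats, and prefers tubes to blobs", {
  expect_true(all(enhance_tubeness(matrix(0.3, 32, 32)) == 0))

  ridge <- gauss_ridge(41, 60, 21, 2, height = 0.8, c0 = 10, c1 = 50)
  resp <- enhance_tubeness(ridge, scale_sigma = 2)
  # maximal along the centerline, weak at 3 sigma lateral offset
  expect_equal(max(resp[, 30]), resp[21, 30])
  expect_lt(resp[21 + 6, 30], 0.2 * resp[21, 30])

  blob <- draw_dots(41, 41, cbind(21, 21), sigma = 2, amp = 0.8)
  both <- matrix(0, 41, 102)
  both[, 1:60] <- ridge
  both[, 62:102] <- blob
  r2 <- enhance_tubeness(both, scale_sigma = 2)
  expect_gt(r2[21, 30], r2[21, 82])  # equal-height blob scores lower
})

test_that("mitochondria segmentation counts clean tubes and filters sizes", {
  img <- matrix(0.01, 128, 128)
  rows <- seq(12, 120, by = 12)
  for (r in rows) img <- img + gauss_ridge(128, 128, r, 1.2, height = 0.6,
                                           c0 = 30, c1 = 98)
  enh <- enhance_tubeness(pmin(img, 1), scale_sigma = 1)
  lab <- segment_mitochondria(enh)
  expect_equal(attr(lab, "n_objects"), length(rows))

  # 1-px speckles below the diameter floor are removed
  sp <- matrix(0, 64, 64); sp[cbind(c(10, 30, 50), c(10, 30, 50))] <- 1
  lab2 <- segment_mitochondria(sp, manual_floor = 0.5)
  expect_equal(attr(lab2, "n_objects"), 0L)

  # a 150-px-diameter solid blob exceeds the window
  blob <- matrix(0, 200, 200)
  d2 <- (row(blob) - 100)^2 + (col(blob) - 100)^2
  blob[d2 <= 75^2] <- 1
  expect_equal(attr(segment_mitochondria(blob, manual_floor = 0.5),
                    "n_objects"), 0L)
})

test_that("granular spectrum matches an independent implementation", {
  set.seed(23)
  # many 2-px dots
  centers <- as.matrix(expand.grid(r = seq(6, 58, by = 8),
                                   c = seq(6, 58, by = 8)))
  dots <- matrix(0, 64, 64)
  dots[centers] <- 0.9
  dots[centers + cbind(rep(1, nrow(centers)), rep(0, nrow(centers)))] <- 0.9
  region <- matrix(TRUE, 64, 64)
  sp <- granularity_spectrum(dots, region, subsample = 1,
                             element_size = 5, length = 8)
  want <- oracle_granularity(dots, region, element_size = 5, length_out = 8)
  expect_lt(max(abs(sp$values - want)), 1e-9)
  expect_gte(sum(sp$values[1:2]), 90)

  # single solid 40-px disk: almost nothing at the smallest scale
  disk <- matrix(0, 64, 64)
  d2 <- (row(disk) - 32)^2 + (col(disk) - 32)^2
  disk[d2 <= 20^2] <- 0.8
  spd <- granularity_spectrum(disk, region, subsample = 1,
                              element_size = 30, length = 8)
  wantd <- oracle_granularity(disk, region, element_size = 30, length_out = 8)
  expect_lt(max(abs(spd$values - wantd)), 1e-9)
  expect_lt(spd$values[1], 10)

  # random texture: oracle agreement and the spectrum-sum bound
  tex <- matrix(runif(64 * 64), 64, 64)
  spt <- granularity_spectrum(tex, region, subsample = 1,
                              element_size = 5, length = 8)
  wantt <- oracle_granularity(tex, region, element_size = 5, length_out = 8)
  expect_lt(max(abs(spt$values - wantt)), 1e-9)
  expect_true(all(spt$values >= 0))
  expect_lte(sum(spt$values), 100 + 1e-9)
})

test_that("blank regions give an all-zero spectrum with a warning", {
  blank <- matrix(0, 32, 32)
  expect_warning(sp <- granularity_spectrum(blank, NULL, subsample = 1,
                                            element_size = 3, length = 5),
                 "zero total intensity")
  expect_equal(sp$values, rep(0, 5))
})

test_that("fragmentation percentage projects the leading spectrum bins", {
  sp <- structure(list(values = c(60, 20, 5, 1, 0), element_size = 10,
                       subsample = 1), class = "granularity_spectrum")
  expect_equal(fragmentation_percent(sp, 1), 60)
  expect_equal(fragmentation_percent(sp, 5), 86)
  expect_error(fragmentation_percent(sp, 6), "1..L")
})

test_that("skeleton lengths equal Dijkstra on the skeleton graph", {
  # horizontal bar 1 x 10
  bar <- matrix(0L, 5, 14); bar[3, 3:12] <- 1L
  rb <- skeletonize_and_measure(bar, pixel_size_um = 0.299)
  expect_equal(rb$objects$length_px, 9)
  expect_equal(rb$objects$length_um, 9 * 0.299)
  expect_equal(rb$objects$n_endpoints, 2L)

  # perfect 10-px diagonal
  dg <- matrix(0L, 14, 14); dg[cbind(3:12, 3:12)] <- 1L
  expect_equal(skeletonize_and_measure(dg)$objects$length_px, 9 * sqrt(2))

  # L of two 10-px arms sharing a corner
  L <- matrix(0L, 15, 15); L[3:12, 3] <- 1L; L[12, 3:12] <- 1L
  expect_equal(skeletonize_and_measure(L)$objects$length_px, 18)

  # branched cross: arms of 6 from a center; longest endpoint pair = 12
  cr <- matrix(0L, 15, 15); cr[8, 2:14] <- 1L; cr[2:14, 8] <- 1L
  rc <- skeletonize_and_measure(cr)
  expect_equal(rc$objects$n_endpoints, 4L)
  expect_equal(rc$objects$length_px, 12)

  # every fixture agrees with the independent Dijkstra oracle
  for (fix in list(bar, dg, L, cr)) {
    skel <- fix > 0
    ep <- skeleton_endpoints(skel)
    dists <- apply(utils::combn(nrow(ep), 2), 2, function(pr)
      oracle_skeleton_distance(skel, ep[pr[1], ], ep[pr[2], ]))
    expect_equal(skeletonize_and_measure(fix)$objects$length_px, max(dists))
  }
})

test_that("degenerate single-pixel objects are flagged with zero length", {
  dot <- matrix(0L, 9, 9); dot[5, 5] <- 1L
  r <- skeletonize_and_measure(dot)
  expect_true(r$objects$degenerate)
  expect_equal(r$objects$length_px, 0)
})

test_that("per-cell means and micrometre conversion are exact", {
  lab <- matrix(0L, 30, 40)
  lab[5, 5:14] <- 1L    # length 9
  lab[20, 5:10] <- 2L   # length 5
  lab[5, 30:37] <- 3L   # length 7, second cell
  cells <- matrix(0L, 30, 40); cells[, 1:20] <- 1L; cells[, 21:40] <- 2L
  r <- skeletonize_and_measure(lab, cells, pixel_size_um = 0.5)
  expect_equal(r$per_cell$mean_length_px, c(7, 7))
  expect_equal(r$per_cell$mean_length_um, r$per_cell$mean_length_px * 0.5)
  expect_equal(r$per_cell$n_mitochondria, c(2L, 1L))

  # endpoints have exactly one skeleton neighbour
  skel <- mitoscreen:::cpp_thin(lab > 0)
  ep <- skeleton_endpoints(skel)
  pad <- matrix(FALSE, 32, 42); pad[2:31, 2:41] <- skel
  for (k in seq_len(nrow(ep))) {
    nb <- sum(pad[ep[k, 1] + 1 + (-1:1), ep[k, 2] + 1 + (-1:1)]) - 1
    expect_equal(nb, 1)
  }
})

test_that("total-branch-length summary measures the whole skeleton", {
  cr <- matrix(0L, 15, 15); cr[8, 2:14] <- 1L; cr[2:14, 8] <- 1L
  rt <- skeletonize_and_measure(cr, summary = "total")
  expect_equal(rt$objects$length_px, 24)  # two 12-step arms
})
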