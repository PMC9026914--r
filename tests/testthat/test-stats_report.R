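test_that("condition summaries use the closed-form normal CI", {
  df <- data.frame(condition = "a", well_row = 1, well_column = 1,
                   field = c(1, 1, 1, 2), value = c(1, 2, 3, 2))
  s <- summarize_conditions(df, "value")[[1]]
  m <- mean(df$value); se <- sd(df$value) / 2
  z <- qnorm(0.975)
  expect_equal(s$mean, m)
  expect_equal(s$ci_lower, m - z * se, tolerance = 1e-9)
  expect_equal(s$ci_upper, m + z * se, tolerance = 1e-9)
  expect_equal(s$n_cells, 4L)
  expect_equal(s$n_fields, 2L)
  expect_true(s$ci_defined)

  # closed-form check on {1,2,3}
  df3 <- data.frame(condition = "a", well_row = 1, well_column = 1,
                    field = 1, value = c(1, 2, 3))
  s3 <- summarize_conditions(df3, "value")[[1]]
  expect_equal(s3$mean, 2)
  expect_equal(s3$ci_upper - s3$mean, qnorm(0.975) * 1 / sqrt(3),
               tolerance = 1e-9)

  # single value: mean reported, CI flagged undefined
  d1 <- data.frame(condition = "b", well_row = 1, well_column = 1,
                   field = 1, value = 5)
  s1 <- summarize_conditions(d1, "value")[[1]]
  expect_equal(s1$mean, 5)
  expect_false(s1$ci_defined)
})

test_that("replicate wells of the same condition agree within sampling error", {
  set.seed(71)
  inside <- 0
  for (i in 1:100) {
    v1 <- rnorm(40, 1, 0.2); v2 <- rnorm(40, 1, 0.2)
    se <- sqrt(var(v1) / 40 + var(v2) / 40)
    if (abs(mean(v1) - mean(v2)) <= 2 * se) inside <- inside + 1
  }
  expect_gte(inside, 93)  # ~95% expected under the normal approximation
})

test_that("boxplot-rule outlier flags match direct quartile computation", {
  v <- c(1, 2, 3, 4, 100)
  expect_equal(which(flag_outliers(v)), 5L)
  expect_true(all(!flag_outliers(c(1, 1, 1, 1, 1))))
  expect_warning(f <- flag_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(f, rep(FALSE, 3))

  # expected flag rate for a Gaussian sample is about 0.7%
  set.seed(61)
  rates <- vapply(1:20, function(i) mean(flag_outliers(rnorm(1000))),
                  numeric(1))
  expect_gt(mean(rates), 0.002)
  expect_lt(mean(rates), 0.015)
})

test_that("group comparisons reproduce textbook closed forms", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- compare_groups(g, design = "two")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$stars, "")

  # one-way ANOVA F on a 3-value-per-group toy example, closed form
  g3 <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  r3 <- compare_groups(g3, design = "multi")
  means <- vapply(g3, mean, numeric(1)); gm <- mean(unlist(g3))
  ssb <- 3 * sum((means - gm)^2); ssw <- sum(vapply(g3, function(v)
    sum((v - mean(v))^2), numeric(1)))
  f_want <- (ssb / 2) / (ssw / 6)
  expect_equal(r3$statistic, f_want, tolerance = 1e-12)
  expect_equal(nrow(r3$pairwise), 3L)
  # Tukey-adjusted p-values are never smaller than the unadjusted ones
  df_all <- data.frame(value = unlist(g3),
                       group = rep(names(g3), each = 3))
  pt <- pairwise.t.test(df_all$value, df_all$group, p.adjust.method = "none",
                        pool.sd = TRUE)$p.value
  praw <- c(pt["b", "a"], pt["c", "a"], pt["c", "b"])
  expect_true(all(r3$pairwise$p_adj >= praw - 1e-12))

  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(compare_groups(list(a = c(1, 2))), "at least 2 groups")
})

test_that("clearly separated groups are always detected", {
  set.seed(41)
  for (i in 1:5) {
    r <- compare_groups(list(a = rnorm(50, 0), b = rnorm(50, 5)),
                        design = "two")
    expect_lt(r$p_value, 0.001)
    expect_equal(r$stars, "***")
  }
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})

test_that("sampling-frame cell totals multiply out exactly", {
  expect_equal(unname(cell_count_range(c(48, 60), c(15, 40), 3)),
               c(2160, 7200))
  expect_equal(unname(cell_count_range(c(60, 80), c(15, 40), 2)),
               c(1800, 6400))
})
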