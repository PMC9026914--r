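# Condition/well/field summaries, boxplot-rule outlier flagging, and the
# group comparisons used to call dose effects: one-way ANOVA with Tukey
# post-hoc for >2 groups, equal-variance two-sample t-test for 2.

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-condition cell-total range from a sampling frame
#'
#' Given per-well field-count and per-field cell-count ranges and a
#' number of replicate wells, returns the minimal and maximal number of
#' cells a condition can contribute — the arithmetic printed in
#' figure captions of plate-based screens.
#'
#' @param fields_per_well `(min, max)` fields imaged per well.
#' @param cells_per_field `(min, max)` cells per field.
#' @param wells Number of replicate wells.
#' @return `c(min, max)` cell totals.
#' @export
cell_count_range <- function(fields_per_well, cells_per_field, wells) {
  c(min = fields_per_well[1] * cells_per_field[1] * wells,
    max = fields_per_well[2] * cells_per_field[2] * wells)
}

.mean_ci <- function(x, level = 0.95) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(mean = m, ci_lower = NA_real_, ci_upper = NA_real_, n = n))
  se <- stats::sd(x, na.rm = TRUE) / sqrt(n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean = m, ci_lower = m - z * se, ci_upper = m + z * se, n = n)
}

#' Flag outliers by the Tukey boxplot rule
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles
#' by linear interpolation (`quantile` type 7). Fewer than 4 values
#' cannot support the rule: nothing is flagged and a warning is issued.
#'
#' @param values Numeric vector.
#' @return Logical vector of flags, same length as `values`.
#' @export
flag_outliers <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values; no outlier flags assigned")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Summarize a per-cell metric at condition, well and field level
#'
#' For each condition: the pooled per-cell mean with a
#' normal-approximation 95% CI (`mean +/- 1.96 SE`), per-well and
#' per-field means, and boxplot-rule outlier flags of the per-cell
#' values within each well. Groups with a single value have an
#' undefined CI and are flagged.
#'
#' @param per_cell `data.frame` with columns `condition`, `well_row`,
#'   `well_column`, `field`, and the metric.
#' @param metric Name of the metric column.
#' @param level Confidence level.
#' @return List of per-condition summaries (class
#'   `condition_summary`), each with `condition`, `n_cells`,
#'   `n_fields`, `n_wells`, `mean`, `ci_lower`, `ci_upper`,
#'   `ci_defined`, `well_means`, `field_means`, `outliers` (list of
#'   logical vectors, one per well).
#' @export
summarize_conditions <- function(per_cell, metric, level = 0.95) {
  stopifnot(metric %in% names(per_cell),
            all(c("condition", "well_row", "well_column", "field") %in%
                  names(per_cell)))
  per_cell <- per_cell[!is.na(per_cell[[metric]]), , drop = FALSE]
  lapply(split(per_cell, per_cell$condition), function(d) {
    v <- d[[metric]]
    ci <- .mean_ci(v, level)
    wkey <- paste(d$well_row, d$well_column, sep = ":")
    wm <- tapply(v, wkey, mean)
    fkey <- paste(wkey, d$field, sep = ":")
    fm <- tapply(v, fkey, mean)
    outl <- lapply(split(v, wkey), function(x)
      if (length(x) >= 4) flag_outliers(x) else rep(FALSE, length(x)))
    structure(list(condition = d$condition[1],
                   n_cells = length(v),
                   n_fields = length(unique(fkey)),
                   n_wells = length(unique(wkey)),
                   mean = ci[["mean"]],
                   ci_lower = ci[["ci_lower"]],
                   ci_upper = ci[["ci_upper"]],
                   ci_defined = !is.na(ci[["ci_lower"]]),
                   well_means = data.frame(well = names(wm),
                                           mean = as.vector(wm)),
                   field_means = data.frame(well_field = names(fm),
                                            mean = as.vector(fm)),
                   outliers = outl),
              class = "condition_summary")
  })
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s: n=%d cells, %d fields, %d wells\n",
              x$condition, x$n_cells, x$n_fields, x$n_wells))
  cat(sprintf("  mean %.4f  95%% CI [%.4f, %.4f]%s\n", x$mean,
              x$ci_lower, x$ci_upper,
              if (!x$ci_defined) " (CI undefined, n < 2)" else ""))
  invisible(x)
}

#' Compare metric values across conditions
#'
#' `design = "multi"`: one-way ANOVA followed by Tukey's HSD for all
#' pairwise comparisons. `design = "two"`: Student's equal-variance
#' independent-samples t-test (`welch = TRUE` switches to Welch).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param design `"multi"` or `"two"`.
#' @param welch Use the Welch t-test instead of the pooled-variance
#'   Student test (two-group design only).
#' @return A `comparison_result`: list with `test`, `groups`,
#'   `statistic`, `p_value`, `pairwise` (`data.frame` of Tukey-adjusted
#'   pairwise p-values for the multi design) and `stars`.
#' @export
compare_groups <- function(values_by_group, design = c("multi", "two"),
                           welch = FALSE) {
  design <- match.arg(design)
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  ns <- vapply(values_by_group, length, integer(1))
  vs <- vapply(values_by_group, function(v) stats::var(v), numeric(1))
  bad <- names(values_by_group)[ns < 2 & (is.na(vs) | vs == 0)]
  if (length(bad) > 0)
    stop("group(s) with fewer than 2 values: ", paste(bad, collapse = ", "))
  if (design == "two") {
    if (length(values_by_group) != 2)
      stop("two-group design requires exactly 2 groups")
    tt <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                        var.equal = !welch)
    res <- list(test = if (welch) "welch_t" else "t_test",
                groups = names(values_by_group),
                statistic = unname(tt$statistic), p_value = tt$p.value,
                pairwise = NULL, stars = significance_stars(tt$p.value))
  } else {
    df <- data.frame(
      value = unlist(values_by_group, use.names = FALSE),
      group = factor(rep(names(values_by_group), ns),
                     levels = names(values_by_group)))
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$group
    pairwise <- data.frame(comparison = rownames(tuk),
                           diff = tuk[, "diff"],
                           p_adj = tuk[, "p adj"],
                           stars = significance_stars(tuk[, "p adj"]),
                           row.names = NULL)
    res <- list(test = "anova_tukey", groups = names(values_by_group),
                statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                pairwise = pairwise,
                stars = significance_stars(an[["Pr(>F)"]][1]))
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s over %d groups: statistic %.4g, p = %.3g %s\n",
              x$test, length(x$groups), x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}
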