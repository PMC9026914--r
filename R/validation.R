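# Reduced-scale dose-response study: the package's built-in validation
# experiment. Simulated plates sweep the three dose knobs together
# (H2O2 puncta density up, polarization down, fragmentation up) and every
# assay is run end to end, so qualitative dose trends and their
# statistics can be checked without a microscope.

#' Run the reduced-scale dose-response study
#'
#' Simulates `n_seeds` independent plates from [validation_design()]
#' (3 conditions x `wells_per_condition` wells x `fields_per_well`
#' fields, 256 px fields) and analyzes every field with all three
#' assays, sharing the segmentation front end between the assays that
#' use the mitochondrial channel.
#'
#' @param seed Master seed; each replicate plate derives its own seed
#'   from it.
#' @param n_seeds Number of independent replicate plates.
#' @param conditions Condition table (see [stress_conditions()]).
#' @param wells_per_condition,fields_per_well Plate layout.
#' @param params Analysis parameters (see [validation_params()]).
#' @return List of per-cell `data.frame`s (`h2o2`, `mmp`,
#'   `morphology`), each with `seed_rep` and `condition` columns.
#' @export
run_dose_response_study <- function(seed = 1L, n_seeds = 10L,
                                    conditions = stress_conditions(),
                                    wells_per_condition = 2L,
                                    fields_per_well = 10L,
                                    params = validation_params()) {
  acc <- list(h2o2 = list(), mmp = list(), morphology = list())
  for (k in seq_len(n_seeds)) {
    d <- validation_design(conditions = conditions,
                           seed = (seed + 977L * (k - 1L)) %% 2147483647L,
                           wells_per_condition = wells_per_condition,
                           fields_per_well = fields_per_well)
    for (w in seq_len(nrow(d$wells))) {
      for (f in seq_len(d$fields_per_well)) {
        gf <- generate_field(d, w, f)
        seg <- suppressWarnings(segment_field(gf$images, params,
                                              cell_channel = "mitoid_red"))
        res <- list(
          h2o2 = suppressWarnings(analyze_field_h2o2(gf$images, params, seg)),
          mmp = suppressWarnings(analyze_field_mmp(gf$images, params)),
          morphology = suppressWarnings(
            analyze_field_morphology(gf$images, params, seg)))
        for (a in names(res)) {
          r <- res[[a]]
          if (nrow(r) == 0) next
          r$condition <- d$wells$condition[w]
          r$seed_rep <- k
          acc[[a]][[length(acc[[a]]) + 1L]] <- r
        }
      }
    }
  }
  lapply(acc, function(lst) {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  })
}

#' Dose-trend summary of a per-cell metric
#'
#' Orders conditions as given (assumed increasing dose), computes the
#' per-condition means of the metric, the Spearman correlation between
#' dose rank and condition mean, and the one-way ANOVA across
#' conditions on the per-cell values.
#'
#' @param per_cell Per-cell `data.frame` with `condition` and the
#'   metric.
#' @param metric Metric column name.
#' @param condition_order Conditions in increasing dose order.
#' @return List with `means` (named, in dose order), `spearman_rho`,
#'   `anova` (a `comparison_result`), `monotone_increasing`,
#'   `monotone_decreasing`.
#' @export
dose_trend <- function(per_cell, metric,
                       condition_order = stress_conditions()$condition) {
  v <- per_cell[[metric]]
  keep <- !is.na(v)
  v <- v[keep]; cond <- as.character(per_cell$condition)[keep]
  stopifnot(all(cond %in% condition_order))
  means <- vapply(condition_order, function(cc) mean(v[cond == cc]), numeric(1))
  rho <- stats::cor(seq_along(means), means, method = "spearman")
  groups <- split(v, factor(cond, levels = condition_order))
  an <- compare_groups(groups, design = "multi")
  list(means = means, spearman_rho = rho, anova = an,
       monotone_increasing = all(diff(means) > 0),
       monotone_decreasing = all(diff(means) < 0))
}
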