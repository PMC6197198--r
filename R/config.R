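#' Analysis configuration
#'
#' All thresholds of the pipeline live in one flat configuration list so that
#' a whole analysis is reproducible from a single YAML file. Defaults are the
#' values used throughout the study design: intervals are delimited by two
#' same-ingredient prescriptions at most 20 days apart, intervals shorter
#' than 6 hours are outliers and the combined outlier trim is 10%, profile
#' features must pass an uncorrected p < 0.05 screen, fall outside the risk
#' ratio band (0.5, 2), sit inside the per-type information-content
#' interquartile band and survive a Bonferroni-corrected p < 0.05, and
#' classifiers are random forests with 100 trees evaluated over 10 folds.
#'
#' @param max_gap_days maximum allowed gap between the two delimiting
#'   prescriptions of an interval, in days.
#' @param min_interval_hours intervals shorter than this are trimmed as
#'   outliers.
#' @param outlier_fraction total fraction of intervals removed by outlier
#'   trimming (short intervals first, then the longest).
#' @param trim_scope `"ingredient"` trims within each ingredient's interval
#'   pool, `"global"` over all intervals jointly.
#' @param continuation_scope continuations are kept only for patients who
#'   never had a dose change; `"ingredient"` scopes "never" to the same
#'   (patient, ingredient) pair, `"patient"` to the whole patient record.
#' @param max_lookback_days history window before t1 used to build features
#'   (`Inf` = the entire prior record).
#' @param p_screen uncorrected p-value screen (cascade step 1).
#' @param rr_band risk-ratio exclusion band: features with
#'   `rr_band[1] < RR < rr_band[2]` are removed (cascade step 2).
#' @param ic_reference reference distribution for the per-type IC quartile
#'   band: `"all"` uses every feature tested for that type, `"post_rr"` only
#'   the survivors of the RR filter.
#' @param ic_band_conditions optional fixed (open) IC band for condition
#'   features, e.g. `c(4.25, 12.75)`, overriding the quartile rule for that
#'   type; `NULL` applies the quartile rule to conditions too.
#' @param alpha family-wise significance level for the Bonferroni step.
#' @param bonferroni_scope `"all_tested"` sets the Bonferroni m to the number
#'   of features tested for this subject and outcome; `"post_ic"` to the
#'   number entering the correction step after the IC filter.
#' @param top_k per-type cap for the reduced profile variant (top `k`
#'   smallest p-values per feature type).
#' @param profile_variant `"top_k"` uses the capped profile for
#'   classification, `"all_significant"` every feature that survived the
#'   cascade.
#' @param rf_num_trees number of trees in the random forest.
#' @param n_folds number of cross-validation folds.
#' @param balance `"before"` balances classes once before fold splitting,
#'   `"per_fold"` re-balances each training set.
#' @param min_case,min_control minimum case/control interval counts for a
#'   subject to be eligible for classification.
#' @param max_prescriptions subjects whose ingredient(s) were prescribed more
#'   often than this are excluded.
#' @param cutoff_year calendar year held out in the temporal validation.
#'
#' @return A named list of class `pd_config`.
#' @examples
#' cfg <- pd_config(outlier_fraction = 0.10)
#' cfg$max_gap_days
#' @export
pd_config <- function(max_gap_days = 20,
                      min_interval_hours = 6,
                      outlier_fraction = 0.10,
                      trim_scope = c("ingredient", "global"),
                      continuation_scope = c("ingredient", "patient"),
                      max_lookback_days = Inf,
                      p_screen = 0.05,
                      rr_band = c(0.5, 2),
                      ic_reference = c("all", "post_rr"),
                      ic_band_conditions = NULL,
                      alpha = 0.05,
                      bonferroni_scope = c("all_tested", "post_ic"),
                      top_k = 100,
                      profile_variant = c("top_k", "all_significant"),
                      rf_num_trees = 100,
                      n_folds = 10,
                      balance = c("before", "per_fold"),
                      min_case = 150,
                      min_control = 150,
                      max_prescriptions = 55000,
                      cutoff_year = 2014) {
  stopifnot(max_gap_days > 0, min_interval_hours >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            length(rr_band) == 2, rr_band[1] < rr_band[2],
            p_screen > 0, p_screen <= 1, alpha > 0, alpha <= 1,
            top_k >= 1, rf_num_trees >= 1, n_folds >= 2)
  cfg <- list(
    max_gap_days = max_gap_days,
    min_interval_hours = min_interval_hours,
    outlier_fraction = outlier_fraction,
    trim_scope = match.arg(trim_scope),
    continuation_scope = match.arg(continuation_scope),
    max_lookback_days = max_lookback_days,
    p_screen = p_screen,
    rr_band = rr_band,
    ic_reference = match.arg(ic_reference),
    ic_band_conditions = ic_band_conditions,
    alpha = alpha,
    bonferroni_scope = match.arg(bonferroni_scope),
    top_k = as.integer(top_k),
    profile_variant = match.arg(profile_variant),
    rf_num_trees = as.integer(rf_num_trees),
    n_folds = as.integer(n_folds),
    balance = match.arg(balance),
    min_case = min_case,
    min_control = min_control,
    max_prescriptions = max_prescriptions,
    cutoff_year = as.integer(cutoff_year)
  )
  structure(cfg, class = "pd_config")
}

#' Read an analysis configuration from YAML
#'
#' Unspecified keys fall back to the [pd_config()] defaults; unknown keys are
#' an error so typos cannot silently change an analysis.
#'
#' @param path path to a YAML file whose keys are [pd_config()] arguments.
#' @return A `pd_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pd_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pd_config, vals)
}

#' @export
print.pd_config <- function(x, ...) {
  cat("<pd_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
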