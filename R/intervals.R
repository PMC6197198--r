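# Dose-change interval detection. An interval is a pair of consecutive
# same-ingredient prescriptions for one patient, with the same route and
# unit, at most `max_gap_days` apart; its label (reduction / increase /
# continuation) compares the two (quantity, frequency) doses.

#' Pair consecutive same-ingredient prescriptions into candidate intervals
#'
#' Every consecutive pair of prescriptions of the same ingredient within a
#' patient yields one candidate interval; consecutiveness guarantees that no
#' third same-ingredient prescription falls strictly between the two. Pairs
#' with differing route or unit, a non-positive gap, or a gap above
#' `max_gap_days` are discarded.
#'
#' @param prescriptions a prescriptions tibble (see [read_prescriptions()]).
#' @param max_gap_days maximum allowed gap in days.
#' @return A tibble of candidate intervals with columns `interval_id,
#'   patient_id, ingredient, t1, t2, quantity1, frequency1, quantity2,
#'   frequency2, route, unit, duration_hours`.
#' @export
pair_prescriptions <- function(prescriptions, max_gap_days = 20) {
  require_columns(prescriptions, RX_COLS, "prescriptions")
  out <- prescriptions |>
    arrange(.data$patient_id, .data$ingredient, .data$timestamp) |>
    group_by(.data$patient_id, .data$ingredient) |>
    mutate(t2 = lead(.data$timestamp),
           quantity2 = lead(.data$dose_quantity),
           frequency2 = lead(.data$frequency),
           route2 = lead(.data$route),
           unit2 = lead(.data$unit),
           pair_index = row_number()) |>
    ungroup() |>
    filter(!is.na(.data$t2)) |>
    rename(t1 = "timestamp", quantity1 = "dose_quantity", frequency1 = "frequency") |>
    mutate(duration_hours = as.numeric(difftime(.data$t2, .data$t1, units = "hours"))) |>
    filter(.data$route == .data$route2, .data$unit == .data$unit2,
           .data$duration_hours > 0,
           .data$duration_hours <= max_gap_days * 24) |>
    mutate(interval_id = paste(.data$patient_id, .data$ingredient,
                               .data$pair_index, sep = "#")) |>
    select("interval_id", "patient_id", "ingredient", "t1", "t2",
           "quantity1", "frequency1", "quantity2", "frequency2",
           "route", "unit", "duration_hours")
  out
}

#' Classify a dose move as reduction, increase or continuation
#'
#' A reduction is a decrease in quantity with a non-increasing frequency, or
#' a decrease in frequency with a non-increasing quantity; increases are
#' symmetric; unchanged quantity and frequency is a continuation. Conflicting
#' moves (one component up, the other down) are resolved on the daily dose
#' `quantity * frequency`, with an exact tie classified as continuation.
#' Comparisons are exact: doses are entered values, not measurements.
#'
#' @param quantity1,frequency1 dose of the first prescription (vectorized).
#' @param quantity2,frequency2 dose of the second prescription.
#' @return Character vector with values `"reduction"`, `"increase"`,
#'   `"continuation"`.
#' @examples
#' classify_dose_change(10, 1, 5, 1)    # reduction
#' classify_dose_change(10, 2, 20, 1)   # daily dose tie -> continuation
#' @export
classify_dose_change <- function(quantity1, frequency1, quantity2, frequency2) {
  daily1 <- quantity1 * frequency1
  daily2 <- quantity2 * frequency2
  case_when(
    quantity2 < quantity1 & frequency2 <= frequency1 ~ "reduction",
    frequency2 < frequency1 & quantity2 <= quantity1 ~ "reduction",
    quantity2 > quantity1 & frequency2 >= frequency1 ~ "increase",
    frequency2 > frequency1 & quantity2 >= quantity1 ~ "increase",
    quantity2 == quantity1 & frequency2 == frequency1 ~ "continuation",
    daily2 < daily1 ~ "reduction",
    daily2 > daily1 ~ "increase",
    .default = "continuation"
  )
}

#' Trim outlier intervals
#'
#' Removes all intervals shorter than `min_hours`, then the longest intervals
#' until the combined removed fraction reaches `target_fraction` of the input
#' count (if the short-side removal already reaches the target, nothing more
#' is trimmed). Long-side ties are broken deterministically by duration
#' (descending), then patient id and t1 (ascending). Pools with fewer than 10
#' intervals get no long-side trimming (with a warning), since a quantile cut
#' is meaningless there. Trimming is applied within each ingredient's pool by
#' default, mirroring the per-drug design of the study.
#'
#' @param intervals a labelled or unlabelled interval tibble.
#' @param min_hours short-interval threshold, hours.
#' @param target_fraction combined fraction of intervals to remove.
#' @param scope `"ingredient"` or `"global"`.
#' @return The surviving intervals; attribute `trimmed` holds per-arm removal
#'   counts (`short`, `long`).
#' @export
trim_outliers <- function(intervals, min_hours = 6, target_fraction = 0.10,
                          scope = c("ingredient", "global")) {
  scope <- match.arg(scope)
  if (nrow(intervals) == 0) {
    attr(intervals, "trimmed") <- c(short = 0L, long = 0L)
    return(intervals)
  }
  groups <- if (scope == "ingredient") intervals$ingredient else rep("all", nrow(intervals))
  keep <- logical(nrow(intervals))
  n_short_total <- 0L; n_long_total <- 0L; warned <- FALSE
  for (g in unique(groups)) {
    idx <- which(groups == g)
    dur <- intervals$duration_hours[idx]
    short <- dur < min_hours
    n_target <- floor(target_fraction * length(idx) + 1e-9)
    n_long <- max(0L, n_target - sum(short))
    if (length(idx) < 10) {
      n_long <- 0L
      if (!warned) {
        warn("Fewer than 10 intervals in a trimming pool; no long-side trimming applied")
        warned <- TRUE
      }
    }
    surv <- idx[!short]
    drop_long <- integer(0)
    if (n_long > 0 && length(surv) > 0) {
      ord <- order(-intervals$duration_hours[surv],
                   intervals$patient_id[surv],
                   intervals$t1[surv])
      drop_long <- surv[ord][seq_len(min(n_long, length(surv)))]
    }
    keep[setdiff(surv, drop_long)] <- TRUE
    n_short_total <- n_short_total + sum(short)
    n_long_total <- n_long_total + length(drop_long)
  }
  out <- intervals[keep, , drop = FALSE]
  attr(out, "trimmed") <- c(short = n_short_total, long = n_long_total)
  out
}

#' Restrict continuations to never-changed patients
#'
#' Dose-continuation intervals are kept only when the patient never
#' experienced a dose change (up or down) for that ingredient anywhere in
#' the record; all reduction and increase intervals are kept, as dose
#' changes may legitimately precede or follow continuations. The "never
#' changed" scope is per (patient, ingredient) by default so that a change
#' on one drug does not disqualify a patient's other drugs.
#'
#' @param intervals a labelled interval tibble (column `label`).
#' @param scope `"ingredient"` or `"patient"`.
#' @return The retained study intervals.
#' @export
select_study_intervals <- function(intervals, scope = c("ingredient", "patient")) {
  scope <- match.arg(scope)
  require_columns(intervals, "label", "intervals")
  key <- if (scope == "ingredient") c("patient_id", "ingredient") else "patient_id"
  changed <- intervals |>
    filter(.data$label != "continuation") |>
    distinct(dplyr::across(dplyr::all_of(key)))
  keep_changes <- intervals |> filter(.data$label != "continuation")
  keep_cont <- intervals |>
    filter(.data$label == "continuation") |>
    anti_join(changed, by = key)
  bind_rows(keep_changes, keep_cont) |>
    arrange(.data$patient_id, .data$ingredient, .data$t1)
}

#' Extract labelled study intervals from prescriptions
#'
#' Runs the full interval stage: consecutive-pair candidates, dose-move
#' classification, outlier trimming and the never-changed continuation
#' restriction.
#'
#' @param prescriptions a prescriptions tibble.
#' @param config a [pd_config()].
#' @return A labelled interval tibble; attribute `counts` holds per-label
#'   totals and attribute `trimmed` the outlier removal counts.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 50, seed = 1))
#' iv <- extract_intervals(sim$prescriptions)
#' table(iv$label)
#' @export
extract_intervals <- function(prescriptions, config = pd_config()) {
  candidates <- pair_prescriptions(prescriptions, config$max_gap_days)
  labelled <- candidates |>
    mutate(label = classify_dose_change(.data$quantity1, .data$frequency1,
                                        .data$quantity2, .data$frequency2))
  trimmed <- trim_outliers(labelled, config$min_interval_hours,
                           config$outlier_fraction,
                           scope = config$trim_scope)
  out <- select_study_intervals(trimmed, scope = config$continuation_scope)
  attr(out, "trimmed") <- attr(trimmed, "trimmed")
  attr(out, "counts") <- table(out$label)
  out
}

#' Write / read labelled intervals
#'
#' @param intervals interval tibble.
#' @param path CSV path.
#' @return `path` (writer) or the interval tibble (reader).
#' @export
write_intervals <- function(intervals, path) {
  out <- intervals |>
    mutate(t1 = format(.data$t1, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           t2 = format(.data$t2, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  stopifnot(file.exists(path))
  readr::read_csv(path, col_types = readr::cols(
    interval_id = readr::col_character(),
    patient_id = readr::col_character(),
    ingredient = readr::col_character(),
    t1 = readr::col_datetime(), t2 = readr::col_datetime(),
    route = readr::col_character(), unit = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double())) |>
    mutate(t1 = lubridate::with_tz(.data$t1, "UTC"),
           t2 = lubridate::with_tz(.data$t2, "UTC"))
}
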