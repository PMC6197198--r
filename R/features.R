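# Per-interval binary phenotype features: everything observed in the
# patient's record strictly before the first prescription of the interval,
# optionally expanded with all is-a ancestors. Features are presence-only
# sets; counts and temporal order are deliberately not encoded.

#' History features of intervals
#'
#' For each interval, collects the deduplicated set of `(feature_type,
#' feature_id)` pairs over all clinical events of the same patient with a
#' timestamp strictly before `t1` (events at exactly `t1` are excluded). The
#' lookback window defaults to the entire prior record.
#'
#' @param intervals an interval tibble (needs `interval_id, patient_id, t1`).
#' @param events a clinical-events tibble.
#' @param max_lookback_days restrict history to this many days before `t1`.
#' @return A long tibble `interval_id, feature_type, feature_id`; intervals
#'   with no qualifying events contribute no rows.
#' @export
history_features <- function(intervals, events, max_lookback_days = Inf) {
  require_columns(intervals, c("interval_id", "patient_id", "t1"), "intervals")
  require_columns(events, EV_COLS, "clinical events")
  if (nrow(events) == 0 || nrow(intervals) == 0) {
    return(tibble(interval_id = character(0), feature_type = character(0),
                  feature_id = character(0)))
  }
  ev <- events |> select("patient_id", "feature_type", "feature_id",
                         ev_time = "timestamp")
  out <- intervals |>
    select("interval_id", "patient_id", "t1") |>
    inner_join(ev, by = "patient_id", relationship = "many-to-many") |>
    filter(.data$ev_time < .data$t1)
  if (is.finite(max_lookback_days)) {
    out <- out |> filter(.data$ev_time >= .data$t1 - max_lookback_days * 86400)
  }
  out |>
    distinct(.data$interval_id, .data$feature_type, .data$feature_id) |>
    arrange(.data$interval_id, .data$feature_type, .data$feature_id)
}

#' Expand feature sets through ontology hierarchies
#'
#' Adds, for every diagnosis and condition feature of an interval, all of its
#' strict is-a ancestors; laboratory features are never expanded (their
#' vocabulary has no hierarchy). The result is a superset of the input for
#' every interval.
#'
#' @param features a long feature tibble (`interval_id, feature_type,
#'   feature_id`).
#' @param ontologies a named list of `pd_ontology` objects keyed by feature
#'   type; types without an entry (or with an empty ontology) pass through
#'   unchanged.
#' @return The expanded long feature tibble (deduplicated).
#' @export
expand_features <- function(features, ontologies) {
  require_columns(features, c("interval_id", "feature_type", "feature_id"),
                  "features")
  added <- list()
  for (type in intersect(names(ontologies), unique(features$feature_type))) {
    ont <- ontologies[[type]]
    if (is.null(ont) || nrow(ont$closure) == 0) next
    stopifnot(inherits(ont, "pd_ontology"))
    added[[type]] <- features |>
      filter(.data$feature_type == type) |>
      inner_join(ont$closure, by = c(feature_id = "child"),
                 relationship = "many-to-many") |>
      mutate(feature_id = .data$ancestor) |>
      select("interval_id", "feature_type", "feature_id")
  }
  bind_rows(features, bind_rows(added)) |>
    distinct(.data$interval_id, .data$feature_type, .data$feature_id) |>
    arrange(.data$interval_id, .data$feature_type, .data$feature_id)
}

#' Build the per-interval feature dataset
#'
#' History collection followed by ontology expansion, with per-type raw and
#' expanded totals attached (attribute `feature_counts`) in the shape of a
#' feature-count summary table.
#'
#' @inheritParams history_features
#' @inheritParams expand_features
#' @param patients optional character vector of known patient ids; an
#'   interval referencing a patient outside it is a fatal error.
#' @param config a [pd_config()]; supplies the lookback window.
#' @return The expanded long feature tibble with attribute `feature_counts`.
#' @export
build_feature_dataset <- function(intervals, events, ontologies = list(),
                                  patients = NULL, config = pd_config()) {
  if (!is.null(patients)) {
    unknown <- setdiff(intervals$patient_id, patients)
    if (length(unknown) > 0) {
      abort(paste0("Interval references unknown patient '", unknown[1], "'"))
    }
  }
  raw <- history_features(intervals, events, config$max_lookback_days)
  expanded <- expand_features(raw, ontologies)
  counts <- dplyr::full_join(
    raw |> count(.data$feature_type, name = "n_raw"),
    expanded |> count(.data$feature_type, name = "n_expanded"),
    by = "feature_type")
  attr(expanded, "feature_counts") <- counts
  expanded
}

#' Write / read long-format feature tables
#' @param features long feature tibble.
#' @param path CSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  stopifnot(file.exists(path))
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}
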