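# Result tables, profile JSON export and the adverse-drug-response (ADR)
# disproportionality check.

#' ADR disproportionality between reduction and continuation intervals
#'
#' Counts mentions of ADR-classified conditions whose timestamp falls inside
#' an interval (the closed window `[t1, t2]`) and compares the per-interval
#' mention rate of dose-reduction intervals against continuations with a
#' risk ratio. Mentions, not distinct conditions, are counted. When either
#' arm has zero mentions the Haldane-Anscombe +0.5 correction keeps the
#' ratio finite.
#'
#' @param intervals labelled interval tibble.
#' @param condition_events condition-mention events tibble.
#' @param adr_codes character vector of condition feature ids classified as
#'   adverse drug responses (an input list, never hard-coded).
#' @param subject display name.
#' @return A one-row tibble `subject, adr_mentions_reduction, n_reduction,
#'   adr_mentions_continuation, n_continuation, rr`.
#' @export
adr_disproportionality <- function(intervals, condition_events, adr_codes,
                                   subject = "all") {
  n_red <- sum(intervals$label == "reduction")
  n_cont <- sum(intervals$label == "continuation")
  if (n_cont == 0) abort("No continuation intervals: ADR disproportion undefined")
  if (n_red == 0) abort("No reduction intervals: ADR disproportion undefined")
  mentions <- intervals |>
    filter(.data$label %in% c("reduction", "continuation")) |>
    select("interval_id", "patient_id", "t1", "t2", "label") |>
    inner_join(condition_events |>
                 filter(.data$feature_id %in% adr_codes) |>
                 select("patient_id", "timestamp"),
               by = "patient_id", relationship = "many-to-many") |>
    filter(.data$timestamp >= .data$t1, .data$timestamp <= .data$t2) |>
    count(.data$label)
  m_red <- sum(mentions$n[mentions$label == "reduction"])
  m_cont <- sum(mentions$n[mentions$label == "continuation"])
  corr <- (m_red == 0 || m_cont == 0) * 0.5
  rr <- ((m_red + corr) / n_red) / ((m_cont + corr) / n_cont)
  tibble(subject = subject,
         adr_mentions_reduction = m_red, n_reduction = n_red,
         adr_mentions_continuation = m_cont, n_continuation = n_cont,
         rr = rr)
}

#' Combine evaluation results into a ranked results table
#'
#' A pure rendering of already-computed `dose_eval` objects: one row per
#' subject with cross-validation and holdout metrics side by side, sorted by
#' holdout F-measure descending. Subjects skipped in the holdout setting
#' keep their row with `NA` metrics and the skip reason (rendered as a dash
#' by [format_results()]).
#'
#' @param results a list of `dose_eval` objects (any mix of settings).
#' @return A tibble, one row per subject x outcome.
#' @export
results_table <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- bind_rows(lapply(results, glance))
  wide <- rows |>
    tidyr::pivot_wider(id_cols = c("subject", "outcome"),
                       names_from = "setting",
                       values_from = c("n_instances", "auc_roc", "f_measure",
                                       "precision", "recall", "reason")) |>
    arrange(dplyr::desc(!is.na(.data[["f_measure_holdout"]])),
            desc(.data[["f_measure_holdout"]]))
  wide
}

#' @rdname results_table
#' @param table a results table from [results_table()].
#' @param digits number of digits for metric columns.
#' @return `format_results()`: a character matrix with dashes for skipped
#'   cells, suitable for printing.
#' @export
format_results <- function(table, digits = 2) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    v <- round(out[[j]], digits)
    out[[j]] <- if_else(is.na(v), "—", format(v, nsmall = digits))
  }
  as.matrix(out)
}

#' Export / read a phenotype profile as JSON
#'
#' The JSON schema is the one behind a profile browser: subject, outcome,
#' Bonferroni m, case/control sizes and an ordered feature array with
#' fields `type, id, label, a, b, c, d, p, p_bonferroni_threshold, rr, ic,
#' direction`, ordered by `|log RR|` descending. Negative associations carry
#' the `"NO "` label prefix. `read_profile_json()` reconstructs an
#' equivalent `phenotype_profile`.
#'
#' @param profile a `phenotype_profile`.
#' @param path output path.
#' @return `path` invisibly (writer); a `phenotype_profile` (reader).
#' @export
export_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "phenotype_profile"))
  feats <- profile$features |>
    arrange(desc(abs(.data$log_rr)), .data$p_value, .data$feature_id)
  obj <- list(
    subject = profile$subject,
    outcome = profile$outcome,
    n_case = profile$n_case,
    n_control = profile$n_control,
    bonferroni_m = profile$bonferroni_m,
    features = lapply(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      list(type = f$feature_type, id = f$feature_id, label = f$display_label,
           a = f$a, b = f$b, c = f$c, d = f$d,
           p = f$p_value, p_bonferroni_threshold = f$p_bonferroni_threshold,
           rr = f$rr, ic = f$ic, direction = f$direction)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname export_profile_json
#' @export
read_profile_json <- function(path) {
  stopifnot(file.exists(path))
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (length(obj$features) == 0) {
    tibble(feature_type = character(0), feature_id = character(0),
           a = integer(0), b = integer(0), c = integer(0), d = integer(0),
           n_corpus = integer(0), rr = numeric(0), direction = character(0),
           p_value = numeric(0), ic = numeric(0), log_rr = numeric(0),
           display_label = character(0), p_bonferroni_threshold = numeric(0))
  } else {
    bind_rows(lapply(obj$features, function(f) {
      tibble(feature_type = f$type, feature_id = f$id,
             a = as.integer(f$a), b = as.integer(f$b),
             c = as.integer(f$c), d = as.integer(f$d),
             n_corpus = NA_integer_,
             rr = f$rr, direction = f$direction, p_value = f$p,
             ic = f$ic, log_rr = log(f$rr), display_label = f$label,
             p_bonferroni_threshold = f$p_bonferroni_threshold)
    }))
  }
  structure(list(subject = obj$subject, outcome = obj$outcome,
                 features = feats, filtering = NULL,
                 bonferroni_m = obj$bonferroni_m,
                 n_case = obj$n_case, n_control = obj$n_control,
                 interval_ids = NULL),
            class = "phenotype_profile")
}
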