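# Phenotype-profile construction: per-feature enrichment statistics of case
# intervals (dose reduction or increase) against continuation intervals, and
# the filter cascade (p screen, risk-ratio band, information-content band,
# Bonferroni, ontology-aware elim pruning). The analysis unit is always the
# interval, never the patient.

#' One-sided hypergeometric tail p-value for a 2x2 presence table
#'
#' The table counts case intervals with/without the feature (`a`, `b`) and
#' control intervals with/without it (`c`, `d`). With population
#' `N = a+b+c+d`, feature-positive total `K = a+c` and case draws `n = a+b`,
#' the positive direction tests `P(X >= a)` and the negative direction
#' `P(X <= a)` under the hypergeometric distribution.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorized).
#' @param direction `"positive"` (over-representation, upper tail) or
#'   `"negative"` (lower tail); vectorized.
#' @return Numeric vector of exact tail probabilities.
#' @examples
#' hypergeom_pvalue(0, 10, 0, 10, "positive")  # 1
#' @export
hypergeom_pvalue <- function(a, b, c, d, direction = "positive") {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  n_case <- a + b
  K <- a + c
  N <- a + b + c + d
  up <- phyper(a - 1, K, N - K, n_case, lower.tail = FALSE)
  lo <- phyper(a, K, N - K, n_case, lower.tail = TRUE)
  ifelse(rep(direction, length.out = length(a)) == "negative", lo, up)
}

#' Exact integer-arithmetic hypergeometric tail (reference enumeration)
#'
#' Independent of [hypergeom_pvalue()]'s distribution-function route: the
#' tail is enumerated term by term from exact 64-bit binomial coefficients
#' with 128-bit accumulation (supported for tables with `N <= 62`). Intended
#' as a verification oracle.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of tail probabilities.
#' @export
hypergeom_tail_exact <- function(a, b, c, d, direction = "positive") {
  lower <- rep(direction, length.out = length(a)) == "negative"
  n <- max(length(a), length(b), length(c), length(d))
  hypergeom_tail_exact_cpp(as.integer(rep(a, length.out = n)),
                           as.integer(rep(b, length.out = n)),
                           as.integer(rep(c, length.out = n)),
                           as.integer(rep(d, length.out = n)),
                           rep(lower, length.out = n))
}

#' Risk ratio of a presence table
#'
#' `RR = (a/(a+b)) / (c/(c+d))`. When a zero in `a` or `c` would make the
#' ratio zero or infinite, the Haldane-Anscombe correction (+0.5 to every
#' cell) is applied first.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of risk ratios (finite and positive).
#' @examples
#' risk_ratio(10, 10, 5, 15)  # 2
#' @export
risk_ratio <- function(a, b, c, d) {
  corr <- a == 0 | c == 0
  a2 <- a + 0.5 * corr; b2 <- b + 0.5 * corr
  c2 <- c + 0.5 * corr; d2 <- d + 0.5 * corr
  (a2 / (a2 + b2)) / (c2 / (c2 + d2))
}

#' Information content of features over an interval corpus
#'
#' `IC = -log2(f)` where `f` is the fraction of corpus intervals whose
#' feature set contains the feature. High IC marks rare features, IC = 0 a
#' feature present in every interval.
#'
#' @param n_with number of corpus intervals containing the feature
#'   (vectorized).
#' @param n_total total number of corpus intervals.
#' @return Numeric vector of IC values in bits.
#' @export
information_content <- function(n_with, n_total) {
  stopifnot(n_total > 0)
  if (any(n_with <= 0)) {
    abort("Information content is undefined for unobserved features")
  }
  -log2(n_with / n_total)
}

#' Per-feature contingency counts of case vs control interval groups
#'
#' Exact presence counts over intervals. Every feature observed in either
#' group is reported.
#'
#' @param case_ids,control_ids disjoint character vectors of interval ids.
#' @param features long feature tibble (`interval_id, feature_type,
#'   feature_id`), typically the expanded dataset.
#' @return A tibble `feature_type, feature_id, a, b, c, d`.
#' @export
contingency_counts <- function(case_ids, control_ids, features) {
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    abort("Empty case or control interval group")
  }
  if (length(intersect(case_ids, control_ids)) > 0) {
    abort("Case and control interval groups must be disjoint")
  }
  n_case <- length(case_ids)
  n_control <- length(control_ids)
  feats <- features |>
    filter(.data$interval_id %in% c(case_ids, control_ids)) |>
    mutate(arm = if_else(.data$interval_id %in% case_ids, "a", "c")) |>
    count(.data$feature_type, .data$feature_id, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n", values_fill = 0L)
  if (!"a" %in% names(feats)) feats$a <- 0L
  if (!"c" %in% names(feats)) feats$c <- 0L
  feats |>
    mutate(b = n_case - .data$a, d = n_control - .data$c) |>
    select("feature_type", "feature_id", "a", "b", "c", "d") |>
    arrange(.data$feature_type, .data$feature_id)
}

feature_stats_table <- function(case_ids, control_ids, features,
                                corpus_ids = NULL) {
  counts <- contingency_counts(case_ids, control_ids, features)
  if (is.null(corpus_ids)) corpus_ids <- c(case_ids, control_ids)
  corpus_n <- features |>
    filter(.data$interval_id %in% corpus_ids) |>
    count(.data$feature_type, .data$feature_id, name = "n_corpus")
  counts |>
    left_join(corpus_n, by = c("feature_type", "feature_id")) |>
    mutate(
      rr = risk_ratio(.data$a, .data$b, .data$c, .data$d),
      direction = if_else(.data$rr < 1, "negative", "positive"),
      p_value = hypergeom_pvalue(.data$a, .data$b, .data$c, .data$d,
                                 .data$direction),
      n_corpus = dplyr::coalesce(.data$n_corpus, .data$a + .data$c),
      ic = information_content(pmax(.data$n_corpus, 1L), length(corpus_ids)),
      log_rr = log(.data$rr),
      display_label = if_else(.data$direction == "negative",
                              paste0("NO ", .data$feature_id),
                              .data$feature_id)
    )
}

#' Ontology-aware elim pruning of enrichment results
#'
#' Removes every feature that is more general than another feature in the
#' list (i.e. is one of its strict ancestors) but is associated with the
#' outcome with an equal or higher p-value. Decisions are taken in a single
#' pass against the original p-values, not iterated to a fixpoint. With an
#' empty ontology (laboratory orders) this is a no-op.
#'
#' @param stats a feature-statistics tibble for ONE feature type (columns
#'   `feature_id`, `p_value`).
#' @param ontology a `pd_ontology` for that type (or `NULL`).
#' @return `stats` with the dominated general features removed.
#' @export
elim_filter <- function(stats, ontology = NULL) {
  if (is.null(ontology) || nrow(ontology$closure) == 0 || nrow(stats) == 0) {
    return(stats)
  }
  pairs <- ontology$closure |>
    filter(.data$child %in% stats$feature_id,
           .data$ancestor %in% stats$feature_id)
  if (nrow(pairs) == 0) return(stats)
  p_of <- setNames(stats$p_value, stats$feature_id)
  dominated <- unique(pairs$ancestor[p_of[pairs$ancestor] >= p_of[pairs$child]])
  stats |> filter(!(.data$feature_id %in% dominated))
}

#' Build a phenotype profile for one subject and outcome
#'
#' Computes per-feature enrichment statistics of case intervals (label ==
#' `outcome`) against continuation intervals, then applies the filter
#' cascade in order: (1) uncorrected p < `p_screen`; (2) remove features
#' with risk ratio inside `rr_band`; (3) remove features with information
#' content in the first or fourth quartile of the per-type IC reference
#' distribution (for conditions a fixed band can be configured instead);
#' (4) Bonferroni-corrected p < `alpha`; (5) elim pruning per feature type.
#' Per-step survivor counts are recorded. An empty profile is a valid
#' result.
#'
#' @param intervals labelled interval tibble for one subject (drug or drug
#'   set); case intervals are those with `label == outcome`, controls the
#'   continuations.
#' @param features expanded long feature tibble covering these intervals.
#' @param ontologies named list of `pd_ontology` per feature type.
#' @param config a [pd_config()].
#' @param outcome `"reduction"` or `"increase"`.
#' @param subject display name of the drug or drug set.
#' @param corpus_ids interval ids defining the IC corpus (defaults to the
#'   case and control intervals supplied).
#' @return An object of class `phenotype_profile`: the surviving feature
#'   statistics (ordered by `|log RR|` descending), the per-step filter
#'   counts, the Bonferroni `m`, and the interval ids the statistics were
#'   computed from.
#' @export
build_profile <- function(intervals, features, ontologies = list(),
                          config = pd_config(),
                          outcome = c("reduction", "increase"),
                          subject = NULL, corpus_ids = NULL) {
  outcome <- match.arg(outcome)
  case_ids <- intervals$interval_id[intervals$label == outcome]
  control_ids <- intervals$interval_id[intervals$label == "continuation"]
  stats <- feature_stats_table(case_ids, control_ids, features, corpus_ids)

  count_row <- function(step, s) {
    tibble(step = step,
           diagnosis = sum(s$feature_type == "diagnosis"),
           condition = sum(s$feature_type == "condition"),
           lab = sum(s$feature_type == "lab"))
  }

  # (1) uncorrected screen
  s1 <- stats |> filter(.data$p_value < config$p_screen)
  # (2) risk-ratio band
  s2 <- s1 |> filter(.data$rr <= config$rr_band[1] | .data$rr >= config$rr_band[2])
  # (3) information-content band, per type
  ic_ref <- if (config$ic_reference == "all") stats else s2
  keep3 <- logical(nrow(s2))
  for (type in unique(s2$feature_type)) {
    sel <- s2$feature_type == type
    if (type == "condition" && !is.null(config$ic_band_conditions)) {
      band <- config$ic_band_conditions
      keep3[sel] <- s2$ic[sel] > band[1] & s2$ic[sel] < band[2]
    } else {
      ref <- ic_ref$ic[ic_ref$feature_type == type]
      q <- quantile(ref, c(0.25, 0.75), names = FALSE, type = 7)
      keep3[sel] <- s2$ic[sel] >= q[1] & s2$ic[sel] <= q[2]
    }
  }
  s3 <- s2[keep3, , drop = FALSE]
  # (4) Bonferroni
  m <- if (config$bonferroni_scope == "all_tested") nrow(stats) else nrow(s3)
  m <- max(m, 1L)
  s4 <- s3 |> filter(.data$p_value < config$alpha / m)
  # (5) elim, per type
  if (nrow(s4) > 0) {
    s5 <- bind_rows(lapply(split(s4, s4$feature_type), function(g)
      elim_filter(g, ontologies[[g$feature_type[1]]])))
  } else {
    s5 <- s4
  }

  filtering <- bind_rows(
    count_row("tested", stats), count_row("p_screen", s1),
    count_row("rr_filter", s2), count_row("ic_filter", s3),
    count_row("p_correction", s4), count_row("elim", s5))

  feats <- s5 |>
    mutate(p_bonferroni_threshold = config$alpha / m) |>
    arrange(desc(abs(.data$log_rr)), .data$p_value, .data$feature_id)

  structure(list(subject = subject %||% "all",
                 outcome = outcome,
                 features = feats,
                 filtering = filtering,
                 bonferroni_m = m,
                 n_case = length(case_ids),
                 n_control = length(control_ids),
                 interval_ids = c(case_ids, control_ids)),
            class = "phenotype_profile")
}

#' Keep the top-k smallest-p features per type
#'
#' Selection is on the p-value (ties broken by `|log RR|` descending, then
#' feature id); the surviving features are re-ordered for display by
#' `|log RR|` descending.
#'
#' @param profile a `phenotype_profile`.
#' @param k per-type cap.
#' @return The capped `phenotype_profile`.
#' @export
top_k_per_type <- function(profile, k = 100) {
  stopifnot(inherits(profile, "phenotype_profile"))
  profile$features <- profile$features |>
    arrange(.data$p_value, desc(abs(.data$log_rr)), .data$feature_id) |>
    group_by(.data$feature_type) |>
    slice(seq_len(min(k, n()))) |>
    ungroup() |>
    arrange(desc(abs(.data$log_rr)), .data$p_value, .data$feature_id)
  profile$top_k <- k
  profile
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat("<phenotype_profile> ", x$subject, " / ", x$outcome, "\n", sep = "")
  cat("  cases: ", x$n_case, "  controls: ", x$n_control,
      "  Bonferroni m: ", x$bonferroni_m, "\n", sep = "")
  if (nrow(x$features) == 0) {
    cat("  (empty profile: no feature met significance)\n")
  } else {
    cat("  ", nrow(x$features), " features (",
        paste(sprintf("%s: %d", FEATURE_TYPES,
                      sapply(FEATURE_TYPES, function(t)
                        sum(x$features$feature_type == t))), collapse = ", "),
        ")\n", sep = "")
    print(head(x$features |>
                 select("display_label", "feature_type", "p_value", "rr", "ic"), 10))
  }
  invisible(x)
}

#' @export
tidy.phenotype_profile <- function(x, ...) {
  x$features |>
    mutate(subject = x$subject, outcome = x$outcome) |>
    select("subject", "outcome", dplyr::everything())
}

#' @export
glance.phenotype_profile <- function(x, ...) {
  tibble(subject = x$subject, outcome = x$outcome,
         n_case = x$n_case, n_control = x$n_control,
         bonferroni_m = x$bonferroni_m,
         n_features = nrow(x$features),
         empty = nrow(x$features) == 0)
}

#' @export
autoplot.phenotype_profile <- function(object, top_n = 30, ...) {
  feats <- head(object$features, top_n)
  if (nrow(feats) == 0) {
    return(ggplot() +
             labs(title = paste0(object$subject, " / ", object$outcome,
                                 ": empty profile")))
  }
  feats <- feats |>
    mutate(display_label = factor(.data$display_label,
                                  levels = rev(unique(.data$display_label))))
  ggplot(feats, aes(x = .data$display_label, y = .data$log_rr / log(2),
                    fill = .data$feature_type)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~feature_type, scales = "free_y") +
    labs(x = NULL, y = "log2 risk ratio",
         title = paste0("Phenotype profile: ", object$subject, " / ",
                        object$outcome)) +
    theme_minimal()
}
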