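# Balanced random-forest classification of dose-change vs continuation
# intervals over profile-filtered binary feature matrices, with the two
# evaluation protocols: stratified 10-fold cross-validation with per-fold
# profile construction, and hold-last-year-out temporal validation. Feature
# selection always sees training intervals only.

#' Eligibility of a subject for classification
#'
#' A drug or drug set is eligible when it has at least `min_case` case and
#' `min_control` control intervals, a non-empty phenotype profile, and (when
#' a prescription count is supplied) no more than `max_prescriptions` total
#' prescriptions.
#'
#' @param intervals labelled interval tibble for the subject.
#' @param profile a `phenotype_profile` (or `NULL` to skip that check).
#' @param outcome the case label.
#' @param n_prescriptions optional total prescription count for the subject.
#' @param config a [pd_config()].
#' @return A one-row tibble `eligible, reason, n_case, n_control`.
#' @export
check_eligibility <- function(intervals, profile = NULL,
                              outcome = c("reduction", "increase"),
                              n_prescriptions = NULL, config = pd_config()) {
  outcome <- match.arg(outcome)
  n_case <- sum(intervals$label == outcome)
  n_control <- sum(intervals$label == "continuation")
  reason <- NA_character_
  if (n_case < config$min_case) {
    reason <- "min case count"
  } else if (n_control < config$min_control) {
    reason <- "min control count"
  } else if (!is.null(profile) && nrow(profile$features) == 0) {
    reason <- "empty profile"
  } else if (!is.null(n_prescriptions) &&
             n_prescriptions > config$max_prescriptions) {
    reason <- "too many prescriptions"
  }
  tibble(eligible = is.na(reason), reason = reason,
         n_case = n_case, n_control = n_control)
}

#' Encode intervals as a binary profile-feature matrix
#'
#' Entry `(i, j)` is 1 iff profile feature `j` belongs to interval `i`'s
#' (expanded) feature set; absent or missing features are 0. Columns are
#' exactly the profile's features; a profile feature absent from the feature
#' universe is a fatal error (it cannot have been selected from these data).
#'
#' @param intervals interval tibble (rows of the matrix).
#' @param profile a `phenotype_profile`.
#' @param features expanded long feature tibble (the feature universe).
#' @return A list with `x` (0/1 matrix, rownames = interval ids, colnames =
#'   `type|id` keys) and `y` (factor with levels `control`, `case` when a
#'   `label` column and profile outcome are available).
#' @export
encode_matrix <- function(intervals, profile, features) {
  stopifnot(inherits(profile, "phenotype_profile"))
  if (nrow(profile$features) == 0) abort("Cannot encode an empty profile")
  keys <- paste(profile$features$feature_type, profile$features$feature_id,
                sep = "|")
  universe <- unique(paste(features$feature_type, features$feature_id, sep = "|"))
  missing <- setdiff(keys, universe)
  if (length(missing) > 0) {
    abort(paste0("Profile feature absent from the feature universe: ",
                 missing[1]))
  }
  ids <- intervals$interval_id
  x <- matrix(0L, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  hits <- features |>
    filter(.data$interval_id %in% ids) |>
    mutate(key = paste(.data$feature_type, .data$feature_id, sep = "|")) |>
    filter(.data$key %in% keys)
  x[cbind(match(hits$interval_id, ids), match(hits$key, keys))] <- 1L
  y <- NULL
  if ("label" %in% names(intervals)) {
    y <- factor(if_else(intervals$label == profile$outcome, "case", "control"),
                levels = c("control", "case"))
  }
  list(x = x, y = y)
}

#' Balance case and control intervals by undersampling
#'
#' The majority class is randomly undersampled without replacement to the
#' minority size; the draw is seeded and reproducible.
#'
#' @param intervals labelled interval tibble.
#' @param outcome the case label.
#' @param seed integer seed for the draw.
#' @return The balanced interval tibble (cases first, then controls).
#' @export
balance_intervals <- function(intervals, outcome = "reduction", seed = 1L) {
  cases <- intervals |> filter(.data$label == outcome)
  controls <- intervals |> filter(.data$label == "continuation")
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    abort("Both classes must be non-empty to balance")
  }
  n <- min(nrow(cases), nrow(controls))
  withr::with_seed(seed, {
    if (nrow(cases) > n) cases <- cases[sample(nrow(cases), n), , drop = FALSE]
    if (nrow(controls) > n) controls <- controls[sample(nrow(controls), n), , drop = FALSE]
  })
  bind_rows(cases, controls)
}

#' Train the dose-change random forest
#'
#' 100 trees by default, unlimited depth, and `floor(log2(m) + 1)` candidate
#' features per split for `m` columns; the forest emits class-probability
#' scores. Training is single-threaded for bitwise reproducibility.
#'
#' @param x binary feature matrix.
#' @param y factor of class labels (`control`/`case`).
#' @param config a [pd_config()].
#' @param seed integer seed for the forest.
#' @return A fitted `ranger` probability forest.
#' @export
train_dose_rf <- function(x, y, config = pd_config(), seed = 1L) {
  m <- ncol(x)
  if (m == 0) abort("Cannot train on a matrix with zero features")
  mtry <- max(1L, floor(log2(m) + 1))
  ranger::ranger(x = x, y = y,
                 num.trees = config$rf_num_trees,
                 mtry = min(mtry, m),
                 min.node.size = 1,
                 probability = TRUE,
                 num.threads = 1,
                 seed = seed)
}

rf_case_scores <- function(model, x) {
  p <- stats::predict(model, data = x, num.threads = 1)$predictions
  p[, "case"]
}

auc_score <- function(y, scores) {
  if (length(unique(scores)) < 2 || length(unique(y)) < 2) return(0.5)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                 levels = c("control", "case"),
                                 direction = "<", quiet = TRUE)))
}

# unweighted two-class average precision/recall at a 0.5 score threshold;
# undefined precision (no predictions for a class) counts as 0
macro_prf <- function(y, scores) {
  pred <- factor(if_else(scores > 0.5, "case", "control"),
                 levels = c("control", "case"))
  prec <- rec <- numeric(2)
  for (i in seq_along(levels(y))) {
    cl <- levels(y)[i]
    tp <- sum(pred == cl & y == cl)
    prec[i] <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec[i] <- if (sum(y == cl) > 0) tp / sum(y == cl) else 0
  }
  c(precision = mean(prec), recall = mean(rec))
}

new_dose_eval <- function(subject, outcome, setting, folds, n_instances,
                          instrumentation = NULL, skipped = FALSE,
                          reason = NA_character_) {
  if (!skipped) {
    precision <- mean(folds$precision)
    recall <- mean(folds$recall)
    f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    auc <- mean(folds$auc)
  } else {
    precision <- recall <- f <- auc <- NA_real_
  }
  structure(list(subject = subject, outcome = outcome, setting = setting,
                 folds = folds, n_instances = n_instances,
                 auc_roc = auc, precision = precision, recall = recall,
                 f_measure = f, skipped = skipped, reason = reason,
                 instrumentation = instrumentation),
            class = "dose_eval")
}

#' Ten-fold cross-validation with per-fold profile construction
#'
#' The balanced interval set is split into stratified folds. Within each
#' fold, the full profile cascade (and the per-type top-k cap, when the
#' `top_k` profile variant is configured) runs on the nine training folds
#' only; the held-out fold is then encoded over that fold's profile and
#' scored. A fold whose training profile is empty yields uninformative
#' constant scores (0.5). AUC and the two-class-averaged precision/recall
#' are macro-averaged over folds; the F-measure is the harmonic mean of the
#' aggregated precision and recall. `n_instances` is the mean training-set
#' size over folds.
#'
#' @param intervals labelled interval tibble for one subject.
#' @param features expanded long feature tibble.
#' @param ontologies named list of `pd_ontology` per feature type.
#' @param config a [pd_config()].
#' @param seed integer seed (balancing, folds, forests).
#' @param outcome the case label.
#' @param subject display name.
#' @return A `dose_eval` object (setting `"cv10"`) with per-fold metrics and
#'   instrumentation (per-fold profile features and the interval ids used to
#'   build them).
#' @export
cross_validate_10fold <- function(intervals, features, ontologies = list(),
                                  config = pd_config(), seed = 1L,
                                  outcome = c("reduction", "increase"),
                                  subject = NULL) {
  outcome <- match.arg(outcome)
  balanced <- balance_intervals(intervals, outcome, seed = seed)
  y_all <- if_else(balanced$label == outcome, "case", "control")
  n_folds <- config$n_folds
  fold_of <- integer(nrow(balanced))
  withr::with_seed(seed + 1L, {
    for (cl in c("case", "control")) {
      idx <- which(y_all == cl)
      fold_of[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  folds <- list(); instr <- list()
  for (k in seq_len(n_folds)) {
    train <- balanced[fold_of != k, , drop = FALSE]
    test <- balanced[fold_of == k, , drop = FALSE]
    prof <- build_profile(train, features, ontologies, config,
                          outcome = outcome, subject = subject,
                          corpus_ids = train$interval_id)
    if (config$profile_variant == "top_k") prof <- top_k_per_type(prof, config$top_k)
    y_test <- factor(if_else(test$label == outcome, "case", "control"),
                     levels = c("control", "case"))
    if (nrow(prof$features) == 0) {
      scores <- rep(0.5, nrow(test))
    } else {
      enc_train <- encode_matrix(train, prof, features)
      enc_test <- encode_matrix(test, prof, features)
      model <- train_dose_rf(enc_train$x, enc_train$y, config, seed = seed + k)
      scores <- rf_case_scores(model, enc_test$x)
    }
    pr <- macro_prf(y_test, scores)
    folds[[k]] <- tibble(fold = k, n_train = nrow(train), n_test = nrow(test),
                         n_profile_features = nrow(prof$features),
                         auc = auc_score(y_test, scores),
                         precision = pr[["precision"]], recall = pr[["recall"]])
    instr[[k]] <- list(
      train_ids = train$interval_id,
      test_ids = test$interval_id,
      profile_interval_ids = prof$interval_ids,
      profile_features = paste(prof$features$feature_type,
                               prof$features$feature_id, sep = "|"))
  }
  folds <- bind_rows(folds)
  new_dose_eval(subject %||% "all", outcome, "cv10", folds,
                n_instances = mean(folds$n_train), instrumentation = instr)
}

#' Hold-last-year-out temporal validation
#'
#' Intervals are assigned to the training or test side by the calendar year
#' of `t1`: years before `cutoff_year` train, the cutoff year tests. Both
#' sides are balanced independently; the profile is built from the training
#' side only. A subject whose training-side profile is empty is skipped with
#' a reason rather than scored.
#'
#' @inheritParams cross_validate_10fold
#' @param cutoff_year test calendar year.
#' @return A `dose_eval` (setting `"holdout"`), possibly skipped.
#' @export
holdout_last_year <- function(intervals, features, ontologies = list(),
                              config = pd_config(), seed = 1L,
                              outcome = c("reduction", "increase"),
                              subject = NULL, cutoff_year = NULL) {
  outcome <- match.arg(outcome)
  cutoff_year <- cutoff_year %||% config$cutoff_year
  yr <- lubridate::year(intervals$t1)
  train_all <- intervals[yr < cutoff_year, , drop = FALSE]
  test_all <- intervals[yr == cutoff_year, , drop = FALSE]
  if (nrow(train_all) == 0) abort("Empty training side: no intervals before the cutoff year")
  if (nrow(test_all) == 0) abort("Empty test side: no intervals in the cutoff year")
  train <- balance_intervals(train_all, outcome, seed = seed)
  test <- balance_intervals(test_all, outcome, seed = seed + 1L)
  prof <- build_profile(train, features, ontologies, config,
                        outcome = outcome, subject = subject,
                        corpus_ids = train$interval_id)
  if (config$profile_variant == "top_k") prof <- top_k_per_type(prof, config$top_k)
  if (nrow(prof$features) == 0) {
    return(new_dose_eval(subject %||% "all", outcome, "holdout",
                         folds = tibble(), n_instances = nrow(train),
                         skipped = TRUE, reason = "empty profile"))
  }
  enc_train <- encode_matrix(train, prof, features)
  enc_test <- encode_matrix(test, prof, features)
  model <- train_dose_rf(enc_train$x, enc_train$y, config, seed = seed + 2L)
  scores <- rf_case_scores(model, enc_test$x)
  y_test <- enc_test$y
  pr <- macro_prf(y_test, scores)
  folds <- tibble(fold = 1L, n_train = nrow(train), n_test = nrow(test),
                  n_profile_features = nrow(prof$features),
                  auc = auc_score(y_test, scores),
                  precision = pr[["precision"]], recall = pr[["recall"]])
  new_dose_eval(subject %||% "all", outcome, "holdout", folds,
                n_instances = nrow(train),
                instrumentation = list(list(
                  train_ids = train$interval_id,
                  test_ids = test$interval_id,
                  profile_interval_ids = prof$interval_ids,
                  profile_features = paste(prof$features$feature_type,
                                           prof$features$feature_id, sep = "|"))))
}

#' @export
print.dose_eval <- function(x, ...) {
  cat("<dose_eval> ", x$subject, " / ", x$outcome, " [", x$setting, "]\n", sep = "")
  if (x$skipped) {
    cat("  skipped: ", x$reason, "\n", sep = "")
  } else {
    cat(sprintf("  n_instances: %.0f  AUC-ROC: %.3f  F: %.3f (P %.3f; R %.3f)\n",
                x$n_instances, x$auc_roc, x$f_measure, x$precision, x$recall))
  }
  invisible(x)
}

#' @export
tidy.dose_eval <- function(x, ...) {
  if (nrow(x$folds) == 0) return(x$folds)
  x$folds |>
    mutate(subject = x$subject, outcome = x$outcome, setting = x$setting) |>
    select("subject", "outcome", "setting", dplyr::everything())
}

#' @export
glance.dose_eval <- function(x, ...) {
  tibble(subject = x$subject, outcome = x$outcome, setting = x$setting,
         n_instances = x$n_instances, auc_roc = x$auc_roc,
         f_measure = x$f_measure, precision = x$precision, recall = x$recall,
         skipped = x$skipped, reason = x$reason)
}

#' @export
autoplot.dose_eval <- function(object, ...) {
  if (nrow(object$folds) == 0) {
    return(ggplot() + labs(title = paste0(object$subject, ": skipped (",
                                          object$reason, ")")))
  }
  ggplot(object$folds, aes(x = factor(.data$fold), y = .data$auc)) +
    geom_point(size = 2) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = "fold", y = "AUC-ROC",
         title = paste0(object$subject, " / ", object$outcome, " [",
                        object$setting, "]")) +
    theme_minimal()
}
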