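fake_intervals <- function(n_case, n_control) {
  tibble::tibble(
    interval_id = sprintf("i%05d", seq_len(n_case + n_control)),
    patient_id = sprintf("p%05d", seq_len(n_case + n_control)),
    ingredient = "X",
    t1 = ts("2010-01-01") + seq_len(n_case + n_control) * 3600,
    label = c(rep("reduction", n_case), rep("continuation", n_control)))
}

test_that("eligibility applies the instance, profile and volume rules", {
  cfg <- pd_config()
  el <- check_eligibility(fake_intervals(149, 10000), config = cfg)
  expect_false(el$eligible); expect_equal(el$reason, "min case count")
  el2 <- check_eligibility(fake_intervals(300, 149), config = cfg)
  expect_false(el2$eligible); expect_equal(el2$reason, "min control count")
  empty_prof <- structure(list(features = tibble::tibble()), class = "phenotype_profile")
  el3 <- check_eligibility(fake_intervals(300, 300), empty_prof, config = cfg)
  expect_false(el3$eligible); expect_equal(el3$reason, "empty profile")
  full_prof <- structure(list(features = tibble::tibble(feature_id = "F")),
                         class = "phenotype_profile")
  el4 <- check_eligibility(fake_intervals(300, 300), full_prof,
                           n_prescriptions = 54000, config = cfg)
  expect_true(el4$eligible)
  el5 <- check_eligibility(fake_intervals(300, 300), full_prof,
                           n_prescriptions = 55001, config = cfg)
  expect_false(el5$eligible); expect_equal(el5$reason, "too many prescriptions")
})

test_that("matrix encoding is binary over exactly the profile features", {
  iv <- fake_intervals(2, 1)
  feats <- tibble::tibble(
    interval_id = c("i00001", "i00001", "i00002"),
    feature_type = c("lab", "diagnosis", "lab"),
    feature_id = c("L1", "D1", "L1"))
  prof <- structure(list(
    outcome = "reduction",
    features = tibble::tibble(feature_type = c("lab", "diagnosis"),
                              feature_id = c("L1", "D1"))),
    class = "phenotype_profile")
  enc <- encode_matrix(iv, prof, feats)
  expect_equal(dim(enc$x), c(3, 2))
  expect_equal(unname(enc$x[, "lab|L1"]), c(1, 1, 0))
  expect_equal(unname(enc$x[, "diagnosis|D1"]), c(1, 0, 0))
  expect_equal(as.character(enc$y), c("case", "case", "control"))
  # all-zero row for the feature-less interval is valid
  expect_equal(sum(enc$x[3, ]), 0)
  # row order invariance
  enc2 <- encode_matrix(iv[c(3, 1, 2), ], prof, feats)
  expect_equal(enc2$x[rownames(enc$x), ], enc$x)
  # leakage guard: profile feature outside the universe is fatal
  bad_prof <- prof
  bad_prof$features <- tibble::tibble(feature_type = "lab", feature_id = "NOPE")
  expect_error(encode_matrix(iv, bad_prof, feats), "absent from the feature universe")
})

test_that("balancing undersamples the majority class reproducibly", {
  iv <- fake_intervals(400, 1000)
  bal <- balance_intervals(iv, seed = 3)
  expect_equal(sum(bal$label == "reduction"), 400)
  expect_equal(sum(bal$label == "continuation"), 400)
  expect_equal(balance_intervals(iv, seed = 3), bal)
  expect_false(identical(balance_intervals(iv, seed = 4), bal))
  # already balanced: all rows kept
  iv2 <- fake_intervals(50, 50)
  expect_setequal(balance_intervals(iv2, seed = 1)$interval_id, iv2$interval_id)
  expect_error(balance_intervals(fake_intervals(5, 0), seed = 1), "non-empty")
})

test_that("forest uses floor(log2(m)+1) split candidates and separates planted signal", {
  withr::with_seed(42, {
    x300 <- matrix(rbinom(40 * 300, 1, 0.3), nrow = 40,
                   dimnames = list(NULL, sprintf("f%03d", 1:300)))
    y <- factor(rep(c("control", "case"), 20), levels = c("control", "case"))
    model <- train_dose_rf(x300, y, seed = 1)
    expect_equal(model$mtry, 9)  # floor(log2(300) + 1)
    x1 <- matrix(rbinom(40, 1, 0.5), ncol = 1, dimnames = list(NULL, "f1"))
    expect_equal(train_dose_rf(x1, y, seed = 1)$mtry, 1)
    # one perfectly predictive feature: training-set AUC is 1
    xsep <- cbind(sep = as.integer(y == "case"),
                  noise = rbinom(40, 1, 0.5))
    msep <- train_dose_rf(xsep, y, seed = 1)
    scores <- predict(msep, data = xsep, num.threads = 1)$predictions[, "case"]
    expect_equal(phenodose:::auc_score(y, scores), 1.0)
  })
})

test_that("cross-validation discriminates planted signal and is reproducible", {
  ev <- strong_eval(1)
  expect_gt(ev$cv$auc_roc, 0.85)
  expect_equal(nrow(ev$cv$folds), 10)
  # harmonic-mean F contract
  expect_equal(ev$cv$f_measure,
               2 * ev$cv$precision * ev$cv$recall /
                 (ev$cv$precision + ev$cv$recall))
  # reproducibility: identical folds and metrics under the same seed
  cv2 <- cross_validate_10fold(ev$intervals, ev$features, ev$sim$ontologies,
                               seed = 1, subject = "drugA")
  expect_equal(cv2$folds, ev$cv$folds)
})

test_that("per-fold profiles never see their own test intervals", {
  ev <- strong_eval(1)
  for (fold in ev$cv$instrumentation) {
    expect_length(intersect(fold$test_ids, fold$profile_interval_ids), 0)
    expect_setequal(fold$profile_interval_ids, fold$train_ids)
  }
})

test_that("label permutation drives cross-validated AUC to chance", {
  ev <- strong_eval(1)
  iv <- ev$intervals
  iv$label <- withr::with_seed(8, sample(iv$label))
  cvp <- cross_validate_10fold(iv, ev$features, ev$sim$ontologies, seed = 2)
  expect_gte(cvp$auc_roc, 0.4)
  expect_lte(cvp$auc_roc, 0.6)
})

test_that("temporal holdout trains strictly before the cutoff year", {
  ev <- strong_eval(1)
  ho <- ev$holdout
  expect_false(ho$skipped)
  expect_gt(ho$auc_roc, 0.8)
  instr <- ho$instrumentation[[1]]
  yr_train <- lubridate::year(ev$intervals$t1[match(instr$train_ids,
                                                    ev$intervals$interval_id)])
  yr_test <- lubridate::year(ev$intervals$t1[match(instr$test_ids,
                                                   ev$intervals$interval_id)])
  expect_true(all(yr_train < 2014))
  expect_true(all(yr_test == 2014))
  expect_setequal(instr$profile_interval_ids, instr$train_ids)
  # all intervals in the cutoff year: no training side
  iv14 <- ev$intervals |> dplyr::filter(lubridate::year(t1) == 2014)
  expect_error(holdout_last_year(iv14, ev$features, ev$sim$ontologies),
               "Empty training side")
})

test_that("evaluation objects expose tidy, glance and autoplot", {
  ev <- strong_eval(1)
  td <- tidy(ev$cv)
  expect_equal(nrow(td), 10)
  gl <- glance(ev$cv)
  expect_equal(gl$setting, "cv10")
  expect_s3_class(autoplot(ev$cv), "ggplot")
})
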