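test_that("hypergeometric tails match their exact frozen values", {
  # X >= 0 is certain
  expect_equal(hypergeom_pvalue(0, 10, 0, 10, "positive"), 1.0)
  # all case intervals carry the feature, no control does: 1 / C(20,10)
  expect_equal(hypergeom_pvalue(10, 0, 0, 10, "positive"), 1 / 184756,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail_exact(10, 0, 0, 10, "positive"), 1 / 184756)
  # balanced table: P(X >= 5 | N=20, K=10, n=10); exact enumeration oracle
  expect_equal(hypergeom_pvalue(5, 5, 5, 5, "positive"),
               hypergeom_tail_exact(5, 5, 5, 5, "positive"),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(5, 5, 5, 5, "positive"), 0.6718591,
               tolerance = 1e-6)
  # lower tail complements within the discrete distribution
  expect_equal(hypergeom_pvalue(2, 8, 8, 2, "negative"),
               hypergeom_tail_exact(2, 8, 8, 2, "negative"),
               tolerance = 1e-12)
})

test_that("risk ratio applies the Haldane-Anscombe correction on zero cells", {
  expect_equal(risk_ratio(10, 10, 5, 15), 2.0)
  expect_equal(risk_ratio(5, 5, 5, 5), 1.0)
  expect_equal(risk_ratio(0, 10, 5, 5), (0.5 / 11) / (5.5 / 11))
  expect_true(is.finite(risk_ratio(10, 0, 0, 10)))
})

test_that("information content is the negative log2 corpus frequency", {
  expect_equal(information_content(1024, 1024), 0)
  expect_equal(information_content(1, 1024), 10)
  expect_error(information_content(0, 10), "undefined")
})

test_that("contingency counts are interval-level presence counts", {
  feats <- tibble::tibble(
    interval_id = c("c1", "c2", "c3", "k1", "k2"),
    feature_type = "lab",
    feature_id = c("F", "F", "G", "F", "G"))
  counts <- contingency_counts(c("c1", "c2", "c3"), c("k1", "k2"), feats)
  f <- counts[counts$feature_id == "F", ]
  expect_equal(c(f$a, f$b, f$c, f$d), c(2, 1, 1, 1))
  expect_error(contingency_counts(character(0), c("k1"), feats), "Empty")
  expect_error(contingency_counts(c("c1", "k1"), c("k1"), feats), "disjoint")
})

test_that("elim removes general features with equal-or-higher p than a descendant", {
  ont <- as_ontology(tibble::tibble(child = "leaf", parent = "parent"))
  stats_eq <- tibble::tibble(feature_id = c("leaf", "parent"),
                             p_value = c(1e-6, 1e-6))
  expect_equal(elim_filter(stats_eq, ont)$feature_id, "leaf")
  stats_lt <- tibble::tibble(feature_id = c("leaf", "parent"),
                             p_value = c(1e-6, 1e-9))
  expect_setequal(elim_filter(stats_lt, ont)$feature_id, c("leaf", "parent"))
  # empty ontology (labs): no-op
  empty <- as_ontology(tibble::tibble(child = character(0), parent = character(0)))
  expect_equal(elim_filter(stats_eq, empty), stats_eq)
  expect_equal(elim_filter(stats_eq, NULL), stats_eq)
})

test_that("elim equals the brute-force all-pairs check on random DAGs", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      edges <- random_dag_edges(sample(5:50, 1))
      ont <- as_ontology(edges)
      nodes <- if (length(ont$nodes) > 0) ont$nodes else sprintf("n%02d", 1:5)
      stats <- tibble::tibble(feature_id = nodes,
                              p_value = round(stats::runif(length(nodes)), 3))
      expect_equal(elim_filter(stats, ont)$feature_id,
                   bf_elim(stats, edges)$feature_id)
    }
  })
})

test_that("the filter cascade is monotone and directional on planted data", {
  pl <- planted_pipeline()
  prof <- pl$profile
  counts <- prof$filtering
  totals <- rowSums(counts[, c("diagnosis", "condition", "lab")])
  expect_true(all(diff(totals) <= 0))  # survivor counts never increase
  per_type <- as.matrix(counts[, c("diagnosis", "condition", "lab")])
  expect_true(all(apply(per_type, 2, function(x) all(diff(x) <= 0))))
  # every surviving feature is outside the RR band
  expect_true(all(prof$features$rr <= 0.5 | prof$features$rr >= 2))
  # NO prefix iff negative direction
  expect_equal(grepl("^NO ", prof$features$display_label),
               prof$features$direction == "negative")
  expect_equal(prof$features$direction == "negative", prof$features$rr <= 0.5)
})

test_that("planted features dominate the profile and ordering is by |log RR|", {
  pl <- planted_pipeline()
  prof <- pl$profile
  planted <- pl$sim$truth$features$feature_id[pl$sim$truth$features$planted]
  expect_true(all(planted %in% prof$features$feature_id))
  expect_true(all(diff(abs(prof$features$log_rr)) <= 1e-12))
})

test_that("screen and band filters remove the features they should", {
  pl <- planted_pipeline()
  iv <- pl$intervals
  feats <- pl$features
  stats <- phenodose:::feature_stats_table(
    iv$interval_id[iv$label == "reduction"],
    iv$interval_id[iv$label == "continuation"], feats)
  prof_feats <- pl$profile$features
  rejected <- dplyr::anti_join(stats, prof_feats,
                               by = c("feature_type", "feature_id"))
  # no feature with p >= 0.05 or RR inside the band survived
  expect_true(all(prof_feats$p_value < 0.05))
  expect_true(all(prof_feats$p_value < 0.05 / pl$profile$bonferroni_m))
  in_band <- stats$rr > 0.5 & stats$rr < 2
  expect_true(all(stats$feature_id[in_band] %in% rejected$feature_id))
})

test_that("an all-null contrast yields a valid empty profile", {
  sim <- simulate_cohort(sim_config_null(seed = 301, n_patients = 200))
  iv <- extract_intervals(sim$prescriptions)
  feats <- build_feature_dataset(iv, sim$events, sim$ontologies)
  prof <- build_profile(iv, feats, sim$ontologies)
  expect_s3_class(prof, "phenotype_profile")
  expect_true(glance(prof)$empty || nrow(prof$features) < 3)
})

test_that("top-k keeps the k smallest p per type with deterministic ties", {
  feats <- tibble::tibble(
    feature_type = c(rep("lab", 150), rep("condition", 40)),
    feature_id = c(sprintf("L%03d", 1:150), sprintf("C%03d", 1:40)),
    p_value = c(seq(1e-10, 1e-3, length.out = 150), rep(1e-5, 40)),
    rr = c(rep(4, 150), seq(2, 8, length.out = 40)),
    log_rr = log(c(rep(4, 150), seq(2, 8, length.out = 40))),
    a = 1L, b = 1L, c = 1L, d = 1L, ic = 3, n_corpus = 10L,
    direction = "positive",
    display_label = c(sprintf("L%03d", 1:150), sprintf("C%03d", 1:40)))
  prof <- structure(list(subject = "s", outcome = "reduction",
                         features = feats, filtering = NULL,
                         bonferroni_m = 100, n_case = 10, n_control = 10,
                         interval_ids = character(0)),
                    class = "phenotype_profile")
  top <- top_k_per_type(prof, k = 100)
  expect_equal(sum(top$features$feature_type == "lab"), 100)
  expect_equal(sum(top$features$feature_type == "condition"), 40)
  # lab selection: the 100 smallest p
  expect_setequal(top$features$feature_id[top$features$feature_type == "lab"],
                  sprintf("L%03d", 1:100))
  # equal-p conditions kept; display ordered by |log rr| desc
  expect_true(all(diff(abs(top$features$log_rr)) <= 1e-12))

  # tie-break among equal p: |log rr| descending, then feature_id
  tie <- feats[feats$feature_type == "condition", ][1:5, ]
  tie$p_value <- 1e-4
  tie$log_rr <- log(c(2, 8, 8, 4, 4))
  prof2 <- prof; prof2$features <- tie
  top2 <- top_k_per_type(prof2, k = 3)
  expect_equal(top2$features$feature_id, c("C002", "C003", "C004"))
})

test_that("tidy and glance summarize profiles", {
  pl <- planted_pipeline()
  td <- tidy(pl$profile)
  expect_true(all(c("subject", "outcome", "feature_id", "p_value", "rr") %in%
                    names(td)))
  gl <- glance(pl$profile)
  expect_equal(gl$n_features, nrow(pl$profile$features))
  expect_false(gl$empty)
  p <- autoplot(pl$profile)
  expect_s3_class(p, "ggplot")
})
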