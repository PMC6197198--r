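# Shared fixtures and independent brute-force oracles. Expensive shared
# objects are computed lazily and cached for the whole run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, fn(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

ts <- function(x) as.POSIXct(x, tz = "UTC")

make_rx <- function(patient_id, ingredient, quantity, frequency, timestamp,
                    route = "oral", unit = "mg") {
  tibble::tibble(patient_id = patient_id, ingredient = ingredient,
                 dose_quantity = quantity, frequency = frequency,
                 route = route, unit = unit, timestamp = ts(timestamp))
}

make_event <- function(patient_id, feature_id, feature_type, timestamp) {
  tibble::tibble(patient_id = patient_id, feature_id = feature_id,
                 feature_type = feature_type, timestamp = ts(timestamp))
}

# --- the 14-prescription interval fixture ----------------------------------
# Covers: route mismatch (P2), unit mismatch (P3), >20-day gap (P4),
# <6h interval (P5), mixed quantity/frequency move with a daily-dose tie
# (P6), the never-changed continuation rule (P1), and a pairless singleton
# (P7). Hand-derived study labels: one reduction (P1), one continuation (P6).
interval_fixture <- function() {
  dplyr::bind_rows(
    make_rx("P1", "X", 10, 1, "2010-01-01 08:00:00"),
    make_rx("P1", "X", 5, 1, "2010-01-03 08:00:00"),   # reduction
    make_rx("P1", "X", 5, 1, "2010-01-05 08:00:00"),   # continuation, dropped (P1 changed)
    make_rx("P2", "X", 10, 1, "2010-02-01 08:00:00"),
    make_rx("P2", "X", 10, 1, "2010-02-04 08:00:00", route = "intravenous"),
    make_rx("P3", "X", 10, 1, "2010-03-01 08:00:00"),
    make_rx("P3", "X", 10, 1, "2010-03-04 08:00:00", unit = "mL"),
    make_rx("P4", "X", 10, 1, "2010-04-01 08:00:00"),
    make_rx("P4", "X", 5, 1, "2010-04-26 08:00:00"),   # 25-day gap
    make_rx("P5", "X", 10, 1, "2010-05-01 10:00:00"),
    make_rx("P5", "X", 20, 1, "2010-05-01 13:00:00"),  # 3 h, trimmed
    make_rx("P6", "X", 10, 2, "2010-06-01 08:00:00"),
    make_rx("P6", "X", 20, 1, "2010-06-03 08:00:00"),  # daily-dose tie
    make_rx("P7", "X", 10, 1, "2010-07-01 08:00:00")
  )
}

# --- brute-force graph oracles ---------------------------------------------

bf_ancestors <- function(edges, node) {
  out <- character(0)
  frontier <- node
  while (length(frontier) > 0) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, node)
}

random_dag_edges <- function(n_nodes, p_edge = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p_edge) { from <- c(from, i); to <- c(to, j) }
    }
  }
  tibble::tibble(child = nodes[from], parent = nodes[to])
}

bf_elim <- function(stats, edges) {
  anc <- lapply(stats$feature_id, function(f) bf_ancestors(edges, f))
  removed <- vapply(seq_len(nrow(stats)), function(i) {
    g <- stats$feature_id[i]
    any(vapply(seq_len(nrow(stats)), function(j) {
      g %in% anc[[j]] && stats$p_value[i] >= stats$p_value[j]
    }, logical(1)))
  }, logical(1))
  stats[!removed, , drop = FALSE]
}

# --- cached simulated corpora ----------------------------------------------

planted_pipeline <- function(seed = 101, prev_case = 0.2) {
  cached(paste0("planted_", seed, "_", prev_case), function() {
    sim <- simulate_cohort(sim_config_planted(seed = seed, prev_case = prev_case))
    iv <- extract_intervals(sim$prescriptions)
    feats <- build_feature_dataset(iv, sim$events, sim$ontologies)
    prof <- build_profile(iv, feats, sim$ontologies, subject = "drugA")
    list(sim = sim, intervals = iv, features = feats, profile = prof)
  })
}

small_pipeline <- function(seed = 11) {
  cached(paste0("small_", seed), function() {
    sim <- simulate_cohort(sim_config(n_patients = 120, seed = seed))
    iv <- extract_intervals(sim$prescriptions)
    feats <- build_feature_dataset(iv, sim$events, sim$ontologies)
    list(sim = sim, intervals = iv, features = feats)
  })
}

# cross-validation + holdout on the strong-signal corpus, cached per seed
strong_eval <- function(seed) {
  cached(paste0("strong_eval_", seed), function() {
    sim <- simulate_cohort(sim_config_planted(seed = seed, prev_case = 0.3))
    iv <- extract_intervals(sim$prescriptions)
    feats <- build_feature_dataset(iv, sim$events, sim$ontologies)
    cv <- cross_validate_10fold(iv, feats, sim$ontologies, seed = seed,
                                subject = "drugA")
    ho <- holdout_last_year(iv, feats, sim$ontologies, seed = seed,
                            subject = "drugA")
    list(sim = sim, intervals = iv, features = feats, cv = cv, holdout = ho)
  })
}
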