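test_that("prescription reader validates, sorts and round-trips", {
  rx <- dplyr::bind_rows(
    make_rx("B", "drugA", 10, 2, "2010-05-01 09:00:00"),
    make_rx("A", "drugA", 5, 1, "2010-01-02 12:30:45"),
    make_rx("A", "drugA", 20, 3, "2010-01-01 00:00:00"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(rx, path)
  back <- read_prescriptions(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$patient_id, c("A", "A", "B"))
  expect_true(all(diff(back$timestamp[back$patient_id == "A"]) > 0))
  expect_equal(attr(back, "n_rejected"), 0)
  # byte-level round trip
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_events(back, path2)
  back2 <- read_prescriptions(path2)
  expect_equal(as.data.frame(back2), as.data.frame(back))
})

test_that("malformed prescription rows are rejected and counted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,ingredient,dose_quantity,frequency,route,unit,timestamp",
               "A,drugA,10,1,oral,mg,2010-01-01T00:00:00Z",
               "A,drugA,-5,1,oral,mg,2010-01-02T00:00:00Z",
               "B,drugA,10,1,oral,mg,not-a-date"), path)
  expect_warning(rx <- read_prescriptions(path), "2 malformed")
  expect_equal(nrow(rx), 1)
  expect_equal(attr(rx, "n_rejected"), 2)
})

test_that("header-only event files load as empty tables without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,ingredient,dose_quantity,frequency,route,unit,timestamp", path)
  expect_equal(nrow(read_prescriptions(path)), 0)
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,feature_id,feature_type,timestamp", path2)
  expect_equal(nrow(read_clinical_events(path2)), 0)
})

test_that("missing mandatory columns are a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,ingredient", "A,drugA"), path)
  expect_error(read_prescriptions(path), "Missing mandatory column")
})

test_that("condition events honour the semantic-type allow-list when supplied", {
  ev <- dplyr::bind_rows(
    make_event("A", "C1", "condition", "2010-01-01"),
    make_event("A", "C2", "condition", "2010-01-02"),
    make_event("A", "D1", "diagnosis", "2010-01-03"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  map <- tibble::tibble(feature_id = c("C1", "C2"),
                        semantic_type = c("Disease or Syndrome", "Plant"))
  out <- read_clinical_events(path, semantic_map = map,
                              allowed_semantic_types = "Disease or Syndrome")
  expect_setequal(out$feature_id, c("C1", "D1"))  # diagnoses untouched
  # without a map nothing is filtered
  out2 <- read_clinical_events(path)
  expect_equal(nrow(out2), 3)
})

test_that("ontology ancestors follow the transitive closure", {
  ont <- as_ontology(tibble::tibble(child = c("A", "B"), parent = c("B", "C")))
  expect_setequal(ancestors(ont, "A"), c("B", "C"))
  expect_setequal(ancestors(ont, "B"), "C")
  expect_equal(ancestors(ont, "C"), character(0))  # root
  # diamond: D counted once
  dia <- as_ontology(tibble::tibble(child = c("A", "A", "B", "C"),
                                    parent = c("B", "C", "D", "D")))
  expect_setequal(ancestors(dia, "A"), c("B", "C", "D"))
})

test_that("cycles are fatal and name a member; empty graphs are valid", {
  expect_error(as_ontology(tibble::tibble(child = c("A", "B"), parent = c("B", "A"))),
               "cycle involving")
  expect_error(as_ontology(tibble::tibble(child = "A", parent = "A")),
               "cycle involving")
  empty <- as_ontology(tibble::tibble(child = character(0), parent = character(0)))
  expect_equal(length(empty$nodes), 0)
  expect_equal(ancestors(empty, "anything"), character(0))
})

test_that("ancestors matches brute-force reachability on random DAGs", {
  withr::with_seed(2024, {
    for (rep in 1:20) {
      edges <- random_dag_edges(sample(5:50, 1))
      if (nrow(edges) == 0) next
      ont <- as_ontology(edges)
      for (node in sample(ont$nodes, min(8, length(ont$nodes)))) {
        expect_setequal(ancestors(ont, node), bf_ancestors(edges, node))
      }
    }
  })
})

test_that("ontology CSV and OBO readers agree on is-a edges", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child,parent", "A,B", "B,C"), csv)
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: A", "is_a: B ! b term",
               "", "[Term]", "id: B", "is_a: C", "", "[Typedef]", "id: part_of"),
             obo)
  o1 <- read_ontology(csv)
  o2 <- read_ontology(obo)
  expect_setequal(ancestors(o1, "A"), ancestors(o2, "A"))
})

test_that("drug sets load, validate and synthesize singletons", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"2C9": ["warfarin", "losartan"]}', path)
  sets <- read_drug_sets(path)
  expect_equal(sets$n_members, 2L)
  expect_setequal(sets$members[[1]], c("warfarin", "losartan"))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"empty": []}', bad)
  expect_error(read_drug_sets(bad), "no members")

  dup <- withr::local_tempfile(fileext = ".json")
  writeLines('{"A": ["x"], "A": ["y"]}', dup)
  expect_error(read_drug_sets(dup), "Duplicate")

  single <- singleton_drug_sets(c("warfarin", "tacrolimus", "warfarin"))
  expect_equal(nrow(single), 2)
  expect_equal(single$n_members, c(1L, 1L))
})

test_that("a drug-set catalogue round-trips with its set and member counts", {
  # 25 sets over 205 distinct drugs, as a catalogue-shaped fixture
  members <- split(sprintf("drug%03d", 1:205),
                   rep(1:25, length.out = 205))
  sets <- tibble::tibble(name = sprintf("set%02d", 1:25),
                         members = unname(members),
                         n_members = lengths(members))
  path <- withr::local_tempfile(fileext = ".json")
  write_drug_sets(sets, path)
  back <- read_drug_sets(path)
  expect_equal(nrow(back), 25)
  expect_equal(sum(back$n_members), 205)
  expect_equal(back$members, sets$members)
})
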