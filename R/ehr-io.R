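# Readers/writers for the tabular event formats, is-a ontologies and drug
# sets shared by the whole pipeline. Timestamps are ISO-8601 in files and
# POSIXct (UTC, second resolution) in memory; all temporal comparisons
# downstream are strict.

RX_COLS <- c("patient_id", "ingredient", "dose_quantity", "frequency",
             "route", "unit", "timestamp")
EV_COLS <- c("patient_id", "feature_id", "feature_type", "timestamp")
FEATURE_TYPES <- c("diagnosis", "condition", "lab")

parse_timestamps <- function(x) {
  suppressWarnings(lubridate::as_datetime(x, tz = "UTC"))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing mandatory column(s) in ", what, ": ",
                 paste(missing, collapse = ", ")))
  }
}

report_rejections <- function(bad_rows, what) {
  n_bad <- length(bad_rows)
  if (n_bad > 0) {
    shown <- head(bad_rows + 1L, 5L)  # +1: header line
    warn(paste0(n_bad, " malformed ", what, " row(s) rejected (file line",
                if (n_bad > 1) "s" else "", " ",
                paste(shown, collapse = ", "),
                if (n_bad > 5) ", ..." else "", ")"))
  }
  n_bad
}

#' Read prescription events
#'
#' Reads a prescriptions CSV with columns `patient_id, ingredient,
#' dose_quantity, frequency, route, unit, timestamp`. Rows with a
#' non-positive dose quantity or frequency, or an unparseable timestamp, are
#' rejected with a warning carrying their file line numbers; the rejection
#' count is attached as attribute `n_rejected`. Events are returned sorted by
#' patient, ingredient and time.
#'
#' @param path path to a CSV file (UTF-8, header row).
#' @return A tibble of validated prescription events.
#' @examples
#' rx <- read_prescriptions(system.file("extdata", "example_prescriptions.csv",
#'                                      package = "phenodose"))
#' extract_intervals(rx, pd_config())
#' @export
read_prescriptions <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, RX_COLS, "prescriptions")
  out <- raw |>
    mutate(dose_quantity = suppressWarnings(as.numeric(.data$dose_quantity)),
           frequency = suppressWarnings(as.numeric(.data$frequency)),
           timestamp = parse_timestamps(.data$timestamp))
  bad <- which(is.na(out$patient_id) | is.na(out$ingredient) |
                 !is.finite(out$dose_quantity) | out$dose_quantity <= 0 |
                 !is.finite(out$frequency) | out$frequency <= 0 |
                 is.na(out$timestamp))
  n_bad <- report_rejections(bad, "prescription")
  out <- out[setdiff(seq_len(nrow(out)), bad), RX_COLS] |>
    arrange(.data$patient_id, .data$ingredient, .data$timestamp)
  attr(out, "n_rejected") <- n_bad
  out
}

#' Read clinical events (diagnoses, condition mentions, lab orders)
#'
#' Reads an event CSV with columns `patient_id, feature_id, feature_type,
#' timestamp` where `feature_type` is one of `diagnosis`, `condition`,
#' `lab`. An optional semantic-type allow-list can be applied to condition
#' events at load time: when both `semantic_map` (a `feature_id,
#' semantic_type` table or CSV path) and `allowed_semantic_types` are given,
#' condition rows whose concept is absent from the map or outside the
#' allow-list are dropped. Other feature types are never filtered.
#'
#' @param path path to a CSV file.
#' @param feature_type optional single type; rows of other types are an error.
#' @param semantic_map optional concept-to-semantic-type map (tibble or path).
#' @param allowed_semantic_types optional character vector of admissible
#'   semantic types for condition concepts.
#' @return A tibble of validated events sorted by patient and time, with a
#'   `n_rejected` attribute.
#' @export
read_clinical_events <- function(path, feature_type = NULL,
                                 semantic_map = NULL,
                                 allowed_semantic_types = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, EV_COLS, "clinical events")
  out <- raw |> mutate(timestamp = parse_timestamps(.data$timestamp))
  bad <- which(is.na(out$patient_id) | is.na(out$feature_id) |
                 !(out$feature_type %in% FEATURE_TYPES) |
                 is.na(out$timestamp))
  n_bad <- report_rejections(bad, "clinical event")
  out <- out[setdiff(seq_len(nrow(out)), bad), EV_COLS]
  if (!is.null(feature_type)) {
    feature_type <- match.arg(feature_type, FEATURE_TYPES)
    if (any(out$feature_type != feature_type)) {
      abort(paste0("Event stream mixes feature types; expected only '",
                   feature_type, "'"))
    }
  }
  if (!is.null(semantic_map) && !is.null(allowed_semantic_types)) {
    if (is.character(semantic_map) && length(semantic_map) == 1) {
      semantic_map <- readr::read_csv(
        semantic_map, col_types = readr::cols(.default = readr::col_character()))
    }
    require_columns(semantic_map, c("feature_id", "semantic_type"), "semantic map")
    ok_ids <- semantic_map$feature_id[semantic_map$semantic_type %in%
                                        allowed_semantic_types]
    out <- out |>
      filter(.data$feature_type != "condition" | .data$feature_id %in% ok_ids)
  }
  out <- out |> arrange(.data$patient_id, .data$timestamp, .data$feature_id)
  attr(out, "n_rejected") <- n_bad
  out
}

#' Write prescription or clinical-event tables
#'
#' Inverse of the readers: timestamps are serialized as ISO-8601 at second
#' resolution so `read(write(x))` round-trips exactly.
#'
#' @param x a prescriptions or events tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  out <- x |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ontologies

#' Build an ontology from a child-parent edge list
#'
#' An ontology is a directed acyclic graph of is-a edges (child -> parent)
#' over a feature vocabulary. The transitive ancestor closure of every node
#' is precomputed; cycles (including self-loops) are a fatal error naming one
#' member of the cycle. An empty edge set is valid and models vocabularies
#' without a hierarchy (laboratory order codes).
#'
#' @param edges a two-column data frame `child, parent` (zero rows allowed).
#' @return An object of class `pd_ontology`.
#' @export
as_ontology <- function(edges) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    require_columns(edges, c("child", "parent"), "ontology edge list")
    edges <- edges |>
      mutate(child = as.character(.data$child), parent = as.character(.data$parent)) |>
      select("child", "parent") |>
      distinct()
    loops <- edges$child == edges$parent
    if (any(loops)) {
      abort(paste0("Ontology contains a cycle involving '", edges$child[which(loops)[1]], "'"))
    }
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    comp <- igraph::components(g, mode = "strong")
    if (any(comp$csize > 1)) {
      member <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]][1]
      abort(paste0("Ontology contains a cycle involving '", member, "'"))
    }
    nodes <- igraph::V(g)$name
    anc <- lapply(seq_along(nodes), function(i) {
      reach <- igraph::subcomponent(g, i, mode = "out")$name
      setdiff(reach, nodes[i])
    })
    names(anc) <- nodes
    closure <- tibble(
      child = rep(nodes, lengths(anc)),
      ancestor = unlist(anc, use.names = FALSE)
    )
  } else {
    edges <- tibble(child = character(0), parent = character(0))
    nodes <- character(0)
    anc <- list()
    closure <- tibble(child = character(0), ancestor = character(0))
  }
  structure(list(edges = edges, nodes = nodes,
                 ancestors = anc, closure = closure),
            class = "pd_ontology")
}

#' Read an ontology from a CSV edge list or an OBO file
#'
#' CSV files must have columns `child, parent`; OBO files are parsed for
#' `[Term]` stanzas and their `is_a` edges only.
#'
#' @param path file path; format is inferred from the `.obo` extension unless
#'   given explicitly.
#' @param format `"csv"` or `"obo"`.
#' @return A `pd_ontology`.
#' @export
read_ontology <- function(path, format = c("auto", "csv", "obo")) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "csv"
  }
  if (format == "csv") {
    edges <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    if (nrow(edges) > 0) require_columns(edges, c("child", "parent"), "ontology edge list")
    return(as_ontology(edges))
  }
  lines <- readLines(path, warn = FALSE)
  cur <- NA_character_
  children <- character(0); parents <- character(0)
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    if (grepl("^is_a:", ln) && !is.na(cur)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      children <- c(children, cur); parents <- c(parents, tgt)
    }
  }
  as_ontology(tibble(child = children, parent = parents))
}

#' Strict ancestors of a feature in an ontology
#'
#' Returns every node reachable from `feature_id` along is-a edges, excluding
#' the node itself. A feature absent from the ontology is a valid isolated
#' leaf with no ancestors; the first time each unknown code is queried it is
#' reported once.
#'
#' @param ontology a `pd_ontology`.
#' @param feature_id a single feature identifier.
#' @return Character vector of ancestor identifiers (possibly empty).
#' @export
ancestors <- function(ontology, feature_id) {
  stopifnot(inherits(ontology, "pd_ontology"), length(feature_id) == 1)
  res <- ontology$ancestors[[feature_id]]
  if (is.null(res)) {
    if (!(feature_id %in% the$warned_ids)) {
      the$warned_ids <- c(the$warned_ids, feature_id)
      inform(paste0("Feature '", feature_id,
                    "' not in ontology; treated as isolated leaf"))
    }
    return(character(0))
  }
  res
}

#' @export
print.pd_ontology <- function(x, ...) {
  cat("<pd_ontology> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " is-a edges\n", sep = "")
  invisible(x)
}

#' Write an ontology edge list to CSV
#' @param ontology a `pd_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  readr::write_csv(ontology$edges, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Drug sets

#' Read drug sets from JSON
#'
#' The file is a JSON object mapping each set name to an array of ingredient
#' identifiers. Duplicate set names and empty member lists are fatal.
#'
#' @param path path to a JSON file.
#' @return A tibble with columns `name`, `members` (list-column) and
#'   `n_members`.
#' @examples
#' read_drug_sets(system.file("extdata", "example_drug_sets.json",
#'                            package = "phenodose"))
#' @export
read_drug_sets <- function(path) {
  stopifnot(file.exists(path))
  sets <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(sets) == 0) abort("Drug-set file defines no sets")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) abort("Drug sets must be named")
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate drug-set name: '", nm[duplicated(nm)][1], "'"))
  }
  members <- lapply(sets, function(m) as.character(unlist(m)))
  empty <- lengths(members) == 0
  if (any(empty)) {
    abort(paste0("Drug set '", nm[empty][1], "' has no members"))
  }
  tibble(name = nm, members = unname(members), n_members = lengths(members))
}

#' Singleton drug sets for individually analyzed drugs
#'
#' Each analyzed ingredient also gets a set of its own, so single drugs and
#' drug classes flow through the same profile/classification machinery.
#'
#' @param ingredients character vector of ingredient identifiers.
#' @return A drug-set tibble like [read_drug_sets()]'s.
#' @export
singleton_drug_sets <- function(ingredients) {
  ingredients <- unique(as.character(ingredients))
  tibble(name = ingredients,
         members = as.list(ingredients),
         n_members = 1L)
}

#' Write drug sets to JSON
#' @param drug_sets a drug-set tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_sets <- function(drug_sets, path) {
  obj <- setNames(drug_sets$members, drug_sets$name)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
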