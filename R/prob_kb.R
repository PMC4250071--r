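# Probabilistic database assembly: thresholded entity tuples, best-age and
# formal-unit rules, occurrence export.

#' Entity-level tuples with marginal probabilities
#'
#' Joins the entity-layer variables of a factor graph with their inferred
#' marginals into a machine-output knowledge base: one row per distinct
#' (relation, subject, object) with its probability, the most recent source
#' document and publication year among its mentions, the number of
#' supporting mentions, and the most frequent species epithet (for taxon
#' subjects mentioned binomially).
#'
#' @param graph a `factor_graph` with the entity layer built.
#' @param marginals a `marginal_table` from [gibbs_marginals()] or
#'   [exact_marginals()].
#' @return tibble of scored entity tuples.
#' @export
entity_tuples <- function(graph, marginals) {
  ev <- graph$variables[graph$variables$layer == "entity_relation", ]
  p <- marginals$probability[match(ev$id, marginals$id)]
  mention_counts <- table(paste(
    graph$variables$relation, graph$variables$subject,
    graph$variables$object, sep = "\r")[graph$variables$layer == "mention_relation"])
  key <- paste(ev$relation, ev$subject, ev$object, sep = "\r")
  tibble(
    relation = ev$relation, subject = ev$subject, object = ev$object,
    species = ev$species, doc_id = ev$doc_id, pub_year = ev$pub_year,
    n_mentions = as.integer(mention_counts[key]), probability = p)
}

#' Keep tuples at or above a probability threshold
#'
#' The acceptance rule for the probabilistic database: only tuples whose
#' estimated probability reaches `tau` (0.95 by default elsewhere in the
#' pipeline) enter downstream products. Output size is non-increasing in
#' `tau`.
#'
#' @param tuples tibble with a `probability` column.
#' @param tau threshold in `[0, 1]`.
#' @export
filter_by_probability <- function(tuples, tau) {
  assert_prob(tau)
  tuples[!is.na(tuples$probability) & tuples$probability >= tau, ]
}

#' Best age for a geological unit
#'
#' Given the accepted `formation_age` tuples of one formation, returns the
#' most precise age: the interval with the shortest duration; ties broken by
#' the most recent publication year, then by higher probability, then by
#' lexicographic name. Mirrors inferring across all documents the most
#' precise and recently published age for a unit.
#'
#' @param tuples accepted `formation_age` tuples for a single formation
#'   (must be non-empty).
#' @param table an `interval_table`.
#' @return a single interval name (always one of the input objects).
#' @export
infer_unit_age <- function(tuples, table) {
  if (nrow(tuples) == 0) abort("infer_unit_age needs at least one accepted tuple")
  i <- interval_row(table, tuples$object)
  dur <- table$intervals$t_old[i] - table$intervals$t_young[i]
  year <- if ("pub_year" %in% names(tuples)) tuples$pub_year else NA_integer_
  prob <- if ("probability" %in% names(tuples)) tuples$probability else NA_real_
  ord <- order(dur, -ifelse(is.na(year), -Inf, year),
               -ifelse(is.na(prob), -Inf, prob), tuples$object)
  tuples$object[ord[1]]
}

#' Assemble occurrence records from accepted tuples
#'
#' For each accepted `taxon_in_formation` tuple whose formation has at least
#' one accepted age, emits one occurrence carrying the formation's best age
#' ([infer_unit_age()]) and its best accepted location (highest probability,
#' then most recent year, then lexicographic). Taxa tied to no dated, formally
#' named unit yield nothing — occurrences are only recognised where a well
#' defined geologic unit exists.
#'
#' @param tuples accepted (thresholded) entity tuples.
#' @param table an `interval_table`.
#' @return occurrence tibble: genus, species, formation, interval, location,
#'   doc_id, probability.
#' @export
assemble_occurrences <- function(tuples, table) {
  ages <- tuples[tuples$relation == "formation_age", ]
  locs <- tuples[tuples$relation == "formation_location", ]
  taxa <- tuples[tuples$relation == "taxon_in_formation", ]
  empty <- tibble(genus = character(), species = character(),
                  formation = character(), interval = character(),
                  location = character(), doc_id = character(),
                  probability = numeric())
  if (nrow(taxa) == 0 || nrow(ages) == 0) return(empty)

  unit_age <- vapply(split(ages, ages$subject), infer_unit_age,
                     character(1), table = table)
  best_loc <- vapply(split(locs, locs$subject), function(g) {
    g$object[order(-g$probability, -g$pub_year, g$object)][1]
  }, character(1))

  out <- tibble(
    genus = taxa$subject,
    species = if ("species" %in% names(taxa)) taxa$species else NA_character_,
    formation = taxa$object,
    interval = unname(unit_age[taxa$object]),
    location = unname(best_loc[taxa$object]),
    doc_id = if ("doc_id" %in% names(taxa)) taxa$doc_id else NA_character_,
    probability = taxa$probability)
  out[!is.na(out$interval), ]
}

#' Filter occurrences by temporal resolution
#'
#' Keeps occurrences whose interval rank is `min_rank` or finer (epoch or
#' finer by default, the threshold used for the turnover analyses); coarser
#' records — e.g. period-level ages under an epoch threshold — are dropped.
#'
#' @param occurrences occurrence tibble with an `interval` column.
#' @param table an `interval_table`.
#' @param min_rank coarsest admissible rank.
#' @export
resolution_filter <- function(occurrences, table,
                              min_rank = c("epoch", "stage", "period", "era", "eon")) {
  min_rank <- match.arg(min_rank)
  if (nrow(occurrences) == 0) return(occurrences)
  rk <- interval_rank(table, occurrences$interval)
  occurrences[rank_index(rk) >= rank_index(min_rank), ]
}

OCC_COLS <- c("genus", "species", "formation", "interval", "location",
              "doc_id", "probability")

#' Read / write occurrence CSV files
#'
#' Writes the documented occurrence schema (`genus`, `species`, `formation`,
#' `interval`, `location`, `doc_id`, `probability`), with probabilities
#' printed to 10 decimal places. `column_mapping` lets `read_occurrences()`
#' ingest externally produced occurrence tables whose columns are named
#' differently: a named character vector mapping our column names to
#' theirs.
#'
#' @param occurrences occurrence tibble.
#' @param path CSV path.
#' @param column_mapping named character vector, e.g.
#'   `c(genus = "taxon_name", interval = "stage")`.
#' @export
export_occurrences <- function(occurrences, path) {
  out <- occurrences[intersect(OCC_COLS, names(occurrences))]
  for (m in setdiff(OCC_COLS, names(out))) out[[m]] <- NA
  out <- out[OCC_COLS]
  out$probability <- sprintf("%.10f", out$probability)
  out$probability[out$probability == "NA"] <- ""
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname export_occurrences
#' @export
read_occurrences <- function(path, column_mapping = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(column_mapping)) {
    for (ours in names(column_mapping)) {
      theirs <- column_mapping[[ours]]
      if (!theirs %in% names(raw)) {
        abort(sprintf("column %s (mapped to %s) not found in %s", theirs, ours, path))
      }
      raw[[ours]] <- raw[[theirs]]
    }
  }
  missing_cols <- setdiff(OCC_COLS, names(raw))
  for (m in missing_cols) raw[[m]] <- NA_character_
  out <- raw[OCC_COLS]
  out$probability <- as.numeric(out$probability)
  as_tibble(out)
}

#' Export taxonomic-opinion tuples
#'
#' Writes accepted `opinion_belongs` / `opinion_synonym` tuples in the KB
#' CSV dialect.
#'
#' @param tuples scored entity tuples.
#' @param path CSV path.
#' @export
export_opinions <- function(tuples, path) {
  write_kb(tuples[tuples$relation %in% c("opinion_belongs", "opinion_synonym"), ],
           path)
}
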