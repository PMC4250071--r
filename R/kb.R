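#' Knowledge-base tuples
#'
#' A knowledge base is a tibble of subject-relation-object assertions with
#' optional document provenance (`doc_id`, `pub_year`) and, for machine
#' output only, a `probability`. Recognised relations: `formation_age`,
#' `formation_location`, `taxon_in_formation`, `opinion_belongs`,
#' `opinion_synonym`.
#'
#' @param relation,subject,object character vectors (recycled).
#' @param doc_id,pub_year,probability optional provenance / score columns.
#' @return a `kb` tibble.
#' @export
kb_tuple <- function(relation, subject, object, doc_id = NA_character_,
                     pub_year = NA_integer_, probability = NA_real_) {
  assert_relation(relation)
  out <- tibble(
    relation = as.character(relation), subject = as.character(subject),
    object = as.character(object), doc_id = as.character(doc_id),
    pub_year = as.integer(pub_year), probability = as.numeric(probability)
  )
  class(out) <- c("kb", class(out))
  out
}

kb_empty <- function() {
  kb_tuple(character(), character(), character(), character(), integer(), numeric())
}

KB_COLS <- c("relation", "subject", "object", "doc_id", "pub_year", "probability")

#' Read / write knowledge-base CSV files
#'
#' CSV dialect: comma-separated UTF-8 with the header
#' `relation,subject,object,doc_id,pub_year,probability`; empty fields mean
#' missing. `write_kb()` then `read_kb()` reproduces the tuples exactly.
#' Malformed rows and unknown relation names are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return `read_kb()` returns a `kb` tibble.
#' @export
read_kb <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    relation = readr::col_character(), subject = readr::col_character(),
    object = readr::col_character(), doc_id = readr::col_character(),
    pub_year = readr::col_integer(), probability = readr::col_double()
  ), progress = FALSE)
  if (!all(KB_COLS %in% names(raw))) {
    abort(sprintf("KB file %s must have columns %s", path,
                  paste(KB_COLS, collapse = ",")))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed KB rows in %s at line(s): %s", path,
                  paste(unique(prob$row), collapse = ", ")))
  }
  bad <- which(!raw$relation %in% RELATIONS)
  if (length(bad) > 0) {
    abort(sprintf("unknown relation name(s) in %s at row(s) %s: %s", path,
                  paste(bad, collapse = ", "),
                  paste(unique(raw$relation[bad]), collapse = ", ")))
  }
  kb_tuple(raw$relation, raw$subject, raw$object, raw$doc_id,
           raw$pub_year, raw$probability)
}

#' @param tuples a `kb` tibble (any data frame with the KB columns).
#' @rdname read_kb
#' @export
write_kb <- function(tuples, path) {
  missing_cols <- setdiff(KB_COLS, names(tuples))
  for (m in missing_cols) tuples[[m]] <- NA
  readr::write_csv(tuples[KB_COLS], path, na = "", progress = FALSE)
  invisible(path)
}

# set-style membership key, ignoring provenance
kb_key <- function(x) paste(x$relation, x$subject, x$object, sep = "\r")
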