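# Line-delimited JSON serialisation of a gold world: one record per line,
# typed by a "record" field (config, document, kb, annotation, vocab).

#' Write / read a corpus file
#'
#' Serialises a `gold_world` to a line-delimited JSON file: a config record,
#' then one record per document, then the gold KB, annotations and
#' vocabulary. `read_corpus()` inverts it losslessly.
#'
#' @param world a `gold_world`.
#' @param path file path (conventionally `corpus.jsonl`).
#' @export
write_corpus <- function(world, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  emit <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA), con)
  }
  emit(c(list(record = "config"), unclass(world$config)))
  for (doc in world$documents) {
    emit(list(record = "document", doc_id = doc$doc_id,
              pub_year = doc$pub_year,
              sentences = lapply(doc$sentences, as.list),
              cells = lapply(doc$cells, function(cl) {
                list(row = cl$row, col = cl$col, tokens = as.list(cl$tokens))
              })))
  }
  emit(list(record = "kb", rows = world$gold_kb))
  emit(list(record = "annotations", rows = world$annotations))
  emit(list(record = "vocab", rows = world$vocab))
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  config <- NULL; documents <- list(); gold_kb <- NULL
  annotations <- NULL; vocab <- NULL
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("malformed corpus line %d: %s", i,
                                    conditionMessage(e)))
                    })
    switch(rec$record %||% abort(sprintf("corpus line %d lacks a record type", i)),
      config = {
        rec$record <- NULL
        config <- do.call(world_config, rec)
      },
      document = {
        documents[[length(documents) + 1L]] <- list(
          doc_id = rec$doc_id, pub_year = as.integer(rec$pub_year),
          sentences = lapply(rec$sentences, function(s) unlist(s, use.names = FALSE)),
          cells = lapply(rec$cells, function(cl) {
            list(row = as.integer(cl$row), col = as.integer(cl$col),
                 tokens = unlist(cl$tokens, use.names = FALSE))
          }))
      },
      kb = gold_kb <- json_rows(rec$rows, list(
        relation = "c", subject = "c", object = "c", doc_id = "c",
        pub_year = "i", probability = "d")),
      annotations = annotations <- json_rows(rec$rows, list(
        doc_id = "c", scope = "c", sentence = "i", row = "i", col = "i",
        start = "i", end = "i", entity_type = "c", entity_id = "c")),
      vocab = vocab <- json_rows(rec$rows, list(entity_type = "c", name = "c")),
      abort(sprintf("unknown record type on corpus line %d: %s", i, rec$record)))
  }
  gold_kb <- kb_tuple(gold_kb$relation, gold_kb$subject, gold_kb$object,
                      gold_kb$doc_id, gold_kb$pub_year, gold_kb$probability)
  structure(list(config = config, gold_kb = gold_kb, documents = documents,
                 annotations = annotations, vocab = vocab),
            class = "gold_world")
}

# rebuild a typed tibble from a list of JSON row objects
json_rows <- function(rows, schema) {
  cols <- lapply(names(schema), function(nm) {
    v <- lapply(rows, function(r) r[[nm]])
    v <- lapply(v, function(x) if (is.null(x)) NA else x)
    v <- unlist(v, use.names = FALSE)
    if (length(v) == 0) v <- logical(0)
    switch(schema[[nm]], c = as.character(v), i = as.integer(v),
           d = as.numeric(v))
  })
  names(cols) <- names(schema)
  as_tibble(cols)
}
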