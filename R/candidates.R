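# Relation-candidate generation and feature extraction.

# type signatures: which co-located mention type pairs form which relation
pair_relations <- function(type_a, type_b) {
  key <- paste(sort(c(type_a, type_b)), collapse = "+")
  switch(key,
    "formation+interval" = "formation_age",
    "formation+location" = "formation_location",
    "formation+taxon" = "taxon_in_formation",
    "taxon+taxon" = c("opinion_belongs", "opinion_synonym"),
    character(0))
}

subject_type <- c(formation_age = "formation", formation_location = "formation",
                  taxon_in_formation = "taxon", opinion_belongs = "taxon",
                  opinion_synonym = "taxon")

#' Generate relation candidates from co-located mentions
#'
#' Every type-compatible pair of mentions in the same sentence (scope
#' `"sentence"`) or the same table row (scope `"table_row"`) becomes a
#' candidate. For taxon-taxon pairs both opinion relations are candidates;
#' the leftmost taxon is the subject (child / junior slot). Ordering is
#' deterministic by (document, sentence or row, spans, relation).
#'
#' @param mentions tibble from [extract_mentions()] (one or many documents).
#' @param scope `"sentence"`, `"table_row"`, or both (default).
#' @return tibble of candidates, one row each, with span bookkeeping carried
#'   along for feature extraction.
#' @export
generate_candidates <- function(mentions, scope = c("sentence", "table_row")) {
  scope <- match.arg(scope, several.ok = TRUE)
  out <- list()
  add_pairs <- function(grp, in_table) {
    n <- nrow(grp)
    if (n < 2) return()
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a <- grp[i, ]; b <- grp[j, ]
        if (in_table && a$col == b$col) next
        rels <- pair_relations(a$entity_type, b$entity_type)
        if (a$entity_type == "taxon" && b$entity_type == "taxon") {
          # rank is readable from nomenclature: family-group names end in
          # -idae. A genus-family pair can only be a placement (genus as
          # subject); synonymy requires names of the same rank.
          fam_a <- grepl("idae$", a$entity_id)
          fam_b <- grepl("idae$", b$entity_id)
          if (xor(fam_a, fam_b)) rels <- "opinion_belongs"
          if (fam_a && fam_b) rels <- character(0)
        }
        for (rel in rels) {
          # subject slot: the mention whose type matches; same-type pairs
          # keep document order (leftmost = subject) unless rank decides
          if (a$entity_type == b$entity_type) {
            if (rel == "opinion_belongs" && grepl("idae$", a$entity_id) &&
                !grepl("idae$", b$entity_id)) {
              s <- b; o <- a
            } else {
              s <- a; o <- b
            }
          } else if (a$entity_type == subject_type[[rel]]) {
            s <- a; o <- b
          } else {
            s <- b; o <- a
          }
          out[[length(out) + 1L]] <<- tibble(
            doc_id = a$doc_id, scope = if (in_table) "table_row" else "sentence",
            sentence = a$sentence, row = a$row,
            relation = rel, subject = s$entity_id, object = o$entity_id,
            species = s$species,
            s_start = s$start, s_end = s$end, s_col = s$col,
            o_start = o$start, o_end = o$end, o_col = o$col)
        }
      }
    }
  }
  if ("sentence" %in% scope) {
    sent <- mentions[mentions$scope == "sentence", ]
    if (nrow(sent) > 0) {
      sent <- dplyr::arrange(sent, .data$doc_id, .data$sentence, .data$start)
      for (grp in split(sent, paste(sent$doc_id, sent$sentence))) add_pairs(grp, FALSE)
    }
  }
  if ("table_row" %in% scope) {
    cells <- mentions[mentions$scope == "cell", ]
    if (nrow(cells) > 0) {
      cells <- dplyr::arrange(cells, .data$doc_id, .data$row, .data$col, .data$start)
      for (grp in split(cells, paste(cells$doc_id, cells$row))) add_pairs(grp, TRUE)
    }
  }
  if (length(out) == 0) {
    return(tibble(doc_id = character(), scope = character(), sentence = integer(),
                  row = integer(), relation = character(), subject = character(),
                  object = character(), species = character(),
                  s_start = integer(), s_end = integer(), s_col = integer(),
                  o_start = integer(), o_end = integer(), o_col = integer()))
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$doc_id, .data$scope, .data$sentence,
                        .data$row, .data$s_start, .data$o_start, .data$relation)
  res$candidate_id <- seq_len(nrow(res))
  res
}

dist_bucket <- function(gap) {
  if (gap <= 0) "0" else if (gap == 1) "1" else if (gap == 2) "2"
  else if (gap <= 4) "3-4" else "5+"
}

#' Extract features for relation candidates
#'
#' Deterministic string-valued features per candidate, prefixed by the
#' relation so weights tie only within a relation: inter-mention tokens
#' (`BETWEEN=`), a token-distance bucket (`DIST=`), mention order (`ORDER=`),
#' and for table candidates a same-row flag plus the column-header tokens.
#' Pure: identical inputs give identical feature sets.
#'
#' @param candidates tibble from [generate_candidates()].
#' @param world the corpus the candidates came from (token source).
#' @return `candidates` with a `features` list-column and `pub_year`.
#' @export
extract_features <- function(candidates, world) {
  docs <- stats::setNames(world$documents,
                          vapply(world$documents, `[[`, "", "doc_id"))
  feats <- vector("list", nrow(candidates))
  years <- integer(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    doc <- docs[[cand$doc_id]]
    years[k] <- doc$pub_year
    pre <- function(f) paste0(cand$relation, "|", f)
    if (cand$scope == "sentence") {
      tokens <- doc$sentences[[cand$sentence + 1L]]
      lo <- min(cand$s_end, cand$o_end)   # end of the earlier mention
      hi <- max(cand$s_start, cand$o_start)
      gap <- hi - lo
      between <- if (gap > 0 && gap <= 10) tokens[(lo + 1L):hi] else character(0)
      fs <- c(paste0("BETWEEN=", between),
              paste0("DIST=", dist_bucket(gap)),
              paste0("ORDER=", if (cand$s_start <= cand$o_start) "subj_first" else "obj_first"))
    } else {
      headers <- vapply(doc$cells, function(cl) {
        if (cl$row == 0L) paste(cl$tokens, collapse = "_") else NA_character_
      }, character(1))
      cols <- vapply(doc$cells, function(cl) cl$col, integer(1))
      hdr <- function(col) {
        h <- headers[!is.na(headers) & cols == col]
        if (length(h) > 0) h[1] else "none"
      }
      fs <- c("SAME_TABLE_ROW",
              paste0("COLHEAD=", hdr(cand$s_col), ">", hdr(cand$o_col)))
    }
    feats[[k]] <- unique(vapply(fs, pre, character(1), USE.NAMES = FALSE))
  }
  candidates$features <- feats
  candidates$pub_year <- years
  candidates
}
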