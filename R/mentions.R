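# Gazetteer construction and entity-mention extraction.
# Token spans are 0-based and half-open everywhere: a span (start, end)
# covers tokens start .. end-1 of its sentence or cell.

#' Build per-type gazetteers
#'
#' Maps surface forms to canonical entity ids for each entity type, combining
#' the seed knowledge base with an entity vocabulary (the role played by
#' external dictionaries of taxon, formation and place names). Formation
#' entries also match with their lithology suffix replaced by "Formation" or
#' "Fm", so a KB entry for the Waldron Shale matches "Waldron Fm" in text.
#' Duplicate surface forms are retained as a single ambiguous entry listing
#' all candidate ids.
#'
#' @param seed_kb a `kb` tibble (may be empty).
#' @param vocab tibble with columns `entity_type`, `name` (may be empty).
#' @return named list of gazetteer tibbles (`surface`, `entity_id`,
#'   `n_tokens`), one per entity type, plus an `epithet` surface list.
#' @export
build_gazetteers <- function(seed_kb = kb_empty(), vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- tibble(entity_type = character(), name = character())
  }
  ent <- dplyr::bind_rows(
    vocab[vocab$entity_type %in% ENTITY_TYPES, c("entity_type", "name")],
    kb_entities(seed_kb)
  )
  ent <- dplyr::distinct(ent)

  gaz <- lapply(stats::setNames(ENTITY_TYPES, ENTITY_TYPES), function(ty) {
    nm <- ent$name[ent$entity_type == ty]
    if (length(nm) == 0) {
      return(tibble(surface = character(), entity_id = character(),
                    n_tokens = integer()))
    }
    if (ty == "formation") {
      base <- sub(sprintf(" (%s|Fm)$", paste(FORMATION_SUFFIXES, collapse = "|")),
                  "", nm)
      surf <- tibble(
        surface = c(nm, paste(base, "Formation"), paste(base, "Fm")),
        entity_id = rep(nm, 3))
    } else {
      surf <- tibble(surface = nm, entity_id = nm)
    }
    surf <- dplyr::distinct(surf)
    surf$n_tokens <- lengths(strsplit(surf$surface, " ", fixed = TRUE))
    dplyr::arrange(surf, .data$surface, .data$entity_id)
  })
  gaz$epithet <- sort(unique(vocab$name[vocab$entity_type == "epithet"]))
  gaz$stopwords <- template_stopwords()
  gaz
}

# entity type implied by each KB relation slot
kb_entities <- function(kb) {
  if (nrow(kb) == 0) {
    return(tibble(entity_type = character(), name = character()))
  }
  subj_type <- c(formation_age = "formation", formation_location = "formation",
                 taxon_in_formation = "taxon", opinion_belongs = "taxon",
                 opinion_synonym = "taxon")
  obj_type <- c(formation_age = "interval", formation_location = "location",
                taxon_in_formation = "formation", opinion_belongs = "taxon",
                opinion_synonym = "taxon")
  dplyr::bind_rows(
    tibble(entity_type = unname(subj_type[kb$relation]), name = kb$subject),
    tibble(entity_type = unname(obj_type[kb$relation]), name = kb$object))
}

# priority when two types match the same longest span
TYPE_PRIORITY <- c("formation", "interval", "taxon", "location")

scan_tokens <- function(tokens, lookup, max_len, epithets, stopwords) {
  n <- length(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      surf <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      entry <- lookup[[surf]]
      if (!is.null(entry)) {
        # longest match wins; on a type tie at the same span, fixed priority
        ty <- TYPE_PRIORITY[min(match(entry$type, TYPE_PRIORITY))]
        keep <- entry$type == ty
        ids <- sort(entry$id[keep])
        hit <- list(start = i - 1L, end = i + len - 1L, type = ty,
                    entity_id = ids[1], ambiguous = length(unique(ids)) > 1,
                    surface = surf)
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      # binomial extension: a taxon hit followed by a plausible lowercase
      # epithet absorbs it as the species name
      species <- NA_character_
      if (hit$type == "taxon" && hit$end < n) {
        nxt <- tokens[hit$end + 1L]
        if (grepl("^[a-z]+$", nxt) && !(nxt %in% stopwords) &&
            (nxt %in% epithets || nchar(nxt) >= 4)) {
          species <- paste(hit$entity_id, nxt)
          hit$surface <- paste(hit$surface, nxt)
          hit$end <- hit$end + 1L
        }
      }
      hit$species <- species
      out[[length(out) + 1L]] <- hit
      i <- hit$end + 1L
    }
  }
  out
}

gazetteer_lookup <- function(gazetteers) {
  env <- new.env(parent = emptyenv(), size = 4096L)
  for (ty in ENTITY_TYPES) {
    g <- gazetteers[[ty]]
    for (k in seq_len(nrow(g))) {
      cur <- get0(g$surface[k], envir = env)
      env[[g$surface[k]]] <- list(type = c(cur$type, ty),
                                  id = c(cur$id, g$entity_id[k]))
    }
  }
  env
}

#' Extract entity mentions from a document
#'
#' Scans each sentence and table cell with the gazetteers using
#' longest-match-wins, non-overlapping spans (ties broken by leftmost start,
#' then by a fixed type priority). Taxon hits are extended by the binomial
#' pattern: a capitalised genus followed by a lowercase epithet. Ambiguous
#' surfaces resolve to the lexicographically smallest id and are flagged.
#'
#' @param doc a document (element of `gold_world$documents`).
#' @param gazetteers result of [build_gazetteers()].
#' @return tibble of mentions with 0-based half-open spans.
#' @export
extract_mentions <- function(doc, gazetteers) {
  lookup <- attr(gazetteers, "lookup")
  if (is.null(lookup)) lookup <- gazetteer_lookup(gazetteers)
  max_len <- max(1L, unlist(lapply(gazetteers[ENTITY_TYPES], function(g) g$n_tokens)))
  eps <- gazetteers$epithet %||% character(0)
  sw <- gazetteers$stopwords %||% character(0)

  rows <- list()
  push <- function(hits, scope, sentence, row, col) {
    for (h in hits) {
      rows[[length(rows) + 1L]] <<- tibble(
        doc_id = doc$doc_id, scope = scope, sentence = sentence,
        row = row, col = col, start = h$start, end = h$end,
        entity_type = h$type, surface = h$surface, entity_id = h$entity_id,
        species = h$species, ambiguous = h$ambiguous)
    }
  }
  for (si in seq_along(doc$sentences)) {
    hits <- scan_tokens(doc$sentences[[si]], lookup, max_len, eps, sw)
    push(hits, "sentence", si - 1L, NA_integer_, NA_integer_)
  }
  for (cl in doc$cells) {
    hits <- scan_tokens(cl$tokens, lookup, max_len, eps, sw)
    push(hits, "cell", NA_integer_, cl$row, cl$col)
  }
  if (length(rows) == 0) {
    return(tibble(doc_id = character(), scope = character(), sentence = integer(),
                  row = integer(), col = integer(), start = integer(),
                  end = integer(), entity_type = character(), surface = character(),
                  entity_id = character(), species = character(), ambiguous = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Extract mentions for every document in a corpus
#'
#' @param world a `gold_world` (or any list with `documents`).
#' @inheritParams extract_mentions
#' @return one tibble of mentions across documents.
#' @export
extract_mentions_corpus <- function(world, gazetteers) {
  attr(gazetteers, "lookup") <- gazetteer_lookup(gazetteers)
  dplyr::bind_rows(lapply(world$documents, extract_mentions, gazetteers = gazetteers))
}
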