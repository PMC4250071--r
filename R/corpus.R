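# Synthetic corpus generator: a gold world of formations, taxa, opinions and
# occurrences, rendered as noisy token-level documents plus a seed KB split.
# This stands in for the OCR/NLP front end and the human-built database that
# a real literature-reading run would consume.

FORMATION_SUFFIXES <- c("Formation", "Shale", "Limestone", "Sandstone")

# sentence templates; {S}/{O} are the subject and object mention slots.
# Distractor templates co-locate the same entity types but assert no fact,
# so the candidates they produce must come out negative.
TEMPLATES <- list(
  formation_age = c(
    "the {S} is {O} in age",
    "the {S} is considered {O} in age",
    "fossils of the {S} indicate a {O} age",
    "the {S} was deposited during the {O}",
    "strata of the {S} are assigned to the {O}"),
  formation_age_distractor = c(
    "the {S} overlies rocks of {O} age",
    "the {S} underlies strata of {O} age",
    "the {S} rests unconformably on {O} deposits"),
  formation_location = c(
    "the {S} crops out in {O}",
    "the {S} is exposed in {O}",
    "exposures of the {S} occur in {O}",
    "the {S} of {O} is well known",
    "sections of the {S} were measured in {O}"),
  formation_location_distractor = c(
    "the {S} is not known from {O}",
    "the {S} was once thought to extend into {O}"),
  taxon_in_formation = c(
    "{S} occurs in the {O}",
    "{S} is reported from the {O}",
    "specimens of {S} were collected from the {O}",
    "the {O} yields {S}",
    "{S} is abundant in the {O}"),
  taxon_in_formation_distractor = c(
    "{S} is absent from the {O}",
    "{S} has not been recovered from the {O}",
    "{S} was compared with material from the {O}"),
  opinion_belongs = c(
    "the genus {S} belongs to the family {O}",
    "{S} is assigned to the family {O}",
    "{S} is placed in the {O}",
    "the family {O} includes {S}",
    "{S} is referred to the {O}"),
  opinion_belongs_distractor = c(
    "{S} is excluded from the {O}",
    "{S} was removed from the {O}"),
  opinion_synonym = c(
    "{S} is a junior synonym of {O}",
    "{S} is synonymized with {O}",
    "{S} is regarded as a synonym of {O}",
    "{S} is here considered a synonym of {O}",
    "the name {S} is a subjective synonym of {O}"),
  opinion_synonym_distractor = c(
    "{S} is not a synonym of {O}",
    "{S} is considered distinct from {O}")
)

# every lowercase word any template can emit; used to keep the binomial
# species-epithet pattern from swallowing ordinary words
template_stopwords <- function() {
  toks <- unlist(strsplit(unlist(TEMPLATES), " ", fixed = TRUE))
  sort(unique(toks[toks != "{S}" & toks != "{O}"]))
}

#' Configuration for the synthetic gold world
#'
#' Defaults define the package's reference study conditions: a desk-scale
#' literature with 40 formations, 120 genera and 150 documents, light OCR-style
#' token corruption, a substantial rate of distractor sentences (statements
#' that co-locate entities without asserting the relation), occasional use of
#' junior synonyms and of coarser-than-true ages, and a quarter of
#' taxon-occurrence facts expressed only as table rows.
#'
#' @param n_formations,n_taxa,n_documents world sizes.
#' @param corruption_rate per-token character corruption probability.
#' @param distractor_rate expected distractor sentences per fact sentence.
#' @param synonym_rate fraction of genera that carry a junior synonym (and
#'   probability that a repeat mention uses the junior name).
#' @param coarse_age_rate probability that a repeat rendition of a formation
#'   age states an ancestor interval (e.g. the period) instead of the true
#'   stage.
#' @param table_fraction probability that a taxon-occurrence rendition is a
#'   table row rather than a sentence.
#' @param seed_kb_fraction fraction of gold tuples in the default seed KB.
#' @param doc_redundancy expected extra documents restating each fact.
#' @param rng_seed integer seed; the whole world is a deterministic function
#'   of the configuration.
#' @return a `world_config` list.
#' @export
world_config <- function(n_formations = 40, n_taxa = 120, n_documents = 150,
                         corruption_rate = 0.02, distractor_rate = 0.3,
                         synonym_rate = 0.15, coarse_age_rate = 0.2,
                         table_fraction = 0.25, seed_kb_fraction = 1,
                         doc_redundancy = 0.6, rng_seed = 1L) {
  rates <- c(corruption_rate, distractor_rate, synonym_rate, coarse_age_rate,
             table_fraction, seed_kb_fraction)
  if (any(rates < 0) || any(rates[-2] > 1)) {
    abort("all rates must lie in [0, 1] (distractor_rate may exceed 1)")
  }
  if (n_formations < 0 || n_taxa < 0 || n_documents < 0) {
    abort("counts must be non-negative")
  }
  structure(list(
    n_formations = as.integer(n_formations), n_taxa = as.integer(n_taxa),
    n_documents = as.integer(n_documents), corruption_rate = corruption_rate,
    distractor_rate = distractor_rate, synonym_rate = synonym_rate,
    coarse_age_rate = coarse_age_rate, table_fraction = table_fraction,
    seed_kb_fraction = seed_kb_fraction, doc_redundancy = doc_redundancy,
    rng_seed = as.integer(rng_seed)
  ), class = "world_config")
}

name_pool <- function(first, second, n) {
  combos <- as.vector(outer(first, second, paste0))
  if (n > length(combos)) abort("name pool exhausted")
  sample(combos, n)
}

render_template <- function(tmpl, s_tokens, o_tokens) {
  words <- strsplit(tmpl, " ", fixed = TRUE)[[1]]
  tokens <- character(0)
  s_span <- o_span <- c(NA_integer_, NA_integer_)
  for (w in words) {
    if (w == "{S}") {
      s_span <- c(length(tokens), length(tokens) + length(s_tokens))
      tokens <- c(tokens, s_tokens)
    } else if (w == "{O}") {
      o_span <- c(length(tokens), length(tokens) + length(o_tokens))
      tokens <- c(tokens, o_tokens)
    } else {
      tokens <- c(tokens, w)
    }
  }
  list(tokens = tokens, s_span = s_span, o_span = o_span)
}

formation_surface <- function(canonical) {
  base <- sub(sprintf(" (%s|Fm)$", paste(FORMATION_SUFFIXES, collapse = "|")),
              "", canonical)
  u <- runif(1)
  suffix <- if (u < 0.5) sub("^.* ", "", canonical) else if (u < 0.8) "Formation" else "Fm"
  strsplit(paste(base, suffix), " ", fixed = TRUE)[[1]]
}

#' Generate a gold world and its noisy document renderings
#'
#' Builds formations (each with one true age at stage, epoch or period level,
#' one location, and a set of contained genera), a genus-level taxonomy with
#' family assignments and junior-synonym pairs, the gold knowledge base of
#' tuples those facts imply, and a set of token-level documents in which every
#' gold tuple is expressed at least once through sentence templates or table
#' rows. Noise: per-token character corruption, distractor sentences that must
#' not yield tuples, repeat renditions that use coarser ancestor ages or
#' junior synonyms.
#'
#' The world is a deterministic function of `(config, table)`: a single RNG
#' stream is seeded once from `config$rng_seed`.
#'
#' @param config a [world_config()].
#' @param table an [load_interval_table()] result; formation ages are drawn
#'   from intervals compatible with single analysis bins.
#' @return a `gold_world`: list with `config`, `gold_kb`, `documents`,
#'   `annotations`, `vocab`.
#' @export
generate_world <- function(config = world_config(), table = load_interval_table()) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$rng_seed, build_world(config, table))
}

build_world <- function(config, table) {
  ints <- table$intervals
  bins <- table$bins
  n_bins <- nrow(bins)

  syllA <- c("Wal", "Tsing", "Bar", "Kel", "Mor", "Dun", "Hol", "Ver", "Tam",
             "Ros", "Gal", "Pin", "Sar", "Lod", "Quin", "Bren", "Tor", "Mel",
             "Cas", "Fen", "Har", "Vel", "Nor", "Zan", "Bel", "Cor", "Dar",
             "Eld", "Far", "Gor")
  syllB <- c("don", "ton", "mont", "ville", "field", "bry", "ford", "stone",
             "wick", "ham", "dale", "ley", "mar", "vik", "by", "holm", "gate",
             "thorp", "combe", "shaw")
  gsylA <- c("Acro", "Bello", "Cteno", "Dendro", "Eury", "Gonio", "Hemi",
             "Lepto", "Macro", "Neo", "Ortho", "Pachy", "Rhab", "Stega",
             "Tricho", "Xeno", "Zygo", "Calli", "Platy", "Micro")
  gsylB <- c("ceras", "phyllum", "crinus", "spira", "pora", "graptus",
             "theca", "cystis", "discus", "lithus", "nauta", "batis",
             "mya", "rhynchus", "stoma", "pecten", "coccus", "saurus",
             "therium", "lepis")
  epithets <- c("minor", "magnus", "elegans", "robustus", "gracilis",
                "communis", "rarus", "ovalis", "latus", "brevis", "longus",
                "parvus", "tenuis", "crassus", "obscurus", "primus")

  base_pool <- name_pool(syllA, syllB, min(length(syllA) * length(syllB),
                                           config$n_formations + 40))
  formation_bases <- base_pool[seq_len(config$n_formations)]
  n_loc <- max(8, ceiling(config$n_formations / 4))
  location_names <- paste0(base_pool[config$n_formations + seq_len(n_loc)], "ia")

  n_syn <- rbinom(1, config$n_taxa, config$synonym_rate)
  n_fam <- max(3, ceiling(config$n_taxa / 5))
  taxon_pool <- name_pool(gsylA, gsylB, config$n_taxa + n_syn + n_fam)
  genus_names <- taxon_pool[seq_len(config$n_taxa)]
  junior_names <- taxon_pool[config$n_taxa + seq_len(n_syn)]
  family_names <- paste0(taxon_pool[config$n_taxa + n_syn + seq_len(n_fam)], "idae")

  # one true age per formation, resolvable to a single analysis bin at stage
  # or epoch rank; a minority get only period-level resolution
  stage_rows <- ints[ints$rank == "stage", ]
  pick_age <- function(bin_i) {
    b <- bins[bin_i, ]
    u <- runif(1)
    in_bin <- stage_rows$t_old <= b$t_old + 1e-9 &
      stage_rows$t_young >= b$t_young - 1e-9
    epoch_name <- b$name
    if (u < 0.1) {
      # period-level only: excluded later by the resolution filter
      per <- interval_ancestors(table, epoch_name)
      per[match("period", ints$rank[match(per, ints$name)])]
    } else if (u < 0.7 && any(in_bin)) {
      sample(stage_rows$name[in_bin], 1)
    } else {
      epoch_name
    }
  }

  formations <- tibble(
    name = paste(formation_bases, sample(FORMATION_SUFFIXES,
                                         config$n_formations, replace = TRUE)),
    bin = sample.int(n_bins, config$n_formations, replace = TRUE)
  )
  formations$age <- vapply(formations$bin, pick_age, character(1))
  formations$location <- sample(location_names, config$n_formations, replace = TRUE)

  # genus ranges anchored on formations so every genus has >= 1 occurrence
  genera <- tibble(name = genus_names,
                   family = sample(family_names, config$n_taxa, replace = TRUE))
  senior_for_junior <- if (n_syn > 0) sample(genus_names, n_syn) else character(0)
  occ_list <- vector("list", config$n_taxa)
  for (i in seq_len(config$n_taxa)) {
    f0 <- sample.int(nrow(formations), 1)
    extent <- rpois(1, 1.5)
    first <- max(1L, formations$bin[f0] - sample.int(extent + 1L, 1) + 1L)
    last <- min(n_bins, first + extent)
    eligible <- which(formations$bin >= first & formations$bin <= last)
    k <- min(length(eligible), 1L + rpois(1, 1))
    occ_list[[i]] <- unique(c(f0, sample(eligible, k)))
  }

  gold <- list(
    kb_tuple("formation_age", formations$name, formations$age),
    kb_tuple("formation_location", formations$name, formations$location),
    kb_tuple("taxon_in_formation",
             rep(genus_names, lengths(occ_list)),
             formations$name[unlist(occ_list)]),
    kb_tuple("opinion_belongs", genera$name, genera$family)
  )
  if (n_syn > 0) {
    gold <- c(gold, list(kb_tuple("opinion_synonym", junior_names, senior_for_junior)))
  }
  gold_kb <- dplyr::distinct(dplyr::bind_rows(gold),
                             .data$relation, .data$subject, .data$object,
                             .keep_all = TRUE)

  vocab <- dplyr::bind_rows(
    tibble(entity_type = "formation", name = formations$name),
    tibble(entity_type = "location", name = unique(formations$location)),
    tibble(entity_type = "taxon", name = c(genus_names, junior_names, family_names)),
    tibble(entity_type = "interval", name = ints$name),
    tibble(entity_type = "epithet", name = epithets)
  )

  world <- render_documents(config, table, gold_kb, formations, genera,
                            junior_names, senior_for_junior, epithets, vocab)
  world
}

render_documents <- function(config, table, gold_kb, formations, genera,
                             junior_names, senior_for_junior, epithets, vocab) {
  ints <- table$intervals
  n_docs <- config$n_documents
  doc_ids <- sprintf("doc%04d", seq_len(max(n_docs, 0)))
  pub_years <- if (n_docs > 0) sample(1900:2010, n_docs, replace = TRUE) else integer(0)

  junior_of <- stats::setNames(junior_names, senior_for_junior)
  all_intervals <- ints$name[ints$rank %in% c("period", "epoch", "stage")]
  fam_names <- unique(genera$family)

  # assign each gold tuple to >= 1 documents; the first rendition is exact
  n_fact <- nrow(gold_kb)
  assignments <- vector("list", n_docs)
  if (n_docs > 0 && n_fact > 0) {
    for (i in seq_len(n_fact)) {
      k <- 1L + rpois(1, config$doc_redundancy)
      docs <- sample.int(n_docs, min(k, n_docs))
      for (j in seq_along(docs)) {
        assignments[[docs[j]]] <- rbind(assignments[[docs[j]]],
                                        c(fact = i, exact = as.integer(j == 1L)))
      }
    }
  }

  documents <- vector("list", n_docs)
  ann <- list()
  for (d in seq_len(n_docs)) {
    sentences <- list()
    cells <- list()
    doc_ann <- list()
    n_table_rows <- 0L
    add_ann <- function(scope, sentence, row, col, span, type, id) {
      doc_ann[[length(doc_ann) + 1L]] <<- tibble(
        doc_id = doc_ids[d], scope = scope,
        sentence = sentence, row = row, col = col,
        start = span[1], end = span[2], entity_type = type, entity_id = id)
    }
    emit_sentence <- function(relation, s_tokens, o_tokens, s_type, o_type,
                              s_id, o_id, distractor = FALSE) {
      key <- if (distractor) paste0(relation, "_distractor") else relation
      tmpl <- sample(TEMPLATES[[key]], 1)
      r <- render_template(tmpl, s_tokens, o_tokens)
      sentences[[length(sentences) + 1L]] <<- r$tokens
      si <- length(sentences) - 1L  # 0-based sentence index
      add_ann("sentence", si, NA_integer_, NA_integer_, r$s_span, s_type, s_id)
      add_ann("sentence", si, NA_integer_, NA_integer_, r$o_span, o_type, o_id)
    }
    emit_table_row <- function(taxon_tokens, formation_tokens, genus, formation) {
      if (n_table_rows == 0L) {
        cells[[length(cells) + 1L]] <<- list(row = 0L, col = 0L, tokens = "taxon")
        cells[[length(cells) + 1L]] <<- list(row = 0L, col = 1L, tokens = "unit")
        n_table_rows <<- 1L
      }
      r <- n_table_rows
      cells[[length(cells) + 1L]] <<- list(row = r, col = 0L, tokens = taxon_tokens)
      cells[[length(cells) + 1L]] <<- list(row = r, col = 1L, tokens = formation_tokens)
      add_ann("cell", NA_integer_, r, 0L, c(0L, length(taxon_tokens)), "taxon", genus)
      add_ann("cell", NA_integer_, r, 1L, c(0L, length(formation_tokens)),
              "formation", formation)
      n_table_rows <<- n_table_rows + 1L
    }
    taxon_tokens_for <- function(genus, exact) {
      nm <- genus
      if (!exact && !is.na(junior_of[genus]) && runif(1) < config$synonym_rate) {
        nm <- junior_of[[genus]]
      }
      if (runif(1) < 0.3) c(nm, sample(epithets, 1)) else nm
    }

    facts <- assignments[[d]]
    n_facts_here <- if (is.null(facts)) 0L else nrow(facts)
    if (n_facts_here > 0) {
      ord <- sample.int(n_facts_here)
      for (r in ord) {
        fact <- gold_kb[facts[r, "fact"], ]
        exact <- facts[r, "exact"] == 1L
        switch(fact$relation,
          formation_age = {
            obj <- fact$object
            if (!exact && runif(1) < config$coarse_age_rate) {
              anc <- setdiff(interval_ancestors(table, obj), obj)
              anc <- anc[interval_rank(table, anc) %in% c("period", "epoch")]
              if (length(anc) > 0) obj <- sample(anc, 1)
            }
            emit_sentence("formation_age", formation_surface(fact$subject),
                          strsplit(obj, " ", fixed = TRUE)[[1]],
                          "formation", "interval", fact$subject, obj)
          },
          formation_location = {
            emit_sentence("formation_location", formation_surface(fact$subject),
                          fact$object, "formation", "location",
                          fact$subject, fact$object)
          },
          taxon_in_formation = {
            tt <- taxon_tokens_for(fact$subject, exact)
            if (runif(1) < config$table_fraction) {
              emit_table_row(tt, formation_surface(fact$object),
                             fact$subject, fact$object)
            } else {
              emit_sentence("taxon_in_formation", tt,
                            formation_surface(fact$object),
                            "taxon", "formation", fact$subject, fact$object)
            }
          },
          opinion_belongs = {
            emit_sentence("opinion_belongs", fact$subject, fact$object,
                          "taxon", "taxon", fact$subject, fact$object)
          },
          opinion_synonym = {
            emit_sentence("opinion_synonym", fact$subject, fact$object,
                          "taxon", "taxon", fact$subject, fact$object)
          })
      }
    }

    # distractor sentences: co-located entities, no asserted fact
    n_dis <- rpois(1, config$distractor_rate * max(1L, n_facts_here))
    for (k in seq_len(n_dis)) {
      rel <- sample(RELATIONS, 1)
      switch(rel,
        formation_age = {
          f <- formations[sample.int(nrow(formations), 1), ]
          related <- unique(c(interval_ancestors(table, f$age),
                              ints$name[vapply(ints$name, function(x)
                                f$age %in% interval_ancestors(table, x), logical(1))]))
          wrong <- sample(setdiff(all_intervals, related), 1)
          emit_sentence("formation_age", formation_surface(f$name),
                        strsplit(wrong, " ", fixed = TRUE)[[1]],
                        "formation", "interval", f$name, wrong,
                        distractor = TRUE)
        },
        formation_location = {
          f <- formations[sample.int(nrow(formations), 1), ]
          wrong <- setdiff(unique(formations$location), f$location)
          if (length(wrong) == 0) next
          wrong <- sample(wrong, 1)
          emit_sentence("formation_location", formation_surface(f$name),
                        wrong, "formation", "location",
                        f$name, wrong, distractor = TRUE)
        },
        taxon_in_formation = {
          g <- sample(genera$name, 1)
          held <- gold_kb$object[gold_kb$relation == "taxon_in_formation" &
                                   gold_kb$subject == g]
          wrong <- setdiff(formations$name, held)
          if (length(wrong) == 0) next
          wrong <- sample(wrong, 1)
          emit_sentence("taxon_in_formation", g, formation_surface(wrong),
                        "taxon", "formation", g, wrong, distractor = TRUE)
        },
        opinion_belongs = {
          g <- sample.int(nrow(genera), 1)
          wrong <- setdiff(fam_names, genera$family[g])
          if (length(wrong) == 0) next
          wrong <- sample(wrong, 1)
          emit_sentence("opinion_belongs", genera$name[g], wrong,
                        "taxon", "taxon", genera$name[g], wrong,
                        distractor = TRUE)
        },
        opinion_synonym = {
          pair <- sample(genera$name, 2)
          emit_sentence("opinion_synonym", pair[1], pair[2], "taxon", "taxon",
                        pair[1], pair[2], distractor = TRUE)
        })
    }

    doc <- list(doc_id = doc_ids[d], pub_year = pub_years[d],
                sentences = sentences, cells = cells)
    documents[[d]] <- corrupt_tokens(doc, config$corruption_rate)
    if (length(doc_ann) > 0) ann[[length(ann) + 1L]] <- dplyr::bind_rows(doc_ann)
  }

  annotations <- if (length(ann) > 0) dplyr::bind_rows(ann) else tibble(
    doc_id = character(), scope = character(), sentence = integer(),
    row = integer(), col = integer(), start = integer(), end = integer(),
    entity_type = character(), entity_id = character())

  structure(list(config = config, gold_kb = gold_kb, documents = documents,
                 annotations = annotations, vocab = vocab),
            class = "gold_world")
}

#' Corrupt document tokens with OCR-style noise
#'
#' Each token is independently mutated with probability `rate` by a random
#' single-character substitution or deletion. Annotation spans are unchanged
#' (the tokens under them may no longer match any gazetteer, which is the
#' intended recall-loss mechanism).
#'
#' @param doc a document (element of `gold_world$documents`).
#' @param rate per-token mutation probability in `[0, 1]`.
#' @return the mutated document.
#' @export
corrupt_tokens <- function(doc, rate) {
  assert_prob(rate)
  if (rate == 0) return(doc)
  mutate_vec <- function(tokens) {
    hit <- runif(length(tokens)) < rate
    tokens[hit] <- vapply(tokens[hit], mutate_token, character(1))
    tokens
  }
  doc$sentences <- lapply(doc$sentences, mutate_vec)
  doc$cells <- lapply(doc$cells, function(cl) {
    cl$tokens <- mutate_vec(cl$tokens)
    cl
  })
  doc
}

mutate_token <- function(token) {
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  i <- sample.int(length(chars), 1)
  if (length(chars) > 1 && runif(1) < 0.5) {
    paste(chars[-i], collapse = "")
  } else {
    repl <- sample(letters, 1)
    while (repl == chars[i]) repl <- sample(letters, 1)
    chars[i] <- repl
    paste(chars, collapse = "")
  }
}

#' Split a gold knowledge base into seed and holdout
#'
#' Uniformly samples `round(fraction * n)` tuples as the seed KB used for
#' distant supervision; the rest are the holdout.
#'
#' @param gold_kb a `kb` tibble.
#' @param fraction sampling fraction in `[0, 1]`.
#' @return list with `seed` and `holdout` `kb` tibbles (disjoint).
#' @export
split_seed_kb <- function(gold_kb, fraction) {
  assert_prob(fraction)
  n <- round(fraction * nrow(gold_kb))
  idx <- if (n > 0) sample.int(nrow(gold_kb), n) else integer(0)
  list(seed = gold_kb[idx, ], holdout = gold_kb[setdiff(seq_len(nrow(gold_kb)), idx), ])
}

#' Gold occurrences implied by a world
#'
#' The occurrence set a perfect reading of the corpus should recover: each
#' (genus, formation) gold tuple carries the formation's true age and
#' location.
#'
#' @param world a `gold_world`.
#' @return tibble with genus, formation, interval, location.
#' @export
gold_occurrences <- function(world) {
  kb <- world$gold_kb
  occ <- kb[kb$relation == "taxon_in_formation", c("subject", "object")]
  names(occ) <- c("genus", "formation")
  ages <- kb[kb$relation == "formation_age", c("subject", "object")]
  locs <- kb[kb$relation == "formation_location", c("subject", "object")]
  occ$interval <- ages$object[match(occ$formation, ages$subject)]
  occ$location <- locs$object[match(occ$formation, locs$subject)]
  as_tibble(occ)
}

#' @export
print.gold_world <- function(x, ...) {
  cat(sprintf("<gold_world: %d documents, %d gold tuples, %d entities>\n",
              length(x$documents), nrow(x$gold_kb), nrow(x$vocab)))
  invisible(x)
}
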