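test_that("gazetteers match lithology variants and flag ambiguity", {
  kb <- kb_tuple("formation_age", "Waldron Shale", "Llandovery")
  gaz <- build_gazetteers(kb, tibble::tibble(entity_type = character(),
                                             name = character()))
  expect_setequal(gaz$formation$surface,
                  c("Waldron Shale", "Waldron Formation", "Waldron Fm"))
  expect_true(all(gaz$formation$entity_id == "Waldron Shale"))

  empty <- build_gazetteers(kb_tuple(character(), character(), character()))
  expect_true(all(vapply(empty[c("taxon", "formation", "interval", "location")],
                         nrow, integer(1)) == 0))

  dup <- tibble::tibble(entity_type = "location",
                        name = c("Springfield", "Springfield"))
  g2 <- build_gazetteers(vocab = dup)
  expect_equal(nrow(g2$location), 1)
})

test_that("mention extraction finds formations, intervals and binomials", {
  kb <- kb_tuple("formation_age", "Waldron Shale", "Llandovery")
  vocab <- tibble::tibble(entity_type = c("interval", "taxon", "epithet"),
                          name = c("Silurian", "Acroceras", "minor"))
  gaz <- build_gazetteers(kb, vocab)
  doc <- list(doc_id = "d1", pub_year = 1980L,
              sentences = list(
                c("the", "Waldron", "Formation", "is", "Silurian", "in", "age"),
                c("Acroceras", "minor", "occurs", "here"),
                c("nothing", "relevant", "here")),
              cells = list())
  m <- extract_mentions(doc, gaz)
  s1 <- m[m$sentence == 0, ]
  expect_setequal(s1$entity_type, c("formation", "interval"))
  expect_equal(s1$entity_id[s1$entity_type == "formation"], "Waldron Shale")
  expect_equal(s1$start[s1$entity_type == "formation"], 1)
  expect_equal(s1$end[s1$entity_type == "formation"], 3)

  s2 <- m[m$sentence == 1, ]
  expect_equal(s2$entity_id, "Acroceras")
  expect_equal(s2$species, "Acroceras minor")
  expect_equal(s2$end - s2$start, 2)
  expect_equal(nrow(m[m$sentence == 2, ]), 0)
})

test_that("candidate-level recall is 1 on a clean corpus and drops with noise", {
  tab <- the_table()
  base <- world_config(n_formations = 10, n_taxa = 24, n_documents = 30,
                       corruption_rate = 0, distractor_rate = 0,
                       synonym_rate = 0, coarse_age_rate = 0, rng_seed = 21L)
  w <- generate_world(base, tab)
  gaz <- build_gazetteers(w$gold_kb[0, ], w$vocab)
  cands <- generate_candidates(extract_mentions_corpus(w, gaz))
  ckey <- paste(cands$relation, cands$subject, cands$object)
  gkey <- paste(w$gold_kb$relation, w$gold_kb$subject, w$gold_kb$object)
  expect_true(all(gkey %in% ckey))

  noisy <- base
  noisy$corruption_rate <- 0.3
  wn <- generate_world(noisy, tab)
  cn <- generate_candidates(extract_mentions_corpus(wn, gaz))
  nkey <- paste(cn$relation, cn$subject, cn$object)
  gkey_n <- paste(wn$gold_kb$relation, wn$gold_kb$subject, wn$gold_kb$object)
  expect_lt(mean(gkey_n %in% nkey), 1)
})

test_that("candidates respect scope and type signatures", {
  m <- tibble::tibble(
    doc_id = "d", scope = c("sentence", "sentence", "sentence"),
    sentence = c(0L, 0L, 1L), row = NA_integer_, col = NA_integer_,
    start = c(1L, 4L, 0L), end = c(2L, 5L, 1L),
    entity_type = c("formation", "interval", "interval"),
    surface = c("X Fm", "Silurian", "Devonian"),
    entity_id = c("X Formation", "Silurian", "Devonian"),
    species = NA_character_, ambiguous = FALSE)
  cands <- generate_candidates(m)
  expect_equal(nrow(cands), 1)  # cross-sentence pair must not pair up
  expect_equal(cands$relation, "formation_age")
  expect_equal(cands$subject, "X Formation")
  expect_equal(cands$object, "Silurian")

  cells <- tibble::tibble(
    doc_id = "d", scope = "cell", sentence = NA_integer_,
    row = c(1L, 1L), col = c(0L, 1L), start = 0L, end = 1L,
    entity_type = c("taxon", "formation"),
    surface = c("Aus", "Y Fm"), entity_id = c("Aus", "Y Formation"),
    species = NA_character_, ambiguous = FALSE)
  tc <- generate_candidates(cells)
  expect_equal(tc$relation, "taxon_in_formation")
  expect_equal(tc$scope, "table_row")
})

test_that("genus-family pairs are typed by nomenclatural suffix", {
  m <- tibble::tibble(
    doc_id = "d", scope = "sentence", sentence = 0L,
    row = NA_integer_, col = NA_integer_,
    start = c(4L, 1L), end = c(5L, 2L),
    entity_type = "taxon", surface = c("Aus", "Busidae"),
    entity_id = c("Aus", "Busidae"), species = NA_character_,
    ambiguous = FALSE)
  cands <- generate_candidates(m)
  expect_equal(cands$relation, "opinion_belongs")
  expect_equal(cands$subject, "Aus")   # genus is the child even when second
  expect_equal(cands$object, "Busidae")
})

test_that("feature extraction is pure and encodes context", {
  w <- small_world()
  gaz <- build_gazetteers(w$gold_kb[0, ], w$vocab)
  cands <- generate_candidates(extract_mentions_corpus(w, gaz))
  f1 <- extract_features(cands, w)
  f2 <- extract_features(cands, w)
  expect_identical(f1$features, f2$features)

  sent_feats <- unlist(f1$features[f1$scope == "sentence"])
  expect_true(any(grepl("\\|BETWEEN=", sent_feats)))
  expect_true(any(grepl("\\|DIST=", sent_feats)))
  tab_feats <- unlist(f1$features[f1$scope == "table_row"])
  expect_true(all(grepl("SAME_TABLE_ROW|COLHEAD", tab_feats)))
  # the worked sentence pattern: "<F> Formation is <I> in age" carries its
  # trigger word
  fa <- f1$features[f1$relation == "formation_age" & f1$scope == "sentence"]
  expect_true(any(vapply(fa, function(f) "formation_age|BETWEEN=is" %in% f,
                         logical(1))))
})
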