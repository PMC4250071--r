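cand_fixture <- function() {
  tibble::tibble(
    candidate_id = 1:4, doc_id = c("d1", "d2", "d3", "d1"),
    scope = "sentence", sentence = 0L, row = NA_integer_,
    relation = "formation_age",
    subject = c("Tsingyuan Formation", "Tsingyuan Formation",
                "Tsingyuan Formation", "Tsingyuan Formation"),
    object = c("Namurian", "Namurian", "Namurian", "Carboniferous"),
    species = NA_character_, pub_year = c(1950L, 1960L, 1980L, 1975L),
    features = list(c("f|a", "f|b", "f|c"), c("f|a"), c("f|b"), c("f|a")))
}

test_that("mention layer: one variable per candidate, tied unary weights", {
  g <- build_mention_layer(cand_fixture()[1, ])
  expect_equal(nrow(g$variables), 1)
  expect_equal(nrow(g$factors), 3)

  g2 <- build_mention_layer(cand_fixture())
  expect_equal(sum(g2$factors$weight_id == "f|a"), 3)  # three factors ...
  expect_equal(sum(names(g2$weights) == "f|a"), 1)     # ... one shared weight

  g0 <- build_mention_layer(cand_fixture()[0, ])
  expect_equal(nrow(g0$variables), 0)
  expect_equal(nrow(g0$factors), 0)
})

test_that("entity layer aggregates mentions of the same tuple", {
  g <- build_entity_layer(build_mention_layer(cand_fixture()))
  ev <- g$variables[g$variables$layer == "entity_relation", ]
  expect_equal(nrow(ev), 2)  # (Tsingyuan, Namurian) and (Tsingyuan, Carboniferous)
  agg <- g$factors[g$factors$kind == "aggregation", ]
  expect_equal(nrow(agg), 2)
  # the thrice-mentioned tuple gets an arity-4 factor (entity + 3 mentions)
  expect_setequal(lengths(agg$vars), c(4, 2))
  nam <- ev[ev$object == "Namurian", ]
  expect_equal(nam$pub_year, 1980L)  # provenance: most recent mention
})

test_that("hierarchy factors connect nested candidate ages only", {
  tab <- the_table()
  g <- build_factor_graph(cand_fixture(), tab)
  imp <- g$factors[g$factors$kind == "implication", ]
  expect_equal(nrow(imp), 1)  # Carboniferous contains Namurian
  ev <- g$variables[g$variables$layer == "entity_relation", ]
  coarse <- ev$id[ev$object == "Carboniferous"]
  fine <- ev$id[ev$object == "Namurian"]
  expect_equal(imp$vars[[1]], c(coarse, fine))  # coarse -> fine direction

  disjoint <- cand_fixture()
  disjoint$object[4] <- "Frasnian"
  g2 <- build_factor_graph(disjoint, tab)
  expect_equal(sum(g2$factors$kind == "implication"), 0)

  single <- cand_fixture()[1:3, ]  # one candidate age only
  g3 <- build_factor_graph(single, tab)
  expect_equal(sum(g3$factors$kind == "implication"), 0)
})

test_that("log potentials implement the three indicator forms", {
  w <- c(u = 2, r = 1.5, a = 1)
  unary <- list(kind = "unary_feature", weight_id = "u", vars = list(1L))
  expect_equal(log_potential(unary, c(`1` = 1L), w), 2)
  expect_equal(log_potential(unary, c(`1` = 0L), w), 0)

  imp <- list(kind = "implication", weight_id = "r", vars = list(c(1L, 2L)))
  expect_equal(log_potential(imp, c(`1` = 1L, `2` = 0L), w), 0)  # violated
  expect_equal(log_potential(imp, c(`1` = 1L, `2` = 1L), w), 1.5)
  expect_equal(log_potential(imp, c(`1` = 0L, `2` = 0L), w), 1.5)

  agg <- list(kind = "aggregation", weight_id = "a", vars = list(c(3L, 1L, 2L)))
  expect_equal(log_potential(agg, c(`1` = 0L, `2` = 1L, `3` = 1L), w), 1)
  expect_equal(log_potential(agg, c(`1` = 0L, `2` = 0L, `3` = 1L), w), 0)
  expect_error(log_potential(agg, c(`1` = 0L), w), "missing")
})

test_that("graph construction is deterministic and scales linearly", {
  w <- small_world()
  gaz <- build_gazetteers(w$gold_kb[0, ], w$vocab)
  cands <- extract_features(generate_candidates(extract_mentions_corpus(w, gaz)), w)
  tab <- the_table()
  g1 <- build_factor_graph(cands, tab)
  g2 <- build_factor_graph(cands, tab)
  expect_identical(g1, g2)
  # halving candidates cannot grow the graph
  gh <- build_factor_graph(cands[seq_len(nrow(cands) %/% 2), ], tab)
  expect_lt(nrow(gh$variables), nrow(g1$variables))
  expect_lt(nrow(gh$factors), nrow(g1$factors))
})
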