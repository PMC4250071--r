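tuples_fixture <- function() {
  tibble::tibble(
    relation = c("formation_age", "formation_age", "formation_location",
                 "taxon_in_formation", "taxon_in_formation"),
    subject = c("F1 Formation", "F1 Formation", "F1 Formation",
                "Aus", "Bus"),
    object = c("Namurian", "Carboniferous", "Loc1",
               "F1 Formation", "F2 Formation"),
    species = c(NA, NA, NA, "Aus minor", NA),
    doc_id = "d1", pub_year = c(1980L, 1950L, 1970L, 1990L, 1990L),
    n_mentions = 1L, probability = c(0.99, 0.97, 0.96, 0.98, 0.97))
}

test_that("probability thresholding is monotone and validates tau", {
  tu <- tuples_fixture()
  expect_equal(nrow(filter_by_probability(tu, 0)), nrow(tu))
  mix <- tibble::tibble(probability = c(0.96, 0.90))
  expect_equal(nrow(filter_by_probability(mix, 0.95)), 1)
  expect_error(filter_by_probability(tu, 1.01), "\\[0, 1\\]")

  set.seed(6)
  probs <- runif(200)
  taus <- sort(runif(10))
  sizes <- vapply(taus, function(t)
    nrow(filter_by_probability(tibble::tibble(probability = probs), t)),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("best unit age prefers precision, then recency", {
  tab <- the_table()
  tu <- tuples_fixture()[1:2, ]
  # stage (shorter) beats period even when the period is better supported
  expect_equal(infer_unit_age(tu, tab), "Namurian")
  expect_equal(infer_unit_age(tu[1, ], tab), "Namurian")

  two_stages <- tibble::tibble(
    relation = "formation_age", subject = "F", object = c("Frasnian", "Famennian"),
    pub_year = c(1950L, 1980L), probability = c(0.99, 0.96))
  # Frasnian 10.5 Myr vs Famennian 13.34 Myr: precision still wins
  expect_equal(infer_unit_age(two_stages, tab), "Frasnian")
  same_dur <- tibble::tibble(
    relation = "formation_age", subject = "F", object = c("Wordian", "Wordian"),
    pub_year = c(1950L, 1980L), probability = c(0.99, 0.96))
  expect_equal(infer_unit_age(same_dur, tab), "Wordian")
  # equal durations (Gorstian and Ludfordian both span 2.0 Myr) fall back
  # to the most recent publication despite a lower probability
  tie <- tibble::tibble(
    relation = "formation_age", subject = "F",
    object = c("Gorstian", "Ludfordian"),
    pub_year = c(1950L, 1980L), probability = c(0.99, 0.9))
  expect_equal(infer_unit_age(tie, tab), "Ludfordian")
  expect_error(infer_unit_age(tuples_fixture()[0, ], tab), "at least one")
})

test_that("occurrence assembly enforces the formal-unit rule", {
  tab <- the_table()
  occ <- assemble_occurrences(tuples_fixture(), tab)
  # Aus is tied to the dated F1; Bus is tied to the undated F2 and drops out
  expect_equal(occ$genus, "Aus")
  expect_equal(occ$interval, "Namurian")
  expect_equal(occ$location, "Loc1")
  expect_equal(occ$species, "Aus minor")

  # a taxon tuple below threshold never reaches assembly
  acc <- filter_by_probability(tuples_fixture(), 0.985)
  expect_equal(nrow(assemble_occurrences(acc, tab)), 0)
})

test_that("temporal resolution filter keeps epoch-or-finer records", {
  tab <- the_table()
  occ <- tibble::tibble(
    genus = c("A", "B", "C"), species = NA_character_,
    formation = "F", interval = c("Frasnian", "Mississippian", "Devonian"),
    location = NA_character_, doc_id = NA_character_, probability = 1)
  kept <- resolution_filter(occ, tab, "epoch")
  expect_setequal(kept$genus, c("A", "B"))  # stage + epoch stay, period drops

  set.seed(12)
  rnd <- occ[sample(1:3, 40, replace = TRUE), ]
  eo <- resolution_filter(rnd, tab, "epoch")
  po <- resolution_filter(rnd, tab, "period")
  expect_true(all(paste(eo$genus, eo$interval) %in% paste(po$genus, po$interval)))
  expect_gte(nrow(po), nrow(eo))
})

test_that("occurrence CSV round-trips and formats probabilities", {
  tab <- the_table()
  occ <- assemble_occurrences(tuples_fixture(), tab)
  occ <- dplyr::bind_rows(occ, occ[rep(1, 99), ])
  occ$probability <- round(runif(100), 8)
  path <- tempfile(fileext = ".csv")
  export_occurrences(occ, path)
  line2 <- readLines(path)[2]
  expect_match(line2, "\\d\\.\\d{10}")  # >= 4 decimal places guaranteed
  back <- read_occurrences(path)
  expect_equal(back$probability, occ$probability, tolerance = 1e-9)
  expect_equal(back$genus, occ$genus)

  export_occurrences(occ[0, ], path)
  expect_equal(nrow(read_occurrences(path)), 0)

  # column-mapped ingestion of an external occurrence table
  ext <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(taxon_name = "Aus", unit = "F1 Formation",
                                  stage = "Namurian"), ext)
  mapped <- read_occurrences(ext, column_mapping = c(
    genus = "taxon_name", formation = "unit", interval = "stage"))
  expect_equal(mapped$genus, "Aus")
  expect_equal(mapped$interval, "Namurian")
  expect_error(read_occurrences(ext, column_mapping = c(genus = "nope")),
               "not found")
})
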