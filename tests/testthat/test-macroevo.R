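test_that("taxonomy resolution follows recency, transitivity and cycles", {
  ops <- kb_tuple(
    c("opinion_belongs", "opinion_belongs", "opinion_synonym", "opinion_synonym"),
    c("Aus", "Aus", "Xus", "Yus"),
    c("F1idae", "F2idae", "Yus", "Zus"),
    pub_year = c(1990L, 2000L, 1980L, 1995L))
  tx <- resolve_taxonomy(ops)
  expect_equal(tx$parent[tx$name == "Aus"], "F2idae")  # most recent wins
  expect_equal(tx$senior[tx$name == "Xus"], "Zus")     # transitive chain
  expect_equal(tx$senior[tx$name == "Zus"], "Zus")

  cyc <- kb_tuple(c("opinion_synonym", "opinion_synonym"),
                  c("Aus", "Bus"), c("Bus", "Aus"),
                  pub_year = c(1950L, 1990L))
  tx2 <- resolve_taxonomy(cyc)
  # the most recent cycle-closing opinion is dropped: Bus -> Aus goes
  expect_equal(tx2$senior[tx2$name == "Aus"], "Bus")
  expect_equal(tx2$senior[tx2$name == "Bus"], "Bus")
  expect_equal(attr(tx2, "dropped")$subject, "Bus")

  # year ties break by majority, then lexicographically
  maj <- kb_tuple(rep("opinion_belongs", 3), "Aus", c("F1idae", "F2idae", "F2idae"),
                  pub_year = 2000L)
  expect_equal(resolve_taxonomy(maj)$parent[1], "F2idae")
})

test_that("genus ranges bin occurrences and drop multi-bin intervals", {
  tab <- the_table()
  occ <- tibble::tibble(
    genus = c("A", "A", "B", "C"),
    species = NA_character_, formation = "F",
    interval = c("Frasnian", "Wenlock", "Namurian", "Eifelian"),
    location = NA_character_, doc_id = NA_character_, probability = 1)
  r <- genus_ranges(occ, tab)
  # Namurian straddles the Mississippian/Pennsylvanian bin boundary -> dropped
  expect_false("B" %in% r$genus)
  expect_equal(attr(r, "n_dropped"), 1L)
  a <- r[r$genus == "A", ]
  wen <- which(tab$bins$name == "Wenlock")
  ldev <- which(tab$bins$name == "Late Devonian")
  expect_equal(c(a$first_bin, a$last_bin), c(wen, ldev))
  expect_equal(a$first_age, interval_midpoint(tab, "Wenlock"))
  c_ <- r[r$genus == "C", ]
  expect_equal(c_$first_bin, c_$last_bin)
})

test_that("range-through diversity counts covering genera", {
  r <- tibble::tibble(genus = c("A", "B", "C", "D"),
                      first_bin = c(1L, 2L, 2L, 1L),
                      last_bin = c(3L, 2L, 4L, 4L))
  d <- rangethrough_diversity(r, 6)
  expect_equal(d$diversity, c(2L, 4L, 3L, 2L, 0L, 0L))
  expect_equal(rangethrough_diversity(r[0, ], 6)$diversity, rep(0L, 6))
  one <- rangethrough_diversity(tibble::tibble(genus = "X", first_bin = 2L,
                                               last_bin = 5L), 6)
  expect_equal(one$diversity, c(0L, 1L, 1L, 1L, 1L, 0L))
})

test_that("per-capita rates match hand-counted boundary crossers", {
  r <- tibble::tibble(genus = c("A", "B", "C", "D"),
                      first_bin = c(1L, 2L, 2L, 1L),
                      last_bin = c(3L, 2L, 4L, 4L))
  fr <- foote_rates(r, 5)
  # bin 3: bottom crossers {A, C, D}, through-rangers {C, D}
  expect_equal(fr$q_rate[3], -log(2 / 3))
  # bin 2: top crossers {A, C, D}, through-rangers {A, D}
  expect_equal(fr$p_rate[2], -log(2 / 3))
  expect_equal(fr$diversity, rangethrough_diversity(r, 5)$diversity)
  # counts identity and singleton bookkeeping
  expect_equal(fr$N_b, fr$N_bt + fr$N_bL)
  expect_equal(fr$N_t, fr$N_bt + fr$N_Ft)
  expect_equal(fr$N_FL[2], 1L)  # B is confined to bin 2

  # a genus spanning everything has zero turnover in interior bins
  all_span <- tibble::tibble(genus = "Z", first_bin = 1L, last_bin = 5L)
  fa <- foote_rates(all_span, 5)
  expect_true(all(fa$p_rate[2:4] == 0 & fa$q_rate[2:4] == 0))

  # per-Myr normalisation divides by bin durations
  tab <- the_table()
  fr_myr <- foote_rates(r, nrow(tab$bins), per_myr = TRUE, table = tab)
  dur <- tab$bins$t_old - tab$bins$t_young
  plain <- foote_rates(r, nrow(tab$bins))
  expect_equal(fr_myr$q_rate, plain$q_rate / dur)
})

test_that("rates and diversity agree with the brute-force oracle", {
  set.seed(88)
  for (rep in 1:20) {
    n_bins <- sample(5:15, 1)
    r <- random_ranges(sample(5:60, 1), n_bins)
    expect_equal(rangethrough_diversity(r, n_bins)$diversity,
                 brute_diversity(r, n_bins))
    fr <- foote_rates(r, n_bins)
    br <- brute_rates(r, n_bins)
    expect_equal(fr$p_rate, unname(br[, "p"]))
    expect_equal(fr$q_rate, unname(br[, "q"]))
    # conservation: every genus appears exactly once as a first and a last
    expect_equal(sum(tabulate(r$first_bin, n_bins)), nrow(r))
    expect_equal(sum(tabulate(r$last_bin, n_bins)), nrow(r))
  }
})

test_that("range offsets difference bin-midpoint ages with a sign convention", {
  ra <- tibble::tibble(genus = c("A", "B"), first_bin = c(2L, 3L),
                       last_bin = c(4L, 5L),
                       first_age = c(100, 80), last_age = c(60, 40))
  rb <- tibble::tibble(genus = c("A", "C"), first_bin = 2L, last_bin = 4L,
                       first_age = 100, last_age = 50)
  off <- range_offsets(ra, rb)
  expect_equal(off$genus, "A")  # intersection only
  expect_equal(off$first_offset, 0)
  expect_equal(off$last_offset, 10)
  flipped <- range_offsets(ra, rb, sign = "b_minus_a")
  expect_equal(flipped$last_offset, -10)

  same <- range_offsets(ra, ra)
  expect_true(all(same$first_offset == 0 & same$last_offset == 0))
})

test_that("first-difference Spearman matches the rank-formula oracle", {
  s <- c(0, 1, 3, 6, 10, 15)
  expect_equal(first_difference_spearman(s, s)$rho, 1)
  expect_equal(first_difference_spearman(s, -s)$rho, -1)

  # differences (1,2,3,4,5) vs (2,1,4,3,5): rank formula 1 - 6*sum(d^2)/(n(n^2-1))
  a <- cumsum(c(0, 1, 2, 3, 4, 5))
  b <- cumsum(c(0, 2, 1, 4, 3, 5))
  d <- rank(diff(a)) - rank(diff(b))
  oracle <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  expect_equal(oracle, 0.8)
  got <- first_difference_spearman(a, b)
  expect_equal(got$rho, 0.8)
  expect_lt(got$p_value, 0.2)

  expect_error(first_difference_spearman(c(1, 2, NA), c(1, 2, 3)),
               "insufficient overlap")
})

test_that("relaxing the resolution filter never lowers diversity", {
  tab <- the_table()
  w <- small_world()
  occ <- gold_occurrences(w)
  occ$probability <- 1
  d_epoch <- rangethrough_diversity(
    genus_ranges(resolution_filter(occ, tab, "epoch"), tab), nrow(tab$bins))
  d_period <- rangethrough_diversity(
    genus_ranges(resolution_filter(occ, tab, "period"), tab), nrow(tab$bins))
  expect_true(all(d_period$diversity >= d_epoch$diversity))
})
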