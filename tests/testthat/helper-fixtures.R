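# shared fixtures, built in code

the_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- load_interval_table()
    tab
  }
})

# a small world with every noise channel active, cached across tests
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      w <<- generate_world(world_config(
        n_formations = 12, n_taxa = 30, n_documents = 40, rng_seed = 404L),
        the_table())
    }
    w
  }
})

# unary-only factor graph over an indicator design matrix: one mention
# variable per row, one unary factor per (row, active feature)
make_unary_graph <- function(X) {
  n <- nrow(X)
  cands <- tibble::tibble(
    candidate_id = seq_len(n), doc_id = "d", scope = "sentence",
    sentence = 0L, row = NA_integer_, relation = "formation_age",
    subject = paste0("s", seq_len(n)), object = "o",
    species = NA_character_, pub_year = 2000L,
    features = lapply(seq_len(n), function(i) colnames(X)[X[i, ] == 1]))
  build_mention_layer(cands)
}

# independent oracle for range statistics: per-genus membership scan
brute_diversity <- function(ranges, n_bins) {
  vapply(seq_len(n_bins), function(i) {
    sum(ranges$first_bin <= i & ranges$last_bin >= i)
  }, integer(1))
}

brute_rates <- function(ranges, n_bins) {
  t(vapply(seq_len(n_bins), function(i) {
    bt <- sum(ranges$first_bin < i & ranges$last_bin > i)
    b <- sum(ranges$first_bin < i & ranges$last_bin >= i)
    tt <- sum(ranges$first_bin <= i & ranges$last_bin > i)
    p <- if (bt > 0 && tt > 0) -log(bt / tt) else NA_real_
    q <- if (bt > 0 && b > 0) -log(bt / b) else NA_real_
    c(p = p, q = q)
  }, c(p = 0, q = 0)))
}

random_ranges <- function(n_genera, n_bins) {
  f <- sample.int(n_bins, n_genera, replace = TRUE)
  len <- rpois(n_genera, 2)
  tibble::tibble(genus = paste0("g", seq_len(n_genera)),
                 first_bin = f, last_bin = pmin(n_bins, f + len),
                 first_age = NA_real_, last_age = NA_real_,
                 n_occurrences = 1L)
}
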