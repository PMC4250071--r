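test_that("distant supervision labels by match, hierarchy and closed world", {
  tab <- the_table()
  cands <- tibble::tibble(
    candidate_id = 1:5, doc_id = "d", scope = "sentence", sentence = 0L,
    row = NA_integer_,
    relation = c("formation_age", "formation_age", "formation_age",
                 "opinion_synonym", "opinion_belongs"),
    subject = c("Tsingyuan Formation", "Tsingyuan Formation", "Mystery Formation",
                "Aus", "Aus"),
    object = c("Namurian", "Frasnian", "Silurian", "Bus", "Busidae"),
    species = NA_character_, pub_year = 2000L,
    features = replicate(5, "f|x", simplify = FALSE))
  g <- build_factor_graph(cands, tab)
  seed <- kb_tuple(c("formation_age", "opinion_belongs"),
                   c("Tsingyuan Formation", "Aus"),
                   c("Carboniferous", "Busidae"))
  lab <- distant_supervision_labels(g, seed, tab)
  v <- g$variables
  lab_of <- function(rel, s, o, layer = "mention_relation") {
    id <- v$id[v$relation == rel & v$subject == s & v$object == o & v$layer == layer]
    val <- lab$value[lab$id %in% id]
    if (length(val) == 0) NA_integer_ else unique(val)
  }
  # seed (F, Carboniferous) supports the contained Namurian candidate
  expect_equal(lab_of("formation_age", "Tsingyuan Formation", "Namurian"), 1L)
  # disjoint interval for a known subject is closed-world negative
  expect_equal(lab_of("formation_age", "Tsingyuan Formation", "Frasnian"), 0L)
  # unknown subject stays unlabeled
  expect_true(is.na(lab_of("formation_age", "Mystery Formation", "Silurian")))
  # a synonym pair with no seed entry for the subject stays unlabeled
  expect_equal(lab_of("opinion_synonym", "Aus", "Bus"), NA_integer_)
  expect_equal(lab_of("opinion_belongs", "Aus", "Busidae"), 1L)
  # entity-layer variables carry the same labels
  expect_equal(lab_of("formation_age", "Tsingyuan Formation", "Namurian",
                      "entity_relation"), 1L)

  # negative subsampling removes negatives but never positives
  set.seed(2)
  lab0 <- distant_supervision_labels(g, seed, tab, negative_rate = 0)
  expect_true(all(lab0$value == 1L))
})

test_that("opinion pairs asserted under the other relation are negatives", {
  tab <- the_table()
  cands <- tibble::tibble(
    candidate_id = 1:2, doc_id = "d", scope = "sentence", sentence = 0L,
    row = NA_integer_, relation = c("opinion_synonym", "opinion_belongs"),
    subject = "Aus", object = c("Cus", "Cus"), species = NA_character_,
    pub_year = 2000L, features = replicate(2, "f|x", simplify = FALSE))
  g <- build_factor_graph(cands, tab)
  seed <- kb_tuple("opinion_belongs", "Aus", "Cus")
  lab <- distant_supervision_labels(g, seed, tab)
  v <- g$variables
  syn_id <- v$id[v$relation == "opinion_synonym" & v$layer == "mention_relation"]
  expect_equal(lab$value[lab$id == syn_id], 0L)
})

test_that("unary-only learning equals penalised ridge logistic regression", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  n <- 1500; p <- 8
  wstar <- runif(p, -1, 1)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rbinom(n, 1, plogis(drop(X %*% wstar)))
  g <- set_evidence(make_unary_graph(X), tibble::tibble(id = seq_len(n), value = y))
  l2 <- 0.1
  fit <- learn_weights(g, l2 = l2)
  ours <- fit$weights[colnames(X)]
  # glmnet scales the penalty by 1/n against the mean log-likelihood
  gl <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = l2 / n,
                       intercept = FALSE, standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(ours - as.numeric(stats::coef(gl))[-1])), 1e-3)
})

test_that("a perfectly separating feature earns a decisive weight", {
  set.seed(8)
  n <- 1000
  X <- cbind(hit = rep(c(1L, 0L), each = n / 2),
             noise = rbinom(n, 1, 0.5))
  y <- X[, "hit"]
  g <- set_evidence(make_unary_graph(X), tibble::tibble(id = seq_len(n), value = y))
  fit <- learn_weights(g, l2 = 0.1)
  expect_gt(fit$weights[["hit"]], 1)
  expect_gt(plogis(fit$weights[["hit"]]), 0.9)

  # labels independent of a balanced feature: its weight stays near zero
  y2 <- rep(c(1L, 0L), n / 2)
  g2 <- set_evidence(make_unary_graph(X), tibble::tibble(id = seq_len(n), value = y2))
  fit2 <- learn_weights(g2, l2 = 0.1)
  expect_lt(abs(fit2$weights[["hit"]]), 0.15)
})

test_that("learning recovers planted weights with sign agreement", {
  set.seed(77)
  n <- 5000; p <- 6
  wstar <- runif(p, 0.3, 1.2) * sample(c(-1, 1), p, replace = TRUE)
  names(wstar) <- sprintf("f%02d", 1:p)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p, dimnames = list(NULL, names(wstar)))
  y <- rbinom(n, 1, plogis(drop(X %*% wstar)))
  g <- set_evidence(make_unary_graph(X), tibble::tibble(id = seq_len(n), value = y))
  fit <- learn_weights(g, l2 = 0.01)
  what <- fit$weights[names(wstar)]
  expect_lt(max(abs(what - wstar)), 0.2)
  big <- abs(wstar) >= 0.5
  expect_equal(sign(what[big]), sign(wstar[big]))
})

test_that("learning requires both label classes and reports fit metadata", {
  X <- matrix(1L, 10, 1, dimnames = list(NULL, "f"))
  g <- set_evidence(make_unary_graph(X), tibble::tibble(id = 1:10, value = 1L))
  expect_error(learn_weights(g), "positive and one negative")

  g2 <- set_evidence(make_unary_graph(X),
                     tibble::tibble(id = 1:10, value = rep(0:1, 5)))
  fit <- learn_weights(g2)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "learned") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_pos, 5L)
  expect_true(gl$converged)
})

test_that("Gibbs marginals match closed forms and the enumeration oracle", {
  # isolated variable: uniform
  g0 <- random_factor_graph(1, n_factors = 0)
  m0 <- gibbs_marginals(g0, n_samples = 4000, rng_seed = 1)
  expect_lt(abs(m0$probability - 0.5), 0.05)

  # single unary factor: logistic(w) exactly in expectation
  X <- matrix(1L, 1, 1, dimnames = list(NULL, "f"))
  g1 <- make_unary_graph(X)
  g1$weights[["f"]] <- 2
  m1 <- gibbs_marginals(g1, n_samples = 6000, rng_seed = 2)
  expect_lt(abs(m1$probability - plogis(2)), 0.02)
  e1 <- exact_marginals(g1)
  expect_equal(e1$probability, plogis(2), tolerance = 1e-12)

  # three-variable implication chain vs enumeration
  g3 <- make_unary_graph(matrix(c(1L, 0L, 0L), 3, 1,
                                dimnames = list(NULL, "f")))
  g3$weights[["f"]] <- 1.2
  g3$factors <- dplyr::bind_rows(
    g3$factors,
    tibble::tibble(factor_id = max(g3$factors$factor_id) + 1:2,
                   kind = "implication",
                   weight_id = "RULE:interval_implication",
                   vars = list(c(1L, 2L), c(2L, 3L))))
  ex <- exact_marginals(g3)
  gb <- gibbs_marginals(g3, n_samples = 20000, burn_in = 2000, rng_seed = 3)
  expect_lt(max(abs(ex$probability - gb$probability)), 0.01)
})

test_that("evidence clamps and monotonicity in a positive weight holds", {
  X <- matrix(1L, 2, 1, dimnames = list(NULL, "f"))
  g <- make_unary_graph(X)
  g <- set_evidence(g, tibble::tibble(id = 1L, value = 0L))
  m <- gibbs_marginals(g, n_samples = 2000, rng_seed = 4)
  expect_equal(m$probability[1], 0)

  probs <- vapply(c(0, 1, 2, 3), function(w) {
    g$weights[["f"]] <- w
    exact_marginals(g)$probability[2]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("sampler agrees with enumeration on random mixed graphs", {
  set.seed(606)
  devs <- replicate(25, {
    g <- random_factor_graph(sample(3:10, 1), n_evidence = sample(0:2, 1))
    ex <- exact_marginals(g)
    gb <- gibbs_marginals(g, n_samples = 20000, burn_in = 2000,
                          rng_seed = sample.int(1e6, 1))
    max(abs(ex$probability - gb$probability))
  })
  expect_lt(max(devs), 0.01)
})

test_that("long chains agree with enumeration even under strong coupling", {
  # hand-built frustrated graph at the edge of the weight range: an
  # implication chain against opposing unaries plus a strong aggregation
  X <- matrix(c(1L, 0L, 1L, 0L, 1L), 5, 1, dimnames = list(NULL, "f"))
  g <- make_unary_graph(X)
  g$weights[["f"]] <- -1.5
  extra <- tibble::tibble(
    factor_id = max(g$factors$factor_id) + 1:3,
    kind = c("implication", "implication", "aggregation"),
    weight_id = c("RULE:interval_implication", "RULE:interval_implication",
                  "RULE:aggregation"),
    vars = list(c(1L, 2L), c(2L, 3L), c(4L, 1L, 5L)))
  g$factors <- dplyr::bind_rows(g$factors, extra)
  g$weights[["RULE:interval_implication"]] <- 2
  g$weights[["RULE:aggregation"]] <- 2
  ex <- exact_marginals(g)
  gb <- gibbs_marginals(g, n_samples = 2e5, burn_in = 2e4, rng_seed = 10)
  expect_lt(max(abs(ex$probability - gb$probability)), 0.01)
  # and the frequency estimator targets the same distribution
  gf <- gibbs_marginals(g, n_samples = 2e5, burn_in = 2e4, rng_seed = 11,
                        estimator = "frequency")
  expect_lt(max(abs(ex$probability - gf$probability)), 0.02)
})

test_that("exact enumeration guards its size limit", {
  set.seed(1)
  g <- random_factor_graph(21, n_factors = 5)
  expect_error(exact_marginals(g), "20 free variables")
})

test_that("calibration table bins predictions against gold labels", {
  ct <- calibration_table(rep(1, 50), rep(TRUE, 50))
  expect_equal(ct$empirical_accuracy[10], 1)
  expect_equal(sum(ct$n_predictions), 50)

  ct0 <- calibration_table(numeric(0), logical(0))
  expect_true(all(ct0$n_predictions == 0))
  expect_true(all(is.na(ct0$empirical_accuracy)))

  set.seed(99)
  p <- runif(4000)
  y <- rbinom(4000, 1, p)
  ct2 <- calibration_table(p, y)
  cen <- (ct2$bin_lo + ct2$bin_hi) / 2
  expect_lt(max(abs(ct2$empirical_accuracy - cen)), 0.06)
})
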