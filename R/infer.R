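# Marginal inference: Gibbs sampling (compiled inner loop) and an exact
# enumeration oracle for small graphs.

KIND_CODES <- c(unary_feature = 0L, implication = 1L, aggregation = 2L)

graph_arrays <- function(graph, weights) {
  vars_list <- graph$factors$vars
  id_index <- stats::setNames(seq_len(nrow(graph$variables)), graph$variables$id)
  fvars <- unname(id_index[as.character(unlist(vars_list))]) - 1L
  list(
    n_vars = nrow(graph$variables),
    evidence = ifelse(graph$variables$is_evidence,
                      graph$variables$evidence, -1L),
    fkind = unname(KIND_CODES[graph$factors$kind]),
    fweight = unname(weights[graph$factors$weight_id]),
    fptr = c(0L, cumsum(lengths(vars_list))),
    fvars = as.integer(fvars)
  )
}

#' Gibbs-sampling marginals
#'
#' Single-site Gibbs sweeps in fixed variable order with evidence variables
#' clamped. Two unbiased estimators of each free variable's marginal are
#' available from the post-burn-in sweeps: `"rao_blackwell"` (default)
#' averages the full-conditional probability used at each resampling of the
#' variable, which has substantially smaller Monte Carlo variance;
#' `"frequency"` is the plain fraction of sweeps in which the variable was 1.
#' Deterministic given `rng_seed`.
#'
#' @param graph a `factor_graph` (evidence set via [set_evidence()] or
#'   already attached).
#' @param weights named weight vector; defaults to `graph$weights`.
#' @param n_samples total sweeps (> 0).
#' @param burn_in sweeps discarded before counting (default 10% of
#'   `n_samples`).
#' @param rng_seed integer seed.
#' @param estimator marginal estimator (see above).
#' @return a `marginal_table` tibble: `id`, `probability`, plus the sampler
#'   settings as attributes.
#' @export
gibbs_marginals <- function(graph, weights = NULL, n_samples = 2000,
                            burn_in = ceiling(n_samples / 10), rng_seed = 1L,
                            estimator = c("rao_blackwell", "frequency")) {
  stopifnot(n_samples > 0, burn_in >= 0, burn_in < n_samples)
  estimator <- match.arg(estimator)
  w <- resolve_weights(graph, weights)
  arr <- graph_arrays(graph, w)
  marg <- with_seed(rng_seed, gibbs_sample_cpp(
    arr$n_vars, as.integer(arr$evidence), arr$fkind, arr$fweight,
    as.integer(arr$fptr), arr$fvars, as.integer(n_samples), as.integer(burn_in)))
  out <- tibble(id = graph$variables$id,
                probability = marg[, if (estimator == "frequency") 1 else 2])
  structure(out, class = c("marginal_table", class(out)),
            n_samples = n_samples, burn_in = burn_in, rng_seed = rng_seed,
            estimator = estimator)
}

resolve_weights <- function(graph, weights) {
  w <- graph$weights
  if (!is.null(weights)) {
    if (inherits(weights, "weight_fit")) weights <- weights$weights
    w[names(weights)] <- weights
  }
  missing_w <- setdiff(unique(graph$factors$weight_id), names(w))
  if (length(missing_w) > 0) {
    abort(sprintf("weights missing for: %s", paste(head(missing_w, 5), collapse = ", ")))
  }
  if (any(!is.finite(w))) abort("non-finite weight values")
  w
}

#' Exact marginals by enumeration
#'
#' Sums exp(total log-potential) over all assignments of the free variables
#' (evidence fixed); intended as the small-graph oracle the sampler is
#' checked against. Limited to 20 free variables.
#'
#' @inheritParams gibbs_marginals
#' @return a `marginal_table` tibble.
#' @export
exact_marginals <- function(graph, weights = NULL) {
  nv <- nrow(graph$variables)
  if (nv == 0) {
    return(structure(tibble(id = integer(), probability = numeric()),
                     class = c("marginal_table", "tbl_df", "tbl", "data.frame")))
  }
  w <- resolve_weights(graph, weights)
  free <- which(!graph$variables$is_evidence)
  if (length(free) > 20) {
    abort(sprintf("exact enumeration limited to 20 free variables, got %d",
                  length(free)))
  }
  # assignment matrix: all configurations x all variables
  n_cfg <- 2^length(free)
  A <- matrix(rep(ifelse(graph$variables$is_evidence,
                         graph$variables$evidence, 0L), each = n_cfg),
              nrow = n_cfg)
  if (length(free) > 0) {
    grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
    A[, free] <- grid
  }
  id_index <- stats::setNames(seq_len(nv), graph$variables$id)

  logw <- numeric(n_cfg)
  for (k in seq_len(nrow(graph$factors))) {
    vars <- unname(id_index[as.character(graph$factors$vars[[k]])])
    wk <- w[[graph$factors$weight_id[k]]]
    phi <- switch(graph$factors$kind[k],
      unary_feature = A[, vars[1]],
      implication = as.numeric(A[, vars[1]] == 0 | A[, vars[2]] == 1),
      aggregation = {
        mx <- if (length(vars) > 2) {
          do.call(pmax, lapply(vars[-1], function(v) A[, v]))
        } else A[, vars[2]]
        as.numeric(A[, vars[1]] == mx)
      })
    logw <- logw + wk * phi
  }
  p_cfg <- exp(logw - max(logw))
  p_cfg <- p_cfg / sum(p_cfg)
  marg <- as.numeric(crossprod(A, p_cfg))
  structure(tibble(id = graph$variables$id, probability = marg),
            class = c("marginal_table", "tbl_df", "tbl", "data.frame"))
}

#' Calibration table for predicted probabilities
#'
#' Bins predictions into `n_bins` equal-width probability bins (the top bin
#' closed at 1) and reports the empirical accuracy per bin: the fraction of
#' predictions in the bin whose asserted fact is actually true. With a
#' well-calibrated system each bin's accuracy tracks its centre.
#'
#' @param probability numeric vector of predicted probabilities.
#' @param truth logical (or 0/1) vector of gold labels, same length.
#' @param n_bins number of equal-width bins (default 10).
#' @return a `calibration_table` tibble: `bin_lo`, `bin_hi`, `n_predictions`,
#'   `n_correct`, `empirical_accuracy`.
#' @export
calibration_table <- function(probability, truth, n_bins = 10) {
  stopifnot(length(probability) == length(truth))
  truth <- as.logical(truth)
  lo <- seq(0, 1, length.out = n_bins + 1)[-(n_bins + 1)]
  hi <- lo + 1 / n_bins
  idx <- pmin(pmax(findInterval(probability, lo), 1L), n_bins)
  n_pred <- tabulate(idx, n_bins)
  n_corr <- tabulate(idx[truth], n_bins)
  out <- tibble(
    bin_lo = lo, bin_hi = hi, n_predictions = n_pred, n_correct = n_corr,
    empirical_accuracy = ifelse(n_pred > 0, n_corr / n_pred, NA_real_))
  structure(out, class = c("calibration_table", class(out)))
}
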