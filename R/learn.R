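# Weight learning: L2-penalised likelihood of the evidence variables.
#
# The objective is the penalised pseudo-likelihood of the evidence
# variables: sum over evidence v of log P(x_v | x_-v) under the
# exponential-family model, restricted to factors whose entire scope is
# evidence (factors touching unlabeled variables do not enter the
# objective; unlabeled variables still participate at inference). Because
# each conditional is logistic in the weights, the objective is concave;
# for variables touched only by unary feature factors it reduces exactly to
# L2-penalised logistic regression on the feature indicators.

#' Learn factor-graph weights
#'
#' Maximises the L2-penalised conditional likelihood of the evidence
#' variables by L-BFGS from a zero start (deterministic; `rng_seed` is
#' recorded for provenance but the optimisation is not stochastic). Weights
#' attached to no fully-observed factor (typically the aggregation and
#' implication rule weights when no entity-layer evidence exists) keep their
#' current values in the graph.
#'
#' @param graph a `factor_graph` with evidence attached ([set_evidence()]).
#' @param l2 ridge penalty on the weight vector (default 0.1).
#' @param max_iter maximum L-BFGS iterations.
#' @param tol relative convergence tolerance.
#' @param rng_seed recorded seed (the fit itself is deterministic).
#' @return a `weight_fit` object: full weight vector plus fit metadata;
#'   supports [tidy()] and [glance()].
#' @export
learn_weights <- function(graph, l2 = 0.1, max_iter = 200, tol = 1e-8,
                          rng_seed = 1L) {
  vars <- graph$variables
  ev_ids <- vars$id[vars$is_evidence]
  ev_val <- stats::setNames(vars$evidence[vars$is_evidence], ev_ids)
  n_pos <- sum(ev_val == 1L); n_neg <- sum(ev_val == 0L)
  if (n_pos < 1 || n_neg < 1) {
    abort(sprintf(
      "learning needs at least one positive and one negative evidence variable (have %d/%d)",
      n_pos, n_neg))
  }

  is_ev <- stats::setNames(vars$is_evidence, vars$id)
  observed <- function(ids) ev_val[as.character(ids)]

  # fully-observed factors only
  obs_fac <- vapply(graph$factors$vars,
                    function(v) all(is_ev[as.character(v)]), logical(1))
  fac <- graph$factors[obs_fac, ]
  if (nrow(fac) == 0) abort("no fully-observed factors to learn from")

  wid <- sort(unique(fac$weight_id))
  n_w <- length(wid)

  # design: D[v, k] = sum over factors f with weight k containing v of
  #   phi_f(x_v = 1, rest observed) - phi_f(x_v = 0, rest observed)
  row_of <- stats::setNames(seq_along(ev_ids), ev_ids)
  ri <- integer(0); ci <- integer(0); dx <- numeric(0)
  unary <- fac$kind == "unary_feature"
  if (any(unary)) {
    ri <- unname(row_of[as.character(unlist(fac$vars[unary]))])
    ci <- match(fac$weight_id[unary], wid)
    dx <- rep(1, sum(unary))
  }
  for (k in which(!unary)) {
    vids <- fac$vars[[k]]
    col <- match(fac$weight_id[k], wid)
    vals <- unname(observed(vids))
    kind <- fac$kind[k]
    for (j in seq_along(vids)) {
      d <- switch(kind,
        implication = if (j == 1) {
          as.numeric(vals[2] == 1) - 1
        } else {
          1 - as.numeric(vals[1] == 0)
        },
        aggregation = if (j == 1) {
          mx <- if (length(vals) > 1) max(vals[-1]) else 0
          as.numeric(mx == 1) - as.numeric(mx == 0)
        } else {
          mx0 <- if (length(vals) > 2) max(vals[-c(1, j)]) else 0
          as.numeric(vals[1] == 1) - as.numeric(vals[1] == mx0)
        })
      ri <- c(ri, row_of[[as.character(vids[j])]])
      ci <- c(ci, col)
      dx <- c(dx, d)
    }
  }
  D <- as.matrix(Matrix::sparseMatrix(i = ri, j = ci, x = dx,
                                      dims = c(length(ev_ids), n_w)))
  dimnames(D) <- list(as.character(ev_ids), wid)

  y <- unname(ev_val[rownames(D)])
  negloglik <- function(w) {
    eta <- drop(D %*% w)
    # overflow-safe log(1 + e^eta)
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - lse) + l2 / 2 * sum(w^2)
  }
  grad <- function(w) {
    eta <- drop(D %*% w)
    p <- 1 / (1 + exp(-eta))
    -drop(crossprod(D, y - p)) + l2 * w
  }
  fit <- stats::optim(rep(0, n_w), negloglik, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  if (fit$convergence != 0) {
    warn(sprintf("weight learning did not converge after %d iterations (%s); returning partial result",
                 max_iter, fit$message))
  }

  weights <- graph$weights
  weights[wid] <- fit$par
  structure(list(
    weights = weights, learned_ids = wid,
    objective = -fit$value, converged = fit$convergence == 0,
    iterations = fit$counts[["function"]], l2 = l2,
    n_evidence = length(ev_ids), n_pos = n_pos, n_neg = n_neg,
    rng_seed = rng_seed
  ), class = "weight_fit")
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("<weight_fit: %d weights (%d learned), %d evidence (%d+/%d-), %s>\n",
              length(x$weights), length(x$learned_ids), x$n_evidence,
              x$n_pos, x$n_neg,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a learned weight vector
#'
#' @param x a `weight_fit` object.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `learned`.
#' @export
tidy.weight_fit <- function(x, ...) {
  tibble(term = names(x$weights), estimate = unname(x$weights),
         learned = names(x$weights) %in% x$learned_ids)
}

#' One-row fit summary of a weight fit
#'
#' @inheritParams tidy.weight_fit
#' @export
glance.weight_fit <- function(x, ...) {
  tibble(n_weights = length(x$weights), n_learned = length(x$learned_ids),
         n_evidence = x$n_evidence, n_pos = x$n_pos, n_neg = x$n_neg,
         objective = x$objective, l2 = x$l2, converged = x$converged)
}
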