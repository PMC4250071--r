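# Three-layer boolean factor graph: mention-level relation variables,
# entity-level relation variables, and factors with tied weights.
#
# Potentials (log scale, all linear in a tied weight w):
#   unary_feature on v:          w * v
#   implication (a -> b):        w * 1{a = 0 or b = 1}
#   aggregation (e; m1..mk):     w * 1{e = max(m1..mk)}
# The unnormalised log-probability of a full assignment is the sum of
# log-potentials over all factors, which defines the exponential-family
# model both the Gibbs sampler and the enumeration oracle target.

WEIGHT_AGGREGATION <- "RULE:aggregation"
WEIGHT_IMPLICATION <- "RULE:interval_implication"
DEFAULT_RULE_WEIGHTS <- c(4, 1)

new_factor_graph <- function() {
  structure(list(
    variables = tibble(id = integer(), layer = character(),
                       relation = character(), subject = character(),
                       object = character(), candidate_id = integer(),
                       doc_id = character(), pub_year = integer(),
                       species = character(),
                       is_evidence = logical(), evidence = integer()),
    factors = tibble(factor_id = integer(), kind = character(),
                     weight_id = character(), vars = list()),
    weights = stats::setNames(DEFAULT_RULE_WEIGHTS,
                              c(WEIGHT_AGGREGATION, WEIGHT_IMPLICATION))
  ), class = "factor_graph")
}

#' Build the mention layer of a factor graph
#'
#' One boolean variable per relation candidate and one unary feature factor
#' per (candidate, feature); weights are tied across factors by exact
#' feature-string equality.
#'
#' @param candidates tibble from [extract_features()] (must carry `features`).
#' @return a `factor_graph` with mention variables and unary factors.
#' @export
build_mention_layer <- function(candidates) {
  if (is.null(candidates$features)) {
    abort("candidates must carry a `features` list-column; run extract_features()")
  }
  g <- new_factor_graph()
  n <- nrow(candidates)
  if (n == 0) return(g)
  g$variables <- tibble(
    id = seq_len(n), layer = "mention_relation",
    relation = candidates$relation, subject = candidates$subject,
    object = candidates$object, candidate_id = candidates$candidate_id,
    doc_id = candidates$doc_id, pub_year = candidates$pub_year,
    species = candidates$species,
    is_evidence = FALSE, evidence = NA_integer_)
  feat <- tibble(
    var = rep(seq_len(n), lengths(candidates$features)),
    weight_id = unlist(candidates$features) %||% character(0))
  g$factors <- tibble(
    factor_id = seq_len(nrow(feat)), kind = "unary_feature",
    weight_id = feat$weight_id, vars = as.list(feat$var))
  new_w <- setdiff(unique(feat$weight_id), names(g$weights))
  g$weights <- c(g$weights, stats::setNames(rep(0, length(new_w)), new_w))
  g
}

#' Add the entity layer
#'
#' One boolean variable per distinct (relation, subject, object) entity
#' tuple, linked to all of its mention variables by an OR-style aggregation
#' factor (the cross-document layer): the factor rewards assignments where
#' the entity variable equals the maximum of its mention variables, under
#' one shared weight.
#'
#' @param graph result of [build_mention_layer()].
#' @return the graph with entity variables and aggregation factors added.
#' @export
build_entity_layer <- function(graph) {
  mv <- graph$variables[graph$variables$layer == "mention_relation", ]
  if (nrow(mv) == 0) return(graph)
  key <- paste(mv$relation, mv$subject, mv$object, sep = "\r")
  grp <- split(mv, key)
  ord <- order(vapply(grp, function(g) min(g$id), integer(1)))
  grp <- grp[ord]
  next_id <- max(graph$variables$id)
  next_fid <- if (nrow(graph$factors) > 0) max(graph$factors$factor_id) else 0L

  evars <- vector("list", length(grp))
  efac <- vector("list", length(grp))
  for (i in seq_along(grp)) {
    m <- grp[[i]]
    sp <- m$species[!is.na(m$species)]
    sp <- if (length(sp) > 0) names(sort(table(sp), decreasing = TRUE))[1] else NA_character_
    # provenance of the aggregate: the most recently published mention
    best <- m[order(-m$pub_year, m$doc_id), ][1, ]
    evars[[i]] <- tibble(
      id = next_id + i, layer = "entity_relation",
      relation = m$relation[1], subject = m$subject[1], object = m$object[1],
      candidate_id = NA_integer_, doc_id = best$doc_id,
      pub_year = max(m$pub_year), species = sp,
      is_evidence = FALSE, evidence = NA_integer_)
    efac[[i]] <- tibble(
      factor_id = next_fid + i, kind = "aggregation",
      weight_id = WEIGHT_AGGREGATION, vars = list(c(next_id + i, m$id)))
  }
  graph$variables <- dplyr::bind_rows(graph$variables, dplyr::bind_rows(evars))
  graph$factors <- dplyr::bind_rows(graph$factors, dplyr::bind_rows(efac))
  graph
}

#' Add interval-hierarchy implication factors
#'
#' For each formation with several candidate ages, every ordered pair of
#' entity variables whose intervals are hierarchically nested (a contains b)
#' gets one implication factor a -> b: if the formation is Carboniferous it
#' is likely also Namurian. The implication strength is a single tied weight
#' estimated from the data (a statistical, not logical, implication).
#'
#' @param graph a graph with the entity layer built.
#' @param table an `interval_table`.
#' @return the graph with implication factors added.
#' @export
add_hierarchy_factors <- function(graph, table) {
  ev <- graph$variables[graph$variables$layer == "entity_relation" &
                          graph$variables$relation == "formation_age", ]
  if (nrow(ev) == 0) return(graph)
  next_fid <- if (nrow(graph$factors) > 0) max(graph$factors$factor_id) else 0L
  fac <- list()
  for (grp in split(ev, ev$subject)) {
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$id), ]
    anc <- lapply(grp$object, interval_ancestors, table = table)
    for (i in seq_len(nrow(grp))) {
      for (j in seq_len(nrow(grp))) {
        if (i == j) next
        # interval i contains interval j: factor (coarse -> fine)
        if (grp$object[i] %in% anc[[j]]) {
          fac[[length(fac) + 1L]] <- tibble(
            factor_id = NA_integer_, kind = "implication",
            weight_id = WEIGHT_IMPLICATION,
            vars = list(c(grp$id[i], grp$id[j])))
        }
      }
    }
  }
  if (length(fac) > 0) {
    fac <- dplyr::bind_rows(fac)
    fac$factor_id <- next_fid + seq_len(nrow(fac))
    graph$factors <- dplyr::bind_rows(graph$factors, fac)
  }
  graph
}

#' Build the full factor graph from featurised candidates
#'
#' Convenience composition of [build_mention_layer()],
#' [build_entity_layer()] and (when an interval table is supplied)
#' [add_hierarchy_factors()]. Construction is deterministic: stable variable
#' ids and factor ordering given the same candidates.
#'
#' @inheritParams build_mention_layer
#' @param table optional `interval_table` for hierarchy implications.
#' @return a `factor_graph`.
#' @export
build_factor_graph <- function(candidates, table = NULL) {
  g <- build_entity_layer(build_mention_layer(candidates))
  if (!is.null(table)) g <- add_hierarchy_factors(g, table)
  g
}

#' Log-potential of one factor under an assignment
#'
#' @param factor one-row tibble (or list) with `kind`, `weight_id`, `vars`.
#' @param assignment integer 0/1 vector indexed (or named) by variable id.
#' @param weights named weight vector.
#' @return the scalar log-potential contribution.
#' @export
log_potential <- function(factor, assignment, weights) {
  vars <- if (is.list(factor$vars)) factor$vars[[1]] else factor$vars
  vals <- if (!is.null(names(assignment))) {
    assignment[as.character(vars)]
  } else {
    assignment[vars]
  }
  if (anyNA(vals)) abort("assignment is missing a factor variable")
  w <- weights[[factor$weight_id]]
  vals <- unname(vals)
  kind <- if (is.list(factor$kind)) factor$kind[[1]] else factor$kind
  switch(kind,
    unary_feature = w * vals[1],
    implication = w * as.numeric(vals[1] == 0 || vals[2] == 1),
    aggregation = w * as.numeric(vals[1] == max(vals[-1])),
    abort(sprintf("unknown factor kind: %s", kind)))
}

#' Attach evidence values to a factor graph
#'
#' @param graph a `factor_graph`.
#' @param evidence tibble with columns `id`, `value` (0/1); other variables
#'   stay free.
#' @export
set_evidence <- function(graph, evidence) {
  i <- match(evidence$id, graph$variables$id)
  if (anyNA(i)) abort("evidence refers to unknown variable ids")
  graph$variables$is_evidence[] <- FALSE
  graph$variables$evidence[] <- NA_integer_
  graph$variables$is_evidence[i] <- TRUE
  graph$variables$evidence[i] <- as.integer(evidence$value)
  graph
}

#' @export
print.factor_graph <- function(x, ...) {
  cat(sprintf(paste0("<factor_graph: %d variables (%d mention, %d entity, ",
                     "%d evidence), %d factors, %d weights>\n"),
              nrow(x$variables),
              sum(x$variables$layer == "mention_relation"),
              sum(x$variables$layer == "entity_relation"),
              sum(x$variables$is_evidence),
              nrow(x$factors), length(x$weights)))
  invisible(x)
}

#' Dump a factor graph to TSV triple files
#'
#' Writes `variables.tsv`, `factors.tsv` and `weights.tsv` under `dir` for
#' inspection.
#'
#' @param graph a `factor_graph`.
#' @param dir output directory (created if needed).
#' @export
write_factor_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(graph$variables, file.path(dir, "variables.tsv"), progress = FALSE)
  fac <- graph$factors
  fac$vars <- vapply(fac$vars, paste, character(1), collapse = ",")
  readr::write_tsv(fac, file.path(dir, "factors.tsv"), progress = FALSE)
  readr::write_tsv(tibble(weight_id = names(graph$weights),
                          value = unname(graph$weights)),
                   file.path(dir, "weights.tsv"), progress = FALSE)
  invisible(dir)
}
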