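# Distant supervision: label extraction candidates against a seed knowledge
# base instead of hand annotation.

#' Distant-supervision evidence labels
#'
#' Labels factor-graph variables against a seed KB:
#' * positive (1): the variable's entity tuple is in the seed KB, or — for
#'   `formation_age` — the seed holds the same formation with an interval
#'   that contains, or is contained by, the candidate interval;
#' * negative (0): the subject appears in the seed KB for that relation but
#'   only with disjoint objects (no hierarchical overlap for ages, different
#'   object otherwise), or — for the two taxonomic-opinion relations — the
#'   exact pair is asserted in the seed under the other opinion relation
#'   (a placement and a synonymy between the same pair of names are
#'   mutually exclusive); negatives are subsampled at `negative_rate`;
#' * all other variables stay unlabeled and are marginalised at inference.
#'
#' Labels are decided once per entity tuple and applied to the entity
#' variable and all of its mention variables, so a tuple's variables are
#' labelled consistently and the aggregation and implication rule weights
#' have fully-observed factors to be learned from. Negative subsampling is
#' also per entity tuple, drawn from the current RNG stream.
#'
#' @param graph a `factor_graph`.
#' @param seed_kb a `kb` tibble of known-true tuples.
#' @param table an `interval_table` (for hierarchical age matching).
#' @param negative_rate probability a negative-eligible tuple is kept as
#'   evidence 0 (default 1, the closed-world-per-subject rule).
#' @param label_entities also label entity-layer variables (default TRUE).
#' @return evidence tibble (`id`, `value`); attach with [set_evidence()].
#' @export
distant_supervision_labels <- function(graph, seed_kb, table,
                                       negative_rate = 1, label_entities = TRUE) {
  assert_prob(negative_rate)
  vars <- graph$variables
  tuples <- dplyr::distinct(vars[, c("relation", "subject", "object")])
  if (nrow(tuples) == 0 || nrow(seed_kb) == 0) {
    return(tibble(id = integer(), value = integer()))
  }

  seed_key <- kb_key(seed_kb)
  subj_key <- paste(seed_kb$relation, seed_kb$subject, sep = "\r")
  label <- rep(NA_integer_, nrow(tuples))

  for (k in seq_len(nrow(tuples))) {
    rel <- tuples$relation[k]; s <- tuples$subject[k]; o <- tuples$object[k]
    exact <- paste(rel, s, o, sep = "\r") %in% seed_key
    if (exact) { label[k] <- 1L; next }
    if (rel %in% c("opinion_belongs", "opinion_synonym")) {
      other <- setdiff(c("opinion_belongs", "opinion_synonym"), rel)
      if (paste(other, s, o, sep = "\r") %in% seed_key) {
        label[k] <- 0L
        next
      }
    }
    hit <- subj_key == paste(rel, s, sep = "\r")
    if (!any(hit)) next
    seed_obj <- seed_kb$object[hit]
    if (rel == "formation_age") {
      known <- o %in% table$intervals$name
      overlap <- known && any(vapply(seed_obj, function(so) {
        so %in% table$intervals$name &&
          (interval_contains(table, so, o) || interval_contains(table, o, so))
      }, logical(1)))
      if (overlap) label[k] <- 1L else label[k] <- 0L
    } else {
      label[k] <- 0L  # subject known, object disjoint: closed world
    }
  }

  neg <- which(label == 0L)
  if (negative_rate < 1 && length(neg) > 0) {
    drop <- neg[runif(length(neg)) >= negative_rate]
    label[drop] <- NA_integer_
  }

  tkey <- paste(tuples$relation, tuples$subject, tuples$object, sep = "\r")
  vkey <- paste(vars$relation, vars$subject, vars$object, sep = "\r")
  vlab <- label[match(vkey, tkey)]
  keep <- !is.na(vlab) &
    (label_entities | vars$layer == "mention_relation")
  tibble(id = vars$id[keep], value = vlab[keep])
}
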