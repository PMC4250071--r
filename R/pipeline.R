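# End-to-end orchestration: corpus -> mentions -> candidates -> factor graph
# -> distant supervision -> weight learning -> Gibbs marginals -> thresholded
# tuples -> occurrences -> diversity, plus the training-size experiment.

#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run. All randomness flows from
#' `seed`: the world, the seed-KB split, negative subsampling and the Gibbs
#' chain each get sub-seeds derived from it, so a run is reproducible from
#' its manifest.
#'
#' @param world_config a [world_config()] (its `rng_seed` is overridden by
#'   `seed`).
#' @param tau probability acceptance threshold (default 0.95).
#' @param min_rank coarsest admissible temporal resolution.
#' @param samples,burn_in Gibbs sampler schedule.
#' @param l2,max_iter learner settings.
#' @param negative_rate distant-supervision negative subsampling rate.
#' @param seed master integer seed.
#' @param out_dir optional directory for CSV exports and the run manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(world_config = paleomine::world_config(),
                            tau = 0.95, min_rank = "epoch",
                            samples = 3000, burn_in = 300,
                            l2 = 0.1, max_iter = 200,
                            negative_rate = 1, seed = 1L, out_dir = NULL) {
  assert_prob(tau)
  structure(list(world_config = world_config, tau = tau, min_rank = min_rank,
                 samples = samples, burn_in = burn_in, l2 = l2,
                 max_iter = max_iter, negative_rate = negative_rate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full extraction pipeline
#'
#' Executes generate -> extract -> graph -> supervise -> learn -> infer ->
#' export -> diversity on a synthetic world (or a supplied one), returning a
#' run report with per-stage counts, the probabilistic database, the
#' occurrence set, diversity statistics, and precision/recall of the
#' accepted tuples against the gold KB. Idempotent given the seeds in the
#' configuration.
#'
#' Tuple-level evaluation is containment-aware for ages: an accepted
#' `formation_age` tuple whose interval contains the gold age (e.g. the
#' period when the gold age is a stage of it) is counted correct, since the
#' statement is true, merely coarse.
#'
#' @param config a [pipeline_config()].
#' @param world optionally a pre-generated `gold_world` (skips generation).
#' @param table an `interval_table`.
#' @param seed_kb optionally a pre-split seed KB; defaults to sampling
#'   `world_config$seed_kb_fraction` of the gold KB.
#' @return a `pipeline_run` list; see components in the run's `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), world = NULL,
                         table = load_interval_table(), seed_kb = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  wc <- config$world_config
  wc$rng_seed <- derive_seed(config$seed, 1L)
  if (is.null(world)) world <- generate_world(wc, table)
  if (is.null(seed_kb)) {
    seed_kb <- with_seed(derive_seed(config$seed, 2L),
                         split_seed_kb(world$gold_kb, wc$seed_kb_fraction))$seed
  }

  gaz <- build_gazetteers(seed_kb, world$vocab)
  mentions <- extract_mentions_corpus(world, gaz)
  candidates <- extract_features(generate_candidates(mentions), world)
  graph <- build_factor_graph(candidates, table)
  labels <- with_seed(derive_seed(config$seed, 3L),
                      distant_supervision_labels(graph, seed_kb, table,
                                                 config$negative_rate))
  graph <- set_evidence(graph, labels)
  # a corpus can label only one class (e.g. a complete seed KB over a clean
  # corpus yields no negatives); evidence clamping then carries the run and
  # the feature weights stay at their defaults
  fit <- tryCatch(
    learn_weights(graph, l2 = config$l2, max_iter = config$max_iter,
                  rng_seed = derive_seed(config$seed, 4L)),
    error = function(e) {
      if (!grepl("at least one positive and one negative", conditionMessage(e))) {
        abort(sprintf("learning stage failed: %s", conditionMessage(e)))
      }
      NULL
    })
  marginals <- gibbs_marginals(graph, fit, n_samples = config$samples,
                               burn_in = config$burn_in,
                               rng_seed = derive_seed(config$seed, 5L))
  tuples <- entity_tuples(graph, marginals)
  accepted <- filter_by_probability(tuples, config$tau)
  taxonomy <- resolve_taxonomy(accepted)
  occurrences <- assemble_occurrences(accepted, table)
  occ_res <- resolution_filter(apply_taxonomy(occurrences, taxonomy),
                               table, config$min_rank)
  ranges <- genus_ranges(occ_res, table)
  n_bins <- nrow(table$bins)
  diversity <- foote_rates(ranges, n_bins)

  metrics <- eval_extractions(accepted, world$gold_kb, table)

  manifest <- list(
    seed = config$seed, tau = config$tau, min_rank = config$min_rank,
    samples = config$samples, burn_in = config$burn_in, l2 = config$l2,
    negative_rate = config$negative_rate, world_config = unclass(wc),
    learning = if (is.null(fit)) "skipped: single-class evidence" else "ok",
    counts = list(
      documents = length(world$documents), mentions = nrow(mentions),
      candidates = nrow(candidates), variables = nrow(graph$variables),
      factors = nrow(graph$factors), evidence = nrow(labels),
      tuples = nrow(tuples), accepted = nrow(accepted),
      occurrences = nrow(occurrences), genera = nrow(ranges)))

  run <- structure(list(
    world = world, seed_kb = seed_kb, mentions = mentions,
    candidates = candidates, graph = graph, fit = fit,
    marginals = marginals, tuples = tuples, accepted = accepted,
    taxonomy = taxonomy, occurrences = occurrences, ranges = ranges,
    diversity = diversity, metrics = metrics, manifest = manifest,
    table = table), class = "pipeline_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_occurrences(occ_res, file.path(config$out_dir, "occurrences.csv"))
    export_opinions(accepted, file.path(config$out_dir, "opinions.csv"))
    write_kb(accepted, file.path(config$out_dir, "tuples.csv"))
    readr::write_csv(diversity, file.path(config$out_dir, "diversity.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

#' Precision and recall of accepted tuples against a gold KB
#'
#' Precision: fraction of accepted tuples that are gold-consistent (exact
#' match, or for `formation_age` an interval hierarchically related to the
#' gold age, or a junior synonym re-keyed by the gold synonymy for taxon
#' subjects). Recall: fraction of gold tuples with a consistent accepted
#' tuple.
#'
#' @param accepted accepted entity tuples.
#' @param gold_kb the gold `kb`.
#' @param table an `interval_table`.
#' @return one-row tibble: precision, recall, n_accepted, n_gold.
#' @export
eval_extractions <- function(accepted, gold_kb, table) {
  if (nrow(accepted) == 0) {
    return(tibble(precision = NA_real_, recall = 0,
                  n_accepted = 0L, n_gold = nrow(gold_kb)))
  }
  senior <- stats::setNames(
    gold_kb$object[gold_kb$relation == "opinion_synonym"],
    gold_kb$subject[gold_kb$relation == "opinion_synonym"])
  canon <- function(x) ifelse(x %in% names(senior), senior[x], x)

  gk <- gold_kb
  gk$subject <- canon(gk$subject)
  gold_key <- kb_key(gk)
  acc <- accepted
  acc$subject <- canon(acc$subject)

  consistent <- function(rel, s, o) {
    if (paste(rel, s, o, sep = "\r") %in% gold_key) return(TRUE)
    if (rel == "formation_age") {
      gold_o <- gk$object[gk$relation == rel & gk$subject == s]
      return(any(vapply(gold_o, function(go) {
        go %in% table$intervals$name && o %in% table$intervals$name &&
          (interval_contains(table, o, go) || interval_contains(table, go, o))
      }, logical(1))))
    }
    FALSE
  }
  ok <- vapply(seq_len(nrow(acc)), function(i) {
    consistent(acc$relation[i], acc$subject[i], acc$object[i])
  }, logical(1))

  acc_key <- kb_key(acc)
  acc_age <- acc[acc$relation == "formation_age", ]
  recalled <- vapply(seq_len(nrow(gk)), function(i) {
    if (gold_key[i] %in% acc_key) return(TRUE)
    if (gk$relation[i] == "formation_age") {
      cand <- acc_age$object[acc_age$subject == gk$subject[i]]
      return(any(vapply(cand, function(o) {
        o %in% table$intervals$name &&
          (interval_contains(table, o, gk$object[i]) ||
             interval_contains(table, gk$object[i], o))
      }, logical(1))))
    }
    FALSE
  }, logical(1))

  tibble(precision = mean(ok), recall = mean(recalled),
         n_accepted = nrow(acc), n_gold = nrow(gk))
}

#' Training-size experiment
#'
#' Regenerates the distant-supervision labels from seed KBs subsampled at
#' each fraction, reruns learning and inference on the same corpus, and
#' records the detrended Spearman correlation between the extracted and gold
#' range-through diversity series plus the count of accepted tuples. Rows
#' where a fraction leaves learning without both label classes are flagged
#' (`status = "no_evidence"`), not fatal.
#'
#' @param config a [pipeline_config()].
#' @param fractions seed-KB fractions to scan.
#' @param replicates replicate seed-KB draws per fraction.
#' @param table an `interval_table`.
#' @return a `training_curve` tibble: fraction, replicate, rho, p_value,
#'   tuple_count, status.
#' @export
training_size_curve <- function(config = pipeline_config(),
                                fractions = c(0.02, 0.1, 0.5, 1.0),
                                replicates = 5,
                                table = load_interval_table()) {
  stopifnot(length(fractions) > 0)
  wc <- config$world_config
  wc$rng_seed <- derive_seed(config$seed, 1L)
  world <- generate_world(wc, table)
  gold_div <- gold_diversity(world, table, config$min_rank)

  # the corpus, mentions, candidates and graph skeleton are identical across
  # the grid (the gazetteer vocabulary already covers every seed subset);
  # only supervision, learning, inference and assembly are rerun
  gaz <- build_gazetteers(world$gold_kb[0, ], world$vocab)
  mentions <- extract_mentions_corpus(world, gaz)
  candidates <- extract_features(generate_candidates(mentions), world)
  graph0 <- build_factor_graph(candidates, table)

  rows <- list()
  for (fi in seq_along(fractions)) {
    for (r in seq_len(replicates)) {
      sub_seed <- derive_seed(config$seed, 100L + fi * 17L + r)
      seed_kb <- with_seed(sub_seed,
                           split_seed_kb(world$gold_kb, fractions[fi]))$seed
      res <- tryCatch({
        labels <- with_seed(derive_seed(sub_seed, 3L),
                            distant_supervision_labels(graph0, seed_kb, table,
                                                       config$negative_rate))
        graph <- set_evidence(graph0, labels)
        fit <- learn_weights(graph, l2 = config$l2,
                             max_iter = config$max_iter,
                             rng_seed = derive_seed(sub_seed, 4L))
        marginals <- gibbs_marginals(graph, fit, n_samples = config$samples,
                                     burn_in = config$burn_in,
                                     rng_seed = derive_seed(sub_seed, 5L))
        accepted <- filter_by_probability(entity_tuples(graph, marginals),
                                          config$tau)
        occ <- resolution_filter(
          apply_taxonomy(assemble_occurrences(accepted, table),
                         resolve_taxonomy(accepted)),
          table, config$min_rank)
        div <- rangethrough_diversity(genus_ranges(occ, table),
                                      nrow(table$bins))
        keep <- gold_div$diversity + div$diversity > 0
        sp <- first_difference_spearman(
          ifelse(keep, div$diversity, NA),
          ifelse(keep, gold_div$diversity, NA))
        tibble(fraction = fractions[fi], replicate = r, rho = sp$rho,
               p_value = sp$p_value, tuple_count = nrow(accepted),
               status = if (is.na(sp$rho)) "degenerate" else "ok")
      }, error = function(e) {
        tibble(fraction = fractions[fi], replicate = r, rho = NA_real_,
               p_value = NA_real_, tuple_count = 0L,
               status = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("training_curve", class(out)))
}

#' Gold diversity series for a world
#'
#' Range-through diversity computed from the gold occurrence set through the
#' same binning and resolution filter as the machine output.
#'
#' @param world a `gold_world`.
#' @param table an `interval_table`.
#' @param min_rank resolution threshold.
#' @export
gold_diversity <- function(world, table, min_rank = "epoch") {
  occ <- gold_occurrences(world)
  occ$probability <- 1
  occ <- resolution_filter(occ, table, min_rank)
  ranges <- genus_ranges(occ, table)
  rangethrough_diversity(ranges, nrow(table$bins))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(paste0("<pipeline_run: %d docs -> %d mentions -> %d candidates -> ",
                     "%d tuples (%d accepted) -> %d occurrences, %d genera>\n"),
              cts$documents, cts$mentions, cts$candidates, cts$tuples,
              cts$accepted, cts$occurrences, cts$genera))
  if (!is.null(x$metrics)) {
    cat(sprintf("  precision %.3f, recall %.3f vs gold\n",
                x$metrics$precision, x$metrics$recall))
  }
  invisible(x)
}
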