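# internal helpers shared across modules

RANK_LEVELS <- c("eon", "era", "period", "epoch", "stage")

RELATIONS <- c("formation_age", "formation_location", "taxon_in_formation",
               "opinion_belongs", "opinion_synonym")

ENTITY_TYPES <- c("taxon", "formation", "interval", "location")

rank_index <- function(rank) match(rank, RANK_LEVELS)

assert_prob <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  what, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_relation <- function(relation) {
  bad <- setdiff(unique(relation), RELATIONS)
  if (length(bad) > 0) {
    abort(sprintf("unknown relation name(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(relation)
}

# deterministic sub-seed derivation, kept below 2^31 (double arithmetic:
# exact well past the products involved, and safe from integer overflow)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 12289) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
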