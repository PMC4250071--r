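#' Load a geologic interval table
#'
#' Reads a CSV of named geologic time intervals (columns `name`, `rank`,
#' `parent`, `t_old`, `t_young`; ages in Ma, old > young) into a validated
#' `interval_table` object holding both the interval hierarchy and an ordered
#' set of contiguous analysis bins.
#'
#' Validation enforces: unique names; known ranks (eon, era, period, epoch,
#' stage); exactly one root; every child's span inside its parent's; ranks
#' strictly refining along each parent chain; and no overlap between
#' same-rank children of the same parent (regional stages parented directly
#' to a period may overlap standard epochs of that period, as real regional
#' schemes do).
#'
#' Bins default to the spans of all intervals at `bin_rank`, ordered old to
#' young; they must tile a contiguous range with no gaps. An explicit bin
#' table (data frame or CSV path with columns `name`, `t_old`, `t_young`)
#' overrides the rank-derived bins, e.g. to use a custom set of analysis
#' intervals.
#'
#' A point age on a shared bin boundary belongs to the younger bin: bin
#' membership is the half-open age span (t_young, t_old], with age 0 assigned
#' to the youngest bin.
#'
#' @param path CSV path; defaults to the Phanerozoic table shipped with the
#'   package (ICS-style hierarchy down to stage).
#' @param bin_rank rank whose intervals become the analysis bins
#'   (default `"epoch"`).
#' @param bins optional explicit bin table (data frame or CSV path).
#' @return An `interval_table`: list with tibbles `intervals` and `bins`.
#' @examples
#' tab <- load_interval_table()
#' interval_contains(tab, "Carboniferous", "Namurian")
#' @export
load_interval_table <- function(path = NULL, bin_rank = "epoch", bins = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "intervals.csv", package = "paleomine")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), rank = readr::col_character(),
    parent = readr::col_character(), t_old = readr::col_double(),
    t_young = readr::col_double()
  ), progress = FALSE)
  required <- c("name", "rank", "parent", "t_old", "t_young")
  if (!all(required %in% names(raw))) {
    abort(sprintf("interval table must have columns %s",
                  paste(required, collapse = ", ")))
  }
  ints <- as_tibble(raw[required])
  ints$parent[!is.na(ints$parent) & ints$parent == ""] <- NA_character_
  validate_intervals(ints)

  if (is.null(bins)) {
    bins <- ints[ints$rank == bin_rank, c("name", "t_old", "t_young")]
  } else if (is.character(bins)) {
    bins <- readr::read_csv(bins, col_types = readr::cols(
      name = readr::col_character(), t_old = readr::col_double(),
      t_young = readr::col_double()
    ), progress = FALSE)
  }
  bins <- as_tibble(bins[, c("name", "t_old", "t_young")])
  bins <- bins[order(-bins$t_old), ]
  validate_bins(bins)
  bins <- tibble(bin = seq_len(nrow(bins)), bins)

  structure(list(intervals = ints, bins = bins), class = "interval_table")
}

validate_intervals <- function(ints) {
  eps <- 1e-9
  if (anyDuplicated(ints$name)) {
    abort(sprintf("duplicated interval names: %s",
                  paste(unique(ints$name[duplicated(ints$name)]), collapse = ", ")))
  }
  bad_rank <- setdiff(ints$rank, RANK_LEVELS)
  if (length(bad_rank) > 0) {
    abort(sprintf("unknown rank(s): %s", paste(bad_rank, collapse = ", ")))
  }
  if (any(ints$t_young < 0) || any(ints$t_old < ints$t_young)) {
    bad <- ints$name[ints$t_young < 0 | ints$t_old < ints$t_young]
    abort(sprintf("bad age spans (need t_old >= t_young >= 0): %s",
                  paste(bad, collapse = ", ")))
  }
  roots <- ints$name[is.na(ints$parent)]
  if (length(roots) != 1L) {
    abort(sprintf("expected exactly one root interval, found %d (%s)",
                  length(roots), paste(roots, collapse = ", ")))
  }
  known <- ints$parent %in% ints$name | is.na(ints$parent)
  if (!all(known)) {
    abort(sprintf("unknown parent(s): %s",
                  paste(unique(ints$parent[!known]), collapse = ", ")))
  }
  pi <- match(ints$parent, ints$name)
  has_parent <- !is.na(pi)
  contained <- ints$t_old[has_parent] <= ints$t_old[pi[has_parent]] + eps &
    ints$t_young[has_parent] >= ints$t_young[pi[has_parent]] - eps
  if (!all(contained)) {
    abort(sprintf("interval(s) extend beyond their parent span: %s",
                  paste(ints$name[has_parent][!contained], collapse = ", ")))
  }
  refine <- rank_index(ints$rank[has_parent]) > rank_index(ints$rank[pi[has_parent]])
  if (!all(refine)) {
    abort(sprintf("interval rank does not refine its parent's: %s",
                  paste(ints$name[has_parent][!refine], collapse = ", ")))
  }
  # same-parent, same-rank siblings must not overlap
  key <- paste(ints$parent, ints$rank)
  for (k in unique(key[has_parent])) {
    sib <- ints[key == k & has_parent, ]
    if (nrow(sib) < 2) next
    sib <- sib[order(-sib$t_old), ]
    gap <- sib$t_young[-nrow(sib)] - sib$t_old[-1]
    if (any(gap < -eps)) {
      i <- which(gap < -eps)[1]
      abort(sprintf("overlapping sibling intervals: %s and %s",
                    sib$name[i], sib$name[i + 1]))
    }
  }
  invisible(ints)
}

validate_bins <- function(bins) {
  eps <- 1e-9
  if (nrow(bins) == 0) abort("bin table is empty")
  if (any(bins$t_old <= bins$t_young)) {
    abort(sprintf("zero or negative-length bin(s): %s",
                  paste(bins$name[bins$t_old <= bins$t_young], collapse = ", ")))
  }
  if (nrow(bins) > 1) {
    gap <- abs(bins$t_young[-nrow(bins)] - bins$t_old[-1])
    if (any(gap > eps)) {
      i <- which(gap > eps)[1]
      abort(sprintf("bins are not contiguous between %s and %s",
                    bins$name[i], bins$name[i + 1]))
    }
  }
  invisible(bins)
}

interval_row <- function(table, name) {
  i <- match(name, table$intervals$name)
  if (anyNA(i)) {
    abort(sprintf("unknown interval name(s): %s",
                  paste(name[is.na(i)], collapse = ", ")))
  }
  i
}

#' Ancestor chain of an interval
#'
#' Interval names from `name` itself up to the root, in that order.
#'
#' @param table an `interval_table`.
#' @param name interval name.
#' @export
interval_ancestors <- function(table, name) {
  ints <- table$intervals
  out <- character()
  cur <- name
  interval_row(table, name)
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- ints$parent[match(cur, ints$name)]
  }
  out
}

#' Does interval `a` contain interval `b`?
#'
#' TRUE iff `b` equals `a` or is a descendant of `a` in the interval
#' hierarchy (so the Carboniferous contains the Namurian). Containment is by
#' the named hierarchy, not by age overlap.
#'
#' @inheritParams interval_ancestors
#' @param a,b interval names.
#' @return logical scalar.
#' @export
interval_contains <- function(table, a, b) {
  interval_row(table, c(a, b))
  a %in% interval_ancestors(table, b)
}

#' Midpoint age of an interval, in Ma
#'
#' @inheritParams interval_ancestors
#' @export
interval_midpoint <- function(table, name) {
  i <- interval_row(table, name)
  (table$intervals$t_old[i] + table$intervals$t_young[i]) / 2
}

#' Rank of an interval
#'
#' @inheritParams interval_ancestors
#' @export
interval_rank <- function(table, name) {
  table$intervals$rank[interval_row(table, name)]
}

# bin indices whose (t_young, t_old] span intersects the interval's
bins_overlapped <- function(table, name) {
  i <- interval_row(table, name)
  b <- table$bins
  which(table$intervals$t_old[i] > b$t_young & table$intervals$t_young[i] < b$t_old)
}

# bin owning a point age; shared boundaries go to the younger bin
bin_of_age <- function(table, age) {
  b <- table$bins
  hit <- which(age > b$t_young & age <= b$t_old)
  if (length(hit) == 0 && age == min(b$t_young)) hit <- nrow(b)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' @export
print.interval_table <- function(x, ...) {
  cat(sprintf("<interval_table: %d intervals, %d bins (%s to %s Ma)>\n",
              nrow(x$intervals), nrow(x$bins),
              format(max(x$bins$t_old)), format(min(x$bins$t_young))))
  invisible(x)
}
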