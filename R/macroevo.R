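# Range-based macroevolutionary statistics: genus ranges, range-through
# diversity, per-capita origination/extinction rates from boundary-crosser
# counts, range offsets between two databases, and detrended rank
# correlations.

#' Genus stratigraphic ranges from occurrences
#'
#' Maps each occurrence's interval onto the analysis bins it overlaps.
#' Occurrences whose interval spans more than one bin are dropped (their
#' count is kept in the `n_dropped` attribute); each genus's range is the
#' span from its oldest to youngest occupied bin, with first/last ages at
#' the bin midpoints in Ma. Genera should be re-keyed to senior names
#' ([apply_taxonomy()]) first.
#'
#' @param occurrences occurrence tibble (after [resolution_filter()]).
#' @param table an `interval_table`.
#' @return `genus_ranges` tibble: genus, first_bin, last_bin, first_age,
#'   last_age, n_occurrences.
#' @export
genus_ranges <- function(occurrences, table) {
  empty <- structure(
    tibble(genus = character(), first_bin = integer(), last_bin = integer(),
           first_age = numeric(), last_age = numeric(), n_occurrences = integer()),
    class = c("genus_ranges", "tbl_df", "tbl", "data.frame"), n_dropped = 0L)
  if (nrow(occurrences) == 0) return(empty)

  bins_per <- lapply(unique(occurrences$interval), bins_overlapped, table = table)
  names(bins_per) <- unique(occurrences$interval)
  n_bin <- lengths(bins_per)[occurrences$interval]
  dropped <- sum(n_bin != 1L)
  occ <- occurrences[n_bin == 1L, ]
  if (nrow(occ) == 0) {
    attr(empty, "n_dropped") <- dropped
    return(empty)
  }
  occ$bin <- vapply(bins_per[occ$interval], `[`, integer(1), 1)

  mid <- (table$bins$t_old + table$bins$t_young) / 2
  out <- dplyr::summarise(dplyr::group_by(occ, .data$genus),
                          first_bin = min(.data$bin), last_bin = max(.data$bin),
                          n_occurrences = dplyr::n(), .groups = "drop")
  out$first_age <- mid[out$first_bin]
  out$last_age <- mid[out$last_bin]
  out <- out[, c("genus", "first_bin", "last_bin", "first_age", "last_age",
                 "n_occurrences")]
  structure(out, class = c("genus_ranges", class(out)), n_dropped = dropped)
}

#' Range-through diversity per bin
#'
#' Diversity in bin i is the number of genera whose range covers i
#' (first_bin <= i <= last_bin): a genus is counted in every bin between
#' its first and last occurrence.
#'
#' @param ranges a `genus_ranges` tibble.
#' @param n_bins number of analysis bins.
#' @return tibble (`bin`, `diversity`).
#' @export
rangethrough_diversity <- function(ranges, n_bins) {
  div <- integer(n_bins)
  for (k in seq_len(nrow(ranges))) {
    span <- ranges$first_bin[k]:ranges$last_bin[k]
    div[span] <- div[span] + 1L
  }
  tibble(bin = seq_len(n_bins), diversity = div)
}

#' Per-capita origination and extinction rates from boundary crossers
#'
#' For each bin i, counts genera by how their ranges cross its boundaries:
#' `N_bt` (cross bottom and top), `N_bL` (cross bottom, end within), `N_Ft`
#' (start within, cross top), `N_FL` (confined singletons). With
#' `N_b = N_bt + N_bL` and `N_t = N_bt + N_Ft`, the per-capita per-interval
#' rates are `p = -ln(N_bt / N_t)` (origination) and `q = -ln(N_bt / N_b)`
#' (extinction); both are NA where `N_bt` or the denominator is 0.
#' Singletons contribute to diversity but to neither rate. `per_myr = TRUE`
#' divides both rates by the bin duration in Myr.
#'
#' @inheritParams rangethrough_diversity
#' @param per_myr divide rates by bin duration (needs `table`).
#' @param table an `interval_table` (only for `per_myr`).
#' @return `diversity_counts` tibble with the counts, range-through
#'   diversity, `p_rate` and `q_rate` per bin.
#' @export
foote_rates <- function(ranges, n_bins, per_myr = FALSE, table = NULL) {
  f <- ranges$first_bin; l <- ranges$last_bin
  count <- function(pred) vapply(seq_len(n_bins), function(i) sum(pred(i)), integer(1))
  N_bt <- count(function(i) f < i & l > i)
  N_bL <- count(function(i) f < i & l == i)
  N_Ft <- count(function(i) f == i & l > i)
  N_FL <- count(function(i) f == i & l == i)
  N_b <- N_bt + N_bL
  N_t <- N_bt + N_Ft
  p <- ifelse(N_bt > 0 & N_t > 0, -log(N_bt / N_t), NA_real_)
  q <- ifelse(N_bt > 0 & N_b > 0, -log(N_bt / N_b), NA_real_)
  if (per_myr) {
    if (is.null(table)) abort("per_myr rates need the interval table for durations")
    dur <- table$bins$t_old - table$bins$t_young
    p <- p / dur
    q <- q / dur
  }
  out <- tibble(bin = seq_len(n_bins), N_bt = N_bt, N_bL = N_bL, N_Ft = N_Ft,
                N_FL = N_FL, N_b = N_b, N_t = N_t,
                diversity = N_bt + N_bL + N_Ft + N_FL,
                p_rate = p, q_rate = q)
  structure(out, class = c("diversity_counts", class(out)))
}

#' Genus range offsets between two databases
#'
#' For genera present in both range sets, the first- and last-occurrence
#' offsets in Myr, computed from the bin-midpoint ages:
#' `offset = age_in_a - age_in_b` (positive first-offset means `a` places
#' the first occurrence earlier, i.e. at an older age in Ma; flip with
#' `sign = "b_minus_a"`).
#'
#' @param ranges_a,ranges_b `genus_ranges` tibbles (e.g. machine vs
#'   reference).
#' @param sign direction convention.
#' @return `range_offsets` tibble: genus, first_offset, last_offset (Myr).
#' @export
range_offsets <- function(ranges_a, ranges_b,
                          sign = c("a_minus_b", "b_minus_a")) {
  sign <- match.arg(sign)
  common <- dplyr::inner_join(ranges_a, ranges_b, by = "genus",
                              suffix = c("_a", "_b"))
  s <- if (sign == "a_minus_b") 1 else -1
  out <- tibble(
    genus = common$genus,
    first_offset = s * (common$first_age_a - common$first_age_b),
    last_offset = s * (common$last_age_a - common$last_age_b))
  structure(out, class = c("range_offsets", class(out)))
}

#' Detrended Spearman correlation of two time series
#'
#' First-differences both series over bins where both are defined, then
#' computes the Spearman rank correlation of the differences with the
#' asymptotic large-sample p-value. Detrending by first differences removes
#' the shared long-term trend so the correlation reflects
#' interval-to-interval changes.
#'
#' @param series_a,series_b numeric vectors aligned on the same bins (NA
#'   where undefined).
#' @return tibble (`rho`, `p_value`, `n`): `n` is the number of difference
#'   pairs used.
#' @export
first_difference_spearman <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  ok <- !is.na(series_a) & !is.na(series_b)
  da <- diff(series_a[ok])
  db <- diff(series_b[ok])
  if (length(da) < 3) abort("insufficient overlap: need at least 3 difference pairs")
  ct <- suppressWarnings(cor.test(da, db, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(da))
}
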