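# Taxonomic opinion resolution: nested placements (child belongs to parent)
# and synonymy (junior is a synonym of senior), resolved to a working
# taxonomy.

#' Resolve taxonomic opinions to a working taxonomy
#'
#' For each name, the governing opinion of each kind is the most recently
#' published one (ties: the majority object among tied opinions, then the
#' lexicographically smallest). Synonymy is resolved transitively so a name
#' maps to its ultimate senior name; synonym cycles are broken by dropping
#' the most recent cycle-closing opinion (recorded in the `dropped`
#' attribute, never fatal).
#'
#' @param opinions tibble of opinion tuples (`relation` in
#'   `opinion_belongs` / `opinion_synonym`, `subject`, `object`, optional
#'   `pub_year`).
#' @return tibble (`name`, `senior`, `parent`): `senior` is the resolved
#'   valid name (itself if not a junior synonym), `parent` the governing
#'   parent assignment, NA when none. Attribute `dropped` lists discarded
#'   cycle-closing opinions.
#' @export
resolve_taxonomy <- function(opinions) {
  op <- opinions[opinions$relation %in% c("opinion_belongs", "opinion_synonym"), ]
  if (!"pub_year" %in% names(op)) op$pub_year <- NA_integer_

  governing <- function(rel) {
    g <- op[op$relation == rel, ]
    if (nrow(g) == 0) {
      return(tibble(subject = character(), object = character()))
    }
    picked <- lapply(split(g, g$subject), function(s) {
      yr <- ifelse(is.na(s$pub_year), -Inf, s$pub_year)
      s <- s[yr == max(yr), ]
      cnt <- table(s$object)
      best <- names(cnt)[cnt == max(cnt)]
      tibble(subject = s$subject[1], object = sort(best)[1])
    })
    dplyr::bind_rows(picked)
  }

  syn <- governing("opinion_synonym")
  bel <- governing("opinion_belongs")

  # transitive senior resolution with deterministic cycle breaking
  dropped <- list()
  senior_of <- stats::setNames(syn$object, syn$subject)
  repeat {
    cyc <- find_cycle(senior_of)
    if (is.null(cyc)) break
    sub <- op[op$relation == "opinion_synonym" & op$subject %in% cyc, ]
    yr <- ifelse(is.na(sub$pub_year), -Inf, sub$pub_year)
    victim <- sub[order(-yr, sub$subject), ][1, ]
    dropped[[length(dropped) + 1L]] <- victim
    senior_of <- senior_of[names(senior_of) != victim$subject]
  }
  resolve1 <- function(nm) {
    seen <- character(0)
    while (nm %in% names(senior_of) && !(nm %in% seen)) {
      seen <- c(seen, nm)
      nm <- senior_of[[nm]]
    }
    nm
  }

  names_all <- sort(unique(c(op$subject, op$object)))
  senior <- vapply(names_all, resolve1, character(1))
  parent <- stats::setNames(bel$object, bel$subject)[names_all]
  out <- tibble(name = names_all, senior = unname(senior),
                parent = unname(parent))
  attr(out, "dropped") <- if (length(dropped) > 0) dplyr::bind_rows(dropped) else NULL
  out
}

# first cycle found in a functional graph given as a named vector, or NULL
find_cycle <- function(edge) {
  for (start in names(edge)) {
    seen <- character(0)
    nm <- start
    while (nm %in% names(edge)) {
      if (nm %in% seen) {
        cyc <- seen[which(seen == nm):length(seen)]
        return(cyc)
      }
      seen <- c(seen, nm)
      nm <- edge[[nm]]
    }
  }
  NULL
}

#' Re-key occurrence genera to their senior names
#'
#' @param occurrences occurrence tibble.
#' @param taxonomy result of [resolve_taxonomy()] (or NULL for identity).
#' @export
apply_taxonomy <- function(occurrences, taxonomy = NULL) {
  if (is.null(taxonomy) || nrow(occurrences) == 0) return(occurrences)
  i <- match(occurrences$genus, taxonomy$name)
  hit <- !is.na(i)
  occurrences$genus[hit] <- taxonomy$senior[i[hit]]
  occurrences
}
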