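#' Red List category vocabulary and ordinal ranks
#'
#' Ranked categories run LC < NT < VU < EN < CR < EW < EX (ranks 0-6).
#' DD (data deficient) and NE (not evaluated) carry no rank.
#'
#' @return character vector of the seven ranked categories in order.
#' @export
rl_categories <- function() c("LC", "NT", "VU", "EN", "CR", "EW", "EX")

#' Ordinal rank of Red List categories
#' @param cat character vector of category codes.
#' @return integer ranks 0-6; \code{NA} for DD/NE. Unknown codes are an error.
#' @export
rl_rank <- function(cat) {
  known <- c(rl_categories(), "DD", "NE")
  bad <- setdiff(unique(cat), known)
  if (length(bad)) stop("unknown category string: ", paste(bad, collapse = ", "))
  r <- match(cat, rl_categories()) - 1L
  r
}

#' Filter a species catalogue to the analysable set
#'
#' Excludes species not evaluated, data deficient at either date, and those
#' already extinct (EX, and by default EW) at the start of the period.
#'
#' @param catalogue data.frame with columns \code{species_id},
#'   \code{cat_start}, \code{cat_end}.
#' @param exclude_ew_start treat species starting at EW as already extinct
#'   (documented toggle; the source methods exclude "already extinct" species
#'   without naming EW).
#' @return list with \code{retained} (the analysis set) and \code{excluded}
#'   (species_id + reason).
#' @export
filter_species <- function(catalogue, exclude_ew_start = TRUE) {
  stopifnot(all(c("species_id", "cat_start", "cat_end") %in% names(catalogue)))
  if (anyDuplicated(catalogue$species_id))
    stop("duplicate species_id in catalogue")
  rs <- rl_rank(catalogue$cat_start)
  re <- rl_rank(catalogue$cat_end)
  reason <- rep(NA_character_, nrow(catalogue))
  ne <- catalogue$cat_start == "NE" | catalogue$cat_end == "NE"
  dd <- catalogue$cat_start == "DD" | catalogue$cat_end == "DD"
  ext <- !is.na(rs) &
    (catalogue$cat_start == "EX" |
       (exclude_ew_start & catalogue$cat_start == "EW"))
  reason[dd] <- "data deficient"
  reason[ne] <- "not evaluated"
  reason[ext & is.na(reason)] <- "extinct at start"
  keep <- is.na(reason)
  list(retained = catalogue[keep, , drop = FALSE],
       excluded = data.frame(species_id = catalogue$species_id[!keep],
                             reason = reason[!keep]))
}

#' Classify a Red List category pair as a low- or high-risk transition
#'
#' Low-risk: LC retained, or any downlisting (rank decreased). High-risk:
#' any uplisting (rank increased), or a non-LC category retained (threatened
#' or near-threatened species keeping their category imply continued decline).
#' Total and mutually exclusive over all ranked pairs.
#'
#' @param cat_start,cat_end ranked category codes (vectors recycle).
#' @return character vector, \code{"low-risk"} or \code{"high-risk"}.
#' @export
classify_transition <- function(cat_start, cat_end) {
  rs <- rl_rank(cat_start)
  re <- rl_rank(cat_end)
  if (anyNA(rs) || anyNA(re)) stop("unranked category in transition input")
  ifelse(re > rs | (re == rs & rs > 0L), "high-risk", "low-risk")
}

#' Classify a category pair as uplisted or not
#'
#' Uplisted means the species moved to a higher (worse) category; retaining a
#' category or improving it is not-uplisted.
#'
#' @inheritParams classify_transition
#' @return character vector, \code{"uplisted"} or \code{"not-uplisted"}.
#' @export
classify_uplisting <- function(cat_start, cat_end) {
  rs <- rl_rank(cat_start)
  re <- rl_rank(cat_end)
  if (anyNA(rs) || anyNA(re)) stop("unranked category in transition input")
  ifelse(re > rs, "uplisted", "not-uplisted")
}

#' Label every species in an analysis set
#'
#' @param histories data.frame with \code{species_id}, \code{cat_start},
#'   \code{cat_end} (already filtered to ranked pairs).
#' @return data.frame with \code{species_id}, \code{risk_class},
#'   \code{uplist_class}.
#' @export
classify_species <- function(histories) {
  data.frame(species_id = histories$species_id,
             risk_class = classify_transition(histories$cat_start,
                                              histories$cat_end),
             uplist_class = classify_uplisting(histories$cat_start,
                                               histories$cat_end))
}

#' Tabulate category transitions and headline shares
#'
#' @param histories filtered analysis set (\code{species_id},
#'   \code{cat_start}, \code{cat_end}).
#' @return list with \code{matrix} (7 x 7 counts, rows = initial category) and
#'   \code{shares}: percentages (of the analysis set) of low-risk, high-risk,
#'   uplisted, downlisted and threatened/NT-retained species, plus \code{n}.
#' @export
tabulate_transitions <- function(histories) {
  if (!nrow(histories)) stop("empty analysis set")
  cats <- rl_categories()
  rs <- rl_rank(histories$cat_start)
  re <- rl_rank(histories$cat_end)
  if (anyNA(rs) || anyNA(re)) stop("unranked category in analysis set")
  m <- table(factor(histories$cat_start, cats), factor(histories$cat_end, cats))
  m <- matrix(as.integer(m), 7, 7, dimnames = list(initial = cats, final = cats))
  n <- nrow(histories)
  risk <- classify_transition(histories$cat_start, histories$cat_end)
  pct <- function(x) 100 * sum(x) / n
  shares <- c(low_risk = pct(risk == "low-risk"),
              high_risk = pct(risk == "high-risk"),
              uplisted = pct(re > rs),
              downlisted = pct(re < rs),
              threatened_retained = pct(re == rs & rs > 0L),
              lc_retained = pct(re == rs & rs == 0L))
  list(matrix = m, shares = shares, n = n)
}
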