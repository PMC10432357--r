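## Post-episode annotation: COVID-19 status, analysis cohorts 1/2/3,
## pandemic-era strata, ongoing-pregnancy flag, and the held-out-concept
## overlap QC.

#' COVID-19 status of one episode
#'
#' Positivity is the first in-episode occurrence of either a positive
#' PCR/antigen lab result or a COVID-19 diagnosis code; screening is any
#' in-episode PCR/Ag test regardless of result; reinfection is any later
#' in-episode positive at least 60 days after the index infection date.
#'
#' @param events event table (any person; filtered internally).
#' @param episode one-row episode (needs `person_id`, `start_date` or
#'   `inferred_start_date`, `end_date`).
#' @param registry a `concept_registry` with COVID concept sets.
#' @param positive_values lab values counted as positive
#'   (case-insensitive; default "positive", "detected").
#' @return list `(covid_positive, covid_index_date, covid_screened,
#'   reinfection)`.
#' @export
covid_status <- function(events, episode, registry,
                         positive_values = c("positive", "detected")) {
  ev <- as.data.table(events)
  s <- .as_date(episode$start_date %||% episode$inferred_start_date)
  if (is.null(episode$start_date) || is.na(s)) s <- .as_date(episode$inferred_start_date)
  e <- .as_date(episode$end_date)
  sub <- ev[person_id == episode$person_id & event_date >= s & event_date <= e]
  tests <- sub[concept_id %in% registry$covid$pcr_ag_test]
  dx <- sub[concept_id %in% registry$covid$covid_diagnosis]
  pos_dates <- sort(unique(c(
    tests$event_date[tolower(tests$value) %in% tolower(positive_values)],
    dx$event_date)))
  index <- if (length(pos_dates)) pos_dates[1] else as.Date(NA)
  reinf <- length(pos_dates) > 1 &&
    any(.days(pos_dates[-1], index) >= 60)
  list(covid_positive = length(pos_dates) > 0,
       covid_index_date = index,
       covid_screened = nrow(tests) > 0,
       reinfection = isTRUE(reinf))
}

#' Assign analysis cohorts and pandemic-era stratum
#'
#' Cohort 1: all episodes. Cohort 2: episodes with an outcome other than a
#' bare delivery record and month-level-or-better start-date precision
#' (week, week_poor-support, two-week, three-week, month). Cohort 3:
#' episodes with such an outcome, concordance score 2, and week-level
#' precision. The stratum keys on the episode end date versus 2020-03-01
#' and, after that date, on in-episode COVID-19 positivity.
#'
#' @param episode one-row episode (needs `outcome_category`,
#'   `precision_category`, `concordance_score`, `end_date`).
#' @param covid_positive logical from [covid_status()].
#' @return list `(cohort1, cohort2, cohort3, stratum)`.
#' @export
assign_cohorts <- function(episode, covid_positive = FALSE) {
  cat <- episode$outcome_category
  has_outcome <- !is.na(cat) && !cat %in% c("NONE", "DELIVERY_ONLY")
  prec <- episode$precision_category
  month_level <- prec %in% c("week", "week_poor-support", "two-week",
                             "three-week", "month")
  score <- episode$concordance_score
  cohort2 <- has_outcome && month_level
  cohort3 <- has_outcome && !is.na(score) && score == 2L && prec == "week"
  stratum <- if (.as_date(episode$end_date) < as.Date("2020-03-01")) {
    "pre_2020-03-01"
  } else if (isTRUE(covid_positive)) "covid_pos_post" else "covid_neg_post"
  list(cohort1 = TRUE, cohort2 = cohort2, cohort3 = cohort3, stratum = stratum)
}

#' Flag a likely ongoing pregnancy
#'
#' An outcome-less episode is ongoing when, as of the given date, it has not
#' yet reached the minimum plausible gestational length of a delivery
#' outcome (the smaller of the live-birth and stillbirth term-window
#' minima, 140 days by default).
#'
#' @param episode one-row episode (needs `outcome_category` and an inferred
#'   start in `inferred_start_date` or `start_date`).
#' @param as_of reference date.
#' @param config a [hierarchy_config()].
#' @return logical; FALSE whenever an outcome is present.
#' @export
flag_ongoing <- function(episode, as_of, config = hierarchy_config()) {
  cat <- episode$outcome_category
  if (!is.na(cat) && cat != "NONE") return(FALSE)
  s <- episode$inferred_start_date %||% episode$start_date
  s <- .as_date(s)
  if (is.na(s)) s <- .as_date(episode$start_date)
  min_delivery <- min(config$term_windows$LIVE_BIRTH[1],
                      config$term_windows$STILLBIRTH[1])
  .days(.as_date(as_of), s) < min_delivery
}

#' Held-out concept overlap QC
#'
#' For each held-out validation concept (expected gestational window 4-10
#' months, never used for inference), the percentage of its occurrences
#' that fall inside some episode of the same person AND whose offset in
#' months from that episode's inferred start lies inside the concept's
#' expected window. Concepts with zero occurrences are omitted.
#'
#' @param events event table.
#' @param episodes final episode table (needs `person_id`, a start in
#'   `inferred_start_date` (falling back to `start_date`), `end_date`).
#' @param registry a `concept_registry`.
#' @return `data.table(concept_id, n_total, n_overlap, overlap_pct)`.
#' @export
heldout_overlap <- function(events, episodes, registry) {
  ev <- as.data.table(events)
  eps <- as.data.table(episodes)
  dpm <- registry$hierarchy$days_per_month
  held <- registry$timing[usage == "HELD_OUT"]
  if ("inferred_start_date" %in% names(eps)) {
    st <- eps$inferred_start_date
    st[is.na(st)] <- eps$start_date[is.na(st)]
  } else {
    st <- eps$start_date
  }
  eps$.start <- st
  rows <- vector("list", 0)
  for (r in seq_len(nrow(held))) {
    occ <- ev[concept_id == held$concept_id[r]]
    if (!nrow(occ)) next
    n_ok <- 0L
    for (k in seq_len(nrow(occ))) {
      sub <- eps[person_id == occ$person_id[k] &
                   occ$event_date[k] >= .start & occ$event_date[k] <= end_date]
      if (nrow(sub)) {
        off <- .days(occ$event_date[k], sub$.start) / dpm
        if (any(off >= held$min_month[r] & off <= held$max_month[r])) {
          n_ok <- n_ok + 1L
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.table(
      concept_id = held$concept_id[r], n_total = nrow(occ), n_overlap = n_ok,
      overlap_pct = 100 * n_ok / nrow(occ))
  }
  if (length(rows)) rbindlist(rows) else
    data.table(concept_id = integer(), n_total = integer(),
               n_overlap = integer(), overlap_pct = numeric())
}

#' Annotate every episode of a pipeline result
#'
#' @param episodes final episode table.
#' @param events event table.
#' @param registry a `concept_registry`.
#' @param as_of reference date for the ongoing flag (default: latest event).
#' @return `data.table` joinable on `episode_id` with COVID status, cohort
#'   flags, stratum, and the ongoing flag.
#' @export
annotate_episodes <- function(episodes, events, registry,
                              as_of = max(as.data.table(events)$event_date)) {
  eps <- as.data.table(episodes)
  rows <- vector("list", nrow(eps))
  for (r in seq_len(nrow(eps))) {
    ep <- eps[r]
    ## structural span for in-episode checks
    ep_span <- list(person_id = ep$person_id,
                    start_date = if (!is.null(ep$start_date)) ep$start_date else ep$inferred_start_date,
                    end_date = ep$end_date,
                    inferred_start_date = ep$inferred_start_date)
    cv <- covid_status(events, ep_span, registry)
    ch <- assign_cohorts(ep, cv$covid_positive)
    rows[[r]] <- data.table(
      episode_id = ep$episode_id,
      covid_positive = cv$covid_positive,
      covid_index_date = cv$covid_index_date,
      covid_screened = cv$covid_screened,
      reinfection = cv$reinfection,
      stratum = ch$stratum,
      cohort1 = ch$cohort1, cohort2 = ch$cohort2, cohort3 = ch$cohort3,
      ongoing = flag_ongoing(ep, as_of, registry$hierarchy))
  }
  if (length(rows)) rbindlist(rows) else
    data.table(episode_id = character(), covid_positive = logical(),
               covid_index_date = as.Date(character()),
               covid_screened = logical(), reinfection = logical(),
               stratum = character(), cohort1 = logical(),
               cohort2 = logical(), cohort3 = logical(), ongoing = logical())
}
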