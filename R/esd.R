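## ESD: Estimated Start Date.
## Fuses week-level (GW) point evidence and ranged (GR3m) interval evidence
## within an episode into an inferred LMP with a precision category, plus
## the no-filtering baseline comparator.

.precision_levels <- c("week", "week_poor-support", "two-week", "three-week",
                       "month", "two-months", "three-months", "non-specific")

#' Precision category ladder
#'
#' Maps the width in days of the plausible start-date window to a category:
#' `week` (<= 7), `two-week` (7-14], `three-week` (14-21], `month` (21-28],
#' `two-months` (28-56], `three-months` (56-84], `non-specific` (> 84 or no
#' timing information). A window supported by a single GW record is
#' `week_poor-support` regardless of width.
#'
#' @param window_days window width in days, or NA/NULL for no information.
#' @param n_gw number of retained GW records supporting the window.
#' @return category string.
#' @export
precision_category <- function(window_days, n_gw = 0L) {
  if (is.null(window_days) || length(window_days) == 0 || is.na(window_days)) {
    return("non-specific")
  }
  if (window_days < 0) stop("window_days must be non-negative")
  if (!is.na(n_gw) && n_gw == 1L) return("week_poor-support")
  if (window_days <= 7) "week"
  else if (window_days <= 14) "two-week"
  else if (window_days <= 21) "three-week"
  else if (window_days <= 28) "month"
  else if (window_days <= 56) "two-months"
  else if (window_days <= 84) "three-months"
  else "non-specific"
}

#' Rank of a precision category (1 = finest)
#' @param category character vector of precision categories.
#' @return integer ranks.
#' @export
precision_rank <- function(category) {
  match(category, .precision_levels)
}

#' Collect start-date evidence within one episode
#'
#' GW records are deduplicated per calendar date keeping the maximum week,
#' then back-projected (`derived_start = record_date - 7 * week`). Each GR3m
#' record yields a plausible start interval
#' `[record_date - max_month * dpm, record_date - min_month * dpm]`.
#'
#' @param episode_events events restricted to one episode's span.
#' @param registry a `concept_registry`.
#' @param days_per_month day length of a gestational month.
#' @return object of class `start_evidence`: list with `gw`
#'   (`record_date, week, derived_start`) and `gr3m`
#'   (`record_date, lower, upper`).
#' @export
collect_evidence <- function(episode_events, registry,
                             days_per_month = registry$hierarchy$days_per_month) {
  ev <- as.data.table(episode_events)
  gw <- gw_events(ev, registry)
  if (nrow(gw)) {
    gw <- gw[, .(week = max(week)), by = .(record_date = event_date)]
    gw$derived_start <- gw$record_date - 7L * gw$week
    setorder(gw, record_date)
  } else {
    gw <- data.table(record_date = as.Date(character()), week = integer(),
                     derived_start = as.Date(character()))
  }
  gr <- registry$timing[usage == "GR3m", .(concept_id, min_month, max_month)]
  g3 <- merge(ev[, .(concept_id, event_date)], gr, by = "concept_id")
  if (nrow(g3)) {
    g3 <- data.table(record_date = g3$event_date,
                     lower = g3$event_date - round(g3$max_month * days_per_month),
                     upper = g3$event_date - round(g3$min_month * days_per_month))
    setorder(g3, record_date)
  } else {
    g3 <- data.table(record_date = as.Date(character()),
                     lower = as.Date(character()), upper = as.Date(character()))
  }
  structure(list(gw = gw, gr3m = g3), class = "start_evidence")
}

## intersection of all GR3m intervals; NULL when no GR3m or when intervals
## conflict (empty intersection -> ranged evidence discarded for filtering)
.gr3m_intersection <- function(evidence) {
  g3 <- evidence$gr3m
  if (!nrow(g3)) return(NULL)
  lo <- max(g3$lower); hi <- min(g3$upper)
  if (lo > hi) return(NULL)
  c(lo, hi)
}

#' Remove outlier GW evidence
#'
#' A GW candidate is removed when its derived start lies outside the
#' intersection of all GR3m start intervals AND outside the Tukey fences
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the GW derived starts (quartiles by
#' linear interpolation, quantile type 7). With no usable GR3m evidence
#' (none present, or conflicting intervals with empty intersection) only
#' the IQR condition applies. With fewer than 3 GW candidates the IQR
#' condition never removes. `conjunctive = FALSE` switches to the
#' disjunctive reading (either condition suffices) for sensitivity
#' analysis.
#'
#' @param evidence a `start_evidence`.
#' @param conjunctive require both conditions to reject (default TRUE).
#' @return filtered `start_evidence`; removed rows in `attr(x, "removed")`.
#' @export
filter_outliers <- function(evidence, conjunctive = TRUE) {
  gw <- evidence$gw
  n <- nrow(gw)
  if (!n) {
    attr(evidence, "removed") <- gw
    return(evidence)
  }
  inter <- .gr3m_intersection(evidence)
  ds <- as.numeric(gw$derived_start)
  if (n >= 3) {
    q <- quantile(ds, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out_iqr <- ds < q[1] - 1.5 * iqr | ds > q[2] + 1.5 * iqr
  } else {
    out_iqr <- rep(FALSE, n)
  }
  if (is.null(inter)) {
    remove <- out_iqr
  } else {
    out_int <- gw$derived_start < inter[1] | gw$derived_start > inter[2]
    remove <- if (conjunctive) out_int & out_iqr else out_int | out_iqr
  }
  res <- structure(list(gw = gw[!remove], gr3m = evidence$gr3m),
                   class = "start_evidence")
  attr(res, "removed") <- gw[remove]
  res
}

#' Estimate the start date (LMP) from filtered evidence
#'
#' The inferred start is the derived start of the retained GW record with
#' the latest record date (late-pregnancy GW records are empirically the
#' most precise). The plausible window is the range of retained GW derived
#' starts when two or more are retained; with a single GW record the
#' estimate is point-valued (`week_poor-support`); with only ranged
#' evidence the window is the GR3m intersection and no point start is
#' assigned; with no timing evidence the result is `non-specific`.
#'
#' @param evidence a (typically filtered) `start_evidence`.
#' @return object of class `start_estimate`: list with `start_date`,
#'   `window` (Date pair or NULL), `precision_days`, `precision_category`,
#'   `n_gw_retained`, `n_gr3m`.
#' @export
estimate_start <- function(evidence) {
  gw <- evidence$gw
  n_gw <- nrow(gw)
  n_g3 <- nrow(evidence$gr3m)
  if (n_gw >= 1) {
    start <- gw$derived_start[which.max(as.numeric(gw$record_date))]
    window <- range(gw$derived_start)
    width <- .days(window[2], window[1])
  } else {
    inter <- .gr3m_intersection(evidence)
    if (!is.null(inter)) {
      start <- as.Date(NA)
      window <- inter
      width <- .days(window[2], window[1])
    } else {
      return(structure(list(start_date = as.Date(NA), window = NULL,
                            precision_days = NA_integer_,
                            precision_category = "non-specific",
                            n_gw_retained = 0L, n_gr3m = n_g3),
                       class = "start_estimate"))
    }
  }
  structure(list(start_date = start, window = window,
                 precision_days = as.integer(width),
                 precision_category = precision_category(width, n_gw),
                 n_gw_retained = n_gw, n_gr3m = n_g3),
            class = "start_estimate")
}

#' Baseline start-date estimator
#'
#' Uses every GW candidate within the episode without outlier removal and
#' without ranged evidence; precision is assigned from the maximum pairwise
#' difference of the GW derived starts. The comparator against which the
#' filtering gain of [estimate_start()] is measured.
#'
#' @param evidence a `start_evidence` as collected (unfiltered).
#' @return a `start_estimate`.
#' @export
baseline_start <- function(evidence) {
  ev <- structure(list(gw = evidence$gw,
                       gr3m = evidence$gr3m[0]), class = "start_evidence")
  estimate_start(ev)
}

#' Run ESD for every episode of an episode table
#'
#' @param episodes episode table with `person_id`, `start_date`, `end_date`.
#' @param events full event table (subset per episode span internally).
#' @param registry a `concept_registry`.
#' @param conjunctive outlier-filter mode, see [filter_outliers()].
#' @return `data.table` keyed like `episodes` with columns
#'   `inferred_start_date`, `window_low`, `window_high`, `precision_days`,
#'   `precision_category`, `n_gw_retained`, `n_gr3m`, plus the baseline's
#'   `baseline_precision_category` and `baseline_precision_days`.
#' @export
esd_estimates <- function(episodes, events, registry, conjunctive = TRUE) {
  eps <- as.data.table(episodes)
  ev <- as.data.table(events)
  if (!nrow(eps)) {
    eps$inferred_start_date <- as.Date(character())
    eps$window_low <- as.Date(character())
    eps$window_high <- as.Date(character())
    eps$precision_days <- integer()
    eps$precision_category <- character()
    eps$n_gw_retained <- integer()
    eps$n_gr3m <- integer()
    eps$baseline_precision_category <- character()
    eps$baseline_precision_days <- integer()
    return(eps)
  }
  out <- vector("list", nrow(eps))
  for (r in seq_len(nrow(eps))) {
    sub <- ev[person_id == eps$person_id[r] &
                event_date >= eps$start_date[r] &
                event_date <= eps$end_date[r]]
    evd <- collect_evidence(sub, registry)
    est <- estimate_start(filter_outliers(evd, conjunctive = conjunctive))
    base <- baseline_start(evd)
    out[[r]] <- data.table(
      inferred_start_date = est$start_date,
      window_low = if (is.null(est$window)) as.Date(NA) else est$window[1],
      window_high = if (is.null(est$window)) as.Date(NA) else est$window[2],
      precision_days = est$precision_days,
      precision_category = est$precision_category,
      n_gw_retained = est$n_gw_retained,
      n_gr3m = est$n_gr3m,
      baseline_precision_category = base$precision_category,
      baseline_precision_days = base$precision_days)
  }
  cbind(eps, rbindlist(out))
}
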