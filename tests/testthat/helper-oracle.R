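## Independent exhaustive oracle for progression-episode building.
## Enumerates every assignment of events (in date order) to
## {extend current episode, start new episode, unassigned noise}, keeping
## only assignments that satisfy the compatibility and retry predicates,
## and returns the set of valid complete segmentations. Implemented by
## direct recursion with its own compatibility arithmetic -- no shared code
## with build_progressions().

oracle_compat <- function(a_date, a_min, a_max, b_date, b_min, b_max, dpm) {
  delta <- as.numeric(b_date) - as.numeric(a_date)
  delta >= max(0, b_min - a_max) * dpm && delta <= (b_max - a_min) * dpm
}

## events: data.frame(event_date, min_month, max_month) sorted by date.
## Returns list of valid segmentations; each is a list(assign = integer
## vector (episode number per event, 0 = noise)).
oracle_segmentations <- function(events, retry_days, dpm) {
  n <- nrow(events)
  results <- list()
  recurse <- function(i, assign, n_ep) {
    if (i > n) {
      results[[length(results) + 1L]] <<- assign
      return(invisible())
    }
    cur_members <- which(assign == n_ep)
    if (n_ep == 0L) {
      recurse(i + 1L, { a <- assign; a[i] <- 1L; a }, 1L)
      return(invisible())
    }
    compat <- any(vapply(cur_members, function(m) {
      oracle_compat(events$event_date[m], events$min_month[m], events$max_month[m],
                    events$event_date[i], events$min_month[i], events$max_month[i],
                    dpm)
    }, logical(1)))
    gap <- as.numeric(events$event_date[i]) - as.numeric(events$event_date[i - 1L])
    if (compat) {
      recurse(i + 1L, { a <- assign; a[i] <- n_ep; a }, n_ep)
    } else if (gap >= retry_days) {
      recurse(i + 1L, { a <- assign; a[i] <- n_ep + 1L; a }, n_ep + 1L)
    } else {
      recurse(i + 1L, { a <- assign; a[i] <- 0L; a }, n_ep)
    }
  }
  recurse(1L, integer(n), 0L)
  results
}

## random per-person instance generator for oracle comparison
random_instance <- function(n_events, windows = NULL) {
  if (is.null(windows)) {
    mins <- round(runif(n_events, 0.5, 8), 2)
    spans <- round(runif(n_events, 0.4, 2.5), 2)
    windows <- cbind(mins, pmin(mins + spans, 10))
  }
  data.frame(
    event_date = as.Date("2019-01-01") + sort(sample(0:600, n_events, replace = TRUE)),
    min_month = windows[, 1], max_month = windows[, 2])
}
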