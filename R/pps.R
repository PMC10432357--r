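## PPS: Pregnancy Progression Signature.
## Builds episodes from gestationally timed "progression" concepts by
## temporal compatibility (an adaptation of longest-increasing-consecutive-
## subsequence scanning), cleans up implausible episodes, and attaches
## outcomes by hierarchy within a bounded search window.

#' Extract progression events with their expected gestational windows
#' @param events event table.
#' @param registry a `concept_registry` (usage `"PROGRESSION"` concepts).
#' @return `data.table(person_id, event_date, concept_id, min_month,
#'   max_month)` sorted by person, date, concept.
#' @export
progression_events <- function(events, registry) {
  ev <- as.data.table(events)
  prog <- registry$timing[usage == "PROGRESSION",
                          .(concept_id, min_month, max_month)]
  out <- merge(ev[, .(person_id, concept_id, event_date)], prog,
               by = "concept_id")
  out <- out[, .(person_id, event_date, concept_id, min_month, max_month)]
  setorder(out, person_id, event_date, concept_id)
  out[]
}

#' Temporal compatibility of two timed concepts
#'
#' Events `a` (earlier) and `b` (later) are compatible when the elapsed days
#' between them can be explained by their expected gestational windows:
#' `b.date - a.date` must lie within
#' `[max(0, b.min_month - a.max_month), b.max_month - a.min_month] *
#' days_per_month` (bounds inclusive).
#'
#' @param a,b lists or one-row data.frames with `event_date`, `min_month`,
#'   `max_month`; `a$event_date <= b$event_date`.
#' @param days_per_month day length of a gestational month.
#' @return logical.
#' @export
pair_compatible <- function(a, b, days_per_month = 365.25 / 12) {
  delta <- .days(.as_date(b$event_date), .as_date(a$event_date))
  lo <- max(0, b$min_month - a$max_month) * days_per_month
  hi <- (b$max_month - a$min_month) * days_per_month
  delta >= lo & delta <= hi
}

## vectorized compatibility of one later event b against earlier events
.compat_any <- function(dates, mins, maxs, bd, bmin, bmax, dpm) {
  delta <- as.numeric(bd) - as.numeric(dates)
  lo <- pmax(0, bmin - maxs) * dpm
  hi <- (bmax - mins) * dpm
  any(delta >= lo & delta <= hi)
}

#' Build progression episodes by a single temporal-compatibility scan
#'
#' Events are scanned in date order per person. An event extends the current
#' episode if at least one compatibility comparison against the episode's
#' members is TRUE. If every comparison is FALSE, a new episode starts only
#' when the gap from the immediately preceding scanned event is at least the
#' retry period (60 days by default); otherwise the event is held out as
#' unassigned noise (`attr(x, "unassigned")`).
#'
#' @param events progression events from [progression_events()].
#' @param config a [hierarchy_config()].
#' @return `data.table(person_id, episode_idx, first_event_date,
#'   last_event_date, n_events, last_min_month)` plus a `members` attribute
#'   mapping events to episodes.
#' @export
build_progressions <- function(events, config = hierarchy_config()) {
  pe <- as.data.table(events)
  dpm <- config$days_per_month
  retry <- config$retry_days
  eps <- vector("list", 0)
  members <- vector("list", 0)
  unassigned <- vector("list", 0)
  if (nrow(pe)) {
    setorder(pe, person_id, event_date, concept_id)
    for (pid in unique(pe$person_id)) {
      sub <- pe[person_id == pid]
      ep_idx <- 0L
      cur <- integer(0)  # row indices of current episode members
      prev_date <- as.Date(NA)
      flush <- function() {
        if (!length(cur)) return()
        eps[[length(eps) + 1L]] <<- data.table(
          person_id = pid, episode_idx = ep_idx,
          first_event_date = sub$event_date[cur[1]],
          last_event_date = sub$event_date[cur[length(cur)]],
          n_events = length(cur),
          last_min_month = sub$min_month[cur[length(cur)]])
        members[[length(members) + 1L]] <<- data.table(
          person_id = pid, episode_idx = ep_idx,
          event_date = sub$event_date[cur], concept_id = sub$concept_id[cur])
      }
      for (r in seq_len(nrow(sub))) {
        if (!length(cur)) {
          ep_idx <- ep_idx + 1L
          cur <- r
        } else {
          ok <- .compat_any(sub$event_date[cur], sub$min_month[cur],
                            sub$max_month[cur], sub$event_date[r],
                            sub$min_month[r], sub$max_month[r], dpm)
          if (ok) {
            cur <- c(cur, r)
          } else if (.days(sub$event_date[r], prev_date) >= retry) {
            flush()
            ep_idx <- ep_idx + 1L
            cur <- r
          } else {
            unassigned[[length(unassigned) + 1L]] <- data.table(
              person_id = pid, event_date = sub$event_date[r],
              concept_id = sub$concept_id[r], reason = "incompatible_within_retry")
          }
        }
        prev_date <- sub$event_date[r]
      }
      flush()
    }
  }
  res <- if (length(eps)) rbindlist(eps) else
    data.table(person_id = character(), episode_idx = integer(),
               first_event_date = as.Date(character()),
               last_event_date = as.Date(character()),
               n_events = integer(), last_min_month = numeric())
  attr(res, "members") <- if (length(members)) rbindlist(members) else
    data.table(person_id = character(), episode_idx = integer(),
               event_date = as.Date(character()), concept_id = integer())
  attr(res, "unassigned") <- if (length(unassigned)) rbindlist(unassigned) else
    data.table(person_id = character(), event_date = as.Date(character()),
               concept_id = integer(), reason = character())
  res
}

#' PPS cleanup: drop implausibly long episodes and hyper-frequent persons
#'
#' Removes episodes whose recorded length (last minus first event date)
#' exceeds `max_episode_months`, then removes all episodes of any person
#' with more than `max_episodes_per_year` episode starts inside any sliding
#' 365-day window.
#'
#' @param episodes output of [build_progressions()].
#' @param config a [hierarchy_config()].
#' @return filtered episode table (attributes preserved and filtered).
#' @export
pps_cleanup <- function(episodes, config = hierarchy_config()) {
  eps <- as.data.table(episodes)
  members <- attr(episodes, "members")
  if (!nrow(eps)) return(episodes)
  max_len <- config$max_episode_months * config$days_per_month
  len <- .days(eps$last_event_date, eps$first_event_date)
  eps <- eps[len <= max_len]
  ## sliding 365-day window over episode start dates
  drop_pid <- character(0)
  mx <- config$max_episodes_per_year
  for (pid in unique(eps$person_id)) {
    s <- sort(as.numeric(eps$first_event_date[eps$person_id == pid]))
    if (length(s) > mx && any(s[seq_len(length(s) - mx) + mx] - s[seq_len(length(s) - mx)] <= 364)) {
      drop_pid <- c(drop_pid, pid)
    }
  }
  eps <- eps[!person_id %in% drop_pid]
  if (!is.null(members)) {
    members <- merge(members, eps[, .(person_id, episode_idx)],
                     by = c("person_id", "episode_idx"))
    attr(eps, "members") <- members
  }
  attr(eps, "unassigned") <- attr(episodes, "unassigned")
  eps
}

#' Attach an outcome to one PPS episode
#'
#' Searches for outcome events from 14 days before the episode's last
#' record up to the earlier of (1) the next episode's start date and
#' (2) `last_event_date + (10 - last event's expected minimum month) *
#' days_per_month`. Among in-window outcomes the category is selected by
#' hierarchy priority (earliest date within the winning category).
#'
#' @param episode one-row episode (needs `last_event_date`,
#'   `last_min_month`, `person_id`).
#' @param outcomes outcome events of the same person
#'   (`person_id, event_date, category`).
#' @param next_episode_start optional date capping the search window.
#' @param config a [hierarchy_config()].
#' @return list with `outcome_category` (`"NONE"` when no outcome is found)
#'   and `outcome_date` (NA when none).
#' @export
attach_outcome <- function(episode, outcomes, next_episode_start = NULL,
                           config = hierarchy_config()) {
  last_date <- .as_date(episode$last_event_date)
  win_start <- last_date - 14L
  win_end <- last_date + round((10 - episode$last_min_month) * config$days_per_month)
  if (!is.null(next_episode_start) && !is.na(next_episode_start)) {
    win_end <- min(win_end, .as_date(next_episode_start))
  }
  oc <- as.data.table(outcomes)
  if (nrow(oc)) {
    oc <- oc[person_id == episode$person_id &
               event_date >= win_start & event_date <= win_end]
  }
  if (!nrow(oc)) {
    return(list(outcome_category = "NONE", outcome_date = as.Date(NA)))
  }
  oc$rank_ <- outcome_priority(oc$category)
  best <- oc[rank_ == min(rank_)]
  list(outcome_category = best$category[1],
       outcome_date = min(best$event_date))
}

#' Run the full PPS stage
#'
#' Build, clean up, and attach outcomes; the search window of each episode
#' is capped by the next retained episode's first event date.
#'
#' @param events event table.
#' @param registry a `concept_registry`.
#' @param config a [hierarchy_config()] (defaults to the registry's).
#' @return `data.table(person_id, episode_idx, first_event_date,
#'   last_event_date, n_events, outcome_category, outcome_date, end_date)`
#'   where `end_date` is the outcome date when attached, else the last
#'   event date.
#' @export
pps_episodes <- function(events, registry, config = registry$hierarchy) {
  pe <- progression_events(events, registry)
  eps <- pps_cleanup(build_progressions(pe, config), config)
  oc <- outcome_events(events, registry)
  if (!nrow(eps)) {
    eps$outcome_category <- character(0)
    eps$outcome_date <- as.Date(character(0))
    eps$end_date <- as.Date(character(0))
    return(eps)
  }
  setorder(eps, person_id, first_event_date)
  cats <- character(nrow(eps)); dates <- as.Date(rep(NA, nrow(eps)))
  for (r in seq_len(nrow(eps))) {
    nxt <- if (r < nrow(eps) && eps$person_id[r + 1] == eps$person_id[r]) {
      eps$first_event_date[r + 1]
    } else NULL
    att <- attach_outcome(eps[r], oc[person_id == eps$person_id[r]], nxt, config)
    cats[r] <- att$outcome_category
    dates[r] <- att$outcome_date
  }
  eps$outcome_category <- cats
  eps$outcome_date <- dates
  end <- eps$last_event_date
  later <- !is.na(dates) & dates > end
  end[later] <- dates[later]
  eps$end_date <- end
  eps[]
}
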