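## HIP: Hierarchy-based Inference of Pregnancy.
## Outcome-based episodes from an outcome hierarchy with minimum-separation
## rules, gestation-based episodes from "Gestation period, X weeks" records
## with back-projection, and their merge.

#' Extract outcome events from an event table
#' @param events event table.
#' @param registry a `concept_registry`.
#' @return `data.table(person_id, event_date, category)` sorted by person
#'   and date.
#' @export
outcome_events <- function(events, registry) {
  ev <- as.data.table(events)
  out <- merge(ev[, .(person_id, concept_id, event_date)],
               registry$outcomes[, .(concept_id, category)],
               by = "concept_id")
  out <- out[, .(person_id, event_date, category)]
  setorder(out, person_id, event_date, category)
  out[]
}

#' Extract week-level gestational age events
#' @param events event table.
#' @param registry a `concept_registry`; week is taken from the registry GW
#'   map, falling back to [parse_gestation_week()] on the concept name.
#' @return `data.table(person_id, event_date, week)` sorted by person, date,
#'   week.
#' @export
gw_events <- function(events, registry) {
  ev <- as.data.table(events)
  wk <- registry$gestation_weeks$week[match(ev$concept_id,
                                            registry$gestation_weeks$concept_id)]
  miss <- is.na(wk) & !is.na(ev$concept_name)
  if (any(miss)) wk[miss] <- parse_gestation_week(ev$concept_name[miss])
  out <- ev[!is.na(wk), .(person_id, event_date)]
  out$week <- as.integer(wk[!is.na(wk)])
  setorder(out, person_id, event_date, week)
  out[]
}

#' Outcome assessment and classification
#'
#' Processes outcome events category by category in hierarchy priority
#' order. Within a category, a date-ordered greedy scan retains events
#' separated by at least the same-category minimum (live birth 182 days,
#' stillbirth 168 days by default). Each surviving event is then checked
#' against every already-retained higher-priority event: an event of
#' category `a` occurring after a retained event of category `b` must be at
#' least `min_separation_days[a, b]` days later, and one occurring before
#' must precede it by at least `min_separation_days[b, a]` days. Dropped
#' events are recorded in `attr(result, "audit")`.
#'
#' Idempotent: re-running on its own output returns it unchanged.
#'
#' @param outcomes `data.table(person_id, event_date, category)`.
#' @param config a [hierarchy_config()].
#' @return retained outcome events, sorted by person and date.
#' @export
assess_outcomes <- function(outcomes, config = hierarchy_config()) {
  oc <- as.data.table(outcomes)
  if (!nrow(oc)) {
    res <- oc
    attr(res, "audit") <- oc
    return(res)
  }
  M <- config$min_separation_days
  kept_all <- vector("list", 0)
  audit <- vector("list", 0)
  for (pid in unique(oc$person_id)) {
    sub <- oc[person_id == pid]
    retained <- sub[0]
    for (cat in config$priority) {
      evs <- sub[category == cat]
      if (!nrow(evs)) next
      setorder(evs, event_date)
      ## same-category greedy spacing
      keep_idx <- integer(0)
      last_date <- as.Date(NA)
      for (r in seq_len(nrow(evs))) {
        d <- evs$event_date[r]
        if (length(keep_idx) == 0 || .days(d, last_date) >= M[cat, cat]) {
          keep_idx <- c(keep_idx, r)
          last_date <- d
        } else {
          audit[[length(audit) + 1L]] <- data.table(
            person_id = pid, event_date = d, category = cat,
            reason = "same_category_separation")
        }
      }
      evs <- evs[keep_idx]
      ## cross-category spacing against retained higher-priority events
      for (r in seq_len(nrow(evs))) {
        d <- evs$event_date[r]
        ok <- TRUE
        if (nrow(retained)) {
          for (h in seq_len(nrow(retained))) {
            hd <- retained$event_date[h]; hc <- retained$category[h]
            gap <- .days(d, hd)
            need <- if (gap >= 0) M[cat, hc] else M[hc, cat]
            if (abs(gap) < need) { ok <- FALSE; break }
          }
        }
        if (ok) {
          retained <- rbind(retained, evs[r])
        } else {
          audit[[length(audit) + 1L]] <- data.table(
            person_id = pid, event_date = d, category = cat,
            reason = "cross_category_separation")
        }
      }
    }
    kept_all[[length(kept_all) + 1L]] <- retained
  }
  res <- rbindlist(kept_all)
  if (nrow(res)) setorder(res, person_id, event_date, category)
  attr(res, "audit") <- if (length(audit)) rbindlist(audit) else
    data.table(person_id = character(), event_date = as.Date(character()),
               category = character(), reason = character())
  res
}

#' Delineate gestation-based draft episodes from GW records
#'
#' Walks each person's date-ordered GW records. A record whose week is less
#' than or equal to the previous accepted record's week marks a potential
#' new episode; the split is accepted only if the record's projected start
#' (`date - 7 * week`) does not fall inside the span of the current draft
#' (from its back-projected start to its last record date). Records failing
#' that check are excluded from delineation entirely as noise (so a stale
#' historical record cannot corrupt back-projection). Each draft's
#' `derived_start` is back-projected from its maximum week (ties broken by
#' the latest record date).
#'
#' @param gw `data.table(person_id, event_date, week)` as from [gw_events()].
#' @return `data.table(person_id, derived_start, first_gw_date,
#'   last_gw_date, max_week, n_gw)`; noise records in `attr(x, "noise")`.
#' @export
infer_gestation_episodes <- function(gw) {
  gw <- as.data.table(gw)
  drafts <- vector("list", 0)
  noise <- vector("list", 0)
  if (nrow(gw)) {
    setorder(gw, person_id, event_date, week)
    for (pid in unique(gw$person_id)) {
      sub <- gw[person_id == pid]
      cur_dates <- as.Date(character()); cur_weeks <- integer()
      flush <- function() {
        if (!length(cur_dates)) return(NULL)
        mw <- max(cur_weeks)
        anchor <- max(cur_dates[cur_weeks == mw])
        data.table(person_id = pid, derived_start = anchor - 7L * mw,
                   first_gw_date = min(cur_dates), last_gw_date = max(cur_dates),
                   max_week = mw, n_gw = length(cur_dates))
      }
      for (r in seq_len(nrow(sub))) {
        d <- sub$event_date[r]; w <- sub$week[r]
        if (!length(cur_dates)) {
          cur_dates <- d; cur_weeks <- w
        } else if (w > cur_weeks[length(cur_weeks)]) {
          cur_dates <- c(cur_dates, d); cur_weeks <- c(cur_weeks, w)
        } else {
          proj <- d - 7L * w
          mw <- max(cur_weeks)
          ds <- max(cur_dates[cur_weeks == mw]) - 7L * mw
          if (proj >= ds && proj <= max(cur_dates)) {
            noise[[length(noise) + 1L]] <- data.table(
              person_id = pid, event_date = d, week = w,
              reason = "projected_start_overlaps_previous_episode")
          } else {
            drafts[[length(drafts) + 1L]] <- flush()
            cur_dates <- d; cur_weeks <- w
          }
        }
      }
      drafts[[length(drafts) + 1L]] <- flush()
    }
  }
  res <- if (length(drafts)) rbindlist(drafts) else
    data.table(person_id = character(), derived_start = as.Date(character()),
               first_gw_date = as.Date(character()),
               last_gw_date = as.Date(character()),
               max_week = integer(), n_gw = integer())
  attr(res, "noise") <- if (length(noise)) rbindlist(noise) else
    data.table(person_id = character(), event_date = as.Date(character()),
               week = integer(), reason = character())
  res
}

#' Merge outcome-based and gestation-based episodes (HIP)
#'
#' An outcome pairs with the latest-starting unused draft whose plausible
#' extent `[derived_start, derived_start + term_max(category)]` contains the
#' outcome date. A paired outcome is kept only if the draft's maximum
#' gestational age (`7 * max_week` days) falls inside the outcome's expected
#' term-duration window; otherwise the outcome is a misclassification and is
#' stripped, leaving the draft as a gestation-only episode. Outcomes with no
#' overlapping draft become outcome-only episodes with
#' `start = outcome_date - term_max(category)`. Finally, overlapping
#' episodes of a person are resolved deterministically by clipping the later
#' start to the day after the previous end (degenerate episodes dropped).
#'
#' @param outcome_seq retained outcomes from [assess_outcomes()].
#' @param gestation_drafts drafts from [infer_gestation_episodes()].
#' @param config a [hierarchy_config()].
#' @return `data.table(person_id, start_date, end_date, outcome_category,
#'   outcome_date, basis, max_week, recorded_start_date)`; stripped outcomes
#'   in `attr(x, "audit")`.
#' @export
merge_hip <- function(outcome_seq, gestation_drafts, config = hierarchy_config()) {
  oc <- as.data.table(outcome_seq)
  gd <- as.data.table(gestation_drafts)
  eps <- vector("list", 0)
  audit <- vector("list", 0)
  pids <- unique(c(oc$person_id, gd$person_id))
  for (pid in pids) {
    osub <- oc[person_id == pid]
    gsub <- gd[person_id == pid]
    used <- rep(FALSE, nrow(gsub))
    if (nrow(osub)) setorder(osub, event_date)
    for (r in seq_len(nrow(osub))) {
      od <- osub$event_date[r]; cat <- osub$category[r]
      tw <- term_window(config, cat)
      cand <- which(!used &
                      gsub$derived_start <= od &
                      od <= gsub$derived_start + tw[2])
      if (length(cand)) {
        g <- cand[which.max(as.numeric(gsub$derived_start[cand]))]
        ga_days <- 7L * gsub$max_week[g]
        if (ga_days >= tw[1] && ga_days <= tw[2]) {
          used[g] <- TRUE
          eps[[length(eps) + 1L]] <- data.table(
            person_id = pid, start_date = gsub$derived_start[g],
            end_date = od, outcome_category = cat, outcome_date = od,
            basis = "merged", max_week = gsub$max_week[g],
            recorded_start_date = gsub$first_gw_date[g])
        } else {
          audit[[length(audit) + 1L]] <- data.table(
            person_id = pid, event_date = od, category = cat,
            reason = "outcome_misaligned_with_gestational_age")
        }
      } else {
        eps[[length(eps) + 1L]] <- data.table(
          person_id = pid, start_date = od - as.integer(tw[2]),
          end_date = od, outcome_category = cat, outcome_date = od,
          basis = "outcome_only", max_week = NA_integer_,
          recorded_start_date = od)
      }
    }
    for (g in which(!used)) {
      eps[[length(eps) + 1L]] <- data.table(
        person_id = pid, start_date = gsub$derived_start[g],
        end_date = gsub$last_gw_date[g], outcome_category = "NONE",
        outcome_date = as.Date(NA), basis = "gestation_only",
        max_week = gsub$max_week[g],
        recorded_start_date = gsub$first_gw_date[g])
    }
  }
  res <- if (length(eps)) rbindlist(eps) else
    data.table(person_id = character(), start_date = as.Date(character()),
               end_date = as.Date(character()), outcome_category = character(),
               outcome_date = as.Date(character()), basis = character(),
               max_week = integer(), recorded_start_date = as.Date(character()))
  res <- .clip_overlaps(res)
  attr(res, "audit") <- if (length(audit)) rbindlist(audit) else
    data.table(person_id = character(), event_date = as.Date(character()),
               category = character(), reason = character())
  res
}

## deterministic per-person overlap resolution: sort by start (then end),
## clip a start that falls inside the previous episode to prev end + 1 day;
## drop episodes that become degenerate (start >= end)
.clip_overlaps <- function(eps) {
  if (!nrow(eps)) return(eps)
  setorder(eps, person_id, start_date, end_date)
  keep <- rep(TRUE, nrow(eps))
  prev_end <- as.Date(NA); prev_pid <- ""
  for (r in seq_len(nrow(eps))) {
    if (eps$person_id[r] != prev_pid) {
      prev_pid <- eps$person_id[r]; prev_end <- as.Date(NA)
    }
    if (!is.na(prev_end) && eps$start_date[r] <= prev_end) {
      new_start <- prev_end + 1L
      if (new_start >= eps$end_date[r]) { keep[r] <- FALSE; next }
      data.table::set(eps, i = r, j = "start_date", value = new_start)
    }
    prev_end <- eps$end_date[r]
  }
  eps[keep]
}

#' Run the full HIP stage
#' @param events event table.
#' @param registry a `concept_registry`.
#' @param config a [hierarchy_config()] (defaults to the registry's).
#' @return HIP episode table as from [merge_hip()].
#' @export
hip_episodes <- function(events, registry, config = registry$hierarchy) {
  oc <- assess_outcomes(outcome_events(events, registry), config)
  gd <- infer_gestation_episodes(gw_events(events, registry))
  merge_hip(oc, gd, config)
}
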