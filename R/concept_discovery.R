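## Data-driven concept discovery: enrichment of pregnancy-specific concepts
## (person-level presence in possibly-pregnant cases vs controls) and
## gestational-timing statistics relative to HIP episode starts.

#' Concept enrichment among case persons versus controls
#'
#' Person-level presence (not event counts) defines the rates, so the
#' result is invariant to event duplication within a person. Concepts absent
#' in controls get infinite fold and are kept whenever the case-person
#' threshold is met.
#'
#' @param events event table.
#' @param case_ids,control_ids disjoint, nonempty person id sets.
#' @param min_persons minimum case persons carrying the concept (default 1000).
#' @param min_fold minimum case/control rate ratio (default 10).
#' @return `data.table` with columns concept_id, n_case_persons, case_rate,
#'   control_rate, fold, restricted to concepts passing both thresholds,
#'   sorted by decreasing fold.
#' @export
enrich_concepts <- function(events, case_ids, control_ids,
                            min_persons = 1000L, min_fold = 10) {
  case_ids <- unique(as.character(case_ids))
  control_ids <- unique(as.character(control_ids))
  if (!length(case_ids) || !length(control_ids)) {
    stop("case and control id sets must be nonempty")
  }
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control id sets must be disjoint")
  }
  ev <- as.data.table(events)
  pres <- unique(ev[, .(person_id, concept_id)])
  n_case <- pres[person_id %in% case_ids, .(n_case_persons = .N), by = concept_id]
  n_ctrl <- pres[person_id %in% control_ids, .(n_ctrl = .N), by = concept_id]
  res <- merge(n_case, n_ctrl, by = "concept_id", all.x = TRUE)
  res[is.na(res$n_ctrl), "n_ctrl"] <- 0L
  res$case_rate <- res$n_case_persons / length(case_ids)
  res$control_rate <- res$n_ctrl / length(control_ids)
  res$fold <- ifelse(res$control_rate == 0, Inf, res$case_rate / res$control_rate)
  res <- res[n_case_persons >= min_persons & fold >= min_fold,
             .(concept_id, n_case_persons, case_rate, control_rate, fold)]
  setorder(res, -fold, concept_id)
  res[]
}

#' Timing statistics of concepts relative to HIP episode starts
#'
#' For every concept with events falling inside a HIP episode that carries a
#' pregnancy outcome, computes the mean and sample (n-1) standard deviation
#' of the offset `(event_date - episode_start) / days_per_month` in months.
#' Concepts with `sd < max_sd_months` (and at least 2 in-episode
#' observations) are flagged as gestational-timing candidates; a clinician
#' then assigns each candidate an expected min/max month window, and windows
#' spanning more than 3 months are rejected on registry import.
#'
#' @param events event table.
#' @param hip_episodes HIP episodes (needs person_id, start_date, end_date,
#'   outcome_category); only episodes with an outcome are used.
#' @param registry a `concept_registry` (outcome and GW concepts are not
#'   themselves timing candidates and are excluded from the result).
#' @param max_sd_months candidate threshold on the sd (default 1.5).
#' @return `data.table` with columns concept_id, mean_offset_months,
#'   sd_offset_months, n_observations, is_candidate.
#' @export
timing_statistics <- function(events, hip_episodes, registry,
                              max_sd_months = 1.5) {
  ev <- as.data.table(events)
  eps <- as.data.table(hip_episodes)
  eps <- eps[!is.na(outcome_category) & outcome_category != "NONE"]
  if (!nrow(eps) || !nrow(ev)) {
    return(data.table(concept_id = integer(), mean_offset_months = numeric(),
                      sd_offset_months = numeric(), n_observations = integer(),
                      is_candidate = logical()))
  }
  dpm <- registry$hierarchy$days_per_month
  skip <- c(registry$outcomes$concept_id, registry$gestation_weeks$concept_id)
  ev <- ev[!concept_id %in% skip]
  hit <- merge(ev[, .(person_id, concept_id, event_date)],
               eps[, .(person_id, start_date, end_date)],
               by = "person_id", allow.cartesian = TRUE)
  hit <- hit[event_date >= start_date & event_date <= end_date]
  if (!nrow(hit)) {
    return(data.table(concept_id = integer(), mean_offset_months = numeric(),
                      sd_offset_months = numeric(), n_observations = integer(),
                      is_candidate = logical()))
  }
  hit$offset_months <- .days(hit$event_date, hit$start_date) / dpm
  res <- hit[, .(mean_offset_months = mean(offset_months),
                 sd_offset_months = sd(offset_months),
                 n_observations = .N), by = concept_id]
  res$is_candidate <- !is.na(res$sd_offset_months) &
    res$sd_offset_months < max_sd_months
  setorder(res, concept_id)
  res[]
}

#' Emit a clinician curation template for timing candidates
#'
#' Writes the timing candidates with empty `min_month` / `max_month` columns
#' for clinician vetting; the edited file can be imported as the registry's
#' timing table (spans over 3 months are rejected by registry validation).
#' @param stats output of [timing_statistics()].
#' @param path output CSV path.
#' @export
write_curation_template <- function(stats, path) {
  st <- as.data.table(stats)[is_candidate == TRUE]
  out <- data.table(concept_id = st$concept_id,
                    mean_offset_months = round(st$mean_offset_months, 2),
                    sd_offset_months = round(st$sd_offset_months, 2),
                    n_observations = st$n_observations,
                    min_month = NA_real_, max_month = NA_real_,
                    usage = "PROGRESSION")
  fwrite(out, path)
  invisible(path)
}
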