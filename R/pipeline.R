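## Pipeline orchestration: candidate filter -> HIP -> PPS -> merge -> ESD
## -> concordance -> annotation, as a library call and as a file-based run.

#' Run the full inference pipeline in memory
#'
#' Stages, in order: candidate-person filter (female, 15-55 at first
#' event), HIP (outcome hierarchy + gestation-based episodes), PPS
#' (progression-signature episodes with outcome attachment), episode merge
#' with support flags, ESD start-date estimation (and baseline comparator),
#' outcome concordance scoring, and episode annotation.
#'
#' @param events normalized event table ([read_events()] / [bind_events()]
#'   or `sim$events`).
#' @param persons person table; NULL skips the candidate filter.
#' @param registry a `concept_registry`.
#' @param config a [hierarchy_config()] (defaults to the registry's).
#' @param conjunctive ESD outlier-filter mode, see [filter_outliers()].
#' @param as_of reference date for the ongoing flag (default: latest event).
#' @return list with `episodes` (final table), `annotations`,
#'   `heldout_overlap`, `hip`, `pps`, and `audit` (dropped/noise records per
#'   stage).
#' @export
hipps_pipeline <- function(events, persons = NULL, registry = example_registry(),
                           config = registry$hierarchy, conjunctive = TRUE,
                           as_of = NULL) {
  validate_registry(registry)
  ev <- as.data.table(events)
  setorder(ev, person_id, event_date, concept_id)
  candidate_report <- NULL
  if (!is.null(persons)) {
    ids <- filter_candidates(persons, events = ev)
    candidate_report <- attr(ids, "report")
    ev <- ev[person_id %in% ids]
  }
  if (is.null(as_of)) as_of <- if (nrow(ev)) max(ev$event_date) else Sys.Date()

  oc_raw <- outcome_events(ev, registry)
  oc <- assess_outcomes(oc_raw, config)
  gd <- infer_gestation_episodes(gw_events(ev, registry))
  hip <- merge_hip(oc, gd, config)
  pps <- pps_episodes(ev, registry, config)
  merged <- resolve_overlaps(hip, pps)

  est <- esd_estimates(merged, ev, registry, conjunctive = conjunctive)
  n <- nrow(est)
  final_start <- est$inferred_start_date
  fallback <- is.na(final_start)
  final_start[fallback] <- est$start_date[fallback]

  score <- integer(n); final_cat <- character(n)
  final_date <- as.Date(rep(NA, n))
  for (r in seq_len(n)) {
    prelim <- concordance(
      list(category = est$hip_outcome_category[r], date = est$hip_outcome_date[r]),
      list(category = est$pps_outcome_category[r], date = est$pps_outcome_date[r]),
      NA, config)
    ga <- if (!is.na(prelim$outcome_date) && !is.na(final_start[r])) {
      .days(prelim$outcome_date, final_start[r])
    } else NA
    cc <- concordance(
      list(category = est$hip_outcome_category[r], date = est$hip_outcome_date[r]),
      list(category = est$pps_outcome_category[r], date = est$pps_outcome_date[r]),
      ga, config)
    score[r] <- cc$score
    final_cat[r] <- cc$outcome_category
    final_date[r] <- cc$outcome_date
  }

  end_date <- est$end_date
  upd <- !is.na(final_date) & final_date > end_date
  end_date[upd] <- final_date[upd]

  episodes <- data.table(
    person_id = est$person_id,
    episode_id = character(n),
    inferred_start_date = final_start,
    recorded_start_date = est$recorded_start_date,
    end_date = end_date,
    outcome_category = final_cat,
    outcome_date = final_date,
    hip_flag = est$hip_flag,
    pps_flag = est$pps_flag,
    concordance_score = score,
    precision_category = est$precision_category,
    precision_days = est$precision_days,
    max_week = est$max_week,
    recorded_length_days = .days(end_date, est$recorded_start_date),
    inferred_length_days = ifelse(is.na(final_date), NA_integer_,
                                  .days(final_date, final_start)),
    baseline_precision_category = est$baseline_precision_category,
    baseline_precision_days = est$baseline_precision_days,
    n_gw_retained = est$n_gw_retained,
    n_gr3m = est$n_gr3m,
    structural_start_date = est$start_date
  )
  ## final non-overlap guarantee: corrupted evidence can back-project an
  ## episode's estimated start into the preceding episode; clip it to the
  ## day after the preceding episode ends
  setorder(episodes, person_id, inferred_start_date, end_date)
  prev_pid <- ""; prev_end <- as.Date(NA)
  for (r in seq_len(nrow(episodes))) {
    if (episodes$person_id[r] != prev_pid) {
      prev_pid <- episodes$person_id[r]; prev_end <- as.Date(NA)
    }
    if (!is.na(prev_end) && episodes$inferred_start_date[r] <= prev_end &&
        prev_end + 1L < episodes$end_date[r]) {
      data.table::set(episodes, i = r, j = "inferred_start_date",
                      value = prev_end + 1L)
      data.table::set(episodes, i = r, j = "inferred_length_days",
                      value = if (is.na(episodes$outcome_date[r])) NA_integer_ else
                        .days(episodes$outcome_date[r], prev_end + 1L))
    }
    prev_end <- episodes$end_date[r]
  }
  setorder(episodes, person_id, inferred_start_date, end_date)
  episodes$episode_id <- paste0(episodes$person_id, "_E",
                                ave(seq_len(n), episodes$person_id, FUN = seq_along))

  annotations <- annotate_episodes(episodes, ev, registry, as_of = as_of)
  ho <- heldout_overlap(ev, episodes, registry)

  list(episodes = episodes[],
       annotations = annotations,
       heldout_overlap = ho,
       hip = hip, pps = pps,
       audit = list(candidates = candidate_report,
                    outcomes_dropped = attr(oc, "audit"),
                    gw_noise = attr(gd, "noise"),
                    outcomes_stripped = attr(hip, "audit")))
}

#' File-based pipeline run
#'
#' Reads OMOP-lite CSV tables from `input_dir` (persons.csv plus any of
#' condition/procedure/observation/measurement/drug `_occurrence.csv`),
#' loads and validates the registry before any stage runs, executes the
#' selected stages, and writes `episodes.csv`, `annotations.csv`,
#' `heldout_overlap.csv`, audit CSVs and a deterministic `manifest.json`
#' (no timestamps, so identical inputs give byte-identical outputs).
#'
#' @param input_dir directory of input CSVs.
#' @param registry_path registry JSON path; NULL uses [example_registry()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of c("hip", "pps", "merge", "esd", "annotate");
#'   later stages imply earlier ones.
#' @param conjunctive ESD outlier-filter mode.
#' @return invisibly, the in-memory result list.
#' @export
run_pipeline <- function(input_dir, registry_path = NULL, out_dir,
                         stages = c("hip", "pps", "merge", "esd", "annotate"),
                         conjunctive = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  registry <- if (is.null(registry_path)) example_registry() else load_registry(registry_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  person_path <- file.path(input_dir, "persons.csv")
  persons <- if (file.exists(person_path)) read_persons(person_path) else NULL
  evs <- list()
  for (dom in names(.table_specs)) {
    f <- file.path(input_dir, sprintf("%s_occurrence.csv", dom))
    if (file.exists(f)) evs[[dom]] <- read_events(f, dom)
  }
  if (!length(evs)) stop("no input event tables found under ", input_dir)
  events <- do.call(bind_events, evs)

  full <- any(c("merge", "esd", "annotate") %in% stages)
  if (full) {
    res <- hipps_pipeline(events, persons, registry, conjunctive = conjunctive)
    write_episode_table(res$episodes, file.path(out_dir, "episodes.csv"))
    fwrite(res$annotations, file.path(out_dir, "annotations.csv"))
    fwrite(res$heldout_overlap, file.path(out_dir, "heldout_overlap.csv"))
    fwrite(res$hip, file.path(out_dir, "hip_episodes.csv"))
    fwrite(res$pps, file.path(out_dir, "pps_episodes.csv"))
    fwrite(res$audit$outcomes_dropped, file.path(out_dir, "audit_outcomes_dropped.csv"))
    fwrite(res$audit$gw_noise, file.path(out_dir, "audit_gw_noise.csv"))
  } else {
    res <- list()
    if ("hip" %in% stages) {
      res$hip <- hip_episodes(events, registry)
      fwrite(res$hip, file.path(out_dir, "hip_episodes.csv"))
    }
    if ("pps" %in% stages) {
      res$pps <- pps_episodes(events, registry)
      fwrite(res$pps, file.path(out_dir, "pps_episodes.csv"))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("hipps")),
    stages = stages,
    registry = if (is.null(registry_path)) "builtin:example_registry" else basename(registry_path),
    n_events = nrow(events),
    n_persons = if (is.null(persons)) NA else nrow(persons),
    days_per_month = registry$hierarchy$days_per_month,
    retry_days = registry$hierarchy$retry_days
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
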