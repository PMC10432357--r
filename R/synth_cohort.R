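## Synthetic OMOP-lite cohort generator with known ground-truth pregnancies.
## Emulates the statistical structure the inference stages assume: week-level
## gestational age records emitted on a prenatal visit schedule, gestationally
## timed concepts drawn inside their expected windows, outcome records at the
## outcome date, and configurable noise/missingness applied by corrupt_events().

#' Simulation configuration
#'
#' @param n_persons number of simulated persons (all female, reproductive age).
#' @param pregnancies_per_person named probability vector over pregnancy
#'   counts, e.g. `c("1" = 0.8, "2" = 0.2)`.
#' @param outcome_mix named probability vector over
#'   [outcome_categories()] plus `"NONE"` (pregnancy whose outcome is never
#'   coded); must sum to 1.
#' @param visit_schedule gestational weeks at which "Gestation period, X
#'   weeks" records are emitted (only weeks reached before the outcome are
#'   emitted). Default `c(8, 12, 16, 20, 24, 28, 32, 36)`, a typical
#'   prenatal-visit cadence.
#' @param p_missing_outcome probability the outcome record is not emitted
#'   (ground truth keeps the outcome).
#' @param p_missing_gw per-record GW dropout probability (applied by
#'   [corrupt_events()]).
#' @param p_outlier_gw per-record probability of inserting an erroneous GW
#'   record whose back-projected start deviates from truth by more than 28
#'   days (applied by [corrupt_events()]).
#' @param p_duplicate_outcome probability of emitting a duplicate outcome
#'   record 0-3 days after the true one.
#' @param p_historical per-record probability of inserting a historical copy
#'   of a held-out validation concept, dated before the person's first
#'   pregnancy (applied by [corrupt_events()]).
#' @param covid_positive_rate probability a pregnancy's COVID-19 test (one
#'   PCR/Ag event per pregnancy) is positive; positives also receive a
#'   same-day diagnosis event.
#' @param random_seed mandatory integer seed; the full simulation is
#'   reproducible from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 500L,
                       pregnancies_per_person = c("1" = 0.8, "2" = 0.2),
                       outcome_mix = c(LIVE_BIRTH = 0.60, STILLBIRTH = 0.04,
                                       ECTOPIC = 0.04, SPONTANEOUS_ABORTION = 0.12,
                                       INDUCED_ABORTION = 0.08, DELIVERY_ONLY = 0.04,
                                       NONE = 0.08),
                       visit_schedule = c(8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L),
                       p_missing_outcome = 0,
                       p_missing_gw = 0,
                       p_outlier_gw = 0,
                       p_duplicate_outcome = 0,
                       p_historical = 0,
                       covid_positive_rate = 0.1,
                       random_seed) {
  if (missing(random_seed) || is.null(random_seed)) stop("random_seed is mandatory")
  if (abs(sum(outcome_mix) - 1) > 1e-8) stop("outcome_mix must sum to 1")
  if (abs(sum(pregnancies_per_person) - 1) > 1e-8) {
    stop("pregnancies_per_person must sum to 1")
  }
  bad <- setdiff(names(outcome_mix), c(outcome_categories(), "NONE"))
  if (length(bad)) stop("unknown outcome_mix category: ", paste(bad, collapse = ", "))
  probs <- c(p_missing_outcome, p_missing_gw, p_outlier_gw, p_duplicate_outcome,
             p_historical, covid_positive_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(
    n_persons = as.integer(n_persons),
    pregnancies_per_person = pregnancies_per_person,
    outcome_mix = outcome_mix,
    visit_schedule = sort(as.integer(visit_schedule)),
    p_missing_outcome = p_missing_outcome,
    p_missing_gw = p_missing_gw,
    p_outlier_gw = p_outlier_gw,
    p_duplicate_outcome = p_duplicate_outcome,
    p_historical = p_historical,
    covid_positive_rate = covid_positive_rate,
    random_seed = as.integer(random_seed)
  ), class = "sim_config")
}

## gestational length draw (days): discretized truncated normal per outcome.
## Live-birth-like outcomes mode 273 days (39 weeks).
.draw_gest_length <- function(category, config_windows) {
  pars <- switch(category,
    LIVE_BIRTH           = c(273, 10),
    STILLBIRTH           = c(238, 35),
    ECTOPIC              = c(49, 14),
    SPONTANEOUS_ABORTION = c(70, 25),
    INDUCED_ABORTION     = c(70, 21),
    DELIVERY_ONLY        = c(273, 10),
    NONE                 = c(273, 10)
  )
  win <- if (category == "NONE") c(140, 301) else config_windows[[category]]
  repeat {
    g <- round(rnorm(1, pars[1], pars[2]))
    if (g >= win[1] && g <= win[2]) return(as.integer(g))
  }
}

#' Simulate a cohort with ground-truth pregnancies
#'
#' For each pregnancy the generator emits: GW records exactly at
#' `true_lmp + 7 * week` for each scheduled week reached before the outcome
#' (no date jitter, so noise-free back-projection recovers the LMP exactly);
#' one event per applicable registry timing concept (GR3m, PROGRESSION,
#' HELD_OUT) at a date drawn uniformly inside the concept's expected
#' gestational window (with a small 0.05-month margin so day rounding never
#' pushes an event outside its window), gated to dates the pregnancy
#' actually reaches; the outcome concept record at the outcome date; and one
#' COVID-19 PCR/Ag test per pregnancy. Consecutive pregnancies of a person
#' are separated by an inter-pregnancy gap drawn uniformly in [290, 420]
#' days so retry-period and outcome-separation constraints hold and the
#' truth is recoverable.
#'
#' @param config a [sim_config()].
#' @param registry a `concept_registry` supplying concept ids and windows.
#' @return object of class `sim_result`: list with `persons`, `events`
#'   (sorted event table), and `truth` (one row per ground-truth pregnancy).
#' @export
simulate_cohort <- function(config, registry = example_registry()) {
  stopifnot(inherits(config, "sim_config"))
  validate_registry(registry)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$random_seed)

  dpm <- registry$hierarchy$days_per_month
  tw <- registry$hierarchy$term_windows
  outcome_concept <- setNames(registry$outcomes$concept_id, registry$outcomes$category)
  outcome_name <- setNames(registry$outcomes$concept_name, registry$outcomes$category)
  gw_map <- registry$gestation_weeks
  timing <- registry$timing

  n <- config$n_persons
  ids <- sprintf("P%05d", seq_len(n))
  npreg <- as.integer(sample(names(config$pregnancies_per_person), n, replace = TRUE,
                             prob = config$pregnancies_per_person))
  lmp1 <- as.Date("2018-03-01") + round(runif(n, 0, 1035))  # through 2020-12
  age1 <- runif(n, 16, 45)
  persons <- data.table(
    person_id = ids,
    birth_date = lmp1 - round(age1 * 365.25),
    sex = "female",
    race = sample(c("White", "Black or African American", "Asian", "Other"),
                  n, replace = TRUE, prob = c(0.55, 0.2, 0.1, 0.15)),
    ethnicity = sample(c("Not Hispanic or Latino", "Hispanic or Latino"),
                       n, replace = TRUE, prob = c(0.8, 0.2))
  )

  truth_rows <- vector("list", sum(npreg))
  event_rows <- vector("list", sum(npreg))
  k <- 0L
  for (i in seq_len(n)) {
    lmp <- lmp1[i]
    for (j in seq_len(npreg[i])) {
      k <- k + 1L
      category <- sample(names(config$outcome_mix), 1, prob = config$outcome_mix)
      gest <- .draw_gest_length(category, tw)
      outcome_date <- if (category == "NONE") as.Date(NA) else lmp + gest
      truth_rows[[k]] <- data.table(
        person_id = ids[i], pregnancy_id = sprintf("%s_T%d", ids[i], j),
        true_lmp = lmp, outcome_category = category,
        outcome_date = outcome_date, gestational_length_days = gest
      )
      ev <- .emit_pregnancy_events(ids[i], lmp, gest, category, config, registry,
                                   dpm, outcome_concept, outcome_name, gw_map, timing)
      event_rows[[k]] <- ev
      ## next pregnancy: gap large enough that retry, outcome-separation and
      ## progression-compatibility constraints always separate the truths
      lmp <- lmp + gest + round(runif(1, 290, 420))
    }
  }
  truth <- rbindlist(truth_rows)
  events <- rbindlist(event_rows, use.names = TRUE)
  setorder(events, person_id, event_date, concept_id)
  structure(list(persons = persons, events = events[], truth = truth[]),
            class = "sim_result")
}

.emit_pregnancy_events <- function(pid, lmp, gest, category, config, registry,
                                   dpm, outcome_concept, outcome_name, gw_map, timing) {
  rows <- list()
  ## GW records at scheduled weeks reached before the outcome
  wks <- config$visit_schedule[config$visit_schedule * 7L <= gest]
  wks <- wks[wks %in% gw_map$week]
  if (length(wks)) {
    gwsub <- gw_map[match(wks, gw_map$week)]
    rows$gw <- data.table(person_id = pid, concept_id = gwsub$concept_id,
                          concept_name = gwsub$concept_name,
                          event_date = lmp + 7L * wks,
                          domain = "observation", value = NA_character_)
  }
  ## timing concepts (all usages): uniform draw inside expected window,
  ## gated to offsets the pregnancy reaches before its last emitted record
  gest_mo <- gest / dpm
  ub_cap <- if (category == "NONE") {
    if (length(wks)) min(gest_mo, max(wks) * 7 / dpm) else gest_mo
  } else gest_mo
  for (r in seq_len(nrow(timing))) {
    lo <- timing$min_month[r] + 0.05
    hi <- min(timing$max_month[r], ub_cap) - 0.05
    if (lo > hi) next
    u <- runif(1, lo, hi)
    rows[[paste0("t", r)]] <- data.table(
      person_id = pid, concept_id = timing$concept_id[r],
      concept_name = timing$concept_name[r],
      event_date = lmp + round(u * dpm),
      domain = if (timing$usage[r] == "GR3m") "measurement" else "procedure",
      value = NA_character_)
  }
  ## outcome record(s)
  if (category != "NONE" && runif(1) > config$p_missing_outcome) {
    od <- lmp + gest
    rows$outcome <- data.table(person_id = pid,
                               concept_id = outcome_concept[[category]],
                               concept_name = outcome_name[[category]],
                               event_date = od, domain = "condition",
                               value = NA_character_)
    if (runif(1) < config$p_duplicate_outcome) {
      rows$outcome_dup <- data.table(person_id = pid,
                                     concept_id = outcome_concept[[category]],
                                     concept_name = outcome_name[[category]],
                                     event_date = od + sample(0:3, 1),
                                     domain = "condition", value = NA_character_)
    }
  }
  ## one COVID-19 PCR/Ag test per pregnancy, mid-episode
  test_hi <- if (category == "NONE") max(10, round(ub_cap * dpm) - 10) else gest - 10
  if (test_hi > 10 && length(registry$covid$pcr_ag_test)) {
    td <- lmp + round(runif(1, 10, test_hi))
    pos <- runif(1) < config$covid_positive_rate
    rows$covid_test <- data.table(person_id = pid,
                                  concept_id = registry$covid$pcr_ag_test[1],
                                  concept_name = "SARS-CoV-2 PCR/Ag test (synthetic)",
                                  event_date = td, domain = "measurement",
                                  value = if (pos) "positive" else "negative")
    if (pos && length(registry$covid$covid_diagnosis)) {
      rows$covid_dx <- data.table(person_id = pid,
                                  concept_id = registry$covid$covid_diagnosis[1],
                                  concept_name = "COVID-19 diagnosis (synthetic)",
                                  event_date = td, domain = "condition",
                                  value = NA_character_)
    }
  }
  rbindlist(rows, use.names = TRUE)
}

#' Apply configured noise to a simulated event table
#'
#' Three corruptions, each reproducible from `config$random_seed`:
#' GW dropout (each GW record removed with `p_missing_gw`); outlier GW
#' insertion (with `p_outlier_gw` per surviving GW record, a new GW record
#' is added 1-6 days later whose week is shifted by 5-12, so its
#' back-projected start deviates from the source record's by at least 29
#' days); and historical-record insertion (with `p_historical` per held-out
#' concept record, a copy dated 305-500 days before the person's earliest
#' event, i.e. outside any pregnancy). The input table is not modified.
#'
#' @param events event table from [simulate_cohort()].
#' @param config a [sim_config()].
#' @param registry the registry used to simulate.
#' @return a new, sorted event table.
#' @export
corrupt_events <- function(events, config, registry = example_registry()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$random_seed + 1L)

  ev <- copy(as.data.table(events))
  gw_map <- registry$gestation_weeks
  is_gw <- ev$concept_id %in% gw_map$concept_id

  ## GW dropout
  if (config$p_missing_gw > 0) {
    drop <- is_gw & runif(nrow(ev)) < config$p_missing_gw
    ev <- ev[!drop]
    is_gw <- ev$concept_id %in% gw_map$concept_id
  }
  ## outlier GW insertion
  new_rows <- list()
  if (config$p_outlier_gw > 0 && any(is_gw)) {
    idx <- which(is_gw & runif(nrow(ev)) < config$p_outlier_gw)
    if (length(idx)) {
      wk <- gw_map$week[match(ev$concept_id[idx], gw_map$concept_id)]
      k <- sample(5:12, length(idx), replace = TRUE)
      wk_new <- ifelse(wk - k >= 1L, wk - k, wk + k)
      wk_new <- pmin(wk_new, 44L)
      u <- sample(1:6, length(idx), replace = TRUE)
      sub <- gw_map[match(wk_new, gw_map$week)]
      new_rows$outliers <- data.table(
        person_id = ev$person_id[idx], concept_id = sub$concept_id,
        concept_name = sub$concept_name,
        event_date = ev$event_date[idx] + u,
        domain = "observation", value = NA_character_)
    }
  }
  ## historical held-out insertion (pre-pregnancy recording of a
  ## pregnancy-specific validation concept)
  if (config$p_historical > 0) {
    held_ids <- registry$timing$concept_id[registry$timing$usage == "HELD_OUT"]
    first_ev <- ev[, .(first_date = min(event_date)), by = person_id]
    is_held <- ev$concept_id %in% held_ids
    idx <- which(is_held & runif(nrow(ev)) < config$p_historical)
    if (length(idx)) {
      fd <- first_ev$first_date[match(ev$person_id[idx], first_ev$person_id)]
      new_rows$historical <- data.table(
        person_id = ev$person_id[idx], concept_id = ev$concept_id[idx],
        concept_name = ev$concept_name[idx],
        event_date = fd - round(runif(length(idx), 305, 500)),
        domain = ev$domain[idx], value = NA_character_)
    }
  }
  out <- rbindlist(c(list(ev), new_rows), use.names = TRUE)
  setorder(out, person_id, event_date, concept_id)
  out[]
}

#' Write a simulated cohort as OMOP-lite CSV tables
#'
#' Writes `persons.csv`, one CSV per clinical domain present in the events,
#' and `truth.csv` under `out_dir`.
#' @param sim a `sim_result` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @export
write_sim_tables <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sim$persons, file.path(out_dir, "persons.csv"))
  for (dom in unique(sim$events$domain)) {
    spec <- .table_specs[[dom]]
    sub <- sim$events[domain == dom]
    out <- data.table(person_id = sub$person_id)
    out[[spec$concept]] <- sub$concept_id
    out[[spec$date]] <- sub$event_date
    out$concept_name <- sub$concept_name
    out$value_as_string <- sub$value
    fwrite(out, file.path(out_dir, sprintf("%s_occurrence.csv", dom)))
  }
  fwrite(sim$truth, file.path(out_dir, "truth.csv"))
  invisible(out_dir)
}
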