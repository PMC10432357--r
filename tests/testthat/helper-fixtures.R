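## Shared fixtures: tiny event builders and cached simulations.

REG <- example_registry()
DPM <- REG$hierarchy$days_per_month
D0 <- as.Date("2019-01-01")

## minimal normalized event table
mk_events <- function(person_id, concept_id, event_date,
                      concept_name = NA_character_, domain = "condition",
                      value = NA_character_) {
  data.table::data.table(
    person_id = as.character(person_id),
    concept_id = as.integer(concept_id),
    concept_name = concept_name,
    event_date = as.Date(event_date),
    domain = domain, value = value)
}

mk_outcomes <- function(person_id, event_date, category) {
  data.table::data.table(person_id = as.character(person_id),
                         event_date = as.Date(event_date),
                         category = category)
}

mk_gw <- function(person_id, event_date, week) {
  data.table::data.table(person_id = as.character(person_id),
                         event_date = as.Date(event_date),
                         week = as.integer(week))
}

## progression event rows with explicit windows
mk_prog <- function(person_id, event_date, min_month, max_month,
                    concept_id = seq_along(event_date)) {
  data.table::data.table(person_id = as.character(person_id),
                         event_date = as.Date(event_date),
                         concept_id = as.integer(concept_id),
                         min_month = min_month, max_month = max_month)
}

## GW concept id for week w in the example registry
gw_cid <- function(w) 200000L + as.integer(w)

## simulations are the slowest fixture; cache per (n, seed, knobs)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n, seed, ...) {
  key <- paste(n, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n_persons = n, random_seed = seed, ...)
    .sim_cache[[key]] <- list(cfg = cfg, sim = simulate_cohort(cfg, REG))
  }
  .sim_cache[[key]]
}

## retained rows only, audit metadata dropped (audits legitimately differ
## between a first pass and a re-run on already-clean input)
drop_audit <- function(x) {
  attr(x, "audit") <- NULL
  as.data.frame(x)
}

## align episodes to ground truth per person by date order; returns merged
## data.table with one row per (truth pregnancy, matched episode) or NA
align_truth <- function(truth, episodes) {
  tr <- data.table::as.data.table(truth)
  ep <- data.table::as.data.table(episodes)
  data.table::setorder(tr, person_id, true_lmp)
  data.table::setorder(ep, person_id, inferred_start_date)
  tr[, idx := seq_len(.N), by = person_id]
  ep[, idx := seq_len(.N), by = person_id]
  merge(tr, ep, by = c("person_id", "idx"), all.x = TRUE)
}
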