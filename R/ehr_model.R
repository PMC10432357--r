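## OMOP-lite data model and I/O: normalize the five clinical domain tables
## to a single event layout, filter candidate persons, and round-trip the
## final episode table.

.table_specs <- list(
  condition   = list(concept = "condition_concept_id",   date = "condition_start_date"),
  procedure   = list(concept = "procedure_concept_id",   date = "procedure_date"),
  observation = list(concept = "observation_concept_id", date = "observation_date"),
  measurement = list(concept = "measurement_concept_id", date = "measurement_date"),
  drug        = list(concept = "drug_concept_id",        date = "drug_exposure_start_date")
)

#' Read one OMOP-style table into the normalized event layout
#'
#' Expects a comma-separated, UTF-8 file with a header row using OMOP 5.3.1
#' column names for the given table kind (e.g. `condition_concept_id` and
#' `condition_start_date` for `"condition"`). Generic `concept_id` /
#' `event_date` columns are also accepted. Rows whose date cannot be parsed
#' are dropped and counted in the load report (`attr(x, "load_report")`).
#'
#' @param path CSV file path.
#' @param table_kind one of `"condition"`, `"procedure"`, `"observation"`,
#'   `"measurement"`, `"drug"`.
#' @return A `data.table` with columns `person_id`, `concept_id`,
#'   `concept_name`, `event_date` (Date), `domain`, `value`, stably sorted by
#'   (person_id, event_date, concept_id).
#' @export
read_events <- function(path, table_kind = names(.table_specs)) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- .table_specs[[table_kind]]
  if (file.size(path) == 0) return(.empty_events())
  dt <- fread(path, showProgress = FALSE)
  if (nrow(dt) == 0 && ncol(dt) == 0) {
    return(.empty_events())
  }
  if (!"person_id" %in% names(dt)) {
    stop("missing required column: person_id (table kind '", table_kind, "')")
  }
  pick <- function(preferred, generic) {
    hit <- intersect(c(preferred, generic), names(dt))
    if (!length(hit)) {
      stop("missing required column: ", preferred, " (table kind '", table_kind, "')")
    }
    hit[1]
  }
  concept_col <- pick(spec$concept, "concept_id")
  date_col <- pick(spec$date, "event_date")
  name_col <- intersect(c("concept_name", paste0(table_kind, "_concept_name")),
                        names(dt))[1]
  value_col <- intersect(c("value_as_string", "value_source_value", "value"),
                         names(dt))[1]
  ev <- data.table(
    person_id = as.character(dt$person_id),
    concept_id = as.integer(dt[[concept_col]]),
    concept_name = if (!is.na(name_col)) as.character(dt[[name_col]]) else NA_character_,
    event_date = suppressWarnings(as.Date(as.character(dt[[date_col]]))),
    domain = table_kind,
    value = if (!is.na(value_col)) as.character(dt[[value_col]]) else NA_character_
  )
  n_bad <- sum(is.na(ev$event_date))
  ev <- ev[!is.na(event_date)]
  setorder(ev, person_id, event_date, concept_id)
  attr(ev, "load_report") <- list(path = path, table_kind = table_kind,
                                  n_read = nrow(dt), n_dropped = n_bad)
  ev[]
}

.empty_events <- function() {
  data.table(person_id = character(), concept_id = integer(),
             concept_name = character(), event_date = as.Date(character()),
             domain = character(), value = character())
}

#' Combine per-table event sets into one sorted event table
#' @param ... event tables from [read_events()] or equivalent.
#' @return a single sorted `data.table`.
#' @export
bind_events <- function(...) {
  ev <- rbindlist(list(...), use.names = TRUE, fill = TRUE)
  setorder(ev, person_id, event_date, concept_id)
  ev[]
}

#' Read a person table
#'
#' Accepts either a `birth_date` column or OMOP `year_of_birth` /
#' `month_of_birth` / `day_of_birth` parts (missing parts default to
#' mid-year / mid-month).
#'
#' @param path CSV file path.
#' @return `data.table` with columns `person_id`, `birth_date`, `sex`,
#'   `race`, `ethnicity`.
#' @export
read_persons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, colClasses = list(character = "person_id"), showProgress = FALSE)
  if (!"person_id" %in% names(dt)) stop("missing required column: person_id")
  if ("birth_date" %in% names(dt)) {
    bd <- suppressWarnings(as.Date(as.character(dt$birth_date)))
  } else if ("year_of_birth" %in% names(dt)) {
    y <- dt$year_of_birth
    m <- if ("month_of_birth" %in% names(dt)) ifelse(is.na(dt$month_of_birth), 6L, dt$month_of_birth) else 6L
    d <- if ("day_of_birth" %in% names(dt)) ifelse(is.na(dt$day_of_birth), 15L, dt$day_of_birth) else 15L
    bd <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  } else {
    stop("missing required column: birth_date (or year_of_birth)")
  }
  sex_col <- intersect(c("sex", "gender", "gender_source_value"), names(dt))[1]
  out <- data.table(
    person_id = as.character(dt$person_id),
    birth_date = bd,
    sex = if (!is.na(sex_col)) tolower(as.character(dt[[sex_col]])) else NA_character_,
    race = if ("race" %in% names(dt)) as.character(dt$race) else NA_character_,
    ethnicity = if ("ethnicity" %in% names(dt)) as.character(dt$ethnicity) else NA_character_
  )
  setorder(out, person_id)
  out[]
}

## completed years between birth and ref (calendar arithmetic, floor)
.age_years <- function(birth, ref) {
  b <- as.POSIXlt(birth); r <- as.POSIXlt(ref)
  age <- r$year - b$year
  before_bday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  age - as.integer(before_bday)
}

#' Identify candidate persons: female, reproductive age 15-55 inclusive
#'
#' Age is computed as completed years at the reference date. When no single
#' `reference_date` is supplied, each person's earliest event date in
#' `events` is used (the reproducible per-person analogue of filtering a
#' population once). Persons with missing sex or birth date are excluded and
#' counted in `attr(result, "report")`.
#'
#' @param persons person table from [read_persons()].
#' @param reference_date optional single Date applied to everyone.
#' @param events optional event table used to derive per-person reference
#'   dates when `reference_date` is NULL.
#' @param min_age,max_age inclusive age bounds (defaults 15 and 55).
#' @return character vector of candidate person ids.
#' @export
filter_candidates <- function(persons, reference_date = NULL, events = NULL,
                              min_age = 15L, max_age = 55L) {
  p <- as.data.table(persons)
  missing_fields <- is.na(p$sex) | is.na(p$birth_date)
  p2 <- p[!missing_fields]
  if (is.null(reference_date)) {
    if (is.null(events)) stop("supply reference_date or events")
    ref <- as.data.table(events)[, .(ref_date = min(event_date)), by = person_id]
    p2 <- merge(p2, ref, by = "person_id")
    refd <- p2$ref_date
  } else {
    refd <- rep(.as_date(reference_date), nrow(p2))
  }
  age <- .age_years(p2$birth_date, refd)
  keep <- p2$sex == "female" & age >= min_age & age <= max_age
  ids <- sort(p2$person_id[keep])
  attr(ids, "report") <- list(n_total = nrow(p),
                              n_missing_fields = sum(missing_fields),
                              n_candidates = length(ids))
  ids
}

.episode_cols <- c("person_id", "episode_id", "inferred_start_date",
                   "recorded_start_date", "end_date", "outcome_category",
                   "outcome_date", "hip_flag", "pps_flag", "concordance_score",
                   "precision_category", "precision_days", "max_week",
                   "recorded_length_days", "inferred_length_days")

#' Write the final episode table to CSV
#'
#' Columns, in order: person_id, episode_id, inferred_start_date,
#' recorded_start_date, end_date, outcome_category, outcome_date, hip_flag,
#' pps_flag, concordance_score, precision_category, precision_days,
#' max_week, recorded_length_days, inferred_length_days. Round-trips
#' losslessly through [read_episode_table()].
#'
#' @param episodes episode `data.table` (missing columns are written as NA).
#' @param path output CSV path.
#' @export
write_episode_table <- function(episodes, path) {
  ep <- as.data.table(episodes)
  for (col in setdiff(.episode_cols, names(ep))) ep[[col]] <- NA
  fwrite(ep[, .episode_cols, with = FALSE], path)
  invisible(path)
}

#' Read an episode table written by [write_episode_table()]
#' @param path CSV path.
#' @return episode `data.table` with typed columns.
#' @export
read_episode_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, colClasses = list(character = c("person_id", "episode_id")),
              showProgress = FALSE)
  for (col in setdiff(.episode_cols, names(dt))) {
    stop("missing required column: ", col)
  }
  for (col in c("inferred_start_date", "recorded_start_date", "end_date", "outcome_date")) {
    dt[[col]] <- as.Date(dt[[col]])
  }
  for (col in c("hip_flag", "pps_flag")) dt[[col]] <- as.logical(dt[[col]])
  for (col in c("concordance_score", "precision_days", "max_week",
                "recorded_length_days", "inferred_length_days")) {
    dt[[col]] <- as.integer(dt[[col]])
  }
  dt$outcome_category <- as.character(dt$outcome_category)
  dt$precision_category <- as.character(dt$precision_category)
  setorder(dt, person_id, inferred_start_date, episode_id)
  dt[]
}
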