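## Concept registry: classification of vocabulary concepts into pregnancy
## outcome categories, week-level gestational age ("GW") concepts, ranged
## gestational timing concepts, and COVID-19 concept sets, plus the tunable
## hierarchy configuration shared by all inference stages.

#' Pregnancy outcome categories, in hierarchy priority order
#'
#' The outcome hierarchy resolves competing outcome evidence: live birth
#' outranks stillbirth, which outranks ectopic pregnancy, then spontaneous
#' abortion, induced abortion, and finally a bare delivery record.
#'
#' @return Character vector of the six categories, highest priority first.
#' @export
outcome_categories <- function() {
  c("LIVE_BIRTH", "STILLBIRTH", "ECTOPIC",
    "SPONTANEOUS_ABORTION", "INDUCED_ABORTION", "DELIVERY_ONLY")
}

#' Priority rank of an outcome category (1 = highest)
#' @param category character vector of category names.
#' @return integer ranks; NA for unknown categories.
#' @export
outcome_priority <- function(category) {
  match(category, outcome_categories())
}

#' Hierarchy configuration for episode inference
#'
#' Bundles every tunable constant used by the HIP, PPS, merge and ESD
#' stages: the outcome priority order, the pairwise minimum separation (in
#' days) required between retained outcome records, per-category plausible
#' term-duration windows, the inter-pregnancy retry period, PPS cleanup
#' limits, and the day length of a "month".
#'
#' Separations stated for the method are live birth to live birth 182 days
#' (26 weeks), stillbirth to stillbirth 168 days (24 weeks), a stillbirth
#' following a live birth 168 days and preceding one 182 days; all other
#' category pairs default to 56 days and are configurable. Only the live
#' birth maximum term of 301 days (43 weeks) is method-anchored; the
#' remaining term windows are documented defaults.
#'
#' @param min_separation_days 6x6 numeric matrix, rows/cols named by
#'   [outcome_categories()]. Entry `[a, b]` is the minimum days required when
#'   an event of category `a` occurs after an event of category `b`.
#' @param term_windows named list of `c(min_days, max_days)` per category.
#' @param retry_days minimum permissible days between the end of one
#'   pregnancy episode and the start of the next (default 60).
#' @param max_episode_months PPS cleanup: drop episodes recorded longer than
#'   this many months (default 12).
#' @param max_episodes_per_year PPS cleanup: drop all episodes of a person
#'   with more than this many episode starts in any 365-day window (default 5).
#' @param days_per_month day length of one gestational month
#'   (default 365.25/12 = 30.4375).
#' @return object of class `hierarchy_config`.
#' @export
hierarchy_config <- function(min_separation_days = NULL,
                             term_windows = NULL,
                             retry_days = 60L,
                             max_episode_months = 12L,
                             max_episodes_per_year = 5L,
                             days_per_month = 365.25 / 12) {
  cats <- outcome_categories()
  if (is.null(min_separation_days)) {
    min_separation_days <- matrix(56, 6, 6, dimnames = list(cats, cats))
    min_separation_days["LIVE_BIRTH", "LIVE_BIRTH"] <- 182
    min_separation_days["STILLBIRTH", "STILLBIRTH"] <- 168
    min_separation_days["STILLBIRTH", "LIVE_BIRTH"] <- 168
    min_separation_days["LIVE_BIRTH", "STILLBIRTH"] <- 182
  }
  stopifnot(is.matrix(min_separation_days),
            identical(dim(min_separation_days), c(6L, 6L)),
            all(min_separation_days > 0))
  if (is.null(term_windows)) {
    term_windows <- list(
      LIVE_BIRTH           = c(140, 301),
      STILLBIRTH           = c(140, 301),
      ECTOPIC              = c(14, 84),
      SPONTANEOUS_ABORTION = c(14, 168),
      INDUCED_ABORTION     = c(14, 168),
      DELIVERY_ONLY        = c(140, 301)
    )
  }
  stopifnot(setequal(names(term_windows), cats),
            all(vapply(term_windows, function(w) length(w) == 2 &&
                         w[1] > 0 && w[1] <= w[2], logical(1))))
  structure(list(
    priority = cats,
    min_separation_days = min_separation_days,
    term_windows = term_windows[cats],
    retry_days = as.integer(retry_days),
    max_episode_months = as.integer(max_episode_months),
    max_episodes_per_year = as.integer(max_episodes_per_year),
    days_per_month = as.numeric(days_per_month)
  ), class = "hierarchy_config")
}

term_window <- function(config, category) {
  w <- config$term_windows[[category]]
  if (is.null(w)) stop("unknown outcome category: ", category)
  w
}

#' Parse a week-level gestational age concept name
#'
#' Extracts X from names of the form `"Gestation period, X weeks"`
#' (the singular `"1 week"` is accepted).
#'
#' @param concept_name character vector of concept names.
#' @return integer vector of weeks; `NA` where the name does not match.
#' @examples
#' parse_gestation_week("Gestation period, 12 weeks") # 12
#' parse_gestation_week("Polyhydramnios")             # NA
#' @export
parse_gestation_week <- function(concept_name) {
  m <- regmatches(concept_name,
                  regexec("^Gestation period, ([0-9]+) week(s?)$", concept_name))
  vapply(m, function(g) {
    if (length(g) == 0) return(NA_integer_)
    wk <- as.integer(g[2])
    if (g[3] == "" && wk != 1L) return(NA_integer_)  # "12 week" is malformed
    wk
  }, integer(1))
}

#' Construct and validate a concept registry
#'
#' @param outcomes data.frame with columns `concept_id`, `concept_name`,
#'   `category` (one of [outcome_categories()]).
#' @param gestation_weeks data.frame with columns `concept_id`,
#'   `concept_name`, `week` (1-44).
#' @param timing data.frame with columns `concept_id`, `concept_name`,
#'   `min_month`, `max_month`, `usage` (one of `"GR3m"`, `"PROGRESSION"`,
#'   `"HELD_OUT"`). GR3m/PROGRESSION windows must span more than one week and
#'   at most 3 months; HELD_OUT validation windows span 4-10 months.
#' @param covid list with integer vectors `pcr_ag_test` and `covid_diagnosis`.
#' @param hierarchy a [hierarchy_config()].
#' @return object of class `concept_registry`.
#' @export
concept_registry <- function(outcomes, gestation_weeks, timing,
                             covid = list(pcr_ag_test = integer(),
                                          covid_diagnosis = integer()),
                             hierarchy = hierarchy_config()) {
  outcomes <- as.data.table(outcomes)
  gestation_weeks <- as.data.table(gestation_weeks)
  timing <- as.data.table(timing)
  reg <- structure(list(outcomes = outcomes,
                        gestation_weeks = gestation_weeks,
                        timing = timing,
                        covid = covid,
                        hierarchy = hierarchy),
                   class = "concept_registry")
  validate_registry(reg)
  reg
}

#' Validate a concept registry
#'
#' Checks category names, week bounds (1-44), timing-window invariants per
#' usage, and that no concept id is registered in more than one role.
#' @param registry a `concept_registry`.
#' @return the registry, invisibly; errors name the offending concept id.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "concept_registry"))
  out <- registry$outcomes; gw <- registry$gestation_weeks; tm <- registry$timing
  bad <- setdiff(out$category, outcome_categories())
  if (length(bad)) stop("unknown outcome category: ", paste(bad, collapse = ", "))
  if (nrow(gw)) {
    off <- gw$concept_id[is.na(gw$week) | gw$week < 1 | gw$week > 44]
    if (length(off)) stop("gestation week out of range [1, 44] for concept_id: ",
                          paste(off, collapse = ", "))
  }
  if (nrow(tm)) {
    bad_use <- setdiff(tm$usage, c("GR3m", "PROGRESSION", "HELD_OUT"))
    if (length(bad_use)) stop("unknown timing usage: ", paste(bad_use, collapse = ", "))
    off <- tm$concept_id[!(tm$min_month > 0 & tm$min_month <= tm$max_month &
                             tm$max_month <= 10)]
    if (length(off)) stop("timing window outside (0, 10] months for concept_id: ",
                          paste(off, collapse = ", "))
    span <- tm$max_month - tm$min_month
    narrow <- tm$usage %in% c("GR3m", "PROGRESSION")
    off <- tm$concept_id[narrow & !(span <= 3 & span > 7 / 30.4375)]
    if (length(off)) stop("GR3m/PROGRESSION window span must be >1 week and <=3 months; ",
                          "offending concept_id: ", paste(off, collapse = ", "))
    off <- tm$concept_id[!narrow & !(span >= 4 & span <= 10)]
    if (length(off)) stop("HELD_OUT window span must be in [4, 10] months; ",
                          "offending concept_id: ", paste(off, collapse = ", "))
  }
  ids <- c(out$concept_id, gw$concept_id, tm$concept_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("concept_id registered in more than one role: ",
                        paste(dup, collapse = ", "))
  invisible(registry)
}

#' Write a concept registry to JSON
#' @param registry a `concept_registry`.
#' @param path output file path.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  h <- registry$hierarchy
  obj <- list(
    schema_version = "1.0",
    outcomes = registry$outcomes,
    gestation_weeks = registry$gestation_weeks,
    timing = registry$timing,
    covid = registry$covid,
    hierarchy = list(
      min_separation_days = h$min_separation_days,
      term_windows = h$term_windows,
      retry_days = h$retry_days,
      max_episode_months = h$max_episode_months,
      max_episodes_per_year = h$max_episodes_per_year,
      days_per_month = h$days_per_month
    )
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a concept registry from JSON
#' @param path path to a registry JSON file written by [write_registry()]
#'   or following the same schema.
#' @return a validated `concept_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$hierarchy
  sep <- h$min_separation_days
  if (!is.null(sep)) {
    sep <- as.matrix(sep)
    dimnames(sep) <- list(outcome_categories(), outcome_categories())
  }
  tw <- h$term_windows
  if (!is.null(tw)) tw <- lapply(tw, as.numeric)
  hierarchy <- hierarchy_config(
    min_separation_days = sep,
    term_windows = tw,
    retry_days = h$retry_days %||% 60L,
    max_episode_months = h$max_episode_months %||% 12L,
    max_episodes_per_year = h$max_episodes_per_year %||% 5L,
    days_per_month = h$days_per_month %||% (365.25 / 12)
  )
  covid <- list(pcr_ag_test = as.integer(obj$covid$pcr_ag_test),
                covid_diagnosis = as.integer(obj$covid$covid_diagnosis))
  concept_registry(outcomes = obj$outcomes,
                   gestation_weeks = obj$gestation_weeks,
                   timing = obj$timing,
                   covid = covid,
                   hierarchy = hierarchy)
}

#' Built-in example concept registry (synthetic)
#'
#' A small, fully valid registry used by the synthetic cohort generator and
#' the test-suite. Concept ids and most timing windows are synthetic
#' stand-ins chosen to be clinically plausible (one documented anchor:
#' serum estriol is testable between gestational months 3.75 and 5.5); drop
#' in real OMOP concept sets via [load_registry()] for production use.
#'
#' Roles covered: one outcome concept per category, "Gestation period, X
#' weeks" concepts for weeks 1-44, three GR3m ranged-timing concepts, five
#' progression concepts spanning early to late pregnancy, two held-out
#' validation concepts (4-10 month windows), and COVID-19 test/diagnosis
#' concept sets.
#'
#' @param hierarchy optional [hierarchy_config()] override.
#' @return a `concept_registry`.
#' @export
example_registry <- function(hierarchy = hierarchy_config()) {
  outcomes <- data.table(
    concept_id = 100001:100006,
    concept_name = c("Livebirth delivery (synthetic)",
                     "Stillbirth delivery (synthetic)",
                     "Ectopic pregnancy (synthetic)",
                     "Spontaneous abortion (synthetic)",
                     "Induced termination of pregnancy (synthetic)",
                     "Delivery procedure, outcome unspecified (synthetic)"),
    category = outcome_categories()
  )
  wk <- 1:44
  gw <- data.table(
    concept_id = 200000L + wk,
    concept_name = ifelse(wk == 1L, "Gestation period, 1 week",
                          sprintf("Gestation period, %d weeks", wk)),
    week = wk
  )
  timing <- data.table(
    concept_id = c(300001L, 300002L, 300003L,
                   400001L, 400002L, 400003L, 400004L, 400005L,
                   500001L, 500002L),
    concept_name = c(
      "Nuchal translucency ultrasound scan (synthetic)",
      "Estriol measurement, serum (synthetic)",
      "Alpha-fetoprotein serum screening (synthetic)",
      "First trimester prenatal panel (synthetic)",
      "Cell-free fetal DNA screening (synthetic)",
      "Fetal anatomy survey ultrasound (synthetic)",
      "Glucose tolerance test, 3 specimens (synthetic)",
      "Group B streptococcus culture screening (synthetic)",
      "Polyhydramnios",
      "Supervision of normal pregnancy (synthetic)"
    ),
    min_month = c(2.5, 3.75, 3.5,
                  0.5, 2.0, 4.0, 5.5, 8.0,
                  6.0, 0.5),
    max_month = c(3.5, 5.5, 4.6,
                  1.5, 3.2, 5.2, 7.0, 9.2,
                  10.0, 9.5),
    usage = c("GR3m", "GR3m", "GR3m",
              rep("PROGRESSION", 5),
              "HELD_OUT", "HELD_OUT")
  )
  covid <- list(pcr_ag_test = 700001L, covid_diagnosis = 700002L)
  concept_registry(outcomes, gw, timing, covid = covid, hierarchy = hierarchy)
}
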