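cfg <- hierarchy_config()

test_that("pair_compatible matches hand-computed interval arithmetic", {
  ## estriol window [3.75, 5.5] vs [6, 7]: allowed gap 0.5-3.25 months,
  ## i.e. 15.2-98.9 days at 30.4375 days/month
  a <- list(event_date = D0, min_month = 3.75, max_month = 5.5)
  b <- list(event_date = D0 + 75, min_month = 6, max_month = 7)
  expect_true(pair_compatible(a, b, DPM))
  b$event_date <- D0 + 150
  expect_false(pair_compatible(a, b, DPM))
  b$event_date <- D0 + 15   # just below 15.2-day lower bound
  expect_false(pair_compatible(a, b, DPM))
  b$event_date <- D0 + 16
  expect_true(pair_compatible(a, b, DPM))
  ## degenerate pair: same concept, same day
  expect_true(pair_compatible(a, list(event_date = D0, min_month = 3.75,
                                      max_month = 5.5), DPM))
})

test_that("build_progressions extends, restarts, and holds noise", {
  ## three in-window events of one pregnancy -> one episode
  pe <- mk_prog("1", c(D0 + round(2 * DPM), D0 + round(5 * DPM), D0 + round(8 * DPM)),
                c(1.5, 4.5, 7.5), c(2.5, 5.5, 8.5))
  eps <- build_progressions(pe, cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_events, 3L)

  ## incompatible event with a 70-day gap starts a new episode
  pe <- mk_prog("1", c(D0, D0 + 70), c(5, 1), c(6, 2))
  eps <- build_progressions(pe, cfg)
  expect_equal(nrow(eps), 2)

  ## incompatible event with a 30-day gap is unassigned noise
  pe <- mk_prog("1", c(D0, D0 + 30), c(5, 1), c(6, 2))
  eps <- build_progressions(pe, cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(nrow(attr(eps, "unassigned")), 1)
})

test_that("build_progressions matches the exhaustive oracle", {
  set.seed(77)
  for (i in 1:60) {
    inst <- random_instance(sample(2:8, 1))
    pe <- mk_prog("1", inst$event_date, inst$min_month, inst$max_month,
                  concept_id = seq_len(nrow(inst)))
    got <- build_progressions(pe, cfg)
    oracle <- oracle_segmentations(inst, cfg$retry_days, cfg$days_per_month)
    expect_length(oracle, 1)
    assign <- oracle[[1]]
    ## same episode count and membership
    expect_equal(nrow(got), max(assign))
    ## concept_id was set to the row index, so membership maps back directly
    members <- attr(got, "members")
    got_assign <- integer(nrow(inst))
    got_assign[members$concept_id] <- members$episode_idx
    expect_equal(got_assign, assign)
  }
})

test_that("cleanup drops long episodes and hyper-frequent persons", {
  base <- data.table::data.table(
    person_id = "1", episode_idx = 1L,
    first_event_date = D0, last_event_date = D0 + 400,
    n_events = 2L, last_min_month = 1)
  expect_equal(nrow(pps_cleanup(base, cfg)), 0)  # > 12 months

  ok <- data.table::copy(base); ok$last_event_date <- D0 + 200
  expect_equal(nrow(pps_cleanup(ok, cfg)), 1)

  ## 6 episode starts inside one 365-day window -> person dropped entirely
  many <- data.table::data.table(
    person_id = "2", episode_idx = 1:6,
    first_event_date = D0 + (0:5) * 60,
    last_event_date = D0 + (0:5) * 60 + 10,
    n_events = 1L, last_min_month = 1)
  expect_equal(nrow(pps_cleanup(many, cfg)), 0)

  ## two episodes 8 months apart are retained
  two <- many[1:2]
  two$first_event_date <- c(D0, D0 + 240)
  two$last_event_date <- two$first_event_date + 10
  expect_equal(nrow(pps_cleanup(two, cfg)), 2)
})

test_that("attach_outcome windows and hierarchy selection", {
  ep <- list(person_id = "1", last_event_date = D0 + 250, last_min_month = 8)
  ## live birth 3 days after the last record: inside the window,
  ## which ends at last + (10 - 8) months = ~61 days
  oc <- mk_outcomes("1", D0 + 253, "LIVE_BIRTH")
  att <- attach_outcome(ep, oc, NULL, cfg)
  expect_equal(att$outcome_category, "LIVE_BIRTH")
  expect_equal(att$outcome_date, D0 + 253)
  ## an outcome past the window end is not attached
  oc_far <- mk_outcomes("1", D0 + 250 + round(2 * DPM) + 5, "LIVE_BIRTH")
  expect_equal(attach_outcome(ep, oc_far, NULL, cfg)$outcome_category, "NONE")
  ## the next episode start caps the window
  expect_equal(attach_outcome(ep, oc, D0 + 251, cfg)$outcome_category, "NONE")

  ## hierarchy: live birth beats induced abortion in-window
  oc2 <- mk_outcomes("1", c(D0 + 255, D0 + 253),
                     c("LIVE_BIRTH", "INDUCED_ABORTION"))
  expect_equal(attach_outcome(ep, oc2, NULL, cfg)$outcome_category, "LIVE_BIRTH")

  ## outcomes more than 14 days before the episode end are out of window
  oc3 <- mk_outcomes("1", D0 + 230, "LIVE_BIRTH")
  expect_equal(attach_outcome(ep, oc3, NULL, cfg)$outcome_category, "NONE")
  oc4 <- mk_outcomes("1", D0 + 236, "LIVE_BIRTH")
  expect_equal(attach_outcome(ep, oc4, NULL, cfg)$outcome_category, "LIVE_BIRTH")
})

test_that("PPS episodes respect structural invariants on simulated data", {
  s <- cached_sim(120, 55)$sim
  pps <- pps_episodes(s$events, REG)
  max_len <- cfg$max_episode_months * cfg$days_per_month
  expect_true(all(as.numeric(pps$last_event_date - pps$first_event_date) <= max_len))
  pps <- pps[order(pps$person_id, pps$first_event_date)]
  for (sub in split(pps, pps$person_id)) {
    if (nrow(sub) > 1) {
      gaps <- as.numeric(sub$first_event_date[-1] - sub$last_event_date[-nrow(sub)])
      expect_true(all(gaps >= cfg$retry_days))
    }
  }
  ## every HIP episode with an outcome is overlapped by a PPS episode
  ## whenever the pregnancy produced at least one progression event
  hip <- hip_episodes(s$events, REG)
  hip_out <- hip[hip$outcome_category != "NONE" & hip$basis == "merged"]
  prog <- progression_events(s$events, REG)
  for (r in seq_len(nrow(hip_out))) {
    has_prog <- nrow(prog[prog$person_id == hip_out$person_id[r] &
                            prog$event_date >= hip_out$start_date[r] &
                            prog$event_date <= hip_out$end_date[r]]) > 0
    if (has_prog) {
      ov <- pps[pps$person_id == hip_out$person_id[r] &
                  pps$first_event_date <= hip_out$end_date[r] &
                  pps$end_date >= hip_out$start_date[r]]
      expect_gte(nrow(ov), 1)
    }
  }
})
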