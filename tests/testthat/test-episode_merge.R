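cfg <- hierarchy_config()

mk_hip <- function(person_id, start, end, cat = "NONE", odate = NA) {
  data.table::data.table(
    person_id = person_id, start_date = as.Date(start), end_date = as.Date(end),
    outcome_category = cat, outcome_date = as.Date(odate),
    basis = "merged", max_week = NA_integer_,
    recorded_start_date = as.Date(start))
}
mk_pps <- function(person_id, first, last, cat = "NONE", odate = NA) {
  end <- if (!is.na(odate) && as.Date(odate) > as.Date(last)) as.Date(odate) else as.Date(last)
  data.table::data.table(
    person_id = person_id, episode_idx = 1L,
    first_event_date = as.Date(first), last_event_date = as.Date(last),
    n_events = 2L, last_min_month = 8,
    outcome_category = cat, outcome_date = as.Date(odate), end_date = end)
}

test_that("overlapping HIP and PPS episodes merge to their union", {
  h <- mk_hip("1", "2020-01-01", "2020-10-01", "LIVE_BIRTH", "2020-10-01")
  p <- mk_pps("1", "2020-02-01", "2020-09-20", "LIVE_BIRTH", "2020-10-01")
  m <- resolve_overlaps(h, p)
  expect_equal(nrow(m), 1)
  expect_equal(m$start_date, as.Date("2020-01-01"))
  expect_equal(m$end_date, as.Date("2020-10-01"))
  expect_true(m$hip_flag & m$pps_flag)
})

test_that("unpaired episodes pass through with a single flag", {
  h <- mk_hip("1", "2020-01-01", "2020-10-01")
  p <- mk_pps("1", "2021-02-01", "2021-09-20")
  m <- resolve_overlaps(h, p)
  expect_equal(nrow(m), 2)
  expect_equal(m$hip_flag, c(TRUE, FALSE))
  expect_equal(m$pps_flag, c(FALSE, TRUE))
})

test_that("conflicts resolve to the closest end dates", {
  ## one PPS episode overlapping two HIP episodes: ends 5 vs 40 days away
  h <- rbind(mk_hip("1", "2020-01-01", "2020-06-01"),
             mk_hip("1", "2020-07-15", "2020-09-25"))
  p <- mk_pps("1", "2020-03-01", "2020-08-20")   # overlaps both
  p$end_date <- as.Date("2020-08-20")
  h$end_date <- as.Date(c("2020-08-25", "2020-09-29"))  # |diff| = 5 vs 40
  h$start_date <- as.Date(c("2020-01-01", "2020-08-27"))
  m <- resolve_overlaps(h, p)
  both <- m[m$hip_flag & m$pps_flag]
  expect_equal(nrow(both), 1)
  expect_equal(both$end_date, as.Date("2020-08-25"))
  solo <- m[m$hip_flag & !m$pps_flag]
  expect_equal(nrow(solo), 1)
})

test_that("merge is symmetric up to flag labels", {
  h <- mk_hip("1", "2020-01-01", "2020-10-01", "LIVE_BIRTH", "2020-10-01")
  p <- mk_pps("1", "2020-02-01", "2020-09-20")
  m1 <- resolve_overlaps(h, p)
  ## swap roles by relabeling inputs
  h2 <- mk_hip("1", "2020-02-01", "2020-09-20")
  p2 <- mk_pps("1", "2020-01-01", "2020-10-01", "LIVE_BIRTH", "2020-10-01")
  m2 <- resolve_overlaps(h2, p2)
  expect_equal(m1$start_date, m2$start_date)
  expect_equal(m1$end_date, m2$end_date)
})

test_that("concordance scores follow the 0-2 definition", {
  lb <- function(d) list(category = "LIVE_BIRTH", date = as.Date(d))
  sb <- function(d) list(category = "STILLBIRTH", date = as.Date(d))
  ## match within 14 days, GA inside the live-birth window -> 2
  r <- concordance(lb(D0 + 280), lb(D0 + 285), 280, cfg)
  expect_equal(r$score, 2L)
  expect_equal(r$outcome_category, "LIVE_BIRTH")
  expect_equal(r$outcome_date, D0 + 285)
  ## category mismatch: later outcome kept, score 1 when GA in that window
  r <- concordance(lb(D0 + 280), sb(D0 + 290), 290, cfg)
  expect_equal(r$outcome_category, "STILLBIRTH")
  expect_equal(r$score, 1L)
  ## matched but GA outside the window -> 0 even with a match
  r <- concordance(lb(D0 + 80), lb(D0 + 82), 80, cfg)
  expect_equal(r$score, 0L)
  ## single-sided outcome adopted, score 1 in-window
  r <- concordance(lb(D0 + 280), NULL, 280, cfg)
  expect_equal(r$score, 1L)
  expect_equal(r$outcome_category, "LIVE_BIRTH")
  r <- concordance(NULL, sb(D0 + 200), 200, cfg)
  expect_equal(r$outcome_category, "STILLBIRTH")
  ## matched categories more than 14 days apart are not a match
  r <- concordance(lb(D0 + 280), lb(D0 + 300), 300, cfg)
  expect_equal(r$score, 1L)
  expect_equal(r$outcome_date, D0 + 300)
  ## no outcome on either side
  r <- concordance(NULL, NULL, NA, cfg)
  expect_true(is.na(r$score))
  expect_equal(r$outcome_category, "NONE")
})

test_that("final episodes never overlap and clean live births score 2", {
  s <- cached_sim(120, 55)$sim
  res <- hipps_pipeline(s$events, s$persons, REG)
  ep <- res$episodes[order(res$episodes$person_id, res$episodes$inferred_start_date)]
  for (sub in split(ep, ep$person_id)) {
    if (nrow(sub) > 1) {
      expect_true(all(sub$inferred_start_date[-1] > sub$end_date[-nrow(sub)]))
    }
  }
  lb <- ep[ep$outcome_category == "LIVE_BIRTH"]
  expect_gt(nrow(lb), 0)
  expect_true(all(lb$concordance_score == 2L))
})
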