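cfg <- hierarchy_config()

test_that("assess_outcomes enforces same- and cross-category separations", {
  ## second live birth 100 days later is dropped (minimum 182)
  oc <- mk_outcomes("1", c(D0, D0 + 100), c("LIVE_BIRTH", "LIVE_BIRTH"))
  res <- assess_outcomes(oc, cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$event_date, D0)
  expect_equal(attr(res, "audit")$reason, "same_category_separation")

  ## stillbirth 200 days after a live birth is retained (200 >= 168)
  oc <- mk_outcomes("1", c(D0, D0 + 200), c("LIVE_BIRTH", "STILLBIRTH"))
  expect_equal(nrow(assess_outcomes(oc, cfg)), 2)

  ## stillbirth 100 days after a live birth is dropped (100 < 168)
  oc <- mk_outcomes("1", c(D0, D0 + 100), c("LIVE_BIRTH", "STILLBIRTH"))
  res <- assess_outcomes(oc, cfg)
  expect_equal(res$category, "LIVE_BIRTH")
  expect_equal(attr(res, "audit")$reason, "cross_category_separation")

  ## stillbirth preceding a live birth needs 182 days
  oc <- mk_outcomes("1", c(D0, D0 + 170), c("STILLBIRTH", "LIVE_BIRTH"))
  res <- assess_outcomes(oc, cfg)
  expect_equal(res$category, "LIVE_BIRTH")  # higher priority wins
  oc <- mk_outcomes("1", c(D0, D0 + 190), c("STILLBIRTH", "LIVE_BIRTH"))
  expect_equal(nrow(assess_outcomes(oc, cfg)), 2)
})

test_that("assess_outcomes is idempotent on random inputs", {
  set.seed(99)
  for (i in 1:20) {
    oc <- mk_outcomes(sample(1:3, 12, replace = TRUE),
                      D0 + sample(0:900, 12, replace = TRUE),
                      sample(outcome_categories(), 12, replace = TRUE))
    r1 <- assess_outcomes(oc, cfg)
    r2 <- assess_outcomes(r1, cfg)
    expect_equal(drop_audit(r1), drop_audit(r2))
  }
})

test_that("gestation drafts back-project from the maximum week", {
  ## increasing weeks extend one draft
  gw <- mk_gw("1", c(D0, D0 + 28), c(8, 12))
  d <- infer_gestation_episodes(gw)
  expect_equal(nrow(d), 1)
  expect_equal(d$derived_start, D0 + 28 - 84)  # d0 - 56
  expect_equal(d$max_week, 12L)

  ## a non-increasing week whose projected start clears the draft splits
  gw <- mk_gw("1", c(D0, D0 + 240), c(20, 6))
  d <- infer_gestation_episodes(gw)
  expect_equal(nrow(d), 2)
  expect_equal(d$derived_start[2], D0 + 240 - 42)

  ## projected start inside the previous draft span -> noise, no split
  gw <- mk_gw("1", c(D0, D0 + 14), c(8, 8))
  d <- infer_gestation_episodes(gw)
  expect_equal(nrow(d), 1)
  expect_equal(d$max_week, 8L)
  expect_equal(nrow(attr(d, "noise")), 1)
})

test_that("drafts never overlap and noise records never shift back-projection", {
  s <- cached_sim(80, 31)$sim
  d <- infer_gestation_episodes(gw_events(s$events, REG))
  d <- d[order(d$person_id, d$derived_start)]
  byp <- split(d, d$person_id)
  for (sub in byp) {
    if (nrow(sub) > 1) {
      expect_true(all(sub$derived_start[-1] > sub$last_gw_date[-nrow(sub)]))
    }
  }
})

test_that("merge_hip pairs outcomes with drafts and strips misaligned outcomes", {
  ## live birth at day 280 over a 39-week draft merges with back-projected start
  oc <- mk_outcomes("1", D0 + 280, "LIVE_BIRTH")
  gd <- infer_gestation_episodes(mk_gw("1", c(D0 + 84, D0 + 273), c(12, 39)))
  ep <- merge_hip(oc, gd, cfg)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$basis, "merged")
  expect_equal(ep$start_date, D0)
  expect_equal(ep$end_date, D0 + 280)
  expect_equal(ep$outcome_category, "LIVE_BIRTH")

  ## live birth over an 8-week draft (56 days, outside the 140-301 term
  ## window) is a misclassification: outcome removed, gestation-only kept
  oc <- mk_outcomes("1", D0 + 70, "LIVE_BIRTH")
  gd <- infer_gestation_episodes(mk_gw("1", c(D0 + 42, D0 + 56), c(6, 8)))
  ep <- merge_hip(oc, gd, cfg)
  expect_equal(ep$basis, "gestation_only")
  expect_equal(ep$outcome_category, "NONE")
  expect_equal(attr(ep, "audit")$reason, "outcome_misaligned_with_gestational_age")

  ## a lone live birth becomes outcome-only, start = date - 301
  oc <- mk_outcomes("1", as.Date("2021-10-28"), "LIVE_BIRTH")
  ep <- merge_hip(oc, infer_gestation_episodes(mk_gw(character(0), character(0), integer(0))), cfg)
  expect_equal(ep$basis, "outcome_only")
  expect_equal(ep$start_date, as.Date("2020-12-31"))
})

test_that("HIP episodes per person never overlap", {
  s <- cached_sim(120, 55)$sim
  hip <- hip_episodes(s$events, REG)
  hip <- hip[order(hip$person_id, hip$start_date)]
  for (sub in split(hip, hip$person_id)) {
    expect_true(all(sub$start_date <= sub$end_date))
    if (nrow(sub) > 1) {
      expect_true(all(sub$start_date[-1] > sub$end_date[-nrow(sub)]))
    }
  }
})

test_that("HIP recovers one episode per truth pregnancy with its outcome", {
  s <- cached_sim(120, 55)$sim
  hip <- hip_episodes(s$events, REG)
  expect_equal(nrow(hip), nrow(s$truth))
  tr <- data.table::as.data.table(s$truth)
  data.table::setorder(tr, person_id, true_lmp)
  data.table::setorder(hip, person_id, start_date)
  expect_equal(hip$outcome_category,
               ifelse(tr$outcome_category == "NONE", "NONE", tr$outcome_category))
})
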