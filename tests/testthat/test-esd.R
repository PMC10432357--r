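## evidence builders operating directly on the start_evidence layout
ev_gw <- function(record_dates, weeks) {
  data.table::data.table(record_date = as.Date(record_dates),
                         week = as.integer(weeks),
                         derived_start = as.Date(record_dates) - 7L * as.integer(weeks))
}
ev_gr <- function(record_dates, lowers, uppers) {
  data.table::data.table(record_date = as.Date(record_dates),
                         lower = as.Date(lowers), upper = as.Date(uppers))
}
mk_evidence <- function(gw = ev_gw(character(0), integer(0)),
                        gr3m = ev_gr(character(0), character(0), character(0))) {
  structure(list(gw = gw, gr3m = gr3m), class = "start_evidence")
}

test_that("collect_evidence dedupes same-date GW by max week and builds intervals", {
  ev <- rbind(
    mk_events("1", gw_cid(12), D0, domain = "observation"),
    mk_events("1", gw_cid(14), D0, domain = "observation"),
    mk_events("1", 300002L, D0 + 10, domain = "measurement"))  # estriol
  evd <- collect_evidence(ev, REG)
  expect_equal(nrow(evd$gw), 1)
  expect_equal(evd$gw$week, 14L)
  expect_equal(evd$gw$derived_start, D0 - 98)
  ## estriol record at D: interval [D - 5.5 dpm, D - 3.75 dpm]
  expect_equal(evd$gr3m$lower, D0 + 10 - round(5.5 * DPM))
  expect_equal(evd$gr3m$upper, D0 + 10 - round(3.75 * DPM))

  empty <- collect_evidence(mk_events(character(0), integer(0), character(0)), REG)
  expect_equal(nrow(empty$gw), 0)
  expect_equal(nrow(empty$gr3m), 0)
})

test_that("filter_outliers removes only candidates failing both conditions", {
  ## derived starts {d0, d0+2, d0+3, d0+40}; GR3m intersection [d0-5, d0+10]
  gw <- ev_gw(D0 + c(56, 58, 59, 96), rep(8, 4))  # derived d0-56+... use explicit
  gw$derived_start <- D0 + c(0, 2, 3, 40)
  gr <- ev_gr(D0 + 100, D0 - 5, D0 + 10)
  filt <- filter_outliers(mk_evidence(gw, gr))
  expect_equal(filt$gw$derived_start, D0 + c(0, 2, 3))
  expect_equal(attr(filt, "removed")$derived_start, D0 + 40)

  ## two candidates 3 days apart: never removed (fewer than 3)
  gw2 <- ev_gw(D0 + c(56, 59), c(8, 8))
  filt2 <- filter_outliers(mk_evidence(gw2, gr))
  expect_equal(nrow(filt2$gw), 2)

  ## all inside the intersection: nothing removed
  gw3 <- gw[1:3]
  expect_equal(nrow(filter_outliers(mk_evidence(gw3, gr))$gw), 3)

  ## conflicting GR3m intervals (empty intersection) fall back to IQR only
  gr_bad <- ev_gr(D0 + c(100, 101), c(D0 - 5, D0 + 30), c(D0 + 10, D0 + 60))
  filt4 <- filter_outliers(mk_evidence(gw, gr_bad))
  expect_equal(nrow(filt4$gw), 3)  # d0+40 still out by IQR alone
})

test_that("disjunctive switch removes on intersection alone", {
  ## {0, 2, 40}: Tukey fences retain 40 (n = 3), but the GR3m intersection
  ## excludes it under the disjunctive reading
  gw <- ev_gw(D0 + c(140, 142, 180), rep(20, 3))
  gw$derived_start <- D0 + c(0, 2, 40)
  gr <- ev_gr(D0 + 100, D0 - 5, D0 + 10)
  conj <- filter_outliers(mk_evidence(gw, gr), conjunctive = TRUE)
  expect_equal(nrow(conj$gw), 3)   # conservative default retains
  disj <- filter_outliers(mk_evidence(gw, gr), conjunctive = FALSE)
  expect_equal(disj$gw$derived_start, D0 + c(0, 2))
  ## and the baseline/filtered contrast: window 40 days (two-months)
  ## versus 2 days (week)
  expect_equal(estimate_start(mk_evidence(gw))$precision_category, "two-months")
  expect_equal(estimate_start(disj)$precision_category, "week")
})

test_that("estimate_start uses the latest-dated GW and the category ladder", {
  ## retained starts within 4 days, latest record wins
  gw <- ev_gw(D0 + c(56, 120), c(8, 17))
  est <- estimate_start(mk_evidence(gw))
  expect_equal(est$start_date, D0 + 120 - 119)   # latest record's projection
  expect_equal(est$precision_days, 1L)
  expect_equal(est$precision_category, "week")

  ## single GW record: point estimate, week_poor-support
  est1 <- estimate_start(mk_evidence(ev_gw(D0 + 56, 8)))
  expect_equal(est1$start_date, D0)
  expect_equal(est1$precision_category, "week_poor-support")

  ## ranged evidence only: window from the intersection, no point start
  gr <- ev_gr(D0 + c(100, 120), c(D0 - 30, D0 - 20), c(D0 + 50, D0 + 60))
  est2 <- estimate_start(mk_evidence(gr3m = gr))
  expect_true(is.na(est2$start_date))
  expect_equal(est2$precision_days, 70L)
  expect_equal(est2$precision_category, "three-months")

  ## nothing at all
  est3 <- estimate_start(mk_evidence())
  expect_equal(est3$precision_category, "non-specific")
})

test_that("precision ladder boundaries", {
  expect_equal(precision_category(NA), "non-specific")
  expect_equal(precision_category(0, n_gw = 1), "week_poor-support")
  expect_equal(precision_category(7, 2), "week")
  expect_equal(precision_category(10, 3), "two-week")
  expect_equal(precision_category(14, 2), "two-week")
  expect_equal(precision_category(21, 2), "three-week")
  expect_equal(precision_category(28, 2), "month")
  expect_equal(precision_category(56, 2), "two-months")
  expect_equal(precision_category(60, 2), "three-months")
  expect_equal(precision_category(84, 2), "three-months")
  expect_equal(precision_category(85, 2), "non-specific")
  expect_error(precision_category(-1, 2), "non-negative")
})

test_that("baseline uses all GW candidates and no ranged evidence", {
  gw <- ev_gw(D0 + c(56, 58, 96), rep(8, 3))
  gw$derived_start <- D0 + c(0, 2, 40)
  gr <- ev_gr(D0 + 100, D0 - 5, D0 + 10)
  base <- baseline_start(mk_evidence(gw, gr))
  expect_equal(base$precision_days, 40L)
  expect_equal(base$precision_category, "two-months")
  expect_equal(baseline_start(mk_evidence())$precision_category, "non-specific")
})

test_that("ESD is never coarser than baseline over a corrupted cohort", {
  cache <- cached_sim(80, 7, p_outlier_gw = 0.15)
  ev <- corrupt_events(cache$sim$events, cache$cfg, REG)
  res <- hipps_pipeline(ev, cache$sim$persons, REG)
  ep <- res$episodes
  expect_true(all(precision_rank(ep$precision_category) <=
                    precision_rank(ep$baseline_precision_category)))
  expect_gt(mean(ep$precision_category == "week"),
            mean(ep$baseline_precision_category == "week"))
})

test_that("noise-free recovery: estimated start equals true LMP exactly", {
  s <- cached_sim(60, 42)$sim
  res <- hipps_pipeline(s$events, s$persons, REG)
  m <- align_truth(s$truth, res$episodes)
  multi_gw <- m[!is.na(m$n_gw_retained) & m$n_gw_retained >= 2]
  expect_gt(nrow(multi_gw), 40)
  expect_equal(multi_gw$inferred_start_date, multi_gw$true_lmp)
  expect_true(all(multi_gw$precision_category == "week"))
})
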