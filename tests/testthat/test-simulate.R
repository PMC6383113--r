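test_that("generators are deterministic in the seed", {
  c1 <- generate_cohort(10, 50, seed = 7)
  c2 <- generate_cohort(10, 50, seed = 7)
  expect_identical(c1, c2)
  e1 <- generate_event_streams(c1, behavior_model(), seed = 7)
  e2 <- generate_event_streams(c2, behavior_model(), seed = 7)
  expect_identical(e1, e2)
  t1 <- generate_inbasket_traffic(c1, traffic_model(weekly_arrival_rate = 20),
                                  horizon_days = 30, seed = 7)
  t2 <- generate_inbasket_traffic(c1, traffic_model(weekly_arrival_rate = 20),
                                  horizon_days = 30, seed = 7)
  expect_identical(t1, t2)
  expect_false(identical(
    e1, generate_event_streams(c1, behavior_model(), seed = 8)))
})

test_that("cohort respects sizes, weights, and parameter validation", {
  cohort <- generate_cohort(75, 799, c(593, 37, 169) / 799, seed = 3)
  expect_equal(nrow(cohort$providers), 75)
  expect_equal(nrow(cohort$alerts), 799)
  expect_equal(nrow(cohort$patients), 799)
  expect_equal(anyDuplicated(cohort$alerts$patient_id), 0)
  # multinomial types: observed counts within 4 SD of expectation
  counts <- table(factor(cohort$alerts$alert_type, alert_types()))
  expfr <- c(593, 37, 169)
  sds <- sqrt(expfr * (1 - expfr / 799))
  expect_true(all(abs(counts - expfr) < 4 * sds))
  one <- generate_cohort(1, 1, c(1, 0, 0), seed = 1)
  expect_equal(one$alerts$alert_type, "information_only")
  expect_error(generate_cohort(5, 10, c(-1, 1, 1)),
               class = "alertlog_parameter_error")
  expect_error(generate_cohort(5, 10, c(0, 0, 0)),
               class = "alertlog_parameter_error")
})

test_that("degenerate behavior parameters force or forbid relevant actions", {
  cohort <- generate_cohort(5, 60, seed = 11)
  always <- behavior_model(opener_mix = 1, missing_window_prob = 0,
                           immediate_logit = list(intercept = 50))
  ev <- generate_event_streams(cohort, always, seed = 11)
  op <- find_first_openings(ev, cohort$alerts)
  im <- track_immediate(ev, op)
  expect_equal(nrow(im), 60)
  expect_true(all(im$evaluable))
  expect_true(all(im$relevant))

  nothing <- behavior_model(
    opener_mix = 1, missing_window_prob = 0,
    immediate_logit = list(intercept = -50),
    subsequent_logits = list(
      general = list(intercept = -50),
      medication_specific = list(intercept = -50),
      laboratory_specific = list(intercept = -50)))
  ev0 <- generate_event_streams(cohort, nothing, seed = 11)
  acts <- ev0[ev0$action %in% c("section_view", "order_placed") &
                ev0$patient_id %in% cohort$alerts$patient_id, ]
  # no action events concern any alert's own patient
  key_ev <- paste(acts$actor_id, acts$patient_id)
  key_al <- paste(cohort$alerts$pcp_id, cohort$alerts$patient_id)
  expect_false(any(key_ev %in% key_al))
  expect_error(behavior_model(opener_mix = 1.4),
               class = "alertlog_parameter_error")
})

test_that("event streams are chronologically sound", {
  cohort <- generate_cohort(8, 80, seed = 13)
  ev <- generate_event_streams(cohort, behavior_model(), seed = 13)
  deliv <- stats::setNames(as.numeric(
    ev$ts[ev$action == "alert_delivered"]),
    ev$alert_id[ev$action == "alert_delivered"])
  opens <- ev[ev$action == "alert_opened", ]
  expect_true(all(as.numeric(opens$ts) >= deliv[opens$alert_id]))
  tr <- generate_inbasket_traffic(cohort,
                                  traffic_model(weekly_arrival_rate = 30),
                                  horizon_days = 60, seed = 13)
  dts <- stats::setNames(as.numeric(tr$ts[tr$action == "message_delivered"]),
                         tr$message_id[tr$action == "message_delivered"])
  life <- tr[tr$action != "message_delivered", ]
  expect_true(all(as.numeric(life$ts) > dts[life$message_id]))
})

test_that("traffic model honors degenerate rates and hazards", {
  cohort <- generate_cohort(3, 3, seed = 2)
  none <- generate_inbasket_traffic(cohort, traffic_model(weekly_arrival_rate = 0),
                                    horizon_days = 30, seed = 2)
  expect_equal(nrow(none), 0)
  # open and complete on the day of delivery: any later-day snapshot is empty
  fast <- generate_inbasket_traffic(
    cohort, traffic_model(weekly_arrival_rate = 20, open_prob = 1,
                          complete_prob = 1, postpone_prob = 0),
    horizon_days = 10, seed = 2,
    start = ts_utc("2010-01-01 00:00:00"))
  for (d in c(3, 6, 9)) {
    at <- ts_utc("2010-01-01 00:00:00") + d * 86400
    for (p in cohort$providers$provider_id) {
      snap <- reconstruct_inbasket(fast, p, at)
      expect_equal(snap$total_messages, 0)
    }
  }
})

test_that("empirical action rates converge to the logistic probabilities", {
  # one alert per provider, no random effect: rates are iid Bernoulli
  n <- 20000
  cohort <- generate_cohort(n, n, c(593, 37, 169) / 799, seed = 21)
  cohort$alerts$pcp_id <- cohort$providers$provider_id  # one alert each
  beh <- behavior_model(opener_mix = 1, missing_window_prob = 0,
                        provider_random_effect_sd = 0)
  ev <- generate_event_streams(cohort, beh, seed = 21)
  pl <- run_pipeline(list(alerts = cohort$alerts, events = ev))
  rows <- dplyr::inner_join(pl$rows,
                            cohort$alerts[, c("alert_id", "alert_type")],
                            by = c("alert_id", "alert_type"))
  info <- rows[rows$alert_type == "information_only", ]
  for (chk in list(
    list(p = plogis(beh$immediate_logit$intercept),
         x = info$immediate_relevant),
    list(p = plogis(beh$subsequent_logits$medication_specific$intercept),
         x = info$medication_specific),
    list(p = plogis(beh$subsequent_logits$laboratory_specific$intercept),
         x = info$laboratory_specific))) {
    x <- chk$x[!is.na(chk$x)]
    se <- sqrt(chk$p * (1 - chk$p) / length(x))
    expect_lt(abs(mean(x) - chk$p), 3 * se)
  }
})

test_that("prior-week arrival counts track the weekly rate", {
  cohort <- generate_cohort(1, 1, seed = 31)
  tr <- generate_inbasket_traffic(cohort, traffic_model(weekly_arrival_rate = 450),
                                  horizon_days = 60, seed = 31,
                                  start = ts_utc("2010-01-01 00:00:00"))
  at <- ts_utc("2010-01-01 00:00:00") + c(30, 40, 50) * 86400
  pw <- vapply(as.list(at), function(t)
    reconstruct_inbasket(tr, cohort$providers$provider_id[1], t,
                         lookback_days = 365)$prior_week_arrivals,
    numeric(1))
  # Poisson(450) weekly totals: each within 5 SD, mean much closer
  expect_true(all(abs(pw - 450) < 5 * sqrt(450)))
  expect_lt(abs(mean(pw) - 450), 3 * sqrt(450 / 3))
})

test_that("the canonical fixture is byte-identical across rebuilds", {
  f1 <- make_canonical_fixture()
  f2 <- make_canonical_fixture()
  expect_identical(f1, f2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(f1, d1)
  write_dataset(f2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
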