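test_that("the action window ends at the second local midnight, exclusive", {
  tz <- "America/New_York"
  mk <- function(x) lubridate::with_tz(lubridate::ymd_hms(x, tz = tz), "UTC")
  w <- action_window(mk("2011-03-01 14:03:00"), tz)       # Tuesday
  expect_equal(lubridate::with_tz(w$end, tz),
               lubridate::ymd_hms("2011-03-03 00:00:00", tz = tz))
  w2 <- action_window(mk("2011-02-28 23:59:59"), tz)      # Monday, last second
  expect_equal(lubridate::with_tz(w2$end, tz),
               lubridate::ymd_hms("2011-03-02 00:00:00", tz = tz))
  w3 <- action_window(mk("2011-03-05 09:00:00"), tz)      # Saturday
  expect_equal(lubridate::with_tz(w3$end, tz),
               lubridate::ymd_hms("2011-03-07 00:00:00", tz = tz))
  expect_error(action_window("2011-03-01 14:03:00"),
               class = "alertlog_validation_error")
})

test_that("action detection classifies general/medication/laboratory correctly", {
  tz <- "America/New_York"
  t0 <- lubridate::with_tz(lubridate::ymd_hms("2011-03-01 10:00:00", tz = tz),
                           "UTC")
  w <- action_window(t0, tz)
  # one medication discontinuation order
  ev <- mk_events(t0 + 3600, "P1", "order_placed", patient_id = "PT1",
                  order_kind = "medication", med_action = "discontinue")
  got <- detect_actions(ev, "P1", "PT1", w$start, w$end)
  expect_equal(got, list(general = TRUE, medication_specific = TRUE,
                         laboratory_specific = FALSE))
  # lab result view at the last second of the following day
  last <- w$end - 1
  ev2 <- mk_events(last, "P1", "section_view", patient_id = "PT1",
                   section = "results", is_lab_result = TRUE)
  got2 <- detect_actions(ev2, "P1", "PT1", w$start, w$end)
  expect_true(got2$laboratory_specific)
  # untagged results view counts only toward general
  ev2b <- mk_events(last, "P1", "section_view", patient_id = "PT1",
                    section = "results")
  got2b <- detect_actions(ev2b, "P1", "PT1", w$start, w$end)
  expect_true(got2b$general)
  expect_false(got2b$laboratory_specific)
  # events two calendar days later fall outside the window
  ev3 <- mk_events(w$end + 60, "P1", "section_view", patient_id = "PT1",
                   section = "medications")
  got3 <- detect_actions(ev3, "P1", "PT1", w$start, w$end)
  expect_equal(got3, list(general = FALSE, medication_specific = FALSE,
                          laboratory_specific = FALSE))
})

test_that("specific flags imply general, and flags are monotone in events", {
  set.seed(99)
  tz <- "America/New_York"
  t0 <- ts_utc("2011-03-01 15:00:00")
  w <- action_window(t0, tz)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    offs <- sample(0:(30 * 3600), k)
    act <- sample(c("section_view", "order_placed"), k, TRUE)
    ev <- mk_events(
      t0 + offs, "P1", act,
      patient_id = sample(c("PT1", "PT2"), k, TRUE),
      section = ifelse(act == "section_view",
                       sample(section_codes(), k, TRUE), NA),
      order_kind = ifelse(act == "order_placed",
                          sample(c("medication", "laboratory"), k, TRUE), NA),
      med_action = "new")
    ev$med_action[!(ev$action == "order_placed" &
                      ev$order_kind %in% "medication")] <- NA
    ev$is_lab_result[ev$section %in% "results"] <- sample(
      c(TRUE, FALSE), sum(ev$section %in% "results"), TRUE)
    got <- detect_actions(ev, "P1", "PT1", w$start, w$end)
    if (got$medication_specific) expect_true(got$general)
    if (got$laboratory_specific) expect_true(got$general)
    # adding one more qualifying event never switches a flag off
    extra <- mk_events(t0 + 60, "P1", "section_view", event_id = "EX1",
                       patient_id = "PT1", section = "medications")
    got2 <- detect_actions(dplyr::bind_rows(ev, extra), "P1", "PT1",
                           w$start, w$end)
    expect_true(got2$general >= got$general)
    expect_true(got2$medication_specific >= got$medication_specific)
    expect_true(got2$laboratory_specific >= got$laboratory_specific)
  }
})

test_that("the addressed PCP is tracked even when staff opened the alert", {
  al <- mk_alert()
  t <- al$delivery_ts
  ev <- mk_events(
    c(t, t + 600, t + 3600),
    c("P1", "S9", "P1"),
    c("alert_delivered", "alert_opened", "section_view"),
    actor_role = c("pcp", "staff", "pcp"),
    patient_id = c(NA, NA, "PT1"),
    section = c(NA, NA, "medications"),
    alert_id = c("A1", "A1", NA))
  op <- find_first_openings(ev, al)
  expect_false(op$opened_by_pcp)
  sub <- track_subsequent(ev, op)
  expect_true(sub$general)
  expect_true(sub$medication_specific)
})

test_that("subsequent counts on the canonical fixture hit the quotas", {
  fx <- make_canonical_fixture()
  op <- find_first_openings(fx$events, fx$alerts)
  sub <- track_subsequent(fx$events, op)
  joined <- dplyr::inner_join(sub, fx$alerts[, c("alert_id", "alert_type")],
                              by = "alert_id")
  agg <- sapply(split(joined, joined$alert_type)[alert_types()], function(d)
    c(sum(d$general), sum(d$medication_specific),
      sum(d$laboratory_specific)))
  expect_equal(unname(agg[, "information_only"]), c(382, 95, 100))
  expect_equal(unname(agg[, "medication_recommendation"]), c(29, 18, 20))
  expect_equal(unname(agg[, "test_recommendation"]), c(127, 41, 60))
})
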