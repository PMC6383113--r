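test_that("the 5-minute window is half-open and actor-specific", {
  t0 <- ts_utc("2011-03-01 10:00:00")
  ev <- mk_events(
    c(t0, t0 + 299, t0 + 300, t0 + 100),
    c("P1", "P1", "P1", "P2"),
    c("alert_opened", "section_view", "section_view", "section_view"),
    patient_id = c(NA, "PT1", "PT1", "PT1"),
    section = c(NA, "medications", "medications", "medications"),
    alert_id = c("A1", NA, NA, NA))
  w <- extract_window(ev, "P1", t0, trigger_alert_id = "A1")
  expect_equal(nrow(w), 1)                       # +299 in, +300 out, P2 out
  expect_equal(as.numeric(w$ts - t0, units = "secs"), 299)
})

test_that("first-action classification follows the relevance rules", {
  t0 <- ts_utc("2011-03-01 10:00:00")
  rel <- mk_events(t0 + 20, "P1", "section_view", patient_id = "PT1",
                   section = "medications")
  expect_equal(classify_first_action(rel, "PT1"),
               list(relevant = TRUE, category = "medications"))
  other_alert <- mk_events(t0 + 20, "P1", "alert_opened", alert_id = "A2")
  expect_equal(classify_first_action(other_alert, "PT1"),
               list(relevant = FALSE, category = "other_patient_notification"))
  other_chart <- mk_events(t0 + 20, "P1", "section_view",
                           patient_id = "PT2", section = "laboratory")
  expect_equal(classify_first_action(other_chart, "PT1"),
               list(relevant = FALSE, category = "other_patient_chart"))
  empty <- rel[0, ]
  expect_equal(classify_first_action(empty, "PT1"),
               list(relevant = FALSE, category = "no_action"))
  # an order for the target patient is an action inside their record
  ord <- mk_events(t0 + 5, "P1", "order_placed", patient_id = "PT1",
                   order_kind = "laboratory")
  expect_equal(classify_first_action(ord, "PT1"),
               list(relevant = TRUE, category = "order_laboratory"))
})

test_that("time attribution matches the worked interval cases", {
  t0 <- ts_utc("2011-03-01 10:00:00")
  w <- mk_events(c(t0 + 20, t0 + 50), "P1",
                 c("section_view", "section_view"),
                 patient_id = c("PT1", "PT9"),
                 section = c("medications", "encounters"))
  got <- attribute_time(w, t0, "PT1")
  expect_equal(got$alert_display_seconds, 20)
  expect_equal(got$relevant_patient_seconds, 30)
  expect_equal(got$total_seconds, 50)

  empty <- w[0, ]
  got2 <- attribute_time(empty, t0, "PT1")
  expect_equal(got2$alert_display_seconds, 300)
  expect_equal(got2$total_seconds, 300)

  short <- mk_events(t0 + 15, "P1", "section_view", patient_id = "PT9",
                     section = "encounters")
  got3 <- attribute_time(short, t0, "PT1")
  expect_equal(got3$alert_display_seconds, 15)
  expect_equal(got3$relevant_patient_seconds, 0)
  expect_equal(got3$total_seconds, 15)
})

test_that("durations are bounded, additive, and agree with the interval oracle", {
  set.seed(271)
  for (i in 1:1000) {
    cs <- random_window_case()
    got <- attribute_time(cs$window, cs$t0, cs$target)
    ora <- oracle_attribute_time(cs$window, cs$t0, cs$target)
    expect_identical(got$alert_display_seconds, as.integer(ora$display))
    expect_identical(got$relevant_patient_seconds, as.integer(ora$relevant))
    expect_equal(got$total_seconds,
                 got$alert_display_seconds + got$relevant_patient_seconds)
    expect_true(got$alert_display_seconds >= 0 &&
                  got$relevant_patient_seconds >= 0)
    expect_true(got$total_seconds <= 300)
    cls <- classify_first_action(cs$window, cs$target)
    expect_true(cls$relevant %in% c(TRUE, FALSE))
    if (!cls$relevant) {
      expect_true(cls$category %in% c("no_action", "other_patient_chart",
                                      "other_patient_notification"))
    }
  }
})

test_that("tracking marks end-of-coverage windows non-evaluable", {
  al <- mk_alert()
  t <- al$delivery_ts
  # opening is the actor's last logged event: no display estimate exists
  ev <- mk_events(c(t, t + 600), "P1", c("alert_delivered", "alert_opened"),
                  alert_id = "A1")
  op <- find_first_openings(ev, al)
  im <- track_immediate(ev, op)
  expect_false(im$evaluable)
  expect_true(is.na(im$total_seconds))
  # same empty window, but a later event terminates the display estimate
  later <- mk_events(t + 2 * 3600, "P1", "section_view", event_id = "EL",
                     patient_id = "PT9", section = "encounters")
  im2 <- track_immediate(dplyr::bind_rows(ev, later), op)
  expect_true(im2$evaluable)
  expect_false(im2$relevant)
  expect_equal(im2$first_action_category, "no_action")
  expect_equal(im2$alert_display_seconds, 300)
})

test_that("immediate per-type counts on the canonical fixture hit the quotas", {
  fx <- make_canonical_fixture()
  op <- find_first_openings(fx$events, fx$alerts)
  im <- track_immediate(fx$events, op)
  expect_equal(nrow(im), 627)
  expect_equal(sum(im$evaluable), 616)
  joined <- dplyr::inner_join(im[im$evaluable, ],
                              fx$alerts[, c("alert_id", "alert_type")],
                              by = "alert_id")
  counts <- table(joined$alert_type, joined$relevant)
  expect_equal(unname(counts[alert_types(), "TRUE"]), c(125, 17, 66))
  expect_equal(unname(rowSums(counts)[alert_types()]), c(445, 31, 140))
})
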