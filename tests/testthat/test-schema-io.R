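test_that("logs round-trip through jsonl and csv, including absent optionals", {
  fx <- make_canonical_fixture()
  ev <- fx$events[1:100, ]
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_log(ev, path, fmt)
    back <- read_log(path, fmt)
    expect_equal(as.data.frame(back), as.data.frame(ev))
  }
  # cross-format: jsonl -> csv -> jsonl preserves every field
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".csv")
  p3 <- withr::local_tempfile(fileext = ".jsonl")
  write_log(ev, p1, "jsonl")
  write_log(read_log(p1, "jsonl"), p2, "csv")
  write_log(read_log(p2, "csv"), p3, "jsonl")
  expect_equal(as.data.frame(read_log(p3, "jsonl")), as.data.frame(ev))
  # an event with every optional field absent survives the trip
  bare <- mk_events(ts_utc("2011-01-01 08:00:00"), "P1", "alert_opened",
                    alert_id = "A1")
  p4 <- withr::local_tempfile(fileext = ".jsonl")
  write_log(bare, p4, "jsonl")
  expect_equal(as.data.frame(read_log(p4, "jsonl")), as.data.frame(bare))
})

test_that("reading sorts by timestamp with event_id tiebreak; empty file is empty", {
  t <- ts_utc("2011-01-01 08:00:00")
  ev <- mk_events(c(t + 10, t, t), "P1", "alert_opened",
                  event_id = c("E3", "E2", "E1"), alert_id = "A1")
  path <- withr::local_tempfile(fileext = ".jsonl")
  # write deliberately out of order
  write_log(ev[c(1, 3, 2), ], path, "jsonl")
  back <- read_log(path, "jsonl")
  expect_equal(back$event_id, c("E1", "E2", "E3"))
  writeLines(character(), path)
  expect_equal(nrow(read_log(path, "jsonl")), 0)
})

test_that("validation names the offending record and field", {
  t <- ts_utc("2011-01-01 08:00:00")
  no_section <- mk_events(t, "P1", "section_view", patient_id = "PT1")
  expect_error(validate_events(no_section), "section",
               class = "alertlog_validation_error")
  dup <- mk_events(c(t, t + 1), "P1", "alert_opened",
                   event_id = c("E1", "E1"), alert_id = "A1")
  expect_error(validate_events(dup), "duplicate",
               class = "alertlog_validation_error")
  bad_enum <- mk_events(t, "P1", "section_view", patient_id = "PT1",
                        section = "not_a_section")
  expect_error(validate_events(bad_enum), "unknown section",
               class = "alertlog_validation_error")
  stray_order <- mk_events(t, "P1", "alert_opened", alert_id = "A1",
                           order_kind = "medication")
  expect_error(validate_events(stray_order), "order_kind",
               class = "alertlog_validation_error")
  # malformed file reporting includes the line
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"event_id":"E1","ts":"2011-01-01T08:00:00+0000","actor_id":"P1","actor_role":"pcp","action":"alert_opened","alert_id":"A1"}',
               '{not json'), path)
  expect_error(read_log(path, "jsonl"), "line 2")
})

test_that("round-trip identity holds on arbitrary generated logs", {
  for (s in 1:5) {
    cohort <- generate_cohort(5, 30, seed = s)
    ev <- generate_event_streams(cohort, behavior_model(), seed = s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_log(ev, path, "csv")
    expect_equal(as.data.frame(read_log(path, "csv")), as.data.frame(ev))
  }
})

test_that("cohort validation reports referential failures, counts never-opened", {
  fx <- make_canonical_fixture()
  rep0 <- validate_cohort(fx$alerts, fx$providers, fx$patients, fx$events)
  expect_true(rep0$valid)
  expect_equal(nrow(rep0$problems), 0)
  expect_equal(rep0$never_opened, 0)

  bad_alerts <- fx$alerts
  bad_alerts$pcp_id[1] <- "P999"
  rep1 <- validate_cohort(bad_alerts, fx$providers, fx$patients, fx$events)
  expect_false(rep1$valid)
  expect_equal(rep1$problems$kind, "alert_unknown_provider")

  # a delivered-but-never-opened alert is tallied, not flagged
  extra <- mk_alert("A_NEW", pcp_id = fx$providers$provider_id[1],
                    patient_id = fx$patients$patient_id[1])
  alerts2 <- dplyr::bind_rows(fx$alerts, extra)
  deliv <- mk_events(extra$delivery_ts, extra$pcp_id, "alert_delivered",
                     event_id = "XD1", alert_id = "A_NEW")
  ev2 <- dplyr::bind_rows(fx$events, deliv)
  rep2 <- validate_cohort(alerts2, fx$providers, fx$patients, ev2)
  expect_true(rep2$valid)
  expect_equal(rep2$never_opened, 1)
})

test_that("rosters round-trip through csv", {
  fx <- make_canonical_fixture()
  for (what in c("alerts", "providers", "patients")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_roster(fx[[what]], path, what)
    expect_equal(as.data.frame(read_roster(path, what)),
                 as.data.frame(fx[[what]]))
  }
})
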