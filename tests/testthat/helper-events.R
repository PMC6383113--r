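# construction helpers: build small, valid event tables in code

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

mk_events <- function(ts, actor_id, action, event_id = NULL,
                      actor_role = "pcp", patient_id = NA_character_,
                      section = NA_character_, order_kind = NA_character_,
                      med_action = NA_character_, alert_id = NA_character_,
                      message_id = NA_character_, is_lab_result = NA) {
  n <- length(ts)
  if (is.null(event_id)) event_id <- sprintf("E%04d", seq_len(n))
  dplyr::arrange(tibble::tibble(
    event_id = event_id, ts = ts,
    actor_id = rep_len(actor_id, n), actor_role = rep_len(actor_role, n),
    patient_id = rep_len(patient_id, n), action = rep_len(action, n),
    section = rep_len(section, n), order_kind = rep_len(order_kind, n),
    med_action = rep_len(med_action, n),
    alert_id = rep_len(alert_id, n), message_id = rep_len(message_id, n),
    is_lab_result = rep_len(is_lab_result, n)), ts, event_id)
}

mk_alert <- function(alert_id = "A1", alert_type = "information_only",
                     pcp_id = "P1", patient_id = "PT1",
                     delivery_ts = ts_utc("2011-03-01 09:00:00")) {
  tibble::tibble(alert_id = alert_id, alert_type = alert_type,
                 pcp_id = pcp_id, patient_id = patient_id,
                 delivery_ts = delivery_ts)
}

# a random small mixed-action window for property tests
random_window_case <- function(target = "PT1", actor = "P1",
                               t0 = ts_utc("2011-03-01 10:00:00")) {
  k <- sample(0:6, 1)
  if (k == 0) {
    w <- mk_events(ts_utc(character()), actor, character())
  } else {
    offs <- sort(sample(1:299, k))
    act <- sample(c("section_view", "order_placed", "alert_opened"), k, TRUE,
                  prob = c(0.6, 0.2, 0.2))
    pat <- sample(c(target, "PT_OTHER"), k, TRUE)
    w <- mk_events(
      t0 + offs, actor, act,
      patient_id = ifelse(act == "alert_opened", NA, pat),
      section = ifelse(act == "section_view",
                       sample(section_codes()[1:6], k, TRUE), NA),
      order_kind = ifelse(act == "order_placed", "laboratory", NA),
      alert_id = ifelse(act == "alert_opened", "A_OTHER", NA))
  }
  list(window = w, t0 = t0, target = target)
}
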