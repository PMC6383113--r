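#' Two-day action window for an alert opening
#'
#' The window for subsequent actions runs from the opening instant through
#' the end of the *following* local calendar day: the upper bound is the
#' second local midnight after the opening day, exclusive. Calendar-day (not
#' 48-hour) semantics: an alert opened Monday 23:59 is still tracked through
#' all of Tuesday.
#'
#' @param first_open_ts POSIXct vector of first-opening times (by any actor).
#' @param tz Clinic timezone.
#' @return A list with POSIXct vectors `start` and `end` (`end` exclusive).
#' @export
action_window <- function(first_open_ts, tz = clinic_tz()) {
  assert_tz_aware(first_open_ts)
  local <- lubridate::with_tz(first_open_ts, tz)
  end_local <- lubridate::floor_date(local, "day") + lubridate::days(2)
  list(start = first_open_ts, end = lubridate::with_tz(end_local, "UTC"))
}

#' Detect general, medication-specific and laboratory-specific actions
#'
#' Scans the addressed PCP's events for the alert's patient inside a window.
#' A *general* action is any chart-section view (including the alert's
#' summary links) or any order. A *medication-specific* action is a
#' medications-section view or a medication order; a *laboratory-specific*
#' action is a laboratory-section view, a results-section view tagged as a
#' laboratory result, or a laboratory order. The specific flags imply the
#' general flag by construction, and all flags are monotone in the event set.
#'
#' @param events A sorted, validated log-event tibble.
#' @param pcp_id The addressed PCP (tracked even when someone else opened the
#'   alert).
#' @param target_patient_id The patient who triggered the alert.
#' @param window_start,window_end Window bounds (`end` exclusive).
#' @return A list of logicals: `general`, `medication_specific`,
#'   `laboratory_specific`.
#' @export
detect_actions <- function(events, pcp_id, target_patient_id, window_start,
                           window_end) {
  sub <- events[events$actor_id == pcp_id &
                  !is.na(events$patient_id) &
                  events$patient_id == target_patient_id &
                  events$action %in% c("section_view", "order_placed") &
                  events$ts >= window_start & events$ts < window_end, ]
  general <- nrow(sub) > 0
  med <- any(sub$action == "section_view" & sub$section == "medications",
             na.rm = TRUE) ||
    any(sub$action == "order_placed" & sub$order_kind == "medication",
        na.rm = TRUE)
  lab <- any(sub$action == "section_view" & sub$section == "laboratory",
             na.rm = TRUE) ||
    any(sub$action == "section_view" & sub$section == "results" &
          sub$is_lab_result %in% TRUE) ||
    any(sub$action == "order_placed" & sub$order_kind == "laboratory",
        na.rm = TRUE)
  list(general = general, medication_specific = med,
       laboratory_specific = lab)
}

#' Track two-day subsequent actions for all opened alerts
#'
#' For every opened alert — irrespective of whether the addressed PCP, staff
#' or another provider opened it first — builds the calendar-day window from
#' the first opening and detects the addressed PCP's actions for the alert's
#' patient inside it.
#'
#' @param events A sorted, validated log-event tibble.
#' @param openings Output of [find_first_openings()].
#' @param tz Clinic timezone.
#' @return A tibble with one row per opened alert: `alert_id`,
#'   `window_start`, `window_end`, `general`, `medication_specific`,
#'   `laboratory_specific`.
#' @export
track_subsequent <- function(events, openings, tz = clinic_tz()) {
  opened <- openings[!openings$never_opened, ]
  win <- action_window(opened$first_open_ts, tz)
  w_start <- as.numeric(win$start)
  w_end <- as.numeric(win$end)

  acts <- events[events$action %in% c("section_view", "order_placed") &
                   !is.na(events$patient_id), ]
  key <- paste(acts$actor_id, acts$patient_id, sep = "\r")
  by_key <- split(seq_len(nrow(acts)), key)
  a_ts <- as.numeric(acts$ts)
  a_med <- (acts$action == "section_view" & !is.na(acts$section) &
              acts$section == "medications") |
    (acts$action == "order_placed" & !is.na(acts$order_kind) &
       acts$order_kind == "medication")
  a_lab <- (acts$action == "section_view" & !is.na(acts$section) &
              (acts$section == "laboratory" |
                 (acts$section == "results" & acts$is_lab_result %in% TRUE))) |
    (acts$action == "order_placed" & !is.na(acts$order_kind) &
       acts$order_kind == "laboratory")

  n <- nrow(opened)
  general <- logical(n)
  med <- logical(n)
  lab <- logical(n)
  keys <- paste(opened$pcp_id, opened$patient_id, sep = "\r")
  for (i in seq_len(n)) {
    rows <- by_key[[keys[i]]]
    if (is.null(rows)) next
    inw <- rows[a_ts[rows] >= w_start[i] & a_ts[rows] < w_end[i]]
    if (length(inw) == 0) next
    general[i] <- TRUE
    med[i] <- any(a_med[inw])
    lab[i] <- any(a_lab[inw])
  }
  tibble::tibble(
    alert_id = opened$alert_id, window_start = win$start,
    window_end = win$end, general = general, medication_specific = med,
    laboratory_specific = lab)
}
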