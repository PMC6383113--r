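#' Extract an actor's actions in the 5-minute window after an opening
#'
#' Returns the events performed by `actor_id` in the half-open window
#' `[t_open, t_open + window_secs)`, excluding the triggering `alert_opened`
#' event itself and excluding passive delivery events (`alert_delivered`,
#' `message_delivered`), which are not actions taken by the actor.
#'
#' @param events A sorted, validated log-event tibble.
#' @param actor_id The acting provider.
#' @param t_open Window anchor (the first opening by the addressed PCP).
#' @param window_secs Window length in seconds (default 300).
#' @param trigger_alert_id Alert whose opening anchors the window; its
#'   `alert_opened` event at `t_open` is excluded.
#' @return The qualifying events, in log order.
#' @export
extract_window <- function(events, actor_id, t_open, window_secs = 300,
                           trigger_alert_id = NULL) {
  w <- events[events$actor_id == actor_id &
                events$ts >= t_open &
                events$ts < t_open + window_secs &
                !events$action %in% c("alert_delivered", "message_delivered"), ]
  if (!is.null(trigger_alert_id)) {
    trig <- w$action == "alert_opened" & !is.na(w$alert_id) &
      w$alert_id == trigger_alert_id & w$ts == t_open
    w <- w[!trig, ]
  }
  w
}

#' Classify the first action in an immediate window
#'
#' The first action is *relevant* when it is a chart-section view (including
#' the alert's direct summary links) or an order placed for the patient who
#' triggered the alert. Non-relevant first actions are subcategorized as
#' opening a notification about a different patient
#' (`other_patient_notification`), entering a different patient's chart
#' (`other_patient_chart`), or doing nothing further for the whole window
#' (`no_action`). Order placement for the target patient counts as relevant:
#' it is an action inside that patient's record.
#'
#' @param window Events from [extract_window()].
#' @param target_patient_id The patient who triggered the alert.
#' @return A list with `relevant` (logical) and `category` (character: the
#'   section code or `order_<kind>` when relevant, otherwise the
#'   non-relevant subcategory).
#' @export
classify_first_action <- function(window, target_patient_id) {
  if (nrow(window) == 0) {
    return(list(relevant = FALSE, category = "no_action"))
  }
  first <- window[1, ]
  acting <- first$action %in% c("section_view", "order_placed")
  same_patient <- !is.na(first$patient_id) &&
    first$patient_id == target_patient_id
  if (acting && same_patient) {
    category <- if (first$action == "section_view") first$section
    else paste0("order_", first$order_kind)
    return(list(relevant = TRUE, category = category))
  }
  category <- if (acting) "other_patient_chart" else "other_patient_notification"
  list(relevant = FALSE, category = category)
}

#' Attribute viewing time within an immediate window
#'
#' Access logs record openings, not closings, so each on-screen duration is
#' estimated as the gap to the actor's next logged event, truncated at the
#' window end. `alert_display_seconds` runs from the opening to the actor's
#' first subsequent event (any patient), capped at the window length;
#' `relevant_patient_seconds` sums the spans whose current event is a
#' section view of the target patient. `total_seconds` is their sum.
#'
#' @inheritParams classify_first_action
#' @param t_open Window anchor.
#' @param target_patient_id The patient who triggered the alert.
#' @param window_secs Window length in seconds.
#' @return A list with integer `alert_display_seconds`,
#'   `relevant_patient_seconds` and `total_seconds`, all in `[0, window_secs]`.
#' @export
attribute_time <- function(window, t_open, target_patient_id,
                           window_secs = 300) {
  w_end <- as.numeric(t_open) + window_secs
  if (nrow(window) == 0) {
    return(list(alert_display_seconds = as.integer(window_secs),
                relevant_patient_seconds = 0L,
                total_seconds = as.integer(window_secs)))
  }
  t <- as.numeric(window$ts)
  display <- min(t[1] - as.numeric(t_open), window_secs)
  ends <- c(t[-1], w_end)
  rel_view <- window$action == "section_view" &
    !is.na(window$patient_id) & window$patient_id == target_patient_id
  rel <- sum(pmax(ends - t, 0)[rel_view])
  list(alert_display_seconds = as.integer(round(display)),
       relevant_patient_seconds = as.integer(round(rel)),
       total_seconds = as.integer(round(display + rel)))
}

#' Track immediate actions for all PCP-opened alerts
#'
#' Applies the 5-minute-window pipeline to every alert whose first opening
#' was by the addressed PCP (alerts first opened by staff or another provider
#' are out of scope for the immediate analysis). An alert is non-evaluable
#' (`evaluable = FALSE`) when its window holds no events *and* the log holds
#' no event by that actor at or after the window end — i.e. the log coverage
#' for that actor ends with the opening, so no display-time estimate exists.
#'
#' @param events A sorted, validated log-event tibble.
#' @param openings Output of [find_first_openings()].
#' @param window_secs Window length in seconds.
#' @return A tibble with one row per PCP-first-opened alert: `alert_id`,
#'   `evaluable`, `relevant`, `first_action_category`,
#'   `alert_display_seconds`, `relevant_patient_seconds`, `total_seconds`
#'   (durations `NA` when not evaluable).
#' @export
track_immediate <- function(events, openings, window_secs = 300) {
  anchor <- openings[!is.na(openings$opened_by_pcp) & openings$opened_by_pcp, ]
  n <- nrow(anchor)
  # flat vectors + per-actor index for speed; events are already sorted
  ev_ts <- as.numeric(events$ts)
  ev_action <- events$action
  ev_patient <- events$patient_id
  ev_alert <- events$alert_id
  ev_section <- events$section
  ev_order <- events$order_kind
  actor_rows <- split(seq_len(nrow(events)), events$actor_id)
  a_open <- as.numeric(anchor$first_open_ts)

  evaluable <- logical(n)
  relevant <- rep(NA, n)
  category <- rep(NA_character_, n)
  display <- rep(NA_integer_, n)
  rel_secs <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    t0 <- a_open[i]
    target <- anchor$patient_id[i]
    rows <- actor_rows[[anchor$pcp_id[i]]]
    ts_a <- ev_ts[rows]
    win <- rows[ts_a >= t0 & ts_a < t0 + window_secs]
    keep <- !(ev_action[win] %in% c("alert_delivered", "message_delivered")) &
      !(ev_action[win] == "alert_opened" & !is.na(ev_alert[win]) &
          ev_alert[win] == anchor$alert_id[i] & ev_ts[win] == t0)
    win <- win[keep]
    if (length(win) == 0) {
      if (!any(ts_a >= t0 + window_secs)) next  # log coverage ends here
      evaluable[i] <- TRUE
      relevant[i] <- FALSE
      category[i] <- "no_action"
      display[i] <- as.integer(window_secs)
      rel_secs[i] <- 0L
      next
    }
    evaluable[i] <- TRUE
    acting <- ev_action[win[1]] %in% c("section_view", "order_placed")
    same_pt <- !is.na(ev_patient[win[1]]) && ev_patient[win[1]] == target
    if (acting && same_pt) {
      relevant[i] <- TRUE
      category[i] <- if (ev_action[win[1]] == "section_view") ev_section[win[1]]
      else paste0("order_", ev_order[win[1]])
    } else {
      relevant[i] <- FALSE
      category[i] <- if (acting) "other_patient_chart"
      else "other_patient_notification"
    }
    t <- ev_ts[win]
    display[i] <- as.integer(round(min(t[1] - t0, window_secs)))
    ends <- c(t[-1], t0 + window_secs)
    rel_view <- ev_action[win] == "section_view" &
      !is.na(ev_patient[win]) & ev_patient[win] == target
    rel_secs[i] <- as.integer(round(sum(pmax(ends - t, 0)[rel_view])))
  }
  tibble::tibble(
    alert_id = anchor$alert_id, evaluable = evaluable, relevant = relevant,
    first_action_category = category, alert_display_seconds = display,
    relevant_patient_seconds = rel_secs,
    total_seconds = display + rel_secs)
}
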