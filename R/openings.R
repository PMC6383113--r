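#' Categorize opening delay relative to delivery
#'
#' Delay is measured in exact seconds between delivery and opening. Bin
#' boundaries at exactly 24 h and 48 h resolve to the earlier bin, i.e. the
#' bins are `<=24h`, `(24h, 48h]`, `>48h`.
#'
#' @param delivery_ts,open_ts POSIXct vectors (recycled to common length).
#' @return A factor with levels `"<=24h"`, `"24-48h"`, `">48h"`.
#' @export
classify_delay <- function(delivery_ts, open_ts) {
  delta <- as.numeric(difftime(open_ts, delivery_ts, units = "secs"))
  if (any(delta < 0, na.rm = TRUE)) {
    rlang::abort("opening precedes delivery", class = "alertlog_consistency_error")
  }
  cut(delta, breaks = c(-Inf, 86400, 172800, Inf),
      labels = c("<=24h", "24-48h", ">48h"), right = TRUE)
}

#' Fine-grained opening-delay categories
#'
#' A coarser-to-finer companion of [classify_delay()]: splits the first day
#' at one hour (`<=1h`, `1-24h`, `>24h`), the alternative categorization used
#' when summarizing immediate actions. Both categorizations are emitted by
#' [find_first_openings()].
#'
#' @inheritParams classify_delay
#' @return A factor with levels `"<=1h"`, `"1-24h"`, `">24h"`.
#' @export
classify_delay_fine <- function(delivery_ts, open_ts) {
  delta <- as.numeric(difftime(open_ts, delivery_ts, units = "secs"))
  if (any(delta < 0, na.rm = TRUE)) {
    rlang::abort("opening precedes delivery", class = "alertlog_consistency_error")
  }
  cut(delta, breaks = c(-Inf, 3600, 86400, Inf),
      labels = c("<=1h", "1-24h", ">24h"), right = TRUE)
}

assert_tz_aware <- function(ts) {
  if (!inherits(ts, "POSIXct")) {
    rlang::abort("timestamp must be a timezone-aware POSIXct",
                 class = "alertlog_validation_error")
  }
  invisible(ts)
}

#' Is a timestamp within office hours?
#'
#' Office hours are Monday through Friday, 08:00:00 (inclusive) to 17:00:00
#' (exclusive), evaluated in the clinic-local timezone. The half-open
#' interval avoids double counting the 5 PM boundary.
#'
#' @param ts A POSIXct vector.
#' @param tz Clinic timezone (default [clinic_tz()]).
#' @return A logical vector.
#' @export
is_office_hours <- function(ts, tz = clinic_tz()) {
  assert_tz_aware(ts)
  local <- lubridate::with_tz(ts, tz)
  wd <- lubridate::wday(local, week_start = 1)  # 1 = Monday
  secs <- lubridate::hour(local) * 3600 + lubridate::minute(local) * 60 +
    lubridate::second(local)
  wd <= 5 & secs >= 8 * 3600 & secs < 17 * 3600
}

#' Was an alert delivered on a Saturday?
#'
#' Saturday deliveries are the only ones for which the first 24 hours after
#' delivery contain no weekday time, so they are flagged as a delivery-context
#' covariate.
#'
#' @inheritParams is_office_hours
#' @return A logical vector.
#' @export
is_saturday_delivery <- function(ts, tz = clinic_tz()) {
  assert_tz_aware(ts)
  lubridate::wday(lubridate::with_tz(ts, tz), week_start = 1) == 6
}

#' Find the first opening of each alert and its context
#'
#' For every alert, locates the earliest `alert_opened` event (any actor) and
#' the earliest one by the addressed PCP, attributes the opener, and derives
#' the delay categories, office-hours flag (of the first opening) and
#' Saturday-delivery flag. Alerts with no opening event are returned with
#' `never_opened = TRUE` and empty optional fields; downstream stages exclude
#' them.
#'
#' @param events A sorted, validated log-event tibble.
#' @param alerts An alert roster tibble.
#' @param tz Clinic timezone for the context flags.
#' @return A tibble with one row per alert: identifiers, `never_opened`,
#'   `first_open_ts`, `first_opener_id`, `opened_by_pcp`, `first_pcp_open_ts`,
#'   `delay_category`, `delay_category_fine`, `within_office_hours`,
#'   `saturday_delivery`.
#' @export
find_first_openings <- function(events, alerts, tz = clinic_tz()) {
  opens <- events[events$action == "alert_opened", ]
  opens <- dplyr::inner_join(
    opens, alerts[, c("alert_id", "pcp_id", "delivery_ts")], by = "alert_id")
  if (any(opens$ts < opens$delivery_ts)) {
    bad <- opens$alert_id[opens$ts < opens$delivery_ts][1]
    rlang::abort(sprintf("alert %s has an opening before its delivery", bad),
                 class = "alertlog_consistency_error")
  }
  opens <- dplyr::arrange(opens, .data$ts, .data$event_id)
  first_any <- opens |>
    dplyr::group_by(.data$alert_id) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("alert_id", first_open_ts = "ts", first_opener_id = "actor_id")
  first_pcp <- opens[opens$actor_id == opens$pcp_id, ] |>
    dplyr::group_by(.data$alert_id) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("alert_id", first_pcp_open_ts = "ts")

  out <- alerts |>
    dplyr::select("alert_id", "alert_type", "pcp_id", "patient_id",
                  "delivery_ts") |>
    dplyr::left_join(first_any, by = "alert_id") |>
    dplyr::left_join(first_pcp, by = "alert_id")
  out$never_opened <- is.na(out$first_open_ts)
  out$opened_by_pcp <- !out$never_opened &
    out$first_opener_id == out$pcp_id
  out$opened_by_pcp[out$never_opened] <- NA
  out$delay_category <- classify_delay(out$delivery_ts, out$first_open_ts)
  out$delay_category_fine <- classify_delay_fine(out$delivery_ts,
                                                 out$first_open_ts)
  out$within_office_hours <- NA
  opened <- !out$never_opened
  out$within_office_hours[opened] <-
    is_office_hours(out$first_open_ts[opened], tz)
  out$saturday_delivery <- is_saturday_delivery(out$delivery_ts, tz)
  out
}
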