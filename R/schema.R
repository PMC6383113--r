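#' Controlled vocabularies for the event-log schema
#'
#' The schema models a unified EHR access/audit-log stream: every record is one
#' time-stamped action by one actor, discriminated by `action`. Alert and
#' InBasket-message lifecycle events, chart-section views, and order placements
#' share the same stream so that window logic can operate on a single sorted
#' collection.
#'
#' @return A character vector of admissible values.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
log_actions <- function() {
  c("alert_delivered", "alert_opened", "section_view", "order_placed",
    "message_delivered", "message_opened", "message_completed",
    "message_postponed")
}

#' @rdname vocabularies
#' @export
section_codes <- function() {
  c("medications", "laboratory", "orders", "results", "encounters",
    "demographics", "other_clinical", "nonclinical", "info_entry",
    "alert_link_summary")
}

#' @rdname vocabularies
#' @export
alert_types <- function() {
  c("information_only", "medication_recommendation", "test_recommendation")
}

#' @rdname vocabularies
#' @export
actor_roles <- function() {
  c("pcp", "staff", "other_provider")
}

# column order and prototypes shared by readers, writers and generators
event_columns <- function() {
  c("event_id", "ts", "actor_id", "actor_role", "patient_id", "action",
    "section", "order_kind", "med_action", "alert_id", "message_id",
    "is_lab_result")
}

empty_events <- function() {
  tibble::tibble(
    event_id = character(), ts = as.POSIXct(character(), tz = "UTC"),
    actor_id = character(), actor_role = character(),
    patient_id = character(), action = character(), section = character(),
    order_kind = character(), med_action = character(),
    alert_id = character(), message_id = character(),
    is_lab_result = logical()
  )
}

#' Default clinic timezone
#'
#' All office-hours, Saturday and calendar-day window logic is evaluated in a
#' single clinic-local timezone; timestamps themselves are stored in UTC.
#' Override globally with `options(alertlog.tz = ...)` or per call via the
#' `tz` argument of the relevant functions.
#'
#' @return A timezone name (default `"America/New_York"`).
#' @export
clinic_tz <- function() {
  getOption("alertlog.tz", "America/New_York")
}

#' Read a YAML configuration for schema and timezone options
#'
#' A minimal configuration file holds the clinic timezone and (optionally)
#' model parameters for the simulators. Only the `timezone` key is
#' interpreted by the package itself.
#'
#' @param path Path to a YAML file.
#' @return A named list; `$timezone` defaults to [clinic_tz()] when absent.
#' @export
read_clinic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$timezone)) cfg$timezone <- clinic_tz()
  cfg
}

ts_format <- "%Y-%m-%dT%H:%M:%S%z"

format_ts <- function(ts) format(ts, ts_format, tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & x != ""
  out[ok] <- as.POSIXct(strptime(x[ok], ts_format, tz = "UTC"))
  out
}

#' Validate a log-event table against the schema invariants
#'
#' Checks column presence, closed vocabularies, uniqueness of `event_id`,
#' parseable timestamps, and the conditional-field invariants (`section`
#' present iff the action is a section view, order fields present iff an order
#' was placed, `alert_id` present iff the action is an alert event,
#' `message_id` present iff the action is a message lifecycle event, and the
#' laboratory-result tag only on results-section views).
#'
#' @param events A tibble of log events.
#' @param context Optional string (e.g. a file name) prefixed to error
#'   messages.
#' @return `events`, invisibly, if valid; otherwise an error listing each
#'   offending row and field.
#' @export
validate_events <- function(events, context = NULL) {
  problems <- event_problems(events)
  if (nrow(problems) > 0) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    msg <- paste0(
      "Invalid log events", where, ":\n",
      paste(utils::head(sprintf("  record %d, field '%s': %s",
                                problems$row, problems$field,
                                problems$message), 10L),
            collapse = "\n"),
      if (nrow(problems) > 10) sprintf("\n  ... and %d more", nrow(problems) - 10L) else ""
    )
    rlang::abort(msg, class = "alertlog_validation_error")
  }
  invisible(events)
}

event_problems <- function(events) {
  probs <- list()
  note <- function(rows, field, message) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = as.integer(rows), field = field, message = message)
    }
  }
  missing_cols <- setdiff(event_columns(), names(events))
  if (length(missing_cols) > 0) {
    return(tibble::tibble(row = 0L, field = missing_cols,
                          message = "required column is missing"))
  }
  n <- nrow(events)
  if (n == 0) return(tibble::tibble(row = integer(), field = character(),
                                    message = character()))

  note(which(is.na(events$event_id) | events$event_id == ""),
       "event_id", "missing identifier")
  dup <- duplicated(events$event_id) & !is.na(events$event_id)
  note(which(dup), "event_id", "duplicate event_id")
  note(which(is.na(events$ts)), "ts", "timestamp missing or unparseable")
  note(which(is.na(events$actor_id) | events$actor_id == ""),
       "actor_id", "missing actor")
  note(which(!events$actor_role %in% actor_roles()),
       "actor_role", "unknown actor role")
  bad_action <- !events$action %in% log_actions()
  note(which(bad_action), "action", "unknown action value")

  is_view <- !bad_action & events$action == "section_view"
  note(which(is_view & is.na(events$section)),
       "section", "section required for section_view")
  note(which(is_view & !is.na(events$section) &
               !events$section %in% section_codes()),
       "section", "unknown section code")
  note(which(!is_view & !is.na(events$section)),
       "section", "section only allowed for section_view")

  is_order <- !bad_action & events$action == "order_placed"
  note(which(is_order & is.na(events$order_kind)),
       "order_kind", "order_kind required for order_placed")
  note(which(is_order & !is.na(events$order_kind) &
               !events$order_kind %in% c("medication", "laboratory")),
       "order_kind", "unknown order kind")
  note(which(!is_order & !is.na(events$order_kind)),
       "order_kind", "order_kind only allowed for order_placed")
  is_med_order <- is_order & !is.na(events$order_kind) &
    events$order_kind == "medication"
  note(which(is_med_order & is.na(events$med_action)),
       "med_action", "med_action required for medication orders")
  note(which(is_med_order & !is.na(events$med_action) &
               !events$med_action %in% c("new", "change", "discontinue")),
       "med_action", "unknown medication action")
  note(which(!is_med_order & !is.na(events$med_action)),
       "med_action", "med_action only allowed for medication orders")

  is_alert <- !bad_action & events$action %in% c("alert_delivered", "alert_opened")
  note(which(is_alert & is.na(events$alert_id)),
       "alert_id", "alert_id required for alert events")
  note(which(!is_alert & !is.na(events$alert_id)),
       "alert_id", "alert_id only allowed for alert events")

  is_msg <- !bad_action & events$action %in%
    c("message_delivered", "message_opened", "message_completed",
      "message_postponed")
  note(which(is_msg & is.na(events$message_id)),
       "message_id", "message_id required for message events")
  note(which(!is_msg & !is.na(events$message_id)),
       "message_id", "message_id only allowed for message events")

  is_results <- is_view & !is.na(events$section) & events$section == "results"
  note(which(!is_results & !is.na(events$is_lab_result)),
       "is_lab_result", "is_lab_result only allowed for results-section views")

  if (length(probs) == 0) {
    tibble::tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  }
}

sort_events <- function(events) {
  dplyr::arrange(events, .data$ts, .data$event_id)
}

coerce_events <- function(df) {
  for (col in event_columns()) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "is_lab_result") NA else NA_character_
    }
  }
  df <- df[event_columns()]
  if (!inherits(df$ts, "POSIXct")) df$ts <- parse_ts(as.character(df$ts))
  chr_cols <- setdiff(event_columns(), c("ts", "is_lab_result"))
  for (col in chr_cols) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  df$is_lab_result <- as.logical(df$is_lab_result)
  tibble::as_tibble(df)
}

#' Read an event log from JSONL or CSV
#'
#' Events are returned sorted by `(ts, event_id)` — timestamps have 1-second
#' resolution so ties are common, and the lexicographic `event_id` tiebreak
#' makes downstream window logic deterministic. All schema invariants are
#' enforced; malformed records abort with the offending record and field.
#'
#' @param path Path to the log file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (RFC 4180,
#'   header row, UTF-8).
#' @return A tibble of log events, sorted and validated.
#' @export
read_log <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "alertlog_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_events())
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) {
                        rlang::abort(sprintf("line %d: malformed JSON (%s)",
                                             i, conditionMessage(e)),
                                     class = "alertlog_validation_error")
                      })
      rec[vapply(rec, is.null, logical(1))] <- NA
      tibble::as_tibble(rec)
    })
    df <- dplyr::bind_rows(recs)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (nrow(df) == 0) return(empty_events())
  }
  events <- coerce_events(df)
  validate_events(events, context = path)
  sort_events(events)
}

#' Write an event log to JSONL or CSV
#'
#' Timestamps are serialized as ISO-8601 with an explicit UTC offset; absent
#' optional fields are written as explicit JSON nulls / empty CSV cells so
#' that `read_log(write_log(x))` reproduces `x` field for field.
#'
#' @param events A validated tibble of log events.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_log <- function(events, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  events <- coerce_events(events)
  validate_events(events)
  out <- events
  out$ts <- format_ts(out$ts)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1))
    con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                    error = function(e) rlang::abort(
                      paste0("cannot write: ", path), class = "alertlog_io_error"))
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    tryCatch(readr::write_csv(out, path, na = "", progress = FALSE),
             error = function(e) rlang::abort(
               paste0("cannot write: ", path), class = "alertlog_io_error"))
  }
  invisible(path)
}

roster_specs <- function() {
  list(
    alerts = list(
      cols = c("alert_id", "alert_type", "pcp_id", "patient_id", "delivery_ts"),
      id = "alert_id"),
    providers = list(
      cols = c("provider_id", "age_group", "gender", "specialty",
               "encounters_prior_year"),
      id = "provider_id"),
    patients = list(
      cols = c("patient_id", "age_group", "gender", "charlson_category",
               "length_of_stay_cat", "office_visits_prior_year"),
      id = "patient_id")
  )
}

provider_specialties <- function() {
  c("internal_medicine", "family_medicine", "non_md_pcp", "subspecialty")
}

validate_roster <- function(x, what) {
  spec <- roster_specs()[[what]]
  missing_cols <- setdiff(spec$cols, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("%s roster is missing columns: %s", what,
                         paste(missing_cols, collapse = ", ")),
                 class = "alertlog_validation_error")
  }
  fail <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      rlang::abort(sprintf("%s roster: %s (first at record %d)", what, msg,
                           which(cond)[1]),
                   class = "alertlog_validation_error")
    }
  }
  ids <- x[[spec$id]]
  fail(is.na(ids) | ids == "", "missing identifier")
  fail(duplicated(ids), "duplicate identifier")
  if (what == "alerts") {
    fail(!x$alert_type %in% alert_types(), "unknown alert_type")
    fail(is.na(x$delivery_ts), "missing delivery timestamp")
  }
  if (what == "providers") {
    fail(!x$age_group %in% c("<50", ">=50"), "unknown age_group")
    fail(!x$specialty %in% provider_specialties(), "unknown specialty")
    fail(x$encounters_prior_year < 0, "negative encounter count")
  }
  if (what == "patients") {
    fail(!x$age_group %in% c("65-74", "75-84", ">=85"), "unknown age_group")
    fail(!x$charlson_category %in% c("0", "1", "2", ">=3"),
         "unknown charlson_category")
    fail(!x$length_of_stay_cat %in% c("<=2d", "3d", ">=4d"),
         "unknown length_of_stay_cat")
    fail(x$office_visits_prior_year < 0, "negative visit count")
  }
  invisible(x)
}

#' Read and write roster tables (alerts, providers, patients)
#'
#' Rosters are exchanged as CSV with a mandatory header row. Alert delivery
#' timestamps use the same ISO-8601/UTC-offset convention as event logs.
#'
#' @param path Path to a CSV file.
#' @param what One of `"alerts"`, `"providers"`, `"patients"`.
#' @return A validated tibble.
#' @export
read_roster <- function(path, what = c("alerts", "providers", "patients")) {
  what <- match.arg(what)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "alertlog_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (what == "alerts" && "delivery_ts" %in% names(df)) {
    df$delivery_ts <- parse_ts(df$delivery_ts)
  }
  int_col <- c(alerts = NA, providers = "encounters_prior_year",
               patients = "office_visits_prior_year")[[what]]
  if (!is.na(int_col) && int_col %in% names(df)) {
    df[[int_col]] <- as.integer(df[[int_col]])
  }
  df <- tibble::as_tibble(df)
  validate_roster(df, what)
  df
}

#' @param x A roster tibble.
#' @rdname read_roster
#' @export
write_roster <- function(x, path, what = c("alerts", "providers", "patients")) {
  what <- match.arg(what)
  validate_roster(x, what)
  out <- x
  if (what == "alerts") out$delivery_ts <- format_ts(out$delivery_ts)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Cross-check referential consistency of a cohort
#'
#' Reports (rather than errors on) referential failures: alerts addressed to
#' unknown providers or patients, and alert events referencing unknown
#' alerts. Alerts that were delivered but never opened are tallied
#' separately — they are an expected outcome, not a data failure.
#'
#' @param alerts,providers,patients Roster tibbles.
#' @param events A log-event tibble.
#' @return A list with `problems` (tibble of `kind`, `id`, `detail`),
#'   `never_opened` (count of alerts with no opening event), and `valid`
#'   (`TRUE` when `problems` is empty). Inputs are never mutated.
#' @export
validate_cohort <- function(alerts, providers, patients, events) {
  probs <- list()
  bad_pcp <- !alerts$pcp_id %in% providers$provider_id
  if (any(bad_pcp)) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      kind = "alert_unknown_provider", id = alerts$alert_id[bad_pcp],
      detail = alerts$pcp_id[bad_pcp])
  }
  bad_pt <- !alerts$patient_id %in% patients$patient_id
  if (any(bad_pt)) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      kind = "alert_unknown_patient", id = alerts$alert_id[bad_pt],
      detail = alerts$patient_id[bad_pt])
  }
  ev_alert <- events[!is.na(events$alert_id), ]
  bad_ev <- !ev_alert$alert_id %in% alerts$alert_id
  if (any(bad_ev)) {
    probs[[length(probs) + 1L]] <- tibble::tibble(
      kind = "event_unknown_alert", id = ev_alert$event_id[bad_ev],
      detail = ev_alert$alert_id[bad_ev])
  }
  opened <- unique(events$alert_id[events$action == "alert_opened"])
  never_opened <- sum(!alerts$alert_id %in% opened)
  problems <- if (length(probs) == 0) {
    tibble::tibble(kind = character(), id = character(), detail = character())
  } else {
    dplyr::bind_rows(probs)
  }
  list(problems = problems, never_opened = never_opened,
       valid = nrow(problems) == 0)
}
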