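#' Join stage outputs into one analysis table
#'
#' Inner-joins opening, immediate-action and subsequent-action records (and
#' optional context covariates) on `alert_id` into the row format the
#' bivariate and multivariate analyses consume. Never-opened alerts are
#' excluded with a logged reason; the immediate outcome is populated only
#' for evaluable alerts first opened by the addressed PCP, while the
#' subsequent outcomes cover every opened alert. Row counts at each filter
#' are reported via `message()` so the accounting that leads from all
#' alerts to each analysis population stays visible.
#'
#' @param openings Output of [find_first_openings()].
#' @param immediate Output of [track_immediate()].
#' @param subsequent Output of [track_subsequent()].
#' @param context Optional output of [build_context_covariates()].
#' @return A tibble with one row per opened alert: identifiers, alert type,
#'   opener/delay/office-hours/Saturday context, `immediate_evaluable`,
#'   `immediate_relevant`, the time-attribution columns, and the three
#'   two-day outcome flags.
#' @export
build_analysis_table <- function(openings, immediate, subsequent,
                                 context = NULL) {
  for (nm in c("openings", "immediate", "subsequent")) {
    x <- get(nm)
    if (anyDuplicated(x$alert_id) > 0) {
      rlang::abort(sprintf("duplicate alert_id in %s input", nm),
                   class = "alertlog_validation_error")
    }
  }
  n_all <- nrow(openings)
  rows <- openings[!openings$never_opened, ]
  message(sprintf("%d alerts; %d opened (%d never opened, excluded)",
                  n_all, nrow(rows), n_all - nrow(rows)))
  rows <- dplyr::inner_join(
    rows,
    subsequent[, c("alert_id", "general", "medication_specific",
                   "laboratory_specific")],
    by = "alert_id")
  rows <- dplyr::left_join(rows, immediate, by = "alert_id")
  rows$immediate_evaluable <- !is.na(rows$opened_by_pcp) &
    rows$opened_by_pcp & !is.na(rows$evaluable) & rows$evaluable
  rows$immediate_relevant <- ifelse(rows$immediate_evaluable, rows$relevant,
                                    NA)
  rows$evaluable <- NULL
  rows$relevant <- NULL
  message(sprintf(
    "%d opened by the addressed PCP; %d evaluable for immediate action",
    sum(rows$opened_by_pcp, na.rm = TRUE), sum(rows$immediate_evaluable)))
  if (!is.null(context)) {
    rows <- dplyr::inner_join(
      rows, dplyr::select(context, -dplyr::any_of(
        c("alert_type", "pcp_id", "patient_id", "saturday_delivery"))),
      by = "alert_id")
  }
  if (nrow(rows) == 0) {
    rlang::warn("no alerts shared between the inputs; empty analysis table")
  }
  rows
}

#' Cross-tabulate a binary outcome against a categorical stratifier
#'
#' Produces the counts and column percentages used in the descriptive
#' tables: for each stratifier level, the number of rows, the number with
#' and without the outcome, and each as a percentage of its outcome column.
#'
#' @param rows An analysis table.
#' @param outcome Name of a logical outcome column (rows with `NA` outcome
#'   are dropped).
#' @param stratifier Name of a categorical column.
#' @return A tibble with `level`, `n`, `n_action`, `pct_action`,
#'   `n_no_action`, `pct_no_action`.
#' @export
bivariate_table <- function(rows, outcome, stratifier) {
  y <- rows[[outcome]]
  keep <- !is.na(y)
  rows <- rows[keep, ]
  y <- as.logical(y[keep])
  if (nrow(rows) == 0) {
    rlang::abort("no rows with a non-missing outcome",
                 class = "alertlog_parameter_error")
  }
  tab <- rows |>
    dplyr::mutate(.level = as.character(.data[[stratifier]]),
                  .y = y) |>
    dplyr::group_by(.data$.level) |>
    dplyr::summarise(n = dplyr::n(), n_action = sum(.data$.y),
                     n_no_action = sum(!.data$.y), .groups = "drop")
  tab$pct_action <- 100 * tab$n_action / sum(tab$n_action)
  tab$pct_no_action <- 100 * tab$n_no_action / sum(tab$n_no_action)
  if (sum(tab$n_action) == 0) tab$pct_action <- 0
  if (sum(tab$n_no_action) == 0) tab$pct_no_action <- 0
  dplyr::select(tab, level = ".level", "n", "n_action", "pct_action",
                "n_no_action", "pct_no_action")
}

#' Render the descriptive and multivariate reports
#'
#' Writes four deterministic reports: an immediate-action bivariate table
#' (counts and column percentages by alert type and context), a
#' time-attribution summary (mean and median seconds in the relevant
#' patient's chart, overall, by action status and by alert type), the
#' adjusted-odds-ratio table for the fitted outcome models, and a plain-text
#' accounting block tracing alerts from delivery through opener class to
#' action status. The multivariate report carries a footer noting that no
#' multiple-testing adjustment is applied.
#'
#' @param rows An analysis table from [build_analysis_table()].
#' @param fits Named list of `alertlog_gee` fits (name = outcome).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the report tibbles/paths.
#' @export
report_tables <- function(rows, fits, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fits)) {
    if (is.null(fits[[nm]])) {
      rlang::abort(sprintf("missing fit for outcome '%s'", nm),
                   class = "alertlog_parameter_error")
    }
  }
  ev <- rows[rows$immediate_evaluable, ]
  t1 <- dplyr::bind_rows(
    dplyr::mutate(bivariate_table(ev, "immediate_relevant", "alert_type"),
                  block = "alert_type"),
    dplyr::mutate(bivariate_table(ev, "immediate_relevant",
                                  "delay_category_fine"),
                  block = "time_to_opening"),
    dplyr::mutate(bivariate_table(ev, "immediate_relevant",
                                  "within_office_hours"),
                  block = "office_hours"))
  readr::write_csv(t1, file.path(out_dir, "table_immediate_bivariate.csv"),
                   progress = FALSE)

  timesum <- function(d, label) {
    tibble::tibble(group = label, n = nrow(d),
                   mean_seconds = mean(d$total_seconds),
                   median_seconds = stats::median(d$total_seconds))
  }
  t2 <- dplyr::bind_rows(
    timesum(ev, "all_evaluable"),
    timesum(ev[ev$immediate_relevant, ], "immediate_action"),
    timesum(ev[!ev$immediate_relevant, ], "no_immediate_action"),
    dplyr::bind_rows(lapply(alert_types(), function(ty)
      timesum(ev[ev$alert_type == ty, ], ty))))
  readr::write_csv(t2, file.path(out_dir, "table_time_attribution.csv"),
                   progress = FALSE)

  t3 <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    dplyr::mutate(or_table(fits[[nm]]), outcome = nm)
  }))
  readr::write_csv(t3, file.path(out_dir, "table_adjusted_or.csv"),
                   progress = FALSE)
  writeLines(
    "Note: no multiple-testing adjustment is applied to these intervals.",
    file.path(out_dir, "table_adjusted_or_footer.txt"))

  acct <- c(
    sprintf("alerts opened: %d", nrow(rows)),
    sprintf("  first opened by addressed PCP: %d",
            sum(rows$opened_by_pcp, na.rm = TRUE)),
    sprintf("    evaluable for immediate action: %d",
            sum(rows$immediate_evaluable)),
    sprintf("      immediate relevant action: %d",
            sum(rows$immediate_relevant, na.rm = TRUE)),
    sprintf("  first opened by staff/other provider: %d",
            sum(!rows$opened_by_pcp, na.rm = TRUE)),
    sprintf("  action by end of following day: %d", sum(rows$general)),
    sprintf("  no timely action: %d", sum(!rows$general)))
  writeLines(acct, file.path(out_dir, "accounting.txt"))
  invisible(list(immediate_bivariate = t1, time_attribution = t2,
                 adjusted_or = t3, accounting = acct))
}
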