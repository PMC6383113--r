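#' Reconstruct a provider's InBasket at a past instant
#'
#' Access logs keep no rolling snapshot of the inbox, so its historical state
#' is rebuilt by replay: assemble every message delivered to the provider in
#' the lookback window ending at `t`, then remove the ones whose record shows
#' a completion — or a postponement to a future date — before `t`. What
#' remains is the inbox content at `t`; the unopened subset has no opening
#' event at or before `t`. Messages older than the lookback horizon are
#' invisible even if still open, a truncation shared with the replay's
#' one-year design.
#'
#' @param events A sorted log-event tibble containing message lifecycle
#'   events (`message_delivered` / `message_opened` / `message_completed` /
#'   `message_postponed`); the recipient provider is the `actor_id`.
#' @param provider_id Provider whose inbox is reconstructed.
#' @param at POSIXct instant of interest (typically an alert delivery time).
#' @param lookback_days Lookback horizon in days (default 365).
#' @return A one-row tibble: `provider_id`, `at`, `total_messages`,
#'   `unopened_messages`, `prior_week_arrivals`.
#' @export
reconstruct_inbasket <- function(events, provider_id, at,
                                 lookback_days = 365) {
  assert_tz_aware(at)
  msg <- events[!is.na(events$message_id) & events$actor_id == provider_id, ]
  deliv <- msg[msg$action == "message_delivered", ]
  life <- msg[msg$action != "message_delivered", ]
  if (nrow(life) > 0) {
    d_ts <- stats::setNames(as.numeric(deliv$ts), deliv$message_id)
    ref <- d_ts[life$message_id]
    if (any(!is.na(ref) & as.numeric(life$ts) < ref)) {
      rlang::abort("message lifecycle event precedes its delivery",
                   class = "alertlog_consistency_error")
    }
  }
  t_num <- as.numeric(at)
  d_num <- as.numeric(deliv$ts)
  cand <- deliv$message_id[d_num >= t_num - lookback_days * 86400 &
                             d_num < t_num]
  gone <- unique(life$message_id[
    life$action %in% c("message_completed", "message_postponed") &
      as.numeric(life$ts) < t_num])
  present <- setdiff(cand, gone)
  opened <- unique(life$message_id[life$action == "message_opened" &
                                     as.numeric(life$ts) <= t_num])
  tibble::tibble(
    provider_id = provider_id, at = at,
    total_messages = length(present),
    unopened_messages = length(setdiff(present, opened)),
    prior_week_arrivals = sum(d_num >= t_num - 7 * 86400 & d_num < t_num))
}

#' InBasket snapshots at each alert's delivery time
#'
#' Convenience wrapper applying [reconstruct_inbasket()] to every alert,
#' using the addressed PCP and the delivery timestamp.
#'
#' @param events Message lifecycle events.
#' @param alerts Alert roster tibble.
#' @param lookback_days Lookback horizon in days.
#' @return A tibble with one snapshot row per alert, keyed by `alert_id`.
#' @export
inbasket_snapshots <- function(events, alerts, lookback_days = 365) {
  snaps <- purrr::map2(alerts$pcp_id, as.list(alerts$delivery_ts),
                       function(p, t) reconstruct_inbasket(events, p, t,
                                                           lookback_days))
  out <- dplyr::bind_rows(snaps)
  out$alert_id <- alerts$alert_id
  dplyr::relocate(out, "alert_id")
}

#' Bin values into empirical quartiles
#'
#' Cut points sit at the 25th/50th/75th empirical percentiles; a value equal
#' to a cut point falls in the lower bin (bins are `<=q1`, `(q1,q2]`,
#' `(q2,q3]`, `>q3`). When ties collapse the cut points, the degenerate bins
#' are merged and a warning is emitted.
#'
#' @param values Numeric vector, at least 4 values.
#' @return A list with `bins` (factor aligned to `values`) and `cuts`
#'   (the three percentile cut points).
#' @export
quartile_bin <- function(values) {
  if (length(values) < 4) {
    rlang::abort("need at least 4 values to form quartiles",
                 class = "alertlog_parameter_error")
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE)
  uq <- unique(q)
  if (length(uq) < 3) {
    rlang::warn("degenerate quartile cut points; bins merged")
  }
  labs <- quartile_labels(uq)
  bins <- cut(values, breaks = c(-Inf, uq, Inf), labels = labs, right = TRUE)
  list(bins = bins, cuts = q)
}

quartile_labels <- function(cuts) {
  k <- length(cuts)
  fmt <- function(x) format(x, trim = TRUE, digits = 10)
  if (k == 0) return("all")
  labs <- paste0("<=", fmt(cuts[1]))
  if (k > 1) {
    labs <- c(labs, paste0("(", fmt(cuts[-k]), ",", fmt(cuts[-1]), "]"))
  }
  c(labs, paste0(">", fmt(cuts[k])))
}

bin_fixed <- function(values, edges) {
  cut(values, breaks = c(-Inf, edges, Inf), labels = quartile_labels(edges),
      right = TRUE)
}

#' Fixed InBasket-load cut points on the canonical fixture scale
#'
#' The quartile edges for the InBasket context covariates at the scale the
#' canonical fixture emulates: total messages at delivery (42/69/157),
#' unopened messages (0/4/9) and prior-week arrivals (344/453/546). Pass
#' this list as `edges` to [build_context_covariates()] to bin on this fixed
#' scale instead of recomputing quartiles.
#'
#' @return A named list of numeric edge vectors.
#' @export
reference_context_edges <- function() {
  list(total = c(42, 69, 157), unopened = c(0, 4, 9),
       prior_week = c(344, 453, 546))
}

#' Assemble per-alert context covariates
#'
#' Joins roster attributes and reconstructed InBasket state into the
#' categorical covariates the analyses consume: InBasket totals, unopened
#' counts and prior-week arrivals (quartile-binned, or binned on fixed
#' edges), provider encounter quartiles (computed across providers, then
#' joined to alerts), patient office-visit categories (fixed edges 6/11/18),
#' the Saturday-delivery flag and all roster categories.
#'
#' @param alerts Alert roster tibble.
#' @param snapshots Output of [inbasket_snapshots()] (one row per alert), or
#'   `NULL` to skip the InBasket covariates.
#' @param providers,patients Roster tibbles.
#' @param edges `NULL` to recompute empirical quartiles for the InBasket
#'   covariates, or a list like [reference_context_edges()].
#' @param tz Clinic timezone for the Saturday flag.
#' @return A tibble with one covariate row per alert, keyed by `alert_id`.
#' @export
build_context_covariates <- function(alerts, snapshots = NULL, providers,
                                     patients, edges = NULL,
                                     tz = clinic_tz()) {
  enc <- quartile_bin(providers$encounters_prior_year)
  prov <- tibble::tibble(
    pcp_id = providers$provider_id,
    pcp_age_group = providers$age_group,
    pcp_gender = providers$gender,
    pcp_specialty = providers$specialty,
    encounter_quartile = as.character(enc$bins))
  pat <- tibble::tibble(
    patient_id = patients$patient_id,
    patient_age_group = patients$age_group,
    patient_gender = patients$gender,
    charlson_category = patients$charlson_category,
    length_of_stay_cat = patients$length_of_stay_cat,
    office_visit_cat = as.character(
      bin_fixed(patients$office_visits_prior_year, c(6, 11, 18))))
  out <- alerts |>
    dplyr::select("alert_id", "alert_type", "pcp_id", "patient_id",
                  "delivery_ts") |>
    dplyr::left_join(prov, by = "pcp_id") |>
    dplyr::left_join(pat, by = "patient_id")
  out$saturday_delivery <- is_saturday_delivery(out$delivery_ts, tz)
  if (!is.null(snapshots)) {
    missing <- setdiff(alerts$alert_id, snapshots$alert_id)
    if (length(missing) > 0) {
      rlang::abort(sprintf("no InBasket snapshot for alert %s", missing[1]),
                   class = "alertlog_validation_error")
    }
    sn <- snapshots
    if (is.null(edges)) {
      sn$inbasket_total_cat <- as.character(quartile_bin(sn$total_messages)$bins)
      sn$inbasket_unopened_cat <- as.character(quartile_bin(sn$unopened_messages)$bins)
      sn$prior_week_cat <- as.character(quartile_bin(sn$prior_week_arrivals)$bins)
    } else {
      sn$inbasket_total_cat <- as.character(bin_fixed(sn$total_messages, edges$total))
      sn$inbasket_unopened_cat <- as.character(bin_fixed(sn$unopened_messages, edges$unopened))
      sn$prior_week_cat <- as.character(bin_fixed(sn$prior_week_arrivals, edges$prior_week))
    }
    out <- dplyr::left_join(
      out,
      sn[, c("alert_id", "inbasket_total_cat", "inbasket_unopened_cat",
             "prior_week_cat")],
      by = "alert_id")
  }
  dplyr::select(out, -"delivery_ts")
}
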