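#' Behavioral model for synthetic clinician responses
#'
#' Collects every parameter that governs how simulated providers respond to
#' alerts. Defaults reproduce the marginal behavior of the cohort the
#' canonical fixture emulates: 78.5\% of first openings by the addressed PCP,
#' a heavy-right-tailed (log-normal, 30-day-truncated) opening delay whose
#' mass matches the observed under-24h / 24-48h / over-48h split, an
#' immediate-action rate of 28.1\% for information-only alerts with
#' log-odds offsets ln(4.03) and ln(2.14) for medication- and
#' test-recommendation alerts, and two-day outcome models on the same
#' pattern. A provider-level normal random intercept (shared across that
#' provider's alerts and outcomes) induces within-PCP clustering; a small
#' probability of end-of-coverage truncation reproduces alerts whose
#' 5-minute window has no usable data.
#'
#' @param ... Named overrides of the top-level defaults (nested lists are
#'   merged element-wise).
#' @return An object of class `alertlog_behavior`.
#' @export
behavior_model <- function(...) {
  defaults <- list(
    opener_mix = 627 / 799,
    never_open_prob = 0,
    missing_window_prob = 11 / 627,
    opening_delay = list(meanlog = 2.85, sdlog = 1.43, cap_hours = 720),
    immediate_logit = list(
      intercept = stats::qlogis(125 / 445),
      offsets = c(medication_recommendation = log(4.03),
                  test_recommendation = log(2.14))),
    subsequent_logits = list(
      general = list(
        intercept = stats::qlogis(382 / 593),
        offsets = c(medication_recommendation = log(2.0),
                    test_recommendation = log(1.7))),
      medication_specific = list(
        intercept = stats::qlogis(95 / 593),
        offsets = c(medication_recommendation = log(5.59),
                    test_recommendation = log(1.71))),
      laboratory_specific = list(
        intercept = stats::qlogis(100 / 593),
        offsets = c(medication_recommendation = log(7.37),
                    test_recommendation = log(2.75)))),
    session_model = list(
      first_gap_meanlog = log(20), first_gap_sdlog = 0.6,
      extra_views_lambda = 2, dwell_meanlog = log(30), dwell_sdlog = 0.8,
      idle_event_prob = 0.9, idle_gap_meanlog = log(15),
      idle_gap_sdlog = 0.6, order_frac = 0.4),
    provider_random_effect_sd = 0.3)
  model <- utils::modifyList(defaults, list(...))
  probs <- c(model$opener_mix, model$never_open_prob,
             model$missing_window_prob, model$session_model$idle_event_prob,
             model$session_model$order_frac)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("behavior probabilities must lie in [0, 1]",
                 class = "alertlog_parameter_error")
  }
  offs <- c(model$immediate_logit$offsets,
            unlist(lapply(model$subsequent_logits, `[[`, "offsets")))
  if (any(!is.finite(offs))) {
    rlang::abort("log-odds offsets must be finite",
                 class = "alertlog_parameter_error")
  }
  if (is.na(model$provider_random_effect_sd) ||
      model$provider_random_effect_sd < 0) {
    rlang::abort("provider_random_effect_sd must be >= 0",
                 class = "alertlog_parameter_error")
  }
  structure(model, class = "alertlog_behavior")
}

#' InBasket traffic model
#'
#' Parameters of the simulated message stream flowing into each provider's
#' inbox: mean weekly arrivals, daily hazards of opening and (after opening)
#' completing a message, and the probability that a message is postponed to
#' return later instead of being completed.
#'
#' @param weekly_arrival_rate Mean messages delivered per provider per week.
#' @param open_prob,complete_prob Per-day hazards of opening / completing.
#' @param postpone_prob Probability a message is postponed rather than
#'   completed.
#' @return An object of class `alertlog_traffic`.
#' @export
traffic_model <- function(weekly_arrival_rate = 450, open_prob = 0.5,
                          complete_prob = 0.3, postpone_prob = 0.05) {
  if (weekly_arrival_rate < 0) {
    rlang::abort("arrival rate must be >= 0", class = "alertlog_parameter_error")
  }
  probs <- c(open_prob, complete_prob, postpone_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("traffic probabilities must lie in [0, 1]",
                 class = "alertlog_parameter_error")
  }
  structure(list(weekly_arrival_rate = weekly_arrival_rate,
                 open_prob = open_prob, complete_prob = complete_prob,
                 postpone_prob = postpone_prob),
            class = "alertlog_traffic")
}

#' Generate a provider/patient/alert cohort
#'
#' Draws rosters with the covariate structure of a year of post-discharge
#' medication alerts: alert types multinomial with the given weights, alerts
#' assigned to providers with replacement (so providers accumulate repeated
#' alerts — the clustering the analysis must respect), and one distinct
#' patient per alert. Fully reproducible from the seed.
#'
#' @param n_providers,n_alerts Cohort sizes.
#' @param type_weights Nonnegative weights for the three alert types
#'   (information only, medication recommendation, test recommendation).
#' @param seed Integer seed.
#' @param start POSIXct start of the delivery horizon.
#' @param horizon_days Length of the delivery horizon in days.
#' @return A list with tibbles `providers`, `patients`, `alerts`.
#' @export
generate_cohort <- function(n_providers, n_alerts,
                            type_weights = c(593, 37, 169) / 799,
                            seed = 1L,
                            start = as.POSIXct("2011-01-01 00:00:00",
                                               tz = "UTC"),
                            horizon_days = 365) {
  if (n_providers < 1 || n_alerts < 1) {
    rlang::abort("need at least one provider and one alert",
                 class = "alertlog_parameter_error")
  }
  if (length(type_weights) != 3 || any(is.na(type_weights)) ||
      any(type_weights < 0) || sum(type_weights) <= 0) {
    rlang::abort("type_weights must be 3 nonnegative values with positive sum",
                 class = "alertlog_parameter_error")
  }
  set.seed(seed)
  pid <- sprintf("P%04d", seq_len(n_providers))
  providers <- tibble::tibble(
    provider_id = pid,
    age_group = sample(c("<50", ">=50"), n_providers, TRUE, c(0.37, 0.63)),
    gender = sample(c("female", "male"), n_providers, TRUE, c(0.33, 0.67)),
    specialty = sample(provider_specialties(), n_providers, TRUE,
                       c(0.35, 0.55, 0.06, 0.04)),
    encounters_prior_year = as.integer(round(stats::runif(n_providers,
                                                          1500, 4300))))
  patients <- tibble::tibble(
    patient_id = sprintf("PT%05d", seq_len(n_alerts)),
    age_group = sample(c("65-74", "75-84", ">=85"), n_alerts, TRUE,
                       c(0.32, 0.44, 0.24)),
    gender = sample(c("female", "male"), n_alerts, TRUE, c(0.52, 0.48)),
    charlson_category = sample(c("0", "1", "2", ">=3"), n_alerts, TRUE,
                               c(0.10, 0.115, 0.148, 0.637)),
    length_of_stay_cat = sample(c("<=2d", "3d", ">=4d"), n_alerts, TRUE,
                                c(0.45, 0.35, 0.20)),
    office_visits_prior_year = as.integer(
      pmin(stats::rpois(n_alerts, 12), 60)))
  alerts <- tibble::tibble(
    alert_id = sprintf("A%05d", seq_len(n_alerts)),
    alert_type = sample(alert_types(), n_alerts, TRUE, type_weights),
    pcp_id = sample(pid, n_alerts, TRUE),
    patient_id = patients$patient_id,
    delivery_ts = start + round(stats::runif(n_alerts, 0,
                                             horizon_days * 86400)))
  list(providers = providers, patients = patients, alerts = alerts)
}

type_offset <- function(spec, types) {
  off <- c(information_only = 0, spec$offsets)
  unname(off[types])
}

#' Generate the alert-response event stream for a cohort
#'
#' For each alert: a delivery event; a first opening by the addressed PCP
#' (with probability `opener_mix`) or a staff member, after a log-normal
#' delay; Bernoulli draws on the logit scale (with the provider random
#' intercept) decide the immediate action and the two-day general,
#' medication-specific and laboratory-specific outcomes, which are realized
#' as section-view and order events inside the corresponding windows. Alerts
#' hit by end-of-coverage truncation (probability `missing_window_prob`, at
#' most one per provider) have their opening placed after the provider's
#' last other logged event and carry no further events, so the immediate
#' stage finds no usable window data for them.
#'
#' @param cohort Output of [generate_cohort()].
#' @param behavior A [behavior_model()].
#' @param seed Integer seed.
#' @param tz Clinic timezone (used for the subsequent-action window bound).
#' @return A sorted, validated log-event tibble.
#' @export
generate_event_streams <- function(cohort, behavior = behavior_model(),
                                   seed = 1L, tz = clinic_tz()) {
  stopifnot(inherits(behavior, "alertlog_behavior"))
  set.seed(seed)
  al <- cohort$alerts
  n <- nrow(al)
  sm <- behavior$session_model

  re <- stats::rnorm(nrow(cohort$providers), 0,
                     behavior$provider_random_effect_sd)
  names(re) <- cohort$providers$provider_id
  re_a <- unname(re[al$pcp_id])

  opener_pcp <- stats::runif(n) < behavior$opener_mix
  never <- stats::runif(n) < behavior$never_open_prob
  delay_s <- round(pmin(stats::rlnorm(n, behavior$opening_delay$meanlog,
                                      behavior$opening_delay$sdlog),
                        behavior$opening_delay$cap_hours) * 3600)
  open_ts <- al$delivery_ts + delay_s
  missing <- opener_pcp & !never &
    stats::runif(n) < behavior$missing_window_prob
  # at most one truncated alert per provider so truncations cannot shadow
  # each other as terminating evidence
  im <- which(missing)
  missing[im[duplicated(al$pcp_id[im])]] <- FALSE

  p_imm <- stats::plogis(behavior$immediate_logit$intercept +
                           type_offset(behavior$immediate_logit,
                                       al$alert_type) + re_a)
  imm <- opener_pcp & !never & !missing & stats::runif(n) < p_imm
  draw_out <- function(spec) {
    p <- stats::plogis(spec$intercept + type_offset(spec, al$alert_type) +
                         re_a)
    !never & !missing & stats::runif(n) < p
  }
  gen <- draw_out(behavior$subsequent_logits$general)
  med <- draw_out(behavior$subsequent_logits$medication_specific)
  lab <- draw_out(behavior$subsequent_logits$laboratory_specific)

  # truncated alerts: opening after every other event by anyone
  if (any(missing)) {
    tail_base <- max(c(as.numeric(al$delivery_ts),
                       as.numeric(open_ts[!missing]))) + 3 * 86400
    open_ts[missing] <- as.POSIXct(
      tail_base + 7200 * seq_len(sum(missing)), tz = "UTC",
      origin = "1970-01-01")
  }

  staff_id <- paste0("S_", al$pcp_id)
  ev <- list()
  add <- function(ts, actor, role, action, patient = NA_character_,
                  section = NA_character_, order_kind = NA_character_,
                  med_action = NA_character_, alert_id = NA_character_,
                  is_lab_result = NA) {
    k <- length(ts)
    if (k == 0) return()
    ev[[length(ev) + 1L]] <<- tibble::tibble(
      ts = ts, actor_id = actor, actor_role = role, action = action,
      patient_id = rep_len(patient, k), section = rep_len(section, k),
      order_kind = rep_len(order_kind, k),
      med_action = rep_len(med_action, k),
      alert_id = rep_len(alert_id, k), message_id = NA_character_,
      is_lab_result = rep_len(is_lab_result, k))
  }

  add(al$delivery_ts, al$pcp_id, "pcp", "alert_delivered",
      alert_id = al$alert_id)
  op <- !never
  add(open_ts[op], ifelse(opener_pcp[op], al$pcp_id[op], staff_id[op]),
      ifelse(opener_pcp[op], "pcp", "staff"), "alert_opened",
      alert_id = al$alert_id[op])

  # immediate relevant: first view of the target patient, then extra views
  ii <- which(imm)
  if (length(ii) > 0) {
    g1 <- pmin(pmax(round(stats::rlnorm(length(ii), sm$first_gap_meanlog,
                                        sm$first_gap_sdlog)), 1), 290)
    first_sec <- ifelse(med[ii], "medications",
                        ifelse(lab[ii], "laboratory", "encounters"))
    add(open_ts[ii] + g1, al$pcp_id[ii], "pcp", "section_view",
        patient = al$patient_id[ii], section = first_sec)
    k_extra <- stats::rpois(length(ii), sm$extra_views_lambda)
    rep_i <- rep(seq_along(ii), k_extra)
    if (length(rep_i) > 0) {
      dwell <- round(stats::rlnorm(length(rep_i), sm$dwell_meanlog,
                                   sm$dwell_sdlog))
      toff <- stats::ave(dwell, rep_i, FUN = cumsum)
      tt <- open_ts[ii][rep_i] + g1[rep_i] + toff
      keep <- as.numeric(tt) < as.numeric(open_ts[ii][rep_i]) + 295
      neutral <- c("encounters", "demographics", "other_clinical",
                   "orders", "info_entry")
      add(tt[keep], al$pcp_id[ii][rep_i][keep], "pcp", "section_view",
          patient = al$patient_id[ii][rep_i][keep],
          section = sample(neutral, sum(keep), TRUE))
    }
  }

  # evaluable but idle: a view of some other patient's chart
  id_idle <- which(opener_pcp & !never & !missing & !imm)
  if (length(id_idle) > 0) {
    hit <- stats::runif(length(id_idle)) < sm$idle_event_prob
    id_idle <- id_idle[hit]
    gap <- pmin(pmax(round(stats::rlnorm(length(id_idle),
                                         sm$idle_gap_meanlog,
                                         sm$idle_gap_sdlog)), 1), 290)
    # charts of patients outside the cohort: never collides with another
    # alert's (pcp, patient) key
    add(open_ts[id_idle] + gap, al$pcp_id[id_idle], "pcp", "section_view",
        patient = paste0("PTX_", al$alert_id[id_idle]),
        section = "encounters")
  }

  # two-day outcomes, realized outside the 5-minute window
  sub_gap <- function(k) round(stats::runif(k, 2 * 3600, 20 * 3600))
  im_med <- which(med)
  if (length(im_med) > 0) {
    as_order <- stats::runif(length(im_med)) < sm$order_frac
    tt <- open_ts[im_med] + sub_gap(length(im_med))
    add(tt[!as_order], al$pcp_id[im_med][!as_order], "pcp", "section_view",
        patient = al$patient_id[im_med][!as_order], section = "medications")
    macts <- sample(c("new", "change", "discontinue"), sum(as_order), TRUE)
    add(tt[as_order], al$pcp_id[im_med][as_order], "pcp", "order_placed",
        patient = al$patient_id[im_med][as_order], order_kind = "medication",
        med_action = macts)
  }
  im_lab <- which(lab)
  if (length(im_lab) > 0) {
    u <- stats::runif(length(im_lab))
    tt <- open_ts[im_lab] + sub_gap(length(im_lab))
    v_lab <- u < 0.4
    v_res <- u >= 0.4 & u < 0.6
    v_ord <- u >= 0.6
    add(tt[v_lab], al$pcp_id[im_lab][v_lab], "pcp", "section_view",
        patient = al$patient_id[im_lab][v_lab], section = "laboratory")
    add(tt[v_res], al$pcp_id[im_lab][v_res], "pcp", "section_view",
        patient = al$patient_id[im_lab][v_res], section = "results",
        is_lab_result = TRUE)
    add(tt[v_ord], al$pcp_id[im_lab][v_ord], "pcp", "order_placed",
        patient = al$patient_id[im_lab][v_ord], order_kind = "laboratory")
  }
  im_gen <- which(gen & !med & !lab & !imm)
  if (length(im_gen) > 0) {
    add(open_ts[im_gen] + sub_gap(length(im_gen)), al$pcp_id[im_gen], "pcp",
        "section_view", patient = al$patient_id[im_gen],
        section = "encounters")
  }

  events <- dplyr::bind_rows(ev)
  events <- dplyr::arrange(events, .data$ts)
  events$event_id <- sprintf("E%07d", seq_len(nrow(events)))
  events <- coerce_events(events)
  validate_events(events)
  events
}

#' Generate InBasket message traffic for a cohort
#'
#' Per provider, messages arrive as a Poisson stream at the weekly rate,
#' then move through their lifecycle: opening after a geometric number of
#' days (daily hazard `open_prob`), followed either by postponement (with
#' probability `postpone_prob`) or completion (daily hazard
#' `complete_prob`). Lifecycle events falling beyond the horizon are not
#' emitted — those messages are still pending when observation ends. The
#' stream is chronologically consistent: no lifecycle event precedes its
#' delivery.
#'
#' @param cohort Output of [generate_cohort()].
#' @param traffic A [traffic_model()].
#' @param horizon_days Days of traffic to generate from `start`; at least
#'   365 is recommended when snapshots with the default one-year lookback
#'   will be taken near the end of the horizon.
#' @param seed Integer seed.
#' @param start POSIXct start of the traffic horizon.
#' @return A sorted, validated log-event tibble of message events.
#' @export
generate_inbasket_traffic <- function(cohort, traffic = traffic_model(),
                                      horizon_days = 365, seed = 1L,
                                      start = as.POSIXct("2010-01-01 00:00:00",
                                                         tz = "UTC")) {
  stopifnot(inherits(traffic, "alertlog_traffic"))
  set.seed(seed)
  pid <- cohort$providers$provider_id
  daily <- traffic$weekly_arrival_rate / 7
  counts <- stats::rpois(length(pid) * horizon_days, daily)
  if (sum(counts) == 0) return(empty_events())
  prov <- rep(rep(pid, each = horizon_days), counts)
  day <- rep(rep(seq_len(horizon_days) - 1L, length(pid)), counts)
  m <- length(prov)
  day_start <- start + day * 86400
  deliver <- day_start + round(stats::runif(m, 0, 86340))
  msg_id <- sprintf("M%07d", seq_len(m))
  horizon_end <- start + horizon_days * 86400

  # day offsets are geometric (0 = same day), times uniform within the day
  open_off <- if (traffic$open_prob > 0) stats::rgeom(m, traffic$open_prob)
  else rep(horizon_days + 1, m)
  open_ts <- day_start + open_off * 86400 + round(stats::runif(m, 0, 86340))
  same <- open_off == 0
  frac <- stats::runif(m)
  open_ts[same] <- deliver[same] + pmax(
    1, round(frac[same] * (86399 - as.numeric(deliver[same] - day_start[same],
                                              units = "secs"))))
  postponed <- stats::runif(m) < traffic$postpone_prob
  done_off <- if (traffic$complete_prob > 0)
    stats::rgeom(m, traffic$complete_prob) else rep(horizon_days + 1, m)
  open_day_start <- day_start + (open_off + (open_ts >= day_start +
                                               (open_off + 1) * 86400)) * 86400
  done_ts <- open_day_start + done_off * 86400 +
    round(stats::runif(m, 0, 86340))
  dsame <- done_off == 0
  dfrac <- stats::runif(m)
  done_ts[dsame] <- open_ts[dsame] + pmax(
    1, round(dfrac[dsame] *
               pmax(1, 86399 - as.numeric(open_ts[dsame] -
                                            open_day_start[dsame],
                                          units = "secs"))))
  done_ts <- pmax(done_ts, open_ts + 1)

  has_open <- open_ts < horizon_end
  has_done <- has_open & done_ts < horizon_end
  ev <- dplyr::bind_rows(
    tibble::tibble(ts = deliver, actor_id = prov, action = "message_delivered",
                   message_id = msg_id),
    tibble::tibble(ts = open_ts[has_open], actor_id = prov[has_open],
                   action = "message_opened", message_id = msg_id[has_open]),
    tibble::tibble(ts = done_ts[has_done], actor_id = prov[has_done],
                   action = ifelse(postponed[has_done], "message_postponed",
                                   "message_completed"),
                   message_id = msg_id[has_done]))
  ev$actor_role <- "pcp"
  ev <- dplyr::arrange(ev, .data$ts)
  ev$event_id <- sprintf("N%07d", seq_len(nrow(ev)))
  ev <- coerce_events(ev)
  validate_events(ev)
  ev
}
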