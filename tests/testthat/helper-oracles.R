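# independent brute-force oracles, deliberately written on different
# principles than the package implementations they check

# interval materialization: every event owns [t_k, next event or window end)
oracle_attribute_time <- function(window, t0, target, W = 300) {
  t0n <- as.numeric(t0)
  if (nrow(window) == 0) {
    return(list(display = W, relevant = 0, total = W))
  }
  t <- as.numeric(window$ts)
  display <- min(t[1] - t0n, W)
  relevant <- 0
  for (k in seq_len(nrow(window))) {
    int_end <- if (k < nrow(window)) t[k + 1] else t0n + W
    is_rel <- window$action[k] == "section_view" &&
      !is.na(window$patient_id[k]) && window$patient_id[k] == target
    if (is_rel) relevant <- relevant + max(int_end - t[k], 0)
  }
  list(display = display, relevant = relevant, total = display + relevant)
}

# filter-all-then-min scan for first openings
oracle_first_opening <- function(events, alert) {
  op <- events[events$action == "alert_opened" & !is.na(events$alert_id) &
                 events$alert_id == alert$alert_id, ]
  if (nrow(op) == 0) return(list(first = NA, opener = NA, pcp_first = NA))
  key <- order(op$ts, op$event_id)
  op <- op[key, ]
  pcp_op <- op[op$actor_id == alert$pcp_id, ]
  list(first = op$ts[1], opener = op$actor_id[1],
       pcp_first = if (nrow(pcp_op) > 0) pcp_op$ts[1] else NA)
}

# stateful forward replay of a mailbox, queried at t
oracle_inbasket <- function(events, provider, t, lookback = 365) {
  ev <- events[events$actor_id == provider & !is.na(events$message_id), ]
  ev <- ev[order(ev$ts, ev$event_id), ]
  delivered <- list()
  present <- character()
  opened <- character()
  tn <- as.numeric(t)
  prior_week <- 0L
  for (k in seq_len(nrow(ev))) {
    tk <- as.numeric(ev$ts[k])
    id <- ev$message_id[k]
    if (ev$action[k] == "message_delivered") {
      if (tk < tn) {
        delivered[[id]] <- tk
        present <- union(present, id)
        if (tk >= tn - 7 * 86400) prior_week <- prior_week + 1L
      }
    } else if (ev$action[k] == "message_opened") {
      if (tk <= tn) opened <- union(opened, id)
    } else {
      if (tk < tn) present <- setdiff(present, id)
    }
  }
  horizon <- tn - lookback * 86400
  in_look <- vapply(present, function(id) delivered[[id]] >= horizon,
                    logical(1))
  present <- present[in_look]
  list(total = length(present),
       unopened = length(setdiff(present, opened)),
       prior_week = prior_week)
}
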