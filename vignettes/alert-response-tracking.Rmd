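---
title: "Measuring clinician responses to noninterruptive alerts from EHR logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clinician responses to noninterruptive alerts from EHR logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alertlog)
```

## The measurement problem

Noninterruptive clinical decision support (CDS) alerts are delivered to a
provider's EHR inbox ("InBasket") rather than popping up during an order.
Whether they work is hard to see from clinical outcomes alone: the relevant
intermediate question is behavioral — did the addressed primary care
physician (PCP) open the alert, and did they then do anything for that
patient? EHR *access logs* (who opened which part of the chart, to the
second) and *audit logs* (what was created, reviewed or changed) contain
exactly this information, but as a raw event stream with no notion of
"response to alert".

`alertlog` turns that stream into analyzable quantities in four steps:

1. **Opening detection** — for each alert, the earliest `alert_opened`
   event and its actor; delivery-context categories (opening delay,
   office hours, Saturday delivery).
2. **Immediate action** — the first action by the addressed PCP in the
   5 minutes after their first opening, classified by whether it concerns
   the alert's patient, plus an estimate of time spent.
3. **Subsequent action** — any qualifying PCP action for that patient from
   the opening through the end of the *following calendar day*, flagged as
   general, medication-specific, and laboratory-specific.
4. **Context reconstruction and inference** — the InBasket state at
   delivery time rebuilt by event replay, and adjusted odds ratios of
   action by alert type from a clustered logistic model.

Because real clinician-level log data cannot be redistributed, the package
also contains a first-class synthetic-data module: a seeded generator with
an explicit behavioral model, and a quota-constructed canonical fixture on
which every counting stage has a known exact answer.

## The event schema

All sources are unified into one stream of `LogEvent` records — one
time-stamped action by one actor, discriminated by an `action` code
(alert delivery/opening, chart-section view, order placement, and the four
message lifecycle events). Section codes form a closed vocabulary
(medications, laboratory, orders, results, encounters, demographics, other
clinical, nonclinical, information entry, plus the alert's own summary
links). Timestamps are stored in UTC at 1-second resolution and sorted with
the lexicographic `event_id` as tiebreak: at this resolution ties are
common, and a deterministic order is what makes window logic and the replay
reconstruction reproducible. All local-time concepts (office hours,
Saturday, "the following day") are evaluated in a single configured clinic
timezone (default `America/New_York`), because they are local-clock
notions while arithmetic on the stream itself stays in UTC.

## Window semantics and numerical choices

Choices the logs do not dictate are fixed as follows, each on the side
that avoids double counting:

* **5-minute window**: half-open `[t_open, t_open + 300 s)`; the
  triggering opening itself and passive delivery events are excluded.
* **Delay bins**: boundaries at exactly 24 h / 48 h fall in the earlier
  bin (`<=24h`, `(24,48]h`, `>48h`); a finer `<=1h` split is also emitted
  since both categorizations are useful descriptively.
* **Office hours**: `[08:00, 17:00)` local, Monday-Friday — inclusive
  start, exclusive end.
* **Two-day window**: from the opening instant to the second local
  midnight after the opening day (calendar-day, not 48-hour, semantics;
  "by the end of the following day"). Daylight-saving transitions are
  handled by doing the day arithmetic on local calendar days.
* **Time attribution**: access logs record openings, not closings, so the
  time an alert stayed on display is estimated by next-event truncation —
  from the opening to the actor's next logged event, capped at 300 s —
  and time on the relevant patient sums the spans whose current event is a
  section view of that patient. Totals are therefore bounded by 300 s and
  exactly additive (`total = display + relevant`), which the tests check
  against an independent interval-materialization oracle.
* **Quartile binning** of context covariates puts values equal to a cut
  point in the lower bin; degenerate (tied) cut points merge bins with a
  warning.

Two interpretation points deserve flagging. An `order_placed` event for
the target patient counts as a *relevant* first action (it is an action
inside that patient's record), and the two-day window starts at the
opening instant rather than at the start of the opening day — actions
earlier the same day do not count. Both are choices among readings the
log data cannot distinguish.

### Evaluability of the immediate window

Some alerts are opened by the addressed PCP and yet yield no usable
5-minute data. The package models this as *end-of-coverage truncation*: an
alert is non-evaluable when its window holds no events **and** the log
holds nothing by that actor at or after the window end, so there is no
terminating event from which any display estimate could be formed. An
empty window with later activity is, by contrast, a genuine "did nothing
for 5 minutes" (display capped at 300 s). The generator reproduces
truncation with `missing_window_prob`, placing at most one truncated
opening per provider after that provider's last other event, so
truncations cannot serve as each other's terminating evidence.

### InBasket replay

The inbox has no historical snapshots, so state at time *t* is rebuilt by
replay: take all messages delivered to the provider in the 365 days before
*t*, drop those completed or postponed before *t*, and count the remainder
(those without an opening event at or before *t* are the unopened subset).
The one-year lookback means a message still pending after more than a year
is invisible — a truncation inherent to the replay design. Comparisons use
full timestamp resolution rather than day resolution for determinism.
Correctness is checked exactly against a naive stateful forward simulation
on 1,000 random traffic streams.

## The clustered logistic model

Several alerts go to the same PCP, so alert-level outcomes are correlated
within provider. Inference uses generalized estimating equations with a
logit link: marginal model
\[
\operatorname{logit}\Pr(Y_{ij} = 1) = \mathbf{x}_{ij}^\top \beta ,
\]
an exchangeable working correlation for alerts within a PCP, and robust
(sandwich) variance estimates, so the standard errors remain valid even if
the working correlation is wrong. No GEE implementation was available in
the dependency set, so the package carries its own Liang-Zeger scoring
loop; its closed-form inverse of the exchangeable correlation reduces all
cluster work to group sums, making fits on tens of thousands of rows take
milliseconds. Three properties pin the implementation down in the tests:
with singleton clusters it reproduces ordinary logistic regression to
high precision; under a no-effect simulation with clustering, robust 95%
intervals cover 1 at nominal rates; and permuting rows or relabeling
clusters leaves estimates unchanged. Confidence intervals are Wald on the
log-odds scale, exponentiated; reference levels mirror the descriptive
tables (information-only alerts, opening within 24 h, opened by
staff/other). No multiple-testing adjustment is applied, and the reports
say so in a footer.

## What the generator emulates — and what it does not

`behavior_model()` collects every behavioral knob, with defaults set once
to the study conditions the package targets: 78.5% of first openings by
the addressed PCP; a log-normal opening delay (`meanlog 2.85`, `sdlog
1.43` on the hours scale, truncated at 30 days) chosen to match the
observed 59/17/24% split at the 24 h/48 h cuts — any positive
right-skewed family would serve, so tests never depend on its exact form;
an immediate-action probability of 28.1% for information-only alerts with
log-odds offsets `ln 4.03` and `ln 2.14` for medication- and
test-recommendation alerts; two-day outcome models with baselines
64.4%/16.0%/16.9% (general / medication-specific / laboratory-specific)
and offsets `ln 2.0`/`ln 1.7`, `ln 5.59`/`ln 1.71`, `ln 7.37`/`ln 2.75`;
a provider-level normal random intercept (SD 0.3 by default) as the
simplest clustering mechanism compatible with a marginal model; and
`missing_window_prob = 11/627`. Session shape (number of extra views,
dwell times) and InBasket traffic (Poisson arrivals at 450 messages per
provider-week, geometric daily opening/completion hazards, 5%
postponement) are stand-ins with no empirical basis beyond scale; they are
isolated in `session_model` and `traffic_model()` so nothing downstream
depends on their specific form.

Two bookkeeping details make the generated streams exactly faithful to the
generating probabilities, which the law-of-large-numbers and
odds-ratio-recovery tests rely on. Outcome draws are realized as events
whose sections match the drawn flags (the immediate first view is a
medications view only when the medication-specific flag was drawn, etc.),
so detected rates equal the model's probabilities; the detected *general*
rate exceeds its own draw probability because any immediate or specific
event also qualifies — the general contrast is therefore descriptive, not
a recovery target. And idle 5-minute windows view charts of out-of-cohort
patients, so they can never masquerade as actions for another alert by
the same provider.

The generator does **not** emulate: clinical content (drug names, lab
values), re-openings beyond the first per actor class, multi-session or
multi-monitor concurrency, actions outside the EHR, or any causal link
between opening and action. Passing tests show the *pipeline* measures
what it claims on streams with this structure; they say nothing about how
messy real vendor logs are to map into the schema (the section vocabulary
deliberately abstracts proprietary audit codes, which an adapter must
translate).

## The canonical fixture

`make_canonical_fixture()` is quota-constructed, not sampled: 799 alerts
(593/37/169 by type) across 75 providers, with exact pre-placed margins —
627 PCP-first openings, 11 truncated windows (all information-only, on 11
distinct providers), immediate relevant actions 125/17/66 of 445/31/140,
two-day general actions 382/29/127 (538 total, 261 none),
medication-specific 95/18/41, laboratory-specific 100/20/60, delay margins
472/137/190 (and 119/252/245 at the finer cuts within the evaluable 616),
304 of 616 openings within office hours, 166 Saturday deliveries. Each
alert occupies its own calendar week, so windows cannot overlap within a
provider and every count is attributable. The seed argument only shuffles
roster covariates over alerts; all margins hold for any seed, and the
default defines the canonical byte-exact dataset. Hard construction is the
point: it turns the whole opening → immediate → subsequent → report chain
into a bit-exact end-to-end test.

```{r fixture}
fx <- make_canonical_fixture()
acct <- pipeline_accounting(fx)
unlist(acct)
```

## Problem sizes used in the shipped experiments

The parameter-recovery experiment (`run_or_recovery()`) uses 20 seeded
cohorts of 75 providers x 800 alerts with the 593:37:169 type mix and no
provider random effect, averaging estimated odds ratios across seeds on
the log scale (the geometric mean — the natural averaging scale for odds
ratios). With only ~37 medication-recommendation alerts per cohort, a
single replicate's odds ratio is noisy (log-scale SD around 0.4); the
20-seed average stabilizes it to a few percent. The estimator-calibration
checks simulate analysis rows directly on the logistic scale (the quantity
under test is the estimator, not the event plumbing): null coverage uses
200 replicates of n = 5,000 over 75 clusters, and the oracle-equivalence
checks use 1,000 random windows and 1,000 random traffic streams. These
sizes keep the whole suite under a few minutes while leaving Monte-Carlo
error well below the tolerances asserted.

## Known limitations

* Display time is an upper-bounded estimate from next-event truncation,
  not true on-screen time.
* Temporal co-occurrence is not causality; the pipeline deliberately
  reports association only.
* The laboratory-specific flag requires the results-section lab tag;
  untagged results views count only toward general action.
* Quartile edges recomputed on small cohorts are unstable; the fixed
  reference edges are provided for comparability.
* The GEE implementation supports the exchangeable and independence
  working structures only — sufficient here, where robust errors do the
  inferential work.
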