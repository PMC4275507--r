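---
title: "The education-and-coaching engine: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The education-and-coaching engine: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcoach)
```

## The problem

Patients with chronic heart failure are asked to carry a large share of
their own care: take medication as prescribed, stay physically active, eat
a low-salt diet, restrict fluids, and watch their symptoms. Adherence to
these behaviors is notoriously poor, and nurse-led counselling does not
scale. `hfcoach` implements an automated education-and-coaching program
for these self-care behaviors as a deterministic, testable rules engine:
questionnaire-driven assessment, tailored education, goal-based weekly
coaching with diary feedback, adherence and relapse tracking — everything
an automated tele-coaching system decides, minus the delivery hardware.

The engine is event-sourced. Everything a patient does is a timestamped
record (questionnaire answer, goal, diary entry, choice, follow-up
answer), and every analysis is a *replay* of those records through a
per-behavior state machine. This has two consequences worth making
explicit: replay is deterministic (the same log always produces the same
states, weekly verdicts, feedback messages and nurse alerts), and every
reported count is derived from engine states, never from annotations
carried alongside the log.

## Assessment: the knowledge-by-behavior matrix

For each of the four coachable behaviors (`physical_activity`,
`low_salt_diet`, `fluid_restriction`, `medication_intake`) the patient
answers behavior items (5-point agree scale) and knowledge items (3
options plus "I don't know"). Scoring is deliberately conservative:

* a behavior is flagged *not performed* if **any** of its behavior items
  is answered below the adherent cutoff (default 4 of 5). Coaching is
  low-harm, so the cheap error is to offer it too often;
* knowledge is flagged *insufficient* if the number of
  wrong-or-don't-know answers exceeds a tolerance (default 0). "I don't
  know" always scores as not correct — the option exists precisely so
  that patients do not guess.

The two flags place the patient in a 2×2 matrix per behavior: area 1
(neither knows nor does — education first, then coaching), area 2 (does
without knowing — education only), area 3 (knows but does not do —
coaching only), area 4 (knows and does — nothing required). Area-1
education is *gating*: the replay engine rejects a first goal before any
education record for that behavior.

The shipped item bank (12 behavior items, 15 knowledge items) is
configuration, not a validated instrument: the scales the program is
modelled on are not reproduced here, and deployments are expected to
supply their own bank in the same shape.

## Readiness: importance and confidence rulers

For each behavior a patient does not perform, readiness to change is
assessed on two 0–10 rulers — perceived importance and confidence — the
standard motivational-interviewing convention. Both thresholds default
to 7, the usual rule-of-thumb boundary on such rulers. Importance is
evaluated first: low importance returns myth/truth messages for the
behavior, otherwise low confidence returns barrier tips, otherwise an
encouragement message. Exactly one category fires per assessment; if both
ratings are low, the importance feedback wins because misconceptions are
the cheaper thing to fix first and the source program lists importance
first.

## Coaching: goals, diaries, weekly verdicts

A coaching week is a fixed 7-day window opened by a goal record. Goals are
behavior-specific: active days per week (1–7) plus a minutes band per
active day (`<=15`, `15-30`, `30-45`, `45-60`) for physical activity; a
daily sodium target of 1–5 g (5 encoding "5 or more") for diet; a daily
limit of 1.5 or 2.0 L for fluids; planned doses per day for medication.

The week is evaluated when its window closes — operationally, at the
first event dated after the window, or at study end. The achievement
predicates:

* **physical activity** — achieved when the number of diary days at or
  above the planned band reaches the planned days. Both dimensions count:
  being active often enough but in shorter sessions than planned misses
  the goal;
* **salt / fluid** — achieved when the daily target was met on at least
  `met_fraction` of the 7 days (default all 7). A day with no diary entry
  counts as not met: the diary is the only evidence the engine has, and
  crediting silence would make the adherence claim vacuous;
* **medication** — achieved when the planned doses were taken on every
  day.

Weekly feedback is a total decision table keyed by the verdict, the
days/minutes shortfalls, and the modal effort rating over active days
(ties resolve toward the harder rating, again the conservative reading):
missed + fewer days + shorter sessions + "too hard" advises a less
ambitious goal; missed + "too easy" suggests retrying or raising the
plan; achieved + "too easy" suggests raising; any other achieved week is
congratulated; any other missed week is encouraged to retry.

## Adherence, continuation, relapse

A patient becomes **adherent** to a behavior on reaching the personal
goal for 2 consecutive weeks within the current coaching spell. The
system acknowledges this and asks whether to continue coaching.
Continuing starts a fresh spell (the 2-week counter resets), and the next
continue/stop prompt arrives only after the goal is again reached twice
in a row — the reading consistent with patients having answered the
prompt repeatedly, once per 2-week achievement.

A patient who stops receives a maintenance questionnaire every 60 days
("2 months" is taken as exactly 60 days). A relapsed patient may resume
coaching (a new spell from the follow-up date) or decline, which is
terminal. Struggling is operationalized as 3 consecutive missed weeks
(the source gives no number; 3 balances alert fatigue against delay) and
raises one nurse alert per missed streak, at the week the streak reaches
the threshold.

All states are per patient-*and*-behavior: the same patient can be in
follow-up for diet while still coaching activity.

## The study fixture

`fixture_study_cohort()` is a hand-scripted, fully deterministic event
log for the 123-patient observational cohort the program was evaluated
on. It is a first-class artifact, not a test convenience: replaying it
through the engine reproduces the published journey tables exactly — per
behavior 50/56/6/6 nonadherent, 35/47/4/4 coaching starters, 28/36/2/4
adherent, the immediate-stop/continue splits, the follow-up tallies, the
distributions of reached activity and sodium goals, and the non-start
reason counts.

Scripting choices, where the published tables leave freedom:

* adherent journeys end their spell `achieved, achieved`; censored
  coaching journeys cycle `missed, achieved, missed` so that no
  accidental adherence occurs (two of them are scripted `missed ×3` to
  exercise nurse alerts);
* the published tables do not list starters who never became adherent;
  their count is forced by arithmetic (e.g. 35 − 28 = 7 for activity) and
  they are scripted as censored in coaching at study end;
* 17 distinct patients cover the 28 non-started behavior slots; the
  overlap composition (2 patients nonadherent to activity+salt+fluid, 2
  to activity+salt+medication, 3 to activity+salt, 8 activity-only, 2
  salt-only) is one of the assignments consistent with the per-behavior
  differences, chosen fixed;
* the reason table holds 20 records for those 17 patients; three patients
  carry a second (technical) reason — reasons are recorded per patient,
  and the published reason counts exceed the patient count;
* one activity patient is scripted with 15 continuation loops, matching
  the reported maximum;
* study-end censoring is an explicit event at day 364 for every patient.

The fixture emulates *recorded journeys*, not human behavior: every
scripted patient keeps a perfect diary inside coaching weeks, dates are
day-granular and regular, and dropout happens only at scripted points.
Passing fixture tests therefore demonstrates that the engine classifies
journeys exactly as the published tables do — not that the engine would
reproduce those tables on messier real-world logs.

## The cohort simulator

`simulate_cohort()` samples journeys from per-behavior transition
probabilities (`cohort_params()`): nonadherence at assessment, coaching
start, weekly achievement, continuation at the first adherent prompt,
per-prompt later stopping, relapse at follow-up, retry after relapse. The
defaults are calibrated to the observed study rates and are configuration,
not constants. Every simulated log is engine-legal by construction and
reproducible from its seed. Parameter recovery is tested on the
unconditioned draws (assessment flags, start decisions, first week of
each spell, first adherent prompt), since the stopping rule truncates
sequences right after successes and would bias a naive all-weeks average
of the weekly achievement probability.

## Numerical and formatting choices

* Table percentages round half away from zero to 1 decimal (50/123
  prints as 40.7); shares of reached goals are quoted as whole
  percentages. Base R's banker's rounding would print some cells
  differently.
* Bands and efforts are ordered scales; band comparison uses the order
  `<=15 < 15-30 < 30-45 < 45-60`.
* Degenerate inputs are errors, not silences: diary entries outside any
  open week, duplicate diary days, a goal while a week is open, a
  coaching event on a behavior that was adherent at assessment, ratings
  out of range, unknown loop diuretics in the eligibility screener, and
  malformed or out-of-order event-log lines (reported with their line
  number) all fail loudly.
* An empty log yields an all-zero transition table rather than an error;
  a replay without any questionnaire records is an error, since nothing
  can be assessed.

## Problem sizes

The test suite replays the 123-patient fixture (about 6,000 events,
under a second), exercises property suites with 1,000 randomized cases
where sequences are cheap, and runs one 5,000-patient simulation
(~450,000 events, about a minute end-to-end) to check that empirical
transition frequencies recover the generating parameters within three
standard errors. These sizes were chosen so the whole suite completes in
a couple of minutes while keeping the binomial standard errors small
enough for 3-SE checks to be meaningful.

## Limitations

The engine models the decision logic of an automated coaching program,
not its delivery or its patients: no reminder scheduling, no media
content (content is identifier + stub), no vital-sign telemonitoring, no
nurse dashboard beyond alert records, and no statistical inference on the
journey tables (the underlying study reported none). Everything rests on
self-report — a diary entry is taken at face value, as it was in the
program itself.
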