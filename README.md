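# hfcoach

An automated **education-and-coaching engine for heart-failure
self-care**, built as a deterministic, event-sourced rules engine in R.

Patients with heart failure are asked to manage much of their own care —
take medication as prescribed, stay physically active, eat a low-salt
diet, restrict fluids — and adherence is poor. Tele-coaching systems
address this with questionnaire-driven assessment, tailored education,
and goal-based weekly coaching. `hfcoach` implements that program logic
end to end for researchers and engineers who want to study, test, or
re-analyze such a program: every patient interaction is a timestamped
event record, and every analysis is a replay of those records through a
per-behavior state machine.

## The model

For each coachable behavior *b*, questionnaire scoring yields two flags —
*does(b)* (no behavior item answered below the adherent cutoff) and
*knows(b)* (wrong-or-don't-know answers within tolerance) — which place
the patient in a 2×2 matrix: area 1 (¬does ∧ ¬knows → education, then
coaching), area 2 (does ∧ ¬knows → education), area 3 (¬does ∧ knows →
coaching), area 4 (does ∧ knows → nothing). Before coaching, importance
and confidence are rated on 0–10 motivational-interviewing rulers
(threshold 7, importance first) to select myth/truth, barrier-tip, or
encouragement feedback.

Coaching proceeds in 7-day goal windows with daily diary entries. A
physical-activity week with planned days *d* and minutes band *m* is
**achieved** iff `#{days with band ≥ m} ≥ d`; salt/fluid weeks require
the target met on all 7 days (configurable); medication weeks require the
planned doses every day. A patient becomes **adherent** on two
consecutive achieved weeks, then chooses to continue (fresh spell) or
stop; stopped patients get a follow-up questionnaire every 60 days, with
relapse offering a return to coaching. Three consecutive missed weeks
raise a nurse alert. The full journey state machine is

```
nonadherent → ic_assessed → coaching → adherent → {continued_coaching | stopped_after_adherent}
continued_coaching → coaching          stopped_after_adherent → {followup_maintained | relapsed_recoaching → coaching | relapsed_stopped}
```

with study-end censoring resolving pre-coaching states to
`never_started_coaching`.

The package also ships an eligibility screener (NT-proBNP thresholds by
rhythm, loop-diuretic furosemide-equivalence, advanced/unstable disease),
a stochastic cohort simulator driven by per-behavior transition
probabilities, a deterministic 123-patient study fixture, journey-table
reporting, and a CLI (`exec/hfcoach`).

## Worked example

```r
library(hfcoach)

events <- fixture_study_cohort()   # 123 patients, ~6,000 events
rep    <- replay_journeys(events)  # drive every journey through the engine
glance(rep)
#> # A tibble: 1 × 7
#>   n_patients n_journeys n_nonadherent n_started n_adherent n_weeks n_alerts
#> 1        123        492           118        90         70     321        2

transition_table(rep)
#>  row                 physical_activity low_salt_diet fluid_restriction medication_intake
#>  were_nonadherent    50/123 (40.7)     56/123 (45.5) 6/123 (4.9)       6/123 (4.9)
#>  started_coaching    35/50 (70.0)      47/56 (83.9)  4/6 (66.7)        4/6 (66.7)
#>  became_adherent     28/35 (80.0)      36/47 (76.6)  2/4 (50.0)        4/4 (100.0)
#>  stopped_immediately 11/28 (39.3)      23/36 (63.9)  1/2 (50.0)        1/4 (25.0)
#>  continued_coaching  17/28 (60.7)      13/36 (36.1)  1/2 (50.0)        3/4 (75.0)
#>  stopped_later       9/17 (52.9)       6/13 (46.2)   0/1 (0.0)         1/3 (33.3)
#>  continued_until_end 8/17 (47.1)       7/13 (53.8)   1/1 (100.0)       2/3 (66.7)

aggregate_goal_share(goal_distribution(rep, "physical_activity"), days >= 4)
#> # A tibble: 1 × 3
#>   count total   pct
#> 1    17    28    61
```

Reading: of 123 patients, 50 (40.7%) reported not being physically
active; 35 of those 50 (70%) completed the importance/confidence
assessment and set a first goal; 28 of 35 (80%) reached their personal
goal for 2 consecutive weeks; and of those, 17 continued coaching while
11 stopped. Among the 28 who became adherent, 17 (61%) had reached a goal
of being active on at least 4 days per week. All of these numbers come
from engine replay, not from annotations in the log.

Simulated cohorts work the same way:

```r
params <- cohort_params(n_patients = 500, seed = 42)
sim    <- simulate_cohort(params)      # engine-legal event log
transition_table(replay_journeys(sim))
```

Each result type has an `autoplot()` method; `tidy()`/`glance()` work on
replay results.

## CLI

```sh
exec/hfcoach fixture  --out cohort.ndjson
exec/hfcoach replay   --log cohort.ndjson --states-out states.csv
exec/hfcoach report   --log cohort.ndjson --table transitions --format csv
exec/hfcoach simulate --out sim.ndjson --seed 7 --n 200
exec/hfcoach screen   --records candidates.csv
```

Event logs are line-delimited JSON (one record per line, canonical key
order, byte-stable); configuration is YAML (see
`inst/extdata/config.yaml`). Exit codes: 0 success, 1 validation error,
2 internal error.
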