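# Shared fixtures and independent brute-force oracles for the test suite.

# The fixture cohort and its replay are expensive enough to share.
fixture_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$replay)) {
      env$events <- fixture_study_cohort()
      env$replay <- replay_journeys(env$events)
    }
    list(events = env$events, replay = env$replay)
  }
})

# Responses for one patient: `behavior_answers` / `knowledge_answers` are
# named lists mapping item_id -> answer; unnamed defaults fill the rest.
make_responses <- function(patient_id, bank = default_item_bank(),
                           behavior_default = 5L, knowledge_correct = TRUE,
                           overrides = list()) {
  ans <- integer(nrow(bank))
  ans[bank$kind == "behavior"] <- behavior_default
  ans[bank$kind == "knowledge"] <-
    if (knowledge_correct) bank$correct[bank$kind == "knowledge"] else 0L
  names(ans) <- bank$item_id
  for (id in names(overrides)) ans[[id]] <- overrides[[id]]
  tibble::tibble(patient_id = patient_id, item_id = bank$item_id,
                 answer = as.integer(ans))
}

# Brute-force rescoring: per behavior, recount adherence and knowledge from
# raw answers without the grouped pipeline.
oracle_flags <- function(responses, bank = default_item_bank(),
                         cutoff = 4L, tolerance = 0L) {
  merged <- merge(as.data.frame(responses), as.data.frame(bank),
                  by = "item_id")
  out <- list()
  for (pid in unique(merged$patient_id)) {
    for (beh in hc_behaviors()) {
      rows <- merged[merged$patient_id == pid & merged$behavior == beh, ]
      brows <- rows[rows$kind == "behavior", ]
      krows <- rows[rows$kind == "knowledge", ]
      does <- TRUE
      for (i in seq_len(nrow(brows))) {
        if (brows$answer[i] < cutoff) does <- FALSE
      }
      wrong <- 0L
      for (i in seq_len(nrow(krows))) {
        if (krows$answer[i] != krows$correct[i]) wrong <- wrong + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, behavior = beh,
        does_behavior = does, has_knowledge = wrong <= tolerance
      )
    }
  }
  do.call(rbind, out)
}

# Independent eligibility oracle: each criterion evaluated as a standalone
# predicate, verdict is their conjunction.
oracle_eligible <- function(rec) {
  eq <- c(furosemide = 40, bumetanide = 1, torasemide = 10)
  crits <- c(
    isTRUE(rec$hf_diagnosis),
    !isTRUE(rec$rapidly_reversible_cause),
    rec$diuretic_mg_day / eq[[tolower(rec$diuretic)]] >= 1,
    (!is.na(rec$hf_admission_within_days) &&
       rec$hf_admission_within_days <= 60) || rec$nyha >= 3,
    if (rec$sinus_rhythm) rec$ntprobnp >= 1000 else rec$ntprobnp >= 2000,
    rec$age_years >= 18,
    isTRUE(rec$can_operate_system),
    isTRUE(rec$speaks_local_language)
  )
  all(crits)
}

random_eligibility_record <- function() {
  eligibility_record(
    ntprobnp = sample(c(500, 900, 1000, 1500, 2000, 3000), 1),
    sinus_rhythm = sample(c(TRUE, FALSE), 1),
    diuretic = sample(c("furosemide", "bumetanide", "torasemide"), 1),
    diuretic_mg_day = sample(c(0.5, 1, 10, 20, 40, 80), 1),
    nyha = sample(1:4, 1),
    hf_admission_within_days = sample(c(NA, 10L, 59L, 61L, 200L), 1),
    hf_diagnosis = sample(c(TRUE, TRUE, FALSE), 1),
    rapidly_reversible_cause = sample(c(FALSE, FALSE, TRUE), 1),
    age_years = sample(c(17L, 18L, 45L, 80L), 1),
    can_operate_system = sample(c(TRUE, TRUE, FALSE), 1),
    speaks_local_language = sample(c(TRUE, TRUE, FALSE), 1)
  )
}

# Day-counting oracle for weekly evaluation, written against the rules
# directly rather than the engine's code path.
oracle_outcome <- function(goal, entries, met_fraction = 1) {
  beh <- goal$behavior
  if (beh == "physical_activity") {
    on_target <- 0L
    for (i in seq_len(nrow(entries))) {
      if (match(entries$minutes_band[i], c("<=15", "15-30", "30-45", "45-60")) >=
          match(goal$band, c("<=15", "15-30", "30-45", "45-60"))) {
        on_target <- on_target + 1L
      }
    }
    if (on_target >= goal$days) "achieved" else "missed"
  } else if (beh %in% c("low_salt_diet", "fluid_restriction")) {
    met <- 0L
    for (i in seq_len(nrow(entries))) {
      if (isTRUE(entries$met_target[i])) met <- met + 1L
    }
    if (met >= ceiling(7 * met_fraction)) "achieved" else "missed"
  } else {
    ok <- 0L
    for (i in seq_len(nrow(entries))) {
      if (entries$doses_taken[i] == goal$doses) ok <- ok + 1L
    }
    if (ok == 7L) "achieved" else "missed"
  }
}

# Random diary entries for a goal week.
random_entries <- function(goal, n_days = sample(0:7, 1)) {
  week <- seq(goal$week_start, by = "day", length.out = 7)
  dates <- sort(sample(week, n_days))
  beh <- goal$behavior
  if (beh == "physical_activity") {
    tibble::tibble(
      date = dates,
      minutes_band = sample(hc_bands(), n_days, replace = TRUE),
      effort = sample(c("too_easy", "just_right", "too_hard"), n_days,
                      replace = TRUE)
    )
  } else if (beh %in% c("low_salt_diet", "fluid_restriction")) {
    tibble::tibble(date = dates,
                   met_target = sample(c(TRUE, FALSE), n_days, replace = TRUE))
  } else {
    tibble::tibble(date = dates,
                   doses_taken = sample(0:3, n_days, replace = TRUE))
  }
}

random_goal <- function(behavior, week_start = as.Date("2012-03-05")) {
  switch(behavior,
    physical_activity = set_goal(behavior, week_start,
                                 days = sample(1:7, 1),
                                 band = sample(hc_bands(), 1)),
    low_salt_diet = set_goal(behavior, week_start,
                             sodium_target = sample(1:5, 1)),
    fluid_restriction = set_goal(behavior, week_start,
                                 max_intake = sample(c(1.5, 2), 1)),
    medication_intake = set_goal(behavior, week_start,
                                 doses = sample(1:3, 1))
  )
}
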