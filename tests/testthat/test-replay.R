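d0 <- as.Date("2012-03-01")

mk_events <- function(...) {
  ev <- dplyr::bind_rows(empty_events(), ...)
  ev[, hfcoach:::event_columns()]
}

q_block <- function(pid, overrides = list()) {
  r <- make_responses(pid, overrides = overrides)
  bank <- default_item_bank()
  tibble::tibble(patient_id = pid, date = d0,
                 behavior = bank$behavior,
                 event_type = "questionnaire_response",
                 item_id = r$item_id, answer = r$answer)
}

# one nonadherent physical-activity patient with a knowledge gap (area 1)
area1_journey <- function(pid = "x1", with_education = TRUE) {
  rows <- list(
    q_block(pid, overrides = list(phy_b1 = 2L, phy_k1 = 0L)),
    if (with_education) {
      tibble::tibble(patient_id = pid, date = d0 + 1, behavior = "physical_activity",
                     event_type = "education_viewed",
                     content_id = "video_physical_activity")
    },
    tibble::tibble(patient_id = pid, date = d0 + 2, behavior = "physical_activity",
                   event_type = "ic_rating", importance = 8L, confidence = 8L),
    tibble::tibble(patient_id = pid, date = d0 + c(3, 10),
                   behavior = "physical_activity", event_type = "goal_set",
                   days = 2L, band = "<=15"),
    tibble::tibble(patient_id = pid, date = d0 + c(3, 4, 10, 11),
                   behavior = "physical_activity", event_type = "diary_entry",
                   minutes_band = "<=15", effort = "just_right"),
    tibble::tibble(patient_id = pid, date = d0 + 17, behavior = "physical_activity",
                   event_type = "continue_choice", choice = "stop"),
    tibble::tibble(patient_id = pid, date = d0 + 77, behavior = "physical_activity",
                   event_type = "followup_response", followup = "maintained"),
    tibble::tibble(patient_id = pid, date = d0 + 364, behavior = "global",
                   event_type = "study_end")
  )
  ev <- mk_events(purrr::compact(rows))
  ev[order(ev$date), ]
}

test_that("a hand-built journey replays to the expected states, weeks and follow-up", {
  rep <- replay_journeys(area1_journey())
  j <- rep$journeys[rep$journeys$behavior == "physical_activity", ]
  expect_false(j$does_behavior)
  expect_equal(j$area, 1L)
  expect_true(j$started_coaching)
  expect_true(j$became_adherent)
  expect_equal(j$first_choice, "stop")
  expect_equal(j$first_followup, "maintained")
  expect_equal(j$final_state, "followup_maintained")
  expect_equal(j$goal_days, 2L)
  expect_equal(j$goal_band, "<=15")
  ev <- rep$evaluations
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$outcome, c("achieved", "achieved"))
  # other behaviors stay at their assessment state
  other <- rep$journeys[rep$journeys$behavior != "physical_activity", ]
  expect_true(all(other$final_state == "adherent_at_assessment"))
})

test_that("replaying the same log twice yields identical results", {
  events <- area1_journey()
  r1 <- replay_journeys(events)
  r2 <- replay_journeys(events)
  expect_identical(r1$journeys, r2$journeys)
  expect_identical(r1$evaluations, r2$evaluations)
  expect_identical(r1$alerts, r2$alerts)
  expect_identical(r1$states, r2$states)
})

test_that("coaching in area 1 is gated on prior education", {
  expect_error(replay_journeys(area1_journey(with_education = FALSE)),
               "education")
})

test_that("a goal inside an open week and a stray diary entry are rejected", {
  base <- area1_journey()
  clash <- mk_events(base, tibble::tibble(
    patient_id = "x1", date = d0 + 5, behavior = "physical_activity",
    event_type = "goal_set", days = 2L, band = "<=15"
  ))
  clash <- clash[order(clash$date), ]
  expect_error(replay_journeys(clash), "still open")

  stray <- mk_events(base, tibble::tibble(
    patient_id = "x1", date = d0 + 30, behavior = "physical_activity",
    event_type = "diary_entry", minutes_band = "<=15", effort = "just_right"
  ))
  stray <- stray[order(stray$date), ]
  expect_error(replay_journeys(stray), "outside any goal week")
})

test_that("coaching events on an adherent-at-assessment behavior are illegal", {
  bad <- mk_events(
    q_block("x2"),
    tibble::tibble(patient_id = "x2", date = d0 + 2, behavior = "low_salt_diet",
                   event_type = "ic_rating", importance = 8L, confidence = 8L)
  )
  expect_error(replay_journeys(bad), "illegal transition")
})

test_that("a patient can hold different states for different behaviors simultaneously", {
  ev <- mk_events(
    q_block("x3", overrides = list(phy_b1 = 2L, low_b1 = 2L)),
    tibble::tibble(patient_id = "x3", date = d0 + 2, behavior = "physical_activity",
                   event_type = "ic_rating", importance = 8L, confidence = 8L),
    tibble::tibble(patient_id = "x3", date = d0 + 3, behavior = "physical_activity",
                   event_type = "goal_set", days = 1L, band = "<=15")
  )
  rep <- replay_journeys(ev)
  states <- rep$journeys$final_state[match(hc_behaviors(), rep$journeys$behavior)]
  expect_equal(states, c("coaching", "nonadherent",
                         "adherent_at_assessment", "adherent_at_assessment"))
})

test_that("weekly windows partition diary days: no entry feeds two evaluations", {
  cache <- fixture_cache()
  ev <- cache$replay$evaluations
  diary_counts <- cache$events |>
    dplyr::filter(.data$event_type == "diary_entry") |>
    dplyr::count(.data$patient_id, .data$behavior, name = "n_entries")
  eval_counts <- ev |>
    dplyr::group_by(.data$patient_id, .data$behavior) |>
    dplyr::summarise(n_counted = sum(.data$days_achieved), .groups = "drop")
  both <- dplyr::inner_join(diary_counts, eval_counts,
                            by = c("patient_id", "behavior"))
  # counted active/met days can never exceed diary entries written
  expect_true(all(both$n_counted <= both$n_entries))
  # consecutive week starts within a journey never overlap a 7-day window
  gaps <- ev |>
    dplyr::group_by(.data$patient_id, .data$behavior) |>
    dplyr::summarise(min_gap = if (dplyr::n() > 1)
      min(diff(sort(as.integer(week_start)))) else 7L, .groups = "drop")
  expect_true(all(gaps$min_gap >= 7))
})

test_that("importance/confidence categories are recorded during replay", {
  rep <- fixture_cache()$replay
  expect_true(all(rep$ic$category %in%
                    c("low_importance", "low_confidence", "ready")))
  p1 <- rep$ic[rep$ic$patient_id == "P001" &
                 rep$ic$behavior == "physical_activity", ]
  expect_equal(p1$category, "low_importance")
})
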