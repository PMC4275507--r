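monday <- as.Date("2012-03-05")

test_that("goals validate their behavior-specific parameters", {
  g <- set_goal("physical_activity", monday, days = 3, band = "15-30")
  expect_equal(g$days, 3L)
  expect_equal(g$band, "15-30")
  expect_equal(set_goal("low_salt_diet", monday, sodium_target = 1)$sodium_target, 1L)
  expect_equal(set_goal("fluid_restriction", monday, max_intake = 1.5)$max_intake, 1.5)
  expect_equal(set_goal("medication_intake", monday, doses = 2)$doses, 2L)

  expect_error(set_goal("physical_activity", monday, days = 8, band = "15-30"))
  expect_error(set_goal("physical_activity", monday, days = 3, band = "20-40"))
  expect_error(set_goal("low_salt_diet", monday, sodium_target = 6))
  expect_error(set_goal("fluid_restriction", monday, max_intake = 3))
  expect_error(set_goal("medication_intake", monday, doses = 0))
  # fields from another behavior's variant are rejected
  expect_error(set_goal("low_salt_diet", monday, sodium_target = 2, days = 3),
               "not valid")
})

test_that("an exactly satisfied activity week is achieved with congratulation", {
  g <- set_goal("physical_activity", monday, days = 3, band = "15-30")
  e <- tibble::tibble(date = monday + 0:2, minutes_band = "15-30",
                     effort = "just_right")
  ev <- evaluate_week(g, e)
  expect_equal(ev$outcome, "achieved")
  expect_equal(ev$days_achieved, 3L)
  expect_equal(ev$days_on_target_band, 3L)
  expect_equal(ev$dominant_effort, "just_right")
  expect_equal(ev$feedback_id, "congratulate")
})

test_that("fewer, shorter, too-hard days miss the goal and advise reducing it", {
  g <- set_goal("physical_activity", monday, days = 5, band = "30-45")
  e <- tibble::tibble(date = monday + 0:2, minutes_band = "15-30",
                     effort = "too_hard")
  ev <- evaluate_week(g, e)
  expect_equal(ev$outcome, "missed")
  expect_equal(ev$dominant_effort, "too_hard")
  expect_true(ev$fewer_days)
  expect_true(ev$band_short)
  expect_equal(ev$feedback_id, "reduce_goal")
})

test_that("salt, fluid and medication weeks follow their achievement predicates", {
  gs <- set_goal("low_salt_diet", monday, sodium_target = 2)
  all_met <- tibble::tibble(date = monday + 0:6, met_target = TRUE)
  expect_equal(evaluate_week(gs, all_met)$outcome, "achieved")
  one_miss <- all_met
  one_miss$met_target[4] <- FALSE
  expect_equal(evaluate_week(gs, one_miss)$outcome, "missed")
  # a laxer met fraction tolerates the missed day
  expect_equal(
    evaluate_week(gs, one_miss, config = hc_config(met_fraction = 6 / 7))$outcome,
    "achieved"
  )
  # a missing diary day counts as not met
  six_days <- all_met[1:6, ]
  expect_equal(evaluate_week(gs, six_days)$outcome, "missed")

  gm <- set_goal("medication_intake", monday, doses = 2)
  all_doses <- tibble::tibble(date = monday + 0:6, doses_taken = 2L)
  expect_equal(evaluate_week(gm, all_doses)$outcome, "achieved")
  short <- all_doses
  short$doses_taken[1] <- 1L
  expect_equal(evaluate_week(gm, short)$outcome, "missed")
})

test_that("weekly outcomes equal a brute-force day-counting oracle on random weeks", {
  set.seed(404)
  for (i in 1:200) {
    beh <- sample(hc_behaviors(), 1)
    g <- random_goal(beh)
    e <- random_entries(g)
    expect_equal(evaluate_week(g, e)$outcome, oracle_outcome(g, e),
                 info = paste(beh, "case", i))
  }
})

test_that("entries outside the week or duplicated days are rejected", {
  g <- set_goal("physical_activity", monday, days = 2, band = "<=15")
  outside <- tibble::tibble(date = monday + 7, minutes_band = "<=15",
                            effort = "just_right")
  expect_error(evaluate_week(g, outside), "outside the goal week")
  dup <- tibble::tibble(date = c(monday, monday), minutes_band = "<=15",
                        effort = "just_right")
  expect_error(evaluate_week(g, dup), "more than one")
})

test_that("the feedback decision table is total over all key combinations", {
  keys <- expand.grid(
    outcome = c("achieved", "missed"),
    fewer_days = c(TRUE, FALSE),
    band_short = c(TRUE, FALSE),
    dominant_effort = c("too_easy", "just_right", "too_hard", NA_character_),
    stringsAsFactors = FALSE
  )
  known <- c("congratulate", "consider_raising", "encourage_retry",
             "encourage_retry_or_raise", "reduce_goal")
  for (i in seq_len(nrow(keys))) {
    id <- select_feedback(as.list(keys[i, ]))
    expect_true(id %in% known, info = paste(keys[i, ], collapse = "/"))
  }
  expect_equal(select_feedback(list(outcome = "missed", fewer_days = TRUE,
                                    band_short = TRUE,
                                    dominant_effort = "too_hard")),
               "reduce_goal")
  expect_equal(select_feedback(list(outcome = "missed", fewer_days = FALSE,
                                    band_short = FALSE,
                                    dominant_effort = "too_easy")),
               "encourage_retry_or_raise")
  expect_equal(select_feedback(list(outcome = "achieved", fewer_days = FALSE,
                                    band_short = FALSE,
                                    dominant_effort = "too_easy")),
               "consider_raising")
})

test_that("modal effort ties resolve toward the harder rating", {
  g <- set_goal("physical_activity", monday, days = 2, band = "<=15")
  e <- tibble::tibble(date = monday + 0:1, minutes_band = "<=15",
                      effort = c("too_easy", "too_hard"))
  expect_equal(evaluate_week(g, e)$dominant_effort, "too_hard")
  e2 <- tibble::tibble(date = monday + 0:1, minutes_band = "<=15",
                       effort = c("too_easy", "just_right"))
  expect_equal(evaluate_week(g, e2)$dominant_effort, "just_right")
})

test_that("adherence fires exactly when the two most recent weeks are achieved", {
  expect_true(update_adherence(c("achieved", "achieved")))
  expect_false(update_adherence(c("achieved", "missed", "achieved")))
  expect_false(update_adherence(character()))
  expect_false(update_adherence("achieved"))

  # property: equivalent to a sliding window of width 2 at the sequence end
  set.seed(405)
  for (i in 1:1000) {
    n <- sample(0:10, 1)
    seq_i <- sample(c("achieved", "missed"), n, replace = TRUE)
    window <- n >= 2 && seq_i[n] == "achieved" && seq_i[n - 1] == "achieved"
    expect_identical(update_adherence(seq_i), window)
  }
})

test_that("struggle alerts fire on a full missed streak and only then", {
  expect_equal(detect_struggle(rep("missed", 3))$trigger_week, 3L)
  expect_null(detect_struggle(c("missed", "achieved", "missed", "missed")))
  expect_null(detect_struggle(rep("achieved", 5)))
  expect_equal(detect_struggle(rep("missed", 2),
                               config = hc_config(struggle_weeks = 2L))$trigger_week,
               2L)
})

test_that("the adherent choice routes to continuation or stop with follow-up", {
  expect_equal(handle_adherent_choice(TRUE), "continued_coaching")
  expect_equal(handle_adherent_choice(FALSE), "stopped_after_adherent")
  expect_equal(schedule_followup(as.Date("1970-01-01") + 100), as.Date("1970-01-01") + 160)
  expect_equal(schedule_followup(as.Date("1970-01-01") + 160), as.Date("1970-01-01") + 220)
})
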