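test_that("a fully adherent, fully knowledgeable profile scores positive everywhere", {
  resp <- make_responses("p1")
  does <- score_behavior(resp)
  knows <- score_knowledge(resp)
  expect_equal(nrow(does), 4L)
  expect_true(all(does$does_behavior))
  expect_true(all(knows$has_knowledge))
})

test_that("any behavior item below the cutoff flags the behavior, at the configured cutoff", {
  resp <- make_responses("p1", overrides = list(phy_b2 = 3L))
  does <- score_behavior(resp)
  expect_false(does$does_behavior[does$behavior == "physical_activity"])
  expect_true(all(does$does_behavior[does$behavior != "physical_activity"]))
  # the same answers pass under a laxer cutoff
  does3 <- score_behavior(resp, config = hc_config(behavior_cutoff = 3L))
  expect_true(all(does3$does_behavior))
})

test_that("a single don't-know answer breaks knowledge at tolerance 0 but not at 1", {
  resp <- make_responses("p1", overrides = list(low_k2 = 0L))
  knows <- score_knowledge(resp)
  expect_false(knows$has_knowledge[knows$behavior == "low_salt_diet"])
  expect_true(all(knows$has_knowledge[knows$behavior != "low_salt_diet"]))
  knows1 <- score_knowledge(resp, config = hc_config(knowledge_tolerance = 1L))
  expect_true(all(knows1$has_knowledge))
})

test_that("scoring agrees with a brute-force recount on randomized response sets", {
  set.seed(401)
  bank <- default_item_bank()
  resp <- dplyr::bind_rows(lapply(sprintf("r%02d", 1:40), function(pid) {
    tibble::tibble(
      patient_id = pid, item_id = bank$item_id,
      answer = ifelse(bank$kind == "behavior",
                      sample(1:5, nrow(bank), replace = TRUE),
                      sample(0:3, nrow(bank), replace = TRUE) %% 4L)
    ) |>
      dplyr::mutate(answer = ifelse(bank$kind == "knowledge",
                                    pmin(.data$answer, bank$n_options),
                                    .data$answer))
  }))
  got <- dplyr::inner_join(score_behavior(resp), score_knowledge(resp),
                           by = c("patient_id", "behavior")) |>
    dplyr::arrange(.data$patient_id, .data$behavior)
  want <- oracle_flags(resp) |>
    dplyr::arrange(.data$patient_id, .data$behavior) |>
    tibble::as_tibble()
  expect_equal(got$does_behavior, want$does_behavior)
  expect_equal(got$has_knowledge, want$has_knowledge)
})

test_that("scoring is monotone: a more adherent or more correct answer never flips a flag down", {
  set.seed(402)
  bank <- default_item_bank()
  for (rep_i in 1:25) {
    resp <- make_responses("p1",
                           behavior_default = sample(1:5, 1),
                           overrides = stats::setNames(
                             as.list(sample(1:5, 3)),
                             sample(bank$item_id[bank$kind == "behavior"], 3)))
    before <- score_behavior(resp)
    i <- sample(which(resp$item_id %in% bank$item_id[bank$kind == "behavior"] &
                        resp$answer < 5L), 1)
    resp$answer[i] <- resp$answer[i] + 1L
    after <- score_behavior(resp)
    expect_true(all(after$does_behavior >= before$does_behavior))
  }
})

test_that("missing items for a behavior raise an incomplete-assessment error naming it", {
  bank <- default_item_bank()
  resp <- make_responses("p1")
  resp <- resp[!resp$item_id %in%
                 bank$item_id[bank$behavior == "fluid_restriction" &
                                bank$kind == "behavior"], ]
  expect_error(score_behavior(resp), "fluid_restriction")
  expect_error(score_behavior(resp), "incomplete")
})

test_that("matrix placement is a bijection between flag pairs and areas 1-4", {
  grid <- expand.grid(does = c(FALSE, TRUE), knows = c(FALSE, TRUE))
  placed <- place_in_matrix(grid$does, grid$knows)
  expect_setequal(placed$area, 1:4)
  expect_equal(placed$area[!placed$does_behavior & !placed$has_knowledge], 1L)
  expect_equal(placed$area[placed$does_behavior & !placed$has_knowledge], 2L)
  expect_equal(placed$area[!placed$does_behavior & placed$has_knowledge], 3L)
  expect_equal(placed$area[placed$does_behavior & placed$has_knowledge], 4L)
  expect_equal(placed$path[placed$area == 1L], "education_then_coaching")
  expect_equal(placed$path[placed$area == 2L], "education")
  expect_equal(placed$path[placed$area == 3L], "coaching")
  expect_equal(placed$path[placed$area == 4L], "none")
})

test_that("importance is evaluated before confidence and messages match the category", {
  low_imp <- assess_importance_confidence("physical_activity", 2, 9)
  expect_equal(low_imp$category, "low_importance")
  expect_true("activity_not_safe" %in% low_imp$messages[[1]])

  ready <- assess_importance_confidence("low_salt_diet", 10, 10)
  expect_equal(ready$category, "ready")

  both_low <- assess_importance_confidence("medication_intake", 3, 3)
  expect_equal(both_low$category, "low_importance")

  low_conf <- assess_importance_confidence("fluid_restriction", 9, 4)
  expect_equal(low_conf$category, "low_confidence")
  expect_true(all(grepl("barrier", low_conf$messages[[1]])))

  expect_error(assess_importance_confidence("physical_activity", 11, 5),
               "0-10")
  expect_error(assess_importance_confidence("physical_activity", 5, -1),
               "0-10")
})

test_that("eligibility follows the inclusion and exclusion rules", {
  expect_true(check_eligibility(eligibility_record(
    ntprobnp = 1000, sinus_rhythm = TRUE, diuretic = "furosemide",
    diuretic_mg_day = 40, nyha = 3L, age_years = 66L
  ))$eligible)

  v <- check_eligibility(eligibility_record(ntprobnp = 1500,
                                            sinus_rhythm = FALSE))
  expect_false(v$eligible)
  expect_true("NT-proBNP below 2000 for non-sinus rhythm" %in% v$reasons)

  expect_false(check_eligibility(eligibility_record(age_years = 17L))$eligible)

  # diuretic equivalence: 1 mg/d bumetanide and 10 mg/d torasemide qualify
  expect_true(check_eligibility(eligibility_record(
    diuretic = "bumetanide", diuretic_mg_day = 1
  ))$eligible)
  expect_false(check_eligibility(eligibility_record(
    diuretic = "torasemide", diuretic_mg_day = 5
  ))$eligible)

  # advanced/unstable disease: recent admission rescues NYHA < III
  expect_true(check_eligibility(eligibility_record(
    nyha = 2L, hf_admission_within_days = 30L
  ))$eligible)
  expect_false(check_eligibility(eligibility_record(
    nyha = 2L, hf_admission_within_days = NA_integer_
  ))$eligible)

  expect_error(check_eligibility(eligibility_record(diuretic = "spironolactone")),
               "unknown loop diuretic")
})

test_that("eligibility verdicts equal the conjunction of independent criterion predicates", {
  set.seed(403)
  for (i in 1:100) {
    rec <- random_eligibility_record()
    expect_equal(check_eligibility(rec)$eligible, oracle_eligible(rec),
                 info = paste(unlist(rec), collapse = ","))
  }
})

test_that("screen_eligibility vectorizes over a record table", {
  records <- dplyr::bind_rows(
    tibble::as_tibble(eligibility_record()),
    tibble::as_tibble(eligibility_record(age_years = 17L))
  )
  out <- screen_eligibility(records)
  expect_equal(out$eligible, c(TRUE, FALSE))
  expect_equal(out$reasons[[2]], "aged under 18")
})
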