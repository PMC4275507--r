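#' Cohort simulation parameters
#'
#' Per-behavior transition probabilities driving the synthetic-cohort
#' simulator. The defaults are calibrated to the observed study journey
#' tables (they are configuration, not constants): the nonadherence and
#' coaching-start rates per behavior, the weekly goal-achievement
#' probability, the continue-after-adherent split, the per-prompt
#' stop-later probability, and the relapse/retry probabilities at the
#' 2-month follow-ups.
#'
#' @param n_patients Number of patients to simulate.
#' @param horizon_days Study horizon in days; an explicit study-end event
#'   censors every journey at this day.
#' @param seed Integer seed making the simulation reproducible.
#' @param p_nonadherent,p_start_coaching,p_knowledge_gap,p_weekly_achieve,p_continue_after_adherent,p_stop_later,p_relapse_at_followup,p_retry_after_relapse
#'   Probabilities in `[0, 1]`; scalars are recycled across the four
#'   behaviors, or give one value per behavior in [hc_behaviors()] order.
#' @return A list of class `hc_cohort_params`.
#' @export
#' @examples
#' cohort_params(n_patients = 50, seed = 7)
cohort_params <- function(n_patients = 123L, horizon_days = 364L, seed = 1L,
                          p_nonadherent = c(50, 56, 6, 6) / 123,
                          p_start_coaching = c(35 / 50, 47 / 56, 4 / 6, 4 / 6),
                          p_knowledge_gap = 0.3,
                          p_weekly_achieve = 0.6,
                          p_continue_after_adherent =
                            c(17 / 28, 13 / 36, 1 / 2, 3 / 4),
                          p_stop_later = c(9 / 17, 6 / 13, 0, 1 / 3),
                          p_relapse_at_followup = c(4 / 13, 1 / 15, 0, 0),
                          p_retry_after_relapse = c(3 / 4, 0, 0, 0)) {
  stopifnot(n_patients >= 1, horizon_days >= 28)
  probs <- list(
    p_nonadherent = p_nonadherent, p_start_coaching = p_start_coaching,
    p_knowledge_gap = p_knowledge_gap, p_weekly_achieve = p_weekly_achieve,
    p_continue_after_adherent = p_continue_after_adherent,
    p_stop_later = p_stop_later,
    p_relapse_at_followup = p_relapse_at_followup,
    p_retry_after_relapse = p_retry_after_relapse
  )
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!length(p) %in% c(1L, 4L) || any(is.na(p)) || any(p < 0 | p > 1)) {
      stop(nm, " must be 1 or 4 probabilities in [0, 1]", call. = FALSE)
    }
    probs[[nm]] <- rep_len(p, 4L)
  }
  behaviors <- tibble::as_tibble(c(list(behavior = hc_behaviors()), probs))
  structure(list(
    n_patients = as.integer(n_patients),
    horizon_days = as.integer(horizon_days),
    seed = as.integer(seed),
    behaviors = behaviors
  ), class = "hc_cohort_params")
}

#' Simulate a synthetic patient cohort
#'
#' Samples per-patient, per-behavior journeys from the transition
#' probabilities in `params` and emits a complete, engine-legal event log:
#' questionnaire responses consistent with the sampled adherence and
#' knowledge flags, education viewing for area-1 starters, importance and
#' confidence ratings, weekly goals and diary entries consistent with each
#' sampled weekly outcome, continue/stop choices at every adherence prompt,
#' 2-month follow-up responses with relapse and retry, non-start reasons
#' for nonadherent patients who never start coaching, and a study-end
#' event per patient at the horizon. Reproducible given `params$seed`.
#'
#' @param params An [cohort_params()] object.
#' @return An event tibble accepted by [replay_journeys()].
#' @export
#' @examples
#' \donttest{
#' events <- simulate_cohort(cohort_params(n_patients = 20, seed = 42))
#' glance(replay_journeys(events))
#' }
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "hc_cohort_params"))
  set.seed(params$seed)
  d0 <- as.Date("2012-03-01")
  horizon <- as.integer(d0) + params$horizon_days
  n <- params$n_patients
  width <- max(4L, nchar(as.character(n)))
  pids <- sprintf(paste0("S%0", width, "d"), seq_len(n))
  bank <- default_item_bank()
  B <- params$behaviors
  bern <- function(p) stats::runif(1) < p

  # sample assessment flags up front so the questionnaire can be vectorized
  nonadh <- matrix(FALSE, n, 4, dimnames = list(pids, B$behavior))
  gap <- matrix(FALSE, n, 4, dimnames = list(pids, B$behavior))
  for (b in 1:4) {
    nonadh[, b] <- stats::runif(n) < B$p_nonadherent[b]
    gap[, b] <- stats::runif(n) < B$p_knowledge_gap[b]
  }

  q <- tidyr::expand_grid(patient_id = pids, bank)
  pi <- match(q$patient_id, pids)
  bi <- match(q$behavior, B$behavior)
  item_pos <- as.integer(sub(".*[bk]", "", q$item_id))
  q_nonadh <- nonadh[cbind(pi, bi)]
  q_gap <- gap[cbind(pi, bi)]
  answer <- ifelse(
    q$kind == "behavior",
    ifelse(q_nonadh & item_pos == 1L, 2L, ifelse(item_pos == 2L, 4L, 5L)),
    ifelse(q_gap & item_pos == 1L, 0L, q$correct)
  )
  q_events <- tibble::tibble(
    patient_id = q$patient_id, date = d0, behavior = q$behavior,
    event_type = "questionnaire_response",
    item_id = q$item_id, answer = as.integer(answer)
  )

  reasons <- fixture_reasons()
  reason_pool <- unique(reasons$reason)
  reason_wt <- as.numeric(table(reasons$reason)[reason_pool])

  acc <- new_acc()
  for (p in seq_len(n)) {
    pid <- pids[p]
    nonstart_any <- FALSE
    for (b in 1:4) {
      if (!nonadh[p, b]) next
      beh <- B$behavior[b]
      if (!bern(B$p_start_coaching[b])) {
        nonstart_any <- TRUE
        if (bern(0.5)) {
          acc_add(acc, pid, as.integer(d0) + 2L, beh, "ic_rating",
                  importance = 2L, confidence = 2L)
        }
        next
      }
      if (gap[p, b]) {
        acc_add(acc, pid, as.integer(d0) + 1L, beh, "education_viewed",
                content_id = paste0("video_", beh))
      }
      acc_add(acc, pid, as.integer(d0) + 2L, beh, "ic_rating",
              importance = sample(5:10, 1L), confidence = sample(5:10, 1L))
      goal <- switch(beh,
        physical_activity = list(days = sample(2:7, 1L),
                                 band = sample(hc_bands()[1:3], 1L)),
        low_salt_diet = list(sodium_target = sample(1:5, 1L)),
        fluid_restriction = list(max_intake = sample(c(1.5, 2.0), 1L)),
        medication_intake = list(doses = 2L)
      )
      simulate_journey(acc, pid, beh, goal, B[b, ],
                       start = as.integer(d0) + 3L, horizon = horizon,
                       bern = bern)
    }
    if (nonstart_any) {
      acc_add(acc, pid, as.integer(d0) + 5L, "global", "non_start_reason",
              reason = sample(reason_pool, 1L, prob = reason_wt))
    }
    acc_add(acc, pid, horizon, "global", "study_end")
  }

  events <- dplyr::bind_rows(q_events, acc_events(acc))
  events <- events[order(match(events$patient_id, pids), events$date,
                         method = "radix"), ]
  events <- dplyr::bind_rows(empty_events()[0, ], events)[, event_columns()]
  tibble::as_tibble(events)
}

# Weekly coaching loop for one simulated starter, including adherence
# prompts, follow-up cycles, and relapse/retry. All diary entries are
# consistent with the sampled weekly outcome.
simulate_journey <- function(acc, pid, beh, goal, pr, start, horizon, bern) {
  cur <- start
  prompt_no <- 0L
  mode <- "coaching"
  spell <- character()
  while (TRUE) {
    if (mode == "coaching") {
      if (cur + 6L >= horizon) break
      achieved <- bern(pr$p_weekly_achieve)
      goal_fields <- goal[!vapply(goal, is.null, logical(1))]
      do.call(acc_add, c(list(acc, pid, cur, beh, "goal_set"), goal_fields))
      emit_diary(acc, pid, beh, goal, cur, achieved)
      spell <- c(spell, if (achieved) "achieved" else "missed")
      cur <- cur + 7L
      if (update_adherence(spell)) {
        prompt_no <- prompt_no + 1L
        stop_now <- if (prompt_no == 1L) {
          !bern(pr$p_continue_after_adherent)
        } else {
          bern(pr$p_stop_later)
        }
        acc_add(acc, pid, cur, beh, "continue_choice",
                choice = if (stop_now) "stop" else "continue")
        if (stop_now) {
          mode <- "stopped"
        } else {
          spell <- character()
        }
      }
    } else {  # stopped: 2-month follow-up cycle
      cur <- cur + 60L
      if (cur >= horizon) break
      if (!bern(pr$p_relapse_at_followup)) {
        acc_add(acc, pid, cur, beh, "followup_response",
                followup = "maintained")
      } else if (bern(pr$p_retry_after_relapse)) {
        acc_add(acc, pid, cur, beh, "followup_response",
                followup = "relapsed_retry")
        mode <- "coaching"
        spell <- character()
      } else {
        acc_add(acc, pid, cur, beh, "followup_response",
                followup = "relapsed_stop")
        break
      }
    }
  }
  invisible(NULL)
}
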