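# ---- internal cores -------------------------------------------------------
# The engine replays thousands of goal weeks, so goal validation and weekly
# evaluation run on plain vectors/lists; the exported tibble API wraps them.

goal_core <- function(behavior, week_start, days = NULL, band = NULL,
                      sodium_target = NULL, max_intake = NULL, doses = NULL) {
  assert_behavior(behavior)
  week_start <- as.Date(week_start)
  stopifnot(length(week_start) == 1L, !is.na(week_start))
  extra <- list(days = days, band = band, sodium_target = sodium_target,
                max_intake = max_intake, doses = doses)
  given <- names(extra)[!vapply(extra, is.null, logical(1))]
  allowed <- switch(behavior,
    physical_activity = c("days", "band"),
    low_salt_diet = "sodium_target",
    fluid_restriction = "max_intake",
    medication_intake = "doses"
  )
  stray <- setdiff(given, allowed)
  if (length(stray) > 0) {
    stop("goal fields not valid for ", behavior, ": ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  goal <- list(behavior = behavior, week_start = week_start)
  switch(behavior,
    physical_activity = {
      if (is.null(days) || is.null(band) || is.na(days) || is.na(band) ||
          !days %in% 1:7 || !band %in% hc_bands()) {
        stop("physical activity goal needs days in 1-7 and a minutes band",
             call. = FALSE)
      }
      goal$days <- as.integer(days)
      goal$band <- band
    },
    low_salt_diet = {
      if (is.null(sodium_target) || is.na(sodium_target) ||
          !sodium_target %in% 1:5) {
        stop("low-salt goal needs sodium_target in 1-5 g/d", call. = FALSE)
      }
      goal$sodium_target <- as.integer(sodium_target)
    },
    fluid_restriction = {
      if (is.null(max_intake) || is.na(max_intake) ||
          !max_intake %in% c(1.5, 2.0)) {
        stop("fluid goal needs max_intake of 1.5 or 2.0 L/d", call. = FALSE)
      }
      goal$max_intake <- max_intake
    },
    medication_intake = {
      if (is.null(doses) || is.na(doses) || doses < 1 ||
          doses != as.integer(doses)) {
        stop("medication goal needs planned doses per day >= 1", call. = FALSE)
      }
      goal$doses <- as.integer(doses)
    }
  )
  goal
}

# Weekly evaluation on plain vectors. `dates` etc. are the diary entries of
# the week; returns a plain list. Errors on entries outside the window or
# duplicate days.
eval_core <- function(goal, dates, minutes_band, effort, met_target,
                      doses_taken, config, week_index = 1L) {
  behavior <- goal$behavior
  start <- as.integer(goal$week_start)
  if (length(dates) > 0) {
    offs <- as.integer(dates) - start
    if (any(offs < 0L | offs > 6L)) {
      stop("diary entries outside the goal week starting ",
           int2date(start), call. = FALSE)
    }
    if (anyDuplicated(offs) > 0) {
      stop("more than one diary entry on a day", call. = FALSE)
    }
  }
  dominant_effort <- NA_character_
  band_short <- FALSE
  if (behavior == "physical_activity") {
    days_achieved <- length(dates)
    days_on_target <- if (days_achieved == 0L) 0L else
      sum(band_rank(minutes_band) >= band_rank(goal$band))
    achieved <- days_on_target >= goal$days
    planned_days <- goal$days
    band_short <- days_on_target < days_achieved
    if (days_achieved > 0L) {
      counts <- tabulate(effort_rank(effort), nbins = 3L)
      dominant_effort <- hc_efforts()[max(which(counts == max(counts)))]
    }
  } else if (behavior %in% c("low_salt_diet", "fluid_restriction")) {
    days_achieved <- if (length(dates) == 0L) 0L else sum(met_target)
    days_on_target <- days_achieved
    planned_days <- as.integer(ceiling(7 * config$met_fraction))
    achieved <- days_achieved >= planned_days
  } else {  # medication_intake
    days_achieved <- if (length(dates) == 0L) 0L else
      sum(doses_taken == goal$doses)
    days_on_target <- days_achieved
    planned_days <- 7L
    achieved <- days_achieved == 7L
  }
  ev <- list(
    week_index = as.integer(week_index), behavior = behavior,
    week_start = int2date(start),
    days_achieved = as.integer(days_achieved),
    days_on_target_band = as.integer(days_on_target),
    planned_days = as.integer(planned_days),
    fewer_days = days_achieved < planned_days,
    band_short = band_short,
    dominant_effort = dominant_effort,
    outcome = if (achieved) "achieved" else "missed"
  )
  ev$feedback_id <- select_feedback(ev)
  ev
}

# ---- exported API ---------------------------------------------------------

#' Set a weekly personal goal
#'
#' Goals are behavior-specific: physical activity plans active days per week
#' (1-7) and a minutes band per active day; low-salt diet plans a daily
#' sodium target in grams (1-5, where 5 encodes ">= 5"); fluid restriction
#' plans a maximum daily intake (1.5 or 2.0 L); medication intake plans the
#' prescribed doses per day. The goal governs the 7-day window starting at
#' `week_start`.
#'
#' @param behavior A coached behavior identifier.
#' @param week_start Start date of the goal week.
#' @param days,band Physical activity: planned active days (1-7) and
#'   minutes band, one of `"<=15"`, `"15-30"`, `"30-45"`, `"45-60"`.
#' @param sodium_target Low-salt diet: daily sodium target in g (1-5).
#' @param max_intake Fluid restriction: daily limit in litres (1.5 or 2.0).
#' @param doses Medication intake: planned doses per day (>= 1).
#' @return A one-row goal tibble.
#' @export
#' @examples
#' set_goal("physical_activity", days = 3, band = "15-30",
#'          week_start = as.Date("2012-03-05"))
set_goal <- function(behavior, week_start, days = NULL, band = NULL,
                     sodium_target = NULL, max_intake = NULL, doses = NULL) {
  g <- goal_core(behavior, week_start, days, band, sodium_target,
                 max_intake, doses)
  tibble::tibble(
    behavior = g$behavior, week_start = g$week_start,
    days = g$days %||% NA_integer_, band = g$band %||% NA_character_,
    sodium_target = g$sodium_target %||% NA_integer_,
    max_intake = g$max_intake %||% NA_real_,
    doses = g$doses %||% NA_integer_
  )
}

#' Evaluate a coaching week against its goal
#'
#' Physical activity: `days_achieved` counts diary days with any activity,
#' `days_on_target_band` counts days at or above the planned minutes band,
#' and the week is achieved when `days_on_target_band >= planned days`.
#' Salt and fluid weeks are achieved when the target was met on at least
#' `config$met_fraction` of the 7 days (default all 7; days without an
#' entry count as not met). Medication weeks are achieved when the planned
#' doses were taken on every day. The dominant effort is the modal effort
#' over active days, ties resolved toward the harder rating.
#'
#' @param goal A goal tibble from [set_goal()].
#' @param entries A tibble of diary entries with `date` and the
#'   behavior-specific fields (`minutes_band` + `effort`, `met_target`, or
#'   `doses_taken`); at most one entry per day, all within the goal week.
#' @param config An [hc_config()] list.
#' @param week_index Week number carried into the result.
#' @return A one-row evaluation tibble with `outcome` (`"achieved"` or
#'   `"missed"`), counts, `dominant_effort`, and the selected `feedback_id`.
#' @export
evaluate_week <- function(goal, entries, config = hc_config(), week_index = 1L) {
  stopifnot(is.data.frame(goal), nrow(goal) == 1L)
  g <- goal_core(
    goal$behavior, goal$week_start,
    days = na_null(goal$days), band = na_null(goal$band),
    sodium_target = na_null(goal$sodium_target),
    max_intake = na_null(goal$max_intake), doses = na_null(goal$doses)
  )
  col <- function(nm) if (nm %in% names(entries)) entries[[nm]] else
    rep(NA, nrow(entries))
  ev <- eval_core(
    g, dates = if (nrow(entries) > 0) as.Date(entries$date) else
      as.Date(character()),
    minutes_band = col("minutes_band"), effort = col("effort"),
    met_target = col("met_target"), doses_taken = col("doses_taken"),
    config = config, week_index = week_index
  )
  out <- tibble::as_tibble(ev)
  out$goal <- list(goal)
  out
}

na_null <- function(x) if (is.null(x) || is.na(x)) NULL else x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select weekly feedback from the decision table
#'
#' The table is keyed by (outcome, fewer days than planned?, sessions
#' shorter than planned?, dominant effort) and is total: a missed week with
#' fewer and shorter days rated too hard advises a less ambitious goal; a
#' missed week rated too easy encourages a retry or a raised plan; an
#' achieved week rated too easy suggests raising the goal; any other
#' achieved week congratulates; any other missed week encourages a retry.
#'
#' @param eval A one-row evaluation (tibble or list, see [evaluate_week()])
#'   with fields `outcome`, `fewer_days`, `band_short`, `dominant_effort`.
#' @return A feedback message id resolvable in the content catalog.
#' @export
select_feedback <- function(eval) {
  stopifnot(eval$outcome %in% c("achieved", "missed"))
  effort <- eval$dominant_effort
  if (eval$outcome == "missed") {
    if (isTRUE(eval$fewer_days) && isTRUE(eval$band_short) &&
        identical(effort, "too_hard")) {
      return("reduce_goal")
    }
    if (identical(effort, "too_easy")) return("encourage_retry_or_raise")
    return("encourage_retry")
  }
  if (identical(effort, "too_easy")) return("consider_raising")
  "congratulate"
}

#' Detect adherence from a weekly outcome history
#'
#' A patient is adherent to a behavior once the personal goal has been
#' reached for 2 consecutive weeks: the two most recent weeks must both be
#' achieved.
#'
#' @param outcomes Character vector of `"achieved"`/`"missed"` ordered by
#'   week.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' update_adherence(c("achieved", "achieved"))
#' update_adherence(c("achieved", "missed", "achieved"))
update_adherence <- function(outcomes) {
  stopifnot(all(outcomes %in% c("achieved", "missed")))
  n <- length(outcomes)
  n >= 2L && all(outcomes[c(n - 1L, n)] == "achieved")
}

#' Detect a struggling patient
#'
#' When the last `config$struggle_weeks` consecutive weeks (default 3) were
#' all missed, the system recommends contacting the heart-failure nurse and
#' raises a dashboard alert — one alert per missed streak, at the week the
#' streak reaches the threshold.
#'
#' @param outcomes Character vector of weekly outcomes, ordered by week.
#' @param config An [hc_config()] list.
#' @param patient_id,behavior Identification carried into the alert.
#' @return A one-row alert tibble, or `NULL` when no alert is due.
#' @export
detect_struggle <- function(outcomes, config = hc_config(),
                            patient_id = NA_character_,
                            behavior = NA_character_) {
  stopifnot(all(outcomes %in% c("achieved", "missed")))
  k <- config$struggle_weeks
  n <- length(outcomes)
  streak <- 0L
  while (streak < n && outcomes[n - streak] == "missed") streak <- streak + 1L
  if (streak < k) return(NULL)
  tibble::tibble(
    patient_id = patient_id, behavior = behavior,
    trigger_week = as.integer(n - streak + k),
    reason = "missed_goal_streak"
  )
}

#' Choice after becoming adherent
#'
#' After the achievement is acknowledged the patient chooses whether to
#' continue coaching (a fresh goal is then required) or to stop, in which
#' case a maintenance follow-up is scheduled.
#'
#' @param continue_coaching Logical.
#' @return The successor state name.
#' @export
handle_adherent_choice <- function(continue_coaching) {
  stopifnot(is.logical(continue_coaching), length(continue_coaching) == 1L,
            !is.na(continue_coaching))
  if (continue_coaching) "continued_coaching" else "stopped_after_adherent"
}

#' Schedule the maintenance follow-up
#'
#' Patients who stop coaching after becoming adherent are asked 2 months
#' (60 days) later whether the behavior has been maintained, recurring
#' every 60 days while they remain stopped.
#'
#' @param stop_date Date coaching stopped (or date of the last maintained
#'   follow-up response).
#' @param config An [hc_config()] list.
#' @return The next follow-up date.
#' @export
#' @examples
#' schedule_followup(as.Date("2012-03-01"))
schedule_followup <- function(stop_date, config = hc_config()) {
  as.Date(stop_date) + config$followup_days
}
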