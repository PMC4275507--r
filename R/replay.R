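# Assemble a tibble from a list of plain named-list rows. `fields` maps
# column name -> prototype ("character", "integer", "double", "logical",
# "date"); missing fields become NA.
bind_plain_rows <- function(rows, fields) {
  n <- length(rows)
  out <- vector("list", length(fields))
  names(out) <- names(fields)
  for (nm in names(fields)) {
    type <- fields[[nm]]
    proto <- switch(type, character = NA_character_, integer = NA_integer_,
                    double = NA_real_, logical = NA, date = NA_integer_)
    fv <- switch(type, character = character(1), integer = integer(1),
                 double = double(1), logical = logical(1), date = integer(1))
    vals <- vapply(rows, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) == 0L || is.na(v)) proto
      else if (type == "date") as.integer(v) else v
    }, fv)
    out[[nm]] <- if (type == "date")
      int2date(vals) else vals
  }
  tibble::as_tibble(out)
}

journey_fields <- function() {
  c(patient_id = "character", behavior = "character",
    does_behavior = "logical", has_knowledge = "logical", area = "integer",
    started_coaching = "logical", became_adherent = "logical",
    first_choice = "character", continued = "logical",
    stopped_later = "logical", n_continues = "integer",
    ever_stopped = "logical", first_followup = "character",
    final_state = "character",
    goal_days = "integer", goal_band = "character",
    goal_sodium_target = "integer", goal_max_intake = "double",
    goal_doses = "integer")
}

evaluation_fields <- function() {
  c(patient_id = "character", behavior = "character",
    week_index = "integer", week_start = "date",
    days_achieved = "integer", days_on_target_band = "integer",
    planned_days = "integer", fewer_days = "logical",
    band_short = "logical", dominant_effort = "character",
    outcome = "character", feedback_id = "character",
    goal_days = "integer", goal_band = "character",
    goal_sodium_target = "integer", goal_max_intake = "double",
    goal_doses = "integer")
}

#' Replay event logs through the coaching engine
#'
#' Drives every patient-behavior journey in an event log through the
#' coaching state machine: questionnaire responses are scored into the
#' knowledge-by-behavior matrix, education gating is enforced for area-1
#' patients, goal weeks are evaluated against diary entries when their
#' 7-day window closes (or at the first event after it), adherence fires on
#' two consecutive achieved weeks within the current coaching spell, nurse
#' alerts fire on a configured streak of missed weeks, and follow-up
#' responses resolve maintenance or relapse. Replay is deterministic: the
#' same log always yields the same states, evaluations, feedback ids, and
#' alerts.
#'
#' @param events An event tibble (see [read_event_log()]).
#' @param items Questionnaire item bank, default [default_item_bank()].
#' @param config An [hc_config()] list.
#' @return An object of class `hc_replay`: a list of tibbles `journeys`
#'   (one row per patient-behavior with flags, final state, and the goal
#'   reached on becoming adherent in `goal_*` columns), `evaluations`,
#'   `alerts`, `followups`, `states` (every state entered, with dates),
#'   `ic`, and `nonstart_reasons`.
#' @export
replay_journeys <- function(events, items = default_item_bank(),
                            config = hc_config()) {
  validate_events(events)
  responses <- events |>
    dplyr::filter(.data$event_type == "questionnaire_response") |>
    dplyr::select("patient_id", "item_id", "answer")
  if (nrow(responses) == 0) {
    stop("event log contains no questionnaire responses to assess",
         call. = FALSE)
  }
  does <- score_behavior(responses, items, config)
  knows <- score_knowledge(responses, items, config)
  flags <- dplyr::inner_join(does, knows, by = c("patient_id", "behavior"))
  placement <- place_in_matrix(flags$does_behavior, flags$has_knowledge,
                               flags$behavior)
  flags$area <- placement$area

  machine <- events |>
    dplyr::filter(!.data$event_type %in%
                    c("questionnaire_response", "non_start_reason"))
  is_global_end <- machine$event_type == "study_end" &
    machine$behavior == "global"
  end_dates <- stats::setNames(
    as.integer(machine$date[is_global_end]),
    machine$patient_id[is_global_end]
  )
  machine <- machine[!machine$behavior == "global", , drop = FALSE]
  E <- list(
    date = as.integer(machine$date), event_type = machine$event_type,
    importance = machine$importance, confidence = machine$confidence,
    days = machine$days, band = machine$band,
    sodium_target = machine$sodium_target,
    max_intake = machine$max_intake, doses = machine$doses,
    minutes_band = machine$minutes_band, effort = machine$effort,
    met_target = machine$met_target, doses_taken = machine$doses_taken,
    choice = machine$choice, followup = machine$followup
  )
  key <- paste(machine$patient_id, machine$behavior, sep = "\r")
  idx_by_key <- split(seq_along(key), key)

  n_j <- nrow(flags)
  journeys <- vector("list", n_j)
  evals <- list(); alerts <- list(); followups <- list(); ics <- list()
  state_vecs <- vector("list", n_j)
  for (j in seq_len(n_j)) {
    pid <- flags$patient_id[j]
    beh <- flags$behavior[j]
    res <- replay_one(
      pid, beh,
      does = flags$does_behavior[j], area = flags$area[j],
      E = E, idx = idx_by_key[[paste(pid, beh, sep = "\r")]],
      end_date = if (pid %in% names(end_dates)) end_dates[[pid]] else NULL,
      config = config
    )
    res$journey$has_knowledge <- flags$has_knowledge[j]
    journeys[[j]] <- res$journey
    if (length(res$evaluations) > 0) evals <- c(evals, res$evaluations)
    if (length(res$alerts) > 0) alerts <- c(alerts, res$alerts)
    if (length(res$followups) > 0) followups <- c(followups, res$followups)
    if (length(res$ic) > 0) ics <- c(ics, res$ic)
    state_vecs[[j]] <- res$states
  }

  lens <- vapply(state_vecs, function(s) length(s$state), integer(1))
  states <- tibble::tibble(
    patient_id = rep(flags$patient_id, lens),
    behavior = rep(flags$behavior, lens),
    state = unlist(lapply(state_vecs, `[[`, "state"), use.names = FALSE),
    date = int2date(unlist(lapply(state_vecs, `[[`, "date"),
                           use.names = FALSE))
  )
  reasons <- events |>
    dplyr::filter(.data$event_type == "non_start_reason") |>
    dplyr::select("patient_id", "date", "reason")

  structure(list(
    journeys = bind_plain_rows(journeys, journey_fields()),
    evaluations = bind_plain_rows(evals, evaluation_fields()),
    alerts = bind_plain_rows(alerts, c(patient_id = "character",
                                       behavior = "character",
                                       trigger_week = "integer",
                                       reason = "character")),
    followups = bind_plain_rows(followups, c(patient_id = "character",
                                             behavior = "character",
                                             date = "date",
                                             answer = "character",
                                             response_index = "integer")),
    states = states,
    ic = bind_plain_rows(ics, c(patient_id = "character",
                                behavior = "character", date = "date",
                                importance = "integer",
                                confidence = "integer",
                                category = "character")),
    nonstart_reasons = reasons
  ), class = "hc_replay")
}

# Fold one patient-behavior journey through the state machine. `E` holds
# the machine-event columns as plain vectors, `idx` this journey's indices.
replay_one <- function(pid, beh, does, area, E, idx, end_date, config) {
  state <- step(NULL, list(type = if (does) "assessed_adherent" else
    "assessed_nonadherent"))
  states_seen <- state
  state_dates <- NA_integer_
  open_goal <- NULL
  entry_idx <- integer()
  spell_outcomes <- character()
  missed_streak <- 0L
  week_counter <- 0L
  education_seen <- FALSE
  became_adherent <- FALSE
  reached_goal <- NULL
  choices <- character()
  evaluations <- list(); alert_rows <- list(); followup_rows <- list()
  ic_rows <- list()

  push_state <- function(date, new_state) {
    if (!identical(new_state, state)) {
      states_seen[length(states_seen) + 1L] <<- new_state
      state_dates[length(state_dates) + 1L] <<- date
    }
    state <<- new_state
  }

  close_week <- function() {
    if (is.null(open_goal)) return(invisible())
    week_counter <<- week_counter + 1L
    ev <- eval_core(
      open_goal,
      dates = E$date[entry_idx],
      minutes_band = E$minutes_band[entry_idx],
      effort = E$effort[entry_idx],
      met_target = E$met_target[entry_idx],
      doses_taken = E$doses_taken[entry_idx],
      config = config, week_index = week_counter
    )
    spell_outcomes[length(spell_outcomes) + 1L] <<- ev$outcome
    if (ev$outcome == "missed") {
      missed_streak <<- missed_streak + 1L
      if (missed_streak == config$struggle_weeks) {
        alert_rows[[length(alert_rows) + 1L]] <<- list(
          patient_id = pid, behavior = beh,
          trigger_week = week_counter, reason = "missed_goal_streak"
        )
      }
    } else {
      missed_streak <<- 0L
    }
    adherence_met <- update_adherence(spell_outcomes)
    push_state(as.integer(open_goal$week_start) + 7L,
               step(state, list(type = "week_evaluated",
                                adherence_met = adherence_met)))
    if (adherence_met && !became_adherent) {
      became_adherent <<- TRUE
      reached_goal <<- open_goal
    }
    ev$patient_id <- pid
    ev$goal_days <- open_goal$days
    ev$goal_band <- open_goal$band
    ev$goal_sodium_target <- open_goal$sodium_target
    ev$goal_max_intake <- open_goal$max_intake
    ev$goal_doses <- open_goal$doses
    evaluations[[length(evaluations) + 1L]] <<- ev
    open_goal <<- NULL
    entry_idx <<- integer()
  }

  for (i in idx) {
    date <- E$date[i]
    type <- E$event_type[i]
    if (!is.null(open_goal) && date > as.integer(open_goal$week_start) + 6L) {
      close_week()
    }
    if (type == "education_viewed") {
      education_seen <- TRUE
      push_state(date, step(state, list(type = type)))
    } else if (type == "ic_rating") {
      imp <- E$importance[i]
      conf <- E$confidence[i]
      if (is.na(imp) || is.na(conf) || imp < 0 || imp > 10 ||
          conf < 0 || conf > 10) {
        stop("patient ", pid, " (", beh, "): importance and confidence ",
             "must be integers in 0-10", call. = FALSE)
      }
      category <- if (imp < config$importance_threshold) "low_importance"
        else if (conf < config$confidence_threshold) "low_confidence"
        else "ready"
      ic_rows[[length(ic_rows) + 1L]] <- list(
        patient_id = pid, behavior = beh, date = date,
        importance = as.integer(imp), confidence = as.integer(conf),
        category = category
      )
      push_state(date, step(state, list(type = type)))
    } else if (type == "goal_set") {
      if (!is.null(open_goal)) {
        stop("patient ", pid, " (", beh, "): goal set on ",
             int2date(date),
             " while the week of ", open_goal$week_start,
             " is still open", call. = FALSE)
      }
      if (state == "ic_assessed" && area == 1L && !education_seen) {
        stop("patient ", pid, " (", beh, "): coaching requires the ",
             "prescribed education first (area 1)", call. = FALSE)
      }
      if (state %in% c("continued_coaching", "relapsed_recoaching")) {
        spell_outcomes <- character()
        missed_streak <- 0L
      }
      goal <- goal_core(
        beh, int2date(date),
        days = na_null(E$days[i]), band = na_null(E$band[i]),
        sodium_target = na_null(E$sodium_target[i]),
        max_intake = na_null(E$max_intake[i]),
        doses = na_null(E$doses[i])
      )
      push_state(date, step(state, list(type = type)))
      open_goal <- goal
    } else if (type == "diary_entry") {
      if (is.null(open_goal)) {
        stop("patient ", pid, " (", beh, "): diary entry on ",
             int2date(date),
             " outside any goal week", call. = FALSE)
      }
      push_state(date, step(state, list(type = type)))
      entry_idx[length(entry_idx) + 1L] <- i
    } else if (type == "continue_choice") {
      choice <- E$choice[i]
      if (!choice %in% c("continue", "stop")) {
        stop("unknown continue choice: ", choice, call. = FALSE)
      }
      choices[length(choices) + 1L] <- choice
      push_state(date, step(state, list(type = type,
                                        continue = choice == "continue")))
    } else if (type == "followup_response") {
      push_state(date, step(state, list(type = type,
                                        answer = E$followup[i])))
      followup_rows[[length(followup_rows) + 1L]] <- list(
        patient_id = pid, behavior = beh, date = date,
        answer = E$followup[i],
        response_index = length(followup_rows) + 1L
      )
    } else if (type == "study_end") {
      close_week()
      push_state(date, step(state, list(type = type)))
    } else {
      stop("unhandled event type: ", type, call. = FALSE)
    }
  }
  close_week()
  if (!is.null(end_date)) {
    push_state(end_date, step(state, list(type = "study_end")))
  }

  journey <- list(
    patient_id = pid, behavior = beh,
    does_behavior = does, area = area,
    started_coaching = "coaching" %in% states_seen,
    became_adherent = became_adherent,
    first_choice = if (length(choices) > 0) choices[1] else NA_character_,
    continued = length(choices) > 0 && choices[1] == "continue",
    stopped_later = length(choices) > 1 && choices[1] == "continue" &&
      "stop" %in% choices[-1],
    n_continues = sum(choices == "continue"),
    ever_stopped = "stop" %in% choices,
    first_followup = if (length(followup_rows) > 0)
      followup_rows[[1]]$answer else NA_character_,
    final_state = state,
    goal_days = reached_goal$days,
    goal_band = reached_goal$band,
    goal_sodium_target = reached_goal$sodium_target,
    goal_max_intake = reached_goal$max_intake,
    goal_doses = reached_goal$doses
  )
  list(
    journey = journey,
    evaluations = evaluations,
    alerts = alert_rows,
    followups = followup_rows,
    states = list(state = states_seen, date = state_dates),
    ic = ic_rows
  )
}

#' @export
print.hc_replay <- function(x, ...) {
  cat("<hc_replay>\n")
  cat("  patients:  ", dplyr::n_distinct(x$journeys$patient_id), "\n")
  cat("  journeys:  ", nrow(x$journeys), "\n")
  cat("  weeks:     ", nrow(x$evaluations), "\n")
  cat("  alerts:    ", nrow(x$alerts), "\n")
  invisible(x)
}

#' Tidy a replay result
#'
#' @param x An `hc_replay` object.
#' @param ... Unused.
#' @return The per patient-behavior journey tibble.
#' @export
tidy.hc_replay <- function(x, ...) x$journeys

#' One-row summary of a replay result
#'
#' @param x An `hc_replay` object.
#' @param ... Unused.
#' @return A one-row tibble with cohort-level counts.
#' @export
glance.hc_replay <- function(x, ...) {
  tibble::tibble(
    n_patients = dplyr::n_distinct(x$journeys$patient_id),
    n_journeys = nrow(x$journeys),
    n_nonadherent = sum(!x$journeys$does_behavior),
    n_started = sum(x$journeys$started_coaching),
    n_adherent = sum(x$journeys$became_adherent),
    n_weeks = nrow(x$evaluations),
    n_alerts = nrow(x$alerts)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
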