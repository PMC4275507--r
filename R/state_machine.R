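#' One step of the per-behavior coaching state machine
#'
#' Applies a single event to the current journey state and returns the
#' unique successor, or throws an illegal-transition error naming the state
#' and event. States are per patient and behavior (see [hc_states()]).
#'
#' Event types and the edges they drive:
#' \itemize{
#'   \item `assessed_adherent` / `assessed_nonadherent`: from the initial
#'     (`NULL`) state after questionnaire scoring.
#'   \item `education_viewed`: stays in `nonadherent` or `ic_assessed`.
#'   \item `ic_rating`: `nonadherent` -> `ic_assessed`.
#'   \item `goal_set`: `ic_assessed`, `continued_coaching` or
#'     `relapsed_recoaching` -> `coaching` (also legal inside `coaching`
#'     for the next week's goal).
#'   \item `diary_entry`: stays in `coaching`.
#'   \item `week_evaluated` (payload `adherence_met`): `coaching` ->
#'     `adherent` when the two-consecutive-achieved-weeks rule fires,
#'     otherwise stays in `coaching`.
#'   \item `continue_choice` (payload `continue`): `adherent` ->
#'     `continued_coaching` or `stopped_after_adherent`.
#'   \item `followup_response` (payload `answer`): from
#'     `stopped_after_adherent` or `followup_maintained` to
#'     `followup_maintained`, `relapsed_recoaching`, or `relapsed_stopped`.
#'   \item `study_end`: legal everywhere; `nonadherent`/`ic_assessed`
#'     resolve to `never_started_coaching`, any other state is frozen.
#' }
#'
#' @param state Current state name, or `NULL` before assessment.
#' @param event A list with at least `type`, plus the payload fields above.
#' @return The successor state name.
#' @export
#' @examples
#' step("nonadherent", list(type = "ic_rating"))
step <- function(state, event) {
  type <- event$type
  illegal <- function() {
    stop(sprintf("illegal transition: event '%s' in state '%s'",
                 type, if (is.null(state)) "<unassessed>" else state),
         call. = FALSE)
  }
  if (is.null(state)) {
    return(switch(type,
      assessed_adherent = "adherent_at_assessment",
      assessed_nonadherent = "nonadherent",
      illegal()
    ))
  }
  stopifnot(state %in% hc_states())
  if (type == "study_end") {
    if (state %in% c("nonadherent", "ic_assessed")) {
      return("never_started_coaching")
    }
    return(state)
  }
  switch(state,
    adherent_at_assessment = illegal(),
    nonadherent = switch(type,
      education_viewed = "nonadherent",
      ic_rating = "ic_assessed",
      illegal()
    ),
    ic_assessed = switch(type,
      education_viewed = "ic_assessed",
      goal_set = "coaching",
      illegal()
    ),
    coaching = switch(type,
      diary_entry = "coaching",
      goal_set = "coaching",
      week_evaluated =
        if (isTRUE(event$adherence_met)) "adherent" else "coaching",
      illegal()
    ),
    adherent = switch(type,
      continue_choice = handle_adherent_choice(isTRUE(event$continue)),
      illegal()
    ),
    continued_coaching = switch(type,
      goal_set = "coaching",
      illegal()
    ),
    stopped_after_adherent = ,
    followup_maintained = switch(type,
      followup_response = switch(event$answer,
        maintained = "followup_maintained",
        relapsed_retry = "relapsed_recoaching",
        relapsed_stop = "relapsed_stopped",
        stop("unknown follow-up answer: ", event$answer, call. = FALSE)
      ),
      illegal()
    ),
    relapsed_recoaching = switch(type,
      goal_set = "coaching",
      illegal()
    ),
    relapsed_stopped = illegal(),
    never_started_coaching = illegal()
  )
}
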