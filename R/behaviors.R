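#' Coached self-care behaviors and education-only topics
#'
#' The program coaches four self-care behaviors; further topics receive
#' education and tips but are never coached.
#'
#' @return A character vector of behavior identifiers.
#' @export
#' @examples
#' hc_behaviors()
hc_behaviors <- function() {
  c("physical_activity", "low_salt_diet", "fluid_restriction", "medication_intake")
}

#' @rdname hc_behaviors
#' @export
hc_education_only_topics <- function() {
  c("symptom_monitoring", "alcohol", "sleep")
}

# Ordered activity-minute bands (minutes per active day).
hc_bands <- function() c("<=15", "15-30", "30-45", "45-60")

# Effort ratings ordered from easiest to hardest; ties in the weekly modal
# effort resolve toward the harder rating.
hc_efforts <- function() c("too_easy", "just_right", "too_hard")

band_rank <- function(band) match(band, hc_bands())

# days-since-epoch integer -> Date without parsing an origin string
int2date <- function(x) structure(as.numeric(x), class = "Date")

effort_rank <- function(effort) match(effort, hc_efforts())

assert_behavior <- function(behavior, allow_global = FALSE) {
  ok <- hc_behaviors()
  if (allow_global) ok <- c(ok, "global")
  if (!is.character(behavior) || length(behavior) != 1L || !behavior %in% ok) {
    stop("unknown behavior: ", paste(behavior, collapse = ", "), call. = FALSE)
  }
  invisible(behavior)
}

#' Journey states of the coaching state machine
#'
#' Per patient and behavior, the engine tracks one of these states. A patient
#' can hold different states for different behaviors simultaneously.
#'
#' @return Character vector of state names.
#' @export
hc_states <- function() {
  c("adherent_at_assessment", "nonadherent", "ic_assessed", "coaching",
    "adherent", "continued_coaching", "stopped_after_adherent",
    "followup_maintained", "relapsed_recoaching", "relapsed_stopped",
    "never_started_coaching")
}
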