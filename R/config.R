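#' Program configuration
#'
#' All tunable thresholds of the education-and-coaching engine in one list.
#' Defaults:
#' \describe{
#'   \item{behavior_cutoff}{4 — on the 5-point agree scale of the behavior
#'     questionnaire, an answer at or above this counts as performing the
#'     behavior; any item below the cutoff flags the behavior nonadherent.}
#'   \item{knowledge_tolerance}{0 — number of wrong-or-don't-know knowledge
#'     answers tolerated per behavior before knowledge is flagged
#'     insufficient ("don't know" always scores as not correct).}
#'   \item{importance_threshold, confidence_threshold}{7 — on the 0-10
#'     motivational-interviewing rulers, ratings below the threshold trigger
#'     myth/truth (importance) or barrier/tip (confidence) feedback;
#'     importance is evaluated first.}
#'   \item{struggle_weeks}{3 — consecutive missed weeks that raise a nurse
#'     alert.}
#'   \item{followup_days}{60 — days between stopping coaching (after
#'     becoming adherent) and each maintenance follow-up questionnaire.}
#'   \item{met_fraction}{1 — fraction of the 7 diary days that must meet the
#'     target for a salt/fluid week to count as achieved (1 = all days;
#'     missing diary days count as not met).}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A list with class `hc_config`.
#' @export
#' @examples
#' hc_config(struggle_weeks = 2)
hc_config <- function(...) {
  cfg <- list(
    behavior_cutoff = 4L,
    knowledge_tolerance = 0L,
    importance_threshold = 7L,
    confidence_threshold = 7L,
    struggle_weeks = 3L,
    followup_days = 60L,
    met_fraction = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "hc_config")
}

#' Read a configuration file
#'
#' Configuration is a flat YAML mapping of the fields of [hc_config()];
#' missing fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `hc_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(hc_config, raw)
}

#' @export
print.hc_config <- function(x, ...) {
  cat("<hc_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}
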