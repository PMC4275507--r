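#' Score the behavior questionnaire
#'
#' A behavior is flagged as not performed (`does_behavior = FALSE`) if any
#' of its behavior items is answered below the adherent cutoff
#' (`config$behavior_cutoff`, default 4 on the 5-point agree scale).
#'
#' @param responses Tibble of questionnaire responses with columns
#'   `patient_id`, `item_id`, `answer` (integer index into the item's
#'   options; for knowledge items 0 encodes "I don't know").
#' @param items An item bank tibble, default [default_item_bank()].
#' @param config An [hc_config()] list.
#' @return A tibble with columns `patient_id`, `behavior`, `does_behavior`.
#' @export
#' @examples
#' bank <- default_item_bank()
#' resp <- tibble::tibble(
#'   patient_id = "p1",
#'   item_id = bank$item_id[bank$kind == "behavior"],
#'   answer = 5L
#' )
#' score_behavior(resp)
score_behavior <- function(responses, items = default_item_bank(),
                           config = hc_config()) {
  scored <- join_responses(responses, items, kind = "behavior")
  check_assessment_complete(scored, responses, kind = "behavior")
  scored |>
    dplyr::group_by(.data$patient_id, .data$behavior) |>
    dplyr::summarise(
      does_behavior = all(.data$answer >= config$behavior_cutoff),
      .groups = "drop"
    )
}

#' Score the knowledge questionnaire
#'
#' Knowledge for a behavior is flagged insufficient
#' (`has_knowledge = FALSE`) when the count of wrong-or-don't-know answers
#' exceeds `config$knowledge_tolerance` (default 0). "I don't know"
#' (answer 0) always scores as not correct.
#'
#' @inheritParams score_behavior
#' @return A tibble with columns `patient_id`, `behavior`, `has_knowledge`.
#' @export
score_knowledge <- function(responses, items = default_item_bank(),
                            config = hc_config()) {
  scored <- join_responses(responses, items, kind = "knowledge")
  check_assessment_complete(scored, responses, kind = "knowledge")
  scored |>
    dplyr::group_by(.data$patient_id, .data$behavior) |>
    dplyr::summarise(
      has_knowledge =
        sum(.data$answer != .data$correct) <= config$knowledge_tolerance,
      .groups = "drop"
    )
}

join_responses <- function(responses, items, kind) {
  stopifnot(all(c("patient_id", "item_id", "answer") %in% names(responses)))
  bank <- items[items$kind == kind, ]
  scored <- dplyr::inner_join(responses, bank, by = "item_id")
  bad <- scored$answer > scored$n_options |
    scored$answer < ifelse(kind == "knowledge", 0L, 1L)
  if (any(bad)) {
    stop("answer index out of range for item(s): ",
         paste(unique(scored$item_id[bad]), collapse = ", "), call. = FALSE)
  }
  scored
}

check_assessment_complete <- function(scored, responses, kind) {
  patients <- unique(responses$patient_id)
  have <- dplyr::distinct(scored, .data$patient_id, .data$behavior)
  need <- tidyr::expand_grid(patient_id = patients, behavior = hc_behaviors())
  missing <- dplyr::anti_join(need, have, by = c("patient_id", "behavior"))
  if (nrow(missing) > 0) {
    stop("incomplete ", kind, " assessment: no items answered for ",
         paste(unique(missing$behavior), collapse = ", "),
         " (patient ", paste(unique(missing$patient_id), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(scored)
}

#' Place a patient in the knowledge-by-behavior matrix
#'
#' The 2x2 grid drives what the program offers per behavior:
#' area 1 (neither knows nor does) gets education followed by coaching;
#' area 2 (does but doesn't know) gets education only; area 3 (knows but
#' doesn't do) gets coaching only; area 4 (knows and does) needs neither.
#'
#' @param does_behavior,has_knowledge Logical vectors (recycled together).
#' @param behavior Optional behavior identifier(s) carried through.
#' @return A tibble with columns `behavior`, `does_behavior`,
#'   `has_knowledge`, `area`, `path`.
#' @export
#' @examples
#' place_in_matrix(FALSE, FALSE)
place_in_matrix <- function(does_behavior, has_knowledge, behavior = NA_character_) {
  stopifnot(is.logical(does_behavior), is.logical(has_knowledge),
            !anyNA(does_behavior), !anyNA(has_knowledge))
  n <- max(length(does_behavior), length(has_knowledge), length(behavior))
  does <- rep_len(does_behavior, n)
  knows <- rep_len(has_knowledge, n)
  area <- dplyr::case_when(
    !does & !knows ~ 1L,
    does & !knows ~ 2L,
    !does & knows ~ 3L,
    does & knows ~ 4L
  )
  path <- c("education_then_coaching", "education", "coaching", "none")[area]
  tibble::tibble(
    behavior = rep_len(behavior, n),
    does_behavior = does, has_knowledge = knows,
    area = area, path = path
  )
}

#' Importance and confidence assessment
#'
#' For each behavior a patient does not perform, the patient rates perceived
#' importance and confidence on 0-10 rulers. Low importance (below
#' `config$importance_threshold`) triggers myth/truth messages for the
#' behavior; otherwise low confidence triggers barrier tips; otherwise the
#' patient is ready and gets an encouragement message. Importance is
#' evaluated first, so exactly one category fires.
#'
#' @param behavior A coached behavior identifier.
#' @param importance,confidence Integer ratings 0-10.
#' @param config An [hc_config()] list.
#' @param catalog A content catalog tibble.
#' @return A one-row tibble with `behavior`, `importance`, `confidence`,
#'   `category`, and a `messages` list-column of content ids.
#' @export
#' @examples
#' assess_importance_confidence("physical_activity", 2, 9)
assess_importance_confidence <- function(behavior, importance, confidence,
                                         config = hc_config(),
                                         catalog = default_catalog()) {
  assert_behavior(behavior)
  for (r in c(importance, confidence)) {
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 10 ||
        r != as.integer(r)) {
      stop("importance and confidence must be integers in 0-10", call. = FALSE)
    }
  }
  if (importance < config$importance_threshold) {
    category <- "low_importance"
    msgs <- catalog$content_id[catalog$kind == "myth_truth" &
                                 catalog$behavior == behavior]
  } else if (confidence < config$confidence_threshold) {
    category <- "low_confidence"
    msgs <- catalog$content_id[catalog$kind == "barrier_tip" &
                                 catalog$behavior == behavior]
  } else {
    category <- "ready"
    msgs <- catalog$content_id[catalog$kind == "encouragement" &
                                 catalog$behavior == behavior]
  }
  tibble::tibble(
    behavior = behavior,
    importance = as.integer(importance), confidence = as.integer(confidence),
    category = category, messages = list(msgs)
  )
}

# Loop-diuretic doses equivalent to 40 mg/d furosemide.
diuretic_equivalents <- c(furosemide = 40, bumetanide = 1, torasemide = 10)

#' Screen a patient record for trial eligibility
#'
#' Inclusion requires a heart-failure diagnosis that is not rapidly
#' reversible, a loop diuretic at >= 40 mg/d furosemide equivalent
#' (1 mg/d bumetanide, 10 mg/d torasemide), evidence of advanced or
#' unstable disease (hospital admission for heart failure within 60 days,
#' or persistent NYHA class III/IV), and elevated NT-proBNP
#' (>= 1000 pg/mL in sinus rhythm, >= 2000 pg/mL otherwise). Exclusions:
#' age under 18, inability to operate the telehealth system, inability to
#' communicate in the local language.
#'
#' @param rec A named list or one-row data frame with fields `ntprobnp`,
#'   `sinus_rhythm`, `diuretic`, `diuretic_mg_day`, `nyha`,
#'   `hf_admission_within_days` (days since admission, or `NA`),
#'   `hf_diagnosis`, `rapidly_reversible_cause`, `age_years`,
#'   `can_operate_system`, `speaks_local_language`.
#' @return A list with `eligible` (logical) and `reasons` (character vector
#'   naming every failed criterion; empty when eligible).
#' @export
#' @examples
#' check_eligibility(eligibility_record(ntprobnp = 1500, sinus_rhythm = FALSE))
check_eligibility <- function(rec) {
  rec <- as.list(rec)
  required <- c("ntprobnp", "sinus_rhythm", "diuretic", "diuretic_mg_day",
                "nyha", "hf_admission_within_days", "hf_diagnosis",
                "rapidly_reversible_cause", "age_years", "can_operate_system",
                "speaks_local_language")
  miss <- setdiff(required, names(rec))
  if (length(miss) > 0) {
    stop("incomplete eligibility record, missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(rec$ntprobnp >= 0, rec$nyha %in% 1:4)
  drug <- tolower(rec$diuretic)
  if (!drug %in% names(diuretic_equivalents)) {
    stop("unknown loop diuretic: ", rec$diuretic, call. = FALSE)
  }
  reasons <- character()
  if (!isTRUE(rec$hf_diagnosis)) {
    reasons <- c(reasons, "no clinical diagnosis of heart failure")
  }
  if (isTRUE(rec$rapidly_reversible_cause)) {
    reasons <- c(reasons, "rapidly reversible cause of heart failure")
  }
  furosemide_eq <- rec$diuretic_mg_day / diuretic_equivalents[[drug]] * 40
  if (furosemide_eq < 40) {
    reasons <- c(reasons, "loop diuretic below 40 mg/d furosemide equivalent")
  }
  recent_admission <- !is.na(rec$hf_admission_within_days) &&
    rec$hf_admission_within_days <= 60
  if (!recent_admission && rec$nyha < 3) {
    reasons <- c(reasons, "no evidence of advanced or unstable disease")
  }
  if (rec$sinus_rhythm && rec$ntprobnp < 1000) {
    reasons <- c(reasons, "NT-proBNP below 1000 for sinus rhythm")
  }
  if (!rec$sinus_rhythm && rec$ntprobnp < 2000) {
    reasons <- c(reasons, "NT-proBNP below 2000 for non-sinus rhythm")
  }
  if (rec$age_years < 18) {
    reasons <- c(reasons, "aged under 18")
  }
  if (!isTRUE(rec$can_operate_system)) {
    reasons <- c(reasons, "unable to operate or comply with the telehealth system")
  }
  if (!isTRUE(rec$speaks_local_language)) {
    reasons <- c(reasons, "unable to communicate in the local language")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' @rdname check_eligibility
#' @param ... Overrides of the default (eligible) record fields.
#' @export
eligibility_record <- function(...) {
  rec <- list(
    ntprobnp = 1000, sinus_rhythm = TRUE,
    diuretic = "furosemide", diuretic_mg_day = 40,
    nyha = 3L, hf_admission_within_days = NA_integer_,
    hf_diagnosis = TRUE, rapidly_reversible_cause = FALSE,
    age_years = 66L, can_operate_system = TRUE, speaks_local_language = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(rec))
  if (length(unknown) > 0) {
    stop("unknown eligibility fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rec[names(dots)] <- dots
  rec
}

#' Screen a table of eligibility records
#'
#' @param records A tibble whose columns are the fields of
#'   [eligibility_record()], one row per candidate.
#' @return `records` with `eligible` and a `reasons` list-column appended.
#' @export
screen_eligibility <- function(records) {
  verdicts <- purrr::pmap(records, function(...) check_eligibility(list(...)))
  records$eligible <- purrr::map_lgl(verdicts, "eligible")
  records$reasons <- purrr::map(verdicts, "reasons")
  records
}
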