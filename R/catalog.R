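#' Default questionnaire item bank
#'
#' Twelve behavior items (three per coached behavior) on a 5-point agree
#' scale modelled on the European Heart Failure Self-Care Behaviour Scale —
#' including the added food-label reading item — and fifteen knowledge items
#' (3 answer options plus a "don't know" option) modelled on the Dutch Heart
#' Failure Knowledge Scale. The bank is configuration, not a claim of
#' fidelity to the validated instruments, which are not reproduced here:
#' deployments supply their own bank in the same shape.
#'
#' Behavior items are answered 1 ("I don't agree at all / never") to
#' 5 ("I fully agree / always"); knowledge items are answered 1-3 with the
#' correct option recorded in `correct`, and 0 encodes "I don't know".
#'
#' @return A tibble with columns `item_id`, `behavior`, `kind`
#'   (`"behavior"` or `"knowledge"`), `n_options`, `correct` (NA for
#'   behavior items), `text`.
#' @export
#' @examples
#' default_item_bank()
default_item_bank <- function() {
  b <- function(behavior, n, texts) {
    tibble::tibble(
      item_id = paste0(substr(behavior, 1, 3), "_b", seq_len(n)),
      behavior = behavior, kind = "behavior",
      n_options = 5L, correct = NA_integer_, text = texts
    )
  }
  k <- function(behavior, n, correct, texts) {
    tibble::tibble(
      item_id = paste0(substr(behavior, 1, 3), "_k", seq_len(n)),
      behavior = behavior, kind = "knowledge",
      n_options = 3L, correct = as.integer(correct), text = texts
    )
  }
  dplyr::bind_rows(
    b("physical_activity", 3, c(
      "I am physically active on a regular basis",
      "I exercise even on days I feel tired",
      "I take rest breaks between periods of activity"
    )),
    b("low_salt_diet", 3, c(
      "I eat a low salt diet",
      "I read the label information on food packages to know their salt (sodium) content",
      "I avoid adding salt when cooking"
    )),
    b("fluid_restriction", 3, c(
      "I limit the amount of fluids I drink",
      "I count all drinks towards my daily fluid allowance",
      "I keep to my fluid limit on warm days"
    )),
    b("medication_intake", 3, c(
      "I take my medication as prescribed",
      "I take my medication at the same times every day",
      "I use a routine so I do not forget doses"
    )),
    k("physical_activity", 4, c(2, 1, 3, 2), c(
      "How often should a person with heart failure be active?",
      "What should you do when activity feels too hard?",
      "Why is regular rest important during activity?",
      "Which activity intensity is recommended?"
    )),
    k("low_salt_diet", 4, c(1, 3, 2, 1), c(
      "Why does salt matter in heart failure?",
      "Which foods are typically high in salt?",
      "What does sodium on a food label refer to?",
      "What is a sensible daily sodium target?"
    )),
    k("fluid_restriction", 3, c(2, 2, 1), c(
      "Why are fluids restricted in heart failure?",
      "Which items count as fluid intake?",
      "What is a common daily fluid limit?"
    )),
    k("medication_intake", 4, c(3, 1, 2, 3), c(
      "Why must diuretics be taken daily?",
      "What should you do if you miss a dose?",
      "Why continue medication when feeling well?",
      "What can worsen if medication is skipped?"
    ))
  )
}

#' Default content catalog
#'
#' Maps behaviors and knowledge gaps to education items (video and tip
#' identifiers with title stubs), myth/truth messages used for
#' low-importance feedback, barrier tips used for low-confidence feedback,
#' encouragement messages, and the weekly feedback message templates used
#' by the coaching decision table. Media are identifier and stub only.
#'
#' @return A tibble with columns `content_id`, `behavior` (a coached
#'   behavior, an education-only topic, or `"any"` for generic feedback
#'   templates), `kind`, `text`.
#' @export
default_catalog <- function() {
  rows <- function(kind, behavior, content_id, text) {
    tibble::tibble(content_id = content_id, behavior = behavior, kind = kind, text = text)
  }
  coached <- hc_behaviors()
  dplyr::bind_rows(
    # education videos and tips, one pair per coached behavior and topic
    rows("video", rep(c(coached, hc_education_only_topics()), each = 1),
         paste0("video_", c(coached, hc_education_only_topics())),
         paste("Video:", gsub("_", " ", c(coached, hc_education_only_topics())))),
    rows("tip", rep(c(coached, hc_education_only_topics()), each = 1),
         paste0("tip_", c(coached, hc_education_only_topics())),
         paste("Tips:", gsub("_", " ", c(coached, hc_education_only_topics())))),
    # myth/truth messages delivered on low importance
    rows("myth_truth", "physical_activity", "activity_not_safe",
         paste("Myth: Physical activity is not safe for people with heart failure.",
               "Truth: It is important to be physically active and to rest regularly in between.")),
    rows("myth_truth", "low_salt_diet", "salt_food_tasteless",
         "Myth: Low-salt food has no taste. Truth: herbs and spices keep meals tasty."),
    rows("myth_truth", "fluid_restriction", "fluid_thirst_harmful",
         "Myth: Restricting fluids is harmful. Truth: an agreed limit reduces congestion."),
    rows("myth_truth", "medication_intake", "medication_only_when_ill",
         "Myth: Medication is only needed when feeling unwell. Truth: daily intake keeps you stable."),
    # barrier tips delivered on low confidence
    rows("barrier_tip", coached, paste0("barrier_", coached),
         paste("Practical tips for everyday barriers:", gsub("_", " ", coached))),
    # encouragement when importance and confidence are both high
    rows("encouragement", coached, paste0("ready_", coached),
         paste("You seem ready to work on", gsub("_", " ", coached), "- let's set a goal.")),
    # weekly feedback templates (decision-table outputs)
    rows("feedback_template", "any", "congratulate",
         "Well done - you reached your goal this week."),
    rows("feedback_template", "any", "consider_raising",
         "You reached your goal and found it easy - consider a more ambitious goal."),
    rows("feedback_template", "any", "encourage_retry",
         "You did not quite reach your goal - keep going next week."),
    rows("feedback_template", "any", "encourage_retry_or_raise",
         "You missed your goal but found the sessions easy - try again, or adjust the plan."),
    rows("feedback_template", "any", "reduce_goal",
         "That looked hard - consider setting a less ambitious goal for next week."),
    rows("feedback_template", "any", "contact_nurse",
         "Reaching your goal keeps being difficult - please contact your heart failure nurse.")
  )
}

#' Tailored education plan for a matrix placement
#'
#' Area 1 patients (neither know nor do) get gap-matched videos and tips
#' that must be viewed before coaching starts; area 2 (do but don't know)
#' get the same items without gating; areas 3 and 4 get no required items —
#' the full library stays available.
#'
#' @param placement A one-row tibble from [place_in_matrix()].
#' @param knowledge_gaps Character vector of behaviors with insufficient
#'   knowledge (usually from [score_knowledge()]).
#' @param catalog A content catalog tibble, default [default_catalog()].
#' @return A tibble of content rows with a `required_before_coaching` flag.
#' @export
education_plan <- function(placement, knowledge_gaps = character(),
                           catalog = default_catalog()) {
  stopifnot(is.data.frame(placement), nrow(placement) == 1L)
  behavior <- placement$behavior
  assert_behavior(behavior)
  area <- placement$area
  if (area %in% c(3L, 4L)) {
    return(dplyr::mutate(catalog[0, ], required_before_coaching = logical()))
  }
  gapped <- union(behavior, intersect(knowledge_gaps, behavior))
  items <- dplyr::filter(
    catalog, .data$kind %in% c("video", "tip"), .data$behavior %in% gapped
  )
  items <- dplyr::arrange(items, dplyr::desc(.data$kind == "video"), .data$content_id)
  dplyr::mutate(items, required_before_coaching = area == 1L)
}

#' Read a content catalog from a CSV file
#'
#' Deployments can swap the educational and feedback content by supplying
#' their own catalog file with columns `content_id`, `behavior`, `kind`,
#' `text`. The packaged default lives at
#' `system.file("extdata", "catalog.csv", package = "hfcoach")`.
#'
#' @param path Path to a catalog CSV.
#' @return A catalog tibble.
#' @export
read_catalog <- function(path) {
  cat <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("content_id", "behavior", "kind", "text")
  miss <- setdiff(needed, names(cat))
  if (length(miss) > 0) {
    stop("catalog is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cat$content_id) > 0) {
    stop("duplicate content ids in catalog", call. = FALSE)
  }
  cat[, needed]
}

#' Resolve a message or content identifier
#'
#' @param message_id A content identifier.
#' @param catalog A content catalog tibble.
#' @return The single matching catalog row.
#' @export
resolve_message <- function(message_id, catalog = default_catalog()) {
  hit <- dplyr::filter(catalog, .data$content_id == message_id)
  if (nrow(hit) != 1L) {
    stop("unknown content id: ", message_id, call. = FALSE)
  }
  hit
}
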