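coerce_to <- function(vec, proto) {
  switch(class(proto)[1],
    character = as.character(vec),
    integer = as.integer(vec),
    numeric = as.numeric(vec),
    logical = as.logical(vec),
    vec
  )
}

# Canonical column order of the event tibble; also the canonical key order
# of the line-delimited JSON log format.
event_columns <- function() {
  c("patient_id", "date", "behavior", "event_type",
    "item_id", "answer", "importance", "confidence", "content_id",
    "days", "band", "sodium_target", "max_intake", "doses",
    "minutes_band", "effort", "met_target", "doses_taken",
    "choice", "followup", "reason")
}

event_types <- function() {
  c("questionnaire_response", "ic_rating", "education_viewed", "goal_set",
    "diary_entry", "continue_choice", "followup_response", "study_end",
    "non_start_reason")
}

# Payload fields that must be present (non-NA) per event type.
required_payload <- function(type) {
  switch(type,
    questionnaire_response = c("item_id", "answer"),
    ic_rating = c("importance", "confidence"),
    education_viewed = "content_id",
    goal_set = character(),   # behavior-specific, checked below
    diary_entry = character(),
    continue_choice = "choice",
    followup_response = "followup",
    study_end = character(),
    non_start_reason = "reason"
  )
}

#' An empty journey-event tibble
#'
#' The event log is a tibble with one row per timestamped event and a fixed
#' wide schema; fields not used by an event type are `NA` and are omitted
#' when the log is written to disk.
#'
#' @return A zero-row tibble with the canonical event columns.
#' @export
empty_events <- function() {
  tibble::tibble(
    patient_id = character(), date = as.Date(character()),
    behavior = character(), event_type = character(),
    item_id = character(), answer = integer(),
    importance = integer(), confidence = integer(),
    content_id = character(),
    days = integer(), band = character(), sodium_target = integer(),
    max_intake = double(), doses = integer(),
    minutes_band = character(), effort = character(),
    met_target = logical(), doses_taken = integer(),
    choice = character(), followup = character(), reason = character()
  )
}

# Row constructor used by the fixture and the simulator.
event_row <- function(patient_id, date, behavior, event_type, ...) {
  row <- empty_events()[0, ]
  row[1, "patient_id"] <- patient_id
  row$date <- as.Date(date)
  row$behavior <- behavior
  row$event_type <- event_type
  dots <- list(...)
  for (nm in names(dots)) row[[nm]][1] <- dots[[nm]]
  row
}

validate_events <- function(events, where = NULL) {
  loc <- function(i) if (is.null(where)) paste0("event ", i) else
    paste0("line ", where[i])
  base_needed <- c("patient_id", "date", "behavior", "event_type")
  for (col in base_needed) {
    bad <- which(is.na(events[[col]]) | events[[col]] == "")
    if (length(bad) > 0) {
      stop("malformed record at ", loc(bad[1]), ": missing ", col,
           call. = FALSE)
    }
  }
  bad_type <- which(!events$event_type %in% event_types())
  if (length(bad_type) > 0) {
    stop("malformed record at ", loc(bad_type[1]), ": unknown event_type '",
         events$event_type[bad_type[1]], "'", call. = FALSE)
  }
  bad_beh <- which(!events$behavior %in% c(hc_behaviors(), "global"))
  if (length(bad_beh) > 0) {
    stop("malformed record at ", loc(bad_beh[1]), ": unknown behavior '",
         events$behavior[bad_beh[1]], "'", call. = FALSE)
  }
  for (type in unique(events$event_type)) {
    needed <- required_payload(type)
    if (length(needed) == 0) next
    idx <- which(events$event_type == type)
    for (col in needed) {
      bad <- idx[is.na(events[[col]][idx])]
      if (length(bad) > 0) {
        stop("malformed record at ", loc(bad[1]), ": ", type,
             " requires ", col, call. = FALSE)
      }
    }
  }
  # events per patient must be timestamp-ordered (file order within a day)
  ord <- events |>
    dplyr::mutate(.line = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$date), .groups = "drop")
  if (any(!ord$ok)) {
    stop("out-of-order timestamps for patient ",
         ord$patient_id[!ord$ok][1], call. = FALSE)
  }
  invisible(events)
}

#' Read a line-delimited event log
#'
#' One JSON object per line; fields are validated against the event schema
#' (required payload per event type, known event types and behaviors) and
#' each patient's events must be date-ordered. Errors name the offending
#' line.
#'
#' @param path Path to an event-log file.
#' @return A validated event tibble.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("no such event log: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_events())
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(names(rec))) {
      stop("malformed record at line ", i, ": not a JSON object",
           call. = FALSE)
    }
    parsed[[i]] <- rec
  }
  cols <- event_columns()
  get_col <- function(nm, proto) {
    vals <- lapply(parsed, function(r) if (is.null(r[[nm]])) NA else r[[nm]])
    vec <- unlist(vals, use.names = FALSE)
    if (inherits(proto, "Date")) as.Date(vec) else coerce_to(vec, proto)
  }
  proto <- empty_events()
  data <- lapply(cols, function(nm) get_col(nm, proto[[nm]]))
  names(data) <- cols
  events <- tibble::as_tibble(data)
  validate_events(events, where = seq_len(nrow(events)))
  events
}

#' Write a line-delimited event log
#'
#' One JSON object per line in canonical field order with `NA` fields
#' omitted; output is byte-stable for identical input, so rewriting a log
#' reproduces it exactly.
#'
#' @param events An event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  validate_events(events)
  cols <- event_columns()
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    rec <- list()
    for (nm in cols) {
      v <- events[[nm]][i]
      if (is.na(v)) next
      rec[[nm]] <- if (inherits(v, "Date")) format(v, "%Y-%m-%d") else v
    }
    lines[i] <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}
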