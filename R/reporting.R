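#' Round half away from zero
#'
#' Percentages in the journey tables round half-up (50/123 prints as 40.7),
#' unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

table_pct <- function(n, den) {
  ifelse(den > 0, round_half_up(100 * n / den, 1), NA_real_)
}

transition_rows <- function() {
  c("were_nonadherent", "started_coaching", "became_adherent",
    "stopped_immediately", "continued_coaching", "stopped_later",
    "continued_until_end")
}

as_replay <- function(x, ...) {
  if (inherits(x, "hc_replay")) x else replay_journeys(x, ...)
}

#' Journey transition table
#'
#' Counts, per behavior, the patients who entered each state of the
#' coaching process at least once: were nonadherent at assessment, started
#' coaching, became adherent (two consecutive achieved weeks), stopped
#' coaching immediately versus continued after becoming adherent, and —
#' among continuers — stopped later versus continued until study end.
#' Each row's denominator is the count of its parent row, and percentages
#' round half-up to one decimal. Patients still in coaching at study end
#' without having become adherent are reported in the `censored` attribute.
#'
#' @param x An `hc_replay` object or an event tibble (replayed first).
#' @param ... Passed to [replay_journeys()] when `x` is an event tibble.
#' @return A tibble of class `hc_transition_table` with columns `behavior`,
#'   `row`, `n`, `denominator`, `pct`.
#' @export
transition_table <- function(x, ...) {
  if (is.data.frame(x) && nrow(x) == 0) {
    out <- tidyr::expand_grid(behavior = hc_behaviors(), row = transition_rows())
    out$n <- 0L
    out$denominator <- 0L
    out$pct <- NA_real_
    return(new_transition_table(out, censored = integer()))
  }
  j <- as_replay(x, ...)$journeys
  per_behavior <- function(beh) {
    b <- j[j$behavior == beh, ]
    nonadh <- sum(!b$does_behavior)
    started <- sum(b$started_coaching)
    adherent <- sum(b$became_adherent)
    stopped_now <- sum(b$first_choice == "stop", na.rm = TRUE)
    continued <- sum(b$continued)
    stopped_later <- sum(b$stopped_later)
    until_end <- sum(b$continued & !b$stopped_later)
    n <- c(nonadh, started, adherent, stopped_now, continued,
           stopped_later, until_end)
    den <- c(nrow(b), nonadh, started, adherent, adherent,
             continued, continued)
    tibble::tibble(behavior = beh, row = transition_rows(),
                   n = as.integer(n), denominator = as.integer(den),
                   pct = table_pct(n, den))
  }
  out <- dplyr::bind_rows(lapply(hc_behaviors(), per_behavior))
  censored <- j |>
    dplyr::filter(.data$started_coaching, !.data$became_adherent) |>
    dplyr::count(.data$behavior, name = "still_coaching_at_end")
  new_transition_table(out, censored = censored)
}

new_transition_table <- function(x, censored) {
  structure(x, censored = censored,
            class = c("hc_transition_table", class(tibble::tibble())))
}

#' @export
print.hc_transition_table <- function(x, ...) {
  wide <- tibble::as_tibble(x) |>
    dplyr::mutate(cell = sprintf("%d/%d (%s)", .data$n, .data$denominator,
                                 ifelse(is.na(.data$pct), "-",
                                        formatC(.data$pct, format = "f",
                                                digits = 1)))) |>
    dplyr::select("behavior", "row", "cell") |>
    tidyr::pivot_wider(names_from = "behavior", values_from = "cell")
  print(as.data.frame(wide), right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Follow-up questionnaire tally
#'
#' Counts, per behavior, the patients who received (i.e. responded to) a
#' maintenance follow-up questionnaire after stopping coaching, split by
#' their first response: behavior maintained, relapsed and restarted
#' coaching, or relapsed without retrying.
#'
#' @inheritParams transition_table
#' @return A tibble with one row per behavior.
#' @export
followup_table <- function(x, ...) {
  if (is.data.frame(x) && nrow(x) == 0) {
    return(tibble::tibble(
      behavior = hc_behaviors(), received = 0L, maintained = 0L,
      relapsed_retry = 0L, relapsed_no_retry = 0L
    ))
  }
  j <- as_replay(x, ...)$journeys
  j |>
    dplyr::group_by(behavior = factor(.data$behavior, hc_behaviors())) |>
    dplyr::summarise(
      received = sum(!is.na(.data$first_followup)),
      maintained = sum(.data$first_followup == "maintained", na.rm = TRUE),
      relapsed_retry = sum(.data$first_followup == "relapsed_retry",
                           na.rm = TRUE),
      relapsed_no_retry = sum(.data$first_followup == "relapsed_stop",
                              na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::complete(behavior, fill = list(received = 0L, maintained = 0L,
                                          relapsed_retry = 0L,
                                          relapsed_no_retry = 0L)) |>
    dplyr::mutate(behavior = as.character(.data$behavior))
}

#' Distribution of goals reached on becoming adherent
#'
#' For each patient who became adherent, the goal reached in the second of
#' the two consecutive achieved weeks. Physical activity yields a minutes
#' band by planned-days matrix; low-salt diet yields counts per daily
#' sodium target (1-5 g, 5 encoding ">= 5").
#'
#' @inheritParams transition_table
#' @param behavior `"physical_activity"` or `"low_salt_diet"`.
#' @return An `hc_goal_matrix` tibble; for physical activity columns
#'   `band`, `days`, `n` over the full grid, for low-salt columns
#'   `sodium_target`, `n`.
#' @export
goal_distribution <- function(x, behavior, ...) {
  assert_behavior(behavior)
  if (!behavior %in% c("physical_activity", "low_salt_diet")) {
    stop("goal distributions are reported for physical activity and ",
         "low-salt diet", call. = FALSE)
  }
  goals <- if (is.data.frame(x) && nrow(x) == 0) {
    tibble::tibble(goal_band = character(), goal_days = integer(),
                   goal_sodium_target = integer())
  } else {
    j <- as_replay(x, ...)$journeys
    j[j$behavior == behavior & j$became_adherent, , drop = FALSE]
  }
  if (behavior == "physical_activity") {
    grid <- tidyr::expand_grid(band = hc_bands(), days = 1:7)
    counts <- dplyr::count(goals, band = .data$goal_band,
                           days = .data$goal_days)
    out <- grid |>
      dplyr::left_join(counts, by = c("band", "days")) |>
      dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))
  } else {
    grid <- tibble::tibble(sodium_target = 1:5)
    counts <- dplyr::count(goals, sodium_target = .data$goal_sodium_target)
    out <- grid |>
      dplyr::left_join(counts, by = "sodium_target") |>
      dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))
  }
  as_goal_matrix(out, behavior)
}

#' Construct a goal matrix from counts
#'
#' Builds the same object as [goal_distribution()] from a plain table of
#' counts — for example a published distribution — so that
#' [aggregate_goal_share()] and subtotals work on it.
#'
#' @param counts For physical activity a tibble with `band`, `days`, `n`;
#'   for low-salt diet a tibble with `sodium_target`, `n`.
#' @param behavior `"physical_activity"` or `"low_salt_diet"`.
#' @return An `hc_goal_matrix` tibble.
#' @export
as_goal_matrix <- function(counts, behavior) {
  assert_behavior(behavior)
  stopifnot(is.data.frame(counts), "n" %in% names(counts))
  if (behavior == "physical_activity") {
    stopifnot(all(c("band", "days") %in% names(counts)),
              all(counts$band %in% hc_bands()), all(counts$days %in% 1:7))
  } else {
    stopifnot("sodium_target" %in% names(counts),
              all(counts$sodium_target %in% 1:5))
  }
  structure(tibble::as_tibble(counts), behavior = behavior,
            class = c("hc_goal_matrix", class(tibble::tibble())))
}

#' Subtotals of a goal matrix
#'
#' @param matrix An `hc_goal_matrix`.
#' @return A list with `total` and, for physical activity, `by_band` and
#'   `by_days` subtotal tibbles.
#' @export
goal_subtotals <- function(matrix) {
  stopifnot(inherits(matrix, "hc_goal_matrix"))
  out <- list(total = sum(matrix$n))
  if (attr(matrix, "behavior") == "physical_activity") {
    out$by_band <- matrix |>
      dplyr::group_by(.data$band) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
    out$by_days <- matrix |>
      dplyr::group_by(.data$days) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  }
  out
}

#' Share of reached goals satisfying a predicate
#'
#' Sums the matrix cells whose goal satisfies a predicate over the matrix
#' total, e.g. the share of adherent patients active on at least 4 days a
#' week, or with a sodium target of at most 2 g/d.
#'
#' @param matrix An `hc_goal_matrix`.
#' @param predicate An expression in the matrix columns (`days`, `band` —
#'   compare bands with [band_at_least()] — or `sodium_target`).
#' @param digits Decimal places for the percentage (default 0, as shares
#'   are quoted as whole percentages).
#' @return A one-row tibble with `count`, `total`, `pct`.
#' @export
#' @examples
#' m <- as_goal_matrix(
#'   tibble::tibble(band = "15-30", days = c(3, 5), n = c(2, 3)),
#'   "physical_activity"
#' )
#' aggregate_goal_share(m, days >= 4)
aggregate_goal_share <- function(matrix, predicate, digits = 0) {
  stopifnot(inherits(matrix, "hc_goal_matrix"))
  hit <- dplyr::filter(matrix, {{ predicate }})
  count <- sum(hit$n)
  total <- sum(matrix$n)
  tibble::tibble(
    count = as.integer(count), total = as.integer(total),
    pct = if (total > 0) round_half_up(100 * count / total, digits)
          else NA_real_
  )
}

#' Compare minute bands
#'
#' `TRUE` where `band` is at or above `reference` in the ordered band scale
#' `<=15 < 15-30 < 30-45 < 45-60`.
#'
#' @param band,reference Band labels.
#' @return Logical vector.
#' @export
band_at_least <- function(band, reference) {
  band_rank(band) >= band_rank(reference)
}

#' Reasons for not starting coaching
#'
#' Tallies the non-start reason records of patients who were nonadherent to
#' at least one behavior but never started coaching.
#'
#' @inheritParams transition_table
#' @return A tibble with `reason` and `n`, plus the number of distinct
#'   patients in the `n_patients` attribute.
#' @export
nonstart_reason_table <- function(x, ...) {
  reasons <- if (inherits(x, "hc_replay")) x$nonstart_reasons else
    dplyr::filter(x, .data$event_type == "non_start_reason")
  out <- dplyr::count(reasons, .data$reason)
  attr(out, "n_patients") <- dplyr::n_distinct(reasons$patient_id)
  out
}

#' Plot a transition table
#'
#' @param object An `hc_transition_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hc_transition_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(row = factor(.data$row, rev(transition_rows())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$row)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~behavior, nrow = 1) +
    ggplot2::labs(x = "patients entering state", y = NULL,
                  title = "Patient journeys through the coaching process")
}

#' Plot a goal matrix
#'
#' @param object An `hc_goal_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hc_goal_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (attr(object, "behavior") == "physical_activity") {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$days),
                                     y = factor(.data$band, hc_bands()),
                                     fill = .data$n)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
      ggplot2::labs(x = "planned active days per week",
                    y = "planned minutes per day",
                    title = "Physical activity goals reached when becoming adherent")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$sodium_target),
                                     y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "daily sodium target (g/d, 5 = >=5)",
                    y = "patients",
                    title = "Low-salt diet goals reached when becoming adherent")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
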