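#' Daily behavior totals and reporting coverage
#'
#' Classifies every entry (see [classify_behavior()]) and sums minutes per
#' child-day into physical-activity, sedentary, sleep and excluded-category
#' time, together with the day's reporting coverage in hours.
#'
#' Coverage counts all reported entries, including the three excluded
#' categories: a "my child was with someone else" block documents the day
#' even though it enters no behavior total. Set
#' `coverage_includes_excluded = FALSE` to count analyzable entries only.
#'
#' @param entries Tibble of diary entries.
#' @param profiles Tibble of child profiles.
#' @param coverage_includes_excluded Should excluded-category minutes count
#'   toward reported coverage? Default `TRUE`.
#' @param strict Error if any entry classifies to `NA` (combination outside
#'   the rule table). Default `TRUE`.
#' @return A tibble with one row per child-day: `child_id`, `date`,
#'   `weekday`, `weekend`, `pa_min`, `sb_min`, `sleep_min`, `excluded_min`,
#'   `coverage_hours`.
#' @examples
#' cfg <- simulation_config(n_children = 2, n_days = 2, seed = 1)
#' sim <- simulate_diary(simulate_cohort(cfg), cfg)
#' daily_totals(sim$entries, sim$profiles)
#' @export
daily_totals <- function(entries, profiles,
                         coverage_includes_excluded = TRUE,
                         strict = TRUE) {
  classified <- classify_behavior(entries, profiles)
  if (strict && anyNA(classified$behavior)) {
    n_bad <- sum(is.na(classified$behavior))
    rlang::abort(paste0(n_bad, " entr", if (n_bad == 1) "y" else "ies",
                        " could not be classified (outside the rule table)"))
  }
  classified$duration <- classified$end_min - classified$start_min
  classified$covered <- if (coverage_includes_excluded) {
    rep(TRUE, nrow(classified))
  } else {
    classified$behavior != "excluded"
  }
  classified |>
    dplyr::group_by(.data$child_id, .data$date) |>
    dplyr::summarise(
      pa_min = sum(.data$duration[.data$behavior %in% "PA"]),
      sb_min = sum(.data$duration[.data$behavior %in% "SB"]),
      sleep_min = sum(.data$duration[.data$behavior %in% "sleep"]),
      excluded_min = sum(.data$duration[.data$behavior %in% "excluded"]),
      coverage_hours = sum(.data$duration[.data$covered]) / 60,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      weekday = weekdays(.data$date),
      weekend = format(.data$date, "%u") %in% c("6", "7"),
      .after = "date"
    )
}

#' Randomly select reporting days per child under an inclusion criterion
#'
#' A child is eligible when at least `n_days` of their days reach
#' `min_hours` of reported coverage (and, when `require_weekend = TRUE`,
#' at least one qualifying Saturday/Sunday exists). For eligible children
#' with surplus qualifying days, exactly `n_days` days are drawn uniformly
#' without replacement under `seed`; with `require_weekend` one qualifying
#' weekend day is drawn first so the selected subset always contains one.
#'
#' @param totals Daily totals tibble from [daily_totals()].
#' @param min_hours Minimum reported hours for a day to qualify (12-24).
#' @param n_days Number of days to select per child (2-7).
#' @param require_weekend Must the selection contain a weekend day?
#' @param seed Integer seed controlling the random draws.
#' @return Tibble of selected days: `child_id`, `date`, `day_slot`
#'   (1..`n_days`, the draw order), with attributes `n_eligible` and
#'   `n_ineligible`.
#' @export
select_days <- function(totals, min_hours, n_days, require_weekend = FALSE,
                        seed = 1L) {
  stopifnot(min_hours >= 0, min_hours <= 24, n_days >= 1)
  qualifying <- dplyr::filter(totals, .data$coverage_hours >= min_hours)
  picks <- withr::with_seed(seed, {
    qualifying |>
      dplyr::group_by(.data$child_id) |>
      dplyr::group_map(function(df, key) {
        eligible <- nrow(df) >= n_days &&
          (!require_weekend || any(df$weekend))
        if (!eligible) return(NULL)
        idx <- seq_len(nrow(df))
        if (require_weekend) {
          wk <- idx[df$weekend]
          first <- if (length(wk) == 1) wk else sample(wk, 1)
          rest <- setdiff(idx, first)
          extra <- if (n_days > 1) {
            if (length(rest) == 1) rest else sample(rest, n_days - 1)
          } else integer(0)
          chosen <- c(first, extra)
        } else {
          chosen <- if (length(idx) == 1) idx else sample(idx, n_days)
        }
        tibble::tibble(child_id = key$child_id, date = df$date[chosen],
                       day_slot = seq_len(n_days))
      }) |>
      dplyr::bind_rows()
  })
  n_children <- dplyr::n_distinct(totals$child_id)
  if (nrow(picks) == 0) {
    picks <- tibble::tibble(child_id = character(0),
                            date = as.Date(character(0)),
                            day_slot = integer(0))
  }
  attr(picks, "n_eligible") <- dplyr::n_distinct(picks$child_id)
  attr(picks, "n_ineligible") <- n_children - attr(picks, "n_eligible")
  picks
}
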