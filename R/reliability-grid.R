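#' Reliability grid: single-day ICCs and minimum reporting days per
#' inclusion criterion
#'
#' For every combination of outcome, minimum daily reported hours (12-24)
#' and number of reporting days (2-7), the grid: (1) selects, five times
#' under different seeds, a random `n_days`-subset of qualifying days per
#' eligible child ([select_days()]); (2) computes the single-day ICC of
#' the children x selected-days matrix per repetition; (3) averages the
#' ICC over the repetitions (the repetition spread is retained); and (4)
#' converts the averaged single-day ICC into the minimum number of
#' reporting days needed to reach the target reliability via the
#' Spearman-Brown prophecy formula. Eligibility counts per criterion are
#' attached. Minute-scale outcomes are log-transformed (`log(x + 1)`, so
#' zero-PA days are tolerated) before the ICC; ilr coordinates enter as
#' they are.
#'
#' @param daily Daily outcome table: [daily_totals()] output, with ilr
#'   columns if compositional outcomes are requested (see
#'   [add_ilr_coordinates()]).
#' @param outcomes Character vector of outcome columns; defaults to the
#'   six analysis outcomes.
#' @param min_hours,n_days Grid axes.
#' @param reps Random day-subset repetitions per cell.
#' @param seed Master seed; each cell x repetition derives its own stream.
#' @param icc_type Passed to [icc_single_day()].
#' @param target Target reliability for the Spearman-Brown step.
#' @param require_weekend Require a weekend day in every selected subset.
#' @return A tibble of class `reliability_grid`: `outcome`, `min_hours`,
#'   `n_days`, `icc`, `icc_sd_over_reps`, `ci_low`, `ci_high`, `min_days`,
#'   `n_eligible`, `pct_eligible`. Cells with fewer than 2 eligible
#'   children carry `NA` estimates.
#' @export
reliability_grid <- function(daily,
                             outcomes = c("pa_min", "sb_min", "sleep_min",
                                          "ilr_pa", "ilr_sb", "ilr_sleep"),
                             min_hours = 12:24, n_days = 2:7, reps = 5,
                             seed = 1L,
                             icc_type = c("agreement", "consistency"),
                             target = 0.70, require_weekend = FALSE) {
  icc_type <- match.arg(icc_type)
  outcomes <- intersect(outcomes, names(daily))
  n_children <- dplyr::n_distinct(daily$child_id)
  minute_scale <- grepl("_min$", outcomes)
  names(minute_scale) <- outcomes
  cells <- tidyr::expand_grid(min_hours = min_hours, n_days = n_days)
  rows <- purrr::pmap(cells, function(min_hours, n_days) {
    sels <- lapply(seq_len(reps), function(r) {
      select_days(daily, min_hours = min_hours, n_days = n_days,
                  require_weekend = require_weekend,
                  seed = derive_seed(seed, "grid", min_hours, n_days, r))
    })
    n_eligible <- attr(sels[[1]], "n_eligible")
    purrr::map_dfr(outcomes, function(oc) {
      base <- tibble::tibble(
        outcome = oc, min_hours = min_hours, n_days = n_days,
        icc = NA_real_, icc_sd_over_reps = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, min_days = NA_real_,
        n_eligible = n_eligible,
        pct_eligible = 100 * n_eligible / n_children
      )
      if (n_eligible < 2) return(base)
      fits <- lapply(sels, function(sel) {
        m <- outcome_matrix(daily, sel, oc, log_minutes = minute_scale[[oc]])
        icc_single_day(m, type = icc_type)
      })
      iccs <- vapply(fits, function(f) f$icc, 1)
      base$icc <- mean(iccs)
      base$icc_sd_over_reps <- if (reps > 1) sd(iccs) else 0
      base$ci_low <- mean(vapply(fits, function(f) f$ci_low, 1))
      base$ci_high <- mean(vapply(fits, function(f) f$ci_high, 1))
      base$min_days <- if (base$icc > 0) {
        spearman_brown_days(base$icc, target)
      } else NA_real_
      base
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reliability_grid", class(out))
  attr(out, "icc_type") <- icc_type
  attr(out, "target") <- target
  attr(out, "reps") <- reps
  out
}

# children x day-slot matrix of an outcome for the selected days
outcome_matrix <- function(daily, sel, outcome, log_minutes = FALSE) {
  joined <- dplyr::inner_join(sel, daily, by = c("child_id", "date"))
  wide <- tidyr::pivot_wider(
    joined[, c("child_id", "day_slot", outcome)],
    names_from = "day_slot", values_from = dplyr::all_of(outcome)
  )
  m <- as.matrix(wide[, -1])
  if (log_minutes) m <- log(m + 1)
  m
}

#' @export
print.reliability_grid <- function(x, ...) {
  cat(sprintf(
    "Reliability grid (%s ICC, target %.2f): %d cells over hours %d-%d, days %d-%d\n",
    attr(x, "icc_type"), attr(x, "target"),
    nrow(x), min(x$min_hours), max(x$min_hours), min(x$n_days), max(x$n_days)
  ))
  NextMethod()
}

#' Weekday-versus-weekend difference in a daily outcome
#'
#' Fits a linear mixed model of the (optionally log-transformed) daily
#' outcome on a weekend indicator, adjusted for the child's sex and age in
#' months at the first diary day, with a random intercept per child, and
#' reports the weekend coefficient with its Satterthwaite-df p-value.
#' Children enter when they have at least `min_days` days of at least
#' `min_hours` reported coverage including one weekend day. If the mixed
#' model is singular the function falls back to a paired within-child
#' contrast (mean weekend minus mean weekday, one-sample t-test), flagged
#' in the result.
#'
#' @param daily Daily outcome table (with ilr columns when needed).
#' @param outcome Outcome column name.
#' @param profiles Child profiles (`sex`, `birth_date`).
#' @param min_hours Coverage criterion defining a valid day.
#' @param min_days Minimum valid days per child.
#' @param log_minutes Log-transform (`log(x + 1)`) the outcome; default
#'   `TRUE` for minute-scale outcomes.
#' @return Object of class `weekend_fit`: list with `estimate`, `se`,
#'   `df`, `p_value`, `method` (`"lmm"` or `"paired"`), `n_children`,
#'   `outcome`, and the fitted model. Has a [tidy()] method.
#' @export
weekend_effect_model <- function(daily, outcome, profiles, min_hours = 12,
                                 min_days = 2,
                                 log_minutes = grepl("_min$", outcome)) {
  valid <- dplyr::filter(daily, .data$coverage_hours >= min_hours)
  keep <- valid |>
    dplyr::group_by(.data$child_id) |>
    dplyr::filter(dplyr::n() >= min_days, any(.data$weekend)) |>
    dplyr::ungroup()
  if (nrow(keep) == 0 || !any(keep$weekend) || all(keep$weekend)) {
    rlang::abort("no children meet the weekend-model inclusion criterion")
  }
  first_day <- keep |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(first_date = min(.data$date), .groups = "drop")
  dat <- keep |>
    dplyr::left_join(first_day, by = "child_id") |>
    dplyr::left_join(profiles[, c("child_id", "sex", "birth_date")],
                     by = "child_id") |>
    dplyr::mutate(
      age_months = as.numeric(.data$first_date - .data$birth_date) / 30.44,
      y = if (log_minutes) log(.data[[outcome]] + 1) else .data[[outcome]]
    )
  fit <- suppressMessages(lmerTest::lmer(
    y ~ weekend + sex + age_months + (1 | child_id), data = dat
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (!singular) {
    co <- stats::coef(summary(fit))["weekendTRUE", ]
    res <- list(estimate = unname(co["Estimate"]),
                se = unname(co["Std. Error"]), df = unname(co["df"]),
                p_value = unname(co["Pr(>|t|)"]), method = "lmm",
                n_children = dplyr::n_distinct(dat$child_id),
                outcome = outcome, model = fit)
  } else {
    paired <- dat |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(
        d = mean(.data$y[.data$weekend]) - mean(.data$y[!.data$weekend]),
        .groups = "drop"
      ) |>
      dplyr::filter(is.finite(.data$d))
    tt <- stats::t.test(paired$d)
    res <- list(estimate = unname(tt$estimate), se = unname(tt$stderr),
                df = unname(tt$parameter), p_value = tt$p.value,
                method = "paired", n_children = nrow(paired),
                outcome = outcome, model = fit)
  }
  structure(res, class = "weekend_fit")
}

#' @export
print.weekend_fit <- function(x, ...) {
  cat(sprintf(
    "Weekend effect on %s (%s): %.3f (SE %.3f), p = %.4g, %d children\n",
    x$outcome, x$method, x$estimate, x$se, x$p_value, x$n_children
  ))
  invisible(x)
}

#' @method tidy weekend_fit
#' @export
tidy.weekend_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, term = "weekend", estimate = x$estimate,
    std.error = x$se, df = x$df, p.value = x$p_value, method = x$method,
    n_children = x$n_children
  )
}
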