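#' Enumerate the activity-category hypothesis ledger
#'
#' Builds the 55 sub-hypotheses comparing accelerometer-derived
#' acceleration across the eleven analyzed activity groupings (seven
#' predominantly-sedentary, three predominantly-active, and sleep):
#' \itemize{
#'   \item 1-21: similarity (no significant difference) within each pair
#'     of the seven sedentary groupings (7 choose 2);
#'   \item 22-24: similarity within each pair of the three active
#'     groupings (3 choose 2);
#'   \item 25-34: sleep lower than each of the ten waking groupings;
#'   \item 35-55: each active grouping higher than each sedentary grouping
#'     (3 x 7).
#' }
#' The main hypothesis -- acceleration lowest during sleep, then sedentary
#' behavior, highest during physical activity -- is available as
#' [main_hypothesis()] at the behavior level.
#'
#' @return A tibble: `id` (1-55), `kind` (`"similarity"`/`"difference"`),
#'   `left`, `right`, `expected` (`"left=right"` or `"left<right"`).
#' @examples
#' nrow(enumerate_hypotheses())  # 55
#' @export
enumerate_hypotheses <- function() {
  sb_pairs <- utils::combn(sb_activity_groups, 2)
  pa_pairs <- utils::combn(pa_activity_groups, 2)
  waking <- c(sb_activity_groups, pa_activity_groups)
  sim <- tibble::tibble(
    kind = "similarity",
    left = c(sb_pairs[1, ], pa_pairs[1, ]),
    right = c(sb_pairs[2, ], pa_pairs[2, ]),
    expected = "left=right"
  )
  sleep_diff <- tibble::tibble(
    kind = "difference", left = "sleeping", right = waking,
    expected = "left<right"
  )
  pa_sb <- tidyr::expand_grid(right = pa_activity_groups,
                              left = sb_activity_groups)
  pa_sb <- tibble::tibble(kind = "difference", left = pa_sb$left,
                          right = pa_sb$right, expected = "left<right")
  out <- dplyr::bind_rows(sim, sleep_diff, pa_sb)
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

#' @rdname enumerate_hypotheses
#' @return `main_hypothesis()`: the three behavior-level orderings
#'   (sleep < SB, sleep < PA, SB < PA) in the same layout.
#' @export
main_hypothesis <- function() {
  tibble::tibble(
    id = c("main-1", "main-2", "main-3"),
    kind = "difference",
    left = c("sleep", "sleep", "SB"),
    right = c("SB", "PA", "PA"),
    expected = "left<right"
  )
}

#' Fit the acceleration mixed model for one metric and placement
#'
#' Models the log-transformed per-entry median acceleration
#' (`log(median + eps)`; sleep entries can have a zero median) with a
#' fixed effect for the grouping (24-h movement behavior or activity
#' grouping), adjustment for the child's sex and age in months, and nested
#' random intercepts for child and day-within-child. Singular nested fits
#' drop the day-within-child term and are flagged.
#'
#' @param entry_acc Entry-acceleration tibble from [summarize_entries()].
#' @param profiles Child profiles (`sex`, `birth_date`).
#' @param metric `"enmo"` or `"mad"`.
#' @param placement `"hip"` or `"wrist"`.
#' @param grouping `"behavior"` (3 levels) or `"category"` (the 11
#'   activity groupings).
#' @param eps Offset inside the log, in g.
#' @return Object of class `acc_model`: list with the `lmerTest` fit
#'   (`model`), `metric`, `placement`, `grouping`, `groups` present,
#'   `dropped_day_term`, and `data`.
#' @export
fit_category_model <- function(entry_acc, profiles,
                               metric = c("enmo", "mad"),
                               placement = c("hip", "wrist"),
                               grouping = c("behavior", "category"),
                               eps = 0.001) {
  metric <- match.arg(metric)
  placement <- match.arg(placement)
  grouping <- match.arg(grouping)
  dat <- dplyr::filter(entry_acc, .data$placement == .env$placement,
                       !.data$excluded)
  dat$group_var <- if (grouping == "behavior") dat$behavior else dat$group
  dat <- dplyr::filter(dat, !is.na(.data$group_var))
  counts <- dat |>
    dplyr::group_by(.data$group_var) |>
    dplyr::summarise(n_children = dplyr::n_distinct(.data$child_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_children >= 2)
  dat <- dplyr::filter(dat, .data$group_var %in% counts$group_var)
  if (nrow(counts) < 2) {
    rlang::abort("need at least 2 groups with at least 2 children each")
  }
  first_day <- dat |>
    dplyr::group_by(.data$child_id) |>
    dplyr::summarise(first_date = min(.data$date), .groups = "drop")
  dat <- dat |>
    dplyr::left_join(first_day, by = "child_id") |>
    dplyr::left_join(profiles[, c("child_id", "sex", "birth_date")],
                     by = "child_id") |>
    dplyr::mutate(
      age_months = as.numeric(.data$first_date - .data$birth_date) / 30.44,
      y = log(.data[[paste0("median_", metric)]] + eps),
      group_var = factor(.data$group_var),
      day_id = paste(.data$child_id, .data$date)
    )
  form <- y ~ group_var + sex + age_months + (1 | child_id) + (1 | day_id)
  fit <- suppressMessages(lmerTest::lmer(form, data = dat))
  dropped <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    fit2 <- suppressMessages(lmerTest::lmer(
      y ~ group_var + sex + age_months + (1 | child_id), data = dat
    ))
    if (!lme4::isSingular(fit2, tol = 1e-4)) {
      fit <- fit2
      dropped <- TRUE
    }
  }
  structure(
    list(model = fit, metric = metric, placement = placement,
         grouping = grouping, groups = levels(dat$group_var),
         dropped_day_term = dropped, eps = eps, data = dat),
    class = "acc_model"
  )
}

#' @export
print.acc_model <- function(x, ...) {
  cat(sprintf(
    "Acceleration mixed model: log(%s + %g), %s placement, %d %s groups%s\n",
    x$metric, x$eps, x$placement, length(x$groups), x$grouping,
    if (x$dropped_day_term) " (day-within-child term dropped)" else ""
  ))
  invisible(x)
}

#' @method tidy acc_model
#' @export
tidy.acc_model <- function(x, ...) {
  co <- stats::coef(summary(x$model))
  tibble::tibble(
    metric = x$metric, placement = x$placement,
    term = rownames(co), estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"], df = co[, "df"],
    statistic = co[, "t value"], p.value = co[, "Pr(>|t|)"]
  )
}

#' @method glance acc_model
#' @export
glance.acc_model <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, placement = x$placement, grouping = x$grouping,
    n_obs = nrow(x$data), n_children = dplyr::n_distinct(x$data$child_id),
    r2_marginal = r2_marginal(x$model),
    dropped_day_term = x$dropped_day_term
  )
}

#' Pairwise group contrasts with Satterthwaite degrees of freedom
#'
#' Evaluates each hypothesis's left-minus-right contrast of adjusted group
#' means from a fitted [fit_category_model()] via estimated marginal
#' means, using Satterthwaite-approximated degrees of freedom and
#' two-tailed p-values at alpha = 0.05. A similarity hypothesis is
#' supported when p >= alpha; a difference hypothesis when p < alpha and
#' the estimate's sign matches the expected direction. No multiplicity
#' correction is applied across hypotheses.
#'
#' @param model An `acc_model`.
#' @param specs Hypothesis tibble ([enumerate_hypotheses()] or
#'   [main_hypothesis()]); defaults to the enumeration matching the
#'   model's grouping.
#' @param alpha Two-tailed significance level.
#' @return Tibble: the spec columns plus `metric`, `placement`,
#'   `estimate` (left minus right, log scale), `p_value`, `supported`,
#'   `available`.
#' @export
pairwise_contrasts <- function(model, specs = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "acc_model"))
  if (is.null(specs)) {
    specs <- if (model$grouping == "behavior") main_hypothesis()
             else enumerate_hypotheses()
  }
  emm <- emmeans::emmeans(model$model, "group_var",
                          lmer.df = "satterthwaite",
                          lmerTest.limit = 1e6)
  emm_sum <- summary(emm)
  lev <- as.character(emm_sum$group_var)
  pairs_sum <- summary(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"),
                       infer = c(FALSE, TRUE))
  key <- function(a, b) paste(a, "-", b)
  pair_key <- as.character(pairs_sum$contrast)
  # emmeans labels contrasts "(A) - (B)" when levels contain spaces
  pair_key <- gsub("[()]", "", pair_key)
  out <- specs
  out$metric <- model$metric
  out$placement <- model$placement
  est <- p <- rep(NA_real_, nrow(specs))
  avail <- specs$left %in% lev & specs$right %in% lev
  for (i in seq_len(nrow(specs))) {
    if (!avail[i]) next
    j <- match(key(specs$left[i], specs$right[i]), pair_key)
    if (!is.na(j)) {
      est[i] <- pairs_sum$estimate[j]
      p[i] <- pairs_sum$p.value[j]
    } else {
      j <- match(key(specs$right[i], specs$left[i]), pair_key)
      est[i] <- -pairs_sum$estimate[j]
      p[i] <- pairs_sum$p.value[j]
    }
  }
  out$estimate <- est
  out$p_value <- p
  out$available <- avail
  out$supported <- dplyr::case_when(
    !avail ~ NA,
    specs$expected == "left=right" ~ p >= alpha,
    TRUE ~ p < alpha & est < 0
  )
  out
}

#' Consistency ledger over the four metric-by-placement combinations
#'
#' Combines per-combination hypothesis results into the +/-/plus-minus
#' verdict scheme: `+` when all four combinations (ENMO/MAD at hip/wrist)
#' support the hypothesis, `-` when none does, and `±` otherwise, with
#' the supporting combinations listed. Unavailable combinations (a group
#' absent from a fit) count as not supporting and are reported.
#'
#' @param results Row-bound [pairwise_contrasts()] output covering the
#'   four combinations.
#' @return Tibble of class `hypothesis_ledger`: `id`, `kind`, `left`,
#'   `right`, `expected`, `n_supporting`, `n_available`, `verdict`,
#'   `supporting_combos`.
#' @export
consistency_ledger <- function(results) {
  out <- results |>
    dplyr::mutate(combo = paste(.data$placement, toupper(.data$metric))) |>
    dplyr::group_by(.data$id, .data$kind, .data$left, .data$right,
                    .data$expected) |>
    dplyr::summarise(
      n_supporting = sum(.data$supported, na.rm = TRUE),
      n_available = sum(.data$available),
      verdict = dplyr::case_when(
        sum(.data$supported, na.rm = TRUE) == dplyr::n() ~ "+",
        sum(.data$supported, na.rm = TRUE) == 0 ~ "-",
        TRUE ~ "±"
      ),
      supporting_combos = paste(
        sort(.data$combo[!is.na(.data$supported) & .data$supported]),
        collapse = ", "
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$id)
  class(out) <- c("hypothesis_ledger", class(out))
  out
}

#' Marginal R-squared of the fixed effects of a mixed model
#'
#' Variance explained by the fixed effects relative to the total (fixed +
#' random-intercept + residual) variance, the usual marginal R-squared for
#' linear mixed models.
#'
#' @param model A fitted `lmerMod` / `lmerModLmerTest`.
#' @return A single number in `[0, 1]`.
#' @export
r2_marginal <- function(model) {
  fe <- lme4::fixef(model)
  X <- lme4::getME(model, "X")
  var_f <- var(as.vector(X %*% fe))
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(v) v[1, 1], 1))
  var_e <- attr(vc, "sc")^2
  var_f / (var_f + var_r + var_e)
}

#' Cohen band for an explained-variance value
#'
#' Classifies a marginal R-squared into the conventional bands: very weak
#' `[0, 0.02)`, weak `[0.02, 0.13)`, moderate `[0.13, 0.26]`, substantial
#' `(0.26, 1]`.
#'
#' @param r2 Numeric vector in `[0, 1]`.
#' @return Character vector of band labels.
#' @examples
#' classify_r2(c(0.14, 0.28, 0))
#' @export
classify_r2 <- function(r2) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) {
    rlang::abort("R-squared must lie in [0, 1]")
  }
  dplyr::case_when(
    r2 > 0.26 ~ "substantial",
    r2 >= 0.13 ~ "moderate",
    r2 >= 0.02 ~ "weak",
    TRUE ~ "very weak"
  )
}

#' Test the main sleep < SB < PA ordering on entry accelerations
#'
#' Fits the behavior-level acceleration model for each metric x placement
#' combination and checks the three pairwise orderings (sleep < SB,
#' sleep < PA, SB < PA) with Satterthwaite p-values.
#'
#' @param entry_acc Entry accelerations ([summarize_entries()]).
#' @param profiles Child profiles.
#' @param alpha Two-tailed significance level.
#' @return Tibble: `metric`, `placement`, `ordered` (fitted means ordered
#'   sleep < SB < PA), `all_significant`, `confirmed`, `r2_marginal`.
#' @export
test_main_hypothesis <- function(entry_acc, profiles, alpha = 0.05) {
  combos <- tidyr::expand_grid(metric = c("enmo", "mad"),
                               placement = c("hip", "wrist"))
  purrr::pmap_dfr(combos, function(metric, placement) {
    fit <- fit_category_model(entry_acc, profiles, metric, placement,
                              grouping = "behavior")
    res <- pairwise_contrasts(fit, main_hypothesis(), alpha = alpha)
    tibble::tibble(
      metric = metric, placement = placement,
      ordered = all(res$estimate < 0, na.rm = TRUE) && all(res$available),
      all_significant = all(res$supported),
      confirmed = all(res$supported),
      r2_marginal = r2_marginal(fit$model)
    )
  })
}

#' Run the full 55-hypothesis ledger on entry accelerations
#'
#' Fits the category-level acceleration model for each metric x placement
#' combination, evaluates all 55 enumerated sub-hypotheses, and collapses
#' them into the consistency ledger.
#'
#' @inheritParams test_main_hypothesis
#' @return A list with `results` (per-combination contrasts) and `ledger`
#'   (the [consistency_ledger()]).
#' @export
test_hypotheses <- function(entry_acc, profiles, alpha = 0.05) {
  combos <- tidyr::expand_grid(metric = c("enmo", "mad"),
                               placement = c("hip", "wrist"))
  results <- purrr::pmap_dfr(combos, function(metric, placement) {
    fit <- fit_category_model(entry_acc, profiles, metric, placement,
                              grouping = "category")
    pairwise_contrasts(fit, enumerate_hypotheses(), alpha = alpha)
  })
  list(results = results, ledger = consistency_ledger(results))
}
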