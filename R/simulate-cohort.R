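#' Simulate a cohort with known ground truth
#'
#' Draws child profiles, daily behavior minutes and a full day schedule
#' (a sequence of labeled activity intervals tiling 00:00-24:00 on the
#' 5-min grid) for every child-day. The returned truth object is the input
#' to [simulate_diary()], [simulate_raw_acceleration()] and
#' [simulate_epoch_series()]; because the relabeling and coverage
#' truncation happen downstream, the truth keeps every interval's real
#' label for oracle checks.
#'
#' @param config A [simulation_config()].
#' @param schedule Build the interval schedules (default `TRUE`). Studies
#'   that only need daily minutes (e.g. reliability simulations) can skip
#'   them.
#' @return An object of class `cohort_truth`: list with
#'   \describe{
#'     \item{profiles}{tibble: `child_id`, `sex`, `birth_date`,
#'       `age_months`, `age_group`, milestone flags.}
#'     \item{daily}{tibble of true daily minutes: `child_id`, `date`,
#'       `weekend`, `pa_min`, `sb_min`, `sleep_min` (grid-rounded, summing
#'       to 1440).}
#'     \item{schedule}{tibble of true intervals: `child_id`, `date`,
#'       `start_min`, `end_min`, `group`, `category`, `intensity`,
#'       `posture`, `behavior`.}
#'     \item{true_icc}{the configured between-child variance share per
#'       behavior.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' truth <- simulate_cohort(simulation_config(n_children = 3, n_days = 2))
#' head(truth$schedule)
#' @export
simulate_cohort <- function(config, schedule = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  profiles <- withr::with_seed(
    derive_seed(config$seed, "profiles"),
    simulate_profiles(config)
  )
  daily <- withr::with_seed(
    derive_seed(config$seed, "daily"),
    simulate_daily_minutes(config)
  )
  schedule <- if (schedule) {
    withr::with_seed(
      derive_seed(config$seed, "schedule"),
      simulate_schedules(daily, profiles, config)
    )
  } else {
    tibble::tibble(child_id = character(0), date = as.Date(character(0)),
                   start_min = numeric(0), end_min = numeric(0),
                   group = character(0), category = character(0),
                   intensity = character(0), posture = character(0),
                   behavior = character(0))
  }
  structure(
    list(profiles = profiles, daily = daily, schedule = schedule,
         true_icc = config$icc_target, config = config),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d children x %d days (%d scheduled intervals), seed %d\n",
    x$config$n_children, x$config$n_days, nrow(x$schedule), x$config$seed
  ))
  invisible(x)
}

simulate_profiles <- function(config) {
  n <- config$n_children
  age_months <- round(runif(n, 1, 47), 1)
  # Milestones switch on at typical attainment ages (months).
  thresholds <- c(
    roll_back_to_belly = 4, roll_belly_to_back = 5, sit_without_support = 7,
    crawl = 9, stand_without_support = 11, walk_without_support = 13
  )
  prof <- tibble::tibble(
    child_id = sprintf("c%04d", seq_len(n)),
    sex = sample(c("female", "male"), n, replace = TRUE),
    birth_date = config$start_date - round(age_months * 30.44),
    age_months = age_months,
    age_group = dplyr::case_when(
      age_months < 6 ~ "0-6m",
      age_months < 12 ~ "6-12m",
      age_months < 24 ~ "1-2y",
      age_months < 36 ~ "2-3y",
      TRUE ~ "3-4y"
    )
  )
  for (m in names(thresholds)) {
    prof[[m]] <- age_months >= thresholds[[m]]
  }
  prof
}

simulate_daily_minutes <- function(config) {
  n <- config$n_children
  d <- config$n_days
  dates <- config$start_date + 0:(d - 1)
  weekend <- format(dates, "%u") %in% c("6", "7")
  mins <- matrix(0, n * d, 3, dimnames = list(NULL, c("pa", "sb", "sleep")))
  for (b in c("pa", "sb", "sleep")) {
    theta <- config$icc_target[[b]]
    u <- rnorm(n, 0, sqrt(theta) * config$sd_log)
    e <- rnorm(n * d, 0, sqrt(1 - theta) * config$sd_log)
    x <- config$mean_minutes[[b]] * exp(rep(u, each = d) + e)
    x <- x + config$weekend_shift[[b]] * rep(weekend, n)
    mins[, b] <- pmax(x, 5)
  }
  mins <- mins * 1440 / rowSums(mins)
  mins <- t(apply(mins, 1, round_to_grid_sum, total = 1440, grid = 5))
  tibble::tibble(
    child_id = rep(sprintf("c%04d", seq_len(n)), each = d),
    date = rep(dates, n),
    weekend = rep(weekend, n),
    pa_min = unname(mins[, 1]), sb_min = unname(mins[, 2]),
    sleep_min = unname(mins[, 3])
  )
}

# Largest-remainder rounding of a composition to `grid`-minute multiples
# preserving `total`.
round_to_grid_sum <- function(x, total, grid = 5) {
  units <- x / grid
  base <- floor(units)
  short <- total / grid - sum(base)
  frac <- units - base
  if (short > 0) {
    add <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  } else if (short < 0) {
    # guard: can only occur through upstream numeric noise
    drop <- order(frac)[seq_len(-short)]
    base[drop] <- base[drop] - 1
  }
  base * grid
}

simulate_schedules <- function(daily, profiles, config) {
  prof_list <- split(profiles, profiles$child_id)
  rows <- vector("list", nrow(daily))
  for (i in seq_len(nrow(daily))) {
    day <- daily[i, ]
    rows[[i]] <- schedule_one_day(
      day$pa_min, day$sb_min, day$sleep_min,
      prof_list[[day$child_id]], config
    )
    rows[[i]]$child_id <- day$child_id
    rows[[i]]$date <- day$date
  }
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "child_id", "date")
}

# Tile one day: sleep as a morning block, optional early-afternoon nap and
# an evening block; awake gaps filled with bouts drawn from the bout model,
# with behavior chosen in proportion to the remaining PA/SB budgets.
schedule_one_day <- function(pa, sb, sleep, profile, config) {
  s_m <- min(5 * round(0.45 * sleep / 5), 720)
  s_e <- min(5 * round(0.35 * sleep / 5), 1440 - 785)
  nap <- sleep - s_m - s_e
  if (nap < 0) { s_e <- s_e + nap; nap <- 0 }
  if (s_e < 0) { s_m <- s_m + s_e; s_e <- 0 }
  # nap must fit between 13:00 and evening sleep onset
  overflow <- (780 + nap) - (1440 - s_e)
  if (nap > 0 && overflow > 0) {
    nap <- nap - overflow
    s_m <- s_m + overflow
  }
  # plain-vector accumulation: this runs once per child-day
  v_start <- v_end <- numeric(0)
  v_group <- v_cat <- v_int <- v_post <- v_beh <- character(0)
  add <- function(start, end, group, category, intensity, posture) {
    v_start[length(v_start) + 1] <<- start
    v_end[length(v_end) + 1] <<- end
    v_group[length(v_group) + 1] <<- group
    v_cat[length(v_cat) + 1] <<- category
    v_int[length(v_int) + 1] <<- intensity
    v_post[length(v_post) + 1] <<- posture
    v_beh[length(v_beh) + 1] <<- if (group == "sleeping") "sleep"
      else if (group %in% pa_activity_groups) "PA" else "SB"
  }
  if (s_m > 0) add(0, s_m, "sleeping", "sleeping", "n/a", "n/a")
  if (nap > 0) add(780, 780 + nap, "sleeping", "sleeping", "n/a", "n/a")
  if (s_e > 0) add(1440 - s_e, 1440, "sleeping", "sleeping", "n/a", "n/a")

  segments <- if (nap > 0) {
    list(c(s_m, 780), c(780 + nap, 1440 - s_e))
  } else {
    list(c(s_m, 1440 - s_e))
  }
  budget <- c(pa = pa, sb = sb)
  w <- child_category_weights(profile, config)
  for (seg in segments) {
    t <- seg[1]
    while (t < seg[2]) {
      remaining <- seg[2] - t
      draw <- config$bout_length_model(1)
      behavior <- if (budget[["pa"]] <= 0) "sb"
        else if (budget[["sb"]] <= 0) "pa"
        else sample(c("pa", "sb"), 1, prob = budget)
      len <- min(draw, remaining, budget[[behavior]])
      grp <- sample(names(w[[behavior]]), 1, prob = w[[behavior]])
      lab <- group_labels(grp, profile)
      add(t, t + len, grp, lab$category, lab$intensity, lab$posture)
      budget[[behavior]] <- budget[[behavior]] - len
      t <- t + len
    }
  }
  ord <- order(v_start)
  tibble::tibble(
    start_min = v_start[ord], end_min = v_end[ord], group = v_group[ord],
    category = v_cat[ord], intensity = v_int[ord], posture = v_post[ord],
    behavior = v_beh[ord]
  )
}

# Per-child category weights: zero out activity groupings the app would not
# offer at the child's developmental stage.
child_category_weights <- function(profile, config) {
  w <- config$category_weights
  pa <- w$pa
  if (!(profile$age_group %in% c("2-3y", "3-4y") ||
        profile$walk_without_support)) {
    pa[["active transport"]] <- 0
  }
  if (profile$age_group == "0-6m") pa[["active screen use"]] <- 0
  if (sum(pa) == 0) pa[["active play"]] <- 1
  list(pa = pa / sum(pa), sb = w$sb / sum(w$sb))
}

# Category / intensity / posture realizing a given activity grouping, with
# postures drawn from the rule rows consistent with the intended behavior.
group_labels <- function(group, profile) {
  under1 <- profile$age_group %in% c("0-6m", "6-12m")
  calm_postures <- if (under1) {
    c("changing posture", "being carried", "lying on back",
      "sitting with support")
  } else {
    c("changing posture", "sitting", "lying")
  }
  switch(
    group,
    "sitting/lying" = list(category = "sitting/lying calmly",
                           intensity = "n/a",
                           posture = sample(calm_postures, 1,
                                            prob = c(0.3, rep(0.7 / (length(calm_postures) - 1),
                                                              length(calm_postures) - 1)))),
    "calm play" = list(category = "playing", intensity = "calm",
                       posture = sample(calm_postures, 1,
                                        prob = c(0.56, rep(0.44 / (length(calm_postures) - 1),
                                                           length(calm_postures) - 1)))),
    "play unknown intensity" = list(category = "playing",
                                    intensity = "unknown",
                                    posture = "I don't know"),
    "active play" = list(category = "playing", intensity = "active",
                         posture = "changing posture"),
    "active screen use" = list(category = "screen use", intensity = "active",
                               posture = "n/a"),
    "passive screen use" = list(category = "screen use",
                                intensity = "watching", posture = "n/a"),
    "active transport" = list(category = "active transport",
                              intensity = "n/a", posture = "n/a"),
    list(category = group, intensity = "n/a", posture = "n/a")
  )
}
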