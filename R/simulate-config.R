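#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data generator: cohort size, the
#' behavior-minute model (means, day-to-day spread and its between-child
#' share), reporting coverage and bout-length models, relabeling rates for
#' the descriptive categories, and the acceleration signal model (per-group
#' signal levels, sensor noise, non-wear, the passive-transport vibration
#' confound, sampling rate).
#'
#' Daily behavior minutes follow a lognormal child intercept plus normal
#' day deviation on the log scale: for behavior \eqn{b},
#' \eqn{\log x_{bij} = \log \mu_b + u_{bi} + e_{bij}} with
#' \eqn{u_{bi} \sim N(0, \theta_b s^2)} and
#' \eqn{e_{bij} \sim N(0, (1-\theta_b) s^2)}, after which the three
#' behaviors are closed to the 1440-min day. `icc_target` is
#' \eqn{\theta_b}, the between-child share of log-scale variance, which the
#' closure approximately preserves on the minute scale.
#'
#' @param n_children Number of children in the cohort.
#' @param n_days Diary days per child (consecutive, starting `start_date`).
#' @param seed Integer master seed; every stage derives its own stream.
#' @param start_date First diary day (default a Monday so a 7-day week
#'   contains one weekend).
#' @param icc_target Named (`pa`, `sb`, `sleep`) or scalar target
#'   between-child variance share in (0, 1).
#' @param mean_minutes Named mean minutes/day per behavior; must sum to at
#'   most 1440.
#' @param sd_log Total log-scale standard deviation of daily minutes.
#' @param weekend_shift Named additive minute shift applied to Saturdays
#'   and Sundays before closure (default all 0).
#' @param coverage_model Function `n -> hours` drawing reported hours/day
#'   (12-24); see [coverage_constant()].
#' @param bout_length_model Function `n -> minutes` drawing awake bout
#'   lengths as 5-min multiples; see [bout_constant()].
#' @param category_weights List with elements `sb` and `pa`: named sampling
#'   weights over the sedentary and active activity groupings.
#' @param relabel_someone_else,relabel_dont_know Probability that a
#'   reported entry is relabeled "my child was with someone else" / "I
#'   don't know" after scheduling (truth labels remain in the cohort).
#' @param accel_level Named acceleration level (g) per activity grouping
#'   plus `sleeping`: the standard deviation of the dynamic (gravity-free)
#'   signal component while that activity is underway.
#' @param noise_sd Sensor noise floor (g), added in quadrature.
#' @param nonwear_rate Fraction of each day spent with the device off-body
#'   (simulated as constant-signal blocks of at least 30 min).
#' @param passive_transport_vibration External-motion vibration level (g)
#'   added in quadrature during passive transport at the hip (stroller /
#'   car vibration reaching the trunk); 0 disables the confound.
#' @param wrist_vibration_frac Fraction of the vibration level reaching
#'   the wrist.
#' @param sample_rate Accelerometer sampling rate in Hz.
#' @param epoch_s Epoch length in seconds for derived metrics.
#' @return A `simulation_config` list (validated).
#' @examples
#' cfg <- simulation_config(n_children = 5, n_days = 7, seed = 42)
#' @export
simulation_config <- function(
    n_children = 50,
    n_days = 7,
    seed = 1L,
    start_date = as.Date("2023-03-06"),
    icc_target = 0.5,
    mean_minutes = c(pa = 240, sb = 420, sleep = 780),
    sd_log = 0.35,
    weekend_shift = c(pa = 0, sb = 0, sleep = 0),
    coverage_model = coverage_beta(),
    bout_length_model = bout_constant(30),
    category_weights = default_category_weights(),
    relabel_someone_else = 0.02,
    relabel_dont_know = 0.01,
    accel_level = default_accel_levels(),
    noise_sd = 0.003,
    nonwear_rate = 0.05,
    passive_transport_vibration = 0,
    wrist_vibration_frac = 0.3,
    sample_rate = 50,
    epoch_s = 5) {
  if (length(icc_target) == 1 && is.null(names(icc_target))) {
    icc_target <- c(pa = icc_target, sb = icc_target, sleep = icc_target)
  }
  stopifnot(
    n_children >= 1, n_days >= 1,
    all(icc_target > 0), all(icc_target < 1),
    all(mean_minutes > 0), sum(mean_minutes) <= 1440,
    sd_log >= 0, is.function(coverage_model), is.function(bout_length_model),
    relabel_someone_else >= 0, relabel_dont_know >= 0,
    relabel_someone_else + relabel_dont_know < 1,
    all(accel_level >= 0), noise_sd >= 0,
    nonwear_rate >= 0, nonwear_rate < 1,
    passive_transport_vibration >= 0,
    wrist_vibration_frac >= 0, wrist_vibration_frac <= 1,
    sample_rate > 0, epoch_s > 0
  )
  lv <- accel_level
  if (!(lv[["sleeping"]] < min(lv[sb_activity_groups]) &&
        max(lv[sb_activity_groups]) < min(lv[pa_activity_groups]))) {
    rlang::warn("acceleration levels are not ordered sleep < sedentary < active")
  }
  structure(
    list(
      n_children = as.integer(n_children), n_days = as.integer(n_days),
      seed = as.integer(seed), start_date = as.Date(start_date),
      icc_target = icc_target[c("pa", "sb", "sleep")],
      mean_minutes = mean_minutes[c("pa", "sb", "sleep")],
      sd_log = sd_log,
      weekend_shift = weekend_shift[c("pa", "sb", "sleep")],
      coverage_model = coverage_model,
      bout_length_model = bout_length_model,
      category_weights = category_weights,
      relabel_someone_else = relabel_someone_else,
      relabel_dont_know = relabel_dont_know,
      accel_level = accel_level, noise_sd = noise_sd,
      nonwear_rate = nonwear_rate,
      passive_transport_vibration = passive_transport_vibration,
      wrist_vibration_frac = wrist_vibration_frac,
      sample_rate = sample_rate, epoch_s = epoch_s
    ),
    class = "simulation_config"
  )
}

#' Coverage and bout-length model constructors
#'
#' Coverage models draw the hours of the day a parent actually reports
#' (12-24 h); bout models draw awake activity bout lengths as 5-min
#' multiples. Each constructor returns a function of `n`.
#'
#' `coverage_beta()` (the default) skews toward full days
#' (`min + (max - min) * Beta(shape1, shape2)` rounded to 5-min
#' resolution), reflecting that most parents report most of the day.
#'
#' @param hours,minutes Constant value for the degenerate models.
#' @param min,max,shape1,shape2 Beta-rescaling parameters.
#' @param mean Mean bout length for the geometric model.
#' @name generator_models
#' @export
coverage_constant <- function(hours) {
  force(hours)
  function(n) rep(hours, n)
}

#' @rdname generator_models
#' @export
coverage_uniform <- function(min = 12, max = 24) {
  function(n) round(runif(n, min, max) * 12) / 12
}

#' @rdname generator_models
#' @export
coverage_beta <- function(shape1 = 3, shape2 = 1, min = 12, max = 24) {
  function(n) round((min + (max - min) * rbeta(n, shape1, shape2)) * 12) / 12
}

#' @rdname generator_models
#' @export
bout_constant <- function(minutes = 30) {
  stopifnot(minutes %% 5 == 0, minutes >= 5)
  function(n) rep(minutes, n)
}

#' @rdname generator_models
#' @export
bout_geometric <- function(mean = 30) {
  stopifnot(mean > 5)
  p <- 5 / mean
  function(n) 5 * (1 + stats::rgeom(n, p))
}

#' @rdname generator_models
#' @export
default_category_weights <- function() {
  list(
    sb = c("eating/drinking" = 0.30, "personal care" = 0.22,
           "passive transport" = 0.17, "calm play" = 0.14,
           "sitting/lying" = 0.11, "passive screen use" = 0.05,
           "play unknown intensity" = 0.01),
    pa = c("active play" = 0.85, "active transport" = 0.12,
           "active screen use" = 0.03)
  )
}

#' @rdname generator_models
#' @export
default_accel_levels <- function() {
  c(
    "sleeping" = 0.005,
    "passive screen use" = 0.012, "sitting/lying" = 0.015,
    "personal care" = 0.02, "eating/drinking" = 0.02,
    "passive transport" = 0.02, "calm play" = 0.03,
    "play unknown intensity" = 0.03,
    "active screen use" = 0.12, "active transport" = 0.15,
    "active play" = 0.2
  )
}
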