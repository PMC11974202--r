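test_that("mean squares agree with the two-way ANOVA fit", {
  set.seed(7)
  n <- 20; k <- 4
  y <- matrix(rnorm(n * k), n, k) + rnorm(n) + rep(rnorm(k), each = n)
  fit <- icc_single_day(y, type = "consistency")
  long <- data.frame(
    y = as.vector(y),
    child = factor(rep(seq_len(n), k)),
    day = factor(rep(seq_len(k), each = n))
  )
  av <- summary(stats::aov(y ~ child + day, data = long))[[1]]
  expect_equal(fit$msr, av["child", "Mean Sq"], tolerance = 1e-10)
  expect_equal(fit$msc, av["day", "Mean Sq"], tolerance = 1e-10)
  expect_equal(fit$mse, av["Residuals", "Mean Sq"], tolerance = 1e-10)
  # consistency form from the independent mean squares
  msr <- av["child", "Mean Sq"]; mse <- av["Residuals", "Mean Sq"]
  expect_equal(fit$icc, (msr - mse) / (msr + (k - 1) * mse),
               tolerance = 1e-12)
  # agreement form penalizes the day effect, so here it is smaller
  fit_a <- icc_single_day(y, type = "agreement")
  expect_lt(fit_a$icc, fit$icc)
  expect_true(fit_a$ci_low <= fit_a$icc && fit_a$icc <= fit_a$ci_high)
})

test_that("ICC hits its degenerate limits", {
  # constant within child, varying between children
  y <- matrix(rep(c(1, 5, 9, 13), each = 3), 4, 3, byrow = TRUE)
  expect_equal(icc_single_day(y, "consistency")$icc, 1)
  expect_equal(icc_single_day(y, "agreement")$icc, 1)
  # pure noise: near zero at large n
  set.seed(11)
  noise <- matrix(rnorm(2000), 500, 4)
  expect_lt(abs(icc_single_day(noise)$icc), 0.07)
  expect_error(icc_single_day(matrix(1, 3, 3)), "zero total variance")
  expect_error(icc_single_day(matrix(1, 1, 4)), "at least 2")
})

test_that("Spearman-Brown worked values and monotonicity", {
  expect_equal(round(spearman_brown_days(0.56), 2), 1.83)
  expect_equal(spearman_brown_days(0.70), 1)
  expect_equal(spearman_brown_days(0.50), 7 / 3, tolerance = 1e-12)
  # strictly decreasing in the single-day ICC
  d <- spearman_brown_days(seq(0.05, 0.95, by = 0.05))
  expect_true(all(diff(d) < 0))
  expect_warning(out <- spearman_brown_days(-0.1), "not achievable")
  expect_true(is.na(out))
})

test_that("k-day averages reach the reliability the prophecy formula predicts", {
  set.seed(13)
  n <- 400; k <- 6
  sigma_b <- 1; sigma_w <- 1.2
  y <- matrix(rnorm(n * k, sd = sigma_w), n, k) + rnorm(n, sd = sigma_b)
  r1 <- icc_single_day(y, "consistency")$icc
  for (kk in c(2, 3)) {
    means <- sapply(seq_len(k %/% kk), function(j) {
      rowMeans(y[, ((j - 1) * kk + 1):(j * kk)])
    })
    r_k <- icc_single_day(means, "consistency")$icc
    expect_equal(r_k, spearman_brown_step_up(r1, kk), tolerance = 0.06)
  }
})

test_that("the reliability grid enumerates criteria and recovers the target ICC", {
  cfg <- simulation_config(n_children = 800, n_days = 7, seed = 17,
                           icc_target = 0.55,
                           coverage_model = coverage_constant(24))
  truth <- simulate_cohort(cfg, schedule = FALSE)
  daily <- dplyr::mutate(truth$daily,
                         coverage_hours = 24,
                         excluded_min = 0)
  daily <- add_ilr_coordinates(daily)
  grid <- reliability_grid(daily, min_hours = c(12, 18, 24),
                           n_days = c(2, 4), reps = 3, seed = 23)
  expect_s3_class(grid, "reliability_grid")
  expect_identical(nrow(grid), 6L * 3L * 2L)
  expect_true(all(grid$n_eligible == 800))
  expect_true(all(grid$pct_eligible == 100))
  # full coverage: criteria cannot censor days, ICCs recover the target.
  # Individual cells carry the sampling error of an ICC at the cell's k
  # (sd ~ 0.04 for k = 2 at this n), the average across cells is tight.
  minute_rows <- grid[grid$outcome %in% c("pa_min", "sb_min", "sleep_min"), ]
  expect_lt(abs(mean(minute_rows$icc) - 0.55), 0.05)
  expect_lt(max(abs(minute_rows$icc - 0.55)), 0.12)
  # no surplus days at n_days = 7: only slot ordering differs between reps
  grid7 <- reliability_grid(daily, outcomes = "pa_min", min_hours = 24,
                            n_days = 7, reps = 3, seed = 29)
  expect_lt(grid7$icc_sd_over_reps, 0.005)
  # Spearman-Brown column is consistent with the averaged ICC
  ok <- !is.na(grid$min_days)
  expect_equal(
    spearman_brown_step_up(grid$icc[ok], grid$min_days[ok]),
    rep(0.70, sum(ok)), tolerance = 1e-12
  )
})

test_that("cells with too few eligible children are marked unavailable", {
  daily <- tibble::tibble(
    child_id = rep(c("a", "b"), each = 3),
    date = rep(as.Date("2023-03-06") + 0:2, 2),
    weekend = FALSE,
    pa_min = rnorm(6, 240, 10), sb_min = rnorm(6, 420, 10),
    sleep_min = rnorm(6, 780, 10),
    coverage_hours = c(24, 24, 24, 10, 10, 10)
  )
  grid <- reliability_grid(daily, outcomes = "pa_min", min_hours = 24,
                           n_days = 2, reps = 2, seed = 3)
  expect_identical(grid$n_eligible, 1L)
  expect_true(is.na(grid$icc))
})

test_that("weekend model: nominal size under the null and power for a sleep shift", {
  null_daily <- function(seed, n = 40, d = 7, weekend_effect = 0) {
    cfg <- simulation_config(n_children = n, n_days = d, seed = seed,
                             weekend_shift = c(pa = 0, sb = 0,
                                               sleep = weekend_effect))
    truth <- simulate_cohort(cfg, schedule = FALSE)
    daily <- dplyr::mutate(truth$daily, coverage_hours = 24)
    list(daily = daily, profiles = truth$profiles)
  }
  reps <- 120
  p_null <- vapply(seq_len(reps), function(s) {
    sim <- null_daily(1000 + s)
    weekend_effect_model(sim$daily, "sleep_min", sim$profiles)$p_value
  }, 1)
  rate <- mean(p_null < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)

  p_shift <- vapply(1:25, function(s) {
    sim <- null_daily(2000 + s, n = 300, weekend_effect = 60)
    fit <- weekend_effect_model(sim$daily, "sleep_min", sim$profiles)
    fit$p_value < 0.05 && fit$estimate > 0
  }, TRUE)
  expect_gte(mean(p_shift), 0.8)

  # no weekend days at all is a precondition failure
  sim <- null_daily(1)
  wk_only <- dplyr::filter(sim$daily, !weekend)
  expect_error(weekend_effect_model(wk_only, "sleep_min", sim$profiles),
               "inclusion criterion")
})
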