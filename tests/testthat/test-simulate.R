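test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_children = 5, n_days = 3, seed = 1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$daily, b$daily)
  expect_identical(simulate_diary(a, cfg)$entries,
                   simulate_diary(b, cfg)$entries)
})

test_that("schedules tile the day on the 5-min grid and match daily minutes", {
  sim <- shared_sim()
  sched <- sim$truth$schedule
  expect_true(all(sched$start_min %% 5 == 0))
  expect_true(all(sched$end_min %% 5 == 0))
  expect_true(all(sched$end_min > sched$start_min))
  by_day <- sched |>
    dplyr::group_by(child_id, date) |>
    dplyr::summarise(
      total = sum(end_min - start_min),
      tiles = all(start_min[-1] == end_min[-dplyr::n()]),
      first = dplyr::first(start_min), last = dplyr::last(end_min),
      .groups = "drop"
    )
  expect_true(all(by_day$total == 1440))
  expect_true(all(by_day$tiles))
  expect_true(all(by_day$first == 0))
  expect_true(all(by_day$last == 1440))
  # scheduled behavior minutes equal the generated daily minutes
  beh <- sched |>
    dplyr::group_by(child_id, date, behavior) |>
    dplyr::summarise(min = sum(end_min - start_min), .groups = "drop") |>
    tidyr::pivot_wider(names_from = behavior, values_from = min,
                       values_fill = 0)
  joined <- dplyr::inner_join(beh, sim$truth$daily,
                              by = c("child_id", "date"))
  expect_equal(joined$PA, joined$pa_min)
  expect_equal(joined$SB, joined$sb_min)
  expect_equal(joined$sleep, joined$sleep_min)
  # schedule labels are consistent with the classification rules
  lab <- classify_behavior(sched, sim$truth$profiles)
  expect_identical(lab$behavior, sched$behavior)
})

test_that("zero day-to-day variance collapses each child's days", {
  cfg <- simulation_config(n_children = 4, n_days = 5, seed = 8,
                           sd_log = 0)
  truth <- simulate_cohort(cfg, schedule = FALSE)
  per_child <- truth$daily |>
    dplyr::group_by(child_id) |>
    dplyr::summarise(v = var(pa_min) + var(sb_min) + var(sleep_min))
  expect_true(all(per_child$v == 0))
})

test_that("the generated between-child variance share matches the target", {
  cfg <- simulation_config(n_children = 500, n_days = 4, seed = 21,
                           icc_target = 0.5)
  truth <- simulate_cohort(cfg, schedule = FALSE)
  # independent one-way ANOVA moment estimate on daily PA minutes
  wide <- matrix(truth$daily$pa_min, nrow = 500, byrow = TRUE)
  k <- ncol(wide)
  msb <- k * var(rowMeans(wide))
  msw <- mean(apply(wide, 1, var))
  sigma_b2 <- (msb - msw) / k
  share <- sigma_b2 / (sigma_b2 + msw)
  expect_lt(abs(share - 0.5), 0.05)
})

test_that("coverage truncation hits the drawn reporting hours exactly", {
  cfg <- simulation_config(n_children = 3, n_days = 2, seed = 4,
                           coverage_model = coverage_constant(12))
  sim <- simulate_diary(simulate_cohort(cfg), cfg)
  mins <- sim$entries |>
    dplyr::group_by(child_id, date) |>
    dplyr::summarise(m = sum(end_min - start_min), .groups = "drop")
  expect_true(all(mins$m == 720))
  # full coverage keeps the complete tiling
  cfg24 <- simulation_config(n_children = 3, n_days = 2, seed = 4,
                             coverage_model = coverage_constant(24),
                             relabel_someone_else = 0,
                             relabel_dont_know = 0)
  truth24 <- simulate_cohort(cfg24)
  sim24 <- simulate_diary(truth24, cfg24)
  expect_identical(nrow(sim24$entries), nrow(truth24$schedule))
})

test_that("bout lengths follow the configured model up to tiling remainders", {
  sim <- shared_sim()
  awake <- dplyr::filter(sim$truth$schedule, behavior != "sleep")
  dur <- awake$end_min - awake$start_min
  expect_true(all(dur %% 5 == 0))
  expect_true(all(dur <= 30))
  expect_gt(mean(dur == 30), 0.6)
})

test_that("descriptive relabeling approximately matches its configured rate", {
  cfg <- simulation_config(n_children = 30, n_days = 7, seed = 6,
                           relabel_someone_else = 0.05,
                           relabel_dont_know = 0.02)
  truth <- simulate_cohort(cfg)
  sim <- simulate_diary(truth, cfg)
  frac <- mean(sim$entries$category %in% excluded_categories)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.10)
  # truth schedule keeps the real labels
  expect_false(any(truth$schedule$category %in% excluded_categories))
})

test_that("raw acceleration reduces to pure gravity when noise is absent", {
  lv <- default_accel_levels()
  lv[] <- 0
  suppressWarnings(
    cfg <- simulation_config(n_children = 1, n_days = 1, seed = 14,
                             accel_level = lv, noise_sd = 0,
                             nonwear_rate = 0, sample_rate = 5)
  )
  truth <- simulate_cohort(cfg)
  sig <- simulate_raw_acceleration(truth, "c0001", cfg$start_date, "hip",
                                   cfg)
  r <- sqrt(sig$x^2 + sig$y^2 + sig$z^2)
  expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)
  ep <- compute_epochs(sig, sample_rate = 5)
  expect_equal(max(ep$enmo), 0, tolerance = 1e-12)
})

test_that("raw streams order activities and reproduce byte-identically", {
  cfg <- simulation_config(n_children = 1, n_days = 1, seed = 15,
                           nonwear_rate = 0, sample_rate = 10)
  truth <- simulate_cohort(cfg)
  sig <- simulate_raw_acceleration(truth, "c0001", cfg$start_date, "hip",
                                   cfg)
  ep <- compute_epochs(sig, sample_rate = 10)
  sched <- truth$schedule
  idx <- findInterval(ep$epoch_start, sched$start_min * 60)
  mean_by <- tapply(ep$enmo, sched$behavior[idx], mean)
  expect_gt(mean_by[["PA"]], mean_by[["SB"]])
  expect_gt(mean_by[["SB"]], mean_by[["sleep"]])
  # unknown placement is rejected
  expect_error(
    simulate_raw_acceleration(truth, "c0001", cfg$start_date, "ankle", cfg)
  )
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, cfg$start_date, f1)
  sig2 <- simulate_raw_acceleration(truth, "c0001", cfg$start_date, "hip",
                                    cfg)
  write_signal_csv(sig2, cfg$start_date, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  # and the CSV round-trips through the reader
  back <- read_signal_csv(f1)
  expect_equal(back$z, sig$z, tolerance = 1e-5)
})

test_that("epoch-level sampler agrees with epoch metrics on the raw stream", {
  cfg <- simulation_config(n_children = 1, n_days = 1, seed = 16,
                           nonwear_rate = 0, sample_rate = 25)
  truth <- simulate_cohort(cfg)
  raw <- simulate_raw_acceleration(truth, "c0001", cfg$start_date, "hip",
                                   cfg)
  ep_raw <- compute_epochs(raw, sample_rate = 25)
  ep_fast <- simulate_epoch_series(truth, placements = "hip", config = cfg)
  sched <- truth$schedule
  by_group <- function(ep) {
    idx <- findInterval(ep$epoch_start, sched$start_min * 60)
    grp <- sched$behavior[idx]
    tapply(ep$enmo, grp, mean)
  }
  a <- by_group(ep_raw)
  b <- by_group(ep_fast)
  for (g in names(a)) {
    expect_lt(abs(a[[g]] - b[[g]]) / max(a[[g]], 0.001), 0.15)
  }
  # MAD agrees too at the behavior level
  idx <- findInterval(ep_raw$epoch_start, sched$start_min * 60)
  mad_raw <- tapply(ep_raw$mad, sched$behavior[idx], mean)
  idxf <- findInterval(ep_fast$epoch_start, sched$start_min * 60)
  mad_fast <- tapply(ep_fast$mad, sched$behavior[idxf], mean)
  for (g in names(mad_raw)) {
    expect_lt(abs(mad_raw[[g]] - mad_fast[[g]]) / max(mad_raw[[g]], 0.001),
              0.15)
  }
})

test_that("nonwear appears as constant blocks of at least 30 minutes", {
  cfg <- simulation_config(n_children = 1, n_days = 1, seed = 18,
                           nonwear_rate = 0.15, sample_rate = 10)
  truth <- simulate_cohort(cfg)
  sig <- simulate_raw_acceleration(truth, "c0001", cfg$start_date, "wrist",
                                   cfg)
  blocks <- attr(sig, "nonwear_blocks")
  expect_gt(nrow(blocks), 0)
  expect_true(all(blocks$end_s - blocks$start_s >= 30 * 60))
  # the detector finds them
  nw <- detect_nonwear(sig)
  for (b in seq_len(nrow(blocks))) {
    inside <- nw$epoch_start >= blocks$start_s[b] &
      nw$epoch_start < blocks$end_s[b]
    expect_true(all(!nw$wear[inside]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(icc_target = 1.2))
  expect_error(simulation_config(mean_minutes = c(pa = 800, sb = 500,
                                                  sleep = 500)))
  expect_error(simulation_config(sd_log = -1))
  expect_warning(
    simulation_config(accel_level = replace(default_accel_levels(),
                                            "sleeping", 0.5)),
    "not ordered"
  )
})
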