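test_that("the hypothesis enumeration is combinatorially exact", {
  h <- enumerate_hypotheses()
  expect_identical(nrow(h), 55L)
  expect_identical(h$id, 1:55)
  sim_sb <- h[h$kind == "similarity" & h$left %in% sb_activity_groups, ]
  sim_pa <- h[h$kind == "similarity" & h$left %in% pa_activity_groups, ]
  expect_identical(nrow(sim_sb), as.integer(choose(7, 2)))
  expect_identical(nrow(sim_pa), as.integer(choose(3, 2)))
  expect_true(all(sim_sb$right %in% sb_activity_groups))
  expect_true(all(sim_pa$right %in% pa_activity_groups))
  diff <- h[h$kind == "difference", ]
  expect_identical(nrow(diff), 31L)
  sleep_rows <- diff[diff$left == "sleeping", ]
  expect_identical(nrow(sleep_rows), 10L)
  expect_setequal(sleep_rows$right,
                  c(sb_activity_groups, pa_activity_groups))
  pa_sb <- diff[diff$left != "sleeping", ]
  expect_identical(nrow(pa_sb), 21L)
  expect_true(all(pa_sb$left %in% sb_activity_groups))
  expect_true(all(pa_sb$right %in% pa_activity_groups))
  # no pair occurs twice
  expect_identical(anyDuplicated(paste(pmin(h$left, h$right),
                                       pmax(h$left, h$right), h$kind)), 0L)
  expect_identical(nrow(main_hypothesis()), 3L)
})

test_that("explained-variance bands follow the published cut-offs", {
  expect_identical(classify_r2(0.00), "very weak")
  expect_identical(classify_r2(0.019), "very weak")
  expect_identical(classify_r2(0.02), "weak")
  expect_identical(classify_r2(0.13), "moderate")
  expect_identical(classify_r2(0.14), "moderate")
  expect_identical(classify_r2(0.26), "moderate")
  expect_identical(classify_r2(0.28), "substantial")
  expect_error(classify_r2(1.2), "0, 1")
})

test_that("the consistency ledger is a pure function of the support flags", {
  base <- tidyr::expand_grid(metric = c("enmo", "mad"),
                             placement = c("hip", "wrist"))
  mk <- function(id, supported) {
    dplyr::mutate(base, id = id, kind = "difference", left = "sleeping",
                  right = "active play", expected = "left<right",
                  estimate = -1, p_value = 0.01,
                  available = TRUE, supported = supported)
  }
  res <- dplyr::bind_rows(
    mk(1, c(TRUE, TRUE, TRUE, TRUE)),
    mk(2, c(TRUE, FALSE, TRUE, FALSE)),
    mk(3, c(FALSE, FALSE, FALSE, FALSE))
  )
  led <- consistency_ledger(res)
  expect_identical(led$verdict, c("+", "±", "-"))
  expect_identical(led$supporting_combos[1],
                   "hip ENMO, hip MAD, wrist ENMO, wrist MAD")
  expect_identical(led$supporting_combos[2], "hip ENMO, hip MAD")
  expect_identical(led$supporting_combos[3], "")
})

# Hand-built entry accelerations with known group means, many children.
synthetic_entry_acc <- function(n_children = 30, entries_per_group = 4,
                                means = c("sleeping" = 0.002,
                                          "calm play" = 0.01,
                                          "active play" = 0.1),
                                sd = 0.3, seed = 1) {
  set.seed(seed)
  groups <- names(means)
  beh <- ifelse(groups == "sleeping", "sleep",
                ifelse(groups %in% pa_activity_groups, "PA", "SB"))
  combos <- tidyr::expand_grid(metric = c("enmo", "mad"),
                               placement = c("hip", "wrist"))
  rows <- list()
  for (ci in seq_len(n_children)) {
    child <- sprintf("c%03d", ci)
    u <- rnorm(1, 0, 0.1)
    for (g in seq_along(groups)) {
      for (e in seq_len(entries_per_group)) {
        val <- exp(log(means[g]) + u + rnorm(1, 0, sd))
        rows[[length(rows) + 1]] <- tibble::tibble(
          child_id = child, date = as.Date("2023-03-06") + (e %% 3),
          entry_index = e, category = groups[g], group = groups[g],
          behavior = beh[g], excluded = FALSE,
          placement = rep(c("hip", "wrist"), each = 1)[1],
          median_enmo = val, median_mad = val * 0.8, n_epochs = 60L
        )
      }
    }
  }
  acc <- dplyr::bind_rows(rows)
  dplyr::bind_rows(acc, dplyr::mutate(acc, placement = "wrist"))
}

synthetic_profiles <- function(n_children = 30) {
  prof <- tiny_profile(child_id = sprintf("c%03d", seq_len(n_children)))
  prof$sex <- rep(c("female", "male"), length.out = n_children)
  prof
}

test_that("category models recover large separations with the right sign", {
  ea <- synthetic_entry_acc()
  prof <- synthetic_profiles()
  fit <- fit_category_model(ea, prof, "enmo", "hip", grouping = "category")
  expect_s3_class(fit, "acc_model")
  specs <- tibble::tibble(
    id = 1:3, kind = c("difference", "difference", "similarity"),
    left = c("sleeping", "calm play", "calm play"),
    right = c("active play", "active play", "active play"),
    expected = c("left<right", "left<right", "left=right")
  )
  res <- pairwise_contrasts(fit, specs)
  expect_true(all(res$available))
  expect_true(res$supported[1])
  expect_true(res$supported[2])
  # a clearly separated pair does not pass as similar
  expect_false(res$supported[3])
  # direction rule: reversed expectation is not supported despite p < .05
  rev_spec <- tibble::tibble(id = 1, kind = "difference",
                             left = "active play", right = "sleeping",
                             expected = "left<right")
  expect_false(pairwise_contrasts(fit, rev_spec)$supported)
  # tidy/glance interfaces
  expect_true(all(c("term", "p.value") %in% names(tidy(fit))))
  expect_gt(glance(fit)$r2_marginal, 0.2)
})

test_that("similarity verdicts hold for identical groups at roughly nominal rate", {
  prof <- synthetic_profiles(20)
  support <- vapply(1:30, function(s) {
    ea <- synthetic_entry_acc(
      n_children = 20, entries_per_group = 3,
      means = c("calm play" = 0.01, "passive screen use" = 0.01,
                "active play" = 0.1),
      seed = 100 + s
    )
    fit <- fit_category_model(ea, prof, "enmo", "hip",
                              grouping = "category")
    spec <- tibble::tibble(id = 1, kind = "similarity", left = "calm play",
                           right = "passive screen use",
                           expected = "left=right")
    pairwise_contrasts(fit, spec)$supported
  }, TRUE)
  expect_gte(mean(support), 0.8)
})

test_that("single-group data is a precondition failure", {
  ea <- synthetic_entry_acc(means = c("active play" = 0.1))
  expect_error(
    fit_category_model(ea, synthetic_profiles(), "enmo", "hip",
                       grouping = "category"),
    "at least 2 groups"
  )
})

test_that("the main hypothesis is confirmed on one default synthetic cohort", {
  cfg <- simulation_config(n_children = 15, n_days = 3, seed = 77)
  truth <- simulate_cohort(cfg)
  sim <- simulate_diary(truth, cfg)
  ep <- simulate_epoch_series(truth, config = cfg)
  ea <- summarize_entries(sim$entries, ep, sim$profiles)
  mh <- test_main_hypothesis(ea, sim$profiles)
  expect_identical(nrow(mh), 4L)
  expect_true(all(mh$confirmed))
  expect_true(all(mh$r2_marginal > 0.26))
  # and the full ledger runs, with every hypothesis getting a verdict
  hyp <- test_hypotheses(ea, sim$profiles)
  expect_identical(nrow(hyp$ledger), 55L)
  expect_true(all(hyp$ledger$verdict %in% c("+", "±", "-")))
  # differences in the generator's design are overwhelmingly confirmed:
  # sleep sits far below every waking category
  sleep_rows <- hyp$ledger[hyp$ledger$left == "sleeping", ]
  expect_gte(mean(sleep_rows$verdict == "+"), 0.8)
})

test_that("ledger and grid autoplots build", {
  sim <- shared_sim()
  tot <- add_ilr_coordinates(daily_totals(sim$diary$entries,
                                          sim$diary$profiles))
  grid <- reliability_grid(tot, outcomes = "pa_min", min_hours = c(12, 16),
                           n_days = 2, reps = 2, seed = 1)
  expect_s3_class(autoplot(grid), "ggplot")
  ea <- summarize_entries(sim$diary$entries, sim$epochs, sim$diary$profiles)
  hyp <- test_hypotheses(ea, sim$diary$profiles)
  expect_s3_class(autoplot(hyp$ledger), "ggplot")
  expect_s3_class(plot_entry_accelerations(ea), "ggplot")
})
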