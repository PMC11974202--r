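# Small fixture builders shared across test files.

tiny_profile <- function(child_id = "c1", age_group = "2-3y",
                         sex = "female", age_months = 30,
                         milestones = TRUE) {
  prof <- tibble::tibble(
    child_id = child_id, sex = sex,
    birth_date = as.Date("2023-03-06") - round(age_months * 30.44),
    age_months = age_months, age_group = age_group
  )
  for (m in movediary::milestone_names) prof[[m]] <- milestones
  prof
}

tiny_entry <- function(child_id = "c1", date = as.Date("2023-03-06"),
                       category = "sleeping", start_min = 0, end_min = 30,
                       intensity = "n/a", posture = "n/a") {
  tibble::tibble(child_id = child_id, date = date, category = category,
                 start_min = start_min, end_min = end_min,
                 intensity = intensity, posture = posture)
}

# Gapless full-day 5-s epoch table for one child-day-placement.
flat_epochs <- function(child_id = "c1", date = as.Date("2023-03-06"),
                        placement = "hip", enmo = 0, mad = 0, wear = TRUE) {
  n <- 86400 / 5
  tibble::tibble(
    child_id = child_id, date = date, placement = placement,
    epoch_start = (seq_len(n) - 1) * 5,
    enmo = rep_len(enmo, n), mad = rep_len(mad, n), wear = rep_len(wear, n)
  )
}

# One shared small simulated cohort with diary + epochs, reused across
# files to keep the suite fast.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_children = 12, n_days = 7, seed = 2024)
      truth <- simulate_cohort(cfg)
      diary <- simulate_diary(truth, cfg)
      epochs <- simulate_epoch_series(truth, config = cfg)
      cache <<- list(cfg = cfg, truth = truth, diary = diary,
                     epochs = epochs)
    }
    cache
  }
})
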