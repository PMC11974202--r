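#' Emit diary entries from a simulated cohort
#'
#' Converts the true schedules into parent-reported diary entries:
#' coverage truncation first drops (and finally trims) entries until each
#' day's reported minutes match that day's draw from the coverage model,
#' then a configured fraction of entries is relabeled to the descriptive
#' categories "my child was with someone else" and "I don't know". The
#' truth object is untouched, so every emitted entry can be compared with
#' its true label.
#'
#' @param truth A `cohort_truth` from [simulate_cohort()].
#' @param config The [simulation_config()] used to build `truth`.
#' @return List with `entries` (diary tibble: `child_id`, `date`,
#'   `category`, `start_min`, `end_min`, `intensity`, `posture`) and
#'   `profiles`.
#' @examples
#' cfg <- simulation_config(n_children = 2, n_days = 2,
#'                          coverage_model = coverage_constant(24))
#' sim <- simulate_diary(simulate_cohort(cfg), cfg)
#' nrow(sim$entries)
#' @export
simulate_diary <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "cohort_truth"))
  entries <- withr::with_seed(derive_seed(config$seed, "diary"), {
    sched <- dplyr::group_split(truth$schedule, .data$child_id, .data$date)
    kept <- lapply(sched, function(df) {
      target <- round(config$coverage_model(1) * 60 / 5) * 5
      truncate_day(df, target)
    })
    out <- dplyr::bind_rows(kept)
    # Relabeling to descriptive categories happens after scheduling so the
    # truth keeps the real labels.
    u <- runif(nrow(out))
    se <- u < config$relabel_someone_else
    dk <- !se & u < config$relabel_someone_else + config$relabel_dont_know
    out$category[se] <- "my child was with someone else"
    out$category[dk] <- "I don't know"
    out$intensity[se | dk] <- "n/a"
    out$posture[se | dk] <- "n/a"
    dplyr::arrange(out, .data$child_id, .data$date, .data$start_min)
  })
  list(
    entries = dplyr::select(entries, "child_id", "date", "category",
                            "start_min", "end_min", "intensity", "posture"),
    profiles = truth$profiles
  )
}

# Keep a random subset of a day's entries whose minutes sum to `target`
# exactly: accumulate entries in random order, trimming the last kept entry
# to fit (trimmed-to-zero entries are dropped).
truncate_day <- function(df, target) {
  dur <- df$end_min - df$start_min
  if (target >= sum(dur)) return(df)
  ord <- sample.int(nrow(df))
  cum <- cumsum(dur[ord])
  n_keep <- which(cum >= target)[1]
  keep <- ord[seq_len(n_keep)]
  out <- df[keep, ]
  excess <- cum[n_keep] - target
  if (excess > 0) {
    out$end_min[n_keep] <- out$end_min[n_keep] - excess
    if (out$end_min[n_keep] <= out$start_min[n_keep]) {
      out <- out[-n_keep, ]
    }
  }
  out
}
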