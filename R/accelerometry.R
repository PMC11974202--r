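#' Aggregate a raw triaxial signal into 5-s epoch ENMO and MAD
#'
#' Computes the two cut-point-free acceleration metrics used throughout
#' the package from the per-sample vector magnitude
#' \eqn{r = \sqrt{x^2 + y^2 + z^2}}:
#' \itemize{
#'   \item ENMO (Euclidean norm minus one): per-sample
#'     \eqn{\max(r - 1, 0)} (gravity-corrected, negatives truncated at the
#'     sample level), averaged over the epoch;
#'   \item MAD (mean amplitude deviation): the mean absolute deviation of
#'     \eqn{r} from its epoch mean.
#' }
#' Samples are clipped to +/- 8 g (the device's dynamic range) before the
#' magnitude is taken. Epochs sit on a grid anchored at midnight and are
#' labeled by their start instant; epochs with fewer than the nominal
#' number of samples (partial leading/trailing epochs, gaps) are dropped.
#'
#' @param signal Tibble with `time_s` (seconds since midnight, strictly
#'   increasing) and `x`, `y`, `z` in g.
#' @param epoch_s Epoch length in seconds (default 5).
#' @param sample_rate Sampling rate in Hz; inferred from the median
#'   timestamp spacing when `NULL`.
#' @return Tibble with `epoch_start` (s), `enmo` (g), `mad` (g), `n`
#'   (samples in the epoch).
#' @examples
#' sig <- tibble::tibble(time_s = (0:499) / 50, x = 0, y = 0, z = 1.25)
#' compute_epochs(sig)  # ENMO 0.25, MAD 0
#' @export
compute_epochs <- function(signal, epoch_s = 5, sample_rate = NULL) {
  stopifnot(all(c("time_s", "x", "y", "z") %in% names(signal)))
  if (nrow(signal) == 0) {
    return(tibble::tibble(epoch_start = numeric(0), enmo = numeric(0),
                          mad = numeric(0), n = integer(0)))
  }
  if (is.unsorted(signal$time_s, strictly = TRUE)) {
    rlang::abort("timestamps must be strictly increasing")
  }
  if (is.null(sample_rate)) {
    sample_rate <- 1 / median(diff(signal$time_s))
  }
  expected <- round(epoch_s * sample_rate)
  acc <- pmin(pmax(as.matrix(signal[, c("x", "y", "z")]), -8), 8)
  r <- sqrt(rowSums(acc^2))
  id <- floor(signal$time_s / epoch_s)
  present <- sort(unique(id))
  pos <- match(id, present)
  n_per <- tabulate(pos, nbins = length(present))
  enmo_sum <- rowsum_vec(pmax(r - 1, 0), pos)
  r_mean <- rowsum_vec(r, pos) / n_per
  mad_sum <- rowsum_vec(abs(r - r_mean[pos]), pos)
  keep <- which(n_per == expected)
  tibble::tibble(
    epoch_start = present[keep] * epoch_s,
    enmo = enmo_sum[keep] / n_per[keep],
    mad = mad_sum[keep] / n_per[keep],
    n = n_per[keep]
  )
}

rowsum_vec <- function(x, id) {
  as.vector(rowsum(x, id, reorder = TRUE))
}

#' Detect non-wear periods from sustained signal stillness
#'
#' Slides a 30-min window (in one-epoch steps) over per-epoch, per-axis
#' standard deviations pooled within the window; a window is classed
#' non-wear when at least `min_axes` axes have pooled standard deviation
#' below `sd_crit`, and every epoch covered by any non-wear window is
#' masked. This is a single-pass simplification of the van Hees-style
#' heuristic family; thresholds default to the 30 min / 0.013 g / 2 axes
#' convention.
#'
#' @param signal Tibble with `time_s`, `x`, `y`, `z`.
#' @param epoch_s Epoch length in seconds.
#' @param window_min Window length in minutes.
#' @param sd_crit Per-axis standard deviation threshold in g.
#' @param min_axes Number of still axes required to call non-wear.
#' @return Tibble with `epoch_start` and logical `wear`.
#' @export
detect_nonwear <- function(signal, epoch_s = 5, window_min = 30,
                           sd_crit = 0.013, min_axes = 2) {
  stats <- epoch_axis_stats(signal, epoch_s)
  n_ep <- nrow(stats)
  w <- round(window_min * 60 / epoch_s)
  if (n_ep < w) {
    return(tibble::tibble(epoch_start = stats$epoch_start,
                          wear = rep(TRUE, n_ep)))
  }
  still_axes <- integer(n_ep - w + 1)
  for (axis in c("x", "y", "z")) {
    s <- stats[[paste0("sum_", axis)]]
    q <- stats[[paste0("sumsq_", axis)]]
    m <- stats$n
    cs <- cumsum(c(0, s)); cq <- cumsum(c(0, q)); cm <- cumsum(c(0, m))
    i <- seq_len(n_ep - w + 1)
    win_n <- cm[i + w] - cm[i]
    win_s <- cs[i + w] - cs[i]
    win_q <- cq[i + w] - cq[i]
    win_var <- pmax((win_q - win_s^2 / win_n) / (win_n - 1), 0)
    still_axes <- still_axes + (sqrt(win_var) < sd_crit)
  }
  nonwear_win <- which(still_axes >= min_axes)
  wear <- rep(TRUE, n_ep)
  for (i in nonwear_win) wear[i:(i + w - 1)] <- FALSE
  tibble::tibble(epoch_start = stats$epoch_start, wear = wear)
}

# Per-epoch per-axis sums, sums of squares and counts (complete epochs).
epoch_axis_stats <- function(signal, epoch_s = 5) {
  id <- floor(signal$time_s / epoch_s)
  present <- sort(unique(id))
  pos <- match(id, present)
  n_per <- tabulate(pos, nbins = length(present))
  expected <- max(n_per)
  out <- tibble::tibble(
    epoch_start = present * epoch_s,
    n = n_per
  )
  for (axis in c("x", "y", "z")) {
    v <- signal[[axis]]
    out[[paste0("sum_", axis)]] <- rowsum_vec(v, pos)
    out[[paste0("sumsq_", axis)]] <- rowsum_vec(v^2, pos)
    out[[paste0("mean_", axis)]] <- out[[paste0("sum_", axis)]] / n_per
    out[[paste0("sd_", axis)]] <- sqrt(pmax(
      (out[[paste0("sumsq_", axis)]] -
         out[[paste0("sum_", axis)]]^2 / n_per) / pmax(n_per - 1, 1), 0))
  }
  out[out$n == expected, ]
}

#' Autocalibrate a raw signal against local gravity
#'
#' Estimates per-axis offset and gain so that the vector magnitude of
#' still (low-movement) epochs approaches 1 g, by iteratively regressing
#' each axis of the still-epoch mean vectors onto their projection on the
#' unit sphere. Still epochs are those with all three per-axis standard
#' deviations below `sd_crit`; the procedure needs still data spanning
#' several orientations to identify the six parameters. The
#' post-calibration error is the mean absolute deviation of the still
#' vector magnitudes from 1 g; signals whose error exceeds `max_error`
#' (0.01 g) are flagged for exclusion. With insufficient still data the
#' signal passes through unchanged, flagged `calibrated = FALSE`.
#'
#' @param signal Tibble with `time_s`, `x`, `y`, `z`.
#' @param epoch_s Epoch length for stillness screening.
#' @param sd_crit Stillness threshold per axis (g).
#' @param min_still_min Minimum minutes of still data required.
#' @param max_error Post-calibration error above which the file is flagged
#'   excluded (g).
#' @param max_iter Maximum refinement iterations.
#' @return An object of class `calibration`: list with `signal` (adjusted),
#'   `offset`, `scale`, `calibration_error`, `calibrated`, `excluded`,
#'   `n_still_epochs`.
#' @export
calibrate <- function(signal, epoch_s = 5, sd_crit = 0.013,
                      min_still_min = 15, max_error = 0.01, max_iter = 50) {
  stats <- epoch_axis_stats(signal, epoch_s)
  still <- stats[stats$sd_x < sd_crit & stats$sd_y < sd_crit &
                   stats$sd_z < sd_crit, ]
  need <- min_still_min * 60 / epoch_s
  m0 <- as.matrix(still[, c("mean_x", "mean_y", "mean_z")])
  spread <- if (nrow(m0) > 1) max(apply(m0, 2, function(v) diff(range(v))))
            else 0
  if (nrow(still) < need || spread < 0.1) {
    err <- if (nrow(still) > 0) {
      mean(abs(sqrt(rowSums(m0^2)) - 1))
    } else NA_real_
    rlang::warn("insufficient still data for autocalibration; signal passed through")
    return(structure(
      list(signal = signal, offset = c(0, 0, 0), scale = c(1, 1, 1),
           calibration_error = err, calibrated = FALSE,
           excluded = isTRUE(err > max_error), n_still_epochs = nrow(still)),
      class = "calibration"
    ))
  }
  offset <- c(0, 0, 0)
  scale <- c(1, 1, 1)
  for (it in seq_len(max_iter)) {
    curr <- sweep(sweep(m0, 2, scale, "*"), 2, offset, "+")
    target <- curr / sqrt(rowSums(curr^2))
    change <- 0
    for (a in 1:3) {
      fit <- stats::lm.fit(cbind(1, curr[, a]), target[, a])
      int <- fit$coefficients[1]
      sl <- fit$coefficients[2]
      offset[a] <- offset[a] * sl + int
      scale[a] <- scale[a] * sl
      change <- max(change, abs(int), abs(sl - 1))
    }
    if (change < 1e-10) break
  }
  adj <- sweep(sweep(m0, 2, scale, "*"), 2, offset, "+")
  err <- mean(abs(sqrt(rowSums(adj^2)) - 1))
  out <- signal
  out$x <- signal$x * scale[1] + offset[1]
  out$y <- signal$y * scale[2] + offset[2]
  out$z <- signal$z * scale[3] + offset[3]
  structure(
    list(signal = out, offset = offset, scale = scale,
         calibration_error = err, calibrated = TRUE,
         excluded = err > max_error, n_still_epochs = nrow(still)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "Autocalibration: %s, error %.5f g (%d still epochs)%s\n",
    if (x$calibrated) "fitted" else "pass-through",
    x$calibration_error, x$n_still_epochs,
    if (x$excluded) " -- FLAGGED FOR EXCLUSION" else ""
  ))
  invisible(x)
}

#' @rdname compute_epochs
#' @param epochs Epoch tibble from `compute_epochs()`.
#' @param wear Wear mask from [detect_nonwear()].
#' @param path Output CSV path.
#' @export
write_epochs_csv <- function(epochs, wear, path) {
  out <- dplyr::left_join(epochs, wear, by = "epoch_start")
  out$wear[is.na(out$wear)] <- TRUE
  readr::write_csv(
    tibble::tibble(epoch_start = out$epoch_start,
                   enmo_g = out$enmo, mad_g = out$mad, wear = out$wear),
    path
  )
  invisible(path)
}
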