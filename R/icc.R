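#' Single-day intraclass correlation from a children-by-days matrix
#'
#' Estimates the day-to-day reproducibility of a daily diary outcome as an
#' intraclass correlation from the two-way (children x days) ANOVA mean
#' squares, in single-measurement form. Two variants are available:
#' `"agreement"` is the absolute-agreement coefficient ICC(A,1), which
#' charges systematic day effects against reliability; `"consistency"` is
#' ICC(C,1), which does not. Confidence intervals use the standard F-based
#' construction (McGraw & Wong 1996): an exact F interval for ICC(C,1) and
#' the Satterthwaite-df approximation for ICC(A,1).
#'
#' Negative estimates (possible when between-child variance is tiny) are
#' reported as computed, not floored, since the interval construction
#' expects the raw estimate.
#'
#' @param x Numeric matrix, children in rows, days (or selected day slots)
#'   in columns; no missing cells.
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf Confidence level for the interval.
#' @return An object of class `icc_fit`: a list with `icc`, `ci_low`,
#'   `ci_high`, `type`, `n` (children), `k` (days), and the mean squares
#'   `msr`, `msc`, `mse`. Has [tidy()] and [glance()] methods.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(100, sd = 1), 50, 2) + rnorm(50)  # icc ~ 0.5
#' icc_single_day(y)
#' @export
icc_single_day <- function(x, type = c("agreement", "consistency"),
                           conf = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) {
    rlang::abort("ICC needs at least 2 children and 2 days")
  }
  if (anyNA(x)) rlang::abort("ICC matrix must have no missing cells")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  if (msr == 0 && msc == 0 && mse == 0) {
    rlang::abort("ICC undefined: the matrix has zero total variance")
  }
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse > 0) {
      fobs <- msr / mse
      fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      icc <- 1
      ci <- c(1, 1)
    }
  } else {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    icc <- (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      icc <- 1
      ci <- c(1, 1)
    } else {
      r <- icc
      a <- k * r / (n * (1 - r))
      b <- 1 + k * r * (n - 1) / (n * (1 - r))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- qf(1 - alpha / 2, n - 1, v)
      f2 <- qf(1 - alpha / 2, v, n - 1)
      ci <- c(
        n * (msr - f1 * mse) /
          (f1 * (k * msc + (k * n - k - n) * mse) + n * msr),
        n * (f2 * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * f2 * msr)
      )
    }
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], conf = conf,
         type = type, n = n, k = k, msr = msr, msc = msc, mse = mse),
    class = "icc_fit"
  )
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "Single-measurement ICC (%s): %.3f [%.0f%% CI %.3f, %.3f], n = %d children x %d days\n",
    x$type, x$icc, 100 * x$conf, x$ci_low, x$ci_high, x$n, x$k
  ))
  invisible(x)
}

#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type, icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    conf = x$conf
  )
}

#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(n_children = x$n, n_days = x$k, msr = x$msr, msc = x$msc,
                 mse = x$mse)
}

#' Spearman-Brown prophecy: minimum days and stepped-up reliability
#'
#' `spearman_brown_days()` inverts the Spearman-Brown prophecy formula to
#' find how many repeated reporting days are needed so that the mean of
#' the days reaches a target reliability:
#' \deqn{k = \frac{target (1 - r)}{r (1 - target)}}
#' where `r` is the single-day ICC. A single-day ICC at or below zero makes
#' the target unachievable and returns `NA` with a warning.
#'
#' `spearman_brown_step_up()` is the forward direction: the reliability of
#' the mean of `k` days given single-day reliability `r`,
#' \eqn{k r / (1 + (k - 1) r)}.
#'
#' @param icc Single-day ICC (vectorized), in (0, 1) for an achievable
#'   target.
#' @param target Target reliability, default 0.70.
#' @param k Number of averaged days.
#' @return `spearman_brown_days()`: required days (numeric, not rounded
#'   up -- fractional values match how the criterion grid is reported).
#' @examples
#' spearman_brown_days(0.56)        # 1.83 days for a 0.70 target
#' spearman_brown_step_up(0.56, 2)  # reliability of a 2-day mean
#' @export
spearman_brown_days <- function(icc, target = 0.70) {
  stopifnot(target > 0, target < 1)
  out <- target * (1 - icc) / (icc * (1 - target))
  bad <- !is.na(icc) & icc <= 0
  if (any(bad)) {
    rlang::warn("single-day ICC <= 0: the target reliability is not achievable")
    out[bad] <- NA_real_
  }
  out
}

#' @rdname spearman_brown_days
#' @export
spearman_brown_step_up <- function(icc, k) {
  k * icc / (1 + (k - 1) * icc)
}
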