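#' Compositional coordinates for daily PA / SB / sleep time
#'
#' Daily time use is a 3-part composition: minutes in physical activity,
#' sedentary behavior and sleep are mutually exclusive and constrained by
#' the 24-h day, so analyses operate on isometric log-ratio (ilr) pivot
#' coordinates rather than raw minutes. With a chosen reference part (say
#' PA) the pair is
#' \deqn{z_1 = \sqrt{2/3}\,\ln\frac{PA}{(SB \cdot sleep)^{1/2}}, \qquad
#'       z_2 = \sqrt{1/2}\,\ln\frac{SB}{sleep}.}
#' Only the first pivot coordinate of each pair (`ilr.PA`, `ilr.SB`,
#' `ilr.sleep`) feeds downstream analyses; the second exists so the pair
#' inverts back to the closed composition.
#'
#' @param pa,sb,sleep Strictly positive parts (minutes); vectors recycle.
#' @param reference Which part is the pivot numerator.
#' @return `ilr_pivot()`: the first pivot coordinate (numeric vector).
#' @examples
#' ilr_pivot(400, 100, 100, reference = "pa")  # sqrt(2/3) * log(4)
#' ilr_pivot(480, 480, 480)                    # 0: equal split
#' @export
ilr_pivot <- function(pa, sb, sleep, reference = c("pa", "sb", "sleep")) {
  reference <- match.arg(reference)
  parts <- vctrs_recycle(pa = pa, sb = sb, sleep = sleep)
  if (any(unlist(parts) <= 0)) {
    rlang::abort("ilr coordinates require strictly positive parts; see zero_replace()")
  }
  others <- setdiff(c("pa", "sb", "sleep"), reference)
  sqrt(2 / 3) * log(parts[[reference]] /
                      sqrt(parts[[others[1]]] * parts[[others[2]]]))
}

#' @rdname ilr_pivot
#' @return `ilr_pivot_pair()`: a tibble with columns `z1`, `z2`.
#' @export
ilr_pivot_pair <- function(pa, sb, sleep, reference = c("pa", "sb", "sleep")) {
  reference <- match.arg(reference)
  parts <- vctrs_recycle(pa = pa, sb = sb, sleep = sleep)
  if (any(unlist(parts) <= 0)) {
    rlang::abort("ilr coordinates require strictly positive parts; see zero_replace()")
  }
  others <- setdiff(c("pa", "sb", "sleep"), reference)
  tibble::tibble(
    z1 = sqrt(2 / 3) * log(parts[[reference]] /
                             sqrt(parts[[others[1]]] * parts[[others[2]]])),
    z2 = sqrt(1 / 2) * log(parts[[others[1]]] / parts[[others[2]]])
  )
}

#' @rdname ilr_pivot
#' @param z1,z2 Pivot coordinate pair.
#' @return `ilr_inverse()`: a tibble with columns `pa`, `sb`, `sleep`
#'   closed to sum 1.
#' @export
ilr_inverse <- function(z1, z2, reference = c("pa", "sb", "sleep")) {
  reference <- match.arg(reference)
  stopifnot(all(is.finite(z1)), all(is.finite(z2)))
  n <- max(length(z1), length(z2))
  z1 <- rep_len(z1, n); z2 <- rep_len(z2, n)
  # clr = V %*% z with the pivot basis for part order (reference, o1, o2)
  l_ref <- sqrt(2 / 3) * z1
  l_o1 <- -sqrt(1 / 6) * z1 + sqrt(1 / 2) * z2
  l_o2 <- -sqrt(1 / 6) * z1 - sqrt(1 / 2) * z2
  e <- cbind(exp(l_ref), exp(l_o1), exp(l_o2))
  e <- e / rowSums(e)
  others <- setdiff(c("pa", "sb", "sleep"), reference)
  out <- tibble::tibble(a = e[, 1], b = e[, 2], c = e[, 3])
  names(out) <- c(reference, others)
  out[, c("pa", "sb", "sleep")]
}

#' Multiplicative replacement of zero parts
#'
#' The ilr transform is undefined at zero. Zero parts are replaced by
#' `delta` (default 1 min, below the diary's 5-min resolution) and the
#' non-zero parts are shrunk multiplicatively so the total is preserved.
#'
#' @param pa,sb,sleep Non-negative parts (minutes); not all zero.
#' @param delta Replacement value for zero parts, in minutes.
#' @return A tibble with columns `pa`, `sb`, `sleep` (all positive, same
#'   row totals as the input).
#' @examples
#' zero_replace(0, 720, 720)   # (1, 719.5, 719.5)
#' @export
zero_replace <- function(pa, sb, sleep, delta = 1) {
  stopifnot(delta > 0)
  parts <- vctrs_recycle(pa = pa, sb = sb, sleep = sleep)
  m <- cbind(parts$pa, parts$sb, parts$sleep)
  if (any(m < 0)) rlang::abort("parts must be non-negative")
  total <- rowSums(m)
  if (any(total <= 0)) rlang::abort("all-zero composition cannot be replaced")
  zero <- m == 0
  n0 <- rowSums(zero)
  shrink <- (total - n0 * delta) / total
  if (any(shrink <= 0)) {
    rlang::abort("delta too large for the composition total")
  }
  out <- m * shrink
  out[zero] <- delta
  tibble::tibble(pa = out[, 1], sb = out[, 2], sleep = out[, 3])
}

#' Append ilr pivot coordinates to a daily totals table
#'
#' Applies [zero_replace()] then computes the three first pivot
#' coordinates `ilr_pa`, `ilr_sb`, `ilr_sleep` from the daily minutes.
#' Coordinates are computed on minutes as reported; the log-transform used
#' for min/day reliability outcomes is a separate, downstream step.
#'
#' @param totals Daily totals tibble (columns `pa_min`, `sb_min`,
#'   `sleep_min`).
#' @param delta Zero-replacement value in minutes.
#' @return `totals` with `ilr_pa`, `ilr_sb`, `ilr_sleep` columns appended.
#' @export
add_ilr_coordinates <- function(totals, delta = 1) {
  parts <- zero_replace(totals$pa_min, totals$sb_min, totals$sleep_min,
                        delta = delta)
  dplyr::mutate(
    totals,
    ilr_pa = ilr_pivot(parts$pa, parts$sb, parts$sleep, "pa"),
    ilr_sb = ilr_pivot(parts$pa, parts$sb, parts$sleep, "sb"),
    ilr_sleep = ilr_pivot(parts$pa, parts$sb, parts$sleep, "sleep")
  )
}

vctrs_recycle <- function(...) {
  parts <- list(...)
  n <- max(vapply(parts, length, 1L))
  lapply(parts, rep_len, n)
}
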