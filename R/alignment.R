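#' Match diary entries with accelerometer epochs
#'
#' `match_epochs()` implements the inclusive matching rule for a single
#' entry: every epoch whose start instant is greater than or equal to the
#' entry's start time and less than or equal to its end time belongs to
#' the entry. Back-to-back entries therefore share their boundary epoch.
#' Only wear epochs are eligible.
#'
#' `summarize_entries()` applies the rule to a whole entry table against a
#' cohort epoch series and returns the analysis unit for hypothesis
#' testing: one row per diary entry x placement carrying the median epoch
#' ENMO and MAD (the acceleration distributions are strongly right-skewed,
#' so the median summarizes an entry better than the mean). Entries in the
#' three excluded categories are summarized too but flagged `excluded`;
#' entries whose span contains no wear epoch are omitted and counted in
#' the `n_unmatched` attribute.
#'
#' @param entry One-row tibble with `start_min`, `end_min`.
#' @param epochs Epoch tibble with `epoch_start` (seconds since midnight),
#'   `enmo`, `mad`, `wear`.
#' @param clock_offset_s Fixed diary-vs-device clock offset in seconds
#'   added to entry times (sensitivity analyses; default 0, clocks
#'   synchronized).
#' @return `match_epochs()`: the subset of `epochs` matched to the entry.
#' @examples
#' ep <- tibble::tibble(epoch_start = seq(0, 86395, 5), enmo = 0, mad = 0,
#'                      wear = TRUE)
#' e <- tibble::tibble(start_min = 600, end_min = 605)
#' nrow(match_epochs(e, ep))  # 61: inclusive at both ends
#' @export
match_epochs <- function(entry, epochs, clock_offset_s = 0) {
  start_s <- entry$start_min * 60 + clock_offset_s
  end_s <- entry$end_min * 60 + clock_offset_s
  epochs[epochs$epoch_start >= start_s & epochs$epoch_start <= end_s &
           epochs$wear, , drop = FALSE]
}

#' @rdname match_epochs
#' @param entries Diary entry tibble (`child_id`, `date`, `category`,
#'   `intensity`, `posture`, `start_min`, `end_min`).
#' @param profiles Child profiles (for behavior classification).
#' @return `summarize_entries()`: a tibble with one row per entry x
#'   placement: `child_id`, `date`, `entry_index`, `category`, `group`,
#'   `behavior`, `excluded`, `placement`, `median_enmo`, `median_mad`,
#'   `n_epochs`; attribute `n_unmatched` counts entry-placement pairs with
#'   no wear epoch.
#' @export
summarize_entries <- function(entries, epochs, profiles,
                              clock_offset_s = 0) {
  entries <- classify_behavior(entries, profiles)
  entries$group <- activity_group(entries$category, entries$intensity)
  entries$excluded <- entries$category %in% excluded_categories
  entries <- dplyr::mutate(
    dplyr::group_by(entries, .data$child_id, .data$date),
    entry_index = dplyr::row_number()
  )
  entries <- dplyr::ungroup(entries)
  # Contiguous child-day-placement blocks in the epoch table (the epoch
  # series is emitted sorted within blocks). Times are lifted onto a
  # strictly increasing global axis (one disjoint window per block) so a
  # single findInterval call resolves every entry's epoch range.
  n_ep <- nrow(epochs)
  chg <- c(TRUE, epochs$placement[-1] != epochs$placement[-n_ep] |
             epochs$child_id[-1] != epochs$child_id[-n_ep] |
             epochs$date[-1] != epochs$date[-n_ep])
  block_id <- cumsum(chg)
  block_first <- which(chg)
  block_last <- c(block_first[-1] - 1, n_ep)
  block_key <- paste(epochs$placement[block_first],
                     epochs$child_id[block_first],
                     as.character(epochs$date[block_first]), sep = "\r")
  if (anyDuplicated(block_key) > 0) {
    rlang::abort("epoch series must be grouped by placement, child and date")
  }
  span <- 2 * 86400 + max(abs(clock_offset_s)) + 1
  global_t <- epochs$epoch_start + (block_id - 1) * span
  if (is.unsorted(global_t, strictly = TRUE)) {
    rlang::abort("epoch timestamps must be strictly increasing within blocks")
  }
  wear_v <- epochs$wear
  enmo_v <- epochs$enmo
  mad_v <- epochs$mad
  placements <- unique(epochs$placement)
  out <- vector("list", length(placements))
  for (p in seq_along(placements)) {
    pl <- placements[p]
    b <- match(paste(pl, entries$child_id, as.character(entries$date),
                     sep = "\r"), block_key)
    off <- (b - 1) * span
    lo <- findInterval(off + entries$start_min * 60 + clock_offset_s - 1e-9,
                       global_t) + 1
    hi <- findInterval(off + entries$end_min * 60 + clock_offset_s + 1e-9,
                       global_t)
    lo <- pmax(lo, block_first[b])
    hi <- pmin(hi, block_last[b])
    n_e <- nrow(entries)
    med_enmo <- med_mad <- rep(NA_real_, n_e)
    n_wear <- integer(n_e)
    for (i in seq_len(n_e)) {
      if (is.na(b[i]) || is.na(hi[i]) || hi[i] < lo[i]) next
      sel <- lo[i]:hi[i]
      w <- wear_v[sel]
      if (!any(w)) next
      n_wear[i] <- sum(w)
      med_enmo[i] <- median(enmo_v[sel][w])
      med_mad[i] <- median(mad_v[sel][w])
    }
    out[[p]] <- dplyr::mutate(
      dplyr::select(entries, "child_id", "date", "entry_index", "category",
                    "group", "behavior", "excluded"),
      placement = pl,
      median_enmo = med_enmo, median_mad = med_mad, n_epochs = n_wear
    )
  }
  res <- dplyr::bind_rows(out)
  n_unmatched <- sum(res$n_epochs == 0)
  res <- dplyr::filter(res, .data$n_epochs > 0)
  attr(res, "n_unmatched") <- n_unmatched
  res
}
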