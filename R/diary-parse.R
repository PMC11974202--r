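#' Read and write diary entries and child profiles
#'
#' Diary entries travel as JSON (an array with one object per reported
#' activity: `child_id`, `date` in ISO-8601, `category`, `start`/`end` as
#' `"HH:MM"` clock times on the 5-min grid, `intensity`, `posture`) or as
#' an equivalent flat CSV. Internally entries are a tibble with start and
#' end expressed in minutes since midnight; `end` may be 1440 (midnight at
#' the end of the day). Entries crossing midnight are split at midnight
#' into two within-day entries.
#'
#' @param path File path. `parse_diary()` dispatches on the `.json` /
#'   `.csv` extension.
#' @return `parse_diary()`: a tibble of validated entries with columns
#'   `child_id`, `date`, `category`, `start_min`, `end_min`, `intensity`,
#'   `posture`. Malformed rows raise an error naming the row index.
#' @examples
#' f <- tempfile(fileext = ".json")
#' ent <- tibble::tibble(child_id = "c1", date = as.Date("2023-03-06"),
#'   category = "sleeping", start_min = 780, end_min = 810,
#'   intensity = "n/a", posture = "n/a")
#' write_diary_json(ent, f)
#' parse_diary(f)
#' @export
parse_diary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(
    ext,
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    csv = readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c")),
    rlang::abort("diary files must be .json or .csv")
  )
  required <- c("child_id", "date", "category", "start", "end")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("diary file lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  n <- nrow(raw)
  entries <- tibble::tibble(
    child_id = as.character(raw$child_id),
    date = as.Date(raw$date),
    category = as.character(raw$category),
    start_min = parse_clock(as.character(raw$start)),
    end_min = parse_clock(as.character(raw$end)),
    intensity = as.character(raw$intensity %||% rep("n/a", n)),
    posture = as.character(raw$posture %||% rep("n/a", n))
  )
  problems <- character(0)
  bad_cat <- which(!entries$category %in% diary_categories)
  if (length(bad_cat) > 0) {
    problems <- c(problems, paste0(
      "row ", bad_cat, ": unknown category '", entries$category[bad_cat], "'"
    ))
  }
  bad_time <- which(is.na(entries$start_min) | is.na(entries$end_min))
  if (length(bad_time) > 0) {
    problems <- c(problems,
                  paste0("row ", bad_time, ": time not on the 5-min grid"))
  }
  if (length(problems) > 0) {
    rlang::abort(c("malformed diary rows:", problems))
  }
  # Split entries that cross midnight (end clock-time before start).
  at_zero <- entries$end_min == 0L
  entries$end_min[at_zero] <- 1440L
  crosses <- entries$end_min < entries$start_min
  if (any(crosses)) {
    first <- entries[crosses, ]
    second <- entries[crosses, ]
    first$end_min <- 1440L
    second$date <- second$date + 1L
    second$start_min <- 0L
    entries <- dplyr::bind_rows(entries[!crosses, ], first, second)
    entries <- dplyr::arrange(entries, .data$child_id, .data$date,
                              .data$start_min)
  }
  zero_len <- which(entries$end_min == entries$start_min)
  if (length(zero_len) > 0) {
    rlang::abort(paste0("zero-duration entry at row(s) ",
                        paste(zero_len, collapse = ", ")))
  }
  entries
}

# "HH:MM" (or "24:00") to minutes since midnight; NA when off the 5-min grid.
parse_clock <- function(x) {
  ok <- grepl("^([01]?[0-9]|2[0-4]):[0-5][0-9]$", x)
  h <- as.integer(sub(":.*", "", x))
  m <- as.integer(sub(".*:", "", x))
  mins <- h * 60L + m
  mins[!ok | mins %% 5L != 0L | mins > 1440L] <- NA_integer_
  mins
}

format_clock <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
}

#' @rdname parse_diary
#' @param entries Tibble of diary entries (internal representation).
#' @export
write_diary_json <- function(entries, path) {
  out <- diary_external(entries)
  jsonlite::write_json(out, path, auto_unbox = FALSE, dataframe = "rows",
                       pretty = FALSE)
  invisible(path)
}

#' @rdname parse_diary
#' @export
write_diary_csv <- function(entries, path) {
  readr::write_csv(diary_external(entries), path)
  invisible(path)
}

diary_external <- function(entries) {
  tibble::tibble(
    child_id = entries$child_id,
    date = format(entries$date, "%Y-%m-%d"),
    category = entries$category,
    start = format_clock(entries$start_min),
    end = format_clock(entries$end_min %% 1440L),
    intensity = entries$intensity,
    posture = entries$posture
  )
}

#' @rdname parse_diary
#' @param profiles Tibble of child profiles.
#' @export
write_profiles_csv <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname parse_diary
#' @export
read_profiles_csv <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      child_id = "c", sex = "c", birth_date = readr::col_date(),
      age_group = "c", .default = "l"
    )
  )
}

#' Validate parsed diary entries
#'
#' Checks the structural invariants of a set of entries: clock times on the
#' 5-min grid, durations of at least 5 min, and no overlapping intervals
#' within a child-day (entries may share an endpoint). Overlaps are
#' reported, not repaired: silent truncation could bias daily totals.
#'
#' @param entries Tibble of diary entries.
#' @return A tibble of violations with columns `child_id`, `date`, `rule`,
#'   `detail`; zero rows when the entries are clean.
#' @export
validate_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  viol <- list()
  off_grid <- entries$start_min %% 5L != 0L | entries$end_min %% 5L != 0L
  if (any(off_grid)) {
    viol$grid <- tibble::tibble(
      child_id = entries$child_id[off_grid],
      date = entries$date[off_grid],
      rule = "off_grid",
      detail = paste0(format_clock(entries$start_min[off_grid]), "-",
                      format_clock(entries$end_min[off_grid]))
    )
  }
  short <- entries$end_min - entries$start_min < 5L
  if (any(short)) {
    viol$short <- tibble::tibble(
      child_id = entries$child_id[short],
      date = entries$date[short],
      rule = "too_short",
      detail = paste0("duration ",
                      entries$end_min[short] - entries$start_min[short],
                      " min")
    )
  }
  overlaps <- entries |>
    dplyr::arrange(.data$child_id, .data$date, .data$start_min) |>
    dplyr::group_by(.data$child_id, .data$date) |>
    dplyr::filter(dplyr::lead(.data$start_min) < .data$end_min) |>
    dplyr::ungroup()
  if (nrow(overlaps) > 0) {
    viol$overlap <- tibble::tibble(
      child_id = overlaps$child_id,
      date = overlaps$date,
      rule = "overlap",
      detail = paste0("entry starting ", format_clock(overlaps$start_min),
                      " overlaps the next entry")
    )
  }
  out <- dplyr::bind_rows(viol)
  if (nrow(out) == 0) {
    out <- tibble::tibble(child_id = character(0),
                          date = as.Date(character(0)),
                          rule = character(0), detail = character(0))
  }
  out
}
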