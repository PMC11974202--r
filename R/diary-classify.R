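#' Classify diary entries into physical activity, sedentary behavior or sleep
#'
#' Applies the developmentally-adapted classification rules mapping each
#' activity category -- together with the intensity and posture follow-ups,
#' the child's age group and achieved motor milestones -- onto one of the
#' 24-h movement behaviors `"PA"`, `"SB"` or `"sleep"`. The three
#' descriptive categories ("other activity", "I don't know", "my child was
#' with someone else") classify as `"excluded"`.
#'
#' The rules in brief: personal care, eating/drinking and passive transport
#' are always SB; sleeping is sleep; passive screen use (watching/calm/
#' unknown intensity) is SB while active screen use is PA (defined for
#' children older than 6 months); active transport is PA (defined once the
#' child walks without support or is older than 2 years); active play is PA
#' in every posture; sitting/lying calmly and calm play (or play of unknown
#' intensity) are SB except for postures demanding postural control at the
#' child's stage: lying on the tummy (0-1 y), sitting without support
#' (0-1 y, milestone achieved) and standing without support (6 m-2 y,
#' milestone achieved) are PA.
#'
#' A missing posture where one is required falls back to the category's
#' "I don't know" posture row. Combinations outside the defined rule set
#' (e.g. active transport for a pre-walking 1-year-old, a posture offered
#' only to another age group) return `NA` so that no entry is silently
#' miscounted.
#'
#' @param entries Data frame of diary entries with columns `child_id`,
#'   `category`, `intensity`, `posture`.
#' @param profiles Data frame of child profiles with columns `child_id`,
#'   `age_group`, and logical milestone columns (see [milestone_names]).
#' @return `entries` as a tibble with a `behavior` column added
#'   (`"PA"`, `"SB"`, `"sleep"`, `"excluded"`, or `NA` if undefined).
#' @examples
#' prof <- tibble::tibble(child_id = "c1", age_group = "0-6m",
#'   roll_back_to_belly = FALSE, roll_belly_to_back = FALSE,
#'   sit_without_support = FALSE, crawl = FALSE,
#'   stand_without_support = FALSE, walk_without_support = FALSE)
#' ent <- tibble::tibble(child_id = "c1", category = "sitting/lying calmly",
#'   intensity = "n/a", posture = "lying on tummy")
#' classify_behavior(ent, prof)$behavior
#' @export
classify_behavior <- function(entries, profiles) {
  stopifnot(is.data.frame(entries), is.data.frame(profiles))
  need <- c("child_id", "age_group", milestone_names)
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("profiles is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  joined <- dplyr::left_join(
    tibble::as_tibble(entries),
    dplyr::select(profiles, dplyr::all_of(need)),
    by = "child_id"
  )
  if (anyNA(joined$age_group)) {
    rlang::abort("some entries have no matching child profile")
  }
  out <- tibble::as_tibble(entries)
  out$behavior <- classify_behavior_vec(
    category = joined$category,
    intensity = joined$intensity %||% rep("n/a", nrow(joined)),
    posture = joined$posture %||% rep("n/a", nrow(joined)),
    age_group = joined$age_group,
    sit_milestone = joined$sit_without_support,
    stand_milestone = joined$stand_without_support,
    walk_milestone = joined$walk_without_support
  )
  out
}

# Vectorized rule core. Age-band predicates follow the rule table's bands:
# "0-1 year" = {0-6m, 6-12m}; "> 1 year" = {1-2y, 2-3y, 3-4y};
# "< 2 years" = {0-6m, 6-12m, 1-2y}; "> 2 years" = {2-3y, 3-4y};
# "6 months-2 years" = {6-12m, 1-2y}.
classify_behavior_vec <- function(category, intensity, posture, age_group,
                                  sit_milestone, stand_milestone,
                                  walk_milestone) {
  bad <- !category %in% diary_categories
  if (any(bad)) {
    rlang::abort(paste0("unknown activity category: ",
                        paste(unique(category[bad]), collapse = ", ")))
  }
  intensity[is.na(intensity)] <- "n/a"
  posture[is.na(posture) | posture == "n/a"] <- "I don't know"

  under1 <- age_group %in% c("0-6m", "6-12m")
  over1 <- age_group %in% c("1-2y", "2-3y", "3-4y")
  under2 <- age_group %in% c("0-6m", "6-12m", "1-2y")
  over2 <- age_group %in% c("2-3y", "3-4y")
  m6to2 <- age_group %in% c("6-12m", "1-2y")
  over6m <- age_group != "0-6m"

  # Shared posture rules for the calm categories (sitting/lying calmly and
  # calm / unknown-intensity play). Standing postures exist only for play.
  calm_posture <- function(allow_standing) {
    dplyr::case_when(
      posture %in% c("changing posture", "I don't know") ~ "SB",
      under1 & posture == "being carried" ~ "SB",
      under1 & posture == "lying on tummy" ~ "PA",
      under1 & posture %in% c("lying on back", "lying on side") ~ "SB",
      under1 & posture == "sitting with support" ~ "SB",
      under1 & posture == "sitting without support" & sit_milestone ~ "PA",
      over1 & posture %in% c("lying", "sitting") ~ "SB",
      allow_standing & under2 & posture == "standing with support" ~ "SB",
      allow_standing & m6to2 & posture == "standing without support" &
        stand_milestone ~ "PA",
      allow_standing & over2 & posture == "standing" ~ "SB",
      TRUE ~ NA_character_
    )
  }

  dplyr::case_when(
    category %in% excluded_categories ~ "excluded",
    category == "sleeping" ~ "sleep",
    category %in% c("personal care", "eating/drinking",
                    "passive transport") ~ "SB",
    category == "screen use" & intensity == "active" & over6m ~ "PA",
    category == "screen use" & intensity == "active" ~ NA_character_,
    category == "screen use" ~ "SB",
    category == "active transport" & (over2 | walk_milestone) ~ "PA",
    category == "active transport" ~ NA_character_,
    category == "playing" & intensity == "active" &
      posture %in% diary_postures ~ "PA",
    category == "playing" ~ calm_posture(TRUE),
    category == "sitting/lying calmly" ~ calm_posture(FALSE),
    TRUE ~ NA_character_
  )
}

#' Enumerate the defined classification rule combinations
#'
#' Expands the full cross-product of category, intensity, posture, age
#' group and relevant milestone states that the classification rule table
#' defines, together with the resulting behavior label. Useful for
#' exhaustiveness checks: every row is a defined combination and carries
#' exactly one label.
#'
#' @return A tibble with columns `category`, `intensity`, `posture`,
#'   `age_group`, `sit_without_support`, `stand_without_support`,
#'   `walk_without_support`, `behavior`.
#' @export
classification_rules <- function() {
  grid <- tidyr::expand_grid(
    category = setdiff(diary_categories, character(0)),
    intensity = diary_intensities,
    posture = diary_postures,
    age_group = age_groups,
    sit_without_support = c(FALSE, TRUE),
    stand_without_support = c(FALSE, TRUE),
    walk_without_support = c(FALSE, TRUE)
  )
  # Intensity applies only to playing and screen use; posture only to
  # sitting/lying calmly and playing. Restrict to the app's question flow.
  grid <- dplyr::filter(
    grid,
    (.data$category %in% c("playing", "screen use")) ==
      (.data$intensity != "n/a"),
    !(.data$category == "screen use" & .data$intensity == "unknown") |
      .data$intensity %in% c("watching", "calm", "unknown"),
    (.data$category %in% c("sitting/lying calmly", "playing")) ==
      (.data$posture != "n/a")
  )
  grid$behavior <- classify_behavior_vec(
    grid$category, grid$intensity, grid$posture, grid$age_group,
    grid$sit_without_support, grid$stand_without_support,
    grid$walk_without_support
  )
  dplyr::filter(grid, !is.na(.data$behavior))
}
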