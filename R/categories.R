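#' Diary vocabulary: activity categories, intensities, postures, age groups
#'
#' The diary records one row per reported activity. Eleven activity
#' categories are available to parents; three of them ("other activity",
#' "I don't know", "my child was with someone else") are descriptive only
#' and are excluded from behavior analyses. Follow-up questions record the
#' intensity (for playing and screen use) and posture (for sitting/lying
#' calmly and playing) of the activity.
#'
#' @format Character vectors of the closed vocabularies.
#' @name diary_vocabulary
NULL

#' @rdname diary_vocabulary
#' @export
diary_categories <- c(
  "personal care", "eating/drinking", "active transport",
  "passive transport", "playing", "screen use", "sitting/lying calmly",
  "sleeping", "other activity", "I don't know",
  "my child was with someone else"
)

#' @rdname diary_vocabulary
#' @export
excluded_categories <- c(
  "other activity", "I don't know", "my child was with someone else"
)

#' @rdname diary_vocabulary
#' @export
diary_intensities <- c("active", "calm", "watching", "unknown", "n/a")

#' @rdname diary_vocabulary
#' @export
diary_postures <- c(
  "being carried", "lying on tummy", "lying on back", "lying on side",
  "sitting with support", "sitting without support", "lying", "sitting",
  "standing with support", "standing without support", "standing",
  "changing posture", "I don't know", "n/a"
)

#' @rdname diary_vocabulary
#' @export
age_groups <- c("0-6m", "6-12m", "1-2y", "2-3y", "3-4y")

#' @rdname diary_vocabulary
#' @export
milestone_names <- c(
  "roll_back_to_belly", "roll_belly_to_back", "sit_without_support",
  "crawl", "stand_without_support", "walk_without_support"
)

# The 11 analysis groupings used in hypothesis testing: sleep, seven
# predominantly-sedentary category groupings and three predominantly-active
# ones. "playing" and "screen use" split by the intensity follow-up.
#' @rdname diary_vocabulary
#' @export
sb_activity_groups <- c(
  "sitting/lying", "personal care", "eating/drinking", "passive transport",
  "passive screen use", "calm play", "play unknown intensity"
)

#' @rdname diary_vocabulary
#' @export
pa_activity_groups <- c("active play", "active transport", "active screen use")

#' Map diary category and intensity to the analysis activity grouping
#'
#' Collapses the diary's category x intensity vocabulary onto the eleven
#' groupings compared in hypothesis testing: "sleeping", seven sedentary
#' groupings and three active groupings. Excluded categories map to `NA`.
#'
#' @param category Character vector of diary categories.
#' @param intensity Character vector of reported intensities (`"n/a"` where
#'   the category has no intensity follow-up).
#' @return Character vector of activity groupings (`NA` for the three
#'   excluded categories).
#' @examples
#' activity_group("playing", "active")
#' activity_group("screen use", "watching")
#' @export
activity_group <- function(category, intensity = "n/a") {
  n <- max(length(category), length(intensity))
  category <- rep_len(category, n)
  intensity <- rep_len(intensity, n)
  dplyr::case_when(
    category %in% excluded_categories ~ NA_character_,
    category == "sleeping" ~ "sleeping",
    category == "sitting/lying calmly" ~ "sitting/lying",
    category == "personal care" ~ "personal care",
    category == "eating/drinking" ~ "eating/drinking",
    category == "passive transport" ~ "passive transport",
    category == "active transport" ~ "active transport",
    category == "playing" & intensity == "active" ~ "active play",
    category == "playing" & intensity == "calm" ~ "calm play",
    category == "playing" ~ "play unknown intensity",
    category == "screen use" & intensity == "active" ~ "active screen use",
    category == "screen use" ~ "passive screen use",
    TRUE ~ NA_character_
  )
}
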