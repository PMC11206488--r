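#' Apply survey eligibility rules
#'
#' Retains respondents aged 2 years or older who were not breastfeeding.
#' A missing age or breastfeeding flag is an error: eligibility cannot be
#' decided silently.
#'
#' @param respondents Tibble with columns `respondent_id`, `age_years`,
#'   `breastfeeding` (logical), `survey_weight` and replicate-weight
#'   columns `replicate_weight_1` .. `replicate_weight_B`.
#' @return The eligible subset.
#' @export
filter_sample <- function(respondents) {
  if (anyNA(respondents$age_years)) {
    stop("age_years is missing for respondent(s) ",
         paste(utils::head(respondents$respondent_id[is.na(respondents$age_years)], 5),
               collapse = ", "),
         "; cannot decide eligibility", call. = FALSE)
  }
  if (anyNA(respondents$breastfeeding)) {
    stop("breastfeeding flag is missing for some respondents", call. = FALSE)
  }
  respondents[respondents$age_years >= 2 & !respondents$breastfeeding, ,
              drop = FALSE]
}

#' Portions consumed
#'
#' A portion is the weight of food consumed divided by the food's
#' reference amount (its standard serving mass).
#'
#' @param grams_consumed Weight of food consumed (g), positive.
#' @param reference_amount_g Reference amount of the food (g), positive.
#' @return Numeric vector of portions.
#' @export
portion <- function(grams_consumed, reference_amount_g) {
  if (any(!is.finite(reference_amount_g) | reference_amount_g <= 0)) {
    stop("reference_amount_g must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(grams_consumed) | grams_consumed <= 0)) {
    stop("grams_consumed must be positive and finite", call. = FALSE)
  }
  grams_consumed / reference_amount_g
}

#' Dietary Ofcom score of one recall
#'
#' The portion-weighted mean of per-food Ofcom scores over all foods in a
#' recall: `sum(score * portion) / sum(portion)`. A one-item recall
#' scores exactly that food's score, and splitting a line into two lines
#' of half the grams leaves the result unchanged.
#'
#' @param scores Per-food Ofcom scores.
#' @param portions Portions from [portion()].
#' @return The dietary Ofcom score (scalar).
#' @export
dietary_ofcom_score <- function(scores, portions) {
  if (!length(scores)) {
    stop("dietary Ofcom score is undefined for an empty recall", call. = FALSE)
  }
  if (length(scores) != length(portions)) {
    stop("scores and portions must have equal length", call. = FALSE)
  }
  sum(scores * portions) / sum(portions)
}

#' Per-respondent daily intakes
#'
#' Aggregates effective recall lines (baseline or post-substitution) into
#' one row per respondent: daily calories, saturated fat, sodium and
#' total sugars (each `sum(grams * per-100 g value / 100)`), and the
#' dietary Ofcom score. Respondents appear only if they have at least one
#' recall line; empty recalls are undefined and handled upstream.
#'
#' @param effective_recalls Output of [baseline_recalls()] or
#'   `apply_scenario()$recalls`.
#' @return Tibble: `respondent_id`, `calories_kcal`, `satfat_g`,
#'   `sodium_mg`, `sugars_g`, `dietary_ofcom`, `n_items`.
#' @export
daily_intakes <- function(effective_recalls) {
  df <- effective_recalls
  if (anyNA(df$ofcom_score)) {
    stop("some recall lines are unscored; check food IDs", call. = FALSE)
  }
  df$portion <- portion(df$grams_consumed, df$reference_amount_g)
  dplyr::summarise(
    dplyr::group_by(df, .data$respondent_id),
    calories_kcal = sum(.data$grams_consumed * .data$energy_kcal / 100),
    satfat_g = sum(.data$grams_consumed * .data$satfat_g / 100),
    sodium_mg = sum(.data$grams_consumed * .data$sodium_mg / 100),
    sugars_g = sum(.data$grams_consumed * .data$sugars_g / 100),
    dietary_ofcom = sum(.data$ofcom_score * .data$portion) / sum(.data$portion),
    n_items = dplyr::n(),
    .groups = "drop"
  )
}
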