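# Build a food row whose Ofcom score is controlled through sodium (one
# point per 90 mg band, strict comparison) and, for negative scores,
# through fibre points. All other nutrients zero, MIN FVN.
mk_food <- function(id, category = "X", score = 0, kcal = 0, fibre = 0,
                    sugars = 0, sodium = NULL, share = NULL, ref = 100) {
  if (is.null(sodium)) {
    sodium <- if (score > 0) 90 * score + 1 else 0
    if (score < 0) fibre <- c(0.91, 1.91, 2.81, 3.71, 4.71)[-score]
  }
  row <- tibble::tibble(
    food_id = id, name = paste("food", id), category_code = category,
    category_name = paste("category", category),
    energy_kcal = kcal, satfat_g = 0, sugars_g = sugars,
    sodium_mg = sodium, fibre_g = fibre, protein_g = 0,
    fvn_level = "MIN", reference_amount_g = ref
  )
  if (!is.null(share)) row$market_share <- share
  row
}

mk_db <- function(rows, source = "generic") {
  score_foods(validate_food_db(dplyr::bind_rows(rows), source))
}

# minimal respondent table with constant-ish replicate weights
mk_respondents <- function(ids, B = 4, seed = 42) {
  set.seed(seed)
  n <- length(ids)
  w <- runif(n, 10, 100)
  rw <- matrix(w * rlnorm(n * B, -0.02, 0.2), n, B)
  colnames(rw) <- paste0("replicate_weight_", seq_len(B))
  dplyr::bind_cols(
    tibble::tibble(respondent_id = ids, age_years = 30,
                   breastfeeding = FALSE, survey_weight = w),
    tibble::as_tibble(rw)
  )
}

write_food_csv <- function(rows, path) {
  readr::write_csv(dplyr::bind_rows(rows), path, na = "")
  path
}
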