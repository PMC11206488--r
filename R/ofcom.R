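#' @keywords internal
"_PACKAGE"

#' Fruit/vegetable/nut assumption levels
#'
#' Food composition databases rarely carry ingredient lists, so the FVN
#' percentage required by the Ofcom model cannot be computed and must be
#' assumed per food. Five assumption levels are supported:
#' `MIN` (content at or below 40%, 0 points), `LOW_MID` (just above 40%,
#' 1 point), `HIGH_MID` (just above 60%, 2 points), `MAX` (above 80%,
#' the top point level) and `AVERAGED_MID`, for foods of ambiguous
#' composition, whose final score is the mean of the two complete scores
#' computed at `LOW_MID` and `HIGH_MID`.
#'
#' @format A character vector of the five level names.
#' @export
fvn_levels <- c("MIN", "LOW_MID", "HIGH_MID", "MAX", "AVERAGED_MID")

check_fvn_level <- function(fvn_level, allow_averaged = TRUE) {
  allowed <- if (allow_averaged) fvn_levels else setdiff(fvn_levels, "AVERAGED_MID")
  bad <- is.na(fvn_level) | !(fvn_level %in% allowed)
  if (any(bad)) {
    if (!allow_averaged && any(fvn_level[bad] %in% "AVERAGED_MID", na.rm = TRUE)) {
      stop("AVERAGED_MID is resolved by averaging two complete scores; ",
           "it has no point value of its own", call. = FALSE)
    }
    stop("invalid fvn_level: ",
         paste(unique(fvn_level[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(fvn_level)
}

#' A-points of the Ofcom model
#'
#' Sums the four unfavourable component point scores (energy, saturated
#' fat, total sugars, sodium), each 0-10. Energy is supplied in kcal per
#' 100 g and converted to kJ before the threshold lookup. All comparisons
#' are strict: a value earns a point only when it exceeds the threshold.
#'
#' @param energy_kcal,satfat_g,sugars_g,sodium_mg Nutrient amounts per
#'   100 g of food (kcal, g, g, mg). Vectors are scored elementwise.
#' @param tables An `ofcom_tables` object, see [ofcom_point_tables()].
#' @return Integer vector of A-point totals in `[0, 40]`.
#' @export
a_points <- function(energy_kcal, satfat_g, sugars_g, sodium_mg,
                     tables = ofcom_point_tables()) {
  check_nonneg_finite(energy_kcal, "energy_kcal")
  check_nonneg_finite(satfat_g, "satfat_g")
  check_nonneg_finite(sugars_g, "sugars_g")
  check_nonneg_finite(sodium_mg, "sodium_mg")
  points_from_thresholds(energy_kcal * tables$kcal_to_kj, tables$energy_kj) +
    points_from_thresholds(satfat_g, tables$satfat_g) +
    points_from_thresholds(sugars_g, tables$sugars_g) +
    points_from_thresholds(sodium_mg, tables$sodium_mg)
}

#' Fruit/vegetable/nut points for an assumption level
#'
#' @param fvn_level Character vector of levels among `MIN`, `LOW_MID`,
#'   `HIGH_MID`, `MAX`. `AVERAGED_MID` is rejected: averaging happens at
#'   the level of complete scores, never of FVN points, because the
#'   protein-cap rule is nonlinear in FVN points.
#' @inheritParams a_points
#' @return Numeric vector of FVN points (0, 1, 2 or the maximum level).
#' @export
fvn_points <- function(fvn_level, tables = ofcom_point_tables()) {
  check_fvn_level(fvn_level, allow_averaged = FALSE)
  unname(tables$fvn_points[fvn_level])
}

#' C-points of the Ofcom model
#'
#' Sums the favourable component points: FVN, fibre and protein. Protein
#' points are withheld (the "protein cap") when the food's A-points reach
#' `tables$cap_a_points` and its FVN points are below the maximum level.
#'
#' @param fibre_g,protein_g Nutrient amounts per 100 g.
#' @param fvn_level Single-level FVN assumption (no `AVERAGED_MID`).
#' @param a Integer vector of A-points, as returned by [a_points()].
#' @inheritParams a_points
#' @return A tibble with columns `c_points`, `protein_capped`,
#'   `fvn_points`, `fibre_points`, `protein_points`.
#' @export
c_points <- function(fibre_g, protein_g, fvn_level, a,
                     tables = ofcom_point_tables()) {
  check_nonneg_finite(fibre_g, "fibre_g")
  check_nonneg_finite(protein_g, "protein_g")
  check_fvn_level(fvn_level, allow_averaged = FALSE)
  fvn <- unname(tables$fvn_points[fvn_level])
  fibre <- points_from_thresholds(fibre_g, tables$fibre)
  protein <- points_from_thresholds(protein_g, tables$protein_g)
  capped <- a >= tables$cap_a_points & fvn < max(tables$fvn_points)
  tibble::tibble(
    c_points = fvn + fibre + ifelse(capped, 0L, protein),
    protein_capped = capped,
    fvn_points = fvn,
    fibre_points = fibre,
    protein_points = protein
  )
}

#' Ofcom nutrient-profiling score
#'
#' Computes the total Ofcom score, A-points minus counted C-points, per
#' 100 g of food. Lower scores indicate more favourable nutrient
#' profiles. For `AVERAGED_MID` foods, two complete scores are computed
#' at the `LOW_MID` and `HIGH_MID` assumption levels (the protein cap
#' re-evaluated independently at each) and averaged, so totals may be
#' half-integers; all other totals are integers.
#'
#' @inheritParams a_points
#' @inheritParams c_points
#' @param fvn_level Character vector of FVN assumption levels; any of the
#'   five levels in [fvn_levels].
#' @return A tibble with columns `a_points`, `c_points` (half-integer
#'   under averaging), `protein_capped` (`TRUE` if the cap applied at
#'   either averaged level) and `total_score`.
#' @examples
#' # plain brewed coffee: nothing in it, minimum FVN assumption
#' ofcom_score(0, 0, 0, 0, 0, 0, "MIN")$total_score
#' @export
ofcom_score <- function(energy_kcal, satfat_g, sugars_g, sodium_mg,
                        fibre_g, protein_g, fvn_level,
                        tables = ofcom_point_tables()) {
  check_fvn_level(fvn_level)
  n <- max(lengths(list(energy_kcal, satfat_g, sugars_g, sodium_mg,
                        fibre_g, protein_g, fvn_level)))
  fvn_level <- rep_len(fvn_level, n)
  a <- rep_len(a_points(energy_kcal, satfat_g, sugars_g, sodium_mg, tables), n)
  fibre_g <- rep_len(fibre_g, n)
  protein_g <- rep_len(protein_g, n)

  averaged <- fvn_level == "AVERAGED_MID"
  lv_lo <- ifelse(averaged, "LOW_MID", fvn_level)
  lv_hi <- ifelse(averaged, "HIGH_MID", fvn_level)
  c_lo <- c_points(fibre_g, protein_g, lv_lo, a, tables)
  c_hi <- c_points(fibre_g, protein_g, lv_hi, a, tables)

  tibble::tibble(
    a_points = a,
    c_points = (c_lo$c_points + c_hi$c_points) / 2,
    protein_capped = c_lo$protein_capped | c_hi$protein_capped,
    total_score = ((a - c_lo$c_points) + (a - c_hi$c_points)) / 2
  )
}

#' Score every food in a database
#'
#' Adds Ofcom scoring columns to a food table. All nutrient fields must
#' be complete; impute first with [impute_missing_nutrients()].
#'
#' @param db A food table, see [load_food_table()].
#' @inheritParams a_points
#' @return `db` with columns `a_points`, `c_points`, `protein_capped`
#'   and `ofcom_score` appended.
#' @export
score_foods <- function(db, tables = ofcom_point_tables()) {
  miss <- vapply(db[nutrient_columns], anyNA, logical(1))
  if (any(miss)) {
    stop("cannot score a database with missing nutrients (",
         paste(names(miss)[miss], collapse = ", "),
         "); run impute_missing_nutrients() first", call. = FALSE)
  }
  sc <- ofcom_score(db$energy_kcal, db$satfat_g, db$sugars_g, db$sodium_mg,
                    db$fibre_g, db$protein_g, db$fvn_level, tables)
  db$a_points <- sc$a_points
  db$c_points <- sc$c_points
  db$protein_capped <- sc$protein_capped
  db$ofcom_score <- sc$total_score
  db
}
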