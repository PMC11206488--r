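#' Load and validate a branded-to-generic match table
#'
#' The cross-walk between a branded product database and the generic
#' database it substitutes into. Each branded product maps to at most one
#' generic food; a generic food may have many branded matches. Matching
#' itself (name similarity, nutritional distance, manual review) happens
#' upstream; this function only ingests its output. Pairs that span food
#' categories are rejected, because substitution is defined within a
#' category.
#'
#' @param x Path to a delimited file with columns `generic_food_id` and
#'   `branded_food_id`, or a data frame with those columns.
#' @param generic_db,branded_db Validated food tables the IDs must
#'   resolve against.
#' @return A tibble with columns `generic_food_id`, `branded_food_id`,
#'   `category_code`.
#' @export
load_matches <- function(x, generic_db, branded_db) {
  if (is.character(x)) {
    reader <- if (grepl("\\.csv$", x, ignore.case = TRUE)) {
      readr::read_csv
    } else {
      readr::read_tsv
    }
    x <- reader(x, col_types = readr::cols(.default = "c"), progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c("generic_food_id", "branded_food_id"), names(x))
  if (length(missing_cols)) {
    stop("match table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown_g <- setdiff(x$generic_food_id, generic_db$food_id)
  if (length(unknown_g)) {
    stop("match table references unknown generic food(s): ",
         paste(utils::head(unknown_g, 5), collapse = ", "), call. = FALSE)
  }
  unknown_b <- setdiff(x$branded_food_id, branded_db$food_id)
  if (length(unknown_b)) {
    stop("match table references unknown branded food(s): ",
         paste(utils::head(unknown_b, 5), collapse = ", "), call. = FALSE)
  }
  dup <- x$branded_food_id[duplicated(x$branded_food_id)]
  if (length(dup)) {
    stop("branded food(s) matched to more than one generic food: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  cat_g <- generic_db$category_code[match(x$generic_food_id, generic_db$food_id)]
  cat_b <- branded_db$category_code[match(x$branded_food_id, branded_db$food_id)]
  cross <- which(cat_g != cat_b)
  if (length(cross)) {
    i <- cross[1]
    stop("cross-category match pair rejected: ", x$generic_food_id[i],
         " (", cat_g[i], ") / ", x$branded_food_id[i], " (", cat_b[i], ")",
         call. = FALSE)
  }
  x$category_code <- cat_g
  x
}

#' Match coverage of consumed foods
#'
#' Reports the fraction of distinct foods reported as consumed that have
#' at least one branded match, and the fraction with at least one match
#' whose Ofcom score is strictly lower than the consumed food's own
#' score. Both fractions are computed over distinct food IDs, so
#' duplicated recall lines do not affect them.
#'
#' @param recalls A recall table with a `food_id` column (generic IDs).
#' @param matches A validated match table, see [load_matches()].
#' @param generic_db,branded_db Scored food tables (see [score_foods()]).
#' @return A one-row tibble: `n_consumed`, `matched_fraction`,
#'   `lower_fraction`.
#' @export
match_coverage <- function(recalls, matches, generic_db, branded_db) {
  for (db in list(generic_db, branded_db)) {
    if (!"ofcom_score" %in% names(db)) {
      stop("databases must be scored with score_foods() before computing coverage",
           call. = FALSE)
    }
  }
  consumed <- unique(recalls$food_id)
  unknown <- setdiff(consumed, generic_db$food_id)
  if (length(unknown)) {
    stop("recalls reference food(s) absent from the generic database: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  matched <- intersect(consumed, matches$generic_food_id)
  score_g <- generic_db$ofcom_score[match(matches$generic_food_id, generic_db$food_id)]
  score_b <- branded_db$ofcom_score[match(matches$branded_food_id, branded_db$food_id)]
  lower_ids <- unique(matches$generic_food_id[score_b < score_g])
  tibble::tibble(
    n_consumed = length(consumed),
    matched_fraction = length(matched) / length(consumed),
    lower_fraction = length(intersect(consumed, lower_ids)) / length(consumed)
  )
}
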