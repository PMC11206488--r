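#' @importFrom rlang .data
NULL

#' Required columns of a food table
#'
#' Food tables are delimited files with one row per food and per-100 g
#' nutrient columns. `market_share` is additionally allowed (and only
#' allowed) for branded databases.
#'
#' @format Character vector of column names.
#' @export
required_food_columns <- c(
  "food_id", "name", "category_code", "category_name",
  "energy_kcal", "satfat_g", "sugars_g", "sodium_mg",
  "fibre_g", "protein_g", "fvn_level", "reference_amount_g"
)

#' Nutrient columns subject to imputation
#' @format Character vector of column names.
#' @export
nutrient_columns <- c(
  "energy_kcal", "satfat_g", "sugars_g", "sodium_mg", "fibre_g", "protein_g"
)

#' Validate an in-memory food table
#'
#' Checks schema, ID uniqueness, nutrient sign, reference amounts and FVN
#' levels. Missing nutrient cells (`NA`) are preserved: missingness is
#' meaningful (it triggers imputation) and is never coerced to zero.
#'
#' @param df A data frame of foods.
#' @param source `"generic"` for an aggregated national database,
#'   `"branded"` for an individually branded product database (which may
#'   carry `market_share`).
#' @return A validated tibble with a `source` column.
#' @export
validate_food_db <- function(df, source = c("generic", "branded")) {
  source <- match.arg(source)
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(required_food_columns, names(df))
  if (length(missing_cols)) {
    stop("food table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("market_share" %in% names(df) && source != "branded") {
    stop("market_share is only meaningful for a branded database", call. = FALSE)
  }
  dup <- df$food_id[duplicated(df$food_id)]
  if (length(dup)) {
    stop("duplicate food_id in ", source, " table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (col in nutrient_columns) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | !is.finite(df[[col]])))
    if (length(bad)) {
      stop("negative or non-finite ", col, " at row ", bad[1],
           " (food_id ", df$food_id[bad[1]], ")", call. = FALSE)
    }
  }
  if (anyNA(df$reference_amount_g) || any(df$reference_amount_g <= 0)) {
    stop("reference_amount_g must be present and positive for every food",
         call. = FALSE)
  }
  check_fvn_level(df$fvn_level)
  df$source <- source
  df
}

#' Load a food-composition table from a delimited file
#'
#' Reads a CSV (`.csv`) or TSV (`.tsv`/`.txt`) food table and validates
#' it. Blank nutrient cells are kept as explicit missing values.
#'
#' @param path Path to the delimited file.
#' @inheritParams validate_food_db
#' @return A validated food tibble.
#' @export
load_food_table <- function(path, source = c("generic", "branded")) {
  source <- match.arg(source)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(
    path,
    col_types = readr::cols(
      food_id = "c", name = "c", category_code = "c",
      category_name = "c", fvn_level = "c", .default = "d"
    ),
    progress = FALSE
  )
  validate_food_db(df, source)
}

#' Foods in one category
#'
#' @param db A food table.
#' @param code A category code (e.g. `"51B"`).
#' @return The subset of `db` in that category.
#' @export
foods_in_category <- function(db, code) {
  db[db$category_code == code, , drop = FALSE]
}

#' Impute missing nutrients with category medians
#'
#' Each missing nutrient cell is replaced by the median of the
#' non-missing values of that nutrient among foods of the same category.
#' When a category has no non-missing donor for a nutrient, the
#' whole-database median is used instead and a warning is raised. Medians
#' of an even donor count are the mean of the two central values.
#' Non-missing cells are never altered, so the operation is idempotent.
#'
#' @param db A validated food table.
#' @return A list with elements `db` (the completed table) and `log`, a
#'   tibble of one row per imputed cell: `food_id`, `nutrient`, `value`,
#'   `donor_count`, `scope` (`"category"` or `"global"`).
#' @export
impute_missing_nutrients <- function(db) {
  log_rows <- list()
  for (col in nutrient_columns) {
    x <- db[[col]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    if (all(is.na(x))) {
      stop("nutrient ", col, " is missing for every food; cannot impute",
           call. = FALSE)
    }
    global_median <- stats::median(x, na.rm = TRUE)
    for (i in miss) {
      same_cat <- db$category_code == db$category_code[i]
      donors <- x[same_cat & !is.na(x)]
      if (length(donors)) {
        value <- stats::median(donors)
        scope <- "category"
        n_donors <- length(donors)
      } else {
        value <- global_median
        scope <- "global"
        n_donors <- sum(!is.na(x))
        warning("no donors for ", col, " in category ", db$category_code[i],
                "; using whole-database median for food ", db$food_id[i],
                call. = FALSE)
      }
      db[[col]][i] <- value
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        food_id = db$food_id[i], nutrient = col, value = value,
        donor_count = n_donors, scope = scope
      )
    }
  }
  log <- if (length(log_rows)) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(
      food_id = character(), nutrient = character(), value = double(),
      donor_count = integer(), scope = character()
    )
  }
  list(db = db, log = log)
}
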