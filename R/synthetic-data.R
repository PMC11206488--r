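#' Configuration of the synthetic world generator
#'
#' Defines the statistical structure of a generated "study world": a
#' category-structured generic food database, a branded database matched
#' into it, multi-item 24 h recalls and a survey design with bootstrap
#' replicate weights. Match-coverage targets default to the coverage
#' observed in the motivating survey data: about 8% of distinct consumed
#' foods have a branded match and about 2.9% have a match with a strictly
#' lower Ofcom score.
#'
#' @param seed Integer seed; all randomness in [generate_world()] flows
#'   from it.
#' @param n_respondents Number of survey respondents.
#' @param n_categories Number of food categories.
#' @param foods_per_category Generic foods per category.
#' @param branded_match_fraction Target fraction of distinct consumed
#'   foods with at least one branded match.
#' @param lower_score_match_fraction Target fraction with at least one
#'   strictly lower-scoring branded match (must not exceed
#'   `branded_match_fraction`).
#' @param items_min,items_max Range of recall lines per respondent.
#' @param B Number of bootstrap replicate weight vectors.
#' @param planted_sodium_delta Optional sodium reduction (mg per 100 g).
#'   When set, every lower-scoring branded match is an exact copy of its
#'   generic parent with sodium reduced by this amount (and the parents'
#'   sodium is drawn high enough that the reduction always lowers the
#'   score), enabling analytic parameter-recovery checks.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_respondents = 2000L,
                         n_categories = 30L,
                         foods_per_category = 20L,
                         branded_match_fraction = 0.08,
                         lower_score_match_fraction = 0.029,
                         items_min = 5L,
                         items_max = 15L,
                         B = 50L,
                         planted_sodium_delta = NULL) {
  if (lower_score_match_fraction < 0 ||
      branded_match_fraction > 1 ||
      lower_score_match_fraction > branded_match_fraction) {
    stop("need 0 <= lower_score_match_fraction <= branded_match_fraction <= 1",
         call. = FALSE)
  }
  if (items_min < 1 || items_max < items_min) {
    stop("invalid items_per_recall range", call. = FALSE)
  }
  if (!is.null(planted_sodium_delta) && planted_sodium_delta < 90) {
    # sodium points change every 90 mg; a smaller planted reduction could
    # leave the score unchanged and the food unsubstituted
    stop("planted_sodium_delta must be at least 90 mg/100 g", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_respondents = as.integer(n_respondents),
      n_categories = as.integer(n_categories),
      foods_per_category = as.integer(foods_per_category),
      branded_match_fraction = branded_match_fraction,
      lower_score_match_fraction = lower_score_match_fraction,
      items_min = as.integer(items_min),
      items_max = as.integer(items_max),
      B = as.integer(B),
      planted_sodium_delta = planted_sodium_delta
    ),
    class = "synth_config"
  )
}

# per-100 g nutrient archetypes (lognormal medians and sd on the log
# scale), chosen so synthetic daily intakes land near 1800 kcal/day
synth_archetypes <- list(
  produce  = list(energy = 50,  satfat = 0.1,  sugars = 8,  sodium = 10,
                  fibre = 2.5, protein = 1.5, fvn = "MAX",
                  ref = c(80, 150)),
  beverage = list(energy = 20,  satfat = 0.05, sugars = 5,  sodium = 15,
                  fibre = 0.1, protein = 0.5, fvn = "MIN",
                  ref = c(200, 260)),
  packaged = list(energy = 350, satfat = 5,    sugars = 15, sodium = 450,
                  fibre = 2,   protein = 6,   fvn = "AVERAGED_MID",
                  ref = c(30, 60)),
  staple   = list(energy = 250, satfat = 1,    sugars = 2,  sodium = 300,
                  fibre = 3,   protein = 8,   fvn = "LOW_MID",
                  ref = c(50, 100)),
  dairy    = list(energy = 150, satfat = 4,    sugars = 6,  sodium = 80,
                  fibre = 0.05, protein = 5,  fvn = "MIN",
                  ref = c(100, 250))
)

rln <- function(n, median, sdlog = 0.4) stats::rlnorm(n, log(median), sdlog)

# derive a strictly lower-scoring branded variant of a generic parent by
# progressively shrinking its A-nutrients; terminates because with all
# A-nutrients at zero the score is <= 0 and parents are chosen to score >= 1
make_lower_variant <- function(parent, tables) {
  out <- parent
  for (i in 1:10) {
    out$energy_kcal <- out$energy_kcal * 0.7
    out$satfat_g <- out$satfat_g * 0.6
    out$sugars_g <- out$sugars_g * 0.6
    out$sodium_mg <- out$sodium_mg * 0.6
    out$fibre_g <- out$fibre_g * 1.05 + 0.1
    s <- ofcom_score(out$energy_kcal, out$satfat_g, out$sugars_g,
                     out$sodium_mg, out$fibre_g, out$protein_g,
                     out$fvn_level, tables)$total_score
    if (s < parent$ofcom_score) return(out)
  }
  out$energy_kcal <- 0
  out$satfat_g <- 0
  out$sugars_g <- 0
  out$sodium_mg <- 0
  out
}

# derive a branded variant scoring no lower than its parent
make_nonlower_variant <- function(parent, tables) {
  out <- parent
  out$sodium_mg <- out$sodium_mg * stats::runif(1, 1.0, 1.3) + 20
  out$sugars_g <- out$sugars_g * stats::runif(1, 1.0, 1.2) + 1
  for (i in 1:30) {
    s <- ofcom_score(out$energy_kcal, out$satfat_g, out$sugars_g,
                     out$sodium_mg, out$fibre_g, out$protein_g,
                     out$fvn_level, tables)$total_score
    if (s >= parent$ofcom_score) return(out)
    out$sodium_mg <- out$sodium_mg * 1.4 + 60
    out$sugars_g <- out$sugars_g * 1.2 + 2
  }
  out
}

#' Generate a synthetic study world
#'
#' Deterministic given the config seed. Draws happen in a fixed,
#' documented order — categories, generic foods, respondents, recalls,
#' match planting, branded foods, weights — so a given seed always yields
#' the identical world. Branded products are built as perturbations of
#' the generic foods they match, and the matched / lower-scoring-match
#' fractions are planted directly on the realised set of distinct
#' consumed foods, so [match_coverage()] reproduces the configured
#' targets up to rounding.
#'
#' @param config A [synth_config()].
#' @return A list: `generic` and `branded` food tibbles, `matches`,
#'   `respondents`, `recalls`, plus bookkeeping vectors
#'   `planted_matched_ids` and `planted_lower_ids` and the `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tables <- ofcom_point_tables()

  # --- categories ------------------------------------------------------
  arch_names <- rep_len(names(synth_archetypes), config$n_categories)
  codes <- sprintf("C%02d", seq_len(config$n_categories))
  # give the first cereal-staple and the first two beverage categories the
  # codes that carry designated substitutes in the generic-optimistic
  # scenario, so the override path is exercised
  bev <- which(arch_names == "beverage")
  stp <- which(arch_names == "staple")
  if (length(stp) >= 1) codes[stp[1]] <- "01C"
  if (length(bev) >= 1) codes[bev[1]] <- "51A"
  if (length(bev) >= 2) codes[bev[2]] <- "51B"

  # --- generic foods ---------------------------------------------------
  n_foods <- config$n_categories * config$foods_per_category
  cat_idx <- rep(seq_len(config$n_categories), each = config$foods_per_category)
  gen_rows <- lapply(seq_len(config$n_categories), function(i) {
    a <- synth_archetypes[[arch_names[i]]]
    m <- config$foods_per_category
    tibble::tibble(
      category_code = codes[i],
      category_name = paste0(arch_names[i], " ", codes[i]),
      energy_kcal = rln(m, a$energy),
      satfat_g = rln(m, a$satfat, 0.6),
      sugars_g = rln(m, a$sugars, 0.6),
      sodium_mg = rln(m, a$sodium, 0.6),
      fibre_g = rln(m, a$fibre, 0.5),
      protein_g = rln(m, a$protein, 0.5),
      fvn_level = a$fvn,
      reference_amount_g = round(stats::runif(m, a$ref[1], a$ref[2]), 1)
    )
  })
  generic <- dplyr::bind_rows(gen_rows)
  generic <- dplyr::bind_cols(
    tibble::tibble(
      food_id = sprintf("G%04d", seq_len(n_foods)),
      name = sprintf("%s food %04d", arch_names[cat_idx], seq_len(n_foods))
    ),
    generic
  )
  generic <- validate_food_db(generic, "generic")

  # --- respondents -----------------------------------------------------
  n <- config$n_respondents
  age <- stats::runif(n, 2, 90)
  under2 <- stats::runif(n) < 0.02
  age[under2] <- stats::runif(sum(under2), 0.2, 1.9)
  breastfeeding <- stats::runif(n) < 0.01 & age >= 18
  w <- stats::rlnorm(n, log(50), 0.5)
  respondents <- tibble::tibble(
    respondent_id = sprintf("R%05d", seq_len(n)),
    age_years = round(age, 1),
    breastfeeding = breastfeeding,
    survey_weight = w
  )

  # --- recalls ---------------------------------------------------------
  k <- sample(config$items_min:config$items_max, n, replace = TRUE)
  rid <- rep(respondents$respondent_id, k)
  fid <- generic$food_id[sample.int(n_foods, sum(k), replace = TRUE)]
  grams <- generic$reference_amount_g[match(fid, generic$food_id)] *
    stats::rlnorm(sum(k), log(1.2), 0.4)
  recalls <- tibble::tibble(
    respondent_id = rid,
    food_id = fid,
    grams_consumed = round(grams, 1)
  )

  # --- match planting --------------------------------------------------
  scored <- score_foods(generic, tables)
  consumed <- unique(recalls$food_id)
  n_match <- round(config$branded_match_fraction * length(consumed))
  n_lower <- round(config$lower_score_match_fraction * length(consumed))
  planted <- if (!is.null(config$planted_sodium_delta)) {
    delta <- config$planted_sodium_delta
    lower_ids <- sample(consumed, n_lower)
    # redraw parents' sodium high enough that sodium - delta always drops
    # at least one 90 mg point threshold, guaranteeing a lower score
    i <- match(lower_ids, generic$food_id)
    generic$sodium_mg[i] <- round(stats::runif(n_lower, delta + 250, 900), 1)
    scored <- score_foods(generic, tables)
    lower_ids
  } else {
    eligible <- consumed[scored$ofcom_score[match(consumed, scored$food_id)] >= 1]
    sample(eligible, min(n_lower, length(eligible)))
  }
  other_ids <- sample(setdiff(consumed, planted), n_match - length(planted))

  # --- branded foods ---------------------------------------------------
  branded_rows <- list()
  match_rows <- list()
  next_id <- 1L
  add_branded <- function(variant, parent_id, share) {
    bid <- sprintf("B%04d", next_id)
    next_id <<- next_id + 1L
    variant$food_id <- bid
    variant$name <- paste0("brand of ", variant$name)
    variant$market_share <- share
    branded_rows[[length(branded_rows) + 1L]] <<- variant
    match_rows[[length(match_rows) + 1L]] <<- tibble::tibble(
      generic_food_id = parent_id, branded_food_id = bid
    )
  }
  for (id in planted) {
    parent <- scored[scored$food_id == id, , drop = FALSE]
    if (!is.null(config$planted_sodium_delta)) {
      v <- parent
      v$sodium_mg <- v$sodium_mg - config$planted_sodium_delta
      add_branded(v[, names(generic)], id, stats::runif(1, 0.2, 1))
    } else {
      n_low <- sample(1:2, 1)
      shares <- stats::runif(n_low + 1, 0.05, 1)
      for (j in seq_len(n_low)) {
        v <- make_lower_variant(parent, tables)
        add_branded(v[, names(generic)], id, shares[j])
      }
      v <- make_nonlower_variant(parent, tables)
      add_branded(v[, names(generic)], id, shares[n_low + 1])
    }
  }
  for (id in other_ids) {
    parent <- scored[scored$food_id == id, , drop = FALSE]
    for (j in seq_len(sample(1:2, 1))) {
      v <- make_nonlower_variant(parent, tables)
      add_branded(v[, names(generic)], id, stats::runif(1, 0.05, 1))
    }
  }
  branded <- if (length(branded_rows)) {
    validate_food_db(dplyr::bind_rows(branded_rows), "branded")
  } else {
    empty <- generic[0, ]
    empty$market_share <- numeric(0)
    validate_food_db(empty, "branded")
  }
  matches <- if (length(match_rows)) {
    dplyr::bind_rows(match_rows)
  } else {
    tibble::tibble(generic_food_id = character(), branded_food_id = character())
  }

  # --- replicate weights ----------------------------------------------
  mult <- matrix(stats::rlnorm(n * config$B, -0.125, 0.5), n, config$B)
  rw <- respondents$survey_weight * mult
  colnames(rw) <- paste0("replicate_weight_", seq_len(config$B))
  respondents <- dplyr::bind_cols(respondents, tibble::as_tibble(rw))

  list(
    generic = generic,
    branded = branded,
    matches = matches,
    respondents = respondents,
    recalls = recalls,
    planted_matched_ids = c(planted, other_ids),
    planted_lower_ids = planted,
    config = config
  )
}

#' Blank nutrient cells at random
#'
#' Independently blanks each nutrient cell with the given probability,
#' while guaranteeing that every (category, nutrient) combination keeps
#' at least one non-missing donor (a blanked cell is restored at random
#' in any group that would otherwise lose all donors), so category-median
#' imputation is always feasible.
#'
#' @param db A validated food table.
#' @param rate Blanking probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The table with `NA` holes punched in its nutrient columns.
#' @export
generate_missingness <- function(db, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) {
    stop("rate must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(db)
  for (col in nutrient_columns) {
    mask <- stats::runif(nrow(db)) < rate
    for (code in unique(db$category_code)) {
      grp <- which(db$category_code == code)
      if (all(mask[grp])) {
        keep <- grp[sample.int(length(grp), 1)]
        mask[keep] <- FALSE
      }
    }
    db[[col]][mask] <- NA_real_
  }
  db
}

#' Write a synthetic world to delimited files
#'
#' Writes the five files consumed by the pipeline: `generic_foods.csv`,
#' `branded_foods.csv`, `matches.csv`, `respondents.csv`, `recalls.csv`.
#'
#' @param world Output of [generate_world()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    generic_foods = file.path(dir, "generic_foods.csv"),
    branded_foods = file.path(dir, "branded_foods.csv"),
    matches = file.path(dir, "matches.csv"),
    respondents = file.path(dir, "respondents.csv"),
    recalls = file.path(dir, "recalls.csv")
  )
  drop_source <- function(df) df[, setdiff(names(df), "source"), drop = FALSE]
  readr::write_csv(drop_source(world$generic), paths[["generic_foods"]])
  readr::write_csv(drop_source(world$branded), paths[["branded_foods"]])
  readr::write_csv(world$matches[, c("generic_food_id", "branded_food_id")],
                   paths[["matches"]])
  readr::write_csv(world$respondents, paths[["respondents"]])
  readr::write_csv(world$recalls, paths[["recalls"]])
  invisible(paths)
}
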