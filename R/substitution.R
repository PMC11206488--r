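# ordering of FVN assumption levels by their implied point value,
# used when a composite inherits the most conservative constituent level
fvn_rank <- c(MIN = 0, LOW_MID = 1, AVERAGED_MID = 1.5, HIGH_MID = 2, MAX = 5)

#' Configure a substitution scenario
#'
#' Four scenarios are modelled. Scenarios 1A/1B substitute consumed foods
#' with branded products matched into the same category; Scenarios 2A/2B
#' substitute within the generic database itself. The "optimistic" A
#' variants use the lowest-scoring alternative, the "realistic" B
#' variants a lower-scoring one (for 2B, the next-lowest score below the
#' original's).
#'
#' @param scenario One of `"1A"`, `"1B"`, `"2A"`, `"2B"` (an `"S"` prefix
#'   is tolerated).
#' @param overrides Named character vector mapping category codes to a
#'   designated substitute `food_id`, used instead of the lowest-scoring
#'   food in those categories. The default `NULL` means: for Scenario 2A,
#'   compute [default_overrides()] for the cereal-grain, tea and coffee
#'   categories (`"01C"`, `"51A"`, `"51B"`) if present in the database —
#'   categories where the lowest-scoring food is unrepresentative and
#'   would inflate population calorie intake; for every other scenario,
#'   no overrides. Pass `character(0)` to disable overrides entirely.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("1A", "1B", "2A", "2B"),
                            overrides = NULL) {
  scenario <- sub("^S", "", toupper(scenario[1]))
  scenario <- match.arg(scenario)
  structure(
    list(
      scenario_id = paste0("S", scenario),
      candidate_source = if (startsWith(scenario, "1")) "branded" else "generic",
      rule = if (endsWith(scenario, "A")) "optimistic" else "realistic",
      overrides = overrides
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$scenario_id, "-", x$rule,
      "substitution from the", x$candidate_source, "database\n")
  if (length(x$overrides)) {
    cat("  overrides:", paste(names(x$overrides), x$overrides,
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default manual overrides for unrepresentative categories
#'
#' In categories dominated by near-zero-calorie beverages or dry staples,
#' the lowest-scoring food can be an energy-dense outlier (e.g. a
#' cereal-grain coffee substitute powder), so substituting it everywhere
#' inflates population calorie intake. For each requested category
#' present in the database this helper designates instead the
#' lowest-calorie food among those holding the *next-lowest* distinct
#' Ofcom score (ties broken by food ID). Categories with fewer than two
#' distinct scores get no override.
#'
#' @param generic_db A scored generic food table.
#' @param categories Category codes to consider.
#' @return Named character vector `category_code -> food_id`.
#' @export
default_overrides <- function(generic_db, categories = c("01C", "51A", "51B")) {
  out <- character(0)
  for (code in intersect(categories, unique(generic_db$category_code))) {
    cat_db <- foods_in_category(generic_db, code)
    scores <- sort(unique(cat_db$ofcom_score))
    if (length(scores) < 2) next
    pool <- cat_db[cat_db$ofcom_score == scores[2], , drop = FALSE]
    pool <- pool[order(pool$energy_kcal, pool$food_id), , drop = FALSE]
    out[[code]] <- pool$food_id[1]
  }
  out
}

#' Candidate substitutes for one food
#'
#' For Scenarios 1A/1B, candidates are the branded products matched (via
#' the match table) to the food under consideration — the match table
#' encodes which branded products are "similar" to which generic food, so
#' an unmatched food has no branded substitute; for 2A/2B, all other
#' generic foods in the same category. Only candidates with an Ofcom
#' score strictly below the food's own score are retained.
#'
#' @param food_id A generic food ID.
#' @param config A [scenario_config()].
#' @param generic_db,branded_db Scored food tables.
#' @param matches Validated match table (Scenario 1 only).
#' @return The candidate rows of the relevant database.
#' @export
candidates <- function(food_id, config, generic_db, branded_db = NULL,
                       matches = NULL) {
  row <- generic_db[generic_db$food_id == food_id, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("unknown food_id: ", food_id, call. = FALSE)
  }
  if (config$candidate_source == "branded") {
    if (is.null(branded_db) || is.null(matches)) {
      stop("Scenario 1 requires a branded database and a match table",
           call. = FALSE)
    }
    own <- matches$generic_food_id == food_id
    pool <- branded_db[branded_db$food_id %in% matches$branded_food_id[own], ,
                       drop = FALSE]
  } else {
    pool <- foods_in_category(generic_db, row$category_code)
    pool <- pool[pool$food_id != food_id, , drop = FALSE]
  }
  pool[pool$ofcom_score < row$ofcom_score, , drop = FALSE]
}

# nutrient-wise weighted mean of candidate profiles; the composite's own
# score is recomputed from the blended profile, never averaged from the
# constituents' scores
composite_substitute <- function(cands, weights, original, tables) {
  w <- weights / sum(weights)
  profile <- vapply(
    nutrient_columns,
    function(col) sum(w * cands[[col]]),
    numeric(1)
  )
  # composite inherits the constituent level with the smallest implied
  # point value, to avoid inflating C-points of synthesised foods
  lv <- unique(cands$fvn_level)
  fvn <- lv[which.min(fvn_rank[lv])]
  score <- ofcom_score(
    profile[["energy_kcal"]], profile[["satfat_g"]], profile[["sugars_g"]],
    profile[["sodium_mg"]], profile[["fibre_g"]], profile[["protein_g"]],
    fvn, tables
  )$total_score
  tibble::tibble(
    replacement_id = paste0("COMP_", original$food_id),
    energy_kcal = profile[["energy_kcal"]],
    satfat_g = profile[["satfat_g"]],
    sugars_g = profile[["sugars_g"]],
    sodium_mg = profile[["sodium_mg"]],
    fibre_g = profile[["fibre_g"]],
    protein_g = profile[["protein_g"]],
    fvn_level = fvn,
    replacement_score = score
  )
}

as_replacement <- function(row) {
  tibble::tibble(
    replacement_id = row$food_id,
    energy_kcal = row$energy_kcal,
    satfat_g = row$satfat_g,
    sugars_g = row$sugars_g,
    sodium_mg = row$sodium_mg,
    fibre_g = row$fibre_g,
    protein_g = row$protein_g,
    fvn_level = row$fvn_level,
    replacement_score = row$ofcom_score
  )
}

unreplaced <- function(original) {
  out <- as_replacement(original)
  out$replacement_score <- original$ofcom_score
  out
}

# lowest score, then lowest calories, then lexicographically smallest ID
pick_with_ties <- function(pool, target_score) {
  tied <- pool[pool$ofcom_score == target_score, , drop = FALSE]
  tied[order(tied$energy_kcal, tied$food_id), , drop = FALSE][1, , drop = FALSE]
}

#' Select the substitute for one food under a scenario
#'
#' Applies the scenario's selection rule to a precomputed candidate set:
#' * **S1A** — candidates tied at the minimum score; if several, a
#'   composite food is synthesised whose nutrients are their unweighted
#'   means ("a new food ID").
#' * **S1B** — all strictly-lower-scoring candidates, blended by market
#'   share (renormalised over the set; unweighted with a warning when all
#'   shares are absent or zero).
#' * **S2A** — the minimum-score candidate, ties broken by lower
#'   calories, then smaller ID. In override categories the designated
#'   food is used instead, provided its score does not exceed the
#'   original's.
#' * **S2B** — the candidate at the *next-lowest* score (the largest
#'   candidate score strictly below the original's), same tie-breaks.
#'
#' An empty candidate set, or a composite whose recomputed score fails to
#' beat the original's, leaves the food as is.
#'
#' @param food_id A generic food ID.
#' @param cands Candidate rows from [candidates()].
#' @param config A [scenario_config()] whose `overrides` are fully
#'   resolved (a named character vector).
#' @param generic_db Scored generic table.
#' @param tables Point tables for rescoring composites.
#' @return One-row tibble: `original_food_id`, `replaced`, `via_override`,
#'   replacement profile columns, `replacement_score`, `original_score`.
#' @export
select_substitute <- function(food_id, cands, config, generic_db,
                              tables = ofcom_point_tables()) {
  original <- generic_db[generic_db$food_id == food_id, , drop = FALSE]
  finish <- function(repl, replaced, via_override = FALSE) {
    dplyr::bind_cols(
      tibble::tibble(
        original_food_id = food_id,
        replaced = replaced,
        via_override = via_override
      ),
      repl,
      tibble::tibble(
        original_score = original$ofcom_score,
        reference_amount_g = original$reference_amount_g
      )
    )
  }

  ov <- config$overrides
  if (length(ov) && original$category_code %in% names(ov)) {
    target <- generic_db[generic_db$food_id == ov[[original$category_code]], ,
                         drop = FALSE]
    if (nrow(target) != 1) {
      stop("override for category ", original$category_code,
           " names an unknown food: ", ov[[original$category_code]],
           call. = FALSE)
    }
    if (target$food_id != food_id && target$ofcom_score <= original$ofcom_score) {
      return(finish(as_replacement(target), TRUE, via_override = TRUE))
    }
    return(finish(unreplaced(original), FALSE))
  }

  if (nrow(cands) == 0) {
    return(finish(unreplaced(original), FALSE))
  }

  repl <- switch(
    config$scenario_id,
    S1A = {
      best <- cands[cands$ofcom_score == min(cands$ofcom_score), , drop = FALSE]
      if (nrow(best) == 1) {
        as_replacement(best)
      } else {
        composite_substitute(best, rep(1, nrow(best)), original, tables)
      }
    },
    S1B = {
      if (nrow(cands) == 1) {
        as_replacement(cands)
      } else {
        w <- cands$market_share
        if (is.null(w) || all(is.na(w)) || sum(w, na.rm = TRUE) <= 0) {
          warning("all market shares absent or zero for substitutes of ",
                  food_id, "; using an unweighted mean", call. = FALSE)
          w <- rep(1, nrow(cands))
        }
        w[is.na(w)] <- 0
        composite_substitute(cands, w, original, tables)
      }
    },
    S2A = as_replacement(pick_with_ties(cands, min(cands$ofcom_score))),
    S2B = as_replacement(pick_with_ties(cands, max(cands$ofcom_score)))
  )

  if (repl$replacement_score >= original$ofcom_score) {
    # a blended composite can score worse than its constituents; keep the
    # guarantee that every replacement strictly improves the score
    return(finish(unreplaced(original), FALSE))
  }
  finish(repl, TRUE)
}

#' Substitution map for a set of consumed foods
#'
#' Resolves the scenario once per distinct food; the map is then reused
#' for every respondent, so two consumers of the same food always receive
#' the identical replacement.
#'
#' @inheritParams candidates
#' @param consumed_ids Distinct generic food IDs to map. Defaults to the
#'   whole generic database.
#' @param tables Point tables for rescoring composites.
#' @return A tibble with one row per food in `consumed_ids`.
#' @export
substitution_map <- function(config, generic_db, branded_db = NULL,
                             matches = NULL, consumed_ids = NULL,
                             tables = ofcom_point_tables()) {
  if (!"ofcom_score" %in% names(generic_db)) {
    stop("score the databases with score_foods() before substituting",
         call. = FALSE)
  }
  if (is.null(consumed_ids)) consumed_ids <- generic_db$food_id
  if (is.null(config$overrides)) {
    config$overrides <- if (config$scenario_id == "S2A") {
      default_overrides(generic_db)
    } else {
      character(0)
    }
  }
  rows <- lapply(consumed_ids, function(id) {
    cands <- candidates(id, config, generic_db, branded_db, matches)
    select_substitute(id, cands, config, generic_db, tables)
  })
  dplyr::bind_rows(rows)
}

#' Apply a substitution scenario to recall data
#'
#' Replaces each recall line's per-100 g nutrient profile and Ofcom score
#' with the mapped substitute's, keeping grams consumed and the original
#' food's reference amount unchanged (the scenario changes what the food
#' is made of, not how much of it was eaten).
#'
#' @param recalls Recall tibble: `respondent_id`, `food_id`,
#'   `grams_consumed`.
#' @inheritParams substitution_map
#' @return A list with `recalls` (effective recall lines carrying profile
#'   columns, `ofcom_score`, `reference_amount_g`, `replaced`,
#'   `replacement_id`) and `map` (the substitution map).
#' @export
apply_scenario <- function(recalls, config, generic_db, branded_db = NULL,
                           matches = NULL, tables = ofcom_point_tables()) {
  map <- substitution_map(
    config, generic_db, branded_db, matches,
    consumed_ids = unique(recalls$food_id), tables = tables
  )
  eff <- dplyr::left_join(
    recalls,
    dplyr::rename(map, food_id = "original_food_id", ofcom_score = "replacement_score"),
    by = "food_id"
  )
  keep <- c("respondent_id", "food_id", "grams_consumed", "replaced",
            "replacement_id", nutrient_columns, "fvn_level",
            "ofcom_score", "reference_amount_g")
  list(recalls = eff[, keep], map = map)
}

#' Baseline (unsubstituted) effective recalls
#'
#' Joins recall lines to their original foods' profiles and scores so
#' baseline intakes are computed from the same table shape as scenario
#' intakes.
#'
#' @inheritParams apply_scenario
#' @param generic_db Scored generic table.
#' @return An effective recall tibble, as in [apply_scenario()].
#' @export
baseline_recalls <- function(recalls, generic_db) {
  unknown <- setdiff(unique(recalls$food_id), generic_db$food_id)
  if (length(unknown)) {
    stop("recalls reference food(s) absent from the generic database: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  eff <- dplyr::left_join(
    recalls,
    generic_db[, c("food_id", nutrient_columns, "fvn_level",
                   "ofcom_score", "reference_amount_g")],
    by = "food_id"
  )
  eff$replaced <- FALSE
  eff$replacement_id <- eff$food_id
  keep <- c("respondent_id", "food_id", "grams_consumed", "replaced",
            "replacement_id", nutrient_columns, "fvn_level",
            "ofcom_score", "reference_amount_g")
  eff[, keep]
}
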