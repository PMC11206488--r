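#' Run the full substitution-modelling pipeline
#'
#' Orchestrates the stages in fixed order: load (or generate) inputs,
#' impute missing nutrients, score, filter the sample, compute baseline
#' intakes, then for each requested scenario substitute, aggregate and
#' estimate against baseline. Returns the results table, a run manifest
#' that fully determines the outputs, and per-stage log counts.
#'
#' The configuration is a named list or a path to a `key = value` file.
#' Either a `synth_seed` key (with optional `n_respondents`,
#' `n_categories`, `foods_per_category`, `items_min`, `items_max`, `b`,
#' `missing_rate` keys) requests a generated world, or file keys
#' `generic_foods`, `respondents`, `recalls` (and optionally
#' `branded_foods` + `matches`, required for Scenarios 1A/1B) name the
#' delimited inputs. `scenarios` is a comma-separated subset of
#' `1A,1B,2A,2B` (default: all four when a branded database is present,
#' otherwise `2A,2B`). `point_tables` optionally names an alternative
#' threshold file.
#'
#' @param config Named list or path to a key/value config file.
#' @param out_dir Optional directory; when given, writes `results.tsv`,
#'   `subset_results.tsv` (when Scenario 1 runs), and `manifest.json`,
#'   with numbers rounded to 6 significant digits at serialisation only.
#' @return A list: `results`, `subset_results` (or `NULL`), `intakes`,
#'   `maps`, `coverage`, `manifest`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_kv_config(config)
  log <- list()
  note <- function(...) {
    msg <- paste0(...)
    log[[length(log) + 1L]] <<- msg
    message(msg)
  }
  tables <- if (!is.null(config$point_tables)) {
    ofcom_point_tables(config$point_tables)
  } else {
    ofcom_point_tables()
  }

  # --- stage: inputs ---------------------------------------------------
  synthetic <- !is.null(config$synth_seed)
  if (synthetic) {
    sc_args <- config[intersect(
      names(config),
      c("n_respondents", "n_categories", "foods_per_category",
        "branded_match_fraction", "lower_score_match_fraction",
        "items_min", "items_max")
    )]
    sc_args$seed <- config$synth_seed
    if (!is.null(config$b)) sc_args$B <- config$b
    scfg <- do.call(synth_config, sc_args)
    world <- generate_world(scfg)
    generic <- world$generic
    branded <- world$branded
    matches_raw <- world$matches
    respondents <- world$respondents
    recalls <- world$recalls
    if (!is.null(config$missing_rate) && config$missing_rate > 0) {
      generic <- generate_missingness(generic, config$missing_rate,
                                      seed = scfg$seed + 1L)
    }
    inputs <- list(synth_config = unclass(scfg),
                   synth_hash = rlang::hash(unclass(scfg)))
    note("generated synthetic world (seed ", scfg$seed, "): ",
         nrow(generic), " generic foods, ", nrow(branded), " branded foods, ",
         nrow(respondents), " respondents")
  } else {
    for (key in c("generic_foods", "respondents", "recalls")) {
      if (is.null(config[[key]])) {
        stop("config error: missing required input '", key, "'", call. = FALSE)
      }
    }
    generic <- load_food_table(config$generic_foods, "generic")
    branded <- if (!is.null(config$branded_foods)) {
      load_food_table(config$branded_foods, "branded")
    } else {
      NULL
    }
    respondents <- readr::read_csv(
      config$respondents,
      col_types = readr::cols(respondent_id = "c", breastfeeding = "l",
                              .default = "d"),
      progress = FALSE
    )
    recalls <- readr::read_csv(
      config$recalls,
      col_types = readr::cols(respondent_id = "c", food_id = "c",
                              grams_consumed = "d"),
      progress = FALSE
    )
    matches_raw <- if (!is.null(config$matches)) config$matches else NULL
    files <- unlist(config[intersect(
      names(config),
      c("generic_foods", "branded_foods", "matches", "respondents", "recalls")
    )])
    inputs <- list(files = as.list(files),
                   hashes = as.list(tools::md5sum(files)))
    note("loaded ", nrow(generic), " generic foods, ",
         if (is.null(branded)) 0 else nrow(branded), " branded foods, ",
         nrow(respondents), " respondents, ", nrow(recalls), " recall lines")
  }

  scenarios <- if (!is.null(config$scenarios)) {
    trimws(unlist(strsplit(as.character(config$scenarios), ",")))
  } else if (!is.null(branded) && nrow(branded) > 0) {
    c("1A", "1B", "2A", "2B")
  } else {
    c("2A", "2B")
  }

  # --- stage: imputation ----------------------------------------------
  imp <- impute_missing_nutrients(generic)
  generic <- imp$db
  note("imputed ", nrow(imp$log), " missing nutrient cells in the generic database")
  if (!is.null(branded) && nrow(branded) > 0) {
    imp_b <- impute_missing_nutrients(branded)
    branded <- imp_b$db
    note("imputed ", nrow(imp_b$log), " missing nutrient cells in the branded database")
  }

  # --- stage: scoring --------------------------------------------------
  generic <- score_foods(generic, tables)
  if (!is.null(branded) && nrow(branded) > 0) {
    branded <- score_foods(branded, tables)
  }
  note("scored all foods (point tables: ", tables$version, ")")

  matches <- if (!is.null(matches_raw) && !is.null(branded) && nrow(branded) > 0) {
    load_matches(matches_raw, generic, branded)
  } else {
    NULL
  }
  coverage <- if (!is.null(matches)) {
    cov <- match_coverage(recalls, matches, generic, branded)
    note(sprintf("match coverage: %.1f%% matched, %.1f%% with a lower score",
                 100 * cov$matched_fraction, 100 * cov$lower_fraction))
    cov
  } else {
    NULL
  }

  # --- stage: sample ---------------------------------------------------
  eligible <- filter_sample(respondents)
  note("sample filter retained ", nrow(eligible), " of ", nrow(respondents),
       " respondents")
  recalls <- recalls[recalls$respondent_id %in% eligible$respondent_id, ,
                     drop = FALSE]
  empty <- setdiff(eligible$respondent_id, unique(recalls$respondent_id))
  if (length(empty)) {
    warning(length(empty), " eligible respondent(s) with an empty recall excluded",
            call. = FALSE)
    eligible <- eligible[!eligible$respondent_id %in% empty, , drop = FALSE]
  }
  design <- survey_design(eligible)

  # --- stage: baseline -------------------------------------------------
  eff <- list(baseline = baseline_recalls(recalls, generic))
  intakes <- list(baseline = daily_intakes(eff$baseline))

  # --- stage: scenarios ------------------------------------------------
  maps <- list()
  for (sc in scenarios) {
    cfg <- scenario_config(sc)
    if (cfg$candidate_source == "branded" && is.null(matches)) {
      stop("config error: scenario ", sc,
           " needs branded_foods and matches inputs", call. = FALSE)
    }
    applied <- apply_scenario(recalls, cfg, generic, branded, matches,
                              tables = tables)
    nm <- cfg$scenario_id
    eff[[nm]] <- applied$recalls
    maps[[nm]] <- applied$map
    intakes[[nm]] <- daily_intakes(applied$recalls)
    note(nm, ": substituted ", sum(applied$map$replaced), " of ",
         nrow(applied$map), " distinct consumed foods")
  }

  # --- stage: estimation -----------------------------------------------
  results <- scenario_report(intakes, design)
  subset_results <- NULL
  s1 <- intersect(c("S1A", "S1B"), names(maps))
  if (length(s1)) {
    substituted_ids <- unique(unlist(
      lapply(maps[s1], function(m) m$original_food_id[m$replaced])
    ))
    subset_results <- subset_scenario_report(
      eff[c("baseline", s1)], substituted_ids, design
    )
    note("subset analysis over ", length(substituted_ids),
         " substituted foods")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("npsubstitute")),
    inputs = inputs,
    scenarios = scenarios,
    point_tables = list(version = tables$version,
                        hash = rlang::hash(unclass(tables))),
    B = design$B,
    n_respondents = nrow(eligible)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(results, file.path(out_dir, "results.tsv"))
    if (!is.null(subset_results)) {
      write_results_table(subset_results, file.path(out_dir, "subset_results.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(
    results = results, subset_results = subset_results, intakes = intakes,
    maps = maps, coverage = coverage, manifest = manifest,
    log = unlist(log)
  )
}

#' Write a results table, rounding only at serialisation
#'
#' @param results A [scenario_report()] tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  readr::write_tsv(out, path)
  invisible(path)
}
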