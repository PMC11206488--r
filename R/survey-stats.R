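#' Extract a survey design from a respondent table
#'
#' @param respondents Respondent tibble with `survey_weight` and
#'   `replicate_weight_1` .. `replicate_weight_B` columns.
#' @return A list of class `survey_design`: `respondent_id`, `weights`,
#'   `replicate_weights` (an `n x B` matrix), `B`.
#' @export
survey_design <- function(respondents) {
  rep_cols <- grep("^replicate_weight_[0-9]+$", names(respondents), value = TRUE)
  if (!length(rep_cols)) {
    stop("no replicate_weight_* columns found", call. = FALSE)
  }
  ord <- order(as.integer(sub("replicate_weight_", "", rep_cols)))
  rep_cols <- rep_cols[ord]
  rw <- as.matrix(respondents[, rep_cols])
  if (anyNA(rw) || any(rw < 0)) {
    stop("replicate weights must be non-negative and complete", call. = FALSE)
  }
  if (anyNA(respondents$survey_weight) || any(respondents$survey_weight <= 0)) {
    stop("survey_weight must be positive for every respondent", call. = FALSE)
  }
  structure(
    list(
      respondent_id = respondents$respondent_id,
      weights = respondents$survey_weight,
      replicate_weights = rw,
      B = ncol(rw)
    ),
    class = "survey_design"
  )
}

#' Survey-weighted mean
#'
#' @param x Numeric values, one per respondent.
#' @param w Non-negative weights summing to a positive total.
#' @return `sum(w * x) / sum(w)`.
#' @export
weighted_mean <- function(x, w) {
  if (length(x) != length(w)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(w < 0) || anyNA(w)) {
    stop("weights must be non-negative and complete", call. = FALSE)
  }
  if (sum(w) <= 0) {
    stop("weights sum to zero; the weighted mean is undefined", call. = FALSE)
  }
  sum(w * x) / sum(w)
}

#' Bootstrap replicate-weight variance of a weighted mean
#'
#' Point estimate from the main weights; the estimate is recomputed under
#' each of the B survey-provided bootstrap replicate weight vectors and
#' the variance taken as `mean((theta_b - theta)^2)` (the Statistics
#' Canada mean-bootstrap convention, no Fay factor). The 95% confidence
#' interval uses the normal multiplier 1.96. Replicates whose weights sum
#' to zero are dropped with a warning and B adjusted.
#'
#' @param x Numeric values, one per respondent.
#' @param weights Main survey weights.
#' @param replicate_weights `n x B` matrix of replicate weights.
#' @return One-row tibble: `estimate`, `se`, `ci_low`, `ci_high`, `n`, `B`.
#' @export
replicate_variance <- function(x, weights, replicate_weights) {
  rw <- as.matrix(replicate_weights)
  if (nrow(rw) != length(x)) {
    stop("replicate weight matrix must have one row per respondent",
         call. = FALSE)
  }
  if (ncol(rw) == 0) {
    stop("at least one replicate weight vector is required", call. = FALSE)
  }
  est <- weighted_mean(x, weights)
  tot <- colSums(rw)
  if (any(tot <= 0)) {
    warning(sum(tot <= 0), " replicate(s) with zero total weight dropped",
            call. = FALSE)
    rw <- rw[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
    if (!ncol(rw)) stop("no usable replicates remain", call. = FALSE)
  }
  est_b <- as.vector(crossprod(rw, x)) / tot
  se <- sqrt(mean((est_b - est)^2))
  tibble::tibble(
    estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    n = length(x), B = ncol(rw)
  )
}

#' Paired baseline-vs-scenario comparison
#'
#' Computes per-respondent differences (scenario minus baseline) for each
#' intake outcome, their survey-weighted mean and replicate-weight
#' standard error, and a paired t-test of zero difference with B - 1
#' degrees of freedom. When the replicate SE is exactly zero the p-value
#' is 1 for a zero difference and 0 otherwise.
#'
#' @param baseline,scenario [daily_intakes()] tibbles covering the same
#'   respondents.
#' @param design A [survey_design()].
#' @param outcomes Outcome columns to compare.
#' @return Tibble with one row per outcome: `outcome`, `estimate` (mean
#'   difference), `se`, `ci_low`, `ci_high`, `statistic`, `df`,
#'   `p_value`.
#' @export
paired_scenario_test <- function(baseline, scenario, design,
                                 outcomes = intake_outcomes) {
  if (!setequal(baseline$respondent_id, scenario$respondent_id)) {
    stop("baseline and scenario cover different respondent sets", call. = FALSE)
  }
  idx <- match(baseline$respondent_id, design$respondent_id)
  if (anyNA(idx)) {
    stop("some respondents are absent from the survey design", call. = FALSE)
  }
  scenario <- scenario[match(baseline$respondent_id, scenario$respondent_id), ]
  w <- design$weights[idx]
  rw <- design$replicate_weights[idx, , drop = FALSE]
  rows <- lapply(outcomes, function(col) {
    d <- scenario[[col]] - baseline[[col]]
    rv <- replicate_variance(d, w, rw)
    if (rv$se == 0) {
      stat <- if (rv$estimate == 0) 0 else Inf * sign(rv$estimate)
      p <- if (rv$estimate == 0) 1 else 0
    } else {
      stat <- rv$estimate / rv$se
      p <- 2 * stats::pt(-abs(stat), df = rv$B - 1)
    }
    dplyr::bind_cols(
      tibble::tibble(outcome = col), rv,
      tibble::tibble(statistic = stat, df = rv$B - 1, p_value = p)
    )
  })
  dplyr::bind_rows(rows)
}

#' Intake outcomes reported by the pipeline
#' @format Character vector of column names in [daily_intakes()] output.
#' @export
intake_outcomes <- c("dietary_ofcom", "calories_kcal", "satfat_g",
                     "sodium_mg", "sugars_g")

#' Scenario results table
#'
#' One row per scenario and outcome: the survey-weighted mean with
#' replicate-weight SE and 95% CI, and for non-baseline scenarios the
#' paired difference from baseline with its p-value and a significance
#' flag at 0.05.
#'
#' @param intakes Named list of [daily_intakes()] tibbles; must contain a
#'   `baseline` element, plus one element per scenario.
#' @param design A [survey_design()].
#' @return A tibble: `scenario`, `outcome`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n`, `B`, `diff`, `p_value`, `significant`.
#' @export
scenario_report <- function(intakes, design) {
  if (!"baseline" %in% names(intakes)) {
    stop("intakes must include a 'baseline' element", call. = FALSE)
  }
  baseline <- intakes$baseline
  rows <- lapply(names(intakes), function(nm) {
    df <- intakes[[nm]]
    idx <- match(df$respondent_id, design$respondent_id)
    if (anyNA(idx)) {
      stop("some respondents are absent from the survey design", call. = FALSE)
    }
    w <- design$weights[idx]
    rw <- design$replicate_weights[idx, , drop = FALSE]
    per_outcome <- lapply(intake_outcomes, function(col) {
      rv <- replicate_variance(df[[col]], w, rw)
      dplyr::bind_cols(tibble::tibble(scenario = nm, outcome = col), rv)
    })
    out <- dplyr::bind_rows(per_outcome)
    if (nm == "baseline") {
      out$diff <- NA_real_
      out$p_value <- NA_real_
      out$significant <- NA
    } else {
      cmp <- paired_scenario_test(baseline, df, design)
      out$diff <- cmp$estimate[match(out$outcome, cmp$outcome)]
      out$p_value <- cmp$p_value[match(out$outcome, cmp$outcome)]
      out$significant <- out$p_value < 0.05
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Subset analysis restricted to substitutable foods
#'
#' Mirrors the follow-up analysis in which intakes are recomputed over
#' only the foods that actually received a substitute in the branded
#' scenarios: recall lines are restricted to those foods, partial daily
#' intakes and the dietary score recomputed over the restriction, for
#' baseline and each supplied scenario. Respondents with no restricted
#' lines drop out, so the subset n is typically smaller.
#'
#' @param effective_recalls Named list of effective recall tibbles
#'   (a `baseline` element plus scenarios), all sharing the original
#'   `food_id` column.
#' @param substituted_ids Food IDs that received a substitution.
#' @param design A [survey_design()].
#' @return A [scenario_report()]-shaped tibble over the restricted lines.
#' @export
subset_scenario_report <- function(effective_recalls, substituted_ids, design) {
  restricted <- lapply(effective_recalls, function(df) {
    daily_intakes(df[df$food_id %in% substituted_ids, , drop = FALSE])
  })
  ids <- Reduce(intersect, lapply(restricted, function(df) df$respondent_id))
  restricted <- lapply(restricted, function(df) {
    df[df$respondent_id %in% ids, , drop = FALSE]
  })
  scenario_report(restricted, design)
}
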