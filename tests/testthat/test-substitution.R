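# category "X" with per-food scores {3, 1, 1, 4, 6}; the score-4 food is
# the one under substitution
s2_world <- function() {
  mk_db(list(
    mk_food("F3", "X", score = 3),
    mk_food("F1a", "X", score = 1, kcal = 80),
    mk_food("F1b", "X", score = 1, kcal = 50),
    mk_food("F4", "X", score = 4),
    mk_food("F6", "X", score = 6)
  ))
}

# generic food scoring 5, with branded matches tied at score 3 that
# differ in sodium/sugars mix (sodium 100 + sugars 10, sodium 300)
s1_world <- function(shares = c(0.75, 0.25)) {
  generic <- mk_db(list(mk_food("G1", "X", sodium = 451)))
  branded <- mk_db(list(
    mk_food("B1", "X", sodium = 100, sugars = 10, share = shares[1]),
    mk_food("B2", "X", sodium = 300, share = shares[2])
  ), source = "branded")
  matches <- load_matches(
    tibble::tibble(generic_food_id = c("G1", "G1"),
                   branded_food_id = c("B1", "B2")),
    generic, branded
  )
  list(generic = generic, branded = branded, matches = matches)
}

test_that("candidate sets keep only strictly lower-scoring same-category foods", {
  db <- s2_world()
  cfg <- scenario_config("2A", overrides = character(0))
  cands <- candidates("F4", cfg, db)
  expect_setequal(cands$food_id, c("F3", "F1a", "F1b"))
  expect_true(all(cands$ofcom_score < 4))
  # the lowest-scoring food has no candidates; ties are not "lower"
  expect_equal(nrow(candidates("F1b", cfg, db)), 0)
  expect_error(candidates("NOPE", cfg, db), "unknown food_id")
  # S1: only the food's own branded matches count, and only lower ones
  w <- s1_world()
  c1 <- candidates("G1", scenario_config("1A"), w$generic, w$branded, w$matches)
  expect_setequal(c1$food_id, c("B1", "B2"))
})

test_that("optimistic generic selection takes the minimum score, then calories, then ID", {
  db <- s2_world()
  cfg <- scenario_config("2A", overrides = character(0))
  cands <- candidates("F4", cfg, db)
  res <- select_substitute("F4", cands, cfg, db)
  expect_true(res$replaced)
  expect_equal(res$replacement_id, "F1b") # tied at 1, 50 kcal < 80 kcal
  expect_equal(res$replacement_score, 1)
  expect_lt(res$replacement_score, res$original_score)
  # equal calories fall back to the smaller food ID
  db2 <- mk_db(list(
    mk_food("Fz", "X", score = 1, kcal = 50),
    mk_food("Fa", "X", score = 1, kcal = 50),
    mk_food("F4", "X", score = 4)
  ))
  res2 <- select_substitute(
    "F4", candidates("F4", cfg, db2), cfg, db2
  )
  expect_equal(res2$replacement_id, "Fa")
})

test_that("realistic generic selection takes the next-lowest score", {
  db <- s2_world()
  cfg <- scenario_config("2B")
  res <- select_substitute("F4", candidates("F4", cfg, db), cfg, db)
  expect_true(res$replaced)
  expect_equal(res$replacement_id, "F3") # max of the lower scores {3,1,1}
  expect_equal(res$replacement_score, 3)
})

test_that("foods without a lower-scoring option are left as is", {
  db <- s2_world()
  for (sc in c("2A", "2B")) {
    cfg <- scenario_config(sc, overrides = character(0))
    res <- select_substitute("F1a", candidates("F1a", cfg, db), cfg, db)
    expect_false(res$replaced)
    expect_equal(res$replacement_id, "F1a")
    expect_equal(res$replacement_score, res$original_score)
  }
})

test_that("tied-minimum branded matches blend into an unweighted composite", {
  w <- s1_world()
  cfg <- scenario_config("1A")
  res <- select_substitute(
    "G1", candidates("G1", cfg, w$generic, w$branded, w$matches),
    cfg, w$generic
  )
  expect_true(res$replaced)
  expect_match(res$replacement_id, "^COMP_")
  expect_equal(res$sodium_mg, 200) # mean of 100 and 300
  expect_equal(res$sugars_g, 5)
  # the composite's score is recomputed from the blended profile
  expect_equal(res$replacement_score,
               ofcom_score(0, 0, 5, 200, 0, 0, "MIN")$total_score)
})

test_that("realistic branded substitution weights the blend by market share", {
  w <- s1_world(shares = c(0.75, 0.25))
  cfg <- scenario_config("1B")
  res <- select_substitute(
    "G1", candidates("G1", cfg, w$generic, w$branded, w$matches),
    cfg, w$generic
  )
  expect_true(res$replaced)
  expect_equal(res$sodium_mg, 0.75 * 100 + 0.25 * 300)
  # absent shares fall back to an unweighted mean with a warning
  w0 <- s1_world(shares = c(0, 0))
  expect_warning(
    res0 <- select_substitute(
      "G1", candidates("G1", cfg, w0$generic, w0$branded, w0$matches),
      cfg, w0$generic
    ),
    "market shares"
  )
  expect_equal(res0$sodium_mg, 200)
})

test_that("branded scenarios coincide when exactly one lower candidate exists", {
  generic <- mk_db(list(mk_food("G1", "X", score = 5)))
  branded <- mk_db(list(
    mk_food("B1", "X", score = 2, share = 0.4),
    mk_food("B2", "X", score = 7, share = 0.6)
  ), source = "branded")
  matches <- load_matches(
    tibble::tibble(generic_food_id = c("G1", "G1"),
                   branded_food_id = c("B1", "B2")),
    generic, branded
  )
  m1a <- substitution_map(scenario_config("1A"), generic, branded, matches)
  m1b <- substitution_map(scenario_config("1B"), generic, branded, matches)
  expect_equal(m1a, m1b)
  expect_equal(m1a$replacement_id, "B1")
})

test_that("designated category overrides replace the lowest-scoring rule", {
  db <- mk_db(list(
    mk_food("L", "51B", score = -5, kcal = 80), # lowest score, caloric
    mk_food("M", "51B", score = 0, kcal = 0),
    mk_food("H", "51B", score = 5, kcal = 10)
  ))
  ov <- default_overrides(db)
  expect_equal(unname(ov["51B"]), "M") # next-lowest score, zero calories
  # default S2A config resolves the override automatically
  map <- substitution_map(scenario_config("2A"), db)
  expect_equal(map$replacement_id[map$original_food_id == "H"], "M")
  expect_true(map$via_override[map$original_food_id == "H"])
  # the override target is worse than L's own score, so L stays as is
  expect_false(map$replaced[map$original_food_id == "L"])
  # without overrides, the optimistic rule picks the true minimum
  map0 <- substitution_map(scenario_config("2A", overrides = character(0)), db)
  expect_equal(map0$replacement_id[map0$original_food_id == "H"], "L")
})

test_that("applying a scenario preserves grams and reuses the map across respondents", {
  db <- s2_world()
  recalls <- tibble::tibble(
    respondent_id = c("R1", "R2", "R2"),
    food_id = c("F4", "F4", "F1b"),
    grams_consumed = c(120, 80, 30)
  )
  cfg <- scenario_config("2A", overrides = character(0))
  out <- apply_scenario(recalls, cfg, db)
  expect_equal(out$recalls$grams_consumed, recalls$grams_consumed)
  # both consumers of F4 receive the identical replacement
  f4 <- out$recalls[out$recalls$food_id == "F4", ]
  expect_equal(unique(f4$replacement_id), "F1b")
  expect_equal(f4$sodium_mg[1], f4$sodium_mg[2])
  # the unsubstitutable line is untouched
  f1b <- out$recalls[out$recalls$food_id == "F1b", ]
  expect_false(f1b$replaced)
  # reference amounts come from the original food
  expect_equal(unique(out$recalls$reference_amount_g), 100)
  # deterministic: a second run is identical
  expect_identical(out, apply_scenario(recalls, cfg, db))
})

test_that("substitution invariants hold across a generated world", {
  world <- generate_world(synth_config(
    seed = 5, n_respondents = 120, n_categories = 15,
    foods_per_category = 12, B = 8
  ))
  tables <- ofcom_point_tables()
  generic <- score_foods(world$generic)
  branded <- score_foods(world$branded)
  matches <- load_matches(world$matches, generic, branded)
  consumed <- unique(world$recalls$food_id)
  maps <- list(
    S1A = substitution_map(scenario_config("1A"), generic, branded, matches, consumed),
    S1B = substitution_map(scenario_config("1B"), generic, branded, matches, consumed),
    S2A = substitution_map(scenario_config("2A", overrides = character(0)),
                           generic, branded, matches, consumed),
    S2B = substitution_map(scenario_config("2B"), generic, branded, matches, consumed)
  )
  for (nm in names(maps)) {
    m <- maps[[nm]]
    expect_true(all(m$replacement_score[m$replaced] < m$original_score[m$replaced]),
                info = nm)
    expect_true(all(m$replacement_score <= m$original_score), info = nm)
    expect_true(all(m$replacement_score[!m$replaced] == m$original_score[!m$replaced]),
                info = nm)
  }
  # optimistic generic replacement never scores above the realistic one
  expect_true(all(maps$S2A$replacement_score <= maps$S2B$replacement_score))
})
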