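test_that("A-points follow the 2004-05 tables with strict thresholds", {
  expect_identical(a_points(0, 0, 0, 0), 0L)
  # sodium alone above the top band
  expect_identical(a_points(0, 0, 0, 950), 10L)
  # one unit above every first threshold: 81 kcal = 338.9 kJ > 335
  expect_identical(a_points(81, 1.1, 4.6, 91), 4L)
  # values sitting exactly on a threshold earn no point
  expect_identical(a_points(0, 1, 4.5, 90), 0L)
  # vectorised and monotone in each nutrient
  expect_identical(a_points(c(0, 81), c(0, 1.1), c(0, 4.6), c(0, 91)),
                   c(0L, 4L))
})

test_that("invalid nutrient input is rejected with the field named", {
  expect_error(a_points(-1, 0, 0, 0), "energy_kcal")
  expect_error(a_points(0, NA, 0, 0), "satfat_g")
  expect_error(a_points(0, 0, Inf, 0), "sugars_g")
  expect_error(ofcom_score(0, 0, 0, -5, 0, 0, "MIN"), "sodium_mg")
  expect_error(ofcom_score(0, 0, 0, 0, 0, 0, "banana"), "fvn_level")
})

test_that("FVN assumption levels map to their point values", {
  expect_equal(fvn_points("MIN"), 0)
  expect_equal(fvn_points("LOW_MID"), 1)
  expect_equal(fvn_points("HIGH_MID"), 2)
  expect_equal(fvn_points("MAX"), 5)
  expect_error(fvn_points("AVERAGED_MID"), "AVERAGED_MID")
})

test_that("protein points are capped at high A-points unless FVN is maximal", {
  # satfat 10.5 -> 10 pts, sodium 91 -> 1 pt, so A = 11 (the cap)
  capped <- ofcom_score(0, 10.5, 0, 91, 0, 8.1, "MIN")
  expect_true(capped$protein_capped)
  expect_equal(capped$total_score, 11)
  uncapped <- ofcom_score(0, 10.5, 0, 91, 0, 8.1, "MAX")
  expect_false(uncapped$protein_capped)
  # MAX restores 5 FVN points and the 5 protein points
  expect_equal(uncapped$total_score, 11 - 5 - 5)
  # below the cap, protein always counts
  low_a <- ofcom_score(0, 0, 0, 91, 0, 8.1, "MIN")
  expect_false(low_a$protein_capped)
  expect_equal(low_a$total_score, 1 - 5)
})

test_that("a zero-nutrient beverage at minimum FVN scores exactly zero", {
  sc <- ofcom_score(0, 0, 0, 0, 0, 0, "MIN")
  expect_identical(sc$total_score, 0)
  expect_identical(sc$a_points, 0L)
  expect_identical(sc$c_points, 0)
})

test_that("AVERAGED_MID totals are the mean of the two mid-level scores", {
  prof <- random_profiles(300, seed = 11)
  lo <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                    prof$sodium_mg, prof$fibre_g, prof$protein_g, "LOW_MID")
  hi <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                    prof$sodium_mg, prof$fibre_g, prof$protein_g, "HIGH_MID")
  av <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                    prof$sodium_mg, prof$fibre_g, prof$protein_g, "AVERAGED_MID")
  expect_equal(av$total_score, (lo$total_score + hi$total_score) / 2)
  # every score is a multiple of 0.5 and twice it is an integer
  expect_true(all(av$total_score * 2 == round(av$total_score * 2)))
})

test_that("scores match the independent table-lookup oracle exactly", {
  prof <- random_profiles(2000, seed = 23)
  got <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                     prof$sodium_mg, prof$fibre_g, prof$protein_g,
                     prof$fvn_level)$total_score
  want <- vapply(seq_len(nrow(prof)), function(i) {
    oracle_ofcom(prof$energy_kcal[i], prof$satfat_g[i], prof$sugars_g[i],
                 prof$sodium_mg[i], prof$fibre_g[i], prof$protein_g[i],
                 prof$fvn_level[i])
  }, numeric(1))
  expect_identical(got, want)
  # pure function: repeated calls agree bit-for-bit
  again <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                       prof$sodium_mg, prof$fibre_g, prof$protein_g,
                       prof$fvn_level)$total_score
  expect_identical(got, again)
})

test_that("the total score is monotone in each nutrient and in FVN level", {
  prof <- random_profiles(200, seed = 31)
  base <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                      prof$sodium_mg, prof$fibre_g, prof$protein_g,
                      prof$fvn_level)
  set.seed(32)
  bump <- runif(nrow(prof), 0, 200)
  for (col in c("energy_kcal", "satfat_g", "sugars_g", "sodium_mg")) {
    up <- prof
    up[[col]] <- up[[col]] + bump
    sc <- ofcom_score(up$energy_kcal, up$satfat_g, up$sugars_g,
                      up$sodium_mg, up$fibre_g, up$protein_g, up$fvn_level)
    expect_true(all(sc$total_score >= base$total_score), info = col)
  }
  more_fibre <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                            prof$sodium_mg, prof$fibre_g + runif(200, 0, 4),
                            prof$protein_g, prof$fvn_level)
  expect_true(all(more_fibre$total_score <= base$total_score))
  # non-increasing along the FVN ladder
  ladder <- c("MIN", "LOW_MID", "HIGH_MID", "MAX")
  scores <- sapply(ladder, function(lv) {
    ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                prof$sodium_mg, prof$fibre_g, prof$protein_g, lv)$total_score
  })
  expect_true(all(diff(t(scores)) <= 0))
  # more protein never raises the score while uncapped at both points
  more_prot <- ofcom_score(prof$energy_kcal, prof$satfat_g, prof$sugars_g,
                           prof$sodium_mg, prof$fibre_g,
                           prof$protein_g + runif(200, 0, 5), prof$fvn_level)
  ok <- !base$protein_capped & !more_prot$protein_capped
  expect_true(all(more_prot$total_score[ok] <= base$total_score[ok]))
  # bounded for single-level FVN
  single <- prof$fvn_level != "AVERAGED_MID"
  expect_true(all(base$total_score[single] >= -15 &
                    base$total_score[single] <= 40))
})

test_that("point tables load from config, with selectable fibre basis", {
  tab <- ofcom_point_tables()
  expect_s3_class(tab, "ofcom_tables")
  expect_equal(tab$cap_a_points, 11)
  expect_equal(tab$fibre_basis, "aoac")
  nsp <- ofcom_point_tables(fibre_basis = "nsp")
  expect_equal(nsp$fibre, c(0.7, 1.4, 2.1, 2.8, 3.5))
  # fibre 0.8 earns a point on the NSP table only
  expect_equal(ofcom_score(0, 0, 0, 0, 0.8, 0, "MIN", tables = nsp)$total_score, -1)
  expect_equal(ofcom_score(0, 0, 0, 0, 0.8, 0, "MIN", tables = tab)$total_score, 0)
  # a truncated config is rejected
  broken <- tempfile(fileext = ".conf")
  writeLines("energy_kj = 335, 670", broken)
  expect_error(ofcom_point_tables(broken), "missing keys")
})
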