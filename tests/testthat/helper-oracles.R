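# Independent oracles, deliberately coded without reusing package
# internals: scalar loops and hard-coded thresholds.

oracle_ofcom <- function(energy_kcal, satfat, sugars, sodium, fibre, protein,
                         fvn_level) {
  pts <- function(x, thr) {
    p <- 0L
    for (t in thr) if (x > t) p <- p + 1L
    p
  }
  score_at <- function(level) {
    a <- pts(energy_kcal * 4.184,
             c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350)) +
      pts(satfat, 1:10) +
      pts(sugars, c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45)) +
      pts(sodium, seq(90, 900, by = 90))
    fvn <- switch(level, MIN = 0, LOW_MID = 1, HIGH_MID = 2, MAX = 5)
    fib <- pts(fibre, c(0.9, 1.9, 2.8, 3.7, 4.7))
    pro <- pts(protein, c(1.6, 3.2, 4.8, 6.4, 8.0))
    if (a >= 11 && fvn < 5) pro <- 0L
    a - (fvn + fib + pro)
  }
  if (fvn_level == "AVERAGED_MID") {
    (score_at("LOW_MID") + score_at("HIGH_MID")) / 2
  } else {
    score_at(fvn_level)
  }
}

oracle_dietary_score <- function(scores, grams, ref) {
  num <- 0
  den <- 0
  for (i in seq_along(scores)) {
    p <- grams[i] / ref[i]
    num <- num + scores[i] * p
    den <- den + p
  }
  num / den
}

oracle_replicate_variance <- function(x, w, rw) {
  wm <- function(x, w) {
    s <- 0
    tot <- 0
    for (i in seq_along(x)) {
      s <- s + w[i] * x[i]
      tot <- tot + w[i]
    }
    s / tot
  }
  est <- wm(x, w)
  B <- ncol(rw)
  acc <- 0
  for (b in seq_len(B)) {
    acc <- acc + (wm(x, rw[, b]) - est)^2
  }
  list(estimate = est, se = sqrt(acc / B))
}

# random profiles spanning the scoring tables, with a sprinkling of
# values sitting exactly on thresholds to exercise strict comparisons
random_profiles <- function(n, seed) {
  set.seed(seed)
  df <- tibble::tibble(
    energy_kcal = stats::runif(n, 0, 900),
    satfat_g = stats::runif(n, 0, 12),
    sugars_g = stats::runif(n, 0, 50),
    sodium_mg = stats::runif(n, 0, 1100),
    fibre_g = stats::runif(n, 0, 6),
    protein_g = stats::runif(n, 0, 10),
    fvn_level = sample(fvn_levels, n, replace = TRUE)
  )
  on_thr <- seq_len(min(n, 50))
  df$satfat_g[on_thr] <- sample(1:10, length(on_thr), replace = TRUE)
  df$sodium_mg[on_thr] <- sample(seq(90, 900, 90), length(on_thr), replace = TRUE)
  df
}
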