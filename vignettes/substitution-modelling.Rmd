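---
title: "Modelling food substitution with the Ofcom nutrient profiling score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling food substitution with the Ofcom nutrient profiling score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(npsubstitute)
library(dplyr)
```

## The question the package answers

National 24-hour dietary recall surveys tell us what a population eats;
food-composition databases tell us what those foods are made of. If
consumers (or reformulating manufacturers) shifted each consumed food to
a *similar product in the same food category* with a more favourable
nutrient profile, how much would population intakes of calories,
saturated fat, sodium and total sugars change? `npsubstitute`
implements that substitution model end to end: it scores foods with the
UK FSA/Ofcom nutrient profiling (NP) model, swaps consumed foods for
better-scoring same-category alternatives under four scenarios, and
estimates the population-level change with survey-weighted bootstrap
variance and paired tests.

## The Ofcom score

The Ofcom NP model (the UK FSA 2004-05 model, developed to decide which
foods may be advertised to children) assigns, per 100 g of food:

* **A-points** (0-10 each) for energy, saturated fat, total sugars and
  sodium — increasing point bands, strict thresholds (a food on the
  boundary earns no point);
* **C-points** for fruit/vegetable/nut (FVN) content (0, 1, 2 or 5),
  fibre (0-5) and protein (0-5).

The total score is A-points minus C-points; *lower is better*. One
nonlinearity matters: when A-points reach 11, protein points are
withheld unless FVN points are at the maximum level (the "protein
cap"). Energy thresholds are tabulated in kJ while North American
databases report kcal, so values are converted (× 4.184) before lookup;
fibre thresholds default to the AOAC table for the same reason, with
the NSP table selectable. The thresholds themselves live in a versioned
plain-text config (`inst/extdata/ofcom_points_2004_2005.conf`), not in
code, so alternative threshold sets can be swapped in.

### FVN assumption levels

Aggregated food databases carry no ingredient lists, so the FVN
percentage cannot be computed. Each food therefore declares an
*assumption level*: `MIN` (0 points, e.g. cow's milk), `MAX` (top
level, e.g. apples), `LOW_MID` (just above 40%, 1 point), `HIGH_MID`
(just above 60%, 2 points), or `AVERAGED_MID` for ambiguous foods such
as a fruit-and-nut granola bar. An `AVERAGED_MID` food's score is the
mean of its two *complete* scores computed at `LOW_MID` and `HIGH_MID`
— the cap rule is re-evaluated at each level, and FVN points are never
averaged before scoring, because the cap is nonlinear in FVN points.
Averaged totals can thus be half-integers; scores are carried as reals
and compared by exact equality (every value is a multiple of 0.5, which
binary floating point represents exactly). Note that under the 2004-05
tables the cap can never differ *between* the two mid levels (neither
reaches the maximum FVN points), so averaging is exactly a half-point
adjustment; the two-pass implementation is kept because it is the
correct general rule for any threshold configuration.

```{r}
# plain brewed coffee: nothing in it, minimum FVN assumption
ofcom_score(0, 0, 0, 0, 0, 0, "MIN")$total_score
# an ambiguous mid-level food gets the mean of its two mid scores
ofcom_score(450, 6, 18, 300, 2.5, 5, "AVERAGED_MID")$total_score
```

## From foods to diets

Food tables are delimited files with per-100 g nutrients, a category
code, an FVN level and a *reference amount* (standard serving mass).
Missing nutrient cells are kept as explicit `NA` — never zero — and
repaired by `impute_missing_nutrients()` with the median of the same
nutrient within the same food category (mean-of-central-values for even
donor counts; the whole-database median with a warning in the rare case
of a donorless category). Imputation is idempotent and never touches a
non-missing cell. A missing reference amount is an error rather than an
imputable value, because it scales every portion downstream.

For one respondent's recall, each line's *portion* is grams consumed
divided by the food's reference amount, and the **dietary Ofcom score**
is the portion-weighted mean of per-food scores:

```{r}
dietary_ofcom_score(c(0, 4, 10), portion(c(200, 100, 100), c(100, 100, 100)))
```

Daily nutrient totals are the grams-weighted sums of the per-100 g
values. Only one recall day is modelled — the design compares
descriptive population means between scenarios, not usual intakes —
and respondents younger than 2 years or breastfeeding are excluded, as
is standard for such surveys. A respondent with an empty recall is
excluded with a warning rather than assigned zeros, which would distort
scenario means.

## The four substitution scenarios

A substitution map is computed once per distinct consumed food and
reused for every respondent, so substitution is deterministic and
identical across consumers of the same food. Candidates are always from
the same food category and must score *strictly* below the consumed
food's own score; a food with no such option is left as is.

* **Scenario 1A** (branded, optimistic): candidates are the branded
  products matched to the food in the branded-product cross-walk. Among
  those tied at the minimum score, a *composite* food is synthesised
  whose nutrients are their unweighted means.
* **Scenario 1B** (branded, realistic): all lower-scoring matched
  products are blended, weighted by market share (renormalised over the
  blend; unweighted with a warning if no shares are available).
* **Scenario 2A** (generic, optimistic): the lowest-scoring
  same-category generic food; ties broken by lower calories, then
  smaller food ID.
* **Scenario 2B** (generic, realistic): the food at the *next-lowest*
  score — the largest distinct candidate score below the original's —
  with the same tie-breaks.

Composites are rescored from their blended profile (a mean of
low-scoring foods does not necessarily score low, since the point bands
are nonlinear); if the rescored composite fails to beat the original,
the food is left as is, preserving the guarantee that every replacement
strictly improves the per-food score. A composite inherits the
original's reference amount, so portions are comparable between
baseline and scenario, and the most conservative constituent FVN level,
so synthesised foods never gain C-points by construction. Market-share
weighting in 1B deliberately excludes candidates tied *with* the
original ("lower-scoring" is read strictly). Grams consumed are held
fixed throughout: the scenarios replace what a food is made of, not how
much of it is eaten — which is why a realistic generic scenario can
*raise* calorie intake even as it lowers the score.

### Category overrides

In beverage-like categories the lowest-scoring food can be an
energy-dense outlier (a powdered cereal-grain coffee substitute scores
below brewed coffee but carries ~3.6 kcal/g), and substituting it into
every coffee consumed inflates population calories. Scenario 2A
therefore supports designated per-category substitutes; by default,
`default_overrides()` picks, for the cereal-grain/tea/coffee category
codes (`01C`, `51A`, `51B`), the lowest-calorie food at the
next-lowest distinct score. An override is only applied when its score
does not exceed the original's. Overrides are deliberately absent from
Scenario 2B (mirroring the asymmetry of the modelled design), which is
one driver of 2B's calorie increase.

## Estimation

Population means are survey-weighted; variance comes from the
survey-provided bootstrap replicate weights: the mean is recomputed
under each of the B replicate weight vectors and the variance is
`mean((theta_b - theta)^2)` — the Statistics Canada mean-bootstrap
convention, with no Fay factor, matching how public-use replicate
weights are intended to be used. Confidence intervals use the normal
1.96 multiplier. Scenario-versus-baseline comparisons are paired: the
per-respondent difference is formed first, then its weighted mean and
replicate SE, and the t statistic is referred to B − 1 degrees of
freedom (the replicate-based choice; the reference analysis is silent
on the df, and with hundreds of replicates the distinction is
immaterial). Significance is declared at p < 0.05, unadjusted. A subset
report recomputes partial intakes over only the foods that actually
received a branded substitute, the analogue of analysing the
substitutable corner of the diet on its own.

## The synthetic world

No national recall survey, food-composition database or branded
market-share database is redistributable, so `generate_world()` builds
a seeded emulation with the structural features the pipeline assumes:

* ~30 categories drawn from five archetypes (produce, beverage,
  packaged, staple, dairy) with lognormal per-100 g nutrient draws
  around archetype medians, FVN levels assigned by archetype
  (produce → `MAX`, beverages/dairy → `MIN`, packaged → `AVERAGED_MID`);
  ranges were chosen once so baseline synthetic diets land near
  1800 kcal/day, purely for plausibility;
* recalls of 5-15 items per respondent with grams proportional to the
  food's reference amount; ~2% of respondents under age 2 and ~1%
  breastfeeding, to exercise the eligibility filter;
* a branded database built by perturbing the generic foods it matches:
  8.0% of distinct consumed foods get a match and 2.9% a strictly
  lower-scoring match — the coverage of the motivating survey data —
  planted directly on the realised consumed set so the coverage report
  reproduces the targets up to rounding;
* main survey weights lognormal around 50 with B = 50 mean-one
  lognormal replicate multipliers by default (the real design's B = 500
  is configurable; 50 keeps routine runs fast at n = 2000 respondents,
  the problem size used throughout the tests).

All randomness flows from one seed through a fixed draw order
(categories → generic foods → respondents → recalls → match planting →
branded foods → weights), so worlds are byte-reproducible.

For parameter-recovery checks, `planted_sodium_delta` makes every
lower-scoring branded match an exact copy of its parent with sodium
reduced by δ mg/100 g, with parents' sodium drawn high enough
(δ + 250 to 900 mg) that the reduction always crosses a 90 mg point
band and therefore always triggers substitution; δ below 90 is
rejected for the same reason. The population sodium change then has a
closed-form value — minus δ/100 times the weighted mean grams of
planted foods consumed — which the pipeline must reproduce.

What the generator does *not* emulate: real demographic structure,
correlated food choices, distributions fitted to any real composition
database, or realistic market-share dynamics. Passing tests demonstrate
that the machinery is correct under the stated structural assumptions,
not that any particular real-world effect size is reproduced.

## A worked run

```{r, message = FALSE, warning = FALSE}
res <- run_pipeline(list(
  synth_seed = 7, n_respondents = 300, b = 20
))
res$results %>%
  filter(outcome %in% c("dietary_ofcom", "sodium_mg")) %>%
  select(scenario, outcome, estimate, se, diff, p_value)
```

The optimistic generic scenario (S2A) moves the population furthest;
the branded scenarios move only the ~3% of foods with a lower-scoring
branded match and are correspondingly modest; the realistic generic
scenario (S2B) improves scores least. `run_pipeline()` also returns a
manifest (input hashes, point-table version, B, package version) that
fully determines the outputs, and the substitution maps and per-stage
log counts for audit.

## Numerical choices and limitations

* Threshold comparisons are strict everywhere; scores are exact
  multiples of 0.5 and compared by equality.
* Floating-point output is rounded only at serialisation (6 significant
  digits), never internally.
* Ties in substitute selection resolve by calories then food ID, so
  maps are deterministic.
* The pass/fail "healthier" classification thresholds of the NP model
  are out of scope, as is usual-intake (multi-day) modelling and any
  behavioural model of whether consumers would actually switch; the
  scenarios are mechanical upper envelopes, not predictions.
* The branded cross-walk is an *input*: the fuzzy/threshold matching
  algorithm that produces it in practice is a separate concern and is
  not reimplemented here.
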