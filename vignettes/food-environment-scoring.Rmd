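---
title: "Scoring state food environments and predicting obesity rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring state food environments and predicting obesity rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodscape)
```

## The problem

Regional food environments shape diet, and diet shapes obesity. foodscape
quantifies a region's food environment from two crowd-sourced inputs — a
business-listing table (what kinds of food are on offer, at what price, with
what customer reception) and a nutrition-record table (how energy-dense the
popular dishes of each food category are) — and relates the result to the
region's adult obesity prevalence. The unit of analysis is a region (by
default the 49 US states plus DC, excluding New Jersey, whose surveillance
estimate is unavailable); the outcome is the self-reported adult obesity
rate in percent.

Three dimensions of food access are measured:

* **availability** of a category `c` in region `s`: the share of the
  region's food businesses carrying the category,
  `a_sc = N_sc / N_s`. A business may carry up to three category labels, so
  it contributes to up to three numerators but to the denominator once;
  availabilities therefore do not sum to 1 across categories.
* **affordability**: the mean ordinal price tier (1–4, the count of dollar
  signs in the listing symbol) of the category's businesses in the region.
* **acceptability**: the mean star rating (half steps, 0.5–5) and the mean
  review count of those businesses.

## Caloric density and the weighted score

Nutrition records carry free-text serving units in mixed dialects. Only
records whose unit is a gram variant (`g`, `gr`, `gram`, `grams`, after
trimming and lowercasing) can be compared on a common scale, so only those
enter density estimation:

* dish density (kcal/gram) = mean of `calories / serving_qty` over the
  dish's gram-denominated records;
* category density = unweighted mean over the category's popular dishes
  that have a density (a dish listed twice counts once; dishes with no gram
  record are excluded and counted). Being a mean, a category's density
  always lies inside the range of its dishes' densities — it can never
  exceed the densest dish, which is a useful sanity check on any reported
  aggregate.
* the region's **weighted score** = `sum_c(a_sc * d_c) / sum_c(a_sc)` over
  categories with availability > 0 *and* a density. The normalization by
  summed availability matters: because availabilities do not sum to one, an
  unnormalized sum would scale with how many categories a region's
  businesses list, not with how calorie-dense its offer is. The normalized
  score is invariant to rescaling all availabilities and is bounded by the
  contributing category densities — both properties are tested.

Dish names are joined across the two sources by exact match after
lowercasing and whitespace collapsing; no fuzzy matching is attempted, so
unmatched spellings simply leave a dish without records. No plausibility
filter is applied to gram quantities by default — a record claiming 10,000
kcal in 100 g is taken at face value — because any cap is a modelling
choice the user should make consciously.

## Inference

Two z-tests are provided. Between-region availability contrasts use the
pooled two-proportion z-test
(`z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`, `p` pooled), the textbook
variant for a shared-null proportion; a pooled estimate of exactly 0 or 1
carries no information and is reported as `z = 0, p = 1`. The
between-region *density* contrast assigns each business the mean density of
its categories and compares the two per-business samples with an unpooled
(Welch-type) z, since the two samples have no common variance under the
alternative. Contrast tables rank categories by the absolute availability
difference ("net value"), break ties by label, annotate significance tiers
(≤.001 / ≤.01 / ≤.05) and report raw p-values by default; a
Benjamini–Hochberg column is available via `adjust = "BH"` for users who
want multiplicity control, but it is off by default to keep the headline
ranking interpretable as published-style raw tiers.

## Features and prediction

`build_features()` assembles, per region: four columns per category
(availability, mean price, mean rating, mean reviews) and one weighted-score
column. Category–region combinations with no supporting data are filled
with 0 and counted; the zero-fill share is `zero_fill_fraction()`. Cells
backed by data are never altered. Businesses without a price tier are
excluded from the price mean but kept for ratings and reviews — dropping
one field beats imputing an ordinal tier. Column order is deterministic
(category label, then metric), and the matrix is invariant to business row
order.

`loocv_predict()` runs leave-one-out cross-validation: each region is
predicted by a model refitted from scratch on the other regions, and the
result is summarized by the Pearson correlation between actual and
predicted rates. Four families are supported: linear least squares (with a
minimum-norm pseudo-inverse fallback, and a warning, when features
outnumber training regions), random forest (100 trees), radial-basis
support-vector regression (library defaults), and gradient-boosted trees
(100 rounds). Hyperparameters are deliberately library defaults, exposed
via `model_spec()`: with ~50 observations there is no honest basis for
tuning, and defaults are transparent. Features are standardized with
*train-fold* statistics for the linear and kernel families (scale-sensitive)
and left raw for the tree families; fold-local standardization avoids
leaking the held-out region's scale. Stochastic families are re-seeded per
fold from the spec seed plus the held-out region's rank in the sorted
region universe, and training rows are put in canonical region order before
fitting, so per-region predictions are reproducible and invariant to input
row order. The single-feature weighted-score-only input is evaluated for
the linear family only; tree and kernel regressors on one feature are
marked not applicable in `evaluate_grid()`.

## The synthetic world

`generate_world()` produces complete input tables with planted truth, so
every stage is testable offline. What it emulates:

* multi-category businesses: three iid category draws per business from its
  region's mix, deduplicated, giving 1–3 distinct labels;
* region heterogeneity: Dirichlet(2) base mixes per region, tilted by
  `exp(skew * u_s * w_c)` where `u_s` is a latent region obesogenicity in
  [-1, 1] and `w_c` is the category's standardized density — regions thus
  lean toward high- or low-density offers, the structural analogue of the
  contrast between high- and low-obesity states;
* heavy-tailed review counts: log-normal with `meanlog = 3.56`,
  `sdlog = 1.44`, matched by moments to a listing-wide mean of ≈99 reviews
  with SD ≈260; price tiers with probabilities (.50, .42, .06, .02), mean
  1.60; ratings centred on 4.0 stars with SD 0.75, rounded to half steps;
* mixed serving-unit dialects: 30% of nutrition records use non-gram units
  by default; gram records have `E[calories/qty]` exactly equal to the
  category's planted density under multiplicative log-normal noise with
  coefficient of variation `calorie_noise_cv` (0.15 by default; 0 gives the
  exactly recoverable noiseless limit);
* a planted outcome link: `obesity_s = intercept + slope * E_s + eps`,
  `eps ~ N(0, sd)`, clamped to (5, 60)%.

The per-region truth `E_s` is defined as the *realized*
availability-weighted mean of planted category densities — the quantity the
estimation pipeline targets — rather than the latent mix expectation, so
that in the noiseless all-gram limit recovery is exact at every level
(dish, category, region score), not merely consistent.

Defaults are the study-scale desk configuration: 50 regions × 2000
businesses, 60 categories, 20 dishes per category × 8 records per dish.
The obesity link defaults (`intercept = -3`, `slope = 15`, `sd = 0.7`) were
fixed once from the generator's own geometry: the realized `E_s` spans
roughly 1.5–3.1 kcal/g with SD ≈0.36, so the generated rates span roughly
20–42% and the planted signal-to-noise ratio `slope * sd(E) / sd` is ≈7.5,
comfortably above the ≥5 regime in which recovery tests are meaningful. A
configuration whose signal is weaker than its noise (e.g. `slope = 0`)
warns but still generates, because null worlds are exactly what the
leakage-guard tests need.

What the generator does *not* emulate: geography (no spatial correlation,
no city/zip structure), chain businesses, temporal dynamics, review text,
and any nonlinearity or confounding in the environment–obesity link.
Passing recovery tests therefore shows the pipeline measures what it
defines, with correct plumbing and no leakage — not that the linear planted
link is how real obesity rates arise.

## Numerical and design choices

* Region universe is configuration, defaulting to the 50 analysis regions;
  regions missing from the outcome table are dropped with a warning.
* Ties in net-value ranking break by category label; all orderings in the
  package are deterministic.
* A region with zero businesses has *undefined* availability (flagged), not
  zero; a category merely absent from a region has availability zero.
* Zero variance anywhere a correlation is requested is an error, never NaN.
* Percentages quoted at two decimals in the worked examples are truncated,
  not rounded, matching the convention of the count-table displays they
  accompany.
* Test problem sizes: property tests run on worlds of 6–25 regions with
  30–150 businesses each; the planted-recovery acceptance checks run one
  full default-scale world (50 × 2000) and 20 null-slope worlds of 25 × 100.
  The whole suite completes in well under a minute on one CPU.

## Limitations

This is an ecological design: region-level associations say nothing about
individual risk, and the feature matrix has far more columns (4 × categories
+ 1) than the ~50 observations, so the linear family is always in the
pseudo-inverse regime and tree ensembles carry the predictive weight.
Listing categories are a coarse proxy for diet; density estimation trusts
crowd-sourced records and discards every non-gram record rather than
modelling unit conversions. The accessibility and accommodation dimensions
of food access are not represented, and no spatial measures (buffers, travel
times) are built.
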