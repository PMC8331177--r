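---
title: "Measuring and modelling delay discounting with ddcurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling delay discounting with ddcurve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcurve)
```

## The measurement problem

Delay discounting (DD) is the decline in the subjective value of a reward
as the delay to its receipt grows. In the adjusting-amount paradigm a
participant repeatedly chooses between a delayed reward (for example $2000
in 3 years) and an immediate amount that a staircase titrates toward the
point of indifference. `ddcurve` implements the complete analysis chain of
a two-group (patients vs controls) study of this task with two crossed
within-participant manipulations — reward magnitude (e.g. $100 vs $2000)
and episodic future thinking (EFT) cueing, in which participants imagine a
personal future event at the relevant delay before choosing.

## The staircase

Each block fixes a delayed amount $A$ and a delay, and opens with an
immediate offer of $A/2$. A choice of the delayed reward raises the next
offer by the current adjustment; a choice of the immediate reward lowers
it. The first adjustment is $A/4$ and each subsequent one is half the
preceding adjustment, *rounded to the nearest currency unit*. After six
choices, the offer that would have been presented on a seventh trial is
taken as the subjective value (SV) of the delayed reward.

```{r staircase}
st <- init_block(2000, 36)   # $2000 at 3 years
st$immediate_offer           # 1000
st <- staircase_step(st, "delayed")
st$immediate_offer           # 1500
st <- staircase_step(st, "immediate")
st$immediate_offer           # 1250
```

Two numerical choices deserve a note, because the verbal description of
the procedure does not fully determine them:

* **Rounding.** Each new adjustment halves the previously *rounded*
  adjustment, with ties rounded away from zero. This reproduces the
  canonical 1000 → 1500 → 1250 trace and keeps all offers integral. Under
  this rule an all-delayed block at $A = 2000$ passes through offers 1000,
  1500, 1750, 1875, 1938, 1970 and yields SV 1986.
* **Clamping.** For small amounts the rounding can overshoot the reward
  itself (at $A = 100$: 50, 75, 88, 95, 99, then 101). Presented offers
  are therefore clamped to stay strictly inside $(0, A)$, and the
  hypothetical seventh offer into $[0, A]$. Offers at the canonical
  magnitudes of interest never reach the clamp.

Because the adjustments halve geometrically from $A/4$, the staircase
brackets any deterministic indifference point to within $A/64$ plus a few
units of rounding slack; the test suite verifies
$|SV - \text{threshold}| \le A/64 + 5$ over a 200-point threshold grid.

## Discounting measures

Per participant, condition and magnitude the seven SVs (normalized by the
delayed amount) form an empirical discounting curve, summarized three
ways:

* **Hyperbolic fit.** $SV = 1/(1 + kD)$ with $D$ in days (1 week = 7,
  1 month = 30, 1 year = 365). `fit_hyperbolic()` minimizes the residual
  sum of squares over $k \in [0, 10]$ from a coarse logarithmic scan
  followed by golden-section refinement — deterministic, and verified in
  the tests against a 1000-point brute-force grid search. $R^2$ may be
  negative for nonmonotone curves; a flat curve has no variance to
  explain and is flagged `degenerate` ($R^2 = 1$ when residuals vanish).
* **Area under the curve (AuC).** Delays are normalized by the maximum
  delay (120 months), SVs by the delayed amount, and the area is the
  trapezoid sum $(x_2 - x_1)(y_1 + y_2)/2$ over successive delays. A
  zero-delay anchor at $(0, 1)$ is prepended: without it a participant
  who never discounts could not attain the theoretical maximum of 1. The
  anchor convention is not universal in the literature; it is stated here
  so that results are interpretable.
* **Inconsistent preferences.** A point that *rises* above its
  predecessor by more than 10% of the delayed amount
  ($SV_2 > SV_1 + R/10$, strictly, consecutive delays only) counts as an
  inconsistency (0–6 per curve), a standard criterion for nonsystematic
  discounting data.

```{r curves}
d <- c(0.25, 1, 3, 6, 12, 36, 120)  # months; 0.25 = 1 week
sv <- 1 / (1 + 0.005 * months_to_days(d))
fit_hyperbolic(discounting_curve(d, sv))$k
auc(discounting_curve(d, sv))
```

## Group-level inference

`mixed_anova()` runs the classical univariate split-plot ANOVA — one
between factor (group), two within factors (condition, magnitude) — with
Type III (unweighted-means) sums of squares, the convention of mainstream
commercial packages, so a 12 vs 41 design yields the familiar
$F(1, 51)$ tests. Effect sizes are partial $\eta^2 =
SS_\text{eff}/(SS_\text{eff}+SS_\text{err})$. No sphericity correction is
applied: with two-level within factors sphericity holds trivially.
`fisher_lsd()` provides unprotected pairwise post hocs using the pooled
error term of the stratum in which the compared cells differ; which error
term an original commercial analysis used for interaction cells is
generally not reported, so the choice (and the resulting df) is explicit
in the output.

Summary-statistic utilities cover the remaining tests that papers report
from printed means and SDs: `pooled_t()` (Student's pooled-variance
two-sample t), `chi_square_2x2()` (Pearson, uncorrected — a Yates
correction would not reproduce typical printed values), and
`jzs_bf_ttest()`, the default-prior (JZS) Bayes factor with a Cauchy
scale of $\sqrt{2}/2 \approx 0.707$ on the standardized effect,
marginalized by numerical integration. The implementation integrates over
the inverse-gamma $g$ representation; the tests cross-check it against an
independent quadrature that marginalizes the noncentral-$t$ likelihood
over the Cauchy prior directly. Note that Bayes factors recomputed from
*printed, rounded* summaries can differ noticeably from those computed on
raw data: rounding two-decimal means and SDs perturbs $t$, and the Bayes
factor is steeply convex in $t$ in the evidential range.

## The synthetic cohort

`simulate_study()` generates a full factorial data set — by default 12
patients and 41 controls, 2 conditions × 2 magnitudes × 7 delays × 6
choices — by running hyperbolic agents through the *actual* staircase
implementation. An agent discounts with baseline rate `k_small` (per
day), multiplied by `magnitude_multiplier` for the large reward and
`eft_multiplier` under EFT cueing; choices follow a logistic function of
the value difference normalized by the delayed amount (inverse
temperature `beta`) mixed with a `lapse` probability of random
responding. Normalizing the value difference makes the noise scale-free,
so magnitude effects in the simulation come from the rate multiplier, not
from the noise model. Low `beta` or high `lapse` produces nonmonotone
curves, exercising the inconsistency criterion.

Group parameters are log-normal in $k$ (rates are positive and heavily
right-skewed in empirical work) with log-normal jitter on the two
multipliers, truncated to $(0, 2]$. The shipped defaults
(`default_study_spec()`) were fixed by a one-time Monte-Carlo calibration
of the full staircase-to-AuC pipeline against four group-level anchors —
mean EFT effect (AuC difference EFT − Standard) near 0.26 in controls and
0.17 in patients, mean magnitude effect (large − small) near 0.14 in
controls and 0.01 in patients — with multiplier jitter chosen so the
between-participant spread of those effect scores approaches the 0.10–0.21
SD range such studies report. Under these defaults a typical simulated
study shows a strong condition effect and a group-by-magnitude
interaction without a group-by-condition interaction. Patients are also
noisier choosers (`beta` 6 vs 10, `lapse` 0.05 vs 0.02), yielding more
inconsistent preferences.

What the generator does *not* emulate: session order and practice
effects, reaction times, the content of EFT cues, correlations between
demographic variables and discounting, and any trial-level dependence
beyond the staircase itself. Passing tests on synthetic cohorts therefore
validate the *pipeline arithmetic and statistics*, not the psychological
model of any real population.

```{r pipeline}
spec <- default_study_spec(seed = 42)
spec$n_patients <- 4L; spec$n_controls <- 6L   # small demo cohort
choices <- simulate_study(spec)
svs <- replay_choices(choices)                  # validates every offer
curves <- analyze_curves(svs)
head(curves, 4)
results <- reproduce(curves, inconsistency_table = curves, seed = 42)
results$anova_auc[, c("effect", "df_effect", "df_error", "F", "p",
                      "partial_eta_sq")]
```

`reproduce()` chains the inference stack (AuC ANOVA, LSD post hocs, both
Bayes factors from the derived per-participant difference scores, and the
inconsistency ANOVA when trial-level analytics are available) into a
single results bundle with provenance (seed, sizes, package version),
serializable with `write_results_json()`. Externally deposited
per-participant AuC tables can be fed into the same stack through
`read_auc_source()`, whose column mapping accommodates arbitrary CSV
layouts; `exclude_ids` supports sensitivity analyses that drop flagged
participants (e.g. by lesion extent).

## Numerical and design notes

* Problem sizes in the shipped tests: property checks use 100–1000
  randomized cases per invariant and Monte-Carlo checks use up to 200
  simulated studies, sizes at which all sampling error bounds used in the
  assertions are comfortable.
* All simulation is deterministic given `spec$seed`; the simulator
  consumes the RNG in a fixed order (agents, then block orders, then
  choices).
* `fit_hyperbolic()` snaps to $k = 0$ whenever the boundary is not
  strictly beaten by an interior optimum, so no-discounting data do not
  acquire spurious tiny rates.
* The ANOVA requires a complete crossed within design and at least two
  participants per group, and reports the offending participant/cell
  otherwise; partial missingness is out of scope by design (the staircase
  always yields complete blocks).
* Limitations: only the hyperbolic discount function is built in
  (exponential or two-parameter forms would slot into
  `fit_hyperbolic()`'s interface but are not provided); the Fisher LSD
  error-term convention for cross-stratum contrasts is a documented
  choice, not a reproduction of any specific commercial package; and the
  JZS integration targets two-sample designs only.
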