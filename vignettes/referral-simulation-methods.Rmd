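---
title: "Methods: facility quality profiling and counterfactual referral simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facility quality profiling and counterfactual referral simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(referralsim)
```

This vignette is the package's own account of its statistical machinery:
the models, the assumptions they rest on, the tunable parameters, what the
synthetic generator does and does not emulate, and the design choices made
where the design was genuinely open.

## 1. The estimand

For each patient in a held-out test cohort we ask what their model-expected
outcome (probability of a 30-day serious adverse event, expected length of
stay, expected standardized cost) would have been had the operation taken
place at an alternative, higher-quality facility, holding everything
patient-specific fixed. The reported contrast is the cohort mean of
original minus counterfactual predictions, with paired tests. It is a
*model-predicted* contrast: no outcome is re-drawn at the new facility, and
no causal claim beyond the fitted regression structure is made.

## 2. Facility quality: Wilson score midpoints

Facility event rates at low volume are dominated by noise: a 12-case
facility with zero SAEs is not evidently excellent. We therefore rank
facilities by the midpoint of the 95% Wilson score interval of their
training-cohort SAE rate,

$$ m = \frac{\hat p + z^2/2n}{1 + z^2/n}, $$

a weighted average of the observed rate $\hat p$ and $1/2$ with weights
$n$ and $z^2$. Key properties (all tested):

* $m$ lies strictly between $\hat p$ and $1/2$ (equality at $\hat p = 1/2$),
  and the shrinkage gap $|m - \hat p|$ is decreasing in $n$;
* $m$ is strictly increasing in $k$ at fixed $n$, so ranking is faithful
  to the data at equal volume;
* the closed form agrees with numerical inversion of the score test to
  $10^{-10}$, and the interval's coverage at $n = 30$, $p = 0.07$ sits in
  the documented 93–98% band.

Facilities are ranked by ascending midpoint (ties: larger $n$ first, then
facility id) and cut into quartiles at ranks $\lceil F/4 \rceil$,
$\lceil F/2 \rceil$, $\lceil 3F/4 \rceil$; quartile 1 is *best*. The
confidence level (default 95%) is exposed because no canonical value is
forced by the method. Facilities with no training encounters receive no
estimate and can be neither origins (their test patients are set aside and
counted) nor destinations.

## 3. Risk adjustment with facility fixed effects

Each outcome is fitted on the training cohort with the fixed covariate
set — age, race, sex, insurance, setting, admission type, discharge year,
facility volume tertile, patient–facility great-circle distance (3958.8-mile
sphere), Elixhauser category (0/1/2/3+) — plus one indicator per facility.
Families: logistic (SAE, components, readmission), Poisson (length of
stay), linear (cost in 2020 USD). Costs are standardized as
charges × cost-to-charge ratio ÷ wage index × CPI factor; the wage-index
division normalizes local price levels and is documented as a convention
(the direction is not dictated by the inputs), and the CPI table is a
small bundled year → factor lookup, overridable.

Three numerical points deserve note:

* **Collinearity.** Volume tertile is constant within facility and thus
  exactly collinear with the facility indicators. The facility terms enter
  the formula first; aliased tertile coefficients are recorded as zero and
  flagged. Their explanatory content is absorbed by the fixed effects, so
  predictions are unaffected.
* **Separation.** A facility with zero (or all) events has a divergent
  maximum-likelihood fixed effect — precisely the situation that motivates
  Wilson shrinkage for *ranking*. For *prediction* we refit the whole
  model with a weak ridge penalty (glmnet, λ = 10⁻³) applied to a full,
  symmetric set of facility dummies only, patient covariates and intercept
  unpenalized, then re-center so the reference facility's effect is zero.
  The symmetric encoding makes the fit independent of which facility is
  declared the reference.
* **Reference.** The reference facility defaults to the largest training
  volume; predictions are invariant to the choice (tested to 10⁻⁶ for the
  MLE path and exactly, by construction, for the penalized path).

The default counterfactual mode, `fixed_effect_only`, changes only
$\alpha_j$ between facilities, matching the prediction rule of the
simulation design; `full_facility_swap` additionally updates distance and
volume tertile for readers who want the fully-swapped covariate vector.
Both are exposed.

## 4. Referral rules

Eligible alternatives must sit in a strictly smaller quartile than the
origin; the proximity method additionally requires the destination within
30 miles of the patient's home zip centroid, the system method requires
the same health-system identifier as the origin (distance unlimited).
Which eligible facility to pick is not forced by the design, so both
policies are implemented: `best_quality` (lowest midpoint; ties to
nearest, then id — the default) and `nearest_eligible` (ties to lower
midpoint). Capacity constraints, patient preference and insurance networks
are deliberately out of scope.

Because quartiles come from Wilson midpoints while predictions come from
regression fixed effects, a mover can occasionally land at a facility
whose *fitted* α is not lower ("discordant" moves); the simulation summary
reports their share (typically a few percent on calibrated data).

## 5. The synthetic generator

The generator emulates the structure the analysis needs, with defaults
chosen once to mirror a parathyroidectomy cohort drawn from all-payer
state surgical databases:

* patient mix: 77% female, age ≈ N(64, 11) clamped to 18–95 (median 65),
  97% ambulatory, mostly white and Medicare/privately insured, Elixhauser
  categories ≈ 31/30/22/17%;
* facility quality: i.i.d. Normal log-odds offsets, sd 0.6, around a
  baseline logit(0.07) — giving a median facility SAE rate near 7% with an
  interquartile interval of roughly 5–10%;
* geography: homes and facilities uniform in a ~275 × 245-mile box; 30
  facilities by default, sized so that the 30-mile proximity rule yields a
  meaningful mover share (~20% at the defaults) comparable in order to
  observed referral studies;
* facility choice by a gravity rule (weight ∝ attractiveness ×
  exp(−distance/15 mi)), with lognormal attractiveness (sdlog 1.5)
  producing right-skewed volumes;
* outcomes: SAE drawn from the logistic truth model with covariates
  *centered at their configured marginals* (so the baseline logit is the
  rate of an average patient at a median facility), then attributed
  top-down to components so the composite definition holds exactly;
  Poisson length of stay and lognormal charges with facility-level
  offsets, both tied to the quality effect at reduced strength (0.5 and
  0.1 of the SAE effect respectively).

Sub-seeds for facilities, patients and outcomes derive deterministically
from the master seed, so changing the patient count leaves the facility
table untouched. A `case_mix_confounding` knob can tilt comorbidity burden
toward low-quality facilities; the default is zero — independence of case
mix and quality is an assumption, not a finding.

What the generator does *not* emulate: real zip-code geography, diagnosis
code semantics (outcomes are boolean flags), multi-encounter patients,
volume dispersion as extreme as real data (real annual volumes span
roughly 10–3000; the gravity mechanism here produces a milder skew), or
correlation between quality and volume. Passing tests therefore
demonstrate the *method's* correctness and calibration behaviour, not
fidelity of any particular clinical estimate.

## 6. Problem sizes and known limitations

The shipped tests run the pipeline at 12–30 facilities and 3,000–15,000
patients — sizes chosen so the full battery of property checks and
multi-seed replications completes quickly while leaving per-facility
volumes (hundreds of encounters) in the regime the method assumes.

Two limitations surfaced by the package's own acceptance checks are worth
stating plainly:

* **Information bound on fixed-effect recovery.** With ~200 encounters and
  ~16 events per facility, the sampling standard error of a facility
  log-odds effect is ≈ 0.27. When true effects have sd 0.5, the
  attenuation bound caps the expected correlation between fitted and true
  effects at ≈ 0.89, and quartile labels built from such estimates
  misclassify adjacent facilities routinely. Demands of near-perfect
  recovery at this scale are not achievable by any unpenalized estimator;
  at 1,000 encounters per facility the correlation comfortably exceeds
  0.9 (tested).
* **Selection on estimation noise under the null.** If all facilities are
  truly identical (effect sd 0), the simulation still predicts a small
  systematic SAE reduction (≈ −0.5 percentage points at the default
  scale). Both the quartile ranking and the fixed effects are estimated
  from the *same* training realization, so "higher-quality" destinations
  are partly facilities whose noise happened to be favourable — classic
  regression to the mean. A portion of any predicted improvement in this
  design is therefore attributable to selection on noise; an unbiased
  variant would rank facilities on data disjoint from the data used to
  fit the prediction model (e.g. split-half profiling), which this package
  exposes the pieces for but does not impose. The per-mover share whose
  predicted change exceeds estimation noise stays near the nominal 5%
  under the null (tested), which is the honest diagnostic to inspect
  alongside any headline contrast.

## 7. Reporting conventions

All p-values are two-sided; α = 0.05 is used only for flagging. Chi-square
tests carry no continuity correction and escalate to Fisher's exact test
for 2×2 tables with expected counts below 5 (larger sparse tables keep
chi-square with a warning). Signed-rank zeros are dropped and the count
reported; exact small-sample branches switch to tie- and
continuity-corrected normal approximations at n > 12 (signed-rank) and
min(n) > 8 (rank-sum), where the two branches agree within 0.02. Mean
differences carry t-based 95% confidence intervals. Categorical cells with
counts between 1 and 10 are masked in every human- and machine-readable
export, following the usual administrative data-use convention.
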