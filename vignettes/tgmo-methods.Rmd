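---
title: "Models and methods behind tgmo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tgmo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgmo)
```

This vignette documents the statistical machinery of `tgmo`: the composite
experimental design, the stepwise second-order viability model and its
diagnostics, the drug-elimination and dose-refinement logic, the
Bliss-independence scoring, and the synthetic-data model the test suite is
built on. It also records the numerical and design choices made where more
than one defensible option existed.

## The screening design

A multidrug screen over $k$ drugs assigns each drug one of three coded
levels per combination: $-1$ (drug absent), $0$ (dose 1, the low dose) and
$+1$ (dose 2, the high dose). `assemble_oacd(k)` concatenates two parts:

* a **regular two-level fractional factorial** over $\{-1,+1\}$. Its job
  is to estimate linear and two-drug interaction effects over a large
  search space with few runs. We require resolution $\ge$ IV so that no
  drug's main effect is aliased with any two-drug interaction. Generator
  words are fixed per panel size from standard minimum-aberration tables;
  for 11 drugs we use the $2^{11-4}$ fraction (128 runs) with generators
  $H{=}ABCD$, $J{=}ABEF$, $K{=}ACEG$, $L{=}BDFG$, whose shortest defining
  word has length 5 (resolution V — `resolution()` verifies this by
  enumerating the defining-contrast subgroup). 128 + 27 gives the familiar
  155-combination screen for 11 drugs.
* the **27-run three-level orthogonal array** OA$(27, 3^{13})$ of
  strength 2, built over GF(3) (each column is the inner product of the 27
  run vectors with one of the 13 projective directions of GF$(3)^3$) and
  truncated to the first $k$ columns. Squared codes are identically 1 on
  the two-level rows, so this part is what makes the quadratic terms
  estimable.

The vehicle control (all codes $-1$) is guaranteed present: the
orthogonal array's all-zero run recodes to it. Panel sizes for the
elimination rounds default to 11 → 7 → 4 but are arguments, not
assumptions: run counts for the intermediate rounds follow from the
generator table ($2^{7-2}+27 = 59$ for 7 drugs, $2^{4-1}+27 = 35$ for 4).

## Screening doses

Dose 2 is the ED20 — the dose inhibiting metabolic activity by 20% of the
untreated control on the single-drug curve — and dose 1 is exactly half of
it. Curves are fit with the four-parameter logistic
$y = b + (t-b)/(1 + (d/e)^h)$ by Levenberg–Marquardt with an analytic
Jacobian (a finite-difference Jacobian can freeze the log-EC50 when its
start value is numerically zero, so the derivative is supplied in closed
form). `effective_dose()` defines the inhibition level relative to the
zero-dose control, not to the curve span: a curve whose maximal inhibition
is 10% has no ED20 and the request fails rather than extrapolating. Flat
curves are flagged `no_effect` instead of being fitted to meaningless
parameters.

Clinical realism is imposed by the plasma concentration limit
$\mathrm{PCL} = \mathrm{AUC}_{0-24h}/24\,\mathrm{h}$, the time-averaged
plasma concentration at the clinically recommended dose. Dose 2 is capped
at the PCL (and falls back to it when the ED20 is unattainable), which
deliberately biases the screen toward the strongest interactions — a weak
synergy that needs supra-clinical doses is not one we want to find. AUC
values are user inputs per drug (µg·h/mL, converted to molar when a
molecular weight is given); the package computes trapezoidal AUC/Cmax
summaries from sparse sampled profiles but does not extrapolate beyond the
last sample.

## The viability model

Responses are viability in % of control. The model is the full
second-order surface in the coded doses,

$$y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
      \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon,$$

with terms chosen by bidirectional stepwise selection: starting from the
intercept-plus-linear model, the candidate with the smallest partial-F
p-value enters while below `p_enter` (default 0.05) and the least
significant selected term leaves while above `p_remove` (default 0.10).
These defaults mirror the long-standing stepwise-regression convention.
Any second-order term may enter regardless of whether its parent linear
terms are currently selected (parents stay in the candidate pool but are
not forced in). Ties are broken by smaller p-value, then column order
(drugs in panel order, pairs lexicographic), so selection is
deterministic. A visited-state check and a step cap guard against
entry/removal cycling.

Noise-free inputs need care: with zero residual variance the F statistics
are 0/0. Selection then falls back to sum-of-squares comparisons at a
relative tolerance of $10^{-10}$ of the total SS, which is what makes the
fit recover an exact sparse truth term-for-term (and agree with ordinary
least squares on the active set to 8+ digits — the test suite checks this
against an independent `lm.fit` oracle).

Interpretation follows the response-surface sign conventions: negative
linear or interaction coefficients are efficacious/synergistic, positive
are stimulatory/antagonistic, and for the quadratic (drug²) terms a
positive coefficient means the effect is stable over the tested dose
range while a negative one means it is dose-dependent. $R^2$ is the
ordinary (unadjusted) coefficient of determination, defined as 0 for a
constant response.

The **therapeutic window** is the per-combination difference between
nonmalignant and tumor viability, modelled with the same machinery. We
model the raw difference of per-row replicate means without
re-normalization — an assumption, since the difference of two %-CTRL
scales is itself well-defined only up to that choice. With this sign
convention the desirable pattern is a negative efficacy coefficient
paired with a positive TW coefficient, and `classify_interactions()`
flags exactly that.

Replicate datasets can be fit separately and pooled (`fit_combined()`);
the pooled fit is the "combined model" used for reporting, and terms that
recur across the per-dataset fits with matching signs are the ones to
trust.

## Diagnostics

* **Lack of fit.** With replicated design rows the residual SS
  decomposes exactly into pure error (within-row scatter) and lack of fit;
  the F test compares their mean squares. Non-significance supports the
  second-order model; significance flags the rare case where a
  higher-order surface would be needed. The decomposition identity
  $SS_{res} = SS_{lof} + SS_{pe}$ is asserted exactly in the tests, and
  the test's type-I error is calibrated by simulation (200 correct-model
  screens; the rejection rate must stay in $[0.02, 0.09]$ at
  $\alpha = 0.05$).
* **Cook's distance** is computed from the hat matrix
  ($D_i = r_i^2 h_{ii} / (p\, s^2 (1-h_{ii})^2)$) and is tested to agree
  with explicit leave-one-out refitting to $10^{-10}$. An exact fit
  returns all zeros (no residual variance, no influence).
* **Model variants.** Three fits are compared: the model on all data, the
  model with the single most influential observation removed, and the
  model with every observation above 3 × the mean Cook's distance (taken
  from the full fit, removed simultaneously, not iteratively). "The model
  on all data" is our reading of the first variant; stepwise selection is
  re-run per variant by default (`reselect = FALSE` refits the same
  terms). Terms selected in all variants with stable sign and p < 0.05
  are reported by `robust_terms()` and are the basis for elimination
  decisions.

## Elimination, ODC selection and dose refinement

Elimination is a scored codification of "keep the most active and
synergistic drugs, drop the most inactive and antagonistic": per drug,
+2 for each significant synergistic pair it belongs to, +1 for a
significant inhibitory linear term, +1 for a significant
selectivity-enhancing TW term, −2 per significant antagonistic pair, −1
if the drug carries no significant term at all. The weights are
configurable; ties break by the more negative linear estimate, then panel
order. Scores are categorical rather than magnitude-weighted, which keeps
the rule transparent; the cost is that a borderline-significant small
effect counts as much as a large one, a limitation accepted deliberately.

`select_odc()` enumerates all 3- and 4-drug subsets of the final panel at
the available dose codes and optimizes lexicographically: minimize
predicted tumor viability first, and within a tie-band (default 5
percentage points) prefer the larger predicted therapeutic window. This
avoids inventing a weighted efficacy/selectivity composite. If even the
best candidate inhibits less than `min_inhibition` (default 10 pp) the
result carries a warning flag rather than failing.

`refine_doses()` then searches fractional codes in $[-1, +1]$ per
combination drug on a grid (default 9 points per drug). The fitted
surface is quadratic, so a coarse grid is adequate and a gradient method
would add nothing; grid density is configurable. Fractional codes map
piecewise-linearly to concentrations (code 0 = dose 1, +1 = dose 2; and
because dose 1 is exactly half of dose 2, concentration is proportional
to code + 1), refined concentrations are checked against the PCL, and a
dose-sparing table reports predicted viability at 100/75/50% of the
refined concentrations.

## Bliss independence and in-vivo scoring

For $k$ single-drug fractions remaining $F_1,\dots,F_k$ (tumor volume or
viability vs 100% control; values above 1 allowed, as growth-stimulating
drugs occur), the Bliss prediction is the product $\prod F_i$. Because
the field sometimes quotes this product directly on a percent scale as an
"inhibition rate" even though it is, by construction, the predicted
*remaining* fraction, `bliss_ir()` returns all three quantities under
unambiguous names (`product`, `paper_pct` = 100 × product,
`complement_pct` = 100 × (1 − product)) and leaves the choice explicit.
`classify_combination_effect()` compares an observed combination effect
with the prediction using a ±5-pp additivity band by default (no
published consensus tolerance exists; the band is configurable).

The caliper tumor-volume helper defaults to the standard ellipsoid
approximation $V = d_{small}^2 \, d_{big}/2$; a literal
"$d_{small}^2 + d_{big}/2$" reading sometimes seen in print is available
behind `formula = "sum"` but is dimensionally incoherent and not
recommended.

## The synthetic-data model

Simulated screens are generated exactly from the second-order model:
a `make_truth()` object fixes $\beta$ coefficients per population, the
intercept is solved so the vehicle control sits at 100% CTRL, and
homoscedastic Gaussian noise (default sd 5 % CTRL) is added independently
per replicate (default 3 technical replicates). Because the generator
satisfies the model assumptions exactly, the calibration tests
(lack-of-fit type-I error) are well-posed. Coefficient magnitudes in the
preset scenarios (linear −8 to −15, interactions −10 to −15 % CTRL) are
chosen to resemble the coefficient scales seen in real low-dose screens;
they are fixtures with a documented rationale, not measured values.

What the generator deliberately does **not** emulate: heteroscedastic or
plate-positional noise, non-quadratic dose–response curvature inside the
coded range, biological replicate-to-replicate drift, and any mechanism
linking tumor and nonmalignant responses. Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to every artifact of real plates — the
Cook's-distance variant workflow exists precisely because real screens
violate these assumptions occasionally.

Problem sizes used by the validation suite were chosen to exercise the
method at realistic scale while staying quick on a laptop: the
recovery/retention study runs the full Search 1 → 3 pipeline on 200
seeded 11-drug screens (155 combinations × 3 replicates each round), and
calibration uses 200 simulations of the 35-run 4-drug design.

## Known limitations

* Third-order (three-drug) interaction models are not fitted; a
  significant lack-of-fit test is the pointer that one might be needed.
* The therapeutic window uses raw differences; alternative scalings
  (ratios, normalized differences) are not implemented.
* Elimination scores are categorical; magnitude-weighted variants are a
  plausible extension via the `weights` argument.
* `read_design()` round-trips codes and part labels but not generator
  words, so `resolution()` needs the in-memory design object.
* In-vivo dose conversion (mg/kg from in-vitro concentrations) and
  multi-cell-line consensus combinations are out of scope.
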