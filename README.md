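# tgmo — therapeutically guided multidrug optimization

`tgmo` is an R package for designing and interpreting phenotypic low-dose
drug-combination screens of the kind used to assemble optimized drug
combinations (ODCs) against cancer cells: a small panel of drugs (typically
around eleven) is screened at two low doses plus "no drug" across a compact
experimental design, cell viability is modelled with a second-order
response surface, and iterative rounds of drug elimination narrow the
panel to a 3–4-drug combination that maximizes tumor-cell kill while
sparing nonmalignant cells.

It is written for screeners and computational biologists who have viability
data (ATP readouts, % of control) from combination plates — or who want to
plan such a screen — and need the full analysis chain in one place:

* **Design.** `assemble_oacd()` builds the orthogonal-array composite
  design: a regular two-level fractional factorial of resolution ≥ IV
  (main effects clear of two-drug interactions) concatenated with the
  27-run three-level orthogonal array OA(27, 3¹³) that makes quadratic
  dose effects estimable. For 11 drugs this is the classic 128 + 27 = 155
  combination screen. Dose codes are −1/0/+1 = no drug / dose 1 / dose 2.
* **Dose selection.** `fit_four_param_logistic()` fits single-drug
  dose–response curves; `effective_dose()` extracts ED10/ED20;
  `plasma_concentration_limit()` computes the clinical cap
  PCL = AUC₀₋₂₄ₕ/24 h and `select_screen_doses()` applies it
  (dose 2 = min(ED20, PCL), dose 1 = dose 2 / 2).
* **Modelling.** `tgmo_fit()` fits the stepwise second-order regression

  y = β₀ + Σᵢ βᵢ xᵢ + Σᵢ βᵢᵢ xᵢ² + Σᵢ<ⱼ βᵢⱼ xᵢxⱼ + ε

  on the coded doses, with bidirectional partial-F term selection.
  Negative βᵢ / βᵢⱼ = efficacy / synergy; positive = stimulation /
  antagonism; the sign of βᵢᵢ distinguishes dose-dependent from
  dose-range-stable contributions. `fit_therapeutic_window()` models the
  nonmalignant-minus-tumor difference (TW) the same way.
* **Diagnostics.** `lack_of_fit_test()` (replicate-based ANOVA),
  `cooks.distance()`, `build_model_variants()` (full / max-outlier-removed /
  Cook's > 3×mean removed) and `robust_terms()` identify the coefficients
  that survive outlier handling.
* **Selection.** `classify_interactions()`, `eliminate_drugs()` (scored
  elimination per search round), `select_odc()` and `refine_doses()`
  (fractional-dose grid refinement with a TW tie-band).
* **Bliss scoring.** `bliss_ir()` computes the Bliss-independence
  prediction from single-drug fractions remaining;
  `classify_combination_effect()` calls synergy/additivity/antagonism.
* **Synthetic truth.** `make_truth()`, `simulate_screen()` and
  `preset_scenarios()` generate seeded screens with known coefficients so
  every stage can be validated end to end; `tgmo_run()` drives the whole
  Search 1 → 3 pipeline on such a truth.

## Worked example

An 11-drug panel in which drugs A and B are truly synergistic in tumor
cells only (the `selective_synergy` scenario; noise sd 5 % CTRL, technical
triplicates):

```r
library(tgmo)

assemble_oacd(11)
#> Orthogonal-array composite design: 11 drugs, 155 combinations
#>   three_level_oa: 27 rows
#>   two_level_ff: 128 rows
#>   generators: H=ABCD J=ABEF K=ACEG L=BDFG

sc  <- preset_scenarios()$selective_synergy
run <- tgmo_run(sc$tumor, sc$normal, seed = 42)
run
#> Multidrug optimization run (seed 42 )
#>   Search 1: 11 drugs -> kept A, B, C, D, H, J, K
#>   Search 2: 7 drugs -> kept A, B, C, H
#>   Search 3: 4 drugs -> kept A, B, C, H
#> Optimized drug combination: A + B + C + H
#>   dose codes: A=1, B=1, C=1, H=0
#>   predicted viability 28.5% CTRL (control 100.7), predicted TW +74.1 pp
```

The true synergistic pair A:B survives all three elimination rounds and
ends up in the ODC. The final-round tumor model recovers the generating
coefficients (truth: A −15, B −12, C −8, A:B −15):

```r
summary(run$rounds[[3]]$tumor)
#> Stepwise second-order viability model (tumor)
#>   n = 105   residual df = 100   sigma = 4.655   R-squared = 0.958
#>
#>         term        type estimate     se      t         p
#>  (Intercept)   intercept  79.6174 0.4543 175.25 2.92e-126
#>            A      linear -15.0793 0.5271 -28.61  5.93e-50
#>            B      linear -12.6573 0.5271 -24.01  2.61e-43
#>            C      linear  -8.3427 0.5271 -15.83  5.46e-29
#>          A:B interaction -15.0054 0.6010 -24.97  9.20e-45

lack_of_fit_test(run$rounds[[3]]$tumor)$p.value   # 0.797: model order adequate
```

The negative A:B term is the synergy call; its therapeutic-window
counterpart (`run$rounds[[3]]$tw`) carries the opposite sign, the
"efficacious in tumor, sparing in normal" pattern the search optimizes
for. A non-significant lack of fit (p = 0.80) says the second-order
surface is adequate for these data.

Bliss independence from four single-drug fractions of tumor volume
remaining:

```r
bliss_ir(c(0.90, 0.82, 0.62, 1.06))
#> $product        0.4850136     # predicted fraction remaining
#> $paper_pct      48.50136      # the product on the percent scale
#> $complement_pct 51.49864      # predicted % inhibition (1 - product)
```

## Command line

A thin CLI over the same functions lives at `inst/cli/tgmo.R`:

```sh
Rscript inst/cli/tgmo.R design   --drugs 11 --out design.csv
Rscript inst/cli/tgmo.R simulate --scenario selective_synergy --seed 7 --out screen.csv
Rscript inst/cli/tgmo.R fit      --design design.csv --responses screen.csv --out model.json
Rscript inst/cli/tgmo.R bliss    --fractions fractions.csv
Rscript inst/cli/tgmo.R run      --scenario one_synergistic_pair --seed 1 --out odc.json
```

See `vignettes/tgmo-methods.Rmd` for the modelling assumptions, parameter
choices and limitations.
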