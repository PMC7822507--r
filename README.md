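# pkarisk

Sequential population pharmacokinetic–pharmacodynamic modelling of
immunosuppressant exposure and urinary biomarkers in adult kidney
transplant recipients, for pharmacometricians and transplant
researchers who want to quantify how urinary miR155-5p expression (and
candidate markers such as CXCL-10, tacrolimus and mycophenolic acid
exposure) predicts the probability of acute rejection (AR).

The pipeline has three stages:

1. **Population PK.** Tacrolimus and MPA concentration–time data are
   described by two-compartment models with first-order absorption,
   lag time and fixed allometric scaling
   (CL, Q ∝ (W/70)^0.75; Vc, Vp ∝ W/70), with log-normal
   between-subject variability, estimated by a deterministic
   Laplace-type approximate marginal likelihood (`fit_poppk()`).
2. **Exposure.** Individual empirical-Bayes parameters give cumulative
   exposure AUC(0,t) = ∫₀ᵗ C·dt and mean trough concentrations per
   visit (`cumulative_auc()`, `mean_trough()`).
3. **Risk model.** A visit-level logistic regression
   logit(Pᵢ) = β₀ + Σ βᵢXᵢ links these predictors to AR, with each
   rejection placed on the visit *preceding* its diagnosis so the
   model is prognostic (`build_logistic_dataset()`, `fit_logistic()`,
   `risk()`, `select_explanatory()`).

Model evaluation follows pharmacometric practice:
prediction-corrected VPC (`pcvpc()`), categorical VPC and grouped-bar
calibration for the binary outcome (`categorical_vpc()`,
`grouped_bar()`), normalized prediction distribution errors
(`npde()`), and nonparametric bootstrap (`bootstrap_fit()`).

Because the underlying clinical data cannot be redistributed, the
package includes a synthetic-trial generator (`simulate_trial()`)
emulating the study design — 58 subjects, five visits over six months,
rich week-1 and sparse later sampling, twice-daily titrated dosing,
occasion-specific biomarker distributions with an elevated
pre-rejection component — and the published parameter estimates are
available as `tacrolimus_model()`, `mpa_model()` and the logistic
truth in `trial_config()`. See the methods vignette
(`vignettes/pkarisk-methods.Rmd`) for the models, calibration
decisions and limitations.

## Worked example

Simulate a complete synthetic trial at the study design, fit the
rejection-risk model, and evaluate risk at published coefficients:

```r
library(pkarisk)

trial <- simulate_trial(trial_config(), seed = 42)
nrow(trial$logistic)          # 189 visit records (study had 183)
trial$truth$n_ar_subjects     # 7 rejecting subjects (study had 8)

fit <- fit_logistic(trial$logistic, "miR155")
fit
#> Acute-rejection logistic regression (ML, Newton-Raphson)
#>   189 records, 7 events; MOFV = 41.138
#>             estimate     se rse_pct
#> (Intercept)   -5.010 0.8155   16.28
#> miR155         2.651 0.6567   24.77
```

A single 58-subject trial is a small sample for 7–8 events, so the
coefficients scatter around the generating values (β₀ = −5.89,
β₁ = 3.51); at n = 5000 records they are recovered within a few
percent (see the recovery study below). The forward/backward
likelihood-ratio selection retains miR155 and rejects the other
candidates, as in the study:

```r
select_explanatory(trial$logistic)$retained
#> [1] "miR155"
```

Risk predictions with the published model: a patient at the non-AR
miR155 level (~0) carries ~0.3% rejection risk per visit interval; at
the pre-AR geometric mean (1.5) this rises to ~35%:

```r
risk(list(beta0 = -5.89, beta1 = 3.51), c(0, 1.5))
#> [1] 0.0028 0.3486
```

The PK side is driven the same way, e.g.
`fit_poppk(tacrolimus_model(), trial$tac)` refits the tacrolimus model
to the simulated trial and prints an estimate/RSE%/shrinkage table;
`pcvpc(fit)`, `npde(fit)` and `bootstrap_fit()` evaluate it.

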