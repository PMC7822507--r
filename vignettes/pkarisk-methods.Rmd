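---
title: "Models and methods: immunosuppressant exposure, urinary miR155-5p and the risk of acute kidney-graft rejection"
author: "pkarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Adult kidney-transplant recipients receive tacrolimus and mycophenolate
mofetil (MMF, the prodrug of mycophenolic acid, MPA) titrated by
therapeutic drug monitoring (TDM). Despite titration, some patients
reject the graft. Urinary biomarkers — miR155-5p expression in the
urinary pellet (relative expression, $2^{-\Delta Cq}$ units) and CXCL-10
concentration (pg/mL) — rise before rejection and are candidate
prognostic markers. `pkarisk` implements a sequential population
analysis of this problem:

1. **Population pharmacokinetics.** Concentration–time data for each
   drug are described by a two-compartment model with first-order
   absorption, a lag time, and fixed allometric body-weight scaling,
   estimated by nonlinear mixed-effects (NLME) methodology.
2. **Exposure metrics.** Individual (empirical-Bayes) parameters give
   each patient's cumulative exposure $AUC(0,t)=\int_0^t C\,dt$ and
   mean pre-dose (trough) concentrations up to each study visit.
3. **Exposure–response.** A visit-level logistic regression links the
   probability of an acute-rejection (AR) episode to the candidate
   explanatory variables, with each rejection assigned to the record of
   the visit *before* its diagnosis, so the model measures prognostic
   rather than concurrent association:
   $$\operatorname{logit}(P_i) = \beta_0 + \sum_i \beta_i X_i .$$
4. **Model evaluation.** Prediction-corrected visual predictive checks
   (pcVPC) for the continuous PK data, a categorical VPC and a 10-bin
   grouped-bar calibration display for the binary outcome, normalized
   prediction distribution errors (npde), and nonparametric bootstrap.

Because the underlying clinical data cannot be redistributed, the
package ships a synthetic-trial generator (`simulate_trial()`) that
emulates the study design, and the validation strategy is
simulate-and-refit recovery of the published parameter values.

# Structural PK model

The model is parameterised by apparent clearance CL/F, central and
peripheral volumes Vc/F and Vp/F, intercompartmental clearance Q/F,
absorption rate constant Ka and lag time tlag (all "per 70 kg"
reference values). Micro-constants $k_{10}=CL/V_c$, $k_{12}=Q/V_c$,
$k_{21}=Q/V_p$ give disposition exponents $\alpha,\beta$ (roots of
$\lambda^2-(k_{10}+k_{12}+k_{21})\lambda+k_{10}k_{21}$), and a single
oral dose contributes the familiar three-exponential profile
$C(t) = \frac{D\,K_a}{V_c}\sum_k c_k e^{-\lambda_k (t - t_D - t_{lag})}$.

Design choices worth recording:

* **Superposition over explicit dose events.** No steady-state
  shortcut is used; the dosing history is an explicit event record.
  Runs of identical doses on a regular grid are summed in closed form
  by geometric series — algebraically identical to dose-by-dose
  superposition — so a six-month twice-daily history (about 360 doses)
  costs the same as a handful of doses. This matters because the
  likelihood machinery evaluates each subject's profile thousands of
  times.
* **Degenerate absorption rates.** If Ka collides with a disposition
  exponent (relative distance below $10^{-8}$) the three-exponential
  form is rescued by nudging Ka by a relative $10^{-8}$; the
  perturbation is far below any data-resolvable difference.
* **Allometry.** Flow parameters scale with $(W/70)^{0.75}$ and
  volumes with $(W/70)^{1}$; the exponents are fixed by convention,
  never estimated.
* **Units.** Time is hours; doses mg; tacrolimus concentrations ng/mL
  (`conc_scale = 1000` maps mg/L model output to ng/mL) and MPA
  µg/mL (`conc_scale = 1`). MMF doses are converted to MPA molar
  equivalents with the molecular-weight ratio 320.34/433.49; the
  conversion factor is a chemical constant, not a fitted quantity.
* **Cumulative AUC** is integrated analytically per exponential term;
  quadrature exists in the test suite only, as an oracle.

The published parameterisations are available as `tacrolimus_model()`
(CL/F 16.5 L/h/70 kg, Vc/F 311 L, Q/F 20.5 L/h, Vp/F 56300 L, Ka
3.08 1/h, tlag 0.295 h; BSV on CL/Q/Vc of 57.6/68.9/55.6%; additive
residual error of 36.6% on log-transformed data) and `mpa_model()`
(CL/F 11.8 L/h/70 kg, Vc/F 106 L, Q/F 37.1 L/h, Vp/F fixed at 800 L,
Ka 1.79 1/h, tlag 0.243 h; BSV on CL/Vc/Vp of 34.9/133.8/164.6%;
proportional residual error of 55.3%).

# Estimation: a deterministic Laplace-type marginal likelihood

Between-subject variability is log-normal,
$\theta_i = \theta_{pop} (W_i/70)^{e} e^{\eta_i}$,
$\eta \sim N(0, \Omega)$. The reference analysis estimated the models
by SAEM with importance-sampling objective evaluation; this package
substitutes a deterministic approximation targeting the same marginal
likelihood, which makes every fit exactly reproducible and testable:

* Per subject, the joint negative log-density $h(\eta)$ is minimised
  by a damped Newton iteration whose Hessian is the Gauss-Newton
  (first-order-conditional) matrix $J^TWJ + \Omega^{-1}$, with the
  residual Jacobian $J$ obtained by central differences.
* The marginal contribution is the Laplace expression
  $-2\log L_i = 2h(\hat\eta) + \log\det H - d\log 2\pi$; summing over
  subjects gives the objective function value (MOFV, $-2\log L$). On
  models whose prediction is linear in $\eta$ this is exact, which is
  how the machinery is unit-tested against a closed-form
  linear-mixed-model oracle.
* The outer problem (log typical values, log diagonal $\Omega$
  variances, log residual SD, covariate coefficients) is solved by a
  quasi-Newton box-constrained optimiser with an explicit
  forward-difference gradient (step $10^{-5}$). The gradient is
  evaluated in two regimes: a fast *envelope* form — at the inner mode
  the objective's outer gradient equals the partial derivative with
  the modes and residual Jacobians frozen, so each component costs one
  profile evaluation per subject — followed by an exact-gradient
  polish stage that removes the envelope form's small residual drift
  along flat directions (the neglected log-determinant mode-shift
  term). The explicit step matters: per-subject modes are warm-started
  across outer iterations, which leaves $\sim 10^{-8}$ evaluation
  noise that would swamp a machine-precision difference step.
* Convergence is declared at a relative MOFV change below $10^{-6}$.
  By default, initial typical values come from a naive-pooled pre-fit
  — except the absorption parameters (Ka, tlag), which keep the
  supplied starting values because pooling across subjects smears the
  absorption peak and systematically distorts them — and
  between-subject variances start at 0.1 (log-scale variance). The
  simulate-and-refit recovery studies instead start from the published
  model itself (`pooled_init = FALSE`), which is the defining
  configuration of such a study and empirically reaches the best
  objective values.

**Residual models.** Additive on log-transformed observations
(reported as ~% on the original scale), proportional, additive, and
combined error models are supported; for proportional error the
weighting uses the individual prediction (interaction).

**Reporting conventions.** BSV% is $100\sqrt{\omega^2}$ (log-scale SD
as a percentage); this matches the magnitude of published values such
as 133.8%, which are impossible under the small-variance CV reading.
RSE% comes from the inverse observed information (numerical Hessian of
the objective, evaluated with inner modes restarted from the fitted
EBEs so the objective is deterministic); the delta method maps
log-scale SEs to the reported quantities. The condition number is the
eigenvalue ratio of the *correlation* matrix of the estimates, flagged
at 1000. $\eta$-shrinkage is $100(1-SD(EBE)/\omega)$ and
$\epsilon$-shrinkage $100(1-SD(IWRES))$.

**Identifiability guard.** With a first post-dose sample at 0.5 h, lag
times approaching 0.5 h become indistinguishable from instantaneous
absorption: the likelihood develops a flat ridge along which
$t_{lag} \to$ first sample and $K_a \to \infty$ with essentially
unchanged fit everywhere else. Estimation therefore bounds $t_{lag}$
below 80% of the smallest observed time-after-dose (plus broad ±4
log-unit sanity envelopes around the initial values for all
parameters). Disposition and variability estimates are insensitive to
the position on this ridge; absorption constants reported near the
bound should be read as "fast, weakly identified", mirroring the
reference analysis's own difficulty with the absorption phase (Ka RSE
39%).

**Scope.** $\Omega$ is estimated diagonal. Block (correlated) $\Omega$
and interoccasion variability are supported in *simulation* but not
searched during estimation; EBE correlation screening is the intended
trigger for a block structure, and the final published models carry
neither a block nor IOV. MU-referencing is a NONMEM-internal device
with no counterpart here.

# Covariate machinery

`stepwise_covariates()` implements forward inclusion (retain if MOFV
drops by at least $\chi^2_1(0.05)=3.841$) and backward elimination
(retain only if removal raises MOFV by at least
$\chi^2_1(0.001)=10.828$) over linear, power and exponential
covariate-parameter relationships centred at the population median.
Candidates whose refit fails are skipped and logged; AIC is reported
for non-nested comparisons. The fitting function is injectable, which
keeps the decision logic testable without paying for full NLME refits
in every logic test.

# The logistic stage

`build_logistic_dataset()` assembles one record per subject-visit from
individual predicted exposures (cumulative AUC and mean trough, both
evaluated at the subject's empirical-Bayes parameters with the PK
stage fixed) and observed biomarker levels, then applies the
prior-visit shift. A rejection diagnosed at the first available visit
has no predecessor; it is assigned to that same first record and
counted separately (`n_first_visit_events`) — dropping those events
would discard half of the observed episodes. Records with missing
predictors are dropped and counted. Biomarker values enter on their
tabulated relative-expression scale, untransformed, because the
published slope is on that scale; the outcome-1 record carries the
prior visit's *observed* biomarker value, not an interpolation.

`fit_logistic()` maximises the Bernoulli likelihood by damped
Newton-Raphson (an authored implementation, cross-checked in the test
suite against `stats::glm`, which is never in the execution path).
Complete separation is detected and reported with the offending
predictor named. `select_explanatory()` reuses the forward/backward
thresholds above. `risk()` is the inverse-logit evaluation with the
published coefficients $\beta_0 = -5.89$, $\beta_1 = 3.51$ available
as the default truth in `trial_config()`.

# The synthetic-trial generator

`simulate_trial()` emulates the study: 58 subjects; visits at week 1
(day uniform on 1–11) and months 1, 2, 3, 6; rich week-1 sampling
(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12 h post-dose) and sparse later
sampling (0, 1.5, 2, 4 h); twice-daily dosing from transplant with
occasion-specific mean daily dose levels (tacrolimus
14.60/10.63/7.78/6.79/5.29 mg/day; MMF 1875.91 → 1238.67 mg/day,
converted to MPA equivalents), each level holding to the midpoint
between visits; body weight log-normal with median 73 kg and IQR
62.9–86.8. Calibration choices that deserve explanation:

* **Dose interpretation.** The published occasion doses are read as
  *daily* totals split over two administrations: ~14.6 mg/day of
  tacrolimus in week 1 matches the usual 0.15–0.2 mg/kg/day, and the
  MPA dose table is explicitly labelled as daily MMF dose.
* **TDM emulation.** With static mean doses, the log-trough is concave
  in the random effects, so the simulated trough *geometric mean*
  falls ~35% below the observed values even though the typical-subject
  prediction matches. Observed troughs arise under titration that
  correlates dose with individual clearance. The generator therefore
  scales each subject's doses by
  $(C^{ref}_{trough}/C^i_{trough})^{g}$, clipped to $[1/3, 3]$, with
  the troughs evaluated on a steady twice-daily probe; the default
  strength $g = 0.9$ reproduces the observed week-1 trough geometric
  means (tacrolimus ≈ 7.0 vs 8.85 ng/mL observed, MPA ≈ 2.0 vs 2.37
  µg/mL) within the fidelity this approximation can offer. $g = 0$
  recovers static dosing. The titration feedback loop itself (doses
  responding to *measured* troughs over time) is not modelled.
* **Biomarkers.** miR155-5p and CXCL-10 are log-normal per occasion,
  with an elevated pre-rejection component (miR155 geometric mean
  1.50, IQR 1.15–1.85) mixed in with probability `p_elevated`. The
  published occasion IQRs describe the *marginal mixture*, so using
  them as component spreads inflates the tails — the heavy log-normal
  tail of the non-elevated component alone would, through the logistic
  truth, generate several-fold too many rejection events. Component
  log-SDs are therefore capped at 1, and `p_elevated = 0.03` is set so
  that the expected number of rejecting subjects per trial matches the
  observed 8 of 58 given the published coefficients. Rejection at
  visit $v$ is Bernoulli in the *previous* visit's miR155 (the week-1
  visit acting as its own predictor), so the prognostic structure of
  the analysis dataset is generated, not assumed.
* **Missingness** removes visit records at rate 0.369 so that about
  183 of the 290 possible records survive, matching the analysis
  dataset's size; predictor records of diagnosed rejections are always
  kept (in the study, pre-rejection urine was always collected before
  treatment modification).
* **Not simulated:** the 22 recruited-but-excluded patients,
  infection/CMV/BK dynamics, GFR trajectories (covariates are one-off
  draws), or assay-level detail.

What passing recovery tests on these data do *not* show: robustness to
real-data features the generator lacks — non-log-normal biomarker
shapes, within-patient biomarker autocorrelation, informative
missingness, dose-history recording errors, or absorption profiles
outside the lag + first-order family.

# Model evaluation machinery

* **pcVPC** (`pcvpc()`): `n_sim` replicate datasets (default 1000) at
  the original design; observed and simulated values are
  prediction-corrected by the bin-median population prediction,
  binned by time-after-dose into quantile bins (default 8; bins with
  fewer than 2 observations merge into a neighbour), and the observed
  2.5/50/97.5 percentiles are compared with the 95% confidence bands
  of the simulated percentiles.
* **Categorical VPC** (`categorical_vpc()`): simulated rejection
  outcomes at the observed predictor values; observed proportion per
  biomarker bin against the simulated median and 95% interval.
* **Grouped bars** (`grouped_bar()`): ten contiguous equal-width bins
  covering the biomarker range; observed mean outcome next to mean
  predicted risk per bin.
* **npde** (`npde()`): per subject, observations are decorrelated with
  the simulation mean and Cholesky factor of the simulation
  covariance; rank-based prediction discrepancies (with a
  $(r+0.5)/(n_{sim}+1)$ continuity correction) map through
  $\Phi^{-1}$. Under a correct model the npde are ~N(0,1); the summary
  carries mean, variance and a Shapiro-Wilk statistic. A singular
  simulation covariance is ridge-regularised and reported.
* **Bootstrap** (`bootstrap_fit()`): plain (unstratified) resampling
  of subjects with replacement, refitting, and per-parameter
  median/2.5th/97.5th percentiles; failed refits are counted, never
  dropped, and >20% failures flag the result unstable. The reference
  analysis used 1000 resamples for the PK models and 200 for the
  logistic model.

All stochastic diagnostics are bit-for-bit reproducible given
`(seed, n_sim)`. Simulated concentrations are kept strictly positive
by redrawing offending residual draws (relevant only for the
proportional-error model, where about 3% of naive draws would be
negative); observed and simulated data pass through the same
truncation, so the simulation-based diagnostics stay internally
calibrated.

# Validation scale

The package's own validation (test suite and the recovery study in
`scripts/acceptance.R`) runs at these problem sizes, chosen as the
smallest that leave the conclusions stable: recovery studies use the
full 58-subject design with 5 replicate trials per drug (medians
reported) and n = 5000 records with 10 replicates for the logistic
stage; diagnostic calibration uses 40 subjects with 200–400
simulation replicates; the desk-scale bootstrap uses 50 resamples
with warm-started refits (iteration-capped at the resample stage),
against the reference analysis's 1000/200.

# Known limitations

* The Laplace/FOCE-type objective is an approximation; its small
  biases (variance components shrink slightly, absorption parameters
  wander along the identifiability ridge described above) are absorbed
  into the recovery tolerances but would differ from a SAEM fit of the
  same data.
* Vp/F of tacrolimus is reported by the reference analysis itself as
  probably overpredicted (no BSV, post-distributive sampling sparse);
  nothing here improves that, and Vp recovery is deliberately not a
  validation target.
* The exposure metrics condition on the fitted PK model (sequential,
  not joint, estimation); uncertainty in the PK stage does not
  propagate into the logistic standard errors, exactly as in the
  reference analysis.
* The discussion-level claim that +0.1 miR155 units raises AR risk by
  10% is not algebraically reproducible from the published
  coefficients under a plain odds or risk reading
  ($e^{3.51 \times 0.1} \approx 1.42$ odds ratio); the package
  reproduces the coefficients, not that reading.
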