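# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A small complete synthetic trial (12 subjects) for structural checks.
small_trial <- function() {
  fixture("small_trial", function()
    simulate_trial(trial_config(n_subjects = 12), seed = 101))
}

# A moderate self-simulated tacrolimus dataset (40 subjects) used by the
# diagnostic-calibration tests; no refitting involved.
calib_tac <- function() {
  fixture("calib_tac", function() {
    cfg <- trial_config(n_subjects = 40)
    pop <- sample_population(cfg, 21)
    list(cfg = cfg, model = tacrolimus_model(),
         courses = simulate_pk(pop, tacrolimus_model(), cfg, "tac", 22))
  })
}

# A 20-subject tacrolimus fit with standard errors, reused by the
# fit-method, shrinkage and condition-number tests.
small_fit <- function() {
  fixture("small_fit", function() {
    trial <- simulate_trial(trial_config(n_subjects = 20), seed = 7)
    list(trial = trial,
         fit = fit_poppk(tacrolimus_model(), trial$tac, se = TRUE))
  })
}

# Reference parameter sets.
tac_params <- function()
  structural_params(CL = 16.5, Vc = 311, Q = 20.5, Vp = 56300,
                    Ka = 3.08, tlag = 0.295)

mpa_params <- function()
  structural_params(CL = 11.8, Vc = 106, Q = 37.1, Vp = 800,
                    Ka = 1.79, tlag = 0.243)

# Random but physiologically plausible structural parameters.
random_params <- function() {
  structural_params(CL = exp(stats::runif(1, 1, 3.5)),
                    Vc = exp(stats::runif(1, 3, 6)),
                    Q = exp(stats::runif(1, 1, 4)),
                    Vp = exp(stats::runif(1, 4, 9)),
                    Ka = exp(stats::runif(1, -1, 1.5)),
                    tlag = stats::runif(1, 0, 0.5))
}

# Numerical ODE solution of the three-state system (depot, central,
# peripheral) used as the independent oracle for the closed form.
ode_concentration <- function(p, doses, times) {
  rhs <- function(t, y, pp) {
    k10 <- pp$CL / pp$Vc; k12 <- pp$Q / pp$Vc; k21 <- pp$Q / pp$Vp
    list(c(-pp$Ka * y[1],
           pp$Ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  ev <- data.frame(var = "A", time = doses$time + p[["tlag"]],
                   value = doses$amt, method = "add")
  allt <- sort(unique(c(0, times, ev$time)))
  out <- deSolve::ode(c(A = 0, C = 0, P = 0), allt, rhs,
                      as.list(unclass(p)), events = list(data = ev),
                      rtol = 1e-11, atol = 1e-14)
  out[match(times, allt), "C"] / p[["Vc"]]
}
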