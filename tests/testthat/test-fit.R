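test_that("population fit recovers a 20-subject trial and reports diagnostics", {
  sf <- small_fit()
  fit <- sf$fit
  truth <- tacrolimus_model()
  expect_true(fit$converged)
  ## point estimates in the neighbourhood of the simulation truth
  ## (wide bounds at n = 20; the full-scale recovery study asserts
  ## tighter ones)
  expect_lt(abs(fit$model$typical[["CL"]] / 16.5 - 1), 0.35)
  expect_lt(abs(fit$model$typical[["Vc"]] / 311 - 1), 0.40)
  ## objective not worse than at the initial model
  expect_lte(fit$mofv, fit$init_mofv + 1e-6)
  ## accepted objective values decrease monotonically
  expect_true(all(diff(fit$trace) < 0))
  ## precision machinery
  expect_true(all(is.finite(fit$rse)))
  expect_true(all(fit$rse > 0))
  cn <- fit$condition_number
  expect_gte(cn, 1)
  expect_lt(cn, 1000)
  expect_false(attr(cn, "ill_conditioned"))
  ## shrinkage within plausible bounds
  sh <- shrinkage(fit)
  expect_true(all(sh$eta > -30 & sh$eta < 100))
  expect_true(sh$eps > -30 && sh$eps < 100)
  ## summary table carries estimate / RSE / shrinkage columns
  tab <- summary(fit)$table
  expect_true(all(c("parameter", "estimate", "rse_pct",
                    "shrinkage_pct") %in% names(tab)))
  expect_equal(sum(grepl("^BSV_", tab$parameter)), 3L)
  ## standard S3 surface
  expect_s3_class(fit, "poppk_fit")
  expect_equal(as.numeric(logLik(fit)), -fit$mofv / 2)
  expect_named(coef(fit))
  expect_output(print(fit), "MOFV")
})

test_that("a single-subject fit without random effects matches least squares", {
  ct <- calib_tac()
  s <- ct$courses[[2]]
  m0 <- poppk_model(tac_params(), random_effects_spec(),
                    residual_spec("additive_log", 0.366),
                    conc_scale = 1000)
  fit <- fit_poppk(m0, list(s), se = FALSE)
  ## with additive-log residuals the ML typicals minimise the log-scale
  ## sum of squares; oracle: direct least-squares optimisation
  ss <- function(lp) {
    p <- unclass(tac_params())
    p[] <- exp(lp)
    class(p) <- "structural_params"
    f <- predict_concentration(apply_allometry(p, s$weight), s$doses,
                               s$obs$time) * 1000
    sum((log(s$obs$dv) - log(pmax(f, 1e-12)))^2)
  }
  ls <- stats::optim(log(unclass(tac_params())), ss,
                     method = "BFGS", control = list(maxit = 500,
                                                     reltol = 1e-12))
  expect_lte(ss(log(unclass(fit$model$typical))), ls$value * (1 + 1e-4))
  ## sigma-hat equals the root mean square residual
  expect_equal(fit$model$residual$sigma,
               sqrt(ss(log(unclass(fit$model$typical))) / nrow(s$obs)),
               tolerance = 1e-3)
})

test_that("refits from perturbed starts reach the same optimum", {
  sf <- small_fit()
  trial <- sf$trial
  base <- sf$fit
  pert <- tacrolimus_model()
  typ <- unclass(pert$typical)
  set.seed(5)
  typ <- typ * exp(stats::runif(6, log(0.5), log(1.5)))
  class(typ) <- "structural_params"
  pert$typical <- typ
  refit <- fit_poppk(pert, trial$tac, se = FALSE)
  expect_equal(refit$mofv, base$mofv, tolerance = 1e-4)
  expect_equal(refit$model$typical[["CL"]], base$model$typical[["CL"]],
               tolerance = 0.01)
})

test_that("residual diagnostics are calibrated on self-simulated data", {
  ct <- calib_tac()
  ## evaluate at the true model: no fitting involved
  ee <- new.env(parent = emptyenv())
  ee$etas <- vector("list", length(ct$courses))
  det <- pkarisk:::population_neg2ll(ct$model, ct$courses, ee,
                                     details = TRUE)
  fit <- structure(list(model = ct$model, courses = ct$courses,
                        per_subject = det$per,
                        ebes = do.call(rbind, lapply(det$per, `[[`, "eta")),
                        iwres = unlist(lapply(det$per, function(z)
                          z$r / z$sd)),
                        map = pkarisk:::param_map(ct$model)),
                   class = "poppk_fit")
  rd <- residual_diagnostics(fit)
  expect_true(all(c("PRED", "IPRED", "IWRES", "CWRES") %in% names(rd)))
  expect_gt(nrow(rd), 900)
  expect_lt(abs(mean(rd$CWRES)), 0.1)
  expect_gt(stats::sd(rd$CWRES), 0.85)
  expect_lt(stats::sd(rd$CWRES), 1.15)
  ## a mis-specified model (pseudo one-compartment fit to
  ## two-compartment data) inflates the conditional residuals
  bad <- ct$model
  typ <- unclass(bad$typical)
  typ[["Q"]] <- 0.05      # effectively removes the peripheral exchange
  typ[["Vp"]] <- 100
  class(typ) <- "structural_params"
  bad$typical <- typ
  ee2 <- new.env(parent = emptyenv())
  ee2$etas <- vector("list", length(ct$courses))
  det2 <- pkarisk:::population_neg2ll(bad, ct$courses, ee2, details = TRUE)
  fit2 <- fit
  fit2$model <- bad
  fit2$per_subject <- det2$per
  rd2 <- residual_diagnostics(fit2)
  expect_gt(mean(abs(rd2$CWRES)), mean(abs(rd$CWRES)))
})

test_that("zero-noise synthetic data give zero individual residuals", {
  m0 <- poppk_model(tac_params(), random_effects_spec(),
                    residual_spec("additive_log", 0.3), conc_scale = 1000)
  cfg <- trial_config(n_subjects = 3)
  pop <- sample_population(cfg, 13)
  courses <- simulate_pk(pop, m0, cfg, "tac", 14)
  ## replace observations by exact predictions
  courses <- lapply(courses, function(s) {
    f <- predict_concentration(individual_params(m0, weight = s$weight),
                               s$doses, s$obs$time) * 1000
    s$obs$dv <- f
    s
  })
  ee <- new.env(parent = emptyenv())
  ee$etas <- vector("list", 3)
  det <- pkarisk:::population_neg2ll(m0, courses, ee, details = TRUE)
  iwres <- unlist(lapply(det$per, function(z) z$r / z$sd))
  expect_equal(max(abs(iwres)), 0, tolerance = 1e-10)
})

test_that("simulate method reproduces bit-for-bit under a fixed seed", {
  sf <- small_fit()
  s1 <- simulate(sf$fit, nsim = 3, seed = 88)
  s2 <- simulate(sf$fit, nsim = 3, seed = 88)
  expect_identical(s1, s2)
  expect_true(all(s1$sim_1 > 0))
  expect_equal(nrow(s1),
               sum(vapply(sf$fit$courses, function(s) nrow(s$obs),
                          integer(1))))
})

test_that("condition number follows the eigenvalue ratio convention", {
  expect_equal(as.numeric(condition_number(diag(2))), 1)
  ## a covariance with SD ratio 10 has correlation identity; supply a
  ## correlated matrix instead
  cv <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(as.numeric(condition_number(cv)), 1.9 / 0.1,
               tolerance = 1e-10)
  sing <- matrix(c(1, 1, 1, 1), 2)
  expect_true(is.infinite(condition_number(sing)))
  expect_true(attr(condition_number(sing), "ill_conditioned"))
})

test_that("eta shrinkage grows as the design gets sparser", {
  cfg <- trial_config(n_subjects = 25)
  pop <- sample_population(cfg, 31)
  m <- tacrolimus_model()
  rich <- simulate_pk(pop, m, cfg, "tac", 32)
  ## sparse version: keep only the four late sparse samples per subject
  sparse <- lapply(rich, function(s) {
    keep <- s$obs$occ == "M6"
    s$obs <- s$obs[keep, ]
    s
  })
  sh_for <- function(courses) {
    ee <- new.env(parent = emptyenv())
    ee$etas <- vector("list", length(courses))
    det <- pkarisk:::population_neg2ll(m, courses, ee, details = TRUE)
    fit <- structure(list(model = m, courses = courses,
                          per_subject = det$per,
                          ebes = do.call(rbind, lapply(det$per, `[[`,
                                                       "eta")),
                          iwres = unlist(lapply(det$per, function(z)
                            z$r / z$sd)),
                          map = pkarisk:::param_map(m)),
                     class = "poppk_fit")
    shrinkage(fit)
  }
  expect_gt(sh_for(sparse)$eta[["CL"]], sh_for(rich)$eta[["CL"]])
})
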