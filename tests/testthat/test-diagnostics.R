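test_that("npde is N(0,1)-calibrated on self-simulated data", {
  ct <- calib_tac()
  res <- npde(ct$model, ct$courses, n_sim = 400, seed = 13)
  s <- attr(res, "summary")
  expect_lt(abs(s$mean), 0.1)
  expect_gt(s$variance, 0.85)
  expect_lt(s$variance, 1.15)
  expect_equal(nrow(res),
               sum(vapply(ct$courses, function(s) nrow(s$obs),
                          integer(1))))
  ## bit-for-bit reproducibility and subject-order invariance
  res2 <- npde(ct$model, ct$courses, n_sim = 400, seed = 13)
  expect_identical(res$npde, res2$npde)
  perm <- c(7, 1:6, 8:length(ct$courses))
  res3 <- npde(ct$model, ct$courses[perm], n_sim = 400, seed = 13)
  m3 <- res3[order(match(res3$id, res$id), res3$time), ]
  ## same per-subject simulation stream is not guaranteed under
  ## permutation, but the calibration must be unchanged
  expect_lt(abs(attr(res3, "summary")$mean), 0.1)
})

test_that("npde reduces to the simulation-rank normal score for one observation", {
  m0 <- poppk_model(tac_params(),
                    random_effects_spec("CL", 0.3),
                    residual_spec("additive_log", 0.3),
                    conc_scale = 1000)
  cfg <- trial_config(n_subjects = 5)
  pop <- sample_population(cfg, 15)
  courses <- simulate_pk(pop, m0, cfg, "tac", 16)
  courses <- lapply(courses, function(s) { s$obs <- s$obs[3, ]; s })
  n_sim <- 300
  res <- npde(m0, courses, n_sim = n_sim, seed = 17)
  sims <- pkarisk:::simulate_observations(m0, courses, n_sim, seed = 17)
  for (i in seq_along(courses)) {
    cnt <- sum(sims$dv[i, ] < courses[[i]]$obs$dv)
    expect_equal(res$npde[i],
                 stats::qnorm((cnt + 0.5) / (n_sim + 1)),
                 tolerance = 1e-12)
  }
})

test_that("npde detects an inflated residual error", {
  ct <- calib_tac()
  wrong <- ct$model
  wrong$residual$sigma <- 2 * wrong$residual$sigma
  res <- npde(wrong, ct$courses, n_sim = 300, seed = 19)
  expect_lt(attr(res, "summary")$variance, 0.7)
})

test_that("the prediction-corrected VPC is self-consistent and detects misfit", {
  ct <- calib_tac()
  v <- pcvpc(ct$model, ct$courses, n_sim = 200, bins = 8, seed = 14)
  expect_s3_class(v, "vpc_result")
  ## ordered percentiles per bin
  expect_true(all(v$sim_p2.5_med <= v$sim_p50_med))
  expect_true(all(v$sim_p50_med <= v$sim_p97.5_med))
  ## observed median inside the simulated median band in >= 90% of bins
  inside <- v$obs_p50 >= v$sim_p50_lo & v$obs_p50 <= v$sim_p50_hi
  expect_gte(mean(inside), 0.9)
  ## reproducible bit-for-bit
  v2 <- pcvpc(ct$model, ct$courses, n_sim = 200, bins = 8, seed = 14)
  expect_identical(as.data.frame(v), as.data.frame(v2))
  ## a model with halved clearance is flagged
  wrong <- ct$model
  typ <- unclass(wrong$typical); typ[["CL"]] <- typ[["CL"]] / 2
  class(typ) <- "structural_params"; wrong$typical <- typ
  vw <- pcvpc(wrong, ct$courses, n_sim = 200, bins = 8, seed = 14)
  outside <- vw$obs_p50 < vw$sim_p50_lo | vw$obs_p50 > vw$sim_p50_hi
  expect_gte(sum(outside), 1)
})

test_that("prediction correction is the identity for homogeneous bins", {
  obsbin <- c(3.1, 2.9, 3.4)
  pred <- rep(4, 3)
  corr <- stats::median(pred) / pred
  expect_identical(obsbin * corr, obsbin)
})

test_that("the categorical VPC tracks the logistic model", {
  trial <- small_trial()
  rec <- simulate_logistic_records(400, trial_config(), seed = 23)
  fit <- fit_logistic(rec, "miR155")
  v <- categorical_vpc(fit, n_sim = 300, n_bins = 5, seed = 24)
  ## observed proportion inside the band in >= 9/10 of bins
  inside <- v$obs_prop >= v$sim_lo & v$obs_prop <= v$sim_hi
  expect_gte(mean(inside), 0.9)
  ## medians non-decreasing in the biomarker for a positive slope
  expect_true(all(diff(v$sim_med) >= -1e-9))
  ## a slope-free model is flat at expit(beta0)
  f0 <- list(beta0 = stats::qlogis(0.12), betas = c(miR155 = 0),
             predictors = "miR155", records = rec)
  class(f0) <- "ar_logit"
  v0 <- categorical_vpc(f0, records = rec, n_sim = 400, n_bins = 4,
                        seed = 25)
  expect_lt(max(v0$sim_med) - min(v0$sim_med), 0.08)
})

test_that("grouped bars partition the range and are calibrated", {
  rec <- simulate_logistic_records(4000, trial_config(), seed = 26)
  fit <- fit_logistic(rec, "miR155")
  gb <- grouped_bar(fit, n_bins = 10)
  expect_identical(nrow(gb), 10L)
  ## contiguous bins covering the biomarker range
  expect_lte(gb$x_lo[1], min(rec$miR155))
  expect_gte(gb$x_hi[10], max(rec$miR155))
  expect_equal(gb$x_lo[-1], gb$x_hi[-10], tolerance = 1e-12)
  expect_identical(sum(gb$n), 4000L)
  ## calibration: |observed - predicted| within 3 binomial SEs
  ok <- is.na(gb$observed) |
    abs(gb$observed - gb$predicted) <=
      3 * sqrt(pmax(gb$predicted * (1 - gb$predicted), 1e-6) /
                 pmax(gb$n, 1)) + 1e-9
  expect_true(all(ok))
  ## all-zero outcomes give all-zero observed bars
  rec0 <- rec; rec0$outcome <- 0L
  f1 <- fit; f1$records <- rec0
  gb0 <- grouped_bar(f1, records = rec0, n_bins = 5)
  expect_true(all(gb0$observed[!is.na(gb0$observed)] == 0))
})

test_that("the bootstrap summarises resampled fits honestly", {
  ## degenerate data: identical subjects give zero-width intervals
  trial <- small_trial()
  s <- trial$tac[[1]]
  clones <- lapply(1:6, function(i) { s2 <- s; s2$id <- i; s2 })
  fitproc <- function(d) {
    c(gm = exp(mean(log(unlist(lapply(d, function(x) x$obs$dv))))))
  }
  bt <- bootstrap_fit(fitproc, clones, n_resamples = 50, seed = 31)
  expect_equal(bt$table$p2.5, bt$table$p97.5, tolerance = 1e-12)
  expect_identical(bt$n_failed, 0L)
  ## failures are counted and flagged
  flaky <- function(d) if (stats::runif(1) < 0.5) stop("no") else c(a = 1)
  bt2 <- bootstrap_fit(flaky, clones, n_resamples = 60, seed = 32)
  expect_gt(bt2$n_failed, 0L)
  expect_true(bt2$unstable)
  ## reproducibility
  bt3 <- bootstrap_fit(fitproc, clones, n_resamples = 50, seed = 31)
  expect_identical(bt$table, bt3$table)
  expect_error(bootstrap_fit(fitproc, clones, n_resamples = 10), "50")
})

test_that("bootstrap interval width shrinks with the subject count", {
  cfg <- trial_config(n_subjects = 60)
  pop <- sample_population(cfg, 35)
  m <- tacrolimus_model()
  courses <- simulate_pk(pop, m, cfg, "tac", 36)
  gmfit <- function(d)
    c(gm = exp(mean(log(unlist(lapply(d, function(x) x$obs$dv))))))
  w_small <- with(bootstrap_fit(gmfit, courses[1:15],
                                n_resamples = 100, seed = 37)$table,
                  p97.5 - p2.5)
  w_large <- with(bootstrap_fit(gmfit, courses,
                                n_resamples = 100, seed = 38)$table,
                  p97.5 - p2.5)
  expect_lt(w_large, w_small)
})

test_that("diagnostic plots render without error", {
  ct <- calib_tac()
  v <- pcvpc(ct$model, ct$courses[1:10], n_sim = 60, bins = 5, seed = 41)
  rec <- simulate_logistic_records(300, trial_config(), seed = 42)
  fit <- fit_logistic(rec, "miR155")
  cv <- categorical_vpc(fit, n_sim = 60, n_bins = 4, seed = 43)
  gb <- grouped_bar(fit, n_bins = 5)
  nr <- npde(ct$model, ct$courses[1:5], n_sim = 120, seed = 44)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(v))
  expect_silent(plot(cv))
  expect_no_error(plot(gb))
  expect_no_error(plot(nr))
})
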