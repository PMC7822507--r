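test_that("the prior-visit shift places events on the preceding record", {
  exposures <- expand.grid(subject = 1:2,
                           visit = c("W1", "M1", "M2", "M3", "M6"),
                           stringsAsFactors = FALSE)
  exposures[c("auc_tac", "auc_mpa", "trough_tac", "trough_mpa")] <- 1
  bio <- exposures[c("subject", "visit")]
  bio$miR155 <- 0.1
  bio$CXCL10 <- 50
  ## subject 1: AR diagnosed at M1 -> outcome on the W1 record
  rec <- build_logistic_dataset(exposures, bio,
                                data.frame(subject = 1, visit = "M1"))
  expect_identical(rec$outcome[rec$subject == 1 & rec$visit == "W1"], 1L)
  expect_identical(sum(rec$outcome), 1L)
  ## subject with no AR: all outcomes zero
  expect_true(all(rec$outcome[rec$subject == 2] == 0L))
  ## AR at the first visit: same-record assignment, counted separately
  rec2 <- build_logistic_dataset(exposures, bio,
                                 data.frame(subject = 2, visit = "W1"))
  expect_identical(rec2$outcome[rec2$subject == 2 & rec2$visit == "W1"], 1L)
  expect_identical(attr(rec2, "n_first_visit_events"), 1L)
  ## records with missing predictors are dropped and counted
  bio3 <- bio; bio3$miR155[1] <- NA
  rec3 <- build_logistic_dataset(exposures, bio3, NULL)
  expect_identical(attr(rec3, "n_dropped"), 1L)
  expect_identical(nrow(rec3), 9L)
})

test_that("outcome 1 is never placed at or after the diagnosis visit", {
  vord <- c("W1", "M1", "M2", "M3", "M6")
  for (sd in 1:5) {
    trial <- simulate_trial(trial_config(n_subjects = 30), seed = 200 + sd)
    rec <- trial$logistic
    ar <- trial$biomarkers[trial$biomarkers$ar_diagnosed == 1, ]
    pos <- rec[rec$outcome == 1, ]
    for (k in seq_len(nrow(pos))) {
      ev <- match(ar$visit[ar$subject == pos$subject[k]], vord)
      rk <- match(pos$visit[k], vord)
      ## each outcome-1 record precedes one of the subject's diagnosis
      ## visits, or is the first visit for a first-visit diagnosis
      expect_true(any(ev > rk) || (rk == 1 && any(ev == 1)))
    }
    ## number of outcome-1 records never exceeds the number of events
    expect_lte(sum(rec$outcome), trial$truth$n_ar_events)
  }
})

test_that("risk reproduces the logit model and its published evaluations", {
  fit <- list(beta0 = -5.89, beta1 = 3.51)
  expect_equal(risk(fit, 0), stats::plogis(-5.89), tolerance = 1e-12)
  expect_equal(risk(fit, 0), 0.00276, tolerance = 2e-3)
  expect_equal(risk(fit, 1.5), 0.349, tolerance = 2e-3)
  ## round trip through the logit is exact
  x <- seq(0, 3, by = 0.25)
  expect_equal(stats::qlogis(risk(fit, x)), -5.89 + 3.51 * x,
               tolerance = 1e-12)
  ## strictly increasing for positive slope, always inside (0, 1)
  p <- risk(fit, x)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  ## intercept-only model is constant
  expect_equal(risk(list(beta0 = 0.3, betas = numeric(0)), 5),
               stats::plogis(0.3))
})

test_that("the Bernoulli ML fit matches the independent glm oracle", {
  set.seed(9)
  n <- 400
  x <- stats::rlnorm(n, log(0.3), 1)
  z <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-2 + 2 * x - 0.5 * z))
  rec <- data.frame(subject = seq_len(n), visit = "W1", miR155 = x,
                    CXCL10 = z, outcome = y)
  f <- fit_logistic(rec, c("miR155", "CXCL10"))
  g <- stats::glm(y ~ x + z, family = stats::binomial())
  expect_equal(unname(c(f$beta0, f$betas)), unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(g)))),
               tolerance = 1e-5)
  expect_equal(f$mofv, g$deviance, tolerance = 1e-8)
  ## predict method agrees with direct evaluation
  expect_equal(predict(f), unname(stats::fitted(g)), tolerance = 1e-6)
})

test_that("degenerate logistic data raise informative errors", {
  rec <- data.frame(subject = 1:20, visit = "W1",
                    miR155 = stats::runif(20), outcome = 0L)
  expect_error(fit_logistic(rec, "miR155"), "each outcome class")
  ## complete separation names the offending predictor
  rec2 <- data.frame(subject = 1:40, visit = "W1",
                     miR155 = c(stats::runif(20, 0, 1),
                                stats::runif(20, 2, 3)),
                     outcome = rep(c(0L, 1L), each = 20))
  expect_error(fit_logistic(rec2, "miR155"), "miR155")
})

test_that("perfectly symmetric data give a zero intercept", {
  rec <- data.frame(subject = 1:8, visit = "W1",
                    miR155 = rep(c(-1, -1, 1, 1), 2),
                    outcome = c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L))
  f <- fit_logistic(rec, "miR155")
  expect_equal(f$beta0, 0, tolerance = 1e-8)
})

test_that("selection keeps a true miR155 effect and rejects a constant", {
  set.seed(77)
  kept_mir <- 0
  for (rep in 1:20) {
    rec <- simulate_logistic_records(400, trial_config(), seed = 300 + rep)
    rec$CXCL10 <- stats::rlnorm(400, log(50), 1)
    rec$auc_tac <- stats::rlnorm(400, log(3000), 0.4)
    sel <- select_explanatory(rec, c("miR155", "CXCL10", "auc_tac"))
    if (identical(sel$retained, "miR155")) kept_mir <- kept_mir + 1
  }
  expect_gte(kept_mir, 18)
  ## a constant candidate carries no information
  rec$const <- 1.7
  sel2 <- select_explanatory(rec, c("const"))
  expect_length(sel2$retained, 0)
  tr <- sel2$trace
  expect_lt(abs(tr$delta_mofv[tr$candidate == "const"][1]), 1e-6)
})

test_that("selection under the null retains candidates rarely", {
  set.seed(78)
  n_any <- 0
  for (rep in 1:20) {
    n <- 300
    rec <- data.frame(subject = seq_len(n), visit = "W1",
                      miR155 = stats::rlnorm(n, log(0.2), 1),
                      CXCL10 = stats::rlnorm(n, log(50), 1),
                      outcome = stats::rbinom(n, 1, 0.1))
    sel <- select_explanatory(rec, c("miR155", "CXCL10"))
    if (length(sel$retained)) n_any <- n_any + 1
  }
  ## backward elimination at alpha = 0.001 keeps the familywise
  ## retention rate far below the forward alpha
  expect_lte(n_any, 2)
})

test_that("logistic table I/O round-trips", {
  trial <- small_trial()
  rec <- trial$logistic
  path <- tempfile(fileext = ".csv")
  write_logistic_table(rec, path)
  back <- read_logistic_table(path)
  expect_equal(back$outcome, rec$outcome)
  expect_equal(back$miR155, rec$miR155, tolerance = 1e-12)
  expect_error(read_logistic_table(write_logistic_table(
    data.frame(a = 1), tempfile(fileext = ".csv"))), "outcome")
})
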