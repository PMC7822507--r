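test_that("allometric scaling follows the fixed-exponent power law", {
  p <- tac_params()
  expect_identical(unclass(apply_allometry(p, 70)), unclass(p))
  p140 <- apply_allometry(p, 140)
  expect_equal(p140[["CL"]], 16.5 * 2^0.75, tolerance = 1e-12)
  expect_equal(p140[["Q"]], 20.5 * 2^0.75, tolerance = 1e-12)
  expect_equal(p140[["Vc"]], 311 * 2, tolerance = 1e-12)
  p35 <- apply_allometry(p, 35)
  expect_equal(p35[["Vc"]], 155.5, tolerance = 1e-12)
  expect_identical(p140[["Ka"]], p[["Ka"]])
  expect_identical(p140[["tlag"]], p[["tlag"]])
  ## exact power law: re-referencing through an intermediate weight is
  ## consistent with a single application
  p1 <- apply_allometry(p, 50)
  p2 <- apply_allometry(p1, 90, allometric_rule(reference_weight = 50))
  expect_equal(unclass(p2), unclass(apply_allometry(p, 90)),
               tolerance = 1e-12)
  expect_error(apply_allometry(p, -5), "positive")
  expect_error(apply_allometry(p, 0), "positive")
})

test_that("MMF doses convert to MPA molar equivalents", {
  expect_identical(mmf_to_mpa_equivalent(0), 0)
  expect_equal(mmf_to_mpa_equivalent(1000), 1000 * 320.34 / 433.49)
  expect_equal(mmf_to_mpa_equivalent(1000), 739.0, tolerance = 1e-4)
  expect_equal(mmf_to_mpa_equivalent(2000), 1477.9, tolerance = 1e-4)
  expect_error(mmf_to_mpa_equivalent(-1), "non-negative")
})

test_that("concentration is causal and linear in the dose history", {
  p <- tac_params()
  d <- data.frame(time = c(0, 12), amt = 5)
  ## causality: zero before first dose + lag
  expect_identical(predict_concentration(p, d, c(0, 0.1, 0.29)),
                   c(0, 0, 0))
  expect_gt(predict_concentration(p, d, 0.4), 0)
  ## two identical simultaneous doses give exactly twice one dose
  d2 <- data.frame(time = c(0, 0), amt = 5)
  t <- c(0.5, 1, 6, 24)
  expect_equal(predict_concentration(p, d2, t),
               2 * predict_concentration(p, data.frame(time = 0, amt = 5), t),
               tolerance = 1e-12)
  ## superposition: concatenated dose lists add
  da <- data.frame(time = c(0, 24), amt = c(5, 3))
  db <- data.frame(time = c(7), amt = c(4))
  expect_equal(predict_concentration(p, rbind(da, db), t),
               predict_concentration(p, da, t) +
                 predict_concentration(p, db, t),
               tolerance = 1e-10)
  ## no doses
  expect_identical(predict_concentration(p, NULL, t), numeric(4))
})

test_that("block compression reproduces dose-by-dose superposition", {
  set.seed(42)
  p <- tac_params()
  ## regular grid with level changes plus irregular extra doses
  d <- rbind(data.frame(time = seq(0, 120, by = 12), amt = 7),
             data.frame(time = seq(132, 240, by = 12), amt = 5),
             data.frame(time = c(3.5, 77.2), amt = c(2, 9)))
  t <- sort(stats::runif(25, 0, 260))
  single <- Reduce(`+`, lapply(seq_len(nrow(d)), function(i)
    predict_concentration(p, d[i, ], t)))
  expect_equal(predict_concentration(p, d, t), single, tolerance = 1e-10)
})

test_that("closed form matches the stiff ODE oracle on random designs", {
  skip_if_not_installed("deSolve")
  set.seed(1)
  for (rep in 1:30) {
    p <- random_params()
    nd <- sample(1:6, 1)
    d <- data.frame(time = sort(stats::runif(nd, 0, 48)),
                    amt = stats::runif(nd, 1, 20))
    t <- sort(stats::runif(15, 0.1, 96))
    cf <- predict_concentration(p, d, t)
    oc <- ode_concentration(p, d, t)
    expect_equal(cf, unname(oc), tolerance = 1e-6)
  }
})

test_that("absorption rate colliding with a disposition rate is handled", {
  p <- tac_params()
  dt <- pkarisk:::disposition_terms(p)
  alpha <- dt$lambda[1]
  q <- unclass(p); q[["Ka"]] <- alpha   # exact collision
  class(q) <- "structural_params"
  t <- c(0.5, 2, 12)
  d <- data.frame(time = 0, amt = 10)
  f_exact <- predict_concentration(q, d, t)
  q2 <- unclass(p); q2[["Ka"]] <- alpha * (1 + 1e-6)
  class(q2) <- "structural_params"
  f_near <- predict_concentration(q2, d, t)
  expect_true(all(is.finite(f_exact)))
  expect_equal(f_exact, f_near, tolerance = 1e-4)
})

test_that("cumulative AUC is analytic, monotone and mass-balanced", {
  p <- tac_params()
  expect_identical(cumulative_auc(p, NULL, 100), 0)
  expect_identical(cumulative_auc(p, data.frame(time = 0, amt = 10), 0), 0)
  expect_error(cumulative_auc(p, NULL, -1), "non-negative")
  ## mass balance: AUC(inf) = D / CL
  expect_equal(cumulative_auc(p, data.frame(time = 0, amt = 10), Inf),
               10 / 16.5, tolerance = 1e-12)
  expect_equal(cumulative_auc(p, data.frame(time = 0, amt = 10), Inf),
               0.606, tolerance = 1e-3)
  ## analytic integral converges to the mass-balance limit
  expect_equal(cumulative_auc(p, data.frame(time = 0, amt = 10), 2e5),
               10 / 16.5, tolerance = 1e-3)
  ## multi-dose mass balance within 0.1%
  d <- data.frame(time = seq(0, 96, by = 12), amt = 7.3)
  expect_equal(cumulative_auc(p, d, Inf), sum(d$amt) / p[["CL"]],
               tolerance = 1e-3)
  ## finite AUC agrees with dense trapezoidal quadrature within 0.1%
  t2 <- seq(0, 200, by = 0.01)
  c2 <- predict_concentration(p, d, t2)
  trap2 <- sum((c2[-1] + c2[-length(c2)]) / 2 * diff(t2))
  expect_equal(cumulative_auc(p, d, 200), trap2, tolerance = 1e-3)
  ## monotone in t_end
  aucs <- vapply(c(10, 50, 100, 500), function(tt)
    cumulative_auc(p, d, tt), numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("mean trough averages predicted pre-dose concentrations", {
  p <- mpa_params()
  d <- data.frame(time = seq(0, 228, by = 12), amt = 700)
  expect_error(mean_trough(p, d, numeric(0)), "at least one")
  expect_equal(mean_trough(p, d, 120),
               predict_concentration(p, d, 120))
  vt <- c(24, 120, 240)
  expect_equal(mean_trough(p, d, vt),
               mean(predict_concentration(p, d, vt)), tolerance = 1e-12)
})

test_that("structural parameter validation rejects bad values", {
  expect_error(structural_params(-1, 311, 20.5, 56300, 3.08, 0.295),
               "positive")
  expect_error(structural_params(16.5, 311, 20.5, 56300, 3.08, -0.1),
               "tlag")
  expect_silent(validate_structural_params <- NULL)  # no export leakage
})
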