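#' Structural parameters of the two-compartment oral model
#'
#' Constructs and validates the parameter set of a two-compartment
#' disposition model with first-order absorption and a lag time, the
#' structural backbone used for both tacrolimus and mycophenolic acid
#' (MPA). All disposition parameters are apparent (divided by oral
#' bioavailability F) and refer to a 70 kg reference subject; see
#' [apply_allometry()] for body-weight scaling.
#'
#' @param CL Apparent clearance (L/h per 70 kg).
#' @param Vc Apparent central volume of distribution (L per 70 kg).
#' @param Q Apparent intercompartmental clearance (L/h per 70 kg).
#' @param Vp Apparent peripheral volume of distribution (L per 70 kg).
#' @param Ka First-order absorption rate constant (1/h).
#' @param tlag Absorption lag time (h).
#' @return An object of class `structural_params` (named numeric vector).
#' @examples
#' structural_params(CL = 16.5, Vc = 311, Q = 20.5, Vp = 56300,
#'                   Ka = 3.08, tlag = 0.295)
#' @export
structural_params <- function(CL, Vc, Q, Vp, Ka, tlag) {
  p <- c(CL = CL, Vc = Vc, Q = Q, Vp = Vp, Ka = Ka, tlag = tlag)
  validate_structural_params(p)
  class(p) <- "structural_params"
  p
}

validate_structural_params <- function(p) {
  needed <- c("CL", "Vc", "Q", "Vp", "Ka", "tlag")
  if (!all(needed %in% names(p)))
    stop("structural parameters must contain ", paste(needed, collapse = ", "))
  if (any(!is.finite(p[needed])))
    stop("structural parameters must be finite")
  pos <- c("CL", "Vc", "Q", "Vp", "Ka")
  if (any(p[pos] <= 0))
    stop("structural parameters ", paste(pos[p[pos] <= 0], collapse = ", "),
         " must be strictly positive")
  if (p[["tlag"]] < 0) stop("tlag must be non-negative")
  invisible(p)
}

#' Allometric body-weight scaling rule
#'
#' Fixed-exponent allometry: flow parameters (CL, Q) scale with
#' (weight/reference)^0.75 and distribution volumes (Vc, Vp) with
#' (weight/reference)^1. The exponents are fixed by convention, not
#' estimated.
#'
#' @param reference_weight Reference body weight in kg (default 70).
#' @param exponent_flow Allometric exponent for flow parameters (0.75).
#' @param exponent_volume Allometric exponent for volumes (1).
#' @return An object of class `allometric_rule`.
#' @export
allometric_rule <- function(reference_weight = 70, exponent_flow = 0.75,
                            exponent_volume = 1) {
  if (reference_weight <= 0) stop("reference_weight must be positive")
  structure(list(reference_weight = reference_weight,
                 exponent_flow = exponent_flow,
                 exponent_volume = exponent_volume),
            class = "allometric_rule")
}

#' Apply allometric scaling to structural parameters
#'
#' @param p A [structural_params()] object at the reference weight.
#' @param weight Body weight in kg; must be positive.
#' @param rule An [allometric_rule()]; default fixed exponents 0.75 / 1
#'   at 70 kg.
#' @return A `structural_params` object scaled to `weight`. Ka and tlag
#'   are unchanged.
#' @examples
#' p <- structural_params(16.5, 311, 20.5, 56300, 3.08, 0.295)
#' apply_allometry(p, weight = 140)
#' @export
apply_allometry <- function(p, weight, rule = allometric_rule()) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number")
  w <- weight / rule$reference_weight
  q <- unclass(p)
  q[c("CL", "Q")] <- q[c("CL", "Q")] * w^rule$exponent_flow
  q[c("Vc", "Vp")] <- q[c("Vc", "Vp")] * w^rule$exponent_volume
  class(q) <- "structural_params"
  q
}

#' Convert a mycophenolate mofetil dose to its MPA molar equivalent
#'
#' Mycophenolate mofetil (MMF) is the prodrug of mycophenolic acid
#' (MPA); doses are converted to the parent-drug molar equivalent via
#' the molecular-weight ratio 320.34 / 433.49 (MPA / MMF).
#'
#' @param mmf_dose_mg MMF dose in mg (vectorised); must be non-negative.
#' @return MPA molar-equivalent dose in mg.
#' @examples
#' mmf_to_mpa_equivalent(1000)  # ~739 mg MPA
#' @export
mmf_to_mpa_equivalent <- function(mmf_dose_mg) {
  if (any(!is.finite(mmf_dose_mg)) || any(mmf_dose_mg < 0))
    stop("MMF dose must be non-negative and finite")
  mmf_dose_mg * (320.34 / 433.49)
}

## Disposition macro-constants.
##
## Returns the three exponential rates (alpha, beta, Ka) and the matching
## coefficients c_k such that, for a unit oral dose given at time 0 (after
## the lag), C(t) = sum_k c_k * exp(-lambda_k * t).
## If Ka collides with a disposition rate (relative distance < 1e-8) it is
## nudged by a relative 1e-8 so the three-exponential form stays valid.
disposition_terms <- function(p) {
  k10 <- p[["CL"]] / p[["Vc"]]
  k12 <- p[["Q"]] / p[["Vc"]]
  k21 <- p[["Q"]] / p[["Vp"]]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta  <- (s - disc) / 2
  ka <- p[["Ka"]]
  eps <- 1e-8
  if (abs(ka - alpha) < eps * alpha) ka <- alpha * (1 + eps)
  if (abs(ka - beta)  < eps * beta)  ka <- beta * (1 + eps)
  co <- ka / p[["Vc"]] * c(
    (k21 - alpha) / ((ka - alpha) * (beta - alpha)),
    (k21 - beta)  / ((ka - beta) * (alpha - beta)),
    (k21 - ka)    / ((alpha - ka) * (beta - ka)))
  list(lambda = c(alpha, beta, ka), coef = co)
}

## Compress a dose-event history into arithmetic blocks
## (start time, inter-dose interval, number of doses, amount per dose).
## A block groups a maximal run of doses with constant amount and constant
## spacing; isolated doses become single-dose blocks. The multiple-dose
## geometric-series evaluation over blocks is algebraically identical to
## dose-by-dose superposition.
dose_blocks <- function(times, amounts) {
  stopifnot(length(times) == length(amounts))
  n <- length(times)
  if (n == 0L)
    return(data.frame(t0 = numeric(0), tau = numeric(0), n = integer(0),
                      amt = numeric(0)))
  o <- order(times)
  times <- times[o]; amounts <- amounts[o]
  t0 <- numeric(0); tau <- numeric(0); nn <- integer(0); amt <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- i
    dt <- NA_real_
    while (j < n && amounts[j + 1L] == amounts[i]) {
      step <- times[j + 1L] - times[j]
      if (is.na(dt)) {
        dt <- step
      } else if (abs(step - dt) > 1e-9) break
      j <- j + 1L
    }
    t0 <- c(t0, times[i]); tau <- c(tau, if (is.na(dt)) 1 else dt)
    nn <- c(nn, j - i + 1L); amt <- c(amt, amounts[i])
    i <- j + 1L
  }
  data.frame(t0 = t0, tau = tau, n = nn, amt = amt)
}

## Multiple-dose exponential sum for one rate constant.
## For a block of n doses of unit amount at s0, s0+tau, ..., and evaluation
## times t, returns sum_{j=0}^{m(t)} exp(-lambda*(t - s0 - j*tau)) where
## m(t) counts doses already administered (strictly before t). All exponents
## are non-positive, so the evaluation is overflow-safe.
block_exp_sum <- function(lambda, t, s0, tau, nblk) {
  u <- t - s0
  out <- numeric(length(t))
  act <- u > 0
  if (!any(act)) return(out)
  uu <- u[act]
  m <- pmin(nblk - 1L, floor(uu / tau - 1e-12))
  r <- exp(-lambda * tau)
  ## sum_{j=0}^{m} exp(-lambda*(u - j*tau)) = exp(-lambda*(u - m*tau)) *
  ##   (1 - r^(m+1)) / (1 - r)
  geom <- if (abs(1 - r) < 1e-12) (m + 1) else (1 - r^(m + 1)) / (1 - r)
  out[act] <- exp(-lambda * (uu - m * tau)) * geom
  out
}

## As above but the running integral: sum over administered doses of
## (1 - exp(-lambda*(t - s_j))) / lambda.
block_int_sum <- function(lambda, t, s0, tau, nblk) {
  u <- t - s0
  out <- numeric(length(t))
  act <- u > 0
  if (!any(act)) return(out)
  uu <- u[act]
  m <- pmin(nblk - 1L, floor(uu / tau - 1e-12))
  r <- exp(-lambda * tau)
  geom <- if (abs(1 - r) < 1e-12) (m + 1) else (1 - r^(m + 1)) / (1 - r)
  esum <- exp(-lambda * (uu - m * tau)) * geom
  out[act] <- ((m + 1) - esum) / lambda
  out
}

normalize_doses <- function(doses) {
  if (is.null(doses) || NROW(doses) == 0L)
    return(data.frame(time = numeric(0), amt = numeric(0)))
  if (!is.data.frame(doses)) stop("doses must be a data.frame")
  nm <- names(doses)
  tcol <- intersect(c("time", "TIME"), nm)[1]
  acol <- intersect(c("amt", "AMT", "amount"), nm)[1]
  if (is.na(tcol) || is.na(acol))
    stop("doses must have time and amt columns")
  d <- data.frame(time = as.numeric(doses[[tcol]]),
                  amt = as.numeric(doses[[acol]]))
  if (any(d$amt < 0)) stop("dose amounts must be non-negative")
  d[order(d$time), , drop = FALSE]
}

#' Predict drug concentration over time
#'
#' Closed-form concentration of the two-compartment first-order
#' absorption model with lag time, by linear superposition over the
#' recorded dose history. Repeated identical doses on a regular grid are
#' evaluated by exact geometric-series summation, so arbitrarily long
#' twice-daily histories cost the same as a handful of doses.
#'
#' @param p A [structural_params()] object (already scaled to the
#'   subject's weight if applicable).
#' @param doses A data.frame with columns `time` (h) and `amt` (mg).
#' @param times Numeric vector of times (h) at which to predict.
#' @return Numeric vector of concentrations (dose mg / volume L, i.e.
#'   mg/L; equal to ug/mL, and to ng/mL after multiplying doses given
#'   in mg by 1000 -- callers keep their own unit convention).
#' @examples
#' p <- structural_params(16.5, 311, 20.5, 56300, 3.08, 0.295)
#' d <- data.frame(time = seq(0, 132, by = 12), amt = 7.3)
#' predict_concentration(p, d, times = c(1, 12, 144))
#' @export
predict_concentration <- function(p, doses, times) {
  validate_structural_params(p)
  d <- normalize_doses(doses)
  if (nrow(d) == 0L) return(numeric(length(times)))
  blk <- dose_blocks(d$time, d$amt)
  dt <- disposition_terms(p)
  out <- numeric(length(times))
  for (b in seq_len(nrow(blk))) {
    s0 <- blk$t0[b] + p[["tlag"]]
    acc <- numeric(length(times))
    for (k in 1:3)
      acc <- acc + dt$coef[k] *
        block_exp_sum(dt$lambda[k], times, s0, blk$tau[b], blk$n[b])
    out <- out + blk$amt[b] * acc
  }
  pmax(out, 0)
}

#' Cumulative area under the concentration-time curve
#'
#' Analytic integral of the predicted concentration from time 0 to
#' `t_end`, the cumulative-exposure metric AUC(0, t). For
#' `t_end = Inf` this equals total dose / CL (mass balance).
#'
#' @inheritParams predict_concentration
#' @param t_end Upper integration limit (h); must be >= 0 (may be `Inf`).
#' @return AUC in concentration x h units.
#' @examples
#' p <- structural_params(16.5, 311, 20.5, 56300, 3.08, 0.295)
#' cumulative_auc(p, data.frame(time = 0, amt = 10), t_end = Inf)
#' @export
cumulative_auc <- function(p, doses, t_end) {
  validate_structural_params(p)
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end < 0)
    stop("t_end must be a single non-negative number")
  d <- normalize_doses(doses)
  if (nrow(d) == 0L || t_end == 0) return(0)
  dt <- disposition_terms(p)
  if (is.infinite(t_end)) return(sum(d$amt) / p[["CL"]])
  blk <- dose_blocks(d$time, d$amt)
  auc <- 0
  for (b in seq_len(nrow(blk))) {
    s0 <- blk$t0[b] + p[["tlag"]]
    acc <- 0
    for (k in 1:3)
      acc <- acc + dt$coef[k] *
        block_int_sum(dt$lambda[k], t_end, s0, blk$tau[b], blk$n[b])
    auc <- auc + blk$amt[b] * acc
  }
  max(auc, 0)
}

#' Mean predicted trough concentration over visits
#'
#' Arithmetic mean of model-predicted pre-dose concentrations at the
#' supplied visit (pre-dose sampling) times.
#'
#' @inheritParams predict_concentration
#' @param visit_times Numeric vector of pre-dose sampling times (h);
#'   must be non-empty.
#' @return Mean predicted trough concentration.
#' @export
mean_trough <- function(p, doses, visit_times) {
  if (length(visit_times) == 0L)
    stop("visit_times must contain at least one time")
  mean(predict_concentration(p, doses, visit_times))
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Two-compartment oral structural parameters (per 70 kg):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
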