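## Laplace-type approximate marginal likelihood for the nonlinear
## mixed-effects PK models.
##
## Per subject the joint negative log-density
##   h(eta) = sum_j [ r_j^2/(2 sd_j^2) + log(2 pi sd_j^2)/2 ]
##          + eta' Oinv eta / 2 + log det(2 pi Omega) / 2
## is minimised over eta (empirical Bayes mode) by a damped Newton
## iteration whose Hessian is the Gauss-Newton / first-order-conditional
## approximation J' W J + Oinv (J = d r / d eta by central differences,
## W = diag(1/sd^2)). The marginal contribution is then
##   -2 log L_i = 2 h(eta_hat) + log det H - d log(2 pi).
## With no random effects this collapses to the plain Gaussian -2 log L.

inner_control <- function(maxit = 40L, step_tol = 1e-8, grad_tol = 1e-6,
                          h = 1e-4) {
  list(maxit = maxit, step_tol = step_tol, grad_tol = grad_tol, h = h)
}

## residfun(eta) must return list(r = residuals, sd = residual SDs).
## Returns the mode, the GN Hessian there, and the -2logL contribution.
laplace_subject <- function(residfun, Oinv, logdet2piO, eta0,
                            ctrl = inner_control()) {
  d <- length(eta0)
  gres <- function(z) 0.5 * sum(z$r^2 / z$sd^2 + log(2 * pi * z$sd^2))
  if (d == 0L) {
    z <- residfun(numeric(0))
    return(list(eta = numeric(0), neg2ll = 2 * gres(z), H = matrix(0, 0, 0),
                r = z$r, sd = z$sd, J = matrix(0, length(z$r), 0),
                converged = TRUE))
  }
  eta <- eta0
  z <- residfun(eta)
  gb <- gres(z)
  if (!is.finite(gb)) { eta <- numeric(d); z <- residfun(eta); gb <- gres(z) }
  H <- NULL; J <- NULL
  converged <- FALSE
  for (it in seq_len(ctrl$maxit)) {
    gradr <- numeric(d)
    J <- matrix(0, length(z$r), d)
    for (k in seq_len(d)) {
      ep <- eta; ep[k] <- ep[k] + ctrl$h
      em <- eta; em[k] <- em[k] - ctrl$h
      zp <- residfun(ep); zm <- residfun(em)
      gradr[k] <- (gres(zp) - gres(zm)) / (2 * ctrl$h)
      J[, k] <- (zp$r - zm$r) / (2 * ctrl$h)
    }
    grad <- gradr + drop(Oinv %*% eta)
    H <- crossprod(J / z$sd) + Oinv
    if (max(abs(grad)) < ctrl$grad_tol * (1 + abs(gb))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(-solve(H + diag(1e-10, d), grad),
                     error = function(e) -grad)
    fb <- gb + 0.5 * sum(eta * drop(Oinv %*% eta))
    lam <- 1; ok <- FALSE
    for (ls in 1:15) {
      etan <- eta + lam * step
      zn <- residfun(etan)
      gn <- gres(zn)
      fn <- gn + 0.5 * sum(etan * drop(Oinv %*% etan))
      if (is.finite(fn) && fn <= fb + 1e-12) { ok <- TRUE; break }
      lam <- lam / 2
    }
    if (!ok) { converged <- TRUE; break }  # no descent possible: at mode
    moved <- max(abs(lam * step))
    eta <- etan; z <- zn; gb <- gn
    if (moved < ctrl$step_tol) { converged <- TRUE }
    if (converged) {
      ## refresh J/H at the final iterate
      for (k in seq_len(d)) {
        ep <- eta; ep[k] <- ep[k] + ctrl$h
        em <- eta; em[k] <- em[k] - ctrl$h
        zp <- residfun(ep); zm <- residfun(em)
        J[, k] <- (zp$r - zm$r) / (2 * ctrl$h)
      }
      H <- crossprod(J / z$sd) + Oinv
      break
    }
  }
  hfull <- gb + 0.5 * sum(eta * drop(Oinv %*% eta)) + 0.5 * logdet2piO
  ld <- determinant(H, logarithm = TRUE)
  neg2 <- 2 * hfull + as.numeric(ld$modulus) - d * log(2 * pi)
  list(eta = eta, neg2ll = neg2, H = H, r = z$r, sd = z$sd, J = J,
       converged = converged)
}

## Fast per-subject residual function: precomputes dose blocks, covariate
## and allometric multipliers; only the exp(eta) factors vary per call.
## The dose-grid geometry (which doses precede each observation, and the
## geometric-series block structure) depends on tlag only, so it is
## cached inside the closure and reused across the inner Newton
## iterations, leaving three matrix exponentials per evaluation.
make_subject_prep <- function(subj) {
  blk <- dose_blocks(subj$doses$time, subj$doses$amt)
  prep <- new.env(parent = emptyenv())
  prep$t0 <- blk$t0; prep$tau <- blk$tau; prep$nn <- blk$n
  prep$amt <- blk$amt
  prep$nblk <- nrow(blk)
  prep$times <- subj$obs$time
  prep$nt <- length(subj$obs$time)
  prep$dv <- subj$obs$dv
  prep$ylog <- log(subj$obs$dv)
  prep$cache_tlag <- NA_real_
  prep$UE <- prep$TM <- NULL
  prep
}

refresh_geometry <- function(prep, tlag) {
  nt <- prep$nt; nblk <- prep$nblk
  UE <- TM <- matrix(0, nt, nblk)
  for (b in seq_len(nblk)) {
    u <- prep$times - prep$t0[b] - tlag
    act <- u > 0
    m <- pmin(prep$nn[b] - 1L, floor(u / prep$tau[b] - 1e-12))
    ue <- u - m * prep$tau[b]
    ue[!act] <- Inf            # exp(-lambda*Inf) = 0 kills inactive cells
    tm <- prep$tau[b] * (m + 1)
    tm[!act] <- 0              # avoid overflow in the dead cells
    UE[, b] <- ue
    TM[, b] <- tm
  }
  prep$UE <- UE; prep$TM <- TM; prep$cache_tlag <- tlag
  invisible(prep)
}

conc_from_prep <- function(prep, p) {
  if (!identical(p[["tlag"]], prep$cache_tlag))
    refresh_geometry(prep, p[["tlag"]])
  dt <- disposition_terms(p)
  f <- numeric(prep$nt)
  for (k in 1:3) {
    lam <- dt$lambda[k]
    r1 <- -expm1(-lam * prep$tau)           # 1 - exp(-lam*tau), per block
    S <- exp(-lam * prep$UE) * (-expm1(-lam * prep$TM))
    if (any(r1 < 1e-300)) {
      deg <- r1 < 1e-300
      S[, deg] <- exp(-lam * prep$UE[, deg, drop = FALSE]) *
        prep$TM[, deg, drop = FALSE] / rep(prep$tau[deg], each = prep$nt)
      r1[deg] <- 1
    }
    f <- f + dt$coef[k] * drop(S %*% (prep$amt / r1))
  }
  f
}

make_resid_fun <- function(model, subj, prep = NULL) {
  pbase <- unclass(model$typical)
  for (eff in model$covariates)
    pbase[[eff$param]] <- pbase[[eff$param]] *
      covariate_multiplier(eff, subj$covariates)
  w <- subj$weight / model$allometry$reference_weight
  pbase[c("CL", "Q")] <- pbase[c("CL", "Q")] * w^model$allometry$exponent_flow
  pbase[c("Vc", "Vp")] <- pbase[c("Vc", "Vp")] *
    w^model$allometry$exponent_volume
  if (is.null(prep)) prep <- make_subject_prep(subj)
  kind <- model$residual$kind
  dv <- prep$dv
  ylog <- prep$ylog
  sig <- model$residual$sigma
  labels <- model$random$labels
  scale <- model$conc_scale
  residual <- model$residual
  function(eta) {
    p <- pbase
    if (length(eta)) p[labels] <- p[labels] * exp(eta)
    f <- conc_from_prep(prep, p)
    f[f < 0] <- 0
    f <- f * scale
    if (kind == "additive_log") {
      fl <- f
      fl[fl < 1e-12] <- 1e-12
      list(r = ylog - log(fl), sd = rep.int(sig, length(f)), f = f)
    } else {
      list(r = dv - f, sd = residual_sd(residual, f), f = f)
    }
  }
}

omega_pieces <- function(omega) {
  d <- nrow(omega)
  if (is.null(d) || d == 0L)
    return(list(Oinv = matrix(0, 0, 0), logdet2piO = 0))
  Oinv <- solve(omega)
  list(Oinv = Oinv,
       logdet2piO = as.numeric(determinant(2 * pi * omega,
                                           logarithm = TRUE)$modulus))
}

## Evaluate the approximate marginal -2 log-likelihood over all subjects.
## eta_env, if supplied, is an environment holding warm-start modes keyed
## by subject index; it is updated in place.
population_neg2ll <- function(model, courses, eta_env = NULL,
                              ctrl = inner_control(), details = FALSE) {
  d <- length(model$random$labels)
  op <- omega_pieces(model$random$omega)
  total <- 0
  per <- vector("list", length(courses))
  if (!is.null(eta_env) && is.null(eta_env$preps))
    eta_env$preps <- lapply(courses, make_subject_prep)
  for (i in seq_along(courses)) {
    subj <- courses[[i]]
    if (nrow(subj$obs) == 0L) {
      per[[i]] <- list(eta = numeric(d), neg2ll = 0, r = numeric(0),
                       sd = numeric(0), J = matrix(0, 0, d),
                       H = diag(0, d), converged = TRUE)
      next
    }
    rf <- make_resid_fun(model, subj,
                         prep = if (!is.null(eta_env)) eta_env$preps[[i]])
    eta0 <- if (!is.null(eta_env) && !is.null(eta_env$etas[[i]]))
      eta_env$etas[[i]] else numeric(d)
    res <- laplace_subject(rf, op$Oinv, op$logdet2piO, eta0, ctrl)
    if (!is.finite(res$neg2ll))
      stop("non-finite likelihood contribution for subject ", subj$id)
    if (!is.null(eta_env)) {
      eta_env$etas[[i]] <- res$eta
      if (is.null(eta_env$Js)) eta_env$Js <- vector("list", length(courses))
      eta_env$Js[[i]] <- res$J
    }
    total <- total + res$neg2ll
    per[[i]] <- res
  }
  if (details) list(neg2ll = total, per = per) else total
}

#' Approximate marginal -2 log-likelihood (MOFV)
#'
#' Evaluates the objective function value of a population PK model on a
#' dataset: the Laplace-type approximation of -2 log marginal
#' likelihood, additive over subjects, with the empirical Bayes mode
#' found by damped Gauss-Newton per subject. For the additive-log
#' residual model the likelihood is that of the log-transformed
#' observations.
#'
#' @param model A [poppk_model()].
#' @param data An event-record data.frame or a list of
#'   [subject_course()] objects; every subject must have at least one
#'   observation (subjects without observations contribute 0).
#' @return The MOFV (numeric scalar).
#' @export
neg2ll <- function(model, data) {
  courses <- as_subject_courses(data)
  population_neg2ll(model, courses)
}

#' Empirical Bayes estimates of a subject's random effects
#'
#' Mode of the conditional density of the subject's log-scale random
#' effects given their observations. A subject with no observations
#' returns the prior mode (all zeros).
#'
#' @param model A [poppk_model()] with at least one random effect.
#' @param subject A single [subject_course()] (or an event-record
#'   data.frame containing exactly one subject).
#' @return Named numeric vector of EBEs (one per random-effect label).
#' @export
ebe <- function(model, subject) {
  if (length(model$random$labels) == 0L)
    stop("model has no random effects")
  courses <- as_subject_courses(subject)
  if (length(courses) != 1L) stop("ebe() expects a single subject")
  subj <- courses[[1]]
  d <- length(model$random$labels)
  if (nrow(subj$obs) == 0L)
    return(stats::setNames(numeric(d), model$random$labels))
  op <- omega_pieces(model$random$omega)
  rf <- make_resid_fun(model, subj)
  res <- laplace_subject(rf, op$Oinv, op$logdet2piO, numeric(d),
                         inner_control(maxit = 200L))
  if (!res$converged) stop("EBE optimisation failed for subject ", subj$id)
  stats::setNames(res$eta, model$random$labels)
}


## Frozen-mode (envelope) evaluation of the Laplace objective: the
## per-subject modes and residual Jacobians are held at the values from
## the last exact evaluation and only the residuals, weights and Omega
## terms are recomputed. At the inner mode the objective's gradient with
## respect to the outer parameters equals the partial derivative holding
## the mode fixed (envelope property), so differencing two frozen
## evaluations yields the outer gradient at one residual call per
## subject per component instead of a full inner re-optimisation.
population_neg2ll_frozen <- function(model, courses, eta_env) {
  d <- length(model$random$labels)
  op <- omega_pieces(model$random$omega)
  total <- 0
  for (i in seq_along(courses)) {
    subj <- courses[[i]]
    if (nrow(subj$obs) == 0L) next
    rf <- make_resid_fun(model, subj, prep = eta_env$preps[[i]])
    eta <- eta_env$etas[[i]]
    if (is.null(eta)) eta <- numeric(d)
    z <- rf(eta)
    gres <- 0.5 * sum(z$r^2 / z$sd^2 + log(2 * pi * z$sd^2))
    if (d == 0L) {
      total <- total + 2 * gres
      next
    }
    J <- eta_env$Js[[i]]
    H <- crossprod(J / z$sd) + op$Oinv
    hfull <- gres + 0.5 * sum(eta * drop(op$Oinv %*% eta)) +
      0.5 * op$logdet2piO
    ld <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
    total <- total + 2 * hfull + ld - d * log(2 * pi)
  }
  total
}
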