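#' Build the visit-level logistic dataset with the prior-visit shift
#'
#' Assembles one record per subject-visit from individual predicted
#' exposures and observed biomarker values, and places each rejection
#' event on the record of the visit *preceding* its diagnosis, so that
#' the fitted model measures prognostic (not concurrent) capacity. A
#' rejection diagnosed at the first available visit, which has no
#' predecessor, is assigned to that same first record and counted
#' separately. Records with missing predictors are dropped and counted.
#'
#' @param pk_exposures data.frame with columns `subject`, `visit`,
#'   `auc_tac`, `auc_mpa`, `trough_tac`, `trough_mpa`.
#' @param biomarker_series data.frame with columns `subject`, `visit`,
#'   `miR155`, `CXCL10` (one row per observed visit record).
#' @param ar_events data.frame with columns `subject` and `visit` (the
#'   diagnosis visit), one row per rejection event.
#' @param visit_order Character vector giving visit chronology.
#' @return data.frame of visit records with an `outcome` column and
#'   attributes `n_dropped` (records lost to missing predictors),
#'   `n_first_visit_events` (events diagnosed at a first visit) and
#'   `n_unplaced_events` (events whose predictor record was missing).
#' @export
build_logistic_dataset <- function(pk_exposures, biomarker_series,
                                   ar_events,
                                   visit_order = c("W1", "M1", "M2",
                                                   "M3", "M6")) {
  bio <- biomarker_series
  if (!all(c("subject", "visit", "miR155") %in% names(bio)))
    stop("biomarker_series needs subject, visit and miR155 columns")
  rec <- merge(bio[, intersect(names(bio),
                               c("subject", "visit", "miR155", "CXCL10"))],
               pk_exposures, by = c("subject", "visit"), all.x = TRUE,
               sort = FALSE)
  pred_cols <- setdiff(names(rec), c("subject", "visit"))
  complete <- stats::complete.cases(rec[pred_cols])
  n_dropped <- sum(!complete)
  rec <- rec[complete, , drop = FALSE]
  rec$outcome <- 0L
  n_first <- 0L; n_unplaced <- 0L
  if (!is.null(ar_events) && nrow(ar_events)) {
    for (k in seq_len(nrow(ar_events))) {
      s <- ar_events$subject[k]
      vd <- match(ar_events$visit[k], visit_order)
      if (is.na(vd)) stop("unknown diagnosis visit: ", ar_events$visit[k])
      srows <- which(rec$subject == s)
      svis <- match(rec$visit[srows], visit_order)
      prior <- srows[svis < vd]
      if (length(prior)) {
        tgt <- prior[which.max(svis[svis < vd])]
      } else {
        ## diagnosis at the subject's first available visit
        same <- srows[svis == vd]
        if (length(same)) {
          tgt <- same[1]
          n_first <- n_first + 1L
        } else {
          n_unplaced <- n_unplaced + 1L
          next
        }
      }
      rec$outcome[tgt] <- 1L
    }
  }
  rec <- rec[order(rec$subject, match(rec$visit, visit_order)), ,
             drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- n_dropped
  attr(rec, "n_first_visit_events") <- n_first
  attr(rec, "n_unplaced_events") <- n_unplaced
  rec
}

#' Fit the acute-rejection logistic regression
#'
#' Maximum-likelihood fit of `logit(P) = beta0 + sum_i beta_i * x_i`
#' for the binary rejection outcome, by Newton-Raphson on the Bernoulli
#' log-likelihood. Reports the -2 log-likelihood (MOFV), Wald standard
#' errors from the inverse Fisher information, and raises an error on
#' complete separation (naming the offending predictor) or single-class
#' data.
#'
#' @param records Visit-record data.frame with an `outcome` column (as
#'   from [build_logistic_dataset()]).
#' @param predictors Character vector of explanatory-variable columns
#'   (empty for the intercept-only model).
#' @return An object of class `ar_logit`: coefficients (`beta0`,
#'   `betas`), `se`, `vcov`, `mofv`, `n`, and the fitted records.
#' @export
fit_logistic <- function(records, predictors = "miR155") {
  if (!"outcome" %in% names(records)) stop("records need an outcome column")
  miss <- !stats::complete.cases(records[c("outcome", predictors)])
  records <- records[!miss, , drop = FALSE]
  y <- records$outcome
  if (length(unique(y)) < 2L)
    stop("need at least one record of each outcome class")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(records[, predictors, drop = FALSE]))
  beta <- c(stats::qlogis(mean(y)), rep(0, length(predictors)))
  deviance <- function(b)
    -2 * sum(stats::dbinom(y, 1, stats::plogis(drop(X %*% b)), log = TRUE))
  dev_old <- deviance(beta)
  converged <- FALSE
  for (it in 1:200) {
    lp <- drop(X %*% beta)
    p <- stats::plogis(lp)
    w <- p * (1 - p)
    if (any(!is.finite(w))) break
    H <- crossprod(X, X * w)
    g <- crossprod(X, y - p)
    if (max(abs(g)) < 1e-9 * length(y)) { converged <- TRUE; break }
    step <- tryCatch(drop(solve(H + diag(1e-10, ncol(X)), g)),
                     error = function(e) NULL)
    if (is.null(step)) break
    ## damped Newton: halve the step until the deviance does not increase
    lam <- 1; dev <- Inf
    for (ls in 1:40) {
      dev <- deviance(beta + lam * step)
      if (is.finite(dev) && dev <= dev_old + 1e-12) break
      lam <- lam / 2
    }
    if (!is.finite(dev) || dev > dev_old + 1e-12) break
    beta <- beta + lam * step
    if (dev_old - dev < 1e-10 && max(abs(lam * step)) < 1e-8) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  scale <- apply(X, 2, function(col) max(stats::sd(col), 1e-12))
  big <- abs(beta) * scale > 30
  if (any(big[-1]) || !converged) {
    off <- predictors[big[-1]]
    if (length(off))
      stop("complete or quasi-complete separation on predictor: ",
           paste(off, collapse = ", "))
    if (!converged) stop("logistic fit did not converge")
  }
  lp <- drop(X %*% beta)
  p <- stats::plogis(lp)
  Hfin <- crossprod(X, X * (p * (1 - p)))
  ## degenerate designs (e.g. a constant predictor) get a ridge so the
  ## fit still reports its (huge) standard errors instead of failing
  vc <- tryCatch(solve(Hfin), error = function(e)
    solve(Hfin + diag(1e-8 * max(diag(Hfin)), ncol(X))))
  dimnames(vc) <- list(colnames(X), colnames(X))
  mofv <- -2 * sum(stats::dbinom(y, 1, p, log = TRUE))
  structure(list(beta0 = unname(beta[1]),
                 betas = stats::setNames(beta[-1], predictors),
                 se = stats::setNames(sqrt(diag(vc)),
                                      colnames(X)),
                 vcov = vc, mofv = mofv, n = length(y),
                 predictors = predictors, records = records,
                 converged = converged),
            class = "ar_logit")
}

#' Probability of acute rejection for given predictor values
#'
#' Inverse-logit risk `expit(beta0 + sum beta_i x_i)`, always in
#' (0, 1), strictly increasing in any predictor with positive
#' coefficient.
#'
#' @param fit An [fit_logistic()] result, or any list with elements
#'   `beta0` and either `betas` (named) or `beta1` (single predictor).
#' @param x Predictor values: a numeric vector (single predictor,
#'   vectorised), a named vector, or a data.frame with the predictor
#'   columns.
#' @return Numeric vector of probabilities.
#' @examples
#' risk(list(beta0 = -5.89, beta1 = 3.51), c(0, 1.5))
#' @export
risk <- function(fit, x) {
  betas <- if (!is.null(fit$betas)) fit$betas
           else if (!is.null(fit$beta1)) c(x = fit$beta1)
           else stop("fit must carry betas or beta1")
  if (length(betas) == 0L) {
    n <- if (is.data.frame(x)) nrow(x) else length(x)
    return(rep(stats::plogis(fit$beta0), max(n, 1L)))
  }
  if (is.data.frame(x)) {
    if (!all(names(betas) %in% names(x)))
      stop("x is missing predictor columns: ",
           paste(setdiff(names(betas), names(x)), collapse = ", "))
    lp <- fit$beta0 + drop(as.matrix(x[names(betas)]) %*% betas)
  } else if (length(betas) == 1L) {
    lp <- fit$beta0 + unname(betas) * as.numeric(x)
  } else {
    if (length(x) != length(betas))
      stop("predictor vector length ", length(x),
           " does not match the ", length(betas), " fitted predictors")
    lp <- fit$beta0 + sum(betas * as.numeric(x))
  }
  unname(stats::plogis(lp))
}

#' Stepwise selection of explanatory variables for rejection risk
#'
#' Forward inclusion / backward elimination over candidate explanatory
#' variables using likelihood-ratio thresholds on the Bernoulli MOFV:
#' a candidate enters if it lowers the MOFV by at least
#' `lrt_threshold(1, forward_alpha)` and is retained in the backward
#' pass only if its removal raises the MOFV by at least
#' `lrt_threshold(1, backward_alpha)`.
#'
#' @param records Visit-record data.frame with `outcome`.
#' @param candidates Character vector of candidate predictor columns.
#' @param forward_alpha,backward_alpha Significance levels of the two
#'   passes (defaults 0.05 and 0.001).
#' @return List with `fit` (final [fit_logistic()]), `retained`
#'   (character) and `trace` (data.frame of tested steps with
#'   delta-MOFV values).
#' @export
select_explanatory <- function(records,
                               candidates = c("auc_tac", "auc_mpa",
                                              "trough_tac", "trough_mpa",
                                              "miR155", "CXCL10"),
                               forward_alpha = 0.05,
                               backward_alpha = 0.001) {
  candidates <- intersect(candidates, names(records))
  if (!length(candidates)) stop("no candidate columns present in records")
  thr_f <- lrt_threshold(1, forward_alpha)
  thr_b <- lrt_threshold(1, backward_alpha)
  retained <- character(0)
  trace <- list()
  base_fit <- fit_logistic(records, retained)
  repeat {
    pool <- setdiff(candidates, retained)
    if (!length(pool)) break
    dm <- rep(NA_real_, length(pool))
    for (j in seq_along(pool)) {
      f <- tryCatch(fit_logistic(records, c(retained, pool[j])),
                    error = function(e) NULL)
      if (!is.null(f)) dm[j] <- base_fit$mofv - f$mofv
      trace[[length(trace) + 1L]] <- data.frame(
        step = "forward", candidate = pool[j],
        delta_mofv = dm[j], accepted = FALSE)
    }
    if (all(is.na(dm)) || max(dm, na.rm = TRUE) < thr_f) break
    best <- pool[which.max(dm)]
    retained <- c(retained, best)
    for (k in seq_along(trace))
      if (trace[[k]]$step == "forward" && trace[[k]]$candidate == best)
        trace[[k]]$accepted <- TRUE
    base_fit <- fit_logistic(records, retained)
  }
  for (v in rev(retained)) {
    reduced <- setdiff(retained, v)
    f0 <- fit_logistic(records, reduced)
    inc <- f0$mofv - base_fit$mofv
    drop_it <- inc < thr_b
    trace[[length(trace) + 1L]] <- data.frame(
      step = "backward", candidate = v, delta_mofv = inc,
      accepted = !drop_it)
    if (drop_it) {
      retained <- reduced
      base_fit <- f0
    }
  }
  list(fit = base_fit, retained = retained,
       trace = do.call(rbind, trace))
}

## ---- methods --------------------------------------------------------

#' @export
print.ar_logit <- function(x, ...) {
  cat("Acute-rejection logistic regression (ML, Newton-Raphson)\n")
  cat(sprintf("  %d records, %d events; MOFV = %.3f\n", x$n,
              sum(x$records$outcome), x$mofv))
  cf <- c(`(Intercept)` = x$beta0, x$betas)
  tab <- data.frame(estimate = cf, se = x$se,
                    rse_pct = 100 * abs(x$se / cf))
  print(signif(tab, 4))
  invisible(x)
}

#' @export
summary.ar_logit <- function(object, ...) {
  cf <- c(`(Intercept)` = object$beta0, object$betas)
  z <- cf / object$se
  tab <- data.frame(estimate = cf, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, mofv = object$mofv, n = object$n),
            class = "summary.ar_logit")
}

#' @export
print.summary.ar_logit <- function(x, ...) {
  print(signif(x$table, 4))
  cat(sprintf("n = %d, MOFV = %.3f\n", x$n, x$mofv))
  invisible(x)
}

#' @export
coef.ar_logit <- function(object, ...)
  c(`(Intercept)` = object$beta0, object$betas)

#' @export
vcov.ar_logit <- function(object, ...) object$vcov

#' @export
logLik.ar_logit <- function(object, ...)
  structure(-object$mofv / 2, df = 1 + length(object$betas),
            class = "logLik")

#' @export
predict.ar_logit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  df <- if (is.null(newdata)) object$records else newdata
  pr <- risk(object, df)
  if (type == "response") pr else stats::qlogis(pr)
}

#' @export
simulate.ar_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- risk(object, object$records)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
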