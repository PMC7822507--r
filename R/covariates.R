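#' Likelihood-ratio retention threshold
#'
#' Upper-alpha quantile of the chi-square distribution with `df`
#' degrees of freedom, the MOFV drop required to retain an added
#' parameter in a nested comparison: 3.841 for df = 1 at alpha = 0.05
#' (forward inclusion), 7.879 at 0.005, 10.828 at 0.001 (backward
#' elimination).
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return MOFV units (numeric).
#' @examples
#' lrt_threshold(1, 0.05)   # 3.841
#' lrt_threshold(1, 0.001)  # 10.828
#' @export
lrt_threshold <- function(df, alpha) {
  if (!is.numeric(df) || df < 1 || df != round(df))
    stop("df must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  stats::qchisq(1 - alpha, df)
}

add_covariate_effect <- function(model, param, cov, form, courses) {
  vals <- vapply(courses, function(s) {
    v <- s$covariates[[cov]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(is.na(vals)))
    stop("covariate '", cov, "' missing for some subjects")
  model$covariates <- c(model$covariates,
                        list(list(param = param, cov = cov, form = form,
                                  theta = 0,
                                  ref = stats::median(vals))))
  model
}

#' Stepwise covariate selection for a population PK model
#'
#' Forward inclusion / backward elimination of covariate-parameter
#' relationships (linear, power or exponential, centred at the
#' population median) on the approximate marginal likelihood: a
#' candidate enters if it lowers the MOFV by at least
#' `lrt_threshold(1, forward_alpha)` and survives the backward pass
#' only if its removal would raise the MOFV by at least
#' `lrt_threshold(1, backward_alpha)`. Candidates whose fit fails are
#' skipped and logged.
#'
#' @param base A [poppk_model()] (typically an already-fitted base
#'   model's `$model`).
#' @param data Event-record data.frame or list of [subject_course()]s.
#' @param candidates List of candidates, each
#'   `list(param = , cov = , form = )` with
#'   `form` in `"linear"`, `"power"`, `"exponential"`.
#' @param forward_alpha,backward_alpha Thresholds (0.05 / 0.001).
#' @param fit_fun Fitting function `(model, data, ...) -> list` with
#'   elements `mofv` and `model`; defaults to [fit_poppk()]. An
#'   injectable fit function keeps the machinery testable at small
#'   scale.
#' @param ... Passed to `fit_fun` (e.g. `se = FALSE`).
#' @return List with `model` (final), `fit` (final fit), `retained`
#'   (list of retained candidates) and `trace` (decision log
#'   data.frame; AIC included for non-nested comparison).
#' @export
stepwise_covariates <- function(base, data, candidates,
                                forward_alpha = 0.05,
                                backward_alpha = 0.001,
                                fit_fun = fit_poppk, ...) {
  courses <- as_subject_courses(data)
  thr_f <- lrt_threshold(1, forward_alpha)
  thr_b <- lrt_threshold(1, backward_alpha)
  cand_name <- function(cd) paste0(cd$param, "~", cd$cov, "(", cd$form, ")")
  base_fit <- fit_fun(base, courses, ...)
  model <- base_fit$model
  npar_base <- param_map(model)$n
  retained <- list()
  trace <- list()
  if (length(candidates)) {
    repeat {
      pool <- candidates[!vapply(candidates, function(cd)
        any(vapply(retained, identical, logical(1), cd)), logical(1))]
      if (!length(pool)) break
      dm <- rep(NA_real_, length(pool))
      fits <- vector("list", length(pool))
      for (j in seq_along(pool)) {
        cd <- pool[[j]]
        f <- tryCatch({
          m <- add_covariate_effect(model, cd$param, cd$cov, cd$form,
                                    courses)
          fit_fun(m, courses, ...)
        }, error = function(e) NULL)
        if (!is.null(f)) { dm[j] <- base_fit$mofv - f$mofv; fits[[j]] <- f }
        trace[[length(trace) + 1L]] <- data.frame(
          step = "forward", candidate = cand_name(cd),
          delta_mofv = dm[j],
          aic = if (!is.null(f)) f$mofv + 2 * (npar_base +
                                                 length(retained) + 1)
                else NA_real_,
          accepted = FALSE, failed = is.null(f))
      }
      if (all(is.na(dm)) || max(dm, na.rm = TRUE) < thr_f) break
      jbest <- which.max(dm)
      retained <- c(retained, list(pool[[jbest]]))
      base_fit <- fits[[jbest]]
      model <- base_fit$model
      nm <- cand_name(pool[[jbest]])
      for (k in seq_along(trace))
        if (trace[[k]]$step == "forward" && trace[[k]]$candidate == nm)
          trace[[k]]$accepted <- TRUE
    }
    for (idx in rev(seq_along(retained))) {
      cd <- retained[[idx]]
      m0 <- model
      keep <- !vapply(m0$covariates, function(e)
        e$param == cd$param && e$cov == cd$cov && e$form == cd$form,
        logical(1))
      m0$covariates <- m0$covariates[keep]
      f0 <- tryCatch(fit_fun(m0, courses, ...), error = function(e) NULL)
      inc <- if (!is.null(f0)) f0$mofv - base_fit$mofv else NA_real_
      drop_it <- !is.na(inc) && inc < thr_b
      trace[[length(trace) + 1L]] <- data.frame(
        step = "backward", candidate = cand_name(cd), delta_mofv = inc,
        aic = if (!is.null(f0)) f0$mofv + 2 * (npar_base +
                                                 length(retained) - 1)
              else NA_real_,
        accepted = !drop_it, failed = is.null(f0))
      if (drop_it) {
        retained <- retained[-idx]
        base_fit <- f0
        model <- base_fit$model
      }
    }
  }
  list(model = model, fit = base_fit, retained = retained,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = character(0), candidate = character(0),
                    delta_mofv = numeric(0), aic = numeric(0),
                    accepted = logical(0), failed = logical(0)))
}
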