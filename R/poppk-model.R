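#' Random-effects specification
#'
#' Between-subject variability (BSV) of structural parameters is
#' modelled with multiplicative log-normal random effects:
#' `param_i = typical * exp(eta_i)`, `eta ~ N(0, Omega)`. Interoccasion
#' variability (IOV) can be declared for simulation (occasion-level
#' exponential effects); it is not estimated.
#'
#' @param labels Character vector naming the structural parameters that
#'   carry a random effect (subset of CL, Vc, Q, Vp, Ka, tlag).
#' @param omega Either a vector of log-scale variances (diagonal
#'   structure) or a full positive semi-definite covariance matrix.
#' @param iov Optional named vector of occasion-level log-scale
#'   variances (names must be structural parameters); simulation only.
#' @return An object of class `random_effects_spec`.
#' @export
random_effects_spec <- function(labels = character(0), omega = numeric(0),
                                iov = NULL) {
  d <- length(labels)
  if (is.matrix(omega)) {
    if (!all(dim(omega) == d)) stop("omega dimension must match labels")
    om <- omega
  } else {
    if (length(omega) != d) stop("omega length must match labels")
    om <- diag(as.numeric(omega), d)
  }
  if (d > 0) {
    dimnames(om) <- list(labels, labels)
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10)) stop("omega must be positive semi-definite")
  }
  structure(list(labels = labels, omega = om,
                 structure = if (d > 0 && any(om[lower.tri(om)] != 0))
                   "block" else "diagonal",
                 iov = iov),
            class = "random_effects_spec")
}

#' Residual-error specification
#'
#' @param kind One of `"additive_log"` (additive error on
#'   log-transformed observations; reported as an approximate
#'   proportional \%), `"proportional"`, `"additive"`, or `"combined"`
#'   (proportional + additive).
#' @param sigma Error magnitude: log-scale SD (`additive_log`),
#'   fractional CV (`proportional`, and the proportional part of
#'   `combined`), or SD in concentration units (`additive`).
#' @param sigma2 Additive SD component, `combined` only.
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(kind = c("additive_log", "proportional",
                                   "additive", "combined"),
                          sigma, sigma2 = NULL) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive")
  if (kind == "combined") {
    if (is.null(sigma2) || sigma2 < 0)
      stop("combined residual error needs sigma2 >= 0")
  } else if (!is.null(sigma2)) {
    stop("sigma2 is only meaningful for kind = 'combined'")
  }
  structure(list(kind = kind, sigma = sigma, sigma2 = sigma2),
            class = "residual_spec")
}

#' Population pharmacokinetic model
#'
#' Bundles the structural typical values (at 70 kg), the allometric
#' scaling rule, the random-effects covariance, the residual-error
#' model, any parameters held fixed during estimation, and the unit
#' factor mapping model concentrations (dose mg / volume L) to the
#' observation scale.
#'
#' @param typical A [structural_params()] object (70 kg reference).
#' @param random A [random_effects_spec()].
#' @param residual A [residual_spec()].
#' @param allometry An [allometric_rule()].
#' @param fixed Character vector of typical-parameter names excluded
#'   from estimation (e.g. `"Vp"` when fixed to a literature value).
#' @param conc_scale Multiplier from mg/L predictions to the DV unit
#'   (1000 for ng/mL, 1 for ug/mL).
#' @param covariates Optional list of covariate effects, each a list
#'   with elements `param`, `cov`, `form` (`"linear"`, `"power"`,
#'   `"exponential"`), `theta`, and `ref` (centering value).
#' @return An object of class `poppk_model`.
#' @seealso [tacrolimus_model()], [mpa_model()] for the published
#'   parameterisations.
#' @export
poppk_model <- function(typical, random = random_effects_spec(),
                        residual, allometry = allometric_rule(),
                        fixed = character(0), conc_scale = 1,
                        covariates = list()) {
  validate_structural_params(typical)
  if (!inherits(random, "random_effects_spec"))
    stop("random must be a random_effects_spec")
  if (!inherits(residual, "residual_spec"))
    stop("residual must be a residual_spec")
  bad <- setdiff(random$labels, names(unclass(typical)))
  if (length(bad))
    stop("random-effect labels without a structural parameter: ",
         paste(bad, collapse = ", "))
  if (length(fixed) && !all(fixed %in% names(unclass(typical))))
    stop("fixed labels must name structural parameters")
  structure(list(typical = typical, random = random, residual = residual,
                 allometry = allometry, fixed = fixed,
                 conc_scale = conc_scale, covariates = covariates),
            class = "poppk_model")
}

#' Final tacrolimus population PK model
#'
#' Two-compartment oral model with lag time for whole-blood tacrolimus
#' in adult kidney transplant recipients: CL/F 16.5 L/h/70 kg, Vc/F
#' 311 L/70 kg, Q/F 20.5 L/h/70 kg, Vp/F 56300 L/70 kg, Ka 3.08 1/h,
#' tlag 0.295 h; BSV on CL (57.6\%), Q (68.9\%) and Vc (55.6\%);
#' additive residual error on log-transformed concentrations (36.6\%).
#' Concentrations in ng/mL, doses in mg.
#'
#' @return A [poppk_model()] object.
#' @export
tacrolimus_model <- function() {
  poppk_model(
    typical = structural_params(CL = 16.5, Vc = 311, Q = 20.5,
                                Vp = 56300, Ka = 3.08, tlag = 0.295),
    random = random_effects_spec(c("CL", "Q", "Vc"),
                                 c(0.576, 0.689, 0.556)^2),
    residual = residual_spec("additive_log", sigma = 0.366),
    conc_scale = 1000)
}

#' Final mycophenolic acid population PK model
#'
#' Two-compartment oral model with lag time for plasma MPA: CL/F
#' 11.8 L/h/70 kg, Vc/F 106 L/70 kg, Q/F 37.1 L/h/70 kg, Vp/F fixed at
#' 800 L/70 kg (literature value), Ka 1.79 1/h, tlag 0.243 h; BSV on CL
#' (34.9\%), Vc (133.8\%) and Vp (164.6\%); proportional residual error
#' (55.3\%). Concentrations in ug/mL, doses in mg of MPA molar
#' equivalent (see [mmf_to_mpa_equivalent()]).
#'
#' @return A [poppk_model()] object.
#' @export
mpa_model <- function() {
  poppk_model(
    typical = structural_params(CL = 11.8, Vc = 106, Q = 37.1,
                                Vp = 800, Ka = 1.79, tlag = 0.243),
    random = random_effects_spec(c("CL", "Vc", "Vp"),
                                 c(0.349, 1.338, 1.646)^2),
    residual = residual_spec("proportional", sigma = 0.553),
    fixed = "Vp",
    conc_scale = 1)
}

covariate_multiplier <- function(effect, covs) {
  x <- covs[[effect$cov]]
  if (is.null(x) || is.na(x))
    stop("missing covariate '", effect$cov, "' for covariate effect")
  switch(effect$form,
         linear = 1 + effect$theta * (x - effect$ref),
         power = (x / effect$ref)^effect$theta,
         exponential = exp(effect$theta * (x - effect$ref)),
         stop("unknown covariate form: ", effect$form))
}

#' Individual structural parameters
#'
#' Combines typical values, covariate effects, allometric body-weight
#' scaling and the subject's log-normal random effects:
#' `param_i = typical * cov_effects * (W/70)^exp * exp(eta)`.
#'
#' @param model A [poppk_model()].
#' @param eta Named numeric vector of log-scale random effects; names
#'   must be among the model's random-effect labels. Parameters without
#'   a random effect implicitly use `eta = 0`.
#' @param weight Body weight in kg.
#' @param covs Optional named list/vector of covariate values (needed
#'   only if the model carries covariate effects).
#' @return A [structural_params()] object for the individual.
#' @export
individual_params <- function(model, eta = numeric(0), weight = 70,
                              covs = NULL) {
  p <- unclass(model$typical)
  for (eff in model$covariates)
    p[[eff$param]] <- p[[eff$param]] * covariate_multiplier(eff, covs)
  class(p) <- "structural_params"
  p <- apply_allometry(p, weight, model$allometry)
  if (length(eta)) {
    if (is.null(names(eta))) {
      if (length(eta) != length(model$random$labels))
        stop("eta length must match the random-effect labels")
      names(eta) <- model$random$labels
    }
    bad <- setdiff(names(eta), model$random$labels)
    if (length(bad))
      stop("eta names not in random-effect labels: ",
           paste(bad, collapse = ", "))
    q <- unclass(p)
    q[names(eta)] <- q[names(eta)] * exp(eta)
    class(q) <- "structural_params"
    p <- q
  }
  p
}

#' Residual standard deviation at a given prediction
#'
#' @param residual A [residual_spec()].
#' @param f Predicted value(s) on the observation scale (for
#'   `additive_log`, on the log scale the SD is constant).
#' @return Vector of residual SDs, same length as `f`.
#' @keywords internal
residual_sd <- function(residual, f) {
  switch(residual$kind,
         additive_log = rep(residual$sigma, length(f)),
         additive = rep(residual$sigma, length(f)),
         proportional = residual$sigma * pmax(abs(f), 1e-12),
         combined = sqrt(residual$sigma2^2 +
                           (residual$sigma * f)^2))
}

#' @export
print.poppk_model <- function(x, ...) {
  cat("Population PK model: two-compartment oral with lag time\n")
  cat("Typical values (per 70 kg):\n")
  print(round(unclass(x$typical), 4))
  if (length(x$fixed))
    cat("Fixed during estimation:", paste(x$fixed, collapse = ", "), "\n")
  if (length(x$random$labels)) {
    bsv <- 100 * sqrt(diag(x$random$omega))
    cat("Between-subject variability (%):\n")
    print(round(stats::setNames(bsv, x$random$labels), 1))
  } else cat("No random effects\n")
  cat("Residual error:", x$residual$kind, "sigma =", x$residual$sigma,
      if (!is.null(x$residual$sigma2)) paste("sigma2 =", x$residual$sigma2),
      "\n")
  if (length(x$covariates))
    for (eff in x$covariates)
      cat(sprintf("Covariate effect: %s on %s (%s), theta = %.4g (ref %.4g)\n",
                  eff$cov, eff$param, eff$form, eff$theta, eff$ref))
  invisible(x)
}
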