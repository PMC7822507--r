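#' Synthetic-trial configuration
#'
#' Defines the design of the emulated kidney-transplant trial: 58
#' subjects, five visits (week 1 on a day uniform in 1-11, then months
#' 1, 2, 3 and 6), rich week-1 sampling (0, 0.5, 1, 1.5, 2, 3, 4, 6, 8,
#' 12 h post-dose) and sparse later sampling (0, 1.5, 2, 4 h),
#' twice-daily dosing with occasion-specific mean daily dose levels,
#' log-normal body weights (median 73 kg, IQR 62.9-86.8), log-normal
#' urinary biomarker distributions per occasion with an elevated
#' pre-rejection miR155-5p distribution, and the published PK and
#' logistic parameters as simulation truth.
#'
#' Doses are entered as daily totals (mg/day; MPA as MMF mg/day,
#' converted internally to MPA molar equivalents) and split over two
#' administrations 12 h apart. Dose titration is not fed back; each
#' occasion's mean dose level holds until the midpoint to the next
#' visit.
#'
#' Therapeutic drug monitoring is emulated by a per-subject dose
#' multiplier `(target trough / individual predicted trough)^tdm_strength`
#' clipped to `[1/3, 3]`, reflecting partial titration of each
#' subject's dose toward the population-typical trough; `tdm_strength
#' = 0` gives fully static dosing. Biomarker component spreads are
#' capped at log-SD 1 so that the elevated/non-elevated *mixture* (not
#' each component) carries the published inter-quartile spread; without
#' the cap the log-normal tails of the non-elevated component alone
#' would generate far more rejection events than observed.
#'
#' @param n_subjects Number of subjects (58).
#' @param miss_rate Probability that a visit record is missing from the
#'   logistic dataset (calibrated so about 183 of 290 records survive).
#' @param p_elevated Probability that a visit's miR155-5p value is
#'   drawn from the elevated pre-rejection distribution (calibrated,
#'   jointly with the logistic truth, so that about 8 of 58 subjects
#'   reject).
#' @param tdm_strength Exponent of the dose-titration multiplier
#'   (default 0.9; 0 disables TDM emulation).
#' @param sdlog_cap Upper bound on biomarker component log-SDs
#'   (default 1).
#' @param pk_truth_tac,pk_truth_mpa Simulation-truth PK models; default
#'   the published final models.
#' @param logit_truth Simulation-truth logistic model (list with
#'   `beta0`, `beta1` on the miR155-5p scale).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_subjects = 58, miss_rate = 0.369,
                         p_elevated = 0.03, tdm_strength = 0.9,
                         sdlog_cap = 1,
                         pk_truth_tac = tacrolimus_model(),
                         pk_truth_mpa = mpa_model(),
                         logit_truth = list(beta0 = -5.89, beta1 = 3.51)) {
  stopifnot(n_subjects >= 1, miss_rate >= 0, miss_rate <= 1,
            p_elevated >= 0, p_elevated <= 1, tdm_strength >= 0,
            tdm_strength <= 1)
  visits <- c("W1", "M1", "M2", "M3", "M6")
  structure(list(
    n_subjects = n_subjects,
    visits = visits,
    visit_days = c(W1 = NA, M1 = 30, M2 = 60, M3 = 90, M6 = 180),
    week1_day_range = c(1, 11),
    rich_times = c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12),
    sparse_times = c(0, 1.5, 2, 4),
    ## Occasion mean daily doses (mg/day); MPA doses are MMF mg/day
    dose_daily_tac = c(W1 = 14.60, M1 = 10.63, M2 = 7.78, M3 = 6.79,
                       M6 = 5.29),
    dose_daily_mmf = c(W1 = 1875.91, M1 = 1655.41, M2 = 1552.02,
                       M3 = 1402.64, M6 = 1238.67),
    dose_interval = 12,
    weight = list(meanlog = log(73),
                  sdlog = (log(86.8) - log(62.9)) / (2 * stats::qnorm(0.75))),
    ## Biomarker log-normal parameters per occasion: geometric mean and
    ## IQR-derived sdlog
    mir155 = lognorm_table(
      gm = c(W1 = 0.08, M1 = 0.20, M2 = 0.21, M3 = 0.12, M6 = 0.14),
      q25 = c(0.03, 0.05, 0.06, 0.04, 0.04),
      q75 = c(0.23, 0.96, 0.81, 0.40, 0.61), cap = sdlog_cap),
    mir155_elevated = lognorm_table(gm = c(all = 1.50), q25 = 1.15,
                                    q75 = 1.85, cap = sdlog_cap),
    cxcl10 = lognorm_table(
      gm = c(W1 = 73.81, M1 = 38.04, M2 = 36.65, M3 = 43.90, M6 = 43.66),
      q25 = c(37.98, 18.59, 15.81, 23.65, 20.19),
      q75 = c(144.49, 72.44, 66.12, 86.83, 107.53), cap = sdlog_cap),
    cxcl10_elevated = lognorm_table(gm = c(all = 171.2), q25 = 148.09,
                                    q75 = 206.64, cap = sdlog_cap),
    miss_rate = miss_rate,
    p_elevated = p_elevated,
    tdm_strength = tdm_strength,
    pk_truth_tac = pk_truth_tac,
    pk_truth_mpa = pk_truth_mpa,
    logit_truth = logit_truth),
    class = "trial_config")
}

lognorm_table <- function(gm, q25, q75, cap = Inf) {
  data.frame(occ = names(gm), meanlog = log(as.numeric(gm)),
             sdlog = pmin((log(q75) - log(q25)) / (2 * stats::qnorm(0.75)),
                          cap),
             row.names = NULL)
}

rlnorm_occ <- function(n, tab, occ) {
  i <- if (nrow(tab) == 1L) rep(1L, length(occ)) else match(occ, tab$occ)
  stats::rlnorm(n, tab$meanlog[i], tab$sdlog[i])
}

#' Sample the trial population
#'
#' Draws subject skeletons: body weight (log-normal, median 73 kg),
#' demographic covariates and the week-1 visit day (uniform on days
#' 1-11).
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return data.frame with one row per subject: `id`, `weight`, `age`,
#'   `sex`, `donor_type`, `donor_age`, `gfr`, `diabetes`, `week1_day`.
#' @export
sample_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  data.frame(
    id = seq_len(n),
    weight = stats::rlnorm(n, config$weight$meanlog, config$weight$sdlog),
    age = round(stats::rlnorm(n, log(48), 0.27)),
    sex = sample(c("F", "M"), n, TRUE, prob = c(20, 38) / 58),
    donor_type = sample(c("living", "cadaveric"), n, TRUE,
                        prob = c(30, 28) / 58),
    donor_age = round(stats::rlnorm(n, log(52), 0.2)),
    gfr = stats::rlnorm(n, log(44), 0.55),
    diabetes = stats::rbinom(n, 1, 5 / 58),
    week1_day = sample(seq(config$week1_day_range[1],
                           config$week1_day_range[2]), n, TRUE))
}

## Visit days (h) for one subject.
visit_hours <- function(config, week1_day) {
  days <- config$visit_days
  days["W1"] <- week1_day
  24 * days[config$visits]
}

## Twice-daily dose events with occasion-specific amounts. The level of
## each occasion holds from the midpoint to the previous visit until the
## midpoint to the next one (week-1 level from time 0).
dose_events <- function(config, week1_day, daily_levels) {
  vh <- visit_hours(config, week1_day)
  tau <- config$dose_interval
  end <- vh[["M6"]] + tau
  bounds <- c(0, (vh[-length(vh)] + vh[-1]) / 2, end)
  times <- seq(0, end, by = tau)
  lev <- daily_levels[findInterval(times, bounds, rightmost.closed = TRUE)]
  data.frame(time = times, amt = as.numeric(lev) / 2)
}

#' Simulate PK observations for a sampled population
#'
#' Builds each subject's twice-daily dose history, draws log-normal
#' between-subject random effects from the truth model's omega, computes
#' individual predictions and adds residual noise per the truth model's
#' residual specification. All simulated concentrations are strictly
#' positive.
#'
#' @param population A [sample_population()] data.frame.
#' @param pk_truth A [poppk_model()] used as simulation truth.
#' @param config A [trial_config()].
#' @param drug `"tac"` (tacrolimus, ng/mL) or `"mpa"` (MPA molar
#'   equivalents of the MMF dose, ug/mL).
#' @param seed Integer seed.
#' @return List of [subject_course()] objects with attribute `etas`
#'   (matrix of the simulated random effects).
#' @export
simulate_pk <- function(population, pk_truth, config,
                        drug = c("tac", "mpa"), seed = NULL) {
  drug <- match.arg(drug)
  if (!is.null(seed)) set.seed(seed)
  d <- length(pk_truth$random$labels)
  Lo <- if (d) t(chol(pk_truth$random$omega)) else NULL
  etas <- matrix(0, nrow(population), d,
                 dimnames = list(population$id, pk_truth$random$labels))
  courses <- vector("list", nrow(population))
  tdm <- config$tdm_strength
  if (is.null(tdm)) tdm <- 0
  if (tdm > 0) {
    ## steady-dosing probe used to titrate each subject toward the
    ## population-typical trough
    probe <- data.frame(time = seq(0, 156, by = 12), amt = 1)
    m_ref <- pk_truth
    m_ref$covariates <- list()   # reference subject sits at the covariate refs
    c_ref <- predict_concentration(
      individual_params(m_ref, numeric(0), 70), probe, 168)
  }
  for (i in seq_len(nrow(population))) {
    s <- population[i, ]
    daily <- if (drug == "tac") config$dose_daily_tac
             else mmf_to_mpa_equivalent(config$dose_daily_mmf)
    doses <- dose_events(config, s$week1_day, daily)
    vh <- visit_hours(config, s$week1_day)
    obs_t <- c(vh[["W1"]] + config$rich_times,
               unlist(lapply(config$visits[-1], function(v)
                 vh[[v]] + config$sparse_times)))
    occ <- c(rep("W1", length(config$rich_times)),
             rep(config$visits[-1], each = length(config$sparse_times)))
    eta <- if (d) drop(Lo %*% stats::rnorm(d)) else numeric(0)
    if (d) etas[i, ] <- eta
    names(eta) <- pk_truth$random$labels
    p <- individual_params(pk_truth, eta, s$weight, covs = as.list(s))
    if (tdm > 0) {
      c_i <- predict_concentration(p, probe, 168)
      doses$amt <- doses$amt * min(max((c_ref / c_i)^tdm, 1/3), 3)
    }
    f <- predict_concentration(p, doses, obs_t) * pk_truth$conc_scale
    dv <- draw_residual(pk_truth$residual, f)
    courses[[i]] <- subject_course(
      id = s$id, weight = s$weight, doses = doses,
      obs = data.frame(time = obs_t, dv = dv, occ = occ),
      covariates = as.list(s[c("age", "sex", "donor_type", "donor_age",
                               "gfr", "diabetes")]))
  }
  attr(courses, "etas") <- etas
  courses
}

#' Simulate urinary biomarkers and acute-rejection events
#'
#' Each visit's miR155-5p value is drawn from the occasion-specific
#' log-normal distribution, or from the elevated pre-rejection
#' distribution with probability `p_elevated`. A rejection diagnosed at
#' visit `v` occurs with probability
#' `plogis(beta0 + beta1 * miR155[prior visit])`; for the first visit
#' (no predecessor) the same visit's value is used. CXCL-10 is drawn
#' from its occasion distribution (elevated distribution on pre-AR
#' visits).
#'
#' @inheritParams simulate_pk
#' @param logit_truth List with `beta0` and `beta1` (miR155-5p scale).
#' @return data.frame with one row per subject-visit: `subject`,
#'   `visit`, `miR155`, `CXCL10`, `elevated` (simulation bookkeeping)
#'   and `ar_diagnosed` (1 if rejection is diagnosed at that visit).
#' @export
simulate_biomarkers_and_ar <- function(population, logit_truth, config,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  visits <- config$visits
  nv <- length(visits)
  rows <- list()
  for (i in seq_len(nrow(population))) {
    elev <- stats::runif(nv) < config$p_elevated
    mir <- ifelse(elev,
                  rlnorm_occ(nv, config$mir155_elevated, visits),
                  rlnorm_occ(nv, config$mir155, visits))
    cx <- ifelse(elev,
                 rlnorm_occ(nv, config$cxcl10_elevated, visits),
                 rlnorm_occ(nv, config$cxcl10, visits))
    prior <- c(1, seq_len(nv - 1))  # predecessor index (first maps to itself)
    p_ar <- stats::plogis(logit_truth$beta0 + logit_truth$beta1 * mir[prior])
    ar <- stats::rbinom(nv, 1, p_ar)
    rows[[i]] <- data.frame(subject = population$id[i], visit = visits,
                            miR155 = mir, CXCL10 = cx,
                            elevated = as.integer(elev),
                            ar_diagnosed = ar)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate visit records directly from the logistic truth
#'
#' Draws miR155-5p values from the generator's marginal mixture
#' (occasion-specific log-normal components plus the elevated
#' pre-rejection component) and Bernoulli outcomes from
#' `plogis(beta0 + beta1 * miR155)`. This is the direct
#' record-level experiment used for coefficient-recovery studies,
#' without the visit-sequence bookkeeping of [simulate_trial()].
#'
#' @param n Number of visit records.
#' @param config A [trial_config()] (supplies biomarker distributions
#'   and the logistic truth).
#' @param seed Integer seed.
#' @return data.frame with columns `subject`, `visit`, `miR155`,
#'   `outcome`.
#' @export
simulate_logistic_records <- function(n, config = trial_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  visits <- sample(config$visits, n, TRUE)
  elev <- stats::runif(n) < config$p_elevated
  mir <- ifelse(elev,
                rlnorm_occ(n, config$mir155_elevated, visits),
                rlnorm_occ(n, config$mir155, visits))
  p <- stats::plogis(config$logit_truth$beta0 +
                       config$logit_truth$beta1 * mir)
  data.frame(subject = seq_len(n), visit = visits, miR155 = mir,
             outcome = stats::rbinom(n, 1, p))
}

#' Simulate a complete synthetic trial
#'
#' Composes [sample_population()], [simulate_pk()] for both drugs and
#' [simulate_biomarkers_and_ar()], applies visit-record missingness,
#' and assembles the three analysis datasets plus a truth record for
#' recovery studies.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; the stage seeds are derived from it.
#' @return List with elements `tac` and `mpa` (lists of
#'   [subject_course()]), `biomarkers` (all simulated visit rows),
#'   `logistic` (the visit-level dataset after missingness, built with
#'   the prior-visit outcome shift via [build_logistic_dataset()]), and
#'   `truth` (simulation bookkeeping: PK models, logistic coefficients,
#'   simulated etas, rejection counts).
#' @export
simulate_trial <- function(config = trial_config(), seed = 1) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)
  population <- sample_population(config, stage_seeds[1])
  tac <- simulate_pk(population, config$pk_truth_tac, config, "tac",
                     stage_seeds[2])
  mpa <- simulate_pk(population, config$pk_truth_mpa, config, "mpa",
                     stage_seeds[3])
  bio <- simulate_biomarkers_and_ar(population, config$logit_truth, config,
                                    stage_seeds[4])
  keep <- stats::runif(nrow(bio)) >= config$miss_rate
  ## Never drop the predictor record of a diagnosed rejection: those
  ## visits were always sampled before treatment modification.
  vidx <- match(bio$visit, config$visits)
  prior_of_ar <- rep(FALSE, nrow(bio))
  for (s in unique(bio$subject)) {
    rows <- which(bio$subject == s)
    arv <- vidx[rows][bio$ar_diagnosed[rows] == 1]
    if (length(arv))
      prior_of_ar[rows[vidx[rows] %in% pmax(arv - 1, 1)]] <- TRUE
  }
  keep <- keep | prior_of_ar
  bio_obs <- bio[keep, , drop = FALSE]
  exposures <- trial_exposures(tac, mpa, config, population)
  ar_events <- bio[bio$ar_diagnosed == 1, c("subject", "visit")]
  logistic <- build_logistic_dataset(exposures, bio_obs, ar_events,
                                     visit_order = config$visits)
  list(tac = tac, mpa = mpa, biomarkers = bio, logistic = logistic,
       truth = list(config = config,
                    pk_tac = config$pk_truth_tac,
                    pk_mpa = config$pk_truth_mpa,
                    logit = config$logit_truth,
                    etas_tac = attr(tac, "etas"),
                    etas_mpa = attr(mpa, "etas"),
                    n_ar_events = sum(bio$ar_diagnosed),
                    n_ar_subjects = length(unique(
                      bio$subject[bio$ar_diagnosed == 1]))))
}

## Individual predicted exposures (cumulative AUC from transplant to
## each visit and mean predicted trough up to each visit) at the
## simulation-truth individual parameters.
trial_exposures <- function(tac, mpa, config, population) {
  rows <- list()
  for (i in seq_along(tac)) {
    st <- tac[[i]]; sm <- mpa[[i]]
    vh <- visit_hours(config, population$week1_day[i])
    eta_t <- attr(tac, "etas")[i, ]
    eta_m <- attr(mpa, "etas")[i, ]
    pt <- individual_params(config$pk_truth_tac, eta_t, st$weight)
    pm <- individual_params(config$pk_truth_mpa, eta_m, sm$weight)
    for (v in seq_along(config$visits)) {
      tv <- vh[[v]]
      troughs <- vh[seq_len(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = st$id, visit = config$visits[v],
        auc_tac = cumulative_auc(pt, st$doses, tv) *
          config$pk_truth_tac$conc_scale,
        auc_mpa = cumulative_auc(pm, sm$doses, tv) *
          config$pk_truth_mpa$conc_scale,
        trough_tac = mean_trough(pt, st$doses, troughs) *
          config$pk_truth_tac$conc_scale,
        trough_mpa = mean_trough(pm, sm$doses, troughs) *
          config$pk_truth_mpa$conc_scale)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
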