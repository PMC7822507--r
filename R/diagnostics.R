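## Model-evaluation machinery: prediction-corrected VPC for the PK
## models, categorical VPC and calibration bars for the logistic model,
## normalized prediction distribution errors, nonparametric bootstrap.
## All stochastic diagnostics are reproducible bit-for-bit given
## (seed, n_sim).

quantile_bins <- function(x, n_bins, min_per_bin = 2L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  if (length(br) < 2L) br <- range(x) + c(-1e-9, 1e-9)
  br[1] <- br[1] - 1e-9; br[length(br)] <- br[length(br)] + 1e-9
  idx <- findInterval(x, br, rightmost.closed = TRUE)
  ## merge under-filled bins into their left neighbour
  repeat {
    tab <- tabulate(idx, nbins = length(br) - 1L)
    small <- which(tab > 0 & tab < min_per_bin)
    if (!length(small) || length(br) <= 2L) break
    b <- small[1]
    br <- br[-max(b, 2L)]
    idx <- findInterval(x, br, rightmost.closed = TRUE)
  }
  list(idx = idx, breaks = br)
}

time_after_dose <- function(subj) {
  vapply(subj$obs$time, function(t) {
    prev <- subj$doses$time[subj$doses$time <= t]
    if (length(prev)) t - max(prev) else t
  }, numeric(1))
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset at the original design,
#' prediction-corrects observed and simulated values by
#' `pcY = Y * median(PRED in bin) / PRED` (PRED = population
#' prediction), bins by time after dose, and compares the observed
#' 2.5th/50th/97.5th percentiles per bin with the 95% confidence bands
#' of the same percentiles across simulations.
#'
#' @param fit A [fit_poppk()] result, or a [poppk_model()] together
#'   with `data`.
#' @param data Event-record data / subject courses (unused when `fit`
#'   is a `poppk_fit`).
#' @param n_sim Number of simulated replicate datasets (default 1000).
#' @param bins Number of time-after-dose quantile bins (default 8;
#'   bins with fewer than 2 observations are merged with a neighbour).
#' @param seed Integer seed.
#' @return An object of class `vpc_result`: per-bin observed
#'   percentiles and simulated percentile confidence bands.
#' @export
pcvpc <- function(fit, data = NULL, n_sim = 1000, bins = 8, seed = 1) {
  if (inherits(fit, "poppk_fit")) {
    model <- fit$model; courses <- fit$courses
  } else {
    model <- fit; courses <- as_subject_courses(data)
  }
  obs <- unlist(lapply(courses, function(s) s$obs$dv))
  tad <- unlist(lapply(courses, time_after_dose))
  pred <- unlist(lapply(courses, function(s) {
    if (nrow(s$obs) == 0L) return(numeric(0))
    make_resid_fun(model, s)(numeric(length(model$random$labels)))$f
  }))
  sims <- simulate_observations(model, courses, n_sim, seed)$dv
  qb <- quantile_bins(tad, bins)
  probs <- c(0.025, 0.5, 0.975)
  out <- list()
  for (b in sort(unique(qb$idx))) {
    sel <- qb$idx == b
    corr <- stats::median(pred[sel]) / pred[sel]
    po <- stats::quantile(obs[sel] * corr, probs, names = FALSE)
    sim_q <- apply(sims[sel, , drop = FALSE] * corr, 2, stats::quantile,
                   probs = probs, names = FALSE)
    ci <- apply(sim_q, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      bin = b, tad_lo = qb$breaks[b], tad_hi = qb$breaks[b + 1],
      tad_mid = stats::median(tad[sel]), n = sum(sel),
      obs_p2.5 = po[1], obs_p50 = po[2], obs_p97.5 = po[3],
      sim_p2.5_lo = ci[1, 1], sim_p2.5_med = ci[2, 1],
      sim_p2.5_hi = ci[3, 1],
      sim_p50_lo = ci[1, 2], sim_p50_med = ci[2, 2], sim_p50_hi = ci[3, 2],
      sim_p97.5_lo = ci[1, 3], sim_p97.5_med = ci[2, 3],
      sim_p97.5_hi = ci[3, 3])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("vpc_result", "data.frame"),
            type = "pcvpc", n_sim = n_sim, seed = seed)
}

#' Visual predictive check for the binary rejection outcome
#'
#' Simulates rejection outcomes `n_sim` times at the observed predictor
#' values and compares the observed rejection proportion per
#' explanatory-variable bin with the median and 95% prediction interval
#' of the simulated proportions.
#'
#' @param fit An [fit_logistic()] result.
#' @param records Visit records (defaults to those used in the fit).
#' @param n_sim Number of outcome simulations (default 1000).
#' @param n_bins Number of quantile bins over the explanatory variable
#'   (default 6; empty bins merged).
#' @param x Explanatory variable to bin on (default the first fitted
#'   predictor).
#' @param seed Integer seed.
#' @return An object of class `vpc_result` with per-bin observed
#'   proportion, simulated median and 95% band.
#' @export
categorical_vpc <- function(fit, records = NULL, n_sim = 1000, n_bins = 6,
                            x = NULL, seed = 1) {
  if (is.null(records)) records <- fit$records
  if (is.null(x)) x <- fit$predictors[1]
  xv <- records[[x]]
  p <- risk(fit, records)
  qb <- quantile_bins(xv, n_bins)
  set.seed(seed)
  simy <- matrix(stats::rbinom(length(p) * n_sim, 1, rep(p, n_sim)),
                 ncol = n_sim)
  out <- list()
  for (b in sort(unique(qb$idx))) {
    sel <- qb$idx == b
    simprop <- colMeans(simy[sel, , drop = FALSE])
    qs <- stats::quantile(simprop, c(0.025, 0.5, 0.975), names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      bin = b, x_lo = qb$breaks[b], x_hi = qb$breaks[b + 1],
      x_mid = stats::median(xv[sel]), n = sum(sel),
      obs_prop = mean(records$outcome[sel]),
      sim_lo = qs[1], sim_med = qs[2], sim_hi = qs[3])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("vpc_result", "data.frame"),
            type = "categorical", n_sim = n_sim, seed = seed,
            variable = x)
}

#' Observed versus predicted rejection proportions in bins
#'
#' Partitions the explanatory variable into `n_bins` contiguous
#' equal-width bins covering its range and reports the observed mean
#' outcome and mean model-predicted risk per bin (the grouped-bar
#' calibration display).
#'
#' @inheritParams categorical_vpc
#' @param n_bins Number of bins (default 10).
#' @return An object of class `grouped_bar` (data.frame): bin bounds,
#'   count, observed and predicted proportions (`NA` for empty bins).
#' @export
grouped_bar <- function(fit, records = NULL, n_bins = 10, x = NULL) {
  if (is.null(records)) records <- fit$records
  if (is.null(x)) x <- fit$predictors[1]
  xv <- records[[x]]
  br <- seq(min(xv), max(xv), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  idx <- findInterval(xv, br, rightmost.closed = TRUE)
  p <- risk(fit, records)
  res <- data.frame(bin = seq_len(n_bins),
                    x_lo = br[-(n_bins + 1)], x_hi = br[-1],
                    n = tabulate(idx, n_bins),
                    observed = NA_real_, predicted = NA_real_)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    if (any(sel)) {
      res$observed[b] <- mean(records$outcome[sel])
      res$predicted[b] <- mean(p[sel])
    }
  }
  structure(res, class = c("grouped_bar", "data.frame"), variable = x)
}

#' Normalized prediction distribution errors
#'
#' For each subject, decorrelates the observed and simulated
#' observation vectors with the mean and Cholesky factor of the
#' simulation covariance, computes each observation's rank-based
#' prediction discrepancy among its simulated counterparts, and maps it
#' through the inverse standard-normal CDF. Under a correct model the
#' npde are approximately N(0, 1).
#'
#' @inheritParams pcvpc
#' @param n_sim Number of simulations (>= 100; default 1000).
#' @return An object of class `npde_result`: data.frame (`id`, `time`,
#'   `occ`, `npde`) with a `summary` attribute (mean, variance,
#'   Shapiro-Wilk statistic and p-value).
#' @export
npde <- function(fit, data = NULL, n_sim = 1000, seed = 1) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (inherits(fit, "poppk_fit")) {
    model <- fit$model; courses <- fit$courses
  } else {
    model <- fit; courses <- as_subject_courses(data)
  }
  sims <- simulate_observations(model, courses, n_sim, seed)
  res <- list()
  row0 <- 0L
  for (subj in courses) {
    no <- nrow(subj$obs)
    if (no == 0L) next
    rows <- row0 + seq_len(no)
    S <- sims$dv[rows, , drop = FALSE]
    mu <- rowMeans(S)
    V <- stats::cov(t(S))
    L <- tryCatch(t(chol(V)), error = function(e) {
      message("singular simulation covariance for subject ", subj$id,
              "; ridge-regularized")
      t(chol(V + diag(1e-8 * mean(diag(V)), no)))
    })
    ystar <- forwardsolve(L, subj$obs$dv - mu)
    sstar <- forwardsolve(L, S - mu)
    cnt <- rowSums(sstar < ystar)
    pd <- (cnt + 0.5) / (n_sim + 1)
    res[[length(res) + 1L]] <- data.frame(
      id = subj$id, time = subj$obs$time, occ = subj$obs$occ,
      npde = stats::qnorm(pd))
    row0 <- row0 + no
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  v <- out$npde
  sw <- if (length(v) >= 3 && length(v) <= 5000)
    stats::shapiro.test(v) else NULL
  structure(out, class = c("npde_result", "data.frame"),
            summary = list(mean = mean(v), variance = stats::var(v),
                           shapiro_W = if (!is.null(sw)) unname(sw$statistic)
                           else NA_real_,
                           shapiro_p = if (!is.null(sw)) sw$p.value
                           else NA_real_),
            n_sim = n_sim, seed = seed)
}

#' Nonparametric bootstrap of a fitting procedure
#'
#' Resamples subjects with replacement, refits, and summarises the
#' resampled parameter estimates by their median and 2.5th/97.5th
#' percentiles. Failed refits are counted, never silently dropped; the
#' result is flagged unstable if more than 20% fail.
#'
#' @param fit_procedure Function taking a list of [subject_course()]
#'   objects (or, for the logistic model, a record data.frame) and
#'   returning a named numeric vector of parameter estimates.
#' @param data The original dataset (subject courses, event records, or
#'   a visit-record data.frame with a `subject` column).
#' @param n_resamples Number of bootstrap resamples (>= 50; the
#'   published analyses used 1000 for the PK models and 200 for the
#'   logistic model).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_result`: per-parameter median
#'   and percentile table, `n_resamples`, `n_failed`, `unstable` flag
#'   and the raw estimate matrix.
#' @export
bootstrap_fit <- function(fit_procedure, data, n_resamples = 200,
                          seed = 1) {
  if (n_resamples < 50) stop("n_resamples must be at least 50")
  is_records <- is.data.frame(data) && "subject" %in% names(data)
  units <- if (is_records) unique(data$subject)
           else as_subject_courses(data)
  n <- if (is_records) length(units) else length(units)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  nrow = n)
  est <- NULL
  n_failed <- 0L
  for (k in seq_len(n_resamples)) {
    take <- draws[, k]
    resample <- if (is_records) {
      do.call(rbind, lapply(seq_along(take), function(j) {
        d <- data[data$subject == units[take[j]], , drop = FALSE]
        d$subject <- j
        d
      }))
    } else {
      lapply(seq_along(take), function(j) {
        s <- units[[take[j]]]
        s$id <- j
        s
      })
    }
    v <- tryCatch(fit_procedure(resample), error = function(e) NULL)
    if (is.null(v) || any(!is.finite(v))) {
      n_failed <- n_failed + 1L
    } else {
      est <- rbind(est, v)
    }
  }
  if (is.null(est)) stop("all bootstrap refits failed")
  tab <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, stats::median),
    p2.5 = apply(est, 2, stats::quantile, 0.025),
    p97.5 = apply(est, 2, stats::quantile, 0.975))
  rownames(tab) <- NULL
  structure(list(table = tab, n_resamples = n_resamples,
                 n_failed = n_failed,
                 unstable = n_failed > 0.2 * n_resamples,
                 estimates = est),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d resamples, %d failed%s\n",
              x$n_resamples, x$n_failed,
              if (x$unstable) "  [UNSTABLE: >20% failures]" else ""))
  print(transform(x$table, median = signif(median, 4),
                  p2.5 = signif(p2.5, 4), p97.5 = signif(p97.5, 4)))
  invisible(x)
}

## ---- plotting (cosmetic layer) --------------------------------------

#' @export
plot.vpc_result <- function(x, log = "", xlab = NULL, ylab = NULL, ...) {
  if (attr(x, "type") == "pcvpc") {
    xv <- x$tad_mid
    if (is.null(xlab)) xlab <- "time after dose (h)"
    if (is.null(ylab)) ylab <- "prediction-corrected concentration"
    ylim <- range(x$obs_p2.5, x$obs_p97.5, x$sim_p2.5_lo, x$sim_p97.5_hi)
    graphics::plot(xv, x$obs_p50, type = "n", ylim = ylim, log = log,
                   xlab = xlab, ylab = ylab, ...)
    band <- function(lo, hi, col)
      graphics::polygon(c(xv, rev(xv)), c(lo, rev(hi)), border = NA,
                        col = col)
    band(x$sim_p2.5_lo, x$sim_p2.5_hi, grDevices::adjustcolor("steelblue", 0.4))
    band(x$sim_p97.5_lo, x$sim_p97.5_hi, grDevices::adjustcolor("steelblue", 0.4))
    band(x$sim_p50_lo, x$sim_p50_hi, grDevices::adjustcolor("firebrick", 0.4))
    graphics::lines(xv, x$obs_p50, col = "firebrick", lwd = 2)
    graphics::lines(xv, x$obs_p2.5, col = "firebrick", lty = 2)
    graphics::lines(xv, x$obs_p97.5, col = "firebrick", lty = 2)
  } else {
    xv <- x$x_mid
    if (is.null(xlab)) xlab <- attr(x, "variable")
    if (is.null(ylab)) ylab <- "rejection proportion"
    graphics::plot(xv, x$obs_prop, type = "n",
                   ylim = range(0, x$obs_prop, x$sim_hi), xlab = xlab,
                   ylab = ylab, ...)
    graphics::polygon(c(xv, rev(xv)), c(x$sim_lo, rev(x$sim_hi)),
                      border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.4))
    graphics::lines(xv, x$sim_med, lty = 2)
    graphics::lines(xv, x$obs_prop, lwd = 2)
  }
  invisible(x)
}

#' @export
plot.grouped_bar <- function(x, ...) {
  h <- t(as.matrix(x[, c("predicted", "observed")]))
  h[is.na(h)] <- 0
  mids <- (x$x_lo + x$x_hi) / 2
  graphics::barplot(h, beside = TRUE, names.arg = signif(mids, 2),
                    col = c("darkgreen", "grey60"),
                    xlab = attr(x, "variable"),
                    ylab = "rejection proportion",
                    legend.text = c("predicted", "observed"), ...)
  invisible(x)
}

#' @export
plot.npde_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  stats::qqnorm(x$npde, main = "npde Q-Q", ...)
  stats::qqline(x$npde)
  graphics::hist(x$npde, freq = FALSE, main = "npde", xlab = "npde", ...)
  graphics::curve(stats::dnorm(x), add = TRUE, col = "steelblue", lwd = 2)
  invisible(x)
}
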