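#' Subject course container
#'
#' One subject's body weight, covariates, dose events and concentration
#' observations. This is the unit of data consumed by the estimation
#' machinery; [read_event_table()] and [as_subject_courses()] build
#' lists of these from event-record tables.
#'
#' @param id Subject identifier.
#' @param weight Body weight (kg), constant within subject.
#' @param doses data.frame with columns `time` (h) and `amt`.
#' @param obs data.frame with columns `time` (h), `dv` (observed
#'   concentration, > 0) and optionally `occ` (occasion label).
#' @param covariates Named list of subject-level covariates.
#' @return An object of class `subject_course`.
#' @export
subject_course <- function(id, weight, doses, obs, covariates = list()) {
  doses <- normalize_doses(doses)
  if (!is.data.frame(obs)) stop("obs must be a data.frame")
  if (is.null(obs$occ)) obs$occ <- NA_character_
  obs <- obs[order(obs$time), c("time", "dv", "occ"), drop = FALSE]
  if (nrow(obs) && any(!is.finite(obs$dv) | obs$dv <= 0))
    stop("subject ", id, ": observed concentrations must be positive")
  if (!is.finite(weight) || weight <= 0)
    stop("subject ", id, ": weight must be positive")
  structure(list(id = id, weight = weight, doses = doses, obs = obs,
                 covariates = covariates),
            class = "subject_course")
}

#' @export
print.subject_course <- function(x, ...) {
  cat(sprintf("Subject %s: weight %.1f kg, %d doses, %d observations\n",
              x$id, x$weight, nrow(x$doses), nrow(x$obs)))
  invisible(x)
}

event_cols <- c(ID = "ID", TIME = "TIME", AMT = "AMT", DV = "DV",
                EVID = "EVID", MDV = "MDV", OCC = "OCC", WT = "WT")

#' Convert an event-record table to subject courses
#'
#' Accepts a data.frame in the pharmacometric event-record convention
#' (columns ID, TIME, AMT, DV, EVID, MDV, OCC, WT; EVID 1 marks dose
#' rows, EVID 0 observation rows, MDV 1 missing observations) and
#' returns a validated list of [subject_course()] objects. Unknown
#' columns are carried along as subject-level covariates (first value
#' per subject).
#'
#' @param data A data.frame of event records, or already a list of
#'   `subject_course` objects (returned unchanged after validation).
#' @param column_map Optional named character vector mapping the
#'   standard names (ID, TIME, AMT, DV, EVID, MDV, OCC, WT) to the
#'   columns actually present.
#' @return A list of `subject_course` objects.
#' @export
as_subject_courses <- function(data, column_map = NULL) {
  if (is.list(data) && !is.data.frame(data) &&
      all(vapply(data, inherits, logical(1), "subject_course")))
    return(data)
  if (inherits(data, "subject_course")) return(list(data))
  if (!is.data.frame(data)) stop("data must be a data.frame or course list")
  map <- event_cols
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  for (need in c("ID", "TIME")) {
    if (!map[[need]] %in% names(data))
      stop("mandatory column missing: ", map[[need]])
  }
  get <- function(key, default = NULL) {
    if (map[[key]] %in% names(data)) data[[map[[key]]]] else default
  }
  n <- nrow(data)
  id <- get("ID"); time <- as.numeric(get("TIME"))
  amt <- suppressWarnings(as.numeric(get("AMT", rep(NA_real_, n))))
  dv <- suppressWarnings(as.numeric(get("DV", rep(NA_real_, n))))
  evid <- get("EVID", ifelse(!is.na(amt) & amt > 0, 1L, 0L))
  mdv <- get("MDV", ifelse(is.na(dv), 1L, 0L))
  occ <- get("OCC", rep(NA_character_, n))
  wt <- suppressWarnings(as.numeric(get("WT", rep(70, n))))
  known <- unname(map[map %in% names(data)])
  covcols <- setdiff(names(data), known)
  out <- list()
  for (s in unique(id)) {
    i <- which(id == s)
    if (is.unsorted(time[i]))
      stop("times not sorted for subject ", s)
    if (length(unique(wt[i][!is.na(wt[i])])) > 1)
      stop("weight not constant within subject ", s)
    isdose <- evid[i] == 1
    isobs <- evid[i] == 0 & mdv[i] == 0
    covs <- lapply(covcols, function(cc) data[[cc]][i[1]])
    names(covs) <- covcols
    out[[length(out) + 1L]] <- subject_course(
      id = s, weight = wt[i][!is.na(wt[i])][1],
      doses = data.frame(time = time[i][isdose], amt = amt[i][isdose]),
      obs = data.frame(time = time[i][isobs], dv = dv[i][isobs],
                       occ = as.character(occ[i][isobs])),
      covariates = covs)
  }
  out
}

#' Flatten subject courses into an event-record table
#'
#' Inverse of [as_subject_courses()]: one dose row (EVID 1) per dose
#' event and one observation row (EVID 0, MDV 0) per concentration.
#'
#' @param courses List of [subject_course()] objects.
#' @return A data.frame with columns ID, TIME, AMT, DV, EVID, MDV, OCC,
#'   WT plus any covariate columns.
#' @export
event_table <- function(courses) {
  courses <- as_subject_courses(courses)
  rows <- lapply(courses, function(s) {
    nd <- nrow(s$doses); no <- nrow(s$obs)
    df <- data.frame(
      ID = rep(s$id, nd + no),
      TIME = c(s$doses$time, s$obs$time),
      AMT = c(s$doses$amt, rep(NA_real_, no)),
      DV = c(rep(NA_real_, nd), s$obs$dv),
      EVID = c(rep(1L, nd), rep(0L, no)),
      MDV = c(rep(1L, nd), rep(0L, no)),
      OCC = c(rep(NA_character_, nd), as.character(s$obs$occ)),
      WT = rep(s$weight, nd + no))
    for (cc in names(s$covariates)) df[[cc]] <- s$covariates[[cc]]
    df[order(df$TIME, -df$EVID), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pharmacometric event-record CSV
#'
#' Comma-separated, period decimal, header row; missing values coded
#' as `"."` (the event-record convention) or empty cells.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_subject_courses
#' @return A list of [subject_course()] objects. A zero-row file gives
#'   an empty list with a warning.
#' @export
read_event_table <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, na.strings = c(".", "", "NA"),
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no event records in ", path)
    return(list())
  }
  as_subject_courses(df, column_map)
}

#' Write a pharmacometric event-record CSV
#'
#' @param x A list of [subject_course()] objects or an event-record
#'   data.frame (as from [event_table()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_event_table <- function(x, path) {
  df <- if (is.data.frame(x)) x else event_table(x)
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the visit-level logistic dataset
#'
#' The logistic table has one row per subject-visit with columns
#' `subject`, `visit`, the candidate explanatory variables (`miR155`,
#' `CXCL10`, `auc_tac`, `auc_mpa`, `trough_tac`, `trough_mpa`) and the
#' binary `outcome`.
#'
#' @param path CSV path.
#' @return `read_logistic_table()`: a data.frame of visit records.
#' @export
read_logistic_table <- function(path) {
  df <- utils::read.csv(path, na.strings = c(".", "", "NA"),
                        stringsAsFactors = FALSE)
  if (!all(c("subject", "visit", "outcome") %in% names(df)))
    stop("logistic table needs subject, visit and outcome columns")
  if (nrow(df) && !all(df$outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  df
}

#' @rdname read_logistic_table
#' @param records Visit-record data.frame to write.
#' @export
write_logistic_table <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "."
    out[[j]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
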