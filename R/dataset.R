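#' Assay configuration
#'
#' Lower and upper reporting limits of the drug assay. Concentrations below
#' the lower limit of quantification (LOQ) are imputed to LOQ/2 during
#' dataset assembly.
#'
#' @param loq Lower limit of quantification (mg/L).
#' @param upper_limit Upper end of the reporting range (mg/L).
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(loq = 0.2, upper_limit = 8) {
  stopifnot(is.numeric(loq), loq > 0, upper_limit > loq)
  structure(list(loq = loq, upper_limit = upper_limit), class = "assay_config")
}

.covariate_names <- c("liver_abnormal", "ppi_h2ra", "clarithromycin",
                      "rifampicin", "rifabutin", "orkambi")

#' Dose event
#'
#' One administration. A steady-state marker (`ss = TRUE`) states that the
#' dose has been repeated every `ii` hours long enough to reach steady state;
#' the prediction engine then expands the history analytically.
#'
#' @param time Hours since the subject's reference origin (first dose = 0).
#' @param amount Dose amount (mg).
#' @param ss Steady-state marker.
#' @param ii Dosing interval (h); required when `ss = TRUE`.
#' @return A one-row data.frame with columns `time`, `amount`, `ss`, `ii`.
#' @export
dose_event <- function(time, amount, ss = FALSE, ii = NA_real_) {
  stopifnot(is.finite(time), amount > 0)
  if (isTRUE(ss) && (!is.finite(ii) || ii <= 0)) {
    stop("a steady-state dose event requires a positive interval 'ii'",
         call. = FALSE)
  }
  data.frame(time = time, amount = amount, ss = as.integer(isTRUE(ss)),
             ii = ii)
}

#' Observation (TDM sample)
#'
#' @param time Hours since the subject's reference origin.
#' @param concentration Reported concentration (mg/L, non-negative).
#' @param blq Below-limit-of-quantification flag.
#' @param excluded Exclusion flag (set by [apply_exclusions()]).
#' @param reason Exclusion reason, or an annotation flag such as
#'   `"timing_unknown"` recognised by [apply_exclusions()].
#' @return A one-row data.frame.
#' @export
observation <- function(time, concentration, blq = FALSE, excluded = FALSE,
                        reason = NA_character_) {
  stopifnot(is.finite(time), is.numeric(concentration), concentration >= 0)
  data.frame(time = time, concentration = concentration, blq = isTRUE(blq),
             excluded = isTRUE(excluded), reason = reason)
}

#' Subject record
#'
#' Dosing history, observations, body weight and covariate flags for one
#' child. Times are hours since the subject's first recorded dose; weight is
#' the value at sampling and treated as constant.
#'
#' @param id Subject identifier.
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param sex `"M"` or `"F"`.
#' @param setting `"inpatient"` or `"outpatient"`.
#' @param covariates Named logical vector with exactly the six flags
#'   `liver_abnormal`, `ppi_h2ra`, `clarithromycin`, `rifampicin`,
#'   `rifabutin`, `orkambi`.
#' @param doses data.frame of dose events (see [dose_event()]).
#' @param observations data.frame of observations (see [observation()]).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(id, age, weight, sex = "F",
                           setting = c("outpatient", "inpatient"),
                           covariates = stats::setNames(rep(FALSE, 6),
                                                        .covariate_names),
                           doses, observations) {
  setting <- match.arg(setting)
  stopifnot(weight > 0)
  if (!is.na(age)) stopifnot(age > 0)
  covariates <- as.logical(covariates[.covariate_names])
  if (anyNA(covariates)) {
    stop("covariates must contain exactly the six named flags", call. = FALSE)
  }
  names(covariates) <- .covariate_names
  if (nrow(doses) > 0 && nrow(observations) > 0 &&
      any(observations$time < min(doses$time))) {
    stop(sprintf("subject %s: observation precedes the first dose", id),
         call. = FALSE)
  }
  structure(list(id = as.character(id), age = age, weight = weight,
                 sex = sex, setting = setting, covariates = covariates,
                 doses = doses, observations = observations),
            class = "subject_record")
}

#' Study dataset
#'
#' @param subjects List of [subject_record()] objects with unique ids.
#' @param assay An [assay_config()].
#' @param provenance_log Character vector of assembly/cleaning notes.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(subjects, assay = assay_config(),
                          provenance_log = character()) {
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  structure(list(subjects = subjects, assay = assay,
                 provenance_log = provenance_log),
            class = "study_dataset")
}

#' Number of non-excluded observations in a dataset
#' @param ds A [study_dataset()].
#' @return Integer count.
#' @export
n_observations <- function(ds) {
  sum(vapply(ds$subjects, function(s) sum(!s$observations$excluded),
             integer(1)))
}

#' Impute below-LOQ observations to LOQ/2
#'
#' Observations reported below the assay's lower limit of quantification are
#' recorded at half that limit, the convention used for dataset assembly.
#'
#' @param obs A one-row observation data.frame (see [observation()]).
#' @param assay An [assay_config()].
#' @return The observation, imputed if below the LOQ.
#' @export
impute_blq <- function(obs, assay) {
  if (any(obs$concentration < 0)) {
    stop("negative concentration", call. = FALSE)
  }
  below <- obs$concentration < assay$loq | obs$blq
  obs$concentration[below] <- assay$loq / 2
  obs$blq[below] <- TRUE
  obs
}

#' Expand an outpatient record to the 8 am steady-state dosing convention
#'
#' For outpatients whose last dose time was not recorded, the last dose is
#' presumed to have been taken at a fixed clock time (8 am) on the day of the
#' sample, with the maintenance regimen at steady state. The dose history is
#' replaced either by a single dose event carrying the steady-state marker
#' (default) or by `n_prior_days` of explicit repeated doses; both yield the
#' same steady-state predictions.
#'
#' @param subject A [subject_record()] with `setting = "outpatient"`.
#' @param maintenance_dose Maintenance dose (mg).
#' @param interval Maintenance dosing interval (h).
#' @param time_after_dose Hours between the presumed 8 am dose and each
#'   sample; defaults to the recorded observation times (origin = last dose).
#' @param n_prior_days If given, emit an explicit history of that many days
#'   of doses instead of the steady-state marker.
#' @return The subject with a rebuilt dose history; inpatient subjects are
#'   returned unchanged.
#' @export
expand_outpatient_dosing <- function(subject, maintenance_dose, interval = 24,
                                     time_after_dose = NULL,
                                     n_prior_days = NULL) {
  if (subject$setting != "outpatient") return(subject)
  if (missing(maintenance_dose) || !is.finite(maintenance_dose) ||
      maintenance_dose <= 0) {
    stop(sprintf("subject %s: unknown maintenance dose; flag for exclusion",
                 subject$id), call. = FALSE)
  }
  tad <- if (is.null(time_after_dose)) subject$observations$time else
    time_after_dose
  if (is.null(n_prior_days)) {
    subject$doses <- dose_event(0, maintenance_dose, ss = TRUE, ii = interval)
    subject$observations$time <- tad
  } else {
    n_doses <- ceiling(n_prior_days * 24 / interval)
    subject$doses <- do.call(rbind, lapply(seq_len(n_doses), function(i) {
      dose_event((i - 1) * interval, maintenance_dose)
    }))
    last <- (n_doses - 1) * interval
    subject$observations$time <- last + tad
  }
  subject
}

#' Apply the study exclusion rules
#'
#' Observations annotated with `timing_unknown`, `dose_history_incomplete`
#' or `known_nonadherent` are marked excluded with that reason; subjects left
#' with no usable observations are dropped. Idempotent; counts are appended
#' to the provenance log.
#'
#' @param ds A [study_dataset()].
#' @return The filtered dataset.
#' @export
apply_exclusions <- function(ds) {
  flags <- c("timing_unknown", "dose_history_incomplete", "known_nonadherent")
  n_before <- n_observations(ds)
  ds$subjects <- lapply(ds$subjects, function(s) {
    hit <- !is.na(s$observations$reason) & s$observations$reason %in% flags
    s$observations$excluded[hit] <- TRUE
    s
  })
  keep <- vapply(ds$subjects, function(s) any(!s$observations$excluded),
                 logical(1))
  dropped <- vapply(ds$subjects[!keep], `[[`, character(1), "id")
  ds$subjects <- ds$subjects[keep]
  n_after <- n_observations(ds)
  if (n_after != n_before || length(dropped)) {
    ds$provenance_log <- c(ds$provenance_log, sprintf(
      "exclusions: %d of %d observations excluded; %d subject(s) dropped%s",
      n_before - n_after, n_before, length(dropped),
      if (length(dropped)) paste0(" (", paste(dropped, collapse = ", "), ")")
      else ""))
  }
  ds
}

.nm_columns <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "SS", "II",
                 "WT", "AGE", "SEX", "SETTING", "BLQ", "EXFL",
                 "LIVER", "PPI", "CLARI", "RIF", "RFB", "ORK")

.default_column_map <- stats::setNames(as.list(.nm_columns), .nm_columns)

#' Read a sparse TDM PK dataset from NMTRAN-style CSV
#'
#' One row per dose or observation event. Mandatory columns: `ID`, `TIME`
#' (h), `AMT` (mg), `DV` (mg/L), `EVID` (1 = dose, 0 = observation), `MDV`,
#' `WT` (kg); optional: `SS`, `II`, `AGE`, `SEX`, `SETTING`, `BLQ`, `EXFL`
#' (exclusion-annotation text) and the 0/1 covariate columns `LIVER`, `PPI`,
#' `CLARI`, `RIF`, `RFB`, `ORK`. Missing numeric cells are written as `"."`.
#' Weight and covariates are taken as constant per subject (first value wins;
#' discrepancies are logged).
#'
#' @param path CSV file path.
#' @param column_map Optional named list mapping the canonical column names
#'   above to the names used in the file.
#' @param assay An [assay_config()] recorded with the dataset.
#' @return A [study_dataset()].
#' @export
read_pk_dataset <- function(path, column_map = NULL, assay = assay_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c(".", "NA", ""))
  cmap <- .default_column_map
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  get_col <- function(nm, required = FALSE) {
    col <- cmap[[nm]]
    if (!col %in% names(raw)) {
      if (required) stop(sprintf("missing mandatory column '%s'", col),
                         call. = FALSE)
      return(NULL)
    }
    raw[[col]]
  }
  for (nm in c("ID", "TIME", "AMT", "DV", "EVID", "WT")) get_col(nm, TRUE)

  id <- as.character(get_col("ID"))
  time <- as.numeric(get_col("TIME"))
  amt <- as.numeric(get_col("AMT"))
  dv <- as.numeric(get_col("DV"))
  evid <- as.integer(get_col("EVID"))
  ss <- get_col("SS"); if (is.null(ss)) ss <- rep(0L, nrow(raw))
  ss[is.na(ss)] <- 0L
  ii <- get_col("II"); if (is.null(ii)) ii <- rep(NA_real_, nrow(raw))
  wt <- as.numeric(get_col("WT"))
  age <- get_col("AGE"); if (is.null(age)) age <- rep(NA_real_, nrow(raw))
  sex <- get_col("SEX"); if (is.null(sex)) sex <- rep("F", nrow(raw))
  setting <- get_col("SETTING")
  if (is.null(setting)) setting <- rep("inpatient", nrow(raw))
  blq <- get_col("BLQ"); if (is.null(blq)) blq <- rep(0L, nrow(raw))
  blq[is.na(blq)] <- 0L
  exfl <- get_col("EXFL"); if (is.null(exfl)) exfl <- rep(NA_character_,
                                                          nrow(raw))
  covs <- list(LIVER = "liver_abnormal", PPI = "ppi_h2ra",
               CLARI = "clarithromycin", RIF = "rifampicin",
               RFB = "rifabutin", ORK = "orkambi")
  cov_cols <- lapply(names(covs), function(nm) {
    v <- get_col(nm)
    if (is.null(v)) rep(0L, nrow(raw)) else { v[is.na(v)] <- 0L; v }
  })
  names(cov_cols) <- unlist(covs)

  log <- character()
  subjects <- lapply(unique(id), function(sid) {
    rows <- which(id == sid)
    tt <- time[rows]
    if (is.unsorted(tt)) {
      stop(sprintf("non-monotone event times for subject %s", sid),
           call. = FALSE)
    }
    first_val <- function(v) v[rows][1]
    wts <- unique(wt[rows][!is.na(wt[rows])])
    if (length(wts) > 1) {
      log <<- c(log, sprintf("subject %s: discordant WT values; first used",
                             sid))
    }
    is_dose <- evid[rows] == 1L
    doses <- data.frame(time = tt[is_dose], amount = amt[rows][is_dose],
                        ss = as.integer(ss[rows][is_dose]),
                        ii = as.numeric(ii[rows][is_dose]))
    obs <- data.frame(time = tt[!is_dose],
                      concentration = dv[rows][!is_dose],
                      blq = as.logical(blq[rows][!is_dose]),
                      excluded = FALSE,
                      reason = as.character(exfl[rows][!is_dose]))
    covariates <- vapply(cov_cols, function(v) first_val(v) > 0, logical(1))
    subject_record(id = sid, age = first_val(age), weight = wts[1],
                   sex = first_val(sex),
                   setting = if (first_val(setting) %in%
                                 c("outpatient", "inpatient"))
                     first_val(setting) else "inpatient",
                   covariates = covariates, doses = doses, observations = obs)
  })
  study_dataset(subjects, assay = assay, provenance_log = log)
}

#' Write a study dataset to NMTRAN-style CSV
#'
#' Inverse of [read_pk_dataset()]: one row per dose or observation event,
#' missing numeric cells written as `"."`.
#'
#' @param ds A [study_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  rows <- lapply(ds$subjects, function(s) {
    nd <- nrow(s$doses); no <- nrow(s$observations)
    ev <- data.frame(
      ID = s$id,
      TIME = c(s$doses$time, s$observations$time),
      AMT = c(s$doses$amount, rep(NA_real_, no)),
      DV = c(rep(NA_real_, nd), s$observations$concentration),
      EVID = c(rep(1L, nd), rep(0L, no)),
      MDV = c(rep(1L, nd), rep(0L, no)),
      SS = c(s$doses$ss, rep(0L, no)),
      II = c(s$doses$ii, rep(NA_real_, no)),
      WT = s$weight, AGE = s$age, SEX = s$sex, SETTING = s$setting,
      BLQ = c(rep(0L, nd), as.integer(s$observations$blq)),
      EXFL = c(rep(NA_character_, nd), s$observations$reason),
      LIVER = as.integer(s$covariates[["liver_abnormal"]]),
      PPI = as.integer(s$covariates[["ppi_h2ra"]]),
      CLARI = as.integer(s$covariates[["clarithromycin"]]),
      RIF = as.integer(s$covariates[["rifampicin"]]),
      RFB = as.integer(s$covariates[["rifabutin"]]),
      ORK = as.integer(s$covariates[["orkambi"]]))
    ev[order(ev$TIME, -ev$EVID), ]
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), ".",
                                                  format(v, digits = 10)))
  out[!num] <- lapply(out[!num], function(v) ifelse(is.na(v), ".", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Sparse TDM PK dataset: %d subjects, %d usable observations (LOQ %.3g mg/L)\n",
              length(x$subjects), n_observations(x), x$assay$loq))
  invisible(x)
}

#' Summarise a study dataset (study-design style table)
#'
#' @param object A [study_dataset()].
#' @param ... Unused.
#' @return A named list of summary statistics, printed in a demographics
#'   table layout.
#' @export
summary.study_dataset <- function(object, ...) {
  subj <- object$subjects
  ages <- vapply(subj, `[[`, numeric(1), "age")
  wts <- vapply(subj, `[[`, numeric(1), "weight")
  nobs <- vapply(subj, function(s) sum(!s$observations$excluded), integer(1))
  conc <- unlist(lapply(subj, function(s)
    s$observations$concentration[!s$observations$excluded]))
  cov_mat <- t(vapply(subj, `[[`, logical(6), "covariates"))
  res <- list(
    n_subjects = length(subj),
    n_samples = sum(nobs),
    samples_per_subject = stats::median(nobs),
    samples_range = range(nobs),
    age_median = stats::median(ages), age_range = range(ages),
    weight_median = stats::median(wts), weight_range = range(wts),
    concentration_median = stats::median(conc),
    concentration_range = range(conc),
    covariate_prevalence = colMeans(cov_mat))
  class(res) <- "summary.study_dataset"
  res
}

#' @export
print.summary.study_dataset <- function(x, ...) {
  cat(sprintf("Subjects: %d   TDM samples: %d\n", x$n_subjects, x$n_samples))
  cat(sprintf("Samples/subject, median (range): %g (%d-%d)\n",
              x$samples_per_subject, x$samples_range[1], x$samples_range[2]))
  cat(sprintf("Age, years, median (range): %.1f (%.1f-%.1f)\n",
              x$age_median, x$age_range[1], x$age_range[2]))
  cat(sprintf("Weight, kg, median (range): %.1f (%.1f-%.1f)\n",
              x$weight_median, x$weight_range[1], x$weight_range[2]))
  cat(sprintf("Concentration, mg/L, median (range): %.2f (%.2f-%.2f)\n",
              x$concentration_median, x$concentration_range[1],
              x$concentration_range[2]))
  cat("Covariate prevalence:\n")
  for (nm in names(x$covariate_prevalence)) {
    cat(sprintf("  %-15s %.0f%%\n", nm, 100 * x$covariate_prevalence[[nm]]))
  }
  invisible(x)
}
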