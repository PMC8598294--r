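#' Default virtual-study design
#'
#' Study design matched to the sparse TDM study: 37 subjects contributing
#' about 100 samples (1-9 per subject, median 2), ages 7-17 y with the
#' younger (6-11 y) band holding 14/37 subjects, once-daily doses of
#' 100-600 mg assigned by age band, sample times 1-31 h post dose (drawn
#' log-uniformly: TDM sampling skews early), 47% of samples from outpatients
#' handled with the 8 am steady-state convention, assay LOQ 0.2 mg/L, and
#' the published covariate prevalences.
#'
#' @param seed Default seed carried by the design (individual generator
#'   calls can override it).
#' @return An object of class `study_design_spec`.
#' @export
default_design <- function(seed = 1L) {
  structure(list(
    n_subjects = 37L,
    # distribution of samples/subject over 1..9: median 2, mean ~2.7, so the
    # expected study total is ~100 samples
    samples_per_subject = c(0.30, 0.28, 0.15, 0.10, 0.07, 0.04,
                            0.03, 0.02, 0.01),
    young_fraction = 14 / 37,
    young_band = c(7, 12),
    old_band = c(12, 17),
    male_fraction = 13 / 37,
    age_weight = fit_age_weight(summaries = study_demographics()),
    # once-daily dose policy (mg) by band; medians 300, ranges as published
    dose_levels_young = c(100, 200, 300),
    dose_probs_young = c(0.08, 0.17, 0.75),
    dose_levels_old = c(200, 300, 400, 600),
    dose_probs_old = c(0.20, 0.55, 0.15, 0.10),
    dose_interval = 24,
    outpatient_fraction = 0.47,
    sample_time_window = c(1, 31),
    inpatient_history_hours = 48,
    covariate_prevalence = c(liver_abnormal = 0.60, ppi_h2ra = 0.76,
                             clarithromycin = 0.02, rifampicin = 0.02,
                             rifabutin = 0.11, orkambi = 0.03),
    assay = assay_config(loq = 0.2, upper_limit = 8),
    seed = seed), class = "study_design_spec")
}

#' Generate a synthetic sparse TDM study
#'
#' Forward-simulates the study design from the population model: draws
#' demographics from the age/log-weight model, assigns doses by age band,
#' draws a clearance random effect per subject, simulates concentrations at
#' log-uniform sampling times with combined additive + proportional residual
#' error (`y = f*(1 + eps_p) + eps_a`), imputes below-LOQ values to LOQ/2,
#' and emits outpatient records with the steady-state dosing marker and
#' inpatient records with an explicit 48 h dose history. The generating
#' truth (random effects, individual parameters, noise draws) is returned
#' alongside the dataset for parameter-recovery testing.
#'
#' @param pop A [pop_params()] object (simulation truth).
#' @param var A [var_params()] object (simulation truth).
#' @param design A `study_design_spec` from [default_design()].
#' @param seed Integer seed; same seed gives an identical dataset.
#' @param covariate_effects Optional list of [covariate_effect()] objects
#'   applied to clearance in the simulation truth.
#' @param rule An [allometric_rule()].
#' @return List with elements `dataset` (a [study_dataset()]) and `truth`
#'   (per-subject eta, individual parameters, doses, covariate coefficients
#'   and resample counts).
#' @export
generate_study <- function(pop, var, design = default_design(),
                           seed = design$seed, covariate_effects = list(),
                           rule = allometric_rule()) {
  betas <- .make_betas(covariate_effects)
  prev <- design$covariate_prevalence[.covariate_names]
  .with_seed(seed, {
    subjects <- vector("list", design$n_subjects)
    truth <- vector("list", design$n_subjects)
    n_resampled <- 0L
    for (i in seq_len(design$n_subjects)) {
      young <- stats::runif(1) < design$young_fraction
      band <- if (young) design$young_band else design$old_band
      aw <- .sample_age_weight(design$age_weight, band, 1)
      covs <- stats::setNames(stats::runif(6) < prev, .covariate_names)
      dose <- if (young) {
        sample(design$dose_levels_young, 1, prob = design$dose_probs_young)
      } else {
        sample(design$dose_levels_old, 1, prob = design$dose_probs_old)
      }
      n_obs <- sample(seq_along(design$samples_per_subject), 1,
                      prob = design$samples_per_subject)
      outpatient <- stats::runif(1) < design$outpatient_fraction
      w <- design$sample_time_window
      tad <- sort(exp(stats::runif(n_obs, log(w[1]), log(w[2]))))
      if (outpatient) {
        doses <- dose_event(0, dose, ss = TRUE, ii = design$dose_interval)
        obs_t <- tad
      } else {
        n_d <- floor(design$inpatient_history_hours /
                       design$dose_interval) + 1
        doses <- do.call(rbind, lapply(seq_len(n_d), function(j) {
          dose_event((j - 1) * design$dose_interval, dose)
        }))
        obs_t <- max(doses$time) + tad
      }
      id <- sprintf("S%02d", i)
      cs <- list(y = numeric(n_obs), times = obs_t, doses = doses,
                 cov = as.numeric(covs))
      eta <- stats::rnorm(1, 0, sqrt(var$omega2_cl))
      frac <- aw$weight / rule$reference_weight
      cl_i <- pop$cl_f * frac^rule$exponent_cl * .cov_multiplier(cs, betas) *
        exp(eta)
      v_i <- pop$v_f * frac^rule$exponent_v
      f <- .conc_dose_table(cl_i, v_i, pop$ka, doses, obs_t)
      eps_p <- stats::rnorm(n_obs, 0, var$sigma_prop)
      eps_a <- stats::rnorm(n_obs, 0, var$sigma_add)
      y <- f * (1 + eps_p) + eps_a
      tries <- 0
      while (any(y < 0) && tries < 1000) {
        bad <- y < 0
        n_resampled <- n_resampled + sum(bad)
        eps_p[bad] <- stats::rnorm(sum(bad), 0, var$sigma_prop)
        eps_a[bad] <- stats::rnorm(sum(bad), 0, var$sigma_add)
        y <- f * (1 + eps_p) + eps_a
        tries <- tries + 1
      }
      obs <- data.frame(time = obs_t, concentration = y, blq = FALSE,
                        excluded = FALSE, reason = NA_character_)
      obs <- impute_blq(obs, design$assay)
      subjects[[i]] <- subject_record(
        id = id, age = aw$age, weight = aw$weight,
        sex = if (stats::runif(1) < design$male_fraction) "M" else "F",
        setting = if (outpatient) "outpatient" else "inpatient",
        covariates = covs, doses = doses, observations = obs)
      truth[[i]] <- list(id = id, eta_cl = eta, cl = cl_i, v = v_i,
                         ka = pop$ka, f = f, eps_p = eps_p, eps_a = eps_a,
                         dose = dose)
    }
    log <- sprintf("generated %d subjects, %d observations (seed %d)%s",
                   design$n_subjects,
                   sum(vapply(subjects, function(s) nrow(s$observations),
                              integer(1))), seed,
                   if (n_resampled > 0)
                     sprintf("; %d negative noise draws resampled",
                             n_resampled) else "")
    ds <- study_dataset(subjects, assay = design$assay,
                        provenance_log = log)
    names(truth) <- vapply(truth, `[[`, character(1), "id")
    list(dataset = ds,
         truth = list(pop = pop, var = var,
                      covariate_effects = covariate_effects,
                      subjects = truth, n_resampled = n_resampled))
  })
}

#' Generate a study with a known covariate effect on clearance
#'
#' Convenience wrapper around [generate_study()] for power testing of the
#' stepwise covariate search: the generating clearance is additionally
#' multiplied by `exp(theta_cov * x)`.
#'
#' @param pop,var,design,seed As in [generate_study()].
#' @param effect A [covariate_effect()] with the generating coefficient.
#' @param prevalence Optional override of the design prevalence for the
#'   effect's covariate.
#' @return As [generate_study()].
#' @export
generate_with_covariate <- function(pop, var, effect,
                                    design = default_design(),
                                    seed = design$seed, prevalence = NULL) {
  if (!is.null(prevalence)) {
    design$covariate_prevalence[[effect$covariate]] <- prevalence
  }
  if (design$covariate_prevalence[[effect$covariate]] <= 0) {
    stop(sprintf("covariate '%s' has zero prevalence in the design",
                 effect$covariate), call. = FALSE)
  }
  generate_study(pop, var, design, seed, covariate_effects = list(effect))
}
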