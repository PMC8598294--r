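#' Allometric weight-scaling rule
#'
#' Fixed allometric scaling of clearance and volume terms to a reference
#' body weight: `p_i = theta_p * (w_i / w_ref)^exponent`, with exponent 0.75
#' for clearance and 1 for central volume by default, and a 70 kg reference.
#'
#' @param reference_weight Reference body weight in kg.
#' @param exponent_cl Allometric exponent applied to clearance.
#' @param exponent_v Allometric exponent applied to central volume.
#' @return An object of class `allometric_rule`.
#' @export
allometric_rule <- function(reference_weight = 70,
                            exponent_cl = 0.75,
                            exponent_v = 1) {
  stopifnot(is.numeric(reference_weight), reference_weight > 0)
  structure(list(reference_weight = reference_weight,
                 exponent_cl = exponent_cl,
                 exponent_v = exponent_v),
            class = "allometric_rule")
}

#' Population (typical) pharmacokinetic parameters
#'
#' Apparent oral clearance and volume (CL/F, V/F) standardised to the
#' allometric reference weight, and the first-order absorption rate constant.
#' Bioavailability F is not carried as a separate symbol: with oral data only,
#' clearance and volume are apparent quantities.
#'
#' @param cl_f Apparent clearance (L/h) at the reference weight.
#' @param v_f Apparent central volume (L) at the reference weight.
#' @param ka First-order absorption rate constant (1/h).
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(cl_f, v_f, ka) {
  stopifnot(is.numeric(cl_f), cl_f > 0,
            is.numeric(v_f), v_f > 0,
            is.numeric(ka), ka > 0)
  structure(list(cl_f = cl_f, v_f = v_f, ka = ka), class = "pop_params")
}

#' Individual pharmacokinetic parameters
#'
#' @param cl Individual apparent clearance (L/h).
#' @param v Individual apparent volume (L).
#' @param ka Absorption rate constant (1/h).
#' @return An object of class `ind_params`.
#' @export
ind_params <- function(cl, v, ka) {
  stopifnot(cl > 0, v > 0, ka > 0)
  structure(list(cl = cl, v = v, ka = ka), class = "ind_params")
}

#' Scale population parameters to an individual body weight
#'
#' Applies the fixed allometric rule to clearance and volume; the absorption
#' rate constant is not weight-scaled. Returns the typical individual
#' parameters (random effect eta = 0).
#'
#' @param pop A [pop_params()] object.
#' @param weight Individual body weight in kg (must be positive).
#' @param rule An [allometric_rule()]; defaults to 0.75/1 exponents at 70 kg.
#' @return An [ind_params()] object.
#' @export
#' @examples
#' scale_parameters(pop_params(8.43, 186, 0.16), weight = 31.5)
scale_parameters <- function(pop, weight, rule = allometric_rule()) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("'weight' must be a single positive number", call. = FALSE)
  }
  frac <- weight / rule$reference_weight
  ind_params(cl = pop$cl_f * frac^rule$exponent_cl,
             v  = pop$v_f * frac^rule$exponent_v,
             ka = pop$ka)
}

#' Apply inter-individual variability to clearance
#'
#' Multiplies clearance by `exp(eta_cl)`, the log-normal random-effect model
#' used for between-subject variability in clearance. Volume and absorption
#' are unchanged.
#'
#' @param typical An [ind_params()] object (typical values for the subject).
#' @param eta_cl Subject-level random effect on log-clearance.
#' @return An [ind_params()] object.
#' @export
apply_iiv <- function(typical, eta_cl) {
  stopifnot(is.finite(eta_cl))
  ind_params(cl = typical$cl * exp(eta_cl), v = typical$v, ka = typical$ka)
}

#' Dosing regimen
#'
#' Either an explicit list of dose events, or a loading/maintenance pattern
#' ("D mg every q h for n doses, then M mg every tau h") that expands to a
#' deterministic event list.
#'
#' @param events Optional data.frame with columns `time` (h) and `amount`
#'   (mg), one row per dose.
#' @param loading_dose,loading_interval,n_loading Loading phase: dose (mg),
#'   interval (h) and number of loading doses.
#' @param maintenance_dose,maintenance_interval Maintenance dose (mg) and
#'   interval (h).
#' @return An object of class `regimen` carrying the event list and, when
#'   built from a pattern, the pattern fields.
#' @export
#' @examples
#' # 300 mg every 12 h for two doses (loading) then 300 mg once daily
#' regimen(loading_dose = 300, loading_interval = 12, n_loading = 2,
#'         maintenance_dose = 300, maintenance_interval = 24)
regimen <- function(events = NULL, loading_dose = NULL, loading_interval = NULL,
                    n_loading = 0, maintenance_dose = NULL,
                    maintenance_interval = NULL) {
  if (is.null(events)) {
    stopifnot(!is.null(maintenance_dose), maintenance_dose > 0,
              !is.null(maintenance_interval), maintenance_interval > 0)
    t0 <- 0
    ev <- NULL
    if (n_loading > 0) {
      stopifnot(!is.null(loading_dose), loading_dose > 0,
                !is.null(loading_interval), loading_interval > 0)
      ev <- data.frame(time = loading_interval * (seq_len(n_loading) - 1),
                       amount = loading_dose)
      t0 <- loading_interval * n_loading
    }
    pattern <- list(loading_dose = loading_dose,
                    loading_interval = loading_interval,
                    n_loading = n_loading,
                    maintenance_dose = maintenance_dose,
                    maintenance_interval = maintenance_interval,
                    maintenance_start = t0)
  } else {
    stopifnot(is.data.frame(events), all(c("time", "amount") %in% names(events)),
              all(events$amount > 0), all(is.finite(events$time)))
    ev <- events[order(events$time), c("time", "amount")]
    pattern <- NULL
  }
  structure(list(events = ev, pattern = pattern), class = "regimen")
}

#' Expand a regimen pattern to an explicit dose-event list
#'
#' @param reg A [regimen()].
#' @param n_maintenance Number of maintenance doses to expand (ignored for
#'   regimens given as explicit events).
#' @return data.frame with columns `time`, `amount`.
#' @export
expand_regimen <- function(reg, n_maintenance = 1) {
  stopifnot(inherits(reg, "regimen"))
  if (is.null(reg$pattern)) return(reg$events)
  p <- reg$pattern
  maint <- data.frame(
    time = p$maintenance_start + p$maintenance_interval *
      (seq_len(n_maintenance) - 1),
    amount = p$maintenance_dose)
  rbind(reg$events, maint)
}

# Single-dose (or steady-state) concentration contribution of one dose,
# vectorised over time-after-dose. `dt` must be >= 0. `ss`/`ii` request the
# analytic steady-state superposition (geometric series over an infinite
# history of doses `ii` hours apart).  The near-degenerate ka ~= k case
# switches to the analytic limit to avoid catastrophic cancellation.
.conc_one_dose <- function(dose, cl, v, ka, dt, ss = FALSE, ii = NA_real_) {
  k <- cl / v
  if (abs(ka - k) <= 1e-6 * k) {
    km <- sqrt(ka * k)  # symmetric handling of the limit point
    if (ss) {
      q <- exp(-km * ii)
      dose * km / v * exp(-km * dt) * (dt / (1 - q) + ii * q / (1 - q)^2)
    } else {
      dose * km * dt * exp(-km * dt) / v
    }
  } else {
    a <- dose * ka / (v * (ka - k))
    if (ss) {
      a * (exp(-k * dt) / (1 - exp(-k * ii)) -
           exp(-ka * dt) / (1 - exp(-ka * ii)))
    } else {
      a * (exp(-k * dt) - exp(-ka * dt))
    }
  }
}

# Concentration from a dose table (columns time, amount, ss, ii; matrix or
# data.frame) at `times`. Internal work-horse shared by the public API and
# the estimation machinery, so it avoids data.frame access in the loop.
.conc_dose_table <- function(cl, v, ka, doses, times) {
  tm <- doses[, "time"]; am <- doses[, "amount"]
  ssv <- doses[, "ss"]; iiv <- doses[, "ii"]
  ct <- numeric(length(times))
  for (i in seq_along(tm)) {
    dt <- times - tm[i]
    pos <- dt >= 0
    if (!any(pos)) next
    ct[pos] <- ct[pos] +
      .conc_one_dose(am[i], cl, v, ka, dt[pos],
                     ss = !is.na(ssv[i]) && ssv[i] > 0, ii = iiv[i])
  }
  ct
}

#' Concentration-time prediction for a one-compartment oral model
#'
#' Closed-form superposition of first-order absorption/elimination dose
#' contributions: each dose adds
#' `D*ka/(V*(ka - k)) * (exp(-k*dt) - exp(-ka*dt))` with `k = CL/V`.
#' Dose events carrying a steady-state marker are expanded analytically
#' (geometric series over the implied infinite dosing history).
#'
#' @param ind An [ind_params()] object.
#' @param reg A [regimen()], or a data.frame of dose events with columns
#'   `time`, `amount` and optionally `ss`, `ii`.
#' @param t Times (h) at which to evaluate the concentration; must not
#'   precede the first dose.
#' @return Numeric vector of concentrations (mg/L).
#' @export
#' @examples
#' ind <- ind_params(cl = 4.63, v = 83.7, ka = 0.16)
#' concentration(ind, regimen(events = data.frame(time = 0, amount = 300)), 24)
concentration <- function(ind, reg, t) {
  doses <- if (inherits(reg, "regimen")) {
    n_m <- if (is.null(reg$pattern)) 1 else
      max(1, ceiling((max(t) - reg$pattern$maintenance_start) /
                       reg$pattern$maintenance_interval) + 1)
    expand_regimen(reg, n_maintenance = n_m)
  } else {
    reg
  }
  if (is.null(doses$ss)) doses$ss <- 0
  if (is.null(doses$ii)) doses$ii <- NA_real_
  if (any(t < min(doses$time))) {
    stop("prediction time precedes the first dose", call. = FALSE)
  }
  .conc_dose_table(ind$cl, ind$v, ind$ka, doses, t)
}

#' Steady-state trough concentration
#'
#' Closed-form trough (concentration at the end of a dosing interval, just
#' before the next dose) for repeated dosing of `dose` mg every `tau` hours:
#' `D*ka/(V*(ka - k)) * (exp(-k*tau)/(1 - exp(-k*tau)) -
#'  exp(-ka*tau)/(1 - exp(-ka*tau)))`.
#'
#' @param ind An [ind_params()] object.
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h).
#' @return Steady-state trough concentration (mg/L).
#' @export
steady_state_trough <- function(ind, dose, tau) {
  stopifnot(dose > 0, tau > 0)
  .conc_one_dose(dose, ind$cl, ind$v, ind$ka, dt = tau, ss = TRUE, ii = tau)
}

#' Steady-state AUC over 24 hours
#'
#' For a linear model at steady state the daily area under the curve equals
#' daily dose divided by clearance, independent of volume and absorption rate.
#'
#' @param ind An [ind_params()] object.
#' @param daily_dose Total daily dose (mg).
#' @return AUC over one 24 h day at steady state (mg.h/L).
#' @export
steady_state_auc24 <- function(ind, daily_dose) {
  stopifnot(daily_dose > 0)
  daily_dose / ind$cl
}

#' @export
print.pop_params <- function(x, ...) {
  cat(sprintf("Population PK parameters (at reference weight):\n  CL/F %.4g L/h, V/F %.4g L, Ka %.4g 1/h\n",
              x$cl_f, x$v_f, x$ka))
  invisible(x)
}

#' @export
print.ind_params <- function(x, ...) {
  cat(sprintf("Individual PK parameters: CL %.4g L/h, V %.4g L, Ka %.4g 1/h (k = %.4g 1/h)\n",
              x$cl, x$v, x$ka, x$cl / x$v))
  invisible(x)
}
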