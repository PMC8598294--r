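# Shared fixtures: published reference parameters, a fast fitting
# configuration for bulk tests, and a small hand-built subject.

ref_model <- posaconazole_reference_model()

fast_settings <- estimation_settings(n_starts = 1L, compute_se = FALSE)

# one outpatient subject on 300 mg once daily at steady state
make_subject <- function(id = "A", weight = 35, conc = c(1.1, 2.4, 2.0),
                         times = c(2, 8, 24), age = 10) {
  obs <- do.call(rbind, lapply(seq_along(times), function(i) {
    observation(times[i], conc[i])
  }))
  subject_record(id = id, age = age, weight = weight,
                 doses = dose_event(0, 300, ss = TRUE, ii = 24),
                 observations = obs)
}

random_ind_params <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ind_params(cl = exp(runif(1, log(2), log(20))),
                 v = exp(runif(1, log(40), log(400))),
                 ka = exp(runif(1, log(0.05), log(2))))
    })
  })
}

# numerical oracle: two-state absorption/central ODE system solved with
# deSolve, for single- or multiple-dose histories given as (time, amount)
ode_concentration <- function(ind, dose_times, dose_amounts, t_out) {
  rhs <- function(t, y, p) {
    list(c(-p$ka * y[1], p$ka * y[1] - (p$cl / p$v) * y[2]))
  }
  events <- data.frame(var = "gut", time = dose_times,
                       value = dose_amounts, method = "add")
  times <- sort(unique(c(0, dose_times, t_out)))
  out <- deSolve::lsoda(c(gut = 0, central = 0), times = times, func = rhs,
                        parms = list(ka = ind$ka, cl = ind$cl, v = ind$v),
                        events = list(data = events),
                        rtol = 1e-10, atol = 1e-12)
  unname(out[match(t_out, out[, "time"]), "central"] / ind$v)
}
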