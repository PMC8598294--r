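#' Random-effect and residual-error variance parameters
#'
#' Inter-individual variability is a log-normal random effect on clearance
#' with variance `omega2_cl`; the residual error combines a proportional and
#' an additive term: `y = f*(1 + eps_p) + eps_a`, giving observation variance
#' `f^2 * sigma_prop^2 + sigma_add^2`.
#'
#' @param omega2_cl Variance of the log-clearance random effect.
#' @param sigma_prop Proportional residual SD (fraction, e.g. 0.36 for 36%).
#' @param sigma_add Additive residual SD (mg/L).
#' @return An object of class `var_params`.
#' @export
var_params <- function(omega2_cl, sigma_prop, sigma_add) {
  stopifnot(omega2_cl >= 0, sigma_prop >= 0, sigma_add >= 0)
  if (sigma_prop == 0 && sigma_add == 0) {
    stop("at least one residual error term must be positive", call. = FALSE)
  }
  structure(list(omega2_cl = omega2_cl, sigma_prop = sigma_prop,
                 sigma_add = sigma_add), class = "var_params")
}

#' Estimation settings
#'
#' @param method `"foce_i"` (first-order conditional estimation with
#'   interaction) or `"agq"` (adaptive Gauss-Hermite quadrature).
#' @param agq_nodes Number of quadrature nodes (odd, >= 5) for `"agq"`.
#' @param convergence_tol Relative convergence tolerance of the outer
#'   optimiser.
#' @param max_iter Maximum outer iterations.
#' @param fixed_parameters Character vector of parameter names to hold at
#'   their initial values (among `cl_f`, `v_f`, `ka`, `omega2_cl`,
#'   `sigma_prop`, `sigma_add`).
#' @param seed Seed for the multi-start jitter.
#' @param n_starts Number of optimiser starts (first from the initial values,
#'   the rest jittered).
#' @param compute_se Compute standard errors from a finite-difference Hessian
#'   of OFV/2 (skipped in bulk refitting such as the bootstrap).
#' @return An object of class `estimation_settings`.
#' @export
estimation_settings <- function(method = c("foce_i", "agq"), agq_nodes = 21,
                                convergence_tol = 1e-8, max_iter = 500,
                                fixed_parameters = character(), seed = 1L,
                                n_starts = 3L, compute_se = TRUE) {
  method <- match.arg(method)
  if (method == "agq") {
    stopifnot(agq_nodes >= 5, agq_nodes %% 2 == 1)
  }
  structure(list(method = method, agq_nodes = agq_nodes,
                 convergence_tol = convergence_tol, max_iter = max_iter,
                 fixed_parameters = fixed_parameters, seed = seed,
                 n_starts = n_starts, compute_se = compute_se),
            class = "estimation_settings")
}

#' Residual variance of one prediction
#'
#' @param f Predicted concentration (mg/L, non-negative).
#' @param var A [var_params()] object.
#' @return Observation variance `f^2 * sigma_prop^2 + sigma_add^2`.
#' @export
residual_variance <- function(f, var) {
  stopifnot(all(f >= 0))
  f^2 * var$sigma_prop^2 + var$sigma_add^2
}

# ---- internal compiled representation --------------------------------------

# Flatten a study_dataset into per-subject structures for fast repeated
# evaluation. Each subject becomes an environment holding the observation
# vector, a flattened (dose x observation)-pair representation of the
# superposition sum (only pairs with non-negative time-after-dose), an
# aggregation matrix mapping pair contributions back to observations, the
# precomputed allometric weight fractions and the covariate indicators.
# The environment also caches the absorption-rate terms exp(-ka*dt), which
# are constant across the inner (random-effect) minimisation.
.compile_dataset <- function(ds, rule = allometric_rule()) {
  lapply(ds$subjects, function(s) {
    keep <- !s$observations$excluded
    doses <- s$doses
    if (is.null(doses$ss)) doses$ss <- 0L
    if (is.null(doses$ii)) doses$ii <- NA_real_
    frac <- s$weight / rule$reference_weight
    dmat <- cbind(time = doses$time, amount = doses$amount,
                  ss = as.numeric(doses$ss), ii = as.numeric(doses$ii))
    times <- unname(s$observations$time[keep])
    n <- length(times)
    nd <- nrow(dmat)
    dt <- rep(times, times = nd) - rep(dmat[, "time"], each = n)
    pair_dose <- rep(seq_len(nd), each = n)
    pair_obs <- rep(seq_len(n), times = nd)
    ok <- dt >= 0
    dtp <- dt[ok]; pd <- pair_dose[ok]; po <- pair_obs[ok]
    M <- matrix(0, n, length(dtp))
    if (length(dtp)) M[cbind(po, seq_along(dtp))] <- 1
    ss <- dmat[pd, "ss"] > 0 & !is.na(dmat[pd, "ss"])
    ce <- new.env(parent = emptyenv())
    ce$id <- s$id
    ce$y <- unname(s$observations$concentration[keep])
    ce$times <- times
    ce$doses <- dmat
    ce$n <- n
    ce$dtp <- unname(dtp)
    ce$amt <- unname(dmat[pd, "amount"])
    ce$ss_idx <- which(ss)
    ce$ii_ss <- unname(dmat[pd, "ii"][ss])
    ce$one_to_one <- nd == 1L && length(dtp) == n
    ce$M <- M
    ce$wf_cl <- frac^rule$exponent_cl
    ce$wf_v <- frac^rule$exponent_v
    ce$cov <- as.numeric(s$covariates)
    ce$ka_cache <- NA_real_
    ce$eka <- NULL
    ce$c2 <- NULL
    ce
  })
}

# Covariate multiplier on clearance per subject: exp(theta * x) per
# exponential-form effect, (1 + theta * x) per proportional-form effect.
.cov_multiplier <- function(cs, betas) {
  if (is.null(betas) || length(betas) == 0) return(1)
  x <- cs$cov[attr(betas, "idx")]
  expo <- attr(betas, "form") == "exponential"
  m <- exp(sum(betas[expo] * x[expo]))
  if (any(!expo)) m <- m * prod(pmax(1 + betas[!expo] * x[!expo], 1e-6))
  m
}

.subject_pred <- function(cs, cl_i, v_i, ka) {
  k <- cl_i / v_i
  if (abs(ka - k) <= 1e-6 * k) {
    # rare degenerate ka ~= k: defer to the guarded slow path
    return(.conc_dose_table(cl_i, v_i, ka, cs$doses, cs$times))
  }
  if (!identical(ka, cs$ka_cache)) {
    cs$eka <- exp(-ka * cs$dtp)
    c2 <- rep(1, length(cs$dtp))
    if (length(cs$ss_idx)) {
      c2[cs$ss_idx] <- 1 / (1 - exp(-ka * cs$ii_ss))
    }
    cs$c2 <- c2
    cs$ka_cache <- ka
  }
  ek <- exp(-k * cs$dtp)
  if (length(cs$ss_idx)) {
    c1 <- rep(1, length(cs$dtp))
    c1[cs$ss_idx] <- 1 / (1 - exp(-k * cs$ii_ss))
    ek <- ek * c1
  }
  contrib <- (cs$amt * ka / (v_i * (ka - k))) * (ek - cs$eka * cs$c2)
  if (cs$one_to_one) contrib else as.numeric(cs$M %*% contrib)
}

# Conditional (empirical Bayes) objective for one subject:
# sum_j [(y_j - f_j)^2 / g_j + ln g_j] + eta^2 / omega2.
.ebe_objective <- function(eta, cs, cl_base, v_i, ka, omega2, sp2, sa2) {
  f <- .subject_pred(cs, cl_base * exp(eta), v_i, ka)
  g <- f * f * sp2 + sa2
  if (sa2 < 1e-12) g[g < 1e-12] <- 1e-12
  val <- sum((cs$y - f)^2 / g + log(g)) + eta^2 / omega2
  if (!is.finite(val)) 1e10 else val
}

# Mode search: warm-started 1-D minimisation with boundary widening.
.find_ebe <- function(cs, cl_base, v_i, ka, omega2, sp2, sa2,
                      eta_start = 0) {
  if (omega2 <= 0) return(0)
  obj <- function(e) .ebe_objective(e, cs, cl_base, v_i, ka, omega2, sp2, sa2)
  lo <- eta_start - 1; hi <- eta_start + 1
  for (round in 1:6) {
    # tol balances mode precision against outer-objective smoothness: the
    # OFV error is O(tol^2) while cost grows ~log(1/tol)
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-7)
    at_edge <- min(opt$minimum - lo, hi - opt$minimum) < 1e-3
    if (!at_edge || (lo <= -8 && hi >= 8)) break
    lo <- max(lo - 2, -8); hi <- min(hi + 2, 8)
  }
  opt$minimum
}

# FOCE-I marginal-likelihood contribution of one subject, linearised around
# the conditional mode: y ~ N(f(eta_hat) - F*eta_hat + F*eta, V) with
# V = F omega2 F' + diag(g(eta_hat)) (interaction: residual variance at the
# mode). Returns -2 log L including the 2*pi constant so that FOCE-I and
# quadrature OFVs are directly comparable.
.foce_contrib <- function(cs, cl_base, v_i, ka, omega2, sp2, sa2,
                          eta_hat) {
  h <- 1e-4
  f0 <- .subject_pred(cs, cl_base * exp(eta_hat), v_i, ka)
  if (omega2 > 0) {
    fp <- .subject_pred(cs, cl_base * exp(eta_hat + h), v_i, ka)
    fm <- .subject_pred(cs, cl_base * exp(eta_hat - h), v_i, ka)
    Fg <- (fp - fm) / (2 * h)
  } else {
    Fg <- numeric(length(f0))
  }
  g <- pmax(f0^2 * sp2 + sa2, 1e-12)
  r <- cs$y - (f0 - Fg * eta_hat)
  den <- 1 + omega2 * sum(Fg^2 / g)
  if (den <= 0 || !is.finite(den)) return(NA_real_)
  quad <- sum(r^2 / g) -
    omega2 * (sum(Fg * r / g))^2 / den
  length(cs$y) * log(2 * pi) + sum(log(g)) + log(den) + quad
}

# Adaptive Gauss-Hermite contribution: -2 log of the 1-D marginal integral
# int p(y | eta) phi(eta; 0, omega2) d eta, centred and scaled at the
# conditional mode.
.agq_contrib <- function(cs, cl_base, v_i, ka, omega2, sp2, sa2,
                         eta_hat, gh) {
  nll <- function(e) {
    f <- .subject_pred(cs, cl_base * exp(e), v_i, ka)
    g <- pmax(f^2 * sp2 + sa2, 1e-12)
    0.5 * sum(log(2 * pi * g) + (cs$y - f)^2 / g) +
      0.5 * log(2 * pi * omega2) + e^2 / (2 * omega2)
  }
  hh <- 1e-3
  H <- (nll(eta_hat + hh) - 2 * nll(eta_hat) + nll(eta_hat - hh)) / hh^2
  if (!is.finite(H) || H <= 0) H <- 1 / omega2
  s_hat <- 1 / sqrt(H)
  etas <- eta_hat + sqrt(2) * s_hat * gh$x
  lt <- log(gh$w) + gh$x^2 - vapply(etas, nll, numeric(1)) +
    0.5 * log(2) + log(s_hat)
  m <- max(lt)
  -2 * (m + log(sum(exp(lt - m))))
}

# Shared OFV driver over a compiled dataset. `betas` is a named numeric
# vector of covariate coefficients with attribute "idx" giving covariate
# positions; `etas_env` optionally carries warm-start modes across calls.
.ofv_compiled <- function(compiled, pop, var, betas = NULL,
                          method = "foce_i", gh = NULL, etas_env = NULL) {
  sp2 <- var$sigma_prop^2; sa2 <- var$sigma_add^2
  omega2 <- var$omega2_cl
  total <- 0
  etas <- if (!is.null(etas_env)) etas_env$etas else
    numeric(length(compiled))
  for (i in seq_along(compiled)) {
    cs <- compiled[[i]]
    cl_base <- pop$cl_f * cs$wf_cl * .cov_multiplier(cs, betas)
    v_i <- pop$v_f * cs$wf_v
    eta_hat <- .find_ebe(cs, cl_base, v_i, pop$ka, omega2, sp2, sa2,
                         eta_start = etas[i])
    etas[i] <- eta_hat
    contrib <- if (method == "foce_i") {
      .foce_contrib(cs, cl_base, v_i, pop$ka, omega2, sp2, sa2, eta_hat)
    } else {
      if (omega2 <= 0) {
        .foce_contrib(cs, cl_base, v_i, pop$ka, 0, sp2, sa2, 0)
      } else {
        .agq_contrib(cs, cl_base, v_i, pop$ka, omega2, sp2, sa2, eta_hat, gh)
      }
    }
    if (!is.finite(contrib)) return(NA_real_)
    total <- total + contrib
  }
  if (!is.null(etas_env)) etas_env$etas <- etas
  total
}

.make_betas <- function(covariate_effects) {
  if (length(covariate_effects) == 0) return(NULL)
  idx <- vapply(covariate_effects, function(e)
    match(e$covariate, .covariate_names), integer(1))
  b <- vapply(covariate_effects, `[[`, numeric(1), "theta_cov")
  names(b) <- vapply(covariate_effects, `[[`, character(1), "covariate")
  attr(b, "idx") <- idx
  attr(b, "form") <- vapply(covariate_effects, function(e)
    if (is.null(e$form)) "exponential" else e$form, character(1))
  b
}

#' Predict a subject's concentrations
#'
#' Composes allometric scaling, the clearance random effect and any covariate
#' effects with the structural model, evaluated at the subject's non-excluded
#' observation times.
#'
#' @param pop A [pop_params()] object.
#' @param var A [var_params()] object (unused for the mean prediction but
#'   accepted for interface symmetry).
#' @param subject A [subject_record()].
#' @param eta_cl Random effect on log-clearance (default 0: typical-value
#'   prediction).
#' @param covariate_effects Optional list of [covariate_effect()] objects.
#' @param rule An [allometric_rule()].
#' @return Numeric vector of predicted concentrations.
#' @export
predict_subject <- function(pop, var, subject, eta_cl = 0,
                            covariate_effects = list(),
                            rule = allometric_rule()) {
  if (sum(!subject$observations$excluded) < 1) {
    stop("subject has no usable observations", call. = FALSE)
  }
  cs <- .compile_dataset(study_dataset(list(subject)), rule)[[1]]
  betas <- .make_betas(covariate_effects)
  cl <- pop$cl_f * cs$wf_cl * .cov_multiplier(cs, betas) * exp(eta_cl)
  .subject_pred(cs, cl, pop$v_f * cs$wf_v, pop$ka)
}

#' Empirical Bayes estimate of a subject's clearance random effect
#'
#' The conditional mode: minimiser of
#' `sum_j [(y_j - f_j(eta))^2 / g_j(eta) + ln g_j(eta)] + eta^2 / omega2`.
#'
#' @inheritParams predict_subject
#' @return The mode `eta_hat` (0 when `omega2_cl` is 0).
#' @export
ebe <- function(pop, var, subject, covariate_effects = list(),
                rule = allometric_rule()) {
  if (var$omega2_cl <= 0) return(0)
  cs <- .compile_dataset(study_dataset(list(subject)), rule)[[1]]
  betas <- .make_betas(covariate_effects)
  cl_base <- pop$cl_f * cs$wf_cl * .cov_multiplier(cs, betas)
  test <- .ebe_objective(0, cs, cl_base, pop$v_f * cs$wf_v, pop$ka,
                         var$omega2_cl, var$sigma_prop^2, var$sigma_add^2)
  if (test >= 1e10) {
    stop(sprintf("non-finite conditional objective for subject %s",
                 subject$id), call. = FALSE)
  }
  .find_ebe(cs, cl_base, pop$v_f * cs$wf_v, pop$ka,
            var$omega2_cl, var$sigma_prop^2, var$sigma_add^2)
}

#' FOCE-with-interaction objective function value
#'
#' Sum over subjects of the linearised marginal -2 log-likelihood, expanded
#' around each subject's conditional mode with residual variance evaluated at
#' the mode (the "interaction" term). Includes the `2*pi` constants so the
#' value is directly comparable with [agq_ofv()].
#'
#' @param pop A [pop_params()] object.
#' @param var A [var_params()] object.
#' @param dataset A [study_dataset()].
#' @param covariate_effects Optional list of [covariate_effect()] objects.
#' @param rule An [allometric_rule()].
#' @return The objective function value (a -2 log-likelihood approximation).
#' @export
foce_ofv <- function(pop, var, dataset, covariate_effects = list(),
                     rule = allometric_rule()) {
  compiled <- .compile_dataset(dataset, rule)
  out <- .ofv_compiled(compiled, pop, var, .make_betas(covariate_effects),
                       method = "foce_i")
  if (!is.finite(out)) {
    stop("singular linearised covariance in FOCE objective", call. = FALSE)
  }
  out
}

#' Adaptive Gauss-Hermite quadrature objective function value
#'
#' Gold-standard evaluation of the marginal -2 log-likelihood: with a single
#' random effect the marginal likelihood is a one-dimensional integral,
#' evaluated per subject by Gauss-Hermite quadrature centred and scaled at
#' the conditional mode.
#'
#' @inheritParams foce_ofv
#' @param nodes Number of quadrature nodes (>= 5).
#' @return The quadrature -2 log-likelihood.
#' @export
agq_ofv <- function(pop, var, dataset, nodes = 21, covariate_effects = list(),
                    rule = allometric_rule()) {
  stopifnot(nodes >= 5)
  compiled <- .compile_dataset(dataset, rule)
  gh <- pracma::gaussHermite(nodes)
  .ofv_compiled(compiled, pop, var, .make_betas(covariate_effects),
                method = "agq", gh = gh)
}

.pop_par_names <- c("cl_f", "v_f", "ka", "omega2_cl", "sigma_prop",
                    "sigma_add")

# Assemble pop/var objects from a full named natural-scale parameter vector.
.split_params <- function(theta) {
  list(pop = pop_params(theta[["cl_f"]], theta[["v_f"]], theta[["ka"]]),
       var = var_params(theta[["omega2_cl"]], theta[["sigma_prop"]],
                        theta[["sigma_add"]]))
}

#' Fit the population PK model by nonlinear mixed-effects estimation
#'
#' Minimises the FOCE-I (or adaptive-quadrature) objective over
#' log-transformed parameters with a quasi-Newton optimiser and seeded
#' multi-start jitter. Non-convergence is reported in the result, never as an
#' error, so that bulk refitting (bootstrap, covariate search) can triage
#' failed replicates.
#'
#' @param dataset A [study_dataset()].
#' @param init Named list with elements `pop` ([pop_params()]) and `var`
#'   ([var_params()]) giving initial values.
#' @param settings An [estimation_settings()] object.
#' @param covariate_effects Optional list of [covariate_effect()] objects;
#'   their `theta_cov` values are used as initial values and estimated.
#' @param rule An [allometric_rule()].
#' @return An object of class `fit_result` with elements `pop`, `var`,
#'   `covariate_effects`, `ofv`, `se`, `rse`, `ebes` (named by subject id),
#'   `converged`, `suspect_zero_gradient`, `gradient_norm`,
#'   `n_function_evals` and the settings used.
#' @export
fit_poppk <- function(dataset, init, settings = estimation_settings(),
                      covariate_effects = list(), rule = allometric_rule()) {
  compiled <- .compile_dataset(dataset, rule)
  stopifnot(length(compiled) > 0)
  gh <- if (settings$method == "agq") pracma::gaussHermite(settings$agq_nodes)
        else NULL

  init_theta <- c(cl_f = init$pop$cl_f, v_f = init$pop$v_f, ka = init$pop$ka,
                  omega2_cl = init$var$omega2_cl,
                  sigma_prop = init$var$sigma_prop,
                  sigma_add = init$var$sigma_add)
  beta0 <- .make_betas(covariate_effects)
  beta_names <- if (is.null(beta0)) character() else
    paste0("beta_", names(beta0))
  free_pop <- setdiff(.pop_par_names, settings$fixed_parameters)
  free <- c(free_pop, beta_names)

  etas_env <- new.env(parent = emptyenv())
  etas_env$etas <- numeric(length(compiled))
  n_eval <- 0L

  # x: transformed free parameters (log scale for the positive PK/variance
  # parameters, natural scale for covariate coefficients).
  to_x <- function(theta, betas) {
    c(log(theta[free_pop]),
      if (length(beta_names)) stats::setNames(as.numeric(betas), beta_names))
  }
  from_x <- function(x) {
    theta <- init_theta
    theta[free_pop] <- exp(x[free_pop])
    betas <- beta0
    if (length(beta_names)) {
      b <- as.numeric(x[beta_names])
      attributes(b) <- attributes(beta0)
      betas <- b
    }
    list(theta = theta, betas = betas)
  }
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    p <- from_x(x)
    pv <- tryCatch(.split_params(p$theta), error = function(e) NULL)
    if (is.null(pv)) return(1e10)
    val <- .ofv_compiled(compiled, pv$pop, pv$var, p$betas,
                         method = settings$method, gh = gh,
                         etas_env = etas_env)
    if (!is.finite(val)) 1e10 else val
  }

  x0 <- to_x(init_theta, beta0)
  if (length(x0) == 0) {
    # everything fixed: evaluate the objective at the initial values
    ofv0 <- objective(x0)
    etas_env$etas <- numeric(length(compiled))
    invisible(.ofv_compiled(compiled, init$pop, init$var, beta0,
                            method = settings$method, gh = gh,
                            etas_env = etas_env))
    return(structure(list(pop = init$pop, var = init$var,
                          covariate_effects = covariate_effects,
                          ofv = ofv0, se = NULL, rse = NULL,
                          ebes = stats::setNames(etas_env$etas,
                                                 vapply(compiled, `[[`,
                                                        character(1), "id")),
                          converged = TRUE,
                          suspect_zero_gradient = FALSE,
                          gradient_norm = 0,
                          n_function_evals = n_eval,
                          settings = settings, rule = rule),
                     class = "fit_result"))
  }
  num_grad <- function(x, h = 1e-5) {
    vapply(seq_along(x), function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (objective(xp) - objective(xm)) / (2 * h)
    }, numeric(1))
  }
  g0 <- num_grad(x0)
  suspect_zero_gradient <- any(abs(g0) < 1e-8)

  starts <- list(x0)
  if (settings$n_starts > 1) {
    rng <- .with_seed(settings$seed, {
      lapply(seq_len(settings$n_starts - 1), function(i)
        x0 + stats::rnorm(length(x0), sd = 0.25))
    })
    starts <- c(starts, rng)
  }
  best <- NULL
  for (s in starts) {
    etas_env$etas <- numeric(length(compiled))
    res <- tryCatch(
      stats::nlminb(s, objective,
                    control = list(iter.max = settings$max_iter,
                                   rel.tol = settings$convergence_tol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (res$convergence != 0) {
      # polish restart: flat directions (weakly identified v/ka) often trip
      # nlminb's false-convergence test; a restart from the solution either
      # confirms the optimum or improves it
      res2 <- tryCatch(
        stats::nlminb(res$par, objective,
                      control = list(iter.max = settings$max_iter,
                                     rel.tol = settings$convergence_tol)),
        error = function(e) NULL)
      if (!is.null(res2) && is.finite(res2$objective) &&
          res2$objective <= res$objective + 1e-8) res <- res2
    }
    if (is.null(best) || res$objective < best$objective - 1e-8) best <- res
  }

  if (is.null(best)) {
    return(structure(list(pop = init$pop, var = init$var,
                          covariate_effects = covariate_effects,
                          ofv = NA_real_, se = NULL, rse = NULL,
                          ebes = NULL, converged = FALSE,
                          suspect_zero_gradient = suspect_zero_gradient,
                          gradient_norm = NA_real_,
                          n_function_evals = n_eval,
                          settings = settings, rule = rule),
                     class = "fit_result"))
  }

  p_hat <- from_x(best$par)
  pv <- .split_params(p_hat$theta)
  grad <- num_grad(best$par)
  gradient_norm <- sqrt(sum(grad^2))
  # nlminb code 0 or an explicit *-convergence message counts as converged;
  # a "false convergence" stop is accepted only when the gradient is flat
  # (weakly identified directions), mirroring how minimisation-terminated
  # replicates are triaged in bulk refitting
  converged <- (best$convergence == 0 ||
                  grepl("relative convergence|X-convergence|absolute function",
                        best$message) ||
                  gradient_norm < 1) &&
    is.finite(best$objective) && best$objective < 1e10

  # EBEs at the final estimates
  etas_env$etas <- numeric(length(compiled))
  invisible(.ofv_compiled(compiled, pv$pop, pv$var, p_hat$betas,
                          method = settings$method, gh = gh,
                          etas_env = etas_env))
  ebes <- stats::setNames(etas_env$etas,
                          vapply(compiled, `[[`, character(1), "id"))

  se <- rse <- NULL
  if (settings$compute_se) {
    est_nat <- c(p_hat$theta[free_pop],
                 if (length(beta_names))
                   stats::setNames(as.numeric(p_hat$betas), beta_names))
    obj_nat <- function(v) {
      x <- c(log(pmax(v[seq_along(free_pop)], 1e-12)),
             if (length(beta_names)) v[-seq_along(free_pop)])
      names(x) <- free
      objective(x) / 2
    }
    H <- tryCatch(pracma::hessian(obj_nat, as.numeric(est_nat)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0)) {
        se <- stats::setNames(sqrt(diag(cov)), free)
        rse <- 100 * se / abs(est_nat)
      }
    }
  }

  fitted_effects <- covariate_effects
  if (length(beta_names)) {
    for (i in seq_along(fitted_effects)) {
      fitted_effects[[i]]$theta_cov <- as.numeric(p_hat$betas[i])
    }
  }

  structure(list(pop = pv$pop, var = pv$var,
                 covariate_effects = fitted_effects,
                 ofv = best$objective, se = se, rse = rse, ebes = ebes,
                 converged = converged,
                 suspect_zero_gradient = suspect_zero_gradient,
                 gradient_norm = gradient_norm,
                 n_function_evals = n_eval,
                 settings = settings, rule = rule),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Population PK fit (", x$settings$method, ")\n", sep = "")
  cat(sprintf("  OFV: %.3f   converged: %s\n", x$ofv, x$converged))
  est <- c("CL/F (L/h)" = x$pop$cl_f, "V/F (L)" = x$pop$v_f,
           "Ka (1/h)" = x$pop$ka,
           "IIV CL %CV" = cv_percent(x$var$omega2_cl),
           "Prop. error (%CV)" = 100 * x$var$sigma_prop,
           "Add. error (mg/L)" = x$var$sigma_add)
  rse_nm <- c("cl_f", "v_f", "ka", "omega2_cl", "sigma_prop", "sigma_add")
  for (i in seq_along(est)) {
    r <- if (!is.null(x$rse) && rse_nm[i] %in% names(x$rse))
      sprintf(" (%.1f%% RSE)", x$rse[[rse_nm[i]]]) else ""
    cat(sprintf("  %-18s %8.4g%s\n", names(est)[i], est[[i]], r))
  }
  for (e in x$covariate_effects) {
    cat(sprintf("  theta[%s] = %.4g (CL x %.3g)\n", e$covariate, e$theta_cov,
                exp(e$theta_cov)))
  }
  invisible(x)
}

#' Likelihood-ratio test for nested models
#'
#' The drop in objective function value between nested models is referred to
#' a chi-squared distribution with `df` degrees of freedom.
#'
#' @param ofv_reduced OFV of the reduced model.
#' @param ofv_full OFV of the full model.
#' @param df Degrees of freedom (number of added parameters).
#' @return The upper-tail p-value.
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1) {
  stopifnot(df >= 1)
  delta <- ofv_reduced - ofv_full
  if (delta < -1e-6) {
    warning("negative OFV drop beyond tolerance; returning p = 1")
    return(1)
  }
  stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
}

#' Coefficient of variation from a log-scale variance
#'
#' Reporting convention: `%CV = 100 * sqrt(omega2)`, the approximation
#' customarily printed for log-normal inter-individual variability.
#' [cv_percent_exact()] gives the exact log-normal CV
#' `100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 Variance on the log scale (>= 0).
#' @return CV in percent.
#' @export
cv_percent <- function(omega2) {
  stopifnot(omega2 >= 0)
  100 * sqrt(omega2)
}

#' @rdname cv_percent
#' @export
cv_percent_exact <- function(omega2) {
  stopifnot(omega2 >= 0)
  100 * sqrt(exp(omega2) - 1)
}

#' Reference model parameter values
#'
#' The published final-model estimates for posaconazole gastroresistant
#' tablets in children with cystic fibrosis: CL/F 8.43 L/h and V/F 186 L at
#' 70 kg, Ka 0.16 1/h, 38 %CV inter-individual variability on clearance
#' (omega = 0.38 under the `100*sqrt(omega2)` convention), 36 %CV
#' proportional and 0.15 mg/L additive residual error. Used as the simulation
#' truth throughout the package.
#'
#' @return List with elements `pop` ([pop_params()]) and `var`
#'   ([var_params()]).
#' @export
posaconazole_reference_model <- function() {
  list(pop = pop_params(cl_f = 8.43, v_f = 186, ka = 0.16),
       var = var_params(omega2_cl = 0.38^2, sigma_prop = 0.36,
                        sigma_add = 0.15))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
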