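# Time after most recent dose for each non-excluded observation of a subject.
.time_after_dose <- function(subject) {
  keep <- !subject$observations$excluded
  obs_t <- subject$observations$time[keep]
  vapply(obs_t, function(t) {
    prior <- subject$doses$time[subject$doses$time <= t]
    t - max(prior)
  }, numeric(1))
}

#' Conditional weighted residuals
#'
#' Per subject, `CWRES = V^{-1/2} (y - E)` where `E = f(eta_hat) -
#' F * eta_hat` is the FOCE-linearised conditional expectation,
#' `V = F omega2 F' + diag(g(eta_hat))` the linearised subject covariance
#' (`F = df/deta` at the conditional mode), and `V^{-1/2}` its symmetric
#' inverse square root. Under a correctly specified model the residuals are
#' approximately standard normal.
#'
#' @param fit A converged [fit_poppk()] result with empirical Bayes
#'   estimates.
#' @param dataset The [study_dataset()] the model was fitted to.
#' @return data.frame with columns `id`, `time`, `tad` (time after dose) and
#'   `cwres`, one row per non-excluded observation.
#' @export
cwres <- function(fit, dataset) {
  stopifnot(fit$converged, !is.null(fit$ebes))
  compiled <- .compile_dataset(dataset, fit$rule)
  betas <- .make_betas(fit$covariate_effects)
  sp2 <- fit$var$sigma_prop^2; sa2 <- fit$var$sigma_add^2
  omega2 <- fit$var$omega2_cl
  rows <- lapply(seq_along(compiled), function(i) {
    cs <- compiled[[i]]
    eta_hat <- fit$ebes[[cs$id]]
    cl_base <- fit$pop$cl_f * cs$wf_cl * .cov_multiplier(cs, betas)
    v_i <- fit$pop$v_f * cs$wf_v
    h <- 1e-4
    f0 <- .subject_pred(cs, cl_base * exp(eta_hat), v_i, fit$pop$ka)
    Fg <- if (omega2 > 0) {
      (.subject_pred(cs, cl_base * exp(eta_hat + h), v_i, fit$pop$ka) -
       .subject_pred(cs, cl_base * exp(eta_hat - h), v_i, fit$pop$ka)) /
        (2 * h)
    } else numeric(length(f0))
    g <- pmax(f0^2 * sp2 + sa2, 1e-12)
    V <- omega2 * tcrossprod(Fg) + diag(g, nrow = length(g))
    eg <- eigen(V, symmetric = TRUE)
    if (any(eg$values <= 0)) {
      stop(sprintf("singular linearised covariance for subject %s", cs$id),
           call. = FALSE)
    }
    Vm12 <- eg$vectors %*% diag(1 / sqrt(eg$values),
                                nrow = length(eg$values)) %*% t(eg$vectors)
    r <- as.numeric(Vm12 %*% (cs$y - (f0 - Fg * eta_hat)))
    data.frame(id = cs$id, time = cs$times,
               tad = .time_after_dose(dataset$subjects[[i]]), cwres = r)
  })
  do.call(rbind, rows)
}

# Simulate one replicate of the observed design from model parameters:
# returns the list of simulated concentration vectors (per subject), with
# combined residual error and below-LOQ values set to LOQ/2 as in the
# observed-data handling.
.simulate_design <- function(compiled, pop, var, betas, loq) {
  lapply(compiled, function(cs) {
    eta <- stats::rnorm(1, 0, sqrt(var$omega2_cl))
    cl <- pop$cl_f * cs$wf_cl * .cov_multiplier(cs, betas) * exp(eta)
    f <- .subject_pred(cs, cl, pop$v_f * cs$wf_v, pop$ka)
    n <- length(f)
    y <- f * (1 + stats::rnorm(n, 0, var$sigma_prop)) +
      stats::rnorm(n, 0, var$sigma_add)
    tries <- 0
    while (any(y < 0) && tries < 100) {
      bad <- y < 0
      y[bad] <- f[bad] * (1 + stats::rnorm(sum(bad), 0, var$sigma_prop)) +
        stats::rnorm(sum(bad), 0, var$sigma_add)
      tries <- tries + 1
    }
    y[y < 0] <- loq / 2
    y[y < loq] <- loq / 2
    y
  })
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design (same
#' subjects, doses, sampling times and weights), bins observations by time
#' after dose, and compares the observed 2.5th/50th/97.5th concentration
#' percentiles per bin with the 95% confidence band of those percentiles
#' across replicates. Simulated concentrations below the assay LOQ are set
#' to LOQ/2, matching the observed-data handling.
#'
#' @param fit A converged [fit_poppk()] result.
#' @param dataset The [study_dataset()].
#' @param n_sim Number of simulation replicates (default 1000).
#' @param bins Number of quantile-based bins on time after dose (default 6);
#'   bins with fewer than 2 observations are merged with a neighbour.
#' @param seed Integer seed; same seed, identical bands.
#' @return An object of class `vpc_result`: data.frame with one row per bin
#'   and columns `tad_lo`, `tad_hi`, `n_obs`, observed percentiles
#'   `obs_p2.5`, `obs_p50`, `obs_p97.5`, and simulated 95% CI bounds
#'   `sim_p<q>_lo` / `sim_p<q>_hi` for each percentile.
#' @export
vpc <- function(fit, dataset, n_sim = 1000, bins = 6, seed = 1L) {
  stopifnot(fit$converged, n_sim >= 1)
  compiled <- .compile_dataset(dataset, fit$rule)
  betas <- .make_betas(fit$covariate_effects)
  tad <- unlist(lapply(dataset$subjects, .time_after_dose))
  yobs <- unlist(lapply(compiled, `[[`, "y"))

  edges <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1),
                             length(edges) - 1)
  b <- bin_of(tad)
  # merge underpopulated bins with their left neighbour
  repeat {
    counts <- tabulate(b, nbins = length(edges) - 1)
    small <- which(counts > 0 & counts < 2)
    if (length(small) == 0) break
    i <- small[1]
    edges <- edges[-max(i, 2)]
    b <- bin_of(tad)
  }
  nb <- length(edges) - 1
  probs <- c(0.025, 0.5, 0.975)
  obs_pct <- t(vapply(seq_len(nb), function(i) {
    stats::quantile(yobs[b == i], probs = probs, names = FALSE)
  }, numeric(3)))

  sims <- .with_seed(seed, {
    lapply(seq_len(n_sim), function(r) {
      ys <- unlist(.simulate_design(compiled, fit$pop, fit$var, betas,
                                    dataset$assay$loq))
      t(vapply(seq_len(nb), function(i) {
        stats::quantile(ys[b == i], probs = probs, names = FALSE)
      }, numeric(3)))
    })
  })
  arr <- simplify2array(sims)            # nb x 3 x n_sim
  ci_lo <- apply(arr, c(1, 2), stats::quantile, probs = 0.025)
  ci_hi <- apply(arr, c(1, 2), stats::quantile, probs = 0.975)

  out <- data.frame(tad_lo = edges[-length(edges)], tad_hi = edges[-1],
                    n_obs = tabulate(b, nbins = nb),
                    obs_p2.5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
                    obs_p97.5 = obs_pct[, 3],
                    sim_p2.5_lo = ci_lo[, 1], sim_p2.5_hi = ci_hi[, 1],
                    sim_p50_lo = ci_lo[, 2], sim_p50_hi = ci_hi[, 2],
                    sim_p97.5_lo = ci_lo[, 3], sim_p97.5_hi = ci_hi[, 3])
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement to the original subject count and
#' refits each replicate. Replicates are dropped from the summaries when
#' minimisation fails or when the fit starts with a suspect all-zero
#' gradient; both failure modes are counted.
#'
#' @param dataset A [study_dataset()].
#' @param init Initial values (list with `pop`, `var`) for each refit.
#' @param settings [estimation_settings()] for the refits (standard errors
#'   are never computed here).
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param covariate_effects Optional covariate effects kept in the model.
#' @return An object of class `bootstrap_result`: list with `n_requested`,
#'   `n_used`, `n_failed_minimization`, `n_zero_gradient`, `estimates` (one
#'   row per usable replicate) and `summary` (per-parameter median and 95%
#'   percentile CI, including the IIV %CV).
#' @export
pk_bootstrap <- function(dataset, init,
                         settings = estimation_settings(n_starts = 1L,
                                                        compute_se = FALSE),
                         n = 1000, seed = 1L, covariate_effects = list()) {
  stopifnot(length(dataset$subjects) >= 2)
  settings$compute_se <- FALSE
  if (n == 0) {
    return(structure(list(n_requested = 0L, n_used = 0L,
                          n_failed_minimization = 0L, n_zero_gradient = 0L,
                          estimates = NULL, summary = NULL),
                     class = "bootstrap_result"))
  }
  ns <- length(dataset$subjects)
  idx_list <- .with_seed(seed, {
    lapply(seq_len(n), function(r) sample.int(ns, ns, replace = TRUE))
  })
  n_fail <- 0L; n_zg <- 0L
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    subj <- dataset$subjects[idx_list[[r]]]
    for (j in seq_along(subj)) subj[[j]]$id <- sprintf("bs%03d", j)
    bds <- study_dataset(subj, assay = dataset$assay)
    f <- fit_poppk(bds, init, settings, covariate_effects = covariate_effects)
    if (!f$converged || !is.finite(f$ofv)) {
      n_fail <- n_fail + 1L
    } else if (f$suspect_zero_gradient) {
      n_zg <- n_zg + 1L
    } else {
      rows[[r]] <- data.frame(cl_f = f$pop$cl_f, v_f = f$pop$v_f,
                              ka = f$pop$ka, omega2_cl = f$var$omega2_cl,
                              sigma_prop = f$var$sigma_prop,
                              sigma_add = f$var$sigma_add,
                              iiv_cv = cv_percent(f$var$omega2_cl))
    }
  }
  est <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n_used <- if (is.null(est)) 0L else nrow(est)
  if (n_used < n / 2) {
    stop(sprintf("bootstrap unstable: only %d of %d replicates usable",
                 n_used, n), call. = FALSE)
  }
  summ <- do.call(rbind, lapply(names(est), function(p) {
    q <- stats::quantile(est[[p]], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, median = q[2], ci_lo = q[1], ci_hi = q[3])
  }))
  structure(list(n_requested = n, n_used = n_used,
                 n_failed_minimization = n_fail, n_zero_gradient = n_zg,
                 estimates = est, summary = summ),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d requested, %d used (%d failed minimisation, %d zero-gradient)\n",
              x$n_requested, x$n_used, x$n_failed_minimization,
              x$n_zero_gradient))
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("  %-10s median %8.4g (95%% CI %.4g-%.4g)\n", s$parameter,
                  s$median, s$ci_lo, s$ci_hi))
    }
  }
  invisible(x)
}
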