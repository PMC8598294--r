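#' Binary covariate effect on clearance
#'
#' Exponential-binary parameterisation, `CL = TVCL * exp(theta_cov * x)` for
#' a 0/1 covariate `x`: guarantees positive clearance for any coefficient.
#' A proportional form `CL = TVCL * (1 + theta_cov * x)` is available for
#' comparison.
#'
#' @param covariate One of `liver_abnormal`, `ppi_h2ra`, `clarithromycin`,
#'   `rifampicin`, `rifabutin`, `orkambi`.
#' @param theta_cov Coefficient (initial value when passed to a fit).
#' @param form `"exponential"` (default) or `"proportional"`.
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(covariate, theta_cov = 0,
                             form = c("exponential", "proportional")) {
  form <- match.arg(form)
  if (!covariate %in% .covariate_names) {
    stop(sprintf("unknown covariate '%s'", covariate), call. = FALSE)
  }
  structure(list(parameter = "cl", covariate = covariate,
                 theta_cov = theta_cov, form = form),
            class = "covariate_effect")
}

#' Liver-function abnormality flag
#'
#' TRUE when any available liver analyte (ALT, alkaline phosphatase, AST,
#' GGT, bilirubin) lies outside its reference range, on either side. Missing
#' analytes are ignored.
#'
#' @param labs Named list; each element is a numeric vector
#'   `c(value, low_ref, high_ref)` for one of `alt`, `alp`, `ast`, `ggt`,
#'   `bilirubin`.
#' @return Logical flag, with attribute `"missing"` listing analytes not
#'   supplied.
#' @export
#' @examples
#' liver_flag(list(alt = c(80, 10, 40), bilirubin = c(10, 2, 21)))
liver_flag <- function(labs) {
  known <- c("alt", "alp", "ast", "ggt", "bilirubin")
  present <- intersect(names(labs), known)
  if (length(present) == 0) {
    stop("at least one liver analyte must be supplied", call. = FALSE)
  }
  out <- any(vapply(labs[present], function(v) {
    v[1] < v[2] || v[1] > v[3]
  }, logical(1)))
  attr(out, "missing") <- setdiff(known, present)
  out
}

# Number of subjects in the minority class of a binary covariate; candidates
# with fewer than 2 are uninformative and skipped with a log entry.
.minority_count <- function(dataset, covariate) {
  x <- vapply(dataset$subjects, function(s) s$covariates[[covariate]],
              logical(1))
  min(sum(x), sum(!x))
}

#' Forward step of stepwise covariate model building
#'
#' Iteratively refits the model with each remaining candidate effect added;
#' the candidate with the smallest likelihood-ratio p-value is included if
#' `p <= alpha` (an OFV drop of at least 3.84 for one degree of freedom at
#' the default 0.05). Ties are broken by larger OFV drop, then candidate
#' order. Candidates whose fit fails to converge, or with fewer than two
#' subjects in the minority class, are skipped that round and logged.
#'
#' @param base A converged [fit_poppk()] result for the covariate-free (or
#'   current) model.
#' @param dataset The [study_dataset()] the base model was fitted to.
#' @param candidates List of [covariate_effect()] objects to test.
#' @param alpha Forward inclusion threshold (default 0.05).
#' @param settings [estimation_settings()] used for the candidate fits.
#' @return List with elements `fit` (the final forward model), `result` (an
#'   `scm_result` step log) and `effects` (the selected effects).
#' @export
scm_forward <- function(base, dataset, candidates, alpha = 0.05,
                        settings = NULL) {
  stopifnot(base$converged)
  if (is.null(settings)) {
    settings <- base$settings
    settings$compute_se <- FALSE
    settings$n_starts <- 1L
  }
  steps <- list()
  current_fit <- base
  current_effects <- base$covariate_effects
  remaining <- candidates
  init <- list(pop = base$pop, var = base$var)
  repeat {
    if (length(remaining) == 0) break
    trial <- lapply(remaining, function(cand) {
      if (.minority_count(dataset, cand$covariate) < 2) {
        return(list(cand = cand, skip = "minority class < 2 subjects"))
      }
      f <- fit_poppk(dataset,
                     init = list(pop = current_fit$pop,
                                 var = current_fit$var),
                     settings = settings,
                     covariate_effects = c(current_effects, list(cand)))
      if (!f$converged || !is.finite(f$ofv)) {
        return(list(cand = cand, skip = "candidate fit did not converge"))
      }
      list(cand = cand, fit = f,
           dofv = current_fit$ofv - f$ofv,
           p = lrt(current_fit$ofv, f$ofv, df = 1))
    })
    ok <- !vapply(trial, function(t) !is.null(t$skip), logical(1))
    for (t in trial[!ok]) {
      steps[[length(steps) + 1]] <- list(
        step = "forward", candidate = t$cand$covariate, dofv = NA_real_,
        p = NA_real_, accepted = FALSE, note = t$skip)
    }
    trial <- trial[ok]
    if (length(trial) == 0) break
    ps <- vapply(trial, `[[`, numeric(1), "p")
    ds <- vapply(trial, `[[`, numeric(1), "dofv")
    best <- order(ps, -ds)[1]
    accepted <- ps[best] <= alpha
    for (j in seq_along(trial)) {
      steps[[length(steps) + 1]] <- list(
        step = "forward", candidate = trial[[j]]$cand$covariate,
        dofv = ds[j], p = ps[j], accepted = accepted && j == best,
        note = NA_character_)
    }
    if (!accepted) break
    current_fit <- trial[[best]]$fit
    current_effects <- current_fit$covariate_effects
    chosen <- trial[[best]]$cand$covariate
    remaining <- Filter(function(c) c$covariate != chosen, remaining)
  }
  list(fit = current_fit, effects = current_effects,
       result = .scm_result(steps,
                            forward_set = vapply(current_effects, `[[`,
                                                 character(1), "covariate"),
                            final_set = NULL))
}

#' Backward elimination step of stepwise covariate model building
#'
#' Iteratively removes the effect whose removal is least significant
#' (largest p-value) while that p exceeds `alpha`; retained effects must
#' survive at the stricter backward threshold (an OFV increase of at least
#' 6.63 for one degree of freedom at the default 0.01).
#'
#' @param full A converged [fit_poppk()] result containing the forward-
#'   selected effects.
#' @param dataset The [study_dataset()].
#' @param alpha Backward retention threshold (default 0.01).
#' @param settings [estimation_settings()] for the reduced-model fits.
#' @return List with elements `fit`, `effects` and `result` as in
#'   [scm_forward()].
#' @export
scm_backward <- function(full, dataset, alpha = 0.01, settings = NULL) {
  stopifnot(full$converged)
  if (is.null(settings)) {
    settings <- full$settings
    settings$compute_se <- FALSE
    settings$n_starts <- 1L
  }
  steps <- list()
  current_fit <- full
  current_effects <- full$covariate_effects
  repeat {
    if (length(current_effects) == 0) break
    trial <- lapply(seq_along(current_effects), function(i) {
      f <- fit_poppk(dataset,
                     init = list(pop = current_fit$pop,
                                 var = current_fit$var),
                     settings = settings,
                     covariate_effects = current_effects[-i])
      if (!f$converged || !is.finite(f$ofv)) {
        return(list(i = i, skip = "reduced fit did not converge"))
      }
      list(i = i, fit = f, dofv = f$ofv - current_fit$ofv,
           p = lrt(f$ofv, current_fit$ofv, df = 1))
    })
    ok <- !vapply(trial, function(t) !is.null(t$skip), logical(1))
    for (t in trial[!ok]) {
      steps[[length(steps) + 1]] <- list(
        step = "backward", candidate = current_effects[[t$i]]$covariate,
        dofv = NA_real_, p = NA_real_, accepted = FALSE, note = t$skip)
    }
    trial <- trial[ok]
    if (length(trial) == 0) break
    ps <- vapply(trial, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    removed <- ps[worst] > alpha
    for (j in seq_along(trial)) {
      steps[[length(steps) + 1]] <- list(
        step = "backward",
        candidate = current_effects[[trial[[j]]$i]]$covariate,
        dofv = trial[[j]]$dofv, p = ps[j],
        accepted = removed && j == worst, note = NA_character_)
    }
    if (!removed) break
    current_fit <- trial[[worst]]$fit
    current_effects <- current_effects[-trial[[worst]]$i]
  }
  list(fit = current_fit, effects = current_effects,
       result = .scm_result(steps, forward_set = NULL,
                            final_set = vapply(current_effects, `[[`,
                                               character(1), "covariate")))
}

#' Full stepwise covariate model building
#'
#' Forward inclusion at `alpha_forward` followed by backward elimination at
#' `alpha_backward` on the forward-selected set.
#'
#' @param dataset A [study_dataset()].
#' @param init Initial values (list with `pop`, `var`) for the base fit.
#' @param candidates List of [covariate_effect()] objects.
#' @param alpha_forward,alpha_backward Inclusion/retention thresholds.
#' @param settings [estimation_settings()] for all fits.
#' @return List with `base_fit`, `final_fit`, `final_effects` and `result`
#'   (combined step log with `forward_set` and `final_set`).
#' @export
scm <- function(dataset, init, candidates, alpha_forward = 0.05,
                alpha_backward = 0.01,
                settings = estimation_settings(n_starts = 1L,
                                               compute_se = FALSE)) {
  base <- fit_poppk(dataset, init, settings)
  if (!base$converged) stop("base model fit did not converge", call. = FALSE)
  fwd <- scm_forward(base, dataset, candidates, alpha = alpha_forward,
                     settings = settings)
  bwd <- scm_backward(fwd$fit, dataset, alpha = alpha_backward,
                      settings = settings)
  steps <- c(fwd$result$steps, bwd$result$steps)
  list(base_fit = base, final_fit = bwd$fit, final_effects = bwd$effects,
       result = .scm_result(steps,
                            forward_set = fwd$result$forward_set,
                            final_set = bwd$result$final_set))
}

.scm_result <- function(steps, forward_set = NULL, final_set = NULL) {
  structure(list(steps = steps, forward_set = forward_set,
                 final_set = final_set), class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate model building\n")
  for (s in x$steps) {
    if (!is.na(s$note)) {
      cat(sprintf("  [%s] %-15s skipped: %s\n", s$step, s$candidate, s$note))
    } else {
      cat(sprintf("  [%s] %-15s dOFV %7.3f  p %.4f  %s\n", s$step,
                  s$candidate, s$dofv, s$p,
                  if (s$accepted) "<-- selected" else ""))
    }
  }
  if (!is.null(x$final_set)) {
    cat("Final covariate set:",
        if (length(x$final_set)) paste(x$final_set, collapse = ", ")
        else "(empty)", "\n")
  }
  invisible(x)
}
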