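test_that("residual variance combines proportional and additive terms", {
  v <- var_params(0.1444, 0.36, 0.15)
  expect_equal(residual_variance(0, v), 0.15^2)
  expect_equal(residual_variance(2, v), 0.5409)
  f <- seq(0, 10, by = 0.5)
  expect_true(all(diff(residual_variance(f, v)) >= 0))
  expect_error(var_params(0.1, 0, 0), "residual")
})

test_that("subject predictions compose scaling, IIV and the structural model", {
  s <- make_subject(times = c(2, 8, 24), conc = c(1, 2, 1.5))
  f0 <- predict_subject(ref_model$pop, ref_model$var, s)
  expect_length(f0, 3)

  # eta = 0 reproduces the typical-value profile
  ind <- scale_parameters(ref_model$pop, s$weight)
  direct <- concentration(ind, data.frame(time = 0, amount = 300, ss = 1,
                                          ii = 24), c(2, 8, 24))
  expect_equal(f0, direct)

  # eta shifts clearance multiplicatively
  f1 <- predict_subject(ref_model$pop, ref_model$var, s, eta_cl = 0.3)
  ind1 <- apply_iiv(ind, 0.3)
  expect_equal(f1, concentration(ind1, data.frame(time = 0, amount = 300,
                                                  ss = 1, ii = 24),
                                 c(2, 8, 24)))

  # one-observation subject at the reference weight: the prediction is the
  # bare single-dose closed form
  s1 <- subject_record(id = "B", age = 10, weight = 70,
                       doses = dose_event(0, 300),
                       observations = observation(24, 1))
  expect_equal(predict_subject(pop_params(4.63, 83.7, 0.16),
                               ref_model$var, s1),
               concentration(ind_params(4.63, 83.7, 0.16),
                             data.frame(time = 0, amount = 300), 24))
})

test_that("empirical Bayes estimates are the conditional mode", {
  s <- make_subject()
  # observation exactly at the typical prediction with additive-only error:
  # the residual weighting is flat in eta and the prior mode wins exactly
  s0 <- make_subject(times = 8, conc = 1)
  add_only <- var_params(ref_model$var$omega2_cl, 0, 0.15)
  s0$observations$concentration <- predict_subject(ref_model$pop, add_only,
                                                   s0)
  expect_equal(ebe(ref_model$pop, add_only, s0), 0, tolerance = 1e-4)
  # with interaction (proportional error) the ln g term shifts the mode
  # only slightly
  s1 <- s
  s1$observations$concentration <- predict_subject(ref_model$pop,
                                                   ref_model$var, s1)
  expect_lt(abs(ebe(ref_model$pop, ref_model$var, s1)), 0.1)

  # shrinkage limit: vanishing omega2 forces eta to 0
  tight <- var_params(1e-10, 0.36, 0.15)
  expect_equal(ebe(ref_model$pop, tight, s), 0, tolerance = 1e-4)

  # brute-force grid oracle
  grid <- seq(-3, 3, by = 1e-4)
  obj <- vapply(grid, function(e) {
    f <- predict_subject(ref_model$pop, ref_model$var, s, eta_cl = e)
    g <- residual_variance(f, ref_model$var)
    sum((s$observations$concentration - f)^2 / g + log(g)) +
      e^2 / ref_model$var$omega2_cl
  }, numeric(1))
  expect_equal(ebe(ref_model$pop, ref_model$var, s), grid[which.min(obj)],
               tolerance = 1e-3)
})

test_that("EBE shrinkage grows as per-subject information shrinks", {
  withr::with_seed(10, {
    d <- default_design(); d$n_subjects <- 30L
    rich <- d; rich$samples_per_subject <- c(0, 0, 0, 0, 0, 1, 0, 0, 0)
    poor <- d; poor$samples_per_subject <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
    g_rich <- generate_study(ref_model$pop, ref_model$var, rich, seed = 11)
    g_poor <- generate_study(ref_model$pop, ref_model$var, poor, seed = 11)
    eta_rich <- vapply(g_rich$dataset$subjects, function(s)
      ebe(ref_model$pop, ref_model$var, s), numeric(1))
    eta_poor <- vapply(g_poor$dataset$subjects, function(s)
      ebe(ref_model$pop, ref_model$var, s), numeric(1))
    # shrinkage: 1 - sd(eta_hat)/omega larger for the sparse design
    expect_lt(sd(eta_poor), sd(eta_rich))
  })
})

test_that("FOCE-I objective reduces to weighted least squares without IIV", {
  g <- generate_study(ref_model$pop, ref_model$var, seed = 12)
  v0 <- var_params(0, 0.36, 0.15)
  ofv <- foce_ofv(ref_model$pop, v0, g$dataset)
  direct <- sum(vapply(g$dataset$subjects, function(s) {
    f <- predict_subject(ref_model$pop, v0, s)
    g_ <- residual_variance(f, v0)
    sum(log(2 * pi * g_) + (s$observations$concentration - f)^2 / g_)
  }, numeric(1)))
  expect_equal(ofv, direct, tolerance = 1e-8)
  # quadrature agrees exactly in the no-random-effect limit
  expect_equal(agq_ofv(ref_model$pop, v0, g$dataset), ofv, tolerance = 1e-8)
})

test_that("adaptive quadrature matches direct integration and converges", {
  s <- make_subject(times = c(2, 5, 10, 16, 24),
                    conc = c(1.1, 2.4, 2.0, 1.6, 1.2))
  ds <- study_dataset(list(s))
  marg <- function(e) {
    vapply(e, function(eta) {
      f <- predict_subject(ref_model$pop, ref_model$var, s, eta_cl = eta)
      g <- residual_variance(f, ref_model$var)
      exp(sum(dnorm(s$observations$concentration, f, sqrt(g), log = TRUE)) +
            dnorm(eta, 0, sqrt(ref_model$var$omega2_cl), log = TRUE))
    }, numeric(1))
  }
  direct <- -2 * log(integrate(marg, -5, 5, rel.tol = 1e-12)$value)
  expect_equal(agq_ofv(ref_model$pop, ref_model$var, ds, nodes = 21), direct,
               tolerance = 1e-6)
  # node-count convergence
  expect_lt(abs(agq_ofv(ref_model$pop, ref_model$var, ds, nodes = 21) -
                  agq_ofv(ref_model$pop, ref_model$var, ds, nodes = 51)),
            0.01)
  expect_error(estimation_settings(method = "agq", agq_nodes = 4))
})

test_that("fitting with every parameter fixed evaluates without moving", {
  g <- generate_study(ref_model$pop, ref_model$var, seed = 13)
  all_fixed <- estimation_settings(
    fixed_parameters = c("cl_f", "v_f", "ka", "omega2_cl", "sigma_prop",
                         "sigma_add"),
    n_starts = 1L, compute_se = FALSE)
  f <- fit_poppk(g$dataset, ref_model, all_fixed)
  expect_true(f$converged)
  expect_equal(f$pop$cl_f, ref_model$pop$cl_f)
  expect_equal(f$var$omega2_cl, ref_model$var$omega2_cl)
  expect_equal(f$ofv, foce_ofv(ref_model$pop, ref_model$var, g$dataset),
               tolerance = 1e-8)
  expect_length(f$ebes, 37)
})

test_that("the fit is invariant to subject ordering", {
  d <- default_design(); d$n_subjects <- 15L
  g <- generate_study(ref_model$pop, ref_model$var, d, seed = 14)
  init <- list(pop = pop_params(10, 150, 0.3),
               var = var_params(0.2, 0.3, 0.2))
  f1 <- fit_poppk(g$dataset, init, fast_settings)
  ds2 <- g$dataset
  ds2$subjects <- rev(ds2$subjects)
  f2 <- fit_poppk(ds2, init, fast_settings)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-4)
  expect_equal(f1$pop$cl_f, f2$pop$cl_f, tolerance = 1e-3)
})

test_that("likelihood-ratio tests use the chi-squared reference", {
  expect_equal(lrt(103.841, 100, df = 1), 0.05, tolerance = 1e-3)
  expect_equal(lrt(106.635, 100, df = 1), 0.01, tolerance = 1e-3)
  expect_equal(lrt(100, 100, df = 1), 1)
  expect_warning(p <- lrt(99, 100, df = 1), "negative")
  expect_equal(p, 1)
})

test_that("CV conventions for log-normal variability", {
  expect_equal(cv_percent(0.1444), 38.0)
  expect_equal(cv_percent(0), 0)
  expect_equal(cv_percent_exact(0.1444), 39.43, tolerance = 1e-3)
})
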