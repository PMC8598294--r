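aw_model <- fit_age_weight(summaries = study_demographics())

test_that("the demographic model reproduces the published band medians", {
  # the printed age bands, sampled over their stated ranges
  p_young <- sample_population(aw_model, c(6, 11), 5000, seed = 41)
  p_old <- sample_population(aw_model, c(12, 17), 5000, seed = 42)
  expect_equal(median(p_young$weight), 31.5, tolerance = 0.1)
  expect_equal(median(p_old$weight), 50, tolerance = 0.1)
  expect_true(all(p_young$age >= 6 & p_young$age <= 11))
  expect_true(all(p_young$weight >= aw_model$weight_bounds[1] &
                    p_young$weight <= aw_model$weight_bounds[2]))
})

test_that("demographic model estimation validates its inputs", {
  same <- data.frame(age = rep(10, 5), weight = rep(30, 5))
  expect_error(fit_age_weight(pairs = same), "degenerate")

  pairs <- data.frame(age = c(7, 9, 11, 13, 15, 17),
                      weight = c(24, 29, 34, 42, 50, 58))
  m <- fit_age_weight(pairs = pairs)
  expect_equal(m$mean[1], mean(pairs$age))
  expect_equal(m$mean[2], mean(log(pairs$weight)))

  bad_cov <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(age_weight_model(c(10, 3.5), bad_cov), "positive-definite")
})

test_that("population sampling is reproducible and respects the band", {
  p1 <- sample_population(aw_model, c(9, 12), 1000, seed = 5)
  p2 <- sample_population(aw_model, c(9, 12), 1000, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$age >= 9 & p1$age <= 12))

  # law of large numbers: empirical age/log-weight correlation near the model
  big <- sample_population(aw_model, c(6, 18), 5e4, seed = 6)
  rho_model <- aw_model$cov[1, 2] / sqrt(prod(diag(aw_model$cov)))
  expect_equal(cor(big$age, log(big$weight)), rho_model, tolerance = 0.1)

  expect_error(sample_population(aw_model, c(30, 40), 10), "overlap|mass")
})

test_that("exposure simulation composes allometry, IIV and steady state", {
  reg <- regimen(loading_dose = 300, loading_interval = 12, n_loading = 2,
                 maintenance_dose = 300, maintenance_interval = 24)
  pts <- data.frame(age = c(12, 12), weight = c(70, 70))
  novar <- var_params(0, 0.36, 0.15)
  ex <- simulate_exposure(ref_model$pop, novar, pts, reg, seed = 7)
  # without IIV, identical patients have identical exposure
  expect_equal(ex$ss_trough[1], ex$ss_trough[2])
  # daily AUC identity at the reference weight: 300 / 8.43
  expect_equal(ex$ss_auc24[1], 300 / 8.43)
  expect_equal(ex$ss_auc24,
               attr(ex, "daily_dose") / (ref_model$pop$cl_f *
                                           (ex$weight / 70)^0.75 *
                                           exp(ex$eta_cl)))

  # trough below the daily average concentration for every patient
  pop1 <- sample_population(aw_model, c(6, 18), 500, seed = 8)
  ex1 <- simulate_exposure(ref_model$pop, ref_model$var, pop1, reg, seed = 9)
  expect_true(all(ex1$ss_trough < ex1$ss_auc24 / 24))
  expect_true(all(ex1$ss_trough > 0 & ex1$ss_auc24 > 0))
})

test_that("PTA reports exact binomial uncertainty", {
  ex <- data.frame(ss_trough = c(2, 3, 4), ss_auc24 = c(40, 50, 60))
  p <- pta(ex, target_definition("trough", 1))
  expect_equal(p$proportion, 1)
  expect_true(p$ci[1] <= p$proportion && p$proportion <= p$ci[2])
  p2 <- pta(ex, target_definition("auc24", 55))
  expect_equal(p2$proportion, 1 / 3)
  expect_error(target_definition("trough", -1))
})

test_that("simulated AUC attainment matches the closed-form integral", {
  # point mass at the reference weight: hand value Phi(ln(10/8.43)/0.38)
  point <- age_weight_model(c(12, log(70)),
                            matrix(c(4, 0, 0, 1e-8), 2, 2),
                            weight_bounds = c(15, 200))
  p_hand <- pta_closed_form_auc(ref_model$pop, ref_model$var, point,
                                c(6, 18), daily_dose = 300, auc_target = 30)
  expect_equal(p_hand, pnorm(log(300 / 30 / 8.43) / 0.38), tolerance = 1e-3)

  # vanishing target: certain attainment
  expect_equal(pta_closed_form_auc(ref_model$pop, ref_model$var, aw_model,
                                   c(6, 18), 300, auc_target = 1e-6), 1,
               tolerance = 1e-6)

  # Monte Carlo within 3 binomial SEs of the integral, several scenarios
  for (sc in list(list(band = c(6, 12), dose = 300),
                  list(band = c(12, 18), dose = 400),
                  list(band = c(9, 12), dose = 200))) {
    n <- 2e4
    pts <- sample_population(aw_model, sc$band, n, seed = 10 + sc$dose)
    reg <- regimen(maintenance_dose = sc$dose, maintenance_interval = 24)
    ex <- simulate_exposure(ref_model$pop, ref_model$var, pts, reg,
                            seed = 11 + sc$dose)
    mc <- pta(ex, target_definition("auc24", 30))$proportion
    cf <- pta_closed_form_auc(ref_model$pop, ref_model$var, aw_model,
                              sc$band, sc$dose)
    se <- sqrt(cf * (1 - cf) / n)
    expect_lt(abs(mc - cf), 3 * se + 1e-4)
  }
})

test_that("PTA is monotone in dose and AUC is the easier target", {
  curve_tr <- pta_curve(ref_model$pop, ref_model$var, aw_model, c(9, 12),
                        doses = seq(100, 600, by = 100),
                        target = target_definition("trough", 1),
                        n = 400, seed = 12)
  expect_true(all(diff(curve_tr$pta) >= 0))

  # at the recommended doses AUC >= 30 is attained at least as often as
  # trough >= 1
  for (sc in list(list(band = c(6, 12), dose = 300),
                  list(band = c(12, 18), dose = 400))) {
    pts <- sample_population(aw_model, sc$band, 1000, seed = 13)
    reg <- regimen(maintenance_dose = sc$dose, maintenance_interval = 24)
    ex <- simulate_exposure(ref_model$pop, ref_model$var, pts, reg, seed = 14)
    expect_gte(pta(ex, target_definition("auc24", 30))$proportion,
               pta(ex, target_definition("trough", 1))$proportion)
  }
})

test_that("AUC and trough are tightly correlated, invariant to units", {
  pts <- data.frame(age = rep(12, 800), weight = rep(45, 800))
  reg <- regimen(maintenance_dose = 300, maintenance_interval = 24)
  ex <- simulate_exposure(ref_model$pop, ref_model$var, pts, reg, seed = 15)
  # a single latent driver (eta) at fixed weight
  r2 <- auc_trough_r2(ex)
  expect_gt(r2, 0.95)
  ex_scaled <- ex
  ex_scaled$ss_auc24 <- ex_scaled$ss_auc24 * 1000
  expect_equal(auc_trough_r2(ex_scaled), r2)
  expect_error(auc_trough_r2(data.frame(ss_trough = rep(1, 5),
                                        ss_auc24 = rep(2, 5))), "variance")
})

test_that("the trough surrogate scan behaves at the boundaries", {
  # everyone attains the AUC target: any trough qualifies
  ex <- data.frame(ss_trough = c(0.5, 1, 2), ss_auc24 = c(40, 50, 60))
  expect_equal(trough_threshold_for_auc(ex), 0)

  # mixed attainment: cutoff is monotone in the required coverage
  withr::with_seed(16, {
    n <- 5000
    tr <- exp(rnorm(n, 0, 0.6))
    auc <- 30 * tr * exp(rnorm(n, 0.1, 0.35))
    ex2 <- data.frame(ss_trough = tr, ss_auc24 = auc)
    c80 <- trough_threshold_for_auc(ex2, coverage = 0.8)
    c90 <- trough_threshold_for_auc(ex2, coverage = 0.9)
    expect_lte(c80, c90)
  })

  # unattainable coverage is an error naming the best achievable
  ex3 <- data.frame(ss_trough = c(1, 2, 3), ss_auc24 = c(10, 10, 10))
  expect_error(trough_threshold_for_auc(ex3), "unattainable")
})
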