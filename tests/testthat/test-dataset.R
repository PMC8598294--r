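test_that("below-LOQ observations are imputed to half the LOQ", {
  assay <- assay_config(loq = 0.2)
  blq <- observation(4, 0.05)
  out <- impute_blq(blq, assay)
  expect_equal(out$concentration, 0.1)
  expect_true(out$blq)

  above <- impute_blq(observation(4, 0.25), assay)
  expect_equal(above$concentration, 0.25)
  expect_false(above$blq)

  other <- impute_blq(observation(4, 0.1), assay_config(loq = 0.5))
  expect_equal(other$concentration, 0.25)

  expect_error(impute_blq(data.frame(time = 1, concentration = -1,
                                     blq = FALSE), assay), "negative")

  # imputation never pushes a concentration above the LOQ
  withr::with_seed(1, {
    raw <- runif(200, 0, 0.4)
    obs <- data.frame(time = 1, concentration = raw, blq = FALSE)
    imp <- impute_blq(obs, assay)
    expect_true(all(imp$concentration[raw < 0.2] <= 0.2))
    expect_true(all(imp$concentration[raw >= 0.2] == raw[raw >= 0.2]))
  })
})

test_that("minimal two-row files read into a one-subject dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV,WT",
               "p1,0,300,.,1,1,40",
               "p1,6,.,2.1,0,0,40"), path)
  ds <- read_pk_dataset(path)
  expect_length(ds$subjects, 1)
  expect_equal(nrow(ds$subjects[[1]]$doses), 1)
  expect_equal(nrow(ds$subjects[[1]]$observations), 1)
  expect_equal(ds$subjects[[1]]$observations$concentration, 2.1)
  expect_equal(ds$subjects[[1]]$weight, 40)
})

test_that("malformed files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,DV,EVID,MDV,WT", "p1,0,.,1,1,40"), path)
  expect_error(read_pk_dataset(path), "mandatory column")

  # observation before any dose
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV,WT",
               "p1,0,.,2.1,0,0,40",
               "p1,2,300,.,1,1,40"), path2)
  expect_error(read_pk_dataset(path2), "precedes")

  # non-monotone event times within subject
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV,WT",
               "p1,10,300,.,1,1,40",
               "p1,2,.,2.1,0,0,40"), path3)
  expect_error(read_pk_dataset(path3), "non-monotone.*p1")
})

test_that("a generated study round-trips through write/read", {
  g <- generate_study(ref_model$pop, ref_model$var, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(g$dataset, path)
  back <- read_pk_dataset(path)
  expect_length(back$subjects, length(g$dataset$subjects))
  for (i in seq_along(back$subjects)) {
    a <- g$dataset$subjects[[i]]; b <- back$subjects[[i]]
    expect_equal(b$id, a$id)
    expect_equal(b$weight, a$weight, tolerance = 1e-8)
    expect_equal(b$age, a$age, tolerance = 1e-8)
    expect_equal(b$sex, a$sex)
    expect_equal(b$setting, a$setting)
    expect_equal(b$covariates, a$covariates)
    expect_equal(b$doses$time, a$doses$time, tolerance = 1e-8)
    expect_equal(b$doses$amount, a$doses$amount)
    expect_equal(b$observations$time, a$observations$time, tolerance = 1e-8)
    # concentrations preserved to at least 4 significant figures
    expect_equal(b$observations$concentration, a$observations$concentration,
                 tolerance = 1e-4)
    expect_equal(b$observations$blq, a$observations$blq)
  }
})

test_that("the outpatient 8 am steady-state convention is prediction-equivalent", {
  s <- make_subject(times = c(6), conc = c(2))
  ind <- scale_parameters(ref_model$pop, s$weight)

  # steady-state-marker representation
  ss_sub <- expand_outpatient_dosing(s, maintenance_dose = 300, interval = 24)
  f_ss <- predict_subject(ref_model$pop, ref_model$var, ss_sub)

  # explicit 14-day history ending at the presumed 8 am dose
  ex_sub <- expand_outpatient_dosing(s, maintenance_dose = 300, interval = 24,
                                     n_prior_days = 14)
  f_ex <- predict_subject(ref_model$pop, ref_model$var, ex_sub)
  expect_equal(f_ss, f_ex, tolerance = 1e-3)

  # inpatients are out of the rule's scope
  s_in <- s; s_in$setting <- "inpatient"
  expect_identical(expand_outpatient_dosing(s_in, 300), s_in)

  expect_error(expand_outpatient_dosing(s), "unknown maintenance dose")
})

test_that("exclusion rules drop flagged samples and empty subjects", {
  g <- generate_study(ref_model$pop, ref_model$var, seed = 6)
  ds <- g$dataset
  n0 <- n_observations(ds)

  # flag one observation of subject 1 and all of subject 2
  ds$subjects[[1]]$observations$reason[1] <- "timing_unknown"
  n2 <- nrow(ds$subjects[[2]]$observations)
  ds$subjects[[2]]$observations$reason <- rep("known_nonadherent", n2)

  out <- apply_exclusions(ds)
  expect_equal(n_observations(out), n0 - 1 - n2)
  expect_false("S02" %in% vapply(out$subjects, `[[`, character(1), "id"))
  expect_true(any(grepl("excluded", out$provenance_log)))

  # idempotence
  out2 <- apply_exclusions(out)
  expect_equal(n_observations(out2), n_observations(out))
  expect_equal(length(out2$subjects), length(out$subjects))

  # no flags: identity
  clean <- apply_exclusions(g$dataset)
  expect_equal(n_observations(clean), n0)
})

test_that("dataset summaries report the study-design quantities", {
  g <- generate_study(ref_model$pop, ref_model$var, seed = 2)
  s <- summary(g$dataset)
  expect_equal(s$n_subjects, 37)
  expect_true(s$samples_range[1] >= 1 && s$samples_range[2] <= 9)
  expect_named(s$covariate_prevalence,
               c("liver_abnormal", "ppi_h2ra", "clarithromycin",
                 "rifampicin", "rifabutin", "orkambi"))
  expect_output(print(s), "TDM samples")
})
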