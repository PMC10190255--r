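test_that("a-priori prediction is self-consistent for an eta = 0 subject", {
  m <- toy_model_2cpt()
  doses <- dose_events(c(0, 8, 16), 1000, 0.5)
  times <- c(7.75, 23.75)
  pars <- typical_parameters(m)
  truth <- predict_concentration(pars, doses, times)$conc
  s <- new_subject("SC", doses = doses,
                   observations = data.frame(time = times, conc = truth))
  s <- with_occasions(s)
  rec <- predict_a_priori(m, s)
  expect_equal(rec$predicted, rec$observed, tolerance = 1e-12)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$occasion, c(1L, 2L))
})

test_that("MAP shrinks to zero when the prior variance vanishes", {
  m <- toy_model_1cpt(omega_cl = 1e-8, omega_v1 = 1e-8)
  s <- toy_subject("shrink", conc = c(25, 24))
  s <- with_occasions(s)
  est <- map_estimate(m, s, data.frame(time = 7.75, conc = 25))
  expect_true(est$converged)
  expect_lt(max(abs(est$eta_hat)), 1e-3)
})

test_that("single-observation MAP matches a 1-D grid-search oracle", {
  m <- new_model_spec(
    name = "cl_only", n_compartments = 1,
    thetas = c(CL = 5, V1 = 30),
    iiv_parameters = "CL", omega = matrix(0.09),
    residual_error = list(main = list(kind = "proportional",
                                      sd_additive = 0,
                                      sd_proportional = 0.2,
                                      variant_label = "main")))
  s <- toy_subject("grid", conc = c(14, 9))
  s <- with_occasions(s)
  cond <- data.frame(time = 7.75, conc = 14)
  est <- map_estimate(m, s, cond)

  # independent brute-force minimization of the same objective on a grid
  grid <- seq(-3, 3, by = 1e-4)
  obj <- vapply(grid, function(eta) {
    pars <- c(CL = 5 * exp(eta), V1 = 30)
    f <- predict_concentration(pars, s$doses, cond$time)$conc
    g2 <- (0.2 * f)^2
    (cond$conc - f)^2 / g2 + log(g2) + eta^2 / 0.09
  }, numeric(1))
  eta_grid <- grid[which.min(obj)]
  expect_equal(unname(est$eta_hat), eta_grid, tolerance = 2e-4)
})

test_that("MAP recovers the true eta when residual noise vanishes", {
  m <- toy_model_1cpt(prop_sd = 1e-6)
  doses <- dose_events(c(0, 8, 16), 1000, 0.5)
  withr::local_seed(31)
  for (i in 1:10) {
    eta_true <- c(rnorm(1, 0, 0.3), rnorm(1, 0, 0.2))
    pars <- individual_parameters(m, eta = eta_true)
    times <- c(2, 5, 7.75)
    obs <- predict_concentration(pars, doses, times)$conc
    s <- new_subject(paste0("R", i), doses = doses,
                     observations = data.frame(time = times, conc = obs))
    est <- map_estimate(m, s, data.frame(time = times, conc = obs))
    expect_lt(max(abs(est$eta_hat - eta_true)), 1e-3)
  }
})

test_that("Bayesian occasion-2 forecast conditions on exactly the occasion-1 trough", {
  m <- toy_model_2cpt(prop_sd = 1e-6)
  doses <- dose_events(c(0, 8, 16), 1000, 0.5)
  eta_true <- c(0.4, -0.2)
  pars <- individual_parameters(m, eta = eta_true)
  times <- c(7.75, 23.75)
  truth <- predict_concentration(pars, doses, times)$conc
  s <- new_subject("BX", doses = doses,
                   observations = data.frame(time = times, conc = truth))
  rec <- predict_bayesian_occasion2(m, s)
  expect_equal(rec$type, "bayesian")
  expect_equal(rec$time, 23.75)
  # noise-free conditioning: forecast lands on the individual truth far more
  # tightly than the population prediction does
  expect_equal(rec$predicted, truth[2], tolerance = 0.02)
  apriori <- predict_concentration(typical_parameters(m), doses, 23.75)$conc
  expect_gt(abs(apriori - truth[2]), 10 * abs(rec$predicted - truth[2]))
})

test_that("the occasion-2 forecast ignores observations after the conditioning sample", {
  m <- toy_model_1cpt()
  doses <- dose_events(c(0, 8, 16), 1000, 0.5)
  s1 <- new_subject("L1", doses = doses,
                    observations = data.frame(time = c(7.75, 23.75),
                                              conc = c(14, 12)))
  s2 <- new_subject("L2", doses = doses,
                    observations = data.frame(time = c(7.75, 23.75),
                                              conc = c(14, 55)))
  r1 <- predict_bayesian_occasion2(m, s1)
  r2 <- predict_bayesian_occasion2(m, s2)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("subjects without an occasion-2 trough are skipped with a message", {
  m <- toy_model_1cpt()
  s <- new_subject("skip", doses = dose_events(0, 1000, 0.5),
                   observations = data.frame(time = 6, conc = 12))
  expect_message(out <- predict_bayesian_occasion2(m, s), "skipped")
  expect_null(out)
})

test_that("a model without IIV forecasts identically to a priori", {
  m <- new_model_spec(
    name = "noiiv", n_compartments = 1,
    thetas = c(CL = 5, V1 = 30),
    residual_error = list(main = list(kind = "proportional",
                                      sd_additive = 0,
                                      sd_proportional = 0.2,
                                      variant_label = "main")))
  s <- toy_subject("NI", conc = c(14, 12))
  s <- with_occasions(s)
  bay <- predict_bayesian_occasion2(m, s)
  ap <- predict_a_priori(m, s)
  expect_equal(bay$predicted, ap$predicted[ap$time == 23.75])
})

test_that("a self-simulated cohort evaluated under its generator has MPE near zero", {
  cs <- generate_cohort(cohort_recipe(n_subjects = 250, seed = 77))
  m <- load_builtin_model("ojeanson_2021")
  recs <- do.call(rbind, lapply(cs, function(s) {
    predict_a_priori(m, impute_missing_covariates(s, m))
  }))
  ci <- mpe_confidence_interval(recs, n_boot = 300, seed = 1)
  expect_lte(ci[1], 0)
  expect_gte(ci[2], 0)
})
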