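test_that("occasions split at dose events and merge unobserved intervals", {
  s <- new_subject(
    "A", doses = dose_events(c(0, 8, 16), 1000, 0.5),
    observations = data.frame(time = c(7.5, 23), conc = c(10, 9)),
    crrt_hours_after_first_dose = 48)
  part <- assign_occasions(s)
  expect_equal(part$occasion, c(1L, 2L))
  # doses at 8 and 16 merged: occasion 2 starts at 8
  expect_equal(part$boundaries$lo, c(0, 8))
})

test_that("one dose with one later observation forms a single occasion", {
  s <- new_subject("B", doses = dose_events(0, 1000, 0.5),
                   observations = data.frame(time = 6, conc = 12))
  part <- assign_occasions(s)
  expect_equal(nrow(part$boundaries), 1)
  expect_equal(part$occasion, 1L)
})

test_that("continuous infusion without bag changes uses midpoint boundaries", {
  s <- new_subject("C", doses = dose_events(0, 6000, 48),
                   observations = data.frame(time = c(10, 30), conc = c(20, 21)),
                   infusion_mode = "CI")
  part <- assign_occasions(s)
  expect_equal(part$occasion, c(1L, 2L))
  expect_equal(part$boundaries$lo, c(0, 20))
})

test_that("pre-dose observations land in pseudo-occasion zero", {
  s <- new_subject("D", doses = dose_events(2, 1000, 0.5),
                   observations = data.frame(time = c(1, 6), conc = c(3, 12)))
  expect_equal(assign_occasions(s)$occasion, c(0L, 1L))
})

test_that("occasion assignment is stable under appending later observations", {
  s <- new_subject(
    "E", doses = dose_events(c(0, 8, 16, 24), 1000, 0.5),
    observations = data.frame(time = c(7.5, 15.5), conc = c(10, 9)))
  first <- assign_occasions(s)$occasion
  s2 <- s
  s2$observations <- rbind(s2$observations,
                           data.frame(time = 31.5, conc = 8, occasion = NA))
  second <- assign_occasions(s2)$occasion
  expect_equal(second[1:2], first)
})

test_that("the inclusion filter encodes both study criteria", {
  ok <- toy_subject("ok")
  one_occ <- new_subject(
    "one_occ", doses = dose_events(0, 1000, 0.5),
    observations = data.frame(time = c(2, 6), conc = c(20, 10)),
    crrt_hours_after_first_dose = 72)
  short_crrt <- toy_subject("short", crrt_h = 23)
  res <- apply_inclusion_filter(list(ok, one_occ, short_crrt))
  expect_length(res$included, 1)
  expect_equal(res$included[[1]]$subject_id, "ok")
  expect_equal(res$excluded$reason[res$excluded$subject_id == "one_occ"],
               "occasions")
  expect_equal(res$excluded$reason[res$excluded$subject_id == "short"],
               "crrt_duration")
})

test_that("residual-diuresis categories map to their lower limits", {
  expect_equal(map_residual_diuresis_category(1), 1000)
  expect_equal(map_residual_diuresis_category(2), 500)
  expect_equal(map_residual_diuresis_category(3), 0)
  expect_equal(map_residual_diuresis_category(c(3, 1)), c(0, 1000))
  expect_error(map_residual_diuresis_category(4), "category")
})

test_that("imputation fills model covariates from model-population medians", {
  s <- toy_subject("imp")
  s$residual_diuresis <- NA_real_
  m <- load_builtin_model("ojeanson_2021")
  s2 <- impute_missing_covariates(s, m)
  expect_equal(s2$residual_diuresis, 845)
  expect_equal(attr(s2, "imputed"), "residual_diuresis")
  # idempotent; present values never overwritten
  s3 <- impute_missing_covariates(s2, m)
  expect_equal(s3$residual_diuresis, 845)
  expect_length(attr(s3, "imputed"), 0)
  s$residual_diuresis <- 300
  expect_equal(impute_missing_covariates(s, m)$residual_diuresis, 300)
  # a different model imputes its own median
  m2 <- load_builtin_model("ulldemolins_2015")
  s$residual_diuresis <- NA_real_
  expect_equal(impute_missing_covariates(s, m2)$residual_diuresis, 500)
  # missing median is an error naming the covariate
  m3 <- m
  m3$population_medians <- numeric()
  expect_error(impute_missing_covariates(s, m3), "residual_diuresis")
})

test_that("Cockcroft-Gault matches hand arithmetic and the female factor", {
  # ((140 - 60) * 77) / (72 * 2.1) = 40.74 mL/min
  expect_equal(egfr_cockcroft_gault(60, 77, 2.1, "male"), 40.74,
               tolerance = 1e-3)
  expect_equal(egfr_cockcroft_gault(60, 77, 2.1, "female") /
                 egfr_cockcroft_gault(60, 77, 2.1, "male"), 0.85)
  expect_error(egfr_cockcroft_gault(60, 77, 0, "male"), "creatinine")
})

test_that("CKD-EPI is monotone decreasing in creatinine for both sexes", {
  scr <- seq(0.4, 9, by = 0.2)
  for (sex in c("male", "female")) {
    e <- egfr_ckdepi(60, scr, sex)
    expect_true(all(diff(e) < 0))
  }
  # sanity: moderate dysfunction lands in a plausible range
  expect_true(egfr_ckdepi(60, 2.1, "male") > 20 &&
                egfr_ckdepi(60, 2.1, "male") < 45)
})

test_that("a cohort round-trips losslessly through the CSV dialects", {
  cs <- generate_cohort(cohort_recipe(n_subjects = 8, seed = 21))
  ev <- withr::local_tempfile(fileext = ".csv")
  cv <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(cs, ev, cv)
  back <- read_pk_dataset(ev, cv)
  expect_length(back, length(cs))
  for (i in seq_along(cs)) {
    expect_equal(back[[i]]$subject_id, cs[[i]]$subject_id)
    expect_equal(back[[i]]$doses, cs[[i]]$doses, ignore_attr = TRUE)
    expect_equal(back[[i]]$observations$conc, cs[[i]]$observations$conc)
    expect_equal(back[[i]]$observations$occasion,
                 cs[[i]]$observations$occasion)
    expect_equal(subject_covariates(back[[i]]), subject_covariates(cs[[i]]))
  }
})
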