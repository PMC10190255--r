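test_that("a minimal spec round-trips through save/load unchanged", {
  m <- new_model_spec(
    name = "mini", n_compartments = 1,
    thetas = c(CL = 5, V1 = 30),
    residual_error = list(main = list(kind = "proportional",
                                      sd_additive = 0,
                                      sd_proportional = 0.2,
                                      variant_label = "main"))
  )
  path <- withr::local_tempfile(fileext = ".json")
  save_model_spec(m, path)
  m2 <- load_model_spec(path)
  expect_equal(m2$thetas, m$thetas)
  expect_equal(m2$n_compartments, m$n_compartments)
  expect_equal(m2$residual_error$main$sd_proportional, 0.2)
  expect_equal(length(m2$covariate_effects), 0)
})

test_that("covariate-effect declaration order survives a round trip", {
  m <- new_model_spec(
    name = "ordered", n_compartments = 1,
    thetas = c(CL = 4, V1 = 30),
    covariate_effects = list(
      list(parameter = "CL", covariate = "residual_diuresis", form = "linear",
           coefficients = 0.001, reference_value = 0),
      list(parameter = "CL", covariate = "total_flow_rate", form = "power",
           coefficients = 0.5, reference_value = 2000)
    ),
    residual_error = list(main = list(kind = "additive", sd_additive = 1,
                                      sd_proportional = 0,
                                      variant_label = "main"))
  )
  path <- withr::local_tempfile(fileext = ".json")
  save_model_spec(m, path)
  m2 <- load_model_spec(path)
  expect_equal(vapply(m2$covariate_effects, `[[`, "", "covariate"),
               c("residual_diuresis", "total_flow_rate"))
  covs <- c(residual_diuresis = 500, total_flow_rate = 3000)
  expect_identical(typical_parameters(m, covs), typical_parameters(m2, covs))
})

test_that("a non-positive-semi-definite omega is rejected", {
  expect_error(
    new_model_spec(
      name = "bad", n_compartments = 1,
      thetas = c(CL = 5, V1 = 30),
      iiv_parameters = c("CL", "V1"),
      omega = matrix(c(0.09, 0.2, 0.2, 0.09), 2, 2),
      residual_error = list(main = list(kind = "proportional",
                                        sd_additive = 0,
                                        sd_proportional = 0.2,
                                        variant_label = "main"))
    ),
    "positive semi-definite"
  )
})

test_that("invalid specs are rejected with the offending field named", {
  re <- list(main = list(kind = "proportional", sd_additive = 0,
                         sd_proportional = 0.2, variant_label = "main"))
  expect_error(new_model_spec("x", 3, c(CL = 5, V1 = 30),
                              residual_error = re), "n_compartments")
  expect_error(new_model_spec("x", 2, c(CL = 5, V1 = 30),
                              residual_error = re), "missing thetas")
  expect_error(new_model_spec("x", 1, c(CL = -5, V1 = 30),
                              residual_error = re), "thetas")
  expect_error(
    new_model_spec("x", 1, c(CL = 5, V1 = 30),
                   covariate_effects = list(list(parameter = "CL",
                                                 covariate = "weight",
                                                 form = "spline",
                                                 coefficients = 1)),
                   residual_error = re),
    "unsupported covariate form")
  expect_error(
    new_model_spec("x", 1, c(CL = 5, V1 = 30),
                   covariate_effects = list(list(parameter = "CL",
                                                 covariate = "weight",
                                                 form = "power",
                                                 coefficients = 1,
                                                 reference_value = 0)),
                   residual_error = re),
    "reference_value")
  expect_error(
    new_model_spec("x", 1, c(CL = 5, V1 = 30),
                   residual_error = list(main = list(kind = "combined",
                                                     sd_additive = 1,
                                                     sd_proportional = 0,
                                                     variant_label = "m"))),
    "combined")
})

test_that("all eight shipped candidate models load and validate", {
  names <- builtin_models()
  expect_length(names, 8)
  for (nm in names) {
    m <- load_builtin_model(nm)
    expect_s3_class(m, "poppk_model")
    expect_true(all(m$thetas > 0))
  }
})

test_that("typical parameters equal thetas when a model has no covariates", {
  m <- load_builtin_model("grensemann_2020")
  expect_identical(typical_parameters(m, c(age = 60)), m$thetas)
})

test_that("a missing required covariate raises a named error", {
  m <- load_builtin_model("ojeanson_2021")
  expect_error(typical_parameters(m, c(age = 60)), "residual_diuresis")
  expect_error(typical_parameters(m, c(residual_diuresis = NA)),
               "residual_diuresis")
})

test_that("eta = 0 reproduces typical parameters bit-for-bit", {
  m <- load_builtin_model("shekar_2014")
  expect_identical(individual_parameters(m, eta = c(0, 0)),
                   typical_parameters(m))
})

test_that("log-normal IIV multiplies parameters by exp(eta)", {
  m <- toy_model_1cpt(cl = 5)
  p <- individual_parameters(m, eta = c(log(2), 0))
  expect_equal(unname(p["CL"]), 10)
  expect_equal(unname(p["V1"]), 30)
  expect_error(individual_parameters(m, eta = 0.1), "length")
})

test_that("the geometric mean of sampled individual CL matches typical CL", {
  m <- load_builtin_model("ojeanson_2021")
  withr::local_seed(42)
  etas <- matrix(rnorm(10000 * 2), ncol = 2) %*% chol(as.matrix(m$omega))
  covs <- c(residual_diuresis = 845)
  cl_typ <- typical_parameters(m, covs)[["CL"]]
  cl_ind <- cl_typ * exp(etas[, 1])
  # geometric mean of a log-normal equals the typical value; MC error ~ 0.3%
  expect_equal(exp(mean(log(cl_ind))), cl_typ, tolerance = 0.01)
})

test_that("categorical-factor effects select the matching level", {
  m <- new_model_spec(
    name = "cat", n_compartments = 1,
    thetas = c(CL = 4, V1 = 30),
    covariate_effects = list(
      list(parameter = "CL", covariate = "dialysis_code",
           form = "categorical-factor",
           coefficients = c(`1` = 1, `2` = 1.3), reference_value = 1)
    ),
    residual_error = list(main = list(kind = "additive", sd_additive = 1,
                                      sd_proportional = 0,
                                      variant_label = "main"))
  )
  expect_equal(typical_parameters(m, c(dialysis_code = 2))[["CL"]], 5.2)
  expect_error(typical_parameters(m, c(dialysis_code = 3)), "level")
})

test_that("YAML is accepted as a convenience spec dialect", {
  spec <- list(
    name = "yml", n_compartments = 1,
    thetas = list(CL = 5, V1 = 30),
    iiv_parameters = list("CL"),
    omega = list(list(0.09)),
    residual_error = list(main = list(kind = "proportional",
                                      sd_additive = 0,
                                      sd_proportional = 0.2,
                                      variant_label = "main"))
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, path)
  m <- load_model_spec(path)
  expect_equal(unname(m$thetas["CL"]), 5)
  expect_equal(as.numeric(m$omega), 0.09)
})
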