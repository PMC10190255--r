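#' Declarative population-PK model specifications
#'
#' A `poppk_model` bundles everything needed to predict meropenem plasma
#' concentrations for a patient: the structural model (1 or 2 compartments in
#' clearance--volume parameterization), typical parameter values (thetas),
#' covariate effects on those parameters, the inter-individual variability
#' (IIV) variance--covariance matrix on the log scale (omega), and one or more
#' residual unexplained variability models (sigma). Candidate models published
#' for critically ill patients on continuous renal replacement therapy ship
#' with the package (see [builtin_models()]); arbitrary user models are loaded
#' from JSON or YAML files with [load_model_spec()].
#'
#' Canonical units throughout: time h, concentration mg/L, amount mg,
#' clearances L/h, volumes L, CRRT flow rates mL/h, residual diuresis mL/24 h.
#'
#' @param name identifier (used in result tables)
#' @param n_compartments 1 or 2
#' @param thetas named numeric vector of typical values; names must include
#'   `CL` and `V1`, plus `Q` and `V2` for two-compartment models
#' @param covariate_effects list of covariate effects, each a list with
#'   elements `parameter`, `covariate`, `form` (one of `"linear"`, `"power"`,
#'   `"proportional-shift"`, `"categorical-factor"`), `coefficients`, and
#'   `reference_value`
#' @param iiv_parameters character vector naming the parameters carrying IIV;
#'   defines the dimension and order of `omega`
#' @param omega symmetric positive semi-definite variance matrix of the
#'   log-normal random effects, one row/column per entry of `iiv_parameters`
#' @param residual_error named list of residual-error variants, each a list
#'   with `kind` (`"additive"`, `"proportional"`, `"combined"`),
#'   `sd_additive` (mg/L), `sd_proportional` (fraction), `variant_label`
#' @param population_medians named numeric vector of covariate medians of the
#'   model's development population, used to impute missing covariates
#' @param label human-readable model name
#' @param theta_units named character vector of units (documentation only)
#' @param provenance free-text citation / transcription note
#' @return an object of class `poppk_model`
#' @export
new_model_spec <- function(name, n_compartments, thetas,
                           covariate_effects = list(),
                           iiv_parameters = character(),
                           omega = matrix(numeric(), 0, 0),
                           residual_error = list(),
                           population_medians = numeric(),
                           label = name, theta_units = NULL,
                           provenance = "") {
  spec <- structure(
    list(
      name = name, label = label,
      n_compartments = as.integer(n_compartments),
      parameterization = "clearance-volume",
      thetas = unlist(thetas),
      theta_units = theta_units,
      covariate_effects = covariate_effects,
      iiv_parameters = as.character(iiv_parameters),
      omega = omega,
      residual_error = residual_error,
      population_medians = unlist(population_medians),
      provenance = provenance
    ),
    class = "poppk_model"
  )
  validate_model_spec(spec)
}

.covariate_forms <- c("linear", "power", "proportional-shift",
                      "categorical-factor")

#' Validate a model specification
#'
#' Checks the structural invariants: compartment count, positivity of thetas,
#' supported covariate-effect forms, finite coefficients, positive reference
#' values for power forms, symmetry and positive semi-definiteness of omega,
#' and well-formed residual-error variants (at least one SD strictly positive;
#' a combined model declares both SDs).
#'
#' @param spec a `poppk_model`
#' @return the validated spec, invisibly unchanged; errors name the offending
#'   field
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "poppk_model"))
  if (!spec$n_compartments %in% c(1L, 2L)) {
    stop("model '", spec$name, "': n_compartments must be 1 or 2")
  }
  req <- if (spec$n_compartments == 2L) c("CL", "V1", "Q", "V2") else c("CL", "V1")
  missing_th <- setdiff(req, names(spec$thetas))
  if (length(missing_th)) {
    stop("model '", spec$name, "': missing thetas: ",
         paste(missing_th, collapse = ", "))
  }
  if (any(!is.finite(spec$thetas)) || any(spec$thetas <= 0)) {
    stop("model '", spec$name, "': all thetas must be finite and > 0")
  }
  for (ce in spec$covariate_effects) {
    for (f in c("parameter", "covariate", "form", "coefficients")) {
      if (is.null(ce[[f]])) {
        stop("model '", spec$name, "': covariate effect lacks field '", f, "'")
      }
    }
    if (!ce$form %in% .covariate_forms) {
      stop("model '", spec$name, "': unsupported covariate form '", ce$form,
           "' (supported: ", paste(.covariate_forms, collapse = ", "), ")")
    }
    if (any(!is.finite(unlist(ce$coefficients)))) {
      stop("model '", spec$name, "': non-finite coefficients for covariate '",
           ce$covariate, "'")
    }
    if (ce$form == "power" &&
        (is.null(ce$reference_value) || ce$reference_value <= 0)) {
      stop("model '", spec$name, "': power form for covariate '",
           ce$covariate, "' requires reference_value > 0")
    }
    if (!ce$parameter %in% names(spec$thetas)) {
      stop("model '", spec$name, "': covariate effect targets unknown ",
           "parameter '", ce$parameter, "'")
    }
  }
  k <- length(spec$iiv_parameters)
  om <- spec$omega
  if (k > 0) {
    om <- as.matrix(om)
    if (!all(dim(om) == c(k, k))) {
      stop("model '", spec$name, "': omega dimension ", nrow(om), "x", ncol(om),
           " does not match ", k, " IIV parameter(s)")
    }
    if (max(abs(om - t(om))) > 1e-10) {
      stop("model '", spec$name, "': omega is not symmetric")
    }
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("model '", spec$name, "': omega is not positive semi-definite ",
           "(smallest eigenvalue ", format(min(ev)), ")")
    }
  }
  if (length(spec$residual_error) == 0) {
    stop("model '", spec$name, "': at least one residual-error variant required")
  }
  for (vn in names(spec$residual_error)) {
    re <- spec$residual_error[[vn]]
    if (!re$kind %in% c("additive", "proportional", "combined")) {
      stop("model '", spec$name, "': residual error '", vn,
           "': unknown kind '", re$kind, "'")
    }
    sa <- re$sd_additive %||% 0
    sp <- re$sd_proportional %||% 0
    if (sa < 0 || sp < 0 || (sa == 0 && sp == 0)) {
      stop("model '", spec$name, "': residual error '", vn,
           "': needs at least one SD strictly positive, none negative")
    }
    if (re$kind == "combined" && (sa == 0 || sp == 0)) {
      stop("model '", spec$name, "': residual error '", vn,
           "': combined kind requires both sd_additive and sd_proportional")
    }
  }
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a model specification from JSON or YAML
#'
#' The file format mirrors the `poppk_model` fields; `omega` is a nested
#' array (row-major). YAML is accepted as a convenience dialect, chosen by
#' file extension (`.yaml`/`.yml`).
#'
#' @param path path to a `.json`, `.yaml`, or `.yml` spec file
#' @return validated `poppk_model`
#' @seealso [save_model_spec()], [builtin_models()]
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  }
  omega <- raw$omega
  if (is.list(omega)) omega <- do.call(rbind, lapply(omega, unlist))
  omega <- if (is.null(omega) || length(omega) == 0) {
    matrix(numeric(), 0, 0)
  } else {
    as.matrix(omega)
  }
  ce <- raw$covariate_effects
  if (is.data.frame(ce)) {
    ce <- lapply(seq_len(nrow(ce)), function(i) as.list(ce[i, , drop = FALSE]))
    ce <- lapply(ce, function(x) {
      x$coefficients <- unlist(x$coefficients)
      x
    })
  }
  if (is.null(ce)) ce <- list()
  res <- raw$residual_error
  new_model_spec(
    name = raw$name,
    n_compartments = raw$n_compartments,
    thetas = raw$thetas,
    covariate_effects = ce,
    iiv_parameters = raw$iiv_parameters %||% character(),
    omega = omega,
    residual_error = res,
    population_medians = raw$population_medians %||% numeric(),
    label = raw$label %||% raw$name,
    theta_units = unlist(raw$theta_units),
    provenance = raw$provenance %||% ""
  )
}

#' Save a model specification to JSON
#'
#' Writes the spec so that [load_model_spec()] reproduces it exactly,
#' including the declaration order of covariate effects.
#'
#' @param spec a `poppk_model`
#' @param path output path (`.json`)
#' @return `path`, invisibly
#' @export
save_model_spec <- function(spec, path) {
  out <- unclass(spec)
  out$omega <- if (length(spec$iiv_parameters)) {
    lapply(seq_len(nrow(spec$omega)), function(i) spec$omega[i, ])
  } else {
    list()
  }
  out$thetas <- as.list(out$thetas)
  out$population_medians <- as.list(out$population_medians)
  out$theta_units <- as.list(out$theta_units)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' List or load the shipped candidate models
#'
#' Eight published meropenem models for adult CRRT patients are shipped as
#' JSON spec files under `inst/models/`. Each file's `provenance` field
#' records what was transcribed from its source publication and which
#' secondary parameters were set to representative values.
#'
#' @return `builtin_models()`: character vector of model names.
#' @export
builtin_models <- function() {
  files <- list.files(system.file("models", package = "crrtmipd"),
                      pattern = "\\.json$")
  sort(sub("\\.json$", "", files))
}

#' @rdname builtin_models
#' @param name one of the names returned by `builtin_models()`
#' @return `load_builtin_model()`: a validated `poppk_model`.
#' @export
load_builtin_model <- function(name) {
  path <- system.file("models", paste0(name, ".json"), package = "crrtmipd")
  if (path == "") {
    stop("no built-in model '", name, "'; available: ",
         paste(builtin_models(), collapse = ", "))
  }
  load_model_spec(path)
}

#' @export
print.poppk_model <- function(x, ...) {
  cat("<poppk_model> ", x$label, " (", x$n_compartments, "-compartment)\n",
      sep = "")
  cat("  thetas: ",
      paste(names(x$thetas), signif(x$thetas, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(x$covariate_effects)) {
    for (ce in x$covariate_effects) {
      cat("  covariate: ", ce$covariate, " -> ", ce$parameter,
          " [", ce$form, "]\n", sep = "")
    }
  }
  cat("  IIV on: ", paste(x$iiv_parameters, collapse = ", "),
      "; residual variants: ", paste(names(x$residual_error), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Apply one covariate effect to a scalar parameter value.
.apply_covariate_effect <- function(value, ce, cov_value, model_name) {
  co <- unlist(ce$coefficients)
  ref <- ce$reference_value %||% 0
  switch(ce$form,
    "linear" = value + co[[1]] * (cov_value - ref),
    "power" = value * (cov_value / ref)^co[[1]],
    "proportional-shift" = value * (1 + co[[1]] * (cov_value - ref)),
    "categorical-factor" = {
      lev <- as.character(cov_value)
      if (!lev %in% names(co)) {
        stop("model '", model_name, "': no factor for level '", lev,
             "' of covariate '", ce$covariate, "'")
      }
      value * co[[lev]]
    },
    stop("unsupported covariate form: ", ce$form)
  )
}

#' Typical (population) PK parameters for a covariate vector
#'
#' Applies each covariate effect to its theta in declaration order and
#' returns the typical individual's parameters. This is the deterministic
#' fixed-effect prediction; random effects enter via
#' [individual_parameters()].
#'
#' @param model a `poppk_model`
#' @param covariates named vector/list of covariate values (canonical units)
#' @return named numeric vector (`CL`, `V1`, and for two-compartment models
#'   `Q`, `V2`), all strictly positive
#' @examples
#' m <- load_builtin_model("ojeanson_2021")
#' typical_parameters(m, c(residual_diuresis = 0))["CL"]  # 5.78 L/h
#' @export
typical_parameters <- function(model, covariates = numeric()) {
  stopifnot(inherits(model, "poppk_model"))
  covariates <- unlist(covariates)
  pars <- model$thetas
  for (ce in model$covariate_effects) {
    if (!ce$covariate %in% names(covariates) ||
        is.na(covariates[[ce$covariate]])) {
      stop("model '", model$name, "': covariate '", ce$covariate,
           "' is required but missing (impute before prediction)")
    }
    pars[[ce$parameter]] <- .apply_covariate_effect(
      pars[[ce$parameter]], ce, covariates[[ce$covariate]], model$name)
  }
  if (any(pars <= 0)) {
    stop("model '", model$name, "': covariate effects drove a parameter ",
         "non-positive (", paste(names(pars)[pars <= 0], collapse = ", "), ")")
  }
  pars
}

#' Individual PK parameters from typical values and random effects
#'
#' IIV is log-normal multiplicative: `parameter = typical * exp(eta)` for
#' every parameter listed in the model's `iiv_parameters`; `eta = 0`
#' reproduces [typical_parameters()] exactly.
#'
#' @inheritParams typical_parameters
#' @param eta numeric random-effect vector, same length and order as
#'   `model$iiv_parameters`
#' @return named numeric parameter vector
#' @export
individual_parameters <- function(model, covariates = numeric(),
                                  eta = numeric()) {
  k <- length(model$iiv_parameters)
  if (length(eta) != k) {
    stop("model '", model$name, "': eta has length ", length(eta),
         " but omega dimension is ", k)
  }
  pars <- typical_parameters(model, covariates)
  if (k > 0) {
    pars[model$iiv_parameters] <- pars[model$iiv_parameters] * exp(eta)
  }
  pars
}

# Covariates referenced by a model's effects, in declaration order.
model_covariates <- function(model) {
  unique(vapply(model$covariate_effects, `[[`, "", "covariate"))
}
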