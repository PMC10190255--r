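#' Dose events
#'
#' A dosing history is a data frame with one row per zero-order input event:
#' `start_time` (h), `amount` (mg), `duration` (h, > 0). Intermittent
#' infusions use short durations (default 0.5 h for meropenem); a continuous
#' infusion is simply one long event per bag or rate change -- there is no
#' special-cased mode, both flow through the same superposition code path.
#'
#' @param start_time numeric vector, h
#' @param amount numeric vector, mg (> 0)
#' @param duration numeric vector, h (> 0); recycled
#' @return data.frame sorted by `start_time`
#' @export
dose_events <- function(start_time, amount, duration = 0.5) {
  if (length(start_time) == 0) {
    return(data.frame(start_time = numeric(), amount = numeric(),
                      duration = numeric()))
  }
  d <- data.frame(start_time = start_time, amount = amount,
                  duration = duration)
  if (any(d$amount <= 0)) stop("dose amounts must be > 0")
  if (any(d$duration <= 0)) stop("infusion durations must be > 0")
  d[order(d$start_time), , drop = FALSE]
}

# Macro-constants of the disposition model: exponents (lambda) and central
# unit-bolus coefficients (coef, summing to 1/V1 * c(A, B)).
.macro_constants <- function(params) {
  cl <- params[["CL"]]; v1 <- params[["V1"]]
  k10 <- cl / v1
  if ("Q" %in% names(params) && !is.na(params[["Q"]])) {
    q <- params[["Q"]]; v2 <- params[["V2"]]
    k12 <- q / v1; k21 <- q / v2
    s <- k10 + k12 + k21
    p <- k10 * k21
    disc <- s^2 - 4 * p
    if (disc < (1e-12 * s^2)) {
      # degenerate (alpha == beta): perturb k21 slightly so the
      # bi-exponential form stays well-defined
      warning("near-degenerate disposition eigenvalues; ",
              "perturbing k21 by 1e-6 relative", call. = FALSE)
      k21 <- k21 * (1 + 1e-6)
      s <- k10 + k12 + k21
      p <- k10 * k21
      disc <- s^2 - 4 * p
    }
    rt <- sqrt(disc)
    alpha <- (s + rt) / 2
    beta <- (s - rt) / 2
    a <- (alpha - k21) / (alpha - beta)
    b <- (k21 - beta) / (alpha - beta)
    list(lambda = c(alpha, beta), coef = c(a, b) / v1)
  } else {
    list(lambda = k10, coef = 1 / v1)
  }
}

# Central concentration (mg/L) at `times` for parameter vector `params`
# and a dose-event data frame. Exact analytic zero-order-input solution,
# superposed across doses; numeric-vector hot path.
.predict_conc <- function(params, doses, times) {
  conc <- numeric(length(times))
  if (is.null(doses) || nrow(doses) == 0) return(conc)
  mc <- .macro_constants(params)
  for (i in seq_len(nrow(doses))) {
    tt <- times - doses$start_time[i]
    tau <- doses$duration[i]
    r0 <- doses$amount[i] / tau
    on <- tt > 0
    if (!any(on)) next
    t_on <- tt[on]
    contrib <- numeric(length(t_on))
    for (m in seq_along(mc$lambda)) {
      lam <- mc$lambda[m]
      cf <- r0 * mc$coef[m] / lam
      during <- t_on <= tau
      contrib[during] <- contrib[during] + cf * (1 - exp(-lam * t_on[during]))
      after <- !during
      if (any(after)) {
        contrib[after] <- contrib[after] +
          cf * (1 - exp(-lam * tau)) * exp(-lam * (t_on[after] - tau))
      }
    }
    conc[on] <- conc[on] + contrib
  }
  conc
}

#' Predict noise-free plasma concentrations
#'
#' Exact closed-form solution of the 1- or 2-compartment disposition model
#' with zero-order (infusion) input, superposed over an arbitrary dosing
#' history. The solution is linear in dose amount and additive over dose
#' events; for a constant-rate infusion the concentration approaches
#' `rate / CL` at steady state.
#'
#' @param params named numeric vector with `CL` (L/h), `V1` (L) and, for a
#'   two-compartment model, `Q` (L/h), `V2` (L)
#' @param doses data.frame from [dose_events()] (may have zero rows)
#' @param times numeric vector of evaluation times (h, >= 0)
#' @return data.frame `time`, `conc` (mg/L, central compartment)
#' @examples
#' p <- c(CL = 5, V1 = 30)
#' ci <- dose_events(0, 125 * 1000, duration = 1000)  # 125 mg/h
#' tail(predict_concentration(p, ci, c(1, 10, 500))$conc, 1)  # ~ 25 mg/L
#' @export
predict_concentration <- function(params, doses, times) {
  if (any(times < 0)) stop("times must be >= 0")
  data.frame(time = times, conc = .predict_conc(params, doses, times))
}

# sd of the residual-error model at predicted value f (vectorized)
.residual_sd <- function(re, f) {
  sa <- re$sd_additive %||% 0
  sp <- re$sd_proportional %||% 0
  sqrt(sa^2 + (sp * f)^2)
}

#' Simulate observed concentrations under a model's residual-error variant
#'
#' Draws `y = f * (1 + eps_prop) + eps_add` with centered normal errors of
#' the declared SDs. Negative draws are truncated at 0 and counted in the
#' `n_truncated` attribute.
#'
#' @param model a `poppk_model` (supplies the residual-error variants)
#' @param params individual parameter vector (see [individual_parameters()])
#' @param doses data.frame of dose events
#' @param times observation times (h)
#' @param error_variant name of the residual-error variant; defaults to the
#'   model's first variant
#' @return numeric vector of simulated concentrations (mg/L), attribute
#'   `n_truncated`
#' @export
simulate_observations <- function(model, params, doses, times,
                                  error_variant = NULL) {
  re <- .get_error_variant(model, error_variant)
  f <- .predict_conc(params, doses, times)
  sa <- re$sd_additive %||% 0
  sp <- re$sd_proportional %||% 0
  n <- length(f)
  y <- f * (1 + if (sp > 0) stats::rnorm(n, 0, sp) else 0) +
    (if (sa > 0) stats::rnorm(n, 0, sa) else 0)
  ntr <- sum(y < 0)
  y[y < 0] <- 0
  attr(y, "n_truncated") <- ntr
  y
}

.get_error_variant <- function(model, error_variant) {
  if (is.null(error_variant)) error_variant <- names(model$residual_error)[1]
  re <- model$residual_error[[error_variant]]
  if (is.null(re)) {
    stop("model '", model$name, "': unknown residual-error variant '",
         error_variant, "'; available: ",
         paste(names(model$residual_error), collapse = ", "))
  }
  re
}

# One multivariate-normal draw matrix (n x k) via Cholesky; omega may be
# singular PSD, in which case a small ridge is added.
.rmvnorm <- function(n, omega) {
  k <- nrow(omega)
  if (k == 0) return(matrix(numeric(), n, 0))
  ch <- tryCatch(chol(omega), error = function(e) {
    chol(omega + diag(1e-8 * max(diag(omega), 1e-8), k))
  })
  matrix(stats::rnorm(n * k), n, k) %*% ch
}
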