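#' A-priori (population) predictions for one subject
#'
#' Predicts every observed concentration from the subject's covariates alone
#' (random effects at zero, no residual noise), the prediction used to judge
#' models for initial-dose selection before any drug level is available.
#'
#' @param model a `poppk_model`
#' @param subject a `pk_subject` with complete model covariates (see
#'   [impute_missing_covariates()])
#' @return data.frame of prediction records: `subject_id`, `time`,
#'   `occasion`, `observed`, `predicted`, `type = "a_priori"`
#' @export
predict_a_priori <- function(model, subject) {
  pars <- typical_parameters(model, subject_covariates(subject))
  obs <- subject$observations
  data.frame(
    subject_id = subject$subject_id,
    time = obs$time,
    occasion = obs$occasion,
    observed = obs$conc,
    predicted = .predict_conc(pars, subject$doses, obs$time),
    type = "a_priori",
    center = subject$center,
    infusion_mode = subject$infusion_mode,
    stringsAsFactors = FALSE
  )
}

# fixed deterministic jitter starts (no RNG involvement): scaled quantile
# lattice over the prior SDs
.map_starts <- function(omega, n_extra = 4) {
  k <- nrow(omega)
  sds <- sqrt(diag(omega))
  starts <- list(rep(0, k))
  for (j in seq_len(n_extra)) {
    u <- ((seq_len(k) - 1 + j * 2) %% 7 + 1) / 8
    starts[[j + 1]] <- stats::qnorm(u) * sds * (if (j %% 2) 1 else -1)
  }
  starts
}

#' MAP (maximum a posteriori) estimate of a subject's random effects
#'
#' Minimizes the standard extended-least-squares MAP objective
#' \deqn{\sum_j \left[ \frac{(y_j - f_j(\eta))^2}{g_j^2} + \log g_j^2 \right]
#'   + \eta^T \Omega^{-1} \eta}
#' with \eqn{g_j^2 = \sigma_{add}^2 + \sigma_{prop}^2 f_j^2}. Optimization is
#' a fixed deterministic multistart (eta = 0 plus 4 jittered starts) of a
#' derivative-free/quasi-Newton hybrid, so the estimate is reproducible
#' bit-for-bit given identical inputs.
#'
#' @param model a `poppk_model` with at least one IIV parameter
#' @param subject a `pk_subject`
#' @param conditioning_obs data.frame `time`, `conc`: the observations the
#'   posterior is conditioned on (nonempty)
#' @param error_variant residual-error variant name (default: first)
#' @return list with `eta_hat` (named by IIV parameter), `objective_value`,
#'   `converged`, `n_restarts_used`
#' @export
map_estimate <- function(model, subject, conditioning_obs,
                         error_variant = NULL) {
  if (is.null(conditioning_obs) || nrow(conditioning_obs) == 0) {
    stop("MAP estimation needs at least one conditioning observation")
  }
  k <- length(model$iiv_parameters)
  re <- .get_error_variant(model, error_variant)
  covs <- subject_covariates(subject)
  typ <- typical_parameters(model, covs)
  if (k == 0) {
    return(list(eta_hat = numeric(), objective_value = NA_real_,
                converged = TRUE, n_restarts_used = 0L))
  }
  om <- as.matrix(model$omega)
  om_inv <- tryCatch(chol2inv(chol(om)), error = function(e) {
    warning("omega not invertible; ridge-repaired", call. = FALSE)
    chol2inv(chol(om + diag(1e-8 * max(diag(om)), k)))
  })
  y <- conditioning_obs$conc
  t_obs <- conditioning_obs$time
  sa2 <- (re$sd_additive %||% 0)^2
  sp2 <- (re$sd_proportional %||% 0)^2
  doses <- subject$doses
  iiv <- model$iiv_parameters
  objective <- function(eta) {
    pars <- typ
    pars[iiv] <- pars[iiv] * exp(eta)
    f <- .predict_conc(pars, doses, t_obs)
    g2 <- sa2 + sp2 * f^2
    g2 <- pmax(g2, 1e-12)
    sum((y - f)^2 / g2 + log(g2)) + drop(eta %*% om_inv %*% eta)
  }
  starts <- .map_starts(om)
  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    fit <- if (k == 1) {
      sd1 <- sqrt(om[1, 1])
      stats::optim(st, function(e) objective(e), method = "Brent",
                   lower = -10 * max(sd1, 0.1), upper = 10 * max(sd1, 0.1),
                   control = list(reltol = 1e-12))
    } else {
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (k > 1) {
    # quasi-Newton polish from the best simplex solution
    polish <- tryCatch(
      stats::optim(best$par, objective, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value + 1e-8) best <- polish
  }
  eta_hat <- best$par
  names(eta_hat) <- iiv
  converged <- best$convergence == 0
  if (!converged) {
    warning("MAP estimation did not converge for subject '",
            subject$subject_id, "' (model '", model$name,
            "'); best-found eta returned", call. = FALSE)
  }
  list(eta_hat = eta_hat, objective_value = best$value,
       converged = converged, n_restarts_used = n_used)
}

# last observation of an occasion = operational trough
.occasion_trough <- function(subject, occasion) {
  obs <- subject$observations
  sel <- obs[!is.na(obs$occasion) & obs$occasion == occasion, , drop = FALSE]
  if (nrow(sel) == 0) return(NULL)
  sel[which.max(sel$time), , drop = FALSE]
}

#' Bayesian forecast of the second-occasion trough from one TDM sample
#'
#' Mirrors the single-sample real-world forecasting scenario: the random
#' effects are MAP-conditioned on exactly the last measured concentration of
#' the first occasion, and the trough of the second occasion (its last
#' measured concentration) is predicted with the resulting individual
#' parameters. Observations after the conditioning sample play no role, so
#' no future information leaks into the forecast.
#'
#' @inheritParams map_estimate
#' @return one-row data.frame of the occasion-2 trough prediction record
#'   (`type = "bayesian"`), or `NULL` with a message when the subject lacks
#'   an occasion-2 trough
#' @export
predict_bayesian_occasion2 <- function(model, subject, error_variant = NULL) {
  if (any(is.na(subject$observations$occasion))) {
    subject <- with_occasions(subject)
  }
  cond <- .occasion_trough(subject, 1L)
  target <- .occasion_trough(subject, 2L)
  if (is.null(cond) || is.null(target)) {
    message("subject '", subject$subject_id,
            "' skipped: no occasion-1 sample or occasion-2 trough")
    return(NULL)
  }
  est <- map_estimate(model, subject, cond[, c("time", "conc")],
                      error_variant = error_variant)
  pars <- individual_parameters(model, subject_covariates(subject),
                                est$eta_hat)
  data.frame(
    subject_id = subject$subject_id,
    time = target$time,
    occasion = 2L,
    observed = target$conc,
    predicted = .predict_conc(pars, subject$doses, target$time),
    type = "bayesian",
    center = subject$center,
    infusion_mode = subject$infusion_mode,
    stringsAsFactors = FALSE
  )
}
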