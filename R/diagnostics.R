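#' Normalized prediction distribution errors (NPDE)
#'
#' For each subject, `n_simulations` replicate observation vectors are
#' simulated under the full model (log-normal IIV plus the declared residual
#' error, untruncated so the Gaussian decorrelation theory applies). The
#' observed and simulated vectors are decorrelated with the empirical
#' simulated mean and the lower-triangular Cholesky square root of the
#' simulated covariance; the prediction discrepancy `pd` of each observation
#' is the fraction of decorrelated simulations falling below the decorrelated
#' observation, clamped to `[1/(2K), 1 - 1/(2K)]`, and mapped through the
#' standard-normal quantile. Under a correct model the NPDE are standard
#' normal; the summary reports the mean with a two-sided t-test against 0 and
#' the variance with a two-sided chi-square test against 1 (the
#' Fisher-variance check), plus a global Shapiro--Wilk p-value.
#'
#' @param model a `poppk_model`
#' @param subjects list of `pk_subject` with occasions assigned
#' @param n_simulations replicate count per subject (>= 100)
#' @param seed integer RNG seed
#' @param error_variant residual-error variant (default: first)
#' @return list of class `npde_result`: `npde` (one value per observation,
#'   dataset order), `mean_stat`, `mean_test_p`, `variance_stat`,
#'   `variance_test_p`, `shapiro_p`, `n_simulations`
#' @export
compute_npde <- function(model, subjects, n_simulations = 1000, seed = 1,
                         error_variant = NULL) {
  if (n_simulations < 100) stop("n_simulations must be >= 100")
  if (length(subjects) == 0) stop("empty dataset")
  re <- .get_error_variant(model, error_variant)
  sa <- re$sd_additive %||% 0
  sp <- re$sd_proportional %||% 0
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  k <- n_simulations
  npde_all <- list()
  for (s in subjects) {
    covs <- subject_covariates(s)
    t_obs <- s$observations$time
    n_i <- length(t_obs)
    y_obs <- s$observations$conc
    etas <- .rmvnorm(k, as.matrix(model$omega))
    sims <- matrix(0, k, n_i)
    typ <- typical_parameters(model, covs)
    iiv <- model$iiv_parameters
    for (r in seq_len(k)) {
      pars <- typ
      if (length(iiv)) pars[iiv] <- pars[iiv] * exp(etas[r, ])
      f <- .predict_conc(pars, s$doses, t_obs)
      sims[r, ] <- f * (1 + if (sp > 0) stats::rnorm(n_i, 0, sp) else 0) +
        (if (sa > 0) stats::rnorm(n_i, 0, sa) else 0)
    }
    m <- colMeans(sims)
    v <- stats::cov(sims)
    ch <- tryCatch(t(chol(v)), error = function(e) {
      warning("singular simulated covariance; ridge-regularized",
              call. = FALSE)
      t(chol(v + diag(1e-8 * max(diag(v)), n_i)))
    })
    y_star <- forwardsolve(ch, y_obs - m)
    sim_star <- t(forwardsolve(ch, t(sims) - m))
    pd <- vapply(seq_len(n_i),
                 function(j) mean(sim_star[, j] < y_star[j]), numeric(1))
    pd <- pmin(pmax(pd, 1 / (2 * k)), 1 - 1 / (2 * k))
    npde_all[[length(npde_all) + 1L]] <- stats::qnorm(pd)
  }
  npde <- unlist(npde_all)
  n <- length(npde)
  tt <- if (n >= 2) stats::t.test(npde, mu = 0) else list(p.value = NA_real_)
  s2 <- stats::var(npde)
  var_p <- if (n >= 2) {
    chi <- (n - 1) * s2  # against unit variance
    min(1, 2 * min(stats::pchisq(chi, n - 1),
                   stats::pchisq(chi, n - 1, lower.tail = FALSE)))
  } else {
    NA_real_
  }
  sw <- if (n < 3) NA_real_ else if (n <= 5000) {
    stats::shapiro.test(npde)$p.value
  } else {
    stats::shapiro.test(sample(npde, 5000))$p.value
  }
  structure(
    list(npde = npde, mean_stat = mean(npde),
         mean_test_p = tt$p.value, variance_stat = s2,
         variance_test_p = var_p, shapiro_p = sw,
         n_simulations = k),
    class = "npde_result"
  )
}

#' @export
print.npde_result <- function(x, ...) {
  cat("<npde_result> n =", length(x$npde), "observations,",
      x$n_simulations, "simulations\n")
  cat(sprintf("  mean %.3f (t-test p = %.3g); variance %.3f (chi-sq p = %.3g); Shapiro-Wilk p = %.3g\n",
              x$mean_stat, x$mean_test_p, x$variance_stat, x$variance_test_p,
              x$shapiro_p))
  invisible(x)
}

# binning variable: time after most recent dose start (II) or time since
# infusion start (CI / within a long zero-order event)
.time_after_dose <- function(subject) {
  obs_t <- subject$observations$time
  starts <- sort(subject$doses$start_time)
  vapply(obs_t, function(t) {
    prev <- starts[starts <= t]
    if (length(prev) == 0) t else t - max(prev)
  }, numeric(1))
}

#' Prediction-corrected visual predictive check (pcVPC)
#'
#' Observations and simulated replicates are rescaled by the ratio of the
#' bin-median population prediction to each record's own population
#' prediction, removing dose and covariate heterogeneity before percentile
#' comparison. Records are binned on time after the most recent dose
#' (equivalently, time since infusion start for continuous infusion), with
#' quantile-spaced edges by default, and strata (e.g. infusion modes) are
#' processed independently.
#'
#' @param model a `poppk_model`
#' @param subjects list of `pk_subject`
#' @param n_simulations replicate datasets (>= 200)
#' @param bins integer number of quantile-spaced bins, or a numeric vector
#'   of strictly increasing bin edges
#' @param stratify_by subject field used for stratification
#'   (`"infusion_mode"`, `"center"`, or `NULL` for none)
#' @param seed integer RNG seed
#' @param min_bin_n bins with fewer observations are dropped with a warning
#' @param error_variant residual-error variant (default: first)
#' @return data.frame with one row per stratum x bin: `stratum`, `bin_lo`,
#'   `bin_hi`, `n_obs`, observed percentiles `obs_p5`, `obs_p50`, `obs_p95`,
#'   and simulated 95 % band edges `sim_p5_lo/hi`, `sim_p50_lo/hi`,
#'   `sim_p95_lo/hi`
#' @export
compute_pcvpc <- function(model, subjects, n_simulations = 500, bins = 8,
                          stratify_by = "infusion_mode", seed = 1,
                          min_bin_n = 3, error_variant = NULL) {
  if (n_simulations < 200) stop("n_simulations must be >= 200")
  re <- .get_error_variant(model, error_variant)
  sa <- re$sd_additive %||% 0
  sp <- re$sd_proportional %||% 0
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # per-record population predictions and binning variable
  rec <- do.call(rbind, lapply(subjects, function(s) {
    pars <- typical_parameters(model, subject_covariates(s))
    data.frame(
      subject = s$subject_id,
      tad = .time_after_dose(s),
      obs = s$observations$conc,
      pred = .predict_conc(pars, s$doses, s$observations$time),
      stratum = if (is.null(stratify_by)) "all" else
        as.character(s[[stratify_by]]),
      stringsAsFactors = FALSE
    )
  }))

  # simulate replicate observation matrices once (rows = records)
  sim_mat <- matrix(0, nrow(rec), n_simulations)
  row0 <- 0
  for (s in subjects) {
    covs <- subject_covariates(s)
    typ <- typical_parameters(model, covs)
    iiv <- model$iiv_parameters
    t_obs <- s$observations$time
    n_i <- length(t_obs)
    etas <- .rmvnorm(n_simulations, as.matrix(model$omega))
    for (r in seq_len(n_simulations)) {
      pars <- typ
      if (length(iiv)) pars[iiv] <- pars[iiv] * exp(etas[r, ])
      f <- .predict_conc(pars, s$doses, t_obs)
      y <- f * (1 + if (sp > 0) stats::rnorm(n_i, 0, sp) else 0) +
        (if (sa > 0) stats::rnorm(n_i, 0, sa) else 0)
      sim_mat[row0 + seq_len(n_i), r] <- pmax(y, 0)
    }
    row0 <- row0 + n_i
  }

  probs <- c(0.05, 0.5, 0.95)
  out <- list()
  for (st in unique(rec$stratum)) {
    idx <- which(rec$stratum == st)
    tad <- rec$tad[idx]
    edges <- if (length(bins) == 1) {
      e <- unique(stats::quantile(tad, probs = seq(0, 1, length.out = bins + 1),
                                  type = 7))
      e[length(e)] <- e[length(e)] + 1e-9
      e
    } else {
      if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
      bins
    }
    bin_id <- findInterval(tad, edges, rightmost.closed = FALSE)
    for (b in seq_len(length(edges) - 1)) {
      in_bin <- idx[bin_id == b]
      if (length(in_bin) < min_bin_n) {
        if (length(in_bin) > 0) {
          warning("dropping pcVPC bin [", signif(edges[b], 3), ", ",
                  signif(edges[b + 1], 3), ") in stratum '", st,
                  "': only ", length(in_bin), " observation(s)",
                  call. = FALSE)
        }
        next
      }
      pred_bin <- rec$pred[in_bin]
      pc_factor <- stats::median(pred_bin) / pred_bin
      pc_obs <- rec$obs[in_bin] * pc_factor
      obs_q <- stats::quantile(pc_obs, probs, type = 7)
      # percentile of each replicate, then band across replicates
      rep_q <- apply(sim_mat[in_bin, , drop = FALSE] * pc_factor, 2,
                     stats::quantile, probs = probs, type = 7)
      band <- apply(rep_q, 1, stats::quantile, probs = c(0.025, 0.975),
                    type = 7)
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, bin_lo = edges[b], bin_hi = edges[b + 1],
        n_obs = length(in_bin),
        obs_p5 = obs_q[[1]], obs_p50 = obs_q[[2]], obs_p95 = obs_q[[3]],
        sim_p5_lo = band[1, 1], sim_p5_hi = band[2, 1],
        sim_p50_lo = band[1, 2], sim_p50_hi = band[2, 2],
        sim_p95_lo = band[1, 3], sim_p95_hi = band[2, 3],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Goodness-of-fit table: population predictions versus observations
#'
#' @param records prediction-record data.frame (see [predict_a_priori()])
#' @return tidy data.frame `subject_id`, `time`, `observed`, `predicted`,
#'   plus any stratum columns present (`center`, `infusion_mode`), ready for
#'   identity-line plotting
#' @export
gof_table <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no records")
  keep <- intersect(
    c("subject_id", "time", "observed", "predicted", "center",
      "infusion_mode"),
    names(records))
  records[, keep, drop = FALSE]
}
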