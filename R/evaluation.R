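#' Symmetric relative prediction error
#'
#' The per-sample prediction error uses the mean of predicted and observed as
#' denominator,
#' \deqn{PE = \frac{c_{pred} - c_{obs}}{(c_{pred} + c_{obs})/2},}
#' which is antisymmetric under swapping the two concentrations, scale-free,
#' and bounded in (-2, 2) for positive inputs (so a vanishing observation
#' yields +200 %). Pairs with `c_pred + c_obs <= 0` are undefined and
#' returned as `NA` (callers drop and count them).
#'
#' @param c_pred,c_obs predicted and observed concentrations (mg/L)
#' @return numeric vector of fractional errors (not yet in percent)
#' @examples
#' prediction_error(12, 8)  # 0.4
#' @export
prediction_error <- function(c_pred, c_obs) {
  denom <- (c_pred + c_obs) / 2
  pe <- (c_pred - c_obs) / denom
  pe[denom <= 0] <- NA_real_
  pe
}

.pe_from_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no prediction records supplied")
  }
  pe <- prediction_error(records$predicted, records$observed)
  pe[!is.na(pe)]
}

#' Median prediction error (accuracy) and median absolute prediction error
#' (precision)
#'
#' `mpe()` is the median of the per-record symmetric prediction errors times
#' 100; `mape()` the median of their absolute values times 100. Both use R's
#' standard median convention (mean of the two central order statistics for
#' even counts) and are invariant to record order and to uniform rescaling of
#' all concentrations. Records with undefined PE are dropped.
#'
#' @param records data.frame with columns `predicted` and `observed` (one
#'   row per concentration sample)
#' @return percent value
#' @export
mpe <- function(records) {
  pe <- .pe_from_records(records)
  if (length(pe) == 0) stop("no valid prediction errors")
  stats::median(pe) * 100
}

#' @rdname mpe
#' @export
mape <- function(records) {
  pe <- .pe_from_records(records)
  if (length(pe) == 0) stop("no valid prediction errors")
  stats::median(abs(pe)) * 100
}

#' Bootstrap 95 % confidence interval of the MPE
#'
#' Nonparametric percentile bootstrap resampling whole subjects (not
#' records), which respects within-subject correlation of prediction errors.
#' Deterministic given `seed`.
#'
#' @param records data.frame with `subject_id`, `predicted`, `observed`
#' @param n_boot number of bootstrap resamples
#' @param seed integer RNG seed
#' @param level confidence level
#' @return numeric `c(low, high)` in percent; attribute `degenerate` is TRUE
#'   when only one subject was available
#' @export
mpe_confidence_interval <- function(records, n_boot = 1000, seed = 1,
                                    level = 0.95) {
  ids <- unique(records$subject_id)
  if (length(ids) < 2) {
    warning("single subject: degenerate confidence interval", call. = FALSE)
    ci <- rep(mpe(records), 2)
    attr(ci, "degenerate") <- TRUE
    return(ci)
  }
  pe <- prediction_error(records$predicted, records$observed)
  keep <- !is.na(pe)
  pe_by_id <- split(pe[keep], records$subject_id[keep])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_id <- length(pe_by_id)
  stat <- vapply(seq_len(n_boot), function(b) {
    take <- sample.int(n_id, n_id, replace = TRUE)
    stats::median(unlist(pe_by_id[take], use.names = FALSE)) * 100
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  attr(ci, "degenerate") <- FALSE
  ci
}

#' Clinical acceptability of a model's predictive performance
#'
#' Accuracy is acceptable when the MPE lies between -20 and +20 % with the
#' 95 % confidence interval including zero; precision is acceptable when the
#' MAPE is at most 30 %.
#'
#' @param mpe_percent MPE in percent
#' @param mpe_ci95 length-2 numeric, percent
#' @param mape_percent MAPE in percent
#' @return list with logicals `acceptable_accuracy`, `acceptable_precision`
#' @export
classify_acceptance <- function(mpe_percent, mpe_ci95, mape_percent) {
  list(
    acceptable_accuracy = mpe_percent >= -20 && mpe_percent <= 20 &&
      mpe_ci95[1] <= 0 && mpe_ci95[2] >= 0,
    acceptable_precision = mape_percent <= 30
  )
}

#' Full evaluation summary of a set of prediction records
#'
#' @param records prediction-record data.frame
#' @param stratum label carried into the result row
#' @param n_boot,seed bootstrap settings for the MPE confidence interval
#' @return one-row data.frame: `stratum`, `n_records`, `n_subjects`,
#'   `mpe_percent`, `mpe_ci_low`, `mpe_ci_high`, `mape_percent`,
#'   `acceptable_accuracy`, `acceptable_precision`
#' @export
evaluate_records <- function(records, stratum = "total", n_boot = 1000,
                             seed = 1) {
  m <- mpe(records)
  ma <- mape(records)
  ci <- suppressWarnings(
    mpe_confidence_interval(records, n_boot = n_boot, seed = seed))
  cls <- classify_acceptance(m, ci, ma)
  data.frame(
    stratum = stratum,
    n_records = sum(!is.na(prediction_error(records$predicted,
                                            records$observed))),
    n_subjects = length(unique(records$subject_id)),
    mpe_percent = m, mpe_ci_low = ci[1], mpe_ci_high = ci[2],
    mape_percent = ma,
    acceptable_accuracy = cls$acceptable_accuracy,
    acceptable_precision = cls$acceptable_precision,
    stringsAsFactors = FALSE
  )
}
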