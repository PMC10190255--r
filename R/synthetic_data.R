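#' Recipe for a virtual two-center CRRT cohort
#'
#' The default recipe emulates the covariate structure, dosing strategies,
#' and sampling patterns of a 73-patient, 193-sample two-center cohort of
#' critically ill adults on CRRT: 60 subjects in center 1 (56 intermittent /
#' 4 continuous infusion, mixed CRRT modalities, continuous residual-diuresis
#' records, 11 richly sampled subjects) and 13 in center 2 (all continuous
#' infusion on CVVHD at a fixed 2,000 mL/h flow, categorical
#' residual-diuresis records, two samples each). Covariate medians and
#' ranges target: age 60 y (19--89), weight 77 kg (48--140), height 170 cm,
#' flow rate 2,000 mL/h (1,500--5,700), residual diuresis median 0
#' (0--1,500 mL/24 h), dialysis mix CVVH/CVVHD/CVVHDF about 59/32/10 %.
#'
#' Distribution families: log-normal for weight, creatinine, and flow rate;
#' truncated normal for age, height, and albumin; zero-inflated log-normal
#' for residual diuresis (a median of 0 with a range up to 1,500 demands a
#' point mass at zero). Family parameters are moment-matched to the target
#' median and range: the log-median anchors the location and the spread is
#' set so the stated range spans approximately the central 99 % of the
#' untruncated distribution, then draws are rejected outside the bounds.
#'
#' @param n_subjects total cohort size
#' @param generating_model name of the built-in model (or a `poppk_model`)
#'   used to simulate concentrations
#' @param error_variant residual-error variant of the generating model
#' @param seed integer RNG seed (mandatory; the cohort is a pure function of
#'   the recipe)
#' @param iiv_scale multiplier on the generating model's omega (0 switches
#'   IIV off)
#' @param residual_scale multiplier on the residual-error SDs (0 gives
#'   noise-free observations)
#' @param regimen_ii list(amount mg, interval h, duration h) intermittent
#'   template (default 1,000 mg q8h over 0.5 h)
#' @param regimen_ci list(rate mg/h, horizon h) continuous template (default
#'   125 mg/h = 3,000 mg/24 h over 48 h)
#' @return list of class `cohort_recipe`
#' @export
cohort_recipe <- function(n_subjects = 73,
                          generating_model = "ojeanson_2021",
                          error_variant = NULL,
                          seed = 1,
                          iiv_scale = 1,
                          residual_scale = 1,
                          regimen_ii = list(amount = 1000, interval = 8,
                                            duration = 0.5),
                          regimen_ci = list(rate = 125, horizon = 48)) {
  n1 <- round(n_subjects * 60 / 73)
  n2 <- n_subjects - n1
  structure(
    list(
      n_subjects = n_subjects,
      centers = list(
        center_1 = list(
          n = n1,
          p_male = 43 / 60,
          age = list(family = "tnorm", median = 56, lo = 19, hi = 87),
          weight = list(family = "lnorm", median = 77, lo = 48, hi = 140),
          height = list(family = "tnorm", median = 170, lo = 150, hi = 190),
          serum_albumin = list(family = "tnorm", median = 25, lo = 17, hi = 39),
          serum_creatinine = list(family = "lnorm", median = 2.0, lo = 0.6,
                                  hi = 6.1),
          total_flow_rate = list(family = "lnorm", median = 2000, lo = 1500,
                                 hi = 5700),
          residual_diuresis = list(family = "zilnorm", p_zero = 0.62,
                                   median_pos = 400, lo = 50, hi = 1500),
          dialysis_probs = c(CVVH = 43, CVVHD = 10, CVVHDF = 7) / 60,
          n_ii = round(n1 * 56 / 60),
          n_rich = round(n1 * 11 / 60),
          rd_categorical = FALSE
        ),
        center_2 = list(
          n = n2,
          p_male = 10 / 13,
          age = list(family = "tnorm", median = 76, lo = 55, hi = 89),
          weight = list(family = "lnorm", median = 85, lo = 55, hi = 120),
          height = list(family = "tnorm", median = 170, lo = 160, hi = 190),
          serum_albumin = list(family = "tnorm", median = 18, lo = 8, hi = 28),
          serum_creatinine = list(family = "lnorm", median = 2.3, lo = 0.9,
                                  hi = 8.6),
          total_flow_rate = list(family = "fixed", value = 2000),
          # categories drawn so the mapped median is 1,000 mL/24 h
          rd_cat_probs = c(`1` = 0.55, `2` = 0.15, `3` = 0.30),
          dialysis_probs = c(CVVH = 0, CVVHD = 1, CVVHDF = 0),
          n_ii = 0,
          n_rich = 0,
          rd_categorical = TRUE
        )
      ),
      crrt_hours = list(family = "lnorm", median = 72, lo = 26, hi = 400),
      regimen_ii = regimen_ii,
      regimen_ci = regimen_ci,
      generating_model = generating_model,
      error_variant = error_variant,
      iiv_scale = iiv_scale,
      residual_scale = residual_scale,
      seed = seed
    ),
    class = "cohort_recipe"
  )
}

# draw n values from a moment-matched, range-truncated family
.draw_covariate <- function(n, d) {
  if (d$family == "fixed") return(rep(d$value, n))
  z99 <- stats::qnorm(0.995)
  draw_one <- switch(d$family,
    "tnorm" = {
      sd <- (d$hi - d$lo) / (2 * z99)
      function(m) stats::rnorm(m, d$median, sd)
    },
    "lnorm" = {
      sdlog <- (log(d$hi) - log(d$lo)) / (2 * z99)
      function(m) stats::rlnorm(m, log(d$median), sdlog)
    },
    stop("unknown covariate family: ", d$family)
  )
  out <- numeric(0)
  while (length(out) < n) {
    x <- draw_one(2 * n)
    out <- c(out, x[x >= d$lo & x <= d$hi])
  }
  out[seq_len(n)]
}

.draw_residual_diuresis <- function(n, d) {
  zero <- stats::runif(n) < d$p_zero
  pos <- .draw_covariate(n, list(family = "lnorm", median = d$median_pos,
                                 lo = d$lo, hi = d$hi))
  ifelse(zero, 0, pos)
}

# scale a model's variability terms (returns a modified copy)
.scale_model_variability <- function(model, iiv_scale, residual_scale) {
  if (length(model$iiv_parameters)) {
    model$omega <- as.matrix(model$omega) * iiv_scale
  }
  if (residual_scale != 1) {
    model$residual_error <- lapply(model$residual_error, function(re) {
      re$sd_additive <- (re$sd_additive %||% 0) * residual_scale
      re$sd_proportional <- (re$sd_proportional %||% 0) * residual_scale
      if (re$sd_additive == 0 && re$sd_proportional == 0) {
        re$sd_additive <- 1e-12  # keep the variant structurally valid
      }
      re
    })
  }
  model
}

#' Generate a virtual CRRT cohort
#'
#' Draws covariates per center from the recipe's distribution families,
#' assigns dosing regimens (intermittent q8h short infusions or one long
#' continuous-infusion event) and sampling templates (one trough per
#' occasion; richly sampled subjects add early post-infusion samples), and
#' simulates observed concentrations from the generating model with IIV and
#' residual error. Every generated subject satisfies the study inclusion
#' filter by construction (>= 24 h CRRT, >= 2 samples in >= 2 occasions).
#' Deterministic given the recipe (byte-identical across runs).
#'
#' @param recipe a [cohort_recipe()]
#' @return list of `pk_subject` with occasions assigned; attribute
#'   `true_eta` holds the simulated random effects (subjects x IIV dim)
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  model <- recipe$generating_model
  if (is.character(model)) model <- load_builtin_model(model)
  model <- .scale_model_variability(model, recipe$iiv_scale,
                                    recipe$residual_scale)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(recipe$seed)

  subjects <- list()
  true_eta <- list()
  idx <- 0
  for (cname in names(recipe$centers)) {
    cc <- recipe$centers[[cname]]
    if (cc$n == 0) next
    age <- .draw_covariate(cc$n, cc$age)
    weight <- .draw_covariate(cc$n, cc$weight)
    height <- .draw_covariate(cc$n, cc$height)
    albumin <- .draw_covariate(cc$n, cc$serum_albumin)
    creat <- .draw_covariate(cc$n, cc$serum_creatinine)
    flow <- .draw_covariate(cc$n, cc$total_flow_rate)
    rd <- if (cc$rd_categorical) {
      cats <- sample(1:3, cc$n, replace = TRUE, prob = cc$rd_cat_probs)
      map_residual_diuresis_category(cats)
    } else {
      .draw_residual_diuresis(cc$n, cc$residual_diuresis)
    }
    sex <- ifelse(stats::runif(cc$n) < cc$p_male, "male", "female")
    dial <- sample(names(cc$dialysis_probs), cc$n, replace = TRUE,
                   prob = cc$dialysis_probs)
    crrt_h <- .draw_covariate(cc$n, recipe$crrt_hours)
    mode <- c(rep("II", cc$n_ii), rep("CI", cc$n - cc$n_ii))
    rich <- c(rep(TRUE, min(cc$n_rich, cc$n_ii)),
              rep(FALSE, cc$n - min(cc$n_rich, cc$n_ii)))

    for (i in seq_len(cc$n)) {
      idx <- idx + 1
      if (mode[i] == "II") {
        rg <- recipe$regimen_ii
        n_doses <- 4
        doses <- dose_events(start_time = rg$interval * (0:(n_doses - 1)),
                             amount = rg$amount, duration = rg$duration)
        trough1 <- rg$interval - 0.25
        trough2 <- 3 * rg$interval - 0.25
        times <- if (rich[i]) {
          base <- c(rg$duration + c(0.5, 1.5, 3.5, 5.5), trough1, trough2)
          if (idx %% 4 == 1) c(rg$duration + 0.25, base) else base
        } else {
          c(trough1, trough2)
        }
      } else {
        rg <- recipe$regimen_ci
        doses <- dose_events(start_time = 0,
                             amount = rg$rate * rg$horizon,
                             duration = rg$horizon)
        times <- c(rg$horizon * 0.4, rg$horizon * 0.9)
      }
      eta <- drop(.rmvnorm(1, as.matrix(model$omega)))
      covs <- c(age = age[i], weight = weight[i], height = height[i],
                serum_albumin = albumin[i], serum_creatinine = creat[i],
                egfr_cg = egfr_cockcroft_gault(age[i], weight[i], creat[i],
                                               sex[i]),
                egfr_ckdepi = egfr_ckdepi(age[i], creat[i], sex[i]),
                total_flow_rate = flow[i], residual_diuresis = rd[i])
      pars <- individual_parameters(model, covs, eta)
      y <- simulate_observations(model, pars, doses, times,
                                 recipe$error_variant)
      y <- pmax(as.numeric(y), 0.01)  # observations must stay positive
      subj <- new_subject(
        subject_id = sprintf("S%03d", idx),
        center = cname, sex = sex[i], age = age[i], weight = weight[i],
        height = height[i], serum_albumin = albumin[i],
        serum_creatinine = creat[i], dialysis_type = dial[i],
        total_flow_rate = flow[i], residual_diuresis = rd[i],
        crrt_hours_after_first_dose = crrt_h[i],
        infusion_mode = mode[i],
        doses = doses,
        observations = data.frame(time = times, conc = y)
      )
      subjects[[idx]] <- with_occasions(subj)
      true_eta[[idx]] <- eta
    }
  }
  attr(subjects, "true_eta") <- do.call(rbind, true_eta)
  attr(subjects, "generating_model") <- model$name
  subjects
}

#' Mask covariates at random to emulate incomplete clinical records
#'
#' @param subjects list of `pk_subject`
#' @param rates named numeric vector of masking probabilities per covariate
#'   (e.g. `c(residual_diuresis = 0.1)`); the emulated registries were
#'   missing under 11 % per covariate
#' @param seed integer RNG seed
#' @return the cohort with masked values set to `NA`; attribute
#'   `masking_log` is a data.frame `subject_id`, `covariate`
#' @export
inject_missingness <- function(subjects, rates, seed = 1) {
  if (any(rates < 0 | rates > 1)) stop("masking rates must lie in [0, 1]")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  log <- list()
  for (i in seq_along(subjects)) {
    for (cov in names(rates)) {
      if (stats::runif(1) < rates[[cov]]) {
        subjects[[i]][[cov]] <- NA_real_
        log[[length(log) + 1L]] <- data.frame(
          subject_id = subjects[[i]]$subject_id, covariate = cov)
      }
    }
  }
  attr(subjects, "masking_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(subject_id = character(), covariate = character())
  subjects
}
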