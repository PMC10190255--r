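#' Construct a subject record
#'
#' A subject carries the covariates used by the candidate models, the dosing
#' history, and the observed concentrations. Covariates are single values per
#' subject (the candidate models use no time-varying covariates). Units:
#' Table-1 conventions -- age years, weight kg, height cm, albumin g/L,
#' creatinine mg/dL, flow rate mL/h, residual diuresis mL/24 h.
#'
#' @param subject_id identifier
#' @param center study-center label
#' @param sex "male" or "female"
#' @param age,weight,height,serum_albumin,serum_creatinine numeric covariates
#' @param egfr_cg,egfr_ckdepi estimated GFR (computed from the creatinine
#'   covariates when `NULL`)
#' @param dialysis_type one of "CVVH", "CVVHD", "CVVHDF"
#' @param total_flow_rate mL/h (dialysate + replacement fluid)
#' @param residual_diuresis mL/24 h
#' @param crrt_hours_after_first_dose h of CRRT after the first meropenem dose
#' @param infusion_mode "II" (intermittent) or "CI" (continuous)
#' @param doses data.frame from [dose_events()]
#' @param observations data.frame with `time` (h), `conc` (mg/L) and
#'   optionally `occasion` (filled by [assign_occasions()])
#' @return object of class `pk_subject`
#' @export
new_subject <- function(subject_id, doses, observations,
                        center = "center_1", sex = "male",
                        age = NA_real_, weight = NA_real_, height = NA_real_,
                        serum_albumin = NA_real_,
                        serum_creatinine = NA_real_,
                        egfr_cg = NULL, egfr_ckdepi = NULL,
                        dialysis_type = NA_character_,
                        total_flow_rate = NA_real_,
                        residual_diuresis = NA_real_,
                        crrt_hours_after_first_dose = NA_real_,
                        infusion_mode = "II") {
  observations <- observations[order(observations$time), , drop = FALSE]
  if (is.null(observations$occasion)) observations$occasion <- NA_integer_
  if (is.null(egfr_cg)) {
    egfr_cg <- if (is.na(age) || is.na(weight) || is.na(serum_creatinine)) {
      NA_real_
    } else {
      egfr_cockcroft_gault(age, weight, serum_creatinine, sex)
    }
  }
  if (is.null(egfr_ckdepi)) {
    egfr_ckdepi <- if (is.na(age) || is.na(serum_creatinine)) NA_real_ else
      egfr_ckdepi(age, serum_creatinine, sex)
  }
  structure(
    list(subject_id = subject_id, center = center, sex = sex, age = age,
         weight = weight, height = height, serum_albumin = serum_albumin,
         serum_creatinine = serum_creatinine, egfr_cg = egfr_cg,
         egfr_ckdepi = egfr_ckdepi, dialysis_type = dialysis_type,
         total_flow_rate = total_flow_rate,
         residual_diuresis = residual_diuresis,
         crrt_hours_after_first_dose = crrt_hours_after_first_dose,
         infusion_mode = infusion_mode,
         doses = doses, observations = observations),
    class = "pk_subject"
  )
}

#' @export
print.pk_subject <- function(x, ...) {
  cat("<pk_subject> ", x$subject_id, " (", x$center, ", ", x$infusion_mode,
      "): ", nrow(x$doses), " dose event(s), ", nrow(x$observations),
      " observation(s)\n", sep = "")
  invisible(x)
}

#' Extract the covariate vector of a subject
#'
#' @param subject a `pk_subject`
#' @return named numeric vector of the continuous covariates (categorical
#'   `dialysis_type` is carried separately by models that need it)
#' @export
subject_covariates <- function(subject) {
  c(age = subject$age, weight = subject$weight, height = subject$height,
    serum_albumin = subject$serum_albumin,
    serum_creatinine = subject$serum_creatinine,
    egfr_cg = subject$egfr_cg, egfr_ckdepi = subject$egfr_ckdepi,
    total_flow_rate = subject$total_flow_rate,
    residual_diuresis = subject$residual_diuresis)
}

#' Partition a subject's observations into dosing occasions
#'
#' An occasion is the time interval containing at least one measured
#' concentration between two dosing events; consecutive dosing events with no
#' intervening measurement are merged into one occasion. For a continuous
#' infusion with a single long dose event and no bag changes, each
#' observation defines its own occasion with boundaries at the midpoints
#' between consecutive observations (the discrete-dose rule has no interior
#' boundaries there).
#'
#' @param subject a `pk_subject` with >= 1 dose and >= 1 observation
#' @return list with `boundaries` (data.frame `occasion`, `lo`, `hi`;
#'   half-open intervals) and `occasion` (integer index per observation;
#'   0 flags observations before the first dose)
#' @export
assign_occasions <- function(subject) {
  doses <- subject$doses
  obs_t <- subject$observations$time
  if (nrow(doses) == 0 || length(obs_t) == 0) {
    stop("occasion assignment needs >= 1 dose and >= 1 observation")
  }
  dstart <- sort(doses$start_time)
  single_ci <- nrow(doses) == 1 &&
    sum(obs_t > dstart[1] & obs_t <= dstart[1] + doses$duration[1]) > 1
  if (single_ci) {
    # continuous infusion, no bag changes: midpoint rule
    inside <- obs_t[obs_t > dstart[1]]
    mids <- (utils::head(inside, -1) + inside[-1]) / 2
    lo <- c(dstart[1], mids)
    hi <- c(mids, Inf)
  } else {
    # boundary at every dose event preceded by >= 1 observation since the
    # previous boundary (merges back-to-back doses without measurements)
    lo <- dstart[1]
    for (d in dstart[-1]) {
      if (any(obs_t >= lo[length(lo)] & obs_t < d)) lo <- c(lo, d)
    }
    hi <- c(lo[-1], Inf)
  }
  occ <- rep(0L, length(obs_t))
  for (k in seq_along(lo)) {
    occ[obs_t >= lo[k] & obs_t < hi[k]] <- k
  }
  list(boundaries = data.frame(occasion = seq_along(lo), lo = lo, hi = hi),
       occasion = occ)
}

#' Fill the `occasion` column of a subject's observations
#'
#' @param subject a `pk_subject`
#' @return the subject with `observations$occasion` set (0 = pre-dose)
#' @export
with_occasions <- function(subject) {
  subject$observations$occasion <- assign_occasions(subject)$occasion
  subject
}

#' Apply the study inclusion filter to a cohort
#'
#' A subject is included when on CRRT for at least 24 h after the first
#' meropenem dose and carrying at least two measured concentrations spanning
#' at least two occasions. Exclusions carry machine-readable reasons
#' ("crrt_duration", "occasions").
#'
#' @param subjects list of `pk_subject` (occasions are assigned on the fly
#'   when missing)
#' @return list with `included` (list of subjects, occasions filled) and
#'   `excluded` (data.frame `subject_id`, `reason`)
#' @export
apply_inclusion_filter <- function(subjects) {
  included <- list()
  excl <- list()
  for (s in subjects) {
    if (any(is.na(s$observations$occasion))) s <- with_occasions(s)
    reasons <- character()
    if (is.na(s$crrt_hours_after_first_dose) ||
        s$crrt_hours_after_first_dose < 24) {
      reasons <- c(reasons, "crrt_duration")
    }
    occ <- s$observations$occasion[s$observations$occasion > 0]
    if (length(occ) < 2 || length(unique(occ)) < 2) {
      reasons <- c(reasons, "occasions")
    }
    if (length(reasons) == 0) {
      included[[length(included) + 1L]] <- s
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = s$subject_id, reason = paste(reasons, collapse = ";"))
    }
  }
  list(included = included,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(subject_id = character(), reason = character()))
}

#' Map a categorical residual-diuresis class to mL/24 h
#'
#' Center 2 recorded residual diuresis in three classes; for evaluation each
#' class is set to its lower limit: class 1 (> 1,000 mL/24 h) -> 1,000;
#' class 2 (500--1,000) -> 500; class 3 (< 500) -> 0.
#'
#' @param category integer vector with values in \{1, 2, 3\}
#' @return numeric vector, mL/24 h
#' @export
map_residual_diuresis_category <- function(category) {
  if (any(!category %in% 1:3)) {
    stop("residual-diuresis category must be 1, 2, or 3")
  }
  unname(c(`1` = 1000, `2` = 500, `3` = 0)[as.character(category)])
}

#' Impute missing model-relevant covariates with model-population medians
#'
#' Each candidate model declares the covariate medians of its development
#' population; a missing covariate that the model needs is replaced by that
#' median. Present values are never overwritten, so the operation is
#' idempotent, and different models impute different values.
#'
#' @param subject a `pk_subject`
#' @param model a `poppk_model`
#' @return the subject with missing model covariates filled; attribute
#'   `imputed` lists the covariates touched
#' @export
impute_missing_covariates <- function(subject, model) {
  needed <- model_covariates(model)
  imputed <- character()
  for (cov in needed) {
    val <- subject[[cov]]
    if (!is.null(val) && !is.na(val)) next
    med <- model$population_medians[cov]
    if (is.null(med) || length(med) == 0 || is.na(med)) {
      stop("model '", model$name, "' declares no population median for ",
           "missing covariate '", cov, "'")
    }
    subject[[cov]] <- unname(med)
    imputed <- c(imputed, cov)
  }
  attr(subject, "imputed") <- imputed
  subject
}

#' Estimated glomerular filtration rate
#'
#' `egfr_cockcroft_gault()` implements the Cockcroft--Gault creatinine
#' clearance, `((140 - age) * weight) / (72 * Scr)`, times 0.85 for female
#' sex, in mL/min. `egfr_ckdepi()` implements the 2009 CKD-EPI creatinine
#' equation (sex term only), in mL/min/1.73 m^2.
#'
#' @param age years
#' @param weight kg
#' @param serum_creatinine mg/dL (> 0)
#' @param sex "male" or "female"
#' @return numeric eGFR
#' @export
egfr_cockcroft_gault <- function(age, weight, serum_creatinine, sex) {
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be > 0")
  cg <- ((140 - age) * weight) / (72 * serum_creatinine)
  cg * ifelse(sex == "female", 0.85, 1)
}

#' @rdname egfr_cockcroft_gault
#' @export
egfr_ckdepi <- function(age, serum_creatinine, sex) {
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be > 0")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- serum_creatinine / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

.cov_cols <- c("center", "sex", "age", "weight", "height", "serum_albumin",
               "serum_creatinine", "egfr_cg", "egfr_ckdepi", "dialysis_type",
               "total_flow_rate", "residual_diuresis",
               "crrt_hours_after_first_dose", "infusion_mode")

#' Write / read a cohort as rectangular CSV files
#'
#' The dosing/observation table follows the NONMEM-style contract: columns
#' `ID`, `TIME` (h), `AMT` (mg), `RATE` (mg/h), `DUR` (h), `DV` (mg/L),
#' `EVID` (1 = dose, 0 = observation), `OCC` (occasion index, NA if
#' unassigned). Covariates live in a separate subject-level CSV keyed by
#' `ID`. The round trip through `write_pk_dataset()` / `read_pk_dataset()`
#' is lossless.
#'
#' @param subjects list of `pk_subject`
#' @param events_path CSV path for the dosing/observation table
#' @param covariates_path CSV path for the subject-level covariate table
#' @return `write_pk_dataset()`: paths, invisibly; `read_pk_dataset()`: a
#'   list of `pk_subject`
#' @export
write_pk_dataset <- function(subjects, events_path, covariates_path) {
  ev <- list(); cv <- list()
  for (s in subjects) {
    d <- s$doses; o <- s$observations
    ev[[length(ev) + 1L]] <- rbind(
      data.frame(ID = s$subject_id, TIME = d$start_time, AMT = d$amount,
                 RATE = d$amount / d$duration, DUR = d$duration,
                 DV = NA_real_, EVID = 1L, OCC = NA_integer_),
      data.frame(ID = s$subject_id, TIME = o$time, AMT = NA_real_,
                 RATE = NA_real_, DUR = NA_real_, DV = o$conc, EVID = 0L,
                 OCC = o$occasion)
    )
    cv[[length(cv) + 1L]] <- cbind(data.frame(ID = s$subject_id),
                                   as.data.frame(s[.cov_cols]))
  }
  utils::write.csv(do.call(rbind, ev), events_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, cv), covariates_path, row.names = FALSE)
  invisible(c(events_path, covariates_path))
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(events_path, covariates_path) {
  ev <- utils::read.csv(events_path)
  cv <- utils::read.csv(covariates_path)
  lapply(seq_len(nrow(cv)), function(i) {
    row <- cv[i, ]
    e <- ev[ev$ID == row$ID, ]
    d <- e[e$EVID == 1L, ]
    o <- e[e$EVID == 0L, ]
    args <- c(
      list(subject_id = row$ID,
           doses = dose_events(d$TIME, d$AMT, d$DUR),
           observations = data.frame(time = o$TIME, conc = o$DV,
                                     occasion = o$OCC)),
      as.list(row[.cov_cols])
    )
    # stored eGFRs win over recomputation (they may have been imputed)
    do.call(new_subject, args)
  })
}
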