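# small fixtures built in code, shared across test files

# minimal one-compartment model, optionally without covariates/IIV
toy_model_1cpt <- function(cl = 5, v1 = 30, omega_cl = 0.09, omega_v1 = 0.16,
                           prop_sd = 0.2, add_sd = 0) {
  kind <- if (add_sd > 0 && prop_sd > 0) "combined" else
    if (add_sd > 0) "additive" else "proportional"
  new_model_spec(
    name = "toy1", n_compartments = 1,
    thetas = c(CL = cl, V1 = v1),
    iiv_parameters = c("CL", "V1"),
    omega = diag(c(omega_cl, omega_v1)),
    residual_error = list(main = list(kind = kind, sd_additive = add_sd,
                                      sd_proportional = prop_sd,
                                      variant_label = "main"))
  )
}

toy_model_2cpt <- function(cl = 5, v1 = 20, q = 6, v2 = 15, prop_sd = 0.2) {
  new_model_spec(
    name = "toy2", n_compartments = 2,
    thetas = c(CL = cl, V1 = v1, Q = q, V2 = v2),
    iiv_parameters = c("CL", "V1"),
    omega = diag(c(0.09, 0.16)),
    residual_error = list(main = list(kind = "proportional",
                                      sd_additive = 0,
                                      sd_proportional = prop_sd,
                                      variant_label = "main"))
  )
}

# simple intermittent-infusion subject: q8h x 3, troughs at 7.75 / 23.75 h
toy_subject <- function(id = "T01", conc = c(10, 9), extra_times = NULL,
                        crrt_h = 72) {
  times <- sort(c(7.75, 23.75, extra_times))
  stopifnot(length(conc) == length(times))
  new_subject(
    subject_id = id,
    doses = dose_events(c(0, 8, 16), 1000, 0.5),
    observations = data.frame(time = times, conc = conc),
    age = 60, weight = 77, height = 170, serum_albumin = 25,
    serum_creatinine = 2.1, dialysis_type = "CVVH",
    total_flow_rate = 2000, residual_diuresis = 0,
    crrt_hours_after_first_dose = crrt_h, infusion_mode = "II"
  )
}

# numerical ODE oracle for the 2-compartment infusion model (independent of
# the closed-form engine); requires deSolve
ode_oracle_conc <- function(params, doses, times) {
  two_cpt <- "Q" %in% names(params)
  k10 <- params[["CL"]] / params[["V1"]]
  rhs <- function(t, y, p) {
    if (two_cpt) {
      k12 <- p$q / p$v1; k21 <- p$q / p$v2
      list(c(p$r0 - (k10 + k12) * y[1] + k21 * y[2],
             k12 * y[1] - k21 * y[2]))
    } else {
      list(p$r0 - k10 * y[1])
    }
  }
  seg_rate <- function(t) {
    r <- 0
    for (i in seq_len(nrow(doses))) {
      if (t >= doses$start_time[i] &&
          t < doses$start_time[i] + doses$duration[i]) {
        r <- r + doses$amount[i] / doses$duration[i]
      }
    }
    r
  }
  breaks <- sort(unique(c(0, doses$start_time,
                          doses$start_time + doses$duration, max(times))))
  breaks <- breaks[breaks <= max(times)]
  if (max(breaks) < max(times)) breaks <- c(breaks, max(times))
  y <- if (two_cpt) c(0, 0) else 0
  sol_t <- 0
  sol_c <- 0
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    inner <- times[times > lo & times <= hi]
    grid <- sort(unique(c(lo, inner, hi)))
    p <- list(r0 = seg_rate((lo + hi) / 2),
              q = if (two_cpt) params[["Q"]] else NULL,
              v1 = params[["V1"]], v2 = if (two_cpt) params[["V2"]] else NULL)
    out <- deSolve::ode(y, grid, rhs, p, rtol = 1e-11, atol = 1e-11)
    y <- out[nrow(out), -1]
    sol_t <- c(sol_t, grid[-1])
    sol_c <- c(sol_c, out[-1, 2] / params[["V1"]])
  }
  unname(sol_c[match(times, sol_t)])
}
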