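#' Configure an end-to-end model evaluation run
#'
#' @param models list of `poppk_model` objects or built-in model names;
#'   models with several residual-error variants are expanded into one
#'   evaluation arm per variant (named `model:variant`)
#' @param subjects list of `pk_subject` (e.g. from [generate_cohort()] or
#'   [read_pk_dataset()])
#' @param arms evaluation arms, subset of `"a_priori_all"` (population
#'   predictions of every sample), `"a_priori_occ2_trough"` (population
#'   prediction of the second-occasion trough only), and
#'   `"bayesian_occ2_trough"` (single-sample MAP forecast of the same trough)
#' @param strata stratification schemes, subset of `"total"`, `"center"`,
#'   `"infusion_mode"`
#' @param n_boot bootstrap resamples for the MPE confidence interval
#' @param seed master seed (bootstrap and diagnostics seeds derive from it)
#' @param diagnostics compute NPDE and pcVPC for the a-priori arm?
#' @param npde_sims,pcvpc_sims simulation counts for the diagnostics
#' @return list of class `run_config`
#' @export
run_config <- function(models, subjects,
                       arms = c("a_priori_all", "a_priori_occ2_trough",
                                "bayesian_occ2_trough"),
                       strata = c("total", "center", "infusion_mode"),
                       n_boot = 1000, seed = 1, diagnostics = FALSE,
                       npde_sims = 1000, pcvpc_sims = 500) {
  if (length(models) == 0 || length(arms) == 0) {
    stop("need at least one model and one evaluation arm")
  }
  models <- lapply(models, function(m) {
    if (is.character(m)) load_builtin_model(m) else m
  })
  structure(
    list(models = models, subjects = subjects, arms = arms, strata = strata,
         n_boot = n_boot, seed = seed, diagnostics = diagnostics,
         npde_sims = npde_sims, pcvpc_sims = pcvpc_sims),
    class = "run_config"
  )
}

# expand models into (model, variant) evaluation units
.model_variants <- function(models) {
  units <- list()
  for (m in models) {
    vs <- names(m$residual_error)
    if (length(vs) == 1) {
      units[[m$name]] <- list(model = m, variant = vs[1], label = m$name)
    } else {
      for (v in vs) {
        lab <- paste0(m$name, ":", v)
        units[[lab]] <- list(model = m, variant = v, label = lab)
      }
    }
  }
  units
}

.strata_split <- function(records, scheme) {
  if (scheme == "total") {
    return(list(total = records))
  }
  split(records, paste0(scheme, "=", records[[scheme]]))
}

#' Run the full evaluation workflow
#'
#' For every model (x residual-error variant) the subjects are imputed
#' against that model, predictions are produced for each configured arm, and
#' stratified MPE/MAPE summaries with bootstrap confidence intervals and
#' acceptance verdicts are assembled, optionally together with NPDE and
#' pcVPC diagnostics of the a-priori arm. A failure in one model is isolated
#' (that model is dropped with a warning; the run continues). The returned
#' manifest, together with the inputs, fully determines the outputs.
#'
#' @param config a [run_config()]
#' @return list of class `evaluation_run`: `results` (one row per model x
#'   arm x stratum), `predictions` (per-record table), `diagnostics` (per
#'   model: `npde`, `pcvpc`), `manifest`
#' @export
run_evaluation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  subjects <- lapply(config$subjects, function(s) {
    if (any(is.na(s$observations$occasion))) with_occasions(s) else s
  })
  units <- .model_variants(config$models)
  results <- list()
  predictions <- list()
  diags <- list()
  for (u in units) {
    rows <- tryCatch(
      .evaluate_one_model(u, subjects, config),
      error = function(e) {
        warning("model '", u$label, "' failed and was skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(rows)) next
    results[[u$label]] <- rows$results
    predictions[[u$label]] <- rows$predictions
    if (config$diagnostics) diags[[u$label]] <- rows$diagnostics
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crrtmipd")),
    seed = config$seed, n_boot = config$n_boot,
    arms = config$arms, strata = config$strata,
    models = names(units),
    n_subjects = length(subjects),
    n_observations = sum(vapply(subjects,
                                function(s) nrow(s$observations), 0L)),
    diagnostics = config$diagnostics,
    npde_sims = config$npde_sims, pcvpc_sims = config$pcvpc_sims
  )
  structure(
    list(results = do.call(rbind, c(results, list(make.row.names = FALSE))),
         predictions = do.call(rbind,
                               c(predictions, list(make.row.names = FALSE))),
         diagnostics = diags,
         manifest = manifest),
    class = "evaluation_run"
  )
}

.evaluate_one_model <- function(unit, subjects, config) {
  model <- unit$model
  variant <- unit$variant
  imputed <- lapply(subjects, impute_missing_covariates, model = model)
  arm_records <- list()
  if ("a_priori_all" %in% config$arms ||
      "a_priori_occ2_trough" %in% config$arms) {
    ap <- do.call(rbind, lapply(imputed, predict_a_priori, model = model))
    if ("a_priori_all" %in% config$arms) arm_records$a_priori_all <- ap
    if ("a_priori_occ2_trough" %in% config$arms) {
      occ2 <- do.call(rbind, lapply(imputed, function(s) {
        tr <- .occasion_trough(s, 2L)
        if (is.null(tr)) return(NULL)
        ap[ap$subject_id == s$subject_id & ap$time == tr$time, , drop = FALSE]
      }))
      arm_records$a_priori_occ2_trough <- occ2
    }
  }
  if ("bayesian_occ2_trough" %in% config$arms) {
    arm_records$bayesian_occ2_trough <- do.call(rbind, lapply(
      imputed, predict_bayesian_occasion2, model = model,
      error_variant = variant))
  }
  res <- list()
  preds <- list()
  for (arm in names(arm_records)) {
    rec <- arm_records[[arm]]
    if (is.null(rec) || nrow(rec) == 0) next
    rec$model <- unit$label
    rec$arm <- arm
    preds[[arm]] <- rec
    for (scheme in config$strata) {
      pieces <- .strata_split(rec, scheme)
      for (sname in names(pieces)) {
        sub <- pieces[[sname]]
        row <- evaluate_records(sub, stratum = sname,
                                n_boot = config$n_boot, seed = config$seed)
        row <- cbind(data.frame(model = unit$label, arm = arm,
                                stringsAsFactors = FALSE), row)
        res[[length(res) + 1L]] <- row
      }
    }
  }
  diagnostics <- NULL
  if (config$diagnostics) {
    diagnostics <- list(
      npde = compute_npde(model, imputed, n_simulations = config$npde_sims,
                          seed = config$seed + 1, error_variant = variant),
      pcvpc = compute_pcvpc(model, imputed,
                            n_simulations = config$pcvpc_sims,
                            seed = config$seed + 2, error_variant = variant)
    )
  }
  list(results = do.call(rbind, res),
       predictions = do.call(rbind, c(preds, list(make.row.names = FALSE))),
       diagnostics = diagnostics)
}

#' @export
print.evaluation_run <- function(x, ...) {
  cat("<evaluation_run> ", length(unique(x$results$model)), " model(s), ",
      x$manifest$n_subjects, " subjects, ", nrow(x$results),
      " result rows\n", sep = "")
  print(x$results[, c("model", "arm", "stratum", "n_records", "mpe_percent",
                      "mape_percent")], digits = 3)
  invisible(x)
}

#' Median-of-models summary comparing evaluation arms
#'
#' Collapses the per-model results (stratum "total") to the median MPE and
#' MAPE across models per arm, the summary used to quantify how much a
#' single TDM sample improves the model set as a whole.
#'
#' @param results the `results` data.frame of an `evaluation_run` (or the
#'   run itself)
#' @return data.frame `arm`, `n_models`, `median_mpe_percent`,
#'   `median_mape_percent`
#' @export
summarize_across_models <- function(results) {
  if (inherits(results, "evaluation_run")) results <- results$results
  tot <- results[results$stratum == "total", , drop = FALSE]
  out <- lapply(split(tot, tot$arm), function(d) {
    data.frame(arm = d$arm[1], n_models = nrow(d),
               median_mpe_percent = stats::median(d$mpe_percent),
               median_mape_percent = stats::median(d$mape_percent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
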