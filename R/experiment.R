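# Experiment orchestration: the three delivery arms over a synthetic
# cohort, report generation, and plain-text serialization of configs and
# trained policies.

#' Run one delivery arm over a cohort
#'
#' Simulates every patient for \code{days} days under the testing meal
#' protocol (4 meals/day, +/- 30 min jitter) and computes the consensus
#' CGM metrics and insulin totals. Hybrid arms announce meals and never
#' consult the detector; the fully automatic arm sees only detector flags
#' (true meal times are used only for scoring).
#'
#' @param arm "haid_sbc", "haid_drl", "faid" or "pd_only"
#' @param patients list of \code{patient_params} (e.g. from
#'   \code{\link{make_cohort}})
#' @param policies list of \code{faid_policy}, one per patient (DRL arms)
#' @param days simulation days per patient
#' @param seed master seed; patient i uses seed + i
#' @param vcfg \code{variability_config}
#' @param tuning \code{detector_tuning}
#' @param mis_sigma CHO misestimation SD (haid_sbc)
#' @return object of class \code{arm_result}: per-patient traces, metric
#'   reports, and (faid) detection scores
#' @export
run_arm <- function(arm = c("haid_sbc", "haid_drl", "faid", "pd_only"),
                    patients, policies = NULL, days = 14, seed = 1L,
                    vcfg = variability_config(),
                    tuning = detector_tuning(), mis_sigma = 0.2) {
  arm <- match.arg(arm)
  if (arm %in% c("haid_drl", "faid")) {
    if (is.null(policies) || length(policies) != length(patients))
      stop("arm '", arm, "' needs one trained policy per patient; ",
           "run drl_train() first")
  }
  res <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    sc <- generate_scenario("testing", days, seed = seed + i,
                            absorption_cv = vcfg$absorption_cv)
    bank <- if (!is.null(policies)) policies[[i]]$bank else NULL
    sim <- simulate_loop(p, sc, days, arm = arm, vcfg = vcfg,
                         bank = bank, tuning = tuning,
                         mis_sigma = mis_sigma, seed = seed + 1000L * i)
    rep <- cgm_metrics(sim$trace)
    rep[c("basal_per_day", "bolus_per_day", "tdi_per_day")] <-
      insulin_totals(sim$trace)
    detection <- if (arm == "faid")
      score_detections(sc$time_min, sim$flags) else NULL
    list(trace = sim$trace, report = rep, scenario = sc,
         flags = sim$flags, detection = detection)
  })
  structure(list(arm = arm, results = res, days = days, seed = seed),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s: %d patients x %d days\n",
              x$arm, length(x$results), x$days))
  tir <- vapply(x$results, function(r) r$report$tir70_180, numeric(1))
  tbr <- vapply(x$results, function(r) r$report$tbr, numeric(1))
  tar <- vapply(x$results, function(r) r$report$tar, numeric(1))
  cat(sprintf("  TIR 70-180: median %.1f%%  TBR: %.1f%%  TAR: %.1f%%\n",
              stats::median(tir), stats::median(tbr), stats::median(tar)))
  invisible(x)
}

#' Compare two arm results patient-by-patient
#'
#' @param a,b \code{arm_result} objects over the same cohort
#' @param ... passed to \code{\link{paired_compare}}
#' @return data.frame of medians (IQR) and Wilcoxon signed-rank p-values
#' @export
compare_arms <- function(a, b, ...) {
  paired_compare(lapply(a$results, `[[`, "report"),
                 lapply(b$results, `[[`, "report"), ...)
}

# ---- config & policy serialization ----------------------------------------

#' Write / read an experiment configuration (YAML)
#'
#' The configuration is a plain hierarchical list with blocks
#' \code{patient}, \code{variability}, \code{controller}, \code{detector},
#' \code{therapy}, \code{training} and \code{experiment}; unknown keys are
#' rejected on read.
#'
#' @param cfg named list
#' @param path file path
#' @return \code{read_experiment_config} returns the list
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("patient", "variability", "controller", "detector",
             "therapy", "training", "experiment")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Save / load a trained policy as JSON
#'
#' Weights of all 24 networks plus a manifest (architecture, seeds, action
#' grids, training configuration) in one JSON file; text-only and
#' round-trip exact to double precision.
#'
#' @param policy \code{faid_policy}
#' @param path file path (.json)
#' @return \code{load_policy} returns the \code{faid_policy}
#' @export
save_policy <- function(policy, path) {
  ser <- list(
    manifest = list(
      package = "faidsim", class = "faid_policy",
      layers = policy$bank$dqns[[1]]$net$layers,
      n_dqns = length(policy$bank$dqns),
      TDI = policy$bank$TDI, seed = policy$seed,
      announced = policy$announced,
      config = unclass(policy$config)),
    k_bob = policy$bank$k_bob,
    params = unclass(policy$params),
    log = policy$log,
    dqns = lapply(policy$bank$dqns, function(d)
      list(meal = d$meal, sas = d$sas, grid = d$grid,
           updates = d$net$t, W = d$net$W, b = d$net$b,
           target_W = d$target$W, target_b = d$target$b)))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- ser$manifest
  params <- do.call(patient_params,
                    ser$params[names(ser$params) != "glucose_floor"])
  cfg <- do.call(train_config, man$config)
  k_bob <- as.matrix(ser$k_bob)
  colnames(k_bob) <- c("breakfast", "lunch", "dinner")
  bank <- dqn_bank(man$TDI, seed = man$seed, k_bob = k_bob)
  for (key in names(ser$dqns)) {
    d <- ser$dqns[[key]]
    bank$dqns[[key]]$grid <- as.numeric(d$grid)
    bank$dqns[[key]]$net$W <- lapply(d$W, as.matrix)
    bank$dqns[[key]]$net$b <- lapply(d$b, as.numeric)
    bank$dqns[[key]]$net$t <- as.integer(d$updates)
    bank$dqns[[key]]$target <- list(W = lapply(d$target_W, as.matrix),
                                    b = lapply(d$target_b, as.numeric))
  }
  structure(list(bank = bank, log = as.data.frame(ser$log), config = cfg,
                 params = params, seed = man$seed,
                 announced = man$announced),
            class = "faid_policy")
}
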