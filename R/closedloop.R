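# Closed-loop engine: one virtual patient under the PD+SAFE+IFB controller
# with one of four bolus policies per 5-min tick:
#   pd_only   - no boluses (controller only)
#   haid_sbc  - announced meals, standard bolus calculator, CHO misestimation
#   haid_drl  - announced meals, DRL bolus calculator
#   faid      - unannounced meals, detector-triggered DRL boluses
# Tick order: sense CGM -> detector (faid) -> bolus decision -> controller
# (PD, IFB, pump cap, IOB, SAFE) -> deliver -> advance patient.

#' Simulate a closed-loop episode
#'
#' @param params \code{patient_params} of the plant
#' @param scenario meal scenario data.frame from
#'   \code{\link{generate_scenario}}
#' @param days episode length (days); ticks are 5 min
#' @param arm one of "pd_only", "haid_sbc", "haid_drl", "faid"
#' @param vcfg \code{variability_config} (circadian sensitivity, CGM noise)
#' @param ctrl_cfg \code{controller_config}; default derived from the
#'   patient's TDI
#' @param bank \code{dqn_bank} (required for DRL arms)
#' @param therapy \code{therapy_params} (required for haid_sbc); default
#'   guideline rules on the patient's TDI
#' @param tuning \code{detector_tuning} (faid arm)
#' @param detector_model detector-internal \code{patient_params}; the
#'   nominal model, deliberately not the (jittered) plant
#' @param mis_mu,mis_sigma CHO misestimation parameters (haid_sbc)
#' @param epsilon exploration probability for DRL action choice
#' @param random_actions if TRUE, DRL actions are drawn uniformly from the
#'   selected SAS (replay-memory generation)
#' @param seed RNG seed for sensor noise, misestimation and exploration
#' @param start_state initial patient state; default basal steady state
#' @return list(trace, events, flags): \code{trace} is a data.frame with
#'   columns time_min, cgm, basal_U_per_h, bolus_U, meal_g, meal_detected,
#'   iob_U (controller IOB estimate);
#'   \code{events} records every DRL bolus decision (for training);
#'   \code{flags} the detection times (min)
#' @export
simulate_loop <- function(params, scenario, days,
                          arm = c("pd_only", "haid_sbc", "haid_drl", "faid"),
                          vcfg = variability_config(),
                          ctrl_cfg = NULL, bank = NULL, therapy = NULL,
                          tuning = detector_tuning(),
                          detector_model = patient_params(),
                          mis_mu = 0, mis_sigma = 0.2,
                          epsilon = 0, random_actions = FALSE,
                          seed = 1L, start_state = NULL) {
  arm <- match.arg(arm)
  if (arm %in% c("haid_drl", "faid") && is.null(bank))
    stop("arm '", arm, "' needs a trained dqn_bank; train one first")
  if (is.null(ctrl_cfg)) ctrl_cfg <- controller_config(TDI = params$TDI)
  if (arm == "haid_sbc" && is.null(therapy))
    therapy <- derive_therapy(params$TDI)

  ticks <- as.integer(days * 288)
  pstate <- if (is.null(start_state)) patient_steady_state(params)
            else start_state
  cst <- controller_init(ctrl_cfg, params$ubl, detector_model)
  det <- if (arm == "faid")
    detector_init(detector_model, params$ubl, tuning,
                  r_sd = max(vcfg$cgm_noise_sd, 1)) else NULL
  bob <- c(0, 0)
  tmax_eff <- params$tmax_meal
  prev_u <- params$ubl

  hist_len <- 48L
  cgm_hist <- rep(pstate[["Gs"]], hist_len)

  time_min <- numeric(ticks); cgm_v <- numeric(ticks)
  basal_v <- numeric(ticks); bolus_v <- numeric(ticks)
  meal_v <- numeric(ticks); det_v <- integer(ticks)
  iob_v <- numeric(ticks)
  events <- list(); flags <- numeric(0)

  mt <- scenario$time_min

  with_seed(seed, {
    for (k in seq_len(ticks)) {
      t <- (k - 1L) * 5
      cgm <- sample_cgm(pstate, vcfg$cgm_noise_sd)
      cgm_hist <- c(cgm_hist[-1L], cgm)

      flagged <- FALSE
      if (!is.null(det)) {
        det <- ukf_step(det, cgm, prev_u, 5)
        mf <- meal_flag(det, t)
        det <- mf$det
        flagged <- mf$flag
        if (flagged) flags <- c(flags, t)
      }

      due <- which(mt >= t & mt < t + 5)
      bolus <- 0
      if (arm == "haid_sbc" && length(due)) {
        for (i in due) {
          cho_est <- misestimate_cho(scenario$cho[i], mis_mu, mis_sigma)
          bolus <- bolus + standard_bolus(cho_est, cgm, therapy, iob_hat(cst))
        }
      } else if (arm == "haid_drl" && length(due)) {
        for (i in due) {
          dec <- drl_decision(bank, cgm_hist, t, sum(bob),
                              epsilon, random_actions)
          bolus <- bolus + dec$bolus
          dec$tick <- k
          events[[length(events) + 1L]] <- dec
        }
      } else if (arm == "faid" && flagged) {
        dec <- drl_decision(bank, cgm_hist, t, sum(bob),
                            epsilon, random_actions)
        bolus <- dec$bolus
        dec$tick <- k
        events[[length(events) + 1L]] <- dec
      }

      ctrl <- controller_step(cst, cgm, ctrl_cfg, params$ubl, bolus, 5)
      cst <- ctrl$state
      bob <- bob_update(bob, bolus, ctrl_cfg$kdia, 5)

      if (length(due)) {
        for (i in due) {
          pstate <- ingest_meal(pstate, scenario$cho[i])
          tmax_eff <- params$tmax_meal /
            scenario$absorption_rate_multiplier[i]
        }
      }
      p3_eff <- circadian_p3(params, t + 2.5, vcfg)
      pstate <- step_patient(pstate, params, ctrl$u, 0, 5,
                             p3_eff = p3_eff, tmax_meal_eff = tmax_eff)
      prev_u <- ctrl$u

      time_min[k] <- t; cgm_v[k] <- cgm
      basal_v[k] <- ctrl$u_cont; bolus_v[k] <- bolus
      iob_v[k] <- iob_hat(cst)
      meal_v[k] <- if (length(due)) sum(scenario$cho[due]) else 0
      det_v[k] <- as.integer(flagged)
    }
  })

  trace <- data.frame(time_min = time_min, cgm = cgm_v,
                      basal_U_per_h = basal_v, bolus_U = bolus_v,
                      meal_g = meal_v, meal_detected = det_v,
                      iob_U = iob_v)
  list(trace = trace, events = events, flags = flags)
}

# one DRL bolus decision (epsilon-greedy or uniformly random action)
drl_decision <- function(bank, cgm_hist, clock_min, bob_hat,
                         epsilon, random_actions) {
  if (random_actions) {
    meal <- meal_label(clock_min)
    g_bm <- cgm_hist[length(cgm_hist)]
    sas <- select_sas(g_bm)
    d <- bank$dqns[[dqn_key(meal, sas)]]
    j <- sample.int(length(d$grid), 1L)
    a_j <- d$grid[j]
    u <- adjust_bolus(a_j, bob_hat, bank$k_bob[sas, meal], g_bm)
    list(bolus = u, meal = meal, sas = sas, action = j, a_j = a_j,
         g_bm = g_bm, state = build_state(cgm_hist, "pre-prandial"))
  } else {
    faid_bolus(bank, cgm_hist, clock_min, bob_hat, epsilon)
  }
}

#' Write / read an episode trace as CSV
#'
#' @param trace episode trace data.frame
#' @param path file path
#' @return \code{read_trace} returns the data.frame
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.csv(path)
}
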