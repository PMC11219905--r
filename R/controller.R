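# PD controller with insulin feedback (IFB) and the SAFE layer: a
# sliding-mode reference-conditioning (SMRC) block that bounds estimated
# insulin-on-board by raising the glucose reference.

#' Controller configuration
#'
#' The proportional gain follows the published tuning rule
#' \eqn{k_p = 60 \cdot TDI / (\tau_d \cdot 1500)} (U/h per mg/dL) with
#' derivative time \eqn{\tau_d = 90} min. The SAFE layer bounds the
#' estimated IOB below \code{IOB_max} through a sliding surface
#' \eqn{s = (\widehat{IOB} - \overline{IOB}) + \tau_{sm}\,d\widehat{IOB}/dt}
#' (the bound is constant, so its derivative is zero), a switching signal of
#' amplitude \code{nu_plus} and a first-order low-pass filter with rate
#' \code{lam} whose output raises the reference:
#' \eqn{G_{vref} = G_{ref} + \nu_f}.
#'
#' @param TDI total daily insulin (U), used by the gain rule
#' @param tau_d derivative time constant (min)
#' @param kp proportional gain (U/h per mg/dL); default from the gain rule
#' @param Gref glucose reference (mg/dL)
#' @param IOB_max upper IOB bound (U); default 1.5 x hourly basal x DIA
#'   hours, i.e. 1.5 * (TDI/24) * dia_hours
#' @param dia_hours duration of insulin action (h) used for the default bound
#' @param tau_sm sliding-surface time constant (min)
#' @param nu_plus switching amplitude (mg/dL)
#' @param lam low-pass filter rate (1/min)
#' @param eta insulin-feedback gain (U/h per mU/L)
#' @param kdia IOB-model time constant (1/min)
#' @param pump_max maximum continuous infusion rate (U/h)
#' @return object of class \code{controller_config}
#' @export
controller_config <- function(TDI = 30, tau_d = 90,
                              kp = 60 * TDI / (tau_d * 1500),
                              Gref = 120,
                              dia_hours = 4,
                              IOB_max = 1.5 * (TDI / 24) * dia_hours,
                              tau_sm = 20, nu_plus = 100, lam = 1 / 20,
                              eta = 0.3, kdia = 0.025, pump_max = 6) {
  stopifnot(kp > 0, tau_d > 0, IOB_max > 0, lam > 0, tau_sm > 0,
            nu_plus >= 0, eta >= 0, kdia > 0, pump_max > 0)
  structure(list(TDI = TDI, tau_d = tau_d, kp = kp, Gref = Gref,
                 IOB_max = IOB_max, tau_sm = tau_sm, nu_plus = nu_plus,
                 lam = lam, eta = eta, kdia = kdia, pump_max = pump_max),
            class = "controller_config")
}

#' Initial controller state
#'
#' IOB compartments are started at the basal steady state
#' (\eqn{c_1 = c_2 = u_{bl}/(60 k_{dia})}), the virtual reference at
#' \code{Gref}, and the plasma-insulin estimate at its basal steady state so
#' that the basal operating point is a closed-loop fixed point.
#'
#' @param cfg \code{controller_config}
#' @param ubl basal rate (U/h)
#' @param model_params \code{patient_params} used for the internal
#'   plasma-insulin estimator (nominal model, not the plant)
#' @return object of class \code{controller_state}
#' @export
controller_init <- function(cfg, ubl, model_params = patient_params()) {
  c_b <- ubl / 60 / cfg$kdia
  upm <- ubl / 60
  ipss <- 1000 * upm / (model_params$kf * model_params$Vi)
  structure(list(c1 = c_b, c2 = c_b, nu_f = 0, Gvref = cfg$Gref,
                 prev_cgm = NA_real_, prev_cgm2 = NA_real_,
                 prev_iob = 2 * c_b,
                 # internal insulin-estimator compartments (nominal model)
                 est_S1 = upm * model_params$tmaxI,
                 est_S2 = upm * model_params$tmaxI,
                 ip_hat = ipss, ipss_hat = ipss,
                 model = model_params, ubl = ubl),
            class = "controller_state")
}

#' PD control action
#'
#' \eqn{u = k_p [e + \tau_d\,dG/dt] + u_{bl} + u_{bolus}} with
#' \eqn{e = CGM - G_{vref}}; the result is clamped at zero (the pump cannot
#' remove insulin). The bolus enters as an equivalent rate over one step.
#'
#' @param cgm current CGM (mg/dL)
#' @param dG_dt CGM rate of change (mg/dL/min)
#' @param cfg \code{controller_config}
#' @param st \code{controller_state} (supplies the virtual reference)
#' @param ubl basal rate (U/h)
#' @param ubolus bolus (U) injected this step as a rate over \code{dt}
#' @param dt step (min), used to convert the bolus to a rate
#' @return infusion command (U/h), >= 0
#' @export
pd_action <- function(cgm, dG_dt, cfg, st, ubl, ubolus = 0, dt = 5) {
  stopifnot(cgm > 0)
  e <- cgm - st$Gvref
  u <- cfg$kp * (e + cfg$tau_d * dG_dt) + ubl + ubolus * 60 / dt
  max(0, u)
}

#' Update the two-compartment IOB model
#'
#' Integrates \eqn{dc_1/dt = u - k_{dia} c_1},
#' \eqn{dc_2/dt = k_{dia}(c_1 - c_2)} (u in U/min) exactly over the step
#' (matrix exponential of the linear system), so steady state and impulse
#' responses hold to machine precision.
#'
#' @param st \code{controller_state}
#' @param u delivered infusion rate (U/h), bolus included as rate
#' @param kdia time constant (1/min)
#' @param dt step (min)
#' @return updated state; \code{iob_hat(st)} reads \eqn{c_1 + c_2}
#' @export
update_iob <- function(st, u, kdia, dt) {
  stopifnot(dt > 0)
  upm <- u / 60
  ek <- exp(-kdia * dt)
  c1_ss <- upm / kdia
  c1 <- c1_ss + (st$c1 - c1_ss) * ek
  # c2' = kdia (c1 - c2) with c1(t) known; exact convolution
  c2 <- c1_ss + (st$c2 - c1_ss) * ek + kdia * dt * (st$c1 - c1_ss) * ek
  st$prev_iob <- st$c1 + st$c2
  st$c1 <- c1
  st$c2 <- c2
  st
}

#' Estimated insulin on board
#' @param st \code{controller_state}
#' @return IOB (U)
#' @export
iob_hat <- function(st) st$c1 + st$c2

#' SAFE layer: sliding-mode reference conditioning
#'
#' Evaluates the sliding surface on the current IOB estimate, advances the
#' low-pass filter on the switching signal and returns the virtual glucose
#' reference \eqn{G_{vref} = G_{ref} + \nu_f}. Call after
#' \code{\link{update_iob}} for the step.
#'
#' @param st \code{controller_state}
#' @param cfg \code{controller_config}
#' @param dt step (min)
#' @return updated state with fields \code{nu_f}, \code{Gvref}
#' @export
safe_layer <- function(st, cfg, dt) {
  iob <- iob_hat(st)
  diob <- (iob - st$prev_iob) / dt
  s <- (iob - cfg$IOB_max) + cfg$tau_sm * diob  # constant bound: d/dt = 0
  nu <- if (s > 0) cfg$nu_plus else 0
  # exact first-order filter step toward nu
  st$nu_f <- nu + (st$nu_f - nu) * exp(-cfg$lam * dt)
  st$Gvref <- cfg$Gref + st$nu_f
  st
}

#' Insulin feedback (IFB) correction
#'
#' Attenuates the control action by the estimated plasma-insulin excess over
#' its basal steady state: \eqn{u_{IFB} = u - \eta(\hat i_p - \hat i_{pss})},
#' clamped at zero.
#'
#' @param u infusion command (U/h)
#' @param st \code{controller_state} carrying \code{ip_hat}, \code{ipss_hat}
#' @param eta feedback gain (U/h per mU/L)
#' @return corrected command (U/h), >= 0
#' @export
ifb_correction <- function(u, st, eta) {
  max(0, u - eta * (st$ip_hat - st$ipss_hat))
}

#' Advance the controller's plasma-insulin estimator
#'
#' Propagates the nominal subcutaneous/plasma insulin sub-model driven by
#' the insulin actually delivered, giving the online estimate used by IFB.
#'
#' @param st \code{controller_state}
#' @param u delivered rate (U/h)
#' @param dt step (min)
#' @return updated state
#' @export
update_insulin_estimator <- function(st, u, dt) {
  m <- st$model
  upm <- u / 60
  n <- max(1L, as.integer(ceiling(dt)))
  h <- dt / n
  S1 <- st$est_S1; S2 <- st$est_S2; ip <- st$ip_hat
  for (i in seq_len(n)) {
    dS1 <- upm - S1 / m$tmaxI
    dS2 <- (S1 - S2) / m$tmaxI
    dip <- -m$kf * ip + 1000 * S2 / (m$tmaxI * m$Vi)
    S1 <- S1 + h * dS1; S2 <- S2 + h * dS2; ip <- ip + h * dip
  }
  st$est_S1 <- S1; st$est_S2 <- S2; st$ip_hat <- ip
  st
}

#' One full controller tick
#'
#' Composes the per-sample sequence: CGM derivative (backward difference
#' over one 5-min sample), PD action against the current virtual reference,
#' IFB attenuation, pump saturation of the continuous part, IOB update with
#' the delivered insulin, SAFE reference update for the next sample, and the
#' plasma-insulin estimator.
#'
#' @param st \code{controller_state}
#' @param cgm CGM sample (mg/dL)
#' @param cfg \code{controller_config}
#' @param ubl basal rate (U/h)
#' @param ubolus bolus (U) to superimpose this step
#' @param dt sample period (min)
#' @return list(state, u = delivered rate U/h incl. bolus,
#'   u_cont = continuous part U/h)
#' @export
controller_step <- function(st, cgm, cfg, ubl, ubolus = 0, dt = 5) {
  # two-sample smoothed backward difference (attenuates sensor noise)
  dG <- if (!is.na(st$prev_cgm2)) (cgm - st$prev_cgm2) / (2 * dt)
        else if (!is.na(st$prev_cgm)) (cgm - st$prev_cgm) / dt
        else 0
  u_pd <- pd_action(cgm, dG, cfg, st, ubl, 0, dt)
  u_cont <- ifb_correction(u_pd, st, cfg$eta)
  u_cont <- min(u_cont, cfg$pump_max)
  u <- u_cont + ubolus * 60 / dt
  st <- update_iob(st, u, cfg$kdia, dt)
  st <- safe_layer(st, cfg, dt)
  st <- update_insulin_estimator(st, u, dt)
  st$prev_cgm2 <- st$prev_cgm
  st$prev_cgm <- cgm
  list(state = st, u = u, u_cont = u_cont)
}
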