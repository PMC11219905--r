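# Virtual patient: extended Bergman minimal model with subcutaneous insulin
# absorption, a two-compartment meal-absorption chain, circadian insulin
# sensitivity, and CGM sensing on a 5-min grid.

#' Physiological parameters of a virtual patient
#'
#' Constructs the parameter set of the minimal-model virtual patient. The
#' glucose subsystem is the Bergman model
#' \deqn{dG_{pl}/dt = -(p_1 + X)G_{pl} + p_1 G_{bl} + D(t)/V_g}
#' with remote insulin action \eqn{X}, plasma insulin \eqn{I} fed by a
#' two-compartment subcutaneous chain (\eqn{S_1, S_2}, time constant
#' \code{tmaxI}), a first-order subcutaneous glucose sensor compartment
#' (\code{tau_s}, gain \code{g_s}) and meal glucose appearance \eqn{D(t)}
#' from a two-compartment absorption chain with time-to-peak
#' \code{tmax_meal} and fractional bioavailability \code{bioavailability}.
#'
#' \code{Gbl} is the glucose asymptote in the absence of insulin; under the
#' basal infusion \code{ubl} the model settles at a lower operating glucose
#' (about 120 mg/dL with the defaults). Defaults are anchored to clinical
#' rules of thumb for an adult with type 1 diabetes (correction drop per
#' unit near 1800/TDI, 60 g meal excursion on the order of 100 mg/dL).
#'
#' @param p1 insulin-independent glucose utilisation rate (1/min)
#' @param p2 remote-insulin disappearance rate (1/min)
#' @param p3 insulin sensitivity (1/min^2 per mU/L)
#' @param Gbl zero-insulin basal glucose asymptote (mg/dL), in [70, 180]
#' @param body_weight body weight (kg)
#' @param Vg glucose distribution volume (dL); default 1.6 dL/kg
#' @param Vi insulin distribution volume (L); default 0.12 L/kg
#' @param kf fractional plasma-insulin disappearance rate (1/min)
#' @param tmaxI time-to-maximum of subcutaneous insulin absorption (min)
#' @param kdia insulin-action (duration-of-insulin-action) time constant
#'   (1/min); default gives roughly 4 h of action
#' @param tau_s subcutaneous sensor time constant (min)
#' @param g_s sensor static gain (dimensionless, ~1)
#' @param TDI total daily insulin requirement (U): basal plus full coverage
#'   of a nominal 210 g/day meal load; anchors controller gain, guideline
#'   therapy (CR = 500/TDI, CF = 1800/TDI) and the bolus action grids
#' @param ubl basal insulin infusion (U/h)
#' @param tmax_meal time-to-peak of meal absorption (min)
#' @param bioavailability fraction of ingested CHO reaching plasma
#' @param glucose_floor lower clamp for plasma glucose (mg/dL)
#' @return object of class \code{patient_params} (named list)
#' @export
patient_params <- function(p1 = 0.01, p2 = 0.02, p3 = 2.5e-5,
                           Gbl = 170, body_weight = 70,
                           Vg = 1.6 * body_weight, Vi = 0.12 * body_weight,
                           kf = 0.138, tmaxI = 55, kdia = 0.025,
                           tau_s = 10, g_s = 1,
                           TDI = 30, ubl = 0.232,
                           tmax_meal = 40, bioavailability = 0.8,
                           glucose_floor = 20) {
  p <- list(p1 = p1, p2 = p2, p3 = p3, Gbl = Gbl,
            body_weight = body_weight, Vg = Vg, Vi = Vi,
            kf = kf, tmaxI = tmaxI, kdia = kdia,
            tau_s = tau_s, g_s = g_s, TDI = TDI, ubl = ubl,
            tmax_meal = tmax_meal, bioavailability = bioavailability,
            glucose_floor = glucose_floor)
  rates <- c("p1", "p2", "p3", "kf", "kdia")
  if (any(unlist(p[rates]) <= 0))
    stop("all rate parameters must be strictly positive")
  if (Gbl < 70 || Gbl > 180)
    stop("Gbl must lie in [70, 180] mg/dL")
  if (TDI <= 0) stop("TDI must be positive")
  if (any(c(Vg, Vi, tmaxI, tau_s, tmax_meal) <= 0))
    stop("volumes and time constants must be positive")
  class(p) <- "patient_params"
  p
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Minimal-model virtual patient\n")
  cat(sprintf("  p1 = %.4g /min, p2 = %.4g /min, p3 = %.3g /min^2 per mU/L\n",
              x$p1, x$p2, x$p3))
  cat(sprintf("  Gbl = %.0f mg/dL, Vg = %.0f dL, Vi = %.1f L, BW = %.0f kg\n",
              x$Gbl, x$Vg, x$Vi, x$body_weight))
  cat(sprintf("  TDI = %.1f U, basal = %.2f U/h, DIA constant kdia = %.3g /min\n",
              x$TDI, x$ubl, x$kdia))
  invisible(x)
}

.state_names <- c("Gpl", "Gs", "X", "I", "S1", "S2", "M1", "M2")

#' Basal steady state of the virtual patient
#'
#' Analytic fixed point of the model at constant infusion \code{u} (U/h) and
#' no meal: \eqn{S_1 = S_2 = u\,t_{maxI}}, \eqn{I = 1000 u /(k_f V_i)} (with
#' u in U/min), \eqn{X = p_3 I / p_2}, \eqn{G_{pl} = p_1 G_{bl}/(p_1 + X)}.
#'
#' @param params \code{patient_params}
#' @param u infusion rate (U/h); defaults to the patient's basal
#' @return named state vector (class \code{patient_state})
#' @export
patient_steady_state <- function(params, u = params$ubl) {
  upm <- u / 60                              # U/min
  S1 <- upm * params$tmaxI
  S2 <- S1
  I <- 1000 * upm / (params$kf * params$Vi)  # mU/L
  X <- params$p3 * I / params$p2
  Gpl <- params$p1 * params$Gbl / (params$p1 + X)
  st <- c(Gpl = Gpl, Gs = params$g_s * Gpl, X = X, I = I,
          S1 = S1, S2 = S2, M1 = 0, M2 = 0)
  class(st) <- c("patient_state", "numeric")
  st
}

# Time derivative of the patient state. insulin U/min, meal g/min.
# p3_eff allows circadian modulation; tmax_meal_eff per-meal absorption rate.
patient_deriv <- function(s, p, insulin_upm, meal_gpm, p3_eff, tmax_meal_eff) {
  D <- p$bioavailability * 1000 * s[[8]] / tmax_meal_eff   # mg/min
  c(-(p$p1 + s[[3]]) * s[[1]] + p$p1 * p$Gbl + D / p$Vg,
    (p$g_s * s[[1]] - s[[2]]) / p$tau_s,
    -p$p2 * s[[3]] + p3_eff * s[[4]],
    -p$kf * s[[4]] + 1000 * s[[6]] / (p$tmaxI * p$Vi),
    insulin_upm - s[[5]] / p$tmaxI,
    (s[[5]] - s[[6]]) / p$tmaxI,
    meal_gpm - s[[7]] / tmax_meal_eff,
    (s[[7]] - s[[8]]) / tmax_meal_eff)
}

#' Advance the virtual patient one step
#'
#' Integrates the patient ODEs with fixed-step fourth-order Runge-Kutta,
#' holding the insulin infusion and meal ingestion rates constant over the
#' step. Substeps of at most \code{ode_dt} minutes are used internally.
#'
#' @param state named state vector from \code{\link{patient_steady_state}}
#'   (elements Gpl, Gs, X, I, S1, S2, M1, M2)
#' @param params \code{patient_params}
#' @param insulin_rate infusion rate (U/h), >= 0
#' @param meal_rate carbohydrate ingestion rate (g/min), >= 0
#' @param dt step length (min)
#' @param p3_eff effective insulin sensitivity for this step (circadian
#'   modulation); defaults to \code{params$p3}
#' @param tmax_meal_eff effective meal time-to-peak for this step (min);
#'   defaults to \code{params$tmax_meal}
#' @param ode_dt internal RK4 substep (min)
#' @return updated state vector
#' @export
step_patient <- function(state, params, insulin_rate, meal_rate, dt,
                         p3_eff = params$p3,
                         tmax_meal_eff = params$tmax_meal,
                         ode_dt = 1) {
  stopifnot(dt > 0, insulin_rate >= 0, meal_rate >= 0)
  s <- unclass(state)
  upm <- insulin_rate / 60
  n <- max(1L, as.integer(ceiling(dt / ode_dt)))
  h <- dt / n
  for (i in seq_len(n)) {
    k1 <- patient_deriv(s, params, upm, meal_rate, p3_eff, tmax_meal_eff)
    k2 <- patient_deriv(s + h / 2 * k1, params, upm, meal_rate, p3_eff, tmax_meal_eff)
    k3 <- patient_deriv(s + h / 2 * k2, params, upm, meal_rate, p3_eff, tmax_meal_eff)
    k4 <- patient_deriv(s + h * k3, params, upm, meal_rate, p3_eff, tmax_meal_eff)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (any(!is.finite(s)))
    stop("patient state became non-finite; check inputs and step size")
  if (s[[1]] < params$glucose_floor) {
    warning("plasma glucose clamped at floor (", params$glucose_floor, " mg/dL)")
    s[[1]] <- params$glucose_floor
  }
  # compartment masses cannot go negative
  s[3:8] <- pmax(s[3:8], 0)
  names(s) <- .state_names
  class(s) <- c("patient_state", "numeric")
  s
}

#' Ingest a meal as an impulse into the absorption chain
#'
#' Adds \code{cho} grams to the first meal compartment. The per-meal
#' \code{absorption_rate_multiplier} rescales the absorption time constant
#' used from this meal onward (>1 means faster absorption).
#'
#' @param state patient state
#' @param cho carbohydrate mass (g), > 0
#' @return updated state
#' @export
ingest_meal <- function(state, cho) {
  stopifnot(cho > 0)
  state[["M1"]] <- state[["M1"]] + cho
  state
}

#' Intrapatient variability configuration
#'
#' @param si_amplitude fractional circadian amplitude of insulin sensitivity
#'   p3, in [0, 1)
#' @param si_phase circadian phase (min since midnight); the default puts
#'   the sensitivity minimum near 04:00 (dawn phenomenon)
#' @param absorption_cv coefficient of variation of the per-meal absorption
#'   rate multiplier (log-normal, mean 1)
#' @param cgm_noise_sd additive CGM noise standard deviation (mg/dL)
#' @param seed integer seed for the variability stream
#' @return object of class \code{variability_config}
#' @export
variability_config <- function(si_amplitude = 0.2, si_phase = 600,
                               absorption_cv = 0.2, cgm_noise_sd = 2,
                               seed = 1L) {
  stopifnot(si_amplitude >= 0, si_amplitude < 1,
            absorption_cv >= 0, cgm_noise_sd >= 0)
  structure(list(si_amplitude = si_amplitude, si_phase = si_phase,
                 absorption_cv = absorption_cv, cgm_noise_sd = cgm_noise_sd,
                 seed = as.integer(seed)),
            class = "variability_config")
}

#' Circadian effective insulin sensitivity
#'
#' \eqn{p_3(t) = p_3 (1 + a \sin(2\pi (t - \phi)/1440))}; period 24 h,
#' bounded in \eqn{[p_3(1-a), p_3(1+a)]}.
#'
#' @param params \code{patient_params}
#' @param time_min time since midnight (min; any real, wraps every 1440)
#' @param vcfg \code{variability_config}
#' @return effective p3
#' @export
circadian_p3 <- function(params, time_min, vcfg) {
  params$p3 * (1 + vcfg$si_amplitude *
                 sin(2 * pi * (time_min - vcfg$si_phase) / 1440))
}

#' Sample the CGM
#'
#' Returns the subcutaneous glucose plus additive Gaussian noise, clamped to
#' be non-negative. Uses the current R RNG stream.
#'
#' @param state patient state
#' @param noise_sd noise standard deviation (mg/dL)
#' @param floor lower clamp (mg/dL), >= 0
#' @return CGM reading (mg/dL)
#' @export
sample_cgm <- function(state, noise_sd = 2, floor = 0) {
  stopifnot(noise_sd >= 0, floor >= 0)
  g <- state[["Gs"]]
  if (noise_sd > 0) g <- g + stats::rnorm(1, 0, noise_sd)
  max(floor, g)
}

# run expr under a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a meal scenario
#'
#' Training scenarios have three meals per day at fixed clock times
#' (breakfast 08:00 with 30-50 g, lunch 14:00 with 50-70 g, dinner 20:00
#' with 60-80 g CHO). Testing scenarios have four meals per day (breakfast
#' 07:00 30-50 g, lunch 13:00 50-70 g, snack 17:00 30-50 g, dinner 20:00
#' 60-80 g) with uniform +/- 30 min jitter on every meal time. CHO is drawn
#' uniformly within its range; each meal receives a log-normal absorption
#' rate multiplier (mean 1, CV \code{absorption_cv}).
#'
#' @param kind "training" or "testing"
#' @param days number of days, >= 1
#' @param seed integer seed; the same seed reproduces the same scenario
#' @param absorption_cv CV of the per-meal absorption multiplier
#' @return data.frame with columns day, label, time_of_day (min since
#'   midnight), time_min (min since simulation start), cho (g),
#'   absorption_rate_multiplier, announced
#' @export
generate_scenario <- function(kind = c("training", "testing"), days, seed,
                              absorption_cv = 0.2) {
  kind <- match.arg(kind)
  stopifnot(days >= 1)
  proto <- if (kind == "training") {
    data.frame(label = c("breakfast", "lunch", "dinner"),
               tod = c(8, 14, 20) * 60,
               lo = c(30, 50, 60), hi = c(50, 70, 80),
               jitter = 0)
  } else {
    data.frame(label = c("breakfast", "lunch", "snack", "dinner"),
               tod = c(7, 13, 17, 20) * 60,
               lo = c(30, 50, 30, 60), hi = c(50, 70, 50, 80),
               jitter = 30)
  }
  with_seed(seed, {
    n <- nrow(proto)
    out <- do.call(rbind, lapply(seq_len(days), function(d) {
      jit <- if (proto$jitter[1] > 0)
        stats::runif(n, -proto$jitter, proto$jitter) else rep(0, n)
      tod <- proto$tod + jit
      cho <- stats::runif(n, proto$lo, proto$hi)
      mult <- if (absorption_cv > 0) {
        sdl <- sqrt(log(1 + absorption_cv^2))
        stats::rlnorm(n, -sdl^2 / 2, sdl)
      } else rep(1, n)
      data.frame(day = d, label = proto$label, time_of_day = tod,
                 time_min = (d - 1) * 1440 + tod, cho = cho,
                 absorption_rate_multiplier = mult, announced = TRUE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Total daily insulin requirement of a patient
#'
#' Basal delivery plus full coverage of a nominal daily meal load,
#' estimated from the model's own physiology: the peak glucose rise of a
#' 60 g meal and the peak drop of a 1 U bolus are probed by short
#' open-loop simulations at basal, and the prandial requirement is the
#' daily CHO load divided by the implied grams-per-unit, with a 15%
#' allowance for corrections.
#'
#' @param params \code{patient_params}
#' @param daily_cho nominal daily carbohydrate load (g)
#' @return TDI requirement (U/day)
#' @export
insulin_requirement <- function(params, daily_cho = 210) {
  st <- patient_steady_state(params)
  s <- st; s[["S1"]] <- s[["S1"]] + 1
  drop <- 0
  g0 <- st[["Gpl"]]
  for (i in 1:72) {
    s <- step_patient(s, params, params$ubl, 0, 5)
    drop <- max(drop, g0 - s[["Gpl"]])
  }
  s <- ingest_meal(st, 60)
  rise <- 0
  for (i in 1:72) {
    s <- step_patient(s, params, params$ubl, 0, 5)
    rise <- max(rise, s[["Gpl"]] - g0)
  }
  24 * params$ubl + 1.15 * (daily_cho / 60) * rise / drop
}

#' Generate a synthetic patient cohort
#'
#' Produces \code{n} parameter sets by log-normal jitter (default CV 15%)
#' around the package defaults, with the basal infusion re-solved per
#' patient so that every patient's basal operating glucose equals
#' \code{G_op}, and TDI set to the patient's insulin requirement
#' (\code{\link{insulin_requirement}}).
#'
#' @param n number of patients
#' @param seed master seed
#' @param cv coefficient of variation of the jitter
#' @param G_op basal operating glucose (mg/dL)
#' @return list of \code{patient_params}
#' @export
make_cohort <- function(n, seed = 1L, cv = 0.15, G_op = 120) {
  base <- patient_params()
  sdl <- sqrt(log(1 + cv^2))
  jit <- function(x) x * stats::rlnorm(1, -sdl^2 / 2, sdl)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p1 <- jit(base$p1); p2 <- jit(base$p2); p3 <- jit(base$p3)
      kf <- jit(base$kf); tmaxI <- jit(base$tmaxI)
      Vg <- jit(base$Vg); Vi <- jit(base$Vi)
      tmax_meal <- jit(base$tmax_meal)
      Gbl <- min(180, max(100, base$Gbl * stats::rlnorm(1, 0, 0.03)))
      # solve basal infusion for the target operating glucose
      X_need <- p1 * (Gbl - G_op) / G_op
      I_need <- X_need * p2 / p3
      ubl <- I_need * kf * Vi * 60 / 1000
      pp <- patient_params(p1 = p1, p2 = p2, p3 = p3, Gbl = Gbl,
                           body_weight = base$body_weight, Vg = Vg, Vi = Vi,
                           kf = kf, tmaxI = tmaxI, kdia = base$kdia,
                           tau_s = base$tau_s, g_s = base$g_s,
                           TDI = base$TDI, ubl = ubl,
                           tmax_meal = tmax_meal,
                           bioavailability = base$bioavailability)
      pp$TDI <- insulin_requirement(pp)
      pp
    })
  })
}
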