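# Unannounced-meal detector: unscented Kalman filter over the minimal model
# augmented with a random-walk disturbance state D (meal glucose appearance,
# mg/min), plus a cross-covariance trigger between CGM and the forward
# difference of D, with night suppression and a refractory hold-off.

#' Detector tuning presets
#'
#' The three named settings trade sensitivity against false positives
#' through the trigger threshold \code{T} and cross-covariance window
#' \code{m}. Threshold values were calibrated in-package on synthetic traces
#' (trade-off: >= 90% sensitivity on 60 g meals with <= 1 false positive per
#' day and median latency in the 30-40 min band).
#'
#' @param mode one of "highest_sensitivity", "trade_off", "lowest_fp"
#' @param threshold trigger threshold on the raw cross-covariance
#'   ((mg/dL)(mg/min)); overrides the preset
#' @param window_len cross-covariance window m (5-min samples), >= 3
#' @param night_start,night_end night suppression window bounds (hours);
#'   flags are suppressed for clock times in [night_start, night_end)
#' @param refractory_min hold-off after a detection (min)
#' @return object of class \code{detector_tuning}
#' @export
detector_tuning <- function(mode = c("trade_off", "highest_sensitivity",
                                     "lowest_fp"),
                            threshold = NULL, window_len = NULL,
                            night_start = 23, night_end = 6,
                            refractory_min = 120) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    highest_sensitivity = list(T = 100, m = 12L),
    trade_off           = list(T = 300, m = 12L),
    lowest_fp           = list(T = 500, m = 12L))
  T <- if (is.null(threshold)) preset$T else threshold
  m <- if (is.null(window_len)) preset$m else as.integer(window_len)
  stopifnot(T > 0, m >= 3)
  structure(list(mode = mode, threshold = T, window_len = m,
                 night_start = night_start, night_end = night_end,
                 refractory_min = refractory_min),
            class = "detector_tuning")
}

#' Initialise the meal detector
#'
#' The filter state is the augmented vector
#' \eqn{[G_{pl}, G_s, X, I, S_1, S_2, D]} started at the basal steady state
#' of the detector's internal model (which may deliberately differ from the
#' plant) with \eqn{D = 0}.
#'
#' @param model \code{patient_params} owned by the detector (nominal model)
#' @param ubl basal rate (U/h) used for initialisation
#' @param tuning \code{detector_tuning}
#' @param q_diag process-noise standard deviations per 5-min step for
#'   (Gpl, Gs, X, I, S1, S2, D); D is a random walk
#' @param r_sd measurement (CGM) noise standard deviation (mg/dL)
#' @param ut_alpha,ut_beta,ut_kappa scaled unscented-transform parameters
#' @param ode_dt RK4 substep (min) for sigma-point propagation
#' @return object of class \code{detector_state}
#' @export
detector_init <- function(model = patient_params(), ubl = model$ubl,
                          tuning = detector_tuning(),
                          q_diag = c(1, 1, 1e-5, 0.5, 0.02, 0.02, 30),
                          r_sd = 2,
                          ut_alpha = 1e-3, ut_beta = 2, ut_kappa = 0,
                          ode_dt = 5) {
  ss <- patient_steady_state(model, ubl)
  x0 <- c(ss[["Gpl"]], ss[["Gs"]], ss[["X"]], ss[["I"]],
          ss[["S1"]], ss[["S2"]], 0)
  P0 <- diag(c(4, 4, 1e-8, 1, 1e-3, 1e-3, 25))
  structure(list(x = x0, P = P0, Q = diag(q_diag^2), R = r_sd^2,
                 model = model, tuning = tuning,
                 ut = list(alpha = ut_alpha, beta = ut_beta,
                           kappa = ut_kappa), ode_dt = ode_dt,
                 gs_buf = numeric(0), dd_buf = numeric(0),
                 prev_D = 0, consecutive_hits = 0L,
                 last_flag_time = -Inf, cross_cov = NA_real_),
            class = "detector_state")
}

# deriv of the augmented 7-state model; X is a 7 x k matrix of sigma points
det_deriv <- function(X, m, upm) {
  rbind(-(m$p1 + X[3, ]) * X[1, ] + m$p1 * m$Gbl + X[7, ] / m$Vg,
        (m$g_s * X[1, ] - X[2, ]) / m$tau_s,
        -m$p2 * X[3, ] + m$p3 * X[4, ],
        -m$kf * X[4, ] + 1000 * X[6, ] / (m$tmaxI * m$Vi),
        upm - X[5, ] / m$tmaxI,
        (X[5, ] - X[6, ]) / m$tmaxI,
        rep(0, ncol(X)))
}

# RK4 propagation of a sigma-point matrix over dt minutes (1-min substeps)
det_propagate <- function(X, m, insulin_rate, dt, ode_dt = 5) {
  upm <- insulin_rate / 60
  n <- max(1L, as.integer(ceiling(dt / ode_dt)))
  h <- dt / n
  for (i in seq_len(n)) {
    k1 <- det_deriv(X, m, upm)
    k2 <- det_deriv(X + h / 2 * k1, m, upm)
    k3 <- det_deriv(X + h / 2 * k2, m, upm)
    k4 <- det_deriv(X + h * k3, m, upm)
    X <- X + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  X
}

# Cholesky with symmetrisation and escalating jitter
safe_chol <- function(P) {
  P <- (P + t(P)) / 2
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    ch <- tryCatch(chol(P + diag(j, nrow(P))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("detector covariance lost positive-definiteness beyond repair")
}

#' One UKF predict/update step of the meal detector
#'
#' Propagates scaled sigma points through the augmented model (D held as a
#' random walk over the step), updates against the CGM measurement (which
#' observes the Gs component linearly), and appends the CGM value and the
#' forward difference of the disturbance estimate to the trigger buffers.
#'
#' @param det \code{detector_state}
#' @param cgm CGM sample (mg/dL)
#' @param insulin_rate insulin delivered over the elapsed interval (U/h)
#' @param dt sample period (min), normally 5
#' @return updated \code{detector_state}; field \code{cross_cov} holds the
#'   current trigger statistic (NA while the window is warming up)
#' @export
ukf_step <- function(det, cgm, insulin_rate, dt = 5) {
  n <- 7L
  ut <- det$ut
  lambda <- ut$alpha^2 * (n + ut$kappa) - n
  gamma <- sqrt(n + lambda)
  Wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  Wc <- Wm
  Wc[1] <- Wc[1] + 1 - ut$alpha^2 + ut$beta

  S <- t(safe_chol(det$P))             # lower triangular
  X <- cbind(det$x, det$x + gamma * S, det$x - gamma * S)
  X <- det_propagate(X, det$model, insulin_rate, dt, det$ode_dt)
  x_pred <- drop(X %*% Wm)
  dX <- X - x_pred
  P_pred <- dX %*% (t(dX) * Wc) + det$Q
  P_pred <- (P_pred + t(P_pred)) / 2

  # measurement z = Gs + v is linear: exact Kalman update
  Sz <- P_pred[2, 2] + det$R
  K <- P_pred[, 2] / Sz
  innov <- cgm - x_pred[2]
  x_new <- x_pred + K * innov
  P_new <- P_pred - outer(K, P_pred[2, ])
  P_new <- (P_new + t(P_new)) / 2

  d_diff <- x_new[7] - det$prev_D
  det$prev_D <- x_new[7]
  det$x <- x_new
  det$P <- P_new

  m <- det$tuning$window_len
  det$gs_buf <- c(det$gs_buf, cgm)
  det$dd_buf <- c(det$dd_buf, d_diff)
  if (length(det$gs_buf) > m) {
    det$gs_buf <- det$gs_buf[-1]
    det$dd_buf <- det$dd_buf[-1]
  }
  det$cross_cov <- if (length(det$gs_buf) == m)
    cross_cov_stat(det$gs_buf, det$dd_buf) else NA_real_
  det$consecutive_hits <- if (!is.na(det$cross_cov) &&
                              det$cross_cov >= det$tuning$threshold)
    det$consecutive_hits + 1L else 0L
  det
}

#' Raw cross-covariance of two buffered sequences at one lag
#'
#' Biased (1/m-normalised) cross-covariance of the mean-removed sequences,
#' \deqn{c(l) = \frac{1}{m} \sum_n (G_s(n+l) - \bar G_s)(D_{diff}(n) - \bar D_{diff})}
#' where m is the buffer length.
#'
#' @param gs_buffer CGM buffer (length m)
#' @param ddiff_buffer disturbance forward-difference buffer (length m)
#' @param lag non-negative lag l < m
#' @return cross-covariance value ((mg/dL)(mg/min))
#' @export
cross_covariance <- function(gs_buffer, ddiff_buffer, lag = 0) {
  m <- length(gs_buffer)
  stopifnot(length(ddiff_buffer) == m, lag >= 0, lag < m)
  g <- gs_buffer - mean(gs_buffer)
  d <- ddiff_buffer - mean(ddiff_buffer)
  idx <- seq_len(m - lag)
  sum(g[idx + lag] * d[idx]) / m
}

# trigger statistic: maximum raw cross-covariance over lags 0..(m-1)
cross_cov_stat <- function(gs_buffer, ddiff_buffer) {
  m <- length(gs_buffer)
  max(vapply(0:(m - 1L), function(l)
    cross_covariance(gs_buffer, ddiff_buffer, l), numeric(1)))
}

# clock (min since midnight) falls inside [night_start, night_end) hours?
is_night <- function(clock_min, night_start = 23, night_end = 6) {
  tod <- clock_min %% 1440
  a <- night_start * 60; b <- night_end * 60
  if (a <= b) tod >= a & tod < b else tod >= a | tod < b
}

#' Evaluate the meal-detection flag
#'
#' True iff the cross-covariance statistic met the threshold on the last
#' three consecutive samples (15 min), the disturbance estimate is rising
#' (\eqn{D_{diff}(k) > 0}), CGM rose over the last three samples
#' (\eqn{G_s(k) - G_s(k-3) > 0}), the clock is outside the night window
#' [23:00, 06:00), and the refractory hold-off since the previous flag has
#' elapsed. Call once per sample after \code{\link{ukf_step}}.
#'
#' @param det \code{detector_state}
#' @param clock_min time of day (min since simulation start; wraps daily)
#' @return list(flag = logical, det = updated state)
#' @export
meal_flag <- function(det, clock_min) {
  tun <- det$tuning
  nb <- length(det$gs_buf)
  flag <- FALSE
  if (nb >= 4 && det$consecutive_hits >= 3L) {
    dd_k <- det$dd_buf[nb]
    rise <- det$gs_buf[nb] - det$gs_buf[nb - 3L]
    if (dd_k > 0 && rise > 0 &&
        !is_night(clock_min, tun$night_start, tun$night_end) &&
        (clock_min - det$last_flag_time) >= tun$refractory_min) {
      flag <- TRUE
      det$last_flag_time <- clock_min
      det$consecutive_hits <- 0L
    }
  }
  list(flag = flag, det = det)
}

#' Score detections against true meals
#'
#' A flag within \code{association_window} minutes after a true meal is a
#' true positive with latency flag time minus meal time (each flag matches
#' at most one meal and vice versa, earliest first); unmatched flags are
#' false positives and unmatched meals false negatives.
#'
#' @param meal_times true meal times (min since start)
#' @param flag_times detection times (min since start)
#' @param association_window matching window (min)
#' @return list(TP, FP, FN, sensitivity (%), latencies (min))
#' @export
score_detections <- function(meal_times, flag_times,
                             association_window = 120) {
  meal_times <- sort(meal_times)
  flag_times <- sort(flag_times)
  used <- logical(length(flag_times))
  lat <- numeric(0)
  for (mt in meal_times) {
    j <- which(!used & flag_times >= mt &
                 flag_times <= mt + association_window)
    if (length(j)) {
      used[j[1]] <- TRUE
      lat <- c(lat, flag_times[j[1]] - mt)
    }
  }
  TP <- length(lat)
  FN <- length(meal_times) - TP
  FP <- sum(!used)
  sens <- if (length(meal_times)) 100 * TP / (TP + FN) else NA_real_
  list(TP = TP, FP = FP, FN = FN, sensitivity = sens, latencies = lat)
}
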