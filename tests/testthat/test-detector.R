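# UKF meal detector: estimator behaviour, cross-covariance trigger,
# night suppression, detection scoring.

make_stream <- function(days, seed, noise = 2, meals = TRUE) {
  p <- patient_params()
  sc <- if (meals) generate_scenario("training", days, seed = seed)
        else generate_scenario("training", 1, seed = seed)[0, ]
  v <- variability_config(cgm_noise_sd = noise)
  sim <- simulate_loop(p, sc, days, arm = "pd_only", vcfg = v, seed = seed)
  insulin <- c(p$ubl, utils::head(sim$trace$basal_U_per_h +
                                    sim$trace$bolus_U * 12, -1))
  list(trace = sim$trace, insulin = insulin, scenario = sc, params = p)
}

run_detector <- function(stream, tuning = detector_tuning()) {
  det <- detector_init(tuning = tuning)
  n <- nrow(stream$trace)
  flags <- numeric(0)
  D <- cc <- numeric(n)
  for (k in seq_len(n)) {
    det <- ukf_step(det, stream$trace$cgm[k], stream$insulin[k], 5)
    mf <- meal_flag(det, stream$trace$time_min[k])
    det <- mf$det
    if (mf$flag) flags <- c(flags, stream$trace$time_min[k])
    D[k] <- det$x[7]; cc[k] <- det$cross_cov
  }
  list(flags = flags, D = D, cc = cc)
}

test_that("with no disturbance the D estimate stays near zero", {
  stream <- make_stream(1, seed = 21, noise = 0, meals = FALSE)
  out <- run_detector(stream)
  expect_true(all(abs(out$D) < 3 * 30))   # within 3 sd of its process noise
  expect_length(out$flags, 0)
})

test_that("a meal drives the disturbance estimate up with positive increments", {
  stream <- make_stream(1, seed = 22, noise = 0)
  out <- run_detector(stream)
  mt <- stream$scenario$time_min[1]
  k0 <- which(stream$trace$time_min >= mt)[1]
  rise <- out$D[k0 + 8] - out$D[k0]       # 40 min after the meal
  expect_gt(rise, 50)
  expect_gt(max(out$D), 200)
})

test_that("UKF tracks a near-linear regime like a linearized Kalman filter", {
  # with insulin action pinned (p3 ~ 0) the model is linear in the state;
  # an exact Kalman filter on the same matrices is the oracle
  model <- patient_params(p3 = 1e-12)
  det <- detector_init(model, tuning = detector_tuning())
  n <- 7
  # build the linear ODE matrix of [Gpl, Gs, X, I, S1, S2, D]
  A <- matrix(0, n, n)
  A[1, 1] <- -model$p1; A[1, 7] <- 1 / model$Vg
  A[2, 1] <- model$g_s / model$tau_s; A[2, 2] <- -1 / model$tau_s
  A[3, 3] <- -model$p2
  A[4, 4] <- -model$kf; A[4, 6] <- 1000 / (model$tmaxI * model$Vi)
  A[5, 5] <- -1 / model$tmaxI
  A[6, 5] <- 1 / model$tmaxI; A[6, 6] <- -1 / model$tmaxI
  cvec <- c(model$p1 * model$Gbl, 0, 0, 0, model$ubl / 60, 0, 0)
  # exact discretization of the affine system via the augmented matrix
  aug <- rbind(cbind(A, cvec), 0)
  Phi <- as.matrix(Matrix::expm(aug * 5))
  Ad <- Phi[1:n, 1:n]; Bd <- Phi[1:n, n + 1]
  H <- matrix(0, 1, n); H[1, 2] <- 1
  x <- det$x; P <- det$P
  cgm_stream <- rep(det$x[2], 12) + c(0, 0, 1, 3, 8, 15, 20, 22, 20, 15, 10, 6)
  for (k in seq_along(cgm_stream)) {
    det <- ukf_step(det, cgm_stream[k], model$ubl, 5)
    x <- Ad %*% x + Bd
    P <- Ad %*% P %*% t(Ad) + det$Q
    S <- drop(H %*% P %*% t(H)) + det$R
    K <- P %*% t(H) / S
    x <- x + K * drop(cgm_stream[k] - H %*% x)
    P <- P - K %*% H %*% P
    expect_equal(drop(det$x), drop(x), tolerance = 0.02)
  }
})

test_that("cross-covariance of constant sequences is zero", {
  expect_identical(cross_covariance(rep(5, 10), rep(3, 10), 0), 0)
})

test_that("cross-covariance matches the direct formula on a proportional pair", {
  set.seed(12)
  gs <- rnorm(12, 120, 10)
  a <- 0.7
  dd <- a * (gs - mean(gs))
  expect_equal(cross_covariance(gs, dd, 0),
               a * sum((gs - mean(gs))^2) / 12)
  expect_gt(cross_covariance(gs, dd, 0), 0)
})

test_that("independent white sequences have near-zero mean cross-covariance", {
  set.seed(13)
  vals <- replicate(2000, cross_covariance(rnorm(12), rnorm(12), 0))
  expect_lt(abs(mean(vals)), 3 / sqrt(2000))
})

test_that("night window is inclusive at 23:00 and exclusive at 06:00", {
  night <- faidsim:::is_night
  expect_true(night(23 * 60))
  expect_true(night(0))
  expect_true(night(5 * 60 + 59))
  expect_false(night(6 * 60))
  expect_false(night(22 * 60 + 59))
  expect_true(night(1440 + 23 * 60))      # wraps daily
})

test_that("meal flag needs all trigger conditions and respects the night window", {
  tun <- detector_tuning(threshold = 10)
  base <- detector_init(tuning = tun)
  base$gs_buf <- c(rep(100, 8), 104, 108, 112, 116)
  base$dd_buf <- c(rep(0, 8), 5, 6, 7, 8)
  base$consecutive_hits <- 3L
  expect_true(meal_flag(base, 12 * 60)$flag)                 # noon: fires
  expect_false(meal_flag(base, 2 * 60)$flag)                 # night: suppressed
  falling <- base
  falling$gs_buf <- rev(base$gs_buf)                         # CGM not rising
  expect_false(meal_flag(falling, 12 * 60)$flag)
  negdd <- base; negdd$dd_buf[12] <- -1                      # D not rising
  expect_false(meal_flag(negdd, 12 * 60)$flag)
  few <- base; few$consecutive_hits <- 2L                    # < 3 hits
  expect_false(meal_flag(few, 12 * 60)$flag)
})

test_that("a detection starts a refractory hold-off", {
  tun <- detector_tuning(threshold = 10, refractory_min = 120)
  det <- detector_init(tuning = tun)
  det$gs_buf <- c(rep(100, 8), 104, 108, 112, 116)
  det$dd_buf <- c(rep(0, 8), 5, 6, 7, 8)
  det$consecutive_hits <- 3L
  out <- meal_flag(det, 12 * 60)
  expect_true(out$flag)
  det2 <- out$det
  det2$consecutive_hits <- 3L
  expect_false(meal_flag(det2, 12 * 60 + 30)$flag)           # within hold-off
  expect_true(meal_flag(det2, 12 * 60 + 125)$flag)           # after hold-off
})

test_that("lowering the threshold never decreases the number of flags", {
  stream <- make_stream(2, seed = 24)
  n_lo <- length(run_detector(stream, detector_tuning(threshold = 100))$flags)
  n_mid <- length(run_detector(stream, detector_tuning(threshold = 300))$flags)
  n_hi <- length(run_detector(stream, detector_tuning(threshold = 600))$flags)
  expect_gte(n_lo, n_mid)
  expect_gte(n_mid, n_hi)
})

test_that("detection scoring separates TP, FP, FN and latency", {
  meals <- c(420, 780, 1200)
  perfect <- score_detections(meals, meals + 35)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$FP, 0)
  expect_equal(unique(perfect$latencies), 35)
  none <- score_detections(meals, numeric(0))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$FN, 3)
  spurious <- score_detections(meals, c(meals[1] + 20, 180))
  expect_equal(spurious$TP, 1)
  expect_equal(spurious$FP, 1)
  expect_equal(spurious$FN, 2)
})
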