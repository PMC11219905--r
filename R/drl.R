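# Deep-RL bolus calculator primitives: RL state construction from CGM
# windows, pre-meal glucose banding into subaction spaces (SAS), discrete
# bolus menus, bolus-on-board safety adjustment, the immediate reward, and
# the replay memory / multi-DQN bank.

#' Build the 15-dimensional RL state from a 4-h CGM window
#'
#' State = (Gmax, Gmin, the 12 most recent CGM samples, AUC), where AUC is
#' the area of the CGM excursion outside [70, 180] mg/dL over the window
#' (sample-and-hold integration at 5 min, absolute distance from the
#' violated bound, hypo- and hyperglycemic excesses summed). For a
#' pre-prandial anchor the window is the 4 h up to the detection; for a
#' post-prandial anchor the 4 h after it; the 12 samples are the last hour
#' of the window in both cases.
#'
#' @param cgm_window exactly 48 five-minute CGM samples (mg/dL), oldest first
#' @param anchor "pre-prandial" or "post-prandial" (semantics only; the
#'   computation is identical)
#' @return numeric vector of length 15, class \code{rl_state}
#' @export
build_state <- function(cgm_window,
                        anchor = c("pre-prandial", "post-prandial")) {
  anchor <- match.arg(anchor)
  if (length(cgm_window) != 48L)
    stop("cgm_window must contain exactly 48 samples (4 h at 5 min)")
  auc <- 5 * sum(pmax(cgm_window - 180, 0) + pmax(70 - cgm_window, 0))
  s <- c(max(cgm_window), min(cgm_window),
         rev(cgm_window[37:48]), auc)
  class(s) <- c("rl_state", "numeric")
  s
}

# network input scaling (glucose features ~O(1), AUC likewise)
norm_state <- function(s) c(unclass(s)[1:14] / 180, unclass(s)[15] / 1000)

#' Select the subaction space from the pre-meal CGM value
#'
#' The eight half-open glucose bands: >= 200 -> 1, [180, 200) -> 2,
#' [160, 180) -> 3, [140, 160) -> 4, [120, 140) -> 5, [100, 120) -> 6,
#' [80, 100) -> 7, < 80 -> 8. The bands partition (0, Inf).
#'
#' @param g_bm CGM sample immediately before the (detected) meal (mg/dL)
#' @return SAS index in 1..8
#' @export
select_sas <- function(g_bm) {
  stopifnot(g_bm > 0)
  if (g_bm >= 200) 1L
  else if (g_bm >= 180) 2L
  else if (g_bm >= 160) 3L
  else if (g_bm >= 140) 4L
  else if (g_bm >= 120) 5L
  else if (g_bm >= 100) 6L
  else if (g_bm >= 80) 7L
  else 8L
}

# band midpoints used to seed correction components of the action grids
.sas_mid <- c(220, 190, 170, 150, 130, 110, 90, 70)

#' Discrete bolus menu for one (meal, SAS) pair
#'
#' Fifteen non-negative, non-decreasing bolus magnitudes anchored to the
#' patient's therapy: a power-curve grid from 0 to \code{max_mult} times
#' the guideline meal bolus (mean meal CHO / CR), shifted upward by the
#' guideline correction for the band midpoint when it exceeds 120 mg/dL,
#' and scaled down in the lowest band (pre-meal hypoglycemia).
#'
#' @param meal "breakfast", "lunch" or "dinner"
#' @param sas_index SAS index 1..8
#' @param TDI total daily insulin (U); CR = 500/TDI, CF = 1800/TDI
#' @param n_actions number of actions (15)
#' @param max_mult top of the grid as a multiple of the guideline bolus
#' @param curve exponent shaping the grid (denser at small boluses)
#' @param meal_cho nominal CHO (g) per meal used for the guideline bolus
#' @return numeric vector of \code{n_actions} bolus magnitudes (U)
#' @export
action_grid <- function(meal, sas_index, TDI, n_actions = 15L,
                        max_mult = 1.8, curve = 1.3,
                        meal_cho = c(breakfast = 40, lunch = 60,
                                     dinner = 70)) {
  stopifnot(meal %in% names(meal_cho), sas_index %in% 1:8, TDI > 0)
  CR <- 500 / TDI
  CF <- 1800 / TDI
  guideline <- meal_cho[[meal]] / CR
  f <- max_mult * (seq(0, 1, length.out = n_actions))^curve
  shift <- max(0, (.sas_mid[sas_index] - 120)) / CF
  scale <- if (sas_index == 8L) 0.6 else 1
  a <- pmax(0, f * guideline * scale + shift)
  a[1] <- 0           # the no-bolus action is always available
  stopifnot(!is.unsorted(a))
  a
}

#' Epsilon-greedy action selection
#'
#' With probability \code{epsilon} a uniform random index; otherwise the
#' argmax of the Q-values, ties broken by the lowest index (the smaller
#' bolus).
#'
#' @param qvals numeric vector of Q-values (one per action)
#' @param epsilon exploration probability in [0, 1]
#' @return action index
#' @export
choose_action <- function(qvals, epsilon = 0) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon)
    sample.int(length(qvals), 1L)
  else
    which.max(qvals)        # first maximum = lowest index
}

#' Bolus-on-board safety adjustment
#'
#' The five-branch piecewise adjustment of the selected bolus \code{a_j}
#' against the estimated bolus insulin on board:
#' \itemize{
#' \item \code{a_j > BOB/k} and \code{G_BM >= 180}: deliver
#'   \code{a_j - BOB/k};
#' \item \code{a_j < BOB/k} and \code{140 <= G_BM < 180}: decrease by 5\%;
#' \item \code{a_j < BOB/k} and \code{120 <= G_BM < 140}: decrease by 10\%;
#' \item \code{a_j < BOB/k} and \code{80 <= G_BM < 120}: decrease by 20\%;
#' \item otherwise: deliver \code{a_j} unchanged.
#' }
#' The result is clamped at zero.
#'
#' @param a_j selected bolus (U)
#' @param bob_hat estimated bolus insulin on board (U)
#' @param k_bob scaling hyperparameter (> 0)
#' @param g_bm pre-meal CGM (mg/dL)
#' @return adjusted bolus (U)
#' @export
adjust_bolus <- function(a_j, bob_hat, k_bob, g_bm) {
  stopifnot(a_j >= 0, bob_hat >= 0, k_bob > 0, g_bm > 0)
  ratio <- bob_hat / k_bob
  u <- if (a_j > ratio && g_bm >= 180) a_j - ratio
  else if (a_j < ratio && g_bm >= 140 && g_bm < 180) a_j * 0.95
  else if (a_j < ratio && g_bm >= 120 && g_bm < 140) a_j * 0.90
  else if (a_j < ratio && g_bm >= 80 && g_bm < 120) a_j * 0.80
  else a_j
  max(0, u)
}

#' Immediate reward from the postprandial window
#'
#' Piecewise reward on the postprandial glucose extrema. Hypoglycemia takes
#' precedence: if \code{g_minp < 70} the minimum-glucose branch applies
#' regardless of the maximum. Codomain:
#' \{50, 20, 10, -5, -15, -20, -30, -40, -50, -60, -70, -80\}.
#'
#' @param g_maxp maximum CGM in the 4-h postprandial window (mg/dL)
#' @param g_minp minimum CGM in the window (mg/dL)
#' @return reward (dimensionless)
#' @export
compute_reward <- function(g_maxp, g_minp) {
  stopifnot(g_minp <= g_maxp)
  if (g_minp < 70) {
    if (g_minp >= 65) -30
    else if (g_minp >= 60) -40
    else if (g_minp >= 55) -50
    else if (g_minp >= 50) -60
    else if (g_minp >= 45) -70
    else -80
  } else {
    if (g_maxp < 180) 50
    else if (g_maxp < 200) 20
    else if (g_maxp < 230) 10
    else if (g_maxp < 250) -5
    else if (g_maxp < 300) -15
    else -20
  }
}

#' Meal label from clock time
#'
#' Time-of-day bins: [05:00, 11:00) breakfast, [11:00, 17:00) lunch,
#' [17:00, 23:00) dinner. A detection in the residual night hours is routed
#' to the nearest meal bank (before 02:00 dinner, otherwise breakfast).
#'
#' @param clock_min time (min); wraps daily
#' @return "breakfast", "lunch" or "dinner"
#' @export
meal_label <- function(clock_min) {
  tod <- clock_min %% 1440
  if (tod >= 300 && tod < 660) "breakfast"
  else if (tod >= 660 && tod < 1020) "lunch"
  else if (tod >= 1020 && tod < 1380) "dinner"
  else if (tod < 120 || tod >= 1380) "dinner"
  else "breakfast"
}

# ---- replay memory ---------------------------------------------------------

new_memory <- function(capacity = 5000L) {
  structure(list(buf = vector("list", 0L), capacity = capacity),
            class = "replay_memory")
}

memory_push <- function(mem, exp) {
  mem$buf[[length(mem$buf) + 1L]] <- exp
  if (length(mem$buf) > mem$capacity) mem$buf <- mem$buf[-1L]
  mem
}

# uniform mini-batch without replacement
memory_sample <- function(mem, batch_size) {
  n <- length(mem$buf)
  stopifnot(n >= batch_size)
  mem$buf[sample.int(n, batch_size)]
}

# ---- multi-DQN bank --------------------------------------------------------

.meals <- c("breakfast", "lunch", "dinner")

dqn_key <- function(meal, sas) paste0(meal, "_", sas)

#' Create a multi-DQN bank (24 networks: 3 meals x 8 SAS)
#'
#' Each (meal, SAS) pair owns a Q-network, a frozen target copy, a replay
#' memory and its action grid. Networks are 15-28-28-28-15 fully connected.
#'
#' @param TDI patient total daily insulin (U), anchors the action grids
#' @param seed master seed; each network gets a derived seed
#' @param capacity replay-memory capacity per DQN
#' @param k_bob per-(meal, SAS) BOB-scaling hyperparameter; scalar or an
#'   8 x 3 matrix (rows SAS, columns breakfast/lunch/dinner)
#' @param ... passed to \code{\link{action_grid}}
#' @return object of class \code{dqn_bank}
#' @export
dqn_bank <- function(TDI, seed = 1L, capacity = 5000L, k_bob = 1, ...) {
  if (length(k_bob) == 1L)
    k_bob <- matrix(k_bob, 8, 3, dimnames = list(NULL, .meals))
  bank <- list()
  i <- 0L
  for (meal in .meals) for (sas in 1:8) {
    i <- i + 1L
    key <- dqn_key(meal, sas)
    net <- qnet_init(seed = seed * 1000L + i)
    bank[[key]] <- list(meal = meal, sas = sas,
                        net = net, target = qnet_weights(net),
                        memory = new_memory(capacity),
                        grid = action_grid(meal, sas, TDI, ...))
  }
  structure(list(dqns = bank, TDI = TDI, k_bob = k_bob, seed = seed,
                 n_updates = 0L),
            class = "dqn_bank")
}

#' Greedy (or epsilon-greedy) bolus from the bank for a detected meal
#'
#' Composes state construction, SAS selection, action choice and the BOB
#' adjustment: the full bolus decision of the automatic system.
#'
#' @param bank \code{dqn_bank}
#' @param cgm_window 48-sample pre-prandial CGM window, oldest first
#' @param clock_min time of the detection (min)
#' @param bob_hat estimated bolus insulin on board (U)
#' @param epsilon exploration probability (0 = greedy deployment)
#' @return list(bolus, meal, sas, action, a_j, g_bm, state)
#' @export
faid_bolus <- function(bank, cgm_window, clock_min, bob_hat,
                       epsilon = 0) {
  meal <- meal_label(clock_min)
  g_bm <- cgm_window[length(cgm_window)]
  sas <- select_sas(g_bm)
  s <- build_state(cgm_window, "pre-prandial")
  d <- bank$dqns[[dqn_key(meal, sas)]]
  # a network that never accrued enough replay data to train defers to the
  # nearest trained band of the same meal; with none, no bolus (the
  # continuous controller compensates)
  sas_used <- sas
  if (d$net$t == 0L && epsilon == 0) {   # deployment only; training explores
    trained <- Filter(function(k) bank$dqns[[k]]$net$t > 0L,
                      sapply(1:8, function(ss) dqn_key(meal, ss)))
    if (length(trained)) {
      ss_tr <- vapply(trained, function(k) bank$dqns[[k]]$sas, integer(1))
      sas_used <- ss_tr[which.min(abs(ss_tr - sas))]
      d <- bank$dqns[[dqn_key(meal, sas_used)]]
    } else {
      return(list(bolus = 0, meal = meal, sas = sas, action = 1L,
                  a_j = 0, g_bm = g_bm, state = s))
    }
  }
  q <- drop(qnet_forward(d$net, matrix(norm_state(s), 1)))
  j <- choose_action(q, epsilon)
  a_j <- d$grid[j]
  u <- adjust_bolus(a_j, bob_hat, bank$k_bob[sas_used, meal], g_bm)
  list(bolus = u, meal = meal, sas = sas, action = j, a_j = a_j,
       g_bm = g_bm, state = s)
}

# BOB two-compartment update (bolus channel only); exact over the step
bob_update <- function(bob, bolus_U, kdia, dt) {
  upm <- bolus_U / dt
  ek <- exp(-kdia * dt)
  css <- upm / kdia
  b1 <- css + (bob[1] - css) * ek
  b2 <- css + (bob[2] - css) * ek + kdia * dt * (bob[1] - css) * ek
  c(b1, b2)
}
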