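# Training of the multi-DQN bolus calculator: replay-memory generation by
# random acting, then iterative epsilon-greedy training with experience
# replay and periodically synchronized target networks.

#' Convert bolus events of an episode into experiences
#'
#' For each DRL bolus event the reward window is the 4 h after the bolus,
#' truncated at the next bolus event or the episode end. The reward is the
#' piecewise function of the window's CGM extrema; the next state is built
#' from the 48 samples ending at the window end.
#'
#' @param trace episode trace (5-min grid)
#' @param events event list from \code{\link{simulate_loop}}
#' @return list of experiences: list(key, s, a, r, s_next, terminal,
#'   next_key, s_next_decision); the last bolus event of an episode is
#'   terminal (its value does not bootstrap into the night), and earlier
#'   events record the network and pre-prandial state of the next bolus
#'   decision, which is where their value actually continues
#' @export
build_experiences <- function(trace, events) {
  n <- nrow(trace)
  cgm <- trace$cgm
  ticks <- vapply(events, function(e) e$tick, numeric(1))
  out <- vector("list", length(events))
  for (i in seq_along(events)) {
    e <- events[[i]]
    k <- e$tick
    end <- min(k + 48L, n)
    nxt <- ticks[ticks > k]
    if (length(nxt)) end <- min(end, min(nxt))
    if (end <= k) next
    win <- cgm[(k + 1L):end]
    r <- compute_reward(max(win), min(win))
    lo <- max(1L, end - 47L)
    w2 <- cgm[lo:end]
    if (length(w2) < 48L) w2 <- c(rep(w2[1], 48L - length(w2)), w2)
    s_next <- build_state(w2, "post-prandial")
    nxt_ev <- if (length(nxt)) events[[which(ticks == min(nxt))[1]]] else NULL
    out[[i]] <- list(key = dqn_key(e$meal, e$sas), s = e$state,
                     a = e$action, r = r, s_next = s_next,
                     terminal = !length(nxt),
                     next_key = if (is.null(nxt_ev)) NA_character_ else
                       dqn_key(nxt_ev$meal, nxt_ev$sas),
                     s_next_decision = if (is.null(nxt_ev)) NULL else
                       nxt_ev$state)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Training configuration for the DRL bolus calculator
#'
#' @param gamma discount factor in [0, 1)
#' @param alpha learning rate
#' @param batch_size replay mini-batch size
#' @param target_sync_period iterations between target-network syncs
#' @param memory_days days of random acting used to seed the replay memory
#' @param iterations training iterations (one simulated day each)
#' @param epsilon_start,epsilon_end linear exploration schedule
#' @param updates_per_event gradient steps per bolus event
#' @param consolidation_steps offline replay updates per network after the
#'   online phase (fits rarely-acting networks to their data)
#' @return list of class \code{train_config}
#' @export
train_config <- function(gamma = 0.9, alpha = 1e-3, batch_size = 32L,
                         target_sync_period = 15L,
                         memory_days = 1500L, iterations = 1500L,
                         epsilon_start = 1.0, epsilon_end = 0.05,
                         updates_per_event = 2L,
                         consolidation_steps = 300L) {
  stopifnot(gamma >= 0, gamma < 1, alpha > 0, batch_size >= 1,
            epsilon_start >= epsilon_end, epsilon_end >= 0,
            epsilon_start <= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Seed the replay memories by random acting
#'
#' Simulates \code{days} independent training-protocol days (three fixed
#' meals) with actions drawn uniformly from the selected SAS, and stores
#' one experience per bolus event in the memory of the (meal, SAS) network
#' that acted. In announced mode every meal produces an event; in
#' unannounced mode only detected meals do.
#'
#' @param params plant \code{patient_params}
#' @param bank \code{dqn_bank}
#' @param days number of memory days
#' @param seed master seed
#' @param announced announced meals (TRUE) or detector-driven (FALSE)
#' @param vcfg \code{variability_config}
#' @param tuning \code{detector_tuning} (unannounced mode)
#' @return updated bank, with attribute \code{n_experiences}
#' @export
generate_memory <- function(params, bank, days, seed = 1L,
                            announced = TRUE,
                            vcfg = variability_config(),
                            tuning = detector_tuning()) {
  arm <- if (announced) "haid_drl" else "faid"
  total <- 0L
  for (d in seq_len(days)) {
    sc <- generate_scenario("training", 1, seed = seed * 100000L + d,
                            absorption_cv = vcfg$absorption_cv)
    # one protocol day plus 4 h so the dinner postprandial window completes
    sim <- simulate_loop(params, sc, 336 / 288, arm = arm, vcfg = vcfg,
                         bank = bank, tuning = tuning,
                         random_actions = TRUE,
                         seed = seed * 100000L + 50000L + d)
    exps <- build_experiences(sim$trace, sim$events)
    for (x in exps) {
      bank$dqns[[x$key]]$memory <- memory_push(bank$dqns[[x$key]]$memory, x)
      total <- total + 1L
    }
  }
  small <- vapply(bank$dqns, function(d) length(d$memory$buf), integer(1))
  attr(bank, "n_experiences") <- total
  attr(bank, "memory_sizes") <- small
  bank
}

# One replay update of a single DQN. The Bellman continuation of a bolus
# decision is the next bolus decision, taken by the next event's network at
# its own pre-prandial state, so the max term is evaluated by that
# network's frozen target copy (strictly in-distribution); the last event
# of an episode is terminal. Rewards are scaled to O(1) for the regression
# (a monotone rescaling of Q; argmax unaffected).
dqn_replay_update <- function(d, cfg, bank) {
  if (length(d$memory$buf) < cfg$batch_size) return(list(d = d, loss = NA_real_))
  batch <- memory_sample(d$memory, cfg$batch_size)
  X <- t(vapply(batch, function(x) norm_state(x$s), numeric(15)))
  r <- vapply(batch, function(x) x$r, numeric(1))
  a <- vapply(batch, function(x) x$a, integer(1))
  cont <- numeric(length(batch))
  for (i in seq_along(batch)) {
    x <- batch[[i]]
    if (isTRUE(x$terminal) || is.null(x$next_key) || is.na(x$next_key)) next
    nd <- bank$dqns[[x$next_key]]
    tgt <- qnet_set_weights(nd$net, nd$target)
    cont[i] <- max(qnet_forward(tgt, matrix(norm_state(x$s_next_decision), 1)))
  }
  y <- r / 80 + cfg$gamma * cont
  up <- qnet_train_step(d$net, X, a, y, lr = cfg$alpha)
  d$net <- up$net
  list(d = d, loss = up$loss)
}

#' Train the multi-DQN bolus calculator
#'
#' Seeds the replay memories by random acting, then runs training
#' iterations. Each iteration simulates one closed-loop day under the
#' current epsilon-greedy policy, stores the day's experiences, performs
#' replay updates on the networks that acted, and synchronizes every target
#' network with its online network every \code{target_sync_period}
#' iterations. The per-day hypoglycemia event count, mean reward, mean loss
#' and epsilon are logged.
#'
#' @param params plant \code{patient_params}
#' @param cfg \code{train_config}
#' @param seed master seed
#' @param announced train with announced meals (default) or with the
#'   detector in the loop
#' @param vcfg \code{variability_config}
#' @param tuning \code{detector_tuning}
#' @param k_bob BOB-scaling hyperparameter passed to \code{\link{dqn_bank}}
#' @param verbose print progress every 50 iterations
#' @return object of class \code{faid_policy}: the trained bank, the
#'   training log and the configuration
#' @export
drl_train <- function(params, cfg = train_config(), seed = 1L,
                      announced = TRUE, vcfg = variability_config(),
                      tuning = detector_tuning(), k_bob = 1,
                      verbose = FALSE) {
  bank <- dqn_bank(params$TDI, seed = seed, k_bob = k_bob)
  bank <- generate_memory(params, bank, cfg$memory_days, seed = seed,
                          announced = announced, vcfg = vcfg,
                          tuning = tuning)
  arm <- if (announced) "haid_drl" else "faid"
  eps_sched <- seq(cfg$epsilon_start, cfg$epsilon_end,
                   length.out = max(cfg$iterations, 2L))
  log <- data.frame(iteration = integer(0), epsilon = numeric(0),
                    hypo_events = integer(0), mean_reward = numeric(0),
                    mean_loss = numeric(0))
  for (it in seq_len(cfg$iterations)) {
    eps <- eps_sched[it]
    sc <- generate_scenario("training", 1,
                            seed = seed * 100000L + 70000L + it,
                            absorption_cv = vcfg$absorption_cv)
    sim <- simulate_loop(params, sc, 336 / 288, arm = arm, vcfg = vcfg,
                         bank = bank, tuning = tuning, epsilon = eps,
                         seed = seed * 100000L + 80000L + it)
    exps <- build_experiences(sim$trace, sim$events)
    losses <- numeric(0)
    for (x in exps) {
      bank$dqns[[x$key]]$memory <-
        memory_push(bank$dqns[[x$key]]$memory, x)
      for (u in seq_len(cfg$updates_per_event)) {
        up <- dqn_replay_update(bank$dqns[[x$key]], cfg, bank)
        bank$dqns[[x$key]] <- up$d
        if (is.finite(up$loss)) losses <- c(losses, up$loss)
      }
    }
    if (it %% cfg$target_sync_period == 0L) {
      for (key in names(bank$dqns))
        bank$dqns[[key]]$target <- qnet_weights(bank$dqns[[key]]$net)
    }
    log <- rbind(log, data.frame(
      iteration = it, epsilon = eps,
      hypo_events = hypo_events(sim$trace$cgm),
      mean_reward = if (length(exps))
        mean(vapply(exps, function(x) x$r, numeric(1))) else NA_real_,
      mean_loss = if (length(losses)) mean(losses) else NA_real_))
    if (verbose && it %% 50L == 0L)
      message(sprintf("iter %d  eps %.2f  hypo %d  reward %.1f",
                      it, eps, log$hypo_events[it], log$mean_reward[it]))
  }
  # consolidation: networks only receive online updates when they act, so
  # rarely-acting (meal, band) pairs can end underfitted to their replay
  # data; finish with offline replay epochs on every trainable network
  for (key in names(bank$dqns)) {
    if (length(bank$dqns[[key]]$memory$buf) < cfg$batch_size) next
    for (k in seq_len(cfg$consolidation_steps)) {
      up <- dqn_replay_update(bank$dqns[[key]], cfg, bank)
      bank$dqns[[key]] <- up$d
      if (k %% cfg$target_sync_period == 0L)
        bank$dqns[[key]]$target <- qnet_weights(bank$dqns[[key]]$net)
    }
    bank$dqns[[key]]$target <- qnet_weights(bank$dqns[[key]]$net)
  }
  structure(list(bank = bank, log = log, config = cfg,
                 params = params, seed = seed, announced = announced),
            class = "faid_policy")
}

#' @export
print.faid_policy <- function(x, ...) {
  cat("Trained DRL bolus calculator (multi-DQN)\n")
  cat(sprintf("  %d networks (3 meals x 8 SAS), 15-28-28-28-15 fully connected\n",
              length(x$bank$dqns)))
  cat(sprintf("  trained %d iterations on %d memory days (%s meals)\n",
              nrow(x$log), x$config$memory_days,
              if (x$announced) "announced" else "detected"))
  cat(sprintf("  patient TDI %.1f U; final epsilon %.2f\n",
              x$params$TDI, utils::tail(x$log$epsilon, 1)))
  invisible(x)
}

#' @export
summary.faid_policy <- function(object, ...) {
  lg <- object$log
  dec <- max(1L, floor(nrow(lg) / 10))
  first <- lg$hypo_events[seq_len(dec)]
  last <- lg$hypo_events[(nrow(lg) - dec + 1L):nrow(lg)]
  out <- list(
    iterations = nrow(lg),
    hypo_first_decile = stats::median(first),
    hypo_last_decile = stats::median(last),
    mean_reward_first = mean(lg$mean_reward[seq_len(dec)], na.rm = TRUE),
    mean_reward_last = mean(lg$mean_reward[(nrow(lg) - dec + 1L):nrow(lg)],
                            na.rm = TRUE),
    memory_sizes = vapply(object$bank$dqns,
                          function(d) length(d$memory$buf), integer(1)))
  class(out) <- "summary.faid_policy"
  out
}

#' @export
print.summary.faid_policy <- function(x, ...) {
  cat(sprintf("Training: %d iterations\n", x$iterations))
  cat(sprintf("  daily hypoglycemia events, median: first decile %.1f -> last decile %.1f\n",
              x$hypo_first_decile, x$hypo_last_decile))
  cat(sprintf("  mean per-meal reward: %.1f -> %.1f\n",
              x$mean_reward_first, x$mean_reward_last))
  cat(sprintf("  replay memories: %d-%d experiences per active DQN\n",
              min(x$memory_sizes[x$memory_sizes > 0]),
              max(x$memory_sizes)))
  invisible(x)
}

#' Greedy bolus prediction from a trained policy
#'
#' @param object \code{faid_policy}
#' @param cgm_window 48-sample pre-prandial CGM window, oldest first
#' @param clock_min time of the (detected) meal (min)
#' @param bob_hat estimated bolus insulin on board (U)
#' @param ... unused
#' @return list(bolus, meal, sas, action, ...) as \code{\link{faid_bolus}}
#' @export
predict.faid_policy <- function(object, cgm_window, clock_min,
                                bob_hat = 0, ...) {
  faid_bolus(object$bank, cgm_window, clock_min, bob_hat, epsilon = 0)
}

#' Simulate the closed loop under a trained policy
#'
#' @param object \code{faid_policy}
#' @param nsim number of episodes
#' @param seed RNG seed
#' @param days days per episode
#' @param arm "faid" (detector-driven) or "haid_drl" (announced)
#' @param scenario optional meal scenario; default a testing scenario
#' @param ... passed to \code{\link{simulate_loop}}
#' @return a single episode list, or a list of episodes if \code{nsim > 1}
#' @export
simulate.faid_policy <- function(object, nsim = 1, seed = 1L, days = 14,
                                 arm = c("faid", "haid_drl"),
                                 scenario = NULL, ...) {
  arm <- match.arg(arm)
  runs <- lapply(seq_len(nsim), function(i) {
    sc <- if (is.null(scenario))
      generate_scenario("testing", days, seed = seed + i - 1L) else scenario
    simulate_loop(object$params, sc, days, arm = arm, bank = object$bank,
                  seed = seed + 1000L * i, ...)
  })
  if (nsim == 1) runs[[1]] else runs
}

#' Training-progress plot (daily hypoglycemia events)
#'
#' @param x \code{faid_policy}
#' @param window smoothing window (iterations) for the running median
#' @param ... passed to \code{plot}
#' @export
plot.faid_policy <- function(x, window = 25L, ...) {
  lg <- x$log
  plot(lg$iteration, lg$hypo_events, pch = 16, cex = 0.4, col = "grey60",
       xlab = "training iteration (day)",
       ylab = "hypoglycemia events / day", ...)
  if (nrow(lg) >= window) {
    rm <- stats::runmed(lg$hypo_events, k = window - (1 - window %% 2))
    graphics::lines(lg$iteration, rm, lwd = 2)
  }
  invisible(x)
}
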