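# DRL bolus calculator primitives: state, SAS bands, action choice, BOB
# adjustment, reward, replay memory and Q-network training mechanics.

test_that("state construction reproduces hand-computed windows", {
  flat <- rep(120, 48)
  s <- build_state(flat)
  expect_length(s, 15)
  expect_equal(unclass(s), c(120, 120, rep(120, 12), 0))

  high <- rep(200, 48)
  s <- build_state(high)
  expect_equal(s[[1]], 200)
  expect_equal(s[[2]], 200)
  expect_equal(s[[15]], 20 * 240)          # constant 20 mg/dL excess, 4 h

  ramp <- seq(100, 190, length.out = 48)
  s <- build_state(ramp)
  expect_equal(s[[1]], 190)
  expect_equal(s[[2]], 100)
  expect_equal(s[[15]], 5 * sum(pmax(ramp - 180, 0)))  # brute-force sum
  expect_true(all(s[3:14] >= s[[2]] & s[3:14] <= s[[1]]))

  expect_error(build_state(rep(120, 47)), "48")
})

test_that("hypoglycemic excursions count toward the AUC with absolute distance", {
  w <- rep(120, 48); w[1:6] <- 60
  expect_equal(build_state(w)[[15]], 5 * 6 * 10)
})

test_that("SAS bands partition glucose exactly as printed", {
  expect_identical(select_sas(210), 1L)
  expect_identical(select_sas(200), 1L)
  expect_identical(select_sas(180), 2L)
  expect_identical(select_sas(199.9), 2L)
  expect_identical(select_sas(160), 3L)
  expect_identical(select_sas(140), 4L)
  expect_identical(select_sas(120), 5L)
  expect_identical(select_sas(100), 6L)
  expect_identical(select_sas(80), 7L)
  expect_identical(select_sas(79), 8L)
  # every positive glucose maps to exactly one band
  g <- seq(1, 400, by = 0.5)
  idx <- vapply(g, select_sas, integer(1))
  expect_true(all(idx %in% 1:8))
  expect_true(all(diff(idx) <= 0))         # monotone non-increasing in g
})

test_that("epsilon-greedy selection is uniform at epsilon 1 and greedy at 0", {
  set.seed(31)
  draws <- replicate(15000, choose_action(rnorm(15), epsilon = 1))
  tab <- table(factor(draws, levels = 1:15))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  q <- rep(0, 15); q[7] <- 1
  expect_identical(choose_action(q, 0), 7L)
  q2 <- rep(0, 15); q2[c(3, 9)] <- 2
  expect_identical(choose_action(q2, 0), 3L)   # tie -> lowest index
})

test_that("BOB adjustment reproduces all five branches and the clamp", {
  expect_equal(adjust_bolus(5, bob_hat = 2, k_bob = 1, g_bm = 200), 3)
  expect_equal(adjust_bolus(4, bob_hat = 5, k_bob = 1, g_bm = 150), 4 * 0.95)
  expect_equal(adjust_bolus(4, bob_hat = 5, k_bob = 1, g_bm = 130), 4 * 0.90)
  expect_equal(adjust_bolus(4, bob_hat = 5, k_bob = 1, g_bm = 100), 4 * 0.80)
  expect_equal(adjust_bolus(4, bob_hat = 3, k_bob = 1, g_bm = 150), 4)
  expect_equal(adjust_bolus(4, bob_hat = 5, k_bob = 1, g_bm = 70), 4)
  # a_j below the on-board ratio at high glucose matches no reduction branch
  expect_identical(adjust_bolus(1, bob_hat = 10, k_bob = 1, g_bm = 250), 1)
  # the subtraction branch never undershoots zero by construction
  expect_gte(adjust_bolus(5.01, bob_hat = 5, k_bob = 1, g_bm = 250), 0)
  # k_bob rescales the on-board ratio
  expect_equal(adjust_bolus(5, bob_hat = 2, k_bob = 2, g_bm = 200), 4)
})

test_that("reward reproduces the printed piecewise values with hypo precedence", {
  expect_equal(compute_reward(150, 100), 50)
  expect_equal(compute_reward(190, 100), 20)
  expect_equal(compute_reward(210, 100), 10)
  expect_equal(compute_reward(240, 100), -5)
  expect_equal(compute_reward(260, 100), -15)
  expect_equal(compute_reward(320, 100), -20)
  expect_equal(compute_reward(150, 67), -30)
  expect_equal(compute_reward(150, 62), -40)
  expect_equal(compute_reward(150, 57), -50)
  expect_equal(compute_reward(150, 52), -60)
  expect_equal(compute_reward(150, 47), -70)
  expect_equal(compute_reward(150, 40), -80)
  expect_equal(compute_reward(260, 40), -80)     # hypo precedence
  # map is total with codomain exactly the 12 printed values
  set.seed(32)
  gmin <- runif(4000, 20, 300)
  gmax <- gmin + runif(4000, 0, 150)
  r <- mapply(compute_reward, gmax, gmin)
  expect_true(all(r %in% c(50, 20, 10, -5, -15, -20,
                           -30, -40, -50, -60, -70, -80)))
})

test_that("action grids are non-negative, non-decreasing and therapy-scaled", {
  for (meal in c("breakfast", "lunch", "dinner")) for (sas in 1:8) {
    g <- action_grid(meal, sas, TDI = 30)
    expect_length(g, 15)
    expect_true(all(g >= 0))
    expect_true(!is.unsorted(g))
  }
  # high-glucose bands are shifted upward by the guideline correction
  # (from the second action; the no-bolus action stays 0 in every band)
  expect_identical(action_grid("lunch", 1, 30)[1], 0)
  expect_gt(action_grid("lunch", 1, 30)[2], action_grid("lunch", 6, 30)[2])
  # grids scale with meal size
  expect_gt(max(action_grid("dinner", 5, 30)), max(action_grid("breakfast", 5, 30)))
})

test_that("meal labelling follows the time-of-day bins", {
  expect_identical(meal_label(7.5 * 60), "breakfast")
  expect_identical(meal_label(5 * 60), "breakfast")
  expect_identical(meal_label(13 * 60), "lunch")
  expect_identical(meal_label(17 * 60), "dinner")
  expect_identical(meal_label(22.9 * 60), "dinner")
  expect_identical(meal_label(0.5 * 60), "dinner")    # night: nearest meal
  expect_identical(meal_label(4 * 60), "breakfast")
})

test_that("the bank has 24 networks with the contracted architecture", {
  bank <- dqn_bank(TDI = 30, seed = 1)
  expect_length(bank$dqns, 24)
  for (d in bank$dqns) {
    expect_identical(d$net$layers, c(15L, 28L, 28L, 28L, 15L))
    expect_length(d$net$W, 4)              # 5 layers = 4 weight matrices
    expect_identical(dim(d$net$W[[1]]), c(15L, 28L))
    expect_identical(dim(d$net$W[[4]]), c(28L, 15L))
    expect_length(d$grid, 15)
  }
  expect_identical(train_config()$target_sync_period, 15L)
})

test_that("replay memory respects capacity and samples without replacement", {
  mem <- faidsim:::new_memory(capacity = 5L)
  for (i in 1:8) mem <- faidsim:::memory_push(mem, list(id = i))
  expect_length(mem$buf, 5)
  expect_identical(mem$buf[[1]]$id, 4L)      # oldest dropped
  set.seed(5)
  batch <- faidsim:::memory_sample(mem, 5L)
  expect_setequal(vapply(batch, `[[`, numeric(1), "id"), 4:8)
})

test_that("Q-learning converges to the immediate reward without bootstrap", {
  net <- qnet_init(seed = 7)
  x <- faidsim:::norm_state(build_state(rep(150, 48)))
  X <- matrix(x, 1)
  for (i in 1:500) {
    st <- faidsim:::qnet_train_step(net, X, actions = 4L, targets = 50,
                                    lr = 5e-3)
    net <- st$net
  }
  expect_equal(qnet_forward(net, X)[1, 4], 50, tolerance = 0.5)
})

test_that("a gradient step decreases the loss on a fixed mini-batch", {
  set.seed(8)
  net <- qnet_init(seed = 8)
  X <- matrix(rnorm(32 * 15), 32, 15)
  a <- sample.int(15, 32, replace = TRUE)
  y <- runif(32, -80, 50)
  l0 <- faidsim:::qnet_train_step(net, X, a, y, lr = 1e-4)
  l1 <- faidsim:::qnet_train_step(l0$net, X, a, y, lr = 1e-4)
  expect_lt(l1$loss, l0$loss)
})

test_that("the trained greedy policy solves a two-state bandit exactly", {
  # two contexts with known best actions; brute-force optimum is the oracle
  rewards <- matrix(-20, 2, 15)
  rewards[1, 4] <- 50; rewards[2, 11] <- 50
  states <- rbind(faidsim:::norm_state(build_state(rep(100, 48))),
                  faidsim:::norm_state(build_state(rep(220, 48))))
  oracle <- apply(rewards, 1, which.max)
  net <- qnet_init(seed = 9)
  set.seed(9)
  for (i in 1:1500) {
    s <- sample(1:2, 1)
    a <- sample.int(15, 1)
    st <- faidsim:::qnet_train_step(net, states[s, , drop = FALSE], a,
                                    rewards[s, a], lr = 3e-3)
    net <- st$net
  }
  got <- apply(qnet_forward(net, states), 1, which.max)
  expect_identical(got, oracle)
})

test_that("the regression target is frozen between target-network syncs", {
  p <- patient_params()
  bank <- dqn_bank(p$TDI, seed = 2)
  key <- "lunch_5"
  # seed the memory with a fixed batch whose value continues at dinner_5
  set.seed(10)
  for (i in 1:40) {
    s <- build_state(rep(runif(1, 100, 200), 48))
    bank$dqns[[key]]$memory <- faidsim:::memory_push(
      bank$dqns[[key]]$memory,
      list(key = key, s = s, a = sample.int(15, 1),
           r = sample(c(50, -20), 1), s_next = s,
           terminal = FALSE, next_key = "dinner_5",
           s_next_decision = s))
  }
  d <- bank$dqns[[key]]
  tgt <- function(bank, key) {
    nd <- bank$dqns[[key]]
    tn <- faidsim:::qnet_set_weights(nd$net, nd$target)
    qnet_forward(tn, matrix(faidsim:::norm_state(
      bank$dqns[["lunch_5"]]$memory$buf[[1]]$s), 1))
  }
  before <- tgt(bank, "dinner_5")
  cfg <- train_config(batch_size = 32L)
  for (i in 1:10)
    bank$dqns[[key]] <- faidsim:::dqn_replay_update(bank$dqns[[key]], cfg,
                                                    bank)$d
  # online lunch net moved; the dinner target the regression bootstraps on
  # did not
  expect_false(identical(faidsim:::qnet_weights(bank$dqns[[key]]$net)$W,
                         bank$dqns[[key]]$target$W))
  expect_identical(tgt(bank, "dinner_5"), before)
  bank$dqns[["dinner_5"]]$target <-
    faidsim:::qnet_weights(bank$dqns[["dinner_5"]]$net)
  expect_identical(tgt(bank, "dinner_5"), before)  # dinner net untouched
})

test_that("experience building truncates reward windows at the next bolus", {
  cgm <- rep(120, 200)
  cgm[60:70] <- 250                          # excursion after the 2nd event
  trace <- data.frame(time_min = (0:199) * 5, cgm = cgm)
  ev <- list(list(tick = 10, meal = "lunch", sas = 5, action = 3,
                  state = build_state(rep(120, 48))),
             list(tick = 55, meal = "dinner", sas = 5, action = 3,
                  state = build_state(rep(120, 48))))
  xs <- build_experiences(trace, ev)
  expect_length(xs, 2)
  # first window [11, 55]: all 120 -> reward 50 (never sees the excursion)
  expect_equal(xs[[1]]$r, 50)
  # second window [56, 103]: contains the 250 spike -> reward -15
  expect_equal(xs[[2]]$r, -15)
  expect_length(xs[[2]]$s_next, 15)
})

test_that("an untrained band defers to the nearest trained band at deployment", {
  bank <- dqn_bank(TDI = 30, seed = 4)
  # mark lunch_4 as trained by giving it one update
  X <- matrix(faidsim:::norm_state(build_state(rep(150, 48))), 1)
  up <- faidsim:::qnet_train_step(bank$dqns[["lunch_4"]]$net, X, 1L, 0)
  bank$dqns[["lunch_4"]]$net <- up$net
  dec <- faid_bolus(bank, rep(125, 48), clock_min = 13 * 60, bob_hat = 0)
  expect_identical(dec$sas, 5L)              # banding is still reported
  expect_true(dec$bolus %in% bank$dqns[["lunch_4"]]$grid ||
                dec$bolus == 0)
  # with no trained network for the meal: no bolus at all
  bank0 <- dqn_bank(TDI = 30, seed = 4)
  dec0 <- faid_bolus(bank0, rep(125, 48), clock_min = 13 * 60, bob_hat = 0)
  expect_identical(dec0$bolus, 0)
})
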