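test_that("orientation binning follows the one-degree convention", {
  expect_identical(angle_to_state(0), 1L)
  expect_identical(angle_to_state(-pi / 4), 316L) # 315 deg -> bin 316
  expect_identical(angle_to_state(2 * pi - 1e-9), 360L)
  expect_identical(angle_to_state(pi / 2), 91L)
  expect_identical(angle_to_state(2 * pi), 1L)

  # property: any finite angle lands in the bin covering it
  set.seed(1)
  phis <- runif(500, -50, 50)
  mu <- angle_to_state(phis)
  deg <- (phis %% (2 * pi)) * 180 / pi
  expect_true(all(mu >= 1 & mu <= 360))
  expect_identical(mu, as.integer(floor(deg)) + 1L)
})

test_that("greedy action maximises and breaks exact ties at random", {
  q <- new_qmatrix()
  q[10, ] <- c(0.1, 0.2)
  expect_identical(greedy_action(q, 10), 1L)
  q[11, ] <- c(0.2, 0.1)
  expect_identical(greedy_action(q, 11), 0L)

  set.seed(7)
  draws <- replicate(1e4, greedy_action(q, 50)) # all-zero row: a tie
  f <- mean(draws)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("exploration decays linearly from one to zero", {
  expect_equal(epsilon_schedule(0, 1000), 1)
  expect_equal(epsilon_schedule(999, 1000), 0)
  expect_equal(epsilon_schedule(500, 1000), 0.4995, tolerance = 1e-4)
  expect_equal(epsilon_schedule(0, 1), 0)
  expect_error(epsilon_schedule(1000, 1000))
  expect_error(epsilon_schedule(-1, 1000))
})

test_that("the update rule reproduces hand-computed values", {
  q <- new_qmatrix()
  # fixed point: zero Q, zero reward
  q1 <- q_update(q, 5, 1, 0, 17)
  expect_identical(q1, q)
  # terminal reward on a zero Q: alpha * R = 1.0
  q2 <- q_update(q, 5, 1, 100, NULL)
  expect_equal(unname(q2[5, 2]), 1.0)
  # bootstrap: 0.99 * 1 + 0.01 * 0.9 * 1 = 0.999
  q3 <- new_qmatrix()
  q3[5, 2] <- 1.0
  q3[17, 1] <- 1.0
  q4 <- q_update(q3, 5, 1, 0, 17)
  expect_equal(unname(q4[5, 2]), 0.999)
})

test_that("terminal rewards fire at the box edges with the right signs", {
  expect_equal(terminal_reward(12.5), 100)
  expect_equal(terminal_reward(0), 0)
  expect_equal(terminal_reward(-12.5), -100)
  expect_equal(terminal_reward(c(-13, 3, 13)), c(-100, 0, 100))
})

test_that("a scripted upward partner carries the agent to the goal", {
  fx <- make_fixture("single-upward-abp")
  q <- new_qmatrix()
  q[, "go"] <- 1e-8 # forces greedy GO everywhere
  ep <- run_episode(fx$state, fx$params, q, train_config(), epsilon = 0,
                    seed = 1, record_trajectory = TRUE)
  # jump to y = 0.5 at t = 0, then v0 = 1.5 per epoch: reaches 12.5 at t = 8
  expect_equal(ep$duration, 8)
  expect_equal(ep$outcome, 1)
  expect_equal(ep$n_decisions, 8)
  # goal-frame state of an upward partner is bin 1
  expect_true(all(ep$decisions$mu == 1))
  expect_true(all(ep$decisions$nu == 1))
  # terminal update: alpha * (R + gamma * 0) on a (nearly) zero entry
  expect_equal(unname(ep$q[1, "go"]), 1.0, tolerance = 1e-6)
  # rides the partner exactly: y(t) = 0.5 + 1.5 t
  tr <- ep$trajectory
  expect_equal(tr$y[nrow(tr)], 12.5, tolerance = 1e-9)
  expect_equal(max(abs(tr$x)), 0, tolerance = 1e-9)
})

test_that("a shunned downward partner leaves the agent at rest until t_max", {
  fx <- make_fixture("single-downward-abp")
  q <- new_qmatrix()
  q[, "no_go"] <- 1 # trained aversion to every orientation
  ep <- run_episode(fx$state, fx$params, q, train_config(), epsilon = 0,
                    seed = 2)
  expect_equal(ep$duration, 6e4)
  expect_equal(ep$outcome, 0)
  expect_true(all(ep$decisions$nu == 0))
})

test_that("an empty bath yields no decisions and an unchanged Q", {
  fx <- make_fixture("empty")
  q <- new_qmatrix()
  ep <- run_episode(fx$state, fx$params, q, train_config(), epsilon = 1,
                    seed = 3)
  expect_equal(ep$duration, 6e4)
  expect_equal(ep$n_decisions, 0L)
  expect_equal(unname(ep$q), unname(q))
})

test_that("the tabular learner reaches the Bellman optimum on the toy MDP", {
  mdp <- make_fixture("toy-mdp")
  q_star <- value_iteration(mdp)
  expect_equal(unname(q_star), matrix(c(-100, 81, 90, 100), 2, 2))
  set.seed(42)
  q <- train_toy_mdp(mdp, episodes = 1e4, epsilon = 0.5)
  expect_lt(max(abs(q - q_star)), 1e-3)
})

test_that("episode durations shrink over a training cycle", {
  cy <- run_training_cycle(bath_params(), train_config(), seed = 515)
  lc <- cy$learning_curve
  expect_equal(nrow(lc), 1000L)
  expect_lt(mean(lc$duration[901:1000]), mean(lc$duration[1:100]))
  # value bound |Q| <= R / (1 - gamma)
  expect_true(all(abs(cy$q) <= 1000))
  # late episodes mostly reach the goal
  expect_gt(mean(lc$outcome[901:1000] == 1), 0.5)
})

test_that("training cycles are reproducible from their seed", {
  cfg <- train_config(episodes_per_cycle = 25)
  a <- run_training_cycle(bath_params(), cfg, seed = 99)
  b <- run_training_cycle(bath_params(), cfg, seed = 99)
  expect_identical(a$q, b$q)
  expect_identical(a$action_map, b$action_map)
  expect_identical(a$learning_curve, b$learning_curve)
})

test_that("a single greedy episode on an empty bath leaves all states tied", {
  cfg <- train_config(episodes_per_cycle = 1, t_max = 50)
  cy <- run_training_cycle(bath_params(density = 0), cfg, seed = 4)
  expect_true(all(cy$tie))
  expect_true(all(cy$q == 0))
  expect_true(all(cy$action_map %in% 0:1))
})

test_that("perception time must be commensurate with the time step", {
  b <- bath_params(dt = 0.3)
  expect_error(run_training_cycle(b, train_config(), seed = 1), "multiple")
})

test_that("action maps aggregate into thresholded decision diagrams", {
  maps <- matrix(0L, nrow = 3, ncol = 360)
  maps[, 1] <- 1L
  d <- aggregate_diagram(maps)
  expect_equal(d$h_go[1], 1)
  expect_true(d$go_mask[1])
  expect_equal(d$n_cycles, 3L)

  # h = 0.5 counts as GO (threshold is >=)
  maps2 <- matrix(0L, nrow = 4, ncol = 360)
  maps2[1:2, 7] <- 1L
  d2 <- aggregate_diagram(maps2)
  expect_equal(d2$h_go[7], 0.5)
  expect_true(d2$go_mask[7])

  # minority states stay NO GO
  maps3 <- matrix(0L, nrow = 10, ncol = 360)
  maps3[1:3, 100] <- 1L
  expect_false(aggregate_diagram(maps3)$go_mask[100])

  expect_error(aggregate_diagram(list()))
})

test_that("GO arcs are extracted with the stated conventions", {
  m <- rep(FALSE, 360)
  m[c(316:360, 1:45)] <- TRUE # symmetric arc across 0
  expect_equal(extract_go_interval(m), c(phi0 = 0, dphi = pi / 2))

  m2 <- rep(FALSE, 360)
  m2[271:360] <- TRUE
  expect_equal(extract_go_interval(m2), c(phi0 = -pi / 4, dphi = pi / 2))

  expect_equal(extract_go_interval(rep(TRUE, 360)),
               c(phi0 = 0, dphi = 2 * pi))
  expect_equal(extract_go_interval(rep(FALSE, 360)), c(phi0 = 0, dphi = 0))

  # longest run wins over a shorter disjoint run
  m3 <- rep(FALSE, 360)
  m3[81:100] <- TRUE # 20 bins centred at 90 deg
  m3[200:205] <- TRUE
  arc <- extract_go_interval(m3)
  expect_equal(arc[["dphi"]], 20 * pi / 180)
  expect_equal(arc[["phi0"]], 90 * pi / 180)

  # arc construction round-trips through extraction
  d <- diagram_from_arc(pi / 2, pi / 2)
  expect_equal(sum(d$go_mask), 90)
  expect_equal(d$phi0, pi / 2, tolerance = 1e-9)
  expect_equal(d$dphi, pi / 2, tolerance = 1e-9)
})
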