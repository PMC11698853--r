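test_that("the trained agent is inert without partners or GO states", {
  d_all <- diagram_from_arc(0, pi / 2)
  empty <- bath_params(density = 0)
  tr <- simulate_q_ihp(d_all, empty, duration = 5, seed = 1)
  expect_true(all(tr$x == 0) && all(tr$y == 0))
  expect_true(all(is.na(tr$partner)))

  d_none <- decision_diagram(rep(0, 360))
  tr2 <- simulate_q_ihp(d_none, bath_params(), duration = 5, seed = 2)
  expect_true(all(tr2$x == 0) && all(tr2$y == 0))

  tr3 <- simulate_potential_ihp(d_all, empty, duration = 2, seed = 3)
  expect_true(all(tr3$x == 0) && all(tr3$y == 0))
  tr4 <- simulate_potential_ihp(d_none, bath_params(), duration = 2, seed = 4)
  expect_true(all(tr4$x == 0) && all(tr4$y == 0))
})

test_that("a scripted upward partner is ridden at v0 after the wait", {
  d <- diagram_from_arc(0, pi / 2)
  p <- bath_params(n_particles = 1, rot_diffusivity = 0)

  # partner starts at the agent's side: immediate attachment
  st <- scripted_state(0, 0.5, pi / 2)
  tr <- simulate_q_ihp(d, p, 4, seed = 1, state = st)
  # row at t = 0 is the pre-decision origin; then jump + ride at v0
  expect_equal(tr$y[-1], 0.5 + 1.5 * tr$time[-1], tolerance = 1e-9)
  expect_equal(tr$y[1], 0)

  # partner approaching from below: rest one epoch, then attach and ride
  st2 <- scripted_state(0, 22.5, pi / 2) # minimum image: 2.5 below
  tr2 <- simulate_q_ihp(d, p, 4, seed = 1, state = st2)
  ep <- attr(tr2, "epochs")
  expect_equal(ep$attached, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(tr2$y[tr2$time == 2], 0.5, tolerance = 1e-9)
  expect_equal(tr2$y[tr2$time == 4], 3.5, tolerance = 1e-9)
})

test_that("the agent's speed is 0 or v0, apart from bounded attach jumps", {
  fit_d <- diagram_from_arc(0, 2) # generous arc
  p <- bath_params(rot_diffusivity = 0.1)
  tr <- simulate_q_ihp(fit_d, p, 50, seed = 31)
  disp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  step_len <- p$speed * p$dt
  first_sub <- (seq_along(disp) - 1) %% 6 == 0 # first substep of each epoch
  ok_plain <- abs(disp) < 1e-9 | abs(disp - step_len) < 1e-9
  # attach jumps (<= scan radius) only ever at a decision substep
  expect_true(all(ok_plain[!first_sub]))
  expect_true(all(ok_plain[first_sub] | disp[first_sub] <= 1 + step_len))
  expect_gt(sum(!ok_plain[first_sub]), 0) # some partner changes happened
})

test_that("pair velocities follow the 1/r^2 kick inside the GO window", {
  pp <- potential_params(diagram_from_arc(0, pi / 2))
  up <- pi / 2 # goal-ward orientation, relative angle 0
  expect_equal(potential_pair_velocity(c(0, 1), up, pp), c(0, 7.5))
  expect_equal(potential_pair_velocity(c(0.5, 0), up, pp), c(30, 0))
  expect_equal(potential_pair_velocity(c(0, 0.1), up, pp), c(0, 750))
  # outside the GO window, out of range, inside the core: no force
  expect_equal(potential_pair_velocity(c(0, 1), -pi / 2, pp), c(0, 0))
  expect_equal(potential_pair_velocity(c(0, 1.2), up, pp), c(0, 0))
  expect_equal(potential_pair_velocity(c(0, 0.04), up, pp), c(0, 0))
  expect_equal(potential_pair_velocity(c(0, 0), up, pp), c(0, 0))
})

test_that("potential steps are capped at the nearest contributing partner", {
  d <- diagram_from_arc(0, pi / 2)
  pp <- potential_params(d)
  # strong kick from r = 0.1: displacement capped at exactly 0.1
  st <- scripted_state(5, 5.1, pi / 2)
  newpos <- step_potential_ihp(c(5, 5), st, pp, dt = 1 / 6)
  expect_equal(newpos, c(5, 5.1), tolerance = 1e-12)
  # a particle resting inside r_min gives no kick at all
  st2 <- scripted_state(5, 5.04, pi / 2)
  expect_equal(step_potential_ihp(c(5, 5), st2, pp, dt = 1 / 6), c(5, 5))
  # no contributing particles: no displacement
  st3 <- scripted_state(5, 8, pi / 2)
  expect_equal(step_potential_ihp(c(5, 5), st3, pp, dt = 1 / 6), c(5, 5))
})

test_that("the compiled potential dynamics match the R reference step", {
  # deterministic chiral bath: both paths see identical particle motion
  d <- diagram_from_arc(0, 3)
  n <- 40
  p <- bath_params(n_particles = n, rot_diffusivity = 0,
                   circ_frequency = 0.5)
  st <- init_bath(p, seed = 77)
  sim <- simulate_potential_ihp(d, p, duration = 2, seed = 1, state = st)
  # R reference: bath substep first, then the capped potential step
  pp <- potential_params(d)
  pos <- c(0, 0)
  stt <- st
  for (k in 1:12) {
    stt <- propagate_bath(stt, p, 1, seed = 1)
    pos <- step_potential_ihp(pos, stt, pp, dt = p$dt)
  }
  expect_equal(c(sim$x[13], sim$y[13]), pos, tolerance = 1e-9)
})

test_that("the friction coefficient cancels from the dynamics", {
  d <- diagram_from_arc(0, pi / 2)
  p <- bath_params(density = 1, rot_diffusivity = 0.1)
  a <- simulate_potential_ihp(d, p, duration = 3, seed = 8, friction = 1)
  b <- simulate_potential_ihp(d, p, duration = 3, seed = 8, friction = 250)
  expect_identical(a, b)
  expect_error(potential_params(d, friction = 0))
  expect_error(potential_params(d, r_min = 2)) # must stay below scan radius
})

test_that("simulate() dispatches both models from a fitted object", {
  fit <- ihp_train(config = train_config(episodes_per_cycle = 40),
                   cycles = 2, seed = 1234)
  ens <- simulate(fit, nsim = 3, seed = 9, duration = 10)
  expect_length(ens, 3)
  expect_s3_class(ens[[1]], "ihp_trajectory")
  ens2 <- simulate(fit, nsim = 2, seed = 9, model = "potential",
                   duration = 2)
  expect_length(ens2, 2)
  # reproducible from the seed
  ens3 <- simulate(fit, nsim = 3, seed = 9, duration = 10)
  expect_identical(ens, ens3)
})
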