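test_that("bath initialisation respects density, ranges and determinism", {
  p <- bath_params()
  expect_equal(p$n_particles, 375L) # round(0.6 * 25^2)
  st <- init_bath(p, seed = 5)
  expect_equal(nrow(st$positions), 375L)
  expect_true(all(st$positions >= 0 & st$positions < 25))
  expect_true(all(st$angles >= 0 & st$angles < 2 * pi))
  expect_identical(st$time, 0)

  # same seed => bitwise identical; different seed => different
  st2 <- init_bath(p, seed = 5)
  expect_identical(st, st2)
  st3 <- init_bath(p, seed = 6)
  expect_false(identical(st$positions, st3$positions))

  # empty bath is a valid state
  e <- init_bath(bath_params(density = 0), seed = 1)
  expect_equal(nrow(e$positions), 0L)

  expect_error(bath_params(density = -1), "density")
  expect_error(bath_params(dt = 0))
})

test_that("noiseless kinematics are exact: straight motion and rotation", {
  p <- bath_params(n_particles = 1, rot_diffusivity = 0)
  st <- scripted_state(5, 5, 0)
  st1 <- step_bath(st, p, seed = 1)
  expect_equal(st1$positions[1, ], c(x = 5.25, y = 5), tolerance = 1e-12)
  expect_equal(st1$time, 1 / 6)

  # constant angular drift: phi(n) = phi(0) + omega n dt (mod 2 pi)
  pc <- bath_params(n_particles = 1, rot_diffusivity = 0,
                    circ_frequency = 0.6)
  stn <- propagate_bath(scripted_state(5, 5, 1), pc, 40, seed = 1)
  expect_equal(attr(stn, "angles_unwrapped"), 1 + 0.6 * 40 / 6,
               tolerance = 1e-12)
})

test_that("every particle moves at exactly v0 at every substep", {
  p <- bath_params(n_particles = 20, rot_diffusivity = 0.4)
  st <- init_bath(p, seed = 3)
  st$positions[] <- 10 # away from the box edges
  for (k in 1:5) {
    stn <- propagate_bath(st, p, 1, seed = 100 + k)
    disp <- sqrt(rowSums((stn$positions - st$positions)^2))
    expect_equal(disp, rep(p$speed * p$dt, 20), tolerance = 1e-12)
    st <- stn
  }
})

test_that("a circle swimmer traces a closed orbit of radius v0/omega", {
  fx <- make_fixture("circling-abp")
  omega <- fx$params$circ_frequency
  period_steps <- round(2 * pi / omega / fx$params$dt)
  # record the whole orbit step by step (deterministic, noiseless)
  st <- fx$state
  xs <- ys <- numeric(period_steps)
  for (k in seq_len(period_steps)) {
    st <- step_bath(st, fx$params, seed = 1)
    xs[k] <- st$positions[1, 1]
    ys[k] <- st$positions[1, 2]
  }
  # closes exactly (deterministic polygon)
  expect_equal(c(xs[period_steps], ys[period_steps]),
               unname(fx$state$positions[1, ]), tolerance = 1e-10)
  # circumradius within O(dt) of v0/omega
  r <- sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)
  expect_equal(mean(r), fx$params$speed / omega, tolerance = 0.01)
})

test_that("orientation variance grows as 2 D_r t", {
  n <- 2e4
  p <- bath_params(n_particles = n, rot_diffusivity = 0.1, box_length = 25)
  st <- init_bath(p, seed = 9)
  stn <- propagate_bath(st, p, 60, seed = 10) # t = 10 tau_Q
  dphi <- attr(stn, "angles_unwrapped") - st$angles
  v <- var(dphi)
  expected <- 2 * 0.1 * 10
  se <- expected * sqrt(2 / (n - 1))
  expect_lt(abs(v - expected), 3 * se)
  expect_lt(abs(mean(dphi)), 3 * sqrt(expected / n))
})

test_that("free-ABP ensemble MSD matches the closed form", {
  # beyond the first few steps the O(dt) integrator bias is well below
  # the sampling noise and the continuum closed form applies
  p <- bath_params(rot_diffusivity = 6 * pi^2 * 1e-3)
  times <- c(20, 50, 100)
  msd <- abp_ensemble_msd(p, n = 2e4, times = times, seed = 21)
  ref <- abp_msd_closed_form(times, p)
  dev <- abs(msd$msd[-1] - ref)
  expect_true(all(dev < 3 * msd$se[-1]))

  # the exact discrete-time second moment of the Euler scheme matches at
  # every lag: v0^2 dt^2 (n + 2 sum_m (n - m) exp(-Dr dt m))
  disc <- vapply(round(times / p$dt), function(n) {
    m <- seq_len(n - 1)
    p$speed^2 * p$dt^2 *
      (n + 2 * sum((n - m) * exp(-p$rot_diffusivity * p$dt * m)))
  }, numeric(1))
  expect_true(all(abs(msd$msd[-1] - disc) < 3 * msd$se[-1]))
})

test_that("closed-form MSD has the right limits and rejects chirality", {
  p <- bath_params(rot_diffusivity = 0.0592)
  t_small <- 1e-4
  expect_equal(abp_msd_closed_form(t_small, p) / t_small^2, p$speed^2,
               tolerance = 1e-3)
  t_big <- 1e6 / p$rot_diffusivity
  expect_equal(abp_msd_closed_form(t_big, p) / t_big,
               2 * p$speed^2 / p$rot_diffusivity, tolerance = 1e-5)
  expect_error(abp_msd_closed_form(1, bath_params(circ_frequency = 1)),
               "achiral")
  expect_error(abp_msd_closed_form(1, bath_params(rot_diffusivity = 0)))
})

test_that("nearest particle search uses the minimum image", {
  st <- scripted_state(5, 5.5, 0)
  idx <- nearest_particle(c(5, 5), st, scan_radius = 1)
  expect_equal(as.integer(idx), 1L)
  expect_equal(attr(idx, "distance"), 0.5)

  # out of scan range
  st2 <- scripted_state(5, 6.2, 0)
  expect_true(is.na(nearest_particle(c(5, 5), st2, scan_radius = 1)))

  # across the periodic seam: (0.1, 0) vs (24.9, 0) are 0.2 apart
  st3 <- scripted_state(24.9, 0, 0)
  idx3 <- nearest_particle(c(0.1, 0), st3, scan_radius = 1)
  expect_equal(as.integer(idx3), 1L)
  expect_equal(attr(idx3, "distance"), 0.2, tolerance = 1e-12)

  # empty bath
  fx <- make_fixture("empty")
  expect_true(is.na(nearest_particle(c(0, 0), fx$state)))
})

test_that("orientation wrapping round-trips", {
  phis <- c(0, 1e-9, pi, 2 * pi - 1e-9, -3.2, 17.5, -40)
  wrapped <- phis %% (2 * pi)
  expect_true(all(wrapped >= 0 & wrapped < 2 * pi))
  # wrapping is idempotent and preserves the angle modulo 2 pi
  expect_equal(wrapped %% (2 * pi), wrapped)
  expect_equal(sin(wrapped), sin(phis), tolerance = 1e-9)
  expect_equal(cos(wrapped), cos(phis), tolerance = 1e-9)
})
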