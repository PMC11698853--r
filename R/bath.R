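#' Parameters of the active Brownian bath
#'
#' Bundles the physical parameters of the periodic two-dimensional bath of
#' non-interacting (chiral) active Brownian particles. Defaults are the
#' standard working point: density 0.6 per squared scan radius in a box of
#' side 25, self-propulsion speed 1.5, time step 1/6 of the perception
#' time.
#'
#' The particle number is tied to the density through
#' `n_particles = round(density * box_length^2)`. Supply either `density`
#' or `n_particles`; the other is derived.
#'
#' @param density number density (particles per squared scan radius).
#' @param box_length side length `L` of the periodic square box.
#' @param speed self-propulsion speed `v0` (lengths per perception time).
#' @param rot_diffusivity rotational diffusion constant `D_r` (1/time);
#'   sets the persistence time `1/D_r` and length `v0/D_r`.
#' @param circ_frequency circular frequency `omega` (radians/time) of a
#'   chiral bath; 0 for the achiral bath.
#' @param dt Euler-Maruyama time step.
#' @param n_particles optional explicit particle count (overrides
#'   `density`).
#'
#' @return An object of class `bath_params`.
#' @examples
#' p <- bath_params()
#' p$n_particles # 375
#' @export
bath_params <- function(density = 0.6, box_length = 25, speed = 1.5,
                        rot_diffusivity = 6 * pi^2 * 1e-3,
                        circ_frequency = 0, dt = 1 / 6,
                        n_particles = NULL) {
  stopifnot(box_length > 0, dt > 0, speed >= 0, rot_diffusivity >= 0)
  if (is.null(n_particles)) {
    if (density < 0) stop("density must be non-negative")
    n_particles <- as.integer(round(density * box_length^2))
  } else {
    stopifnot(n_particles >= 0, n_particles == round(n_particles))
    n_particles <- as.integer(n_particles)
    density <- n_particles / box_length^2
  }
  structure(
    list(
      n_particles = n_particles,
      box_length = box_length,
      density = density,
      speed = speed,
      rot_diffusivity = rot_diffusivity,
      circ_frequency = circ_frequency,
      dt = dt,
      persistence_time = if (rot_diffusivity > 0) 1 / rot_diffusivity else Inf,
      persistence_length = if (rot_diffusivity > 0) speed / rot_diffusivity else Inf
    ),
    class = "bath_params"
  )
}

#' @export
print.bath_params <- function(x, ...) {
  cat("Active Brownian bath\n")
  cat(sprintf("  N = %d particles, box L = %g, density = %g\n",
              x$n_particles, x$box_length, x$density))
  cat(sprintf("  v0 = %g, D_r = %g, omega = %g, dt = %g\n",
              x$speed, x$rot_diffusivity, x$circ_frequency, x$dt))
  cat(sprintf("  persistence time = %g, persistence length = %g\n",
              x$persistence_time, x$persistence_length))
  invisible(x)
}

new_bath_state <- function(positions, angles, time, box_length) {
  structure(
    list(positions = positions, angles = angles, time = time),
    box_length = box_length,
    class = "bath_state"
  )
}

#' Draw a random initial bath configuration
#'
#' Positions are i.i.d. uniform over the periodic box, orientations i.i.d.
#' uniform over `[0, 2*pi)` (the maximum-entropy state of a homogeneous
#' bath). Two calls with the same seed return identical states.
#'
#' @param params a [bath_params()] object.
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @return A `bath_state`: list with `positions` (N x 2 matrix, wrapped to
#'   `[0, L)`), `angles` (wrapped to `[0, 2*pi)`) and `time = 0`.
#' @export
init_bath <- function(params, seed = NULL) {
  stopifnot(inherits(params, "bath_params"))
  s <- resolve_seed(seed)
  raw <- cpp_init_bath(params$n_particles, params$box_length, s)
  new_bath_state(cbind(x = raw$x, y = raw$y), raw$phi, 0, params$box_length)
}

#' @export
print.bath_state <- function(x, ...) {
  cat(sprintf("Bath state: %d particles at t = %g (box L = %g)\n",
              nrow(x$positions), x$time, attr(x, "box_length")))
  invisible(x)
}

#' Propagate the bath by forward Euler-Maruyama steps
#'
#' Each substep updates positions with the pre-step orientation,
#' `r <- r + v0 * dt * (cos phi, sin phi)`, then draws the orientation
#' increment `phi <- phi + omega * dt + sqrt(2 D_r dt) * eta` with standard
#' normal `eta`. `step_bath()` performs a single step.
#'
#' @param state a `bath_state`.
#' @param params a [bath_params()] object.
#' @param n_steps number of substeps of length `params$dt`.
#' @param seed integer seed for the rotational noise.
#' @param periodic wrap positions into the box (default). With
#'   `periodic = FALSE` positions evolve in free space (unwrapped), which
#'   is the right frame for displacement statistics.
#' @return A `bath_state` at the advanced time. Unwrapped orientation
#'   angles are attached as attribute `"angles_unwrapped"`.
#' @export
propagate_bath <- function(state, params, n_steps, seed = NULL,
                           periodic = TRUE) {
  stopifnot(inherits(state, "bath_state"), inherits(params, "bath_params"),
            n_steps >= 1)
  s <- resolve_seed(seed)
  out <- cpp_bath_evolve(state$positions[, 1], state$positions[, 2],
                         state$angles, params$box_length, params$speed,
                         params$rot_diffusivity, params$circ_frequency,
                         params$dt, as.integer(n_steps), s, periodic,
                         as.integer(n_steps))
  n <- nrow(state$positions)
  pos <- cbind(x = as.numeric(out$x[1, seq_len(n)]),
               y = as.numeric(out$y[1, seq_len(n)]))
  phi_unwrapped <- as.numeric(out$phi[1, seq_len(n)])
  st <- new_bath_state(pos, phi_unwrapped %% (2 * pi),
                       state$time + n_steps * params$dt, params$box_length)
  attr(st, "angles_unwrapped") <- phi_unwrapped
  attr(st, "periodic") <- periodic
  st
}

#' @rdname propagate_bath
#' @export
step_bath <- function(state, params, seed = NULL) {
  propagate_bath(state, params, 1L, seed = seed)
}

#' Closed-form mean-squared displacement of a free achiral ABP
#'
#' `MSD(t) = (2 v0^2 / D_r^2) (D_r t + exp(-D_r t) - 1)`: ballistic
#' `(v0 t)^2` at short times, diffusive `2 v0^2 t / D_r` at long times.
#' Only defined for the achiral bath; a chiral closed form is out of scope.
#'
#' @param t vector of lag times (>= 0).
#' @param params a [bath_params()] with `rot_diffusivity > 0` and
#'   `circ_frequency == 0`.
#' @return MSD values on `t`.
#' @export
abp_msd_closed_form <- function(t, params) {
  stopifnot(inherits(params, "bath_params"), all(t >= 0))
  if (params$rot_diffusivity <= 0) {
    stop("abp_msd_closed_form requires rot_diffusivity > 0")
  }
  if (params$circ_frequency != 0) {
    stop("abp_msd_closed_form is only defined for an achiral bath (omega = 0)")
  }
  dr <- params$rot_diffusivity
  v0 <- params$speed
  2 * v0^2 / dr^2 * (dr * t + expm1(-dr * t))
}

#' Nearest bath particle under the minimum-image convention
#'
#' @param point length-2 position.
#' @param state a `bath_state`.
#' @param scan_radius perception range; particles farther away are
#'   invisible.
#' @param box_length box side; defaults to the state's own.
#' @return The index of the closest particle within `scan_radius`, or
#'   `NA_integer_` if none (or the bath is empty). The minimum-image
#'   distance is attached as attribute `"distance"`.
#' @export
nearest_particle <- function(point, state, scan_radius = 1,
                             box_length = attr(state, "box_length")) {
  stopifnot(length(point) == 2, inherits(state, "bath_state"))
  if (nrow(state$positions) == 0) {
    return(structure(NA_integer_, distance = NA_real_))
  }
  res <- cpp_nearest(state$positions[, 1], state$positions[, 2],
                     point[1], point[2], box_length)
  if (res$distance > scan_radius) {
    return(structure(NA_integer_, distance = res$distance))
  }
  structure(as.integer(res$index), distance = res$distance)
}

#' Ensemble mean-squared displacement of free ABPs by direct simulation
#'
#' Simulates `n` independent achiral or chiral ABPs from the origin (free
#' space, uniform random initial orientations) and returns the empirical
#' MSD with standard errors. Used as the simulator's reference against
#' [abp_msd_closed_form()].
#'
#' @param params a [bath_params()] object (only the dynamical fields are
#'   used; the box plays no role in free space).
#' @param n number of independent particles.
#' @param times strictly increasing multiples of `params$dt` at which to
#'   evaluate the MSD.
#' @param seed integer seed.
#' @return An object of class `msd_curve` (see [ensemble_msd()]).
#' @export
abp_ensemble_msd <- function(params, n, times, seed = NULL) {
  stopifnot(inherits(params, "bath_params"), n >= 1, all(times > 0))
  steps <- times / params$dt
  if (any(abs(steps - round(steps)) > 1e-8)) {
    stop("times must be multiples of params$dt")
  }
  steps <- as.integer(round(steps))
  stopifnot(!is.unsorted(steps, strictly = TRUE))
  s <- resolve_seed(seed)
  phi0 <- cpp_init_bath(n, 1, s)$phi # uniform orientations from the same seed
  out <- cpp_bath_evolve(numeric(n), numeric(n), phi0, params$box_length,
                         params$speed, params$rot_diffusivity,
                         params$circ_frequency, params$dt,
                         max(steps), s, FALSE, steps)
  d2 <- out$x^2 + out$y^2 # nrec x n matrix of squared displacements
  msd <- rowMeans(d2)
  se <- apply(d2, 1, sd) / sqrt(n)
  new_msd_curve(c(0, times), c(0, msd), c(0, se), n)
}
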