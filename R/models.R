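scripted_init <- function(state, bath) {
  if (is.null(state)) {
    return(list(x = numeric(0), y = numeric(0), phi = numeric(0)))
  }
  stopifnot(inherits(state, "bath_state"),
            nrow(state$positions) == bath$n_particles)
  list(x = state$positions[, 1], y = state$positions[, 2],
       phi = state$angles)
}

new_ihp_trajectory <- function(df, epochs = NULL) {
  stopifnot(all(c("time", "x", "y") %in% names(df)))
  class(df) <- c("ihp_trajectory", "data.frame")
  if (!is.null(epochs)) attr(df, "epochs") <- epochs
  df
}

#' Simulate the fully trained Q-learning hitchhiker
#'
#' Identical dynamics to a training episode, but with greedy decisions
#' taken from a fixed decision diagram, no exploration, no learning, and
#' no termination at the box edges: the agent runs for the full duration
#' and its position is tracked unwrapped (the box only sets the bath's
#' periodicity). The agent can move only by riding a partner, so its speed
#' is either 0 or the bath speed, apart from the attachment jump of at
#' most one scan radius.
#'
#' @param diagram a [decision_diagram()].
#' @param bath a [bath_params()] object.
#' @param duration run length, an integer number of perception times.
#' @param seed integer seed (bath draw + rotational noise).
#' @param scan_radius perception range.
#' @param perception_time decision interval `tau_Q`; must be an integer
#'   multiple of `bath$dt`.
#' @param state optional initial `bath_state` (e.g. a scripted fixture);
#'   by default a fresh uniform bath is drawn from `seed`.
#' @return An `ihp_trajectory` data frame (`time`, `x`, `y`, `partner`;
#'   one row per substep, `partner` is `NA` while resting) with attribute
#'   `"epochs"`: a data frame of per-decision times and attachment
#'   status.
#' @export
simulate_q_ihp <- function(diagram, bath, duration, seed = NULL,
                           scan_radius = 1, perception_time = 1,
                           state = NULL) {
  stopifnot(inherits(diagram, "decision_diagram"),
            inherits(bath, "bath_params"))
  nsub <- perception_time / bath$dt
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("perception_time must be an integer multiple of bath$dt")
  }
  n_epochs <- duration / perception_time
  if (abs(n_epochs - round(n_epochs)) > 1e-9 || n_epochs < 1) {
    stop("duration must be a positive integer number of perception times")
  }
  s <- resolve_seed(seed)
  init <- scripted_init(state, bath)
  out <- cpp_simulate_q(as.integer(diagram$go_mask), bath$n_particles,
                        bath$box_length, bath$speed, bath$rot_diffusivity,
                        bath$circ_frequency, bath$dt,
                        as.integer(round(n_epochs)), perception_time,
                        scan_radius, s, init$x, init$y, init$phi)
  epochs <- data.frame(
    time = (seq_along(out$attached) - 1) * perception_time,
    attached = as.logical(out$attached)
  )
  new_ihp_trajectory(
    data.frame(time = out$time, x = out$x, y = out$y, partner = out$partner),
    epochs = epochs
  )
}

#' Parameters of the potential hitchhiker
#'
#' The potential variant replaces discrete attachment by a non-reciprocal
#' attractive potential `V0(r) = amplitude * friction * v0 * Rs (1 - Rs/r)`
#' acting between the agent and every favourably oriented bath particle
#' with `r_min <= r <= Rs`. The friction coefficient cancels exactly in
#' the overdamped mobility product and is kept only for completeness.
#'
#' @param go_set a [decision_diagram()] defining the favourable
#'   orientations (transferred from a trained Q-learning agent).
#' @param speed bath self-propulsion speed `v0`.
#' @param scan_radius interaction cut-off `Rs`.
#' @param r_min lower cut-off preventing the force divergence; inside it
#'   the agent is considered attached and feels no kick.
#' @param friction friction coefficient (must be positive; does not affect
#'   the dynamics).
#' @param amplitude dimensionless prefactor of the potential (5 in the
#'   reference parametrisation, giving speed `5 v0` at `r = Rs`).
#' @return An object of class `potential_params`.
#' @export
potential_params <- function(go_set, speed = 1.5, scan_radius = 1,
                             r_min = scan_radius / 20, friction = 1,
                             amplitude = 5) {
  stopifnot(inherits(go_set, "decision_diagram"),
            r_min > 0, r_min < scan_radius, friction > 0, speed >= 0,
            amplitude >= 0)
  structure(
    list(go_set = go_set, speed = speed, scan_radius = scan_radius,
         r_min = r_min, friction = friction, amplitude = amplitude,
         amplitude_scale = amplitude * friction * speed * scan_radius),
    class = "potential_params"
  )
}

#' Velocity contribution of one bath particle on the potential hitchhiker
#'
#' The mobility product `-grad(V)/friction` for a single particle:
#' magnitude `amplitude * v0 * Rs^2 / r^2` directed from the agent towards
#' the particle when the particle's orientation is in the GO set and
#' `r_min <= r <= Rs`; zero otherwise (including `r < r_min` and `r = 0`).
#'
#' @param displacement length-2 vector from the agent to the particle
#'   (minimum-image).
#' @param phi the particle's orientation angle.
#' @param pp a [potential_params()] object.
#' @return Length-2 velocity contribution.
#' @export
potential_pair_velocity <- function(displacement, phi, pp) {
  stopifnot(inherits(pp, "potential_params"), length(displacement) == 2)
  r <- sqrt(sum(displacement^2))
  if (r > pp$scan_radius || r < pp$r_min) return(c(0, 0))
  if (!pp$go_set$go_mask[goal_state(phi)]) return(c(0, 0))
  mag <- pp$amplitude * pp$speed * pp$scan_radius^2 / r^2
  mag * displacement / r
}

#' One overdamped step of the potential hitchhiker
#'
#' Sums [potential_pair_velocity()] over all bath particles
#' (minimum-image displacements) and advances the agent by `dt` times the
#' total. To suppress the finite-time-step artefact of overshooting a
#' close particle, the displacement is rescaled to the distance of the
#' nearest contributing particle whenever it is larger (direction
#' unchanged).
#'
#' @param ihp_pos length-2 (unwrapped) agent position.
#' @param state a `bath_state`.
#' @param pp a [potential_params()] object.
#' @param dt time step.
#' @return The new (unwrapped) agent position.
#' @export
step_potential_ihp <- function(ihp_pos, state, pp, dt) {
  stopifnot(length(ihp_pos) == 2, inherits(state, "bath_state"),
            inherits(pp, "potential_params"))
  L <- attr(state, "box_length")
  n <- nrow(state$positions)
  if (n == 0) return(ihp_pos)
  wrapped <- ihp_pos %% L
  dx <- state$positions[, 1] - wrapped[1]
  dy <- state$positions[, 2] - wrapped[2]
  dx <- dx - L * round(dx / L)
  dy <- dy - L * round(dy / L)
  r <- sqrt(dx^2 + dy^2)
  go <- pp$go_set$go_mask[goal_state(state$angles)]
  contrib <- go & r >= pp$r_min & r <= pp$scan_radius
  if (!any(contrib)) return(ihp_pos)
  mag <- pp$amplitude * pp$speed * pp$scan_radius^2 / r[contrib]^2
  vx <- sum(mag * dx[contrib] / r[contrib])
  vy <- sum(mag * dy[contrib] / r[contrib])
  disp <- dt * c(vx, vy)
  dmin <- min(r[contrib])
  dl <- sqrt(sum(disp^2))
  if (dl > dmin) disp <- disp * (dmin / dl)
  ihp_pos + disp
}

#' Simulate the potential hitchhiker
#'
#' Interleaves bath substeps with [step_potential_ihp()] at every `dt`
#' (bath first, then the agent reacts to the post-step bath). There is no
#' perception time: the continuous force field updates the effective
#' decision at every substep.
#'
#' @inheritParams simulate_q_ihp
#' @param r_min lower interaction cut-off.
#' @param friction friction coefficient; validated positive, provably
#'   cancels from the dynamics.
#' @param amplitude potential prefactor.
#' @param state optional initial `bath_state`.
#' @return An `ihp_trajectory` data frame (`time`, `x`, `y`).
#' @export
simulate_potential_ihp <- function(diagram, bath, duration, seed = NULL,
                                   scan_radius = 1,
                                   r_min = scan_radius / 20,
                                   friction = 1, amplitude = 5,
                                   state = NULL) {
  stopifnot(inherits(diagram, "decision_diagram"),
            inherits(bath, "bath_params"),
            r_min > 0, r_min < scan_radius, friction > 0)
  n_steps <- duration / bath$dt
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps < 1) {
    stop("duration must be a positive integer number of time steps")
  }
  s <- resolve_seed(seed)
  init <- scripted_init(state, bath)
  out <- cpp_simulate_potential(as.integer(diagram$go_mask),
                                bath$n_particles, bath$box_length,
                                bath$speed, bath$rot_diffusivity,
                                bath$circ_frequency, bath$dt,
                                as.integer(round(n_steps)), scan_radius,
                                r_min, amplitude, s, init$x, init$y,
                                init$phi)
  new_ihp_trajectory(data.frame(time = out$time, x = out$x, y = out$y))
}

#' @export
print.ihp_trajectory <- function(x, ...) {
  cat(sprintf("IHP trajectory: %d points, t in [%g, %g]\n",
              nrow(x), min(x$time), max(x$time)))
  invisible(x)
}
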