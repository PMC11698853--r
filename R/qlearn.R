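#' Training hyperparameters of the Q-learning hitchhiker
#'
#' Defaults are the full training protocol: learning rate 0.01, discount
#' 0.9, terminal reward magnitude 100, 1000 episodes per cycle, 303
#' independent cycles, episode cap 6e4 perception times.
#'
#' @param learning_rate update step `alpha` in `(0, 1]`.
#' @param discount discount factor `gamma` in `[0, 1]`.
#' @param reward_magnitude absolute terminal reward/punishment `R`.
#' @param episodes_per_cycle episodes in one training cycle.
#' @param n_cycles number of independent training cycles to aggregate.
#' @param t_max episode time cap (perception times).
#' @param perception_time interval `tau_Q` between successive decisions;
#'   must be an integer multiple of the bath time step.
#' @param scan_radius perception range `R_s`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, discount = 0.9,
                         reward_magnitude = 100, episodes_per_cycle = 1000,
                         n_cycles = 303, t_max = 6e4, perception_time = 1,
                         scan_radius = 1) {
  stopifnot(
    learning_rate > 0, learning_rate <= 1,
    discount >= 0, discount <= 1,
    reward_magnitude >= 0,
    episodes_per_cycle >= 1, episodes_per_cycle == round(episodes_per_cycle),
    n_cycles >= 1, n_cycles == round(n_cycles),
    t_max > 0, perception_time > 0, scan_radius > 0
  )
  structure(
    list(
      learning_rate = learning_rate, discount = discount,
      reward_magnitude = reward_magnitude,
      episodes_per_cycle = as.integer(episodes_per_cycle),
      n_cycles = as.integer(n_cycles), t_max = t_max,
      perception_time = perception_time, scan_radius = scan_radius
    ),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat("Q-learning configuration\n")
  cat(sprintf("  alpha = %g, gamma = %g, |R| = %g\n",
              x$learning_rate, x$discount, x$reward_magnitude))
  cat(sprintf("  %d episodes/cycle, %d cycles, T_max = %g tau_Q\n",
              x$episodes_per_cycle, x$n_cycles, x$t_max))
  cat(sprintf("  perception time = %g, scan radius = %g\n",
              x$perception_time, x$scan_radius))
  invisible(x)
}

check_timestep <- function(config, bath) {
  nsub <- config$perception_time / bath$dt
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("perception_time must be an integer multiple of the bath time step dt")
  }
  as.integer(round(nsub))
}

#' Fresh all-zero Q matrix
#'
#' 360 orientation states (one-degree bins) by two actions
#' (`no_go`, `go`).
#' @return A 360 x 2 numeric matrix of zeros.
#' @export
new_qmatrix <- function() {
  matrix(0, nrow = 360, ncol = 2, dimnames = list(NULL, c("no_go", "go")))
}

#' Discretise an orientation angle into its state index
#'
#' State `mu` in `1..360`; bin `k` covers the interval
#' `[(k-1) degrees, k degrees)` of the angle wrapped to `[0, 2*pi)`.
#'
#' @param phi angle(s) in radians (any finite value).
#' @return Integer state indices.
#' @examples
#' angle_to_state(0) # 1
#' angle_to_state(-pi / 4) # 316
#' @export
angle_to_state <- function(phi) {
  stopifnot(all(is.finite(phi)))
  mu <- floor((phi %% (2 * pi)) * (180 / pi)) + 1
  as.integer(pmin(pmax(mu, 1), 360))
}

#' Greedy action from a Q matrix
#'
#' Picks the action with the larger value in row `mu`; an exact tie is
#' resolved by a fair coin from the session RNG.
#'
#' @param q a Q matrix (any number of rows, two action columns).
#' @param mu state index.
#' @return 0 (NO GO) or 1 (GO).
#' @export
greedy_action <- function(q, mu) {
  stopifnot(mu >= 1, mu <= nrow(q))
  q0 <- q[mu, 1]
  q1 <- q[mu, 2]
  if (q1 > q0) return(1L)
  if (q0 > q1) return(0L)
  if (runif(1) < 0.5) 0L else 1L
}

#' Linearly decaying exploration probability
#'
#' `epsilon = 1 - e / (E - 1)` for episode index `e = 0, ..., E - 1`:
#' fully random in the first episode, fully greedy in the last. A single
#' episode (`E = 1`) is greedy by convention.
#'
#' @param episode zero-based episode index.
#' @param n_episodes episodes per cycle `E`.
#' @return Exploration probability in `[0, 1]`.
#' @export
epsilon_schedule <- function(episode, n_episodes) {
  stopifnot(n_episodes >= 1, episode >= 0, episode < n_episodes)
  if (n_episodes == 1) return(0)
  1 - episode / (n_episodes - 1)
}

#' Single tabular Q-learning update
#'
#' `Q[mu, nu] <- (1 - alpha) Q[mu, nu] + alpha (R + gamma max_a Q[mu', a])`.
#' When the transition is terminal (`mu_next = NULL` or `NA`) the
#' bootstrap term is 0 (absorbing-state convention).
#'
#' @param q a Q matrix.
#' @param mu state in which action `nu` was taken.
#' @param nu action taken (0 or 1).
#' @param reward reward collected on the transition.
#' @param mu_next successor state, or `NULL`/`NA` for a terminal
#'   transition.
#' @param learning_rate,discount hyperparameters `alpha`, `gamma`.
#' @return The updated Q matrix.
#' @export
q_update <- function(q, mu, nu, reward, mu_next = NULL,
                     learning_rate = 0.01, discount = 0.9) {
  stopifnot(mu >= 1, mu <= nrow(q), nu %in% c(0, 1))
  boot <- if (is.null(mu_next) || is.na(mu_next)) 0 else max(q[mu_next, ])
  q[mu, nu + 1L] <- (1 - learning_rate) * q[mu, nu + 1L] +
    learning_rate * (reward + discount * boot)
  q
}

#' Terminal reward at the end of an episode
#'
#' `+R` when the agent reaches the goal edge at `y >= L/2`, `-R` when it
#' hits the bottom at `y <= -L/2`, 0 otherwise.
#'
#' @param y unwrapped vertical position(s).
#' @param half_length half the box side, `L/2`.
#' @param magnitude reward magnitude `R`.
#' @return Reward value(s) in `{+R, 0, -R}`.
#' @export
terminal_reward <- function(y, half_length = 12.5, magnitude = 100) {
  ifelse(y >= half_length, magnitude,
         ifelse(y <= -half_length, -magnitude, 0))
}

#' Run one training episode
#'
#' The hitchhiker starts at the origin with the supplied Q matrix. Every
#' perception time it looks for the nearest bath particle under the
#' minimum-image convention; if none lies within the scan radius it rests
#' (no state, no decision, no learning). Otherwise it observes the
#' partner's orientation state, decides epsilon-greedily, and either
#' shares the partner's path for the next perception interval (GO,
#' including the initial jump onto the partner) or rests (NO GO). Each
#' decision's Q update is applied with reward 0 once the next defined
#' state is observed; the episode ends with a terminal update (+/- R,
#' bootstrap 0) when `|y| >= L/2`, or without one at `t_max`.
#'
#' @param state initial `bath_state` (e.g. from [init_bath()] or a
#'   scripted fixture from [make_fixture()]).
#' @param bath a [bath_params()] object.
#' @param q the Q matrix carried into the episode.
#' @param config a [train_config()] object.
#' @param epsilon exploration probability for this episode.
#' @param seed integer seed.
#' @param record_trajectory also return the substep-resolved trajectory.
#' @return A list with the updated `q`, episode `duration` (perception
#'   times), `outcome` (+1 goal, -1 bottom, 0 timeout), `n_decisions`, a
#'   per-decision data frame `decisions` (time, state, action, explored
#'   flag, partner id), and optionally `trajectory`.
#' @export
run_episode <- function(state, bath, q, config, epsilon, seed = NULL,
                        record_trajectory = FALSE) {
  stopifnot(inherits(state, "bath_state"), inherits(bath, "bath_params"),
            inherits(config, "train_config"),
            epsilon >= 0, epsilon <= 1,
            is.matrix(q), nrow(q) == 360, ncol(q) == 2)
  check_timestep(config, bath)
  s <- resolve_seed(seed)
  out <- cpp_run_episode(
    state$positions[, 1], state$positions[, 2], state$angles,
    bath$box_length, bath$speed, bath$rot_diffusivity, bath$circ_frequency,
    bath$dt, q, config$learning_rate, config$discount,
    config$reward_magnitude, config$t_max, config$perception_time,
    config$scan_radius, epsilon, s, record_trajectory
  )
  dec <- as.data.frame(out$decisions)
  res <- list(q = out$q, duration = out$duration, outcome = out$outcome,
              n_decisions = out$n_decisions, decisions = dec)
  colnames(res$q) <- c("no_go", "go")
  if (record_trajectory) {
    res$trajectory <- new_ihp_trajectory(as.data.frame(out$trajectory))
  }
  res
}

#' Run one complete training cycle
#'
#' A cycle is `episodes_per_cycle` episodes with the exploration
#' probability decaying linearly from one to zero
#' ([epsilon_schedule()]), the Q matrix initialised to zero and carried
#' across episodes, and the bath re-drawn uniformly at every episode
#' start. The per-state greedy action map is extracted from the final Q
#' matrix, with exact ties resolved by recorded coin flips so the
#' aggregate over cycles is reproducible.
#'
#' @inheritParams run_episode
#' @param seed integer seed; episode `e` uses the derived sub-stream
#'   `seed * 1000003 + e`.
#' @return A list with the final `q`, the greedy `action_map` (360 values
#'   0/1), the logical `tie` vector marking states whose action was a
#'   recorded random draw, and the `learning_curve` data frame (episode,
#'   epsilon, duration, outcome, n_decisions).
#' @export
run_training_cycle <- function(bath, config, seed = NULL) {
  stopifnot(inherits(bath, "bath_params"), inherits(config, "train_config"))
  check_timestep(config, bath)
  s <- resolve_seed(seed)
  out <- cpp_run_cycle(
    bath$n_particles, bath$box_length, bath$speed, bath$rot_diffusivity,
    bath$circ_frequency, bath$dt, new_qmatrix(), config$learning_rate,
    config$discount, config$reward_magnitude, config$episodes_per_cycle,
    config$t_max, config$perception_time, config$scan_radius, s
  )
  q <- out$q
  colnames(q) <- c("no_go", "go")
  list(
    q = q,
    action_map = as.integer(out$action_map),
    tie = as.logical(out$tie),
    learning_curve = data.frame(
      episode = seq_len(config$episodes_per_cycle),
      epsilon = out$epsilon,
      duration = out$duration,
      outcome = out$outcome,
      n_decisions = out$n_decisions
    ),
    seed = s
  )
}

#' Tabular Q-learning on a scripted toy Markov decision process
#'
#' Runs the same update rule as the hitchhiker training on a small
#' deterministic MDP (see `make_fixture("toy-mdp")`), which makes the
#' learner directly comparable to a value-iteration oracle.
#'
#' @param mdp a `toy_mdp` fixture: `n_states`, `next_state` and `reward`
#'   matrices indexed by (state, action + 1), with `next_state = 0`
#'   denoting a terminal transition, and a `start` state.
#' @param episodes number of episodes.
#' @param epsilon exploration probability (held fixed).
#' @param learning_rate,discount hyperparameters.
#' @param max_steps per-episode step cap.
#' @return The learned Q matrix (`n_states` x 2).
#' @export
train_toy_mdp <- function(mdp, episodes = 1e4, epsilon = 0.5,
                          learning_rate = 0.01, discount = 0.9,
                          max_steps = 100) {
  stopifnot(inherits(mdp, "toy_mdp"))
  q <- matrix(0, nrow = mdp$n_states, ncol = 2,
              dimnames = list(NULL, c("no_go", "go")))
  for (e in seq_len(episodes)) {
    s <- mdp$start
    for (k in seq_len(max_steps)) {
      a <- if (runif(1) < epsilon) {
        if (runif(1) < 0.5) 0L else 1L
      } else {
        greedy_action(q, s)
      }
      s2 <- mdp$next_state[s, a + 1L]
      r <- mdp$reward[s, a + 1L]
      q <- q_update(q, s, a, r, if (s2 == 0) NULL else s2,
                    learning_rate, discount)
      if (s2 == 0) break
      s <- s2
    }
  }
  q
}
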