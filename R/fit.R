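#' Decision diagram of a trained hitchhiker
#'
#' A decision diagram is the 360-bin binary GO/NO-GO map over partner
#' orientations, together with its pointwise GO probability `h_GO` and the
#' arc descriptors: the GO angle `dphi` (width of the largest contiguous
#' GO arc) and the anticipation angle `phi0` (its circular midpoint,
#' mapped to `(-pi, pi]`). Orientations are indexed in the goal frame:
#' bin 1 starts at relative angle 0, i.e. a partner moving straight
#' towards the goal, so an achiral bath yields a diagram symmetric around
#' `phi0 = 0`.
#'
#' @param h_go numeric vector of 360 GO probabilities in `[0, 1]`.
#' @param n_cycles number of training cycles aggregated into `h_go`.
#' @return An object of class `decision_diagram` with fields `h_go`,
#'   `go_mask` (`h_go >= 0.5`), `phi0`, `dphi` (radians) and `n_cycles`.
#' @seealso [aggregate_diagram()], [diagram_from_arc()],
#'   [extract_go_interval()]
#' @export
decision_diagram <- function(h_go, n_cycles = NA_integer_) {
  stopifnot(length(h_go) == 360, all(h_go >= 0), all(h_go <= 1))
  go_mask <- h_go >= 0.5
  arc <- extract_go_interval(go_mask)
  structure(
    list(h_go = as.numeric(h_go), go_mask = go_mask,
         phi0 = arc[["phi0"]], dphi = arc[["dphi"]],
         n_cycles = n_cycles),
    class = "decision_diagram"
  )
}

#' @export
print.decision_diagram <- function(x, ...) {
  cat("Decision diagram\n")
  cat(sprintf("  GO angle     dphi = %.4f rad (%.1f deg)\n",
              x$dphi, x$dphi * 180 / pi))
  cat(sprintf("  anticipation phi0 = %+.4f rad (%+.1f deg)\n",
              x$phi0, x$phi0 * 180 / pi))
  cat(sprintf("  %d of 360 states GO; aggregated over %s cycle(s)\n",
              sum(x$go_mask), format(x$n_cycles)))
  invisible(x)
}

#' Aggregate per-cycle action maps into a decision diagram
#'
#' `h_GO` for each orientation state is the relative frequency of GO over
#' the supplied greedy action maps (tie draws count as the action that was
#' recorded); states with `h_GO >= 0.5` form the GO set.
#'
#' @param action_maps a matrix (cycles x 360) of 0/1 actions, or a list of
#'   length-360 vectors.
#' @return A [decision_diagram()].
#' @export
aggregate_diagram <- function(action_maps) {
  if (is.list(action_maps)) {
    action_maps <- do.call(rbind, action_maps)
  }
  stopifnot(is.matrix(action_maps), ncol(action_maps) == 360,
            nrow(action_maps) >= 1)
  decision_diagram(colMeans(action_maps), n_cycles = nrow(action_maps))
}

#' Extract the GO arc from a binary mask
#'
#' Finds maximal circular runs of GO states and summarises the longest as
#' an arc `[phi0 - dphi/2, phi0 + dphi/2]`. Length ties are broken towards
#' the run whose midpoint is closest to orientation 0. All-GO gives
#' `(0, 2*pi)`, all-NO-GO gives `(0, 0)`.
#'
#' @param go_mask 360 logicals.
#' @return Named vector `c(phi0 = , dphi = )` in radians, `phi0` in
#'   `(-pi, pi]`.
#' @export
extract_go_interval <- function(go_mask) {
  stopifnot(length(go_mask) == 360)
  go_mask <- as.logical(go_mask)
  if (all(go_mask)) return(c(phi0 = 0, dphi = 2 * pi))
  if (!any(go_mask)) return(c(phi0 = 0, dphi = 0))
  # rotate so the mask starts on a NO-GO bin, making runs non-circular
  first_off <- which(!go_mask)[1]
  rot <- c(go_mask[first_off:360], go_mask[seq_len(first_off - 1)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  # map back to original bin indices (1-based)
  run_start <- (starts[keep] + first_off - 2) %% 360 + 1
  run_len <- r$lengths[keep]
  mid_deg <- ((run_start - 1) + run_len / 2) %% 360
  phi0 <- mid_deg * pi / 180
  phi0 <- ifelse(phi0 > pi, phi0 - 2 * pi, phi0)
  best <- which(run_len == max(run_len))
  if (length(best) > 1) best <- best[which.min(abs(phi0[best]))]
  c(phi0 = phi0[best], dphi = run_len[best] * pi / 180)
}

#' Build a decision diagram from a prescribed GO arc
#'
#' Marks every one-degree state whose bin centre lies within
#' `dphi/2` of `phi0` (with circular periodicity) as GO. Handy for theory
#' comparisons and scripted tests.
#'
#' @param phi0 anticipation angle (radians).
#' @param dphi GO angle (radians, in `[0, 2*pi]`).
#' @return A [decision_diagram()] with 0/1 GO probabilities.
#' @export
diagram_from_arc <- function(phi0, dphi) {
  stopifnot(dphi >= 0, dphi <= 2 * pi)
  centers <- (seq_len(360) - 0.5) * pi / 180
  d <- (centers - phi0) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  decision_diagram(as.numeric(d <= dphi / 2 + 1e-12), n_cycles = NA_integer_)
}

#' Train the intelligent hitchhiking particle
#'
#' Runs `cycles` independent training cycles ([run_training_cycle()]) and
#' aggregates their final greedy action maps into the decision diagram of
#' the fully trained agent. This is the package's model-fitting entry
#' point; the returned object supports `print`, `summary`, `coef`,
#' `predict`, `plot` and `simulate`.
#'
#' With the full protocol (303 cycles of 1000 episodes) this takes hours;
#' scaled-down runs (tens of cycles of a few hundred episodes) already
#' recover the structure of the decision diagram with a few degrees of
#' boundary noise.
#'
#' @param bath a [bath_params()] object (training density 0.6 by default).
#' @param config a [train_config()] object.
#' @param cycles number of training cycles (defaults to
#'   `config$n_cycles`).
#' @param seed integer base seed; cycle `c` uses `seed + c - 1`.
#' @param verbose print a progress line per cycle.
#' @return An object of class `ihp_fit`.
#' @examples
#' \donttest{
#' fit <- ihp_train(cycles = 2,
#'                  config = train_config(episodes_per_cycle = 50),
#'                  seed = 1)
#' coef(fit)
#' }
#' @export
ihp_train <- function(bath = bath_params(), config = train_config(),
                      cycles = config$n_cycles, seed = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(bath, "bath_params"), inherits(config, "train_config"),
            cycles >= 1)
  check_timestep(config, bath)
  base_seed <- resolve_seed(seed)
  cycle_seeds <- base_seed + seq_len(cycles) - 1
  action_maps <- matrix(NA_integer_, nrow = cycles, ncol = 360)
  ties <- matrix(NA, nrow = cycles, ncol = 360)
  durations <- matrix(NA_real_, nrow = cycles,
                      ncol = config$episodes_per_cycle)
  outcomes <- matrix(NA_integer_, nrow = cycles,
                     ncol = config$episodes_per_cycle)
  for (cy in seq_len(cycles)) {
    res <- run_training_cycle(bath, config, seed = cycle_seeds[cy])
    action_maps[cy, ] <- res$action_map
    ties[cy, ] <- res$tie
    durations[cy, ] <- res$learning_curve$duration
    outcomes[cy, ] <- res$learning_curve$outcome
    if (verbose) {
      message(sprintf("cycle %d/%d: mean episode %.0f tau_Q, %d%% reached goal",
                      cy, cycles, mean(res$learning_curve$duration),
                      round(100 * mean(res$learning_curve$outcome == 1))))
    }
  }
  diagram <- aggregate_diagram(action_maps)
  structure(
    list(
      diagram = diagram, h_go = diagram$h_go,
      action_maps = action_maps, ties = ties,
      durations = durations, outcomes = outcomes,
      bath = bath, config = config, cycles = cycles,
      seed = base_seed, cycle_seeds = cycle_seeds,
      call = match.call()
    ),
    class = "ihp_fit"
  )
}

#' @export
print.ihp_fit <- function(x, ...) {
  cat("Trained intelligent hitchhiking particle\n")
  cat(sprintf("  %d cycles x %d episodes (D_r = %g, omega = %g, rho = %g)\n",
              x$cycles, x$config$episodes_per_cycle,
              x$bath$rot_diffusivity, x$bath$circ_frequency,
              x$bath$density))
  print(x$diagram)
  invisible(x)
}

#' @export
summary.ihp_fit <- function(object, ...) {
  d <- object$durations
  ne <- ncol(d)
  head_n <- min(100L, ne)
  out <- list(
    diagram = object$diagram,
    cycles = object$cycles,
    episodes_per_cycle = ne,
    mean_duration_first = mean(d[, seq_len(head_n)]),
    mean_duration_last = mean(d[, ne - seq_len(head_n) + 1]),
    goal_rate_last = mean(object$outcomes[, ne - seq_len(head_n) + 1] == 1),
    bath = object$bath
  )
  class(out) <- "summary.ihp_fit"
  out
}

#' @export
print.summary.ihp_fit <- function(x, ...) {
  print(x$diagram)
  cat(sprintf("Learning curve (%d cycles x %d episodes):\n",
              x$cycles, x$episodes_per_cycle))
  cat(sprintf("  mean episode duration, first %d episodes: %.0f tau_Q\n",
              min(100L, x$episodes_per_cycle), x$mean_duration_first))
  cat(sprintf("  mean episode duration, last  %d episodes: %.0f tau_Q\n",
              min(100L, x$episodes_per_cycle), x$mean_duration_last))
  cat(sprintf("  goal success rate over the last episodes: %.2f\n",
              x$goal_rate_last))
  invisible(x)
}

#' @export
coef.ihp_fit <- function(object, ...) {
  c(phi0 = object$diagram$phi0, dphi = object$diagram$dphi)
}

#' Predict the trained action for partner orientations
#'
#' @param object an `ihp_fit`.
#' @param angles partner orientation angles (radians, bath frame: `pi/2`
#'   is the goal direction, which maps to orientation state 0 of the
#'   diagram).
#' @param type `"action"` for the binary GO/NO-GO decision,
#'   `"probability"` for the aggregated GO frequency `h_GO`.
#' @param ... unused.
#' @return A factor with levels `NO GO`/`GO`, or numeric probabilities.
#' @export
predict.ihp_fit <- function(object, angles,
                            type = c("action", "probability"), ...) {
  type <- match.arg(type)
  mu <- goal_state(angles)
  if (type == "probability") return(object$h_go[mu])
  factor(ifelse(object$diagram$go_mask[mu], "GO", "NO GO"),
         levels = c("NO GO", "GO"))
}

#' Plot a decision diagram
#'
#' Bars show the pointwise GO probability per one-degree orientation bin;
#' the shaded band marks the thresholded GO set.
#'
#' @param x a `decision_diagram` or `ihp_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.decision_diagram <- function(x, ...) {
  deg <- seq_len(360) - 0.5
  bp <- barplot(x$h_go, names.arg = NULL, space = 0, border = NA,
                col = ifelse(x$go_mask, "#2c9e4b", "#c84f4f"),
                xlab = "partner orientation (degrees)",
                ylab = expression(h[GO]), ylim = c(0, 1), ...)
  abline(h = 0.5, lty = 2)
  at <- seq(0, 360, by = 90)
  graphics::axis(1, at = at * max(bp) / 360, labels = at)
  invisible(x)
}

#' @rdname plot.decision_diagram
#' @export
plot.ihp_fit <- function(x, ...) {
  plot(x$diagram, ...)
}

#' Simulate trajectories of a trained hitchhiker
#'
#' Generates `nsim` independent trajectories of the fully trained agent in
#' freshly drawn baths, either with the discrete Q-learning dynamics
#' ([simulate_q_ihp()]) or the continuous potential dynamics
#' ([simulate_potential_ihp()]).
#'
#' @param object an `ihp_fit`.
#' @param nsim number of independent runs.
#' @param seed integer base seed; run `i` uses `seed + i - 1`.
#' @param model `"qlearn"` or `"potential"`.
#' @param bath bath to simulate in (defaults to the training bath).
#' @param duration run length in perception times.
#' @param ... passed on to the simulator.
#' @return A list of `ihp_trajectory` data frames (class
#'   `ihp_ensemble`).
#' @export
simulate.ihp_fit <- function(object, nsim = 1, seed = NULL,
                             model = c("qlearn", "potential"),
                             bath = object$bath, duration = 100, ...) {
  model <- match.arg(model)
  base_seed <- resolve_seed(seed)
  sim1 <- switch(model,
    qlearn = function(s) simulate_q_ihp(object$diagram, bath, duration,
                                        seed = s,
                                        scan_radius = object$config$scan_radius,
                                        perception_time = object$config$perception_time,
                                        ...),
    potential = function(s) simulate_potential_ihp(object$diagram, bath,
                                                   duration, seed = s,
                                                   scan_radius = object$config$scan_radius,
                                                   ...)
  )
  runs <- lapply(seq_len(nsim), function(i) sim1(base_seed + i - 1))
  structure(runs, class = "ihp_ensemble", model = model, seed = base_seed)
}
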