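new_msd_curve <- function(time, msd, se, n_runs) {
  structure(data.frame(time = time, msd = msd, se = se),
            n_runs = n_runs, class = c("msd_curve", "data.frame"))
}

#' Ensemble mean-squared displacement
#'
#' `MSD(t) = < |r(t) - r(0)|^2 >` over a list of equal-grid trajectories
#' with unwrapped positions, together with the standard error of the mean.
#'
#' @param trajectories a non-empty list of `ihp_trajectory` data frames
#'   (or any data frames with `time`, `x`, `y`) sharing one time grid.
#' @return An object of class `msd_curve`: data frame with `time`, `msd`,
#'   `se`, and attribute `n_runs`.
#' @export
ensemble_msd <- function(trajectories) {
  if (!is.list(trajectories) || length(trajectories) == 0) {
    stop("trajectories must be a non-empty list")
  }
  t0 <- trajectories[[1]]$time
  d2 <- vapply(trajectories, function(tr) {
    stopifnot(nrow(tr) == length(t0))
    if (max(abs(tr$time - t0)) > 1e-9) {
      stop("all trajectories must share the same time grid")
    }
    (tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2
  }, numeric(length(t0)))
  d2 <- matrix(d2, nrow = length(t0))
  n <- length(trajectories)
  se <- if (n > 1) apply(d2, 1, sd) / sqrt(n) else rep(NA_real_, length(t0))
  new_msd_curve(t0, rowMeans(d2), se, n)
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lag times in [%g, %g], %s runs\n",
              nrow(x), min(x$time), max(x$time),
              format(attr(x, "n_runs"))))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "xy") {
  keep <- x$time > 0 & x$msd > 0
  plot(x$time[keep], x$msd[keep], type = "l", log = log,
       xlab = "t", ylab = "MSD", ...)
  invisible(x)
}

#' Fraction of runs attached to a partner
#'
#' Reads the per-decision attachment log of [simulate_q_ihp()]
#' trajectories and returns, for each decision epoch, the fraction of
#' runs that are currently riding a partner. The theoretical cumulative
#' probability [p_of_t()] is an upper bound for this fraction.
#'
#' @param trajectories list of trajectories from [simulate_q_ihp()].
#' @return Data frame with `time`, `fraction` and binomial `se`.
#' @export
attachment_fraction <- function(trajectories) {
  eps <- lapply(trajectories, attr, "epochs")
  if (any(vapply(eps, is.null, logical(1)))) {
    stop("trajectories must carry an 'epochs' attribute (see simulate_q_ihp)")
  }
  t0 <- eps[[1]]$time
  att <- vapply(eps, function(e) as.numeric(e$attached), numeric(length(t0)))
  att <- matrix(att, nrow = length(t0))
  n <- length(trajectories)
  fr <- rowMeans(att)
  data.frame(time = t0, fraction = fr, se = sqrt(fr * (1 - fr) / n))
}

#' Probability of an instantaneously suitable travel partner
#'
#' The chance that, at a single decision instant, the nearest-particle
#' scan succeeds: at least one of the `N = round(density * L^2)` uniform
#' particles lies in the observation disc `pi * Rs^2` and the scanned
#' (nearest) particle is favourably oriented, giving
#' `p(0) = (1 - (1 - pi Rs^2 / L^2)^N) * dphi / (2 pi)`.
#'
#' @param go_angle GO angle `dphi` (radians).
#' @param density bath number density.
#' @param box_length box side `L`.
#' @param scan_radius perception range `Rs`.
#' @return Probability in `[0, 1]`.
#' @export
p0 <- function(go_angle, density = 0.6, box_length = 25, scan_radius = 1) {
  stopifnot(go_angle >= 0, go_angle <= 2 * pi, density >= 0,
            pi * scan_radius^2 <= box_length^2)
  n <- round(density * box_length^2)
  (1 - (1 - pi * scan_radius^2 / box_length^2)^n) * go_angle / (2 * pi)
}

#' Partner probability of the potential hitchhiker
#'
#' The potential variant is pulled by every suitable particle at once, so
#' success requires at least one particle that is simultaneously in range
#' and favourably oriented:
#' `1 - (1 - (pi Rs^2 / L^2) * dphi / (2 pi))^N`. This is never smaller
#' than [p0()] and tends to 1 at high density for any positive GO angle,
#' whereas `p0` saturates at `dphi / (2 pi)`.
#'
#' @inheritParams p0
#' @param scan_radius effective perception range; can be reduced below
#'   the nominal scan radius to mimic the looser continuous coupling.
#' @return Probability in `[0, 1]`.
#' @export
p0_potential <- function(go_angle, density = 0.6, box_length = 25,
                         scan_radius = 1) {
  stopifnot(go_angle >= 0, go_angle <= 2 * pi, density >= 0,
            pi * scan_radius^2 <= box_length^2)
  n <- round(density * box_length^2)
  1 - (1 - (pi * scan_radius^2 / box_length^2) * go_angle / (2 * pi))^n
}

#' Cumulative probability of having found a travel partner
#'
#' The agent gets an independent chance [p0()] at every decision epoch
#' (including `t = 0`), so
#' `p(t) = 1 - (1 - p0)^(floor(t / tau_Q) + 1)`: piecewise constant,
#' non-decreasing, bounded in `[0, 1]`.
#'
#' @param t times (>= 0).
#' @inheritParams p0
#' @param perception_time decision interval `tau_Q`.
#' @return Probabilities on `t`.
#' @export
p_of_t <- function(t, go_angle, density = 0.6, box_length = 25,
                   scan_radius = 1, perception_time = 1) {
  stopifnot(all(t >= 0))
  pz <- p0(go_angle, density, box_length, scan_radius)
  1 - (1 - pz)^(floor(t / perception_time) + 1)
}

# exact integral of the piecewise-constant p(t') over [0, t]
integrate_p <- function(t, pz, tau_q) {
  q <- 1 - pz
  m <- floor(t / tau_q)
  # sum_{k=0}^{m-1} (1 - q^{k+1}) * tau_q  +  (1 - q^{m+1}) * (t - m tau_q)
  full <- if (pz >= 1) {
    m * tau_q
  } else if (pz <= 0) {
    0 * m
  } else {
    (m - (q - q^(m + 1)) / (1 - q)) * tau_q
  }
  full + (1 - q^(m + 1)) * (t - m * tau_q)
}

#' Drift-based MSD predictions for the trained hitchhiker
#'
#' The agent either rests or rides at the bath speed, so its mean motion
#' is a drift with hitchhiking velocity `v_H(t) = p(t) v0`. The
#' short-time prediction is the squared integrated drift,
#' `MSD0(t) = (v0 * integral_0^t p(t') dt')^2`, exact while the first
#' partner is still being sought or held. At long times partners are
#' dropped and re-found repeatedly; averaging `p(t) v0` over one
#' persistence time `tau = 1/D_r` gives the asymptotic velocity
#' `v_inf` and `MSDinf(t) = (v_inf t)^2`. Integrals over the
#' piecewise-constant `p` are evaluated exactly.
#'
#' @param t time grid (>= 0).
#' @inheritParams p_of_t
#' @param speed bath speed `v0`.
#' @param rot_diffusivity bath rotational diffusivity (`> 0`).
#' @return A data frame with `time`, `msd0`, `msd_inf`; the asymptotic
#'   hitchhiking velocity is attached as attribute `"v_inf"`.
#' @export
msd_theory <- function(t, go_angle, density = 0.6, box_length = 25,
                       speed = 1.5, rot_diffusivity = 6 * pi^2 * 1e-3,
                       scan_radius = 1, perception_time = 1) {
  stopifnot(all(t >= 0), rot_diffusivity > 0)
  pz <- p0(go_angle, density, box_length, scan_radius)
  tau <- 1 / rot_diffusivity
  s_t <- integrate_p(t, pz, perception_time)
  v_inf <- speed / tau * integrate_p(tau, pz, perception_time)
  structure(
    data.frame(time = t, msd0 = (speed * s_t)^2, msd_inf = (v_inf * t)^2),
    v_inf = v_inf
  )
}

#' Slope of the anticipation angle against the circular frequency
#'
#' Least-squares fit of `phi0 = s * omega * tau_Q` through the origin
#' (symmetry forces `phi0(0) = 0`). The trained agent anticipates the
#' rotation of chiral partners, giving a slope of about -0.64: it picks
#' partners whose orientation will have rotated into the travel direction
#' roughly half a perception time later.
#'
#' @param omegas circular frequencies of the training baths.
#' @param phi0s fitted anticipation angles (radians).
#' @param perception_time decision interval `tau_Q`.
#' @return The slope (radians per unit `omega * tau_Q`).
#' @export
fit_phi0_slope <- function(omegas, phi0s, perception_time = 1) {
  stopifnot(length(omegas) == length(phi0s), length(omegas) >= 2)
  if (length(unique(omegas)) < 2 || all(omegas == 0)) {
    stop("need at least two distinct omega values, not all zero")
  }
  x <- omegas * perception_time
  unname(coef(lm(phi0s ~ 0 + x))[1])
}

#' Empirical trend of the GO angle with the rotational diffusivity
#'
#' Fits `dphi = a + b * D_r + c / D_r` (the 1/D_r term captures the
#' deviation in the extreme-persistence regime) by least squares.
#'
#' @param drs rotational diffusivities (all `> 0`, at least 3 distinct).
#' @param dphis GO angles (radians).
#' @return Named coefficients `c(a = , b = , c = )`.
#' @export
fit_dphi_vs_dr <- function(drs, dphis) {
  stopifnot(length(drs) == length(dphis))
  if (any(drs <= 0)) stop("all D_r values must be positive")
  if (length(unique(drs)) < 3) {
    stop("need at least three distinct D_r values")
  }
  fit <- lm(dphis ~ drs + I(1 / drs))
  stats::setNames(unname(coef(fit)), c("a", "b", "c"))
}

#' Log-log slope of an MSD curve over a time window
#'
#' Least-squares slope of `log(msd)` against `log(t)` on the window:
#' 2 for ballistic, 1 for diffusive motion.
#'
#' @param curve an [ensemble_msd()] curve (or data frame with `time`,
#'   `msd`).
#' @param window length-2 time interval (inclusive).
#' @return The fitted exponent.
#' @export
loglog_slope <- function(curve, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- curve$time >= window[1] & curve$time <= window[2] & curve$time > 0
  if (sum(keep) < 2) stop("window contains fewer than two grid points")
  if (any(curve$msd[keep] <= 0)) {
    stop("msd must be positive throughout the window")
  }
  unname(coef(lm(log(curve$msd[keep]) ~ log(curve$time[keep])))[2])
}
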