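# Independent oracles used against the package's implementations.

# Value iteration on a toy_mdp fixture: the Bellman-optimal Q table.
value_iteration <- function(mdp, discount = 0.9, tol = 1e-12) {
  q <- matrix(0, mdp$n_states, 2)
  repeat {
    qn <- q
    for (s in seq_len(mdp$n_states)) {
      for (a in 0:1) {
        s2 <- mdp$next_state[s, a + 1]
        qn[s, a + 1] <- mdp$reward[s, a + 1] +
          if (s2 == 0) 0 else discount * max(q[s2, ])
      }
    }
    if (max(abs(qn - q)) < tol) return(qn)
    q <- qn
  }
}

# Monte-Carlo placement oracle for the partner probability: scatter N
# uniform points in the box `trials` times, estimate P(at least one within
# Rs of the centre), multiply by the favourable-angle fraction.
mc_p0 <- function(go_angle, density, box_length, scan_radius = 1,
                  trials = 2e4, chunk = 2000) {
  n <- round(density * box_length^2)
  cx <- box_length / 2
  hits <- 0
  done <- 0
  while (done < trials) {
    m <- min(chunk, trials - done)
    dx <- matrix(runif(m * n, 0, box_length) - cx, m, n)
    dy <- matrix(runif(m * n, 0, box_length) - cx, m, n)
    hits <- hits + sum(rowSums(dx^2 + dy^2 <= scan_radius^2) > 0)
    done <- done + m
  }
  p_in <- hits / trials
  list(
    estimate = p_in * go_angle / (2 * pi),
    se = sqrt(p_in * (1 - p_in) / trials) * go_angle / (2 * pi)
  )
}

# Joint consistency check for a sweep of Monte-Carlo z-scores: k separate
# 3-sigma tests carry a 1 - 0.9973^k designed-in false-alarm rate, so the
# sweep is judged at the same 99.73% confidence jointly (chi-square), with
# a 5-sigma gross-error bound per point.
expect_sweep_consistent <- function(z) {
  expect_lt(sum(z^2), stats::qchisq(0.9973, df = length(z)))
  expect_lt(max(abs(z)), 5)
}

# Deterministic single-particle bath state at an arbitrary location.
scripted_state <- function(x, y, phi, box_length = 25) {
  structure(
    list(positions = cbind(x = x, y = y), angles = phi %% (2 * pi), time = 0),
    box_length = box_length, class = "bath_state"
  )
}
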