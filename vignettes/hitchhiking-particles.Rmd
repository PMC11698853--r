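---
title: "Hitchhiking on an active bath: model, training and transport theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hitchhiking on an active bath: model, training and transport theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Many motorless organisms travel by attaching to self-propelled carriers.
This package studies a minimal two-dimensional version of that strategy:
an *intelligent hitchhiking particle* (IHP) without any propulsion of its
own, immersed in a periodic box of `N` non-interacting active Brownian
particles (ABPs). Each bath particle moves at constant speed $v_0$ along
its orientation $\mathbf u_i = (\cos\phi_i, \sin\phi_i)$,

$$\dot{\mathbf r}_i = v_0\,\mathbf u_i(t), \qquad
  \dot\phi_i = \xi_i + \omega,$$

where $\xi_i$ is rotational white noise of strength $2D_\mathrm r$ and a
nonzero circular frequency $\omega$ makes the particles chiral (circle
swimmers). Translational diffusion, inertia and particle–particle
interactions are neglected. The equations are integrated with a forward
Euler–Maruyama scheme: the translation uses the pre-step orientation, and
the orientation increment $\omega\,\Delta t + \sqrt{2D_\mathrm r\Delta
t}\,\eta$ is drawn afterwards.

Units are set by the agent: lengths in scan radii $R_\mathrm s$ and times
in perception times $\tau_Q$. The working point, used as the package
default, is $\rho = 0.6/R_\mathrm s^2$, $L = 25\,R_\mathrm s$ (so $N =
375$), $v_0 = 1.5\,R_\mathrm s/\tau_Q$, $\Delta t = \tau_Q/6$.

The agent's task is to reach the top of the box, half a box length above
its start at the origin. Every perception time it scans for the nearest
bath particle within $R_\mathrm s$ (minimum-image convention) and makes a
binary decision: **GO** — share that particle's path for the next
$\tau_Q$, including an initial jump of at most $R_\mathrm s$ onto the
partner — or **NO GO** — rest (or let go of the current partner). Its
speed is therefore always either $0$ or $v_0$.

### Orientation states and the goal frame

Decisions are based solely on the partner's instantaneous orientation,
discretised into 360 one-degree bins. The state is observed *in the goal
frame*: a partner moving straight towards the goal is in state bin 1
(relative angle $0$). With this convention the trained decision diagram
of an achiral bath is symmetric around $0$, and chirality shows up as a
nonzero arc centre. The diagram is summarised by the GO angle
$\Delta\phi$ (width of the largest contiguous GO arc) and the
anticipation angle $\phi_0$ (its circular midpoint), i.e. the favourable
set is $\Phi_\mathrm{GO} = [\phi_0 - \Delta\phi/2,\, \phi_0 +
\Delta\phi/2]$.

## Training

`ihp_train()` runs tabular Q-learning on the $360\times 2$ state–action
table. Within one *cycle* of `episodes_per_cycle` episodes the Q matrix
starts at zero and is carried across episodes; each episode draws a fresh
uniform bath, places the agent at the origin and runs until it reaches
the top ($+R$) or bottom ($-R$) edge or times out at $t_{\max}$. The
update after action $\nu$ in state $\mu$ is

$$Q_{\mu\nu} \leftarrow (1-\alpha)\,Q_{\mu\nu}
  + \alpha\,(R + \gamma\,\max_\lambda Q_{\mu'\lambda}),$$

with $\alpha = 0.01$, $\gamma = 0.9$, $R = \pm 100$ only at termination
and $0$ within an episode. Decisions are $\varepsilon$-greedy with
$\varepsilon$ decaying linearly from one to zero across the episodes of a
cycle; exact value ties fall to a fair coin.

Conventions the update rule leaves open were fixed as follows:

* **Terminal bootstrap.** The final update of an episode treats the edge
  as an absorbing state (bootstrap term $0$), the standard episodic
  convention. Timeouts end without a terminal update.
* **Deferred updates.** An update needs a successor state. If no particle
  is perceivable at the next decision epoch, the pending update waits for
  the next epoch with a defined state; stateless epochs involve no
  decision, no learning and no exploration draw.
* **Punishment condition.** The terminal reward is $+R$ at $y \ge L/2$
  and $-R$ at $y \le -L/2$ — the bottom edge, matching the task
  symmetry.
* **Literal attachment.** On GO the agent's position *becomes* the
  partner's (tracked unwrapped), including the initial jump of up to
  $R_\mathrm s$. The jump is a genuine, if small, transport channel that
  the drift theory below ignores.

Because the final Q values for sideways orientations are nearly tied,
single-cycle diagrams are noisy. The fully trained diagram is the
aggregate over independent cycles: $h_\mathrm{GO}(\mu)$ is the fraction
of cycles whose final greedy action in state $\mu$ is GO (recorded coin
flips included), thresholded at $1/2$. The reference protocol is 303
cycles of 1000 episodes; the package's tests scale this down to minutes
rather than hours. The two scale knobs are *not* interchangeable:
shortening cycles (fewer episodes) leaves the Q table under-converged
and systematically inflates the anticipation angle (in a chiral bath at
$\omega\tau_Q = 0.36\pi$ the measured ratio $\phi_0/\omega\tau_Q$ is
about $-0.97$ at 300 episodes per cycle but $-0.59$ at the full 1000),
whereas reducing the number of aggregated cycles only adds symmetric
boundary noise of a few degrees. The scaled achiral trainings therefore
use 30–60 shortened cycles (arc structure and symmetry are robust),
while the chiral anticipation sweep keeps full-length 1000-episode
cycles and aggregates 12 of them.

## The potential variant

The learned rule can be transferred to a purely physical, non-reciprocal
interaction: every favourably oriented particle within
$[R_{\min}, R_\mathrm s]$ attracts the agent with potential
$V_0(r) = 5\gamma v_0 R_\mathrm s (1 - R_\mathrm s / r)$, giving the
mobility-normalised kick $5 v_0 R_\mathrm s^2 / r^2$; the friction
$\gamma$ cancels identically (a property the test suite asserts
bitwise). The lower cut-off $R_{\min} = R_\mathrm s / 20$ prevents the
force divergence; inside it the agent is considered attached and feels
no kick. Two discretisation choices matter:

* each substep advances the bath first, then moves the agent against the
  post-step bath (the two orderings differ at $O(\Delta t)$);
* to avoid overshooting a close partner at finite $\Delta t$, the step is
  rescaled to the distance of the *nearest contributing* particle
  whenever it is longer, direction unchanged.

## Transport theory

The agent either rests or rides at $v_0$, so its mean motion is a drift
with hitchhiking velocity $v_\mathrm H(t) = p(t)\,v_0$. At a single
decision instant, the scan succeeds with probability

$$p(0) = \Bigl(1 - \bigl(1 - \tfrac{\pi R_\mathrm s^2}{L^2}\bigr)^{N}\Bigr)
  \frac{\Delta\phi}{2\pi},$$

the chance that at least one uniformly placed particle is in range times
the chance that the scanned orientation is favourable. Successive epochs
are treated as independent draws — the bath decorrelates between epochs —
giving the cumulative staircase $p(t) = 1 - (1 -
p(0))^{\lfloor t/\tau_Q\rfloor + 1}$, an upper bound for the probability
of currently having a partner. From it the package computes

* the short-time prediction $\mathrm{MSD}_0(t) = \bigl(v_0 \int_0^t
  p\,\mathrm dt'\bigr)^2$ (squared integrated drift, fluctuation-free),
* the long-time asymptote $\mathrm{MSD}_\infty(t) = (\bar v_\infty t)^2$
  with $\bar v_\infty = (v_0/\tau)\int_0^\tau p\,\mathrm dt'$, the drift
  averaged over one persistence time $\tau = 1/D_\mathrm r$, which
  accounts for the repeated letting-go and re-finding of partners.

Integrals over the piecewise-constant $p$ are evaluated exactly. For a
ragged aggregated mask the fraction $\Delta\phi/2\pi$ is taken as the GO
fraction `mean(go_mask)` — the literal meaning of the favourable-angle
fraction — rather than the width of the largest arc alone.

Two caveats, both visible in the package's own simulations: at sub-epoch
times the simulated MSD exceeds $\mathrm{MSD}_0$ because of the
attachment jump (a displacement of order $R_\mathrm s$ the drift picture
omits), and $\bar v_\infty$ slightly overestimates the late-time velocity
because riding partners spread over the GO arc rather than moving
straight towards the goal. The quantitative checks in the test suite are
therefore placed where the theory claims validity: the staircase as an
upper bound on the attachment fraction, the late-time log–log slope of
$2$, and the ordering of agent versus bath MSDs.

The analogous partner probability of the potential variant,
`p0_potential()`, requires simultaneous range and orientation,
$1 - (1 - \frac{\pi R_\mathrm s^2}{L^2}\frac{\Delta\phi}{2\pi})^N$; it
dominates $p(0)$ everywhere and tends to one at high density, which is
why the potential agent moves first at short times while the Q-agent,
whose scan is confined to a single nearest particle, saturates at
$\Delta\phi/2\pi$.

## What the learned strategy looks like

Two robust trends emerge from training, both covered by the acceptance
tests:

* **GO angle vs persistence.** The less persistent the bath (larger
  $D_\mathrm r$, larger $|\omega|$), the wider the learned GO angle: with
  quickly randomising partners it pays to take a leap of faith and opt
  out later, whereas in a persistent bath selectivity wins. The empirical
  trend is fitted by `fit_dphi_vs_dr()` as $a + b D_\mathrm r + c /
  D_\mathrm r$, the $1/D_\mathrm r$ term capturing the extreme-persistence
  regime ($l_\mathrm p \gg L$) where the finite box suppresses learning.
* **Anticipation vs chirality.** In a chiral bath the agent prefers
  partners whose orientation will have rotated *into* the goal direction
  during the ride: $\phi_0 \approx -0.64\,\omega\tau_Q$, about half the
  angle a partner turns in one perception time, with the opposite sign of
  $\omega$. `fit_phi0_slope()` fits this through the origin, since
  symmetry forces $\phi_0(\omega = 0) = 0$.

```{r example}
library(ihp)
fit <- ihp_train(bath = bath_params(circ_frequency = 0.36 * pi),
                 config = train_config(episodes_per_cycle = 1000),
                 cycles = 12, seed = 1)
coef(fit)     # phi0 < 0: anticipates the counter-clockwise-turning partners
plot(fit)     # pointwise GO probability with the thresholded arc
```

## Numerical choices and degenerate inputs

* Orientation bins follow `floor(deg) + 1`: bin $k$ covers
  $[(k-1)^\circ, k^\circ)$; binning and box/angle wrapping use identical
  floor-based arithmetic in R and in the compiled core.
* The arc extractor takes the longest circular GO run; length ties go to
  the run whose midpoint is closest to the goal direction. An all-GO mask
  yields $(\phi_0, \Delta\phi) = (0, 2\pi)$, an all-NO-GO mask $(0, 0)$.
* Empty baths are valid states everywhere: episodes run to $t_{\max}$
  without decisions, simulators return trajectories pinned at the
  origin.
* The perception time must be an integer multiple of $\Delta t$
  (enforced, tolerance $10^{-9}$).
* All randomness in the compiled core comes from a
  xoshiro256++/Marsaglia-polar stream seeded from one integer;
  cycle $c$ of a training uses `seed + c - 1`, and the Q-learning and
  potential simulators consume draws in the same order so that
  seed-matched runs see identical baths (used for the paired model
  comparison). Runs are bitwise reproducible given a seed.

## What the synthetic world does and does not establish

All inputs are generated in-package; there is no external data. The bath
is drawn uniformly in position and orientation — the maximum-entropy
choice for a homogeneous bath — and re-drawn each episode, so the agent
never exploits a particular configuration. Green tests establish that
the implementation reproduces the stated dynamics, that training
converges to the expected strategy structure at reduced scale, and that
the analytic theory describes the package's own simulations in their
regimes of validity. They do not establish behaviour for interacting
bath particles, inertial dynamics, reciprocal agent–bath coupling, or
translational diffusion, all of which are outside the model.

## Known limitations

* Reduced-scale diagrams carry a few degrees of boundary noise; the
  anticipation-slope check correspondingly uses a wider tolerance than a
  full 303-cycle protocol would need, and episodes-per-cycle must not be
  scaled down for that check (see the training section).
* The drift theory has no closed form for the intermediate sub-ballistic
  regime; only its short- and long-time limbs are predicted.
* The chiral single-particle MSD has no closed form in the package; the
  achiral expression `abp_msd_closed_form()` refuses $\omega \neq 0$.
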