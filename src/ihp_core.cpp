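// Core numerics: Euler-Maruyama bath integration, Q-learning episodes,
// and trajectory generation for both IHP variants. Everything here is
// driven from thin R wrappers; all randomness comes from a self-contained
// counter-seeded xoshiro256++ stream so that a run is reproducible from a
// single integer seed regardless of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925286766559;
// the navigational goal lies along +y; orientation states are observed in
// the goal frame, so state 0 means "moving towards the goal"
const double GOAL_ANGLE = 1.5707963267948966;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++ with cached Box-Muller normals.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Rng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }

  inline double unif() {  // [0, 1)
    return (double)(next() >> 11) * 0x1.0p-53;
  }

  inline double norm() {  // Marsaglia polar method, spare cached
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }

  inline int coin() { return (next() >> 63) ? 1 : 0; }
};

inline uint64_t mix_seed(double seed, uint64_t stream) {
  // distinct sub-streams from one base seed
  return (uint64_t)(int64_t)seed * 0x9e3779b97f4a7c15ULL + stream;
}

// ---------------------------------------------------------------------------
// Bath of non-interacting (chiral) active Brownian particles.
// ---------------------------------------------------------------------------
struct BathPar {
  int n;
  double L, v0, Dr, om, dt;
};

struct Bath {
  std::vector<double> x, y, phi;  // positions wrapped to [0,L); phi unwrapped
};

// floor-based wrap, matching R's %% semantics exactly
inline double wrap_box(double v, double L) {
  double u = v - L * std::floor(v / L);
  if (u < 0) u = 0.0;
  if (u >= L) u = 0.0;
  return u;
}

inline double wrap_angle(double a) {
  double u = a - TWO_PI * std::floor(a / TWO_PI);
  if (u < 0) u = 0.0;
  if (u >= TWO_PI) u = 0.0;
  return u;
}

// state bin: bin k covers [(k-1) deg, k deg); identical formula on the R side
inline int angle_bin(double phi) {
  int mu = (int)std::floor(wrap_angle(phi) * (180.0 / M_PI)) + 1;
  if (mu < 1) mu = 1;
  if (mu > 360) mu = 360;
  return mu;
}

inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

void init_bath_uniform(Bath &b, const BathPar &p, Rng &rng) {
  b.x.resize(p.n);
  b.y.resize(p.n);
  b.phi.resize(p.n);
  for (int i = 0; i < p.n; ++i) {
    b.x[i] = rng.unif() * p.L;
    b.y[i] = rng.unif() * p.L;
    b.phi[i] = rng.unif() * TWO_PI;
  }
}

// One Euler-Maruyama substep for the whole bath. The translation uses the
// pre-step angle; the orientation update is drawn afterwards. If `partner`
// is >= 0 that particle's raw displacement is reported (for a riding IHP).
inline void bath_substep(Bath &b, const BathPar &p, Rng &rng, bool periodic,
                         int partner, double *pdx, double *pdy) {
  const double sig = std::sqrt(2.0 * p.Dr * p.dt);
  const double wdt = p.om * p.dt;
  const double vdt = p.v0 * p.dt;
  const double L = p.L;
  const int n = p.n;
  for (int i = 0; i < n; ++i) {
    double c = std::cos(b.phi[i]);
    double s = std::sin(b.phi[i]);
    double dx = vdt * c, dy = vdt * s;
    if (i == partner) {
      *pdx = dx;
      *pdy = dy;
    }
    double nx = b.x[i] + dx, ny = b.y[i] + dy;
    if (periodic) {
      if (nx < 0) nx += L; else if (nx >= L) nx -= L;
      if (ny < 0) ny += L; else if (ny >= L) ny -= L;
    }
    b.x[i] = nx;
    b.y[i] = ny;
    double dphi = wdt;
    if (sig > 0) dphi += sig * rng.norm();
    b.phi[i] += dphi;
  }
}

// nearest particle to (px,py) under the minimum-image convention
inline int nearest_idx(const Bath &b, const BathPar &p, double px, double py,
                       double *best_d2) {
  int bi = -1;
  double bd = HUGE_VAL;
  for (int j = 0; j < p.n; ++j) {
    double dx = min_image(b.x[j] - px, p.L);
    double dy = min_image(b.y[j] - py, p.L);
    double d2 = dx * dx + dy * dy;
    if (d2 < bd) {
      bd = d2;
      bi = j;
    }
  }
  *best_d2 = bd;
  return bi;
}

// ---------------------------------------------------------------------------
// Q-learning episode
// ---------------------------------------------------------------------------
struct TrainPar {
  double alpha, gamma, Rmag, tauQ, Rs, half;
  int nsub;        // substeps per perception time
  int max_epochs;  // T_max / tauQ
};

struct EpisodeLog {
  std::vector<double> time;
  std::vector<int> mu, nu, explored, partner;
};

struct EpisodeOut {
  double duration;
  int outcome;  // +1 top, -1 bottom, 0 timeout
  int ndecisions;
};

inline void q_upd(double *Q, int mu, int nu, double alpha, double gamma,
                  double reward, double boot) {
  double *cell = Q + (mu - 1) + 360 * nu;
  *cell = (1.0 - alpha) * (*cell) + alpha * (reward + gamma * boot);
}

inline int greedy(const double *Q, int mu, Rng &rng) {
  double q0 = Q[mu - 1], q1 = Q[mu - 1 + 360];
  if (q1 > q0) return 1;
  if (q0 > q1) return 0;
  return rng.coin();
}

EpisodeOut run_episode_core(Bath &b, const BathPar &p, const TrainPar &tp,
                            double *Q, double eps, Rng &rng, bool learn,
                            const int *go_mask,  // non-null => fixed policy
                            EpisodeLog *log, std::vector<double> *traj,
                            std::vector<int> *traj_partner,
                            std::vector<int> *epoch_attached) {
  double ix = 0.0, iy = 0.0;  // IHP position, tracked unwrapped
  int attached = -1;
  int pend_mu = -1, pend_nu = 0;
  EpisodeOut out;
  out.duration = NA_REAL;
  out.outcome = 0;
  out.ndecisions = 0;

  const bool terminate_at_goal = (go_mask == nullptr);
  if (traj) {
    traj->push_back(0.0);
    traj->push_back(ix);
    traj->push_back(iy);
    if (traj_partner) traj_partner->push_back(NA_INTEGER);
  }

  for (int n = 0; n < tp.max_epochs; ++n) {
    // ---- decision at t = n tauQ ----
    double d2;
    int j = (p.n > 0) ? nearest_idx(b, p, wrap_box(ix, p.L), wrap_box(iy, p.L), &d2)
                      : -1;
    if (j >= 0 && d2 <= tp.Rs * tp.Rs) {
      int mu = angle_bin(b.phi[j] - GOAL_ANGLE);
      if (learn && pend_mu >= 0) {
        double boot = std::max(Q[mu - 1], Q[mu - 1 + 360]);
        q_upd(Q, pend_mu, pend_nu, tp.alpha, tp.gamma, 0.0, boot);
        pend_mu = -1;
      }
      int nu, expl = 0;
      if (go_mask != nullptr) {
        nu = go_mask[mu - 1];
      } else if (eps > 0 && rng.unif() < eps) {
        nu = rng.coin();
        expl = 1;
      } else {
        nu = greedy(Q, mu, rng);
      }
      out.ndecisions++;
      if (log) {
        log->time.push_back(n * tp.tauQ);
        log->mu.push_back(mu);
        log->nu.push_back(nu);
        log->explored.push_back(expl);
        log->partner.push_back(j + 1);
      }
      if (learn) {
        pend_mu = mu;
        pend_nu = nu;
      }
      if (nu == 1) {
        // literal attachment: IHP position becomes the partner's, the jump
        // expressed as a minimum-image displacement so unwrapped tracking holds
        double dx = min_image(b.x[j] - wrap_box(ix, p.L), p.L);
        double dy = min_image(b.y[j] - wrap_box(iy, p.L), p.L);
        ix += dx;
        iy += dy;
        attached = j;
        if (terminate_at_goal && std::fabs(iy) >= tp.half) {
          out.duration = n * tp.tauQ;
          out.outcome = (iy >= tp.half) ? 1 : -1;
          break;
        }
      } else {
        attached = -1;
      }
    } else {
      attached = -1;  // nothing perceivable: rest, no state, no learning
    }
    if (epoch_attached) epoch_attached->push_back(attached >= 0 ? 1 : 0);

    // ---- propagate one perception interval ----
    bool terminated = false;
    for (int k = 0; k < tp.nsub; ++k) {
      double pdx = 0.0, pdy = 0.0;
      bath_substep(b, p, rng, true, attached, &pdx, &pdy);
      if (attached >= 0) {
        ix += pdx;
        iy += pdy;
      }
      if (traj) {
        traj->push_back(n * tp.tauQ + (k + 1) * p.dt);
        traj->push_back(ix);
        traj->push_back(iy);
        if (traj_partner)
          traj_partner->push_back(attached >= 0 ? attached + 1 : NA_INTEGER);
      }
      if (terminate_at_goal && attached >= 0 && std::fabs(iy) >= tp.half) {
        out.duration = n * tp.tauQ + (k + 1) * p.dt;
        out.outcome = (iy >= tp.half) ? 1 : -1;
        terminated = true;
        break;
      }
    }
    if (terminated || out.outcome != 0) break;
  }

  if (out.outcome != 0) {
    if (learn && pend_mu >= 0) {  // terminal update, absorbing state: boot = 0
      q_upd(Q, pend_mu, pend_nu, tp.alpha, tp.gamma, out.outcome * tp.Rmag, 0.0);
    }
  } else {
    out.duration = (double)tp.max_epochs * tp.tauQ;  // timed out, no reward
  }
  return out;
}

TrainPar make_train_par(double alpha, double gamma, double Rmag, double tauQ,
                        double Rs, double L, double dt, double tmax) {
  TrainPar tp;
  tp.alpha = alpha;
  tp.gamma = gamma;
  tp.Rmag = Rmag;
  tp.tauQ = tauQ;
  tp.Rs = Rs;
  tp.half = 0.5 * L;
  tp.nsub = (int)std::lround(tauQ / dt);
  tp.max_epochs = (int)std::ceil(tmax / tauQ - 1e-9);
  return tp;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_init_bath(int n, double L, double seed) {
  Rng rng(mix_seed(seed, 1));
  BathPar p;
  p.n = n;
  p.L = L;
  Bath b;
  init_bath_uniform(b, p, rng);
  return List::create(_["x"] = NumericVector(b.x.begin(), b.x.end()),
                      _["y"] = NumericVector(b.y.begin(), b.y.end()),
                      _["phi"] = NumericVector(b.phi.begin(), b.phi.end()));
}

// Propagate a bath for `nsteps` substeps, recording snapshots after the step
// counts listed in `record` (1-based, increasing). phi is returned unwrapped;
// positions are wrapped when `periodic`, free-space otherwise.
// [[Rcpp::export]]
List cpp_bath_evolve(NumericVector x0, NumericVector y0, NumericVector phi0,
                     double L, double v0, double Dr, double om, double dt,
                     int nsteps, double seed, bool periodic,
                     IntegerVector record) {
  BathPar p;
  p.n = x0.size();
  p.L = L;
  p.v0 = v0;
  p.Dr = Dr;
  p.om = om;
  p.dt = dt;
  Bath b;
  b.x.assign(x0.begin(), x0.end());
  b.y.assign(y0.begin(), y0.end());
  b.phi.assign(phi0.begin(), phi0.end());
  Rng rng(mix_seed(seed, 2));

  int nrec = record.size();
  NumericMatrix xs(nrec, p.n), ys(nrec, p.n), phis(nrec, p.n);
  int ri = 0;
  double pdx, pdy;
  for (int s = 1; s <= nsteps; ++s) {
    bath_substep(b, p, rng, periodic, -1, &pdx, &pdy);
    while (ri < nrec && record[ri] == s) {
      for (int i = 0; i < p.n; ++i) {
        xs(ri, i) = b.x[i];
        ys(ri, i) = b.y[i];
        phis(ri, i) = b.phi[i];
      }
      ++ri;
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["phi"] = phis);
}

// [[Rcpp::export]]
List cpp_nearest(NumericVector x, NumericVector y, double px, double py,
                 double L) {
  BathPar p;
  p.n = x.size();
  p.L = L;
  Bath b;
  b.x.assign(x.begin(), x.end());
  b.y.assign(y.begin(), y.end());
  if (p.n == 0)
    return List::create(_["index"] = NA_INTEGER, _["distance"] = NA_REAL);
  double d2;
  int j = nearest_idx(b, p, wrap_box(px, L), wrap_box(py, L), &d2);
  return List::create(_["index"] = j + 1, _["distance"] = std::sqrt(d2));
}

// Single episode on a caller-supplied bath configuration (scripted fixtures).
// [[Rcpp::export]]
List cpp_run_episode(NumericVector x0, NumericVector y0, NumericVector phi0,
                     double L, double v0, double Dr, double om, double dt,
                     NumericMatrix Qin, double alpha, double gamma,
                     double Rmag, double tmax, double tauQ, double Rs,
                     double eps, double seed, bool record_traj) {
  BathPar p;
  p.n = x0.size();
  p.L = L;
  p.v0 = v0;
  p.Dr = Dr;
  p.om = om;
  p.dt = dt;
  Bath b;
  b.x.assign(x0.begin(), x0.end());
  b.y.assign(y0.begin(), y0.end());
  b.phi.assign(phi0.begin(), phi0.end());
  for (int i = 0; i < p.n; ++i) b.x[i] = wrap_box(b.x[i], L);
  for (int i = 0; i < p.n; ++i) b.y[i] = wrap_box(b.y[i], L);

  NumericMatrix Q = clone(Qin);
  TrainPar tp = make_train_par(alpha, gamma, Rmag, tauQ, Rs, L, dt, tmax);
  Rng rng(mix_seed(seed, 3));
  EpisodeLog log;
  std::vector<double> traj;
  std::vector<int> traj_partner;
  EpisodeOut out = run_episode_core(b, p, tp, REAL(Q), eps, rng, true, nullptr,
                                    &log, record_traj ? &traj : nullptr,
                                    record_traj ? &traj_partner : nullptr,
                                    nullptr);

  List res = List::create(
      _["q"] = Q, _["duration"] = out.duration, _["outcome"] = out.outcome,
      _["n_decisions"] = out.ndecisions,
      _["decisions"] = List::create(
          _["time"] = NumericVector(log.time.begin(), log.time.end()),
          _["mu"] = IntegerVector(log.mu.begin(), log.mu.end()),
          _["nu"] = IntegerVector(log.nu.begin(), log.nu.end()),
          _["explored"] = IntegerVector(log.explored.begin(), log.explored.end()),
          _["partner"] = IntegerVector(log.partner.begin(), log.partner.end())));
  if (record_traj) {
    int np = traj.size() / 3;
    NumericVector t(np), tx(np), ty(np);
    IntegerVector pr(np);
    for (int i = 0; i < np; ++i) {
      t[i] = traj[3 * i];
      tx[i] = traj[3 * i + 1];
      ty[i] = traj[3 * i + 2];
      pr[i] = traj_partner[i];
    }
    res["trajectory"] =
        List::create(_["time"] = t, _["x"] = tx, _["y"] = ty, _["partner"] = pr);
  }
  return res;
}

// One full training cycle: E episodes on freshly drawn baths, epsilon
// decaying linearly from 1 to 0, Q carried across episodes.
// [[Rcpp::export]]
List cpp_run_cycle(int n_particles, double L, double v0, double Dr, double om,
                   double dt, NumericMatrix Qin, double alpha, double gamma,
                   double Rmag, int episodes, double tmax, double tauQ,
                   double Rs, double seed) {
  BathPar p;
  p.n = n_particles;
  p.L = L;
  p.v0 = v0;
  p.Dr = Dr;
  p.om = om;
  p.dt = dt;
  TrainPar tp = make_train_par(alpha, gamma, Rmag, tauQ, Rs, L, dt, tmax);
  NumericMatrix Q = clone(Qin);
  double *q = REAL(Q);

  NumericVector durations(episodes);
  IntegerVector outcomes(episodes), ndec(episodes);
  NumericVector epsv(episodes);
  Bath b;
  for (int e = 0; e < episodes; ++e) {
    double eps = (episodes > 1) ? 1.0 - (double)e / (episodes - 1) : 0.0;
    epsv[e] = eps;
    Rng rng(mix_seed(seed, 1000003ULL * (uint64_t)(e + 1)));
    init_bath_uniform(b, p, rng);
    EpisodeOut out = run_episode_core(b, p, tp, q, eps, rng, true, nullptr,
                                      nullptr, nullptr, nullptr, nullptr);
    durations[e] = out.duration;
    outcomes[e] = out.outcome;
    ndec[e] = out.ndecisions;
    if (e % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // final greedy action map; exact ties resolved by a recorded coin flip
  IntegerVector action(360);
  LogicalVector tie(360);
  Rng rng_a(mix_seed(seed, 0xA11ACEDULL));
  for (int mu = 1; mu <= 360; ++mu) {
    double q0 = q[mu - 1], q1 = q[mu - 1 + 360];
    tie[mu - 1] = (q0 == q1);
    action[mu - 1] = (q1 > q0) ? 1 : (q0 > q1 ? 0 : rng_a.coin());
  }
  return List::create(_["q"] = Q, _["action_map"] = action, _["tie"] = tie,
                      _["duration"] = durations, _["outcome"] = outcomes,
                      _["n_decisions"] = ndec, _["epsilon"] = epsv);
}

// Fully trained Q-IHP: greedy decisions from a fixed GO mask, no learning,
// no goal termination; runs for n_epochs perception times.
// [[Rcpp::export]]
List cpp_simulate_q(IntegerVector go_mask, int n_particles, double L,
                    double v0, double Dr, double om, double dt, int n_epochs,
                    double tauQ, double Rs, double seed, NumericVector x0,
                    NumericVector y0, NumericVector phi0) {
  BathPar p;
  p.n = n_particles;
  p.L = L;
  p.v0 = v0;
  p.Dr = Dr;
  p.om = om;
  p.dt = dt;
  TrainPar tp = make_train_par(0.0, 0.0, 0.0, tauQ, Rs, L, dt,
                               (double)n_epochs * tauQ);
  Rng rng(mix_seed(seed, 4));
  Bath b;
  if (x0.size() == p.n && p.n > 0) {
    b.x.assign(x0.begin(), x0.end());
    b.y.assign(y0.begin(), y0.end());
    b.phi.assign(phi0.begin(), phi0.end());
  } else {
    init_bath_uniform(b, p, rng);
  }
  std::vector<double> traj;
  std::vector<int> traj_partner, epoch_attached;
  std::vector<int> mask(360);
  for (int i = 0; i < 360; ++i) mask[i] = go_mask[i];
  run_episode_core(b, p, tp, nullptr, 0.0, rng, false, mask.data(), nullptr,
                   &traj, &traj_partner, &epoch_attached);
  int np = traj.size() / 3;
  NumericVector t(np), tx(np), ty(np);
  IntegerVector pr(np);
  for (int i = 0; i < np; ++i) {
    t[i] = traj[3 * i];
    tx[i] = traj[3 * i + 1];
    ty[i] = traj[3 * i + 2];
    pr[i] = traj_partner[i];
  }
  return List::create(
      _["time"] = t, _["x"] = tx, _["y"] = ty, _["partner"] = pr,
      _["attached"] =
          IntegerVector(epoch_attached.begin(), epoch_attached.end()));
}

// Potential IHP: bath advances first, then the IHP is displaced by the sum
// of mobility-normalised kicks 5 v0 Rs^2 / r^2 from every favourably
// oriented particle with Rmin <= r <= Rs; the step is capped at the distance
// to the nearest contributing particle.
// [[Rcpp::export]]
List cpp_simulate_potential(IntegerVector go_mask, int n_particles, double L,
                            double v0, double Dr, double om, double dt,
                            int n_steps, double Rs, double Rmin, double amp,
                            double seed, NumericVector x0, NumericVector y0,
                            NumericVector phi0) {
  BathPar p;
  p.n = n_particles;
  p.L = L;
  p.v0 = v0;
  p.Dr = Dr;
  p.om = om;
  p.dt = dt;
  Rng rng(mix_seed(seed, 4));  // same stream id as the Q variant: paired baths
  Bath b;
  if (x0.size() == p.n && p.n > 0) {
    b.x.assign(x0.begin(), x0.end());
    b.y.assign(y0.begin(), y0.end());
    b.phi.assign(phi0.begin(), phi0.end());
  } else {
    init_bath_uniform(b, p, rng);
  }
  double ix = 0.0, iy = 0.0;
  NumericVector t(n_steps + 1), tx(n_steps + 1), ty(n_steps + 1);
  t[0] = 0.0;
  tx[0] = 0.0;
  ty[0] = 0.0;
  const double Rs2 = Rs * Rs, Rmin2 = Rmin * Rmin;
  double pdx, pdy;
  for (int s = 1; s <= n_steps; ++s) {
    bath_substep(b, p, rng, true, -1, &pdx, &pdy);
    double wx = wrap_box(ix, L), wy = wrap_box(iy, L);
    double fx = 0.0, fy = 0.0, dmin2 = HUGE_VAL;
    for (int i = 0; i < p.n; ++i) {
      double dx = min_image(b.x[i] - wx, L);
      double dy = min_image(b.y[i] - wy, L);
      double r2 = dx * dx + dy * dy;
      if (r2 > Rs2 || r2 < Rmin2) continue;
      if (!go_mask[angle_bin(b.phi[i] - GOAL_ANGLE) - 1]) continue;
      double r = std::sqrt(r2);
      double mag = amp * v0 * Rs2 / r2;
      fx += mag * dx / r;
      fy += mag * dy / r;
      if (r2 < dmin2) dmin2 = r2;
    }
    double sx = dt * fx, sy = dt * fy;
    if (dmin2 < HUGE_VAL) {
      double dl = std::sqrt(sx * sx + sy * sy);
      double dmin = std::sqrt(dmin2);
      if (dl > dmin) {
        double sc = dmin / dl;
        sx *= sc;
        sy *= sc;
      }
    }
    ix += sx;
    iy += sy;
    t[s] = s * dt;
    tx[s] = ix;
    ty[s] = iy;
  }
  return List::create(_["time"] = t, _["x"] = tx, _["y"] = ty);
}
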