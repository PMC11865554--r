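// Policy-tree planner core for the TCG surprise model.
//
// States are 0-based row-major indices on an nr x nc grid.  Absolute
// directions are 0=N, 1=E, 2=S, 3=W (clockwise; N decreases the row).
// Heading-relative index rel = (move - heading + 4) % 4: 0=F, 1=R, 2=B, 3=L.
// Variants: 0 = surprise (combined priors, phase 2 drops surprise),
//           1 = state   (state prior only, both phases),
//           2 = movement (movement prior only, both phases).
// Branch aggregation over trajectories sharing a first move:
//           0 = max (default), 1 = sum, 2 = mean.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int DROW[4] = {-1, 0, 1, 0};
static const int DCOL[4] = {0, 1, 0, -1};
static const double LOG2E = 1.4426950408889634;  // 1/log(2)

struct Ctx {
  int nr, nc, sg, rg;
  double eps;
  int variant, horizon, agg;
  double mvrel[4];               // movement prior by relative F, R, B, L
  std::vector<double> apow;      // alpha^-d for d = 0..max distance
  std::vector<double> epow;      // eps^i for i = 0..horizon
};

static inline int rdist(const Ctx &c, int a, int b) {
  return std::abs(a / c.nc - b / c.nc) + std::abs(a % c.nc - b % c.nc);
}

static inline bool feasible(const Ctx &c, int s, int d, int &next) {
  int r = s / c.nc + DROW[d], cc = s % c.nc + DCOL[d];
  if (r < 0 || r >= c.nr || cc < 0 || cc >= c.nc) return false;
  next = r * c.nc + cc;
  return true;
}

// action prior over the four absolute moves; infeasible moves get -1.
// mode: 0 combined movement x state, 1 state only, 2 movement only.
static void action_prior(const Ctx &c, int s, int heading, int mode,
                         double p[4]) {
  double tot = 0.0;
  for (int d = 0; d < 4; ++d) {
    int next;
    if (!feasible(c, s, d, next)) { p[d] = -1.0; continue; }
    double w = 1.0;
    if (mode != 1)  // movement factor (uniform before the first move)
      w *= (heading < 0) ? 1.0 : c.mvrel[(d - heading + 4) % 4];
    if (mode != 2)  // state factor
      w *= c.apow[rdist(c, next, c.sg)];
    p[d] = w;
    tot += w;
  }
  for (int d = 0; d < 4; ++d) if (p[d] >= 0.0) p[d] /= tot;
}

static inline double surprise_bits(double p) {
  if (p < 1e-15) p = 1e-15;  // only reachable with lambda = 0 demo priors
  return -std::log(p) * LOG2E;
}

// per-move step values at a node: val[d] = NA-like (-inf) for infeasible
// moves; `steps` moves were taken before this node, rgvis marks a prior
// visit to the receiver goal, i is the planning depth (0 = immediate).
static void node_values(const Ctx &c, int s, int heading, int steps,
                        bool rgvis, int i, double val[4]) {
  double p[4];
  bool use_surprise;
  switch (c.variant) {
  case 0:
    use_surprise = !rgvis;
    action_prior(c, s, heading, rgvis ? 1 : 0, p);
    break;
  case 1:
    use_surprise = false;
    action_prior(c, s, heading, 1, p);
    break;
  default:
    use_surprise = true;
    action_prior(c, s, heading, 2, p);
  }
  double disc = c.epow[i];
  for (int d = 0; d < 4; ++d) {
    int next;
    if (!feasible(c, s, d, next)) { val[d] = R_NegInf; continue; }
    bool vis_next = rgvis || next == c.rg;
    int rem = vis_next ? rdist(c, next, c.sg)
                       : rdist(c, next, c.rg) + rdist(c, c.rg, c.sg);
    double r = 10.0 - (steps + 1) - rem;
    val[d] = (use_surprise ? surprise_bits(p[d]) : p[d]) * disc * r;
  }
}

// aggregated continuation value of the subtree rooted at a node reached
// after `steps` moves, at planning depth i.  Branches stop at the sender
// goal (arrival there ends the message) and at the horizon.
static double cont_value(const Ctx &c, int s, int heading, int steps,
                         bool rgvis, int i) {
  if (i >= c.horizon || s == c.sg) return 0.0;
  double val[4];
  node_values(c, s, heading, steps, rgvis, i, val);
  double best = 0.0, sum = 0.0;
  int k = 0;
  for (int d = 0; d < 4; ++d) {
    if (val[d] == R_NegInf) continue;
    int next;
    feasible(c, s, d, next);
    double v = val[d] +
      cont_value(c, next, d, steps + 1, rgvis || next == c.rg, i + 1);
    if (k == 0 || v > best) best = v;
    sum += v;
    ++k;
  }
  if (c.agg == 0) return best;
  if (c.agg == 1) return sum;
  return sum / k;
}

// EV over the four absolute moves at the current node (NA for infeasible)
static void expected_values(const Ctx &c, int s, int heading, int steps,
                            bool rgvis, double ev[4]) {
  double val[4];
  node_values(c, s, heading, steps, rgvis, 0, val);
  for (int d = 0; d < 4; ++d) {
    if (val[d] == R_NegInf) { ev[d] = NA_REAL; continue; }
    int next;
    feasible(c, s, d, next);
    ev[d] = val[d] +
      cont_value(c, next, d, steps + 1, rgvis || next == c.rg, 1);
  }
}

static void softmax4(const double ev[4], double tau, double pr[4]) {
  double mx = R_NegInf;
  for (int d = 0; d < 4; ++d)
    if (!ISNA(ev[d]) && ev[d] > mx) mx = ev[d];
  double tot = 0.0;
  for (int d = 0; d < 4; ++d) {
    if (ISNA(ev[d])) { pr[d] = NA_REAL; continue; }
    pr[d] = std::exp(tau * (ev[d] - mx));
    tot += pr[d];
  }
  for (int d = 0; d < 4; ++d) if (!ISNA(pr[d])) pr[d] /= tot;
}

static Ctx make_ctx(int nr, int nc, int sg, int rg, double lambda,
                    double gamma, double alpha, double eps, int variant,
                    int horizon, int agg) {
  Ctx c;
  c.nr = nr; c.nc = nc; c.sg = sg; c.rg = rg;
  c.eps = eps;
  c.variant = variant; c.horizon = horizon; c.agg = agg;
  double pf = gamma / (gamma + 1.0) * (1.0 - lambda);
  double plr = 0.5 * (1.0 - gamma / (gamma + 1.0)) * (1.0 - lambda);
  c.mvrel[0] = pf; c.mvrel[1] = plr; c.mvrel[2] = lambda; c.mvrel[3] = plr;
  int dmax = nr + nc;
  c.apow.resize(dmax + 1);
  for (int d = 0; d <= dmax; ++d) c.apow[d] = std::pow(alpha, -d);
  c.epow.resize(horizon + 1);
  for (int i = 0; i <= horizon; ++i) c.epow[i] = std::pow(eps, i);
  return c;
}

// recorded (observer-side) prior for step records: the variant's own prior
// structure, with the surprise variant keeping the combined prior in both
// phases so the step surprise is defined for the whole message.
static int record_mode(int variant) {
  return variant == 0 ? 0 : (variant == 1 ? 1 : 2);
}

// [[Rcpp::export]]
List cpp_plan_step(int nr, int nc, int sg, int rg, int s, int heading,
                   int steps, bool rgvis, int variant, double lambda,
                   double gamma, double alpha, double eps, double tau,
                   int horizon, int agg) {
  Ctx c = make_ctx(nr, nc, sg, rg, lambda, gamma, alpha, eps, variant,
                   horizon, agg);
  double ev[4], pr[4], prior[4];
  expected_values(c, s, heading, steps, rgvis, ev);
  softmax4(ev, tau, pr);
  action_prior(c, s, heading, record_mode(variant), prior);
  NumericVector evv(4), prv(4), prior_v(4), sup(4);
  for (int d = 0; d < 4; ++d) {
    evv[d] = ev[d]; prv[d] = pr[d];
    prior_v[d] = prior[d] < 0 ? NA_REAL : prior[d];
    sup[d] = prior[d] < 0 ? NA_REAL : surprise_bits(prior[d]);
  }
  return List::create(_["ev"] = evv, _["policy"] = prv,
                      _["prior"] = prior_v, _["surprise"] = sup);
}

// [[Rcpp::export]]
double cpp_sequence_loglik(IntegerVector traj, int nr, int nc, int sg, int rg,
                           int variant, double lambda, double gamma,
                           double alpha, double eps, double tau, int horizon,
                           int agg) {
  Ctx c = make_ctx(nr, nc, sg, rg, lambda, gamma, alpha, eps, variant,
                   horizon, agg);
  int n = traj.size();
  if (n < 2) stop("trajectory needs at least one move");
  double ll = 0.0;
  int heading = -1;
  bool rgvis = false;
  for (int t = 0; t + 1 < n; ++t) {
    int s = traj[t], nxt = traj[t + 1], move = -1;
    for (int d = 0; d < 4; ++d) {
      int cand;
      if (feasible(c, s, d, cand) && cand == nxt) { move = d; break; }
    }
    if (move < 0) stop("illegal move in trajectory at step %d", t + 1);
    double ev[4], pr[4];
    expected_values(c, s, heading, t, rgvis, ev);
    softmax4(ev, tau, pr);
    double p = pr[move];
    if (p < 1e-300) p = 1e-300;
    ll += std::log(p);
    heading = move;
    rgvis = rgvis || nxt == c.rg;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_nll_subject(List trajs, IntegerMatrix goals, int nr, int nc,
                       int variant, double lambda, double gamma, double alpha,
                       double eps, double tau, int horizon, int agg) {
  double nll = 0.0;
  for (int i = 0; i < trajs.size(); ++i) {
    IntegerVector traj = trajs[i];
    nll -= cpp_sequence_loglik(traj, nr, nc, goals(i, 0), goals(i, 1),
                               variant, lambda, gamma, alpha, eps, tau,
                               horizon, agg);
  }
  return nll;
}

// [[Rcpp::export]]
List cpp_generate(int nr, int nc, int start, int sg, int rg, int variant,
                  double lambda, double gamma, double alpha, double eps,
                  double tau, int horizon, int agg, int guard,
                  NumericVector unifs) {
  Ctx c = make_ctx(nr, nc, sg, rg, lambda, gamma, alpha, eps, variant,
                   horizon, agg);
  std::vector<int> traj;
  traj.push_back(start);
  int s = start, heading = -1;
  bool rgvis = false, aborted = false;
  int t = 0;
  while (s != c.sg) {
    if (t >= guard) { aborted = true; break; }
    double ev[4], pr[4];
    expected_values(c, s, heading, t, rgvis, ev);
    softmax4(ev, tau, pr);
    double u = unifs[t], cum = 0.0;
    int move = -1;
    for (int d = 0; d < 4; ++d) {
      if (ISNA(pr[d])) continue;
      cum += pr[d];
      move = d;
      if (u <= cum) break;
    }
    int next;
    feasible(c, s, move, next);
    traj.push_back(next);
    heading = move;
    rgvis = rgvis || next == c.rg;
    s = next;
    ++t;
  }
  return List::create(_["traj"] = wrap(traj), _["aborted"] = aborted);
}

// [[Rcpp::export]]
DataFrame cpp_step_info(IntegerVector traj, int nr, int nc, int sg, int rg,
                        int variant, double lambda, double gamma, double alpha,
                        double eps, double tau, int horizon, int agg) {
  Ctx c = make_ctx(nr, nc, sg, rg, lambda, gamma, alpha, eps, variant,
                   horizon, agg);
  int n = traj.size() - 1;
  IntegerVector phase(n), move(n);
  NumericVector sup(n), prior_p(n), policy_p(n), evv(n);
  int heading = -1;
  bool rgvis = false;
  for (int t = 0; t < n; ++t) {
    int s = traj[t], nxt = traj[t + 1], mv = -1;
    for (int d = 0; d < 4; ++d) {
      int cand;
      if (feasible(c, s, d, cand) && cand == nxt) { mv = d; break; }
    }
    if (mv < 0) stop("illegal move in trajectory at step %d", t + 1);
    double ev[4], pr[4], prior[4];
    expected_values(c, s, heading, t, rgvis, ev);
    softmax4(ev, tau, pr);
    action_prior(c, s, heading, record_mode(variant), prior);
    phase[t] = rgvis ? 2 : 1;
    move[t] = mv;
    sup[t] = surprise_bits(prior[mv]);
    prior_p[t] = prior[mv];
    policy_p[t] = pr[mv];
    evv[t] = ev[mv];
    heading = mv;
    rgvis = rgvis || nxt == c.rg;
  }
  return DataFrame::create(_["phase"] = phase, _["move"] = move,
                           _["surprise"] = sup, _["prior_p"] = prior_p,
                           _["policy_p"] = policy_p, _["ev"] = evv);
}
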