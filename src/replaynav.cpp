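// Core simulation engine: grid-world water maze, place-cell network,
// trajectory memory vault, replay consolidation, striatal action selection,
// and the tabular Q-learning baselines.  All randomness goes through R's RNG
// (unif_rand), so set.seed() at the R level makes every run reproducible.
//
// Draw order per environment step:
//   [selection] epsilon draw, then either 1 uniform (explore) or 0/1 tie draw;
//   cold start: 1 branch draw, then 0/1 uniform action draw.
//   [environment] 1 perturbation draw for a movement action, plus 1 side draw
//   when the 20% deviation fires; the stay action draws nothing.
// Replay and virtual-path construction are deterministic (no draws).

#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// actions: 0=N 1=NE 2=E 3=SE 4=S 5=SW 6=W 7=NW 8=stay
static const int DX[9] = { 0, 1, 1, 1, 0,-1,-1,-1, 0};
static const int DY[9] = { 1, 1, 0,-1,-1,-1, 0, 1, 0};
static const double SQ2 = 0.7071067811865476;
// heading unit vectors; stay maps to angle 0 (east) by convention
static const double HCOS[9] = { 0, SQ2, 1, SQ2, 0,-SQ2,-1,-SQ2, 1};
static const double HSIN[9] = { 1, SQ2, 0,-SQ2,-1,-SQ2, 0, SQ2, 0};

static const int N_ACT = 9;
static const int N_MOVE = 8;
static const int SDIM = 5;

// ---------------------------------------------------------------------------
struct Maze {
  int w, h;
  std::vector<char> obst;       // w*h, 1 = obstacle
  int sx, sy, gx, gy;
  double r_obs, r_goal, r_step;
  double p_intended;
  bool blocked(int x, int y) const {
    if (x < 0 || y < 0 || x >= w || y >= h) return true;
    return obst[x + y * w] != 0;
  }
};

static Maze maze_from_list(const List& m) {
  Maze z;
  z.w = as<int>(m["width"]);
  z.h = as<int>(m["height"]);
  z.obst.assign(z.w * z.h, 0);
  IntegerMatrix ob = m["obstacles"];
  for (int i = 0; i < ob.nrow(); ++i) {
    int x = ob(i, 0), y = ob(i, 1);
    if (x >= 0 && y >= 0 && x < z.w && y < z.h) z.obst[x + y * z.w] = 1;
  }
  IntegerVector s = m["start"], g = m["goal"];
  z.sx = s[0]; z.sy = s[1]; z.gx = g[0]; z.gy = g[1];
  NumericVector rw = m["rewards"];
  z.r_obs = rw[0]; z.r_goal = rw[1]; z.r_step = rw[2];
  z.p_intended = as<double>(m["p_intended"]);
  return z;
}

struct NetCfg {
  double sigma, delta, s_gate, m_gate;
  double recruit_threshold, recruit_floor;
  int max_cells;
  bool position_only;   // zero out heading/occupancy channels of the encoder
};

static NetCfg netcfg_from_list(const List& c) {
  NetCfg n;
  n.sigma = as<double>(c["sigma_pc"]);
  n.delta = as<double>(c["delta"]);
  n.s_gate = as<double>(c["s_gate"]);
  n.m_gate = as<double>(c["m_gate"]);
  n.recruit_threshold = as<double>(c["recruit_threshold"]);
  n.recruit_floor = as<double>(c["recruit_floor"]);
  n.max_cells = as<int>(c["max_cells"]);
  n.position_only = as<bool>(c["position_only"]);
  return n;
}

struct PolCfg {
  double eps, p_random, theta, alpha, gamma;
  bool cold_start;
  int live_td;   // 0 = off, 1 = full (plain on-line TD), 2 = refresh-only
};

static PolCfg polcfg_from_list(const List& c) {
  PolCfg p;
  p.eps = as<double>(c["epsilon"]);
  p.p_random = as<double>(c["p_random"]);
  p.theta = as<double>(c["theta"]);
  p.alpha = as<double>(c["alpha"]);
  p.gamma = as<double>(c["gamma"]);
  p.cold_start = as<bool>(c["cold_start"]);
  std::string lt = as<std::string>(c["live_td"]);
  p.live_td = lt == "full" ? 1 : (lt == "refresh" ? 2 : 0);
  return p;
}

// ---------------------------------------------------------------------------
// place-cell pool
struct Pool {
  int n = 0;
  std::vector<double> WS;   // n x SDIM, row-major
  std::vector<double> WM;   // n
  std::vector<double> Q;    // n x N_ACT, row-major
  std::vector<int> react;   // n
  std::vector<int> last_react;  // consolidation round of last reactivation
  int saturated_events = 0; // pool full while input below recruit threshold
};

static Pool pool_from_list(const List& p) {
  Pool q;
  NumericMatrix ws = p["W_S"];
  NumericVector wm = p["W_M"];
  NumericMatrix qv = p["q_values"];
  IntegerVector rc = p["reactivations"];
  IntegerVector lr = p["last_reactivated"];
  q.n = ws.nrow();
  q.WS.resize(q.n * SDIM);
  q.WM.resize(q.n);
  q.Q.resize(q.n * N_ACT);
  q.react.resize(q.n);
  q.last_react.resize(q.n);
  for (int i = 0; i < q.n; ++i) {
    for (int k = 0; k < SDIM; ++k) q.WS[i * SDIM + k] = ws(i, k);
    q.WM[i] = wm[i];
    for (int a = 0; a < N_ACT; ++a) q.Q[i * N_ACT + a] = qv(i, a);
    q.react[i] = rc[i];
    q.last_react[i] = lr[i];
  }
  return q;
}

static List pool_to_list(const Pool& p) {
  NumericMatrix ws(p.n, SDIM);
  NumericVector wm(p.n);
  NumericMatrix qv(p.n, N_ACT);
  IntegerVector rc(p.n);
  IntegerVector lr(p.n);
  for (int i = 0; i < p.n; ++i) {
    for (int k = 0; k < SDIM; ++k) ws(i, k) = p.WS[i * SDIM + k];
    wm[i] = p.WM[i];
    for (int a = 0; a < N_ACT; ++a) qv(i, a) = p.Q[i * N_ACT + a];
    rc[i] = p.react[i];
    lr[i] = p.last_react[i];
  }
  return List::create(_["W_S"] = ws, _["W_M"] = wm, _["q_values"] = qv,
                      _["reactivations"] = rc, _["last_reactivated"] = lr,
                      _["saturated_events"] = p.saturated_events);
}

// firing rate of one cell: channel-gated Gaussian over the joint input
static inline double cell_rate(const Pool& p, int i, const double* S, double M,
                               const NetCfg& cfg) {
  double d2 = 0.0;
  const double* w = &p.WS[i * SDIM];
  for (int k = 0; k < SDIM; ++k) { double d = S[k] - w[k]; d2 += d * d; }
  double dist = cfg.s_gate * std::sqrt(d2) + cfg.m_gate * std::fabs(M - p.WM[i]);
  return std::exp(-(dist * dist) / (2.0 * cfg.sigma * cfg.sigma));
}

static void activate_all(const Pool& p, const double* S, double M,
                         const NetCfg& cfg, std::vector<double>& v) {
  v.resize(p.n);
  for (int i = 0; i < p.n; ++i) v[i] = cell_rate(p, i, S, M, cfg);
}

static int argmax_rate(const std::vector<double>& v) {
  int w = 0;
  for (int i = 1; i < (int)v.size(); ++i) if (v[i] > v[w]) w = i;
  return w;
}

// competitive observation: recruit on novelty, else move the winner
static int observe_core(Pool& p, const double* S, double M, const NetCfg& cfg,
                        std::vector<double>& v, bool learn) {
  activate_all(p, S, M, cfg, v);
  double vmax = p.n ? v[argmax_rate(v)] : -1.0;
  if (p.n == 0 || (vmax < cfg.recruit_threshold && p.n < cfg.max_cells)) {
    for (int k = 0; k < SDIM; ++k) p.WS.push_back(S[k]);
    p.WM.push_back(M);
    for (int a = 0; a < N_ACT; ++a) p.Q.push_back(0.0);
    p.react.push_back(0);
    p.last_react.push_back(-1);
    p.n++;
    v.push_back(1.0);
    return p.n - 1;
  }
  int win = argmax_rate(v);
  if (vmax < cfg.recruit_threshold) p.saturated_events++;
  if (learn) {
    double* w = &p.WS[win * SDIM];
    for (int k = 0; k < SDIM; ++k) w[k] += cfg.delta * (S[k] - w[k]);
    p.WM[win] += cfg.delta * (M - p.WM[win]);
  }
  return win;
}

// filtered mean q-values over the active cells; returns the active count
static int filtered_q(const Pool& p, const std::vector<double>& v, double theta,
                      double* qv, std::vector<int>* active) {
  for (int a = 0; a < N_ACT; ++a) qv[a] = 0.0;
  int m = 0;
  for (int i = 0; i < p.n; ++i) {
    if (v[i] > theta) {
      ++m;
      if (active) active->push_back(i);
      for (int a = 0; a < N_ACT; ++a) qv[a] += p.Q[i * N_ACT + a];
    }
  }
  if (m > 0) for (int a = 0; a < N_ACT; ++a) qv[a] /= m;
  return m;
}

static double max_q(const double* qv) {
  double m = qv[0];
  for (int a = 1; a < N_ACT; ++a) if (qv[a] > m) m = qv[a];
  return m;
}

// best continuation under the cognitive-map prior: an action the map has
// never valued is taken at the reward-free fixed point r_step/(1-gamma),
// the value of moving forever without finding reward.  Known routes beat
// ignorance, and looping regions drain to the prior and release the agent.
static inline double map_prior(const PolCfg& c, double r_step) {
  return r_step / (1.0 - c.gamma);
}

static double guided_max(const double* qv, double prior) {
  double m = qv[0] != 0.0 ? qv[0] : prior;
  for (int a = 1; a < N_ACT; ++a) {
    double q = qv[a] != 0.0 ? qv[a] : prior;
    if (q > m) m = q;
  }
  return m;
}

// ---------------------------------------------------------------------------
// state encoder: position in grid-cell units + heading + local occupancy
static void encode_core(const Maze& z, int x, int y, int heading,
                        bool position_only, double* S) {
  S[0] = (double)x;
  S[1] = (double)y;
  if (position_only) { S[2] = S[3] = S[4] = 0.0; return; }
  S[2] = HCOS[heading];
  S[3] = HSIN[heading];
  int occ = 0;
  for (int a = 0; a < N_MOVE; ++a)
    if (z.blocked(x + DX[a], y + DY[a])) ++occ;
  S[4] = occ / 8.0;
}

// ---------------------------------------------------------------------------
// environment step with 80/20 action perturbation
struct StepOut { int nx, ny, executed; double reward; bool hit, goal; };

static StepOut step_core(const Maze& z, int x, int y, int a) {
  StepOut o;
  o.executed = a;
  if (a != 8) {
    double u = unif_rand();
    if (u >= z.p_intended) {
      double v = unif_rand();
      o.executed = (a + (v < 0.5 ? 7 : 1)) % N_MOVE;  // compass-adjacent
    }
  }
  int nx = x + DX[o.executed], ny = y + DY[o.executed];
  if (z.blocked(nx, ny)) {
    o.nx = x; o.ny = y; o.hit = true; o.goal = false; o.reward = z.r_obs;
  } else {
    o.nx = nx; o.ny = ny; o.hit = false;
    o.goal = (nx == z.gx && ny == z.gy);
    o.reward = o.goal ? z.r_goal : z.r_step;
  }
  return o;
}

// ---------------------------------------------------------------------------
// shared epsilon-greedy / cold-start action selection
static int select_core(const double* qv, bool any_active, const PolCfg& c,
                       int last_action, double r_step) {
  // Cold start is judged on the incumbent state-direction pair: while the
  // current direction is still unvalued the agent keeps moving ballistically
  // (or turns at random with probability P), the behaviour that lets it
  // explore corridor mazes before any reward information exists.  Greedy
  // choice is guided by the cognitive map, i.e. it ranges over the movement
  // actions the map has actually valued; with the brain-inspired policy
  // disabled (cold_start = FALSE) selection is plain epsilon-greedy over all
  // eight movements, as in the tabular baselines.
  bool cold = !any_active;
  double prior = map_prior(c, r_step);
  double qe[N_MOVE];
  if (any_active) {
    if (c.cold_start) {
      int nvalued = 0;
      for (int a = 0; a < N_MOVE; ++a) {
        qe[a] = qv[a] != 0.0 ? qv[a] : prior;
        if (qv[a] != 0.0) ++nvalued;
      }
      if (nvalued == 0) cold = true;
      else if (last_action >= 0 && qv[last_action] == 0.0) cold = true;
      else {
        // the map only guides where its best promise exceeds the aimless-
        // wandering baseline by at least one step's cost; beyond the
        // discount horizon the value signal is below that margin and the
        // explorer takes over
        double best = qe[0];
        for (int a = 1; a < N_MOVE; ++a) if (qe[a] > best) best = qe[a];
        if (best <= prior - r_step) cold = true;
      }
    } else {
      for (int a = 0; a < N_MOVE; ++a) qe[a] = qv[a];
    }
  }
  if (cold && (c.cold_start || !any_active)) {
    double u = unif_rand();
    if (u < c.p_random) return (int)std::floor(unif_rand() * N_ACT) % N_ACT;
    if (last_action >= 0) return last_action;
    return (int)std::floor(unif_rand() * N_MOVE) % N_MOVE;
  }
  double u = unif_rand();
  if (u < c.eps) return (int)std::floor(unif_rand() * N_ACT) % N_ACT;
  // greedy over the 8 movements, ties uniform
  double best = qe[0];
  for (int a = 1; a < N_MOVE; ++a) if (qe[a] > best) best = qe[a];
  int ties[N_MOVE], m = 0;
  for (int a = 0; a < N_MOVE; ++a) if (qe[a] == best) ties[m++] = a;
  if (m == 1) return ties[0];
  return ties[(int)std::floor(unif_rand() * m) % m];
}

// ---------------------------------------------------------------------------
// trajectory sequences and the memory vault
struct Seq {
  std::vector<int> x, y, a, cell;
  std::vector<double> r;
  std::vector<double> svec;   // n x SDIM
  int outcome;                // 0 low, 1 high, 2 virtual
  double total;
  long serial;
  int len() const { return (int)x.size(); }
};

static List seq_to_list(const Seq& s) {
  int n = s.len();
  NumericMatrix sv(n, SDIM);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < SDIM; ++k) sv(i, k) = s.svec[i * SDIM + k];
  CharacterVector oc(1);
  oc[0] = s.outcome == 1 ? "high" : (s.outcome == 2 ? "virtual" : "low");
  return List::create(
    _["x"] = IntegerVector(s.x.begin(), s.x.end()),
    _["y"] = IntegerVector(s.y.begin(), s.y.end()),
    _["action"] = IntegerVector(s.a.begin(), s.a.end()),
    _["cell_id"] = IntegerVector(s.cell.begin(), s.cell.end()),
    _["reward"] = NumericVector(s.r.begin(), s.r.end()),
    _["state_vec"] = sv,
    _["outcome"] = oc,
    _["total_reward"] = s.total,
    _["serial"] = (double)s.serial);
}

static Seq seq_from_list(const List& l) {
  Seq s;
  IntegerVector x = l["x"], y = l["y"], a = l["action"], c = l["cell_id"];
  NumericVector r = l["reward"];
  NumericMatrix sv = l["state_vec"];
  int n = x.size();
  s.x.assign(x.begin(), x.end());
  s.y.assign(y.begin(), y.end());
  s.a.assign(a.begin(), a.end());
  s.cell.assign(c.begin(), c.end());
  s.r.assign(r.begin(), r.end());
  s.svec.resize(n * SDIM);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < SDIM; ++k) s.svec[i * SDIM + k] = sv(i, k);
  std::string oc = as<std::string>(l["outcome"]);
  s.outcome = oc == "high" ? 1 : (oc == "virtual" ? 2 : 0);
  s.total = as<double>(l["total_reward"]);
  s.serial = (long)as<double>(l["serial"]);
  return s;
}

struct Vault {
  std::vector<Seq> high, low, virt;
  int cap_high, cap_low, cap_virt;
  int max_len = 64;          // stored tail length (about the gamma-horizon)
  long serial = 0;
  std::set<std::pair<long,long> > tried;          // (low serial, high serial)
  std::set<std::vector<int> > virt_keys;          // cell-id sequences

  // keep only the final max_len triples: beyond the discount horizon the
  // stored prefix carries no recoverable reward signal, and bounded storage
  // keeps every stored sequence fully replayable within the budget
  void truncate(Seq& s) const {
    int n = s.len();
    if (max_len <= 0 || n <= max_len) return;
    int cut = n - max_len;
    s.x.erase(s.x.begin(), s.x.begin() + cut);
    s.y.erase(s.y.begin(), s.y.begin() + cut);
    s.a.erase(s.a.begin(), s.a.begin() + cut);
    s.cell.erase(s.cell.begin(), s.cell.begin() + cut);
    s.r.erase(s.r.begin(), s.r.begin() + cut);
    s.svec.erase(s.svec.begin(), s.svec.begin() + (size_t)cut * SDIM);
  }

  void push(std::vector<Seq>& lst, int cap, Seq s) {
    truncate(s);
    s.serial = ++serial;
    lst.push_back(std::move(s));
    while ((int)lst.size() > cap) lst.erase(lst.begin());   // FIFO
  }
};

static Vault vault_from_list(const List& vl) {
  Vault v;
  v.cap_high = as<int>(vl["capacity_high"]);
  v.cap_low = as<int>(vl["capacity_low"]);
  v.cap_virt = as<int>(vl["capacity_virtual"]);
  v.max_len = as<int>(vl["max_stored_length"]);
  v.serial = (long)as<double>(vl["serial"]);
  List hi = vl["high"], lo = vl["low"], vi = vl["virtual"];
  for (int i = 0; i < hi.size(); ++i) v.high.push_back(seq_from_list(hi[i]));
  for (int i = 0; i < lo.size(); ++i) v.low.push_back(seq_from_list(lo[i]));
  for (int i = 0; i < vi.size(); ++i) {
    Seq s = seq_from_list(vi[i]);
    v.virt_keys.insert(s.cell);
    v.virt.push_back(std::move(s));
  }
  NumericMatrix tr = vl["tried"];
  for (int i = 0; i < tr.nrow(); ++i)
    v.tried.insert(std::make_pair((long)tr(i,0), (long)tr(i,1)));
  return v;
}

static List vault_to_list(const Vault& v) {
  List hi(v.high.size()), lo(v.low.size()), vi(v.virt.size());
  for (size_t i = 0; i < v.high.size(); ++i) hi[i] = seq_to_list(v.high[i]);
  for (size_t i = 0; i < v.low.size(); ++i) lo[i] = seq_to_list(v.low[i]);
  for (size_t i = 0; i < v.virt.size(); ++i) vi[i] = seq_to_list(v.virt[i]);
  NumericMatrix tr(v.tried.size(), 2);
  int i = 0;
  for (std::set<std::pair<long,long> >::const_iterator it = v.tried.begin();
       it != v.tried.end(); ++it, ++i) {
    tr(i, 0) = (double)it->first; tr(i, 1) = (double)it->second;
  }
  return List::create(_["high"] = hi, _["low"] = lo, _["virtual"] = vi,
                      _["capacity_high"] = v.cap_high,
                      _["capacity_low"] = v.cap_low,
                      _["capacity_virtual"] = v.cap_virt,
                      _["max_stored_length"] = v.max_len,
                      _["serial"] = (double)v.serial, _["tried"] = tr);
}

// intersections: every shared cell id, last index in low / first in high
static void intersections_core(const std::vector<int>& low,
                               const std::vector<int>& high,
                               std::vector<int>& ids, std::vector<int>& li,
                               std::vector<int>& hi) {
  std::set<int> hset(high.begin(), high.end());
  std::set<int> done;
  for (int j = (int)low.size() - 1; j >= 0; --j) {
    int id = low[j];
    if (hset.count(id) && !done.count(id)) {
      done.insert(id);
      int first = 0;
      while (high[first] != id) ++first;
      ids.push_back(id); li.push_back(j); hi.push_back(first);
    }
  }
}

// choose: longest low prefix; ties -> longest high suffix, then lowest cell id
static int select_intersection_core(const std::vector<int>& ids,
                                    const std::vector<int>& li,
                                    const std::vector<int>& hi) {
  int best = 0;
  for (size_t k = 1; k < ids.size(); ++k) {
    if (li[k] > li[best] ||
        (li[k] == li[best] && hi[k] < hi[best]) ||
        (li[k] == li[best] && hi[k] == hi[best] && ids[k] < ids[best]))
      best = (int)k;
  }
  return best;
}

// action index moving (x,y) -> (nx,ny), or -1 if not a single move
static int action_towards(int x, int y, int nx, int ny) {
  for (int a = 0; a < N_ACT; ++a)
    if (x + DX[a] == nx && y + DY[a] == ny) return a;
  return -1;
}

// splice low[0..li] with high[hi+1..]; the splice triple's action is redirected
// onto the high branch and its reward reset to the ordinary step penalty
static bool construct_virtual_core(const Seq& low, const Seq& high, int li,
                                   int hi, double r_step, Seq& out) {
  int nh = high.len();
  out = Seq();
  out.outcome = 2;
  for (int j = 0; j <= li; ++j) {
    out.x.push_back(low.x[j]); out.y.push_back(low.y[j]);
    out.a.push_back(low.a[j]); out.cell.push_back(low.cell[j]);
    out.r.push_back(low.r[j]);
    for (int k = 0; k < SDIM; ++k) out.svec.push_back(low.svec[j * SDIM + k]);
  }
  if (hi + 1 < nh) {
    int act = action_towards(low.x[li], low.y[li], high.x[hi + 1], high.y[hi + 1]);
    if (act < 0) return false;                 // non-adjacent splice: reject
    out.a[li] = act;
    out.r[li] = r_step;
    for (int j = hi + 1; j < nh; ++j) {
      out.x.push_back(high.x[j]); out.y.push_back(high.y[j]);
      out.a.push_back(high.a[j]); out.cell.push_back(high.cell[j]);
      out.r.push_back(high.r[j]);
      for (int k = 0; k < SDIM; ++k) out.svec.push_back(high.svec[j * SDIM + k]);
    }
  } else {
    // splice at the final high triple: the low prefix must already sit next to
    // the goal transition; redirect the last action onto the goal if adjacent
    int act = action_towards(low.x[li], low.y[li], high.x[nh - 1] + DX[high.a[nh-1]],
                             high.y[nh - 1] + DY[high.a[nh-1]]);
    if (act < 0) return false;
    out.a[li] = act;
    out.r[li] = high.r[nh - 1];
  }
  out.total = 0.0;
  for (size_t j = 0; j < out.r.size(); ++j) out.total += out.r[j];
  return true;
}

// refresh the virtual store from stored low x high pairs (newest first)
static int refresh_virtual_core(Vault& v, double r_step, int pair_budget) {
  int used = 0, made = 0;
  for (int ih = (int)v.high.size() - 1; ih >= 0 && used < pair_budget; --ih) {
    for (int il = (int)v.low.size() - 1; il >= 0 && used < pair_budget; --il) {
      std::pair<long,long> key(v.low[il].serial, v.high[ih].serial);
      if (v.tried.count(key)) continue;
      v.tried.insert(key);
      ++used;
      std::vector<int> ids, li, hi;
      intersections_core(v.low[il].cell, v.high[ih].cell, ids, li, hi);
      if (ids.empty()) continue;
      int k = select_intersection_core(ids, li, hi);
      Seq vs;
      if (!construct_virtual_core(v.low[il], v.high[ih], li[k], hi[k], r_step, vs))
        continue;
      if (v.virt_keys.count(vs.cell)) continue;
      v.virt_keys.insert(vs.cell);
      v.push(v.virt, v.cap_virt, vs);
      while ((int)v.virt.size() > v.cap_virt) v.virt.erase(v.virt.begin());
      ++made;
    }
  }
  return made;
}

// ---------------------------------------------------------------------------
// replay one reward-associated sequence through the filtered TD update;
// the memory channel is driven at 1 and stored state vectors are re-presented
static int replay_seq_core(Pool& p, const Seq& s, const NetCfg& nc,
                           const PolCfg& pc, double r_step, int round) {
  int n = s.len();
  if (n == 0) return 0;
  std::vector<double> v, vnext;
  double qv[N_ACT], qnext[N_ACT];
  std::vector<int> active;
  activate_all(p, &s.svec[0], 1.0, nc, v);
  for (int j = 0; j < n; ++j) {
    active.clear();
    int m = filtered_q(p, v, pc.theta, qv, &active);
    double target_next = 0.0;
    bool next_defined = (j + 1 == n);   // terminal triple bootstraps from 0
    if (j + 1 < n) {
      activate_all(p, &s.svec[(j + 1) * SDIM], 1.0, nc, vnext);
      if (filtered_q(p, vnext, pc.theta, qnext, 0) > 0) {
        // bootstrap from the best continuation under the map prior:
        // unvalued actions count as r_step/(1-gamma), so propagation starts
        // pessimistically from below and rises as goal information arrives
        target_next = guided_max(qnext, map_prior(pc, r_step));
        next_defined = true;
      }
      // an undefined next-state value (all cells below the filter after
      // competitive drift) skips the update rather than bootstrapping at 0
    }
    if (m > 0 && next_defined) {
      int a = s.a[j];
      double delta = s.r[j] + pc.gamma * target_next - qv[a];
      for (size_t t = 0; t < active.size(); ++t) {
        p.Q[active[t] * N_ACT + a] += pc.alpha * delta;
        p.react[active[t]]++;
        p.last_react[active[t]] = round;
      }
    }
    if (j + 1 < n) v.swap(vnext);
  }
  return n;
}

struct Sched { int passes, niter, p_runs, forget_after; };

static Sched sched_from_list(const List& l) {
  Sched s;
  s.passes = as<int>(l["passes_per_sequence"]);  // 0 = auto (longest, cap 50)
  s.niter = as<int>(l["niter"]);
  s.p_runs = as<int>(l["p_runs"]);
  s.forget_after = as<int>(l["forget_after"]);   // 0 = no forgetting
  return s;
}

// consolidation round: refresh virtual paths, then replay high + virtual
static void consolidate_core(Pool& p, Vault& v, const Sched& sc,
                             const NetCfg& nc, const PolCfg& pc, double r_step,
                             int round) {
  refresh_virtual_core(v, r_step, sc.p_runs);
  int longest = 0;
  for (size_t i = 0; i < v.high.size(); ++i) longest = std::max(longest, v.high[i].len());
  for (size_t i = 0; i < v.virt.size(); ++i) longest = std::max(longest, v.virt[i].len());
  int passes = sc.passes > 0 ? sc.passes : std::min(longest, 50);
  int used = 0;
  // newest stored sequences first: replay favours the most recent
  // reward-associated memories when the niter budget binds
  for (int pass = 0; pass < passes && used < sc.niter; ++pass) {
    for (int i = (int)v.high.size() - 1; i >= 0 && used < sc.niter; --i)
      used += replay_seq_core(p, v.high[i], nc, pc, r_step, round);
    for (int i = (int)v.virt.size() - 1; i >= 0 && used < sc.niter; --i)
      used += replay_seq_core(p, v.virt[i], nc, pc, r_step, round);
  }
  // forgetting: action values a cell has accumulated are erased when replay
  // has not reactivated the cell for forget_after rounds; memories that are
  // not repeatedly stimulated fade, returning their territory to the
  // cold-start explorer
  if (sc.forget_after > 0) {
    for (int i = 0; i < p.n; ++i) {
      if (round - std::max(p.last_react[i], 0) > sc.forget_after) {
        bool any = false;
        for (int a = 0; a < N_ACT; ++a) if (p.Q[i * N_ACT + a] != 0.0) { any = true; break; }
        if (any) for (int a = 0; a < N_ACT; ++a) p.Q[i * N_ACT + a] = 0.0;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// replay-agent episode
struct EpCfg { double fail_threshold; int step_cap; };

struct EpStats { double ret; int steps; bool success; };

static EpStats episode_core(Pool& p, const Maze& z, const NetCfg& nc,
                            const PolCfg& pc, const EpCfg& ec, Seq& seq,
                            bool learn) {
  int x = z.sx, y = z.sy, heading = 8, last_action = -1;
  double cum = 0.0;
  int steps = 0;
  bool success = false;
  double S[SDIM], S2[SDIM], qv[N_ACT], qnext[N_ACT];
  std::vector<double> v, v2;
  std::vector<int> active;
  encode_core(z, x, y, heading, nc.position_only, S);
  int win = observe_core(p, S, 0.0, nc, v, learn);
  seq = Seq();
  seq.outcome = 0;
  for (;;) {
    active.clear();
    int m = filtered_q(p, v, pc.theta, qv, &active);
    int a = select_core(qv, m > 0, pc, last_action, z.r_step);
    StepOut o = step_core(z, x, y, a);
    cum += o.reward; ++steps;
    encode_core(z, o.nx, o.ny, o.executed, nc.position_only, S2);
    // record the executed triple
    seq.x.push_back(x); seq.y.push_back(y);
    seq.a.push_back(o.executed); seq.cell.push_back(win);
    seq.r.push_back(o.reward);
    for (int k = 0; k < SDIM; ++k) seq.svec.push_back(S[k]);
    // gated TD update against the next-state value.  "full" is the plain
    // on-line learner (used by the tabular-reduction analysis); "refresh"
    // only re-calibrates pairs the replay-written map has already valued,
    // so stale memories are corrected by live experience while unexplored
    // actions keep the zero value that drives cold-start exploration
    if (learn && pc.live_td != 0 && m > 0 &&
        (pc.live_td == 1 || qv[a] != 0.0)) {
      double target_next = 0.0;
      if (!o.goal) {
        activate_all(p, S2, 0.0, nc, v2);
        int m2 = filtered_q(p, v2, pc.theta, qnext, 0);
        if (m2 > 0) {
          if (pc.live_td == 1) target_next = max_q(qnext);
          else target_next = guided_max(qnext, map_prior(pc, z.r_step));
        }
      }
      double delta = o.reward + pc.gamma * target_next - qv[a];
      for (size_t t = 0; t < active.size(); ++t)
        p.Q[active[t] * N_ACT + a] += pc.alpha * delta;
    }
    if (o.goal) { success = true; break; }
    if (cum <= ec.fail_threshold || steps >= ec.step_cap) break;
    x = o.nx; y = o.ny; heading = o.executed;
    // a bump leaves no incumbent direction to continue; stay is not one
    last_action = (o.hit || o.executed == 8) ? -1 : o.executed;
    for (int k = 0; k < SDIM; ++k) S[k] = S2[k];
    win = observe_core(p, S, 0.0, nc, v, learn);
  }
  seq.outcome = success ? 1 : 0;
  seq.total = cum;
  EpStats st; st.ret = cum; st.steps = steps; st.success = success;
  return st;
}

// greedy evaluation episode (no learning, exploration frozen)
static bool eval_episode_core(Pool& p, const Maze& z, const NetCfg& nc,
                              const PolCfg& pc0, int step_cap) {
  // exploration frozen: epsilon off, but the agent's own guided policy
  // (including cold-start momentum off the valued web) stays in force
  PolCfg pc = pc0;
  pc.eps = 0.0;
  int x = z.sx, y = z.sy, heading = 8, last_action = -1;
  double S[SDIM], qv[N_ACT];
  std::vector<double> v;
  for (int t = 0; t < step_cap; ++t) {
    encode_core(z, x, y, heading, nc.position_only, S);
    activate_all(p, S, 0.0, nc, v);
    int m = filtered_q(p, v, pc.theta, qv, 0);
    int a = select_core(qv, m > 0, pc, last_action, z.r_step);
    StepOut o = step_core(z, x, y, a);
    if (o.goal) return true;
    x = o.nx; y = o.ny; heading = o.executed;
    last_action = (o.hit || o.executed == 8) ? -1 : o.executed;
  }
  return false;
}

// ---------------------------------------------------------------------------
// tabular baselines
struct Tab {
  std::vector<double> Q;      // (w*h) x N_ACT
  int w, h;
  double& q(int x, int y, int a) { return Q[(x + y * w) * N_ACT + a]; }
};

static EpStats tab_episode_core(Tab& T, const Maze& z, const PolCfg& pc,
                                const EpCfg& ec, double lambda,
                                std::vector<double>* buf_s, int buf_cap,
                                int batch, long* buf_n, long* buf_head,
                                bool learn, Seq* path) {
  int x = z.sx, y = z.sy, last_action = -1;
  double cum = 0.0;
  int steps = 0;
  bool success = false;
  // replacing eligibility traces, reset each episode, no exploratory cutting
  std::vector<double> E;
  std::vector<int> touched;
  bool use_traces = lambda > 0.0 && buf_s == 0;
  if (use_traces) E.assign(z.w * z.h * N_ACT, 0.0);
  for (;;) {
    double* qrow = &T.Q[(x + y * z.w) * N_ACT];
    int a = select_core(qrow, true, pc, last_action, z.r_step);
    StepOut o = step_core(z, x, y, a);
    cum += o.reward; ++steps;
    if (path) {
      path->x.push_back(x); path->y.push_back(y);
      path->a.push_back(o.executed); path->r.push_back(o.reward);
      path->cell.push_back(x + y * z.w);
    }
    if (learn) {
      double* qn = &T.Q[(o.nx + o.ny * z.w) * N_ACT];
      double target = o.reward + (o.goal ? 0.0 : pc.gamma * max_q(qn));
      double delta = target - qrow[a];
      if (buf_s) {
        // buffer learner: all value updates flow through uniform batch
        // replay of stored single transitions (no direct on-policy update)
        long pos = *buf_head;
        double* rec = &(*buf_s)[pos * 5];
        rec[0] = x + y * z.w; rec[1] = a; rec[2] = o.reward;
        rec[3] = o.nx + o.ny * z.w; rec[4] = o.goal ? 1.0 : 0.0;
        *buf_head = (pos + 1) % buf_cap;
        if (*buf_n < buf_cap) (*buf_n)++;
        for (int b = 0; b < batch; ++b) {
          long j = (long)std::floor(unif_rand() * (double)(*buf_n));
          if (j >= *buf_n) j = *buf_n - 1;
          double* rb = &(*buf_s)[j * 5];
          int s0 = (int)rb[0], a0 = (int)rb[1], s1 = (int)rb[3];
          double tgt = rb[2] + (rb[4] > 0.5 ? 0.0 : pc.gamma * max_q(&T.Q[s1 * N_ACT]));
          T.Q[s0 * N_ACT + a0] += pc.alpha * (tgt - T.Q[s0 * N_ACT + a0]);
        }
      } else if (use_traces) {
        int base = (x + y * z.w) * N_ACT;
        for (int k = 0; k < N_ACT; ++k) E[base + k] = 0.0;
        if (E[base + a] == 0.0) touched.push_back(base + a);
        E[base + a] = 1.0;
        double decay = pc.gamma * lambda;
        size_t keep = 0;
        for (size_t t = 0; t < touched.size(); ++t) {
          int idx = touched[t];
          if (E[idx] <= 1e-10) { E[idx] = 0.0; continue; }
          T.Q[idx] += pc.alpha * delta * E[idx];
          E[idx] *= decay;
          touched[keep++] = idx;
        }
        touched.resize(keep);
      } else {
        qrow[a] += pc.alpha * delta;
      }
    }
    if (o.goal) { success = true; break; }
    if (cum <= ec.fail_threshold || steps >= ec.step_cap) break;
    x = o.nx; y = o.ny;
    last_action = (o.hit || o.executed == 8) ? -1 : o.executed;
  }
  EpStats st; st.ret = cum; st.steps = steps; st.success = success;
  return st;
}

static bool tab_eval_core(Tab& T, const Maze& z, const PolCfg& pc0, int cap) {
  PolCfg pc = pc0; pc.eps = 0.0; pc.cold_start = false;
  int x = z.sx, y = z.sy, last_action = -1;
  for (int t = 0; t < cap; ++t) {
    int a = select_core(&T.Q[(x + y * z.w) * N_ACT], true, pc, last_action,
                        z.r_step);
    StepOut o = step_core(z, x, y, a);
    if (o.goal) return true;
    x = o.nx; y = o.ny;
    last_action = (o.hit || o.executed == 8) ? -1 : o.executed;
  }
  return false;
}

// ---------------------------------------------------------------------------
// exported fine-grained operations
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_step")]]
List cpp_step(List maze, int x, int y, int action) {
  Maze z = maze_from_list(maze);
  StepOut o = step_core(z, x, y, action);
  return List::create(_["next_state"] = IntegerVector::create(o.nx, o.ny),
                      _["reward"] = o.reward, _["hit_obstacle"] = o.hit,
                      _["reached_goal"] = o.goal, _["executed_action"] = o.executed);
}

// [[Rcpp::export(name = ".cpp_lidar")]]
IntegerVector cpp_lidar(List maze, int x, int y) {
  Maze z = maze_from_list(maze);
  IntegerVector out(N_MOVE);
  for (int a = 0; a < N_MOVE; ++a)
    out[a] = z.blocked(x + DX[a], y + DY[a]) ? 1 : 0;
  return out;
}

// [[Rcpp::export(name = ".cpp_encode")]]
NumericVector cpp_encode(List maze, int x, int y, int heading, bool position_only) {
  Maze z = maze_from_list(maze);
  NumericVector out(SDIM);
  double S[SDIM];
  encode_core(z, x, y, heading, position_only, S);
  for (int k = 0; k < SDIM; ++k) out[k] = S[k];
  return out;
}

// [[Rcpp::export(name = ".cpp_activate")]]
NumericVector cpp_activate(List pool, NumericVector S, double M, List net_cfg) {
  Pool p = pool_from_list(pool);
  NetCfg nc = netcfg_from_list(net_cfg);
  std::vector<double> v;
  activate_all(p, &S[0], M, nc, v);
  return NumericVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".cpp_observe")]]
List cpp_observe(List pool, NumericVector S, double M, List net_cfg, bool learn) {
  Pool p = pool_from_list(pool);
  NetCfg nc = netcfg_from_list(net_cfg);
  std::vector<double> v;
  int before = p.n;
  int win = observe_core(p, &S[0], M, nc, v, learn);
  return List::create(_["pool"] = pool_to_list(p),
                      _["rates"] = NumericVector(v.begin(), v.end()),
                      _["winner"] = win + 1,           // 1-based for R
                      _["recruited"] = p.n > before);
}

// [[Rcpp::export(name = ".cpp_select_action")]]
int cpp_select_action(NumericVector qv, bool any_active, List pol_cfg,
                      int last_action, double r_step) {
  PolCfg pc = polcfg_from_list(pol_cfg);
  double q[N_ACT];
  for (int a = 0; a < N_ACT; ++a) q[a] = qv[a];
  return select_core(q, any_active, pc, last_action, r_step);
}

// [[Rcpp::export(name = ".cpp_find_intersections")]]
List cpp_find_intersections(IntegerVector low_ids, IntegerVector high_ids) {
  std::vector<int> lo(low_ids.begin(), low_ids.end());
  std::vector<int> hi(high_ids.begin(), high_ids.end());
  std::vector<int> ids, li, hj;
  intersections_core(lo, hi, ids, li, hj);
  return List::create(_["cell_id"] = IntegerVector(ids.begin(), ids.end()),
                      _["low_index"] = IntegerVector(li.begin(), li.end()),
                      _["high_index"] = IntegerVector(hj.begin(), hj.end()));
}

// [[Rcpp::export(name = ".cpp_select_intersection")]]
int cpp_select_intersection(IntegerVector ids, IntegerVector li, IntegerVector hi) {
  std::vector<int> a(ids.begin(), ids.end()), b(li.begin(), li.end()),
    c(hi.begin(), hi.end());
  return select_intersection_core(a, b, c) + 1;   // 1-based
}

// [[Rcpp::export(name = ".cpp_construct_virtual")]]
List cpp_construct_virtual(List low, List high, int li, int hi, double r_step) {
  Seq l = seq_from_list(low), h = seq_from_list(high), out;
  if (!construct_virtual_core(l, h, li, hi, r_step, out))
    return List::create(_["ok"] = false);
  out.serial = 0;
  return List::create(_["ok"] = true, _["sequence"] = seq_to_list(out));
}

// [[Rcpp::export(name = ".cpp_refresh_virtual")]]
List cpp_refresh_virtual(List vault, double r_step, int pair_budget) {
  Vault v = vault_from_list(vault);
  int made = refresh_virtual_core(v, r_step, pair_budget);
  return List::create(_["vault"] = vault_to_list(v), _["constructed"] = made);
}

// [[Rcpp::export(name = ".cpp_replay_sequence")]]
List cpp_replay_sequence(List pool, List seq, List net_cfg, List pol_cfg,
                         double r_step) {
  Pool p = pool_from_list(pool);
  Seq s = seq_from_list(seq);
  NetCfg nc = netcfg_from_list(net_cfg);
  PolCfg pc = polcfg_from_list(pol_cfg);
  int n = replay_seq_core(p, s, nc, pc, r_step, 0);
  return List::create(_["pool"] = pool_to_list(p), _["steps"] = n);
}

// [[Rcpp::export(name = ".cpp_consolidate")]]
List cpp_consolidate(List pool, List vault, List sched, List net_cfg,
                     List pol_cfg, double r_step, int round) {
  Pool p = pool_from_list(pool);
  Vault v = vault_from_list(vault);
  Sched sc = sched_from_list(sched);
  NetCfg nc = netcfg_from_list(net_cfg);
  PolCfg pc = polcfg_from_list(pol_cfg);
  consolidate_core(p, v, sc, nc, pc, r_step, round);
  return List::create(_["pool"] = pool_to_list(p), _["vault"] = vault_to_list(v));
}

// [[Rcpp::export(name = ".cpp_run_episode")]]
List cpp_run_episode(List pool, List maze, List net_cfg, List pol_cfg,
                     double fail_threshold, int step_cap, bool learn) {
  Pool p = pool_from_list(pool);
  Maze z = maze_from_list(maze);
  NetCfg nc = netcfg_from_list(net_cfg);
  PolCfg pc = polcfg_from_list(pol_cfg);
  EpCfg ec; ec.fail_threshold = fail_threshold; ec.step_cap = step_cap;
  Seq s;
  EpStats st = episode_core(p, z, nc, pc, ec, s, learn);
  s.serial = 0;
  return List::create(_["pool"] = pool_to_list(p), _["sequence"] = seq_to_list(s),
                      _["return"] = st.ret, _["steps"] = st.steps,
                      _["success"] = st.success);
}

// forced-action rollout used to build bespoke trajectory fixtures
// [[Rcpp::export(name = ".cpp_trace_episode")]]
List cpp_trace_episode(List pool, List maze, List net_cfg, IntegerVector actions,
                       bool learn) {
  Pool p = pool_from_list(pool);
  Maze z = maze_from_list(maze);
  NetCfg nc = netcfg_from_list(net_cfg);
  int x = z.sx, y = z.sy, heading = 8;
  double S[SDIM];
  std::vector<double> v;
  Seq seq; seq.outcome = 0; seq.serial = 0;
  double cum = 0.0;
  bool success = false;
  for (int t = 0; t < actions.size(); ++t) {
    encode_core(z, x, y, heading, nc.position_only, S);
    int win = observe_core(p, S, 0.0, nc, v, learn);
    StepOut o = step_core(z, x, y, actions[t]);
    cum += o.reward;
    seq.x.push_back(x); seq.y.push_back(y);
    seq.a.push_back(o.executed); seq.cell.push_back(win);
    seq.r.push_back(o.reward);
    for (int k = 0; k < SDIM; ++k) seq.svec.push_back(S[k]);
    if (o.goal) { success = true; break; }
    x = o.nx; y = o.ny; heading = o.executed;
  }
  seq.outcome = success ? 1 : 0;
  seq.total = cum;
  return List::create(_["pool"] = pool_to_list(p), _["sequence"] = seq_to_list(seq),
                      _["success"] = success);
}

// ---------------------------------------------------------------------------
// full training runs
// ---------------------------------------------------------------------------

// replay-agent experiment; optional greedy evaluation checkpoints
// [[Rcpp::export(name = ".cpp_run_replay_experiment")]]
List cpp_run_replay_experiment(List maze, List net_cfg, List pol_cfg, List sched,
                               List vault, List pool0, int episodes,
                               double fail_threshold, int step_cap,
                               bool consolidate, int eval_every,
                               int eval_episodes, bool keep_paths) {
  Maze z = maze_from_list(maze);
  NetCfg nc = netcfg_from_list(net_cfg);
  PolCfg pc = polcfg_from_list(pol_cfg);
  Sched sc = sched_from_list(sched);
  Vault v = vault_from_list(vault);
  EpCfg ec; ec.fail_threshold = fail_threshold; ec.step_cap = step_cap;
  Pool p = pool_from_list(pool0);
  NumericVector ret(episodes);
  IntegerVector steps(episodes);
  LogicalVector succ(episodes);
  std::vector<double> eval_frac;
  std::vector<int> eval_ep;
  List paths(keep_paths ? episodes : 0);
  for (int ep = 0; ep < episodes; ++ep) {
    Seq s;
    EpStats st = episode_core(p, z, nc, pc, ec, s, true);
    ret[ep] = st.ret; steps[ep] = st.steps; succ[ep] = st.success;
    if (keep_paths) paths[ep] = seq_to_list(s);
    if (st.success) v.push(v.high, v.cap_high, std::move(s));
    else v.push(v.low, v.cap_low, std::move(s));
    if (consolidate) consolidate_core(p, v, sc, nc, pc, z.r_step, ep);
    if (eval_every > 0 && (ep + 1) % eval_every == 0) {
      int ok = 0;
      for (int e = 0; e < eval_episodes; ++e)
        if (eval_episode_core(p, z, nc, pc, step_cap)) ++ok;
      eval_frac.push_back((double)ok / eval_episodes);
      eval_ep.push_back(ep + 1);
    }
  }
  List out = List::create(
    _["returns"] = ret, _["steps"] = steps, _["success"] = succ,
    _["pool"] = pool_to_list(p), _["vault"] = vault_to_list(v),
    _["eval_episode"] = IntegerVector(eval_ep.begin(), eval_ep.end()),
    _["eval_success"] = NumericVector(eval_frac.begin(), eval_frac.end()));
  if (keep_paths) out["paths"] = paths;
  return out;
}

// tabular baseline experiment (plain Q(lambda) or uniform random-ER)
// [[Rcpp::export(name = ".cpp_run_tabular_experiment")]]
List cpp_run_tabular_experiment(List maze, List pol_cfg, int episodes,
                                double fail_threshold, int step_cap,
                                double lambda, bool use_buffer, int buf_cap,
                                int batch, int eval_every, int eval_episodes,
                                bool keep_paths) {
  Maze z = maze_from_list(maze);
  PolCfg pc = polcfg_from_list(pol_cfg);
  EpCfg ec; ec.fail_threshold = fail_threshold; ec.step_cap = step_cap;
  Tab T; T.w = z.w; T.h = z.h; T.Q.assign(z.w * z.h * N_ACT, 0.0);
  std::vector<double> buf;
  long buf_n = 0, buf_head = 0;
  if (use_buffer) buf.assign((size_t)buf_cap * 5, 0.0);
  NumericVector ret(episodes);
  IntegerVector steps(episodes);
  LogicalVector succ(episodes);
  std::vector<double> eval_frac;
  std::vector<int> eval_ep;
  List paths(keep_paths ? episodes : 0);
  for (int ep = 0; ep < episodes; ++ep) {
    Seq path;
    EpStats st = tab_episode_core(T, z, pc, ec, lambda,
                                  use_buffer ? &buf : 0, buf_cap, batch,
                                  &buf_n, &buf_head, true,
                                  keep_paths ? &path : 0);
    ret[ep] = st.ret; steps[ep] = st.steps; succ[ep] = st.success;
    if (keep_paths) { path.outcome = st.success ? 1 : 0; path.total = st.ret;
      path.serial = 0; path.svec.assign(path.len() * SDIM, 0.0);
      paths[ep] = seq_to_list(path); }
    if (eval_every > 0 && (ep + 1) % eval_every == 0) {
      int ok = 0;
      for (int e = 0; e < eval_episodes; ++e)
        if (tab_eval_core(T, z, pc, step_cap)) ++ok;
      eval_frac.push_back((double)ok / eval_episodes);
      eval_ep.push_back(ep + 1);
    }
  }
  NumericMatrix Q(z.w * z.h, N_ACT);
  for (int s = 0; s < z.w * z.h; ++s)
    for (int a = 0; a < N_ACT; ++a) Q(s, a) = T.Q[s * N_ACT + a];
  List out = List::create(
    _["returns"] = ret, _["steps"] = steps, _["success"] = succ,
    _["Q"] = Q,
    _["eval_episode"] = IntegerVector(eval_ep.begin(), eval_ep.end()),
    _["eval_success"] = NumericVector(eval_frac.begin(), eval_frac.end()));
  if (keep_paths) out["paths"] = paths;
  return out;
}

// signal-strength and reactivation maps from a trained pool
// [[Rcpp::export(name = ".cpp_signal_maps")]]
List cpp_signal_maps(List pool, List maze, List net_cfg, List pol_cfg) {
  Pool p = pool_from_list(pool);
  Maze z = maze_from_list(maze);
  NetCfg nc = netcfg_from_list(net_cfg);
  PolCfg pc = polcfg_from_list(pol_cfg);
  NumericMatrix strength(z.w, z.h);
  IntegerMatrix react(z.w, z.h);
  double S[SDIM], qv[N_ACT];
  std::vector<double> v;
  double smax = 0.0;
  for (int x = 0; x < z.w; ++x)
    for (int y = 0; y < z.h; ++y) {
      if (z.blocked(x, y)) { strength(x, y) = NA_REAL; react(x, y) = NA_INTEGER; continue; }
      encode_core(z, x, y, 8, nc.position_only, S);
      activate_all(p, S, 0.0, nc, v);
      int m = filtered_q(p, v, pc.theta, qv, 0);
      double s = m > 0 ? max_q(qv) : 0.0;
      if (s < 0.0) s = 0.0;
      strength(x, y) = s;
      if (s > smax) smax = s;
    }
  if (smax > 0)
    for (int x = 0; x < z.w; ++x)
      for (int y = 0; y < z.h; ++y)
        if (!ISNAN(strength(x, y))) strength(x, y) /= smax;
  for (int i = 0; i < p.n; ++i) {
    int gx = (int)std::lround(p.WS[i * SDIM]);
    int gy = (int)std::lround(p.WS[i * SDIM + 1]);
    if (gx < 0) gx = 0; if (gx >= z.w) gx = z.w - 1;
    if (gy < 0) gy = 0; if (gy >= z.h) gy = z.h - 1;
    if (react(gx, gy) == NA_INTEGER) react(gx, gy) = 0;
    react(gx, gy) += p.react[i];
  }
  return List::create(_["strength"] = strength, _["reactivations"] = react);
}

// breadth-first-search distance over free cells (8-connectivity); -1 unreachable
// [[Rcpp::export(name = ".cpp_bfs_distance")]]
int cpp_bfs_distance(List maze, IntegerVector from, IntegerVector to) {
  Maze z = maze_from_list(maze);
  std::vector<int> dist(z.w * z.h, -1);
  std::vector<int> queue;
  int s = from[0] + from[1] * z.w, g = to[0] + to[1] * z.w;
  if (z.blocked(from[0], from[1]) || z.blocked(to[0], to[1])) return -1;
  dist[s] = 0;
  queue.push_back(s);
  for (size_t head = 0; head < queue.size(); ++head) {
    int cur = queue[head];
    if (cur == g) return dist[cur];
    int x = cur % z.w, y = cur / z.w;
    for (int a = 0; a < N_MOVE; ++a) {
      int nx = x + DX[a], ny = y + DY[a];
      if (z.blocked(nx, ny)) continue;
      int idx = nx + ny * z.w;
      if (dist[idx] < 0) { dist[idx] = dist[cur] + 1; queue.push_back(idx); }
    }
  }
  return -1;
}
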