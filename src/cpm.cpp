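// Cellular Potts engine: lattice bookkeeping, Metropolis kernel, MCS loop,
// and the pluggable energy terms (adhesion/area, basic persistence, Act,
// pseudopod FSM with actin coupling, tip adhesion, pulling, touch behaviors).
//
// Conventions: sites are (x, y) with 0 <= x < W, 0 <= y < H, flattened as
// idx = x + y * W; owner 0 is medium; the lattice is periodic; centroids are
// maintained as unwrapped running sums so exported tracks are continuous
// across the periodic boundary.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int NBX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int NBY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

static const double INF = std::numeric_limits<double>::infinity();

inline int wrapi(int a, int n) {
  int r = a % n;
  return r < 0 ? r + n : r;
}

// minimal-image signed difference a - b on a ring of size n
inline double ring_diff(double a, double b, int n) {
  double d = a - b;
  if (d > n / 2.0) d -= n;
  if (d < -n / 2.0) d += n;
  return d;
}

// ---------------------------------------------------------------------------
// von Mises sampling (Best & Fisher 1979 rejection scheme); kappa = 0 is the
// uniform circular distribution. Uses R's RNG so set.seed() governs draws.
double rvm1(double mu, double kappa) {
  if (kappa < 1e-10) return R::runif(-M_PI, M_PI);
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double z = std::cos(M_PI * R::unif_rand());
    double f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u2 = R::unif_rand();
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double th = (R::unif_rand() > 0.5 ? 1.0 : -1.0) * std::acos(f) + mu;
      return std::atan2(std::sin(th), std::cos(th));
    }
  }
}

// [[Rcpp::export]]
NumericVector rvonmises_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm1(mu, kappa);
  return out;
}

// ---------------------------------------------------------------------------
// Local connectivity test: would removing `site` from its owner leave the
// owner's sites within the Moore neighborhood in a single Moore-connected
// component? (Standard local approximation of the global constraint.)
// Zero remaining neighbors => true (the cell simply vanishes).
static bool local_connectivity(const int *owner, int W, int H, int x, int y) {
  int own = owner[wrapi(x, W) + wrapi(y, H) * W];
  bool mask[8];
  int cnt = 0;
  for (int k = 0; k < 8; ++k) {
    int idx = wrapi(x + NBX[k], W) + wrapi(y + NBY[k], H) * W;
    mask[k] = owner[idx] == own;
    if (mask[k]) ++cnt;
  }
  if (cnt <= 1) return true;
  // flood fill over the 8 neighbor slots; slots are adjacent when their
  // lattice offsets are Moore-adjacent (the removed center does not connect)
  int stack[8], top = 0, seen = 0;
  bool vis[8] = {false};
  for (int k = 0; k < 8; ++k)
    if (mask[k]) { stack[top++] = k; vis[k] = true; ++seen; break; }
  while (top > 0) {
    int k = stack[--top];
    for (int j = 0; j < 8; ++j) {
      if (!mask[j] || vis[j]) continue;
      if (std::abs(NBX[k] - NBX[j]) <= 1 && std::abs(NBY[k] - NBY[j]) <= 1) {
        vis[j] = true;
        stack[top++] = j;
        ++seen;
      }
    }
  }
  return seen == cnt;
}

// [[Rcpp::export]]
bool local_connectivity_cpp(IntegerMatrix owner, int x, int y) {
  // owner is [W x H] with owner(x, y); x, y are 0-based
  int W = owner.nrow(), H = owner.ncol();
  std::vector<int> buf(W * H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < W; ++i) buf[i + j * W] = owner(i, j);
  return local_connectivity(buf.data(), W, H, x, y);
}

// ---------------------------------------------------------------------------
// Base Hamiltonian difference for one copy attempt: site v adopts the owner
// of source site vn. Adhesion pairs are counted once, so only pairs involving
// v change; the area term is the usual elastic difference.
static double dh_adhesion_area(const int *owner, int W, int H,
                               const int *ctype, const NumericMatrix &J,
                               const double *lamv, const double *targ,
                               const int *area, int x, int y, int o_new) {
  int v = wrapi(x, W) + wrapi(y, H) * W;
  int o_old = owner[v];
  int t_old = o_old > 0 ? ctype[o_old] : 0;
  int t_new = o_new > 0 ? ctype[o_new] : 0;
  double dh = 0.0;
  for (int k = 0; k < 8; ++k) {
    int u = wrapi(x + NBX[k], W) + wrapi(y + NBY[k], H) * W;
    int ou = owner[u];
    int tu = ou > 0 ? ctype[ou] : 0;
    if (ou != o_new) dh += J(t_new, tu);
    if (ou != o_old) dh -= J(t_old, tu);
  }
  if (o_old > 0) {
    double d = area[o_old] - targ[o_old];
    dh += lamv[o_old] * ((d - 1.0) * (d - 1.0) - d * d);
  }
  if (o_new > 0) {
    double d = area[o_new] - targ[o_new];
    dh += lamv[o_new] * ((d + 1.0) * (d + 1.0) - d * d);
  }
  return dh;
}

// [[Rcpp::export]]
double delta_h_base_cpp(IntegerMatrix owner, IntegerVector cell_type,
                        NumericMatrix J, NumericVector lambda_v,
                        NumericVector target_area, int x, int y,
                        int xn, int yn) {
  int W = owner.nrow(), H = owner.ncol();
  int nc = cell_type.size();
  std::vector<int> buf(W * H), area(nc + 1, 0), ct(nc + 1, 0);
  std::vector<double> lv(nc + 1, 0.0), ta(nc + 1, 0.0);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < W; ++i) {
      int o = owner(i, j);
      buf[i + j * W] = o;
      if (o > 0) {
        if (o > nc) stop("unknown cell id on lattice");
        ++area[o];
      }
    }
  for (int c = 1; c <= nc; ++c) {
    ct[c] = cell_type[c - 1];
    lv[c] = lambda_v[c - 1];
    ta[c] = target_area[c - 1];
  }
  int o_new = buf[wrapi(xn, W) + wrapi(yn, H) * W];
  int o_old = buf[wrapi(x, W) + wrapi(y, H) * W];
  if (o_new == o_old) stop("copy attempt requires differing owners");
  return dh_adhesion_area(buf.data(), W, H, ct.data(), J, lv.data(),
                          ta.data(), area.data(), x, y, o_new);
}

// ---------------------------------------------------------------------------
// Act geometric mean over the Moore neighborhood including the central site,
// restricted to sites sharing the central site's owner; medium contexts are 0.
static double act_gm(const int *owner, const double *act, int W, int H,
                     int x, int y) {
  int v = wrapi(x, W) + wrapi(y, H) * W;
  int own = owner[v];
  if (own == 0) return 0.0;
  double prod = act[v];
  int n = 1;
  if (prod == 0.0) return 0.0;
  for (int k = 0; k < 8; ++k) {
    int u = wrapi(x + NBX[k], W) + wrapi(y + NBY[k], H) * W;
    if (owner[u] != own) continue;
    if (act[u] == 0.0) return 0.0;
    prod *= act[u];
    ++n;
  }
  return std::pow(prod, 1.0 / n);
}

// [[Rcpp::export]]
double act_gm_cpp(IntegerMatrix owner, NumericMatrix activity, int x, int y) {
  int W = owner.nrow(), H = owner.ncol();
  std::vector<int> buf(W * H);
  std::vector<double> act(W * H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < W; ++i) {
      buf[i + j * W] = owner(i, j);
      act[i + j * W] = activity(i, j);
    }
  return act_gm(buf.data(), act.data(), W, H, x, y);
}

// ---------------------------------------------------------------------------
// Engine

struct Pod {
  int state;                 // 0 INIT 1 GROWING 2 RETRACTING 3 INACTIVE 4 TOUCHING
  std::deque<int> chain;     // site indices, origin first, tip last
  double gdir;               // continuous growth direction (radians)
  int timer;                 // MCS since INIT -> GROWING
  int stall;                 // MCS since last successful extension
};

class Engine {
public:
  // lattice
  int W, H, nsites;
  std::vector<int> owner;
  // cells (1-based ids)
  int ncell;
  std::vector<int> area, ctype;
  std::vector<double> lamv, targ;
  std::vector<double> sumx, sumy;            // unwrapped running sums
  std::vector<double> pcx, pcy;              // centroid at previous MCS
  std::vector<double> tdx, tdy;              // persistence target direction
  std::vector<double> mdx, mdy;              // smoothed movement direction
  std::vector<char> alive;
  NumericMatrix J;
  double T;
  bool connectivity;
  // models
  bool use_pers, use_act, use_pods, use_tip, use_pull;
  double lambda_p, pers_dt;
  double lambda_act, max_act;
  std::vector<double> act_stamp;             // MCS of last protrusive activity
  int mcs;                                   // current MCS (1-based during run)
  // pseudopods
  int n_pods, max_growth, stall_limit, time_between, retraction_mode;
  double p_ext, p_retr, kap_init, kap_cont, actin_bonus, mov_dt;
  double tip_bonus, r_max, pull_F, p_touch_retr, cos_thresh;
  int touch_behavior;                        // 0 nothing 1 retract 2 attach 3 poof-dir
  std::vector<std::vector<Pod> > pods;
  std::vector<int> actin_cnt;                // per-site actin multiplicity
  // diagnostics
  long n_growing_mcs, n_ext_attempts, n_ext_success, n_touch, n_inactive_mcs,
       n_init_events;

  Engine(List p) : J(as<NumericMatrix>(p["J"])) {
    W = p["width"]; H = p["height"]; nsites = W * H;
    ncell = p["n_cells"];
    T = p["temperature"];
    connectivity = p["connectivity"];
    use_pers = p["use_persistence"]; use_act = p["use_act"];
    use_pods = p["use_pseudopods"]; use_tip = p["use_tip_adhesion"];
    use_pull = p["use_pulling"];
    lambda_p = p["lambda_p"]; pers_dt = p["persistence_decay_time"];
    lambda_act = p["lambda_act"]; max_act = p["max_act"];
    n_pods = p["n_pseudopods"]; p_ext = p["p_ext"]; p_retr = p["p_retr"];
    kap_init = p["kappa_init"]; kap_cont = p["kappa_cont"];
    max_growth = p["max_growth_time"]; stall_limit = p["stall_limit"];
    time_between = p["time_between_extensions"];
    retraction_mode = p["retraction_mode"];
    actin_bonus = p["neighboring_actin_bonus"];
    mov_dt = p["movement_decay_time"];
    tip_bonus = p["tip_bonus"]; r_max = p["r_max"]; pull_F = p["pull_strength"];
    touch_behavior = p["touch_behavior"]; p_touch_retr = p["p_touch_retr"];
    cos_thresh = p["lateral_threshold"];

    owner.assign(nsites, 0);
    area.assign(ncell + 1, 0);
    ctype.assign(ncell + 1, 0);
    lamv.assign(ncell + 1, 0.0);
    targ.assign(ncell + 1, 0.0);
    sumx.assign(ncell + 1, 0.0); sumy.assign(ncell + 1, 0.0);
    pcx.assign(ncell + 1, 0.0); pcy.assign(ncell + 1, 0.0);
    tdx.assign(ncell + 1, 0.0); tdy.assign(ncell + 1, 0.0);
    mdx.assign(ncell + 1, 0.0); mdy.assign(ncell + 1, 0.0);
    alive.assign(ncell + 1, 1);
    NumericVector lv = p["lambda_v"], ta = p["target_area"];
    IntegerVector ty = p["cell_type"];
    for (int c = 1; c <= ncell; ++c) {
      lamv[c] = lv[c - 1]; targ[c] = ta[c - 1]; ctype[c] = ty[c - 1];
    }
    act_stamp.assign(nsites, -1e18);
    actin_cnt.assign(nsites, 0);
    pods.assign(ncell + 1, std::vector<Pod>());
    if (use_pods)
      for (int c = 1; c <= ncell; ++c) {
        pods[c].assign(n_pods, Pod());
        for (int q = 0; q < n_pods; ++q) {
          pods[c][q].state = 0; pods[c][q].gdir = 0.0;
          pods[c][q].timer = 0; pods[c][q].stall = 0;
        }
      }
    mcs = 0;
    n_growing_mcs = n_ext_attempts = n_ext_success = n_touch =
      n_inactive_mcs = n_init_events = 0;
  }

  inline int sidx(int x, int y) const { return wrapi(x, W) + wrapi(y, H) * W; }

  double activity(int idx) const {
    if (owner[idx] == 0) return 0.0;
    double a = max_act - (mcs - act_stamp[idx]);
    return a > 0.0 ? a : 0.0;
  }

  double gm_at(int x, int y) const {
    int v = sidx(x, y);
    int own = owner[v];
    if (own == 0) return 0.0;
    double prod = activity(v);
    if (prod == 0.0) return 0.0;
    int n = 1;
    for (int k = 0; k < 8; ++k) {
      int u = sidx(x + NBX[k], y + NBY[k]);
      if (owner[u] != own) continue;
      double a = activity(u);
      if (a == 0.0) return 0.0;
      prod *= a;
      ++n;
    }
    return std::pow(prod, 1.0 / n);
  }

  // place cells as distinct random single pixels
  void init_random_cells() {
    if (ncell > nsites) stop("cell count exceeds lattice capacity");
    for (int c = 1; c <= ncell; ++c) {
      for (;;) {
        int x = (int)std::floor(R::unif_rand() * W);
        int y = (int)std::floor(R::unif_rand() * H);
        int idx = sidx(x, y);
        if (owner[idx] == 0) {
          owner[idx] = c;
          area[c] = 1;
          sumx[c] = x; sumy[c] = y;
          pcx[c] = x; pcy[c] = y;
          break;
        }
      }
    }
  }

  void set_owner_matrix(IntegerMatrix m) {
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < W; ++i) {
        int o = m(i, j);
        owner[i + j * W] = o;
        if (o > 0) {
          ++area[o];
          // accumulate near first-seen image; cells are assumed compact
          if (area[o] == 1) { sumx[o] = i; sumy[o] = j; }
          else {
            double cx = sumx[o] / (area[o] - 1), cy = sumy[o] / (area[o] - 1);
            sumx[o] += i + W * std::floor((cx - i) / W + 0.5);
            sumy[o] += j + H * std::floor((cy - j) / H + 0.5);
          }
        }
      }
    for (int c = 1; c <= ncell; ++c) {
      if (area[c] == 0) alive[c] = 0;
      pcx[c] = area[c] ? sumx[c] / area[c] : 0.0;
      pcy[c] = area[c] ? sumy[c] / area[c] : 0.0;
    }
  }

  // centroid helpers (unwrapped)
  inline double cx(int c) const { return sumx[c] / area[c]; }
  inline double cy(int c) const { return sumy[c] / area[c]; }

  void add_site(int c, int x, int y) {
    double xe = x, ye = y;
    if (area[c] > 0) {
      xe = x + W * std::floor((cx(c) - x) / W + 0.5);
      ye = y + H * std::floor((cy(c) - y) / H + 0.5);
    }
    sumx[c] += xe; sumy[c] += ye;
    ++area[c];
  }

  void remove_site(int c, int x, int y) {
    double xe = x + W * std::floor((cx(c) - x) / W + 0.5);
    double ye = y + H * std::floor((cy(c) - y) / H + 0.5);
    sumx[c] -= xe; sumy[c] -= ye;
    --area[c];
    if (area[c] == 0) alive[c] = 0;  // retired; pseudopods are already empty
  }

  // --- energy terms ------------------------------------------------------
  double dh_persistence(int o_old, int o_new, double sx, double sy) {
    double dh = 0.0;
    if (o_old > 0) dh += -lambda_p * area[o_old] * (sx * tdx[o_old] + sy * tdy[o_old]);
    if (o_new > 0) dh += -lambda_p * area[o_new] * (sx * tdx[o_new] + sy * tdy[o_new]);
    return dh;
  }

  double dh_act(int x, int y, int xn, int yn) {
    // favorable when the extending (source) side has the more active context
    double gm_src = gm_at(xn, yn);
    double gm_tgt = gm_at(x, y);
    return -(lambda_act / max_act) * (gm_src - gm_tgt);
  }

  // actin coupling: growth next to the growing cell's actin is promoted;
  // shrinking next to the losing cell's actin is blocked
  double dh_actin(int x, int y, int o_old, int o_new) {
    bool near_new = false, near_old = false;
    int v = sidx(x, y);
    if (actin_cnt[v] > 0) {
      if (owner[v] == o_old && o_old > 0) near_old = true;
      if (owner[v] == o_new && o_new > 0) near_new = true;
    }
    for (int k = 0; k < 8; ++k) {
      int u = sidx(x + NBX[k], y + NBY[k]);
      if (actin_cnt[u] == 0) continue;
      if (o_new > 0 && owner[u] == o_new) near_new = true;
      if (o_old > 0 && owner[u] == o_old) near_old = true;
    }
    if (near_old) return INF;  // prevents loss of sites holding/adjacent to actin
    return near_new ? -actin_bonus : 0.0;
  }

  double pod_vec_x(int c) {
    double fx = 0.0;
    for (size_t q = 0; q < pods[c].size(); ++q) {
      const Pod &p = pods[c][q];
      if (p.chain.size() < 1) continue;
      int o = p.chain.front(), t = p.chain.back();
      fx += ring_diff(t % W, o % W, W);
    }
    return fx;
  }
  double pod_vec_y(int c) {
    double fy = 0.0;
    for (size_t q = 0; q < pods[c].size(); ++q) {
      const Pod &p = pods[c][q];
      if (p.chain.size() < 1) continue;
      int o = p.chain.front(), t = p.chain.back();
      fy += ring_diff(t / W, o / W, H);
    }
    return fy;
  }

  double dh_pulling(int o_old, int o_new, double sx, double sy) {
    double dh = 0.0;
    if (o_old > 0)
      dh += -pull_F * (sx * pod_vec_x(o_old) + sy * pod_vec_y(o_old)) / area[o_old];
    if (o_new > 0)
      dh += -pull_F * (sx * pod_vec_x(o_new) + sy * pod_vec_y(o_new)) / area[o_new];
    return dh;
  }

  double tip_dist(int c, int x, int y) {
    double best = INF;
    for (size_t q = 0; q < pods[c].size(); ++q) {
      const Pod &p = pods[c][q];
      if (p.chain.empty()) continue;
      int t = p.chain.back();
      double dx = ring_diff(t % W, x, W), dy = ring_diff(t / W, y, H);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) best = d;
    }
    return best;
  }

  // tip-adhesion case table for one involved cell; the shrinking cell's
  // contribution carries the opposite sign (growth displacing a cell nets 0)
  double dh_tip(int x, int y, int o_old, int o_new) {
    double dh = 0.0;
    int cand[9];
    int ncand = 0;
    cand[ncand++] = owner[sidx(x, y)];
    for (int k = 0; k < 8; ++k) cand[ncand++] = owner[sidx(x + NBX[k], y + NBY[k])];
    int invol[2] = {o_new, o_old};
    double sign[2] = {1.0, -1.0};
    for (int s = 0; s < 2; ++s) {
      int c = invol[s];
      if (c <= 0) continue;
      // nearest (by tip distance) foreign cell adjacent to the flipping site
      int best_o = 0;
      double best_d = INF;
      for (int k = 0; k < ncand; ++k) {
        int oc = cand[k];
        if (oc == 0 || oc == c) continue;
        double d = tip_dist(oc, x, y);
        if (d < best_d) { best_d = d; best_o = oc; }
      }
      if (best_o == 0) continue;
      double rs = tip_dist(c, x, y);
      double ro = best_d;
      double b = 0.0;
      bool in_s = rs <= r_max, in_o = ro <= r_max;
      if (in_s && in_o) b = -2.0 * tip_bonus;
      else if (in_s || in_o) b = -tip_bonus;
      dh += sign[s] * b;
    }
    return dh;
  }

  // --- one elementary copy attempt ---------------------------------------
  void attempt() {
    int x = (int)std::floor(R::unif_rand() * W);
    int y = (int)std::floor(R::unif_rand() * H);
    int k = (int)std::floor(R::unif_rand() * 8);
    int xn = x + NBX[k], yn = y + NBY[k];
    int v = sidx(x, y), vn = sidx(xn, yn);
    int o_old = owner[v], o_new = owner[vn];
    if (o_old == o_new) return;
    if (connectivity && o_old > 0 &&
        !local_connectivity(owner.data(), W, H, x, y))
      return;
    double nrm = std::sqrt((double)(NBX[k] * NBX[k] + NBY[k] * NBY[k]));
    double sx = -NBX[k] / nrm, sy = -NBY[k] / nrm;  // from source toward target
    double dh = dh_adhesion_area(owner.data(), W, H, ctype.data(), J,
                                 lamv.data(), targ.data(), area.data(),
                                 x, y, o_new);
    if (use_pods) {
      double da = dh_actin(x, y, o_old, o_new);
      if (da == INF) return;
      dh += da;
    }
    if (use_pers) dh += dh_persistence(o_old, o_new, sx, sy);
    if (use_act) dh += dh_act(x, y, xn, yn);
    if (use_pull) dh += dh_pulling(o_old, o_new, sx, sy);
    if (use_tip) dh += dh_tip(x, y, o_old, o_new);
    if (dh > 0.0 && R::unif_rand() >= std::exp(-dh / T)) return;
    // accept
    if (o_old > 0) remove_site(o_old, x, y);
    if (o_new > 0) add_site(o_new, x, y);
    owner[v] = o_new;
    if (use_act) act_stamp[v] = o_new > 0 ? mcs : -1e18;
  }

  // --- pseudopod FSM ------------------------------------------------------
  void clear_chain(Pod &p) {
    for (size_t i = 0; i < p.chain.size(); ++i) --actin_cnt[p.chain[i]];
    p.chain.clear();
  }

  void touch_event(int c, Pod &p) {
    ++n_touch;
    switch (touch_behavior) {
      case 0: break;                       // nothing
      case 1: p.state = 2; break;          // retract
      case 2: p.state = 4; break;          // attach -> TOUCHING
      case 3: {                            // poof-dir (CIL)
        int o = p.chain.front(), t = p.chain.back();
        double px = ring_diff(t % W, o % W, W), py = ring_diff(t / W, o / W, H);
        double pn = std::sqrt(px * px + py * py);
        double mn = std::sqrt(mdx[c] * mdx[c] + mdy[c] * mdy[c]);
        if (pn < 1e-12 || mn < 1e-12) break;  // alignment undefined
        double ca = (px * mdx[c] + py * mdy[c]) / (pn * mn);
        if (ca < cos_thresh) {
          clear_chain(p);
          p.state = 0;                     // instant retraction, re-init
        }
        break;
      }
      default: stop("unknown touch behavior");
    }
  }

  void pod_step(int c, Pod &p) {
    switch (p.state) {
      case 0: {  // INIT: seed actin at rounded centroid if owned by the cell
        int x = wrapi((int)std::floor(cx(c) + 0.5), W);
        int y = wrapi((int)std::floor(cy(c) + 0.5), H);
        int idx = x + y * W;
        if (owner[idx] != c) break;  // retry next MCS
        p.chain.push_back(idx);
        ++actin_cnt[idx];
        double mn = std::sqrt(mdx[c] * mdx[c] + mdy[c] * mdy[c]);
        double mu = mn < 1e-12 ? 0.0 : std::atan2(mdy[c], mdx[c]);
        p.gdir = rvm1(mu, mn < 1e-12 ? 0.0 : kap_init);
        p.timer = 0;
        p.stall = 0;
        p.state = 1;
        ++n_init_events;
        break;
      }
      case 1: {  // GROWING
        ++n_growing_mcs;
        ++p.timer;
        bool extended = false;
        if (R::unif_rand() < p_ext) {
          ++n_ext_attempts;
          double th = rvm1(p.gdir, kap_cont);
          // discretize to the nearest Moore step
          int oct = (int)std::floor(th / (M_PI / 4.0) + 0.5);
          oct = ((oct % 8) + 8) % 8;
          static const int OX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
          static const int OY[8] = {0, 1, 1, 1, 0, -1, -1, -1};
          int tx = p.chain.back() % W, ty = p.chain.back() / W;
          int nx = wrapi(tx + OX[oct], W), ny = wrapi(ty + OY[oct], H);
          int idx = nx + ny * W;
          int oo = owner[idx];
          if (oo == c) {
            p.chain.push_back(idx);
            ++actin_cnt[idx];
            p.gdir = std::atan2((double)OY[oct], (double)OX[oct]);
            p.stall = 0;
            extended = true;
            ++n_ext_success;
          } else if (oo > 0) {
            touch_event(c, p);   // growth into a neighboring cell
            if (p.state != 1) break;
          }
          // growth into medium: plain failure (site not part of the cell)
        }
        if (!extended) ++p.stall;
        if (p.timer > max_growth || p.stall >= stall_limit) p.state = 2;
        break;
      }
      case 2: {  // RETRACTING
        if (!p.chain.empty() && R::unif_rand() < p_retr) {
          int idx;
          if (retraction_mode == 0) { idx = p.chain.back(); p.chain.pop_back(); }
          else { idx = p.chain.front(); p.chain.pop_front(); }
          --actin_cnt[idx];
        }
        if (p.chain.empty()) p.state = 3;
        break;
      }
      case 3: {  // INACTIVE
        ++n_inactive_mcs;
        if (R::unif_rand() < 1.0 / time_between) p.state = 0;
        break;
      }
      case 4: {  // TOUCHING (attach behavior)
        if (R::unif_rand() < p_touch_retr) p.state = 2;
        break;
      }
    }
  }

  void end_of_mcs() {
    for (int c = 1; c <= ncell; ++c) {
      if (!alive[c]) continue;
      double ncx = cx(c), ncy = cy(c);
      double dx = ncx - pcx[c], dy = ncy - pcy[c];
      double nrm = std::sqrt(dx * dx + dy * dy);
      if (nrm > 1e-12) {
        if (use_pers) {
          double dr = std::min(1.0 / pers_dt, 1.0);
          tdx[c] = (1.0 - dr) * tdx[c] + dr * dx / nrm;
          tdy[c] = (1.0 - dr) * tdy[c] + dr * dy / nrm;
        }
        double drm = std::min(1.0 / mov_dt, 1.0);
        mdx[c] = (1.0 - drm) * mdx[c] + drm * dx / nrm;
        mdy[c] = (1.0 - drm) * mdy[c] + drm * dy / nrm;
      }
      pcx[c] = ncx; pcy[c] = ncy;
    }
    if (use_pods)
      for (int c = 1; c <= ncell; ++c) {
        if (!alive[c]) {
          for (size_t q = 0; q < pods[c].size(); ++q)
            if (!pods[c][q].chain.empty()) clear_chain(pods[c][q]);
          continue;
        }
        for (size_t q = 0; q < pods[c].size(); ++q) pod_step(c, pods[c][q]);
      }
  }
};

// [[Rcpp::export]]
List cpm_run_cpp(List params) {
  RNGScope scope;
  Engine e(params);
  bool given_owner = params.containsElementNamed("owner_init") &&
    !Rf_isNull(params["owner_init"]);
  if (given_owner) e.set_owner_matrix(as<IntegerMatrix>(params["owner_init"]));
  else e.init_random_cells();

  int total = params["total_mcs"], equil = params["equilibration_mcs"];
  int interval = params["sample_interval"];
  int snap_int = params["snapshot_interval"];
  bool rec_actin = params["record_actin"];
  bool rec_states = params["record_states"];

  std::vector<double> tr_id, tr_t, tr_x, tr_y;
  List snapshots, actin_samples;
  std::vector<int> snap_t;
  IntegerMatrix state_log;
  if (rec_states && e.use_pods)
    state_log = IntegerMatrix(total, e.ncell * e.n_pods);

  for (e.mcs = 1; e.mcs <= total; ++e.mcs) {
    for (int a = 0; a < e.nsites; ++a) e.attempt();
    e.end_of_mcs();
    if (rec_states && e.use_pods)
      for (int c = 1; c <= e.ncell; ++c)
        for (int q = 0; q < e.n_pods; ++q)
          state_log(e.mcs - 1, (c - 1) * e.n_pods + q) = e.pods[c][q].state;
    bool sample = e.mcs > equil && (e.mcs - equil) % interval == 0;
    if (sample) {
      for (int c = 1; c <= e.ncell; ++c) {
        if (!e.alive[c]) continue;
        tr_id.push_back(c);
        tr_t.push_back(e.mcs);
        tr_x.push_back(e.cx(c));
        tr_y.push_back(e.cy(c));
      }
      if (rec_actin && e.use_pods) {
        // rows: cell, pod, order, x, y, owner-at-sample-time
        int nrow = 0;
        for (int c = 1; c <= e.ncell; ++c)
          for (int q = 0; q < e.n_pods; ++q) nrow += e.pods[c][q].chain.size();
        IntegerMatrix am(nrow, 6);
        int r = 0;
        for (int c = 1; c <= e.ncell; ++c)
          for (int q = 0; q < e.n_pods; ++q) {
            const std::deque<int> &ch = e.pods[c][q].chain;
            for (size_t i = 0; i < ch.size(); ++i) {
              am(r, 0) = c; am(r, 1) = q + 1; am(r, 2) = (int)i + 1;
              am(r, 3) = ch[i] % e.W; am(r, 4) = ch[i] / e.W;
              am(r, 5) = e.owner[ch[i]];
              ++r;
            }
          }
        actin_samples.push_back(am);
        snap_t.push_back(e.mcs);
      }
    }
    if (snap_int > 0 && e.mcs % snap_int == 0) {
      IntegerMatrix m(e.W, e.H);
      for (int j = 0; j < e.H; ++j)
        for (int i = 0; i < e.W; ++i) m(i, j) = e.owner[i + j * e.W];
      snapshots.push_back(m);
    }
  }

  int n = tr_id.size();
  NumericMatrix tracks(n, 4);
  for (int i = 0; i < n; ++i) {
    tracks(i, 0) = tr_id[i]; tracks(i, 1) = tr_t[i];
    tracks(i, 2) = tr_x[i]; tracks(i, 3) = tr_y[i];
  }
  IntegerMatrix final_owner(e.W, e.H);
  for (int j = 0; j < e.H; ++j)
    for (int i = 0; i < e.W; ++i) final_owner(i, j) = e.owner[i + j * e.W];
  IntegerVector areas(e.ncell);
  for (int c = 1; c <= e.ncell; ++c) areas[c - 1] = e.area[c];

  return List::create(
    _["tracks"] = tracks,
    _["final_owner"] = final_owner,
    _["areas"] = areas,
    _["snapshots"] = snapshots,
    _["actin"] = actin_samples,
    _["actin_mcs"] = snap_t,
    _["states"] = state_log,
    _["diagnostics"] = List::create(
      _["growing_mcs"] = (double)e.n_growing_mcs,
      _["ext_attempts"] = (double)e.n_ext_attempts,
      _["ext_success"] = (double)e.n_ext_success,
      _["touch_events"] = (double)e.n_touch,
      _["inactive_mcs"] = (double)e.n_inactive_mcs,
      _["init_events"] = (double)e.n_init_events));
}

// Combined incremental ΔH on explicit state (base + optional persistence and
// Act terms), sharing the engine's code path; used for oracle-equivalence
// tests against full-Hamiltonian recomputation.
// [[Rcpp::export]]
double cpm_delta_h_cpp(IntegerMatrix owner, IntegerVector cell_type,
                       NumericMatrix J, NumericVector lambda_v,
                       NumericVector target_area, int x, int y, int xn, int yn,
                       double lambda_p, NumericMatrix target_dir,
                       double lambda_act, double max_act,
                       NumericMatrix activity) {
  int W = owner.nrow(), H = owner.ncol();
  int nc = cell_type.size();
  std::vector<int> buf(W * H), area(nc + 1, 0), ct(nc + 1, 0);
  std::vector<double> lv(nc + 1, 0.0), ta(nc + 1, 0.0), act(W * H, 0.0);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < W; ++i) {
      buf[i + j * W] = owner(i, j);
      act[i + j * W] = activity(i, j);
      if (owner(i, j) > 0) ++area[owner(i, j)];
    }
  for (int c = 1; c <= nc; ++c) {
    ct[c] = cell_type[c - 1]; lv[c] = lambda_v[c - 1]; ta[c] = target_area[c - 1];
  }
  int o_new = buf[wrapi(xn, W) + wrapi(yn, H) * W];
  int o_old = buf[wrapi(x, W) + wrapi(y, H) * W];
  if (o_new == o_old) stop("copy attempt requires differing owners");
  double dh = dh_adhesion_area(buf.data(), W, H, ct.data(), J, lv.data(),
                               ta.data(), area.data(), x, y, o_new);
  if (lambda_p != 0.0) {
    double dx = ring_diff(x, xn, W), dy = ring_diff(y, yn, H);
    double nrm = std::sqrt(dx * dx + dy * dy);
    double sx = dx / nrm, sy = dy / nrm;
    if (o_old > 0)
      dh += -lambda_p * area[o_old] *
            (sx * target_dir(o_old - 1, 0) + sy * target_dir(o_old - 1, 1));
    if (o_new > 0)
      dh += -lambda_p * area[o_new] *
            (sx * target_dir(o_new - 1, 0) + sy * target_dir(o_new - 1, 1));
  }
  if (lambda_act != 0.0) {
    double gm_src = act_gm(buf.data(), act.data(), W, H, xn, yn);
    double gm_tgt = act_gm(buf.data(), act.data(), W, H, x, y);
    dh += -(lambda_act / max_act) * (gm_src - gm_tgt);
  }
  return dh;
}
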