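// Optimized per-step update loop for the group chase-and-escape model.
//
// Draws every random number from R's global RNG (unif_rand) in exactly the
// same sequence as the pure-R reference step (reference_step), so that both
// implementations produce bitwise-identical world states from the same seed.
// All "within distance x" predicates are closed (<= x); nearest-entity ties
// break to the lowest index via strict-< minimum scans.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cfg {
  double R, vT, vD, vG, dt, rmin, rhaz, rlearn, Thunt, Trest;
  double eps, wstart, wend, hwin;
  int NC, NT, maxatt, sample_every;
  bool modelC, rest_haz, rest_gamma, rest_sets;
};

inline void disk_point(double R, double &x, double &y) {
  do {
    x = (2.0 * unif_rand() - 1.0) * R;
    y = (2.0 * unif_rand() - 1.0) * R;
  } while (x * x + y * y > R * R);
}

inline void runit(double &dx, double &dy) {
  double th = 2.0 * M_PI * unif_rand();
  dx = std::cos(th);
  dy = std::sin(th);
}

inline void fy_perm(std::vector<int> &p) {
  int n = (int)p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int k = n; k >= 2; --k) {
    double u = unif_rand();
    int j = (int)(u * k);
    if (j >= k) j = k - 1;
    int tmp = p[k - 1]; p[k - 1] = p[j]; p[j] = tmp;
  }
}

// branch-free minimum of squared distances; the compiler can vectorize the
// min reduction (exact: fp min is associative), unlike the early-exit scan
inline double vmin_d2(const double *xs, const double *ys, int n,
                      double px, double py) {
  double m = R_PosInf;
  // exact SIMD reduction: fp min is associative and commutative, and the
  // per-element d2 arithmetic is unchanged, so results match the scalar scan
#pragma omp simd reduction(min : m)
  for (int k = 0; k < n; ++k) {
    double dx = xs[k] - px, dy = ys[k] - py;
    double d2 = dx * dx + dy * dy;
    m = (d2 < m) ? d2 : m;
  }
  return m;
}

// first index attaining the (already known) minimum: identical result to a
// strict-< first-minimum scan, i.e. ties break to the lowest index
inline int first_at(const double *xs, const double *ys, int n,
                    double px, double py, double m) {
  for (int k = 0; k < n; ++k) {
    double dx = xs[k] - px, dy = ys[k] - py;
    if (dx * dx + dy * dy == m) return k;
  }
  return -1;
}

inline void clampd(double R, double &x, double &y) {
  // iterated so the projection is exactly idempotent despite rounding;
  // after two passes force a strict shrink so a half-ulp tie cannot stall
  double n2 = x * x + y * y;
  int iter = 0;
  while (n2 > R * R) {
    double s = R / std::sqrt(n2);
    if (iter >= 2) s = s * (1 - 2.220446049250313e-16);
    x *= s; y *= s;
    n2 = x * x + y * y;
    ++iter;
  }
}

// Cell-list spatial index. Queries enumerate the 3x3 cell neighbourhood,
// which covers every point within one cell size of the query position; all
// distance decisions on candidates use the same arithmetic as a full scan
// and ties resolve by lowest id, so results are identical to brute force
// whenever the relevant radius is at most the cell size.
struct Grid {
  double cell, orig;
  int dim;
  std::vector<int> head, nxt, cellof;

  void setup(double R, double cell_, int n) {
    cell = cell_;
    orig = -(R + 2.0 * cell);
    dim = (int)std::ceil(2.0 * (R + 2.0 * cell) / cell) + 1;
    head.assign((size_t)dim * dim, -1);
    nxt.assign(n, -1);
    cellof.assign(n, -1);
  }
  inline int cidx(double x, double y) const {
    int ix = (int)((x - orig) / cell);
    int iy = (int)((y - orig) / cell);
    if (ix < 0) ix = 0; else if (ix >= dim) ix = dim - 1;
    if (iy < 0) iy = 0; else if (iy >= dim) iy = dim - 1;
    return iy * dim + ix;
  }
  inline void insert(int k, double x, double y) {
    int ci = cidx(x, y);
    cellof[k] = ci;
    nxt[k] = head[ci];
    head[ci] = k;
  }
  inline void remove(int k) {
    int ci = cellof[k];
    int p = head[ci];
    if (p == k) { head[ci] = nxt[k]; return; }
    while (nxt[p] != k) p = nxt[p];
    nxt[p] = nxt[k];
  }
  inline void relocate(int k, double x, double y) {
    int ci = cidx(x, y);
    if (ci == cellof[k]) return;
    remove(k);
    cellof[k] = ci;
    nxt[k] = head[ci];
    head[ci] = k;
  }
  template <class F> inline void around(double x, double y, F f) const {
    int ix = (int)((x - orig) / cell);
    int iy = (int)((y - orig) / cell);
    for (int gy = iy - 1; gy <= iy + 1; ++gy) {
      if (gy < 0 || gy >= dim) continue;
      for (int gx = ix - 1; gx <= ix + 1; ++gx) {
        if (gx < 0 || gx >= dim) continue;
        for (int k = head[gy * dim + gx]; k >= 0; k = nxt[k]) f(k);
      }
    }
  }
};

struct Engine {
  Cfg c;
  double t;
  std::vector<double> cx, cy, th_, tr_;   // chaser positions and timers
  std::vector<int> strat, mode;           // 1 = GCS / HUNT
  std::vector<double> tx, ty;             // target positions

  // spatial indices (kept current through incremental updates)
  Grid gridCc;  // chasers, coarse (cell >= r_haz): hazard queries
  Grid gridCf;  // chasers, fine: exclusion and capture queries
  Grid gridTf;  // targets, fine: target-target exclusion, replacement

  // scratch
  std::vector<int> nt;          // nearest target of each hunting chaser
  std::vector<double> d2c;      // its squared distance
  std::vector<int> setG, setD;  // per-target strategy composition
  std::vector<double> pax, pay; // chaser attempted positions
  std::vector<int> snap;
  std::vector<double> qax, qay; // target attempted positions
  std::vector<int> permC, permT;

  // logs
  std::vector<double> ev_t, ev_x, ev_y;
  std::vector<int> ev_ch, ev_st, ev_tg, ev_ng, ev_nd, ev_inset;
  std::vector<double> ser_t;
  std::vector<int> ser_g;
  std::vector<double> Nmat, HG, HD;      // (NC+1)^2 dense class counts
  int nbins;
  std::vector<double> steps_bin, captot_bin;
  std::vector<double> cap_gh[2], cap_het[2]; // [strat] hom / het captures
  std::vector<double> occ_hom[2], occ_het[2];
  double fix_time;
  int fix_strat;    // -1 none, 0 DCS, 1 GCS
  long long n_unclassed;

  int cls(int g, int d) const { return g * (c.NC + 1) + d; }

  void init_grids() {
    double fine = std::max(4.0, 2.0 * c.rmin);
    // 5% margin keeps the r_haz sphere robustly inside the 3x3 coverage
    gridCc.setup(c.R, std::max(1.05 * c.rhaz, 4.0), c.NC);
    gridCf.setup(c.R, fine, c.NC);
    gridTf.setup(c.R, fine, c.NT);
    for (int i = 0; i < c.NC; ++i) {
      gridCc.insert(i, cx[i], cy[i]);
      gridCf.insert(i, cx[i], cy[i]);
    }
    for (int j = 0; j < c.NT; ++j) gridTf.insert(j, tx[j], ty[j]);
  }

  void init_logs(int nsteps) {
    double tend = t + (double)nsteps * c.dt;
    nbins = (int)std::ceil(tend / c.hwin);
    if (nbins < 1) nbins = 1;
    steps_bin.assign(nbins, 0.0);
    captot_bin.assign(nbins, 0.0);
    for (int s = 0; s < 2; ++s) {
      cap_gh[s].assign(nbins, 0.0);
      cap_het[s].assign(nbins, 0.0);
      occ_hom[s].assign(nbins, 0.0);
      occ_het[s].assign(nbins, 0.0);
    }
    Nmat.assign((size_t)(c.NC + 1) * (c.NC + 1), 0.0);
    HG.assign(Nmat.size(), 0.0);
    HD.assign(Nmat.size(), 0.0);
    fix_time = -1.0;
    fix_strat = -1;
    n_unclassed = 0;
  }

  int bin_of(double tev) const {
    int b = (int)(tev / c.hwin);
    if (b > nbins - 1) b = nbins - 1;
    if (b < 0) b = 0;
    return b;
  }

  void check_fixation(double at) {
    if (!c.modelC || fix_strat >= 0) return;
    int ng = 0;
    for (int i = 0; i < c.NC; ++i) ng += strat[i];
    if (ng == 0) { fix_strat = 0; fix_time = at; }
    else if (ng == c.NC) { fix_strat = 1; fix_time = at; }
  }

  void record_series(double at) {
    int ng = 0;
    for (int i = 0; i < c.NC; ++i) ng += strat[i];
    ser_t.push_back(at);
    ser_g.push_back(ng);
  }

  void place_replacement(int skip, double &nx, double &ny) {
    double rmin2 = c.rmin * c.rmin;
    for (int attempt = 0; attempt < c.maxatt; ++attempt) {
      double px, py;
      disk_point(c.R, px, py);
      bool clear = true;
      gridCf.around(px, py, [&](int k) {
        if (!clear) return;
        double dx = px - cx[k], dy = py - cy[k];
        if (dx * dx + dy * dy < rmin2) clear = false;
      });
      if (clear) {
        gridTf.around(px, py, [&](int k) {
          if (k == skip || !clear) return;
          double dx = px - tx[k], dy = py - ty[k];
          if (dx * dx + dy * dy < rmin2) clear = false;
        });
      }
      if (clear) { nx = px; ny = py; return; }
    }
    stop("placement failure: max_placement_attempts exceeded");
  }

  void step() {
    const double rmin2 = c.rmin * c.rmin;
    const double eps2 = c.eps * c.eps;
    const double tev = t + c.dt;

    // --- phase 0: mode draws (one uniform per chaser, id order) ---
    for (int i = 0; i < c.NC; ++i) {
      double u = unif_rand();
      if (mode[i] == 1) {
        double p = std::min(th_[i] / c.Thunt, 1.0);
        if (u < p) { mode[i] = 0; tr_[i] = 0.0; }
      } else {
        double p = std::min(tr_[i] / c.Trest, 1.0);
        if (u < p) { mode[i] = 1; th_[i] = 0.0; }
      }
      if (mode[i] == 1) th_[i] += c.dt; else tr_[i] += c.dt;
    }

    // --- phase 0.5: set decomposition (no RNG) ---
    for (int j = 0; j < c.NT; ++j) { setG[j] = 0; setD[j] = 0; }
    for (int i = 0; i < c.NC; ++i) {
      nt[i] = -1;
      if (mode[i] != 1 && !c.rest_sets) continue;
      double best = vmin_d2(tx.data(), ty.data(), c.NT, cx[i], cy[i]);
      int bj = first_at(tx.data(), ty.data(), c.NT, cx[i], cy[i], best);
      nt[i] = bj; d2c[i] = best;
      if (strat[i] == 1) ++setG[bj]; else ++setD[bj];
    }
    {
      int b = bin_of(tev);
      steps_bin[b] += 1.0;
      bool inwin = (tev >= c.wstart && tev <= c.wend);
      for (int j = 0; j < c.NT; ++j) {
        int g = setG[j], d = setD[j];
        if (g + d == 0) continue;
        if (g > 0 && d > 0) {
          occ_het[1][b] += g; occ_het[0][b] += d;
        } else {
          occ_hom[1][b] += g; occ_hom[0][b] += d;
        }
        if (inwin) Nmat[cls(g, d)] += 1.0;
      }
    }

    // --- phase 1: chaser proposals (id order) ---
    for (int i = 0; i < c.NC; ++i) {
      double vdt = (strat[i] == 1 ? c.vG : c.vD) * c.dt;
      snap[i] = -1;
      double ax, ay;
      if (mode[i] != 1) {
        double dx, dy;
        runit(dx, dy);
        ax = cx[i] + vdt * dx; ay = cy[i] + vdt * dy;
      } else {
        int j = nt[i];
        double d = std::sqrt(d2c[i]);
        if (d <= vdt) {
          ax = tx[j]; ay = ty[j];
          snap[i] = j;
        } else {
          double dirx, diry;
          if (strat[i] == 0) {
            dirx = (tx[j] - cx[i]) / d; diry = (ty[j] - cy[i]) / d;
          } else {
            int n = 0;
            double sx = 0.0, sy = 0.0;
            for (int k = 0; k < c.NC; ++k) {
              if (k == i) continue;
              if (!c.rest_gamma && mode[k] != 1) continue;
              double dx = tx[j] - cx[k], dy = ty[j] - cy[k];
              if (dx * dx + dy * dy <= d2c[i]) {
                ++n; sx += cx[k]; sy += cy[k];
              }
            }
            double Xx = (double)(n + 1) * tx[j] - sx;
            double Xy = (double)(n + 1) * ty[j] - sy;
            double vx = Xx - cx[i], vy = Xy - cy[i];
            double nv = std::sqrt(vx * vx + vy * vy);
            if (nv == 0.0) runit(dirx, diry);
            else { dirx = vx / nv; diry = vy / nv; }
          }
          ax = cx[i] + vdt * dirx; ay = cy[i] + vdt * diry;
        }
      }
      clampd(c.R, ax, ay);
      pax[i] = ax; pay[i] = ay;
    }

    // --- phase 2: target proposals (id order) ---
    const double vTdt = c.vT * c.dt;
    for (int j = 0; j < c.NT; ++j) {
      double best = R_PosInf;
      int bk = -1;
      gridCc.around(tx[j], ty[j], [&](int k) {
        if (!c.rest_haz && mode[k] != 1) return;
        double dx = cx[k] - tx[j], dy = cy[k] - ty[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < best || (d2 == best && k < bk)) { best = d2; bk = k; }
      });
      double dch = (bk >= 0) ? std::sqrt(best) : R_PosInf;
      double rT = std::sqrt(tx[j] * tx[j] + ty[j] * ty[j]);
      double db = c.R - rT;
      double hx = 0.0, hy = 0.0;
      int kind = 0; // 0 none, 1 chaser, 2 boundary
      if (bk >= 0 && dch <= c.rhaz && dch <= db) {
        kind = 1; hx = cx[bk]; hy = cy[bk];
      } else if (db <= c.rhaz && rT > 0.0) {
        kind = 2;
        double s = c.R / rT;
        hx = s * tx[j]; hy = s * ty[j];
      }
      double dirx, diry;
      if (kind == 0) {
        runit(dirx, diry);
      } else {
        double vx = tx[j] - hx, vy = ty[j] - hy;
        double nv = std::sqrt(vx * vx + vy * vy);
        if (nv == 0.0) runit(dirx, diry);
        else { dirx = vx / nv; diry = vy / nv; }
      }
      double ax = tx[j] + vTdt * dirx, ay = ty[j] + vTdt * diry;
      clampd(c.R, ax, ay);
      qax[j] = ax; qay[j] = ay;
    }

    // --- phase 3: commit chasers in random order ---
    fy_perm(permC);
    for (int idx = 0; idx < c.NC; ++idx) {
      int i = permC[idx];
      double ax = pax[i], ay = pay[i];
      bool ok = true;
      gridCf.around(ax, ay, [&](int k) {
        if (k == i || !ok) return;
        double dx = ax - cx[k], dy = ay - cy[k];
        if (dx * dx + dy * dy <= rmin2) ok = false;
      });
      if (ok) {
        cx[i] = ax; cy[i] = ay;
        gridCf.relocate(i, ax, ay);
        gridCc.relocate(i, ax, ay);
      } else snap[i] = -1;
    }

    // --- phase 4: commit targets, captures, replacement ---
    fy_perm(permT);
    size_t ev_first = ev_t.size();
    for (int idx = 0; idx < c.NT; ++idx) {
      int j = permT[idx];
      double tjx = tx[j], tjy = ty[j];
      int best = -1;
      double bestd2 = R_PosInf;
      gridCf.around(tjx, tjy, [&](int k) {
        double dx = cx[k] - tjx, dy = cy[k] - tjy;
        double d2 = dx * dx + dy * dy;
        if (d2 < bestd2 || (d2 == bestd2 && k < best)) {
          bestd2 = d2; best = k;
        }
      });
      if (!(bestd2 <= eps2)) best = -1;
      if (best >= 0) {
        int g = setG[j], d = setD[j];
        bool in_set = (nt[best] == j);  // nt is -1 for non-members
        if (!in_set) {
          if (strat[best] == 1) ++g; else ++d;
          ++n_unclassed;
        }
        ev_t.push_back(tev);
        ev_ch.push_back(best);
        ev_st.push_back(strat[best]);
        ev_tg.push_back(j);
        ev_x.push_back(tjx);
        ev_y.push_back(tjy);
        ev_ng.push_back(g);
        ev_nd.push_back(d);
        ev_inset.push_back(in_set ? 1 : 0);
        // fitness and performance accumulators
        int b = bin_of(tev);
        captot_bin[b] += 1.0;
        bool het = (g > 0 && d > 0);
        if (het) cap_het[strat[best]][b] += 1.0;
        else cap_gh[strat[best]][b] += 1.0;
        if (in_set && tev >= c.wstart && tev <= c.wend) {
          if (strat[best] == 1) HG[cls(setG[j], setD[j])] += 1.0;
          else HD[cls(setG[j], setD[j])] += 1.0;
        }
        double nx2, ny2;
        place_replacement(j, nx2, ny2);
        tx[j] = nx2; ty[j] = ny2;
        gridTf.relocate(j, nx2, ny2);
      } else {
        double ax = qax[j], ay = qay[j];
        bool ok = true;
        gridTf.around(ax, ay, [&](int k) {
          if (k == j || !ok) return;
          double dx = ax - tx[k], dy = ay - ty[k];
          if (dx * dx + dy * dy <= rmin2) ok = false;
        });
        if (ok) {
          tx[j] = ax; ty[j] = ay;
          gridTf.relocate(j, ax, ay);
        }
      }
    }

    // --- phase 5: imitation learning (model C) ---
    if (c.modelC && ev_t.size() > ev_first) {
      double rl2 = c.rlearn * c.rlearn;
      for (size_t e = ev_first; e < ev_t.size(); ++e) {
        double ex = ev_x[e], ey = ev_y[e];
        int s_new = strat[ev_ch[e]];
        for (int k = 0; k < c.NC; ++k) {
          double dx = cx[k] - ex, dy = cy[k] - ey;
          if (dx * dx + dy * dy <= rl2) strat[k] = s_new;
        }
      }
    }

    t = tev;
  }
};

Cfg parse_cfg(List cfg) {
  Cfg c;
  c.R = as<double>(cfg["R"]);
  c.NC = as<int>(cfg["N_C"]);
  c.NT = as<int>(cfg["N_T"]);
  c.vT = as<double>(cfg["v_T"]);
  c.vD = as<double>(cfg["v_D"]);
  c.vG = as<double>(cfg["v_G"]);
  c.dt = as<double>(cfg["delta_t"]);
  c.rmin = as<double>(cfg["r_min"]);
  c.rhaz = as<double>(cfg["r_haz"]);
  c.rlearn = as<double>(cfg["r_learn"]);
  c.Thunt = as<double>(cfg["T_hunt"]);
  c.Trest = as<double>(cfg["T_rest"]);
  c.eps = as<double>(cfg["eps_capture"]);
  c.maxatt = as<int>(cfg["max_placement_attempts"]);
  c.sample_every = as<int>(cfg["sample_every"]);
  NumericVector w = cfg["ss_window"];
  c.wstart = w[0]; c.wend = w[1];
  c.hwin = as<double>(cfg["h_window"]);
  std::string model = as<std::string>(cfg["model"]);
  c.modelC = (model == "C");
  c.rest_haz = as<bool>(cfg["resting_are_hazards"]);
  c.rest_gamma = as<bool>(cfg["resting_in_gamma"]);
  c.rest_sets = as<bool>(cfg["resting_in_sets"]);
  return c;
}

} // namespace

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List world, int nsteps) {
  List cfg = world["cfg"];
  Cfg c = parse_cfg(cfg);

  Engine e;
  e.c = c;
  e.t = as<double>(world["t"]);
  NumericMatrix pc = world["pos_c"], pt = world["pos_t"];
  if (pc.nrow() != c.NC || pt.nrow() != c.NT)
    stop("world does not match its configuration");
  e.cx.resize(c.NC); e.cy.resize(c.NC);
  for (int i = 0; i < c.NC; ++i) { e.cx[i] = pc(i, 0); e.cy[i] = pc(i, 1); }
  e.tx.resize(c.NT); e.ty.resize(c.NT);
  for (int j = 0; j < c.NT; ++j) { e.tx[j] = pt(j, 0); e.ty[j] = pt(j, 1); }
  e.strat = as<std::vector<int>>(world["strategy"]);
  e.mode = as<std::vector<int>>(world["mode"]);
  e.th_ = as<std::vector<double>>(world["t_hunt"]);
  e.tr_ = as<std::vector<double>>(world["t_rest"]);

  e.nt.resize(c.NC); e.d2c.resize(c.NC);
  e.setG.resize(c.NT); e.setD.resize(c.NT);
  e.pax.resize(c.NC); e.pay.resize(c.NC); e.snap.resize(c.NC);
  e.qax.resize(c.NT); e.qay.resize(c.NT);
  e.permC.resize(c.NC); e.permT.resize(c.NT);

  e.init_grids();
  e.init_logs(nsteps);
  e.check_fixation(e.t);
  e.record_series(e.t);

  for (int s = 1; s <= nsteps; ++s) {
    e.step();
    e.check_fixation(e.t);
    if (s % c.sample_every == 0) e.record_series(e.t);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // repackage world
  NumericMatrix opc(c.NC, 2), opt(c.NT, 2);
  for (int i = 0; i < c.NC; ++i) { opc(i, 0) = e.cx[i]; opc(i, 1) = e.cy[i]; }
  for (int j = 0; j < c.NT; ++j) { opt(j, 0) = e.tx[j]; opt(j, 1) = e.ty[j]; }
  List oworld = List::create(
    _["t"] = e.t, _["pos_c"] = opc, _["strategy"] = wrap(e.strat),
    _["mode"] = wrap(e.mode), _["t_hunt"] = wrap(e.th_),
    _["t_rest"] = wrap(e.tr_), _["pos_t"] = opt, _["cfg"] = cfg);
  oworld.attr("class") = "chase_world";

  int nev = (int)e.ev_t.size();
  List captures = List::create(
    _["t"] = wrap(e.ev_t), _["chaser_id"] = wrap(e.ev_ch),
    _["strategy"] = wrap(e.ev_st), _["target_id"] = wrap(e.ev_tg),
    _["x"] = wrap(e.ev_x), _["y"] = wrap(e.ev_y),
    _["n_G"] = wrap(e.ev_ng), _["n_D"] = wrap(e.ev_nd),
    _["in_set"] = wrap(e.ev_inset), _["n"] = nev);

  // sparse class-count triplets
  std::vector<int> cc_g, cc_d;
  std::vector<double> cc_n, cc_hg, cc_hd;
  for (int g = 0; g <= c.NC; ++g) {
    for (int d = 0; d <= c.NC; ++d) {
      size_t k = (size_t)g * (c.NC + 1) + d;
      if (e.Nmat[k] > 0.0 || e.HG[k] > 0.0 || e.HD[k] > 0.0) {
        cc_g.push_back(g); cc_d.push_back(d);
        cc_n.push_back(e.Nmat[k]);
        cc_hg.push_back(e.HG[k]); cc_hd.push_back(e.HD[k]);
      }
    }
  }
  List class_counts = List::create(
    _["n_G"] = wrap(cc_g), _["n_D"] = wrap(cc_d), _["N"] = wrap(cc_n),
    _["H_G"] = wrap(cc_hg), _["H_D"] = wrap(cc_hd));

  NumericMatrix hb(e.nbins, 11);
  for (int b = 0; b < e.nbins; ++b) {
    hb(b, 0) = (b + 0.5) * c.hwin;
    hb(b, 1) = e.steps_bin[b];
    hb(b, 2) = e.captot_bin[b];
    hb(b, 3) = e.cap_gh[1][b];
    hb(b, 4) = e.cap_het[1][b];
    hb(b, 5) = e.cap_gh[0][b];
    hb(b, 6) = e.cap_het[0][b];
    hb(b, 7) = e.occ_hom[1][b];
    hb(b, 8) = e.occ_het[1][b];
    hb(b, 9) = e.occ_hom[0][b];
    hb(b, 10) = e.occ_het[0][b];
  }
  colnames(hb) = CharacterVector::create(
    "t", "steps", "capt_total", "capt_G_hom", "capt_G_het", "capt_D_hom",
    "capt_D_het", "occ_G_hom", "occ_G_het", "occ_D_hom", "occ_D_het");

  return List::create(
    _["world"] = oworld,
    _["captures"] = captures,
    _["series_t"] = wrap(e.ser_t),
    _["series_gcs"] = wrap(e.ser_g),
    _["class_counts"] = class_counts,
    _["h_bins"] = hb,
    _["fixation_time"] = e.fix_time,
    _["fixation_strategy"] = e.fix_strat,
    _["n_unclassed"] = (double)e.n_unclassed);
}
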