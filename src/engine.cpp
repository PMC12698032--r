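// Event-driven core of the range-resident logistic IBM and pairwise kernel
// sums used by the crowding estimators. All randomness goes through R's RNG
// so set.seed() on the R side makes every run reproducible bit-for-bit.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double wrap1(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L || w < 0.0) w = 0.0; // rounding at an exact multiple of L
  return w;
}

// minimum-image reduction of a coordinate difference; result in [-L/2, L/2)
static inline double min_image1(double d, double L) {
  d -= L * std::floor(d / L);
  if (d >= L || d < 0.0) d = 0.0;
  if (d >= 0.5 * L) d -= L;
  return d;
}

// Truncated isotropic Gaussian kernel. When the truncation radius reaches
// L/2 a single periodic image is no longer enough and the kernel is summed
// over the (2m+1)^2 image grid (m = ceil(rt/L)); this is the path that makes
// a very wide kernel flat (~1/A) over the torus.
struct Kernel {
  double pref, inv2s2, rt, rt2, L;
  int m;
  void init(double sd2, double rtrunc, double Lbox) {
    pref = 1.0 / (2.0 * M_PI * sd2);
    inv2s2 = 1.0 / (2.0 * sd2);
    rt = rtrunc;
    rt2 = rtrunc * rtrunc;
    L = Lbox;
    m = (rtrunc < 0.5 * Lbox) ? 0 : (int)std::ceil(rtrunc / Lbox);
  }
  inline double val(double dx, double dy) const {
    if (m == 0) {
      double r2 = dx * dx + dy * dy;
      return (r2 <= rt2) ? pref * std::exp(-r2 * inv2s2) : 0.0;
    }
    double s = 0.0;
    for (int jx = -m; jx <= m; ++jx)
      for (int jy = -m; jy <= m; ++jy) {
        double ux = dx + jx * L, uy = dy + jy * L;
        double r2 = ux * ux + uy * uy;
        if (r2 <= rt2) s += pref * std::exp(-r2 * inv2s2);
      }
    return s;
  }
};

// Full recompute of all death rates from wrapped positions, using a grid hash
// (cell size >= truncation radius) when the kernel is short-ranged, otherwise
// brute-force all pairs. Shared by the simulation engine and the exported
// rate function so tests exercise the same code path the engine uses.
static void compute_rates(const std::vector<double>& wx,
                          const std::vector<double>& wy,
                          const Kernel& K, double L, double d0, double gam,
                          std::vector<double>& dr, double& Dtot) {
  int N = (int)wx.size();
  dr.assign(N, d0);
  int nc = (K.m == 0) ? (int)std::floor(L / K.rt) : 0;
  if (nc >= 3) {
    double cs = L / nc;
    std::vector<int> head(nc * nc, -1), nxt(N);
    std::vector<int> cx(N), cy(N);
    for (int i = 0; i < N; ++i) {
      int ix = (int)(wx[i] / cs); if (ix >= nc) ix = nc - 1;
      int iy = (int)(wy[i] / cs); if (iy >= nc) iy = nc - 1;
      cx[i] = ix; cy[i] = iy;
      int c = iy * nc + ix;
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay) {
          int ix = (cx[i] + ax + nc) % nc, iy = (cy[i] + ay + nc) % nc;
          for (int j = head[iy * nc + ix]; j != -1; j = nxt[j]) {
            if (j == i) continue;
            s += K.val(min_image1(wx[j] - wx[i], L),
                       min_image1(wy[j] - wy[i], L));
          }
        }
      dr[i] += gam * s;
    }
  } else {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double w = gam * K.val(min_image1(wx[j] - wx[i], L),
                               min_image1(wy[j] - wy[i], L));
        dr[i] += w; dr[j] += w;
      }
  }
  Dtot = 0.0;
  for (int i = 0; i < N; ++i) Dtot += dr[i];
}

// [[Rcpp::export]]
NumericVector cpp_death_rates(NumericVector x, NumericVector y, double L,
                              double d0, double gam, double sigma_q,
                              double trunc_mult) {
  int N = x.size();
  Kernel K; K.init(sigma_q * sigma_q, trunc_mult * sigma_q, L);
  std::vector<double> wx(N), wy(N), dr;
  for (int i = 0; i < N; ++i) { wx[i] = wrap1(x[i], L); wy[i] = wrap1(y[i], L); }
  double Dtot;
  compute_rates(wx, wy, K, L, d0, gam, dr, Dtot);
  return NumericVector(dr.begin(), dr.end());
}

class Engine {
public:
  double L, b, d0, gam;
  Kernel K;
  int disp_family;            // 0 gaussian, 1 gamma-distance
  double sigma_d, g_shape, g_scale;
  int mode;                   // 0 sessile, 1 OU, 2 BM
  double tau, sigma_r2, D;

  std::vector<double> mux, muy, px, py, dr;
  std::vector<int> id;
  int next_id;
  double t, Dtot;

  // persistent grid for the sessile incremental path
  bool incremental, use_grid;
  int nc; double cs;
  std::vector<std::vector<int>> cell;
  std::vector<int> cellof;

  std::vector<double> wx, wy; // scratch wrapped positions

  void setup_grid() {
    use_grid = false;
    incremental = (mode == 0);
    if (!incremental) return;
    if (K.m == 0) {
      nc = (int)std::floor(L / K.rt);
      if (nc >= 3) {
        use_grid = true;
        cs = L / nc;
        cell.assign(nc * nc, std::vector<int>());
        int N = (int)px.size();
        cellof.assign(N, 0);
        for (int i = 0; i < N; ++i) {
          int c = cell_index(px[i], py[i]);
          cellof[i] = c;
          cell[c].push_back(i);
        }
      }
    }
  }

  inline int cell_index(double x, double y) const {
    int ix = (int)(x / cs); if (ix >= nc) ix = nc - 1;
    int iy = (int)(y / cs); if (iy >= nc) iy = nc - 1;
    return iy * nc + ix;
  }

  // full recompute (movement modes every event; sessile periodic refresh)
  void recompute_all() {
    int N = (int)px.size();
    wx.resize(N); wy.resize(N);
    for (int i = 0; i < N; ++i) { wx[i] = wrap1(px[i], L); wy[i] = wrap1(py[i], L); }
    compute_rates(wx, wy, K, L, d0, gam, dr, Dtot);
  }

  template <class F>
  void for_neighbours(int k, F f) { // sessile path; positions already wrapped
    if (use_grid) {
      int kx = cellof[k] % nc, ky = cellof[k] / nc;
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay) {
          int ix = (kx + ax + nc) % nc, iy = (ky + ay + nc) % nc;
          const std::vector<int>& v = cell[iy * nc + ix];
          for (size_t q = 0; q < v.size(); ++q) if (v[q] != k) f(v[q]);
        }
    } else {
      int N = (int)px.size();
      for (int j = 0; j < N; ++j) if (j != k) f(j);
    }
  }

  void incr_insert(int k) { // arrays already hold organism k
    if (use_grid) {
      int c = cell_index(px[k], py[k]);
      cellof.push_back(c);
      cell[c].push_back(k);
    }
    double extra = 0.0;
    for_neighbours(k, [&](int j) {
      double w = gam * K.val(min_image1(px[j] - px[k], L),
                             min_image1(py[j] - py[k], L));
      if (w != 0.0) { dr[j] += w; extra += w; }
    });
    double dk = d0 + extra;
    dr.push_back(dk);
    Dtot += dk + extra; // own rate plus symmetric additions to neighbours
  }

  void incr_remove(int j) {
    double rem = 0.0;
    for_neighbours(j, [&](int i) {
      double w = gam * K.val(min_image1(px[i] - px[j], L),
                             min_image1(py[i] - py[j], L));
      if (w != 0.0) { dr[i] -= w; rem += w; }
    });
    Dtot -= rem + dr[j];
    if (use_grid) {
      std::vector<int>& v = cell[cellof[j]];
      v.erase(std::find(v.begin(), v.end(), j));
    }
    swap_remove(j);
  }

  void swap_remove(int j) {
    int last = (int)px.size() - 1;
    if (j != last) {
      px[j] = px[last]; py[j] = py[last];
      mux[j] = mux[last]; muy[j] = muy[last];
      dr[j] = dr[last]; id[j] = id[last];
      if (use_grid) {
        std::vector<int>& v = cell[cellof[last]];
        *std::find(v.begin(), v.end(), last) = j;
        cellof[j] = cellof[last];
      }
    }
    px.pop_back(); py.pop_back(); mux.pop_back(); muy.pop_back();
    dr.pop_back(); id.pop_back();
    if (use_grid) cellof.pop_back();
  }

  void propagate_all(double dt) {
    int N = (int)px.size();
    if (mode == 1) {
      double f = std::exp(-dt / tau);
      double s = std::sqrt(sigma_r2 * (1.0 - f * f));
      for (int i = 0; i < N; ++i) {
        px[i] = mux[i] + (px[i] - mux[i]) * f + s * norm_rand();
        py[i] = muy[i] + (py[i] - muy[i]) * f + s * norm_rand();
      }
    } else if (mode == 2) {
      double s = std::sqrt(2.0 * D * dt);
      for (int i = 0; i < N; ++i) {
        px[i] += s * norm_rand();
        py[i] += s * norm_rand();
      }
    }
  }

  void do_birth() {
    int N = (int)px.size();
    int p = (int)(unif_rand() * N); if (p >= N) p = N - 1;
    double ux, uy;
    if (disp_family == 0) {
      ux = sigma_d * norm_rand(); uy = sigma_d * norm_rand();
    } else {
      double dist = R::rgamma(g_shape, g_scale);
      double ang = 2.0 * M_PI * unif_rand();
      ux = dist * std::cos(ang); uy = dist * std::sin(ang);
    }
    double mx = wrap1(mux[p] + ux, L), my = wrap1(muy[p] + uy, L);
    double nx, ny;
    if (mode == 0) { nx = mx; ny = my; }
    else if (mode == 1) {
      double s = std::sqrt(sigma_r2);
      nx = mx + s * norm_rand(); ny = my + s * norm_rand();
    } else { nx = L * unif_rand(); ny = L * unif_rand(); }
    mux.push_back(mx); muy.push_back(my);
    px.push_back(nx); py.push_back(ny);
    id.push_back(next_id++);
    if (incremental) incr_insert((int)px.size() - 1);
    else dr.push_back(d0); // placeholder, recomputed next event
  }

  int select_death() {
    int N = (int)px.size();
    double u = unif_rand() * Dtot, acc = 0.0;
    for (int i = 0; i < N; ++i) {
      acc += dr[i];
      if (u <= acc) return i;
    }
    return N - 1;
  }

  void do_death() {
    int j = select_death();
    if (incremental) incr_remove(j);
    else swap_remove(j);
  }
};

// [[Rcpp::export]]
List cpp_simulate(NumericVector mux0, NumericVector muy0,
                  NumericVector px0, NumericVector py0,
                  IntegerVector id0, int next_id,
                  double L, double b, double d0, double gam,
                  double sigma_q, double trunc_mult,
                  int disp_family, double sigma_d,
                  double g_shape, double g_scale,
                  int mode, double tau, double sigma_r2, double D,
                  int max_events, int stride) {
  Engine E;
  E.L = L; E.b = b; E.d0 = d0; E.gam = gam;
  E.K.init(sigma_q * sigma_q, trunc_mult * sigma_q, L);
  E.disp_family = disp_family; E.sigma_d = sigma_d;
  E.g_shape = g_shape; E.g_scale = g_scale;
  E.mode = mode; E.tau = tau; E.sigma_r2 = sigma_r2; E.D = D;
  int N0 = mux0.size();
  E.mux.assign(mux0.begin(), mux0.end());
  E.muy.assign(muy0.begin(), muy0.end());
  E.px.assign(px0.begin(), px0.end());
  E.py.assign(py0.begin(), py0.end());
  E.id.assign(id0.begin(), id0.end());
  E.next_id = next_id;
  E.t = 0.0;

  E.setup_grid();
  E.recompute_all();

  std::vector<double> rec_t; std::vector<int> rec_N, rec_e;
  int cap = max_events / stride + 4;
  rec_t.reserve(cap); rec_N.reserve(cap); rec_e.reserve(cap);
  rec_t.push_back(0.0); rec_N.push_back(N0); rec_e.push_back(0);

  int ev = 0, births = 0, deaths = 0;
  bool extinct = (N0 == 0);
  while (ev < max_events && !extinct) {
    int N = (int)E.px.size();
    if (!E.incremental) E.recompute_all();
    else if ((ev & 4095) == 0 && ev > 0) E.recompute_all(); // kill drift
    double B = b * N, Rtot = B + E.Dtot;
    double dt = exp_rand() / Rtot;
    if (E.mode != 0) E.propagate_all(dt);
    int etype;
    if (unif_rand() * Rtot < B) { E.do_birth(); ++births; etype = 1; }
    else { E.do_death(); ++deaths; etype = 2; }
    E.t += dt; ++ev;
    int Nn = (int)E.px.size();
    if (Nn == 0) extinct = true;
    if (ev % stride == 0 || ev == max_events || extinct) {
      rec_t.push_back(E.t); rec_N.push_back(Nn); rec_e.push_back(etype);
    }
    if ((ev & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["N"] = IntegerVector(rec_N.begin(), rec_N.end()),
    _["event"] = IntegerVector(rec_e.begin(), rec_e.end()),
    _["mu_x"] = NumericVector(E.mux.begin(), E.mux.end()),
    _["mu_y"] = NumericVector(E.muy.begin(), E.muy.end()),
    _["x"] = NumericVector(E.px.begin(), E.px.end()),
    _["y"] = NumericVector(E.py.begin(), E.py.end()),
    _["id"] = IntegerVector(E.id.begin(), E.id.end()),
    _["next_id"] = E.next_id,
    _["t_final"] = E.t,
    _["events"] = ev,
    _["births"] = births,
    _["deaths"] = deaths,
    _["extinct"] = extinct);
}

// Sum over ordered pairs (i != j) of a truncated isotropic Gaussian density
// with per-component variance `var`, evaluated at minimum-image displacements
// (image-summed when the truncation radius reaches L/2). Shared by the
// position- and home-range-based crowding estimators.
// [[Rcpp::export]]
double cpp_pair_kernel_sum(NumericVector x, NumericVector y, double L,
                           double var, double rtrunc) {
  int N = x.size();
  Kernel K; K.init(var, rtrunc, L);
  std::vector<double> wx(N), wy(N);
  for (int i = 0; i < N; ++i) { wx[i] = wrap1(x[i], L); wy[i] = wrap1(y[i], L); }
  double s = 0.0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      s += K.val(min_image1(wx[j] - wx[i], L), min_image1(wy[j] - wy[i], L));
  return 2.0 * s;
}

// Ordered-pair counts of minimum-image distances per histogram bin
// (breaks half-open (lo, hi]); used by the torus pair-correlation estimator.
// [[Rcpp::export]]
NumericVector cpp_pair_dist_counts(NumericVector x, NumericVector y, double L,
                                   NumericVector breaks) {
  int N = x.size(), nb = breaks.size() - 1;
  std::vector<double> wx(N), wy(N);
  for (int i = 0; i < N; ++i) { wx[i] = wrap1(x[i], L); wy[i] = wrap1(y[i], L); }
  NumericVector counts(nb);
  double lo = breaks[0], hi = breaks[nb];
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = min_image1(wx[j] - wx[i], L), dy = min_image1(wy[j] - wy[i], L);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r <= lo || r > hi) continue;
      int k = (int)(std::upper_bound(breaks.begin(), breaks.end(), r)
                    - breaks.begin()) - 1;
      if (k >= 0 && k < nb) counts[k] += 2.0;
    }
  return counts;
}
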