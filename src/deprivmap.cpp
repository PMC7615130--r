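// Compiled kernels: logistic-model slice sampler, planar polygon predicates,
// queen-adjacency candidate screening, conditional permutations for local
// Moran's I. All randomness uses an explicit 64-bit Mersenne Twister so draws
// are reproducible from an integer seed, independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// numerics
// ---------------------------------------------------------------------------

static inline double dm_log1pexp(double x) {
  // stable log(1 + e^x); no overflow for |x| up to ~1e308
  if (x > 33.3)  return x;
  if (x > 18.0)  return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

struct Rng {
  std::mt19937_64 g;
  std::uniform_real_distribution<double> U{0.0, 1.0};
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() {
    double u;
    do { u = U(g); } while (u <= 0.0 || u >= 1.0);
    return u;
  }
  double expo() { return -std::log(unif()); }
};

// univariate slice sampler with stepping-out and shrinkage (Neal 2003).
// logf must be a callable double -> double (log target up to a constant).
template <typename F>
static double slice_draw(double x0, double f0, F logf, double w, Rng& rng,
                         double* f_out) {
  const double y = f0 - rng.expo();
  double L = x0 - w * rng.unif();
  double R = L + w;
  int guard = 0;
  while (guard++ < 1000 && logf(L) > y) L -= w;
  guard = 0;
  while (guard++ < 1000 && logf(R) > y) R += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + rng.unif() * (R - L);
    double f1 = logf(x1);
    if (f1 > y) { *f_out = f1; return x1; }
    if (x1 < x0) L = x1; else R = x1;
  }
  *f_out = f0;
  return x0;
}

// ---------------------------------------------------------------------------
// Bayesian logistic regression sampler
// ---------------------------------------------------------------------------

// prior_family: 0 = normal(0, prior_scale^2), 1 = double-exponential(scale
// prior_scale), 2 = ridge: normal(0, 1/lambda) with lambda ~ InvGamma(shape,
// rate). alpha always gets normal(0, alpha_scale^2). Random effects V_j ~
// N(0, sigma_v^2), sigma_v ~ half-Cauchy(re_scale), both sampled.
//
// [[Rcpp::export]]
List cpp_fit_chain(NumericMatrix X, IntegerVector y, IntegerVector nb, int J,
                   int prior_family, double prior_scale, double alpha_scale,
                   double re_scale, double ig_shape, double ig_rate,
                   int n_keep, int burn, int thin, double seed,
                   bool store_loglik) {
  const int n = X.nrow(), k = X.ncol();
  const bool has_re = (J > 0);
  const bool ridge  = (prior_family == 2);

  Rng rng(static_cast<uint64_t>(seed));

  // state
  double alpha = 0.0;
  std::vector<double> beta(k, 0.0), V(J, 0.0);
  double log_sv = std::log(0.5);   // sigma_v init 0.5
  double log_lambda = 0.0;         // ridge precision init 1
  std::vector<double> eta(n, 0.0); // linear predictor, kept incrementally

  std::vector<std::vector<int> > groups(J);
  if (has_re) {
    for (int i = 0; i < n; ++i) groups[nb[i]].push_back(i);
  }

  const double* Xp = X.begin(); // column-major
  const int* yp = y.begin();

  auto loglik_shift_all = [&](double d) {
    // log-likelihood when the whole eta vector is shifted by d
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i] + d;
      s += yp[i] * e - dm_log1pexp(e);
    }
    return s;
  };

  auto lp_beta = [&](double b) {
    switch (prior_family) {
      case 0:  return -0.5 * b * b / (prior_scale * prior_scale);
      case 1:  return -std::fabs(b) / prior_scale;
      default: return -0.5 * b * b * std::exp(log_lambda);
    }
  };

  const int total_cols = 1 + k + (has_re ? J + 1 : 0) + (ridge ? 1 : 0);
  NumericMatrix draws(n_keep, total_cols);
  NumericMatrix ll(store_loglik ? n_keep : 0, store_loglik ? n : 0);

  const int n_iter = burn + n_keep * thin;
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- alpha ---
    {
      double cur = alpha;
      auto f = [&](double a) {
        return loglik_shift_all(a - cur) -
               0.5 * a * a / (alpha_scale * alpha_scale);
      };
      double f0 = f(cur), fn;
      double nw = slice_draw(cur, f0, f, 1.0, rng, &fn);
      double d = nw - cur;
      if (d != 0.0) for (int i = 0; i < n; ++i) eta[i] += d;
      alpha = nw;
    }

    // --- beta_j ---
    for (int j = 0; j < k; ++j) {
      const double* xj = Xp + (size_t)j * n;
      double cur = beta[j];
      auto f = [&](double b) {
        double d = b - cur, s = 0.0;
        for (int i = 0; i < n; ++i) {
          double e = eta[i] + d * xj[i];
          s += yp[i] * e - dm_log1pexp(e);
        }
        return s + lp_beta(b);
      };
      double f0 = f(cur), fn;
      double nw = slice_draw(cur, f0, f, 1.0, rng, &fn);
      double d = nw - cur;
      if (d != 0.0) for (int i = 0; i < n; ++i) eta[i] += d * xj[i];
      beta[j] = nw;
    }

    if (has_re) {
      double sv = std::exp(log_sv);
      // --- V_g ---
      for (int g = 0; g < J; ++g) {
        const std::vector<int>& idx = groups[g];
        double cur = V[g];
        auto f = [&](double v) {
          double d = v - cur, s = 0.0;
          for (size_t t = 0; t < idx.size(); ++t) {
            int i = idx[t];
            double e = eta[i] + d;
            s += yp[i] * e - dm_log1pexp(e);
          }
          return s - 0.5 * v * v / (sv * sv);
        };
        double f0 = f(cur), fn;
        double nw = slice_draw(cur, f0, f, 1.0, rng, &fn);
        double d = nw - cur;
        if (d != 0.0)
          for (size_t t = 0; t < idx.size(); ++t) eta[idx[t]] += d;
        V[g] = nw;
      }
      // --- log sigma_v: N(0, sv) likelihood of V + half-Cauchy + Jacobian ---
      {
        auto f = [&](double t) {
          double s = std::exp(t);
          double acc = -(double)J * t; // product of 1/s terms
          double inv2 = 0.5 / (s * s);
          for (int g = 0; g < J; ++g) acc -= V[g] * V[g] * inv2;
          acc += -std::log1p((s / re_scale) * (s / re_scale)); // half-Cauchy kernel
          acc += t;                                            // Jacobian
          return acc;
        };
        double f0 = f(log_sv), fn;
        log_sv = slice_draw(log_sv, f0, f, 0.7, rng, &fn);
      }
    }

    if (ridge) {
      double ssb = 0.0;
      for (int j = 0; j < k; ++j) ssb += beta[j] * beta[j];
      auto f = [&](double t) {
        double lam = std::exp(t);
        // k/2 * log lam - lam*ssb/2 + InvGamma(shape, rate) on lam + Jacobian
        return 0.5 * k * t - 0.5 * lam * ssb -
               (ig_shape + 1.0) * t - ig_rate / lam + t;
      };
      double f0 = f(log_lambda), fn;
      log_lambda = slice_draw(log_lambda, f0, f, 1.0, rng, &fn);
    }

    if (iter >= burn && (iter - burn) % thin == 0) {
      int c = 0;
      draws(kept, c++) = alpha;
      for (int j = 0; j < k; ++j) draws(kept, c++) = beta[j];
      if (has_re) {
        for (int g = 0; g < J; ++g) draws(kept, c++) = V[g];
        draws(kept, c++) = std::exp(log_sv);
      }
      if (ridge) draws(kept, c++) = std::exp(log_lambda);
      if (store_loglik) {
        for (int i = 0; i < n; ++i)
          ll(kept, i) = yp[i] * eta[i] - dm_log1pexp(eta[i]);
      }
      ++kept;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// polygon predicates
// ---------------------------------------------------------------------------

// even-odd ray casting; points exactly on the boundary may land either side
// (documented: zonal statistics use cell *centres*, which generically avoid
// boundaries).
//
// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector px, NumericVector py,
                                 NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int p = 0; p < n; ++p) {
    bool in = false;
    double x = px[p], yy = py[p];
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((vy[i] > yy) != (vy[j] > yy)) &&
          (x < (vx[j] - vx[i]) * (yy - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        in = !in;
    }
    out[p] = in;
  }
  return out;
}

static inline double pt_seg_dist2(double px, double py, double ax, double ay,
                                  double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// distance from each point to the polygon *boundary* (0 inside is NOT
// applied here; callers combine with cpp_points_in_poly).
//
// [[Rcpp::export]]
NumericVector cpp_dist_to_boundary(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double best = R_PosInf;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double d2 = pt_seg_dist2(px[p], py[p], vx[j], vy[j], vx[i], vy[i]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

static inline double seg_seg_dist2(double ax, double ay, double bx, double by,
                                   double cx, double cy, double dx, double dy) {
  // proper intersection => 0
  auto orient = [](double ox, double oy, double px, double py, double qx,
                   double qy) {
    return (px - ox) * (qy - oy) - (py - oy) * (qx - ox);
  };
  double o1 = orient(ax, ay, bx, by, cx, cy);
  double o2 = orient(ax, ay, bx, by, dx, dy);
  double o3 = orient(cx, cy, dx, dy, ax, ay);
  double o4 = orient(cx, cy, dx, dy, bx, by);
  if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0))) return 0.0;
  double d = pt_seg_dist2(ax, ay, cx, cy, dx, dy);
  d = std::min(d, pt_seg_dist2(bx, by, cx, cy, dx, dy));
  d = std::min(d, pt_seg_dist2(cx, cy, ax, ay, bx, by));
  d = std::min(d, pt_seg_dist2(dx, dy, ax, ay, bx, by));
  return d;
}

// minimum gap between two polygon boundaries (0 if touching/crossing)
//
// [[Rcpp::export]]
double cpp_poly_gap(NumericVector ax, NumericVector ay, NumericVector bx,
                    NumericVector by) {
  const int m = ax.size(), q = bx.size();
  double best = R_PosInf;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    for (int s = 0, t = q - 1; s < q; t = s++) {
      double d2 = seg_seg_dist2(ax[j], ay[j], ax[i], ay[i], bx[t], by[t],
                                bx[s], by[s]);
      if (d2 < best) best = d2;
      if (best == 0.0) return 0.0;
    }
  }
  return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// local Moran conditional permutations
// ---------------------------------------------------------------------------

// z: centred variable; nb/w: 0-based neighbour ids and weights per unit
// (ragged, as concatenated vectors with offsets); m2 = sum(z^2)/n.
// For each unit, permute the *other* n-1 values onto its neighbour slots
// n_perm times (sampling without replacement) and count |I_perm| >= |I_obs|.
//
// [[Rcpp::export]]
List cpp_local_moran_perm(NumericVector z, IntegerVector nb_flat,
                          NumericVector w_flat, IntegerVector offset,
                          double m2, int n_perm, double seed) {
  const int n = z.size();
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector li(n), pp(n);
  std::vector<int> pick;
  for (int i = 0; i < n; ++i) {
    int from = offset[i], to = offset[i + 1];
    int k = to - from;
    if (k == 0) { li[i] = NA_REAL; pp[i] = NA_REAL; continue; }
    double lag = 0.0;
    for (int t = from; t < to; ++t) lag += w_flat[t] * z[nb_flat[t]];
    double obs = z[i] * lag / m2;
    li[i] = obs;
    int hits = 0;
    pick.resize(k);
    for (int p = 0; p < n_perm; ++p) {
      // k distinct indices from {0..n-1} \ {i} by rejection (k << n)
      for (int t = 0; t < k; ++t) {
        int cand;
        bool dup;
        do {
          cand = (int)(rng.unif() * (n - 1));
          if (cand >= i) ++cand;
          dup = false;
          for (int s = 0; s < t; ++s)
            if (pick[s] == cand) { dup = true; break; }
        } while (dup);
        pick[t] = cand;
      }
      double plag = 0.0;
      for (int t = 0; t < k; ++t) plag += w_flat[from + t] * z[pick[t]];
      double iperm = z[i] * plag / m2;
      if (std::fabs(iperm) >= std::fabs(obs)) ++hits;
    }
    pp[i] = (hits + 1.0) / (n_perm + 1.0);
  }
  return List::create(_["local_i"] = li, _["pseudo_p"] = pp);
}
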