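// Event-driven (Gillespie) simulation engine, steady-state transport solver
// and exact Spearman permutation enumeration.
//
// Rate evaluation mirrors the R reference implementation in R/energetics.R:
// kind 0 = constant (one-way steps), kind 2 = detailed-balance pair,
// rate = c0 exp(q (G_gi(x) - G_gj(x))) times an optional symmetric reach
// factor. Reversible pairs are capped multiplicatively so forward/reverse
// ratios -- hence detailed balance -- stay exact where the cap binds.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Pack {
  int n, n_canon, nt;
  std::vector<int> attached, canon;   // canon is 1-based canonical index
  std::vector<double> xshift, g;
  double ks, kBT, w, cap;
  std::vector<int> from, to, kind, gi, gj, pair_; // 1-based (pair 0 = none)
  std::vector<double> c0, q, wlo, whi, rf_c, rf_i2;
  std::vector<std::vector<int>> by_from; // 0-based transition ids per state
};

static Pack make_pack(List pk) {
  Pack p;
  p.n = as<int>(pk["n"]);
  p.n_canon = as<int>(pk["n_canon"]);
  p.attached = as<std::vector<int>>(pk["attached"]);
  p.canon = as<std::vector<int>>(pk["canon"]);
  p.xshift = as<std::vector<double>>(pk["xshift"]);
  p.g = as<std::vector<double>>(pk["g"]);
  p.ks = as<double>(pk["ks"]);
  p.kBT = as<double>(pk["kBT"]);
  p.w = as<double>(pk["w"]);
  p.cap = as<double>(pk["cap"]);
  p.from = as<std::vector<int>>(pk["from"]);
  p.to = as<std::vector<int>>(pk["to"]);
  p.kind = as<std::vector<int>>(pk["kind"]);
  p.gi = as<std::vector<int>>(pk["gi"]);
  p.gj = as<std::vector<int>>(pk["gj"]);
  p.c0 = as<std::vector<double>>(pk["c0"]);
  p.q = as<std::vector<double>>(pk["q"]);
  p.rf_c = as<std::vector<double>>(pk["rf_c"]);
  p.rf_i2 = as<std::vector<double>>(pk["rf_i2"]);
  p.pair_ = as<std::vector<int>>(pk["pair"]);
  p.wlo = as<std::vector<double>>(pk["wlo"]);
  p.whi = as<std::vector<double>>(pk["whi"]);
  p.nt = (int)p.from.size();
  p.by_from.assign(p.n, {});
  for (int t = 0; t < p.nt; ++t) p.by_from[p.from[t] - 1].push_back(t);
  return p;
}

static inline double e_energy(const Pack& p, double s) {
  if (!std::isfinite(p.w)) return 0.5 * p.ks * s * s;
  if (s >= 0) return 0.5 * p.ks * s * s;
  return p.ks * p.w * (p.w * (std::exp(s / p.w) - 1.0) - s);
}
static inline double e_force(const Pack& p, double s) {
  if (!std::isfinite(p.w)) return p.ks * s;
  if (s >= 0) return p.ks * s;
  return p.ks * p.w * (std::exp(s / p.w) - 1.0);
}
static inline double e_stiff(const Pack& p, double s) {
  if (!std::isfinite(p.w) || s >= 0) return p.ks;
  return p.ks * std::exp(s / p.w);
}
static inline double G_of(const Pack& p, int st, double x) { // st 0-based
  if (!p.attached[st]) return p.g[st];
  return p.g[st] + e_energy(p, x - p.xshift[st]) / p.kBT;
}

// raw (uncapped) directed rate
static inline double rate_raw(const Pack& p, int t, double x) {
  if (x < p.wlo[t] || x > p.whi[t]) return 0.0;
  if (p.kind[t] == 0) return p.c0[t];
  double dx = x - p.rf_c[t];
  return p.c0[t] *
      std::exp(p.q[t] * (G_of(p, p.gi[t] - 1, x) - G_of(p, p.gj[t] - 1, x)) -
               p.rf_i2[t] * dx * dx);
}

// capped rate (pairwise cap preserves detailed balance)
static inline double rate_at(const Pack& p, int t, double x) {
  double r = rate_raw(p, t, x);
  int pr = p.pair_[t];
  if (pr == 0) return std::min(r, p.cap);
  double r2 = rate_raw(p, pr - 1, x);
  double m = std::max(r, r2);
  if (m > p.cap) r *= p.cap / m;
  return r;
}

// [[Rcpp::export]]
NumericVector cpp_rates_all(List pk, double x) {
  Pack p = make_pack(pk);
  NumericVector out(p.nt);
  for (int t = 0; t < p.nt; ++t) out[t] = rate_at(p, t, x);
  return out;
}

// ---------------------------------------------------------------------------
// quasi-static force balance: find displacement increment delta so that the
// summed cross-bridge force of the attached heads equals the external load
static double rebalance(const Pack& p, const std::vector<double>& xcur,
                        const std::vector<int>& st, double load, double tol) {
  int nat = 0;
  for (size_t h = 0; h < st.size(); ++h) if (p.attached[st[h]]) ++nat;
  if (nat == 0) return 0.0;
  double delta = 0.0;
  for (int it = 0; it < 200; ++it) {
    double F = 0.0, K = 0.0;
    for (size_t h = 0; h < st.size(); ++h) {
      if (!p.attached[st[h]]) continue;
      double s = (xcur[h] - delta) - p.xshift[st[h]];
      F += e_force(p, s);
      K += e_stiff(p, s);
    }
    double resid = F - load;
    if (std::fabs(resid) < tol) return delta;
    delta += resid / K; // F decreases in delta, so Newton step is +resid/K
  }
  // bisection fallback
  double lo = delta - 200.0, hi = delta + 200.0;
  auto Fat = [&](double d) {
    double F = 0.0;
    for (size_t h = 0; h < st.size(); ++h)
      if (p.attached[st[h]]) F += e_force(p, (xcur[h] - d) - p.xshift[st[h]]);
    return F - load;
  };
  while (Fat(lo) < 0) lo -= 200.0;
  while (Fat(hi) > 0) hi += 200.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi), fm = Fat(mid);
    if (fm > 0) lo = mid; else hi = mid;
    if (hi - lo < 1e-12) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_rebalance(List pk, NumericVector x_att, IntegerVector states,
                     double load, double tol) {
  Pack p = make_pack(pk);
  std::vector<double> xc = as<std::vector<double>>(x_att);
  std::vector<int> st(states.size());
  for (int i = 0; i < states.size(); ++i) st[i] = states[i] - 1;
  return rebalance(p, xc, st, load, tol);
}

static inline double wrap_period(double x, double d) {
  return x - d * std::floor(x / d + 0.5);
}

// ---------------------------------------------------------------------------
// coupled ensemble Gillespie with quasi-static filament mechanics
// (zero-load / constant-load). Event-level trace.
// [[Rcpp::export]]
List cpp_sim_coupled(List pk, NumericVector offsets, IntegerVector init_state,
                     double load, double duration, double d_period,
                     double max_excursion, double tol) {
  Pack p = make_pack(pk);
  int nh = offsets.size();
  std::vector<int> st(nh);
  std::vector<double> base(nh); // x = base - D for attached heads
  for (int h = 0; h < nh; ++h) { st[h] = init_state[h] - 1; base[h] = offsets[h]; }
  double D = 0.0, t = 0.0;
  int held = 0, runaway = 0;
  std::vector<double> xs(nh), prop;
  std::vector<int> ev_head, ev_tr;

  // initial rebalance if any head starts attached
  {
    std::vector<double> xc(nh); std::vector<int> stc;
    std::vector<double> xat;
    for (int h = 0; h < nh; ++h) if (p.attached[st[h]]) {
      xat.push_back(base[h] - D); stc.push_back(st[h]);
    }
    if (!xat.empty()) D += rebalance(p, xat, stc, load, tol);
  }

  std::vector<double> T, POS, F;
  std::vector<int> CNT;
  auto record = [&](double tt) {
    T.push_back(tt); POS.push_back(D);
    double Ftot = 0.0;
    std::vector<int> cnt(p.n_canon, 0);
    for (int h = 0; h < nh; ++h) {
      cnt[p.canon[st[h]] - 1]++;
      if (p.attached[st[h]])
        Ftot += e_force(p, (base[h] - D) - p.xshift[st[h]]);
    }
    F.push_back(Ftot);
    for (int c = 0; c < p.n_canon; ++c) CNT.push_back(cnt[c]);
  };
  record(0.0);

  while (t < duration) {
    // head coordinates (detached heads wrapped to the nearest zone)
    double Rtot = 0.0;
    prop.clear(); ev_head.clear(); ev_tr.clear();
    for (int h = 0; h < nh; ++h) {
      double x = base[h] - D;
      if (!p.attached[st[h]]) x = wrap_period(x, d_period);
      xs[h] = x;
      for (int tid : p.by_from[st[h]]) {
        double r = rate_at(p, tid, x);
        if (r > 0) { Rtot += r; prop.push_back(r); ev_head.push_back(h); ev_tr.push_back(tid); }
      }
    }
    if (Rtot <= 0) break; // absorbing configuration
    double tau = R::exp_rand() / Rtot;
    if (t + tau > duration) { t = duration; break; }
    t += tau;
    double u = R::unif_rand() * Rtot, acc = 0.0;
    size_t pick = prop.size() - 1;
    for (size_t i = 0; i < prop.size(); ++i) {
      acc += prop[i];
      if (u <= acc) { pick = i; break; }
    }
    int h = ev_head[pick], tid = ev_tr[pick];
    int snew = p.to[tid] - 1;
    if (!p.attached[st[h]] && p.attached[snew]) {
      base[h] = xs[h] + D;              // freeze anchor on attachment
    } else if (p.attached[st[h]] && !p.attached[snew]) {
      base[h] = offsets[h];             // detached coordinate re-wraps
    }
    st[h] = snew;
    // quasi-static mechanics: re-equilibrate the filament
    std::vector<double> xat; std::vector<int> stc;
    for (int hh = 0; hh < nh; ++hh) if (p.attached[st[hh]]) {
      xat.push_back(base[hh] - D); stc.push_back(st[hh]);
    }
    if (!xat.empty()) D += rebalance(p, xat, stc, load, tol);
    else if (load != 0) ++held;        // unsupported load: position held
    record(t);
    if (std::fabs(D) > max_excursion) { runaway = 1; break; }
  }

  IntegerMatrix cnt((int)T.size(), p.n_canon);
  for (size_t i = 0; i < T.size(); ++i)
    for (int c = 0; c < p.n_canon; ++c) cnt(i, c) = CNT[i * p.n_canon + c];
  return List::create(_["time"] = T, _["position"] = POS, _["force"] = F,
                      _["counts"] = cnt, _["held_events"] = held,
                      _["runaway"] = runaway, _["t_end"] = t);
}

// ---------------------------------------------------------------------------
// isometric ensemble: filament fixed, heads independent; grid-sampled trace
// [[Rcpp::export]]
List cpp_sim_isometric(List pk, NumericVector x_heads, IntegerVector init_state,
                       double duration, double burn, double record_dt) {
  Pack p = make_pack(pk);
  int nh = x_heads.size();
  int ngrid = (int)std::floor(duration / record_dt + 1e-9) + 1;
  NumericVector Fgrid(ngrid);
  IntegerMatrix cnt(ngrid, p.n_canon);
  double favg = 0.0, att_time = 0.0;
  double denom = duration - burn;
  long long n_events = 0;

  for (int h = 0; h < nh; ++h) {
    double x = x_heads[h];
    int s = init_state[h] - 1;
    double t = 0.0;
    int kg = 0;
    while (true) {
      double Rtot = 0.0;
      for (int tid : p.by_from[s]) Rtot += rate_at(p, tid, x);
      double tau = (Rtot > 0) ? R::exp_rand() / Rtot : R_PosInf;
      double t_next = std::min(t + tau, duration);
      double f = p.attached[s] ? e_force(p, x - p.xshift[s]) : 0.0;
      while (kg < ngrid && kg * record_dt < t_next - 1e-12) {
        Fgrid[kg] += f; cnt(kg, p.canon[s] - 1)++; ++kg;
      }
      double ov = std::min(t_next, duration) - std::max(t, burn);
      if (ov > 0) { favg += f * ov; if (p.attached[s]) att_time += ov; }
      if (t + tau >= duration) {
        while (kg < ngrid) { Fgrid[kg] += f; cnt(kg, p.canon[s] - 1)++; ++kg; }
        break;
      }
      t += tau;
      double u = R::unif_rand() * Rtot, acc = 0.0;
      int tid_pick = p.by_from[s].back();
      for (int tid : p.by_from[s]) {
        acc += rate_at(p, tid, x);
        if (u <= acc) { tid_pick = tid; break; }
      }
      s = p.to[tid_pick] - 1;
      ++n_events;
    }
  }
  NumericVector tgrid(ngrid);
  for (int k = 0; k < ngrid; ++k) tgrid[k] = k * record_dt;
  return List::create(_["time"] = tgrid, _["force"] = Fgrid, _["counts"] = cnt,
                      _["mean_force"] = favg / denom,
                      _["attached_fraction"] = att_time / (denom * nh),
                      _["n_events"] = (double)n_events);
}

// ---------------------------------------------------------------------------
// velocity clamp: filament slides at fixed v; heads independent; rates taken
// from per-bin tables (bin-centre values, identical to the steady-state
// solver's discretisation).
// [[Rcpp::export]]
List cpp_sim_clamp(NumericMatrix rate_tab, IntegerVector tfrom, IntegerVector tto,
                   LogicalVector attached, NumericMatrix force_tab,
                   double x_top, double dx, int n_core, double v,
                   NumericVector x0, IntegerVector s0,
                   double duration, double burn) {
  int nt = rate_tab.nrow(), nbins = rate_tab.ncol(), n = force_tab.nrow();
  double period = n_core * dx;
  std::vector<std::vector<int>> by_from(n);
  for (int t = 0; t < nt; ++t) by_from[tfrom[t] - 1].push_back(t);
  int nh = x0.size();
  double favg = 0.0, att_time = 0.0, denom = duration - burn;
  long long n_events = 0, ext_clamp = 0;

  for (int h = 0; h < nh; ++h) {
    double x = x0[h], t = 0.0;
    int s = s0[h] - 1;
    while (t < duration) {
      if (!attached[s]) while (x < x_top - period + 1e-12) x += period;
      int ib = (int)std::floor((x_top - x) / dx);
      if (ib < 0) ib = 0;
      if (ib >= nbins) { ib = nbins - 1; ++ext_clamp; }
      double Rtot = 0.0;
      for (int tid : by_from[s]) Rtot += rate_tab(tid, ib);
      double edge_x = x_top - (ib + 1) * dx;
      double t_edge = (v > 0) ? (x - edge_x) / v : R_PosInf;
      if (t_edge < 0) t_edge = 0;
      double tau = (Rtot > 0) ? R::exp_rand() / Rtot : R_PosInf;
      double step = std::min({tau, t_edge, duration - t});
      double f = force_tab(s, ib);
      double ov = std::min(t + step, duration) - std::max(t, burn);
      if (ov > 0) { favg += f * ov; if (attached[s]) att_time += ov; }
      if (tau <= t_edge && tau <= duration - t) {
        double u = R::unif_rand() * Rtot, acc = 0.0;
        int pick = by_from[s].back();
        for (int tid : by_from[s]) {
          acc += rate_tab(tid, ib);
          if (u <= acc) { pick = tid; break; }
        }
        s = tto[pick] - 1;
        x -= v * tau; t += tau; ++n_events;
      } else if (t_edge < duration - t) {
        x = edge_x - 1e-12; t += t_edge;
      } else {
        t = duration;
      }
    }
  }
  return List::create(_["mean_force"] = favg / denom,
                      _["attached_fraction"] = att_time / (denom * nh),
                      _["n_events"] = (double)n_events,
                      _["ext_clamp"] = (double)ext_clamp);
}

// ---------------------------------------------------------------------------
// dense matrix exponential (scaling-and-squaring Taylor) for small generators
static void expm_small(const std::vector<double>& A, int n, double dt,
                       std::vector<double>& M) {
  std::vector<double> X(A);
  for (auto& v : X) v *= dt;
  double nrm = 0.0;
  for (int j = 0; j < n; ++j) {
    double c = 0.0;
    for (int i = 0; i < n; ++i) c += std::fabs(X[i + j * n]);
    nrm = std::max(nrm, c);
  }
  int k = 0;
  while (nrm > 0.5) { nrm *= 0.5; ++k; }
  double sc = std::ldexp(1.0, -k);
  for (auto& v : X) v *= sc;
  // Taylor series
  std::vector<double> term(X), tmp(n * n);
  M.assign(n * n, 0.0);
  for (int i = 0; i < n; ++i) M[i + i * n] = 1.0;
  for (int i = 0; i < n * n; ++i) M[i] += X[i];
  for (int it = 2; it <= 30; ++it) {
    // term = term * X / it
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < n; ++j)
      for (int l = 0; l < n; ++l) {
        double x = X[l + j * n] / it;
        if (x == 0.0) continue;
        for (int i = 0; i < n; ++i) tmp[i + j * n] += term[i + l * n] * x;
      }
    term = tmp;
    double tn = 0.0;
    for (auto v : term) tn += std::fabs(v);
    for (int i = 0; i < n * n; ++i) M[i] += term[i];
    if (tn < 1e-17) break;
  }
  // square k times
  for (int q = 0; q < k; ++q) {
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < n; ++j)
      for (int l = 0; l < n; ++l) {
        double x = M[l + j * n];
        if (x == 0.0) continue;
        for (int i = 0; i < n; ++i) tmp[i + j * n] += M[i + l * n] * x;
      }
    M = tmp;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_expm(NumericMatrix A, double dt) {
  int n = A.nrow();
  std::vector<double> Av(A.begin(), A.end()), M;
  expm_small(Av, n, dt, M);
  NumericMatrix out(n, n);
  std::copy(M.begin(), M.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// steady-state transport at sliding velocity v: semi-Lagrangian march over
// the strain grid (descending bin edges), periodic wrap for detached states
// at the core boundary, open extension for attached states dragged past it,
// with reinjection of probability detaching below the boundary. Fixed-point
// (power) iteration of the one-period map.
// A: n x n x N transposed generators (dphi/dt = A phi), bin-centre values.
// [[Rcpp::export]]
List cpp_steady_march(NumericVector A, int n, int N, IntegerVector det_idx,
                      int n_core, double dt, int max_sweeps, double tol) {
  std::vector<std::vector<double>> M(N);
  {
    std::vector<double> Ak(n * n);
    for (int k = 0; k < N; ++k) {
      std::copy(A.begin() + (size_t)k * n * n, A.begin() + (size_t)(k + 1) * n * n,
                Ak.begin());
      expm_small(Ak, n, dt, M[k]);
    }
  }
  std::vector<int> det(det_idx.begin(), det_idx.end()); // 1-based
  std::vector<double> inflow(n, 0.0), S((size_t)n * N, 0.0);
  inflow[det[0] - 1] = 1.0;
  std::vector<double> phi(n), tmp(n), Snew((size_t)n * N), outw(n);
  NumericMatrix rho(n, N);
  double delta = R_PosInf;
  int sweep = 0;
  bool record = false;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    std::fill(Snew.begin(), Snew.end(), 0.0);
    std::fill(outw.begin(), outw.end(), 0.0);
    phi = inflow;
    for (int j = 0; j < N; ++j) {
      const std::vector<double>& Mj = M[j];
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int l = 0; l < n; ++l) {
        double x = phi[l];
        if (x == 0.0) continue;
        for (int i = 0; i < n; ++i) tmp[i] += Mj[i + l * n] * x;
      }
      phi = tmp;
      for (int dix : det) phi[dix - 1] += S[(dix - 1) + (size_t)j * n];
      if (j == n_core - 1) {
        for (int dix : det) { outw[dix - 1] += phi[dix - 1]; phi[dix - 1] = 0.0; }
      } else if (j > n_core - 1) {
        for (int dix : det) {
          Snew[(dix - 1) + (size_t)(j - n_core) * n] += phi[dix - 1];
          phi[dix - 1] = 0.0;
        }
      }
      if (record) for (int i = 0; i < n; ++i) rho(i, j) = phi[i];
    }
    if (record) break;
    double tot = 0.0;
    for (double v2 : outw) tot += v2;
    for (double v2 : Snew) tot += v2;
    if (tot <= 0) stop("steady-state march lost all probability");
    delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double nv = outw[i] / tot;
      delta = std::max(delta, std::fabs(nv - inflow[i]));
      inflow[i] = nv;
    }
    for (size_t i = 0; i < S.size(); ++i) {
      double nv = Snew[i] / tot;
      delta = std::max(delta, std::fabs(nv - S[i]));
      S[i] = nv;
    }
    if (delta < tol || sweep == max_sweeps - 2) record = true; // final recording sweep
  }
  double leak = 0.0;
  for (int i = 0; i < n; ++i) leak += phi[i];
  return List::create(_["rho"] = rho, _["sweeps"] = sweep,
                      _["converged"] = (delta < tol), _["leak"] = leak,
                      _["delta"] = delta);
}

// ---------------------------------------------------------------------------
// exact two-sided permutation p-value for Spearman rank correlation
// [[Rcpp::export]]
List cpp_spearman_perm(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sx = 0, sy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += (rx[i] - mx) * (rx[i] - mx);
    sy += (ry[i] - my) * (ry[i] - my);
    sxy += (rx[i] - mx) * (ry[i] - my);
  }
  if (sx <= 0 || sy <= 0) stop("constant input: correlation undefined");
  double denom = std::sqrt(sx * sy);
  double r_obs = sxy / denom;
  std::vector<double> yp(ry.begin(), ry.end());
  std::sort(yp.begin(), yp.end());
  double count = 0.0, total = 0.0, thr = std::fabs(r_obs) - 1e-12;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (rx[i] - mx) * (yp[i] - my);
    if (std::fabs(s / denom) >= thr) count += 1.0;
    total += 1.0;
  } while (std::next_permutation(yp.begin(), yp.end()));
  return List::create(_["r"] = r_obs, _["p"] = count / total,
                      _["n_perm"] = total);
}
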