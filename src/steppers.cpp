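#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Self-contained RNG: mt19937_64 + Marsaglia-Tsang ziggurat, so
// trajectories are reproducible from an integer seed independently of the
// C++ standard library's distribution implementations.
struct BoxMuller {
  std::mt19937_64 eng;
  double wn[128], fn[128];
  int64_t kn[128];
  explicit BoxMuller(uint64_t seed) : eng(seed) {
    const double m = 2147483648.0;  // 2^31
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    const double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<int64_t>((dn / q) * m);
    kn[1] = 0;
    wn[0] = q / m;
    wn[127] = dn / m;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<int64_t>((dn / tn) * m);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m;
    }
  }
  double unif() {
    // uniform in (0,1): never exactly 0 (log-safe)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    for (;;) {
      const int64_t hz = static_cast<int32_t>(static_cast<uint32_t>(eng()));
      const int iz = static_cast<int>(hz & 127);
      if (std::llabs(hz) < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      const double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

struct ActinPars {
  double a1, a2, a3, a4, a5, c1, c2, eps, Du, Dv;
  explicit ActinPars(const List& p)
    : a1(p["a1"]), a2(p["a2"]), a3(p["a3"]), a4(p["a4"]), a5(p["a5"]),
      c1(p["c1"]), c2(p["c2"]), eps(p["eps"]), Du(p["Du"]), Dv(p["Dv"]) {}
};

// Euler(-Maruyama) integration of the actin reaction-diffusion system on a
// periodic grid. noise_mode: 0 none (deterministic), 1 full CLE, 2 reaction
// noise only, 3 additive white noise on u only. var_conv: 0 amplitude^2 =
// sum of propensities, 1 as-printed signed form for the v amplitude.
// [[Rcpp::export]]
List sim_actin_cpp(NumericVector u0, NumericVector v0, double dx, double dt,
                   int nsteps, int save_every, List pars_list, double sigma,
                   int noise_mode, int var_conv, double seed) {
  const ActinPars p(pars_list);
  const int n = u0.size();
  if (v0.size() != n) stop("u0 and v0 must have equal length");
  const bool stochastic = noise_mode != 0 && sigma > 0.0;
  const double idx2 = 1.0 / (dx * dx);
  const double sqdtdx = std::sqrt(dt / dx);

  BoxMuller rng(static_cast<uint64_t>(seed));

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> du(n), dv(n), fu(n), fv(n);

  const int nframes = nsteps / save_every + 1;
  NumericMatrix U(nframes, n), V(nframes, n);
  for (int k = 0; k < n; ++k) { U(0, k) = u[k]; V(0, k) = v[k]; }

  long clamped = 0;
  int frame = 1;
  double bad_time = -1.0;

  const double noise_scale = sigma * sqdtdx;           // per-cell reaction noise
  const double flux_scale = sigma * sqdtdx / dx;       // interface flux difference

  for (int s = 1; s <= nsteps; ++s) {
    if (stochastic && noise_mode == 1) {
      // conservative diffusion noise: one normal per cell interface,
      // flux F_{k+1/2} = sqrt(2 D max(0, (X_k+X_{k+1})/2)) xi / sqrt(dx dt)
      for (int k = 0; k < n; ++k) {
        const int kp = (k == n - 1) ? 0 : k + 1;
        double mu = 0.5 * (u[k] + u[kp]); if (mu < 0.0) mu = 0.0;
        double mv = 0.5 * (v[k] + v[kp]); if (mv < 0.0) mv = 0.0;
        fu[k] = std::sqrt(2.0 * p.Du * mu) * rng.norm();
        fv[k] = std::sqrt(2.0 * p.Dv * mv) * rng.norm();
      }
    }

    for (int k = 0; k < n; ++k) {
      const int km = (k == 0) ? n - 1 : k - 1;
      const int kp = (k == n - 1) ? 0 : k + 1;
      const double lap_u = (u[km] - 2.0 * u[k] + u[kp]) * idx2;
      const double lap_v = (v[km] - 2.0 * v[k] + v[kp]) * idx2;
      const double degr = (p.a1 + p.a2 * v[k]) * u[k];
      const double hill = p.a3 * u[k] * u[k] / (p.a4 + u[k] * u[k]);
      double inc_u = dt * (p.Du * lap_u - degr + hill + p.a5);
      double inc_v = dt * (p.Dv * lap_v + p.eps * (-p.c1 * v[k] + p.c2 * u[k]));
      if (stochastic) {
        if (noise_mode == 3) {         // additive white noise on u only
          inc_u += noise_scale * rng.norm();
        } else {
          double varu = degr + hill + p.a5;
          double varv = (var_conv == 1)
            ? p.eps * (-p.c1 * v[k] + p.c2 * u[k])
            : p.eps * (p.c1 * v[k] + p.c2 * u[k]);
          if (varu < 0.0) varu = 0.0;
          if (varv < 0.0) varv = 0.0;
          inc_u += noise_scale * std::sqrt(varu) * rng.norm();
          inc_v += noise_scale * std::sqrt(varv) * rng.norm();
          if (noise_mode == 1) {
            inc_u += flux_scale * (fu[k] - fu[km]);
            inc_v += flux_scale * (fv[k] - fv[km]);
          }
        }
      }
      du[k] = u[k] + inc_u;
      dv[k] = v[k] + inc_v;
    }
    // clamp-to-zero keeps the multiplicative-noise modes well defined; the
    // additive ablation is left unclamped (its solutions may go negative)
    const bool clamp = stochastic && noise_mode != 3;
    for (int k = 0; k < n; ++k) {
      u[k] = du[k];
      v[k] = dv[k];
      if (clamp) {
        if (u[k] < 0.0) { u[k] = 0.0; ++clamped; }
        if (v[k] < 0.0) { v[k] = 0.0; ++clamped; }
      }
    }

    if (s % save_every == 0) {
      bool bad = false;
      for (int k = 0; k < n; ++k) {
        if (!std::isfinite(u[k]) || !std::isfinite(v[k])) { bad = true; break; }
        U(frame, k) = u[k]; V(frame, k) = v[k];
      }
      if (bad) { bad_time = s * dt; break; }
      ++frame;
    }
  }

  return List::create(
    _["u"] = U, _["v"] = V, _["nframes"] = frame,
    _["clamp_fraction"] = static_cast<double>(clamped) /
      (2.0 * static_cast<double>(n) * static_cast<double>(nsteps)),
    _["bad_time"] = bad_time);
}

static inline double cell_channel_prop(int ch, double nu, double nv,
                                       const ActinPars& p, double vol,
                                       double hop_u, double hop_v,
                                       bool reactions_on) {
  switch (ch) {
    case 0: return reactions_on ? p.a1 * nu : 0.0;
    case 1: return reactions_on ? p.a2 * nu * nv / vol : 0.0;
    case 2: {
      if (!reactions_on) return 0.0;
      const double uc = nu / vol;
      return vol * p.a3 * uc * uc / (p.a4 + uc * uc);
    }
    case 3: return reactions_on ? p.a5 * vol : 0.0;
    case 4: return reactions_on ? p.eps * p.c1 * nv : 0.0;
    case 5: return reactions_on ? p.eps * p.c2 * nu : 0.0;
    case 6: return nu * hop_u;   // u hops left
    case 7: return nu * hop_u;   // u hops right
    case 8: return nv * hop_v;   // v hops left
    default: return nv * hop_v;  // v hops right
  }
}

// Exact well-mixed Gillespie (direct method). Counts are doubles (they can
// exceed 2^31) but always integral. Propensities are count-rates obtained by
// the standard concentration <-> count conversion at system size omega.
// [[Rcpp::export]]
List ssa_wellmixed_cpp(List pars_list, double omega, double nu0, double nv0,
                       NumericVector save_times, double seed) {
  const ActinPars p(pars_list);
  BoxMuller rng(static_cast<uint64_t>(seed));
  double nu = nu0, nv = nv0, t = 0.0;
  const int ns = save_times.size();
  NumericVector Us(ns), Vs(ns);
  int si = 0;
  long nevents = 0;
  double first_event = NA_REAL;
  const double Tend = save_times[ns - 1];

  while (t <= Tend) {
    const double uc = nu / omega;
    double props[6] = {
      p.a1 * nu,
      p.a2 * nu * nv / omega,
      omega * p.a3 * uc * uc / (p.a4 + uc * uc),
      p.a5 * omega,
      p.eps * p.c1 * nv,
      p.eps * p.c2 * nu };
    double a0 = 0.0;
    for (int j = 0; j < 6; ++j) a0 += props[j];
    double tau = (a0 > 0.0) ? -std::log(rng.unif()) / a0 : R_PosInf;
    double tnext = t + tau;
    while (si < ns && save_times[si] < tnext) {
      Us[si] = nu; Vs[si] = nv; ++si;
    }
    if (si >= ns || !R_FINITE(tnext)) break;
    t = tnext;
    if (nevents == 0) first_event = t;
    ++nevents;
    double r = rng.unif() * a0, acc = 0.0;
    int j = 0;
    for (; j < 5; ++j) { acc += props[j]; if (r < acc) break; }
    switch (j) {
      case 0: case 1: nu -= 1.0; break;
      case 2: case 3: nu += 1.0; break;
      case 4: nv -= 1.0; break;
      default: nv += 1.0; break;
    }
  }
  while (si < ns) { Us[si] = nu; Vs[si] = nv; ++si; }
  return List::create(_["u_counts"] = Us, _["v_counts"] = Vs,
                      _["n_events"] = static_cast<double>(nevents),
                      _["first_event_time"] = first_event);
}

// Spatial SSA (reaction-diffusion master equation): per-cell reactions plus
// molecule hops to either neighbour at rate D/dx^2, periodic domain.
// Direct method with per-cell propensity totals and incremental bookkeeping.
// [[Rcpp::export]]
List rdme_cpp(List pars_list, double omega, double dx,
              NumericVector nu0, NumericVector nv0,
              NumericVector save_times, double seed, bool reactions_on) {
  const ActinPars p(pars_list);
  const int n = nu0.size();
  const double vol = omega * dx;
  const double hop_u = p.Du / (dx * dx), hop_v = p.Dv / (dx * dx);
  BoxMuller rng(static_cast<uint64_t>(seed));

  std::vector<double> nu(nu0.begin(), nu0.end()), nv(nv0.begin(), nv0.end());
  std::vector<double> cell_tot(n);
  double a0 = 0.0;
  auto cell_total = [&](int k) {
    double s = 0.0;
    for (int ch = 0; ch < 10; ++ch)
      s += cell_channel_prop(ch, nu[k], nv[k], p, vol, hop_u, hop_v, reactions_on);
    return s;
  };
  for (int k = 0; k < n; ++k) { cell_tot[k] = cell_total(k); a0 += cell_tot[k]; }

  const int ns = save_times.size();
  NumericMatrix U(ns, n), V(ns, n);
  int si = 0;
  double t = 0.0;
  long nevents = 0;
  const double Tend = save_times[ns - 1];

  while (t <= Tend) {
    double tau = (a0 > 1e-300) ? -std::log(rng.unif()) / a0 : R_PosInf;
    double tnext = t + tau;
    while (si < ns && save_times[si] < tnext) {
      for (int k = 0; k < n; ++k) { U(si, k) = nu[k]; V(si, k) = nv[k]; }
      ++si;
    }
    if (si >= ns || !R_FINITE(tnext)) break;
    t = tnext;
    ++nevents;

    // select cell then channel
    double r = rng.unif() * a0, before = 0.0;
    int k = 0;
    for (; k < n - 1; ++k) {
      if (r < before + cell_tot[k]) break;
      before += cell_tot[k];
    }
    double rc = r - before;
    int ch = 0; double cacc = 0.0;
    for (; ch < 9; ++ch) {
      cacc += cell_channel_prop(ch, nu[k], nv[k], p, vol, hop_u, hop_v, reactions_on);
      if (rc < cacc) break;
    }

    const int km = (k == 0) ? n - 1 : k - 1;
    const int kp = (k == n - 1) ? 0 : k + 1;
    int other = -1;
    switch (ch) {
      case 0: case 1: nu[k] -= 1.0; break;
      case 2: case 3: nu[k] += 1.0; break;
      case 4: nv[k] -= 1.0; break;
      case 5: nv[k] += 1.0; break;
      case 6: nu[k] -= 1.0; nu[km] += 1.0; other = km; break;
      case 7: nu[k] -= 1.0; nu[kp] += 1.0; other = kp; break;
      case 8: nv[k] -= 1.0; nv[km] += 1.0; other = km; break;
      default: nv[k] -= 1.0; nv[kp] += 1.0; other = kp; break;
    }

    a0 -= cell_tot[k];
    cell_tot[k] = cell_total(k);
    a0 += cell_tot[k];
    if (other >= 0) {
      a0 -= cell_tot[other];
      cell_tot[other] = cell_total(other);
      a0 += cell_tot[other];
    }
    if (nevents % 1000000 == 0) {  // refresh running sum against FP drift
      a0 = 0.0;
      for (int kk = 0; kk < n; ++kk) a0 += cell_tot[kk];
    }
  }
  while (si < ns) {
    for (int k = 0; k < n; ++k) { U(si, k) = nu[k]; V(si, k) = nv[k]; }
    ++si;
  }
  return List::create(_["u_counts"] = U, _["v_counts"] = V,
                      _["n_events"] = static_cast<double>(nevents));
}

// 8-connected component labelling of a logical mask on the space-time
// lattice: rows are time (not wrapped), columns are space (periodic).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nt = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(nt, nx);
  std::vector<int> stack;
  int nlab = 0;
  for (int start = 0; start < nt * nx; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++nlab;
    lab[start] = nlab;
    stack.push_back(start);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int i = cur % nt, j = cur / nt;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = (j + dj + nx) % nx;
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nt || (di == 0 && dj == 0)) continue;
          const int idx = jj * nt + ii;
          if (mask[idx] && lab[idx] == 0) {
            lab[idx] = nlab;
            stack.push_back(idx);
          }
        }
      }
    }
  }
  return lab;
}
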