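#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// TRAM / TRAMMBAR self-consistent iteration, all in log space.
//
// Unknowns: f[i][k] = -log of the joint weight of (state i, ensemble k),
// Lagrange multipliers nu[i][k] of the row-normalization of the reversible
// per-ensemble transition matrices, and point weights mu(x) for every sample.
// The likelihood being maximized is
//   sum_kij c_ij^k log p_ij^k
//   + sum_k sum_{x in TRAM^k} [log mu(x) + f_{s(x)}^k - b^k(x)]
//   + sum_k sum_{x in MBAR^k} [log mu(x) + f^k - b^k(x)],
// with e^{-f^k} = sum_i e^{-f_i^k}, p^k row-stochastic and reversible w.r.t.
// e^{-f_i^k}, and sum_{x in S_i} mu(x) e^{f_i^k - b^k(x)} = 1 for every (i,k)
// with sampled state i. Stationarity gives the updates implemented below;
// equilibrium samples enter through an extra M^k e^{f^k - f_i^k} term in the
// normalization multipliers and through the per-state sums.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Reversible maximum-likelihood transition matrix from a count matrix via
// the standard self-consistent update on symmetric fluxes x_ij = pi_i p_ij.
// [[Rcpp::export(name = ".rev_mle_cpp")]]
List rev_mle_cpp(NumericMatrix Cm, double tol, int max_iter) {
  int n = Cm.nrow();
  std::vector<double> ci(n, 0.0), xi(n, 0.0);
  std::vector<double> x((size_t)n * n), csym((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      csym[(size_t)i * n + j] = Cm(i, j) + Cm(j, i);
      ci[i] += Cm(i, j);
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      x[(size_t)i * n + j] = csym[(size_t)i * n + j];
      xi[i] += csym[(size_t)i * n + j];
    }
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double ch = 0.0;
    std::vector<double> xnew((size_t)n * n, 0.0), xin(n, 0.0), r(n);
    for (int j = 0; j < n; ++j) r[j] = xi[j] > 0.0 ? ci[j] / xi[j] : 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double s = csym[(size_t)i * n + j];
        if (s <= 0.0) continue;
        xnew[(size_t)i * n + j] = s / (r[i] + r[j]);
      }
    double tot = 0.0;
    for (size_t e = 0; e < xnew.size(); ++e) tot += xnew[e];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) xin[i] += xnew[(size_t)i * n + j];
    double tot_old = 0.0;
    for (size_t e = 0; e < x.size(); ++e) tot_old += x[e];
    for (size_t e = 0; e < x.size(); ++e) {
      double d = std::fabs(xnew[e] / tot - x[e] / tot_old);
      if (d > ch) ch = d;
    }
    x.swap(xnew);
    for (int i = 0; i < n; ++i) xi[i] = xin[i];
    if (ch < tol) break;
  }
  NumericMatrix T(n, n);
  NumericVector pi0(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += xi[i];
  for (int i = 0; i < n; ++i) {
    pi0[i] = xi[i] / tot;
    for (int j = 0; j < n; ++j) T(i, j) = x[(size_t)i * n + j] / xi[i];
  }
  return List::create(_["T"] = T, _["pi"] = pi0, _["iterations"] = it);
}

// [[Rcpp::export(name = ".tram_core_cpp")]]
List tram_core_cpp(NumericVector counts_arr, // dim (n, n, K)
                   IntegerVector tram_state, IntegerVector tram_ens,
                   NumericMatrix tram_bias,
                   IntegerVector mbar_state, IntegerVector mbar_ens,
                   NumericMatrix mbar_bias,
                   double tol, int max_iter, bool keep_trace) {
  IntegerVector dims = counts_arr.attr("dim");
  int n = dims[0], K = dims[2];
  int Nt = tram_state.size(), Nm = mbar_state.size();
  int N = Nt + Nm;

  auto C = [&](int i, int j, int k) -> double {
    return counts_arr[i + (R_xlen_t)j * n + (R_xlen_t)k * n * n];
  };

  // symmetric counts and bookkeeping
  std::vector<std::vector<double>> csym(K), crow(K), ccol(K);
  // sparse pattern of csym per k: list of (i, j, val) with i <= j
  std::vector<std::vector<int>> pi_(K), pj_(K);
  std::vector<std::vector<double>> pv_(K);
  for (int k = 0; k < K; ++k) {
    csym[k].assign((size_t)n * n, 0.0);
    crow[k].assign(n, 0.0);
    ccol[k].assign(n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double c = C(i, j, k);
        crow[k][i] += c;
        ccol[k][j] += c;
      }
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j) {
        double s = C(i, j, k) + C(j, i, k);
        csym[k][(size_t)i * n + j] = s;
        csym[k][(size_t)j * n + i] = s;
        if (s > 0.0) { pi_[k].push_back(i); pj_[k].push_back(j); pv_[k].push_back(s); }
      }
  }

  // TRAM sample counts per (i,k), MBAR counts per k, and overall state support
  std::vector<double> Nik((size_t)n * K, 0.0), Mk(K, 0.0);
  std::vector<int> nsamp(n, 0);
  for (int x = 0; x < Nt; ++x) {
    Nik[(size_t)tram_state[x] * K + tram_ens[x]] += 1.0;
    nsamp[tram_state[x]]++;
  }
  for (int x = 0; x < Nm; ++x) {
    Mk[mbar_ens[x]] += 1.0;
    nsamp[mbar_state[x]]++;
  }
  for (int i = 0; i < n; ++i)
    if (nsamp[i] == 0)
      stop("state %d has no samples in any ensemble", i + 1);

  std::vector<double> f((size_t)n * K, 0.0), newf((size_t)n * K, 0.0);
  std::vector<double> lognu((size_t)n * K, R_NegInf);
  std::vector<double> logR((size_t)n * K, R_NegInf);
  std::vector<double> loggam((size_t)n * K, R_NegInf);
  std::vector<double> fk(K, 0.0);
  std::vector<double> logmu(N, 0.0);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i)
      if (crow[k][i] > 0.0) lognu[(size_t)i * K + k] = std::log(crow[k][i]);

  std::vector<double> ll_trace;
  std::vector<double> mx((size_t)n * K), acc((size_t)n * K);
  double increment = R_PosInf, loglik = R_NegInf, prev_loglik = R_NegInf;
  int iter = 0;
  bool converged = false;

  auto sigma_of = [&](int i, int j, int k) -> double {
    double a = lognu[(size_t)i * K + k] - f[(size_t)j * K + k];
    double b = lognu[(size_t)j * K + k] - f[(size_t)i * K + k];
    if (a == R_NegInf && b == R_NegInf) return NA_REAL;
    if (a == R_NegInf) return 0.0;
    if (b == R_NegInf) return 1.0;
    return 1.0 / (1.0 + std::exp(b - a));
  };

  // converge the row-normalization multipliers nu for the current f:
  // exact maximization over the reversible transition matrices given f
  auto converge_nu = [&](double nu_tol, int nu_max) {
    std::vector<double> nunew((size_t)n * K);
    for (int pass = 0; pass < nu_max; ++pass) {
      double ch = 0.0;
      std::fill(nunew.begin(), nunew.end(), 0.0);
      for (int k = 0; k < K; ++k)
        for (size_t e = 0; e < pv_[k].size(); ++e) {
          int i = pi_[k][e], j = pj_[k][e];
          double sig = sigma_of(i, j, k);
          if (ISNA(sig)) continue;
          double v = pv_[k][e];
          nunew[(size_t)i * K + k] += v * sig;
          if (j != i) nunew[(size_t)j * K + k] += v * (1.0 - sig);
          // diagonal: csym_ii = 2 c_ii, sig = 1/2 gives nu += c_ii
        }
      for (size_t idx = 0; idx < nunew.size(); ++idx) {
        double nl = nunew[idx] > 0.0 ? std::log(nunew[idx]) : R_NegInf;
        if (nl != R_NegInf && lognu[idx] != R_NegInf)
          ch = std::max(ch, std::fabs(nl - lognu[idx]));
        else if (nl != lognu[idx])
          ch = R_PosInf;
        lognu[idx] = nl;
      }
      if (ch < nu_tol) break;
    }
  };

  converge_nu(0.0, 1);  // one interleaved pass: f and nu co-evolve

  for (iter = 1; iter <= max_iter; ++iter) {
    // f^k = -log sum_i e^{-f_i^k}
    for (int k = 0; k < K; ++k) {
      double m = R_PosInf;
      for (int i = 0; i < n; ++i) m = std::min(m, f[(size_t)i * K + k]);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += std::exp(m - f[(size_t)i * K + k]);
      fk[k] = m - std::log(s);
    }

    // normalization multipliers R from the converged nu
    std::vector<double> Rlin((size_t)n * K, 0.0);
    for (int k = 0; k < K; ++k) {
      for (size_t e = 0; e < pv_[k].size(); ++e) {
        int i = pi_[k][e], j = pj_[k][e];
        double sig = sigma_of(i, j, k);
        if (ISNA(sig)) continue;
        double v = pv_[k][e];
        Rlin[(size_t)i * K + k] += v * (1.0 - sig);
        if (j != i) Rlin[(size_t)j * K + k] += v * sig;
      }
      for (int i = 0; i < n; ++i) {
        size_t idx = (size_t)i * K + k;
        double R = Rlin[idx] + Nik[idx] - ccol[k][i];
        logR[idx] = R > 0.0 ? std::log(R) : R_NegInf;
        double mb = Mk[k] > 0.0
                        ? std::log(Mk[k]) + fk[k] - f[idx]
                        : R_NegInf;
        loggam[idx] = lse2(logR[idx], mb);
      }
    }

    // mu update: log mu(x) = -lse_k(loggam[s,k] + f[s,k] - b^k(x))
    for (int x = 0; x < N; ++x) {
      int s = (x < Nt) ? tram_state[x] : mbar_state[x - Nt];
      double m = R_NegInf;
      double vals[64]; // K is small
      for (int k = 0; k < K; ++k) {
        size_t idx = (size_t)s * K + k;
        double b = (x < Nt) ? tram_bias(x, k) : mbar_bias(x - Nt, k);
        double v = (loggam[idx] == R_NegInf) ? R_NegInf
                                             : loggam[idx] + f[idx] - b;
        vals[k] = v;
        if (v > m) m = v;
      }
      double ssum = 0.0;
      for (int k = 0; k < K; ++k)
        if (vals[k] != R_NegInf) ssum += std::exp(vals[k] - m);
      logmu[x] = -(m + std::log(ssum));
    }

    // f update: e^{-f_i^k} = sum_{x in S_i} mu(x) e^{-b^k(x)}; two-pass LSE
    std::fill(mx.begin(), mx.end(), R_NegInf);
    for (int x = 0; x < N; ++x) {
      int s = (x < Nt) ? tram_state[x] : mbar_state[x - Nt];
      for (int k = 0; k < K; ++k) {
        double b = (x < Nt) ? tram_bias(x, k) : mbar_bias(x - Nt, k);
        double v = logmu[x] - b;
        if (v > mx[(size_t)s * K + k]) mx[(size_t)s * K + k] = v;
      }
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int x = 0; x < N; ++x) {
      int s = (x < Nt) ? tram_state[x] : mbar_state[x - Nt];
      for (int k = 0; k < K; ++k) {
        double b = (x < Nt) ? tram_bias(x, k) : mbar_bias(x - Nt, k);
        acc[(size_t)s * K + k] += std::exp(logmu[x] - b - mx[(size_t)s * K + k]);
      }
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) {
        size_t idx = (size_t)i * K + k;
        newf[idx] = -(mx[idx] + std::log(acc[idx]));
      }

    // gauge fix f^0 = 0 (=> sum_x mu(x) = 1)
    {
      double m = R_PosInf;
      for (int i = 0; i < n; ++i) m = std::min(m, newf[(size_t)i * K]);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += std::exp(m - newf[(size_t)i * K]);
      double f0 = m - std::log(s);
      for (size_t idx = 0; idx < newf.size(); ++idx) newf[idx] -= f0;
      for (int x = 0; x < N; ++x) logmu[x] += f0;
    }

    increment = 0.0;
    for (size_t idx = 0; idx < newf.size(); ++idx) {
      double d = std::fabs(newf[idx] - f[idx]);
      if (d > increment) increment = d;
      f[idx] = newf[idx];
    }

    // re-converge nu for the updated f so the likelihood is evaluated at a
    // consistent feasible point (p reversible w.r.t. e^{-f}, rows summing
    // to 1, per-state normalization exact by construction of the f update)
    converge_nu(0.0, 1);  // one interleaved pass: f and nu co-evolve

    // log-likelihood at the current iterate; when no trace is kept, only
    // evaluated near convergence (the increment criterion gates first)
    bool do_ll = keep_trace || increment < tol * 10;
    if (do_ll) {
      for (int k = 0; k < K; ++k) {
        double m = R_PosInf;
        for (int i = 0; i < n; ++i) m = std::min(m, f[(size_t)i * K + k]);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += std::exp(m - f[(size_t)i * K + k]);
        fk[k] = m - std::log(s);
      }
      // Transition term at an exactly feasible point: row-normalize the
      // raw reversible estimate into a proposal A, then Metropolis-ize it
      // against pi = e^{-f}. The result is row-stochastic AND reversible at
      // every iterate and coincides with the raw p at convergence, so the
      // trace is a genuine likelihood value converging to the optimum.
      double ll = 0.0;
      for (int k = 0; k < K; ++k) {
        std::vector<double> rowlse(n, R_NegInf);
        std::vector<std::vector<std::pair<int, double>>> rows(n);
        for (size_t e = 0; e < pv_[k].size(); ++e) {
          int i = pi_[k][e], j = pj_[k][e];
          double v = pv_[k][e];
          double den = lse2(lognu[(size_t)i * K + k] - f[(size_t)j * K + k],
                            lognu[(size_t)j * K + k] - f[(size_t)i * K + k]);
          if (den == R_NegInf) continue;
          // the same expression is valid on the diagonal: csym_ii = 2 c_ii
          // and the denominator doubles, giving p_ii = c_ii / nu_i
          double lpij = std::log(v) - f[(size_t)j * K + k] - den;
          double lpji = std::log(v) - f[(size_t)i * K + k] - den;
          rows[i].push_back({j, lpij});
          rowlse[i] = lse2(rowlse[i], lpij);
          if (j != i) {
            rows[j].push_back({i, lpji});
            rowlse[j] = lse2(rowlse[j], lpji);
          }
        }
        // log A_ij = lp_ij - rowlse_i; Metropolis acceptance against pi
        std::vector<std::vector<std::pair<int, double>>> met(n);
        std::vector<double> offsum(n, 0.0);
        for (int i = 0; i < n; ++i)
          for (auto& pr : rows[i]) {
            int j = pr.first;
            if (j == i) continue;
            double lAij = pr.second - rowlse[i];
            // find A_ji
            double lAji = R_NegInf;
            for (auto& qr : rows[j])
              if (qr.first == i) { lAji = qr.second - rowlse[j]; break; }
            double lr = (-f[(size_t)j * K + k] + lAji) -
                        (-f[(size_t)i * K + k] + lAij);
            double lp = lAij + std::min(0.0, lr);
            met[i].push_back({j, lp});
            offsum[i] += std::exp(lp);
          }
        for (int i = 0; i < n; ++i) {
          for (auto& pr : met[i]) {
            double c = C(i, pr.first, k);
            if (c > 0.0) ll += c * pr.second;
          }
          double cii = C(i, i, k);
          if (cii > 0.0) {
            double pii = 1.0 - offsum[i];
            ll += cii * std::log(std::max(pii, 1e-300));
          }
        }
      }
      for (int x = 0; x < Nt; ++x)
        ll += logmu[x] + f[(size_t)tram_state[x] * K + tram_ens[x]] -
              tram_bias(x, tram_ens[x]);
      for (int x = 0; x < Nm; ++x)
        ll += logmu[Nt + x] + fk[mbar_ens[x]] - mbar_bias(x, mbar_ens[x]);
      loglik = ll;
      if (keep_trace) ll_trace.push_back(ll);
    }

    bool ll_ok = do_ll && ((prev_loglik == R_NegInf) ||
                           std::fabs(loglik - prev_loglik) < 1e-8);
    if (do_ll) prev_loglik = loglik;
    if (increment < tol && ll_ok) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // final transition matrices (row-normalized on states with counts)
  NumericVector parr(Dimension(n, n, K));
  std::fill(parr.begin(), parr.end(), NA_REAL);
  for (int k = 0; k < K; ++k) {
    std::vector<double> row(n, 0.0);
    std::vector<std::vector<std::pair<int, double>>> rows(n);
    for (size_t e = 0; e < pv_[k].size(); ++e) {
      int i = pi_[k][e], j = pj_[k][e];
      double v = pv_[k][e];
      double den_log = lse2(lognu[(size_t)i * K + k] - f[(size_t)j * K + k],
                            lognu[(size_t)j * K + k] - f[(size_t)i * K + k]);
      if (den_log == R_NegInf) continue;
      double pij = v * std::exp(-f[(size_t)j * K + k] - den_log);
      double pji = v * std::exp(-f[(size_t)i * K + k] - den_log);
      rows[i].push_back({j, pij});
      row[i] += pij;
      if (j != i) { rows[j].push_back({i, pji}); row[j] += pji; }
    }
    for (int i = 0; i < n; ++i) {
      if (crow[k][i] <= 0.0 || row[i] <= 0.0) continue;
      for (int j = 0; j < n; ++j) parr[i + (R_xlen_t)j * n + (R_xlen_t)k * n * n] = 0.0;
      for (auto& pr : rows[i])
        parr[i + (R_xlen_t)pr.first * n + (R_xlen_t)k * n * n] = pr.second / row[i];
    }
  }

  NumericMatrix fout(n, K), lognuout(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      fout(i, k) = f[(size_t)i * K + k];
      lognuout(i, k) = lognu[(size_t)i * K + k];
    }
  NumericVector logmu_t(Nt), logmu_m(Nm), fkout(K);
  for (int x = 0; x < Nt; ++x) logmu_t[x] = logmu[x];
  for (int x = 0; x < Nm; ++x) logmu_m[x] = logmu[Nt + x];
  for (int k = 0; k < K; ++k) fkout[k] = fk[k];

  return List::create(
      _["f_ik"] = fout, _["f_k"] = fkout, _["log_nu"] = lognuout,
      _["log_mu_tram"] = logmu_t, _["log_mu_mbar"] = logmu_m,
      _["transition_arr"] = parr, _["iterations"] = iter,
      _["max_increment"] = increment, _["log_likelihood"] = loglik,
      _["log_likelihood_trace"] = wrap(ll_trace), _["converged"] = converged);
}
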