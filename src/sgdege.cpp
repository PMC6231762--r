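// Compiled inner loops for the SGDEGE simulators. All randomness is drawn
// in R and passed in (perturbation flags/bins), so these loops are purely
// deterministic given their inputs; the R "r" engines reproduce them
// exactly up to floating-point summation order.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double clamp_rate(double x, double rmax) {
  if (x < 0.0) return 0.0;
  if (x > rmax) return rmax;
  return x;
}

// Full microzone network: threshold-linear rates, global error vs adaptive
// olivary cancellation, perturbation-gated w updates and always-on v updates.
// act/bin: (N*S/2) x p, 0-based flat fibre index and firing bin per pattern.
// targets: length L*T*p, index l + L*(t + T*mu).
// pflag/pbin: L x n_trials perturbation draws (bin 0-based).
// Each pattern's synaptic drives onto Purkinje cells (G) and nucleo-olivary
// cells (vd) are cached and updated incrementally: a trial changes only the
// weights of fibres active in a perturbed bin (w) and of the pattern's
// active fibres (v), a small fraction of all synapses.
// [[Rcpp::export]]
List cpp_run_network(IntegerMatrix act, IntegerMatrix bin,
                     NumericMatrix w0, NumericMatrix sigma, NumericVector v0,
                     IntegerVector lpn, IntegerVector lno,
                     NumericVector targets,
                     int S, int L, int T, int N,
                     double rmax, double A, double alpha_w, double alpha_v,
                     double uMPN, double uPCPN, double uPCNO,
                     LogicalMatrix pflag, IntegerMatrix pbin, int n_trials) {
  const int nfib = N * S, nact = act.nrow(), p = act.ncol(), nst = S * T;
  // transposed copies (L fastest) for cache-friendly per-fibre access
  std::vector<double> wT((size_t)nfib * L), sT((size_t)nfib * L),
      wsT((size_t)nfib * L);
  for (int f = 0; f < nfib; ++f)
    for (int l = 0; l < L; ++l) {
      wT[(size_t)f * L + l] = w0(f, l);
      sT[(size_t)f * L + l] = sigma(f, l);
      wsT[(size_t)f * L + l] = w0(f, l) * sigma(f, l);
    }
  std::vector<double> v(v0.begin(), v0.end());
  // per-pattern precomputations and drive caches
  std::vector<std::vector<int>> flats(p), stIdx(p);
  std::vector<std::vector<std::vector<int>>> byBin(
      p, std::vector<std::vector<int>>(T));
  std::vector<std::vector<double>> cntPN(p, std::vector<double>(L * T, 0.0));
  std::vector<std::vector<double>> G(p, std::vector<double>((size_t)nst * L, 0.0));
  std::vector<std::vector<double>> vd(p, std::vector<double>(L * T, 0.0));
  // fibre -> patterns it is active in, with its (s,t) slot there (CSR)
  std::vector<int> membCnt(nfib + 1, 0);
  for (int mu = 0; mu < p; ++mu) {
    flats[mu].resize(nact);
    stIdx[mu].resize(nact);
    for (int k = 0; k < nact; ++k) {
      int f = act(k, mu), b = bin(k, mu), s = f / N;
      flats[mu][k] = f;
      stIdx[mu][k] = s * T + b;
      byBin[mu][b].push_back(f);
      cntPN[mu][lpn[f] + L * b] += 1.0;
      ++membCnt[f + 1];
      double* g = &G[mu][(size_t)(s * T + b) * L];
      const double* wc = &wsT[(size_t)f * L];
      for (int l = 0; l < L; ++l) g[l] += wc[l];
      vd[mu][lno[f] + L * b] += v[f];
    }
  }
  std::vector<int> membStart(membCnt);
  for (int f = 0; f < nfib; ++f) membStart[f + 1] += membStart[f];
  std::vector<int> membPat(membStart[nfib]), membSt(membStart[nfib]);
  {
    std::vector<int> pos(membStart.begin(), membStart.end() - 1);
    for (int mu = 0; mu < p; ++mu)
      for (int k = 0; k < nact; ++k) {
        const int f = flats[mu][k];
        membPat[pos[f]] = mu;
        membSt[pos[f]] = stIdx[mu][k];
        ++pos[f];
      }
  }
  std::vector<double> pcsum(L * T);
  std::vector<int> etaBin(L);
  NumericVector errOut(n_trials), inhOut(n_trials);
  IntegerVector ecsOut(n_trials), npOut(n_trials), patOut(n_trials);
  const double inv_lt = 1.0 / (double)(L * T);

  for (int tr = 0; tr < n_trials; ++tr) {
    const int mu = tr % p;
    int npert = 0;
    for (int l = 0; l < L; ++l) {
      if (pflag(l, tr)) { etaBin[l] = pbin(l, tr); ++npert; }
      else etaBin[l] = -1;
    }
    std::fill(pcsum.begin(), pcsum.end(), 0.0);
    const std::vector<double>& Gmu = G[mu];
    for (int st = 0; st < nst; ++st) {
      const int t = st % T;
      const double* g = &Gmu[(size_t)st * L];
      for (int l = 0; l < L; ++l) {
        double x = g[l];
        if (etaBin[l] == t) x += A;
        pcsum[l + L * t] += clamp_rate(x, rmax);
      }
    }
    double esum = 0.0, isum = 0.0;
    const double* tg = &targets[(size_t)mu * L * T];
    for (int j = 0; j < L * T; ++j) {
      double pn = clamp_rate(uMPN * cntPN[mu][j] + uPCPN * pcsum[j], rmax);
      double no = clamp_rate(vd[mu][j] + uPCNO * pcsum[j], rmax);
      esum += std::abs(pn - tg[j]);
      isum += no;
    }
    const double E = esum * inv_lt, I = isum * inv_lt;
    const int c = (E - I > 0.0) ? 1 : -1;
    errOut[tr] = E; inhOut[tr] = I; ecsOut[tr] = c;
    npOut[tr] = npert; patOut[tr] = mu;
    // w: only synapses of fibres active in a perturbed bin of that column
    const double dw = alpha_w * (double)c;
    for (int l = 0; l < L; ++l) {
      if (etaBin[l] < 0) continue;
      const std::vector<int>& fb = byBin[mu][etaBin[l]];
      for (size_t k = 0; k < fb.size(); ++k) {
        const int f = fb[k];
        const size_t j = (size_t)f * L + l;
        wT[j] -= dw;
        if (sT[j] != 0.0) {
          wsT[j] -= dw;
          for (int m = membStart[f]; m < membStart[f + 1]; ++m)
            G[membPat[m]][(size_t)membSt[m] * L + l] -= dw;
        }
      }
    }
    // v: all fibres active anywhere in the movement, rectified at 0
    const double dv = alpha_v * (double)c;
    const std::vector<int>& ff = flats[mu];
    for (int k = 0; k < nact; ++k) {
      const int f = ff[k];
      const double old = v[f];
      double nv = old + dv;
      if (nv < 0.0) nv = 0.0;
      if (nv != old) {
        v[f] = nv;
        const double delta = nv - old;
        for (int m = membStart[f]; m < membStart[f + 1]; ++m)
          vd[membPat[m]][lno[f] + L * (membSt[m] % T)] += delta;
      }
    }
  }
  NumericMatrix wOut(nfib, L);
  for (int f = 0; f < nfib; ++f)
    for (int l = 0; l < L; ++l) wOut(f, l) = wT[(size_t)f * L + l];
  return List::create(_["error"] = errOut, _["inhibition"] = inhOut,
                      _["ecs"] = ecsOut, _["npert"] = npOut,
                      _["pattern"] = patOut, _["w"] = wOut,
                      _["v"] = NumericVector(v.begin(), v.end()));
}

// Marr-Albus-Ito baseline: same rate equations, broadcast error, no
// perturbations and no nucleo-olivary population.
// [[Rcpp::export]]
List cpp_run_mai(IntegerMatrix act, IntegerMatrix bin,
                 NumericMatrix w0, NumericMatrix sigma,
                 IntegerVector lpn, NumericVector targets,
                 int S, int L, int T, int N,
                 double rmax, double uMPN, double uPCPN,
                 double alpha_w, double beta_w, bool signed_mode,
                 int n_trials) {
  const int nfib = N * S, nact = act.nrow(), p = act.ncol(), nst = S * T;
  std::vector<double> wT((size_t)nfib * L), sT((size_t)nfib * L),
      wsT((size_t)nfib * L);
  for (int f = 0; f < nfib; ++f)
    for (int l = 0; l < L; ++l) {
      wT[(size_t)f * L + l] = w0(f, l);
      sT[(size_t)f * L + l] = sigma(f, l);
      wsT[(size_t)f * L + l] = w0(f, l) * sigma(f, l);
    }
  std::vector<std::vector<int>> flats(p), stIdx(p);
  std::vector<std::vector<double>> cntPN(p, std::vector<double>(L * T, 0.0));
  for (int mu = 0; mu < p; ++mu) {
    flats[mu].resize(nact);
    stIdx[mu].resize(nact);
    for (int k = 0; k < nact; ++k) {
      int f = act(k, mu), b = bin(k, mu), s = f / N;
      flats[mu][k] = f;
      stIdx[mu][k] = s * T + b;
      cntPN[mu][lpn[f] + L * b] += 1.0;
    }
  }
  std::vector<double> G((size_t)nst * L), pcsum(L * T);
  NumericVector errOut(n_trials), uerrOut(n_trials), mpnOut(n_trials);
  const double inv_lt = 1.0 / (double)(L * T);

  for (int tr = 0; tr < n_trials; ++tr) {
    const int mu = tr % p;
    std::fill(G.begin(), G.end(), 0.0);
    const std::vector<int>& ff = flats[mu];
    const std::vector<int>& ss = stIdx[mu];
    for (int k = 0; k < nact; ++k) {
      double* g = &G[(size_t)ss[k] * L];
      const double* wc = &wsT[(size_t)ff[k] * L];
      for (int l = 0; l < L; ++l) g[l] += wc[l];
    }
    std::fill(pcsum.begin(), pcsum.end(), 0.0);
    for (int st = 0; st < nst; ++st) {
      const int t = st % T;
      const double* g = &G[(size_t)st * L];
      for (int l = 0; l < L; ++l) pcsum[l + L * t] += clamp_rate(g[l], rmax);
    }
    double ssum = 0.0, usum = 0.0, pnsum = 0.0;
    const double* tg = &targets[(size_t)mu * L * T];
    for (int j = 0; j < L * T; ++j) {
      double pn = clamp_rate(uMPN * cntPN[mu][j] + uPCPN * pcsum[j], rmax);
      ssum += tg[j] - pn;
      usum += std::abs(pn - tg[j]);
      pnsum += pn;
    }
    const double err = (signed_mode ? ssum : usum) * inv_lt;
    errOut[tr] = err;
    uerrOut[tr] = usum * inv_lt;
    mpnOut[tr] = pnsum * inv_lt;
    if (err > 0.0) {
      for (int k = 0; k < nact; ++k) {
        const size_t base = (size_t)ff[k] * L;
        for (int l = 0; l < L; ++l) {
          wT[base + l] -= alpha_w;
          wsT[base + l] = wT[base + l] * sT[base + l];
        }
      }
    } else {
      const size_t n = (size_t)nfib * L;
      for (size_t j = 0; j < n; ++j) {
        wT[j] += beta_w;
        wsT[j] = wT[j] * sT[j];
      }
    }
  }
  NumericMatrix wOut(nfib, L);
  for (int f = 0; f < nfib; ++f)
    for (int l = 0; l < L; ++l) wOut(f, l) = wT[(size_t)f * L + l];
  return List::create(_["error"] = errOut, _["unsigned"] = uerrOut,
                      _["mean_pn"] = mpnOut, _["w"] = wOut);
}

// Reduced single-cell phase-plane dynamics.
// [[Rcpp::export]]
List cpp_run_reduced(double P0, double J0, double R, double A, double q,
                     double dP, double dJ, LogicalVector perturbed,
                     bool rectify_unperturbed) {
  const int n = perturbed.size();
  NumericVector P(n), J(n);
  IntegerVector cOut(n);
  double Pc = P0, Jc = J0;
  for (int tr = 0; tr < n; ++tr) {
    int c;
    if (perturbed[tr]) {
      double err = std::abs(Pc + A - R);
      double est = Jc - q * (Pc + A);
      if (est < 0.0) est = 0.0;
      c = (err - est > 0.0) ? 1 : -1;
      Pc -= c * dP;
    } else {
      double err = std::abs(Pc - R);
      double est = Jc - q * Pc;
      if (rectify_unperturbed && est < 0.0) est = 0.0;
      c = (err - est > 0.0) ? 1 : -1;
    }
    Jc += c * dJ;
    P[tr] = Pc; J[tr] = Jc; cOut[tr] = c;
  }
  return List::create(_["P"] = P, _["J"] = J, _["c"] = cOut);
}

// Analog perceptron, SGDEGE or delta rule, cyclic presentation.
// act_cat/offsets: concatenated 0-based active-fibre indices per pattern.
// pflags: length n_sweeps*p (sgdege) or empty (delta).
// curve: per sweep, the mean over patterns of the unperturbed pre-update
// error.
// [[Rcpp::export]]
List cpp_run_perceptron(IntegerVector act_cat, IntegerVector offsets,
                        NumericVector R, NumericVector w0, NumericVector v0,
                        double Pmax, double theta, double gamma,
                        double A, double q, double dP, double dJ, double lr,
                        bool sgdege, LogicalVector pflags,
                        int n_sweeps, int p) {
  std::vector<double> w(w0.begin(), w0.end()), v(v0.begin(), v0.end());
  NumericVector curve(n_sweeps);
  for (int sw = 0; sw < n_sweeps; ++sw) {
    double errsum = 0.0;
    for (int mu = 0; mu < p; ++mu) {
      const int a0 = offsets[mu], a1 = offsets[mu + 1], na = a1 - a0;
      double wx = 0.0;
      for (int k = a0; k < a1; ++k) wx += w[act_cat[k]];
      const double Pun = clamp_rate(gamma * (wx - theta), Pmax);
      errsum += std::abs(Pun - R[mu]);
      if (na == 0) continue;
      if (!sgdege) {
        const double step = lr * (R[mu] - Pun) / (gamma * (double)na);
        for (int k = a0; k < a1; ++k) {
          const int i = act_cat[k];
          w[i] += step;
          if (w[i] < 0.0) w[i] = 0.0;
        }
      } else {
        const bool pert = pflags[(size_t)sw * p + mu];
        const double P =
            clamp_rate(gamma * (wx - theta) + (pert ? A : 0.0), Pmax);
        const double err = std::abs(P - R[mu]);
        double vx = 0.0;
        for (int k = a0; k < a1; ++k) vx += v[act_cat[k]];
        double est = vx - q * P;
        if (est < 0.0) est = 0.0;
        const int c = (err - est > 0.0) ? 1 : -1;
        if (pert) {
          const double stepw = c * dP / (gamma * (double)na);
          for (int k = a0; k < a1; ++k) {
            const int i = act_cat[k];
            w[i] -= stepw;
            if (w[i] < 0.0) w[i] = 0.0;
          }
        }
        const double stepv = c * dJ / (double)na;
        for (int k = a0; k < a1; ++k) {
          const int i = act_cat[k];
          v[i] += stepv;
          if (v[i] < 0.0) v[i] = 0.0;
        }
      }
    }
    curve[sw] = errsum / (double)p;
  }
  return List::create(_["curve"] = curve,
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["v"] = NumericVector(v.begin(), v.end()));
}
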