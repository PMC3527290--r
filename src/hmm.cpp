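// Scaled HMM recursions and an event-driven CTMC path sampler.
//
// The forward likelihood over a 3-symbol alphabet exploits run-length
// compression: a run of k identical symbols advances the forward vector by
// the k-th power of the per-symbol update matrix, applied through cached
// binary-power matrices with explicit log-scale bookkeeping.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> vec;

// dest = v * M (n x n row-major); returns sum(dest)
static double vecmat(const vec& v, const vec& M, vec& dest, int n) {
  double s = 0.0;
  for (int j = 0; j < n; ++j) dest[j] = 0.0;
  for (int i = 0; i < n; ++i) {
    double vi = v[i];
    if (vi == 0.0) continue;
    const double* row = &M[(size_t)i * n];
    for (int j = 0; j < n; ++j) dest[j] += vi * row[j];
  }
  for (int j = 0; j < n; ++j) s += dest[j];
  return s;
}

// C = A * B, then normalize by max entry; returns log(max)
static double matmat_norm(const vec& A, const vec& B, vec& C, int n) {
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += A[(size_t)i * n + k] * B[(size_t)k * n + j];
      C[(size_t)i * n + j] = s;
      if (s > mx) mx = s;
    }
  }
  if (mx <= 0.0) stop("forward update matrix vanished");
  for (size_t t = 0; t < C.size(); ++t) C[t] /= mx;
  return std::log(mx);
}

// [[Rcpp::export(name = ".forward_rle_cpp")]]
double forward_rle_cpp(NumericVector pi, NumericMatrix T, NumericMatrix E,
                       IntegerVector run_sym, NumericVector run_len) {
  const int n = pi.size();
  const int n_sym = E.ncol();
  const int n_runs = run_sym.size();
  if (T.nrow() != n || T.ncol() != n || E.nrow() != n)
    stop("dimension mismatch in forward recursion");

  // per-symbol update matrices M_s = T * diag(E[, s]), row-major
  std::vector<vec> M(n_sym, vec((size_t)n * n));
  for (int s = 0; s < n_sym; ++s)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        M[s][(size_t)i * n + j] = T(i, j) * E(j, s);

  double max_run = 0.0;
  for (int r = 0; r < n_runs; ++r) if (run_len[r] > max_run) max_run = run_len[r];
  int levels = 1;
  while (std::pow(2.0, levels) <= max_run) ++levels;

  // cached binary powers with log-scales
  std::vector<std::vector<vec> > pw(n_sym);
  std::vector<std::vector<double> > lsc(n_sym);
  std::vector<bool> built(n_sym, false);
  vec tmp((size_t)n * n);

  vec f(n), g(n);
  double ll = 0.0;
  bool first = true;
  for (int r = 0; r < n_runs; ++r) {
    int s = run_sym[r];
    if (s < 0 || s >= n_sym) stop("symbol code out of range");
    double k = run_len[r];
    if (first) {
      double tot = 0.0;
      for (int i = 0; i < n; ++i) { f[i] = pi[i] * E(i, s); tot += f[i]; }
      if (tot <= 0.0) stop("zero emission probability at first position");
      for (int i = 0; i < n; ++i) f[i] /= tot;
      ll += std::log(tot);
      k -= 1.0;
      first = false;
    }
    if (k <= 0.0) continue;
    if (!built[s]) {
      pw[s].assign(levels, vec());
      lsc[s].assign(levels, 0.0);
      pw[s][0] = M[s];
      double mx = 0.0;
      for (size_t t = 0; t < pw[s][0].size(); ++t)
        if (pw[s][0][t] > mx) mx = pw[s][0][t];
      if (mx <= 0.0) stop("forward update matrix vanished");
      for (size_t t = 0; t < pw[s][0].size(); ++t) pw[s][0][t] /= mx;
      lsc[s][0] = std::log(mx);
      for (int l = 1; l < levels; ++l) {
        pw[s][l].resize((size_t)n * n);
        double lm = matmat_norm(pw[s][l - 1], pw[s][l - 1], pw[s][l], n);
        lsc[s][l] = 2.0 * lsc[s][l - 1] + lm;
      }
      built[s] = true;
    }
    long long kk = (long long)k;
    int bit = 0;
    while (kk > 0) {
      if (kk & 1LL) {
        double tot = vecmat(f, pw[s][bit], g, n);
        if (tot <= 0.0) stop("forward vector vanished");
        for (int i = 0; i < n; ++i) f[i] = g[i] / tot;
        ll += std::log(tot) + lsc[s][bit];
      }
      kk >>= 1;
      ++bit;
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(NumericVector pi, NumericMatrix T, NumericMatrix E,
                          IntegerVector obs) {
  const int n = pi.size();
  const long L = obs.size();
  NumericMatrix fwd(L, n);
  NumericVector scale(L);
  double ll = 0.0;
  for (long t = 0; t < L; ++t) {
    int s = obs[t];
    double tot = 0.0;
    if (t == 0) {
      for (int i = 0; i < n; ++i) { fwd(0, i) = pi[i] * E(i, s); tot += fwd(0, i); }
    } else {
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += fwd(t - 1, i) * T(i, j);
        fwd(t, j) = acc * E(j, s);
        tot += fwd(t, j);
      }
    }
    if (tot <= 0.0) stop("zero total emission probability at position %ld", t + 1);
    for (int i = 0; i < n; ++i) fwd(t, i) /= tot;
    scale[t] = tot;
    ll += std::log(tot);
  }
  // backward pass, reusing the forward scales; gamma overwrites fwd
  vec b(n, 1.0), bn(n);
  for (long t = L - 1; t >= 0; --t) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) { fwd(t, i) *= b[i]; tot += fwd(t, i); }
    for (int i = 0; i < n; ++i) fwd(t, i) /= tot;
    if (t > 0) {
      int s = obs[t];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += T(i, j) * E(j, s) * b[j];
        bn[i] = acc / scale[t];
      }
      b = bn;
    }
  }
  return List::create(_["gamma"] = fwd, _["loglik"] = ll);
}

// Event-driven simulation of the two-nucleotide epoch-switching CTMC.
// Returns per-path left and right coalescence times.
// [[Rcpp::export(name = ".gillespie_paths_cpp")]]
NumericMatrix gillespie_paths_cpp(NumericMatrix Qiso, NumericMatrix Qmig,
                                  NumericMatrix Qanc,
                                  IntegerVector inj, IntegerVector proj,
                                  int init_iso,
                                  LogicalVector ldone_iso, LogicalVector rdone_iso,
                                  LogicalVector ldone_mig, LogicalVector rdone_mig,
                                  LogicalVector ldone_anc, LogicalVector rdone_anc,
                                  double tau1, double tau2, int n_paths) {
  NumericMatrix out(n_paths, 2);
  RNGScope rngScope;
  for (int p = 0; p < n_paths; ++p) {
    int epoch = 0;
    int i = init_iso - 1;
    double t = 0.0, tl = -1.0, tr = -1.0;
    bool ld = false, rd = false;
    while (!(ld && rd)) {
      const NumericMatrix& Q = (epoch == 0) ? Qiso : (epoch == 1 ? Qmig : Qanc);
      double rate = -Q(i, i);
      double bound = (epoch == 0) ? tau1 : (epoch == 1 ? tau2 : R_PosInf);
      double dt = (rate > 0.0) ? ::Rf_rexp(1.0 / rate) : R_PosInf;
      if (t + dt >= bound) {
        t = bound;
        if (epoch == 0) i = inj[i] - 1; else i = proj[i] - 1;
        ++epoch;
        continue;
      }
      t += dt;
      double u = ::unif_rand() * rate;
      double acc = 0.0;
      int j = -1;
      const int n = Q.ncol();
      for (int c = 0; c < n; ++c) {
        if (c == i) continue;
        acc += Q(i, c);
        if (u <= acc) { j = c; break; }
      }
      if (j < 0) continue;  // numerical slack: no jump selected
      i = j;
      bool ld2 = (epoch == 0) ? ldone_iso[i] : (epoch == 1 ? ldone_mig[i] : ldone_anc[i]);
      bool rd2 = (epoch == 0) ? rdone_iso[i] : (epoch == 1 ? rdone_mig[i] : rdone_anc[i]);
      if (ld2 && !ld) { tl = t; ld = true; }
      if (rd2 && !rd) { tr = t; rd = true; }
    }
    out(p, 0) = tl;
    out(p, 1) = tr;
  }
  return out;
}
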