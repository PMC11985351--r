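#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over a K/T/N observation sequence.
//
// obs: 1 = heterozygous window (K), 2 = homozygous (T), 3 = missing (N).
// A: n x n row-stochastic transition matrix; emit: n x 3 with the N column
// identically 1 (missing windows contribute no emission factor).
// seg_starts: 1-based indices where the chain restarts at `init`
// (sequence start and after each contig break).
//
// Returns the total log-likelihood, optionally the per-window posteriors,
// and optionally the expected transition / emission / initial counts needed
// by Baum-Welch.  The inner loops run on raw row-major copies of A (and of
// A pre-multiplied by each symbol's emission column) for cache locality.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(IntegerVector obs, NumericMatrix A, NumericMatrix emit,
             NumericVector init, IntegerVector seg_starts,
             bool want_post, bool want_counts) {
  const int T = obs.size();
  const int n = A.nrow();
  if (A.ncol() != n || emit.nrow() != n || init.size() != n)
    stop("dimension mismatch in forward-backward inputs");

  std::vector<bool> is_start(T, false);
  for (int k = 0; k < seg_starts.size(); ++k) {
    int s = seg_starts[k] - 1;
    if (s < 0 || s >= T) stop("segment start out of range");
    is_start[s] = true;
  }
  if (T > 0 && !is_start[0]) stop("first window must be a segment start");

  // column-major copy of A (for the forward recursion: dot over rows) and
  // row-major A*emit products per symbol (for backward/counts)
  std::vector<double> Acol((size_t)n * n), Me(3 * (size_t)n * n);
  std::vector<double> em(3 * (size_t)n);
  for (int c = 0; c < 3; ++c)
    for (int s = 0; s < n; ++s) em[(size_t)c * n + s] = emit(s, c);
  for (int r = 0; r < n; ++r)
    for (int s = 0; s < n; ++s) {
      const double a = A(r, s);
      Acol[(size_t)s * n + r] = a;
      for (int c = 0; c < 3; ++c)
        Me[(size_t)c * n * n + (size_t)r * n + s] = a * em[(size_t)c * n + s];
    }

  std::vector<double> alpha((size_t)n * T);
  std::vector<double> scale(T);

  // forward
  for (int i = 0; i < T; ++i) {
    double *ai = &alpha[(size_t)n * i];
    const int sym = obs[i] - 1;
    if (sym < 0 || sym > 2) stop("illegal observation symbol at window %d", i + 1);
    const double *es = &em[(size_t)sym * n];
    if (is_start[i]) {
      for (int s = 0; s < n; ++s) ai[s] = init[s] * es[s];
    } else {
      const double *ap = &alpha[(size_t)n * (i - 1)];
      for (int s = 0; s < n; ++s) {
        const double *col = &Acol[(size_t)s * n];
        double acc = 0.0;
        for (int r = 0; r < n; ++r) acc += ap[r] * col[r];
        ai[s] = acc * es[s];
      }
    }
    double c = 0.0;
    for (int s = 0; s < n; ++s) c += ai[s];
    if (!(c > 0.0))
      stop("zero-probability observation sequence at window %d", i + 1);
    scale[i] = c;
    const double inv = 1.0 / c;
    for (int s = 0; s < n; ++s) ai[s] *= inv;
  }

  double loglik = 0.0;
  for (int i = 0; i < T; ++i) loglik += std::log(scale[i]);

  NumericMatrix post;
  std::vector<double> tc;
  NumericMatrix ec;
  NumericVector ic;
  if (want_post) post = NumericMatrix(n, T);
  if (want_counts) {
    tc.assign((size_t)n * n, 0.0);
    ec = NumericMatrix(n, 3);
    ic = NumericVector(n);
  }

  // backward, accumulating posteriors and expected counts
  std::vector<double> beta(n, 1.0), beta_prev(n), ebeta(n);
  for (int i = T - 1; i >= 0; --i) {
    const bool last_of_seg = (i == T - 1) || is_start[i + 1];
    if (last_of_seg) {
      for (int s = 0; s < n; ++s) beta[s] = 1.0;
    } else {
      const int sym = obs[i + 1] - 1;
      const double cinv = 1.0 / scale[i + 1];
      const double *es = &em[(size_t)sym * n];
      for (int s = 0; s < n; ++s) {
        beta_prev[s] = beta[s];
        ebeta[s] = es[s] * beta[s] * cinv;
      }
      const double *M = &Me[(size_t)sym * n * n];
      const double *ai = &alpha[(size_t)n * i];
      for (int r = 0; r < n; ++r) {
        const double *Ar = &Acol[0]; (void)Ar;
        const double *Mr = &M[(size_t)r * n];
        double acc = 0.0;
        if (want_counts) {
          double *tr = &tc[(size_t)r * n];
          const double fr = ai[r];
          for (int s = 0; s < n; ++s) {
            const double term = Mr[s] * beta_prev[s];
            acc += term;
            tr[s] += fr * term * cinv;
          }
        } else {
          for (int s = 0; s < n; ++s) acc += Mr[s] * beta_prev[s];
        }
        beta[r] = acc * cinv;
      }
    }
    const double *ai = &alpha[(size_t)n * i];
    const int sym = obs[i] - 1;
    for (int s = 0; s < n; ++s) {
      const double p = ai[s] * beta[s];
      if (want_post) post(s, i) = p;
      if (want_counts) {
        ec(s, sym) += p;
        if (is_start[i]) ic[s] += p;
      }
    }
  }

  List out = List::create(_["loglik"] = loglik);
  if (want_post) out["posterior"] = post;
  if (want_counts) {
    NumericMatrix tcm(n, n);
    for (int r = 0; r < n; ++r)
      for (int s = 0; s < n; ++s) tcm(r, s) = tc[(size_t)r * n + s];
    out["trans_counts"] = tcm;
    out["emit_counts"] = ec;
    out["init_counts"] = ic;
  }
  return out;
}

// Forward-only log-likelihood (no alpha matrix kept).
// [[Rcpp::export(name = ".forward_loglik")]]
double forward_loglik(IntegerVector obs, NumericMatrix A, NumericMatrix emit,
                      NumericVector init, IntegerVector seg_starts) {
  const int T = obs.size();
  const int n = A.nrow();
  std::vector<bool> is_start(T, false);
  for (int k = 0; k < seg_starts.size(); ++k) is_start[seg_starts[k] - 1] = true;
  std::vector<double> Acol((size_t)n * n), em(3 * (size_t)n);
  for (int c = 0; c < 3; ++c)
    for (int s = 0; s < n; ++s) em[(size_t)c * n + s] = emit(s, c);
  for (int r = 0; r < n; ++r)
    for (int s = 0; s < n; ++s) Acol[(size_t)s * n + r] = A(r, s);
  std::vector<double> a(n), anew(n);
  double loglik = 0.0;
  for (int i = 0; i < T; ++i) {
    const int sym = obs[i] - 1;
    if (sym < 0 || sym > 2) stop("illegal observation symbol at window %d", i + 1);
    const double *es = &em[(size_t)sym * n];
    if (is_start[i]) {
      for (int s = 0; s < n; ++s) anew[s] = init[s] * es[s];
    } else {
      for (int s = 0; s < n; ++s) {
        const double *col = &Acol[(size_t)s * n];
        double acc = 0.0;
        for (int r = 0; r < n; ++r) acc += a[r] * col[r];
        anew[s] = acc * es[s];
      }
    }
    double c = 0.0;
    for (int s = 0; s < n; ++s) c += anew[s];
    if (!(c > 0.0))
      stop("zero-probability observation sequence at window %d", i + 1);
    loglik += std::log(c);
    const double inv = 1.0 / c;
    for (int s = 0; s < n; ++s) a[s] = anew[s] * inv;
  }
  return loglik;
}

// Sample a hidden-state path and K/T symbols from the discretized HMM.
// Uses R's RNG so results are reproducible via set.seed().
// pK: per-state probability of a heterozygous window.
// [[Rcpp::export(name = ".sim_chain")]]
List sim_chain(NumericMatrix A, NumericVector pK, NumericVector init,
               int n_windows) {
  const int n = A.nrow();
  IntegerVector states(n_windows), symbols(n_windows);
  // per-row cumulative transition distributions (row-major)
  std::vector<double> cumA((size_t)n * n);
  for (int r = 0; r < n; ++r) {
    double acc = 0.0;
    for (int s = 0; s < n; ++s) { acc += A(r, s); cumA[(size_t)r * n + s] = acc; }
  }
  std::vector<double> cumI(n);
  double acc = 0.0;
  for (int s = 0; s < n; ++s) { acc += init[s]; cumI[s] = acc; }

  int cur = 0;
  for (int i = 0; i < n_windows; ++i) {
    const double u = unif_rand();
    if (i == 0) {
      cur = std::lower_bound(cumI.begin(), cumI.end(), u * cumI[n - 1]) -
            cumI.begin();
    } else {
      const double *row = &cumA[(size_t)cur * n];
      const double target = u * row[n - 1];
      int s = 0;
      while (s < n - 1 && row[s] < target) ++s;
      cur = s;
    }
    states[i] = cur + 1;
    symbols[i] = (unif_rand() < pK[cur]) ? 1 : 2;
  }
  return List::create(_["states"] = states, _["symbols"] = symbols);
}

// Closed-form P(new TMRCA in each interval) for one recombination scenario:
// piecewise-constant rate lam over the grid intervals, breakpoint u uniform
// on (u0, u1) with u0 on a boundary. Mirrors the derivation in
// R/transitions.R (the R reference implementation .scenario_pvec_r).
// [[Rcpp::export(name = ".scenario_pvec_cpp")]]
NumericVector scenario_pvec_cpp(NumericVector boundaries, NumericVector lam,
                                double u0, double u1) {
  const int n = lam.size();
  const double *b = boundaries.begin();
  NumericVector out(n);
  // cumulative hazard at boundaries
  std::vector<double> Lam(n + 1);
  Lam[0] = 0.0;
  for (int j = 0; j < n; ++j) {
    const double w = b[j + 1] - b[j];
    Lam[j + 1] = Lam[j] + lam[j] * w;   // last may be Inf
  }
  // C(y) recurrence from u0
  int j0 = -1;
  for (int j = 0; j < n; ++j) if (b[j] == u0) { j0 = j; break; }
  if (j0 < 0) stop("internal: u0 is not a grid boundary");
  int ju = n - 1;
  for (int j = 0; j < n; ++j) {
    if (u1 < b[j + 1]) { ju = j; break; }
  }
  std::vector<double> Cb(n, 0.0);
  for (int j = j0; j < ju; ++j) {
    const double w = b[j + 1] - b[j];
    const double dl = lam[j] * w;
    Cb[j + 1] = (lam[j] > 0.0)
      ? Cb[j] * std::exp(-dl) + (-std::expm1(-dl)) / lam[j]
      : Cb[j] + w;
  }
  const double rem = u1 - b[ju];
  double I_total, Lam_u1;
  if (rem > 0.0) {
    const double dl = lam[ju] * rem;
    I_total = (lam[ju] > 0.0)
      ? Cb[ju] * std::exp(-dl) + (-std::expm1(-dl)) / lam[ju]
      : Cb[ju] + rem;
    Lam_u1 = Lam[ju] + dl;
  } else {
    I_total = Cb[ju];
    Lam_u1 = Lam[ju];
  }
  const double invlen = 1.0 / (u1 - u0);
  for (int a = 0; a < n; ++a) {
    const double lo = b[a], hi = b[a + 1];
    const double dLam = lam[a] * (hi - lo);   // may be Inf for a == n-1
    double Jint = 0.0;
    if (lo >= u1) Jint = I_total * std::exp(Lam_u1 - Lam[a]);
    else if (lo > u0) Jint = Cb[a];
    double w1 = Jint * (-std::expm1(-dLam));
    // u inside the interval
    const double x2 = std::max(u0, lo), y2 = std::min(u1, hi);
    double w2 = 0.0;
    if (y2 > x2 && lam[a] > 0.0) {
      const double tail = (std::isfinite(hi)) ? lam[a] * (hi - y2) : INFINITY;
      w2 = (y2 - x2) -
        std::exp(-tail) * (-std::expm1(-lam[a] * (y2 - x2))) / lam[a];
    }
    out[a] = (w1 + w2) * invlen;
  }
  return out;
}

// -- full marginal transition kernel ----------------------------------------
// Compiled construction of the time-only conditional kernel; mirrors the
// scenario enumeration in R/transitions.R (kernel_scenarios +
// .marginal_kernel_row), which serves as the readable reference and is
// cross-checked against this in the test suite.

static void pvec_accum(const double *b, const double *lam, int n,
                       double u0, double u1, double w, double *out) {
  if (!(w > 0.0) || !(u1 > u0)) return;
  // cumulative hazard at boundaries
  std::vector<double> Lam(n + 1);
  Lam[0] = 0.0;
  for (int j = 0; j < n; ++j) Lam[j + 1] = Lam[j] + lam[j] * (b[j + 1] - b[j]);
  int j0 = -1;
  for (int j = 0; j < n; ++j) if (b[j] == u0) { j0 = j; break; }
  if (j0 < 0) stop("internal: u0 is not a grid boundary");
  int ju = n - 1;
  for (int j = 0; j < n; ++j) if (u1 < b[j + 1]) { ju = j; break; }
  std::vector<double> Cb(n, 0.0);
  for (int j = j0; j < ju; ++j) {
    const double wd = b[j + 1] - b[j];
    const double dl = lam[j] * wd;
    Cb[j + 1] = (lam[j] > 0.0)
      ? Cb[j] * std::exp(-dl) + (-std::expm1(-dl)) / lam[j]
      : Cb[j] + wd;
  }
  const double rem = u1 - b[ju];
  double I_total, Lam_u1;
  if (rem > 0.0) {
    const double dl = lam[ju] * rem;
    I_total = (lam[ju] > 0.0)
      ? Cb[ju] * std::exp(-dl) + (-std::expm1(-dl)) / lam[ju]
      : Cb[ju] + rem;
    Lam_u1 = Lam[ju] + dl;
  } else {
    I_total = Cb[ju];
    Lam_u1 = Lam[ju];
  }
  const double scale = w / (u1 - u0);
  for (int a = 0; a < n; ++a) {
    const double lo = b[a], hi = b[a + 1];
    const double dLam = lam[a] * (hi - lo);
    double Jint = 0.0;
    if (lo >= u1) Jint = I_total * std::exp(Lam_u1 - Lam[a]);
    else if (lo > u0) Jint = Cb[a];
    double acc = Jint * (-std::expm1(-dLam));
    const double x2 = std::max(u0, lo), y2 = std::min(u1, hi);
    if (y2 > x2 && lam[a] > 0.0) {
      const double tail = std::isfinite(hi) ? lam[a] * (hi - y2) : INFINITY;
      acc += (y2 - x2) -
        std::exp(-tail) * (-std::expm1(-lam[a] * (y2 - x2))) / lam[a];
    }
    out[a] += scale * acc;
  }
}

// rate_A: 1/n_A per interval; rate_B: 1/n_B per structured interval
// (i1 <= j < i2, 1-based boundary indices); gamma: pulse fraction;
// i1 = i2 = 0 requests the unstructured kernel (rate_A only).
// [[Rcpp::export(name = ".marginal_kernel_cpp")]]
NumericMatrix marginal_kernel_cpp(NumericVector boundaries,
                                  NumericVector rate_A, NumericVector rate_B,
                                  double gamma, int i1, int i2,
                                  NumericVector t_bar) {
  const int n = rate_A.size();
  const double *b = boundaries.begin();
  NumericMatrix q(n, n);
  std::vector<double> LA(rate_A.begin(), rate_A.end());
  // NumericMatrix storage is column-major; accumulate each row in a buffer
  std::vector<double> row(n);
  const double g = gamma;
  std::vector<double> LB(LA), LM(LA);
  double T1 = 0, T2 = 0;
  std::vector<double> HA, HB, HM;
  if (i1 > 0) {
    for (int j = i1 - 1; j < i2 - 1; ++j) {
      LB[j] = rate_B[j - (i1 - 1)];
      LM[j] = 0.0;
    }
    T1 = b[i1 - 1];
    T2 = b[i2 - 1];
    HA.assign(n + 1, 0.0); HB.assign(n + 1, 0.0); HM.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      const double wd = b[j + 1] - b[j];
      HA[j + 1] = HA[j] + LA[j] * wd;
      HB[j + 1] = HB[j] + LB[j] * wd;
      HM[j + 1] = HM[j] + LM[j] * wd;
    }
  }
  for (int r = 0; r < n; ++r) {
    std::fill(row.begin(), row.end(), 0.0);
    const double t = t_bar[r];
    if (i1 == 0) {
      pvec_accum(b, LA.data(), n, 0.0, t, 1.0, row.data());
    } else if (t < T1) {
      pvec_accum(b, LA.data(), n, 0.0, t, (1 - g) * (1 - g), row.data());
      pvec_accum(b, LB.data(), n, 0.0, t, g * g, row.data());
      pvec_accum(b, LM.data(), n, 0.0, t, 2 * g * (1 - g), row.data());
    } else if (t < T2) {
      // posterior over the pair's deme given coalescence at t (log-space)
      const int j = r;  // t_bar[r] lies in interval r
      const double lHA = HA[j] + LA[j] * (t - b[j]);
      const double lHB = HB[j] + LB[j] * (t - b[j]);
      double lwA = std::log((1 - g) * (1 - g)) + std::log(LA[j]) - lHA;
      double lwB = std::log(g * g) + std::log(LB[j]) - lHB;
      const double mx = std::max(lwA, lwB);
      double wA = std::isfinite(lwA) ? std::exp(lwA - mx) : 0.0;
      double wB = std::isfinite(lwB) ? std::exp(lwB - mx) : 0.0;
      const double tot = wA + wB;
      wA /= tot; wB /= tot;
      const double s1 = T1 / t, s2 = (t - T1) / t;
      if (wA > 0) {
        pvec_accum(b, LA.data(), n, 0.0, T1, wA * s1 * (1 - g), row.data());
        pvec_accum(b, LM.data(), n, 0.0, T1, wA * s1 * g, row.data());
        pvec_accum(b, LA.data(), n, T1, t, wA * s2, row.data());
      }
      if (wB > 0) {
        pvec_accum(b, LM.data(), n, 0.0, T1, wB * s1 * (1 - g), row.data());
        pvec_accum(b, LB.data(), n, 0.0, T1, wB * s1 * g, row.data());
        pvec_accum(b, LB.data(), n, T1, t, wB * s2, row.data());
      }
    } else {
      // posterior over path components given t >= T2: the post-T2 hazard is
      // common, so only survival through [T1, T2) differentiates them
      const int k2 = i2 - 1;
      double lwAA = std::log((1 - g) * (1 - g)) - HA[k2];
      double lwBB = std::log(g * g) - HB[k2];
      double lwAB = std::log(2 * g * (1 - g)) - HM[k2];
      double mx = std::max(lwAA, std::max(lwBB, lwAB));
      double wAA = std::isfinite(lwAA) ? std::exp(lwAA - mx) : 0.0;
      double wBB = std::isfinite(lwBB) ? std::exp(lwBB - mx) : 0.0;
      double wAB = std::isfinite(lwAB) ? std::exp(lwAB - mx) : 0.0;
      const double tot = wAA + wBB + wAB;
      wAA /= tot; wBB /= tot; wAB /= tot;
      const double s1 = T1 / t, s2 = (T2 - T1) / t, s3 = (t - T2) / t;
      if (wAA > 0) {
        pvec_accum(b, LA.data(), n, 0.0, T1, wAA * s1 * (1 - g), row.data());
        pvec_accum(b, LM.data(), n, 0.0, T1, wAA * s1 * g, row.data());
        pvec_accum(b, LA.data(), n, T1, T2, wAA * s2, row.data());
        pvec_accum(b, LM.data(), n, T2, t, wAA * s3, row.data());
      }
      if (wBB > 0) {
        pvec_accum(b, LM.data(), n, 0.0, T1, wBB * s1 * (1 - g), row.data());
        pvec_accum(b, LB.data(), n, 0.0, T1, wBB * s1 * g, row.data());
        pvec_accum(b, LB.data(), n, T1, T2, wBB * s2, row.data());
        pvec_accum(b, LM.data(), n, T2, t, wBB * s3, row.data());
      }
      if (wAB > 0) {
        // broken branch A / target B, and the mirror image, each 1/2
        pvec_accum(b, LM.data(), n, 0.0, T1, wAB * 0.5 * s1 * (1 - g), row.data());
        pvec_accum(b, LB.data(), n, 0.0, T1, wAB * 0.5 * s1 * g, row.data());
        pvec_accum(b, LA.data(), n, 0.0, T1, wAB * 0.5 * s1 * (1 - g), row.data());
        pvec_accum(b, LM.data(), n, 0.0, T1, wAB * 0.5 * s1 * g, row.data());
        pvec_accum(b, LM.data(), n, T1, T2, wAB * s2, row.data());
        pvec_accum(b, LM.data(), n, T2, t, wAB * s3, row.data());
      }
    }
    double rs = 0.0;
    for (int a = 0; a < n; ++a) rs += row[a];
    for (int a = 0; a < n; ++a) q(r, a) = row[a] / rs;
  }
  return q;
}
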