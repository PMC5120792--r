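#include <Rcpp.h>
using namespace Rcpp;

// MLSA (Mel Log Spectrum Approximation) filter, sample-by-sample.
//
// The transfer function exp(sum_m c(m) zt^-m), zt^-1 = (z^-1 - a)/(1 - a z^-1),
// is rewritten on the filter basis b = mc2b(c):
//   H(z) = exp(b0) * exp(b1*Phi1(z)) * exp(sum_{m>=2} b_m*Phi_m(z)),
//   Phi_1(z)   = (1-a^2) z^-1 / (1 - a z^-1),
//   Phi_m(z)   = Phi_1(z) * zt^-(m-1).
// Each exponential stage is realised by the order-L Pade rational
// approximation R_L(F) = P(F)/P(-F), P(w) = 1 + sum_l A_l w^l, in the
// canonical feedback ladder: with s = u / P(-F) and p_l = F^l s,
//   s = u + sum_l (-1)^(l+1) A_l p_l,   y = s + sum_l A_l p_l.
// All basic filters F are strictly proper (every Phi carries z^-1), so each
// p_l(t) is computable from states before feeding the current inputs back.

// ---- basic filter F2 = sum_{m=2..M} b_m Phi_m -------------------------------
// state layout per instance: st[0] = x_prev, st[m] = e_prev[m], m = 1..M
// (M+1 doubles per instance)
static inline double f2_output(const double *st, const double *b, int M,
                               double a, double *e_cur) {
  const double aa = 1.0 - a * a;
  // e_1(t) = (1-a^2) x(t-1) + a e_1(t-1)
  e_cur[1] = aa * st[0] + a * st[1];
  double y = 0.0;
  for (int m = 2; m <= M; ++m) {
    // zt^-1: e_m(t) = e_{m-1}(t-1) - a e_{m-1}(t) + a e_m(t-1)
    e_cur[m] = st[m - 1] - a * e_cur[m - 1] + a * st[m];
    y += b[m] * e_cur[m];
  }
  return y;
}

// ---- basic filter F1 = b1 * Phi1 -------------------------------------------
// state layout per instance: [x_prev, phi_prev]  (2 doubles)
static inline double f1_output(const double *st, double b1, double a,
                               double *phi_cur) {
  const double aa = 1.0 - a * a;
  *phi_cur = aa * st[0] + a * st[1];
  return b1 * (*phi_cur);
}

// One Pade exp-stage built on F1. st: L instances x 2 doubles.
static inline double pade_stage1(double u, double b1, double a,
                                 const NumericVector &A, double *st) {
  const int L = A.size();
  double o[8], phi[8];
  for (int l = 0; l < L; ++l) o[l] = f1_output(st + 2 * l, b1, a, &phi[l]);
  double s = u, y = 0.0;
  for (int l = 0; l < L; ++l) {
    const double v = A[l] * o[l];
    s += ((l + 1) % 2 == 1) ? v : -v;
    y += v;
  }
  y += s;
  // push inputs: instance 0 <- s, instance l <- o_{l-1}
  for (int l = L - 1; l >= 1; --l) {
    st[2 * l] = o[l - 1];
    st[2 * l + 1] = phi[l];
  }
  st[0] = s;
  st[1] = phi[0];
  return y;
}

// One Pade exp-stage built on F2. st: L instances x (M+1) doubles.
static inline double pade_stage2(double u, const double *b, int M, double a,
                                 const NumericVector &A, double *st,
                                 double *scratch) {
  const int L = A.size();
  const int w = M + 1;
  double o[8];
  // scratch: L x (M+1) current e values
  for (int l = 0; l < L; ++l)
    o[l] = f2_output(st + w * l, b, M, a, scratch + (M + 1) * l);
  double s = u, y = 0.0;
  for (int l = 0; l < L; ++l) {
    const double v = A[l] * o[l];
    s += ((l + 1) % 2 == 1) ? v : -v;
    y += v;
  }
  y += s;
  for (int l = L - 1; l >= 0; --l) {
    double *stl = st + w * l;
    const double xin = (l == 0) ? s : o[l - 1];
    const double *e = scratch + (M + 1) * l;
    stl[0] = xin;
    for (int m = 1; m <= M; ++m) stl[m] = e[m];
  }
  return y;
}

// Run one frame (hop samples) of MLSA filtering with per-sample linear
// interpolation of the filter coefficients from b_from to b_to.
// b vectors have length M+1 (b[0] = log gain). state is modified in place.
// inverse = true applies 1/H (negated coefficients, stages in reverse order).
// [[Rcpp::export]]
NumericVector mlsa_step_cpp(NumericVector x, NumericVector b_from,
                            NumericVector b_to, double alpha,
                            NumericVector pade, bool inverse,
                            NumericVector state) {
  const int n = x.size();
  const int M = b_from.size() - 1;
  const int L = pade.size();
  if (L > 8) stop("Pade order too large (max 8)");
  if (b_to.size() != b_from.size()) stop("coefficient length mismatch");
  const int n1 = 2 * L;            // stage-1 state size
  const int n2 = L * (M + 1);      // stage-2 state size
  if (state.size() != n1 + n2) stop("bad filter state size");

  NumericVector y(n);
  std::vector<double> b(M + 1), scratch((M + 1) * L);
  double *st1 = REAL(state);
  double *st2 = REAL(state) + n1;

  for (int j = 0; j < n; ++j) {
    const double w = (double)(j + 1) / n;
    for (int m = 0; m <= M; ++m)
      b[m] = b_from[m] + w * (b_to[m] - b_from[m]);
    double v;
    if (!inverse) {
      v = pade_stage1(x[j], b[1], alpha, pade, st1);
      v = pade_stage2(v, b.data(), M, alpha, pade, st2, scratch.data());
      y[j] = std::exp(b[0]) * v;
    } else {
      std::vector<double> nb(M + 1);
      for (int m = 0; m <= M; ++m) nb[m] = -b[m];
      v = x[j] * std::exp(-b[0]);
      v = pade_stage2(v, nb.data(), M, alpha, pade, st2, scratch.data());
      v = pade_stage1(v, -b[1], alpha, pade, st1);
      y[j] = v;
    }
  }
  return y;
}
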