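#include <Rcpp.h>
using namespace Rcpp;

// Multi-head decay-aware attention over precomputed neighbor pairs.
//
// Matrices are passed transposed (D x n, one contiguous column per node) so
// each head block is a contiguous slice. Pairs (ii[e], jj[e]) must be sorted
// by ii (contiguous segments per target node). phi[e] = exp(-lambda * d_e).
// For each head (block of hd = D / n_heads rows):
//   logit_e = phi_e * <Qt[, i] block, Kt[, j] block>
//   alpha   = softmax of logit within the segment of node i
//   Ot[, i] block = sum_e alpha_e * Vt[, j] block
// Returns Ot plus the per-pair alpha and raw dot products for the backward
// pass.

// [[Rcpp::export(name = ".attn_forward")]]
List attn_forward(NumericMatrix Qt, NumericMatrix Kt, NumericMatrix Vt,
                  IntegerVector ii, IntegerVector jj, NumericVector phi,
                  int n, int n_heads) {
  const int E = ii.size();
  const int D = Qt.nrow();
  const int hd = D / n_heads;
  NumericMatrix Ot(D, n);
  NumericMatrix alpha(std::max(E, 1), n_heads);
  NumericMatrix qdot(std::max(E, 1), n_heads);
  if (E == 0) return List::create(_["O"] = Ot, _["alpha"] = alpha, _["qdot"] = qdot);

  const double *q = REAL(Qt), *k = REAL(Kt), *v = REAL(Vt);
  double *o = REAL(Ot);
  const int *pi = INTEGER(ii), *pj = INTEGER(jj);
  const double *ph = REAL(phi);
  std::vector<double> logit(E);

  for (int h = 0; h < n_heads; ++h) {
    const int c0 = h * hd;
    double *al = REAL(alpha) + (R_xlen_t)h * std::max(E, 1);
    double *qd = REAL(qdot) + (R_xlen_t)h * std::max(E, 1);
    for (int e = 0; e < E; ++e) {
      const double *qi = q + (R_xlen_t)(pi[e] - 1) * D + c0;
      const double *kj = k + (R_xlen_t)(pj[e] - 1) * D + c0;
      double s = 0.0;
      for (int c = 0; c < hd; ++c) s += qi[c] * kj[c];
      qd[e] = s;
      logit[e] = ph[e] * s;
    }
    int s0 = 0;
    while (s0 < E) {
      int s1 = s0;
      while (s1 < E && pi[s1] == pi[s0]) ++s1;
      double mx = logit[s0];
      for (int e = s0 + 1; e < s1; ++e) if (logit[e] > mx) mx = logit[e];
      double tot = 0.0;
      for (int e = s0; e < s1; ++e) { al[e] = std::exp(logit[e] - mx); tot += al[e]; }
      double *oi = o + (R_xlen_t)(pi[s0] - 1) * D + c0;
      for (int e = s0; e < s1; ++e) {
        al[e] /= tot;
        const double *vj = v + (R_xlen_t)(pj[e] - 1) * D + c0;
        const double a = al[e];
        for (int c = 0; c < hd; ++c) oi[c] += a * vj[c];
      }
      s0 = s1;
    }
  }
  return List::create(_["O"] = Ot, _["alpha"] = alpha, _["qdot"] = qdot);
}

// Backward pass of attn_forward. dOt is the gradient at Ot (D x n); returns
// gradients for Qt, Kt, Vt (D x n) and for the decay coefficient lambda
// (phi_e = exp(-lambda d_e), so d phi_e / d lambda = -d_e phi_e).

// [[Rcpp::export(name = ".attn_backward")]]
List attn_backward(NumericMatrix Qt, NumericMatrix Kt, NumericMatrix Vt,
                   IntegerVector ii, IntegerVector jj, NumericVector phi,
                   NumericVector dist, NumericMatrix alpha, NumericMatrix qdot,
                   NumericMatrix dOt, int n_heads) {
  const int E = ii.size();
  const int D = Qt.nrow();
  const int n = Qt.ncol();
  const int hd = D / n_heads;
  NumericMatrix dQt(D, n), dKt(D, n), dVt(D, n);
  double dlambda = 0.0;
  if (E == 0)
    return List::create(_["dQ"] = dQt, _["dK"] = dKt, _["dV"] = dVt,
                        _["dlambda"] = dlambda);

  const double *q = REAL(Qt), *k = REAL(Kt), *v = REAL(Vt), *go = REAL(dOt);
  double *gq = REAL(dQt), *gk = REAL(dKt), *gv = REAL(dVt);
  const int *pi = INTEGER(ii), *pj = INTEGER(jj);
  const double *ph = REAL(phi), *pd = REAL(dist);
  std::vector<double> da(E), dl(E);

  for (int h = 0; h < n_heads; ++h) {
    const int c0 = h * hd;
    const double *al = REAL(alpha) + (R_xlen_t)h * std::max(E, 1);
    const double *qd = REAL(qdot) + (R_xlen_t)h * std::max(E, 1);
    for (int e = 0; e < E; ++e) {
      const double *goi = go + (R_xlen_t)(pi[e] - 1) * D + c0;
      const double *vj = v + (R_xlen_t)(pj[e] - 1) * D + c0;
      double *gvj = gv + (R_xlen_t)(pj[e] - 1) * D + c0;
      const double a = al[e];
      double s = 0.0;
      for (int c = 0; c < hd; ++c) {
        s += goi[c] * vj[c];
        gvj[c] += a * goi[c];
      }
      da[e] = s;
    }
    int s0 = 0;
    while (s0 < E) {
      int s1 = s0;
      while (s1 < E && pi[s1] == pi[s0]) ++s1;
      double sg = 0.0;
      for (int e = s0; e < s1; ++e) sg += al[e] * da[e];
      for (int e = s0; e < s1; ++e) dl[e] = al[e] * (da[e] - sg);
      s0 = s1;
    }
    for (int e = 0; e < E; ++e) {
      const double dqv = dl[e] * ph[e];
      dlambda += dl[e] * qd[e] * (-pd[e]) * ph[e];
      const double *qi = q + (R_xlen_t)(pi[e] - 1) * D + c0;
      const double *kj = k + (R_xlen_t)(pj[e] - 1) * D + c0;
      double *gqi = gq + (R_xlen_t)(pi[e] - 1) * D + c0;
      double *gkj = gk + (R_xlen_t)(pj[e] - 1) * D + c0;
      for (int c = 0; c < hd; ++c) {
        gqi[c] += dqv * kj[c];
        gkj[c] += dqv * qi[c];
      }
    }
  }
  return List::create(_["dQ"] = dQt, _["dK"] = dKt, _["dV"] = dVt,
                      _["dlambda"] = dlambda);
}
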