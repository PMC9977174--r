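#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial likelihood kernels shared by the reference MLE and
// the spot-level MAP fit. Both objectives reduce to sums over (gene,
// unit) pairs of
//   lgamma(x + r) - lgamma(r) + r * log(1 - p)
// and their gradients need digamma(x + r) - digamma(r). For integer x
// these differences telescope:
//   lgamma(x + r) - lgamma(r)  = sum_{j=0}^{x-1} log(r + j)
//   digamma(x + r) - digamma(r) = sum_{j=0}^{x-1} 1 / (r + j)
// which is cheaper than two special-function calls for small counts;
// large counts fall back to the special functions. Both branches are
// exact.

static inline double lgamma_diff(int x, double r) {
  if (x == 0) return 0.0;
  if (x <= 6) {
    double s = 0.0;
    for (int j = 0; j < x; ++j) s += std::log(r + j);
    return s;
  }
  return R::lgammafn(x + r) - R::lgammafn(r);
}

static inline double digamma_diff(int x, double r) {
  if (x == 0) return 0.0;
  if (x <= 8) {
    double s0 = 0.0, s1 = 0.0;
    int j = 0;
    for (; j + 1 < x; j += 2) {
      s0 += 1.0 / (r + j);
      s1 += 1.0 / (r + j + 1);
    }
    if (j < x) s0 += 1.0 / (r + j);
    return s0 + s1;
  }
  return R::digamma(x + r) - R::digamma(r);
}

// Reference model: counts X (genes x cells), NB size r = S_c *
// sp_theta[g, z_c]. Returns the count-dependent part of the
// log-likelihood plus the r * log(1-p) term, the unscaled theta
// gradient (to be multiplied by d softplus / d theta in R) and the
// row sums of r (for the dispersion gradient).
// [[Rcpp::export]]
List ref_nb_kernel(NumericMatrix sp_theta, IntegerVector zc,
                   NumericVector S, IntegerMatrix X,
                   NumericVector log_1mp) {
  const int G = X.nrow(), C = X.ncol();
  double obj = 0.0;
  NumericMatrix g_theta(G, sp_theta.ncol());
  NumericVector rs_r(G);
  for (int c = 0; c < C; ++c) {
    const int z = zc[c] - 1;
    const double Sc = S[c];
    for (int g = 0; g < G; ++g) {
      const double r = Sc * sp_theta(g, z);
      const int x = X(g, c);
      obj += lgamma_diff(x, r) + r * log_1mp[g];
      g_theta(g, z) += (digamma_diff(x, r) + log_1mp[g]) * Sc;
      rs_r[g] += r;
    }
  }
  return List::create(_["objective"] = obj, _["g_theta"] = g_theta,
                      _["rs_r"] = rs_r);
}

// Spot model: counts X (genes x spots), NB size
// R_sg = sum_z bM_l(g, z) * n(s, z) with bM_l = beta * softplus(theta +
// T_l) for the spot's layer l. `bM` and `bsig` (beta * sigmoid(theta +
// T_l), the dT derivative factor) are lists with one genes x types
// matrix per layer. Returns the count-dependent objective part and raw
// gradients for n (spots x types), T (layers x genes) and log-beta.
// [[Rcpp::export]]
List spatial_nb_kernel(NumericMatrix n, List bM, List bsig,
                       IntegerVector layer, IntegerMatrix X,
                       NumericVector log_1mp) {
  const int G = X.nrow(), S = X.ncol(), Z = n.ncol();
  const int L = bM.size();
  double obj = 0.0;
  NumericMatrix g_n(S, Z), g_T(L, G);
  NumericVector g_b(G);
  std::vector<NumericMatrix> bMv, bsigv;
  for (int l = 0; l < L; ++l) {
    bMv.push_back(as<NumericMatrix>(bM[l]));
    bsigv.push_back(as<NumericMatrix>(bsig[l]));
  }
  for (int s = 0; s < S; ++s) {
    const int l = layer[s] - 1;
    const NumericMatrix &M = bMv[l];
    const NumericMatrix &Msig = bsigv[l];
    for (int g = 0; g < G; ++g) {
      double r = 0.0, dsig = 0.0;
      for (int z = 0; z < Z; ++z) {
        r += M(g, z) * n(s, z);
        dsig += Msig(g, z) * n(s, z);
      }
      const int x = X(g, s);
      obj += lgamma_diff(x, r) + r * log_1mp[g];
      const double A = digamma_diff(x, r) + log_1mp[g];
      for (int z = 0; z < Z; ++z) g_n(s, z) += A * M(g, z);
      g_T(l, g) += A * dsig;
      g_b[g] += A * r;
    }
  }
  return List::create(_["objective"] = obj, _["g_n"] = g_n,
                      _["g_T"] = g_T, _["g_b"] = g_b);
}
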