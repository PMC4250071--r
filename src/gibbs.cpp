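// Single-site Gibbs sampler for the boolean factor graph.
//
// Factor kinds (log-potentials linear in the tied weight w):
//   0 unary:        w * x[v]
//   1 implication:  w * 1{x[a] == 0 || x[b] == 1}   (vars = a, b)
//   2 aggregation:  w * 1{x[e] == max(x[m..])}      (vars = e, m1..mk)
//
// Sweeps visit variables in fixed index order; evidence variables stay
// clamped. Randomness comes from R's RNG so results are reproducible under
// set.seed(). Two marginal estimators are accumulated per variable over the
// post-burn-in sweeps: the fraction of sweeps with value 1, and the
// Rao-Blackwellised average of the full-conditional P(x_v = 1 | rest) at
// the moment v is resampled (unbiased for the same marginal, with much
// smaller Monte Carlo variance).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix gibbs_sample_cpp(int n_vars, IntegerVector evidence,
                               IntegerVector fkind, NumericVector fweight,
                               IntegerVector fptr, IntegerVector fvars,
                               int n_samples, int burn_in) {
  const int nf = fkind.size();

  // variable -> adjacent factor CSR
  std::vector<int> deg(n_vars, 0);
  for (int f = 0; f < nf; ++f)
    for (int k = fptr[f]; k < fptr[f + 1]; ++k) deg[fvars[k]]++;
  std::vector<int> vptr(n_vars + 1, 0);
  for (int v = 0; v < n_vars; ++v) vptr[v + 1] = vptr[v] + deg[v];
  std::vector<int> vfac(vptr[n_vars]);
  std::vector<int> fill(n_vars, 0);
  for (int f = 0; f < nf; ++f)
    for (int k = fptr[f]; k < fptr[f + 1]; ++k) {
      int v = fvars[k];
      vfac[vptr[v] + fill[v]++] = f;
    }

  RNGScope scope;
  std::vector<int> x(n_vars);
  for (int v = 0; v < n_vars; ++v)
    x[v] = (evidence[v] >= 0) ? evidence[v] : (unif_rand() < 0.5 ? 1 : 0);

  std::vector<double> ones(n_vars, 0.0);
  std::vector<double> cond(n_vars, 0.0);
  int kept = 0;

  for (int t = 0; t < n_samples; ++t) {
    for (int v = 0; v < n_vars; ++v) {
      if (evidence[v] >= 0) continue;
      double delta = 0.0;
      for (int a = vptr[v]; a < vptr[v + 1]; ++a) {
        const int f = vfac[a];
        const double w = fweight[f];
        const int lo = fptr[f], hi = fptr[f + 1];
        const int kind = fkind[f];
        if (kind == 0) {
          delta += w;
        } else if (kind == 1) {
          const int va = fvars[lo], vb = fvars[lo + 1];
          if (v == va) {
            delta += w * ((x[vb] == 1 ? 1.0 : 0.0) - 1.0);
          } else {
            delta += w * (1.0 - (x[va] == 0 ? 1.0 : 0.0));
          }
        } else {
          const int ve = fvars[lo];
          if (v == ve) {
            int mx = 0;
            for (int k = lo + 1; k < hi; ++k) if (x[fvars[k]]) { mx = 1; break; }
            delta += w * (mx ? 1.0 : -1.0);
          } else {
            int mx0 = 0;
            for (int k = lo + 1; k < hi; ++k) {
              int vm = fvars[k];
              if (vm != v && x[vm]) { mx0 = 1; break; }
            }
            // phi with this mention = 1 (max = 1) minus phi with it = 0
            delta += w * ((x[ve] == 1 ? 1.0 : 0.0) - (x[ve] == mx0 ? 1.0 : 0.0));
          }
        }
      }
      const double p1 = 1.0 / (1.0 + std::exp(-delta));
      x[v] = (unif_rand() < p1) ? 1 : 0;
      if (t >= burn_in) cond[v] += p1;
    }
    if (t >= burn_in) {
      ++kept;
      for (int v = 0; v < n_vars; ++v) ones[v] += x[v];
    }
  }

  NumericMatrix out(n_vars, 2);
  for (int v = 0; v < n_vars; ++v) {
    if (evidence[v] >= 0) {
      out(v, 0) = out(v, 1) = (double)evidence[v];
    } else if (kept > 0) {
      out(v, 0) = ones[v] / kept;
      out(v, 1) = cond[v] / kept;
    } else {
      out(v, 0) = out(v, 1) = NA_REAL;
    }
  }
  return out;
}
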