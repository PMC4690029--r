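#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Online Kohonen training of a rectangular SOM.
//
// x        : gene x sample data matrix
// codebook : unit x sample initial metagene matrix (not modified)
// order    : epochs x genes presentation order (1-based gene indices)
// urow/ucol: grid coordinates of each unit
// alpha0/1 : initial/final learning rate, exponential decay
// radius0/1: initial/final Gaussian neighborhood radius, exponential decay
//
// Learning rate and radius decay per presentation step; the best-matching
// unit (BMU) is the Euclidean argmin with ties broken by lowest index.
// Internally profiles are held sample-major so the hot loops touch
// contiguous memory.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& x, const NumericMatrix& codebook,
                            const IntegerMatrix& order,
                            const NumericVector& urow, const NumericVector& ucol,
                            double alpha0, double alpha1,
                            double radius0, double radius1) {
  const int G = x.nrow(), S = x.ncol(), U = codebook.nrow();
  const int E = order.nrow();

  // transpose to sample-major: xt[g*S + s], cb[u*S + s]
  std::vector<double> xt((size_t)G * S), cb((size_t)U * S);
  for (int g = 0; g < G; ++g)
    for (int s = 0; s < S; ++s) xt[(size_t)g * S + s] = x(g, s);
  for (int u = 0; u < U; ++u)
    for (int s = 0; s < S; ++s) cb[(size_t)u * S + s] = codebook(u, s);

  const double total = (double)E * (double)G;
  double step = 0.0;
  for (int e = 0; e < E; ++e) {
    for (int i = 0; i < G; ++i, step += 1.0) {
      const double frac = total > 1.0 ? step / (total - 1.0) : 0.0;
      const double alpha = alpha0 * std::pow(alpha1 / alpha0, frac);
      const double radius = radius0 * std::pow(radius1 / radius0, frac);
      const int g = order(e, i) - 1;
      const double* xg = &xt[(size_t)g * S];

      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < U; ++u) {
        const double* cu = &cb[(size_t)u * S];
        double d = 0.0;
        for (int s = 0; s < S; ++s) {
          const double df = cu[s] - xg[s];
          d += df * df;
        }
        if (d < best) { best = d; bmu = u; }
      }

      const double denom = 2.0 * radius * radius;
      // Gaussian kernel is negligible beyond d2max; skip those units
      const double d2max = -denom * std::log(1e-12 / alpha);
      const double br = urow[bmu], bc = ucol[bmu];
      for (int u = 0; u < U; ++u) {
        const double dr = urow[u] - br;
        const double dc = ucol[u] - bc;
        const double d2 = dr * dr + dc * dc;
        if (d2 > d2max) continue;
        const double ah = alpha * std::exp(-d2 / denom);
        double* cu = &cb[(size_t)u * S];
        for (int s = 0; s < S; ++s) cu[s] += ah * (xg[s] - cu[s]);
      }
    }
  }

  NumericMatrix out(U, S);
  for (int u = 0; u < U; ++u)
    for (int s = 0; s < S; ++s) out(u, s) = cb[(size_t)u * S + s];
  return out;
}
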