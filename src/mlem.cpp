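#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// ML-EM iteration core for Poisson emission data.
//
// The system matrix is supplied as the CSC slots of t(A) (pixels x LORs,
// one column per LOR), so a single index structure serves both the forward
// projection (gather down a column) and the backprojection (scatter down a
// column). Update: x <- (x / s) * A^T (y / (A x)), with eps guarding empty
// forward projections. Pixels with zero sensitivity stay at zero.
//
// Returns the final image, a decimated trajectory (every storeEvery-th
// iteration plus the last), and the Poisson log-likelihood
// sum_i y_i log(yhat_i + eps) - yhat_i per iteration.

// [[Rcpp::export(name = ".mlemCsc")]]
List mlemCsc(IntegerVector p, IntegerVector i, NumericVector a,
             int npix, NumericVector y, NumericVector sens,
             int nIter, int storeEvery, double eps) {
  const int nlor = p.size() - 1;
  if (y.size() != nlor) stop("counts length does not match system matrix");
  if (sens.size() != npix) stop("sensitivity length does not match grid");
  if (nIter < 1) stop("nIter must be >= 1");
  if (storeEvery < 1) storeEvery = nIter;

  std::vector<double> x(npix), z(npix), yhat(nlor);
  for (int j = 0; j < npix; ++j) x[j] = sens[j] > 0 ? 1.0 : 0.0;

  std::vector<int> storeIdx;
  for (int it = 1; it <= nIter; ++it)
    if (it % storeEvery == 0 || it == nIter) storeIdx.push_back(it);
  NumericMatrix traj(npix, (int)storeIdx.size());
  NumericVector loglik(nIter);

  const int* pp = INTEGER(p);
  const int* ii = INTEGER(i);
  const double* aa = REAL(a);

  int sPos = 0;
  for (int it = 1; it <= nIter; ++it) {
    // forward projection
    double ll = 0.0;
    for (int l = 0; l < nlor; ++l) {
      double acc = 0.0;
      for (int k = pp[l]; k < pp[l + 1]; ++k) acc += aa[k] * x[ii[k]];
      yhat[l] = acc;
      ll += (y[l] > 0 ? y[l] * std::log(acc + eps) : 0.0) - acc;
    }
    loglik[it - 1] = ll;
    // backproject the ratio
    std::fill(z.begin(), z.end(), 0.0);
    for (int l = 0; l < nlor; ++l) {
      double rl = y[l] / (yhat[l] + eps);
      if (rl == 0.0) continue;
      for (int k = pp[l]; k < pp[l + 1]; ++k) z[ii[k]] += aa[k] * rl;
    }
    for (int j = 0; j < npix; ++j)
      x[j] = sens[j] > 0 ? x[j] * z[j] / sens[j] : 0.0;

    if (sPos < (int)storeIdx.size() && it == storeIdx[sPos]) {
      for (int j = 0; j < npix; ++j) traj(j, sPos) = x[j];
      ++sPos;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["x"] = wrap(x),
                      _["trajectory"] = traj,
                      _["iterations"] = wrap(storeIdx),
                      _["loglik"] = loglik);
}
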