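#include <Rcpp.h>
using namespace Rcpp;

// In-place optimizer steps. Parameter updates touch every weight of the
// ~2M-parameter network once per mini-batch; fused single-pass C++ loops
// over raw REAL() pointers avoid both R's per-batch temporaries and Rcpp's
// element-accessor overhead. Callers guarantee the buffers are uniquely
// referenced REALSXP objects.

// [[Rcpp::export]]
void adadelta_step(NumericVector w, NumericVector eg, NumericVector ed,
                   NumericVector g, double rho, double eps, double lr) {
  double *pw = REAL(w), *pe = REAL(eg), *pd = REAL(ed), *pg = REAL(g);
  const R_xlen_t n = w.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double egi = rho * pe[i] + (1.0 - rho) * gi * gi;
    const double step = -lr * std::sqrt((pd[i] + eps) / (egi + eps)) * gi;
    pe[i] = egi;
    pd[i] = rho * pd[i] + (1.0 - rho) * step * step;
    pw[i] += step;
  }
}

// [[Rcpp::export]]
void sgd_momentum_step(NumericVector w, NumericVector v, NumericVector g,
                       double lr, double momentum) {
  double *pw = REAL(w), *pv = REAL(v), *pg = REAL(g);
  const R_xlen_t n = w.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double vi = momentum * pv[i] - lr * pg[i];
    pv[i] = vi;
    pw[i] += vi;
  }
}

// add a bias row-vector to every row of z, in place
// [[Rcpp::export]]
void add_bias(NumericMatrix z, NumericVector b) {
  double *pz = REAL(z);
  const double *pb = REAL(b);
  const R_xlen_t nr = z.nrow(), nc = z.ncol();
  for (R_xlen_t j = 0; j < nc; ++j) {
    const double bj = pb[j];
    double *col = pz + j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) col[i] += bj;
  }
}
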