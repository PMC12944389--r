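#include <Rcpp.h>
#include <complex>
#include <vector>
#include <limits>
using namespace Rcpp;

// ADMM iterations for variational mode decomposition, restricted to the
// non-negative half of the (fftshifted) spectrum. The input spectrum must
// already have its negative-frequency bins dropped; with a one-sided
// forcing term and a one-sided dual variable the negative bins of every
// mode stay identically zero, so they are never carried.
//
// Per sweep, mode k is refit as a Wiener-type filter around its current
// center frequency against the residual of all other modes (Gauss-Seidel:
// modes i < k already updated), then the center frequency is moved to the
// power-weighted mean frequency of the refit mode. The dual ascent step
// (step size tau) enforces the reconstruction constraint; tau = 0 leaves
// the constraint relaxed, which is the usual choice for noisy input.
// Convergence: sum over modes of the relative squared change of the mode
// spectra falls below tol.
//
// [[Rcpp::export]]
List vmd_admm_cpp(ComplexVector f_plus, NumericVector freqs, int K,
                  double alpha, double tau, double tol, int max_iter,
                  NumericVector omega_init) {
  const int Tp = f_plus.size();
  std::vector< std::complex<double> > f(Tp), lambda(Tp), sumU(Tp);
  for (int j = 0; j < Tp; ++j)
    f[j] = std::complex<double>(f_plus[j].r, f_plus[j].i);
  std::vector< std::vector< std::complex<double> > > u(
      K, std::vector< std::complex<double> >(Tp));
  std::vector<double> omega(omega_init.begin(), omega_init.end());
  const double *fr = REAL(freqs);
  const double eps = std::numeric_limits<double>::epsilon();

  int n_iter = 0;
  bool converged = false;
  std::vector<double> res_hist;
  res_hist.reserve(64);
  for (int it = 1; it <= max_iter; ++it) {
    double udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      double normsq_old = 0.0, diffsq = 0.0, wsum = 0.0, psum = 0.0;
      const double wk = omega[k];
      std::complex<double> *uk = u[k].data();
      for (int j = 0; j < Tp; ++j) {
        const std::complex<double> old = uk[j];
        normsq_old += std::norm(old);
        sumU[j] -= old;
        const double d = fr[j] - wk;
        const std::complex<double> nu =
            (f[j] - sumU[j] - 0.5 * lambda[j]) / (1.0 + 2.0 * alpha * d * d);
        diffsq += std::norm(nu - old);
        uk[j] = nu;
        sumU[j] += nu;
        const double p = std::norm(nu);
        wsum += fr[j] * p;
        psum += p;
      }
      udiff += diffsq / (normsq_old + eps);
      if (psum > 0.0) omega[k] = wsum / psum;
      if (omega[k] < 0.0) omega[k] = 0.0;
    }
    if (tau > 0.0)
      for (int j = 0; j < Tp; ++j) lambda[j] += tau * (sumU[j] - f[j]);
    double rsq = 0.0, fsq = 0.0;
    for (int j = 0; j < Tp; ++j) {
      rsq += std::norm(f[j] - sumU[j]);
      fsq += std::norm(f[j]);
    }
    res_hist.push_back(std::sqrt(rsq / (fsq + eps)));
    n_iter = it;
    if (it > 1 && udiff < tol) { converged = true; break; }
  }

  ComplexMatrix U(Tp, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < Tp; ++j) {
      U(j, k).r = u[k][j].real();
      U(j, k).i = u[k][j].imag();
    }
  return List::create(_["u_plus"] = U,
                      _["omega"] = NumericVector(omega.begin(), omega.end()),
                      _["n_iter"] = n_iter,
                      _["converged"] = converged,
                      _["residual_history"] =
                          NumericVector(res_hist.begin(), res_hist.end()));
}
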