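// Per-frequency kernels for the spectral MIR decomposition.
// The R level prepares the innovation transforms once per model; the loop
// over frequencies (solve, spectral factorization, log-determinants) runs
// here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logdet_herm(const cx_mat& z) {
  // Hermitian positive definite log-determinant via complex Cholesky
  cx_mat R;
  if (chol(R, (z + z.t()) / 2.0)) {
    return 2.0 * accu(log(abs(R.diag())));
  }
  vec ev;
  cx_mat dummy;
  eig_sym(ev, dummy, (z + z.t()) / 2.0);
  if (ev.min() <= 0) return datum::nan;
  return accu(log(ev));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mir_spectra(const arma::mat& A, const arma::mat& C,
                                    const arma::mat& K,
                                    const arma::mat& Sigma,
                                    const arma::mat& T1inv,
                                    const arma::mat& T2inv,
                                    const arma::mat& Sig_II_p,
                                    const arma::mat& Sig_MM_p,
                                    const arma::vec& omega, int N) {
  const uword m = A.n_rows, d = C.n_rows, nf = omega.n_elem;
  const uvec iM = regspace<uvec>(0, N - 1);
  const uvec iI = regspace<uvec>(N, 2 * N - 1);
  const cx_mat Id = cx_mat(eye(d, d), zeros(d, d));
  const cx_mat Im = cx_mat(eye(m, m), zeros(m, m));
  const cx_mat Cc = cx_mat(C, zeros(size(C)));
  const cx_mat Kc = cx_mat(K, zeros(size(K)));
  const cx_mat Ac = cx_mat(A, zeros(size(A)));
  const cx_mat Sig = cx_mat(Sigma, zeros(size(Sigma)));
  const cx_mat T1 = cx_mat(T1inv, zeros(size(T1inv)));
  const cx_mat T2 = cx_mat(T2inv, zeros(size(T2inv)));
  const cx_mat S2p = cx_mat(Sig_II_p, zeros(size(Sig_II_p)));
  const cx_mat S1p = cx_mat(Sig_MM_p, zeros(size(Sig_MM_p)));

  Rcpp::NumericMatrix out(nf, 4);
  for (uword k = 0; k < nf; ++k) {
    const cx_double z = std::exp(cx_double(0.0, -omega(k)));
    cx_mat X = solve(Im - Ac * z, Kc);
    cx_mat H = Id + Cc * X * z;
    cx_mat S = H * Sig * H.t();
    const double ld_S = logdet_herm(S);
    const double ld_SM = logdet_herm(S.submat(iM, iM));
    const double ld_SI = logdet_herm(S.submat(iI, iI));
    cx_mat H1 = H * T1;
    cx_mat H2 = H * T2;
    cx_mat HI = H1.submat(iI, iI);
    cx_mat HM = H2.submat(iM, iM);
    const double ld_G1 = logdet_herm(HI * S2p * HI.t());
    const double ld_G2 = logdet_herm(HM * S1p * HM.t());
    out(k, 0) = ld_SM + ld_SI - ld_S;       // total interdependence
    out(k, 1) = ld_SI - ld_G1;              // M -> I
    out(k, 2) = ld_SM - ld_G2;              // I -> M
    out(k, 3) = ld_G1 + ld_G2 - ld_S;       // instantaneous
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_cube cpp_transfer(const arma::mat& A, const arma::mat& C,
                           const arma::mat& K, const arma::vec& omega) {
  const uword m = A.n_rows, d = C.n_rows, nf = omega.n_elem;
  const cx_mat Id = cx_mat(eye(d, d), zeros(d, d));
  const cx_mat Im = cx_mat(eye(m, m), zeros(m, m));
  const cx_mat Cc = cx_mat(C, zeros(size(C)));
  const cx_mat Kc = cx_mat(K, zeros(size(K)));
  const cx_mat Ac = cx_mat(A, zeros(size(A)));
  cx_cube H(d, d, nf);
  for (uword k = 0; k < nf; ++k) {
    const cx_double z = std::exp(cx_double(0.0, -omega(k)));
    H.slice(k) = Id + Cc * solve(Im - Ac * z, Kc) * z;
  }
  return H;
}
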