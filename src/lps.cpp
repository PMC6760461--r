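// Lagged phase synchronization between all ROI pairs from phase-normalized
// segment spectra.  The per-pair measure follows the determinant-based
// decomposition of linear dependence between two 3-dimensional series:
//   F_total = ln det(Sxx) + ln det(Syy) - ln det(S)
//   F_inst  = same expression on the real parts of the covariance blocks
//   lagged  = F_total - F_inst
// with an optional leave-one-segment-out jackknife that removes the
// first-order small-sample bias of the log-determinants.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// log-determinant of a Hermitian PSD matrix after a relative ridge,
// via eigenvalues (R's det() does not handle complex matrices).
static double ld_cx(const cx_mat& M, double ridge) {
  double d = ridge * real(trace(M)) / M.n_rows;
  cx_mat R = M + d * eye<cx_mat>(M.n_rows, M.n_cols);
  vec ev = eig_sym(R);
  ev = clamp(ev, 1e-300, datum::inf);
  return accu(log(ev));
}

static double ld_re(const mat& M, double ridge) {
  double d = ridge * trace(M) / M.n_rows;
  mat R = M + d * eye(M.n_rows, M.n_cols);
  vec ev = eig_sym(R);
  ev = clamp(ev, 1e-300, datum::inf);
  return accu(log(ev));
}

// V: cx_cube (3, nseg, nroi * nbin), slice index r + nroi * b holding the
// phase-normalized Fourier 3-vectors of ROI r at frequency bin b, one column
// per segment.  Returns cubes (nroi, nroi, nbin) of F_total and F_inst.
// [[Rcpp::export]]
Rcpp::List lps_pairs_cpp(const arma::cx_cube& V, int nroi, double ridge,
                         bool jackknife) {
  const int nseg = V.n_cols;
  const int nbin = V.n_slices / nroi;
  cube Ftot(nroi, nroi, nbin, fill::zeros);
  cube Finst(nroi, nroi, nbin, fill::zeros);

  for (int b = 0; b < nbin; ++b) {
    // per-ROI auto-covariances and their (LOO) log-determinants
    std::vector<cx_mat> A(nroi);
    std::vector<double> ldA(nroi), ldAr(nroi);
    mat ldA_loo(nroi, nseg), ldAr_loo(nroi, nseg);
    for (int r = 0; r < nroi; ++r) {
      const cx_mat& Vr = V.slice(r + nroi * b);
      A[r] = (Vr * Vr.t()) / double(nseg);
      ldA[r] = ld_cx(A[r], ridge);
      ldAr[r] = ld_re(real(A[r]), ridge);
      if (jackknife) {
        for (int s = 0; s < nseg; ++s) {
          cx_mat As = (double(nseg) * A[r] - Vr.col(s) * Vr.col(s).t()) /
                      double(nseg - 1);
          ldA_loo(r, s) = ld_cx(As, ridge);
          ldAr_loo(r, s) = ld_re(real(As), ridge);
        }
      }
    }
    for (int i = 0; i < nroi - 1; ++i) {
      const cx_mat& Vi = V.slice(i + nroi * b);
      for (int j = i + 1; j < nroi; ++j) {
        const cx_mat& Vj = V.slice(j + nroi * b);
        cx_mat C = (Vi * Vj.t()) / double(nseg);
        cx_mat S = join_cols(join_rows(A[i], C), join_rows(C.t(), A[j]));
        double ft = ldA[i] + ldA[j] - ld_cx(S, ridge);
        double fi = ldAr[i] + ldAr[j] - ld_re(real(S), ridge);
        if (jackknife) {
          double ft_loo = 0.0, fi_loo = 0.0;
          for (int s = 0; s < nseg; ++s) {
            cx_vec u = join_cols(Vi.col(s), Vj.col(s));
            cx_mat Ss = (double(nseg) * S - u * u.t()) / double(nseg - 1);
            ft_loo += ldA_loo(i, s) + ldA_loo(j, s) - ld_cx(Ss, ridge);
            fi_loo += ldAr_loo(i, s) + ldAr_loo(j, s) - ld_re(real(Ss), ridge);
          }
          ft = nseg * ft - (nseg - 1) * (ft_loo / nseg);
          fi = nseg * fi - (nseg - 1) * (fi_loo / nseg);
        }
        Ftot(i, j, b) = Ftot(j, i, b) = ft;
        Finst(i, j, b) = Finst(j, i, b) = fi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("f_total") = Ftot,
                            Rcpp::Named("f_inst") = Finst);
}
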