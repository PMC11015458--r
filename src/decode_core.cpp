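#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ledoit-Wolf shrinkage toward a scaled identity. Rows of R are
// (condition-demeaned) observations; they are centered again here so that
// degenerate inputs (identical rows) surface as a singular-covariance error.
static arma::mat lwCov(const arma::mat& R) {
  const arma::uword n = R.n_rows, d = R.n_cols;
  arma::rowvec cm = arma::mean(R, 0);
  arma::mat Xc = R.each_row() - cm;
  arma::mat S = (Xc.t() * Xc) / n;
  double mu = arma::trace(S) / d;
  if (mu <= 0.0)
    stop("singular covariance: residuals have no variance");
  double frob2 = arma::accu(arma::square(S));
  double d2 = frob2 - 2.0 * mu * arma::trace(S) + d * mu * mu;
  if (d2 <= 0.0)                       // sample covariance already ~ mu * I
    return S;
  arma::vec rs = arma::sum(arma::square(Xc), 1);
  double b2bar = arma::accu(arma::square(rs)) / ((double)n * n) - frob2 / n;
  double b2 = std::min(std::max(b2bar, 0.0), d2);
  double shrink = b2 / d2;
  arma::mat out = (1.0 - shrink) * S;
  out.diag() += shrink * mu;
  return out;
}

// Cross-validated Mahalanobis scoring of one fold plan (one repetition of
// one color space), applied independently at every slice (time point) of X.
//
// X:       trials x dims x timepoints cube (one slice for window decoding)
// bins:    0..15 color-bin index per trial
// foldOf:  1..nFolds fold assignment per trial
// keep:    per fold, 0-based indices of the bin-equalized training subsample
// basis:   16x16 row-normalized half-cosine smoothing weights
// cosMat:  cosMat(b, k) = cos(angular difference between centers k and b)
//
// Returns per-trial accuracy (trials x timepoints) and the tuning-curve sum
// over trials (16 x timepoints), ordered by signed angular difference
// (-180 ... +157.5 deg, position 8 = 0 deg).
// [[Rcpp::export]]
List cppScoreRep(const arma::cube& X, const arma::ivec& bins,
                 const arma::ivec& foldOf, const List& keep,
                 const arma::mat& basis, const arma::mat& cosMat) {
  const arma::uword n = X.n_rows, d = X.n_cols, nT = X.n_slices;
  const int nFolds = keep.size();
  arma::mat acc(n, nT, arma::fill::zeros);
  arma::mat tun(16, nT, arma::fill::zeros);

  for (int f = 1; f <= nFolds; ++f) {
    arma::uvec testIdx = arma::find(foldOf == f);
    arma::uvec trainIdx = arma::find(foldOf != f);
    arma::uvec keepIdx = as<arma::uvec>(keep[f - 1]);
    if (testIdx.n_elem == 0) continue;

    for (arma::uword t = 0; t < nT; ++t) {
      const arma::mat& Xt = X.slice(t);

      // bin means over the full training set, for condition-demeaning
      arma::mat Mall(16, d, arma::fill::zeros);
      arma::vec cntAll(16, arma::fill::zeros);
      for (arma::uword ii = 0; ii < trainIdx.n_elem; ++ii) {
        int b = bins[trainIdx[ii]];
        Mall.row(b) += Xt.row(trainIdx[ii]);
        cntAll[b] += 1.0;
      }
      for (int b = 0; b < 16; ++b)
        if (cntAll[b] > 0) Mall.row(b) /= cntAll[b];

      arma::mat Rres(trainIdx.n_elem, d);
      for (arma::uword ii = 0; ii < trainIdx.n_elem; ++ii)
        Rres.row(ii) = Xt.row(trainIdx[ii]) - Mall.row(bins[trainIdx[ii]]);
      arma::mat Sigma = lwCov(Rres);

      // bin-equalized class means, then half-cosine smoothing
      arma::mat Msub(16, d, arma::fill::zeros);
      arma::vec cnt(16, arma::fill::zeros);
      for (arma::uword ii = 0; ii < keepIdx.n_elem; ++ii) {
        int b = bins[keepIdx[ii]];
        Msub.row(b) += Xt.row(keepIdx[ii]);
        cnt[b] += 1.0;
      }
      for (int b = 0; b < 16; ++b) {
        if (cnt[b] == 0) stop("empty training bin %d after subsampling", b);
        Msub.row(b) /= cnt[b];
      }
      arma::mat Msm = basis * Msub;

      arma::mat L = arma::chol(Sigma, "lower");
      arma::mat Mw = arma::solve(arma::trimatl(L), Msm.t());   // d x 16
      arma::mat Xtest(testIdx.n_elem, d);
      for (arma::uword j = 0; j < testIdx.n_elem; ++j)
        Xtest.row(j) = Xt.row(testIdx[j]);
      arma::mat Xw = arma::solve(arma::trimatl(L), Xtest.t()); // d x ntest

      arma::rowvec mn2 = arma::sum(arma::square(Mw), 0);
      arma::vec xn2 = arma::sum(arma::square(Xw), 0).t();
      arma::mat D2 = -2.0 * (Xw.t() * Mw);
      D2.each_col() += xn2;
      D2.each_row() += mn2;
      D2.elem(arma::find(D2 < 0)).zeros();
      arma::mat D = arma::sqrt(D2);

      arma::vec rm = arma::mean(D, 1);
      arma::mat Sc = -(D.each_col() - rm);

      for (arma::uword j = 0; j < testIdx.n_elem; ++j) {
        int b = bins[testIdx[j]];
        acc(testIdx[j], t) += arma::dot(Sc.row(j), cosMat.row(b)) / 16.0;
        for (int k = 0; k < 16; ++k) {
          int pos = ((k - b) % 16 + 16 + 8) % 16;
          tun(pos, t) += Sc(j, k);
        }
      }
    }
  }
  return List::create(Named("acc") = acc, Named("tun") = tun);
}
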