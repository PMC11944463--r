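// Hot loops of the pipeline: leave-one-trial-out shrinkage LDA and the
// TFCE sign-flip permutation null. Pure-R reference implementations of
// both exist in R/ and the test suite asserts equivalence.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// TFCE of a 1-d map, positive tail: for thresholds h = dh, 2dh, ...,
// max(map), every point in a contiguous run of {map >= h} of length e
// accumulates e^E * h^H * dh.
static void tfce_1d_core(const arma::vec &map, double E, double H,
                         double dh, arma::vec &out) {
  const int T = map.n_elem;
  out.zeros(T);
  double mx = map.max();
  if (mx <= 0.0) return;
  int n_thresh = (int)std::floor(mx / dh + 1e-12);
  for (int k = 1; k <= n_thresh; ++k) {
    double h = k * dh;
    double hH = std::pow(h, H) * dh;
    int t = 0;
    while (t < T) {
      if (map[t] >= h) {
        int start = t;
        while (t < T && map[t] >= h) ++t;
        double add = std::pow((double)(t - start), E) * hH;
        for (int j = start; j < t; ++j) out[j] += add;
      } else {
        ++t;
      }
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_tfce_1d(const arma::vec &map, double E, double H, double dh) {
  arma::vec out;
  tfce_1d_core(map, E, H, dh, out);
  return out;
}

// One-sample t of sign-flipped deviations per column. `signs` is +-1 per
// subject; column sums of squares are flip-invariant and precomputed.
static void flipped_tmap(const arma::mat &d, const arma::vec &signs,
                         const arma::rowvec &css, double t_cap,
                         arma::vec &t) {
  const int n = d.n_rows, T = d.n_cols;
  arma::rowvec s = signs.t() * d; // column sums of flipped deviations
  for (int j = 0; j < T; ++j) {
    double m = s[j] / n;
    double var = (css[j] - n * m * m) / (n - 1);
    if (var < 0) var = 0;
    double se = std::sqrt(var / n);
    if (se > 0) {
      t[j] = m / se;
    } else {
      t[j] = (m == 0.0) ? 0.0 : ((m > 0) ? t_cap : -t_cap);
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_perm_null_max(const arma::mat &d, int n_iter, double E,
                            double H, double dh, double t_cap) {
  const int n = d.n_rows;
  arma::rowvec css = arma::sum(arma::square(d), 0);
  arma::vec signs(n), t(d.n_cols), tf;
  arma::vec out(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) signs[i] = (unif_rand() < 0.5) ? -1.0 : 1.0;
    flipped_tmap(d, signs, css, t_cap, t);
    tfce_1d_core(t, E, H, dh, tf);
    out[it] = tf.max();
  }
  return out;
}

// All 2^n sign assignments; bit i of the iteration index flips subject i.
// [[Rcpp::export]]
arma::vec cpp_perm_null_max_exhaustive(const arma::mat &d, double E,
                                       double H, double dh, double t_cap) {
  const int n = d.n_rows;
  if (n > 16) stop("exhaustive enumeration supports at most 16 subjects");
  const unsigned long total = 1UL << n;
  arma::rowvec css = arma::sum(arma::square(d), 0);
  arma::vec signs(n), t(d.n_cols), tf;
  arma::vec out(total);
  for (unsigned long code = 0; code < total; ++code) {
    for (int i = 0; i < n; ++i) {
      signs[i] = (code >> i) & 1UL ? -1.0 : 1.0;
    }
    flipped_tmap(d, signs, css, t_cap, t);
    tfce_1d_core(t, E, H, dh, tf);
    out[code] = tf.max();
  }
  return out;
}

// Shrinkage-LDA leave-one-trial-out accuracy at a single timepoint.
// X: trials x features (training pool), y: 1..K class codes.
// Pooled covariance of each fold is obtained by rank-one downdates of the
// full-data scatter; Sigma_reg = Sigma + lambda * mean(diag(Sigma)) * I.
static double lda_loto_core(const arma::mat &X, const arma::ivec &y, int K,
                            double lambda) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec nk(K, arma::fill::zeros);
  arma::mat S(p, K, arma::fill::zeros); // class sums
  for (int i = 0; i < n; ++i) {
    int k = y[i] - 1;
    nk[k] += 1.0;
    S.col(k) += X.row(i).t();
  }
  for (int k = 0; k < K; ++k) {
    if (nk[k] < 2) {
      stop("class %d has %d trial(s); >= 2 required per class", k + 1,
           (int)nk[k]);
    }
  }
  arma::mat C = X.t() * X; // total crossprod
  arma::mat M(p, K);       // full-data class means
  for (int k = 0; k < K; ++k) M.col(k) = S.col(k) / nk[k];
  arma::mat A(p, p, arma::fill::zeros); // sum_k nk mu mu'
  for (int k = 0; k < K; ++k) A += nk[k] * (M.col(k) * M.col(k).t());

  int correct = 0;
  arma::mat Mf(p, K);
  arma::vec prior(K);
  for (int i = 0; i < n; ++i) {
    int k = y[i] - 1;
    arma::vec x = X.row(i).t();
    double nkf = nk[k] - 1.0;
    arma::vec muk = (S.col(k) - x) / nkf;
    arma::mat W = C - x * x.t() - A + nk[k] * (M.col(k) * M.col(k).t()) -
                  nkf * (muk * muk.t());
    arma::mat Sigma = W / (double)(n - 1 - K);
    double scale = arma::trace(Sigma) / p;
    if (scale <= 0) scale = 1.0; // degenerate zero scatter
    Sigma.diag() += lambda * scale;
    arma::mat L = arma::chol(Sigma, "lower");
    Mf = M;
    Mf.col(k) = muk;
    for (int j = 0; j < K; ++j) {
      prior[j] = ((j == k) ? nkf : nk[j]) / (double)(n - 1);
    }
    int best = 0;
    double best_score = -arma::datum::inf;
    for (int j = 0; j < K; ++j) {
      arma::vec z = arma::solve(arma::trimatl(L), x - Mf.col(j));
      double score = std::log(prior[j]) - 0.5 * arma::dot(z, z);
      if (score > best_score) {
        best_score = score;
        best = j;
      }
    }
    if (best == k) ++correct;
  }
  return (double)correct / n;
}

// [[Rcpp::export]]
double cpp_lda_loto(const arma::mat &X, const arma::ivec &y, int K,
                    double lambda) {
  return lda_loto_core(X, y, K, lambda);
}

// LOTO accuracy at each requested timepoint of an epoched array.
// data: trials x channels x timepoints cube; train_idx, tp_idx: 1-based.
// [[Rcpp::export]]
arma::vec cpp_lda_loto_timecourse(const arma::cube &data,
                                  const arma::uvec &train_idx,
                                  const arma::ivec &y,
                                  const arma::uvec &tp_idx, int K,
                                  double lambda) {
  const int nt = train_idx.n_elem;
  arma::ivec yt(nt);
  for (int i = 0; i < nt; ++i) yt[i] = y[train_idx[i] - 1];
  arma::vec out(tp_idx.n_elem);
  arma::mat X(nt, data.n_cols);
  for (arma::uword s = 0; s < tp_idx.n_elem; ++s) {
    arma::mat slice = data.slice(tp_idx[s] - 1); // trials x channels
    for (int i = 0; i < nt; ++i) X.row(i) = slice.row(train_idx[i] - 1);
    out[s] = lda_loto_core(X, yt, K, lambda);
  }
  return out;
}
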