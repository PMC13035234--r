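// Recurrent signaling core: forward simulation and backpropagation through
// time. The activation is piecewise: leaky-linear for negative pre-activation,
// identity on [0, 0.5], and a saturating 1 - 0.25/z branch above 0.5, so
// activities are bounded by 1 while negative inputs (drug inhibition) decay
// the state smoothly. Its derivative is recoverable from the activity itself,
// which lets the backward pass run from the stored state sequence alone.
// The prior-knowledge mask keeps W sparse, so the recurrent products use a
// sparse representation of W.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double act(double z, double leak) {
  if (z < 0.0) return leak * z;
  if (z <= 0.5) return z;
  return 1.0 - 0.25 / z;
}

// derivative of the activation expressed through the activity h = f(z):
// h < 0   <=> z < 0      : f' = leak
// h <= 0.5 <=> z <= 0.5  : f' = 1
// h > 0.5 <=> z > 0.5    : z = 0.25/(1-h), f' = 0.25/z^2 = 4 (1-h)^2
static inline double dact_from_h(double h, double leak) {
  if (h < 0.0) return leak;
  if (h <= 0.5) return 1.0;
  const double d = 1.0 - h;
  return 4.0 * d * d;
}

// Forward simulation of h_{t+1} = f(W h_t + b + x), h_0 = f(b + x).
// W: nodes x nodes (row = target, col = source), X: nodes x samples of
// constant external inputs. Returns a nodes x samples x L cube of states.
// [[Rcpp::export(name = ".rnnForwardCpp")]]
arma::cube rnnForwardCpp(const arma::mat& W, const arma::vec& b,
                         const arma::mat& X, const int L,
                         const double leak) {
  const uword n = W.n_rows, B = X.n_cols;
  sp_mat Ws(W);
  cube H(n, B, L);
  mat pre = X.each_col() + b;          // step 0 pre-activation
  mat h(n, B);
  for (uword j = 0; j < B; ++j)
    for (uword i = 0; i < n; ++i)
      h(i, j) = act(pre(i, j), leak);
  H.slice(0) = h;
  for (int t = 1; t < L; ++t) {
    pre = Ws * h;
    pre.each_col() += b;
    pre += X;
    for (uword j = 0; j < B; ++j)
      for (uword i = 0; i < n; ++i)
        h(i, j) = act(pre(i, j), leak);
    H.slice(t) = h;
  }
  return H;
}

// Backpropagation through time. G holds dL/dh_t (same layout as H). Returns
// dL/dW, dL/db and dL/dX (per-sample input gradient). With e_t = dL/dz_t:
//   e_t = f'(z_t) o (G_t + W^T e_{t+1}),  e_L = 0
//   dW  = sum_{t>=1} e_t h_{t-1}^T,  db = sum_t e_t (over samples too), dX = sum_t e_t
// When a support index matrix (0-based rows/cols of the prior mask) is
// supplied, dW is accumulated on the support only; otherwise densely via one
// matrix product.
// [[Rcpp::export(name = ".rnnBackwardCpp")]]
Rcpp::List rnnBackwardCpp(const arma::mat& W, const arma::cube& H,
                          const arma::cube& G, const double leak,
                          Rcpp::Nullable<Rcpp::IntegerMatrix> support =
                            R_NilValue) {
  const uword n = H.n_rows, B = H.n_cols;
  const int L = H.n_slices;
  sp_mat Wt(W.t());
  vec db(n, fill::zeros);
  mat dX(n, B, fill::zeros);
  mat e_next(n, B, fill::zeros);
  // e_t for t = 1..L-1 alongside h_{t-1}; dW reduces to (sparse or dense)
  // products of these blocks
  mat Emat(n, B * std::max(L - 1, 0));
  mat Hmat(n, B * std::max(L - 1, 0));
  for (int t = L - 1; t >= 0; --t) {
    mat e = G.slice(t);
    if (t < L - 1) e += Wt * e_next;
    const mat& h = H.slice(t);
    for (uword j = 0; j < B; ++j)
      for (uword i = 0; i < n; ++i)
        e(i, j) *= dact_from_h(h(i, j), leak);
    if (t >= 1) {
      Emat.cols((t - 1) * B, t * B - 1) = e;
      Hmat.cols((t - 1) * B, t * B - 1) = H.slice(t - 1);
    }
    db += sum(e, 1);
    dX += e;
    e_next = std::move(e);
  }
  mat dW(n, n, fill::zeros);
  if (L > 1) {
    if (support.isNotNull()) {
      Rcpp::IntegerMatrix sup(support);
      const uword m = Emat.n_cols;
      for (int k = 0; k < sup.nrow(); ++k) {
        const uword r = sup(k, 0), c = sup(k, 1);
        double acc = 0.0;
        const double* er = Emat.memptr();
        const double* hr = Hmat.memptr();
        for (uword j = 0; j < m; ++j)
          acc += er[r + j * n] * hr[c + j * n];
        dW(r, c) = acc;
      }
    } else {
      dW = Emat * Hmat.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
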