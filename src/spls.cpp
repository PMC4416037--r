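#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sparse NIPALS for PLS2 in regression mode, one pass per component.
//
// Each component takes the dominant covariance direction between the current
// X residual and Y, hard-thresholds it to the `nkeep` entries of largest
// magnitude (ties resolved toward the lower feature index via a stable sort),
// renormalises to unit length, forms scores/loadings/response weights and
// deflates both blocks.  Blocks are centred here, so cross-validation folds
// are handled uniformly; the centring vectors are returned for prediction.
//
// Returns the number of components actually achieved (early stop when the
// residual covariance is numerically exhausted).
static int spls_engine(const mat& X, const mat& Y, int ncomp, int nkeep,
                       double tol, mat& W, mat& T, mat& P, mat& C,
                       vec& ssy, rowvec& mx, rowvec& my, double& toty) {
  const uword p = X.n_cols, K = Y.n_cols;
  mx = mean(X, 0);
  my = mean(Y, 0);
  mat Xc = X.each_row() - mx;
  mat Yc = Y.each_row() - my;
  toty = accu(square(Yc));
  W.zeros(p, ncomp); T.zeros(X.n_rows, ncomp);
  P.zeros(p, ncomp); C.zeros(K, ncomp);
  ssy.zeros(ncomp);
  const double ref = norm(Xc, "fro") * norm(Yc, "fro");
  if (ref <= 0.0) return 0;
  const int keep = std::min<int>(nkeep, (int)p);
  int h = 0;
  for (; h < ncomp; ++h) {
    mat M = Xc.t() * Yc;  // p x K cross-covariance block
    vec w;
    if (K == 1) {
      w = M.col(0);
    } else {
      vec ev; mat V;
      eig_sym(ev, V, symmatu(M.t() * M));
      w = M * V.col(K - 1);
    }
    double nw = norm(w);
    if (nw <= tol * ref) break;
    w /= nw;
    // deterministic sign convention: largest-|w| coordinate positive
    uword imax = index_max(abs(w));
    if (w(imax) < 0.0) w = -w;
    if (keep < (int)p) {
      uvec ord = stable_sort_index(abs(w), "descend");
      vec ws(p, fill::zeros);
      for (int j = 0; j < keep; ++j) ws(ord(j)) = w(ord(j));
      w = ws / norm(ws);
    }
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt <= tol * tol * ref) break;
    vec c = Yc.t() * t / tt;
    vec pl = Xc.t() * t / tt;
    Xc -= t * pl.t();
    Yc -= t * c.t();
    W.col(h) = w; T.col(h) = t; P.col(h) = pl; C.col(h) = c;
    ssy(h) = tt * dot(c, c);  // Y sum of squares captured by component h
  }
  return h;
}

// B = W (P'W)^-1 C' from the first h components
static mat coef_from(const mat& W, const mat& P, const mat& C, int h) {
  const mat Wh = W.cols(0, h - 1);
  const mat Ph = P.cols(0, h - 1);
  const mat Ch = C.cols(0, h - 1);
  return Wh * solve(Ph.t() * Wh, Ch.t());
}

// [[Rcpp::export]]
Rcpp::List cpp_spls_fit(const arma::mat& X, const arma::mat& Y,
                        int ncomp, int nkeep, double tol) {
  mat W, T, P, C; vec ssy; rowvec mx, my; double toty;
  int h = spls_engine(X, Y, ncomp, nkeep, tol, W, T, P, C, ssy, mx, my, toty);
  mat B(X.n_cols, Y.n_cols, fill::zeros);
  if (h > 0) {
    B = coef_from(W, P, C, h);
    W = W.cols(0, h - 1); T = T.cols(0, h - 1);
    P = P.cols(0, h - 1); C = C.cols(0, h - 1);
    ssy = ssy.subvec(0, h - 1);
  } else {
    W.set_size(X.n_cols, 0); T.set_size(X.n_rows, 0);
    P.set_size(X.n_cols, 0); C.set_size(Y.n_cols, 0);
    ssy.set_size(0);
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("scores") = T,
      Rcpp::Named("P") = P, Rcpp::Named("C") = C,
      Rcpp::Named("B") = B, Rcpp::Named("ssy") = ssy,
      Rcpp::Named("x_center") = mx, Rcpp::Named("y_center") = my,
      Rcpp::Named("toty") = toty, Rcpp::Named("ncomp_used") = h);
}

// Leave-one-out MSEP of the sparse fit at fixed (ncomp, nkeep); every fold is
// refitted (with its own centring) and the held-out row predicted.  Folds
// whose fit degenerates to zero components predict the training Y mean.
// [[Rcpp::export]]
double cpp_loocv_msep(const arma::mat& X, const arma::mat& Y,
                      int ncomp, int nkeep, double tol) {
  const uword n = X.n_rows, K = Y.n_cols;
  double acc = 0.0;
  mat W, T, P, C; vec ssy; rowvec mx, my; double toty;
  for (uword i = 0; i < n; ++i) {
    uvec idx = regspace<uvec>(0, n - 1);
    idx.shed_row(i);
    const mat Xi = X.rows(idx), Yi = Y.rows(idx);
    int h = spls_engine(Xi, Yi, ncomp, nkeep, tol, W, T, P, C, ssy, mx, my, toty);
    rowvec yhat = my;
    if (h > 0) yhat += (X.row(i) - mx) * coef_from(W, P, C, h);
    acc += accu(square(yhat - Y.row(i)));
  }
  return acc / double(n * K);
}
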