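// Training core for the dense attention network (DAN) and the plain
// feed-forward reference network.
//
// Architecture: input (D features) -> per-feature gate logits ->
// softmax = attention distribution a (sums to 1, one weight per input
// feature) -> gated input x * a * D -> dense ReLU hidden layer (H) ->
// dropout -> dense ReLU hidden layer (H/2) -> dropout -> 2-class
// softmax output. Cross-entropy loss with label smoothing, minibatch
// Adam with decoupled weight decay on the dense weights. Setting
// use_gate = false removes the attention layer (feed-forward
// reference model).
//
// All randomness (weight init, minibatch shuffling, dropout masks)
// comes from R's RNG, so results are reproducible with set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat r_randn(unsigned int r, unsigned int c, double sd) {
  mat out(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i)
      out(i, j) = R::norm_rand() * sd;
  return out;
}

static uvec r_shuffle(unsigned int n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (unsigned int i = n - 1; i > 0; --i) {
    unsigned int j = (unsigned int)(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

struct Adam {
  mat m, v;
  Adam(unsigned int r, unsigned int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  // single fused pass; avoids large temporaries on every step
  void step(mat &w, const mat &g, double lr, int t, double wd) {
    const double c1 = 1.0 / (1.0 - std::pow(0.9, t));
    const double c2 = 1.0 / (1.0 - std::pow(0.999, t));
    double *wp = w.memptr(), *mp = m.memptr(), *vp = v.memptr();
    const double *gp = g.memptr();
    const uword n = w.n_elem;
    for (uword i = 0; i < n; ++i) {
      mp[i] = 0.9 * mp[i] + 0.1 * gp[i];
      vp[i] = 0.999 * vp[i] + 0.001 * gp[i] * gp[i];
      wp[i] -= lr * (mp[i] * c1) / (std::sqrt(vp[i] * c2) + 1e-8) +
               lr * wd * wp[i];
    }
  }
};

static mat softmax_rows(const mat &S) {
  vec mx = max(S, 1);
  mat E = exp(S.each_col() - mx);
  return E.each_col() / sum(E, 1);
}

static mat dropmask(unsigned int m, unsigned int H, double p) {
  mat d(m, H, fill::ones);
  if (p > 0)
    for (uword j = 0; j < H; ++j)
      for (uword i = 0; i < m; ++i)
        d(i, j) = (R::unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return d;
}

// [[Rcpp::export(name = ".nn_train_cpp")]]
Rcpp::List nn_train_cpp(const arma::mat &X, const arma::ivec &y,
                        int hidden, double dropout, int epochs, double lr,
                        int batch, double weight_decay, double label_smoothing,
                        bool use_gate, double input_noise) {
  const unsigned int n = X.n_rows, D = X.n_cols;
  const unsigned int H1 = (unsigned int)hidden, H2 = std::max(2u, H1 / 2);
  const double ls = label_smoothing, wd = weight_decay;

  rowvec g(D, fill::zeros);
  mat W1 = r_randn(D, H1, std::sqrt(2.0 / D));
  rowvec b1(H1, fill::zeros);
  mat W2 = r_randn(H1, H2, std::sqrt(2.0 / H1));
  rowvec b2(H2, fill::zeros);
  mat W3 = r_randn(H2, 2, std::sqrt(2.0 / H2));
  rowvec b3(2, fill::zeros);
  Adam sg(1, D), sW1(D, H1), sb1(1, H1), sW2(H1, H2), sb2(1, H2), sW3(H2, 2), sb3(1, 2);
  int t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    uvec idx = r_shuffle(n);
    for (unsigned int st = 0; st < n; st += batch) {
      uvec ii = idx.subvec(st, std::min(st + (unsigned int)batch, n) - 1);
      const unsigned int m = ii.n_elem;
      mat xb = X.rows(ii);
      if (input_noise > 0)          // train-time jitter of the inputs
        xb += r_randn(m, D, input_noise);

      rowvec a(D);
      mat xg;
      if (use_gate) {
        a = exp(g - g.max());
        a /= accu(a);
        xg = xb.each_row() % (a * (double)D);
      } else {
        xg = xb;
      }
      mat h1 = xg * W1; h1.each_row() += b1;
      mat r1 = clamp(h1, 0.0, datum::inf);
      mat d1 = dropmask(m, H1, dropout);
      mat r1d = r1 % d1;
      mat h2 = r1d * W2; h2.each_row() += b2;
      mat r2 = clamp(h2, 0.0, datum::inf);
      mat d2 = dropmask(m, H2, dropout);
      mat r2d = r2 % d2;
      mat o = r2d * W3; o.each_row() += b3;
      mat p = softmax_rows(o);

      mat Y(m, 2, fill::zeros);
      for (uword i = 0; i < m; ++i) {
        Y(i, y[ii[i]] == 1 ? 1 : 0) = 1.0 - ls;
        Y(i, y[ii[i]] == 1 ? 0 : 1) = ls;
      }
      mat dout = (p - Y) / (double)m;
      mat gW3 = r2d.t() * dout;
      rowvec gb3 = sum(dout, 0);
      mat dr2 = (dout * W3.t()) % d2 % conv_to<mat>::from(h2 > 0);
      mat gW2 = r1d.t() * dr2;
      rowvec gb2 = sum(dr2, 0);
      mat dr1 = (dr2 * W2.t()) % d1 % conv_to<mat>::from(h1 > 0);
      mat gW1 = xg.t() * dr1;
      rowvec gb1 = sum(dr1, 0);

      ++t;
      if (use_gate) {
        mat dxg = dr1 * W1.t();
        rowvec da = sum(dxg % xb, 0) * (double)D;
        rowvec gg = a % (da - accu(da % a));
        mat gm = g, ggr = gg;
        sg.step(gm, ggr, lr, t, 0.0);
        g = gm.row(0);
      }
      sW1.step(W1, gW1, lr, t, wd);
      mat x1 = b1, y1 = gb1; sb1.step(x1, y1, lr, t, 0.0); b1 = x1.row(0);
      sW2.step(W2, gW2, lr, t, wd);
      mat x2 = b2, y2 = gb2; sb2.step(x2, y2, lr, t, 0.0); b2 = x2.row(0);
      sW3.step(W3, gW3, lr, t, wd);
      mat x3 = b3, y3 = gb3; sb3.step(x3, y3, lr, t, 0.0); b3 = x3.row(0);
    }
  }

  rowvec a = exp(g - g.max());
  a /= accu(a);
  return Rcpp::List::create(
      Rcpp::Named("gate") = Rcpp::NumericVector(g.begin(), g.end()),
      Rcpp::Named("attention") = Rcpp::NumericVector(a.begin(), a.end()),
      Rcpp::Named("W1") = W1,
      Rcpp::Named("b1") = Rcpp::NumericVector(b1.begin(), b1.end()),
      Rcpp::Named("W2") = W2,
      Rcpp::Named("b2") = Rcpp::NumericVector(b2.begin(), b2.end()),
      Rcpp::Named("W3") = W3,
      Rcpp::Named("b3") = Rcpp::NumericVector(b3.begin(), b3.end()),
      Rcpp::Named("use_gate") = use_gate);
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
arma::mat nn_forward_cpp(const arma::mat &X, const arma::rowvec &gate,
                         const arma::mat &W1, const arma::rowvec &b1,
                         const arma::mat &W2, const arma::rowvec &b2,
                         const arma::mat &W3, const arma::rowvec &b3,
                         bool use_gate) {
  mat xg;
  if (use_gate) {
    rowvec a = exp(gate - gate.max());
    a /= accu(a);
    xg = X.each_row() % (a * (double)X.n_cols);
  } else {
    xg = X;
  }
  mat r1 = clamp(xg * W1 + repmat(b1, X.n_rows, 1), 0.0, datum::inf);
  mat r2 = clamp(r1 * W2 + repmat(b2, X.n_rows, 1), 0.0, datum::inf);
  mat o = r2 * W3 + repmat(b3, X.n_rows, 1);
  return softmax_rows(o);
}
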