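// CPU kernels for the segmentation network: same-padding stride-1
// convolution via im2col + GEMM, 2x2 max-pooling, 2x2 stride-2 transpose
// convolution, and depthwise 3x3 convolution. Feature maps are (h, w, c)
// arrays; conv weights arrive flattened column-major from (k, k, cin, cout)
// so matrix row index a + k*b + k*k*ci matches R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int pad = (k - 1) / 2;
  mat C(h * w, k * k * cin, fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    const mat& xs = x.slice(ci);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * ci;
        const int dr = a - pad, dc = b - pad;
        for (int j = 0; j < w; ++j) {
          const int js = j + dc;
          if (js < 0 || js >= w) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
          for (int i = r0; i < r1; ++i)
            C(i + h * j, col) = xs(i + dr, js);
        }
      }
    }
  }
  return C;
}

// scatter-add transpose of im2col
static cube col2im(const mat& C, const int h, const int w, const int cin,
                   const int k) {
  const int pad = (k - 1) / 2;
  cube dx(h, w, cin, fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    mat& xs = dx.slice(ci);
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int col = a + k * b + k * k * ci;
        const int dr = a - pad, dc = b - pad;
        for (int j = 0; j < w; ++j) {
          const int js = j + dc;
          if (js < 0 || js >= w) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(h, h - dr);
          for (int i = r0; i < r1; ++i)
            xs(i + dr, js) += C(i + h * j, col);
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, const int k) {
  const int h = x.n_rows, w = x.n_cols;
  const int cout = W.n_cols;
  mat Y = im2col(x, k) * W;
  Y.each_row() += b.t();
  cube y(h, w, cout);
  for (int co = 0; co < cout; ++co)
    y.slice(co) = reshape(Y.col(co), h, w);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& W,
                       const arma::cube& dy, const int k) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  mat dY(h * w, cout);
  for (int co = 0; co < cout; ++co)
    dY.col(co) = vectorise(dy.slice(co));
  mat C = im2col(x, k);
  mat dW = C.t() * dY;
  vec db = sum(dY, 0).t();
  cube dx = col2im(dY * W.t(), h, w, cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int h2 = h / 2, w2 = w / 2;
  cube y(h2, w2, c);
  Rcpp::IntegerVector idx(h2 * w2 * c);
  int q = 0;
  for (int ci = 0; ci < c; ++ci) {
    const mat& xs = x.slice(ci);
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        double best = xs(2 * i, 2 * j);
        int code = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double v = xs(2 * i + a, 2 * j + b);
            if (v > best) { best = v; code = a + 2 * b; }
          }
        y(i, j, ci) = best;
        idx[q++] = code;
      }
    }
  }
  idx.attr("dim") = Rcpp::IntegerVector::create(h2, w2, c);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const Rcpp::IntegerVector& idx, const arma::cube& dy,
                          const int h, const int w) {
  const int h2 = dy.n_rows, w2 = dy.n_cols, c = dy.n_slices;
  cube dx(h, w, c, fill::zeros);
  int q = 0;
  for (int ci = 0; ci < c; ++ci) {
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        const int code = idx[q++];
        dx(2 * i + (code % 2), 2 * j + (code / 2), ci) += dy(i, j, ci);
      }
    }
  }
  return dx;
}

// W flattened from (2, 2, cin, cout): row index a + 2*b + 4*ci.
static mat upc_block(const mat& W, const int a, const int b, const int cin) {
  mat Wab(cin, W.n_cols);
  for (int ci = 0; ci < cin; ++ci)
    Wab.row(ci) = W.row(a + 2 * b + 4 * ci);
  return Wab;
}

// [[Rcpp::export]]
arma::cube cpp_upconv_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = W.n_cols;
  mat Xm(h * w, cin);
  for (int ci = 0; ci < cin; ++ci)
    Xm.col(ci) = vectorise(x.slice(ci));
  cube y(2 * h, 2 * w, cout);
  for (int bb = 0; bb < 2; ++bb) {
    for (int aa = 0; aa < 2; ++aa) {
      mat Yab = Xm * upc_block(W, aa, bb, cin);
      Yab.each_row() += b.t();
      for (int co = 0; co < cout; ++co) {
        mat& ys = y.slice(co);
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i)
            ys(2 * i + aa, 2 * j + bb) = Yab(i + h * j, co);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv_bw(const arma::cube& x, const arma::mat& W,
                         const arma::cube& dy) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = dy.n_slices;
  mat Xm(h * w, cin);
  for (int ci = 0; ci < cin; ++ci)
    Xm.col(ci) = vectorise(x.slice(ci));
  mat dXm(h * w, cin, fill::zeros);
  mat dW(4 * cin, cout, fill::zeros);
  vec db(cout, fill::zeros);
  for (int bb = 0; bb < 2; ++bb) {
    for (int aa = 0; aa < 2; ++aa) {
      mat dYab(h * w, cout);
      for (int co = 0; co < cout; ++co) {
        const mat& ds = dy.slice(co);
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i)
            dYab(i + h * j, co) = ds(2 * i + aa, 2 * j + bb);
      }
      dXm += dYab * upc_block(W, aa, bb, cin).t();
      mat dWab = Xm.t() * dYab;
      for (int ci = 0; ci < cin; ++ci)
        dW.row(aa + 2 * bb + 4 * ci) += dWab.row(ci);
      db += sum(dYab, 0).t();
    }
  }
  cube dx(h, w, cin);
  for (int ci = 0; ci < cin; ++ci)
    dx.slice(ci) = reshape(dXm.col(ci), h, w);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_dwconv_fw(const arma::cube& x, const arma::cube& Wd,
                         const arma::vec& b) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int k = Wd.n_rows, pad = (k - 1) / 2;
  cube y(h, w, c);
  for (int ci = 0; ci < c; ++ci) {
    const mat& xs = x.slice(ci);
    const mat& ws = Wd.slice(ci);
    mat& ys = y.slice(ci);
    ys.fill(b(ci));
    for (int bb = 0; bb < k; ++bb) {
      for (int aa = 0; aa < k; ++aa) {
        const double wv = ws(aa, bb);
        if (wv == 0.0) continue;
        const int dr = aa - pad, dc = bb - pad;
        const int j0 = std::max(0, -dc), j1 = std::min(w, w - dc);
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            ys(i, j) += wv * xs(i + dr, j + dc);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_dwconv_bw(const arma::cube& x, const arma::cube& Wd,
                         const arma::cube& dy) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int k = Wd.n_rows, pad = (k - 1) / 2;
  cube dx(h, w, c, fill::zeros);
  cube dWd(k, k, c, fill::zeros);
  vec db(c, fill::zeros);
  for (int ci = 0; ci < c; ++ci) {
    const mat& xs = x.slice(ci);
    const mat& ws = Wd.slice(ci);
    const mat& ds = dy.slice(ci);
    mat& dxs = dx.slice(ci);
    mat& dws = dWd.slice(ci);
    db(ci) = accu(ds);
    for (int bb = 0; bb < k; ++bb) {
      for (int aa = 0; aa < k; ++aa) {
        const int dr = aa - pad, dc = bb - pad;
        const int j0 = std::max(0, -dc), j1 = std::min(w, w - dc);
        const int i0 = std::max(0, -dr), i1 = std::min(h, h - dr);
        double g = 0.0;
        const double wv = ws(aa, bb);
        for (int j = j0; j < j1; ++j) {
          for (int i = i0; i < i1; ++i) {
            g += ds(i, j) * xs(i + dr, j + dc);
            dxs(i + dr, j + dc) += wv * ds(i, j);
          }
        }
        dws(aa, bb) = g;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dWd,
                            Rcpp::Named("db") = db);
}
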