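// Low-level tensor ops for the segmentation network.
//
// Feature maps are R arrays of dim (H, W, C), mapped without copy onto
// arma::cube (column-major, slice = channel).  Because slices are
// contiguous, the same memory doubles as an (H*W) x C matrix, so every
// convolution reduces to a handful of GEMMs over spatially shifted copies
// of the input (one per kernel tap) -- no im2col buffer is ever held.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube view_cube(Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  return cube(x.begin(), d[0], d[1], d[2], false, true);
}

static Rcpp::NumericVector wrap_cube(const cube& c) {
  Rcpp::NumericVector out(c.begin(), c.end());
  out.attr("dim") = Rcpp::IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// weight tensor w has dim (kh, kw, Cin, Cout); tap (oi, oj) as Cin x Cout
static mat tap_matrix(const Rcpp::NumericVector& w, int kh, int kw,
                      int cin, int cout, int oi, int oj) {
  mat wk(cin, cout);
  const double* p = w.begin();
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      wk(ci, co) = p[(std::size_t)oi + kh * oj + (std::size_t)kh * kw * ci +
                     (std::size_t)kh * kw * cin * co];
  return wk;
}

// s(i, j, c) = x(i + di, j + dj, c), zero outside the frame
static cube shifted(const cube& x, int di, int dj) {
  cube s(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  int H = x.n_rows, W = x.n_cols;
  int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
  int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
  if (r0 <= r1 && c0 <= c1)
    s.subcube(r0, c0, 0, r1, c1, x.n_slices - 1) =
        x.subcube(r0 + di, c0 + dj, 0, r1 + di, c1 + dj, x.n_slices - 1);
  return s;
}

// d(i, j, c) += s(i + di, j + dj, c) over the valid overlap
static void add_shifted(cube& d, const cube& s, int di, int dj) {
  int H = d.n_rows, W = d.n_cols;
  int r0 = std::max(0, -di), r1 = std::min(H - 1, H - 1 - di);
  int c0 = std::max(0, -dj), c1 = std::min(W - 1, W - 1 - dj);
  if (r0 <= r1 && c0 <= c1)
    d.subcube(r0, c0, 0, r1, c1, d.n_slices - 1) +=
        s.subcube(r0 + di, c0 + dj, 0, r1 + di, c1 + dj, s.n_slices - 1);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_fwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                                   Rcpp::NumericVector b_) {
  cube x = view_cube(x_);
  Rcpp::IntegerVector wd = w_.attr("dim");
  int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  int H = x.n_rows, W = x.n_cols;

  cube out(H, W, cout, fill::zeros);
  mat om(out.memptr(), (std::size_t)H * W, cout, false, true);

  for (int oi = 0; oi < kh; ++oi) {
    for (int oj = 0; oj < kw; ++oj) {
      mat wk = tap_matrix(w_, kh, kw, cin, cout, oi, oj);
      int di = oi - ph, dj = oj - pw;
      if (di == 0 && dj == 0) {
        mat xm(const_cast<double*>(x.memptr()), (std::size_t)H * W, cin, false, true);
        om += xm * wk;
      } else {
        cube s = shifted(x, di, dj);
        mat sm(s.memptr(), (std::size_t)H * W, cin, false, true);
        om += sm * wk;
      }
    }
  }
  rowvec b(b_.begin(), cout);
  om.each_row() += b;
  return wrap_cube(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                          Rcpp::NumericVector g_) {
  cube x = view_cube(x_);
  cube g = view_cube(g_);
  Rcpp::IntegerVector wd = w_.attr("dim");
  int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  int H = x.n_rows, W = x.n_cols;

  mat gm(g.memptr(), (std::size_t)H * W, cout, false, true);
  cube gx(H, W, cin, fill::zeros);
  Rcpp::NumericVector gw_(Rcpp::no_init(w_.size()));
  gw_.attr("dim") = wd;
  double* gwp = gw_.begin();

  for (int oi = 0; oi < kh; ++oi) {
    for (int oj = 0; oj < kw; ++oj) {
      mat wk = tap_matrix(w_, kh, kw, cin, cout, oi, oj);
      int di = oi - ph, dj = oj - pw;

      mat gwk;
      if (di == 0 && dj == 0) {
        mat xm(const_cast<double*>(x.memptr()), (std::size_t)H * W, cin, false, true);
        gwk = xm.t() * gm;
      } else {
        cube s = shifted(x, di, dj);
        mat sm(s.memptr(), (std::size_t)H * W, cin, false, true);
        gwk = sm.t() * gm;
      }
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gwp[(std::size_t)oi + kh * oj + (std::size_t)kh * kw * ci +
              (std::size_t)kh * kw * cin * co] = gwk(ci, co);

      // out(i,j) consumed x(i+di, j+dj): scatter g * W^T back
      mat tm = gm * wk.t();
      cube tc(tm.memptr(), H, W, cin, false, true);
      add_shifted(gx, tc, -di, -dj);
    }
  }
  rowvec gb = sum(gm, 0);
  return Rcpp::List::create(Rcpp::Named("gx") = wrap_cube(gx),
                            Rcpp::Named("gw") = gw_,
                            Rcpp::Named("gb") = Rcpp::NumericVector(gb.begin(), gb.end()));
}

// 2x2 max pooling, stride 2; idx records the winning corner (0..3)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(Rcpp::NumericVector x_) {
  cube x = view_cube(x_);
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  Rcpp::IntegerVector idx((std::size_t)Ho * Wo * C);
  idx.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C);
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bk = 0;
        for (int k = 1; k < 4; ++k) {
          double v = x(2 * i + (k & 1), 2 * j + (k >> 1), c);
          if (v > best) { best = v; bk = k; }
        }
        out(i, j, c) = best;
        ip[(std::size_t)i + Ho * j + (std::size_t)Ho * Wo * c] = bk;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = wrap_cube(out),
                            Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_maxpool_bwd(Rcpp::NumericVector g_, Rcpp::IntegerVector idx,
                                    int H, int W) {
  cube g = view_cube(g_);
  int Ho = g.n_rows, Wo = g.n_cols, C = g.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int k = ip[(std::size_t)i + Ho * j + (std::size_t)Ho * Wo * c];
        gx(2 * i + (k & 1), 2 * j + (k >> 1), c) += g(i, j, c);
      }
  return wrap_cube(gx);
}

// transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling):
// out(2i+oi, 2j+oj, co) = sum_ci x(i, j, ci) * w(oi, oj, ci, co) + b(co)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_upconv_fwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                                   Rcpp::NumericVector b_) {
  cube x = view_cube(x_);
  Rcpp::IntegerVector wd = w_.attr("dim");
  int cin = wd[2], cout = wd[3];
  int H = x.n_rows, W = x.n_cols;
  mat xm(const_cast<double*>(x.memptr()), (std::size_t)H * W, cin, false, true);
  cube out(2 * H, 2 * W, cout);
  for (int oi = 0; oi < 2; ++oi) {
    for (int oj = 0; oj < 2; ++oj) {
      mat wk = tap_matrix(w_, 2, 2, cin, cout, oi, oj);
      mat tm = xm * wk;
      cube tc(tm.memptr(), H, W, cout, false, true);
      for (int c = 0; c < cout; ++c)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            out(2 * i + oi, 2 * j + oj, c) = tc(i, j, c) + b_[c];
    }
  }
  return wrap_cube(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv_bwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                          Rcpp::NumericVector g_) {
  cube x = view_cube(x_);
  cube g = view_cube(g_);
  Rcpp::IntegerVector wd = w_.attr("dim");
  int cin = wd[2], cout = wd[3];
  int H = x.n_rows, W = x.n_cols;
  mat xm(const_cast<double*>(x.memptr()), (std::size_t)H * W, cin, false, true);

  cube gx(H, W, cin, fill::zeros);
  mat gxm(gx.memptr(), (std::size_t)H * W, cin, false, true);
  Rcpp::NumericVector gw_(Rcpp::no_init(w_.size()));
  gw_.attr("dim") = wd;
  double* gwp = gw_.begin();
  vec gb(cout, fill::zeros);

  for (int oi = 0; oi < 2; ++oi) {
    for (int oj = 0; oj < 2; ++oj) {
      cube gsub(H, W, cout);
      for (int c = 0; c < cout; ++c)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            gsub(i, j, c) = g(2 * i + oi, 2 * j + oj, c);
      mat gsm(gsub.memptr(), (std::size_t)H * W, cout, false, true);
      mat wk = tap_matrix(w_, 2, 2, cin, cout, oi, oj);
      mat gwk = xm.t() * gsm;
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gwp[(std::size_t)oi + 2 * oj + (std::size_t)4 * ci +
              (std::size_t)4 * cin * co] = gwk(ci, co);
      gxm += gsm * wk.t();
      gb += sum(gsm, 0).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = wrap_cube(gx),
                            Rcpp::Named("gw") = gw_,
                            Rcpp::Named("gb") = Rcpp::NumericVector(gb.begin(), gb.end()));
}
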