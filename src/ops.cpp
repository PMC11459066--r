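// Low-level layer primitives for the segmentation network.
// Feature maps are H x W x C numeric arrays (arma::cube, column-major, row
// index fastest — matching R's array layout). Convolutions are 3x3, stride 1,
// zero padding 1, implemented as im2col + BLAS GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Build the transposed im2col matrix: At is (H*W) x (9*Cin) with
// At(h + H*w, kh+1 + 3*(kw+1) + 9*ci) = x(h+kh, w+kw, ci), zero outside.
// Column r of At has the same memory layout as an H x W matrix, so each
// column is a shifted copy of one input slice.
arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat At(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword ci = 0; ci < C; ++ci) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const arma::uword r = (kh + 1) + 3 * (kw + 1) + 9 * ci;
        arma::mat V(At.colptr(r), H, W, false, true);
        const int h0 = kh < 0 ? 1 : 0, h1 = kh > 0 ? (int)H - 2 : (int)H - 1;
        const int w0 = kw < 0 ? 1 : 0, w1 = kw > 0 ? (int)W - 2 : (int)W - 1;
        if (h0 > h1 || w0 > w1) continue;  // 1-pixel extent: nothing in range
        V.submat(h0, w0, h1, w1) =
          x.slice(ci).submat(h0 + kh, w0 + kw, h1 + kh, w1 + kw);
      }
    }
  }
  return At;
}

arma::cube cube_from(const NumericVector& v) {
  const IntegerVector d = v.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (H x W x C)");
  return arma::cube(const_cast<double*>(v.begin()), d[0], d[1], d[2], false);
}

NumericVector cube_to(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

}  // namespace

// 3x3 same-padding convolution. w has dim (3, 3, Cin, Cout); b has length
// Cout. Returns H x W x Cout.
// [[Rcpp::export]]
NumericVector conv3x3Forward(NumericVector x, NumericVector w, NumericVector b) {
  const arma::cube xc = cube_from(x);
  const IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 3 || wd[1] != 3)
    stop("weights must have dim (3, 3, Cin, Cout)");
  const arma::uword Cin = wd[2], Cout = wd[3];
  if (xc.n_slices != Cin) stop("input channel count does not match weights");
  const arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false);
  const arma::mat At = im2col3(xc);
  arma::mat Y = At * Wm;  // (H*W) x Cout
  arma::cube yc(Y.memptr(), xc.n_rows, xc.n_cols, Cout);
  const arma::vec bv(const_cast<double*>(b.begin()), Cout, false);
  for (arma::uword co = 0; co < Cout; ++co) yc.slice(co) += bv[co];
  return cube_to(yc);
}

// Gradients of the 3x3 convolution. gy is H x W x Cout. Returns
// list(gx, gw, gb).
// [[Rcpp::export]]
List conv3x3Backward(NumericVector x, NumericVector w, NumericVector gy) {
  const arma::cube xc = cube_from(x), gyc = cube_from(gy);
  const IntegerVector wd = w.attr("dim");
  const arma::uword Cin = wd[2], Cout = wd[3];
  const arma::uword H = xc.n_rows, W = xc.n_cols;
  const arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false);
  const arma::mat gYm(const_cast<double*>(gy.begin()), H * W, Cout, false);

  const arma::mat At = im2col3(xc);
  arma::mat gW = At.t() * gYm;                    // (9*Cin) x Cout
  arma::rowvec gb = arma::sum(gYm, 0);            // 1 x Cout
  arma::mat gAt = gYm * Wm.t();                   // (H*W) x (9*Cin)

  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (arma::uword ci = 0; ci < Cin; ++ci) {
    for (int kw = -1; kw <= 1; ++kw) {
      for (int kh = -1; kh <= 1; ++kh) {
        const arma::uword r = (kh + 1) + 3 * (kw + 1) + 9 * ci;
        arma::mat V(gAt.colptr(r), H, W, false, true);
        const int h0 = kh < 0 ? 1 : 0, h1 = kh > 0 ? (int)H - 2 : (int)H - 1;
        const int w0 = kw < 0 ? 1 : 0, w1 = kw > 0 ? (int)W - 2 : (int)W - 1;
        if (h0 > h1 || w0 > w1) continue;
        gx.slice(ci).submat(h0 + kh, w0 + kw, h1 + kh, w1 + kw) +=
          V.submat(h0, w0, h1, w1);
      }
    }
  }

  NumericVector gwOut(gW.begin(), gW.end());
  gwOut.attr("dim") = IntegerVector::create(3, 3, (int)Cin, (int)Cout);
  return List::create(_["gx"] = cube_to(gx), _["gw"] = gwOut,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 max-pool, stride 2. Returns list(y, idx) where idx in {0,1,2,3} encodes
// the argmax corner (dh + 2*dw) for routing gradients; ties break toward the
// first element in column-major order.
// [[Rcpp::export]]
List maxpool2Forward(NumericVector x) {
  const arma::cube xc = cube_from(x);
  const arma::uword H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  if (H % 2 || W % 2) stop("spatial dimensions must be even for 2x2 max-pool");
  arma::cube y(H / 2, W / 2, C);
  arma::ucube idx(H / 2, W / 2, C);
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < W / 2; ++j) {
      for (arma::uword i = 0; i < H / 2; ++i) {
        double best = xc(2 * i, 2 * j, c);
        arma::uword bi = 0;
        const double cand[3] = { xc(2 * i + 1, 2 * j, c),
                                 xc(2 * i, 2 * j + 1, c),
                                 xc(2 * i + 1, 2 * j + 1, c) };
        for (arma::uword k = 0; k < 3; ++k)
          if (cand[k] > best) { best = cand[k]; bi = k + 1; }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  IntegerVector idxOut(idx.begin(), idx.end());
  idxOut.attr("dim") = IntegerVector::create(H / 2, W / 2, C);
  return List::create(_["y"] = cube_to(y), _["idx"] = idxOut);
}

// Route max-pool gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector maxpool2Backward(NumericVector gy, IntegerVector idx) {
  const arma::cube gyc = cube_from(gy);
  const arma::uword h = gyc.n_rows, w = gyc.n_cols, C = gyc.n_slices;
  arma::cube gx(2 * h, 2 * w, C, arma::fill::zeros);
  const int* ip = idx.begin();
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < w; ++j)
      for (arma::uword i = 0; i < h; ++i) {
        const int k = ip[i + h * j + h * w * c];
        gx(2 * i + (k & 1), 2 * j + (k >> 1), c) += gyc(i, j, c);
      }
  return cube_to(gx);
}

namespace {

// 1-d doubling interpolation along rows with half-pixel centers: output row
// 2r mixes rows (r-1, r) with weights (1/4, 3/4); row 2r+1 mixes (r, r+1)
// with (3/4, 1/4); out-of-range taps clamp to the edge. The doubling of a
// single row is therefore that row repeated.
arma::mat up_rows(const arma::mat& a) {
  const arma::uword H = a.n_rows;
  arma::mat out(2 * H, a.n_cols);
  for (arma::uword r = 0; r < H; ++r) {
    const arma::uword rm = r == 0 ? 0 : r - 1, rp = r + 1 == H ? r : r + 1;
    out.row(2 * r) = 0.25 * a.row(rm) + 0.75 * a.row(r);
    out.row(2 * r + 1) = 0.75 * a.row(r) + 0.25 * a.row(rp);
  }
  return out;
}

arma::mat up_rows_adj(const arma::mat& g) {
  const arma::uword H = g.n_rows / 2;
  arma::mat out(H, g.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < H; ++r) {
    const arma::uword rm = r == 0 ? 0 : r - 1, rp = r + 1 == H ? r : r + 1;
    out.row(rm) += 0.25 * g.row(2 * r);
    out.row(r) += 0.75 * g.row(2 * r);
    out.row(r) += 0.75 * g.row(2 * r + 1);
    out.row(rp) += 0.25 * g.row(2 * r + 1);
  }
  return out;
}

}  // namespace

// 2x bilinear upsampling with half-pixel alignment (the doubling of a 1x1
// map is constant). Separable: rows then columns.
// [[Rcpp::export]]
NumericVector upsample2Forward(NumericVector x) {
  const arma::cube xc = cube_from(x);
  arma::cube y(2 * xc.n_rows, 2 * xc.n_cols, xc.n_slices);
  for (arma::uword c = 0; c < xc.n_slices; ++c)
    y.slice(c) = up_rows(up_rows(xc.slice(c).t()).t());
  return cube_to(y);
}

// Adjoint (transpose) of upsample2Forward, for backpropagation.
// [[Rcpp::export]]
NumericVector upsample2Adjoint(NumericVector gy) {
  const arma::cube gc = cube_from(gy);
  if (gc.n_rows % 2 || gc.n_cols % 2) stop("gradient dims must be even");
  arma::cube gx(gc.n_rows / 2, gc.n_cols / 2, gc.n_slices);
  for (arma::uword c = 0; c < gc.n_slices; ++c)
    gx.slice(c) = up_rows_adj(up_rows_adj(gc.slice(c).t()).t());
  return cube_to(gx);
}
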