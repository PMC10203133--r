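#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3D "same" convolution (zero padding), float32 internally. Feature maps
// are matrices of shape (D*H*W, C): voxels column-major (x fastest), one
// column per channel. Weights are ((k^3*Cin), Cout) with row block o*Cin +
// cin, o enumerating kernel offsets column-major over (dx, dy, dz) in
// {-p..p}^3. Instead of one monolithic im2col buffer, the kernel loops
// over the k^3 offsets and accumulates a GEMM per offset through a small
// shift buffer — much lighter on memory bandwidth for narrow channel
// counts.

// buf = x shifted by (-dx, -dy, -dz) with zero fill, all channels
static void fill_shift(const arma::fmat& x, int D, int H, int W,
                       int dx, int dy, int dz, arma::fmat& buf) {
  int C = x.n_cols;
  buf.zeros();
  int xlo = std::max(0, -dx), xhi = std::min(D, D - dx);
  if (xlo >= xhi) return;
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* dst = buf.colptr(c);
    for (int z = 0; z < W; ++z) {
      int zz = z + dz;
      if (zz < 0 || zz >= W) continue;
      for (int y = 0; y < H; ++y) {
        int yy = y + dy;
        if (yy < 0 || yy >= H) continue;
        std::memcpy(dst + (size_t)xlo + (size_t)D * (y + (size_t)H * z),
                    src + (size_t)(xlo + dx) + (size_t)D * (yy + (size_t)H * zz),
                    sizeof(float) * (xhi - xlo));
      }
    }
  }
}

// scatter-add of buf shifted by (+dx, +dy, +dz) into out (adjoint of
// fill_shift)
static void add_shift(const arma::fmat& buf, int D, int H, int W,
                      int dx, int dy, int dz, arma::fmat& out) {
  int C = out.n_cols;
  int xlo = std::max(0, -dx), xhi = std::min(D, D - dx);
  if (xlo >= xhi) return;
  for (int c = 0; c < C; ++c) {
    const float* src = buf.colptr(c);
    float* dst = out.colptr(c);
    for (int z = 0; z < W; ++z) {
      int zz = z + dz;
      if (zz < 0 || zz >= W) continue;
      for (int y = 0; y < H; ++y) {
        int yy = y + dy;
        if (yy < 0 || yy >= H) continue;
        const float* s = src + (size_t)xlo + (size_t)D * (y + (size_t)H * z);
        float* d = dst + (size_t)(xlo + dx) + (size_t)D * (yy + (size_t)H * zz);
        for (int x1 = xlo; x1 < xhi; ++x1) *d++ += *s++;
      }
    }
  }
}

static arma::fmat to_f(const NumericMatrix& m) {
  arma::fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_forward(NumericMatrix x, IntegerVector dims,
                                NumericMatrix w, NumericVector bias, int k) {
  int D = dims[0], H = dims[1], W = dims[2];
  int p = k / 2, k3 = k * k * k;
  arma::fmat xf = to_f(x), wf = to_f(w);
  int Cin = xf.n_cols, Cout = wf.n_cols;
  size_t N = (size_t)D * H * W;
  arma::fmat y(N, Cout, arma::fill::zeros);
  arma::fmat buf(N, Cin);
  for (int o = 0; o < k3; ++o) {
    int dx = o % k - p, dy = (o / k) % k - p, dz = o / (k * k) - p;
    if (dx == 0 && dy == 0 && dz == 0) {
      y += xf * wf.rows((size_t)o * Cin, (size_t)(o + 1) * Cin - 1);
    } else {
      fill_shift(xf, D, H, W, dx, dy, dz, buf);
      y += buf * wf.rows((size_t)o * Cin, (size_t)(o + 1) * Cin - 1);
    }
  }
  arma::frowvec bf(Cout);
  for (int c = 0; c < Cout; ++c) bf(c) = (float)bias[c];
  y.each_row() += bf;
  NumericMatrix out(N, Cout);
  std::copy(y.begin(), y.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericMatrix x, IntegerVector dims,
                        NumericMatrix w, NumericMatrix dy, int k) {
  int D = dims[0], H = dims[1], W = dims[2];
  int p = k / 2, k3 = k * k * k;
  arma::fmat xf = to_f(x), wf = to_f(w), dyf = to_f(dy);
  int Cin = xf.n_cols;
  size_t N = (size_t)D * H * W;
  arma::fmat dwf(wf.n_rows, wf.n_cols, arma::fill::zeros);
  arma::fmat dxf(N, Cin, arma::fill::zeros);
  arma::fmat buf(N, Cin), dbuf(N, Cin);
  for (int o = 0; o < k3; ++o) {
    int dx = o % k - p, dy2 = (o / k) % k - p, dz = o / (k * k) - p;
    arma::span rows((size_t)o * Cin, (size_t)(o + 1) * Cin - 1);
    if (dx == 0 && dy2 == 0 && dz == 0) {
      dwf.rows(rows) = xf.t() * dyf;
      dxf += dyf * wf.rows(rows).t();
    } else {
      fill_shift(xf, D, H, W, dx, dy2, dz, buf);
      dwf.rows(rows) = buf.t() * dyf;
      dbuf = dyf * wf.rows(rows).t();
      add_shift(dbuf, D, H, W, dx, dy2, dz, dxf);
    }
  }
  arma::frowvec dbf = arma::sum(dyf, 0);
  NumericMatrix dxo(N, Cin), dwo(dwf.n_rows, dwf.n_cols);
  std::copy(dxf.begin(), dxf.end(), dxo.begin());
  std::copy(dwf.begin(), dwf.end(), dwo.begin());
  NumericVector dbo(dbf.n_elem);
  std::copy(dbf.begin(), dbf.end(), dbo.begin());
  return List::create(_["dx"] = dxo, _["dw"] = dwo, _["db"] = dbo);
}
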