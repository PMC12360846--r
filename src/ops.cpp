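// Volumetric neural-network primitives: 3D convolution (im2col + BLAS),
// 2x2x2 max pooling, and trilinear resizing with its adjoint.
//
// Array layout matches R's column-major order: a volume with C channels is
// a numeric array dim = c(nx, ny, nz, C); index x is fastest.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Build the patch matrix P (K x Nout), K = kx*ky*kz*Cin, column j holds the
// receptive field of output voxel j (zero padding).
static void im2col(const double* x, int nx, int ny, int nz, int cin,
                   int k, int stride, int pad, arma::mat& P) {
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  const long nout = (long)ox * oy * oz;
  P.zeros((long)k * k * k * cin, nout);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (long)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const long row = kx + (long)k * (ky + (long)k * (kz + (long)k * c));
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride + kz - pad;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              if (iy < 0 || iy >= ny) continue;
              const long colbase = (long)ox * (y + (long)oy * z);
              const long inbase = (long)nx * (iy + (long)ny * iz);
              for (int xo = 0; xo < ox; ++xo) {
                const int ix = xo * stride + kx - pad;
                if (ix < 0 || ix >= nx) continue;
                P(row, colbase + xo) = xc[inbase + ix];
              }
            }
          }
        }
  }
}

// Scatter-add of the patch-matrix gradient back onto the input grid.
static void col2im(const arma::mat& dP, int nx, int ny, int nz, int cin,
                   int k, int stride, int pad, double* dx) {
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  for (int c = 0; c < cin; ++c) {
    double* xc = dx + (long)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const long row = kx + (long)k * (ky + (long)k * (kz + (long)k * c));
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride + kz - pad;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              if (iy < 0 || iy >= ny) continue;
              const long colbase = (long)ox * (y + (long)oy * z);
              const long inbase = (long)nx * (iy + (long)ny * iz);
              for (int xo = 0; xo < ox; ++xo) {
                const int ix = xo * stride + kx - pad;
                if (ix < 0 || ix >= nx) continue;
                xc[inbase + ix] += dP(row, colbase + xo);
              }
            }
          }
        }
  }
}

// x: (nx,ny,nz,Cin); w: (k,k,k,Cin,Cout); returns (ox,oy,oz,Cout)
// [[Rcpp::export(name = "cpp_conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("conv3d: channel mismatch");
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1) stop("conv3d: output size < 1");
  arma::mat P;
  im2col(x.begin(), nx, ny, nz, cin, k, stride, pad, P);
  const arma::mat W(const_cast<double*>(w.begin()), (long)k * k * k * cin,
                    cout, false, true);
  arma::mat O = W.t() * P;  // (Cout x Nout)
  NumericVector out((long)ox * oy * oz * cout);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  const long nvox = (long)ox * oy * oz;
  for (int c = 0; c < cout; ++c) {
    const double b = bias[c];
    double* oc = out.begin() + (long)c * nvox;
    for (long j = 0; j < nvox; ++j) oc[j] = O(c, j) + b;
  }
  return out;
}

// [[Rcpp::export(name = "cpp_conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector gout,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gout.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  const long nvox = (long)gd[0] * gd[1] * gd[2];
  arma::mat P;
  im2col(x.begin(), nx, ny, nz, cin, k, stride, pad, P);
  // gradient wrt output as (Cout x Nout)
  arma::mat G(cout, nvox);
  for (int c = 0; c < cout; ++c) {
    const double* gc = gout.begin() + (long)c * nvox;
    for (long j = 0; j < nvox; ++j) G(c, j) = gc[j];
  }
  const long K = (long)k * k * k * cin;
  const arma::mat W(const_cast<double*>(w.begin()), K, cout, false, true);
  arma::mat dW = P * G.t();        // (K x Cout)
  arma::mat dP = W * G;            // (K x Nout)
  NumericVector dx((long)nx * ny * nz * cin);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  col2im(dP, nx, ny, nz, cin, k, stride, pad, dx.begin());
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  std::copy(dW.begin(), dW.end(), dw.begin());
  NumericVector db(cout);
  for (int c = 0; c < cout; ++c) db[c] = arma::accu(G.row(c));
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 stride-2 max pool; odd trailing voxels are dropped.
// [[Rcpp::export(name = "cpp_maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  if (ox < 1 || oy < 1 || oz < 1) stop("maxpool: input smaller than 2 voxels");
  NumericVector out((long)ox * oy * oz * C);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  IntegerVector arg(out.size());  // 0-based linear index into x
  long j = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * nx * ny * nz;
    const long coff = (long)c * nx * ny * nz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xo = 0; xo < ox; ++xo, ++j) {
          double best = -std::numeric_limits<double>::infinity();
          long bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const long idx = (2 * xo + dx) +
                  (long)nx * ((2 * y + dy) + (long)ny * (2 * z + dz));
                if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
              }
          out[j] = best;
          arg[j] = (int)(coff + bidx);
        }
  }
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = "cpp_maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector gout, IntegerVector argmax,
                                 IntegerVector in_dim) {
  NumericVector dx((long)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (long j = 0; j < gout.size(); ++j) dx[argmax[j]] += gout[j];
  return dx;
}

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w1;  // weight of i1; i0 gets (1 - w1)
};

// half-pixel (align_corners = FALSE) source mapping with edge clamping
static AxisMap axis_map(int n_out, int n_in) {
  AxisMap m;
  m.i0.resize(n_out); m.i1.resize(n_out); m.w1.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int t = 0; t < n_out; ++t) {
    double s = (t + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int lo = (int)std::floor(s);
    if (lo > n_in - 2) lo = std::max(0, n_in - 2);
    m.i0[t] = lo;
    m.i1[t] = std::min(lo + 1, n_in - 1);
    m.w1[t] = s - lo;
  }
  return m;
}

// [[Rcpp::export(name = "cpp_resize_trilinear")]]
NumericVector resize_trilinear_cpp(NumericVector x, IntegerVector out_dim) {
  IntegerVector xd = x.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], C = xd[3];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  AxisMap mx = axis_map(ox, nx), my = axis_map(oy, ny), mz = axis_map(oz, nz);
  NumericVector out((long)ox * oy * oz * C);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * nx * ny * nz;
    double* oc = out.begin() + (long)c * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int t = 0; t < ox; ++t) {
          double v = 0;
          for (int dz = 0; dz < 2; ++dz) {
            const double wz = dz ? mz.w1[z] : 1 - mz.w1[z];
            if (wz == 0) continue;
            const int iz = dz ? mz.i1[z] : mz.i0[z];
            for (int dy = 0; dy < 2; ++dy) {
              const double wy = dy ? my.w1[y] : 1 - my.w1[y];
              if (wy == 0) continue;
              const int iy = dy ? my.i1[y] : my.i0[y];
              for (int dx = 0; dx < 2; ++dx) {
                const double wx = dx ? mx.w1[t] : 1 - mx.w1[t];
                if (wx == 0) continue;
                const int ix = dx ? mx.i1[t] : mx.i0[t];
                v += wz * wy * wx * xc[ix + (long)nx * (iy + (long)ny * iz)];
              }
            }
          }
          oc[t + (long)ox * (y + (long)oy * z)] = v;
        }
  }
  return out;
}

// Adjoint of resize_trilinear: scatter gradient from the output grid back.
// [[Rcpp::export(name = "cpp_resize_trilinear_adjoint")]]
NumericVector resize_trilinear_adjoint(NumericVector gout, IntegerVector in_dim) {
  IntegerVector gd = gout.attr("dim");
  const int ox = gd[0], oy = gd[1], oz = gd[2], C = gd[3];
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  AxisMap mx = axis_map(ox, nx), my = axis_map(oy, ny), mz = axis_map(oz, nz);
  NumericVector dx((long)nx * ny * nz * C);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gout.begin() + (long)c * ox * oy * oz;
    double* xc = dx.begin() + (long)c * nx * ny * nz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int t = 0; t < ox; ++t) {
          const double g = gc[t + (long)ox * (y + (long)oy * z)];
          if (g == 0) continue;
          for (int dz = 0; dz < 2; ++dz) {
            const double wz = dz ? mz.w1[z] : 1 - mz.w1[z];
            if (wz == 0) continue;
            const int iz = dz ? mz.i1[z] : mz.i0[z];
            for (int dy = 0; dy < 2; ++dy) {
              const double wy = dy ? my.w1[y] : 1 - my.w1[y];
              if (wy == 0) continue;
              const int iy = dy ? my.i1[y] : my.i0[y];
              for (int dx2 = 0; dx2 < 2; ++dx2) {
                const double wx = dx2 ? mx.w1[t] : 1 - mx.w1[t];
                if (wx == 0) continue;
                const int ix = dx2 ? mx.i1[t] : mx.i0[t];
                xc[ix + (long)nx * (iy + (long)ny * iz)] += wz * wy * wx * g;
              }
            }
          }
        }
  }
  return dx;
}
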