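#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Volumes are R arrays dim (nx, ny, nz), column-major, x fastest.
// All voxel coordinates here are 0-based; the R layer owns the 1-based view.

static inline double tri_gather(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return acc;
}

static inline void tri_scatter(double* v, int nx, int ny, int nz,
                               double x, double y, double z, double val) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  for (int dz = 0; dz < 2; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        v[xx + (size_t)nx * (yy + (size_t)ny * zz)] += wx * wy * wz * val;
      }
    }
  }
}

// out(r) = vol(A %*% r + b), r 0-based output voxel; zero outside the grid.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dims,
                                NumericMatrix A, NumericVector b) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  double* o = out.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  size_t n = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++n) {
        double qx = a00*i + a01*j + a02*k + b[0];
        double qy = a10*i + a11*j + a12*k + b[1];
        double qz = a20*i + a21*j + a22*k + b[2];
        o[n] = tri_gather(v, nx, ny, nz, qx, qy, qz);
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Tilt-series projector. Beam = z, tilt axis = y. For tilt angle theta the
// projection image is the z-sum of the volume resampled at
// q = Ry(theta) (r - c) + c, i.e. the volume rotated by -theta about y.
// [[Rcpp::export]]
NumericVector cpp_project_y(NumericVector vol, IntegerVector dims,
                            NumericVector theta_deg, NumericVector center) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nt = theta_deg.size();
  NumericVector out((size_t)nx * ny * nt);
  const double* v = vol.begin();
  double cx = center[0], cy = center[1], cz = center[2];
  for (int t = 0; t < nt; ++t) {
    double th = theta_deg[t] * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    double* img = out.begin() + (size_t)t * nx * ny;
    for (int k = 0; k < nz; ++k) {
      double dz = k - cz;
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double dx = i - cx;
          // Ry(th): x' = ct*dx + st*dz ; z' = -st*dx + ct*dz
          double qx = ct*dx + st*dz + cx;
          double qz = -st*dx + ct*dz + cz;
          img[i + (size_t)nx * j] += tri_gather(v, nx, ny, nz, qx, (double)j, qz);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nt);
  return out;
}

// Exact adjoint of cpp_project_y: smears each image back along the beam
// direction at its tilt angle, scattering with the same trilinear weights.
// [[Rcpp::export]]
NumericVector cpp_backproject_y(NumericVector images, IntegerVector imdims,
                                NumericVector theta_deg, int nz,
                                NumericVector center) {
  int nx = imdims[0], ny = imdims[1];
  int nt = theta_deg.size();
  NumericVector out((size_t)nx * ny * nz);
  double* v = out.begin();
  double cx = center[0], cy = center[1], cz = center[2];
  for (int t = 0; t < nt; ++t) {
    double th = theta_deg[t] * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    const double* img = images.begin() + (size_t)t * nx * ny;
    for (int k = 0; k < nz; ++k) {
      double dz = k - cz;
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double dx = i - cx;
          double qx = ct*dx + st*dz + cx;
          double qz = -st*dx + ct*dz + cz;
          double val = img[i + (size_t)nx * j];
          if (val != 0.0) tri_scatter(v, nx, ny, nz, qx, (double)j, qz, val);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
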