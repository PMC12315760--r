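#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Periodic separable convolution along one axis of a 3D array stored
// column-major (x fastest). taps must sum to 1; radius = (len-1)/2.
static void conv_axis(std::vector<double> &re, std::vector<double> &im,
                      std::vector<double> &tre, std::vector<double> &tim,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double> &taps) {
  const int rad = ((int)taps.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  // inner = contiguous block below the axis, outer = blocks above it
  long inner = 1, outer = 1;
  for (int a = 0; a < axis; ++a) inner *= n[a];
  for (int a = axis + 1; a < 3; ++a) outer *= n[a];

  if (rad == 1 && inner == 1 && len >= 3) {
    // 3-tap stencil along the contiguous axis
    const double w0 = taps[0], w1 = taps[1], w2 = taps[2];
    for (long o = 0; o < outer; ++o) {
      const double *rs = re.data() + o * len;
      const double *is = im.data() + o * len;
      double *rd = tre.data() + o * len;
      double *id = tim.data() + o * len;
      rd[0] = w0 * rs[len - 1] + w1 * rs[0] + w2 * rs[1];
      id[0] = w0 * is[len - 1] + w1 * is[0] + w2 * is[1];
      for (int i = 1; i < len - 1; ++i) {
        rd[i] = w0 * rs[i - 1] + w1 * rs[i] + w2 * rs[i + 1];
        id[i] = w0 * is[i - 1] + w1 * is[i] + w2 * is[i + 1];
      }
      rd[len - 1] = w0 * rs[len - 2] + w1 * rs[len - 1] + w2 * rs[0];
      id[len - 1] = w0 * is[len - 2] + w1 * is[len - 1] + w2 * is[0];
    }
    re.swap(tre);
    im.swap(tim);
    return;
  }
  if (rad == 1 && inner > 1 && len >= 3) {
    // 3-tap stencil along a strided axis: one fused sweep per slab
    const double w0 = taps[0], w1 = taps[1], w2 = taps[2];
    const long plane = inner * (long)len;
    for (long o = 0; o < outer; ++o) {
      const double *rs = re.data() + o * plane;
      const double *is = im.data() + o * plane;
      double *rd = tre.data() + o * plane;
      double *id = tim.data() + o * plane;
      for (int i = 0; i < len; ++i) {
        const long im1 = (long)(i == 0 ? len - 1 : i - 1) * inner;
        const long ip1 = (long)(i == len - 1 ? 0 : i + 1) * inner;
        const double *ra = rs + im1, *rb = rs + (long)i * inner, *rc = rs + ip1;
        const double *ia = is + im1, *ib = is + (long)i * inner, *ic = is + ip1;
        double *rdi = rd + (long)i * inner;
        double *idi = id + (long)i * inner;
        for (long c = 0; c < inner; ++c) {
          rdi[c] = w0 * ra[c] + w1 * rb[c] + w2 * rc[c];
          idi[c] = w0 * ia[c] + w1 * ib[c] + w2 * ic[c];
        }
      }
    }
    re.swap(tre);
    im.swap(tim);
    return;
  }
  if (inner == 1) {
    // axis 0: contiguous lines of length len
    for (long o = 0; o < outer; ++o) {
      const double *rs = re.data() + o * len;
      const double *is = im.data() + o * len;
      double *rd = tre.data() + o * len;
      double *id = tim.data() + o * len;
      for (int i = 0; i < len; ++i) {
        double ar = 0.0, ai = 0.0;
        for (int j = -rad; j <= rad; ++j) {
          int k = i + j;
          if (k < 0) k += len;
          else if (k >= len) k -= len;
          const double w = taps[j + rad];
          ar += w * rs[k];
          ai += w * is[k];
        }
        rd[i] = ar;
        id[i] = ai;
      }
    }
  } else {
    // higher axes: combine whole contiguous blocks plane by plane
    const long plane = inner * (long)len;
    for (long o = 0; o < outer; ++o) {
      const double *rs = re.data() + o * plane;
      const double *is = im.data() + o * plane;
      double *rd = tre.data() + o * plane;
      double *id = tim.data() + o * plane;
      for (int i = 0; i < len; ++i) {
        double *rdi = rd + i * inner;
        double *idi = id + i * inner;
        {
          int k = i - rad;
          while (k < 0) k += len;
          const double w = taps[0];
          const double *rsk = rs + (long)k * inner;
          const double *isk = is + (long)k * inner;
          for (long c = 0; c < inner; ++c) {
            rdi[c] = w * rsk[c];
            idi[c] = w * isk[c];
          }
        }
        for (int j = -rad + 1; j <= rad; ++j) {
          int k = i + j;
          while (k < 0) k += len;
          while (k >= len) k -= len;
          const double w = taps[j + rad];
          const double *rsk = rs + (long)k * inner;
          const double *isk = is + (long)k * inner;
          for (long c = 0; c < inner; ++c) {
            rdi[c] += w * rsk[c];
            idi[c] += w * isk[c];
          }
        }
      }
    }
  }
  re.swap(tre);
  im.swap(tim);
}

//' @noRd
// [[Rcpp::export(name = ".sim_gesfidse_core")]]
NumericVector sim_gesfidse_core(NumericVector db, IntegerVector dims,
                                double dt_ms, int n_steps,
                                IntegerVector echo_steps, int refocus_step,
                                List taps_list) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long N = (long)nx * ny * nz;
  if ((long)db.size() != N) stop("field size does not match grid");

  // per-cell rotation per step (T2 decay is a uniform scalar and is applied
  // analytically outside this kernel)
  std::vector<double> cs(N), sn(N);
  const double dt_s = dt_ms * 1e-3;
  for (long i = 0; i < N; ++i) {
    const double ph = db[i] * dt_s;
    cs[i] = std::cos(ph);
    sn[i] = std::sin(ph);
  }

  std::vector<std::vector<double> > taps(3);
  bool any_diff = false;
  for (int a = 0; a < 3; ++a) {
    SEXP el = taps_list[a];
    if (!Rf_isNull(el)) {
      NumericVector t(el);
      if (t.size() > 1) {
        taps[a] = std::vector<double>(t.begin(), t.end());
        any_diff = true;
      }
    }
  }

  std::vector<double> re(N, 1.0), im(N, 0.0);
  std::vector<double> tre, tim;
  if (any_diff) {
    tre.resize(N);
    tim.resize(N);
  }

  NumericVector out(echo_steps.size());
  int next_echo = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // dephasing
    for (long i = 0; i < N; ++i) {
      const double r = re[i], m = im[i];
      re[i] = r * cs[i] - m * sn[i];
      im[i] = r * sn[i] + m * cs[i];
    }
    // diffusion
    if (any_diff) {
      for (int a = 0; a < 3; ++a)
        if (!taps[a].empty())
          conv_axis(re, im, tre, tim, nx, ny, nz, a, taps[a]);
    }
    // ideal 180 deg refocusing pulse
    if (step == refocus_step)
      for (long i = 0; i < N; ++i) im[i] = -im[i];
    // record echoes
    while (next_echo < echo_steps.size() && echo_steps[next_echo] == step) {
      double sr = 0.0, si = 0.0;
      for (long i = 0; i < N; ++i) {
        sr += re[i];
        si += im[i];
      }
      sr /= (double)N;
      si /= (double)N;
      out[next_echo] = std::sqrt(sr * sr + si * si);
      ++next_echo;
    }
  }
  return out;
}

static inline double wrap_min_image(double w, double L) {
  return w - L * std::round(w / L);
}

//' @noRd
// [[Rcpp::export(name = ".stamp_cylinder")]]
int stamp_cylinder(IntegerVector lab, IntegerVector dims, NumericVector spacing,
                   NumericVector p0, NumericVector u, double r, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double Lx = nx * hx, Ly = ny * hy, Lz = nz * hz;
  const double r2 = r * r;
  int count = 0;
  long idx = 0;
  for (int z = 0; z < nz; ++z) {
    const double cz = (z + 0.5) * hz;
    for (int y = 0; y < ny; ++y) {
      const double cy = (y + 0.5) * hy;
      for (int x = 0; x < nx; ++x, ++idx) {
        const double cx = (x + 0.5) * hx;
        double wx = wrap_min_image(cx - p0[0], Lx);
        double wy = wrap_min_image(cy - p0[1], Ly);
        double wz = wrap_min_image(cz - p0[2], Lz);
        const double t = wx * u[0] + wy * u[1] + wz * u[2];
        const double d2 = wx * wx + wy * wy + wz * wz - t * t;
        if (d2 <= r2 && lab[idx] == 0) {
          lab[idx] = label;
          ++count;
        }
      }
    }
  }
  return count;
}

//' @noRd
// [[Rcpp::export(name = ".stamp_disk")]]
int stamp_disk(IntegerVector lab, IntegerVector dims, NumericVector spacing,
               NumericVector p0, double r, int label) {
  const int nx = dims[0], ny = dims[1];
  const double hx = spacing[0], hy = spacing[1];
  const double Lx = nx * hx, Ly = ny * hy;
  const double r2 = r * r;
  int count = 0;
  long idx = 0;
  for (int y = 0; y < ny; ++y) {
    const double cy = (y + 0.5) * hy;
    for (int x = 0; x < nx; ++x, ++idx) {
      const double cx = (x + 0.5) * hx;
      const double wx = wrap_min_image(cx - p0[0], Lx);
      const double wy = wrap_min_image(cy - p0[1], Ly);
      if (wx * wx + wy * wy <= r2 && lab[idx] == 0) {
        lab[idx] = label;
        ++count;
      }
    }
  }
  return count;
}

//' @noRd
// [[Rcpp::export(name = ".stamp_capsule")]]
int stamp_capsule(IntegerVector lab, IntegerVector dims, NumericVector spacing,
                  NumericVector p1, NumericVector p2, double r, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double Lx = nx * hx, Ly = ny * hy, Lz = nz * hz;
  const double ax = p2[0] - p1[0], ay = p2[1] - p1[1], az = p2[2] - p1[2];
  const double a2 = ax * ax + ay * ay + az * az;
  const double r2 = r * r;
  // bounding box in index space (capsule is short relative to the box)
  const double xmin = std::min(p1[0], p2[0]) - r, xmax = std::max(p1[0], p2[0]) + r;
  const double ymin = std::min(p1[1], p2[1]) - r, ymax = std::max(p1[1], p2[1]) + r;
  const double zmin = std::min(p1[2], p2[2]) - r, zmax = std::max(p1[2], p2[2]) + r;
  int count = 0;
  const int ix0 = (int)std::floor(xmin / hx) - 1, ix1 = (int)std::ceil(xmax / hx) + 1;
  const int iy0 = (int)std::floor(ymin / hy) - 1, iy1 = (int)std::ceil(ymax / hy) + 1;
  const int iz0 = (int)std::floor(zmin / hz) - 1, iz1 = (int)std::ceil(zmax / hz) + 1;
  for (int z = iz0; z <= iz1; ++z) {
    int zi = ((z % nz) + nz) % nz;
    const double cz = (z + 0.5) * hz;
    for (int y = iy0; y <= iy1; ++y) {
      int yi = ((y % ny) + ny) % ny;
      const double cy = (y + 0.5) * hy;
      for (int x = ix0; x <= ix1; ++x) {
        int xi = ((x % nx) + nx) % nx;
        const double cx = (x + 0.5) * hx;
        double wx = cx - p1[0], wy = cy - p1[1], wz = cz - p1[2];
        double t = a2 > 0 ? (wx * ax + wy * ay + wz * az) / a2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        const double dx = wx - t * ax, dy = wy - t * ay, dz = wz - t * az;
        if (dx * dx + dy * dy + dz * dz <= r2) {
          const long idx = (long)xi + (long)nx * (yi + (long)ny * zi);
          if (lab[idx] == 0) {
            lab[idx] = label;
            ++count;
          }
        }
      }
    }
  }
  (void)Lx; (void)Ly; (void)Lz;
  return count;
}
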