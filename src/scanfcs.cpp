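#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_into(double v, double lo, double hi) {
  // periodic boundary (loop form; steps are << span in practice)
  double span = hi - lo;
  if (span <= 0) return lo;
  for (int guard = 0; guard < 64; ++guard) {
    if (v < lo) v += span;
    else if (v >= hi) v -= span;
    else return v;
  }
  return lo;
}

static inline double reflect_into(double v, double lo, double hi) {
  // fold a coordinate back into [lo, hi] (reflecting boundaries)
  double span = hi - lo;
  if (span <= 0) return lo;
  for (int guard = 0; guard < 64; ++guard) {
    if (v < lo) v = 2.0 * lo - v;
    else if (v > hi) v = 2.0 * hi - v;
    else return v;
  }
  // pathological step (>> domain); clamp
  if (v < lo) v = lo;
  if (v > hi) v = hi;
  return v;
}

//' @noRd
// [[Rcpp::export]]
NumericVector bd_simulate_cpp(int n_steps, double dt, NumericVector D,
                              NumericMatrix start, NumericVector domain,
                              NumericMatrix walls, int periodic_x) {
  const int np = start.nrow();
  const int nw = walls.nrow();
  const int nt = n_steps + 1;
  NumericVector out(Dimension(nt, np, 3));

  std::vector<double> x(np), y(np), z(np), sig(np);
  for (int p = 0; p < np; ++p) {
    x[p] = start(p, 0);
    y[p] = start(p, 1);
    z[p] = start(p, 2);
    sig[p] = std::sqrt(2.0 * D[p] * dt);
    out[0 + nt * p] = x[p];
    out[0 + nt * (p + np)] = y[p];
    out[0 + nt * (p + 2 * np)] = z[p];
  }

  const double xlo = domain[0], xhi = domain[1];
  const double ylo = domain[2], yhi = domain[3];
  const double zlo = domain[4], zhi = domain[5];

  for (int s = 1; s < nt; ++s) {
    for (int p = 0; p < np; ++p) {
      double xn = x[p], yn = y[p], zn = z[p];
      if (sig[p] > 0) {
        xn += sig[p] * norm_rand();
        yn += sig[p] * norm_rand();
        zn += sig[p] * norm_rand();
        // semi-permeable walls are planes of constant x
        for (int w = 0; w < nw; ++w) {
          const double wx = walls(w, 0);
          if (x[p] < wx && xn >= wx) {          // crossing left -> right
            if (unif_rand() >= walls(w, 1)) xn = 2.0 * wx - xn;
          } else if (x[p] > wx && xn <= wx) {   // crossing right -> left
            if (unif_rand() >= walls(w, 2)) xn = 2.0 * wx - xn;
          }
        }
        xn = periodic_x ? wrap_into(xn, xlo, xhi)
                        : reflect_into(xn, xlo, xhi);
        yn = reflect_into(yn, ylo, yhi);
        zn = reflect_into(zn, zlo, zhi);
      }
      x[p] = xn; y[p] = yn; z[p] = zn;
      out[s + nt * p] = xn;
      out[s + nt * (p + np)] = yn;
      out[s + nt * (p + 2 * np)] = zn;
    }
  }
  return out;
}

// Accumulate the expected photon rate for every pixel of a raster (or line)
// scan.  traj has dim (n_time, np, 3) on a uniform grid of spacing traj_dt
// seconds; particle positions at pixel acquisition times are linearly
// interpolated.  Pixel (f, r, c) is acquired at
//   t = f*frame_s + r*line_s + c*dwell_s
// and sits at (x0 + c*px, y0 + r*px, z_focus).  Rate contribution of a
// particle is eps_peak * exp(-2*dr2/w0^2 - 2*dz^2/wz^2).
//' @noRd
// [[Rcpp::export]]
NumericVector render_scan_cpp(NumericVector traj, double traj_dt,
                              int n_frames, int ny, int nx,
                              double x0, double y0, double px,
                              double dwell_s, double line_s, double frame_s,
                              double w0, double wz, NumericVector eps_peak,
                              NumericVector slack, double z_focus) {
  IntegerVector tdim = traj.attr("dim");
  const int nt = tdim[0];
  const int np = tdim[1];
  NumericVector out(Dimension(n_frames, ny, nx)); // zero-initialised
  const double cutoff = 3.2 * w0;   // exp(-2*3.2^2) ~ 1e-9
  const double zcut = 3.2 * wz;
  const double inv_w02 = 1.0 / (w0 * w0);
  const double inv_wz2 = 1.0 / (wz * wz);

  for (int f = 0; f < n_frames; ++f) {
    for (int r = 0; r < ny; ++r) {
      const double t_row = f * frame_s + r * line_s;
      const double yr = y0 + r * px;
      for (int p = 0; p < np; ++p) {
        if (eps_peak[p] <= 0) continue;
        // coarse gate on the particle position at the start of the line
        double s = t_row / traj_dt;
        int i0 = (int)std::floor(s);
        if (i0 >= nt - 1) i0 = nt - 2;
        double frac = s - i0;
        const double pxx = (1 - frac) * traj[i0 + nt * p] + frac * traj[i0 + 1 + nt * p];
        const double pyy = (1 - frac) * traj[i0 + nt * (p + np)] + frac * traj[i0 + 1 + nt * (p + np)];
        const double pzz = (1 - frac) * traj[i0 + nt * (p + 2 * np)] + frac * traj[i0 + 1 + nt * (p + 2 * np)];
        const double slk = slack[p];
        if (std::fabs(pyy - yr) > cutoff + slk) continue;
        if (std::fabs(pzz - z_focus) > zcut + slk) continue;
        int c_lo = (int)std::floor((pxx - cutoff - slk - x0) / px);
        int c_hi = (int)std::ceil((pxx + cutoff + slk - x0) / px);
        if (c_lo < 0) c_lo = 0;
        if (c_hi > nx - 1) c_hi = nx - 1;
        for (int c = c_lo; c <= c_hi; ++c) {
          const double t = t_row + c * dwell_s;
          double sc = t / traj_dt;
          int j0 = (int)std::floor(sc);
          if (j0 >= nt - 1) j0 = nt - 2;
          double fr = sc - j0;
          const double qx = (1 - fr) * traj[j0 + nt * p] + fr * traj[j0 + 1 + nt * p];
          const double qy = (1 - fr) * traj[j0 + nt * (p + np)] + fr * traj[j0 + 1 + nt * (p + np)];
          const double qz = (1 - fr) * traj[j0 + nt * (p + 2 * np)] + fr * traj[j0 + 1 + nt * (p + 2 * np)];
          const double dx = qx - (x0 + c * px);
          const double dy = qy - yr;
          const double dz = qz - z_focus;
          const double arg = 2.0 * ((dx * dx + dy * dy) * inv_w02 + dz * dz * inv_wz2);
          if (arg < 40.0)
            out[f + n_frames * (r + ny * c)] += eps_peak[p] * std::exp(-arg);
        }
      }
    }
  }
  return out;
}

// Direct O(n^4) spatial autocorrelation of a single frame of fluctuations,
// used only as a smallness-bounded reference path.
//' @noRd
// [[Rcpp::export]]
NumericMatrix acf_direct_frame_cpp(NumericMatrix dI, int max_xi, int max_psi) {
  const int ny = dI.nrow(), nx = dI.ncol();
  NumericMatrix out(2 * max_psi + 1, 2 * max_xi + 1);
  for (int psi = -max_psi; psi <= max_psi; ++psi) {
    for (int xi = -max_xi; xi <= max_xi; ++xi) {
      double acc = 0.0;
      long n = 0;
      for (int r = 0; r < ny; ++r) {
        int r2 = r + psi;
        if (r2 < 0 || r2 >= ny) continue;
        for (int c = 0; c < nx; ++c) {
          int c2 = c + xi;
          if (c2 < 0 || c2 >= nx) continue;
          acc += dI(r, c) * dI(r2, c2);
          ++n;
        }
      }
      out(psi + max_psi, xi + max_xi) = (n > 0) ? acc / n : NA_REAL;
    }
  }
  return out;
}

// Streaming Brownian-dynamics + rendering: particles advance by exact
// Gaussian steps at sub-line resolution while the raster (or line) scan is
// rendered, so no trajectory is stored.  Pixel times within a substep use
// linearly interpolated positions.  Geometry as in bd_simulate_cpp.
//' @noRd
// [[Rcpp::export]]
List stream_render_cpp(NumericMatrix start, NumericVector D,
                       NumericMatrix eps_peak,
                       NumericVector domain, NumericMatrix walls,
                       int n_frames, int ny, int nx,
                       double x0, double y0, double px,
                       double dwell_s, double line_s,
                       double w0, double wz, double z_focus,
                       int nsub, int periodic_x) {
  const int np = start.nrow();
  const int nw = walls.nrow();
  const int nch = eps_peak.ncol();
  List out_list(nch);
  std::vector<NumericVector> out;
  for (int ch = 0; ch < nch; ++ch) {
    NumericVector o(Dimension(n_frames, ny, nx));
    out.push_back(o);
    out_list[ch] = o;
  }
  // per-particle gate: any channel bright
  std::vector<bool> bright(np, false);
  for (int p = 0; p < np; ++p)
    for (int ch = 0; ch < nch; ++ch)
      if (eps_peak(p, ch) > 0) bright[p] = true;
  const double cutoff = 3.2 * w0;
  const double zcut = 3.2 * wz;
  const double inv_w02 = 1.0 / (w0 * w0);
  const double inv_wz2 = 1.0 / (wz * wz);
  const double xlo = domain[0], xhi = domain[1];
  const double ylo = domain[2], yhi = domain[3];
  const double zlo = domain[4], zhi = domain[5];
  const double active_s = nx * dwell_s;
  const double sub_dt = active_s / nsub;
  const double retrace_s = line_s - active_s;

  std::vector<double> x(np), y(np), z(np), sig_sub(np), sig_ret(np);
  for (int p = 0; p < np; ++p) {
    x[p] = start(p, 0); y[p] = start(p, 1); z[p] = start(p, 2);
    sig_sub[p] = std::sqrt(2.0 * D[p] * sub_dt);
    sig_ret[p] = (retrace_s > 0) ? std::sqrt(2.0 * D[p] * retrace_s) : 0.0;
  }
  auto advance = [&](int p, double sig) {
    if (sig <= 0) return;
    double xn = x[p] + sig * norm_rand();
    double yn = y[p] + sig * norm_rand();
    double zn = z[p] + sig * norm_rand();
    for (int w = 0; w < nw; ++w) {
      const double wx = walls(w, 0);
      if (x[p] < wx && xn >= wx) {
        if (unif_rand() >= walls(w, 1)) xn = 2.0 * wx - xn;
      } else if (x[p] > wx && xn <= wx) {
        if (unif_rand() >= walls(w, 2)) xn = 2.0 * wx - xn;
      }
    }
    x[p] = periodic_x ? wrap_into(xn, xlo, xhi)
                      : reflect_into(xn, xlo, xhi);
    y[p] = reflect_into(yn, ylo, yhi);
    z[p] = reflect_into(zn, zlo, zhi);
  };

  for (int f = 0; f < n_frames; ++f) {
    for (int r = 0; r < ny; ++r) {
      const double yr = y0 + r * px;
      // columns covered per substep: [c_begin, c_end)
      for (int s = 0; s < nsub; ++s) {
        const double t0 = s * sub_dt;
        int c_begin = (int)std::ceil(t0 / dwell_s - 1e-9);
        int c_end = (int)std::ceil((t0 + sub_dt) / dwell_s - 1e-9);
        if (c_end > nx) c_end = nx;
        std::vector<double> px0(np), py0(np), pz0(np);
        for (int p = 0; p < np; ++p) {
          px0[p] = x[p]; py0[p] = y[p]; pz0[p] = z[p];
          advance(p, sig_sub[p]);
        }
        if (c_begin >= c_end) continue;
        for (int p = 0; p < np; ++p) {
          if (!bright[p]) continue;
          const double slk = sig_sub[p];
          if (std::fabs(py0[p] - yr) > cutoff + slk &&
              std::fabs(y[p] - yr) > cutoff + slk) continue;
          if (std::fabs(pz0[p] - z_focus) > zcut + slk &&
              std::fabs(z[p] - z_focus) > zcut + slk) continue;
          for (int c = c_begin; c < c_end; ++c) {
            const double frac = (c * dwell_s - t0) / sub_dt;
            const double qx = (1 - frac) * px0[p] + frac * x[p];
            const double qy = (1 - frac) * py0[p] + frac * y[p];
            const double qz = (1 - frac) * pz0[p] + frac * z[p];
            const double dx = qx - (x0 + c * px);
            if (std::fabs(dx) > cutoff + slk) continue;
            const double dy = qy - yr;
            const double dz = qz - z_focus;
            const double arg = 2.0 * ((dx * dx + dy * dy) * inv_w02 +
                                      dz * dz * inv_wz2);
            if (arg < 40.0) {
              const double shape = std::exp(-arg);
              const int idx = f + n_frames * (r + ny * c);
              for (int ch = 0; ch < nch; ++ch)
                if (eps_peak(p, ch) > 0)
                  out[ch][idx] += eps_peak(p, ch) * shape;
            }
          }
        }
      }
      // retrace: one exact Gaussian step, no pixels rendered
      for (int p = 0; p < np; ++p) advance(p, sig_ret[p]);
    }
  }
  return out_list;
}
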