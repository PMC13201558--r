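#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>

using namespace Rcpp;

// Bilinear sample of a velocity grid (rows = z, cols = x, column-major),
// zero outside the grid hull.
static inline double sample_grid(const double* v, int nz, int nx,
                                 double z0, double dz, double x0, double dx,
                                 double zq, double xq) {
  double fi = (zq - z0) / dz;
  double fj = (xq - x0) / dx;
  if (fi < 0 || fj < 0 || fi > nz - 1 || fj > nx - 1) return 0.0;
  int i0 = (int)std::floor(fi); if (i0 > nz - 2) i0 = nz - 2;
  int j0 = (int)std::floor(fj); if (j0 > nx - 2) j0 = nx - 2;
  double ti = fi - i0, tj = fj - j0;
  const double* c0 = v + (size_t)j0 * nz;
  const double* c1 = v + (size_t)(j0 + 1) * nz;
  return c0[i0] * (1 - ti) * (1 - tj) + c0[i0 + 1] * ti * (1 - tj) +
         c1[i0] * (1 - ti) * tj + c1[i0 + 1] * ti * tj;
}

// Renders an ensemble of beamformed IQ frames from point scatterers advected
// by a steady velocity field. The point-spread function is separable:
//   axial:   Gaussian envelope (sigma_z) times pulse-echo carrier
//            exp(i * 4 * pi * (z - zs) / lambda_z)
//   lateral: Gaussian envelope (sigma_x), optionally modulated by
//            cos(2 * pi * (x - xs) / lambda_lat)  (transverse oscillation)
// Scatterers leaving the axial extent [z_lo, z_hi] re-enter at the inlet
// (wrap-around), keeping the concentration steady. Distances in mm,
// velocities in m/s, prf in 1/s.
// [[Rcpp::export]]
ComplexVector render_iq_cpp(NumericVector zs0, NumericVector xs0,
                            ComplexVector amps,
                            NumericMatrix vz, NumericMatrix vx,
                            double gz0, double gdz, double gx0, double gdx,
                            int nz, int nx, int n_frames, double prf,
                            double sigma_z, double lambda_z,
                            double sigma_x, double lambda_lat,
                            double trunc_sigma,
                            double z_lo, double z_hi) {
  const int ns = zs0.size();
  std::vector<double> zs(zs0.begin(), zs0.end());
  std::vector<double> xs(xs0.begin(), xs0.end());
  std::vector<std::complex<double> > a(ns);
  for (int s = 0; s < ns; ++s)
    a[s] = std::complex<double>(amps[s].r, amps[s].i);

  ComplexVector out((R_xlen_t)nz * nx * n_frames);
  std::vector<std::complex<double> > frame((size_t)nz * nx);
  std::vector<std::complex<double> > axial(256);
  std::vector<double> lateral(1024);

  const int gnz = vz.nrow(), gnx = vz.ncol();
  const double* pvz = vz.begin();
  const double* pvx = vx.begin();
  const bool to_on = lambda_lat > 0;
  const double kz = 4.0 * M_PI / lambda_z;      // pulse-echo axial wavenumber
  const double kx = to_on ? 2.0 * M_PI / lambda_lat : 0.0;
  const double rz = trunc_sigma * sigma_z;
  const double rx = trunc_sigma * sigma_x;
  const double inv2sz2 = 1.0 / (2.0 * sigma_z * sigma_z);
  const double inv2sx2 = 1.0 / (2.0 * sigma_x * sigma_x);

  for (int t = 0; t < n_frames; ++t) {
    std::fill(frame.begin(), frame.end(), std::complex<double>(0, 0));
    for (int s = 0; s < ns; ++s) {
      const double zsv = zs[s], xsv = xs[s];
      int iz0 = (int)std::ceil((zsv - rz - gz0) / gdz);
      int iz1 = (int)std::floor((zsv + rz - gz0) / gdz);
      int ix0 = (int)std::ceil((xsv - rx - gx0) / gdx);
      int ix1 = (int)std::floor((xsv + rx - gx0) / gdx);
      if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
      if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
      if (iz0 > iz1 || ix0 > ix1) continue;

      const int nzf = iz1 - iz0 + 1, nxf = ix1 - ix0 + 1;
      if ((int)axial.size() < nzf) axial.resize(nzf);
      if ((int)lateral.size() < nxf) lateral.resize(nxf);

      // Gaussian by multiplicative recurrence: with u_{i+1} = u_i + d,
      // g_{i+1} = g_i * q * m_i where q = exp(-d^2/(2 s^2)) is constant and
      // m_{i+1} = m_i * q^2; carriers advance by a fixed complex rotation.
      {
        const double u0 = gz0 + iz0 * gdz - zsv;
        double g = std::exp(-u0 * u0 * inv2sz2);
        const double q = std::exp(-gdz * gdz * inv2sz2);
        const double q2 = q * q;
        double m = std::exp(-2.0 * u0 * gdz * inv2sz2);
        std::complex<double> carrier(std::cos(kz * u0), std::sin(kz * u0));
        const std::complex<double> crot(std::cos(kz * gdz), std::sin(kz * gdz));
        for (int i = 0; i < nzf; ++i) {
          axial[i] = a[s] * g * carrier;
          g *= q * m;
          m *= q2;
          carrier *= crot;
        }
      }
      {
        const double w0 = gx0 + ix0 * gdx - xsv;
        double g = std::exp(-w0 * w0 * inv2sx2);
        const double q = std::exp(-gdx * gdx * inv2sx2);
        const double q2 = q * q;
        double m = std::exp(-2.0 * w0 * gdx * inv2sx2);
        if (to_on) {
          std::complex<double> cw(std::cos(kx * w0), std::sin(kx * w0));
          const std::complex<double> wrot(std::cos(kx * gdx), std::sin(kx * gdx));
          for (int j = 0; j < nxf; ++j) {
            lateral[j] = g * cw.real();
            g *= q * m;
            m *= q2;
            cw *= wrot;
          }
        } else {
          for (int j = 0; j < nxf; ++j) {
            lateral[j] = g;
            g *= q * m;
            m *= q2;
          }
        }
      }
      std::complex<double>* base = frame.data();
      for (int j = 0; j < nxf; ++j) {
        const double lj = lateral[j];
        if (lj == 0.0) continue;
        std::complex<double>* col = base + (size_t)(ix0 + j) * nz + iz0;
        for (int i = 0; i < nzf; ++i) col[i] += axial[i] * lj;
      }
    }
    // copy frame into output
    Rcomplex* dst = out.begin() + (R_xlen_t)t * nz * nx;
    for (size_t k = 0; k < frame.size(); ++k) {
      dst[k].r = frame[k].real();
      dst[k].i = frame[k].imag();
    }
    // advect scatterers to the next frame
    if (t < n_frames - 1) {
      const double dt = 1.0 / prf;
      for (int s = 0; s < ns; ++s) {
        double vzi = sample_grid(pvz, gnz, gnx, gz0, gdz, gx0, gdx, zs[s], xs[s]);
        double vxi = sample_grid(pvx, gnz, gnx, gz0, gdz, gx0, gdx, zs[s], xs[s]);
        zs[s] += vzi * dt * 1e3;  // m/s over dt, in mm
        xs[s] += vxi * dt * 1e3;
        if (zs[s] > z_hi) zs[s] = z_lo + (zs[s] - z_hi);
        else if (zs[s] < z_lo) zs[s] = z_hi - (z_lo - zs[s]);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, nx, n_frames);
  return out;
}
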