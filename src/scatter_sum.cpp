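#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Coherent accumulation of point-scatterer echoes into a complex B-scan.
//
// Each image column j is one A-scan: a beam entering the (flat) surface at
// lateral position entry_x[j], refracted to the in-sample angle, focused at
// distance s_f along its axis. A scatterer contributes with the Gaussian
// beam amplitude envelope evaluated at its across-axis offset, a Gaussian
// axial gate (sigma gate_sigma_px pixels) centred at the pixel encoding its
// one-way optical pathlength, and the round-trip phase -2 k0 OPL.
//
// Geometry here must stay the exact mirror of gaussian_field() /
// round_trip_pathlength() / forward_map() on the R side; a cross-check test
// enforces this.
// [[Rcpp::export]]
ComplexMatrix cpp_scatter_image(NumericVector sx, NumericVector sz,
                                NumericVector samp, NumericVector entry_x,
                                double surface_z, double sin_as,
                                double cos_as, double s_f, double w0,
                                double ry, double k0, double ri, double p_v,
                                NumericVector v_surf, int n_v,
                                double gate_sigma_px, double amp_thresh,
                                double phase0) {
  const int n_u = entry_x.size();
  const int n_s = sx.size();
  std::vector<std::complex<double> > img((size_t)n_v * n_u,
                                         std::complex<double>(0.0, 0.0));
  const double gate_halfwidth = 4.0 * gate_sigma_px;
  const double inv2s2 = 1.0 / (2.0 * gate_sigma_px * gate_sigma_px);

  for (int j = 0; j < n_u; ++j) {
    const double xe = entry_x[j];
    const double vs = v_surf[j];
    for (int i = 0; i < n_s; ++i) {
      const double dz = sz[i] - surface_z;
      if (dz < -1e-9) continue;  // above the surface
      const double dx = sx[i] - xe;
      const double s_ax = dx * sin_as + dz * cos_as;
      if (s_ax < -1e-9) continue;
      const double xp = dx * cos_as - dz * sin_as;
      const double yp = s_ax - s_f;
      const double wb = w0 * std::sqrt(1.0 + (yp * yp) / (ry * ry));
      if (std::fabs(xp) > 3.2 * wb) continue;  // exp(-3.2^2) ~ 3.6e-5
      const double amp = (w0 / wb) * std::exp(-(xp * xp) / (wb * wb));
      if (amp * samp[i] < amp_thresh) continue;
      const double lat = xp * xp * yp / (2.0 * (yp * yp + ry * ry));
      const double opl = ri * (s_ax + lat);
      const double vc = vs + opl / p_v;  // 1-based fractional row
      const double phase = phase0 - 2.0 * k0 * opl;
      const std::complex<double> c =
          amp * samp[i] *
          std::complex<double>(std::cos(phase), std::sin(phase));
      int v_lo = (int)std::ceil(vc - gate_halfwidth);
      int v_hi = (int)std::floor(vc + gate_halfwidth);
      if (v_lo < 1) v_lo = 1;
      if (v_hi > n_v) v_hi = n_v;
      for (int v = v_lo; v <= v_hi; ++v) {
        const double dv = v - vc;
        img[(size_t)(v - 1) + (size_t)j * n_v] +=
            c * std::exp(-dv * dv * inv2s2);
      }
    }
  }

  ComplexMatrix out(n_v, n_u);
  for (size_t t = 0; t < img.size(); ++t) {
    out[t] = Rcomplex{img[t].real(), img[t].imag()};
  }
  return out;
}
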