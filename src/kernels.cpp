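#include <Rcpp.h>
using namespace Rcpp;

// Deposit analytic N-shaped (bipolar) pressure pulses from a set of uniform
// spherical sources onto per-element time traces, averaging over sub-element
// receive points (finite-aperture directivity).
//
// subpos:  (n_sub_total x 3) receive sub-point positions, mm (already rotated
//          into the sample frame for this acquisition frame)
// sub_el:  0-based element index of each sub-point
// centers: (K x 3) sphere centres, mm
// radius:  sphere radii, mm
// strength: per-sphere source strength (mu_a * lumped scale * radius * step weight)
// n_el:    number of elements
// n_sub:   sub-points per element (averaging divisor)
// n_samp:  samples of the (possibly supersampled) trace
// fs:      sampling rate of the deposited trace, MHz
// c:       speed of sound, mm/us
//
// The pulse at distance d is p(t) = (strength/d) * (t0 - t)/tau for
// |t - t0| <= tau, with t0 = d/c and tau = a/c: a linear "N" ramp from +A to
// -A whose time integral is zero.
// [[Rcpp::export]]
NumericMatrix cpp_forward_frame(NumericMatrix subpos, IntegerVector sub_el,
                                NumericMatrix centers, NumericVector radius,
                                NumericVector strength,
                                int n_el, int n_sub, int n_samp,
                                double fs, double c) {
  const int m = subpos.nrow();
  const int K = centers.nrow();
  NumericMatrix traces(n_samp, n_el);
  const double dtf = 1.0 / fs;
  const double invsub = 1.0 / n_sub;
  for (int s = 0; s < m; ++s) {
    const double sx = subpos(s, 0), sy = subpos(s, 1), sz = subpos(s, 2);
    const int e = sub_el[s];
    double *col = &traces(0, e);
    for (int k = 0; k < K; ++k) {
      const double dx = centers(k, 0) - sx;
      const double dy = centers(k, 1) - sy;
      const double dz = centers(k, 2) - sz;
      const double d = sqrt(dx * dx + dy * dy + dz * dz);
      const double a = radius[k];
      if (d <= a) stop("receive point inside an absorber");
      const double t0 = d / c;
      const double tau = a / c;
      const double amp = strength[k] / d * invsub;
      int ilo = (int)std::ceil((t0 - tau) * fs);
      int ihi = (int)std::floor((t0 + tau) * fs);
      if (ilo < 0) ilo = 0;
      if (ihi > n_samp - 1) ihi = n_samp - 1;
      for (int i = ilo; i <= ihi; ++i) {
        const double u = (t0 - i * dtf) / tau;
        col[i] += amp * u;
      }
    }
  }
  return traces;
}

// Delay-and-sum back-projection of filtered traces onto voxels, in the sample
// frame (the detector is virtually rotated by -angle for each frame).
//
// traces: (n_samp x n_el x n_frames) filtered channel data, flattened
// elem:   (n_el x 3) nominal element positions at azimuth 0, mm
// angles: per-frame sample rotation, radians
// vox:    (Nv x 3) voxel centres, mm
// c:      speed of sound mm/us;  fs: sampling rate MHz
// solid_angle: weight contributions by element area * cos(incidence)/d^2
// elem_area: element area, mm^2 (used only with solid_angle weighting)
//
// Returns a list: values (weight-normalised sum), weight (total weight per
// voxel) and n_skipped (contributions whose delay fell outside the record).
// [[Rcpp::export]]
List cpp_backproject(NumericVector traces, IntegerVector dims,
                     NumericMatrix elem, NumericVector angles,
                     NumericMatrix vox, double c, double fs,
                     bool solid_angle, double elem_area) {
  const int n_samp = dims[0], n_el = dims[1], n_frames = dims[2];
  const int nv = vox.nrow();
  NumericVector acc(nv), wsum(nv);
  double nskip = 0.0;
  const double *tr = REAL(traces);
  const double *vx = &vox(0, 0), *vy = &vox(0, 1), *vz = &vox(0, 2);
  double *pacc = REAL(acc), *pw = REAL(wsum);
  const double inv_cfs = fs / c;  // mm -> fractional sample index
  std::vector<double> ex(n_el), ey(n_el), ez(n_el);
  for (int f = 0; f < n_frames; ++f) {
    const double ca = std::cos(-angles[f]), sa = std::sin(-angles[f]);
    for (int e = 0; e < n_el; ++e) {
      ex[e] = ca * elem(e, 0) - sa * elem(e, 1);
      ey[e] = sa * elem(e, 0) + ca * elem(e, 1);
      ez[e] = elem(e, 2);
    }
    const double *frame = tr + (size_t)f * n_samp * n_el;
    for (int e = 0; e < n_el; ++e) {
      const double px = ex[e], py = ey[e], pz = ez[e];
      // element normal points at the origin
      const double en = std::sqrt(px * px + py * py + pz * pz);
      const double nxe = -px / en, nye = -py / en, nze = -pz / en;
      const double *col = frame + (size_t)e * n_samp;
      for (int v = 0; v < nv; ++v) {
        const double dx = vx[v] - px;
        const double dy = vy[v] - py;
        const double dz = vz[v] - pz;
        const double d2 = dx * dx + dy * dy + dz * dz;
        const double inv_d = 1.0 / std::sqrt(d2);
        const double ti = d2 * inv_d * inv_cfs;  // fractional sample (t=i/fs)
        const int i0 = (int)ti;
        if (ti < 0 || i0 >= n_samp - 1) { nskip += 1.0; continue; }
        const double frac = ti - i0;
        const double val = col[i0] + (col[i0 + 1] - col[i0]) * frac;
        double w = 1.0;
        if (solid_angle) {
          double cosg = (dx * nxe + dy * nye + dz * nze) * inv_d;
          if (cosg < 0) cosg = 0;
          w = elem_area * cosg * inv_d * inv_d;
        }
        pacc[v] += w * val;
        pw[v] += w;
      }
    }
  }
  for (int v = 0; v < nv; ++v)
    if (wsum[v] > 0) acc[v] /= wsum[v];
  return List::create(_["values"] = acc, _["weight"] = wsum,
                      _["n_skipped"] = nskip);
}
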