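#include <Rcpp.h>
using namespace Rcpp;

// Point-in-removed-material test against the union of swept volumes of the
// previously machined paths. Each prior path sweeps a ball of radius R along
// a +x line segment: a cylinder with spherical end caps. Coordinates are the
// nominal (plan-frame) ones; a rigid workspace deviation moves all executed
// paths together, so relative engagement geometry is deviation-invariant.
static inline bool removed_by_prior(double x, double y, double z,
                                    const double *pr, int npr, double R2,
                                    int stride) {
  for (int k = 0; k < npr; ++k) {
    const double *row = pr + k;
    double dy = y - row[0];
    double dz = z - row[stride];
    double d2 = dy * dy + dz * dz;
    if (d2 >= R2) continue;
    double x0 = row[2 * stride], x1 = row[3 * stride];
    if (x >= x0 && x <= x1) return true;
    double dx = (x < x0) ? x - x0 : x - x1;
    if (d2 + dx * dx < R2) return true;
  }
  return false;
}

// Four-channel instantaneous milling wrench along one path.
//
// t, feed_pos, feed_rate: per-sample time [s], centre offset along +x [mm]
//   (nominal frame) and instantaneous feed rate [mm/s].
// omega, phase0: spindle speed [rad/s] and initial cutter phase [rad];
//   n_sub spindle-phase substeps spanning one flute period are averaged
//   per sample (sensor-bandwidth abstraction).
// edges: one row per micro-edge with columns theta, phi0eff (circumferential
//   angle at zero spin phase, lag included), db, ds.
// origin_path: ball-centre position at feed offset 0 (nominal WCS, mm).
// prior: completed swept paths, columns y, z_centre, x_start, x_end.
// stock_lo/stock_hi: axis-aligned stock box in WCS; stock_hi[2] is the
//   original top surface.
// devR (3x3), devT, wsO: rigid workspace deviation p = devR (q - wsO) + wsO + devT.
// vol/dim/spacing/vorigin: CT grid, voxel-corner origin convention.
// K: Krc, Kac, Ktc, Kre, Kae, Kte; lambda = clamp((g - mmin)/(mmax - mmin)),
//   weight lambda^mu.
// vt_per_feed: feed-per-tooth per unit feed rate, 60/(n N) [s].
//
// Returns an n x 6 matrix: Fx, Fy, Fz [N], Mz [N mm] in the i-MCCS,
// mean raw gray over engaged edges, mean engaged-edge count.
// [[Rcpp::export(name = ".force_trace_cpp")]]
NumericMatrix force_trace_cpp(NumericVector t, NumericVector feed_pos,
                              NumericVector feed_rate, double omega,
                              double phase0, int n_sub, int n_flutes,
                              NumericMatrix edges, double R, double incline,
                              NumericVector origin_path, NumericMatrix prior,
                              NumericVector stock_lo, NumericVector stock_hi,
                              NumericMatrix devR, NumericVector devT,
                              NumericVector wsO, NumericVector vol,
                              IntegerVector dim, NumericVector spacing,
                              NumericVector vorigin, double mmin, double mmax,
                              double mu, NumericVector K, double vt_per_feed) {
  const int n = t.size(), ne = edges.nrow(), npr = prior.nrow();
  const int prstride = npr;
  const double R2 = R * R;
  const double ci = std::cos(incline), si = std::sin(incline);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double invsx = 1.0 / spacing[0], invsy = 1.0 / spacing[1],
               invsz = 1.0 / spacing[2];
  const double inv_span = 1.0 / (mmax - mmin);

  // precompute per-edge trigonometry
  std::vector<double> cth(ne), sth(ne), phi0e(ne), db(ne), ds(ne);
  for (int e = 0; e < ne; ++e) {
    cth[e] = std::cos(edges(e, 0));
    sth[e] = std::sin(edges(e, 0));
    phi0e[e] = edges(e, 1);
    db[e] = edges(e, 2);
    ds[e] = edges(e, 3);
  }

  NumericMatrix out(n, 6);
  const double sub_step = 2.0 * M_PI / n_flutes / n_sub;
  for (int s = 0; s < n; ++s) {
    double Fx = 0, Fy = 0, Fz = 0, Mz = 0, gsum = 0;
    long gcnt = 0;
    const double vt = vt_per_feed * feed_rate[s];
    const double cx = feed_pos[s];
    const double base_phase = omega * t[s] + phase0;
    for (int sub = 0; sub < n_sub; ++sub) {
      const double phase = base_phase + sub * sub_step;
      for (int e = 0; e < ne; ++e) {
        const double a = phi0e[e] + phase;
        const double ca = std::cos(a), sa = std::sin(a);
        const double r = R * cth[e];
        // position in i-MCCS with feed, then incline, then path origin
        const double px = r * ca + cx;
        const double py = r * sa;
        const double pz = -R * sth[e];
        const double qx = origin_path[0] + px;
        const double qy = origin_path[1] + ci * py - si * pz;
        const double qz = origin_path[2] + si * py + ci * pz;
        // chip thickness tn = vt * (radial unit vector . feed direction).
        // Both vectors live in the deviated WCS; the incline (about x) and the
        // deviation rotation preserve the inner product, so it collapses to
        // the x component of the radial direction in the i-MCCS.
        const double tn = vt * cth[e] * ca;
        if (tn <= 0.0) continue;
        // actual position under the workspace deviation
        const double ux = qx - wsO[0], uy = qy - wsO[1], uz = qz - wsO[2];
        const double wx = devR(0, 0) * ux + devR(0, 1) * uy + devR(0, 2) * uz + wsO[0] + devT[0];
        const double wy = devR(1, 0) * ux + devR(1, 1) * uy + devR(1, 2) * uz + wsO[1] + devT[1];
        const double wz = devR(2, 0) * ux + devR(2, 1) * uy + devR(2, 2) * uz + wsO[2] + devT[2];
        if (wx < stock_lo[0] || wx > stock_hi[0] || wy < stock_lo[1] ||
            wy > stock_hi[1] || wz < stock_lo[2] || wz >= stock_hi[2])
          continue; // outside stock / above the original top surface
        if (npr && removed_by_prior(qx, qy, qz, &prior(0, 0), npr, R2, prstride))
          continue;
        // nearest-voxel gray, air (lambda = 0) outside the image grid
        const int ix = (int)std::floor((wx - vorigin[0]) * invsx);
        const int iy = (int)std::floor((wy - vorigin[1]) * invsy);
        const int iz = (int)std::floor((wz - vorigin[2]) * invsz);
        double g = 0.0;
        if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
          g = vol[(size_t)iz * nx * ny + (size_t)iy * nx + ix];
        gsum += g;
        ++gcnt;
        double lam = (g - mmin) * inv_span;
        lam = lam < 0.0 ? 0.0 : (lam > 1.0 ? 1.0 : lam);
        if (lam == 0.0) continue;
        const double w = std::pow(lam, mu);
        const double dFr = w * (K[0] * tn * db[e] + K[3] * ds[e]);
        const double dFa = w * (K[1] * tn * db[e] + K[4] * ds[e]);
        const double dFt = w * (K[2] * tn * db[e] + K[5] * ds[e]);
        Fx += -cth[e] * ca * dFr - sth[e] * ca * dFa + sa * dFt;
        Fy += -cth[e] * sa * dFr - sth[e] * sa * dFa - ca * dFt;
        Fz += -sth[e] * dFr + cth[e] * dFa;
        Mz += r * dFt;
      }
    }
    out(s, 0) = Fx / n_sub;
    out(s, 1) = Fy / n_sub;
    out(s, 2) = Fz / n_sub;
    out(s, 3) = Mz / n_sub;
    out(s, 4) = gcnt ? gsum / gcnt : 0.0;
    out(s, 5) = (double)gcnt / n_sub;
  }
  return out;
}
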