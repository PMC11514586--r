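#include <Rcpp.h>
using namespace Rcpp;

// Probe-molecule interaction energy. Terms per atom:
//   * 12-6 Lennard-Jones, eps/rmin pre-combined per atom in R
//   * electrostatics with distance-dependent dielectric eps(r) = 4r:
//       332.0636 * qp * qa / (4 r^2)   [kcal/mol, charges in e, r in Angstrom]
//   * Gaussian hydrogen-bond well between complementary probe/atom polarities,
//     scaled by a directional weight ((1 + cos theta)/2)^2 against the atom's
//     donor/acceptor axis (weight 1 when no axis is defined).
// Total energy clamped at +clamp kcal/mol (points inside atoms).
static const double COULOMB = 332.0636;

static inline double energy_at(const double px, const double py, const double pz,
                               const NumericMatrix &xyz,
                               const NumericVector &qa,
                               const NumericVector &eps,
                               const NumericVector &rmin,
                               const NumericVector &hbd_depth,
                               const NumericMatrix &hb_dir,
                               const double qp, const double hb_r0,
                               const double hb_sigma, const double clamp) {
  const int m = xyz.nrow();
  double e = 0.0;
  for (int a = 0; a < m; ++a) {
    double dx = px - xyz(a, 0), dy = py - xyz(a, 1), dz = pz - xyz(a, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 2.5e-3) r2 = 2.5e-3;  // r >= 0.05 A guard
    double r = std::sqrt(r2);
    // Lennard-Jones
    if (eps[a] > 0.0) {
      double s = rmin[a] / r;
      double s2 = s * s;
      double s6 = s2 * s2 * s2;
      e += eps[a] * (s6 * s6 - 2.0 * s6);
    }
    // electrostatics, eps(r) = 4r
    if (qp != 0.0 && qa[a] != 0.0) e += COULOMB * qp * qa[a] / (4.0 * r2);
    // H-bond well
    if (hbd_depth[a] > 0.0) {
      double w = 1.0;
      double nx = hb_dir(a, 0), ny = hb_dir(a, 1), nz = hb_dir(a, 2);
      double nn = nx * nx + ny * ny + nz * nz;
      if (nn > 1e-12) {
        double ct = (dx * nx + dy * ny + dz * nz) / (r * std::sqrt(nn));
        w = 0.5 * (1.0 + ct);
        w = w * w;
      }
      double dr = r - hb_r0;
      e -= hbd_depth[a] * w * std::exp(-dr * dr / (2.0 * hb_sigma * hb_sigma));
    }
  }
  return e > clamp ? clamp : e;
}

// [[Rcpp::export]]
NumericVector cpp_probe_energy(const NumericMatrix &points,
                               const NumericMatrix &xyz,
                               const NumericVector &qa,
                               const NumericVector &eps,
                               const NumericVector &rmin,
                               const NumericVector &hbd_depth,
                               const NumericMatrix &hb_dir,
                               const double qp, const double hb_r0,
                               const double hb_sigma, const double clamp) {
  const int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = energy_at(points(i, 0), points(i, 1), points(i, 2), xyz, qa, eps,
                       rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp);
  return out;
}

// TIP shape field: -1 on a shell of thickness `spacing` outside the
// van-der-Waals surface, 0 elsewhere.
// [[Rcpp::export]]
NumericVector cpp_tip_field(const NumericMatrix &points,
                            const NumericMatrix &xyz,
                            const NumericVector &rvdw,
                            const double spacing) {
  const int n = points.nrow(), m = xyz.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    for (int a = 0; a < m; ++a) {
      double dx = points(i, 0) - xyz(a, 0);
      double dy = points(i, 1) - xyz(a, 1);
      double dz = points(i, 2) - xyz(a, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - rvdw[a];
      if (d < dmin) dmin = d;
    }
    out[i] = (dmin >= 0.0 && dmin < spacing) ? -1.0 : 0.0;
  }
  return out;
}

// Local minimisation of the analytic probe energy from grid seeds.
// Steepest descent with central-difference gradients and backtracking;
// the energy surface is smooth away from the clamp plateau and starts are
// negative-energy points, so this converges tightly into the local basin.
// [[Rcpp::export]]
List cpp_refine_nodes(const NumericMatrix &starts,
                      const NumericMatrix &xyz,
                      const NumericVector &qa,
                      const NumericVector &eps,
                      const NumericVector &rmin,
                      const NumericVector &hbd_depth,
                      const NumericMatrix &hb_dir,
                      const double qp, const double hb_r0,
                      const double hb_sigma, const double clamp) {
  const int k = starts.nrow();
  NumericMatrix coords(k, 3);
  NumericVector energy(k);
  LogicalVector is_min(k);
  NumericMatrix hess(k, 6);  // xx, yy, zz, xy, xz, yz at convergence
  const double h = 1e-4;
  for (int s = 0; s < k; ++s) {
    double x = starts(s, 0), y = starts(s, 1), z = starts(s, 2);
    double e = energy_at(x, y, z, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp,
                         hb_r0, hb_sigma, clamp);
    double step = 0.05;  // displacement cap, Angstrom (adaptive)
    for (int it = 0; it < 3000; ++it) {
      double gx = (energy_at(x + h, y, z, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp) -
                   energy_at(x - h, y, z, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)) / (2 * h);
      double gy = (energy_at(x, y + h, z, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp) -
                   energy_at(x, y - h, z, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)) / (2 * h);
      double gz = (energy_at(x, y, z + h, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp) -
                   energy_at(x, y, z - h, xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)) / (2 * h);
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-7) break;
      // cap displacement at `step` Angstrom, backtrack until downhill
      double sc = step / gn;
      bool full = true;
      bool moved = false;
      for (int bt = 0; bt < 40; ++bt) {
        double nx = x - sc * gx, ny = y - sc * gy, nz = z - sc * gz;
        double en = energy_at(nx, ny, nz, xyz, qa, eps, rmin, hbd_depth,
                              hb_dir, qp, hb_r0, hb_sigma, clamp);
        if (en < e) {
          x = nx; y = ny; z = nz;
          e = en;
          moved = true;
          break;
        }
        sc *= 0.5;
        full = false;
      }
      if (!moved) break;          // flat to machine precision
      step = full ? std::min(step * 1.3, 0.3) : std::max(step * 0.5, 1e-4);
    }
    // Newton polish: lands exactly on the stationary point of the basin,
    // making converged positions reproducible across rigid-body frames.
    bool pd = false;
    double Hlast[6] = {0, 0, 0, 0, 0, 0};
    {
      double p[3] = {x, y, z};
      for (int it = 0; it < 60; ++it) {
        double g[3], H[3][3];
        double f0 = energy_at(p[0], p[1], p[2], xyz, qa, eps, rmin, hbd_depth,
                              hb_dir, qp, hb_r0, hb_sigma, clamp);
        double fp_[3], fm_[3];
        for (int d = 0; d < 3; ++d) {
          double q1[3] = {p[0], p[1], p[2]}, q2[3] = {p[0], p[1], p[2]};
          q1[d] += h; q2[d] -= h;
          fp_[d] = energy_at(q1[0], q1[1], q1[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp);
          fm_[d] = energy_at(q2[0], q2[1], q2[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp);
          g[d] = (fp_[d] - fm_[d]) / (2 * h);
          H[d][d] = (fp_[d] - 2 * f0 + fm_[d]) / (h * h);
        }
        for (int d1 = 0; d1 < 3; ++d1) for (int d2 = d1 + 1; d2 < 3; ++d2) {
          double qpp[3] = {p[0], p[1], p[2]}, qmm[3] = {p[0], p[1], p[2]};
          double qpm[3] = {p[0], p[1], p[2]}, qmp[3] = {p[0], p[1], p[2]};
          qpp[d1] += h; qpp[d2] += h; qmm[d1] -= h; qmm[d2] -= h;
          qpm[d1] += h; qpm[d2] -= h; qmp[d1] -= h; qmp[d2] += h;
          double v = (energy_at(qpp[0], qpp[1], qpp[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)
                    - energy_at(qpm[0], qpm[1], qpm[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)
                    - energy_at(qmp[0], qmp[1], qmp[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)
                    + energy_at(qmm[0], qmm[1], qmm[2], xyz, qa, eps, rmin, hbd_depth, hb_dir, qp, hb_r0, hb_sigma, clamp)) / (4 * h * h);
          H[d1][d2] = H[d2][d1] = v;
        }
        // positive definiteness via leading principal minors
        double m1 = H[0][0];
        double m2 = H[0][0] * H[1][1] - H[0][1] * H[1][0];
        double det = H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1])
                   - H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0])
                   + H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
        pd = (m1 > 0 && m2 > 0 && det > 0);
        Hlast[0] = H[0][0]; Hlast[1] = H[1][1]; Hlast[2] = H[2][2];
        Hlast[3] = H[0][1]; Hlast[4] = H[0][2]; Hlast[5] = H[1][2];
        double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
        if (gn < 1e-9) break;
        double s0, s1, s2;
        if (pd && std::fabs(det) > 1e-12) {
          // Cramer solve H s = g
          double A00 = H[1][1] * H[2][2] - H[1][2] * H[2][1];
          double A01 = H[0][2] * H[2][1] - H[0][1] * H[2][2];
          double A02 = H[0][1] * H[1][2] - H[0][2] * H[1][1];
          double A10 = H[1][2] * H[2][0] - H[1][0] * H[2][2];
          double A11 = H[0][0] * H[2][2] - H[0][2] * H[2][0];
          double A12 = H[0][2] * H[1][0] - H[0][0] * H[1][2];
          double A20 = H[1][0] * H[2][1] - H[1][1] * H[2][0];
          double A21 = H[0][1] * H[2][0] - H[0][0] * H[2][1];
          double A22 = H[0][0] * H[1][1] - H[0][1] * H[1][0];
          s0 = (A00 * g[0] + A01 * g[1] + A02 * g[2]) / det;
          s1 = (A10 * g[0] + A11 * g[1] + A12 * g[2]) / det;
          s2 = (A20 * g[0] + A21 * g[1] + A22 * g[2]) / det;
        } else {
          double sc = 0.01 / (gn > 1e-12 ? gn : 1.0);
          s0 = sc * g[0]; s1 = sc * g[1]; s2 = sc * g[2];
        }
        double sn = std::sqrt(s0 * s0 + s1 * s1 + s2 * s2);
        if (sn > 0.5) { s0 *= 0.5 / sn; s1 *= 0.5 / sn; s2 *= 0.5 / sn; }
        p[0] -= s0; p[1] -= s1; p[2] -= s2;
      }
      double ep = energy_at(p[0], p[1], p[2], xyz, qa, eps, rmin, hbd_depth,
                            hb_dir, qp, hb_r0, hb_sigma, clamp);
      if (pd && ep <= e + 1e-9) { x = p[0]; y = p[1]; z = p[2]; e = ep; }
      else pd = false;  // polish wandered or saddle: report unpolished point
    }
    coords(s, 0) = x; coords(s, 1) = y; coords(s, 2) = z;
    energy[s] = e;
    is_min[s] = pd;
    for (int d = 0; d < 6; ++d) hess(s, d) = Hlast[d];
  }
  return List::create(_["coords"] = coords, _["energy"] = energy,
                      _["is_minimum"] = is_min, _["hessian"] = hess);
}
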