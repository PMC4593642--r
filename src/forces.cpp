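// Hot force kernels: fiber stretching/bending, edge springs, acto-myosin
// compartments and node-vs-fiber contact repulsion.  These mirror the
// documented energy expressions in R/mechanics.R; the R wrappers are the
// public interface and the finite-difference oracle in the test suite
// checks force/energy consistency end to end.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// stretching + bending nodal forces; optionally accumulates energy
// [[Rcpp::export(name = ".cpp_net_forces")]]
List cpp_net_forces(const NumericMatrix& P,
                    const IntegerVector& seg_a, const IntegerVector& seg_b,
                    const NumericVector& seg_L0, const LogicalVector& seg_act,
                    double kappa_s,
                    const IntegerVector& bend_a, const IntegerVector& bend_b,
                    const IntegerVector& bend_c,
                    const NumericVector& bend_theta0,
                    const NumericVector& bend_L0,
                    const IntegerVector& bend_s1, const IntegerVector& bend_s2,
                    double kappa_b) {
  const int n = P.nrow();
  NumericMatrix F(n, 3);
  double energy = 0.0;
  const int ns = seg_a.size();
  for (int s = 0; s < ns; ++s) {
    if (!seg_act[s]) continue;
    const int a = seg_a[s] - 1, b = seg_b[s] - 1;
    double dx = P(b, 0) - P(a, 0);
    double dy = P(b, 1) - P(a, 1);
    double dz = P(b, 2) - P(a, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L < 1e-300) continue;
    double L0 = seg_L0[s];
    double ext = L - L0;
    double f = kappa_s * ext / L0;       // tension, + = stretched
    energy += 0.5 * kappa_s * ext * ext / L0;
    double ux = dx / L, uy = dy / L, uz = dz / L;
    F(a, 0) += ux * f; F(a, 1) += uy * f; F(a, 2) += uz * f;
    F(b, 0) -= ux * f; F(b, 1) -= uy * f; F(b, 2) -= uz * f;
  }
  const int nb = bend_a.size();
  for (int t = 0; t < nb; ++t) {
    if (!seg_act[bend_s1[t] - 1] || !seg_act[bend_s2[t] - 1]) continue;
    const int a = bend_a[t] - 1, b = bend_b[t] - 1, c = bend_c[t] - 1;
    double ux = P(b, 0) - P(a, 0), uy = P(b, 1) - P(a, 1), uz = P(b, 2) - P(a, 2);
    double vx = P(c, 0) - P(b, 0), vy = P(c, 1) - P(b, 1), vz = P(c, 2) - P(b, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-300 || nv < 1e-300) continue;
    ux /= nu; uy /= nu; uz /= nu;
    vx /= nv; vy /= nv; vz /= nv;
    double cth = ux * vx + uy * vy + uz * vz;
    if (cth > 1.0) cth = 1.0; else if (cth < -1.0) cth = -1.0;
    double theta = std::acos(cth);
    double dth = theta - bend_theta0[t];
    energy += 0.5 * kappa_b * dth * dth / bend_L0[t];
    double sth = std::sqrt(std::max(1.0 - cth * cth, 0.0));
    double w = dth / std::max(sth, 1e-8);     // -> 1 at straight rest angles
    double g = kappa_b * w / bend_L0[t];
    // gradients of cos(theta)
    double dax = -(vx - cth * ux) / nu;
    double day = -(vy - cth * uy) / nu;
    double daz = -(vz - cth * uz) / nu;
    double dcx = (ux - cth * vx) / nv;
    double dcy = (uy - cth * vy) / nv;
    double dcz = (uz - cth * vz) / nv;
    F(a, 0) += g * dax; F(a, 1) += g * day; F(a, 2) += g * daz;
    F(c, 0) += g * dcx; F(c, 1) += g * dcy; F(c, 2) += g * dcz;
    F(b, 0) += g * (-dax - dcx);
    F(b, 1) += g * (-day - dcy);
    F(b, 2) += g * (-daz - dcz);
  }
  return List::create(_["F"] = F, _["energy"] = energy);
}

// linear edge springs (membrane layers)
// [[Rcpp::export(name = ".cpp_edge_springs")]]
NumericMatrix cpp_edge_springs(const NumericMatrix& X,
                               const IntegerMatrix& edges,
                               const NumericVector& L0, double kappa) {
  NumericMatrix F(X.nrow(), 3);
  const int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    const int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double dx = X(b, 0) - X(a, 0);
    double dy = X(b, 1) - X(a, 1);
    double dz = X(b, 2) - X(a, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L < 1e-300) continue;
    double f = kappa * (L - L0[e]) / L;
    F(a, 0) += dx * f; F(a, 1) += dy * f; F(a, 2) += dz * f;
    F(b, 0) -= dx * f; F(b, 1) -= dy * f; F(b, 2) -= dz * f;
  }
  return F;
}

// contact repulsion of probe nodes against fiber cylinders, using a uniform
// grid over segment midpoints built per call.  Returns forces on probes and
// the symmetric reactions on network nodes.
// [[Rcpp::export(name = ".cpp_contact_forces")]]
List cpp_contact_forces(const NumericMatrix& P,
                        const IntegerVector& seg_a, const IntegerVector& seg_b,
                        const LogicalVector& seg_act,
                        const NumericMatrix& probes,
                        const NumericVector& range, double stiffness) {
  const int ns = seg_a.size(), np = probes.nrow();
  NumericMatrix Fp(np, 3), Fn(P.nrow(), 3);
  if (np == 0 || ns == 0) return List::create(_["probes"] = Fp, _["net"] = Fn);
  // grid over segment midpoints; cell size covers range + half-lengths
  double maxhalf = 0.0;
  std::vector<double> mx(ns), my(ns), mz(ns);
  std::vector<int> act;
  act.reserve(ns);
  for (int s = 0; s < ns; ++s) {
    if (!seg_act[s]) continue;
    const int a = seg_a[s] - 1, b = seg_b[s] - 1;
    mx[s] = 0.5 * (P(a, 0) + P(b, 0));
    my[s] = 0.5 * (P(a, 1) + P(b, 1));
    mz[s] = 0.5 * (P(a, 2) + P(b, 2));
    double hx = P(b, 0) - P(a, 0), hy = P(b, 1) - P(a, 1), hz = P(b, 2) - P(a, 2);
    double hl = 0.5 * std::sqrt(hx * hx + hy * hy + hz * hz);
    if (hl > maxhalf) maxhalf = hl;
    act.push_back(s);
  }
  double rmax = 0.0;
  for (int i = 0; i < np; ++i) if (range[i] > rmax) rmax = range[i];
  const double cell = std::max(rmax + maxhalf, 1e-6);
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(act.size() * 2);
  auto key = [cell](double x, double y, double z) -> long long {
    long long ix = (long long)std::floor(x / cell) + 1048576;
    long long iy = (long long)std::floor(y / cell) + 1048576;
    long long iz = (long long)std::floor(z / cell) + 1048576;
    return (ix << 42) ^ (iy << 21) ^ iz;
  };
  for (int idx : act) grid[key(mx[idx], my[idx], mz[idx])].push_back(idx);
  const double r2lim = (rmax + maxhalf) * (rmax + maxhalf) * 4.0;
  for (int i = 0; i < np; ++i) {
    const double x = probes(i, 0), y = probes(i, 1), z = probes(i, 2);
    const double ri = range[i];
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          auto it = grid.find(key(x + ox * cell, y + oy * cell, z + oz * cell));
          if (it == grid.end()) continue;
          for (int s : it->second) {
            double ddx = mx[s] - x, ddy = my[s] - y, ddz = mz[s] - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz > r2lim) continue;
            const int a = seg_a[s] - 1, b = seg_b[s] - 1;
            double ax = P(a, 0), ay = P(a, 1), az = P(a, 2);
            double ex = P(b, 0) - ax, ey = P(b, 1) - ay, ez = P(b, 2) - az;
            double len2 = ex * ex + ey * ey + ez * ez;
            double t = 0.0;
            if (len2 > 1e-300) {
              t = ((x - ax) * ex + (y - ay) * ey + (z - az) * ez) / len2;
              if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
            }
            double fx = ax + t * ex, fy = ay + t * ey, fz = az + t * ez;
            double wx = x - fx, wy = y - fy, wz = z - fz;
            double d = std::sqrt(wx * wx + wy * wy + wz * wz);
            if (d >= ri) continue;
            double nxv, nyv, nzv;
            if (d > 1e-9) { nxv = wx / d; nyv = wy / d; nzv = wz / d; }
            else { nxv = 1e-3; nyv = 0.0; nzv = 0.0; }
            double mag = stiffness * (ri - d);
            double gx = mag * nxv, gy = mag * nyv, gz = mag * nzv;
            Fp(i, 0) += gx; Fp(i, 1) += gy; Fp(i, 2) += gz;
            Fn(a, 0) -= (1 - t) * gx; Fn(a, 1) -= (1 - t) * gy;
            Fn(a, 2) -= (1 - t) * gz;
            Fn(b, 0) -= t * gx; Fn(b, 1) -= t * gy; Fn(b, 2) -= t * gz;
          }
        }
  }
  return List::create(_["probes"] = Fp, _["net"] = Fn);
}

// acto-myosin compartment chain forces (one spring per compartment)
// [[Rcpp::export(name = ".cpp_chain_springs")]]
NumericMatrix cpp_chain_springs(const NumericMatrix& X,
                                const NumericVector& L0,
                                const NumericVector& kappa) {
  const int nc = L0.size();
  NumericMatrix F(X.nrow(), 3);
  for (int j = 0; j < nc; ++j) {
    double dx = X(j + 1, 0) - X(j, 0);
    double dy = X(j + 1, 1) - X(j, 1);
    double dz = X(j + 1, 2) - X(j, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L < 1e-300) continue;
    double f = kappa[j] * (L - L0[j]) / L;
    F(j, 0) += dx * f; F(j, 1) += dy * f; F(j, 2) += dz * f;
    F(j + 1, 0) -= dx * f; F(j + 1, 1) -= dy * f; F(j + 1, 2) -= dz * f;
  }
  return F;
}
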