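// Whole-scene velocity kernel: one call evaluates every force term of the
// coupled system (fiber network, triple-membrane cell, filopodia, focal
// complexes/adhesions, contact repulsion, tethers) on a packed position
// matrix and converts forces to overdamped velocities, including the
// membrane/cortex mobility coupling.  The R module functions implement the
// same expressions individually; a test pins this kernel against their
// assembly on randomized scenes.
//
// Packed layout of Y (rows):
//   [0, n_net)                 network nodes
//   [n_net, n_net+n_c)         cell membrane x_c
//   [.., +n_c)                 transduce layer x_t
//   [.., +n_c)                 nucleus x_n
//   then per filopodium k: filo_len[k] rows (root first, tip last)

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double dist3(const NumericMatrix& Y, int a, int b) {
  double dx = Y(b, 0) - Y(a, 0), dy = Y(b, 1) - Y(a, 1), dz = Y(b, 2) - Y(a, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export(name = ".cpp_scene_eval")]]
List cpp_scene_eval(
    const NumericMatrix& Y,
    int n_net, int n_c,
    const IntegerVector& seg_a, const IntegerVector& seg_b,
    const NumericVector& seg_L0, const LogicalVector& seg_act,
    double kappa_s,
    const IntegerVector& bend_a, const IntegerVector& bend_b,
    const IntegerVector& bend_c, const NumericVector& bend_theta0,
    const NumericVector& bend_L0, const IntegerVector& bend_s1,
    const IntegerVector& bend_s2, double kappa_b,
    const LogicalVector& net_free,
    const IntegerVector& tether_idx, const NumericMatrix& tether_anchor,
    double tether_k,
    const IntegerMatrix& edges, const NumericVector& L0_c,
    const NumericVector& L0_t, const NumericVector& L0_n,
    const NumericVector& cort_L0, double kappa_memb, double kappa_cort,
    const IntegerMatrix& faces, double vol0_n, double kappa_vol,
    const NumericVector& polarization, double cos_cone, double F_L,
    const IntegerVector& fa_i, const IntegerVector& fa_seg,
    const NumericVector& fa_nb, double kappa_LR, double lambda,
    const IntegerVector& sf_t, const IntegerVector& sf_n,
    const NumericVector& sf_L0, double EA_am,
    double C_c, double C_t, double C_n, double C_cort, double C_e, double C_f,
    const IntegerVector& filo_off, const IntegerVector& filo_len,
    const IntegerVector& filo_state, const NumericVector& L_am,
    const IntegerVector& L_am_off,
    const IntegerVector& fc_seg, const NumericVector& fc_nb,
    const NumericMatrix& F_P, const IntegerVector& root_node,
    bool root_fixed,
    double contact_range, double contact_pad, double contact_pad_cell,
    double contact_k) {

  const int ntot = Y.nrow();
  NumericMatrix F(ntot, 3);
  const int oc = n_net, ot = n_net + n_c, on = n_net + 2 * n_c;
  const int nfilo = filo_off.size();

  // ---- network elasticity ----
  const int ns = seg_a.size();
  for (int s = 0; s < ns; ++s) {
    if (!seg_act[s]) continue;
    const int a = seg_a[s] - 1, b = seg_b[s] - 1;
    double dx = Y(b, 0) - Y(a, 0), dy = Y(b, 1) - Y(a, 1), dz = Y(b, 2) - Y(a, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L < 1e-300) continue;
    double f = kappa_s * (L - seg_L0[s]) / seg_L0[s] / L;
    F(a, 0) += dx * f; F(a, 1) += dy * f; F(a, 2) += dz * f;
    F(b, 0) -= dx * f; F(b, 1) -= dy * f; F(b, 2) -= dz * f;
  }
  const int nb = bend_a.size();
  for (int t = 0; t < nb; ++t) {
    if (!seg_act[bend_s1[t] - 1] || !seg_act[bend_s2[t] - 1]) continue;
    const int a = bend_a[t] - 1, b = bend_b[t] - 1, c = bend_c[t] - 1;
    double ux = Y(b, 0) - Y(a, 0), uy = Y(b, 1) - Y(a, 1), uz = Y(b, 2) - Y(a, 2);
    double vx = Y(c, 0) - Y(b, 0), vy = Y(c, 1) - Y(b, 1), vz = Y(c, 2) - Y(b, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-300 || nv < 1e-300) continue;
    ux /= nu; uy /= nu; uz /= nu; vx /= nv; vy /= nv; vz /= nv;
    double cth = ux * vx + uy * vy + uz * vz;
    if (cth > 1.0) cth = 1.0; else if (cth < -1.0) cth = -1.0;
    double theta = std::acos(cth);
    double sth = std::sqrt(std::max(1.0 - cth * cth, 0.0));
    double g = kappa_b * (theta - bend_theta0[t]) /
      std::max(sth, 1e-8) / bend_L0[t];
    double dax = -(vx - cth * ux) / nu, day = -(vy - cth * uy) / nu,
      daz = -(vz - cth * uz) / nu;
    double dcx = (ux - cth * vx) / nv, dcy = (uy - cth * vy) / nv,
      dcz = (uz - cth * vz) / nv;
    F(a, 0) += g * dax; F(a, 1) += g * day; F(a, 2) += g * daz;
    F(c, 0) += g * dcx; F(c, 1) += g * dcy; F(c, 2) += g * dcz;
    F(b, 0) -= g * (dax + dcx); F(b, 1) -= g * (day + dcy);
    F(b, 2) -= g * (daz + dcz);
  }
  // tethers
  for (int i = 0; i < tether_idx.size(); ++i) {
    const int a = tether_idx[i] - 1;
    F(a, 0) -= tether_k * (Y(a, 0) - tether_anchor(i, 0));
    F(a, 1) -= tether_k * (Y(a, 1) - tether_anchor(i, 1));
    F(a, 2) -= tether_k * (Y(a, 2) - tether_anchor(i, 2));
  }

  // ---- cell ----
  if (n_c > 0) {
    const int ne = edges.nrow();
    for (int e = 0; e < ne; ++e) {
      const int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
      const int offs[3] = { oc, ot, on };
      const double* L0s[3] = { &L0_c[0], &L0_t[0], &L0_n[0] };
      for (int l = 0; l < 3; ++l) {
        const int a = offs[l] + i, b = offs[l] + j;
        double dx = Y(b, 0) - Y(a, 0), dy = Y(b, 1) - Y(a, 1),
          dz = Y(b, 2) - Y(a, 2);
        double L = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (L < 1e-300) continue;
        double f = kappa_memb * (L - L0s[l][e]) / L;
        F(a, 0) += dx * f; F(a, 1) += dy * f; F(a, 2) += dz * f;
        F(b, 0) -= dx * f; F(b, 1) -= dy * f; F(b, 2) -= dz * f;
      }
    }
    // cortex pairs
    for (int i = 0; i < n_c; ++i) {
      double dx = Y(oc + i, 0) - Y(ot + i, 0);
      double dy = Y(oc + i, 1) - Y(ot + i, 1);
      double dz = Y(oc + i, 2) - Y(ot + i, 2);
      double L = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (L < 1e-300) continue;
      double f = kappa_cort * (L - cort_L0[i]) / L;
      F(oc + i, 0) -= dx * f; F(oc + i, 1) -= dy * f; F(oc + i, 2) -= dz * f;
      F(ot + i, 0) += dx * f; F(ot + i, 1) += dy * f; F(ot + i, 2) += dz * f;
    }
    // membrane normals (area-weighted) and nucleus volume
    const int nf = faces.nrow();
    std::vector<double> nx(n_c, 0.0), ny(n_c, 0.0), nz(n_c, 0.0);
    double vol = 0.0;
    for (int r = 0; r < nf; ++r) {
      const int a = faces(r, 0) - 1, b = faces(r, 1) - 1, c = faces(r, 2) - 1;
      // membrane face normal
      double ux = Y(oc + b, 0) - Y(oc + a, 0), uy = Y(oc + b, 1) - Y(oc + a, 1),
        uz = Y(oc + b, 2) - Y(oc + a, 2);
      double wx = Y(oc + c, 0) - Y(oc + a, 0), wy = Y(oc + c, 1) - Y(oc + a, 1),
        wz = Y(oc + c, 2) - Y(oc + a, 2);
      double fx = uy * wz - uz * wy, fy = uz * wx - ux * wz,
        fz = ux * wy - uy * wx;
      nx[a] += fx; ny[a] += fy; nz[a] += fz;
      nx[b] += fx; ny[b] += fy; nz[b] += fz;
      nx[c] += fx; ny[c] += fy; nz[c] += fz;
      // nucleus signed volume
      vol += (Y(on + a, 0) * (Y(on + b, 1) * Y(on + c, 2) -
                              Y(on + b, 2) * Y(on + c, 1)) -
              Y(on + a, 1) * (Y(on + b, 0) * Y(on + c, 2) -
                              Y(on + b, 2) * Y(on + c, 0)) +
              Y(on + a, 2) * (Y(on + b, 0) * Y(on + c, 1) -
                              Y(on + b, 1) * Y(on + c, 0))) / 6.0;
    }
    bool flip = vol < 0;
    double volabs = std::fabs(vol);
    double vc = -kappa_vol * (volabs - vol0_n) / vol0_n / 6.0 * (flip ? -1.0 : 1.0);
    for (int r = 0; r < nf; ++r) {
      const int a = faces(r, 0) - 1, b = faces(r, 1) - 1, c = faces(r, 2) - 1;
      double bx = Y(on + b, 0), by = Y(on + b, 1), bz = Y(on + b, 2);
      double cx = Y(on + c, 0), cy = Y(on + c, 1), cz = Y(on + c, 2);
      double ax = Y(on + a, 0), ay = Y(on + a, 1), az = Y(on + a, 2);
      F(on + a, 0) += vc * (by * cz - bz * cy);
      F(on + a, 1) += vc * (bz * cx - bx * cz);
      F(on + a, 2) += vc * (bx * cy - by * cx);
      F(on + b, 0) += vc * (cy * az - cz * ay);
      F(on + b, 1) += vc * (cz * ax - cx * az);
      F(on + b, 2) += vc * (cx * ay - cy * ax);
      F(on + c, 0) += vc * (ay * bz - az * by);
      F(on + c, 1) += vc * (az * bx - ax * bz);
      F(on + c, 2) += vc * (ax * by - ay * bx);
    }
    // lamellipodium force on leading-edge nodes (unit outward normals)
    for (int i = 0; i < n_c; ++i) {
      double nn = std::sqrt(nx[i] * nx[i] + ny[i] * ny[i] + nz[i] * nz[i]);
      if (nn < 1e-300) continue;
      double ux = nx[i] / nn, uy = ny[i] / nn, uz = nz[i] / nn;
      if (ux * polarization[0] + uy * polarization[1] + uz * polarization[2] >
          cos_cone) {
        F(oc + i, 0) += F_L * ux; F(oc + i, 1) += F_L * uy;
        F(oc + i, 2) += F_L * uz;
      }
    }
    // focal adhesions
    for (int q = 0; q < fa_i.size(); ++q) {
      const int i = oc + fa_i[q] - 1;
      const int s = fa_seg[q] - 1;
      const int a = seg_a[s] - 1, b = seg_b[s] - 1;
      double ax = Y(a, 0), ay = Y(a, 1), az = Y(a, 2);
      double ex = Y(b, 0) - ax, ey = Y(b, 1) - ay, ez = Y(b, 2) - az;
      double len2 = ex * ex + ey * ey + ez * ez;
      double t = 0.0;
      if (len2 > 1e-300) {
        t = ((Y(i, 0) - ax) * ex + (Y(i, 1) - ay) * ey + (Y(i, 2) - az) * ez) /
          len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double wx = ax + t * ex - Y(i, 0), wy = ay + t * ey - Y(i, 1),
        wz = az + t * ez - Y(i, 2);
      double Lb = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (Lb < 1e-12) continue;
      double f = fa_nb[q] * kappa_LR * (Lb - lambda) / Lb;
      double gx = f * wx, gy = f * wy, gz = f * wz;
      F(i, 0) += gx; F(i, 1) += gy; F(i, 2) += gz;
      F(a, 0) -= (1 - t) * gx; F(a, 1) -= (1 - t) * gy; F(a, 2) -= (1 - t) * gz;
      F(b, 0) -= t * gx; F(b, 1) -= t * gy; F(b, 2) -= t * gz;
    }
    // stress fibers (transduce <-> nucleus)
    for (int q = 0; q < sf_t.size(); ++q) {
      const int a = ot + sf_t[q] - 1, b = on + sf_n[q] - 1;
      double dx = Y(b, 0) - Y(a, 0), dy = Y(b, 1) - Y(a, 1),
        dz = Y(b, 2) - Y(a, 2);
      double L = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (L < 1e-300) continue;
      double L0 = std::max(sf_L0[q], 0.05);
      double f = (EA_am / L0) * (L - sf_L0[q]) / L;
      F(a, 0) += dx * f; F(a, 1) += dy * f; F(a, 2) += dz * f;
      F(b, 0) -= dx * f; F(b, 1) -= dy * f; F(b, 2) -= dz * f;
    }
  }

  // ---- filopodia ----
  for (int k = 0; k < nfilo; ++k) {
    if (filo_state[k] < 2 || filo_state[k] > 5) continue;
    const int off = filo_off[k], len = filo_len[k];
    const int lo = L_am_off[k];
    for (int j = 0; j < len - 1; ++j) {
      const int a = off + j, b = off + j + 1;
      double dx = Y(b, 0) - Y(a, 0), dy = Y(b, 1) - Y(a, 1),
        dz = Y(b, 2) - Y(a, 2);
      double L = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (L < 1e-300) continue;
      double L0 = L_am[lo + j];
      double f = (EA_am / L0) * (L - L0) / L;
      F(a, 0) += dx * f; F(a, 1) += dy * f; F(a, 2) += dz * f;
      F(b, 0) -= dx * f; F(b, 1) -= dy * f; F(b, 2) -= dz * f;
    }
    const int tip = off + len - 1;
    // focal complex at the tip (anchor re-projected to the closest point)
    if (fc_seg[k] > 0 && fc_nb[k] > 0) {
      const int s = fc_seg[k] - 1;
      const int a = seg_a[s] - 1, b = seg_b[s] - 1;
      double ax = Y(a, 0), ay = Y(a, 1), az = Y(a, 2);
      double ex = Y(b, 0) - ax, ey = Y(b, 1) - ay, ez = Y(b, 2) - az;
      double len2 = ex * ex + ey * ey + ez * ez;
      double t = 0.0;
      if (len2 > 1e-300) {
        t = ((Y(tip, 0) - ax) * ex + (Y(tip, 1) - ay) * ey +
             (Y(tip, 2) - az) * ez) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double wx = ax + t * ex - Y(tip, 0), wy = ay + t * ey - Y(tip, 1),
        wz = az + t * ez - Y(tip, 2);
      double Lb = std::sqrt(wx * wx + wy * wy + wz * wz);
      if (Lb > 1e-12) {
        double f = fc_nb[k] * kappa_LR * (Lb - lambda) / Lb;
        double gx = f * wx, gy = f * wy, gz = f * wz;
        F(tip, 0) += gx; F(tip, 1) += gy; F(tip, 2) += gz;
        F(a, 0) -= (1 - t) * gx; F(a, 1) -= (1 - t) * gy;
        F(a, 2) -= (1 - t) * gz;
        F(b, 0) -= t * gx; F(b, 1) -= t * gy; F(b, 2) -= t * gz;
      }
    }
    // protrusion at the tip, reaction at the rooted actin bundle
    F(tip, 0) += F_P(k, 0); F(tip, 1) += F_P(k, 1); F(tip, 2) += F_P(k, 2);
    F(off, 0) -= F_P(k, 0); F(off, 1) -= F_P(k, 1); F(off, 2) -= F_P(k, 2);
  }

  // ---- contact repulsion (probes: membrane + live filopodium nodes) ----
  // Membrane and filopodial shaft nodes repel within the fiber radius plus
  // a surface-thickness pad; tip nodes repel only within the bare fiber
  // radius so focal-complex bonds (rest length 30 nm) can hold the tip at
  // its adhesion distance.
  if (n_net > 0 && contact_range > 0) {
    std::vector<int> probes;
    std::vector<double> pranges;
    probes.reserve(n_c + 64);
    for (int i = 0; i < n_c; ++i) {
      probes.push_back(oc + i);
      pranges.push_back(contact_range + contact_pad_cell);
    }
    for (int k = 0; k < nfilo; ++k) {
      if (filo_state[k] < 2 || filo_state[k] > 5) continue;
      for (int j = 0; j < filo_len[k]; ++j) {
        probes.push_back(filo_off[k] + j);
        pranges.push_back(j == filo_len[k] - 1 ? contact_range
                                               : contact_range + contact_pad);
      }
    }
    if (!probes.empty()) {
      double maxhalf = 0.0;
      std::vector<int> act;
      act.reserve(ns);
      std::vector<double> mx(ns), my(ns), mz(ns);
      for (int s = 0; s < ns; ++s) {
        if (!seg_act[s]) continue;
        const int a = seg_a[s] - 1, b = seg_b[s] - 1;
        mx[s] = 0.5 * (Y(a, 0) + Y(b, 0));
        my[s] = 0.5 * (Y(a, 1) + Y(b, 1));
        mz[s] = 0.5 * (Y(a, 2) + Y(b, 2));
        double hl = 0.5 * dist3(Y, a, b);
        if (hl > maxhalf) maxhalf = hl;
        act.push_back(s);
      }
      const double cell = std::max(contact_range + contact_pad + maxhalf, 1e-6);
      // flat CSR grid over the midpoint bounding box (no per-bucket allocs)
      double lox = 1e300, loy = 1e300, loz = 1e300;
      double hix = -1e300, hiy = -1e300, hiz = -1e300;
      for (int idx : act) {
        if (mx[idx] < lox) lox = mx[idx]; if (mx[idx] > hix) hix = mx[idx];
        if (my[idx] < loy) loy = my[idx]; if (my[idx] > hiy) hiy = my[idx];
        if (mz[idx] < loz) loz = mz[idx]; if (mz[idx] > hiz) hiz = mz[idx];
      }
      const int gx = (int)((hix - lox) / cell) + 1;
      const int gy = (int)((hiy - loy) / cell) + 1;
      const int gz = (int)((hiz - loz) / cell) + 1;
      const int ncell = gx * gy * gz;
      std::vector<int> count(ncell + 1, 0), order(act.size());
      auto cix = [&](double x, double y, double z) -> int {
        int ix = (int)((x - lox) / cell);
        int iy = (int)((y - loy) / cell);
        int iz = (int)((z - loz) / cell);
        if (ix < 0 || iy < 0 || iz < 0 || ix >= gx || iy >= gy || iz >= gz)
          return -1;
        return ix + gx * (iy + gy * iz);
      };
      std::vector<int> cell_of(act.size());
      for (size_t q = 0; q < act.size(); ++q) {
        int c = cix(mx[act[q]], my[act[q]], mz[act[q]]);
        cell_of[q] = c;
        ++count[c + 1];
      }
      for (int c = 0; c < ncell; ++c) count[c + 1] += count[c];
      std::vector<int> fill = count;
      for (size_t q = 0; q < act.size(); ++q) order[fill[cell_of[q]]++] = act[q];
      for (size_t q = 0; q < probes.size(); ++q) {
        const int pi = probes[q];
        const double prange = pranges[q];
        const double x = Y(pi, 0), y = Y(pi, 1), z = Y(pi, 2);
        int ix0 = (int)std::floor((x - lox) / cell);
        int iy0 = (int)std::floor((y - loy) / cell);
        int iz0 = (int)std::floor((z - loz) / cell);
        for (int ox = -1; ox <= 1; ++ox) {
          int ix = ix0 + ox;
          if (ix < 0 || ix >= gx) continue;
          for (int oy = -1; oy <= 1; ++oy) {
            int iy = iy0 + oy;
            if (iy < 0 || iy >= gy) continue;
            for (int oz = -1; oz <= 1; ++oz) {
              int iz = iz0 + oz;
              if (iz < 0 || iz >= gz) continue;
              const int c = ix + gx * (iy + gy * iz);
              for (int qq = count[c]; qq < count[c + 1]; ++qq) {
                const int s = order[qq];
                const int a = seg_a[s] - 1, b = seg_b[s] - 1;
                double ax = Y(a, 0), ay = Y(a, 1), az = Y(a, 2);
                double ex = Y(b, 0) - ax, ey = Y(b, 1) - ay, ez = Y(b, 2) - az;
                double len2 = ex * ex + ey * ey + ez * ez;
                double t = 0.0;
                if (len2 > 1e-300) {
                  t = ((x - ax) * ex + (y - ay) * ey + (z - az) * ez) / len2;
                  if (t < 0) t = 0; else if (t > 1) t = 1;
                }
                double wx = x - (ax + t * ex), wy = y - (ay + t * ey),
                  wz = z - (az + t * ez);
                double d = std::sqrt(wx * wx + wy * wy + wz * wz);
                if (d >= prange) continue;
                double nxv = 1e-3, nyv = 0.0, nzv = 0.0;
                if (d > 1e-9) { nxv = wx / d; nyv = wy / d; nzv = wz / d; }
                double mag = contact_k * (prange - d);
                double gxf = mag * nxv, gyf = mag * nyv, gzf = mag * nzv;
                F(pi, 0) += gxf; F(pi, 1) += gyf; F(pi, 2) += gzf;
                F(a, 0) -= (1 - t) * gxf; F(a, 1) -= (1 - t) * gyf;
                F(a, 2) -= (1 - t) * gzf;
                F(b, 0) -= t * gxf; F(b, 1) -= t * gyf; F(b, 2) -= t * gzf;
              }
            }
          }
        }
      }
    }
  }

  // root force transfer to the attached membrane node
  if (n_c > 0) {
    for (int k = 0; k < nfilo; ++k) {
      if (filo_state[k] < 2 || filo_state[k] > 5) continue;
      if (root_node[k] <= 0) continue;
      const int i = oc + root_node[k] - 1;
      F(i, 0) += F(filo_off[k], 0);
      F(i, 1) += F(filo_off[k], 1);
      F(i, 2) += F(filo_off[k], 2);
    }
  }

  // ---- velocities ----
  NumericMatrix V(ntot, 3);
  for (int i = 0; i < n_net; ++i) {
    if (!net_free[i]) continue;
    V(i, 0) = F(i, 0) / C_e; V(i, 1) = F(i, 1) / C_e; V(i, 2) = F(i, 2) / C_e;
  }
  if (n_c > 0) {
    const double det = C_c * C_t + C_cort * (C_c + C_t);
    for (int i = 0; i < n_c; ++i) {
      for (int d = 0; d < 3; ++d) {
        double fc = F(oc + i, d), ft = F(ot + i, d);
        V(oc + i, d) = ((C_t + C_cort) * fc + C_cort * ft) / det;
        V(ot + i, d) = (C_cort * fc + (C_c + C_cort) * ft) / det;
        V(on + i, d) = F(on + i, d) / C_n;
      }
    }
  }
  for (int k = 0; k < nfilo; ++k) {
    const int off = filo_off[k], len = filo_len[k];
    if (filo_state[k] < 2 || filo_state[k] > 5) continue;
    for (int j = 0; j < len; ++j) {
      V(off + j, 0) = F(off + j, 0) / C_f;
      V(off + j, 1) = F(off + j, 1) / C_f;
      V(off + j, 2) = F(off + j, 2) / C_f;
    }
    if (root_fixed || root_node[k] <= 0) {
      V(off, 0) = V(off, 1) = V(off, 2) = 0.0;
    } else {
      const int i = oc + root_node[k] - 1;
      V(off, 0) = V(i, 0); V(off, 1) = V(i, 1); V(off, 2) = V(i, 2);
    }
  }
  return List::create(_["V"] = V, _["F"] = F);
}
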