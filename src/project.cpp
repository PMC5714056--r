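#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact ray-grid traversal (Amanatides & Woo / Siddon style).
// Grid of nx x ny cells, cell size dx, dy (cm), lower-left corner (gx0, gy0).
// Visits every cell crossed by the segment [(x0,y0), (x1,y1)] with the exact
// intersection length (cm).
template <typename F>
static inline void traverse_segment(double x0, double y0, double x1, double y1,
                                    double gx0, double gy0, double dx, double dy,
                                    int nx, int ny, F visit) {
  double ddx = x1 - x0, ddy = y1 - y0;
  double L = std::sqrt(ddx * ddx + ddy * ddy);
  if (L <= 0) return;
  double tmin = 0.0, tmax = 1.0;
  // slab clipping against the grid bounding box
  double lox = gx0, hix = gx0 + nx * dx, loy = gy0, hiy = gy0 + ny * dy;
  if (std::fabs(ddx) < 1e-14) {
    if (x0 < lox || x0 > hix) return;
  } else {
    double t0 = (lox - x0) / ddx, t1 = (hix - x0) / ddx;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
  }
  if (std::fabs(ddy) < 1e-14) {
    if (y0 < loy || y0 > hiy) return;
  } else {
    double t0 = (loy - y0) / ddy, t1 = (hiy - y0) / ddy;
    if (t0 > t1) std::swap(t0, t1);
    tmin = std::max(tmin, t0); tmax = std::min(tmax, t1);
  }
  if (tmin >= tmax) return;

  double px = x0 + ddx * tmin, py = y0 + ddy * tmin;
  int ix = (int)std::floor((px - gx0) / dx);
  int iy = (int)std::floor((py - gy0) / dy);
  ix = std::min(std::max(ix, 0), nx - 1);
  iy = std::min(std::max(iy, 0), ny - 1);
  int stepx = ddx > 0 ? 1 : -1, stepy = ddy > 0 ? 1 : -1;
  double tDeltaX = std::fabs(ddx) < 1e-14 ? 1e30 : dx / std::fabs(ddx);
  double tDeltaY = std::fabs(ddy) < 1e-14 ? 1e30 : dy / std::fabs(ddy);
  double nextX = std::fabs(ddx) < 1e-14 ? 1e30
      : ((gx0 + (ix + (stepx > 0 ? 1 : 0)) * dx) - x0) / ddx;
  double nextY = std::fabs(ddy) < 1e-14 ? 1e30
      : ((gy0 + (iy + (stepy > 0 ? 1 : 0)) * dy) - y0) / ddy;
  double t = tmin;
  while (t < tmax - 1e-13) {
    double tNext = std::min(std::min(nextX, nextY), tmax);
    double seg = (tNext - t) * L;
    if (seg > 0) visit(ix, iy, seg);
    if (nextX <= nextY) { ix += stepx; nextX += tDeltaX; }
    else               { iy += stepy; nextY += tDeltaY; }
    t = tNext;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
}

// Per-material intersection lengths for a parallel-beam sinogram.
// lab: 1-based material labels; returns array [nbins, nviews, nmat] of cm.
// [[Rcpp::export]]
NumericVector cpp_project_paths(IntegerMatrix lab, int nmat,
                                double dx, double dy,
                                double gx0, double gy0,
                                NumericVector angles, NumericVector dets) {
  int nx = lab.nrow(), ny = lab.ncol();
  int nv = angles.size(), nb = dets.size();
  NumericVector out(nb * (R_xlen_t)nv * nmat);
  double T = std::sqrt((nx * dx) * (nx * dx) + (ny * dy) * (ny * dy));
  for (int v = 0; v < nv; ++v) {
    double c = std::cos(angles[v]), s = std::sin(angles[v]);
    // ray direction (-sin, cos), offset along (cos, sin)
    for (int b = 0; b < nb; ++b) {
      double sx = dets[b] * c, sy = dets[b] * s;
      double x0 = sx + s * T, y0 = sy - c * T;
      double x1 = sx - s * T, y1 = sy + c * T;
      double *col = &out[(R_xlen_t)v * nb + b];
      traverse_segment(x0, y0, x1, y1, gx0, gy0, dx, dy, nx, ny,
                       [&](int ix, int iy, double len) {
                         int m = lab(ix, iy) - 1;
                         if (m >= 0 && m < nmat)
                           col[(R_xlen_t)m * nb * nv] += len;
                       });
    }
  }
  out.attr("dim") = IntegerVector::create(nb, nv, nmat);
  return out;
}

// Line integrals of an arbitrary image (values per cm) -> [nbins, nviews].
// [[Rcpp::export]]
NumericMatrix cpp_project_image(NumericMatrix img, double dx, double dy,
                                double gx0, double gy0,
                                NumericVector angles, NumericVector dets) {
  int nx = img.nrow(), ny = img.ncol();
  int nv = angles.size(), nb = dets.size();
  NumericMatrix out(nb, nv);
  double T = std::sqrt((nx * dx) * (nx * dx) + (ny * dy) * (ny * dy));
  for (int v = 0; v < nv; ++v) {
    double c = std::cos(angles[v]), s = std::sin(angles[v]);
    for (int b = 0; b < nb; ++b) {
      double sx = dets[b] * c, sy = dets[b] * s;
      double acc = 0.0;
      traverse_segment(sx + s * T, sy - c * T, sx - s * T, sy + c * T,
                       gx0, gy0, dx, dy, nx, ny,
                       [&](int ix, int iy, double len) {
                         acc += img(ix, iy) * len;
                       });
      out(b, v) = acc;
    }
  }
  return out;
}

// Pixel-driven backprojection of ramp-filtered projections q [nbins, nviews].
// Linear interpolation on a uniform detector; scaled by pi / nviews.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix q, NumericVector angles,
                              NumericVector dets, int nx, int ny,
                              double dx, double dy, double gx0, double gy0) {
  int nv = angles.size(), nb = dets.size();
  double s0 = dets[0], ds = dets[1] - dets[0];
  NumericMatrix img(nx, ny);
  std::vector<double> cs(nv), sn(nv);
  for (int v = 0; v < nv; ++v) { cs[v] = std::cos(angles[v]); sn[v] = std::sin(angles[v]); }
  for (int iy = 0; iy < ny; ++iy) {
    double y = gy0 + (iy + 0.5) * dy;
    for (int ix = 0; ix < nx; ++ix) {
      double x = gx0 + (ix + 0.5) * dx;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        double sp = x * cs[v] + y * sn[v];
        double f = (sp - s0) / ds;
        int j = (int)std::floor(f);
        if (j < 0 || j >= nb - 1) continue;
        double w = f - j;
        acc += (1.0 - w) * q(j, v) + w * q(j + 1, v);
      }
      img(ix, iy) = acc * M_PI / nv;
    }
  }
  return img;
}

// Cumulative radiological path (g/cm^2 per unit water density; i.e. cm of
// water-equivalent) from the grid entry to each voxel center, for a beam
// travelling along direction (cos angle, sin angle). dens holds relative
// electron density.
// [[Rcpp::export]]
NumericMatrix cpp_radpath(NumericMatrix dens, double dx, double dy,
                          double gx0, double gy0, double angle) {
  int nx = dens.nrow(), ny = dens.ncol();
  double ux = std::cos(angle), uy = std::sin(angle);
  double T = 2.0 * std::sqrt((nx * dx) * (nx * dx) + (ny * dy) * (ny * dy));
  NumericMatrix out(nx, ny);
  for (int iy = 0; iy < ny; ++iy) {
    double y = gy0 + (iy + 0.5) * dy;
    for (int ix = 0; ix < nx; ++ix) {
      double x = gx0 + (ix + 0.5) * dx;
      double acc = 0.0;
      // integrate upstream from the voxel center to the grid boundary
      traverse_segment(x, y, x - ux * T, y - uy * T,
                       gx0, gy0, dx, dy, nx, ny,
                       [&](int jx, int jy, double len) {
                         acc += dens(jx, jy) * len;
                       });
      out(ix, iy) = acc;
    }
  }
  return out;
}

static inline double interp_mu(const NumericVector &eg, const NumericVector &val,
                               double E) {
  int n = eg.size();
  if (E <= eg[0]) return val[0];
  if (E >= eg[n - 1]) return val[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (eg[mid] <= E) lo = mid; else hi = mid; }
  double w = (E - eg[lo]) / (eg[hi] - eg[lo]);
  return (1 - w) * val[lo] + w * val[hi];
}

// Kerma-approximation Monte Carlo photon transport on a 2-D density slice
// (medium modelled as water of scaled density; in-plane scattering).
// blt_*: one entry per beamlet (angle rad, offset cm, photons to launch).
// Returns deposited energy per voxel (keV, photon-weighted) and a
// batch-based relative uncertainty estimate.
// [[Rcpp::export]]
List cpp_mc_dose(NumericMatrix dens, double dx, double dy,
                 double gx0, double gy0,
                 NumericVector blt_angle, NumericVector blt_s,
                 NumericVector blt_nphot, double width, double E0,
                 NumericVector egrid, NumericVector mu_w,
                 NumericVector pe_frac, int histories, int nbatch) {
  int nx = dens.nrow(), ny = dens.ncol();
  int nblt = blt_angle.size();
  double total_phot = 0.0;
  std::vector<double> cum(nblt);
  for (int b = 0; b < nblt; ++b) { total_phot += blt_nphot[b]; cum[b] = total_phot; }
  NumericMatrix edep(nx, ny);
  std::vector<NumericMatrix> batches;
  for (int k = 0; k < nbatch; ++k) batches.push_back(NumericMatrix(nx, ny));
  if (total_phot <= 0 || histories <= 0) {
    return List::create(_["edep"] = edep, _["rel_unc"] = NumericMatrix(nx, ny),
                        _["emitted"] = 0.0, _["deposited"] = 0.0);
  }
  double W = total_phot / histories;   // photons per history
  double T = 2.0 * std::sqrt((nx * dx) * (nx * dx) + (ny * dy) * (ny * dy));
  const double mec2 = 511.0, ecut = 10.0;
  double emitted = 0.0, deposited = 0.0;

  for (int h = 0; h < histories; ++h) {
    int batch = h % nbatch;
    // pick a beamlet proportional to its photon count
    double r = unif_rand() * total_phot;
    int b = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
    if (b >= nblt) b = nblt - 1;
    double ang = blt_angle[b];
    double c = std::cos(ang), s = std::sin(ang);
    double off = blt_s[b] + (unif_rand() - 0.5) * width;
    // beam travels along (c, s); offset axis is (-s, c)
    double px = -off * s - c * T * 0.5, py = off * c - s * T * 0.5;
    double ux = c, uy = s;
    double E = E0;
    emitted += E * W;
    bool alive = true;
    int nscat = 0;
    while (alive && nscat < 1000) {
      double mu_ref = interp_mu(egrid, mu_w, E);   // 1/cm at unit density
      double tau = -std::log(unif_rand());
      // walk to the interaction point (or out of the grid)
      double acc = 0.0;
      int hit_ix = -1, hit_iy = -1;
      double need = tau;
      double sx = px, sy = py;
      bool interacted = false;
      double travelled_to_hit = 0.0, travelled = 0.0;
      traverse_segment(px, py, px + ux * T, py + uy * T,
                       gx0, gy0, dx, dy, nx, ny,
                       [&](int ix, int iy, double len) {
                         if (interacted) return;
                         double m = mu_ref * dens(ix, iy);
                         if (acc + m * len >= need) {
                           double frac = m > 0 ? (need - acc) / m : len;
                           travelled_to_hit = travelled + frac;
                           hit_ix = ix; hit_iy = iy;
                           interacted = true;
                         }
                         acc += m * len;
                         travelled += len;
                       });
      if (!interacted) break;   // escaped
      px = sx + ux * travelled_to_hit; py = sy + uy * travelled_to_hit;
      // photoelectric vs incoherent
      double pfrac = interp_mu(egrid, pe_frac, E);
      if (unif_rand() < pfrac) {
        edep(hit_ix, hit_iy) += E * W;
        batches[batch](hit_ix, hit_iy) += E * W;
        deposited += E * W;
        alive = false;
      } else {
        // Klein-Nishina: rejection sampling of eps = E'/E
        double alpha = E / mec2;
        double emin = 1.0 / (1.0 + 2.0 * alpha);
        double gmax = (1.0 / emin + emin);
        double eps = 1.0, ct = 1.0;
        for (int it = 0; it < 1000; ++it) {
          eps = emin + unif_rand() * (1.0 - emin);
          ct = 1.0 - (1.0 / eps - 1.0) / alpha;
          double st2 = 1.0 - ct * ct;
          double g = (1.0 / eps + eps) * (1.0 - eps * st2 / (1.0 + eps * eps));
          if (unif_rand() * gmax <= g) break;
        }
        double Eprime = E * eps;
        double et = E - Eprime;
        edep(hit_ix, hit_iy) += et * W;
        batches[batch](hit_ix, hit_iy) += et * W;
        deposited += et * W;
        if (Eprime < ecut) {
          edep(hit_ix, hit_iy) += Eprime * W;
          batches[batch](hit_ix, hit_iy) += Eprime * W;
          deposited += Eprime * W;
          alive = false;
        } else {
          // rotate direction in-plane by +-theta
          double theta = std::acos(std::max(-1.0, std::min(1.0, ct)));
          if (unif_rand() < 0.5) theta = -theta;
          double nux = ux * std::cos(theta) - uy * std::sin(theta);
          double nuy = ux * std::sin(theta) + uy * std::cos(theta);
          ux = nux; uy = nuy; E = Eprime;
          ++nscat;
        }
      }
    }
  }
  // batch-based relative uncertainty of the mean
  NumericMatrix rel(nx, ny);
  for (int iy = 0; iy < ny; ++iy) for (int ix = 0; ix < nx; ++ix) {
    double m = 0, m2 = 0;
    for (int k = 0; k < nbatch; ++k) {
      double v = batches[k](ix, iy) * nbatch;   // scale to full-run estimate
      m += v; m2 += v * v;
    }
    m /= nbatch; m2 /= nbatch;
    double var = (m2 - m * m) / std::max(1, nbatch - 1);
    rel(ix, iy) = m > 0 ? std::sqrt(var) / m : 0.0;
  }
  return List::create(_["edep"] = edep, _["rel_unc"] = rel,
                      _["emitted"] = emitted, _["deposited"] = deposited);
}
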