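// Toy voxel dose engine: ray sampling over a jaw/MLC aperture, 3-D DDA
// traversal of the density grid, exponential attenuation deposit, and a
// history-by-history uncertainty estimator.  Deliberately non-physical
// (single effective mass attenuation coefficient, no scatter): it exercises
// the pipeline's statistics and plumbing, not dosimetry.
//
// RNG: counter-based splitmix64.  Each history derives an independent stream
// from (seed1, seed2, history index), so outputs are bit-reproducible across
// platforms and independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  Rng(uint32_t s1, uint32_t s2, uint64_t ctr) {
    uint64_t key = (static_cast<uint64_t>(s1) << 32) | s2;
    state = mix64(key ^ mix64(ctr + 0x632BE59BD9B4E019ULL));
  }
  double u01() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct V3 {
  double x, y, z;
};

static inline V3 rot_gantry_table(double v[3], double cg, double sg,
                                  double ct, double st) {
  // gantry rotation about patient z (IEC: gantry 90 deg -> source at +x),
  // then table rotation about patient y through the isocenter
  double x1 = v[0] * cg - v[1] * sg;
  double y1 = v[0] * sg + v[1] * cg;
  double z1 = v[2];
  V3 out;
  out.x = x1 * ct + z1 * st;
  out.y = y1;
  out.z = -x1 * st + z1 * ct;
  return out;
}

// [[Rcpp::export]]
List toy_engine_run_cpp(NumericVector density, IntegerVector dims,
                        NumericVector spacing_mm, NumericVector origin_mm,
                        double gantry_deg, double coll_deg, double table_deg,
                        NumericVector iso_mm, NumericVector jaws_mm,
                        NumericVector mlc_a, NumericVector mlc_b,
                        NumericVector leaf_bounds_mm, double sad_mm,
                        double mu_att_cm2g, double e_per_hist, int nhist,
                        int seed1, int seed2, bool ledger, bool emit_phsp,
                        double phsp_ecut_frac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = static_cast<long>(nx) * ny * nz;
  const double dx = spacing_mm[0], dy = spacing_mm[1], dz = spacing_mm[2];
  const double vox_cm3 = (dx / 10.0) * (dy / 10.0) * (dz / 10.0);
  // grid corner (outer boundary of voxel (0,0,0))
  const double cx = origin_mm[0] - dx / 2.0;
  const double cy = origin_mm[1] - dy / 2.0;
  const double cz = origin_mm[2] - dz / 2.0;
  const double gx = cx + nx * dx, gy = cy + ny * dy, gz = cz + nz * dz;

  const double deg = M_PI / 180.0;
  const double cg = std::cos(gantry_deg * deg), sg = std::sin(gantry_deg * deg);
  const double ct = std::cos(table_deg * deg), st = std::sin(table_deg * deg);
  const double cc = std::cos(coll_deg * deg), sc = std::sin(coll_deg * deg);

  // source and in-plane aperture axes in patient coordinates
  double src0[3] = {0.0, -sad_mm, 0.0};
  double e1b[3] = {1.0, 0.0, 0.0};   // beam x (crossplane, MLC travel)
  double e2b[3] = {0.0, 0.0, 1.0};   // beam y (inplane, leaf stacking)
  V3 S = rot_gantry_table(src0, cg, sg, ct, st);
  V3 E1 = rot_gantry_table(e1b, cg, sg, ct, st);
  V3 E2 = rot_gantry_table(e2b, cg, sg, ct, st);
  S.x += iso_mm[0]; S.y += iso_mm[1]; S.z += iso_mm[2];

  // per-leaf open rectangles at the isocenter plane, clipped by the jaws
  const int nleaf = mlc_a.size();
  std::vector<double> rx0(nleaf), rx1(nleaf), ry0(nleaf), ry1(nleaf), carea(nleaf + 1, 0.0);
  const double X1 = jaws_mm[0], X2 = jaws_mm[1], Y1 = jaws_mm[2], Y2 = jaws_mm[3];
  for (int l = 0; l < nleaf; ++l) {
    double x0 = std::max(mlc_a[l], X1), x1 = std::min(mlc_b[l], X2);
    double y0 = std::max(leaf_bounds_mm[l], Y1), y1 = std::min(leaf_bounds_mm[l + 1], Y2);
    double w = std::max(0.0, x1 - x0), h = std::max(0.0, y1 - y0);
    rx0[l] = x0; rx1[l] = x1; ry0[l] = y0; ry1[l] = y1;
    carea[l + 1] = carea[l] + w * h;
  }
  const double area = carea[nleaf];

  std::vector<double> sum(nvox, 0.0), sumsq(nvox, 0.0);
  std::vector<int> led_hist, led_vox;
  std::vector<double> led_dose;
  std::vector<double> ph_rec;  // 9 doubles per record
  std::vector<int> tvox;       // per-history touched voxels
  std::vector<double> tdose;
  tvox.reserve(nx + ny + nz);
  tdose.reserve(nx + ny + nz);

  bool closed = (area <= 0.0);
  const double ecut = phsp_ecut_frac * e_per_hist;

  for (int h = 0; h < nhist && !closed; ++h) {
    Rng rng(static_cast<uint32_t>(seed1), static_cast<uint32_t>(seed2),
            static_cast<uint64_t>(h));
    // sample an aperture point: leaf row by open area, then uniform in row
    double u = rng.u01() * area;
    int lo = 0, hi = nleaf;
    while (lo + 1 < hi) { int mid = (lo + hi) / 2; if (carea[mid] <= u) lo = mid; else hi = mid; }
    double xb = rx0[lo] + rng.u01() * (rx1[lo] - rx0[lo]);
    double yb = ry0[lo] + rng.u01() * (ry1[lo] - ry0[lo]);
    // collimator rotation within the aperture plane
    double xc = xb * cc - yb * sc;
    double yc = xb * sc + yb * cc;
    double Px = iso_mm[0] + xc * E1.x + yc * E2.x;
    double Py = iso_mm[1] + xc * E1.y + yc * E2.y;
    double Pz = iso_mm[2] + xc * E1.z + yc * E2.z;
    double ux = Px - S.x, uy = Py - S.y, uz = Pz - S.z;
    double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= nrm; uy /= nrm; uz /= nrm;

    // slab entry/exit times for the grid bounding box
    double t0 = 0.0, t1 = 1e30;
    double o[3] = {S.x, S.y, S.z}, d[3] = {ux, uy, uz};
    double lo_b[3] = {cx, cy, cz}, hi_b[3] = {gx, gy, gz};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (o[a] < lo_b[a] || o[a] > hi_b[a]) { miss = true; break; }
      } else {
        double ta = (lo_b[a] - o[a]) / d[a], tb = (hi_b[a] - o[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) { miss = true; break; }
      }
    }
    double E = e_per_hist;
    tvox.clear(); tdose.clear();
    if (!miss && t1 > t0) {
      // Amanatides-Woo DDA from entry point
      double px = o[0] + t0 * d[0], py = o[1] + t0 * d[1], pz = o[2] + t0 * d[2];
      int ix = static_cast<int>(std::floor((px - cx) / dx));
      int iy = static_cast<int>(std::floor((py - cy) / dy));
      int iz = static_cast<int>(std::floor((pz - cz) / dz));
      ix = std::min(std::max(ix, 0), nx - 1);
      iy = std::min(std::max(iy, 0), ny - 1);
      iz = std::min(std::max(iz, 0), nz - 1);
      int stepx = (d[0] > 0) - (d[0] < 0);
      int stepy = (d[1] > 0) - (d[1] < 0);
      int stepz = (d[2] > 0) - (d[2] < 0);
      double big = 1e30;
      double tmaxx = (stepx != 0) ? (cx + (ix + (stepx > 0)) * dx - o[0]) / d[0] : big;
      double tmaxy = (stepy != 0) ? (cy + (iy + (stepy > 0)) * dy - o[1]) / d[1] : big;
      double tmaxz = (stepz != 0) ? (cz + (iz + (stepz > 0)) * dz - o[2]) / d[2] : big;
      double tdx = (stepx != 0) ? dx / std::fabs(d[0]) : big;
      double tdy = (stepy != 0) ? dy / std::fabs(d[1]) : big;
      double tdz = (stepz != 0) ? dz / std::fabs(d[2]) : big;
      double tcur = t0;
      while (tcur < t1 - 1e-12 && E > 1e-12 * e_per_hist) {
        double tnext = std::min(std::min(tmaxx, tmaxy), std::min(tmaxz, t1));
        double L_cm = (tnext - tcur) / 10.0;  // mm -> cm
        long v = static_cast<long>(ix) + nx * (static_cast<long>(iy) + static_cast<long>(ny) * iz);
        double rho = density[v];
        if (rho > 0.0 && L_cm > 0.0) {
          double tau = mu_att_cm2g * rho * L_cm;
          double dep = E * (1.0 - std::exp(-tau));
          double dosev = dep / (rho * vox_cm3);  // per-history dose units / g
          tvox.push_back(static_cast<int>(v));
          tdose.push_back(dosev);
          E -= dep;
        }
        tcur = tnext;
        if (tnext >= t1 - 1e-12) break;
        if (tmaxx <= tmaxy && tmaxx <= tmaxz) { ix += stepx; tmaxx += tdx; if (ix < 0 || ix >= nx) break; }
        else if (tmaxy <= tmaxz)              { iy += stepy; tmaxy += tdy; if (iy < 0 || iy >= ny) break; }
        else                                  { iz += stepz; tmaxz += tdz; if (iz < 0 || iz >= nz) break; }
      }
    }
    for (size_t k = 0; k < tvox.size(); ++k) {
      sum[tvox[k]] += tdose[k];
      sumsq[tvox[k]] += tdose[k] * tdose[k];
      if (ledger) {
        led_hist.push_back(h + 1);
        led_vox.push_back(tvox[k] + 1);
        led_dose.push_back(tdose[k]);
      }
    }
    if (emit_phsp && E > ecut) {
      // particle leaving the grid (or never entering it)
      double texit = (!miss && t1 > t0) ? t1 : 0.0;
      ph_rec.push_back(1.0);                 // type: photon
      ph_rec.push_back(E);
      ph_rec.push_back(o[0] + texit * d[0]);
      ph_rec.push_back(o[1] + texit * d[1]);
      ph_rec.push_back(o[2] + texit * d[2]);
      ph_rec.push_back(ux); ph_rec.push_back(uy); ph_rec.push_back(uz);
      ph_rec.push_back(1.0);                 // statistical weight
    }
  }

  const double n = static_cast<double>(nhist);
  NumericVector dose(nvox), sigma(nvox);
  for (long v = 0; v < nvox; ++v) {
    dose[v] = sum[v] / n;
    double var = 0.0;
    if (nhist > 1) {
      var = (sumsq[v] - sum[v] * sum[v] / n) / (n * (n - 1.0));
      if (var < 0.0) var = 0.0;
    }
    sigma[v] = std::sqrt(var);
  }

  List out = List::create(
    _["dose"] = dose, _["sigma"] = sigma,
    _["aperture_closed"] = closed, _["aperture_area_mm2"] = area);
  if (ledger) {
    out["ledger"] = DataFrame::create(_["history"] = led_hist,
                                      _["voxel"] = led_vox,
                                      _["dose"] = led_dose);
  }
  if (emit_phsp) {
    int nrec = static_cast<int>(ph_rec.size() / 9);
    NumericMatrix M(nrec, 9);
    for (int r = 0; r < nrec; ++r)
      for (int c = 0; c < 9; ++c) M(r, c) = ph_rec[9 * r + c];
    colnames(M) = CharacterVector::create("type", "energy_mev", "x_mm", "y_mm",
                                          "z_mm", "u", "v", "w", "weight");
    out["phsp"] = M;
  }
  return out;
}
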