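// Voxel-walking ray tracing and pencil-beam dose deposition.
//
// Geometry convention: isotropic voxel grid, spacing h (cm), origin at the
// corner of voxel (0,0,0); voxel (i,j,k) spans the half-open box
// [origin + i*h, origin + (i+1)*h) per axis; column-major linear index
// i + nx*(j + ny*k). All rays are parameterized p(t) = p0 + t*dir with dir a
// unit vector and t in cm.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS_DIR = 1e-12;

// Clip ray to the grid bounding box. Returns false if no intersection.
static bool clip_to_grid(const double* p0, const double* d,
                         const double* o, const int* dim, double h,
                         double& t0, double& t1) {
  t0 = 0.0;
  t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    double lo = o[a], hi = o[a] + dim[a] * h;
    if (std::fabs(d[a]) > EPS_DIR) {
      double ta = (lo - p0[a]) / d[a];
      double tb = (hi - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    } else if (p0[a] < lo || p0[a] >= hi) {
      return false;
    }
  }
  return t0 < t1;
}

// Core Siddon-style walk. Calls seg(idx, t_begin, t_end) for every voxel
// segment in increasing t, with t measured from p0.
template <typename F>
static void walk(const double* p0, const double* d, const double* o,
                 const int* dim, double h, double tmax, F seg) {
  double t0, t1;
  if (!clip_to_grid(p0, d, o, dim, h, t0, t1)) return;
  t1 = std::min(t1, tmax);
  if (t0 >= t1) return;

  const double tprobe = t0 + 1e-9;
  int idx[3], step[3];
  double tMax[3], tDel[3];
  for (int a = 0; a < 3; ++a) {
    double x = p0[a] + tprobe * d[a];
    int i = (int)std::floor((x - o[a]) / h);
    if (i < 0) i = 0;
    if (i >= dim[a]) i = dim[a] - 1;
    idx[a] = i;
    if (d[a] > EPS_DIR) {
      step[a] = 1;
      tMax[a] = ((i + 1) * h + o[a] - p0[a]) / d[a];
      tDel[a] = h / d[a];
    } else if (d[a] < -EPS_DIR) {
      step[a] = -1;
      tMax[a] = (i * h + o[a] - p0[a]) / d[a];
      tDel[a] = -h / d[a];
    } else {
      step[a] = 0;
      tMax[a] = std::numeric_limits<double>::infinity();
      tDel[a] = std::numeric_limits<double>::infinity();
    }
  }

  const int nx = dim[0], ny = dim[1];
  double t = t0;
  while (t < t1 - 1e-12) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tn = std::min(tMax[a], t1);
    if (tn > t) {
      int lin = idx[0] + nx * (idx[1] + ny * idx[2]);
      seg(lin, t, tn);
    }
    if (tMax[a] >= t1) break;
    t = tMax[a];
    tMax[a] += tDel[a];
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dim[a]) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_wet_rays(NumericVector spr, IntegerVector dim, double spacing,
                           NumericVector origin, NumericMatrix p0,
                           NumericMatrix dir, NumericVector tmax) {
  const int n = p0.nrow();
  NumericVector out(n);
  const double* s = spr.begin();
  const double* o = origin.begin();
  const int* dm = dim.begin();
  for (int r = 0; r < n; ++r) {
    double P[3] = {p0(r, 0), p0(r, 1), p0(r, 2)};
    double D[3] = {dir(r, 0), dir(r, 1), dir(r, 2)};
    double w = 0.0;
    walk(P, D, o, dm, spacing, tmax[r],
         [&](int lin, double ta, double tb) { w += (tb - ta) * s[lin]; });
    out[r] = w;
  }
  return out;
}

// Cumulative WET sampled at t = 0, ds, 2*ds, ..., (n-1)*ds from p0.
// Constant before grid entry (0) and after grid exit (total WET).
// [[Rcpp::export]]
NumericVector cpp_cum_wet(NumericVector spr, IntegerVector dim, double spacing,
                          NumericVector origin, NumericVector p0,
                          NumericVector dir, double ds, int n) {
  std::vector<double> bt, bw;  // breakpoints: t, cumulative wet at t
  bt.push_back(0.0);
  bw.push_back(0.0);
  double cum = 0.0;
  const double* s = spr.begin();
  walk(p0.begin(), dir.begin(), origin.begin(), dim.begin(), spacing,
       std::numeric_limits<double>::infinity(),
       [&](int lin, double ta, double tb) {
         if (bt.back() < ta) {  // gap (entry); cum unchanged
           bt.push_back(ta);
           bw.push_back(cum);
         }
         cum += (tb - ta) * s[lin];
         bt.push_back(tb);
         bw.push_back(cum);
       });
  NumericVector out(n);
  size_t k = 0;
  for (int i = 0; i < n; ++i) {
    double t = i * ds;
    while (k + 1 < bt.size() && bt[k + 1] <= t) ++k;
    if (k + 1 >= bt.size()) {
      out[i] = bw.back();
    } else {
      double span = bt[k + 1] - bt[k];
      double f = span > 0 ? (t - bt[k]) / span : 0.0;
      out[i] = bw[k] + f * (bw[k + 1] - bw[k]);
    }
  }
  return out;
}

static inline double lin_interp(const double* x, const double* y, int n,
                                double q) {
  if (q <= x[0]) return y[0];
  if (q >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= q) lo = mid; else hi = mid;
  }
  double f = (q - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + f * (y[hi] - y[lo]);
}

// Dose influence for all spots of one beam direction (parallel-beam geometry).
//
// vox_xyz: score voxel centres (n x 3). dvec/uhat/vhat: beam axis and
// beam's-eye-view basis (unit, mutually orthogonal); iso: beam isocenter
// (already including any scenario setup shift of the beam relative to the
// patient). spots: (m x 2) lateral (u,v) positions. Per spot: index into the
// shared depth-dose curve table dd_val (rows = curves, sampled on dd_z),
// range R, entrance sigma, aperture index (-1 = open field).
// Apertures: list of lists (umin, vmin, h, nu, nv, trans) giving a bilinear
// transmission field in BEV coordinates about iso.
// Returns triplets (0-based row into vox_xyz, 0-based spot index, dose per MU).
// [[Rcpp::export]]
List cpp_dose_direction(NumericVector spr, IntegerVector dim, double spacing,
                        NumericVector origin, NumericMatrix vox_xyz,
                        NumericVector dvec, NumericVector uhat,
                        NumericVector vhat, NumericVector iso,
                        NumericMatrix spots, IntegerVector dd_index,
                        NumericVector spot_R, NumericVector spot_sig_air,
                        NumericVector dd_z, NumericMatrix dd_val,
                        IntegerVector aper_index, List apertures,
                        double sigma_mcs_coef, double cutoff_sigma,
                        double calib, double rbe, double source_dist) {
  const int nvox = vox_xyz.nrow();
  const int nspot = spots.nrow();
  const int nz = dd_z.size();

  // Voxel coordinates in the beam frame (relative to iso).
  std::vector<double> tv(nvox), uv(nvox), vv(nvox);
  for (int i = 0; i < nvox; ++i) {
    double rx = vox_xyz(i, 0) - iso[0];
    double ry = vox_xyz(i, 1) - iso[1];
    double rz = vox_xyz(i, 2) - iso[2];
    tv[i] = rx * dvec[0] + ry * dvec[1] + rz * dvec[2];
    uv[i] = rx * uhat[0] + ry * uhat[1] + rz * uhat[2];
    vv[i] = rx * vhat[0] + ry * vhat[1] + rz * vhat[2];
  }
  // Sort voxels by u for windowed lookup per spot.
  std::vector<int> ord(nvox);
  for (int i = 0; i < nvox; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return uv[a] < uv[b]; });
  std::vector<double> u_sorted(nvox);
  for (int i = 0; i < nvox; ++i) u_sorted[i] = uv[ord[i]];

  // Pre-extract apertures.
  const int nap = apertures.size();
  std::vector<double> ap_umin(nap), ap_vmin(nap), ap_h(nap);
  std::vector<int> ap_nu(nap), ap_nv(nap);
  std::vector<NumericVector> ap_tr(nap);
  for (int a = 0; a < nap; ++a) {
    List ap = apertures[a];
    ap_umin[a] = as<double>(ap["umin"]);
    ap_vmin[a] = as<double>(ap["vmin"]);
    ap_h[a] = as<double>(ap["h"]);
    ap_nu[a] = as<int>(ap["nu"]);
    ap_nv[a] = as<int>(ap["nv"]);
    ap_tr[a] = as<NumericVector>(ap["trans"]);
  }

  const double ds = spacing * 0.5;
  const int ncum = (int)std::ceil(2.0 * source_dist / ds) + 2;
  std::vector<double> cumt(ncum);
  for (int i = 0; i < ncum; ++i) cumt[i] = i * ds;

  std::vector<int> out_i, out_j;
  std::vector<double> out_x;
  out_i.reserve(1 << 20);
  out_j.reserve(1 << 20);
  out_x.reserve(1 << 20);

  for (int sidx = 0; sidx < nspot; ++sidx) {
    const double us = spots(sidx, 0), vs = spots(sidx, 1);
    const double R = spot_R[sidx];
    const double sig_air = spot_sig_air[sidx];
    const int di = dd_index[sidx];
    const double* ddv = &dd_val(di, 0);
    const double zmax_dd = dd_z[nz - 1];
    // Central-axis ray: start source_dist upstream of the BEV plane.
    double P[3], C[3];
    for (int a = 0; a < 3; ++a)
      P[a] = iso[a] + us * uhat[a] + vs * vhat[a] - source_dist * dvec[a];
    NumericVector cum = cpp_cum_wet(spr, dim, spacing, origin,
                                    NumericVector(P, P + 3), dvec, ds, ncum);
    (void)C;
    const double sig_max =
        std::sqrt(sig_air * sig_air +
                  sigma_mcs_coef * R * sigma_mcs_coef * R);
    const double cut = cutoff_sigma * sig_max;

    int lo = (int)(std::lower_bound(u_sorted.begin(), u_sorted.end(),
                                    us - cut) - u_sorted.begin());
    int hi = (int)(std::upper_bound(u_sorted.begin(), u_sorted.end(),
                                    us + cut) - u_sorted.begin());
    for (int k = lo; k < hi; ++k) {
      const int i = ord[k];
      const double dvr = vv[i] - vs;
      if (std::fabs(dvr) > cut) continue;
      const double t = tv[i] + source_dist;  // distance from ray start
      if (t < 0) continue;
      double wed = lin_interp(cumt.data(), cum.begin(), ncum, t);
      if (wed > zmax_dd) continue;
      double dd = lin_interp(dd_z.begin(), ddv, nz, wed);
      if (dd <= 0) continue;
      double wedc = std::min(wed, R);
      double smcs = sigma_mcs_coef * R * std::pow(wedc / R, 1.5);
      double sig = std::sqrt(sig_air * sig_air + smcs * smcs);
      double dur = uv[i] - us;
      double r2 = dur * dur + dvr * dvr;
      if (r2 > cutoff_sigma * cutoff_sigma * sig * sig) continue;
      double g = std::exp(-r2 / (2.0 * sig * sig)) /
                 (2.0 * M_PI * sig * sig);
      double T = 1.0;
      int ai = aper_index[sidx];
      if (ai >= 0) {
        // bilinear lookup of transmission at the voxel's BEV position
        double gu = (uv[i] - ap_umin[ai]) / ap_h[ai];
        double gv = (vv[i] - ap_vmin[ai]) / ap_h[ai];
        int iu = (int)std::floor(gu), iv = (int)std::floor(gv);
        if (iu < 0 || iv < 0 || iu >= ap_nu[ai] - 1 || iv >= ap_nv[ai] - 1) {
          T = 0.0;
        } else {
          double fu = gu - iu, fv = gv - iv;
          const NumericVector& tr = ap_tr[ai];
          int n_u = ap_nu[ai];
          double t00 = tr[iu + n_u * iv], t10 = tr[iu + 1 + n_u * iv];
          double t01 = tr[iu + n_u * (iv + 1)],
                 t11 = tr[iu + 1 + n_u * (iv + 1)];
          T = (1 - fu) * (1 - fv) * t00 + fu * (1 - fv) * t10 +
              (1 - fu) * fv * t01 + fu * fv * t11;
        }
        if (T <= 1e-9) continue;
      }
      double dose = calib * dd * g * T * rbe;
      if (dose > 0) {
        out_i.push_back(i);
        out_j.push_back(sidx);
        out_x.push_back(dose);
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}

// For each query point, the minimum Euclidean distance to any reference point.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::infinity();
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
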