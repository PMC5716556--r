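#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D volume at one point given in voxel index units
// (0-based, voxel centers at integer coordinates). Returns `fill` outside.
static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sxy = (size_t)nx * ny;
  const double *p = v + x0 + (size_t)nx * y0 + sxy * z0;
  double c000 = p[0],          c100 = p[1];
  double c010 = p[nx],         c110 = p[nx + 1];
  double c001 = p[sxy],        c101 = p[sxy + 1];
  double c011 = p[sxy + nx],   c111 = p[sxy + nx + 1];
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// Bilinear sample of a 2D image at (x, y) in 0-based pixel units.
// valid is set to 0 when the point lies outside the image.
static inline double bi_sample(const double *img, int nx, int ny,
                               double x, double y, int *valid) {
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) {
    if (valid) *valid = 0;
    return 0.0;
  }
  if (valid) *valid = 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  double fx = x - x0, fy = y - y0;
  const double *p = img + x0 + (size_t)nx * y0;
  double c00 = p[0], c10 = p[1], c01 = p[nx], c11 = p[nx + 1];
  double c0 = c00 + fx * (c10 - c00);
  double c1 = c01 + fx * (c11 - c01);
  return c0 + fy * (c1 - c0);
}

// Resample a volume at arbitrary room-coordinate points.
// vol: 3D array; spacing/origin: mm; pts: n x 3 matrix of room coordinates.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, NumericVector spacing,
                                     NumericVector origin, NumericMatrix pts,
                                     double fill) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int i = 0; i < n; i++) {
    double x = (pts(i, 0) - origin[0]) / spacing[0];
    double y = (pts(i, 1) - origin[1]) / spacing[1];
    double z = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = tri_sample(v, nx, ny, nz, x, y, z, fill);
  }
  return out;
}

// Cone-beam line-integral image (DRR) of an attenuation volume.
// All positions are in the volume's own coordinate system (mm).
// src: source position; det_center: detector center; e1/e2: detector axes
// (unit); npx: pixels per axis; px_mm: pixel pitch; step: integration step mm.
// Rays are clipped to the volume bounding box before integration.
// [[Rcpp::export]]
NumericMatrix cpp_drr(NumericVector vol, NumericVector spacing,
                      NumericVector origin, NumericVector src,
                      NumericVector det_center, NumericVector e1,
                      NumericVector e2, IntegerVector npx,
                      NumericVector px_mm, double step) {
  IntegerVector dim = vol.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(vol);
  int npu = npx[0], npv = npx[1];
  NumericMatrix out(npu, npv);
  // bounding box (outer voxel faces)
  double lo[3], hi[3];
  int dims[3] = {nx, ny, nz};
  for (int a = 0; a < 3; a++) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  double cu = (npu - 1) / 2.0, cv = (npv - 1) / 2.0;
  for (int j = 0; j < npv; j++) {
    double vmm = (j - cv) * px_mm[1];
    for (int i = 0; i < npu; i++) {
      double umm = (i - cu) * px_mm[0];
      double dir[3], D[3];
      double len = 0.0;
      for (int a = 0; a < 3; a++) {
        D[a] = det_center[a] + umm * e1[a] + vmm * e2[a];
        dir[a] = D[a] - src[a];
        len += dir[a] * dir[a];
      }
      len = std::sqrt(len);
      for (int a = 0; a < 3; a++) dir[a] /= len;
      // slab clipping
      double t0 = 0.0, t1 = len;
      bool miss = false;
      for (int a = 0; a < 3; a++) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (src[a] < lo[a] || src[a] > hi[a]) { miss = true; break; }
        } else {
          double ta = (lo[a] - src[a]) / dir[a];
          double tb = (hi[a] - src[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
      }
      if (miss || t1 <= t0) { out(i, j) = 0.0; continue; }
      int nstep = (int)std::ceil((t1 - t0) / step);
      if (nstep < 1) nstep = 1;
      double dt = (t1 - t0) / nstep;
      double acc = 0.0;
      // midpoint rule along the clipped chord
      for (int s = 0; s < nstep; s++) {
        double t = t0 + (s + 0.5) * dt;
        double x = (src[0] + t * dir[0] - origin[0]) / spacing[0];
        double y = (src[1] + t * dir[1] - origin[1]) / spacing[1];
        double z = (src[2] + t * dir[2] - origin[2]) / spacing[2];
        acc += tri_sample(v, nx, ny, nz, x, y, z, 0.0);
      }
      out(i, j) = acc * dt;
    }
  }
  return out;
}

// Shift-and-add back-projection onto a beam-aligned slice stack.
// projs: npu x npv x nA array of projection images.
// srcs / dcs: nA x 3 source and detector-center positions (room mm);
// e1s / e2s: nA x 3 detector axes. ucoord/vcoord/depth: grid coordinates of
// the stack (mm in the beam frame); U/V/W: beam frame axes (room unit vecs).
// Returns the mean over covering projections plus a coverage count array.
// [[Rcpp::export]]
List cpp_backproject(NumericVector projs, NumericMatrix srcs,
                     NumericMatrix dcs, NumericMatrix e1s, NumericMatrix e2s,
                     NumericVector px_mm, NumericVector ucoord,
                     NumericVector vcoord, NumericVector depth,
                     NumericVector U, NumericVector V, NumericVector W) {
  IntegerVector pd = projs.attr("dim");
  int npu = pd[0], npv = pd[1], nA = pd[2];
  int nu = ucoord.size(), nv = vcoord.size(), nd = depth.size();
  NumericVector stack(nu * nv * nd);
  IntegerVector cover(nu * nv * nd);
  stack.attr("dim") = IntegerVector::create(nu, nv, nd);
  cover.attr("dim") = IntegerVector::create(nu, nv, nd);
  const double *P = REAL(projs);
  double cu = (npu - 1) / 2.0, cv = (npv - 1) / 2.0;
  // detector plane normals
  std::vector<double> nrm(3 * nA);
  for (int k = 0; k < nA; k++) {
    nrm[3 * k + 0] = e1s(k, 1) * e2s(k, 2) - e1s(k, 2) * e2s(k, 1);
    nrm[3 * k + 1] = e1s(k, 2) * e2s(k, 0) - e1s(k, 0) * e2s(k, 2);
    nrm[3 * k + 2] = e1s(k, 0) * e2s(k, 1) - e1s(k, 1) * e2s(k, 0);
  }
  size_t idx = 0;
  for (int kd = 0; kd < nd; kd++) {
    for (int jv = 0; jv < nv; jv++) {
      for (int iu = 0; iu < nu; iu++, idx++) {
        double pos[3];
        for (int a = 0; a < 3; a++)
          pos[a] = ucoord[iu] * U[a] + vcoord[jv] * V[a] + depth[kd] * W[a];
        double acc = 0.0;
        int cnt = 0;
        for (int k = 0; k < nA; k++) {
          double dS[3], CS[3];
          for (int a = 0; a < 3; a++) {
            dS[a] = pos[a] - srcs(k, a);
            CS[a] = dcs(k, a) - srcs(k, a);
          }
          const double *n = &nrm[3 * k];
          double denom = dS[0] * n[0] + dS[1] * n[1] + dS[2] * n[2];
          if (std::fabs(denom) < 1e-12) continue;
          double s = (CS[0] * n[0] + CS[1] * n[1] + CS[2] * n[2]) / denom;
          if (s <= 0) continue;  // behind source
          double q[3];
          for (int a = 0; a < 3; a++)
            q[a] = srcs(k, a) + s * dS[a] - dcs(k, a);
          double du = q[0] * e1s(k, 0) + q[1] * e1s(k, 1) + q[2] * e1s(k, 2);
          double dv = q[0] * e2s(k, 0) + q[1] * e2s(k, 1) + q[2] * e2s(k, 2);
          double pu = du / px_mm[0] + cu;
          double pv = dv / px_mm[1] + cv;
          int ok = 0;
          double val = bi_sample(P + (size_t)npu * npv * k, npu, npv, pu, pv, &ok);
          if (ok) { acc += val; cnt++; }
        }
        stack[idx] = cnt > 0 ? acc / cnt : 0.0;
        cover[idx] = cnt;
      }
    }
  }
  return List::create(_["stack"] = stack, _["coverage"] = cover);
}

// Selective-plane-removal deblurring of a shift-and-add stack.
// raw: nu x nv x nd stack (beam frame, in-plane coords ucoord/vcoord mm,
// slice depths `depth` mm along the central beam). phis: per-projection
// angular offsets from the central angle (radians). sad: source-isocenter
// distance mm. For each requested output slice i, every slice j of the
// initial stack with guard_mm < |d_j - d_i| <= win_half_mm is warped to
// slice i's geometry along the exact back-projection rays (per-angle
// perspective scaling about the source footprint); the mean over the
// contributing slices and angles (the out-of-plane estimate) is
// subtracted. An empty window leaves the slice unchanged.
// [[Rcpp::export]]
NumericVector cpp_deblur(NumericVector raw, NumericVector ucoord,
                         NumericVector vcoord, NumericVector depth,
                         NumericVector phis, double sad, double win_half_mm,
                         double guard_mm, IntegerVector out_idx) {
  IntegerVector dim = raw.attr("dim");
  int nu = dim[0], nv = dim[1], nd = dim[2];
  int nA = phis.size(), nout = out_idx.size();
  NumericVector out(nu * nv * (size_t)nout);
  out.attr("dim") = IntegerVector::create(nu, nv, nout);
  const double *R = REAL(raw);
  double u0 = ucoord[0], du = nu > 1 ? ucoord[1] - ucoord[0] : 1.0;
  double v0 = vcoord[0], dv = nv > 1 ? vcoord[1] - vcoord[0] : 1.0;
  std::vector<double> acc((size_t)nu * nv), cnt((size_t)nu * nv);
  for (int oi = 0; oi < nout; oi++) {
    int i = out_idx[oi] - 1;  // 1-based from R
    double di = depth[i];
    const double *Ri = R + (size_t)nu * nv * i;
    double *Oi = REAL(out) + (size_t)nu * nv * oi;
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int j = 0; j < nd; j++) {
      double ddm = std::fabs(depth[j] - di);
      if (ddm <= guard_mm || ddm > win_half_mm) continue;
      const double *Rj = R + (size_t)nu * nv * j;
      for (int k = 0; k < nA; k++) {
        double su = sad * std::sin(phis[k]);
        double sw = sad * std::cos(phis[k]);
        double t = (di + sw) / (depth[j] + sw);
        // inverse map: target (x_u, x_v) on plane i -> source coords on j
        for (int jv = 0; jv < nv; jv++) {
          double xv = v0 + jv * dv;
          double vp = (xv / t - v0) / dv;
          for (int iu = 0; iu < nu; iu++) {
            double xu = u0 + iu * du;
            double up = ((su + (xu - su) / t) - u0) / du;
            int ok = 0;
            double val = bi_sample(Rj, nu, nv, up, vp, &ok);
            if (ok) {
              acc[iu + (size_t)nu * jv] += val;
              cnt[iu + (size_t)nu * jv] += 1.0;
            }
          }
        }
      }
    }
    for (size_t p = 0; p < (size_t)nu * nv; p++)
      Oi[p] = Ri[p] - (cnt[p] > 0 ? acc[p] / cnt[p] : 0.0);
  }
  return out;
}

// Zero-mean normalized cross-correlation of a template against a search
// volume over an integer displacement lattice.
// tmpl: template block; vol: treatment volume; t0: 0-based index of the
// template origin inside vol at zero displacement (3 ints); offs: n x 3
// integer displacements (voxels). Returns NCC per displacement (NA when the
// shifted block leaves the volume).
// [[Rcpp::export]]
NumericVector cpp_ncc_lattice(NumericVector tmpl, NumericVector vol,
                              IntegerVector t0, IntegerMatrix offs) {
  IntegerVector td = tmpl.attr("dim"), vd = vol.attr("dim");
  int tx = td[0], ty = td[1], tz = td[2];
  int vx = vd[0], vy = vd[1], vz = vd[2];
  const double *T = REAL(tmpl);
  const double *Vv = REAL(vol);
  size_t nT = (size_t)tx * ty * tz;
  double tmean = 0.0;
  for (size_t p = 0; p < nT; p++) tmean += T[p];
  tmean /= nT;
  double tss = 0.0;
  for (size_t p = 0; p < nT; p++) tss += (T[p] - tmean) * (T[p] - tmean);
  int n = offs.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; r++) {
    int ox = t0[0] + offs(r, 0), oy = t0[1] + offs(r, 1), oz = t0[2] + offs(r, 2);
    if (ox < 0 || oy < 0 || oz < 0 ||
        ox + tx > vx || oy + ty > vy || oz + tz > vz) {
      out[r] = NA_REAL;
      continue;
    }
    double bmean = 0.0;
    for (int k = 0; k < tz; k++)
      for (int j = 0; j < ty; j++) {
        const double *B = Vv + (ox) + (size_t)vx * (oy + j) + (size_t)vx * vy * (oz + k);
        for (int i = 0; i < tx; i++) bmean += B[i];
      }
    bmean /= nT;
    double num = 0.0, bss = 0.0;
    size_t p = 0;
    for (int k = 0; k < tz; k++)
      for (int j = 0; j < ty; j++) {
        const double *B = Vv + (ox) + (size_t)vx * (oy + j) + (size_t)vx * vy * (oz + k);
        for (int i = 0; i < tx; i++, p++) {
          double b = B[i] - bmean;
          num += (T[p] - tmean) * b;
          bss += b * b;
        }
      }
    double den = std::sqrt(tss * bss);
    out[r] = den > 0 ? num / den : NA_REAL;
  }
  return out;
}
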