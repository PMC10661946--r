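// Voxel-level primitives for 3D microvascular image analysis.
//
// All arrays use R's column-major layout: linear index i1 + d1*(i2 + d2*i3),
// 0-based internally. Axis order is (z, y, x) by package convention but the
// routines are symmetric in the axes; anisotropy enters only through the
// per-axis spacing in micrometres. World positions sit at voxel centres:
// world = (index + 0.5) * spacing for 0-based indices.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Exact euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// lower-envelope-of-parabolas), with per-axis spacing so anisotropic stacks
// give true micrometre distances.
// ---------------------------------------------------------------------------

// 1D squared distance transform along a line; w2 = spacing^2.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * q - 2.0 * w2 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dim, NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int dmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(dmax), dbuf(dmax), z(dmax + 1);
  std::vector<int> v(dmax);

  // axis 1 (fastest varying)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; ++i) f[i] = out[base + i];
      dt1d(f, dbuf, v, z, d1, spacing[0] * spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = dbuf[i];
    }
  // axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * d2 * k;
      for (int j = 0; j < d2; ++j) f[j] = out[base + (R_xlen_t)d1 * j];
      dt1d(f, dbuf, v, z, d2, spacing[1] * spacing[1]);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)d1 * j] = dbuf[j];
    }
  // axis 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = i + (R_xlen_t)d1 * j;
      R_xlen_t stride = (R_xlen_t)d1 * d2;
      for (int k = 0; k < d3; ++k) f[k] = out[base + stride * k];
      dt1d(f, dbuf, v, z, d3, spacing[2] * spacing[2]);
      for (int k = 0; k < d3; ++k) out[base + stride * k] = dbuf[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == INF) ? INF : std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling (iterative BFS).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = p % d1, j = (p / d1) % d2, k = p / ((R_xlen_t)d1 * d2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exhaustive multilevel Otsu on a histogram: choose k-1 cuts maximising the
// between-class weighted sum of squared means. Ties broken toward the lowest
// cut vector (loops ascend, improvement must be strict). k in 2..4.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_multi_otsu(NumericVector counts, NumericVector centers, int k) {
  int n = counts.size();
  std::vector<double> w(n + 1, 0.0), m(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    w[i + 1] = w[i] + counts[i];
    m[i + 1] = m[i] + counts[i] * centers[i];
  }
  auto crit = [&](int a, int b) { // bins [a, b), contribution w * mu^2
    double ww = w[b] - w[a];
    if (ww <= 0.0) return 0.0;
    double mu = (m[b] - m[a]) / ww;
    return ww * mu * mu;
  };
  double best = -1.0;
  IntegerVector cuts(k - 1);
  if (k == 2) {
    for (int t = 0; t < n - 1; ++t) {
      double s = crit(0, t + 1) + crit(t + 1, n);
      if (s > best) { best = s; cuts[0] = t; }
    }
  } else if (k == 3) {
    for (int t1 = 0; t1 < n - 2; ++t1)
      for (int t2 = t1 + 1; t2 < n - 1; ++t2) {
        double s = crit(0, t1 + 1) + crit(t1 + 1, t2 + 1) + crit(t2 + 1, n);
        if (s > best) { best = s; cuts[0] = t1; cuts[1] = t2; }
      }
  } else if (k == 4) {
    for (int t1 = 0; t1 < n - 3; ++t1) {
      double c0 = crit(0, t1 + 1);
      for (int t2 = t1 + 1; t2 < n - 2; ++t2) {
        double c1 = c0 + crit(t1 + 1, t2 + 1);
        for (int t3 = t2 + 1; t3 < n - 1; ++t3) {
          double s = c1 + crit(t2 + 1, t3 + 1) + crit(t3 + 1, n);
          if (s > best) { best = s; cuts[0] = t1; cuts[1] = t2; cuts[2] = t3; }
        }
      }
    }
  } else {
    stop("multilevel Otsu supports 2 to 4 classes");
  }
  return cuts; // 0-based bin index; class boundary is 'after this bin'
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis with reflected boundaries.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int nk = kernel.size();
  const int half = nk / 2;
  NumericVector out(arr.size());
  int len = dim[axis - 1];
  R_xlen_t stride = 1;
  for (int a = 0; a < axis - 1; ++a) stride *= dim[a];
  R_xlen_t nlines = (R_xlen_t)d1 * d2 * d3 / len;

  std::vector<double> line(len), res(len);
  // enumerate all lines along `axis`
  R_xlen_t outer_dims[2];
  int nouter = 0;
  for (int a = 0; a < 3; ++a) if (a != axis - 1) outer_dims[nouter++] = dim[a];

  for (R_xlen_t l = 0; l < nlines; ++l) {
    R_xlen_t o1 = l % outer_dims[0], o2 = l / outer_dims[0];
    // reconstruct base linear index with the axis coordinate = 0
    R_xlen_t idx[3];
    int pos = 0;
    for (int a = 0; a < 3; ++a) {
      if (a == axis - 1) { idx[a] = 0; }
      else { idx[a] = (pos == 0) ? o1 : o2; ++pos; }
    }
    R_xlen_t base = idx[0] + (R_xlen_t)d1 * (idx[1] + (R_xlen_t)d2 * idx[2]);
    for (int t = 0; t < len; ++t) line[t] = arr[base + stride * t];
    for (int t = 0; t < len; ++t) {
      double acc = 0.0;
      for (int u = 0; u < nk; ++u) {
        int p = t + u - half;
        if (p < 0) p = -p - 1;           // reflect
        if (p >= len) p = 2 * len - p - 1;
        if (p < 0) p = 0;                // degenerate very short lines
        if (p >= len) p = len - 1;
        acc += line[p] * kernel[u];
      }
      res[t] = acc;
    }
    for (int t = 0; t < len; ++t) out[base + stride * t] = res[t];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Capsule (rounded cylinder) rasterization: union of tubes around polylines.
// Paths are m x 3 matrices of world coordinates (micrometres) in axis order
// (dim1, dim2, dim3); voxel centre of 0-based index i is (i + 0.5) * spacing.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_paint_capsules(IntegerVector dim, NumericVector spacing,
                                 List paths, NumericVector radii) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector mask(n, false);
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  int dims[3] = {d1, d2, d3};
  double sp[3] = {s1, s2, s3};

  for (int si = 0; si < paths.size(); ++si) {
    NumericMatrix path = paths[si];
    double r = radii[si];
    double r2 = r * r;
    int m = path.nrow();
    int nseg = (m >= 2) ? m - 1 : 1;
    for (int e = 0; e < nseg; ++e) {
      double a[3], b[3];
      for (int c = 0; c < 3; ++c) {
        a[c] = path(e, c);
        b[c] = (m >= 2) ? path(e + 1, c) : path(e, c);
      }
      int lo[3], hi[3];
      for (int c = 0; c < 3; ++c) {
        double mn = std::min(a[c], b[c]) - r, mx = std::max(a[c], b[c]) + r;
        lo[c] = std::max(0, (int)std::floor(mn / sp[c] - 0.5));
        hi[c] = std::min(dims[c] - 1, (int)std::ceil(mx / sp[c] - 0.5));
      }
      double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
      double ab2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
      for (int k = lo[2]; k <= hi[2]; ++k) {
        double pz = (k + 0.5) * sp[2];
        for (int j = lo[1]; j <= hi[1]; ++j) {
          double py = (j + 0.5) * sp[1];
          for (int i = lo[0]; i <= hi[0]; ++i) {
            double px = (i + 0.5) * sp[0];
            double ap[3] = {px - a[0], py - a[1], pz - a[2]};
            double t = 0.0;
            if (ab2 > 0.0) {
              t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / ab2;
              t = std::max(0.0, std::min(1.0, t));
            }
            double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
            if (dx * dx + dy * dy + dz * dz <= r2)
              mask[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] = true;
          }
        }
      }
    }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Homotopic 3D thinning to a curve skeleton.
//
// A voxel is deletable when it is a border point (some face neighbour is
// background), is not a curve endpoint (more than one 26-neighbour in the
// foreground), and is a simple point: exactly one 26-connected foreground
// component in its 26-neighbourhood AND exactly one 6-connected background
// component in its 18-neighbourhood touching a face neighbour
// (Bertrand-Malandain characterisation). Deletions are sequential, ordered
// by increasing distance to the background so the medial curve stays centred.
// ---------------------------------------------------------------------------

static inline int nb_index(int a, int b, int c) { // offsets in {-1,0,1}
  return (a + 1) + 3 * (b + 1) + 9 * (c + 1);
}

// precomputed neighbourhood geometry
struct NbGeom {
  int off[27][3];
  bool adj26[27][27];
  bool adj6[27][27];
  bool in18[27];
  bool face[27];
  NbGeom() {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          int p = nb_index(a, b, c);
          off[p][0] = a; off[p][1] = b; off[p][2] = c;
          int l1 = std::abs(a) + std::abs(b) + std::abs(c);
          in18[p] = (l1 == 1 || l1 == 2);
          face[p] = (l1 == 1);
        }
    for (int p = 0; p < 27; ++p)
      for (int q = 0; q < 27; ++q) {
        int da = std::abs(off[p][0] - off[q][0]);
        int db = std::abs(off[p][1] - off[q][1]);
        int dc = std::abs(off[p][2] - off[q][2]);
        int cheb = std::max(da, std::max(db, dc));
        adj26[p][q] = (p != q) && cheb == 1;
        adj6[p][q] = (da + db + dc) == 1;
      }
  }
};
static NbGeom GEOM;

// nb: 27 values of the neighbourhood (centre at 13 ignored for fg check)
static bool is_simple(const int *nb) {
  // one 26-component of foreground among the 26 neighbours
  bool seen[27] = {false};
  int ncomp_fg = 0;
  int stack[27], top;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    top = 0; stack[top++] = p; seen[p] = true;
    while (top) {
      int u = stack[--top];
      for (int q = 0; q < 27; ++q)
        if (q != 13 && nb[q] && !seen[q] && GEOM.adj26[u][q]) {
          seen[q] = true; stack[top++] = q;
        }
    }
  }
  if (ncomp_fg != 1) return false;

  // one 6-component of background in the 18-neighbourhood touching a face cell
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int p = 0; p < 27; ++p) {
    if (!GEOM.face[p] || nb[p] || seenb[p]) continue; // start only from face cells
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    top = 0; stack[top++] = p; seenb[p] = true;
    while (top) {
      int u = stack[--top];
      for (int q = 0; q < 27; ++q)
        if (GEOM.in18[q] && !nb[q] && !seenb[q] && GEOM.adj6[u][q]) {
          seenb[q] = true; stack[top++] = q;
        }
    }
  }
  return ncomp_bg == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  // pad by one background voxel on each side
  const int p1 = d1 + 2, p2 = d2 + 2, p3 = d3 + 2;
  const R_xlen_t pn = (R_xlen_t)p1 * p2 * p3;
  std::vector<char> img(pn, 0);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        if (mask[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)])
          img[(i + 1) + (R_xlen_t)p1 * ((j + 1) + (R_xlen_t)p2 * (k + 1))] = 1;

  // interior depth (distance to background) for centred deletion ordering
  LogicalVector inv(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) inv[i] = !mask[i];
  NumericVector depth = cpp_edt(inv, dim, spacing);

  auto pidx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)p1 * ((R_xlen_t)j + (R_xlen_t)p2 * k);
  };
  auto getdepth = [&](R_xlen_t p) {
    int i = p % p1, j = (p / p1) % p2, k = p / ((R_xlen_t)p1 * p2);
    return depth[(i - 1) + (R_xlen_t)d1 * ((j - 1) + (R_xlen_t)d2 * (k - 1))];
  };

  const R_xlen_t face_off[6] = {1, -1, (R_xlen_t)p1, -(R_xlen_t)p1,
                                (R_xlen_t)p1 * p2, -(R_xlen_t)p1 * p2};

  // Deletion is restricted to one border direction per sub-iteration (the
  // classic 6-subiteration scheme): this caps end-on erosion of tubes and
  // ribbons at one layer per cycle, so elongated structures shrink to
  // centred curves instead of unzipping from their free ends. Within a
  // sub-iteration candidates are processed shallow-first (distance to
  // background) and deleted sequentially, re-checking simplicity against
  // the current image, which preserves topology exactly.
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (int k = 1; k <= d3; ++k)
        for (int j = 1; j <= d2; ++j)
          for (int i = 1; i <= d1; ++i) {
            R_xlen_t p = pidx(i, j, k);
            if (img[p] && !img[p + face_off[dir]]) cand.push_back(p);
          }
      // shallow-first; ties scattered by a fixed hash of the voxel index so
      // flat ribbons collapse to a centred zigzag curve instead of being
      // consumed monotonically from one end
      auto hashp = [](R_xlen_t p) {
        return (uint32_t)((uint64_t)p * 2654435761u);
      };
      std::stable_sort(cand.begin(), cand.end(),
                       [&](R_xlen_t a, R_xlen_t b) {
                         double da = getdepth(a), db = getdepth(b);
                         if (da != db) return da < db;
                         return hashp(a) < hashp(b);
                       });
      for (R_xlen_t p : cand) {
        if (!img[p]) continue;
        if (img[p + face_off[dir]]) continue; // direction border re-check
        // gather 3x3x3 neighbourhood
        int nb[27], nfg = 0;
        int ci = p % p1, cj = (p / p1) % p2, ck = p / ((R_xlen_t)p1 * p2);
        for (int c = -1; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              int q = nb_index(a, b, c);
              nb[q] = img[pidx(ci + a, cj + b, ck + c)];
              if (q != 13 && nb[q]) ++nfg;
            }
        if (nfg <= 1) continue; // endpoint or isolated: keep
        if (!is_simple(nb)) continue;
        img[p] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(mask.size(), false);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i)
        out[i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k)] =
          img[pidx(i + 1, j + 1, k + 1)] != 0;
  return out;
}
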