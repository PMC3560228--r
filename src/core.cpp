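#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// Exact Euclidean distance transform with nearest-background coordinates.
//
// mask: logical, TRUE = foreground (vessel candidate). Distances are measured
// to the nearest FALSE (background) pixel; background pixels map to themselves.
// Ties are broken towards the background pixel with the smaller row, then the
// smaller column, so nearest-pixel lookups are reproducible.
//
// max_dist: optional cutoff; pixels farther than max_dist from any background
// pixel get dist = max_dist and NA coordinates. Distances below the cutoff are
// exact. Pass R_PosInf for the unrestricted transform.
//
// Algorithm: per-column nearest background row (two sweeps), then a bounded
// outward column scan per pixel. Exact because every column whose horizontal
// offset can still beat (or tie) the incumbent is examined.
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalMatrix mask, double max_dist) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix dist(H, W);
  IntegerMatrix nrow_(H, W), ncol_(H, W);

  // nearest background row within each column (-1 if none)
  std::vector<int> near_row((size_t)H * W, -1);
  for (int j = 0; j < W; ++j) {
    int last = -1;
    for (int i = 0; i < H; ++i) {           // sweep down: nearest at or above
      if (!mask(i, j)) last = i;
      near_row[(size_t)j * H + i] = last;
    }
    last = -1;
    for (int i = H - 1; i >= 0; --i) {      // sweep up: nearest at or below
      if (!mask(i, j)) last = i;
      int &cur = near_row[(size_t)j * H + i];
      if (last >= 0) {
        if (cur < 0) cur = last;
        else {
          int d_up = i - cur, d_dn = last - i;
          if (d_dn < d_up) cur = last;      // tie keeps cur (smaller row)
        }
      }
    }
  }

  const bool capped = R_finite(max_dist);
  const double cap2 = capped ? max_dist * max_dist : R_PosInf;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) { dist(i, j) = 0.0; nrow_(i, j) = i + 1; ncol_(i, j) = j + 1; continue; }
      double best = R_PosInf;
      int br = -1, bc = -1;
      for (int o = 0; ; ++o) {
        double o2 = (double)o * o;
        if (o2 > best || o2 > cap2) break;
        for (int s = 0; s < (o == 0 ? 1 : 2); ++s) {
          int jc = (s == 0) ? j - o : j + o;
          if (jc < 0 || jc >= W) continue;
          int r = near_row[(size_t)jc * H + i];
          if (r < 0) continue;
          double dr = (double)(i - r);
          double d2 = o2 + dr * dr;
          if (d2 < best ||
              (d2 == best && (r < br || (r == br && jc < bc)))) {
            best = d2; br = r; bc = jc;
          }
        }
      }
      if (br >= 0 && best <= cap2) {
        dist(i, j) = std::sqrt(best);
        nrow_(i, j) = br + 1;
        ncol_(i, j) = bc + 1;
      } else {
        if (!capped) stop("mask has no background pixel");
        dist(i, j) = max_dist;
        nrow_(i, j) = NA_INTEGER;
        ncol_(i, j) = NA_INTEGER;
      }
    }
  }
  return List::create(_["dist"] = dist, _["nearest_row"] = nrow_,
                      _["nearest_col"] = ncol_);
}

// Per-candidate diameter, angle and contrast-ratio features from the EDT.
//
// For each foreground pixel p at least `margin` pixels from every border:
//   b_p   = nearest background pixel of p
//   b_j   = nearest background pixel of each of the 24 neighbours in the 5x5
//   d     = max_j ||b_p - b_j||, with the argmax b_max ("opposite" background)
//   theta = angle at p in the triangle (b_p, p, b_max), cosine rule with
//           opposite side d, cosine clamped to [-1, 1], degrees
//   C     = max_j gray(b_j) / gray(p); +Inf when gray(p) == 0
// Pixels whose own or neighbour EDT lookup was cut off get d = +Inf (they can
// never verify as capillary). Non-candidates hold NA. Also returns the b_p
// and b_max coordinates for vessel reconstruction.
// [[Rcpp::export(name = ".pixel_features_cpp")]]
List pixel_features_cpp(LogicalMatrix mask, IntegerMatrix nrow_, IntegerMatrix ncol_,
                        NumericMatrix gray, int margin) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d(H, W), theta(H, W), C(H, W);
  IntegerMatrix bmr_(H, W), bmc_(H, W);
  std::fill(d.begin(), d.end(), NA_REAL);
  std::fill(theta.begin(), theta.end(), NA_REAL);
  std::fill(C.begin(), C.end(), NA_REAL);
  std::fill(bmr_.begin(), bmr_.end(), NA_INTEGER);
  std::fill(bmc_.begin(), bmc_.end(), NA_INTEGER);
  const int *nr = INTEGER(nrow_), *nc = INTEGER(ncol_);
  const int *mk = LOGICAL(mask);
  const double *gl = REAL(gray);

  for (int j = margin; j < W - margin; ++j) {
    for (int i = margin; i < H - margin; ++i) {
      if (!mk[(size_t)j * H + i]) continue;
      const size_t idx = (size_t)j * H + i;
      int bpr = nr[idx], bpc = nc[idx];
      if (bpr == NA_INTEGER) { d(i, j) = R_PosInf; theta(i, j) = 0.0; C(i, j) = 0.0; continue; }
      double dmax2 = -1.0;
      int bmr = bpr, bmc = bpc;
      double cmax = R_NegInf;
      bool far = false;
      const double glp = gl[idx];
      for (int dj = -2; dj <= 2; ++dj) {
        const size_t base = (size_t)(j + dj) * H + i;
        for (int di = -2; di <= 2; ++di) {
          if (di == 0 && dj == 0) continue;
          const size_t nidx = base + di;
          int br = nr[nidx], bc = nc[nidx];
          if (br == NA_INTEGER) { far = true; continue; }
          double ddr = (double)(bpr - br), ddc = (double)(bpc - bc);
          double dd2 = ddr * ddr + ddc * ddc;
          if (dd2 > dmax2) { dmax2 = dd2; bmr = br; bmc = bc; }
          double g = gl[(size_t)(bc - 1) * H + (br - 1)];
          double c = (glp <= 0.0) ? R_PosInf : g / glp;
          if (c > cmax) cmax = c;
        }
      }
      if (far) { d(i, j) = R_PosInf; theta(i, j) = 0.0; C(i, j) = cmax; continue; }
      d(i, j) = std::sqrt(dmax2);
      C(i, j) = cmax;
      bmr_(i, j) = bmr;
      bmc_(i, j) = bmc;
      // cosine rule at p: sides |p b_p|, |p b_max|, opposite side d
      double a2 = (double)(bpr - 1 - i) * (bpr - 1 - i) + (double)(bpc - 1 - j) * (bpc - 1 - j);
      double b2 = (double)(bmr - 1 - i) * (bmr - 1 - i) + (double)(bmc - 1 - j) * (bmc - 1 - j);
      double denom = 2.0 * std::sqrt(a2 * b2);
      if (denom <= 0.0) { theta(i, j) = 0.0; continue; }
      double cv = (a2 + b2 - dmax2) / denom;
      cv = std::max(-1.0, std::min(1.0, cv));
      theta(i, j) = std::acos(cv) * 180.0 / M_PI;
    }
  }
  return List::create(_["d"] = d, _["theta"] = theta, _["C"] = C,
                      _["bmax_row"] = bmr_, _["bmax_col"] = bmc_);
}

// Vessel reconstruction: for each verified pixel, a disk of radius
// floor((d - 1) / 2) centred at the midpoint of (b_p, b_max) — the local
// vessel-centre estimate spanned by the diameter d. Reproduces a width-w
// straight band exactly in the continuous limit.
// [[Rcpp::export(name = ".reconstruct_cpp")]]
LogicalMatrix reconstruct_cpp(LogicalMatrix verified, NumericMatrix dmap,
                              IntegerMatrix bpr_, IntegerMatrix bpc_,
                              IntegerMatrix bmr_, IntegerMatrix bmc_) {
  const int H = verified.nrow(), W = verified.ncol();
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!verified(i, j)) continue;
      double dv = dmap(i, j);
      int r = (R_finite(dv) && dv > 1.0) ? (int)std::floor((dv - 1.0) / 2.0) : 0;
      int ci = i, cj = j;
      if (bmr_(i, j) != NA_INTEGER && bpr_(i, j) != NA_INTEGER) {
        ci = (int)std::lround(0.5 * (bpr_(i, j) + bmr_(i, j))) - 1;
        cj = (int)std::lround(0.5 * (bpc_(i, j) + bmc_(i, j))) - 1;
      }
      int r2 = r * r;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = cj + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -r; di <= r; ++di) {
          int ii = ci + di;
          if (ii < 0 || ii >= H) continue;
          if (di * di + dj * dj <= r2) out(ii, jj) = TRUE;
        }
      }
      out(i, j) = TRUE;   // the verified pixel itself is always vessel
    }
  return out;
}

// Guo-Hall thinning to a 1-px, topology-preserving skeleton.
// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalMatrix skeletonize_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> img((size_t)H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      img[(size_t)j * H + i] = mask(i, j) ? 1 : 0;
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int j = 1; j < W - 1; ++j) {
        for (int i = 1; i < H - 1; ++i) {
          if (!img[(size_t)j * H + i]) continue;
          // p2..p9 clockwise starting north
          int p2 = img[(size_t)j * H + (i - 1)];
          int p3 = img[(size_t)(j + 1) * H + (i - 1)];
          int p4 = img[(size_t)(j + 1) * H + i];
          int p5 = img[(size_t)(j + 1) * H + (i + 1)];
          int p6 = img[(size_t)j * H + (i + 1)];
          int p7 = img[(size_t)(j - 1) * H + (i + 1)];
          int p8 = img[(size_t)(j - 1) * H + i];
          int p9 = img[(size_t)(j - 1) * H + (i - 1)];
          int Cn = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                   ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = std::min(N1, N2);
          int m = (iter == 0) ? ((p6 || p7 || (!p9)) && p8)
                              : ((p2 || p3 || (!p5)) && p4);
          if (Cn == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k)
        img[(size_t)del[k].second * H + del[k].first] = 0;
      if (!del.empty()) changed = true;
    }
  }
  LogicalMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = img[(size_t)j * H + i] != 0;
  return out;
}

// 8-connected component labelling (0 = background).
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

static inline void med_swap(double &a, double &b) {
  if (b < a) { double t = a; a = b; b = t; }
}

// Paeth's 19-comparison exact median of 9.
static inline double median9(double *p) {
  med_swap(p[1], p[2]); med_swap(p[4], p[5]); med_swap(p[7], p[8]);
  med_swap(p[0], p[1]); med_swap(p[3], p[4]); med_swap(p[6], p[7]);
  med_swap(p[1], p[2]); med_swap(p[4], p[5]); med_swap(p[7], p[8]);
  med_swap(p[0], p[3]); med_swap(p[5], p[8]); med_swap(p[4], p[7]);
  med_swap(p[3], p[6]); med_swap(p[1], p[4]); med_swap(p[2], p[5]);
  med_swap(p[4], p[7]); med_swap(p[4], p[2]); med_swap(p[6], p[4]);
  med_swap(p[4], p[2]);
  return p[4];
}

// in-place Hoare quickselect for the k-th smallest of n
static double quickselect(double *a, int n, int k) {
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    double pivot = a[(lo + hi) / 2];
    int i = lo, j = hi;
    while (i <= j) {
      while (a[i] < pivot) ++i;
      while (a[j] > pivot) --j;
      if (i <= j) { double t = a[i]; a[i] = a[j]; a[j] = t; ++i; --j; }
    }
    if (k <= j) hi = j; else if (k >= i) lo = i; else break;
  }
  return a[k];
}

// Exact k x k median filter with edge-replicated borders.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  const int H = img.nrow(), W = img.ncol(), r = (k - 1) / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf((size_t)k * k);
  const int mid = (k * k) / 2;  // k odd -> k*k odd -> true median
  const double *src = REAL(img);
  for (int j = 0; j < W; ++j) {
    const bool jint = (j >= r && j < W - r);
    for (int i = 0; i < H; ++i) {
      double *b = &buf[0];
      if (jint && i >= r && i < H - r) {        // interior: contiguous copies
        for (int dj = -r; dj <= r; ++dj) {
          const double *p = src + (size_t)(j + dj) * H + (i - r);
          for (int di = 0; di < k; ++di) *b++ = p[di];
        }
      } else {
        for (int dj = -r; dj <= r; ++dj) {
          int jj = std::min(std::max(j + dj, 0), W - 1);
          const double *col = src + (size_t)jj * H;
          for (int di = -r; di <= r; ++di) {
            int ii = std::min(std::max(i + di, 0), H - 1);
            *b++ = col[ii];
          }
        }
      }
      out(i, j) = (k == 3) ? median9(&buf[0])
                           : quickselect(&buf[0], k * k, mid);
    }
  }
  return out;
}

// Separable correlation with edge-replicated borders: rows with ky (vertical
// taps), then columns with kx (horizontal taps). Kernel lengths must be odd.
// [[Rcpp::export(name = ".sep_filter_cpp")]]
NumericMatrix sep_filter_cpp(NumericMatrix img, NumericVector ky, NumericVector kx) {
  const int H = img.nrow(), W = img.ncol();
  const int ry = (ky.size() - 1) / 2, rx = (kx.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int u = -ry; u <= ry; ++u) {
        int ii = std::min(std::max(i + u, 0), H - 1);
        s += img(ii, j) * ky[u + ry];
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int v = -rx; v <= rx; ++v) {
        int jj = std::min(std::max(j + v, 0), W - 1);
        s += tmp(i, jj) * kx[v + rx];
      }
      out(i, j) = s;
    }
  return out;
}
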