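#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Closest pair of parameters (s on a, t on b) between two closed segments.
// Robust variant of the standard clamped closest-point algorithm; the
// parallel-overlap case is resolved to the midpoint of the overlapping
// parameter interval so the answer is unique and symmetric.
static void seg_closest_core(const double *a0, const double *a1,
                             const double *b0, const double *b1,
                             double &s, double &t, double &dist) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = a1[k] - a0[k];
    d2[k] = b1[k] - b0[k];
    r[k]  = a0[k] - b0[k];
  }
  double A = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double E = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double F = d2[0]*r[0]  + d2[1]*r[1]  + d2[2]*r[2];
  const double eps = 1e-14;

  if (A <= eps && E <= eps) {            // both degenerate: point-point
    s = 0.0; t = 0.0;
  } else if (A <= eps) {                 // a is a point
    s = 0.0; t = clamp01(F / E);
  } else {
    double C = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (E <= eps) {                      // b is a point
      t = 0.0; s = clamp01(-C / A);
    } else {
      double B = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = A*E - B*B;
      if (denom <= 1e-12 * A * E) {
        // parallel: minimizing set may be an interval; take its midpoint
        double ta0 = -C / A;             // b0 projected on a
        double ta1 = (B - C) / A;        // b1 projected on a
        double lo = std::max(0.0, std::min(ta0, ta1));
        double hi = std::min(1.0, std::max(ta0, ta1));
        if (lo <= hi) {
          s = 0.5 * (lo + hi);
          double px[3];
          for (int k = 0; k < 3; ++k) px[k] = a0[k] + s*d1[k] - b0[k];
          t = clamp01((px[0]*d2[0] + px[1]*d2[1] + px[2]*d2[2]) / E);
        } else {                         // disjoint parallel: endpoint answer
          s = clamp01(ta0 < 0.0 ? 0.0 : 1.0);
          t = clamp01((B*s + F) / E);
          s = clamp01((B*t - C) / A);
        }
      } else {
        s = clamp01((B*F - C*E) / denom);
        t = (B*s + F) / E;
        if (t < 0.0)      { t = 0.0; s = clamp01(-C / A); }
        else if (t > 1.0) { t = 1.0; s = clamp01((B - C) / A); }
      }
    }
  }
  double w0 = r[0] + s*d1[0] - t*d2[0];
  double w1 = r[1] + s*d1[1] - t*d2[1];
  double w2 = r[2] + s*d1[2] - t*d2[2];
  dist = std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// [[Rcpp::export]]
NumericVector cpp_seg_closest(NumericVector a, NumericVector b) {
  double s, t, dist;
  seg_closest_core(&a[0], &a[3], &b[0], &b[3], s, t, dist);
  NumericVector out(9);
  out[0] = dist; out[1] = s; out[2] = t;
  for (int k = 0; k < 3; ++k) {
    out[3 + k] = a[k] + s * (a[3 + k] - a[k]);   // closest point on a
    out[6 + k] = b[k] + t * (b[3 + k] - b[k]);   // closest point on b
  }
  return out;
}

// [[Rcpp::export]]
double cpp_seg_dist(NumericVector a, NumericVector b) {
  double s, t, dist;
  seg_closest_core(&a[0], &a[3], &b[0], &b[3], s, t, dist);
  return dist;
}

// Distance from one query segment to each row of a segment matrix
// (columns x0,y0,z0,x1,y1,z1).
// [[Rcpp::export]]
NumericVector cpp_seg_dist_many(NumericVector a, NumericMatrix segs) {
  int n = segs.nrow();
  NumericVector out(n);
  double s, t, d;
  double b0[3], b1[3];
  for (int i = 0; i < n; ++i) {
    b0[0] = segs(i, 0); b0[1] = segs(i, 1); b0[2] = segs(i, 2);
    b1[0] = segs(i, 3); b1[1] = segs(i, 4); b1[2] = segs(i, 5);
    seg_closest_core(&a[0], &a[3], b0, b1, s, t, d);
    out[i] = d;
  }
  return out;
}

// Brute-force all-pairs capsule overlap audit. segs: n x 6 endpoint matrix,
// r: capsule radii, front_id: owning front, parent_id: owning front's parent
// (-1 for somata). Pairs are skipped when adjacent in the tree sense:
// parent/child segments or siblings sharing their proximal endpoint.
// Returns a 2-column matrix of 1-based offending row pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_audit_overlaps(NumericMatrix segs, NumericVector r,
                                 IntegerVector front_id, IntegerVector parent_id,
                                 int max_report = 1000) {
  int n = segs.nrow();
  std::vector<double> cx(n), cy(n), cz(n), reach(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = 0.5 * (segs(i,0) + segs(i,3));
    cy[i] = 0.5 * (segs(i,1) + segs(i,4));
    cz[i] = 0.5 * (segs(i,2) + segs(i,5));
    double hx = segs(i,3) - segs(i,0), hy = segs(i,4) - segs(i,1),
           hz = segs(i,5) - segs(i,2);
    reach[i] = 0.5 * std::sqrt(hx*hx + hy*hy + hz*hz) + r[i];
  }
  std::vector<int> hits;
  double s, t, d;
  double a0[3], a1[3], b0[3], b1[3];
  for (int i = 0; i < n && (int)hits.size() < 2 * max_report; ++i) {
    a0[0]=segs(i,0); a0[1]=segs(i,1); a0[2]=segs(i,2);
    a1[0]=segs(i,3); a1[1]=segs(i,4); a1[2]=segs(i,5);
    for (int j = i + 1; j < n; ++j) {
      double dx = cx[i]-cx[j], dy = cy[i]-cy[j], dz = cz[i]-cz[j];
      double rr = reach[i] + reach[j];
      if (dx*dx + dy*dy + dz*dz >= rr*rr) continue;        // sphere prune
      if (front_id[i] == parent_id[j] || front_id[j] == parent_id[i]) continue;
      if (parent_id[i] >= 0 && parent_id[i] == parent_id[j]) continue;
      b0[0]=segs(j,0); b0[1]=segs(j,1); b0[2]=segs(j,2);
      b1[0]=segs(j,3); b1[1]=segs(j,4); b1[2]=segs(j,5);
      seg_closest_core(a0, a1, b0, b1, s, t, d);
      if (d < r[i] + r[j]) {
        hits.push_back(i + 1);
        hits.push_back(j + 1);
        if ((int)hits.size() >= 2 * max_report) break;
      }
    }
  }
  int m = (int)hits.size() / 2;
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) { out(k,0) = hits[2*k]; out(k,1) = hits[2*k+1]; }
  return out;
}

// Dense-grid oracle for segment-segment distance: minimizes |a(s) - b(t)|
// over an n x n grid of the two segment parameters. Deliberately independent
// of seg_closest_core; used as the reference in tests.
// [[Rcpp::export]]
NumericVector cpp_seg_dist_grid(NumericVector a, NumericVector b, int n = 2001) {
  double d1[3], d2[3], r0[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = a[3 + k] - a[k];
    d2[k] = b[3 + k] - b[k];
    r0[k] = a[k] - b[k];
  }
  double best = R_PosInf, bs = 0.0, bt = 0.0;
  double step = 1.0 / (n - 1);
  for (int i = 0; i < n; ++i) {
    double s = i * step;
    double u0 = r0[0] + s*d1[0], u1 = r0[1] + s*d1[1], u2 = r0[2] + s*d1[2];
    for (int j = 0; j < n; ++j) {
      double t = j * step;
      double w0 = u0 - t*d2[0], w1 = u1 - t*d2[1], w2 = u2 - t*d2[2];
      double q = w0*w0 + w1*w1 + w2*w2;
      if (q < best) { best = q; bs = s; bt = t; }
    }
  }
  return NumericVector::create(std::sqrt(best), bs, bt);
}
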