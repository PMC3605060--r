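// Geometric-topology kernels: KMT chain simplification, crossing
// enumeration of a generic planar projection, and evaluation of the
// Alexander determinant |Delta(-1)| from the underpass presentation.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a[1] * b[2] - a[2] * b[1],
              a[2] * b[0] - a[0] * b[2],
              a[0] * b[1] - a[1] * b[0]};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Does segment p->q cross triangle (a,b,c)?  Borderline hits count as
// crossings so that KMT stays conservative (never removes a vertex whose
// elimination might change topology).
static bool seg_hits_triangle(const Vec3 &p, const Vec3 &q,
                              const Vec3 &a, const Vec3 &b, const Vec3 &c,
                              double tol) {
  Vec3 e1 = sub(b, a), e2 = sub(c, a), d = sub(q, p);
  Vec3 n = cross(e1, e2);
  double area2 = norm(n);
  if (area2 < 1e-12) return false; // degenerate triangle sweeps ~no area
  double denom = dot(n, d);
  Vec3 ap = sub(p, a);
  if (std::fabs(denom) < 1e-14) {
    // segment parallel to plane: treat as hit if it lies essentially in
    // the plane and overlaps the triangle's bounding sphere (conservative)
    if (std::fabs(dot(n, ap)) / area2 > tol) return false;
    return true; // conservative: do not remove
  }
  double t = -dot(n, ap) / denom;
  if (t < -tol || t > 1 + tol) return false;
  // intersection point
  Vec3 x{p[0] + t * d[0], p[1] + t * d[1], p[2] + t * d[2]};
  // barycentric inside-test (with tolerance, inclusive)
  Vec3 v0 = e1, v1 = e2, v2 = sub(x, a);
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double d20 = dot(v2, v0), d21 = dot(v2, v1);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-14) return true; // conservative
  double u = (d11 * d20 - d01 * d21) / den;
  double v = (d00 * d21 - d01 * d20) / den;
  return (u >= -tol && v >= -tol && u + v <= 1 + tol);
}

static std::vector<Vec3> mat_to_vec(const NumericMatrix &m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3{m(i, 0), m(i, 1), m(i, 2)};
  return v;
}
static NumericMatrix vec_to_mat(const std::vector<Vec3> &v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i][0]; m(i, 1) = v[i][1]; m(i, 2) = v[i][2];
  }
  return m;
}

// Can vertex i (with cyclic neighbours im, ip) be removed?  True when no
// other chain segment pierces the elimination triangle (v[im], v[i], v[ip]).
// Segments sharing a triangle corner are tested with that endpoint nudged
// slightly off the corner, so the unavoidable corner contact does not
// block removal while a genuine near-corner piercing still does.
static bool kmt_removable(const std::vector<Vec3> &v, int i, int im, int ip,
                          bool closed) {
  const Vec3 &a = v[im], &b = v[i], &c = v[ip];
  double area = norm(cross(sub(b, a), sub(c, a)));
  if (area < 1e-9) return true; // collinear spike: zero-area sweep
  int n = v.size();
  int nseg = closed ? n : n - 1;
  const double nudge = 1e-6, tol = 1e-9;
  for (int s = 0; s < nseg; ++s) {
    int s2 = (s + 1) % n;
    if (s == im || s == i) continue; // the triangle's own two segments
    Vec3 p = v[s], q = v[s2];
    if (s == ip) { // starts at corner c
      for (int d = 0; d < 3; ++d) p[d] += (q[d] - p[d]) * nudge;
    }
    if (s2 == im) { // ends at corner a
      for (int d = 0; d < 3; ++d) q[d] += (p[d] - q[d]) * nudge;
    }
    if (seg_hits_triangle(p, q, a, b, c, tol)) return false;
  }
  return true;
}

// KMT simplification.  Repeatedly removes an interior vertex whose
// elimination triangle is not pierced by any other chain segment; for
// closed = true the chain is treated cyclically (a true isotopy of the
// ring), for open chains the two endpoints are fixed.
// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix coords, bool closed) {
  std::vector<Vec3> v = mat_to_vec(coords);
  bool changed = true;
  while (changed) {
    changed = false;
    if ((int)v.size() <= 3) break;
    int i = closed ? 0 : 1;
    while ((int)v.size() > 3 && i < (int)v.size()) {
      int n = v.size();
      if (!closed && (i == 0 || i >= n - 1)) break;
      int im = (i - 1 + n) % n, ip = (i + 1) % n;
      if (kmt_removable(v, i, im, ip, closed)) {
        v.erase(v.begin() + i);
        changed = true; // stay at index i (next vertex slid into place)
      } else {
        ++i;
      }
    }
  }
  return vec_to_mat(v);
}

// ---- Alexander determinant ------------------------------------------------

struct Underpass {
  double pos_under;  // chain position (segment + parameter) of under-strand
  double pos_over;   // chain position of over-strand point
};

// Bareiss fraction-free determinant over __int128.  Returns -1 on overflow.
static double int_det(std::vector<std::vector<long long>> M) {
  int n = M.size();
  if (n == 0) return 1.0;
  typedef __int128 big;
  std::vector<std::vector<big>> a(n, std::vector<big>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) a[i][j] = M[i][j];
  big prev = 1;
  int sign = 1;
  const big LIM = (big)1 << 100;
  for (int k = 0; k < n - 1; ++k) {
    if (a[k][k] == 0) {
      int p = -1;
      for (int i = k + 1; i < n; ++i) if (a[i][k] != 0) { p = i; break; }
      if (p < 0) return 0.0;
      std::swap(a[k], a[p]);
      sign = -sign;
    }
    for (int i = k + 1; i < n; ++i) {
      for (int j = k + 1; j < n; ++j) {
        big num = a[i][j] * a[k][k] - a[i][k] * a[k][j];
        a[i][j] = num / prev;
        if (a[i][j] > LIM || a[i][j] < -LIM) return -1.0;
      }
      a[i][k] = 0;
    }
    prev = a[k][k];
  }
  big det = a[n - 1][n - 1];
  double out = (double)det * sign;
  return std::fabs(out);
}

// Alexander determinant |Delta(-1)| of a closed polygon (rows = vertices,
// closure from last row back to the first).  The polygon must be in generic
// position with respect to the z-projection; returns NA_real_ when the
// projection is degenerate so the caller can re-rotate and retry.
// [[Rcpp::export]]
double cpp_alexander_det(NumericMatrix ring) {
  int m = ring.nrow();
  if (m < 3) return 1.0;
  std::vector<Vec3> v = mat_to_vec(ring);
  const double eps_par = 1e-10, eps_t = 1e-7, eps_z = 1e-9;
  std::vector<Underpass> ups;
  for (int i = 0; i < m; ++i) {
    int i2 = (i + 1) % m;
    double pix = v[i][0], piy = v[i][1];
    double rix = v[i2][0] - pix, riy = v[i2][1] - piy;
    for (int j = i + 1; j < m; ++j) {
      // skip adjacent segments
      if (j == i + 1 || (i == 0 && j == m - 1)) continue;
      int j2 = (j + 1) % m;
      double pjx = v[j][0], pjy = v[j][1];
      double sjx = v[j2][0] - pjx, sjy = v[j2][1] - pjy;
      double denom = rix * sjy - riy * sjx;
      double qpx = pjx - pix, qpy = pjy - piy;
      if (std::fabs(denom) < eps_par) {
        // parallel in projection: crossing impossible unless collinear
        // overlap, which is degenerate
        double crossq = qpx * riy - qpy * rix;
        if (std::fabs(crossq) < eps_par) return NA_REAL;
        continue;
      }
      double t = (qpx * sjy - qpy * sjx) / denom;
      double u = (qpx * riy - qpy * rix) / denom;
      if (t <= -eps_t || t >= 1 + eps_t || u <= -eps_t || u >= 1 + eps_t)
        continue;
      if (t < eps_t || t > 1 - eps_t || u < eps_t || u > 1 - eps_t)
        return NA_REAL; // crossing at/near a vertex: degenerate projection
      double zi = v[i][2] + t * (v[i2][2] - v[i][2]);
      double zj = v[j][2] + u * (v[j2][2] - v[j][2]);
      if (std::fabs(zi - zj) < eps_z) return NA_REAL;
      Underpass up;
      if (zi < zj) { up.pos_under = i + t; up.pos_over = j + u; }
      else         { up.pos_under = j + u; up.pos_over = i + t; }
      ups.push_back(up);
    }
  }
  int n = ups.size();
  if (n <= 1) return 1.0;
  std::sort(ups.begin(), ups.end(),
            [](const Underpass &a, const Underpass &b) {
              return a.pos_under < b.pos_under;
            });
  std::vector<double> upos(n);
  for (int k = 0; k < n; ++k) upos[k] = ups[k].pos_under;
  // arc containing chain position p: arc k+1 follows underpass k (1-based);
  // positions before the first underpass (or after the last) lie on arc 1.
  auto arc_of = [&](double p) {
    int k = std::upper_bound(upos.begin(), upos.end(), p) - upos.begin();
    return (k % n) + 1; // k underpasses are <= p -> arc k+1, cyclic
  };
  // Alexander matrix at t = -1: row k (1-based) for underpass k with
  // over-arc i_k:  i_k in {k, k+1}:  A[k,k] -= 1, A[k,k+1] += 1;
  // otherwise A[k,k] += 1, A[k,k+1] += 1, A[k,i_k] -= 2.
  std::vector<std::vector<long long>> A(n, std::vector<long long>(n, 0));
  for (int k = 1; k <= n; ++k) {
    int ik = arc_of(ups[k - 1].pos_over);
    int kp1 = (k % n) + 1;
    if (ik == k || ik == kp1) {
      A[k - 1][k - 1] += -1;
      A[k - 1][kp1 - 1] += 1;
    } else {
      A[k - 1][k - 1] += 1;
      A[k - 1][kp1 - 1] += 1;
      A[k - 1][ik - 1] += -2;
    }
  }
  // first minor: delete last row and column
  std::vector<std::vector<long long>> Mi(n - 1, std::vector<long long>(n - 1));
  for (int i = 0; i < n - 1; ++i)
    for (int j = 0; j < n - 1; ++j) Mi[i][j] = A[i][j];
  double d = int_det(Mi);
  if (d < 0) return NA_REAL; // overflow: extraordinarily unlikely
  return d;
}
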