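// 3-D computational geometry for morphospace disparity:
//  - incremental convex hull (volume only)
//  - Bowyer-Watson Delaunay tetrahedralization (for alpha-shape volumes)
// Coordinates are morphospace scores; alpha is in score units.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm2(const Vec3 &a) { return dot(a, a); }

// signed volume of tetrahedron (a,b,c,d) * 6
static inline double orient6(const Vec3 &a, const Vec3 &b, const Vec3 &c, const Vec3 &d) {
  return dot(cross(sub(b, a), sub(c, a)), sub(d, a));
}

static std::vector<Vec3> as_points(const NumericMatrix &pts) {
  std::vector<Vec3> p(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    p[i].x = pts(i, 0);
    p[i].y = pts(i, 1);
    p[i].z = pts(i, 2);
  }
  return p;
}

static double extent(const std::vector<Vec3> &p) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (size_t i = 0; i < p.size(); ++i) {
    const double c[3] = {p[i].x, p[i].y, p[i].z};
    for (int k = 0; k < 3; ++k) {
      if (c[k] < lo[k]) lo[k] = c[k];
      if (c[k] > hi[k]) hi[k] = c[k];
    }
  }
  double e = 0;
  for (int k = 0; k < 3; ++k) e = std::max(e, hi[k] - lo[k]);
  return e;
}

// ---------------------------------------------------------------------------
// Convex hull volume, incremental algorithm with horizon repair.
// Returns -1 for degenerate (affinely dependent) input.
// ---------------------------------------------------------------------------

struct Face {
  int a, b, c;    // vertex indices, outward orientation
  bool alive;
};

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return -1.0;
  std::vector<Vec3> p = as_points(pts);
  const double scale = extent(p);
  if (scale <= 0) return -1.0;
  const double eps = 1e-12 * scale * scale * scale; // on 6*volume terms

  // initial simplex: spread-maximizing vertices
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n; ++i)
    if (p[i].x < p[i0].x || (p[i].x == p[i0].x && p[i].y < p[i0].y)) i0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = norm2(sub(p[i], p[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 0) return -1.0;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = norm2(cross(sub(p[i], p[i0]), sub(p[i1], p[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= 1e-24 * scale * scale * scale * scale) return -1.0;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(orient6(p[i0], p[i1], p[i2], p[i]));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) return -1.0; // coplanar point set

  // interior reference point
  Vec3 interior = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
                   (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
                   (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};

  std::vector<Face> faces;
  int init[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc = {init[f][0], init[f][1], init[f][2], true};
    // orient outward: interior must be on the negative side
    if (orient6(p[fc.a], p[fc.b], p[fc.c], interior) > 0) std::swap(fc.b, fc.c);
    faces.push_back(fc);
  }

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient6(p[faces[f].a], p[faces[f].b], p[faces[f].c], p[i]) > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue; // inside (or on) current hull
    // horizon = directed edges of visible faces whose undirected form occurs once
    std::map<std::pair<int, int>, std::pair<int, int> > edges; // sorted -> directed + count
    for (size_t k = 0; k < visible.size(); ++k) {
      const Face &fc = faces[visible[k]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int j = 0; j < 3; ++j) {
        std::pair<int, int> key(std::min(e[j][0], e[j][1]), std::max(e[j][0], e[j][1]));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = edges.find(key);
        if (it == edges.end())
          edges[key] = std::make_pair(e[j][0] * n + e[j][1], 1);
        else
          it->second.second += 1;
      }
      faces[visible[k]].alive = false;
    }
    for (std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (it->second.second != 1) continue;
      int a = it->second.first / n, b = it->second.first % n;
      Face fc = {a, b, i, true};
      if (orient6(p[fc.a], p[fc.b], p[fc.c], interior) > 0) std::swap(fc.b, fc.c);
      faces.push_back(fc);
    }
  }

  // outward faces put the interior on their negative side, so each term of
  // the fan decomposition comes out negative; the hull volume is -sum/6
  double vol6 = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    vol6 += orient6(p[faces[f].a], p[faces[f].b], p[faces[f].c], interior);
  }
  return -vol6 / 6.0;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay tetrahedralization.
// A deterministic relative jitter (~1e-9 of the extent) breaks cosphericity
// ties; it perturbs volumes far below reporting precision.
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];
  double cc[3]; // circumcenter
  double r2;    // squared circumradius
  bool alive;
};

// in-sphere predicate: > 0 when e lies inside the circumsphere of (a,b,c,d),
// with (a,b,c,d) positively oriented. 4x4 determinant of lifted differences.
static double insphere(const Vec3 &a, const Vec3 &b, const Vec3 &c, const Vec3 &d,
                       const Vec3 &e) {
  double m[4][4];
  const Vec3 *q[4] = {&a, &b, &c, &d};
  for (int i = 0; i < 4; ++i) {
    m[i][0] = q[i]->x - e.x;
    m[i][1] = q[i]->y - e.y;
    m[i][2] = q[i]->z - e.z;
    m[i][3] = m[i][0] * m[i][0] + m[i][1] * m[i][1] + m[i][2] * m[i][2];
  }
  double det = 0;
  for (int j = 0; j < 4; ++j) {
    // minor over rows 1..3 excluding column j
    int cols[3], cidx = 0;
    for (int k = 0; k < 4; ++k)
      if (k != j) cols[cidx++] = k;
    double minor =
        m[1][cols[0]] * (m[2][cols[1]] * m[3][cols[2]] - m[2][cols[2]] * m[3][cols[1]]) -
        m[1][cols[1]] * (m[2][cols[0]] * m[3][cols[2]] - m[2][cols[2]] * m[3][cols[0]]) +
        m[1][cols[2]] * (m[2][cols[0]] * m[3][cols[1]] - m[2][cols[1]] * m[3][cols[0]]);
    det += ((j % 2 == 0) ? 1.0 : -1.0) * m[0][j] * minor;
  }
  // with orient6(a,b,c,d) > 0 the raw determinant is negative for interior e
  return -det;
}

static bool circumsphere(const std::vector<Vec3> &p, Tet &t) {
  const Vec3 &a = p[t.v[0]], &b = p[t.v[1]], &c = p[t.v[2]], &d = p[t.v[3]];
  double M[3][3] = {{b.x - a.x, b.y - a.y, b.z - a.z},
                    {c.x - a.x, c.y - a.y, c.z - a.z},
                    {d.x - a.x, d.y - a.y, d.z - a.z}};
  double rhs[3] = {(norm2(b) - norm2(a)) / 2.0, (norm2(c) - norm2(a)) / 2.0,
                   (norm2(d) - norm2(a)) / 2.0};
  // Cramer's rule
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double x[3];
  for (int k = 0; k < 3; ++k) {
    double Mk[3][3];
    for (int r = 0; r < 3; ++r)
      for (int s = 0; s < 3; ++s) Mk[r][s] = (s == k) ? rhs[r] : M[r][s];
    double dk = Mk[0][0] * (Mk[1][1] * Mk[2][2] - Mk[1][2] * Mk[2][1]) -
                Mk[0][1] * (Mk[1][0] * Mk[2][2] - Mk[1][2] * Mk[2][0]) +
                Mk[0][2] * (Mk[1][0] * Mk[2][1] - Mk[1][1] * Mk[2][0]);
    x[k] = dk / det;
  }
  t.cc[0] = x[0];
  t.cc[1] = x[1];
  t.cc[2] = x[2];
  Vec3 ccv = {x[0], x[1], x[2]};
  t.r2 = norm2(sub(ccv, a));
  return true;
}

// [[Rcpp::export(name = ".delaunay_cpp")]]
List delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<Vec3> p = as_points(pts);
  const double scale = extent(p);
  if (scale <= 0) stop("degenerate point set");

  // deterministic jitter (LCG), independent of R's RNG
  unsigned long long s = 88172645463325252ULL;
  for (int i = 0; i < n; ++i) {
    double *c[3] = {&p[i].x, &p[i].y, &p[i].z};
    for (int k = 0; k < 3; ++k) {
      s = s * 6364136223846793005ULL + 1442695040888963407ULL;
      double u = (double)(s >> 11) / 9007199254740992.0; // [0,1)
      *c[k] += scale * 1e-7 * (u - 0.5);
    }
  }

  // super-tetrahedron (alternate corners of a big cube around the data)
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += p[i].x; cy += p[i].y; cz += p[i].z; }
  cx /= n; cy /= n; cz /= n;
  double R = 0;
  Vec3 ctr = {cx, cy, cz};
  for (int i = 0; i < n; ++i) R = std::max(R, std::sqrt(norm2(sub(p[i], ctr))));
  double K = 50.0 * (R > 0 ? R : 1.0);
  Vec3 s0 = {cx + K, cy + K, cz + K};
  Vec3 s1 = {cx + K, cy - K, cz - K};
  Vec3 s2 = {cx - K, cy + K, cz - K};
  Vec3 s3 = {cx - K, cy - K, cz + K};
  p.push_back(s0); p.push_back(s1); p.push_back(s2); p.push_back(s3);

  std::vector<Tet> tets;
  Tet t0;
  t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
  if (orient6(p[t0.v[0]], p[t0.v[1]], p[t0.v[2]], p[t0.v[3]]) < 0)
    std::swap(t0.v[2], t0.v[3]);
  t0.alive = true;
  if (!circumsphere(p, t0)) stop("super-tetrahedron degenerate");
  tets.push_back(t0);

  for (int i = 0; i < n; ++i) {
    std::vector<int> bad;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      const Tet &tt = tets[t];
      if (insphere(p[tt.v[0]], p[tt.v[1]], p[tt.v[2]], p[tt.v[3]], p[i]) > 0)
        bad.push_back((int)t);
    }
    if (bad.empty()) stop("Delaunay insertion failed (no containing circumsphere)");
    // cavity boundary: faces of bad tets occurring exactly once
    std::map<std::array<int, 3>, std::pair<std::array<int, 3>, int> > fmap;
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tet &t = tets[bad[k]];
      int fv[4][3] = {{t.v[0], t.v[1], t.v[2]}, {t.v[0], t.v[1], t.v[3]},
                      {t.v[0], t.v[2], t.v[3]}, {t.v[1], t.v[2], t.v[3]}};
      for (int f = 0; f < 4; ++f) {
        std::array<int, 3> key = {{fv[f][0], fv[f][1], fv[f][2]}};
        std::sort(key.begin(), key.end());
        std::array<int, 3> dir = {{fv[f][0], fv[f][1], fv[f][2]}};
        std::map<std::array<int, 3>, std::pair<std::array<int, 3>, int> >::iterator it =
            fmap.find(key);
        if (it == fmap.end())
          fmap[key] = std::make_pair(dir, 1);
        else
          it->second.second += 1;
      }
      tets[bad[k]].alive = false;
    }
    for (std::map<std::array<int, 3>, std::pair<std::array<int, 3>, int> >::iterator it =
             fmap.begin();
         it != fmap.end(); ++it) {
      if (it->second.second != 1) continue;
      Tet nt;
      nt.v[0] = it->first[0];
      nt.v[1] = it->first[1];
      nt.v[2] = it->first[2];
      nt.v[3] = i;
      if (orient6(p[nt.v[0]], p[nt.v[1]], p[nt.v[2]], p[nt.v[3]]) < 0)
        std::swap(nt.v[1], nt.v[2]);
      nt.alive = true;
      if (!circumsphere(p, nt)) continue; // flat sliver against cavity wall
      tets.push_back(nt);
    }
    // periodic compaction
    if (tets.size() > 4000) {
      std::vector<Tet> keep;
      keep.reserve(tets.size());
      for (size_t t = 0; t < tets.size(); ++t)
        if (tets[t].alive) keep.push_back(tets[t]);
      tets.swap(keep);
    }
  }

  std::vector<int> out;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k)
      if (tets[t].v[k] >= n) super = true;
    if (!super) out.push_back((int)t);
  }

  IntegerMatrix tet_idx(out.size(), 4);
  NumericVector vol(out.size()), crad(out.size());
  for (size_t k = 0; k < out.size(); ++k) {
    const Tet &t = tets[out[k]];
    for (int j = 0; j < 4; ++j) tet_idx(k, j) = t.v[j] + 1; // 1-based for R
    vol[k] = std::fabs(orient6(p[t.v[0]], p[t.v[1]], p[t.v[2]], p[t.v[3]])) / 6.0;
    crad[k] = std::sqrt(t.r2);
  }
  return List::create(_["tetrahedra"] = tet_idx, _["volume"] = vol,
                      _["circumradius"] = crad);
}
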