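// Core geometry and force kernels for the active vertex model.
//
// All triangles are stored with counter-clockwise (CCW) orientation, 1-based
// site indices at the R interface, 0-based internally.  The dual Voronoi cell
// of an interior site is read off as the CCW-ordered circumcenters of its
// incident triangles; the walk requires every interior site to be completely
// surrounded by triangles (guaranteed when a closed ring of boundary ghosts
// encloses all interior sites).

#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

typedef std::array<int, 3> Tri;

static inline long long ekey(int a, int b, long long n) {
  if (a > b) std::swap(a, b);
  return (long long)a * n + b;
}

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// incircle determinant: for CCW triangle (a,b,c), positive iff d strictly inside
// the circumcircle.  Computed relative to d for accuracy.
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx)
       + ad * (bdx * cdy - bdy * cdx);
}

// circumcenter of (p1,p2,p3), solved relative to p1.  Returns false when the
// triangle is (near) degenerate.
static inline bool circumcenter3(double x1, double y1, double x2, double y2,
                                 double x3, double y3, double* cx, double* cy,
                                 double* det_out) {
  double ux = x2 - x1, uy = y2 - y1;
  double wx = x3 - x1, wy = y3 - y1;
  double det = 2.0 * (ux * wy - uy * wx);
  if (det_out) *det_out = det;
  double u2 = ux * ux + uy * uy, w2 = wx * wx + wy * wy;
  double scale = std::max(u2, w2);
  if (std::fabs(det) < 1e-14 * scale) return false;
  double yx = (wy * u2 - uy * w2) / det;
  double yy = (ux * w2 - wx * u2) / det;
  *cx = x1 + yx;
  *cy = y1 + yy;
  return true;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 sites to triangulate");

  // bounding box and duplicate check
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(pts(i, 0)) || !R_finite(pts(i, 1)))
      stop("non-finite site coordinates");
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("all sites coincide");
  {
    // O(n log n) duplicate detection via sorting
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (pts(a, 0) != pts(b, 0)) return pts(a, 0) < pts(b, 0);
      return pts(a, 1) < pts(b, 1);
    });
    for (int i = 1; i < n; ++i) {
      int a = ord[i - 1], b = ord[i];
      double dx = pts(a, 0) - pts(b, 0), dy = pts(a, 1) - pts(b, 1);
      if (dx * dx + dy * dy < 1e-24 * span * span)
        stop("duplicate points at sites %d and %d", a + 1, b + 1);
    }
  }

  // super-triangle, vertices n, n+1, n+2
  double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  double R = 64.0 * span;
  // deterministic symbolic-perturbation jitter: exactly cocircular inputs
  // (regular ghost rings, lattices) make the strict incircle cavity test
  // inconsistent; a tiny tie-breaking offset keeps the cavity star-shaped.
  // The caller restores exact Delaunayhood by equiangulating with the true
  // coordinates (ties are legal either way).
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    unsigned long long u = 1103515245ULL * (i + 1) + 12345ULL;
    u = (1103515245ULL * u + 12345ULL) % 2147483648ULL;
    double j1 = (double)(u % 65536) / 65536.0 - 0.5;
    double j2 = (double)((u / 65536) % 65536) / 65536.0 - 0.5;
    px[i] = pts(i, 0) + 1e-8 * span * j1;
    py[i] = pts(i, 1) + 1e-8 * span * j2;
  }
  for (int k = 0; k < 3; ++k) {
    double ang = M_PI / 2.0 + 2.0 * M_PI * k / 3.0;
    px[n + k] = cx + R * std::cos(ang);
    py[n + k] = cy + R * std::sin(ang);
  }

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2});
  if (orient2d(px[n], py[n], px[n + 1], py[n + 1], px[n + 2], py[n + 2]) < 0)
    tris[0] = {n, n + 2, n + 1};

  std::vector<char> bad;
  std::vector<std::pair<int, int>> cavity;
  for (int ip = 0; ip < n; ++ip) {
    double qx = px[ip], qy = py[ip];
    bad.assign(tris.size(), 0);
    bool found = false;
    for (size_t t = 0; t < tris.size(); ++t) {
      const Tri& T = tris[t];
      if (incircle(px[T[0]], py[T[0]], px[T[1]], py[T[1]],
                   px[T[2]], py[T[2]], qx, qy) > 0) {
        bad[t] = 1; found = true;
      }
    }
    if (!found) stop("triangulation insertion failed (degenerate input?)");
    // boundary of the cavity: directed edges of bad triangles whose undirected
    // twin appears only once
    cavity.clear();
    std::unordered_map<long long, int> ecount;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!bad[t]) continue;
      const Tri& T = tris[t];
      for (int e = 0; e < 3; ++e) {
        int a = T[e], b = T[(e + 1) % 3];
        ecount[ekey(a, b, n + 3)]++;
      }
    }
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!bad[t]) continue;
      const Tri& T = tris[t];
      for (int e = 0; e < 3; ++e) {
        int a = T[e], b = T[(e + 1) % 3];
        if (ecount[ekey(a, b, n + 3)] == 1) cavity.push_back({a, b});
      }
    }
    // remove bad triangles (compact in place)
    size_t w = 0;
    for (size_t t = 0; t < tris.size(); ++t)
      if (!bad[t]) tris[w++] = tris[t];
    tris.resize(w);
    // re-triangulate cavity, preserving CCW orientation
    for (auto& e : cavity) {
      double o = orient2d(qx, qy, px[e.first], py[e.first], px[e.second], py[e.second]);
      if (o > 0) tris.push_back({ip, e.first, e.second});
      else tris.push_back({ip, e.second, e.first});
    }
  }

  // drop triangles using super vertices
  std::vector<Tri> out;
  for (auto& T : tris)
    if (T[0] < n && T[1] < n && T[2] < n) out.push_back(T);
  if (out.empty())
    stop("degenerate input: sites are collinear, no triangulation exists");

  IntegerMatrix res(out.size(), 3);
  for (size_t t = 0; t < out.size(); ++t)
    for (int k = 0; k < 3; ++k) res(t, k) = out[t][k] + 1;
  return res;
}

// ---------------------------------------------------------------------------
// Lawson equiangulation (restore the Delaunay property by edge flips)
// ---------------------------------------------------------------------------

struct EdgeRec { int t1, t2; };

// [[Rcpp::export]]
List cpp_equiangulate(NumericMatrix pts, IntegerMatrix tri, double tol = 1e-12,
                      int max_flips = -1) {
  int n = pts.nrow();
  int nt = tri.nrow();
  if (max_flips < 0) max_flips = 100 * nt + 1000;
  std::vector<Tri> tris(nt);
  for (int t = 0; t < nt; ++t)
    tris[t] = {tri(t, 0) - 1, tri(t, 1) - 1, tri(t, 2) - 1};

  // length^4 scale for the incircle determinant tolerance
  double span = 0;
  for (int i = 1; i < n; ++i) {
    span = std::max(span, std::fabs(pts(i, 0) - pts(0, 0)));
    span = std::max(span, std::fabs(pts(i, 1) - pts(0, 1)));
  }
  if (span <= 0) span = 1.0;
  double eps = tol * span * span * span * span;

  std::unordered_map<long long, EdgeRec> emap;
  emap.reserve(3 * nt);
  for (int t = 0; t < nt; ++t) {
    for (int e = 0; e < 3; ++e) {
      int a = tris[t][e], b = tris[t][(e + 1) % 3];
      long long k = ekey(a, b, n);
      auto it = emap.find(k);
      if (it == emap.end()) emap[k] = {t, -1};
      else if (it->second.t2 == -1) it->second.t2 = t;
      else stop("corrupted mesh: edge %d-%d borders more than two triangles",
                a + 1, b + 1);
    }
  }

  std::deque<long long> queue;
  for (auto& kv : emap)
    if (kv.second.t2 >= 0) queue.push_back(kv.first);

  auto third = [](const Tri& T, int a, int b) {
    for (int k = 0; k < 3; ++k)
      if (T[k] != a && T[k] != b) return T[k];
    return -1;
  };

  int nflips = 0;
  std::vector<std::array<int, 4>> fliprec;
  std::vector<long long> blocked;  // unflippable edges, retried after a flip
  while (!queue.empty()) {
    long long k = queue.front();
    queue.pop_front();
    auto it = emap.find(k);
    if (it == emap.end() || it->second.t2 < 0) continue;  // stale entry
    int a = (int)(k / n), b = (int)(k % n);
    int t1 = it->second.t1, t2 = it->second.t2;
    int c = third(tris[t1], a, b);
    int d = third(tris[t2], a, b);
    if (c < 0 || d < 0) continue;
    // orient (a,b,c) CCW for the predicate
    double aa[2] = {pts(a, 0), pts(a, 1)};
    double bb[2] = {pts(b, 0), pts(b, 1)};
    double cc[2] = {pts(c, 0), pts(c, 1)};
    double dd[2] = {pts(d, 0), pts(d, 1)};
    double o = orient2d(aa[0], aa[1], bb[0], bb[1], cc[0], cc[1]);
    double inc = (o >= 0)
      ? incircle(aa[0], aa[1], bb[0], bb[1], cc[0], cc[1], dd[0], dd[1])
      : incircle(bb[0], bb[1], aa[0], aa[1], cc[0], cc[1], dd[0], dd[1]);
    if (inc <= eps) continue;  // Delaunay (or cocircular tie): do not flip
    // relabel so that t1 = (a,b,c) and t2 = (b,a,d) are both CCW
    if (o < 0) { std::swap(a, b); }
    // candidate new triangles (a,d,c) and (d,b,c); skip flip if either would
    // be inverted (non-convex quadrilateral)
    double o1 = orient2d(pts(a, 0), pts(a, 1), pts(d, 0), pts(d, 1), pts(c, 0), pts(c, 1));
    double o2 = orient2d(pts(d, 0), pts(d, 1), pts(b, 0), pts(b, 1), pts(c, 0), pts(c, 1));
    if (o1 <= 0 || o2 <= 0 || emap.count(ekey(c, d, n))) {
      // flip would invert a triangle or duplicate an existing edge (possible
      // transiently when sites moved far); retry once surroundings change
      blocked.push_back(k);
      if (queue.empty() && !blocked.empty()) break;
      continue;
    }
    tris[t1] = {a, d, c};
    tris[t2] = {d, b, c};
    emap.erase(it);
    emap[ekey(c, d, n)] = {t1, t2};
    // edge (b,c): t1 -> t2 ; edge (a,d): t2 -> t1
    auto fix = [&](int u, int v, int from, int to) {
      auto jt = emap.find(ekey(u, v, n));
      if (jt == emap.end()) stop("corrupted mesh during flip");
      if (jt->second.t1 == from) jt->second.t1 = to;
      else if (jt->second.t2 == from) jt->second.t2 = to;
    };
    fix(b, c, t1, t2);
    fix(a, d, t2, t1);
    for (auto uv : { std::make_pair(a, c), std::make_pair(c, b),
                     std::make_pair(b, d), std::make_pair(d, a) }) {
      auto jt = emap.find(ekey(uv.first, uv.second, n));
      if (jt != emap.end() && jt->second.t2 >= 0)
        queue.push_back(ekey(uv.first, uv.second, n));
    }
    fliprec.push_back({a + 1, b + 1, c + 1, d + 1});
    for (long long bk : blocked) queue.push_back(bk);
    blocked.clear();
    if (++nflips > max_flips)
      stop("equiangulation did not converge after %d flips (corrupted mesh?)",
           nflips);
  }

  IntegerMatrix newtri(tris.size(), 3);
  for (size_t t = 0; t < tris.size(); ++t)
    for (int q = 0; q < 3; ++q) newtri(t, q) = tris[t][q] + 1;
  IntegerMatrix flips(fliprec.size(), 4);
  for (size_t f = 0; f < fliprec.size(); ++f)
    for (int q = 0; q < 4; ++q) flips(f, q) = fliprec[f][q];
  colnames(flips) = CharacterVector::create("old1", "old2", "new1", "new2");
  return List::create(_["triangles"] = newtri, _["n_flips"] = nflips,
                      _["flipped"] = flips);
}

// ---------------------------------------------------------------------------
// Dual-cell geometry: ordered Voronoi polygons of all interior sites
// ---------------------------------------------------------------------------

struct CellGeom {
  std::vector<double> circx, circy;        // per-triangle circumcenter
  std::vector<int> cell_ptr;               // offsets into cell_tri / cell_nbr
  std::vector<int> cell_tri;               // CCW fan of incident triangles
  std::vector<int> cell_nbr;               // neighbour site dual to edge mu->mu+1
  std::vector<int> cell_site;              // owning site of each cell
  std::vector<double> area, perim;
};

static void build_cells(const NumericMatrix& pts, const IntegerMatrix& tri,
                        const LogicalVector& interior, CellGeom& G) {
  int n = pts.nrow(), nt = tri.nrow();
  G.circx.resize(nt); G.circy.resize(nt);
  for (int t = 0; t < nt; ++t) {
    int i = tri(t, 0) - 1, j = tri(t, 1) - 1, k = tri(t, 2) - 1;
    double det;
    if (!circumcenter3(pts(i, 0), pts(i, 1), pts(j, 0), pts(j, 1),
                       pts(k, 0), pts(k, 1), &G.circx[t], &G.circy[t], &det))
      stop("degenerate (near-collinear) triangle over sites %d, %d, %d",
           i + 1, j + 1, k + 1);
  }
  // directed edge (u -> v) -> triangle containing it in its CCW cycle
  std::unordered_map<long long, int> dmap;
  dmap.reserve(3 * nt);
  std::vector<int> anytri(n, -1);
  for (int t = 0; t < nt; ++t) {
    for (int e = 0; e < 3; ++e) {
      int u = tri(t, e) - 1, v = tri(t, (e + 1) % 3) - 1;
      dmap[(long long)u * n + v] = t;
      anytri[u] = t;
    }
  }
  G.cell_ptr.clear(); G.cell_tri.clear(); G.cell_nbr.clear(); G.cell_site.clear();
  G.area.clear(); G.perim.clear();
  G.cell_ptr.push_back(0);
  for (int i = 0; i < n; ++i) {
    if (!interior[i]) continue;
    int t0 = anytri[i];
    if (t0 < 0)
      stop("interior site %d is not part of any triangle", i + 1);
    int t = t0;
    int count = 0;
    int start = (int)G.cell_tri.size();
    do {
      // locate i within t; CCW-next triangle shares directed edge (i -> k)
      int ii = -1;
      for (int e = 0; e < 3; ++e) if (tri(t, e) - 1 == i) { ii = e; break; }
      int kv = tri(t, (ii + 2) % 3) - 1;  // vertex "k" of (i,j,k)
      G.cell_tri.push_back(t);
      G.cell_nbr.push_back(kv);
      auto it = dmap.find((long long)i * n + kv);
      if (it == dmap.end())
        stop("interior site %d is on the convex hull; its Voronoi cell is unbounded (add boundary ghosts)",
             i + 1);
      t = it->second;
      if (++count > nt)
        stop("corrupted triangle fan around site %d", i + 1);
    } while (t != t0);
    // shoelace area and perimeter over the CCW circumcenter polygon
    int m = (int)G.cell_tri.size() - start;
    double A = 0, P = 0;
    for (int q = 0; q < m; ++q) {
      int ta = G.cell_tri[start + q];
      int tb = G.cell_tri[start + (q + 1) % m];
      double xa = G.circx[ta], ya = G.circy[ta];
      double xb = G.circx[tb], yb = G.circy[tb];
      A += xa * yb - xb * ya;
      P += std::sqrt((xb - xa) * (xb - xa) + (yb - ya) * (yb - ya));
    }
    G.cell_site.push_back(i);
    G.area.push_back(0.5 * A);
    G.perim.push_back(P);
    G.cell_ptr.push_back((int)G.cell_tri.size());
  }
}

// [[Rcpp::export]]
List cpp_cell_geometry(NumericMatrix pts, IntegerMatrix tri,
                       LogicalVector interior) {
  CellGeom G;
  build_cells(pts, tri, interior, G);
  int nc = (int)G.cell_site.size();
  NumericMatrix circ(tri.nrow(), 2);
  for (int t = 0; t < tri.nrow(); ++t) {
    circ(t, 0) = G.circx[t]; circ(t, 1) = G.circy[t];
  }
  IntegerVector site(nc), ptr(nc + 1);
  NumericVector area(nc), perim(nc);
  for (int c = 0; c < nc; ++c) {
    site[c] = G.cell_site[c] + 1;
    area[c] = G.area[c];
    perim[c] = G.perim[c];
  }
  for (int c = 0; c <= nc; ++c) ptr[c] = G.cell_ptr[c];
  IntegerVector ctri(G.cell_tri.size()), cnbr(G.cell_nbr.size());
  for (size_t q = 0; q < G.cell_tri.size(); ++q) {
    ctri[q] = G.cell_tri[q] + 1;
    cnbr[q] = G.cell_nbr[q] + 1;
  }
  return List::create(_["circumcenters"] = circ, _["site"] = site,
                      _["ptr"] = ptr, _["fan_tri"] = ctri,
                      _["fan_nbr"] = cnbr, _["area"] = area,
                      _["perimeter"] = perim);
}

// ---------------------------------------------------------------------------
// Vertex-model energy and forces on all sites
// ---------------------------------------------------------------------------

// Kvec, Gvec, A0vec: per-site (values used for interior sites only).
// type_idx: 1-based row/column into lambda for every site (boundary sites
// point at the boundary type M).  Junction energy is accumulated per cell
// (each cell pays lambda * l for each of its own Voronoi edges), the form
// consistent with the per-cell force sums and with P0 = -Lambda/Gamma.

// [[Rcpp::export]]
List cpp_vm_forces(NumericMatrix pts, IntegerMatrix tri, LogicalVector interior,
                   NumericVector Kvec, NumericVector Gvec, NumericVector A0vec,
                   NumericMatrix lambda, IntegerVector type_idx,
                   double k_core, double a_core, bool want_forces = true) {
  int n = pts.nrow(), nt = tri.nrow();
  CellGeom G;
  build_cells(pts, tri, interior, G);
  int nc = (int)G.cell_site.size();

  double E_area = 0, E_perim = 0, E_junc = 0, E_core = 0;
  std::vector<double> gx(nt, 0.0), gy(nt, 0.0);  // dE/d(circumcenter)

  for (int c = 0; c < nc; ++c) {
    int i = G.cell_site[c];
    int s = G.cell_ptr[c], m = G.cell_ptr[c + 1] - s;
    double A = G.area[c], P = G.perim[c];
    double K = Kvec[i], Ga = Gvec[i], A0 = A0vec[i];
    E_area += 0.5 * K * (A - A0) * (A - A0);
    E_perim += 0.5 * Ga * P * P;
    double ka = K * (A - A0);
    double gp = Ga * P;
    int ti = type_idx[i] - 1;
    for (int q = 0; q < m; ++q) {
      int tprev = G.cell_tri[s + (q + m - 1) % m];
      int tcur  = G.cell_tri[s + q];
      int tnext = G.cell_tri[s + (q + 1) % m];
      double xc = G.circx[tcur], yc = G.circy[tcur];
      double xp = G.circx[tprev], yp = G.circy[tprev];
      double xn = G.circx[tnext], yn = G.circy[tnext];
      // area term: dA/dr_mu = 0.5 * (y_{mu+1} - y_{mu-1}, x_{mu-1} - x_{mu+1})
      gx[tcur] += ka * 0.5 * (yn - yp);
      gy[tcur] += ka * 0.5 * (xp - xn);
      // perimeter + junction tensions on edges (prev,cur) and (cur,next)
      double lxp = xc - xp, lyp = yc - yp;
      double lp = std::sqrt(lxp * lxp + lyp * lyp);
      double lxn = xc - xn, lyn = yc - yn;
      double ln = std::sqrt(lxn * lxn + lyn * lyn);
      int nb_prev = G.cell_nbr[s + (q + m - 1) % m];  // edge prev->cur dual
      int nb_next = G.cell_nbr[s + q];                // edge cur->next dual
      double lam_p = lambda(ti, type_idx[nb_prev] - 1);
      double lam_n = lambda(ti, type_idx[nb_next] - 1);
      if (lp > 1e-14) {
        gx[tcur] += (gp + lam_p) * lxp / lp;
        gy[tcur] += (gp + lam_p) * lyp / lp;
      }
      if (ln > 1e-14) {
        gx[tcur] += (gp + lam_n) * lxn / ln;
        gy[tcur] += (gp + lam_n) * lyn / ln;
      }
      // junction energy: count each of the cell's edges once (edge cur->next)
      E_junc += lam_n * ln;
    }
  }

  NumericMatrix F(n, 2);
  bool capped = false;
  if (want_forces) {
    // chain rule through the circumcenter Jacobians:
    //   with M = 2 [(p2-p1)^T ; (p3-p1)^T] and h = M^{-T} g,
    //   J1^T g = 2 (h1+h2) (c-p1),  J2^T g = 2 h1 (p2-c),  J3^T g = 2 h2 (p3-c)
    for (int t = 0; t < nt; ++t) {
      double g1 = gx[t], g2 = gy[t];
      if (g1 == 0 && g2 == 0) continue;
      int i = tri(t, 0) - 1, j = tri(t, 1) - 1, k = tri(t, 2) - 1;
      double ux = pts(j, 0) - pts(i, 0), uy = pts(j, 1) - pts(i, 1);
      double wx = pts(k, 0) - pts(i, 0), wy = pts(k, 1) - pts(i, 1);
      double det = 4.0 * (ux * wy - uy * wx);
      // M = [[2ux, 2uy], [2wx, 2wy]], M^{-T} = adj(M)^T / det(M)
      double h1 = (2.0 * wy * g1 - 2.0 * wx * g2) / det;
      double h2 = (-2.0 * uy * g1 + 2.0 * ux * g2) / det;
      double cx = G.circx[t], cy = G.circy[t];
      F(i, 0) -= 2.0 * (h1 + h2) * (cx - pts(i, 0));
      F(i, 1) -= 2.0 * (h1 + h2) * (cy - pts(i, 1));
      F(j, 0) -= 2.0 * h1 * (pts(j, 0) - cx);
      F(j, 1) -= 2.0 * h1 * (pts(j, 1) - cy);
      F(k, 0) -= 2.0 * h2 * (pts(k, 0) - cx);
      F(k, 1) -= 2.0 * h2 * (pts(k, 1) - cy);
    }
  }

  // soft-core repulsion over unique Delaunay edges
  if (k_core > 0) {
    std::unordered_map<long long, char> seen;
    seen.reserve(3 * nt);
    for (int t = 0; t < nt; ++t) {
      for (int e = 0; e < 3; ++e) {
        int u = tri(t, e) - 1, v = tri(t, (e + 1) % 3) - 1;
        long long k2 = ekey(u, v, n);
        if (seen.count(k2)) continue;
        seen[k2] = 1;
        double dx = pts(u, 0) - pts(v, 0), dy = pts(u, 1) - pts(v, 1);
        double r = std::sqrt(dx * dx + dy * dy);
        if (r >= a_core) continue;
        E_core += 0.5 * k_core * (a_core - r) * (a_core - r);
        if (want_forces) {
          double fmag;
          if (r < 1e-9) { fmag = k_core * a_core / 1e-9; capped = true; dx = 1e-9; dy = 0; r = 1e-9; }
          else fmag = k_core * (a_core - r) / r;
          F(u, 0) += fmag * dx; F(u, 1) += fmag * dy;
          F(v, 0) -= fmag * dx; F(v, 1) -= fmag * dy;
        }
      }
    }
  }

  IntegerVector site(nc);
  NumericVector area(nc), perim(nc);
  for (int c = 0; c < nc; ++c) {
    site[c] = G.cell_site[c] + 1;
    area[c] = G.area[c];
    perim[c] = G.perim[c];
  }
  return List::create(
    _["forces"] = F,
    _["area_term"] = E_area, _["perimeter_term"] = E_perim,
    _["junction_term"] = E_junc, _["soft_core_term"] = E_core,
    _["site"] = site, _["area"] = area, _["perimeter"] = perim,
    _["capped"] = capped);
}
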