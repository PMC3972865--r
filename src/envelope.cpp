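// Scattered-data envelope interpolation backends for the BEMD sifting loop.
//
// cpp_tri_interp: incremental (Bowyer-Watson) Delaunay triangulation of the
// extrema, barycentric linear interpolation on the full pixel grid, and
// nearest-data-point extrapolation outside the convex hull.  Data coordinates
// receive a tiny deterministic jitter before triangulation so that the
// cocircular degeneracies of integer pixel grids cannot break the incircle
// tests; exact data values are re-imposed on the output grid by the R wrapper.
//
// cpp_tps_eval: evaluation of a fitted thin-plate spline (the dense solve is
// done in R; only the O(npixels * npoints) kernel sum lives here).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <stdexcept>

using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex indices, CCW
  int n[3];   // n[i]: neighbour across the edge opposite v[i]; -1 = none
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// strict incircle test for CCW triangle (a,b,c)
inline bool in_circum(double ax, double ay, double bx, double by,
                      double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx) > 0.0;
}

// deterministic jitter in (-5e-4, 5e-4), a function of the point index only
inline double jitter(uint32_t i, uint32_t salt) {
  uint32_t h = i * 2654435761u + salt * 0x9e3779b9u;
  h ^= h >> 16; h *= 0x85ebca6bu; h ^= h >> 13; h *= 0xc2b2ae35u; h ^= h >> 16;
  return (static_cast<double>(h % 100001u) / 100000.0 - 0.5) * 1e-3;
}

class Delaunay {
public:
  std::vector<double> x, y;
  std::vector<Tri> tris;
  int n_data;

  bool has_super(int t) const {
    return tris[t].v[0] >= n_data || tris[t].v[1] >= n_data ||
           tris[t].v[2] >= n_data;
  }

  // walking point location; returns a live triangle containing (qx, qy)
  int locate(double qx, double qy, int hint) const {
    int t = hint;
    if (t < 0 || t >= static_cast<int>(tris.size()) || !tris[t].alive) {
      t = -1;
      for (int i = static_cast<int>(tris.size()) - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
      if (t < 0) return -1;
    }
    int steps = 0;
    const int max_steps = static_cast<int>(tris.size()) + 16;
    while (steps++ < max_steps) {
      int next = -1;
      for (int i = 0; i < 3; ++i) {
        const int a = tris[t].v[(i + 1) % 3];
        const int b = tris[t].v[(i + 2) % 3];
        if (orient2d(x[a], y[a], x[b], y[b], qx, qy) < 0.0) {
          if (tris[t].n[i] >= 0) { next = tris[t].n[i]; break; }
        }
      }
      if (next == -1) return t;
      t = next;
    }
    // degenerate walk (should not happen): exhaustive scan
    for (int i = 0; i < static_cast<int>(tris.size()); ++i) {
      if (!tris[i].alive) continue;
      bool inside = true;
      for (int k = 0; k < 3 && inside; ++k) {
        const int a = tris[i].v[(k + 1) % 3];
        const int b = tris[i].v[(k + 2) % 3];
        if (orient2d(x[a], y[a], x[b], y[b], qx, qy) < -1e-9) inside = false;
      }
      if (inside) return i;
    }
    return -1;
  }

  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<int>& order) {
    n_data = static_cast<int>(px.size());
    x = px; y = py;
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
    for (int i = 1; i < n_data; ++i) {
      if (px[i] < xmin) xmin = px[i];
      if (px[i] > xmax) xmax = px[i];
      if (py[i] < ymin) ymin = py[i];
      if (py[i] > ymax) ymax = py[i];
    }
    const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    const double span = std::max(xmax - xmin, ymax - ymin) + 1.0;
    const double R = 8.0 * span;
    // CCW super-triangle comfortably containing the bounding box
    x.push_back(cx);          y.push_back(cy + 5.0 * R);
    x.push_back(cx - 5.0 * R); y.push_back(cy - 4.0 * R);
    x.push_back(cx + 5.0 * R); y.push_back(cy - 4.0 * R);
    Tri t0;
    t0.v[0] = n_data; t0.v[1] = n_data + 1; t0.v[2] = n_data + 2;
    t0.n[0] = t0.n[1] = t0.n[2] = -1;
    t0.alive = true;
    tris.clear();
    tris.push_back(t0);
    int hint = 0;
    for (int k = 0; k < n_data; ++k) insert(order[k], hint);
  }

private:
  // scratch reused across insertions (generation-stamped membership)
  std::vector<int> mark_;
  int gen_ = 0;

  void insert(int ip, int& hint) {
    const double qx = x[ip], qy = y[ip];
    const int t0 = locate(qx, qy, hint);
    if (t0 < 0) throw std::runtime_error("triangulation: point location failed");
    // cavity: BFS over triangles whose circumcircle contains the new point
    ++gen_;
    if (mark_.size() < tris.size() + 64) mark_.resize(tris.size() * 2 + 64, 0);
    std::vector<int> bad, stack_;
    stack_.push_back(t0); mark_[t0] = gen_;
    while (!stack_.empty()) {
      const int t = stack_.back(); stack_.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 3; ++i) {
        const int nb = tris[t].n[i];
        if (nb < 0 || mark_[nb] == gen_) continue;
        const Tri& T = tris[nb];
        if (in_circum(x[T.v[0]], y[T.v[0]], x[T.v[1]], y[T.v[1]],
                      x[T.v[2]], y[T.v[2]], qx, qy)) {
          mark_[nb] = gen_; stack_.push_back(nb);
        }
      }
    }
    struct Edge { int a, b, outside; };
    std::vector<Edge> bound;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      const int t = bad[bi];
      for (int i = 0; i < 3; ++i) {
        const int nb = tris[t].n[i];
        if (nb >= 0 && mark_[nb] == gen_) continue;
        Edge e;
        e.a = tris[t].v[(i + 1) % 3];
        e.b = tris[t].v[(i + 2) % 3];
        e.outside = nb;
        bound.push_back(e);
      }
    }
    for (size_t bi = 0; bi < bad.size(); ++bi) tris[bad[bi]].alive = false;
    const int first_new = static_cast<int>(tris.size());
    std::vector<int> newtris;
    std::unordered_map<int, int> by_a, by_b;
    for (size_t ei = 0; ei < bound.size(); ++ei) {
      const Edge& e = bound[ei];
      if (orient2d(qx, qy, x[e.a], y[e.a], x[e.b], y[e.b]) <= 0.0)
        throw std::runtime_error("triangulation: degenerate cavity edge");
      Tri T;
      T.v[0] = ip; T.v[1] = e.a; T.v[2] = e.b;
      T.n[0] = e.outside; T.n[1] = -1; T.n[2] = -1;
      T.alive = true;
      const int id = static_cast<int>(tris.size());
      if (e.outside >= 0) {
        Tri& O = tris[e.outside];
        for (int i = 0; i < 3; ++i) {
          const int a = O.v[(i + 1) % 3], b = O.v[(i + 2) % 3];
          if ((a == e.b && b == e.a) || (a == e.a && b == e.b)) O.n[i] = id;
        }
      }
      tris.push_back(T);
      newtris.push_back(id);
      by_a[e.a] = id;  // triangle whose v[1] is e.a
      by_b[e.b] = id;  // triangle whose v[2] is e.b
    }
    // stitch the fan: edge (ip, a) of T joins the new triangle whose b' == a;
    // edge (b, ip) joins the one whose a' == b
    for (size_t ni = 0; ni < newtris.size(); ++ni) {
      Tri& T = tris[newtris[ni]];
      std::unordered_map<int, int>::const_iterator it;
      it = by_b.find(T.v[1]);
      T.n[2] = (it != by_b.end()) ? it->second : -1;
      it = by_a.find(T.v[2]);
      T.n[1] = (it != by_a.end()) ? it->second : -1;
    }
    hint = first_new;
  }
};

}  // namespace

// points given as 0-based (row, col, value); output is nrow_out x ncol_out
// [[Rcpp::export]]
NumericMatrix cpp_tri_interp(NumericVector pr, NumericVector pc,
                             NumericVector pv, int nrow_out, int ncol_out) {
  const int n = pr.size();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pc[i] + jitter(static_cast<uint32_t>(i), 1u);
    py[i] = pr[i] + jitter(static_cast<uint32_t>(i), 2u);
  }
  // locality-preserving insertion order: 16-row bands, columns within a band
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> key(n);
  for (int i = 0; i < n; ++i)
    key[i] = std::floor(pr[i] / 16.0) * 1e7 + pc[i] * 1e2 + pr[i] / 16.0;
  std::sort(order.begin(), order.end(),
            [&key](int a, int b) { return key[a] < key[b]; });

  Delaunay dt;
  dt.build(px, py, order);

  NumericMatrix out(nrow_out, ncol_out);
  std::vector<int> out_r, out_c;  // pixels outside the convex hull
  int hint = 0;
  for (int r = 0; r < nrow_out; ++r) {
    const double qy = static_cast<double>(r);
    for (int c = 0; c < ncol_out; ++c) {
      const double qx = static_cast<double>(c);
      const int t = dt.locate(qx, qy, hint);
      if (t < 0) { out_r.push_back(r); out_c.push_back(c); continue; }
      hint = t;
      if (dt.has_super(t)) { out_r.push_back(r); out_c.push_back(c); continue; }
      const Tri& T = dt.tris[t];
      const double x0 = dt.x[T.v[0]], y0 = dt.y[T.v[0]];
      const double x1 = dt.x[T.v[1]], y1 = dt.y[T.v[1]];
      const double x2 = dt.x[T.v[2]], y2 = dt.y[T.v[2]];
      const double a0 = orient2d(x1, y1, x2, y2, qx, qy);
      const double a1 = orient2d(x2, y2, x0, y0, qx, qy);
      const double a2 = orient2d(x0, y0, x1, y1, qx, qy);
      const double s = a0 + a1 + a2;
      if (s == 0.0) { out_r.push_back(r); out_c.push_back(c); continue; }
      out(r, c) = (a0 * pv[T.v[0]] + a1 * pv[T.v[1]] + a2 * pv[T.v[2]]) / s;
    }
  }
  // nearest-data-point extrapolation outside the hull
  for (size_t k = 0; k < out_r.size(); ++k) {
    const double qy = out_r[k], qx = out_c[k];
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = pc[i] - qx, dy = pr[i] - qy;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = i; }
    }
    out(out_r[k], out_c[k]) = pv[bi];
  }
  return out;
}

// thin-plate spline evaluation: f(r,c) = a0 + a1*r + a2*c + sum_i w_i U(d_i),
// U(d) = d^2 log d (points 0-based, grid 0-based)
// [[Rcpp::export]]
NumericMatrix cpp_tps_eval(NumericVector pr, NumericVector pc,
                           NumericVector w, NumericVector a,
                           int nrow_out, int ncol_out) {
  const int n = pr.size();
  NumericMatrix out(nrow_out, ncol_out);
  for (int r = 0; r < nrow_out; ++r) {
    for (int c = 0; c < ncol_out; ++c) {
      double v = a[0] + a[1] * r + a[2] * c;
      for (int i = 0; i < n; ++i) {
        const double dr = r - pr[i], dc = c - pc[i];
        const double d2 = dr * dr + dc * dc;
        if (d2 > 0.0) v += w[i] * 0.5 * d2 * std::log(d2);
      }
      out(r, c) = v;
    }
  }
  return out;
}
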