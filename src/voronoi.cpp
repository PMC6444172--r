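// Bounded 3D Voronoi tessellation by sequential half-space clipping.
//
// Each cell starts as the bounding box and is clipped by the bisector plane
// of every candidate neighbour seed, nearest first, stopping once the next
// neighbour is further than twice the cell's current circumradius (at that
// point no later bisector can cut the cell). This is the standard cell-based
// construction used by Voro++; it yields, per cell, the vertex coordinates,
// the faces as vertex loops, the generating neighbour of every face and the
// cell volume.

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 3> P3;

static inline double dot3(const P3 &a, const P3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline P3 sub3(const P3 &a, const P3 &b) {
  return P3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline P3 cross3(const P3 &a, const P3 &b) {
  return P3{a[1] * b[2] - a[2] * b[1], a[2] * b[0] - a[0] * b[2],
            a[0] * b[1] - a[1] * b[0]};
}

struct Cell {
  std::vector<P3> V;
  std::vector<std::vector<int>> F;  // vertex loops
  std::vector<int> nbr;             // >=0 neighbour seed, -1..-6 box walls
};

static void init_box_cell(Cell &c, const double *bx) {
  // vertices of the box, index = x + 2y + 4z over corner bits
  c.V.clear(); c.F.clear(); c.nbr.clear();
  for (int k = 0; k < 8; ++k) {
    c.V.push_back(P3{bx[(k & 1)], bx[2 + ((k >> 1) & 1)], bx[4 + ((k >> 2) & 1)]});
  }
  int faces[6][4] = {
    {0, 2, 6, 4},  // x = min
    {1, 5, 7, 3},  // x = max
    {0, 4, 5, 1},  // y = min
    {2, 3, 7, 6},  // y = max
    {0, 1, 3, 2},  // z = min
    {4, 6, 7, 5}}; // z = max
  for (int f = 0; f < 6; ++f) {
    c.F.push_back(std::vector<int>(faces[f], faces[f] + 4));
    c.nbr.push_back(-(f + 1));
  }
}

// Clip cell by half-space dot(n, x) <= cval; returns false if cell vanishes.
static bool clip_cell(Cell &c, const P3 &n, double cval, int nbr_id,
                      double eps) {
  size_t nv = c.V.size();
  std::vector<double> s(nv);
  bool any_cut = false, all_cut = true;
  for (size_t i = 0; i < nv; ++i) {
    s[i] = dot3(n, c.V[i]) - cval;
    if (s[i] > eps) any_cut = true; else all_cut = false;
  }
  if (!any_cut) return true;
  if (all_cut) return false;

  std::map<std::pair<int, int>, int> cut_pt;  // edge -> new vertex id
  auto intersect = [&](int a, int b) -> int {
    std::pair<int, int> key(std::min(a, b), std::max(a, b));
    auto it = cut_pt.find(key);
    if (it != cut_pt.end()) return it->second;
    double t = s[a] / (s[a] - s[b]);
    P3 p{c.V[a][0] + t * (c.V[b][0] - c.V[a][0]),
         c.V[a][1] + t * (c.V[b][1] - c.V[a][1]),
         c.V[a][2] + t * (c.V[b][2] - c.V[a][2])};
    c.V.push_back(p);
    int id = (int)c.V.size() - 1;
    cut_pt[key] = id;
    return id;
  };
  auto keep = [&](int i) { return s[i] <= eps; };

  std::vector<std::vector<int>> newF;
  std::vector<int> newNbr;
  std::vector<std::pair<int, int>> cap_seg;  // one segment per clipped face
  for (size_t f = 0; f < c.F.size(); ++f) {
    const std::vector<int> &L = c.F[f];
    std::vector<int> out;
    std::vector<int> added;
    int m = (int)L.size();
    for (int i = 0; i < m; ++i) {
      int a = L[i], b = L[(i + 1) % m];
      if (keep(b)) {
        if (!keep(a)) { int I = intersect(a, b); out.push_back(I); added.push_back(I); }
        out.push_back(b);
      } else if (keep(a)) {
        int I = intersect(a, b); out.push_back(I); added.push_back(I);
      }
    }
    // drop consecutive duplicates
    std::vector<int> ded;
    for (size_t i = 0; i < out.size(); ++i) {
      if (ded.empty() || ded.back() != out[i]) ded.push_back(out[i]);
    }
    if (ded.size() > 1 && ded.front() == ded.back()) ded.pop_back();
    if ((int)ded.size() >= 3) {
      newF.push_back(ded);
      newNbr.push_back(c.nbr[f]);
      if (added.size() == 2 && added[0] != added[1])
        cap_seg.push_back(std::make_pair(added[0], added[1]));
    }
  }
  // assemble the cap face by chaining the per-face cut segments
  if (cap_seg.size() >= 3) {
    std::map<int, std::vector<int>> adj;
    for (auto &pr : cap_seg) {
      adj[pr.first].push_back(pr.second);
      adj[pr.second].push_back(pr.first);
    }
    bool ok = true;
    for (auto &kv : adj) if (kv.second.size() != 2) { ok = false; break; }
    if (ok) {
      std::vector<int> loop;
      int start = cap_seg[0].first, prev = -1, cur = start;
      do {
        loop.push_back(cur);
        int nxt = (adj[cur][0] != prev) ? adj[cur][0] : adj[cur][1];
        prev = cur; cur = nxt;
        if ((int)loop.size() > (int)cap_seg.size() + 1) { ok = false; break; }
      } while (cur != start);
      if (ok && (int)loop.size() >= 3) {
        newF.push_back(loop);
        newNbr.push_back(nbr_id);
      }
    }
  }
  // compact vertices
  std::vector<int> remap(c.V.size(), -1);
  std::vector<P3> V2;
  for (auto &L : newF)
    for (int &v : L) {
      if (remap[v] < 0) { remap[v] = (int)V2.size(); V2.push_back(c.V[v]); }
      v = remap[v];
    }
  c.V.swap(V2);
  c.F.swap(newF);
  c.nbr.swap(newNbr);
  return !c.F.empty();
}

static double cell_volume(const Cell &c, const P3 &seed) {
  // convex cell containing the seed: V = sum over faces of A_f * h_f / 3
  double vol = 0.0;
  for (size_t f = 0; f < c.F.size(); ++f) {
    const std::vector<int> &L = c.F[f];
    int m = (int)L.size();
    P3 cen{0, 0, 0};
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < 3; ++k) cen[k] += c.V[L[i]][k] / m;
    P3 nrm{0, 0, 0};
    for (int i = 0; i < m; ++i) {
      P3 a = sub3(c.V[L[i]], cen), b = sub3(c.V[L[(i + 1) % m]], cen);
      P3 cr = cross3(a, b);
      for (int k = 0; k < 3; ++k) nrm[k] += 0.5 * cr[k];
    }
    double area = std::sqrt(dot3(nrm, nrm));
    if (area <= 0) continue;
    P3 u{nrm[0] / area, nrm[1] / area, nrm[2] / area};
    double h = std::fabs(dot3(u, sub3(cen, seed)));
    vol += area * h / 3.0;
  }
  return vol;
}

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericMatrix seeds, NumericVector box) {
  int n = seeds.nrow();
  if (n < 8) stop("tessellation needs at least 8 seeds");
  double bx[6] = {box[0], box[1], box[2], box[3], box[4], box[5]};
  double diag = 0;
  for (int k = 0; k < 3; ++k)
    diag += (bx[2 * k + 1] - bx[2 * k]) * (bx[2 * k + 1] - bx[2 * k]);
  double eps = 1e-9 * std::sqrt(diag);

  std::vector<P3> S(n);
  for (int i = 0; i < n; ++i) S[i] = P3{seeds(i, 0), seeds(i, 1), seeds(i, 2)};

  List cells(n);
  std::vector<double> d2(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      P3 d = sub3(S[j], S[i]);
      d2[j] = dot3(d, d);
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });
    Cell c;
    init_box_cell(c, bx);
    for (int jj = 1; jj < n; ++jj) {
      int j = ord[jj];
      if (d2[j] <= 0)
        stop("degenerate seed set: coincident seeds %d and %d", i + 1, j + 1);
      // stopping rule: furthest cell vertex from the seed
      double r2 = 0;
      for (size_t v = 0; v < c.V.size(); ++v) {
        P3 d = sub3(c.V[v], S[i]);
        double q = dot3(d, d);
        if (q > r2) r2 = q;
      }
      if (d2[j] > 4.0 * r2) break;
      P3 mid{(S[i][0] + S[j][0]) / 2, (S[i][1] + S[j][1]) / 2,
             (S[i][2] + S[j][2]) / 2};
      P3 nrm = sub3(S[j], S[i]);
      double nn = std::sqrt(dot3(nrm, nrm));
      P3 u{nrm[0] / nn, nrm[1] / nn, nrm[2] / nn};
      if (!clip_cell(c, u, dot3(u, mid), j, eps))
        stop("cell %d vanished during clipping (degenerate seeds?)", i + 1);
    }
    int nv = (int)c.V.size();
    NumericMatrix V(nv, 3);
    for (int v = 0; v < nv; ++v)
      for (int k = 0; k < 3; ++k) V(v, k) = c.V[v][k];
    List F(c.F.size());
    IntegerVector nb(c.F.size());
    bool wall = false;
    for (size_t f = 0; f < c.F.size(); ++f) {
      IntegerVector L(c.F[f].size());
      for (size_t v = 0; v < c.F[f].size(); ++v) L[v] = c.F[f][v] + 1;
      F[f] = L;
      nb[f] = (c.nbr[f] >= 0) ? c.nbr[f] + 1 : c.nbr[f];
      if (c.nbr[f] < 0) wall = true;
    }
    cells[i] = List::create(_["vertices"] = V, _["faces"] = F,
                            _["nbr"] = nb,
                            _["volume"] = cell_volume(c, S[i]),
                            _["interior"] = !wall);
  }
  return cells;
}
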