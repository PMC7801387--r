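#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

// Vietoris-Rips persistence in degrees 0 and 1 for a Euclidean point cloud.
//
// Degree 0 comes from Kruskal-style union-find over edges sorted by length.
// Degree 1 is the standard persistence pairing from GF(2) reduction of the
// triangle boundary matrix (columns over edges, processed in filtration
// order, pivot = largest edge index). A simplex enters the filtration at its
// largest pairwise distance, so a triangle's value equals its longest edge.
//
// Two exact truncations keep the triangle set small without changing the
// diagram below max_filtration:
//  * enclosing radius: at eps >= min_i max_j d(i,j) some vertex is adjacent
//    to every other, the clique 2-skeleton is a cone and H1 vanishes, so no
//    simplex beyond that scale can matter for degree 1;
//  * max_filtration: births at or beyond it are discarded and surviving
//    classes have their death capped there.

namespace {

struct Tri {
  int e1, e2, e3;  // edge indices, ascending
  int key;         // filtration position = largest edge index (== e3)
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  // returns true if a merge happened
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
Rcpp::List rips_pairs_cpp(Rcpp::NumericMatrix coords, double max_filtration) {
  const int n = coords.nrow();
  const int d = coords.ncol();

  std::vector<double> dist(static_cast<size_t>(n) * n, 0.0);
  double diameter = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = coords(i, k) - coords(j, k);
        s += diff * diff;
      }
      const double dij = std::sqrt(s);
      dist[i * n + j] = dij;
      dist[j * n + i] = dij;
      if (dij > diameter) diameter = dij;
    }
  }

  // enclosing radius: min over vertices of its eccentricity
  double r_enc = diameter;
  for (int i = 0; i < n; ++i) {
    double ecc = 0.0;
    for (int j = 0; j < n; ++j)
      if (dist[i * n + j] > ecc) ecc = dist[i * n + j];
    if (ecc < r_enc) r_enc = ecc;
  }
  if (n < 2) r_enc = 0.0;

  double maxf = max_filtration;
  if (!(maxf > 0.0) || Rcpp::NumericVector::is_na(maxf)) maxf = diameter;
  const double thresh = std::min(maxf, r_enc);

  // edges with length <= thresh, sorted by (length, i, j)
  struct Edge { double len; int i, j; };
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist[i * n + j] <= thresh) edges.push_back({dist[i * n + j], i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.len != b.len) return a.len < b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = static_cast<int>(edges.size());

  // edge index lookup and degree-0 pairing
  std::vector<int> eidx(static_cast<size_t>(n) * n, -1);
  std::vector<char> h0_negative(m, 0);
  std::vector<double> h0_death;
  UnionFind uf(n);
  for (int e = 0; e < m; ++e) {
    eidx[edges[e].i * n + edges[e].j] = e;
    eidx[edges[e].j * n + edges[e].i] = e;
    if (uf.unite(edges[e].i, edges[e].j)) {
      h0_negative[e] = 1;
      h0_death.push_back(edges[e].len);
    }
  }

  // triangles whose three edges are all present, in filtration order
  std::vector<Tri> tris;
  for (int e = 0; e < m; ++e) {
    // triangles having edge e as their LONGEST edge: third vertex k adjacent
    // to both endpoints through shorter (earlier-indexed) edges
    const int i = edges[e].i, j = edges[e].j;
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      const int a = eidx[i * n + k], b = eidx[j * n + k];
      if (a < 0 || b < 0 || a >= e || b >= e) continue;
      tris.push_back({std::min(a, b), std::max(a, b), e, e});
    }
  }
  // enumeration order (ascending longest-edge index) IS filtration order;
  // triangle id = position in `tris`

  // Reduce the anti-transpose: one column per edge (descending filtration),
  // rows = the triangles containing it, pivot = earliest triangle. The
  // persistence pairs (edge birth, triangle death) are identical to those
  // of the triangle boundary matrix, but in this direction almost every
  // column finds a free pivot at once, which is what makes Rips tractable.
  const int n_tris = static_cast<int>(tris.size());
  std::vector<int> cof_count(m, 0);
  for (const Tri& t : tris) {
    ++cof_count[t.e1]; ++cof_count[t.e2]; ++cof_count[t.e3];
  }
  std::vector<int> cof_start(m + 1, 0);
  for (int e = 0; e < m; ++e) cof_start[e + 1] = cof_start[e] + cof_count[e];
  std::vector<int> cof(cof_start[m]);
  {
    std::vector<int> fill(cof_start.begin(), cof_start.end() - 1);
    for (int tid = 0; tid < n_tris; ++tid) {
      cof[fill[tris[tid].e1]++] = tid;
      cof[fill[tris[tid].e2]++] = tid;
      cof[fill[tris[tid].e3]++] = tid;  // ids ascending within each list
    }
  }

  // apparent pair: edge e whose earliest cofacet triangle has e as its
  // longest edge; such pairs have zero persistence in Rips (the triangle
  // enters with e), are persistence pairs, and both their rows and columns
  // can be left out of the explicit reduction (Morse-pairing argument).
  // When another column's pivot lands on an apparent row, eliminating it
  // with the partner edge's full cofacet column is exact.
  auto is_apparent_col = [&](int e) {
    return cof_start[e] < cof_start[e + 1] &&
           tris[cof[cof_start[e]]].key == e;
  };

  std::vector<int> pivot_to_col(n_tris, -1);
  std::vector<std::vector<int>> stored;
  std::vector<double> h1_birth, h1_death;
  std::vector<char> h1_paired_edge(m, 0);
  std::vector<int> col, tmp;
  auto xor_range = [&](std::vector<int>& c, const int* beg, const int* end) {
    tmp.clear();
    std::set_symmetric_difference(c.begin(), c.end(), beg, end,
                                  std::back_inserter(tmp));
    c.swap(tmp);
  };
  for (int e = m - 1; e >= 0; --e) {
    if (h0_negative[e]) continue;        // clearing: column reduces to zero
    if (is_apparent_col(e)) {
      h1_paired_edge[e] = 1;             // zero-persistence pair, implicit
      continue;
    }
    col.assign(cof.begin() + cof_start[e], cof.begin() + cof_start[e + 1]);
    int piv = -1;
    while (!col.empty()) {
      piv = col.front();                 // earliest triangle
      const int sc = pivot_to_col[piv];
      if (sc >= 0) {
        const std::vector<int>& other = stored[sc];
        xor_range(col, other.data(), other.data() + other.size());
        continue;
      }
      const int partner = tris[piv].key;  // piv's longest edge
      if (partner != e && is_apparent_col(partner) &&
          cof[cof_start[partner]] == piv) {
        // apparent row: eliminate with the partner's full cofacet column
        xor_range(col, cof.data() + cof_start[partner],
                  cof.data() + cof_start[partner + 1]);
        continue;
      }
      break;
    }
    if (col.empty()) continue;           // essential edge (or H0 artifact)
    pivot_to_col[piv] = static_cast<int>(stored.size());
    stored.push_back(col);
    h1_paired_edge[e] = 1;
    const double birth = edges[e].len;
    const double death = std::min(edges[tris[piv].key].len, maxf);
    if (death > birth && birth < maxf) {
      h1_birth.push_back(birth);
      h1_death.push_back(death);
    }
  }

  // positive edges never killed by a triangle up to thresh: only possible
  // when maxf < r_enc; they are still alive at maxf
  if (thresh < r_enc) {
    for (int e = 0; e < m; ++e) {
      if (!h0_negative[e] && !h1_paired_edge[e] && edges[e].len < maxf) {
        h1_birth.push_back(edges[e].len);
        h1_death.push_back(maxf);
      }
    }
  }

  Rcpp::NumericMatrix h1(static_cast<int>(h1_birth.size()), 2);
  for (size_t r = 0; r < h1_birth.size(); ++r) {
    h1(r, 0) = h1_birth[r];
    h1(r, 1) = h1_death[r];
  }
  Rcpp::NumericMatrix h0(static_cast<int>(h0_death.size()), 2);
  for (size_t r = 0; r < h0_death.size(); ++r) {
    h0(r, 0) = 0.0;
    h0(r, 1) = std::min(h0_death[r], maxf);
  }
  return Rcpp::List::create(Rcpp::Named("h0") = h0, Rcpp::Named("h1") = h1,
                            Rcpp::Named("diameter") = diameter,
                            Rcpp::Named("enclosing_radius") = r_enc,
                            Rcpp::Named("max_filtration") = maxf);
}
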