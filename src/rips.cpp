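#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Persistence of the Vietoris-Rips (flag) filtration of a finite metric
// space, homology dimensions 0 and 1 over Z/2.
//
// Dimension 0: Kruskal-style union-find over edges in filtration order;
// each merging edge kills a component born at 0.
//
// Dimension 1: standard boundary-matrix reduction of the triangle/edge
// block.  Columns (triangles, in filtration order) are kept as ascending
// vectors of edge ranks and reduced by symmetric-difference against stored
// columns sharing the same pivot; the final pivot edge is the creator of
// the 1-cycle killed by the triangle.
//
// The enumeration is truncated adaptively: persistence pairs with death
// <= R depend only on the <=R subcomplex, and an edge (a,b) "dominated" by
// a vertex c with max(d(a,c), d(b,c)) <= d(a,b) creates a cycle that dies
// at its own birth value (its filling triangle enters simultaneously), so
// it never contributes a reported point.  Reduction therefore runs up to
// the smallest radius R with (i) R at least the connectivity radius, (ii)
// every edge beyond R dominated, and (iii) no 1-cycle born within R still
// open at R, growing R toward max_radius if (iii) fails.  The reported
// diagram is identical to full enumeration at max_radius.

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

static void sym_diff(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (a[i] > b[j]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  a.swap(out);
}

struct Edge { double w; int i, j; };

// one reduction pass over the subcomplex of radius r_enum; returns pairs
// and the births of still-open cycles
static void reduce_dim1(const std::vector<double> &d, int n, double r_enum,
                        std::vector<double> &births,
                        std::vector<double> &deaths,
                        std::vector<double> &open_births) {
  births.clear(); deaths.clear(); open_births.clear();
  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = d[(size_t)i * n + j];
      if (w <= r_enum) edges.push_back({w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int ne = (int)edges.size();
  if (!ne) return;

  std::vector<char> edge_negative(ne, 0);
  {
    UnionFind uf(n);
    for (int e = 0; e < ne; ++e)
      if (uf.unite(edges[e].i, edges[e].j)) edge_negative[e] = 1;
  }
  std::vector<std::vector<std::pair<int,int>>> rank_of(n);
  for (int e = 0; e < ne; ++e) rank_of[edges[e].i].push_back({edges[e].j, e});
  for (int i = 0; i < n; ++i) std::sort(rank_of[i].begin(), rank_of[i].end());
  auto edge_rank = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    const auto &v = rank_of[a];
    auto it = std::lower_bound(v.begin(), v.end(), std::make_pair(b, -1));
    return it->second;
  };

  struct Tri { double w; int e1, e2, e3; };
  std::vector<Tri> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = d[(size_t)i * n + j];
      if (dij > r_enum) continue;
      for (int k = j + 1; k < n; ++k) {
        double dik = d[(size_t)i * n + k], djk = d[(size_t)j * n + k];
        if (dik > r_enum || djk > r_enum) continue;
        double w = std::max(dij, std::max(dik, djk));
        tris.push_back({w, edge_rank(i, j), edge_rank(i, k), edge_rank(j, k)});
      }
    }
  std::sort(tris.begin(), tris.end(), [](const Tri &a, const Tri &b) {
    if (a.w != b.w) return a.w < b.w;
    int am = std::max(a.e1, std::max(a.e2, a.e3));
    int bm = std::max(b.e1, std::max(b.e2, b.e3));
    return am < bm;
  });

  std::vector<int> pivot_col(ne, -1);
  std::vector<std::vector<int>> cols;
  cols.reserve(tris.size() / 8 + 4);
  std::vector<int> col(3);
  for (size_t t = 0; t < tris.size(); ++t) {
    col.assign({tris[t].e1, tris[t].e2, tris[t].e3});
    std::sort(col.begin(), col.end());
    std::vector<int> work(col);
    while (!work.empty()) {
      int piv = work.back();
      int owner = pivot_col[piv];
      if (owner < 0) break;
      sym_diff(work, cols[owner]);
    }
    if (!work.empty()) {
      int piv = work.back();
      pivot_col[piv] = (int)cols.size();
      cols.push_back(work);
      double birth = edges[piv].w, death = tris[t].w;
      if (death > birth) { births.push_back(birth); deaths.push_back(death); }
    }
  }
  for (int e = 0; e < ne; ++e)
    if (!edge_negative[e] && pivot_col[e] < 0)
      open_births.push_back(edges[e].w);
}

// [[Rcpp::export]]
List rips_pairs_cpp(NumericMatrix dist, double max_radius, int max_dimension) {
  const int n = dist.nrow();
  std::vector<double> d((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[(size_t)i * n + j] = dist(i, j);

  // dimension 0 over all edges within max_radius
  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = d[(size_t)i * n + j];
      if (w <= max_radius) edges.push_back({w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  UnionFind uf(n);
  std::vector<double> deaths0;
  double r_connect = 0.0;
  for (const Edge &e : edges)
    if (uf.unite(e.i, e.j)) { deaths0.push_back(e.w); r_connect = e.w; }
  int n_components = n - (int)deaths0.size();

  NumericMatrix d1pairs(0, 2);
  NumericVector d1_unpaired;
  if (max_dimension >= 1 && !edges.empty()) {
    // largest non-dominated edge weight
    double r_dom = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double w = d[(size_t)i * n + j];
        if (w > max_radius || w <= r_dom) continue;
        bool dominated = false;
        for (int k = 0; k < n; ++k) {
          if (k == i || k == j) continue;
          if (d[(size_t)i * n + k] <= w && d[(size_t)j * n + k] <= w) {
            dominated = true; break;
          }
        }
        if (!dominated) r_dom = w;
      }
    double r_enum = std::min(max_radius,
                             std::max(r_connect, r_dom) * (1 + 1e-12));
    std::vector<double> births, deaths, open_births;
    for (;;) {
      reduce_dim1(d, n, r_enum, births, deaths, open_births);
      if (open_births.empty() || r_enum >= max_radius) break;
      r_enum = std::min(max_radius, r_enum * 1.5);
    }
    d1pairs = NumericMatrix((int)births.size(), 2);
    for (size_t r = 0; r < births.size(); ++r) {
      d1pairs(r, 0) = births[r];
      d1pairs(r, 1) = deaths[r];
    }
    d1_unpaired = wrap(open_births);
  }

  return List::create(
    _["dim0_deaths"] = wrap(deaths0),
    _["n_infinite0"] = n_components,
    _["dim1_pairs"] = d1pairs,
    _["dim1_unpaired_births"] = d1_unpaired);
}
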