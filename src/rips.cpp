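// Vietoris-Rips persistent homology in dimensions 0-2 over a prime field.
//
// Simplices up to dimension 3 with diameter <= threshold are enumerated
// explicitly (neighbour bitsets), sorted by (filtration value, vertex
// lexicographic), and the boundary matrices are reduced with the standard
// column algorithm processed from the top dimension down ("twist"):
// columns whose row becomes a pivot in dimension d+1 are cleared in
// dimension d, so only genuinely informative columns are reduced. H0 is
// computed by union-find over the sorted edges. Classes still alive at the
// threshold are reported with death = Inf.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

typedef std::pair<int, int> Entry;          // (row index, coefficient)
typedef std::vector<Entry> Column;          // sorted ascending by row

struct Simplex1 { float f; int i, j; };
struct Simplex2 { float f; int i, j, k; };
struct Simplex3 { float f; int i, j, k, l; };

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

// add col_from * mult into col_to (mod p), keeping sorted-by-row order
Column add_scaled(const Column& a, const Column& b, int mult, int p) {
  Column out;
  out.reserve(a.size() + b.size());
  size_t ia = 0, ib = 0;
  while (ia < a.size() || ib < b.size()) {
    if (ib == b.size() || (ia < a.size() && a[ia].first < b[ib].first)) {
      out.push_back(a[ia++]);
    } else if (ia == a.size() || b[ib].first < a[ia].first) {
      int c = int((int64_t)b[ib].second * mult % p);
      if (c) out.push_back(Entry(b[ib].first, c));
      ++ib;
    } else {
      int c = int(((int64_t)a[ia].second + (int64_t)b[ib].second * mult) % p);
      if (c) out.push_back(Entry(a[ia].first, c));
      ++ia; ++ib;
    }
  }
  return out;
}

std::vector<int> inverse_table(int p) {
  std::vector<int> inv(p, 0);
  inv[1] = 1;
  for (int a = 2; a < p; ++a) inv[a] = p - (int)((int64_t)(p / a) * inv[p % a] % p);
  return inv;
}

// Reduce one column against the stored reduced columns; record the pair or
// report the column as zero (creator).
// pivot2col maps pivot row -> index into `stored`.
bool reduce_column(Column& col, std::unordered_map<int, int>& pivot2col,
                   std::vector<Column>& stored, const std::vector<int>& inv,
                   int p) {
  while (!col.empty()) {
    int piv = col.back().first;
    std::unordered_map<int, int>::iterator it = pivot2col.find(piv);
    if (it == pivot2col.end()) return true;  // new pivot found
    const Column& other = stored[it->second];
    int c = col.back().second;
    int co = other.back().second;
    int mult = (int)((int64_t)(p - c) * inv[co] % p);
    col = add_scaled(col, other, mult, p);
  }
  return false;  // reduced to zero: creator
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_rips_persistence(const arma::mat& D, double threshold,
                                int prime = 47, int max_dim = 2,
                                double max_simplices = 4e7) {
  const int n = D.n_rows;
  const int p = prime;
  const std::vector<int> inv = inverse_table(p);
  const float t = (float)threshold;

  std::vector<int> dims;
  std::vector<double> births, deaths;
  const double INF = R_PosInf;

  // ---- edges ----
  std::vector<Simplex1> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D(i, j) <= t) edges.push_back(Simplex1{(float)D(i, j), i, j});
  std::sort(edges.begin(), edges.end(),
            [](const Simplex1& a, const Simplex1& b) {
              if (a.f != b.f) return a.f < b.f;
              if (a.i != b.i) return a.i < b.i;
              return a.j < b.j;
            });
  const int ne = (int)edges.size();
  std::vector<int> eidx((size_t)n * n, -1);
  for (int e = 0; e < ne; ++e)
    eidx[(size_t)edges[e].i * n + edges[e].j] = e;

  // ---- H0 by union-find ----
  UnionFind uf(n);
  std::vector<char> edge_creator(ne, 0);
  for (int e = 0; e < ne; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      if (edges[e].f > 0) { dims.push_back(0); births.push_back(0.0);
                            deaths.push_back(edges[e].f); }
    } else {
      edge_creator[e] = 1;
    }
  }
  int n_comp = 0;
  for (int i = 0; i < n; ++i) if (uf.find(i) == i) ++n_comp;
  for (int c = 0; c < n_comp; ++c) {
    dims.push_back(0); births.push_back(0.0); deaths.push_back(INF);
  }

  if (max_dim < 1) {
    return Rcpp::List::create(Rcpp::Named("dim") = dims,
                              Rcpp::Named("birth") = births,
                              Rcpp::Named("death") = deaths);
  }

  // ---- neighbour bitsets ----
  const int words = (n + 63) / 64;
  std::vector<uint64_t> nbr((size_t)n * words, 0);
  for (int e = 0; e < ne; ++e) {
    int i = edges[e].i, j = edges[e].j;
    nbr[(size_t)i * words + j / 64] |= (uint64_t)1 << (j % 64);
    nbr[(size_t)j * words + i / 64] |= (uint64_t)1 << (i % 64);
  }

  // ---- triangles ----
  std::vector<Simplex2> tris;
  {
    std::vector<uint64_t> common(words);
    for (int e = 0; e < ne; ++e) {
      int i = edges[e].i, j = edges[e].j;
      for (int w = 0; w < words; ++w)
        common[w] = nbr[(size_t)i * words + w] & nbr[(size_t)j * words + w];
      for (int w = (j + 1) / 64; w < words; ++w) {
        uint64_t bits = common[w];
        if (w == (j + 1) / 64 && (j + 1) % 64)
          bits &= ~(((uint64_t)1 << ((j + 1) % 64)) - 1);
        while (bits) {
          int k = w * 64 + __builtin_ctzll(bits);
          bits &= bits - 1;
          float f = std::max(edges[e].f,
                             std::max((float)D(i, k), (float)D(j, k)));
          tris.push_back(Simplex2{f, i, j, k});
          if ((double)tris.size() > max_simplices)
            Rcpp::stop("triangle count exceeds max_simplices; lower the threshold");
        }
      }
    }
  }
  std::sort(tris.begin(), tris.end(),
            [](const Simplex2& a, const Simplex2& b) {
              if (a.f != b.f) return a.f < b.f;
              if (a.i != b.i) return a.i < b.i;
              if (a.j != b.j) return a.j < b.j;
              return a.k < b.k;
            });
  const size_t nt = tris.size();
  std::unordered_map<uint64_t, int> tidx;
  tidx.reserve(nt * 2);
  for (size_t m = 0; m < nt; ++m) {
    uint64_t key = ((uint64_t)tris[m].i * n + tris[m].j) * n + tris[m].k;
    tidx[key] = (int)m;
  }

  std::vector<char> tri_cleared(nt, 0);   // births paired in dim 3
  std::vector<char> tri_negative(nt, 0);  // pivots of reduced d2 columns

  // ---- tetrahedra and the dimension-3 reduction (H2 deaths) ----
  if (max_dim >= 2) {
    std::vector<Simplex3> tets;
    {
      std::vector<uint64_t> common(words);
      for (size_t m = 0; m < nt; ++m) {
        int i = tris[m].i, j = tris[m].j, k = tris[m].k;
        for (int w = 0; w < words; ++w)
          common[w] = nbr[(size_t)i * words + w] & nbr[(size_t)j * words + w] &
                      nbr[(size_t)k * words + w];
        for (int w = (k + 1) / 64; w < words; ++w) {
          uint64_t bits = common[w];
          if (w == (k + 1) / 64 && (k + 1) % 64)
            bits &= ~(((uint64_t)1 << ((k + 1) % 64)) - 1);
          while (bits) {
            int l = w * 64 + __builtin_ctzll(bits);
            bits &= bits - 1;
            float f = std::max(std::max(tris[m].f, (float)D(i, l)),
                               std::max((float)D(j, l), (float)D(k, l)));
            tets.push_back(Simplex3{f, i, j, k, l});
            if ((double)tets.size() > max_simplices)
              Rcpp::stop("tetrahedron count exceeds max_simplices; lower the threshold");
          }
        }
      }
    }
    std::sort(tets.begin(), tets.end(),
              [](const Simplex3& a, const Simplex3& b) {
                if (a.f != b.f) return a.f < b.f;
                if (a.i != b.i) return a.i < b.i;
                if (a.j != b.j) return a.j < b.j;
                if (a.k != b.k) return a.k < b.k;
                return a.l < b.l;
              });

    std::unordered_map<int, int> pivot2col;
    std::vector<Column> stored;
    pivot2col.reserve(tets.size());
    for (size_t c = 0; c < tets.size(); ++c) {
      const Simplex3& s = tets[c];
      int v[4] = {s.i, s.j, s.k, s.l};
      Column col;
      for (int fdrop = 0; fdrop < 4; ++fdrop) {
        int a = 0, fv[3];
        for (int q = 0; q < 4; ++q) if (q != fdrop) fv[a++] = v[q];
        uint64_t key = ((uint64_t)fv[0] * n + fv[1]) * n + fv[2];
        int row = tidx.find(key)->second;
        int sgn = (fdrop % 2 == 0) ? 1 : p - 1;  // +,-,+,- for drop 0..3
        col.push_back(Entry(row, sgn));
      }
      std::sort(col.begin(), col.end());
      if (reduce_column(col, pivot2col, stored, inv, p)) {
        int piv = col.back().first;
        pivot2col[piv] = (int)stored.size();
        stored.push_back(col);
        tri_cleared[piv] = 1;
        if (tets[c].f > tris[piv].f) {
          dims.push_back(2);
          births.push_back(tris[piv].f);
          deaths.push_back(tets[c].f);
        }
      }
    }
  }

  // ---- dimension-2 reduction (H1 deaths, essential H2 births) ----
  {
    std::unordered_map<int, int> pivot2col;
    std::vector<Column> stored;
    pivot2col.reserve(nt);
    std::vector<char> edge_paired(ne, 0);
    for (size_t c = 0; c < nt; ++c) {
      if (tri_cleared[c]) continue;  // known creator, paired in dim 3
      const Simplex2& s = tris[c];
      Column col;
      int rows[3] = {eidx[(size_t)s.j * n + s.k], eidx[(size_t)s.i * n + s.k],
                     eidx[(size_t)s.i * n + s.j]};
      int sgns[3] = {1, p - 1, 1};
      for (int q = 0; q < 3; ++q) col.push_back(Entry(rows[q], sgns[q]));
      std::sort(col.begin(), col.end());
      if (reduce_column(col, pivot2col, stored, inv, p)) {
        int piv = col.back().first;
        pivot2col[piv] = (int)stored.size();
        stored.push_back(col);
        edge_paired[piv] = 1;
        tri_negative[c] = 1;
        if (tris[c].f > edges[piv].f) {
          dims.push_back(1);
          births.push_back(edges[piv].f);
          deaths.push_back(tris[c].f);
        }
      } else if (max_dim >= 2) {
        // creator never killed by a tetrahedron: essential H2
        dims.push_back(2);
        births.push_back(tris[c].f);
        deaths.push_back(INF);
      }
    }
    // essential H1: creator edges never paired with a triangle
    for (int e = 0; e < ne; ++e) {
      if (edge_creator[e] && !edge_paired[e]) {
        dims.push_back(1);
        births.push_back(edges[e].f);
        deaths.push_back(INF);
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("dim") = dims,
                            Rcpp::Named("birth") = births,
                            Rcpp::Named("death") = deaths);
}
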