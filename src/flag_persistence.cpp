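#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Enumerate the simplices (dims 1..max_dim) of the flag complex of the
// distance-threshold graph at level `cap`.  `dmat` holds integer geodesic
// distances with -1 marking unreachable pairs.  The appearance value of a
// simplex is the maximum pairwise distance among its vertices, so faces never
// appear after cofaces.  Vertices (dim 0) are handled on the R side.
// [[Rcpp::export]]
List flag_simplices_cpp(IntegerMatrix dmat, int cap, int max_dim) {
  const int n = dmat.nrow();
  std::vector<std::vector<int>> nb(n); // neighbours j > i with 0 < d <= cap
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = dmat(i, j);
      if (d > 0 && d <= cap) nb[i].push_back(j);
    }

  std::vector<int> e1, e2, ev;
  std::vector<int> t1, t2, t3, tv;
  std::vector<int> q1, q2, q3, q4, qv;

  for (int i = 0; i < n; ++i) {
    for (size_t a = 0; a < nb[i].size(); ++a) {
      int j = nb[i][a];
      int dij = dmat(i, j);
      e1.push_back(i); e2.push_back(j); ev.push_back(dij);
      if (max_dim < 2) continue;
      for (size_t b = a + 1; b < nb[i].size(); ++b) {
        int k = nb[i][b];
        int djk = dmat(j, k);
        if (djk <= 0 || djk > cap) continue;
        int vt = std::max(dij, std::max(dmat(i, k), djk));
        t1.push_back(i); t2.push_back(j); t3.push_back(k); tv.push_back(vt);
        if (max_dim < 3) continue;
        for (size_t c = b + 1; c < nb[i].size(); ++c) {
          int l = nb[i][c];
          int djl = dmat(j, l), dkl = dmat(k, l);
          if (djl <= 0 || djl > cap || dkl <= 0 || dkl > cap) continue;
          int vq = std::max(std::max(vt, dmat(i, l)), std::max(djl, dkl));
          q1.push_back(i); q2.push_back(j); q3.push_back(k); q4.push_back(l);
          qv.push_back(vq);
        }
      }
    }
  }

  List out = List::create(
    _["edge_v"] = IntegerMatrix(0, 2), _["edge_val"] = IntegerVector(0),
    _["tri_v"]  = IntegerMatrix(0, 3), _["tri_val"]  = IntegerVector(0),
    _["tet_v"]  = IntegerMatrix(0, 4), _["tet_val"]  = IntegerVector(0));

  {
    IntegerMatrix m(e1.size(), 2);
    for (size_t r = 0; r < e1.size(); ++r) { m(r, 0) = e1[r] + 1; m(r, 1) = e2[r] + 1; }
    out["edge_v"] = m; out["edge_val"] = wrap(ev);
  }
  if (max_dim >= 2) {
    IntegerMatrix m(t1.size(), 3);
    for (size_t r = 0; r < t1.size(); ++r) { m(r, 0) = t1[r] + 1; m(r, 1) = t2[r] + 1; m(r, 2) = t3[r] + 1; }
    out["tri_v"] = m; out["tri_val"] = wrap(tv);
  }
  if (max_dim >= 3) {
    IntegerMatrix m(q1.size(), 4);
    for (size_t r = 0; r < q1.size(); ++r) { m(r, 0) = q1[r] + 1; m(r, 1) = q2[r] + 1; m(r, 2) = q3[r] + 1; m(r, 3) = q4[r] + 1; }
    out["tet_v"] = m; out["tet_val"] = wrap(qv);
  }
  return out;
}

static inline std::vector<int> xor_cols(const std::vector<int>& a,
                                        const std::vector<int>& b) {
  std::vector<int> r;
  r.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(r));
  return r;
}

// Standard persistence pairing over Z2 by column reduction with the
// twist/clearing optimisation (columns processed by decreasing dimension;
// the pivot row of a reduced column is a known birth simplex whose own
// column is skipped).  Input simplices must already be in filtration order:
// (appearance value, dimension, lexicographic vertex tuple).
//
// verts: ns x 4 matrix of 1-based vertex ids, ascending within a row, 0-padded.
// dims:  simplex dimension 0..3.  n: number of vertices of the network.
// Returns partner[i]: 0-based index of the simplex paired with i, or -1.
// [[Rcpp::export]]
IntegerVector reduce_filtration_cpp(IntegerMatrix verts, IntegerVector dims,
                                    int n) {
  const int ns = verts.nrow();
  const int64_t base = (int64_t)n + 1;

  // position lookup: encode a sorted vertex tuple as an integer key
  std::unordered_map<int64_t, int> pos;
  pos.reserve(ns * 2);
  std::vector<int64_t> key(ns);
  for (int i = 0; i < ns; ++i) {
    int64_t k = 0;
    for (int c = 0; c <= dims[i]; ++c) k = k * base + verts(i, c);
    key[i] = k;
    pos[k] = i;
  }

  int max_dim = 0;
  for (int i = 0; i < ns; ++i) if (dims[i] > max_dim) max_dim = dims[i];

  std::vector<int> partner(ns, -1);
  std::vector<int> pivot_col(ns, -1);           // row index -> reduced column
  std::vector<std::vector<int>> stored(ns);     // reduced column of that col
  std::vector<char> cleared(ns, 0);

  for (int d = max_dim; d >= 1; --d) {
    for (int j = 0; j < ns; ++j) {
      if (dims[j] != d || cleared[j]) continue;
      // boundary of simplex j: drop one vertex at a time
      std::vector<int> col;
      col.reserve(d + 1);
      for (int drop = 0; drop <= d; ++drop) {
        int64_t k = 0;
        for (int c = 0; c <= d; ++c) {
          if (c == drop) continue;
          k = k * base + verts(j, c);
        }
        auto it = pos.find(k);
        if (it == pos.end()) stop("face of a stored simplex is missing");
        col.push_back(it->second);
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        int other = pivot_col[low];
        if (other < 0) {
          pivot_col[low] = j;
          stored[j] = col;
          partner[low] = j;
          partner[j] = low;
          cleared[low] = 1;
          break;
        }
        col = xor_cols(col, stored[other]);
      }
      // empty column: j creates a d-class; pairing (if any) was or will be
      // recorded when the (d+1)-columns pivot on j (already done: d+1 > d).
    }
  }
  return wrap(partner);
}
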