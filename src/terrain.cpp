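#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nodata-aware focal mean over an arbitrary offset neighbourhood.
// Offsets are (dr, dc) pairs; edge policy is shrink-to-valid (mean of the
// in-bounds, non-NA part). Returns NA where no neighbour is valid.
// [[Rcpp::export(name = ".focal_mean_cpp")]]
NumericMatrix focal_mean_cpp(NumericMatrix m, IntegerVector dr, IntegerVector dc) {
  int nr = m.nrow(), nc = m.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0; int n = 0;
      for (int k = 0; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = m(rr, cc);
        if (NumericMatrix::is_na(v)) continue;
        s += v; ++n;
      }
      out(r, c) = (n > 0) ? s / n : NA_REAL;
    }
  }
  return out;
}

struct PFCell {
  double z; int r, c;
  bool operator<(const PFCell &o) const { return z > o.z; } // min-heap
};

// Priority-flood depression filling with an epsilon gradient so every cell
// has a strictly descending path to the border. NA cells are left NA and
// act as drains.
// [[Rcpp::export(name = ".pitfill_cpp")]]
NumericMatrix pitfill_cpp(NumericMatrix dem, double eps = 1e-6) {
  int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  std::vector<char> closed((size_t)nr * nc, 0);
  std::priority_queue<PFCell> pq;
  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      out(r, c) = dem(r, c);
      bool border = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      bool na = NumericMatrix::is_na(dem(r, c));
      if (na) { closed[idx(r, c)] = 1; continue; }
      // cells next to NA drain into them like a border
      if (!border) {
        for (int dr2 = -1; dr2 <= 1 && !border; ++dr2)
          for (int dc2 = -1; dc2 <= 1; ++dc2) {
            if (NumericMatrix::is_na(dem(r + dr2, c + dc2))) { border = true; break; }
          }
      }
      if (border) { closed[idx(r, c)] = 1; pq.push({dem(r, c), r, c}); }
    }
  const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    PFCell cur = pq.top(); pq.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = cur.r + DR[k], cc = cur.c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (closed[idx(rr, cc)]) continue;
      closed[idx(rr, cc)] = 1;
      double z = out(rr, cc);
      if (z <= cur.z) z = cur.z + eps;
      out(rr, cc) = z;
      pq.push({z, rr, cc});
    }
  }
  return out;
}

// D8 flow accumulation on a pit-filled DEM. Each cell sends its entire
// accumulated load to the steepest-descent neighbour (drop / distance).
// `weights` is each cell's own contribution (in cell units). Cells are
// processed from high to low so upslope loads arrive before dispatch.
// [[Rcpp::export(name = ".d8_accum_cpp")]]
NumericMatrix d8_accum_cpp(NumericMatrix filled, NumericMatrix weights) {
  int nr = filled.nrow(), nc = filled.ncol();
  size_t n = (size_t)nr * nc;
  NumericMatrix acc(nr, nc);
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  // column-major linear index; sort descending by elevation, NA last
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    double za = filled[a], zb = filled[b];
    bool na_a = NumericMatrix::is_na(za), na_b = NumericMatrix::is_na(zb);
    if (na_a != na_b) return !na_a;
    if (na_a) return a < b;
    if (za != zb) return za > zb;
    return a < b;
  });
  const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double DIST[8] = {M_SQRT2, 1, M_SQRT2, 1, 1, M_SQRT2, 1, M_SQRT2};
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      acc(r, c) = NumericMatrix::is_na(filled(r, c)) ? NA_REAL : weights(r, c);
  for (size_t i = 0; i < n; ++i) {
    size_t lin = ord[i];
    int c = (int)(lin / nr), r = (int)(lin % nr);
    double z = filled(r, c);
    if (NumericMatrix::is_na(z)) continue;
    int best = -1; double bestslope = 0.0;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double zn = filled(rr, cc);
      if (NumericMatrix::is_na(zn)) continue;
      double s = (z - zn) / DIST[k];
      if (s > bestslope) { bestslope = s; best = k; }
    }
    if (best >= 0) acc(r + DR[best], c + DC[best]) += acc(r, c);
  }
  return acc;
}

// Euclidean distance (in cells) from every cell to the nearest target cell.
// Brute force over the target list; grids used here are modest.
// [[Rcpp::export(name = ".dist_to_targets_cpp")]]
NumericMatrix dist_to_targets_cpp(int nr, int nc, IntegerVector tr, IntegerVector tc) {
  NumericMatrix out(nr, nc);
  int K = tr.size();
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double best = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double dr2 = r - tr[k], dc2 = c - tc[k];
        double d = dr2 * dr2 + dc2 * dc2;
        if (d < best) best = d;
      }
      out(r, c) = std::sqrt(best);
    }
  return out;
}
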