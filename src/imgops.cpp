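#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Connected-component labelling of a binary mask.
// Labels are assigned in raster-scan order of each component's first pixel,
// so the output is deterministic. connectivity is 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher 2004).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest FALSE pixel.
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), g(std::max(nr, nc));
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, g, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = g[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, g, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = g[c];
  }
  return d;
}

struct WsNode {
  double elev;
  unsigned long order;
  int r, c, label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // lowest elevation first
    return a.order > b.order;                      // FIFO on ties
  }
};

// Marker-based watershed by priority flooding in ascending elevation.
// Seeds are pushed in increasing label order so that on exact ties the
// lowest label wins deterministically. Pixels outside mask stay 0.
// [[Rcpp::export(name = ".watershed_markers")]]
IntegerMatrix watershed_markers(const NumericMatrix& elev,
                                const IntegerMatrix& markers,
                                const LogicalMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long order = 0;
  const int dr[] = {-1, 1, 0, 0};
  const int dc[] = {0, 0, -1, 1};
  // seed in label order for deterministic tie-breaking
  int maxlab = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > maxlab) maxlab = markers(r, c);
  for (int l = 1; l <= maxlab; ++l) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (markers(r, c) == l && mask(r, c)) {
          lab(r, c) = l;
          WsNode n = {elev(r, c), order++, r, c, l};
          pq.push(n);
        }
      }
    }
  }
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = n.r + dr[k], cc = n.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = n.label;
      WsNode m = {elev(rr, cc), order++, rr, cc, n.label};
      pq.push(m);
    }
  }
  return lab;
}

// For every TRUE pixel, the label of the nearest seed point (Euclidean
// distance to seed coordinates, 0-based rows/cols); ties go to the lowest
// label. Used for the nucleus-seeded Voronoi cell partition.
// [[Rcpp::export(name = ".nearest_seed")]]
IntegerMatrix nearest_seed(const LogicalMatrix& mask,
                           const NumericVector& seed_r,
                           const NumericVector& seed_c) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int ns = seed_r.size();
  IntegerMatrix lab(nr, nc);
  if (ns == 0) return lab;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int s = 0; s < ns; ++s) {
        double dr = r - seed_r[s], dc = c - seed_c[s];
        double d2 = dr * dr + dc * dc;
        if (d2 < best - 1e-12) {
          best = d2;
          bi = s + 1;
        }
      }
      lab(r, c) = bi;
    }
  }
  return lab;
}
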