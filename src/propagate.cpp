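#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Multi-source lowest-cumulative-cost region growing.
//
// A unit step from pixel p to neighbour n costs
//   sqrt( dI(p,n)^2 + lambda * step_len^2 )
// where dI is the (pre-normalized) intensity difference and step_len is the
// Euclidean neighbour distance (1 or sqrt(2)).  Each masked pixel receives
// the label of the seed reachable at minimal path cost.  Ties (within
// tie_tol) are broken toward the lowest seed id so output is deterministic.

struct PqNode {
  double cost;
  int label;
  int idx;
};

struct PqCmp {
  bool operator()(const PqNode &a, const PqNode &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.label > b.label;
  }
};

// [[Rcpp::export(name = ".propagate_core")]]
IntegerMatrix propagate_core(NumericMatrix intensity, IntegerMatrix seeds,
                             LogicalMatrix mask, double lambda,
                             int connectivity, double tie_tol) {
  const int nr = intensity.nrow(), nc = intensity.ncol();
  const int n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);

  // neighbour offsets (dr, dc) and step lengths
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  double step2[8];
  for (int k = 0; k < 8; ++k) step2[k] = (k < 4) ? 1.0 : 2.0;

  std::priority_queue<PqNode, std::vector<PqNode>, PqCmp> pq;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int s = seeds(i, j);
      if (s > 0) {
        int idx = i + j * nr;
        dist[idx] = 0.0;
        if (lab[idx] == 0 || s < lab[idx]) lab[idx] = s;
      }
    }
  }
  for (int idx = 0; idx < n; ++idx)
    if (lab[idx] > 0) pq.push(PqNode{0.0, lab[idx], idx});

  while (!pq.empty()) {
    PqNode nd = pq.top();
    pq.pop();
    int u = nd.idx;
    if (nd.cost > dist[u] + tie_tol) continue;            // stale entry
    if (std::abs(nd.cost - dist[u]) <= tie_tol && nd.label > lab[u]) continue;
    int ui = u % nr, uj = u / nr;
    double iu = intensity(ui, uj);
    for (int k = 0; k < nnb; ++k) {
      int vi = ui + dr8[k], vj = uj + dc8[k];
      if (vi < 0 || vi >= nr || vj < 0 || vj >= nc) continue;
      if (!mask(vi, vj)) continue;                        // growth stays in mask
      int v = vi + vj * nr;
      if (seeds(vi, vj) > 0) continue;                    // seeds keep their label
      double dI = intensity(vi, vj) - iu;
      double w = std::sqrt(dI * dI + lambda * step2[k]);
      double ncost = dist[u] + w;
      if (ncost < dist[v] - tie_tol) {
        dist[v] = ncost;
        lab[v] = nd.label;
        pq.push(PqNode{ncost, nd.label, v});
      } else if (ncost <= dist[v] + tie_tol && nd.label < lab[v]) {
        if (ncost < dist[v]) dist[v] = ncost;
        lab[v] = nd.label;
        pq.push(PqNode{dist[v], nd.label, v});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      // unmasked, unseeded pixels stay background even if a stray seed value
      // touched them through initialization
      if (seeds(i, j) > 0 || mask(i, j)) out(i, j) = lab[idx];
    }
  return out;
}

// [[Rcpp::export(name = ".propagate_cost")]]
NumericMatrix propagate_cost(NumericMatrix intensity, IntegerMatrix seeds,
                             LogicalMatrix mask, double lambda,
                             int connectivity, double tie_tol) {
  // Same search as propagate_core but returns the arrival cost surface,
  // used by tests to identify genuine cost ties.
  const int nr = intensity.nrow(), nc = intensity.ncol();
  const int n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  double step2[8];
  for (int k = 0; k < 8; ++k) step2[k] = (k < 4) ? 1.0 : 2.0;
  std::priority_queue<PqNode, std::vector<PqNode>, PqCmp> pq;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0) {
        int idx = i + j * nr;
        dist[idx] = 0.0;
        lab[idx] = seeds(i, j);
        pq.push(PqNode{0.0, seeds(i, j), idx});
      }
  while (!pq.empty()) {
    PqNode nd = pq.top();
    pq.pop();
    int u = nd.idx;
    if (nd.cost > dist[u] + tie_tol) continue;
    int ui = u % nr, uj = u / nr;
    double iu = intensity(ui, uj);
    for (int k = 0; k < nnb; ++k) {
      int vi = ui + dr8[k], vj = uj + dc8[k];
      if (vi < 0 || vi >= nr || vj < 0 || vj >= nc) continue;
      if (!mask(vi, vj)) continue;
      int v = vi + vj * nr;
      if (seeds(vi, vj) > 0) continue;
      double dI = intensity(vi, vj) - iu;
      double w = std::sqrt(dI * dI + lambda * step2[k]);
      double ncost = dist[u] + w;
      if (ncost < dist[v] - tie_tol) {
        dist[v] = ncost;
        pq.push(PqNode{ncost, nd.label, v});
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = dist[i + j * nr];
  return out;
}

// [[Rcpp::export(name = ".median_disc_core")]]
NumericMatrix median_disc_core(NumericMatrix img, int radius) {
  // Per-pixel median over a disc neighbourhood; reflection at borders.
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> offr, offc;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  const int m = (int)offr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(m);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int k = 0; k < m; ++k) {
        int ri = i + offr[k], cj = j + offc[k];
        if (ri < 0) ri = -ri - 1;                 // reflect
        if (ri >= nr) ri = 2 * nr - ri - 1;
        if (cj < 0) cj = -cj - 1;
        if (cj >= nc) cj = 2 * nc - cj - 1;
        buf[k] = img(ri, cj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}
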