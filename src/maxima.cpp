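#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Topographic prominence of regional local maxima within a mask.
//
// Plateaus (8-connected regions of equal value) are treated as units; a
// plateau is a local maximum iff every masked neighbour is lower.  The
// prominence of a maximum is its height minus the highest saddle connecting
// it to a *dominating* maximum — one of greater height, or equal height with
// a smaller minimum linear index (the deterministic tie rule).  Maxima never
// dominated get prominence = height - min(masked values).
//
// Implemented as a watershed-by-flooding with union-find over plateau
// regions, processed in decreasing height order.

static inline int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
DataFrame cpp_find_maxima(NumericMatrix img, LogicalMatrix mask) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("image/mask dimension mismatch");
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // --- plateau labelling -------------------------------------------------
  std::vector<int> region(n, -1);
  std::vector<double> rval;
  std::vector<int> rmin;                 // min linear index per region
  std::vector<std::vector<int> > rpix;
  std::vector<int> stack;
  int nreg = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || region[idx] >= 0) continue;
    const double v = img[idx];
    stack.clear();
    stack.push_back(idx);
    region[idx] = nreg;
    std::vector<int> pix;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      pix.push_back(cur);
      int ci = cur % nr, cj = cur / nr;
      for (int k = 0; k < 8; ++k) {
        int ni = ci + dr[k], nj = cj + dc[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int nidx = ni + nj * nr;
        if (mask[nidx] && region[nidx] < 0 && img[nidx] == v) {
          region[nidx] = nreg;
          stack.push_back(nidx);
        }
      }
    }
    rval.push_back(v);
    rmin.push_back(*std::min_element(pix.begin(), pix.end()));
    rpix.push_back(pix);
    ++nreg;
  }
  if (nreg == 0)
    return DataFrame::create(_["row"] = IntegerVector(0),
                             _["col"] = IntegerVector(0),
                             _["value"] = NumericVector(0),
                             _["prominence"] = NumericVector(0),
                             _["plateau_px"] = IntegerVector(0));

  // --- local-maximum flags ----------------------------------------------
  std::vector<bool> ismax(nreg, true);
  double minval = R_PosInf;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx]) continue;
    if (img[idx] < minval) minval = img[idx];
    int ci = idx % nr, cj = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ni = ci + dr[k], nj = cj + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      int nidx = ni + nj * nr;
      if (mask[nidx] && img[nidx] > img[idx]) { ismax[region[idx]] = false; break; }
    }
  }

  // --- flood from the top: union-find over regions -----------------------
  std::vector<int> order(nreg);
  for (int r = 0; r < nreg; ++r) order[r] = r;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (rval[a] != rval[b]) return rval[a] > rval[b];
    return rmin[a] < rmin[b];
  });
  std::vector<int> rank(nreg);           // processing order of each region
  for (int k = 0; k < nreg; ++k) rank[order[k]] = k;

  std::vector<int> parent(nreg), peak(nreg);
  std::vector<double> prom(nreg, NA_REAL);
  std::vector<bool> done(nreg, false);
  std::vector<int> nbr;
  for (int k = 0; k < nreg; ++k) {
    const int r = order[k];
    const double v = rval[r];
    // distinct already-processed neighbouring regions (strictly higher)
    nbr.clear();
    for (size_t p = 0; p < rpix[r].size(); ++p) {
      int ci = rpix[r][p] % nr, cj = rpix[r][p] / nr;
      for (int q = 0; q < 8; ++q) {
        int ni = ci + dr[q], nj = cj + dc[q];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int nidx = ni + nj * nr;
        if (!mask[nidx]) continue;
        int nreg2 = region[nidx];
        if (nreg2 != r && done[nreg2]) nbr.push_back(find_root(parent, nreg2));
      }
    }
    std::sort(nbr.begin(), nbr.end());
    nbr.erase(std::unique(nbr.begin(), nbr.end()), nbr.end());

    parent[r] = r; peak[r] = r; done[r] = true;
    if (!nbr.empty()) {
      // winner: component whose peak dominates (higher, tie -> smaller rmin)
      int win = nbr[0];
      for (size_t q = 1; q < nbr.size(); ++q) {
        int cand = nbr[q];
        if (rval[peak[cand]] > rval[peak[win]] ||
            (rval[peak[cand]] == rval[peak[win]] &&
             rmin[peak[cand]] < rmin[peak[win]]))
          win = cand;
      }
      for (size_t q = 0; q < nbr.size(); ++q) {
        int root = nbr[q];
        if (root == win) continue;
        // losing component's peak is killed at saddle level v
        prom[peak[root]] = rval[peak[root]] - v;
        parent[root] = win;
      }
      parent[r] = win;   // current region joins the surviving component
    }
  }
  // surviving components: prominence relative to the masked minimum
  for (int r = 0; r < nreg; ++r) {
    if (!ismax[r]) continue;
    if (ISNA(prom[r]) && find_root(parent, r) == r)
      prom[r] = rval[r] - minval;
    if (ISNA(prom[r])) {
      // max whose component survived under another peak never happens:
      // a component's peak is set at creation and only loses via merge.
      prom[r] = 0.0;   // defensive; unreachable
    }
  }

  // --- representative pixel: plateau pixel nearest the centroid ----------
  std::vector<int> out_row, out_col, out_sz;
  std::vector<double> out_val, out_prom;
  for (int r = 0; r < nreg; ++r) {
    if (!ismax[r]) continue;
    double sr = 0, sc = 0;
    for (size_t p = 0; p < rpix[r].size(); ++p) {
      sr += rpix[r][p] % nr;
      sc += rpix[r][p] / nr;
    }
    sr /= rpix[r].size(); sc /= rpix[r].size();
    int best = rpix[r][0];
    double bestd = R_PosInf;
    for (size_t p = 0; p < rpix[r].size(); ++p) {
      int px = rpix[r][p];
      double di = (px % nr) - sr, dj = (px / nr) - sc;
      double d2 = di * di + dj * dj;
      if (d2 < bestd - 1e-12 ||
          (std::abs(d2 - bestd) <= 1e-12 && px < best)) { bestd = d2; best = px; }
    }
    out_row.push_back(best % nr + 1);    // 1-based for R
    out_col.push_back(best / nr + 1);
    out_val.push_back(rval[r]);
    out_prom.push_back(prom[r]);
    out_sz.push_back((int)rpix[r].size());
  }
  return DataFrame::create(_["row"] = wrap(out_row),
                           _["col"] = wrap(out_col),
                           _["value"] = wrap(out_val),
                           _["prominence"] = wrap(out_prom),
                           _["plateau_px"] = wrap(out_sz));
}
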