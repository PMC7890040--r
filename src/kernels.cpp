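#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect out-of-range indices, scipy 'reflect' convention: (d c b a | a b c d | d c b a).
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// Square-window rank (maximum/minimum) filter, side 2*radius+1, reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter(NumericMatrix x, int radius, bool maximum) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double v = maximum ? R_NegInf : R_PosInf;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = reflect_index(j + dj, W);
        for (int di = -radius; di <= radius; ++di) {
          int ii = reflect_index(i + di, H);
          double w = x(ii, jj);
          if (maximum ? (w > v) : (w < v)) v = w;
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Separable Gaussian blur, kernel truncated at ceil(3*sigma) (>= 1), normalized to
// unit sum, reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma) {
  int H = x.nrow(), W = x.ncol();
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int d = -h; d <= h; ++d) {
    k[d + h] = std::exp(-0.5 * (double)d * (double)d / (sigma * sigma));
    s += k[d + h];
  }
  for (int d = 0; d < 2 * h + 1; ++d) k[d] /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // rows (vertical pass)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = 0.0;
      for (int d = -h; d <= h; ++d) v += k[d + h] * x(reflect_index(i + d, H), j);
      tmp(i, j) = v;
    }
  // cols (horizontal pass)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double v = 0.0;
      for (int d = -h; d <= h; ++d) v += k[d + h] * tmp(i, reflect_index(j + d, W));
      out(i, j) = v;
    }
  return out;
}

struct PeakRec {
  double score, prom;
  int row, col;  // 1-based, rounded plateau centroid
};

static inline int uf_find(std::vector<int> &parent, int p) {
  while (parent[p] != p) {
    parent[p] = parent[parent[p]];
    p = parent[p];
  }
  return p;
}

// Local maxima by topographic prominence (persistence sweep).
//
// Pixels are processed in descending value (ties: row, then col). Components are
// merged with union-find; when a component whose birth level exceeds the current
// level is absorbed by a higher-born component, it dies with prominence
// birth - level and is emitted if prominence >= the threshold. Equal-height
// plateaus accumulate a centroid; twin peaks of equal height are both emitted
// (the one absorbed gets the saddle-limited prominence). The last surviving
// component gets prominence birth - min(image).
// Returns row, col (1-based rounded centroid), score (= birth height) and
// prominence, sorted by descending score then (row, col).
// [[Rcpp::export]]
DataFrame cpp_prominence_maxima(NumericMatrix x, double prominence) {
  int H = x.nrow(), W = x.ncol(), n = H * W;
  std::vector<int> ord(n);
  for (int p = 0; p < n; ++p) ord[p] = p;
  // col-major: p = i + j*H, row i = p % H, col j = p / H
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    double va = x[a], vb = x[b];
    if (va != vb) return va > vb;
    int ia = a % H, ja = a / H, ib = b % H, jb = b / H;
    if (ia != ib) return ia < ib;
    return ja < jb;
  });

  std::vector<int> parent(n, -1);
  std::vector<double> birth(n, 0.0), psr(n, 0.0), psc(n, 0.0);
  std::vector<int> pn(n, 0);
  std::vector<PeakRec> peaks;

  double vmin = x[ord[n - 1]];
  int roots_seen[8];

  for (int t = 0; t < n; ++t) {
    int p = ord[t];
    int i = p % H, j = p / H;
    double v = x[p];
    int nroots = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      int jj = j + dj;
      if (jj < 0 || jj >= W) continue;
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di;
        if (ii < 0 || ii >= H) continue;
        int q = ii + jj * H;
        if (parent[q] < 0) continue;
        int r = uf_find(parent, q);
        bool seen = false;
        for (int k = 0; k < nroots; ++k)
          if (roots_seen[k] == r) { seen = true; break; }
        if (!seen) roots_seen[nroots++] = r;
      }
    }
    if (nroots == 0) {
      parent[p] = p;
      birth[p] = v;
      psr[p] = i; psc[p] = j; pn[p] = 1;
      continue;
    }
    // survivor: highest birth; tie -> smaller (row, col) of root pixel
    int surv = roots_seen[0];
    for (int k = 1; k < nroots; ++k) {
      int r = roots_seen[k];
      if (birth[r] > birth[surv]) surv = r;
      else if (birth[r] == birth[surv]) {
        int ir = r % H, jr = r / H, is = surv % H, js = surv / H;
        if (ir < is || (ir == is && jr < js)) surv = r;
      }
    }
    parent[p] = surv;
    if (v == birth[surv]) { psr[surv] += i; psc[surv] += j; pn[surv] += 1; }
    for (int k = 0; k < nroots; ++k) {
      int r = roots_seen[k];
      if (r == surv) continue;
      if (birth[r] == v && birth[surv] == v) {
        // same plateau, joined now: pool centroid sums
        psr[surv] += psr[r]; psc[surv] += psc[r]; pn[surv] += pn[r];
      } else {
        double pr = birth[r] - v;
        if (pr >= prominence) {
          PeakRec rec;
          rec.score = birth[r];
          rec.prom = pr;
          rec.row = (int)std::floor(psr[r] / pn[r] + 0.5) + 1;
          rec.col = (int)std::floor(psc[r] / pn[r] + 0.5) + 1;
          peaks.push_back(rec);
        }
      }
      parent[r] = surv;
    }
  }

  // final root(s): an 8-connected full grid leaves exactly one
  for (int p = 0; p < n; ++p) {
    if (parent[p] == p && uf_find(parent, p) == p) {
      double pr = birth[p] - vmin;
      if (pr >= prominence && pn[p] > 0) {
        PeakRec rec;
        rec.score = birth[p];
        rec.prom = pr;
        rec.row = (int)std::floor(psr[p] / pn[p] + 0.5) + 1;
        rec.col = (int)std::floor(psc[p] / pn[p] + 0.5) + 1;
        peaks.push_back(rec);
      }
      break;
    }
  }

  std::sort(peaks.begin(), peaks.end(), [](const PeakRec &a, const PeakRec &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.row != b.row) return a.row < b.row;
    return a.col < b.col;
  });

  int m = peaks.size();
  IntegerVector rr(m), cc(m);
  NumericVector sc(m), pm(m);
  for (int k = 0; k < m; ++k) {
    rr[k] = peaks[k].row; cc[k] = peaks[k].col;
    sc[k] = peaks[k].score; pm[k] = peaks[k].prom;
  }
  return DataFrame::create(_["row"] = rr, _["col"] = cc,
                           _["score"] = sc, _["prominence"] = pm);
}

// 8-connected component labeling of a logical mask; labels 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = pj + dj;
          if (jj < 0 || jj >= W) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = pi + di;
            if (ii < 0 || ii >= H) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
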