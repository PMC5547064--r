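#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Type-7 sample quantile of buf (modified in place), matching R's
// quantile(type = 7) arithmetic exactly: x[lo] + g * (x[hi] - x[lo]).
static double quantile7(std::vector<double>& buf, double prob) {
  const int n = (int)buf.size();
  if (n == 1) return buf[0];
  const double h = (n - 1) * prob;
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  const double xlo = buf[lo];
  if (g == 0.0 || lo + 1 >= n) return xlo;
  const double xhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return xlo + g * (xhi - xlo);
}

// Windowed calendar-day quantiles over a set of reference years.
//
// values:  nKeys x nYears matrix of daily values (NA where the day is
//          missing or does not exist in that year).
// exists:  nKeys x nYears logical matrix: does the calendar day exist in
//          that year (leap-day bookkeeping, independent of data gaps).
// windows: nKeys x windowDays matrix of 0-based key positions pooled for
//          each calendar day (circular window).
// yearIdx: 0-based column indices of the years pooled; duplicates allowed
//          (bootstrap surrogates duplicate one year).
// prob:    quantile level.
// minFrac: minimum fraction of the nominal pool that must be non-missing,
//          otherwise the day's threshold is NA.
// [[Rcpp::export(name = ".cppWindowQuantiles")]]
NumericVector cppWindowQuantiles(NumericMatrix values, LogicalMatrix exists,
                                 IntegerMatrix windows, IntegerVector yearIdx,
                                 double prob, double minFrac) {
  const int K = values.nrow();
  const int W = windows.ncol();
  const int S = yearIdx.size();
  NumericVector out(K);
  std::vector<double> buf;
  std::vector<int> win(W);
  buf.reserve((size_t)W * S);
  for (int k = 0; k < K; ++k) {
    buf.clear();
    int nominal = 0;
    for (int j = 0; j < W; ++j) win[j] = windows(k, j);
    // year-major loop: window key positions are near-contiguous, so the
    // inner loop walks down one column of the matrices (cache-friendly)
    for (int s = 0; s < S; ++s) {
      const int y = yearIdx[s];
      for (int j = 0; j < W; ++j) {
        const int kk = win[j];
        if (exists(kk, y)) {
          ++nominal;
          const double v = values(kk, y);
          if (!ISNAN(v)) buf.push_back(v);
        }
      }
    }
    const int n = (int)buf.size();
    if (nominal == 0 || n == 0 || n < minFrac * nominal) {
      out[k] = NA_REAL;
    } else {
      out[k] = quantile7(buf, prob);
    }
  }
  return out;
}

// All bootstrap surrogates of one held-out year in a single pass.
//
// baseIdx holds the 0-based columns of the reference years with the
// held-out year removed (29 of 30). Column m of the result contains the
// calendar-day thresholds of the surrogate base in which year baseIdx[m]
// is counted twice. The base pool is gathered once per calendar day and
// each surrogate only appends the duplicated year's window values.
// [[Rcpp::export(name = ".cppSurrogateThresholds")]]
NumericMatrix cppSurrogateThresholds(NumericMatrix values, LogicalMatrix exists,
                                     IntegerMatrix windows, IntegerVector baseIdx,
                                     double prob, double minFrac) {
  const int K = values.nrow();
  const int W = windows.ncol();
  const int B = baseIdx.size();
  NumericMatrix out(K, B);
  std::vector<std::vector<double>> perYear(B);
  std::vector<int> perNom(B);
  std::vector<double> base, buf;
  std::vector<int> win(W);
  base.reserve((size_t)W * B);
  buf.reserve((size_t)W * (B + 1));
  for (int k = 0; k < K; ++k) {
    base.clear();
    int baseNom = 0;
    for (int j = 0; j < W; ++j) win[j] = windows(k, j);
    for (int b = 0; b < B; ++b) {
      perYear[b].clear();
      perNom[b] = 0;
      const int y = baseIdx[b];
      for (int j = 0; j < W; ++j) {
        const int kk = win[j];
        if (exists(kk, y)) {
          ++perNom[b];
          const double v = values(kk, y);
          if (!ISNAN(v)) perYear[b].push_back(v);
        }
      }
      base.insert(base.end(), perYear[b].begin(), perYear[b].end());
      baseNom += perNom[b];
    }
    for (int m = 0; m < B; ++m) {
      buf.assign(base.begin(), base.end());
      buf.insert(buf.end(), perYear[m].begin(), perYear[m].end());
      const int nominal = baseNom + perNom[m];
      const int n = (int)buf.size();
      if (nominal == 0 || n == 0 || n < minFrac * nominal) {
        out(k, m) = NA_REAL;
      } else {
        out(k, m) = quantile7(buf, prob);
      }
    }
  }
  return out;
}
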