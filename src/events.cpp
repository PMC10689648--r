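#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven open-window coincidence sorter: the first single opens a
// window of length ctw; all singles inside form a cluster and every
// geometrically valid pair in the cluster is emitted (takeAllGoods).
// type 1 (flat panels): valid = different panels, first endpoint = panel 0
// (+Y side). type 2 (cylindrical): valid = circular tangential index
// separation >= minTangSep.
// [[Rcpp::export]]
IntegerMatrix cpp_sort_coincidences(const NumericVector& time,
                                    const IntegerVector& det,
                                    const IntegerVector& ia,
                                    double ctw, int type, int minTangSep,
                                    int nTang) {
  int n = time.size();
  for (int i = 1; i < n; ++i)
    if (time[i] < time[i - 1]) stop("singles must be sorted by time");
  std::vector<int> o1, o2;
  int i = 0;
  while (i < n) {
    double tend = time[i] + ctw;
    int j = i + 1;
    while (j < n && time[j] <= tend) ++j;
    for (int p = i; p < j; ++p) {
      for (int q = p + 1; q < j; ++q) {
        bool good;
        int first = p, second = q;
        if (type == 1) {
          good = det[p] != det[q];
          if (good && det[p] != 0) { first = q; second = p; }
        } else {
          int dd = std::abs(ia[p] - ia[q]);
          dd = std::min(dd, nTang - dd);
          good = dd >= minTangSep;
        }
        if (good) { o1.push_back(first + 1); o2.push_back(second + 1); }
      }
    }
    i = j;
  }
  IntegerMatrix out(o1.size(), 2);
  for (size_t k = 0; k < o1.size(); ++k) {
    out(k, 0) = o1[k];
    out(k, 1) = o2[k];
  }
  return out;
}

// Per-block dead time on a time-sorted singles stream.
// [[Rcpp::export]]
LogicalVector cpp_dead_time(const NumericVector& time,
                            const IntegerVector& block, double tau,
                            bool paralyzable) {
  int n = time.size();
  for (int i = 1; i < n; ++i)
    if (time[i] < time[i - 1]) stop("singles must be sorted by time");
  LogicalVector keep(n);
  std::unordered_map<int, double> last;
  for (int i = 0; i < n; ++i) {
    auto it = last.find(block[i]);
    bool ok = (it == last.end()) || (time[i] - it->second >= tau);
    keep[i] = ok;
    if (paralyzable) {
      last[block[i]] = time[i]; // every hit extends the dead period
    } else if (ok) {
      last[block[i]] = time[i];
    }
  }
  return keep;
}
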