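#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// NA-aware 2-D windowed median with reflect padding.
// A nodata (NA) center stays nodata; NA neighbours are excluded from the
// window; a window with no valid neighbour yields NA.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int window) {
  const int nr = x.nrow(), nc = x.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (NumericMatrix::is_na(x(i, j))) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = -jj - 1;            // reflect (edge not repeated twice
        if (jj >= nc) jj = 2 * nc - jj - 1;  //  beyond one bounce)
        for (int di = -h; di <= h; ++di) {
          int ii = i + di;
          if (ii < 0) ii = -ii - 1;
          if (ii >= nr) ii = 2 * nr - ii - 1;
          double v = x(ii, jj);
          if (!NumericMatrix::is_na(v)) buf.push_back(v);
        }
      }
      if (buf.empty()) { out(i, j) = NA_REAL; continue; }
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        m = (m + buf[mid - 1]) / 2.0;
      }
      out(i, j) = m;
    }
  }
  return out;
}
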