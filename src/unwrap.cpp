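// Quality-guided flood-fill 2D phase unwrapping.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

struct QPix {
  double q;
  int idx;
  bool operator<(const QPix& o) const { return q < o.q; }
};

// [[Rcpp::export(name = ".unwrap2d_cpp")]]
NumericMatrix unwrap2d_cpp(const NumericMatrix& img,
                           const NumericMatrix& quality) {
  const int nx = img.nrow(), nz = img.ncol(), n = nx * nz;
  NumericMatrix out = clone(img);
  std::vector<bool> done(n, false), queued(n, false);
  const double* q = &quality(0, 0);

  int start = 0;
  for (int k = 1; k < n; ++k) if (q[k] > q[start]) start = k;
  done[start] = true;

  std::priority_queue<QPix> pq;
  auto push_nb = [&](int k) {
    const int i = k % nx, j = k / nx;
    const int nb[4] = {i > 0 ? k - 1 : -1, i < nx - 1 ? k + 1 : -1,
                       j > 0 ? k - nx : -1, j < nz - 1 ? k + nx : -1};
    for (int m = 0; m < 4; ++m)
      if (nb[m] >= 0 && !done[nb[m]] && !queued[nb[m]]) {
        pq.push({q[nb[m]], nb[m]});
        queued[nb[m]] = true;
      }
  };
  push_nb(start);

  double* o = &out(0, 0);
  const double twopi = 2.0 * M_PI;
  while (!pq.empty()) {
    const int k = pq.top().idx;
    pq.pop();
    if (done[k]) continue;
    const int i = k % nx, j = k / nx;
    const int nb[4] = {i > 0 ? k - 1 : -1, i < nx - 1 ? k + 1 : -1,
                       j > 0 ? k - nx : -1, j < nz - 1 ? k + nx : -1};
    // unwrap against the highest-quality already-done neighbor
    int ref = -1;
    for (int m = 0; m < 4; ++m)
      if (nb[m] >= 0 && done[nb[m]] && (ref < 0 || q[nb[m]] > q[ref]))
        ref = nb[m];
    if (ref >= 0)
      o[k] += twopi * std::round((o[ref] - o[k]) / twopi);
    done[k] = true;
    push_nb(k);
  }
  return out;
}
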