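#include <Rcpp.h>
using namespace Rcpp;

// Co-occurrence counts of quantized gray levels (0..G-1) at pixel offset
// (dx, dy): dx shifts columns, dy shifts rows. Counts every in-bounds
// ordered pair ((r, c), (r + dy, c + dx)); when symmetric, the reversed
// pairs are added too. Returns a G x G count matrix (not normalized).
// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts_cpp(IntegerMatrix q, int dx, int dy, int G,
                              bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  NumericMatrix counts(G, G);
  const int *qp = INTEGER(q);
  double *cp = REAL(counts);
  const int r0 = std::max(0, -dy), r1 = std::min(nr, nr - dy);
  const int c0 = std::max(0, -dx), c1 = std::min(nc, nc - dx);
  const long shift = (long)dy + (long)dx * nr; // column-major neighbour step
  for (int c = c0; c < c1; ++c) {
    const int *col = qp + (long)c * nr;
    const int *nbr = col + shift;
    for (int r = r0; r < r1; ++r) {
      const int i = col[r];
      const int j = nbr[r];
      cp[i + (long)j * G] += 1.0;
      if (symmetric) cp[j + (long)i * G] += 1.0;
    }
  }
  return counts;
}
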