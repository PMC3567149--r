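#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// PWM window scan over both strands of an integer-encoded sequence
// (1=A, 2=C, 3=G, 4=T, 0=N/other). `probs` is the 4 x L pseudocount-
// normalized column-probability matrix, rows in A,C,G,T order.
//
// Returns the TRAP-style affinity (sum over windows of the likelihood
// ratio product against the background) and the maximum log-odds window
// score; windows containing an ambiguous base are skipped entirely.

// [[Rcpp::export]]
List scan_pwm_cpp(IntegerVector seq, NumericMatrix probs, NumericVector bg) {
  int S = seq.size();
  int L = probs.ncol();
  if (S < L) stop("sequence shorter than motif");
  double aff = 0.0;
  double best = R_NegInf;
  for (int strand = 0; strand < 2; ++strand) {
    std::vector<double> lr(4 * L);
    for (int j = 0; j < L; ++j)
      for (int b = 0; b < 4; ++b) {
        // reverse strand: complement base, reversed column order
        double p = (strand == 0) ? probs(b, j) : probs(3 - b, L - 1 - j);
        lr[j * 4 + b] = std::log(p / bg[b]);
      }
    for (int i = 0; i + L <= S; ++i) {
      double s = 0.0;
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        int c = seq[i + j];
        if (c == 0) { ok = false; break; }
        s += lr[j * 4 + (c - 1)];
      }
      if (!ok) continue;
      aff += std::exp(s);
      if (s > best) best = s;
    }
  }
  return List::create(_["affinity"] = aff, _["max_logodds"] = best);
}
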