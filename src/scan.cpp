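#include <Rcpp.h>
using namespace Rcpp;

// Scan an integer-coded sequence (A=0..T=3, N=4) with a log-odds PWM on both
// strands. Minus-strand matches are scored with the reverse-complement PWM at
// the same forward coordinates; windows containing N are skipped.
// [[Rcpp::export]]
List scan_pwm_cpp(IntegerVector seq, NumericMatrix pwm, NumericMatrix pwm_rc,
                  double threshold) {
  const int L = seq.size(), W = pwm.ncol();
  std::vector<int> pos, strand;
  std::vector<double> score;
  for (int i = 0; i + W <= L; ++i) {
    double sp = 0.0, sm = 0.0;
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      const int b = seq[i + j];
      if (b > 3) { ok = false; break; }
      sp += pwm(b, j);
      sm += pwm_rc(b, j);
    }
    if (!ok) continue;
    if (sp >= threshold) { pos.push_back(i); strand.push_back(0); score.push_back(sp); }
    if (sm >= threshold) { pos.push_back(i); strand.push_back(1); score.push_back(sm); }
  }
  return List::create(_["pos"] = wrap(pos), _["strand"] = wrap(strand),
                      _["score"] = wrap(score));
}

// Count k-mers of width w on the forward strand of every sequence, k-mers
// containing N excluded. Returns counts indexed by the 2-bit encoding.
// [[Rcpp::export]]
NumericVector count_kmers_cpp(List seqs, int w) {
  const size_t nk = ((size_t)1) << (2 * w);
  NumericVector counts((R_xlen_t)nk);
  const int mask = (int)(nk - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    IntegerVector v = seqs[s];
    int code = 0, valid = 0;
    for (int i = 0; i < v.size(); ++i) {
      const int b = v[i];
      if (b > 3) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= w) counts[code] += 1.0;
    }
  }
  return counts;
}
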