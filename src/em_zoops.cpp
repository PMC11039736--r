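#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ZOOPS (zero-or-one occurrence per sequence) EM for a single motif.
//
// Model per sequence: with prior gamma the sequence carries exactly one motif
// site at a uniformly chosen offset/strand, emitting bases from the PFM
// columns; all other bases come from the 0-order background. E-step computes
// the posterior over (no site, site at offset j on strand s); M-step
// re-estimates the PFM (flat-per-cell pseudocount `pseudocount`, distributed
// by the background) and gamma. Deterministic given its inputs.
//
// seqs: list of integer vectors (A=0..T=3, N=4). Windows containing N get
// probability 0. Sequences shorter than W are ignored.
// [[Rcpp::export]]
List em_zoops_cpp(List seqs, NumericMatrix theta0, NumericVector bg,
                  double gamma0, int max_iter, double tol, double pseudocount) {
  const int W = theta0.ncol();
  const int n = seqs.size();
  std::vector<std::vector<int> > sv(n);
  std::vector<int> usable;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    sv[i].assign(v.begin(), v.end());
    if ((int)sv[i].size() >= W) usable.push_back(i);
  }
  if (usable.empty()) stop("no sequence is at least as long as the motif");

  NumericMatrix theta = clone(theta0);
  double gamma = gamma0;
  double log_bg[4];
  for (int b = 0; b < 4; ++b) log_bg[b] = std::log(bg[b]);
  double prev_ll = -INFINITY, ll = -INFINITY;
  std::vector<double> ll_trace;

  std::vector<double> lth(4 * W);
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < W; ++j)
      for (int b = 0; b < 4; ++b)
        lth[4 * j + b] = std::log(theta(b, j)) - log_bg[b];

    NumericMatrix C(4, W);
    double site_post_sum = 0.0;
    ll = 0.0;
    for (size_t u = 0; u < usable.size(); ++u) {
      const std::vector<int> &s = sv[usable[u]];
      const int m = (int)s.size() - W + 1;
      // log weights: index 0 = no site, then + strand offsets, then - strand
      std::vector<double> lw(1 + 2 * m);
      lw[0] = std::log1p(-gamma);
      const double lsite = std::log(gamma) - std::log(2.0 * m);
      double lmax = lw[0];
      for (int j = 0; j < m; ++j) {
        double sp = lsite, sm = lsite;
        bool ok = true;
        for (int k = 0; k < W; ++k) {
          const int b = s[j + k];
          if (b > 3) { ok = false; break; }
          sp += lth[4 * k + b];
          sm += lth[4 * (W - 1 - k) + (3 - b)];
        }
        lw[1 + j] = ok ? sp : -INFINITY;
        lw[1 + m + j] = ok ? sm : -INFINITY;
        if (lw[1 + j] > lmax) lmax = lw[1 + j];
        if (lw[1 + m + j] > lmax) lmax = lw[1 + m + j];
      }
      double tot = 0.0;
      for (int k = 0; k < 1 + 2 * m; ++k) tot += std::exp(lw[k] - lmax);
      ll += lmax + std::log(tot);
      // posteriors and expected counts
      double psite = 0.0;
      for (int j = 0; j < m; ++j) {
        const double pp = std::exp(lw[1 + j] - lmax) / tot;
        const double pm = std::exp(lw[1 + m + j] - lmax) / tot;
        psite += pp + pm;
        if (pp > 0)
          for (int k = 0; k < W; ++k) C(s[j + k], k) += pp;
        if (pm > 0)
          for (int k = 0; k < W; ++k) C(3 - s[j + k], W - 1 - k) += pm;
      }
      site_post_sum += psite;
    }
    // M-step
    for (int j = 0; j < W; ++j) {
      double csum = 0.0;
      for (int b = 0; b < 4; ++b) {
        C(b, j) += pseudocount * bg[b];
        csum += C(b, j);
      }
      for (int b = 0; b < 4; ++b) theta(b, j) = C(b, j) / csum;
    }
    gamma = site_post_sum / usable.size();
    if (gamma < 1e-6) gamma = 1e-6;
    if (gamma > 1.0 - 1e-6) gamma = 1.0 - 1e-6;
    ll_trace.push_back(ll);
    if (iter > 0 && ll - prev_ll < tol) break;
    prev_ll = ll;
  }

  // final hard assignment: maximum-posterior site if it beats "no site"
  std::vector<int> a_seq, a_off, a_strand;
  std::vector<double> a_post;
  for (int j = 0; j < W; ++j)
    for (int b = 0; b < 4; ++b)
      lth[4 * j + b] = std::log(theta(b, j)) - log_bg[b];
  for (size_t u = 0; u < usable.size(); ++u) {
    const int i = usable[u];
    const std::vector<int> &s = sv[i];
    const int m = (int)s.size() - W + 1;
    const double lsite = std::log(gamma) - std::log(2.0 * m);
    double lw0 = std::log1p(-gamma);
    double best = -INFINITY, tot = 0.0, lmax = lw0;
    int bj = -1, bs = 0;
    std::vector<double> lw(2 * m);
    for (int j = 0; j < m; ++j) {
      double sp = lsite, sm = lsite;
      bool ok = true;
      for (int k = 0; k < W; ++k) {
        const int b = s[j + k];
        if (b > 3) { ok = false; break; }
        sp += lth[4 * k + b];
        sm += lth[4 * (W - 1 - k) + (3 - b)];
      }
      lw[j] = ok ? sp : -INFINITY;
      lw[m + j] = ok ? sm : -INFINITY;
      if (lw[j] > lmax) lmax = lw[j];
      if (lw[m + j] > lmax) lmax = lw[m + j];
      if (lw[j] > best) { best = lw[j]; bj = j; bs = 0; }
      if (lw[m + j] > best) { best = lw[m + j]; bj = j; bs = 1; }
    }
    tot = std::exp(lw0 - lmax);
    for (int k = 0; k < 2 * m; ++k) tot += std::exp(lw[k] - lmax);
    // assignment requires (i) the best site posterior to beat "no site" and
    // (ii) a positive log-odds window score: without (ii) a large fitted
    // gamma lets pure-background sequences be absorbed and subtracted,
    // collapsing the discovery pool in one iteration
    if (bj >= 0 && best > lw0 && best - lsite > 0) {
      a_seq.push_back(i + 1);
      a_off.push_back(bj);
      a_strand.push_back(bs);
      a_post.push_back(std::exp(best - lmax) / tot);
    }
  }

  return List::create(
    _["theta"] = theta, _["gamma"] = gamma,
    _["loglik"] = wrap(ll_trace),
    _["assign_seq"] = wrap(a_seq), _["assign_offset"] = wrap(a_off),
    _["assign_strand"] = wrap(a_strand), _["assign_posterior"] = wrap(a_post));
}
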