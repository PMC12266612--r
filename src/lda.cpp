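#include <Rcpp.h>
using namespace Rcpp;

// Collapsed-Gibbs sweeps for LDA. Token t belongs to document doc_of[t] and
// word type word_of[t] (both 0-based). Counts are updated in place on clones
// and returned. Uses R's RNG so set.seed() governs reproducibility.

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc_of, IntegerVector word_of,
                   IntegerVector z_in, IntegerMatrix n_dk_in,
                   IntegerMatrix n_kw_in, IntegerVector n_k_in,
                   double alpha, double beta, int n_iter) {
  IntegerVector z = clone(z_in);
  IntegerMatrix n_dk = clone(n_dk_in);
  IntegerMatrix n_kw = clone(n_kw_in);
  IntegerVector n_k = clone(n_k_in);
  const int N = z.size();
  const int K = n_kw.nrow();
  const int V = n_kw.ncol();
  std::vector<double> p(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int t = 0; t < N; ++t) {
      const int d = doc_of[t], w = word_of[t];
      int k = z[t];
      // exclude the current token
      n_dk(d, k)--; n_kw(k, w)--; n_k[k]--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (n_dk(d, kk) + alpha) *
                (n_kw(kk, w) + beta) / (n_k[kk] + V * beta);
        total += p[kk];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u < cum) { k = kk; break; }
      }
      z[t] = k;
      n_dk(d, k)++; n_kw(k, w)++; n_k[k]++;
    }
  }
  return List::create(_["z"] = z, _["n_dk"] = n_dk,
                      _["n_kw"] = n_kw, _["n_k"] = n_k);
}

// Fold-in Gibbs for held-out documents: topic-word distribution phi (K x V)
// is frozen; only the held-out document-topic counts move.

// [[Rcpp::export]]
List lda_foldin_cpp(IntegerVector doc_of, IntegerVector word_of,
                    IntegerVector z_in, IntegerMatrix n_dk_in,
                    NumericMatrix phi, double alpha, int n_iter) {
  IntegerVector z = clone(z_in);
  IntegerMatrix n_dk = clone(n_dk_in);
  const int N = z.size();
  const int K = phi.nrow();
  std::vector<double> p(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int t = 0; t < N; ++t) {
      const int d = doc_of[t], w = word_of[t];
      int k = z[t];
      n_dk(d, k)--;
      double total = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (n_dk(d, kk) + alpha) * phi(kk, w);
        total += p[kk];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      k = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        cum += p[kk];
        if (u < cum) { k = kk; break; }
      }
      z[t] = k;
      n_dk(d, k)++;
    }
  }
  return List::create(_["z"] = z, _["n_dk"] = n_dk);
}
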