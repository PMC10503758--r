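#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// Token-level input: doc[i], word[i] are 0-based indices of the document and
// vocabulary item of token i. Uses R's RNG stream, so results are fully
// reproducible under set.seed() on the calling side.
//
// Estimators are posterior means of the final assignment state,
//   phi[k, w]  = (n_kw + beta)  / (n_k + V * beta)
//   theta[d,k] = (n_dk + alpha) / (n_d + K * alpha)
// or, when average = true, the running mean of those quantities over all
// post-burn-in sweeps.

// [[Rcpp::export]]
List lda_gibbs_cpp(const IntegerVector& doc, const IntegerVector& word,
                   int D, int V, int K,
                   double alpha, double beta,
                   int n_iter, int burn_in, bool average) {
  const int N = doc.size();
  IntegerVector z(N);
  IntegerMatrix n_dk(D, K), n_kw(K, V);
  IntegerVector n_k(K), n_d(D);

  RNGScope scope;

  // random initial assignments
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ++n_dk(doc[i], k);
    ++n_kw(k, word[i]);
    ++n_k[k];
    ++n_d[doc[i]];
  }

  std::vector<double> p(K);
  NumericMatrix phi_acc(K, V), theta_acc(D, K);
  int n_acc = 0;
  const double Vb = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      // exclude current token from counts
      --n_dk(d, k); --n_kw(k, w); --n_k[k];

      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += (n_dk(d, j) + alpha) * (n_kw(j, w) + beta) / (n_k[j] + Vb);
        p[j] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && u > p[k]) ++k;

      z[i] = k;
      ++n_dk(d, k); ++n_kw(k, w); ++n_k[k];
    }

    if (average && it >= burn_in) {
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + Vb;
        for (int w = 0; w < V; ++w)
          phi_acc(k, w) += (n_kw(k, w) + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        const double denom = n_d[d] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (n_dk(d, k) + alpha) / denom;
      }
      ++n_acc;
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  if (average && n_acc > 0) {
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w) phi(k, w) = phi_acc(k, w) / n_acc;
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) theta(d, k) = theta_acc(d, k) / n_acc;
  } else {
    for (int k = 0; k < K; ++k) {
      const double denom = n_k[k] + Vb;
      for (int w = 0; w < V; ++w) phi(k, w) = (n_kw(k, w) + beta) / denom;
    }
    for (int d = 0; d < D; ++d) {
      const double denom = n_d[d] + K * alpha;
      for (int k = 0; k < K; ++k) theta(d, k) = (n_dk(d, k) + alpha) / denom;
    }
  }

  return List::create(_["z"] = z, _["n_dk"] = n_dk, _["n_kw"] = n_kw,
                      _["n_k"] = n_k, _["phi"] = phi, _["theta"] = theta);
}
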