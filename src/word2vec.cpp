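#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// xorshift64* PRNG: training must be bit-reproducible for a given seed on
// one thread, independently of R's RNG state.
static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Train word vectors by CBOW (algorithm = 0) or skip-gram (1) with negative
// sampling. docs holds 1-based vocabulary ids; counts the vocab frequencies
// used to build the unigram^0.75 noise distribution. Single-threaded.
// [[Rcpp::export]]
NumericMatrix w2v_train(List docs, NumericVector counts, int dim, int window,
                        int epochs, int negative, double alpha0,
                        int algorithm, double sample, double seed) {
  const int V = counts.size();
  if (V < 1) stop("empty vocabulary");
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  // input vectors: small random init; output (context) vectors: zeros
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(V);
  double tot = 0.0;
  for (int i = 0; i < V; ++i) { tot += std::pow(counts[i], 0.75); cum[i] = tot; }

  // pre-extract documents
  const int D = docs.size();
  std::vector<std::vector<int>> dv(D);
  long long n_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    dv[d].assign(doc.begin(), doc.end());
    n_tokens += doc.size();
  }
  const double total_steps = (double)n_tokens * epochs;
  if (total_steps <= 0) stop("no trainable tokens");

  // keep-probability for frequent-word subsampling (word2vec formula)
  double corpus_total = 0.0;
  for (int i = 0; i < V; ++i) corpus_total += counts[i];
  std::vector<double> keep(V, 1.0);
  if (sample > 0) {
    for (int i = 0; i < V; ++i) {
      double f = counts[i] / corpus_total;
      double p = std::sqrt(sample / f) + sample / f;
      keep[i] = p < 1.0 ? p : 1.0;
    }
  }

  std::vector<double> neu1(dim), neu1e(dim);
  std::vector<int> sen;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < D; ++d) {
      // subsample frequent words when materialising the sentence
      sen.clear();
      for (int w : dv[d]) {
        if (keep[w - 1] >= 1.0 || runif01(rng) < keep[w - 1]) sen.push_back(w);
      }
      const std::vector<int> &doc = sen;
      const int n = (int)doc.size();
      for (int t = 0; t < n; ++t) {
        double alpha = alpha0 * (1.0 - processed / (total_steps + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int center = doc[t] - 1;
        // reduced window, as in the reference implementation
        const int cw = 1 + (int)(xorshift64(rng) % (uint64_t)window);
        const int lo = std::max(0, t - cw), hi = std::min(n - 1, t + cw);

        if (algorithm == 0) {          // CBOW: mean of context predicts center
          int cn = 0;
          std::fill(neu1.begin(), neu1.end(), 0.0);
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            const double *v = &syn0[(size_t)(doc[j] - 1) * dim];
            for (int k = 0; k < dim; ++k) neu1[k] += v[k];
            ++cn;
          }
          if (cn == 0) continue;
          for (int k = 0; k < dim; ++k) neu1[k] /= cn;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int s = 0; s <= negative; ++s) {
            int target; double label;
            if (s == 0) { target = center; label = 1.0; }
            else {
              double u = runif01(rng) * tot;
              target = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= V) target = V - 1;
              if (target == center) continue;
              label = 0.0;
            }
            double *w = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += neu1[k] * w[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) { neu1e[k] += g * w[k]; w[k] += g * neu1[k]; }
          }
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            double *v = &syn0[(size_t)(doc[j] - 1) * dim];
            for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
          }
        } else {                       // skip-gram: each context predicts center
          for (int j = lo; j <= hi; ++j) {
            if (j == t) continue;
            double *v = &syn0[(size_t)(doc[j] - 1) * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int s = 0; s <= negative; ++s) {
              int target; double label;
              if (s == 0) { target = center; label = 1.0; }
              else {
                double u = runif01(rng) * tot;
                target = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
                if (target >= V) target = V - 1;
                if (target == center) continue;
                label = 0.0;
              }
              double *w = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int k = 0; k < dim; ++k) f += v[k] * w[k];
              const double g = (label - sigmoid(f)) * alpha;
              for (int k = 0; k < dim; ++k) { neu1e[k] += g * w[k]; w[k] += g * v[k]; }
            }
            for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
          }
        }
      }
      processed += (double)dv[d].size();
    }
  }

  NumericMatrix out(V, dim), ctx(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k) {
      out(i, k) = syn0[(size_t)i * dim + k];
      ctx(i, k) = syn1[(size_t)i * dim + k];
    }
  out.attr("context") = ctx;
  return out;
}
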