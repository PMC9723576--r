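// Minimal CBOW word-embedding trainer with negative sampling.
// Single-threaded and driven by its own xorshift RNG so that training is a
// pure function of (corpus, parameters, seed).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of integer vectors of 1-based word ids (0 entries removed
// upstream); counts: per-id corpus frequencies used for the unigram^0.75
// negative-sampling distribution.
// [[Rcpp::export(rng = false)]]
NumericMatrix cbow_train_cpp(List sentences, int vocab_size, NumericVector counts,
                             int dim, int window, int epochs, int negative,
                             double alpha0, int seed) {
  uint64_t rng = (uint64_t)seed * 2654435761u + 1442695040888963407ull;
  for (int k = 0; k < 10; ++k) xorshift64(rng);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (runif01(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling (binary search)
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int w = 0; w < vocab_size; ++w) {
    tot += std::pow(std::max(counts[w], 1.0), 0.75);
    cum[w] = tot;
  }
  auto draw_neg = [&]() {
    double u = runif01(rng) * tot;
    int lo = 0, hi = vocab_size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  long long total_words = 0;
  int n_sent = sentences.size();
  std::vector<std::vector<int>> sent(n_sent);
  for (int si = 0; si < n_sent; ++si) {
    IntegerVector v = sentences[si];
    sent[si].assign(v.begin(), v.end());
    total_words += v.size();
  }
  long long train_total = total_words * (long long)epochs;
  long long processed = 0;

  std::vector<double> neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < n_sent; ++si) {
      const std::vector<int> &s = sent[si];
      int n = (int)s.size();
      for (int pos = 0; pos < n; ++pos) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)(train_total + 1));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        ++processed;
        int target = s[pos] - 1;
        int lo = pos - window; if (lo < 0) lo = 0;
        int hi = pos + window; if (hi > n - 1) hi = n - 1;
        int cw = 0;
        std::fill(neu1.begin(), neu1.end(), 0.0);
        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        for (int p2 = lo; p2 <= hi; ++p2) {
          if (p2 == pos) continue;
          const double *v = &syn0[(size_t)(s[p2] - 1) * dim];
          for (int d = 0; d < dim; ++d) neu1[d] += v[d];
          ++cw;
        }
        if (cw == 0) continue;
        for (int d = 0; d < dim; ++d) neu1[d] /= cw;
        for (int k = 0; k <= negative; ++k) {
          int out;
          double label;
          if (k == 0) { out = target; label = 1.0; }
          else {
            out = draw_neg();
            if (out == target) continue;
            label = 0.0;
          }
          double *o = &syn1[(size_t)out * dim];
          double f = 0.0;
          for (int d = 0; d < dim; ++d) f += neu1[d] * o[d];
          double g = (label - sigmoid(f)) * alpha;
          for (int d = 0; d < dim; ++d) { neu1e[d] += g * o[d]; o[d] += g * neu1[d]; }
        }
        for (int p2 = lo; p2 <= hi; ++p2) {
          if (p2 == pos) continue;
          double *v = &syn0[(size_t)(s[p2] - 1) * dim];
          for (int d = 0; d < dim; ++d) v[d] += neu1e[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = syn0[(size_t)w * dim + d];
  return out;
}
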