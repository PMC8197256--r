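// Continuous bag-of-words word2vec with negative sampling, single thread,
// deterministic given the seed (own xorshift64* RNG, no global state).
// Sentences arrive as 0-based token-id integer vectors.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static inline uint64_t xs64(uint64_t& s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s * 2685821657736338717ULL;
}
static inline double urand(uint64_t& s) {
  return (xs64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double fast_sigmoid(double x) {
  if (x > 12.0) return 1.0;
  if (x < -12.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
arma::mat cbow_train_cpp(List sentences, int vocabSize, int dim, int window,
                         int epochs, int negative, double alpha0, int seed,
                         arma::vec counts) {
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  xs64(rng); xs64(rng);

  // unigram^(3/4) table for negative sampling (cumulative, binary search)
  vec cum = cumsum(pow(counts, 0.75));
  const double ctot = cum(cum.n_elem - 1);

  mat Win(dim, vocabSize), Wout(dim, vocabSize, fill::zeros);
  for (uword j = 0; j < Win.n_cols; ++j)
    for (int i = 0; i < dim; ++i)
      Win(i, j) = (urand(rng) - 0.5) / dim;

  const int nSent = sentences.size();
  double totalWords = 0;
  std::vector<IntegerVector> sv;
  sv.reserve(nSent);
  for (int s = 0; s < nSent; ++s) {
    sv.push_back(as<IntegerVector>(sentences[s]));
    totalWords += sv[s].size();
  }
  totalWords *= epochs;

  vec h(dim), neu1e(dim);
  double processed = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nSent; ++s) {
      const IntegerVector& sent = sv[s];
      const int L = sent.size();
      for (int t = 0; t < L; ++t) {
        processed += 1.0;
        double alpha = alpha0 * (1.0 - processed / (totalWords + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int lo = std::max(0, t - window), hi = std::min(L - 1, t + window);
        int nctx = 0;
        h.zeros();
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          h += Win.col(sent[c]);
          ++nctx;
        }
        if (nctx == 0) continue;
        h /= nctx;
        neu1e.zeros();
        const int target = sent[t];
        for (int d = 0; d <= negative; ++d) {
          int w; double label;
          if (d == 0) { w = target; label = 1.0; }
          else {
            // sample from the unigram^(3/4) table, rejecting the target
            // (bounded retries: a single-token vocabulary has no valid
            // negative, in which case the draw is skipped)
            if (vocabSize < 2) continue;
            w = target;
            for (int tries = 0; tries < 32 && w == target; ++tries) {
              double u = urand(rng) * ctot;
              uword loi = 0, hii = cum.n_elem - 1;
              while (loi < hii) {
                uword mid = (loi + hii) / 2;
                if (cum(mid) < u) loi = mid + 1; else hii = mid;
              }
              w = (int)loi;
            }
            if (w == target) continue;
            label = 0.0;
          }
          const double f = fast_sigmoid(dot(Wout.col(w), h));
          const double g = (label - f) * alpha;
          neu1e += g * Wout.col(w);
          Wout.col(w) += g * h;
        }
        neu1e /= nctx;
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          Win.col(sent[c]) += neu1e;
        }
      }
    }
  }
  return Win.t();   // (vocab x dim)
}
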