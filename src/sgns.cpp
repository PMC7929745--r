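// Skip-gram with negative sampling over a doubled input layer: every word
// owns two input (center) vectors, one per corpus, while the output (context)
// vectors are shared, so the two embeddings of a word live in one comparable
// space. Single-threaded with its own xorshift RNG: results are bit-exact
// reproducible for a given seed.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t xs_next(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double xs_unif(uint64_t &s) {
  return (xs_next(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
List sgns_train_dual_cpp(IntegerVector tokens, IntegerVector sent_corpus,
                         IntegerVector sent_len, int vocab_size, int dim,
                         int window, int negative, int epochs, double alpha,
                         NumericVector unigram_cdf, int seed) {
  const int V = vocab_size;
  std::vector<double> in(2L * (size_t)V * dim);
  std::vector<double> out((size_t)V * dim, 0.0);
  std::vector<double> cdf(unigram_cdf.begin(), unigram_cdf.end());

  uint64_t rng = (uint64_t)seed * 2862933555777941757ULL + 3037000493ULL;
  for (size_t i = 0; i < in.size(); ++i) {
    in[i] = (xs_unif(rng) - 0.5) / dim;
  }

  // flatten sentence offsets
  const int n_sent = sent_len.size();
  std::vector<long long> offset(n_sent + 1, 0);
  for (int s = 0; s < n_sent; ++s) offset[s + 1] = offset[s] + sent_len[s];
  const double total_words = (double)offset[n_sent] * epochs;

  NumericVector epoch_loss(epochs);
  std::vector<double> neu1e(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0;
    long long n_pairs = 0;
    for (int s = 0; s < n_sent; ++s) {
      const int corp = sent_corpus[s];
      const long long a = offset[s], b = offset[s + 1];
      for (long long i = a; i < b; ++i) {
        ++processed;
        double lr = alpha * (1.0 - processed / (total_words + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        const int center = tokens[i];
        const size_t crow = ((size_t)corp * V + center) * dim;
        const int red = (int)(xs_next(rng) % (uint64_t)window);
        for (long long j = i - window + red; j <= i + window - red; ++j) {
          if (j == i || j < a || j >= b) continue;
          const int ctx = tokens[j];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = ctx;
              label = 1.0;
            } else {
              const double u = xs_unif(rng);
              target = (int)(std::lower_bound(cdf.begin(), cdf.end(), u) -
                             cdf.begin());
              if (target >= V) target = V - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            const size_t orow = (size_t)target * dim;
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += in[crow + k] * out[orow + k];
            const double p = sigmoid(f);
            loss -= label > 0.5 ? std::log(p + 1e-12)
                                : std::log(1.0 - p + 1e-12);
            const double g = (label - p) * lr;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += g * out[orow + k];
              out[orow + k] += g * in[crow + k];
            }
          }
          for (int k = 0; k < dim; ++k) in[crow + k] += neu1e[k];
          ++n_pairs;
        }
      }
    }
    epoch_loss[ep] = n_pairs > 0 ? loss / n_pairs : 0.0;
  }

  NumericMatrix in_mat(2 * V, dim), out_mat(V, dim);
  for (int r = 0; r < 2 * V; ++r) {
    for (int k = 0; k < dim; ++k) in_mat(r, k) = in[(size_t)r * dim + k];
  }
  for (int r = 0; r < V; ++r) {
    for (int k = 0; k < dim; ++k) out_mat(r, k) = out[(size_t)r * dim + k];
  }
  return List::create(_["input"] = in_mat, _["output"] = out_mat,
                      _["epoch_loss"] = epoch_loss);
}
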