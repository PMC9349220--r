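// Negative-sampling embedding core: distributed bag-of-words document
// vectors (one trainable vector per document predicting its tokens) and a
// skip-gram word-vector trainer for the averaging mode. Single-threaded and
// driven by an internal xorshift RNG so training is bitwise reproducible at
// a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

const int kTableSize = 100000;

// word2vec-style unigram^0.75 negative-sampling table
std::vector<int> build_table(const NumericVector& counts) {
  int vocab = counts.size();
  std::vector<int> table(kTableSize);
  double total = 0.0;
  for (int i = 0; i < vocab; ++i) total += std::pow(counts[i], 0.75);
  int idx = 0;
  double cum = std::pow(counts[0], 0.75) / total;
  for (int a = 0; a < kTableSize; ++a) {
    table[a] = idx;
    if (static_cast<double>(a) / kTableSize > cum && idx < vocab - 1) {
      ++idx;
      cum += std::pow(counts[idx], 0.75) / total;
    }
  }
  return table;
}

double sigmoid(double x) {
  if (x > 6.0) x = 6.0;
  if (x < -6.0) x = -6.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// One negative-sampling update of `vec` against output rows of `out`,
// positive target plus `neg` sampled noise words.
void ns_update(std::vector<double>& vec, std::vector<double>& out, int dim,
               int target, int neg, const std::vector<int>& table,
               XorShift& rng, double lr, bool update_out) {
  std::vector<double> grad(dim, 0.0);
  for (int d = 0; d < neg + 1; ++d) {
    int tgt;
    double label;
    if (d == 0) {
      tgt = target;
      label = 1.0;
    } else {
      tgt = table[rng.below(kTableSize)];
      if (tgt == target) continue;
      label = 0.0;
    }
    double* o = &out[static_cast<size_t>(tgt) * dim];
    double f = 0.0;
    for (int k = 0; k < dim; ++k) f += vec[k] * o[k];
    double g = (label - sigmoid(f)) * lr;
    for (int k = 0; k < dim; ++k) grad[k] += g * o[k];
    if (update_out)
      for (int k = 0; k < dim; ++k) o[k] += g * vec[k];
  }
  for (int k = 0; k < dim; ++k) vec[k] += grad[k];
}

long long total_tokens(const List& docs) {
  long long n = 0;
  for (int i = 0; i < docs.size(); ++i) n += as<IntegerVector>(docs[i]).size();
  return n;
}

}  // namespace

// Train one document vector per document against a shared output word
// matrix (distributed bag of words with negative sampling).
// docs: list of 0-based token-id vectors; counts: vocab token counts.
// [[Rcpp::export(name = ".cpp_dbow_train")]]
List cpp_dbow_train(List docs, NumericVector counts, int dim, int neg,
                    int epochs, double lr0, double seed) {
  int n_docs = docs.size();
  int vocab = counts.size();
  XorShift rng(static_cast<uint64_t>(seed));
  std::vector<int> table = build_table(counts);

  std::vector<std::vector<double>> dvec(n_docs, std::vector<double>(dim));
  for (int i = 0; i < n_docs; ++i)
    for (int k = 0; k < dim; ++k)
      dvec[i][k] = (rng.unif() - 0.5) / dim;
  std::vector<double> wout(static_cast<size_t>(vocab) * dim, 0.0);

  long long total = total_tokens(docs) * static_cast<long long>(epochs);
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_docs; ++i) {
      IntegerVector doc = docs[i];
      for (int p = 0; p < doc.size(); ++p) {
        double lr = lr0 * (1.0 - static_cast<double>(done) / (total + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ns_update(dvec[i], wout, dim, doc[p], neg, table, rng, lr, true);
        ++done;
      }
    }
  }

  NumericMatrix D(n_docs, dim), W(vocab, dim);
  for (int i = 0; i < n_docs; ++i)
    for (int k = 0; k < dim; ++k) D(i, k) = dvec[i][k];
  for (int w = 0; w < vocab; ++w)
    for (int k = 0; k < dim; ++k) W(w, k) = wout[static_cast<size_t>(w) * dim + k];
  return List::create(_["doc_vectors"] = D, _["w_out"] = W);
}

// Infer a vector for a new document against a frozen output matrix.
// [[Rcpp::export(name = ".cpp_dbow_infer")]]
NumericVector cpp_dbow_infer(IntegerVector doc, NumericMatrix w_out,
                             NumericVector counts, int neg, int epochs,
                             double lr0, double seed) {
  int dim = w_out.ncol();
  int vocab = w_out.nrow();
  XorShift rng(static_cast<uint64_t>(seed));
  std::vector<int> table = build_table(counts);
  std::vector<double> wout(static_cast<size_t>(vocab) * dim);
  for (int w = 0; w < vocab; ++w)
    for (int k = 0; k < dim; ++k) wout[static_cast<size_t>(w) * dim + k] = w_out(w, k);

  std::vector<double> vec(dim);
  for (int k = 0; k < dim; ++k) vec[k] = (rng.unif() - 0.5) / dim;
  long long total = static_cast<long long>(doc.size()) * epochs;
  long long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int p = 0; p < doc.size(); ++p) {
      double lr = lr0 * (1.0 - static_cast<double>(done) / (total + 1));
      if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
      ns_update(vec, wout, dim, doc[p], neg, table, rng, lr, false);
      ++done;
    }
  }
  return NumericVector(vec.begin(), vec.end());
}

// Skip-gram word vectors with negative sampling (averaging mode).
// [[Rcpp::export(name = ".cpp_skipgram_train")]]
NumericMatrix cpp_skipgram_train(List docs, NumericVector counts, int dim,
                                 int neg, int epochs, int window, double lr0,
                                 double seed) {
  int vocab = counts.size();
  XorShift rng(static_cast<uint64_t>(seed));
  std::vector<int> table = build_table(counts);

  std::vector<double> win(static_cast<size_t>(vocab) * dim);
  for (size_t j = 0; j < win.size(); ++j) win[j] = (rng.unif() - 0.5) / dim;
  std::vector<double> wout(static_cast<size_t>(vocab) * dim, 0.0);

  long long total = total_tokens(docs) * static_cast<long long>(epochs);
  long long done = 0;
  std::vector<double> ctx(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < docs.size(); ++i) {
      IntegerVector doc = docs[i];
      int len = doc.size();
      for (int p = 0; p < len; ++p) {
        double lr = lr0 * (1.0 - static_cast<double>(done) / (total + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        int b = rng.below(window) + 1;  // shrunk window, word2vec style
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int q = p + off;
          if (q < 0 || q >= len) continue;
          double* v = &win[static_cast<size_t>(doc[q]) * dim];
          std::copy(v, v + dim, ctx.begin());
          ns_update(ctx, wout, dim, doc[p], neg, table, rng, lr, true);
          std::copy(ctx.begin(), ctx.end(), v);
        }
        ++done;
      }
    }
  }
  NumericMatrix W(vocab, dim);
  for (int w = 0; w < vocab; ++w)
    for (int k = 0; k < dim; ++k) W(w, k) = win[static_cast<size_t>(w) * dim + k];
  return W;
}
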