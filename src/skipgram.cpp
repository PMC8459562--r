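#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Deterministic 64-bit LCG (single-threaded training keeps runs identical
// for a fixed seed regardless of R's RNG state).
static inline unsigned long long nextRand(unsigned long long &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return state;
}

static inline double uniform01(unsigned long long &state) {
  return (double)(nextRand(state) >> 11) / 9007199254740992.0; // 2^53
}

// Skip-gram with negative sampling over random-walk sentences.
// walks: list of integer vectors with 1-based node indices.
// Returns an nNodes x dim matrix (rows for nodes absent from the corpus
// stay at their random initialisation; the caller drops them).
// [[Rcpp::export(name = ".skipgramTrain")]]
NumericMatrix skipgramTrain(List walks, int nNodes, int dim, int window,
                            int epochs, int negative, double alpha0,
                            double minAlpha, int seed) {
  if (nNodes <= 0 || dim <= 0) stop("invalid dimensions");
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  long long nTokens = 0;
  std::vector<double> freq(nNodes, 0.0);
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> cw(w.size());
    for (R_xlen_t j = 0; j < w.size(); ++j) {
      int v = w[j] - 1;
      if (v < 0 || v >= nNodes) stop("walk token out of range");
      cw[j] = v;
      freq[v] += 1.0;
    }
    nTokens += cw.size();
    corpus.push_back(std::move(cw));
  }
  if (nTokens == 0) stop("empty walk corpus");

  // unigram^0.75 table for negative sampling (word2vec convention)
  const int tableSize = 100000;
  std::vector<int> unigram(tableSize);
  double z = 0.0;
  for (int v = 0; v < nNodes; ++v) z += std::pow(freq[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int t = 0; t < tableSize; ++t) {
      unigram[t] = v;
      if ((double)t / tableSize > cum && v < nNodes - 1) {
        ++v;
        cum += std::pow(freq[v], 0.75) / z;
      }
    }
  }

  unsigned long long rng = (unsigned long long)seed * 2654435761ULL + 1ULL;
  std::vector<double> syn0((size_t)nNodes * dim);
  std::vector<double> syn1((size_t)nNodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (uniform01(rng) - 0.5) / dim;

  std::vector<double> grad(dim);
  long long total = nTokens * (long long)epochs;
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < corpus.size(); ++s) {
      const std::vector<int> &walk = corpus[s];
      int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)(total + 1));
        if (alpha < minAlpha) alpha = minAlpha;
        ++processed;
        int center = walk[pos];
        int lo = pos - window; if (lo < 0) lo = 0;
        int hi = pos + window; if (hi > len - 1) hi = len - 1;
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int context = walk[cpos];
          double *v0 = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int tgt; double label;
            if (neg == 0) { tgt = context; label = 1.0; }
            else {
              // high bits only: the low bits of a power-of-two LCG cycle
              tgt = unigram[(int)((nextRand(rng) >> 33) % tableSize)];
              if (tgt == context) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)tgt * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v0[k] * v1[k];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * alpha;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v1[k];
              v1[k] += g * v0[k];
            }
          }
          for (int k = 0; k < dim; ++k) v0[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(nNodes, dim);
  for (int v = 0; v < nNodes; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
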