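// Skip-gram training for DeepWalk node embeddings: hierarchical softmax over
// a Huffman tree built from corpus node frequencies (default), or negative
// sampling. Single-threaded SGD with a self-contained xorshift RNG so results
// are bit-reproducible for a given seed, independent of R's RNG stream.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline std::uint64_t xorshift64(std::uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s * 2685821657736338717ULL;
}
static inline double unif01(std::uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);
}
static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// word2vec-style Huffman coding: vocab sorted by count descending (node id
// ascending on ties, for determinism); code/point per vocab word.
struct HuffmanTree {
  std::vector<std::vector<int> > point;   // inner-node indices, root first
  std::vector<std::vector<char> > code;   // 0/1 branch labels
};

static HuffmanTree build_huffman(const std::vector<long long> &counts_in) {
  const int V = (int)counts_in.size();
  HuffmanTree ht;
  ht.point.resize(V);
  ht.code.resize(V);
  if (V == 1) return ht;  // single word: empty path, Pr = 1
  // internal nodes start at an "infinite" count so they are never picked
  // before both children exist
  std::vector<long long> count(2 * V - 1, (long long)1e15);
  std::vector<int> parent(2 * V - 1, 0), binary(2 * V - 1, 0);
  for (int i = 0; i < V; ++i) count[i] = counts_in[i];
  // vocab is sorted by count descending, so leaves run V-1..0 ascending
  int pos1 = V - 1, pos2 = V;
  for (int a = 0; a < V - 1; ++a) {
    int m1, m2;
    if (pos1 >= 0 && (pos2 >= 2 * V - 1 || count[pos1] < count[pos2]))
      m1 = pos1--;
    else m1 = pos2++;
    if (pos1 >= 0 && (pos2 >= 2 * V - 1 || count[pos1] < count[pos2]))
      m2 = pos1--;
    else m2 = pos2++;
    count[V + a] = count[m1] + count[m2];
    parent[m1] = V + a;
    parent[m2] = V + a;
    binary[m2] = 1;
  }
  for (int a = 0; a < V; ++a) {
    std::vector<int> pt;
    std::vector<char> cd;
    int b = a;
    while (b != 2 * V - 2) {
      cd.push_back((char)binary[b]);
      pt.push_back(parent[b] - V);  // inner-node index in 0..V-2
      b = parent[b];
    }
    std::reverse(pt.begin(), pt.end());
    std::reverse(cd.begin(), cd.end());
    ht.point[a] = pt;
    ht.code[a] = cd;
  }
  return ht;
}

// [[Rcpp::export]]
List cpp_train_skipgram(List walks, int n_nodes, int dim, int window,
                        double alpha0, int seed, bool hs, int negative,
                        int passes, bool eval_objective) {
  const int N = n_nodes;
  std::vector<std::vector<int> > W(walks.size());
  std::vector<long long> count(N, 0);
  long long total_pairs = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    W[i].assign(w.begin(), w.end());
    const int t = (int)W[i].size();
    for (int j = 0; j < t; ++j) {
      if (W[i][j] < 0 || W[i][j] >= N) stop("walk node index out of range");
      count[W[i][j]]++;
      int lo = std::max(0, j - window), hi = std::min(t - 1, j + window);
      total_pairs += hi - lo;  // window size minus the center itself
    }
  }
  if (total_pairs == 0) stop("nothing to train on: no context pairs");

  // vocab: nodes with count > 0, sorted by count desc then id asc
  std::vector<int> vocab;
  for (int v = 0; v < N; ++v) if (count[v] > 0) vocab.push_back(v);
  std::sort(vocab.begin(), vocab.end(), [&](int a, int b) {
    if (count[a] != count[b]) return count[a] > count[b];
    return a < b;
  });
  const int V = (int)vocab.size();
  std::vector<int> vindex(N, -1);
  std::vector<long long> vcount(V);
  for (int i = 0; i < V; ++i) { vindex[vocab[i]] = i; vcount[i] = count[vocab[i]]; }

  HuffmanTree ht;
  if (hs) ht = build_huffman(vcount);

  // negative-sampling cumulative table over unigram^0.75
  std::vector<double> neg_cum;
  if (!hs) {
    neg_cum.resize(V);
    double acc = 0.0;
    for (int i = 0; i < V; ++i) { acc += std::pow((double)vcount[i], 0.75); neg_cum[i] = acc; }
    for (int i = 0; i < V; ++i) neg_cum[i] /= acc;
  }

  std::uint64_t rng = (std::uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  for (int k = 0; k < 8; ++k) xorshift64(rng);

  std::vector<double> syn0((size_t)N * dim, 0.0);
  for (int i = 0; i < V; ++i)
    for (int c = 0; c < dim; ++c)
      syn0[(size_t)vocab[i] * dim + c] = (unif01(rng) - 0.5) / dim;
  std::vector<double> syn1((size_t)std::max(V - 1, 1) * dim, 0.0);   // hs inner nodes
  std::vector<double> syn1neg(hs ? 1 : (size_t)V * dim, 0.0);
  std::vector<double> neu1e(dim);

  const double alpha_min = alpha0 / 100.0;
  long long processed = 0;
  const long long grand_total = total_pairs * (long long)passes;
  std::vector<double> objective;

  for (int pass = 0; pass < passes; ++pass) {
    if (eval_objective) {
      // full-corpus J = sum over pairs of -log Pr(context | psi(center)), hs only
      double J = 0.0;
      for (size_t wi = 0; wi < W.size(); ++wi) {
        const std::vector<int> &wk = W[wi];
        const int t = (int)wk.size();
        for (int j = 0; j < t; ++j) {
          const double *h = &syn0[(size_t)wk[j] * dim];
          int lo = std::max(0, j - window), hi = std::min(t - 1, j + window);
          for (int k = lo; k <= hi; ++k) {
            if (k == j) continue;
            int ctx = vindex[wk[k]];
            const std::vector<int> &pt = ht.point[ctx];
            const std::vector<char> &cd = ht.code[ctx];
            for (size_t b = 0; b < pt.size(); ++b) {
              double dot = 0.0;
              const double *s1 = &syn1[(size_t)pt[b] * dim];
              for (int c = 0; c < dim; ++c) dot += h[c] * s1[c];
              // code 0 branch has probability sigmoid(dot)
              double p = cd[b] ? sigmoid(-dot) : sigmoid(dot);
              J -= std::log(std::max(p, 1e-300));
            }
          }
        }
      }
      objective.push_back(J);
    }
    for (size_t wi = 0; wi < W.size(); ++wi) {
      const std::vector<int> &wk = W[wi];
      const int t = (int)wk.size();
      for (int j = 0; j < t; ++j) {
        double *h = &syn0[(size_t)wk[j] * dim];
        int lo = std::max(0, j - window), hi = std::min(t - 1, j + window);
        for (int k = lo; k <= hi; ++k) {
          if (k == j) continue;
          double alpha = alpha0 - (alpha0 - alpha_min) *
            ((double)processed / (double)grand_total);
          ++processed;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          int ctx = vindex[wk[k]];
          if (hs) {
            const std::vector<int> &pt = ht.point[ctx];
            const std::vector<char> &cd = ht.code[ctx];
            for (size_t b = 0; b < pt.size(); ++b) {
              double *s1 = &syn1[(size_t)pt[b] * dim];
              double dot = 0.0;
              for (int c = 0; c < dim; ++c) dot += h[c] * s1[c];
              double g = (1.0 - (double)cd[b] - sigmoid(dot)) * alpha;
              for (int c = 0; c < dim; ++c) neu1e[c] += g * s1[c];
              for (int c = 0; c < dim; ++c) s1[c] += g * h[c];
            }
          } else {
            for (int d0 = 0; d0 <= negative; ++d0) {
              int target; double label;
              if (d0 == 0) { target = ctx; label = 1.0; }
              else {
                double u = unif01(rng);
                target = (int)(std::lower_bound(neg_cum.begin(), neg_cum.end(), u)
                               - neg_cum.begin());
                if (target >= V) target = V - 1;
                if (target == ctx) continue;
                label = 0.0;
              }
              double *s1 = &syn1neg[(size_t)target * dim];
              double dot = 0.0;
              for (int c = 0; c < dim; ++c) dot += h[c] * s1[c];
              double g = (label - sigmoid(dot)) * alpha;
              for (int c = 0; c < dim; ++c) neu1e[c] += g * s1[c];
              for (int c = 0; c < dim; ++c) s1[c] += g * h[c];
            }
          }
          for (int c = 0; c < dim; ++c) h[c] += neu1e[c];
        }
      }
    }
  }
  if (eval_objective) {
    double J = 0.0;
    for (size_t wi = 0; wi < W.size(); ++wi) {
      const std::vector<int> &wk = W[wi];
      const int t = (int)wk.size();
      for (int j = 0; j < t; ++j) {
        const double *h = &syn0[(size_t)wk[j] * dim];
        int lo = std::max(0, j - window), hi = std::min(t - 1, j + window);
        for (int k = lo; k <= hi; ++k) {
          if (k == j) continue;
          int ctx = vindex[wk[k]];
          const std::vector<int> &pt = ht.point[ctx];
          const std::vector<char> &cd = ht.code[ctx];
          for (size_t b = 0; b < pt.size(); ++b) {
            double dot = 0.0;
            const double *s1 = &syn1[(size_t)pt[b] * dim];
            for (int c = 0; c < dim; ++c) dot += h[c] * s1[c];
            double p = cd[b] ? sigmoid(-dot) : sigmoid(dot);
            J -= std::log(std::max(p, 1e-300));
          }
        }
      }
    }
    objective.push_back(J);
  }

  NumericMatrix psi(N, dim);
  for (int v = 0; v < N; ++v)
    for (int c = 0; c < dim; ++c)
      psi(v, c) = syn0[(size_t)v * dim + c];
  IntegerVector cnt(N);
  for (int v = 0; v < N; ++v) cnt[v] = (int)count[v];
  return List::create(_["psi"] = psi, _["count"] = cnt,
                      _["objective"] = wrap(objective));
}
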