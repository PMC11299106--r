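#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Deterministic 64-bit RNG (splitmix-seeded xorshift), independent of R's RNG
// so that embedding training is bit-reproducible given its seed regardless of
// the caller's RNG state.
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) { uint64_t t = seed; s = splitmix64(t); if (s == 0) s = 0x2545F4914F6CDD1DULL; }
  inline uint64_t next() {
    uint64_t x = s;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    s = x;
    return x;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static const int SIGMOID_TABLE_SIZE = 1024;
static const double MAX_SIGMOID = 6.0;

// Skip-gram with negative sampling (classic word2vec update rules):
// sentences are 0-based token-id vectors; returns the input-layer vectors.
// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha0, double seed) {
  if (vocab_size < 1) stop("empty vocabulary");
  std::vector<double> sigmoid(SIGMOID_TABLE_SIZE);
  for (int i = 0; i < SIGMOID_TABLE_SIZE; i++) {
    double x = (2.0 * MAX_SIGMOID * i) / (SIGMOID_TABLE_SIZE - 1) - MAX_SIGMOID;
    sigmoid[i] = 1.0 / (1.0 + std::exp(-x));
  }
  auto sigm = [&](double x) {
    if (x >= MAX_SIGMOID) return 1.0;
    if (x <= -MAX_SIGMOID) return 0.0;
    int i = (int)((x + MAX_SIGMOID) * (SIGMOID_TABLE_SIZE - 1) / (2.0 * MAX_SIGMOID));
    return sigmoid[i];
  };

  // unigram^0.75 negative-sampling table
  const int table_size = 1 << 20;
  std::vector<int> neg_table(table_size);
  {
    double total = 0.0;
    std::vector<double> pw(vocab_size);
    for (int v = 0; v < vocab_size; v++) { pw[v] = std::pow(counts[v], 0.75); total += pw[v]; }
    int v = 0;
    double cum = pw[0] / total;
    for (int i = 0; i < table_size; i++) {
      neg_table[i] = v;
      if ((i + 1.0) / table_size > cum && v < vocab_size - 1) {
        v++;
        cum += pw[v] / total;
      }
    }
  }

  // single precision in the hot loop (the standard choice for this model);
  // flat buffers avoid any R object access inside training
  XRng rng((uint64_t)seed);
  std::vector<float> syn0((size_t)vocab_size * dim);
  std::vector<float> syn1((size_t)vocab_size * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); i++)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  long long total_words = 0;
  int n_sent = sentences.size();
  std::vector<std::vector<int> > sents(n_sent);
  for (int s = 0; s < n_sent; s++) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    total_words += sents[s].size();
  }
  total_words *= epochs;
  if (total_words == 0) stop("empty corpus");

  std::vector<float> neu1e(dim);
  long long processed = 0;
  const double alpha_min = alpha0 * 1e-4;

  for (int ep = 0; ep < epochs; ep++) {
    for (int s = 0; s < n_sent; s++) {
      const std::vector<int> &sent = sents[s];
      int slen = (int)sent.size();
      for (int pos = 0; pos < slen; pos++) {
        processed++;
        double alpha = alpha0 * (1.0 - (double)processed / (total_words + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        const float alphaf = (float)alpha;
        int w = sent[pos];
        // dynamic window: effective half-width uniform in 1..window
        int b = 1 + (int)(rng.next() % (uint64_t)window);
        int lo = pos - b; if (lo < 0) lo = 0;
        int hi = pos + b; if (hi > slen - 1) hi = slen - 1;
        float *const v_in = &syn0[(size_t)w * dim];
        for (int cpos = lo; cpos <= hi; cpos++) {
          if (cpos == pos) continue;
          int target_pos = sent[cpos];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int d = 0; d < negative + 1; d++) {
            int target; float label;
            if (d == 0) { target = target_pos; label = 1.0f; }
            else {
              target = neg_table[rng.next() % (uint64_t)table_size];
              if (target == target_pos) continue;
              label = 0.0f;
            }
            float *const v_out = &syn1[(size_t)target * dim];
            float f = 0.0f;
            for (int j = 0; j < dim; j++) f += v_in[j] * v_out[j];
            float g = (label - (float)sigm((double)f)) * alphaf;
            for (int j = 0; j < dim; j++) neu1e[j] += g * v_out[j];
            for (int j = 0; j < dim; j++) v_out[j] += g * v_in[j];
          }
          for (int j = 0; j < dim; j++) v_in[j] += neu1e[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; v++)
    for (int j = 0; j < dim; j++) out(v, j) = syn0[(size_t)v * dim + j];
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Overlapping k-mer windows as 0-based integer ids in {0, ..., 4^k - 1};
// windows containing a non-ACGT character are dropped.
// [[Rcpp::export(name = ".tokenize_ids")]]
List tokenize_ids(CharacterVector seqs, int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int n = seqs.size();
  List out(n);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)LENGTH(STRING_ELT(seqs, i));
    std::vector<int> ids;
    if (L >= k) ids.reserve(L - k + 1);
    uint32_t id = 0;
    int run = 0;
    for (int p = 0; p < L; p++) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; id = 0; continue; }
      id = ((id << 2) | (uint32_t)c) & mask;
      run++;
      if (run >= k) ids.push_back((int)id);
    }
    out[i] = IntegerVector(ids.begin(), ids.end());
  }
  return out;
}

// Mean k-mer word vector per sequence. row_of_token maps a 0-based token id
// to a 1-based row of emb (0 = out of vocabulary). Sequences with no usable
// token get an NA row; n_tokens reports usable token counts.
// [[Rcpp::export(name = ".featurize_batch")]]
List featurize_batch(CharacterVector seqs, NumericMatrix emb,
                     IntegerVector row_of_token, int k) {
  const uint32_t mask = (1u << (2 * k)) - 1u;
  int n = seqs.size(), dim = emb.ncol();
  NumericMatrix feats(n, dim);
  IntegerVector n_tokens(n);
  std::vector<double> acc(dim);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)LENGTH(STRING_ELT(seqs, i));
    std::fill(acc.begin(), acc.end(), 0.0);
    int cnt = 0;
    uint32_t id = 0;
    int run = 0;
    for (int p = 0; p < L; p++) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; id = 0; continue; }
      id = ((id << 2) | (uint32_t)c) & mask;
      run++;
      if (run >= k) {
        int row = row_of_token[id];
        if (row > 0) {
          for (int j = 0; j < dim; j++) acc[j] += emb(row - 1, j);
          cnt++;
        }
      }
    }
    n_tokens[i] = cnt;
    if (cnt > 0) for (int j = 0; j < dim; j++) feats(i, j) = acc[j] / cnt;
    else for (int j = 0; j < dim; j++) feats(i, j) = NA_REAL;
  }
  return List::create(_["features"] = feats, _["n_tokens"] = n_tokens);
}

// First-order Markov chain sequence simulator. trans is a row-stochastic
// 4x4 matrix over A,C,G,T; init a length-4 start distribution. Deterministic
// given seed.
// [[Rcpp::export(name = ".markov_generate")]]
CharacterVector markov_generate(NumericMatrix trans, NumericVector init,
                                IntegerVector lengths, double seed) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  XRng rng((uint64_t)seed);
  int n = lengths.size();
  // cumulative rows
  double cum_init[4], cum[4][4];
  double c0 = 0;
  for (int j = 0; j < 4; j++) { c0 += init[j]; cum_init[j] = c0; }
  for (int i = 0; i < 4; i++) {
    double c = 0;
    for (int j = 0; j < 4; j++) { c += trans(i, j); cum[i][j] = c; }
  }
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; i++) {
    int L = lengths[i];
    if (L < 1) stop("lengths must be positive");
    buf.assign(L, 'A');
    double u = rng.unif() * cum_init[3];
    int state = 0;
    while (state < 3 && u > cum_init[state]) state++;
    buf[0] = bases[state];
    for (int p = 1; p < L; p++) {
      u = rng.unif() * cum[state][3];
      int nxt = 0;
      while (nxt < 3 && u > cum[state][nxt]) nxt++;
      state = nxt;
      buf[p] = bases[state];
    }
    out[i] = buf;
  }
  return out;
}
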