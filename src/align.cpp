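#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (free end gap) alignment with unit scores: match +1,
// mismatch -1, gap -1; terminal gaps free on both sequences.
//
// Identity is matches / max(columns, min(la, lb)) where `columns` are the
// aligned columns of one optimal-score alignment (terminal gaps
// excluded); flooring the denominator at the shorter length keeps a
// degenerate short perfect overlap from counting as full identity.

// fast score-only DP (two rows, reusable buffers)
static int sg_score(const char *a, int la, const char *b, int lb,
                    std::vector<int> &prev, std::vector<int> &cur) {
  if ((int)prev.size() < lb + 1) { prev.resize(lb + 1); cur.resize(lb + 1); }
  for (int j = 0; j <= lb; ++j) prev[j] = 0;
  int best = 0;  // empty alignment is admissible under free end gaps
  for (int i = 1; i <= la; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int v = prev[j - 1] + ((ai == b[j - 1]) ? 1 : -1);
      const int up = prev[j] - 1;
      if (up > v) v = up;
      const int left = cur[j - 1] - 1;
      if (left > v) v = left;
      cur[j] = v;
    }
    if (cur[lb] > best) best = cur[lb];  // free end gap in b
    std::swap(prev, cur);
  }
  for (int j = 0; j <= lb; ++j) {
    if (prev[j] > best) best = prev[j];  // free end gap in a
  }
  return best;
}

// full DP with traceback; ties resolved deterministically (endpoint:
// bottom-right-most maximal cell; traceback preference diag, up, left)
static void sg_align(const std::string &a, const std::string &b,
                     int &score, int &matches, int &cols) {
  const int la = a.size(), lb = b.size();
  std::vector<int> H((la + 1) * (lb + 1), 0);
  std::vector<unsigned char> tb((la + 1) * (lb + 1), 0);
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int sub = (a[i - 1] == b[j - 1]) ? 1 : -1;
      int best = H[(i - 1) * (lb + 1) + j - 1] + sub;
      unsigned char dir = 1;
      if (H[(i - 1) * (lb + 1) + j] - 1 > best) {
        best = H[(i - 1) * (lb + 1) + j] - 1; dir = 2;
      }
      if (H[i * (lb + 1) + j - 1] - 1 > best) {
        best = H[i * (lb + 1) + j - 1] - 1; dir = 3;
      }
      H[i * (lb + 1) + j] = best;
      tb[i * (lb + 1) + j] = dir;
    }
  }
  int bi = la, bj = lb, bs = H[la * (lb + 1) + lb];
  for (int j = lb; j >= 0; --j) {
    if (H[la * (lb + 1) + j] > bs) {
      bs = H[la * (lb + 1) + j]; bi = la; bj = j;
    }
  }
  for (int i = la; i >= 0; --i) {
    if (H[i * (lb + 1) + lb] > bs) {
      bs = H[i * (lb + 1) + lb]; bi = i; bj = lb;
    }
  }
  score = bs;
  matches = 0;
  cols = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const unsigned char dir = tb[i * (lb + 1) + j];
    if (dir == 1) {
      ++cols;
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 2) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
}

// [[Rcpp::export(name = ".sg_pair_cpp")]]
IntegerVector sg_pair_cpp(std::string a, std::string b) {
  int score, matches, cols;
  sg_align(a, b, score, matches, cols);
  return IntegerVector::create(_["score"] = score,
                               _["matches"] = matches,
                               _["cols"] = cols);
}

// [[Rcpp::export(name = ".sg_score_cpp")]]
int sg_score_cpp(std::string a, std::string b) {
  std::vector<int> prev, cur;
  return sg_score(a.c_str(), a.size(), b.c_str(), b.size(), prev, cur);
}

// identity of a query against many centroids
// [[Rcpp::export(name = ".sg_identity_many_cpp")]]
NumericVector sg_identity_many_cpp(std::string query,
                                   CharacterVector centroids) {
  const int n = centroids.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    int score, matches, cols;
    const char *c = CHAR(STRING_ELT(centroids, k));
    sg_align(query, std::string(c), score, matches, cols);
    const int lmin = std::min(query.size(), strlen(c));
    const int denom = std::max(cols, lmin);
    out[k] = denom > 0 ? (double)matches / denom : 0.0;
  }
  return out;
}

// first centroid (in creation order) whose identity with the query
// reaches the threshold; 0 when none does. A score-only prescreen skips
// centroids whose identity upper bound (score + lmin) / (2 lmin) cannot
// reach the threshold: identity = M / max(C, lmin) with M = (S + C) / 2
// is maximised over C at C = lmin.
// [[Rcpp::export(name = ".sg_first_match_cpp")]]
int sg_first_match_cpp(std::string query, CharacterVector centroids,
                       double threshold) {
  const int lq = query.size();
  const char *q = query.c_str();
  std::vector<int> prev, cur;
  for (int k = 0; k < centroids.size(); ++k) {
    const char *c = CHAR(STRING_ELT(centroids, k));
    const int lc = strlen(c);
    const int lmin = std::min(lq, lc);
    const int s = sg_score(q, lq, c, lc, prev, cur);
    if ((double)(s + lmin) / (2.0 * lmin) < threshold) continue;
    int score, matches, cols;
    sg_align(query, std::string(c), score, matches, cols);
    const int denom = std::max(cols, lmin);
    const double id = denom > 0 ? (double)matches / denom : 0.0;
    if (id >= threshold) return k + 1;
  }
  return 0;
}
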