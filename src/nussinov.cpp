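#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization (Nussinov) with Watson-Crick + GU wobble pairs and a
// minimum hairpin loop of 3 unpaired bases. Input is DNA-normalized (T == U).
// Traceback is deterministic: leave position i unpaired when that is optimal,
// otherwise pair i with the smallest admissible partner achieving the optimum.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["pairs"] = 0);
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int bestv = M[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[(size_t)i], seq[(size_t)k])) continue;
        int v = 1 + (k - i >= 2 ? M[i + 1][k - 1] : 0) + (k + 1 <= j ? M[k + 1][j] : 0);
        if (v > bestv) bestv = v;
      }
      M[i][j] = bestv;
    }
  }
  // iterative traceback
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  int pairs = 0;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[(size_t)i], seq[(size_t)k])) continue;
      int v = 1 + (k - i >= 2 ? M[i + 1][k - 1] : 0) + (k + 1 <= j ? M[k + 1][j] : 0);
      if (v == M[i][j]) {
        db[(size_t)i] = '('; db[(size_t)k] = ')'; ++pairs;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["pairs"] = pairs);
}
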