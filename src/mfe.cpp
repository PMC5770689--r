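#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov-style minimum-energy folding with per-pair energies and a
// minimum hairpin loop. E(i,j) = min( E(i+1,j),
//   min_k { e(i,k) + E(i+1,k-1) + E(k+1,j) : pairable(i,k), k-i > h } ).
// Indices 0-based half-open on the input string. O(n^3) time, O(n^2) space.

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default: return 4; // N: never pairs
  }
}

// [[Rcpp::export(name = ".mfe_fold_cpp")]]
List mfe_fold_cpp(std::string seq, NumericMatrix pair_energy,
                  int min_hairpin) {
  const int n = seq.size();
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base_index(seq[i]);

  const double NOPAIR = 1.0; // energies are < 0; positive marks forbidden
  std::vector<std::vector<double> > e(5, std::vector<double>(5, NOPAIR));
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j)
      if (pair_energy(i, j) < 0) e[i][j] = pair_energy(i, j);

  // E stored as full matrix; E[i][j] for i > j is 0 (empty subsequence)
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(n + 1, 0.0));
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i + 1][j]; // i unpaired
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        double pe = e[b[i]][b[k]];
        if (pe < 0) {
          double inner = (k - 1 >= i + 1) ? E[i + 1][k - 1] : 0.0;
          double outer = (k + 1 <= j) ? E[k + 1][j] : 0.0;
          double cand = pe + inner + outer;
          if (cand < best) best = cand;
        }
      }
      E[i][j] = best;
    }
  }

  // traceback, deterministic: at (i,j) prefer pairing i with the smallest
  // optimal k over leaving i unpaired
  std::string structure(n, '.');
  std::vector<std::pair<int, int> > stack;
  if (n >= 2) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double target = E[i][j];
    bool paired = false;
    for (int k = i + min_hairpin + 1; k <= j; ++k) {
      double pe = e[b[i]][b[k]];
      if (pe < 0) {
        double inner = (k - 1 >= i + 1) ? E[i + 1][k - 1] : 0.0;
        double outer = (k + 1 <= j) ? E[k + 1][j] : 0.0;
        if (pe + inner + outer == target) {
          structure[i] = '(';
          structure[k] = ')';
          if (k - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
          paired = true;
          break;
        }
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  double dg = (n >= 2) ? E[0][n - 1] : 0.0;
  return List::create(_["delta_g"] = dg, _["structure"] = structure);
}
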