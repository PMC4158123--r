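#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Genotype coding used by all kernels: 0 = A, 1 = B, -1 = missing
// (H and U; heterozygotes carry no phase information in a RIL and are
// treated as missing for recombination counting).
//
// COUNT objective: number of A<->B transitions between consecutive
// non-missing homozygous calls along the marker order, summed over lines.

static int count_order(const IntegerMatrix& g, const std::vector<int>& ord) {
  const int nline = g.nrow();
  int total = 0;
  for (int i = 0; i < nline; ++i) {
    int last = -1;
    for (size_t k = 0; k < ord.size(); ++k) {
      const int v = g(i, ord[k]);
      if (v < 0) continue;
      if (last >= 0 && v != last) ++total;
      last = v;
    }
  }
  return total;
}

// [[Rcpp::export]]
int count_recomb_cpp(IntegerMatrix geno, IntegerVector order) {
  std::vector<int> ord(order.size());
  for (int k = 0; k < order.size(); ++k) ord[k] = order[k] - 1;
  return count_order(geno, ord);
}

// Greedy sequential insertion: markers taken in the given shuffle, each
// placed at the position of the growing order that minimises COUNT
// (ties -> earliest position).
// [[Rcpp::export]]
IntegerVector greedy_insert_cpp(IntegerMatrix geno, IntegerVector shuffle) {
  const int m = shuffle.size();
  std::vector<int> ord;
  ord.reserve(m);
  ord.push_back(shuffle[0] - 1);
  std::vector<int> cand;
  for (int j = 1; j < m; ++j) {
    const int mk = shuffle[j] - 1;
    int best_pos = 0;
    int best_cnt = INT_MAX;
    for (size_t pos = 0; pos <= ord.size(); ++pos) {
      cand = ord;
      cand.insert(cand.begin() + pos, mk);
      const int cnt = count_order(geno, cand);
      if (cnt < best_cnt) { best_cnt = cnt; best_pos = (int)pos; }
    }
    ord.insert(ord.begin() + best_pos, mk);
  }
  IntegerVector out(m);
  for (int k = 0; k < m; ++k) out[k] = ord[k] + 1;
  return out;
}

// Window rippling: slide a window of `window` consecutive markers along the
// order; at each position try every permutation of the window and accept a
// permutation iff it strictly lowers COUNT; repeat full sweeps until a
// sweep yields no improvement.
// [[Rcpp::export]]
IntegerVector ripple_cpp(IntegerMatrix geno, IntegerVector order, int window) {
  const int m = order.size();
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = order[k] - 1;
  if (window < 2 || window > m)
    stop("window must be in [2, number of markers]");
  if (window > 8) stop("ripple window larger than 8 is not supported");

  std::vector<int> idx(window);
  for (int k = 0; k < window; ++k) idx[k] = k;
  std::vector<std::vector<int> > perms;
  std::vector<int> p(idx);
  do { perms.push_back(p); } while (std::next_permutation(p.begin(), p.end()));

  int best = count_order(geno, ord);
  bool improved = true;
  std::vector<int> cand(m);
  while (improved) {
    improved = false;
    for (int start = 0; start + window <= m; ++start) {
      for (size_t pi = 0; pi < perms.size(); ++pi) {
        cand = ord;
        for (int k = 0; k < window; ++k)
          cand[start + k] = ord[start + perms[pi][k]];
        const int cnt = count_order(geno, cand);
        if (cnt < best) {
          best = cnt;
          ord = cand;
          improved = true;
        }
      }
    }
  }
  IntegerVector out(m);
  for (int k = 0; k < m; ++k) out[k] = ord[k] + 1;
  return out;
}
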