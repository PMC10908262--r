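#include <Rcpp.h>
#include <cstring>
#include <map>
#include <vector>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost insertions, deletions, substitutions and adjacent
// transpositions, with the restriction that no substring is edited twice.
static int osa_one(const char *a, int la, const char *b, int lb) {
  if (la == 0) return lb;
  if (lb == 0) return la;
  // two-row DP is not enough with transpositions: keep three rows
  std::vector<int> r0(lb + 1), r1(lb + 1), r2(lb + 1);
  for (int j = 0; j <= lb; ++j) r1[j] = j;
  for (int i = 1; i <= la; ++i) {
    r2[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(r1[j] + 1, r2[j - 1] + 1), r1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, r0[j - 2] + 1);
      r2[j] = d;
    }
    r0.swap(r1);
    r1.swap(r2);
  }
  return r1[lb];
}

// [[Rcpp::export(name = ".osa_distance_impl")]]
IntegerVector osa_distance_impl(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("internal: length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char *sa = a[i];
    const char *sb = b[i];
    out[i] = osa_one(sa, (int)std::strlen(sa), sb, (int)std::strlen(sb));
  }
  return out;
}

// Reference implementation by top-down memoised recursion, kept separate
// from the row-based loop above so the two can be cross-checked.
static int osa_rec(const char *a, const char *b, int i, int j,
                   std::map<std::pair<int, int>, int> &memo) {
  if (i == 0) return j;
  if (j == 0) return i;
  auto key = std::make_pair(i, j);
  auto hit = memo.find(key);
  if (hit != memo.end()) return hit->second;
  int best = osa_rec(a, b, i - 1, j, memo) + 1;
  int ins = osa_rec(a, b, i, j - 1, memo) + 1;
  if (ins < best) best = ins;
  int sub = osa_rec(a, b, i - 1, j - 1, memo) + (a[i - 1] == b[j - 1] ? 0 : 1);
  if (sub < best) best = sub;
  if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1]) {
    int tr = osa_rec(a, b, i - 2, j - 2, memo) + 1;
    if (tr < best) best = tr;
  }
  memo[key] = best;
  return best;
}

// [[Rcpp::export(name = ".osa_distance_ref")]]
IntegerVector osa_distance_ref(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("internal: length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *sa = a[i];
    const char *sb = b[i];
    std::map<std::pair<int, int>, int> memo;
    out[i] = osa_rec(sa, sb, (int)std::strlen(sa), (int)std::strlen(sb), memo);
  }
  return out;
}
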