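// Minimum-energy RNA secondary structure restricted to single-hairpin
// (multibranch-free) components, by dynamic programming over subintervals.
//
// Energies are integer hundredths of a kcal/mol so that the DP and the exhaustive
// R enumeration oracle agree bit-exactly.  The recurrence for a closed pair
// (i,j) allows only a hairpin loop or a single interior pair (stack, bulge
// or internal loop, total unpaired size capped); the exterior level may hold
// any number of side-by-side stems.  Traceback tie-break: prefer pairing
// (i,j) with smallest i, then largest j; at equal energy an extra interior
// pair is preferred over closing the hairpin.

#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

static const int INF = INT_MAX / 4;

struct Model {
  const int *pair_code;      // 4x4, column-major, 0 = not pairable, 1..6
  const int *stack;          // 6x6 column-major, deci-kcal
  const int *hairpin_pen;    // by loop size (1-based -> index size-1)
  const int *bulge_pen;
  const int *internal_pen;
  int n_hairpin, n_bulge, n_internal;
  int min_hairpin, max_interior;
  int pc(int a, int b) const {        // a,b in 0..3, -1 for N
    if (a < 0 || b < 0) return 0;
    return pair_code[a + 4 * b];
  }
  int hp(int size) const { return hairpin_pen[std::min(size, n_hairpin) - 1]; }
  int bp(int size) const { return bulge_pen[std::min(size, n_bulge) - 1]; }
  int ip(int size) const { return internal_pen[std::min(size, n_internal) - 1]; }
  int interior(int pc_out, int pc_in, int l1, int l2) const {
    if (l1 == 0 && l2 == 0) return stack[(pc_out - 1) + 6 * (pc_in - 1)];
    if (l1 == 0 || l2 == 0) return bp(l1 + l2);
    return ip(l1 + l2);
  }
};

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector codes, IntegerVector pair_code,
             IntegerVector stack, IntegerVector hairpin_pen,
             IntegerVector bulge_pen, IntegerVector internal_pen,
             int min_hairpin, int max_interior) {
  Model M;
  M.pair_code = pair_code.begin();
  M.stack = stack.begin();
  M.hairpin_pen = hairpin_pen.begin();
  M.bulge_pen = bulge_pen.begin();
  M.internal_pen = internal_pen.begin();
  M.n_hairpin = hairpin_pen.size();
  M.n_bulge = bulge_pen.size();
  M.n_internal = internal_pen.size();
  M.min_hairpin = min_hairpin;
  M.max_interior = max_interior;

  const int n = codes.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i)
    s[i] = codes[i] == NA_INTEGER ? -1 : codes[i] - 1;  // 0..3 or -1

  // V[i][j]: min energy with (i,j) paired; INF if impossible
  std::vector< std::vector<int> > V(n, std::vector<int>(n, INF));
  for (int span = M.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pco = M.pc(s[i], s[j]);
      if (pco == 0) continue;
      int best = M.hp(j - i - 1);
      int pmax = std::min(j - 1, i + 1 + M.max_interior);
      for (int p = i + 1; p <= pmax; ++p) {
        int l1 = p - i - 1;
        int qmin = std::max(p + M.min_hairpin + 1, j - 1 - (M.max_interior - l1));
        for (int q = j - 1; q >= qmin; --q) {
          if (V[p][q] >= INF) continue;
          int e = V[p][q] + M.interior(pco, M.pc(s[p], s[q]), l1, j - q - 1);
          if (e < best) best = e;
        }
      }
      V[i][j] = best;
    }
  }

  // exterior: W[i] = min energy of suffix i..n-1
  std::vector<int> W(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) {
    int best = W[i + 1];
    for (int j = i + M.min_hairpin + 1; j < n; ++j)
      if (V[i][j] < INF && V[i][j] + W[j + 1] < best)
        best = V[i][j] + W[j + 1];
    W[i] = best;
  }

  // traceback
  IntegerVector pairs(n, 0);
  std::vector< std::pair<int,int> > todo;  // closed pairs to expand
  int i = 0;
  while (i < n) {
    int pick = -1;
    for (int j = n - 1; j >= i + M.min_hairpin + 1; --j) {
      if (V[i][j] < INF && V[i][j] + W[j + 1] == W[i]) { pick = j; break; }
    }
    if (pick < 0) { ++i; continue; }
    todo.push_back(std::make_pair(i, pick));
    i = pick + 1;
  }
  while (!todo.empty()) {
    int a = todo.back().first, b = todo.back().second;
    todo.pop_back();
    pairs[a] = b + 1;  // 1-based partner
    pairs[b] = a + 1;
    int pco = M.pc(s[a], s[b]);
    int target = V[a][b];
    bool found = false;
    int pmax = std::min(b - 1, a + 1 + M.max_interior);
    for (int p = a + 1; p <= pmax && !found; ++p) {
      int l1 = p - a - 1;
      int qmin = std::max(p + M.min_hairpin + 1, b - 1 - (M.max_interior - l1));
      for (int q = b - 1; q >= qmin; --q) {
        if (V[p][q] >= INF) continue;
        if (V[p][q] + M.interior(pco, M.pc(s[p], s[q]), l1, b - q - 1) == target) {
          todo.push_back(std::make_pair(p, q));
          found = true;
          break;
        }
      }
    }
    // if nothing found the pair closes a hairpin loop
  }

  return List::create(_["pairs"] = pairs, _["energy"] = W.empty() ? 0 : W[0]);
}
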