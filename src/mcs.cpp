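#include <Rcpp.h>
#include <chrono>
using namespace Rcpp;

// Connected maximum common substructure search (McGregor-style branch and
// bound over candidate atom pairs). Atoms match when their element codes
// are equal; bonds match when their integer labels (encoding bond order
// and, optionally, ring membership) are equal. Every atom after the first
// must join the mapping through at least one matched bond, so the common
// subgraph is connected. Branching is binary on the lexicographically
// smallest admissible pair (include it / forbid it), which is complete and
// deterministic. Objective: maximise mapped-atom count, then matched-bond
// count; among equal optima the first solution found is kept.

namespace {

struct SearchState {
  int n1, n2;
  const int *elem1, *elem2;
  const int *adj1, *adj2;   // n x n label matrices, 0 = no bond
  std::vector<int> map1;    // g1 atom -> g2 atom (-1 = unmapped)
  std::vector<int> map2;
  std::vector<char> forbidden; // n1 * n2 pair decisions on current path
  int cur_size = 0, cur_bonds = 0;
  int best_size = 0, best_bonds = -1;
  std::vector<int> best_map;
  std::chrono::steady_clock::time_point deadline;
  bool timed_out = false;
  long calls = 0;

  int lab1(int a, int b) const { return adj1[a + n1 * b]; }
  int lab2(int a, int b) const { return adj2[a + n2 * b]; }

  void record() {
    if (cur_size > best_size ||
        (cur_size == best_size && cur_bonds > best_bonds)) {
      best_size = cur_size;
      best_bonds = cur_bonds;
      best_map = map1;
    }
  }

  // matched bonds the pair (a, b) would add to the current mapping
  int matched_bonds(int a, int b) const {
    int add = 0;
    for (int j = 0; j < n1; ++j) {
      if (map1[j] < 0) continue;
      int l1 = lab1(a, j);
      if (l1 != 0 && l1 == lab2(b, map1[j])) ++add;
    }
    return add;
  }

  void recurse() {
    if (timed_out) return;
    if (((++calls) & 1023) == 0 &&
        std::chrono::steady_clock::now() > deadline) {
      timed_out = true;
      return;
    }
    record();

    int free1 = 0, free2 = 0;
    for (int i = 0; i < n1; ++i) if (map1[i] < 0) ++free1;
    for (int j = 0; j < n2; ++j) if (map2[j] < 0) ++free2;
    if (cur_size + std::min(free1, free2) < best_size) return;

    // lexicographically smallest admissible candidate pair
    for (int a = 0; a < n1; ++a) {
      if (map1[a] >= 0) continue;
      for (int b = 0; b < n2; ++b) {
        if (map2[b] >= 0 || forbidden[a * n2 + b]) continue;
        if (elem2[b] != elem1[a]) continue;
        int add = cur_size == 0 ? 0 : matched_bonds(a, b);
        if (cur_size > 0 && add == 0) continue; // must stay connected
        // include branch
        map1[a] = b; map2[b] = a;
        cur_size += 1; cur_bonds += add;
        recurse();
        map1[a] = -1; map2[b] = -1;
        cur_size -= 1; cur_bonds -= add;
        if (timed_out) return;
        // forbid branch
        forbidden[a * n2 + b] = 1;
        recurse();
        forbidden[a * n2 + b] = 0;
        return; // both branches of the chosen pair cover the whole space
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List mcs_search_cpp(IntegerVector elem1, IntegerMatrix adj1,
                    IntegerVector elem2, IntegerMatrix adj2,
                    double timeout_s) {
  SearchState st;
  st.n1 = elem1.size();
  st.n2 = elem2.size();
  st.elem1 = elem1.begin();
  st.elem2 = elem2.begin();
  st.adj1 = adj1.begin();
  st.adj2 = adj2.begin();
  st.map1.assign(st.n1, -1);
  st.map2.assign(st.n2, -1);
  st.forbidden.assign((size_t)st.n1 * st.n2, 0);
  st.deadline = std::chrono::steady_clock::now() +
      std::chrono::milliseconds((long)(timeout_s * 1000.0));
  st.recurse();

  IntegerVector m1, m2;
  for (int i = 0; i < st.n1; ++i) {
    if (!st.best_map.empty() && st.best_map[i] >= 0) {
      m1.push_back(i + 1);
      m2.push_back(st.best_map[i] + 1);
    }
  }
  return List::create(_["map_i"] = m1, _["map_j"] = m2,
                      _["n_bonds"] = st.best_bonds < 0 ? 0 : st.best_bonds,
                      _["timed_out"] = st.timed_out);
}
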