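#include <Rcpp.h>
using namespace Rcpp;

// Single-gene translocation engine.
//
// Maintains the genome as a doubly linked list over gene indices so each
// jump (unlink one gene, relink it at a uniformly chosen slot) is O(1).
// Randomness flows through R's RNG so set.seed() governs reproducibility.
//
// Linear genomes with g genes have g + 1 insertion slots; after removing
// the jumping gene the n - 1 remaining genes leave exactly n slots, all
// equiprobable (the source slot included, so a no-op jump is possible).
// Circular genomes have one slot per remaining gene (n - 1 slots).

// [[Rcpp::export]]
IntegerVector cpp_jump_order(int n, int n_jumps, bool circular) {
  if (n < 2) stop("need at least 2 genes");
  if (n_jumps < 0) stop("n_jumps must be non-negative");
  std::vector<int> nxt(n), prv(n);
  for (int i = 0; i < n; ++i) { nxt[i] = i + 1; prv[i] = i - 1; }
  int head = 0;
  if (circular) { nxt[n - 1] = 0; prv[0] = n - 1; }
  else nxt[n - 1] = -1; // prv[0] already -1

  for (int t = 0; t < n_jumps; ++t) {
    int g = (int)(unif_rand() * n); if (g >= n) g = n - 1;
    // unlink g
    int p = prv[g], q = nxt[g];
    if (p >= 0) nxt[p] = q;
    if (q >= 0) prv[q] = p;
    if (!circular && g == head) head = q;
    if (circular && g == head) head = q; // any resident works as read-out origin
    // choose insertion anchor
    int a;
    if (circular) {
      a = (int)(unif_rand() * (n - 1)); if (a >= n - 1) a = n - 2;
      if (a >= g) ++a;                 // uniform over the n-1 remaining genes
      int q2 = nxt[a];
      nxt[a] = g; prv[g] = a; nxt[g] = q2; prv[q2] = g;
    } else {
      int u = (int)(unif_rand() * n); if (u >= n) u = n - 1;
      if (u == 0) {                    // insert before the first gene
        prv[g] = -1; nxt[g] = head;
        if (head >= 0) prv[head] = g;
        head = g;
      } else {
        a = u - 1;
        if (a >= g) ++a;               // skip g itself among remaining genes
        int q2 = nxt[a];
        nxt[a] = g; prv[g] = a; nxt[g] = q2;
        if (q2 >= 0) prv[q2] = g;
      }
    }
  }

  IntegerVector out(n);
  int c = head;
  for (int i = 0; i < n; ++i) { out[i] = c + 1; c = nxt[c]; }
  return out;
}
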