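#include <Rcpp.h>
using namespace Rcpp;

// Enumerate all maximal pairings (p, t, l) of P in T with l >= ellE.
// A pairing is an occurrence of a common substring; it is maximal when it
// cannot be extended by one character on both sequences in either direction.
// 'N' never matches anything (including 'N'), so it both breaks runs and
// makes a flanking position left/right-maximal.
//
// Rolling-row scan: run(p, t) = length of the exact-match run starting at
// (p, t); run(p, t) = match(p, t) ? 1 + run(p+1, t+1) : 0.  A pairing
// (p, t, run(p, t)) is maximal iff it is left-maximal (run length already
// being the full forward run makes it right-maximal).  O(|P|*|T|) time,
// O(|T|) memory.
// [[Rcpp::export]]
IntegerMatrix mems_scan(std::string P, std::string T, int ellE) {
  const int np = (int)P.size();
  const int nt = (int)T.size();
  std::vector<int> cur(nt + 1, 0), nxt(nt + 1, 0);
  std::vector<int> rp, rt, rl;

  for (int p = np - 1; p >= 0; --p) {
    const char cp = P[p];
    const bool pOk = (cp != 'N');
    for (int t = nt - 1; t >= 0; --t) {
      int run = 0;
      if (pOk && cp == T[t]) run = 1 + nxt[t + 1];
      cur[t] = run;
      if (run >= ellE) {
        bool leftmax = (p == 0) || (t == 0);
        if (!leftmax) {
          const char a = P[p - 1], b = T[t - 1];
          leftmax = (a != b) || (a == 'N');
        }
        if (leftmax) {
          rp.push_back(p);
          rt.push_back(t);
          rl.push_back(run);
        }
      }
    }
    std::swap(cur, nxt);
  }

  const int n = (int)rp.size();
  IntegerMatrix out(n, 3);
  // rows were collected with p descending; reverse for ascending p
  for (int i = 0; i < n; ++i) {
    const int j = n - 1 - i;
    out(i, 0) = rp[j];
    out(i, 1) = rt[j];
    out(i, 2) = rl[j];
  }
  colnames(out) = CharacterVector::create("p", "t", "l");
  return out;
}
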