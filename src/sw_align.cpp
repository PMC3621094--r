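#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-coded sequences.
//
// q and t are 0-based indices into the rows/columns of `mat`.
// A gap of length k costs gap_open + k * gap_ext (BLAST convention).
// Tie-break is deterministic: the first maximal cell in row-major order
// (smallest query end, then smallest target end) wins, and the traceback
// prefers diagonal over vertical over horizontal moves.
//
// With traceback = false only the score and end coordinates are returned
// (linear memory); callers re-run with traceback = true for accepted hits.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector q, IntegerVector t, IntegerMatrix mat,
                  int gap_open, int gap_ext, bool traceback = true) {
  const int m = q.size(), n = t.size();
  const int NEG = INT_MIN / 4;
  const int open_cost = gap_open + gap_ext;
  const int nrow = mat.nrow();

  // flat copies: Rcpp element accessors are too slow for the inner loop
  std::vector<int> smat(mat.begin(), mat.end()); // column-major
  std::vector<int> qv(q.begin(), q.end()), tv(t.begin(), t.end());

  int best = 0, bi = 0, bj = 0;

  if (!traceback) {
    std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
    for (int i = 1; i <= m; ++i) {
      int E = NEG;
      Hcur[0] = 0;
      const int *srow = smat.data() + qv[i - 1]; // + col * nrow
      const int *Hp = Hprev.data();
      int *Hc = Hcur.data(), *Fc = Fcol.data();
      int lbest = best, lbj = 0;
      for (int j = 1; j <= n; ++j) {
        E = std::max(Hc[j - 1] - open_cost, E - gap_ext);
        Fc[j] = std::max(Hp[j] - open_cost, Fc[j] - gap_ext);
        int h = Hp[j - 1] + srow[(size_t)tv[j - 1] * nrow];
        h = std::max(h, std::max(E, Fc[j]));
        h = std::max(h, 0);
        Hc[j] = h;
        if (h > lbest) { lbest = h; lbj = j; }
      }
      if (lbest > best) { best = lbest; bi = i; bj = lbj; }
      std::swap(Hprev, Hcur);
    }
    return List::create(_["score"] = best, _["qend"] = bi, _["tend"] = bj);
  }

  // full DP with per-state traceback
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  // trH: 0 stop, 1 diag, 2 from F, 3 from E; trE/trF: 1 open, 2 extend
  std::vector<unsigned char> trH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> trE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> trF((size_t)(m + 1) * (n + 1), 0);
  const size_t W = n + 1;

  for (int i = 1; i <= m; ++i) {
    const int *srow = smat.data() + qv[i - 1];
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int e_open = H[ro + j - 1] - open_cost;
      int e_ext  = E[ro + j - 1] - gap_ext;
      E[ro + j] = std::max(e_open, e_ext);
      trE[ro + j] = (e_open >= e_ext) ? 1 : 2;
      int f_open = H[rp + j] - open_cost;
      int f_ext  = F[rp + j] - gap_ext;
      F[ro + j] = std::max(f_open, f_ext);
      trF[ro + j] = (f_open >= f_ext) ? 1 : 2;
      int d = H[rp + j - 1] + srow[(size_t)tv[j - 1] * nrow];
      int h = 0; unsigned char tb = 0;
      if (d > h) { h = d; tb = 1; }
      if (F[ro + j] > h) { h = F[ro + j]; tb = 2; }
      if (E[ro + j] > h) { h = E[ro + j]; tb = 3; }
      H[ro + j] = h; trH[ro + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> qpos, tpos;
  int i = bi, j = bj, matches = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tb = trH[(size_t)i * W + j];
      if (tb == 0) break;
      if (tb == 1) {
        qpos.push_back(i); tpos.push_back(j);
        if (q[i - 1] == t[j - 1]) ++matches;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 1;
    } else if (state == 1) { // E: gap consuming target
      unsigned char tb = trE[(size_t)i * W + j];
      qpos.push_back(0); tpos.push_back(j);
      --j;
      state = (tb == 1) ? 0 : 1;
    } else { // F: gap consuming query
      unsigned char tb = trF[(size_t)i * W + j];
      qpos.push_back(i); tpos.push_back(0);
      --i;
      state = (tb == 1) ? 0 : 2;
    }
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  int qstart = 0, tstart = 0;
  for (size_t k = 0; k < qpos.size(); ++k) { if (qpos[k] > 0) { qstart = qpos[k]; break; } }
  for (size_t k = 0; k < tpos.size(); ++k) { if (tpos[k] > 0) { tstart = tpos[k]; break; } }

  return List::create(
    _["score"] = best,
    _["qstart"] = qstart, _["qend"] = bi,
    _["tstart"] = tstart, _["tend"] = bj,
    _["matches"] = matches,
    _["length"] = (int)qpos.size(),
    _["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos));
}
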