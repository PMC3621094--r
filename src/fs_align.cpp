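#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Protein-to-DNA alignment with frameshifts (fastx-style three-state DP):
// global in the protein, local in the DNA. Used to call gene intactness:
// the traceback yields premature-stop and frameshift events with nucleotide
// positions at codon resolution.
//
// prot: 0-based codes into rows of `mat`.
// dna:  0 = A, 1 = C, 2 = G, 3 = T, 4 = N.
// codon_aa: length-125 lookup (d1*25 + d2*5 + d3, 0-based) -> column of
//           `mat`; any codon containing N maps to the X column.
// A residue normally consumes 3 nt; frameshift transitions consume 2 nt
// (flat fs_pen, residue unscored) or 4 nt (fs_pen plus the score of the
// last 3 nt read as a codon). Gaps are affine with cost gap_open + k*gap_ext.
// [[Rcpp::export]]
List cpp_fs_align(IntegerVector prot, IntegerVector dna, IntegerMatrix mat,
                  IntegerVector codon_aa, int gap_open, int gap_ext,
                  int fs_pen, int stop_code) {
  const int q = prot.size(), L = dna.size();
  const int NEG = INT_MIN / 4;
  const int open_cost = gap_open + gap_ext;
  const size_t W = L + 1;

  // aa code of the codon ending at dna position j (1-based), or -1
  std::vector<int> aa_end(L + 1, -1);
  for (int j = 3; j <= L; ++j)
    aa_end[j] = codon_aa[dna[j - 3] * 25 + dna[j - 2] * 5 + dna[j - 1]];

  std::vector<int> M((size_t)(q + 1) * W, NEG);
  std::vector<int> GP((size_t)(q + 1) * W, NEG); // residue unmatched (gap in DNA)
  std::vector<int> GD((size_t)(q + 1) * W, NEG); // codon unmatched (gap in protein)
  // trace codes for M: 1 codon(diag3), 2 fs2, 3 fs4, 4 from GP, 5 from GD
  std::vector<unsigned char> trM((size_t)(q + 1) * W, 0);
  std::vector<unsigned char> trP((size_t)(q + 1) * W, 0); // 1 open, 2 extend
  std::vector<unsigned char> trD((size_t)(q + 1) * W, 0);

  for (int j = 0; j <= L; ++j) M[j] = 0; // free start anywhere in DNA

  for (int i = 1; i <= q; ++i) {
    const int pi = prot[i - 1];
    const size_t ro = (size_t)i * W, rp = (size_t)(i - 1) * W;
    for (int j = 0; j <= L; ++j) {
      // GP: consume residue i, no DNA
      int gp_open = (M[rp + j] > NEG) ? M[rp + j] - open_cost : NEG;
      int gp_ext  = (GP[rp + j] > NEG) ? GP[rp + j] - gap_ext : NEG;
      GP[ro + j] = std::max(gp_open, gp_ext);
      trP[ro + j] = (gp_open >= gp_ext) ? 1 : 2;
      // GD: consume a codon, no residue
      if (j >= 3) {
        int gd_open = (M[ro + j - 3] > NEG) ? M[ro + j - 3] - open_cost : NEG;
        int gd_ext  = (GD[ro + j - 3] > NEG) ? GD[ro + j - 3] - gap_ext : NEG;
        GD[ro + j] = std::max(gd_open, gd_ext);
        trD[ro + j] = (gd_open >= gd_ext) ? 1 : 2;
      }
      // M
      int best = NEG; unsigned char tb = 0;
      if (j >= 3 && aa_end[j] >= 0) {
        int s = mat(pi, aa_end[j]);
        int from = std::max(M[rp + j - 3], std::max(GP[rp + j - 3], GD[rp + j - 3]));
        if (from > NEG && from + s > best) { best = from + s; tb = 1; }
        if (j >= 4 && M[rp + j - 4] > NEG && M[rp + j - 4] - fs_pen + s > best) {
          best = M[rp + j - 4] - fs_pen + s; tb = 3;
        }
      }
      if (j >= 2 && M[rp + j - 2] > NEG && M[rp + j - 2] - fs_pen > best) {
        best = M[rp + j - 2] - fs_pen; tb = 2;
      }
      if (GP[ro + j] > best) { best = GP[ro + j]; tb = 4; }
      if (GD[ro + j] > best) { best = GD[ro + j]; tb = 5; }
      M[ro + j] = best; trM[ro + j] = tb;
    }
  }

  // best end over DNA positions at protein row q
  int best = NEG, bj = 0;
  for (int j = 0; j <= L; ++j)
    if (M[(size_t)q * W + j] > best) { best = M[(size_t)q * W + j]; bj = j; }

  // traceback
  std::vector<int> ev_type;  // 1 frameshift, 2 premature stop
  std::vector<int> ev_pos;   // 1-based DNA position (start of odd consumption / stop codon)
  std::vector<int> ev_shift; // -1 or +1 for frameshifts, 0 for stops
  std::vector<int> res_aa(q, NA_INTEGER);    // emitted aa code per residue
  std::vector<int> res_dna(q, NA_INTEGER);   // DNA start (1-based) per residue
  int i = q, j = bj, matches = 0, aligned = 0;
  int dna_end = bj, dna_start = bj;
  while (i > 0) {
    unsigned char tb = trM[(size_t)i * W + j];
    if (tb == 1 || tb == 3) {
      int consumed = (tb == 1) ? 3 : 4;
      res_aa[i - 1] = aa_end[j];
      res_dna[i - 1] = j - 2;
      ++aligned;
      if (aa_end[j] == prot[i - 1]) ++matches;
      if (aa_end[j] == stop_code) {
        ev_type.push_back(2); ev_pos.push_back(j - 2); ev_shift.push_back(0);
      }
      if (tb == 3) {
        ev_type.push_back(1); ev_pos.push_back(j - consumed + 1); ev_shift.push_back(1);
      }
      dna_start = j - consumed + 1;
      j -= consumed; --i;
    } else if (tb == 2) {
      ev_type.push_back(1); ev_pos.push_back(j - 1); ev_shift.push_back(-1);
      dna_start = j - 1;
      j -= 2; --i;
    } else if (tb == 4) {
      // unwind GP run
      while (i > 0) {
        unsigned char t2 = trP[(size_t)i * W + j];
        --i;
        if (t2 == 1) break;
      }
    } else if (tb == 5) {
      while (j >= 3) {
        unsigned char t2 = trD[(size_t)i * W + j];
        dna_start = j - 2;
        j -= 3;
        if (t2 == 1) break;
      }
    } else break;
  }

  return List::create(
    _["score"] = best,
    _["dna_start"] = dna_start, _["dna_end"] = dna_end,
    _["matches"] = matches, _["aligned"] = aligned,
    _["ev_type"] = wrap(ev_type), _["ev_pos"] = wrap(ev_pos),
    _["ev_shift"] = wrap(ev_shift),
    _["res_aa"] = wrap(res_aa), _["res_dna"] = wrap(res_dna));
}
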