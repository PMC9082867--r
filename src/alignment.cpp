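#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman over plain nucleotide strings.
// Gap of length g scores gap_open + (g-1)*gap_extend (both negative).
// 'N' never counts as a match. Coordinates returned 1-based inclusive.
//
// Optional banding: only cells with dlo <= j - i <= dhi are computed
// (diagonals relative to query position). Out-of-band cells behave as
// empty-alignment cells (H = 0), which is safe for local alignment. Score
// rows are rolled; the traceback is one packed byte per in-band cell,
// stored band-compressed (row i, diagonal j - i - dlo):
//   bits 0-1: H move (0 stop, 1 diag, 2 from E, 3 from F)
//   bit 2:    E extend (vs open)
//   bit 3:    F extend (vs open)

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int dlo = NA_INTEGER, int dhi = NA_INTEGER) {
  const int m = (int) q.size(), n = (int) s.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = -1,
                        _["sstart"] = 0, _["send"] = -1,
                        _["nmatch"] = 0, _["nmismatch"] = 0, _["ngap"] = 0);
  if (dlo == NA_INTEGER) dlo = -m;
  if (dhi == NA_INTEGER) dhi = n;
  dlo = std::max(dlo, -m); dhi = std::min(dhi, n);
  const int width = dhi - dlo + 1;
  if (width <= 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = -1,
                        _["sstart"] = 0, _["send"] = -1,
                        _["nmatch"] = 0, _["nmismatch"] = 0, _["ngap"] = 0);
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 2, 0), Hcur(n + 2, 0);
  std::vector<int> Fcol(n + 2, NEG); // F for current row, per column
  std::vector<unsigned char> tb((size_t)m * width, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char qc = q[(size_t)i - 1];
    int Erow = NEG; // E within this row
    Hcur[0] = 0;
    const int jmin = std::max(1, i + dlo), jmax = std::min(n, i + dhi);
    if (jmin > jmax) { std::swap(Hprev, Hcur); continue; }
    Hcur[jmin - 1] = 0;
    unsigned char *tbrow = &tb[(size_t)(i - 1) * width - (i + dlo)];
    for (int j = jmin; j <= jmax; ++j) {
      unsigned char t = 0;
      int e_open = Hcur[j - 1] + gap_open;
      int e_ext = Erow + gap_extend;
      if (e_ext > e_open) { Erow = e_ext; t |= 4; } else Erow = e_open;
      int f_open = Hprev[j] + gap_open;
      int f_ext = Fcol[j] + gap_extend;
      if (f_ext > f_open) { Fcol[j] = f_ext; t |= 8; } else Fcol[j] = f_open;
      const char sc = s[(size_t)j - 1];
      bool is_match = (qc == sc) && qc != 'N';
      int diag = Hprev[j - 1] + (is_match ? match : mismatch);
      int h = 0; unsigned char mv = 0;
      if (diag > h) { h = diag; mv = 1; }
      if (Erow > h) { h = Erow; mv = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; mv = 3; }
      Hcur[j] = h;
      tbrow[j] = t | mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (jmax + 1 <= n) Hcur[jmax + 1] = 0; // band-edge hygiene
    std::swap(Hprev, Hcur);
  }
  // traceback from (bi, bj); moves leaving the band terminate (H = 0 there)
  int i = bi, j = bj, state = 0; // 0=H 1=E 2=F
  int nmatch = 0, nmismatch = 0, ngap = 0;
  int qend = bi, send = bj, qstart = bi + 1, sstart = bj + 1;
  while (i > 0 && j > 0) {
    const int d = j - i;
    if (d < dlo || d > dhi) break;
    const unsigned char t = tb[(size_t)(i - 1) * width + (d - dlo)];
    if (state == 0) {
      const unsigned char mv = t & 3;
      if (mv == 0) break;
      if (mv == 1) {
        bool is_match = (q[(size_t)i - 1] == s[(size_t)j - 1]) &&
          q[(size_t)i - 1] != 'N';
        if (is_match) ++nmatch; else ++nmismatch;
        qstart = i; sstart = j; --i; --j;
      } else if (mv == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++ngap; sstart = j;
      if (!(t & 4)) state = 0;
      --j;
    } else {
      ++ngap; qstart = i;
      if (!(t & 8)) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["sstart"] = sstart, _["send"] = send,
                      _["nmatch"] = nmatch, _["nmismatch"] = nmismatch,
                      _["ngap"] = ngap);
}
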