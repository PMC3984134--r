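#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded semi-global alignment of many query reads against a small set of
// reference sequences, with linear gap penalties.
//
// The alignment is anchored at the start of both sequences (leading gaps are
// penalized) while trailing gaps on either sequence are free: the optimal
// score is taken over the last row and last column of the DP matrix. This
// matches amplicon reads whose 5' end is primer-anchored but whose 3' end may
// be truncated short of the reference (or overrun it by a few inserted
// bases).
//
// The band restricts |i - j| <= band, which is adequate when indels are rare
// relative to read length; callers should widen the band for divergent
// sequences. Percent identity is matches / aligned columns along the optimal
// path (trailing free gaps excluded), tracked through the DP.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List semiglobal_score_matrix(CharacterVector reads, CharacterVector refs,
                             double match, double mismatch, double gap,
                             int band) {
  const int nr = reads.size();
  const int nf = refs.size();
  if (band < 1) stop("band must be >= 1");
  NumericMatrix score_mat(nr, nf);
  NumericMatrix ident_mat(nr, nf);

  std::vector<std::string> refstr(nf);
  for (int f = 0; f < nf; ++f) refstr[f] = as<std::string>(refs[f]);

  const int W = 2 * band + 1;  // band width, j stored at offset j - (i - band)

  for (int r = 0; r < nr; ++r) {
    std::string q = as<std::string>(reads[r]);
    const int n = (int)q.size();
    // DP rows stored banded: S (score), M (matches on best path),
    // C (aligned columns on best path).
    std::vector<double> Sprev(W), Scur(W);
    std::vector<int> Mprev(W), Mcur(W), Cprev(W), Ccur(W);

    for (int f = 0; f < nf; ++f) {
      const std::string& t = refstr[f];
      const int m = (int)t.size();
      double best = NEG_INF;
      double best_ident = 0.0;

      // row i = 0: leading gaps in the read (consuming the reference).
      for (int w = 0; w < W; ++w) { Sprev[w] = NEG_INF; Mprev[w] = 0; Cprev[w] = 0; }
      for (int j = 0; j <= band && j <= m; ++j) {
        int w = j + band;  // i = 0 -> offset j - (0 - band)
        Sprev[w] = gap * j;
        Mprev[w] = 0;
        Cprev[w] = j;
      }
      if (m <= band) {  // cell (0, m) is on the last column
        double cand = Sprev[m + band];
        if (cand > best) {
          best = cand;
          best_ident = (m == 0) ? 100.0 : 0.0;
        }
      }

      for (int i = 1; i <= n; ++i) {
        const int jlo = std::max(0, i - band);
        const int jhi = std::min(m, i + band);
        for (int w = 0; w < W; ++w) { Scur[w] = NEG_INF; Mcur[w] = 0; Ccur[w] = 0; }
        for (int j = jlo; j <= jhi; ++j) {
          const int w = j - (i - band);
          double s = NEG_INF; int mm = 0, cc = 0;
          if (j > 0) {  // diagonal
            const int wd = (j - 1) - (i - 1 - band);
            if (wd >= 0 && wd < W && Sprev[wd] > NEG_INF) {
              bool is_match = (q[i - 1] == t[j - 1]);
              double cand = Sprev[wd] + (is_match ? match : mismatch);
              if (cand > s) {
                s = cand;
                mm = Mprev[wd] + (is_match ? 1 : 0);
                cc = Cprev[wd] + 1;
              }
            }
          }
          {  // up: gap in reference (consume read base)
            const int wu = j - (i - 1 - band);
            if (wu >= 0 && wu < W && Sprev[wu] > NEG_INF) {
              double cand = Sprev[wu] + gap;
              if (cand > s) { s = cand; mm = Mprev[wu]; cc = Cprev[wu] + 1; }
            }
          }
          if (j > 0) {  // left: gap in read (consume reference base)
            const int wl = (j - 1) - (i - band);
            if (wl >= 0 && wl < W && Scur[wl] > NEG_INF) {
              double cand = Scur[wl] + gap;
              if (cand > s) { s = cand; mm = Mcur[wl]; cc = Ccur[wl] + 1; }
            }
          }
          Scur[w] = s; Mcur[w] = mm; Ccur[w] = cc;
          bool endpoint = (i == n) || (j == m);
          if (endpoint && s > NEG_INF && s >= best) {
            double ident = (cc > 0) ? 100.0 * mm / cc : 100.0;
            if (s > best || ident > best_ident) { best = s; best_ident = ident; }
          }
        }
        std::swap(Sprev, Scur);
        std::swap(Mprev, Mcur);
        std::swap(Cprev, Ccur);
      }

      score_mat(r, f) = best;
      ident_mat(r, f) = best_ident;
    }
  }
  return List::create(_["score"] = score_mat, _["identity"] = ident_mat);
}
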