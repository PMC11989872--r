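#include "gm_common.h"
using namespace Rcpp;

// Seeded local alignment used as the genome-of-origin cross-check. Short
// exact seeds (the index k, typically 11) nominate diagonal groups; each
// group's window is aligned with affine-gap Smith-Waterman (match +2,
// mismatch -3, gap open -5, gap extend -2; a gap of length l costs
// 5 + 2*l). The best-scoring local alignment over all windows and strands is
// reported with its aligned read fraction and percent identity
// (matches / alignment columns * 100).

namespace {

struct LocalHit {
  int score = 0;
  double frac = 0.0, ident = 0.0;
  bool found = false;
};

const int MATCH = 2, MISMATCH = -3, GAP_OPEN = 5, GAP_EXT = 2;

// Full affine SW on read x window with traceback. Sizes are small
// (<= ~160 x ~320), so O(L*W) with byte traceback matrices is cheap.
void sw_window(const std::vector<uint8_t>& rd,
               const std::vector<uint8_t>& ref,
               int winLo, int winHi, LocalHit& best) {
  const int L = (int)rd.size(), W = winHi - winLo;
  if (L == 0 || W <= 0) return;
  const int cols = W + 1;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((L + 1) * cols, 0), E((L + 1) * cols, NEG),
      F((L + 1) * cols, NEG);
  // tbH: 0 stop, 1 diag, 2 from E, 3 from F; tbE/tbF: 1 = opened from H
  std::vector<uint8_t> tbH((L + 1) * cols, 0), tbE((L + 1) * cols, 0),
      tbF((L + 1) * cols, 0);

  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= L; ++i) {
    const int row = i * cols, prow = row - cols;
    for (int j = 1; j <= W; ++j) {
      const int eOpen = H[prow + j] - GAP_OPEN - GAP_EXT;
      const int eExt = E[prow + j] - GAP_EXT;
      E[row + j] = std::max(eOpen, eExt);
      tbE[row + j] = eOpen >= eExt ? 1 : 0;
      const int fOpen = H[row + j - 1] - GAP_OPEN - GAP_EXT;
      const int fExt = F[row + j - 1] - GAP_EXT;
      F[row + j] = std::max(fOpen, fExt);
      tbF[row + j] = fOpen >= fExt ? 1 : 0;
      const int diag = H[prow + j - 1] +
        (gm_match(rd[i - 1], ref[winLo + j - 1]) ? MATCH : MISMATCH);
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[row + j] > h) { h = E[row + j]; t = 2; }
      if (F[row + j] > h) { h = F[row + j]; t = 3; }
      H[row + j] = h; tbH[row + j] = t;
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
  }
  if (bscore <= best.score) return;

  // state-aware traceback counting matches, alignment columns and read span
  int i = bi, j = bj, matches = 0, columnsN = 0, readBases = 0;
  int state = 0;  // 0 = H, 1 = E (gap in ref), 2 = F (gap in read)
  while (i > 0 && j > 0) {
    const int cell = i * cols + j;
    if (state == 0) {
      const uint8_t t = tbH[cell];
      if (t == 0) break;
      if (t == 1) {
        ++columnsN; ++readBases;
        if (gm_match(rd[i - 1], ref[winLo + j - 1])) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columnsN; ++readBases;
      if (tbE[cell]) state = 0;
      --i;
    } else {
      ++columnsN;
      if (tbF[cell]) state = 0;
      --j;
    }
  }
  best.score = bscore;
  best.frac = (double)readBases / (double)L;
  best.ident = columnsN > 0 ? 100.0 * (double)matches / (double)columnsN : 0.0;
  best.found = true;
}

inline std::vector<uint8_t> rc_encoded(const std::vector<uint8_t>& e) {
  std::vector<uint8_t> r(e.rbegin(), e.rend());
  for (auto& b : r) b = (b < GM_CODE_N) ? (uint8_t)(3 - b) : (uint8_t)GM_CODE_N;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List gm_local_search(CharacterVector reads, List index, int pad,
                     int max_groups) {
  const int k = as<int>(index["k"]);
  const std::string concat = as<std::string>(index["concat"]);
  IntegerVector offsets = index["offsets"];
  NumericVector keys = index["keys"];
  IntegerVector kpos = index["pos"];
  const int nchrom = offsets.size() - 1;

  std::vector<uint8_t> ref;
  gm_encode(concat, ref);
  const double* kb = keys.size() ? &keys[0] : nullptr;
  const size_t nk = keys.size();

  const int n = reads.size();
  IntegerVector oScore(n, 0);
  NumericVector oFrac(n, 0.0), oIdent(n, 0.0);
  LogicalVector oFound(n, false);

  for (int r = 0; r < n; ++r) {
    const std::string rstr = as<std::string>(reads[r]);
    const int L = (int)rstr.size();
    if (L < k || nk == 0) continue;
    std::vector<uint8_t> fwd;
    gm_encode(rstr, fwd);
    std::vector<uint8_t> rev = rc_encoded(fwd);

    LocalHit best;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t>& rd = (strand == 0) ? fwd : rev;
      std::vector<std::pair<int, int>> diags;  // (diag, chrom)
      for (int off = 0; off <= L - k; off += k) {
        uint64_t key = 0; bool ok = true;
        for (int x = 0; x < k; ++x) {
          if (rd[off + x] >= GM_CODE_N) { ok = false; break; }
          key = (key << 2) | rd[off + x];
        }
        if (!ok) continue;
        const double dk = (double)key;
        const double* lo = std::lower_bound(kb, kb + nk, dk);
        const double* hi = std::upper_bound(lo, kb + nk, dk);
        for (const double* it = lo; it != hi; ++it) {
          const int p = kpos[it - kb];
          int c = (int)(std::upper_bound(offsets.begin(), offsets.end(), p)
                        - offsets.begin()) - 1;
          diags.push_back({p - off, c});
        }
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      // group nearby diagonals on the same chromosome into one window
      int groups = 0;
      size_t a = 0;
      while (a < diags.size() && groups < max_groups) {
        size_t b = a;
        while (b + 1 < diags.size() &&
               diags[b + 1].second == diags[a].second &&
               diags[b + 1].first - diags[b].first <= 2 * pad) ++b;
        const int c = diags[a].second;
        const int lo = offsets[c], hi = offsets[c + 1];
        const int winLo = std::max(lo, diags[a].first - pad);
        const int winHi = std::min(hi, diags[b].first + L + pad);
        sw_window(rd, ref, winLo, winHi, best);
        a = b + 1;
        ++groups;
      }
    }
    if (best.found) {
      oScore[r] = best.score;
      oFrac[r] = best.frac;
      oIdent[r] = best.ident;
      oFound[r] = true;
    }
  }
  (void)nchrom;
  return List::create(_["found"] = oFound, _["score"] = oScore,
                      _["aligned_fraction"] = oFrac, _["identity"] = oIdent);
}
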