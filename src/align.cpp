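#include "gm_common.h"
using namespace Rcpp;

// Bounded-edit-distance semi-global alignment (read fully consumed, reference
// local) with k-mer seeding and banded verification. Seeds are tiled across
// the read at stride k plus a tail seed at L-k; by the pigeonhole principle an
// alignment with at most `me` edits contains an exact segment of length
// ceil((L-me)/(me+1)), and any such segment of length >= 2k-1 contains a
// tiled seed, so the candidate set is complete whenever the read is long
// enough. Shorter reads fall back to a full dynamic-programming scan, which
// is exact by construction. Every alignment with ed <= me generates its own
// candidate diagonal, so per-candidate verification windows of +/- me around
// the seed diagonal cover the full hit space.

namespace {

const int GM_INF = 1 << 28;
const uint64_t HASH_EMPTY = ~0ULL;

inline uint64_t mix64(uint64_t x) {
  x ^= x >> 33; x *= 0xFF51AFD7ED558CCDULL;
  x ^= x >> 33; x *= 0xC4CEB9FE1A85EC53ULL;
  x ^= x >> 33; return x;
}

// Open-addressing hash over the sorted (key, pos) arrays of the index:
// key -> contiguous range in the position array.
struct SeedHash {
  std::vector<uint64_t> hkey;
  std::vector<int> hstart, hcount;
  uint64_t mask = 0;
  void build(const double* keys, int n) {
    size_t cap = 16;
    while (cap < (size_t)n * 2 + 2) cap <<= 1;
    hkey.assign(cap, HASH_EMPTY);
    hstart.assign(cap, 0);
    hcount.assign(cap, 0);
    mask = cap - 1;
    int i = 0;
    while (i < n) {
      const uint64_t k = (uint64_t)keys[i];
      int j = i;
      while (j < n && (uint64_t)keys[j] == k) ++j;
      uint64_t h = mix64(k) & mask;
      while (hkey[h] != HASH_EMPTY) h = (h + 1) & mask;
      hkey[h] = k; hstart[h] = i; hcount[h] = j - i;
      i = j;
    }
  }
  inline bool find(uint64_t k, int& s, int& c) const {
    uint64_t h = mix64(k) & mask;
    while (hkey[h] != HASH_EMPTY) {
      if (hkey[h] == k) { s = hstart[h]; c = hcount[h]; return true; }
      h = (h + 1) & mask;
    }
    return false;
  }
};

struct Best {
  int ed, chrom, start, strand;  // strand: 0 = '+', 1 = '-'
  Best() : ed(GM_INF), chrom(INT_MAX), start(INT_MAX), strand(INT_MAX) {}
  void update(int e, int c, int s, int st) {
    if (e < ed || (e == ed && (c < chrom || (c == chrom && (s < start ||
        (s == start && st < strand)))))) {
      ed = e; chrom = c; start = s; strand = st;
    }
  }
};

// Reusable DP workspace, sized once per call.
struct Workspace {
  std::vector<int> dpPrev, dpCur, stPrev, stCur;
  std::vector<uint8_t> fwd, rev;
  void reserve_band(int width) {
    if ((int)dpPrev.size() < width) {
      dpPrev.resize(width); dpCur.resize(width);
      stPrev.resize(width); stCur.resize(width);
    }
  }
};

// Banded semi-global DP in window [winLo, winHi): alignment start restricted
// to the first 2*me+1 columns, band keeps j - i within [-me, 3*me]. Exact
// for every alignment with <= me edits starting within +/- me of the window
// anchor. Abandons when the running row minimum exceeds `cutoff`.
void banded_verify(const std::vector<uint8_t>& rd,
                   const std::vector<uint8_t>& ref,
                   int winLo, int winHi, int me, int cutoff,
                   Workspace& ws, int& outEd, int& outStart) {
  const int L = (int)rd.size();
  const int W = winHi - winLo;
  outEd = GM_INF; outStart = INT_MAX;
  if (W < L - me) return;
  ws.reserve_band(W + 2);
  int* dpPrev = ws.dpPrev.data(); int* dpCur = ws.dpCur.data();
  int* stPrev = ws.stPrev.data(); int* stCur = ws.stCur.data();
  const int startCols = std::min(2 * me, W);
  for (int j = 0; j <= std::min(W, startCols + 3 * me + 1); ++j) {
    dpPrev[j] = (j <= startCols) ? 0 : GM_INF;
    stPrev[j] = (j <= startCols) ? j : INT_MAX;
  }
  for (int i = 1; i <= L; ++i) {
    const int jlo = std::max(0, i - me), jhi = std::min(W, i + 3 * me);
    // clear one past each band edge so the next row never reads stale cells
    for (int j = std::max(0, jlo - 1); j <= std::min(W, jhi + 1); ++j) {
      dpCur[j] = GM_INF; stCur[j] = INT_MAX;
    }
    int rowMin = GM_INF;
    if (jlo == 0 && dpPrev[0] < GM_INF) {
      dpCur[0] = dpPrev[0] + 1; stCur[0] = stPrev[0];
      rowMin = dpCur[0];
    }
    const uint8_t rb = rd[i - 1];
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      const int sub = dpPrev[j - 1] + (gm_match(rb, ref[winLo + j - 1]) ? 0 : 1);
      int bestv = sub, bests = stPrev[j - 1];
      const int del = dpCur[j - 1] + 1;          // gap in read (skip ref base)
      if (del < bestv || (del == bestv && stCur[j - 1] < bests)) {
        bestv = del; bests = stCur[j - 1];
      }
      const int ins = dpPrev[j] + 1;             // gap in ref (skip read base)
      if (ins < bestv || (ins == bestv && stPrev[j] < bests)) {
        bestv = ins; bests = stPrev[j];
      }
      dpCur[j] = bestv; stCur[j] = bests;
      if (bestv < rowMin) rowMin = bestv;
    }
    if (rowMin > cutoff) return;  // cannot recover: edits only accumulate
    std::swap(dpPrev, dpCur);
    std::swap(stPrev, stCur);
  }
  const int jlo = std::max(0, L - me), jhi = std::min(W, L + 3 * me);
  for (int j = jlo; j <= jhi; ++j) {
    if (dpPrev[j] < outEd || (dpPrev[j] == outEd && stPrev[j] < outStart)) {
      outEd = dpPrev[j]; outStart = stPrev[j];
    }
  }
  if (outStart != INT_MAX) outStart += winLo;
}

// Full semi-global scan over [lo, hi): exact minimal edit distance with
// leftmost-start tie-break. O(L * n) with start tracking; used for reads too
// short for the pigeonhole guarantee.
void full_scan(const std::vector<uint8_t>& rd,
               const std::vector<uint8_t>& ref,
               int lo, int hi, int& outEd, int& outStart) {
  const int L = (int)rd.size();
  const int n = hi - lo;
  outEd = GM_INF; outStart = INT_MAX;
  if (n <= 0) { outEd = L; outStart = lo; return; }
  std::vector<int> dpPrev(n + 1), dpCur(n + 1);
  std::vector<int> stPrev(n + 1), stCur(n + 1);
  for (int j = 0; j <= n; ++j) { dpPrev[j] = 0; stPrev[j] = j; }
  for (int i = 1; i <= L; ++i) {
    dpCur[0] = dpPrev[0] + 1; stCur[0] = stPrev[0];
    for (int j = 1; j <= n; ++j) {
      const int sub = dpPrev[j - 1] +
        (gm_match(rd[i - 1], ref[lo + j - 1]) ? 0 : 1);
      int bestv = sub, bests = stPrev[j - 1];
      const int del = dpCur[j - 1] + 1;
      if (del < bestv || (del == bestv && stCur[j - 1] < bests)) {
        bestv = del; bests = stCur[j - 1];
      }
      const int ins = dpPrev[j] + 1;
      if (ins < bestv || (ins == bestv && stPrev[j] < bests)) {
        bestv = ins; bests = stPrev[j];
      }
      dpCur[j] = bestv; stCur[j] = bests;
    }
    std::swap(dpPrev, dpCur);
    std::swap(stPrev, stCur);
  }
  for (int j = 0; j <= n; ++j) {
    if (dpPrev[j] < outEd || (dpPrev[j] == outEd && stPrev[j] < outStart)) {
      outEd = dpPrev[j]; outStart = stPrev[j];
    }
  }
  if (outStart != INT_MAX) outStart += lo;
}

inline void rc_encode(const std::vector<uint8_t>& e, std::vector<uint8_t>& r) {
  r.assign(e.rbegin(), e.rend());
  for (auto& b : r) b = (b < GM_CODE_N) ? (uint8_t)(3 - b) : (uint8_t)GM_CODE_N;
}

}  // namespace

// [[Rcpp::export]]
List gm_align_reads(CharacterVector reads, List index, int max_ed) {
  if (max_ed < 0) stop("max_ed must be >= 0");
  const int k = as<int>(index["k"]);
  const std::string concat = as<std::string>(index["concat"]);
  IntegerVector offsets = index["offsets"];
  NumericVector keys = index["keys"];
  IntegerVector kpos = index["pos"];
  const int nchrom = offsets.size() - 1;

  std::vector<uint8_t> ref;
  gm_encode(concat, ref);
  SeedHash hash;
  hash.build(keys.size() ? &keys[0] : nullptr, keys.size());
  const int* posArr = kpos.size() ? &kpos[0] : nullptr;
  const int* offArr = &offsets[0];

  const int n = reads.size();
  IntegerVector oEd(n, NA_INTEGER), oChrom(n, NA_INTEGER),
      oStart(n, NA_INTEGER), oStrand(n, NA_INTEGER);

  Workspace ws;
  std::vector<std::pair<int, int>> cands;  // (diag, chrom)
  std::vector<int> seedOffs;

  for (int r = 0; r < n; ++r) {
    const char* cs = CHAR(STRING_ELT(reads, r));
    int L = 0; while (cs[L]) ++L;
    if (L == 0) continue;
    ws.fwd.resize(L);
    for (int i = 0; i < L; ++i) ws.fwd[i] = (uint8_t)gm_code(cs[i]);
    rc_encode(ws.fwd, ws.rev);

    Best best;
    int best_concat = INT_MAX;  // concat coordinate of the best start
    // pigeonhole: an alignment with <= max_ed edits contains an exact
    // segment of at least g read bases
    const int g = (int)std::ceil((double)(L - max_ed) / (double)(max_ed + 1));
    const bool seedable = (L >= k) && (g >= 2 * k - 1) && keys.size() > 0;

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t>& rd = (strand == 0) ? ws.fwd : ws.rev;
      if (!seedable) {
        for (int c = 0; c < nchrom; ++c) {
          int ed, st;
          full_scan(rd, ref, offArr[c], offArr[c + 1], ed, st);
          if (ed <= max_ed) {
            best.update(ed, c, st - offArr[c], strand);
            best_concat = offArr[best.chrom] + best.start;
          }
        }
        continue;
      }
      // tiled seed offsets: multiples of k plus the tail seed L-k
      seedOffs.clear();
      for (int off = 0; off + k <= L; off += k) seedOffs.push_back(off);
      if (seedOffs.empty() || seedOffs.back() != L - k)
        seedOffs.push_back(L - k);
      cands.clear();
      for (int off : seedOffs) {
        uint64_t key = 0; bool ok = true;
        for (int x = 0; x < k; ++x) {
          if (rd[off + x] >= GM_CODE_N) { ok = false; break; }
          key = (key << 2) | rd[off + x];
        }
        if (!ok) continue;
        int s, c;
        if (hash.find(key, s, c)) {
          for (int t = 0; t < c; ++t) {
            const int p = posArr[s + t];
            int ci = (int)(std::upper_bound(offArr, offArr + nchrom + 1, p)
                           - offArr) - 1;
            cands.push_back({p - off, ci});
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (const auto& dc : cands) {
        const int diag = dc.first, c = dc.second;
        // candidates are in ascending concat order; once a perfect hit is
        // held, a later diagonal can only matter while its window (which
        // reaches back max_ed columns) can still touch a smaller start
        if (best.ed == 0 && diag - max_ed > best_concat) break;
        const int lo = offArr[c], hi = offArr[c + 1];
        int ed = GM_INF, st = INT_MAX;
        // exact-diagonal fast path: zero mismatches means edit distance 0
        if (diag >= lo && diag + L <= hi) {
          int h = 0;
          for (int i = 0; i < L && h == 0; ++i) {
            if (!gm_match(rd[i], ref[diag + i])) h = 1;
          }
          if (h == 0) { ed = 0; st = diag; }
        }
        if (ed != 0) {
          const int winLo = std::max(lo, diag - max_ed);
          const int winHi = std::min(hi, diag + L + max_ed);
          banded_verify(rd, ref, winLo, winHi, max_ed, max_ed, ws, ed, st);
        }
        if (ed <= max_ed) {
          best.update(ed, c, st - lo, strand);
          best_concat = offArr[best.chrom] + best.start;
        }
      }
    }

    if (best.ed <= max_ed) {
      oEd[r] = best.ed;
      oChrom[r] = best.chrom + 1;
      oStart[r] = best.start;
      oStrand[r] = best.strand + 1;
    }
  }

  return List::create(_["edit_distance"] = oEd, _["chrom"] = oChrom,
                      _["start"] = oStart, _["strand"] = oStrand);
}
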