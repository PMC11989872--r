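#ifndef GM_COMMON_H
#define GM_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

// Deterministic RNG independent of the C++ standard library's distribution
// implementations: xoshiro256** seeded via splitmix64. All derived draws
// (uniform doubles, bounded ints, normals) are implemented explicitly so that
// a fixed seed yields identical streams for a given build.
struct GmRng {
  uint64_t s[4];
  explicit GmRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline uint64_t bounded(uint64_t n) {  // [0, n), modulo bias negligible here
    return n ? next() % n : 0;
  }
  inline double normal(double mean, double sd) {  // Box-Muller
    double u1 = unif(), u2 = unif();
    if (u1 <= 0) u1 = 0x1.0p-53;
    return mean + sd * std::sqrt(-2.0 * std::log(u1)) *
                       std::cos(2.0 * M_PI * u2);
  }
};

// A/C/G/T -> 0..3, anything else -> 4 (never matches, including against
// itself: N vs N is a mismatch for edit-distance purposes).
static const int GM_CODE_N = 4;

inline int gm_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return GM_CODE_N;
  }
}

inline char gm_comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

inline std::string gm_revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = gm_comp(c);
  return r;
}

inline void gm_encode(const std::string& s, std::vector<uint8_t>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (uint8_t)gm_code(s[i]);
}

inline bool gm_match(uint8_t a, uint8_t b) {
  return a == b && a < GM_CODE_N;
}

#endif
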