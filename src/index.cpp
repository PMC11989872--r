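#include "gm_common.h"
using namespace Rcpp;

// Build a k-mer position index over the forward strand of a set of
// chromosomes. Chromosomes are concatenated; k-mers that would span a
// chromosome boundary or contain an ambiguous base are skipped. The reverse
// strand is searched at query time by reverse-complementing the read, which
// covers the same hit space as indexing both strands.
//
// Returns a plain R list (numeric/integer vectors only) so that identical
// references serialize to identical objects.
// [[Rcpp::export]]
List gm_build_index(CharacterVector seqs, int k) {
  const int nchrom = seqs.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");

  std::string concat;
  IntegerVector offsets(nchrom + 1);
  for (int i = 0; i < nchrom; ++i) {
    offsets[i] = (int)concat.size();
    concat += std::string(seqs[i]);
  }
  offsets[nchrom] = (int)concat.size();

  std::vector<uint8_t> enc;
  gm_encode(concat, enc);

  std::vector<std::pair<uint64_t, int>> kmers;
  kmers.reserve(enc.size());
  for (int c = 0; c < nchrom; ++c) {
    const int lo = offsets[c], hi = offsets[c + 1];
    if (hi - lo < k) {
      if (hi - lo > 0 && nchrom == 1)
        stop("reference sequence shorter than k");
      continue;
    }
    uint64_t key = 0; int run = 0;
    for (int p = lo; p < hi; ++p) {
      const uint8_t b = enc[p];
      if (b >= GM_CODE_N) { run = 0; key = 0; continue; }
      key = ((key << 2) | b) & ((k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL);
      if (++run >= k) kmers.push_back({key, p - k + 1});
    }
  }
  if (kmers.empty() && nchrom > 0) {
    int maxlen = 0;
    for (int i = 0; i < nchrom; ++i)
      maxlen = std::max(maxlen, offsets[i + 1] - offsets[i]);
    if (maxlen < k) stop("reference sequence shorter than k");
  }
  std::sort(kmers.begin(), kmers.end());

  NumericVector keys(kmers.size());
  IntegerVector pos(kmers.size());
  for (size_t i = 0; i < kmers.size(); ++i) {
    keys[i] = (double)kmers[i].first;  // k <= 31 -> fits exactly in a double
    pos[i] = kmers[i].second;
  }

  return List::create(
    _["k"] = k,
    _["concat"] = concat,
    _["offsets"] = offsets,
    _["keys"] = keys,
    _["pos"] = pos,
    _["n_kmers"] = (double)kmers.size());
}
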