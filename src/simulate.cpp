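#include "gm_common.h"
using namespace Rcpp;

// Paired-end fragment simulator. For each transcript i, counts[i] fragments
// are drawn: fragment length ~ round(Normal(mean, sd)) clamped to
// [read_len, transcript length], start uniform. Mate 1 is the fragment's
// 5' read_len bases, mate 2 the reverse complement of its 3' read_len bases;
// with probability 1/2 the mates are swapped (non-strand-specific library).
// Substitution errors are i.i.d. per base at error_rate; erroneous bases get
// the low quality character, all others the high one, so quality strings
// reflect the error model while keeping mean phred well above the QC cutoff.
// [[Rcpp::export]]
List gm_simulate_reads(CharacterVector transcripts, IntegerVector counts,
                       int read_len, double fraglen_mean, double fraglen_sd,
                       double error_rate, int qual_hi, int qual_lo,
                       double seed) {
  if (transcripts.size() != counts.size())
    stop("transcripts and counts must have equal length");
  GmRng rng((uint64_t)seed);

  int total = 0;
  for (int i = 0; i < counts.size(); ++i) {
    if (counts[i] < 0) stop("negative fragment count");
    total += counts[i];
  }

  CharacterVector seq1(total), qual1(total), seq2(total), qual2(total);
  IntegerVector txIdx(total), fragStart(total), fragLen(total);
  const char qhi = (char)(qual_hi + 33), qlo = (char)(qual_lo + 33);

  std::string s1, s2, q1, q2;
  int out = 0;
  for (int i = 0; i < transcripts.size(); ++i) {
    if (counts[i] == 0) continue;
    const std::string tx = as<std::string>(transcripts[i]);
    const int tlen = (int)tx.size();
    if (tlen < read_len)
      stop("transcript shorter than read length at index %d", i + 1);
    for (int f = 0; f < counts[i]; ++f) {
      int fl = (int)std::lround(rng.normal(fraglen_mean, fraglen_sd));
      fl = std::max(read_len, std::min(fl, tlen));
      const int start = (int)rng.bounded((uint64_t)(tlen - fl + 1));
      s1.assign(tx, start, read_len);
      s2 = gm_revcomp(tx.substr(start + fl - read_len, read_len));
      if (rng.unif() < 0.5) std::swap(s1, s2);
      q1.assign(read_len, qhi);
      q2.assign(read_len, qhi);
      for (int b = 0; b < read_len; ++b) {
        if (rng.unif() < error_rate) {
          const int cur = gm_code(s1[b]);
          int sub = (int)rng.bounded(3);
          if (cur < GM_CODE_N && sub >= cur) ++sub;  // pick a different base
          s1[b] = "ACGT"[sub % 4];
          q1[b] = qlo;
        }
        if (rng.unif() < error_rate) {
          const int cur = gm_code(s2[b]);
          int sub = (int)rng.bounded(3);
          if (cur < GM_CODE_N && sub >= cur) ++sub;
          s2[b] = "ACGT"[sub % 4];
          q2[b] = qlo;
        }
      }
      seq1[out] = s1; qual1[out] = q1;
      seq2[out] = s2; qual2[out] = q2;
      txIdx[out] = i + 1;
      fragStart[out] = start;
      fragLen[out] = fl;
      ++out;
    }
  }

  return List::create(_["seq1"] = seq1, _["qual1"] = qual1,
                      _["seq2"] = seq2, _["qual2"] = qual2,
                      _["tx_idx"] = txIdx, _["frag_start"] = fragStart,
                      _["frag_len"] = fragLen);
}

// Mean phred score (offset 33) per quality string.
// [[Rcpp::export]]
NumericVector gm_mean_phred(CharacterVector quals) {
  const int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    long sum = 0; int len = 0;
    for (; q[len]; ++len) sum += q[len] - 33;
    out[i] = len ? (double)sum / (double)len : 0.0;
  }
  return out;
}

// Fraction of bases that are not A/C/G/T per sequence.
// [[Rcpp::export]]
NumericVector gm_frac_n(CharacterVector seqs) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = 0, bad = 0;
    for (; s[len]; ++len)
      if (gm_code(s[len]) >= GM_CODE_N) ++bad;
    out[i] = len ? (double)bad / (double)len : 0.0;
  }
  return out;
}
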