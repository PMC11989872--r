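---
title: "Detecting graft-mobile mRNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-mobile mRNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a heterografted plant, two genotypes share one vascular system: a scion
(here, a cultivated-tomato-like genotype) grows on the rootstock of a wild
relative. Some mRNAs transcribed in one partner travel through the phloem and
are detectable in the tissues of the other. Because the two genomes differ at
a few percent of sites, bulk RNA-seq of a grafted tissue contains a small
minority of reads whose sequence betrays a foreign genome of origin; finding
the genes behind those reads, without being fooled by sequencing errors or by
regions the genomes share, is the task this package automates.

The sampling design is "one grafted plant, three samples": scion leaf (HL),
rootstock root (RR) and the leaf of a lateral branch left on the rootstock
(RL), each under control (CK) and drought conditions with three biological
replicates (18 samples). Upward mobility is rootstock-to-scion (detected in
HL); downward is scion-to-rootstock (detected in RR and/or RL).

## The classification pipeline

Per sample, after a read QC filter (mean phred strictly above 20, at most
10% ambiguous bases):

1. **Native first pass.** Reads are aligned to the tissue's own genotype
   ("native") with a semi-global bounded-edit-distance aligner: a read maps
   iff some location on either strand aligns the *whole* read within
   Levenshtein distance `k_first = 2`. Mapped reads feed gene-level counts
   and TPM; unmapped reads are the candidate pool.
2. **Cross-check.** Each unmapped read is searched against *both* genomes
   with a seeded local aligner (match +2, mismatch −3, gap open −5, gap
   extend −2). A genome "hits" the read if the best local alignment covers
   ≥ 90% of the read at ≥ 97.5% identity. A read hitting the foreign genome
   only becomes a candidate mobile read (set A for upward, A′ for downward);
   *any* native hit makes it a false positive (B/B′); no hit discards it.
3. **Foreign second pass.** Candidate reads are re-aligned to the foreign
   genome at the stricter `k_second = 1`; reads that map are retained (C/C′)
   and accumulated into per-gene support counts (toward gene sets D/D′).
4. **Calling.** A gene is called mobile in a tissue × condition group iff it
   has ≥ `min_reads_per_gene = 2` retained reads in ≥ `min_replicates = 2`
   of 3 replicates, *and* it is expressed in the source tissue (raw count
   ≥ 5 in ≥ 2 source replicates) — the E/E′ exclusion that removes genes
   whose apparent mobility cannot be backed by transcription at the source.
   For downward calls the source is HL; for upward calls, the rootstock
   tissues (RR or RL).

Downward calls are then partitioned along the transport model
HL → RR → RL: genes in both RR and RL moved through the root; genes in RL
only reached the distal leaf without detectable root passage; genes in RR
only are inferred degraded (or diluted below detection) in transit. The
inference is purely set-theoretic — no decay kinetics are fitted, because
the claim being reproduced is set-membership, not a rate.

## Why the cross-check thresholds are 90% coverage / 97.5% identity

The cross-check must arbitrate between two read populations that both fail
the native first pass: (a) native reads carrying ≥ 3 sequencing errors and
(b) genuinely foreign reads. With a per-base error rate around 10⁻³, an
error-laden native read still aligns to its own genome at ≈ 98% identity or
better; a foreign read's best *native* alignment is its cross-genotype
homolog at ≈ 100 × (1 − divergence) ≈ 95% identity, while its foreign
alignment is near-perfect. A threshold at 97.5% identity over ≥ 90% of the
read therefore sends error reads to the false-positive set B (native hit)
and foreign reads to the candidate set A (foreign-only hit), with a small,
measurable leak of foreign reads whose local homology is atypically high.
Much looser thresholds (say, 80% identity at 50% coverage) would make every
cross-genotype homolog a "native hit" and extinguish the candidate set
entirely — on genomes that are homologous end-to-end, the arbitration power
lives in this margin. Both thresholds are `pipeline_params()` arguments.

The second pass at edit distance ≤ 1 is the decisive precision guard: a
native read needs ≥ 4 errors to dodge the native hit at 97.5% identity, and
such a read cannot then sit within one edit of the foreign genome at 5%
divergence. In 20 simulated experiments with no spiked genes, the pipeline
makes zero calls.

## The alignment core

The bounded-edit-distance aligner is exact, not heuristic: seeds of length
21 are tiled across the read at stride 21 (plus a tail seed), and by the
pigeonhole principle any alignment with ≤ k edits contains an exact segment
of ⌈(L−k)/(k+1)⌉ ≥ 41 bases for 150-nt reads, which always contains a tiled
seed. Every candidate diagonal is verified with a banded
dynamic-programming pass that is exact for alignments within the band; reads
too short for the guarantee fall back to a full DP scan over the reference.
Equal-distance hits are broken deterministically (lowest chromosome, start,
then + strand). The test suite checks the reported minimal distances against
an independent brute-force semi-global DP oracle on 1,000+ randomized
instances, plus monotonicity (the k = 1 mapped set is contained in the
k = 2 set) and strand symmetry.

Mates are classified independently; gene-level evidence requires at least
two retained reads per replicate, which absorbs mate-level noise without a
fragment-concordance model.

## The synthetic heterograft generator

`generate_dataset()` builds the study conditions end to end:

* **Genomes.** A scion genotype of intronless genes (default 300 genes of
  500–2,000 nt on 3 chromosomes, 200–400 nt spacers) and a rootstock
  genotype derived from it by i.i.d. substitutions at rate 0.05 per site
  plus single-base indels at 5 × 10⁻⁴ — the cultivated-by-wild scale of
  divergence at which the pipeline's separation logic is designed to work
  while leaving some reads ambiguous. Gene models are lifted through the
  indels; the generator suppresses indels on gene boundaries so any seed
  yields a valid pair (a deletion destroying a boundary in an unprotected
  call is an error naming the gene).
* **Expression.** Per tissue × condition, log-normal TPM profiles
  (baseline sdlog 1.5 per gene, shared across tissues and between homologs;
  tissue/condition deviation sdlog 0.4), normalised to 10⁶.
* **Mobility.** 10% of scion genes are spiked downward and 1/30 of
  rootstock genes upward. Downward genes split deterministically into the
  three transport classes (34% RL-direct, 33% RR-only, the rest both —
  mirroring the proportions reported for real heterograft data); 25% of
  mobile genes are drought-specific. Sink abundance is uniform on a TPM
  interval (default 0.5–50; the recovery analyses use 2–50), consistent
  with mobility being abundance-independent, so low-abundance recovery is
  genuinely exercised.
* **Reads.** 150-bp paired-end fragments (length ~N(300, 30²)), multinomial
  over the sample's transcript pool weighted by TPM × length, substitution
  errors at 10⁻³ per base. Quality strings mirror the error model (high
  phred on correct bases, low on erroneous ones) so the QC filter passes
  essentially all simulated reads. One master seed; every stage draws from
  a named sub-seed, so adding a stage never perturbs earlier streams, and a
  fixed seed gives byte-identical FASTQ/TSV/JSON output for a given build.

What the simulator does *not* model — splicing, PCR duplication, GC bias,
strand-specific chemistry, adapter contamination, structural variation,
condition-dependent differential expression of non-mobile genes — bounds
what passing tests can show: they validate the set algebra, the alignment
semantics, the false-positive control and the power analysis below on data
whose noise structure is idealised, not the pipeline's robustness to
library artefacts in real tissue.

## Problem sizes and statistical power

The default `fragments_per_sample = 500000` follows from a power
calculation done at design time. With TPM normalised to 10⁶, a sink
transcript at TPM *t* contributes about `2F·t/10⁶` reads per replicate
(two mates per fragment), of which ~85% survive the first-pass loss
(P[Binom(150, 0.05) ≤ 2] ≈ 1.8% of foreign reads map natively), the
cross-check leak (~10%) and the second-pass error loss (~1%). At the
spike floor t = 2 this gives λ ≈ 1.7 supporting reads per replicate —
exactly the regime where the 2-reads-in-2-of-3-replicates rule starts to
fire reliably, especially for genes present in several tissue × condition
groups. The recovery analysis in the test suite runs the full 18-sample
design at these defaults (≈ 18M reads); the zero-mobile negative control
runs 20 seeds at a reduced size (80 genes, 15,000 fragments per sample),
because the property it checks — that no native read survives both the
cross-check and the one-edit second pass — does not depend on depth.

## Quantification and the abundance question

Gene counts are best-hit (no fractional multi-mapping), matching the
aligner's single-best-hit contract; TPM is computed per sample as
`(c/L[kb]) / Σ(c/L[kb]) × 10⁶`. Source abundance is summarised in six
classes — (0,1], (1,10], (10,100], (100,500], (500,1000], >1000; the
(100,500] interval is restored by construction where published class lists
omit it. The claim that mobility is independent of abundance is made
testable with a permutation rank-sum test: the observed rank-sum of mobile
genes' source TPM against ≥ 1,000 label permutations, two-sided around the
null mean, plus the overlap between the mobile set and the 100 most
abundant genes. Under a null where the mobile set is drawn uniformly, the
permutation p-values are uniform (checked by a KS test over 100
simulations); a mobile set equal to the top-100 most abundant genes yields
overlap 100 and p < 0.01.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive in gene tables and GFF3 (converted to
  0-based internally); alignment starts are reported 0-based.
* N bases never match anything, including other Ns, in both the aligner and
  the QC fraction rule.
* An all-zero count vector yields all-zero TPM without error; an empty read
  set passes QC as an empty result with a zeroed report.
* Multi-transcript genes take the exon-length of their longest transcript
  as the TPM length; a gene without annotated exons uses its full span.
* Tie-breaks everywhere are deterministic and documented (alignment:
  lowest chromosome/start/+ strand; gene assignment: first overlapping gene
  in coordinate order).

## Known limitations

Homograft control samples are not modelled: the false-positive sets B/B′
derive from cross-searching the sample's own genotype reference, which is
how the design operationalises them. The graft union itself is never
sampled, so "RL-direct" transport is a statement about detection sets, not
anatomy. Read-level (not fragment-level) classification slightly
double-counts evidence when both mates of one fragment are retained — the
per-gene floor of two reads deliberately sits at this granularity. The
edit-distance caps are calibrated for 150-nt reads at percent-scale
divergence; much shorter reads shift all the operating points.
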