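#' Build a k-mer alignment index over a reference
#'
#' Indexes every forward-strand k-mer position of the reference (the reverse
#' strand is searched at query time by reverse-complementing the read, which
#' spans the same hit space). The index is a plain list of atomic vectors, so
#' identical references serialize to identical indexes.
#'
#' @param reference A [genotype_reference()].
#' @param k Seed length in `[11, 31]`; default 21.
#' @return An object of class `alignment_index`.
#' @export
build_index <- function(reference, k = 21L) {
  stopifnot(inherits(reference, "genotype_reference"))
  if (k < 11L || k > 31L) abort("k must be in [11, 31]")
  idx <- gm_build_index(unname(reference$sequences), as.integer(k))
  structure(list(
    genotype_id = reference$genotype_id,
    k = as.integer(k),
    chrom_names = names(reference$sequences),
    n_kmers = idx$n_kmers,
    core = idx), class = "alignment_index")
}

#' @export
print.alignment_index <- function(x, ...) {
  cat(sprintf("<alignment_index> %s: k=%d, %s k-mer positions\n",
              x$genotype_id, x$k, format(x$n_kmers, big.mark = ",")))
  invisible(x)
}

# First overlapping gene in (chromosome, start) order; genes are effectively
# disjoint in this pipeline, so the rule only breaks rare boundary ties.
assign_gene_ids <- function(chromosome, start0, width, genes) {
  out <- rep(NA_character_, length(chromosome))
  if (nrow(genes) == 0L || length(chromosome) == 0L) return(out)
  hs <- start0 + 1L          # 1-based hit start
  he <- start0 + width       # 1-based hit end (approximate ref span)
  for (ch in unique(chromosome)) {
    g <- genes[genes$chromosome == ch, ]
    sel <- which(chromosome == ch)
    if (nrow(g) == 0L) next
    idx <- findInterval(hs[sel], g$start)
    ov1 <- idx >= 1L & ifelse(idx >= 1L, g$end[pmax(idx, 1L)], 0L) >= hs[sel]
    nxt <- idx + 1L
    ov2 <- nxt <= nrow(g) & g$start[pmin(nxt, nrow(g))] <= he[sel]
    pick <- ifelse(ov1, idx, ifelse(ov2, nxt, NA_integer_))
    out[sel] <- ifelse(is.na(pick), NA_character_, g$gene_id[pick])
  }
  out
}

#' Map reads to a reference with a bounded edit distance
#'
#' Semi-global alignment: the read is fully consumed, the reference locally.
#' A read is mapped iff some location (either strand) aligns with Levenshtein
#' edit distance at most `max_edit_distance`; the minimal edit distance is
#' reported with one best hit per read (ties broken deterministically by
#' lowest chromosome, start, then + strand first). Hits are annotated with
#' the overlapped gene, if any.
#'
#' @param reads Read tibble (columns `read_id`, `sequence`) or a named
#'   character vector of sequences.
#' @param index An [build_index()] object for the reference.
#' @param reference The matching [genotype_reference()] (used for gene
#'   annotation); may be `NULL` to skip gene assignment.
#' @param max_edit_distance Maximum tolerated edit distance (k1 = 2 for the
#'   native first pass, k2 = 1 for the foreign second pass).
#' @return A list with `hits` (tibble: `read_id`, `genotype_id`,
#'   `chromosome`, `start` 0-based, `strand`, `edit_distance`, `width`,
#'   `gene_id`) and `unmapped` (character vector of read ids). Together they
#'   partition the input.
#' @export
align_reads <- function(reads, index, reference = NULL,
                        max_edit_distance = 2L) {
  stopifnot(inherits(index, "alignment_index"))
  if (is.character(reads)) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    seqs <- unname(reads)
  } else {
    reads <- as_tibble(reads)
    ids <- read_keys(reads)
    seqs <- reads$sequence
  }
  res <- gm_align_reads(seqs, index$core, as.integer(max_edit_distance))
  mapped <- !is.na(res$edit_distance)
  hits <- tibble(
    read_id = ids[mapped],
    genotype_id = index$genotype_id,
    chromosome = index$chrom_names[res$chrom[mapped]],
    start = res$start[mapped],
    strand = c("+", "-")[res$strand[mapped]],
    edit_distance = res$edit_distance[mapped],
    width = nchar(seqs[mapped]))
  hits$gene_id <- if (!is.null(reference)) {
    assign_gene_ids(hits$chromosome, hits$start, hits$width,
                    reference$genes)
  } else {
    NA_character_
  }
  list(hits = hits, unmapped = ids[!mapped])
}

#' Arbitrate unmapped reads between the two genomes by local alignment
#'
#' A seeded Smith-Waterman search (match +2, mismatch -3, gap open -5, gap
#' extend -2) against each reference. A reference "hits" a read iff the best
#' local alignment covers at least `min_aligned_fraction` of the read at
#' percent identity at least `min_identity`. The defaults are calibrated to
#' separate the two read populations this step must arbitrate: a read carrying
#' only sequencing errors aligns to its own genome at about 98% identity or
#' better, while the cross-genotype homolog of a foreign read sits near
#' 100 * (1 - divergence) ~ 95%; 97.5% splits the two.
#'
#' @param reads Read tibble or character vector of sequences.
#' @param reference_a,reference_b The two [genotype_reference()] objects.
#' @param min_aligned_fraction Minimum aligned fraction of the read.
#' @param min_identity Minimum percent identity of the local alignment.
#' @param seed_k Seed length for the local search (default 11).
#' @param index_a,index_b Optional prebuilt `seed_k`-mer indexes (via
#'   [build_index()]) to amortise index construction across samples.
#' @return A tibble with one row per read: `read_id`, `hit_a`, `hit_b`
#'   (logicals) plus per-reference `score`, `aligned_fraction`, `identity`.
#' @export
local_search <- function(reads, reference_a, reference_b,
                         min_aligned_fraction = 0.9, min_identity = 97.5,
                         seed_k = 11L, index_a = NULL, index_b = NULL) {
  if (is.character(reads)) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    seqs <- unname(reads)
  } else {
    reads <- as_tibble(reads)
    ids <- reads$read_id
    seqs <- reads$sequence
  }
  index_a <- index_a %||% build_index(reference_a, seed_k)
  index_b <- index_b %||% build_index(reference_b, seed_k)
  ra <- gm_local_search(seqs, index_a$core, 30L, 16L)
  rb <- gm_local_search(seqs, index_b$core, 30L, 16L)
  qualify <- function(r) {
    r$found & r$aligned_fraction >= min_aligned_fraction &
      r$identity >= min_identity
  }
  tibble(
    read_id = ids,
    hit_a = qualify(ra), hit_b = qualify(rb),
    score_a = ra$score, aligned_fraction_a = ra$aligned_fraction,
    identity_a = ra$identity,
    score_b = rb$score, aligned_fraction_b = rb$aligned_fraction,
    identity_b = rb$identity)
}
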