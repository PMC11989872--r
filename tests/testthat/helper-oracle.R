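# Independent brute-force oracle for semi-global alignment: full dynamic
# programming over every offset of every chromosome and both strands, with no
# seeding or banding. Kept deliberately separate from the package's
# implementation.

oracle_ed_one_strand <- function(read, ref) {
  rc <- strsplit(read, "")[[1]]
  tc <- strsplit(ref, "")[[1]]
  n <- length(tc)
  idx <- 0:n
  prev <- rep(0L, n + 1L)
  acgt <- c("A", "C", "G", "T")
  for (i in seq_along(rc)) {
    subc <- prev[1:n] + ifelse(tc == rc[i] & rc[i] %in% acgt, 0L, 1L)
    cur <- c(i, pmin(subc, prev[2:(n + 1)] + 1L))
    # unit-cost left-to-right closure: cur[j] = min_k (cur[k] + (j - k))
    cur <- cummin(cur - idx) + idx
    prev <- cur
  }
  min(prev)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_edit_distance <- function(read, sequences) {
  min(vapply(sequences, function(s) {
    min(oracle_ed_one_strand(read, s),
        oracle_ed_one_strand(revcomp_chr(read), s))
  }, numeric(1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reference wrapper around raw sequences with a trivial gene table.
seqs_as_reference <- function(seqs, genotype_id = "X") {
  genotype_reference(
    genotype_id, seqs,
    tibble::tibble(gene_id = paste0(genotype_id, "_g1"),
                   chromosome = names(seqs)[1], start = 1L,
                   end = min(50L, nchar(seqs[[1]])), strand = "+",
                   exon_length = min(50L, nchar(seqs[[1]]))))
}

# Read tibble from bare sequences (uniform high quality).
reads_from_seqs <- function(seqs, ids = sprintf("r%04d", seq_along(seqs)),
                            sample_id = "S1") {
  tibble::tibble(read_id = ids, mate = 1L, sequence = seqs,
                 quality = strrep("F", nchar(seqs)), sample_id = sample_id)
}

# Apply point mutations to a sequence (substitutions / insertions /
# deletions at sampled positions).
mutate_seq <- function(seq, n_sub = 0, n_ins = 0, n_del = 0) {
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0) {
    for (p in sample(length(ch), n_sub)) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
  }
  if (n_del > 0) ch <- ch[-sample(length(ch), n_del)]
  if (n_ins > 0) {
    for (z in seq_len(n_ins)) {
      ch <- append(ch, sample(bases, 1), after = sample(length(ch), 1))
    }
  }
  paste(ch, collapse = "")
}

# A minimal classified_reads stand-in for exercising the calling rules
# without running the aligner.
fake_classified <- function(gene_reads, tissue = "RR", condition = "CK",
                            replicate = 1L, foreign_genotype = "SCI") {
  structure(list(
    sample_id = sprintf("%s%s_%d", condition, tissue, replicate),
    tissue = tissue, condition = condition, replicate = replicate,
    direction = if (tissue == "HL") "up" else "down",
    foreign_genotype = foreign_genotype,
    n_input = 0L, n_mapped_native = 0L,
    native_gene_counts = tibble::tibble(gene_id = character(0),
                                        count = integer(0)),
    unmapped = character(0), candidate_mobile = character(0),
    false_positive = character(0), n_discarded = 0L,
    retained = tibble::tibble(),
    gene_support = tibble::tibble(gene_id = names(gene_reads),
                                  reads = as.integer(gene_reads))),
    class = "classified_reads")
}

# Source-count table in which every listed gene is comfortably expressed.
expressed_source <- function(gene_ids, tissue = "HL", n_rep = 3L,
                             count = 50L) {
  tidyr::expand_grid(gene_id = gene_ids, replicate = seq_len(n_rep)) |>
    dplyr::mutate(tissue = tissue, count = count)
}
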