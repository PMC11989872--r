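#' Generate a random base genotype
#'
#' Builds a genome of intronless genes separated by intergenic spacers,
#' distributed round-robin over `n_chromosomes`. Used as the scion genotype of
#' the synthetic heterograft; the rootstock genotype is derived from it with
#' [diverge_genome()].
#'
#' @param genotype_id Label for the genotype.
#' @param n_genes Number of genes.
#' @param gene_length_range Length-2 integer vector; gene lengths are drawn
#'   uniformly from this range.
#' @param intergenic_range Length-2 integer vector of spacer lengths.
#' @param n_chromosomes Number of chromosomes.
#' @param seed Integer seed; the same seed yields a byte-identical reference.
#' @return A [genotype_reference()].
#' @export
random_reference <- function(genotype_id, n_genes,
                             gene_length_range = c(500L, 2000L),
                             intergenic_range = c(200L, 400L),
                             n_chromosomes = 3L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_chromosomes >= 1L)
  with_seed(seed, {
    lens <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                   replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    chrom_of <- rep_len(seq_len(n_chromosomes), n_genes)
    bases <- c("A", "C", "G", "T")
    seqs <- character(n_chromosomes)
    rows <- vector("list", n_genes)
    cursor <- integer(n_chromosomes)
    pieces <- vector("list", n_chromosomes)
    for (i in seq_len(n_chromosomes)) pieces[[i]] <- list()
    for (g in seq_len(n_genes)) {
      ch <- chrom_of[g]
      gap <- sample(intergenic_range[1]:intergenic_range[2], 1L)
      gene_seq <- paste(sample(bases, lens[g], replace = TRUE),
                        collapse = "")
      gap_seq <- paste(sample(bases, gap, replace = TRUE), collapse = "")
      start <- cursor[ch] + gap + 1L
      pieces[[ch]] <- c(pieces[[ch]], list(gap_seq, gene_seq))
      cursor[ch] <- start + lens[g] - 1L
      rows[[g]] <- tibble(
        gene_id = sprintf("%s_g%04d", genotype_id, g),
        chromosome = sprintf("chr%d", ch),
        start = start, end = cursor[ch],
        strand = strands[g], exon_length = lens[g])
    }
    tail_gap <- sample(intergenic_range[1]:intergenic_range[2],
                       n_chromosomes, replace = TRUE)
    for (i in seq_len(n_chromosomes)) {
      tail_seq <- paste(sample(bases, tail_gap[i], replace = TRUE),
                        collapse = "")
      seqs[i] <- paste(c(unlist(pieces[[i]]), tail_seq), collapse = "")
    }
    genotype_reference(
      genotype_id,
      setNames(seqs, sprintf("chr%d", seq_len(n_chromosomes))),
      bind_rows(rows))
  })
}

#' Derive a diverged genotype from a base reference
#'
#' Introduces i.i.d. substitutions at rate `divergence` per site and, at rate
#' `indel_rate`, single-base insertions and deletions (half each). Gene models
#' are lifted over through the indels; a deletion that removes a gene's start
#' or end coordinate is an error naming the affected genes. Gene ids are
#' re-prefixed with `genotype_id` and the homolog mapping is attached as the
#' `homologs` attribute.
#'
#' @param reference Base [genotype_reference()].
#' @param divergence Substitution rate per site, in `[0, 0.2]`.
#' @param indel_rate Indel rate per site.
#' @param seed Integer seed.
#' @param genotype_id Label for the derived genotype.
#' @param protect_boundaries If `TRUE`, indels are suppressed at gene start
#'   and end positions so that every gene model remains liftable; the
#'   synthetic-data generator uses this so that any seed yields a valid
#'   genotype pair. Substitutions are unaffected.
#' @return A list with elements `reference` (the diverged
#'   [genotype_reference()]) and `variants` (a tibble of every introduced
#'   difference: `chromosome`, `pos` in base coordinates, `ref`, `alt`,
#'   `type`).
#' @export
diverge_genome <- function(reference, divergence, indel_rate = 0, seed = 1L,
                           genotype_id = paste0(reference$genotype_id, "d"),
                           protect_boundaries = FALSE) {
  stopifnot(inherits(reference, "genotype_reference"))
  assert_scalar_number(divergence, "divergence", 0, 0.2)
  assert_scalar_number(indel_rate, "indel_rate", 0, 0.1)

  new_seqs <- character(length(reference$sequences))
  names(new_seqs) <- names(reference$sequences)
  variant_rows <- list()
  lift_start <- list()  # per chromosome: old pos -> new pos, NA if deleted
  bases <- c("A", "C", "G", "T")

  with_seed(sub_seed(seed, "divergence"), {
    for (ch in names(reference$sequences)) {
      chars <- strsplit(reference$sequences[[ch]], "", fixed = TRUE)[[1]]
      L <- length(chars)
      u <- runif(L)
      v <- runif(L)
      sub_mask <- u < divergence
      del_mask <- !sub_mask & v < indel_rate / 2
      ins_mask <- !sub_mask & !del_mask & v < indel_rate
      if (protect_boundaries) {
        gch <- reference$genes[reference$genes$chromosome == ch, ]
        guard <- unique(c(gch$start, gch$end))
        del_mask[guard] <- FALSE
        ins_mask[guard] <- FALSE
      }
      vals <- chars
      if (any(sub_mask)) {
        # substitute with a uniformly chosen different base
        shift <- sample.int(3L, sum(sub_mask), replace = TRUE)
        cur <- match(chars[sub_mask], bases)
        cur[is.na(cur)] <- 1L
        vals[sub_mask] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      }
      ins_base <- character(L)
      if (any(ins_mask)) {
        ins_base[ins_mask] <- sample(bases, sum(ins_mask), replace = TRUE)
      }
      counts <- rep(1L, L)
      counts[del_mask] <- 0L
      counts[ins_mask] <- 2L
      newpos_last <- cumsum(counts)
      keep <- counts >= 1L
      out <- character(newpos_last[L])
      out[newpos_last[keep] - (counts[keep] - 1L)] <- vals[keep]
      if (any(ins_mask)) out[newpos_last[ins_mask]] <- ins_base[ins_mask]
      new_seqs[[ch]] <- paste(out, collapse = "")
      lift <- newpos_last - pmax(counts - 1L, 0L)
      lift[del_mask] <- NA_integer_
      lift_start[[ch]] <- lift
      variant_rows[[ch]] <- bind_rows(
        if (any(sub_mask)) tibble(chromosome = ch,
                                  pos = which(sub_mask),
                                  ref = chars[sub_mask],
                                  alt = vals[sub_mask], type = "sub"),
        if (any(del_mask)) tibble(chromosome = ch,
                                  pos = which(del_mask),
                                  ref = chars[del_mask],
                                  alt = "", type = "del"),
        if (any(ins_mask)) tibble(chromosome = ch,
                                  pos = which(ins_mask),
                                  ref = chars[ins_mask],
                                  alt = paste0(chars[ins_mask],
                                               ins_base[ins_mask]),
                                  type = "ins"))
    }
  })

  genes <- reference$genes
  new_start <- integer(nrow(genes))
  new_end <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    lift <- lift_start[[genes$chromosome[i]]]
    new_start[i] <- lift[genes$start[i]]
    new_end[i] <- lift[genes$end[i]]
  }
  lost <- is.na(new_start) | is.na(new_end)
  if (any(lost)) {
    abort(paste0("divergence deleted a gene boundary for: ",
                 paste(genes$gene_id[lost], collapse = ", ")))
  }
  core <- sub(paste0("^", reference$genotype_id, "_"), "", genes$gene_id)
  new_genes <- tibble(
    gene_id = paste0(genotype_id, "_", core),
    chromosome = genes$chromosome,
    start = new_start, end = new_end,
    strand = genes$strand,
    exon_length = new_end - new_start + 1L)

  out_ref <- genotype_reference(genotype_id, new_seqs, new_genes)
  variants <- bind_rows(variant_rows)
  if (nrow(variants)) variants <- arrange(variants, .data$chromosome,
                                          .data$pos)
  attr(out_ref, "homologs") <- tibble(base_gene_id = genes$gene_id,
                                      derived_gene_id = new_genes$gene_id)
  list(reference = out_ref, variants = variants)
}
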