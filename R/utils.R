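# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed for a named random stream. Each stage of the
# simulator draws from its own stream so adding a stage never perturbs the
# streams of earlier stages.
sub_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483629) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%not_in%` <- function(x, table) !(x %in% table)

# Unique per-read keys: fragment ids are shared by mates, so the mate number
# is appended whenever ids are duplicated. Used identically by align_reads()
# and classify_sample_reads() so id sets line up across stages.
read_keys <- function(reads) {
  if ("mate" %in% names(reads) && !all(is.na(reads$mate)) &&
      anyDuplicated(reads$read_id)) {
    paste0(reads$read_id, "/", reads$mate)
  } else {
    reads$read_id
  }
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lo), format(hi)))
  }
  invisible(x)
}

tissues_all <- c("HL", "RR", "RL")
conditions_all <- c("CK", "drought")
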