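# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Coerce a FASTA path or DNAStringSet to a named DNAStringSet.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stopf("`genome` must be a DNAStringSet or a path to a FASTA file")
  }
  if (length(genome) > 0L) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("seq", seq_along(genome))
    }
    # keep only the first whitespace-delimited token of FASTA headers
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome
}

# Deterministic per-sample seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(index)) %% 2147483629)
}

is_two_groups <- function(groups) {
  g <- unique(as.character(groups))
  length(g) == 2L
}

# groups as a factor with levels in first-appearance order (group1 = reference)
as_group_factor <- function(groups) {
  g <- as.character(groups)
  factor(g, levels = unique(g))
}
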