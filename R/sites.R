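#' Scan a genome for methyl-sensitive restriction sites
#'
#' Finds every exact occurrence of a 4-base recognition motif (default
#' `"CCGG"`, the HpaII site) on the forward strand of each sequence. CCGG is
#' palindromic, so forward-strand occurrences enumerate all cut sites once.
#' Matching is case-insensitive (soft-masked lowercase is treated as valid
#' sequence); windows containing `N` never match.
#'
#' Coordinates are 0-based half-open. For each occurrence at `motif_start`,
#' the top-strand cut boundary (HpaII cuts `C^CGG`) is `motif_start + 1`, and
#' the internal CpG cytosine is also at `motif_start + 1`.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a (optionally
#'   gzipped) FASTA file.
#' @param motif Recognition sequence; must contain only A/C/G/T.
#' @return A data frame of class `msre_sites` with columns `chrom`,
#'   `motif_start`, `cut_coord`, `cpg_pos`, `site_id`, sorted by
#'   (chromosome appearance order, coordinate).
#' @export
scan_motif_sites <- function(genome, motif = "CCGG") {
  if (!grepl("^[ACGTacgt]+$", motif)) {
    stopf("motif must contain only A/C/G/T (ambiguity codes unsupported): %s", motif)
  }
  genome <- as_genome(genome)
  if (length(genome) == 0L) return(empty_sites())
  hits <- Biostrings::vmatchPattern(toupper(motif), genome, fixed = TRUE)
  out <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]])
    if (length(s) == 0L) return(NULL)
    data.frame(chrom = names(genome)[i], motif_start = sort(s) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_sites())
  out$cut_coord <- out$motif_start + 1L
  out$cpg_pos <- out$motif_start + 1L
  out$site_id <- make_site_id(out$chrom, out$cpg_pos, "M")
  rownames(out) <- NULL
  class(out) <- c("msre_sites", "data.frame")
  out
}

empty_sites <- function() {
  out <- data.frame(chrom = character(), motif_start = integer(),
                    cut_coord = integer(), cpg_pos = integer(),
                    site_id = character(), stringsAsFactors = FALSE)
  class(out) <- c("msre_sites", "data.frame")
  out
}

#' Count forward-strand CpG dinucleotides
#'
#' @inheritParams scan_motif_sites
#' @return Total number of N-free `CG` occurrences across all sequences.
#' @export
count_cpg <- function(genome) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) return(0L)
  sum(Biostrings::vcountPattern("CG", genome, fixed = TRUE))
}

#' Build a channelled CpG site identifier
#'
#' Identifiers take the form `"{channel}.{chrom}.{pos1}"` where `pos1` is the
#' 1-based position of the internal CpG cytosine, zero-padded to 10 digits,
#' e.g. `"M.chr19.0050595864"`.
#'
#' @param chrom Chromosome name(s).
#' @param pos 0-based coordinate(s) of the internal CpG cytosine.
#' @param channel `"M"` (fully-methylated metric) or `"U"` (fully-unmethylated).
#' @return Character vector of site identifiers.
#' @export
make_site_id <- function(chrom, pos, channel) {
  if (!all(channel %in% c("M", "U"))) {
    stopf("channel must be 'M' or 'U'")
  }
  if (any(pos < 0)) stopf("pos must be >= 0")
  sprintf("%s.%s.%010d", channel, chrom, as.integer(pos) + 1L)
}

#' Parse channelled site identifiers
#'
#' Inverse of [make_site_id()].
#'
#' @param site_id Character vector of ids such as `"M.chr1.0000000102"`.
#' @return Data frame with columns `channel`, `chrom`, `cpg_pos` (0-based).
#' @export
parse_site_id <- function(site_id) {
  m <- regmatches(site_id, regexec("^([MU])\\.(.+)\\.([0-9]{10})$", site_id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stopf("malformed site id: %s", site_id[bad][1])
  data.frame(channel = vapply(m, `[`, "", 2L),
             chrom = vapply(m, `[`, "", 3L),
             cpg_pos = as.integer(vapply(m, `[`, "", 4L)) - 1L,
             stringsAsFactors = FALSE)
}

#' Write recognition sites as BED6
#'
#' One line per site covering the 4-bp motif (`motif_start`,
#' `motif_start + 4`), named by the M-channel site id, score 0, strand `+`.
#'
#' @param sites An `msre_sites` data frame from [scan_motif_sites()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(sites$chrom, sites$motif_start, sites$motif_start + 4L,
                    sites$site_id, 0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of recognition sites written by [write_sites_bed()]
#'
#' @param path BED6 file path.
#' @return An `msre_sites` data frame.
#' @export
read_sites_bed <- function(path) {
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(empty_sites())
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    motif_start = as.integer(bed[[2]]),
                    stringsAsFactors = FALSE)
  out$cut_coord <- out$motif_start + 1L
  out$cpg_pos <- out$motif_start + 1L
  out$site_id <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    make_site_id(out$chrom, out$cpg_pos, "M")
  class(out) <- c("msre_sites", "data.frame")
  out
}
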