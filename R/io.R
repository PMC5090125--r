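# Plain-text sequencing I/O: FASTQ, SAM (via Rsamtools for BAM), TSV matrix.

#' Write reads to FASTQ
#'
#' @param reads Data frame with `id`, `seq`, `qual` (Phred+33), as returned
#'   by [library_reads()] or [read_fastq()].
#' @param path Output path; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Data frame `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stopf("malformed FASTQ: %d lines is not a multiple of 4", length(lines))
  }
  n <- length(lines) / 4L
  i <- seq_len(n)
  at <- lines[4L * i - 3L]
  bad <- which(!startsWith(at, "@"))
  if (length(bad)) stopf("malformed FASTQ record %d: missing '@' header", bad[1])
  sq <- lines[4L * i - 2L]
  ql <- lines[4L * i]
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    stopf("malformed FASTQ record %d: sequence/quality length mismatch", bad[1])
  }
  data.frame(id = sub("\\s.*$", "", substring(at, 2L)), seq = sq, qual = ql,
             stringsAsFactors = FALSE)
}

#' Write simulated alignments as coordinate-sorted SAM
#'
#' Emits ungapped single-end records (`<L>M` CIGAR, MAPQ 60, flag 0/16) with
#' a proper `@SQ` header so the file converts cleanly to BAM.
#'
#' @param lib A [simulate_library()] result.
#' @param genome Genome the library was simulated from.
#' @param config The [sim_config()] used (for read length and base quality).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(lib, genome, config, path) {
  aln <- lib$alignments
  reads <- library_reads(lib, genome, config)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  flag <- ifelse(aln$strand == "+", 0L, 16L)
  seq <- reads$seq
  qual <- reads$qual
  rev <- aln$strand == "-"
  # SAM stores sequence in reference orientation
  if (any(rev)) {
    seq[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[rev])))
    qual[rev] <- vapply(strsplit(qual[rev], ""), function(x)
      paste(rev(x), collapse = ""), "")
  }
  rec <- paste(reads$id, flag, aln$chrom, aln$start + 1L, 60L,
               paste0(aln$end - aln$start, "M"), "*", 0L, 0L, seq, qual,
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read coordinate-sorted alignments from SAM/BAM
#'
#' SAM text is converted with `Rsamtools::asBam` and scanned; only primary
#' mapped records are returned. Ungapped reads are assumed (aligned span =
#' read width; CIGAR reference widths are honoured when present).
#'
#' @param path `.sam` or `.bam` file.
#' @return Alignment data frame (`chrom`, `start`, `end` 0-based half-open,
#'   `strand`, `terminus`, `qname`) sorted by position.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand",
                                        "cigar", "qwidth"),
                               flag = Rsamtools::scanBamFlag(
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  refw <- cigar_ref_width(b$cigar, b$qwidth)
  aln <- data.frame(chrom = as.character(b$rname), start = b$pos - 1L,
                    end = b$pos - 1L + refw,
                    strand = as.character(b$strand),
                    qname = b$qname, stringsAsFactors = FALSE)
  aln <- aln[order(aln$chrom, aln$start), , drop = FALSE]
  aln$terminus <- ifelse(aln$strand == "+", aln$start, aln$end)
  rownames(aln) <- NULL
  aln
}

# reference-consuming width from CIGAR (M/D/N/=/X); fall back to query width
cigar_ref_width <- function(cigar, qwidth) {
  out <- qwidth
  has <- !is.na(cigar) & cigar != "*"
  if (any(has)) {
    w <- vapply(regmatches(cigar[has],
                           gregexpr("[0-9]+[MDN=X]", cigar[has])), function(ops) {
      sum(as.numeric(sub("[MDN=X]", "", ops)))
    }, 0)
    out[has] <- as.integer(w)
  }
  out
}

#' Write a methylation matrix to TSV
#'
#' Layout: `site_id` column then one column per sample, values on the
#' percent scale with 3 decimals; a `#groups:` comment line records the
#' manifest (`sample=group`, manifest order).
#'
#' @param mat A `methylation_matrix` (see [build_matrix()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#groups: %s",
                     paste(mat$manifest$sample, mat$manifest$group,
                           sep = "=", collapse = ",")), con)
  df <- data.frame(site_id = rownames(mat$values),
                   format(round(mat$values, 3), nsmall = 3, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("site_id", colnames(mat$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return A `methylation_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  manifest <- NULL
  skip <- 0L
  if (startsWith(first, "#groups:")) {
    skip <- 1L
    kv <- strsplit(trimws(sub("^#groups:", "", first)), ",")[[1]]
    parts <- strsplit(kv, "=")
    manifest <- data.frame(sample = vapply(parts, `[`, "", 1L),
                           group = vapply(parts, `[`, "", 2L),
                           stringsAsFactors = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$site_id
  if (is.null(manifest)) {
    manifest <- data.frame(sample = colnames(vals),
                           group = NA_character_, stringsAsFactors = FALSE)
  }
  new_methylation_matrix(vals, manifest)
}
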