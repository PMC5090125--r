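#' Quantification configuration
#'
#' Tuning constants for reconstructing per-site M/U metrics from aligned
#' reads.
#'
#' @param delta End-match tolerance in bp: a read terminus within `delta` of
#'   a cut boundary counts as digest-end evidence (absorbs end-repair shifts
#'   on real data).
#' @param window Local-coverage half-width in bp (median read depth over
#'   `motif +/- window`, digestion troughs masked).
#' @param read_length Read length in bp.
#' @param min_lambda Minimum local coverage for a site to be scored.
#' @param cal_threshold Sites with raw spanning ratio `S/lambda` below this
#'   are used to calibrate the end-capture factor kappa (they carry most of
#'   the cut-end signal).
#' @param min_cal_sites Minimum number of calibration sites.
#' @return List of class `quant_config`.
#' @export
quant_config <- function(delta = 2, window = 500, read_length = 71,
                         min_lambda = 10, cal_threshold = 0.5,
                         min_cal_sites = 50) {
  if (delta < 0) stopf("delta must be >= 0")
  if (window <= read_length) stopf("window must exceed read_length")
  structure(list(delta = as.integer(delta), window = as.integer(window),
                 read_length = as.integer(read_length),
                 min_lambda = min_lambda, cal_threshold = cal_threshold,
                 min_cal_sites = min_cal_sites),
            class = "quant_config")
}

# Fraction of read placements that span the 4-bp motif with no terminus
# within delta of the cut boundary, relative to per-base depth. Forward reads
# lose `delta` start positions to the terminus exclusion, reverse reads lose
# max(0, delta - 2) end positions (the cut sits after the first motif base).
spanning_factor <- function(L, delta, motif_len = 4L) {
  (2 * (L - motif_len + 1) - delta - max(0, delta - 2)) / (2 * L)
}

#' Quality-control filter for reads
#'
#' A read is retained iff its mean base-call confidence
#' `1 - mean(10^(-Q/10))` exceeds `min_confidence`.
#'
#' @param reads Data frame `id`, `seq`, `qual` (Phred+33) or a FASTQ path.
#' @param min_confidence Retention threshold (default 0.97).
#' @return The retained reads, with a `summary` attribute
#'   (`n_in`, `n_kept`, `retained_fraction`).
#' @export
qc_filter <- function(reads, min_confidence = 0.97) {
  if (is.character(reads)) reads <- read_fastq(reads)
  conf <- vapply(reads$qual, function(q) {
    Q <- utf8ToInt(q) - 33
    1 - mean(10^(-Q / 10))
  }, 0, USE.NAMES = FALSE)
  keep <- conf > min_confidence
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(n_in = nrow(reads), n_kept = sum(keep),
                               retained_fraction = mean(keep))
  out
}

#' Retain alignments near recognition sites
#'
#' Keeps alignments overlapping `[motif_start - radius, motif_start + 4 +
#' radius)` of any site; the default radius equals the local-coverage window
#' so downstream coverage stays computable.
#'
#' @param aln Coordinate-sorted alignment data frame.
#' @param sites Sites data frame.
#' @param radius Flank in bp.
#' @return Filtered alignment data frame.
#' @export
isolate_target_reads <- function(aln, sites, radius = 500) {
  check_sorted(aln)
  keep <- logical(nrow(aln))
  for (ch in unique(aln$chrom)) {
    ai <- which(aln$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(si) == 0L) next
    q <- IRanges::IRanges(aln$start[ai] + 1L, aln$end[ai])
    s <- IRanges::IRanges(sites$motif_start[si] - radius + 1L,
                          sites$motif_start[si] + 4L + radius)
    keep[ai[IRanges::overlapsAny(q, s)]] <- TRUE
  }
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_sorted <- function(aln) {
  if (nrow(aln) > 1L) {
    d <- diff(aln$start)
    newc <- aln$chrom[-1] != aln$chrom[-nrow(aln)]
    if (any(d < 0 & !newc)) stopf("alignments must be coordinate-sorted")
  }
  invisible(TRUE)
}

#' Median local coverage around a site
#'
#' `lambda` is the median per-base depth over `[motif_start - window,
#' motif_start + 4 + window)`, excluding all positions within `read_length`
#' of any site's cut boundary so digestion troughs (and cut-end pileups) do
#' not bias the baseline.
#'
#' @param depth Numeric per-base depth vector for one chromosome (element
#'   `i` = depth at 0-based position `i - 1`).
#' @param sites Sites on that chromosome (all are used for masking).
#' @param config A [quant_config()].
#' @param at Optional subset of `sites` rows to score (default all).
#' @return Numeric vector of `lambda` values (0 when the window is entirely
#'   masked or off-contig).
#' @export
local_coverage <- function(depth, sites, config = quant_config(), at = NULL) {
  G <- length(depth)
  L <- config$read_length
  W <- config$window
  masked <- logical(G)
  for (b in sites$cut_coord) {
    lo <- max(1L, b - L + 1L)
    hi <- min(G, b + L)
    if (lo <= hi) masked[lo:hi] <- TRUE
  }
  rows <- at %||% seq_len(nrow(sites))
  vapply(rows, function(i) {
    t0 <- sites$motif_start[i]
    lo <- max(1L, t0 - W + 1L)
    hi <- min(G, t0 + 4L + W)
    if (lo > hi) return(0)
    win <- depth[lo:hi][!masked[lo:hi]]
    if (length(win) == 0L) return(0)
    stats::median(win)
  }, 0)
}

#' Tabulate per-site cut evidence
#'
#' For each site: `E` counts read termini (forward 5' starts, reverse 3'
#' ends — the fragment end) within `delta` of the cut boundary; `S` counts
#' reads fully spanning the motif that contribute no such terminus;
#' `lambda` is the masked median local coverage; `b = (2 delta + 1)
#' lambda / L` is the expected shearing background among `E` (each read
#' contributes exactly one fragment-end terminus, so background termini
#' arrive at rate `lambda / L` per position).
#'
#' @param aln Coordinate-sorted alignment data frame.
#' @param sites Sites data frame.
#' @param config A [quant_config()].
#' @return Data frame of class `site_counts`: `site_id`, `chrom`,
#'   `cut_coord`, `E`, `S`, `lambda`, `b`, `low_coverage`.
#' @export
tabulate_site_evidence <- function(aln, sites, config = quant_config()) {
  check_sorted(aln)
  delta <- config$delta
  L <- config$read_length
  E <- integer(nrow(sites))
  S <- integer(nrow(sites))
  lambda <- numeric(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ai <- which(aln$chrom == ch)
    b <- sites$cut_coord[si]
    if (length(ai)) {
      term <- sort(aln$terminus[ai])
      E[si] <- findInterval(b + delta, term) -
        findInterval(b - delta - 1L, term)
      # spanning reads: motif strictly inside the aligned span
      rd <- IRanges::IRanges(aln$start[ai] + 1L, aln$end[ai])
      mo <- IRanges::IRanges(sites$motif_start[si] + 1L,
                             sites$motif_start[si] + 4L)
      ov <- IRanges::findOverlaps(mo, rd, type = "within")
      qh <- S4Vectors::queryHits(ov)
      near <- abs(aln$terminus[ai][S4Vectors::subjectHits(ov)] - b[qh]) <= delta
      cnt <- tabulate(qh[!near], nbins = length(si))
      S[si] <- cnt
      G <- max(aln$end[ai], sites$motif_start[si] + 4L + config$window)
      cov <- IRanges::coverage(rd, width = G)
      lambda[si] <- local_coverage(as.numeric(cov), sites[si, , drop = FALSE],
                                   config)
    } else {
      lambda[si] <- 0
    }
  }
  out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    cut_coord = sites$cut_coord, E = E, S = S,
                    lambda = lambda,
                    b = (2 * delta + 1) * lambda / L,
                    low_coverage = lambda < config$min_lambda,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Estimate the per-sample end-capture calibration factor
#'
#' kappa places the excess digest-end count on the local-coverage scale:
#' `kappa = median over calibration sites of (E - b) / (lambda * (1 -
#' min(S/lambda, 1)))`, computed over scored sites with raw spanning ratio
#' below `cal_threshold` (majority-unmethylated sites carry the cut-end
#' signal).
#'
#' @param counts A `site_counts` data frame for one sample.
#' @param config A [quant_config()].
#' @return Positive scalar kappa.
#' @export
estimate_end_capture <- function(counts, config = quant_config()) {
  ok <- !counts$low_coverage
  ratio <- ifelse(counts$lambda > 0, counts$S / counts$lambda, NA_real_)
  cal <- ok & !is.na(ratio) & ratio < config$cal_threshold
  if (sum(cal) < config$min_cal_sites) {
    stopf(paste("only %d calibration sites with S/lambda < %g (need >= %d);",
                "provide more sites or deeper coverage"),
          sum(cal), config$cal_threshold, config$min_cal_sites)
  }
  k <- stats::median((counts$E[cal] - counts$b[cal]) /
                       (counts$lambda[cal] * (1 - pmin(ratio[cal], 1))))
  max(k, 1e-6)
}

#' Per-site M/U metrics from tabulated evidence
#'
#' `m_metric = clip(S / (lambda * g), 0, 1)` where `g` is the geometric
#' fraction of read placements that can span the motif without a
#' delta-adjacent terminus (see the package vignette); it estimates the
#' fully-methylated (uncut) copy fraction. `u_metric = clip((E - b) /
#' (kappa * lambda), 0, 1.5)` estimates the fully-unmethylated (cut)
#' fraction. `pct_met = 100 * m_metric`.
#'
#' @param counts A `site_counts` data frame.
#' @param kappa End-capture factor from [estimate_end_capture()].
#' @param config A [quant_config()].
#' @return Data frame of class `site_metrics`: `site_id`, `m_metric`,
#'   `u_metric`, `pct_met`, `lambda`, `qc_ok`. Low-coverage sites carry `NA`
#'   metrics and `qc_ok = FALSE` rather than erroring.
#' @export
compute_metrics <- function(counts, kappa, config = quant_config()) {
  g <- spanning_factor(config$read_length, config$delta)
  ok <- !counts$low_coverage
  m <- ifelse(ok, clip(counts$S / (counts$lambda * g), 0, 1), NA_real_)
  u <- ifelse(ok, clip((counts$E - counts$b) / (kappa * counts$lambda), 0, 1.5),
              NA_real_)
  out <- data.frame(site_id = counts$site_id, m_metric = m, u_metric = u,
                    pct_met = 100 * m, lambda = counts$lambda, qc_ok = ok,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_metrics", "data.frame")
  out
}

#' Quantify one sample end to end
#'
#' Convenience chain: evidence tabulation, kappa calibration, metric
#' computation.
#'
#' @param aln Coordinate-sorted alignment data frame (or SAM/BAM path).
#' @param sites Sites data frame.
#' @param config A [quant_config()].
#' @return A `site_metrics` data frame with `kappa` attribute.
#' @export
quantify_sample <- function(aln, sites, config = quant_config()) {
  if (is.character(aln)) aln <- read_alignments(aln)
  counts <- tabulate_site_evidence(aln, sites, config)
  kappa <- estimate_end_capture(counts, config)
  out <- compute_metrics(counts, kappa, config)
  attr(out, "kappa") <- kappa
  out
}

new_methylation_matrix <- function(values, manifest) {
  structure(list(values = values, manifest = manifest),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d rows x %d samples (groups: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$manifest$group), collapse = ", ")))
  invisible(x)
}

#' Assemble the sites-by-samples methylation matrix
#'
#' Rows are M-channel (`pct_met`) and U-channel (`100 * u_metric`) values
#' per site, identified with [make_site_id()]; columns are samples in
#' manifest order. Sites flagged in any sample are dropped (complete-case).
#' Rows are sorted lexicographically by (channel, chromosome, position).
#'
#' @param metrics_list Named list of `site_metrics` data frames, one per
#'   sample.
#' @param manifest Data frame `sample`, `group` (two groups; group 1 =
#'   reference listed first).
#' @return A `methylation_matrix`: list with `values` (numeric matrix,
#'   %-scale) and `manifest`.
#' @export
build_matrix <- function(metrics_list, manifest) {
  if (nrow(manifest) < 2L) stopf("need at least 2 samples")
  missing <- setdiff(manifest$sample, names(metrics_list))
  if (length(missing)) {
    stopf("manifest sample(s) absent from inputs: %s",
          paste(missing, collapse = ", "))
  }
  metrics_list <- metrics_list[manifest$sample]
  ids <- metrics_list[[1]]$site_id
  ok <- Reduce(`&`, lapply(metrics_list, function(m) {
    stopifnot(identical(m$site_id, ids))
    m$qc_ok
  }))
  ids <- ids[ok]
  parsed <- parse_site_id(ids)
  mvals <- vapply(metrics_list, function(m) m$pct_met[ok], numeric(sum(ok)))
  uvals <- vapply(metrics_list, function(m) 100 * m$u_metric[ok],
                  numeric(sum(ok)))
  vals <- rbind(mvals, uvals)
  rownames(vals) <- c(ids, make_site_id(parsed$chrom, parsed$cpg_pos, "U"))
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  colnames(vals) <- manifest$sample
  new_methylation_matrix(vals, manifest[, c("sample", "group")])
}

#' Prefilter rows by absolute group-mean difference
#'
#' Retains rows whose two group means differ by strictly more than
#' `min_diff` percentage points.
#'
#' @param mat A `methylation_matrix`.
#' @param min_diff Threshold in percentage points (default 10).
#' @return Filtered `methylation_matrix`.
#' @export
filter_by_group_difference <- function(mat, min_diff = 10) {
  g <- as_group_factor(mat$manifest$group)
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  if (any(tabulate(g, 2L) == 0L)) stopf("each group needs at least one sample")
  m1 <- rowMeans(mat$values[, g == levels(g)[1], drop = FALSE])
  m2 <- rowMeans(mat$values[, g == levels(g)[2], drop = FALSE])
  keep <- abs(m1 - m2) > min_diff
  new_methylation_matrix(mat$values[keep, , drop = FALSE], mat$manifest)
}
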