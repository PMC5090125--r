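# Methylation-load aggregation: signed group differences in %MET summed over
# regions, genes, gene-body domains and functional classes.

# M-channel rows of a matrix with parsed coordinates
m_channel_sites <- function(mat) {
  parsed <- parse_site_id(rownames(mat$values))
  keep <- parsed$channel == "M"
  list(values = mat$values[keep, , drop = FALSE],
       chrom = parsed$chrom[keep], cpg_pos = parsed$cpg_pos[keep])
}

# per-site mean(group1) - mean(group2), %-scale
site_group_diff <- function(mat) {
  g <- as_group_factor(mat$manifest$group)
  if (nlevels(g) != 2L) stopf("exactly two groups required")
  ms <- m_channel_sites(mat)
  d <- rowMeans(ms$values[, g == levels(g)[1], drop = FALSE]) -
    rowMeans(ms$values[, g == levels(g)[2], drop = FALSE])
  data.frame(chrom = ms$chrom, cpg_pos = ms$cpg_pos, diff = d,
             stringsAsFactors = FALSE)
}

#' Differential methylation load of a region
#'
#' Signed sum over every M-channel CpG site whose cytosine lies in
#' `[start, end)` of the per-site difference in group-mean %MET,
#' reference group minus comparison group (manifest order). Positive values
#' mean higher methylation in the reference (healthy) group.
#'
#' @param mat A `methylation_matrix` with two groups.
#' @param region List or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `region_id`.
#' @return List of class `ml_result`: `region_id`, `delta_ml`
#'   (percentage-point units), `n_sites`.
#' @export
delta_ml <- function(mat, region) {
  if (is.null(region$chrom) || is.null(region$start) || is.null(region$end)) {
    stopf("region must have chrom, start and end")
  }
  d <- site_group_diff(mat)
  hit <- d$chrom == region$chrom & d$cpg_pos >= region$start &
    d$cpg_pos < region$end
  structure(list(region_id = region$region_id %||% sprintf(
    "%s:%d-%d", region$chrom, region$start, region$end),
    delta_ml = sum(d$diff[hit]), n_sites = sum(hit)), class = "ml_result")
}

#' Read region annotations from BED
#'
#' BED4+ with optional strand (column 6); column 4 is the region id. A
#' `kind` and `gene_id` can be supplied via extra columns 7 and 8 or set
#' afterwards.
#'
#' @param path BED path.
#' @param kind Region kind recycled over rows when the file has no column 7;
#'   one of `gene`, `promoter3kb`, `exon`, `intron`, `cpg_island`, `custom`.
#' @return Data frame `chrom`, `start`, `end`, `region_id`, `strand`,
#'   `kind`, `gene_id`.
#' @export
read_regions_bed <- function(path, kind = "gene") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
                    region_id = if (ncol(bed) >= 4) as.character(bed[[4]]) else
                      sprintf("%s:%d-%d", bed[[1]], bed[[2]], bed[[3]]),
                    strand = if (ncol(bed) >= 6) as.character(bed[[6]]) else "+",
                    kind = if (ncol(bed) >= 7) as.character(bed[[7]]) else kind,
                    stringsAsFactors = FALSE)
  out$gene_id <- if (ncol(bed) >= 8) as.character(bed[[8]]) else out$region_id
  check_region_kinds(out$kind)
  if (any(out$start >= out$end)) stopf("regions must satisfy start < end")
  out
}

region_kinds <- c("gene", "promoter3kb", "exon", "intron", "cpg_island",
                  "custom")

check_region_kinds <- function(kind) {
  bad <- setdiff(unique(kind), region_kinds)
  if (length(bad)) stopf("unknown region kind(s): %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read a gene-to-functional-class mapping
#'
#' Two-column TSV (`gene_id`, `class`), no header required.
#'
#' @param path TSV path.
#' @return Named character vector, class by gene id.
#' @export
read_class_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Promoter intervals upstream of gene starts
#'
#' `width` bp upstream of the annotated start on the annotated strand
#' (upstream in coordinate order when strand is missing), clipped at 0.
#'
#' @param genes Region data frame (kind `gene`).
#' @param width Promoter width in bp (the assay convention varies between
#'   2 kb and 3 kb; default 3000).
#' @return Region data frame of kind `promoter3kb`.
#' @export
promoter_regions <- function(genes, width = 3000) {
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$end, pmax(0L, genes$start - as.integer(width)))
  end <- ifelse(minus, genes$end + as.integer(width), genes$start)
  ok <- start < end
  out <- data.frame(chrom = genes$chrom, start = as.integer(start),
                    end = as.integer(end),
                    region_id = paste0(genes$region_id, "_prom"),
                    strand = genes$strand, kind = "promoter3kb",
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out[ok, , drop = FALSE]
}

# vectorized delta-ML over many regions
delta_ml_regions <- function(mat, regions) {
  d <- site_group_diff(mat)
  dml <- numeric(nrow(regions))
  nst <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    si <- which(d$chrom == ch)
    if (length(si) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(d$cpg_pos[si] + 1L, width = 1L),
      IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri]))
    if (length(ov) == 0L) next
    sums <- rowsum(d$diff[si][S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov))
    cnts <- rowsum(rep(1L, length(ov)), S4Vectors::subjectHits(ov))
    at <- as.integer(rownames(sums))
    dml[ri[at]] <- sums[, 1]
    nst[ri[at]] <- cnts[, 1]
  }
  data.frame(region_id = regions$region_id, gene_id = regions$gene_id,
             kind = regions$kind, delta_ml = dml, n_sites = nst,
             stringsAsFactors = FALSE)
}

#' Per-gene methylation load
#'
#' Delta-ML of each gene-kind region (one row per region id).
#'
#' @param mat A `methylation_matrix`.
#' @param regions Region annotations (see [read_regions_bed()]).
#' @return Data frame `region_id`, `gene_id`, `kind`, `delta_ml`, `n_sites`.
#' @export
gene_ml_table <- function(mat, regions) {
  check_region_kinds(regions$kind)
  delta_ml_regions(mat, regions)
}

#' Aggregate methylation load over functional class and domain kind
#'
#' Per gene and domain kind the delta-ML is computed, genes are labelled
#' with their functional class (`"unannotated"` when missing from the map),
#' and each (class, kind) cell reports the mean, standard error
#' (sd / sqrt(n)) and gene count. Genes with no scored site in a domain are
#' excluded from that cell.
#'
#' @param mat A `methylation_matrix`.
#' @param regions Region annotations with `gene_id` and `kind`.
#' @param class_map Named vector from [read_class_map()] (may be empty).
#' @return Data frame `class`, `kind`, `mean_delta_ml`, `se`, `n_genes`.
#' @export
aggregate_domains <- function(mat, regions, class_map = character()) {
  per <- delta_ml_regions(mat, regions)
  per <- per[per$n_sites > 0, , drop = FALSE]
  if (nrow(per) == 0L) {
    return(data.frame(class = character(), kind = character(),
                      mean_delta_ml = numeric(), se = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  # one value per (gene, kind): sum over that gene's regions of the kind
  per <- stats::aggregate(delta_ml ~ gene_id + kind, per, sum)
  cls <- unname(class_map[per$gene_id])
  cls[is.na(cls)] <- "unannotated"
  per$class <- cls
  agg <- do.call(rbind, lapply(split(per, list(per$class, per$kind),
                                     drop = TRUE), function(d) {
    data.frame(class = d$class[1], kind = d$kind[1],
               mean_delta_ml = mean(d$delta_ml),
               se = stats::sd(d$delta_ml) / sqrt(nrow(d)),
               n_genes = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$class, agg$kind), , drop = FALSE]
}

#' Rank genes by methylation load
#'
#' Direction `"hypo-in-group2"` sorts descending by delta-ML (positive =
#' comparison group under-methylated relative to reference);
#' `"hyper-in-group2"` sorts ascending (most negative first). Ties break by
#' gene id.
#'
#' @param gene_ml Output of [gene_ml_table()] (or any data frame with
#'   `gene_id` and `delta_ml`).
#' @param direction `"hypo-in-group2"` or `"hyper-in-group2"`.
#' @param top_n Number of genes to return.
#' @return The top `top_n` rows, re-ranked.
#' @export
rank_genes_by_load <- function(gene_ml, direction = c("hypo-in-group2",
                                                      "hyper-in-group2"),
                               top_n = 40) {
  direction <- match.arg(direction)
  if (top_n <= 0) stopf("top_n must be positive")
  o <- if (direction == "hypo-in-group2") {
    order(-gene_ml$delta_ml, gene_ml$gene_id)
  } else {
    order(gene_ml$delta_ml, gene_ml$gene_id)
  }
  out <- gene_ml[utils::head(o, top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
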