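# End-to-end orchestration and report assembly.

pipeline_keys <- c("fasta", "alignments", "manifest", "sites", "regions",
                   "classes", "outdir", "simulate", "delta", "window",
                   "read_length", "min_lambda", "min_cal_sites", "min_diff",
                   "alpha_fdr",
                   "scale", "prior_w", "metric", "n_starts", "top_sites",
                   "n_boot", "n_perm", "seed")

#' Validate a pipeline configuration
#'
#' Either `simulate` (a list of [sim_config()] arguments) or the triplet
#' `fasta` + `alignments` (named SAM/BAM paths) + `manifest` (TSV
#' `sample<TAB>group`) must be supplied, plus `outdir`. Unknown keys are
#' rejected.
#'
#' @param config Named list.
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(config$outdir)) stopf("config requires 'outdir'")
  if (is.null(config$simulate)) {
    for (key in c("fasta", "alignments", "manifest")) {
      if (is.null(config[[key]])) stopf("config requires '%s'", key)
    }
    paths <- c(config$fasta, unlist(config$alignments), config$manifest,
               config$sites, config$regions, config$classes)
    absent <- paths[!file.exists(paths)]
    if (length(absent)) {
      stopf("input file(s) not found: %s", paste(absent, collapse = ", "))
    }
  }
  defaults <- list(delta = 2, window = 500, read_length = 71, min_lambda = 10,
                   min_cal_sites = 50,
                   min_diff = 10, alpha_fdr = 0.05, scale = NULL,
                   prior_w = 10, metric = "bray-curtis", n_starts = 20,
                   top_sites = 60, n_boot = 1000, n_perm = 9999, seed = 1)
  for (key in names(defaults)) {
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  }
  config
}

stage <- function(name, expr, outdir) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full profiling pipeline
#'
#' Site scan, per-sample quantification, matrix assembly, group-difference
#' prefilter, differential testing, methylation load, NMDS ordination with
#' permutation test and ellipses, bootstrap clustering of the top
#' discriminating sites, %MET histograms. Every intermediate table is
#' written as TSV to `outdir`, together with `run_manifest.json`
#' (parameters, seed, input checksums) and `summary.tsv` (headline
#' numbers). Any stage failure aborts with the stage name; partial outputs
#' are retained next to a `FAILED` marker.
#'
#' @param config See [pipeline_config()].
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  qconf <- quant_config(delta = config$delta, window = config$window,
                        read_length = config$read_length,
                        min_lambda = config$min_lambda,
                        min_cal_sites = config$min_cal_sites)
  checksums <- list()

  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", {
      sc <- do.call(sim_config, config$simulate)
      simulate_cohort(sc)
    }, outdir)
    genome <- cohort$genome
    sites <- cohort$sites
    manifest <- cohort$manifest
    alns <- lapply(cohort$libraries, `[[`, "alignments")
    utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    manifest <- stage("manifest", {
      mf <- utils::read.table(config$manifest, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)[, 1:2]
      names(mf) <- c("sample", "group")
      mf
    }, outdir)
    genome <- stage("reference", as_genome(config$fasta), outdir)
    sites <- NULL
    alns <- stage("alignments", {
      a <- lapply(config$alignments, read_alignments)
      if (is.null(names(a)) || any(names(a) == "")) {
        stopf("config$alignments must be a named list (sample -> path)")
      }
      a
    }, outdir)
    checksums <- lapply(c(config$fasta, unlist(config$alignments)),
                        function(p) unname(tools::md5sum(p)))
    names(checksums) <- basename(c(config$fasta, unlist(config$alignments)))
  }

  sites <- stage("sites", {
    s <- if (is.null(sites)) {
      if (!is.null(config$sites)) read_sites_bed(config$sites) else
        scan_motif_sites(genome)
    } else sites
    write_sites_bed(s, file.path(outdir, "sites.bed"))
    s
  }, outdir)

  metrics <- stage("quantify", {
    out <- lapply(manifest$sample, function(id) {
      quantify_sample(alns[[id]], sites, qconf)
    })
    names(out) <- manifest$sample
    out
  }, outdir)

  mat <- stage("matrix", {
    m <- build_matrix(metrics, manifest)
    write_matrix_tsv(m, file.path(outdir, "matrix.tsv"))
    m
  }, outdir)

  hist_tab <- stage("histogram", {
    h <- histogram_pct_met(mat)
    utils::write.table(h, file.path(outdir, "histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    h
  }, outdir)

  filtered <- stage("filter", {
    fm <- filter_by_group_difference(mat, config$min_diff)
    write_matrix_tsv(fm, file.path(outdir, "matrix_filtered.tsv"))
    fm
  }, outdir)

  diff_tab <- stage("diff", {
    dt <- differential_table(filtered, config$alpha_fdr, config$scale,
                             config$prior_w)
    write_diff_tsv(dt, file.path(outdir, "diff.tsv"),
                   group2 = unique(manifest$group)[2])
    dt
  }, outdir)

  ml <- stage("load", {
    regions <- if (!is.null(config$regions)) read_regions_bed(config$regions)
    else default_tiling_regions(genome, width = 10000L)
    gm <- gene_ml_table(mat, regions)
    utils::write.table(gm, file.path(outdir, "ml_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmap <- if (!is.null(config$classes)) read_class_map(config$classes) else
      character()
    dom <- aggregate_domains(mat, regions, cmap)
    utils::write.table(dom, file.path(outdir, "ml_domains.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gm
  }, outdir)

  ord <- stage("ordinate", {
    d <- distance_matrix(filtered, config$metric)
    fit <- nmds(d, k = 2, n_starts = config$n_starts, seed = config$seed)
    coords <- data.frame(sample = rownames(fit$points), fit$points,
                         group = manifest$group, stringsAsFactors = FALSE)
    utils::write.table(coords, file.path(outdir, "ordination_coords.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    test <- permutation_group_test(d, manifest$group, n_perm = config$n_perm,
                                   seed = config$seed)
    ell <- do.call(rbind, lapply(unique(manifest$group), function(gr) {
      e <- confidence_ellipse(fit$points, manifest$group == gr)
      data.frame(group = gr, cx = e$center[1], cy = e$center[2],
                 semi_major = e$semi_axes[1], semi_minor = e$semi_axes[2],
                 angle = e$angle, level = e$level)
    }))
    utils::write.table(ell, file.path(outdir, "ellipses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(statistic = test$statistic, p_value = test$p_value,
                 method = test$method, n_perm = test$n_perm,
                 stress = fit$stress),
      file.path(outdir, "ordination_test.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(fit = fit, test = test, d = d)
  }, outdir)

  tree <- stage("cluster", {
    ranking <- site_discrimination_ranking(filtered, ord$fit$points,
                                           manifest$group)
    utils::write.table(ranking, file.path(outdir, "site_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- utils::head(ranking$site_id, config$top_sites)
    tr <- bootstrap_branch_support(filtered$values[top, , drop = FALSE],
                                   n_boot = config$n_boot,
                                   seed = config$seed)
    write_tree_newick(tr, file.path(outdir, "tree.nwk"))
    utils::write.table(bipartition_table(tr),
                       file.path(outdir, "bipartitions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr
  }, outdir)

  stage("report", {
    summary <- data.frame(
      n_sites = nrow(sites), n_matrix_rows = nrow(mat$values),
      n_filtered_rows = nrow(filtered$values),
      n_significant = sum(diff_tab$p_fdr < config$alpha_fdr),
      n_up = attr(diff_tab, "n_up"), n_down = attr(diff_tab, "n_down"),
      ml_max = max(ml$delta_ml), ml_min = min(ml$delta_ml),
      stress = ord$fit$stress, perm_p = ord$test$p_value)
    utils::write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(package = "msreprof",
           version = as.character(utils::packageVersion("msreprof")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           parameters = config[setdiff(names(config), "alignments")],
           input_checksums = checksums),
      file.path(outdir, "run_manifest.json"), auto_unbox = TRUE, null = "null",
      digits = NA, pretty = TRUE)
  }, outdir)
  invisible(outdir)
}

# fallback regions when no annotation is given: non-overlapping tiles
default_tiling_regions <- function(genome, width = 10000L) {
  genome <- as_genome(genome)
  do.call(rbind, lapply(seq_along(genome), function(i) {
    G <- Biostrings::width(genome)[i]
    start <- seq(0L, max(0L, G - 1L), by = width)
    data.frame(chrom = names(genome)[i], start = start,
               end = pmin(start + width, G),
               region_id = sprintf("%s_tile%05d", names(genome)[i],
                                   seq_along(start)),
               strand = "+", kind = "custom",
               gene_id = sprintf("%s_tile%05d", names(genome)[i],
                                 seq_along(start)),
               stringsAsFactors = FALSE)
  }))
}

#' Per-sample %MET histogram
#'
#' Bins M-channel values into 2-point-wide bins over `[0, 100]`.
#'
#' @param mat A `methylation_matrix`.
#' @param binwidth Bin width in percentage points.
#' @return Long data frame `sample`, `bin_lo`, `bin_hi`, `count`, `density`.
#' @export
histogram_pct_met <- function(mat, binwidth = 2) {
  ms <- m_channel_sites(mat)
  breaks <- seq(0, 100, by = binwidth)
  do.call(rbind, lapply(colnames(ms$values), function(sm) {
    cnt <- hist(clip(ms$values[, sm], 0, 100), breaks = breaks,
                right = FALSE, include.lowest = TRUE, plot = FALSE)$counts
    data.frame(sample = sm, bin_lo = utils::head(breaks, -1),
               bin_hi = breaks[-1], count = cnt,
               density = cnt / sum(cnt) / binwidth,
               stringsAsFactors = FALSE)
  }))
}
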