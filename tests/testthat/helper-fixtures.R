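# Shared fixtures, memoized so expensive cohorts are simulated once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# small cohort for unit-level checks (fast: ~8s total)
small_cohort <- function() {
  memo("small", {
    cfg <- sim_config(genome_length = 3e5, n_sites = 300, n_diff_sites = 30,
                      mean_coverage = 60, seed = 7)
    co <- simulate_cohort(cfg)
    qc <- quant_config(min_cal_sites = 20)
    mets <- lapply(co$manifest$sample, function(s)
      quantify_sample(co$libraries[[s]]$alignments, co$sites, qc))
    names(mets) <- co$manifest$sample
    co$metrics <- mets
    co$matrix <- build_matrix(mets, co$manifest)
    co
  })
}

# acceptance-scale strong-effect cohort (spec conditions: 2000 sites, 100x,
# d = 0.98, delta-f = 0.3 at 100 sites, 3v3, seed 7)
acceptance_cohort <- function() {
  memo("acc", {
    cfg <- sim_config(seed = 7)
    co <- simulate_cohort(cfg)
    mets <- lapply(co$manifest$sample, function(s)
      quantify_sample(co$libraries[[s]]$alignments, co$sites))
    names(mets) <- co$manifest$sample
    co$metrics <- mets
    co$matrix <- build_matrix(mets, co$manifest)
    co
  })
}

# acceptance-scale null cohort (delta-f = 0)
null_cohort <- function() {
  memo("null", {
    cfg <- sim_config(seed = 11, n_diff_sites = 0)
    co <- simulate_cohort(cfg)
    mets <- lapply(co$manifest$sample, function(s)
      quantify_sample(co$libraries[[s]]$alignments, co$sites))
    names(mets) <- co$manifest$sample
    co$matrix <- build_matrix(mets, co$manifest)
    co
  })
}

# hand-built alignment data frame (0-based half-open, like the simulator)
toy_aln <- function(start, end, strand, chrom = "sim1") {
  o <- order(start)
  aln <- data.frame(chrom = chrom, start = as.integer(start[o]),
                    end = as.integer(end[o]), strand = strand[o],
                    stringsAsFactors = FALSE)
  aln$terminus <- ifelse(aln$strand == "+", aln$start, aln$end)
  aln
}

toy_sites <- function(motif_start, chrom = "sim1") {
  data.frame(chrom = chrom, motif_start = as.integer(motif_start),
             cut_coord = as.integer(motif_start) + 1L,
             cpg_pos = as.integer(motif_start) + 1L,
             site_id = make_site_id(chrom, motif_start + 1L, "M"),
             stringsAsFactors = FALSE)
}

# matrix fixture with explicit values (rows = M/U ids)
toy_matrix <- function(values, samples, groups, site_pos = NULL,
                       chrom = "sim1") {
  n <- nrow(values)
  pos <- site_pos %||% (seq_len(n) * 100L)
  rownames(values) <- make_site_id(chrom, pos, "M")
  colnames(values) <- samples
  msreprof:::new_methylation_matrix(
    values, data.frame(sample = samples, group = groups,
                       stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-read site evidence oracle (independent of the vectorized
# implementation): loops reads x sites
brute_force_evidence <- function(aln, sites, config = quant_config()) {
  delta <- config$delta
  E <- integer(nrow(sites))
  S <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    b <- sites$cut_coord[i]
    t0 <- sites$motif_start[i]
    for (r in seq_len(nrow(aln))) {
      if (aln$chrom[r] != sites$chrom[i]) next
      term <- if (aln$strand[r] == "+") aln$start[r] else aln$end[r]
      if (abs(term - b) <= delta) {
        E[i] <- E[i] + 1L
      } else if (aln$start[r] <= t0 && aln$end[r] >= t0 + 4L) {
        S[i] <- S[i] + 1L
      }
    }
  }
  list(E = E, S = S)
}
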