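#' Simulation configuration
#'
#' Collects every knob of the MSRE-seq read simulator. Defaults describe the
#' emulated assay: a small genome carrying isolated CCGG sites, HpaII
#' digestion at efficiency `digestion` on unmethylated genome copies, random
#' shearing to a 300 bp median fragment size, and 71 bp single-end reads. The
#' per-site methylated fraction prior is a two-component Beta mixture with a
#' sharp mode at 0.90 carrying 1/3 of sites and a broad mode at 0.60 carrying
#' the remaining 2/3.
#'
#' @param genome_length Genome size in bp.
#' @param n_sites Number of CCGG sites planted.
#' @param read_length Read length in bp.
#' @param fragment_median Median sheared fragment length in bp.
#' @param fragment_sdlog Log-normal `sdlog` of fragment lengths (shape of the
#'   sonication size distribution; the median is `fragment_median`).
#' @param mean_coverage Target fold coverage (read bases per genome base).
#' @param digestion Probability that an unmethylated site on a genome copy is
#'   actually cut (enzyme efficiency `d`); cut probability is `(1 - f) * d`.
#' @param mixture List with `weight_high`, `mode_high`, `conc_high`,
#'   `weight_low`, `mode_low`, `conc_low`: weights, modes and Beta
#'   concentrations of the methylation-fraction prior.
#' @param n_per_group Samples per group.
#' @param n_diff_sites Number of sites given a planted group difference.
#' @param effect_size Difference in methylated fraction at planted sites.
#' @param base_quality Constant Phred quality for simulated bases.
#' @param frac_low_quality Fraction of reads emitted with `low_quality`
#'   bases instead (for exercising the QC filter); default 0.
#' @param low_quality Phred quality of the injected low-quality reads.
#' @param min_fragment Fragments shorter than this are not sequenced
#'   (defaults to `read_length`); `max_fragment` optionally caps lengths.
#' @param group_names Length-2 character vector; the first group is the
#'   reference ("healthy") group.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_sites = 2000, read_length = 71,
                       fragment_median = 300, fragment_sdlog = 0.35,
                       mean_coverage = 100, digestion = 0.98,
                       mixture = list(weight_high = 1 / 3, mode_high = 0.90,
                                      conc_high = 102, weight_low = 2 / 3,
                                      mode_low = 0.60, conc_low = 26),
                       n_per_group = 3, n_diff_sites = 100, effect_size = 0.3,
                       base_quality = 35, frac_low_quality = 0,
                       low_quality = 10, min_fragment = NULL,
                       max_fragment = Inf, group_names = c("ctrl", "case"),
                       seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_sites = as.integer(n_sites),
              read_length = as.integer(read_length),
              fragment_median = fragment_median,
              fragment_sdlog = fragment_sdlog,
              mean_coverage = mean_coverage, digestion = digestion,
              mixture = mixture, n_per_group = as.integer(n_per_group),
              n_diff_sites = as.integer(n_diff_sites),
              effect_size = effect_size, base_quality = base_quality,
              frac_low_quality = frac_low_quality, low_quality = low_quality,
              min_fragment = min_fragment %||% as.integer(read_length),
              max_fragment = max_fragment, group_names = group_names,
              seed = as.integer(seed))
  w <- cfg$mixture$weight_high + cfg$mixture$weight_low
  if (abs(w - 1) > 1e-8) stopf("mixture weights must sum to 1")
  probs <- c(cfg$digestion, cfg$mixture$mode_high, cfg$mixture$mode_low)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$read_length > cfg$fragment_median) {
    stopf("read_length must not exceed fragment_median")
  }
  if (length(group_names) != 2L) stopf("exactly two group names required")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome with isolated CCGG sites
#'
#' Plants exactly `n_sites` CCGG motifs, spaced at least
#' `2 * fragment_median` apart, on an i.i.d. ACGT background from which every
#' accidental CCGG has been scrubbed (a base of each stray occurrence is
#' rewritten to `A`, which cannot recreate the motif, and the sequence is
#' re-scanned until clean). Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (single-sequence `DNAStringSet`, name `"sim1"`)
#'   and `sites` (the planted sites as returned by [scan_motif_sites()]).
#' @export
generate_genome <- function(config) {
  G <- config$genome_length
  n <- config$n_sites
  gap <- as.integer(2 * config$fragment_median)
  margin <- gap
  if (G < 10 * config$fragment_median) {
    stopf("genome_length must be at least 10 * fragment_median")
  }
  slack <- G - 2L * margin - n * 4L - (n - 1L) * gap
  if (slack < n) {
    stopf("cannot place %d sites %d bp apart in a %d bp genome", n, gap, G)
  }
  set.seed(config$seed)
  # minimum-gap placement: sorted draws plus deterministic offsets
  offs <- sort(sample.int(slack, n)) # distinct, in [1, slack]
  starts <- margin + offs + (seq_len(n) - 1L) * (gap + 4L) # 0-based motif starts
  base <- sample(c("A", "C", "G", "T"), G, replace = TRUE)
  idx <- rep(starts, each = 4L) + 0:3
  base[idx + 1L] <- rep(c("C", "C", "G", "G"), times = n)
  planted <- logical(G)
  planted[idx + 1L] <- TRUE
  # scrub accidental CCGGs on the character vector (vectorized motif scan);
  # rewriting a non-planted base to A can never create a new CCGG
  repeat {
    isC <- base == "C"
    isG <- base == "G"
    occ <- which(isC[1:(G - 3)] & isC[2:(G - 2)] & isG[3:(G - 1)] & isG[4:G])
    stray <- setdiff(occ - 1L, starts) # 0-based motif starts
    if (length(stray) == 0L) break
    for (q in stray) {
      cand <- (q + 0:3)[!planted[q + 1:4]]
      base[cand[1] + 1L] <- "A"
    }
  }
  dna <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(dna) <- "sim1"
  sites <- scan_motif_sites(dna)
  stopifnot(nrow(sites) == n)
  list(genome = dna, sites = sites)
}

#' Assign ground-truth methylation fractions
#'
#' Draws a baseline methylated fraction `f` per site from the bimodal Beta
#' mixture, then plants `n_diff_sites` group differences of exactly
#' `effect_size`: the sign of the shift in the second group is chosen
#' uniformly among the feasible directions so the contrast is never clipped.
#'
#' @param config A [sim_config()].
#' @param sites Sites data frame from [generate_genome()]/[scan_motif_sites()].
#' @return A data frame of class `sim_truth` with columns `site_id`, `f_ref`
#'   (group 1 truth), `f_alt` (group 2 truth), `is_diff`, `effect`
#'   (`f_alt - f_ref`).
#' @export
assign_methylation <- function(config, sites) {
  n <- nrow(sites)
  if (n == 0L) stopf("sites must be nonempty")
  if (config$n_diff_sites > n) stopf("n_diff_sites exceeds number of sites")
  mx <- config$mixture
  set.seed(derive_seed(config$seed, 1L))
  hi <- stats::runif(n) < mx$weight_high
  ab <- function(mode, conc) c(1 + mode * (conc - 2), 1 + (1 - mode) * (conc - 2))
  ph <- ab(mx$mode_high, mx$conc_high)
  pl <- ab(mx$mode_low, mx$conc_low)
  f <- ifelse(hi, stats::rbeta(n, ph[1], ph[2]), stats::rbeta(n, pl[1], pl[2]))
  f <- clip(f, 0, 1)
  f_alt <- f
  is_diff <- rep(FALSE, n)
  if (config$n_diff_sites > 0L) {
    pick <- sample.int(n, config$n_diff_sites)
    is_diff[pick] <- TRUE
    d <- config$effect_size
    up_ok <- f[pick] + d <= 1
    dn_ok <- f[pick] - d >= 0
    if (any(!up_ok & !dn_ok)) {
      stopf("effect_size %g does not fit in [0,1] at some sites", d)
    }
    sign <- ifelse(up_ok & dn_ok, sample(c(-1, 1), length(pick), TRUE),
                   ifelse(up_ok, 1, -1))
    f_alt[pick] <- f[pick] + sign * d
  }
  out <- data.frame(site_id = sites$site_id, f_ref = f, f_alt = f_alt,
                    is_diff = is_diff, effect = f_alt - f,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_truth", "data.frame")
  out
}

# Lognormal renewal breakpoints over [0, total) (exclusive of the ends).
shear_points <- function(total, median_len, sdlog) {
  mu <- log(median_len)
  cs <- numeric(0)
  at <- 0
  while (at < total) {
    need <- ceiling((total - at) / median_len * 1.25) + 50
    lens <- pmax(1, round(stats::rlnorm(need, mu, sdlog)))
    cs <- c(cs, at + cumsum(lens))
    at <- cs[length(cs)]
  }
  cs[cs < total]
}

#' Simulate one MSRE-seq library
#'
#' Draws genome copies until the target coverage is met. On each copy every
#' CCGG site is cut with probability `(1 - f) * d` (methylated copies are
#' protected), shear breakpoints from a log-normal renewal process are pooled
#' with the cut boundaries, and each resulting fragment of at least
#' `min_fragment` bp yields one read of `read_length` bases from a uniformly
#' chosen end (forward from the left end, reverse from the right end). Reads
#' from a cut end therefore start (forward) or end (reverse) exactly at the
#' cut boundary of [scan_motif_sites()]. Deterministic under
#' `(config$seed, sample_index)`.
#'
#' @param genome Single-sequence `DNAStringSet`.
#' @param sites Sites data frame.
#' @param truth A `sim_truth` data frame covering all `sites`.
#' @param sample_id Sample name.
#' @param group `"ref"`-side group uses `f_ref`, otherwise `f_alt`: must be
#'   one of `config$group_names`.
#' @param config A [sim_config()].
#' @param sample_index Integer used (with `config$seed`) to seed this library.
#' @param coverage Optional coverage override.
#' @return List of class `sim_library`: `alignments` (data frame with
#'   `chrom`, `start`, `end` 0-based half-open, `strand`, `terminus` — the
#'   fragment-end boundary coordinate), `sample_id`, `group`, `n_copies`, and
#'   `true_counts` (per-site copies and realized cut events).
#' @export
simulate_library <- function(genome, sites, truth, sample_id, group, config,
                             sample_index = 1L, coverage = NULL) {
  coverage <- coverage %||% config$mean_coverage
  if (coverage <= 0) stopf("coverage must be positive")
  if (!group %in% config$group_names) {
    stopf("unknown group '%s' (expected %s)", group,
          paste(config$group_names, collapse = "/"))
  }
  if (!all(sites$site_id %in% truth$site_id)) {
    stopf("truth table does not cover all sites")
  }
  f <- if (group == config$group_names[1]) {
    truth$f_ref[match(sites$site_id, truth$site_id)]
  } else {
    truth$f_alt[match(sites$site_id, truth$site_id)]
  }
  G <- Biostrings::width(genome)[1]
  L <- config$read_length
  p_cut <- (1 - f) * config$digestion
  cutc <- sites$cut_coord
  set.seed(derive_seed(config$seed, 1000L + sample_index))
  target_bases <- coverage * G
  got <- 0
  copy <- 0L
  chunk <- 0L
  starts_l <- list()
  fwd_l <- list()
  n_cut <- integer(nrow(sites))
  # copies are simulated in vectorized chunks laid out head-to-tail on an
  # "unrolled" coordinate axis; copy boundaries (multiples of G) are
  # breakpoints, so no fragment straddles two copies
  bases_per_copy <- L * G / config$fragment_median # refined after chunk 1
  while (got < target_bases) {
    chunk <- chunk + 1L
    nc <- min(4096L, max(1L, ceiling((target_bases - got) / bases_per_copy)))
    cutm <- which(matrix(stats::runif(nc * length(p_cut)), nc) <
                    rep(p_cut, each = nc), arr.ind = TRUE)
    n_cut <- n_cut + tabulate(cutm[, 2], nbins = length(p_cut))
    cut_u <- (cutm[, 1] - 1) * G + cutc[cutm[, 2]]
    total <- as.numeric(nc) * G
    bp <- c(seq(0, total, by = G),
            shear_points(total, config$fragment_median, config$fragment_sdlog),
            cut_u)
    bp <- sort(bp)
    bp <- bp[c(TRUE, diff(bp) > 0)]
    fs <- bp[-length(bp)]
    fe <- bp[-1]
    len <- fe - fs
    keep <- len >= config$min_fragment & len <= config$max_fragment
    fs <- fs[keep]; fe <- fe[keep]
    fwd <- stats::runif(length(fs)) < 0.5
    rs <- fe - L
    rs[fwd] <- fs[fwd]
    starts_l[[chunk]] <- rs %% G
    fwd_l[[chunk]] <- fwd
    got <- got + length(fs) * L
    copy <- copy + nc
    bases_per_copy <- got / copy
  }
  start <- unlist(starts_l, use.names = FALSE)
  fwd <- unlist(fwd_l, use.names = FALSE)
  end <- start + L
  o <- order(start)
  strand <- rep("-", length(fwd))
  strand[fwd[o]] <- "+"
  aln <- data.frame(chrom = names(genome)[1], start = as.integer(start[o]),
                    end = as.integer(end[o]),
                    strand = strand, stringsAsFactors = FALSE)
  term <- aln$end
  term[strand == "+"] <- aln$start[strand == "+"]
  aln$terminus <- term
  list(alignments = aln, sample_id = sample_id, group = group,
       n_copies = copy,
       true_counts = data.frame(site_id = sites$site_id, f = f,
                                n_copies = copy, n_cut = n_cut,
                                stringsAsFactors = FALSE))
}

#' Simulate a two-group MSRE-seq cohort
#'
#' Builds a genome, plants per-site ground truth, then simulates
#' `2 * n_per_group` independent libraries (sampling noise only; truth is
#' shared within a group). Sample `s<i>_<group>` belongs to the group in the
#' manifest.
#'
#' @param config A [sim_config()].
#' @param coverage Optional per-library coverage override.
#' @return List of class `sim_cohort`: `genome`, `sites`, `truth`,
#'   `libraries` (named list of [simulate_library()] results), `manifest`
#'   (data frame `sample`, `group` — group 1 first), `config`.
#' @export
simulate_cohort <- function(config, coverage = NULL) {
  if (config$n_per_group < 2L) stopf("n_per_group must be >= 2")
  gen <- generate_genome(config)
  truth <- assign_methylation(config, gen$sites)
  groups <- rep(config$group_names, each = config$n_per_group)
  ids <- sprintf("s%d_%s", seq_along(groups), groups)
  libs <- lapply(seq_along(ids), function(i) {
    simulate_library(gen$genome, gen$sites, truth, ids[i], groups[i], config,
                     sample_index = i, coverage = coverage)
  })
  names(libs) <- ids
  out <- list(genome = gen$genome, sites = gen$sites, truth = truth,
              libraries = libs,
              manifest = data.frame(sample = ids, group = groups,
                                    stringsAsFactors = FALSE),
              config = config)
  class(out) <- "sim_cohort"
  out
}

#' Materialise read sequences and qualities for a simulated library
#'
#' Sequences are extracted from the genome (reverse-complemented for minus
#' strand reads) with constant base quality; a `frac_low_quality` subset is
#' emitted at `low_quality` instead, to exercise the QC filter.
#'
#' @param lib A [simulate_library()] result.
#' @param genome The genome it was simulated from.
#' @param config The [sim_config()] used.
#' @return Data frame `id`, `seq`, `qual` (Phred+33).
#' @export
library_reads <- function(lib, genome, config) {
  aln <- lib$alignments
  sq <- Biostrings::extractAt(genome[[aln$chrom[1]]],
                              IRanges::IRanges(aln$start + 1L, aln$end))
  rev <- aln$strand == "-"
  if (any(rev)) sq[rev] <- Biostrings::reverseComplement(sq[rev])
  L <- config$read_length
  qhi <- strrep(rawToChar(as.raw(config$base_quality + 33L)), L)
  qual <- rep(qhi, nrow(aln))
  if (config$frac_low_quality > 0) {
    set.seed(derive_seed(config$seed, 2000L + nrow(aln)))
    lo <- stats::runif(nrow(aln)) < config$frac_low_quality
    qual[lo] <- strrep(rawToChar(as.raw(config$low_quality + 33L)), L)
  }
  data.frame(id = paste0(lib$sample_id, "_r", seq_len(nrow(aln))),
             seq = as.character(sq), qual = qual, stringsAsFactors = FALSE)
}
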