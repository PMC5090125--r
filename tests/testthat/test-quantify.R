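test_that("qc_filter applies the mean-confidence rule", {
  q <- function(Q, n = 10) strrep(rawToChar(as.raw(Q + 33L)), n)
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = strrep("A", 10),
                      qual = c(q(40), q(10),
                               paste0(q(40, 5), q(13, 5))),
                      stringsAsFactors = FALSE)
  kept <- qc_filter(reads)
  # Q40 -> conf 0.9999 kept; Q10 -> 0.90 dropped;
  # half Q40 / half Q13 -> 1 - (5e-5 + 0.02506)/... ~ 0.9749 kept
  conf_c <- 1 - mean(10^(-c(rep(40, 5), rep(13, 5)) / 10))
  expect_gt(conf_c, 0.97)
  expect_equal(kept$id, c("a", "c"))
  expect_equal(attr(kept, "summary")$retained_fraction, 2 / 3)

  # malformed FASTQ names the record
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-bad", "ACGT", "+", "IIII"), fq)
  expect_error(qc_filter(fq), "record 2")
})

test_that("isolate_target_reads keeps only site-proximal alignments", {
  sites <- toy_sites(10000L)
  aln <- toy_aln(start = c(100L, 9980L, 20000L),
                 end = c(171L, 10051L, 20071L),
                 strand = c("+", "+", "-"))
  expect_equal(isolate_target_reads(aln, sites, radius = 500)$start, 9980L)
  # radius 0: only motif-overlapping reads
  aln2 <- toy_aln(start = c(9900L, 9990L), end = c(9971L, 10061L),
                  strand = c("+", "+"))
  expect_equal(isolate_target_reads(aln2, sites, radius = 0)$start, 9990L)
  # unsorted input errors
  bad <- aln[c(2, 1, 3), ]
  expect_error(isolate_target_reads(bad, sites), "sorted")
})

test_that("tabulate_site_evidence classifies single reads correctly", {
  sites <- toy_sites(1000L) # cut boundary at 1001
  # read starting exactly at the cut boundary -> E=1, S=0
  c1 <- tabulate_site_evidence(toy_aln(1001L, 1072L, "+"), sites)
  expect_equal(c(c1$E, c1$S), c(1L, 0L))
  # read covering the motif with both termini far away -> E=0, S=1
  c2 <- tabulate_site_evidence(toy_aln(950L, 1021L, "+"), sites)
  expect_equal(c(c2$E, c2$S), c(0L, 1L))
  # reverse read ending at the boundary -> E=1
  c3 <- tabulate_site_evidence(toy_aln(930L, 1001L, "-"), sites)
  expect_equal(c3$E, 1L)
  # terminus within delta of the cut while spanning: counts as E only
  c4 <- tabulate_site_evidence(toy_aln(999L, 1070L, "+"), sites)
  expect_equal(c(c4$E, c4$S), c(1L, 0L))
  # no overlapping reads -> zero counts, low-coverage flag, no error
  c5 <- tabulate_site_evidence(toy_aln(100000L, 100071L, "+"), sites)
  expect_equal(c(c5$E, c5$S), c(0L, 0L))
  expect_true(c5$low_coverage)
})

test_that("tabulate_site_evidence matches the brute-force oracle", {
  set.seed(31)
  sites <- toy_sites(c(2000L, 2120L, 5000L))
  for (rep in 1:4) {
    n <- sample(30:100, 1)
    start <- sample(1500:5200, n, replace = TRUE)
    aln <- toy_aln(start, start + 71L,
                   sample(c("+", "-"), n, replace = TRUE))
    got <- tabulate_site_evidence(aln, sites)
    oracle <- brute_force_evidence(aln, sites)
    expect_equal(got$E, oracle$E)
    expect_equal(got$S, oracle$S)
  }
})

test_that("local_coverage masks digestion troughs and neighbours", {
  cfgq <- quant_config()
  sites <- toy_sites(1000L)
  depth <- rep(50, 3000)
  expect_equal(local_coverage(depth, sites, cfgq), 50)
  # digestion trough within read length of the cut is excluded
  trough <- depth
  trough[(1001 - 70):(1001 + 70)] <- 3
  expect_equal(local_coverage(trough, sites, cfgq), 50)
  # two adjacent sites: masks union; remaining positions carry the answer
  s2 <- toy_sites(c(1000L, 1100L))
  d2 <- rep(50, 3000)
  d2[(1001 - 71 + 1):(1001 + 71)] <- 0
  d2[(1101 - 71 + 1):(1101 + 71)] <- 0
  d2[500] <- 80
  expect_equal(local_coverage(d2, s2, cfgq), c(50, 50))
  # window fully masked by the union of neighbouring cut-site masks -> 0
  tiny <- toy_sites(c(60L, 100L, 140L))
  expect_equal(local_coverage(rep(1, 200), tiny,
                              quant_config(window = 80), at = 2L), 0)
})

test_that("estimate_end_capture recovers kappa from exact model counts", {
  set.seed(8)
  kappa0 <- 3.7
  lambda <- rep(100, 120)
  f <- runif(120, 0, 0.45)
  cfgq <- quant_config()
  b <- (2 * cfgq$delta + 1) * lambda / cfgq$read_length
  counts <- data.frame(site_id = sprintf("s%03d", 1:120), chrom = "c",
                       cut_coord = 1:120 * 1000,
                       E = b + kappa0 * lambda * (1 - f),
                       S = lambda * f, lambda = lambda, b = b,
                       low_coverage = FALSE)
  expect_equal(estimate_end_capture(counts, cfgq), kappa0)
  # all sites methylated -> no calibration sites -> error
  counts$S <- lambda * 0.9
  expect_error(estimate_end_capture(counts, cfgq), "calibration")
})

test_that("compute_metrics limits and flags", {
  cfgq <- quant_config()
  b <- (2 * cfgq$delta + 1) * 100 / cfgq$read_length
  counts <- data.frame(site_id = c("hi", "lo", "shallow"), chrom = "c",
                       cut_coord = c(1, 2, 3) * 1000,
                       E = c(b, b + 2 * 100, b), S = c(100, 0, 5),
                       lambda = c(100, 100, 2), b = c(b, b, b * 0.02),
                       low_coverage = c(FALSE, FALSE, TRUE))
  m <- compute_metrics(counts, kappa = 2, cfgq)
  expect_equal(m$m_metric[1], 1) # S = lambda -> clipped to 1
  expect_equal(m$u_metric[1], 0)
  expect_equal(m$pct_met[1], 100)
  expect_equal(m$m_metric[2], 0)
  expect_equal(m$u_metric[2], 1)
  expect_true(is.na(m$pct_met[3]) && !m$qc_ok[3])
})

test_that("metrics recover truth on simulation: consistency and monotonicity", {
  co <- small_cohort()
  met <- co$metrics[[1]]
  ok <- met$qc_ok & met$lambda >= 50
  s <- met$m_metric[ok] + met$u_metric[ok]
  expect_gt(mean(s > 0.8 & s < 1.2), 0.90)

  # planted-f grid: mean m increases, mean u decreases
  cfg <- sim_config(genome_length = 1.2e5, n_sites = 120, n_diff_sites = 0,
                    mean_coverage = 60, digestion = 1, seed = 21)
  gen <- generate_genome(cfg)
  truth <- assign_methylation(cfg, gen$sites)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mm <- uu <- numeric(length(grid))
  for (i in seq_along(grid)) {
    tg <- truth
    tg$f_ref[] <- grid[i]
    lib <- simulate_library(gen$genome, gen$sites, tg, paste0("g", i), "ctrl",
                            cfg, i)
    counts <- tabulate_site_evidence(lib$alignments, gen$sites)
    # kappa from a mixed library so calibration sites exist at f = 1
    kap <- if (grid[i] < 0.5) estimate_end_capture(counts) else kap
    met_i <- compute_metrics(counts, kap)
    mm[i] <- mean(met_i$m_metric, na.rm = TRUE)
    uu[i] <- mean(met_i$u_metric, na.rm = TRUE)
  }
  expect_true(all(diff(mm) > 0))
  expect_true(all(diff(uu) < 0))
})

test_that("build_matrix assembles complete-case channelled rows", {
  met <- function(ids, pct, u, ok = TRUE) {
    data.frame(site_id = ids, m_metric = pct / 100, u_metric = u,
               pct_met = pct, lambda = 100,
               qc_ok = rep_len(ok, length(ids)), stringsAsFactors = FALSE)
  }
  ids <- make_site_id("sim1", c(100L, 200L, 300L), "M")
  ml <- list(s1 = met(ids, c(90, 60, 30), c(0.1, 0.4, 0.7)),
             s2 = met(ids, c(80, 50, 20), c(0.2, 0.5, 0.8)))
  manifest <- data.frame(sample = c("s1", "s2"), group = c("g1", "g2"))
  mat <- build_matrix(ml, manifest)
  expect_equal(dim(mat$values), c(6L, 2L))
  expect_equal(rownames(mat$values),
               sort(c(ids, sub("^M", "U", ids))))
  expect_equal(mat$values["M.sim1.0000000101", "s1"], 90)
  expect_equal(mat$values["U.sim1.0000000201", "s2"], 50)

  # complete-case: a site flagged in one sample drops both its rows
  ml$s2$qc_ok[2] <- FALSE
  expect_equal(nrow(build_matrix(ml, manifest)$values), 4L)
  # manifest sample missing from inputs
  expect_error(build_matrix(ml, data.frame(sample = c("s1", "sX"),
                                           group = c("g1", "g2"))), "sX")
})

test_that("group-difference prefilter uses a strict 10-point rule", {
  v <- rbind(c(80, 80, 65, 65), c(80, 80, 75, 75), c(80, 80, 70, 70))
  mat <- toy_matrix(v, paste0("s", 1:4), rep(c("a", "b"), each = 2))
  out <- filter_by_group_difference(mat, 10)
  expect_equal(nrow(out$values), 1L) # 15-diff kept; 5 and exactly-10 dropped
  expect_error(filter_by_group_difference(
    toy_matrix(v, paste0("s", 1:4), rep("a", 4)), 10), "two groups")
})
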