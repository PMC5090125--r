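# msreprof

Quantitative CpG methylation profiling from **MSRE-seq** libraries, with
two-group discrimination statistics and a ground-truth read simulator.

## The problem

Methyl-sensitive restriction endonucleases (MSREs) such as **HpaII** cleave
their recognition site `CCGG` (cutting `C^CGG`) only when the internal CpG
cytosine is unmethylated. If genomic DNA is digested with HpaII, sheared to
~300 bp, and sequenced as short single-end reads, every CCGG locus leaves two
complementary footprints in the alignment:

- reads whose fragment end sits exactly at the cut boundary — evidence that
  genome copies at that locus were **unmethylated** (cut);
- reads spanning the intact motif — evidence that copies were **methylated**
  (protected).

`msreprof` reconstructs, for every site *i* and sample, a pair of metrics on
top of three measured signals — digest-end count `E`, motif-spanning count
`S`, and masked local coverage `λ`:

```
m_i = clip( S / (λ·g), 0, 1 )          "M" channel: fully-methylated fraction
u_i = clip( (E − b) / (κ·λ), 0, 1.5 )  "U" channel: fully-unmethylated fraction
%MET_i = 100 · m_i
```

where `b = (2δ+1)·λ/L` is the random-shearing background among end counts,
`g` the geometric fraction of read placements that can span the motif, and
`κ` a per-sample end-capture factor calibrated on majority-unmethylated
sites. On simulated data with known truth, `m + u ≈ 1` and `%MET` tracks the
planted methylated fraction.

Downstream, two groups of samples (e.g. patients vs controls) are compared
by:

- a per-site **negative-binomial exact test** (counts conditioned on the
  site total; method-of-moments dispersion with shrinkage) with
  **Benjamini–Hochberg** FDR control;
- the **differential methylation load** ΔML over a gene or region — the
  signed sum over its CpG sites of the group difference in %MET, reference
  group minus comparison group (positive = higher methylation in the
  reference group);
- **NMDS** ordination (Kruskal stress-1) with mean-confidence ellipses and
  an exact label-permutation test of group separation;
- **hierarchical clustering** (1 − Pearson, average linkage) of the top
  discriminating sites with bootstrap branch support (n = 1000).

Because real MSRE-seq cohorts are large, the package ships a seeded
simulator (`sim_config()`, `simulate_cohort()`) that emulates the assay —
HpaII digestion at efficiency *d* on a per-copy Bernoulli model with cut
probability `(1−f)·d`, log-normal shearing with a 300 bp median, 71 bp
single-end reads — with a bimodal prior on the per-site methylated fraction
(sharp mode at 0.90 holding ⅓ of sites, broad mode at 0.60 holding ⅔).
Every stage of the pipeline is validated against this planted truth.

## Worked example

```r
library(msreprof)

cfg <- sim_config(genome_length = 3e5, n_sites = 300, n_diff_sites = 30,
                  mean_coverage = 60, seed = 7)
cohort <- simulate_cohort(cfg)                  # 3 ctrl vs 3 case libraries
qc  <- quant_config(min_cal_sites = 20)
metrics <- lapply(cohort$manifest$sample, function(s)
  quantify_sample(cohort$libraries[[s]]$alignments, cohort$sites, qc))
names(metrics) <- cohort$manifest$sample

mat <- build_matrix(metrics, cohort$manifest)
mat
#> methylation_matrix: 600 rows x 6 samples (groups: ctrl, case)

filtered <- filter_by_group_difference(mat, min_diff = 10)
nrow(filtered$values)
#> [1] 143

dt <- differential_table(mat)
head(dt, 5)
#>             site_id logMET logFC    p_std    p_fdr response
#> 1 U.sim1.0000247200   4.71 -4.53 6.18e-37 3.71e-34     down
#> 2 U.sim1.0000055972   4.66 -3.76 1.72e-30 5.16e-28     down
#> 3 U.sim1.0000208900   5.14  2.31 6.04e-23 1.21e-20       up
#> 4 U.sim1.0000245447   5.58  1.99 1.09e-22 1.63e-20       up
#> 5 U.sim1.0000197640   4.89  2.39 6.69e-21 8.03e-19       up
attr(dt, "n_up"); attr(dt, "n_down")   # significant at FDR 0.05
#> [1] 30
#> [1] 29

d   <- distance_matrix(filtered)       # Bray-Curtis between samples
fit <- nmds(d, seed = 7)
fit
#> NMDS: 6 points, k=2, stress-1 = 1.215e-09
permutation_group_test(d, cohort$manifest$group)$p_value
#> [1] 0.1      # the exhaustive minimum for a 3v3 design (20 relabelings)

delta_ml(mat, list(chrom = "sim1", start = 0L, end = 3e5L))$delta_ml
#> [1] 380.4    # positive: higher methylation load in the reference group
```

Reading the output: row ids pair each CpG site's two channels
(`M.sim1.0000247200` / `U.sim1.0000247200`, named by the 1-based position of
the internal CpG cytosine, zero-padded to 10 digits). `response = "up"`
means a higher methylation signal in the *second* manifest group. In this
run 59 rows are significant at FDR 0.05 and 73% of the 30 planted
differential sites are recovered; the 3v3 permutation p of 0.1 is the
smallest value an exact 6-sample relabeling test can produce.

## Command line

```sh
Rscript inst/cli/profiler.R sites    --fasta ref.fa --out sites.bed
Rscript inst/cli/profiler.R simulate --config sim.json --outdir sim/
Rscript inst/cli/profiler.R quantify --bam s1.bam --sites sites.bed --out s1.tsv
Rscript inst/cli/profiler.R diff     --matrix m.tsv --fdr 0.05 --out diff.tsv
Rscript inst/cli/profiler.R run      --config run.json   # full report package
```

`run` writes every intermediate table (matrix, differential table, loads,
ordination, tree, histograms) plus `summary.tsv` and a reproducibility
manifest into the configured output directory.

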