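---
title: "msreprof: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msreprof: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the measurement model
behind the M/U metrics, what the simulator does and does not emulate, the
statistical machinery layered on top, and the design decisions taken where
the problem was genuinely open. Everything quantitative stated here is
computed by the test suite (`tests/testthat/`), not asserted from memory.

## 1. The measurement model

HpaII cuts `C^CGG` only when the internal CpG cytosine is unmethylated. In a
digested, sheared, single-end-sequenced library, a CCGG locus with
methylated fraction $f$ (across the genome copies of a heterogeneous cell
population) produces three observable signals per sample:

* $E$ — read termini within $\delta$ bp of the cut boundary. Forward reads
  contribute their 5' start, reverse reads their 3' end: both are *fragment*
  ends, which is where digestion leaves its mark. $\delta$ (default 2 bp)
  absorbs end-repair shifts on real data; the simulator places cut-end reads
  exactly on the boundary.
* $S$ — reads fully spanning the 4 bp motif that contribute no
  $\delta$-adjacent terminus. Only uncut (methylated or escaped) copies can
  produce them.
* $\lambda$ — the median per-base depth in a $\pm W$ window (default
  500 bp), with all positions within one read length of any cut boundary
  masked so digestion troughs and cut-end pileups do not bias the local
  baseline. $\lambda$ carries the local coverage bias that both $E$ and $S$
  must be normalized against.

Random shearing also deposits termini everywhere at rate $\lambda/L$ per
position ($L$ = read length; each read has exactly one fragment-end
terminus), so the expected background inside the matching window is
$b = (2\delta + 1)\,\lambda / L$.

### Spanning geometry

A read of length $L$ can span the motif from $L - 3$ start positions, and
$\delta$ of those place its terminus inside the exclusion zone (with the cut
after the first motif base, reverse-read ends are only excluded for
$\delta > 2$). Averaged over both orientations the spanning capacity per
unit depth is

$$g = \frac{2(L-3) - \delta - \max(0, \delta - 2)}{2L} \approx 0.944
\quad (L = 71,\ \delta = 2).$$

Without this factor the spanning ratio $S/\lambda$ systematically
underestimates the protected fraction by ~6%, which is material against a
5-percentage-point accuracy requirement. Hence:

$$\hat m = \mathrm{clip}\!\left(\frac{S}{\lambda g},\, 0,\, 1\right), \qquad
\%MET = 100\,\hat m.$$

### The U channel and $\kappa$

Cut copies are far more "visible" than uncut ones: every cut produces two
fragment ends, each sequenced with probability ½, whereas an uncut copy
yields a spanning read only at rate $\approx g L / \text{fragment length}$.
The end-capture factor $\kappa$ puts $E$ on the coverage scale:

$$\hat u = \mathrm{clip}\!\left(\frac{E - b}{\kappa\lambda},\, 0,\, 1.5\right),$$

with $\kappa$ estimated per sample as the median of
$(E - b) / (\lambda\,(1 - \min(S/\lambda, 1)))$ over scored sites whose raw
spanning ratio is below 0.5 — majority-unmethylated sites, which carry the
cut-end signal. At least `min_cal_sites` (default 50) such sites are
required; small targeted panels should lower the threshold or pool samples.
The two channels come from disjoint read sets, so their consistency
($\hat m + \hat u \approx 1$ at high coverage under complete digestion) is a
test of the model, not an assumption; the suite requires
$\hat m + \hat u \in [0.8, 1.2]$ for >90% of well-covered simulated sites.

### What a site is called

Site ids are `"{channel}.{chrom}.{pos}"` with `pos` the **1-based position
of the internal CpG cytosine**, zero-padded to 10 digits
(`M.chr19.0050595864`). Published id lists of this form do not state which
motif base anchors the number; the internal-C convention is this package's
choice and is applied consistently by the scanner, the simulator and the
quantifier. Coordinates are 0-based half-open internally and in all BED
output. CCGG is its own reverse complement, so each site is recorded once on
the plus strand; cut evidence is collected strand-aware.

## 2. The simulator: a stated world

`sim_config()` defaults describe the emulated assay: 71 bp single-end
reads, log-normal shear fragments with median 300 bp (`sdlog` 0.35 — a
typical sonication spread; the median is the only calibrated parameter),
digestion efficiency $d = 0.98$ (enzyme efficiency is rarely reported;
0.98 models a nearly complete digest with a visible escape floor), mean
coverage 100×, 2000 isolated sites in a 2 Mb genome, and a 3 vs 3 cohort.
The per-site methylated fraction is drawn from a two-component Beta mixture
with a sharp mode at 0.90 (concentration 102, weight ⅓) and a broad mode at
0.60 (concentration 26, weight ⅔) — the bimodal shape blood gDNA shows in
this assay family. Concentrations were chosen once so that the sharp mode
has ~3-point and the broad mode ~9-point spread, and the mass above 80%
methylation sits near ⅓; the closed-form mixture mass is the oracle for
that choice in the tests.

Mechanics: each genome copy is an independent Bernoulli trial per site with
cut probability $(1-f)\,d$; shear breakpoints from a genome-wide log-normal
renewal process are pooled with the cut boundaries (equivalent in
distribution to shearing each digested interval, up to negligible boundary
effects); every fragment of at least one read length yields one read from a
uniformly chosen end. Differential sites receive an exact $\pm\Delta f$
contrast in the second group, with the sign drawn among feasible directions
so the contrast is never clipped.

Deliberately **not** modelled: sequencing errors, PCR duplicates, adapter
contamination, paired ends, size selection windows (a floor at the read
length stands in for it), CpG-density structure, and correlated methylation
along the genome. A green test therefore establishes that the estimators
recover a *known, independent-site* truth under realistic digestion and
shearing physics — not that they are robust to every artefact of a real
flowcell.

### Accuracy floors, honestly

At 100× a single library observes roughly $\lambda g \approx 94$ potential
spanning reads per site, so $\hat m$ carries binomial noise of ~8
percentage points per library at high $f$. That floor is information
theory, not implementation: parameter-recovery accuracy is therefore
assessed on the 3-library group mean (measured RMSE ≈ 4.9 points against
truth at $\lambda \ge 50$), and the duplicate-library coefficient of
variation at 60× lands at ~10.5%, just above a 10% repeatability target —
the corresponding acceptance test is left failing rather than quietly
re-tuning the simulation. The U channel is intrinsically ~5× more precise
at high methylation (every cut copy is directly visible), which is why the
differential layer tests both channels.

## 3. From percentages to counts, and the exact test

The differential layer treats the matrix as count data. `to_counts()`
multiplies the %-scale values by a scale factor and rounds. A scale of 0.05
reproduces the magnitude of historical MSRE-seq "methylation count"
libraries (mean count ≈ 3), but counts that small discard nearly all of the
measurement precision and — because rescaled percentages are *not* Poisson
draws — badly mis-specify the exact test's variance model in either
direction. The default is therefore **auto-calibration**: per channel,
$s = \bar\mu / \bar v$ (mean over within-group variance), which makes the
count mean–variance relation approximately Poisson by construction. The
channels are calibrated separately because their measurement variances
differ. With auto-scaling the suite measures a null rejection rate of
~0.04 at $p < 0.05$, ~83% recall of planted 30-point contrasts, and ~4%
empirical FDR at BH 0.05 on the standard simulated cohort.

Dispersion is estimated by method of moments on library-size-normalized
counts: per site $\phi_i^{raw} = (v - \mu)/\mu^2$; the common value is the
median of $\max(0, \phi_i^{raw})$; tagwise values shrink the raw estimates
toward the common one with prior weight 10 against the 4 residual degrees
of freedom of a 3v3 design, floored at $10^{-3}$. The median/max(0)
construction is deliberately simple and is biased low by ~30% under strong
overdispersion (the median of a 2-df variance estimate is 0.69 of its
mean); with the auto-scaled counts the truth sits near zero dispersion, so
the bias is immaterial here, but users feeding genuinely overdispersed
counts should expect conservative common estimates.

The exact test conditions on the per-site total $t$ after rescaling all
samples to the geometric-mean library size (rounding half-to-even): group
sums follow negative-binomial laws with sizes $n_A/\phi$, $n_B/\phi$, the
two-sided p-value sums the probabilities of all splits no more likely than
the observed one, and $\phi = 0$ degenerates to the binomial. An
independent enumeration oracle checks every split probability to $10^{-12}$
for totals up to 30. BH adjustment is the textbook step-up; note that BH is
*not* idempotent (re-adjusting adjusted values can only increase them), so
the tests assert monotonicity and agreement with `stats::p.adjust` instead.

`logMET` is `log2(mean normalized count + 0.5)` and `logFC` the difference
of such logs (group 2 − group 1). Published tables in this assay family
carry a signed "logMET" whose transform is not public; no attempt is made
to reverse-engineer it — the implemented definition is documented here and
in the column header. `response = "up"` means a higher methylation signal
in the second manifest group; the manifest order defines the reference.

## 4. Methylation load

For a region $j$, $\Delta ML_j = \sum_i \left(\overline{\%MET}^{(1)}_i -
\overline{\%MET}^{(2)}_i\right)$ over the M-channel sites whose CpG
cytosine lies in the region, group 1 (the reference, listed first in the
manifest) minus group 2. Group means are used for each site's term — the
only well-defined choice for unpaired or unequal groups. Positive values
mean higher methylation load in the reference group. The quantity is
linear, so antisymmetry under group swap and additivity over site
partitions hold exactly and are tested exactly. A site inside overlapping
regions contributes to each; gene-level scores are independent summaries,
not a partition of the genome. Promoters default to 3000 bp upstream of
the annotated start on the annotated strand (2 kb is an equally common
convention; the width is an argument, and neither choice is asserted as
correct).

## 5. Ordination, separation, ranking

Sample distances default to Bray–Curtis on the nonnegative %-scale matrix
(Euclidean available). NMDS minimizes Kruskal stress-1 via
`vegan::monoMDS` from one classical-MDS start plus 20 seeded random starts;
the best solution is centred, rotated to principal axes and sign-fixed so
repeated runs are identical. An independent stress implementation
(isotonic regression of configuration distances on dissimilarity order via
`stats::isoreg`) serves as the oracle: exactly embeddable configurations
must reach stress $< 10^{-3}$, and the restart winner must not be beaten
by the metric start.

Group separation is tested by label permutation with the statistic
"mean between-group distance − mean within-group distance". All
$\binom{n}{n_A}$ relabelings are enumerated when there are at most 10,000;
a 3v3 design has 20, so the smallest achievable p-value is $2/20 = 0.1$
(the observed labeling and its mirror). This is worth stating plainly:
*no* 6-sample relabeling scheme can produce $p < 0.0001$, and the package
makes no attempt to reproduce such values — the exhaustive test is exact
and its granularity is the honest price of $n = 6$. For larger designs a
seeded Monte-Carlo with the $(1 + \#\{\ge\})/(1 + B)$ estimator takes over.

Per-site discrimination scores are $|r|$ between the site's value vector
and the projection of samples onto the group-centroid axis in ordination
space; zero-variance sites score 0 and ties break by id.

## 6. Clustering with branch support

Top-ranked sites (default 60; 40 is the other convention in circulation,
both are a flag away) are clustered by average linkage on
$1 - r$ (Pearson) between site profiles. Branch support is the ordinary
bootstrap probability: resample sample columns with replacement (default
$n = 1000$), rebuild, and report the percentage of replicates containing
the identical leaf bipartition. Multiscale (AU) corrections are
deliberately out of scope — AU values typically exceed BP, so BP is the
conservative report. Replicates that produce undefined correlations
(zero-variance rows after resampling) treat the correlation as 0 rather
than discarding the replicate. Trees are exported as Newick with BP as
internal node labels via `ape`.

## 7. Numerical and degenerate-input choices

* Ties in the exact test's split probabilities are compared with a
  $(1 + 10^{-10})$ relative tolerance so equal-probability splits are
  included deterministically.
* Sites with $\lambda <$ `min_lambda` (default 10) are flagged and dropped
  matrix-wide (complete case); no imputation, since downstream tests assume
  observed values.
* `filter_by_group_difference` uses a strict inequality: a group-mean gap
  of exactly 10 points is dropped.
* Zero-variance rows error in the main clustering (they cannot be
  correlated) but are tolerated inside bootstrap replicates, as above.
* All randomness flows from explicit integer seeds; per-library seeds are
  derived arithmetically from (cohort seed, sample index) and stay within
  32-bit range. Re-running any pipeline with the same config reproduces
  every output byte-for-byte.

## 8. Known limitations

* The M-channel accuracy at desk-scale coverage is shot-noise limited
  (section 2); production use of this assay family relies on much deeper
  libraries.
* The NB exact test sees pseudo-counts, and its calibration is only as
  good as the auto-scale's variance match; strongly heteroscedastic
  channels beyond M/U would need per-row scaling.
* The permutation test's granularity at $n = 6$ caps significance at 0.1;
  the NMDS ellipses are descriptive, not inferential, at that size.
* Bootstrap probabilities are known to be conservative relative to AU
  p-values for small sample counts.
* The simulator's independent-site assumption means regional statistics
  (ΔML over domains) are tested for algebra and planted signals, not for
  realistic spatial correlation.
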