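---
title: "Mapping quantitative associations between HSC gene expression and clonal blood production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping quantitative associations between HSC gene expression and clonal blood production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneAssoc)
```

## The problem

Individual hematopoietic stem cells (HSCs) produce very different amounts of
blood. When HSCs are labelled with transcribed genetic tracking barcodes
before transplantation, the read counts of each barcode in sorted blood
populations measure each clone's lineage output, and droplet single-cell RNA
sequencing of the same HSC pool measures each cell's transcriptome.
"Molecular bridges" — cDNA molecules carrying both a tracking barcode and a
droplet cellular barcode — link the two measurements, so each single-cell
transcriptome can be annotated with the blood output of its clone.

`cloneAssoc` implements the downstream analysis: quantifying clone-level
lineage output, building the validated cell–clone directory, normalizing the
expression matrix, scanning every lineage-output threshold for differential
expression, and classifying how each gene's association varies across output
levels.

## Clonal output quantification

For each mouse and sorted population, a clone's blood abundance is its read
fraction scaled into percent of all white blood cells:

\[
\%\mathrm{WBC} = (\text{pop.\ \%WBC}) \times (\text{donor frac}) \times
(\text{GFP frac}) \times \frac{\text{barcode reads}}{\text{total reads}},
\]

which makes abundances comparable between mice. HSC abundance is the read
percentage among barcoded HSCs (summing to 100 per mouse). Five measures are
carried per clone: HSC abundance (self-renewal), granulocyte abundance
(myeloid), B cell abundance (lymphoid), their total, and lineage bias

\[
\mathrm{bias} = \frac{\arctan\!\big(\tfrac{b/b_{tot}}{g/g_{tot}}\big) - \pi/4}{\pi/4}
\in [-1, 1],
\]

with the boundary cases fixed at exactly $+1$ (B-only clone) and $-1$
(granulocyte-only clone); we divide the arctan term by $\pi/4$ because that
is the only normalization whose continuous branch matches those boundary
values in the single-lineage limits. Clones contributing less than
0.001 %WBC to blood are excluded from all analyses; clones below 1% of the
per-mouse most abundant clone in *both* lineages are excluded from the bias
analysis only (excluding on either lineage alone would drop exactly the
strongly biased clones the statistic exists to measure). Both bounds are
strict, so equality passes. An optional derived column, total blood
abundance divided by HSC abundance, is carried but is not one of the five
scan measures, because the five-measure list is the one actually scanned.

## Cell–clone linkage

Bridge records are kept only when both barcodes appear on the known lists
and the summed read support reaches `min_support` (default 1 — bridge
quality is normally controlled upstream of this table; the support filter
exists because it is applied *before* the multi-map discard, so chimeric
low-support links can be rescued by raising it). A cellular barcode still
linked to two or more tracking barcodes afterwards is discarded and logged:
such cells are either multiple infections of one cell or droplet doublets,
and in both cases the clone identity is ambiguous. One tracking barcode
keeps all its cellular barcodes, since a clone may contain many HSCs.
Matching is exact string equality; no sequence-level error correction is
attempted.

## Expression QC and normalization

Cells with more than 5% of UMIs in mitochondrial genes are removed
(strictly more; the mito set defaults to symbols starting `mt-`). Genes are
kept when they show at least 3 UMIs in at least 5% of retained cells.
Expression is `log2(10000 * umi / cell_total + 1)`; the per-cell totals are
computed over **all** genes, before gene selection, since library-size
normalization conventionally precedes feature selection and the per-cell
sums are then exactly 10,000 on the pre-log scale. Sensitivity to that
ordering can be probed by passing a pre-filtered matrix.

## The threshold scan

For one output measure, every distinct clone-level output value observed
among mapped cells (pooled over mice) is a candidate threshold; cells at or
below the threshold form the "low" group, cells above it the "high" group.
A threshold is valid when both groups have more than `min_group = 4` cells
in *every* mouse — counted in cells, not clones, because the rank test
compares cell-level expression. At each valid threshold and per mouse, each
gene gets two one-sided Mann-Whitney P values (tie-corrected normal
approximation with continuity correction, the standard production path for
UMI-derived values with heavy ties; an exact tail is used for small
tie-free groups and is verified against exhaustive enumeration in the
tests). Same-direction P values are combined across mice with Fisher's
method, $X = -2\sum \log p_i \sim \chi^2_{2m}$, with P values floored at
1e-300 before the log.

Because the per-mouse expression ranks do not depend on the threshold or on
the clone relabelling, the whole scan reduces to one rank matrix per mouse
and a matrix product per cohort, which is what makes 100 scramble sets
cheap.

**Scramble calibration.** Mock cohorts are built by reassigning every cell,
within its mouse, a tracking barcode drawn uniformly *with replacement*
from that mouse's observed barcodes (with replacement is the minimal scheme
that lets clone sizes vary, which the mock is meant to allow). The
false-positive score of gene $g$ at a (direction, threshold) is

\[
\mathrm{FPS}(g) = \frac{\mathrm{median}_s\, N^{ctrl}_s(g)}{N^{exp}(g)},
\]

where $N^{exp}(g)$ counts genes with combined P at most $g$'s and
$N^{ctrl}_s(g)$ counts the same within scramble set $s$ at $g$'s
experimental P. A gene is called significant when any FPS falls below 0.05.
Note a small-cohort caveat: the gene-level call is a union over all
(threshold, direction) columns, and in cohorts with only a few hundred
tested genes the genes that top some column are a non-trivial fraction of
all genes, so the null gene-level call rate sits near (not far below) the
nominal 0.05; the per-(gene, threshold, direction) null rate is far below
0.05. With thousands of genes, as in a real cohort, the union effect
shrinks proportionally.

Two open readings of the validity rule were settled as: both groups must
exceed `min_group` (not either), and thresholds are enumerated on values
pooled across mice (consistent with ranking clones across mice); both
choices are exposed through `min_group` and the threshold table.

## Pattern classification

A significant gene's curve is its $-\log_{10}(\text{combined } P)$ over
threshold rank, taken in the gene's dominant direction (the one attaining
its minimum FPS). The cascade fits, in order, a constant $y = a$, a
Gaussian $y = b e^{-(x-\mu)^2/2\sigma^2} + c$, a step
$y = d\,[x \le f] + e\,[x > f]$, and finally the minimum-degree polynomial
whose $r^2$ reaches 0.9, counting its peaks: one peak is unimodal, two or
more multimodal. Downstream formulas are strictly more flexible than
upstream ones, which is why the order matters. Residuals are RMS Euclidean
distances on the $-\log_{10} P$ scale.

The acceptance rules around those fits deserve explanation, because the
statistic's power structure shapes every curve. The rank test's $z$ scales
with $\sqrt{n_1 n_2}$, so even a perfectly constant dose-response produces
a curve that sags toward the ends of the valid range, and a gene's peak
height scales with its effect size. Hence:

* the constant cutoff is absolute (`tau_constant = 1.2` $-\log_{10}P$
  units), because flatness is an absolute property, but acceptance is
  vetoed when the Gaussian fits to a near-noise level (`gauss_veto = 0.25`)
  while at least halving the constant residual — the "best fit" comparison
  between formulas;
* the Gaussian and step cutoffs are relative to the curve amplitude
  (`tau_gaussian = 0.085`, `tau_step = 0.14` of the range of $y$), because
  residual noise on these curves grows with amplitude;
* Gaussian acceptance also requires a positive height and an interior peak
  — the fitted curve must fall by at least `min_peak_drop = 0.25` of $b$ at
  both ends of the range, and a step that already explains the curve within
  `tau_step` vetoes it. A half-Gaussian pinned to one range end is the
  typical shape of a one-sided (discrete) association, not of a unimodal
  one;
* polynomial peaks are counted on a 512-point grid with prominence at least
  5% of the amplitude (floored at 0.1); maxima at the range ends must clear
  three times that bar, because the polynomial's edge behaviour is its
  least constrained part, and they set the boundary-peak flag.

All cutoffs sit in `classify_control()` and were calibrated on synthetic
cohorts so that noiseless curves drawn from each formula classify perfectly
and planted cohorts classify with high accuracy. Classification depends on
$x$ only through its order, so any strictly monotone re-indexing followed
by re-ranking leaves the calls unchanged.

Peak positions are reported in rank coordinates (fitted $\mu$ clamped to
the range for the Gaussian route; grid maxima for the polynomial route);
step transitions are the fitted breakpoint $f$. `colocalize()` groups peak
positions (and separately transitions) by single-linkage within a rank
window; boundary-flagged peaks are reported but never merged into interior
clusters, since the data cannot locate a peak that may lie outside the
recorded range.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the analysis assumes:
4 mice; 40 barcoded clones per mouse with independent log-normal
(meanlog 0, sdlog 1.5) true weights per lineage; multinomial read sampling
at $10^5$ reads per sorted population; a log-normal number of profiled HSCs
per clone (defaults give roughly 600 mapped cells per cohort, the order of
the measured cohort it emulates); negative-binomial baseline expression
(log-normal gene means, dispersion 2, log-normal cell size factors);
beta-distributed per-cell mitochondrial fractions realised through
dedicated `mt-*` genes; 10% of cells with no bridge record and 20% of
bridge-linked cells carrying a second tracking barcode. Mouse metadata
defaults (donor 95%, GFP 60%, granulocytes 20% and B cells 40% of WBC) are
of the same order as reported chimerism in such experiments without
claiming to reproduce any particular cohort. The true clone-output law is
not reported anywhere, so the log-normal is a modelling choice, exposed in
the configuration.

Planted genes shift their log2 mean as a function of the clone's pooled
true output-rank fraction: a centred linear dose over the full range
(constant); a centred linear dose on the low side of a single breakpoint
and flat above it (discrete) — centring matters, because an uncentred
one-sided dose plants a global mean shift whose association leaks across
the breakpoint; a two-state on/off toggle at the switch rank (unimodal);
and a state that toggles at each of several switch ranks (multimodal).
With an alternating toggle only up-switches produce peaks in the same test
direction, so the multimodal default uses three switches (0.25, 0.5, 0.75),
giving two same-direction peaks; a two-switch gene's second peak appears in
the opposite direction and its dominant-direction curve is genuinely
unimodal. Default effect sizes (log2 shifts: constant 0.6, discrete 1.5,
unimodal and multimodal 2.0) were chosen so the resulting curves have the
magnitudes such patterns display in practice — a constant dose-response
spreads a moderate effect across the whole range, while toggle genes show a
strong two-state contrast. Planted genes' baseline means are floored at 2
UMIs so they survive the detection filter.

What the generator does **not** emulate: read-level sequencing artifacts,
doublet transcriptome mixing, batch effects, clone-level expression
heterogeneity beyond the planted patterns, and any correlation between a
clone's output and how many of its HSCs are profiled. Passing tests
therefore show the pipeline recovers structure under the stated sampling
models, not that real data are free of further confounders.

## Problem sizes and numerical choices in the shipped tests

The test suite runs entirely on generated data: null calibration uses a
4-mouse, 200-clone, ~330-cell, 300-gene cohort with 20 scramble sets;
pattern recovery pools three cohorts of 4 mice x 40 clones with ~7 profiled
cells per clone (~1100 cells) and 14 planted genes spanning all four
patterns. The larger cell count for the recovery benchmark is deliberate:
at ~650 cells the curves are noisy enough that per-cohort accuracy drops to
roughly 75-80% (constant and multimodal patterns suffer first), and a
single fixed-seed run would measure Monte-Carlo luck rather than the
classifier. Gaussian fits use Levenberg-Marquardt with a 9-point
multi-start ($\mu$ at the argmax and quartiles, $\sigma$ at 1/8, 1/4 and
1/2 of the range) and bounded parameters; non-convergence from every start
yields an infinite residual and the cascade moves on. The step fit is an
exact exhaustive search over observed breakpoints via cumulative sums.
Degenerate inputs are handled explicitly: curves shorter than 5 points are
unclassifiable, empty threshold sets return empty scan results with a
warning, and an all-tied expression vector yields P = 1 in both directions.

## Limitations

The five output measures rely on granulocytes and B cells as the myeloid
and lymphoid proxies; T cells are excluded by design. The FPS procedure is
the only multiplicity control, as specified — no BH or Bonferroni
correction is layered on top. Curve classification operates on the dominant
direction only; a gene with genuinely opposite-direction associations at
different output levels contributes peaks to one direction's curve only.
Finally, acceptance cutoffs for "best fit" are calibrated on the generator;
on real cohorts with different noise structure they are starting points,
and all of them are exposed in `classify_control()`.
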