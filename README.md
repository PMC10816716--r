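# cloneAssoc

Quantitative association between the gene expression of single
hematopoietic stem cells (HSCs) and the amount of blood their clone
produces.

In barcode-tracking transplantation experiments, each HSC clone carries a
transcribed genetic tracking barcode. Sequencing the barcode in sorted
blood populations measures each clone's lineage output; droplet single-cell
RNA sequencing of the same HSC pool measures each cell's transcriptome; and
"molecular bridge" reads, which carry both a tracking barcode and a droplet
cellular barcode, connect the two. `cloneAssoc` is for researchers with
those three data types who want to know *which genes are associated with
blood production, and at which production levels*.

## What it computes

**Clonal output** — per clone and mouse, five measures: HSC abundance
(% barcoded HSCs), granulocyte and B cell abundance in %WBC
(`pop %WBC x donor frac x GFP frac x read fraction`), their total, and the
lineage bias `[arctan((b/b_tot)/(g/g_tot)) - pi/4] / (pi/4)` in [-1, 1],
with B-only clones at exactly +1 and granulocyte-only clones at exactly -1.
Clones below 0.001 %WBC are excluded everywhere; clones below 1% of the
per-mouse maximum in both lineages are excluded from bias analysis only.

**Threshold scan** — at every valid lineage-output threshold (both cell
groups > 4 in every mouse), each gene gets two one-sided Mann-Whitney
P values per mouse (is expression higher in the high- or in the low-output
group?). Same-direction P values are Fisher-combined across mice
(`X = -2 sum log p ~ chi^2_2m`). One hundred scramble cohorts — cells
randomly remapped to their mouse's observed tracking barcodes — calibrate a
false-positive score, `FPS = median(N_ctrl) / N_exp`, where `N` counts
genes at least as significant; `FPS < 0.05` is called significant.

**Pattern classification** — each significant gene's `-log10(combined P)`
curve over output rank is classified by a sequential fitting cascade:
constant `y = a`, Gaussian `y = b exp(-(x-mu)^2 / 2 sigma^2) + c` (unimodal),
step `y = d if x <= f else e` (discrete), then the minimum-degree
polynomial reaching r^2 >= 0.9, whose peak count separates unimodal from
multimodal. Peaks and transitions are colocalized across genes.

A synthetic cohort generator plants genes following each pattern and backs
the entire test suite; no external data are required.

## Worked example

```r
library(cloneAssoc)

specs <- list(
  planted_gene("constant"),
  planted_gene("unimodal", switch_ranks = 0.5),
  planted_gene("discrete", switch_ranks = 0.55)
)
cfg <- synth_config(planted_genes = specs, n_genes = 300,
                    cells_per_clone_law = list(meanlog = 1.6, sdlog = 0.8),
                    seed = 42)
cohort <- generate_cohort(cfg)
directory <- build_directory(cohort$bridges,
  known_tracking = unique(cohort$tracking$tracking_barcode),
  known_cells = cohort$cell_barcodes)
outputs <- clone_output(cohort$tracking, cohort$meta)
qc <- qc_expression(cohort$counts)
scan <- run_scan(qc, directory, outputs, measure = "granulocyte",
                 n_scrambles = 100, seed = 42)
scan
#> Association scan: measure 'granulocyte'
#>   166 genes, 4 mice, 127 valid thresholds, 100 scramble sets
#>   24 genes significant (min FPS < 0.05)

head(summary(scan)[, c("gene", "min_fps", "direction", "threshold_rank",
                       "combined_p")], 4)
#>     gene min_fps direction threshold_rank   combined_p
#> 2  g0002       0      high             65 2.725429e-44
#> 3  g0003       0      high             28 1.873787e-12
#> 1  g0001       0      high             72 6.409833e-10
#> 97 g0184       0       low             92 3.828515e-04

pat <- classify_patterns(scan)
pat[pat$gene %in% c("g0001", "g0002", "g0003"),
    c("gene", "class", "peaks", "transitions", "peak_frac")]
#>    gene      class          peaks transitions  peak_frac
#> 1 g0001 multimodal 7,76.29,124.86             0.05035971
#> 2 g0002   unimodal          62.92             0.45263881
#> 3 g0003   discrete                         63         NA
```

All three planted genes are recovered as significant with `FPS = 0`, well
ahead of the best null gene. The unimodal gene planted with its expression
switch at rank fraction 0.5 is classified unimodal with its association
peak at rank fraction 0.45, and the discrete gene's transition lands at
rank 63 of 139 candidates (~0.45, planted at 0.55). The constant gene is
significant across a broad range but classified multimodal here: the rank
test's power varies with group balance, so a constant dose-response still
yields a gently arched curve whose wiggles can defeat the flatness test —
see the methods vignette (`vignettes/association-patterns.Rmd`) for why
this is intrinsic and how the cascade's cutoffs handle it.

`run_pipeline()` wires these stages together from a YAML or list
configuration and writes TSV tables plus a JSON manifest;
`colocalize()` clusters association peaks across genes.

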