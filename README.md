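# clonotrack

Longitudinal paired single-cell TCR repertoire analysis in R: quality
control of paired α/β chains, clonotype definition by CDR3 alignment
distance, clonal-expansion and diversity statistics, clonotype tracking
across timepoints with phenotype-transition inference, GLIPH-style CDR3
motif clustering, and differential expression between expanded and
non-expanded clones — together with a synthetic cohort generator that
plants every quantity the pipeline is supposed to recover.

## Who it is for

The package targets the analysis setting of a multi-arm longitudinal
immunotherapy trial with paired scTCR-seq + scRNA-seq: patients sampled
before and after treatment (e.g. low-dose IL-2 after acute myocardial
infarction, where the drug preferentially expands regulatory T cells),
with cell phenotype labels already assigned from the expression data.
It takes AIRR Rearrangement TSVs or 10x `filtered_contig_annotations`
CSVs plus a cell metadata table, and optionally a log-normalized
expression matrix.

## The core methods

**Clonotypes by alignment distance.** Two CDR3s are compared by
`d(a,b) = min(S(a,a), S(b,b)) − S(a,b)`, with `S` the global alignment
score under BLOSUM62 and affine gaps (open 11, extend 1). Receptors are
joined when both the α and β distances are ≤ 10 (V genes are not
enforced); clonotypes are the connected components. The all-pairs stage
runs in compiled code with exact, provably lossless shortcuts for the
default parameters.

**Tracking.** The clonotype is a barcode: a clonotype observed in the
same patient at both timepoints links its pre and post cell
populations (never individual cells). Tracked phenotype tables
(2 × states) are tested with an exact r×c Fisher test implemented by
complete enumeration with probability-mass ordering; flows are
summarized by an empirical clonotype-pair transition matrix where every
tracked clonotype counts once.

**Diversity.** Shannon entropy (bits, plus a normalized variant), D50,
and size-bin distributions (1, 2–5, 6–10, 11–20, 21+) compared between
arms by chi-squared tests.

**Motif clustering.** CDR3β specificity groups from the union of
global edges (equal length, one BLOSUM62-exchangeable substitution) and
local edges (shared enriched 3/4-mer in the trimmed interior, start
positions within 3), with cluster-size filters, cross-dataset
clustering fractions against reference CDR3 sets, and position
frequency matrices for logo plots.

**Expansion phenotype.** Expanded = clonotype size ≥ 2 within
post-treatment Tregs; per-gene two-sided Wilcoxon + Benjamini–Hochberg
with an expm1-mean log2 fold change (significant at q < 0.05 and
|log2FC| > 0.3); signal-to-noise GSEA with seeded permutations;
z-score signature scoring.

## Worked example

```r
library(clonotrack)

cfg   <- simulation_config(seed = 42, cells_per_sample = 400)
study <- simulate_study(cfg)           # chains + metadata + ground truth
qc    <- qc_single_paired(study$chains, study$meta)
print(qc$report)
#> QC report
#>   input cells:          12800
#>   single_paired:        7733 (60.41%)
#>   multi_chain:          85 (0.66%)
#>   orphan:               4208 (32.88%)
#>   nonproductive_only:   729 (5.70%)
#>   invariant_removed:    45 (0.35%)
#>   no_metadata:          0 (0.00%)

assignment <- define_clonotype_clusters(qc$cells)   # 5698 clonotypes
shared     <- match_clonotypes(assignment)
shared$by_arm[, c("arm", "n_shared_clonotypes", "shared_cell_fraction")]
#>   arm     n_shared_clonotypes shared_cell_fraction
#> 1 IL2_1.5                  58               0.0508
#> 2 IL2_2.5                  28               0.0281
#> 3 placebo                   7               0.0114
```

The QC report shows the funnel from 12,800 input cells to 60% with a
single paired productive αβ receptor. The shared-cell fractions mirror
the planted arm-dependent clonotype persistence: IL-2-treated arms
carry several-fold more cells in clonotypes seen at both timepoints
than placebo. The exact Fisher test on a tracked Treg phenotype table —
6 Treg and 1 Tcm cell tracking to 1 Treg, 3 Tcm and 2 Tem cells —
gives:

```r
fisher_exact_rxc(rbind(c(6, 1, 0),
                       c(1, 3, 2)))
#> [1] 0.0414
```

a significant contraction of the regulatory compartment. See
`vignettes/clonotrack-methods.Rmd` for the full model description,
parameter conventions and limitations.

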