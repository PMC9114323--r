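# bindsurf

Nuclear RNA-binding proteins such as FUS are retained in the nucleus largely
by binding nascent RNA. When RNA polymerase II output drops — under
transcriptional inhibition, or in sporadic ALS patient-derived iPS cells —
the pool of nascent transcripts a protein can tether to shrinks, and the
protein redistributes to the cytoplasm. `bindsurf` implements the two
quantifications needed to study this:

1. **Nascent-transcript binding surface scoring.** From HOMER-style
   `findPeaks` tables (e.g. Bru-Seq re-analysis), each peak's read count is
   normalized to 10 million total aligned reads (the *peak score*
   `reads × 10^7 / total aligned reads`), peaks with score < 0.1 are
   discarded, and each retained transcript is scored as

   *binding surface score* = log2(peak score × transcript length)

   — the product of expression and length proxies how much protein a
   transcript can tether, since binding is length-dependent. Transcript
   length is the peak-region span. Conditions are compared with empirical
   CDFs and Mann–Whitney U tests, overall and restricted to a CLIP-defined
   target gene list, reporting the percent reduction of means relative to
   control.

2. **Nucleocytoplasmic fluorescence quantification.** From multi-channel
   images with whole-cell and nucleus label masks: per-cell integrated
   densities (sum of intensities = mean × area), background adjustment
   against a staining-free ROI (`ID − background mean × area`), the
   cytoplasmic-to-nuclear ratio `(whole − nuclear) / nuclear`,
   DAPI-normalized totals, nuclear poly(A+) concentration
   `(nuclear ID / DAPI ID) / nuclear area`, Pearson correlation of per-cell
   ratios between channels, and Mann–Whitney / Kruskal–Wallis + Dunn
   comparisons across conditions.

A synthetic-data module generates both input kinds with known ground truth
(configurable expression reduction, true C/N ratio, background and noise),
so every stage of the pipeline is verifiable end to end without downloads.

Intended users: labs quantifying RBP nucleocytoplasmic distribution and
nascent transcription from existing peak calls and segmented micrographs.

## Worked example

```r
library(bindsurf)

# a control/affected pair with a known 10% expression reduction
sim <- simulate_peak_pair(peak_sim_config(seed = 42))
res <- run_peak_pipeline(sim$control, sim$affected, "bru_run",
                         targets = sim$truth$target_genes)
res$comparisons$peak_score
#> <group_comparison> control (n=1971) vs affected (n=1969), Mann-Whitney U-test (normal approximation)
#>   means: 1336.29 vs 1202.13  (percent reduction 10.04%)
#>   U = 1.99119e+06, p = 0.1553 (two.sided)
```

The pipeline logs its stage counts (`control: parsed 2000, zero-read 29,
below min_score 0, retained 1971`) and recovers the simulated 10% reduction
of mean peak score as 10.04%. `bru_run/` now holds the scored tables, ECDF
tables, summaries, the comparison report (TSV + JSON) and a provenance
record. Note the distribution-level Mann–Whitney p (0.16) is insensitive to
a uniform 10% multiplicative shift at this dispersion — the percent
reduction of means, not the rank test, is the effect estimate here.

```r
# a field of 50 synthetic cells with true C/N ratio 0.5, 5% noise
field <- simulate_cell_image(cell_sim_config(true_cn_ratio = 0.5, seed = 42))
cells <- quantify_cells(field$images, "signal", dapi_channel = "dapi")
median(cells$cn_ratio)
#> [1] 0.498
head(cells[, c("cell_id", "adjusted_nuclear_id", "adjusted_cyto_id", "cn_ratio")], 3)
#>   cell_id adjusted_nuclear_id adjusted_cyto_id  cn_ratio
#> 1       1            19825.86         9922.145 0.5004647
#> 2       2            19804.08         9883.388 0.4990581
#> 3       3            19964.63         9998.190 0.5007952
```

The true ratio 0.5 is recovered to 0.4% at the default noise level; with
noise and background switched off the recovery is exact.

A thin command-line wrapper with subcommands (`simulate-peaks`,
`score-peaks`, `compare-peaks`, `simulate-cells`, `quantify-cells`,
`correlate-ratios`) is installed at
`system.file("scripts", "bindsurf.R", package = "bindsurf")`.

## Scope

The package consumes peak calls and label masks; it does not map reads, call
peaks, or segment cells (a threshold-based nucleus labeller is included for
synthetic images only). See the methods vignette
(`vignettes/binding-surface-quantification.Rmd`) for the model, parameter
choices, and limitations.
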