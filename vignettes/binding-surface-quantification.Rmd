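---
title: "Quantifying nascent-transcript binding surface and nucleocytoplasmic protein distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nascent-transcript binding surface and nucleocytoplasmic protein distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsurf)
```

## The scientific problem

Predominantly nuclear RNA-binding proteins (RBPs) such as FUS are anchored in
the nucleus in large part by the RNA they bind. Because binding is
length-dependent and relatively promiscuous, the amount of "anchor" a cell
offers scales with both how much nascent RNA is being made and how long the
transcripts are. When RNA polymerase II output falls, that binding surface
shrinks and the RBP partitions toward the cytoplasm — a behaviour with direct
relevance to ALS/FTD, where cytoplasmic FUS mislocalization is a pathological
hallmark. `bindsurf` provides the two measurement procedures this question
needs: a transcriptome-side score of available binding surface, and an
image-side quantification of where a protein (or poly(A+) RNA) actually sits
within cells.

## Binding surface scoring

### Model and definitions

The unit of analysis is a nascent-transcript *peak region* from a
HOMER-style `findPeaks` table (e.g. from Bru-Seq data). For a peak with raw
read count $r$ in a library of $T$ total aligned reads:

$$\text{peak score} = \frac{r \times 10^7}{T}$$

i.e. reads rescaled to a nominal 10-million-read library, making samples of
different depth comparable. Peaks with score $< 0.1$ are discarded as noise;
a score of exactly 0.1 is retained (the rule is "discard strictly smaller").
Transcript length $L$ is the peak-region span under 0-based half-open
coordinates ($L = \mathrm{end} - \mathrm{start}$), on the assumption that the
actively transcribed region detected as a peak approximates the nascent
transcript's length. The quantity of interest is

$$\text{binding surface score} = \log_2(\text{peak score} \times L),$$

a log-scale proxy for how much RBP one transcript species can tether:
expression multiplies opportunity, length multiplies binding sites. The log
base is 2 and is not configurable. Zero-read peaks are removed before
scoring — their score is undefined and they could never pass the 0.1 filter.

Two samples are compared by (a) the empirical CDFs of their binding surface
scores, (b) a Mann–Whitney U test, and (c) the percent reduction of means,
$100\,(\bar{x}_{\mathrm{ctrl}} - \bar{x}_{\mathrm{aff}})/\bar{x}_{\mathrm{ctrl}}$,
with the control group as reference. Analyses can be restricted to an
RBP target gene list (e.g. CLIP-defined FUS targets); matching is exact,
case-sensitive string equality on gene identifiers, with no alias
resolution — target lists should use the same annotation as the peak tables.

### Design notes and conventions

- **Coordinates.** HOMER input is 1-based inclusive and is converted on read
  to 0-based half-open (start − 1, end), which makes length a plain
  difference; BED export passes coordinates through unchanged; export back
  to the HOMER dialect inverts the conversion exactly.
- **Count column.** The HOMER dialect does not fix which column is "the"
  per-peak read count (and gene names only appear in annotated tables), so
  the reader exposes `count_column` and `gene_column` selectors, defaulting
  to a column matching "Tag Count" and "Gene Name" respectively.
- **Library size.** `total_aligned_reads` is tag-directory metadata and is
  always supplied by the caller, never inferred from the peak table.
- **Peaks vs genes.** Each peak region is scored independently; when one
  gene has several peaks they all enter the analysis, because the unit the
  score is defined on is the peak. An optional per-gene aggregation (sum of
  peak scores, maximum length) exists but is off by default.
- **Filter threshold.** Only the normalized-score threshold (0.1 per 10
  million reads) is implemented. A raw-read-count floor in the millions
  would be inconsistent with this scale — 0.1 per 10 million corresponds to
  a handful of reads in a typical library — so no such floor is offered.
- **Sidedness and multiplicity.** The Mann–Whitney test defaults to
  two-sided, the conservative choice when a direction is not pre-registered;
  comparisons are single and pairwise, so no multiple-testing correction is
  applied in the peak pipeline.

### The rank-sum test

`rank_sum_test()` reports the U statistic of the first (reference) sample,
computed from midranks, so $0 \le U \le n_a n_b$ with ties shared evenly.
The p-value is exact (by the distribution of U over all rank assignments)
when $n_a + n_b \le 12$ and there are no ties; otherwise the normal
approximation with continuity correction and the tie correction to the
variance is used. The exact small-sample p-values are verified in the test
suite against an independent brute-force enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments. For three or more groups, `dunn_test()`
runs Kruskal–Wallis followed by Dunn's pairwise z-tests on mean midranks
with tie correction; the p-value adjustment is Bonferroni by default and
configurable, Bonferroni being the most conservative standard choice where
no particular adjustment is mandated.

## Image quantification

### Measurement model

Inputs are registered intensity channels plus three masks: whole-cell
labels, nucleus labels (same label ids, each nucleus contained in its cell),
and a staining-free background ROI disjoint from all cells. For each cell
and channel:

- integrated density (ID) = sum of intensities over a mask (identically
  mean × area);
- background adjustment subtracts `background mean × area`, where the
  background mean is that channel's mean intensity over the staining-free
  ROI. The subtraction is oriented signal-minus-background so that adjusted
  signals stay nonnegative; negative results (region dimmer than background)
  are non-physical, clamped to 0 and flagged per cell;
- cytoplasmic ID = whole-cell ID − nuclear ID (exact additivity);
- C/N ratio = cytoplasmic ID / nuclear ID, undefined (and excluded from
  downstream statistics) when the adjusted nuclear ID is not positive;
- DAPI-normalized total = adjusted whole-cell ID / adjusted DAPI ID,
  correcting for focal-plane differences across a field;
- nuclear poly(A+) concentration = (adjusted nuclear ID / DAPI ID) /
  nuclear area.

Two conventions were genuinely open and are fixed as follows, each behind a
switch. The DAPI integrated density is measured over the *nuclear* ROI,
since DAPI is a nuclear stain and cytoplasmic DAPI pixels are background.
Background adjustment is applied *before* DAPI normalization
(`dapi_use_adjusted = TRUE`), because normalizing raw totals would divide
one background-contaminated quantity by another; the raw-ratio behaviour
remains available for comparison with analyses that normalized first.

Cells whose whole-cell mask touches the image border are excluded (and
counted in the log): a truncated cytoplasm biases the ratio downward in a
way no correction can undo. Segmentation itself is out of scope — masks are
curated inputs, as in manual ROI workflows; the included
`nucleus_mask_from_dapi()` (global threshold + connected components) is a
convenience for synthetic images only and makes no attempt at touching-object
splitting or illumination correction.

Per-cell ratio pairs across two channels are correlated with Pearson's
product-moment coefficient, p-value from the t distribution with $n-2$
degrees of freedom; pairs with an undefined ratio are dropped first and the
correlation is reported undefined below 3 complete pairs or at zero
variance.

### Numerical choices

All arithmetic is double precision; the additivity and
background-cancellation identities hold to floating-point exactness and are
asserted at 1e−9 in the tests. TIFF I/O stores intensities as 32-bit
samples scaled to a declared full-scale value (default 65535), resolving
about 1.5e−5 intensity units; label masks round-trip exactly. Scored tables
are written with 15 significant digits, preserving 12-digit round trips.

## The synthetic-data generators

### Peak tables

`simulate_peak_pair()` draws per-transcript lengths and base expressions
log-normally: lengths with log10 mean 3.5 and sd 0.6 (median ~3 kb, spanning
hundreds of bases to tens of kilobases) and expression with log10 mean 2 and
sd 1 (spanning roughly four orders of magnitude) — the spread structure,
not any particular dataset, is what these emulate. The affected condition
carries a multiplicative expression reduction `effect_fraction` (default
0.10, the effect size the pipeline is designed to resolve). Replicate noise
is multiplicative log-normal with natural-log sd 0.02 by default — the
technical, not biological, variability of deeply sequenced libraries, where
the dominant realistic dispersion is already carried by the four-decade
expression distribution; a Poisson option provides count-level realism
instead. With the default library size of 1e7, peak scores equal raw reads,
which keeps worked examples legible.

The generator has two coupling modes, because two different validation
questions need two different null structures:

- **paired (default):** both conditions share per-transcript bases, and
  observed counts are independent replicate draws around `base` and
  `base × (1 − effect)` with log-median-1 noise. The expected ratio of mean
  peak scores is then exactly `1 − effect`, and because the heavy-tailed
  base weights cancel between numerator and denominator, the end-to-end
  percent reduction is recoverable to a fraction of a percentage point at
  2,000 transcripts. This is the mode for effect-recovery validation.
- **unpaired:** the affected condition's lengths and expressions are drawn
  independently from the (scaled) population. At zero effect the two
  samples are fully exchangeable i.i.d. draws — precisely the null
  hypothesis a two-independent-sample rank test assumes — so this is the
  mode for calibration studies. Applying a two-sample test to the *paired*
  mode would be statistically inappropriate (the shared bases pin U near
  its mean, making the test arbitrarily conservative), and conversely the
  unpaired mode cannot pin down a mean ratio tightly because the
  heavy-tailed means no longer cancel. The two modes are therefore not
  interchangeable, and each validation uses the one whose assumptions it
  tests.

What the generator does not emulate: gene-level correlation structure,
chromosomal position effects, mappability artefacts, or peak-calling noise
(peak boundaries are taken as given). Passing recovery tests on synthetic
data therefore demonstrates the correctness of the scoring and comparison
arithmetic under the stated statistical structure, not robustness to
upstream peak-calling choices.

### Cell images

`simulate_cell_image()` renders non-overlapping disk cells (nucleus radius
8 px inside cell radius 16 px by default, 50 cells in a 512×512 frame),
placed by rejection sampling with a 10,000-proposal budget so impossible
configurations fail fast with a clear error. The nuclear stain intensity is
100 (arbitrary units); each cell's cytoplasmic intensity is chosen so its
ratio of cytoplasmic to nuclear integrated density equals `true_cn_ratio`
*exactly* before corruption; the default true ratio of 0.5 represents a
predominantly nuclear protein in unstressed cells. A uniform background of
10 is added everywhere, then Gaussian noise of sd 5 (5% of the nuclear
signal), clipped at zero. Exact masks and a staining-free ROI are emitted,
so ground-truth recovery is exact in the noiseless case and a median-based
check at the default noise recovers the ratio within a fraction of a
percent. Not emulated: point-spread blur, uneven illumination, cell-shape
variability, touching cells, or 3D structure — the simulator validates the
measurement arithmetic, not segmentation robustness.

`simulate_ratio_pairs()` produces paired positive ratios by exponentiating
bivariate normals with latent correlation `r_target`; the exp mapping
attenuates intermediate correlations slightly (as real ratio-scale data
does), while `r_target` of 1 or 0 map to exact or near-zero sample
correlations.

## Validation problem sizes

The shipped tests use 1,000 random transcripts for the score-oracle check,
200 random small-sample instances against the brute-force rank-sum
enumeration, 500 simulated pairs of 200 transcripts for null calibration,
2,000 transcripts for effect recovery, and 20–50 cells per image condition —
sizes at which every Monte-Carlo band in the tests is comfortably wide of
its expected sampling error while the whole suite runs in well under a
minute.

## Known limitations

- Gene-identifier matching is exact; cross-annotation target lists must be
  harmonized upstream.
- The rank-sum normal approximation is used whenever ties exist, even for
  tiny samples, where an exact permutation p with ties would be possible
  but is not implemented beyond the enumeration used in the test suite.
- The C/N ratio is undefined for cells whose adjusted nuclear signal is
  zero; fields dominated by such cells yield empty comparisons rather than
  imputed values.
- The image branch treats masks as ground truth; segmentation errors
  propagate directly into integrated densities.
- Percent reduction of means is reported without a confidence interval;
  uncertainty should be assessed by the accompanying rank-sum test or by
  replicate simulation.
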