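---
title: "Models and methods behind ctdseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctdseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctdseq` analyses the genome-wide occupancy of RNA polymerase II and its
CTD phospho-isoforms (Tyr1P, Ser2P, Ser5P, Ser7P) together with chromatin
marks, nucleosome positioning and strand-specific short RNAs. This
vignette explains the models, the conventions, the tunable parameters, and
the design decisions made where more than one reasonable choice existed.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Data model and coordinate conventions

All signal lives in `genome_track` objects: one numeric value per
fixed-width bin per chromosome, bin `i` covering `[i*bin, (i+1)*bin)` in
0-based half-open coordinates. Two bin widths are used in practice: 50 bp
for profiles, selection and enhancer calling, and 10 bp for the
maximal-peak spatial analyses, where single-bin resolution matters.

Internally every coordinate is 0-based half-open; BED is read as-is, GFF3
and wiggle are converted at the I/O boundary, and conversions never happen
anywhere else. This single-convention rule is deliberate: the pipeline is
full of ±N-bp oriented windows, and mixing conventions is the classic
source of one-off errors in this kind of analysis.

Strand-oriented windows are built from boundary anchors: the TSS boundary
of a plus-strand gene is its `start`, of a minus-strand gene its `end`;
an oriented offset `x` maps to `boundary + x` on plus and `boundary - x`
on minus. Consequently the antisense window `[TSS - 500, TSS)` of a
minus-strand gene lies genomically downstream of its TSS boundary, as it
must.

Peak and maximum positions are reported as the 5'-most edge of the summit
bin. On the minus strand the genomic position of an oriented offset `o` is
therefore `tss - o - bin` (`offset_to_genomic()` encodes this); all
internal comparisons use this one convention.

A chromosome-sizes file is required alongside any track file, because
coverage formats do not state where chromosomes end.

# Tag processing

* **Pile filtering.** Duplicated (chromosome, position, strand) towers are
  capped at `k` tags. The default `k` is the smallest value whose Poisson
  upper-tail probability falls below 1e-6 at the genome-wide per-position
  density `n_tags / (2 * genome_size)`; a fixed `k` can be supplied
  instead. The exact thresholding rule used historically for such data is
  not recoverable, so both variants are exposed and the probabilistic one
  is the default.
* **Fragment-length estimation.** The shift maximising the correlation
  between binned forward-read and reverse-read 5'-end densities, scanned
  from the read length upward at 10-bp resolution, ties broken toward the
  smallest shift. This is the standard strand cross-correlation estimator.
* **Elongation and binning.** Tags are extended to the estimated fragment
  length in their 3' direction; the per-bin value is the mean per-bp
  coverage, so total mass equals summed fragment length exactly (the test
  suite checks mass conservation to 1e-9).
* **Input subtraction.** The input track is scaled to the signal track's
  genome-wide mass (per-million scaling is available), subtracted bin-wise
  and clipped at zero. Clipping is intentional: downstream mixture fits
  and profile means assume non-negative occupancy. No separate local
  reweighting step is implemented beyond this global scaling.
* **Nucleosomes.** Paired MNase fragments are scored in two modes:
  *density* (fragment-span coverage, no input subtraction) for depletion,
  and *midpoint* (unit mass at `floor((start+end)/2)`, the approximate
  dyad) for positioning. Orphan single-end tags are connected into
  pseudo-fragments with the estimated fragment length.

# Selection of significantly bound genes

Per-gene mean signals — over `[TSS - 1000, TES + 2000]` for gene-level
selection or TSS ± 500 bp for promoter-level selection — are modelled as a
two-component Gaussian mixture, fitted on the raw (not log) scale by EM
with deterministic initialisation: component means at the 25th/75th
percentiles, both standard deviations at half the overall SD, equal
weights, a log-likelihood tolerance of 1e-8 and at most 500 iterations.
The significance threshold is the mean of the upper component. A log-space
fit is available by flag.

Two degeneracy guards protect the threshold's meaning. First, a minimum
standardised separation `(mu2 - mu1) / sqrt(pi1 s1^2 + pi2 s2^2)`
(default 2). Second, a bimodality check: the fitted mixture density must
have a local minimum strictly between the component means — if the fitted
density is unimodal, "the mean of the second component" is not a
defensible cutoff no matter how far the means sit apart. Degenerate fits
refuse to produce a selection unless an explicit override threshold (for
example 0, for a deliberately relaxed selection) is supplied.

Gene filters applied before profile and statistics analyses: any two gene
intervals closer than 2 kb (including overlaps) remove *both* genes; only
genes strictly longer than 2 kb are kept; histone, rRNA, snomiRNA, snoRNA,
snRNA and tRNA genes are removed; genes whose short-ssRNA mean (TSS ± 500,
both strands summed — the exact region for this rule is our documented
choice) is an upper IQR outlier are removed. Each rule is evaluated on the
full input set, so the rules commute and per-rule counts are reported.

Quartiles use linear interpolation (type 7) throughout; the outlier rule
is strictly one-sided (`x <= Q3 + 1.5 IQR`), so low values are never
removed.

# Profiles

Anchored matrices resample the binned signal onto windows
`[anchor - flank, anchor + flank)` in the anchor's 5'→3' orientation; row
means equal per-region means exactly, which the tests exploit as a
cross-operation consistency check. Composite gene profiles interpolate the
body bins linearly at bin centres onto 1000 points and attach the inner
halves of the TSS and TES flank windows — `[TSS - flank, TSS)` upstream
and `[TES, TES + flank)` downstream — at bin resolution. Rank strata are
the top 5%, 5–20% and bottom 5% of rows by a ranking value (default:
whole-gene mean, since the precise historical ranking window is ambiguous),
ties keeping stable input order.

AT/GC content matrices are binary: W scores A/T, S scores G/C, N is zero
in both classes. Spearman correlations of per-region means serve both
replicate-reproducibility checks and cross-mark correlation at promoter
sections or enhancer centres.

# Antisense/sense statistics

The paired test compares per-gene antisense and sense means (500-bp
oriented windows flanking the TSS). Outlier filtering is applied per side
and intersected — a gene survives only if it is not an upper outlier on
either side; the alternative (pooled filtering) is not distinguishable
from the available descriptions, and the per-side variant is symmetric
under AS/S exchange, which the tests verify (swapping sides negates t and
preserves p). Optional min-max scaling of the surviving pooled values is
affine and therefore cannot change the t statistic or p value — it is kept
because display conventions use the scaled values. Optional Pol II
normalisation divides both sides by the per-gene Pol II mean, dropping and
counting genes with a zero normaliser. A Shapiro–Wilk p value on the
differences is logged as a diagnostic but never used as a gate.

Expression strata merge replicates by the mean, probes by the median per
gene, order genes and cut at two quantile positions (defaults 0.60 and
0.82, chosen to reproduce the low/medium/high stratum proportions used in
this kind of analysis; exact historical boundaries are not recoverable).

# Promoter classes and spatial organisation

Genes are ordered by the oriented offset of their maximal Tyr1P bin within
TSS ± 1000 bp (tie → 5'-most bin; all-zero rows are dropped). Class cuts
default to −100/+100 bp with a closed middle interval; because only the
resulting class sizes, not the cuts, are documented for real data, a
utility back-solves cuts from target class proportions.

The spatial analysis is restricted to class I genes with significant,
dominant antisense transcription, selected in two gates around the
detected Tyr1P maximum (window `[peak - 50, peak + 100]`, oriented): the
antisense short-RNA mean must clear the usual mixture threshold across
genes, and antisense must exceed sense in a per-gene one-sided
Mann-Whitney-Wilcoxon on the window's per-bin values (15 bins per side at
10-bp bins, p < 0.05). Using the window's per-bin values as the two MWW
samples is a documented choice; the available descriptions do not state
the sample construction.

For each mark, the maximum within ±100 bp of the Tyr1P peak is located and
its signed distance to the Pol II maximum computed: positive distances
point away from the TSS on the upstream (antisense) side. Colocalization
tolerance defaults to one bin (10 bp). Distance distributions are compared
to a background set with a two-sample KS test on raw distances; 10-bp
binning appears only in the emitted histograms.

# Enhancer workflows

Both workflows share the same splitting logic. Stage 1 requires ≥1-bp
overlap of the required peak sets (Pol II + H3K4me1 + H3K4me3, or just the
two methylation marks); the candidate region is the merged footprint of
the overlapping peaks — the combination operator is our choice, the
simplest one consistent with "combined enrichment". Stage 2 assigns
candidates overlapping any oriented `[TSS - 2000, TSS + 1000]` window to
the promoter branch. Stage 3 rejects intergenic candidates within 5 kb of
any gene (minimal interval gap, 0 if overlapping) or with an H3K36me3 peak
within 2 kb of their boundaries — the signature of unannotated or
lincRNA-like transcription units; peak presence rather than a signal-mean
rule is the default for "significant H3K36me3 in vicinity". Stage 4
applies the H3K4me3/me1 mean-ratio threshold: intergenic candidates keep
enhancer status below it, promoter candidates at or above it. The
threshold itself was historically drawn by eye between the two ratio
populations; the reproducible default here is the 5th percentile of
annotated-promoter ratios (TSS ± 1000 windows), which is conservative
toward excluding promoter-like regions, and a constant override is
available. Regions with a zero H3K4me1 mean are dropped and counted.
Stage 5 centres regions on the Pol II (or H3K4me3) maximum, computes
short-RNA means on centre ± 2000 and drops IQR outliers per class.

Peak-calling thresholds and merge gaps are data-set-specific inputs, in
signal units and bp respectively (a per-mark table of such values is the
natural companion of real data).

Pol II-normalised mark levels at final regions (centre ± 2000) are
compared between enhancers and promoters with a two-sided MWW. Tissue
specificity takes the nearest gene on each side of each final enhancer and
asks, per tissue, whether the associated genes exceed the whole atlas
(one-sided MWW), ranking tissues by ascending p with alphabetical
tie-breaks.

# The synthetic genome generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery claim is measured.

What it emulates: genes on both strands with promoter-proximal summit
pairs for Pol II and the isoforms; three promoter classes (proportions
57.5/31.2/11.3%, matching the observed class sizes) with planted
Tyr1P-offset ranges −800..−150, −80..+80 and +150..+800 bp; per-mark
placements relative to Pol II drawn from the observed
before/colocalized/after frequencies for Tyr1P, Ser5P and Ser7P with
magnitudes of 20–40 bp; a planted antisense/sense Tyr1P summit asymmetry
(`as_s_delta`, default 2 signal units on a summit height of 8); Ser2P and
H3K36me3 gene bodies; promoter-flavour H3K4me3 > H3K4me1 and
enhancer-flavour H3K4me1 > H3K4me3; intergenic enhancer islands with
Pol II, isoform signal (Tyr1P relatively enriched over Pol II), optional
H3K27ac and bidirectional short RNAs; lincRNA-like distractors whose
H3K36me3 bodies sit within 2 kb of their promoter-like peaks; positioned
−3/−2/−1/+1 nucleosome dyads around an NDR; GC enrichment at class I
promoters; a pure-background input; an 84-tissue expression atlas with a
planted tissue-specific factor (default 4×) on enhancer-flanking genes;
and a tag stream with standard fragment geometry, planted duplicate piles
and paired MNase fragments.

Numerical design choices worth knowing:

* **Summit shape.** Gaussian with sd 40 bp. Wider summits (at the
  ~150-bp fragment scale) proved unusable as planted truth: when two
  summits sit within a few hundred bp their sum displaces each maximum by
  tens of bp, destroying bin-exact recovery. 40 bp keeps every planted
  maximum exactly in its bin while remaining smooth at 10-bp bins.
* **Mirrored summits.** Pol II, Ser5P and Ser7P summits are mirrored about
  the TSS at equal height (the mirror of bin `[o, o+B)` is `[-o-B, -o)`),
  giving exact per-gene antisense/sense symmetry. Mirrors are omitted for
  TSS-proximal summits (|offset| < 150 bp), where the pair would blend
  into a single displaced maximum; those offsets are instead drawn from a
  TSS-symmetric bin grid, so symmetry holds over the gene population. The
  Tyr1P mirror carries height `8 - delta` against the dominant summit's
  `8 + delta`, encoding antisense dominance while keeping the planted
  maximum unambiguous.
* **Background noise.** Poisson counts per bin (rate 0.2 per 50 bp,
  rescaled to the bin width) smoothed over 150 bp to emulate
  fragment-scale autocorrelation, plus optional Gaussian jitter. Unsmoothed
  unit-count noise at 10-bp bins would displace summit bins at random;
  smoothing reproduces the spatial correlation real coverage has after
  fragment elongation.
* **Grid alignment.** All element coordinates live on a 50-bp grid so that
  planted summits land exactly on bin centres of both supported bin sizes.
* **Antisense RNA levels.** Class I genes carry antisense short-RNA levels
  in three groups: none (50%), weak (15%, tight around height 5.5) and
  dominant (35%, tight around height 10, with sense at a quarter of the
  antisense level — a 4× separation). The weak group is deliberately
  placed far from both the background and the dominant cluster: the
  mixture's upper component must absorb it, which holds its mean below the
  dominant cluster and makes the "mean of the second Gaussian" threshold
  recover the planted dominant set stably. This mirrors the situation on
  real data, where the bound population is broad and the threshold falls
  in its lower reaches.
* **Strong planted margins.** Effect sizes default to ≥5 SD separations so
  recovery tests are stable at small n; shrinking the margins (for power
  studies) is a config change, not a code change.

What it does **not** emulate — and what passing tests therefore do not
show about real data: mappability and copy-number artefacts, GC bias,
replicate-level biological variability, overlapping or nested gene
structures beyond the planted spacing violations, sequence-specific
binding, unbound gene populations in the default study (every default gene
is active, so a gene-level mixture on the default study is correctly
flagged degenerate), and the long-tailed peak-height distributions of real
ChIP. Recovery rates measured here are upper bounds for what the same
code achieves on real libraries.

Problem sizes: the default study uses 120 genes, 40 enhancers and 15
distractors on two 1.2-Mb chromosomes at 50-bp bins; class/spatial
analyses use 870 genes (≈500 class I) on five 2.3-Mb chromosomes at 10-bp
bins; calibration loops use 100–1000 replicates at n = 500–2000. These
sizes give stable statistics while keeping the full suite fast enough to
run routinely.

# Known limitations

* The EM threshold is a local optimiser under a fixed, documented
  initialisation; multi-modal inputs with more than two populations can
  settle in different partitions, which is why the degenerate flag and the
  override exist.
* The ratio threshold's quantile default is reproducible but not
  equivalent to a by-eye cut; on data where annotated promoters are
  atypical it should be overridden.
* `estimate_elongation` assumes a dominant point-source geometry; samples
  without localized enrichment give a noise-driven argmax (the read-length
  lower bound and tie-break make the degenerate case deterministic).
* Wiggle output is fixedStep only (variableStep and bedGraph are read);
  bigWig is out of scope.
* The interfaces are R functions plus `scripts/acceptance.R`; there is no
  shell CLI. The functions compose in a few lines (see the README), which
  is the intended mode of use.
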