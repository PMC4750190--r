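---
title: "Characterizing hypomethylated-block boundaries: models and design"
author: "hmboundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing hypomethylated-block boundaries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colon tumors (and several other solid tumors) lose DNA methylation over
megabase-scale contiguous regions — hypomethylated blocks (HMBs) — that
collectively cover roughly half the genome. The blocks have surprisingly
sharp edges, which suggests that whatever nucleates or arrests the loss of
methylation is encoded locally, in the sequence and chromatin immediately
around the block edge. `hmboundary` provides the full analysis used to ask
that question: it builds fixed-length boundary regions around block edges,
asks whether transcription-factor (TF) motif content distinguishes
boundaries from matched control regions, whether promoter-like chromatin
marks and CTCF sites pile up at the edge, and whether the blocks align with
the pre-existing 3D chromatin architecture (TADs, intra-block Hi-C
contacts).

Every stage is exercisable on synthetic inputs with planted structure, so
the whole pipeline is testable without any external download.

## Region model

Coordinates are 0-based half-open (BED convention) at every interface; the
in-memory currency is the Bioconductor `GRanges`. A block's **boundary
region** is 6 kb: 5 kb outside the edge plus 1 kb inside
(`boundary_spec()`), the inside kilobase absorbing imprecision in the mapped
edge. Boundary regions that would run past a chromosome end are dropped, not
truncated, so every feature vector covers exactly 6,000 bases; for unclipped
blocks the count is exactly twice the block count.

Three control classes match the boundary class: regions **inside** blocks,
regions **outside** blocks (both sampled non-overlapping and disjoint from
all boundary regions), and strand-aware **promoters** (5 kb upstream + 1 kb
downstream of the TSS; a minus-strand TSS at coordinate p gives
`[p - 1000, p + 5000)`). Control placement draws a start uniformly from the
remaining eligible positions and removes the occupied span before the next
draw; this is unbiased within the eligible space, always succeeds when
space remains, and is deterministic under the seed. GC matching bins the GC
fraction (2% bins) and subsamples candidates per bin to the case histogram,
reporting—rather than failing on—per-bin shortfalls.

## Motif scanning with exact null p-values

Motifs are position weight matrices over A/C/G/T. A window scores
`sum_i log2(p(base_i, i) / bg(base_i))` bits; both strands are scanned and a
**hit** is any window whose p-value under the i.i.d. background is at or
below the threshold (default 1e-4, the common FIMO default). P-values are
exact: per-column score distributions, discretized to 1/1000 bit, are
convolved by dynamic programming, giving the full null distribution of the
total score. Windows containing N are skipped. A pseudocount (default
0.001) keeps log-odds finite. Overlapping hits all count — the feature is
literally the number of binding sites in the region.

The region-by-feature matrix has one count column per motif plus
`cpg_fraction`, the fraction of the region covered by CpG islands (so a
931-motif library yields 932 features). The tests verify the scanner
against full enumeration of all 4^w words, and the expected false-positive
rate `2 (L - w + 1) p` on background sequence.

## Classification and importance

Discrimination uses a random forest (`randomForest`, as is standard for
this design): unpruned trees, majority vote, 500 trees, `m` features per
split. `tune_m()` scans a multiplier grid around one third of the feature
count by out-of-bag error (ties to the smaller `m`). Evaluation uses a
random 70/30 split; the report carries sensitivity, specificity and
F-measure at the F-optimal vote-fraction threshold, AUC by the trapezoidal
rule (equal, by construction, to the Mann-Whitney statistic of the votes),
and mean-decrease-accuracy importances. Choosing the F-optimal threshold on
the held-out votes is optimistic by construction; the report says so
explicitly. A 10-fold cross-validated SVM (`e1071`) replicates the result
as a robustness check.

## Enrichment statistics

Per-motif enrichment in boundaries versus a control class is a 2x2 Fisher
exact test on presence (count >= 1). We report the *sample* odds ratio
`ad/bc` — the enrichment call uses the thresholds OR > 2 (enriched) and
OR < 0.5 (depleted), which read naturally as sample odds ratios — with a
Haldane 0.5 correction (flagged) only when a cell is zero. P-values are
two-sided; no multiple-testing correction gates the calls (the OR
thresholds are the filter), but a BH-adjusted column is emitted for
transparency. The chromatin-modification-enzyme (CME) test asks whether
top-discriminating motifs are CMEs or interact with one more often than the
remaining motifs, swept over top-20/25/40/50 cutoffs. The positive
definition ("is a CME or interacts with at least one") resolves an
ambiguity in how the two-by-two table can be phrased; the monotone increase
of the odds ratio toward smaller cutoffs is the qualitative signature the
sweep is designed to show.

## Positional bias

For each motif, hits in the 6-kb boundary regions are binned into 100-bp
windows by their start offset, with right-side boundaries mirrored so that
window 0 is always the outside-most end and the block edge sits at 5 kb.
The extreme-window Z-score is `|extreme - mean| / sd` over the 60 windows,
with the population (divide-by-n) standard deviation and ties broken toward
the window nearest the block edge; flat profiles report z = 0 with a flag.
The z is invariant to rescaling the counts, so summed and per-region-mean
profiles give the same answer.

## ChIP signal

Tracks are fixed 20-bp bins per chromosome. Normalization is
`log((t + 0.5) / (i + 0.5))` (natural log; the pseudocount is a parameter —
set it to 0 to recover the pure log ratio). Region means weight partial
edge bins by overlap fraction and skip missing bins. The boundary-aligned
metaprofile averages the normalized signal over a +/-20 kb span around each
block edge, mirroring right-side boundaries so negative offsets always mean
"outside the block". Set comparisons use the two-sided Wilcoxon rank-sum
test (exact for small untied samples, normal approximation with tie
correction otherwise; completely tied comparisons report p = 1). CTCF
stratification splits boundaries by site co-occurrence and compares the
signal strata the same way. The 6-kb region definition and the 20-kb
metaprofile span are both parameters, since narrower (3-kb) windows are
also of interest at the edge.

## Chromatin structure

Hi-C input is a dense, symmetric, normalized per-chromosome contact matrix
at 40-kb bins. A bin belongs to a block only when fully contained, so
blocks shorter than ~80 kb contribute nothing — mirroring the exclusion of
sub-bin blocks in this kind of analysis. Intra-block interaction strength
is the sum over distinct within-block bin pairs (diagonal excluded; a flag
away from including it) divided by the bin count. The null is random
non-overlapping length-matched regions on the same chromosome; note these
may overlap real blocks, which makes the contrast conservative. TAD
proximity takes, for each TAD boundary, the minimum distance to any block
edge, against the same length-matched random-block null; both tests are
two-sided rank-sum.

## The synthetic generator

`sim_config()` defaults are the study conditions at desk scale:

* **Blocks.** ~50 non-overlapping blocks on a 3-Mb genome (two 1.5-Mb
  chromosomes), lognormal lengths with log-sd 1.609 so the mean/median
  ratio is ~3.65 — the heavy tail implied by a 144-kb mean versus a
  39.5-kb median in real colon-cancer blocks — scaled to a 10-kb median so
  ~50 blocks cover about half the genome, as the real blocks do. Placement
  is stick-breaking over the free space with a 12-kb minimum gap; a
  heavy-tail draw that cannot fit triggers a bounded redraw before erroring.
* **Motifs.** 30 random consensus-weighted PWMs (width 8-12), 30% of them
  boundary-enriched: planted instances top the uniform background rate
  (0.3 expected/6 kb) up to 3 expected per boundary region, with a
  positional peak (truncated normal, sd 400 b) just outside the block edge.
  Because the boundary figure is the *total* rate, setting it equal to the
  background removes the signal entirely — the exchangeable null used in
  the acceptance checks.
* **ChIP.** One promoter-like mark: a Gaussian peak (sd 500 b, height 5
  over a gamma-noise background of 1) centered 1 kb outside each edge, plus
  a flat input track.
* **Hi-C / TADs / CTCF.** Within-block bin pairs lifted additively
  (default 5) over a distance-decay background; TAD boundaries are block
  boundaries plus Gaussian jitter (5 kb; infinite jitter decouples them);
  CTCF sites are placed so total boundary occupancy is 21% against ~15%
  background leakage, echoing the 21%/14%/18% occupancies reported for real
  boundaries and controls.

What the generator does **not** emulate: realistic sequence composition
(background is i.i.d., optionally GC-skewed — chosen so scan p-values are
exactly calibrated), nucleosome-scale methylation, read-level noise,
correlated motif co-occurrence, or GC differences between region classes.
Passing tests therefore demonstrate that the machinery recovers planted
structure of the assumed form at realistic effect sizes — not that real
boundaries behave this way.

## Numerical choices and problem sizes

Score discretization 1/1000 bit; scan threshold 1e-4; Haldane 0.5 only on
zero cells; population sd in the Z-score; rank-sum switches from exact to
normal approximation following `stats::wilcox.test`; ties in importance
rankings break lexicographically; all randomness flows from one seed
through fixed substreams, so bundles and pipeline manifests are
byte-identical across re-runs.

Test and acceptance runs use 100 boundary regions vs 60 controls per class
for classification (about the most the 3-Mb genome supports), 20 fresh
null bundles for the null-AUC band — a fixed dataset's realized chance
structure biases its own AUC, so the band must be taken across data
realizations — and a single-chromosome 12-Mb, 50-block (~120 kb each)
configuration for the Hi-C/TAD power checks, since 40-kb bins need blocks
of at least two bins.

## Limitations

The F-optimal operating point is chosen on the test set (flagged in the
report); the interaction map for the CME test is synthetic unless the user
supplies a real one; Hi-C matrices are taken as already normalized; the
scanner supports motifs up to 50 columns in the batched feature path; and
promoter deduplication keeps the first window in sorted order, which is a
convention, not a biological claim.
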