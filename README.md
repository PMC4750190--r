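# hmboundary

Genomic and epigenomic characterization of **hypomethylated-block (HMB)
boundaries**.

Large solid tumors — colon cancer prominently — lose DNA methylation over
megabase-scale blocks that cover about half the genome, with surprisingly
sharp edges. If something local nucleates or arrests that loss, it should be
visible in the ~6 kb around the block edge: in transcription-factor (TF)
binding motifs, in promoter-like chromatin marks, in CTCF binding, and in
the pre-existing 3D chromatin architecture. `hmboundary` implements that
analysis end to end, for anyone with block coordinates, a genome, and the
usual epigenomic track files — and ships a synthetic-data generator with
planted structure so the entire pipeline is testable with no downloads.

## What it computes

* **Boundary regions**: 6-kb windows per block edge — 5 kb outside plus
  1 kb inside — with control classes (inside blocks, outside blocks,
  promoters) sampled non-overlapping and GC-matched.
* **Motif features**: a PWM scanner with *exact* null p-values (per-column
  score distributions convolved by dynamic programming; hits at p ≤ 1e-4 on
  both strands), yielding one count per motif plus the CpG-island overlap
  fraction per region.
* **Discrimination**: a random forest (unpruned, majority vote, out-of-bag
  tuning of the per-split feature sample m) evaluated on a held-out 30%
  split — sensitivity/specificity/F-measure at the F-optimal vote threshold,
  trapezoidal AUC, mean-decrease-accuracy importances — with a 10-fold SVM
  as a cross-check.
* **Enrichment**: two-sided Fisher exact tests per motif (sample odds
  ratio `ad/bc`; enriched above 2, depleted below 0.5) and a
  chromatin-modification-enzyme enrichment sweep over the top 20/25/40/50
  discriminating motifs and their interaction partners.
* **Positional bias**: per-motif 100-bp window profiles across the 6-kb
  region (right boundaries mirrored) and the extreme-window Z-score.
* **ChIP signal**: log-ratio normalization against input, boundary-aligned
  ±20-kb metaprofiles, rank-sum set comparisons, CTCF-stratified signal.
* **Chromatin structure**: intra-block Hi-C interaction strength (sum of
  within-block 40-kb bin-pair contacts / bin count) against length-matched
  random regions, and TAD-boundary-to-block-boundary proximity against the
  same null.

## Worked example

Simulate the default study-condition bundle (two 1.5-Mb chromosomes, 50
blocks with a heavy-tailed length distribution, 30 motifs of which 9 are
planted at boundaries, a promoter-like ChIP peak just outside each edge,
lifted intra-block Hi-C contacts, jittered TADs, CTCF enriched at
boundaries), then run the boundary-vs-inside leg:

```r
library(hmboundary)

b <- simulate_bundle(sim_config(seed = 42))
#> synthetic bundle: 2 chrom x 1.5e+06 b, 50 blocks, 30 motifs (9 planted)

boundaries <- derive_boundaries(b$blocks, boundary_spec(), b$chrom_sizes)
inside <- sample_controls(b$blocks, boundaries, "inside", n = 60,
                          seed = 101, chrom_sizes = b$chrom_sizes)
fm <- rbind_features(
  build_features(boundaries, b$motif_library, b$cpg_islands, b$genome),
  build_features(inside, b$motif_library, b$cpg_islands, b$genome))

report <- train_evaluate(fm, split_spec(seed = 7))
report
#> classifier report (random_forest): sens 1.000 spec 0.938 F 0.985 AUC 0.996 (n_test=48)

rank_importances(report, 10)
#>  [1] "M023" "M018" "M030" "cpg_fraction" "M008" "M009" "M001" "M005" "M021" "M004"
b$truth$planted_motifs
#> [1] "M001" "M004" "M005" "M008" "M009" "M018" "M021" "M023" "M030"
```

The forest separates boundary from inside regions almost perfectly
(AUC 0.996 on the held-out split) and all nine planted motifs surface in the
top ten importance ranks, alongside the CpG fraction (islands are planted at
a fraction of block edges). Enrichment confirms the calls — e.g. motif M030
is present in 56/100 boundaries but 3/60 inside controls (odds ratio 24.2,
p = 6.4e-12, call "enriched"). The epigenomic and structural legs recover
their planted signals the same way:

```r
norm <- normalize_track(b$chip_tracks$H3K4me3$treatment,
                        b$chip_tracks$H3K4me3$input)
mp <- metaprofile(norm, boundaries)
mp$offset[which.max(mp$mean)]
#> [1] -980          # ChIP peak ~1 kb outside the edge, as planted
site_frequency(boundaries, b$ctcf_sites)
#> [1] 0.28          # CTCF occupancy above the ~15% background
```

`run_all(run_config(sim = sim_config(seed = 1)))` strings every stage
together — regions → GC-matched controls → features → the three pairwise
classifications → enrichment, positional and CME analyses → metaprofiles and
CTCF stratification → Hi-C and TAD statistics — and returns a manifest that
is byte-identical across re-runs with the same seed.

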