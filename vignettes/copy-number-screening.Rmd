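---
title: "Ultra-low-pass cfDNA copy-number screening: models and design"
author: "plasmaCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultra-low-pass cfDNA copy-number screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Plasma cell-free DNA (cfDNA) from patients with advanced cancer carries a
tumor-derived fraction f that is often 5-50%. At those fractions,
genome-wide somatic copy-number alterations (CNAs) are detectable from
whole-genome sequencing at far lower coverage (0.005-1.3x) than mutation
calling requires, so a cheap low-pass WGS run can triage samples: estimate
the tumor fraction, call clinically relevant focal amplifications and deep
deletions, and decide which samples merit deeper targeted sequencing.
plasmaCNA implements that screening workflow end to end, together with the
simulation machinery needed to validate it.

# The pipeline

1. **Binned counting** (`makeBins`, `countReads`). The genome is tiled with
   fixed-width bins (default 500 kb) and each retained alignment is
   assigned to one bin by its leftmost aligned base. Retention filters:
   mapped, primary, non-supplementary, non-duplicate, MAPQ >= 37. chrY and
   alt contigs are excluded by default; chrX is kept because the androgen
   receptor (AR) locus -- a key mCRPC biomarker -- lies on it.
2. **Adaptive bin width** (`chooseBinWidth`). The smallest width on the
   ladder 100 kb-5 Mb whose expected reads per bin reaches 30 is used;
   30 reads bounds the per-bin Poisson coefficient of variation near 18%.
   At 0.005x on a human genome (~82,000 reads) this selects 2.5 Mb bins.
3. **GC correction** (`correctGC`). Counts are divided by a
   deterministic trend -- the median count within 20 equal-width GC strata,
   linearly interpolated -- and rescaled to preserve the median. This is a
   dependency-light, testable stand-in for a loess fit; it is idempotent up
   to stratum-median estimation noise.
4. **Log2 copy ratios** (`toLog2Ratio`). Per-bin rates are divided by a
   panel-of-normals reference (per-bin median rate across panel samples; a
   uniform reference when no panel is given), with a pseudocount of 0.5
   reads on both sides of the ratio to keep ultra-low-coverage bins finite.
   Profiles are median-centered to 0 over usable autosomal bins. The panel
   must be sex-matched: a male panel keeps male chrX near 0 so that AR
   amplification stands out, which is why the built-in simulations use
   male panels throughout.
5. **Segmentation** (`cbsSegment`). Circular binary segmentation: each
   chromosome is treated as a circle, the candidate split maximizes the
   pooled-SD-normalized mean-difference statistic over all valid arcs, and
   a split is accepted when its within-span permutation p-value is <= 0.01
   (1000 shuffles by default). Accepted sub-spans are recursed; adjacent
   segments closer than 0.05 log2 units are re-merged. The permutation
   stream is defined as part of the algorithm -- every tested span derives
   its seed from (seed, chromosome index, span offset, span length) -- so a
   given seed always yields the same segmentation, and an independent
   implementation consuming the same stream must reach identical
   decisions. Arcs are enumerated canonically (each circular partition has
   exactly one representative), and ties break to the lexicographically
   first split.
6. **Tumor fraction** (`computeLSS`, `fitTumorFraction`,
   `estimateTumorContent`). Two estimators:
   * *LSS*, the length-weighted RMS deviation of segment means from 0.
     It is zero exactly on flat profiles, scales linearly with segment
     means, and classifies samples as high vs low tumor content at the
     0.1 threshold, which corresponds to an estimated tumor content of
     8.75%.
   * *Grid fit*: each segment mean is matched to the nearest mixture level
     log2((f n + c(1-f))/c) over integer tumor copies n in [0, 40]
     (c = 2 on autosomes, 1 on male chrX), and the reported f is the
     smallest grid value whose length-weighted residual is within 5% of
     the minimum.
7. **Event calling** (`callFocal`, `armLevelEvents`,
   `classifyDeepDeletion`, `detect21qDeletion`, `computeFGA`). Focal CNAs
   are segments 1.5-20 Mb long with |log2| >= 0.2 (bounds inclusive); the
   loss direction uses the symmetric threshold so that focal deep
   deletions are expressible. A loss is *deep* (2-copy) when the nearest
   integer state at the fitted fraction is n = 0. Arms are gained/lost
   when >= 50% of the arm lies in segments beyond |log2| >= 0.1. The
   21q22.2 call is a copy-number proxy for the deletion-type TMPRSS2:ERG
   rearrangement: a loss segment reciprocally overlapping the shipped
   ERG--TMPRSS2 span by >= 50%. FGA is the length fraction of segments
   with |log2| >= 0.2, flagged elevated strictly above 0.15.

```{r example}
library(plasmaCNA)
gb    <- makeBins(grch37Sizes(scale = 20), 2.5e5)
panel <- simulateNormalPanel(gb, coverage = 0.1, seed = 42)
bc    <- simulateCounts(mcrpcTruth(), fraction = 0.4, coverage = 0.1,
                        x = gb, seed = 7)
res   <- runPipeline(bc, panel = panel, genes = geneAnnotation(20),
                     arms = armAnnotation(20), sex = "male", seed = 7)
res$tc
```

# Identifiability of the grid fit

The mixture model is scale-ambiguous: any fit (f, {n_s}) is reproduced
exactly by (f/2, {2 n_s - 2}) whenever all 2 n_s - 2 >= 0. Preferring the
smallest near-optimal f is the conventional fix, with one consequence worth
knowing: a profile containing only states {1, 2, 3, 4} at fraction f is
reported at f/2 with states {0, 2, 4, 6}. The ambiguity collapses as soon
as a genuine deep deletion (n = 0) is present -- 2*0 - 2 < 0 has no valid
pre-image -- which real mCRPC-like profiles (PTEN/RB1 deep deletions)
provide. The test suite pins both behaviors.

A second identifiability hazard appears only under noise: level spacing is
proportional to f, so at small candidate fractions the integer grid is fine
enough to fit pure noise, and an unpenalized fit drifts toward the f/2
solution. The fit therefore clusters on the *altered* segments only:
segments with |mean| below 0.1 (the \code{neutralGate}, matching the
arm-level threshold) are held copy-neutral and excluded from the residual.
This is the clustering reading of segment-based tumor-content estimation --
the copy-number clusters carry the fraction information, the neutral mass
carries none -- and without it the parameter-recovery checks at 0.1x
coverage fail.

# LSS calibration

The mapping from LSS to tumor content depends on how much of the genome a
tumor alters, so it is built by simulation (`calibrateLSS`): the dilution
ladder 0/1/5/10/25/50% is simulated from a truth profile, the median LSS
per fraction becomes a knot, isotonic regression repairs any Monte-Carlo
non-monotonicity, and the tumor-content coordinate is rescaled so the curve
passes the decision anchor (LSS 0.1, tumor content 0.0875). The fallback
`defaultCalibration()` interpolates the anchor proportionally. Samples
whose LSS is dominated by one segment (> 80% of the squared mass with < 2%
of the genome non-neutral, e.g. a lone 19 Mb clonal-hematopoiesis
deletion) are flagged by `flagSingleEvent` and can be reclassified low on
request.

# The synthetic-data engine

`simulateCounts` draws per-bin Poisson counts with expectation
proportional to (f n + (1-f) c) per bin (length-weighted over the truth
intervals), an optional linear GC-bias multiplier, and totals normalized
to coverage x genome length / read length (180 bp by default, matching
cfDNA-like fragmentation). `inSilicoMix` and `downsampleCounts` implement
the in-silico dilution and downsampling experiments by per-bin binomial
thinning. Built-in truth profiles: an mCRPC archetype (8p loss, 8q gain,
AR amplification n = 12, focal 2-copy PTEN and RB1 deletions, 21q22.2
deletion), a VCaP-like and a UMUC-5-like (EGFR n = 20) cell-line profile.

What the generator emulates: Poisson counting noise at realistic
reads-per-bin, tumor/normal mixing, GC bias, male chrX dosage, the
dilution fractions (50/25/10/5/1/0%) and coverages (0.005-1.3x) of the
validation experiments. What it does not emulate: fragment-size biology,
mappability artifacts and blacklist regions, replication-timing waves,
library-preparation overdispersion beyond the optional gamma term, and
subclonal heterogeneity. Passing tests therefore demonstrate correctness
of the estimators under the stated noise model, not robustness to every
artifact of real sequencing.

## Problem sizes

Simulated studies run on two grids, chosen once:

* a **miniature genome** -- GRCh37 autosome + X proportions at 1/20 length
  (155 Mb) -- with 250 kb bins (~620 bins) for the 0.1-1x experiments.
  On a miniature genome, bins must hold enough neighbors per chromosome
  for the permutation test to resolve: with only ~14 bins on a mid-size
  chromosome the permutation null of a 4-bin arc has a hard p-value floor
  above 0.01 (the chance that those 4 values land contiguously by
  shuffle), so no 4-bin event could ever be accepted. 250 kb bins keep
  every planted event >= 8 bins, far from that floor. Focal truth events
  are 2 Mb wide in miniature coordinates so they satisfy the 1.5-20 Mb
  focal rule directly.
* the **full-size GRCh37 coordinates** with adaptive 2.5 Mb bins for the
  0.005x coverage-titration analog: 0.005x of a 155 Mb miniature would be
  ~4,300 reads -- information-starved in a way the real experiment is not
  -- while bin-level simulation on the real coordinates costs only as much
  as its ~1,240 bins.

Detection and recovery checks use 20 seeds per condition; segmentation in
the heavy simulation loops uses 500 permutations (the acceptance threshold
at alpha = 0.01 is then 1/501 ~ 0.002, comfortably below alpha), while the
oracle-equivalence and sensitivity checks use the default 1000.

# Numerical choices

* Pseudocount 0.5 reads on both ratio sides; log2 levels clamped at -8
  (the n = 0, f = 1 level is -Inf in exact arithmetic).
* Tumor-fraction grid: step 0.005 over [0, 0.95]; n up to 40 (enough for
  high-level focal amplifications, > 4 copies).
* Segmentation: minimum 2 bins per segment; merge tolerance 0.05 log2;
  early-stopped permutation testing (a span stops as soon as the
  exceedance budget proves p > alpha, which cannot change the decision).
* Variant fractions round half-away-from-zero to one decimal so printed
  percentages are reproduced independent of banker's rounding.
* `correctGC` requires >= 100 usable GC-annotated bins and degrades to the
  identity (with a warning) when all bins share one GC value.

# Coordinate conventions

Internally everything is a `GRanges` (1-based, closed, the Bioconductor
convention). File formats keep their own dialects: count-table TSV and BED
are 0-based half-open; SEG files are 1-based inclusive.

# Known limitations

* The LSS-tumor content mapping is calibrated against the built-in truth
  archetypes; tumors with very different CNA burdens map differently
  (which is why the high/low decision uses the LSS scale itself).
* Arm-level thresholds (50% of arm length, |log2| >= 0.1) are pragmatic
  conventions; no attempt is made to model arm-level mosaicism.
* The 21q22.2 call is a deletion proxy, not fusion evidence.
* Mappability/blacklist annotation is accepted but no default track ships
  with the package; only GC correction applies out of the box.
* At permutation granularity alpha = 0.01 cannot be reached on spans
  shorter than ~10 bins; chromosomes with fewer usable bins stay single
  segments (with a warning below the 2-bin floor).
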