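---
title: "Mapping mitotic LOH events in sectored colonies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitotic LOH events in sectored colonies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectorloh)
library(dplyr)
```

## The biological system and the measurement

A diploid yeast hybrid of two sequence-diverged haploids (here called W, for
the W303-1A-derived haplotype, and Y, for the YJM789-derived one) is
heterozygous at tens of thousands of single-nucleotide polymorphisms. A
mitotic crossover between a heterozygous colour marker (*SUP4-o*) and the
centromere can segregate the two reciprocal products into the two daughter
cells, producing a red/white *sectored colony*. Culturing each side of the
sector and hybridizing its DNA against an all-heterozygous control on an
allele-specific SNP array yields, per marker, a W-channel and a Y-channel
hybridization ratio: both near 1 at heterozygous markers, roughly
(2-copy, 0-copy) at markers homozygous for one haplotype, and intermediate
patterns for hemizygous deletions and aneuploidy.

The paired daughter cells are the key to mechanism. Comparing where each
sector switches from heterozygous to homozygous markers distinguishes:

* **Crossover without detectable conversion (`CO_SIMPLE`)** — both sectors
  switch at the same position, to opposite haplotypes.
* **Crossover with a 3:1 conversion tract (`CO_3TO1`)** — one sector's
  homozygosity extends proximally beyond the shared exchange point; across
  the four chromatids of the two daughters the tract carries three copies of
  the donor allele. Diagnostic of the repair of a **single chromatid break
  (SCB)**.
* **Crossover with a 4:0 tract (`CO_4TO0`)** or a **3:1/4:0 hybrid tract
  (`CO_HYBRID`)** — part or all of the tract is homozygous for the donor in
  *both* sectors, diagnostic of a **double sister-chromatid break (DSCB)**.
* **Interstitial conversion (`NCO_INTERSTITIAL`)** — a homozygous island in
  one sector only, unassociated with a crossover.
* **Break-induced replication (`BIR_TERMINAL`)** — terminal homozygosity in
  exactly one sector. A crossover occurring in the *second* division after
  plating produces the same pattern, so every such call carries the caveat
  flag `possible_second_division_crossover`.
* **Deletions** (hemizygous segments) and **aneuploidy** (whole-chromosome
  copy-number change) are tallied separately from the recombination
  categories.

Strains too UV-sensitive to form sectored colonies are analysed as *single
colonies*; there a terminal LOH event cannot be split into crossover versus
BIR, and the package pools them into a `CO_BIR` category, mirroring the way
such tables are published.

## The synthetic-data generator

No raw array data accompany the published tables, so the package carries a
first-class generator that plants ground-truth events and emits noisy ratio
tables; every downstream stage is verified against that truth.

**Genome and markers.** The default genome is the 16-chromosome yeast
nuclear genome (~12 Mb) with standard chromosome lengths and centromere
positions. `build_marker_map()` allocates a default of 13,000 heterozygous
markers — the scale of the real whole-genome SNP arrays — to chromosomes
proportionally to length (largest-remainder rounding, so per-chromosome
counts are identical across seeds) and draws positions uniformly without
replacement. The resulting mean inter-marker spacing is ~0.9 kb, which is
the pipeline's intrinsic localisation scale.

**Noise model.** Each channel ratio is drawn as
`mean(copy count) * exp(N(0, sigma))`, with means 1.8 / 1.0 / 0.2 at 2 / 1 /
0 allele copies and `sigma = 0.15` by default. The real arrays report only
that a ratio of 1 indicates heterozygosity; a multiplicative lognormal is
the simplest model producing the observed kind of scatter around
copy-proportional means, and its within-array variance is a plausible but
uncalibrated choice (no published value exists to calibrate against). At
these defaults the miscall structure is benign by construction: a
heterozygous marker is essentially never called homozygous (that would
require a ~4.6-sigma and a ~8-sigma deviation simultaneously); noise instead
produces uncalled markers (~15% of heterozygous, ~5% of homozygous markers)
plus rare hemizygous miscalls, and the smoothing and segmentation stages are
designed around exactly that structure.

**Event planting.** `plant_events()` realizes each class's sector pattern
exactly (the reciprocity of crossovers is a tested invariant). The
rate-based generator `simulate_colony()` draws per-colony event counts from
Poisson distributions whose default means are the study condition the
package emulates — a UV-irradiated NER-deficient (*rad14*) diploid at
1 J/m^2^, with ~3.9 interstitial conversions, ~1.5 crossovers and ~1.3 BIR
events per sectored colony, occasional deletions (0.33) and rare aneuploidy
(0.05). Among conversion-bearing crossovers, 76% are 3:1 (SCB) and 24% are
4:0 or hybrid (DSCB), matching the published break-type proportions; 20% of
crossovers carry no detectable conversion. Tract lengths are lognormal with
medians 4.3 kb (interstitial) and 8.7 kb (crossover-associated), the
published medians for the emulated strain, with `sdlog = 0.6` chosen to give
a realistic spread (2–20 kb). One event is placed per chromosome arm, clear
of centromeres and telomeres, so patterns never collide; a multi-event mode
arises naturally when several arms are drawn.

The generator guarantees each planted conversion tract covers at least 3
markers (each half of a hybrid tract separately). This is deliberate: the
segmentation stage documents a sensitivity floor of `min_markers = 3`
markers per tract, so the generator plants events that are above the floor
at zero noise — making "100% recovery at sigma = 0" a meaningful statement
about the classifier rather than about marker density. What passing these
tests does *not* show: robustness to array artefacts with spatial or
probe-sequence structure (dye bias, print-tip effects), to marker maps with
strongly non-uniform density, or to event classes outside the taxonomy
(translocations, complex clustered events); the generator does not emulate
those.

## Genotyping: calling, smoothing, segmentation

`call_marker_states()` thresholds each marker independently: heterozygous if
both channels lie in [0.7, 1.3]; homozygous for a haplotype if that channel
is ≥ 1.4 and the other ≤ 0.5; hemizygous (`DEL_*`) if one channel is ≤ 0.5
with the other in the heterozygous band; otherwise uncalled. The published
analysis states only that calls were made from relative median hybridization
ratios, so a transparent banded rule with config-exposed thresholds was
preferred over a hidden-state model; the bands are symmetric around the
noiseless means and leave a deliberate uncalled buffer (1.3–1.4) between
the heterozygous and homozygous regimes.

`smooth_calls()` makes one pass: an isolated called marker contradicted by
at least `flank = 3` identically-called markers on both sides (skipping
uncalled markers) is repaired, and an uncalled marker whose nearest called
neighbours agree — each sitting in a run of at least `flank` markers —
inherits their state. The run-length requirement on fills matters: without
it, two isolated miscalls bracketing a dropout can be welded into a
three-marker phantom segment, which at the chromosome end is
indistinguishable from a real terminal event. The repair decisions are all
taken from the input configuration and applied together, which keeps the
operation deterministic and order-free.

`segment_genome()` runs run-length segmentation per chromosome over the
called markers only — uncalled markers never open, close or split a segment,
so sparse dropouts cannot shatter a tract. Non-heterozygous runs covering
fewer than `min_markers = 3` markers are absorbed, shortest first, into the
surrounding state (into the agreeing neighbour state when the two neighbours
match — a micro-run inside a homozygous sea disappears into that sea — and
into the heterozygous state otherwise), and each absorption is logged in the
`absorbed` attribute. The consequence, documented here as the package's
sensitivity limit: conversion tracts covering fewer than three markers
(~2 kb at default density) are invisible, and under noise a 3–4-marker
tract can drop below the floor when one of its markers is uncalled — this
is the dominant residual error mode in the noisy recovery experiments.

Breakpoints are never observed directly: a transition is localized only to
the interval between the last marker of one segment and the first marker of
the next (`find_transitions()`), and its point estimate is the floor of the
interval midpoint. All coordinates are 1-based inclusive.

## Classification of paired sectors

`match_sectors()` intersects the two sectors' segmentations on the shared
marker map into joint blocks over which neither sector changes state;
classification then reads the block pattern per chromosome, in a fixed
order: aneuploidy first (it invalidates pattern logic), then hemizygous
blocks as deletions, then each chromosome end, then the interior.

*Aneuploidy* is detected before pattern analysis from the summed W+Y ratio,
which is copy-number informative but insensitive to which haplotype is
retained: disomic chromosomes (heterozygous or homozygous) sum to 2.0 on
average, monosomy to 1.2, trisomy to 2.8 at the default means. A chromosome
is flagged when its mean total is nearer the 1- or 3-copy expectation than
the 2-copy one *and* the departure exceeds `z_threshold = 6` standard
errors; the two-part rule keeps a long LOH segment (which leaves the sum at
2.0) from ever looking like a copy change while controlling false calls on
~800-marker chromosomes. This is a simplification — the published analysis
does not describe its copy-number method — and is the package's own design.

*Terminal analysis.* If the outermost block has both sectors homozygous for
opposite haplotypes, the event is a crossover, and the classifier walks
inward collecting conversion-like blocks (donor-homozygous in one sector, or
in both). No collected blocks: `CO_SIMPLE`. All one-sector: `CO_3TO1`. All
shared: `CO_4TO0`. Mixed: `CO_HYBRID`. The published taxonomy's "identical
transition" is operationalized as overlapping transition-uncertainty
intervals: with a single intermediate marker the two sectors' intervals
share an endpoint, so a one-marker candidate tract collapses into
`CO_SIMPLE` (`min_conv_markers = 2`). Whether a hybrid tract's shared part
must sit adjacent to the exchange point is not specified in the published
material; adjacency is assumed here, and the generator plants hybrids that
way. If the outermost block is homozygous in exactly one sector the event is
`BIR_TERMINAL`, always flagged with the second-division-crossover caveat
rather than suppressed. Both chromosome ends are analysed symmetrically.

*Interior analysis.* Each maximal run of non-heterozygous joint blocks not
consumed by a terminal event is one interstitial conversion, with its 3:1 /
4:0 / hybrid pattern read the same way; `assign_break_type()` then maps
3:1 to SCB, 4:0 and hybrid to DSCB, and leaves simple crossovers
UNCLASSIFIED, as the published break-type accounting does.

*Tract lengths and localisation intervals.* For every conversion-bearing
event the package records the converted-marker span (`tract_start`,
`tract_end`), the flanking localisation interval between the nearest
heterozygous markers (`region_start`, `region_end`), and the tract length in
kb as the distance between the midpoints of the two flanking transition
intervals — the convention under which a tract of converted markers at
100–105 kb with heterozygous flanks at 99 and 106 kb measures 6.0 kb.
Chromosome-end tracts with a missing flank are flagged `chrom_end` and
measured to the chromosome end.

*The split rule.* Widely separated LOH blocks on one chromosome are distinct
events; blocks separated by a heterozygous gap no larger than the median
conversion tract length plus two median absolute deviations are merged into
one event spanning both (`split_distant_events()`). Two conventions for the
MAD exist — raw, and scaled by the 1.4826 normal-consistency factor that
R's `mad()` applies by default; the published rule's wording is compatible
with either, so both are provided and raw is the default
(`mad_constant = 1`). The reference population for the median/MAD defaults
to the dataset being classified, with fixed values accepted; gaps are
measured between the original block coordinates, which makes the event
count provably non-increasing in the threshold.

## Statistics

* `sector_frequency()` — sectoring frequency with an exact Clopper-Pearson
  95% interval. The published tables' CI method is unstated and their
  printed intervals are not exactly reproducible by any single standard
  method (e.g. 23/4853 prints (3.1–7.1)×10⁻³ where Clopper-Pearson gives
  (3.0–7.1)×10⁻³), so point frequencies — not CIs — are what the package's
  reproduction report asserts.
* `crossover_rate()` — twice the sectoring frequency, because only half of
  crossovers segregate the reciprocal products into different daughters.
* `fold_change()` with `format_fold()` — folds ≥ 10 display as integers,
  smaller folds at two decimals, matching the published tables.
* `median_with_ci()` — percentile bootstrap (default 10,000 replicates,
  seeded); the published "95% CL" method for medians is unstated and the
  bootstrap's coverage is verified by simulation in the test suite.
* `mann_whitney()` — exact two-sided p by dynamic-programming enumeration of
  the U distribution when the smaller sample is ≤ 8 with no ties, otherwise
  a normal approximation with tie and continuity corrections. The exact path
  is deliberately independent of base R's `dwilcox`, which together with
  full-permutation enumeration serves as the oracle in tests.
* `fisher_exact()` — two-sided p as the sum of hypergeometric probabilities
  of tables no more probable than the observed one (with a 1e-7 relative
  tolerance against ties in floating point, the same guard `fisher.test`
  uses); verified exhaustively against a factorial-based enumeration oracle
  for all tables with total ≤ 30.
* `chi_square_gof()` — Σ(obs−exp)²/exp against chi-square with k−1 degrees
  of freedom.

The `report_*()` functions recompute every derived column of the packaged
count fixtures (sectoring frequencies and folds, SCB/DSCB percentages,
per-colony averages and between-strain ratios) from raw counts. Two fixture
notes: one published break-type row's printed totals exceed its
selected+unselected sums, so the fixture re-enters the printed totals
explicitly; and the published single-colony fold column mixes raw-count and
rounded-average arithmetic — the package computes from raw counts.

## Enrichment at breakpoints

The lesion that initiates an event should lie near its breakpoints: for
conversion-bearing events between the heterozygous sites flanking the tract,
for simple crossovers within the transition interval
(`derive_breakpoint_regions()`; both region modes are provided because the
published material is ambiguous about whether crossover intervals were
included — `"conversion"` is the default). Regions are clipped to an array
coverage mask (`coverage_mask()` excludes 10 kb at each telomere, mirroring
the regions real arrays cannot interrogate). For each element class the
observed count of (merged) elements overlapping any region by ≥ 1 bp is
compared with the length-proportional expectation
`n_elements_in_mask × region_bp / mask_bp` by a two-cell (inside/outside)
chi-square goodness-of-fit test, followed by step-up FDR correction
(`multiple_test_correction()`, the Hochberg–Benjamini step-up procedure)
at a 0.05 significance level on adjusted values. Classes with expected
count below 1 are reported untested rather than tested badly. A
permutation alternative (`permutation_expected()`, seeded region shuffling
within the mask) cross-checks the closed form. BED input is converted from
its 0-based half-open convention on load.

The interval primitives behind this module (merge, mask intersection,
overlap counting) are vectorised base-R implementations chosen for
throughput — the type-I calibration experiment runs a thousand simulated
datasets — and the test suite cross-checks them against IRanges
`reduce`/`intersect` on random interval sets.

## Verification strategy and problem sizes

The suite verifies, at sizes chosen to keep the default run in minutes:
exact printed-table reproduction (instantaneous); the Fisher worked example
and the exhaustive ≤ 30-total Fisher check; a 50-colony zero-noise round
trip (every class, 100% class and boundary recovery); a 200-colony run at
default noise (≥ 95% class recovery; measured tract-length median within
one inter-marker spacing of the planted median); exhaustive small-case
split-rule monotonicity; a 1,000-dataset uniform-placement enrichment null
(significance rate well under 0.05) with a planted ~10-fold enrichment
detected as over-represented; 1,000-replicate type-I calibration of the
rank-sum test; and 500-replication coverage of the median bootstrap. The
noisy recovery experiments' residual errors are concentrated exactly where
the design predicts: conversion tracts of 3–4 markers falling below the
segmentation floor when a marker drops out.

## Known limitations

* Tracts covering fewer than `min_markers` markers are undetectable by
  design; lowering the floor trades against noise-induced micro-segments.
* BIR calls are structurally confounded with second-division crossovers in
  genetically unstable strains; the package flags rather than resolves this.
* The aneuploidy test assumes the copy-level means of the noise model; real
  arrays with compressed dynamic range would need recalibrated expectations.
* Deletions are modelled and called as clean hemizygous segments; the
  copy-signal handling of the original arrays is not described and may
  differ.
* The enrichment expectation treats elements as exchangeable points placed
  independently; clustered element classes violate this and are better
  served by the permutation cross-check.
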