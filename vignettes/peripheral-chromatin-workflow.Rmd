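---
title: "Methods: the peripheral-chromatin analysis workflow"
author: "perichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the peripheral-chromatin analysis workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perichrom)
```

# The problem

Nucleoporins are not confined to nuclear pore complexes (NPCs): proteins
such as Elys bind chromatin both at the nuclear periphery, as part of
NPCs, and in the nucleoplasm. Peripheral, NPC-linked binding sites sit
inside lamina-associated domains (LADs) and appear as local *dips* in the
lamina DamID profile; they are A/T-rich, depleted of active histone
marks, and their loss changes both the radial position of peripheral
chromatin and the fine-scale folding (compaction, insulation,
compartmentalization) seen in Hi-C maps.

This package implements the full computational chain needed to
characterize such sites: DamID domain calling, site classification with
permutation enrichment, anchor-averaged signal and A/T profiles, Hi-C
compaction statistics, nuclear-geometry statistics, and expression
summaries. Every stage also has a seeded synthetic generator that plants
the structure the stage is meant to find, so the whole chain is testable
end-to-end at desk scale without any external download.

# DamID normalization and domain calling

Binned counts (default 300-bp bins) from a Dam-fusion sample and a
Dam-only control are processed as: replicate counts summed per bin, a
pseudocount added to the raw counts of both samples, each sample scaled
to reads per million of its own total, and the per-bin
`log2(fusion/Dam)` taken (`normalize_damid()`). The result is invariant
to uniform rescaling of either sample. Bins with zero adjusted Dam
counts are masked. A Pearson correlation between replicates below 0.8
triggers a warning rather than an error: merging is the analyst's call.

*Pseudocount.* The default of 1 raw count keeps sparse bins in the track
while leaving well-covered bins essentially unchanged; setting it to 0
reproduces plain ratios and masks zero-Dam bins.

Domain calling (`fit_hmm()`) uses a Gaussian-emission hidden Markov
model on the log-ratio, fit by Baum-Welch and decoded by Viterbi. Two
states give LAD-type domains; three states give site-type calls for
sharper, rarer enrichment, with the highest-mean state taken as "bound"
by default (`states_to_domains()` exposes the choice). Numerical
choices:

* **Initialization** is deterministic: emission means start at empirical
  quantiles of the unmasked values (25th/75th for 2 states,
  10th/50th/90th for 3), variances at the overall variance, transitions
  at 0.95 self-persistence. Two runs on the same input give identical
  segmentations; the `seed` argument exists only so pipelines can thread
  one seed everywhere.
* **Masked bins split the chain** into independent sequences sharing one
  parameter set; decoded states never bridge a gap.
* **A variance floor** (1e-4 of the overall variance) prevents collapse
  on near-constant tracks; flooring is flagged in the result.
* **Label canonicalization**: states are reported in ascending order of
  emission mean, so "highest state" is well defined regardless of how EM
  happened to label them.

Runs of bound-state bins become domains, and `fill_domain_gaps()` merges
domains separated by *strictly less than* 900 bp (a 900-bp gap stays
open). The strictness matters for reproducibility and is tested
exactly.

# Site classification and permutation enrichment

`classify_sites()` labels each called site by which reference sets it
shares at least `min_overlap` (default 1) bases with: NPC-only,
nucleoplasm-only, both ("ambivalent"), or neither ("unassigned", which
downstream stages drop). `classify_genes_by_sites()` applies the same
idea to genes: overlap with only one class, a mixture, or none.

`permutation_overlap_test()` asks whether the observed number of query
sites touching a reference could arise by chance: query intervals are
repositioned uniformly (lengths preserved exactly, chromosome preserved
by default, self-overlap allowed, no blacklist) and the overlap count
recomputed, by default 10,000 times. The p-value uses the add-one
estimator `(#{null >= observed} + 1)/(n_perm + 1)`, which can never be
zero and is conservative relative to the plain ratio; when no
permutation reaches the observed count the printed report says
`P < 1/n_perm`. Validity (the type-I error stays at or below nominal
under null placement) is part of the test suite, as is agreement with an
exhaustive placement enumeration on a one-site toy genome.

`filter_interior_sites()` keeps sites whose midpoint lies at least 2 kb
inside a domain — the construction used to average signal around
NPC-class sites embedded in LADs.

# Signal, metagene and A/T profiles

`average_anchor_profile()` centers a window of ±flank bp on each anchor
midpoint, resamples it to output positions by area-weighted means of the
overlapping source bins (masked bins carry no weight), and averages over
anchors. Windows truncated by chromosome ends contribute only their
defined positions. `metagene_profile()` rescales each gene body to a
fixed number of positions, keeps flanks in bp, and reverses minus-strand
genes so profiles run 5′→3′ — strand matters only here, by design.

`at_content_profile()` reports percent A/T in consecutive 20-bp windows
(N bases excluded from numerator and denominator);
`at_rich_fraction()` counts sites having at least one sliding (1-bp
step) 20-bp window with ≥90% A/T within ±150 bp of their center. The
90% threshold is a package choice: it captures poly(dA:dT)-like tracts
while tolerating a single substitution per window, and it is exposed as
a parameter.

# Hi-C statistics

All matrices are dense per-chromosome arrays with a per-bin validity
mask — at the 2-Mb scale of the synthetic chromosomes this is simpler
and faster than sparse storage. The preparation chain is
`remove_short_range()` (pairs closer than 1 kb dropped; at 2-kb bins
this only clears the self-ligation-dominated diagonal),
`downsample_contacts()` (binomial thinning for cross-condition depth
matching), `iterative_correction()` (multiplicative balancing until all
unmasked row sums agree to 1e-6 relative; bins below the 5th percentile
of coverage are masked first), and `observed_over_expected()` (each cell
divided by the mean of its diagonal, so every separation has unit mean
O/E by construction).

*When not to balance.* Iterative correction removes technical,
per-bin coverage bias. On a synthetic map with no technical bias, a
planted dense block **is** extra coverage, and balancing absorbs a large
part of it. The parameter-recovery experiments in the test suite and
acceptance script therefore distance-normalize the raw synthetic maps
directly, while the end-to-end pipeline keeps the balancing step that
real data requires.

**TAD calling** (`call_tads()`) maximizes the summed quality
`q(k,l) = s(k,l)/(l-k+1)^γ − μ(l-k+1)` over non-overlapping domains by
dynamic programming, where `s(k,l)` sums the preprocessed cells over
interaction pairs `k ≤ i < j ≤ l` and `μ(d)` is the per-chromosome mean
scaled density of all windows of size `d`. Two definitional points:

* **The self-bin diagonal is excluded from domain density.** Including
  it lets runs of single-bin "domains" outscore genuine blocks, because
  every bin's self-cell is large after preprocessing; with pair-density
  only, a single bin has zero density and is never called.
* **Positivity has a numerical floor** (1e-9 relative): summed-area
  arithmetic leaves 1e-15-scale residues on perfectly uniform matrices,
  which must not become domains.

Ties are broken toward fewer domains. Preprocessing
(`armatus_preprocess()`) interpolates missing cells linearly along
diagonals, clips to the 1st–99th percentile range, replaces zeros by
half the smallest positive value (so the log is finite), and
ln-transforms. The DP is verified against exhaustive partition
enumeration for up to 12 bins at γ ∈ {0.4, 0.6, 1}.

**Compaction and insulation.** `tad_acf()` is the mean off-diagonal O/E
over bin pairs inside a TAD; `acf_log2fc()` compares conditions on TADs
with identical boundaries (`match_tads()`). `jaccard_group()` assigns
each TAD `Jacc = (X−Y)/(X+Y)` from its LAD fraction `X` and
active-chromatin fraction `Y` (defined as 0 when both are 0), with
groups A (`Jacc < −0.8`, active), C (`> 0.8`, inactive) and B between.
`ism_profile()` is the modified insulation score: the mean O/E over the
4×4 square spanning offsets 1–4 bins on each side of a central 2-kb bin,
i.e. only contacts between regions 2–8 kb away on both sides; the
central bin's own contacts and first-diagonal contacts are excluded.
Anchor-averaged ISm curves fill undefined positions by linear
interpolation before averaging.

**Compartments.** `compartment_pc1()` takes the first eigenvector of the
Pearson correlation matrix of O/E rows, with the sign oriented so that
positive values correlate with an activity track (the A-positive
convention). `saddle()` ranks bins by PC1, drops the extreme 1%,
digitizes the rest into 50 equal-count quantiles (50 is a package
default; the difference summary uses the 10 extreme quantiles per side,
so anything above 20 works), and averages O/E within quantile pairs.
`saddle_difference_summary()` reports the condition difference in the AA
(highest-PC1), BB (lowest-PC1) and AB blocks with Wilcoxon signed-rank
tests. `pileup_oe()` averages O/E windows centered on anchor bins.

# Nuclear geometry

`radius_from_volume()` inverts the sphere volume formula; normalized
distances above 1 (reconstruction noise) are kept but flagged.
Distance distributions are compared with a two-sided Mann-Whitney U
test. Diameter intensity profiles are normalized each by its own mean,
rescaled so the two envelope-marker peaks (argmax in each outer third;
an exactly flat channel fails detection and the profile is skipped) map
to 0 and 1, resampled, and averaged. The peripheral-zone test
summarizes each nucleus by its mean normalized intensity within 0–0.15R
of *both* envelope ends and compares conditions on those per-nucleus
summaries — per-nucleus first, to avoid pseudo-replicating pixels; the
unit of replication is the nucleus.

# What the generators emulate — and what they do not

Each generator plants exactly the structure its downstream stage is
designed to detect, at what we consider realistic desk-scale settings:

* **DamID** (`simulate_damid_counts()`): 2 chromosomes × 2 Mb at 300-bp
  bins; alternating ~100-kb LADs (planted log2 levels ±1.2, per-bin
  noise sd 0.4); 2-kb NPC-like sites at LAD centers whose lamina signal
  dips by 1.0 log2 — visible in averaged profiles yet merged over by the
  2-state caller, as in real maps; 2-kb nucleoplasm-like sites between
  LADs. Counts are multinomial at fixed depth (1e6), so RPM
  normalization is exact by construction, over a shared log-normal
  accessibility field (sd 0.35) that makes replicates highly correlated,
  as real binned DamID replicates are.
* **Hi-C** (`simulate_hic()`): one 2-Mb chromosome at 2-kb bins, contact
  intensity ∝ `s^−1`, Poisson counts at 2e6 total (deep enough for
  stable TAD boundaries), planted 100-kb TADs (×2 within-TAD), a 200-kb
  A/B checkerboard at ×1.25 same-compartment (contrast well below the
  TAD enrichment, as in fly maps), and anchor bins whose cross-anchor
  contacts at offsets 1–4 bins are boosted ×2 — the signature the ISm
  peak and pileup cross detect. The knockdown map abolishes the anchor
  boost and strengthens B–B contacts by ×1.15.
* **Geometry** (`simulate_geometry()`): 100 nuclei, radii ~N(2.5, 0.25)
  µm; attached loci at 0.10R (sd 0.05), detached shifted +0.10R;
  64-point diameter profiles with envelope peaks near both ends and a
  chromatin channel that is peripheral or displaced.
* **Expression** (`simulate_expression()`): four gene categories × 200
  genes, log-normal baselines, negative-binomial counts (size 10), +0.5
  log2 planted for the NPC-only class in the knockdown. Note that TPM is
  compositional: boosting one class shifts every other class down by a
  shared constant, so the meaningful recovered quantity is the planted
  *contrast* between classes, not any absolute median.
* **Sequence** (`simulate_sequence()`): ~50% A/T background with ≥95%
  A/T islands.

They deliberately do **not** emulate: GATC-fragment resolution or
restriction-site structure in DamID; mappability, copy-number or
coverage bias in Hi-C (hence the balancing caveat above); cell-type
mixtures; distance-dependent noise correlations; image segmentation
noise beyond Gaussian intensity jitter. Passing the recovery suite shows
the estimators are correct and well calibrated under the generating
model — it does not certify performance on artifacts these simplified
models lack.

# Problem sizes and determinism

All defaults are sized so the full test suite runs in minutes on one
CPU: 2-Mb chromosomes, 1000-bin contact matrices, 200-replicate
calibration loops, 10,000 permutations only where a single call is
involved. Every stochastic function takes an explicit seed, snapshots
the caller's RNG state, and restores it on exit, so library calls never
perturb a user's stream; all arguments are forced before the snapshot
(a lazily evaluated seed expression would otherwise be rewound along
with the stream). The top-level pipeline seed fans out to per-stage
sub-seeds.

# Design choices

* Intervals are `GRanges` (1-based, closed) and the layout is a
  `Seqinfo` — the containers this field's R analyses are built on. The
  BED-family 0-based half-open convention is confined to I/O via
  rtracklayer; `bp_interval()` accepts 0-based half-open coordinates for
  convenience in scripts and tests.
* The "bound" state of the 3-state site caller defaults to the top
  state only; with site enrichment well above both background states
  this is the conservative choice, and the argument is exposed.
* The shuffle preserves chromosomes and allows self-overlap — the
  closest simple reading of standard BED shuffling without a blacklist;
  both behaviours are parameters.
* The saddle is oriented A-positive (highest-PC1 quantiles are the AA
  corner); orientation is fixed by correlation with an activity track,
  never by sign luck.
* 1 TPM is added before fold changes, stabilizing the silent genes that
  dominate NPC-class gene sets.

# Known limitations

* The HMM is fit per track with shared parameters across chromosomes; no
  per-chromosome emission differences are modelled.
* TAD calling is single-γ; no multi-γ consensus.
* PC1 is per-chromosome and cis-only; no trans contacts anywhere.
* Exact TAD-boundary sharing between conditions is sensitive to depth
  and to systematic contact perturbations; at desk scale the shared
  fraction fluctuates broadly between seeds.
* The permutation test counts query sites with ≥1 bp overlap; counting
  reference sites or overlap events would differ on nested
  configurations (the choice is a documented argument default).
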