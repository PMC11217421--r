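# perichrom

Analysis toolkit for **nuclear-pore-anchored peripheral chromatin**: the
question of whether chromatin at the nuclear envelope is held there only
by the nuclear lamina, or also by chromatin-binding nucleoporins (such
as Elys) at nuclear pore complexes (NPCs). It is written for
genomicists working with DamID-seq, Hi-C, RNA-seq and imaging readouts
of nuclear organization, and it implements the complete computational
chain from binned counts to the statistics such a study reports —
exercised end-to-end on seeded synthetic data generators, so every
stage is testable on one CPU with no downloads.

## What it computes

**DamID domain calling.** Binned Dam-fusion and Dam-only counts are
merged across replicates, converted to reads per million, and the
per-bin log ratio taken:

    r_i = log2( (fusion_i + c) / N_f  ×  N_d / (dam_i + c) )

A Gaussian-emission hidden Markov model (2 states for LAD-type domains,
3 states for site-type calls; EM with deterministic quantile
initialization, Viterbi decoding) segments `r`, runs of the top state
become domains, and gaps `< 900 bp` are filled.

**Site classification and enrichment.** Sites are labelled
`Elys_NPC` / `Elys_nucl` / `Elys_NPC/nucl` / `unassigned` by overlap
with NPC and nucleoplasmic reference sets. Association between interval
sets is tested by shuffling intervals uniformly (lengths and
chromosomes preserved) and counting overlaps, with
`p = (#{null ≥ obs} + 1)/(n_perm + 1)`.

**Hi-C compaction statistics.** Iterative correction balances each
per-chromosome matrix; dividing by the per-separation mean gives the
observed/expected (O/E) map. On top of this:

* TADs from an Armatus-style dynamic program maximizing
  `Σ q(k,l)` with `q(k,l) = s(k,l)/(l−k+1)^γ − μ(l−k+1)`, `s` the
  pairwise contact density of `[k,l]`;
* ACF (average contact frequency) = mean off-diagonal O/E within a TAD,
  compared between conditions as log2FC on TADs with identical
  boundaries, grouped by `Jacc = (X−Y)/(X+Y)` of LAD (`X`) vs active
  chromatin (`Y`) content;
* the modified insulation score `ISᵐ(i)` = mean O/E over the 4×4 square
  of contacts between regions 2–8 kb away on both sides of bin `i`;
* compartment PC1 (leading eigenvector of the O/E row correlation,
  A-positive orientation), saddle plots over 50 PC1 quantiles with 1%
  trim, and AA/BB/AB difference summaries;
* anchor-centered O/E pileups.

**Nuclear geometry.** FISH distances normalized by the
sphere-equivalent radius `r = (3V/4π)^(1/3)`, Mann-Whitney U
comparisons, diameter intensity profiles aligned on the
envelope-marker peaks, and a per-nucleus peripheral-zone (0–0.15R)
test.

**Expression.** TPM conversion, gene categorization by site content,
and per-category log2 fold-change summaries with Wilcoxon signed-rank
tests.

Each input has a matching generator (`simulate_damid_counts()`,
`simulate_hic()`, `simulate_geometry()`, `simulate_expression()`,
`simulate_sequence()`) that plants known structure, which is how the
package tests itself.

## Worked example

```r
library(perichrom)
rep <- run_pipeline(pipeline_config(seed = 1, n_perm = 1000))
print(rep)
```

prints (elapsed time will vary):

```
== synthetic peripheral-chromatin workflow report ==
DamID: 22 LADs (55.1% of genome, F1 1.000), 44 sites (median 2.1 kb)
classes: Elys_NPC 50%, Elys_nucl 50%, Elys_NPC/nucl 0%, unassigned 0%
permutation: observed 22, p 0.000999
profiles: Lam dip depth 0.91, A/T-rich sites 100.0%
Hi-C: 20/20 TADs (ctrl/kd), 8 shared, median 100 kb
  median ACF log2FC (kd/ctrl): 0.025
  saddle diff means: AA 0.041, BB 0.057, AB -0.029
geometry: distance p 4.94e-27; peripheral-zone p 2.56e-34
expression medians: NPC_only 0.314, nucl_only -0.086, combination -0.103, none -0.114
elapsed: 13.7 s
```

Reading it: the 2-state caller recovered all 22 planted LADs (55% of
the synthetic genome, base-level F1 1.0); the 3-state caller found 44
sites of median 2.1 kb that classify 50/50 into NPC-like and
nucleoplasm-like; their overlap with the NPC reference is far beyond
chance (p ≈ 1/(n_perm+1)); the lamina signal dips by ~0.9 log2 at
NPC-class sites inside LADs; all planted A/T islands are detected; both
Hi-C maps yield the 20 planted 100-kb TADs, with the knockdown's
planted B–B contact gain visible as a positive BB saddle difference;
the detached condition sits further from the envelope (Mann-Whitney U)
and its peripheral chromatin intensity drops; and the planted +0.5
log2FC of NPC-class genes is recovered as a positive median against the
compositional background shift. `write_pipeline_report(rep, "out/")`
writes every table as TSV/BED.

The same chain is available as narrative scripts under `analysis/`
(`01_simulate.R` … `06_geometry.R`), which write their inputs and
result tables under `results/` via the package's file formats
(bedGraph, BED, COO contact lists, FASTA, TSV).

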