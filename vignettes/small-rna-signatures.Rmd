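---
title: "Small RNA biogenesis signatures: models, parameters and design notes"
author: "srnasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA biogenesis signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnasig)
```

## The problem

Small RNA pathways differ sharply across animals. miRNAs (~21–23 nt) are
diced from hairpin precursors; piRNAs (~25–32 nt) are made PIWI-dependently
by ping-pong amplification and phased Zucchini processing; siRNAs
(~20–23 nt) arise from processive Dicer cleavage of long dsRNA. Each
mechanism constrains the *geometry* of aligned reads, so genome alignments
alone can establish which pathways a species runs. `srnasig` implements
that inference: discover read-dense loci, measure the geometric signatures,
curate miRNA hairpins, classify piRNA loci, and scan for (or rule out)
siRNA production.

## Models and assumptions

**Coordinates.** Everything internal is 0-based half-open; SAM and GFF3 are
converted at the boundary. A read's 5′ end is `start` on the plus strand and
`end − 1` on the minus strand. Reads are assumed end-to-end matches of
15–50 nt (small RNA alignments; indels are out of scope).

**Overlap statistics.** For opposite-strand reads, the 5′–5′ overlap is
`o = fp(minus) − fp(plus) + 1`, valid when each read's 5′ end lies inside
its partner's span, i.e. `1 ≤ o ≤ min(L+, L−)`. All pairs are counted with
an index on (contig, 5′ position, length) — the result is *exactly* the
quadratic all-pairs count, which the test suite verifies against a dense
`outer()` oracle on every simulated locus class. Counts become z-scores
over the window `o = 1..30` using the population SD with the signal bin
included in the background, the convention of the overlap-pair tools this
analysis follows. Two counting modes exist: `per_alignment` (each aligned
pair once, weighted by collapsed multiplicity) and `per_species` (distinct
sequences only). Defaults use per-alignment counting; the siRNA duplex
count reports both.

Ping-pong is the z at `o = 10`. The Dicer statistic restricts to pairs
where both reads have length `L` and reads the z at `o = L − 2`; its
window runs only to `L`, since larger overlaps are geometrically
impossible for same-length pairs and padding the window with structural
zeros would deflate the background.

**Phasing.** Zucchini processing leaves same-strand reads head-to-tail.
Reads are collapsed to distinct 5′ positions (phasing is positional, not
abundance-weighted); each position is given its modal 3′ end; walking
positions in transcript order gives distances
`d = fp(next) − tp(previous)`, so immediately adjacent reads score
`d = 1`. The histogram over `d = 0..30` is z-scored like the overlap
histogram. With a genome available, a positional U profile is computed by
anchoring each read's 5′ end: a phased locus with 30-nt reads and gap 1
shows uridine enrichment at offsets 1 *and* 31 — the first base of the
next read. The generator enforces exactly this geometry (`gap = 1` means
the next read starts at the following base), which is the reading
consistent with the downstream U-profile peak; a convention in which
`gap = 1` left a one-base hole would put that peak at offset 32 instead.

**miRNA curation.** The mature:star duplex is reconstructed from arm
coordinates using a pairing register reflected around the precursor
boundaries (`x` pairs with `h1 + h2 − 1 − x`). Arm coordinates alone
determine only the *difference* of the two 3′ overhangs; anchoring the
register at the precursor — exact for the perfect inverted repeats the
generator writes, and a good approximation for miRDeep2-style candidates
whose precursor is trimmed to the fold — determines both. RNase III
processing requires (2,2). 5′ precision is the modal share of the mature
arm's 5′ pileup, collected with a ±2 nt slop around the annotated arm so
that off-by-one processed reads count in the denominator rather than
silently inflating precision. The triage rule is: both criteria passed and
star coverage ≥ 9 (strictly exceeding eight) → confident; both passed
without star support, or exactly one passed → candidate; neither →
false positive. ">90%" is strict: precision 0.90 exactly fails. The
short-loop scan finds maximal perfect inverted repeats with 3- or 4-nt
loops and no mismatches or bulges; G:U wobble pairs are excluded from
"perfect" by default and available behind a flag.

**piRNA classification.** A locus is a piRNA locus when longer than
1,000 nt with at least one exact 10-nt overlap pair among its 15–31 nt
reads. That literal rule is deliberately permissive — at high depth,
chance overlaps let unstructured loci through — so an optional
`min_pp_z` threshold is exposed; both behaviors are tested. Strand class
uses `r = max / max(min, 1)` with cutoffs 5 and 10 (boundaries belong to
`strand_bias`); genomic context is intronic only when fully inside one
intron, genic otherwise whenever a gene is touched; the size split is at
2.55 kb, strictly. The repeat-peak ("non-arthropod") taxonomy is
operationalized — the source analysis describes the pattern but gives no
formula — as a peak concentration index: the share of reads on the top-10
(strand, 5′ position) stacks. PCI ≥ 0.8 together with at most 0.05
distinct 5′ positions per nt calls a locus non-arthropod; loci under 50
reads are left arthropod-like and flagged. All raw metrics are reported so
calls are auditable and thresholds re-appliable.

**siRNA scan.** Candidate loci are 20–23-nt coverage islands with depth
strictly above 30, minus anything intersecting the miRNA exclusion set;
islands are not merged (the scan targets compact Dicer stacks). Strand
bins follow the published cutoffs — equal 1–1.1, mixed 1.2–1.9, bias ≥ 2 —
with the two gaps resolved to the adjacent category (1.1–1.2 → mixed,
1.9–2.0 → bias) and raw ratios always emitted. Phased runs are chains of
≥ 3 same-strand `L`-mers spaced exactly `L` apart (blunt head-to-tail on
one strand of a processively diced duplex); isolated duplexes are
reported as distributive. The absence signature is a one-sided
two-proportion test comparing the mixed/equal rate among Dicer-positive
loci against Dicer-non-positive loci; loci whose 21-nt Dicer z is
undefined (too few 21-mers on either strand) are excluded, because
counting them as non-positive confounds the test with strand composition
rather than signature.

## The synthetic-data generator

Every locus class is simulated with truth labels, error-free reads whose
sequences equal the (edited) genome slice, and full determinism from the
seed. Defaults encode the canonical biology: piRNA read lengths 26–32 nt,
miRNA arms 18–25 nt with a 2-nt-overhang duplex, 1U and ping-pong 10A
biases 0.7, phasing gaps 1–3, debris 15–20 nt. The ping-pong simulator
plants the 1U/10A bases in the genome itself, so the minus partner's 1U
follows automatically from the plus partner's 10A — the actual coupling
of the amplification loop. One consequence worth knowing when testing
parameter recovery: biased bases are drawn once per 5′ position, so reads
stacked on a position share the outcome and the binomial unit for a
recovery bound is the distinct position, not the read.

What the generator does *not* emulate: sequencing errors and quality
scores (the signatures are alignment-geometric), true multimapping
ambiguity (`n_hits` is metadata, not resampled placements), transposon
sequence content, expression dynamics across developmental stages, and
genome assembly artifacts. Passing tests therefore demonstrate
correctness of the statistics and classification logic under the stated
geometries, not robustness to noisy real libraries.

`simulate_cohort()` lays out any mixture of classes on one genome,
separated by more than the merge window, and writes matching gene models
so each locus has a known intergenic/genic/intronic context.

## Numerical choices and degenerate inputs

- z-scores use the population SD; a zero-variance window yields `NA`
  rather than an arbitrary value, and fewer than two reads (or two
  distinct 5′ positions, for phasing) yields not-available results.
- Locus merging compares gaps strictly (`gap < merge_window` merges), so
  a 500-nt gap at the default window keeps two loci; island depth uses
  `≥ min_cov` for discovery and `> min_cov` for the siRNA scan, each
  matching its stated rule.
- Reads spanning two loci (impossible after merging, possible for custom
  locus sets) go to the leftmost locus.
- Cluster labels from Ward/Euclidean clustering are renumbered by
  decreasing mean read length, so "cluster 1" is stable across runs.
- Strand ratios place one pseudocount on an empty minority strand;
  all-one-strand loci are unistrand by construction.
- Multimapped reads count once per alignment by default; `by_hits`
  weighting (1/`n_hits`) is available for coverage, since published locus
  counts do not state which convention was used.

## Problem sizes used in validation

The test suite and the acceptance script run, by choice, at desk scale:
oracle equivalence on 100 random loci of up to 2,000 reads; 100 seeds for
signature recovery (ping-pong fraction 0.5 at 500 reads, debris
controls); 50 seeds for binomial parameter recovery at ~1,000 positions;
a 150-locus clustering cohort; and an end-to-end cohort of 20 loci per
generative class (~180k alignments) plus a 50-locus siRNA-scan cohort.
These sizes make the whole suite run in a couple of minutes while leaving
every statistical conclusion comfortably powered; all thresholds scale to
full-size data unchanged.

## Known limitations

- Hairpin discovery is not reimplemented: curation consumes candidate
  precursor/arm tables (e.g. parsed miRDeep2 output).
- The duplex-overhang register assumes the precursor is trimmed roughly
  to the fold; grossly padded precursors would bias both overhangs by the
  same offset (the difference is register-free).
- The repeat-peak PCI rule is this package's operationalization and its
  thresholds, while configurable and reported, are conventions — not
  values inferred from any reference dataset.
- No thermodynamic folding, transposon-family annotation, or
  developmental-stage differential expression.
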