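---
title: "In-silico restriction digestion and GBS genome coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico restriction digestion and GBS genome coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redigest)
library(dplyr)
```

## The problem

Genotyping-by-sequencing (GBS) reduces a genome to a sequenceable subset by
restriction digestion: fragments falling in a size-selection window — and,
in double-digest protocols, carrying two *different* enzyme ends so that
both adapters can ligate — are what ends up on the flow cell. The choice of
enzyme or enzyme pair therefore fixes, before any sequencing is done, how
much of the genome a GBS experiment can possibly see. `redigest` predicts
that quantity by simulating the digestion on a sequenced genome.

The central statistic is the **in-silico genome coverage (IgC)**: the
percentage of the genome covered by the fragments that pass selection,

$$\mathrm{IgC} = 100 \times
  \frac{\sum_{f \in \text{selected}} \mathrm{len}(f)}
       {\text{genome length}} .$$

The default selection window is 100–600 bp (inclusive at both bounds), a
deliberately wider window than the 200–400 bp of current wet-lab
protocols so that enzymes can be compared on a common, forward-looking
scale; both bounds are plain arguments. For a pair digest the
different-ends rule is applied on top of the size window; for a single
digest every fragment in the window counts.

## The digestion model

An enzyme is a name, an IUPAC recognition pattern and a top-strand cut
offset (`PstI` is `CTGCA^G`, offset 5). Digestion of one record proceeds
in three steps, each its own function:

1. **Site scanning** (`scan_sites`). Every (possibly overlapping) match of
   the recognition pattern on the forward strand is reported; for
   non-palindromic patterns the reverse-complement pattern is scanned too
   and positions are merged. Genome letters outside A/C/G/T match *no*
   pattern position, including pattern `N`: assembly gaps must not create
   recognition sites or fragments. Input is uppercased first, so
   soft-masked FASTA behaves like its unmasked equivalent.
2. **Cut placement** (`cut_positions`). A forward site at $p$ cuts at
   $p + \text{offset}$; a reverse-orientation site at $p$ cuts at
   $p + \text{len} - \text{offset}$. When two enzymes of a pair cut the
   same inter-base coordinate the single cut carries both labels.
3. **Fragment enumeration** (`enumerate_fragments`). Fragments are the
   half-open intervals between consecutive cuts, each end labeled with the
   cutting enzyme(s) or `CHROM_END`. With terminal fragments included the
   fragment lengths sum exactly to the record length — a conservation
   invariant the test suite checks for arbitrary cut sets.

Coordinates are 0-based and half-open throughout, which keeps the interval
arithmetic and the BED6 export exact. Fragments never span records:
chromosomes are independent molecules.

### Ambiguous end labels

A cut coordinate claimed by both enzymes of a pair propagates its full
label set to the adjacent fragment ends, and a fragment passes the
different-ends rule if *some* assignment of two distinct enzymes to its
two ends exists. The alternative — discarding fragments with shared-cut
ends — would silently drop molecules that either adapter could in fact
ligate to. `CHROM_END` never satisfies the rule, which is also why
pair-mode selection is insensitive to the terminal-fragment policy.

### Open conventions and the sweep harness

Two conventions are genuinely underdetermined when reproducing published
fragment counts from other implementations: whether fragment boundaries
sit at the physical cut coordinate or at the recognition-site start
(`boundary_mode`, default `cut_offset`), and whether terminal fragments
count toward the totals (`terminal_policy`, default `include`, under which
length conservation holds). Both are explicit flags, and
`sweep_conventions()` runs all four combinations so a calibration run can
report which convention set matches an external count exactly; the
differences are a few base pairs per fragment and at most two fragments
per record. The same reasoning applies to the IgC denominator: the default
`all_bases` divides by the reported sequence length including gap Ns, with
`acgt_only` available for gap-heavy assemblies.

## Ranking enzymes and pairs

`build_matrix()` digests an enzymes × genomes grid (each cell an
independent single-genome digest), `summarize_rows()` adds row means and
standard deviations — the *sample* SD, $n-1$ denominator, which is the
convention the published coverage tables use — plus optional group means
(e.g. plants only), and `ratio_to_reference()` compares each row to a
reference pair per genome. Ratios are computed from full-precision values
and averaged per row; genomes where the reference is zero are flagged
missing rather than imputed. Rounding to one decimal (`format_igc`,
half-up) happens only at the presentation layer.

The package ships two small published tables as examples and aggregation
fixtures: a 22-row pair-coverage matrix across 22 genomes
(`pair_igc_22species.tsv`) and a 12-species empirical-coverage table with
per-species ratios to the reference pair PstI+MspI
(`egc_three_pairs_12species.tsv`). Recomputing their printed summaries —
mean 32.3, SD 2.9, plant mean 31.9 for the top pair; mean 4.0 for the
reference; mean ratio 3.45 for HinfI+HpyCH4IV — is part of the test suite
and of `scripts/acceptance.R`. The printed per-species ratios derive from
full-precision coverages, so they are reproduced from the shipped ratio
columns, not by dividing the rounded coverage columns.

## Window profiles

`window_profile()` bins one record into fixed-width windows (default
100 kb) and counts the selected fragments whose *start* lies in each
window, alongside the mean cut coordinate per window. Windows are
tumbling by default (step = width) so counts are disjoint and sum to the
total fragment count — the interpretation that makes a per-chromosome
average-count line meaningful — with `step < width` available for true
sliding windows. The trailing short window is kept so no fragment is
lost. Start-containment was chosen over overlap-counting because it is
unambiguous and order-independent; with ≤600 bp fragments in 100 kb
windows the two differ by at most one fragment per window.

## The synthetic-genome generator

Tests and the acceptance script never download a genome. `random_genome()`
builds FASTA fixtures from a `synthesis_spec()`: i.i.d. background bases
at a target GC fraction (default 0.5, a neutral composition between
AT-rich plant and GC-rich microbial genomes), recognition motifs planted
at known coordinates, and N-runs emulating assembly gaps. Background
freedom from the enzymes' motifs is enforced by rejection at generation
time — any match (either orientation, including matches straddling a
plant boundary) that is not exactly a planted interval has its background
bases resampled — so `expected_digest()` can compute the exact digest
summary purely from the planted coordinates by direct interval
arithmetic, independent of the scanning and digestion code paths. That
oracle-vs-implementation equality, under all four convention
combinations, is the package's strongest correctness check.

Determinism: one PRNG stream per record, sub-seeded as
`seed + 9973 * record_index`, so adding a record never reshuffles earlier
ones and the same spec is byte-identical across runs. The caller's RNG
state is saved and restored.

What the generator does *not* emulate: repeats, isochores, local GC
structure, methylation landscapes, or realistic gap-length distributions.
Passing tests therefore demonstrate the correctness of the interval
arithmetic and selection logic, not that IgC predictions on real genomes
carry the sampling properties of real GBS libraries — on real data,
methylation sensitivity (metadata only here), partial digestion and
flow-cell saturation all push empirical coverage below the in-silico
value.

## Problem sizes and numerical choices

The test suite runs at desk scale: random sequences of 0.5–4 kb for the
oracle-equivalence properties, synthetic chromosomes of 6–10 kb with
20–32 planted sites for the digest oracles, and a 100 kb record for the
GC-composition check (binomial 3-SD bound). These sizes make every
property exhaustively checkable while the whole suite runs in well under
a minute; the digestion code itself is linear in sequence length and is
routinely run on multi-megabase FASTA input through the CLI. Degenerate
inputs are defined, not exceptional: an empty sequence has no sites, a
cut-free record yields one whole-record fragment (or none with terminals
excluded), an all-N record has zero metrics, and an enzyme paired with
itself warns and returns IgC 0 by construction.

## Known limitations

* Star activity, methylation-dependent cutting and partial digestion are
  not simulated; methylation sensitivity and incubation temperature are
  catalog metadata only.
* The built-in catalog covers 25 widely used enzymes with REBASE
  definitions; anything else comes in through `read_enzyme_tsv()`.
* Empirical coverage from sequencing reads is out of scope; the shipped
  empirical table is an aggregation fixture, not something the package
  can recompute from raw data.
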