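---
title: "Detecting structural variants on a metagenome coassembly graph"
author: "graphsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural variants on a metagenome coassembly graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphsv)
```

## The problem

Structural variants (SVs) — insertions, deletions, tandem duplications and
complex indels of 10 bp or more — drive much of bacterial adaptation, but in
metagenomes they are hard to see: there is usually no reference genome, and
mixed strains of the same species confound reference- and MAG-based callers,
which silently discard the reads that do not bin. `graphsv` takes the
reference-free route: all long-read samples of a series (a time course, a
temperature gradient, any ordered design over a largely shared community) are
assembled into **one coassembly graph**, so sequence shared across samples
and strains collapses into common nodes while variant sequence forms
branches. Every read of every sample then contributes signal, and SVs appear
as characteristic *graph motifs* whose coverage shifts between consecutive
samples.

An SV call here means *an increase (or decrease) in abundance of the variant
between consecutive samples*, not the mere existence of a variant branch:
assembly artefacts and standing variation produce branches too, but only
sequence that is actually thriving or declining changes coverage.

## The model

Let the series have samples $t_0, \dots, t_N$, all aligned to the same
collapsed assembly graph $G = (V, E)$, where each node is one segment (or
complementary pair, Bandage's "single" view) and each edge $e_{i,j}$ carries
a weight $w$ equal to the number of distinct links between $i$ and $j$ — a
link and its reverse-complement twin counting once.

For each sample $n$ and node $i$ the **node coverage** $vc_{i,t_n}$ is the
mean per-base depth implied by the alignment paths (interior path segments
covered fully, terminal segments clipped by the path offsets). Coverage
below a floor of 1 is raised to 1, so absent nodes behave like
depth-1 nodes instead of producing unbounded log ratios. Coverage is then
normalized across the series: with $bp_n$ the total aligned bases of sample
$n$ and $m = \mathrm{median}(bp_0..bp_N)$, sample $n$ is multiplied by
$m / bp_n$ and re-floored. (The reciprocal multiplier $bp_n/m$ is available
as `normalization_mode = "bp_ratio"`, and `"none"` disables scaling;
the default direction is the one that actually removes sequencing-depth
differences, which is the stated purpose of the step.) **Edge coverage**
$ec_{(i,j),t_n}$ counts how often a read path steps directly between $i$ and
$j$, pooling both directions; it is floored but not depth-normalized, since
the duplication rule below compares it only across consecutive samples of
similar depth and the floor keeps the ratio defined.

The unit signal is the **log fold change** between consecutive samples,

$$\mathrm{lfc}_i(n) = \log_2 \frac{vc_{i,t_n}}{vc_{i,t_{n-1}}}, \qquad
  \mathrm{lfc}_{(i,j)}(n) = \log_2 \frac{ec_{(i,j),t_n}}{ec_{(i,j),t_{n-1}}}.$$

Base 2 is the default because the duplication threshold "fold change greater
than 1" then reads as "more than doubling"; the base is configurable and
every rule below is base-agnostic except that threshold.

## The motif rules

For every consecutive step pair the caller scans:

* **Triangles** (three mutually adjacent nodes — a bubble with its two
  flanks). The median and standard deviation of the three lfc values are
  computed; a node strictly more than one sd from the median is an outlier.
  Exactly one outlier calls an **insertion** (outlier above the median) or a
  **deletion** (below). The median, not the mean, anchors the rule so one
  extreme value cannot drag the centre and flag all three nodes.
* **Squares** (simple 4-cycles — two parallel paths between flanks, the
  signature of a deletion plus insertion at one locus). One outlier, or two
  outliers on opposite corners (no cycle edge between them) with one above
  and one below the median, calls a **complex indel**. Chords are allowed;
  cycles with repeated nodes are not.
* **Self-loops and weight ≥ 2 edges.** A self-loop edge whose lfc exceeds 1
  calls a **tandem duplication** on the loop node (the collapsed repeat
  loops onto itself). A non-loop edge of weight ≥ 2 whose lfc exceeds 1
  calls a tandem duplication on the endpoint with the greater node lfc —
  *unless* that node already carries another call at this step: indels and
  complex indels are computed first and take precedence.

All thresholds are strict inequalities. The standard deviation is the
population form (÷ n) by default: with three values the sample form (÷ n−1)
can never flag two outliers, which would make the square rule's two-outlier
branch unreachable; `sd_mode = "sample"` restores the other convention. The
median of four values is the mean of the middle two.

A node supported by several motif instances of the same type at the same
step is reported once, keeping the motif with the largest
|outlier − median|; the raw instance counts stay in the `n_motifs` column
and in the `motif_instances` attribute, since per-motif and per-node
counting can differ substantially on dense subgraphs. Ties in the
weight-≥ 2 endpoint selection fall to the lexicographically smaller node id
so output is deterministic. No exclusion is applied between squares and
triangles that share edges: both rules see the full motif catalogue.

## Running it

```{r, eval = FALSE}
res <- run_call("graph.gfa", c("t0.gaf", "t1.gaf", "t2.gaf"), "out/")
res$calls
```

`run_call()` writes the SV table, coverage and lfc dumps, one Bandage
`Name,Colour` CSV per step pair (diverging blue–white–red scale, 0 pinned to
white, endpoints at the configured cap or the step's max |lfc|), a JSON
summary, and a manifest that reproduces the run. The same pipeline is
exposed as a shell command in `inst/cli/graphsv.R`, which can also drive
metaFlye (pooled reads, haplotypes kept) and minigraph (one alignment per
sample) when those binaries are on PATH; they are invoked, never
reimplemented, and their command lines are recorded verbatim.

Alignment records are taken as minigraph emits them: no mapping-quality or
length filter is applied by default (`min_mapq` / `min_length` are
available), coordinates are 0-based half-open throughout, and `bp_n` is the
sum of mapped read lengths in sample *n*'s GAF — unmapped records never
reach the counters.

## The synthetic fixture generator

`build_fixture()` produces desk-scale datasets with known truth: per-genome
backbone chains (node lengths drawn from `node_len_range`), one implanted
motif per event — a triangle bubble for an indel, a square for a complex
indel, a self-loop or weight-2 parallel edge for a duplication — and
per-sample GAF reads realizing the requested depths. A variant node's depth
is the genome depth times a step function: `1/fold` before an insertion's
step and 1 after (so the variant is the *rising* branch), the reverse for a
deletion; a complex indel rises on one parallel node and falls on the other;
a duplication's edge count jumps by `fold` (and the duplicated endpoint's
coverage doubles in the parallel-edge form, marking it as the called node).
Genome abundances may shift between samples; each sample's abundance row is
rescaled to mean 1 so depths stay on the `depth_base` scale, and the
caller's series normalization absorbs the resulting base-pair differences.

Defaults are chosen to look like a modest long-read metagenome experiment:
`depth_base = 20` (a typical per-strain depth at which both assembly and
alignment are dependable), event `fold = 4` in the bundled designs — one
octave above the doubling that the duplication rule's strict `lfc > 1`
threshold demands, so implanted duplications are detectable by construction
— and lognormal multiplicative depth noise with `noise_sd = 0` unless asked
for. Note that a duplication event with `fold ≤ 2` is *by design* invisible
to the caller.

Two presets mirror published benchmark designs at graph level:

* `hgtsim_design()` — 20 genomes (10 donors, 10 recipients), one gene from
  each donor inserted into every recipient: 100 insertion events between a
  pre-transfer sample (equal abundances) and a post-transfer sample whose
  relative quantities are drawn uniformly from 1–5 per genome. The insertion
  fold equals `depth_base`, so the inserted gene sits at the coverage floor
  beforehand — novel, then rising. The mutation-rate label (`m0`/`m30`)
  changes inserted-sequence divergence only, which a graph-level fixture
  does not model, so it is recorded but alters nothing.
* `zymo_design()` — 10 genomes at the nominal ZymoBIOMICS composition
  (eight bacteria at 12 relative units, two fungi at 2; the exact published
  abundances are available only graphically, so the nominal composition is
  used). Each genome gets 20 indels, 10 tandem duplications (half self-loop,
  half parallel-edge) and 10 complex indels — 400 events, all between two
  samples. Genomes 1–5 are variant-dominated in the second sample (full
  fold, default 8); genomes 6–10 carry a 50/50 variant/original mix and
  realize half the fold. Node lengths span 500–2000 bp.

What the generator deliberately does **not** emulate: read-level error and
chimeras, assembler behaviour (mis-collapse, fragmented backbones), sequence
collapse between a donor's gene copy and its inserted copies (each event
gets its own variant node), overlapping or nested SVs, and real abundance
dynamics beyond the configured step functions. Perfect recall/precision on
noiseless fixtures therefore validates the *calling rules and plumbing*, not
robustness to assembly artefacts — on real data the lfc machinery exists
precisely because such artefacts occur, and accuracy there is bounded by the
upstream assembler and aligner.

## Numerical and design choices

* Floors are applied after normalization as well as before, and to edge
  counts, so every log is finite; the floor's side effect is that lfc into
  or out of a floored value is compressed, which slightly shrinks outlier
  deviations for nearly-absent nodes but never flips an outlier's side.
* GFA input is restricted to 1.0 S/L records (the assembler's output);
  sequence-free segments need an `LN:i:` tag. Complement pairing is
  segment-level by default, with an optional explicit pair map.
* Link canonicalization (a link equals its orientation-reversed complement)
  precedes weighting; without it every adjacency would reach weight 2 and
  spuriously satisfy the duplication rule's `w ≥ 2` condition.
* Determinism: identical inputs give byte-identical SV tables; fixture
  generation is fully fixed by its seed; all row orders are sorted.

The bundled tests exercise the property suites at deliberately desk-scale
sizes — brute-force motif and caller oracles on 200 random graphs of up to
30 nodes, presets of 100 and 400 events, noiseless recovery on 3-sample
fixtures with 6 events of each type — sizes at which exhaustive enumeration
is itself cheap enough to serve as the oracle.

## Limitations

Inversions and translocations are out of scope: detecting them would require
keeping node directionality through the collapse rather than pooling
orientations. Series with fewer than two samples have no step pairs and are
rejected. Samples are snapshots: fluctuations that rise and fall entirely
between two sampling points are invisible by construction. Whether published
SV counts for comparable callers are per motif instance or per deduplicated
node-call is ambiguous; `graphsv` reports deduplicated calls and keeps the
instance counts alongside.
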