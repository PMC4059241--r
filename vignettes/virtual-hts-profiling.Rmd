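---
title: "Virtual HTS profiling, g-deNoise, and repeat-aware SNP calling"
author: "gdenoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual HTS profiling, g-deNoise, and repeat-aware SNP calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdenoise)
```

## The method

Repeats make short-read placement ambiguous, and ambiguity propagates into
variant calling: a polymorphic read from one repeat copy aligning onto
another copy looks exactly like a mutation. `gdenoise` addresses this with
an annotation-first design built from three ideas.

**Virtual profiling.** An error-free read is generated at every position of
the reference on the forward strand and aligned back to the reference,
exhaustively: every ungapped placement on either strand with at most $k$
mismatches is kept, with no cap on the number of hits per read and no
best-hit heuristic. For a chromosome of length $L$ and read length $r$
this produces $L-r+1$ reads, covering the interior $r$-fold with a
$1..r$ ramp at the ends. A read with more than one placement is
*multialigned*; discarding all unique placements and recording what is
still covered yields the **M regions**, and the gaps between them are the
**U regions**, at single-nucleotide resolution. Because any read
overlapping a repeat by even one informative window multialigns, an M
region extends up to $r-1$ nt beyond the repeat's exact boundary; this is
the operational definition used throughout, and it is why the minimal M
region length equals $r$ while a U region between two repeats can be a
single nucleotide.

**Intragenomic SNVs.** Virtual reads carry no sequencing errors, so a
mismatch inside a multialignment can only be a true single-base difference
between near-identical repeat copies. Every such mismatch is recorded as a
directed annotation $(\mathrm{chrom}, \mathrm{pos}, \mathrm{ref},
\mathrm{alt})$ with a support count. A mismatch inside a *unique*
placement of a virtual read is impossible and is treated as an internal
error rather than data.

**g-deNoise.** An alignment (virtual or experimental) is discarded iff at
least one of its mismatches matches an annotated SNV exactly on all four
coordinates. Three consequences matter:

* On the virtual run every mismatch is, by construction, annotated, so
  filtering keeps exactly the mismatch-free placements. Reads that span a
  copy-distinguishing site become uniquely aligned; the positions covered
  only by such reads form the **M_U** subregions, the rest remain **M_M**.
  M_U and M_M tile each M region exactly.
* Origin placements of virtual reads are mismatch-free and are therefore
  never discarded (the filter is sound on the reference itself).
* Matching is exact on the alternative base: a read presenting a *third*
  allele at an annotated position is not filtered. This is what lets an
  acquired mutation inside a polymorphic repeat survive the filter while
  the cross-copy noise around it is removed.

**Calling rules.** Pileups are built only from unique alignments:
natively unique reads in U regions; reads whose alignment set was reduced
to a single placement by g-deNoise in M regions. A U-region call requires
an alternative-allele fraction of at least 0.70 (closed threshold) and
support on both strands. An M-region call requires at least 10 rescued
alignments per strand arising from at least 5 distinct (start, strand)
points, at a position outside the low-complexity mask. Across $n$
samples, a variant present in all is *constitutive*, in exactly one
*acquired*, otherwise *shared*.

## Parameters and defaults

* `read_length` (nt): the resolution/sensitivity trade-off. Defaults to
  50; the command surface accepts the usual short-read lengths (25–100).
  Shorter reads inflate the M fraction sharply; `sweep_profile()`
  tabulates cumulative M length, count and genome fraction over a
  (read length × mismatch) grid.
* `k` (mismatches per read): defaults to 3 in base space. Color-space
  budgets are not comparable one-to-one: a single base substitution
  changes exactly two adjacent colors (verified exhaustively in the test
  suite), so a base budget of $k$ corresponds to roughly $2k$ colors.
* `space`: `"base"` or `"color"`. Color space uses the standard SOLiD
  dibase code — the unique 4×4 matrix in which each row and column is a
  permutation and identical pairs map to 0, realized as the XOR of 2-bit
  base codes. The primer base is excluded from mismatch counting, and
  reverse-complementing a sequence simply reverses its color string.
* Caller thresholds `min_fraction = 0.70`, `min_per_strand = 10`,
  `min_starts = 5`: all closed ("at least"). Start-point diversity is
  counted over distinct (start, strand) pairs of alt-supporting
  alignments, guarding against amplification duplicates.
* Mask parameters: homopolymer runs ≥ 5 nt; tandem repeats with unit ≤ 6,
  ≥ 3 copies and tract length ≥ 8; 2-nt flanks. These are deliberately
  conservative and configurable — "noisy" low-complexity tracts are a
  property of the chemistry and genome at hand, not of the method.
* `window = 2000` nt for coverage correlation: non-overlapping windows
  tiled from position 1, a trailing partial window kept when at least half
  a window; window means are log10-transformed with a pseudocount of 1 so
  zero-coverage windows are retained. These conventions are fixed for
  reproducibility.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive everywhere internally; BED exports
  convert to 0-based half-open via `rtracklayer`.
* `N` handling: windows overlapping an `N` produce no virtual read;
  positions inside `N` runs are labeled `undefined`, neither U nor M;
  colors adjacent to an `N` never match a read color; in alignment
  verification a reference `N` counts as a mismatch to any read base. This
  avoids fabricating alignments where the reference is unknown.
* The aligner uses pigeonhole seeding (partition each read into $k+1$
  pieces; any placement with ≤ $k$ mismatches contains an exact piece),
  exact-matching seed prefixes against a per-chromosome index and
  verifying candidates by a full Hamming count with early exit. When
  seeds would be shorter than 4 symbols the index degenerates and a plain
  scan is used; both paths are exhaustive and are checked set-identical to
  an independent naive scan in the tests.
* A palindromic locus aligning to itself on both strands yields two
  distinct placements (distinct strand keys) and the read is therefore
  multialigned; reverse-strand placements are first-class multialignment
  evidence, which is how inverted duplications are annotated.
* An alignment mixing one annotated SNV with a novel mismatch is
  discarded: keeping it would re-admit cross-copy noise into pileups. A
  read whose placements are all discarded drops out of calling entirely.
* Sample comparison generalizes the constitutive/acquired dichotomy to
  $n$ samples (all vs. exactly one); intermediate sharing is reported as
  `shared` rather than silently dropped.
* Color-space mismatches are decoded to base substitutions before SNV
  matching: two adjacent color mismatches whose implied alternative base
  agrees from both sides form one substitution; isolated or inconsistent
  color mismatches are treated as non-SNV mismatches and never enter the
  annotation.

## What the synthetic fixtures emulate — and what they do not

`make_genome()` plants repeat families (unit length, copy number, per-copy
direct/inverted orientation, a chosen number of divergent sites with
random carrier copy and allele) on a random background of configurable GC
content, and self-scans the background so it is repeat-free at the
profiling read length (regenerating on collision). `simulate_reads()`
draws uniform start positions on both strands and applies i.i.d.
substitution errors. This captures the features the method actually
exploits — copy-number structure, orientation, inter-copy polymorphism,
error-bearing reads at realistic depth — and deliberately omits others:
coverage biases, correlated or indel errors, quality strings, paired ends,
and the long tandem arrays (rDNA-scale) of real genomes. Passing tests
therefore demonstrate the correctness of the annotation and filtering
logic, not robustness to every artifact of a particular instrument.

The acquired-mutation scenario used in tests and in the acceptance script
mirrors the polymorphic-gene-family situation the method was designed
for: two locally identical copies are given copy-specific polymorphisms,
one copy additionally receives a private mutation in the sample, and the
call succeeds precisely because the supporting reads also carry the
adjacent copy-specific sites — and fails without the filter, because every
read covering the mutation is multialigned.

## Problem sizes

The package targets desk-scale analyses: the bundled tests and the
acceptance script profile fixtures of 1–8 kb at depths up to 150×, where
an exhaustive run plus oracle verification completes in seconds per
fixture. The same code paths scale to megabase genomes (the index is
linear in genome size and reads stream through in batches), but oracle
cross-checks at that scale are quadratic and are intentionally not part
of the default suite.

## Known limitations

* Ungapped alignment only: indels shift every downstream color/base and
  are out of scope, as are structural variants.
* M_M regions remain uncallable by construction — copies that are locally
  identical within a read length cannot be distinguished by any filter at
  this read length; longer reads or paired information would be needed.
* The U-region fraction rule imposes no absolute minimum coverage beyond
  both-strand support; at very low coverage the 0.70 rule alone is weak,
  and a depth floor should be added by the caller if warranted.
* Color-space support covers encoding, alignment, SNV decoding and
  filtering; experimental SAM ingestion is base-space (decoded reads), as
  produced by standard aligners.
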