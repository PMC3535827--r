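---
title: "Designing degenerate primers and probes from a multiple alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate primers and probes from a multiple alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consoligo)
```

## The problem

PCR primers and probes must hybridize to every target in a set of related
sequences. When the targets are diverse — viral genomes especially — no
single exact oligo binds them all, and the critical design step becomes
finding *conserved* regions of a multiple sequence alignment (MSA) where
primers can sit, tolerating a limited amount of residual variation as
*degenerate* positions (synthesized as base mixtures).

`consoligo` implements that workflow in three stages:

1. **Consensus.** The MSA is collapsed column-by-column into a single
   IUPAC-degenerate consensus, with a per-position conservation track.
2. **Search.** A window the size of the desired PCR product slides along
   the consensus; in each window, candidate forward and reverse primers
   (and, for real-time PCR, a probe between them) are screened against
   conservation-driven rules.
3. **Report.** Every accepted oligo is written to a tabulated text file
   with its coordinates, degeneracy, GC range, Wallace-rule dissociation
   temperature (Td) range and, for longer oligos, a nearest-neighbor
   melting temperature (Tm).

## Consensus construction

For each alignment column the observed characters are expanded to base
sets (an input `R` is evidence for A and for G) and the union of observed
bases becomes the column's IUPAC code, so `{A, G}` gives `R` and all four
bases give `N`. Two tunable decisions sit here:

* **Minor-allele cutoff** (`maf_cutoff`, default 0). With the default,
  *every* observed base is covered — the consensus embraces all observed
  variability, and degeneracy is controlled later at the oligo level. A
  positive cutoff drops bases whose column frequency does not exceed it
  (e.g. one G among ten sequences at `maf_cutoff = 0.15`). In the corner
  case where a cutoff excludes every base, the maximal-frequency base set
  is used so a code is always defined.
* **Conservation** is the frequency of the modal concrete (A/C/G/T)
  character among non-gap characters. Input ambiguity codes count toward
  the inclusion set but not toward the conservation numerator — ambiguous
  evidence should widen the code, not inflate apparent conservation. The
  TSV track also reports `code_match`, the fraction of characters equal
  to the final code letter, since either definition of a GUI-style
  "percent conserved" is defensible.

**Gap policy.** A column containing any gap is marked unusable
(`has_gap`, code `N`): a primer cannot meaningfully span an indel site.
The search refuses to cross such columns unless `allow_gap_columns` is
set. An all-gap column has conservation 0 and depth 0.

A single input record (e.g. a manually curated degenerate sequence) is
used verbatim as the consensus with conservation 1 — useful when the
consensus was built or edited elsewhere.

## Oligo rules

A candidate oligo (a consensus substring, read 5'→3' on either strand)
is accepted iff all of the following hold:

| rule | parameter | default | rationale |
|---|---|---|---|
| length | `oligo_min_len`–`oligo_max_len` | 18–25 nt | conventional primer sizing |
| degeneracy cap | `max_degenerate` | 3 positions | a mixture of >64 species dilutes each variant below useful concentration |
| 3' clamp | `clamp_len` | 3 positions | 3' mismatches abort extension; the extension end must be non-degenerate |
| Td band | `td_min`–`td_max` | 50–65 °C | practical annealing range for the Wallace rule |
| no gap columns | `allow_gap_columns` | off | indel sites break hybridization geometry |
| conservation floor | `min_conservation` | 0 (off) | optional extra stringency |

The 3' clamp is orientation-aware: for a reverse-strand oligo the 3' end
maps to the *left* edge of its consensus footprint. Probes get the same
clamp by default because unextended hydrolysis probes still suffer from
terminal mismatches; `probe_no_clamp` disables it for users who disagree.
Under the default `maf_cutoff = 0`, a non-degenerate consensus position
is precisely one where every observed base agrees, so the clamp enforces
"zero variable sites at the 3' end" without a separate conservation test.

**Td with degeneracy.** The Wallace rule Td = 2·(#A+#T) + 4·(#C+#G) is
positionwise additive, so the min/max over all concrete expansions of a
degenerate oligo equals the sum of per-position extremes (each position
contributes 2 if its base set touches A/T, 4 if it touches G/C). An oligo
passes the Td filter when its [Td_min, Td_max] range *intersects* the
user band — a point test is ill-defined for a mixture. GC content is
ranged the same way.

**Nearest-neighbor Tm.** The Td is always reported from the Wallace
equation; for oligos of ≥ 14 nt (the conventional upper bound of Wallace
validity) a two-state nearest-neighbor Tm is reported as well, using the
unified dinucleotide parameter set with initiation terms, the
0.368·(N−1)·ln[Na⁺] entropy salt correction and the self-complementarity
symmetry correction. Default conditions are 50 mM monovalent salt and
0.25 µM total oligo (`na_molar`, `oligo_molar`). For a degenerate oligo
the Tm is computed on its *modal expansion* (most frequent base per
column) and flagged `modal` in the report. Divalent-cation corrections,
hairpin and dimer prediction are out of scope; dedicated tools exist for
those checks.

## Windowed search

The window size *is* the product size. For each window start
`w ∈ {0, slide, 2·slide, …}` the forward primer must start at `w` and the
reverse primer's binding site must end at `w + window_size`, so the
amplicon length equals the window exactly. This strict anchoring is the
reproducible reading of "a window corresponding to the required product
size"; `anchor_slack = N` relaxes it by letting the primers shift inward
up to N nt. Defaults are window 150 with a probe (real-time PCR sizing,
classically < 150 nt) and 400 without (sequencing amplicons, classically
> 200 nt); the sliding value defaults to 20 nt.

With `probe = TRUE` a window is only reported if a valid probe fits
strictly between the primers (no overlap with either). Probes are sought
on the forward strand by default (`probe_both_strands` widens this),
since strand choice is mostly a labeling-chemistry concern.

One set per window is reported — the best candidate per role under a
deterministic lexicographic score: fewest degenerate positions, then
Td-range midpoint closest to the band centre, then longer oligo, then
smaller start, with strand as a final tie-break so the order is total.
`all_candidates = TRUE` emits every forward/reverse combination instead.
Overlapping windows that select the identical primer pair are
de-duplicated. The exhaustive mode (`enumerate_oligos`) skips windows
altogether and lists every valid oligo with coordinates, which is the
practical fallback for highly variable targets where no window yields a
complete set.

Coordinates are 0-based half-open internally and 1-based inclusive in
everything user-facing.

## The synthetic-alignment generator

`generate_alignment()` draws one random ancestor, copies it, and mutates
each background position independently (uniform over the three
alternative bases) with probability `background_divergence`, adding
single-column gaps with probability `indel_prob`; positions inside
`conserved_blocks` are never touched. This star-shaped model is
deliberately minimal: it has planted, exactly-known conserved blocks and
a background whose conservation decays geometrically with the number of
sequences, which is precisely what the search logic needs exercising.

The defaults (30% per-site divergence, 0.2% gaps) emulate a divergent
viral sequence set. The `hcv_like_stress()` preset — 61 sequences of
10,000 nt with four planted forward/probe/reverse site triples spaced on
the default slide grid, each triple spanning exactly 150 nt — mirrors a
realistic full-genome design task and doubles as the scale check: the
test suite runs the complete pipeline on it and verifies that every
planted triple is recovered, recording the wall time.

What the model does *not* have: phylogenetic structure (no tree, no
rate heterogeneity, no transition/transversion bias), multi-column
indels, or compositional bias. Passing the planted-recovery tests
therefore shows the search machinery is correct, not that real
alignments of comparable divergence will always contain recoverable
sites — on real data, conserved regions have fuzzy edges and may sit off
the slide grid, where `anchor_slack` and the exhaustive mode help.

Planted blocks are 24 nt and drawn uniformly over bases, so a block's
sub-oligo Td values are random; occasionally (a few percent of blocks)
no sub-oligo of a block falls inside the default 50–65 °C band and that
pair is legitimately not recoverable at the defaults. The acceptance
property (≥ 95% recovery over 20 seeds) budgets for this.

## Numerical and degenerate-input choices

* All randomness flows through a caller-supplied integer seed; the
  generator saves and restores the global RNG state.
* `wallace_td` refuses degenerate input (use `td_range`);
  `reverse_complement` refuses gaps; validation functions, by contrast,
  never throw on content — they return reasons.
* A consensus shorter than `oligo_min_len` yields an empty scan with a
  warning, not an error; an empty result still writes a well-formed
  report with its parameter comment block.
* Report formatting is fixed (temperatures and GC to one decimal,
  coordinates as integers, tab separation, '#' comments) so reruns are
  byte-identical and machine-diffable.

## Test problem sizes

The shipped suite checks the Wallace formula exhaustively on all 256
4-mers and the Td range against brute-force expansion on 1,000 random
degenerate oligos (degeneracy ≤ 64); scan/oracle equivalence on 200
random consensuses of 60–300 nt under randomized parameters; planted
recovery on 20 seeds of a 12 × 1,000 nt fixture with three site triples;
and one full 61 × 10,000 nt stress run. These sizes were chosen to make
every property decidable by an independent naive oracle while keeping
the suite quick to run.
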