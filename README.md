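# consoligo

Degenerate PCR primer and probe design from multiple sequence alignments.

## The problem

Primers and probes for PCR must hybridize across an entire set of target
sequences. For diverse targets — viral genomes, environmental amplicons —
the design problem is really a *conserved-region search*: find windows of
a multiple alignment where every sequence (nearly) agrees, and tolerate
the residual variation as IUPAC-degenerate positions synthesized as base
mixtures. `consoligo` automates this for both conventional/sequencing PCR
and real-time (probe-based) PCR.

## Method in brief

1. **Degenerate consensus.** Each alignment column is collapsed to the
   IUPAC code covering every observed base (optionally dropping bases
   below a minor-allele cutoff), with a conservation track — the modal
   base frequency per column. Columns containing gaps are marked
   unusable. A single input sequence (e.g. a curated consensus) is used
   verbatim.
2. **Sliding-window search.** A window equal to the desired product size
   slides along the consensus in steps of the *sliding value* (default
   20 nt). The forward primer is anchored at the window start and the
   reverse primer's binding site at the window end; real-time mode
   additionally requires a probe strictly between them. Every candidate
   oligo must satisfy, by default: length 18–25 nt, at most **3
   degenerate positions**, a **non-degenerate 3' clamp** of 3 positions
   (zero variable sites at the extension end), and a Wallace-rule Td
   range intersecting 50–65 °C. Alternatively, an exhaustive scan lists
   *all* valid oligos with coordinates.
3. **Thermodynamics and report.** Each reported oligo carries its
   coordinates (1-based), degenerate-position count, degeneracy, GC
   range, dissociation temperature range by the Wallace rule

   *Td* = 2 °C · (#A + #T) + 4 °C · (#C + #G),

   where the min/max over all expansions of a degenerate oligo is taken
   positionwise, and — for oligos ≥ 14 nt — a two-state nearest-neighbor
   melting temperature (unified parameter set, entropy salt correction,
   50 mM Na⁺, 0.25 µM oligo by default).

A seedable synthetic-alignment generator with planted conserved blocks
(`generate_alignment()`, `hcv_like_stress()`) provides ground truth for
testing and benchmarking the whole pipeline.

## Worked example

Design a real-time PCR primer/probe set on a synthetic alignment of 12
divergent sequences (35% per-site background divergence) carrying three
planted 24 nt conserved blocks at positions 101–124, 161–184 and
227–250:

```r
library(consoligo)

g <- generate_alignment(synth_spec(12, 1000,
       rbind(c(100, 124), c(160, 184), c(226, 250)),
       background_divergence = 0.35, seed = 42))
cons <- build_consensus(g$alignment)
cons
#> <consensus: 1000 nt, 926 degenerate position(s), source=alignment>

params <- search_params(probe = TRUE)   # window 150, slide 20
sets <- find_primer_sets(cons, params)
sets
#> <1 primer set(s)>
#>   product 101-250 (150 nt): F CTACACTGTATATGCCGAAC  R TTCAAAGCCTAGACTCCGG  P ACCGCTGGCATATCACGC

write_report(sets, cons, params, "report.tsv")
```

The search found exactly one window with a complete set — the planted
one: the forward primer sits on the first conserved block (101–120), the
probe on the middle block (161–178) and the reverse primer (reported
5'→3' on the reverse strand) on the last block (232–250), delimiting a
150 nt product. The tabulated report:

```
product_id  role            sequence              start  end  strand   length  degenerate_count  degeneracy  gc_min  gc_max  td_min  td_max  tm_nn  tm_basis  product_len
set_0001    forward_primer  CTACACTGTATATGCCGAAC  101    120  forward  20      0                 1           45.0    45.0    58.0    58.0    49.9   exact     150
set_0001    probe           ACCGCTGGCATATCACGC    161    178  forward  18      0                 1           61.1    61.1    58.0    58.0    57.4   exact     150
set_0001    reverse_primer  TTCAAAGCCTAGACTCCGG   232    250  reverse  19      0                 1           52.6    52.6    58.0    58.0    53.0   exact     150
```

Every primer here is non-degenerate (`degenerate_count` 0, `degeneracy`
1) so the GC and Td ranges collapse to points: e.g. the forward primer
has Td = 2·11 + 4·9 = 58 °C, inside the default 50–65 °C band, and a
nearest-neighbor Tm of 49.9 °C at the default conditions. On degenerate
oligos these columns become ranges over all expansions and `tm_basis`
switches to `modal`. The first row also carries the 150 nt product
(amplicon) sequence, degenerate where the alignment varies.

The same pipeline is available from the shell via the installed launcher
(`inst/exec/consoligo`):

```sh
consoligo fixtures --out aln.fasta --seed 42 --n-seqs 12 --length 1000 \
          --blocks 101-124,161-184,227-250 --divergence 0.35
consoligo design --in aln.fasta --out report.tsv --window 150 --slide 20 --probe
consoligo scan   --in single.fasta --out oligos.tsv      # all valid oligos
consoligo consensus --in aln.fasta --consensus-fasta cons.fasta \
          --conservation-tsv track.tsv
```

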