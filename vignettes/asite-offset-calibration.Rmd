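---
title: "Calibrating ribosome A-site offsets by integer programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating ribosome A-site offsets by integer programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asiteIP)
options(asiteIP.log_level = "ERROR")
```

## The problem

A ribosome-protected fragment tells us that a ribosome occupied some codon
when translation was halted, but not which one: the codon being decoded sits
in the ribosomal A-site, some distance downstream of the fragment's 5'
end. That distance — the *A-site offset* Δ — is roughly 15 nt for 28-nt
yeast fragments, but nuclease digestion is incomplete and stochastic at both
fragment ends, so the offset varies with fragment size *S* and with the
reading frame *F* of the 5'-end nucleotide (the residue of its CDS-local
position modulo 3). Misassigning the offset by even one codon smears
codon-level signals such as stalling peaks into their neighbours.

`asiteIP` calibrates a per-(S, F) offset table from the data themselves,
using one biological constraint: in steady-state elongation the A-site of a
translating ribosome lies between the **second codon** (after initiation the
start codon occupies the P-site) and the **stop codon** of the CDS.

## The integer program

For gene *i* and a (S, F) class of reads, each candidate offset Δ implies an
A-site nucleotide *p* + Δ for a read whose 5' end is at CDS-local position
*p*. The per-gene objective is

> T(Δ | i, S, F) = number of reads with *p* + Δ in [3, L),

where L is the CDS length in nt, subject to 0 ≤ Δ ≤ S and Δ ≡ 0 (mod 3).
The feasible set has at most ⌊S/3⌋ + 1 points, so the program is solved
exactly by enumeration (`best_offsets_for_gene()`); "integer programming"
names the formulation, not a solver dependency, and the test suite checks
the enumeration against an independent brute-force oracle on randomized
inputs.

Per-gene solutions are then aggregated across genes (`decide_offset()`):

1. **Eligibility.** Genes averaging fewer than `min_reads_per_codon`
   (default 1) reads per codon at that (S, F) are excluded: with fewer
   reads than codons the argmax is dominated by sampling noise.
2. **Voting.** Each eligible gene votes for its argmax offset. Genes whose
   argmax is tied abstain — ambiguous evidence should neither inflate nor
   dilute the vote, so abstainers are also excluded from the vote
   denominator and from the gene count below.
3. **Uniqueness.** The modal offset Δ\* is reported as *unique* when
   (a) at least `min_vote_fraction` (default 70%) of voting genes chose it,
   (b) at least `min_genes` (default 10) genes voted, and
   (c) the *metagene ratio* at Δ\* — the mean of the summed read counts in
   codons 2–4 over the summed count in codon 1, aggregated across eligible
   genes — is at least `min_metagene_ratio` (default 5). A correct offset
   places initiation-paused density on codon 2, not on the start codon, so
   codon 1 should be nearly empty; the ratio is `Inf` when codon 1 is empty
   and the numerator is not, and 0 when all four codons are empty.
4. Otherwise the two top vote-getters are reported as *ambiguous*
   (descending votes, ties broken toward the smaller offset for
   determinism) when at least two offsets received votes and the gene floor
   is met; else the cell is *insufficient*.

The vote-fraction validator rejects values at or below 50%: below that the
"modal" offset need not be unique even in the limit of infinite data.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `size_min`, `size_max` | 20, 35 | nt | fragment-size grid |
| `extra_nt` | `size_max` | nt | flank beyond the CDS in which 5' ends are still assigned to a gene |
| `min_reads_per_codon` | 1 | reads/codon | gene eligibility |
| `min_vote_fraction` | 0.7 | — | uniqueness vote threshold |
| `min_genes` | 10 | genes | uniqueness gene floor |
| `min_metagene_ratio` | 5 | — | codons 2–4 vs codon 1 |
| `window_end` | `"stop"` | — | whether the stop codon is a legal A-site |

`extra_nt` defaults to `size_max` rather than 0 because the score window
starts at nt 3: a fragment whose A-site is codon 2 has its 5' end up to
S − 3 nt *upstream* of the start codon. Truncating the flank discards
exactly the boundary reads that separate Δ from Δ − 3, which share the score
on all interior positions. A read whose 5' end falls inside the CDS-or-flank
window of more than one same-strand gene is dropped (and counted): without
an assignment rule any split would be arbitrary, and only same-strand genes
compete because ribosome-profiling libraries are strand-specific.

The A-site window is taken *inclusive* of the stop codon by default — the
stop codon is a legitimate A-site at termination — with
`window_end = "sense"` offering the exclusive variant.

## Profiles

`apply_offsets_*()` turn the counts plus an offset table into three profile
sets: (1) per-nucleotide, placing each read at *p* + Δ with the offset used
unmodified; (2) per-nucleotide mapped to frame 0, where a frame-F read uses
Δ − F so every assigned position is a multiple of 3; (3) per-codon, binning
the frame-0 positions by 3. Reads in cells without a unique offset are
dropped by default (`drop_ambiguous`), following the recommendation to
disregard reads with uncertain offsets; `use_first` assigns the top
ambiguous candidate instead and is logged. Reads whose offset carries them
outside the CDS are dropped and counted; conservation (reads in = assigned
+ dropped) is asserted per gene and globally in the tests. File output is
1-based; everything internal is 0-based half-open, converted only at
parse/write boundaries so no off-by-one can accumulate.

## The simulator

`synthetic_spec()` + `simulate_dataset()` generate a complete dataset —
FASTA references, TAB annotation, SAM alignments, per-read truth — from a
known offset map. The generator emulates steady-state elongation only:
A-site codons are drawn uniformly from codon 2 through the stop codon, with
two optional multipliers (an initiation pause on codon 2, and stall
enrichment on the third codon of chosen tripeptide motifs such as PPG). A
fragment of size S in frame F is placed with its 5' end at
a − (Δ(S, F) − F), where a is the A-site start. The subtraction of F is
deliberate: with both a and Δ multiples of 3, placing 5' ends at a − Δ
would confine every read to frame 0; the Δ − F convention is the same one
the frame-0 profile transformation inverts, and it makes all three frames
generable. For frame-0 reads the truth file satisfies 5' end = a − Δ
exactly.

`reads_per_codon` (default 10) is the expected per-codon depth within each
(size, frame) class; with the default uniform size and frame distributions
a 60-codon gene under a 4-size × 3-frame map receives ≈ 7200 reads. Default
study conditions are 30 genes of 60 codons with the canonical yeast
geometry (15 nt for 28–29-nt fragments, 18 nt for 30–31-nt), no noise.
Genome-mode references carry one gene each, alternating strands, with 50-nt
random flanks; a transcriptome-mode variant exercises the single-segment
forward-strand path.

What the simulator does *not* model — sequencing error, ligation bias,
nucleotide-specific digestion preferences, overlapping genes, isoforms,
non-steady-state regimes such as run-off after harringtonine — bounds what
a passing test shows: the machinery is correct on data satisfying the
method's own assumptions, not that those assumptions hold in any given
library. (Non-steady-state data violate the codon-2..stop constraint
itself and are out of scope for the method, not just the simulator.)

## Stall-motif evaluation

Pro-Pro-X tripeptides stall elongation with the X codon in the A-site,
giving a rare positional ground truth. `evaluate_motif_offsets()` locates
every (possibly overlapping) occurrence of a motif in the translated CDSs,
reads the codon-resolution density at the third residue under two competing
offset tables, and reports the fraction of instances where table A is
higher (ties counting for neither side) plus a two-sided Wilcoxon
signed-rank p-value; when all pairs tie the degenerate test returns p = 1.
Instance selection uses an explicit `min_density` floor (default 1 read) on
the pairwise maximum — a reproducible surrogate for restricting attention
to well-covered instances. Shifting the true table by +3 nt codifies a
one-codon misassignment; on simulated stall data the true table dominates,
which the acceptance tests verify at 120 instances.

## Numerical and design choices

- **Frame of negative positions.** F = ((p mod 3) + 3) mod 3, the
  non-negative residue, so a 5' end at −2 is frame 1; this keeps frame
  strand- and sign-agnostic.
- **Fragment size** is the aligned query length, excluding soft clips:
  clipped bases were not part of the protected fragment's alignment.
- **Spliced alignments** contribute their 5'-end coordinate mapped through
  the exon union; 5' ends landing in introns are dropped and counted.
- **Multi-mapping**: only primary, non-supplementary alignments count, once
  each. No deduplication or UMI handling is attempted.
- **Isoforms**: the first-encountered mRNA per gene is used; the method is
  per-gene and segment-resolved, and isoform deconvolution is a different
  problem.
- **Non-mod-3 CDSs** are skipped with a warning, never truncated — silent
  truncation shifts every downstream frame.
- **Determinism**: tensors are keyed (gene, size, frame, position), tie
  breaks are explicit, and reruns are byte-identical; the simulator is a
  pure function of its spec (one seed, one PRNG stream).

Test and acceptance runs use deliberately desk-scale problems — up to 30
genes of 60 codons, ~10 reads/codon/class (≈ 2 × 10⁵ reads), five seeds for
recovery, 200 random tensors for oracle equivalence — sizes at which the
brute-force oracles are exact and the full pipeline, SAM round trip
included, runs in seconds per seed.

## Known limitations

- One offset per (size, frame) cell: no per-gene offsets, no modelling of
  the 3' end, no probabilistic deconvolution of mixed offsets.
- P-site/E-site positions are not inferred (subtract 3 or 6 nt at your own
  discretion).
- GFF3 only (no GTF); transcriptome-mode annotations must be
  single-segment, forward strand.
- The uniqueness thresholds are calibrated for libraries with at least tens
  of well-covered genes; sparse single-cell libraries will mostly produce
  `insufficient` cells, which is the intended failure mode, not a bug.
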