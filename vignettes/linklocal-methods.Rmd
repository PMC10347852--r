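---
title: "linklocal: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{linklocal: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and
its assumptions, the parameters that matter, what the bundled simulator
does and does not emulate, the numerical choices, and known limitations.

## The problem and the model

Local assembly reconstructs the unknown sequence between two known
flanking coordinates (a *target*, or gap) de novo from whole-genome
sequencing reads. With plain short reads, the de Bruijn graph of the whole
read set is large, repeat-tangled, and mostly irrelevant to any one locus.
Linked reads change the economics: every read carries the barcode of the
long DNA molecule (tens of kb) it derives from, so reads that *originate*
near the target can be identified by barcode even when they do not *map*
near the target (or do not map at all — the interesting case for novel
insertions).

The method is a three-step pipeline per target:

1. **Subsampling.** Count read alignments per barcode in the two windows
   of size `flank` adjacent to the gap (union of both windows; primary,
   non-duplicate, MAPQ ≥ 1 alignments, one count per read). Keep barcodes
   with at least `occ` observations; recruit all their reads genome-wide.
2. **Assembly.** Build a de Bruijn graph over canonical k-mers of the
   recruited reads, keep k-mers with abundance ≥ `a` (*solid*), anchor the
   traversal at START/STOP k-mers taken from reads aligned at the extended
   target boundaries, and enumerate START→STOP paths breadth-first under
   exploration caps. Reduce the path set to representatives that pairwise
   differ by more than 10%.
3. **Gate and descent.** The assembled sequence deliberately includes
   `ext` bp of each flank. Realign those extensions to the reference; a
   candidate passes only with identity > 0.90 over coverage > 0.90 of
   each extension (per side — the stricter of the two possible readings).
   On failure, retry with the next (k, a) on the ladder. One passing
   candidate is the answer; several mutually divergent passing candidates
   mean the data cannot tell which is right, and by default none is
   returned.

Assumptions worth making explicit: the flanks must be placeable on the
reference the BAM was mapped to (the method is reference-free only for
the *target* sequence); per-molecule read depth must make barcodes
observable in the flank windows (a molecule needs ≥ `occ` reads there);
and the target must be reachable by molecules anchored in the flanks, so
the practical size limit is set by the molecule length distribution.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `flankSize` | 10,000 | bp | window for barcode harvest; performance is insensitive over roughly 5–15 kb, since barcodes of interest concentrate near the target |
| `minOcc` | 2 | reads | one observation can be a stray or collided barcode; two suppress most noise without losing real molecules |
| `ext` | 500 | bp | extension length; must be ≥ k (61) for the anchors, long enough for a meaningful 90/90 alignment test, small against the flanks |
| `kLadder` | 61, 51, 41, 31, 21 | bases | larger k resolves repeats when depth supports it; the descent trades specificity for connectivity as subsample depth thins |
| `aLadder` | 3, 2 | copies | solid-k-mer threshold per rung; `a` descends within each k before k drops |
| `minIdentity`, `minCoverage` | 0.90, 0.90 | fraction | the acceptance rule, applied per side to each extension |
| `maxActiveBranches` | 100 | paths | frontier cap; truncation is flagged and drives the descent |
| `maxNodesExplored` | 1e7 | extensions | global traversal budget |
| `maxPathLength` | gap + 2·ext + 10,000 (50,000 if unknown) | bp | bounded by molecule reach |

## Traversal semantics

The paths enumerated between the anchors are defined precisely as:

- START and STOP are oriented k-mers; membership in the graph is
  strand-symmetric (canonical form, lexicographic min of k-mer and
  reverse complement). k is odd for assembly, so no k-mer is its own
  reverse complement.
- STOP is absorbing: a path ends the first time it spells STOP.
- A path may use a canonical k-mer at most twice. Pure simple paths would
  forbid assembling any tandem repeat; unlimited revisits would not
  terminate on cycles. Two visits admit one extra copy of a tandem unit
  while guaranteeing termination. A 300 bp exact tandem pair inside a
  target therefore yields both the true 2-copy path and a 1-copy
  shortcut; both pass the extension gate (the repeat is internal), the
  result is "multiple solutions", and no chimeric single answer is ever
  reported silently.
- Results are ordered by (length, lexicographic), making every downstream
  step order-deterministic. The test suite checks the traversal against
  an independent brute-force DFS enumerator with the same contract.

## Identity: two definitions, used deliberately

Two different alignments are used and must not be conflated:

- **Extension gate and benchmark classification**: free-end-gap (overlap)
  alignment; identity = matches / alignment columns within the aligned
  region, coverage = aligned reference span / reference length. This is
  the right tool for "does this piece align well over most of that one".
- **Candidate-pair divergence (the 10% rule)**: *global* alignment
  identity with end gaps counted. Candidates share their `ext` bp
  extensions by construction; a free-end-gap comparison of two divergent
  alleles would happily align just the shared extension and call them
  ~100% identical, collapsing exactly the multiple-solutions case the
  rule exists to protect. Whole-sequence identity scores a 1,100 bp and a
  2,100 bp allele sharing 1,100 bp at ~0.52.

Scoring is fixed at match +1, mismatch −1, gap open 2, gap extend 1 — any
sensible scheme works; one is pinned for reproducibility.

Benchmark classification additionally requires the truth/assembly length
ratio to exceed the coverage threshold, so an over-long assembly that
merely *contains* the truth is not counted successful (more than 10% size
divergence is an error, consistent with treating incompleteness as one).

## The simulator: what it emulates, and what it does not

`simulateLinkedReads()` generates: a (or a given) reference; molecules
with lognormal lengths truncated to 5–150 kb (mean 50 kb, log-sd 0.35),
placed uniformly; one barcode per molecule by default
(`molPerBarcode > 1` models barcode collisions); read pairs per molecule
at per-molecule depth 0.2 (Poisson counts, normal insert 350 ± 35 bp,
100 bp reads) to reach a configured genome coverage (default 40×); iid
substitution errors (0.5%); and ground truth: molecule→barcode→interval
and read→molecule tables, plus a coordinate-sorted BAM written from the
*true* placements. `plantTarget()` prepares benchmark scenarios: a random
locus (truth = reference substring), a homozygous/heterozygous deletion
(truth = the 2·pad breakpoint junction), or an insertion (truth = the
padded inserted allele), with donor haplotypes and their collinear
coordinate maps; reads that do not map collinearly to the reference
(inside novel insertions, across deletion junctions) enter the BAM
unmapped, barcode preserved.

Not modeled: GC/coverage bias, PCR and optical duplicates, indel
sequencing errors (available as an option is deliberately omitted — the
default keeps graph behaviour analyzable), quality-score error profiles,
mapping ambiguity (the BAM is truth-placed; real mapping noise in
repeats is absent), chimeric molecules, and reference-vs-donor SNP
background beyond the planted variant. Passing tests therefore
demonstrate the machinery — subsampling arithmetic, graph and traversal
correctness, gate and ladder logic, format round-trips — under clean
statistics; they do not by themselves establish success rates on real
libraries, where repeat content and coverage biases dominate.

## Scenario design in the test suite

Problem sizes were chosen as the smallest that exercise the full method:
random-locus benchmarks use a 500 kb haploid reference at 40× (100,000
read pairs; 1 kb and 5 kb targets), deletion benchmarks ten independent
120 kb simulations, unit tests a shared 100 kb fixture. Two scenarios are
depth-powered on purpose:

- The **heterozygous-insertion** scenario (multiple-solutions semantics)
  uses per-haplotype depth equal to the standard 40× (80× total). The
  junction k-mers of each allele see only half depth; at 40× total and
  k = 61 their dropout probability is high enough that whichever allele
  path happens to survive is reported alone — correct behaviour, but it
  would test coverage luck, not the reporting logic.
- The **ladder-scheduling** scenario uses 65× haploid coverage: with 0.5%
  errors a 61-mer survives a read with probability ≈ 0.74, so per-k-mer
  depth is ≈ 0.29 × coverage. At 65× that is ≈ 19, putting the
  probability that any k-mer of a ~2 kb path falls below 3 copies under
  1e-5 — the top rung is statistically guaranteed, and the test isolates
  *scheduling* (easy targets stop at (61, 3); repeat targets never pass
  as a silent chimera) from sampling noise. At 40× the same probability
  is ≈ 0.5 per target, which is the regime the descent ladder exists for.

One consequence of desk-scale genomes is worth stating: the subsampling
*enrichment* metric (fraction of recruited reads whose molecule lies
within ±50 kb of the target, over the genome-wide fraction) is bounded
above by the reciprocal of the genome-wide fraction, i.e. by
genome length / (target + 100 kb + mean molecule). On a 500 kb genome the
ceiling is ≈ 3.3× no matter how well the subsampler works; ten-fold
enrichment is only observable on references ≳ 1.5 Mb, and the suite
demonstrates it on a 2 Mb simulation. On real genomes (Mb–Gb) the same
metric is large; this is a property of the measure at small scale, not of
the method.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere user-facing (GFA/BED
  convention); conversion to 1-based GRanges/BAM happens only at the
  format boundary.
- Anchor ties (equal read support) break lexicographically; anchor
  extraction uses only reads aligned without indels across the anchor
  window, so substitution-only disagreement is resolved by majority.
- START = STOP degenerates to a single k-length candidate. An empty
  subsample, an anchor side with no spanning read, and an exhausted
  ladder each produce a distinct structured status, never an error.
- Unknown gap length is encoded in GFA 2.0 as `dist` 0 plus a
  `GE:Z:unknown` tag (the G-line `dist` must be an integer); the reader
  maps it back to `NA`.
- Solved gaps are written back as a new segment `<label>.assembled`
  (assembled target plus k−1 bp of each flank) linked to the flank
  segments by two edges declaring the k−1 overlap; unsolved gaps keep
  their G lines, so the output GFA re-parses with exactly the unsolved
  targets.
- Targets are processed independently; parallel runs partition targets
  across forked workers with the barcode index read-only, and outputs are
  written once, in input order — byte-identical for any thread count.

## Known limitations

- The barcode index parses the read file into memory; appropriate for
  targeted work and the simulation scales here, not for a 1.5-billion-read
  library (a disk-backed index behind the same interface would be the
  extension point).
- No diploid phasing: two well-supported divergent alleles are reported
  as multiple solutions, not as a phased pair.
- Tandem repeats longer than one extra unit (three or more copies at unit
  length ≥ k) exceed the two-visit rule and assemble incompletely —
  visible as a gate failure or multiple solutions, not as silent loss.
- Anchor recovery requires reads aligned across the anchor window with
  match-only alignments; loci whose flanks are themselves unmappable at
  MAPQ ≥ 1 fail at anchoring (reported as such, distinct from assembly
  failure).
- Long targets thin out the recruited depth mid-target (molecule reach),
  so success degrades with target size; the k-ladder recovers some of it
  at the cost of repeat resolution.
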