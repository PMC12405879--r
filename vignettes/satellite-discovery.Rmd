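---
title: "Satellite DNA discovery with satmine: model, algorithms and defaults"
author: "satmine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite DNA discovery with satmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmine)
```

# The problem and the model

Satellite DNAs are tandem arrays — often tens of kilobases long — of a
short repeat unit (the *monomer*). Three properties make their annotation
different from ordinary sequence analysis and drive every design decision
in this package:

* **Rotational ambiguity.** An array `...ACGTACGTACGT...` is equally well
  described by the unit `ACGT`, `CGTA`, `GTAC` or `TACG`. Any statement
  about "the" monomer must be invariant under cyclic rotation.
* **Strand symmetry.** Arrays are annotated on double-stranded genomes, so
  a unit and its reverse complement describe the same satellite.
* **Non-primitivity.** A detector may lock onto a doubled unit
  (`ACGTACGT`); the fundamental unit is the *primitive period*, the
  shortest prefix whose exact tandem expansion reproduces the string.

`satmine` therefore standardizes every monomer to its **canonical form**:
the lexicographically least string (A < C < G < T) among all rotations of
the monomer and all rotations of its reverse complement, computed with
Booth's least-rotation algorithm on both strands. The primitive period is
computed from the Knuth–Morris–Pratt failure function: for a string of
length $n$ with border length $f$, the candidate period $p = n - f$ is the
answer when $p \mid n$, otherwise the string is primitive. (Note this is
the *tandem-root* definition: `"ACACA"` has primitive period 5, not 2,
because 2 does not divide 5.)

Monomer similarity is the **rotation/strand-invariant identity**: the
maximum over all $2L$ orientations of one monomer of the global
(Needleman–Wunsch) alignment identity against the other, symmetrized by
taking the larger of the two directions. Identity is matches divided by
alignment columns, so indels — including terminal gaps — count against it.
Alignment scores are +2 match, −3 mismatch, gap opening 5 and extension 2.

# The discovery pipeline

## Array detection

`scanContig()` is a self-contained tandem-array detector:

1. **Seeding.** Every exact 10-mer's distance to its next occurrence is
   computed from a rolling base-4 code. Positions whose recurrence distance
   is a common value $d$ form candidate arrays of period $d$; runs are
   broken when consecutive seed positions are more than $d + 10$ apart.
   Distances are processed in ascending order and seeds already covered by
   a refined array are suppressed, so a 10 bp satellite is not re-reported
   as 20, 30, … bp.
2. **Extension.** From a seed anchor, copies are read at a fixed stride of
   one period in both directions. When the in-phase identity of the next
   copy falls below a fast-path bar, offsets of ±1 and ±2 bp are tried —
   tolerating occasional indels without full dynamic programming.
3. **Refinement.** The unit is first reduced to its primitive period; the
   consensus is rebuilt by per-column majority over all copies and the
   array re-extended, recursing at most twice when the refined consensus
   itself has a sub-period.
4. **Filtering and overlap resolution.** Arrays are kept when the unit
   length is within `[unitMin, unitMax]` (default 20–500 bp), copy number
   ≥ `minCopies` (default 5), mean per-copy identity to the array consensus
   ≥ `minIdentity` (default 0.8), and the alignment score
   (matches·2 − mismatches·3 − jitter·5) ≥ 50. Overlapping candidate
   arrays are resolved by higher score, then smaller unit, then leftmost.

Coordinates are 0-based half-open; runs of N split contigs into
independently scanned segments. The `mean_identity` field is defined as the
mean identity of each copy against the array consensus (not against the
adjacent copy).

## Clustering, consensus and variants

Canonical monomers are weighted by the genomic bp of their arrays and
clustered greedily in decreasing weight (cd-hit style): each monomer joins
the first family whose representative it matches at `cluster_id` (default
**0.8**, permissive enough to hold a family with up to ~20% internal
divergence together while separating unrelated units), else founds a new
family. The family consensus is a weighted per-column majority over all
members, each first put into its best orientation against the
representative and projected onto its frame by global alignment.

**Variants.** Within a family, members are sub-clustered at
`variant_id = 0.95`; when at least two sub-clusters each hold
`variant_min_share = 0.20` of the family bp, they are reported as variants
A, B, … in decreasing share, with the diagnostic positions at which each
differs from variant A. The thresholds mirror the observed structure of
dimorphic satellites, where two co-abundant forms differ at a handful of
diagnostic sites.

**Naming.** Families are named `<prefix>Sat-<consensus length>` (e.g.
`BcopSat-145`); a second family with the same unit length receives a
lowercase suffix (`-155b`). Abundance uses merged (overlap-collapsed)
per-family intervals, reported as total kb and fraction of assembly; the
default "abundant" floor is 200 kb.

## Cross-assembly comparison

`matchFamilies()` matches two family sets greedily by decreasing
rotation-invariant consensus identity (floor 0.8, each family used once).
`flagRestricted()` operationalizes "absent or at very low abundance in the
other assembly": a family is flagged when it is private to one side with
at least `compare_min_kb` (default 200 kb), or shared with a pseudocounted
abundance ratio ≥ `compare_ratio_min` (default 5). The +1 kb pseudocount
keeps ratios finite when a family is absent on one side; 5× is a
conservative enrichment floor well above assembly-to-assembly noise.

## Read profiling

For satellites too short or too collapsed to assemble, `scanReads()`
quantifies exact tandem runs of primitive units ≤ 20 bp directly in reads:
for every unit length, the longest lag-equality run per read is credited to
the canonical unit when it spans ≥ 3 copies and ≥ 50% of the read.
Counting only primitive units prevents a dimer from being counted again at
twice the length; canonical folding makes the profile strand-independent.
Profiles are depth-normalized to bp per Gb of sequenced bases;
`compareProfiles()` flags units with normalized abundance ≥ 10 kb/Gb and a
germ/soma ratio ≥ 5 (denominator pseudocount 1 bp/Gb).

## Probe design

FISH oligos are 30–40-mers constrained to GC ∈ [0.15, 0.65] and no
homopolymer longer than 8. Candidate windows are circular windows of the
family consensus, so probes may span the monomer junction. The **conserved
probe** minimizes the worst-case Hamming mismatch against any member
(members treated as circular tandem templates, both strands), breaking
ties by higher entropy, then position. For units shorter than 30 bp the
probe is the smallest whole-copy concatemer reaching the range — a 10 bp
unit yields a 30-mer of three exact copies. **Variant probes** maximize the
minimum mismatch against the sister variant and fail with an error when no
window reaches `probe_min_disc = 3` mismatches, matching the discrimination
of published A/B probe pairs that differ at three diagnostic positions.

# Synthetic data as ground truth

The generator is a first-class deliverable, not test scaffolding.
`syntheticSpec()` describes background contigs (i.i.d. bases at a chosen
GC) and planted families (ancestral monomer, per-copy substitution/indel
rates, optional A/B variant mixture, per-array position and copy number);
`generateGenome()` inserts arrays and returns germ and soma assemblies plus
a manifest with realized, post-mutation 0-based coordinates and bp.
`generateReads()` draws uniform-coverage reads (both strands, i.i.d.
substitution errors, FASTQ output), and `scoreRecovery()` compares a
discovery run to the truth (recovery at ≥ 0.9 consensus identity,
precision/recall, relative abundance error).

Defaults model realistic satellite landscapes: ~3–5% within-family divergence,
arrays of tens of kb, units of 10–200 bp. Known simplifications: no
background repeat structure (an optional decoy mode is a non-goal here), no
assembly collapse, flat base quality.

# Verification strategy and scaled problem sizes

The test suite checks the string primitives exhaustively against
brute-force oracles over the {A,C} alphabet up to length 14 (the full
≤30-length universe is ~2^31 strings and not enumerable) plus randomized
checks to 200 bp and rotation/strand invariance to 64 bp. End-to-end
checks run at desk scale chosen to keep the suite within minutes on one
CPU while preserving the governing ratios:

* recovery: 2 Mb assembly, 6 families (units 20–200 bp, 5% divergence,
  ≥ 25 kb each) — all recovered at ≥ 95% consensus identity, abundance
  within ±10%, within-family identity > 90%;
* restriction flagging: core/germ pairs with 3 germ-private families
  (units 10, 38, 39 bp) and 5 shared ones, 20 seeded replicates,
  precision = recall = 1 — with the abundance floor scaled from 200 kb to
  5 kb to match the ~8 kb planted arrays;
* read profiles: two short satellites planted at a 3:1 bp ratio are
  recovered within 3 standard errors at 10× coverage, a germ-only unit is
  flagged, and identical tissues yield no flags.

Every output file begins with a header naming the tool version, a hash of
the full configuration and the RNG seed; a single global RNG stream per run
makes reruns byte-identical.

# Session info

```{r}
sessionInfo()
```
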