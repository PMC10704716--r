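---
title: "Constraint-preserving alignment extension: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-preserving alignment extension: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaextend)
```

`msaextend` solves the *alignment extension* problem: given a trusted
backbone alignment `C` on sequences `S0` and a set of unaligned query
sequences `S1`, produce an alignment of `S0 ∪ S1` that, restricted to
`S0` (with all-gap columns removed), is exactly `C`.  This vignette is
the package's account of how it does that, which choices were genuinely
open, and what the synthetic tests do and do not demonstrate.

## The pipeline and its contract

The method is divide-and-conquer in four stages.

**Decomposition.** A guide tree on the backbone is split by repeatedly
deleting *centroid edges* (the edge whose removal bipartitions the
leaves most evenly) until every leaf subset has between `l` and `u`
members.  Working on clades of a tree keeps each subset composed of
closely related sequences, which is what makes small profile models and
small sub-aligner runs accurate.  Each subset `S_i` induces a
subalignment `C_i` (its rows of `C`, all-gap columns dropped; a column
map records where each `C_i` column sits in `C`).

**Routing.** One profile HMM is built per `C_i`.  A query `q` is scored
against each with the forward algorithm, giving a bitscore
`b_i = log2 P(q | HMM_i) − log2 P(q | null)`, and is assigned to the
subset maximizing the size-adjusted probability

```
p_i = s_i 2^{b_i} / Σ_j s_j 2^{b_j}
```

with `s_i` the subset's sequence count.  This is the size-adjusted
bitscore used for query routing by ensemble-HMM methods in the
UPP/WITCH family; it estimates the probability that subset `i`'s model
generated the query, under a prior proportional to subset size.  Note
the HMMs only *route* queries — they do not produce the final alignment
unless the built-in adder is used.

**Extension.** Each subproblem — `C_i` plus the batch of queries routed
to it — is extended by a sub-aligner that must leave `C_i` intact.  If a
subset attracts more queries than fit under the subproblem cap (500
sequences total by default), the queries are split into the minimal
number of batches, balanced to within one sequence, each run against the
same `C_i`.

**Transitivity merge.** Every column of an extended subalignment either
carries one backbone column of `C` (identified through the column maps)
or is an insertion column.  Columns carrying the same backbone column
are unified; insertion columns are emitted between their flanking
backbone columns.  Because each backbone sequence and each query is in
exactly one subset, no two backbone columns can be pulled together, so
the output induces `C` by construction.  `add_sequences()` still
verifies `induces(output, backbone)` at the end and fails hard rather
than return a violating alignment — the contract is checked, not
assumed.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `l`, `u` | 10, 25 | bounds (in sequences) on decomposition subsets. Small subsets keep the sub-aligner fast and its inputs closely related; the defaults are the setting found fastest at comparable accuracy when the method was calibrated on hard, high-rate data. |
| `cap` | 500 | maximum sequences (backbone subset + batch) per sub-aligner run; bounds the quadratic cost of accurate aligners. |
| `pseudocount` | 1.0 | additive smoothing for HMM emissions and transitions; keeps every probability positive and the model deterministic. |
| `backend` | `"fallback"` | `"fallback"` is the built-in Viterbi adder (no dependencies); `"external"` runs a configurable `mafft --add`-style command and re-validates its output. |
| `workers` | 1 | subproblems are independent; results are merged in subproblem order, so parallel and serial runs are identical. |

## Profile HMM construction and scoring

The architecture is the standard match/insert/delete profile: columns of
`C_i` with gap fraction below 0.5 become match states (the common
profile-construction heuristic); the remaining columns are insert
regions.  Match emissions are add-`pseudocount` smoothed column letter
frequencies; insert emissions equal the background (smoothed overall
letter frequencies of the subalignment), which is also the null model
for the bitscore.  Transitions are smoothed counts of the state paths
the gap pattern of each row implies; all nine transitions between
neighbouring M/I/D states are allowed.  Scoring is *global*: the model
generates the entire query.  Queries are routed whole, never trimmed,
so a local mode would only blur the comparison between subsets.
Letters outside the declared alphabet (ambiguity codes) are emitted at
the uniform background value in both model and null, contributing
nothing to the score, and are carried into the output unchanged.

Compatibility with HMMER model files, Dirichlet-mixture priors and
E-values are explicit non-goals; the models exist to rank subsets, and
the forward implementation is verified against exhaustive path
enumeration to `1e-9` in log space.

### Numerical choices

All dynamic programming is in natural-log space with three-way
log-sum-exp; `-Inf` entries (structurally impossible transitions such as
into a delete state at the begin node) are propagated exactly rather
than floored, and the kernels treat them as hard zeros.  Routing
probabilities use the same max-shifted accumulation in base 2.  Ties in
routing go to the smallest subset index; ties in the centroid-edge
search go to the smallest edge in a deterministic postorder; Viterbi
ties prefer match over insert over delete.  A query scoring `-Inf`
against every subset (impossible with smoothing, but guarded) is routed
uniformly with a warning so the partition property always holds.
Degenerate inputs fail early with informative errors: alignments whose
every column is gap-majority cannot produce a model; empty queries are
rejected; a sub-aligner output that does not induce its constraint is a
hard error, not a warning.

## Design choices that were genuinely open

**"Retain only subsets of size at least `l`" cannot discard
sequences.** Dropping undersized subsets would break the partition that
the output guarantee rests on.  It is realized instead as an
*eligibility* rule — the centroid search prefers edges keeping both
sides at least `l` — plus two fallbacks: a backbone smaller than `l` is
one subset, and a subset larger than `u` with no split leaving both
sides at least `l` is retained whole.  Decreasing `u` therefore never
decreases the number of subsets, and every sequence appears in exactly
one.

**Insertion placement.** The built-in adder gives each query *private*
insertion columns anchored immediately after the preceding match
column; it deliberately does not infer homology between different
queries' insertions.  That is weaker than an accurate sub-aligner (which
aligns batch queries to each other, finding homologies the backbone
lacks) but satisfies the same contract, and makes the no-dependency
pipeline fully testable.  At the merge, insertion blocks anchored
between backbone columns `j` and `j+1` are emitted right after `j`
(begin-anchored blocks before the first column), grouped by subproblem
in ascending order and left-to-right within a subproblem.  The
inter-subproblem order is a pure convention: co-anchored blocks from
different subproblems share no letters in any column, so any order
yields the same homology set.

**The subproblem cap counts backbone plus queries.** Batches are sized
so `|S_i| + |batch| ≤ cap`, keeping every sub-aligner run bounded at
`cap` sequences in total.

**Expansion on restricted alignments.** Error is scored on the
alignments restricted to the query sequences, and the expansion score
(estimated length / reference length; 1.0 optimal, > 1 under-aligned,
< 1 over-aligned) uses the same restricted lengths for consistency.
Case plays no role: everything is upper-cased on read, so there is no
lowercase site-masking convention in the scorer.

## What the simulator emulates — and what it does not

`simulate_sequences()` evolves a root sequence down a random binary
tree with exponentially distributed branch lengths (hence
non-ultrametric, like real data and unlike a molecular clock).  Sites
substitute independently and uniformly within the alphabet
(Jukes–Cantor-like); indel events arrive at rate `indel_rate` per site
per unit branch length, are insertions or deletions with equal
probability, and draw geometric lengths with mean `short_mean` — except
that with probability `promote_prob` an event is *promoted* to a long
regime with mean `long_mean`, emulating rare domain-scale gains and
losses.  Site identities are threaded through the whole process, so the
returned true alignment's homologies are exactly the residues descended
from a common ancestral site — tracked, never inferred.

Defaults (`n = 200` taxa, root length 200, `sub_rate = 1`,
`indel_rate = 0.02`, `short_mean = 2`, `promote_prob = 0.05`,
`long_mean = 15`, mean branch length 0.08) give alignments with
realistic gappiness and enough divergence to make extension non-trivial
while keeping every routing decision meaningful.

Backbone selection mirrors three practical situations:
`"large_random"` samples `min(1000, 0.25 F)` of the `F` *full-length*
sequences (ungapped length within 25% of the median), `"small_random"`
samples `min(100, 0.1 F)` with a floor of 10, and `"clade"` picks the
tree clade of at most 1000 leaves closest in size to 25% of the taxa —
the hard case where the backbone is phylogenetically biased and most
queries are only distantly related to it.

The simulator does **not** emulate rate heterogeneity across sites,
realistic substitution matrices, selection, or structure-constrained
evolution.  Passing tests on these fixtures therefore demonstrates the
*structural* guarantees (constraint preservation, letter conservation,
partition and merge correctness) and the *direction* of accuracy trends
(error grows with evolutionary rate; clade-based backbones are harder
than random ones), not absolute error levels on biological data.

## Problem sizes used by the test suite

The package's own verification batteries run at toy scale, chosen as
the smallest sizes at which every pipeline stage is exercised
non-trivially: 51 end-to-end fixtures of 50–300 taxa (root length 60)
cycling through the three backbone scenarios under the default
`l = 10, u = 25, cap = 500`; 100 random trees of 20–400 leaves for the
decomposition audit; 200 exhaustively enumerated tiny HMMs for the
forward oracle; 500 random alignment pairs for the scorer oracle; and a
10-replicate trend comparison at 60 taxa contrasting a slow regime
(`sub_rate = 0.3`, `indel_rate = 0.01`) with a fast one
(`sub_rate = 1.5`, `indel_rate = 0.05`), and a random backbone with a
clade backbone at the default rates.

## Known limitations

* The built-in adder never aligns query letters to other query letters
  in insertion regions; an accurate external backend recovers much of
  that signal (and is re-validated against the constraint on every
  run), but homologies *across* subproblems remain unmergeable by
  design — a post-merge re-alignment of insertion regions would be the
  natural next stage.
* Guide-tree quality matters: the internal k-mer BIONJ tree is plumbing,
  adequate for routing and decomposition at the package's scale, not a
  phylogenetic estimate.  Supply a maximum-likelihood tree when you
  have one.
* A backbone whose subalignment is gap-majority in every column cannot
  produce a profile model; such inputs are rejected rather than guessed
  at.
* Error metrics require the reference and estimate to agree on the raw
  sequences; they score alignments, not assemblies.
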