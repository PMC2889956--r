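---
title: "Models and methods behind mitorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
```

This vignette explains the models, conventions, and numerical choices the
package is built on, in the spirit of a methods section: what is assumed,
what is configurable, and what the tests do and do not demonstrate.

## The gene-order model

A vertebrate mitogenome is a circular molecule carrying 37 genes, the
light-strand replication origin (O~L~) and the control region (CR). We
represent it as a *signed, linearized* sequence: one element per feature,
sign `+` for the heavy strand and `-` for the light strand. All
comparisons happen after linearization at tRNA-Phe — the element the
typical vertebrate arrangement is conventionally drawn from — so two
circular genomes are compared in a common frame. `linearize()` is
idempotent at a fixed anchor, and re-anchoring is a pure rotation.
Coordinates are 1-based inclusive externally (the GenBank convention);
duplicated features are suffixed `-1`/`-2` in genome order so that orders
remain sequences over unique symbols.

Two generic order metrics are provided. `order_diff()` aligns signed
orders by longest common subsequence; LCS ties are broken in favour of
keeping the reference's 5'-most elements fixed (implemented as a
deterministic backtrack that skips observed elements first), so the
reported moved set is reproducible. `breakpoint_distance()` counts
oriented adjacencies present in one circular order but not the other;
each adjacency is read strand-symmetrically (`(a, b)` equals
`(-b, -a)`), and the linearization junction contributes an adjacency like
any other, making the distance independent of rotation.

## Arrangement characters

Five discrete characters describe the rearrangement features that vary
among iguanian mitogenomes (`arrangement_characters()`): the IQM/QIM
tRNA-cluster order, the tRNA-Pro position/strand, CR duplication between
ND5 and ND6, O~L~ presence, and the tRNA-Pro anticodon. Three choices
deserve comment.

* **C2 is unordered.** The draconine inversion and the
  agamine/chamaeleonid translocations are treated as independent
  alternatives of a three-state character, not as steps of a pathway; no
  transition is privileged by the cost matrix. This mirrors the
  comparative evidence that the two translocations arose independently.
* **One `translocated` label for two contexts.** Agamine and chamaeleonid
  translocated tRNA-Pro genes sit in somewhat different sequence
  neighbourhoods (chamaeleonid copies are flanked by the two AT-rich
  repeat classes). The character records position only; the flanking
  context is reported separately by the CR annotator, where it belongs as
  corroborating evidence rather than as part of the character state.
* **O~L~ status and the anticodon are observations, not order features.**
  `encode_characters()` takes them as arguments (`ol_status`,
  `anticodon`); `ol_status = "auto"` falls back to the presence of an
  `OL` element in the order. Unknown inputs yield `"?"`, which downstream
  parsimony treats as unconstrained.

## Parsimony machinery

Ancestral states are reconstructed by Sankoff dynamic programming on a
rooted `ape::phylo` tree. Polytomies are allowed and treated as soft
multifurcations. With the default uniform cost matrix the minimum equals
the Fitch parsimony count; the test suite verifies both against an
exhaustive enumeration oracle and against `phangorn::fitch`.

**Root handling.** `sankoff_min_changes()` leaves the root free by
default. Event *placement*, however, conditions the root on the
character's ancestral state — the typical vertebrate arrangement — which
encodes the outgroup evidence that the typical state is plesiomorphic for
the ingroup. Without this, a character that is derived in one of the two
basal clades has a mirror-image reconstruction (the change pushed onto
the other clade's stem), and the placement claim would be root-ambiguous.
`map_events(root = "free")` restores a cost-minimal root.

**Resolutions and ambiguity.** DELTRAN is the default (ties keep the
parent state, delaying changes tipward); ACCTRAN prefers a change on the
rootward edge (an edge-local preference). Both always produce an event
list whose length equals the DP minimum. `resolution = "all"` enumerates
every most-parsimonious reconstruction up to a bound (`max_mpr`, default
10,000; the exact MPR count is always computed by a product-sum DP) and
flags events not shared by all reconstructions; beyond the bound, random
resolutions are sampled under a fixed seed and the result is flagged
approximate. Ambiguity is always surfaced, never silently resolved.

**Origins and constrained costs.** `count_state_origins()` computes the
minimum and maximum number of gain edges of a derived state *across all
MPRs* by a second dynamic programme restricted to optimal choices — no
enumeration, so it is exact even on trees where the MPR set is large.
`constrained_cost()` pins named internal nodes and reports the
constrained minimum, which is how the package prices a single-origin
hypothesis against independent origins (the pinned cost strictly exceeds
the free cost when the data favour independence).

## Control-region annotation

The CR is modelled in the standard three-domain layout: Domain 1 (ETAS
motifs, often preceded by long tandem-repeat arrays), Domain 2 (the
central conserved boxes F, C, D), Domain 3 (CSBs and, in chameleons,
large AT-rich arrays around the translocated tRNA-Pro).

**Motif search.** Patterns are IUPAC-degenerate strings scanned on the
annotated heavy strand with a per-motif Hamming budget (default
`floor(length/5)`); an `N` in the sequence matches only a pattern `N`.
Overlapping hits of one motif collapse to the lowest-mismatch window,
ties 5'-most. The shipped consensus strings follow the
ETAS/Box/CSB nomenclature of the vertebrate CR literature but are
explicitly configurable (`cr_config()`, YAML/JSON via `read_cr_config()`);
all recovery tests plant their own instances, so nothing in the package's
validation depends on the biological accuracy of the defaults. CSB2 is
searchable but its absence is expected in acrodont CRs (and CSB3 in
agamids): absence is a result, never an error.

**Tandem repeats.** For each candidate period *p* the match vector
`s[i] == s[i+p]` is segmented into all maximal-scoring subsequences
(Ruzzo–Tompa) under scores `+(1 - t)` / `-t`, where `t` is
`min_identity`. Every reported segment therefore has identity above `t`
and cannot be trimmed or extended to score higher — in particular a pure
array cannot inflate its copy number by absorbing chance matches in the
flanking background, a failure mode of greedy run-merging. A vectorized
rolling-window screen skips periods that cannot contain a qualifying
region, which is what makes scanning hundreds of periods affordable.
Regions reported at a multiple of a smaller period are suppressed
(smallest period wins, 80% overlap rule). Defaults: periods 10–200,
`min_copies = 3`, `min_identity = 0.85` — a length-times-identity floor
chosen so that i.i.d. background of realistic composition essentially
never qualifies; the null rate is measured empirically in the tests, not
assumed.

**AT-rich arrays.** The two chamaeleonid classes are detected separately
from generic tandems: `(AT)n` as maximal alternating A/T runs (period-2,
unit `AT`/`TA`), and `(A^xT^y)n` as maximal chains of at least two blocks
with `x, y >= 2`. A region qualifying as both is labelled dinucleotide
(the stricter pattern wins), and generic-tandem views of an AT array are
dropped in `cr_profile()`. The floor `min_len = 20` separates the
large-scale chamaeleonid arrays from the short AT runs any AT-rich CR
contains. Each array is labelled by its position relative to an embedded
tRNA-Pro (`5prime`/`3prime`/`overlapping`/`no_trnP`), which is how the
chamaeleonid geometry — blocks 5' of tRNA-Pro, dinucleotide arrays 3' of
it, with the *Brookesia*-style exception of dinucleotide on both sides —
is expressed.

**Domains.** Domain 1 ends at the 3'-most ETAS hit and Domain 2 at the
3'-most central-box hit; whether boundaries should instead bisect spacers
is not determinable from the comparative evidence, so the 3'-most-anchor
rule is a documented convention. Missing anchors fall back to fractional
positions (defaults 1/3 and 2/3) and flag the partition low-confidence;
anchors out of canonical ETAS < Box < CSB order either error or fall back
with a flag, per configuration.

## Gene-identification heuristics

`translate_mt()` uses the vertebrate mitochondrial code (translation
table 2: AGA/AGG stop, ATA Met, TGA Trp) and accepts a trailing `T` or
`TA` as a stop completed by polyadenylation of the transcript, reporting
it as such; internal stops are validation failures, not exceptions. The
test suite checks all 64 codons and random frames against an
independently hand-written table.

`extract_anticodon()` does not fold the tRNA: it searches for the
anticodon *arm* only — a 5-bp stem (≥ 4 paired positions, Watson–Crick
plus G·U) closing a 7-nt loop whose centre lies in the middle third of
the gene, where the anticodon arm of a cloverleaf sits. The anticodon is
loop positions 3–5 of the best candidate (most pairs, ties 5'-most), with
confidence `pairs/5`. This bounded heuristic is sufficient for annotated
genes, which is all the analysis requires; sequences with no candidate
return an undetermined result rather than an error. The call is invariant
to up to ~3 nt of acceptor-end padding because the middle-third window
moves with the sequence.

`detect_ol_hairpin()` scans for a perfect contiguous stem of at least
`min_stem` pairs (default 6; G·U allowed, configurable) enclosing a loop
of 3–20 nt, reporting the longest stem, ties 5'-most. Bulged stems are
deliberately out of scope: perfect-stem presence/absence is reproducible
and directly testable against a brute-force pairing oracle, whereas a
bulge-tolerant criterion would need a free parameter the comparative data
cannot pin down. Presence is monotone in `min_stem` by construction. The
packaged fixture stores O~L~ presence/absence as reported states (the
published evidence is at the level of statements about taxa, not
deposited spacer sequences), so the fixture check is a bookkeeping check,
not a re-detection.

## The synthetic-data generator

Generators exist so that every analyzer can be tested against *planted*
truth. They emulate, under a fixed seed:

* **Arrangement evolution** — every lineage starts at the typical order;
  planted character transitions are applied on branches and propagated
  tipward. The default `single_event` regime (at most one event per
  character, uniformly placed) is the regime in which recovery must be
  exact: a single transition creates one clean derived clade, and
  `encode_characters()` + `map_events()` must return precisely the
  planted states and branch. A `per_branch` regime with independent
  per-edge events exists for denser histories.
* **Control regions** — domains assembled left to right with planted
  motif instances (concrete realizations of the IUPAC patterns), an
  optional long-unit tandem array with point noise (defaults 64 bp × 8
  copies at 2% noise), AT arrays, and an embedded tRNA-Pro placed
  200–400 bp from the 3' end, the geometry of chamaeleonid CRs.
  Background is i.i.d. nucleotide sequence at configurable GC content; no
  Markov structure. Single `G`/`C` guards separate planted AT arrays from
  the background so planted boundaries are well defined. Before emitting,
  the generator verifies against the annotator's own thresholds that the
  planted motifs are the only hits and the planted arrays the only
  AT-array calls, resampling otherwise — the manifest is therefore a
  guaranteed unique truth, which is what makes "recovery = 100%" a
  meaningful assertion rather than a lucky one.
* **tRNAs and WANCY spacers** — cloverleaf-consistent sequences with the
  anticodon planted at loop positions 3–5, and spacers with or without a
  perfect stem-loop; hairpin-free spacers are rejected-sampled until no
  stem at the guard threshold exists.

What the generator does **not** emulate: sequence evolution (no
substitution models or branch lengths), Markov-correlated background,
degraded or partially annotated genomes, and concerted evolution of
repeat arrays. Passing recovery tests therefore demonstrates correctness
of the algorithms under the stated model, not performance on raw
GenBank-grade data — on real CRs the configurable thresholds, not the
defaults, carry the burden.

## The packaged study fixture

`study_fixture()` returns hand-entered comparative data for 31 iguanian
mitogenomes: per-taxon metadata (family, accession, genome and CR
lengths, the latter absent for the four taxa whose repeat-rich CRs are
unresolved — these are excluded from family means, which is what yields
the 10/9/8 denominators), the arrangement character matrix assembled from
the published per-taxon statements, and the tree topology. The topology
encodes the family and subfamily relationships stated in prose
(iguanids sister to acrodonts; within agamids *Uromastyx*, then
*Leiolepis*, then amphibolurines, *Hydrosaurus*, and
Agaminae + Draconinae; within chamaeleonids *Brookesia* first, then
*Rieppeleon*, then the hornless *Chamaeleo* clade versus
*Kinyongia* + (*Trioceros* + (*Calumma* + *Furcifer*))); groupings not
fixed by prose are left as polytomies, and all parsimony claims are
restricted to clades that are. Feature coordinates in the fixture are
nominal (typical vertebrate gene lengths laid end to end): the order and
strands are the data, per-gene coordinates are not reproduced from the
deposited records.

Family CR means are rounded half away from zero; the three published
means (2505.9 → 2506, 1131.9 → 1132, 1695.125 → 1695) are insensitive to
the tie rule but the convention is fixed and documented.

The MCMC bookkeeping helper applies the burn-in fraction to the *sample*:
`floor(total/interval) × (1 − burnin)`. The alternative reading
(discarding generations before sampling) gives the same number here but
differs in general; the sample-discard interpretation is the one
consistent with a 25,000-tree pool reduced to 18,750.

## Problem sizes and determinism

The test and acceptance workloads are sized for a laptop-class single
core: oracle cross-checks use exhaustive enumeration on trees of up to 12
tips with the labeling grid capped at 2×10⁵ (1,000 random trees), and
recovery runs use 500 arrangement replicates on 10-tip trees, 500
synthetic CRs of roughly 1.5–2 kb, and 100 tRNAs. Every stochastic
component takes an explicit seed, restores the caller's RNG state, and
regenerates bit-identically under the same seed; reports embed the seed
and a configuration digest so a result can be traced to its inputs.

## Known limitations

* Rearrangement *mechanisms* are out of scope: the package encodes and
  maps states but does not model duplication–deletion intermediates.
* The cloverleaf heuristic can mis-localise the anticodon arm in tRNAs
  with strongly non-canonical geometry (e.g. severely truncated D- or
  T-arms) — acceptable for annotated genes, not a de novo gene finder.
* GenBank parsing covers single-segment locations only; joined or
  origin-spanning features must be pre-split.
* The synonym table ships with the anticodon-numbered convention
  (`trnL2` = Leu-UUR); annotations following the human gene-name
  convention for the serine tRNAs need a custom table.
* Likelihood-based ancestral reconstruction and tree inference are
  deliberately absent; the tree is an input.
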