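---
title: "Non-sequential structure alignment from local descriptors"
author: "ldalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-sequential structure alignment from local descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldalign)
```

## The problem

Most structure-alignment programs look for the largest set of residues
superimposable under a single rigid-body transform, in sequence order. That
paradigm fails on the "difficult similarities": proteins related by a
circular permutation or segment swap (same spatial architecture, different
chain threading), and conformer pairs whose domains have moved relative to
each other so that no single superposition exists. `ldalign` takes the
opposite route: it first finds all *local* similarities between the two
structures and only then assembles them into a global alignment, placing no
constraint on sequence order and never requiring one global superposition.

## Local descriptors

The unit of local structure is the *descriptor* of a residue: the set of
five-residue backbone *elements* centred on the residue itself and on every
residue in contact with it, with overlapping elements concatenated into
*segments*. A descriptor is a small, self-contained piece of fold —
typically a few short backbone stretches held together by the central
residue's physical interactions — and, unlike a single backbone fragment or
a secondary-structure element, it carries three-dimensional context.

Two residues are in contact when either

* their Cα distance satisfies $d_\alpha \le 6.5$ Å, or
* their side-chain geometric centers satisfy $d_C \le 8$ Å while
  $d_\alpha - d_C \ge 0.75$ Å (side chains pointing towards each other).

The side-chain center $R_C$ is the unweighted mean of the side-chain heavy
atoms; for glycine it is the Cα, for alanine the Cβ, and a residue with no
resolvable side-chain atoms falls back to its Cα (crystal structures rarely
carry hydrogens, so hydrogens are never used). Contacts close to a cutoff
are handled with a rough-set device: a contact that also satisfies
tightened thresholds (5.5 Å and 7 Å) is *certain*, otherwise *optional*.
Optional contacts may be dropped during comparison without penalty, so two
descriptors are not declared different merely because an interaction sits
on opposite sides of a threshold in the two structures.

Sequence-local pairs (separation below 3 within a connected chain stretch)
are not treated as contacts: they lie inside the central element already
and would only duplicate backbone neighbours. Pairs in different chains, or
across a chain break (chain identifier change, or consecutive Cα–Cα
distance above 4.5 Å), are always eligible.

Segment counting is deliberately not physical-segment counting. For a
segment running from residue $m$ to $n$ the smoothed spatial length is

$$L_{m..n} = \sum_{i=m}^{n-1} \lvert \bar{C}_{\alpha_i} -
\bar{C}_{\alpha_{i+1}} \rvert,\qquad
\bar{C}_{\alpha_i} = \tfrac13 (C_{\alpha_{i-1}} + C_{\alpha_i} +
C_{\alpha_{i+1}}),$$

with the raw Cα used where a smoothing neighbour does not exist (chain
terminus or break). The *perceived* count is
$N_{m..n} = \lceil L_{m..n} / 18\,\text{Å} \rceil$ (at least 1), so a long
hairpin counts as two logical segments connected by a short loop. This is
what makes "three-segmented" a meaningful marker of fold-specific local
structure: three strands of a sheet, or a helix packed against two
neighbours, reach three perceived segments, while a lone helix never does.

## Comparing two descriptors

A valid alignment of two descriptors must satisfy six conditions: the
central residues and their elements are aligned exactly, centre to centre;
elements map to elements one-to-one, preserving the central contacts;
element-vs-element Cα RMSD is at most 1.5 Å; each element pair superposed
*jointly with the central elements* has RMSD at most 2.5 Å (same position
relative to the centre); at least half of each descriptor's perceived
segments are aligned, where unaligned contacts that are only optional are
disregarded before counting; and the total Cα RMSD of all aligned residues
in one joint superposition is at most 2.5 Å.

The search enumerates all element pairs passing the local tests, builds all
maximal mutually consistent sets of them (maximal cliques of a small
compatibility graph), and, when a set violates the total-RMSD bound,
removes element pairs until it fits or the segment-count condition fails.
For sets of up to eight element pairs the reduction is exact over all
subsets, which both matches brute-force enumeration on small descriptors
and is cheap; above that, the pair whose removal most decreases the joint
RMSD is dropped greedily, recomputing each round. No sequence-order
constraint appears anywhere, so a segment of one structure may align to two
shorter segments of the other, and segment order may differ freely.

Two numerical interpretations deserve note. First, "half of the segments"
is evaluated on perceived counts, consistent with the counting scheme's
purpose. Second, a joint superposition distributes discrepancy between both
point sets: displacing one element by 3 Å from its proper relative position
yields a joint RMSD near 1.5 Å, which still passes; rejection by the
relative-position condition begins near 5 Å of displacement. The regime in
which the condition bites is exactly the one that matters: elements on the
wrong side of, or rotated about, the central element.

## Assembling a structure alignment

Descriptor alignments with at least three perceived segments on both sides
form the set $S_3$ of building blocks; all others form $S_1$ and are used
only as extension material. Blocks are *consistent* when their residue-pair
sets agree wherever they overlap — the union is still a partial bijection.
On the graph whose nodes are $S_3$ blocks and whose edges are consistency,
any clique is a conflict-free alignment, and because the monotone part of
the score (aligned-residue count) never decreases as a clique grows, the
best alignments are found among the maximal cliques. No geometric check is
made across blocks: geometry is enforced inside descriptors and, globally,
through the tension term of the score.

The exact *tree search* (TS) walks the include/exclude decision tree with
two cuts: a branch headed by a clique that a previously rejected node could
join unconditionally is abandoned (each maximal clique is generated exactly
once, in another branch), and once enough alignments are known, a branch is
abandoned when current coverage plus the residues coverable by remaining
candidates cannot beat the `n_best`-th best. The bound uses the raw
aligned-residue count because the bound must be monotone under clique
growth; the full score is applied when ranking the results. The
*constrained* variant (CTS) additionally admits a node only if it shares a
residue with the alignment accumulated so far, yielding one structurally
continuous fragment; it restarts from each of the 32 highest-coverage
nodes and de-duplicates. The third stage always uses the constrained rule:
each retained clique is extended greedily with $S_1$ blocks that are
consistent and residue-overlapping, in order of novel residues contributed
(ties by RMSD). Up to five alignments are reported, each sharing at most
half of the smaller pair set with any higher-ranked one.

When the exact search exceeds its time budget (default 120 s — typically
on highly self-similar structures where the graph explodes), a
replica-exchange Monte Carlo sampler takes over. Its move generator picks a
random node $d$ outside the current clique, keeps the members adjacent to
$d$, and then adds every node belonging to all maximal cliques containing
the result (every common neighbour adjacent to all other common
neighbours; this closure is skipped beyond 64 common neighbours). The
energy is the negative aligned-residue count — the same monotone quantity
the exact search bounds; the tension-penalised score would not be monotone
under clique growth, which is the property the whole clique formulation
rests on — and the full score again ranks the final candidates. Defaults:
8 replicas on a geometric temperature ladder whose ends accept a
one-residue coverage drop with probability about 0.1 and 0.9
($T_{\min} = 1/\ln 10 \approx 0.43$, $T_{\max} = 1/\ln(10/9) \approx
9.5$), a state-exchange attempt between neighbouring temperatures every
100 sweeps, and 20 000 total moves. At the graph sizes this package
targets (tens to a few hundred nodes) the sampler reaches the exact
optimum within a few hundred sweeps; the move count is a parameter for
larger problems.

## Scoring

Every aligned pair already sits inside at least one pair of similar
descriptors, so local quality needs no further checking. Global quality is
measured as elastic strain: enumerate all aligned residue pairs in contact
in at least one structure; for each such contact compute the Cα RMSD of
the two five-residue elements around the contacting residues, jointly
superposed onto their counterparts; average per residue over its contacts,
then over all aligned residues (residues with no such contact contribute
zero). This *tension* $\tau$ enters the score as

$$\text{score} = N_{\text{aligned}} - \tau^2 .$$

Two controls restore sequence dependence when wanted. A finite offset
limit $k$ drops pairs whose offset from a direct 1:1 chain correspondence
exceeds $k$; with unequal chain lengths the offset is measured either
against the closest ungapped placement of the shorter chain (default) or
allowing gaps only in the shorter chain. A finite swap budget $M$ first
restricts the alignment to its largest sub-alignment with at most $M$
swaps, where swaps are counted as descents in the second structure's order
of the co-linear blocks (a circular permutation costs exactly one). The
sub-alignment is found by exact dynamic programming over block
subsequences up to 64 blocks, greedily beyond. Alignments need not be
rigidly superposable as a whole: the connected components of the
residue-overlap graph over the clique members are reported as *rigid
regions*, each with its own optimal superposition, and each necessarily
contains a three-segment block because stages two and three are separated.

## Synthetic structures and what the tests show

The package generates its own protein-like test structures: ideal α-helices
(2.3 Å radius, 1.5 Å rise, 100° per residue), pleated strands and hairpins
with exact 3.8 Å Cα spacing, helix bundles at 9.5 Å axial spacing
(close enough that inter-helix contacts produce three-segment
descriptors), two three-stranded sheets face to face, two-domain
constructs joined by a linker, and self-avoiding random walks as a
negative control. Backbone N, C, O and Cβ atoms are placed by simple local
geometry — Cβ pointing away from the local backbone, which gives helices
outward side chains and strands alternating ones — and every ninth residue
is glycine so both side-chain-center rules are exercised. Fixtures are
written as standard PDB ATOM records and re-read through the package's own
parser, so every test exercises the real input path. Transformed twins
carry exact ground truth: rigid rotations, circular permutations (the
junction where the old termini meet becomes a chain break, as in real
permutants), hinge rotations, and coordinate noise.

One generator choice needs explanation. A hinge modelled as a pure
rotation about a pivot *on the chain* leaves every five-residue window on
one side of the pivot congruent with its original, so small extension
blocks along the linker still match and stitch the two halves into one
rigid region — locally, nothing happened. Real hinge conformer pairs
differ precisely in the hinge residues' local conformation, so the hinge
transform also rebuilds the backbone within three residues of the pivot
(preserving spacing and connectivity). With that, the aligner reports two
rigid regions with sub-half-Ångström internal RMSD while the single rigid
superposition of all aligned pairs exceeds 2 Å.

These fixtures emulate geometry, not biology: side chains are single
pseudo-atoms, loops are arcs, packing is ideal, and coordinate error is
either absent or isotropic Gaussian. Passing tests therefore demonstrate
the combinatorial and geometric machinery — contact bookkeeping, the six
comparison conditions, exactness of the clique search against enumeration,
permutation and hinge recovery with known ground truth — not performance
on experimental structures, which additionally face distorted secondary
structure, missing atoms and genuinely ambiguous similarities.

Problem sizes are deliberately desk-scale: fixtures of 40–100 residues and
oracle comparisons on alignment graphs of up to 15 nodes, where exhaustive
enumeration is still exact; the search code paths are identical at larger
sizes.

## Numerical choices and degenerate inputs

Internally residues are addressed by 1-based position in file order;
author chain, residue number and insertion code are carried along and are
the only identifiers ever written to output. Alternate locations keep the
highest-occupancy copy (first on ties). Perceived counts guard the
ceiling with a 10⁻⁹ rounding tolerance so that $L = 18$ Å counts as one
segment regardless of floating-point representation. Clipped terminal
elements (3–4 residues) align over the overlap of their spans, requiring
at least 3 common positions. Superpositions use proper rotations only
(Kabsch with determinant correction); a single-point superposition has
RMSD 0. Ties among equal-coverage alignments are broken by RMSD and then
lexicographically on the pair sets, making every output deterministic for
a given seed — the Monte Carlo sampler is the only stochastic component
and runs on a private, seeded RNG stream that never disturbs the caller's.
Structures with no multi-segment descriptor similarity (single helices,
random coils) correctly align to nothing: an empty result is the honest
answer, not a failure.

## Limitations

The aligner reads PDB-format coordinate files only (no mmCIF) and takes
the file as given — no biological-unit reconstruction from crystal
symmetry. Thresholds (6.5/8/0.75 Å contacts, 1.5/2.5 Å RMSD bounds, 18 Å
logical-segment length) are the method's definition, not tunable knobs,
and are fixed. All-against-all descriptor comparison is quadratic in
residue count and R-hosted; aligning typical domain pairs takes seconds to
minutes on one core, but database-scale scans are out of scope.
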