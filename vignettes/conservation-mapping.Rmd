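---
title: "Mapping hierarchical sequence conservation in tandem repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping hierarchical sequence conservation in tandem repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemmap)
```

## The problem

Large modular proteins such as titin carry long tandems of small domains
(immunoglobulin and fibronectin type III folds, ~100 residues each) organized
into super-repeats — repeats of multi-domain units. In titin's A-band, the
D-zone is built from six `-AC-ABC` units and the C-zone from eleven
`-AC-ABC-ABC` units (letters denote FnIII sequence types, `-` an Ig domain).
Conservation in such a system is layered: some residues are conserved across
*all* domains (the fold signature), some across all members of one sequence
*type*, and some only at one *position within the super-repeat* — the layer
most likely to carry binding sites for partners that dock with the
super-repeat periodicity of the thick filament, such as myosin-binding
protein C. `tandemmap` implements the full chain of analysis that separates
these layers.

## Pairwise-similarity mapping

Sequences are compared pairwise (BLOSUM62; either by global
Needleman–Wunsch alignment with affine gaps 11/1, or "as-is" across the rows
of a fixed multiple sequence alignment, summing scores over doubly occupied
columns). Raw scores are normalized by the geometric mean of the self-scores,

$$cc_{ij} = \frac{raw_{ij}}{\sqrt{raw_{ii}\, raw_{jj}}} \in [-1, 1],$$

and each sequence is represented by a vector $x_i \in \mathbb{R}^d$
minimizing the off-diagonal Gram residual

$$\sum_{i<j} (x_i \cdot x_j - cc_{ij})^2 .$$

The diagonal is excluded because self-similarity carries no relational
information. Dimensions are hierarchically ordered (like principal
components): D1 absorbs the dominant shared signal, D2 and D3 the finer
systematic differences, which is where type structure resolves. The **vector
angle** in the (D2, D3) plane encodes *which* systematic features a sequence
carries; the **vector length** from the origin (over all dimensions) encodes
*how strongly* — long vectors are prototypical members of their group, short
vectors are diversified sequences.

Numerical choices:

* the solver initializes from the top-$d$ positive eigenpairs of $cc$ and
  refines by L-BFGS with the analytic gradient ($2 E X$ with $E$ the
  off-diagonal misfit). Plain iterated eigendecomposition converges far too
  slowly on heavily perturbed similarity matrices (thousands of iterations on
  the derivative alignments below), while the quasi-Newton step reaches a
  stationary point in a few hundred evaluations; default cap 2000
  iterations, error on non-convergence.
* the solution is unique only up to an orthogonal transform. We canonicalize
  by rotating to principal axes (reported eigenvalues are the captured
  variance per axis, non-increasing) and flipping signs so each column sums
  non-negative (first sequence non-negative on ties). Maps are therefore
  bit-for-bit reproducible; published maps from other implementations may be
  mirrored relative to ours, which affects no dot product or RMSD.
* clusters are called by k-medoids on the circular angle distance in
  (D2, D3), $k$ chosen by the silhouette over $k = 2..6$. Points shorter than
  5% of the longest in-plane vector have unreliable angles and stay
  unlabeled. The cluster call is deliberately config-overridable: it
  operationalizes what is, in the original map-inspection practice, a visual
  judgement of angular spread.

## Sum-of-pairs conservation and the differential consensus

Per-column conservation is the unweighted AL2CO-style sum-of-pairs score:
unordered pairs of distinct sequences drawn without replacement from the
non-gap entries of a column,

$$\mathrm{SoP} = \Big[\textstyle\sum_a \binom{n_a}{2} B(a,a) +
\sum_{a<b} n_a n_b B(a,b)\Big] \Big/ \binom{m}{2},$$

with $B$ = BLOSUM62 and $m$ the non-gap count. Columns with $\ge 50\%$ gaps
are zeroed outright (under-occupied columns otherwise score spuriously
high). Gap entries never form pairs; nonstandard residues map to `X`, which
scores 0 against everything, so they neither reward nor penalize.

Which SoP level actually *matters* to the map is decided empirically by the
differential procedure: columns are ranked by SoP (ties broken by ascending
index so the series is deterministic), removed cumulatively (replaced by
gaps), and each derivative alignment re-embedded in as-is mode. The
perturbation is measured as the RMSD between the derivative map and the map
of the unedited alignment after optimal *orthogonal* superposition —
reflections allowed, since axis signs are arbitrary; no translation or
scaling, since embeddings are origin-anchored. Both maps are computed in
as-is mode so that no scoring-mode artifact enters the comparison. With $i$
the number of removed positions:

$$\Delta RMSD(i) = RMSD(i) - RMSD(i-1), \qquad
w(i) = \frac{i_{max} - i}{i_{max}}, \qquad
adjusted(i) = \sum_{n \le i} w(n)\, \Delta RMSD(n).$$

The weight corrects for the shrinking pool of residual columns. $i_{max}$
covers the columns with positive SoP; the pipeline additionally caps the
removal order at 80% of the alignment so the derivative maps stay defined
(a fully masked row has no self-score). The same removals are repeated with
randomly drawn columns (three replicates averaged) — the *sham* baseline.
The conservation consensus is the largest prefix of the ranked removal order
over which each increment of the true adjusted curve exceeds the sham
increment (tolerance $\delta = 0$ by default: any positive differential
counts); the SoP of the last column in that prefix becomes the cutoff, and
all columns scoring strictly above it form the consensus.

The per-step grid may be coarsened (`i_step`); the pipeline default of 3
aggregates removals into 3-column steps, which damps the Monte-Carlo noise
of the 3-replicate sham average that otherwise terminates the prefix
prematurely on single noisy steps. `removal_curve()` itself defaults to the
full step-1 series.

## Hierarchical tiers and linkers

The global consensus columns are masked (as gaps), each type's
sub-alignment is rescored, and columns with SoP > 1 form the type tier — 1
being the smallest positive BLOSUM62 entry, i.e. the weakest conservation
among similar residues, a deliberately conservative bar for the smaller
sequence sets. Then, per tandem-position token over C-zone super-repeats
C2–C11 only (the functionally homogeneous span), the remaining columns are
tested against three simultaneous criteria: SoP ≥ 1, occupancy ≥ 90%, and
identity ≥ 70%, where identity is the best fraction of non-gap entries
matching a single residue or one of the groups (TIL), (DEN), (FY). Identity
is computed over non-gap entries only — gap-inclusive identity would
penalize occupancy twice. The pipeline masks the union of all type tiers
before position scoring so the three tier levels are provably disjoint (a
column may still legitimately appear for two different types within the
type level). Conserved positions are reported with consensus residues and a
compact motif string (`[D/E]` for alternatives, `x` for unconstrained).

Interdomain linkers are classified from the annotation into the three motif
classes observed between FnIII domains — zero-length (direct abutment),
`[N/Y]PF` and `DPI` — with anything else (including degenerate derivatives)
reported as `other`. The extended-chain estimate multiplies linker length by
a per-residue rise of 0.34 nm (β-strand-like, overridable): a three-residue
linker spans ~1 nm, and the ten C-zone copies of a deleted linker ~10 nm of
chain length.

## Structure-side utilities

Cα superposition uses the closed-form Kabsch solution (SVD with determinant
correction; reflections disallowed for chiral molecules — note the contrast
with map superposition above, where reflections are *required*).
NCS-copy comparison superposes each domain span of two copies independently
and reports per-domain RMSDs, skipping unmatched residues with a warning
(more than 10% unmatched is an error). Conservation scores can be written
into the B-factor column of a PDB file for surface inspection in any
viewer; deciding surface vs buried status is explicitly out of scope.
Backbone φ/ψ dihedrals are computed from first principles and cross-checked
against bio3d in the test suite; terminal residues carry `NA` for the
undefined angle.

## The synthetic generator

Every stage is testable offline against
`generate_family(synth_config(...))`, which emulates the study system's
structure: 118 FnIII domains of 95 residues (6 D-zone + 11 C-zone units), a
shared master consensus, and three disjoint planted tiers — 12 global
columns (fold-signature-flavoured residues: P, W, Y, N, G, ...), 4 columns
per type, 2 columns per tandem-position token. Non-planted columns mutate
from the master consensus at a background rate of 0.55 per column,
multiplied by a symmetric V-shaped gradient over repeat index (0.5 at the
zone centre, 1.5 at the termini) so central repeats are closest to
consensus; planted columns violate their motif at rate 0.03. Replacement
residues are drawn from the BLOSUM62 background frequencies, keeping scores
in a realistic range. The background rate was chosen so that unconstrained
positions retain the ~30–50% pairwise identity typical of intra-family
domain homologs; it also keeps the SoP spectrum realistic, with both
positive and non-positive background columns, so the removal pool does not
degenerate.

What the generator does *not* emulate: indels (families are emitted
pre-aligned — the differential machinery operates on a fixed alignment, so
alignment uncertainty is orthogonal to what these tests probe),
phylogenetic correlation between domains (mutations are independent given
the planted tiers, whereas real repeats share duplication history), and
composition biases beyond the BLOSUM62 marginals. Passing tests therefore
demonstrate that each stage recovers planted structure under realistic
divergence and noise — not that real alignments are free of alignment- or
phylogeny-driven artifacts.

## Problem sizes and defaults

The test suite and the acceptance script work at the study scale (118 × 95
families). Clustering recovery is measured over 20 seeds (adjusted Rand
index vs planted types), the differential consensus over 20 seeds
(precision/recall vs planted global columns, grid step 3), and the
conservation gradient over 6 seeds per three types; the informative
dimensionality uses a 10-dimension embedding and counts eigenvalues above
1.5× the median of the spectrum, whose flat bulk sits at the unit diagonal
scale of the normalized similarity matrix.

## Known limitations

* The consensus prefix rule stops at the first non-positive differential
  step; with a noisy sham baseline and a step-1 grid this can truncate the
  prefix early. Coarsening the grid (default) or raising `sham_reps`
  stabilizes it.
* The SoP cutoff is the score of the last column *inside* the prefix and the
  consensus takes columns strictly above it, so a column tied with the
  cutoff is excluded by construction.
* `pairwiseAlignment` conventions: our affine gap cost is
  `gap_open + (L-1) * gap_extend`; implementations differ in whether the
  first gap position charges the extension, and scores are only comparable
  under the same convention (the test suite pins ours against exhaustive
  enumeration).
* Cluster count selection by silhouette assumes angularly separated groups;
  sets with a continuous angular spread will still be partitioned.
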