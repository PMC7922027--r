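---
title: "Methods: structure-based phylogenetics from common cores"
author: "corephylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based phylogenetics from common cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Homologous proteins can keep a recognizable three-dimensional scaffold
long after their sequences have diverged beyond alignability. Viral
RNA-dependent RNA polymerases are the canonical case: the right-hand
fold with its palm catalytic site persists across positive-strand,
negative-strand and double-stranded RNA viruses, some of which carry a
circular permutation of the catalytic sequence motifs, while multiple
sequence alignment of the same proteins fails outright. In that regime
phylogenetic signal must be read from structure. `corephylo`
implements a complete pipeline for doing so: identify the residues
structurally equivalent in *every* member of a structure set (the
common structural core), score pairs of structures on exactly those
residues, convert scores to distances, fit a least-squares tree, and
quantify the stability of both core and tree by structure-level
jackknifing.

# Pairwise alignment model

Structures are reduced to their Cα traces. This is a deliberate
modelling choice, not a shortcut: every downstream quantity
(superposition, rmsd, core geometry) is defined on Cα coordinates, and
a Cα-only representation keeps low-resolution structures usable on the
same footing as atomic ones. Full-backbone support is out of scope.

A correspondence between structures A and B is a one-to-one partial
matching of residues together with one rigid transform. Given a
transform, each candidate residue pair (i, j) with post-superposition
distance $d_{ij} \le d_{\max}$ receives the similarity

$$ s_{ij} = w_g\, e^{-d_{ij}^2 / 2\sigma^2}
          + w_s\, \mathbf{1}[\mathrm{ss}_i = \mathrm{ss}_j]
          + w_a\, \mathbf{1}[\mathrm{class}_i = \mathrm{class}_j], $$

and the alignment score is $S(A,B) = \sum s_{ij}$ over matched pairs.
The three terms weigh geometry, secondary-structure state (H/E/C,
assigned from Cα pseudo-distances) and a five-class physicochemical
partition of the amino acids (hydrophobic AVLIMFWC, polar STNQYG,
positive KRH, negative DE, special P; X never matches). Defaults:
$\sigma = 2$ Å, $(w_g, w_s, w_a) = (0.6, 0.25, 0.15)$,
$d_{\max} = 5$ Å. The ordering geometry > secondary structure > residue
character encodes the view that at extreme divergence geometry carries
most of the signal; all weights are exposed in `align_params()`. With
weights summing to one, a self-alignment scores exactly $|A|$ — the
anchor that later makes distances vanish between identical structures.

Residue *order* appears nowhere in the score. The assignment step is an
optimal linear assignment (a sparse Hungarian solver on the candidate
similarity matrix, with deterministic lexicographic tie-breaks), not a
greedy or order-constrained chaining, so a circular permutation of one
input changes nothing but bookkeeping. This is what lets permuted
palm-domain polymerases align correctly with their unpermuted
relatives.

Optimization is seed-and-refine: all contiguous fragment pairs of
length 15 are Kabsch-superposed, the 20 lowest-rmsd transforms
(deduplicated at 5° of rotation) become seeds, and each seed is refined
by iterating {optimal assignment, similarity-weighted re-superposition}
until the score improves by less than $10^{-4}\,\min(|A|,|B|)$ or 50
iterations. The best correspondence over all seeds wins. Each
unordered pair is computed once, in a canonical orientation (inputs
sorted by id), making the score exactly symmetric. If no candidate pair
survives the distance cutoff under any seed, the result is a defined
empty correspondence with score 0 rather than an error.

# Common core by progressive aggregation

Leaves of the guide clustering are the input structures; repeatedly,
the two live groups with the highest alignment score between their
*consensus pseudo-structures* are merged. A consensus pseudo-structure
has one pseudo-residue per column at the mean of the member coordinates
in the node frame (majority amino acid and secondary-structure state,
ties mapping to X and C). The merged node's columns are exactly the
matched column pairs of the merging alignment, so column counts can
only shrink toward the root: every internal node holds the subcore of
its member set, and the root holds the common structural core. The
procedure is strictly progressive — earlier merges are never revisited —
which is the simplest faithful reading of pairwise aggregation into
subcores and a final core; an iterative refinement pass is a non-goal.

Group-to-group alignment via consensus models (rather than averaging
all cross-group pairs) keeps the number of alignments at $O(n^2)$ and
makes each merge a single well-defined alignment. Merge-order ties are
broken lexicographically on member identifiers, so the clustering is
deterministic and invariant to input order; alignment canonicalization
makes it invariant to rigid motions of any input.

The core's `avg_rmsd` superposes each structure's core residues
*separately* onto the consensus coordinates and averages the per-
structure rmsds (unweighted). This mirrors how per-structure fit to a
common core is reported for real polymerase datasets, and it is why the
value should not be read as a direct pairwise-similarity rmsd.

# Distances and the Fitch–Margoliash tree

Pairwise scores are recomputed on the core columns only: the two
structures' column-paired core residues are Kabsch-superposed and the
same three-term similarity is summed. Self-scores equal the core size
exactly, so the conversion

$$ D(A,B) = -(S(A,B) - \min[S(A,A), S(B,B)]) $$

is a non-negative dissimilarity that vanishes exactly for structurally
identical inputs. There is no standard mapping from structural
alignment scores to evolutionary distances; this score-deficit form is
the one the pipeline is built around, and its monotone tracking of true
divergence is verified on synthetic families rather than assumed.

The tree minimizes the classic weighted least-squares criterion
$\sum_{i<j} (d_{ij} - p_{ij})^2 / d_{ij}^2$ (weights $1/d^2$). For up
to 8 leaves every unrooted topology is evaluated (10,395 shapes at
n = 8; the per-shape path-incidence matrices are cached per leaf
count), which makes the fit oracle-grade on test sizes; beyond that a
neighbor-joining start is improved by nearest-neighbor-interchange
hill climbing, which by construction never ends worse than its start.
Branch lengths are weighted least-squares solutions; negative solutions
are clamped to zero and flagged. Zero distances (identical structures)
would give infinite weight, so they are assigned the weight of the
smallest positive distance — duplicates stay adjacent with near-zero
branches instead of breaking the fit. Rooting places the root at the
midpoint of the outgroup's terminal edge and changes no ingroup
bipartition.

# Jackknife, Robinson–Foulds and consensus

Each jackknife replicate removes one structure (drawn without
replacement until the set is exhausted, then with replacement;
deterministic in the seed) and reruns the whole pipeline — core
extraction included, so the replicate core sizes measure how much any
single structure shapes the core. The outgroup is never removed, since
it anchors rooting. Replicate trees are compared to the full-data tree
pruned of the removed structure by Robinson–Foulds distance (symmetric
difference of non-trivial bipartitions). Internal edges of numerically
zero length are collapsed before comparison: a resolution that the
distances do not support is not a topological disagreement.

The majority-rule consensus is taken over the *union* of the replicate
leaf sets. Replicate trees each lack a different structure, so an
intersection-based consensus would degenerate as replicates accumulate,
while the natural summary — and the one a reader expects next to a
full-data tree — carries all structures. A tree supports a candidate
clade when the clade restricted to the tree's leaves is one of the
tree's clades (or becomes trivial); candidate clades observed in a
tree are also extended by that tree's missing leaves so that full-set
clades are reachable. Clades above the support threshold are screened
greedily for compatibility in decreasing support. With equal leaf sets
all of this reduces exactly to the textbook majority rule (verified
against an independent consensus implementation in the tests).

# Conservation scan

A core column is reported as conserved for amino acid *a* when every
structure has *a* at the equivalent residue or within ±1 sequence
position of it (window configurable; window 0 is strict identity). The
window is a *sequence* notion — immediate chain neighbors — not a
spatial one. All qualifying amino acids per column are reported, with
the smallest-magnitude offset recorded per structure (preferring 0,
then −1, then +1). This is how catalytic residues are recovered when
structural equivalence lands a position away in distant folds.

# The synthetic test bed

`make_ancestor_fold()` builds a compact fold from parametric helices
(rise 1.5 Å/residue, 100°/residue, radius 2.3 Å) and extended strands
(3.8 Å spacing) packed on a jittered grid and joined by self-avoiding
random-walk loops (clash floor 3.5 Å); the default 5 helices + 3
strands give ~150 residues. `evolve_along_tree()` then simulates, per
branch of a given tree: independent Gaussian Cα displacement with
per-coordinate standard deviation $\sigma_c \sqrt{\ell}$ (branch length
$\ell$), Poisson substitutions, Poisson loop indels and optional
circular permutation at a loop cut. Inserted loops bulge outward from
the chain (6 Å amplitude), because an inserted loop must occupy new
space — and because the ground truth of core recovery is only
well-defined if inserted residues are not allowed to impersonate
deleted ones. Indels are restricted to loops so that designed elements
persist, mirroring how real cores concentrate in conserved secondary
structure. Every leaf gets a random rigid motion, so nothing downstream
can rely on a shared frame, and coordinates are rounded to 0.001 Å so
PDB and mmCIF round trips are exact.

Default calibration: $\sigma_c = 1.0$ Å, 0.3 substitutions/residue,
0.2 indels per unit branch length, geometric mean indel length 3, and
random trees with branch lengths uniform in [0.1, 0.4] — chosen once as
a plausible "clearly diverged but alignable" family: leaf-leaf core
rmsds come out around 1–2 Å below the 5 Å match cutoff.

What the generator does *not* emulate matters for interpreting green
tests: displacement is independent per residue, whereas real divergence
moves secondary-structure elements rigidly and remodels loops;
secondary-structure states are inherited (the designed truth), not
re-derived from the noisy coordinates; there are no insertions into
elements, no hinge motions, no crystallographic disorder, and leaves of
one family are all equally "resolved". Passing tests therefore
demonstrate the correctness and self-consistency of the algorithms
under a controlled divergence model — not that any particular real
dataset will yield a core of a given size.

# Numerical choices and degenerate inputs

* Kabsch superposition rejects fewer than 3 points and collinear
  configurations (no unique rotation); reflections are excluded by the
  determinant correction.
* Assignment ties are broken toward lexicographically smaller
  (row, column) pairs via an epsilon far below score resolution, making
  every alignment deterministic.
* Secondary-structure thresholds (helix: d(i,i+2) ∈ [4.8, 6.2] Å and
  d(i,i+3) ∈ [4.3, 6.0] Å; strand: d(i,i+2) ∈ [6.3, 8.2] Å and
  d(i,i+3) ≥ 8.5 Å) bracket the ideal-geometry values; consecutive-Cα
  gaps above 4.5 Å split assignment windows (chain breaks). Termini
  and everything unclassified default to coil.
* Structures read from files keep the first model and first alternate
  location; hetero residues are dropped; protein residues without a Cα
  are skipped and counted. Unresolved residues are simply absent and
  can never become core members.
* Merge alignments with an empty matching abort with the two group
  memberships named — the dataset is too divergent for a common core,
  and silently returning an empty core would poison everything
  downstream.

# Problem sizes used in the checks

The shipped tests and the acceptance script run on families of 4–8
leaves of ~150-residue folds, 10–20 replicate seeds per property, 20
jackknife replicates, and 50-matrix batches for the superposition and
least-squares oracles. These sizes were chosen as the smallest at which
each property is meaningfully exercised (e.g. 8 leaves puts the tree
search at the edge of the exhaustive regime) while keeping a full run
on one CPU in minutes.

# Known limitations

* Strictly progressive core construction: an early suboptimal merge is
  never repaired, and subcores are not re-optimized after the final
  merge.
* One rigid transform per pair: hinged or flexible alignment is out of
  scope, consistent with a single common-core geometry.
* The similarity's functional form and weights are a specified,
  configurable choice; no claim is made that they are optimal for any
  particular protein family.
* Majority consensus over very heterogeneous leaf sets (far beyond the
  one-removed jackknife pattern) can leave candidate clades unobserved;
  extensions are only generated for up to three missing leaves per
  tree.
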