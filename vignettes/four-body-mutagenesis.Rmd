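---
title: "Four-body potentials and structure-based computational mutagenesis"
author: "TessMut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-body potentials and structure-based computational mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TessMut)
```

# The model

TessMut implements a residue-level, structure-based pipeline for scoring
single amino-acid substitutions and for training models that predict their
functional consequences. A protein is coarse-grained to its C-alpha trace,
and the 3D point set is Delaunay-tessellated: partitioned into
space-filling, non-overlapping tetrahedra whose circumspheres contain no
other C-alpha point. Each tetrahedron objectively defines a quadruplet of
nearest-neighbor residues. Tetrahedra containing any edge longer than 12 Å
are discarded before scoring, removing sliver contacts between residues
too far apart to interact.

## The four-body potential

Over the 20-letter alphabet there are $20^4 = 160{,}000$ ordered residue
4-words, but a tetrahedron's vertices are unordered, so each quadruplet is
represented once by its letters in ascending alphabetical order — 8,855
distinct keys. Given a training set of tessellated structures, each
quadruplet $(i,j,k,l)$ receives an observed relative frequency $f_{ijkl}$
(one count per retained tetrahedron) and a multinomial chance rate

$$p_{ijkl} = \frac{4!}{\prod_n t_n!} \prod_n a_n^{t_n},$$

where $a_n$ is the proportion of residue type $n$ pooled over the training
structures and $t_n$ its multiplicity in the quadruplet. The inverted
Boltzmann score is

$$s_{ijkl} = -\log\left(f_{ijkl} / p_{ijkl}\right),$$

so quadruplets observed more often than chance score negative
(favourable) and rare ones positive. The collection of 8,855 scores is the
four-body potential. Note a consequence of this sign convention used
consistently throughout the package: well-packed native environments
accumulate negative residue environment scores, and structurally
disruptive substitutions carry *positive* residual scores. Analyses that
adopt the opposite (log-likelihood) convention show the same relations
with every sign mirrored; the $-\log$ form is what `derivePotential()`
computes, and all downstream algebra is convention-agnostic.

Two configuration points are deliberately explicit because the method
leaves them open:

* **Log base** (`logBase`, default natural log). Scores loaded from an
  external table with `readPotential()` are taken as-is, where the base
  question does not arise.
* **Unobserved quadruplets** (`pseudocount`, default 0). With pseudocount
  0, never-observed keys are explicitly *unscored* (`NA`); scoring a
  structure that contains one is an error naming the quadruplet, never a
  silent zero energy. A positive pseudocount Laplace-smooths the counts
  and scores every key whose letters occur in the training composition.
  Letters entirely absent from the training set have $p = 0$ and remain
  unscorable under any pseudocount.

## Scoring structures and variants

* **Total potential**: sum of $s$ over all retained tetrahedra.
* **Residue environment score (RES)**: per position, the sum of scores of
  the tetrahedra sharing its C-alpha vertex; the RES vector is the 3D-1D
  potential profile. Each tetrahedron contributes at four vertices, so
  $\sum \mathrm{RES} = 4 \times$ total potential — an identity the tests
  assert exactly.
* **Residual profile**: a substitution relabels the residue at the target
  position — at *every* chain copy of that label in a multimer, matching
  how a mutation appears in a homodimer — without moving any coordinate.
  Only tetrahedra incident to mutated sites change score; the per-position
  differences (mutant − native RES) are the environmental perturbation
  (EP) scores, and the change in total potential is the scalar residual
  score. $\sum \mathrm{EP} = 4 \times$ residual score always, EP support
  is confined to the mutated sites and their tessellation neighbors, and
  in a single-chain tessellation the EP at the mutated position *equals*
  the residual score. Incremental rescoring is the implementation
  contract; an exhaustive full-rescore is retained as the test oracle.
* **Comprehensive mutational profile (CMP)**: per position, the mean
  residual score over all 19 substitutions, with conservative (C) and
  non-conservative (NC) submeans. The physicochemical clusters are
  (A,S,T,G,P), (D,E,N,Q), (R,K,H), (F,Y,W), (V,L,I,M) and (C); cysteine
  is a singleton, so substitutions involving it are always NC. CMP and
  RES are strongly inversely related by construction: the residual of
  replacing the native at position $P$ decomposes as (mutant environment
  sum) − RES($P$), so CMP($P$) carries a slope-(−1) dependence on RES($P$)
  plus replacement-averaged noise. For multimers CMP is computed per flat
  position (mutating that site alone) and can be aggregated per residue
  label for reporting.

## Geometry definitions

The method names two per-tetrahedron descriptors and a three-way depth
class without fixing their formulas, so the package documents its own
defaults and keeps them pluggable:

* **Volume**: $|\det(B-A, C-A, D-A)|/6$, cross-checked against a
  Cayley–Menger evaluation in the tests.
* **Tetrahedrality**: the standard edge-length-variance measure
  $\sum_{i<j}(l_i - l_j)^2 / (15\,\bar l^2)$, zero exactly for a regular
  tetrahedron.
* **Depth**: *surface* positions are convex-hull vertices of the point
  set; *undersurface* positions share a retained edge with a surface
  position; the rest are *buried*. The surface-contact count is the
  number of retained edges to surface positions.

## Numerical choices

The tessellation is computed by direct empty-circumsphere enumeration
over 4-cliques of the ≤ cutoff distance graph — exact to the Delaunay
definition and comfortably fast at the problem sizes this method targets
(tens to hundreds of residues; the edge filter is applied per whole
tetrahedron, since a tetrahedron missing an edge is not scoreable as a
quadruplet). Cosphericality is judged by the distance of a point to a
candidate circumsphere *surface*, relative to the bounding-box diagonal
(default $10^{-9}$); judging it relative to the circumradius would let
near-coplanar quadruples with enormous circumspheres raise phantom ties.
Exact ties (e.g., grid or shell geometries) trigger a deterministic,
seeded joggle of at most $10^{-6}$ of the bounding-box diagonal per
round, recorded on the returned object. Convex-hull vertices are found by
brute-force supporting-plane enumeration. Deterministic tie-breaks are
used throughout: nearest-neighbor ordering breaks distance ties by lower
flat index, classifier probability ties at exactly 0.5 predict
"affected" (the conservative call), and zero RES/CMP values are assigned
to the positive quadrant half-planes.

# Variant feature vectors

The 27-attribute encoding describes a mutated position and its six
closest structural neighbors (by C-alpha distance among retained-edge
neighbors): position number; native and replacement residue; EP at the
mutated position; six signed primary-sequence separations
(neighbor − mutated author number); six neighbor identities; six neighbor
EPs; mean volume and mean tetrahedrality of the tetrahedra at the mutated
vertex; depth class and surface-contact count; and secondary structure
(three-state, parsed from PDB HELIX/SHEET records by default, pluggable).
Positions with fewer than six retained-edge neighbors cannot fill the
vector and their variants are dropped with an exclusion manifest — the
dimeric profile encodings (below) can represent them.

For homodimers, each variant yields two 27-attribute rows (one per chain
copy, same output attribute). Alternatively the full residual profile is
used directly: the dimeric EP vector splits into one per-chain vector of
chain length (89 for an 89-residue chain), optionally extended with three
variant-ID attributes (wild-type residue, position, replacement).
Categorical attributes are emitted as factor labels; any one-hot
expansion is a model-side transform.

Activity outputs use the log2(effect size) conventions: Superior (> 0),
Similar ([−2, 0]), Inferior (< −2) three-way, and unaffected (≥ −2)
versus affected (< −2) binary, the −2.0 boundary belonging to
unaffected.

# Models and evaluation

Learners are implemented by contract on standard R fits: random forest
(100 trees), RBF-kernel SVM with logistic probability calibration,
decision tree (optionally bagged), one-hidden-layer neural network, a
reduced-error-pruned regression tree (grown loose, pruned at the
cross-validated complexity minimum), and RBF-kernel support vector
regression. Exact reproduction of any particular toolkit's internals is
a non-goal; hyperparameters are exposed on `learnerSpec()`.

Evaluation is leave-one-out or stratified 10-fold cross-validation;
every row is predicted exactly once, and the same seed always yields the
same folds and predictions. Metrics: sensitivity, specificity, precision,
balanced accuracy BAR $= 0.5(\mathrm{Se} + \mathrm{Sp})$, Matthews
correlation, and AUC via the rank (Mann–Whitney) statistic with ties
averaged; the positive class is "affected". Regression models report
Pearson $r$ and are additionally thresholded at −2.0 to yield the same
classification metrics. A combined classifier averages the per-class
probabilities of several classifiers. Label-permutation controls shuffle
the output attribute among rows (inputs untouched), re-run the
cross-validation per shuffle, and report the null mean ± sd with the
empirical $p$-value; learning curves aggregate repeated stratified
subsamples per training-set size.

# The synthetic study system

Because every stage must be exercisable without downloads, the package
generates its own study systems. `syntheticStructure()` grows a
self-avoiding random walk with a fixed 3.8 Å step, biased toward a sphere
of radius $\propto n^{1/3}$ at typical protein C-alpha density
(~120 Å³/residue), with a 3.4 Å hard core — enough geometric realism to
give protein-like tessellation topology. Homodimers place a second,
independently sampled conformation of the same sequence at a 5.5 Å
interface gap (crystallographic chains are never exactly congruent, and
an exactly symmetric dimer would make the two per-chain feature vectors
of every variant identical); an exact C2 copy is available as an option.
Coordinates are rounded to PDB precision (0.001 Å).

`syntheticStudy()` wires the whole pipeline: six 110-residue training
globules are tessellated to derive a pseudocount-1 potential (at this
training scale most of the 8,855 keys are unobserved, and the
computational mutagenesis must be able to score arbitrary replacements);
the study structure is an 89-residue-per-chain homodimer; 250 variants
are drawn; and activities are generated as
$\log_2(\text{effect}) = \text{slope} \times \text{residual} +
\mathcal N(0, \sigma)$. The slope is calibrated once so the 40th
percentile of the noise-free activities sits at −2, giving roughly a
40/60 affected/unaffected balance — the synthetic residual distribution
is roughly symmetric about zero, so a pure linear coupling cannot push a
majority of variants below the threshold the way a
destabilisation-dominated experimental panel does — and the slope is
negative because disruption is positive under the $-\log$ convention.
The noise defaults to half the standard deviation of the noise-free
activities, keeping the structural signal dominant but visibly degraded.
All problem sizes above are the package's chosen study conditions; tests
and the acceptance script use them as-is.

What the fixtures do *not* emulate: folded secondary-structure geometry,
side chains, residue-type-dependent packing, or any physicochemical
correlation between sequence and conformation. Passing tests therefore
demonstrate that the tessellation topology, the scoring algebra, the
feature plumbing and the learning protocol behave correctly and that the
models recover a planted structure–function coupling against a clean
permutation null — not that the pipeline attains any particular accuracy
on real proteins.

# Known limitations

* Mutations never move coordinates; conformational relaxation,
  side-chain repacking and physical-unit ΔΔG are out of scope, as is
  direct modelling of bound DNA in a residue-level C-alpha
  representation.
* The tessellation and hull routines are exact but brute-force; they are
  sized for single domains and small multimers, not for thousands of
  residues.
* Depth and tetrahedrality definitions are documented defaults for
  quantities the method names but does not define; both are pluggable.
* Scores depend on the training set's composition and scale of counts;
  potentials derived from small synthetic training sets are
  pseudocount-dominated and only exercise the machinery.
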