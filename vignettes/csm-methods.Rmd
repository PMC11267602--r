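---
title: "Continuous symmetry measures: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous symmetry measures: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmeasure)
```

## The model

A continuous symmetry measure asks: how much would a structure have to be
deformed to become exactly symmetric under a chosen point group?  For
coordinates $P_1 \dots P_N$ (centered at the origin) and a cyclic group $G$
of order $h$ generated by the operation $G(m)$ about a unit axis $m$,

$$ S(G) \;=\; 100\,\min_{m,\sigma}
   \frac{\sum_i \lVert P_i - Q_i\rVert^2}{\sum_i \lVert P_i\rVert^2},
   \qquad
   Q_i = \frac1h \sum_{k=0}^{h-1} G(m)^{-k}\, P_{\sigma^k(i)} . $$

$Q$ is the orthogonal projection of the coordinate vector onto the
$G$-symmetric subspace determined by $(m, \sigma)$, so it is the nearest
symmetric structure for that choice, exactly invariant under the group:
$Q_{\sigma(i)} = G(m)\,Q_i$.  The scale is dimensionless: 0 is perfect
symmetry and 100 corresponds to the nearest symmetric structure collapsing
to the origin, the maximal-distortion reference.  The continuous chirality
measure is $\min S(S_n)$ over the achiral cyclic groups
$S_1 (= C_s), S_2 (= C_i), S_4, S_6, \dots$ up to a cutoff `sn_max`.

A permutation $\sigma$ is *admissible* when its cycle lengths divide $h$
(so the $h$-fold averaging closes), when it maps each equivalence class of
atoms into itself, and — under `keep_structure` — when it is an automorphism
of the bond graph.  Equivalence classes are per-element by default, a single
class under `ignore_sym` (a pure shape descriptor), or the
(residue ordinal, residue type, atom name, element) key for proteins.

Cs and Ci are represented internally as the rotoreflection groups S1 and S2,
so one improper-generator code path serves Cs, Ci and Sn.

## Axis optimisation

For a fixed admissible permutation, substituting the Rodrigues expansion of
each group element turns the objective into
$f(m) = c + m^\top B m + w^\top m$ on the unit sphere, with $B$ a symmetric
3×3 matrix and $w$ a 3-vector accumulated over group powers
$k = 1 \dots h-1$.  The maximiser satisfies $(B - \lambda I)m = -w/2$ with
$\lambda$ at or above the top eigenvalue of $B$; `csmeasure` solves the
secular equation $\lVert (B-\lambda I)^{-1} w/2 \rVert = 1$ by bracketed
root finding in the eigenbasis (the root lies in
$(d_1,\, d_1 + \lVert w\rVert/2]$), with the degenerate "hard case"
($w$ orthogonal to the top eigenspace) handled explicitly.  For Ci the
operation is $-I$ and no axis exists; the reported axis is a convention.
The test suite cross-checks this analytic optimum against an independent
dense Fibonacci-grid search polished by Nelder–Mead; agreement is required
to $10^{-6}$ and observed near machine precision.

Two numerical conventions follow from degeneracies of $f$: when
$f(m) = f(-m)$ (all groups with $h \le 2$, and any case with a negligible
linear term) the reported axis is normalised so its first non-negligible
component is positive; ties among equal-valued permutations are broken by
the first one found in the documented enumeration order (classes ascending,
cycles built lexicographically).  Values are clamped to $[0, 100]$ against
roundoff; the reported value is always recomputed from the symmetrised
structure, so results are internally consistent to $10^{-10}$ by
construction.

## Search strategies

**Exact.**  Admissible permutations are enumerated class by class, cycle by
cycle, each cycle anchored at its smallest member so every permutation
appears exactly once.  Under `keep_structure`, a partial cycle is abandoned
as soon as any already-assigned bonded pair maps onto a non-bonded pair;
this pruning is what keeps the structure-preserving search tractable for
larger molecules.  A wall-clock budget (default 300 s) aborts hopeless
searches with a count of permutations examined.

**Approximate.**  The direction–permutation loop: from each start axis
(the Cartesian triple by default, a Fibonacci-sphere lattice of $n$ vectors
with `fibonacci`), atoms rotated by the generator are matched to the
original atoms within each equivalence class — minimum-cost assignment by an
in-package $O(n^3)$ Hungarian solver, or the cheapest-pair-first greedy
scheme, or a bond-consistency-prioritised greedy (`structure_priority`) —
and the axis is then re-optimised analytically for the resulting
permutation.  Raw assignments can contain cycles whose length does not
divide $h$; such cycles are collapsed to fixed points, a conservative repair
that never produces an inadmissible permutation.  An iteration that fails to
improve terminates the loop, so accepted values are non-increasing and the
best visited result is returned.  For $C_n$ with $n > 2$ both orientations
of every start axis are tried, since the generator and its inverse define
the same group but different assignments.  Defaults: tolerance $10^{-10}$
on the improvement, at most 50 alternations — alternating schemes of this
kind converge in a handful of sweeps in practice.  The approximate value is
an upper bound on the exact one; the suite asserts this on every fixture
small enough to enumerate.

**Trivial.**  The identity permutation only — appropriate when the atom
order already encodes the symmetry, and the fast path for user-supplied
permutations (`use_perm`).

**Proteins.**  Homo-oligomers are prepared by dropping non-amino residues,
selecting chains and residue serials, optionally restricting to the
\{N, CA, C, O\} backbone (OXT is excluded because it exists only at termini
and would break per-chain equality), and verifying equal residue signatures
across chains.  Sequence-based equivalence puts one atom per chain in each
class, so fixing a chain permutation (cycle lengths dividing $h$; exhaustive
for up to 8 chains, centroid-Hungarian seeded above that) forces the atom
permutation — the `assignment` and `sequence_dictated` atom modes therefore
coincide by construction, and both labels are accepted.  The trivial protein
mode with `use_chains` keeps the sequence-dictated atom pairing while
searching the chain permutation.

## Centering

The centroid is translated to the origin before any measure is computed.
The default weighting is uniform (geometric centroid), because the measure
is a pure geometric descriptor; a mass-weighted option (`weights = "mass"`)
is provided for workflows that prefer the center of mass.  For the closed-
form two-atom inversion check the low-level `csm_geometry()` constructor
accepts coordinates as given, without centering — translating that pair's
midpoint to the origin makes it exactly centrosymmetric, which is itself a
documented behaviour of the pipeline.

## File formats and connectivity

xyz, PDB (via bio3d, plus in-package CONECT handling), MDL MOL/SDF V2000
(read via ChemmineR; written by an in-package V2000 writer that is
round-trip-tested against the ChemmineR reader) and a small self-describing
`csm` dialect: atom count, `element x y z` lines, then one adjacency line
per atom (`i j k ...`, 1-based), the same layout as the external
connectivity file.  The permutation file is one line of space-separated
1-based images.  These three plain-text dialects are this package's own
definitions and are documented here rather than inherited from elsewhere.
Element sequence and bonds round-trip exactly in all formats; coordinates
round-trip to $10^{-6}$ Å in xyz/csm, while PDB and V2000 are limited to
their fixed-width 3- and 4-decimal columns by format definition.

Connectivity, when absent, is inferred by the covalent-radius rule: a bond
exists when the interatomic distance is at most `tolerance_factor` times the
sum of covalent radii (Cordero values; 0.77 Å fallback for unknown symbols,
with a warning).  The default factor 1.15 is the common perception
heuristic; it reproduces textbook connectivity for ordinary organic
geometries but, like any distance rule, can over- or under-perceive bonds in
strained or metal-containing systems — supply a connectivity file in those
cases.  PDB reading rejects alternate locations other than blank/"A" and
deliberately performs no cleaning (no gap repair, occupancy or insertion-
code handling): structures should be pre-cleaned, as is standard for
symmetry analysis of oligomers.

## The synthetic-geometry generator

`make_symmetric()` closes seeded random orbits under the group generator
(about z by default, optionally re-oriented randomly), keeping seed points
away from the symmetry element so orbits have full size; `perturb()` adds
seeded i.i.d. Gaussian displacements; `make_homomer()` replicates one seeded
random five-atoms-per-residue chain by the group rotation into chains
A, B, C, … .  All randomness is seed-parameterised and the global RNG state
is restored, so fixtures are bit-reproducible.  These fixtures emulate the
*geometry* of near-symmetric molecules — exact orbits, controlled isotropic
noise, equal-length oligomer chains — and deliberately not their chemistry:
there is no force field, no realistic bond-length distribution, no sequence
variation, no crystallographic disorder.  Passing tests therefore
demonstrate the correctness of the mathematics and the search (zeros where
symmetry is exact, oracle-equality of minima, invariances), not robustness
to the pathologies of real experimental files, which is delegated to
upstream cleaning tools.

## Validation problem sizes

The suite checks the exact search against a brute-force oracle — all $N!$
permutations filtered for admissibility, axis minima from a dense Fibonacci
grid with Nelder–Mead polish of the group-averaged functional — on 200
seeded random molecules of 4–7 atoms across C2, C3, C4, Cs, Ci, S4 and S6;
agreement is required within $10^{-6}$ and observed at the $10^{-13}$
level.  Approximate-vs-exact bound ordering uses 40 of the same fixtures;
trivial zeros cover Cs, Ci, C2–C6, S4, S6 and S8 with one or two orbits per
group.  These sizes keep the whole suite at about a minute while exercising
every admissibility regime (fixed points, transpositions, long cycles,
multiple classes).

## Known limitations

Only cyclic groups are supported (Cs, Ci, Cn, Sn); distortion with respect
to a multi-element group such as $C_{nv}$ is analysed per cyclic subgroup
with a user-supplied permutation, as is conventional.  The approximate
search is a local alternation and can miss the global optimum when started
far from the true axis — more Fibonacci directions trade time for
reliability.  The measure itself is a global descriptor: it does not
localise which atoms carry the distortion (inspect
$\lVert P_i - Q_i \rVert$ per atom for that).  Exact search cost grows
combinatorially with class size; `remove_hy`, `select_atoms` and
`keep_structure` are the intended mitigations.
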