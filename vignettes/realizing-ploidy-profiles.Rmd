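---
title: "Realizing ploidy profiles as phylogenetic networks with beads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Realizing ploidy profiles as phylogenetic networks with beads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidynet)
```

## The problem

Polyploid species carry more than two copies of their chromosome set,
acquired either by whole-genome duplication (autopolyploidy) or by
hybridization with a related species (allopolyploidy). Reconstruction
pipelines for polyploid groups usually start from a multiple-labelled gene
tree, which is often not available. This package asks how much reticulate
history can be recovered from the *ploidy levels alone*: a **ploidy
profile** `m = (m1, ..., mn)` assigns each taxon its ploidy level, kept in
descending order.

A rooted phylogenetic network **realizes** `m` when the number of directed
root-to-leaf paths to taxon `i` equals `m_i`. Autopolyploidy appears as a
**bead** (a pair of parallel arcs into a reticulation vertex, doubling the
path count), allopolyploidy as an ordinary reticulation vertex (indegree 2,
outdegree 1, summing the path counts of its parents). Networks here may
contain beads, and the single labelled vertex is admitted as the degenerate
network on one taxon — it realizes the profile `(1)`.

## The construction in outline

1. **Simplification sequence.** With `alpha = m1 - m2`, one of three cases
   shrinks the profile: `alpha = 0` deletes the duplicate first component
   (`REMOVE_EQUAL`); `alpha > m2` replaces the first component by `alpha`
   (`SUBTRACT`); `0 < alpha <= m2` deletes the first component and inserts
   `alpha`, under a fresh internal taxon label, directly after the last
   occurrence of the value `alpha` (`REMOVE_INSERT`). The component sum
   strictly decreases, so the iteration terminates in a *simple* profile
   `(m, 1, ..., 1)` — the terminal element. The all-ones profile collapses
   to `(1)`, which is not simple under the definition (it needs `m1 >= 2`);
   we treat `(1)` as an additional degenerate terminal realized by the
   single-vertex network. When `alpha` does not already occur, "after the
   last occurrence" is vacuous and we insert at the unique position that
   preserves descending order. Fresh labels live in a reserved `_s<k>`
   namespace that cannot collide with user taxa.

2. **Core network.** Any realization of the terminal element will do; two
   are built. `naive_core()` is a path with chords, each chord adding one
   path. `build_B()` is the beaded core driven by the **binary
   representation** `(i1, ..., ik)` of the largest component (decreasing
   exponents of its powers-of-two decomposition, e.g. `77 -> (6,3,2,0)`): a
   chain of `i1` beads realizes `2^i1`; for `k >= 2` a subdivision vertex
   `s_k` on one root arc feeds, through a chain `s_2, ..., s_{k-1}`, one
   subdivision vertex `s_j'` per lower exponent, placed on the outgoing arc
   of the bead reticulation with exactly `i_j` bead reticulations below it,
   so that arc `(s_j, s_j')` contributes `2^{i_j}` paths. Unit-ploidy taxa
   are attached as a caterpillar tree at a vertex `w` carrying one path.
   Where the existence argument allows a choice (which root arc to
   subdivide; `w`'s arc for `k = 1`), we fix it deterministically so that
   serializations are reproducible. Note that subdividing a root arc turns
   the first bead into an ordinary reticulation; bead counts reported by
   `reticulation_inventory()` reflect that.

3. **Traceback.** Walking the simplification sequence backwards grows the
   realization `N(m)`: `REMOVE_EQUAL` turns the top leaf back into a
   cherry; `SUBTRACT` and `REMOVE_INSERT` grow a reticulate cherry whose
   reticulation arc re-adds the subtracted paths; `REMOVE_INSERT`
   additionally deletes the leaf carrying the inserted component. The
   construction's deletion of that leaf's incoming arc is implemented as
   deleting the arc from the freshly inserted subdivision vertex (the only
   reading that leaves a valid network) and suppressing the residual
   degree-(1,1) vertex. `realize_profile()` checks the path counts of its
   output and records whether the minimality conditions of the
   construction hold (beaded core, no `SUBTRACT` step), exposed as the
   attribute `minimal_by_construction` — reported, not asserted, beyond the
   tested fixtures.

## Time stamps and horizontal arcs

A time-stamp map is **HGT-consistent** when (P1) stamps never decrease
along arcs and increase strictly into non-reticulations, (P2) every
non-leaf vertex has a strictly later child, and (P3) every reticulation
*outside a bead* has exactly one parent with an equal stamp — a
**horizontal arc**, two ancestral species that co-existed. The **weak**
variant (P3') exempts at most one reticulation, which must have distinct,
comparable parents. `verify_labelling()` is the sole authority; both
constructors are checked against it in the tests.

`label_core()` implements the constructive labelling: unit increments along
the spine, `t(s_k) = t(h_1)`, `t(s_j) = t(s_j')`, `t(w) = t(s_k')`,
caterpillar leaves at a common late time. Two choices deserve note:

* For a simple non-strictly-simple profile whose largest component is a
  power of two (`k = 1`), `w` subdivides a root arc and the first bead's
  reticulation `h_1` becomes an ordinary reticulation. Plain unit stamps
  would violate (P3) at `h_1`; we set `t(w) = t(h_1)`, the analogue of the
  `t(s_k) = t(h_1)` identification, and the verifier then confirms strict
  consistency. This is the package's reading of a corner the existence
  argument passes over.
* Stamps are dyadic rationals stored in doubles: every inserted value is a
  midpoint (or quarter point) of existing values, so all arithmetic — and
  in particular every equality test in (P3) — is exact in IEEE arithmetic.
  The "sufficiently small epsilon" of the existence argument is realized
  as half of the relevant gap.

The outcome, verified property-style in the tests, is: the core of a
**practical** profile (simple non-strictly-simple, or a single power of
two) labels strictly; the core of an **arc-rich** profile (strictly simple,
`k >= 2`) labels weakly, with `s_k'` the single exempt reticulation.

## Cherry modification sequences and orchards

Four leaf operations reverse the growth steps: `reduce(a,b)` deletes leaf
`b` of a cherry; `cut(a,b)` deletes the reticulation arc of a reticulated
cherry; `simp(a)` deletes one arc of the bead above `a`; `trim(a)` deletes
the prescribed arc above `a`'s reticulation parent. A network reducible to
a single vertex without `trim` is an **orchard**; allowing `trim` gives a
**weak orchard**.

Two definitional choices, both taken so that the worked examples and the
orchard theorems actually hold:

* The degenerate-cherry operations are applied by their *structural*
  condition (the parent of `a` is a bead reticulation, etc.), not only when
  `a` is the last remaining taxon. Restricting to a single-taxon leaf set
  would leave `B((2^l, 1, ..., 1))` with `l >= 2` irreducible — no
  operation applies once the caterpillar is gone — contradicting the
  orchard property of practical profiles, and it would also rule out the
  canonical `simp(x1)` example on a three-taxon core.
* `trim` is defined for the configuration in which one parent of the
  reticulation above `a` is a bead reticulation (case i: delete the arc
  from the *other* parent) as well as for the two diamond-like
  configurations (cases ii-a, ii-b). Case i is exactly what the canonical
  example on `B((77))` performs.

`traceback_cherry_sequence()` derives a certificate without search: each
simplification step maps to one `reduce`/`cut` on the realization, and the
remaining core is reduced by a deterministic greedy pass (cut, else reduce,
else simp, else trim) under which exactly one operation kind is applicable
at every stage of a beaded core. `orchard_status()` is the independent
check: a backtracking search with an isomorphism-checked memo of failed
states.

`label_from_cherry_sequence()` replays a certificate backwards, assigning
stamps as the network regrows; restored reticulation arcs become
horizontal. A certificate with no trim yields a strict labelling, one trim
a weak labelling. An arc-rich terminal whose binary representation has
`k >= 3` exponents forces `k - 1` trims, and the replayed labelling then
has `k - 1` exempt reticulations — more than weakness admits. This is a
real asymmetry between sequence-derived and constructed labellings, not an
implementation artefact: the constructed labelling makes the arcs
`(s_j, s_j')` horizontal directly, which no leaf-operation sequence
reproduces. The strength guarantee is therefore stated for certificates
with at most one trim.

## Ploidy-profile space

The **split** operation removes a reticulation whose child arc is a
cut-arc and duplicates the subgraph below, conserving label-summed path
counts; repeating it (`unzip_to_multree()`) reaches a multiple-labelled
tree. Splits are applied at the topologically first splittable
reticulation; a lowest reticulation always qualifies, so the loop
terminates. Beads are split like any other reticulation — both copies
attach to the bead's tree vertex — because any alternative (removing the
bead) would halve path counts and break the conservation law that makes
unzipping meaningful. `distance_upper_bound()` composes split counts with
a pluggable multiple-labelled-tree metric; the default refuses
non-isomorphic trees rather than silently standing in for a real edit
distance, and no SPR solver is provided (the problem is NP-hard), so exact
space distances are out of scope.

`is_tree_based()` searches over one deleted incoming arc per reticulation
(pruning assignments that strand an internal vertex) for a spanning
structure whose suppression is a phylogenetic tree — the base tree; it
refuses inputs beyond 24 reticulations. `is_tree_child()` checks the
bead-adjusted tree-child condition by dynamic programming.
`enumerate_realizations()` generates all realizations of profiles on at
most two taxa with at most three reticulations: degree accounting fixes
the vertex roles, stub assignment under capacity/acyclicity/bead
constraints generates candidates, and isomorphism deduplicates. The guards
are hard limits, not tunables.

## Synthetic data and test conditions

Profiles for property tests come from `random_profile(n, max_component,
seed)`: uniform ploidy levels sorted descending. This emulates the *input*
of the method — a vector of observed ploidy levels — and nothing else: real
datasets have phylogenetic correlation among levels, a bias toward even
levels (most empirical profiles are all-even, which is why the doubling
identity via `prepend_bead()` matters), and far fewer distinct values.
Passing tests therefore certify the combinatorial machinery, not any
statistical behaviour on real data.

Problem sizes used by the test suite, chosen to exercise every case while
keeping a full run in a few minutes of a single CPU: realization
correctness on 500 profiles with up to 8 taxa and levels up to 200;
labelling classification on 200 simple profiles with largest component up
to 256; certificate and tree-based suites on profiles with practical
terminals drawn with up to 6 taxa and levels up to 30; conservation of
path counts under unzipping on 200 realizations with levels up to 20;
brute-force path-count cross-checks on every fixture with at most 14
vertices. The exhaustive searches for the profile `(3)` run the full
enumerator.

## Known limitations

* Deciding whether an *arbitrary* network admits an HGT-consistent
  labelling is not implemented; labellings come from the two constructors
  or the user, and only verification is general.
* The orchard search is exponential in the worst case; it is intended for
  the construction-sized networks of this package.
* Reticulation-minimality is reported via the known sufficient condition,
  not certified by search.
* eNewick has no canonical bead encoding across tools; this package writes
  a bead as the same hybrid tag appearing twice under one parent, and its
  writer is deterministic per object rather than canonical per isomorphism
  class.
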