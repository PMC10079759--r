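# ploidynet

Reconstructing reticulate evolutionary history from ploidy levels alone.

Polyploidization — whole-genome duplication (autopolyploidy) or genome
acquisition through hybridization (allopolyploidy) — leaves a signal that
trees cannot express. The usual route to a phylogenetic network for a
polyploid group goes through a multiple-labelled gene tree, which is often
unavailable. `ploidynet` starts instead from a **ploidy profile**: a vector
`m = (m1, ..., mn)`, in descending order, giving each taxon its ploidy
level. A rooted phylogenetic network *N* (directed, acyclic, single root of
outdegree 2, possibly containing *beads* — pairs of parallel arcs modelling
whole-genome duplication) **realizes** `m` if the number of directed paths
from the root of *N* to the leaf labelled `x_i` is exactly `m_i`.

The package constructs such realizations and analyses them:

* the **simplification sequence** `sigma(m)`: with `alpha = m1 - m2`,
  repeatedly remove a duplicate top component (`alpha = 0`), replace the
  top by `alpha` (`alpha > m2`), or remove-and-reinsert `alpha`
  (`0 < alpha <= m2`), until a *simple* profile `(m, 1, ..., 1)` remains;
* **core networks** for the terminal: a naive path-with-chords, and the
  beaded core `B(m)` built from the binary representation
  `m = 2^{i1} + ... + 2^{ik}` (a chain of `i1` beads plus one extra arc per
  lower exponent);
* the **traceback** `N(m)`, growing a cherry or reticulate cherry per
  simplification step, plus bead prepending (`prepend_bead`) and the
  power-of-two composition (`compose_scaled`);
* **HGT-consistent time labellings** (strict and weak), their verifier and
  constructors — the horizontal arcs they induce join ancestral species
  that co-existed in time;
* **cherry modification sequences** (reduce / cut / simp / trim), orchard
  and weak-orchard certificates, tree-based and tree-child analysis;
* **ploidy-profile space** operations: the split operation, unzipping to a
  multiple-labelled tree, a distance upper-bound scaffold, and a bounded
  exhaustive enumerator of realizations;
* I/O in extended Newick (beads encoded as a repeated hybrid tag under one
  parent), a JSON graph format, and DOT (equal time stamps rendered on one
  rank, so horizontal arcs draw horizontally).

## Worked example

```r
library(ploidynet)

p <- ploidy_profile(c(7, 6, 6, 5))
simplification_sequence(p)
#> simplification sequence, 4 profiles:
#>   (7,6,6,5)
#>   (6,6,5,1)
#>   (6,5,1)
#>   (5,1,1)
```

The terminal element `(5,1,1)` is *practical*, so its beaded core admits a
strict HGT-consistent labelling. The traceback then realizes the profile:

```r
N <- realize_profile(p)
count_paths(N)
#> x1 x2 x3 x4
#>  7  6  6  5
reticulation_inventory(N)
#>   vertex in_bead
#> 1     h1   FALSE
#> 2     h2    TRUE
#> 3    s2p   FALSE
#> 4    u15   FALSE
#> 5    u19   FALSE
```

Five reticulation vertices: one bead (an autopolyploidization) and four
ordinary reticulations (allopolyploidizations). The path counts are the
ploidy levels, which is what "realizes" means. The profile is an orchard —
a certificate derived from the simplification sequence, with no search,
reduces the network to a single vertex, and replaying it backwards yields a
strict time labelling in which every non-bead reticulation has exactly one
incoming horizontal arc:

```r
cert <- traceback_cherry_sequence(p)
cert$status
#> [1] "ORCHARD"
sapply(cert$sequence, format)
#> [1] "cut(x2,x1)"    "reduce(x3,x2)" "cut(x4,x3)"    "reduce(x1,x3)"
#> [5] "cut(x1,x4)"    "simp(x4)"      "cut(x1,x4)"    "reduce(x1,x4)"
t <- label_from_cherry_sequence(N, cert$sequence)
verify_labelling(N, t)$classification
#> [1] "HGT_CONSISTENT"
nrow(horizontal_arcs(N, t))
#> [1] 4
```

For an all-even profile such as the ten-taxon Viola profile
`(18,14,14,10,8,8,8,4,4,2)`, `realize_profile` handles it directly;
equivalently, realize the halved profile and prepend a bead
(`prepend_bead(realize_profile(halve_profile(p)))`). The Viola realization
uses five reticulation vertices outside beads.

A command-line driver wraps the same functions:

```sh
Rscript exec/ploidynet realize --profile 7,6,6,5 --format enewick
Rscript exec/ploidynet orchard --network net.enwk
Rscript exec/ploidynet enumerate --profile 3 --max-ret 2
```

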