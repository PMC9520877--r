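# tucan

Canonical tuple-style identifiers (TUCAN format) for molecules across the
whole periodic table — hydrogen to oganesson — in R.

Classical line notations (SMILES, InChI) encode Lewis-structure concepts:
bond orders, standard valences, implicit hydrogens. Those concepts break
down for organometallic and coordination compounds, clusters, and anything
with delocalized or multi-centric bonding. This package implements an
identifier that does not use them. A molecule is an undirected labeled
graph: atoms are nodes carrying an element symbol plus optional formal
charge (`CHG`), isotope mass (`MASS`) and radical (`RAD`) fields; whatever
the input molfile declares as a bond is an edge, bond types discarded;
hydrogens are explicit atoms. Beyond the atomic number, canonicalization
uses topology alone, so ferrocene, Zeise's salt, diborane and a benzene
ring are all handled by the same machinery — as are non-chemical graphs.

The serialized identifier has up to three `/`-separated blocks:

```
HillFormula / (a-b)(a-b)... / (label:FIELD=VALUE,...)...
```

Atom labels ascend with atomic number (hydrogens first), so the formula
makes labels self-describing and the string can be parsed back into the
molecular graph: the identifier is also a descriptor.

The canonical form is defined as the lexicographically smallest serialized
string over all labelings that respect element grouping — a definition any
correct implementation must reproduce, checked in the tests against an
independent brute-force enumeration. The minimum is found exactly via
invariant codes, iterative Weisfeiler–Lehman (Morgan) partition refinement,
and a branch-and-bound search with twin, automorphism-orbit and
optimistic-bound pruning (C++ core via Rcpp).

## Worked example

Methanol (CH3OH, explicit hydrogens — 6 atoms, 5 bonds):

```r
library(tucan)

tucan_serialize(tucan_graph_fixture("methanol"))
#> [1] "CH4O/(1-5)(2-5)(3-5)(4-6)(5-6)"
```

Reading the string: the Hill formula `CH4O` expands by ascending atomic
number, so labels 1–4 are H, label 5 is C, label 6 is O. Tuples `(1-5)`,
`(2-5)`, `(3-5)` are the three C–H bonds, `(4-6)` the O–H bond, `(5-6)` the
C–O bond. Deserialization rebuilds the graph:

```r
g <- tucan_deserialize("CH4O/(1-5)(2-5)(3-5)(4-6)(5-6)")
g
#> <molecular graph: 6 nodes, 5 edges, formula CH4O>
```

The format's reference worked example, the Zeise's salt anion
[PtCl3(C2H4)]−, shows the feature block (note the platinum's explicit
`RAD=0` carried through from the molfile):

```r
molfile_to_tucan(tucan_fixture_molfile("zeise"))
#> [1] "C2H4Cl3Pt/(1-5)(2-5)(3-6)(4-6)(5-6)(5-10)(6-10)(7-10)(8-10)(9-10)/(7:CHG=-1)(8:CHG=-1)(9:CHG=-1)(10:CHG=2,MASS=196,RAD=0)"
```

Canonicality is validated by the shuffle (permutation) test — permute the
atom input order, demand one unique string:

```r
shuffle_test(tucan_fixture("methanol"), permutations = 100, seed = 7)
#> $pass
#> [1] TRUE
#> $n_unique
#> [1] 1
#> $reference
#> [1] "CH4O/(1-5)(2-5)(3-5)(4-6)(5-6)"
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/tucan.R serialize mymolecule.mol
Rscript inst/cli/tucan.R deserialize "CH4/(1-5)(2-5)(3-5)(4-5)" --molfile out.mol
Rscript inst/cli/tucan.R shuffle-test fixture:petersen --n 100 --seed 3
Rscript inst/cli/tucan.R trace fixture:bicyclooctenone
```

## Scope

No stereochemistry (enantiomers share an identifier), no `*` pseudo-atoms
or multi-center bonds (metal–ligand bonds must be individual edges), no
v2000 molfiles, no implicit-hydrogen completion. See the vignette
(`vignettes/tucan-format.Rmd`) for the model, the exact canonical-form
definition, and the algorithm.
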