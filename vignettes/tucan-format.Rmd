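---
title: "Canonical tuple identifiers for molecules: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical tuple identifiers for molecules: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tucan)
```

## The problem

Line notations such as SMILES and InChI lean on Lewis-structure concepts —
bond orders, standard valences, aromaticity, implicit hydrogens — that work
well for organic molecules and poorly for much of inorganic and
organometallic chemistry, where bonding is delocalized, multi-centric, or
simply not expressible as integer bond orders. The TUCAN format sidesteps
the whole issue: a molecule is an undirected labeled graph whose nodes carry
nothing but an element (atomic number) and optional charge / isotope /
radical fields, and whose edges carry nothing at all. Whatever the user
declares as a bond in the input molfile becomes an edge; bond types are
discarded. Hydrogens must be explicit nodes, which removes the
standard-valence guesswork entirely. The price is that the format applies
uniformly from H to Og — to ferrocene and Zeise's salt as readily as to
benzene — and even to non-chemical graphs.

An identifier for such graphs must be **canonical** (the same string for
every atom input order), **bijective** at the level of the retained
information, and ideally **bidirectional**, so the string doubles as a
descriptor from which the graph can be rebuilt.

## The identifier string

A serialized molecule has up to three `/`-separated blocks (a fourth is
reserved for future custom data):

```
formula / (a-b)(a-b)... / (label:FIELD=VALUE,...)...
```

* **Formula** in Hill order — C first, then H, then the remaining elements
  alphabetically; with no carbon present, everything alphabetical. Counts
  of one omit the digit. This block is mandatory and suffices on its own for
  monoatomic or fully disconnected species.
* **Edge tuples** `(a-b)` with `a < b`, the list sorted by `(a, b)`; each
  edge appears once.
* **Node features** `(label:FIELD=VALUE,...)`, fields limited to `CHG`,
  `MASS`, `RAD`, sorted by field name within an entry and by label across
  entries. A field present in the input with its default value (Zeise's
  platinum carries `RAD=0`) is carried through, never invented or dropped.

Output labels are **not** in Hill order: atoms are numbered by ascending
atomic number, so hydrogens always occupy the lowest labels. Combined with
the formula this makes labels self-describing — in
`C2H4Cl3Pt/...`, labels 1–4 are H, 5–6 C, 7–9 Cl, 10 Pt — which is what
makes deserialization possible without any further annotation.

```{r zeise}
tucan_serialize(tucan_graph_fixture("zeise"))
```

## What "canonical" means here

The package defines the canonical form as the **lexicographically smallest
serialized identifier over all labelings that respect element grouping**.
The comparison key is the flattened edge-tuple stream first, then the
feature stream (as numeric `(label, fields)` pairs). This choice has three
consequences we consider worth their cost:

* It is a *definition*, not an artifact of a particular search strategy.
  Any correct implementation — including an independent brute-force
  enumeration — must produce the identical string, which makes the
  identifier machine-checkable and keeps the canonicalization stage
  swappable.
* Permutation invariance is automatic: a global minimum does not depend on
  input order.
* It fixes behavior in corner cases that partition-based labeling leaves
  ambiguous, e.g. which of two chemically different oxygens gets the lower
  label in formic acid, or that diborane's bridging hydrogens precede the
  terminal ones (the minimum continues row 1 with `(1-7)(1-8)` rather than
  moving on to `(2-7)`).

`brute_force_canonical()` implements the definition literally — enumerate
all labelings within element classes, keep the smallest string — and is the
independent oracle in the test suite for every fixture with at most 8
atoms, a cap chosen because class-respecting enumeration stays below 8!
evaluations there.

## How the minimum is found

`canonical_labeling()` computes the minimum exactly by branch and bound,
written in C++ (via Rcpp) as canonical-labeling inner loops are throughout
this field's tooling:

1. **Invariant codes and Weisfeiler–Lehman refinement.** Each node's code
   is its atomic number followed by the decreasing multiset of neighbor
   atomic numbers; nodes with equal codes share a cell
   (`assign_invariant_codes()`, `initial_partition()`).
   `refine_partitions()` then iterates the 1-dimensional Weisfeiler–Lehman
   (Morgan) step — split every cell by the multiset of neighbor cells —
   until stable. Cells are numbered by sorted content in the C locale, so
   partition indices are input-order independent. The atomic number is the
   only chemistry-specific invariant anywhere in the pipeline; the charge,
   isotope and radical fields deliberately do not participate (they affect
   only the serialized feature block and tie-breaking among otherwise
   identical labelings).
2. **Branch and bound over label assignments.** Element blocks are assigned
   from the heaviest element down, labels ascending within a block. At each
   step an admissible optimistic bound on the leading tuple stream is
   compared against the incumbent: exact tuples for assigned atoms,
   smallest-free-label fills for unassigned neighbors.
3. **Hydrogen deferral.** A block whose members bond only to heavier
   elements (in practice, hydrogens without H–H bonds) is never branched
   over: its labels appear in no other row of the stream, so once the heavy
   scaffold is placed the optimal internal order is forced — sort the rows,
   ties resolved feature-bearing atoms first. For such blocks the bound
   also knows distinct unassigned parents must occupy distinct labels,
   which is what keeps fused-ring and sandwich-complex searches small.
4. **Symmetry pruning.** Two candidates interchangeable by a transposition
   (identical neighborhoods outside the pair, identical features) or by a
   pendant-matching swap (NH3, CO and similar terminal ligands) generate
   mirror-image subtrees; only one is explored. Whenever two complete
   labelings serialize identically, the permutation relating them is an
   automorphism of the graph; stored generators prune candidates lying in
   the orbit of an explored sibling and trigger backjumping when they prove
   an ancestor choice redundant. All prunings are exact — they never change
   the minimum, only the work to find it.

The WL partition also orders exploration (most constrained candidates
first), which is purely a performance matter. On one CPU the full fixture
library — 84 molecules and symmetric graphs up to 26 atoms — canonicalizes
in well under a second total; the 100-permutation shuffle protocol over the
whole library runs in about half a minute.

## Input handling

`parse_molfile_v3000()` reads the minimal subset of a v3000 connection
table the format consumes: the `COUNTS` line, element symbol plus optional
`CHG`/`MASS`/`RAD` per atom, and the two atom indices per bond. Everything
else — coordinates, bond types, other blocks — is discarded. Line
continuations (`-`) and variable whitespace are tolerated. The file is
otherwise trusted: no valence or chemical validation is attempted, but
structural errors are fatal and explicit: element symbols outside H–Og
(case-sensitive), the `*` pseudo-atom (multi-center attachment is not
supported; metal–ligand bonds must be individual edges), count/record
mismatches, out-of-range bond indices, self-bonds and duplicate bonds.
Disconnected inputs are legal — the formula-only string covers species
whose atoms share no bonds. Implicit hydrogens are never added; a molecule
drawn without explicit H simply gets the identifier of its heavy-atom core.

`write_molfile_v3000()` emits the reconstruction: zeroed coordinates, all
bonds type 1, feature fields only where present. Parsing a written file
reproduces the graph exactly, and a reconstructed molfile re-serializes to
the identical string.

## The fixture library and what passing means

`tucan_fixture()` generates 69 molecules (organic, main-group/cluster,
coordination/organometallic — all with explicit hydrogens where chemistry
requires them, plus charged, isotopic, radical and disconnected species)
and 15 deliberately difficult element-uniform graphs: hypercubes, circulant
graphs, complete and complete-bipartite graphs, prisms, the Petersen graph,
and the Shrikhande / 4×4 rook's graph pair. The last two are cospectral
strongly regular graphs with identical WL partitions; telling them apart is
exactly what the individualization machinery is for, and the suite asserts
their strings differ. Difficult graphs are emitted as all-carbon
pseudo-molecules so only topology discriminates.

The validation protocol is the shuffle test (`shuffle_test()`): permute the
atom input order — 100 seeded permutations per fixture — re-canonicalize,
and require a single unique string. Passing it demonstrates permutation
invariance and, together with the brute-force oracle and the round-trip
tests, correctness of the whole pipeline *at fixture scale*. What it does
not show: behavior on structures far larger than the library (proteins,
polymers), on inputs whose chemistry is mis-drawn (the molfile is trusted),
or any notion of stereochemistry.

## Numerical and design choices

* **ASCII normalization.** Typeset en dashes and minus signs in printed
  examples are ASCII `-` here; `RAD = 0` spacing normalizes to `RAD=0`.
  Identifiers must be bit-stable.
* **Feature tie-breaking** among automorphic labelings compares feature
  streams as numeric `(label, field-string)` pairs, not raw bytes, so label
  10 sorts after label 9.
* **Deserialization** accepts any grammatical string, re-canonicalizing on
  round trip; `strict = TRUE` rejects strings whose re-serialization
  differs. A fourth block is preserved verbatim and ignored. Strict
  validation covers tuple ordering, label ranges, duplicate edges, field
  names and field order.
* **Determinism.** The algorithm uses no randomness anywhere; the only seed
  in the package is the shuffle test's permutation stream, which restores
  the caller's RNG state.
* **Degenerate inputs.** Single atoms serialize as their formula;
  edgeless multi-atom species defer every block and finish without search;
  molecules of one element work like any other (the element block is just
  the whole graph).

## Known limitations

* No stereochemistry: enantiomers and diastereomers share an identifier.
* Tautomers differ (explicit H placement differs); hydrogen-pruned inputs
  of the same heavy-atom core coincide.
* The `*` pseudo-atom and multi-center bonds are rejected rather than
  modeled.
* v2000 molfiles are not read.
* Worst-case search cost is exponential: adversarial regular graphs much
  larger than the fixture families (say, large strongly regular graphs)
  would need orbit machinery beyond what desk-scale validation requires.
  Molecule-shaped inputs of a few hundred atoms are unproblematic.
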